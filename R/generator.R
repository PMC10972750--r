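#' Generator configuration for synthetic sternal marrow
#'
#' Builds the configuration object consumed by [simulate_marrow()]. The
#' defaults emulate one 35-um optical slice of a whole-mounted sternum
#' segment: a dense unclassified haematopoietic pool, sinusoid and
#' arteriole capsule networks, megakaryocytes, dispersed multipotent
#' HSPCs (soft-core repulsion, biased toward megakaryocytes and away from
#' arterioles), single-cell committed progenitors (pre CFU-E placed with
#' 60% probability of direct sinusoid contact), erythroid CFU-E strings
#' with budding erythroblast clusters (string sizes 3-23, mean 8; late
#' clusters 19-96, mean 40), CLP-anchored B-cell sites (2 +/- 1 pre-pro B,
#' 3 +/- 2 pro B, 16 +/- 8 pre B within 150 um), neutrophil and mono/DC
#' sites on sinusoids, and stochastic four-colour Confetti labelling of
#' 7.3% of cells.
#'
#' @param ... named overrides of the default fields (nested lists are
#'   replaced wholesale; see the returned object for the structure).
#' @return an object of class `marrow_config`.
#' @export
#' @examples
#' cfg <- marrow_config(pool_count = 5000)
#' cfg$erythroid_sites$n_sites
marrow_config <- function(...) {
  cfg <- list(
    volume = list(extent = c(2400, 1200, 35)),
    pool_count = 60000,
    vessels = list(
      n_sinusoid = 40, n_arteriole = 12,
      sinusoid_radius_um = 10, arteriole_radius_um = 5,
      step_um = 120, n_steps = 5, tortuosity = 0.35, branch_prob = 0.25
    ),
    megakaryocytes = list(count = 40, radius_um = 15),
    hspc = list(
      counts = c("CD41- LT-HSC" = 5, "CD41+ LT-HSC" = 2, "ST-HSC" = 10,
                 "MPP2" = 4, "MPP3" = 8),
      repulsion_um = 100, mk_weight = 1, arteriole_weight = 1,
      bias_scale_um = 150
    ),
    progenitors = list(
      counts = c("MkP" = 12, "pre Meg-E" = 20, "pre CFU-E" = 30),
      sinusoid_contact_prob = c("pre CFU-E" = 0.6),
      vessel_clearance_um = 5, hard_core_um = 15
    ),
    erythroid_sites = list(
      n_sites = 10,
      string_size = list(min = 3, max = 23, mean = 8, sd = 4),
      cluster_size = list(min = 19, max = 96, mean = 40, sd = 12),
      n_buds = 2, bud_size = list(min = 3, max = 12, mean = 6, sd = 2),
      n_reticulocytes = 12, n_rbc = 15,
      bud_offset_um = 20, cluster_offset_um = 25, cluster_spread_um = 7,
      cluster_max_radius_um = 16
    ),
    b_sites = list(
      n_sites = 10,
      stage_counts = list("pre-pro B" = c(mean = 2, sd = 1),
                          "pro B" = c(mean = 3, sd = 2),
                          "pre B" = c(mean = 16, sd = 8)),
      radius_um = 150, min_separation_um = 320,
      stage_gradient = list("pre-pro B" = c(10, 60), "pro B" = c(20, 100),
                            "pre B" = c(30, 150)),
      arteriole_offset_um = 10
    ),
    neutrophil_sites = list(
      n_sites = 8,
      progeny = list("PN" = c(mean = 8, sd = 3, min = 3, max = 20)),
      capture_um = 50
    ),
    monoDC_sites = list(
      n_sites = 6,
      progeny = list("monocyte" = c(mean = 4, sd = 2, min = 1, max = 12),
                     "cDC" = c(mean = 2, sd = 1, min = 0, max = 8)),
      capture_um = 50
    ),
    confetti = list(
      fraction = 0.073,
      weights = c(GFP = 0.25, YFP = 0.25, RFP = 0.25, CFP = 0.25),
      policy = list(string = "oligoclonal", cluster = "monoclonal",
                    b_site = "oligoclonal", myeloid = "oligoclonal")
    ),
    contact_tolerance_um = 0.5,
    seed = 1L
  )
  dots <- list(...)
  for (j in seq_along(dots)) {
    nm <- names(dots)[j]
    val <- dots[[j]]
    if (is.null(nm) || !nzchar(nm)) {
      rlang::abort("all configuration overrides must be named",
                   class = "marrowmap_config_error")
    }
    if (is.list(cfg[[nm]]) && is.list(val)) {
      cfg[[nm]][names(val)] <- val
    } else {
      cfg[[nm]] <- val
    }
  }
  validate_marrow_config(cfg)
  structure(cfg, class = "marrow_config")
}

validate_marrow_config <- function(cfg) {
  if (any(cfg$volume$extent <= 0)) {
    rlang::abort("volume extent must be positive", class = "marrowmap_config_error")
  }
  fr <- cfg$confetti$fraction
  if (fr < 0 || fr > 1) {
    rlang::abort("confetti fraction must be in [0, 1]", class = "marrowmap_config_error")
  }
  if (cfg$erythroid_sites$string_size$min < 3) {
    rlang::abort("string-size minimum must be >= 3", class = "marrowmap_config_error")
  }
  if (cfg$pool_count < 0) {
    rlang::abort("pool_count must be non-negative", class = "marrowmap_config_error")
  }
  cp <- cfg$progenitors$sinusoid_contact_prob
  if (length(cp) && (any(cp < 0) || any(cp > 1))) {
    rlang::abort("sinusoid contact probabilities must be in [0, 1]",
                 class = "marrowmap_config_error")
  }
  invisible(cfg)
}

#' Anatomical presets
#'
#' Named configurations encoding the anatomical endpoints of the modelled
#' conditions. Presets alter production-site counts and compositions only;
#' the analysis window, vessel architecture, pool and labelling stay at
#' the steady-state defaults.
#'
#' * `steady_state`: 2-month-old sternum defaults.
#' * `phlebotomy_d2`: expanded erythropoiesis (more erythroid sites with
#'   larger late-erythroblast clusters), reduced B-site output.
#' * `gcsf_sternum`: reduced numbers and output of all site types.
#' * `gcsf_tibia`: expanded granulopoiesis (doubled neutrophil sites),
#'   other lineages suppressed.
#' * `aged`: site numbers maintained, per-site output reduced (with a
#'   shift of mono/DC output toward dendritic cells).
#'
#' @param name preset name.
#' @return a `marrow_config`.
#' @export
marrow_preset <- function(name = c("steady_state", "phlebotomy_d2", "gcsf_sternum",
                                   "gcsf_tibia", "aged")) {
  name <- match.arg(name)
  cfg <- marrow_config()
  mod <- switch(
    name,
    steady_state = list(),
    phlebotomy_d2 = list(
      erythroid_sites = list(n_sites = 20,
                             cluster_size = list(min = 19, max = 96, mean = 55, sd = 12)),
      b_sites = list(stage_counts = list("pre-pro B" = c(mean = 2, sd = 1),
                                         "pro B" = c(mean = 2, sd = 1),
                                         "pre B" = c(mean = 8, sd = 4)))
    ),
    gcsf_sternum = list(
      erythroid_sites = list(n_sites = 5),
      b_sites = list(n_sites = 5),
      neutrophil_sites = list(n_sites = 2,
                              progeny = list("PN" = c(mean = 4, sd = 2, min = 1, max = 10))),
      monoDC_sites = list(n_sites = 3)
    ),
    gcsf_tibia = list(
      erythroid_sites = list(n_sites = 5),
      b_sites = list(n_sites = 5),
      neutrophil_sites = list(n_sites = 16)
    ),
    aged = list(
      erythroid_sites = list(cluster_size = list(min = 19, max = 96, mean = 30, sd = 8)),
      b_sites = list(stage_counts = list("pre-pro B" = c(mean = 2, sd = 1),
                                         "pro B" = c(mean = 2, sd = 1),
                                         "pre B" = c(mean = 8, sd = 4))),
      neutrophil_sites = list(progeny = list("PN" = c(mean = 5, sd = 2, min = 1, max = 12))),
      monoDC_sites = list(progeny = list("monocyte" = c(mean = 2, sd = 1, min = 0, max = 6),
                                         "cDC" = c(mean = 4, sd = 2, min = 1, max = 10)))
    )
  )
  do.call(marrow_config, mod)
}

# ---- sampling helpers ---------------------------------------------------

# Discretised gamma with given mean/sd, clipped to [min, max].
r_clipped_gamma <- function(n, mean, sd, min, max) {
  shape <- (mean / sd)^2
  scale <- sd^2 / mean
  pmin(pmax(round(rgamma(n, shape = shape, scale = scale)), min), max)
}

# Discretised normal clipped below/above.
r_clipped_norm <- function(n, mean, sd, min = 0, max = Inf) {
  pmin(pmax(round(rnorm(n, mean, sd)), min), max)
}

runif_box <- function(n, volume, margin = 0) {
  margin <- rep(margin, length.out = 3)
  lo <- volume$origin + margin
  hi <- volume$origin + volume$extent - margin
  cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]), runif(n, lo[3], hi[3]))
}

# Mostly-horizontal unit vectors (small z component), n x 3.
runif_dir_flat <- function(n, z_max = 0.15) {
  th <- runif(n, 0, 2 * pi)
  z <- runif(n, -z_max, z_max)
  r <- sqrt(1 - z^2)
  cbind(r * cos(th), r * sin(th), z)
}

make_cells <- function(prefix, type, xyz, catalog = cell_type_catalog()) {
  n <- nrow(xyz)
  if (n == 0) {
    return(tibble::tibble(id = character(), cell_type = character(),
                          x_um = double(), y_um = double(), z_um = double(),
                          radius_um = double(), confetti = character()))
  }
  tibble::tibble(
    id = sprintf("%s_%04d", prefix, seq_len(n)),
    cell_type = type,
    x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
    radius_um = catalog_radius(type, catalog),
    confetti = "none"
  )
}

# ---- vessel placement ---------------------------------------------------

# Random tortuous polyline: horizontal-ish walk clamped inside the slab.
gen_polyline <- function(start, n_steps, step, tortuosity, volume, radius,
                         z_band) {
  # the x-y wall margin leaves room for cells decorating the surface
  m <- radius + 8
  lo <- volume$origin + c(m, m, 0)
  hi <- volume$origin + volume$extent - c(m, m, 0)
  pts <- matrix(0, n_steps + 1, 3)
  pts[1, ] <- start
  ang <- runif(1, 0, 2 * pi)
  for (i in seq_len(n_steps)) {
    ang <- ang + rnorm(1, 0, tortuosity)
    dz <- rnorm(1, 0, step * 0.03)
    p <- pts[i, ] + c(cos(ang) * step, sin(ang) * step, dz)
    # reflect off the x-y walls, clamp z to the band keeping the capsule in-slab
    for (k in 1:2) {
      if (p[k] < lo[k]) { p[k] <- 2 * lo[k] - p[k]; ang <- ang + pi / 2 }
      if (p[k] > hi[k]) { p[k] <- 2 * hi[k] - p[k]; ang <- ang + pi / 2 }
      p[k] <- min(max(p[k], lo[k]), hi[k])
    }
    p[3] <- min(max(p[3], z_band[1]), z_band[2])
    pts[i + 1, ] <- p
  }
  pts
}

#' Place a synthetic vessel network
#'
#' Generates sinusoid and arteriole capsule segments as tortuous,
#' mostly-horizontal polylines confined to the slab (so that the full
#' capsule surface stays inside the analysed volume). A fraction of
#' sinusoids sprouts a child segment from its distal endpoint, producing
#' branch points (shared endpoints where two or more lumens connect).
#'
#' @param config a [marrow_config()].
#' @param seed optional integer; when given, seeds placement locally.
#' @return a [vessel_network()].
#' @export
place_vessel_network <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vp <- config$vessels
  vol <- tissue_volume(config$volume$extent)
  rows <- list()
  emit <- function(id, vclass, radius, pts) {
    tibble::tibble(segment_id = id, vclass = vclass, radius_um = radius,
                   point_index = seq_len(nrow(pts)),
                   x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3])
  }
  gen_class <- function(n, prefix, vclass, radius, tort_mult = 1, extra_steps = 0) {
    z_band <- c(vol$origin[3] + radius + 2, vol$origin[3] + vol$extent[3] - radius - 2)
    out <- list()
    for (i in seq_len(n)) {
      start <- runif_box(1, vol, margin = c(radius + 8, radius + 8, 0))[1, ]
      start[3] <- runif(1, z_band[1], z_band[2])
      pts <- gen_polyline(start, vp$n_steps + extra_steps, vp$step_um,
                          vp$tortuosity * tort_mult, vol, radius, z_band)
      id <- sprintf("%s_%02d", prefix, i)
      out[[length(out) + 1]] <- emit(id, vclass, radius, pts)
      if (vclass == "sinusoid" && runif(1) < vp$branch_prob) {
        child <- gen_polyline(pts[nrow(pts), ], max(2, vp$n_steps - 2), vp$step_um,
                              vp$tortuosity * tort_mult, vol, radius, z_band)
        out[[length(out) + 1]] <- emit(paste0(id, "b"), vclass, radius, child)
      }
    }
    out
  }
  if (vp$n_sinusoid + vp$n_arteriole == 0) {
    rlang::inform("zero vessel segments requested: returning an empty network")
    return(vessel_network(tibble::tibble(
      segment_id = character(), vclass = character(), radius_um = double(),
      point_index = integer(), x_um = double(), y_um = double(), z_um = double()
    )[0, ]))
  }
  # arterioles are longer, straighter penetrating vessels than sinusoids
  rows <- c(gen_class(vp$n_sinusoid, "sin", "sinusoid", vp$sinusoid_radius_um),
            gen_class(vp$n_arteriole, "art", "arteriole", vp$arteriole_radius_um,
                      tort_mult = 0.25, extra_steps = 1))
  vessel_network(dplyr::bind_rows(rows))
}

# Random points on the surface of a capsule segment (contact placement).
# Returns centre positions for cells of radius cell_r whose surface gap to
# the vessel is jitter (default within +/- 0.2 um). Directions are kept
# near-horizontal so offset centres stay inside the slab. With
# `transport = TRUE` (ordered arcs, e.g. a string of touching cells) the
# radial direction is parallel-transported along the polyline so that it
# rotates continuously through bends instead of jumping at vertices.
surface_points <- function(seg, n, cell_r, volume, arc = NULL, phi = NULL,
                           side = NULL, jitter = 0.2, transport = FALSE) {
  pts <- seg$pts
  d <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(d))
  L <- cum[length(cum)]
  s <- if (is.null(arc)) runif(n, 0, L) else arc
  if (is.null(phi)) phi <- runif(n, -pi / 6, pi / 6)
  iseg <- pmin(findInterval(s, cum, rightmost.closed = TRUE), length(d))
  out <- matrix(0, n, 3)
  z_lo <- volume$origin[3] + cell_r
  z_hi <- volume$origin[3] + volume$extent[3] - cell_r
  prev_dir <- NULL
  for (i in seq_len(n)) {
    j <- iseg[i]
    t <- (s[i] - cum[j]) / d[j]
    base <- pts[j, ] + t * (pts[j + 1, ] - pts[j, ])
    axis <- (pts[j + 1, ] - pts[j, ]) / d[j]
    off <- seg$radius + cell_r + runif(1, -jitter, jitter)
    if (transport && !is.null(prev_dir)) {
      dir <- prev_dir - sum(prev_dir * axis) * axis
      nd <- sqrt(sum(dir^2))
      dir <- if (nd < 1e-9) prev_dir else dir / nd
    } else {
      u <- c(axis[2], -axis[1], 0)
      nu <- sqrt(sum(u^2))
      if (nu < 1e-9) u <- c(1, 0, 0) else u <- u / nu
      w <- c(axis[2] * u[3] - axis[3] * u[2],
             axis[3] * u[1] - axis[1] * u[3],
             axis[1] * u[2] - axis[2] * u[1])
      sgn <- if (is.null(side)) sample(c(-1, 1), 1) else side[i]
      dir <- cos(phi[i]) * sgn * u + sin(phi[i]) * w
      p_try <- base + off * dir
      if (p_try[3] < z_lo || p_try[3] > z_hi) {
        # flip the vertical component rather than clamping, so the centre
        # stays on the capsule surface
        dir <- cos(phi[i]) * sgn * u - sin(phi[i]) * w
      }
    }
    p <- base + off * dir
    p[3] <- min(max(p[3], z_lo), z_hi)
    out[i, ] <- p
    prev_dir <- dir
  }
  out
}

# ---- cell placement -----------------------------------------------------

place_pool <- function(config, volume) {
  xyz <- runif_box(config$pool_count, volume)
  make_cells("bm", "BM", xyz)
}

place_megakaryocytes <- function(config, volume) {
  mk <- config$megakaryocytes
  r <- mk$radius_um
  z_mid <- volume$origin[3] + volume$extent[3] / 2
  z_play <- max(volume$extent[3] / 2 - r, 0)
  xyz <- runif_box(mk$count, volume, margin = 0)
  xyz[, 3] <- runif(mk$count, z_mid - z_play, z_mid + z_play)
  cells <- make_cells("mk", "MK", xyz)
  cells$radius_um <- r
  cells
}

#' Place dispersed multipotent HSPCs
#'
#' Sequential rejection sampling with a soft-core repulsive penalty among
#' all multipotent cells (hard core at half the repulsion scale, soft
#' decay up to the full scale), an exponential attraction toward the
#' nearest megakaryocyte surface, and a near-surface avoidance of
#' arterioles. With all weights and the repulsion scale set to zero the
#' process reduces to complete spatial randomness over the mask.
#'
#' @param config a [marrow_config()].
#' @param scene list with `vessels` (a [vessel_network()]), `megakaryocytes`
#'   (cell table) and `volume`.
#' @param seed optional local seed.
#' @return cell table of placed HSPCs.
#' @export
place_hspc <- function(config, scene, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hp <- config$hspc
  counts <- hp$counts[hp$counts > 0]
  if (!length(counts)) return(make_cells("hspc", character(0), matrix(0, 0, 3)))
  types <- rep(names(counts), counts)
  vol <- scene$volume
  mks <- scene$megakaryocytes
  art <- tibble::as_tibble(scene$vessels)
  art <- art[art$vclass == "arteriole", , drop = FALSE]
  have_art <- nrow(art) > 0
  placed <- matrix(0, 0, 3)
  radii <- catalog_radius(types)
  out <- matrix(NA_real_, length(types), 3)
  half <- hp$repulsion_um / 2
  soft_tau <- max(hp$repulsion_um / 4, 1e-9)
  for (i in seq_along(types)) {
    accepted <- FALSE
    for (batch in seq_len(60)) {
      prop <- runif_box(50, vol)
      prop[, 3] <- runif(50, vol$origin[3] + radii[i],
                         vol$origin[3] + vol$extent[3] - radii[i])
      p <- rep(1, 50)
      if (nrow(placed) > 0 && hp$repulsion_um > 0) {
        dmin <- apply(prop, 1, function(q) {
          sqrt(min(colSums((t(placed) - q)^2)))
        })
        p[dmin < half] <- 0
        soft <- dmin >= half & dmin < hp$repulsion_um
        p[soft] <- p[soft] * exp(-(hp$repulsion_um - dmin[soft]) / soft_tau)
      }
      if (hp$mk_weight > 0 && nrow(mks) > 0) {
        dmk <- apply(prop, 1, function(q) {
          sqrt(min(colSums((t(cells_xyz(mks)) - q)^2)))
        }) - mks$radius_um[1] - radii[i]
        dmk <- pmax(dmk, 0)
        p <- p * exp(-hp$mk_weight * dmk / hp$bias_scale_um)
      }
      if (hp$arteriole_weight > 0 && have_art) {
        dart <- distance_to_vessel(
          tibble::tibble(id = sprintf("q%d", seq_len(nrow(prop))),
                         x_um = prop[, 1], y_um = prop[, 2], z_um = prop[, 3],
                         radius_um = radii[i]),
          scene$vessels, "arteriole")$gap_um
        dart <- pmax(dart, 0)
        p <- p * (1 - hp$arteriole_weight * exp(-dart / 50))
      }
      hit <- which(runif(50) < p)
      if (length(hit)) {
        out[i, ] <- prop[hit[1], ]
        placed <- rbind(placed, out[i, ])
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      rlang::abort(
        paste0("could not place HSPC ", i, " of ", length(types),
               ": repulsion scale ", hp$repulsion_um,
               " um is incompatible with the requested density"),
        class = "marrowmap_placement_failure"
      )
    }
  }
  cells <- make_cells("hspc", types[1], out)
  cells$cell_type <- types
  cells$radius_um <- radii
  cells
}

# Committed single-cell progenitors: MkP and pre Meg-E as dispersed single
# cells (hard core only); pre CFU-E as a contact mixture -- with the
# configured probability the cell sits in direct sinusoid contact, else it
# is placed away from all vessels (beyond the clearance gap).
place_progenitors <- function(config, scene) {
  pp <- config$progenitors
  vol <- scene$volume
  sin_segs <- segment_list(scene$vessels, "sinusoid")
  all_cells <- list()
  for (ty in names(pp$counts)) {
    n <- pp$counts[[ty]]
    if (n == 0) next
    r <- catalog_radius(ty)
    cp <- pp$sinusoid_contact_prob
    contact_p <- if (!is.null(cp) && ty %in% names(cp)) unname(cp[[ty]]) else 0
    is_contact <- runif(n) < contact_p
    xyz <- matrix(0, n, 3)
    # contact cells: random point on a random sinusoid capsule surface
    if (any(is_contact)) {
      if (!length(sin_segs)) {
        rlang::abort("sinusoid-contact placement requested but no sinusoids present",
                     class = "marrowmap_placement_failure")
      }
      lens <- vapply(sin_segs, function(s) sum(sqrt(rowSums(diff(s$pts)^2))), 0)
      for (i in which(is_contact)) {
        s <- sin_segs[[sample.int(length(sin_segs), 1, prob = lens)]]
        xyz[i, ] <- surface_points(s, 1, r, vol)
      }
    }
    # free cells: rejection-sample away from all vessels, soft hard-core
    free_idx <- which(!is_contact)
    placed <- xyz[is_contact, , drop = FALSE]
    for (i in free_idx) {
      ok <- FALSE
      for (batch in seq_len(40)) {
        prop <- runif_box(50, vol)
        prop[, 3] <- runif(50, vol$origin[3] + r, vol$origin[3] + vol$extent[3] - r)
        keep <- rep(TRUE, 50)
        if (nrow(tibble::as_tibble(scene$vessels)) > 0 && pp$vessel_clearance_um > 0) {
          qd <- tibble::tibble(id = sprintf("q%d", 1:50), x_um = prop[, 1],
                               y_um = prop[, 2], z_um = prop[, 3], radius_um = r)
          g_s <- tryCatch(distance_to_vessel(qd, scene$vessels, "sinusoid")$gap_um,
                          marrowmap_empty_target = function(e) rep(Inf, 50))
          g_a <- tryCatch(distance_to_vessel(qd, scene$vessels, "arteriole")$gap_um,
                          marrowmap_empty_target = function(e) rep(Inf, 50))
          keep <- keep & g_s > pp$vessel_clearance_um & g_a > pp$vessel_clearance_um
        }
        if (nrow(placed) > 0 && pp$hard_core_um > 0) {
          dmin <- apply(prop, 1, function(q) sqrt(min(colSums((t(placed) - q)^2))))
          keep <- keep & dmin > pp$hard_core_um
        }
        if (any(keep)) {
          xyz[i, ] <- prop[which(keep)[1], ]
          placed <- rbind(placed, xyz[i, ])
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        rlang::abort(paste0("could not place ", ty, " away from vessels"),
                     class = "marrowmap_placement_failure")
      }
    }
    cells <- make_cells(gsub("[^A-Za-z0-9]", "", tolower(ty)), ty, xyz)
    cells$.contact_truth <- is_contact
    all_cells[[ty]] <- cells
  }
  dplyr::bind_rows(all_cells)
}
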