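# Production-site placement for the synthetic generator, Confetti clone
# assignment, and the top-level scene builder.

empty_truth_sites <- function() {
  tibble::tibble(site_id = character(), lineage = character(),
                 anchor_id = character(), cell_id = character(),
                 role = character(), cluster_id = character())
}

# Pick, per site, a sinusoid chain (excluding chains already claimed by
# another lineage) and within it the longest segment as the anchor.
allocate_chains <- function(network, n, exclude = integer()) {
  ch <- vessel_chains(network)
  ch <- ch[ch$vclass == "sinusoid", , drop = FALSE]
  avail <- setdiff(unique(ch$chain_id), exclude)
  if (length(avail) < n) {
    rlang::abort(
      paste0("placement failure: ", n, " production sites requested but only ",
             length(avail), " unoccupied sinusoid chains are available"),
      class = "marrowmap_placement_failure"
    )
  }
  sample(avail, n)
}

longest_segment <- function(network, chain_id_wanted) {
  ch <- vessel_chains(network)
  segs <- segment_list(network)
  ids <- ch$segment_id[ch$chain_id == chain_id_wanted]
  lens <- vapply(segs[as.character(ids)],
                 function(s) sum(sqrt(rowSums(diff(s$pts)^2))), 0)
  segs[[as.character(ids[which.max(lens)])]]
}

# Scatter n points around a centre with near-horizontal offsets of length
# drawn from [d_lo, d_hi], z kept inside the slab.
scatter_around <- function(centre, n, d_range, volume, cell_r, z_max = 0.15) {
  if (n == 0) return(matrix(0, 0, 3))
  out <- matrix(0, n, 3)
  lo <- volume$origin + c(0, 0, cell_r)
  hi <- volume$origin + volume$extent - c(0, 0, cell_r)
  for (i in seq_len(n)) {
    for (try in 1:50) {
      d <- runif(1, d_range[1], d_range[2])
      dir <- runif_dir_flat(1, z_max)[1, ]
      p <- centre + d * dir
      if (all(p >= lo) && all(p <= hi)) break
    }
    out[i, ] <- pmin(pmax(p, lo), hi)
  }
  out
}

# Compact cell cluster: isotropic normal spread truncated to a maximal
# radius, z clipped to the slab.
scatter_cluster <- function(centre, n, spread, max_radius, volume, cell_r) {
  out <- matrix(0, n, 3)
  lo <- volume$origin + c(0, 0, cell_r)
  hi <- volume$origin + volume$extent - c(0, 0, cell_r)
  for (i in seq_len(n)) {
    for (try in 1:100) {
      off <- c(rnorm(2, 0, spread), rnorm(1, 0, spread / 2))
      if (sqrt(sum(off^2)) <= max_radius) break
    }
    out[i, ] <- pmin(pmax(centre + off, lo), hi)
  }
  out
}

#' Plant lineage-specific production sites
#'
#' Places the cells of one lineage's production sites into an existing
#' scene and returns both the cells and the ground-truth membership
#' table. Erythroid sites are contiguous CFU-E strings in direct surface
#' contact with a single sinusoid chain, with budding early-erythroblast
#' clusters and one compact late-erythroblast cluster within the capture
#' radius, plus nearby reticulocytes and red cells. B sites are single
#' CLPs near an arteriole with pre-pro B, pro B and pre B cells scattered
#' at increasing distances within 150 um. Neutrophil and mono/DC sites
#' are a focal progenitor (GP or MDP) in sinusoid contact with immature
#' progeny clustered within 50 um. Each anchor vessel chain hosts at most
#' one lineage.
#'
#' @param lineage one of `"erythroid"`, `"B"`, `"neutrophil"`, `"monoDC"`.
#' @param config a [marrow_config()].
#' @param scene list with `vessels`, `volume` and (for B sites) nothing
#'   else; for anchored lineages `exclude_chains` lists sinusoid chains
#'   already claimed.
#' @param seed optional local seed.
#' @param exclude_chains integer chain ids unavailable as anchors.
#' @return list with `cells` (cell table) and `truth` (long tibble:
#'   `site_id`, `lineage`, `anchor_id`, `cell_id`, `role`, `cluster_id`)
#'   and `chains` (chain ids claimed).
#' @export
place_production_sites <- function(lineage = c("erythroid", "B", "neutrophil", "monoDC"),
                                   config, scene, seed = NULL,
                                   exclude_chains = integer()) {
  lineage <- match.arg(lineage)
  if (!is.null(seed)) set.seed(seed)
  switch(lineage,
         erythroid = place_erythroid_sites(config, scene, exclude_chains),
         B = place_b_sites_truth(config, scene),
         neutrophil = place_myeloid_sites_truth(config, scene, "neutrophil", exclude_chains),
         monoDC = place_myeloid_sites_truth(config, scene, "monoDC", exclude_chains))
}

place_erythroid_sites <- function(config, scene, exclude_chains = integer()) {
  es <- config$erythroid_sites
  vol <- scene$volume
  n_sites <- es$n_sites
  if (n_sites == 0) {
    return(list(cells = make_cells("x", character(0), matrix(0, 0, 3)),
                truth = empty_truth_sites(), chains = integer()))
  }
  ch_tab <- vessel_chains(scene$vessels)
  avail <- setdiff(unique(ch_tab$chain_id[ch_tab$vclass == "sinusoid"]),
                   exclude_chains)
  if (length(avail) < n_sites) {
    rlang::abort(
      paste0("placement failure: ", n_sites, " erythroid sites requested but only ",
             length(avail), " unoccupied sinusoid chains are available"),
      class = "marrowmap_placement_failure"
    )
  }
  avail <- sample(avail)
  chains <- integer(n_sites)
  r_cfu <- catalog_radius("CFU-E")
  cells <- list(); truth <- list()
  prior_members <- matrix(0, 0, 3)  # members of already-placed strings
  seg_all <- segment_list(scene$vessels, "sinusoid")
  # place one string on one chain; if a chain offers no usable span, move
  # on to the next unoccupied chain
  try_chain <- function(chain_id, N, spacings, total) {
    seg_ids <- ch_tab$segment_id[ch_tab$chain_id == chain_id]
    cand_segs <- seg_all[as.character(seg_ids)]
    lens <- vapply(cand_segs, function(s) sum(sqrt(rowSums(diff(s$pts)^2))), 0)
    ord <- order(-lens)
    for (k in ord) {
      L <- lens[k]
      if (L < total + 10) next
      # retry span/side until the string is contiguous across bends and
      # keeps clear of earlier strings (anchor chains can cross in a
      # dense network; distinct structures must not touch); the
      # contiguity margin is relaxed toward the linkage gap on late tries
      for (try in seq_len(80)) {
        s0 <- runif(1, 5, L - total - 5)
        arcs <- s0 + c(0, cumsum(spacings))
        base_phi <- runif(1, -0.25, 0.25)  # near-horizontal decoration
        phis <- base_phi + runif(N, -0.05, 0.05)
        side <- sample(c(-1, 1), 1)
        cand_xyz <- surface_points(cand_segs[[k]], N, r_cfu, vol, arc = arcs,
                                   phi = phis, side = rep(side, N),
                                   transport = TRUE)
        consec <- sqrt(rowSums(diff(cand_xyz)^2)) - 2 * r_cfu
        margin <- if (try <= 40) 8 else 9.5
        contiguous <- all(consec <= margin & consec >= -4)
        clear <- if (nrow(prior_members) == 0) TRUE else {
          min(apply(cand_xyz, 1, function(q) {
            min(colSums((t(prior_members) - q)^2))
          })) > 30^2
        }
        if (contiguous && clear) {
          return(list(xyz = cand_xyz, seg = cand_segs[[k]]))
        }
      }
    }
    NULL
  }
  for (i in seq_len(n_sites)) {
    sid <- sprintf("ery_%02d", i)
    N <- r_clipped_gamma(1, es$string_size$mean, es$string_size$sd,
                         es$string_size$min, es$string_size$max)
    spacings <- 2 * r_cfu + runif(N - 1, 0, 3)
    total <- sum(spacings)
    placed <- NULL
    while (!is.null(avail) && length(avail)) {
      chain_id <- avail[1]; avail <- avail[-1]
      placed <- try_chain(chain_id, N, spacings, total)
      if (!is.null(placed)) { chains[i] <- chain_id; break }
    }
    if (is.null(placed)) {
      rlang::abort(paste0("placement failure: no sinusoid chain offers a contiguous ",
                          N, "-cell span clear of other strings"),
                   class = "marrowmap_placement_failure")
    }
    xyz <- placed$xyz; seg <- placed$seg
    prior_members <- rbind(prior_members, xyz)
    string <- make_cells(paste0("cfue_", sid), "CFU-E", xyz)
    cells[[length(cells) + 1]] <- string
    truth[[length(truth) + 1]] <- tibble::tibble(
      site_id = sid, lineage = "erythroid", anchor_id = seg$segment_id,
      cell_id = string$id, role = "string", cluster_id = NA_character_)
    string_xyz <- cells_xyz(string)
    # early-erythroblast buds
    for (b in seq_len(es$n_buds)) {
      nb <- r_clipped_gamma(1, es$bud_size$mean, es$bud_size$sd,
                            es$bud_size$min, es$bud_size$max)
      m <- string_xyz[sample.int(N, 1), ]
      centre <- m + runif_dir_flat(1, 0.1)[1, ] * es$bud_offset_um
      bud_xyz <- scatter_cluster(centre, nb, 4, 10, vol, catalog_radius("early erythroblast"))
      bud <- make_cells(sprintf("eeb_%s_b%d", sid, b), "early erythroblast", bud_xyz)
      cells[[length(cells) + 1]] <- bud
      truth[[length(truth) + 1]] <- tibble::tibble(
        site_id = sid, lineage = "erythroid", anchor_id = seg$segment_id,
        cell_id = bud$id, role = "bud", cluster_id = sprintf("%s_b%d", sid, b))
    }
    # late-erythroblast cluster
    M <- r_clipped_gamma(1, es$cluster_size$mean, es$cluster_size$sd,
                         es$cluster_size$min, es$cluster_size$max)
    m <- string_xyz[sample.int(N, 1), ]
    centre <- m + runif_dir_flat(1, 0.1)[1, ] * es$cluster_offset_um
    cl_xyz <- scatter_cluster(centre, M, es$cluster_spread_um,
                              es$cluster_max_radius_um, vol,
                              catalog_radius("late erythroblast"))
    clus <- make_cells(sprintf("leb_%s", sid), "late erythroblast", cl_xyz)
    cells[[length(cells) + 1]] <- clus
    truth[[length(truth) + 1]] <- tibble::tibble(
      site_id = sid, lineage = "erythroid", anchor_id = seg$segment_id,
      cell_id = clus$id, role = "cluster", cluster_id = sprintf("%s_c1", sid))
    # reticulocytes and erythrocytes in close vicinity of the string
    for (spec in list(list(ty = "reticulocyte", n = es$n_reticulocytes, pre = "ret"),
                      list(ty = "RBC", n = es$n_rbc, pre = "rbc"))) {
      if (spec$n == 0) next
      anchors <- string_xyz[sample.int(N, spec$n, replace = TRUE), , drop = FALSE]
      r_ty <- catalog_radius(spec$ty)
      pos <- t(vapply(seq_len(spec$n), function(k) {
        scatter_around(anchors[k, ], 1, c(5, 40), vol, r_ty)[1, ]
      }, numeric(3)))
      cc <- make_cells(sprintf("%s_%s", spec$pre, sid), spec$ty, pos)
      cells[[length(cells) + 1]] <- cc
      truth[[length(truth) + 1]] <- tibble::tibble(
        site_id = sid, lineage = "erythroid", anchor_id = seg$segment_id,
        cell_id = cc$id, role = spec$ty, cluster_id = NA_character_)
    }
  }
  list(cells = dplyr::bind_rows(cells), truth = dplyr::bind_rows(truth),
       chains = chains)
}

place_b_sites_truth <- function(config, scene) {
  bs <- config$b_sites
  vol <- scene$volume
  if (bs$n_sites == 0) {
    return(list(cells = make_cells("x", character(0), matrix(0, 0, 3)),
                truth = empty_truth_sites(), chains = integer()))
  }
  art_segs <- segment_list(scene$vessels, "arteriole")
  if (!length(art_segs)) {
    rlang::abort("placement failure: B sites need arterioles",
                 class = "marrowmap_placement_failure")
  }
  r_clp <- catalog_radius("CLP")
  # candidate CLP positions: arteriole surfaces resampled every 25 um of
  # arc, offset a little further out (near, not necessarily touching)
  cand <- purrr::map(art_segs, function(s) {
    d <- sqrt(rowSums(diff(s$pts)^2)); L <- sum(d)
    arcs <- seq(2, max(L - 2, 2), by = 25)
    # radial offset varies from touching up to the near-vessel band
    p <- surface_points(s, length(arcs), r_clp + bs$arteriole_offset_um / 2, vol,
                        arc = arcs, jitter = bs$arteriole_offset_um / 2)
    tibble::tibble(x = p[, 1], y = p[, 2], z = p[, 3], seg = s$segment_id)
  }) |> purrr::list_rbind()
  pick_separated <- function(order_idx) {
    sel <- integer(0)
    for (i in order_idx) {
      p <- c(cand$x[i], cand$y[i], cand$z[i])
      if (!length(sel) ||
          min(sqrt((cand$x[sel] - p[1])^2 + (cand$y[sel] - p[2])^2 +
                     (cand$z[sel] - p[3])^2)) >= bs$min_separation_um) {
        sel <- c(sel, i)
        if (length(sel) == bs$n_sites) break
      }
    }
    sel
  }
  sel <- integer(0)
  for (restart in seq_len(20)) {
    sel <- pick_separated(sample.int(nrow(cand)))
    if (length(sel) == bs$n_sites) break
  }
  if (length(sel) < bs$n_sites) {
    # farthest-point fallback squeezes out the maximal spread
    sel <- sample.int(nrow(cand), 1)
    while (length(sel) < bs$n_sites) {
      d2 <- outer(cand$x, cand$x[sel], `-`)^2 +
        outer(cand$y, cand$y[sel], `-`)^2 +
        outer(cand$z, cand$z[sel], `-`)^2
      dmin <- sqrt(apply(d2, 1, min))
      if (max(dmin) < bs$min_separation_um) break
      sel <- c(sel, which.max(dmin))
    }
    if (length(sel) < bs$n_sites) {
      rlang::abort(paste0("placement failure: could not place ", bs$n_sites,
                          " CLPs at min separation ", bs$min_separation_um,
                          " um on the arteriole network"),
                   class = "marrowmap_placement_failure")
    }
  }
  clp_pos <- cbind(cand$x[sel], cand$y[sel], cand$z[sel])
  clp_anchor <- cand$seg[sel]
  clp <- make_cells("clp", "CLP", clp_pos)
  cells <- list(clp); truth <- list()
  for (i in seq_len(bs$n_sites)) {
    sid <- sprintf("b_%02d", i)
    truth[[length(truth) + 1]] <- tibble::tibble(
      site_id = sid, lineage = "B", anchor_id = clp$id[i], role = "CLP",
      cell_id = clp$id[i], cluster_id = NA_character_)
    for (ty in names(bs$stage_counts)) {
      mu <- bs$stage_counts[[ty]][["mean"]]; sdv <- bs$stage_counts[[ty]][["sd"]]
      n <- r_clipped_norm(1, mu, sdv, 0)
      if (n == 0) next
      pos <- scatter_around(clp_pos[i, ], n, bs$stage_gradient[[ty]], vol,
                            catalog_radius(ty), z_max = 0.12)
      cc <- make_cells(sprintf("%s_%s", gsub("[^A-Za-z0-9]", "", tolower(ty)), sid), ty, pos)
      cells[[length(cells) + 1]] <- cc
      truth[[length(truth) + 1]] <- tibble::tibble(
        site_id = sid, lineage = "B", anchor_id = clp$id[i], role = ty,
        cell_id = cc$id, cluster_id = NA_character_)
    }
  }
  list(cells = dplyr::bind_rows(cells), truth = dplyr::bind_rows(truth),
       chains = integer())
}

place_myeloid_sites_truth <- function(config, scene, lineage, exclude_chains = integer()) {
  ms <- if (lineage == "neutrophil") config$neutrophil_sites else config$monoDC_sites
  focal_type <- if (lineage == "neutrophil") "GP" else "MDP"
  prefix <- if (lineage == "neutrophil") "neu" else "mdc"
  vol <- scene$volume
  if (ms$n_sites == 0) {
    return(list(cells = make_cells("x", character(0), matrix(0, 0, 3)),
                truth = empty_truth_sites(), chains = integer()))
  }
  chains <- allocate_chains(scene$vessels, ms$n_sites, exclude_chains)
  r_f <- catalog_radius(focal_type)
  cells <- list(); truth <- list()
  for (i in seq_len(ms$n_sites)) {
    sid <- sprintf("%s_%02d", prefix, i)
    seg <- longest_segment(scene$vessels, chains[i])
    fp <- surface_points(seg, 1, r_f, vol)
    focal <- make_cells(sprintf("%s_%s", tolower(focal_type), sid), focal_type, fp)
    cells[[length(cells) + 1]] <- focal
    truth[[length(truth) + 1]] <- tibble::tibble(
      site_id = sid, lineage = lineage, anchor_id = seg$segment_id,
      cell_id = focal$id, role = focal_type, cluster_id = NA_character_)
    for (ty in names(ms$progeny)) {
      pr <- ms$progeny[[ty]]
      n <- r_clipped_norm(1, pr[["mean"]], pr[["sd"]], pr[["min"]], pr[["max"]])
      if (n == 0) next
      r_p <- catalog_radius(ty)
      pos <- scatter_around(fp[1, ], n, c(r_f + r_p + 1, ms$capture_um - 6), vol, r_p)
      cc <- make_cells(sprintf("%s_%s", gsub("[^A-Za-z0-9]", "", tolower(ty)), sid), ty, pos)
      cells[[length(cells) + 1]] <- cc
      truth[[length(truth) + 1]] <- tibble::tibble(
        site_id = sid, lineage = lineage, anchor_id = seg$segment_id,
        cell_id = cc$id, role = ty, cluster_id = NA_character_)
    }
  }
  list(cells = dplyr::bind_rows(cells), truth = dplyr::bind_rows(truth),
       chains = chains)
}

#' Assign Confetti labels and clone identities
#'
#' Clone structure is assigned first, then each cell is labelled
#' independently with the configured recombination fraction; a labelled
#' cell displays its clone's colour, an unlabelled cell shows `"none"`.
#' Within planted structures the clone policy is honoured: CFU-E strings
#' (and their B-site and myeloid analogues) draw members from at least two
#' clones, while each erythroblast cluster inherits a single clone from
#' its parent string. Structure clones carry distinct non-green colours
#' (YFP/RFP/CFP), because green doubles as the imaging dump channel and a
#' green clone would be unreadable; unstructured cells are singleton
#' clones coloured from the full four-colour set.
#'
#' @param cells cell table.
#' @param confetti the `confetti` component of a [marrow_config()].
#' @param truth long site-membership tibble (as produced by
#'   [place_production_sites()]), or NULL for label-only assignment.
#' @param seed optional local seed.
#' @return list `cells` (with `confetti` filled) and `clones` tibble
#'   (`cell_id`, `clone_id`, `colour`).
#' @export
assign_confetti <- function(cells, confetti, truth = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fr <- confetti$fraction
  if (fr < 0 || fr > 1) {
    rlang::abort("confetti fraction must be in [0, 1]", class = "marrowmap_config_error")
  }
  n <- nrow(cells)
  clone_id <- paste0("solo_", cells$id)
  colour <- sample(names(confetti$weights), n, replace = TRUE,
                   prob = confetti$weights)
  names(clone_id) <- names(colour) <- cells$id
  non_green <- setdiff(names(confetti$weights), "GFP")
  pick_structure_colours <- function(k) {
    w <- confetti$weights[non_green]
    sample(non_green, k, prob = w / sum(w))
  }
  # spread members over k clones, every clone used at least once
  spread_clones <- function(m, k) {
    k <- min(k, m)
    idx <- c(seq_len(k), sample.int(k, max(m - k, 0), replace = TRUE))
    sample(idx)
  }
  if (!is.null(truth) && nrow(truth)) {
    for (sid in unique(truth$site_id)) {
      st <- truth[truth$site_id == sid, , drop = FALSE]
      lin <- st$lineage[1]
      if (lin == "erythroid") {
        string_ids <- st$cell_id[st$role == "string"]
        if (length(string_ids)) {
          k <- sample(2:3, 1)
          cl_names <- sprintf("%s_cl%d", sid, seq_len(min(k, length(string_ids))))
          cols <- pick_structure_colours(length(cl_names))
          asg <- spread_clones(length(string_ids), length(cl_names))
          clone_id[string_ids] <- cl_names[asg]
          colour[string_ids] <- cols[asg]
        } else {
          cl_names <- character(0); cols <- character(0)
        }
        # each erythroblast cluster inherits one string clone (its own
        # clone when the truth carries no string); loose
        # reticulocytes/RBC each inherit a random string clone
        for (cid in unique(stats::na.omit(st$cluster_id))) {
          mem <- st$cell_id[!is.na(st$cluster_id) & st$cluster_id == cid]
          if (length(cl_names)) {
            pick <- sample.int(length(cl_names), 1)
            clone_id[mem] <- cl_names[pick]
            colour[mem] <- cols[pick]
          } else {
            clone_id[mem] <- sprintf("%s_%s", sid, cid)
            colour[mem] <- pick_structure_colours(1)
          }
        }
        loose <- st$cell_id[st$role %in% c("reticulocyte", "RBC")]
        if (length(loose) && length(cl_names)) {
          pick <- sample.int(length(cl_names), length(loose), replace = TRUE)
          clone_id[loose] <- cl_names[pick]
          colour[loose] <- cols[pick]
        }
      } else {
        mem <- st$cell_id
        k <- sample(2:3, 1)
        cl_names <- sprintf("%s_cl%d", sid, seq_len(min(k, length(mem))))
        cols <- pick_structure_colours(length(cl_names))
        asg <- spread_clones(length(mem), length(cl_names))
        clone_id[mem] <- cl_names[asg]
        colour[mem] <- cols[asg]
      }
    }
  }
  labelled <- runif(n) < fr
  cells$confetti <- ifelse(labelled, colour[cells$id], "none")
  list(cells = cells,
       clones = tibble::tibble(cell_id = cells$id, clone_id = unname(clone_id),
                               colour = unname(colour),
                               labelled = labelled))
}

#' Simulate a ground-truthed synthetic marrow scene
#'
#' Builds a complete labelled 35-um marrow slab from a configuration:
#' vessel networks, megakaryocytes, the unclassified haematopoietic pool,
#' dispersed multipotent HSPCs, single-cell committed progenitors,
#' production sites for all four lineages, and Confetti labels. The same
#' configuration and seed always reproduce the identical scene.
#'
#' @param config a [marrow_config()] or preset name.
#' @param seed integer seed; defaults to `config$seed`.
#' @return an object of class `synthetic_marrow`: a list with `cells`,
#'   `vessels`, `megakaryocytes` (a view of the MK rows), `volume`,
#'   `truth` (`sites`, `clones`, `placement`) and `config`.
#' @export
#' @examples
#' scene <- simulate_marrow(marrow_config(pool_count = 1000,
#'   erythroid_sites = list(n_sites = 2), b_sites = list(n_sites = 2),
#'   neutrophil_sites = list(n_sites = 2), monoDC_sites = list(n_sites = 1)),
#'   seed = 1)
#' nrow(scene$cells)
simulate_marrow <- function(config = marrow_config(), seed = config$seed) {
  if (is.character(config)) config <- marrow_preset(config)
  validate_marrow_config(config)
  set.seed(seed)
  vol <- tissue_volume(config$volume$extent)
  vessels <- place_vessel_network(config)
  # feasibility: every sinusoid-anchored site needs its own chain
  need <- config$erythroid_sites$n_sites + config$neutrophil_sites$n_sites +
    config$monoDC_sites$n_sites
  ch <- vessel_chains(vessels)
  n_sin_chains <- length(unique(ch$chain_id[ch$vclass == "sinusoid"]))
  if (need > n_sin_chains) {
    rlang::abort(
      paste0("placement failure: ", need, " sinusoid-anchored sites requested but only ",
             n_sin_chains, " sinusoid chains exist"),
      class = "marrowmap_placement_failure"
    )
  }
  mks <- place_megakaryocytes(config, vol)
  scene0 <- list(vessels = vessels, volume = vol, megakaryocytes = mks)
  pool <- place_pool(config, vol)
  hspc <- place_hspc(config, scene0)
  prog <- place_progenitors(config, scene0)
  contact_truth <- tibble::tibble(cell_id = prog$id,
                                  sinusoid_contact = prog$.contact_truth)
  prog$.contact_truth <- NULL
  ery <- place_erythroid_sites(config, scene0)
  neu <- place_myeloid_sites_truth(config, scene0, "neutrophil",
                                   exclude_chains = ery$chains)
  mdc <- place_myeloid_sites_truth(config, scene0, "monoDC",
                                   exclude_chains = c(ery$chains, neu$chains))
  bce <- place_b_sites_truth(config, scene0)
  cells <- dplyr::bind_rows(mks, pool, hspc, prog, ery$cells, neu$cells,
                            mdc$cells, bce$cells)
  truth_sites <- dplyr::bind_rows(ery$truth, neu$truth, mdc$truth, bce$truth)
  conf <- assign_confetti(cells, config$confetti, truth_sites)
  cells <- conf$cells
  placement <- tibble::tibble(
    cell_id = cells$id,
    process = dplyr::case_when(
      cells$id %in% pool$id ~ "pool",
      cells$id %in% mks$id ~ "megakaryocyte",
      cells$id %in% hspc$id ~ "hspc",
      cells$id %in% prog$id ~ "progenitor",
      TRUE ~ "site"
    )
  ) |> dplyr::left_join(contact_truth, by = "cell_id")
  structure(
    list(cells = cells, vessels = vessels,
         megakaryocytes = cells[cells$cell_type == "MK", , drop = FALSE],
         volume = vol,
         truth = list(sites = truth_sites, clones = conf$clones,
                      placement = placement),
         config = config, seed = seed),
    class = "synthetic_marrow"
  )
}

#' @export
print.synthetic_marrow <- function(x, ...) {
  cat(sprintf("<synthetic_marrow> %d cells, %d vessel segments, %.2f mm^2 x %.0f um (seed %s)\n",
              nrow(x$cells), length(unique(x$vessels$segment_id)),
              marrow_area_mm2(x$volume), x$volume$extent[3], format(x$seed)))
  cat("  planted sites:",
      paste(names(table(unique(x$truth$sites[c("site_id", "lineage")])$lineage)),
            table(unique(x$truth$sites[c("site_id", "lineage")])$lineage),
            collapse = ", "), "\n")
  invisible(x)
}
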