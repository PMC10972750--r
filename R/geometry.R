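#' Tissue volume descriptor
#'
#' An axis-aligned marrow slab: an x-y extent times a thin optical slice
#' depth (default 35 um, the uniformly stained analysis window). The
#' endosteal (bone) surfaces are modelled as the two planes bounding the
#' slab in y; the marrow mask is the open box.
#'
#' @param extent numeric length-3, slab extent in um (x, y, depth).
#' @param origin numeric length-3 slab corner, um.
#' @return an object of class `tissue_volume`.
#' @export
tissue_volume <- function(extent = c(2000, 1000, 35), origin = c(0, 0, 0)) {
  extent <- as.numeric(extent)
  if (length(extent) != 3 || any(!is.finite(extent)) || any(extent <= 0)) {
    rlang::abort("`extent` must be 3 positive lengths (um)", class = "marrowmap_config_error")
  }
  structure(list(extent = extent, origin = as.numeric(origin)),
            class = "tissue_volume")
}

#' @export
print.tissue_volume <- function(x, ...) {
  cat(sprintf("<tissue_volume> %.0f x %.0f um, depth %.0f um (%.2f mm^2)\n",
              x$extent[1], x$extent[2], x$extent[3], marrow_area_mm2(x)))
  invisible(x)
}

#' Projected marrow area in mm^2
#'
#' The x-y projection of the slab mask, the normalisation used for
#' production-site densities ("sites per mm^2").
#'
#' @param volume a [tissue_volume()].
#' @return area in mm^2.
#' @export
marrow_area_mm2 <- function(volume) {
  volume$extent[1] * volume$extent[2] / 1e6
}

#' Test whether points fall inside the marrow volume
#'
#' @param xyz numeric matrix (n x 3) of positions, um.
#' @param volume a [tissue_volume()].
#' @return logical vector.
#' @export
in_volume <- function(xyz, volume) {
  xyz <- rbind(xyz)
  lo <- volume$origin
  hi <- volume$origin + volume$extent
  (xyz[, 1] >= lo[1] & xyz[, 1] <= hi[1] &
   xyz[, 2] >= lo[2] & xyz[, 2] <= hi[2] &
   xyz[, 3] >= lo[3] & xyz[, 3] <= hi[3])
}

cells_xyz <- function(cells) {
  cbind(cells$x_um, cells$y_um, cells$z_um)
}

#' Vessel network constructor
#'
#' Validates and classes a long-form vessel table: one row per polyline
#' point, columns `segment_id`, `vclass` (`"sinusoid"` or `"arteriole"`),
#' `radius_um`, `point_index`, `x_um`, `y_um`, `z_um`. Each segment is a
#' capsule: the set of points within `radius_um` of its polyline. Branch
#' points are polyline endpoints shared by two or more segments (where two
#' or more lumens connect).
#'
#' @param segments long-form vessel tibble.
#' @return the table with class `vessel_network`.
#' @export
vessel_network <- function(segments) {
  req <- c("segment_id", "vclass", "radius_um", "point_index", "x_um", "y_um", "z_um")
  missing_cols <- setdiff(req, names(segments))
  if (length(missing_cols)) {
    rlang::abort(paste0("vessel table lacks column(s): ", paste(missing_cols, collapse = ", ")),
                 class = "marrowmap_schema_error")
  }
  bad_class <- setdiff(unique(segments$vclass), c("sinusoid", "arteriole"))
  if (length(bad_class)) {
    rlang::abort(paste0("unknown vessel class: ", paste(bad_class, collapse = ", ")),
                 class = "marrowmap_schema_error")
  }
  if (any(segments$radius_um <= 0)) {
    rlang::abort("vessel radius must be positive", class = "marrowmap_schema_error")
  }
  npts <- table(segments$segment_id)
  if (any(npts < 2)) {
    rlang::abort("every vessel polyline needs at least 2 points",
                 class = "marrowmap_schema_error")
  }
  segments <- dplyr::arrange(tibble::as_tibble(segments), .data$segment_id, .data$point_index)
  if (nrow(segments) == 0) rlang::inform("empty vessel network")
  class(segments) <- c("vessel_network", class(tibble::tibble()))
  segments
}

# Split a vessel network into a list of per-segment descriptors.
segment_list <- function(network, vclass = NULL) {
  df <- tibble::as_tibble(network)
  if (!is.null(vclass)) df <- df[df$vclass %in% vclass, ]
  if (nrow(df) == 0) return(list())
  split(df, df$segment_id) |>
    lapply(function(s) {
      list(segment_id = s$segment_id[1], vclass = s$vclass[1],
           radius = s$radius_um[1], pts = cbind(s$x_um, s$y_um, s$z_um))
    })
}

# Endpoint table: first and last polyline points of each segment, with a
# location key for exact-coordinate matching.
segment_endpoints <- function(network) {
  df <- tibble::as_tibble(network)
  df |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::slice(c(1, dplyr::n())) |>
    dplyr::ungroup() |>
    dplyr::mutate(loc = paste(round(.data$x_um, 6), round(.data$y_um, 6),
                              round(.data$z_um, 6)))
}

#' Branch points of a vessel network
#'
#' A branch is a point where two or more lumens connect: a shared polyline
#' endpoint of at least two segments.
#'
#' @param network a [vessel_network()].
#' @return tibble of branch-point coordinates with the number of joining
#'   segments (`n_segments`).
#' @export
branch_points <- function(network) {
  ep <- segment_endpoints(network)
  if (nrow(ep) == 0) {
    return(tibble::tibble(x_um = double(), y_um = double(), z_um = double(),
                          n_segments = integer()))
  }
  ep |>
    dplyr::distinct(.data$segment_id, .data$loc, .keep_all = TRUE) |>
    dplyr::group_by(.data$loc) |>
    dplyr::summarise(x_um = .data$x_um[1], y_um = .data$y_um[1], z_um = .data$z_um[1],
                     n_segments = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_segments >= 2) |>
    dplyr::select(-"loc")
}

#' Connected vessel chains
#'
#' Groups segments into connected components ("chains") through shared
#' polyline endpoints. Erythroid strings are constrained to decorate a
#' single sinusoid chain.
#'
#' @param network a [vessel_network()].
#' @return tibble `segment_id`, `vclass`, `chain_id`.
#' @export
vessel_chains <- function(network) {
  ep <- segment_endpoints(network)
  segs <- dplyr::distinct(tibble::as_tibble(network), .data$segment_id, .data$vclass)
  if (nrow(segs) == 0) return(tibble::tibble(segment_id = character(), vclass = character(), chain_id = integer()))
  g <- igraph::make_empty_graph(directed = FALSE)
  verts <- unique(c(paste0("s:", segs$segment_id), paste0("p:", unique(ep$loc))))
  g <- igraph::add_vertices(g, length(verts), name = verts)
  edges <- rbind(paste0("s:", ep$segment_id), paste0("p:", ep$loc))
  g <- igraph::add_edges(g, as.vector(edges))
  comp <- igraph::components(g)$membership
  segs$chain_id <- unname(comp[paste0("s:", segs$segment_id)])
  segs
}

# ---- core distance primitives ------------------------------------------

# Minimum distance from each row of P (n x 3) to the 3D line segment A-B.
point_segment_distance <- function(P, A, B) {
  AB <- B - A
  len2 <- sum(AB * AB)
  if (len2 == 0) {
    d <- sweep(P, 2, A)
    return(sqrt(rowSums(d * d)))
  }
  AP <- sweep(P, 2, A)
  t <- pmin(pmax((AP %*% AB) / len2, 0), 1)
  proj <- cbind(A[1] + t * AB[1], A[2] + t * AB[2], A[3] + t * AB[3])
  d <- P - proj
  sqrt(rowSums(d * d))
}

# Minimum distance from each row of P to a polyline (m x 3 matrix).
point_polyline_distance <- function(P, pts) {
  P <- rbind(P)
  best <- rep(Inf, nrow(P))
  for (i in seq_len(nrow(pts) - 1)) {
    d <- point_segment_distance(P, pts[i, ], pts[i + 1, ])
    best <- pmin(best, d)
  }
  best
}

#' Surface-to-surface gap distance between two cells
#'
#' The Euclidean centre distance minus both cells' radii. Negative values
#' (interpenetrating segmented spheres) are preserved, not clamped; a gap
#' at or below the contact tolerance is read as direct contact.
#'
#' @param a,b single cell records (one-row data frames or lists with
#'   `id`, `x_um`, `y_um`, `z_um`, `radius_um`).
#' @return gap in um.
#' @export
#' @examples
#' a <- tibble::tibble(id = "a", x_um = 0, y_um = 0, z_um = 0, radius_um = 5)
#' b <- tibble::tibble(id = "b", x_um = 20, y_um = 0, z_um = 0, radius_um = 5)
#' gap_distance_cells(a, b) # 10
gap_distance_cells <- function(a, b) {
  if (!is.null(a$id) && !is.null(b$id) && identical(a$id, b$id)) {
    rlang::abort("self-distance is undefined (identical cell ids)",
                 class = "marrowmap_self_distance")
  }
  dx <- a$x_um - b$x_um; dy <- a$y_um - b$y_um; dz <- a$z_um - b$z_um
  unname(sqrt(dx^2 + dy^2 + dz^2) - a$radius_um - b$radius_um)
}

# Dense (ns x nt) matrix of gap distances between two cell tables.
pairwise_gap_matrix <- function(src, tgt) {
  S <- cells_xyz(src); T_ <- cells_xyz(tgt)
  d2 <- outer(rowSums(S^2), rep(1, nrow(T_))) +
    outer(rep(1, nrow(S)), rowSums(T_^2)) - 2 * S %*% t(T_)
  d2[d2 < 0] <- 0
  sqrt(d2) - outer(src$radius_um, rep(1, nrow(T_))) -
    outer(rep(1, nrow(S)), tgt$radius_um)
}

#' Radius-corrected distance from cells to the closest vessel of a class
#'
#' For each cell, the minimum over all capsule segments of the requested
#' class of (distance from the cell centre to the segment polyline, minus
#' the vessel radius, minus the cell radius). The result is the
#' surface-to-surface gap; values at or below `contact_tolerance` classify
#' the cell as in direct contact with the vessel.
#'
#' @param cells cell table (`id`, `x_um`, `y_um`, `z_um`, `radius_um`).
#' @param network a [vessel_network()].
#' @param vclass `"sinusoid"` or `"arteriole"`.
#' @param contact_tolerance contact gap threshold in um (default 0.5).
#' @return tibble `id`, `target`, `gap_um`, `nearest_id`, `contact`.
#' @export
distance_to_vessel <- function(cells, network, vclass = c("sinusoid", "arteriole"),
                               contact_tolerance = 0.5) {
  vclass <- match.arg(vclass)
  segs <- segment_list(network, vclass)
  if (length(segs) == 0) {
    rlang::abort(paste0("no vessel segments of class '", vclass, "'"),
                 class = "marrowmap_empty_target")
  }
  P <- cells_xyz(cells)
  best <- rep(Inf, nrow(cells))
  best_id <- rep(NA_character_, nrow(cells))
  for (s in segs) {
    d <- point_polyline_distance(P, s$pts) - s$radius
    upd <- d < best
    best[upd] <- d[upd]
    best_id[upd] <- as.character(s$segment_id)
  }
  gap <- best - cells$radius_um
  tibble::tibble(id = cells$id, target = vclass, gap_um = gap,
                 nearest_id = best_id, contact = gap <= contact_tolerance)
}

#' Nearest radius-corrected distance from each source cell to a target type
#'
#' One row per source cell: the minimum surface-to-surface gap to any
#' target-type cell, the source cell itself excluded from its own targets.
#' Uses a uniform-grid spatial index for large target sets and a dense
#' all-pairs scan otherwise; both paths return identical results.
#'
#' @param cells cell table.
#' @param source_type,target_type character vectors of catalogue type names.
#' @param method `"auto"`, `"brute"` or `"grid"`.
#' @return tibble `id`, `target`, `gap_um`, `nearest_id`.
#' @export
nearest_by_type <- function(cells, source_type, target_type,
                            method = c("auto", "brute", "grid")) {
  method <- match.arg(method)
  src <- cells[cells$cell_type %in% source_type, , drop = FALSE]
  tgt <- cells[cells$cell_type %in% target_type, , drop = FALSE]
  if (nrow(src) == 0) {
    return(tibble::tibble(id = character(), target = character(),
                          gap_um = double(), nearest_id = character()))
  }
  if (nrow(tgt) == 0) {
    rlang::abort("no target cells of the requested type", class = "marrowmap_empty_target")
  }
  nearest_gap(src, tgt, exclude_self = TRUE, method = method) |>
    dplyr::mutate(target = paste(target_type, collapse = "+"), .after = "id")
}

# Nearest-gap query: for each source row, min gap over target rows.
# exclude_self drops same-id pairs. Grid and brute paths must agree.
nearest_gap <- function(src, tgt, exclude_self = TRUE,
                        method = c("auto", "brute", "grid")) {
  method <- match.arg(method)
  ns <- nrow(src); nt <- nrow(tgt)
  if (method == "auto") {
    method <- if (as.double(ns) * nt > 4e6) "grid" else "brute"
  }
  if (method == "brute") {
    g <- pairwise_gap_matrix(src, tgt)
    if (exclude_self) {
      same <- outer(src$id, tgt$id, `==`)
      g[same] <- Inf
    }
    j <- max.col(-g, ties.method = "first")
    tibble::tibble(id = src$id,
                   gap_um = g[cbind(seq_len(ns), j)],
                   nearest_id = tgt$id[j])
  } else {
    grid_nearest_gap(src, tgt, exclude_self = exclude_self)
  }
}

# Uniform-grid accelerated nearest neighbour (by gap distance). Bins the
# targets on a cubic grid and expands Chebyshev rings around each source
# until no unexplored ring can contain a better gap. The radius spread of
# the targets is folded into the stopping bound so varying radii stay exact.
grid_nearest_gap <- function(src, tgt, exclude_self = TRUE, cell_size = NULL) {
  T_ <- cells_xyz(tgt)
  S <- cells_xyz(src)
  max_rt <- max(tgt$radius_um)
  if (is.null(cell_size)) {
    bb <- apply(T_, 2, range)
    vol <- prod(pmax(bb[2, ] - bb[1, ], 1))
    cell_size <- max((vol / nrow(tgt))^(1 / 3), 1)
  }
  key <- function(M) floor(sweep(M, 2, c(0, 0, 0)) / cell_size)
  tk <- key(T_)
  tkey <- paste(tk[, 1], tk[, 2], tk[, 3])
  bins <- split(seq_len(nrow(tgt)), tkey)
  sk <- key(S)
  out_gap <- numeric(nrow(src)); out_id <- character(nrow(src))
  max_ring <- max(abs(range(tk))) + max(abs(range(sk))) + 2L
  for (i in seq_len(nrow(src))) {
    base <- sk[i, ]
    best <- Inf; best_j <- NA_integer_
    ring <- 0L
    repeat {
      # indices of grid cells on Chebyshev shell `ring`
      cand <- integer(0)
      offs <- seq(-ring, ring)
      for (dx in offs) for (dy in offs) for (dz in offs) {
        if (max(abs(c(dx, dy, dz))) != ring) next
        k <- paste(base[1] + dx, base[2] + dy, base[3] + dz)
        b <- bins[[k]]
        if (!is.null(b)) cand <- c(cand, b)
      }
      if (length(cand)) {
        if (exclude_self) cand <- cand[tgt$id[cand] != src$id[i]]
        if (length(cand)) {
          d <- sqrt(colSums((t(T_[cand, , drop = FALSE]) - S[i, ])^2)) -
            src$radius_um[i] - tgt$radius_um[cand]
          jmin <- which.min(d)
          if (d[jmin] < best) { best <- d[jmin]; best_j <- cand[jmin] }
        }
      }
      # smallest centre distance reachable from an unexplored ring
      lower <- ring * cell_size - src$radius_um[i] - max_rt
      if ((is.finite(best) && lower > best) || ring > max_ring) break
      ring <- ring + 1L
    }
    out_gap[i] <- best; out_id[i] <- if (is.na(best_j)) NA_character_ else tgt$id[best_j]
  }
  tibble::tibble(id = src$id, gap_um = out_gap, nearest_id = out_id)
}

#' Radius-corrected distance from cells to the endosteal surface
#'
#' The endosteum is modelled as the two bone-facing planes bounding the
#' slab in y; the gap is the distance to the nearer plane minus the cell
#' radius.
#'
#' @param cells cell table.
#' @param volume a [tissue_volume()].
#' @return tibble `id`, `target`, `gap_um`.
#' @export
distance_to_endosteum <- function(cells, volume) {
  y0 <- volume$origin[2]
  y1 <- volume$origin[2] + volume$extent[2]
  d <- pmin(cells$y_um - y0, y1 - cells$y_um)
  tibble::tibble(id = cells$id, target = "endosteum",
                 gap_um = d - cells$radius_um)
}

#' Vessel morphometry
#'
#' Per-vessel length (polyline arc length between branch points), diameter
#' (largest diameter recorded along the vessel) and class, plus the network
#' branch count as an attribute.
#'
#' @param network a [vessel_network()].
#' @return tibble `segment_id`, `vclass`, `length_um`, `diameter_um`, with
#'   attributes `n_branches` and `branch_points`.
#' @export
measure_vessels <- function(network) {
  df <- tibble::as_tibble(network)
  per_seg <- df |>
    dplyr::group_by(.data$segment_id, .data$vclass) |>
    dplyr::summarise(
      length_um = sum(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2 + diff(.data$z_um)^2)),
      diameter_um = 2 * max(.data$radius_um),
      .groups = "drop"
    )
  degenerate <- per_seg$length_um <= 0
  if (any(degenerate)) {
    rlang::warn(paste0("skipping ", sum(degenerate), " zero-length vessel(s)"))
    per_seg <- per_seg[!degenerate, , drop = FALSE]
  }
  bp <- branch_points(network)
  attr(per_seg, "n_branches") <- nrow(bp)
  attr(per_seg, "branch_points") <- bp
  per_seg
}

#' Daughter-cell separation after division
#'
#' Centre-to-centre distance between two daughter-cell tracks at a given
#' time after division, classified against a separation threshold (strictly
#' greater than 50 um by default). If the query time falls between frames,
#' positions are linearly interpolated, but only when the flanking frames
#' are adjacent (no more than one frame interval apart); otherwise a
#' missing-data error is raised.
#'
#' @param track_a,track_b tibbles with `t_h`, `x_um`, `y_um`, `z_um`.
#' @param t_after_division query time (same units as `t_h`).
#' @param threshold_um separation threshold, default 50.
#' @return tibble `t_h`, `separation_um`, `separated`.
#' @export
daughter_separation <- function(track_a, track_b, t_after_division,
                                threshold_um = 50) {
  pos_at <- function(track, t) {
    track <- dplyr::arrange(track, .data$t_h)
    hit <- which(abs(track$t_h - t) < 1e-9)
    if (length(hit)) return(as.numeric(track[hit[1], c("x_um", "y_um", "z_um")]))
    lo <- max(which(track$t_h < t)); hi <- min(which(track$t_h > t))
    if (!is.finite(lo) || !is.finite(hi) || lo < 1 || hi > nrow(track)) {
      rlang::abort("track does not cover the query time", class = "marrowmap_missing_data")
    }
    frame <- min(diff(track$t_h))
    if (track$t_h[hi] - track$t_h[lo] > frame * 1.5) {
      rlang::abort("track gap at query time exceeds one frame; cannot interpolate",
                   class = "marrowmap_missing_data")
    }
    w <- (t - track$t_h[lo]) / (track$t_h[hi] - track$t_h[lo])
    (1 - w) * as.numeric(track[lo, c("x_um", "y_um", "z_um")]) +
      w * as.numeric(track[hi, c("x_um", "y_um", "z_um")])
  }
  pa <- pos_at(track_a, t_after_division)
  pb <- pos_at(track_b, t_after_division)
  sep <- sqrt(sum((pa - pb)^2))
  tibble::tibble(t_h = t_after_division, separation_um = sep,
                 separated = sep > threshold_um)
}
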