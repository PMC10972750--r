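# Shared fixtures: all built in code at test time.

# A single straight vessel along x at height z, as a network table.
straight_vessel <- function(id = "v1", vclass = "sinusoid", radius = 10,
                            from = c(0, 0, 17.5), to = c(100, 0, 17.5)) {
  vessel_network(tibble::tibble(
    segment_id = id, vclass = vclass, radius_um = radius,
    point_index = 1:2,
    x_um = c(from[1], to[1]), y_um = c(from[2], to[2]), z_um = c(from[3], to[3])
  ))
}

# Y-shaped network: three segments sharing one endpoint.
y_network <- function(radius = 8) {
  hub <- c(100, 100, 17.5)
  mk <- function(id, to) tibble::tibble(
    segment_id = id, vclass = "sinusoid", radius_um = radius, point_index = 1:2,
    x_um = c(hub[1], to[1]), y_um = c(hub[2], to[2]), z_um = c(hub[3], to[3]))
  vessel_network(dplyr::bind_rows(mk("a", c(0, 100, 17.5)),
                                  mk("b", c(200, 0, 17.5)),
                                  mk("c", c(200, 200, 17.5))))
}

# Minimal cell table from coordinates.
toy_cells <- function(xyz, cell_type = "CFU-E", radius = NULL, id_prefix = "c",
                      confetti = "none") {
  xyz <- rbind(xyz)
  tibble::tibble(
    id = sprintf("%s%03d", id_prefix, seq_len(nrow(xyz))),
    cell_type = cell_type,
    x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
    radius_um = if (is.null(radius)) catalog_radius(cell_type) else radius,
    confetti = confetti
  )
}

# A scaled-down generator configuration that keeps every placement process
# and all four site lineages but runs in well under a second.
small_config <- function(...) {
  marrow_config(
    volume = list(extent = c(1600, 900, 35)),
    pool_count = 2000,
    vessels = list(n_sinusoid = 22, n_arteriole = 8),
    megakaryocytes = list(count = 15, radius_um = 15),
    hspc = list(counts = c("CD41- LT-HSC" = 3, "ST-HSC" = 4, "MPP3" = 3)),
    progenitors = list(counts = c("MkP" = 4, "pre Meg-E" = 5, "pre CFU-E" = 10)),
    erythroid_sites = list(n_sites = 4),
    b_sites = list(n_sites = 3),
    neutrophil_sites = list(n_sites = 3),
    monoDC_sites = list(n_sites = 2),
    ...
  )
}

# Independent brute-force oracle for surface-to-surface gaps (a separate
# code path from the package's matrix computation).
oracle_gap <- function(a, b) {
  sqrt((a$x_um - b$x_um)^2 + (a$y_um - b$y_um)^2 + (a$z_um - b$z_um)^2) -
    a$radius_um - b$radius_um
}

# Dense-sampling oracle for cell-to-capsule distance: walk the polyline in
# ~1 um steps and take the minimal distance to the sampled axis points.
oracle_vessel_gap <- function(cell, network, vclass) {
  df <- tibble::as_tibble(network)
  df <- df[df$vclass == vclass, ]
  best <- Inf
  for (sid in unique(df$segment_id)) {
    s <- df[df$segment_id == sid, ]
    s <- s[order(s$point_index), ]
    pts <- cbind(s$x_um, s$y_um, s$z_um)
    for (i in seq_len(nrow(pts) - 1)) {
      seg_len <- sqrt(sum((pts[i + 1, ] - pts[i, ])^2))
      tt <- seq(0, 1, length.out = max(ceiling(seg_len), 2) + 1)
      samp <- cbind(pts[i, 1] + tt * (pts[i + 1, 1] - pts[i, 1]),
                    pts[i, 2] + tt * (pts[i + 1, 2] - pts[i, 2]),
                    pts[i, 3] + tt * (pts[i + 1, 3] - pts[i, 3]))
      d <- sqrt((samp[, 1] - cell$x_um)^2 + (samp[, 2] - cell$y_um)^2 +
                  (samp[, 3] - cell$z_um)^2)
      best <- min(best, min(d) - s$radius_um[1] - cell$radius_um)
    }
  }
  best
}
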