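test_that("cell-cell gap subtracts both radii and preserves negative gaps", {
  a <- toy_cells(c(0, 0, 0), radius = 5, id_prefix = "a")
  b <- toy_cells(c(20, 0, 0), radius = 5, id_prefix = "b")
  expect_equal(gap_distance_cells(a, b), 10)
  # coincident centres interpenetrate
  b2 <- toy_cells(c(0, 0, 0), radius = 6, id_prefix = "b")
  a2 <- toy_cells(c(0, 0, 0), radius = 4, id_prefix = "a")
  expect_equal(gap_distance_cells(a2, b2), -10)
  expect_error(gap_distance_cells(a, a), class = "marrowmap_self_distance")
})

test_that("gap distance matches an independent recomputation on 1,000 random pairs and is symmetric", {
  set.seed(1)
  A <- toy_cells(matrix(runif(3000, 0, 500), ncol = 3), radius = NULL, id_prefix = "a")
  B <- toy_cells(matrix(runif(3000, 0, 500), ncol = 3), radius = NULL, id_prefix = "b")
  A$radius_um <- runif(1000, 2, 10); B$radius_um <- runif(1000, 2, 10)
  for (i in seq(1, 1000, by = 37)) {
    g <- gap_distance_cells(A[i, ], B[i, ])
    expect_equal(g, oracle_gap(A[i, ], B[i, ]), tolerance = 1e-9)
    expect_equal(g, gap_distance_cells(B[i, ], A[i, ]), tolerance = 1e-12)
  }
  # full matrix path agrees too
  g_mat <- marrowmap:::pairwise_gap_matrix(A, B)
  expect_equal(diag(g_mat), oracle_gap(A, B), tolerance = 1e-9)
})

test_that("cell-to-vessel distance handles the canonical capsule cases", {
  net <- straight_vessel(radius = 10, from = c(0, 0, 17.5), to = c(100, 0, 17.5))
  # perpendicular distance 20 from the axis, cell radius 5 -> gap 5
  cell <- toy_cells(c(50, 20, 17.5), radius = 5)
  expect_equal(distance_to_vessel(cell, net, "sinusoid")$gap_um, 5)
  # centre on the axis: gap = -(vessel radius + cell radius)
  on_axis <- toy_cells(c(50, 0, 17.5), radius = 5)
  expect_equal(distance_to_vessel(on_axis, net, "sinusoid")$gap_um, -15)
  expect_error(distance_to_vessel(cell, net, "arteriole"),
               class = "marrowmap_empty_target")
})

test_that("capsule distances agree with a dense polyline-sampling oracle on random scenes", {
  set.seed(2)
  cfg <- marrow_config(vessels = list(n_sinusoid = 4, n_arteriole = 2))
  net <- place_vessel_network(cfg, seed = 2)
  cells <- toy_cells(cbind(runif(40, 0, 2400), runif(40, 0, 1200), runif(40, 0, 35)),
                     radius = 5)
  got <- distance_to_vessel(cells, net, "sinusoid")
  for (i in seq_len(nrow(cells))) {
    expect_equal(got$gap_um[i], oracle_vessel_gap(cells[i, ], net, "sinusoid"),
                 tolerance = 0.01)
  }
})

test_that("nearest-by-type excludes self, matches brute force, and the grid index is exact", {
  set.seed(3)
  n <- 400
  cells <- toy_cells(cbind(runif(n, 0, 800), runif(n, 0, 500), runif(n, 0, 35)),
                     cell_type = sample(c("CFU-E", "pre B", "CLP"), n, TRUE))
  cells$radius_um <- catalog_radius(cells$cell_type)
  # single source-target pair
  a <- toy_cells(c(0, 0, 0), cell_type = "CLP", radius = 5, id_prefix = "s")
  b <- toy_cells(c(50, 0, 0), cell_type = "pre B", radius = 5, id_prefix = "t")
  one <- nearest_by_type(dplyr::bind_rows(a, b), "CLP", "pre B")
  expect_equal(one$gap_um, 40)
  # same type as source and target: nearest is never itself
  three <- toy_cells(rbind(c(0, 0, 0), c(30, 0, 0), c(70, 0, 0)), cell_type = "CLP")
  res3 <- nearest_by_type(three, "CLP", "CLP")
  expect_false(any(res3$nearest_id == res3$id))
  # brute-force all-pairs oracle on the full scene
  res <- nearest_by_type(cells, "CFU-E", "pre B", method = "brute")
  src <- cells[cells$cell_type == "CFU-E", ]
  tgt <- cells[cells$cell_type == "pre B", ]
  for (i in seq_len(nrow(src))) {
    gaps <- oracle_gap(src[i, ], tgt)
    expect_equal(res$gap_um[i], min(gaps), tolerance = 1e-9)
  }
  # grid index returns exactly the brute-force result
  grid <- nearest_by_type(cells, "CFU-E", "pre B", method = "grid")
  expect_equal(grid$gap_um, res$gap_um, tolerance = 1e-12)
  expect_equal(grid$nearest_id, res$nearest_id)
  # and with same-type self-exclusion plus varying radii
  cells$radius_um <- cells$radius_um + runif(n, 0, 3)
  g2 <- nearest_by_type(cells, "CLP", "CLP", method = "grid")
  b2 <- nearest_by_type(cells, "CLP", "CLP", method = "brute")
  expect_equal(g2$gap_um, b2$gap_um, tolerance = 1e-12)
})

test_that("adding a target never increases any source's nearest distance", {
  set.seed(4)
  cells <- toy_cells(matrix(runif(300, 0, 400), ncol = 3), cell_type = "CFU-E")
  extra <- toy_cells(matrix(runif(30, 0, 400), ncol = 3), cell_type = "CFU-E",
                     id_prefix = "x")
  before <- nearest_by_type(dplyr::bind_rows(cells), "CFU-E", "CFU-E")
  after <- nearest_by_type(dplyr::bind_rows(cells, extra), "CFU-E", "CFU-E")
  expect_true(all(after$gap_um[match(before$id, after$id)] <= before$gap_um + 1e-12))
})

test_that("vessel morphometry: length, diameter, branches", {
  one <- straight_vessel(radius = 8, from = c(0, 0, 17.5), to = c(100, 0, 17.5))
  m1 <- measure_vessels(one)
  expect_equal(m1$length_um, 100)
  expect_equal(m1$diameter_um, 16)
  expect_equal(attr(m1, "n_branches"), 0L)
  # Y network: 3 vessels, 1 branch
  my <- measure_vessels(y_network())
  expect_equal(nrow(my), 3L)
  expect_equal(attr(my, "n_branches"), 1L)
  expect_equal(nrow(branch_points(y_network())), 1L)
  # tortuous polylines: arc length equals independently summed chords
  set.seed(5)
  pts <- cbind(cumsum(runif(8, 5, 30)), cumsum(rnorm(8, 0, 10)), runif(8, 5, 30))
  net <- vessel_network(tibble::tibble(
    segment_id = "t", vclass = "sinusoid", radius_um = 6,
    point_index = seq_len(nrow(pts)), x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3]))
  expected_len <- sum(sqrt(rowSums((pts[-1, ] - pts[-nrow(pts), ])^2)))
  expect_equal(measure_vessels(net)$length_um, expected_len, tolerance = 1e-9)
})

test_that("daughter separation classifies strictly above 50 um and interpolates only adjacent frames", {
  mk_track <- function(xyz_by_t) {
    tibble::tibble(t_h = as.numeric(names(xyz_by_t)),
                   x_um = sapply(xyz_by_t, `[`, 1),
                   y_um = sapply(xyz_by_t, `[`, 2),
                   z_um = sapply(xyz_by_t, `[`, 3))
  }
  still <- mk_track(list("0" = c(0, 0, 0), "1" = c(0, 0, 0), "2" = c(0, 0, 0)))
  res0 <- daughter_separation(still, still, 2)
  expect_equal(res0$separation_um, 0)
  expect_false(res0$separated)
  far <- mk_track(list("0" = c(0, 0, 0), "1" = c(30, 0, 0), "2" = c(60, 0, 0)))
  res <- daughter_separation(still, far, 2)
  expect_equal(res$separation_um, 60)
  expect_true(res$separated)
  # exactly 50 um is not "separated" (strict inequality)
  at50 <- mk_track(list("0" = c(0, 0, 0), "2" = c(50, 0, 0)))
  expect_false(daughter_separation(mk_track(list("0" = c(0, 0, 0), "2" = c(0, 0, 0))),
                                   at50, 2)$separated)
  # missing frame beyond one interval: error
  gappy <- mk_track(list("0" = c(0, 0, 0), "0.25" = c(1, 0, 0), "2" = c(8, 0, 0)))
  expect_error(daughter_separation(gappy, gappy, 1),
               class = "marrowmap_missing_data")
})

test_that("a simulated division cohort's separated fraction matches per-track enumeration", {
  set.seed(6)
  frames <- seq(0, 2, by = 0.25)
  cohort <- purrr::map(1:30, function(i) {
    speed <- runif(1, 5, 40)  # um/h random-walk scale
    walk <- function() {
      steps <- matrix(rnorm(3 * (length(frames) - 1), 0, speed * 0.25), ncol = 3)
      pos <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
      tibble::tibble(t_h = frames, x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
    }
    list(a = walk(), b = walk())
  })
  got <- vapply(cohort, function(tr) daughter_separation(tr$a, tr$b, 2)$separated, logical(1))
  oracle <- vapply(cohort, function(tr) {
    pa <- unlist(tr$a[tr$a$t_h == 2, c("x_um", "y_um", "z_um")])
    pb <- unlist(tr$b[tr$b$t_h == 2, c("x_um", "y_um", "z_um")])
    sqrt(sum((pa - pb)^2)) > 50
  }, logical(1))
  expect_equal(got, oracle)
})

test_that("endosteal distance uses the nearer bone-facing plane minus the radius", {
  vol <- tissue_volume(c(100, 80, 35))
  cells <- toy_cells(rbind(c(50, 10, 17), c(50, 70, 17)), radius = 4)
  d <- distance_to_endosteum(cells, vol)
  expect_equal(d$gap_um, c(6, 6))
})
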