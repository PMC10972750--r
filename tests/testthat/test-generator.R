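test_that("configuration invariants are enforced", {
  expect_error(marrow_config(confetti = list(fraction = 1.5)),
               class = "marrowmap_config_error")
  expect_error(marrow_config(erythroid_sites = list(string_size = list(min = 2, max = 23, mean = 8, sd = 4))),
               class = "marrowmap_config_error")
  expect_error(marrow_config(volume = list(extent = c(-1, 10, 35))),
               class = "marrowmap_config_error")
})

test_that("identical config and seed reproduce byte-identical scenes", {
  cfg <- small_config()
  s1 <- simulate_marrow(cfg, seed = 5)
  s2 <- simulate_marrow(cfg, seed = 5)
  expect_identical(s1$cells, s2$cells)
  expect_identical(tibble::as_tibble(s1$vessels), tibble::as_tibble(s2$vessels))
  expect_identical(s1$truth$sites, s2$truth$sites)
  s3 <- simulate_marrow(cfg, seed = 6)
  expect_false(identical(s1$cells, s3$cells))
})

test_that("the background pool count and planted site counts are forced by the config", {
  cfg <- small_config(pool_count = 5000)
  scene <- simulate_marrow(cfg, seed = 2)
  expect_equal(sum(scene$cells$cell_type == "BM"), 5000L)
  planted <- unique(scene$truth$sites[, c("site_id", "lineage")])
  expect_equal(sum(planted$lineage == "erythroid"), 4L)
  expect_equal(sum(planted$lineage == "B"), 3L)
  # every erythroid string is attached to exactly one anchor segment
  ery <- scene$truth$sites[scene$truth$sites$lineage == "erythroid", ]
  anchors_per_site <- tapply(ery$anchor_id, ery$site_id,
                             function(a) length(unique(a)))
  expect_true(all(anchors_per_site == 1L))
  expect_length(anchors_per_site, 4L)
})

test_that("vessel polylines stay inside the volume and branch semantics hold", {
  cfg <- marrow_config()
  net <- place_vessel_network(cfg, seed = 3)
  vol <- tissue_volume(cfg$volume$extent)
  df <- tibble::as_tibble(net)
  expect_true(all(in_volume(cbind(df$x_um, df$y_um, df$z_um), vol)))
  # sinusoids dominate in count
  per_class <- table(unique(df[, c("segment_id", "vclass")])$vclass)
  expect_gt(per_class[["sinusoid"]], per_class[["arteriole"]])
  # single straight segment between two points: 1 segment, 0 branches
  one <- straight_vessel()
  expect_equal(nrow(branch_points(one)), 0L)
  expect_equal(length(unique(one$segment_id)), 1L)
  # Y-shaped: 1 branch
  expect_equal(nrow(branch_points(y_network())), 1L)
  # zero segments: valid empty network with a message
  empty_cfg <- marrow_config(vessels = list(n_sinusoid = 0, n_arteriole = 0))
  expect_message(empty <- place_vessel_network(empty_cfg, seed = 1))
  expect_equal(nrow(tibble::as_tibble(empty)), 0L)
})

test_that("every generated cell centre lies inside the tissue volume", {
  scene <- simulate_marrow(small_config(), seed = 4)
  expect_true(all(in_volume(cbind(scene$cells$x_um, scene$cells$y_um,
                                  scene$cells$z_um), scene$volume)))
})

test_that("HSPC repulsion enforces the hard core and zero counts give empty output", {
  cfg <- marrow_config(hspc = list(counts = c("ST-HSC" = 30), repulsion_um = 100,
                                   mk_weight = 0, arteriole_weight = 0))
  vol <- tissue_volume(cfg$volume$extent)
  scene0 <- list(vessels = place_vessel_network(cfg, seed = 8),
                 volume = vol,
                 megakaryocytes = toy_cells(matrix(runif(30, 100, 900), 10, 3),
                                            cell_type = "MK", radius = 15))
  hspc <- place_hspc(cfg, scene0, seed = 8)
  expect_equal(nrow(hspc), 30L)
  # brute-force pairwise scan: no pair closer than half the repulsion scale
  P <- cbind(hspc$x_um, hspc$y_um, hspc$z_um)
  dmin <- min(dist(P))
  expect_gte(dmin, 50)
  # zero-count type is simply absent
  cfg0 <- marrow_config(hspc = list(counts = c("ST-HSC" = 0)))
  expect_equal(nrow(place_hspc(cfg0, scene0, seed = 1)), 0L)
})

test_that("an incompatible repulsion scale raises a placement failure", {
  cfg <- marrow_config(volume = list(extent = c(200, 200, 35)),
                       hspc = list(counts = c("ST-HSC" = 60), repulsion_um = 120))
  scene0 <- list(vessels = place_vessel_network(marrow_config(), seed = 1),
                 volume = tissue_volume(c(200, 200, 35)),
                 megakaryocytes = toy_cells(matrix(0, 0, 3), cell_type = "MK"))
  expect_error(place_hspc(cfg, scene0, seed = 1),
               class = "marrowmap_placement_failure")
})

test_that("with zero biases HSPC placement is indistinguishable from the random-cell null", {
  # megakaryocyte weight 0: the HSPC-MK median distance should sit inside
  # the random-placement null band
  cfg <- marrow_config(hspc = list(counts = c("ST-HSC" = 25), repulsion_um = 0,
                                   mk_weight = 0, arteriole_weight = 0),
                       pool_count = 4000)
  scene <- simulate_marrow(cfg, seed = 11)
  hspc <- scene$cells[scene$cells$cell_type == "ST-HSC", ]
  obs <- nearest_by_type(scene$cells, "ST-HSC", "MK")
  pool <- build_pool(scene$cells)
  reps <- sample_random_cells(pool, c("ST-HSC" = nrow(hspc)), n_reps = 100, seed = 12)
  nul <- null_distances(reps, "MK", cells = scene$cells)
  res <- compare_to_null(obs, nul, alpha = 0.01)
  expect_equal(res$call, "ns")
})

test_that("more sites than available sinusoid chains is an explicit placement failure", {
  cfg <- small_config(vessels = list(n_sinusoid = 3, n_arteriole = 6, branch_prob = 0),
                      erythroid_sites = list(n_sites = 3),
                      neutrophil_sites = list(n_sites = 2),
                      monoDC_sites = list(n_sites = 1))
  expect_error(simulate_marrow(cfg, seed = 1),
               class = "marrowmap_placement_failure")
})

test_that("confetti labelling honours the fraction and the clone policies", {
  cells <- toy_cells(matrix(runif(600, 0, 300), ncol = 3), cell_type = "BM",
                     id_prefix = "p")
  conf <- marrow_config()$confetti
  # fraction 0: nothing labelled
  conf0 <- conf; conf0$fraction <- 0
  out0 <- assign_confetti(cells, conf0, seed = 1)
  expect_true(all(out0$cells$confetti == "none"))
  # fraction 1 with a monoclonal cluster: all members share one colour
  clus <- toy_cells(matrix(runif(120, 0, 50), ncol = 3),
                    cell_type = "late erythroblast", id_prefix = "lb")
  truth <- tibble::tibble(site_id = "ery_01", lineage = "erythroid",
                          anchor_id = "sin_01", cell_id = clus$id,
                          role = "cluster", cluster_id = "ery_01_c1")
  conf1 <- conf; conf1$fraction <- 1
  out1 <- assign_confetti(clus, conf1, truth, seed = 2)
  expect_equal(length(unique(out1$cells$confetti)), 1L)
  expect_equal(nrow(out1$cells), 40L)
  # labelled fraction within 3 binomial s.e. at the default recombination rate
  big <- toy_cells(matrix(runif(3e5, 0, 1000), ncol = 3), cell_type = "BM",
                   id_prefix = "q")
  out <- assign_confetti(big, conf, seed = 3)
  frac <- mean(out$cells$confetti != "none")
  se <- sqrt(0.073 * (1 - 0.073) / nrow(big))
  expect_lt(abs(frac - 0.073), 3 * se)
  # invalid fraction
  confbad <- conf; confbad$fraction <- -0.1
  expect_error(assign_confetti(cells, confbad), class = "marrowmap_config_error")
})

test_that("clone identities are consistent with colours and truth sites reference real cells", {
  scene <- simulate_marrow(small_config(), seed = 9)
  expect_true(all(scene$truth$sites$cell_id %in% scene$cells$id))
  clones <- scene$truth$clones
  lab <- scene$cells[scene$cells$confetti != "none", ]
  m <- merge(lab, clones, by.x = "id", by.y = "cell_id")
  # a labelled cell displays its clone colour
  expect_true(all(m$confetti == m$colour))
  # within a clone, all labelled members share the colour
  per_clone <- tapply(m$confetti, m$clone_id, function(x) length(unique(x)))
  expect_true(all(per_clone == 1))
})

test_that("presets alter only site counts and compositions", {
  base <- marrow_config()
  phl <- marrow_preset("phlebotomy_d2")
  expect_equal(phl$erythroid_sites$n_sites, 20)
  expect_equal(phl$pool_count, base$pool_count)
  expect_equal(phl$volume, base$volume)
  expect_equal(phl$vessels, base$vessels)
  expect_equal(phl$confetti, base$confetti)
  gt <- marrow_preset("gcsf_tibia")
  expect_gt(gt$neutrophil_sites$n_sites, base$neutrophil_sites$n_sites)
})
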