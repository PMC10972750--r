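# Helper: CFU-E string laid along a straight sinusoid at y = y0.
string_on_vessel <- function(n, y0 = 0, x0 = 10, id_prefix = "s",
                             radius_v = 10, z = 17.5) {
  r <- catalog_radius("CFU-E")
  xs <- x0 + (seq_len(n) - 1) * (2 * r + 0.5)
  toy_cells(cbind(xs, y0 + radius_v + r, z), cell_type = "CFU-E",
            id_prefix = id_prefix)
}

test_that("contiguous CFU-E on one sinusoid form one string; sub-threshold groups do not", {
  net <- straight_vessel(radius = 10, from = c(0, 0, 17.5), to = c(500, 0, 17.5))
  five <- string_on_vessel(5)
  st <- detect_cfu_e_strings(five, net)
  expect_equal(attr(st, "n_strings"), 1L)
  expect_setequal(st$cell_id, five$id)
  # 2 CFU-E only: below the minimum of 3
  two <- string_on_vessel(2)
  st2 <- detect_cfu_e_strings(two, net)
  expect_equal(attr(st2, "n_strings"), 0L)
  # CFU-E away from any sinusoid are ignored
  free <- toy_cells(cbind(250, 200, 17.5), cell_type = "CFU-E", id_prefix = "f")
  st3 <- detect_cfu_e_strings(dplyr::bind_rows(five, free), net)
  expect_false(any(st3$cell_id == free$id))
})

test_that("erythroid capture attaches at 49 um but not 51 um and partitions between strings", {
  net <- straight_vessel(radius = 10, from = c(0, 0, 17.5), to = c(900, 0, 17.5))
  s1 <- string_on_vessel(4, id_prefix = "a", x0 = 10)
  st <- detect_cfu_e_strings(s1, net)
  member <- s1[1, ]
  r_eb <- catalog_radius("early erythroblast")
  mk_eb <- function(gap, id) toy_cells(
    cbind(member$x_um, member$y_um + member$radius_um + r_eb + gap, member$z_um),
    cell_type = "early erythroblast", id_prefix = id)
  near <- mk_eb(49, "near"); far <- mk_eb(51, "far")
  ery <- assemble_erythroid_sites(st, dplyr::bind_rows(s1, near, far))
  expect_true(near$id %in% ery$members$cell_id)
  expect_false(far$id %in% ery$members$cell_id)
})

test_that("cells between two distant strings attach only to the nearer one", {
  net <- straight_vessel(radius = 10, from = c(0, 0, 17.5), to = c(900, 0, 17.5))
  a <- string_on_vessel(3, id_prefix = "a", x0 = 10)
  b <- string_on_vessel(3, id_prefix = "b", x0 = 700)
  cells_all <- dplyr::bind_rows(a, b)
  st <- detect_cfu_e_strings(cells_all, net)
  expect_equal(attr(st, "n_strings"), 2L)
  # erythroblasts scattered around both strings: exhaustive assignment scan
  set.seed(1)
  ebs <- toy_cells(cbind(runif(40, 0, 900), runif(40, 10, 60), 17.5),
                   cell_type = "late erythroblast", id_prefix = "e")
  ery <- assemble_erythroid_sites(st, dplyr::bind_rows(cells_all, ebs))
  att <- ery$members[ery$members$cell_type == "late erythroblast", ]
  expect_false(any(duplicated(att$cell_id)))
  # oracle: per attached cell, nearest string by explicit min over members
  strings_cells <- split(st$cell_id, st$string_id)
  for (i in seq_len(nrow(att))) {
    cell <- ebs[ebs$id == att$cell_id[i], ]
    gaps <- vapply(strings_cells, function(ids) {
      min(oracle_gap(cell, cells_all[cells_all$id %in% ids, ]))
    }, numeric(1))
    expect_equal(att$site_id[i], names(which.min(gaps)))
  }
})

test_that("B sites report planted stage counts and nearest-CLP assignment", {
  clp <- toy_cells(cbind(100, 100, 17.5), cell_type = "CLP", id_prefix = "clp")
  mk_stage <- function(ty, n, d, pre) {
    ang <- seq(0, 2 * pi, length.out = n + 1)[-1]
    toy_cells(cbind(100 + d * cos(ang), 100 + d * sin(ang), 17.5),
              cell_type = ty, id_prefix = pre)
  }
  cells_all <- dplyr::bind_rows(
    clp,
    mk_stage("pre-pro B", 2, 40, "pp"),
    mk_stage("pro B", 3, 80, "pb"),
    mk_stage("pre B", 16, 120, "qb"))
  res <- detect_b_sites(cells_all, NULL)
  expect_equal(nrow(res$sites), 1L)
  expect_equal(res$sites[["pre-pro B"]], 2L)
  expect_equal(res$sites[["pro B"]], 3L)
  expect_equal(res$sites[["pre B"]], 16L)
  # two CLPs: a pre B between them goes to the nearer only
  clp2 <- toy_cells(cbind(200, 100, 17.5), cell_type = "CLP", id_prefix = "cl2")
  between <- toy_cells(cbind(140, 100, 17.5), cell_type = "pre B", id_prefix = "bw")
  res2 <- detect_b_sites(dplyr::bind_rows(clp, clp2, between), NULL)
  att <- res2$members[res2$members$cell_id == between$id, ]
  expect_equal(nrow(att), 1L)
  expect_equal(att$clp_id, clp$id)
})

test_that("myeloid sites need sinusoid contact and report fate ratios", {
  net <- straight_vessel(radius = 10, from = c(0, 0, 17.5), to = c(500, 0, 17.5))
  r_gp <- catalog_radius("GP")
  gp_on <- toy_cells(cbind(100, 10 + r_gp, 17.5), cell_type = "GP", id_prefix = "on")
  gp_off <- toy_cells(cbind(300, 200, 17.5), cell_type = "GP", id_prefix = "off")
  pn <- toy_cells(cbind(100 + runif(6, -30, 30), 30 + runif(6, 0, 10), 17.5),
                  cell_type = "PN", id_prefix = "pn")
  res <- detect_myeloid_sites(dplyr::bind_rows(gp_on, gp_off, pn), net,
                              lineage = "neutrophil")
  expect_equal(nrow(res$sites), 1L)
  expect_equal(res$sites$PN, 6L)
  expect_equal(res$unanchored, gp_off$id)
  # mono/DC fate ratio
  r_mdp <- catalog_radius("MDP")
  mdp <- toy_cells(cbind(200, 10 + r_mdp, 17.5), cell_type = "MDP", id_prefix = "mdp")
  mono <- toy_cells(cbind(200 + runif(3, -20, 20), 35, 17.5), cell_type = "monocyte",
                    id_prefix = "mo")
  cdc <- toy_cells(cbind(200 + runif(1, -20, 20), 35, 17.5), cell_type = "cDC",
                   id_prefix = "dc")
  res2 <- detect_myeloid_sites(dplyr::bind_rows(mdp, mono, cdc), net,
                               lineage = "monoDC")
  expect_equal(res2$sites$cdc_fraction, 0.25)
})

test_that("census densities normalise by projected area", {
  vol <- tissue_volume(c(2000, 1000, 35))  # 2 mm^2
  members <- tibble::tibble(site_id = rep(paste0("s", 1:4), each = 3),
                            cell_id = paste0("c", 1:12),
                            cell_type = rep(c("GP", "PN", "PN"), 4), gap_um = 0)
  cen <- site_census(list(neutrophil = list(members = members)), vol)
  expect_equal(cen$n_sites, 4L)
  expect_equal(cen$density_per_mm2, 2)
  expect_equal(cen$mean_output, 2)
  # empty lineage: density 0
  cen0 <- site_census(list(erythroid = list(members = members[0, ])), vol)
  expect_equal(cen0$density_per_mm2, 0)
})

test_that("raising a capture radius never shrinks a site's output", {
  set.seed(3)
  net <- straight_vessel(radius = 10, from = c(0, 0, 17.5), to = c(600, 0, 17.5))
  s <- string_on_vessel(4)
  ebs <- toy_cells(cbind(runif(60, 0, 600), runif(60, 10, 150), 17.5),
                   cell_type = "late erythroblast", id_prefix = "e")
  st <- detect_cfu_e_strings(s, net)
  cells_all <- dplyr::bind_rows(s, ebs)
  prev <- -1
  for (r_cap in c(20, 50, 80, 120)) {
    p <- site_params(erythroid_capture_um = r_cap)
    n_att <- nrow(assemble_erythroid_sites(st, cells_all, p)$members)
    expect_gte(n_att, prev)
    prev <- n_att
  }
})

test_that("site detection recovers planted ground truth on generated scenes", {
  hits <- 0L; total <- 0L
  for (seed in 1:3) {
    scene <- simulate_marrow(small_config(), seed = seed)
    cells <- scene$cells
    tr <- scene$truth$sites
    params <- site_params()
    st <- detect_cfu_e_strings(cells, scene$vessels, params)
    expect_equal(attr(st, "n_strings"),
                 length(unique(tr$site_id[tr$lineage == "erythroid"])))
    truth_strings <- split(tr$cell_id[tr$role == "string"],
                           tr$site_id[tr$role == "string"])
    det_strings <- split(st$cell_id, st$string_id)
    hits <- hits + sum(vapply(truth_strings, function(ts) {
      any(vapply(det_strings, function(ds) setequal(ds, ts), logical(1)))
    }, logical(1)))
    total <- total + length(truth_strings)
    # B sites: per-stage counts equal truth
    b <- detect_b_sites(cells, scene$vessels, params)
    truth_b <- tr[tr$lineage == "B", ]
    for (sid in unique(truth_b$site_id)) {
      clp_id <- truth_b$anchor_id[truth_b$site_id == sid][1]
      det_row <- b$sites[b$sites$clp_id == clp_id, ]
      for (stg in c("pre-pro B", "pro B", "pre B")) {
        expect_equal(det_row[[stg]],
                     sum(truth_b$site_id == sid & truth_b$role == stg))
      }
    }
    # myeloid site counts equal planted counts
    neu <- detect_myeloid_sites(cells, scene$vessels, params, "neutrophil")
    expect_equal(nrow(neu$sites),
                 length(unique(tr$site_id[tr$lineage == "neutrophil"])))
    mdc <- detect_myeloid_sites(cells, scene$vessels, params, "monoDC")
    expect_equal(nrow(mdc$sites),
                 length(unique(tr$site_id[tr$lineage == "monoDC"])))
  }
  expect_equal(hits, total)
})

test_that("same-lineage sites partition their members", {
  scene <- simulate_marrow(small_config(), seed = 5)
  st <- detect_cfu_e_strings(scene$cells, scene$vessels)
  ery <- assemble_erythroid_sites(st, scene$cells)
  expect_false(any(duplicated(ery$members$cell_id)))
  b <- detect_b_sites(scene$cells, scene$vessels)
  expect_false(any(duplicated(b$members$cell_id)))
})
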