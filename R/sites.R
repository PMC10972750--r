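# Detection and censusing of lineage-specific production sites from
# classified cell coordinates and the vessel network.

#' Site-detection parameters
#'
#' Defaults: consecutive CFU-E in a string may be at most 10 um apart
#' surface-to-surface (about one CFU-E diameter); strings need at least 3
#' members; erythroid output is captured within 50 um of a string member
#' (the median distance expected for random cells), B-site stages within
#' 150 um of the CLP, myeloid progeny within 50 um of the focal
#' progenitor; direct vessel contact means a gap of at most 0.5 um.
#'
#' @param string_link_gap_um max surface gap linking consecutive string CFU-E.
#' @param min_string_size minimum CFU-E per string.
#' @param erythroid_capture_um erythroid output capture radius.
#' @param b_capture_um B-stage capture radius around each CLP.
#' @param myeloid_capture_um myeloid progeny capture radius.
#' @param contact_tolerance_um direct-contact gap threshold.
#' @param cluster_link_gap_um surface gap for single-linkage decomposition
#'   of late-erythroblast clusters within a site.
#' @return a `site_params` list.
#' @export
site_params <- function(string_link_gap_um = 10, min_string_size = 3,
                        erythroid_capture_um = 50, b_capture_um = 150,
                        myeloid_capture_um = 50, contact_tolerance_um = 0.5,
                        cluster_link_gap_um = 10) {
  stopifnot(string_link_gap_um > 0, min_string_size >= 2,
            erythroid_capture_um > 0, b_capture_um > 0, myeloid_capture_um > 0)
  structure(list(string_link_gap_um = string_link_gap_um,
                 min_string_size = min_string_size,
                 erythroid_capture_um = erythroid_capture_um,
                 b_capture_um = b_capture_um,
                 myeloid_capture_um = myeloid_capture_um,
                 contact_tolerance_um = contact_tolerance_um,
                 cluster_link_gap_um = cluster_link_gap_um),
            class = "site_params")
}

# single-linkage components of cells under a max surface gap
gap_components <- function(cells, link_gap) {
  n <- nrow(cells)
  if (n == 1) return(1L)
  g <- pairwise_gap_matrix(cells, cells)
  adj <- g <= link_gap
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::components(gr)$membership)
}

#' Detect CFU-E strings on sinusoids
#'
#' Keeps CFU-E cells in direct contact with a sinusoid, groups them by the
#' connected sinusoid chain they touch, forms single-linkage components
#' within each chain under the string link gap, and retains components of
#' at least the minimum string size.
#'
#' @param cells cell table.
#' @param vessels a [vessel_network()].
#' @param params a [site_params()].
#' @return tibble `string_id`, `cell_id`, `chain_id`, `anchor_id` (one
#'   row per member CFU-E), with attribute `n_strings`.
#' @export
detect_cfu_e_strings <- function(cells, vessels, params = site_params()) {
  cfu <- cells[cells$cell_type == "CFU-E", , drop = FALSE]
  empty <- tibble::tibble(string_id = character(), cell_id = character(),
                          chain_id = integer(), anchor_id = character())
  if (nrow(cfu) == 0) {
    attr(empty, "n_strings") <- 0L
    return(empty)
  }
  dv <- distance_to_vessel(cfu, vessels, "sinusoid",
                           contact_tolerance = params$contact_tolerance_um)
  contact <- cfu[dv$contact, , drop = FALSE]
  nearest_seg <- dv$nearest_id[dv$contact]
  if (nrow(contact) == 0) {
    attr(empty, "n_strings") <- 0L
    return(empty)
  }
  # chain membership as a set: a cell belongs to every sinusoid chain it
  # touches (chains can cross, so the nearest segment alone would split a
  # string whose member grazes a second chain)
  chains <- vessel_chains(vessels)
  sin_chains <- sort(unique(chains$chain_id[chains$vclass == "sinusoid"]))
  segs <- segment_list(vessels, "sinusoid")
  P <- cells_xyz(contact)
  touch <- matrix(FALSE, nrow(contact), length(sin_chains),
                  dimnames = list(NULL, as.character(sin_chains)))
  for (s in segs) {
    chv <- as.character(chains$chain_id[match(s$segment_id, chains$segment_id)])
    g <- point_polyline_distance(P, s$pts) - s$radius - contact$radius_um
    touch[, chv] <- touch[, chv] | (g <= params$contact_tolerance_um)
  }
  gmat <- pairwise_gap_matrix(contact, contact)
  share <- touch %*% t(touch) > 0
  adj <- gmat <= params$string_link_gap_um & share
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- as.integer(igraph::components(gr)$membership)
  out <- list()
  k <- 0L
  for (cmp in sort(unique(comp))) {
    idx <- which(comp == cmp)
    if (length(idx) < params$min_string_size) next
    k <- k + 1L
    # anchor chain: the chain touched by most members
    counts <- colSums(touch[idx, , drop = FALSE])
    out[[k]] <- tibble::tibble(
      string_id = sprintf("string_%03d", k),
      cell_id = contact$id[idx],
      chain_id = as.integer(names(counts)[which.max(counts)]),
      anchor_id = nearest_seg[idx]
    )
  }
  res <- if (k) dplyr::bind_rows(out) else empty
  attr(res, "n_strings") <- k
  res
}

#' Assemble erythroid production sites around detected strings
#'
#' Attaches early and late erythroblasts, reticulocytes and red cells to
#' the string whose nearest member is within the erythroid capture
#' radius; a cell equidistant from two strings goes to the
#' lowest-numbered one. Late erythroblasts attached to a site are further
#' decomposed into clusters by single linkage under the cluster link gap.
#'
#' @param strings output of [detect_cfu_e_strings()].
#' @param cells cell table.
#' @param params a [site_params()].
#' @return list with `members` (tibble `site_id`, `cell_id`, `cell_type`,
#'   `gap_um`), `clusters` (tibble `site_id`, `cluster_id`, `cell_id`),
#'   and `sites` (per-site stage counts).
#' @export
assemble_erythroid_sites <- function(strings, cells, params = site_params()) {
  out_types <- c("early erythroblast", "late erythroblast", "reticulocyte", "RBC")
  members <- tibble::tibble(site_id = character(), cell_id = character(),
                            cell_type = character(), gap_um = double())
  string_members <- tibble::tibble(site_id = strings$string_id,
                                   cell_id = strings$cell_id,
                                   cell_type = "CFU-E", gap_um = 0)
  if (nrow(strings)) {
    string_cells <- cells[match(strings$cell_id, cells$id), , drop = FALSE]
    prog <- cells[cells$cell_type %in% out_types, , drop = FALSE]
    if (nrow(prog)) {
      g <- pairwise_gap_matrix(prog, string_cells)
      # per progeny cell: nearest gap to each string (min over its members)
      sids <- sort(unique(strings$string_id))
      per_string <- vapply(sids, function(s) {
        cols <- which(strings$string_id == s)
        apply(g[, cols, drop = FALSE], 1, min)
      }, numeric(nrow(prog)))
      per_string <- matrix(per_string, nrow = nrow(prog))
      best <- apply(per_string, 1, which.min)  # ties -> lowest string id
      best_gap <- per_string[cbind(seq_len(nrow(prog)), best)]
      keep <- best_gap <= params$erythroid_capture_um
      members <- tibble::tibble(site_id = sids[best[keep]],
                                cell_id = prog$id[keep],
                                cell_type = prog$cell_type[keep],
                                gap_um = best_gap[keep])
    }
  }
  members <- dplyr::bind_rows(string_members, members) |>
    dplyr::arrange(.data$site_id, .data$cell_type, .data$cell_id)
  # late-erythroblast cluster decomposition within each site
  clusters <- list()
  for (s in unique(members$site_id)) {
    leb_ids <- members$cell_id[members$site_id == s &
                                 members$cell_type == "late erythroblast"]
    if (!length(leb_ids)) next
    leb <- cells[match(leb_ids, cells$id), , drop = FALSE]
    comp <- gap_components(leb, params$cluster_link_gap_um)
    clusters[[s]] <- tibble::tibble(
      site_id = s, cluster_id = sprintf("%s_c%d", s, comp), cell_id = leb$id)
  }
  clusters <- if (length(clusters)) dplyr::bind_rows(clusters) else
    tibble::tibble(site_id = character(), cluster_id = character(),
                   cell_id = character())
  sites <- members |>
    dplyr::count(.data$site_id, .data$cell_type) |>
    tidyr::pivot_wider(names_from = "cell_type", values_from = "n",
                       values_fill = 0L)
  list(members = members, clusters = clusters, sites = sites)
}

#' Detect B-cell production sites around CLPs
#'
#' One candidate site per CLP: pre-pro B, pro B and pre B cells within
#' the B capture radius are attached to their nearest CLP. Arteriole
#' proximity of the CLP is reported as a site attribute, never used as a
#' filter.
#'
#' @param cells cell table.
#' @param vessels a [vessel_network()] (for the arteriole-proximity
#'   attribute; may be NULL).
#' @param params a [site_params()].
#' @return list with `members` (tibble `site_id`, `clp_id`, `cell_id`,
#'   `cell_type`, `gap_um`) and `sites` (per-site stage counts plus
#'   `arteriole_gap_um`).
#' @export
detect_b_sites <- function(cells, vessels = NULL, params = site_params()) {
  clp <- cells[cells$cell_type == "CLP", , drop = FALSE]
  stages <- c("pre-pro B", "pro B", "pre B")
  if (nrow(clp) == 0) {
    return(list(members = tibble::tibble(site_id = character(), clp_id = character(),
                                         cell_id = character(), cell_type = character(),
                                         gap_um = double()),
                sites = tibble::tibble(site_id = character())))
  }
  clp <- dplyr::arrange(clp, .data$id)
  bcells <- cells[cells$cell_type %in% stages, , drop = FALSE]
  members <- tibble::tibble(site_id = sprintf("bsite_%03d", seq_len(nrow(clp))),
                            clp_id = clp$id, cell_id = clp$id,
                            cell_type = "CLP", gap_um = 0)
  if (nrow(bcells)) {
    g <- pairwise_gap_matrix(bcells, clp)
    best <- max.col(-g, ties.method = "first")  # nearest CLP, ties -> lowest id
    best_gap <- g[cbind(seq_len(nrow(bcells)), best)]
    keep <- best_gap <= params$b_capture_um
    members <- dplyr::bind_rows(members, tibble::tibble(
      site_id = sprintf("bsite_%03d", best[keep]),
      clp_id = clp$id[best[keep]],
      cell_id = bcells$id[keep], cell_type = bcells$cell_type[keep],
      gap_um = best_gap[keep]))
  }
  sites <- members |>
    dplyr::count(.data$site_id, .data$clp_id, .data$cell_type) |>
    tidyr::pivot_wider(names_from = "cell_type", values_from = "n",
                       values_fill = 0L)
  for (st in stages) if (!st %in% names(sites)) sites[[st]] <- 0L
  if (!is.null(vessels) &&
      any(tibble::as_tibble(vessels)$vclass == "arteriole")) {
    art <- distance_to_vessel(clp, vessels, "arteriole")
    sites$arteriole_gap_um <- art$gap_um[match(sites$clp_id, art$id)]
  }
  list(members = members, sites = sites)
}

#' Detect myeloid (neutrophil or mono/DC) production sites
#'
#' A site is a focal progenitor (GP for neutrophil, MDP for mono/DC) in
#' direct contact with a sinusoid, plus its immature progeny (PN, or
#' monocytes and cDC) within the myeloid capture radius, nearest-assigned
#' among anchored progenitors. Progenitors without sinusoid contact are
#' reported as unanchored, not turned into sites. For mono/DC sites the
#' per-site cDC fraction of progeny (fate ratio) is reported.
#'
#' @param cells cell table.
#' @param vessels a [vessel_network()].
#' @param params a [site_params()].
#' @param lineage `"neutrophil"` or `"monoDC"`.
#' @return list with `members`, `sites` (stage counts, `anchor_id`,
#'   fate ratio for mono/DC) and `unanchored` (progenitor ids without
#'   sinusoid contact).
#' @export
detect_myeloid_sites <- function(cells, vessels, params = site_params(),
                                 lineage = c("neutrophil", "monoDC")) {
  lineage <- match.arg(lineage)
  focal_type <- if (lineage == "neutrophil") "GP" else "MDP"
  progeny_types <- if (lineage == "neutrophil") "PN" else c("monocyte", "cDC")
  focal <- cells[cells$cell_type == focal_type, , drop = FALSE]
  if (nrow(focal) == 0) {
    return(list(members = tibble::tibble(), sites = tibble::tibble(),
                unanchored = character()))
  }
  focal <- dplyr::arrange(focal, .data$id)
  dv <- distance_to_vessel(focal, vessels, "sinusoid",
                           contact_tolerance = params$contact_tolerance_um)
  anchored <- focal[dv$contact, , drop = FALSE]
  anchor_seg <- dv$nearest_id[dv$contact]
  unanchored <- focal$id[!dv$contact]
  if (nrow(anchored) == 0) {
    return(list(members = tibble::tibble(), sites = tibble::tibble(),
                unanchored = unanchored))
  }
  prefix <- if (lineage == "neutrophil") "nsite" else "msite"
  members <- tibble::tibble(site_id = sprintf("%s_%03d", prefix, seq_len(nrow(anchored))),
                            focal_id = anchored$id, cell_id = anchored$id,
                            cell_type = focal_type, gap_um = 0)
  prog <- cells[cells$cell_type %in% progeny_types, , drop = FALSE]
  if (nrow(prog)) {
    g <- pairwise_gap_matrix(prog, anchored)
    best <- max.col(-g, ties.method = "first")
    best_gap <- g[cbind(seq_len(nrow(prog)), best)]
    keep <- best_gap <= params$myeloid_capture_um
    members <- dplyr::bind_rows(members, tibble::tibble(
      site_id = sprintf("%s_%03d", prefix, best[keep]),
      focal_id = anchored$id[best[keep]],
      cell_id = prog$id[keep], cell_type = prog$cell_type[keep],
      gap_um = best_gap[keep]))
  }
  sites <- members |>
    dplyr::count(.data$site_id, .data$focal_id, .data$cell_type) |>
    tidyr::pivot_wider(names_from = "cell_type", values_from = "n",
                       values_fill = 0L)
  for (ty in progeny_types) if (!ty %in% names(sites)) sites[[ty]] <- 0L
  sites$anchor_id <- anchor_seg[match(sites$focal_id, anchored$id)]
  sites$lineage <- lineage
  if (lineage == "monoDC") {
    tot <- sites$monocyte + sites$cDC
    sites$cdc_fraction <- ifelse(tot > 0, sites$cDC / tot, NA_real_)
  }
  list(members = members, sites = sites, unanchored = unanchored)
}

#' Census production sites
#'
#' Counts sites per lineage, normalises by the x-y-projected marrow area
#' (sites per mm^2), and summarises per-site output (mean +/- s.e.m. of
#' total non-focal members).
#'
#' @param site_tables named list of per-lineage site detections: elements
#'   `erythroid` (from [assemble_erythroid_sites()]), `B`
#'   (from [detect_b_sites()]), `neutrophil`, `monoDC`
#'   (from [detect_myeloid_sites()]); any subset.
#' @param volume a [tissue_volume()].
#' @return tibble `lineage`, `n_sites`, `density_per_mm2`, `mean_output`,
#'   `sem_output`.
#' @export
site_census <- function(site_tables, volume) {
  area <- marrow_area_mm2(volume)
  if (area <= 0) rlang::abort("zero-area marrow mask", class = "marrowmap_schema_error")
  one <- function(lineage, det) {
    if (is.null(det)) return(NULL)
    members <- det$members
    if (is.null(members) || nrow(members) == 0) {
      return(tibble::tibble(lineage = lineage, n_sites = 0L,
                            density_per_mm2 = 0, mean_output = NA_real_,
                            sem_output = NA_real_))
    }
    focal_role <- c("CFU-E", "CLP", "GP", "MDP")
    out <- members |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(output = sum(!.data$cell_type %in% focal_role),
                       .groups = "drop")
    tibble::tibble(lineage = lineage, n_sites = nrow(out),
                   density_per_mm2 = nrow(out) / area,
                   mean_output = mean(out$output),
                   sem_output = stats::sd(out$output) / sqrt(nrow(out)))
  }
  purrr::imap(site_tables, function(det, lineage) one(lineage, det)) |>
    purrr::list_rbind()
}
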