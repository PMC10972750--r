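# Empirical random-placement null: pseudo-cells drawn from the positions
# of all segmented haematopoietic cells at the observed per-type
# frequencies, with the identical radius-corrected distance code path as
# the observed data.

#' Build the random-placement candidate pool
#'
#' The pool is the set of positions of every segmented haematopoietic
#' cell in the analysed window, irrespective of type; random pseudo-cells
#' are drawn from these real positions, not from uniform space.
#'
#' @param cells all-cell table.
#' @return tibble `pool_id`, `x_um`, `y_um`, `z_um` with attribute `size`.
#' @export
build_pool <- function(cells) {
  if (is.null(cells) || nrow(cells) == 0) {
    rlang::abort("cannot build a pool from an empty cell table",
                 class = "marrowmap_schema_error")
  }
  if (nrow(cells) < 48964 || nrow(cells) > 81248) {
    rlang::inform(paste0("pool size ", nrow(cells),
                         " is outside the typical full-slice range (48,964-81,248)"))
  }
  pool <- tibble::tibble(pool_id = cells$id, x_um = cells$x_um,
                         y_um = cells$y_um, z_um = cells$z_um)
  attr(pool, "size") <- nrow(pool)
  pool
}

#' Draw replicated random pseudo-cell sets from the pool
#'
#' Per replicate, positions are drawn without replacement from the pool
#' (no duplicated position within a replicate) for each requested type at
#' its observed count; each pseudo-cell receives the catalogue mean
#' radius of its type. Draws are independent across replicates.
#'
#' @param pool a [build_pool()] table.
#' @param counts_by_type named integer vector, observed count per type.
#' @param n_reps number of replicates (default 150, the midpoint of the
#'   customary 100-200).
#' @param seed integer seed for the draw stream.
#' @return tibble `rep`, `id`, `cell_type`, `x_um`, `y_um`, `z_um`,
#'   `radius_um`.
#' @export
sample_random_cells <- function(pool, counts_by_type, n_reps = 150, seed = 1) {
  counts_by_type <- counts_by_type[counts_by_type > 0]
  total <- sum(counts_by_type)
  if (total > nrow(pool)) {
    rlang::abort(paste0("requested ", total, " pseudo-cells per replicate from a pool of ",
                        nrow(pool)), class = "marrowmap_schema_error")
  }
  set.seed(seed)
  types <- rep(names(counts_by_type), counts_by_type)
  radii <- catalog_radius(names(counts_by_type))
  radii <- rep(radii, counts_by_type)
  purrr::map(seq_len(n_reps), function(r) {
    idx <- sample.int(nrow(pool), total, replace = FALSE)
    tibble::tibble(
      rep = r,
      id = sprintf("rnd%d_%04d", r, seq_len(total)),
      cell_type = types,
      x_um = pool$x_um[idx], y_um = pool$y_um[idx], z_um = pool$z_um[idx],
      radius_um = radii
    )
  }) |> purrr::list_rbind()
}

#' Null distance distribution for a target
#'
#' Applies the same radius-corrected distance operations used for
#' observed cells to every replicate of pseudo-cells: nearest gap to a
#' vessel class, to the endosteum, to megakaryocytes, or to the observed
#' cells of a target type.
#'
#' @param replicates output of [sample_random_cells()].
#' @param target `"sinusoid"`, `"arteriole"`, `"endosteum"`, or a cell
#'   type present in `cells` (use `"MK"` for megakaryocytes).
#' @param cells observed cell table (needed for cell-type targets).
#' @param vessels a [vessel_network()] (needed for vessel targets).
#' @param volume a [tissue_volume()] (needed for the endosteum target).
#' @return object of class `null_distribution`: list with `samples`
#'   (tibble `rep`, `id`, `gap_um`), `medians` (per-replicate medians),
#'   `target`, `n_reps`.
#' @export
null_distances <- function(replicates, target, cells = NULL, vessels = NULL,
                           volume = NULL) {
  one_rep <- function(df) {
    if (target %in% c("sinusoid", "arteriole")) {
      res <- distance_to_vessel(df, vessels, target)
    } else if (target == "endosteum") {
      res <- distance_to_endosteum(df, volume)
    } else {
      tgt <- cells[cells$cell_type == target, , drop = FALSE]
      if (nrow(tgt) == 0) {
        rlang::abort(paste0("no observed cells of target type '", target, "'"),
                     class = "marrowmap_empty_target")
      }
      res <- nearest_gap(df, tgt, exclude_self = TRUE)
    }
    tibble::tibble(id = res$id, gap_um = res$gap_um)
  }
  samples <- replicates |>
    dplyr::group_by(.data$rep) |>
    dplyr::group_modify(~ one_rep(.x)) |>
    dplyr::ungroup()
  medians <- samples |>
    dplyr::group_by(.data$rep) |>
    dplyr::summarise(median_um = stats::median(.data$gap_um), .groups = "drop")
  structure(list(samples = samples, medians = medians, target = target,
                 n_reps = max(replicates$rep)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> target %s, %d replicates, median of medians %.1f um\n",
              x$target, x$n_reps, stats::median(x$medians$median_um)))
  invisible(x)
}

#' Compare observed distances with the empirical null
#'
#' Pools the observed gap distances and the null gap distances and
#' dispatches the two-sample comparison through the normality-gated rule
#' (Student's t when both samples pass the normality check, Mann-Whitney
#' otherwise). The call is `enriched` (closer than random) when p <= alpha
#' and the observed median is below the null median, `depleted` when
#' p <= alpha and the observed median is above, `ns` otherwise.
#'
#' @param observed a distance-result tibble with `gap_um` (or a numeric
#'   vector of gaps).
#' @param null a [null_distances()] object.
#' @param alpha significance level (default 0.05).
#' @return object of class `enrichment_result`.
#' @export
compare_to_null <- function(observed, null, alpha = 0.05) {
  obs <- if (is.numeric(observed)) observed else observed$gap_um
  nul <- null$samples$gap_um
  if (length(obs) < 3) {
    res <- structure(list(call = "insufficient-data", p = NA_real_,
                          test = NA_character_, statistic = NA_real_,
                          observed_median = stats::median(obs),
                          null_median = stats::median(nul),
                          n_observed = length(obs), n_null = length(nul),
                          alpha = alpha, target = null$target),
                     class = "enrichment_result")
    return(res)
  }
  tr <- dispatch_two_sample(obs, nul)
  om <- stats::median(obs); nm <- stats::median(nul)
  call <- if (!is.na(tr$p) && tr$p <= alpha) {
    if (om < nm) "enriched" else if (om > nm) "depleted" else "ns"
  } else "ns"
  structure(list(call = call, p = tr$p, test = tr$test, statistic = tr$statistic,
                 observed_median = om, null_median = nm,
                 n_observed = length(obs), n_null = length(nul),
                 alpha = alpha, target = null$target),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s (p = %.3g, %s): observed median %.1f vs null %.1f um\n",
              x$call, x$p, x$test, x$observed_median, x$null_median))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(target = x$target %||% NA_character_, call = x$call,
                 p.value = x$p, test = x$test, statistic = x$statistic,
                 observed_median = x$observed_median,
                 null_median = x$null_median,
                 n_observed = x$n_observed, n_null = x$n_null)
}

#' @export
#' @importFrom generics glance
glance.enrichment_result <- function(x, ...) tidy(x, ...)

#' @export
tidy.null_distribution <- function(x, ...) x$medians
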