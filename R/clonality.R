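# Confetti clonal analysis: dump-channel filtering, site clonality
# classification, and same-colour distance statistics against the
# colour-permutation null.

confetti_colours <- c("GFP", "YFP", "RFP", "CFP")

#' Discard green (dump-channel) cells
#'
#' GFP shares its channel with the dump stain, so green cells cannot be
#' read as clones and are discarded before any clonal analysis; YFP, RFP,
#' CFP and unlabelled cells are retained.
#'
#' @param cells cell table with a `confetti` column.
#' @return the filtered cell table.
#' @export
filter_dump_channel <- function(cells) {
  if (!"confetti" %in% names(cells)) {
    rlang::abort("cell table has no `confetti` column", class = "marrowmap_schema_error")
  }
  cells[cells$confetti != "GFP", , drop = FALSE]
}

#' Classify the clonality of a production site
#'
#' Based on the Confetti colours of labelled, non-green member cells:
#' `monoclonal` requires at least two labelled members all of one colour;
#' `oligoclonal` means two or more colours; fewer than two labelled
#' members is `unlabelled` (no clonal information).
#'
#' @param member_ids ids of the site's member cells.
#' @param cells cell table with `confetti`.
#' @return object of class `clonality_result`.
#' @export
classify_site_clonality <- function(member_ids, cells) {
  mem <- cells[cells$id %in% member_ids, , drop = FALSE]
  mem <- filter_dump_channel(mem)
  lab <- mem$confetti[mem$confetti != "none"]
  comp <- table(factor(lab, levels = setdiff(confetti_colours, "GFP")))
  classification <- if (length(lab) < 2) {
    "unlabelled"
  } else if (length(unique(lab)) == 1) {
    "monoclonal"
  } else {
    "oligoclonal"
  }
  structure(list(classification = classification,
                 n_labelled = length(lab),
                 composition = comp,
                 n_members = length(member_ids)),
            class = "clonality_result")
}

#' @export
print.clonality_result <- function(x, ...) {
  cat(sprintf("<clonality_result> %s (%d labelled of %d members): %s\n",
              x$classification, x$n_labelled, x$n_members,
              paste(names(x$composition), x$composition, sep = "=", collapse = " ")))
  invisible(x)
}

#' @export
tidy.clonality_result <- function(x, ...) {
  tibble::tibble(classification = x$classification, n_labelled = x$n_labelled,
                 n_members = x$n_members,
                 !!!stats::setNames(as.integer(x$composition), names(x$composition)))
}

# All distinct permutations of a label vector (used for exact nulls on
# small inputs). Returns a matrix, one permutation per row.
distinct_permutations <- function(labels) {
  n <- length(labels)
  if (n > 8) rlang::abort("exhaustive enumeration limited to 8 cells")
  perm_idx <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], perm_idx(v[-i]))
    }))
  }
  all_p <- perm_idx(seq_len(n))
  lab <- matrix(labels[all_p], nrow(all_p), n)
  unique(lab)
}

#' Colour-permutation null for same-colour distance statistics
#'
#' Randomises the Confetti labels over the fixed cell coordinates,
#' preserving the per-colour counts, and recomputes a distance statistic
#' per replicate. When the number of distinct label arrangements is small
#' (at most `n_reps` and at most 8 cells), all arrangements are
#' enumerated instead of sampled and the null is exact.
#'
#' @param cells labelled cell table (already dump-filtered as desired).
#' @param statistic function(cells) -> scalar distance statistic.
#' @param n_reps number of permutation replicates (default 150).
#' @param seed integer seed.
#' @return list `stats` (per-replicate statistic), `exhaustive` (logical),
#'   `n_reps`.
#' @export
shuffle_confetti_null <- function(cells, statistic, n_reps = 150, seed = 1) {
  lab <- cells$confetti
  if (sum(lab != "none") < 2) {
    rlang::abort("need at least 2 labelled cells for a colour-permutation null",
                 class = "marrowmap_degenerate_null")
  }
  if (length(unique(lab[lab != "none"])) < 2) {
    rlang::warn("single colour present: the permutation statistic is constant")
  }
  n_distinct <- exp(lgamma(length(lab) + 1) -
                      sum(lgamma(table(lab) + 1)))
  if (length(lab) <= 8 && n_distinct <= n_reps) {
    perms <- distinct_permutations(lab)
    stats_out <- apply(perms, 1, function(p) {
      shuffled <- cells; shuffled$confetti <- p
      statistic(shuffled)
    })
    return(list(stats = stats_out, exhaustive = TRUE, n_reps = nrow(perms)))
  }
  set.seed(seed)
  stats_out <- vapply(seq_len(n_reps), function(r) {
    shuffled <- cells
    shuffled$confetti <- sample(lab)
    statistic(shuffled)
  }, numeric(1))
  list(stats = stats_out, exhaustive = FALSE, n_reps = n_reps)
}

# median over labelled progeny of the gap to the nearest same-colour
# labelled focal cell; NA when no pair shares a colour
same_colour_statistic <- function(focal_type, progeny_type) {
  function(cells) {
    foc <- cells[cells$cell_type %in% focal_type & cells$confetti != "none", , drop = FALSE]
    pro <- cells[cells$cell_type %in% progeny_type & cells$confetti != "none", , drop = FALSE]
    if (nrow(foc) == 0 || nrow(pro) == 0) return(NA_real_)
    d <- vapply(seq_len(nrow(pro)), function(i) {
      same <- foc[foc$confetti == pro$confetti[i], , drop = FALSE]
      if (nrow(same) == 0) return(NA_real_)
      min(pairwise_gap_matrix(pro[i, , drop = FALSE], same))
    }, numeric(1))
    if (all(is.na(d))) NA_real_ else stats::median(d, na.rm = TRUE)
  }
}

#' Test whether same-colour progeny map closer to their focal cell than
#' expected from random labelling
#'
#' The statistic is the median gap from each labelled progeny cell to the
#' nearest focal cell of the same Confetti colour; the null randomises
#' colours over the fixed coordinates (preserving per-colour counts).
#' Green cells are dump-filtered first. The p-value is the two-sided
#' permutation rank of the observed statistic with the add-one
#' correction (exact, without correction, when the null is exhaustive).
#'
#' @param cells cell table.
#' @param focal_type,progeny_type catalogue type names.
#' @param n_reps permutation replicates.
#' @param seed integer seed.
#' @param alpha significance level recorded with the result.
#' @return object of class `clonal_distance_test` (or a no-test result if
#'   only one colour remains after filtering).
#' @export
same_colour_distance_test <- function(cells, focal_type, progeny_type,
                                      n_reps = 150, seed = 1, alpha = 0.05) {
  keep <- filter_dump_channel(cells)
  keep <- keep[keep$cell_type %in% c(focal_type, progeny_type), , drop = FALSE]
  n_focal <- sum(keep$cell_type %in% focal_type & keep$confetti != "none")
  n_prog <- sum(keep$cell_type %in% progeny_type & keep$confetti != "none")
  if (n_focal < 1 || n_prog < 2) {
    rlang::abort("need >= 1 labelled focal and >= 2 labelled progeny cells after filtering",
                 class = "marrowmap_degenerate_null")
  }
  colours_present <- unique(keep$confetti[keep$confetti != "none"])
  if (length(colours_present) < 2) {
    return(structure(list(statistic = NA_real_, p = NA_real_, call = "no-test",
                          reason = "single colour present", n_reps = 0),
                     class = "clonal_distance_test"))
  }
  stat_fn <- same_colour_statistic(focal_type, progeny_type)
  observed <- stat_fn(keep)
  nul <- shuffle_confetti_null(keep, stat_fn, n_reps = n_reps, seed = seed)
  ns <- nul$stats[!is.na(nul$stats)]
  if (is.na(observed) || !length(ns)) {
    return(structure(list(statistic = observed, p = NA_real_, call = "no-test",
                          reason = "statistic undefined", n_reps = nul$n_reps),
                     class = "clonal_distance_test"))
  }
  if (nul$exhaustive) {
    p_lo <- mean(ns <= observed); p_hi <- mean(ns >= observed)
    p <- min(2 * min(p_lo, p_hi), 1)
  } else {
    p_lo <- (sum(ns <= observed) + 1) / (length(ns) + 1)
    p_hi <- (sum(ns >= observed) + 1) / (length(ns) + 1)
    p <- min(2 * min(p_lo, p_hi), 1)
  }
  call <- if (p <= alpha && observed < stats::median(ns)) "closer" else
    if (p <= alpha) "farther" else "ns"
  structure(list(statistic = observed, p = p, call = call,
                 null_median = stats::median(ns), n_reps = nul$n_reps,
                 exhaustive = nul$exhaustive, alpha = alpha),
            class = "clonal_distance_test")
}

#' @export
print.clonal_distance_test <- function(x, ...) {
  if (identical(x$call, "no-test")) {
    cat("<clonal_distance_test> no test:", x$reason, "\n")
  } else {
    cat(sprintf("<clonal_distance_test> %s (p = %.3g, %d reps%s): observed %.1f vs null median %.1f um\n",
                x$call, x$p, x$n_reps, if (isTRUE(x$exhaustive)) ", exact" else "",
                x$statistic, x$null_median))
  }
  invisible(x)
}

#' @export
tidy.clonal_distance_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p, call = x$call,
                 null_median = x$null_median %||% NA_real_,
                 n_reps = x$n_reps,
                 exhaustive = isTRUE(x$exhaustive))
}
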