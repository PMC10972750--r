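# Statistical procedures: normality-gated two-sample dispatch,
# two-proportion chi-square, and the imaging marker-screen rule.

new_test_result <- function(test, statistic, p, n, normality = NULL, extra = list()) {
  structure(c(list(test = test, statistic = unname(statistic), p = unname(p),
                   n = n, normality = normality), extra),
            class = "mm_test_result")
}

#' @export
print.mm_test_result <- function(x, ...) {
  cat(sprintf("<mm_test_result> %s: statistic %.4g, p = %.4g (n = %s)\n",
              x$test, x$statistic, x$p, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.mm_test_result <- function(x, ...) {
  tibble::tibble(test = x$test, statistic = x$statistic, p.value = x$p,
                 n1 = x$n[1], n2 = if (length(x$n) > 1) x$n[2] else NA_integer_,
                 normal1 = x$normality[1] %||% NA,
                 normal2 = if (length(x$normality) > 1) x$normality[2] else NA)
}

#' @export
glance.mm_test_result <- function(x, ...) tidy(x, ...)

# Shapiro-Wilk normality gate; constant samples and samples above the
# test's 5000-observation limit are handled (constant -> not normal;
# large n -> evenly spaced order-statistic subsample).
is_normalish <- function(x, alpha_norm = 0.05) {
  if (length(x) < 3 || stats::sd(x) == 0) return(FALSE)
  if (length(x) > 5000) {
    x <- sort(x)[round(seq(1, length(x), length.out = 5000))]
  }
  stats::shapiro.test(x)$p.value > alpha_norm
}

#' Normality-gated two-sample comparison
#'
#' The dispatch rule used throughout: a two-tailed unpaired Student's
#' t-test when both samples pass the Shapiro-Wilk normality check at
#' `alpha_norm`, a two-tailed Mann-Whitney test otherwise.
#'
#' @param x,y numeric samples.
#' @param alpha_norm normality-gate level (default 0.05).
#' @return an `mm_test_result`; with fewer than 3 observations per sample
#'   an insufficient-data result (`test = "insufficient-data"`, p = NA).
#' @export
#' @examples
#' dispatch_two_sample(rnorm(20), rnorm(20, 2))
dispatch_two_sample <- function(x, y, alpha_norm = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3) {
    return(new_test_result("insufficient-data", NA_real_, NA_real_,
                           c(length(x), length(y))))
  }
  nx <- is_normalish(x, alpha_norm); ny <- is_normalish(y, alpha_norm)
  if (nx && ny) {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    new_test_result("t", ht$statistic, ht$p.value, c(length(x), length(y)),
                    normality = c(nx, ny))
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    new_test_result("mann-whitney", ht$statistic, ht$p.value,
                    c(length(x), length(y)), normality = c(nx, ny))
  }
}

#' Chi-square comparison of two proportions
#'
#' Pearson chi-square on the 2x2 success/failure table, with the Yates
#' continuity correction by default (df = 1, two-sided).
#'
#' @param successes_a,n_a successes and trials in group A.
#' @param successes_b,n_b successes and trials in group B.
#' @param continuity apply the Yates correction (default TRUE).
#' @return an `mm_test_result` (test `"chi-square-yates"` or
#'   `"chi-square"`).
#' @export
#' @examples
#' chi_square_two_proportions(4, 5, 1, 73)$p  # 1.96e-9
chi_square_two_proportions <- function(successes_a, n_a, successes_b, n_b,
                                       continuity = TRUE) {
  if (n_a < 1 || n_b < 1 || successes_a > n_a || successes_b > n_b ||
      successes_a < 0 || successes_b < 0) {
    rlang::abort("invalid success/trial counts", class = "marrowmap_schema_error")
  }
  tab <- matrix(c(successes_a, n_a - successes_a,
                  successes_b, n_b - successes_b), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    rlang::abort("degenerate 2x2 table (empty margin)",
                 class = "marrowmap_degenerate_table")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = continuity))
  new_test_result(if (continuity) "chi-square-yates" else "chi-square",
                  ht$statistic, ht$p.value, c(n_a, n_b),
                  extra = list(proportions = c(successes_a / n_a, successes_b / n_b)))
}

#' Marker screen for imaging-compatible surface markers
#'
#' A marker is useful for in situ HSPC imaging when it is (1) expressed
#' brightly enough for detection -- an absolute fluorescence of at least
#' `threshold` (default 1000) over background -- uniformly in at least one
#' HSPC type, and (2) absent from one or more HSPC types, so it can
#' discriminate stages. "Uniform" means at least 90% of events above
#' background; "absent" means at most 10%.
#'
#' @param profiles tibble with columns `marker`, `hspc_type`,
#'   `median_signal`, `background`, `positive_fraction`.
#' @param threshold required absolute fluorescence over background.
#' @param uniform_fraction,absent_fraction positive-fraction cut-offs.
#' @return tibble `marker`, `n_uniform_positive`, `n_absent`, `selected`.
#' @export
marker_screen <- function(profiles, threshold = 1000,
                          uniform_fraction = 0.9, absent_fraction = 0.1) {
  req <- c("marker", "hspc_type", "median_signal", "background", "positive_fraction")
  missing_cols <- setdiff(req, names(profiles))
  if (length(missing_cols)) {
    rlang::abort(paste0("marker profiles lack column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "marrowmap_schema_error")
  }
  if (length(unique(profiles$hspc_type)) < 2) {
    rlang::abort("marker screen needs at least 2 HSPC types",
                 class = "marrowmap_schema_error")
  }
  profiles |>
    dplyr::mutate(
      uniform_positive = .data$positive_fraction >= uniform_fraction &
        (.data$median_signal - .data$background) >= threshold,
      absent = .data$positive_fraction <= absent_fraction
    ) |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(
      n_uniform_positive = sum(.data$uniform_positive),
      n_absent = sum(.data$absent),
      selected = any(.data$uniform_positive) && any(.data$absent),
      .groups = "drop"
    )
}
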