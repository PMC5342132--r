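#' Paired results container
#'
#' Pairs of MRD percentages measured on the same specimens by two methods
#' (conventionally: manual first, automated second).
#'
#' @param a,b Numeric vectors of equal length (finite).
#' @param ids Optional specimen identifiers.
#' @return A `paired_results` data.frame with columns `id`, `a`, `b`.
#' @export
paired_results <- function(a, b, ids = NULL) {
  if (length(a) != length(b))
    stop_flowmrd("paired columns differ in length (%d vs %d)", length(a), length(b))
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop_flowmrd("paired values must be finite")
  if (is.null(ids)) ids <- paste0("pair", seq_along(a))
  structure(data.frame(id = as.character(ids), a = as.numeric(a),
                       b = as.numeric(b), stringsAsFactors = FALSE),
            class = c("paired_results", "data.frame"))
}

#' Two-tailed paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the per-pair differences
#' `d = a - b`, with sample (n-1) standard deviation, `df = n - 1`, and a
#' two-tailed Student-t p-value.
#'
#' @param pr A [paired_results()] (or anything with columns `a`, `b`).
#' @return List with `t`, `df`, `p`.
#' @export
paired_t_test <- function(pr) {
  d <- pr$a - pr$b
  if (length(d) < 2L) stop_flowmrd("paired t-test needs at least 2 pairs")
  if (stats::sd(d) == 0)
    stop_flowmrd("all per-pair differences are identical (zero variance); the paired t statistic is undefined")
  ht <- stats::t.test(pr$a, pr$b, paired = TRUE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Pearson product-moment correlation of paired results
#'
#' @param pr A [paired_results()].
#' @return The correlation coefficient `r`.
#' @export
pearson_correlation <- function(pr) {
  if (nrow(pr) < 3L) stop_flowmrd("correlation needs at least 3 pairs")
  if (stats::sd(pr$a) == 0 || stats::sd(pr$b) == 0)
    stop_flowmrd("correlation is undefined for a constant column")
  stats::cor(pr$a, pr$b, method = "pearson")
}

#' Bland-Altman limits of agreement
#'
#' Per-pair difference `d = a - b` against the pair mean; bias is the mean
#' difference and the classic 95% limits of agreement are
#' `bias +/- 1.96 * sd(d)` (sample SD). `n_outside` counts differences
#' strictly beyond a limit (a difference exactly on a limit is inside).
#'
#' @param pr A [paired_results()].
#' @return A `bland_altman` list: `bias`, `loa_low`, `loa_high`,
#'   `n_outside`, `n`, and a `points` data.frame of per-pair
#'   `(mean, difference)` coordinates for plotting.
#' @export
bland_altman <- function(pr) {
  if (nrow(pr) < 2L) stop_flowmrd("Bland-Altman needs at least 2 pairs")
  d <- pr$a - pr$b
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1.96, 1.96) * s
  structure(list(bias = bias, loa_low = loa[1], loa_high = loa[2],
                 n_outside = sum(d < loa[1] | d > loa[2]), n = length(d),
                 points = data.frame(id = pr$id, mean = (pr$a + pr$b) / 2,
                                     difference = d, stringsAsFactors = FALSE)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4f, 95%% limits of agreement [%.4f, %.4f], %d/%d pairs outside\n",
              x$bias, x$loa_low, x$loa_high, x$n_outside, x$n))
  invisible(x)
}

#' Full method-agreement report
#'
#' Bundles the paired t-test, Pearson correlation and Bland-Altman summary
#' for a set of (manual %, automated %) pairs. Differences are reported as
#' `a - b` (first method minus second).
#'
#' @param pr A [paired_results()].
#' @return An `agreement_report` list: `t_statistic`, `df`, `p_value`,
#'   `pearson_r`, `bias`, `loa_low`, `loa_high`, `n_outside`, `n`,
#'   `bland_altman` (the full [bland_altman()] object).
#' @export
agreement_report <- function(pr) {
  tt <- paired_t_test(pr)
  ba <- bland_altman(pr)
  structure(list(t_statistic = tt$t, df = tt$df, p_value = tt$p,
                 pearson_r = pearson_correlation(pr),
                 bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
                 n_outside = ba$n_outside, n = ba$n, bland_altman = ba),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement over %d pairs (difference = a - b):\n", x$n))
  cat(sprintf("  paired t-test: t = %.4f, df = %d, p = %.4f\n",
              x$t_statistic, x$df, x$p_value))
  cat(sprintf("  Pearson r = %.4f\n", x$pearson_r))
  cat(sprintf("  Bland-Altman: bias %.4f, LoA [%.4f, %.4f], %d/%d outside\n",
              x$bias, x$loa_low, x$loa_high, x$n_outside, x$n))
  invisible(x)
}
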