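# Statistical layer: Pearson/Spearman correlations, a Shapiro-Wilk
# normality gate, Fisher-z aggregation of per-participant correlations,
# and Bonferroni-corrected significance levels.

#' Correlation with p-value
#'
#' Pearson product-moment correlation with a two-sided p-value from the
#' t distribution on n - 2 degrees of freedom, or Spearman rank
#' correlation (Pearson on mid-ranks; exact p for n <= 10 without ties,
#' asymptotic otherwise).
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with fields `method`, `r`, `p`, `n`.
#' @export
correlation_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_parameter("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_parameter("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop_coordrqa("zero variance: correlation undefined",
                  "coordrqa_degenerate_input")
  ct <- if (method == "spearman") {
    has_ties <- anyDuplicated(x) || anyDuplicated(y)
    suppressWarnings(
      cor.test(x, y, method = "spearman",
               exact = (n <= 10) && !has_ties))
  } else {
    cor.test(x, y, method = "pearson")
  }
  list(method = method, r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Pearson correlation
#'
#' @inheritParams correlation_test
#' @return list with `method`, `r`, `p`, `n`.
#' @export
pearson <- function(x, y) correlation_test(x, y, "pearson")

#' Spearman rank correlation
#'
#' @inheritParams correlation_test
#' @return list with `method`, `r`, `p`, `n`.
#' @export
spearman <- function(x, y) correlation_test(x, y, "spearman")

#' Normality gate for correlation method choice
#'
#' Shapiro-Wilk test on each variable; if any rejects normality at
#' `alpha`, Spearman rank correlation is indicated, otherwise Pearson.
#'
#' @param ... numeric vectors (each 3 <= n <= 5000), or a single list of
#'   them.
#' @param alpha test level (default 0.05).
#' @return `"pearson"` or `"spearman"`.
#' @export
normality_gate <- function(..., alpha = 0.05) {
  samples <- list(...)
  if (length(samples) == 1 && is.list(samples[[1]]) &&
      !is.numeric(samples[[1]]))
    samples <- samples[[1]]
  if (length(samples) == 0) stop_parameter("no samples given")
  ps <- vapply(samples, function(s) {
    s <- as.numeric(s)
    if (length(s) < 3 || length(s) > 5000)
      stop_parameter("Shapiro-Wilk needs 3 <= n <= 5000")
    shapiro.test(s)$p.value
  }, numeric(1))
  if (any(ps < alpha)) "spearman" else "pearson"
}

#' Fisher-z summary of per-participant correlations
#'
#' Transforms each participant's correlation to Fisher z
#' (`z = atanh(r)`), averages, and back-transforms a 95% confidence
#' interval `tanh(mean_z +/- 1.96 * sd(z) / sqrt(n))` built from the
#' between-participant spread of z.
#'
#' @param per_participant_r numeric vector of correlations, each with
#'   `|r| < 1`, length >= 2.
#' @return list with `mean_z`, `mean_r = tanh(mean_z)`, `ci95_r`
#'   (length-2 vector in r units).
#' @export
fisher_summary <- function(per_participant_r) {
  r <- as.numeric(per_participant_r)
  if (length(r) < 2) stop_parameter("need at least 2 correlations")
  if (any(abs(r) >= 1))
    stop_coordrqa("|r| = 1 gives infinite Fisher z",
                  "coordrqa_boundary_error")
  z <- atanh(r)
  mean_z <- mean(z)
  half <- 1.96 * sd(z) / sqrt(length(z))
  list(mean_z = mean_z, mean_r = tanh(mean_z),
       ci95_r = tanh(c(mean_z - half, mean_z + half)))
}

#' Bonferroni-corrected significance level
#'
#' @param base_alpha family-wise level in (0, 1) (e.g. 0.05).
#' @param k_comparisons number of comparisons, >= 1.
#' @return corrected per-comparison alpha, `base_alpha / k`.
#' @seealso [format_alpha_percent()] for the printed form.
#' @export
bonferroni_alpha <- function(base_alpha, k_comparisons) {
  if (!is.numeric(base_alpha) || base_alpha <= 0 || base_alpha >= 1)
    stop_parameter("base_alpha must lie in (0, 1)")
  if (!is.numeric(k_comparisons) || k_comparisons < 1)
    stop_parameter("k_comparisons must be >= 1")
  base_alpha / k_comparisons
}

#' Format a significance level as a percentage
#'
#' Truncates (rather than rounds) to two decimals, so 0.05 / 12 =
#' 0.41667% is reported as "0.41%" and 0.05 / 2 as "2.5%".
#'
#' @param alpha significance level in (0, 1).
#' @return character scalar like `"0.41%"`.
#' @export
format_alpha_percent <- function(alpha) {
  pct <- floor(alpha * 100 * 100 + 1e-9) / 100
  paste0(format(pct, trim = TRUE, drop0trailing = TRUE), "%")
}
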