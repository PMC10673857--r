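# Statistical support operations used by the analysis modules: FDR adjustment
# and the small battery of parametric/non-parametric tests the pipelines call.

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, monotone-enforced and returned in the input
#' order. This is the multiple-comparison control applied to the per-intensity
#' test batteries (e.g. testing disc responses against zero at every UV level).
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values, same length and order as `p`.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdr_adjust <- function(p) {
  .check(is.numeric(p) && length(p) >= 1L, "'p' must be a non-empty numeric vector")
  .check(all(is.finite(p)) && all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypothesis tests used by the behavioral and imaging analyses
#'
#' A thin, uniform wrapper around the tests the pipelines need: one- and
#' two-sample t-tests (pooled variance), Wilcoxon signed-rank for paired
#' samples, Wilcoxon rank-sum for independent samples, and an Anderson-Darling
#' normality screen. Rank tests use the exact null distribution for
#' `n <= 25` (absent ties) and the tie-corrected normal approximation
#' otherwise. Normality screening is advisory: it never gates an analysis.
#'
#' @param kind one of `"one_sample_t"`, `"two_sample_t"`,
#'   `"signed_rank_paired"`, `"rank_sum"`, `"normality_screen"`.
#' @param x numeric sample (first sample for two-sample kinds).
#' @param y second sample, required for two-sample and paired kinds.
#' @param mu null value for `one_sample_t` (default 0).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return an object of class `cm_test`: list with `kind`, `statistic`,
#'   `p_value`, `sidedness`, `n` (named sample sizes) and `adjusted_p`
#'   (`NA` until set by [fdr_adjust()] bookkeeping downstream).
#' @examples
#' run_test("rank_sum", c(1, 2, 3), c(10, 11, 12))$p_value  # exact, 0.1
#' @export
run_test <- function(kind = c("one_sample_t", "two_sample_t",
                              "signed_rank_paired", "rank_sum",
                              "normality_screen"),
                     x, y = NULL, mu = 0, alternative = "two.sided") {
  kind <- match.arg(kind)
  .check(is.numeric(x) && length(x) >= 1L, "'x' must be numeric")
  needs_y <- kind %in% c("two_sample_t", "signed_rank_paired", "rank_sum")
  if (needs_y) .check(is.numeric(y) && length(y) >= 1L,
                      sprintf("'%s' requires a second sample 'y'", kind))
  n <- if (needs_y) c(n_x = length(x), n_y = length(y)) else c(n = length(x))

  res <- switch(kind,
    one_sample_t = {
      .check(length(x) >= 2L, "one_sample_t needs at least 2 observations")
      .check(stats::sd(x) > 0, "one_sample_t: sample has zero variance")
      stats::t.test(x, mu = mu, alternative = alternative)
    },
    two_sample_t = {
      .check(length(x) >= 2L && length(y) >= 2L,
             "two_sample_t needs at least 2 observations per sample")
      stats::t.test(x, y, var.equal = TRUE, alternative = alternative)
    },
    signed_rank_paired = {
      .check(length(x) == length(y), "paired samples must have equal length")
      d <- x - y
      if (all(d == 0)) {
        warning("all paired differences are zero; p = 1", call. = FALSE)
        return(structure(list(kind = kind, statistic = 0, p_value = 1,
                              sidedness = alternative, n = n,
                              adjusted_p = NA_real_),
                         class = "cm_test"))
      }
      exact <- length(d) <= 25L && !any(duplicated(abs(d[d != 0]))) && !any(d == 0)
      suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                          exact = exact,
                                          alternative = alternative))
    },
    rank_sum = {
      exact <- length(x) <= 25L && length(y) <= 25L && !any(duplicated(c(x, y)))
      suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                          alternative = alternative))
    },
    normality_screen = {
      .check(length(x) >= 8L, "Anderson-Darling screen needs n >= 8")
      nortest::ad.test(x)
    })

  structure(list(kind = kind,
                 statistic = unname(res$statistic),
                 p_value = unname(res$p.value),
                 sidedness = if (kind == "normality_screen") "two.sided"
                             else alternative,
                 n = n,
                 adjusted_p = NA_real_),
            class = "cm_test")
}

#' @export
print.cm_test <- function(x, ...) {
  cat(sprintf("<cm_test> %s: statistic = %.4g, p = %.4g (%s), n = %s\n",
              x$kind, x$statistic, x$p_value, x$sidedness,
              paste(x$n, collapse = "/")))
  invisible(x)
}
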