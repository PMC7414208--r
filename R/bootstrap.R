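#' Percentile bootstrap confidence interval for the AUC
#'
#' Resamples the study and recomputes `AUC = (Se + Sp)/2` per replicate;
#' the interval endpoints are the empirical `(1 - level)/2` and
#' `(1 + level)/2` quantiles of the bootstrap distribution.
#'
#' Two resampling schemes are offered.  `"within_arm"` (default) keeps the
#' two randomized arm sizes fixed and redraws `n1` Bernoulli(`a/n1`)
#' correct-indicators in the tap arm and `n2` Bernoulli(`d/n2`) in the
#' filtered arm -- this respects the two-arm design.  `"pooled"` resamples
#' all `n` participants with their (arm, response) pairs (a multinomial
#' draw over the four cells); replicates in which an entire arm vanishes
#' are redrawn, with the redraw count recorded in the result.
#'
#' @inheritParams wald_ci_or
#' @param n_boot number of bootstrap replicates (default 10,000).
#' @param seed integer seed for reproducibility; same seed and inputs give
#'   a bit-identical interval.  `NULL` uses the current RNG state.
#' @param scheme `"within_arm"` or `"pooled"`.
#' @return An object of class `bootstrap_auc`: list with `point_estimate`,
#'   `lower`, `upper`, `level`, `n_boot`, `seed`, `scheme`, `n_redraws`.
#' @export
#' @examples
#' bootstrap_auc_ci(table2x2(106, 33, 110, 29), seed = 1, n_boot = 2000)
bootstrap_auc_ci <- function(t, level = 0.95, n_boot = 10000, seed = NULL,
                             scheme = c("within_arm", "pooled")) {
  stopifnot(is_table2x2(t), level > 0, level < 1, n_boot >= 100)
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  n_redraws <- 0L
  if (scheme == "within_arm") {
    a_star <- stats::rbinom(n_boot, t$n1, t$a / t$n1)
    d_star <- stats::rbinom(n_boot, t$n2, t$d / t$n2)
    auc_star <- (a_star / t$n1 + d_star / t$n2) / 2
  } else {
    draw <- function(k) stats::rmultinom(k, t$n, c(t$a, t$b, t$c, t$d) / t$n)
    cells <- draw(n_boot)
    repeat {
      bad <- which(colSums(cells[1:2, , drop = FALSE]) == 0 |
                   colSums(cells[3:4, , drop = FALSE]) == 0)
      if (!length(bad)) break
      n_redraws <- n_redraws + length(bad)
      cells[, bad] <- draw(length(bad))
    }
    auc_star <- (cells[1, ] / (cells[1, ] + cells[2, ]) +
                 cells[4, ] / (cells[3, ] + cells[4, ])) / 2
  }
  q <- stats::quantile(auc_star, c((1 - level) / 2, (1 + level) / 2),
                       names = FALSE, type = 7)
  structure(
    list(point_estimate = (t$a / t$n1 + t$d / t$n2) / 2,
         lower = q[1], upper = q[2], level = level,
         n_boot = as.integer(n_boot), seed = seed, scheme = scheme,
         n_redraws = n_redraws),
    class = "bootstrap_auc"
  )
}

#' @export
print.bootstrap_auc <- function(x, ...) {
  cat(sprintf(
    "AUC %.2f, %g%% percentile bootstrap CI (%.2f, %.2f)  [B = %d, %s%s]\n",
    round_report(x$point_estimate), 100 * x$level,
    round_report(x$lower), round_report(x$upper),
    x$n_boot, x$scheme,
    if (x$n_redraws > 0) sprintf(", %d redraws", x$n_redraws) else ""))
  invisible(x)
}
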