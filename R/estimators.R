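#' Point estimates of distinguishability from a 2x2 table
#'
#' Computes sensitivity `Se = a/n1` (probability of replying "tap" in the
#' tap-water arm), specificity `Sp = d/n2`, the odds ratio
#' `OR = Se/(1-Se) x Sp/(1-Sp)` (algebraically the cross-product
#' `(a d)/(b c)`), the area under the one-point ROC curve
#' `AUC = (Se + Sp)/2`, and the log-OR standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`.
#'
#' With `correction = "haldane"` (the default) the Haldane--Anscombe
#' continuity correction adds 0.5 to *all four* cells, but only when at
#' least one cell is zero; tables with all cells positive are untouched, so
#' the correction never perturbs an estimable table.  `Se` and `Sp` are
#' always computed on the raw counts.  With `correction = "none"` a zero
#' cell is an explicit error rather than a silently infinite OR.
#'
#' @param t a [table2x2()].
#' @param correction `"haldane"` (0.5 added to all cells iff any cell is
#'   zero) or `"none"`.
#' @return An object of class `discrimination_estimate`: list with `se`,
#'   `sp`, `odds_ratio`, `auc`, `log_or`, `log_or_se`,
#'   `correction_applied`, and the input `table`.
#' @export
#' @examples
#' est <- estimate_discrimination(table2x2(106, 33, 110, 29))
#' round_report(c(est$se, est$sp, est$odds_ratio, est$auc), 2)
estimate_discrimination <- function(t, correction = c("haldane", "none")) {
  stopifnot(is_table2x2(t))
  correction <- match.arg(correction)
  if (t$n1 < 1L) stop("tap arm is empty (a + b = 0)", call. = FALSE)
  if (t$n2 < 1L) stop("filtered arm is empty (c + d = 0)", call. = FALSE)
  cells <- c(t$a, t$b, t$c, t$d)
  zero <- any(cells == 0L)
  if (zero && correction == "none")
    stop("zero cell: odds ratio is infinite or undefined without a ",
         "continuity correction (use correction = \"haldane\")",
         call. = FALSE)
  adj <- if (zero) cells + 0.5 else as.numeric(cells)
  se <- t$a / t$n1
  sp <- t$d / t$n2
  ## cross-product and common-denominator forms round once, so boundary
  ## tables (ad = bc; a n2 + d n1 = n1 n2) land exactly on OR = 1, AUC = 0.5
  ## and the side-of-null equivalence OR > 1 <=> AUC > 0.5 holds exactly
  odds_ratio <- (adj[1] * adj[4]) / (adj[2] * adj[3])
  structure(
    list(se = se, sp = sp,
         odds_ratio = odds_ratio,
         auc = (t$a * t$n2 + t$d * t$n1) / (2 * t$n1 * t$n2),
         log_or = log(odds_ratio),
         log_or_se = sqrt(sum(1 / adj)),
         correction_applied = zero && correction == "haldane",
         table = t),
    class = "discrimination_estimate"
  )
}

#' @export
print.discrimination_estimate <- function(x, ...) {
  cat(sprintf(
    "Se %.2f  Sp %.2f  OR %.2f  AUC %.2f  (log-OR %.4f, SE %.4f)%s\n",
    round_report(x$se), round_report(x$sp), round_report(x$odds_ratio),
    round_report(x$auc), x$log_or, x$log_or_se,
    if (x$correction_applied) "  [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Wald confidence interval for the odds ratio
#'
#' `exp(log OR -/+ z * SE)` with `z` the standard-normal `(1 + level)/2`
#' quantile.  This is the ingredient interval of the five-region confidence
#' interval ([five_region_ci()]).
#'
#' @inheritParams estimate_discrimination
#' @param level confidence level in (0, 1).
#' @return Named numeric vector `c(lower, upper)` on the OR scale, with the
#'   estimate attached as attribute `estimate`.
#' @export
#' @examples
#' wald_ci_or(table2x2(106, 33, 110, 29))  # (0.48, 1.49) at 2 dp
wald_ci_or <- function(t, level = 0.95, correction = c("haldane", "none")) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  est <- estimate_discrimination(t, correction)
  z <- stats::qnorm((1 + level) / 2)
  out <- c(lower = exp(est$log_or - z * est$log_or_se),
           upper = exp(est$log_or + z * est$log_or_se))
  attr(out, "estimate") <- est
  attr(out, "level") <- level
  out
}
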