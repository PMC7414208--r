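#' Region partition of the odds-ratio axis
#'
#' The OR axis is partitioned into five labelled regions whose boundaries
#' default to 0.5, 1 and 2 (with an optional lenient upper boundary of
#' 1.5): `OR > U` ("recognizable ability to distinguish"), `1 < OR <= U`
#' ("negligible ability"), `OR = 1` ("no ability"), `0.5 <= OR < 1` ("weak
#' tendency to guess incorrectly") and `OR < 0.5` ("strong tendency to
#' guess incorrectly").  Concluding `OR <= U` establishes that participants
#' have no recognizable ability; excluding both outer regions establishes
#' statistical equivalence within `[0.5, U]`.
#'
#' @param lower lower outer boundary (default 0.5).
#' @param upper upper outer boundary (default 2).
#' @return An object of class `region_partition`.
#' @export
region_partition <- function(lower = 0.5, upper = 2) {
  if (!(lower > 0 && lower < 1 && upper > 1))
    stop("boundaries must satisfy 0 < lower < 1 < upper", call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "region_partition")
}

region_labels <- function(p) {
  c(sprintf("OR > %g (recognizable ability)", p$upper),
    sprintf("1 < OR <= %g (negligible ability)", p$upper),
    "OR = 1 (no ability)",
    sprintf("%g <= OR < 1 (weak tendency to guess incorrectly)", p$lower),
    sprintf("OR < %g (strong tendency to guess incorrectly)", p$lower))
}

#' One-sided boundary p-value for a composite odds-ratio hypothesis
#'
#' Wald test on the log-OR evaluated at the region boundary.  For a
#' composite region the supremum of the p-value is attained at the
#' boundary (the Wald statistic has monotone power in the true log-OR), so
#' testing at the boundary is testing the whole region.
#'
#' `direction = "greater"` tests H: OR >= boundary with
#' `p = Phi((log OR_hat - log boundary)/SE)`; `direction = "less"` tests
#' H: OR <= boundary with the complementary upper tail.
#'
#' @inheritParams estimate_discrimination
#' @param boundary positive region boundary on the OR scale.
#' @param direction `"greater"` (H: OR >= boundary) or `"less"`
#'   (H: OR <= boundary).
#' @return The one-sided p-value.
#' @export
#' @examples
#' t <- table2x2(106, 33, 110, 29)
#' boundary_pvalue(t, 1.5, "greater")  # 0.02 at 2 dp
#' boundary_pvalue(t, 0.5, "less")     # 0.03 at 2 dp
boundary_pvalue <- function(t, boundary, direction = c("greater", "less"),
                            correction = c("haldane", "none")) {
  stopifnot(is.numeric(boundary), length(boundary) == 1L, boundary > 0)
  direction <- match.arg(direction)
  est <- estimate_discrimination(t, correction)
  z <- (est$log_or - log(boundary)) / est$log_or_se
  if (direction == "greater") stats::pnorm(z) else stats::pnorm(z, lower.tail = FALSE)
}

#' Five-region confidence interval for the odds ratio
#'
#' The level-`level` Wald interval for the OR, truncated at any outer
#' region boundary whose region is rejected by the one-sided boundary test
#' at level `alpha`: if H: OR <= lower is rejected, the interval's lower
#' end is raised to the lower boundary; if H: OR >= upper is rejected, the
#' upper end is capped at the upper boundary.  When neither outer region is
#' rejected the result is the plain Wald interval.
#'
#' @inheritParams wald_ci_or
#' @param alpha one-sided significance level per boundary test.
#' @param partition a [region_partition()].
#' @return Named numeric vector `c(lower, upper)` with attributes
#'   `truncated_lower` / `truncated_upper` (logical) and `wald` (the
#'   untruncated interval).
#' @export
#' @examples
#' five_region_ci(table2x2(106, 33, 110, 29))  # (0.5, 1.49) at 2 dp
five_region_ci <- function(t, level = 0.95, alpha = 0.05,
                           partition = region_partition(),
                           correction = c("haldane", "none")) {
  stopifnot(inherits(partition, "region_partition"),
            alpha > 0, alpha < 0.5)
  correction <- match.arg(correction)
  wald <- wald_ci_or(t, level, correction)
  p_lo <- boundary_pvalue(t, partition$lower, "less", correction)
  p_up <- boundary_pvalue(t, partition$upper, "greater", correction)
  out <- c(lower = unname(wald["lower"]), upper = unname(wald["upper"]))
  trunc_lo <- p_lo < alpha && out["lower"] < partition$lower
  trunc_up <- p_up < alpha && out["upper"] > partition$upper
  if (trunc_lo) out["lower"] <- partition$lower
  if (trunc_up) out["upper"] <- partition$upper
  structure(out, truncated_lower = trunc_lo, truncated_upper = trunc_up,
            wald = c(wald), level = level, alpha = alpha)
}

#' Five-region hypothesis test on the odds ratio
#'
#' The package's primary inference.  One-sided Wald boundary tests are run
#' for the two outer regions (H: OR >= U, the "recognizable ability"
#' region, and H: OR <= 0.5, the "strong tendency to guess incorrectly"
#' region); the three inner regions receive verdicts through their
#' intersection with the five-region confidence interval.  With
#' `lenient_upper = TRUE` the upper boundary test is additionally run at
#' 1.5, the stricter equivalence margin.
#'
#' @inheritParams five_region_ci
#' @param lenient_upper also test the lenient recognizable-ability region
#'   `OR > 1.5`.
#' @return An object of class `five_region_result`: list with `p_upper`
#'   (named by boundary), `p_lower`, `alpha`, `region_verdicts`, `ci`,
#'   `estimate` and `conclusion`.
#' @export
#' @examples
#' five_region_test(table2x2(106, 33, 110, 29), lenient_upper = TRUE)
five_region_test <- function(t, alpha = 0.05, level = 0.95,
                             partition = region_partition(),
                             lenient_upper = FALSE,
                             correction = c("haldane", "none")) {
  correction <- match.arg(correction)
  est <- estimate_discrimination(t, correction)
  upper_bounds <- partition$upper
  if (lenient_upper) upper_bounds <- c(upper_bounds, 1.5)
  p_upper <- vapply(upper_bounds, function(u)
    boundary_pvalue(t, u, "greater", correction), numeric(1))
  names(p_upper) <- sprintf("OR>=%g", upper_bounds)
  p_lower <- boundary_pvalue(t, partition$lower, "less", correction)
  ci <- five_region_ci(t, level = level, alpha = alpha,
                       partition = partition, correction = correction)

  lo <- partition$lower; up <- partition$upper
  upper_rejected <- p_upper[[1]] < alpha
  lower_rejected <- p_lower < alpha
  ## inner regions: rejected iff they do not intersect the closed ci
  intersects <- function(rlo, rup) ci["lower"] <= rup && ci["upper"] >= rlo
  verdicts <- c(
    if (upper_rejected) "rejected" else "retained",
    if (intersects(1, up) && !(ci["upper"] <= 1)) "retained" else "rejected",
    if (ci["lower"] <= 1 && ci["upper"] >= 1) "retained" else "rejected",
    if (intersects(lo, 1) && !(ci["lower"] >= 1)) "retained" else "rejected",
    if (lower_rejected) "rejected" else "retained"
  )
  names(verdicts) <- region_labels(partition)

  conclusion <- if (upper_rejected && lower_rejected)
    sprintf("statistically equivalent within [%g, %g]", lo, up)
  else if (upper_rejected)
    sprintf("no recognizable ability to distinguish (OR <= %g)", up)
  else "inconclusive"

  structure(
    list(p_upper = p_upper, p_lower = p_lower, alpha = alpha,
         region_verdicts = verdicts, ci = ci, estimate = est,
         partition = partition, conclusion = conclusion),
    class = "five_region_result"
  )
}

#' @export
print.five_region_result <- function(x, ...) {
  cat("Five-region test on the odds ratio\n")
  cat(sprintf("  OR estimate %.2f, 95%% five-region CI (%.2f, %.2f)\n",
              round_report(x$estimate$odds_ratio),
              round_report(x$ci[["lower"]]), round_report(x$ci[["upper"]])))
  for (nm in names(x$p_upper))
    cat(sprintf("  p[%s] = %.4f\n", nm, x$p_upper[[nm]]))
  cat(sprintf("  p[OR<=%g] = %.4f   (alpha = %g, one-sided)\n",
              x$partition$lower, x$p_lower, x$alpha))
  for (nm in names(x$region_verdicts))
    cat(sprintf("  %-55s %s\n", nm, x$region_verdicts[[nm]]))
  cat("  conclusion:", x$conclusion, "\n")
  invisible(x)
}
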