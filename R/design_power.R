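#' Design assumptions for the boundary power calculation
#'
#' Power is computed for the one-sided boundary test that rejects
#' H: OR >= `boundary` (concluding "no recognizable ability to
#' distinguish").  Defaults are the natural design under the
#' cannot-distinguish alternative: true `Se = Sp = 0.5` (true OR = 1),
#' boundary 2, one-sided alpha 0.05, 1:1 allocation, target power 80%.
#'
#' @param true_se,true_sp assumed true sensitivity and specificity.
#' @param boundary OR boundary of the region to be rejected (default 2).
#' @param alpha one-sided significance level (in (0, 0.5)).
#' @param allocation `"fixed_equal"` (n/2 per arm) or `"bernoulli_half"`
#'   (each participant assigned to the tap arm independently with
#'   probability 1/2, the threshold-on-a-random-decimal randomization).
#' @param target_power required power for [min_sample_size()].
#' @return An object of class `power_spec`.
#' @export
power_spec <- function(true_se = 0.5, true_sp = 0.5, boundary = 2,
                       alpha = 0.05,
                       allocation = c("fixed_equal", "bernoulli_half"),
                       target_power = 0.80) {
  allocation <- match.arg(allocation)
  stopifnot(true_se > 0, true_se < 1, true_sp > 0, true_sp < 1,
            boundary > 0, alpha > 0, alpha < 0.5,
            target_power > 0, target_power < 1)
  structure(list(true_se = true_se, true_sp = true_sp, boundary = boundary,
                 alpha = alpha, allocation = allocation,
                 target_power = target_power),
            class = "power_spec")
}

true_log_or <- function(spec) {
  log(spec$true_se / (1 - spec$true_se)) +
    log(spec$true_sp / (1 - spec$true_sp))
}

## variance of the log-OR as sum of reciprocal expected cells at total size n
analytic_var_log_or <- function(spec, n_total) {
  n1 <- n_total / 2  # expected arm size under either allocation
  n2 <- n_total / 2
  cells <- c(n1 * spec$true_se, n1 * (1 - spec$true_se),
             n2 * (1 - spec$true_sp), n2 * spec$true_sp)
  if (any(cells < 1))
    warning("expected cell below 1; normal approximation is unreliable",
            call. = FALSE)
  sum(1 / cells)
}

#' Power of the boundary test at a given total sample size
#'
#' Probability that the one-sided Wald test rejects H: OR >= `boundary`
#' (i.e. [boundary_pvalue()] < alpha) when the data arise from the spec's
#' true parameters.
#'
#' The analytic method uses the normal approximation with
#' `Var(log OR) = sum of 1/expected-cell`: power =
#' `Phi((log boundary - log trueOR)/SE - z_(1-alpha))`.  The Monte-Carlo
#' method simulates whole studies from the generator's arm/response model
#' (arm sizes fixed or Binomial(n, 1/2) per the allocation, then binomial
#' correct-guess counts per arm; identical in distribution to aggregating
#' [simulate_study()] output) and applies the boundary test to each,
#' returning the rejection fraction.
#'
#' @param spec a [power_spec()].
#' @param n_total total number of participants (>= 4).
#' @param method `"analytic"` or `"monte_carlo"`.
#' @param mc_reps number of simulated studies for the Monte-Carlo method.
#' @param seed RNG seed for the Monte-Carlo method.
#' @return An object of class `power_result`: list with `n_total`, `power`,
#'   `method`, and (for Monte Carlo) `mc_reps`, `seed`, `mc_se`.
#' @export
#' @examples
#' power_at_n(power_spec(), 278)   # 0.89
power_at_n <- function(spec, n_total, method = c("analytic", "monte_carlo"),
                       mc_reps = 20000, seed = NULL) {
  stopifnot(inherits(spec, "power_spec"), n_total >= 4)
  method <- match.arg(method)
  if (method == "analytic") {
    se_log_or <- sqrt(analytic_var_log_or(spec, n_total))
    z <- (log(spec$boundary) - true_log_or(spec)) / se_log_or -
      stats::qnorm(1 - spec$alpha)
    power <- stats::pnorm(z)
    res <- list(n_total = as.integer(n_total), power = power,
                method = "analytic")
  } else {
    if (!is.null(seed)) set.seed(seed)
    p_reject <- simulate_boundary_pvalues(spec, n_total, mc_reps)
    power <- mean(p_reject < spec$alpha)
    res <- list(n_total = as.integer(n_total), power = power,
                method = "monte_carlo", mc_reps = as.integer(mc_reps),
                seed = seed,
                mc_se = sqrt(power * (1 - power) / mc_reps))
  }
  res$spec <- spec
  structure(res, class = "power_result")
}

## vectorized study simulation at the aggregate (2x2) level; returns the
## boundary p-value for H: OR >= boundary of each simulated study, using the
## same Haldane-corrected Wald statistic as boundary_pvalue()
simulate_boundary_pvalues <- function(spec, n_total, reps) {
  n1 <- if (spec$allocation == "fixed_equal")
    rep.int(n_total %/% 2, reps)
  else stats::rbinom(reps, n_total, 0.5)
  ## an empty arm makes the study unanalysable; redraw (vanishingly rare
  ## except at tiny n)
  repeat {
    bad <- which(n1 == 0L | n1 == n_total)
    if (!length(bad)) break
    n1[bad] <- stats::rbinom(length(bad), n_total, 0.5)
  }
  n2 <- n_total - n1
  a <- stats::rbinom(reps, n1, spec$true_se)
  d <- stats::rbinom(reps, n2, spec$true_sp)
  b <- n1 - a
  cc <- n2 - d
  zero <- a == 0L | b == 0L | cc == 0L | d == 0L
  h <- ifelse(zero, 0.5, 0)  # Haldane-Anscombe on zero-cell tables
  l <- log(a + h) + log(d + h) - log(b + h) - log(cc + h)
  se <- sqrt(1 / (a + h) + 1 / (b + h) + 1 / (cc + h) + 1 / (d + h))
  stats::pnorm((l - log(spec$boundary)) / se)
}

#' Minimal sample size for the boundary test
#'
#' Smallest total sample size whose power ([power_at_n()], analytic)
#' reaches `spec$target_power`.  A closed-form start
#' `n = V * (z_(1-alpha) + z_power)^2 / (log boundary - log trueOR)^2`
#' (with `V` the per-participant variance factor of the log-OR) is refined
#' by a monotone search stepping by 2 (both arms grow together under 1:1
#' allocation).
#'
#' @param spec a [power_spec()].
#' @return A `power_result` whose `n_total` is the minimal size and whose
#'   `power` is the achieved analytic power at that size.
#' @export
#' @examples
#' min_sample_size(power_spec())$n_total   # 206
min_sample_size <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  delta <- log(spec$boundary) - true_log_or(spec)
  ## a true OR at (or numerically indistinguishable from) the boundary can
  ## never be rejected with power above alpha at any n
  if (delta <= 1e-8)
    stop("true OR must lie below the boundary for the rejection to be ",
         "reachable", call. = FALSE)
  v_unit <- 2 * (1 / (spec$true_se * (1 - spec$true_se)) +
                 1 / (spec$true_sp * (1 - spec$true_sp)))  # n * Var(log OR)
  z <- stats::qnorm(1 - spec$alpha) + stats::qnorm(spec$target_power)
  n <- ceiling(v_unit * z^2 / delta^2)
  if (n %% 2 == 1) n <- n + 1  # 1:1 allocation: even totals
  n <- max(n, 4)               # smallest admissible design
  ## monotone refinement around the closed-form start
  while (n > 4 &&
         power_at_n(spec, n - 2)$power >= spec$target_power) n <- n - 2
  while (power_at_n(spec, n)$power < spec$target_power) {
    n <- n + 2
    if (n > 1e7)
      stop("required sample size exceeds 1e7; the margin between the true ",
           "OR and the boundary is too small", call. = FALSE)
  }
  res <- power_at_n(spec, n)
  res$target_power <- spec$target_power
  res
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("power %.4f at n = %d (%s", x$power, x$n_total, x$method))
  if (x$method == "monte_carlo")
    cat(sprintf(", %d reps, MC-SE %.4f", x$mc_reps, x$mc_se))
  cat(")\n")
  invisible(x)
}
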