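#' Baseline covariate balance between arms
#'
#' Tests whether a baseline covariate is distributed equally across the
#' two randomized arms, on the 2x2 arm-by-covariate table.
#' `"chisq_yates"` is the continuity-corrected Pearson chi-square
#' ([stats::chisq.test()] with `correct = TRUE`); `"fisher"` is the
#' two-sided exact test ([stats::fisher.test()], which sums the
#' probabilities of all outcomes no more probable than the observed one).
#'
#' @param ds a [study_dataset()].
#' @param covariate one of `"gender"`, `"position"`,
#'   `"dispenser_last_month"`, `"fountain_before"`.
#' @param method `"chisq_yates"` or `"fisher"`.
#' @return The two-sided p-value.
#' @export
#' @examples
#' baseline_comparison(taipei_participants(), "dispenser_last_month")
baseline_comparison <- function(ds, covariate,
                                method = c("chisq_yates", "fisher")) {
  stopifnot(inherits(ds, "study_dataset"))
  method <- match.arg(method)
  if (!covariate %in% names(COVARIATE_LEVELS))
    stop("unknown covariate: ", covariate, call. = FALSE)
  if (!all(ARM_LEVELS %in% ds$arm))
    stop("both arms must be non-empty", call. = FALSE)
  m <- table(factor(ds$arm, ARM_LEVELS),
             factor(ds[[covariate]], COVARIATE_LEVELS[[covariate]]))
  if (method == "chisq_yates") {
    if (any(rowSums(m) == 0) || any(colSums(m) == 0))
      stop("zero expected cell: chi-square test undefined (use fisher)",
           call. = FALSE)
    suppressWarnings(stats::chisq.test(m, correct = TRUE)$p.value)
  } else {
    stats::fisher.test(m)$p.value
  }
}

## per-table analysis bundle shared by overall and stratum rows
analyse_table <- function(t, alpha, level, n_boot, seed, correction, scheme,
                          lenient_upper) {
  list(
    n = t$n,
    table = t,
    pct_replying_tap = c(
      tap = 100 * t$a / t$n1,
      filtered = 100 * t$c / t$n2,
      overall = 100 * (t$a + t$c) / t$n
    ),
    estimate = estimate_discrimination(t, correction),
    five_region = five_region_test(t, alpha = alpha, level = level,
                                   lenient_upper = lenient_upper,
                                   correction = correction),
    bootstrap = bootstrap_auc_ci(t, level = level, n_boot = n_boot,
                                 seed = seed, scheme = scheme)
  )
}

#' Run the full taste-test analysis
#'
#' End-to-end pipeline mirroring the study's results tables: aggregates a
#' participant-level dataset (or takes an aggregated 2x2 table directly),
#' computes the discrimination estimates, the five-region test and CI, and
#' the bootstrap AUC interval -- overall and, for participant-level input,
#' within each stratum of the four covariates -- plus baseline balance
#' p-values.  All settings are recorded in the report so it can be
#' reproduced bit-identically.
#'
#' @param x a [study_dataset()] or a [table2x2()].
#' @param alpha one-sided significance level per boundary test.
#' @param level confidence level for intervals.
#' @param n_boot bootstrap replicates.
#' @param seed base RNG seed; stratum bootstraps use `seed + stratum
#'   index` so strata are independent but reproducible.
#' @param correction continuity correction, see
#'   [estimate_discrimination()].
#' @param scheme bootstrap resampling scheme, see [bootstrap_auc_ci()].
#' @param lenient_upper also test the lenient `OR > 1.5` region.
#' @param baseline_method test for the baseline table, see
#'   [baseline_comparison()].
#' @return An object of class `taste_report`.
#' @export
#' @examples
#' rep <- run_full_analysis(taipei_counts()$tables$all, seed = 1,
#'                          n_boot = 2000)
#' print(rep)
run_full_analysis <- function(x, alpha = 0.05, level = 0.95,
                              n_boot = 10000, seed = 1L,
                              correction = c("haldane", "none"),
                              scheme = c("within_arm", "pooled"),
                              lenient_upper = TRUE,
                              baseline_method = c("chisq_yates", "fisher")) {
  correction <- match.arg(correction)
  scheme <- match.arg(scheme)
  baseline_method <- match.arg(baseline_method)
  for (nm in c("alpha", "level", "n_boot", "seed")) {
    v <- get(nm)
    if (is.null(v) || length(v) != 1L || is.na(v))
      stop("setting '", nm, "' must be a single non-missing value",
           call. = FALSE)
  }
  settings <- list(alpha = alpha, level = level, n_boot = as.integer(n_boot),
                   seed = as.integer(seed), correction = correction,
                   scheme = scheme, lenient_upper = lenient_upper,
                   baseline_method = baseline_method)

  strata <- list()
  baseline <- NULL
  if (inherits(x, "study_dataset")) {
    provenance <- attr(x, "provenance")
    overall_t <- aggregate_tables(x)$all
    baseline <- vapply(names(COVARIATE_LEVELS), function(cv)
      baseline_comparison(x, cv, baseline_method), numeric(1))
    i <- 0L
    for (cv in names(COVARIATE_LEVELS)) {
      tabs <- aggregate_tables(x, cv)
      for (lev in names(tabs)) {
        i <- i + 1L
        strata[[paste(cv, lev, sep = ":")]] <-
          analyse_table(tabs[[lev]], alpha, level, n_boot, seed + i,
                        correction, scheme, lenient_upper)
      }
    }
  } else if (is_table2x2(x)) {
    provenance <- "aggregated 2x2 table"
    overall_t <- x
  } else {
    stop("x must be a study_dataset or a table2x2", call. = FALSE)
  }

  structure(
    list(provenance = provenance,
         settings = settings,
         overall = analyse_table(overall_t, alpha, level, n_boot, seed,
                                 correction, scheme, lenient_upper),
         strata = strata,
         baseline = baseline),
    class = "taste_report"
  )
}

#' @export
print.taste_report <- function(x, ...) {
  ov <- x$overall
  t <- ov$table
  cat("Randomized single-sample taste test --- analysis report\n")
  cat("input:", x$provenance, "\n\n")
  cat(sprintf("Replying \"tap\": %d (%.1f%%) tap arm, %d (%.1f%%) filtered arm, %d (%.1f%%) overall\n",
              t$a, round_report(ov$pct_replying_tap[["tap"]], 1),
              t$c, round_report(ov$pct_replying_tap[["filtered"]], 1),
              t$a + t$c, round_report(ov$pct_replying_tap[["overall"]], 1)))
  print(ov$estimate)
  print(ov$five_region)
  print(ov$bootstrap)
  if (!is.null(x$baseline)) {
    cat("\nBaseline balance p-values (", x$settings$baseline_method, "):\n",
        sep = "")
    for (nm in names(x$baseline))
      cat(sprintf("  %-22s %.2f\n", nm, round_report(x$baseline[[nm]])))
  }
  if (length(x$strata)) {
    cat("\nSubgroups (OR, five-region CI, AUC, bootstrap CI):\n")
    for (nm in names(x$strata)) {
      s <- x$strata[[nm]]
      cat(sprintf("  %-30s n=%3d  OR %.2f (%.2f, %.2f)  AUC %.2f (%.2f, %.2f)\n",
                  nm, s$n,
                  round_report(s$estimate$odds_ratio),
                  round_report(s$five_region$ci[["lower"]]),
                  round_report(s$five_region$ci[["upper"]]),
                  round_report(s$estimate$auc),
                  round_report(s$bootstrap$lower),
                  round_report(s$bootstrap$upper)))
    }
  }
  invisible(x)
}

## full-precision + 2-dp twin representation of one analysed table
report_entry_json <- function(e) {
  fr <- e$five_region
  list(
    n = e$n,
    table = list(a = e$table$a, b = e$table$b, c = e$table$c,
                 d = e$table$d),
    pct_replying_tap = as.list(e$pct_replying_tap),
    se = e$estimate$se, sp = e$estimate$sp,
    odds_ratio = e$estimate$odds_ratio,
    auc = e$estimate$auc,
    log_or_se = e$estimate$log_or_se,
    five_region = list(
      p_upper = as.list(fr$p_upper), p_lower = fr$p_lower,
      ci = list(lower = fr$ci[["lower"]], upper = fr$ci[["upper"]]),
      verdicts = as.list(fr$region_verdicts),
      conclusion = fr$conclusion),
    bootstrap = list(lower = e$bootstrap$lower, upper = e$bootstrap$upper,
                     n_boot = e$bootstrap$n_boot,
                     scheme = e$bootstrap$scheme),
    rounded = list(se = round_report(e$estimate$se),
                   sp = round_report(e$estimate$sp),
                   odds_ratio = round_report(e$estimate$odds_ratio),
                   auc = round_report(e$estimate$auc),
                   ci_lower = round_report(fr$ci[["lower"]]),
                   ci_upper = round_report(fr$ci[["upper"]]),
                   boot_lower = round_report(e$bootstrap$lower),
                   boot_upper = round_report(e$bootstrap$upper))
  )
}

#' Serialize an analysis report to JSON
#'
#' Writes the report with full-precision values and their 2-dp rounded
#' twins side by side, plus the settings needed to reproduce it.
#'
#' @param report a `taste_report` from [run_full_analysis()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "taste_report"))
  out <- list(
    provenance = report$provenance,
    settings = report$settings,
    overall = report_entry_json(report$overall),
    strata = lapply(report$strata, report_entry_json),
    baseline = if (is.null(report$baseline)) NULL else
      as.list(report$baseline)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
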