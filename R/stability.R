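#' Wald confidence interval for a proportion
#'
#' `p_hat +/- 1.96 sqrt(p_hat (1 - p_hat) / n)`, clamped to `[0, 1]`,
#' reported in percent. The integer-rounded bounds match the usual
#' `k/n (..% , 95% CI: ..-..%)` reporting style.
#'
#' @param k successes (0..n)
#' @param n trials (>= 1)
#' @return list: `percent`, `lower`, `upper` (percent, full precision),
#'   `percent_int`, `lower_int`, `upper_int` (integer-rounded)
#' @export
proportion_ci <- function(k, n) {
  if (n < 1L) stopf("n must be >= 1")
  if (k < 0 || k > n) stopf("k must be in 0..n")
  p <- k / n
  half <- 1.96 * sqrt(p * (1 - p) / n)
  lo <- max(0, p - half); hi <- min(1, p + half)
  list(percent = 100 * p, lower = 100 * lo, upper = 100 * hi,
       percent_int = round(100 * p), lower_int = round(100 * lo),
       upper_int = round(100 * hi))
}

#' Cohen's kappa with asymptotic 95% confidence interval
#'
#' Unweighted kappa on a square confusion matrix;
#' `SE = sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`.
#'
#' @param m square confusion matrix of counts
#' @return list: `kappa`, `se`, `lower`, `upper`, `p_observed`,
#'   `p_expected`, `n`
#' @export
cohen_kappa <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stopf("confusion matrix must be square")
  n <- sum(m)
  if (n < 1) stopf("empty confusion matrix")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  se <- if (pe == 1) 0 else sqrt(po * (1 - po) / (n * (1 - pe)^2))
  list(kappa = kappa, se = se,
       lower = kappa - 1.96 * se, upper = kappa + 1.96 * se,
       p_observed = po, p_expected = pe, n = n)
}

#' Restage every scan of a longitudinal cohort with a frozen model
#'
#' Each scan (baseline and follow-up alike) is z-scored with the frozen
#' control reference and assigned independently with the frozen
#' baseline-trained model; no information flows between a subject's
#' visits.
#'
#' @param table a [cohort_table()] containing patient scans (controls,
#'   if present, are ignored)
#' @param model fitted `sustain_model` (frozen)
#' @param ref the frozen `zscore_model`; omit if `table` already holds
#'   z-scores
#' @param prob_threshold poor-fit exclusion threshold
#' @return `assignment_table` with `time_from_baseline` carried through
#' @export
restage_followups <- function(table, model, ref = NULL,
                              prob_threshold = 0.5) {
  pat <- as.data.frame(table)[table$group == "patient", , drop = FALSE]
  if (nrow(pat) == 0L) stopf("no patient scans to restage")
  pat_tab <- cohort_table(pat, cohort_regions(table))
  Z <- if (is.null(ref)) cohort_values(pat_tab) else
    apply_zscore(pat_tab, ref)
  out <- assign_cohort(Z, model, prob_threshold,
                       ids = pat_tab[, c("subject_id", "visit_index")])
  out <- add_deviations(Z, model, out)
  out$time_from_baseline <- pat_tab$time_from_baseline
  out
}

# Baseline and last usable visit per subject (non-excluded at both ends,
# at least one follow-up).
paired_visits <- function(assignments) {
  a <- as.data.frame(assignments)
  out <- do.call(rbind, lapply(split(a, a$subject_id), function(d) {
    d <- d[order(d$visit_index), , drop = FALSE]
    if (nrow(d) < 2L || d$visit_index[1] != 0L) return(NULL)
    base <- d[1, ]
    last <- d[nrow(d), ]
    if (base$excluded || last$excluded) return(NULL)
    data.frame(subject_id = base$subject_id,
               subtype_baseline = base$subtype, subtype_last = last$subtype,
               stage_baseline = base$stage, stage_last = last$stage,
               dt = last$time_from_baseline - base$time_from_baseline,
               stringsAsFactors = FALSE)
  }))
  out
}

#' Subtype stability report from longitudinal assignments
#'
#' Builds the baseline-vs-last-visit confusion matrix over subjects with
#' at least one follow-up and non-excluded baseline and last scans, with
#' unweighted Cohen's kappa (asymptotic 95% CI) and the retention
#' proportion (trace/total) with its Wald CI.
#'
#' @param assignments an `assignment_table` from [restage_followups()]
#'   (must contain `time_from_baseline`)
#' @param n_subtypes number of subtypes in the model (fixes matrix size)
#' @return list of class `stability_report`: `confusion`, `kappa`,
#'   `retention` (a [proportion_ci()] result), `n_subjects`, `pairs`
#' @export
stability_report <- function(assignments, n_subtypes) {
  pairs <- paired_visits(assignments)
  if (is.null(pairs) || nrow(pairs) == 0L)
    stopf("no subjects with usable baseline and follow-up scans")
  lev <- seq_len(n_subtypes)
  confusion <- table(factor(pairs$subtype_baseline, levels = lev),
                     factor(pairs$subtype_last, levels = lev))
  confusion <- unclass(confusion)
  dimnames(confusion) <- list(baseline = paste0("S", lev),
                              last = paste0("S", lev))
  structure(list(confusion = confusion,
                 kappa = cohen_kappa(confusion),
                 retention = proportion_ci(sum(diag(confusion)),
                                           sum(confusion)),
                 n_subjects = nrow(pairs), pairs = pairs),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Subtype stability over %d subjects\n", x$n_subjects))
  print(x$confusion)
  cat(sprintf("retention: %.1f%% (95%% CI %.0f-%.0f%%)\n",
              x$retention$percent, x$retention$lower_int,
              x$retention$upper_int))
  cat(sprintf("Cohen's kappa: %.2f (95%% CI %.2f-%.2f)\n",
              x$kappa$kappa, x$kappa$lower, x$kappa$upper))
  invisible(x)
}

#' Annual stage-change rates within retained subtypes
#'
#' Restricted to subjects whose last-visit subtype matches baseline, the
#' per-subject rate is `(stage_last - stage_baseline) / dt` (years).
#' Per-subtype summaries include a one-sample t-test of the rate against
#' zero; differences across subtypes are tested with one-way ANOVA.
#' Subjects that regressed (negative rate) are counted with a Wald-CI
#' proportion.
#'
#' @param assignments an `assignment_table` from [restage_followups()]
#' @return list of class `stage_change`: `rates` (per-subject data
#'   frame), `by_subtype` (mean/sd/n/t/p), `anova` (`F`, `p`),
#'   `overall_mean`, `overall_ci` (95% CI on the mean rate),
#'   `regressed` ([proportion_ci()] result),
#'   `stable_or_progressed` ([proportion_ci()] result)
#' @export
annual_stage_change <- function(assignments) {
  pairs <- paired_visits(assignments)
  if (is.null(pairs)) stopf("no usable longitudinal pairs")
  pairs <- pairs[pairs$subtype_baseline == pairs$subtype_last, , drop = FALSE]
  bad <- pairs$dt <= 0
  if (any(bad)) {
    warnf("%d subject(s) with non-positive follow-up interval skipped", sum(bad))
    pairs <- pairs[!bad, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) stopf("no retained subjects with positive dt")
  pairs$rate <- (pairs$stage_last - pairs$stage_baseline) / pairs$dt
  by_sub <- do.call(rbind, lapply(split(pairs, pairs$subtype_baseline),
                                  function(d) {
    tt <- if (nrow(d) >= 2L && stats::sd(d$rate) > 0)
      stats::t.test(d$rate, mu = 0) else NULL
    data.frame(subtype = d$subtype_baseline[1], n = nrow(d),
               mean = mean(d$rate), sd = stats::sd(d$rate),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value)
  }))
  an <- if (length(unique(pairs$subtype_baseline)) >= 2L) {
    if (stats::var(pairs$rate) <= 1e-20 * (1 + mean(pairs$rate)^2)) {
      # identical rates everywhere: no between-group signal at all
      list(F = 0, p = 1,
           df = c(length(unique(pairs$subtype_baseline)) - 1L,
                  nrow(pairs) - length(unique(pairs$subtype_baseline))))
    } else {
      fit <- stats::aov(rate ~ factor(subtype_baseline), data = pairs)
      s <- summary(fit)[[1]]
      a <- list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
                df = c(s[["Df"]][1], s[["Df"]][2]))
      if (is.na(a$F) || is.nan(a$F)) a$F <- 0 # zero residual variance
      a
    }
  } else list(F = NA_real_, p = NA_real_, df = c(NA, NA))
  m <- mean(pairs$rate)
  se <- stats::sd(pairs$rate) / sqrt(nrow(pairs))
  structure(list(rates = pairs, by_subtype = by_sub, anova = an,
                 overall_mean = m, overall_sd = stats::sd(pairs$rate),
                 overall_ci = c(m - 1.96 * se, m + 1.96 * se),
                 regressed = proportion_ci(sum(pairs$rate < 0), nrow(pairs)),
                 stable_or_progressed = proportion_ci(sum(pairs$rate >= 0),
                                                      nrow(pairs))),
            class = "stage_change")
}
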