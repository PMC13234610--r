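#' Match estimated subtype labels to true labels
#'
#' Exhaustive search over label bijections for the permutation
#' maximizing agreement with the true labels.
#'
#' @param true_labels,est_labels integer vectors of equal length with
#'   labels in `1..C`
#' @param C number of subtypes (<= 8)
#' @return list: `permutation` (`perm[est] = matched true label`),
#'   `accuracy` (agreement under the best matching)
#' @export
match_subtypes <- function(true_labels, est_labels, C) {
  if (length(true_labels) != length(est_labels))
    stopf("label vectors must have equal length")
  if (C > 8L) stopf("exhaustive matching supports C <= 8")
  perms <- all_permutations(C)
  best <- NULL; best_acc <- -1
  for (p in perms) {
    acc <- mean(p[est_labels] == true_labels)
    if (acc > best_acc) { best_acc <- acc; best <- p }
  }
  list(permutation = best, accuracy = best_acc)
}

#' Kendall rank correlation between two event sequences
#'
#' Computed between the two position maps over the shared event set; 1
#' for identical orderings.
#'
#' @param S_true,S_est event sequences over the same event set
#' @return Kendall's tau in `[-1, 1]`
#' @export
sequence_recovery <- function(S_true, S_est) {
  if (length(S_true) != length(S_est)) stopf("sequences differ in length")
  stats::cor(sequence_positions(S_true), sequence_positions(S_est),
             method = "kendall")
}

#' Score a fitted model and its assignments against ground truth
#'
#' The label matching is found over all scans; the headline `accuracy`
#' is then computed over scans that pass the poor-fit exclusion (the
#' `excluded` flag of the assignment table), mirroring how
#' low-certainty scans are excluded from post-clustering analyses.
#' `accuracy_all` keeps every scan. `fraction_error` compares the
#' fitted mixing fractions with the cohort's realized subtype
#' proportions (the generating fractions are only the expectation of
#' the multinomial draw).
#'
#' @param model fitted `sustain_model`
#' @param assignments `assignment_table` for the baseline patient scans
#' @param truth the `ground_truth` of the simulated cohort
#' @return list of class `recovery_metrics`: `accuracy` (non-excluded
#'   scans), `accuracy_all`, `n_excluded`, `permutation`, `kendall_tau`
#'   (per matched subtype), `fraction_error` (per subtype, vs realized
#'   proportions), `stage_mae`, `stage_bias`
#' @export
recovery_metrics <- function(model, assignments, truth) {
  C <- length(truth$sequences)
  idx <- match(truth$subjects$subject_id, assignments$subject_id)
  if (anyNA(idx)) stopf("assignments missing some simulated subjects")
  est <- assignments$subtype[idx]
  true_lab <- truth$subjects$subtype
  m <- match_subtypes(true_lab, est, C)
  perm <- m$permutation
  ok <- !assignments$excluded[idx]
  acc <- if (any(ok)) mean(perm[est[ok]] == true_lab[ok]) else NA_real_
  # perm[est] = true label; subtype c_est corresponds to true perm[c_est]
  tau <- vapply(seq_len(C), function(c_est)
    sequence_recovery(truth$sequences[[perm[c_est]]],
                      model$sequences[[c_est]]), numeric(1))
  realized <- tabulate(true_lab, nbins = C) / length(true_lab)
  frac_err <- vapply(seq_len(C), function(c_est)
    model$fractions[c_est] - realized[perm[c_est]], numeric(1))
  stage_err <- assignments$stage[idx] - truth$subjects$stage
  structure(list(accuracy = acc, accuracy_all = m$accuracy,
                 n_excluded = sum(!ok), permutation = perm,
                 kendall_tau = tau, fraction_error = frac_err,
                 stage_mae = mean(abs(stage_err)),
                 stage_bias = mean(stage_err)),
            class = "recovery_metrics")
}

#' Render plain-text and CSV run reports
#'
#' Writes tabular summaries of whatever is supplied: subtype counts with
#' Wald CIs, the CVIC curve, per-subtype positional-variance matrices,
#' stability and stage-progression tables, and recovery metrics. Every
#' percentage printed is recomputed from its counts via
#' [proportion_ci()].
#'
#' @param out_dir output directory (created if needed)
#' @param model optional fitted `sustain_model`
#' @param assignments optional `assignment_table`
#' @param cv optional `cv_result`
#' @param mcmc optional `mcmc_samples`
#' @param stability optional `stability_report`
#' @param stage_change optional `stage_change`
#' @param recovery optional `recovery_metrics`
#' @return character vector of files written, invisibly
#' @export
render_report <- function(out_dir, model = NULL, assignments = NULL,
                          cv = NULL, mcmc = NULL, stability = NULL,
                          stage_change = NULL, recovery = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  txt <- character(0)
  if (!is.null(assignments) && nrow(assignments) > 0) {
    base <- assignments[assignments$visit_index == 0L & !assignments$excluded, ]
    n <- nrow(base)
    counts <- table(factor(base$subtype,
                           levels = seq_len(max(base$subtype, 1))))
    lines <- vapply(names(counts), function(s) {
      ci <- proportion_ci(counts[[s]], max(n, 1))
      sprintf("subtype %s: n = %d/%d, %d%%, 95%% CI: %d-%d%%", s,
              counts[[s]], n, ci$percent_int, ci$lower_int, ci$upper_int)
    }, character(1))
    txt <- c(txt, "== Baseline subtype counts ==", lines,
             sprintf("excluded (poor fit): %d/%d", sum(assignments$excluded &
                       assignments$visit_index == 0L),
                     sum(assignments$visit_index == 0L)), "")
    f <- file.path(out_dir, "assignments.csv")
    utils::write.csv(as.data.frame(assignments), f, row.names = FALSE)
    files <- c(files, f)
  } else if (!is.null(assignments)) {
    warnf("empty assignment set; writing empty report")
  }
  if (!is.null(cv)) {
    f <- file.path(out_dir, "cvic.csv")
    utils::write.csv(data.frame(C = cv$C_range, cvic = cv$cvic,
                                row.names = NULL), f, row.names = FALSE)
    files <- c(files, f)
    txt <- c(txt, "== CVIC ==",
             sprintf("C = %d: CVIC = %.2f", cv$C_range, cv$cvic),
             sprintf("elbow at C = %d", cvic_elbow(cv)), "")
  }
  if (!is.null(mcmc)) {
    for (c in seq_along(mcmc$positional_variance)) {
      f <- file.path(out_dir, sprintf("positional_variance_subtype%d.csv", c))
      utils::write.csv(mcmc$positional_variance[[c]], f)
      files <- c(files, f)
    }
  }
  if (!is.null(stability)) {
    txt <- c(txt, "== Subtype stability ==",
             utils::capture.output(print(stability)), "")
    f <- file.path(out_dir, "confusion_matrix.csv")
    utils::write.csv(stability$confusion, f)
    files <- c(files, f)
  }
  if (!is.null(stage_change)) {
    txt <- c(txt, "== Annual stage change ==",
             sprintf("overall: %.2f +/- %.2f stage/year (95%% CI %.2f-%.2f)",
                     stage_change$overall_mean, stage_change$overall_sd,
                     stage_change$overall_ci[1], stage_change$overall_ci[2]),
             sprintf("regressed: n = %d, %d%%, 95%% CI: %d-%d%%",
                     round(stage_change$regressed$percent / 100 *
                             nrow(stage_change$rates)),
                     stage_change$regressed$percent_int,
                     stage_change$regressed$lower_int,
                     stage_change$regressed$upper_int),
             sprintf("ANOVA across subtypes: F = %.2f, p = %.3g",
                     stage_change$anova$F, stage_change$anova$p), "")
    f <- file.path(out_dir, "stage_change.csv")
    utils::write.csv(stage_change$by_subtype, f, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(recovery)) {
    txt <- c(txt, "== Recovery vs ground truth ==",
             sprintf("subtype accuracy: %.3f", recovery$accuracy),
             sprintf("Kendall tau: %s",
                     paste(sprintf("%.3f", recovery$kendall_tau),
                           collapse = ", ")),
             sprintf("stage MAE: %.2f (bias %.2f)", recovery$stage_mae,
                     recovery$stage_bias), "")
  }
  f <- file.path(out_dir, "report.txt")
  writeLines(txt, f)
  files <- c(files, f)
  invisible(files)
}
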