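#' Generate ground truth for a synthetic cohort
#'
#' Fixes the generative model: an event set (default two thresholds at
#' z = 2 and 5 with ceiling 10 per region), one uniformly-drawn valid
#' event sequence per subtype, and subtype mixing fractions.
#'
#' @param B number of regions
#' @param R thresholds per region
#' @param C number of subtypes
#' @param seed integer seed
#' @param fractions optional subtype fractions (default uniform)
#' @param sequences optional list of C sequences (must respect
#'   within-region threshold order)
#' @param thresholds,z_max event-set geometry (defaults `(2, 5)` and 10;
#'   `thresholds` may be any ascending length-R vector)
#' @param regions region names (default `region1..B`, or the 10-region
#'   lobar preset when `B = 10`)
#' @return list of class `ground_truth`: `event_set`, `sequences`,
#'   `fractions`, `seed`, plus per-region raw-value mapping (`mu`, `sd`)
#'   used by the raw-value mode of [simulate_cohort()]
#' @export
generate_truth <- function(B = 10L, R = 2L, C = 3L, seed = 1L,
                           fractions = NULL, sequences = NULL,
                           thresholds = NULL, z_max = 10,
                           regions = NULL) {
  if (B < 1L || R < 1L || C < 1L) stopf("B, R and C must be >= 1")
  set.seed(seed)
  regions <- regions %||%
    (if (B == 10L) lobar_regions() else paste0("region", seq_len(B)))
  thresholds <- thresholds %||% (if (R == 2L) c(2, 5) else seq(2, 5, length.out = R))
  es <- event_set(regions, thresholds, z_max)
  if (is.null(sequences)) {
    sequences <- replicate(C, random_valid_sequence(es), simplify = FALSE)
  } else {
    if (length(sequences) != C) stopf("need %d sequences", C)
    for (S in sequences)
      if (!is_valid_sequence(S, es))
        stopf("supplied sequence violates within-region threshold order")
  }
  fractions <- fractions %||% rep(1 / C, C)
  if (length(fractions) != C || any(fractions <= 0))
    stopf("fractions must be %d positive values", C)
  # SUVR-like raw mapping for the raw-value cohort mode
  mu <- stats::runif(B, 1.0, 1.4)
  s <- stats::runif(B, 0.08, 0.15)
  names(mu) <- names(s) <- regions
  structure(list(event_set = es, sequences = sequences,
                 fractions = fractions / sum(fractions),
                 mu = mu, sd = s, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Exact model implied by a ground truth
#'
#' Wraps the true sequences and fractions as a `sustain_model`, e.g. to
#' use as a frozen reference when testing assignment and restaging in
#' isolation from fitting.
#'
#' @param truth a `ground_truth`
#' @param sigma per-region noise SD (default 1)
#' @return a `sustain_model`
#' @export
truth_model <- function(truth, sigma = 1) {
  new_sustain_model(truth$event_set, truth$sequences, truth$fractions,
                    sigma = sigma)
}

#' Simulate a baseline cohort from a ground truth
#'
#' Patients draw a subtype by the true fractions and a stage from
#' `stage_dist`, then `z = g_c(k) + Normal(0, sigma)` per region.
#' Controls draw `z ~ Normal(0, 1)`. In raw-value mode (default) z is
#' mapped through the per-region control reference
#' `value = mu_i + s_i z`, so the z-scoring and threshold-preparation
#' steps can be exercised end-to-end. A `mixed_frac` fraction of
#' patients draws values from the average of two subtypes' trajectories
#' (flagged in the truth) to emulate low-certainty, off-model scans.
#'
#' @param truth a `ground_truth`
#' @param n_patients,n_controls cohort sizes
#' @param sigma patient noise SD in z-units (> 0)
#' @param stage_dist optional function(n, N) returning integer stages in
#'   0..N (default uniform)
#' @param mixed_frac fraction of patients generated between two subtypes
#' @param raw_values map z-scores to raw (SUVR-like) values
#' @param seed integer seed
#' @return list: `table` (a [cohort_table()]), `truth` (the input truth
#'   augmented with `subjects`: per-patient true subtype, stage, mixed
#'   flag)
#' @export
simulate_cohort <- function(truth, n_patients = 300L, n_controls = 85L,
                            sigma = 1, stage_dist = NULL, mixed_frac = 0,
                            raw_values = TRUE, seed = 1L) {
  if (n_patients < 1L) stopf("need at least one patient")
  if (sigma <= 0) stopf("sigma must be > 0")
  set.seed(seed)
  es <- truth$event_set
  B <- length(es$regions)
  N <- n_events(es)
  C <- length(truth$sequences)
  stage_dist <- stage_dist %||% function(n, N) sample(0:N, n, replace = TRUE)
  subtype <- sample.int(C, n_patients, replace = TRUE, prob = truth$fractions)
  stage <- as.integer(stage_dist(n_patients, N))
  mixed <- stats::runif(n_patients) < mixed_frac
  G <- lapply(truth$sequences, expected_values, es = es)
  Zpat <- matrix(NA_real_, n_patients, B, dimnames = list(NULL, es$regions))
  mix_with <- rep(NA_integer_, n_patients)
  for (j in seq_len(n_patients)) {
    g <- G[[subtype[j]]][, stage[j] + 1L]
    if (mixed[j] && C > 1L) {
      others <- setdiff(seq_len(C), subtype[j])
      other <- others[sample.int(length(others), 1L)]
      mix_with[j] <- other
      g <- (g + G[[other]][, stage[j] + 1L]) / 2
    }
    Zpat[j, ] <- g + stats::rnorm(B, 0, sigma)
  }
  Zctl <- matrix(stats::rnorm(n_controls * B), n_controls, B,
                 dimnames = list(NULL, es$regions))
  to_values <- function(Z) {
    if (!raw_values) return(Z)
    sweep(sweep(Z, 2, truth$sd, "*"), 2, truth$mu, "+")
  }
  ids_p <- sprintf("pat%04d", seq_len(n_patients))
  ids_c <- sprintf("ctl%04d", seq_len(n_controls))
  df <- data.frame(
    subject_id = c(ids_c, ids_p),
    visit_index = 0L,
    time_from_baseline = 0,
    group = rep(c("control", "patient"), c(n_controls, n_patients)),
    rbind(to_values(Zctl), to_values(Zpat)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  truth$subjects <- data.frame(subject_id = ids_p, subtype = subtype,
                               stage = stage, mixed = mixed,
                               mixed_with = mix_with,
                               stringsAsFactors = FALSE)
  truth$sigma <- sigma
  truth$raw_values <- raw_values
  list(table = cohort_table(df, es$regions), truth = truth)
}

#' Simulate longitudinal follow-up visits
#'
#' Each patient receives follow-up scans whose true stage advances by
#' `round(rate * dt)` (clamped to `0..N`), with a per-subject rate drawn
#' from `Normal(rate_mean, rate_sd)`. Follow-up intervals default to one
#' visit at `|Normal(interval_mean, interval_sd)|` years (floored at
#' 0.25). With probability `switch_prob` a subject's generating subtype
#' switches at follow-up, to exercise the stability metrics. Values are
#' regenerated from the trajectory at the new stage with the same noise
#' model as the baseline cohort.
#'
#' @param cohort output of [simulate_cohort()]
#' @param rate_mean,rate_sd stage/year progression distribution
#'   (defaults 0.56 and 0.70)
#' @param interval_mean,interval_sd follow-up interval distribution in
#'   years (defaults 1.90 and 0.94)
#' @param visit_times optional fixed vector of follow-up times (years,
#'   > 0) applied to every subject
#' @param switch_prob probability of a subtype switch at follow-up
#' @param seed integer seed
#' @return list: `table` (baseline plus follow-up rows), `truth`
#'   (augmented with `followups`: per-visit true subtype and stage)
#' @export
simulate_followups <- function(cohort, rate_mean = 0.56, rate_sd = 0.70,
                               interval_mean = 1.90, interval_sd = 0.94,
                               visit_times = NULL, switch_prob = 0,
                               seed = 1L) {
  set.seed(seed)
  truth <- cohort$truth
  es <- truth$event_set
  B <- length(es$regions)
  N <- n_events(es)
  C <- length(truth$sequences)
  G <- lapply(truth$sequences, expected_values, es = es)
  subj <- truth$subjects
  if (!is.null(visit_times) && any(visit_times <= 0))
    stopf("visit times must be positive")
  rows <- list()
  fu <- list()
  for (j in seq_len(nrow(subj))) {
    times <- visit_times %||% max(0.25, abs(stats::rnorm(1, interval_mean,
                                                         interval_sd)))
    rate <- stats::rnorm(1, rate_mean, rate_sd)
    cur_subtype <- subj$subtype[j]
    for (v in seq_along(times)) {
      if (stats::runif(1) < switch_prob && C > 1L) {
        others <- setdiff(seq_len(C), cur_subtype)
        cur_subtype <- others[sample.int(length(others), 1L)]
      }
      k <- max(0L, min(N, subj$stage[j] + as.integer(round(rate * times[v]))))
      z <- G[[cur_subtype]][, k + 1L] + stats::rnorm(B, 0, truth$sigma)
      val <- if (isTRUE(truth$raw_values)) truth$mu + truth$sd * z else z
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj$subject_id[j], visit_index = v,
        time_from_baseline = times[v], group = "patient",
        as.list(val), check.names = FALSE, stringsAsFactors = FALSE)
      fu[[length(fu) + 1L]] <- data.frame(
        subject_id = subj$subject_id[j], visit_index = v,
        subtype = cur_subtype, stage = k, rate = rate,
        stringsAsFactors = FALSE)
    }
  }
  table <- cohort_table(rbind(as.data.frame(cohort$table),
                              do.call(rbind, rows)),
                        cohort_regions(cohort$table))
  truth$followups <- do.call(rbind, fu)
  list(table = table, truth = truth)
}
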