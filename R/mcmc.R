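#' Metropolis sampling of event orderings
#'
#' Samples subtype event sequences around a fitted model to quantify
#' ordering uncertainty. Each iteration picks a subtype and an event
#' uniformly, proposes a uniformly-random valid position for the event,
#' and accepts with probability `min(1, L_new / L_old)` on the total
#' data likelihood; subtype fractions are held at their EM estimates.
#' Positional-variance matrices (`PV_c[e, pos]` = fraction of retained
#' samples placing event `e` at position `pos`) are assembled from the
#' samples.
#'
#' @param model fitted `sustain_model`
#' @param Z scan x region z-score matrix used for the fit
#' @param n_iter number of iterations (>= 100)
#' @param seed integer seed
#' @param thin keep every `thin`-th state (default 1)
#' @return list of class `mcmc_samples`: `sequences` (per subtype, list
#'   of sampled sequences), `loglik` (per retained state),
#'   `positional_variance` (per subtype `N x N` matrix),
#'   `acceptance_rate`
#' @export
run_mcmc <- function(model, Z, n_iter = 5000L, seed = 1L, thin = 1L) {
  if (n_iter < 100L) stopf("n_iter must be >= 100")
  set.seed(seed)
  es <- model$event_set
  ev <- es$events
  N <- n_events(es)
  C <- length(model$sequences)
  seqs <- model$sequences
  lf <- log(model$fractions)
  # cache per-subtype marginal log-likelihood columns; only the proposed
  # subtype's column changes per iteration
  M <- subject_log_likelihood(Z, model)$subtype_loglik
  ll <- sum(row_logsumexp(sweep(M, 2, lf, "+")))
  kept <- vector("list", C)
  for (c in seq_len(C)) kept[[c]] <- list()
  ll_kept <- numeric(0)
  n_acc <- 0L
  for (it in seq_len(n_iter)) {
    c <- sample.int(C, 1L)
    e <- sample.int(N, 1L)
    S <- seqs[[c]]
    cur_pos <- which(S == e)
    S_rm <- S[-cur_pos]
    same <- ev$event[ev$region_index == ev$region_index[e]]
    below <- same[ev$threshold_index[same] < ev$threshold_index[e]]
    above <- same[ev$threshold_index[same] > ev$threshold_index[e]]
    lo <- if (length(below)) max(match(below, S_rm)) + 1L else 1L
    hi <- if (length(above)) min(match(above, S_rm)) else N
    p <- if (lo == hi) lo else sample(lo:hi, 1L)
    S_new <- append(S_rm, e, after = p - 1L)
    col_new <- row_logsumexp(loglik_matrix(Z, S_new, es, model$sigma)) -
      log(N + 1)
    M_new <- M
    M_new[, c] <- col_new
    ll_prop <- sum(row_logsumexp(sweep(M_new, 2, lf, "+")))
    if (log(stats::runif(1)) < ll_prop - ll) {
      seqs[[c]] <- S_new
      M <- M_new
      ll <- ll_prop
      if (p != cur_pos) n_acc <- n_acc + 1L
    }
    if (it %% thin == 0L) {
      for (cc in seq_len(C))
        kept[[cc]][[length(kept[[cc]]) + 1L]] <- seqs[[cc]]
      ll_kept <- c(ll_kept, ll)
    }
  }
  pv <- lapply(kept, function(samples) {
    m <- matrix(0, N, N, dimnames = list(event_labels(es), NULL))
    for (S in samples) {
      pos <- sequence_positions(S)
      m[cbind(seq_len(N), pos)] <- m[cbind(seq_len(N), pos)] + 1
    }
    m / length(samples)
  })
  structure(list(sequences = kept, loglik = ll_kept,
                 positional_variance = pv,
                 acceptance_rate = n_acc / n_iter),
            class = "mcmc_samples")
}

event_labels <- function(es) {
  with(es$events, paste0(region, "@z", threshold_index))
}

#' Cross-validated model selection over subtype counts
#'
#' Subjects are partitioned into seeded random folds; for each fold the
#' models for every candidate subtype count are fitted on the training
#' portion (one divisive hierarchical pass) and the held-out
#' log-likelihood of the test portion is computed with the training
#' fractions. `CVIC(C) = -2 * sum over folds of held-out log-likelihood`.
#' The curve is reported; no automatic selection is made.
#'
#' @param Z scan x region z-score matrix (one row per subject baseline)
#' @param C_range candidate subtype counts (contiguous from 1 recommended)
#' @param k_folds number of folds (>= 2)
#' @param es event set
#' @param config a [run_config()]
#' @param seed integer seed for the fold partition and fits
#' @return list of class `cv_result`: `cvic` (named by C), `heldout`
#'   (fold x C matrix), `folds` (per-subject fold index), `seed`
#' @export
cross_validate <- function(Z, C_range, k_folds, es, config = run_config(),
                           seed = derive_seed(config$seed, 307L)) {
  if (k_folds < 2L) stopf("k_folds must be >= 2")
  n <- nrow(Z)
  C_max <- max(C_range)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k_folds), n))
  if (min(table(folds)) < C_max) stopf("a fold has fewer subjects than C")
  heldout <- matrix(NA_real_, k_folds, length(C_range),
                    dimnames = list(NULL, paste0("C", C_range)))
  for (f in seq_len(k_folds)) {
    train <- Z[folds != f, , drop = FALSE]
    test <- Z[folds == f, , drop = FALSE]
    models <- hierarchical_fit(train, C_max, es, config,
                               seed = derive_seed(seed, 1000L + f))
    for (j in seq_along(C_range)) {
      m <- models[[C_range[j]]]
      heldout[f, j] <- sum(subject_log_likelihood(test, m)$total_loglik)
    }
  }
  cvic <- -2 * colSums(heldout)
  structure(list(cvic = cvic, heldout = heldout, folds = folds,
                 C_range = C_range, seed = seed),
            class = "cv_result")
}

#' Locate the elbow of a CVIC curve
#'
#' The elbow is the smallest subtype count beyond which no further gain
#' exceeds `frac` of the largest single-step gain (gains below zero
#' count as zero).
#'
#' @param cv a `cv_result` (or a named CVIC vector)
#' @param frac gain fraction defining "flat" (default 0.1)
#' @return integer subtype count at the elbow
#' @export
cvic_elbow <- function(cv, frac = 0.1) {
  cvic <- if (inherits(cv, "cv_result")) cv$cvic else cv
  if (length(cvic) < 2L) return(1L)
  gains <- pmax(-diff(cvic), 0) # gain of moving C -> C+1
  cutoff <- frac * max(gains)
  big <- which(gains > cutoff)
  if (!length(big)) return(1L)
  as.integer(max(big) + 1L)
}
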