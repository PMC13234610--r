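#' Run configuration defaults
#'
#' Central knob container consumed by the fitting, MCMC and
#' cross-validation routines. Every stochastic step derives its stream
#' from the single `seed`.
#'
#' @param regions region names (informational; recorded in outputs)
#' @param n_thresholds thresholds per region used at preparation
#' @param n_subtypes subtype count or range explored
#' @param n_startpoints EM restarts per fit
#' @param em_tol relative log-likelihood convergence tolerance
#' @param em_max_iter EM iteration cap
#' @param mcmc_iter MCMC iterations per subtype set
#' @param cv_folds cross-validation fold count
#' @param prob_threshold poor-fit exclusion threshold on the maximum
#'   subtype posterior
#' @param sigma per-region noise SD for the z-score model
#' @param seed master random seed (integer)
#' @return list of class `run_config`
#' @export
run_config <- function(regions = lobar_regions(), n_thresholds = 2L,
                       n_subtypes = 1:3, n_startpoints = 10L,
                       em_tol = 1e-6, em_max_iter = 100L,
                       mcmc_iter = 5000L, cv_folds = 5L,
                       prob_threshold = 0.5, sigma = 1, seed = 1L) {
  if (n_thresholds < 1L) stopf("n_thresholds must be >= 1")
  if (prob_threshold < 0 || prob_threshold > 1)
    stopf("prob_threshold must be in [0, 1]")
  structure(list(regions = regions, n_thresholds = as.integer(n_thresholds),
                 n_subtypes = as.integer(n_subtypes),
                 n_startpoints = as.integer(n_startpoints),
                 em_tol = em_tol, em_max_iter = as.integer(em_max_iter),
                 mcmc_iter = as.integer(mcmc_iter),
                 cv_folds = as.integer(cv_folds),
                 prob_threshold = prob_threshold, sigma = sigma,
                 seed = as.integer(seed)),
            class = "run_config")
}

new_sustain_model <- function(es, sequences, fractions, sigma = 1,
                              loglik = NA_real_, trace = numeric(0)) {
  structure(list(event_set = es, sequences = sequences,
                 fractions = fractions / sum(fractions),
                 sigma = rep_len(sigma, length(es$regions)),
                 loglik = loglik, trace = trace, mcmc = NULL),
            class = "sustain_model")
}

#' @export
print.sustain_model <- function(x, ...) {
  cat(sprintf("Linear z-score subtype model: %d subtype(s), %d events\n",
              length(x$sequences), n_events(x$event_set)))
  for (c in seq_along(x$sequences))
    cat(sprintf("  subtype %d: fraction %.3f\n", c, x$fractions[c]))
  if (is.finite(x$loglik)) cat(sprintf("  log-likelihood: %.3f\n", x$loglik))
  invisible(x)
}

# Weighted marginal log-likelihood objective for one sequence.
sequence_objective <- function(Z, w, S, es, sigma) {
  LL <- loglik_matrix(Z, S, es, sigma)
  sum(w * (row_logsumexp(LL) - log(n_events(es) + 1)))
}

#' Optimize a single event sequence by greedy reinsertion
#'
#' Coordinate ascent on the weighted marginal log-likelihood
#' `sum_j w_j log P(x_j | S)`: events are swept in a seeded-random
#' order; each is removed and re-inserted at the valid position that
#' maximizes the objective (ties keep the earliest position, and a move
#' is made only on strict improvement). Sweeps repeat until none
#' improves, so the objective never decreases.
#'
#' @param Z scan x region z-score matrix
#' @param w per-scan non-negative weights
#' @param S_init starting sequence
#' @param es event set
#' @param sigma per-region noise SD
#' @return list `sequence`, `objective`
#' @export
optimize_sequence <- function(Z, w, S_init, es, sigma = 1) {
  if (any(w < 0)) stopf("weights must be non-negative")
  if (!is_valid_sequence(S_init, es)) stopf("invalid starting sequence")
  S <- S_init
  N <- n_events(es)
  B <- length(es$regions)
  sigma <- rep_len(as.numeric(sigma), B)
  if (any(sigma <= 0)) stopf("sigma must be positive")
  storage.mode(Z) <- "double"
  repeat {
    res <- .cpp_sweep(Z, as.numeric(w), sigma, S, sample.int(N),
                      es$event_region, es$event_thr,
                      unname(es$thresholds), unname(es$z_max))
    S <- res$sequence
    if (!res$improved) break
  }
  list(sequence = S, objective = res$objective)
}

#' Fit a C-subtype model by expectation-maximization
#'
#' Alternates the E-step (subtype responsibilities under the current
#' sequences and fractions) with the M-step (greedy sequence
#' optimization per subtype and fraction update), from
#' `n_startpoints` seeded random initializations; the best restart is
#' returned. The observed-data log-likelihood is non-decreasing across
#' iterations.
#'
#' @param Z scan x region z-score matrix (baseline patient scans)
#' @param C number of subtypes
#' @param es event set
#' @param config a [run_config()]
#' @param inits optional list of initializations, each a list of C
#'   sequences (overrides random starts)
#' @param seed seed for this fit (default derived from `config$seed`)
#' @return a `sustain_model` with `loglik` and iteration `trace`
#' @export
fit_em <- function(Z, C, es, config = run_config(), inits = NULL,
                   seed = derive_seed(config$seed, 101L)) {
  n <- nrow(Z)
  if (C < 1L) stopf("C must be >= 1")
  if (n < C) stopf("need at least C subjects")
  fits <- em_restarts(Z, C, es, config, inits, seed)
  if (!length(fits))
    stopf("all EM restarts collapsed to an empty subtype")
  fits[[1]]
}

# All EM restarts that did not collapse, sorted by descending
# log-likelihood.
em_restarts <- function(Z, C, es, config, inits = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(inits))
    inits <- replicate(config$n_startpoints,
                       replicate(C, random_valid_sequence(es), simplify = FALSE),
                       simplify = FALSE)
  fits <- list()
  for (init in inits) {
    fit <- tryCatch(em_single(Z, init, es, config),
                    degenerate_subtype = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  fits[order(vapply(fits, `[[`, numeric(1), "loglik"), decreasing = TRUE)]
}

em_single <- function(Z, sequences, es, config, f_init = NULL) {
  n <- nrow(Z)
  C <- length(sequences)
  N <- n_events(es)
  f <- f_init %||% rep(1 / C, C)
  sigma <- rep_len(config$sigma, length(es$regions))
  trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(config$em_max_iter)) {
    M <- vapply(sequences, function(S)
      row_logsumexp(loglik_matrix(Z, S, es, sigma)) - log(N + 1),
      numeric(n))
    M <- matrix(M, nrow = n)
    lw <- sweep(M, 2, log(f), "+")
    lmix <- row_logsumexp(lw)
    ll <- sum(lmix)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < config$em_tol * abs(ll_old)) break
    ll_old <- ll
    w <- exp(lw - lmix)
    f_new <- colMeans(w)
    if (any(f_new < 1 / (10 * n)))
      stop(structure(class = c("degenerate_subtype", "error", "condition"),
                     list(message = "subtype fraction collapsed", call = NULL)))
    f <- f_new
    for (c in seq_len(C))
      sequences[[c]] <- optimize_sequence(Z, w[, c], sequences[[c]],
                                          es, sigma)$sequence
  }
  m <- new_sustain_model(es, sequences, f, sigma,
                         loglik = trace[length(trace)], trace = trace)
  m
}

#' Divisive hierarchical fitting for 1..C_max subtypes
#'
#' The 1-subtype model is fitted directly. Each larger model is seeded
#' by splitting: subjects are hard-assigned to their maximum-likelihood
#' subtype, each sufficiently large subtype's members are fitted with a
#' 2-subtype model, and each resulting candidate (split sequences plus
#' the remaining ones) is refined by EM on the full data; the
#' best-likelihood candidate is kept. Training log-likelihood is
#' non-decreasing in C.
#'
#' @inheritParams fit_em
#' @param C_max largest subtype count to fit
#' @return list of `sustain_model`, element `[[C]]` having C subtypes
#' @export
hierarchical_fit <- function(Z, C_max, es, config = run_config(),
                             seed = derive_seed(config$seed, 211L)) {
  models <- vector("list", C_max)
  models[[1]] <- fit_em(Z, 1L, es, config, seed = derive_seed(seed, 1L))
  if (C_max < 2L) return(models)
  for (C in 2:C_max) {
    prev <- models[[C - 1L]]
    sl <- subject_log_likelihood(Z, prev)$subtype_loglik
    post <- sweep(sl, 2, log(prev$fractions), "+")
    hard <- max.col(post, ties.method = "first")
    candidates <- list()
    for (s in seq_len(C - 1L)) {
      members <- which(hard == s)
      if (length(members) < 2L * C) next # too small to split
      split_fits <- em_restarts(Z[members, , drop = FALSE], 2L, es, config,
                                seed = derive_seed(seed, 10L * C + s))
      # refine the top two distinct split solutions for search diversity
      keep <- seq_len(min(2L, length(split_fits)))
      if (length(keep) == 2L &&
          abs(split_fits[[1]]$loglik - split_fits[[2]]$loglik) < 1e-6)
        keep <- 1L
      for (k in keep) {
        split_fit <- split_fits[[k]]
        seqs <- c(prev$sequences[-s], split_fit$sequences)
        fr <- c(prev$fractions[-s],
                prev$fractions[s] * split_fit$fractions)
        refined <- tryCatch(
          em_single(Z, seqs, es, config, f_init = fr / sum(fr)),
          degenerate_subtype = function(e) NULL)
        if (!is.null(refined)) candidates <- c(candidates, list(refined))
      }
    }
    best <- NULL
    for (cand in candidates)
      if (is.null(best) || cand$loglik > best$loglik) best <- cand
    if (is.null(best) || best$loglik < prev$loglik) {
      # duplicate-subtype fallback: exactly reproduces the C-1 likelihood,
      # then EM can only improve it, preserving nesting in C
      s <- which.max(prev$fractions)
      seqs <- c(prev$sequences, prev$sequences[s])
      fr <- prev$fractions; fr[s] <- fr[s] / 2
      fr <- c(fr, fr[s])
      dup <- tryCatch(em_single(Z, seqs, es, config, f_init = fr),
                      degenerate_subtype = function(e) NULL)
      if (!is.null(dup) && (is.null(best) || dup$loglik > best$loglik))
        best <- dup
    }
    if (is.null(best)) stopf("no viable %d-subtype candidate", C)
    models[[C]] <- best
  }
  models
}
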