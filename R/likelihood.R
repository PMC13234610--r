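#' Expected z-score trajectory of an event sequence
#'
#' Under the linear z-score model a region's expected value is the
#' piecewise-linear interpolant through the knots
#' `(0, 0), (p(i,1), z_i1), ..., (p(i,R), z_iR), (N, z_max_i)`,
#' where `p(i,r)` is the 1-based sequence position of event `(i, r)`.
#' If the region's top event sits at position `N` the ceiling segment is
#' dropped and the trajectory ends at `(N, z_iR)`.
#'
#' @param S integer event sequence (permutation of event ids)
#' @param es the [event_set()]
#' @param stages stages at which to evaluate (default `0:N`)
#' @return matrix `B x length(stages)`: expected z per region (rows) and
#'   stage (columns); non-decreasing along each row.
#' @export
expected_values <- function(S, es, stages = 0:n_events(es)) {
  if (!is_valid_sequence(S, es)) stopf("invalid event sequence")
  G <- expected_values_unchecked(S, es, stages)
  dimnames(G) <- list(es$regions, NULL)
  G
}

# interpolation without validity checks or dimnames; the optimizer's
# inner loop only ever passes sequences it has kept valid
expected_values_unchecked <- function(S, es, stages = 0:length(S)) {
  N <- length(S)
  pos <- sequence_positions(S)
  B <- length(es$regions)
  G <- matrix(0, B, length(stages))
  for (i in seq_len(B)) {
    kx <- c(0, pos[es$region_events[[i]]])
    ky <- c(0, es$thresholds[[i]])
    if (kx[length(kx)] < N) {
      kx <- c(kx, N)
      ky <- c(ky, es$z_max[[i]])
    }
    idx <- findInterval(stages, kx, all.inside = TRUE)
    x0 <- kx[idx]
    G[i, ] <- ky[idx] + (stages - x0) * (ky[idx + 1L] - ky[idx]) /
      (kx[idx + 1L] - x0)
  }
  G
}

#' Per-stage log-likelihood of one scan under one sequence
#'
#' `L(k) = prod_i Normal(x_i; g_i(k), sigma_i)` for `k = 0..N`, computed
#' in log space.
#'
#' @param x numeric z-score vector, one value per region
#' @param S event sequence
#' @param es event set
#' @param sigma per-region noise SD (scalar recycled; default 1)
#' @return numeric vector of `N + 1` log-likelihoods
#' @export
stage_log_likelihoods <- function(x, S, es, sigma = 1) {
  drop(loglik_matrix(matrix(x, nrow = 1), S, es, sigma))
}

# Scan x stage log-likelihood matrix for a whole z-matrix; the workhorse
# behind every fit. One matrix product per call.
loglik_matrix <- function(Z, S, es, sigma = 1) {
  B <- length(es$regions)
  sigma <- rep_len(as.numeric(sigma), B)
  if (any(sigma <= 0)) stopf("sigma must be positive")
  G <- expected_values(S, es)
  Zs <- sweep(Z, 2, sigma, "/")
  Gs <- G / sigma
  const <- -B * 0.5 * log(2 * pi) - sum(log(sigma))
  -0.5 * (outer(rowSums(Zs^2), colSums(Gs^2), "+") - 2 * (Zs %*% Gs)) + const
}

#' Marginal and mixture log-likelihood of scans under a subtype model
#'
#' The stage is marginalised with a uniform prior over `0..N`:
#' `P(x | S_c) = (1/(N+1)) sum_k L_c(k)`; the mixture likelihood is
#' `sum_c f_c P(x | S_c)`. All sums use log-sum-exp.
#'
#' @param Z scan x region z-score matrix (a single scan may be passed as
#'   a vector)
#' @param model a `sustain_model`
#' @return list with `subtype_loglik` (scan x subtype matrix of
#'   `log P(x | S_c)`) and `total_loglik` (per-scan log mixture
#'   likelihood)
#' @export
subject_log_likelihood <- function(Z, model) {
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  es <- model$event_set
  N <- n_events(es)
  C <- length(model$sequences)
  M <- matrix(NA_real_, nrow(Z), C)
  for (c in seq_len(C)) {
    LL <- loglik_matrix(Z, model$sequences[[c]], es, model$sigma)
    M[, c] <- row_logsumexp(LL) - log(N + 1)
  }
  total <- row_logsumexp(sweep(M, 2, log(model$fractions), "+"))
  list(subtype_loglik = M, total_loglik = total)
}
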