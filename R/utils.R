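#' @keywords internal
#' @useDynLib sustainz, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log(sum(exp(x)))
#' @param x numeric vector of log-scale values
#' @return scalar log-sum-exp
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix, vectorised via max.col.
row_logsumexp <- function(m) {
  n <- nrow(m)
  if (n == 0L) return(numeric(0))
  mx <- m[cbind(seq_len(n), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

# Derive a child seed from a base seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
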