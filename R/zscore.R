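#' Fit the control z-score reference
#'
#' Per-region mean and standard deviation (n-1 denominator) of the
#' control baseline scans. Patients and control follow-up visits never
#' contribute to the reference.
#'
#' @param table a [cohort_table()]
#' @return object of class `zscore_model`: `regions`, `mu`, `sd`,
#'   `n_controls`
#' @export
fit_zscore_reference <- function(table) {
  regions <- cohort_regions(table)
  ctrl <- table$group == "control" & baseline_rows(table)
  n <- sum(ctrl)
  if (n < 2L) stopf("need at least 2 control baseline scans (got %d)", n)
  vals <- cohort_values(table)[ctrl, , drop = FALSE]
  mu <- colMeans(vals)
  s <- apply(vals, 2, stats::sd)
  zero <- which(s <= 0)
  if (length(zero))
    stopf("zero variance among controls in region '%s'", regions[zero[1]])
  structure(list(regions = regions, mu = mu, sd = s, n_controls = n),
            class = "zscore_model")
}

#' Apply a z-score reference to a cohort table
#'
#' @param table a [cohort_table()]
#' @param ref a `zscore_model` from [fit_zscore_reference()]
#' @return numeric matrix, one row per scan and one column per region,
#'   `z = (value - mu_i) / s_i`; rows follow the table, row names are
#'   `subject_id|visit_index`.
#' @export
apply_zscore <- function(table, ref) {
  regions <- cohort_regions(table)
  if (!setequal(regions, ref$regions))
    stopf("region mismatch between table and z-score reference")
  vals <- cohort_values(table, ref$regions)
  sweep(sweep(vals, 2, ref$mu, "-"), 2, ref$sd, "/")
}

#' Two-component univariate Gaussian mixture by EM
#'
#' Maximum-likelihood fit with deterministic initialization: the sample
#' is split at its median and the lower/upper halves seed the two
#' components. Components are relabeled so `m1 < m2`.
#'
#' @param values numeric vector (>= 10 values)
#' @param max_iter,tol EM iteration cap and absolute log-likelihood
#'   convergence tolerance
#' @return object of class `gmm_fit`: `mean` (m1 < m2), `sd`, `weight`,
#'   `loglik`, `converged`, `n_iter`
#' @export
fit_2gmm <- function(values, max_iter = 500L, tol = 1e-8) {
  x <- as.numeric(values)
  if (length(x) < 10L) stopf("need >= 10 values to fit a 2-GMM (got %d)", length(x))
  med <- stats::median(x)
  lower <- x[x <= med]; upper <- x[x > med]
  if (length(upper) == 0L) { lower <- x[x < med]; upper <- x[x >= med] }
  sd_floor <- max(1e-3 * stats::sd(x), 1e-6)
  m <- c(mean(lower), mean(upper))
  s <- pmax(c(stats::sd(lower), stats::sd(upper)), sd_floor, na.rm = TRUE)
  s[is.na(s)] <- sd_floor
  w <- c(length(lower), length(upper)) / length(x)
  if (stats::sd(x) == 0) {
    return(structure(list(mean = m, sd = pmax(s, 1e-6), weight = w,
                          loglik = NA_real_, converged = FALSE, n_iter = 0L),
                     class = "gmm_fit"))
  }
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, m[1], s[1])
    d2 <- w[2] * stats::dnorm(x, m[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r2 <- d2 / tot
    if (is.finite(ll_old) && ll < ll_old - 1e-9)
      warnf("2-GMM log-likelihood decreased at iteration %d", it)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; ll_old <- ll; break }
    ll_old <- ll
    n2 <- sum(r2); n1 <- length(x) - n2
    if (n1 < 1e-8 || n2 < 1e-8) { converged <- FALSE; break }
    m <- c(sum((1 - r2) * x) / n1, sum(r2 * x) / n2)
    s <- pmax(c(sqrt(sum((1 - r2) * (x - m[1])^2) / n1),
                sqrt(sum(r2 * (x - m[2])^2) / n2)), sd_floor)
    w <- c(n1, n2) / length(x)
  }
  if (m[1] > m[2]) { m <- rev(m); s <- rev(s); w <- rev(w) }
  structure(list(mean = m, sd = s, weight = w, loglik = ll_old,
                 converged = converged, n_iter = it),
            class = "gmm_fit")
}

#' Derive per-region event thresholds from a 2-GMM fit
#'
#' Default (`"gmm"`) policy: the first threshold is the equal-posterior
#' decision boundary between the two components (smallest z where the
#' abnormal component's posterior reaches 0.5), floored at 1.0; the
#' second is the abnormal component mean `m2`; the ceiling is
#' `m2 + 2 * sd2`. The returned triple is repaired to be strictly
#' ascending (gaps of 0.5) if flooring breaks the order. The `"fixed"`
#' policy ignores the fit and returns `z = (2, 5)` with `z_max = 10`.
#'
#' @param fit a `gmm_fit` (may be `NULL` for policy `"fixed"`)
#' @param policy `"gmm"` or `"fixed"`
#' @param floor lower bound for the first threshold (z-score units)
#' @return list with `z` (ascending thresholds) and `z_max`
#' @export
derive_thresholds <- function(fit, policy = c("gmm", "fixed"), floor = 1.0) {
  policy <- match.arg(policy)
  if (policy == "fixed") return(list(z = c(2, 5), z_max = 10))
  m <- fit$mean; s <- fit$sd; w <- fit$weight
  post2 <- function(z) {
    l2 <- log(w[2]) + stats::dnorm(z, m[2], s[2], log = TRUE)
    l1 <- log(w[1]) + stats::dnorm(z, m[1], s[1], log = TRUE)
    1 / (1 + exp(l1 - l2))
  }
  f <- function(z) post2(z) - 0.5
  z1 <- if (f(m[1]) >= 0 || f(m[2]) <= 0) {
    warnf("2-GMM posterior boundary not bracketed; using component midpoint")
    (m[1] + m[2]) / 2
  } else {
    stats::uniroot(f, c(m[1], m[2]), tol = 1e-10)$root
  }
  z1 <- max(z1, floor)
  z2 <- m[2]
  if (z2 <= z1) {
    warnf("abnormal-component mean (%.3f) not above first threshold (%.3f); repaired", z2, z1)
    z2 <- z1 + 0.5
  }
  z_max <- m[2] + 2 * s[2]
  if (z_max <= z2) z_max <- z2 + 0.5
  list(z = c(z1, z2), z_max = z_max)
}

#' Derive an event set from z-scored data
#'
#' Convenience wrapper for the preparation step: fits a 2-GMM per region
#' on the pooled control + patient baseline z-scores and maps each fit to
#' thresholds via [derive_thresholds()].
#'
#' @param z scan x region z-score matrix (baseline scans)
#' @param policy threshold policy, see [derive_thresholds()]
#' @return list with the `event_set`, the per-region `gmm_fits`, and the
#'   per-region `threshold_table` data frame
#' @export
prep_event_set <- function(z, policy = c("gmm", "fixed")) {
  policy <- match.arg(policy)
  regions <- colnames(z)
  fits <- vector("list", length(regions)); names(fits) <- regions
  th <- vector("list", length(regions))
  zmax <- numeric(length(regions))
  for (i in seq_along(regions)) {
    fits[[i]] <- if (policy == "gmm") fit_2gmm(z[, i]) else NULL
    d <- derive_thresholds(fits[[i]], policy)
    th[[i]] <- d$z; zmax[i] <- d$z_max
  }
  zmat <- do.call(rbind, th)
  colnames(zmat) <- paste0("z", seq_len(ncol(zmat)))
  tab <- data.frame(region = regions, zmat, z_max = zmax,
                    stringsAsFactors = FALSE)
  list(event_set = event_set(regions, th, zmax), gmm_fits = fits,
       threshold_table = tab)
}
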