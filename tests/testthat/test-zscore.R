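test_that("control reference is the baseline-control mean/SD (n-1)", {
  df <- data.frame(
    subject_id = c("c1", "c2", "c3", "p1"),
    visit_index = 0L, time_from_baseline = 0,
    group = c("control", "control", "control", "patient"),
    A = c(1.0, 1.2, 1.4, 2.0), stringsAsFactors = FALSE)
  ref <- fit_zscore_reference(cohort_table(df))
  expect_equal(unname(ref$mu["A"]), 1.2)
  expect_equal(unname(ref$sd["A"]), 0.2)
  expect_equal(ref$n_controls, 3L)

  expect_error(fit_zscore_reference(cohort_table(df[c(1, 4), ])),
               "at least 2 control")
  df$A[1:3] <- 1.1
  expect_error(fit_zscore_reference(cohort_table(df)), "zero variance")
})

test_that("control follow-up visits never enter the reference", {
  df <- data.frame(
    subject_id = c("c1", "c2", "c1", "p1"),
    visit_index = c(0L, 0L, 1L, 0L),
    time_from_baseline = c(0, 0, 1, 0),
    group = c("control", "control", "control", "patient"),
    A = c(1.0, 1.4, 99, 2.0), stringsAsFactors = FALSE)
  ref <- fit_zscore_reference(cohort_table(df))
  expect_equal(unname(ref$mu["A"]), 1.2) # the 99 is ignored
})

test_that("z-scoring matches its definition and self-standardizes controls", {
  set.seed(5)
  tr <- generate_truth(B = 3, R = 2, C = 1, seed = 5)
  sim <- simulate_cohort(tr, n_patients = 20, n_controls = 30, sigma = 1,
                         seed = 6)
  ref <- fit_zscore_reference(sim$table)
  z <- apply_zscore(sim$table, ref)
  ctrl <- sim$table$group == "control"
  expect_lt(max(abs(colMeans(z[ctrl, ]))), 1e-12)
  expect_lt(max(abs(apply(z[ctrl, ], 2, sd) - 1)), 1e-12)

  # pointwise definition
  r1 <- cohort_regions(sim$table)[1]
  v <- as.data.frame(sim$table)[[r1]]
  expect_equal(unname(z[, r1]), unname((v - ref$mu[r1]) / ref$sd[r1]))

  # affine equivariance: shift/scale raw values and the reference inputs
  df2 <- as.data.frame(sim$table)
  df2[[r1]] <- 3 * df2[[r1]] + 7
  tab2 <- cohort_table(df2, cohort_regions(sim$table))
  z2 <- apply_zscore(tab2, fit_zscore_reference(tab2))
  expect_equal(z2, apply_zscore(sim$table, ref), tolerance = 1e-10)

  bad_ref <- ref; bad_ref$regions <- c("x", "y", "z")
  expect_error(apply_zscore(sim$table, bad_ref), "region mismatch")
})

test_that("2-GMM EM recovers a well-separated mixture and is ML-competitive", {
  set.seed(17)
  x <- c(rnorm(250, 0, 1), rnorm(250, 6, 1))
  fit <- fit_2gmm(x)
  expect_true(fit$converged)
  expect_lt(fit$mean[1], fit$mean[2]) # relabeled m1 < m2
  expect_equal(fit$mean[1], 0, tolerance = 0.3)
  expect_equal(fit$mean[2], 6, tolerance = 0.3)
  expect_equal(fit$weight[1], 0.5, tolerance = 0.1)

  # independent oracle: mclust's ML fit of the same model class
  skip_if_not_installed("mclust")
  suppressMessages(withr::local_package("mclust"))
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-4)
})

test_that("2-GMM handles degenerate and single-component input", {
  expect_error(fit_2gmm(rnorm(5)), ">= 10 values")

  const_fit <- fit_2gmm(rep(2.5, 50))
  expect_false(const_fit$converged)

  set.seed(21)
  x <- rnorm(200)
  fit <- fit_2gmm(x)
  single_ll <- sum(dnorm(x, mean(x), sd(x) * sqrt(199 / 200), log = TRUE))
  expect_gte(fit$loglik, single_ll - 1e-6) # mixture nests one Gaussian
})

test_that("threshold derivation follows the posterior-boundary policy", {
  sym <- structure(list(mean = c(0, 6), sd = c(1, 1), weight = c(0.5, 0.5),
                        converged = TRUE), class = "gmm_fit")
  th <- derive_thresholds(sym)
  expect_equal(th$z, c(3, 6))      # boundary at the midpoint by symmetry
  expect_equal(th$z_max, 8)        # m2 + 2 sd2

  near <- structure(list(mean = c(0, 2), sd = c(1, 1), weight = c(0.5, 0.5),
                         converged = TRUE), class = "gmm_fit")
  th2 <- derive_thresholds(near)
  expect_equal(th2$z, c(1, 2))     # boundary 1.0 (= floor), then m2
  expect_equal(th2$z_max, 4)

  # flooring can break the order; the repair keeps a strict ascent
  low <- structure(list(mean = c(-1, 0.8), sd = c(0.4, 0.4),
                        weight = c(0.5, 0.5), converged = TRUE),
                   class = "gmm_fit")
  expect_warning(th3 <- derive_thresholds(low), "repaired")
  expect_true(all(diff(c(th3$z, th3$z_max)) > 0))

  expect_equal(derive_thresholds(NULL, policy = "fixed"),
               list(z = c(2, 5), z_max = 10))
})

test_that("event sets enumerate canonically and validate thresholds", {
  es20 <- event_set(lobar_regions(), c(2, 5), z_max = 10)
  expect_equal(n_events(es20), 20L)

  expect_equal(n_events(event_set("A", 2, 5)), 1L)

  es6 <- event_set(c("A", "B", "C"), c(2, 5), 10)
  expect_equal(n_events(es6), 6L)
  expect_equal(es6$events$region,
               rep(c("A", "B", "C"), each = 2)) # region-major order
  expect_equal(es6$events$threshold_index, rep(1:2, 3))

  expect_error(event_set("A", c(5, 2), 10), "ascending")
  expect_error(event_set("A", c(2, 5), 4), "exceed")

  tab <- data.frame(region = c("A", "B"), z1 = c(2, 1.5), z2 = c(5, 4),
                    z_max = c(10, 9))
  expect_equal(n_events(build_event_set(tab)), 4L)
})

test_that("prep_event_set derives per-region thresholds from pooled z", {
  set.seed(31)
  z <- cbind(r1 = c(rnorm(100), rnorm(100, 5)),
             r2 = c(rnorm(100), rnorm(100, 7)))
  prep <- suppressWarnings(prep_event_set(z, policy = "gmm"))
  expect_equal(n_events(prep$event_set), 4L)
  expect_true(all(diff(c(prep$threshold_table$z1[1],
                         prep$threshold_table$z2[1],
                         prep$threshold_table$z_max[1])) > 0))
  fixed <- prep_event_set(z, policy = "fixed")
  expect_equal(fixed$threshold_table$z1, c(2, 2))
  expect_equal(fixed$threshold_table$z_max, c(10, 10))
})
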