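test_that("ground truth is reproducible and honors supplied pieces", {
  t1 <- generate_truth(B = 10, R = 2, C = 3, seed = 5)
  t2 <- generate_truth(B = 10, R = 2, C = 3, seed = 5)
  expect_identical(t1$sequences, t2$sequences)
  expect_equal(n_events(t1$event_set), 20L)

  es <- event_set(c("A", "B"), c(2, 5), 10)
  S <- c(1L, 3L, 2L, 4L)
  t3 <- generate_truth(B = 2, R = 2, C = 1, seed = 1, sequences = list(S),
                       regions = c("A", "B"))
  expect_identical(t3$sequences[[1]], S)
  expect_error(generate_truth(B = 2, R = 2, C = 1, seed = 1,
                              sequences = list(c(2L, 1L, 3L, 4L)),
                              regions = c("A", "B")),
               "within-region")
  expect_error(generate_truth(B = 0), ">= 1")
})

test_that("simulated cohorts are seed-deterministic with sane controls", {
  tr <- generate_truth(B = 5, R = 2, C = 2, seed = 9)
  s1 <- simulate_cohort(tr, n_patients = 50, n_controls = 200, sigma = 1,
                        seed = 10)
  s2 <- simulate_cohort(tr, n_patients = 50, n_controls = 200, sigma = 1,
                        seed = 10)
  expect_identical(as.data.frame(s1$table), as.data.frame(s2$table))
  expect_identical(s1$truth$subjects, s2$truth$subjects)

  ref <- fit_zscore_reference(s1$table)
  z <- apply_zscore(s1$table, ref)
  ctrl <- s1$table$group == "control"
  expect_lt(max(abs(colMeans(z[ctrl, ]))), 1e-10) # exact post-standardization
  # raw-value mode: control raw values live on the reference scale
  raw <- sustainz:::cohort_values(s1$table)[ctrl, ]
  expect_equal(unname(colMeans(raw)), unname(tr$mu), tolerance = 0.1)

  expect_error(simulate_cohort(tr, n_patients = 10, sigma = 0), "sigma")
})

test_that("the noiseless limit recovers subtype and stage for every patient", {
  # rotated-region sequences: distinct first events, so subtype
  # trajectories are distinguishable at every stage >= 1
  rot_seq <- function(c, B = 5L) {
    regs <- ((c - 1L + 0:(B - 1L)) %% B) + 1L
    c(2L * regs - 1L, 2L * regs)
  }
  tr <- generate_truth(B = 5, R = 2, C = 3, seed = 13,
                       sequences = lapply(1:3, rot_seq))
  sim <- simulate_cohort(tr, n_patients = 60, n_controls = 10, sigma = 1e-4,
                         raw_values = FALSE, seed = 14)
  Z <- sustainz:::cohort_values(sim$table)[sim$table$group == "patient", ]
  m <- truth_model(tr, sigma = 1e-4)
  a <- assign_cohort(Z, m, prob_threshold = 0)
  nonzero <- sim$truth$subjects$stage >= 1
  expect_equal(a$subtype[nonzero], sim$truth$subjects$subtype[nonzero])
  expect_equal(a$stage, sim$truth$subjects$stage)
})

test_that("noiseless end-to-end pipeline with fixed thresholds recovers truth", {
  S <- withr::with_seed(77, {
    tr0 <- generate_truth(B = 4, R = 2, C = 1, seed = 77)
    tr0$sequences[[1]]
  })
  tr <- generate_truth(B = 4, R = 2, C = 1, seed = 77)
  sim <- simulate_cohort(tr, n_patients = 80, n_controls = 40, sigma = 1e-3,
                         stage_dist = function(n, N) rep(0:N, length.out = n),
                         raw_values = TRUE, seed = 78)
  ref <- fit_zscore_reference(sim$table)
  Z <- apply_zscore(sim$table, ref)[sim$table$group == "patient", ]
  prep <- prep_event_set(Z, policy = "fixed")
  fit <- fit_em(Z, 1L, prep$event_set,
                run_config(n_startpoints = 2L, seed = 79L))
  expect_identical(fit$sequences[[1]], tr$sequences[[1]])
})

test_that("follow-up visits advance the true stage as configured", {
  tr <- generate_truth(B = 4, R = 2, C = 2, seed = 21)
  sim <- simulate_cohort(tr, n_patients = 40, n_controls = 10, sigma = 1,
                         seed = 22)
  lon <- simulate_followups(sim, rate_mean = 1, rate_sd = 0,
                            visit_times = 2, switch_prob = 0, seed = 23)
  N <- n_events(tr$event_set)
  fu <- lon$truth$followups
  base <- lon$truth$subjects
  expect_equal(fu$stage,
               pmin(N, pmax(0L, base$stage[match(fu$subject_id,
                                                 base$subject_id)] + 2L)))
  # switch_prob = 0 keeps every subject's generating subtype
  expect_equal(fu$subtype, base$subtype[match(fu$subject_id, base$subject_id)])
  # table gained one row per patient
  expect_equal(nrow(lon$table), nrow(sim$table) + 40)
  expect_error(simulate_followups(sim, visit_times = -1), "positive")
})

test_that("subtype switches appear only when requested", {
  tr <- generate_truth(B = 4, R = 2, C = 2, seed = 31)
  sim <- simulate_cohort(tr, n_patients = 60, n_controls = 10, sigma = 1,
                         seed = 32)
  lon <- simulate_followups(sim, switch_prob = 1, visit_times = 1, seed = 33)
  base <- lon$truth$subjects
  fu <- lon$truth$followups
  expect_true(all(fu$subtype !=
                    base$subtype[match(fu$subject_id, base$subject_id)]))
})
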