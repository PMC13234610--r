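test_that("greedy reinsertion finds the exhaustive-enumeration optimum", {
  # 3 single-threshold events: all 6 permutations are valid
  es <- event_set(c("A", "B", "C"), 2, z_max = 6)
  S_true <- c(2L, 1L, 3L)
  Z <- sim_z(es, S_true, n = 50, sigma = 1, seed = 13)
  w <- rep(1, nrow(Z))
  seqs <- sustainz:::enumerate_valid_sequences(es)
  expect_length(seqs, 6L)
  objs <- vapply(seqs, function(S)
    sum(subject_log_likelihood(Z, sustainz:::new_sustain_model(es, list(S), 1))$total_loglik),
    numeric(1))
  set.seed(14)
  got <- optimize_sequence(Z, w, seqs[[1]], es)
  expect_equal(got$objective, max(objs), tolerance = 1e-10)
  expect_identical(got$sequence, seqs[[which.max(objs)]])
})

test_that("noiseless data recover the generating sequence exactly", {
  es <- event_set(c("A", "B", "C"), c(2, 5), 10)
  S_true <- sustainz:::random_valid_sequence(es)
  Z <- sim_z(es, S_true, n = 40, sigma = 1e-3, stages = rep(0:6, length.out = 40),
             seed = 15)
  set.seed(16)
  got <- optimize_sequence(Z, rep(1, 40), sustainz:::random_valid_sequence(es), es)
  expect_identical(got$sequence, S_true)
})

test_that("all-zero weights leave the starting sequence unchanged", {
  es <- es_ab()
  Z <- matrix(rnorm(10 * 2), 10, 2)
  set.seed(17)
  got <- optimize_sequence(Z, rep(0, 10), seq_ab(), es)
  expect_identical(got$sequence, seq_ab())
  expect_equal(got$objective, 0)

  expect_error(optimize_sequence(Z, rep(-1, 10), seq_ab(), es),
               "non-negative")
  expect_error(optimize_sequence(Z, rep(1, 10), c(2L, 1L, 3L, 4L), es),
               "invalid")
})

test_that("one-subtype EM reduces to plain sequence optimization", {
  es <- event_set(c("A", "B", "C"), c(2, 5), 10)
  Z <- sim_z(es, sustainz:::random_valid_sequence(es), n = 30, sigma = 1,
             seed = 19)
  cfg <- run_config(n_startpoints = 1L, seed = 20L)
  S0 <- list(list(sustainz:::random_valid_sequence(es)))
  fit <- fit_em(Z, 1L, es, cfg, inits = S0, seed = 21L)
  set.seed(21L)
  ref <- optimize_sequence(Z, rep(1, nrow(Z)), S0[[1]][[1]], es)
  expect_identical(fit$sequences[[1]], ref$sequence)
  expect_equal(fit$loglik, ref$objective, tolerance = 1e-10)
})

test_that("EM log-likelihood trace is non-decreasing and C = 2 nests C = 1", {
  es <- event_set(c("A", "B", "C"), c(2, 5), 10)
  cfg <- run_config(n_startpoints = 3L, seed = 1L)
  for (s in 1:8) {
    S1 <- withr::with_seed(s, sustainz:::random_valid_sequence(es))
    S2 <- withr::with_seed(s + 50, sustainz:::random_valid_sequence(es))
    set.seed(s + 100)
    lab <- sample(1:2, 40, replace = TRUE, prob = c(0.6, 0.4))
    Z <- rbind(sim_z(es, S1, sum(lab == 1), sigma = 1, seed = s + 200),
               sim_z(es, S2, sum(lab == 2), sigma = 1, seed = s + 300))
    models <- hierarchical_fit(Z, 2L, es, cfg, seed = s)
    for (m in models)
      expect_true(all(diff(m$trace) >= -1e-8))
    expect_gte(models[[2]]$loglik, models[[1]]$loglik - 1e-8)
    for (m in models)
      for (S in m$sequences)
        expect_true(is_valid_sequence(S, es))
  }
})

test_that("fractions sum to one and respect the degeneracy guard", {
  es <- event_set(c("A", "B", "C"), c(2, 5), 10)
  S_true <- withr::with_seed(9, sustainz:::random_valid_sequence(es))
  Z <- sim_z(es, S_true, n = 40, sigma = 1, seed = 31)
  fit <- fit_em(Z, 2L, es, run_config(n_startpoints = 3L, seed = 5L))
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-12)
  expect_true(all(fit$fractions >= 1 / 400))
  expect_error(fit_em(Z, 0L, es), "C must be")
})

test_that("data from one sequence yield no meaningful 2-subtype split", {
  es <- event_set(c("A", "B", "C"), c(2, 5), 10)
  S_true <- withr::with_seed(10, sustainz:::random_valid_sequence(es))
  Z <- sim_z(es, S_true, n = 60, sigma = 1, seed = 33)
  models <- hierarchical_fit(Z, 2L, es, run_config(n_startpoints = 4L, seed = 6L),
                             seed = 61L)
  sl <- subject_log_likelihood(Z, models[[2]])$subtype_loglik
  # the two subtypes explain each subject about equally well
  expect_lt(mean(abs(sl[, 1] - sl[, 2])), 1)
})
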