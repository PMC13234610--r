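test_that("Cohen's kappa matches hand computation and its invariances", {
  m <- matrix(c(45, 5, 5, 45), 2, 2)
  k <- cohen_kappa(m)
  expect_equal(k$p_observed, 0.9)
  expect_equal(k$p_expected, 0.5)
  expect_equal(k$kappa, 0.8)

  expect_equal(cohen_kappa(diag(c(50, 50)))$kappa, 1)
  expect_equal(cohen_kappa(diag(c(10, 20, 70)))$kappa, 1)

  # simultaneous row/column permutation leaves kappa unchanged
  m3 <- matrix(c(40, 6, 2, 3, 30, 5, 1, 4, 20), 3, 3)
  p <- c(3, 1, 2)
  expect_equal(cohen_kappa(m3[p, p])$kappa, cohen_kappa(m3)$kappa)

  # independent cross-check
  skip_if_not_installed("e1071")
  expect_equal(k$kappa, e1071::classAgreement(m)$kappa)
  expect_equal(cohen_kappa(m3)$kappa, e1071::classAgreement(m3)$kappa)

  expect_error(cohen_kappa(matrix(1:6, 2, 3)), "square")
})

test_that("Wald intervals reproduce printed count/CI triples", {
  # (k, n, percent, lower, upper) reference triples
  triples <- rbind(
    c(14, 23, 61, 41, 81),
    c(11, 172, 6, 3, 10),
    c(161, 172, 94, 90, 97),
    c(359, 365, 98, 97, 100),
    c(6, 365, 2, 0, 3),
    c(144, 359, 40, 35, 45),
    c(111, 359, 31, 26, 36),
    c(104, 359, 29, 24, 34),
    c(290, 359, 81, 77, 85),
    c(78, 104, 75, 67, 83),
    c(69, 359, 19, 15, 23),
    c(19, 24, 79, 63, 95),
    c(201, 359, 56, 51, 61)
  )
  for (i in seq_len(nrow(triples))) {
    ci <- proportion_ci(triples[i, 1], triples[i, 2])
    expect_equal(ci$percent_int, triples[i, 3],
                 label = sprintf("%d/%d percent", triples[i, 1], triples[i, 2]))
    expect_equal(ci$lower_int, triples[i, 4],
                 label = sprintf("%d/%d lower", triples[i, 1], triples[i, 2]))
    expect_equal(ci$upper_int, triples[i, 5],
                 label = sprintf("%d/%d upper", triples[i, 1], triples[i, 2]))
  }
  # retention as a one-decimal percentage
  expect_equal(round(proportion_ci(172, 201)$percent, 1), 85.6)

  # degenerate boundary is clamped
  ci0 <- proportion_ci(0, 10)
  expect_equal(c(ci0$percent_int, ci0$lower_int, ci0$upper_int), c(0, 0, 0))
  expect_error(proportion_ci(5, 0), "n must be")
  expect_error(proportion_ci(11, 10), "k must be")
})

# A hand-built assignment table: 6 subjects, two visits each.
toy_assignments <- function() {
  data.frame(
    subject_id = rep(sprintf("s%d", 1:6), each = 2),
    visit_index = rep(0:1, 6),
    subtype = c(1, 1, 1, 1, 2, 2, 2, 1, 1, 1, 2, 2),
    stage = c(8, 10, 4, 5, 6, 6, 3, 7, 2, 2, 10, 12),
    excluded = FALSE,
    time_from_baseline = rep(c(0, 2), 6),
    stringsAsFactors = FALSE
  )
}

test_that("stability report counts retained subjects and excludes poor fits", {
  a <- toy_assignments()
  st <- stability_report(a, n_subtypes = 2)
  expect_equal(sum(st$confusion), 6)
  expect_equal(unname(diag(st$confusion)), c(3, 2)) # s4 switched 2 -> 1
  expect_equal(st$retention$percent, 100 * 5 / 6)

  # excluding one subject's last visit drops it from the matrix
  a$excluded[a$subject_id == "s1" & a$visit_index == 1] <- TRUE
  st2 <- stability_report(a, n_subtypes = 2)
  expect_equal(sum(st2$confusion), 5)

  expect_error(stability_report(a[a$visit_index == 0, ], 2), "no subjects")
})

test_that("annual stage change restricts to retained subjects", {
  a <- toy_assignments()
  ch <- annual_stage_change(a)
  # retained subjects: s1 (2/2), s2 (1/2), s3 (0/2), s5 (0/2), s6 (2/2)
  expect_equal(nrow(ch$rates), 5)
  expect_equal(sort(ch$rates$rate), sort(c(1, 0.5, 0, 0, 1)))
  expect_equal(ch$overall_mean, 0.5)
  expect_equal(ch$regressed$percent, 0)
  expect_equal(ch$stable_or_progressed$percent, 100)

  # identical rates in every subtype give a zero ANOVA statistic
  b <- toy_assignments()
  b$stage <- b$stage[c(1, 1, 3, 3, 5, 5, 7, 7, 9, 9, 11, 11)] + rep(c(0, 2), 6)
  b$subtype <- rep(c(1, 1, 1, 1, 2, 2), each = 2)
  ch2 <- annual_stage_change(b)
  expect_equal(unique(ch2$rates$rate), 1)
  expect_equal(ch2$anova$F, 0)
})

test_that("frozen-model restaging is stateless and order-invariant", {
  tr <- generate_truth(B = 4, R = 2, C = 2, seed = 51)
  sim <- simulate_cohort(tr, n_patients = 25, n_controls = 15, sigma = 1,
                         seed = 52)
  lon <- simulate_followups(sim, seed = 53)
  ref <- fit_zscore_reference(lon$table)
  m <- truth_model(tr)

  a1 <- restage_followups(lon$table, m, ref)
  # permuting scan rows changes nothing per scan
  df <- as.data.frame(lon$table)
  set.seed(54)
  df_perm <- df[sample(nrow(df)), ]
  a2 <- restage_followups(cohort_table(df_perm, cohort_regions(lon$table)),
                          m, ref)
  key <- function(a) a[order(a$subject_id, a$visit_index), ]
  expect_equal(key(a1)$subtype, key(a2)$subtype)
  expect_equal(key(a1)$stage, key(a2)$stage)

  # a follow-up identical to the baseline scan gets the identical record
  one <- df[df$subject_id == df$subject_id[df$group == "patient"][1] &
              df$visit_index == 0, ]
  dup <- one; dup$visit_index <- 5L; dup$time_from_baseline <- 2
  a3 <- restage_followups(cohort_table(rbind(one, dup),
                                       cohort_regions(lon$table)), m, ref)
  expect_equal(a3$subtype[1], a3$subtype[2])
  expect_equal(a3$stage[1], a3$stage[2])
  expect_equal(a3$p_subtype1[1], a3$p_subtype1[2])
})
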