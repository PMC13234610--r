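# Small in-code fixtures shared across test files.

# Two regions A, B with thresholds (2, 5) and ceiling 10: the 4-event
# model used for hand-computed examples.
es_ab <- function() event_set(c("A", "B"), c(2, 5), z_max = 10)

# The worked-example sequence [A1, B1, A2, B2] in event ids
# (A1 = 1, A2 = 2, B1 = 3, B2 = 4).
seq_ab <- function() c(1L, 3L, 2L, 4L)

# Minimal valid cohort data frame: one control, one patient baseline,
# one patient follow-up, two regions.
tiny_cohort_df <- function() {
  data.frame(
    subject_id = c("c1", "p1", "p1"),
    visit_index = c(0L, 0L, 1L),
    time_from_baseline = c(0, 0, 1.5),
    group = c("control", "patient", "patient"),
    A = c(1.1, 1.9, 2.3),
    B = c(0.9, 1.2, 1.4),
    stringsAsFactors = FALSE
  )
}

# z-matrix simulated from a single known sequence (no subtype mixing).
sim_z <- function(es, S, n, sigma = 1, stages = NULL, seed = 1) {
  set.seed(seed)
  N <- n_events(es)
  stages <- stages %||% sample(0:N, n, replace = TRUE)
  G <- expected_values(S, es)
  Z <- t(vapply(stages, function(k)
    G[, k + 1L] + rnorm(length(es$regions), 0, sigma),
    numeric(length(es$regions))))
  colnames(Z) <- es$regions
  attr(Z, "stages") <- stages
  Z
}

`%||%` <- function(a, b) if (is.null(a)) b else a
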