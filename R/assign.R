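#' Assign a scan to a subtype and stage
#'
#' Subtype posterior `P(c|x) = f_c P(x|S_c) / sum_c' f_c' P(x|S_c')`;
#' the scan is assigned to the maximum-posterior subtype (ties to the
#' lowest index), then to the maximum-probability stage within that
#' subtype (`P(k|x, c) proportional to L_c(k)`, ties to the lowest
#' stage). A scan is flagged excluded when its maximum subtype posterior
#' falls below `prob_threshold`; its subtype and stage are still
#' recorded.
#'
#' @param x z-score vector for one scan (one value per region)
#' @param model fitted `sustain_model`
#' @param prob_threshold poor-fit exclusion threshold in `[0, 1]`
#' @return list of class `assignment`: `subtype_posterior`, `subtype`,
#'   `stage_posterior`, `stage` (0..N), `excluded`, `stage_zero`
#' @export
assign_scan <- function(x, model, prob_threshold = 0.5) {
  if (prob_threshold < 0 || prob_threshold > 1)
    stopf("prob_threshold must be in [0, 1]")
  es <- model$event_set
  if (length(x) != length(es$regions)) stopf("region mismatch")
  sl <- subject_log_likelihood(x, model)
  lp <- sl$subtype_loglik[1, ] + log(model$fractions)
  post <- exp(lp - logsumexp(lp))
  subtype <- which.max(post) # first max: lowest index on ties
  LL <- stage_log_likelihoods(x, model$sequences[[subtype]], es, model$sigma)
  stage_post <- exp(LL - logsumexp(LL))
  stage <- which.max(stage_post) - 1L
  list(subtype_posterior = post, subtype = subtype,
       stage_posterior = stage_post, stage = stage,
       excluded = max(post) < prob_threshold,
       stage_zero = stage == 0L)
}

#' Assign every scan of a z-matrix
#'
#' @param Z scan x region z-score matrix; row names `subject|visit` are
#'   carried through when present
#' @param model fitted `sustain_model`
#' @param prob_threshold poor-fit exclusion threshold
#' @param ids optional data frame with `subject_id` and `visit_index`
#'   (one row per scan)
#' @return data frame of class `assignment_table`: one row per scan with
#'   subtype posteriors (`p_subtype1..C`), `subtype`, `stage`,
#'   `max_posterior`, `excluded`, `stage_zero`
#' @export
assign_cohort <- function(Z, model, prob_threshold = 0.5, ids = NULL) {
  C <- length(model$sequences)
  recs <- lapply(seq_len(nrow(Z)), function(j)
    assign_scan(Z[j, ], model, prob_threshold))
  post <- t(vapply(recs, `[[`, numeric(C), "subtype_posterior"))
  colnames(post) <- paste0("p_subtype", seq_len(C))
  out <- data.frame(
    subject_id = if (!is.null(ids)) ids$subject_id else
      sub("\\|.*$", "", rownames(Z) %||% as.character(seq_len(nrow(Z)))),
    visit_index = if (!is.null(ids)) as.integer(ids$visit_index) else
      as.integer(sub("^.*\\|", "", rownames(Z) %||% "0")),
    post,
    subtype = vapply(recs, `[[`, integer(1), "subtype"),
    stage = vapply(recs, `[[`, integer(1), "stage"),
    max_posterior = apply(post, 1, max),
    excluded = vapply(recs, `[[`, logical(1), "excluded"),
    stage_zero = vapply(recs, `[[`, logical(1), "stage_zero"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("assignment_table", "data.frame")
  out
}

#' Deviation of a scan from its assigned sequence prefix
#'
#' Each event `(i, r)` is binarized as achieved iff `x_i >= z_ir`. A
#' scan assigned to stage `k` of sequence `S` is expected to have
#' achieved exactly the events at positions `<= k`. The deviation is the
#' Hamming distance between the observed and expected achievement
#' vectors ("event imperfections").
#'
#' @param x z-score vector for the scan
#' @param model fitted `sustain_model`
#' @param subtype,stage the scan's assignment
#' @return list: `deviation` (0..N), `mismatch` (per-event logical,
#'   canonical event order), `per_region` (named mismatch counts)
#' @export
sequence_deviation <- function(x, model, subtype, stage) {
  es <- model$event_set
  ev <- es$events
  achieved <- x[ev$region_index] >= ev$z
  pos <- sequence_positions(model$sequences[[subtype]])
  expected <- pos <= stage
  mismatch <- achieved != expected
  pr <- tapply(mismatch, ev$region, sum)
  list(deviation = sum(mismatch), mismatch = unname(mismatch),
       per_region = stats::setNames(as.integer(pr), names(pr))[es$regions])
}

#' Add deviation counts to an assignment table
#'
#' @param Z the z-matrix used for [assign_cohort()]
#' @param model fitted `sustain_model`
#' @param assignments the `assignment_table`
#' @return the table with a `deviation` column appended
#' @export
add_deviations <- function(Z, model, assignments) {
  assignments$deviation <- vapply(seq_len(nrow(Z)), function(j)
    sequence_deviation(Z[j, ], model, assignments$subtype[j],
                       assignments$stage[j])$deviation,
    numeric(1))
  assignments
}
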