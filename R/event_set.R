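#' Define an event set from per-region severity thresholds
#'
#' An event set fixes the model's discrete events: each event is a region
#' crossing one of its z-score severity thresholds. With `B` regions and
#' `R_i` thresholds in region `i` the model has `N = sum(R_i)` events.
#' Events are enumerated canonically: regions in the supplied order, and
#' within a region ascending thresholds.
#'
#' @param regions character vector of region names (unique, non-empty).
#' @param thresholds list (one numeric vector per region, strictly
#'   ascending, all > 0) or a single numeric vector recycled to every
#'   region.
#' @param z_max numeric vector (or scalar, recycled) of per-region
#'   trajectory ceilings; each must exceed the region's top threshold.
#' @return An object of class `event_set` with elements `regions`,
#'   `thresholds`, `z_max` and an `events` data frame (canonical
#'   enumeration: `event`, `region`, `region_index`, `threshold_index`,
#'   `z`).
#' @examples
#' es <- event_set(c("A", "B"), c(2, 5), z_max = 10)
#' n_events(es) # 4
#' @export
event_set <- function(regions, thresholds, z_max) {
  regions <- as.character(regions)
  if (length(regions) < 1L || anyDuplicated(regions) || any(!nzchar(regions)))
    stopf("regions must be a non-empty vector of unique, non-empty names")
  B <- length(regions)
  if (!is.list(thresholds)) thresholds <- rep(list(as.numeric(thresholds)), B)
  if (length(thresholds) != B)
    stopf("need one threshold vector per region (got %d for %d regions)",
          length(thresholds), B)
  z_max <- rep_len(as.numeric(z_max), B)
  for (i in seq_len(B)) {
    th <- as.numeric(thresholds[[i]])
    if (length(th) < 1L || any(!is.finite(th)))
      stopf("region '%s': thresholds must be finite and non-empty", regions[i])
    if (any(diff(th) <= 0) && length(th) > 1L || is.unsorted(th, strictly = TRUE))
      stopf("region '%s': thresholds must be strictly ascending", regions[i])
    if (z_max[i] <= th[length(th)])
      stopf("region '%s': z_max (%g) must exceed top threshold (%g)",
            regions[i], z_max[i], th[length(th)])
    thresholds[[i]] <- th
  }
  names(thresholds) <- regions
  names(z_max) <- regions
  R_i <- lengths(thresholds)
  events <- data.frame(
    event = seq_len(sum(R_i)),
    region = rep(regions, R_i),
    region_index = rep(seq_len(B), R_i),
    threshold_index = unlist(lapply(R_i, seq_len), use.names = FALSE),
    z = unlist(thresholds, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  structure(list(regions = regions, thresholds = thresholds, z_max = z_max,
                 events = events,
                 # fast lookups for the optimizer and samplers
                 region_events = split(events$event, events$region_index),
                 event_region = events$region_index,
                 event_thr = events$threshold_index),
            class = "event_set")
}

#' Number of events in an event set
#' @param es an `event_set`
#' @return integer event count `N`
#' @export
n_events <- function(es) nrow(es$events)

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("Event set: %d regions, %d events\n",
              length(x$regions), n_events(x)))
  for (i in seq_along(x$regions))
    cat(sprintf("  %-18s z = {%s}, z_max = %g\n", x$regions[i],
                paste(x$thresholds[[i]], collapse = ", "), x$z_max[i]))
  invisible(x)
}

#' Build an event set from a per-region threshold table
#'
#' Thin wrapper matching the preparation step: takes the output of
#' [derive_thresholds()] applied region-wise and assembles the event set.
#'
#' @param threshold_table data frame with columns `region`, one column per
#'   ascending threshold (`z1`, `z2`, ...) and `z_max`.
#' @return an [event_set()]
#' @export
build_event_set <- function(threshold_table) {
  zcols <- grep("^z[0-9]+$", names(threshold_table), value = TRUE)
  zcols <- zcols[order(as.integer(sub("^z", "", zcols)))]
  if (length(zcols) < 1L || !"z_max" %in% names(threshold_table))
    stopf("threshold table needs z1..zR and z_max columns")
  th <- lapply(seq_len(nrow(threshold_table)), function(i)
    as.numeric(threshold_table[i, zcols]))
  event_set(threshold_table$region, th, threshold_table$z_max)
}

#' Canonical 10-region unilateral lobar preset
#'
#' The left/right frontal, parietal, lateral temporal, occipital and
#' medial temporal composite regions commonly used for lobar tau-PET
#' quantification.
#' @return character vector of 10 region names
#' @export
lobar_regions <- function() {
  lobes <- c("frontal", "parietal", "lateral_temporal", "occipital",
             "medial_temporal")
  as.vector(t(outer(c("left", "right"), lobes, paste, sep = "_")))
}

## ---- event sequences -------------------------------------------------

# Position map: pos[e] = 1-based position of event e in sequence S
# (S[pos] = event id).
sequence_positions <- function(S) {
  pos <- integer(length(S))
  pos[S] <- seq_along(S)
  pos
}

#' Check within-region threshold ordering of an event sequence
#'
#' A sequence is valid iff, for every region, its lower threshold events
#' occur before its higher ones (required for monotone trajectories).
#'
#' @param S integer permutation of event ids (position 1..N)
#' @param es the `event_set`
#' @return logical scalar
#' @export
is_valid_sequence <- function(S, es) {
  N <- n_events(es)
  if (length(S) != N || anyDuplicated(S) || any(S < 1L | S > N)) return(FALSE)
  pos <- sequence_positions(S)
  ev <- es$events
  for (i in seq_along(es$regions)) {
    p <- pos[ev$event[ev$region_index == i]] # ascending threshold order
    if (is.unsorted(p, strictly = TRUE)) return(FALSE)
  }
  TRUE
}

# Uniform draw over valid sequences: random permutation, then within each
# region sort that region's occupied positions by ascending threshold.
random_valid_sequence <- function(es) {
  ev <- es$events
  N <- nrow(ev)
  S <- sample.int(N)
  pos <- sequence_positions(S)
  for (i in seq_along(es$regions)) {
    ids <- ev$event[ev$region_index == i]
    pos[ids] <- sort(pos[ids])
  }
  S <- integer(N)
  S[pos] <- seq_len(N) # invert event -> position map
  S
}

# All valid sequences (exhaustive; small N only) as a list of integer
# vectors, in lexicographic order of the position-assignment.
enumerate_valid_sequences <- function(es, max_n = 5040L) {
  N <- n_events(es)
  perms <- all_permutations(N)
  keep <- vapply(perms, is_valid_sequence, logical(1), es = es)
  out <- perms[keep]
  if (length(out) > max_n) stopf("too many valid sequences to enumerate")
  out
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(first, rest[p])
    }
  }
  out
}
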