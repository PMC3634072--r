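## Contaminant filters: tandem-repeat detection by period scanning and
## removal of candidates matching a non-coding RNA blacklist.

#' Detect a tandem repeat in a sequence
#'
#' Scans periods 1..`max_period` at every phase for the longest run of
#' consecutive copies of a unit, allowing up to `max_mm_per_copy`
#' mismatches per copy against the first unit (units shorter than 3 nt
#' must match exactly). The best array is the
#' one covering the largest fraction of the sequence; `is_tandem` is
#' true when period <= `max_period`, copies >= `min_copies` and covered
#' fraction >= `min_cov` (defaults 10, 3, 0.6).
#'
#' @param seq RNA sequence.
#' @param max_period,min_copies,min_cov,max_mm_per_copy tuning knobs.
#' @return a `repeat_report`: `period`, `copies`, `start` (0-based),
#'   `covered_fraction`, `is_tandem`.
#' @export
detect_tandem_repeat <- function(seq, max_period = 10, min_copies = 3,
                                 min_cov = 0.6, max_mm_per_copy = 1) {
  n <- nchar(seq)
  stopifnot(n >= 2)
  bs <- strsplit(seq, "")[[1]]
  best <- list(period = NA_integer_, copies = 0L, start = NA_integer_,
               covered_fraction = 0)
  for (p in seq_len(max_period)) {
    mm_allowed <- if (p >= 3) max_mm_per_copy else 0  # short units: exact
    s <- 1
    while (s + 2 * p - 1 <= n) {
      unit <- bs[s:(s + p - 1)]
      copies <- 1L
      pos <- s + p
      while (pos + p - 1 <= n) {
        mm <- sum(bs[pos:(pos + p - 1)] != unit)
        if (mm > mm_allowed) break
        copies <- copies + 1L
        pos <- pos + p
      }
      cov <- copies * p / n
      if (copies >= 2 && (cov > best$covered_fraction ||
                          (cov == best$covered_fraction && !is.na(best$period) &&
                           p < best$period))) {
        best <- list(period = p, copies = copies, start = s - 1L,
                     covered_fraction = cov)
      }
      # skip past this array: restarting inside it cannot do better
      s <- if (copies >= 2) s + p else s + 1
    }
  }
  best$is_tandem <- !is.na(best$period) && best$period <= max_period &&
    best$copies >= min_copies && best$covered_fraction >= min_cov
  class(best) <- "repeat_report"
  best
}

#' @export
print.repeat_report <- function(x, ...) {
  if (is.na(x$period)) cat("no repeat array found\n")
  else cat(sprintf("period %d x %d copies from %d, covering %.2f -> %s\n",
                   x$period, x$copies, x$start, x$covered_fraction,
                   if (x$is_tandem) "tandem repeat" else "not tandem"))
  invisible(x)
}

#' Remove tandem-repeat candidates
#'
#' @param candidates list of `hairpin_candidate` objects.
#' @param ... passed to [detect_tandem_repeat()].
#' @return the retained candidates, with a `removed` attribute logging
#'   id and reason for each removal.
#' @export
repeat_filter <- function(candidates, ...) {
  if (length(candidates) == 0) return(candidates)
  reports <- lapply(candidates, function(cd) detect_tandem_repeat(cd$seq, ...))
  drop <- vapply(reports, function(r) r$is_tandem, logical(1))
  removed <- data.frame(
    id = vapply(candidates[drop], function(cd) cd$id, character(1)),
    reason = rep("tandem_repeat", sum(drop)),
    detail = vapply(reports[drop], function(r)
      sprintf("period=%d,copies=%d,cov=%.2f", r$period, r$copies,
              r$covered_fraction), character(1)),
    stringsAsFactors = FALSE)
  structure(candidates[!drop], removed = removed)
}

#' Remove candidates matching a non-coding RNA blacklist
#'
#' A candidate is removed when it locally aligns to any blacklist entry
#' (rRNA, tRNA, snoRNA, snRNA, ...) under the same acceptance rule as
#' the homology mapper: identity >= 0.80 over at least half the
#' candidate length.
#'
#' @param candidates list of `hairpin_candidate` objects.
#' @param blacklist sequence table of ncRNAs; an empty table passes all
#'   candidates through with a warning.
#' @param min_identity,min_coverage acceptance thresholds.
#' @return retained candidates, with a `removed` attribute (id, reason,
#'   matched entry, identity).
#' @export
ncrna_filter <- function(candidates, blacklist, min_identity = 0.8,
                         min_coverage = 0.5) {
  if (length(candidates) == 0) return(candidates)
  if (is.null(blacklist) || nrow(blacklist) == 0) {
    warning("empty ncRNA blacklist: no filtering applied")
    return(structure(candidates,
                     removed = data.frame(id = character(), reason = character(),
                                          detail = character())))
  }
  drop <- logical(length(candidates))
  detail <- character(length(candidates))
  for (k in seq_along(candidates)) {
    for (b in seq_len(nrow(blacklist))) {
      hit <- local_align(candidates[[k]]$seq, blacklist$seq[b],
                         query_id = candidates[[k]]$id,
                         subject_id = blacklist$id[b],
                         min_identity = min_identity,
                         min_coverage = min_coverage)
      if (!hit$accepted) {  # also try the opposite orientation
        hit <- local_align(candidates[[k]]$seq, rev_comp(blacklist$seq[b]),
                           query_id = candidates[[k]]$id,
                           subject_id = blacklist$id[b],
                           min_identity = min_identity,
                           min_coverage = min_coverage)
      }
      if (hit$accepted) {
        drop[k] <- TRUE
        detail[k] <- sprintf("%s,identity=%.3f", blacklist$id[b], hit$identity)
        break
      }
    }
  }
  removed <- data.frame(
    id = vapply(candidates[drop], function(cd) cd$id, character(1)),
    reason = rep("ncrna_match", sum(drop)), detail = detail[drop],
    stringsAsFactors = FALSE)
  structure(candidates[!drop], removed = removed)
}
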