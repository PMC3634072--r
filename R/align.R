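## Local alignment with the homology acceptance rule used throughout
## the pipeline: identity >= 0.80 over aligned columns AND aligned query
## span >= 50% of the query length ("80% similarity in half of the
## length"), under match +1, mismatch -2, linear gap -3.

#' Optimal local alignment with the homology acceptance criterion
#'
#' Smith-Waterman local alignment (via `Biostrings::pairwiseAlignment`)
#' under match +1, mismatch -2, linear gap -3. Identity is computed
#' over aligned columns (gap columns count against identity); coverage
#' is the aligned query span divided by the query length. A hit is
#' accepted when identity >= `min_identity` and coverage >=
#' `min_coverage`.
#'
#' @param query,subject RNA sequences (character scalars).
#' @param query_id,subject_id optional labels carried into the hit.
#' @param match,mismatch,gap scoring parameters.
#' @param min_identity,min_coverage acceptance thresholds (defaults 0.80
#'   and 0.50).
#' @return a `homology_hit`: `score`, `identity`, `coverage`, `q_span`
#'   and `s_span` (0-based half-open), aligned strings, `accepted`.
#' @export
local_align <- function(query, subject, query_id = "query",
                        subject_id = "subject", match = 1, mismatch = -2,
                        gap = -3, min_identity = 0.8, min_coverage = 0.5) {
  stopifnot(nchar(query) > 0, nchar(subject) > 0)
  mat <- align_submat(match, mismatch)
  al <- Biostrings::pairwiseAlignment(query, subject, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = -gap)
  sc <- Biostrings::score(al)
  if (sc <= 0) {
    return(structure(list(query_id = query_id, subject_id = subject_id,
                          score = 0, identity = 0, coverage = 0,
                          q_span = c(0L, 0L), s_span = c(0L, 0L),
                          aligned_query = "", aligned_subject = "",
                          accepted = FALSE), class = "homology_hit"))
  }
  aq <- as.character(Biostrings::alignedPattern(al))
  as_ <- as.character(Biostrings::alignedSubject(al))
  qc <- strsplit(aq, "")[[1]]
  sc2 <- strsplit(as_, "")[[1]]
  ncol_aln <- length(qc)
  nmatch <- sum(qc == sc2 & qc != "-")
  identity <- nmatch / ncol_aln
  qs <- Biostrings::start(Biostrings::pattern(al)) - 1L
  qe <- Biostrings::end(Biostrings::pattern(al))
  ss <- Biostrings::start(Biostrings::subject(al)) - 1L
  se <- Biostrings::end(Biostrings::subject(al))
  coverage <- (qe - qs) / nchar(query)
  structure(list(query_id = query_id, subject_id = subject_id,
                 score = sc, identity = identity, coverage = coverage,
                 q_span = c(qs, qe), s_span = c(ss, se),
                 aligned_query = aq, aligned_subject = as_,
                 accepted = identity >= min_identity && coverage >= min_coverage),
            class = "homology_hit")
}

align_submat <- function(match, mismatch) {
  letters <- c("A", "C", "G", "U", "N")
  mat <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- match
  mat["N", ] <- mismatch  # N never matches, not even itself
  mat[, "N"] <- mismatch
  mat
}

#' @export
print.homology_hit <- function(x, ...) {
  cat(sprintf("%s vs %s: score %g, identity %.3f, coverage %.3f -> %s\n",
              x$query_id, x$subject_id, x$score, x$identity, x$coverage,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}
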