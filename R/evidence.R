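## Read-stack evidence: mapping small-RNA reads back onto candidate
## precursors, the "block-like alignment outside the loop" criterion,
## precursor classification, and expression summaries.

#' Map small-RNA reads onto one precursor
#'
#' Each read is placed end-to-end (no indels) at its best sense-strand
#' position with at most `max_mm` mismatches; ties resolve to the
#' fewest-mismatch, then leftmost, site. Antisense placements are
#' ignored (miRNA maturation is strand-specific).
#'
#' @param reads collapsed reads (`seq`, `count`).
#' @param precursor a `hairpin_candidate`, or a character sequence.
#' @param max_mm maximum mismatches (default 1).
#' @return a `read_stack`: per-position `coverage`, `start5` counts,
#'   mean read length per start (`len_by_start`), `mapped_total`.
#' @export
map_reads_to_precursor <- function(reads, precursor, max_mm = 1) {
  pseq <- if (inherits(precursor, "hairpin_candidate")) precursor$seq
          else precursor
  pid <- if (inherits(precursor, "hairpin_candidate")) precursor$id else "precursor"
  n <- nchar(pseq)
  coverage <- numeric(n)
  start5 <- numeric(n)
  len_sum <- numeric(n)
  mapped <- 0
  subj <- Biostrings::RNAString(pseq)
  for (k in seq_len(nrow(reads))) {
    rl <- nchar(reads$seq[k])
    if (rl > n) next
    mt <- Biostrings::matchPattern(Biostrings::RNAString(reads$seq[k]), subj,
                                   max.mismatch = max_mm, with.indels = FALSE)
    if (length(mt) == 0) next
    if (length(mt) > 1 && max_mm > 0) {
      mm <- Biostrings::neditStartingAt(Biostrings::RNAString(reads$seq[k]),
                                        subj, starting.at = Biostrings::start(mt))
      best <- which(mm == min(mm))[1]
    } else best <- 1L
    s0 <- Biostrings::start(mt)[best] - 1L
    cnt <- reads$count[k]
    coverage[(s0 + 1):(s0 + rl)] <- coverage[(s0 + 1):(s0 + rl)] + cnt
    start5[s0 + 1] <- start5[s0 + 1] + cnt
    len_sum[s0 + 1] <- len_sum[s0 + 1] + cnt * rl
    mapped <- mapped + cnt
  }
  structure(list(precursor_id = pid, coverage = coverage, start5 = start5,
                 len_by_start = ifelse(start5 > 0, len_sum / pmax(start5, 1), NA),
                 mapped_total = mapped), class = "read_stack")
}

#' @export
print.read_stack <- function(x, ...) {
  cat(sprintf("read_stack on %s: %d reads mapped, %d distinct 5' starts\n",
              x$precursor_id, x$mapped_total, sum(x$start5 > 0)))
  invisible(x)
}

#' Score the block-like alignment criterion on one arm
#'
#' A precursor passes when its mapped reads pile up at essentially one
#' 5' start (the Drosha/Dicer processing signature) on an arm, outside
#' the terminal loop. The modal 5' start is found among reads starting
#' within the chosen arm; `block_fraction` is the fraction of that
#' arm's reads starting within `window` nt of the mode.
#'
#' @param stack a `read_stack`.
#' @param fold the precursor's `hairpin_fold`.
#' @param arm `"auto"` (arm holding most reads), `"5p"` or `"3p"`.
#' @param window modal-start tolerance in nt (default 2).
#' @param min_frac minimum block fraction (default 0.5).
#' @param min_reads minimum reads in the block (default 10).
#' @return a `block_report`: `arm`, `block_interval` (0-based
#'   half-open), `block_fraction`, `block_reads`, `in_loop`, `passes`.
#' @export
block_score <- function(stack, fold, arm = c("auto", "5p", "3p"),
                        window = 2, min_frac = 0.5, min_reads = 10) {
  arm <- match.arg(arm)
  fail <- structure(list(arm = "none", block_interval = c(0L, 0L),
                         block_fraction = 0, block_reads = 0,
                         in_loop = FALSE, passes = FALSE),
                    class = "block_report")
  if (stack$mapped_total == 0) return(fail)
  n <- length(stack$start5)
  pos0 <- seq_len(n) - 1L
  arm_of <- function(p) {
    ifelse(p >= fold$arm5[1] & p < fold$arm5[2], "5p",
           ifelse(p >= fold$arm3[1] & p < fold$arm3[2], "3p", "none"))
  }
  armvec <- arm_of(pos0)
  if (arm == "auto") {
    r5 <- sum(stack$start5[armvec == "5p"])
    r3 <- sum(stack$start5[armvec == "3p"])
    if (r5 == 0 && r3 == 0) return(fail)
    arm <- if (r5 >= r3) "5p" else "3p"
  }
  in_arm <- armvec == arm & stack$start5 > 0
  if (!any(in_arm)) return(fail)
  arm_reads <- sum(stack$start5[in_arm])
  counts <- ifelse(in_arm, stack$start5, 0)
  mode_pos <- pos0[which.max(counts)]  # leftmost on ties
  win <- in_arm & abs(pos0 - mode_pos) <= window
  block_reads <- sum(stack$start5[win])
  block_fraction <- block_reads / arm_reads
  mean_len <- sum(stack$start5[win] * stack$len_by_start[win]) / block_reads
  block_interval <- c(mode_pos, mode_pos + as.integer(round(mean_len)))
  in_loop <- block_interval[1] < fold$loop[2] && fold$loop[1] < block_interval[2]
  passes <- block_fraction >= min_frac && !in_loop && block_reads >= min_reads
  structure(list(arm = arm, block_interval = block_interval,
                 block_fraction = block_fraction, block_reads = block_reads,
                 in_loop = in_loop, passes = passes), class = "block_report")
}

#' @export
print.block_report <- function(x, ...) {
  cat(sprintf("block on %s arm: [%d, %d), fraction %.2f (%d reads), %s%s\n",
              x$arm, x$block_interval[1], x$block_interval[2],
              x$block_fraction, x$block_reads,
              if (x$passes) "PASS" else "fail",
              if (x$in_loop) " (in loop)" else ""))
  invisible(x)
}

#' Classify a precursor candidate
#'
#' Annotation-guideline style rules: `known` requires an accepted
#' catalogue homology hit and a passing block on at least one arm;
#' `novel` requires a passing block and no catalogue hit; everything
#' else is `rejected`. Mature intervals are the block intervals. When
#' both arms carry passing blocks, `star_overhang_ok` records whether
#' the two blocks form a duplex with ~2-nt 3' overhangs (tolerance
#' 2 +/- 1 nt, accommodating imprecise Drosha cleavage).
#'
#' @param candidate a `hairpin_candidate`.
#' @param stack the candidate's `read_stack`.
#' @param blocks list of `block_report`s (one per arm, e.g. from
#'   [block_score()] with `arm = "5p"` and `"3p"`); a single report is
#'   accepted too.
#' @param catalog_hit an accepted `homology_hit` against the hairpin
#'   catalogue, or `NULL`.
#' @return a `precursor_call`: `status`, `mature_5p`, `mature_3p`,
#'   `star_overhang_ok`.
#' @export
classify_precursor <- function(candidate, stack, blocks, catalog_hit = NULL) {
  if (inherits(blocks, "block_report")) blocks <- list(blocks)
  passing <- Filter(function(b) isTRUE(b$passes), blocks)
  arms <- vapply(passing, function(b) b$arm, character(1))
  mature_5p <- if ("5p" %in% arms)
    passing[[which(arms == "5p")[1]]]$block_interval else NULL
  mature_3p <- if ("3p" %in% arms)
    passing[[which(arms == "3p")[1]]]$block_interval else NULL
  has_hit <- !is.null(catalog_hit) && isTRUE(catalog_hit$accepted)
  has_block <- length(passing) > 0
  status <- if (has_block && has_hit) "known"
            else if (has_block) "novel"
            else "rejected"
  star_ok <- NA
  if (!is.null(mature_5p) && !is.null(mature_3p)) {
    star_ok <- star_overhang_ok(candidate$fold, mature_5p, mature_3p)
  }
  structure(list(id = candidate$id, candidate = candidate, status = status,
                 mature_5p = mature_5p, mature_3p = mature_3p,
                 star_overhang_ok = star_ok), class = "precursor_call")
}

## 3' overhang of each strand of the mature:star duplex, via the fold's
## pair map; TRUE when both overhangs are within 2 +/- 1 nt.
star_overhang_ok <- function(fold, mature_5p, mature_3p, tol = 1) {
  p <- fold_partner(fold)
  nearest_paired <- function(pos, dir) {
    for (d in 0:3) {
      q <- pos + dir * d
      if (q >= 0 && q < length(p) && !is.na(p[q + 1])) return(q)
    }
    NA_integer_
  }
  s5 <- nearest_paired(mature_5p[1], +1)
  s3 <- nearest_paired(mature_3p[1], +1)
  if (is.na(s5) || is.na(s3)) return(FALSE)
  ov3 <- (mature_3p[2] - 1) - p[s5 + 1]  # 3' overhang of the 3p strand
  ov5 <- (mature_5p[2] - 1) - p[s3 + 1]  # 3' overhang of the 5p strand
  abs(ov3 - 2) <= tol && abs(ov5 - 2) <= tol
}

#' @export
print.precursor_call <- function(x, ...) {
  cat(sprintf("%s: %s", x$id, x$status))
  if (!is.null(x$mature_5p))
    cat(sprintf("  mature-5p [%d, %d)", x$mature_5p[1], x$mature_5p[2]))
  if (!is.null(x$mature_3p))
    cat(sprintf("  mature-3p [%d, %d)", x$mature_3p[1], x$mature_3p[2]))
  if (!is.na(x$star_overhang_ok))
    cat("  star-overhang:", if (x$star_overhang_ok) "ok" else "off")
  cat("\n")
  invisible(x)
}

#' Relative miRNA frequency within a sample
#'
#' Each miRNA's read count divided by the sample's total miRNA reads;
#' the returned fractions sum to one.
#'
#' @param counts named numeric vector of per-miRNA read counts.
#' @return named vector of fractions.
#' @export
relative_frequency <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("total miRNA count is zero")
  counts / total
}
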