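# Shared fixtures: one model instance and constructors for planted
# hairpins used across the suite.

MODEL <- default_energy_model()

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# perfect stem-loop, optionally flanked so that a 2-nt 3' overhang star
# fits on the precursor
make_hairpin <- function(stem = 30, loop = 8, flank = 0) {
  arm <- rand_rna(stem)
  paste0(if (flank > 0) rand_rna(flank) else "",
         arm, rand_rna(loop), rev_comp(arm),
         if (flank > 0) rand_rna(flank) else "")
}

# Subject containing an exact-identity copy of query positions
# (q_from..q_from+span-1], with n_mm evenly spaced internal mismatches.
# Six forced mismatches flank the segment so the local alignment cannot
# extend beyond it, and runs of >= 3 matches separate mismatches so the
# optimal local alignment is exactly the intended block.
make_boundary_pair <- function(query, q_from, span, n_mm) {
  qa <- strsplit(query, "")[[1]]
  seg <- qa[q_from:(q_from + span - 1)]
  if (n_mm > 0) {
    pos <- round(seq(4, span - 3, length.out = n_mm))
    stopifnot(all(diff(pos) >= 4))
    seg[pos] <- vapply(seg[pos], function(b)
      sample(setdiff(c("A", "C", "G", "U"), b), 1), character(1))
  }
  force_mm <- function(b) sample(setdiff(c("A", "C", "G", "U"), b), 1)
  left <- c(vapply(1:30, function(i) sample(c("A", "C", "G", "U"), 1),
                   character(1)),
            vapply(qa[(q_from - 6):(q_from - 1)], force_mm, character(1)))
  right <- c(vapply(qa[(q_from + span):(q_from + span + 5)], force_mm,
                    character(1)),
             vapply(1:30, function(i) sample(c("A", "C", "G", "U"), 1),
                    character(1)))
  paste(c(left, seg, right), collapse = "")
}

# reads piled at an arbitrary 5' position of a precursor (block_score
# input for loop-centred and custom stacks)
stack_at <- function(precursor_seq, start0, n_reads, jitter_sd = 0,
                     read_len = 22) {
  starts <- round(rnorm(n_reads, start0, jitter_sd))
  starts <- pmax(0, pmin(starts, nchar(precursor_seq) - read_len))
  collapse_reads(data.frame(
    seq = substring(precursor_seq, starts + 1, starts + read_len),
    count = 1L, stringsAsFactors = FALSE))
}
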