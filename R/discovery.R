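## Pre-miRNA candidate generation: de-novo thermodynamic scan of
## contigs, homology mapping of a hairpin catalogue, read-guided
## extraction from a reference, and non-redundant merging.

new_candidate <- function(id, contig, start, end, strand, seq, fold,
                          source, partial = FALSE) {
  structure(list(id = id,
                 locus = if (is.null(contig)) NULL else
                   list(contig = contig, start = start, end = end,
                        strand = strand),
                 seq = seq, fold = fold, dG = fold$dG,
                 source = source, partial = partial),
            class = "hairpin_candidate")
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  loc <- if (is.null(x$locus)) "unplaced" else
    sprintf("%s:%d-%d(%s)", x$locus$contig, x$locus$start, x$locus$end,
            x$locus$strand)
  cat(sprintf("%s  %s  dG=%.1f  source=%s%s\n", x$id, loc, x$dG,
              paste(x$source, collapse = "+"),
              if (x$partial) "  [partial]" else ""))
  invisible(x)
}

#' Convert a candidate list to a data.frame
#'
#' @param x list of `hairpin_candidate` objects.
#' @param ... unused.
#' @return one row per candidate: id, locus, strand, dG, stem pairs,
#'   source, partial flag, sequence.
#' @export
candidates_to_df <- function(x, ...) {
  if (length(x) == 0)
    return(data.frame(id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), dG = numeric(),
                      npairs = integer(), source = character(),
                      partial = logical(), seq = character()))
  do.call(rbind, lapply(x, function(cd) {
    data.frame(id = cd$id,
               contig = if (is.null(cd$locus)) NA_character_ else cd$locus$contig,
               start = if (is.null(cd$locus)) NA_integer_ else cd$locus$start,
               end = if (is.null(cd$locus)) NA_integer_ else cd$locus$end,
               strand = if (is.null(cd$locus)) NA_character_ else cd$locus$strand,
               dG = cd$dG, npairs = cd$fold$npairs,
               source = paste(sort(cd$source), collapse = "+"),
               partial = cd$partial, seq = cd$seq,
               stringsAsFactors = FALSE)
  }))
}

#' Default de-novo scan thresholds
#'
#' Explicit, configurable stand-ins for a hairpin-extraction tool's
#' settings: candidate span 60-120 nt, stem of at least 18 base pairs,
#' dG at most -15 kcal/mol under the shipped model, terminal loop at
#' most 20 nt.
#'
#' @return a named list of thresholds.
#' @export
scan_params <- function() {
  list(min_len = 60L, max_len = 120L, min_pairs = 18L,
       max_loop = 20L, dg_max = -15)
}

#' De-novo hairpin scan of a genomic contig
#'
#' Scores every candidate stem-loop with span within the configured
#' length bounds on both strands of the contig (banded dynamic
#' program), keeps those passing the thermodynamic and structural
#' thresholds, and collapses overlapping survivors on the same strand
#' to the lowest-dG one.
#'
#' @param contig single-row sequence table (or character scalar with a
#'   `contig_id`).
#' @param model an `energy_model`.
#' @param params thresholds from [scan_params()].
#' @param contig_id contig name used in loci when `contig` is a bare string.
#' @return list of `hairpin_candidate` objects (source `"scan"`).
#' @export
scan_hairpins <- function(contig, model = default_energy_model(),
                          params = scan_params(), contig_id = "contig") {
  if (is.data.frame(contig)) {
    stopifnot(nrow(contig) == 1)
    contig_id <- contig$id
    contig <- contig$seq
  }
  n <- nchar(contig)
  if (n < params$min_len) return(list())
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else rev_comp(contig)
    df <- .stem_scan_cpp(seq_to_int(s), model_params(model),
                         params$min_len, params$max_len, params$min_pairs,
                         params$max_loop, params$dg_max)
    if (nrow(df) == 0) next
    if (strand == "-") {
      tmp <- n - df$end
      df$end <- n - df$start
      df$start <- tmp
    }
    df$strand <- strand
    hits[[strand]] <- df
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0) return(list())
  hits <- collapse_overlapping(hits)
  hits <- drop_mirror_hits(hits)

  out <- vector("list", nrow(hits))
  for (k in seq_len(nrow(hits))) {
    seqk <- substr(contig, hits$start[k] + 1, hits$end[k])
    if (hits$strand[k] == "-") seqk <- rev_comp(seqk)
    fold <- fold_hairpin(seqk, model, min_len = params$min_len,
                         max_len = params$max_len)
    id <- sprintf("scan_%s_%d_%s", contig_id, hits$start[k], hits$strand[k])
    out[[k]] <- new_candidate(id, contig_id, hits$start[k], hits$end[k],
                              hits$strand[k], seqk, fold, "scan")
  }
  out
}

## Greedy collapse: sort by dG ascending; keep a hit unless it overlaps
## an already-kept hit on the same strand.
collapse_overlapping <- function(df) {
  df <- df[order(df$dG, df$start, df$strand), , drop = FALSE]
  kept <- list("+" = list(s = integer(), e = integer()),
               "-" = list(s = integer(), e = integer()))
  keep <- logical(nrow(df))
  for (k in seq_len(nrow(df))) {
    kk <- kept[[df$strand[k]]]
    if (!any(kk$s < df$end[k] & df$start[k] < kk$e)) {
      keep[k] <- TRUE
      kept[[df$strand[k]]]$s <- c(kk$s, df$start[k])
      kept[[df$strand[k]]]$e <- c(kk$e, df$end[k])
    }
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start, df$strand), , drop = FALSE]
}

## A G:U-free stem-loop is its own reverse complement, so the same
## physical hairpin scores identically on both strands. Such exact
## mirrors (equal dG, near-identical locus) are reported once, on the
## plus strand; the true strand is decided later by read evidence.
drop_mirror_hits <- function(hits) {
  if (nrow(hits) < 2) return(hits)
  drop <- logical(nrow(hits))
  minus <- which(hits$strand == "-")
  plus <- which(hits$strand == "+")
  for (k in minus) {
    ov <- pmin(hits$end[plus], hits$end[k]) - pmax(hits$start[plus], hits$start[k])
    len_k <- hits$end[k] - hits$start[k]
    len_p <- hits$end[plus] - hits$start[plus]
    mirror <- ov / pmax(len_k, len_p) >= 0.8 &
      abs(hits$dG[plus] - hits$dG[k]) < 1e-9
    if (any(mirror)) drop[k] <- TRUE
  }
  hits[!drop, , drop = FALSE]
}

#' Map a hairpin catalogue onto contigs by homology
#'
#' Each catalogue hairpin is locally aligned against both strands of
#' each contig; accepted hits (identity >= 0.80 over at least half the
#' hairpin length) are extended on the contig to the full catalogue
#' hairpin length where the contig allows, marked `partial` when
#' truncated by a contig edge, and must still fold into a hairpin with
#' dG < 0 to be emitted.
#'
#' @param catalog sequence table (e.g. from [read_mirbase_hairpins()]).
#' @param contigs sequence table of genomic contigs.
#' @param model an `energy_model`.
#' @param min_identity,min_coverage homology acceptance thresholds.
#' @return list of `hairpin_candidate` objects (source `"homology"`).
#' @export
map_known_hairpins <- function(catalog, contigs,
                               model = default_energy_model(),
                               min_identity = 0.8, min_coverage = 0.5) {
  stopifnot(nrow(catalog) > 0)
  out <- list()
  for (ci in seq_len(nrow(contigs))) {
    ctg <- contigs$seq[ci]
    n <- nchar(ctg)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") ctg else rev_comp(ctg)
      for (hi in seq_len(nrow(catalog))) {
        hp <- catalog$seq[hi]
        hit <- local_align(hp, subj, query_id = catalog$id[hi],
                           subject_id = contigs$id[ci],
                           min_identity = min_identity,
                           min_coverage = min_coverage)
        if (!hit$accepted) next
        # extend hit locus to the catalogue hairpin's full extent
        want_s <- hit$s_span[1] - hit$q_span[1]
        want_e <- hit$s_span[2] + (nchar(hp) - hit$q_span[2])
        s0 <- max(0L, want_s)
        e0 <- min(n, want_e)
        partial <- (s0 > want_s) || (e0 < want_e)
        seqk <- substr(subj, s0 + 1, e0)
        fold <- tryCatch(fold_hairpin(seqk, model, min_len = 40,
                                      max_len = 250), error = function(e) NULL)
        if (is.null(fold)) next
        # map back to + strand coordinates
        if (strand == "+") { gs <- s0; ge <- e0 } else { gs <- n - e0; ge <- n - s0 }
        id <- sprintf("hom_%s_%s_%d_%s", catalog$id[hi], contigs$id[ci],
                      gs, strand)
        cand <- new_candidate(id, contigs$id[ci], gs, ge, strand, seqk,
                              fold, "homology", partial = partial)
        cand$catalog_hit <- hit
        out[[length(out) + 1]] <- cand
      }
    }
  }
  out
}

#' Read-guided hairpin candidates from a reference
#'
#' Maps small-RNA reads to a reference (exact or one mismatch, both
#' strands), clusters mapped loci within `cluster_gap` nt on the same
#' strand, extracts each cluster's span extended by `flank` nt on both
#' sides, folds it, and keeps windows passing the de-novo scan
#' thresholds.
#'
#' @param reads collapsed reads (`seq`, `count`).
#' @param reference sequence table to map against.
#' @param model an `energy_model`.
#' @param flank extension on each side of a read cluster (default 70 nt).
#' @param max_mm maximum mismatches in read placement (default 1).
#' @param cluster_gap maximum gap joining read loci into one cluster.
#' @param params scan thresholds, see [scan_params()].
#' @return list of `hairpin_candidate` objects (source
#'   `"reference_guided"`).
#' @export
reference_guided_candidates <- function(reads, reference,
                                        model = default_energy_model(),
                                        flank = 70, max_mm = 1,
                                        cluster_gap = 30,
                                        params = scan_params()) {
  stopifnot(nrow(reference) > 0)
  out <- list()
  n_mapped <- 0L
  for (ri in seq_len(nrow(reference))) {
    refseq <- reference$seq[ri]
    n <- nchar(refseq)
    loci <- list()
    for (strand in c("+", "-")) {
      subj <- Biostrings::RNAString(if (strand == "+") refseq else rev_comp(refseq))
      for (k in seq_len(nrow(reads))) {
        mt <- Biostrings::matchPattern(Biostrings::RNAString(reads$seq[k]),
                                       subj, max.mismatch = max_mm,
                                       with.indels = FALSE)
        if (length(mt) == 0) next
        n_mapped <- n_mapped + 1L
        st <- Biostrings::start(mt) - 1L
        en <- Biostrings::end(mt)
        if (strand == "-") { tmp <- n - en; en <- n - st; st <- tmp }
        loci[[length(loci) + 1]] <- data.frame(start = st, end = en,
                                               strand = strand)
      }
    }
    if (length(loci) == 0) next
    loci <- do.call(rbind, loci)
    for (strand in c("+", "-")) {
      lc <- loci[loci$strand == strand, , drop = FALSE]
      if (nrow(lc) == 0) next
      lc <- lc[order(lc$start), , drop = FALSE]
      grp <- cumsum(c(1, diff(lc$start) > cluster_gap))
      for (g in unique(grp)) {
        cl <- lc[grp == g, , drop = FALSE]
        s0 <- max(0L, min(cl$start) - flank)
        e0 <- min(n, max(cl$end) + flank)
        seqk <- substr(refseq, s0 + 1, e0)
        if (strand == "-") seqk <- rev_comp(seqk)
        if (nchar(seqk) < params$min_len) next
        fold <- tryCatch(fold_hairpin(seqk, model, min_len = params$min_len,
                                      max_len = max(nchar(seqk), params$max_len)),
                         error = function(e) NULL)
        if (is.null(fold)) next
        if (fold$dG > params$dg_max || fold$npairs < params$min_pairs ||
            (fold$loop[2] - fold$loop[1]) > params$max_loop) next
        id <- sprintf("rg_%s_%d_%s", reference$id[ri], s0, strand)
        out[[length(out) + 1]] <- new_candidate(id, reference$id[ri], s0, e0,
                                                strand, seqk, fold,
                                                "reference_guided")
      }
    }
  }
  if (n_mapped == 0L) message("reference_guided_candidates: no read mapped")
  out
}

#' Merge candidate sets, removing redundancy
#'
#' Candidates are merged when their loci overlap at least 50%
#' reciprocally on the same strand of the same contig, or when their
#' sequences align at identity >= 0.95 over coverage >= 0.90 in either
#' orientation (a near-palindromic hairpin reported on both strands of
#' one locus is one precursor). Distinct hairpins on opposite strands
#' of a locus are kept separate. Each
#' merged group keeps its lowest-dG representative; sources are
#' unioned. Output order is deterministic (by contig, start, strand),
#' so the operation is idempotent and input-order independent.
#'
#' @param sets a list of candidate lists (or a single flat list of
#'   `hairpin_candidate` objects).
#' @param min_reciprocal reciprocal-overlap fraction for locus merging.
#' @param seq_identity,seq_coverage sequence-level merge thresholds.
#' @return merged list of `hairpin_candidate` objects.
#' @export
merge_dedupe <- function(sets, min_reciprocal = 0.5, seq_identity = 0.95,
                         seq_coverage = 0.90) {
  cands <- if (length(sets) > 0 && inherits(sets[[1]], "hairpin_candidate"))
    sets else do.call(c, sets)
  if (is.null(cands) || length(cands) == 0) return(list())
  # canonical order first, so grouping is permutation-invariant
  key <- vapply(cands, function(cd) {
    if (is.null(cd$locus)) paste0("z_", cd$seq, "_", cd$id)
    else sprintf("%s_%012d_%s_%s_%s", cd$locus$contig, cd$locus$start,
                 cd$locus$strand, cd$seq, cd$id)
  }, character(1))
  cands <- cands[order(key)]
  n <- length(cands)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (same_locus(cands[[i]], cands[[j]], min_reciprocal) ||
        similar_seq(cands[[i]], cands[[j]], seq_identity, seq_coverage))
      union(i, j)
  }
  groups <- split(seq_len(n), vapply(seq_len(n), find, integer(1)))
  out <- lapply(groups, function(ix) {
    grp <- cands[ix]
    rep_i <- which.min(vapply(grp, function(cd) cd$dG, numeric(1)))
    rep_c <- grp[[rep_i]]
    rep_c$source <- sort(unique(unlist(lapply(grp, function(cd) cd$source))))
    hits <- lapply(grp, function(cd) cd$catalog_hit)
    hits <- hits[!vapply(hits, is.null, logical(1))]
    if (length(hits)) rep_c$catalog_hit <- hits[[1]]
    rep_c$partial <- all(vapply(grp, function(cd) cd$partial, logical(1)))
    rep_c
  })
  names(out) <- NULL
  out
}

#' Reverse-complement a candidate
#'
#' Returns the candidate viewed from the opposite strand (sequence
#' reverse-complemented, refolded, strand flag flipped, locus
#' unchanged), or `NULL` when the opposite orientation does not fold.
#' Used to let read evidence resolve the strand of near-palindromic
#' candidates whose two orientations merge into one.
#'
#' @param cd a `hairpin_candidate`.
#' @param model an `energy_model`.
#' @return a `hairpin_candidate` or `NULL`.
#' @export
flip_candidate <- function(cd, model = default_energy_model()) {
  seq_rc <- rev_comp(cd$seq)
  fold <- tryCatch(fold_hairpin(seq_rc, model, min_len = 40,
                                max_len = max(250, nchar(seq_rc))),
                   error = function(e) NULL)
  if (is.null(fold)) return(NULL)
  out <- cd
  out$seq <- seq_rc
  out$fold <- fold
  out$dG <- fold$dG
  if (!is.null(out$locus))
    out$locus$strand <- if (cd$locus$strand == "+") "-" else "+"
  out
}

same_locus <- function(a, b, min_reciprocal) {
  if (is.null(a$locus) || is.null(b$locus)) return(FALSE)
  if (a$locus$contig != b$locus$contig || a$locus$strand != b$locus$strand)
    return(FALSE)
  ov <- min(a$locus$end, b$locus$end) - max(a$locus$start, b$locus$start)
  if (ov <= 0) return(FALSE)
  la <- a$locus$end - a$locus$start
  lb <- b$locus$end - b$locus$start
  ov / la >= min_reciprocal && ov / lb >= min_reciprocal
}

## Sequence redundancy is orientation-agnostic: a near-palindromic
## hairpin and its reverse complement at the same locus are the same
## physical precursor, so both orientations are tried.
similar_seq <- function(a, b, min_identity, min_coverage) {
  # align shorter as query so coverage is measured on it
  if (nchar(a$seq) <= nchar(b$seq)) { q <- a$seq; s <- b$seq }
  else { q <- b$seq; s <- a$seq }
  hit <- local_align(q, s, min_identity = min_identity,
                     min_coverage = min_coverage)
  if (hit$accepted) return(TRUE)
  hit_rc <- local_align(q, rev_comp(s), min_identity = min_identity,
                        min_coverage = min_coverage)
  hit_rc$accepted
}
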