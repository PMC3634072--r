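## Sequence I/O: FASTA/FASTQ readers (Biostrings-backed), miRBase-dialect
## headers, read collapsing, BED6 export. All sequences are normalized to
## the RNA alphabet (T -> U, upper case) at the parse boundary; internal
## coordinates are 0-based half-open throughout.

normalize_rna <- function(x) {
  x <- chartr("t", "u", chartr("T", "U", toupper(x)))
  bad <- grepl("[^ACGUN]", x)
  if (any(bad))
    stop("non-RNA characters after normalization in sequence(s): ",
         paste(which(bad), collapse = ", "))
  x
}

seq_set <- function(id, seq, desc = NA_character_) {
  if (length(desc) == 1) desc <- rep(desc, length(id))
  if (anyDuplicated(id))
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  data.frame(id = as.character(id), seq = as.character(seq),
             desc = as.character(desc), stringsAsFactors = FALSE)
}

#' Read a FASTA file into a normalized sequence table
#'
#' Sequences are upper-cased and DNA is converted to RNA (T to U); ids
#' must be unique. The returned table has columns `id`, `seq`, `desc`
#' (text after the first whitespace in the header, `NA` if none).
#'
#' @param path FASTA file.
#' @return a `data.frame` with columns `id`, `seq`, `desc`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(ss) == 0) {
    warning("empty FASTA file: ", path)
    return(seq_set(character(), character()))
  }
  hdr <- names(ss)
  id <- sub("\\s.*", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), NA_character_)
  seq_set(id, normalize_rna(as.character(ss)), desc)
}

#' Write sequences to FASTA
#'
#' @param seqs a sequence table as returned by [read_fasta()] (columns
#'   `id`, `seq`, optional `desc`).
#' @param path output file.
#' @param wrap line width for the sequence (default 70).
#' @export
write_fasta <- function(seqs, path, wrap = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(seqs))) {
    hdr <- seqs$id[k]
    if (!is.null(seqs$desc) && !is.na(seqs$desc[k]))
      hdr <- paste(hdr, seqs$desc[k])
    writeLines(paste0(">", hdr), con)
    s <- seqs$seq[k]
    starts <- seq(1, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a miRBase-dialect hairpin catalogue
#'
#' Like [read_fasta()] but parses the species prefix of miRBase-style
#' ids (e.g. `dre-mir-430a` carries species code `dre`) into a
#' `species` column. Records without a hyphenated prefix are kept with
#' an empty species field and a warning.
#'
#' @param path FASTA file with miRBase-style headers.
#' @return a sequence table with an extra `species` column.
#' @export
read_mirbase_hairpins <- function(path) {
  seqs <- read_fasta(path)
  has_prefix <- grepl("^[A-Za-z]{2,4}-", seqs$id)
  if (any(!has_prefix) && nrow(seqs) > 0)
    warning("record(s) without species prefix: ",
            paste(seqs$id[!has_prefix], collapse = ", "))
  seqs$species <- ifelse(has_prefix, sub("-.*", "", seqs$id), "")
  seqs
}

#' Read small-RNA reads (FASTA/FASTQ), with optional collapsed counts
#'
#' FASTA headers in the collapsed dialect `>name_xCOUNT` contribute
#' COUNT copies; all other records count once. FASTQ quality strings
#' (Sanger, offset 33) are parsed and can drive an optional mean-quality
#' filter (off by default). Reads outside the length bounds are dropped.
#'
#' @param path FASTA or FASTQ file (format detected from content).
#' @param min_len,max_len retained read-length bounds (defaults 16 and
#'   30 nt, bracketing the ~22 nt of mature miRNAs).
#' @param min_mean_quality drop reads with mean Phred quality below this
#'   (`NULL`, the default, disables the filter; FASTQ only).
#' @return a `data.frame` with columns `seq`, `count`.
#' @export
read_small_rna <- function(path, min_len = 16, max_len = 30,
                           min_mean_quality = NULL) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1)
  if (length(first) == 0) return(data.frame(seq = character(), count = integer()))
  if (startsWith(first, "@")) {
    ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
    seqs <- normalize_rna(as.character(ss))
    count <- rep(1L, length(seqs))
    if (!is.null(min_mean_quality) && length(seqs)) {
      q <- as.character(S4Vectors::mcols(ss)$qualities)
      meanq <- vapply(q, function(x) mean(utf8ToInt(x)) - 33, numeric(1))
      keep <- meanq >= min_mean_quality
      seqs <- seqs[keep]; count <- count[keep]
    }
  } else {
    tab <- read_fasta(path)
    seqs <- tab$seq
    count <- ifelse(grepl("_x\\d+$", tab$id),
                    as.integer(sub(".*_x(\\d+)$", "\\1", tab$id)), 1L)
  }
  len_ok <- nchar(seqs) >= min_len & nchar(seqs) <= max_len
  collapse_reads(data.frame(seq = seqs[len_ok], count = count[len_ok],
                            stringsAsFactors = FALSE))
}

#' Collapse reads to distinct sequences
#'
#' Sums counts per distinct sequence; output is sorted by descending
#' count, then sequence. Total read count is conserved.
#'
#' @param reads a `data.frame` with columns `seq` and `count`
#'   (`count` defaults to 1 per row if absent).
#' @return a collapsed `data.frame` with columns `seq`, `count`.
#' @export
collapse_reads <- function(reads) {
  if (nrow(reads) == 0)
    return(data.frame(seq = character(), count = integer(),
                      stringsAsFactors = FALSE))
  if (is.null(reads$count)) reads$count <- 1L
  stopifnot(all(reads$count >= 1))
  agg <- tapply(reads$count, reads$seq, sum)
  out <- data.frame(seq = names(agg), count = as.integer(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write collapsed reads in the `>seqN_xCOUNT` FASTA dialect
#'
#' @param reads collapsed reads (`seq`, `count`).
#' @param path output FASTA.
#' @export
write_collapsed_fasta <- function(reads, path) {
  ids <- sprintf("read%d_x%d", seq_len(nrow(reads)), reads$count)
  write_fasta(data.frame(id = ids, seq = reads$seq), path)
}

#' Write genomic intervals as BED6
#'
#' Intervals are 0-based half-open, matching the internal convention,
#' so coordinates are written unchanged.
#'
#' @param intervals `data.frame` with columns `contig`, `start`, `end`,
#'   `name`, optional `score` (default 0) and `strand` (default `+`).
#' @param path output file.
#' @param contig_lengths optional named vector; when supplied, intervals
#'   outside `[0, length]` raise an error.
#' @export
write_bed <- function(intervals, path, contig_lengths = NULL) {
  n <- nrow(intervals)
  if (n == 0) { file.create(path); return(invisible(path)) }
  stopifnot(all(intervals$start >= 0), all(intervals$start < intervals$end))
  if (!is.null(contig_lengths)) {
    lim <- contig_lengths[intervals$contig]
    if (anyNA(lim) || any(intervals$end > lim))
      stop("interval(s) out of contig bounds")
  }
  score <- if (is.null(intervals$score)) rep(0, n) else intervals$score
  strand <- if (is.null(intervals$strand)) rep("+", n) else intervals$strand
  stopifnot(all(strand %in% c("+", "-")))
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s", intervals$contig,
                   as.integer(intervals$start), as.integer(intervals$end),
                   intervals$name, score, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Reverse complement of an RNA sequence
#'
#' @param seq RNA character scalar or vector.
#' @return the reverse complement (RNA alphabet).
#' @export
rev_comp <- function(seq) {
  vapply(seq, function(s) {
    chartr("ACGUN", "UGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
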