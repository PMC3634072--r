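## Synthetic-data generators: contigs with planted hairpins, read
## stacks with a Dicer-like processing signature, and UTRs with planted
## binding sites. Every generator is deterministic under its seed and
## returns a ground-truth table for recovery testing.

#' Plant perfect-stem hairpins in a random genome
#'
#' Builds an i.i.d.-random contig and embeds `n_hairpins`
#' non-overlapping perfect stem-loops (random 5' arm, random loop, 3'
#' arm its reverse complement), each on a random strand, optionally
#' with scattered substitutions. The truth table records each planted
#' locus, strand and sequence.
#'
#' @param genome_len contig length in nt (default 100000).
#' @param n_hairpins number of planted hairpins (default 20).
#' @param stem_len,loop_len stem pairs and loop length (defaults 30, 8).
#' @param mut_rate per-base substitution rate applied to the planted
#'   hairpin (default 0).
#' @param margin minimum spacing between planted loci (default 100 nt).
#' @param seed integer seed.
#' @param contig_id contig name.
#' @return list with `contigs` (sequence table) and `truth`
#'   (data.frame: id, start, end, strand, seq).
#' @export
plant_hairpins <- function(genome_len = 100000, n_hairpins = 20,
                           stem_len = 30, loop_len = 8, mut_rate = 0,
                           margin = 100, seed = NULL,
                           contig_id = "contig_1") {
  hp_len <- 2 * stem_len + loop_len
  if (n_hairpins > 0 && genome_len < n_hairpins * (hp_len + margin))
    stop("impossible packing: genome too short for ", n_hairpins, " hairpins")
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  genome <- strsplit(random_rna(genome_len), "")[[1]]
  starts <- integer(0)
  truth <- list()
  tries <- 0
  while (length(starts) < n_hairpins) {
    tries <- tries + 1
    if (tries > 1000 * max(1, n_hairpins))
      stop("impossible packing: could not place hairpins")
    s <- sample.int(genome_len - hp_len - 1L, 1)
    if (any(abs(s - starts) < hp_len + margin)) next
    arm5 <- random_rna(stem_len)
    loop <- random_rna(loop_len)
    hp <- paste0(arm5, loop, rev_comp(arm5))
    if (mut_rate > 0) {
      bs <- strsplit(hp, "")[[1]]
      mut <- runif(hp_len) < mut_rate
      bs[mut] <- vapply(bs[mut], function(b)
        sample(setdiff(RNA_BASES, b), 1), character(1))
      hp <- paste(bs, collapse = "")
    }
    strand <- sample(c("+", "-"), 1)
    planted <- if (strand == "+") hp else rev_comp(hp)
    genome[(s + 1):(s + hp_len)] <- strsplit(planted, "")[[1]]
    starts <- c(starts, s)
    truth[[length(truth) + 1]] <- data.frame(
      id = sprintf("planted_%d", length(starts)),
      start = s, end = s + hp_len, strand = strand, seq = hp,
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = character(), start = integer(), end = integer(),
               strand = character(), seq = character())
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(contigs = seq_set(contig_id, paste(genome, collapse = "")),
       truth = truth)
}

#' Simulate a small-RNA read stack on a precursor
#'
#' Reads of ~22 nt (length uniform on 20-24) whose 5' starts are
#' normally jittered around the Dicer site of the chosen arm (the arm's
#' first base for 5p, the first base after the loop for 3p); a fraction
#' of reads start uniformly anywhere (background noise).
#'
#' @param precursor a `hairpin_candidate` or a `hairpin_fold`.
#' @param arm `"5p"` or `"3p"`.
#' @param depth number of reads (default 50).
#' @param jitter_sd standard deviation of the 5'-start jitter in nt
#'   (default 1).
#' @param noise_frac fraction of uniformly placed reads (default 0.05).
#' @param read_lens read-length support (default 20:24).
#' @param seed integer seed.
#' @return collapsed reads (`seq`, `count`).
#' @export
simulate_read_stack <- function(precursor, arm = c("5p", "3p"), depth = 50,
                                jitter_sd = 1, noise_frac = 0.05,
                                read_lens = 20:24, seed = NULL) {
  arm <- match.arg(arm)
  fold <- if (inherits(precursor, "hairpin_candidate")) precursor$fold
          else precursor
  stopifnot(inherits(fold, "hairpin_fold"), depth >= 1)
  armint <- if (arm == "5p") fold$arm5 else fold$arm3
  if (armint[2] - armint[1] < 8)
    stop("arm ", arm, " absent or too short in this fold")
  dicer_site <- if (arm == "5p") armint[1] else star_site(fold)
  n <- nchar(fold$seq)
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  n_noise <- rbinom(1, depth, noise_frac)
  n_sig <- depth - n_noise
  lens <- if (length(read_lens) == 1) rep(read_lens, depth)
          else sample(read_lens, depth, replace = TRUE)
  # noise reads start uniformly over each read's valid placement range
  noise_starts <- floor(runif(n_noise) * (n - lens[n_sig + seq_len(n_noise)] + 1))
  starts <- c(round(rnorm(n_sig, dicer_site, jitter_sd)), noise_starts)
  starts <- pmax(0L, pmin(as.integer(starts), n - lens))
  seqs <- substring(fold$seq, starts + 1, starts + lens)
  collapse_reads(data.frame(seq = seqs, count = 1L, stringsAsFactors = FALSE))
}

## 5' start of the star (3p) read consistent with Dicer geometry: the
## partner of the 3p 5' end lies 2 nt inside the 5p mature's 3' end.
star_site <- function(fold, mature_len = 22) {
  p <- fold_partner(fold)
  target <- fold$arm5[1] + mature_len - 3
  cand <- which(!is.na(p)) - 1L
  cand <- cand[cand >= fold$arm3[1]]
  if (length(cand) == 0) return(fold$arm3[1])
  cand[which.min(abs(p[cand + 1L] - target))]
}

#' Plant miRNA binding sites in a synthetic UTR
#'
#' Embeds `n_sites` non-overlapping binding sites for a miRNA in a
#' random background (uniform i.i.d., or first-order Markov when a
#' `profile` is given). Modes: `perfect` plants the exact reverse
#' complement; `seed_only` keeps only the seed-pairing segment
#' (complementary to miRNA positions 1-8) and randomises the rest;
#' `mismatched` scatters `n_mismatch` substitutions over the perfect
#' site.
#'
#' @param utr_len UTR length (default 500 nt).
#' @param mirna miRNA sequence.
#' @param n_sites number of planted sites.
#' @param mode `"perfect"`, `"seed_only"` or `"mismatched"`.
#' @param n_mismatch substitutions for `mismatched` mode (default 4).
#' @param profile optional `dinuc_profile` for the background.
#' @param seed integer seed.
#' @param utr_id sequence id.
#' @return list with `utr` (sequence table) and `truth` (data.frame:
#'   utr_id, mirna_id, start, end, mode).
#' @export
plant_target_sites <- function(utr_len = 500, mirna, n_sites = 1,
                               mode = c("perfect", "seed_only", "mismatched"),
                               n_mismatch = 4, profile = NULL, seed = NULL,
                               utr_id = "utr_1") {
  mode <- match.arg(mode)
  mlen <- nchar(mirna)
  if (n_sites > 0 && utr_len < n_sites * (mlen + 10))
    stop("impossible packing: UTR too short for ", n_sites, " sites")
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  if (is.null(profile)) {
    bg <- strsplit(random_rna(utr_len), "")[[1]]
  } else {
    bg <- strsplit(generate_null_utrs(
      structure(list(trans = profile$trans, base_freq = profile$base_freq,
                     len_mean = utr_len, len_sd = 0),
                class = "dinuc_profile"),
      n = 1, min_len = utr_len)$seq[1], "")[[1]]
  }
  site_seq <- function() {
    rc <- rev_comp(mirna)
    if (mode == "perfect") return(rc)
    bs <- strsplit(rc, "")[[1]]
    if (mode == "seed_only") {
      # seed pairs sit at the site's 3' end (miRNA 5' end); randomize the rest
      keep_from <- mlen - 8 + 1
      bs[seq_len(keep_from - 1)] <- strsplit(random_rna(keep_from - 1), "")[[1]]
    } else {
      mut <- sample.int(mlen, n_mismatch)
      bs[mut] <- vapply(bs[mut], function(b)
        sample(setdiff(RNA_BASES, b), 1), character(1))
    }
    paste(bs, collapse = "")
  }
  starts <- integer(0)
  truth <- list()
  tries <- 0
  while (length(starts) < n_sites) {
    tries <- tries + 1
    if (tries > 1000 * max(1, n_sites))
      stop("impossible packing: could not place sites")
    s <- sample.int(utr_len - mlen, 1) - 1L
    if (any(abs(s - starts) < mlen + 5)) next
    sq <- site_seq()
    bg[(s + 1):(s + mlen)] <- strsplit(sq, "")[[1]]
    starts <- c(starts, s)
    truth[[length(truth) + 1]] <- data.frame(
      utr_id = utr_id, mirna_id = "mirna", start = s, end = s + mlen,
      mode = mode, stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(utr_id = character(), mirna_id = character(),
               start = integer(), end = integer(), mode = character())
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(utr = seq_set(utr_id, paste(bg, collapse = "")), truth = truth)
}
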