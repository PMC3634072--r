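## Dual-engine miRNA target prediction: hybridization MFE with
## extreme-value calibrated p-values, seed-weighted complementarity
## scoring, consensus intersection, cross-species conservation, and the
## UTR-length/site-count correlation.

DINUCS <- paste0(rep(RNA_BASES, each = 4), RNA_BASES)

#' Dinucleotide profile of a UTR set
#'
#' The 16 dinucleotide frequencies (summed over all sequences,
#' normalised to 1), the marginal base frequencies, the implied
#' first-order transition matrix, and the length mean/sd. Degenerate
#' compositions are regularised with a pseudocount of 0.5 per
#' dinucleotide when any base is absent.
#'
#' @param utrs sequence table (columns `id`, `seq`).
#' @return a `dinuc_profile`.
#' @export
dinucleotide_profile <- function(utrs) {
  stopifnot(nrow(utrs) > 0)
  ss <- Biostrings::RNAStringSet(utrs$seq)
  cnt <- colSums(Biostrings::dinucleotideFrequency(ss))
  cnt <- cnt[DINUCS]
  names(cnt) <- DINUCS
  freq <- cnt / sum(cnt)
  m <- matrix(cnt, 4, 4, byrow = TRUE, dimnames = list(RNA_BASES, RNA_BASES))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) m <- m + 0.5
  trans <- m / rowSums(m)
  base_freq <- rowSums(m) / sum(m)
  lens <- nchar(utrs$seq)
  structure(list(freq = freq, base_freq = base_freq, trans = trans,
                 len_mean = mean(lens), len_sd = if (length(lens) > 1) sd(lens) else 0,
                 total_nt = sum(lens)), class = "dinuc_profile")
}

#' @export
print.dinuc_profile <- function(x, ...) {
  cat("dinucleotide profile over", x$total_nt, "nt; length",
      sprintf("%.0f +/- %.0f", x$len_mean, x$len_sd), "\n")
  print(round(matrix(x$freq, 4, 4, byrow = TRUE,
                     dimnames = list(RNA_BASES, RNA_BASES)), 3))
  invisible(x)
}

#' Generate composition-matched null UTRs
#'
#' Random sequences from a first-order Markov chain matching the
#' profile's dinucleotide composition; lengths are drawn from a normal
#' distribution with the profile's mean/sd, rounded and truncated at
#' `min_len`. Used as the calibration null for hybridization energies.
#'
#' @param profile a `dinuc_profile`.
#' @param n number of sequences (default 5000, the standard calibration
#'   size).
#' @param seed integer seed for reproducibility (optional).
#' @param min_len minimum sequence length (default 30).
#' @return a sequence table with ids `null_1` .. `null_n`.
#' @export
generate_null_utrs <- function(profile, n = 5000, seed = NULL, min_len = 30) {
  stopifnot(n >= 1)
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  lens <- pmax(min_len, round(rnorm(n, profile$len_mean, profile$len_sd)))
  maxlen <- max(lens)
  cum <- t(apply(profile$trans, 1, cumsum))
  chars <- matrix("", n, maxlen)
  state <- findInterval(runif(n), cumsum(profile$base_freq)) + 1L
  chars[, 1] <- RNA_BASES[state]
  for (t in 2:maxlen) {
    u <- runif(n)
    nxt <- 1L + (u > cum[state, 1]) + (u > cum[state, 2]) + (u > cum[state, 3])
    state <- nxt
    chars[, t] <- RNA_BASES[state]
  }
  seqs <- vapply(seq_len(n), function(k)
    paste(chars[k, seq_len(lens[k])], collapse = ""), character(1))
  seq_set(sprintf("null_%d", seq_len(n)), seqs)
}

## Gumbel (extreme-value, maximum) distribution helpers -------------------

#' Gumbel distribution: density, CDF, quantiles, simulation, MLE
#'
#' Standard Gumbel (type-I extreme value, maximum convention) used to
#' convert best-in-sequence hybridization scores into p-values.
#' `gumbel_fit` maximises the likelihood over (location, scale) via
#' `optim`, started from moment estimates.
#'
#' @param x,q,p numeric vectors.
#' @param n number of draws.
#' @param location,scale parameters (scale > 0).
#' @return `gumbel_fit` returns a list with `location`, `scale`, `n`.
#' @export
dgumbel <- function(x, location = 0, scale = 1) {
  z <- (x - location) / scale
  exp(-z - exp(-z)) / scale
}

#' @rdname dgumbel
#' @export
pgumbel <- function(q, location = 0, scale = 1)
  exp(-exp(-(q - location) / scale))

#' @rdname dgumbel
#' @export
qgumbel <- function(p, location = 0, scale = 1)
  location - scale * log(-log(p))

#' @rdname dgumbel
#' @export
rgumbel <- function(n, location = 0, scale = 1)
  qgumbel(runif(n), location, scale)

#' @rdname dgumbel
#' @export
gumbel_fit <- function(x) {
  stopifnot(length(x) >= 10)
  if (sd(x) < 1e-9) stop("degenerate sample: zero variance")
  scale0 <- sd(x) * sqrt(6) / pi
  loc0 <- mean(x) - 0.5772156649 * scale0
  nll <- function(par) {
    s <- exp(par[2])
    z <- (x - par[1]) / s
    sum(z + exp(-z)) + length(x) * par[2]
  }
  fit <- optim(c(loc0, log(scale0)), nll, method = "BFGS")
  list(location = fit$par[1], scale = exp(fit$par[2]), n = length(x))
}

#' Calibrate an extreme-value null for one miRNA
#'
#' For every null sequence, the best hybridization site's
#' length-normalised energy (dG / ln L) is computed; a Gumbel
#' distribution is then fitted by maximum likelihood to the negated
#' normalised energies. Site p-values follow as the Gumbel upper-tail
#' probability of a score at least as extreme.
#'
#' @param mirna miRNA sequence (character scalar) or single-row table.
#' @param nulls null sequence table (at least 100 sequences, e.g. from
#'   [generate_null_utrs()]).
#' @param model an `energy_model`.
#' @return an `evd_params`: `location`, `scale`, `n_calibration`.
#' @export
calibrate_evd <- function(mirna, nulls, model = default_energy_model()) {
  if (is.data.frame(mirna)) mirna <- mirna$seq[1]
  if (nrow(nulls) < 100) stop("insufficient calibration: need >= 100 null sequences")
  x <- vapply(seq_len(nrow(nulls)), function(k) {
    s <- best_site_score(mirna, nulls$seq[k], model)
    if (is.na(s)) 0 else s
  }, numeric(1))
  fit <- gumbel_fit(x)
  structure(list(location = fit$location, scale = fit$scale,
                 n_calibration = fit$n), class = "evd_params")
}

## Best-site score statistic: -dG_norm of the best duplex (NA if none).
best_site_score <- function(mirna, target, model) {
  sites <- duplex_sites(mirna, target, model, max_sites = 1)
  if (is.null(sites)) return(NA_real_)
  -sites[[1]]$dG / log(nchar(target))
}

#' @export
print.evd_params <- function(x, ...) {
  cat(sprintf("EVD null: Gumbel(location = %.3f, scale = %.3f), n = %d\n",
              x$location, x$scale, x$n_calibration))
  invisible(x)
}

#' Extreme-value p-value for a normalised duplex energy
#'
#' @param evd an `evd_params`.
#' @param dG_norm length-normalised energy (dG / ln L).
#' @return upper-tail probability of a score at least this good under
#'   the calibrated null.
#' @export
evd_pvalue <- function(evd, dG_norm)
  1 - pgumbel(-dG_norm, evd$location, evd$scale)

#' Hybridization-energy target scan
#'
#' Scans a UTR for miRNA hybridization sites: all non-overlapping local
#' minimum-energy duplexes are found, each site's energy is normalised
#' by ln(UTR length), converted to an extreme-value p-value under the
#' calibrated null, and sites with p <= `p_threshold` are reported. No
#' seed-match constraint is applied unless `require_seed`.
#'
#' @param mirna single-row table or character (with `mirna_id`).
#' @param utr single-row table or character (with `utr_id`).
#' @param evd calibrated `evd_params` for this miRNA.
#' @param model an `energy_model`.
#' @param p_threshold site significance threshold (default 0.05).
#' @param require_seed require the duplex to cover miRNA positions 2-8.
#' @param mirna_id,utr_id labels when sequences are bare strings.
#' @return data.frame of `SiteHit`s: mirna_id, utr_id, start, end
#'   (0-based half-open), dG, dG_norm, pvalue, engine = "hybrid".
#' @export
hybrid_scan <- function(mirna, utr, evd, model = default_energy_model(),
                        p_threshold = 0.05, require_seed = FALSE,
                        mirna_id = "mirna", utr_id = "utr") {
  if (is.data.frame(mirna)) { mirna_id <- mirna$id[1]; mirna <- mirna$seq[1] }
  if (is.data.frame(utr)) { utr_id <- utr$id[1]; utr <- utr$seq[1] }
  empty <- data.frame(mirna_id = character(), utr_id = character(),
                      start = integer(), end = integer(), dG = numeric(),
                      dG_norm = numeric(), pvalue = numeric(),
                      engine = character(), stringsAsFactors = FALSE)
  sites <- duplex_sites(mirna, utr, model)
  if (is.null(sites)) return(empty)
  if (require_seed)
    sites <- Filter(function(s) all(1:7 %in% s$pairs[, 1]), sites)
  if (length(sites) == 0) return(empty)
  dg <- vapply(sites, function(s) s$dG, numeric(1))
  dgn <- dg / log(nchar(utr))
  pv <- evd_pvalue(evd, dgn)
  keep <- pv <= p_threshold
  if (!any(keep)) return(empty)
  out <- data.frame(
    mirna_id = mirna_id, utr_id = utr_id,
    start = vapply(sites, function(s) s$t_start, numeric(1))[keep],
    end = vapply(sites, function(s) s$t_end, numeric(1))[keep],
    dG = dg[keep], dG_norm = dgn[keep], pvalue = pv[keep],
    engine = "hybrid", stringsAsFactors = FALSE)
  out[order(out$pvalue, out$start), , drop = FALSE]
}

#' Seed-weighted complementarity target scan
#'
#' Smith-Waterman-style scan of the miRNA (reversed into pairing
#' register) against the UTR with complementarity scoring: +5 per
#' Watson-Crick pair, +1 per G:U, -3 per mismatch, affine gaps
#' -8/-2, with miRNA positions 2-8 (the seed) weighted x2. Sites must
#' reach `score_threshold` and their window must hybridise at
#' `dG_threshold` or better.
#'
#' @param mirna,utr sequences (single-row tables or characters).
#' @param model an `energy_model` for the energy co-filter.
#' @param score_threshold minimum complementarity score (default 80).
#' @param dG_threshold maximum site hybridization energy (default -14).
#' @param seed_weight weight on seed positions (default 2; 1 disables).
#' @param mirna_id,utr_id labels when sequences are bare strings.
#' @return data.frame of `SiteHit`s with columns mirna_id, utr_id,
#'   start, end, score, dG, engine = "complementarity".
#' @export
complementarity_scan <- function(mirna, utr, model = default_energy_model(),
                                 score_threshold = 80, dG_threshold = -14,
                                 seed_weight = 2, mirna_id = "mirna",
                                 utr_id = "utr") {
  if (is.data.frame(mirna)) { mirna_id <- mirna$id[1]; mirna <- mirna$seq[1] }
  if (is.data.frame(utr)) { utr_id <- utr$id[1]; utr <- utr$seq[1] }
  empty <- data.frame(mirna_id = character(), utr_id = character(),
                      start = integer(), end = integer(), score = numeric(),
                      dG = numeric(), engine = character(),
                      stringsAsFactors = FALSE)
  df <- .comp_scan_cpp(seq_to_int(mirna), rev(seq_to_int(utr)),
                       5, 1, -3, 8, 2, seed_weight, 2L, 8L,
                       score_threshold, 200L)
  if (nrow(df) == 0) return(empty)
  keep <- logical(nrow(df))
  dg <- numeric(nrow(df))
  for (k in seq_len(nrow(df))) {
    s0 <- max(0, df$t_start[k] - 3)
    e0 <- min(nchar(utr), df$t_end[k] + 3)
    dx <- duplex_mfe(mirna, substr(utr, s0 + 1, e0), model)
    dg[k] <- if (is.null(dx)) 0 else dx$dG
    keep[k] <- dg[k] <= dG_threshold
  }
  if (!any(keep)) return(empty)
  out <- data.frame(mirna_id = mirna_id, utr_id = utr_id,
                    start = df$t_start[keep], end = df$t_end[keep],
                    score = df$score[keep], dG = dg[keep],
                    engine = "complementarity", stringsAsFactors = FALSE)
  out[order(-out$score, out$start), , drop = FALSE]
}

#' Consensus targets supported by both engines
#'
#' Hits from the hybridization and complementarity engines for the same
#' (miRNA, UTR) whose sites overlap by at least one nucleotide are
#' paired one-to-one (best overlap first) and merged into consensus
#' targets; the consensus site is the union interval. The result is
#' symmetric in argument order and never larger than either input.
#'
#' @param hybrid_hits,comp_hits site tables from [hybrid_scan()] and
#'   [complementarity_scan()] (possibly row-bound over many pairs).
#' @return data.frame of consensus targets with per-engine columns.
#' @export
consensus <- function(hybrid_hits, comp_hits) {
  empty <- data.frame(mirna_id = character(), utr_id = character(),
                      start = integer(), end = integer(), dG = numeric(),
                      pvalue = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(hybrid_hits) == 0 || nrow(comp_hits) == 0) return(empty)
  out <- list()
  keys <- unique(rbind(hybrid_hits[c("mirna_id", "utr_id")],
                       comp_hits[c("mirna_id", "utr_id")]))
  keys <- keys[order(keys$mirna_id, keys$utr_id), , drop = FALSE]
  for (k in seq_len(nrow(keys))) {
    h <- hybrid_hits[hybrid_hits$mirna_id == keys$mirna_id[k] &
                     hybrid_hits$utr_id == keys$utr_id[k], , drop = FALSE]
    cm <- comp_hits[comp_hits$mirna_id == keys$mirna_id[k] &
                    comp_hits$utr_id == keys$utr_id[k], , drop = FALSE]
    if (nrow(h) == 0 || nrow(cm) == 0) next
    # all overlapping pairs, best (largest) overlap first, then greedy 1-1
    prs <- expand.grid(i = seq_len(nrow(h)), j = seq_len(nrow(cm)))
    prs$ov <- pmin(h$end[prs$i], cm$end[prs$j]) -
      pmax(h$start[prs$i], cm$start[prs$j])
    prs <- prs[prs$ov > 0, , drop = FALSE]
    prs <- prs[order(-prs$ov, prs$i, prs$j), , drop = FALSE]
    used_i <- logical(nrow(h)); used_j <- logical(nrow(cm))
    for (r in seq_len(nrow(prs))) {
      i <- prs$i[r]; j <- prs$j[r]
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      out[[length(out) + 1]] <- data.frame(
        mirna_id = keys$mirna_id[k], utr_id = keys$utr_id[k],
        start = min(h$start[i], cm$start[j]),
        end = max(h$end[i], cm$end[j]),
        dG = h$dG[i], pvalue = h$pvalue[i], score = cm$score[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(res$mirna_id, res$utr_id, res$start), , drop = FALSE]
}

#' Cross-species conservation of consensus target sites
#'
#' For each (miRNA, ortholog group), reports the set of species in
#' which a consensus site exists; a site is conserved when present in
#' at least two species.
#'
#' @param targets_by_species named list (species -> consensus table).
#' @param ortholog_groups data.frame with columns `group_id`, `utr_id`.
#' @return data.frame: mirna_id, group_id, n_species, species
#'   (comma-separated), conserved.
#' @export
conserved_sites <- function(targets_by_species, ortholog_groups) {
  stopifnot(length(targets_by_species) >= 2)
  out <- list()
  for (g in unique(ortholog_groups$group_id)) {
    utrs <- ortholog_groups$utr_id[ortholog_groups$group_id == g]
    if (length(utrs) == 0) { warning("empty ortholog group: ", g); next }
    mirnas <- unique(unlist(lapply(targets_by_species, function(tb)
      tb$mirna_id[tb$utr_id %in% utrs])))
    for (m in sort(mirnas)) {
      sp <- names(targets_by_species)[vapply(targets_by_species, function(tb)
        any(tb$mirna_id == m & tb$utr_id %in% utrs), logical(1))]
      out[[length(out) + 1]] <- data.frame(
        mirna_id = m, group_id = g, n_species = length(sp),
        species = paste(sort(sp), collapse = ","),
        conserved = length(sp) >= 2, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(mirna_id = character(), group_id = character(),
                      n_species = integer(), species = character(),
                      conserved = logical()))
  do.call(rbind, out)
}

#' Spearman correlation of UTR length with per-UTR site count
#'
#' Rank correlation between UTR length and the number of predicted
#' sites per UTR for one engine, with a permutation p-value (two-sided
#' on |rho|). When n! does not exceed `n_perm` the permutation
#' distribution is enumerated exactly; otherwise `n_perm` random
#' permutations are drawn (then the observed arrangement is counted
#' into the numerator and denominator).
#'
#' @param utrs sequence table defining the UTR universe (zero counts
#'   included).
#' @param hits a site table (any engine).
#' @param n_perm permutation budget (default 10000).
#' @param seed optional seed for the sampled-permutation branch.
#' @return a `correlation_result`: `rho`, `pvalue`, `n`, `exact`.
#' @export
utr_length_site_correlation <- function(utrs, hits, n_perm = 10000,
                                        seed = NULL) {
  n <- nrow(utrs)
  stopifnot(n >= 3)
  len <- nchar(utrs$seq)
  cnt <- vapply(utrs$id, function(u) sum(hits$utr_id == u), numeric(1))
  if (sd(len) == 0 || sd(cnt) == 0)
    stop("zero variance in UTR length or site count: rho undefined")
  rho <- cor(len, cnt, method = "spearman")
  exact <- factorial(n) <= n_perm
  if (exact) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) cor(len, cnt[p], method = "spearman"))
    pv <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
    rhos <- replicate(n_perm, cor(len, sample(cnt), method = "spearman"))
    pv <- (1 + sum(abs(rhos) >= abs(rho) - 1e-12)) / (n_perm + 1)
  }
  structure(list(rho = rho, pvalue = pv, n = n, exact = exact),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, permutation p = %.4g (n = %d%s)\n",
              x$rho, x$pvalue, x$n, if (x$exact) ", exact" else ""))
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}
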