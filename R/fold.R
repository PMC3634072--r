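## Hairpin folding and duplex hybridization: R-facing wrappers around the
## dynamic-programming core, plus the exhaustive enumeration oracle used
## to validate the DP on short sequences.

#' Fold a sequence into its minimum-energy single-stem hairpin
#'
#' Finds the minimum-free-energy structure among all single-stem-loop
#' structures (one helix, bulges and internal loops up to
#' `model$max_interior` unpaired bases per interruption, one terminal
#' loop of at least `model$min_loop` nt) by dynamic programming.
#' Flanking bases outside the closing pair stay unpaired at zero energy.
#' Equal-energy ties resolve to the 5'-most, then longest, helix.
#'
#' @param seq RNA sequence (character scalar). More than 10% N within
#'   the sequence is rejected.
#' @param model an `energy_model` (default: shipped table).
#' @param min_len,max_len accepted sequence-length bounds; defaults
#'   40-200 nt bracket typical fish pre-miRNA lengths (~86 nt).
#' @return a `hairpin_fold` object (`structure` dot-bracket, `dG`
#'   kcal/mol, 0-based half-open `arm5`, `loop`, `arm3` intervals,
#'   `pairs` matrix, `npairs`), or `NULL` if no structure with dG < 0
#'   exists.
#' @export
fold_hairpin <- function(seq, model = default_energy_model(),
                         min_len = 40, max_len = 200) {
  stopifnot(is.character(seq), length(seq) == 1)
  n <- nchar(seq)
  if (n < min_len || n > max_len)
    stop("sequence length ", n, " outside [", min_len, ", ", max_len, "]")
  s <- seq_to_int(seq)
  if (any(s > 3) && mean(s > 3) > 0.1) return(NULL)
  res <- .fold_full_cpp(s, model_params(model))
  if (is.null(res)) return(NULL)
  build_fold(seq, res)
}

build_fold <- function(seq, res) {
  n <- nchar(seq)
  pairs <- res$pairs
  st <- rep(".", n)
  st[pairs[, 1] + 1] <- "("
  st[pairs[, 2] + 1] <- ")"
  inner <- pairs[nrow(pairs), ]
  structure(list(
    seq = seq,
    structure = paste(st, collapse = ""),
    dG = res$dG,
    npairs = nrow(pairs),
    pairs = pairs,
    arm5 = c(res$outer_i, inner[1] + 1),
    loop = c(inner[1] + 1, inner[2]),
    arm3 = c(inner[2], res$outer_j + 1)
  ), class = "hairpin_fold")
}

#' @export
print.hairpin_fold <- function(x, ...) {
  cat(x$seq, "\n", x$structure, "\n", sep = "")
  cat(sprintf("dG = %.2f kcal/mol, %d bp stem, loop [%d, %d)\n",
              x$dG, x$npairs, x$loop[1], x$loop[2]))
  invisible(x)
}

## Partner map: position i (0-based) -> paired position or NA.
fold_partner <- function(fold) {
  n <- nchar(fold$seq)
  p <- rep(NA_integer_, n)
  p[fold$pairs[, 1] + 1] <- fold$pairs[, 2]
  p[fold$pairs[, 2] + 1] <- fold$pairs[, 1]
  p
}

#' Minimum-free-energy miRNA:target duplex
#'
#' Best intermolecular hybridization of a miRNA against a target
#' window: no intramolecular pairs, bulges/internal loops up to
#' `model$max_interior` unpaired bases per step, zero helix-initiation
#' term. G:U wobble pairs are permitted at reduced stability. An
#' optional seed-match constraint (miRNA positions 2-8 all paired,
#' default off) can be enforced.
#'
#' @param mirna miRNA sequence (16-30 nt).
#' @param target target RNA window (character scalar).
#' @param model an `energy_model`.
#' @param require_seed if `TRUE`, only duplexes whose helix covers
#'   miRNA positions 2-8 are reported.
#' @return a `duplex_result` (`dG`, `dG_norm` = dG / ln(target length),
#'   `site` 0-based half-open interval on the target, `m_span`,
#'   `structure` as `mirna-part&target-part` dot-bracket, `pairs`), or
#'   `NULL` when no duplex with dG < 0 exists.
#' @export
duplex_mfe <- function(mirna, target, model = default_energy_model(),
                       require_seed = FALSE) {
  stopifnot(nchar(mirna) >= 1, nchar(target) >= 1)
  sites <- duplex_sites(mirna, target, model, max_sites = if (require_seed) 50 else 1)
  if (is.null(sites)) return(NULL)
  if (require_seed) {
    ok <- vapply(sites, function(s)
      all(1:7 %in% s$pairs[, 1]), logical(1))
    sites <- sites[ok]
    if (length(sites) == 0) return(NULL)
  }
  build_duplex(mirna, target, sites[[1]])
}

## All non-overlapping candidate duplex sites on a target, best first.
duplex_sites <- function(mirna, target, model, max_sites = 200) {
  res <- .duplex_cpp(seq_to_int(mirna), seq_to_int(target),
                     model_params(model), TRUE, as.integer(max_sites))
  if (is.null(res)) return(NULL)
  res
}

build_duplex <- function(mirna, target, site) {
  m <- rep(".", nchar(mirna))
  t <- rep(".", nchar(target))
  m[site$pairs[, 1] + 1] <- "("
  t[site$pairs[, 2] + 1] <- ")"
  structure(list(
    dG = site$dG,
    dG_norm = site$dG / log(nchar(target)),
    site = c(site$t_start, site$t_end),
    m_span = c(site$m_start, site$m_end),
    structure = paste0(paste(m, collapse = ""), "&", paste(t, collapse = "")),
    pairs = site$pairs,
    pvalue = NULL
  ), class = "duplex_result")
}

#' @export
print.duplex_result <- function(x, ...) {
  cat(sprintf("duplex: dG = %.2f (normalized %.3f), site [%d, %d)\n",
              x$dG, x$dG_norm, x$site[1], x$site[2]))
  cat(x$structure, "\n")
  if (!is.null(x$pvalue)) cat("p =", format(x$pvalue), "\n")
  invisible(x)
}

#' Recompute a duplex energy from its pair list (additivity check)
#'
#' @param mirna,target the two sequences.
#' @param pairs 0-based two-column matrix of (miRNA, target) pairs in
#'   5'-to-3' miRNA order.
#' @param model an `energy_model`.
#' @return energy in kcal/mol.
#' @export
duplex_energy <- function(mirna, target, pairs, model = default_energy_model()) {
  mb <- strsplit(mirna, "")[[1]]
  tb <- strsplit(target, "")[[1]]
  e <- 0
  for (k in seq_len(nrow(pairs))) {
    pt <- pair_type(mb[pairs[k, 1] + 1], tb[pairs[k, 2] + 1])
    if (is.na(pt)) stop("non-pairable bases at duplex pair ", k)
    if (k > 1) {
      d1 <- pairs[k, 1] - pairs[k - 1, 1] - 1L
      d2 <- pairs[k - 1, 2] - pairs[k, 2] - 1L
      if (d1 < 0 || d2 < 0) stop("pairs not monotone")
      p_out <- pair_type(mb[pairs[k - 1, 1] + 1], tb[pairs[k - 1, 2] + 1])
      if (d1 == 0 && d2 == 0) e <- e + model$stack[p_out, pt]
      else if (d1 == 0 || d2 == 0) e <- e + bulge_penalty(model, d1 + d2)
      else e <- e + internal_penalty(model, d1, d2)
    }
  }
  unname(e)
}

#' Exhaustively enumerate all single-stem structures of a short sequence
#'
#' Test oracle: lists every legal single-stem-loop structure (nested
#' pairs, interior interruptions up to `model$max_interior`, terminal
#' loop of at least `model$min_loop`) with its additive energy,
#' recomputed from the dot-bracket string by [structure_energy()]. Only
#' intended for sequences of a dozen or so bases.
#'
#' @param seq RNA sequence.
#' @param model an `energy_model`.
#' @param max_len guard on sequence length (default 14).
#' @return `data.frame` with columns `structure`, `energy`; always
#'   includes the all-unpaired structure at energy 0.
#' @export
enumerate_structures <- function(seq, model = default_energy_model(),
                                 max_len = 14) {
  n <- nchar(seq)
  if (n > max_len) stop("sequence longer than max_len = ", max_len)
  bs <- strsplit(seq, "")[[1]]
  out_struct <- character()

  # chains of nested pairs (i1,j1) > (i2,j2) > ... obeying interior limits
  grow <- function(chain) {
    last <- chain[[length(chain)]]
    i0 <- last[1]; j0 <- last[2]
    if (j0 - i0 - 1 >= model$min_loop) {
      st <- rep(".", n)
      for (p in chain) { st[p[1]] <- "("; st[p[2]] <- ")" }
      out_struct[[length(out_struct) + 1]] <<- paste(st, collapse = "")
    }
    for (i in (i0 + 1):(j0 - 1)) {
      if (i > j0 - 1) break
      for (j in (j0 - 1):(i + 1)) {
        if (j <= i) break
        if ((i - i0 - 1) + (j0 - j - 1) > model$max_interior) next
        if (!can_pair(bs[i], bs[j])) next
        grow(c(chain, list(c(i, j))))
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (!can_pair(bs[i], bs[j])) next
    grow(list(c(i, j)))
  }
  energy <- vapply(out_struct, structure_energy, numeric(1),
                   seq = seq, model = model, USE.NAMES = FALSE)
  rbind(data.frame(structure = strrep(".", n), energy = 0),
        data.frame(structure = unlist(out_struct), energy = energy))
}
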