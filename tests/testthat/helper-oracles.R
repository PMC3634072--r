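# Independent brute-force oracles. These enumerate explicitly (no
# dynamic programming, no shared search code with the implementation)
# and are only usable on short inputs.

PAIRS6 <- c("AU", "UA", "GC", "CG", "GU", "UG")

oracle_step <- function(model, a1, b1, a2, b2, d1, d2) {
  if (d1 == 0 && d2 == 0) return(model$stack[paste0(a1, b1), paste0(a2, b2)])
  if (d1 == 0 || d2 == 0) return(model$bulge_base + model$bulge_slope * (d1 + d2))
  model$internal_base + model$internal_slope * (d1 + d2)
}

# minimum energy over every legal intermolecular pairing (miRNA indices
# increasing against target indices decreasing), by explicit recursion
brute_duplex_mfe <- function(m, t, model) {
  mb <- strsplit(m, "")[[1]]
  tb <- strsplit(t, "")[[1]]
  M <- length(mb); N <- length(tb)
  pairable <- function(a, b) paste0(a, b) %in% PAIRS6
  best <- Inf
  rec <- function(i, j, e) {
    if (e < best) best <<- e
    if (i >= M || j <= 1) return()
    for (k in (i + 1):M) {
      for (l in (j - 1):1) {
        d1 <- k - i - 1; d2 <- j - l - 1
        if (d1 + d2 > model$max_interior) next
        if (!pairable(mb[k], tb[l])) next
        rec(k, l, e + oracle_step(model, mb[i], tb[j], mb[k], tb[l], d1, d2))
      }
    }
  }
  for (i in 1:M) for (j in 1:N)
    if (pairable(mb[i], tb[j])) rec(i, j, 0)
  if (!is.finite(best) || best >= -1e-12) NA_real_ else best
}

# best local alignment score by explicit recursion over aligned columns
# (linear gap model); no memoization, so only for sequences <= ~10 nt
brute_local_score <- function(q, s, match = 1, mismatch = -2, gap = -3) {
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  n <- length(qa); m <- length(sa)
  rec <- function(i, j) {
    sc <- if (qa[i] == sa[j] && qa[i] != "N") match else mismatch
    ext <- 0
    if (i < n && j < m) {
      for (di in 1:(n - i)) for (dj in 1:(m - j)) {
        cand <- gap * ((di - 1) + (dj - 1)) + rec(i + di, j + dj)
        if (cand > ext) ext <- cand
      }
    }
    sc + ext
  }
  best <- 0
  for (i in 1:n) for (j in 1:m) {
    v <- rec(i, j)
    if (v > best) best <- v
  }
  best
}
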