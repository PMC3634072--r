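# Candidate discovery: de-novo scan, catalogue homology, read-guided
# extraction, non-redundant merge.

test_that("a planted perfect stem is recovered at its locus", {
  set.seed(401)
  ph <- plant_hairpins(genome_len = 3000, n_hairpins = 1, seed = 11)
  cands <- scan_hairpins(ph$contigs, MODEL, contig_id = "c")
  df <- candidates_to_df(cands)
  tr <- ph$truth
  ov <- pmin(df$end, tr$end) - pmax(df$start, tr$start)
  expect_true(any(ov >= tr$end - tr$start - 5))
  expect_lte(abs(df$start[which.max(ov)] - tr$start), 5)
  expect_lte(abs(df$end[which.max(ov)] - tr$end), 5)
})

test_that("reverse-complementing the contig mirrors the candidate loci", {
  set.seed(402)
  ph <- plant_hairpins(genome_len = 4000, n_hairpins = 2, seed = 12)
  n <- nchar(ph$contigs$seq[1])
  fwd <- candidates_to_df(scan_hairpins(ph$contigs, MODEL, contig_id = "c"))
  rc <- data.frame(id = "c", seq = rev_comp(ph$contigs$seq[1]))
  rev <- candidates_to_df(scan_hairpins(rc, MODEL, contig_id = "c"))
  # same number of loci, at mirrored coordinates (within the tolerance
  # of tie-breaking among equal-energy windows)
  expect_equal(nrow(fwd), nrow(rev))
  mirrored <- data.frame(start = sort(n - rev$end), end = sort(n - rev$start))
  expect_true(all(abs(sort(fwd$start) - mirrored$start) <= 5))
})

test_that("catalogue hairpins map by homology, with partial flags at edges", {
  set.seed(403)
  hp <- make_hairpin(stem = 30, loop = 8)
  catalog <- data.frame(id = "dre-mir-x", seq = hp, species = "dre")

  exact <- data.frame(id = "c1", seq = paste0(rand_rna(150), hp, rand_rna(150)))
  out <- map_known_hairpins(catalog, exact, MODEL)
  # the sense copy is a perfect, non-partial hit (a near-palindromic
  # hairpin may additionally hit the opposite strand at ~88% identity)
  ident <- vapply(out, function(cd) cd$catalog_hit$identity, numeric(1))
  best <- out[[which.max(ident)]]
  expect_equal(best$catalog_hit$identity, 1)
  expect_false(best$partial)
  expect_equal(best$seq, hp)

  # last 20 nt run off the contig end
  trunc <- data.frame(id = "c2", seq = paste0(rand_rna(150),
                                              substr(hp, 1, nchar(hp) - 20)))
  out2 <- map_known_hairpins(catalog, trunc, MODEL)
  expect_true(length(out2) >= 1 && out2[[1]]$partial)

  # 15% scattered substitutions still accepted (identity 0.85 >= 0.80)
  bs <- strsplit(hp, "")[[1]]
  mut <- sample(length(bs), round(0.15 * length(bs)))
  bs[mut] <- vapply(bs[mut], function(b)
    sample(setdiff(c("A", "C", "G", "U"), b), 1), character(1))
  diverged <- data.frame(id = "c3",
                         seq = paste0(rand_rna(150), paste(bs, collapse = ""),
                                      rand_rna(150)))
  out3 <- map_known_hairpins(catalog, diverged, MODEL)
  expect_gte(length(out3), 1)
  expect_gte(out3[[1]]$catalog_hit$identity, 0.80)
})

test_that("read clusters guide hairpin extraction from a reference", {
  set.seed(404)
  ph <- plant_hairpins(genome_len = 3000, n_hairpins = 1, seed = 13)
  tr <- ph$truth
  fold <- fold_hairpin(tr$seq[1], MODEL)
  reads <- simulate_read_stack(fold, "5p", depth = 30, jitter_sd = 1, seed = 14)
  out <- reference_guided_candidates(reads, ph$contigs, MODEL)
  df <- candidates_to_df(out)
  expect_gte(nrow(df), 1)
  ov <- pmin(df$end, tr$end) - pmax(df$start, tr$start)
  expect_gte(max(ov), tr$end - tr$start)  # contains the full hairpin

  # unmappable reads yield nothing
  none <- data.frame(seq = vapply(1:3, function(i) rand_rna(22), character(1)),
                     count = 1L)
  expect_message(out2 <- reference_guided_candidates(none, ph$contigs, MODEL),
                 "no read mapped")
  expect_equal(length(out2), 0)

  # doubling counts does not change the candidate set
  reads2 <- reads; reads2$count <- reads2$count * 2L
  out3 <- reference_guided_candidates(reads2, ph$contigs, MODEL)
  expect_equal(candidates_to_df(out3), df)
})

test_that("merging is idempotent, order-independent, and truth-preserving", {
  set.seed(405)
  ph <- plant_hairpins(genome_len = 12000, n_hairpins = 5, seed = 15)
  scan <- scan_hairpins(ph$contigs, MODEL, contig_id = "contig_1")
  catalog <- data.frame(id = sprintf("dre-mir-%d", 1:5), seq = ph$truth$seq)
  hom <- map_known_hairpins(catalog, ph$contigs, MODEL)
  merged <- merge_dedupe(list(scan, hom))
  truth_found <- vapply(seq_len(nrow(ph$truth)), function(k) {
    df <- candidates_to_df(merged)
    any(pmin(df$end, ph$truth$end[k]) - pmax(df$start, ph$truth$start[k]) >
          0.5 * (ph$truth$end[k] - ph$truth$start[k]))
  }, logical(1))
  expect_true(all(truth_found))
  # every planted locus is represented exactly once
  df <- candidates_to_df(merged)
  for (k in seq_len(nrow(ph$truth))) {
    n_at <- sum(pmin(df$end, ph$truth$end[k]) -
                  pmax(df$start, ph$truth$start[k]) > 0)
    expect_equal(n_at, 1)
  }
  # sources united where scan and homology found the same locus
  expect_true(any(vapply(merged, function(cd)
    all(c("homology", "scan") %in% cd$source), logical(1))))

  # idempotence and permutation invariance
  again <- merge_dedupe(merged)
  expect_equal(candidates_to_df(again), candidates_to_df(merged))
  perm <- merge_dedupe(list(rev(hom), rev(scan)))
  expect_equal(candidates_to_df(perm), candidates_to_df(merged))
})

test_that("distinct hairpins on opposite strands are kept separate", {
  set.seed(406)
  sa <- make_hairpin(30, 10)
  sb <- make_hairpin(30, 10)
  a <- mirkit:::new_candidate("a", "c", 100, 170, "+", sa,
                              fold_hairpin(sa, MODEL), "scan")
  b <- mirkit:::new_candidate("b", "c", 110, 180, "-", sb,
                              fold_hairpin(sb, MODEL), "scan")
  merged <- merge_dedupe(list(list(a), list(b)))
  expect_equal(length(merged), 2)
})
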