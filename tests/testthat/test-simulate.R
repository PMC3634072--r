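# Synthetic-data generators: reproducibility and truth-table fidelity.

test_that("planted genomes are reproducible and consistent with their truth", {
  a <- plant_hairpins(10000, 5, seed = 1)
  b <- plant_hairpins(10000, 5, seed = 1)
  expect_identical(a, b)
  expect_equal(nrow(a$truth), 5)
  # truth sequences actually sit at the recorded loci (sense or antisense)
  for (k in 1:5) {
    sub <- substr(a$contigs$seq[1], a$truth$start[k] + 1, a$truth$end[k])
    planted <- if (a$truth$strand[k] == "+") a$truth$seq[k]
               else rev_comp(a$truth$seq[k])
    expect_equal(sub, planted)
  }
  # non-overlapping loci
  o <- order(a$truth$start)
  expect_true(all(diff(a$truth$start[o]) >= a$truth$end[o][-5] -
                    a$truth$start[o][-5]))
})

test_that("planted hairpins fold below the scan energy threshold", {
  ph <- plant_hairpins(8000, 4, seed = 3)
  for (k in 1:4) {
    f <- fold_hairpin(ph$truth$seq[k], MODEL)
    expect_lte(f$dG, -15)
    expect_gte(f$npairs, 18)
  }
})

test_that("impossible packings and empty plantings are handled", {
  expect_error(plant_hairpins(500, 5, seed = 1), "packing")
  bg <- plant_hairpins(5000, 0, seed = 2)
  expect_equal(nrow(bg$truth), 0)
  expect_equal(nchar(bg$contigs$seq[1]), 5000)
})

test_that("read stacks honour jitter, noise and seed", {
  set.seed(801)
  hp <- make_hairpin(30, 8, flank = 6)
  f <- fold_hairpin(hp, MODEL)
  tight <- simulate_read_stack(f, "5p", depth = 100, jitter_sd = 0,
                               noise_frac = 0, read_lens = 22, seed = 4)
  expect_equal(nrow(tight), 1)  # all reads identical
  expect_equal(tight$count, 100)
  expect_identical(tight,
                   simulate_read_stack(f, "5p", depth = 100, jitter_sd = 0,
                                       noise_frac = 0, read_lens = 22, seed = 4))
  expect_equal(sum(simulate_read_stack(f, "5p", depth = 37, seed = 5)$count), 37)

  # pure noise defeats the block criterion downstream
  noisy <- simulate_read_stack(f, "5p", depth = 60, noise_frac = 1, seed = 6)
  st <- map_reads_to_precursor(noisy, hp)
  expect_false(block_score(st, f)$passes)
})

test_that("planted target sites are the reverse complement at the recorded locus", {
  set.seed(802)
  mirna <- rand_rna(22)
  pt <- plant_target_sites(300, mirna, n_sites = 2, seed = 7)
  expect_equal(nrow(pt$truth), 2)
  for (k in 1:2) {
    sub <- substr(pt$utr$seq[1], pt$truth$start[k] + 1, pt$truth$end[k])
    expect_equal(sub, rev_comp(mirna))
  }
  expect_error(plant_target_sites(50, mirna, n_sites = 3, seed = 8), "packing")
  null_utr <- plant_target_sites(200, mirna, n_sites = 0, seed = 9)
  expect_equal(nrow(null_utr$truth), 0)
})

test_that("seed-only sites need a lowered complementarity threshold", {
  set.seed(803)
  recovered <- c(default = 0, lowered = 0)
  for (k in 1:8) {
    mirna <- rand_rna(22)
    pt <- plant_target_sites(300, mirna, n_sites = 1, mode = "seed_only",
                             seed = 30 + k)
    hit_def <- complementarity_scan(mirna, pt$utr$seq[1], MODEL)
    hit_low <- complementarity_scan(mirna, pt$utr$seq[1], MODEL,
                                    score_threshold = 40, dG_threshold = 0)
    at_site <- function(h) nrow(h) > 0 &&
      any(pmin(h$end, pt$truth$end) - pmax(h$start, pt$truth$start) > 0)
    recovered["default"] <- recovered["default"] + at_site(hit_def)
    recovered["lowered"] <- recovered["lowered"] + at_site(hit_low)
  }
  expect_gte(recovered[["lowered"]], 6)  # found when relaxed
  expect_gt(recovered[["lowered"]], recovered[["default"]])
})
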