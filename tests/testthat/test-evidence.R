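# Read-stack evidence: mapping, the block criterion, classification,
# relative frequencies.

test_that("exact reads stack at a single 5' start", {
  set.seed(501)
  hp <- make_hairpin(stem = 30, loop = 8)
  mer <- substr(hp, 1, 22)
  st <- map_reads_to_precursor(data.frame(seq = mer, count = 100L), hp)
  expect_equal(sum(st$start5 > 0), 1)
  expect_equal(st$start5[1], 100)
  expect_equal(st$mapped_total, 100)
  expect_equal(st$coverage[1], 100)
  # an unmappable read leaves the stack unchanged
  st2 <- map_reads_to_precursor(
    data.frame(seq = c(mer, strrep("A", 22)), count = c(100L, 7L)), hp)
  expect_equal(st2$mapped_total, 100)
})

test_that("multi-site reads take the fewest-mismatch, then leftmost, site", {
  # precursor with the same 20-mer at two positions; exact match wins
  unit <- "ACGUACGGUUCAGCAUGCAA"
  mut <- paste0(substr(unit, 1, 19), "G")  # 1 mismatch at the 2nd site
  pre <- paste0(unit, strrep("A", 10), mut)
  st <- map_reads_to_precursor(data.frame(seq = unit, count = 5L), pre)
  expect_equal(unname(st$start5[1]), 5)
  expect_equal(sum(st$start5), 5)
})

test_that("jittered stacks keep the planted Dicer site as modal start", {
  set.seed(502)
  hp <- make_hairpin(stem = 30, loop = 8, flank = 6)
  f <- fold_hairpin(hp, MODEL)
  reads <- simulate_read_stack(f, "5p", depth = 80, jitter_sd = 1, seed = 7)
  st <- map_reads_to_precursor(reads, hp)
  expect_equal(which.max(st$start5) - 1L, f$arm5[1])
})

test_that("block fraction follows its definition on degenerate stacks", {
  set.seed(503)
  hp <- make_hairpin(stem = 30, loop = 8)
  f <- fold_hairpin(hp, MODEL)
  # all reads at one 5' start on the 5' arm
  st <- map_reads_to_precursor(data.frame(seq = substr(hp, 3, 24),
                                          count = 50L), hp)
  b <- block_score(st, f)
  expect_equal(b$block_fraction, 1)
  expect_true(b$passes)
  expect_equal(b$arm, "5p")
  # empty stack fails gracefully
  b0 <- block_score(map_reads_to_precursor(
    data.frame(seq = character(), count = integer()), hp), f)
  expect_false(b0$passes)
  expect_equal(b0$arm, "none")
})

test_that("uniformly tiled reads dilute the block fraction to ~5/N_arm", {
  set.seed(504)
  hp <- make_hairpin(stem = 40, loop = 8)
  f <- fold_hairpin(hp, MODEL)
  # one read per start across the whole precursor
  starts <- 0:(nchar(hp) - 22)
  reads <- data.frame(seq = substring(hp, starts + 1, starts + 22), count = 1L)
  st <- map_reads_to_precursor(collapse_reads(reads), hp)
  b <- block_score(st, f, arm = "5p", min_reads = 1)
  n_arm <- sum(st$start5[(f$arm5[1] + 1):f$arm5[2]] > 0)
  # ties resolve to the leftmost start (the arm edge), so the +/-2
  # window holds 3 of the N_arm single-read starts
  expect_equal(b$block_fraction, 3 / n_arm, tolerance = 1e-9)
  expect_false(b$passes)  # far below the 0.5 threshold
})

test_that("blocks overlapping the loop are rejected", {
  set.seed(505)
  hp <- make_hairpin(stem = 30, loop = 8)
  f <- fold_hairpin(hp, MODEL)
  st <- map_reads_to_precursor(
    stack_at(hp, f$loop[1] - 5, n_reads = 40), hp)
  b <- block_score(st, f)
  expect_true(b$in_loop)
  expect_false(b$passes)
})

test_that("classification follows the annotation rules", {
  set.seed(506)
  hp <- make_hairpin(stem = 30, loop = 8, flank = 6)
  f <- fold_hairpin(hp, MODEL)
  cand <- mirkit:::new_candidate("cand", "c", 0, nchar(hp), "+", hp, f, "scan")
  r5 <- simulate_read_stack(f, "5p", depth = 100, jitter_sd = 0,
                            noise_frac = 0, read_lens = 22, seed = 8)
  r3 <- simulate_read_stack(f, "3p", depth = 100, jitter_sd = 0,
                            noise_frac = 0, read_lens = 22, seed = 9)
  st <- map_reads_to_precursor(collapse_reads(rbind(r5, r3)), hp)
  b5 <- block_score(st, f, arm = "5p")
  b3 <- block_score(st, f, arm = "3p")

  hit <- local_align(hp, hp)  # accepted catalogue hit
  known <- classify_precursor(cand, st, list(b5, b3), hit)
  expect_equal(known$status, "known")
  expect_equal(known$mature_5p, b5$block_interval)

  novel <- classify_precursor(cand, st, list(b5, b3), NULL)
  expect_equal(novel$status, "novel")
  expect_true(novel$star_overhang_ok)  # 2-nt 3' overhangs on both arms

  empty <- map_reads_to_precursor(data.frame(seq = character(),
                                             count = integer()), hp)
  bb <- block_score(empty, f)
  rejected <- classify_precursor(cand, empty, list(bb), NULL)
  expect_equal(rejected$status, "rejected")
  # a catalogue hit without read support is still rejected
  expect_equal(classify_precursor(cand, empty, list(bb), hit)$status,
               "rejected")
})

test_that("relative frequencies normalize to one and preserve ratios", {
  expect_equal(relative_frequency(c(a = 2, b = 8)), c(a = 0.2, b = 0.8))
  expect_equal(relative_frequency(c(x = 5)), c(x = 1))
  expect_error(relative_frequency(c(a = 0, b = 0)), "zero")
  set.seed(507)
  # planted 3-fold enrichment across two tissues survives sampling noise
  # the enriched miRNA is a small share of the pool, so the frequency
  # ratio tracks the planted enrichment
  base <- c(m1 = 20, m2 = 1000, m3 = 1000)
  brain <- rmultinom(1, 50000, base * c(3, 1, 1))[, 1]
  gonad <- rmultinom(1, 50000, base)[, 1]
  fb <- relative_frequency(brain)
  fg <- relative_frequency(gonad)
  expect_equal(sum(fb), 1, tolerance = 1e-12)
  expect_equal(unname(fb["m1"] / fg["m1"]), 3, tolerance = 0.15)
})
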