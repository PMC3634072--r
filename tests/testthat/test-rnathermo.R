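# Thermodynamic core: folding and duplex DP against exhaustive
# enumeration, energy additivity, and model invariants.

test_that("energy model loads with the documented structure", {
  expect_s3_class(MODEL, "energy_model")
  expect_true(all(MODEL$stack <= 0))
  expect_identical(unname(MODEL$stack), unname(t(MODEL$stack)))
  expect_gte(MODEL$min_loop, 3)
  # nondecreasing hairpin penalty
  pen <- vapply(3:30, function(n) mirkit:::hairpin_penalty(MODEL, n), numeric(1))
  expect_true(all(diff(pen) >= 0))
})

test_that("a perfect short stem folds to the expected structure and energy", {
  f <- fold_hairpin("GGGGAAAACCCC", MODEL, min_len = 1, max_len = 50)
  expect_equal(f$structure, "((((....))))")
  # three GC/GC stacks plus a 4-nt terminal loop
  expect_equal(f$dG, 3 * MODEL$stack["GC", "GC"] +
                 mirkit:::hairpin_penalty(MODEL, 4))
  expect_equal(f$npairs, 4)
  expect_equal(f$loop, c(4, 8))
})

test_that("unpairable sequences do not fold", {
  expect_null(fold_hairpin(strrep("A", 40), MODEL))
  expect_error(fold_hairpin("ACGU", MODEL), "outside")
})

test_that("folding equals exhaustive enumeration on random 12-mers", {
  set.seed(101)
  for (k in 1:60) {
    s <- rand_rna(12)
    enum <- enumerate_structures(s, MODEL)
    f <- fold_hairpin(s, MODEL, min_len = 1, max_len = 50)
    if (is.null(f)) {
      expect_gte(min(enum$energy), -1e-12)
    } else {
      expect_equal(f$dG, min(enum$energy), tolerance = 1e-9)
      # the reported structure is among the minimum-energy structures
      argmin <- enum$structure[abs(enum$energy - min(enum$energy)) < 1e-9]
      expect_true(f$structure %in% argmin)
    }
  }
})

test_that("reported fold energy is additive over its structure string", {
  set.seed(102)
  for (k in 1:20) {
    s <- make_hairpin(stem = 12, loop = 5)
    f <- fold_hairpin(s, MODEL, min_len = 20, max_len = 60)
    expect_false(is.null(f))
    expect_equal(structure_energy(f$seq, f$structure, MODEL), f$dG,
                 tolerance = 1e-9)
  }
})

test_that("perfect-complement duplex energy is the hand-summed stack total", {
  d <- duplex_mfe("GGGGGGGG", "CCCCCCCC", MODEL)
  expect_equal(d$dG, 7 * MODEL$stack["GC", "GC"])
  expect_equal(d$site, c(0, 8))
  expect_equal(d$dG_norm, d$dG / log(8))
  expect_null(duplex_mfe("AAAAAAAA", "AAAAAAAA", MODEL))
})

test_that("duplex DP equals exhaustive pairing enumeration on short inputs", {
  set.seed(103)
  for (k in 1:40) {
    m <- rand_rna(sample(6:10, 1))
    t <- rand_rna(sample(8:14, 1))
    d <- duplex_mfe(m, t, MODEL)
    oracle <- brute_duplex_mfe(m, t, MODEL)
    if (is.null(d)) {
      expect_true(is.na(oracle))
    } else {
      expect_equal(d$dG, oracle, tolerance = 1e-9)
      expect_equal(duplex_energy(m, t, d$pairs, MODEL), d$dG,
                   tolerance = 1e-9)
    }
  }
})

test_that("appending a stackable complementary pair never raises duplex dG", {
  set.seed(104)
  for (k in 1:15) {
    n <- sample(6:12, 1)
    m <- rand_rna(n)
    t <- rev_comp(m)
    d0 <- duplex_mfe(m, t, MODEL)
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    b <- sample(c("A", "C", "G", "U"), 1)
    d1 <- duplex_mfe(paste0(m, b), paste0(comp[[b]], t), MODEL)
    expect_lte(d1$dG, d0$dG + 1e-9)
  }
})

test_that("folding is deterministic", {
  set.seed(105)
  s <- rand_rna(80)
  f1 <- fold_hairpin(s, MODEL)
  f2 <- fold_hairpin(s, MODEL)
  if (is.null(f1)) expect_null(f2)
  else expect_identical(f1$structure, f2$structure)
})

test_that("enumeration includes expected structures and rejects long input", {
  en <- enumerate_structures("GCAAAGC", MODEL)
  expect_true("((...))" %in% en$structure)
  expect_equal(enumerate_structures("AAAA", MODEL)$structure, "....")
  expect_error(enumerate_structures(rand_rna(20), MODEL), "max_len")
})
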