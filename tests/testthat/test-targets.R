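# Target engine: composition-matched nulls, extreme-value calibration,
# the two prediction engines, consensus, conservation, correlation.

test_that("dinucleotide profiles count and normalize correctly", {
  p <- dinucleotide_profile(data.frame(id = "a", seq = "ACAC"))
  expect_equal(unname(p$freq["AC"]), 2 / 3)
  expect_equal(unname(p$freq["CA"]), 1 / 3)
  expect_equal(sum(p$freq), 1)
  hp <- dinucleotide_profile(data.frame(id = c("a", "b"),
                                        seq = c("GGGG", "GGG")))
  expect_equal(unname(hp$freq["GG"]), 1)
})

test_that("null UTRs are seed-reproducible and match the source profile", {
  set.seed(701)
  src <- data.frame(id = sprintf("u%d", 1:20),
                    seq = vapply(1:20, function(i)
                      rand_rna(round(rnorm(1, 400, 60))), character(1)))
  prof <- dinucleotide_profile(src)
  a <- generate_null_utrs(prof, n = 50, seed = 99)
  b <- generate_null_utrs(prof, n = 50, seed = 99)
  expect_identical(a, b)
  big <- generate_null_utrs(prof, n = 600, seed = 5)
  got <- dinucleotide_profile(big)
  expect_lt(max(abs(got$freq - prof$freq)), 0.02)
  expect_equal(got$len_mean, prof$len_mean, tolerance = 0.05)
})

test_that("Gumbel MLE recovers known parameters", {
  set.seed(702)
  x <- rgumbel(5000, location = 5, scale = 1.2)
  fit <- gumbel_fit(x)
  expect_equal(fit$location, 5, tolerance = 0.05)
  expect_equal(fit$scale, 1.2, tolerance = 0.05)
  expect_error(gumbel_fit(rep(1, 200)), "degenerate")
})

test_that("degenerate calibration inputs are refused", {
  nulls <- data.frame(id = sprintf("n%d", 1:150),
                      seq = rep(strrep("A", 100), 150))
  expect_error(calibrate_evd(strrep("A", 22), nulls, MODEL), "degenerate")
  expect_error(calibrate_evd("ACGUACGUACGUACGUACGUAC", nulls[1:50, ], MODEL),
               "insufficient")
})

test_that("hybrid scan finds a planted perfect site with the smallest p-value", {
  set.seed(703)
  mirna <- rand_rna(22)
  pt <- plant_target_sites(500, mirna, n_sites = 1, seed = 6)
  prof <- dinucleotide_profile(data.frame(id = "bg", seq = rand_rna(20000)))
  prof$len_mean <- 500; prof$len_sd <- 50
  nulls <- generate_null_utrs(prof, n = 200, seed = 1)
  evd <- calibrate_evd(mirna, nulls, MODEL)
  hits <- hybrid_scan(mirna, pt$utr$seq[1], evd, MODEL, p_threshold = 0.2)
  expect_gte(nrow(hits), 1)
  expect_equal(hits$start[1], pt$truth$start)  # best p at the planted site
  expect_equal(hits$end[1], pt$truth$end)
  # p-values decrease monotonically with dG at fixed length
  expect_true(all(diff(hits$pvalue[order(hits$dG)]) >= -1e-12))
})

test_that("complementarity scores match the hand-computed constants", {
  set.seed(704)
  mirna <- rand_rna(22)
  pt <- plant_target_sites(400, mirna, n_sites = 1, seed = 7)
  hits <- complementarity_scan(mirna, pt$utr$seq[1], MODEL)
  expect_equal(nrow(hits), 1)
  # 7 doubled seed positions (2..8) at +5 each, 15 plain +5 positions
  expect_equal(hits$score, 7 * 10 + 15 * 5)
  expect_equal(hits$start, pt$truth$start)
  # disabling the seed weighting removes exactly the doubled halves
  plain <- complementarity_scan(mirna, pt$utr$seq[1], MODEL, seed_weight = 1)
  expect_equal(hits$score - plain$score, 7 * 5)
  # unpairable window: no sites
  expect_equal(nrow(complementarity_scan(strrep("A", 22), strrep("A", 100),
                                         MODEL)), 0)
})

test_that("consensus is a symmetric one-to-one intersection", {
  h <- data.frame(mirna_id = "m", utr_id = "u", start = c(10, 50),
                  end = c(32, 72), dG = c(-30, -25), dG_norm = NA,
                  pvalue = c(1e-4, 1e-3), engine = "hybrid")
  cm <- data.frame(mirna_id = "m", utr_id = "u", start = c(12, 200),
                   end = c(34, 222), score = c(120, 90),
                   dG = c(-30, -20), engine = "complementarity")
  cons <- consensus(h, cm)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 10)
  expect_equal(cons$end, 34)  # union interval
  expect_lte(nrow(cons), min(nrow(h), nrow(cm)))
  # symmetric in site overlap regardless of argument roles
  cons2 <- consensus(h[2:1, ], cm[2:1, ])
  expect_equal(cons2, cons)
  # disjoint sites give no consensus
  far <- cm; far$start <- far$start + 400; far$end <- far$end + 400
  expect_equal(nrow(consensus(h, far)), 0)
})

test_that("conservation requires a site in at least two species", {
  tb <- function(utr) data.frame(mirna_id = "miR-1", utr_id = utr,
                                 start = 1, end = 22, dG = -30,
                                 pvalue = 1e-3, score = 100)
  by_sp <- list(hhi = tb("g1_hhi"), dre = tb("g1_dre"), ola = tb("g1_ola"))
  groups <- data.frame(group_id = c("g1", "g1", "g1", "g2"),
                       utr_id = c("g1_hhi", "g1_dre", "g1_ola", "g2_hhi"))
  out <- conserved_sites(by_sp, groups)
  g1 <- out[out$group_id == "g1", ]
  expect_equal(g1$n_species, 3)
  expect_true(g1$conserved)
  # a site in one species only is not conserved
  by_sp2 <- list(hhi = tb("g1_hhi"), dre = tb("nope"))
  out2 <- conserved_sites(by_sp2, groups[1:3, ])
  expect_false(out2$conserved[1])
})

test_that("UTR-length correlation matches exhaustive permutation at n = 6", {
  set.seed(705)
  utrs <- data.frame(id = sprintf("u%d", 1:6),
                     seq = vapply(c(100, 150, 220, 300, 380, 450), rand_rna,
                                  character(1)))
  counts <- c(0, 1, 1, 2, 4, 3)
  hits <- data.frame(utr_id = rep(utrs$id, counts))
  res <- utr_length_site_correlation(utrs, hits)
  expect_true(res$exact)
  expect_equal(res$rho, cor(nchar(utrs$seq), counts, method = "spearman"))
  # independent enumeration oracle over all 720 permutations
  permute_all <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(permute_all(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  rhos <- vapply(permute_all(1:6), function(p)
    cor(nchar(utrs$seq), counts[p], method = "spearman"), numeric(1))
  expect_equal(length(rhos), 720)
  expect_equal(res$pvalue, mean(abs(rhos) >= abs(res$rho) - 1e-12))

  # strictly monotone counts give rho = 1
  mono <- data.frame(utr_id = rep(utrs$id, 1:6))
  expect_equal(utr_length_site_correlation(utrs, mono)$rho, 1)
  # zero variance is an error
  expect_error(utr_length_site_correlation(utrs, hits[0, , drop = FALSE]),
               "variance")
})
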