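# Sequence I/O: normalization, round trips, read collapsing, BED.

test_that("FASTA reading normalizes DNA to RNA and parses descriptions", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x some desc", "ACGT", ">y", "acgu"), p)
  tab <- read_fasta(p)
  expect_equal(tab$seq, c("ACGU", "ACGU"))
  expect_equal(tab$id, c("x", "y"))
  expect_equal(tab$desc, c("some desc", NA))
})

test_that("duplicate ids are rejected and empty files warn", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AC", ">a", "GG"), p)
  expect_error(read_fasta(p), "duplicate")
  file.create(p2 <- withr::local_tempfile(fileext = ".fa"))
  expect_warning(tab <- read_fasta(p2), "empty")
  expect_equal(nrow(tab), 0)
})

test_that("write_fasta/read_fasta round-trips normalized records", {
  set.seed(201)
  tab <- data.frame(id = c("r1", "r2", "r3"),
                    seq = vapply(c(150, 70, 23), rand_rna, character(1)),
                    desc = c("alpha", NA, "beta"))
  p <- withr::local_tempfile(fileext = ".fa")
  write_fasta(tab, p)
  back <- read_fasta(p)
  expect_equal(back$id, tab$id)
  expect_equal(back$seq, tab$seq)
  expect_equal(back$desc, tab$desc)
})

test_that("miRBase headers yield species prefixes, with fallback", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">dre-mir-430a MI0001", "ACGU", ">hairpinX", "ACGU"), p)
  expect_warning(tab <- read_mirbase_hairpins(p), "species prefix")
  expect_equal(tab$species, c("dre", ""))
  expect_equal(tab$id[1], "dre-mir-430a")
})

test_that("collapse_reads sums counts, sorts, and conserves totals", {
  out <- collapse_reads(data.frame(seq = c("ACGU", "ACGU"), count = c(1L, 2L)))
  expect_equal(out, data.frame(seq = "ACGU", count = 3L))
  expect_equal(nrow(collapse_reads(data.frame(seq = character(),
                                              count = integer()))), 0)
  set.seed(202)
  pool <- vapply(1:5, function(i) rand_rna(22), character(1))
  reads <- data.frame(seq = sample(pool, 1000, replace = TRUE), count = 1L)
  out <- collapse_reads(reads)
  expect_equal(nrow(out), 5)
  expect_equal(sum(out$count), 1000)
  expect_true(all(diff(out$count) <= 0))
})

test_that("small-RNA input honours the collapsed-count dialect and length bounds", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">read1_x53", strrep("AC", 11), ">read2_x2", strrep("GU", 11),
               ">short_x9", "ACGUACGU"), p)
  reads <- read_small_rna(p)
  expect_equal(sum(reads$count), 55)  # the 8-mer is dropped
  expect_equal(reads$count[reads$seq == strrep("AC", 11)], 53)
})

test_that("FASTQ reads parse with optional mean-quality filtering", {
  p <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", strrep("ACGT", 5), "+", strrep("I", 20),
               "@r2", strrep("GGCC", 5), "+", strrep("#", 20)), p)
  reads <- read_small_rna(p)
  expect_equal(sum(reads$count), 2)
  expect_true(strrep("ACGU", 5) %in% reads$seq)
  hq <- read_small_rna(p, min_mean_quality = 20)
  expect_equal(hq$seq, strrep("ACGU", 5))
})

test_that("BED6 output is 0-based half-open and round-trips through rtracklayer", {
  iv <- data.frame(contig = "c1", start = 10, end = 95,
                   name = "hairpin-n1", score = 0, strand = "+")
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, p)
  expect_equal(readLines(p), "c1\t10\t95\thairpin-n1\t0\t+")
  gr <- rtracklayer::import(p, format = "BED")
  expect_equal(GenomicRanges::start(gr), 11L)  # 1-based in GRanges
  expect_equal(GenomicRanges::end(gr), 95L)
  expect_equal(as.character(GenomicRanges::strand(gr)), "+")
  # empty interval set gives an empty file
  write_bed(iv[0, ], p)
  expect_equal(length(readLines(p)), 0)
  expect_error(write_bed(iv, p, contig_lengths = c(c1 = 50)), "bounds")
})

test_that("reverse complement is an involution over the RNA alphabet", {
  set.seed(203)
  s <- rand_rna(57)
  expect_equal(rev_comp(rev_comp(s)), s)
  expect_equal(rev_comp("ACGUN"), "NACGU")
})
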