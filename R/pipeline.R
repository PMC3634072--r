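## End-to-end orchestration: flat key-value config, the discovery run
## (scan -> homology -> read-guided -> merge -> filters -> evidence ->
## classification) and the target-prediction run (profile -> nulls ->
## calibration -> dual scans -> consensus -> optional conservation and
## correlation), with deterministic, audit-trailed reports.

pipeline_defaults <- function() {
  list(
    # inputs
    contigs = "", reads = "", catalog = "", blacklist = "",
    mirnas = "", utrs = "", ortholog_groups = "",
    out_dir = "run",
    seed = 1,
    # homology criterion
    min_identity = 0.80, min_coverage = 0.50,
    # de-novo scan thresholds
    scan_min_len = 60, scan_max_len = 120, scan_min_pairs = 18,
    scan_max_loop = 20, scan_dg_max = -15,
    # read evidence
    read_max_mm = 1, block_window = 2, block_min_frac = 0.5,
    block_min_reads = 10,
    # target engine
    n_calibration = 5000, p_threshold = 0.05,
    comp_score_threshold = 80, comp_dg_threshold = -14,
    require_seed_match = 0, bh_correction = 0,
    n_perm = 10000
  )
}

#' Read a pipeline configuration file
#'
#' Flat `key = value` text; `#` starts a comment. Unknown keys are
#' rejected; absent keys take the documented defaults (the homology
#' criterion at identity 0.80 over half the query, 5000 calibration
#' sequences, no seed-match constraint).
#'
#' @param path config file, or `NULL` for pure defaults.
#' @return a named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    stopifnot(file.exists(path))
    lines <- trimws(sub("#.*", "", readLines(path)))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
      key <- trimws(sub("=.*", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!key %in% names(cfg)) stop("unknown config key: ", key)
      cfg[[key]] <- if (is.numeric(cfg[[key]])) as.numeric(val) else val
    }
  }
  stopifnot(cfg$min_identity >= 0, cfg$min_identity <= 1,
            cfg$min_coverage >= 0, cfg$min_coverage <= 1,
            cfg$p_threshold > 0, cfg$p_threshold <= 1,
            cfg$n_calibration >= 100)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a pipeline configuration file
#'
#' @param cfg a `pipeline_config` (or plain list of overrides on the
#'   defaults).
#' @param path output file.
#' @export
write_pipeline_config <- function(cfg, path) {
  full <- pipeline_defaults()
  full[names(cfg)] <- cfg
  writeLines(sprintf("%s = %s", names(full),
                     vapply(full, as.character, character(1))), path)
  invisible(path)
}

cfg_scan_params <- function(cfg) {
  list(min_len = as.integer(cfg$scan_min_len),
       max_len = as.integer(cfg$scan_max_len),
       min_pairs = as.integer(cfg$scan_min_pairs),
       max_loop = as.integer(cfg$scan_max_loop),
       dg_max = cfg$scan_dg_max)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the precursor-discovery pipeline
#'
#' Executes the three candidate arms (de-novo scan, catalogue homology,
#' read-guided), merges them non-redundantly, applies the
#' tandem-repeat and ncRNA filters, maps reads back onto the surviving
#' candidates, applies the block criterion on both arms, and classifies
#' every candidate as known / novel / rejected. Writes BED6, FASTA and
#' TSV reports plus a stage-count summary and a removal log into
#' `cfg$out_dir`.
#'
#' @param cfg a `pipeline_config` with `contigs`, `reads`, `catalog`
#'   and `blacklist` paths set.
#' @param model an `energy_model`.
#' @return invisibly, a list with `calls`, `candidates`, `summary`.
#' @export
run_discover <- function(cfg, model = default_energy_model()) {
  for (f in c("contigs", "reads", "catalog", "blacklist"))
    if (!nzchar(cfg[[f]]) || !file.exists(cfg[[f]]))
      stop("missing input: ", f, " (", cfg[[f]], ")")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- read_fasta(cfg$contigs)
  reads <- read_small_rna(cfg$reads)
  catalog <- read_mirbase_hairpins(cfg$catalog)
  blacklist <- read_fasta(cfg$blacklist)
  sp <- cfg_scan_params(cfg)

  scan <- do.call(c, lapply(seq_len(nrow(contigs)), function(i)
    scan_hairpins(contigs[i, ], model, sp)))
  hom <- map_known_hairpins(catalog, contigs, model,
                            cfg$min_identity, cfg$min_coverage)
  rg <- reference_guided_candidates(reads, contigs, model, params = sp)
  merged <- merge_dedupe(list(scan, hom, rg))

  after_repeat <- repeat_filter(merged)
  after_ncrna <- ncrna_filter(after_repeat, blacklist,
                              cfg$min_identity, cfg$min_coverage)
  removal_log <- rbind(attr(after_repeat, "removed"),
                       attr(after_ncrna, "removed"))
  cands <- after_ncrna

  calls <- lapply(cands, function(cd) {
    stack <- map_reads_to_precursor(reads, cd, max_mm = cfg$read_max_mm)
    # the merge step collapses a near-palindromic hairpin's two
    # orientations into one candidate; read evidence decides the strand
    flipped <- flip_candidate(cd, model)
    if (!is.null(flipped)) {
      stack_rc <- map_reads_to_precursor(reads, flipped,
                                         max_mm = cfg$read_max_mm)
      if (stack_rc$mapped_total > stack$mapped_total) {
        cd <- flipped
        stack <- stack_rc
      }
    }
    blocks <- list(
      block_score(stack, cd$fold, arm = "5p", window = cfg$block_window,
                  min_frac = cfg$block_min_frac,
                  min_reads = cfg$block_min_reads),
      block_score(stack, cd$fold, arm = "3p", window = cfg$block_window,
                  min_frac = cfg$block_min_frac,
                  min_reads = cfg$block_min_reads))
    classify_precursor(cd, stack, blocks, cd$catalog_hit)
  })
  status <- vapply(calls, function(x) x$status, character(1))

  # report the evidence-resolved orientation of each candidate
  cands <- lapply(calls, function(x) x$candidate)
  cand_df <- candidates_to_df(cands)
  cand_df$status <- status
  call_df <- do.call(rbind, lapply(calls, function(x) data.frame(
    id = x$id, status = x$status,
    mature_5p = if (is.null(x$mature_5p)) "" else
      sprintf("%d-%d", x$mature_5p[1], x$mature_5p[2]),
    mature_3p = if (is.null(x$mature_3p)) "" else
      sprintf("%d-%d", x$mature_3p[1], x$mature_3p[2]),
    star_overhang_ok = x$star_overhang_ok, stringsAsFactors = FALSE)))
  if (is.null(call_df)) call_df <- data.frame(id = character(),
                                              status = character())
  summary <- data.frame(
    stage = c("scan", "homology", "reference_guided", "merged",
              "after_repeat_filter", "after_ncrna_filter",
              "known", "novel", "rejected"),
    count = c(length(scan), length(hom), length(rg), length(merged),
              length(after_repeat), length(after_ncrna),
              sum(status == "known"), sum(status == "novel"),
              sum(status == "rejected")))

  placed <- cand_df[!is.na(cand_df$start), , drop = FALSE]
  write_bed(data.frame(contig = placed$contig, start = placed$start,
                       end = placed$end, name = placed$id,
                       score = round(-placed$dG), strand = placed$strand),
            file.path(cfg$out_dir, "candidates.bed"))
  write_fasta(data.frame(id = cand_df$id, seq = cand_df$seq),
              file.path(cfg$out_dir, "candidates.fa"))
  write_tsv(cand_df, file.path(cfg$out_dir, "candidates.tsv"))
  write_tsv(call_df, file.path(cfg$out_dir, "calls.tsv"))
  write_tsv(removal_log, file.path(cfg$out_dir, "removal_log.tsv"))
  write_tsv(summary, file.path(cfg$out_dir, "discover_summary.tsv"))
  invisible(list(calls = calls, candidates = cands, summary = summary))
}

#' Run the target-prediction pipeline
#'
#' Builds the UTR dinucleotide profile, generates the calibration
#' nulls, calibrates an extreme-value null per miRNA, runs both
#' prediction engines over every (miRNA, UTR) pair, intersects them
#' into consensus targets, and (when ortholog groups are supplied)
#' reports cross-species conservation, plus the UTR-length/site-count
#' correlation per engine. Writes TSV reports into `cfg$out_dir`.
#'
#' @param cfg a `pipeline_config` with `mirnas` and `utrs` set.
#' @param model an `energy_model`.
#' @return invisibly, a list with `hybrid`, `comp`, `consensus`,
#'   `calibration`, `correlation`.
#' @export
run_targets <- function(cfg, model = default_energy_model()) {
  for (f in c("mirnas", "utrs"))
    if (!nzchar(cfg[[f]]) || !file.exists(cfg[[f]]))
      stop("missing input: ", f, " (", cfg[[f]], ")")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  mirnas <- read_fasta(cfg$mirnas)
  if (nrow(mirnas) == 0) stop("no miRNAs supplied")
  utrs <- read_fasta(cfg$utrs)
  if (nrow(utrs) == 0) stop("no UTRs supplied")

  profile <- dinucleotide_profile(utrs)
  nulls <- generate_null_utrs(profile, n = as.integer(cfg$n_calibration),
                              seed = as.integer(cfg$seed))
  hyb <- list(); cmp <- list(); calib <- list()
  for (mi in seq_len(nrow(mirnas))) {
    evd <- calibrate_evd(mirnas$seq[mi], nulls, model)
    calib[[mi]] <- data.frame(mirna_id = mirnas$id[mi],
                              location = evd$location, scale = evd$scale,
                              n_calibration = evd$n_calibration)
    for (ui in seq_len(nrow(utrs))) {
      hyb[[length(hyb) + 1]] <- hybrid_scan(
        mirnas[mi, ], utrs[ui, ], evd, model,
        p_threshold = cfg$p_threshold,
        require_seed = cfg$require_seed_match > 0)
      cmp[[length(cmp) + 1]] <- complementarity_scan(
        mirnas[mi, ], utrs[ui, ], model,
        score_threshold = cfg$comp_score_threshold,
        dG_threshold = cfg$comp_dg_threshold)
    }
  }
  hyb <- do.call(rbind, hyb)
  cmp <- do.call(rbind, cmp)
  calib <- do.call(rbind, calib)
  if (cfg$bh_correction > 0 && nrow(hyb) > 0) {
    hyb$pvalue_bh <- stats::p.adjust(hyb$pvalue, method = "BH")
  }
  cons <- consensus(hyb, cmp)

  corr <- NULL
  if (nrow(utrs) >= 3) {
    corr <- do.call(rbind, lapply(
      list(complementarity = cmp, hybrid = hyb), function(h) {
        res <- tryCatch(
          utr_length_site_correlation(utrs, h, n_perm = as.integer(cfg$n_perm),
                                      seed = as.integer(cfg$seed)),
          error = function(e) NULL)
        if (is.null(res)) return(NULL)
        data.frame(rho = res$rho, pvalue = res$pvalue, n = res$n)
      }))
    if (!is.null(corr)) corr <- cbind(engine = rownames(corr), corr)
  }

  write_tsv(calib, file.path(cfg$out_dir, "calibration.tsv"))
  write_tsv(hyb, file.path(cfg$out_dir, "hybrid_hits.tsv"))
  write_tsv(cmp, file.path(cfg$out_dir, "complementarity_hits.tsv"))
  write_tsv(cons, file.path(cfg$out_dir, "consensus_targets.tsv"))
  if (!is.null(corr)) write_tsv(corr, file.path(cfg$out_dir, "correlation.tsv"))

  conservation <- NULL
  if (nzchar(cfg$ortholog_groups) && file.exists(cfg$ortholog_groups)) {
    groups <- read.delim(cfg$ortholog_groups, stringsAsFactors = FALSE)
    if (!is.null(groups$species)) {
      by_sp <- split(seq_len(nrow(groups)), groups$species)
      targets_by_species <- lapply(by_sp, function(ix)
        cons[cons$utr_id %in% groups$utr_id[ix], , drop = FALSE])
      if (length(targets_by_species) >= 2) {
        conservation <- conserved_sites(targets_by_species,
                                        groups[c("group_id", "utr_id")])
        write_tsv(conservation, file.path(cfg$out_dir, "conservation.tsv"))
      }
    }
  }

  summary <- data.frame(
    stage = c("mirnas", "utrs", "hybrid_hits", "complementarity_hits",
              "consensus_targets"),
    count = c(nrow(mirnas), nrow(utrs), nrow(hyb), nrow(cmp), nrow(cons)))
  write_tsv(summary, file.path(cfg$out_dir, "targets_summary.tsv"))
  invisible(list(hybrid = hyb, comp = cmp, consensus = cons,
                 calibration = calib, correlation = corr,
                 conservation = conservation, summary = summary))
}

#' Generate a complete demo dataset with ground truth
#'
#' Emits every input the pipeline consumes — a contig with planted
#' hairpins, collapsed small-RNA reads stacked on the planted 5' arms,
#' a homologous hairpin catalogue (mutated copies of half the planted
#' hairpins, miRBase-style ids), an ncRNA blacklist matching planted
#' decoys, mature miRNAs, UTRs with planted sites — plus truth tables
#' and a ready-to-run config file.
#'
#' @param out_dir output directory.
#' @param seed integer seed (drives every randomised choice).
#' @param n_hairpins planted hairpins (default 8).
#' @param genome_len contig length (default 30000).
#' @param n_utrs UTR count (default 8).
#' @param n_calibration calibration-null count for the config
#'   (default 500; the full-scale default is 5000).
#' @return invisibly, the config path.
#' @export
simulate_dataset <- function(out_dir, seed = 1, n_hairpins = 8,
                             genome_len = 30000, n_utrs = 8,
                             n_calibration = 500) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) { old <- local_seed(seed); on.exit(restore_seed(old)) }
  # 5% divergence from the perfect stem, typical of cross-species
  # pre-miRNA conservation
  ph <- plant_hairpins(genome_len, n_hairpins, mut_rate = 0.05,
                       seed = seed + 1)
  model <- default_energy_model()

  # reads: stacks on each planted hairpin's 5' arm
  reads <- list()
  for (k in seq_len(nrow(ph$truth))) {
    fold <- fold_hairpin(ph$truth$seq[k], model)
    reads[[k]] <- simulate_read_stack(fold, "5p", depth = 50, seed = seed + 10 + k)
  }
  reads <- collapse_reads(do.call(rbind, reads))

  # catalogue: mutated copies of half the planted hairpins
  known_ix <- seq_len(ceiling(n_hairpins / 2))
  cat_seqs <- vapply(known_ix, function(k) {
    bs <- strsplit(ph$truth$seq[k], "")[[1]]
    mut <- runif(length(bs)) < 0.05
    bs[mut] <- vapply(bs[mut], function(b)
      sample(setdiff(RNA_BASES, b), 1), character(1))
    paste(bs, collapse = "")
  }, character(1))
  catalog <- seq_set(sprintf("dre-mir-sim%d", known_ix), cat_seqs)

  # blacklist: hairpin-shaped ncRNA decoys, also planted into the contig
  # (they pass the thermodynamic scan and must be removed by the filter)
  contig <- ph$contigs$seq[1]
  bl_seqs <- character(3)
  for (k in 1:3) {
    arm <- random_rna(30)
    bl_seqs[k] <- paste0(arm, random_rna(8), rev_comp(arm))
    contig <- paste0(contig, random_rna(100), bl_seqs[k], random_rna(100))
  }
  ph$contigs$seq[1] <- contig
  blacklist <- seq_set(sprintf("trna_decoy_%d", 1:3), bl_seqs)

  # mature miRNAs: 22-mers from planted 5' arms; UTRs with planted sites
  mat <- substr(ph$truth$seq, 1, 22)
  mirnas <- seq_set(sprintf("sim-miR-%d", seq_len(nrow(ph$truth))), mat)
  utr_tabs <- list(); site_truth <- list()
  for (u in seq_len(n_utrs)) {
    mi <- ((u - 1) %% nrow(mirnas)) + 1
    pt <- plant_target_sites(400 + 40 * u, mirnas$seq[mi],
                             n_sites = if (u %% 2 == 0) 1 else 2,
                             seed = seed + 100 + u,
                             utr_id = sprintf("utr_%d", u))
    pt$truth$mirna_id <- mirnas$id[mi]
    utr_tabs[[u]] <- pt$utr
    site_truth[[u]] <- pt$truth
  }
  utrs <- do.call(rbind, utr_tabs)

  paths <- list(
    contigs = file.path(out_dir, "contigs.fa"),
    reads = file.path(out_dir, "reads.fa"),
    catalog = file.path(out_dir, "catalog.fa"),
    blacklist = file.path(out_dir, "blacklist.fa"),
    mirnas = file.path(out_dir, "mirnas.fa"),
    utrs = file.path(out_dir, "utrs.fa"))
  write_fasta(ph$contigs, paths$contigs)
  write_collapsed_fasta(reads, paths$reads)
  write_fasta(catalog, paths$catalog)
  write_fasta(blacklist, paths$blacklist)
  write_fasta(mirnas, paths$mirnas)
  write_fasta(utrs, paths$utrs)
  write_tsv(ph$truth, file.path(out_dir, "truth_hairpins.tsv"))
  write_tsv(do.call(rbind, site_truth), file.path(out_dir, "truth_sites.tsv"))

  cfg <- c(paths, list(out_dir = file.path(out_dir, "results"), seed = seed,
                       n_calibration = n_calibration))
  cfg_path <- file.path(out_dir, "config.txt")
  write_pipeline_config(cfg, cfg_path)
  invisible(cfg_path)
}
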