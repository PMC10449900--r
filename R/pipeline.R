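## End-to-end orchestration: a structured YAML configuration drives
## simulate -> chimera filter -> coverage -> variant evaluation ->
## somatic filters -> heteroplasmy -> tandem repeats, writing TSV artifacts
## and a machine-readable JSON summary. Identical configurations reproduce
## byte-identical summaries.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = "dropmda_run",
    stages = list(simulate = TRUE, chimera = TRUE, coverage = TRUE,
                  variants = TRUE, heteroplasmy = TRUE, tr = TRUE),
    sim = list(),
    reads = list(n_reads = 300L, n_reads_mito = 80L),
    chimera = list(k = 15L, min_identity = 0.90, min_hit_len = 100L),
    coverage = list(bin_size = 5000L, high_cov_threshold = 200),
    tr = list(coverage = 20, allele_dropout = 0.2, split_prob = 0.3,
              flank = 100L),
    heteroplasmy = list(min_cov = 10, min_freq = 0.30, max_background = 0.05)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown configuration key '%s'", full), call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        stop(sprintf("key '%s' must be a mapping", full), call. = FALSE)
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Parse and validate a pipeline configuration
#'
#' Reads a YAML configuration (file path or literal text), fills defaults,
#' rejects unknown keys, and type-checks the result. The `sim` block is
#' passed through to [sim_config()], so any of its arguments may be set
#' there.
#'
#' @param x path to a YAML file, or a YAML string, or a list.
#' @return a validated `run_config` list (with the `sim` entry replaced by
#'   a built `sim_config`).
#' @export
validate_config <- function(x = list()) {
  user <- if (is.list(x)) {
    x
  } else if (file.exists(x)) {
    yaml::read_yaml(x)
  } else {
    yaml::yaml.load(x)
  }
  if (is.null(user)) user <- list()
  defaults <- pipeline_defaults()
  ## the sim block is validated by sim_config itself
  sim_user <- user$sim
  user$sim <- NULL
  defaults$sim <- NULL
  cfg <- merge_config(defaults, user)
  if (!is.null(sim_user)) {
    bad <- setdiff(names(sim_user), names(formals(sim_config)))
    if (length(bad)) {
      stop(sprintf("unknown sim configuration key(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    if (!is.null(sim_user$sv_counts)) {
      sim_user$sv_counts <- unlist(sim_user$sv_counts)
    }
    if (!is.null(sim_user$fp_sv_counts)) {
      sim_user$fp_sv_counts <- unlist(sim_user$fp_sv_counts)
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  for (nm in names(cfg$stages)) {
    if (!is.logical(cfg$stages[[nm]])) {
      stop(sprintf("stage toggle '%s' must be true/false", nm), call. = FALSE)
    }
  }
  cfg$sim <- do.call(sim_config, c(list(seed = cfg$seed), sim_user))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes the enabled stages in dependency order against one simulated
#' two-clone experiment, writes per-stage TSV artifacts plus FASTA/FASTQ/
#' PAF/VCF/BED files under `outdir`, and returns (and writes) a summary
#' list. Re-running with the same configuration reproduces byte-identical
#' summaries.
#'
#' @param config a `run_config` from [validate_config()] (or anything
#'   [validate_config()] accepts).
#' @param outdir output directory override.
#' @return the summary list, invisibly; written as `summary.json`.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  scfg <- cfg$sim
  roster <- cell_roster(scfg)
  summary <- list(seed = cfg$seed)
  log_stage <- function(...) message("[dropmda] ", sprintf(...))

  ## --- simulate -----------------------------------------------------------
  if (!cfg$stages$simulate) stop("stage 'simulate' is required", call. = FALSE)
  log_stage("simulate: genome")
  genome <- simulate_genome(scfg)
  write_genome_fasta(genome, file.path(cfg$outdir, "reference.fasta"))
  if (nrow(genome$tr_loci)) {
    write_bed(genome$tr_loci, file.path(cfg$outdir, "tr_loci.bed"),
              name_col = "unit")
  }
  summary$genome <- list(
    nuclear_bp = unname(nchar(genome$contigs[[NUC_CONTIG]])),
    mito_bp = unname(nchar(genome$contigs[[MITO_CONTIG]])),
    germline_by_type = as.list(table(genome$germline$svtype)),
    n_tr_loci = nrow(genome$tr_loci),
    somatic_per_clone = lapply(genome$clone_somatic, nrow))

  read_sets <- list()
  mito_sets <- list()
  for (cell in c(roster$cell_id, "bulk")) {
    log_stage("simulate: reads for %s", cell)
    frags <- fragment_and_encapsulate(genome, cell, scfg,
                                      contigs = NUC_CONTIG)
    amp <- amplify(frags, scfg)
    rs <- generate_reads(amp, genome, scfg, cfg$reads$n_reads)
    write_fastq(rs, file.path(cfg$outdir, paste0(cell, ".fastq")),
                qv = scfg$read_qv)
    write_paf(rs, genome, file.path(cfg$outdir, paste0(cell, ".paf")))
    read_sets[[cell]] <- rs
    if (cfg$stages$heteroplasmy && scfg$mito_copies > 0) {
      mfrags <- fragment_and_encapsulate(genome, cell, scfg,
                                         contigs = MITO_CONTIG)
      mamp <- amplify(mfrags, scfg)
      mito_sets[[cell]] <- generate_reads(mamp, genome, scfg,
                                          cfg$reads$n_reads_mito,
                                          seed = child_seed(scfg$seed,
                                                            paste0("mito_", cell)))
    }
  }
  summary$reads <- list(n_reads_per_cell = cfg$reads$n_reads,
                        n_cells = nrow(roster))

  ## --- chimera screen ------------------------------------------------------
  if (cfg$stages$chimera) {
    log_stage("chimera screen")
    chim <- lapply(read_sets, function(rs)
      filter_reads(rs$reads, k = cfg$chimera$k,
                   min_identity = cfg$chimera$min_identity,
                   min_hit_len = cfg$chimera$min_hit_len))
    rep_all <- do.call(rbind, lapply(names(chim), function(cell) {
      r <- chim[[cell]]$report; r$sample_id <- cell; r
    }))
    write.table(rep_all, file.path(cfg$outdir, "chimera_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    truth <- unlist(lapply(read_sets, function(rs) rs$reads$is_chimeric))
    called <- unlist(lapply(chim, function(x) x$report$verdict != "CLEAN"))
    summary$chimera <- list(
      pass_fraction = mean(unlist(lapply(chim, function(x)
        x$stats$pass_fraction))),
      sensitivity = if (any(truth)) sum(called & truth) / sum(truth) else NA,
      false_removal_rate = if (any(!truth))
        sum(called & !truth) / sum(!truth) else NA)
  }

  ## --- coverage metrics ----------------------------------------------------
  if (cfg$stages$coverage) {
    log_stage("coverage metrics")
    clen <- c(chr1 = unname(nchar(genome$contigs[[NUC_CONTIG]])))
    cov_rows <- lapply(names(read_sets), function(cell) {
      aln <- read_sets[[cell]]$segments
      prof <- binned_coverage(aln, clen, cfg$coverage$bin_size)
      data.frame(sample_id = cell,
                 breadth = breadth(aln, clen),
                 coverage_sd = coverage_sd(aln, clen),
                 frac_high_cov = frac_reads_high_cov(
                   aln, prof, cfg$coverage$high_cov_threshold),
                 aligned_n50 = aligned_n50(aln$ref_end - aln$ref_start),
                 stringsAsFactors = FALSE)
    })
    cov_df <- do.call(rbind, cov_rows)
    write.table(cov_df, file.path(cfg$outdir, "coverage_metrics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary$coverage <- list(
      mean_breadth = mean(cov_df$breadth),
      mean_coverage_sd = mean(cov_df$coverage_sd),
      mean_frac_high_cov = mean(cov_df$frac_high_cov))
  }

  ## --- variant evaluation --------------------------------------------------
  if (cfg$stages$variants) {
    log_stage("variant evaluation")
    calls <- emit_callsets(genome, scfg)
    for (s in names(calls)) {
      write_vcf(calls[[s]], file.path(cfg$outdir, paste0(s, ".vcf")), s)
    }
    cells <- setdiff(names(calls), "bulk")
    ev <- do.call(rbind, lapply(cells, function(cl) {
      e <- snv_eval(calls[[cl]], calls$bulk)
      data.frame(sample_id = cl, tp = e$tp, fp = e$fp, fn = e$fn,
                 precision = e$precision, sensitivity = e$sensitivity,
                 stringsAsFactors = FALSE)
    }))
    write.table(ev, file.path(cfg$outdir, "snv_eval.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    merged <- merge_svs(calls)
    write.table(merged, file.path(cfg$outdir, "sv_merged.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sv_ev <- do.call(rbind, lapply(cells, function(cl) {
      r <- sv_true_positives(calls[[cl]], calls$bulk)
      r$sample_id <- cl; r
    }))
    write.table(sv_ev, file.path(cfg$outdir, "sv_eval.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cells_by_clone <- lapply(split(roster$cell_id, roster$clone),
                             function(ids) calls[ids])
    som_snv <- somatic_snv_filter(cells_by_clone, calls$bulk,
                                  repeat_mask = genome$tr_loci)
    write.table(som_snv, file.path(cfg$outdir, "somatic_snv.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    som_sv <- somatic_sv_filter(merged, split(roster$cell_id, roster$clone))
    summary$variants <- list(
      snv_precision = mean(ev$precision),
      snv_sensitivity = mean(ev$sensitivity),
      sv_clusters = nrow(merged),
      somatic_snv_candidates = nrow(som_snv),
      somatic_sv_candidates = nrow(som_sv))
  }

  ## --- heteroplasmy --------------------------------------------------------
  if (cfg$stages$heteroplasmy && length(mito_sets)) {
    log_stage("heteroplasmy scan")
    pileups <- lapply(mito_sets, function(rs)
      base_pileup(rs, MITO_CONTIG, scfg$mito_length))
    clones <- split(roster$cell_id, roster$clone)
    scan <- heteroplasmy_scan(pileups, clones,
                              genome$contigs[[MITO_CONTIG]],
                              min_cov = cfg$heteroplasmy$min_cov,
                              min_freq = cfg$heteroplasmy$min_freq,
                              max_background = cfg$heteroplasmy$max_background)
    write.table(scan$sites, file.path(cfg$outdir, "heteroplasmy.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    hp <- genome$heteroplasmy
    summary$heteroplasmy <- list(
      n_sites = nrow(scan$sites),
      planted_detected = any(scan$sites$pos == hp$pos + 1L &
                               scan$sites$alt == hp$alt &
                               scan$sites$clone == hp$clone))
  }

  ## --- tandem repeats ------------------------------------------------------
  if (cfg$stages$tr && nrow(genome$tr_loci)) {
    log_stage("tandem-repeat genotyping")
    loci <- genome$tr_loci
    bulk_aln <- simulate_tr_reads(loci, coverage = cfg$tr$coverage,
                                  allele_dropout = 0,
                                  split_prob = cfg$tr$split_prob,
                                  flank = cfg$tr$flank,
                                  seed = child_seed(scfg$seed, "tr_bulk"))
    bulk_gt <- genotype_sample(bulk_aln, loci, flank = cfg$tr$flank)
    conc_rows <- lapply(roster$cell_id, function(cell) {
      aln <- simulate_tr_reads(loci, coverage = cfg$tr$coverage,
                               allele_dropout = cfg$tr$allele_dropout,
                               split_prob = cfg$tr$split_prob,
                               flank = cfg$tr$flank,
                               seed = child_seed(scfg$seed, paste0("tr_", cell)))
      gt <- genotype_sample(aln, loci, flank = cfg$tr$flank)
      cc <- tr_concordance(gt, bulk_gt, loci)
      data.frame(sample_id = cell, correct = cc$correct,
                 discordant = cc$discordant, missing = cc$missing,
                 ungenotyped = cc$ungenotyped,
                 n_bulk_loci = cc$n_bulk_loci, stringsAsFactors = FALSE)
    })
    conc <- do.call(rbind, conc_rows)
    write.table(conc, file.path(cfg$outdir, "tr_concordance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    summary$tr <- list(
      n_bulk_pass_loci = sum(bulk_gt$status == "PASS"),
      mean_correct_alleles = mean(conc$correct),
      mean_discordant = mean(conc$discordant))
  }

  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
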