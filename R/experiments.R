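## Experiment drivers: each function sets up one of the simulation
## experiments the package's analyses are built on (chimera screen
## benchmarking, MDA vs dMDA coverage contrast, SNV truth-set recovery,
## somatic SNV recovery, mitochondrial heteroplasmy detection) and runs the
## corresponding measurement end to end. The analysis scripts and the
## acceptance checks call these.

#' Convert a fraction of clean reads into intramolecular chimeras
#'
#' Rebuilds selected reads as fold-back inversions (prefix joined to the
#' reverse complement of its own tail) or tandem duplications (an internal
#' window repeated), with both arms of every junction at least `min_arm`
#' bases. Only reads long enough to host such arms are eligible.
#'
#' @param reads data.frame with `read_id` and `sequence` columns.
#' @param fraction fraction of reads to convert.
#' @param min_arm minimum arm length (bases) on each side of the junction.
#' @param seed RNG seed.
#' @return `reads` with updated `sequence`, `is_chimeric` and
#'   `chimera_type` columns (truth labels).
#' @export
plant_read_chimeras <- function(reads, fraction = 0.3, min_arm = 1000L,
                                seed = 1L) {
  with_seed(seed, {
    reads$is_chimeric <- FALSE
    reads$chimera_type <- "NONE"
    len <- nchar(reads$sequence)
    eligible <- which(len >= 2.5 * min_arm)
    n_want <- round(fraction * nrow(reads))
    if (n_want > length(eligible)) {
      stop("not enough long reads to plant the requested chimera fraction",
           call. = FALSE)
    }
    pick <- sample(eligible, n_want)
    kind <- sample(c("INVERSION", "DUPLICATION"), n_want, replace = TRUE)
    for (i in seq_along(pick)) {
      r <- pick[i]
      S <- reads$sequence[r]
      n <- len[r]
      if (kind[i] == "INVERSION") {
        ## fold-back: S[1..b] + revcomp(S[b-a2+1..b]); both arms >= min_arm
        b <- sample(seq.int(min_arm, n - floor(0.2 * min_arm)), 1L)
        a2 <- sample(seq.int(min_arm, b), 1L)
        reads$sequence[r] <- paste0(substr(S, 1L, b),
                                    revcomp(substr(S, b - a2 + 1L, b)))
      } else {
        ## tandem duplication of an internal window of >= min_arm bases
        w <- sample(seq.int(min_arm, min(2L * min_arm, n - 2L)), 1L)
        w1 <- sample.int(n - w - 1L, 1L)
        reads$sequence[r] <- paste0(substr(S, 1L, w1 + w),
                                    substr(S, w1 + 1L, n))
      }
      reads$is_chimeric[r] <- TRUE
      reads$chimera_type[r] <- kind[i]
    }
    reads
  })
}

#' Chimera-screen benchmark on simulated reads
#'
#' Simulates clean reads from a genome free of structural variation,
#' converts a known fraction into fold-back/duplication chimeras with arms
#' of at least `min_arm` bases, runs the self-alignment screen, and scores
#' it against the planted truth.
#'
#' @param seed master seed.
#' @param n_reads number of reads.
#' @param chimera_fraction fraction of reads converted to chimeras.
#' @param min_arm minimum chimera arm length (bases).
#' @param genome_length nuclear genome length.
#' @param read_error_rate per-base substitution error.
#' @param k,min_identity,min_hit_len screen parameters (see
#'   [self_align()]).
#' @return list with `sensitivity`, `false_removal_rate`, `pass_fraction`,
#'   the per-read `report`, and the truth-labelled `reads`.
#' @export
chimera_experiment <- function(seed = 1L, n_reads = 1000L,
                               chimera_fraction = 0.3, min_arm = 1000L,
                               genome_length = 10e6,
                               read_error_rate = 0.01, k = 15L,
                               min_identity = 0.90, min_hit_len = 100L) {
  cfg <- sim_config(seed = seed, genome_length = genome_length,
                    n_tr_loci = 0L, germline_snv_rate = 1e-5,
                    sv_counts = c(DEL = 0L, INS = 0L, DUP = 0L, INV = 0L),
                    somatic_snvs_per_clone = 0L,
                    chimera_rates = list(inversion_per_amplicon = 0,
                                         duplication_per_amplicon = 0,
                                         intermolecular_per_droplet = 0),
                    read_error_rate = read_error_rate)
  genome <- simulate_genome(cfg)
  frags <- fragment_and_encapsulate(genome, "A1", cfg, contigs = NUC_CONTIG)
  amp <- amplify(frags, cfg)
  rs <- generate_reads(amp, genome, cfg, n_reads)
  reads <- plant_read_chimeras(rs$reads, chimera_fraction, min_arm,
                               seed = child_seed(seed, "plant"))
  res <- filter_reads(reads, k = k, min_identity = min_identity,
                      min_hit_len = min_hit_len)
  truth_chim <- reads$is_chimeric
  called_chim <- res$report$verdict != "CLEAN"
  list(
    sensitivity = sum(called_chim & truth_chim) / max(1L, sum(truth_chim)),
    false_removal_rate = sum(called_chim & !truth_chim) /
      max(1L, sum(!truth_chim)),
    pass_fraction = res$stats$pass_fraction,
    report = res$report, reads = reads
  )
}

## Minimal variation-free config for coverage experiments.
coverage_config <- function(seed, genome_length, mode, mda_log_sigma = 2,
                            dmda_cap_copies = 20L) {
  sim_config(seed = seed, genome_length = genome_length, n_tr_loci = 0L,
             germline_snv_rate = 0,
             sv_counts = c(DEL = 0L, INS = 0L, DUP = 0L, INV = 0L),
             somatic_snvs_per_clone = 0L, mito_copies = 0L,
             gain_model = list(mode = mode, mda_log_sigma = mda_log_sigma,
                               dmda_cap_copies = dmda_cap_copies,
                               mean_copies = 8),
             chimera_rates = list(inversion_per_amplicon = 0,
                                  duplication_per_amplicon = 0,
                                  intermolecular_per_droplet = 0),
             read_error_rate = 0)
}

#' MDA versus dMDA coverage-uniformity contrast
#'
#' Simulates matched read sets from the same genome under the heavy-tailed
#' bulk-MDA gain model and the droplet-capped dMDA gain model, and
#' compares the fraction of reads in extreme-coverage (>= `threshold`)
#' 5 kb bins, the per-base coverage standard deviation, and the Gini
#' coefficient of coverage.
#'
#' @param seed master seed (each replicate derives its own).
#' @param n_replicates paired replicates.
#' @param genome_length nuclear genome length.
#' @param n_reads reads per replicate per mode (matched read counts).
#' @param bin_size coverage bin size (bases).
#' @param threshold extreme-coverage depth threshold.
#' @param mda_log_sigma lognormal sd of the MDA gain model.
#' @return data.frame with one row per replicate: `frac_high_mda`,
#'   `frac_high_dmda`, `sd_mda`, `sd_dmda`, `gini_mda`, `gini_dmda`.
#' @export
coverage_contrast_experiment <- function(seed = 1L, n_replicates = 20L,
                                         genome_length = 1e6,
                                         n_reads = 5000L, bin_size = 5000L,
                                         threshold = 200,
                                         mda_log_sigma = 2) {
  base_cfg <- coverage_config(seed, genome_length, "dmda")
  genome <- simulate_genome(base_cfg)
  clen <- c(chr1 = unname(nchar(genome$contigs[[NUC_CONTIG]])))
  one_mode <- function(mode, rep_seed) {
    cfg <- coverage_config(rep_seed, genome_length, mode,
                           mda_log_sigma = mda_log_sigma)
    frags <- fragment_and_encapsulate(genome, "A1", cfg,
                                      contigs = NUC_CONTIG)
    amp <- amplify(frags, cfg)
    rs <- generate_reads(amp, genome, cfg, n_reads, emit_sequence = FALSE)
    aln <- rs$segments
    prof <- binned_coverage(aln, clen, bin_size)
    c(frac = frac_reads_high_cov(aln, prof, threshold),
      sd = coverage_sd(aln, clen),
      gini = coverage_gini(aln, clen))
  }
  rows <- lapply(seq_len(n_replicates), function(r) {
    rep_seed <- child_seed(seed, "covrep", r)
    m <- one_mode("mda", rep_seed)
    d <- one_mode("dmda", rep_seed + 1L)
    data.frame(replicate = r,
               frac_high_mda = m[["frac"]], frac_high_dmda = d[["frac"]],
               sd_mda = m[["sd"]], sd_dmda = d[["sd"]],
               gini_mda = m[["gini"]], gini_dmda = d[["gini"]])
  })
  do.call(rbind, rows)
}

#' SNV truth-set recovery under dropout and false calls
#'
#' Plants germline SNVs, emits bulk and single-cell call sets under the
#' configured allelic dropout and a false-call rate chosen so the expected
#' precision equals `target_precision`, and measures precision and
#' sensitivity of every cell against bulk.
#'
#' @param seed master seed.
#' @param n_sites expected number of germline SNV sites.
#' @param genome_length nuclear genome length.
#' @param dropout allelic dropout rate.
#' @param target_precision expected precision used to set the false-call
#'   rate: `fp = (1 - dropout) * (1 - p) / p`.
#' @return list with `per_cell` (data.frame of tp/fp/fn/precision/
#'   sensitivity), `precision`, `sensitivity` (means), `n_bulk_sites`,
#'   `expected_precision`, `expected_sensitivity`.
#' @export
snv_recovery_experiment <- function(seed = 1L, n_sites = 10000L,
                                    genome_length = 10e6, dropout = 0.8,
                                    target_precision = 0.86) {
  fp_rate <- (1 - dropout) * (1 - target_precision) / target_precision
  cfg <- sim_config(seed = seed, genome_length = genome_length,
                    n_tr_loci = 0L,
                    germline_snv_rate = n_sites / genome_length,
                    sv_counts = c(DEL = 0L, INS = 0L, DUP = 0L, INV = 0L),
                    somatic_snvs_per_clone = 0L, dropout_rate = dropout,
                    fp_snv_rate = fp_rate,
                    fp_sv_counts = c(DEL = 0, INS = 0, DUP = 0, INV = 0))
  genome <- simulate_genome(cfg)
  calls <- emit_callsets(genome, cfg)
  bulk <- calls$bulk
  cells <- setdiff(names(calls), "bulk")
  per_cell <- do.call(rbind, lapply(cells, function(cl) {
    ev <- snv_eval(calls[[cl]], bulk)
    data.frame(cell_id = cl, tp = ev$tp, fp = ev$fp, fn = ev$fn,
               precision = ev$precision, sensitivity = ev$sensitivity,
               stringsAsFactors = FALSE)
  }))
  list(per_cell = per_cell,
       precision = mean(per_cell$precision),
       sensitivity = mean(per_cell$sensitivity),
       n_bulk_sites = sum(bulk$svtype == "SNV"),
       expected_precision = target_precision,
       expected_sensitivity = 1 - dropout)
}

#' Somatic SNV recovery across clones
#'
#' Plants `n_somatic` somatic SNVs per clone, emits call sets under
#' dropout, runs the clone-aware somatic filter, and reports recovered
#' counts against the closed-form expectation
#' `P(called in >= 2 of n cells) = 1 - q^n - n p q^(n-1)` with
#' `p = 1 - dropout`.
#'
#' @param seed master seed.
#' @param n_somatic somatic SNVs planted per clone.
#' @param dropout allelic dropout rate.
#' @param n_cells_per_clone cells per clone.
#' @param genome_length nuclear genome length.
#' @return list with `candidates` (filter output), `recovered_per_clone`,
#'   `true_positive` (candidates matching planted truth),
#'   `p_detect` (closed-form per-site detection probability) and
#'   `n_planted` per clone.
#' @export
somatic_snv_experiment <- function(seed = 1L, n_somatic = 30L, dropout = 0.5,
                                   n_cells_per_clone = 3L,
                                   genome_length = 10e6) {
  cfg <- sim_config(seed = seed, genome_length = genome_length,
                    n_tr_loci = 0L, germline_snv_rate = 1e-4,
                    sv_counts = c(DEL = 0L, INS = 0L, DUP = 0L, INV = 0L),
                    somatic_snvs_per_clone = n_somatic,
                    n_cells_per_clone = n_cells_per_clone,
                    dropout_rate = dropout, fp_snv_rate = 0.01,
                    fp_sv_counts = c(DEL = 0, INS = 0, DUP = 0, INV = 0))
  genome <- simulate_genome(cfg)
  calls <- emit_callsets(genome, cfg)
  roster <- cell_roster(cfg)
  cells_by_clone <- lapply(split(roster$cell_id, roster$clone),
                           function(ids) calls[ids])
  cand <- somatic_snv_filter(cells_by_clone, calls$bulk)
  truth_keys <- lapply(genome$clone_somatic, function(df)
    paste(df$contig, df$pos + 1L, df$ref, df$alt, sep = ":"))
  cand_keys <- paste(cand$contig, cand$pos, cand$ref, cand$alt, sep = ":")
  p <- 1 - dropout
  q <- dropout
  n <- n_cells_per_clone
  p_detect <- 1 - q^n - n * p * q^(n - 1)
  list(candidates = cand,
       recovered_per_clone = table(factor(cand$clone, levels = c("A", "B"))),
       true_positive = sum(cand_keys %in% unlist(truth_keys)),
       p_detect = p_detect,
       n_planted = n_somatic)
}

#' Mitochondrial heteroplasmy detection experiment
#'
#' Simulates mitochondrial reads for every cell and the bulk sample,
#' builds per-sample pileups, and scans for clone-confined heteroplasmic
#' sites. With `plant = FALSE` the heteroplasmic site is not expressed in
#' any sample (null simulation).
#'
#' @param seed master seed.
#' @param frequency planted alternate-allele frequency in clone B.
#' @param reads_per_cell mitochondrial reads per sample.
#' @param plant express the planted site (`FALSE` for null runs).
#' @param min_cov,min_freq,max_background scan thresholds
#'   (see [heteroplasmy_scan()]).
#' @return list with `scan` (sites + untestable), `truth` (planted site),
#'   `detected` (logical: planted site found with the right clone),
#'   `est_freqs` (per clone-B cell frequency estimates at the site),
#'   `n_false` (detected sites not matching the planted one).
#' @export
heteroplasmy_experiment <- function(seed = 1L, frequency = 0.5,
                                    reads_per_cell = 120L, plant = TRUE,
                                    min_cov = 10, min_freq = 0.30,
                                    max_background = 0.05) {
  cfg <- sim_config(seed = seed, genome_length = 50000L, n_tr_loci = 0L,
                    germline_snv_rate = 0,
                    sv_counts = c(DEL = 0L, INS = 0L, DUP = 0L, INV = 0L),
                    somatic_snvs_per_clone = 0L,
                    heteroplasmy_frequency = frequency,
                    chimera_rates = list(inversion_per_amplicon = 0,
                                         duplication_per_amplicon = 0,
                                         intermolecular_per_droplet = 0))
  genome <- simulate_genome(cfg)
  if (!plant) genome$heteroplasmy$clone <- "none"
  roster <- cell_roster(cfg)
  samples <- c(roster$cell_id, "bulk")
  pileups <- lapply(setNames(samples, samples), function(cell) {
    frags <- fragment_and_encapsulate(genome, cell, cfg, contigs = MITO_CONTIG)
    amp <- amplify(frags, cfg)
    rs <- generate_reads(amp, genome, cfg, reads_per_cell)
    base_pileup(rs, MITO_CONTIG, cfg$mito_length)
  })
  clones <- split(roster$cell_id, roster$clone)
  scan <- heteroplasmy_scan(pileups, clones, genome$contigs[[MITO_CONTIG]],
                            min_cov = min_cov, min_freq = min_freq,
                            max_background = max_background)
  hp <- genome$heteroplasmy
  hit <- scan$sites$pos == hp$pos + 1L & scan$sites$alt == hp$alt &
    scan$sites$clone == "B"
  depth <- vapply(pileups[clones$B], function(m) sum(m[, hp$pos + 1L]),
                  numeric(1))
  alt_n <- vapply(pileups[clones$B], function(m) m[hp$alt, hp$pos + 1L],
                  numeric(1))
  list(scan = scan, truth = hp, detected = any(hit),
       est_freqs = ifelse(depth > 0, alt_n / depth, NA_real_),
       site_depths = depth,
       n_false = nrow(scan$sites) - sum(hit))
}
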