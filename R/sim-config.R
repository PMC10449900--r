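#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by every stage of
#' the synthetic-data generator. Defaults reflect the experimental system
#' the simulator emulates: a droplet generator producing ~50,000 picoliter
#' droplets, genomic fragments peaking near 9 kb, HiFi-grade reads
#' (per-base error ~1%, QV20), two clonal cell populations differing by a
#' small set of somatic SNVs, and one heteroplasmic mitochondrial site in
#' clone B.
#'
#' @param seed master seed; every stage derives its own child seed from it.
#' @param genome_length nuclear contig length in bases.
#' @param mito_length circular mitochondrial contig length in bases.
#' @param n_tr_loci number of tandem-repeat loci planted on the nuclear
#'   contig.
#' @param tr_unit_sizes repeat unit sizes (bases, 1-10) sampled uniformly
#'   per locus.
#' @param germline_snv_rate per-base probability of a germline SNV.
#' @param sv_counts named integer vector `c(DEL=, INS=, DUP=, INV=)` of
#'   germline structural variants to plant.
#' @param sv_length_models per-type length mixtures. Each entry is a list
#'   with `modes` (bp), `sds` (bp) and `weights`; defaults mix an ALU-like
#'   ~300 bp mode with a LINE-like ~6 kb mode for DEL/INS.
#' @param somatic_snvs_per_clone somatic SNVs planted per clone.
#' @param heteroplasmy_frequency alternate-allele frequency of the planted
#'   mitochondrial heteroplasmy in clone B cells (in (0,1)).
#' @param n_cells_per_clone cells simulated per clone.
#' @param fragment_length_mean,fragment_length_sd fragment length
#'   distribution (bases); lengths are truncated at 500 bp.
#' @param mito_copies mitochondrial genome copies fragmented per cell.
#' @param n_droplets droplets available per encapsulation.
#' @param gain_model amplification gain model: list with `mode`
#'   (`"dmda"` or `"mda"`), `mda_log_sigma` (lognormal sd of unclipped MDA
#'   gain), `dmda_cap_copies` (per-droplet total copy cap) and
#'   `mean_copies` (median per-fragment gain before capping).
#' @param chimera_rates list with `inversion_per_amplicon`,
#'   `duplication_per_amplicon` (per amplified copy) and
#'   `intermolecular_per_droplet` (expected events per occupied droplet).
#' @param read_error_rate per-base substitution error applied to reads.
#' @param error_indel_frac fraction of read errors emitted as 1 bp indels
#'   instead of substitutions (default 0: HiFi errors modeled as
#'   substitutions at the configured rate).
#' @param read_qv constant per-base quality value written to FASTQ.
#' @param dropout_rate per-record probability that a true variant is
#'   missing from an emitted single-cell call set (allelic dropout).
#' @param fp_snv_rate expected false SNV calls per germline SNV site
#'   (Poisson mean scale).
#' @param fp_sv_counts named numeric vector: expected false SV calls per
#'   cell by type. The default is inversion-heavy, mirroring chimera-driven
#'   false calls in droplet-MDA data.
#' @param precise_rate_true,precise_rate_false probability that a true
#'   (resp. false) SV record is flagged PRECISE.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 10e6,
                       mito_length = 16569L,
                       n_tr_loci = 50L,
                       tr_unit_sizes = 1:10,
                       germline_snv_rate = 1e-4,
                       sv_counts = c(DEL = 25L, INS = 25L, DUP = 5L, INV = 5L),
                       sv_length_models = NULL,
                       somatic_snvs_per_clone = 15L,
                       heteroplasmy_frequency = 0.5,
                       n_cells_per_clone = 3L,
                       fragment_length_mean = 9000,
                       fragment_length_sd = 2000,
                       mito_copies = 30L,
                       n_droplets = 50000L,
                       gain_model = list(mode = "dmda", mda_log_sigma = 2,
                                         dmda_cap_copies = 20L, mean_copies = 8),
                       chimera_rates = list(inversion_per_amplicon = 0.25,
                                            duplication_per_amplicon = 0.10,
                                            intermolecular_per_droplet = 0.05),
                       read_error_rate = 0.01,
                       error_indel_frac = 0,
                       read_qv = 20L,
                       dropout_rate = 0.5,
                       fp_snv_rate = 0.05,
                       fp_sv_counts = 50 * c(DEL = 0.046, INS = 0.090,
                                             DUP = 0.050, INV = 0.815),
                       precise_rate_true = 0.9,
                       precise_rate_false = 0.3) {
  if (is.null(sv_length_models)) {
    sv_length_models <- list(
      DEL = list(modes = c(300, 6000), sds = c(30, 300), weights = c(0.6, 0.4)),
      INS = list(modes = c(300, 6000), sds = c(30, 300), weights = c(0.8, 0.2)),
      DUP = list(modes = c(1000), sds = c(200), weights = 1),
      INV = list(modes = c(1000), sds = c(200), weights = 1)
    )
  }
  cfg <- list(
    seed = as.integer(seed),
    genome_length = as.integer(genome_length),
    mito_length = as.integer(mito_length),
    n_tr_loci = as.integer(n_tr_loci),
    tr_unit_sizes = as.integer(tr_unit_sizes),
    germline_snv_rate = germline_snv_rate,
    sv_counts = sv_counts,
    sv_length_models = sv_length_models,
    somatic_snvs_per_clone = as.integer(somatic_snvs_per_clone),
    heteroplasmy_frequency = heteroplasmy_frequency,
    n_cells_per_clone = as.integer(n_cells_per_clone),
    fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd,
    mito_copies = as.integer(mito_copies),
    n_droplets = as.integer(n_droplets),
    gain_model = gain_model,
    chimera_rates = chimera_rates,
    read_error_rate = read_error_rate,
    error_indel_frac = error_indel_frac,
    read_qv = as.integer(read_qv),
    dropout_rate = dropout_rate,
    fp_snv_rate = fp_snv_rate,
    fp_sv_counts = fp_sv_counts,
    precise_rate_true = precise_rate_true,
    precise_rate_false = precise_rate_false
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    stopifnot(genome_length > 0, mito_length > 0, n_tr_loci >= 0)
    stopifnot(all(tr_unit_sizes >= 1), all(tr_unit_sizes <= 10))
    stopifnot_prob(germline_snv_rate, "germline_snv_rate")
    stopifnot(all(sv_counts >= 0),
              all(c("DEL", "INS", "DUP", "INV") %in% names(sv_counts)))
    stopifnot(somatic_snvs_per_clone >= 0)
    if (heteroplasmy_frequency <= 0 || heteroplasmy_frequency >= 1) {
      stop("'heteroplasmy_frequency' must lie in (0, 1)", call. = FALSE)
    }
    stopifnot(n_cells_per_clone >= 1, fragment_length_mean > 0,
              fragment_length_sd >= 0, mito_copies >= 0, n_droplets >= 1)
    stopifnot(gain_model$mode %in% c("dmda", "mda"),
              gain_model$dmda_cap_copies >= 1, gain_model$mean_copies > 0,
              gain_model$mda_log_sigma >= 0)
    for (nm in c("inversion_per_amplicon", "duplication_per_amplicon",
                 "intermolecular_per_droplet")) {
      if (is.null(chimera_rates[[nm]]) || chimera_rates[[nm]] < 0) {
        stop(sprintf("chimera rate '%s' must be >= 0", nm), call. = FALSE)
      }
    }
    stopifnot_prob(read_error_rate, "read_error_rate")
    stopifnot_prob(error_indel_frac, "error_indel_frac")
    stopifnot_prob(dropout_rate, "dropout_rate")
    stopifnot(fp_snv_rate >= 0, all(fp_sv_counts >= 0))
    stopifnot_prob(precise_rate_true, "precise_rate_true")
    stopifnot_prob(precise_rate_false, "precise_rate_false")
  })
  cfg
}

#' Cell roster for a two-clone experiment
#'
#' @param cfg a `sim_config`.
#' @return data.frame with `cell_id` and `clone` (A/B), plus the bulk sample.
#' @export
cell_roster <- function(cfg) {
  n <- cfg$n_cells_per_clone
  data.frame(
    cell_id = c(paste0("A", seq_len(n)), paste0("B", seq_len(n))),
    clone = rep(c("A", "B"), each = n),
    stringsAsFactors = FALSE
  )
}

## Clone of a sample id; the unamplified bulk sample carries the germline
## genome only (clone label "bulk" matches no somatic or heteroplasmy set).
sample_clone <- function(cfg, cell_id) {
  if (identical(cell_id, "bulk")) return("bulk")
  roster <- cell_roster(cfg)
  if (!cell_id %in% roster$cell_id) {
    stop(sprintf("unknown cell_id '%s'", cell_id), call. = FALSE)
  }
  roster$clone[roster$cell_id == cell_id]
}
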