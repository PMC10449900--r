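# Shared fixtures: small configs and generators used across test files.

small_config <- function(seed = 1L, ...) {
  args <- list(
    seed = seed, genome_length = 2e5, n_tr_loci = 5L,
    germline_snv_rate = 2e-4,
    sv_counts = c(DEL = 4L, INS = 4L, DUP = 2L, INV = 2L),
    somatic_snvs_per_clone = 3L, mito_copies = 10L
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# config with nothing planted except SNV machinery off
bare_config <- function(seed = 1L, ...) {
  small_config(seed = seed, n_tr_loci = 0L, germline_snv_rate = 0,
               sv_counts = c(DEL = 0L, INS = 0L, DUP = 0L, INV = 0L),
               somatic_snvs_per_clone = 0L, ...)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  random_dna(n)
}

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Brute-force per-base pileup oracle over alignments (0-based half-open)
pileup_oracle <- function(aln, L) {
  depth <- integer(L)
  for (i in seq_len(nrow(aln))) {
    s <- aln$tstart[i] + 1L
    e <- min(aln$tend[i], L)
    if (e >= s) depth[s:e] <- depth[s:e] + 1L
  }
  depth
}

genotype_has_hap_test <- function(gt, hap) {
  if (hap == 1) substr(gt, 1, 1) == "1" else substr(gt, 3, 3) == "1"
}

# Minimal SV call-set row constructor
sv_row <- function(contig, pos, svtype, svlen, sample_id, precise = TRUE) {
  end <- if (svtype == "INS") pos else pos + abs(svlen) - 1L
  data.frame(contig = contig, pos = pos, ref = "N",
             alt = sprintf("<%s>", svtype), svtype = svtype,
             svlen = if (svtype == "DEL") -abs(svlen) else abs(svlen),
             end = end, precise = precise, sample_id = sample_id,
             stringsAsFactors = FALSE)
}

# Random SV call sets for merge tests
random_sv_set <- function(n, sample_id, L = 1e6, seed = 1) {
  set.seed(seed)
  types <- sample(c("DEL", "INS", "DUP", "INV"), n, replace = TRUE)
  pos <- sample.int(L, n)
  len <- sample(60:3000, n, replace = TRUE)
  do.call(rbind, lapply(seq_len(n), function(i)
    sv_row("chr1", pos[i], types[i], len[i], sample_id,
           precise = runif(1) < 0.8)))
}

# SNV call-set row(s)
snv_rows <- function(pos, ref = "A", alt = "T", contig = "chr1",
                     sample_id = "s") {
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
             svtype = "SNV", svlen = 0L, end = pos, precise = NA,
             sample_id = sample_id, stringsAsFactors = FALSE)
}
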