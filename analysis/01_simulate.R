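#!/usr/bin/env Rscript

# Simulate the full two-clone droplet-MDA experiment: diploid genome with
# planted germline SNVs/SVs, tandem-repeat loci and a circular
# mitochondrial contig; three cells per clone plus a bulk sample; dMDA
# amplification with chimera formation; HiFi-grade reads with truth
# alignments and per-sample call sets. Artifacts go to results/simulation/.

suppressPackageStartupMessages(library(dropmda))

outdir <- "results/simulation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  seed = 1L,
  genome_length = 2e6,            # desk-scale stand-in for a genome
  n_tr_loci = 40L,
  germline_snv_rate = 2e-4,
  sv_counts = c(DEL = 20L, INS = 20L, DUP = 5L, INV = 5L),
  somatic_snvs_per_clone = 15L,
  mito_copies = 20L
)

genome <- simulate_genome(cfg)
print(genome)
write_genome_fasta(genome, file.path(outdir, "reference.fasta"))
write_bed(genome$tr_loci, file.path(outdir, "tr_loci.bed"), name_col = "unit")

roster <- cell_roster(cfg)
for (cell in c(roster$cell_id, "bulk")) {
  frags <- fragment_and_encapsulate(genome, cell, cfg, contigs = "chr1")
  amp <- amplify(frags, cfg)
  rs <- generate_reads(amp, genome, cfg, n_reads = 400L)
  write_fastq(rs, file.path(outdir, paste0(cell, ".fastq")), qv = cfg$read_qv)
  write_paf(rs, genome, file.path(outdir, paste0(cell, ".paf")))
  message(sprintf("%s: %d reads (%.0f%% chimeric), %d fragments in %d droplets",
                  cell, nrow(rs$reads), 100 * mean(rs$reads$is_chimeric),
                  nrow(frags), length(unique(frags$droplet_id))))
}

calls <- emit_callsets(genome, cfg)
for (s in names(calls)) {
  write_vcf(calls[[s]], file.path(outdir, paste0(s, ".vcf")), s)
}
message(sprintf("call sets: bulk %d records; cells %s",
                nrow(calls$bulk),
                paste(vapply(roster$cell_id, function(s) nrow(calls[[s]]),
                             integer(1)), collapse = "/")))
message("simulation artifacts written to ", outdir)
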