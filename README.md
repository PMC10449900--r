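# dropmda

Simulation and analysis of single-cell whole-genome sequencing experiments
that combine **droplet multiple displacement amplification (dMDA)** with
**long-read (HiFi-grade) sequencing**.

Amplifying the genome of a single cell distorts it in characteristic ways:
bulk MDA over-amplifies a few fragments to extreme coverage, amplification
creates intramolecular chimeras (fold-back inversions and duplicated
segments inside a read), and allelic dropout removes variants from
single-cell call sets. Performing the MDA inside ~50,000 picoliter
droplets caps the per-molecule gain and confines chimera formation, which
changes what downstream analyses can and cannot trust. `dropmda`
implements the computational side of such an experiment:

* a **synthetic-data generator**: diploid genome with planted germline
  SNVs, SVs (ALU-like ~300 bp / LINE-like ~6 kb length modes),
  tandem-repeat loci and a circular mitochondrial contig; two clonal cell
  populations differing by somatic SNVs and one heteroplasmic
  mitochondrial site; fragmentation to ~9 kb, droplet encapsulation,
  reagent-capped dMDA gain versus heavy-tailed bulk-MDA gain; chimeric
  reads with base-accurate truth alignments; per-sample VCF call sets with
  configurable dropout and false-call rates;
* a **chimera screen**: k-mer seeded self-alignment of each read against
  itself and its reverse complement with Needleman–Wunsch verification —
  reads with a secondary self-hit at ≥ 90% identity are classified
  (INVERSION / DUPLICATION / COMPLEX), removed, and optionally split at
  the inferred junction;
* **coverage-uniformity metrics** from alignments: binned depth, fraction
  of reads in extreme-coverage (≥ 200×) regions, breadth, exact per-base
  coverage SD and Gini, seeded downsampling;
* **truth-set variant evaluation**: SNV precision/sensitivity against a
  bulk sample; multi-sample SV merging (single linkage at ≤ 200 bp start
  distance and ≥ 10% reciprocal overlap); clone-aware somatic SNV/SV
  filters (≥ 2 cells of one clone, absent from the other clone and bulk,
  PRECISE-only for SVs, repeat-masked and indel-free for SNVs);
* **mitochondrial heteroplasmy detection** from per-sample pileups
  (intermediate allele frequency in every cell of one clone, absent
  elsewhere);
* **tandem-repeat genotyping** from spanning reads: signed repeat-length
  difference vs the reference summed over alignment indels (robust to
  split insertion representations), allele clustering, a four-rule
  confidence filter (read support per allele, stray-allele limit, ≥ 90%
  allele support, ≤ 50× coverage), and allele-level concordance with bulk.

The methods vignette (`vignettes/droplet-mda-simulation.Rmd`) documents the
models, parameter choices and limitations.

## Worked example

The numbered scripts under `analysis/` run each analysis at desk scale and
write tables under `results/`. For example, the amplification contrast:

```sh
Rscript analysis/03_coverage_contrast.R
```

prints (seed 1, 20 paired replicates of 5000 reads on a 1 Mb genome):

```
extreme-coverage read fraction: MDA 53.8% vs dMDA 0.0% (MDA larger in 20/20)
coverage SD: MDA 132.6 vs dMDA 18.1 (ratio 7.34x, MDA larger in 20/20)
Gini: MDA 0.76 vs dMDA 0.21
```

i.e. under the heavy-tailed bulk-MDA gain model roughly half of all reads
pile into a few ≥ 200× bins while the droplet-capped reaction puts none
there, and the per-base coverage SD is several-fold higher — the
uniformity contrast that motivates dMDA. The chimera screen benchmark:

```sh
Rscript analysis/02_chimera_screen.R
```

```
truth vs verdict:
             called
truth         CLEAN DUPLICATION INVERSION
  DUPLICATION     0         152         0
  INVERSION       0           0       148
  NONE          700         0           0
sensitivity 1.000 | false removal 0.0000 | pass fraction 0.700
```

detects all 300 planted fold-back/duplication chimeras (arms ≥ 1 kb, 1%
read error) without removing any clean read. `04_variant_evaluation.R`
recovers SNV precision 0.860 and sensitivity 0.201 at the configured
operating point (dropout 0.8, false-call rate set for expected precision
0.86), finds ~2/3 of planted somatic SNVs at dropout 0.5 (the closed-form
per-site detection probability is 0.5), and shows inversion precision
collapsing (0.16 vs 0.92 for deletions) under inversion-heavy false
calls. `05_tandem_repeats.R` and `06_heteroplasmy.R` report per-cell TR
allele concordance (~97% of bulk-confident alleles) and detection of the
planted clone-B heteroplasmy at per-cell frequencies 0.41–0.61 with zero
false sites in 20 null simulations.

The same machinery is callable directly:

```r
library(dropmda)
cfg <- sim_config(seed = 1, genome_length = 2e6)
genome <- simulate_genome(cfg)
frags  <- fragment_and_encapsulate(genome, "A1", cfg)
reads  <- generate_reads(amplify(frags, cfg), genome, cfg, n_reads = 500)
screen <- filter_reads(reads$reads)
screen$stats$pass_fraction
```

A YAML-configured end-to-end run (simulate → screen → coverage → variant
evaluation → heteroplasmy → tandem repeats) is available as
`run_pipeline()`; identical configurations produce byte-identical
`summary.json` outputs.

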