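---
title: "Simulating and analysing droplet-MDA single-cell long-read experiments"
author: "dropmda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing droplet-MDA single-cell long-read experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropmda)
```

# The problem

Whole-genome sequencing of a single cell requires amplifying a few
picograms of DNA by many orders of magnitude. Multiple displacement
amplification (MDA) with a strand-displacing polymerase produces the long
fragments that long-read sequencing needs, but in a bulk reaction a few
molecules capture most of the reagents: coverage becomes extremely uneven,
and the polymerase's template-switching creates *intramolecular chimeras*
— reads that carry a reverse-complemented (fold-back) or duplicated copy
of their own sequence. Performing the MDA inside ~50,000 picoliter
droplets (dMDA) caps the gain per molecule, flattening coverage, and
confines inter-molecular chimera formation to the rare droplets holding
more than one fragment.

Downstream, single-cell call sets suffer allelic dropout (an allele lost
during amplification is simply never called) and chimera-driven false
structural variants, so every analysis is phrased against a *bulk* sample
from the same individual: variants seen in both a cell and bulk are
treated as true; candidate somatic variants must recur in cells of one
clonal population while being absent from the other clone and from bulk.

`dropmda` implements this analysis stack — and, because the motivating
raw data are access-controlled, a synthetic-data generator that reproduces
the statistical structure those analyses rely on, so every stage is
testable end to end without any download.

# The simulator

## Genome and variation

`simulate_genome()` builds one nuclear contig (random uniform base
composition) plus a 16,569 bp circular mitochondrial contig, then plants,
mutually non-overlapping:

* **tandem-repeat loci** (`n_tr_loci`, unit sizes 1–10 bp, 10–40 reference
  copies) whose reference sequence is overwritten with the unit array;
  heterozygous or homozygous length differences of 1–5 units are assigned
  per haplotype. Loci are kept ≥ 200 bp away from any SV breakpoint so
  repeat genotypes and SV calls never interact;
* **structural variants** with per-type length mixtures: deletions and
  insertions mix an ALU-like mode (Normal(300, 30) bp) with a LINE-like
  mode (Normal(6000, 300) bp), reflecting the two length peaks that
  dominate real germline indel SV spectra; duplications and inversions use
  a single ~1 kb mode;
* **germline SNVs** at `germline_snv_rate` per base, each heterozygous on
  a random haplotype or homozygous;
* **somatic SNVs** per clone (disjoint between clones and from germline
  sites), defining two clonal cell populations A and B;
* one **heteroplasmic mitochondrial substitution** expressed only in
  clone B at `heteroplasmy_frequency` (default 0.5, within the 0.41–0.67
  range the analysis is designed to detect).

Coordinates are 0-based half-open everywhere internally; 1-based
coordinates appear only in emitted VCF/PAF. Haplotype sequences are
materialised with a *block map* from haplotype to reference coordinates
(match, inserted, duplicated and inverted blocks), which is what turns a
read interval into truth alignments — including '-' strand segments inside
inversions and repeated intervals inside duplications.

## Cells, droplets, amplification

`fragment_and_encapsulate()` cuts both haplotypes into fragments tiling
each haplotype exactly, with lengths Normal(9000, 2000) bp truncated at
500 bp — the ~9 kb fragment peak of the emulated protocol. Each fragment
is assigned a uniform-random droplet among `n_droplets` (default 50,000);
bulk-MDA mode leaves `droplet_id` empty. Mitochondrial copies
(`mito_copies` per cell) are cut from a random origin offset; fragments
may wrap the circle and their reads split into two truth segments at the
origin.

`amplify()` draws per-fragment copy numbers:

* **dMDA**: lognormal(median 8, sdlog 0.5), then clipped so each droplet's
  total stays ≤ `dmda_cap_copies` (default 20) — reagent-limited gain;
* **MDA**: lognormal with `sdlog = mda_log_sigma` (default 2), unclipped —
  a heavy-tailed gain in which a handful of fragments dominate.

No quantitative gain model is published for either reaction; these are the
simplest two-parameter models that reproduce the *directional* contrast
the analyses measure (extreme-coverage read fraction, coverage SD, Gini),
and both are exposed in the configuration. The contrast itself is checked
as a paired, per-replicate sign property, never as an absolute level.

Chimera events are drawn per amplified copy: fold-back inversions
(`inversion_per_amplicon`), tandem duplications
(`duplication_per_amplicon`), and per droplet inter-molecular junctions —
possible only between co-encapsulated fragments; an event landing in a
single-fragment droplet is physically impossible and is skipped and
counted.

## Reads and call sets

`generate_reads()` samples reads from amplified copies with probability
proportional to copy number × fragment length; each read spans its
fragment. A read drawn from a chimeric copy is restructured: a fold-back
joins a prefix to the reverse complement of its own tail at a uniform
internal breakpoint; a duplication repeats an internal 200–2000 bp window;
an inter-molecular junction concatenates halves of two co-encapsulated
fragments. Truth segments record the reference provenance of every read
base. HiFi-grade errors are substitutions at `read_error_rate`
(default 0.01, i.e. QV20) applied over the pooled read bases; 1 bp indel
errors are available via `error_indel_frac` but default to 0 so that
truth accounting stays alignment-free. FASTQ qualities are constant at the
configured QV — per-base quality evolution is out of scope. The
heteroplasmic allele is drawn per read covering the site (a fragment-level
draw would be marginally more realistic but would over-disperse per-cell
frequency estimates relative to the binomial sampling model the detector
is scored against).

`emit_callsets()` skips variant calling entirely (the callers the
analyses consume are external tools): the bulk call set is the germline
truth; each cell's call set is germline ∪ clone-somatic thinned by
`dropout_rate` per record, plus false calls — Poisson false SNVs at
`fp_snv_rate` per germline site and per-type false SVs whose default
composition is inversion-heavy (81.5% INV / 9% INS / 5% DUP / 4.6% DEL),
the signature of chimera-driven artifact calls. SV records carry
PRECISE/IMPRECISE flags (true SVs PRECISE with probability 0.9, false
ones 0.3). With dropout `d` and false-call rate `f`, expected precision is
`(1-d)/((1-d)+f)` and expected sensitivity `1-d` — the closed forms the
recovery experiments are scored against.

# The chimera screen

The screen re-implements "align each read against itself and remove reads
with a secondary hit above 90% identity" as a k-mer seeded self-comparison:

1. **Seeding** — all k-mer matches (default k = 15) of the read against
   itself (off the main diagonal) and against its reverse complement.
   K-mers occurring more than 10 times are dropped as low-complexity.
2. **Chaining** — seeds sharing a diagonal within a 50 bp band are chained;
   chains need ≥ 3 seeds and ≥ 50 bp span. A fold-back is a *contiguous
   palindrome*, so in read-vs-reverse-complement space each chain coexists
   with its own symmetric twin on the same diagonal; seeds are therefore
   kept only when the mapped-back partner lies downstream of the seed,
   which separates the hit from its mirror image.
3. **Verification** — the chained interval pair is aligned globally
   (Needleman–Wunsch, match 1 / mismatch −1 / gap open 2, extend 1);
   identity = matches / alignment columns, so gaps count against identity.
   Pairs longer than 800 bp are verified on a central 800 bp slice (the
   identity of a uniform-error pair is homogeneous along its length);
   the reported hit length stays the full chained span.

A reverse-complement hit classifies the read as INVERSION, a forward
off-diagonal hit as DUPLICATION, both as COMPLEX; the junction is the
midpoint between the paired intervals, which for the near-contiguous
intervals of a fold-back lands at the turn point. `filter_reads()` removes
all non-CLEAN reads (the removal-based policy of the emulated pipeline);
`split_read()` is additionally provided to cut a chimeric read at its
junctions with a 50 bp trim, since chimeric reads can in principle be
salvaged as non-chimeric parts. Whether the 90% identity applies per hit
or per read is not specified in the emulated method; it is applied per
hit, the stricter reading.

Two caveats are inherent and intentional. Reads crossing a genuine tandem
repeat array longer than the minimum hit length produce *bona fide*
forward self-hits and are removed — the screen is stringent by design,
trading repeat-bearing reads for chimera purity (the screen's benchmark
therefore uses a repeat-free genome so that "false removal" is
well-defined). And hits shorter than `min_hit_len` (100 bp) are ignored
as noise at chimera scale.

The screen's oracle in the test-suite is command-line BLAST (`blastn`
against self) — the method the screen re-implements — plus direct
dynamic-programming alignments on constructed cases; agreement is required
on ≥ 99% of 500 planted cases with junctions within ± k bases.

# Coverage metrics

All depth statistics are computed exactly from run-length encoded
pileups (`IRanges::coverage`), never by sampling positions: binned mean
depth (bins of 5 kb by convention; the final partial bin uses its true
length), breadth (union length of aligned intervals / genome length),
population SD of per-base depth, and the Gini coefficient of depth.
The "extreme-coverage read fraction" counts a read once if any of its
alignments overlaps a bin at or above the threshold (membership, not
apportionment). The threshold is ≥ 200× by default and configurable,
since the emulated analyses state it both as ">200×" and "≥200×";
`>` versus `≥` is immaterial for non-integer bin means. Depth counts
aligned reference bases, matching pileup semantics of standard QC tools.
`downsample()` is a seeded uniform sample without replacement.

# Variant evaluation

SNV matching is site/allele identity (contig, position, ref, alt),
genotype-free; indels sharing a trailing base are flagged, warned about
and left-aligned before comparison. Precision is TP/(TP+FP) against the
cell's calls; sensitivity uses *all* bulk calls as denominator — no
callable-region restriction, since dropout, not callability, drives
single-cell sensitivity.

`merge_svs()` single-links SV records of the same type whose start
positions lie within 200 bp and whose intervals share ≥ 10% reciprocal
overlap; insertions have no interval, so a length ratio ≥ 10% substitutes.
Clusters are found as connected components over an edge list built from a
position-windowed candidate scan; the test-suite checks equality with an
all-pairs transitive-closure oracle and order-invariance. Each cluster
reports per-sample presence flags; a cluster is PRECISE if any member is.

The somatic filters are pure set logic, checked against exhaustive
predicate evaluation over all presence/absence combinations:

* **SNVs** — called in ≥ 2 cells of one clone; absent from bulk; absent
  from every cell of the other clone; not an indel; outside the repeat
  mask (any overlap of the position excludes). "Absent" means *no call*:
  a dropout-induced non-call counts as absence, so dropout can both hide
  true somatic variants (detection probability
  `1 - q^n - n p q^(n-1)` per site with `p = 1 - d`) and, in principle,
  let a germline variant masquerade as somatic if it drops out of every
  cell of one clone — the documented behaviour of this filter design.
* **SVs** — PRECISE clusters present in ≥ 2 cells of one clone, absent
  from the other clone's cells and from bulk.

`heteroplasmy_scan()` reports mitochondrial sites where every cell of one
clone has alternate-allele frequency ≥ 0.30 while every other sample
(including bulk) stays < 0.05, with per-sample frequencies attached.
Sites with any required sample below 10× are *untestable*, not absent.
The 0.30/0.05/10× defaults sit well below the 0.41 lower edge of the
frequencies the detector must catch while staying far above the ~0.003
per-allele error background of QV20 reads.

# Tandem-repeat genotyping

A read's repeat-length difference at a locus is the sum of insertion
lengths minus deletion lengths its alignment places within the locus
± 100 bp flank, taken from CIGAR operations. Summing over the window makes
the measure invariant to how an aligner splits a long expansion (e.g.
662 bp reported as separate 109 bp and 553 bp insertions); the flank
absorbs indels shifted to the array edges. Only reads spanning the flanked
window count; others are non-informative.

Per-locus differences are clustered by 1-D single linkage with tolerance
`max(2, unit)` bp. The largest cluster is always an allele; the
second-largest is promoted to a heterozygous second allele only with ≥ 5
supporting reads (the same floor as the heterozygous read rule below),
otherwise it remains "other-allele" support; allele value is the cluster
median. Loci with more than two clusters of > 2 reads are UNGENOTYPED —
more than two repeat lengths cannot be resolved into a diploid genotype.

The four-rule confidence filter then requires: (i) ≥ 5 reads per allele if
heterozygous, ≥ 10 if homozygous; (ii) no non-allele cluster with > 2
reads; (iii) ≥ 90% of spanning reads supporting the called allele(s);
(iv) total coverage ≤ 50× (higher coverage at a single locus indicates
mapping artifacts). FAIL states carry the first violated rule. Bulk
genotypes passing all four rules form the confident locus set against
which cells are scored; concordance is counted *per allele*, a cell
recovering one of two bulk alleles contributing one correct and one
missing allele. "Same repeat size" is undefined in the emulated analysis;
it is implemented as equality within the locus's clustering tolerance
(configurable), since that is the resolution at which the alleles were
called in the first place.

# Pipeline and reproducibility

`validate_config()` parses a YAML configuration (defaults for everything;
unknown keys rejected by name; the `sim` block feeds `sim_config()`
directly) and `run_pipeline()` executes simulate → chimera screen →
coverage → variant evaluation → somatic filters → heteroplasmy → tandem
repeats, writing FASTA/FASTQ/PAF/VCF/BED/TSV artifacts and a JSON summary.
Determinism is structural: one master seed; every stage, cell and
replicate derives a child seed from it (`child_seed()`), so identical
configurations give byte-identical outputs and any stage can be re-run in
isolation. All randomness is drawn under temporarily-swapped RNG state, so
package functions never disturb the caller's RNG.

## Problem sizes

The analyses and checks run at desk scale, chosen so the full suite
completes in minutes while every statistical check retains power: 10 Mb
genomes for the chimera benchmark (1000 reads, 30% planted chimeras) and
the SNV recovery experiment (10,000 germline sites, dropout 0.8); 1 Mb ×
5000 reads × 20 paired replicates for the amplification contrast; 60 TR
loci at 25× spanning coverage; full-length (16.5 kb) mitochondrial contig
at ~30–65× per cell for heteroplasmy, with 100 null simulations for the
false-site check.

## What passing does and does not show

The generator reproduces the *structure* the analyses assume —
dropout-thinned call sets, inversion-heavy false SVs, capped versus
heavy-tailed gain, fold-back/duplication chimeras, clone-confined
heteroplasmy — not the full texture of real data: base composition is
uniform (no GC bias, no mappability structure), error rates are constant
(no homopolymer-length dependence), fragment lengths are Normal, droplet
loading is uniform, and amplification gain is drawn i.i.d. per fragment.
Passing results therefore validate the *methods* (their logic, their
statistical behaviour at the configured operating points, their
invariances) and the directional amplification contrasts; they do not
certify absolute performance numbers on real single-cell libraries.
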