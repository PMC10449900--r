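## Tandem-repeat genotyping from spanning long reads.
##
## Each locus is genotyped from the signed repeat-length difference of
## every spanning read versus the reference: the sum of insertion lengths
## minus deletion lengths that the read's alignment places within the locus
## plus/minus a flank window. Summing over all edit operations in the
## window makes the measure invariant to how the aligner distributes a long
## expansion across several insertion operations (e.g. a 662 bp expansion
## represented as separate 109 bp and 553 bp insertions). Length
## differences are clustered (1-D single linkage) into one or two alleles;
## a four-rule confidence filter then accepts or rejects the genotype, and
## single-cell genotypes are scored against bulk at allele level.

#' Extract indel operations from a CIGAR alignment
#'
#' @param cigar CIGAR string (reference-aligned read).
#' @param ref_start 0-based reference start of the alignment.
#' @return data.frame with `op` (`"I"`/`"D"`), `len`, and `ref_pos`
#'   (0-based reference position of the operation).
#' @export
cigar_indel_ops <- function(cigar, ref_start) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  consumes_ref <- ops %in% c("M", "D", "N", "=", "X")
  ref_pos <- ref_start + cumsum(c(0L, lens[-length(lens)] * consumes_ref[-length(lens)]))
  keep <- ops %in% c("I", "D")
  data.frame(op = ops[keep], len = lens[keep], ref_pos = ref_pos[keep],
             stringsAsFactors = FALSE)
}

#' Repeat-length difference of one read at one locus
#'
#' @param aln one alignment: list or one-row data.frame with `ref_start`,
#'   `ref_end` (0-based half-open span on the reference) and either a
#'   `cigar` string or an `ops` data.frame as from [cigar_indel_ops()].
#' @param locus one row of a TR locus table (`start`, `end`, 0-based
#'   half-open).
#' @param flank window extension in bases on each side of the locus.
#' @return signed length difference in bases, or `NA` if the alignment
#'   does not fully span `[start - flank, end + flank)`.
#' @export
read_repeat_length <- function(aln, locus, flank = 100L) {
  ws <- locus$start - flank
  we <- locus$end + flank
  if (aln$ref_start > ws || aln$ref_end < we) return(NA_integer_)
  ops <- if (!is.null(aln$ops)) aln$ops else cigar_indel_ops(aln$cigar, aln$ref_start)
  if (!nrow(ops)) return(0L)
  inwin <- ops$ref_pos >= ws & ops$ref_pos < we
  sum(ifelse(ops$op[inwin] == "I", ops$len[inwin], -ops$len[inwin]))
}

## 1-D single-linkage clustering: split sorted values where the gap
## exceeds `tol`. Returns a list of integer index vectors (into `x`).
cluster_1d <- function(x, tol) {
  o <- order(x)
  gaps <- diff(x[o])
  grp <- cumsum(c(1L, gaps > tol))
  split(o, grp)
}

#' Genotype one TR locus from per-read length differences
#'
#' Clusters the length differences with tolerance `max(2, unit_size)`
#' bases; the two largest clusters become candidate alleles (merged to one
#' homozygous allele if their medians agree within tolerance); remaining
#' reads count as other-allele support. A locus where more than two
#' clusters have substantial (>2 reads) support is reported UNGENOTYPED.
#'
#' @param diffs integer vector of per-read length differences (bases),
#'   non-spanning reads already excluded.
#' @param unit_size repeat unit size in bases.
#' @param tol clustering tolerance (default `max(2, unit_size)`).
#' @param min_second_allele minimum cluster size for promotion of the
#'   second-largest cluster to a heterozygous allele (smaller clusters
#'   count as other-allele support; default 5, the heterozygous
#'   minimum-read rule threshold).
#' @return object of class `tr_genotype`: list with `alleles` (sorted
#'   numeric, length 1 or 2), `allele_counts`, `other_count`, `coverage`,
#'   `status` (`"PRE"` or `"UNGENOTYPED"`), `diffs`, `unit_size`.
#' @export
genotype_locus <- function(diffs, unit_size, tol = max(2, unit_size),
                           min_second_allele = 5L) {
  stopifnot(length(diffs) >= 1L)
  cl <- cluster_1d(diffs, tol)
  sizes <- unname(lengths(cl))
  meds <- unname(vapply(cl, function(i) median(diffs[i]), numeric(1)))
  ## deterministic order: by size desc, then median asc
  o <- order(-sizes, meds)
  cl <- cl[o]; sizes <- sizes[o]; meds <- meds[o]
  status <- "PRE"
  if (sum(sizes > 2L) > 2L) status <- "UNGENOTYPED"
  if (length(cl) == 1L || sizes[2L] < min_second_allele) {
    alleles <- meds[1L]; counts <- sizes[1L]
  } else if (abs(meds[1L] - meds[2L]) <= tol) {
    alleles <- median(diffs[c(cl[[1L]], cl[[2L]])])
    counts <- sizes[1L] + sizes[2L]
  } else {
    ord <- order(meds[1:2])
    alleles <- meds[1:2][ord]
    counts <- sizes[1:2][ord]
  }
  structure(list(alleles = alleles, allele_counts = as.integer(counts),
                 other_count = length(diffs) - sum(counts),
                 coverage = length(diffs), status = status,
                 diffs = diffs, unit_size = unit_size),
            class = "tr_genotype")
}

#' Four-rule confidence filter for a TR genotype
#'
#' PASS requires: (i) at least 5 reads per allele for a heterozygous call
#' and at least 10 for a homozygous call; (ii) no non-allele cluster
#' supported by more than 2 reads; (iii) at least 90% of spanning reads
#' supporting the called allele(s); (iv) total coverage at most 50x.
#' FAIL is annotated with the first violated rule; UNGENOTYPED loci stay
#' UNGENOTYPED.
#'
#' @param gt a `tr_genotype`.
#' @param min_het_reads,min_hom_reads,max_other_reads,min_allele_frac,max_cov
#'   the rule thresholds.
#' @return status string: `"PASS"`, `"FAIL(i)"` ... `"FAIL(iv)"`, or
#'   `"UNGENOTYPED"`.
#' @export
confidence_filter <- function(gt, min_het_reads = 5L, min_hom_reads = 10L,
                              max_other_reads = 2L, min_allele_frac = 0.90,
                              max_cov = 50L) {
  stopifnot(inherits(gt, "tr_genotype"))
  if (gt$status == "UNGENOTYPED") return("UNGENOTYPED")
  het <- length(gt$alleles) == 2L
  if (het) {
    if (any(gt$allele_counts < min_het_reads)) return("FAIL(i)")
  } else {
    if (gt$allele_counts[1L] < min_hom_reads) return("FAIL(i)")
  }
  ## rule (ii): any non-allele cluster with more than max_other_reads reads
  tol <- max(2, gt$unit_size)
  other_idx <- setdiff(seq_along(gt$diffs), unlist(lapply(gt$alleles, function(a)
    which(abs(gt$diffs - a) <= tol))))
  if (length(other_idx)) {
    ocl <- cluster_1d(gt$diffs[other_idx], tol)
    if (any(lengths(ocl) > max_other_reads)) return("FAIL(ii)")
  }
  if (sum(gt$allele_counts) / gt$coverage < min_allele_frac) return("FAIL(iii)")
  if (gt$coverage > max_cov) return("FAIL(iv)")
  "PASS"
}

#' Genotype many loci for one sample
#'
#' @param aln_by_locus list (one entry per locus) of alignment tables;
#'   each element a data.frame with `ref_start`, `ref_end` and `cigar`
#'   (or a list-column `ops`).
#' @param loci TR locus table (`start`, `end`, `unit_size`, `locus_id`).
#' @param flank spanning-window flank (bases).
#' @return data.frame: `locus_id`, `allele1`, `allele2` (NA if
#'   homozygous), `count1`, `count2`, `other_count`, `coverage`, `status`.
#' @export
genotype_sample <- function(aln_by_locus, loci, flank = 100L) {
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    locus <- loci[i, ]
    alns <- aln_by_locus[[i]]
    diffs <- if (is.null(alns) || !nrow(alns)) integer(0) else
      vapply(seq_len(nrow(alns)), function(j)
        as.integer(read_repeat_length(alns[j, ], locus, flank)), integer(1))
    diffs <- diffs[!is.na(diffs)]
    if (!length(diffs)) {
      return(data.frame(locus_id = locus$locus_id, allele1 = NA_real_,
                        allele2 = NA_real_, count1 = NA_integer_,
                        count2 = NA_integer_, other_count = NA_integer_,
                        coverage = 0L, status = "UNGENOTYPED",
                        stringsAsFactors = FALSE))
    }
    gt <- genotype_locus(diffs, locus$unit_size)
    status <- confidence_filter(gt)
    data.frame(locus_id = locus$locus_id,
               allele1 = gt$alleles[1L],
               allele2 = if (length(gt$alleles) == 2L) gt$alleles[2L] else NA_real_,
               count1 = gt$allele_counts[1L],
               count2 = if (length(gt$alleles) == 2L) gt$allele_counts[2L] else NA_integer_,
               other_count = gt$other_count, coverage = gt$coverage,
               status = status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Allele-level concordance of single-cell TR genotypes with bulk
#'
#' Bulk genotypes are first restricted to PASS loci (the confident bulk
#' pre-filter). A cell allele is correct when it matches a bulk allele
#' length within `tol`; a cell recovering one of two bulk alleles
#' contributes one correct allele and one missing allele.
#'
#' @param cell_gt,bulk_gt genotype tables from [genotype_sample()].
#' @param loci TR locus table (for per-locus tolerance).
#' @param tol matching tolerance in bases; `NULL` (default) uses each
#'   locus's clustering tolerance `max(2, unit_size)`, so agreement means
#'   equality up to the resolution at which alleles were called.
#' @return list with counts `correct`, `discordant`, `missing`,
#'   `ungenotyped` (allele-level) and `n_bulk_loci`.
#' @export
tr_concordance <- function(cell_gt, bulk_gt, loci, tol = NULL) {
  bulk <- bulk_gt[bulk_gt$status == "PASS", , drop = FALSE]
  locus_tol <- setNames(pmax(2, loci$unit_size), loci$locus_id)
  correct <- discordant <- missing <- ungeno <- 0L
  for (i in seq_len(nrow(bulk))) {
    b <- bulk[i, ]
    tol_i <- if (is.null(tol)) unname(locus_tol[b$locus_id]) else tol
    if (is.na(tol_i)) tol_i <- 2
    b_alleles <- c(b$allele1, b$allele2)
    b_alleles <- b_alleles[!is.na(b_alleles)]
    crow <- cell_gt[cell_gt$locus_id == b$locus_id, , drop = FALSE]
    if (!nrow(crow) || crow$status[1L] %in% c("UNGENOTYPED") ||
        startsWith(crow$status[1L], "FAIL")) {
      ungeno <- ungeno + length(b_alleles)
      next
    }
    c_alleles <- c(crow$allele1[1L], crow$allele2[1L])
    c_alleles <- c_alleles[!is.na(c_alleles)]
    remaining <- b_alleles
    for (a in c_alleles) {
      hit <- which(abs(remaining - a) <= tol_i)
      if (length(hit)) {
        correct <- correct + 1L
        remaining <- remaining[-hit[1L]]
      } else {
        discordant <- discordant + 1L
      }
    }
    missing <- missing + length(remaining)
  }
  list(correct = correct, discordant = discordant, missing = missing,
       ungenotyped = ungeno, n_bulk_loci = nrow(bulk))
}

#' Simulate spanning-read alignments for TR loci
#'
#' Generates, for each locus and sample, spanning-read alignment records
#' whose CIGAR strings carry the allele's length difference as insertion
#' or deletion operations inside the locus. With probability `split_prob`
#' an insertion is split into two separate insertion operations (as
#' aligners do for long expansions). Alleles are sampled from the locus's
#' per-haplotype truth; `allele_dropout` drops one haplotype entirely
#' (amplification dropout), and per-read length noise is off by default
#' (HiFi-grade).
#'
#' @param loci TR locus table from [simulate_genome()] (`tr_loci`).
#' @param coverage mean spanning-read count per locus.
#' @param allele_dropout probability that one haplotype is lost at a locus.
#' @param split_prob probability a long insertion is emitted as two split
#'   insertion operations.
#' @param flank flank used to position alignments around the locus.
#' @param seed RNG seed.
#' @return list (one per locus) of alignment data.frames with `ref_start`,
#'   `ref_end`, `cigar`, `hap`.
#' @export
simulate_tr_reads <- function(loci, coverage = 20, allele_dropout = 0,
                              split_prob = 0.3, flank = 100L, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(nrow(loci)), function(i) {
      locus <- loci[i, ]
      n <- rpois(1L, coverage)
      if (n == 0L) return(data.frame(ref_start = integer(), ref_end = integer(),
                                     cigar = character(), hap = integer(),
                                     stringsAsFactors = FALSE))
      hap_diffs <- c(locus$hap1_diff, locus$hap2_diff)
      haps_avail <- 1:2
      if (runif(1) < allele_dropout) haps_avail <- sample(1:2, 1L)
      hap <- sample(haps_avail, n, replace = TRUE)
      d <- hap_diffs[hap]
      ref_start <- locus$start - flank - sample(200:800, n, replace = TRUE)
      ref_end <- locus$end + flank + sample(200:800, n, replace = TRUE)
      ref_start <- pmax(0L, ref_start)
      cigar <- vapply(seq_len(n), function(j) {
        lead <- locus$start - ref_start[j] + 5L   # op lands inside the locus
        span <- ref_end[j] - ref_start[j]
        dj <- d[j]
        if (dj == 0L) {
          sprintf("%dM", span)
        } else if (dj > 0L) {
          if (dj > 20L && runif(1) < split_prob) {
            p1 <- sample.int(dj - 1L, 1L)
            sprintf("%dM%dI%dM%dI%dM", lead, p1, 10L, dj - p1,
                    span - lead - 10L)
          } else {
            sprintf("%dM%dI%dM", lead, dj, span - lead)
          }
        } else {
          sprintf("%dM%dD%dM", lead, -dj, span - lead + dj)
        }
      }, character(1))
      data.frame(ref_start = ref_start, ref_end = ref_end, cigar = cigar,
                 hap = hap, stringsAsFactors = FALSE)
    })
  })
}
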