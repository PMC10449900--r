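# Tandem-repeat genotyping: length-difference measurement from alignment
# edit operations, allele clustering, the four-rule confidence filter, and
# single-cell/bulk concordance.

locus <- data.frame(locus_id = "TR0001", contig = "chr1", start = 5000L,
                    end = 5100L, unit = "AT", unit_size = 2L,
                    ref_copies = 50L, hap1_diff = 0L, hap2_diff = 0L,
                    stringsAsFactors = FALSE)

aln_row <- function(cigar, ref_start = 4500L, ref_end = 5600L) {
  data.frame(ref_start = ref_start, ref_end = ref_end, cigar = cigar,
             stringsAsFactors = FALSE)
}

test_that("repeat length difference sums indel operations in the window", {
  expect_equal(read_repeat_length(aln_row("1100M"), locus), 0L)
  expect_equal(read_repeat_length(aln_row("550M30I550M"), locus), 30L)
  expect_equal(read_repeat_length(aln_row("520M40D540M"), locus), -40L)
  ## an expansion split by the aligner into two insertions still sums
  expect_equal(read_repeat_length(aln_row("510M109I20M553I570M"), locus),
               662L)
  ## indels outside the locus +/- flank window are ignored
  expect_equal(read_repeat_length(aln_row("100M25I1000M"), locus), 0L)
  ## non-spanning alignments are excluded, not an error
  expect_true(is.na(read_repeat_length(aln_row("300M", 4950L, 5050L), locus)))
})

test_that("length measurement is invariant to how indels are split", {
  set.seed(301)
  for (i in 1:20) {
    total <- sample(40:600, 1)
    p1 <- sample.int(total - 1, 1)
    gap <- sample(5:60, 1)
    whole <- aln_row(sprintf("550M%dI550M", total))
    split2 <- aln_row(sprintf("540M%dI%dM%dI%d0M", p1, gap, total - p1, 55))
    expect_equal(read_repeat_length(whole, locus),
                 read_repeat_length(split2, locus))
  }
})

test_that("allele clustering is exact on simple cases", {
  hom <- genotype_locus(rep(0L, 10), unit_size = 2L)
  expect_equal(hom$alleles, 0)
  expect_equal(hom$allele_counts, 10L)
  expect_equal(hom$other_count, 0L)
  het <- genotype_locus(c(rep(0L, 6), rep(30L, 5)), unit_size = 2L)
  expect_equal(het$alleles, c(0, 30))
  expect_equal(het$allele_counts, c(6L, 5L))
})

test_that("clustering matches a brute-force single-linkage oracle", {
  sl_oracle <- function(x, tol) {
    ## transitive closure over |xi - xj| <= tol
    n <- length(x)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (comp[i] != comp[j] && abs(x[i] - x[j]) <= tol) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    comp
  }
  set.seed(302)
  for (i in 1:200) {
    unit <- sample(1:10, 1)
    tol <- max(2, unit)
    x <- sample(-50:700, sample(3:25, 1), replace = TRUE)
    gt <- genotype_locus(x, unit)
    oracle <- sl_oracle(x, tol)
    ## same number of clusters and same membership partition
    impl <- local({
      o <- order(x)
      grp <- cumsum(c(1L, diff(x[o]) > tol))
      out <- integer(length(x)); out[o] <- grp; out
    })
    expect_equal(length(unique(impl)), length(unique(oracle)))
    expect_true(all(tapply(oracle, impl, function(v) length(unique(v))) == 1))
  }
})

test_that("confidence filter matches direct rule evaluation on boundary fixtures", {
  gt <- function(a_counts, other, unit = 2L) {
    ## build a diffs vector realizing the requested cluster structure
    vals <- seq(0, by = 100, length.out = length(a_counts) + length(other))
    diffs <- integer(0)
    for (i in seq_along(a_counts)) diffs <- c(diffs, rep(vals[i], a_counts[i]))
    for (j in seq_along(other)) {
      diffs <- c(diffs, rep(vals[length(a_counts) + j], other[j]))
    }
    genotype_locus(diffs, unit)
  }
  fixtures <- list(
    list(g = gt(c(5, 5), integer(0)), expect = "PASS"),          # het at rule-i floor
    list(g = gt(c(5, 4), integer(0)), expect = "FAIL(i)"),       # het one read short
    list(g = gt(c(10), integer(0)), expect = "PASS"),            # hom at floor
    list(g = gt(c(9), integer(0)), expect = "FAIL(i)"),          # hom one short
    list(g = gt(c(40), c(3)), expect = "FAIL(ii)"),              # 3-read stray cluster
    list(g = gt(c(40), c(2)), expect = "PASS"),                  # 2-read stray is allowed
    list(g = gt(c(12, 12), c(2, 1)), expect = "FAIL(iii)"),      # 24/27 < 90%
    list(g = gt(c(20, 18), c(2)), expect = "PASS"),              # 38/40 = 95%
    list(g = gt(c(30, 25), integer(0)), expect = "FAIL(iv)"),    # coverage 55 > 50
    list(g = gt(c(50), integer(0)), expect = "PASS"),            # hom at coverage cap
    list(g = gt(c(51), integer(0)), expect = "FAIL(iv)"),        # one over the cap
    list(g = gt(c(25, 20), c(1, 1)), expect = "PASS"),           # strays of 1 tolerated
    list(g = gt(c(5, 5), c(2)), expect = "FAIL(iii)"),           # 10/12 < 90%
    list(g = gt(c(48), c(2)), expect = "PASS"),                  # 48/50 = 96%, cov 50
    list(g = gt(c(10, 10, 10), integer(0)), expect = "UNGENOTYPED"), # 3 lengths
    list(g = gt(c(12), c(4)), expect = "FAIL(ii)")               # 4-read stray
  )
  rule_oracle <- function(g) {
    if (g$status == "UNGENOTYPED") return("UNGENOTYPED")
    het <- length(g$alleles) == 2
    if ((het && any(g$allele_counts < 5)) ||
        (!het && g$allele_counts[1] < 10)) return("FAIL(i)")
    tol <- max(2, g$unit_size)
    others <- g$diffs[!vapply(g$diffs, function(d)
      any(abs(d - g$alleles) <= tol), logical(1))]
    if (length(others)) {
      tab <- table(others)  # fixture strays are exact repeats of a value
      if (any(tab > 2)) return("FAIL(ii)")
    }
    if (sum(g$allele_counts) / g$coverage < 0.90) return("FAIL(iii)")
    if (g$coverage > 50) return("FAIL(iv)")
    "PASS"
  }
  for (i in seq_along(fixtures)) {
    f <- fixtures[[i]]
    expect_equal(confidence_filter(f$g), f$expect,
                 label = sprintf("fixture %d: confidence_filter", i))
    expect_equal(confidence_filter(f$g), rule_oracle(f$g),
                 label = sprintf("fixture %d: oracle agreement", i))
  }
})

test_that("pass counts are monotone in the coverage cap and read floors", {
  set.seed(303)
  gts <- lapply(1:40, function(i) {
    n1 <- sample(3:40, 1); n2 <- sample(0:20, 1)
    genotype_locus(c(rep(0L, n1), rep(60L, n2)), unit_size = 2L)
  })
  pass_count <- function(max_cov = 50, min_het = 5, min_hom = 10) {
    sum(vapply(gts, function(g)
      confidence_filter(g, min_het_reads = min_het, min_hom_reads = min_hom,
                        max_cov = max_cov) == "PASS", logical(1)))
  }
  caps <- vapply(c(20, 35, 50, 80), function(mc) pass_count(max_cov = mc),
                 numeric(1))
  expect_true(all(diff(caps) >= 0))
  floors <- vapply(c(3, 5, 8), function(mh)
    pass_count(min_het = mh, min_hom = 2 * mh), numeric(1))
  expect_true(all(diff(floors) <= 0))
})

test_that("concordance counts alleles, with partial recovery counted correct", {
  bulk <- data.frame(locus_id = c("L1", "L2"), allele1 = c(0, -10),
                     allele2 = c(30, NA), count1 = c(10L, 20L),
                     count2 = c(8L, NA), other_count = 0L,
                     coverage = c(18L, 20L), status = "PASS",
                     stringsAsFactors = FALSE)
  identical_cell <- bulk
  cc <- tr_concordance(identical_cell, bulk, locus)
  expect_equal(cc$correct, 3L)
  expect_equal(cc$discordant, 0L)
  ## cell recovers one of two bulk alleles at L1
  partial <- bulk
  partial$allele2[1] <- NA
  cc2 <- tr_concordance(partial, bulk, locus)
  expect_equal(cc2$correct, 2L)
  expect_equal(cc2$missing, 1L)
  ## a wrong allele is discordant
  wrong <- bulk
  wrong$allele1[2] <- -40
  cc3 <- tr_concordance(wrong, bulk, locus)
  expect_equal(cc3$discordant, 1L)
})

test_that("simulated dropout yields the expected correct-allele fraction", {
  cfg <- small_config(seed = 61, n_tr_loci = 40L, genome_length = 2e6)
  g <- simulate_genome(cfg)
  loci <- g$tr_loci
  bulk_aln <- simulate_tr_reads(loci, coverage = 30, allele_dropout = 0,
                                seed = 611)
  bulk_gt <- genotype_sample(bulk_aln, loci)
  d <- 0.3
  cell_aln <- simulate_tr_reads(loci, coverage = 30, allele_dropout = d,
                                seed = 612)
  cell_gt <- genotype_sample(cell_aln, loci)
  cc <- tr_concordance(cell_gt, bulk_gt, loci)
  expect_gt(cc$n_bulk_loci, 10)
  expect_equal(cc$discordant, 0L)
  total <- cc$correct + cc$missing + cc$ungenotyped
  ## dropout removes one haplotype; het loci then lose about half an allele
  expect_gt(cc$correct / total, 0.5)
})
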