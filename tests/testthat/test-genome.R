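test_that("nothing is planted when all rates are zero", {
  g <- simulate_genome(bare_config(seed = 4))
  expect_equal(nrow(g$germline), 0L)
  expect_equal(nrow(g$tr_loci), 0L)
  expect_equal(nrow(g$clone_somatic$A), 0L)
})

test_that("planted variant counts match the configuration exactly", {
  cfg <- small_config(seed = 11)
  g <- simulate_genome(cfg)
  tab <- table(g$germline$svtype)
  for (type in c("DEL", "INS", "DUP", "INV")) {
    expect_equal(unname(tab[[type]]), unname(cfg$sv_counts[[type]]))
  }
  expect_equal(nrow(g$clone_somatic$A), cfg$somatic_snvs_per_clone)
  expect_equal(nrow(g$clone_somatic$B), cfg$somatic_snvs_per_clone)
  ## somatic sites disjoint between clones and from germline
  keys <- function(df) paste(df$contig, df$pos)
  expect_length(intersect(keys(g$clone_somatic$A), keys(g$clone_somatic$B)), 0)
  expect_length(intersect(keys(g$clone_somatic$A), keys(g$germline)), 0)
})

test_that("planted features never overlap and TR loci keep distance from SVs", {
  g <- simulate_genome(small_config(seed = 12, n_tr_loci = 10L))
  sv <- g$germline[g$germline$svtype != "SNV", ]
  iv <- IRanges::IRanges(c(sv$pos + 1L, g$tr_loci$start + 1L,
                           g$germline$pos[g$germline$svtype == "SNV"] + 1L),
                         c(pmax(sv$end, sv$pos + 1L), g$tr_loci$end,
                           g$germline$pos[g$germline$svtype == "SNV"] + 1L))
  expect_true(all(IRanges::countOverlaps(iv, iv) == 1L))
  ## SV breakpoints at least 200 bp from any TR locus
  bp <- IRanges::IRanges(c(sv$pos, sv$end) + 1L, width = 1L)
  tr_pad <- IRanges::IRanges(g$tr_loci$start + 1L - 199L, g$tr_loci$end + 199L)
  expect_equal(sum(IRanges::countOverlaps(bp, tr_pad)), 0L)
})

test_that("reference sequence at a TR locus is the unit array", {
  g <- simulate_genome(small_config(seed = 13))
  tr <- g$tr_loci[1, ]
  arr <- substr(g$contigs[["chr1"]], tr$start + 1L, tr$end)
  expect_equal(arr, strrep(tr$unit, tr$ref_copies))
})

test_that("LINE-like deletion lengths have their mode near 6 kb", {
  cfg <- small_config(
    seed = 21, genome_length = 5e6, n_tr_loci = 0L, germline_snv_rate = 0,
    sv_counts = c(DEL = 200L, INS = 0L, DUP = 0L, INV = 0L),
    sv_length_models = list(
      DEL = list(modes = 6000, sds = 300, weights = 1),
      INS = list(modes = 300, sds = 30, weights = 1),
      DUP = list(modes = 1000, sds = 200, weights = 1),
      INV = list(modes = 1000, sds = 200, weights = 1)))
  g <- simulate_genome(cfg)
  lens <- abs(g$germline$svlen[g$germline$svtype == "DEL"])
  h <- hist(lens, breaks = seq(0, 10000, by = 500), plot = FALSE)
  modal_bin <- h$mids[which.max(h$counts)]
  expect_gte(modal_bin, 5500)
  expect_lte(modal_bin, 6500)
})

test_that("genome simulation is deterministic given the seed", {
  g1 <- simulate_genome(small_config(seed = 31))
  g2 <- simulate_genome(small_config(seed = 31))
  expect_identical(g1$contigs, g2$contigs)
  expect_identical(g1$germline, g2$germline)
  expect_identical(g1$tr_loci, g2$tr_loci)
})

test_that("impossible placements raise an error naming the feature", {
  cfg <- small_config(seed = 1, genome_length = 20000,
                      sv_counts = c(DEL = 50L, INS = 0L, DUP = 0L, INV = 0L),
                      sv_length_models = list(
                        DEL = list(modes = 6000, sds = 100, weights = 1),
                        INS = list(modes = 300, sds = 30, weights = 1),
                        DUP = list(modes = 300, sds = 30, weights = 1),
                        INV = list(modes = 300, sds = 30, weights = 1)),
                      n_tr_loci = 0L)
  expect_error(simulate_genome(cfg), "sv_DEL")
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(small_config(germline_snv_rate = -0.1), "probability")
  expect_error(small_config(heteroplasmy_frequency = 1.2), "heteroplasmy")
  expect_error(small_config(dropout_rate = 2), "probability")
})

test_that("haplotype block map round-trips SV coordinates", {
  g <- simulate_genome(small_config(seed = 41))
  hb <- build_haplotype(g, "chr1", "A", 1)
  ## total haplotype length = reference +/- planted net indel length
  vars <- g$germline[genotype_has_hap_test(g$germline$genotype, 1), ]
  tr <- g$tr_loci
  net <- sum(vars$svlen[vars$svtype %in% c("INS")]) +
    sum(vars$svlen[vars$svtype == "DEL"]) +
    sum(abs(vars$svlen[vars$svtype == "DUP"])) + sum(tr$hap1_diff)
  expect_equal(nchar(hb$seq), nchar(g$contigs[["chr1"]]) + net)
  ## projection of an interval inside an inversion reports '-' strand
  inv <- vars[vars$svtype == "INV", ][1, ]
  if (!is.na(inv$pos)) {
    blk <- hb$map[hb$map$strand == "-", ][1, ]
    seg <- project_hap_interval(hb$map, blk$hap_start + 5L, blk$hap_end - 5L)
    expect_true(all(seg$strand == "-"))
  }
})
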