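# Truth-set evaluation, SV merging and clone-aware somatic filtering.

# O(n^2) transitive-closure oracle for SV merging
merge_oracle <- function(all, max_dist = 200, min_overlap = 0.10) {
  n <- nrow(all)
  links <- function(i, j) {
    a <- all[i, ]; b <- all[j, ]
    if (a$contig != b$contig || a$svtype != b$svtype) return(FALSE)
    if (abs(a$pos - b$pos) > max_dist) return(FALSE)
    if (a$svtype == "INS") {
      la <- abs(a$svlen); lb <- abs(b$svlen)
      return(min(la, lb) / max(la, lb) >= min_overlap)
    }
    ov <- max(0, min(a$end, b$end) - max(a$pos, b$pos) + 1)
    ov / (a$end - a$pos + 1) >= min_overlap &&
      ov / (b$end - b$pos + 1) >= min_overlap
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (comp[i] != comp[j] && links(i, j)) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

test_that("SNV intersection requires exact site and allele identity", {
  bulk <- snv_rows(c(100, 200, 300), sample_id = "bulk")
  cell <- snv_rows(c(100, 300, 400), sample_id = "c1")
  tp <- intersect_snvs(cell, bulk)
  expect_equal(tp$pos, c(100, 300))
  expect_equal(nrow(intersect_snvs(cell, snv_rows(900))), 0L)
  ## identical sets: precision and sensitivity 1
  ev <- snv_eval(bulk, bulk)
  expect_equal(ev$precision, 1)
  expect_equal(ev$sensitivity, 1)
  ## different alt allele at the same site is not a match
  cell2 <- snv_rows(100, alt = "G")
  expect_equal(nrow(intersect_snvs(cell2, bulk)), 0L)
})

test_that("unnormalized indels trigger a warning and are left-aligned", {
  ref <- c(chr1 = "GGGTCACACACTTTT")
  bulk <- data.frame(contig = "chr1", pos = 4L, ref = "TCA", alt = "T",
                     svtype = "INDEL", svlen = -2L, end = 6L, precise = NA,
                     sample_id = "bulk", stringsAsFactors = FALSE)
  ## same deletion, shifted right and carrying a shared trailing base
  cell <- data.frame(contig = "chr1", pos = 6L, ref = "ACA", alt = "A",
                     svtype = "INDEL", svlen = -2L, end = 8L, precise = NA,
                     sample_id = "c1", stringsAsFactors = FALSE)
  expect_warning(tp <- intersect_snvs(cell, bulk, ref_seqs = ref),
                 "auto-normalizing")
  expect_equal(nrow(tp), 1L)
})

test_that("snv truth-set recovery matches configured dropout and precision", {
  sr <- snv_recovery_experiment(seed = 77, n_sites = 4000L,
                                genome_length = 4e6, dropout = 0.6,
                                target_precision = 0.9)
  n <- sr$n_bulk_sites * nrow(sr$per_cell)
  se_s <- sqrt(0.4 * 0.6 / n)
  expect_lt(abs(sr$sensitivity - 0.4), 4 * se_s)
  expect_lt(abs(sr$precision - 0.9), 0.02)
})

test_that("somatic SNV filter equals the exhaustive presence/absence oracle", {
  ## one variant per presence pattern over (bulk, A1, A2, A3, B1, B2, B3)
  samples <- c("bulk", "A1", "A2", "A3", "B1", "B2", "B3")
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 7))
  names(patterns) <- samples
  pos <- seq_len(nrow(patterns)) * 10L
  sets <- lapply(samples, function(s)
    snv_rows(pos[patterns[[s]]], sample_id = s))
  names(sets) <- samples
  cand <- somatic_snv_filter(
    list(A = sets[c("A1", "A2", "A3")], B = sets[c("B1", "B2", "B3")]),
    sets$bulk)
  ## direct predicate evaluation
  inA <- rowSums(patterns[, c("A1", "A2", "A3")]) >= 2
  inB <- rowSums(patterns[, c("B1", "B2", "B3")]) >= 2
  anyA <- rowSums(patterns[, c("A1", "A2", "A3")]) > 0
  anyB <- rowSums(patterns[, c("B1", "B2", "B3")]) > 0
  keep <- !patterns$bulk & ((inA & !anyB) | (inB & !anyA))
  expect_setequal(cand$pos, pos[keep])
  ## clone annotation agrees
  expect_equal(sort(cand$pos[cand$clone == "A"]), pos[!patterns$bulk & inA & !anyB])
})

test_that("somatic SNV filter drops indels and masked positions", {
  a1 <- rbind(snv_rows(c(100, 200), sample_id = "A1"),
              data.frame(contig = "chr1", pos = 300L, ref = "AT", alt = "A",
                         svtype = "INDEL", svlen = -1L, end = 301L,
                         precise = NA, sample_id = "A1",
                         stringsAsFactors = FALSE))
  a2 <- rbind(snv_rows(c(100, 200), sample_id = "A2"),
              data.frame(contig = "chr1", pos = 300L, ref = "AT", alt = "A",
                         svtype = "INDEL", svlen = -1L, end = 301L,
                         precise = NA, sample_id = "A2",
                         stringsAsFactors = FALSE))
  b <- list(snv_rows(900, sample_id = "B1"), snv_rows(901, sample_id = "B2"))
  bulk <- snv_rows(5000, sample_id = "bulk")
  mask <- data.frame(contig = "chr1", start = 150L, end = 250L)  # covers 200
  cand <- somatic_snv_filter(list(A = list(a1, a2), B = b), bulk, mask)
  expect_equal(cand$pos, 100)  # 200 masked, 300 is an indel
  expect_equal(cand$clone, "A")
})

test_that("a clone with fewer than two cells is skipped with a warning", {
  a <- list(snv_rows(100, sample_id = "A1"))
  b <- list(snv_rows(200, sample_id = "B1"), snv_rows(200, sample_id = "B2"))
  expect_warning(
    cand <- somatic_snv_filter(list(A = a, B = b), snv_rows(999)),
    "clone A")
  expect_equal(cand$pos, 200)
})

test_that("SV merging obeys the distance and reciprocal-overlap thresholds", {
  a <- sv_row("chr1", 1000L, "DEL", 2000L, "s1")
  b <- sv_row("chr1", 1150L, "DEL", 2000L, "s2")   # 150 bp apart, ~88% overlap
  m <- merge_svs(list(a, b))
  expect_equal(nrow(m), 1L)
  expect_true(m$in_s1 & m$in_s2)
  c_ <- sv_row("chr1", 1500L, "DEL", 2000L, "s2")  # 500 bp apart
  expect_equal(nrow(merge_svs(list(a, c_))), 2L)
  ## type mismatch never merges
  d <- sv_row("chr1", 1000L, "DUP", 2000L, "s2")
  expect_equal(nrow(merge_svs(list(a, d))), 2L)
})

test_that("SV merge clusters equal the transitive-closure oracle", {
  for (sd in 1:10) {
    sets <- list(random_sv_set(20, "s1", L = 2e5, seed = sd),
                 random_sv_set(20, "s2", L = 2e5, seed = sd + 100),
                 random_sv_set(10, "s3", L = 2e5, seed = sd + 200))
    all <- do.call(rbind, sets)
    m <- merge_svs(sets)
    comp <- merge_oracle(all)
    expect_equal(nrow(m), length(unique(comp)))
    ## presence flags match the oracle clusters
    key <- function(df) paste(df$svtype, df$pos, df$svlen)
    for (cl in unique(comp)) {
      members <- all[comp == cl, ]
      row <- m[m$svtype == members$svtype[1] &
                 m$pos == as.integer(median(members$pos)) &
                 m$svlen == as.integer(median(members$svlen)), ]
      expect_equal(nrow(row), 1L)
      for (s in c("s1", "s2", "s3")) {
        expect_equal(unname(row[[paste0("in_", s)]]),
                     s %in% members$sample_id)
      }
    }
  }
})

test_that("SV merging is invariant to sample and record order", {
  sets <- list(random_sv_set(25, "s1", seed = 7),
               random_sv_set(25, "s2", seed = 8))
  m1 <- merge_svs(sets)
  m2 <- merge_svs(rev(sets))
  m2 <- m2[, names(m1)]
  o1 <- m1[order(m1$contig, m1$pos, m1$svtype, m1$svlen), ]
  o2 <- m2[order(m2$contig, m2$pos, m2$svtype, m2$svlen), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("SV true positives: identical sets are perfect, FP-only sets score zero", {
  bulk <- random_sv_set(30, "bulk", seed = 31)
  cell <- bulk
  cell$sample_id <- "c1"
  r <- sv_true_positives(cell, bulk)
  present <- r[r$fn + r$tp > 0, ]
  expect_true(all(present$precision == 1))
  expect_true(all(present$sensitivity == 1))
  fp_only <- random_sv_set(30, "c1", seed = 99)
  fp_only$pos <- fp_only$pos + 5e6  # guaranteed disjoint
  r2 <- sv_true_positives(fp_only, bulk)
  expect_equal(sum(r2$tp), 0L)
})

test_that("inversion-heavy false calls drive inversion precision to zero", {
  bulk <- rbind(sv_row("chr1", 10000L, "DEL", 500L, "bulk"),
                sv_row("chr1", 50000L, "INS", 300L, "bulk"))
  set.seed(41)
  false_inv <- do.call(rbind, lapply(1:40, function(i)
    sv_row("chr1", 100000L + i * 5000L, "INV", 800L, "c1")))
  cell <- rbind(sv_row("chr1", 10005L, "DEL", 500L, "c1"),
                sv_row("chr1", 50002L, "INS", 310L, "c1"), false_inv)
  r <- sv_true_positives(cell, bulk)
  expect_equal(r$precision[r$svtype == "INV"], 0)
  expect_equal(r$precision[r$svtype == "DEL"], 1)
  expect_equal(r$sensitivity[r$svtype == "INS"], 1)
})

test_that("somatic SV filter keeps clone-confined PRECISE events only", {
  bulk <- sv_row("chr1", 99000L, "DEL", 400L, "bulk")
  b1 <- sv_row("chr1", 10000L, "DEL", 600L, "B1")
  b2 <- sv_row("chr1", 10020L, "DEL", 600L, "B2")
  impA1 <- sv_row("chr1", 30000L, "DUP", 900L, "A1", precise = FALSE)
  impA2 <- sv_row("chr1", 30010L, "DUP", 900L, "A2", precise = FALSE)
  merged <- merge_svs(list(bulk, b1, b2, impA1, impA2,
                           sv_row("chr1", 99010L, "DEL", 400L, "A1")))
  cand <- somatic_sv_filter(merged, list(A = c("A1", "A2"),
                                         B = c("B1", "B2")))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$clone, "B")
  expect_equal(cand$svtype, "DEL")
  ## nothing planted: empty candidate list
  only_shared <- merge_svs(list(bulk, sv_row("chr1", 99005L, "DEL", 400L, "B1"),
                                sv_row("chr1", 99008L, "DEL", 400L, "B2")))
  expect_equal(nrow(somatic_sv_filter(only_shared,
                                      list(A = c("A1", "A2"),
                                           B = c("B1", "B2")))), 0L)
})

test_that("call-set emission respects dropout and produces TP/FP structure", {
  cfg <- small_config(seed = 55, genome_length = 1e6, n_tr_loci = 0L,
                      germline_snv_rate = 1e-3, dropout_rate = 0,
                      fp_snv_rate = 0, fp_sv_counts = c(DEL = 0, INS = 0,
                                                        DUP = 0, INV = 0))
  g <- simulate_genome(cfg)
  calls <- emit_callsets(g, cfg)
  ## dropout 0, fp 0: cell calls = bulk union somatic, exactly
  key <- function(df) paste(df$contig, df$pos, df$alt)
  exp_keys <- c(key(calls$bulk),
                paste(g$clone_somatic$A$contig, g$clone_somatic$A$pos + 1L,
                      g$clone_somatic$A$alt))
  expect_setequal(key(calls$A1), exp_keys)
  ## dropout 0.8 retains a binomial fraction
  cfg2 <- small_config(seed = 56, genome_length = 1e6, n_tr_loci = 0L,
                       germline_snv_rate = 1e-2, dropout_rate = 0.8,
                       somatic_snvs_per_clone = 0L, fp_snv_rate = 0,
                       fp_sv_counts = c(DEL = 0, INS = 0, DUP = 0, INV = 0))
  g2 <- simulate_genome(cfg2)
  calls2 <- emit_callsets(g2, cfg2)
  n <- nrow(g2$germline)
  kept <- nrow(calls2$A1)
  ci <- qbinom(c(0.005, 0.995), n, 0.2)
  expect_gte(kept, ci[1])
  expect_lte(kept, ci[2])
})

test_that("VCF round-trip preserves calls including SV INFO fields", {
  cfg <- small_config(seed = 57)
  g <- simulate_genome(cfg)
  calls <- emit_callsets(g, cfg)
  f <- tempfile(fileext = ".vcf")
  write_vcf(calls$A1, f, "A1")
  back <- read_vcf(f)
  expect_equal(nrow(back), nrow(calls$A1))
  expect_equal(back$pos, calls$A1$pos)
  expect_equal(back$svtype, calls$A1$svtype)
  expect_equal(back$svlen, calls$A1$svlen)
  sv <- calls$A1$svtype != "SNV"
  expect_equal(back$precise[sv], calls$A1$precise[sv])
  expect_equal(back$sample_id[1], "A1")
})

test_that("pileup-based heteroplasmy scan separates carrier and background", {
  L <- 200L
  ref <- paste(rep("A", L), collapse = "")
  mk <- function(alt_at, alt_frac, depth = 40L) {
    m <- matrix(0L, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    m["A", ] <- depth
    if (!is.na(alt_at)) {
      m["T", alt_at] <- round(alt_frac * depth)
      m["A", alt_at] <- depth - m["T", alt_at]
    }
    m
  }
  pile <- list(A1 = mk(NA, 0), A2 = mk(NA, 0),
               B1 = mk(50L, 0.5), B2 = mk(50L, 0.45), bulk = mk(NA, 0))
  clones <- list(A = c("A1", "A2"), B = c("B1", "B2"))
  sc <- heteroplasmy_scan(pile, clones, ref)
  expect_equal(nrow(sc$sites), 1L)
  expect_equal(sc$sites$pos, 50L)
  expect_equal(sc$sites$clone, "B")
  expect_equal(sc$sites$freq_B1, 0.5)
  ## fixed (germline-like) site present everywhere is excluded
  pile2 <- lapply(pile, function(m) { m["T", 80] <- 40L; m["A", 80] <- 0L; m })
  sc2 <- heteroplasmy_scan(pile2, clones, ref)
  expect_false(80 %in% sc2$sites$pos)
  ## low coverage marks sites untestable rather than absent
  pile3 <- pile
  pile3$B1[, 50] <- c(3L, 0L, 0L, 2L)
  sc3 <- heteroplasmy_scan(pile3, clones, ref)
  expect_true(50 %in% sc3$untestable)
  expect_false(50 %in% sc3$sites$pos)
})
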