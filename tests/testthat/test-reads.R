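test_that("error-free non-chimeric reads are exact haplotype substrings", {
  cfg <- bare_config(seed = 14, read_error_rate = 0,
                     chimera_rates = list(inversion_per_amplicon = 0,
                                          duplication_per_amplicon = 0,
                                          intermolecular_per_droplet = 0))
  g <- simulate_genome(cfg)
  fr <- fragment_and_encapsulate(g, "A1", cfg, contigs = "chr1")
  am <- amplify(fr, cfg)
  rs <- generate_reads(am, g, cfg, 40)
  h1 <- build_haplotype(g, "chr1", "A", 1)$seq
  for (sq in rs$reads$sequence) {
    expect_true(grepl(sq, h1, fixed = TRUE))  # haps identical w/o variants
  }
})

test_that("truth segments partition every read and match the reference", {
  cfg <- small_config(seed = 15, read_error_rate = 0)
  g <- simulate_genome(cfg)
  fr <- fragment_and_encapsulate(g, "B2", cfg)
  am <- amplify(fr, cfg)
  rs <- generate_reads(am, g, cfg, 120)
  segs <- rs$segments
  for (j in seq_len(nrow(rs$reads))) {
    rid <- rs$reads$read_id[j]
    ss <- segs[segs$read_id == rid, ]
    sq <- rs$reads$sequence[j]
    expect_equal(max(ss$read_end), nchar(sq))
    cov <- integer(nchar(sq))
    for (i in seq_len(nrow(ss))) {
      if (ss$read_end[i] > ss$read_start[i]) {
        idx <- (ss$read_start[i] + 1L):ss$read_end[i]
        cov[idx] <- cov[idx] + 1L
      }
    }
    expect_true(all(cov == 1L))  # every base maps to exactly one segment
  }
  ## base-level agreement with the reference (SNV sites aside)
  mism <- 0; bases <- 0
  for (j in seq_len(min(60, nrow(rs$reads)))) {
    rid <- rs$reads$read_id[j]
    ss <- segs[segs$read_id == rid, ]
    sq <- rs$reads$sequence[j]
    for (i in seq_len(nrow(ss))) {
      if (ss$ref_end[i] <= ss$ref_start[i]) next
      ref <- substr(g$contigs[[ss$contig[i]]], ss$ref_start[i] + 1L,
                    ss$ref_end[i])
      part <- substr(sq, ss$read_start[i] + 1L, ss$read_end[i])
      if (ss$strand[i] == "-") part <- rc(part)
      a <- strsplit(ref, "")[[1]]; b <- strsplit(part, "")[[1]]
      expect_length(a, length(b))
      mism <- mism + sum(a != b); bases <- bases + length(a)
    }
  }
  expect_lt(mism / bases, 2 * cfg$germline_snv_rate + 1e-3)
})

test_that("fold-back reads carry overlapping truth segments on opposite strands", {
  cfg <- bare_config(seed = 16, read_error_rate = 0,
                     chimera_rates = list(inversion_per_amplicon = 1,
                                          duplication_per_amplicon = 0,
                                          intermolecular_per_droplet = 0))
  g <- simulate_genome(cfg)
  fr <- fragment_and_encapsulate(g, "A1", cfg, contigs = "chr1")
  am <- amplify(fr, cfg)
  rs <- generate_reads(am, g, cfg, 20)
  inv <- rs$reads[rs$reads$chimera_type == "INVERSION", ]
  expect_gt(nrow(inv), 0L)
  ss <- rs$segments[rs$segments$read_id == inv$read_id[1], ]
  expect_setequal(unique(ss$strand), c("-", "+"))
  plus <- ss[ss$strand == "+", ][1, ]
  minus <- ss[ss$strand == "-", ][1, ]
  ## the inverted arm re-covers reference already covered by the first arm
  expect_lt(max(plus$ref_start, minus$ref_start),
            min(plus$ref_end, minus$ref_end))
})

test_that("observed per-base mismatch rate matches the configured error rate", {
  cfg <- bare_config(seed = 18, germline_snv_rate = 0, read_error_rate = 0.01)
  g <- simulate_genome(cfg)
  fr <- fragment_and_encapsulate(g, "A1", cfg, contigs = "chr1")
  am <- amplify(fr, cfg)
  rs <- generate_reads(am, g, cfg, 250)
  mism <- 0; bases <- 0
  for (j in seq_len(nrow(rs$reads))) {
    if (rs$reads$is_chimeric[j]) next
    rid <- rs$reads$read_id[j]
    ss <- rs$segments[rs$segments$read_id == rid, ]
    sq <- rs$reads$sequence[j]
    for (i in seq_len(nrow(ss))) {
      ref <- substr(g$contigs[[ss$contig[i]]], ss$ref_start[i] + 1L,
                    ss$ref_end[i])
      part <- substr(sq, ss$read_start[i] + 1L, ss$read_end[i])
      if (ss$strand[i] == "-") part <- rc(part)
      a <- strsplit(ref, "")[[1]]; b <- strsplit(part, "")[[1]]
      mism <- mism + sum(a != b); bases <- bases + length(a)
    }
  }
  expect_gt(bases, 1e6)
  se <- sqrt(0.01 * 0.99 / bases)
  expect_lt(abs(mism / bases - 0.01), 3 * se)
})

test_that("FASTQ and PAF round-trip the simulated reads", {
  cfg <- small_config(seed = 19)
  g <- simulate_genome(cfg)
  fr <- fragment_and_encapsulate(g, "A1", cfg)
  am <- amplify(fr, cfg)
  rs <- generate_reads(am, g, cfg, 30)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(rs, fq, qv = cfg$read_qv)
  back <- read_fastq(fq)
  expect_equal(back$read_id, rs$reads$read_id)
  expect_equal(back$sequence, rs$reads$sequence)
  qline <- readLines(fq)[4]
  expect_true(all(strsplit(qline, "")[[1]] == rawToChar(as.raw(33 + 20))))
  paf <- tempfile(fileext = ".paf")
  write_paf(rs, g, paf)
  aln <- read_paf(paf)
  expect_true(all(aln$qend <= aln$qlen))
  expect_true(all(aln$tend <= aln$tlen))
  expect_true(all(aln$strand %in% c("+", "-")))
  expect_setequal(unique(aln$qname), rs$reads$read_id)
})

test_that("read generation is deterministic given the config seed", {
  cfg <- small_config(seed = 20)
  g <- simulate_genome(cfg)
  fr <- fragment_and_encapsulate(g, "A1", cfg)
  am <- amplify(fr, cfg)
  r1 <- generate_reads(am, g, cfg, 50)
  r2 <- generate_reads(am, g, cfg, 50)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$segments, r2$segments)
})
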