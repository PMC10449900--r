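# Self-alignment screen: seeded detection of fold-back inversions and
# tandem duplications, verified against alignment oracles.

mutate_seq <- function(s, rate, seed = 1) {
  set.seed(seed)
  ch <- strsplit(s, "")[[1]]
  k <- rbinom(1, length(ch), rate)
  pos <- sample.int(length(ch), k)
  shift <- sample.int(3, k, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  ch[pos] <- bases[(match(ch[pos], bases) - 1 + shift) %% 4 + 1]
  paste(ch, collapse = "")
}

test_that("random sequence yields no self-hits; short reads are skipped", {
  set.seed(101)
  expect_equal(nrow(self_align(random_dna(5000))), 0L)
  expect_equal(nrow(self_align(random_dna(150))), 0L)  # < 2 * min_hit_len
})

test_that("perfect palindrome gives one reverse-complement hit over both halves", {
  set.seed(102)
  S <- random_dna(2000)
  h <- self_align(paste0(S, rc(S)))
  expect_equal(nrow(h), 1L)
  expect_equal(h$orientation, "revcomp")
  expect_gt(h$identity, 0.99)
  expect_gt(h$length, 1800)
  cl <- classify_chimera(h)
  expect_equal(cl$verdict, "INVERSION")
  expect_lt(abs(cl$junctions - 2000), 20)
})

test_that("tandem duplication with 1% errors is found at the oracle identity", {
  set.seed(103)
  S <- random_dna(2000)
  read <- paste0(S, mutate_seq(S, 0.01))
  h <- self_align(read)
  expect_equal(nrow(h), 1L)
  expect_equal(h$orientation, "forward")
  expect_gte(h$identity, 0.97)
  ## independent oracle: global DP alignment of the two halves
  oracle <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(substr(read, 1, 2000)),
    Biostrings::DNAString(substr(read, 2001, 4000)), type = "global")
  oracle_id <- Biostrings::nmatch(oracle) /
    nchar(as.character(Biostrings::alignedPattern(oracle)))
  expect_lt(abs(h$identity - oracle_id), 0.02)
})

test_that("a duplication at 85% copy identity is retained at the 90% threshold", {
  set.seed(104)
  S <- random_dna(1500)
  read <- paste0(S, mutate_seq(S, 0.15))
  h <- self_align(read, min_identity = 0.90)
  expect_equal(nrow(h), 0L)
  ## the same read is caught when the threshold drops below its identity
  h2 <- self_align(read, min_identity = 0.75)
  expect_gt(nrow(h2), 0L)
})

test_that("verdicts and junction counts follow the hit orientations", {
  expect_equal(classify_chimera(NULL)$verdict, "CLEAN")
  empty <- self_align(paste(rep("A", 10), collapse = ""))
  expect_equal(classify_chimera(empty)$verdict, "CLEAN")
  rc_hit <- data.frame(a_start = 1L, a_end = 1000L, b_start = 1001L,
                       b_end = 2000L, orientation = "revcomp",
                       identity = 0.99, length = 1000L)
  fw_hit <- data.frame(a_start = 2001L, a_end = 3000L, b_start = 3001L,
                       b_end = 4000L, orientation = "forward",
                       identity = 0.99, length = 1000L)
  expect_equal(classify_chimera(rc_hit)$verdict, "INVERSION")
  expect_length(classify_chimera(rc_hit)$junctions, 1L)
  both <- rbind(rc_hit, fw_hit)
  expect_equal(classify_chimera(both)$verdict, "COMPLEX")
  expect_length(classify_chimera(both)$junctions, 2L)
})

test_that("detection is symmetric under reverse complement", {
  set.seed(105)
  for (i in 1:5) {
    S <- random_dna(3000)
    arm <- substr(S, 1500, 2400)
    read <- paste0(substr(S, 1, 2400), rc(arm))
    v1 <- classify_chimera(self_align(read))$verdict
    v2 <- classify_chimera(self_align(rc(read)))$verdict
    expect_equal(v1, v2)
  }
})

test_that("raising the identity threshold never removes more reads", {
  set.seed(106)
  reads <- data.frame(
    read_id = sprintf("r%02d", 1:12),
    sequence = c(
      vapply(1:4, function(i) random_dna(4000), character(1)),
      vapply(1:4, function(i) {               # clean-ish duplications
        S <- random_dna(1800)
        paste0(S, mutate_seq(S, 0.06, seed = i))
      }, character(1)),
      vapply(1:4, function(i) {               # near-perfect fold-backs
        S <- random_dna(3000)
        paste0(S, rc(mutate_seq(substr(S, 1200, 3000), 0.01, seed = i)))
      }, character(1))),
    stringsAsFactors = FALSE)
  removed <- vapply(c(0.80, 0.90, 0.97), function(th)
    nrow(filter_reads(reads, min_identity = th)$removed), numeric(1))
  expect_true(all(diff(removed) <= 0))
})

test_that("split subreads realign collinearly to their fragment", {
  set.seed(107)
  S <- random_dna(6000)
  b <- 3500L; a2 <- 2000L
  read <- paste0(substr(S, 1, b), rc(substr(S, b - a2 + 1, b)))
  h <- self_align(read)
  cl <- classify_chimera(h)
  expect_equal(cl$verdict, "INVERSION")
  sub <- split_read(read, cl$junctions, trim = 50)
  expect_gte(nrow(sub), 1L)
  for (i in seq_len(nrow(sub))) {
    frag <- sub$sequence[i]
    fwd <- grepl(frag, S, fixed = TRUE)
    bwd <- grepl(rc(frag), S, fixed = TRUE)
    expect_true(fwd || bwd)  # each piece maps contiguously to the source
  }
})

test_that("split_read arithmetic, preconditions and bounds checks hold", {
  sq <- strrep("ACGT", 2500)  # 10 kb
  sub <- split_read(sq, junctions = 6000L, trim = 50)
  expect_equal(sub$end - sub$start + 1L, c(5950L, 3950L))
  expect_error(split_read(sq, integer(0)), "non-CLEAN")
  expect_error(split_read(sq, 20000L), "bounds")
})

test_that("N50 matches its brute-force definition", {
  n50_oracle <- function(l) {
    l <- sort(l, decreasing = TRUE)
    l[which(cumsum(l) >= sum(l) / 2)[1]]
  }
  expect_equal(aligned_n50(c(1, 2, 3, 4, 5) * 1000), 4000)
  expect_equal(aligned_n50(c(1, 2, 3, 4, 5) * 1000),
               n50_oracle(c(1, 2, 3, 4, 5) * 1000))
  expect_equal(aligned_n50(rep(7, 10)), 7)
  expect_equal(aligned_n50(42), 42)
  set.seed(108)
  l <- sample(500:20000, 200)
  expect_equal(aligned_n50(l), n50_oracle(l))
  expect_error(aligned_n50(numeric(0)), "empty")
})
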