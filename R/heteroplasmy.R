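## Mitochondrial heteroplasmy detection: per-sample base pileups over the
## mitochondrial contig, then a scan for sites where one clone's cells all
## carry an intermediate-frequency alternate allele that is (near) absent
## from every other sample including bulk.

#' Base pileup over a contig from reads with truth alignments
#'
#' Accumulates per-position base counts from read sequences using their
#' (truth or mapped) alignment segments. Substitution-only reads keep
#' read/reference columns in register, so no realignment is needed.
#'
#' @param read_set a `read_set` with sequences.
#' @param contig contig to pile up.
#' @param contig_length its length.
#' @return matrix (4 x contig_length, rows A/C/G/T) of base counts.
#' @export
base_pileup <- function(read_set, contig, contig_length) {
  counts <- matrix(0L, nrow = 4L, ncol = contig_length,
                   dimnames = list(DNA_BASES, NULL))
  seg <- read_set$segments
  seg <- seg[seg$contig == contig & seg$ref_end > seg$ref_start, , drop = FALSE]
  if (!nrow(seg)) return(counts)
  ridx <- match(seg$read_id, read_set$reads$read_id)
  parts <- substring(read_set$reads$sequence[ridx], seg$read_start + 1L,
                     seg$read_end)
  rs0 <- seg$ref_start; re0 <- seg$ref_end; strands <- seg$strand
  pos_l <- vector("list", nrow(seg)); base_l <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    part <- if (strands[i] == "-") revcomp(parts[i]) else parts[i]
    b <- strsplit(part, "", fixed = TRUE)[[1]]
    p <- seq.int(rs0[i] + 1L, re0[i])
    if (length(b) != length(p)) {   # indel-bearing read: keep the prefix
      n <- min(length(b), length(p))
      b <- b[seq_len(n)]; p <- p[seq_len(n)]
    }
    pos_l[[i]] <- p; base_l[[i]] <- b
  }
  pos_all <- unlist(pos_l); base_all <- unlist(base_l)
  keep <- base_all %in% DNA_BASES
  idx <- match(base_all[keep], DNA_BASES) + 4L * (pos_all[keep] - 1L)
  tab <- tabulate(idx, nbins = 4L * contig_length)
  counts[] <- matrix(tab, nrow = 4L)
  counts
}

#' Scan per-sample pileups for clone-confined heteroplasmic sites
#'
#' Reports sites where, for some clone, every cell of that clone has
#' alternate-allele frequency at or above `min_freq` while every other
#' sample (other clone's cells and bulk) stays below `max_background`.
#' Germline mitochondrial variants (present in bulk) are excluded by the
#' background condition. Positions where any required sample has coverage
#' below `min_cov` are reported as untestable, not absent.
#'
#' @param pileups named list of pileup matrices from [base_pileup()]
#'   (one per sample; must include `bulk`).
#' @param clones named list (clone -> character vector of cell sample ids).
#' @param ref_seq reference sequence of the contig (character).
#' @param min_cov minimum per-sample coverage for a testable site.
#' @param min_freq minimum alternate frequency in carrier cells.
#' @param max_background maximum alternate frequency in non-carrier
#'   samples.
#' @return list with `sites` (data.frame: `pos` 1-based, `ref`, `alt`,
#'   `clone`, per-sample frequency columns) and `untestable` (integer
#'   positions with insufficient coverage).
#' @export
heteroplasmy_scan <- function(pileups, clones, ref_seq, min_cov = 10,
                              min_freq = 0.30, max_background = 0.05) {
  L <- ncol(pileups[[1]])
  stopifnot(nchar(ref_seq) == L)
  samples <- names(pileups)
  depth <- vapply(pileups, colSums, numeric(L))          # L x samples
  refbase <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  untestable <- which(apply(depth < min_cov, 1L, any))
  sites <- list()
  for (alt in DNA_BASES) {
    freq <- vapply(pileups, function(m) {
      d <- colSums(m)
      ifelse(d > 0, m[alt, ] / d, 0)
    }, numeric(L))                                        # L x samples
    cand_pos <- which(refbase != alt)
    cand_pos <- setdiff(cand_pos, untestable)
    if (!length(cand_pos)) next
    for (clone in names(clones)) {
      own <- clones[[clone]]
      oth <- setdiff(samples, own)
      ok <- cand_pos[
        rowSums(freq[cand_pos, own, drop = FALSE] >= min_freq) == length(own) &
        rowSums(freq[cand_pos, oth, drop = FALSE] < max_background) == length(oth)]
      for (p in ok) {
        row <- data.frame(pos = p, ref = refbase[p], alt = alt, clone = clone,
                          stringsAsFactors = FALSE)
        for (s in samples) row[[paste0("freq_", s)]] <- freq[p, s]
        sites[[length(sites) + 1L]] <- row
      }
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else {
    data.frame(pos = integer(), ref = character(), alt = character(),
               clone = character(), stringsAsFactors = FALSE)
  }
  list(sites = sites, untestable = untestable)
}
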