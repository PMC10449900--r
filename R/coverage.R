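## Coverage-uniformity metrics over alignments. An "alignment" here is any
## data.frame with columns qname, tname, tstart, tend (0-based half-open
## reference coordinates) -- the PAF reader and the simulator's truth
## segments both produce this shape.
##
## Depth counts aligned reference bases (pileup semantics); all statistics
## are computed exactly from interval arithmetic via run-length encodings,
## never by sampling positions.

aln_cols <- function(alignments) {
  need <- c("qname", "tname", "tstart", "tend")
  if (!all(need %in% names(alignments))) {
    ## accept truth-segment tables too
    map <- c(read_id = "qname", contig = "tname", ref_start = "tstart",
             ref_end = "tend")
    for (old in names(map)) {
      if (old %in% names(alignments)) {
        names(alignments)[names(alignments) == old] <- map[[old]]
      }
    }
  }
  stopifnot(all(need %in% names(alignments)))
  alignments
}

contig_coverage <- function(alignments, contig_lengths) {
  alignments <- aln_cols(alignments)
  lapply(setNames(names(contig_lengths), names(contig_lengths)), function(cn) {
    a <- alignments[alignments$tname == cn, , drop = FALSE]
    if (!nrow(a)) return(S4Vectors::Rle(0L, contig_lengths[[cn]]))
    IRanges::coverage(IRanges::IRanges(a$tstart + 1L, a$tend),
                      width = contig_lengths[[cn]])
  })
}

#' Binned coverage profile
#'
#' Mean aligned-base depth per fixed-size bin; the final partial bin uses
#' its true length.
#'
#' @param alignments alignment data.frame (PAF columns or truth segments).
#' @param contig_lengths named vector of contig lengths.
#' @param bin_size bin size in bases.
#' @return object of class `coverage_profile`: list with `bins`
#'   (data.frame: `contig`, `start`, `end`, `depth`), `bin_size`,
#'   `total_aligned_bases`, `total_reads`.
#' @export
binned_coverage <- function(alignments, contig_lengths, bin_size) {
  if (!is.numeric(bin_size) || bin_size <= 0) {
    stop("'bin_size' must be a positive number of bases", call. = FALSE)
  }
  alignments <- aln_cols(alignments)
  covs <- contig_coverage(alignments, contig_lengths)
  bins <- lapply(names(covs), function(cn) {
    L <- contig_lengths[[cn]]
    starts <- seq(0L, L - 1L, by = bin_size)
    ends <- pmin(starts + bin_size, L)
    v <- IRanges::Views(covs[[cn]], start = starts + 1L, end = ends)
    data.frame(contig = cn, start = starts, end = ends,
               depth = IRanges::viewMeans(v), stringsAsFactors = FALSE)
  })
  structure(list(bins = do.call(rbind, bins), bin_size = bin_size,
                 total_aligned_bases = sum(as.numeric(alignments$tend) -
                                             alignments$tstart),
                 total_reads = length(unique(alignments$qname))),
            class = "coverage_profile")
}

#' Fraction of reads aligning to extreme-coverage regions
#'
#' A read counts once if any of its alignments overlaps at least one bin
#' whose mean depth is at or above `threshold` (membership, not
#' apportionment).
#'
#' @param alignments alignment data.frame.
#' @param profile a `coverage_profile` (conventionally at 5 kb bins).
#' @param threshold depth threshold (default 200; applied as `>=`).
#' @return fraction of distinct reads in extreme-coverage regions.
#' @export
frac_reads_high_cov <- function(alignments, profile, threshold = 200) {
  alignments <- aln_cols(alignments)
  b <- profile$bins[profile$bins$depth >= threshold, , drop = FALSE]
  if (!nrow(b)) return(0)
  total <- length(unique(alignments$qname))
  hot <- GenomicRanges::GRanges(b$contig, IRanges::IRanges(b$start + 1L, b$end))
  ar <- GenomicRanges::GRanges(alignments$tname,
                               IRanges::IRanges(alignments$tstart + 1L,
                                                alignments$tend))
  ov <- GenomicRanges::countOverlaps(ar, hot) > 0L
  length(unique(alignments$qname[ov])) / total
}

#' Breadth of coverage
#'
#' Fraction of reference bases covered by at least one read.
#'
#' @param alignments alignment data.frame.
#' @param contig_lengths named vector of contig lengths.
#' @return fraction in `[0, 1]`.
#' @export
breadth <- function(alignments, contig_lengths) {
  alignments <- aln_cols(alignments)
  covered <- sum(vapply(names(contig_lengths), function(cn) {
    a <- alignments[alignments$tname == cn, , drop = FALSE]
    if (!nrow(a)) return(0)
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(a$tstart + 1L, pmin(a$tend, contig_lengths[[cn]])))))
  }, numeric(1)))
  covered / sum(as.numeric(contig_lengths))
}

#' Population standard deviation of per-base depth
#'
#' Computed exactly from the run-length encoded pileup over every reference
#' base (uncovered bases count as depth 0).
#'
#' @param alignments alignment data.frame.
#' @param contig_lengths named vector of contig lengths.
#' @return standard deviation of depth.
#' @export
coverage_sd <- function(alignments, contig_lengths) {
  covs <- contig_coverage(aln_cols(alignments), contig_lengths)
  n <- sum(as.numeric(contig_lengths))
  if (n == 0) stop("empty genome", call. = FALSE)
  s1 <- sum(vapply(covs, function(r)
    sum(as.numeric(S4Vectors::runValue(r)) * S4Vectors::runLength(r)),
    numeric(1)))
  s2 <- sum(vapply(covs, function(r)
    sum(as.numeric(S4Vectors::runValue(r))^2 * S4Vectors::runLength(r)),
    numeric(1)))
  sqrt(s2 / n - (s1 / n)^2)
}

#' Gini coefficient of per-base depth
#'
#' A scale-free summary of coverage inequality used to contrast
#' amplification gain models.
#'
#' @param alignments alignment data.frame.
#' @param contig_lengths named vector of contig lengths.
#' @return Gini coefficient in `[0, 1]`.
#' @export
coverage_gini <- function(alignments, contig_lengths) {
  covs <- contig_coverage(aln_cols(alignments), contig_lengths)
  val <- unlist(lapply(covs, function(r) as.numeric(S4Vectors::runValue(r))))
  len <- unlist(lapply(covs, function(r) S4Vectors::runLength(r)))
  o <- order(val)
  val <- val[o]; len <- len[o]
  n <- sum(len)
  mu <- sum(val * len) / n
  if (mu == 0) return(0)
  ## Gini over grouped (run-length) values
  cw <- cumsum(len)
  prev <- c(0, head(cw, -1))
  ## sum over pairs via rank formula: G = (2*sum_i rank_i x_i)/(n^2 mu) - (n+1)/n
  ranks <- prev + (len + 1) / 2   # mean rank within each run
  g <- 2 * sum(ranks * val * len) / (n^2 * mu) - (n + 1) / n
  g
}

#' Downsample reads or alignments uniformly without replacement
#'
#' @param x data.frame (rows sampled) or vector.
#' @param n number of items to keep.
#' @param seed RNG seed (sampling is deterministic given `seed`).
#' @return subset of `x`, in original order.
#' @export
downsample <- function(x, n, seed) {
  size <- if (is.data.frame(x)) nrow(x) else length(x)
  if (n > size) stop(sprintf("cannot downsample %d items to %d", size, n),
                     call. = FALSE)
  idx <- with_seed(seed, sort(sample.int(size, n)))
  if (is.data.frame(x)) x[idx, , drop = FALSE] else x[idx]
}
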