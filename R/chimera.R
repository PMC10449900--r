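## Read self-alignment chimera screen.
##
## Long reads produced after whole-genome amplification can contain
## intramolecular chimeras: fold-back inversions (the strand-displacing
## polymerase turns around and copies its own nascent strand, so the read
## carries a suffix that is the reverse complement of its preceding
## sequence) and tandem duplications. Both leave a diagnostic signature: a
## read that aligns to itself away from the trivial main diagonal (forward
## off-diagonal hit = duplication) or to its reverse complement (fold-back
## inversion).
##
## The screen seeds k-mer matches between the read and itself / its reverse
## complement, chains seeds lying within a diagonal band, and verifies each
## chained candidate by global (Needleman-Wunsch) alignment of the two read
## intervals, reporting hits with identity >= min_identity and alignment
## length >= min_hit_len. Reads with any such secondary self-hit are
## classified and removed (or split at the inferred junction).

## Positions (1-based) of every k-mer in a sequence, keyed by k-mer string.
kmer_positions <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(list(kmers = character(0), pos = integer(0)))
  pos <- seq_len(n)
  list(kmers = substring(seq, pos, pos + k - 1L), pos = pos)
}

## Chain seed pairs (a, b) sharing a diagonal (b - a) within `band`;
## returns one row per chain with the spanned intervals.
chain_seeds <- function(a, b, k, band) {
  if (!length(a)) return(NULL)
  diag <- b - a
  o <- order(diag, a)
  a <- a[o]; b <- b[o]; diag <- diag[o]
  grp <- cumsum(c(1L, diff(diag) > band))
  dt <- data.table::data.table(a = a, b = b, grp = grp)
  ch <- dt[, list(a1 = min(a), a2 = max(a) + k - 1L,
                  b1 = min(b), b2 = max(b) + k - 1L,
                  nseed = .N), by = "grp"]
  as.data.frame(ch)
}

## Identity of a global alignment of two read substrings:
## matches / alignment columns (gaps count as columns). Pairs longer than
## `max_verify` are verified on a central slice (banded-extension cap);
## the reported length stays the full chained span.
aligned_identity <- function(x, y, max_verify = 800L) {
  n <- min(nchar(x), nchar(y))
  if (n > max_verify) {
    off <- (n - max_verify) %/% 2L
    x <- substr(x, off + 1L, off + max_verify)
    y <- substr(y, off + 1L, off + max_verify)
  }
  aligned_identity_full(x, y)
}

aligned_identity_full <- function(x, y) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(x),
                                       Biostrings::DNAString(y),
                                       type = "global", substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 1)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  c(identity = Biostrings::nmatch(aln) / cols, len = cols)
}

#' Find secondary self-alignments of a read
#'
#' Detects off-diagonal forward self-hits (duplicated sequence) and
#' reverse-complement self-hits (fold-back inversions) by k-mer seeding,
#' diagonal-band chaining, and Needleman-Wunsch verification of the chained
#' interval pair. The trivial full-length forward self-match is excluded by
#' construction. Symmetric pairs are reported once (interval A starts
#' before interval B).
#'
#' @param seq read sequence (character).
#' @param k seed k-mer size (11-31; default 15).
#' @param min_identity minimum alignment identity
#'   (matches / alignment columns) for a reported hit.
#' @param min_hit_len minimum alignment length (bases).
#' @param band diagonal band width for seed chaining (bases).
#' @return data.frame of hits: `a_start`, `a_end`, `b_start`, `b_end`
#'   (1-based inclusive read intervals), `orientation`
#'   (`"forward"`/`"revcomp"`), `identity`, `length`.
#' @export
self_align <- function(seq, k = 15L, min_identity = 0.90, min_hit_len = 100L,
                       band = 50L) {
  stopifnot(k >= 11L, k <= 31L)
  empty <- data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      orientation = character(), identity = numeric(),
                      length = integer(), stringsAsFactors = FALSE)
  n <- nchar(seq)
  if (n < 2L * min_hit_len) return(empty)

  kp <- kmer_positions(seq, k)
  hits <- list()

  ## forward off-diagonal: k-mers occurring more than once
  dup <- duplicated(kp$kmers) | duplicated(kp$kmers, fromLast = TRUE)
  if (any(dup)) {
    km <- kp$kmers[dup]; po <- kp$pos[dup]
    sp <- split(po, km)
    sp <- sp[lengths(sp) >= 2L & lengths(sp) <= 10L]  # drop low-complexity
    if (length(sp)) {
      pairs <- do.call(rbind, lapply(sp, function(p) {
        cb <- utils::combn(sort(p), 2L)
        t(cb)
      }))
      a <- pairs[, 1L]; b <- pairs[, 2L]
      keep <- (b - a) > band  # off-diagonal only
      ch <- chain_seeds(a[keep], b[keep], k, band)
      if (!is.null(ch)) {
        ch <- ch[ch$nseed >= 3L &
                   (ch$a2 - ch$a1 + 1L) >= 0.5 * min_hit_len, , drop = FALSE]
        for (i in seq_len(nrow(ch))) {
          x <- substr(seq, ch$a1[i], ch$a2[i])
          y <- substr(seq, ch$b1[i], ch$b2[i])
          v <- aligned_identity(x, y)
          hit_len <- max(ch$a2[i] - ch$a1[i], ch$b2[i] - ch$b1[i]) + 1L
          if (v["identity"] >= min_identity && hit_len >= min_hit_len) {
            hits[[length(hits) + 1L]] <- data.frame(
              a_start = ch$a1[i], a_end = ch$a2[i],
              b_start = ch$b1[i], b_end = ch$b2[i],
              orientation = "forward", identity = unname(v["identity"]),
              length = as.integer(hit_len), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }

  ## reverse complement: shared k-mers between the read and its rc
  rc <- revcomp(seq)
  kprc <- kmer_positions(rc, k)
  dtf <- data.table::data.table(km = kp$kmers, a = kp$pos)
  dtr <- data.table::data.table(km = kprc$kmers, b = kprc$pos)
  ## drop high-multiplicity (low-complexity) k-mers before joining
  dtf <- dtf[, if (.N <= 10L) .SD, by = "km"]
  dtr <- dtr[, if (.N <= 10L) .SD, by = "km"]
  pairs <- merge(dtf, dtr, by = "km", allow.cartesian = TRUE)
  if (nrow(pairs)) {
    {
      ## keep only pairs whose mapped-back partner interval lies downstream
      ## of the seed; a fold-back is a contiguous palindrome, so without
      ## this the chain merges with its own symmetric twin
      rb <- n - pairs$b - k + 2L
      keep <- rb > pairs$a
      ch <- chain_seeds(pairs$a[keep], pairs$b[keep], k, band)
      if (!is.null(ch)) {
        ch <- ch[ch$nseed >= 3L &
                   (ch$a2 - ch$a1 + 1L) >= 0.5 * min_hit_len, , drop = FALSE]
        for (i in seq_len(nrow(ch))) {
          ## map the rc interval back to read coordinates
          rb1 <- n - ch$b2[i] + 1L
          rb2 <- n - ch$b1[i] + 1L
          x <- substr(seq, ch$a1[i], ch$a2[i])
          y <- revcomp(substr(seq, rb1, rb2))
          v <- aligned_identity(x, y)
          hit_len <- max(ch$a2[i] - ch$a1[i], rb2 - rb1) + 1L
          if (v["identity"] >= min_identity && hit_len >= min_hit_len) {
            hits[[length(hits) + 1L]] <- data.frame(
              a_start = ch$a1[i], a_end = ch$a2[i],
              b_start = rb1, b_end = rb2,
              orientation = "revcomp", identity = unname(v["identity"]),
              length = as.integer(hit_len), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  ## deduplicate near-identical interval pairs
  out <- out[!duplicated(paste(out$orientation, out$a_start %/% 20,
                               out$b_start %/% 20)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify self-hits into a chimera verdict with junction positions
#'
#' A reverse-complement self-hit marks a fold-back inversion; a forward
#' off-diagonal hit marks a duplication; both present marks a complex
#' chimera. The junction of a hit is placed at the midpoint between the
#' paired intervals.
#'
#' @param hits data.frame from [self_align()].
#' @return list with `verdict` (`"CLEAN"`, `"INVERSION"`, `"DUPLICATION"`
#'   or `"COMPLEX"`) and `junctions` (integer read positions).
#' @export
classify_chimera <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(list(verdict = "CLEAN", junctions = integer(0)))
  }
  has_rc <- any(hits$orientation == "revcomp")
  has_fw <- any(hits$orientation == "forward")
  verdict <- if (has_rc && has_fw) "COMPLEX"
             else if (has_rc) "INVERSION" else "DUPLICATION"
  ## junction at the midpoint between the paired intervals; for the
  ## (near-)contiguous intervals of a fold-back this lands at the turn point
  junctions <- vapply(seq_len(nrow(hits)), function(i) {
    as.integer(round((hits$a_end[i] + hits$b_start[i]) / 2))
  }, integer(1))
  list(verdict = verdict, junctions = sort(unique(junctions)))
}

#' Screen a set of reads for intramolecular chimeras
#'
#' Applies [self_align()] and [classify_chimera()] to every read; reads
#' with any secondary self-hit at or above the identity threshold are
#' removed.
#'
#' @param reads data.frame with `read_id` and `sequence` (a `read_set$reads`
#'   works directly).
#' @param k,min_identity,min_hit_len,band see [self_align()]. The default
#'   identity threshold of 0.90 removes reads with a secondary self-hit at
#'   more than 90% identity.
#' @return list with `passed` and `removed` (row subsets of `reads`),
#'   `report` (data.frame: `read_id`, `verdict`, `n_junctions`,
#'   `junctions` comma-separated) and `stats` (pass fraction and
#'   per-verdict counts).
#' @export
filter_reads <- function(reads, k = 15L, min_identity = 0.90,
                         min_hit_len = 100L, band = 50L) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  verdicts <- character(nrow(reads))
  juncs <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    h <- self_align(reads$sequence[i], k = k, min_identity = min_identity,
                    min_hit_len = min_hit_len, band = band)
    cl <- classify_chimera(h)
    verdicts[i] <- cl$verdict
    juncs[[i]] <- cl$junctions
  }
  report <- data.frame(
    read_id = reads$read_id, verdict = verdicts,
    n_junctions = lengths(juncs),
    junctions = vapply(juncs, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  clean <- verdicts == "CLEAN"
  stats <- list(
    n_reads = nrow(reads), n_passed = sum(clean),
    pass_fraction = if (nrow(reads)) sum(clean) / nrow(reads) else NA_real_,
    verdict_counts = table(factor(verdicts, levels = c("CLEAN", "INVERSION",
                                                       "DUPLICATION", "COMPLEX"))))
  list(passed = reads[clean, , drop = FALSE],
       removed = reads[!clean, , drop = FALSE],
       report = report, stats = stats)
}

#' Split a chimeric read into non-chimeric subreads
#'
#' Cuts the read at each detected junction, trims `trim` bases on each side
#' of every cut, and discards subreads shorter than `min_len`.
#'
#' @param sequence read sequence.
#' @param junctions integer junction positions (from [classify_chimera()]).
#' @param trim bases trimmed on each side of each cut.
#' @param min_len minimum subread length kept.
#' @return data.frame with `start`, `end` (1-based inclusive intervals on
#'   the original read) and `sequence`.
#' @export
split_read <- function(sequence, junctions, trim = 50L, min_len = 200L) {
  n <- nchar(sequence)
  if (!length(junctions)) {
    stop("split_read() requires a non-CLEAN read with at least one junction",
         call. = FALSE)
  }
  if (any(junctions < 1L | junctions > n)) {
    stop("junction outside read bounds: internal inconsistency", call. = FALSE)
  }
  cuts <- sort(unique(junctions))
  starts <- c(1L, cuts + trim + 1L)
  ends <- c(cuts - trim, n)
  keep <- (ends - starts + 1L) >= min_len & starts >= 1L & ends <= n & starts <= ends
  data.frame(start = starts[keep], end = ends[keep],
             sequence = substring(sequence, starts[keep], ends[keep]),
             stringsAsFactors = FALSE)
}

#' N50 of aligned segment lengths
#'
#' The length L such that segments of length >= L cover at least half of
#' the total aligned bases.
#'
#' @param lengths aligned-segment lengths in bases (or an alignment
#'   data.frame with `tstart`/`tend` columns, e.g. from [read_paf()]).
#' @return N50 in bases.
#' @export
aligned_n50 <- function(lengths) {
  if (is.data.frame(lengths)) lengths <- lengths$tend - lengths$tstart
  if (!length(lengths)) stop("N50 of an empty set is undefined", call. = FALSE)
  l <- sort(as.numeric(lengths), decreasing = TRUE)
  l[which(cumsum(l) >= sum(l) / 2)[1L]]
}
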