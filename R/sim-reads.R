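## Read generation. Reads are sampled from amplified fragment copies in
## proportion to copy number x fragment length; each read spans its full
## fragment. A read drawn from a chimeric copy is restructured as a
## fold-back inversion (suffix rejoined as reverse complement at an internal
## breakpoint), a tandem duplication (an internal 200-2000 bp window
## repeated), or an intermolecular junction between two fragments sharing a
## droplet. Truth segments record the reference provenance of every read
## portion, including '-' strand (inverted) and repeated (duplicated)
## intervals.

QUAL_OFFSET <- 33L

## Project one read part (haplotype interval [hs,he), optionally reverse
## complemented) into reference truth segments with absolute read offsets.
project_read_part <- function(map, contig, hs, he, rc, read_off) {
  segs <- project_hap_interval(map, hs, he)
  w <- he - hs
  if (rc) {
    segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
    new_start <- w - segs$off_end
    new_end <- w - segs$off_start
    segs$off_start <- new_start
    segs$off_end <- new_end
    segs$strand <- ifelse(segs$strand == "+", "-", "+")
  }
  data.frame(contig = contig, ref_start = segs$ref_start,
             ref_end = segs$ref_end, strand = segs$strand,
             read_start = read_off + segs$off_start,
             read_end = read_off + segs$off_end, stringsAsFactors = FALSE)
}

## Truth segments for a (possibly wrapping) mitochondrial interval.
mito_segments <- function(contig, s, e, L, read_off) {
  len <- e - s
  s <- s %% L
  e2 <- s + len
  if (e2 <= L) {
    data.frame(contig = contig, ref_start = s, ref_end = e2, strand = "+",
               read_start = read_off, read_end = read_off + (e2 - s),
               stringsAsFactors = FALSE)
  } else {
    w1 <- L - s
    data.frame(contig = contig, ref_start = c(s, 0L), ref_end = c(L, e2 - L),
               strand = "+",
               read_start = read_off + c(0L, w1),
               read_end = read_off + c(w1, e2 - s), stringsAsFactors = FALSE)
  }
}

## Applied in one batch over the concatenation of all reads: error
## positions are iid per base, so sampling over the pooled bases is
## equivalent to sampling per read.
apply_substitution_errors <- function(seqs, rate, indel_frac) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  ch <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
  N <- length(ch)
  k <- rbinom(1L, N, rate)
  if (k > 0L) {
    pos <- sample.int(N, k)
    is_indel <- runif(k) < indel_frac
    sub_pos <- pos[!is_indel]
    if (length(sub_pos)) {
      ## substitute with one of the three other bases, vectorized
      shift <- sample.int(3L, length(sub_pos), replace = TRUE)
      ch[sub_pos] <- DNA_BASES[(match(ch[sub_pos], DNA_BASES) - 1L + shift) %% 4L + 1L]
    }
    ind_pos <- pos[is_indel]
    if (length(ind_pos)) {
      del <- runif(length(ind_pos)) < 0.5
      ch[ind_pos[del]] <- ""
      ins <- ind_pos[!del]
      if (length(ins)) {
        ch[ins] <- paste0(ch[ins], sample(DNA_BASES, length(ins), replace = TRUE))
      }
    }
  }
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1L) + 1L)
  vapply(seq_along(seqs), function(i)
    paste(ch[starts[i]:ends[i]], collapse = ""), character(1))
}

#' Generate long reads (with truth) from amplified fragments
#'
#' @param amplified data.frame from [amplify()] (single cell).
#' @param genome the `sim_genome`.
#' @param cfg the `sim_config`.
#' @param n_reads number of reads to sample.
#' @param emit_sequence if `FALSE`, skip base-level sequence and error
#'   simulation and return truth intervals only (used by coverage
#'   experiments where only alignment geometry matters).
#' @param seed optional seed override.
#' @return object of class `read_set`: list with `reads` (data.frame:
#'   `read_id`, `cell_id`, `frag_id`, `length`, `is_chimeric`,
#'   `chimera_type`, `sequence` if emitted) and `segments` (truth
#'   alignments: `read_id`, `contig`, `ref_start`, `ref_end`, `strand`,
#'   `read_start`, `read_end`; 0-based half-open).
#' @export
generate_reads <- function(amplified, genome, cfg, n_reads,
                           emit_sequence = TRUE, seed = NULL) {
  stopifnot(nrow(amplified) > 0, n_reads >= 0)
  cell_id <- amplified$cell_id[1]
  clone <- sample_clone(cfg, cell_id)
  if (is.null(seed)) seed <- child_seed(cfg$seed, paste0("reads_", cell_id))
  with_seed(seed, {
    ## haplotype sequences and block maps, built once per (contig, hap)
    haps <- list()
    get_hap <- function(contig, hap) {
      key <- paste0(contig, "_", hap)
      if (is.null(haps[[key]])) {
        if (hap == "mito") {
          sq <- genome$contigs[[contig]]
          haps[[key]] <<- list(seq = paste0(sq, sq),  # doubled for wrap
                               map = NULL, L = nchar(sq))
        } else {
          haps[[key]] <<- c(build_haplotype(genome, contig, clone,
                                            as.integer(hap)), list(L = NA))
        }
      }
      haps[[key]]
    }

    wt <- amplified$copies * (amplified$end - amplified$start)
    idx <- sample.int(nrow(amplified), n_reads, replace = TRUE, prob = wt)
    p_inv <- amplified$n_inv / amplified$copies
    p_dup <- amplified$n_dup / amplified$copies
    p_im <- amplified$n_im / amplified$copies
    im_events <- attr(amplified, "im_events")

    ## vectorized chimera-type draw
    u <- runif(n_reads)
    is_mito_v <- amplified$haplotype[idx] == "mito"
    pi_v <- p_inv[idx]; pd_v <- p_dup[idx]; pm_v <- p_im[idx]
    type_v <- rep("NONE", n_reads)
    type_v[!is_mito_v & u < pi_v] <- "INVERSION"
    type_v[!is_mito_v & u >= pi_v & u < pi_v + pd_v] <- "DUPLICATION"
    im_ok <- !is.null(im_events) && nrow(im_events) > 0
    type_v[!is_mito_v & u >= pi_v + pd_v & u < pi_v + pd_v + pm_v &
             (if (im_ok) amplified$frag_id[idx] %in% im_events$frag_a
              else FALSE)] <- "INTERMOLECULAR"
    read_ids <- sprintf("%s_r%06d", cell_id, seq_len(n_reads))
    hp <- genome$heteroplasmy

    ## fast path: non-chimeric reads from single-block (identity-like) maps
    ## and non-chimeric mitochondrial reads are built vectorized; everything
    ## else goes through the general per-read path below
    simple_map <- vapply(unique(amplified$contig[idx][!is_mito_v]), function(cn) {
      nrow(get_hap(cn, "1")$map) == 1L && nrow(get_hap(cn, "2")$map) == 1L
    }, logical(1))
    simple_nuc <- which(type_v == "NONE" & !is_mito_v &
                          simple_map[amplified$contig[idx]])
    simple_mito <- which(type_v == "NONE" & is_mito_v)
    loop_idx <- setdiff(seq_len(n_reads), c(simple_nuc, simple_mito))

    reads <- vector("list", n_reads)
    segl <- vector("list", n_reads)
    seq_v <- rep(NA_character_, n_reads)
    seg_fast <- list()

    if (length(simple_nuc)) {
      fi <- idx[simple_nuc]
      s <- amplified$start[fi]; e <- amplified$end[fi]
      cn <- amplified$contig[fi]; hap <- amplified$haplotype[fi]
      if (emit_sequence) {
        for (key in unique(paste0(cn, "_", hap))) {
          parts <- strsplit(key, "_(?=[^_]+$)", perl = TRUE)[[1]]
          sel <- cn == parts[1] & hap == parts[2]
          h <- get_hap(parts[1], parts[2])
          off <- h$map$ref_start[1] - h$map$hap_start[1]
          seq_v[simple_nuc[sel]] <- substring(h$seq, s[sel] + 1L, e[sel])
        }
      }
      ## single-block map: haplotype == reference coordinates up to offset
      seg_fast$nuc <- data.frame(
        read_id = read_ids[simple_nuc], contig = cn,
        ref_start = s, ref_end = e, strand = "+",
        read_start = 0L, read_end = e - s, stringsAsFactors = FALSE)
    }
    if (length(simple_mito)) {
      fi <- idx[simple_mito]
      s <- amplified$start[fi]; e <- amplified$end[fi]
      cn <- amplified$contig[fi]
      h <- get_hap(cn[1], "mito")
      L <- h$L
      len <- e - s; sm <- s %% L; e2 <- sm + len
      if (emit_sequence) {
        seq_v[simple_mito] <- substring(h$seq, sm + 1L, sm + len)
        if (clone == hp$clone && cn[1] == hp$contig) {
          ## per-read heteroplasmic allele draw at the planted site
          off <- (hp$pos - sm) %% L
          carrier <- off < len & runif(length(fi)) < hp$frequency
          for (j in which(carrier)) {
            sq <- seq_v[simple_mito[j]]
            substr(sq, off[j] + 1L, off[j] + 1L) <- hp$alt
            seq_v[simple_mito[j]] <- sq
          }
        }
      }
      wrap <- e2 > L
      seg_fast$mito1 <- data.frame(
        read_id = read_ids[simple_mito], contig = cn,
        ref_start = sm, ref_end = pmin(e2, L), strand = "+",
        read_start = 0L, read_end = pmin(e2, L) - sm,
        stringsAsFactors = FALSE)
      if (any(wrap)) {
        seg_fast$mito2 <- data.frame(
          read_id = read_ids[simple_mito[wrap]], contig = cn[wrap],
          ref_start = 0L, ref_end = e2[wrap] - L, strand = "+",
          read_start = (L - sm[wrap]), read_end = len[wrap],
          stringsAsFactors = FALSE)
      }
    }

    for (r in loop_idx) {
      f <- amplified[idx[r], ]
      is_mito <- f$haplotype == "mito"
      type <- type_v[r]
      h <- get_hap(f$contig, f$haplotype)
      s <- f$start; e <- f$end; len <- e - s
      read_id <- read_ids[r]
      if (is_mito) {
        sq <- if (emit_sequence) substr(h$seq, (s %% h$L) + 1L,
                                        (s %% h$L) + len) else NA_character_
        segs <- mito_segments(f$contig, s, e, h$L, 0L)
        if (emit_sequence && clone == hp$clone && f$contig == hp$contig) {
          ## per-read heteroplasmic allele draw at the planted site
          off <- (hp$pos - (s %% h$L)) %% h$L
          if (off < len && runif(1) < hp$frequency) {
            substr(sq, off + 1L, off + 1L) <- hp$alt
          }
        }
      } else if (type == "NONE") {
        sq <- if (emit_sequence) substr(h$seq, s + 1L, e) else NA_character_
        segs <- project_read_part(h$map, f$contig, s, e, FALSE, 0L)
      } else if (type == "INVERSION") {
        b <- s + max(2L, round(runif(1, 0.4, 0.7) * len))
        arm2 <- max(1L, round(runif(1, 0.5, 1.0) * (b - s)))
        sq <- if (emit_sequence) {
          paste0(substr(h$seq, s + 1L, b),
                 revcomp(substr(h$seq, b - arm2 + 1L, b)))
        } else NA_character_
        segs <- rbind(
          project_read_part(h$map, f$contig, s, b, FALSE, 0L),
          project_read_part(h$map, f$contig, b - arm2, b, TRUE, b - s))
      } else if (type == "DUPLICATION") {
        w <- min(len - 2L, sample(200:2000, 1L))
        w <- max(50L, w)
        w1 <- s + sample.int(max(1L, len - w - 1L), 1L)
        sq <- if (emit_sequence) {
          paste0(substr(h$seq, s + 1L, w1 + w),
                 substr(h$seq, w1 + 1L, e))
        } else NA_character_
        segs <- rbind(
          project_read_part(h$map, f$contig, s, w1 + w, FALSE, 0L),
          project_read_part(h$map, f$contig, w1, e, FALSE, (w1 + w) - s))
      } else { # INTERMOLECULAR
        ev <- im_events[im_events$frag_a == f$frag_id, , drop = FALSE][1, ]
        g <- amplified[amplified$frag_id == ev$frag_b, ][1, ]
        h2 <- get_hap(g$contig, g$haplotype)
        mid1 <- s + max(1L, len %/% 2L)
        glen <- g$end - g$start
        mid2 <- g$start + max(1L, glen %/% 2L)
        if (g$haplotype == "mito" || is_mito) {
          ## junctions involving mito copies are skipped at this scale
          sq <- if (emit_sequence) substr(h$seq, s + 1L, e) else NA_character_
          segs <- project_read_part(h$map, f$contig, s, e, FALSE, 0L)
          type <- "NONE"
        } else {
          sq <- if (emit_sequence) {
            paste0(substr(h$seq, s + 1L, mid1), substr(h2$seq, mid2 + 1L, g$end))
          } else NA_character_
          segs <- rbind(
            project_read_part(h$map, f$contig, s, mid1, FALSE, 0L),
            project_read_part(h2$map, g$contig, mid2, g$end, FALSE, mid1 - s))
        }
      }
      segs$read_id <- read_id
      segl[[r]] <- segs
      seq_v[r] <- sq
      type_v[r] <- type
    }
    segments <- rbind(do.call(rbind, seg_fast), do.call(rbind, segl))
    segments <- segments[order(match(segments$read_id, read_ids)),
                         c("read_id", "contig", "ref_start", "ref_end",
                           "strand", "read_start", "read_end")]
    len_v <- vapply(split(segments$read_end, segments$read_id)[read_ids],
                    max, numeric(1))
    reads <- data.frame(
      read_id = read_ids, cell_id = cell_id, frag_id = amplified$frag_id[idx],
      length = as.integer(len_v), is_chimeric = type_v != "NONE",
      chimera_type = type_v, sequence = seq_v, stringsAsFactors = FALSE)
    rownames(reads) <- rownames(segments) <- NULL
    if (emit_sequence && cfg$read_error_rate > 0) {
      reads$sequence <- apply_substitution_errors(
        reads$sequence, cfg$read_error_rate, cfg$error_indel_frac)
    }
    structure(list(reads = reads, segments = segments, cell_id = cell_id),
              class = "read_set")
  })
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads from %s (%d chimeric: %s)\n",
              nrow(x$reads), x$cell_id, sum(x$reads$is_chimeric),
              paste(names(table(x$reads$chimera_type[x$reads$is_chimeric])),
                    table(x$reads$chimera_type[x$reads$is_chimeric]),
                    sep = "=", collapse = " ")))
  invisible(x)
}

## ---- I/O ----------------------------------------------------------------

#' Write reads to FASTQ (constant quality)
#' @param read_set a `read_set` with sequences.
#' @param path output file.
#' @param qv constant per-base quality value.
#' @export
write_fastq <- function(read_set, path, qv = 20L) {
  r <- read_set$reads
  stopifnot(!anyNA(r$sequence))
  qchar <- rawToChar(as.raw(QUAL_OFFSET + qv))
  lines <- character(4L * nrow(r))
  lines[seq(1, length(lines), 4)] <- paste0("@", r$read_id)
  lines[seq(2, length(lines), 4)] <- r$sequence
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- strrep(qchar, nchar(r$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a minimal read table
#' @param path FASTQ file.
#' @return data.frame with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub(" .*", "", names(x)),
             sequence = as.character(x), stringsAsFactors = FALSE)
}

#' Write truth alignments as PAF (12 mandatory columns)
#'
#' One line per truth segment; query/target coordinates are 0-based
#' half-open as PAF requires.
#'
#' @param read_set a `read_set`.
#' @param genome the `sim_genome` (for contig lengths).
#' @param path output file.
#' @export
write_paf <- function(read_set, genome, path) {
  s <- read_set$segments
  s <- s[s$ref_end > s$ref_start, , drop = FALSE]  # drop insertion stubs
  rl <- setNames(read_set$reads$length, read_set$reads$read_id)
  tl <- nchar(genome$contigs)[s$contig]
  span <- s$read_end - s$read_start
  df <- data.frame(
    qname = s$read_id, qlen = as.integer(rl[s$read_id]),
    qstart = s$read_start, qend = s$read_end, strand = s$strand,
    tname = s$contig, tlen = as.integer(tl),
    tstart = s$ref_start, tend = s$ref_end,
    nmatch = span, alen = span, mapq = 60L, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a PAF file into an alignment data.frame
#' @param path PAF file.
#' @return data.frame with the 12 mandatory PAF columns (coordinates
#'   0-based half-open).
#' @export
read_paf <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = FALSE,
                          select = 1:12, data.table = FALSE)
  names(df) <- c("qname", "qlen", "qstart", "qend", "strand", "tname",
                 "tlen", "tstart", "tend", "nmatch", "alen", "mapq")
  df
}

#' Write a genome's contigs to FASTA
#' @param genome a `sim_genome`.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
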