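## Genome simulation: a diploid nuclear contig plus a circular mitochondrial
## contig, with planted germline SNVs, structural variants (ALU-like ~300 bp
## and LINE-like ~6 kb length modes), tandem-repeat loci, per-clone somatic
## SNVs, and one heteroplasmic mitochondrial site confined to clone B.
##
## Coordinates are 0-based half-open throughout; 1-based only at VCF/PAF
## emission.

MITO_CONTIG <- "chrM"
NUC_CONTIG <- "chr1"

empty_variant_df <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), svtype = character(), svlen = integer(),
             end = integer(), genotype = character(), seq = character(),
             source = character(), stringsAsFactors = FALSE)
}

## Rejection-sample a non-overlapping placement; errors with the name of the
## first feature that cannot be placed.
place_features <- function(lens, occupied, L, pad, what, max_try = 500L) {
  starts <- integer(length(lens))
  for (i in seq_along(lens)) {
    len <- lens[i]
    placed <- FALSE
    if (L - len - 2L > 2L * pad) {
      for (tr in seq_len(max_try)) {
        s <- sample.int(L - len - 1L, 1L)
        cand <- IRanges::IRanges(s + 1L - pad, s + len + pad)
        if (length(occupied) == 0L ||
            sum(IRanges::countOverlaps(cand, occupied)) == 0L) {
          starts[i] <- s
          occupied <- c(occupied, IRanges::IRanges(s + 1L, s + len))
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      stop(sprintf("cannot place %s #%d (length %d) without overlap; genome too short or too crowded",
                   what, i, len), call. = FALSE)
    }
  }
  list(starts = starts, occupied = occupied)
}

## Vectorized placement of n single-base features avoiding `occupied`.
place_points <- function(n, occupied, L, what, max_round = 50L) {
  pos <- integer(0)
  for (r in seq_len(max_round)) {
    need <- n - length(pos)
    if (need <= 0L) break
    cand <- sample.int(L, need * 2L, replace = TRUE) - 1L
    cand <- unique(cand)
    if (length(occupied)) {
      ov <- IRanges::countOverlaps(IRanges::IRanges(cand + 1L, width = 1L),
                                   occupied) > 0L
      cand <- cand[!ov]
    }
    cand <- setdiff(cand, pos)
    pos <- c(pos, head(cand, need))
  }
  if (length(pos) < n) {
    stop(sprintf("cannot place %s #%d without overlap; genome too short or too crowded",
                 what, length(pos) + 1L), call. = FALSE)
  }
  list(starts = pos,
       occupied = c(occupied, IRanges::IRanges(pos + 1L, width = 1L)))
}

draw_sv_lengths <- function(n, model) {
  comp <- sample.int(length(model$modes), n, replace = TRUE, prob = model$weights)
  len <- round(rnorm(n, mean = model$modes[comp], sd = model$sds[comp]))
  pmax(50L, as.integer(len))
}

random_genotype <- function(n) {
  sample(c("1|0", "0|1", "1|1"), n, replace = TRUE, prob = c(1, 1, 1) / 3)
}

genotype_has_hap <- function(gt, hap) {
  if (hap == 1) substr(gt, 1, 1) == "1" else substr(gt, 3, 3) == "1"
}

#' Simulate a two-clone diploid genome with planted variation
#'
#' Generates a random nuclear contig and a circular mitochondrial contig,
#' then plants (in this order, all mutually non-overlapping): tandem-repeat
#' loci (kept at least 200 bp away from any SV breakpoint), structural
#' variants with per-type length mixtures, germline SNVs, per-clone somatic
#' SNVs, and one heteroplasmic mitochondrial substitution assigned to
#' clone B.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `sim_genome`: list with `contigs`
#'   (named character vector of sequences), `circular` (named logical),
#'   `germline` (variant data.frame, 0-based `pos`), `tr_loci`
#'   (data.frame of repeat loci with per-haplotype length differences in bp),
#'   `clone_somatic` (named list of SNV data.frames), `heteroplasmy`
#'   (list: contig, pos, ref, alt, frequency, clone) and `config`.
#' @export
simulate_genome <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(child_seed(cfg$seed, "genome"), {
    L <- cfg$genome_length
    nuc <- random_dna(L)
    mito <- random_dna(cfg$mito_length)
    occupied <- IRanges::IRanges()

    ## tandem-repeat loci (planted first; 200 bp padding keeps SV breakpoints
    ## at distance)
    tr <- NULL
    if (cfg$n_tr_loci > 0) {
      units <- sample(cfg$tr_unit_sizes, cfg$n_tr_loci, replace = TRUE)
      copies <- sample(10:40, cfg$n_tr_loci, replace = TRUE)
      lens <- units * copies
      pl <- place_features(lens, occupied, L, pad = 200L, what = "tr_locus")
      occupied <- pl$occupied
      unit_seq <- vapply(units, random_dna, character(1))
      ## heterozygous expansions/contractions in repeat units
      zyg <- sample(c("ref", "het", "hom"), cfg$n_tr_loci, replace = TRUE,
                    prob = c(0.4, 0.5, 0.1))
      d_units <- sample(1:5, cfg$n_tr_loci, replace = TRUE) *
        sample(c(-1L, 1L), cfg$n_tr_loci, replace = TRUE)
      ## contractions must leave at least one copy
      d_units <- ifelse(d_units < 0 & -d_units >= copies - 1L, 1L, d_units)
      hap1 <- ifelse(zyg == "ref", 0L, d_units * units)
      hap2 <- ifelse(zyg == "hom", d_units * units, 0L)
      which_hap <- sample(1:2, cfg$n_tr_loci, replace = TRUE)
      tmp1 <- ifelse(zyg == "het" & which_hap == 2, 0L, hap1)
      hap2 <- ifelse(zyg == "het" & which_hap == 2, hap1, hap2)
      hap1 <- tmp1
      tr <- data.frame(
        locus_id = sprintf("TR%04d", seq_len(cfg$n_tr_loci)),
        contig = NUC_CONTIG, start = pl$starts, end = pl$starts + lens,
        unit = unit_seq, unit_size = units, ref_copies = copies,
        hap1_diff = as.integer(hap1), hap2_diff = as.integer(hap2),
        stringsAsFactors = FALSE
      )
      ## overwrite reference with the repeat array
      for (i in seq_len(nrow(tr))) {
        arr <- strrep(tr$unit[i], tr$ref_copies[i])
        substr(nuc, tr$start[i] + 1L, tr$end[i]) <- arr
      }
      tr <- tr[order(tr$start), ]
      rownames(tr) <- NULL
    } else {
      tr <- data.frame(locus_id = character(), contig = character(),
                       start = integer(), end = integer(), unit = character(),
                       unit_size = integer(), ref_copies = integer(),
                       hap1_diff = integer(), hap2_diff = integer(),
                       stringsAsFactors = FALSE)
    }

    ## structural variants
    svs <- empty_variant_df()
    for (type in c("DEL", "INS", "DUP", "INV")) {
      n <- as.integer(cfg$sv_counts[[type]])
      if (n == 0L) next
      lens <- draw_sv_lengths(n, cfg$sv_length_models[[type]])
      span <- if (type == "INS") rep(1L, n) else lens
      pl <- place_features(span, occupied, L, pad = 200L,
                           what = paste0("sv_", type))
      occupied <- pl$occupied
      pos <- pl$starts
      df <- data.frame(
        contig = NUC_CONTIG, pos = pos,
        ref = substr(rep(nuc, n), pos + 1L, pos + 1L),
        alt = sprintf("<%s>", type), svtype = type,
        svlen = if (type == "DEL") -lens else lens,
        end = if (type == "INS") pos + 1L else pos + lens,
        genotype = random_genotype(n),
        seq = if (type == "INS") vapply(lens, random_dna, character(1)) else "",
        source = "germline", stringsAsFactors = FALSE
      )
      svs <- rbind(svs, df)
    }

    ## germline SNVs (outside all planted intervals)
    n_snv <- rbinom(1L, L, cfg$germline_snv_rate)
    snvs <- empty_variant_df()
    if (n_snv > 0) {
      pl <- place_points(n_snv, occupied, L, what = "snv")
      occupied <- pl$occupied
      pos <- pl$starts
      ref <- substr(rep(nuc, n_snv), pos + 1L, pos + 1L)
      alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), character(1))
      snvs <- data.frame(contig = NUC_CONTIG, pos = pos, ref = ref, alt = alt,
                         svtype = "SNV", svlen = 0L, end = pos + 1L,
                         genotype = random_genotype(n_snv), seq = "",
                         source = "germline", stringsAsFactors = FALSE)
    }
    germline <- rbind(svs, snvs)
    germline <- germline[order(germline$contig, germline$pos), ]
    rownames(germline) <- NULL

    ## somatic SNVs, disjoint between clones and from germline sites
    clone_somatic <- list(A = empty_variant_df(), B = empty_variant_df())
    for (clone in c("A", "B")) {
      n <- cfg$somatic_snvs_per_clone
      if (n == 0L) next
      pl <- place_points(n, occupied, L, what = paste0("somatic_snv_", clone))
      occupied <- pl$occupied
      pos <- pl$starts
      ref <- substr(rep(nuc, n), pos + 1L, pos + 1L)
      alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), character(1))
      df <- data.frame(contig = NUC_CONTIG, pos = pos, ref = ref, alt = alt,
                       svtype = "SNV", svlen = 0L, end = pos + 1L,
                       genotype = sample(c("1|0", "0|1"), n, replace = TRUE),
                       seq = "", source = paste0("somatic_", clone),
                       stringsAsFactors = FALSE)
      clone_somatic[[clone]] <- df[order(df$pos), ]
    }

    ## heteroplasmic mitochondrial site (clone B)
    hpos <- sample.int(cfg$mito_length, 1L) - 1L
    href <- substr(mito, hpos + 1L, hpos + 1L)
    heteroplasmy <- list(contig = MITO_CONTIG, pos = hpos, ref = href,
                         alt = sample(setdiff(DNA_BASES, href), 1L),
                         frequency = cfg$heteroplasmy_frequency, clone = "B")

    genome <- list(
      contigs = c(setNames(nuc, NUC_CONTIG), setNames(mito, MITO_CONTIG)),
      circular = c(chr1 = FALSE, chrM = TRUE),
      germline = germline,
      tr_loci = tr,
      clone_somatic = clone_somatic,
      heteroplasmy = heteroplasmy,
      config = cfg
    )
    class(genome) <- "sim_genome"
    genome
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %d contigs (%s bp nuclear, %d bp mito, circular)\n",
              length(x$contigs), format(nchar(x$contigs[[NUC_CONTIG]]), big.mark = ","),
              nchar(x$contigs[[MITO_CONTIG]])))
  tab <- table(x$germline$svtype)
  cat("  germline:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat(sprintf("  tr_loci: %d; somatic SNVs: A=%d B=%d; heteroplasmy %s:%d %s>%s @ %.2f in clone %s\n",
              nrow(x$tr_loci), nrow(x$clone_somatic$A), nrow(x$clone_somatic$B),
              x$heteroplasmy$contig, x$heteroplasmy$pos, x$heteroplasmy$ref,
              x$heteroplasmy$alt, x$heteroplasmy$frequency, x$heteroplasmy$clone))
  invisible(x)
}

## Variant table for one (clone, haplotype) pair: germline variants on that
## haplotype, TR length differences represented as insertions/deletions at
## the locus end, and the clone's somatic SNVs.
hap_variant_table <- function(genome, clone, hap) {
  g <- genome$germline
  g <- g[genotype_has_hap(g$genotype, hap), , drop = FALSE]
  som <- genome$clone_somatic[[clone]]
  if (!is.null(som) && nrow(som)) {
    som <- som[genotype_has_hap(som$genotype, hap), , drop = FALSE]
    g <- rbind(g, som)
  }
  tr <- genome$tr_loci
  if (nrow(tr)) {
    diffs <- if (hap == 1) tr$hap1_diff else tr$hap2_diff
    keep <- diffs != 0L
    if (any(keep)) {
      tr <- tr[keep, , drop = FALSE]
      diffs <- diffs[keep]
      ins <- diffs > 0
      trv <- data.frame(
        contig = tr$contig,
        pos = ifelse(ins, tr$end, tr$end + diffs),  # deletion removes tail units
        ref = "N", alt = ifelse(ins, "<INS>", "<DEL>"),
        svtype = ifelse(ins, "INS", "DEL"),
        svlen = diffs,
        end = ifelse(ins, tr$end + 1L, tr$end),
        genotype = "",
        seq = ifelse(ins, strrep(tr$unit, pmax(0L, diffs) %/% tr$unit_size), ""),
        source = "tr", stringsAsFactors = FALSE
      )
      g <- rbind(g, trv)
    }
  }
  g <- g[order(g$contig, g$pos), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Build one haplotype sequence and its reference block map
#'
#' Applies the haplotype's structural variants (and tandem-repeat length
#' differences) to the reference contig, recording a block map from
#' haplotype coordinates to reference coordinates, then applies SNV
#' substitutions in place. The map is what turns read intervals into truth
#' alignments, including inverted ('-' strand) and duplicated (repeated
#' interval) segments.
#'
#' @param genome a `sim_genome`.
#' @param contig contig name.
#' @param clone clone id ("A"/"B"); ignored for the mitochondrial contig.
#' @param hap haplotype (1 or 2).
#' @return list with `seq` (character) and `map` (data.frame with 0-based
#'   half-open `hap_start`, `hap_end`, `ref_start`, `ref_end`, `strand`).
#' @export
build_haplotype <- function(genome, contig, clone, hap) {
  refseq <- genome$contigs[[contig]]
  L <- nchar(refseq)
  if (contig == MITO_CONTIG) {
    return(list(seq = refseq,
                map = data.frame(hap_start = 0L, hap_end = L, ref_start = 0L,
                                 ref_end = L, strand = "+",
                                 stringsAsFactors = FALSE)))
  }
  vars <- hap_variant_table(genome, clone, hap)
  svvars <- vars[vars$svtype != "SNV", , drop = FALSE]
  snvvars <- vars[vars$svtype == "SNV", , drop = FALSE]

  pieces <- character(0)
  map <- list()
  cur_ref <- 0L
  cur_hap <- 0L
  add_block <- function(rs, re, strand, piece) {
    w <- nchar(piece)
    map[[length(map) + 1L]] <<- data.frame(
      hap_start = cur_hap, hap_end = cur_hap + w, ref_start = rs, ref_end = re,
      strand = strand, stringsAsFactors = FALSE)
    pieces[length(pieces) + 1L] <<- piece
    cur_hap <<- cur_hap + w
  }
  emit_match <- function(to) {
    if (to > cur_ref) {
      add_block(cur_ref, to, "+", substr(refseq, cur_ref + 1L, to))
      cur_ref <<- to
    }
  }
  if (nrow(svvars)) {
    for (i in seq_len(nrow(svvars))) {
      v <- svvars[i, ]
      emit_match(v$pos)
      if (v$svtype == "DEL") {
        cur_ref <- v$pos - v$svlen  # svlen negative
      } else if (v$svtype == "INS") {
        add_block(v$pos, v$pos, "+", v$seq)
      } else if (v$svtype == "DUP") {
        emit_match(v$end)
        add_block(v$pos, v$end, "+", substr(refseq, v$pos + 1L, v$end))
      } else if (v$svtype == "INV") {
        add_block(v$pos, v$end, "-",
                  revcomp(substr(refseq, v$pos + 1L, v$end)))
        cur_ref <- v$end
      }
    }
  }
  emit_match(L)
  map <- do.call(rbind, map)
  hapseq <- paste(pieces, collapse = "")

  if (nrow(snvvars)) {
    ## SNVs never fall inside SV intervals, so each lies in a '+' match block
    fwd <- map[map$strand == "+" & map$ref_end > map$ref_start, , drop = FALSE]
    idx <- findInterval(snvvars$pos, fwd$ref_start)
    ok <- idx >= 1 & snvvars$pos < fwd$ref_end[pmax(idx, 1L)]
    sp <- snvvars[ok, , drop = FALSE]
    bl <- fwd[idx[ok], , drop = FALSE]
    happos <- bl$hap_start + (sp$pos - bl$ref_start)
    hs <- Biostrings::DNAString(hapseq)
    hs <- Biostrings::replaceLetterAt(hs, happos + 1L, sp$alt)
    hapseq <- as.character(hs)
  }
  list(seq = hapseq, map = map)
}

#' Project a haplotype interval onto the reference through a block map
#'
#' @param map block map from [build_haplotype()].
#' @param s,e 0-based half-open interval in haplotype coordinates.
#' @return data.frame of segments: `ref_start`, `ref_end`, `strand`,
#'   `off_start`, `off_end` (offsets within `[s,e)`); zero-width rows mark
#'   inserted sequence with no reference origin.
#' @export
project_hap_interval <- function(map, s, e) {
  stopifnot(s >= 0, e > s, e <= max(map$hap_end))
  hit <- map[map$hap_end > s & map$hap_start < e, , drop = FALSE]
  segs <- lapply(seq_len(nrow(hit)), function(i) {
    b <- hit[i, ]
    os <- max(s, b$hap_start) - b$hap_start
    oe <- min(e, b$hap_end) - b$hap_start
    if (b$ref_end == b$ref_start) {           # insertion block
      rs <- b$ref_start; re <- b$ref_start; strand <- "+"
    } else if (b$strand == "+") {
      rs <- b$ref_start + os; re <- b$ref_start + oe; strand <- "+"
    } else {                                   # inverted block
      rs <- b$ref_end - oe; re <- b$ref_end - os; strand <- "-"
    }
    data.frame(ref_start = rs, ref_end = re, strand = strand,
               off_start = max(s, b$hap_start) - s,
               off_end = min(e, b$hap_end) - s, stringsAsFactors = FALSE)
  })
  do.call(rbind, segs)
}
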