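## Emission of per-sample variant call sets from the planted truth: the bulk
## call set contains every germline variant; each single-cell call set is
## germline plus that clone's somatic variants, thinned by allelic dropout,
## plus false calls. False SVs are inversion-heavy by default, mimicking the
## chimera-driven false calls of droplet-MDA long-read data, and carry a
## PRECISE/IMPRECISE flag.

#' Emit per-sample call sets (bulk + single cells) from the truth
#'
#' @param genome a `sim_genome`.
#' @param cfg the `sim_config`.
#' @param seed optional seed override.
#' @return named list of call-set data.frames (`bulk`, then one per cell),
#'   each with columns `contig`, `pos` (1-based), `ref`, `alt`, `svtype`,
#'   `svlen`, `end` (1-based inclusive), `precise`, `sample_id`, and
#'   `truth` (`"TP"`/`"FP"`, simulator-only annotation).
#' @export
emit_callsets <- function(genome, cfg, seed = NULL) {
  if (is.null(seed)) seed <- child_seed(cfg$seed, "callsets")
  roster <- cell_roster(cfg)
  germ <- truth_to_calls(genome$germline)
  with_seed(seed, {
    out <- list()
    bulk <- germ
    bulk$precise <- ifelse(bulk$svtype %in% c("SNV"), NA,
                           runif(nrow(bulk)) < cfg$precise_rate_true)
    bulk$sample_id <- "bulk"
    bulk$truth <- "TP"
    out$bulk <- bulk
    for (i in seq_len(nrow(roster))) {
      cell <- roster$cell_id[i]
      clone <- roster$clone[i]
      som <- truth_to_calls(genome$clone_somatic[[clone]])
      calls <- rbind(germ, som)
      keep <- runif(nrow(calls)) >= cfg$dropout_rate
      calls <- calls[keep, , drop = FALSE]
      calls$precise <- ifelse(calls$svtype == "SNV", NA,
                              runif(nrow(calls)) < cfg$precise_rate_true)
      calls$truth <- "TP"
      fp <- make_false_calls(genome, cfg)
      if (nrow(fp)) calls <- rbind(calls, fp)
      calls$sample_id <- cell
      calls <- calls[order(calls$contig, calls$pos), , drop = FALSE]
      rownames(calls) <- NULL
      out[[cell]] <- calls
    }
    out
  })
}

## Convert truth variant rows (0-based pos) to call rows (1-based pos).
truth_to_calls <- function(tv) {
  if (!nrow(tv)) {
    return(data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), svtype = character(), svlen = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  data.frame(contig = tv$contig, pos = tv$pos + 1L, ref = tv$ref,
             alt = tv$alt, svtype = tv$svtype, svlen = tv$svlen,
             end = tv$end, stringsAsFactors = FALSE)
}

make_false_calls <- function(genome, cfg) {
  L <- nchar(genome$contigs[[NUC_CONTIG]])
  n_germ_snv <- sum(genome$germline$svtype == "SNV")
  n_fp_snv <- rpois(1L, cfg$fp_snv_rate * max(1L, n_germ_snv))
  rows <- list()
  if (n_fp_snv > 0) {
    pos <- sample.int(L - 1L, n_fp_snv)
    ref <- substr(rep(genome$contigs[[NUC_CONTIG]], n_fp_snv), pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), character(1))
    rows$snv <- data.frame(contig = NUC_CONTIG, pos = pos, ref = ref, alt = alt,
                           svtype = "SNV", svlen = 0L, end = pos,
                           precise = NA, truth = "FP", stringsAsFactors = FALSE)
  }
  for (type in names(cfg$fp_sv_counts)) {
    n <- rpois(1L, cfg$fp_sv_counts[[type]])
    if (n == 0L) next
    lens <- draw_sv_lengths(n, cfg$sv_length_models[[type]])
    pos <- sample.int(L - max(lens) - 1L, n)
    rows[[type]] <- data.frame(
      contig = NUC_CONTIG, pos = pos, ref = "N", alt = sprintf("<%s>", type),
      svtype = type, svlen = if (type == "DEL") -lens else lens,
      end = if (type == "INS") pos else pos + lens - 1L,
      precise = runif(n) < cfg$precise_rate_false,
      truth = "FP", stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), svtype = character(), svlen = integer(),
                      end = integer(), precise = logical(), truth = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

## ---- VCF I/O ------------------------------------------------------------

#' Write a call set as VCF v4.2
#'
#' SNVs are written with literal REF/ALT alleles; SVs use symbolic ALT
#' alleles with `SVTYPE`, `SVLEN` and `END` INFO keys and a
#' `PRECISE`/`IMPRECISE` flag.
#'
#' @param calls call-set data.frame (see [emit_callsets()]).
#' @param path output file.
#' @param sample_id sample name for the header.
#' @export
write_vcf <- function(calls, path, sample_id = calls$sample_id[1]) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
    "##INFO=<ID=PRECISE,Number=0,Type=Flag,Description=\"Precise breakpoints\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise breakpoints\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           if (is.null(sample_id) || is.na(sample_id)) "SAMPLE" else sample_id))
  if (nrow(calls)) {
    is_sv <- calls$svtype != "SNV"
    info <- ifelse(is_sv,
                   paste0(ifelse(is.na(calls$precise) | calls$precise,
                                 "PRECISE;", "IMPRECISE;"),
                          "SVTYPE=", calls$svtype, ";SVLEN=", calls$svlen,
                          ";END=", calls$end),
                   ".")
    body <- paste(calls$contig, calls$pos, ".", calls$ref, calls$alt, ".",
                  "PASS", info, "GT", "0/1", sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()] back into a call-set data.frame
#'
#' Parses the constrained VCF v4.2 dialect this package emits (literal
#' SNV alleles; symbolic SVs with SVTYPE/SVLEN/END and PRECISE flags).
#'
#' @param path VCF file.
#' @param sample_id sample id to attach (default: from the header column).
#' @return call-set data.frame.
#' @export
read_vcf <- function(path, sample_id = NULL) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (is.null(sample_id)) {
    cols <- strsplit(tail(hdr, 1L), "\t")[[1]]
    sample_id <- if (length(cols) >= 10L) cols[10L] else "SAMPLE"
  }
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), svtype = character(), svlen = integer(),
                      end = integer(), precise = logical(),
                      sample_id = character(), stringsAsFactors = FALSE))
  }
  f <- data.table::fread(text = body, sep = "\t", header = FALSE,
                         data.table = FALSE)
  info <- f$V8
  get_key <- function(key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    out <- rep(NA_character_, length(info))
    out[grepl(paste0(key, "="), info)] <- sub(paste0(key, "="), "", m)
    out
  }
  svtype <- get_key("SVTYPE")
  svtype[is.na(svtype)] <- "SNV"
  svlen <- suppressWarnings(as.integer(get_key("SVLEN")))
  svlen[is.na(svlen)] <- 0L
  endv <- suppressWarnings(as.integer(get_key("END")))
  endv[is.na(endv)] <- f$V2[is.na(endv)]
  data.frame(contig = as.character(f$V1), pos = f$V2, ref = f$V4, alt = f$V5,
             svtype = svtype, svlen = svlen, end = endv,
             precise = ifelse(svtype == "SNV", NA, grepl("PRECISE", info) &
                                !grepl("IMPRECISE", info)),
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Write tandem-repeat loci (or any interval table) as BED
#' @param df data.frame with `contig`, `start`, `end` (0-based half-open)
#'   and optionally a 4th name/unit column given by `name_col`.
#' @param path output file.
#' @param name_col optional column to place in BED column 4.
#' @export
write_bed <- function(df, path, name_col = NULL) {
  out <- df[, c("contig", "start", "end")]
  if (!is.null(name_col)) out$name <- df[[name_col]]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED file (first 3-4 columns)
#' @param path BED file.
#' @return data.frame with `contig`, `start`, `end` (+ `name` if present).
#' @export
read_bed <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  names(df)[1:3] <- c("contig", "start", "end")
  if (ncol(df) >= 4L) names(df)[4] <- "name"
  df[, seq_len(min(4L, ncol(df))), drop = FALSE]
}
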