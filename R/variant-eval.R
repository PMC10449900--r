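## Truth-set evaluation of SNVs and SVs against a bulk sample, multi-sample
## SV merging, and clone-aware somatic variant filtering.
##
## SNV matching is by site/allele identity (contig, pos, ref, alt) between
## normalized records. SV merging follows the distance/overlap rule used by
## multi-sample SV mergers: two calls of the same type link when their start
## positions lie within 200 bp and their intervals share at least 10%
## reciprocal overlap (insertions, which have no interval, substitute a
## length ratio for the overlap); clusters are the transitive closure of
## that relation (single linkage).

snv_key <- function(df) paste(df$contig, df$pos, df$ref, df$alt, sep = ":")

## Left-align simple indels against a reference sequence context if given.
## Records already minimal (SNVs, symbolic SVs) are returned unchanged.
normalize_calls <- function(calls, ref_seqs = NULL) {
  lit <- calls$svtype %in% c("SNV", "INDEL") &
    !startsWith(calls$alt, "<")
  idx <- which(lit & nchar(calls$ref) != nchar(calls$alt) &
                 substr(calls$ref, nchar(calls$ref), nchar(calls$ref)) ==
                 substr(calls$alt, nchar(calls$alt), nchar(calls$alt)))
  if (length(idx) && !is.null(ref_seqs)) {
    for (i in idx) {
      p <- calls$pos[i]; r <- calls$ref[i]; a <- calls$alt[i]
      sq <- ref_seqs[[calls$contig[i]]]
      ## strip shared suffix then shared prefix, shifting left while the
      ## trailing bases match the preceding reference base
      while (nchar(r) > 1L && nchar(a) > 1L &&
             substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
        r <- substr(r, 1L, nchar(r) - 1L); a <- substr(a, 1L, nchar(a) - 1L)
      }
      while (min(nchar(r), nchar(a)) == 1L && p > 1L &&
             substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
        prev <- substr(sq, p - 1L, p - 1L)
        r <- paste0(prev, substr(r, 1L, nchar(r) - 1L))
        a <- paste0(prev, substr(a, 1L, nchar(a) - 1L))
        p <- p - 1L
      }
      calls$pos[i] <- p; calls$ref[i] <- r; calls$alt[i] <- a
    }
  }
  calls
}

#' Intersect single-cell SNVs with the bulk truth set
#'
#' A match requires identical contig, position, reference and alternate
#' allele (genotype-free). Unnormalized indels (shared trailing base)
#' trigger a warning and are auto-normalized when reference context is
#' supplied.
#'
#' @param cell,bulk call-set data.frames.
#' @param ref_seqs optional named character vector of contig sequences for
#'   indel normalization.
#' @return the true-positive subset of `cell`.
#' @export
intersect_snvs <- function(cell, bulk, ref_seqs = NULL) {
  for (nm in c("cell", "bulk")) {
    df <- get(nm)
    lit <- !startsWith(df$alt, "<")
    bad <- lit & nchar(df$ref) != nchar(df$alt) &
      substr(df$ref, nchar(df$ref), nchar(df$ref)) ==
      substr(df$alt, nchar(df$alt), nchar(df$alt))
    if (any(bad)) {
      warning(sprintf("%d unnormalized indel(s) in '%s'; auto-normalizing", sum(bad), nm))
      assign(nm, normalize_calls(df, ref_seqs))
    }
  }
  cell[snv_key(cell) %in% snv_key(bulk), , drop = FALSE]
}

#' Precision and sensitivity of a cell call set against bulk
#'
#' @param cell,bulk SNV call-set data.frames (rows with `svtype == "SNV"`
#'   are compared).
#' @return list with `tp`, `fp`, `fn`, `precision`, `sensitivity`.
#' @export
snv_eval <- function(cell, bulk) {
  cell <- cell[cell$svtype == "SNV", , drop = FALSE]
  bulk <- bulk[bulk$svtype == "SNV", , drop = FALSE]
  tp <- sum(snv_key(cell) %in% snv_key(bulk))
  fp <- nrow(cell) - tp
  fn <- nrow(bulk) - tp
  list(tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else 0)
}

#' Clone-aware somatic SNV filter
#'
#' Retains SNVs that are (1) called in at least two cells of one clone,
#' (2) absent from the bulk call set, (3) absent from every cell of the
#' other clone, (4) not indels, and (5) outside the repeat mask. Absence
#' means no call (a dropout-induced non-call counts as absent).
#'
#' @param cells_by_clone named list (clone -> list of cell call-set
#'   data.frames).
#' @param bulk bulk call-set data.frame.
#' @param repeat_mask optional data.frame with `contig`, `start`, `end`
#'   (0-based half-open) of masked intervals.
#' @return data.frame of candidate somatic SNVs with a `clone` column.
#' @export
somatic_snv_filter <- function(cells_by_clone, bulk, repeat_mask = NULL) {
  stopifnot(length(cells_by_clone) == 2L)
  clones <- names(cells_by_clone)
  bulk_keys <- snv_key(bulk)
  out <- list()
  for (ci in 1:2) {
    clone <- clones[ci]
    cells <- cells_by_clone[[clone]]
    if (length(cells) < 2L) {
      warning(sprintf("clone %s has <2 cells; skipped", clone))
      next
    }
    other <- unlist(lapply(cells_by_clone[[clones[3L - ci]]], snv_key))
    keys <- unlist(lapply(cells, function(df)
      unique(snv_key(df[df$svtype %in% c("SNV", "INDEL") |
                          !startsWith(df$alt, "<"), , drop = FALSE]))))
    tab <- table(keys)
    shared <- names(tab)[tab >= 2L]                      # rule 1
    shared <- setdiff(shared, bulk_keys)                 # rule 2
    shared <- setdiff(shared, other)                     # rule 3
    if (!length(shared)) next
    rep_df <- do.call(rbind, lapply(cells, function(df)
      df[snv_key(df) %in% shared, , drop = FALSE]))
    rep_df <- rep_df[!duplicated(snv_key(rep_df)), , drop = FALSE]
    rep_df <- rep_df[nchar(rep_df$ref) == 1L & nchar(rep_df$alt) == 1L &
                       !startsWith(rep_df$alt, "<"), , drop = FALSE]  # rule 4
    if (!is.null(repeat_mask) && nrow(repeat_mask) && nrow(rep_df)) {
      gr <- GenomicRanges::GRanges(rep_df$contig,
                                   IRanges::IRanges(rep_df$pos, width = 1L))
      mask <- GenomicRanges::GRanges(repeat_mask$contig,
                                     IRanges::IRanges(repeat_mask$start + 1L,
                                                      repeat_mask$end))
      rep_df <- rep_df[GenomicRanges::countOverlaps(gr, mask) == 0L, ,
                       drop = FALSE]                     # rule 5
    }
    if (nrow(rep_df)) {
      rep_df$clone <- clone
      out[[clone]] <- rep_df
    }
  }
  if (!length(out)) {
    res <- bulk[0, , drop = FALSE]
    res$clone <- character(0)
    return(res)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## Do two SV records link under the distance/overlap rule?
sv_pair_links <- function(a, b, max_dist, min_overlap) {
  if (a$contig != b$contig || a$svtype != b$svtype) return(FALSE)
  if (abs(a$pos - b$pos) > max_dist) return(FALSE)
  if (a$svtype == "INS") {
    la <- abs(a$svlen); lb <- abs(b$svlen)
    return(min(la, lb) / max(la, lb) >= min_overlap)
  }
  s <- max(a$pos, b$pos); e <- min(a$end, b$end)
  ov <- max(0, e - s + 1)
  wa <- a$end - a$pos + 1; wb <- b$end - b$pos + 1
  ov / wa >= min_overlap && ov / wb >= min_overlap
}

#' Merge SV call sets across samples
#'
#' Single-linkage clustering of typed SV records: two calls of the same
#' type link when their start positions lie within `max_dist` bases and
#' their intervals share at least `min_overlap` reciprocal overlap
#' (insertions: length ratio). Each cluster yields one row with per-sample
#' presence flags; a cluster is PRECISE if any member is.
#'
#' @param sv_sets list of SV call-set data.frames (each with `sample_id`).
#' @param max_dist maximum start-position distance (default 200 bp).
#' @param min_overlap minimum reciprocal overlap fraction (default 0.10).
#' @return data.frame: cluster representative (`contig`, `pos`, `end`,
#'   `svtype`, `svlen`, `precise`), `n_members`, and one logical presence
#'   column `in_<sample>` per input sample.
#' @export
merge_svs <- function(sv_sets, max_dist = 200, min_overlap = 0.10) {
  all <- data.table::rbindlist(lapply(sv_sets, function(df)
    df[df$svtype %in% c("DEL", "INS", "DUP", "INV"), , drop = FALSE]),
    fill = TRUE)
  samples <- unique(unlist(lapply(sv_sets, function(df) unique(df$sample_id))))
  if (!nrow(all)) {
    out <- data.frame(contig = character(), pos = integer(), end = integer(),
                      svtype = character(), svlen = integer(),
                      precise = logical(), n_members = integer())
    for (s in samples) out[[paste0("in_", s)]] <- logical(0)
    return(out)
  }
  all <- as.data.frame(all)
  all$.row <- seq_len(nrow(all))
  ## candidate pairs: same contig+type, starts within max_dist (windowed join)
  dt <- data.table::as.data.table(all)
  data.table::setkey(dt, contig, svtype, pos)
  edges <- list()
  sp <- split(seq_len(nrow(all)), paste(all$contig, all$svtype))
  for (idx in sp) {
    if (length(idx) < 2L) next
    o <- idx[order(all$pos[idx])]
    pos <- all$pos[o]
    for (i in seq_along(o)) {
      j <- i + 1L
      while (j <= length(o) && pos[j] - pos[i] <= max_dist) {
        if (sv_pair_links(all[o[i], ], all[o[j], ], max_dist, min_overlap)) {
          edges[[length(edges) + 1L]] <- c(o[i], o[j])
        }
        j <- j + 1L
      }
    }
  }
  g <- igraph::make_empty_graph(n = nrow(all), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, unlist(edges))
  }
  comp <- igraph::components(g)$membership
  all$.cluster <- comp
  sp <- split(all, all$.cluster)
  rows <- lapply(sp, function(cl) {
    rep <- cl[which.min(cl$pos), , drop = FALSE]
    row <- data.frame(contig = rep$contig, pos = as.integer(median(cl$pos)),
                      end = as.integer(median(cl$end)), svtype = rep$svtype,
                      svlen = as.integer(median(cl$svlen)),
                      precise = any(cl$precise %in% TRUE),
                      n_members = nrow(cl), stringsAsFactors = FALSE)
    for (s in samples) row[[paste0("in_", s)]] <- s %in% cl$sample_id
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$pos, out$svtype), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-type SV true positives against bulk
#'
#' True positives are single-cell SV calls whose merge cluster also
#' contains a bulk call of the same type; sensitivity uses all bulk calls
#' of the type as denominator.
#'
#' @param cell_svs,bulk_svs SV call-set data.frames.
#' @param max_dist,min_overlap merge thresholds (see [merge_svs()]).
#' @return data.frame per svtype: `tp`, `fp`, `fn`, `precision`,
#'   `sensitivity`.
#' @export
sv_true_positives <- function(cell_svs, bulk_svs, max_dist = 200,
                              min_overlap = 0.10) {
  cs <- unique(cell_svs$sample_id)
  stopifnot(length(cs) == 1L)
  merged <- merge_svs(list(cell_svs, bulk_svs), max_dist, min_overlap)
  types <- c("DEL", "INS", "DUP", "INV")
  incell <- merged[[paste0("in_", cs)]]
  inbulk <- merged[[paste0("in_", unique(bulk_svs$sample_id))]]
  do.call(rbind, lapply(types, function(tp_) {
    m <- merged$svtype == tp_
    tp <- sum(m & incell & inbulk)
    fp <- sum(m & incell & !inbulk)
    nbulk <- sum(bulk_svs$svtype == tp_)
    data.frame(svtype = tp_, tp = tp, fp = fp, fn = nbulk - tp,
               precision = if (tp + fp > 0) tp / (tp + fp) else 0,
               sensitivity = if (nbulk > 0) tp / nbulk else 0,
               stringsAsFactors = FALSE)
  }))
}

#' Clone-aware somatic SV filter
#'
#' From a merged multi-sample table, retains PRECISE events present in at
#' least two cells of one clone, absent from every cell of the other
#' clone, and absent from bulk.
#'
#' @param merged merged table from [merge_svs()].
#' @param cells_by_clone named list (clone -> character vector of cell
#'   sample ids).
#' @param bulk_sample bulk sample id (default `"bulk"`).
#' @return subset of `merged` with a `clone` column.
#' @export
somatic_sv_filter <- function(merged, cells_by_clone, bulk_sample = "bulk") {
  stopifnot(length(cells_by_clone) == 2L)
  clones <- names(cells_by_clone)
  res <- list()
  presence <- function(cols) {
    ## a sample with no calls contributes an all-FALSE column
    got <- intersect(cols, names(merged))
    n <- rowSums(as.data.frame(merged[, got, drop = FALSE]))
    if (!length(got)) n <- rep(0L, nrow(merged))
    n
  }
  for (ci in 1:2) {
    n_own <- presence(paste0("in_", cells_by_clone[[clones[ci]]]))
    n_oth <- presence(paste0("in_", cells_by_clone[[clones[3L - ci]]]))
    in_bulk <- if (paste0("in_", bulk_sample) %in% names(merged)) {
      merged[[paste0("in_", bulk_sample)]]
    } else rep(FALSE, nrow(merged))
    keep <- merged$precise & n_own >= 2L & n_oth == 0L & !in_bulk
    if (any(keep)) {
      sub <- merged[keep, , drop = FALSE]
      sub$clone <- clones[ci]
      res[[clones[ci]]] <- sub
    }
  }
  if (!length(res)) {
    out <- merged[0, , drop = FALSE]
    out$clone <- character(0)
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
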