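## Fragmentation, droplet encapsulation and amplification gain.
##
## Fragments tile each haplotype exactly (no gaps, no overlaps) with lengths
## ~ Normal(mean, sd) truncated at 500 bp; each fragment lands in a
## uniform-random droplet (bulk-MDA mode: no droplet). The mitochondrial
## contig is circular: each genome copy is cut starting from a random origin
## offset, and fragments may wrap past the end (end > contig length; the
## wrapped reference intervals are recovered at projection time).

## Cut a length L into tiling pieces.
tile_lengths <- function(L, mean_len, sd_len, min_len = 500L) {
  n_guess <- max(4L, ceiling(L / max(mean_len - 2 * sd_len, min_len)) + 4L)
  lens <- integer(0)
  total <- 0L
  while (total < L) {
    draw <- pmax(min_len, round(rnorm(n_guess, mean_len, sd_len)))
    lens <- c(lens, as.integer(draw))
    total <- sum(lens)
  }
  cum <- cumsum(lens)
  k <- which(cum >= L)[1L]
  lens <- lens[seq_len(k)]
  lens[k] <- lens[k] - (cum[k] - L)
  if (k > 1L && lens[k] < min_len) {   # merge a short tail into its neighbour
    lens[k - 1L] <- lens[k - 1L] + lens[k]
    lens <- lens[-k]
  }
  lens
}

#' Fragment a cell's genome and encapsulate fragments in droplets
#'
#' Both nuclear haplotypes are cut into fragments that tile the haplotype
#' exactly; `mito_copies` copies of the circular mitochondrial contig are cut
#' starting at random origin offsets (fragments may wrap). Every fragment is
#' assigned a uniform-random droplet among `n_droplets`; in bulk-MDA mode
#' (`gain_model$mode == "mda"`) `droplet_id` is `NA` (one shared reaction
#' volume).
#'
#' @param genome a `sim_genome`.
#' @param cell_id cell identifier present in [cell_roster()].
#' @param cfg the `sim_config`.
#' @param contigs which contigs to fragment (default: all).
#' @return data.frame of fragments: `cell_id`, `frag_id`, `contig`,
#'   `haplotype` (`"1"`, `"2"` or `"mito"`), `start`, `end` (0-based
#'   half-open haplotype coordinates; mito `end` may exceed the contig
#'   length to encode circular wrap), `droplet_id`.
#' @export
fragment_and_encapsulate <- function(genome, cell_id, cfg,
                                     contigs = names(genome$contigs)) {
  clone <- sample_clone(cfg, cell_id)
  with_seed(child_seed(cfg$seed, paste0("frag_", cell_id)), {
    out <- list()
    for (contig in contigs) {
      if (isTRUE(genome$circular[[contig]])) {
        L <- nchar(genome$contigs[[contig]])
        for (cp in seq_len(cfg$mito_copies)) {
          off <- sample.int(L, 1L) - 1L
          lens <- tile_lengths(L, cfg$fragment_length_mean,
                               cfg$fragment_length_sd)
          ends <- off + cumsum(lens)
          starts <- c(off, head(ends, -1L))
          out[[length(out) + 1L]] <- data.frame(
            cell_id = cell_id, contig = contig, haplotype = "mito",
            start = as.integer(starts), end = as.integer(ends),
            stringsAsFactors = FALSE)
        }
      } else {
        for (hap in 1:2) {
          hb <- build_haplotype(genome, contig, clone, hap)
          Lh <- nchar(hb$seq)
          lens <- tile_lengths(Lh, cfg$fragment_length_mean,
                               cfg$fragment_length_sd)
          ends <- cumsum(lens)
          starts <- c(0L, head(ends, -1L))
          out[[length(out) + 1L]] <- data.frame(
            cell_id = cell_id, contig = contig, haplotype = as.character(hap),
            start = as.integer(starts), end = as.integer(ends),
            stringsAsFactors = FALSE)
        }
      }
    }
    frags <- do.call(rbind, out)
    frags$frag_id <- sprintf("%s_f%05d", cell_id, seq_len(nrow(frags)))
    frags$droplet_id <- if (cfg$gain_model$mode == "mda") {
      NA_integer_
    } else {
      sample.int(cfg$n_droplets, nrow(frags), replace = TRUE)
    }
    frags[, c("cell_id", "frag_id", "contig", "haplotype", "start", "end",
              "droplet_id")]
  })
}

#' Reference intervals of a fragment (splitting circular wrap)
#'
#' @param frag one row of a fragment data.frame.
#' @param contig_length length of the fragment's contig.
#' @return data.frame with `start`, `end` (0-based half-open reference
#'   coordinates); two rows when a mitochondrial fragment wraps the origin.
#' @export
fragment_ref_intervals <- function(frag, contig_length) {
  s <- frag$start %% contig_length
  e <- frag$end
  if (frag$start >= contig_length) e <- e - (frag$start - s)
  if (e <= contig_length) {
    data.frame(start = s, end = e)
  } else {
    data.frame(start = c(s, 0L), end = c(contig_length, e - contig_length))
  }
}

#' Amplify fragments with droplet-capped (dMDA) or heavy-tailed (MDA) gain
#'
#' In dMDA mode each fragment draws a lognormal copy number that is then
#' clipped so the total over its droplet does not exceed
#' `gain_model$dmda_cap_copies` (limited reagents per picoliter droplet). In
#' MDA mode copy numbers are unclipped lognormal draws with
#' `sdlog = gain_model$mda_log_sigma`, reproducing the heavy-tailed
#' over-amplification of a bulk reaction. Chimera formation events are drawn
#' per amplified copy (fold-back inversions, tandem duplications) and per
#' droplet (intermolecular junctions, only possible between co-encapsulated
#' fragments; events requested in single-fragment droplets are skipped and
#' counted in `attr(,"skipped_intermolecular")`).
#'
#' @param fragments data.frame from [fragment_and_encapsulate()].
#' @param cfg the `sim_config`.
#' @param seed optional seed override (default derived from `cfg$seed`).
#' @return the fragment data.frame with added columns `copies`, `n_inv`,
#'   `n_dup`, `n_im`, plus attribute `im_events` (data.frame of
#'   intermolecular junction partners) and `skipped_intermolecular`.
#' @export
amplify <- function(fragments, cfg, seed = NULL) {
  gm <- cfg$gain_model
  if (is.null(seed)) {
    seed <- child_seed(cfg$seed, paste0("amp_", fragments$cell_id[1]))
  }
  with_seed(seed, {
    n <- nrow(fragments)
    mu <- log(gm$mean_copies)
    if (gm$mode == "mda") {
      copies <- pmax(1L, as.integer(ceiling(rlnorm(n, mu, gm$mda_log_sigma))))
    } else {
      copies <- pmax(1L, as.integer(ceiling(rlnorm(n, mu, 0.5))))
      cap <- gm$dmda_cap_copies
      by_drop <- split(seq_len(n), fragments$droplet_id)
      for (idx in by_drop) {
        tot <- sum(copies[idx])
        if (tot <= cap) next
        copies[idx] <- pmax(1L, as.integer(floor(copies[idx] * cap / tot)))
        ## the per-fragment floor of 1 can keep a crowded droplet above cap
        while (sum(copies[idx]) > cap && any(copies[idx] > 1L)) {
          j <- idx[which.max(copies[idx])]
          copies[j] <- copies[j] - 1L
        }
      }
    }
    out <- fragments
    out$copies <- copies
    cr <- cfg$chimera_rates
    out$n_inv <- rbinom(n, copies, min(1, cr$inversion_per_amplicon))
    out$n_dup <- rbinom(n, copies, min(1, cr$duplication_per_amplicon))
    out$n_im <- 0L

    im <- data.frame(droplet_id = integer(), frag_a = character(),
                     frag_b = character(), stringsAsFactors = FALSE)
    skipped <- 0L
    if (cr$intermolecular_per_droplet > 0 && gm$mode == "dmda") {
      occ <- split(seq_len(n), fragments$droplet_id)
      n_ev <- rpois(length(occ), cr$intermolecular_per_droplet)
      for (k in which(n_ev > 0L)) {
        idx <- occ[[k]]
        if (length(idx) < 2L) { skipped <- skipped + n_ev[k]; next }
        for (ev in seq_len(n_ev[k])) {
          pair <- sample(idx, 2L)
          im <- rbind(im, data.frame(
            droplet_id = fragments$droplet_id[pair[1]],
            frag_a = fragments$frag_id[pair[1]],
            frag_b = fragments$frag_id[pair[2]], stringsAsFactors = FALSE))
          out$n_im[pair[1]] <- out$n_im[pair[1]] + 1L
        }
      }
    }
    attr(out, "im_events") <- im
    attr(out, "skipped_intermolecular") <- skipped
    out
  })
}
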