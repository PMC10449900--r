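# Independent oracles used by the acceptance checks.

# Self-alignment oracle via command-line blastn (read aligned to itself;
# the method the screen re-implements). Returns verdict + junction.
blast_self_oracle <- function(seq, min_identity = 90, min_len = 100) {
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa))
  writeLines(c(">read", seq), fa)
  out <- suppressWarnings(system2(
    "blastn",
    c("-query", fa, "-subject", fa, "-dust", "no",
      "-outfmt", shQuote("6 qstart qend sstart send pident length")),
    stdout = TRUE, stderr = FALSE))
  if (!length(out)) return(list(verdict = "CLEAN", junction = NA_integer_))
  h <- read.table(text = out, col.names = c("qs", "qe", "ss", "se",
                                            "pident", "len"))
  minus <- h$ss > h$se
  trivial <- !minus & h$qs == h$ss & h$qe == h$se
  h <- h[!trivial & h$pident >= min_identity & h$len >= min_len, ,
         drop = FALSE]
  if (!nrow(h)) return(list(verdict = "CLEAN", junction = NA_integer_))
  minus <- h$ss > h$se
  verdict <- if (any(minus) && any(!minus)) "COMPLEX"
             else if (any(minus)) "INVERSION" else "DUPLICATION"
  ## junction: midpoint between the two paired intervals of the best hit
  best <- h[order(-h$len), ][1, ]
  i1 <- sort(c(best$qs, best$qe))
  i2 <- sort(c(best$ss, best$se))
  if (i1[1] > i2[1]) { tmp <- i1; i1 <- i2; i2 <- tmp }
  junction <- as.integer(round((i1[2] + i2[1]) / 2))
  list(verdict = verdict, junction = junction)
}

# Brute-force all-pairs transitive-closure oracle for SV merging,
# vectorized over the full pair matrix.
merge_oracle_matrix <- function(all, max_dist = 200, min_overlap = 0.10) {
  n <- nrow(all)
  same <- outer(all$contig, all$contig, "==") &
    outer(all$svtype, all$svtype, "==")
  near <- abs(outer(all$pos, all$pos, "-")) <= max_dist
  ins <- all$svtype == "INS"
  la <- abs(all$svlen)
  ratio <- outer(la, la, pmin) / outer(la, la, pmax)
  ov <- pmax(outer(all$end, all$end, pmin) - outer(all$pos, all$pos, pmax) + 1, 0)
  w <- all$end - all$pos + 1
  recip <- (ov / matrix(w, n, n)) >= min_overlap &
    (ov / matrix(w, n, n, byrow = TRUE)) >= min_overlap
  is_ins_pair <- outer(ins, ins, "&")
  link <- same & near & ((is_ins_pair & ratio >= min_overlap) |
                           (!is_ins_pair & recip))
  diag(link) <- TRUE
  ## transitive closure by repeated boolean multiplication
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      mates <- which(link[i, ])
      tgt <- min(comp[mates])
      if (any(comp[mates] != tgt)) {
        comp[comp %in% comp[mates]] <- tgt
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# Generator for short planted chimera cases (reads <= 2 kb)
make_planted_case <- function(kind, len = 2000L, err = 0.01) {
  S <- random_dna(len)
  read <- switch(kind,
    clean = S,
    inversion = {
      b <- sample(seq.int(700L, len - 500L), 1L)
      a2 <- sample(seq.int(400L, b - 100L), 1L)
      paste0(substr(S, 1, b), rc(substr(S, b - a2 + 1, b)))
    },
    duplication = {
      w <- sample(300:600, 1L)
      w1 <- sample.int(len - w - 200L, 1L)
      paste0(substr(S, 1, w1 + w), substr(S, w1 + 1, len))
    })
  if (err > 0) {
    ch <- strsplit(read, "")[[1]]
    k <- rbinom(1, length(ch), err)
    pos <- sample.int(length(ch), k)
    shift <- sample.int(3, k, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    ch[pos] <- bases[(match(ch[pos], bases) - 1 + shift) %% 4 + 1]
    read <- paste(ch, collapse = "")
  }
  read
}
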