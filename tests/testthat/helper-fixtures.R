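# Shared fixture builders and independent brute-force oracles.
# Oracles are deliberately naive (per-base, per-pair loops) and never
# call the code paths they check.

random_peaks <- function(n, chrom = "chr1", max_pos = 100000L,
                         min_len = 50L, max_len = 500L) {
  start <- sample.int(max_pos - max_len, n, replace = TRUE) - 1L
  len <- sample(seq(min_len, max_len), n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = start, end = start + len)
}

# reproducibility rule, applied peak by peak exactly as stated: a peak
# with enough supporting replicates is kept together with each peak
# that supported it
oracle_reproducible <- function(replicate_peaks, min_reps = 2,
                                frac = 0.5) {
  retained <- list()
  for (i in seq_along(replicate_peaks)) {
    pk <- replicate_peaks[[i]]
    for (j in seq_len(nrow(pk))) {
      p <- pk[j, ]
      support_reps <- 0L
      sup_rows <- list()
      for (k in seq_along(replicate_peaks)[-i]) {
        o <- replicate_peaks[[k]]
        ok <- FALSE
        for (l in seq_len(nrow(o))) {
          if (o$chrom[l] != p$chrom) next
          ov <- min(o$end[l], p$end) - max(o$start[l], p$start)
          if (ov >= frac * (p$end - p$start)) {
            ok <- TRUE
            sup_rows[[length(sup_rows) + 1L]] <- o[l, ]
          }
        }
        if (ok) support_reps <- support_reps + 1L
      }
      if (support_reps >= min_reps - 1) {
        retained[[length(retained) + 1L]] <- p
        for (s in sup_rows) retained[[length(retained) + 1L]] <- s
      }
    }
  }
  if (length(retained) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  oracle_merge(dplyr::bind_rows(retained))
}

# per-base union merge of intervals
oracle_merge <- function(df, max_pos = 200000L) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, ]
    covered <- logical(max_pos)
    for (i in seq_len(nrow(d))) {
      covered[(d$start[i] + 1L):d$end[i]] <- TRUE
    }
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    out[[ch]] <- tibble::tibble(chrom = ch, start = starts[keep],
                                end = ends[keep])
  }
  dplyr::bind_rows(out)
}

# per-base presence of condition peaks over merged intervals
oracle_presence <- function(merged, cond_peaks, max_pos = 200000L) {
  pres <- matrix(FALSE, nrow(merged), length(cond_peaks),
                 dimnames = list(NULL, names(cond_peaks)))
  for (cond in names(cond_peaks)) {
    cp <- cond_peaks[[cond]]
    for (i in seq_len(nrow(merged))) {
      hit <- FALSE
      for (j in seq_len(nrow(cp))) {
        if (cp$chrom[j] != merged$chrom[i]) next
        if (min(cp$end[j], merged$end[i]) -
            max(cp$start[j], merged$start[i]) >= 1) { hit <- TRUE; break }
      }
      pres[i, cond] <- hit
    }
  }
  pres
}

oracle_counts <- function(thss, track) {
  samples <- sort(unique(track$sample_id))
  out <- matrix(0L, nrow(thss), length(samples),
                dimnames = list(thss$ths_id, samples))
  for (s in samples) {
    tr <- track[track$sample_id == s, ]
    for (i in seq_len(nrow(thss))) {
      out[i, s] <- sum(tr$chrom == thss$chrom[i] &
                         tr$pos >= thss$start[i] &
                         tr$pos < thss$end[i])
    }
  }
  out
}

# nearest-gene annotation recomputed independently
oracle_annotate <- function(thss, genes) {
  res <- character(nrow(thss))
  gid <- character(nrow(thss))
  for (i in seq_len(nrow(thss))) {
    mid <- (thss$start[i] + thss$end[i]) %/% 2L
    best <- NULL; bestd <- Inf
    for (j in seq_len(nrow(genes))) {
      g <- genes[j, ]
      if (g$chrom != thss$chrom[i]) next
      d <- if (g$strand == "+") mid - g$tss else g$tss - mid
      if (abs(d) < bestd ||
          (abs(d) == bestd && g$gene_id < best$gene_id)) {
        best <- g; bestd <- abs(d); bestsigned <- d
      }
    }
    if (is.null(best)) { res[i] <- "DistalIntergenic"; next }
    gid[i] <- best$gene_id
    g <- best; d <- bestsigned
    cat_i <- NULL
    if (mid >= g$start && mid < g$end) {
      ex <- g$exons[[1]]
      hit <- which(ex$start <= mid & mid < ex$end)
      if (length(hit) > 0) {
        first_ex <- if (g$strand == "+") 1L else nrow(ex)
        up_sc <- if (g$strand == "+") mid < g$start_codon else
          mid > g$start_codon
        cat_i <- if (hit[1] == first_ex && up_sc) "5'UTR-proxy" else "Exon"
      } else cat_i <- "Intron"
    } else if (d < 0 && -d <= 1000) cat_i <- "Promoter<=1kb"
    else if (d < 0 && -d <= 2000) cat_i <- "Promoter1-2kb"
    else if (d < 0 && -d <= 3000) cat_i <- "Promoter2-3kb"
    else {
      p3 <- if (g$strand == "+") mid - (g$end - 1L) else g$start - mid
      cat_i <- if (p3 > 0 && p3 <= 1000) "Downstream<=1kb" else
        "DistalIntergenic"
    }
    res[i] <- cat_i
  }
  list(category = res, gene_id = gid)
}

# all-pairs squared distances for the network
oracle_network_edges <- function(joined, threshold, unit = TRUE) {
  a <- as.matrix(joined[, c("atac_D1", "atac_D2", "atac_D3")])
  r <- as.matrix(joined[, c("rna_D1", "rna_D2", "rna_D3")])
  g <- joined$gene_id
  edges <- list()
  for (i in seq_len(nrow(a))) {
    ai <- a[i, ]
    if (unit) {
      if (sqrt(sum(ai^2)) == 0) next
      ai <- ai / sqrt(sum(ai^2))
    }
    for (j in seq_len(nrow(r))) {
      rj <- r[j, ]
      if (unit) {
        if (sqrt(sum(rj^2)) == 0) next
        rj <- rj / sqrt(sum(rj^2))
      }
      d2 <- sum((ai - rj)^2)
      if (d2 < threshold) {
        edges[[length(edges) + 1L]] <-
          tibble::tibble(atac_gene = g[i], rna_gene = g[j])
      }
    }
  }
  if (length(edges) == 0) {
    return(tibble::tibble(atac_gene = character(),
                          rna_gene = character()))
  }
  dplyr::arrange(dplyr::bind_rows(edges), atac_gene, rna_gene)
}

make_joined <- function(atac, rna, ids = NULL) {
  n <- nrow(atac)
  if (is.null(ids)) ids <- sprintf("g%03d", seq_len(n))
  tibble::tibble(gene_id = ids,
                 atac_D1 = atac[, 1], atac_D2 = atac[, 2],
                 atac_D3 = atac[, 3],
                 rna_D1 = rna[, 1], rna_D2 = rna[, 2], rna_D3 = rna[, 3])
}

oracle_bmu <- function(proto, v) {
  best <- 1L; bd <- Inf
  for (j in seq_len(ncol(proto))) {
    d <- sum((proto[, j] - v)^2)
    if (d < bd) { bd <- d; best <- j }
  }
  best
}

dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  table(paste0(ch[-n], ch[-1]))
}

# random sequences guaranteed not to contain `word` on either strand
random_seqs_without <- function(n, len, word, seed) {
  set.seed(seed)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(word)))
  vapply(seq_len(n), function(i) {
    repeat {
      s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
      if (!grepl(word, s, fixed = TRUE) && !grepl(rc, s, fixed = TRUE)) {
        return(s)
      }
    }
  }, character(1))
}

plant_word <- function(seqs, word, which_idx, seed) {
  set.seed(seed)
  for (i in which_idx) {
    pos <- sample.int(nchar(seqs[i]) - nchar(word) + 1L, 1L)
    substr(seqs[i], pos, pos + nchar(word) - 1L) <- word
  }
  seqs
}

tiny_gene <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 5000L, end = 8000L, utr5 = 200L) {
  e1 <- 600L; intron <- 200L
  ex_start <- c(start, start + e1 + intron)
  ex_end <- c(start + e1, end)
  exons <- tibble::tibble(start = ex_start, end = ex_end)
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = start, end = end,
    tss = if (strand == "+") start else end - 1L,
    start_codon = if (strand == "+") start + utr5 else end - 1L - utr5,
    exons = list(exons), other_mrnas = "")
}
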