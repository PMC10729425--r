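#' Annotate THSs with genomic features and nearest genes
#'
#' The anchor is the THS midpoint. The nearest gene is chosen by absolute
#' strand-aware TSS distance (negative = upstream of the TSS), ties going
#' to the lexicographically smaller gene id. The feature category is
#' assigned against the nearest gene with this priority: midpoint inside
#' the first transcribed exon upstream of the start codon is 5'UTR-proxy;
#' inside any other exon is Exon; inside the gene span otherwise is
#' Intron; upstream within (0,1], (1,2], (2,3] kb of the TSS are the
#' three Promoter bins; within 1 kb past the gene's 3' end is
#' Downstream<=1kb; everything else is DistalIntergenic.
#'
#' @param thss THS tibble from [build_consensus()].
#' @param genes Gene model tibble.
#' @return The THS tibble with `gene_id`, `tss_distance` and `category`
#'   columns appended.
#' @export
annotate_ths <- function(thss, genes) {
  if (nrow(genes) == 0) abort("need at least one gene")
  ann <- purrr::map(seq_len(nrow(thss)), function(i) {
    t <- thss[i, ]
    mid <- (t$start + t$end) %/% 2L
    g_chr <- genes[genes$chrom == t$chrom, ]
    if (nrow(g_chr) == 0) {
      return(tibble(gene_id = NA_character_, tss_distance = NA_integer_,
                    category = "DistalIntergenic"))
    }
    dist <- if_else(g_chr$strand == "+", mid - g_chr$tss, g_chr$tss - mid)
    ord <- order(abs(dist), g_chr$gene_id)
    g <- g_chr[ord[1], ]
    d <- dist[ord[1]]
    category <- categorize_position(mid, g, d)
    tibble(gene_id = g$gene_id, tss_distance = as.integer(d),
           category = category)
  })
  bind_cols(thss, bind_rows(ann))
}

categorize_position <- function(mid, g, tss_dist) {
  if (mid >= g$start && mid < g$end) {
    ex <- g$exons[[1]]
    in_exon <- which(ex$start <= mid & mid < ex$end)
    if (length(in_exon) > 0) {
      # first transcribed exon, upstream of the start codon -> 5'UTR
      first_ex <- if (g$strand == "+") 1L else nrow(ex)
      upstream_of_sc <- if (g$strand == "+") mid < g$start_codon else
        mid > g$start_codon
      if (in_exon[1] == first_ex && upstream_of_sc) return("5'UTR-proxy")
      return("Exon")
    }
    return("Intron")
  }
  if (tss_dist < 0) {
    d <- -tss_dist
    if (d <= 1000) return("Promoter<=1kb")
    if (d <= 2000) return("Promoter1-2kb")
    if (d <= 3000) return("Promoter2-3kb")
  }
  past3p <- if (g$strand == "+") mid - (g$end - 1L) else g$start - mid
  if (past3p > 0 && past3p <= 1000) return("Downstream<=1kb")
  "DistalIntergenic"
}

#' Hypergeometric term over-representation
#'
#' Generic over-representation test of user-supplied term annotations:
#' for each term, the upper-tail hypergeometric probability of observing
#' at least the foreground's hit count, with Benjamini–Hochberg
#' correction across terms. Terms absent from both sets are skipped with
#' a warning.
#'
#' @param foreground Character vector of gene ids (the gene set of
#'   interest).
#' @param background Character vector of gene ids (the universe;
#'   must contain the foreground).
#' @param term_map Tibble with columns `gene_id` and `term`.
#' @return Tibble `term`, `k`, `K`, `n`, `N`, `p`, `q` sorted by `p`.
#' @export
term_enrichment <- function(foreground, background, term_map) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background)) {
    abort("foreground genes missing from background")
  }
  N <- length(background)
  n <- length(foreground)
  terms <- unique(term_map$term)
  rows <- purrr::map(terms, function(tm) {
    members <- term_map$gene_id[term_map$term == tm]
    K <- sum(background %in% members)
    k <- sum(foreground %in% members)
    if (K == 0) {
      warn(paste0("term absent from background, skipped: ", tm))
      return(NULL)
    }
    tibble(term = tm, k = k, K = K, n = n, N = N,
           p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$q <- p.adjust(out$p, method = "BH")
  arrange(out, .data$p)
}
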