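#' Convert fragments to Tn5-corrected insertion positions
#'
#' Each fragment contributes its two transposition events: the left end
#' plus `plus_offset` and the right end minus 1 plus `minus_offset`
#' (0-based positions). Defaults are the standard +4/−5 Tn5 stagger
#' correction; set `plus_offset = 2, minus_offset = -2` for the ±2 bp
#' convention. Out-of-bounds positions are clipped to the chromosome and
#' counted in the `n_clipped` attribute.
#'
#' @param frags Fragment tibble (may hold several samples).
#' @param chrom_lens Named chromosome lengths, see [genome_lengths()].
#' @param plus_offset,minus_offset Offsets applied to the fragment's
#'   plus- and minus-strand transposition ends.
#' @return Insertion tibble `sample_id`, `chrom`, `pos`, sorted within
#'   sample and chromosome; attribute `n_clipped`.
#' @export
make_insertion_track <- function(frags, chrom_lens,
                                 plus_offset = 4L, minus_offset = -5L) {
  if (any(!frags$chrom %in% names(chrom_lens))) {
    abort("fragment chromosome missing from genome")
  }
  left <- frags$start + plus_offset
  right <- frags$end - 1L + minus_offset
  lens <- unname(chrom_lens[frags$chrom])
  pos <- c(left, right)
  lens2 <- c(lens, lens)
  clipped <- sum(pos < 0 | pos >= lens2)
  pos <- pmin(pmax(pos, 0L), lens2 - 1L)
  out <- tibble(sample_id = rep(frags$sample_id, 2),
                chrom = rep(frags$chrom, 2), pos = as.integer(pos))
  out <- arrange(out, .data$sample_id, .data$chrom, .data$pos)
  attr(out, "n_clipped") <- clipped
  out
}

#' Fragment-length histogram
#'
#' Bins fragment lengths (end − start) at `bin` bp. Counts conserve the
#' total fragment number per sample.
#'
#' @param frags Fragment tibble.
#' @param bin Bin width in bp.
#' @return Tibble `sample_id`, `bin_start`, `count`.
#' @export
fragment_length_histogram <- function(frags, bin = 10L) {
  if (nrow(frags) == 0) {
    return(tibble(sample_id = character(), bin_start = integer(),
                  count = integer()))
  }
  frags |>
    mutate(len = .data$end - .data$start,
           bin_start = (.data$len %/% bin) * bin) |>
    count(.data$sample_id, .data$bin_start, name = "count")
}

#' TSS insertion profile and enrichment ratio
#'
#' Collects insertion counts on strand-oriented coordinates around each
#' gene's TSS (negative = upstream). The enrichment ratio is the mean
#' signal over the central ±50 bp divided by the mean over the outer
#' 100 bp of each flank; an all-zero profile has ratio 0.
#'
#' @param track Insertion tibble from [make_insertion_track()] (one
#'   sample, or pool of samples).
#' @param genes Gene model tibble.
#' @param window Half-window in bp.
#' @param chrom_lens Optional named chromosome lengths; when given, genes
#'   whose window exceeds the chromosome are counted in
#'   `n_clipped_genes`.
#' @return A `tss_profile`: list with `positions` (−window..window),
#'   `mean_signal` (insertions per gene per bp), `per_gene` matrix,
#'   `enrichment_ratio`, `n_genes`, `n_clipped_genes`.
#' @export
tss_profile <- function(track, genes, window = 2000L, chrom_lens = NULL) {
  if (nrow(genes) == 0) abort("need at least one gene")
  w <- as.integer(window)
  positions <- seq(-w, w)
  mat <- matrix(0, nrow = nrow(genes), ncol = length(positions),
                dimnames = list(genes$gene_id, NULL))
  by_chrom <- split(track$pos, track$chrom)
  by_chrom <- lapply(by_chrom, sort)
  n_clipped <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lo <- g$tss - w; hi <- g$tss + w
    if (lo < 0 ||
        (!is.null(chrom_lens) && hi >= chrom_lens[[g$chrom]])) {
      n_clipped <- n_clipped + 1L
    }
    pos <- by_chrom[[g$chrom]]
    if (is.null(pos)) next
    sel <- pos[pos >= lo & pos <= hi]
    if (length(sel) == 0) next
    rel <- sel - g$tss
    if (g$strand == "-") rel <- -rel
    tab <- table(rel + w + 1L)
    mat[i, as.integer(names(tab))] <- as.integer(tab)
  }
  mean_signal <- colMeans(mat)
  centre <- mean_signal[abs(positions) <= 50]
  flank <- mean_signal[abs(positions) >= w - 100]
  ratio <- if (sum(mean_signal) == 0) 0 else mean(centre) / mean(flank)
  structure(list(positions = positions, mean_signal = mean_signal,
                 per_gene = mat, enrichment_ratio = ratio,
                 n_genes = nrow(genes), n_clipped_genes = n_clipped),
            class = "tss_profile")
}

#' @export
tidy.tss_profile <- function(x, ...) {
  tibble(position = x$positions, mean_signal = x$mean_signal)
}

#' @export
glance.tss_profile <- function(x, ...) {
  tibble(enrichment_ratio = x$enrichment_ratio, n_genes = x$n_genes,
         total_signal = sum(x$per_gene))
}

#' Replicate correlation clustergram
#'
#' Pearson correlation of log2(x+1)-transformed per-peak counts between
#' samples, followed by average-linkage hierarchical clustering on 1 − r.
#' Zero-variance samples (correlation undefined) are excluded with a
#' warning.
#'
#' @param counts Wide count tibble (first column the interval id, one
#'   numeric column per sample), as from [count_matrix()].
#' @return A `ths_clustergram`: list with the correlation matrix, the
#'   deterministic dendrogram leaf `order`, the `hclust` object and any
#'   `excluded` samples.
#' @export
sample_correlation_clustergram <- function(counts) {
  mat <- as.matrix(counts[, -1, drop = FALSE])
  if (ncol(mat) < 2) abort("need at least two samples")
  lg <- log2(mat + 1)
  v <- apply(lg, 2, stats::var)
  excluded <- colnames(lg)[v == 0]
  if (length(excluded) > 0) {
    warn(paste("zero-variance samples excluded:",
               paste(excluded, collapse = ", ")))
    lg <- lg[, v > 0, drop = FALSE]
  }
  if (ncol(lg) < 2) abort("fewer than two samples with variance")
  r <- cor(lg)
  hc <- hclust(as.dist(1 - r), method = "average")
  structure(list(correlation = r, order = hc$order, hclust = hc,
                 excluded = excluded),
            class = "ths_clustergram")
}

#' @export
tidy.ths_clustergram <- function(x, ...) {
  r <- x$correlation
  as_tibble(as.data.frame.table(r, responseName = "r",
                                stringsAsFactors = FALSE)) |>
    rename(sample_a = "Var1", sample_b = "Var2")
}
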