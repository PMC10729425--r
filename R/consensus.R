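# helper: IRanges from a peak-like tibble (0-based half-open -> IRanges)
as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

# union-merge a peak-like tibble into disjoint intervals per chromosome
reduce_intervals <- function(df) {
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  out <- lapply(split(df, df$chrom), function(d) {
    r <- IRanges::reduce(as_iranges(d))
    tibble(chrom = d$chrom[1], start = IRanges::start(r) - 1L,
           end = IRanges::end(r))
  })
  arrange(bind_rows(out), .data$chrom, .data$start)
}

#' Reproducibility filtering of replicate peak calls
#'
#' A peak is retained iff, in at least `min_reps - 1` other replicates,
#' some peak overlaps it by at least `min_overlap_frac` of the retained
#' peak's own length (asymmetric rule; set `reciprocal = TRUE` to also
#' require the fraction of the other peak's length). Retained peaks and
#' the peaks that supported them are then union-merged into
#' condition-level peaks, so a short reproducible peak carries its wider
#' supporting evidence into the consensus span.
#'
#' @param replicate_peaks List of peak tibbles, one per replicate.
#' @param min_reps Minimum number of replicates supporting a peak
#'   (including its own).
#' @param min_overlap_frac Minimal overlap fraction.
#' @param reciprocal Require the overlap fraction in both directions.
#' @return Tibble of merged condition-level peaks (`chrom`, `start`,
#'   `end`).
#' @export
reproducible_peaks <- function(replicate_peaks, min_reps = 2L,
                               min_overlap_frac = 0.5,
                               reciprocal = FALSE) {
  n_rep <- length(replicate_peaks)
  if (min_reps > n_rep) {
    abort(sprintf("min_reps (%d) exceeds number of replicates (%d)",
                  min_reps, n_rep))
  }
  supporters <- function(p, other) {
    # peaks in `other` overlapping peak p by >= frac of p's length
    o <- other[other$chrom == p$chrom, , drop = FALSE]
    if (nrow(o) == 0) return(o)
    ov <- pmin(o$end, p$end) - pmax(o$start, p$start)
    ok <- ov >= min_overlap_frac * (p$end - p$start)
    if (reciprocal) ok <- ok & ov >= min_overlap_frac * (o$end - o$start)
    o[ok, , drop = FALSE]
  }
  kept <- list()
  for (i in seq_len(n_rep)) {
    peaks_i <- replicate_peaks[[i]]
    if (nrow(peaks_i) == 0) next
    for (j in seq_len(nrow(peaks_i))) {
      p <- peaks_i[j, ]
      sup <- lapply(seq_len(n_rep)[-i], function(k) {
        supporters(p, replicate_peaks[[k]])
      })
      n_support <- sum(vapply(sup, nrow, integer(1)) > 0)
      if (n_support >= min_reps - 1L) {
        kept[[length(kept) + 1L]] <-
          bind_rows(c(list(p), sup))[, c("chrom", "start", "end")]
      }
    }
  }
  reduce_intervals(bind_rows(kept))
}

#' Build consensus THS intervals across conditions
#'
#' Condition-level peaks are union-merged across all conditions into one
#' consensus list; each consensus interval is flagged present in a
#' condition iff any of that condition's peaks overlaps it by at least
#' one bp. The partition (exact set of present conditions) maps onto the
#' named desiccation stage groups: `{C}` watered_unique, `{C,D1}`
#' watered_to_moderate, `{C,D1,D2}` watered_to_severe, `{D2,D3}`
#' severe_to_dry, all four constitutive, anything else other.
#'
#' @param condition_peaks Named list (C, D1, D2, D3) of condition-level
#'   peak tibbles from [reproducible_peaks()].
#' @return THS tibble: `ths_id`, `chrom`, `start`, `end`, logical
#'   presence columns `C`..`D3`, `partition`, `stage_group`.
#' @export
build_consensus <- function(condition_peaks) {
  stopifnot(all(names(condition_peaks) %in% STAGES))
  merged <- reduce_intervals(bind_rows(condition_peaks))
  if (nrow(merged) == 0) {
    return(bind_cols(tibble(ths_id = character()), merged,
                     tibble(C = logical(), D1 = logical(),
                            D2 = logical(), D3 = logical(),
                            partition = character(),
                            stage_group = character())))
  }
  pres <- matrix(FALSE, nrow(merged), length(STAGES),
                 dimnames = list(NULL, STAGES))
  for (cond in STAGES) {
    cp <- condition_peaks[[cond]]
    if (is.null(cp) || nrow(cp) == 0) next
    for (ch in unique(merged$chrom)) {
      mi <- which(merged$chrom == ch)
      ci <- cp[cp$chrom == ch, ]
      if (nrow(ci) == 0) next
      hits <- IRanges::overlapsAny(as_iranges(merged[mi, ]),
                                   as_iranges(ci))
      pres[mi, cond] <- hits
    }
  }
  partition <- apply(pres, 1, function(p)
    paste(STAGES[p], collapse = ","))
  tibble(ths_id = sprintf("THS_%04d", seq_len(nrow(merged)))) |>
    bind_cols(merged) |>
    bind_cols(as_tibble(pres)) |>
    mutate(partition = partition,
           stage_group = vapply(strsplit(partition, ","),
                                stage_group_of, character(1)))
}

#' Venn partition of THSs across conditions
#'
#' Counts THSs by their exact condition subset. Counts over all nonempty
#' subsets sum to the number of THSs.
#'
#' @param thss THS tibble from [build_consensus()].
#' @return Tibble `partition`, `stage_group`, `n`, sorted by descending
#'   `n`.
#' @export
venn_partition <- function(thss) {
  out <- thss |>
    count(.data$partition, .data$stage_group, name = "n") |>
    arrange(dplyr::desc(.data$n), .data$partition)
  stopifnot(sum(out$n) == nrow(thss))
  out
}

#' THS-by-sample insertion count matrix
#'
#' Counts insertions falling inside each THS interval per sample.
#'
#' @param thss THS tibble.
#' @param tracks Insertion tibble covering all samples, from
#'   [make_insertion_track()].
#' @return Wide tibble: `ths_id` plus one integer column per sample.
#' @export
count_matrix <- function(thss, tracks) {
  samples <- sort(unique(tracks$sample_id))
  out <- matrix(0L, nrow(thss), length(samples),
                dimnames = list(thss$ths_id, samples))
  for (sid in samples) {
    tr <- tracks[tracks$sample_id == sid, ]
    for (ch in unique(thss$chrom)) {
      ti <- which(thss$chrom == ch)
      pos <- sort(tr$pos[tr$chrom == ch])
      if (length(pos) == 0) next
      # count of pos in [start, end) via binary search
      lo <- findInterval(thss$start[ti] - 0.5, pos)
      hi <- findInterval(thss$end[ti] - 0.5, pos)
      out[ti, sid] <- hi - lo
    }
  }
  bind_cols(tibble(ths_id = thss$ths_id), as_tibble(out))
}

#' Per-condition log2 fold-change matrix
#'
#' Counts are CPM-normalized per sample, averaged within condition, and
#' each desiccation stage is compared to the watered baseline as
#' `log2((x + 1) / (x_C + 1))`.
#'
#' @param counts Wide count tibble from [count_matrix()].
#' @param samples Sample sheet tibble (`sample_id`, `condition`).
#' @param baseline Baseline condition (default `"C"`).
#' @return Tibble `ths_id` plus one log2-FC column per non-baseline
#'   condition.
#' @export
fold_change_matrix <- function(counts, samples, baseline = "C") {
  mat <- as.matrix(counts[, -1, drop = FALSE])
  libsize <- colSums(mat)
  libsize[libsize == 0] <- 1
  cpm <- sweep(mat, 2, libsize, "/") * 1e6
  conds <- samples$condition[match(colnames(mat), samples$sample_id)]
  cond_means <- vapply(STAGES, function(cond) {
    cols <- which(conds == cond)
    if (length(cols) == 0) rep(NA_real_, nrow(cpm)) else
      rowMeans(cpm[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  others <- setdiff(STAGES, baseline)
  fc <- vapply(others, function(cond) {
    log2((cond_means[, cond] + 1) / (cond_means[, baseline] + 1))
  }, numeric(nrow(mat)))
  bind_cols(tibble(ths_id = counts[[1]]), as_tibble(fc))
}
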