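#' Peak-calling parameters
#'
#' Defaults mirror the single-sample insertion-windowing model: each
#' insertion is shifted by −100 bp and extended to a 200-bp pileup
#' element, scored against a local Poisson background taken as the
#' maximum of the genome-wide rate and rates in 1/5/10-kb windows.
#'
#' @param shift Shift applied to each insertion before extension (bp).
#' @param extsize Pileup element length (bp).
#' @param qvalue_cutoff Benjamini–Hochberg q threshold.
#' @param local_windows Window sizes for the local lambda estimate (bp).
#' @param min_peak_len Minimum peak length; default `extsize / 2`.
#' @param merge_gap Maximum gap between significant runs merged into one
#'   peak (bp).
#' @return A `peak_params` list.
#' @export
peak_params <- function(shift = -100L, extsize = 200L,
                        qvalue_cutoff = 0.05,
                        local_windows = c(1000L, 5000L, 10000L),
                        min_peak_len = NULL, merge_gap = 30L) {
  stopifnot(extsize > 0, qvalue_cutoff > 0, qvalue_cutoff < 1)
  structure(list(shift = as.integer(shift), extsize = as.integer(extsize),
                 qvalue_cutoff = qvalue_cutoff,
                 local_windows = as.integer(local_windows),
                 min_peak_len = as.integer(min_peak_len %||% (extsize %/% 2L)),
                 merge_gap = as.integer(merge_gap)),
            class = "peak_params")
}

#' Insertion pileup coverage
#'
#' Each insertion at position p contributes +1 over
#' `[p + shift, p + shift + extsize)`, clipped to the chromosome.
#'
#' @param positions Integer insertion positions (0-based) on one
#'   chromosome.
#' @param chrom_len Chromosome length (bp).
#' @param shift,extsize See [peak_params()].
#' @return Integer coverage vector of length `chrom_len` (element i is
#'   coverage of base i−1).
#' @export
pileup_coverage <- function(positions, chrom_len, shift = -100L,
                            extsize = 200L) {
  s <- pmin(pmax(positions + shift, 0L), chrom_len)
  e <- pmin(pmax(positions + shift + extsize, 0L), chrom_len)
  keep <- s < e
  s <- s[keep]; e <- e[keep]
  d <- tabulate(s + 1L, nbins = chrom_len + 1L) -
    tabulate(e + 1L, nbins = chrom_len + 1L)
  cumsum(d)[seq_len(chrom_len)]
}

# running mean of cov over a centred window, clipped at chromosome ends
running_mean <- function(cov, w) {
  n <- length(cov)
  cs <- c(0, cumsum(cov))
  i <- seq_len(n) - 1L
  lo <- pmax(i - w %/% 2L, 0L)
  hi <- pmin(i + w %/% 2L, n)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Call peaks from an insertion track
#'
#' Minimal local-lambda Poisson caller. Per position the background rate
#' is the maximum of the genome-wide rate and running means over the
#' local windows (computed from the same sample's pileup); the p-value is
#' the upper Poisson tail of the observed coverage. Benjamini–Hochberg is
#' applied over candidate positions (leftmost points of coverage
#' local-maxima runs); positions whose p-value does not exceed the
#' largest candidate p with q below the cutoff are merged into peaks
#' (gaps up to `merge_gap` joined, peaks shorter than `min_peak_len`
#' dropped). The summit is the leftmost coverage maximum of the peak and
#' the score is −log10 p there.
#'
#' @param track Insertion tibble (one sample) from
#'   [make_insertion_track()].
#' @param chrom_lens Named chromosome lengths.
#' @param params A [peak_params()].
#' @return Peak tibble `chrom`, `start`, `end`, `summit`, `score`,
#'   `pvalue`, `qvalue`, sorted and non-overlapping; empty tibble when no
#'   position is significant.
#' @export
call_peaks <- function(track, chrom_lens, params = peak_params()) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  summit = integer(), score = numeric(),
                  pvalue = numeric(), qvalue = numeric())
  if (nrow(track) == 0) return(empty)
  stopifnot(all(chrom_lens > params$extsize))
  covs <- lapply(names(chrom_lens), function(ch) {
    pileup_coverage(track$pos[track$chrom == ch], chrom_lens[[ch]],
                    params$shift, params$extsize)
  })
  names(covs) <- names(chrom_lens)
  lambda_genome <- sum(vapply(covs, sum, numeric(1))) /
    sum(as.numeric(chrom_lens))

  per_chrom <- lapply(names(chrom_lens), function(ch) {
    cov <- covs[[ch]]
    lam <- rep(lambda_genome, length(cov))
    for (w in params$local_windows) lam <- pmax(lam, running_mean(cov, w))
    # natural-log upper-tail Poisson p-values, safe against underflow
    lp <- ppois(cov - 1L, lam, lower.tail = FALSE, log.p = TRUE)
    # candidates: leftmost position of each local-maximum coverage run
    r <- rle(cov)
    nr <- length(r$values)
    is_max <- (c(TRUE, r$values[-1] > r$values[-nr])) &
      (c(r$values[-nr] > r$values[-1], TRUE)) & r$values > 0
    run_start <- cumsum(c(1L, r$lengths[-nr]))
    cand_pos <- run_start[is_max]   # 1-based index into cov
    list(chrom = ch, cov = cov, lp = lp, cand_pos = cand_pos)
  })

  cand_lp <- unlist(lapply(per_chrom, function(x) x$lp[x$cand_pos]))
  if (length(cand_lp) == 0) return(empty)
  cand_q <- p.adjust(exp(cand_lp), method = "BH")
  if (!any(cand_q < params$qvalue_cutoff)) return(empty)
  # BH q as a step function of p over the candidate set. Every position
  # lies on the hill of some local-maximum candidate whose p is at most
  # its own, so rounding p down to the candidate grid assigns each
  # position the q of its dominating candidate.
  ord <- order(cand_lp)
  slp <- cand_lp[ord]
  sq <- cand_q[ord]          # monotone non-decreasing in p under BH
  q_of_lp <- function(lp) {
    idx <- findInterval(lp, slp)
    idx[idx == 0L] <- 1L
    sq[idx]
  }

  peaks <- list()
  for (pc in per_chrom) {
    idx <- which(q_of_lp(pc$lp) < params$qvalue_cutoff)
    if (length(idx) == 0) next
    brk <- which(diff(idx) > params$merge_gap + 1L)
    starts <- idx[c(1L, brk + 1L)]
    ends <- idx[c(brk, length(idx))]
    for (j in seq_along(starts)) {
      s0 <- starts[j] - 1L; e0 <- ends[j]     # 0-based half-open
      if (e0 - s0 < params$min_peak_len) next
      seg <- pc$cov[starts[j]:ends[j]]
      summit <- s0 + which.max(seg) - 1L
      lp_s <- pc$lp[summit + 1L]
      peaks[[length(peaks) + 1L]] <- tibble(
        chrom = pc$chrom, start = s0, end = e0,
        summit = as.integer(summit),
        score = -lp_s / log(10),
        pvalue = exp(lp_s), qvalue = q_of_lp(lp_s))
    }
  }
  if (length(peaks) == 0) return(empty)
  arrange(bind_rows(peaks), .data$chrom, .data$start)
}
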