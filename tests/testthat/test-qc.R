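test_that("insertion offsets follow the Tn5 convention with clipping", {
  lens <- c(chr1 = 1000L)
  fr <- tibble::tibble(sample_id = "s", condition = "C", replicate = 1L,
                       chrom = "chr1", start = 100L, end = 300L)
  tr <- make_insertion_track(fr, lens, 4L, -5L)
  expect_setequal(tr$pos, c(104L, 294L))
  tr0 <- make_insertion_track(fr, lens, 0L, 0L)
  expect_setequal(tr0$pos, c(100L, 299L))
  edge <- dplyr::mutate(fr, start = 0L, end = 10L)
  tre <- make_insertion_track(edge, lens, 4L, -5L)
  expect_equal(tre$pos, c(4L, 4L))
  expect_true(all(tre$pos >= 0))
})

test_that("insertion count conservation holds exactly", {
  withr::local_seed(21)
  lens <- c(chr1 = 5000L, chr2 = 3000L)
  n <- 500
  fr <- tibble::tibble(
    sample_id = "s", condition = "C", replicate = 1L,
    chrom = sample(names(lens), n, replace = TRUE),
    start = sample.int(2500, n) - 1L)
  fr$end <- fr$start + sample(30:400, n, replace = TRUE)
  fr$end <- pmin(fr$end, lens[fr$chrom])
  tr <- make_insertion_track(fr, lens)
  expect_equal(nrow(tr), 2L * n)
})

test_that("empty fragment sets give an empty histogram", {
  h <- fragment_length_histogram(
    tibble::tibble(sample_id = character(), condition = character(),
                   replicate = integer(), chrom = character(),
                   start = integer(), end = integer()))
  expect_equal(nrow(h), 0L)
})

test_that("TSS profile is a delta when all insertions sit on TSSs", {
  genes <- dplyr::bind_rows(
    tiny_gene("g1", strand = "+", start = 5000L, end = 8000L),
    tiny_gene("g2", strand = "-", start = 15000L, end = 18000L))
  tr <- tibble::tibble(sample_id = "s", chrom = "chr1",
                       pos = rep(genes$tss, each = 3))
  pr <- tss_profile(tr, genes, window = 500L)
  expect_equal(pr$mean_signal[pr$positions == 0], 3)
  expect_equal(sum(pr$mean_signal), 3)
  # brute-force recount of the enrichment ratio
  centre <- mean(pr$mean_signal[abs(pr$positions) <= 50])
  flank <- mean(pr$mean_signal[abs(pr$positions) >= 400])
  expect_equal(pr$enrichment_ratio, centre / flank)
  expect_true(is.infinite(pr$enrichment_ratio))
})

test_that("minus-strand genes orient upstream as negative positions", {
  g <- tiny_gene("gm", strand = "-", start = 10000L, end = 13000L)
  # 100 bp upstream of a minus-strand TSS is to the right
  tr <- tibble::tibble(sample_id = "s", chrom = "chr1",
                       pos = g$tss + 100L)
  pr <- tss_profile(tr, g, window = 500L)
  expect_equal(pr$mean_signal[pr$positions == -100], 1)
  expect_equal(pr$mean_signal[pr$positions == 100], 0)
})

test_that("TSS profile equals a per-gene brute-force recount", {
  withr::local_seed(33)
  genes <- dplyr::bind_rows(lapply(1:20, function(i) {
    tiny_gene(sprintf("g%02d", i),
              strand = sample(c("+", "-"), 1),
              start = 3000L + i * 8000L, end = 6000L + i * 8000L)
  }))
  tr <- tibble::tibble(sample_id = "s", chrom = "chr1",
                       pos = sample.int(200000L, 5000L) - 1L)
  w <- 300L
  pr <- tss_profile(tr, genes, window = w)
  brute <- matrix(0, nrow(genes), 2 * w + 1)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    for (p in tr$pos) {
      rel <- if (g$strand == "+") p - g$tss else g$tss - p
      if (abs(rel) <= w) {
        brute[i, rel + w + 1] <- brute[i, rel + w + 1] + 1
      }
    }
  }
  expect_equal(unname(pr$per_gene), brute)
  expect_equal(pr$mean_signal, colMeans(brute))
})

test_that("all-zero profiles have enrichment ratio 0", {
  g <- tiny_gene("g1")
  tr <- tibble::tibble(sample_id = "s", chrom = "chr1", pos = integer())
  expect_equal(tss_profile(tr, g, 200L)$enrichment_ratio, 0)
})

test_that("correlation clustergram handles exact and degenerate cases", {
  withr::local_seed(5)
  base <- rpois(50, 20)
  counts <- tibble::tibble(ths_id = sprintf("t%02d", 1:50),
                           a = base, b = base,
                           c = rpois(50, 20), d = rpois(50, 20))
  cl <- sample_correlation_clustergram(counts)
  expect_equal(cl$correlation["a", "b"], 1)
  # duplicated samples cluster adjacently
  ord <- colnames(cl$correlation)[cl$order]
  expect_equal(abs(which(ord == "a") - which(ord == "b")), 1L)
  # symmetry and unit diagonal
  expect_lt(max(abs(cl$correlation - t(cl$correlation))), 1e-12)
  expect_equal(unname(diag(cl$correlation)), rep(1, 4))
})

test_that("anti-correlated columns give r = -1 on the log scale", {
  x <- 2^(1:20) - 1
  counts <- tibble::tibble(id = as.character(1:20),
                           up = x, down = rev(x))
  cl <- sample_correlation_clustergram(counts)
  expect_equal(cl$correlation["up", "down"], -1)
})

test_that("zero-variance samples are excluded with a warning", {
  counts <- tibble::tibble(id = as.character(1:10),
                           a = rpois(10, 10), b = rpois(10, 10),
                           flat = rep(5, 10))
  expect_warning(cl <- sample_correlation_clustergram(counts), "flat")
  expect_equal(colnames(cl$correlation), c("a", "b"))
})

test_that("replicates of a condition cluster together on simulated data", {
  cfg <- sim_config(seed = 12, n_chroms = 1L, chrom_len = 400000L,
                    n_genes = 40L, n_accessible_per_condition = 3L,
                    n_intergenic_decoys = 4L,
                    fragments_per_sample = 10000L)
  sim <- simulate_atac_experiment(cfg)
  lens <- genome_lengths(sim$genome)
  track <- make_insertion_track(sim$fragments, lens)
  reg <- sim$truth$accessible_regions
  thss <- tibble::tibble(ths_id = reg$region_id, chrom = reg$chrom,
                         start = reg$start, end = reg$end)
  counts <- count_matrix(thss, track)
  cl <- sample_correlation_clustergram(counts)
  # same-condition replicates are mutually closer than to other stages
  ord <- colnames(cl$correlation)[cl$order]
  conds <- sub("_rep\\d$", "", ord)
  runs <- rle(conds)$lengths
  expect_true(all(runs == 3))
})
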