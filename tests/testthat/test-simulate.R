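small_cfg <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_chroms = 1L, chrom_len = 400000L,
                   n_genes = 40L, n_accessible_per_condition = 2L,
                   n_intergenic_decoys = 4L,
                   fragments_per_sample = 5000L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("the generator is deterministic under its seed", {
  a <- simulate_genome_and_genes(small_cfg(5))
  b <- simulate_genome_and_genes(small_cfg(5))
  expect_equal(as.character(a$genome), as.character(b$genome))
  expect_equal(a$genes, b$genes)
  expect_equal(a$truth, b$truth)
  c <- simulate_genome_and_genes(small_cfg(6))
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
})

test_that("planted words sit at their recorded promoter offsets", {
  sim <- simulate_genome_and_genes(small_cfg(2))
  mp <- sim$truth$motif_positions
  expect_gt(nrow(mp), 0)
  proms <- extract_promoters(mp$gene_id, sim$genes, sim$genome)
  for (i in seq_len(nrow(mp))) {
    s <- proms$seq[proms$gene_id == mp$gene_id[i]]
    expect_equal(substr(s, mp$offset[i] + 1,
                        mp$offset[i] + nchar(mp$word[i])),
                 mp$word[i])
  }
})

test_that("a genome too small for the gene count errors", {
  expect_error(
    simulate_genome_and_genes(
      sim_config(n_chroms = 1L, chrom_len = 100000L, n_genes = 50L,
                 n_accessible_per_condition = 1L,
                 n_intergenic_decoys = 0L)),
    "too small")
})

test_that("fold-1 enrichment gives uniform fragment placement", {
  cfg <- small_cfg(3, enrichment_fold = 1, fragments_per_sample = 20000L)
  sim <- simulate_genome_and_genes(cfg)
  fr <- simulate_fragments(cfg, sim$truth, sim$genome)
  fr1 <- fr[fr$sample_id == "C_rep1", ]
  mid <- (fr1$start + fr1$end) %/% 2
  # chi-square GOF against uniform over 20 equal bins
  bins <- cut(mid, breaks = seq(0, cfg$chrom_len, length.out = 21))
  expect_gt(stats::chisq.test(table(bins))$p.value, 0.01)
})

test_that("condition-specific regions are enriched by the configured fold", {
  cfg <- small_cfg(4, n_accessible_per_condition = 4L,
                   fragments_per_sample = 30000L)
  sim <- simulate_genome_and_genes(cfg)
  fr <- simulate_fragments(cfg, sim$truth, sim$genome)
  reg <- sim$truth$accessible_regions
  c_only <- reg[reg$partition == "C", ]
  count_in <- function(cond) {
    f <- fr[fr$condition == cond, ]
    mid <- (f$start + f$end) %/% 2
    mean(vapply(seq_len(nrow(c_only)), function(i) {
      sum(f$chrom == c_only$chrom[i] & mid >= c_only$start[i] &
            mid < c_only$end[i]) / 3
    }, numeric(1)))
  }
  m_c <- count_in("C"); m_d3 <- count_in("D3")
  # exact expectation: the fold ratio corrected for each condition's
  # total placement weight (accessible area carries fold-1 extra weight)
  w_of <- function(cond) {
    acc <- vapply(strsplit(reg$partition, ","), function(p)
      cond %in% p, logical(1))
    cfg$chrom_len + sum((reg$end - reg$start)[acc]) *
      (cfg$enrichment_fold - 1)
  }
  expected_ratio <- cfg$enrichment_fold * w_of("D3") / w_of("C")
  # Poisson sampling error on both means, the D3 side amplified by the
  # expected ratio
  n_obs <- 3 * nrow(c_only)
  se <- sqrt(m_c / n_obs + expected_ratio^2 * m_d3 / n_obs)
  expect_lt(abs(m_c - expected_ratio * m_d3), 3 * se)
})

test_that("fragment lengths show nucleosomal modes near 180 and 360 bp", {
  cfg <- small_cfg(5, fragments_per_sample = 40000L)
  sim <- simulate_genome_and_genes(cfg)
  fr <- simulate_fragments(cfg, sim$truth, sim$genome)
  h <- fragment_length_histogram(fr[fr$sample_id == "C_rep1", ],
                                 bin = 20L)
  # local maximum detection on the binned histogram
  local_max_near <- function(target) {
    win <- h[abs(h$bin_start - target) <= 60, ]
    peak_bin <- win$bin_start[which.max(win$count)]
    abs(peak_bin - target) <= 40
  }
  expect_true(local_max_near(180))
  expect_true(local_max_near(360))
  expect_equal(sum(h$count), sum(fr$sample_id == "C_rep1"))
})

test_that("expression coupling limits behave as configured", {
  cfg1 <- small_cfg(6, expr_coupling = 1)
  sim <- simulate_genome_and_genes(cfg1)
  ex1 <- simulate_expression(cfg1, sim$truth, sim$genes)
  reg <- sim$truth$accessible_regions
  for (g in sim$truth$coupled_genes) {
    part <- reg$partition[match(g, reg$gene_id)]
    a <- thsdyn:::accessibility_profile(part, cfg1$enrichment_fold)
    expect_equal(unlist(ex1[ex1$gene_id == g, c("D1", "D2", "D3")]),
                 a, ignore_attr = TRUE)
  }
  expect_equal(names(ex1), c("gene_id", "D1", "D2", "D3"))
  expect_equal(nrow(ex1), nrow(sim$genes))

  # zero coupling: coupled genes look like decoys
  cfg0 <- small_cfg(6, expr_coupling = 0)
  ex0 <- simulate_expression(cfg0, sim$truth, sim$genes)
  coupled <- ex0$gene_id %in% sim$truth$coupled_genes
  a_prof <- t(vapply(ex0$gene_id[coupled], function(g) {
    thsdyn:::accessibility_profile(reg$partition[match(g, reg$gene_id)],
                                   cfg0$enrichment_fold)
  }, numeric(3)))
  r_prof <- as.matrix(ex0[coupled, c("D1", "D2", "D3")])
  rs <- vapply(seq_len(nrow(a_prof)), function(i) {
    if (sd(a_prof[i, ]) == 0) 0 else cor(a_prof[i, ], r_prof[i, ])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.3)
})

test_that("OJIP curves reduce to prototypes at zero noise, labels balanced", {
  cfg <- small_cfg(7, ojip_noise_sd = 0)
  oj <- simulate_ojip(cfg, n_per_stage = 5)
  proto <- ojip_prototypes(oj$times)
  expect_equal(unname(oj$values[, 1]), unname(proto[, "C"]))
  expect_equal(as.integer(table(oj$labels)), rep(5L, 4))
  # prototypes rise monotonically (O-J-I-P shape)
  for (s in colnames(proto)) expect_true(all(diff(proto[, s]) > 0))
})

test_that("the written fixture directory is complete and loadable", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(8)
  sim <- simulate_atac_experiment(cfg, dir)
  expect_true(all(file.exists(file.path(
    dir, c("genome.fa", "genes.gff3", "expression.tsv", "ojip.tsv",
           "samples.tsv", "truth.json")))))
  expect_equal(length(list.files(file.path(dir, "fragments"))), 12L)
  g <- read_genome_fasta(file.path(dir, "genome.fa"))
  expect_equal(genome_lengths(g), genome_lengths(sim$genome))
  gm <- read_gene_models(file.path(dir, "genes.gff3"))
  expect_equal(gm$tss, sim$genes$tss)
})
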