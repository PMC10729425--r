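test_that("promoter extraction follows the start-codon window per strand", {
  set.seed(60)
  seq1 <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = seq1))
  gp <- tiny_gene("gp", strand = "+", start = 10000L, end = 14000L,
                  utr5 = 0L)   # start codon at 10000
  pr <- extract_promoters("gp", gp, genome)
  expect_equal(pr$length, 3000L)
  expect_equal(pr$seq, substr(seq1, 7001, 10000))   # [7000, 10000)

  gm <- tiny_gene("gm", strand = "-", start = 2000L, end = 5001L,
                  utr5 = 0L)   # start codon at 5000
  prm <- extract_promoters("gm", gm, genome)
  # base-by-base independent reverse complement of [5001, 8001)
  fwd <- strsplit(substr(seq1, 5002, 8001), "")[[1]]
  rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[fwd])
  expect_equal(prm$seq, paste(rc, collapse = ""))
})

test_that("promoters clip at contig edges with the flag set", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 2000)))
  g <- tiny_gene("g", strand = "+", start = 900L, end = 3000L,
                 utr5 = 100L)   # start codon at 1000
  pr <- extract_promoters("g", g, genome)
  expect_equal(pr$length, 1000L)
  expect_true(pr$clipped)
})

test_that("dinucleotide shuffling conserves composition and is seeded", {
  set.seed(61)
  proms <- tibble::tibble(
    gene_id = c("a", "b"),
    seq = vapply(1:2, function(i)
      paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
            collapse = ""), character(1)),
    length = 400L, clipped = FALSE)
  sh1 <- shuffle_negatives(proms, seed = 3)
  sh2 <- shuffle_negatives(proms, seed = 3)
  expect_identical(sh1$seq, sh2$seq)
  expect_false(identical(sh1$seq, proms$seq))
  for (i in 1:2) {
    expect_equal(dinuc_counts(sh1$seq[i]), dinuc_counts(proms$seq[i]))
  }
})

test_that("a homopolymer has a single Eulerian arrangement", {
  proms <- tibble::tibble(gene_id = "h", seq = "AAAA", length = 4L,
                          clipped = FALSE)
  expect_equal(shuffle_negatives(proms, seed = 1)$seq, "AAAA")
})

test_that("planted hexamer frequency in shuffles matches the binomial expectation", {
  set.seed(62)
  base <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                collapse = "")
  proms <- tibble::tibble(gene_id = sprintf("s%03d", 1:200), seq = base,
                          length = 500L, clipped = FALSE)
  sh <- shuffle_negatives(proms, seed = 9)
  hits <- sum(vapply(sh$seq, function(s)
    lengths(regmatches(s, gregexpr("(?=TTGACC)", s, perl = TRUE))),
    integer(1)))
  # expected occurrences under the dinucleotide model, approximated by
  # the mononucleotide composition of the source sequence
  p <- prod(vapply(c("T", "T", "G", "A", "C", "C"), function(ch)
    sum(strsplit(base, "")[[1]] == ch) / 500, numeric(1)))
  expected <- 200 * 495 * p
  expect_lt(abs(hits - expected), 3 * sqrt(expected) + 3)
})

test_that("identical positive and negative sets yield no enriched motif", {
  set.seed(63)
  seqs <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
          collapse = ""), character(1))
  pr <- tibble::tibble(gene_id = sprintf("g%02d", 1:30), seq = seqs,
                       length = 300L, clipped = FALSE)
  res <- dreme_enrich(pr, pr, max_len = 6)
  expect_equal(nrow(res), 0L)
})

test_that("a planted W-box word is recovered with a Fisher-exact p matching the oracle", {
  seqs_pos <- random_seqs_without(100, 100, "TTGACC", seed = 64)
  seqs_neg <- random_seqs_without(100, 100, "TTGACC", seed = 65)
  seqs_pos <- plant_word(seqs_pos, "TTGACC", 1:80, seed = 66)
  seqs_neg <- plant_word(seqs_neg, "TTGACC", 1:10, seed = 67)
  pos <- tibble::tibble(gene_id = sprintf("p%03d", 1:100),
                        seq = seqs_pos, length = 100L, clipped = FALSE)
  neg <- tibble::tibble(gene_id = sprintf("n%03d", 1:100),
                        seq = seqs_neg, length = 100L, clipped = FALSE)
  res <- dreme_enrich(pos, neg, max_len = 6)
  expect_gt(nrow(res), 0)
  top <- res[1, ]
  expect_true(top$core %in% c("TTGACC", "GGTCAA"))
  # independent oracle: one-sided Fisher on the reported 2x2 table
  tab <- matrix(c(top$pos_hits, top$n_pos - top$pos_hits,
                  top$neg_hits, top$n_neg - top$neg_hits), 2)
  p_oracle <- stats::fisher.test(tab, alternative = "greater")$p.value
  expect_equal(top$p, p_oracle, tolerance = 1e-10)
  expect_equal(top$evalue, top$p * top$candidates_tested)
})

test_that("reverse-strand occurrences count as hits", {
  # W-box on the reverse strand only: GGTCAA on the forward strand
  seqs_pos <- random_seqs_without(40, 80, "TTGACC", seed = 70)
  seqs_pos <- plant_word(seqs_pos, "GGTCAA", 1:35, seed = 71)
  seqs_neg <- random_seqs_without(40, 80, "TTGACC", seed = 72)
  pos <- tibble::tibble(gene_id = sprintf("p%02d", 1:40),
                        seq = seqs_pos, length = 80L, clipped = FALSE)
  neg <- tibble::tibble(gene_id = sprintf("n%02d", 1:40),
                        seq = seqs_neg, length = 80L, clipped = FALSE)
  res <- dreme_enrich(pos, neg, max_len = 6)
  expect_gt(nrow(res), 0)
  expect_true(res$core[1] %in% c("TTGACC", "GGTCAA"))
})

test_that("masking strictly reduces the reported word's positive hits", {
  seqs_pos <- random_seqs_without(60, 100, "TTGACC", seed = 73)
  seqs_pos <- plant_word(seqs_pos, "TTGACC", 1:50, seed = 74)
  seqs_neg <- random_seqs_without(60, 100, "TTGACC", seed = 75)
  pos <- tibble::tibble(gene_id = sprintf("p%02d", 1:60),
                        seq = seqs_pos, length = 100L, clipped = FALSE)
  neg <- tibble::tibble(gene_id = sprintf("n%02d", 1:60),
                        seq = seqs_neg, length = 100L, clipped = FALSE)
  res <- dreme_enrich(pos, neg, max_len = 6)
  expect_gt(nrow(res), 0)
  masked <- thsdyn:::mask_word(toupper(pos$seq), res$word[1], TRUE)
  hits_after <- thsdyn:::pattern_hits(res$word[1], masked, TRUE)
  expect_lt(hits_after, res$pos_hits[1])
})

test_that("PWM matching is a self-match and strand-symmetric", {
  lib <- read_pwm_meme(system.file("extdata",
                                   "plant_motifs_synthetic.meme",
                                   package = "thsdyn"))
  m <- match_known_motifs(c("TTGACC", "GGTCAA", "GATAAG"), lib,
                          n_null = 200, seed = 5)
  expect_equal(m$pwm_name[1], "WBOX_synthetic")
  expect_equal(m$pwm_name[2], "WBOX_synthetic")   # reverse complement
  expect_equal(m$pwm_name[3], "GATA_synthetic")
  expect_true(all(m$p[c(1, 3)] < 0.05))
})

test_that("match p-values are valid under the null of random words", {
  set.seed(80)
  lib <- read_pwm_meme(system.file("extdata",
                                   "plant_motifs_synthetic.meme",
                                   package = "thsdyn"))
  words <- vapply(1:60, function(i)
    paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
          collapse = ""), character(1))
  m <- match_known_motifs(words, lib, n_null = 200, seed = 6)
  # permutation p-values with ties are discrete and conservative: the
  # rejection rate must never exceed the nominal level (plus binomial
  # sampling error), and the p-values must spread over (0, 1]
  for (alpha in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(m$p <= alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / length(words)))
  }
  expect_gt(mean(m$p > 0.5), 0.1)
})
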