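#' Simulation configuration
#'
#' Builds the configuration for the synthetic ATAC-seq experiment. The
#' defaults emulate the study design the pipeline targets: four stages
#' (watered control C plus desiccation stages D1/D2/D3 at ~50/20/6% RWC),
#' three replicates per stage, condition-specific accessible regions
#' placed 200 bp upstream of TSSs, nucleosome-periodic fragment lengths,
#' a W-box word planted in accessible promoters, expression profiles
#' coupled to accessibility, and four OJIP curve prototypes.
#'
#' @param seed Global seed; all per-sample randomness derives from it by
#'   fixed offsets.
#' @param n_chroms,chrom_len Number of chromosomes and their length (bp).
#' @param n_genes Number of gene models, split evenly across chromosomes.
#' @param replicates_per_condition Replicates per stage (default 3).
#' @param n_accessible_per_condition Number of promoter regions assigned
#'   to each canonical condition subset (the four singletons, the three
#'   stage-transition subsets and the constitutive set).
#' @param n_intergenic_decoys Accessible regions placed away from genes.
#' @param enrichment_fold Fragment-midpoint enrichment inside a region
#'   accessible in the sample's condition (>= 1).
#' @param fragments_per_sample Expected fragment count per sample
#'   (replicate totals are Poisson around this).
#' @param nfr_len_mean Mean nucleosome-free-region fragment length (bp).
#' @param nucleosome_period Nucleosomal fragment-length period (bp).
#' @param planted_motifs List of `list(word=, fraction_pos=, fraction_neg=)`;
#'   words are planted on the coding strand of promoters, `fraction_pos`
#'   of accessible-promoter genes and `fraction_neg` of the rest. The
#'   default is a W-box-bearing 8-mer: at the 3-kb promoter length a
#'   bare hexamer occurs in most sequences by chance, so a planted word
#'   must be at least 8 bp for per-sequence presence to carry signal.
#' @param expr_coupling In `[0,1]`; 1 means coupled genes' expression
#'   profiles equal their accessibility profiles exactly.
#' @param ojip_noise_sd Multiplicative Gaussian noise on OJIP curves.
#' @param region_len Accessible-region length (bp).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_len = 500000L,
                       n_genes = 80L,
                       replicates_per_condition = 3L,
                       n_accessible_per_condition = 5L,
                       n_intergenic_decoys = 8L,
                       enrichment_fold = 20,
                       fragments_per_sample = 50000L,
                       nfr_len_mean = 60,
                       nucleosome_period = 180,
                       planted_motifs = list(
                         list(word = "CTTGACCT", fraction_pos = 0.8,
                              fraction_neg = 0.05)),
                       expr_coupling = 0.9,
                       ojip_noise_sd = 0.05,
                       region_len = 300L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_len = as.integer(chrom_len), n_genes = as.integer(n_genes),
              conditions = STAGES,
              replicates_per_condition = as.integer(replicates_per_condition),
              n_accessible_per_condition = as.integer(n_accessible_per_condition),
              n_intergenic_decoys = as.integer(n_intergenic_decoys),
              enrichment_fold = enrichment_fold,
              fragments_per_sample = as.integer(fragments_per_sample),
              nfr_len_mean = nfr_len_mean,
              nucleosome_period = nucleosome_period,
              planted_motifs = planted_motifs,
              expr_coupling = expr_coupling,
              ojip_noise_sd = ojip_noise_sd,
              region_len = as.integer(region_len))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$enrichment_fold >= 1,
            cfg$expr_coupling >= 0, cfg$expr_coupling <= 1,
            cfg$ojip_noise_sd >= 0,
            identical(cfg$conditions, STAGES))
  for (m in cfg$planted_motifs) {
    stopifnot(m$fraction_pos >= 0, m$fraction_pos <= 1,
              m$fraction_neg >= 0, m$fraction_neg <= 1)
  }
  invisible(cfg)
}

# Deterministic fan-out of the global seed to per-stage child seeds.
child_seed <- function(seed, stage, index = 0L) {
  offs <- c(simulate = 11L, fragments = 23L, expression = 57L,
            ojip = 71L, shuffle = 83L, peaks = 97L)
  as.integer((as.numeric(seed) * 131 + offs[[stage]] * 1009 + index) %%
               .Machine$integer.max)
}

# Canonical condition subsets used to assign region partitions; covers the
# stage groups the downstream Venn partition names.
canonical_partitions <- function() {
  list("C", "D1", "D2", "D3",
       c("C", "D1"), c("C", "D1", "D2"), c("D2", "D3"),
       c("C", "D1", "D2", "D3"))
}

#' Simulate a toy genome with gene models and planted ground truth
#'
#' Background sequence is i.i.d. uniform ACGT. Genes are placed
#' non-overlapping with at least 4 kb clearance on both sides, so 3-kb
#' promoter windows never truncate. A subset of genes receives a 300-bp
#' accessible region centred 200 bp upstream of the TSS, with a condition
#' subset drawn from the canonical partitions; intergenic decoy regions
#' are added away from genes. Planted motif words are written into the
#' promoter sequence (coding strand) of designated genes at recorded
#' offsets.
#'
#' @param cfg A [sim_config()].
#' @return A list with `genome` (DNAStringSet), `genes` (gene model
#'   tibble), and `truth` (list: `accessible_regions`, `motif_positions`,
#'   `coupled_genes`).
#' @export
simulate_genome_and_genes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(child_seed(cfg$seed, "simulate"))
  clearance <- 4000L
  max_gene_len <- 3000L
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  slot <- clearance + max_gene_len + 2000L
  if (per_chrom * slot + clearance > cfg$chrom_len) {
    abort(sprintf(
      "genome too small: %d genes/chrom need %d bp, chromosome is %d bp",
      per_chrom, per_chrom * slot + clearance, cfg$chrom_len))
  }
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  seqs <- lapply(chroms, function(ch) {
    sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE)
  })
  names(seqs) <- chroms

  genes <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    ci <- ((i - 1L) %% cfg$n_chroms) + 1L
    si <- (i - 1L) %/% cfg$n_chroms
    glen <- as.integer(round(runif(1, 1500, max_gene_len)))
    jitter <- as.integer(floor(runif(1, 0, 1500)))
    g0 <- clearance + si * slot + jitter
    g1 <- g0 + glen
    strand <- sample(c("+", "-"), 1)
    utr5 <- as.integer(round(runif(1, 100, 300)))
    e1 <- as.integer(round(runif(1, 400, 700)))
    intron <- as.integer(round(runif(1, 100, 300)))
    exons <- tibble(start = c(g0, g0 + e1 + intron), end = c(g0 + e1, g1))
    if (strand == "+") {
      tss <- g0; sc <- g0 + utr5
    } else {
      tss <- g1 - 1L; sc <- g1 - 1L - utr5
    }
    genes[[i]] <- tibble(
      gene_id = sprintf("gene%03d", i), chrom = chroms[ci],
      strand = strand, start = g0, end = g1, tss = tss,
      start_codon = sc, exons = list(exons), other_mrnas = "")
  }
  genes <- bind_rows(genes)

  # accessible promoter regions: 300 bp centred 200 bp upstream of TSS
  parts <- canonical_partitions()
  n_acc <- cfg$n_accessible_per_condition * length(parts)
  stopifnot(n_acc <= cfg$n_genes)
  acc_idx <- sort(sample.int(cfg$n_genes, n_acc))
  part_assign <- rep(seq_along(parts), each = cfg$n_accessible_per_condition)
  part_assign <- sample(part_assign)
  half <- cfg$region_len %/% 2L
  regions <- purrr::map(seq_along(acc_idx), function(k) {
    g <- genes[acc_idx[k], ]
    centre <- if (g$strand == "+") g$tss - 200L else g$tss + 200L
    tibble(region_id = sprintf("reg%03d", k), chrom = g$chrom,
           start = centre - half, end = centre - half + cfg$region_len,
           partition = paste(parts[[part_assign[k]]], collapse = ","),
           gene_id = g$gene_id)
  })
  regions <- bind_rows(regions)

  # intergenic decoy regions in gaps far from any gene
  if (cfg$n_intergenic_decoys > 0) {
    gap_mid <- genes$end + 3000L + (genes$start + 4000L - genes$end) %/% 4L
    free <- setdiff(seq_len(cfg$n_genes), acc_idx)
    pick <- sample(free, min(cfg$n_intergenic_decoys, length(free)))
    dec <- purrr::map(seq_along(pick), function(k) {
      g <- genes[pick[k], ]
      centre <- min(g$end + 3500L, cfg$chrom_len - half - 1L)
      tibble(region_id = sprintf("dec%03d", k), chrom = g$chrom,
             start = centre - half, end = centre - half + cfg$region_len,
             partition = paste(parts[[((k - 1L) %% length(parts)) + 1L]],
                               collapse = ","),
             gene_id = NA_character_)
    })
    regions <- bind_rows(regions, bind_rows(dec))
  }
  stopifnot(all(regions$start >= 0), all(regions$end <= cfg$chrom_len))

  # plant motif words on the coding strand of promoters
  acc_genes <- regions$gene_id[!is.na(regions$gene_id)]
  neg_genes <- setdiff(genes$gene_id, acc_genes)
  motif_positions <- list()
  for (m in cfg$planted_motifs) {
    word <- toupper(m$word)
    wl <- nchar(word)
    targets <- c(
      sample(acc_genes, round(m$fraction_pos * length(acc_genes))),
      sample(neg_genes, round(m$fraction_neg * length(neg_genes))))
    for (gid in targets) {
      g <- genes[genes$gene_id == gid, ]
      off <- as.integer(floor(runif(1, 0, 3000 - wl)))
      if (g$strand == "+") {
        gpos <- g$start_codon - 3000L + off  # 0-based
        seqs[[g$chrom]][(gpos + 1L):(gpos + wl)] <-
          strsplit(word, "")[[1]]
      } else {
        # promoter = revcomp of [sc+1, sc+3001); offset off from window
        # start maps to genomic [sc + 3000 - off - wl + 1, ...], revcomp
        gpos <- g$start_codon + 3000L - off - wl + 1L
        rc <- strsplit(revcomp_string(word), "")[[1]]
        seqs[[g$chrom]][(gpos + 1L):(gpos + wl)] <- rc
      }
      motif_positions[[length(motif_positions) + 1L]] <-
        tibble(gene_id = gid, word = word, offset = off)
    }
  }
  motif_positions <- if (length(motif_positions) > 0) {
    bind_rows(motif_positions)
  } else tibble(gene_id = character(), word = character(), offset = integer())

  # coupled genes: accessible promoters with a stage-varying partition
  varying <- regions$gene_id[!is.na(regions$gene_id) &
                               regions$partition != "C,D1,D2,D3"]
  coupled <- sort(sample(varying, max(1L, round(0.6 * length(varying)))))

  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                            collapse = ""))
  names(genome) <- chroms
  list(genome = genome, genes = genes,
       truth = list(accessible_regions = regions,
                    motif_positions = motif_positions,
                    coupled_genes = coupled))
}

revcomp_string <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Fragment-length mixture: NFR plus decaying nucleosome multiples.
# Weights 0.45/0.30/0.15/0.10 reproduce the qualitative periodic decrease
# of fragment counts between 200 and 800 bp.
draw_fragment_lengths <- function(n, nfr_mean, period) {
  comp <- sample.int(4L, n, replace = TRUE, prob = c(0.45, 0.3, 0.15, 0.1))
  mean_len <- c(nfr_mean, period, 2 * period, 3 * period)[comp]
  sd_len <- c(15, 25, 35, 45)[comp]
  pmax(20L, as.integer(round(rnorm(n, mean_len, sd_len))))
}

#' Simulate per-sample aligned fragments
#'
#' Fragment midpoints are enriched `enrichment_fold`-fold inside regions
#' accessible in the sample's condition and uniform elsewhere; fragment
#' lengths follow the NFR + nucleosome-multiple mixture; each replicate's
#' fragment total is Poisson around `fragments_per_sample`.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth list from [simulate_genome_and_genes()].
#' @param genome The simulated genome (for chromosome lengths).
#' @return A fragment tibble covering all samples (columns `sample_id`,
#'   `condition`, `replicate`, `chrom`, `start`, `end`).
#' @export
simulate_fragments <- function(cfg, truth, genome) {
  lens <- genome_lengths(genome)
  regions <- truth$accessible_regions
  out <- list()
  for (ci in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[ci]
    in_cond <- vapply(strsplit(regions$partition, ","), function(p)
      cond %in% p, logical(1))
    reg_c <- regions[in_cond, ]
    for (rep_i in seq_len(cfg$replicates_per_condition)) {
      set.seed(child_seed(cfg$seed, "fragments", ci * 100L + rep_i))
      n <- rpois(1, cfg$fragments_per_sample)
      # per-chromosome segment table with weights (fold inside accessible)
      segs <- purrr::map(names(lens), function(ch) {
        r <- reg_c[reg_c$chrom == ch, ]
        r <- r[order(r$start), ]
        bounds <- sort(unique(c(0L, r$start, r$end, lens[[ch]])))
        seg <- tibble(chrom = ch, start = head(bounds, -1),
                      end = tail(bounds, -1))
        seg$acc <- purrr::map_lgl(seq_len(nrow(seg)), function(i)
          any(r$start <= seg$start[i] & r$end >= seg$end[i]))
        seg
      })
      segs <- bind_rows(segs)
      w <- (segs$end - segs$start) *
        ifelse(segs$acc, cfg$enrichment_fold, 1)
      idx <- sample.int(nrow(segs), n, replace = TRUE, prob = w)
      mid <- segs$start[idx] +
        floor(runif(n) * (segs$end[idx] - segs$start[idx]))
      len <- draw_fragment_lengths(n, cfg$nfr_len_mean,
                                   cfg$nucleosome_period)
      chrom <- segs$chrom[idx]
      start <- pmax(0L, as.integer(mid - len %/% 2L))
      end <- pmin(lens[chrom], start + len)
      keep <- start < end
      out[[length(out) + 1L]] <- tibble(
        sample_id = paste0(cond, "_rep", rep_i),
        condition = cond, replicate = rep_i,
        chrom = chrom[keep], start = start[keep], end = end[keep])
    }
  }
  bind_rows(out)
}

# log2 accessibility profile (D1..D3 vs C) implied by a region partition
accessibility_profile <- function(partition, fold) {
  p <- strsplit(partition, ",")[[1]]
  lev <- function(cond) if (cond %in% p) fold else 1
  vapply(c("D1", "D2", "D3"), function(d) log2(lev(d) / lev("C")),
         numeric(1))
}

#' Simulate an expression fold-change table coupled to accessibility
#'
#' Coupled genes receive log2 fold-change profiles that are a convex mix
#' of their accessibility profile (weight `expr_coupling`) and Gaussian
#' noise with sd `1 - expr_coupling`, so coupling 1 copies accessibility
#' exactly and coupling 0 is independent noise; all other genes receive
#' independent standard-normal profiles.
#'
#' @inheritParams simulate_fragments
#' @param genes Gene model tibble.
#' @return Tibble `gene_id`, `D1`, `D2`, `D3` (log2 FC vs C).
#' @export
simulate_expression <- function(cfg, truth, genes) {
  set.seed(child_seed(cfg$seed, "expression"))
  regions <- truth$accessible_regions
  prof <- matrix(rnorm(nrow(genes) * 3), ncol = 3)
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    if (gid %in% truth$coupled_genes) {
      part <- regions$partition[match(gid, regions$gene_id)]
      a <- accessibility_profile(part, cfg$enrichment_fold)
      noise <- if (cfg$expr_coupling >= 1) rep(0, 3) else
        rnorm(3, sd = 1 - cfg$expr_coupling)
      # convex mix: coupling 1 copies the accessibility profile exactly,
      # coupling 0 leaves an independent noise profile
      prof[i, ] <- cfg$expr_coupling * a + noise
    }
  }
  tibble(gene_id = genes$gene_id,
         D1 = prof[, 1], D2 = prof[, 2], D3 = prof[, 3])
}

#' Default OJIP time grid (log-spaced, 20 microseconds to 1 second)
#' @param n Number of points.
#' @export
default_ojip_times <- function(n = 64L) {
  10^seq(log10(2e-5), 0, length.out = n)
}

#' Stage-prototype OJIP transients
#'
#' Four monotone-rising O-J-I-P shapes on a log-time grid, built from
#' three logistic steps at the J (~2 ms), I (~30 ms) and P (~300 ms)
#' inflections. Total variable fluorescence decreases from C to D3 while
#' the relative J-step contribution grows, emulating the progressive loss
#' of photosynthetic performance during desiccation.
#'
#' @param times Time grid in seconds.
#' @return Matrix with one column per stage (C, D1, D2, D3).
#' @export
ojip_prototypes <- function(times = default_ojip_times()) {
  lt <- log10(times)
  step <- function(m, s = 0.25) 1 / (1 + exp(-(lt - m) / s))
  pars <- list(
    C  = list(f0 = 0.2, A = 1.00, w = c(0.30, 0.25, 0.45)),
    D1 = list(f0 = 0.2, A = 0.80, w = c(0.40, 0.30, 0.30)),
    D2 = list(f0 = 0.2, A = 0.55, w = c(0.55, 0.25, 0.20)),
    D3 = list(f0 = 0.2, A = 0.35, w = c(0.75, 0.15, 0.10)))
  m <- c(-2.7, -1.5, -0.52)
  out <- vapply(pars, function(p) {
    p$f0 + p$A * (p$w[1] * step(m[1]) + p$w[2] * step(m[2]) +
                    p$w[3] * step(m[3]))
  }, numeric(length(lt)))
  colnames(out) <- STAGES
  out
}

#' Simulate noisy OJIP transients with stage labels
#'
#' @inheritParams simulate_fragments
#' @param n_per_stage Curves per stage.
#' @param times Time grid.
#' @return List with `times`, `values` (matrix, one column per curve) and
#'   `labels` (stage per curve, balanced across the four stages).
#' @export
simulate_ojip <- function(cfg, n_per_stage = 50L,
                          times = default_ojip_times()) {
  set.seed(child_seed(cfg$seed, "ojip"))
  proto <- ojip_prototypes(times)
  labels <- rep(STAGES, each = n_per_stage)
  values <- vapply(labels, function(lab) {
    base <- proto[, lab]
    base * (1 + rnorm(length(base), sd = cfg$ojip_noise_sd))
  }, numeric(length(times)))
  colnames(values) <- sprintf("curve%03d", seq_along(labels))
  list(times = times, values = values, labels = labels)
}

#' Generate and write the complete synthetic fixture set
#'
#' Runs the full generator and writes `genome.fa`, `genes.gff3`,
#' `fragments/<sample>.bed`, `expression.tsv`, `ojip.tsv`,
#' `samples.tsv` and `truth.json` under `dir`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if missing); `NULL` keeps
#'   everything in memory only.
#' @return Invisibly, a list with `genome`, `genes`, `truth`, `fragments`,
#'   `expression`, `ojip`, and `samples` (the sample sheet).
#' @export
simulate_atac_experiment <- function(cfg = sim_config(), dir = NULL) {
  sim <- simulate_genome_and_genes(cfg)
  frags <- simulate_fragments(cfg, sim$truth, sim$genome)
  expr <- simulate_expression(cfg, sim$truth, sim$genes)
  ojip <- simulate_ojip(cfg)
  samples <- distinct(frags[, c("sample_id", "condition", "replicate")])
  res <- list(genome = sim$genome, genes = sim$genes, truth = sim$truth,
              fragments = frags, expression = expr, ojip = ojip,
              samples = samples)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "fragments"), recursive = TRUE,
               showWarnings = FALSE)
    Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
    write_gene_models_gff3(sim$genes, file.path(dir, "genes.gff3"))
    for (sid in samples$sample_id) {
      write_fragments_bed(frags[frags$sample_id == sid, ],
                          file.path(dir, "fragments", paste0(sid, ".bed")))
    }
    readr::write_tsv(expr, file.path(dir, "expression.tsv"))
    write_ojip_tsv(ojip$times, ojip$values, ojip$labels,
                   file.path(dir, "ojip.tsv"))
    readr::write_tsv(samples, file.path(dir, "samples.tsv"))
    jsonlite::write_json(
      list(accessible_regions = sim$truth$accessible_regions,
           motif_positions = sim$truth$motif_positions,
           coupled_genes = sim$truth$coupled_genes,
           ojip_labels = ojip$labels),
      file.path(dir, "truth.json"))
  }
  invisible(res)
}
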