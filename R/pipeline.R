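#' Pipeline configuration
#'
#' Collects input paths, stage parameters and the global seed for
#' [run_pipeline()]. Either build it in code or load it from a YAML file
#' with [read_pipeline_config()].
#'
#' @param genome,gff3,fragment_dir,expression,ojip,pwm_library Input
#'   paths; `fragment_dir` must contain `<sample>.bed` files and a
#'   `samples.tsv` sample sheet (`sample_id`, `condition`, `replicate`).
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @param plus_offset,minus_offset Tn5 offsets (see
#'   [make_insertion_track()]).
#' @param tss_window TSS profile half-window (bp).
#' @param peak Parameters from [peak_params()].
#' @param min_reps,min_overlap_frac Reproducibility rule (see
#'   [reproducible_peaks()]).
#' @param promoter_window Promoter length (bp).
#' @param motif_e_cutoff,motif_max Motif scan controls.
#' @param network_threshold,network_normalization Network controls.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genome, gff3, fragment_dir, expression,
                            ojip = NULL, pwm_library = NULL,
                            out_dir = "thsdyn_out", seed = 1L,
                            plus_offset = 4L, minus_offset = -5L,
                            tss_window = 2000L,
                            peak = peak_params(),
                            min_reps = 2L, min_overlap_frac = 0.5,
                            promoter_window = 3000L,
                            motif_e_cutoff = 0.05, motif_max = 10L,
                            network_threshold = 0.01,
                            network_normalization = "unit") {
  structure(list(genome = genome, gff3 = gff3,
                 fragment_dir = fragment_dir, expression = expression,
                 ojip = ojip, pwm_library = pwm_library,
                 out_dir = out_dir, seed = as.integer(seed),
                 plus_offset = plus_offset, minus_offset = minus_offset,
                 tss_window = tss_window, peak = peak,
                 min_reps = min_reps,
                 min_overlap_frac = min_overlap_frac,
                 promoter_window = promoter_window,
                 motif_e_cutoff = motif_e_cutoff, motif_max = motif_max,
                 network_threshold = network_threshold,
                 network_normalization = network_normalization),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments (peak parameters under a `peak:` mapping).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$peak)) y$peak <- do.call(peak_params, y$peak)
  do.call(pipeline_config, y)
}

validate_pipeline_config <- function(config) {
  paths <- c(genome = config$genome, gff3 = config$gff3,
             fragment_dir = config$fragment_dir,
             expression = config$expression)
  opt <- c(ojip = config$ojip, pwm_library = config$pwm_library)
  paths <- c(paths, opt[!vapply(opt, is.null, logical(1))])
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing) > 0) {
    abort(paste0("config error: missing input path(s): ",
                 paste(names(missing), "=", unlist(missing),
                       collapse = "; ")))
  }
  invisible(config)
}

stage_log <- function(stage, ...) {
  inform(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"),
                 stage, paste0(...)))
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order — stage classification (when
#' OJIP data is given), QC, per-sample peak calling, reproducibility
#' filtering, consensus THS construction with Venn partitioning, count
#' and fold-change matrices, annotation, promoter motif enrichment with
#' PWM matching (when a library is given), and the ATAC-RNA correlation
#' network — writing each stage's tables under `out_dir` and a manifest
#' (inputs, parameter hash, per-output MD5 checksums) at the end.
#' Deterministic stages rerun with an identical config are
#' byte-identical. Any stage failure aborts with the failing stage
#' named; outputs written so far remain on disk next to a `FAILED`
#' marker file.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  current_stage <- "setup"
  run <- function(stage, expr) {
    current_stage <<- stage
    stage_log(stage, "start")
    expr
  }
  tryCatch({
    genome <- run("load", read_genome_fasta(config$genome))
    genes <- read_gene_models(config$gff3)
    lens <- genome_lengths(genome)
    sheet <- file.path(config$fragment_dir, "samples.tsv")
    if (!file.exists(sheet)) {
      sheet <- file.path(dirname(config$fragment_dir), "samples.tsv")
    }
    if (!file.exists(sheet)) abort("samples.tsv not found")
    samples <- readr::read_tsv(sheet, show_col_types = FALSE)
    frags <- bind_rows(purrr::map(seq_len(nrow(samples)), function(i) {
      read_fragments_bed(
        file.path(config$fragment_dir,
                  paste0(samples$sample_id[i], ".bed")),
        samples$sample_id[i], samples$condition[i],
        samples$replicate[i])
    }))
    expr <- read_expression_tsv(config$expression)

    if (!is.null(config$ojip)) {
      run("classify-stage", {
        oj <- read_ojip_tsv(config$ojip)
        som <- train_som(oj, seed = config$seed)
        cls <- classify_stage(som, oj$values)
        readr::write_tsv(cls, file.path(out, "stage_calls.tsv"))
      })
    }

    run("qc", {
      track <- make_insertion_track(frags, lens, config$plus_offset,
                                    config$minus_offset)
      fl <- fragment_length_histogram(frags)
      write_tsv_matrix(fl, file.path(out, "fragment_lengths.tsv"))
      prof <- tss_profile(track, genes, config$tss_window, lens)
      write_tsv_matrix(tidy(prof), file.path(out, "tss_profile.tsv"))
      track
    }) -> track

    run("callpeaks", {
      peaks_by_sample <- lapply(split(track, track$sample_id),
                                call_peaks, chrom_lens = lens,
                                params = config$peak)
      for (sid in names(peaks_by_sample)) {
        write_narrowpeak(peaks_by_sample[[sid]],
                         file.path(out, paste0(sid, ".narrowPeak")))
      }
      peaks_by_sample
    }) -> peaks_by_sample

    run("consensus", {
      cond_peaks <- lapply(setNames(STAGES, STAGES), function(cond) {
        sids <- samples$sample_id[samples$condition == cond]
        reproducible_peaks(peaks_by_sample[sids],
                           min_reps = config$min_reps,
                           min_overlap_frac = config$min_overlap_frac)
      })
      thss <- build_consensus(cond_peaks)
      counts <- count_matrix(thss, track)
      fc <- fold_change_matrix(counts, samples)
      write_tsv_matrix(counts, file.path(out, "ths_counts.tsv"))
      write_tsv_matrix(fc, file.path(out, "ths_fold_change.tsv"))
      readr::write_tsv(venn_partition(thss),
                       file.path(out, "venn_partition.tsv"))
      if (nrow(counts) >= 2 && ncol(counts) >= 3) {
        cl <- sample_correlation_clustergram(counts)
        write_tsv_matrix(tidy(cl),
                         file.path(out, "replicate_correlation.tsv"))
      }
      list(thss = thss, counts = counts, fc = fc)
    }) -> cons

    run("annotate", {
      ann <- annotate_ths(cons$thss, genes)
      readr::write_tsv(select(ann, -dplyr::any_of("exons")),
                       file.path(out, "ths_annotated.tsv"))
      ann
    }) -> ann

    motifs <- NULL
    if (!is.null(config$pwm_library)) {
      run("motifs", {
        fg_genes <- unique(ann$gene_id[!is.na(ann$gene_id)])
        proms <- extract_promoters(fg_genes, genes, genome,
                                   config$promoter_window)
        negs <- shuffle_negatives(proms, seed = config$seed)
        found <- dreme_enrich(proms, negs,
                              e_cutoff = config$motif_e_cutoff,
                              max_motifs = config$motif_max)
        readr::write_tsv(found, file.path(out, "motifs.tsv"))
        if (nrow(found) > 0) {
          lib <- read_pwm_meme(config$pwm_library)
          matches <- match_known_motifs(found$word, lib,
                                        seed = config$seed)
          linked <- link_motifs_to_tf_expression(matches, expr)
          readr::write_tsv(matches, file.path(out, "motif_matches.tsv"))
          readr::write_tsv(linked, file.path(out, "motif_tf_expression.tsv"))
        }
        found
      }) -> motifs
    }

    run("integrate", {
      prof <- gene_atac_profiles(ann, cons$fc)
      joined <- join_ths_expression(prof, expr)
      net <- correlation_network(joined, config$network_threshold,
                                 config$network_normalization)
      write_network(net, file.path(out, "network_edges.tsv"),
                    file.path(out, "network.graphml"))
      net
    }) -> net

    run("manifest", {
      files <- sort(setdiff(list.files(out), "manifest.json"))
      checks <- tools::md5sum(file.path(out, files))
      par <- config[setdiff(names(config), "out_dir")]
      par$peak <- unclass(par$peak)
      tmp <- tempfile()
      writeLines(jsonlite::toJSON(par, auto_unbox = TRUE, digits = NA,
                                  null = "null"), tmp)
      manifest <- list(
        inputs = list(genome = config$genome, gff3 = config$gff3,
                      fragment_dir = config$fragment_dir,
                      expression = config$expression,
                      ojip = config$ojip,
                      pwm_library = config$pwm_library),
        parameter_hash = unname(tools::md5sum(tmp)),
        n_ths = nrow(cons$thss),
        n_network_edges = nrow(net$edges),
        outputs = as.list(setNames(unname(checks), files)))
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      manifest
    }) -> manifest
    stage_log("done", sprintf("%d THSs, %d network edges",
                              manifest$n_ths, manifest$n_network_edges))
    invisible(manifest)
  }, error = function(e) {
    writeLines(paste("failed at stage:", current_stage),
               file.path(out, "FAILED"))
    abort(paste0("pipeline failed at stage '", current_stage, "': ",
                 conditionMessage(e)))
  })
}
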