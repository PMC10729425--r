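#' Read a reference genome from FASTA
#'
#' Loads all records, normalizes case to upper, and maps any character
#' outside the A/C/G/T/N alphabet to N. Record names must be unique and
#' sequences non-empty.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  gen <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(gen))
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate FASTA record name: ",
                 nm[duplicated(nm)][1]))
  }
  if (any(Biostrings::width(gen) == 0)) abort("empty FASTA record")
  seqs <- toupper(as.character(gen))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nm
  out
}

#' Chromosome lengths of a genome
#' @param genome A `DNAStringSet` as from [read_genome_fasta()].
#' @return Named integer vector of lengths in bp.
#' @export
genome_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS features (1-based closed coordinates) and
#' converts them to the package-internal 0-based half-open convention.
#' One gene model is built per gene, using the first mRNA in file order;
#' the IDs of any further mRNAs are kept in the `other_mrnas` column.
#' The TSS is the span start on the + strand and span end − 1 on the
#' − strand; the start codon is taken from the CDS (its first base in
#' transcription order). Genes whose first mRNA lacks a CDS are an error:
#' the promoter windows downstream are anchored on the start codon.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open), `tss`, `start_codon`, `exons` (list column
#'   of tibbles with `start`, `end`), `other_mrnas`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  genes <- df[df$type == "gene", ]
  if (nrow(genes) == 0) abort("no gene features in GFF3")
  if (any(!as.character(genes$strand) %in% c("+", "-"))) {
    abort("gene with unknown strand")
  }
  mrnas <- df[df$type %in% c("mRNA", "transcript"), ]
  parts <- df[df$type %in% c("exon", "CDS"), ]
  out <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gid <- g$ID
    gm <- mrnas[mrnas$Parent == gid, ]
    if (nrow(gm) == 0) abort(paste0("gene without mRNA: ", gid))
    m1 <- gm$ID[1]
    exons <- parts[parts$type == "exon" & parts$Parent == m1, ]
    cds <- parts[parts$type == "CDS" & parts$Parent == m1, ]
    if (nrow(cds) == 0) {
      abort(paste0("gene without CDS (start codon undefined): ", gid))
    }
    # GFF3 1-based closed -> 0-based half-open
    g0 <- g$start - 1L; g1 <- g$end
    ex <- tibble(start = exons$start - 1L, end = exons$end)
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 0) {
      if (any(ex$start < g0 | ex$end > g1)) {
        abort(paste0("exon outside gene span: ", gid))
      }
      if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
        abort(paste0("overlapping exons: ", gid))
      }
    }
    strand <- as.character(g$strand)
    tibble(
      gene_id = gid,
      chrom = as.character(g$seqnames),
      strand = strand,
      start = g0, end = g1,
      tss = if (strand == "+") g0 else g1 - 1L,
      start_codon = if (strand == "+") min(cds$start) - 1L else max(cds$end) - 1L,
      exons = list(ex),
      other_mrnas = paste(gm$ID[-1], collapse = ",")
    )
  })
  bind_rows(out)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gene_models()] for the subset of fields the package
#' uses: each gene is emitted as gene + one mRNA + exons + a single CDS
#' spanning start codon to gene end (transcription order).
#'
#' @param genes Gene model tibble as from [read_gene_models()].
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    s1 <- g$start + 1L; e1 <- g$end
    mid <- paste0(g$gene_id, ".m1")
    lines <- c(lines,
      paste(g$chrom, "thsdyn", "gene", s1, e1, ".", g$strand, ".",
            paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$chrom, "thsdyn", "mRNA", s1, e1, ".", g$strand, ".",
            paste0("ID=", mid, ";Parent=", g$gene_id), sep = "\t"))
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines,
        paste(g$chrom, "thsdyn", "exon", ex$start[j] + 1L, ex$end[j], ".",
              g$strand, ".", paste0("ID=", mid, ".e", j, ";Parent=", mid),
              sep = "\t"))
    }
    if (g$strand == "+") {
      cs <- g$start_codon + 1L; ce <- e1
    } else {
      cs <- s1; ce <- g$start_codon + 1L
    }
    lines <- c(lines,
      paste(g$chrom, "thsdyn", "CDS", cs, ce, ".", g$strand, "0",
            paste0("ID=", mid, ".cds;Parent=", mid), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read aligned fragments from a BED3+ file
#'
#' BED coordinates are 0-based half-open, matching the internal
#' convention, so no offset conversion happens here.
#'
#' @param path Path to a BED file (first three columns used).
#' @param sample_id,condition,replicate Sample metadata attached to every
#'   fragment; `condition` must be one of C, D1, D2, D3.
#' @return A fragment tibble: `sample_id`, `condition`, `replicate`,
#'   `chrom`, `start`, `end`.
#' @export
read_fragments_bed <- function(path, sample_id, condition, replicate) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  stopifnot(condition %in% STAGES)
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 3) abort("BED file needs at least 3 columns")
  start <- suppressWarnings(as.integer(raw[[2]]))
  end <- suppressWarnings(as.integer(raw[[3]]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(paste0("malformed BED line ", bad[1], " in ", path))
  }
  tibble(sample_id = sample_id, condition = condition,
         replicate = as.integer(replicate),
         chrom = raw[[1]], start = start, end = end)
}

#' Write fragments to BED3
#' @param frags Fragment tibble (one sample).
#' @param path Output path.
#' @export
write_fragments_bed <- function(frags, path) {
  readr::write_tsv(frags[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Write peaks in ENCODE narrowPeak format
#'
#' Ten-column dialect: chrom, start, end, name, score, strand, signalValue,
#' pValue, qValue, peak. The score column is `min(1000, round(10 * score))`
#' where `score` is −log10 p, for genome-browser compatibility; the summit
#' is written as an offset relative to `start`.
#'
#' @param peaks Peak tibble with `chrom`, `start`, `end`, `summit`,
#'   `score` (−log10 p at summit), `qvalue`.
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  df <- tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = sprintf("peak_%d", seq_len(n)),
    score = pmin(1000, round(10 * peaks$score)),
    strand = ".",
    signalValue = round(peaks$score, 5),
    pValue = round(peaks$score, 5),
    qValue = round(-log10(pmax(peaks$qvalue, 1e-300)), 5),
    peak = peaks$summit - peaks$start
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read an ENCODE narrowPeak file
#' @param path Path to a narrowPeak file.
#' @return Peak tibble with `chrom`, `start`, `end`, `summit`, `score`,
#'   `qvalue`.
#' @export
read_narrowpeak <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 10) abort("narrowPeak needs 10 columns")
  tibble(chrom = as.character(raw[[1]]),
         start = as.integer(raw[[2]]), end = as.integer(raw[[3]]),
         summit = as.integer(raw[[2]]) + as.integer(raw[[10]]),
         score = as.numeric(raw[[8]]),
         qvalue = 10^(-as.numeric(raw[[9]])))
}

#' Write / read a TSV matrix with row identifiers
#'
#' The first column is the row identifier; remaining columns are numeric.
#' `read_tsv_matrix(write_tsv_matrix(x))` is the identity.
#'
#' @param x A tibble whose first column is an identifier.
#' @param path File path.
#' @return `read_tsv_matrix` returns the tibble.
#' @export
write_tsv_matrix <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @export
read_tsv_matrix <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    readr::col_character(),
                    .default = readr::col_double()))
}

#' Read a MEME minimal-format motif library
#'
#' Parses the minimal motif format (MOTIF blocks with letter-probability
#' matrices over the ACGT alphabet). Each matrix row must sum to 1 within
#' 1e-6.
#'
#' @param path Path to a MEME-format text file.
#' @return A tibble with `name`, `tf_name` and a `matrix` list column of
#'   w-by-4 probability matrices (columns A, C, G, T).
#' @export
read_pwm_meme <- function(path) {
  if (!file.exists(path)) abort(paste0("MEME file not found: ", path))
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0) abort("no MOTIF blocks found")
  out <- purrr::map(seq_along(starts), function(i) {
    hdr <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]]
    name <- hdr[2]
    tf_name <- if (length(hdr) >= 3) hdr[3] else hdr[2]
    to <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    block <- lines[starts[i]:to]
    ml <- grep("letter-probability matrix", block)
    if (length(ml) == 0) abort(paste0("motif without matrix: ", name))
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", block[ml[1]]))
    rows <- block[(ml[1] + 1):(ml[1] + w)]
    mat <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4])
    }))
    colnames(mat) <- c("A", "C", "G", "T")
    if (any(abs(rowSums(mat) - 1) > 1e-6)) {
      abort(paste0("PWM rows do not sum to 1: ", name))
    }
    tibble(name = name, tf_name = tf_name, matrix = list(mat))
  })
  bind_rows(out)
}

#' Write motifs in MEME minimal format
#' @param pwms Tibble as returned by [read_pwm_meme()].
#' @param path Output path.
#' @param background Background letter frequencies (A, C, G, T).
#' @export
write_pwm_meme <- function(pwms, path, background = rep(0.25, 4)) {
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             sprintf("A %.5f C %.5f G %.5f T %.5f",
                     background[1], background[2], background[3], background[4]),
             "")
  for (i in seq_len(nrow(pwms))) {
    m <- pwms$matrix[[i]]
    lines <- c(lines,
      paste("MOTIF", pwms$name[i], pwms$tf_name[i]),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
              nrow(m)),
      apply(m, 1, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                      r[1], r[2], r[3], r[4])),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write OJIP transients as TSV
#'
#' Column 1 holds the time grid in seconds; each remaining column is one
#' transient. Labels, when present, sit in a commented `#labels` line.
#'
#' @param path File path.
#' @return A list with `times` (numeric vector), `values` (matrix, one
#'   column per curve) and `labels` (character or NULL).
#' @export
read_ojip_tsv <- function(path) {
  lines <- readLines(path)
  lab_line <- grep("^#labels\t", lines, value = TRUE)
  labels <- if (length(lab_line) > 0) {
    strsplit(lab_line[1], "\t")[[1]][-1]
  } else NULL
  body <- lines[!startsWith(lines, "#")]
  df <- readr::read_tsv(I(paste(body, collapse = "\n")),
                        show_col_types = FALSE)
  list(times = df[[1]],
       values = as.matrix(df[, -1, drop = FALSE]),
       labels = labels)
}

#' @rdname read_ojip_tsv
#' @param times,values,labels Components to write.
#' @export
write_ojip_tsv <- function(times, values, labels, path) {
  lines <- character(0)
  if (!is.null(labels)) {
    lines <- paste0("#labels\t", paste(labels, collapse = "\t"))
  }
  cn <- colnames(values) %||% sprintf("curve%03d", seq_len(ncol(values)))
  lines <- c(lines, paste(c("time_s", cn), collapse = "\t"),
             vapply(seq_along(times), function(i) {
               paste(sprintf("%.12g", c(times[i], values[i, ])),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression fold-change table
#'
#' One row per gene; columns D1, D2, D3 hold log2 fold change of each
#' desiccation stage against the watered control.
#'
#' @param path TSV path with columns `gene_id`, `D1`, `D2`, `D3`.
#' @return A tibble with those columns.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "D1", "D2", "D3")
  if (!all(need %in% names(df))) {
    abort("expression table must have columns gene_id, D1, D2, D3")
  }
  if (any(!is.finite(as.matrix(df[, c("D1", "D2", "D3")])))) {
    abort("non-finite expression values")
  }
  df[, need]
}
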