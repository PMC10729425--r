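IUPAC_LETTERS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", V = "B", D = "H", H = "D", N = "N")

iupac_regex <- function(word) {
  paste(vapply(strsplit(word, "")[[1]], function(ch) {
    l <- IUPAC_LETTERS[[ch]]
    if (length(l) == 1) l else paste0("[", paste(l, collapse = ""), "]")
  }, character(1)), collapse = "")
}

iupac_revcomp <- function(word) {
  paste(rev(IUPAC_COMPLEMENT[strsplit(word, "")[[1]]]), collapse = "")
}

#' Extract promoter sequences
#'
#' The promoter is the 3000-bp window upstream of the start codon on the
#' coding strand: `[start_codon - w, start_codon)` for + genes and the
#' reverse complement of `(start_codon, start_codon + w]` for − genes,
#' clipped at contig ends (clipping recorded).
#'
#' @param gene_ids Genes to extract.
#' @param genes Gene model tibble.
#' @param genome Genome `DNAStringSet`.
#' @param window Promoter length in bp (default 3000).
#' @return Tibble `gene_id`, `seq`, `length`, `clipped`.
#' @export
extract_promoters <- function(gene_ids, genes, genome, window = 3000L) {
  missing <- setdiff(gene_ids, genes$gene_id)
  if (length(missing) > 0) {
    abort(paste0("unknown gene ids: ", paste(missing, collapse = ",")))
  }
  lens <- genome_lengths(genome)
  rows <- purrr::map(gene_ids, function(gid) {
    g <- genes[genes$gene_id == gid, ]
    sc <- g$start_codon
    if (g$strand == "+") {
      lo <- max(0L, sc - window); hi <- sc
      s <- as.character(Biostrings::subseq(genome[[g$chrom]],
                                           lo + 1L, hi))
    } else {
      lo <- sc + 1L; hi <- min(lens[[g$chrom]], sc + 1L + window)
      s <- revcomp_string(
        as.character(Biostrings::subseq(genome[[g$chrom]], lo + 1L, hi)))
    }
    tibble(gene_id = gid, seq = s, length = nchar(s),
           clipped = nchar(s) < window)
  })
  bind_rows(rows)
}

# Altschul-Erikson dinucleotide-preserving shuffle of one sequence:
# sample a random Eulerian path through the dinucleotide multigraph with
# the original first and last residue fixed.
dinuc_shuffle_one <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n <= 3) return(s)
  verts <- unique(ch)
  adj <- split(ch[-1], factor(ch[-n], levels = verts))
  last <- ch[n]
  repeat {
    last_edge <- list()
    for (v in verts) {
      if (v == last) next
      succ <- adj[[v]]
      if (length(succ) == 0) next
      last_edge[[v]] <- succ[sample.int(length(succ), 1L)]
    }
    reaches <- vapply(names(last_edge), function(v) {
      seen <- character(0); cur <- v
      while (cur != last) {
        if (cur %in% seen) return(FALSE)
        seen <- c(seen, cur)
        nxt <- last_edge[[cur]]
        if (is.null(nxt)) return(FALSE)
        cur <- nxt
      }
      TRUE
    }, logical(1))
    if (all(reaches)) break
  }
  arranged <- lapply(setNames(verts, verts), function(v) {
    succ <- adj[[v]]
    if (length(succ) == 0) return(succ)
    if (!is.null(last_edge[[v]])) {
      idx <- which(succ == last_edge[[v]])[1]
      rest <- succ[-idx]
      c(rest[sample.int(length(rest))], last_edge[[v]])
    } else succ[sample.int(length(succ))]
  })
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- ch[1]; cur <- ch[1]
  for (i in 2:n) {
    nxt <- arranged[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt; cur <- nxt
  }
  paste(out, collapse = "")
}

#' Dinucleotide-shuffled negative promoter set
#'
#' Shuffles each promoter with an Eulerian-path shuffle that preserves
#' its exact mono- and dinucleotide counts; deterministic under `seed`.
#'
#' @param promoters Promoter tibble from [extract_promoters()].
#' @param seed Seed.
#' @return Promoter tibble with shuffled sequences, gene ids suffixed
#'   `_shuf`.
#' @export
shuffle_negatives <- function(promoters, seed = 1L) {
  set.seed(child_seed(seed, "shuffle"))
  mutate(promoters,
         gene_id = paste0(.data$gene_id, "_shuf"),
         seq = vapply(.data$seq, dinuc_shuffle_one, character(1),
                      USE.NAMES = FALSE))
}

# unique words of each length present in a sequence (and strand mate)
seq_words <- function(s, min_len, max_len, both_strands) {
  grab <- function(x) {
    n <- nchar(x)
    unlist(lapply(min_len:max_len, function(k) {
      if (n < k) character(0) else
        unique(substring(x, 1:(n - k + 1), k:n))
    }))
  }
  w <- grab(s)
  if (both_strands) w <- unique(c(w, grab(revcomp_string(s))))
  w[!grepl("N", w, fixed = TRUE)]
}

# named per-word sequence-presence counts over a set of sequences
presence_counts <- function(seqs, min_len, max_len, both_strands) {
  all_w <- unlist(lapply(seqs, seq_words, min_len, max_len, both_strands))
  if (length(all_w) == 0) return(integer(0))
  r <- rle(sort(all_w))
  setNames(r$lengths, r$values)
}

# one-sided Fisher p (hypergeometric upper tail) for per-sequence hits
fisher_greater <- function(a, c, n_pos, n_neg) {
  phyper(a - 1, a + c, n_pos + n_neg - a - c, n_pos, lower.tail = FALSE)
}

# per-sequence binary hit count of an IUPAC word
pattern_hits <- function(word, seqs, both_strands) {
  pat <- iupac_regex(word)
  hit <- grepl(pat, seqs)
  if (both_strands) {
    hit <- hit | grepl(iupac_regex(iupac_revcomp(word)), seqs)
  }
  sum(hit)
}

#' Discriminative promoter motif enrichment
#'
#' DREME-style exact-word scan: every word of length `min_len` to
#' `max_len` present in at least two positive sequences is scored by a
#' one-sided Fisher exact test on per-sequence binary hits (a sequence
#' counts once per word; both strands searched by default). The best word
#' is greedily generalized one IUPAC wildcard position at a time,
#' accepting a wildcard only when the p-value improves. The E-value is
#' the final p times the number of distinct exact words tested. Motifs
#' are reported in increasing E while E stays below `e_cutoff`; after
#' each report all matching sites are masked (set to N) in the positive
#' sequences and the scan repeats.
#'
#' @param pos,neg Promoter tibbles (positive and negative sets).
#' @param min_len,max_len Word length range.
#' @param e_cutoff Stop when the best E-value reaches this.
#' @param max_motifs Maximum motifs reported.
#' @param both_strands Search both strands.
#' @return Tibble `word` (IUPAC), `core` (the seeding exact word),
#'   `pos_hits`, `neg_hits`, `n_pos`, `n_neg`, `p`, `evalue`,
#'   `candidates_tested`, `round`.
#' @export
dreme_enrich <- function(pos, neg, min_len = 3L, max_len = 8L,
                         e_cutoff = 0.05, max_motifs = 10L,
                         both_strands = TRUE) {
  if (nrow(pos) == 0 || nrow(neg) == 0) {
    abort("positive and negative sets must be nonempty")
  }
  pos_seqs <- toupper(pos$seq)
  neg_seqs <- toupper(neg$seq)
  n_pos <- length(pos_seqs); n_neg <- length(neg_seqs)
  neg_cnt <- presence_counts(neg_seqs, min_len, max_len, both_strands)
  results <- list()
  for (round_i in seq_len(max_motifs)) {
    pos_cnt <- presence_counts(pos_seqs, min_len, max_len, both_strands)
    cand <- names(pos_cnt)[pos_cnt >= 2]
    if (length(cand) == 0) break
    a <- unname(pos_cnt[cand])
    cc <- neg_cnt[cand]
    cc[is.na(cc)] <- 0L
    p <- fisher_greater(a, unname(cc), n_pos, n_neg)
    ord <- order(p, -a, cand)
    best <- cand[ord[1]]
    p_best <- p[ord[1]]
    a_best <- a[ord[1]]; c_best <- unname(cc[ord[1]])
    # IUPAC refinement: one wildcard position per step while p improves
    word <- best
    repeat {
      chars <- strsplit(word, "")[[1]]
      improved <- FALSE
      cand_best <- NULL
      for (i in seq_along(chars)) {
        base <- chars[i]
        if (!base %in% c("A", "C", "G", "T")) next
        for (code in c("R", "Y", "S", "W", "K", "M")) {
          if (!base %in% IUPAC_LETTERS[[code]]) next
          w2c <- chars; w2c[i] <- code
          w2 <- paste(w2c, collapse = "")
          a2 <- pattern_hits(w2, pos_seqs, both_strands)
          c2 <- pattern_hits(w2, neg_seqs, both_strands)
          p2 <- fisher_greater(a2, c2, n_pos, n_neg)
          if (p2 < p_best && (is.null(cand_best) || p2 < cand_best$p)) {
            cand_best <- list(word = w2, p = p2, a = a2, c = c2)
          }
        }
      }
      if (!is.null(cand_best)) {
        word <- cand_best$word; p_best <- cand_best$p
        a_best <- cand_best$a; c_best <- cand_best$c
        improved <- TRUE
      }
      if (!improved) break
    }
    evalue <- p_best * length(cand)
    if (evalue >= e_cutoff) break
    results[[round_i]] <- tibble(
      word = word, core = best, pos_hits = a_best, neg_hits = c_best,
      n_pos = n_pos, n_neg = n_neg, p = p_best, evalue = evalue,
      candidates_tested = length(cand), round = round_i)
    pos_seqs <- mask_word(pos_seqs, word, both_strands)
  }
  if (length(results) == 0) {
    return(tibble(word = character(), core = character(),
                  pos_hits = integer(), neg_hits = integer(),
                  n_pos = integer(), n_neg = integer(), p = numeric(),
                  evalue = numeric(), candidates_tested = integer(),
                  round = integer()))
  }
  bind_rows(results)
}

# replace every site matching the word (either strand) with N
mask_word <- function(seqs, word, both_strands) {
  pats <- iupac_regex(word)
  if (both_strands) {
    pats <- unique(c(pats, iupac_regex(iupac_revcomp(word))))
  }
  for (pat in pats) {
    seqs <- vapply(seqs, function(s) {
      m <- gregexpr(pat, s)[[1]]
      if (m[1] == -1) return(s)
      for (k in seq_along(m)) {
        len <- attr(m, "match.length")[k]
        substr(s, m[k], m[k] + len - 1) <- strrep("N", len)
      }
      s
    }, character(1), USE.NAMES = FALSE)
  }
  seqs
}

# IUPAC word -> position probability matrix (rows positions, cols ACGT)
word_to_matrix <- function(word) {
  chars <- strsplit(word, "")[[1]]
  m <- matrix(0, length(chars), 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(chars)) {
    l <- IUPAC_LETTERS[[chars[i]]]
    m[i, l] <- 1 / length(l)
  }
  m
}

# best ungapped log-odds alignment of a word matrix against one PWM,
# over all offsets with >= min_overlap columns and both strands
align_score <- function(wmat, pwm, background, min_overlap = 3L) {
  lo <- log2(pmax(pwm, 1e-3) / rep(background, each = nrow(pwm)))
  score_one <- function(wm) {
    wl <- nrow(wm); pl <- nrow(lo)
    best <- -Inf
    for (off in seq(-(wl - min_overlap), pl - min_overlap)) {
      wi <- seq_len(wl) + off
      keep <- wi >= 1 & wi <= pl
      if (sum(keep) < min_overlap) next
      sc <- sum(wm[keep, , drop = FALSE] * lo[wi[keep], , drop = FALSE])
      if (sc > best) best <- sc
    }
    best
  }
  rc <- function(wm) wm[rev(seq_len(nrow(wm))), c("T", "G", "C", "A"),
                        drop = FALSE]
  max(score_one(wmat), {
    w2 <- rc(wmat); colnames(w2) <- c("A", "C", "G", "T"); score_one(w2)
  })
}

#' Match discovered words against a known PWM library
#'
#' Each IUPAC word is converted to a probability matrix and compared to
#' every library PWM by maximal ungapped log-odds alignment over offsets
#' and strands. The best match's p-value comes from an empirical null of
#' position-shuffled word matrices, each scored with the same
#' best-of-library rule so the selection step does not inflate the
#' observed score relative to the null.
#'
#' @param words Character vector of IUPAC words (e.g. the `word` column
#'   of [dreme_enrich()] output).
#' @param pwm_library PWM tibble from [read_pwm_meme()].
#' @param background Background letter frequencies (A, C, G, T).
#' @param n_null Number of shuffled matrices for the null.
#' @param seed Seed for the shuffle null.
#' @return Tibble `word`, `pwm_name`, `tf_name`, `score`, `p`.
#' @export
match_known_motifs <- function(words, pwm_library,
                               background = rep(0.25, 4),
                               n_null = 1000L, seed = 1L) {
  set.seed(seed)
  rows <- purrr::map(words, function(word) {
    wmat <- word_to_matrix(word)
    scores <- vapply(pwm_library$matrix, align_score, numeric(1),
                     wmat = wmat, background = background)
    best <- which.max(scores)
    null <- vapply(seq_len(n_null), function(i) {
      perm <- wmat[sample.int(nrow(wmat)), , drop = FALSE]
      max(vapply(pwm_library$matrix, align_score, numeric(1),
                 wmat = perm, background = background))
    }, numeric(1))
    tibble(word = word,
           pwm_name = pwm_library$name[best],
           tf_name = pwm_library$tf_name[best],
           score = scores[best],
           p = (1 + sum(null >= scores[best])) / (n_null + 1))
  })
  bind_rows(rows)
}
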