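#' Gene-level ATAC fold-change profiles
#'
#' Averages THS log2 fold-change profiles over the THSs assigned to each
#' gene (by [annotate_ths()]).
#'
#' @param annotated Annotated THS tibble.
#' @param fc Fold-change tibble from [fold_change_matrix()].
#' @return Tibble `gene_id`, `D1`, `D2`, `D3`.
#' @export
gene_atac_profiles <- function(annotated, fc) {
  annotated |>
    filter(!is.na(.data$gene_id)) |>
    select("ths_id", "gene_id") |>
    inner_join(fc, by = "ths_id") |>
    group_by(.data$gene_id) |>
    summarise(across(c("D1", "D2", "D3"), mean), .groups = "drop")
}

#' Join THS-linked genes with the expression table
#'
#' Inner join on gene id; each row carries the gene's ATAC fold-change
#' profile and its RNA fold-change profile. Unmatched ids from either
#' side are reported in the `unmatched` attribute.
#'
#' @param atac_profiles Gene-level ATAC profiles from
#'   [gene_atac_profiles()].
#' @param expr Expression tibble (`gene_id`, `D1`, `D2`, `D3`).
#' @return Tibble `gene_id`, `atac_D1`..`atac_D3`, `rna_D1`..`rna_D3`;
#'   attribute `unmatched` lists ids present on one side only.
#' @export
join_ths_expression <- function(atac_profiles, expr) {
  a <- rename(atac_profiles, atac_D1 = "D1", atac_D2 = "D2",
              atac_D3 = "D3")
  r <- rename(expr, rna_D1 = "D1", rna_D2 = "D2", rna_D3 = "D3")
  joined <- inner_join(a, r, by = "gene_id")
  attr(joined, "unmatched") <- list(
    atac_only = setdiff(atac_profiles$gene_id, expr$gene_id),
    expr_only = setdiff(expr$gene_id, atac_profiles$gene_id))
  joined
}

#' Bipartite ATAC-RNA correlation network
#'
#' Every gene contributes an ATAC node (its per-stage ATAC profile) and
#' an RNA node (its per-stage expression profile). After the chosen
#' normalization (default: scale each profile to unit Euclidean norm;
#' `"raw"` leaves profiles untouched) an edge joins ATAC node i to RNA
#' node j iff the squared Euclidean distance of their profiles is below
#' `threshold`. Only ATAC-RNA pairs are ever evaluated, so the network
#' is bipartite by construction. Zero-norm profiles cannot be
#' unit-scaled; their nodes are excluded with a warning.
#'
#' @param joined Joined table from [join_ths_expression()].
#' @param threshold Squared-distance threshold (default 0.01).
#' @param normalization `"unit"` or `"raw"`.
#' @return A `ths_network`: list with `nodes` (gene_id, source),
#'   `edges` (atac_gene, rna_gene, dist2), `threshold`,
#'   `normalization`.
#' @export
correlation_network <- function(joined, threshold = 0.01,
                                normalization = c("unit", "raw")) {
  normalization <- match.arg(normalization)
  if (nrow(joined) == 0) abort("joined table is empty")
  amat <- as.matrix(joined[, c("atac_D1", "atac_D2", "atac_D3")])
  rmat <- as.matrix(joined[, c("rna_D1", "rna_D2", "rna_D3")])
  rownames(amat) <- rownames(rmat) <- joined$gene_id
  keep_a <- rep(TRUE, nrow(amat)); keep_r <- rep(TRUE, nrow(rmat))
  if (normalization == "unit") {
    na <- sqrt(rowSums(amat^2)); nr <- sqrt(rowSums(rmat^2))
    keep_a <- na > 0; keep_r <- nr > 0
    if (any(!keep_a) || any(!keep_r)) {
      warn(sprintf("%d zero-norm profiles excluded",
                   sum(!keep_a) + sum(!keep_r)))
    }
    amat <- amat[keep_a, , drop = FALSE] / na[keep_a]
    rmat <- rmat[keep_r, , drop = FALSE] / nr[keep_r]
  }
  # all ATAC x RNA squared distances
  d2 <- outer(rowSums(amat^2), rowSums(rmat^2), "+") -
    2 * amat %*% t(rmat)
  d2[d2 < 0] <- 0
  hits <- which(d2 < threshold, arr.ind = TRUE)
  edges <- tibble(atac_gene = rownames(amat)[hits[, 1]],
                  rna_gene = rownames(rmat)[hits[, 2]],
                  dist2 = d2[hits])
  nodes <- bind_rows(
    tibble(gene_id = rownames(amat), source = "ATAC"),
    tibble(gene_id = rownames(rmat), source = "RNA"))
  structure(list(nodes = nodes, edges = arrange(edges, .data$dist2),
                 threshold = threshold, normalization = normalization),
            class = "ths_network")
}

#' @export
tidy.ths_network <- function(x, ...) x$edges

#' @export
glance.ths_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_self_edges = sum(x$edges$atac_gene == x$edges$rna_gene),
         threshold = x$threshold, normalization = x$normalization)
}

#' @export
print.ths_network <- function(x, ...) {
  cat(sprintf(
    "Bipartite ATAC-RNA network: %d nodes, %d edges (d2 < %g, %s)\n",
    nrow(x$nodes), nrow(x$edges), x$threshold, x$normalization))
  invisible(x)
}

#' Write a network as edge-list TSV and GraphML
#' @param network A `ths_network`.
#' @param tsv_path,graphml_path Output paths (`NULL` to skip).
#' @export
write_network <- function(network, tsv_path = NULL, graphml_path = NULL) {
  if (!is.null(tsv_path)) readr::write_tsv(network$edges, tsv_path)
  if (!is.null(graphml_path)) {
    nid <- function(g, s) paste0(s, ":", g)
    nodes <- network$nodes
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '<key id="source" for="node" attr.name="source" attr.type="string"/>',
      '<key id="dist2" for="edge" attr.name="dist2" attr.type="double"/>',
      '<graph edgedefault="undirected">',
      sprintf('<node id="%s"><data key="source">%s</data></node>',
              nid(nodes$gene_id, nodes$source), nodes$source),
      sprintf('<edge source="%s" target="%s"><data key="dist2">%g</data></edge>',
              nid(network$edges$atac_gene, "ATAC"),
              nid(network$edges$rna_gene, "RNA"),
              network$edges$dist2),
      "</graph>", "</graphml>")
    writeLines(lines, graphml_path)
  }
  invisible(network)
}

#' Link enriched motifs to transcription-factor expression
#'
#' For each enriched motif with a known-PWM match, attaches the matched
#' TF's expression profile when present in the expression table; motifs
#' keep the stage group of the THSs whose promoters they came from.
#'
#' @param matches Tibble from [match_known_motifs()], optionally with a
#'   `stage_group` column.
#' @param expr Expression tibble.
#' @return Tibble `word`, `tf_name`, `stage_group`, `D1`, `D2`, `D3`,
#'   `expr_missing`.
#' @export
link_motifs_to_tf_expression <- function(matches, expr) {
  sg <- if ("stage_group" %in% names(matches)) matches$stage_group else
    NA_character_
  out <- tibble(word = matches$word, tf_name = matches$tf_name,
                stage_group = sg)
  hit <- match(out$tf_name, expr$gene_id)
  out$D1 <- expr$D1[hit]; out$D2 <- expr$D2[hit]; out$D3 <- expr$D3[hit]
  out$expr_missing <- is.na(hit)
  out
}
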