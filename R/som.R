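# Hexagonal lattice embedding: odd rows shifted half a unit, rows packed
# at sqrt(3)/2, so lattice distances are Euclidean in the embedding.
hex_grid <- function(nrow, ncol) {
  g <- expand.grid(col = seq_len(ncol) - 1L, row = seq_len(nrow) - 1L)
  tibble(node = seq_len(nrow * ncol),
         row = g$row, col = g$col,
         x = g$col + 0.5 * (g$row %% 2),
         y = g$row * sqrt(3) / 2)
}

# per-curve min-max normalization; constant curves map to zero
normalize_curves <- function(values) {
  apply(values, 2, function(v) {
    r <- max(v) - min(v)
    if (r == 0) rep(0, length(v)) else (v - min(v)) / r
  })
}

#' Train a hexagonal self-organizing map on labeled OJIP transients
#'
#' Online Kohonen training on a hexagonal lattice: curves are min-max
#' normalized, the best-matching unit (BMU) is the prototype at minimal
#' Euclidean distance, and the BMU's Gaussian neighborhood is pulled
#' toward each presented curve. The neighborhood radius and learning rate
#' decay linearly across epochs. After training each node is labeled by
#' majority vote of the training curves mapped to it (ties broken toward
#' the earlier stage in the order C < D1 < D2 < D3); nodes with no mapped
#' curve take the label of their nearest training curve. Together the
#' prototype lattice and its label layer form the two-layer classifier.
#'
#' @param curves List with `times`, `values` (matrix, one curve per
#'   column) and `labels` (stage per curve), as from [simulate_ojip()] or
#'   [read_ojip_tsv()].
#' @param grid_shape `c(rows, cols)`, at least 2x2.
#' @param epochs Training epochs (full passes over the curves).
#' @param radius Neighborhood radius, start and end of the linear decay.
#' @param learning_rate Learning rate, start and end of the linear decay.
#' @param seed Seed for prototype initialization and presentation order.
#' @return A `som_stage_model` with the lattice, prototypes, node labels,
#'   training parameters and the per-epoch mean quantization error.
#' @export
train_som <- function(curves, grid_shape = c(4L, 4L), epochs = 500L,
                      radius = c(2, 0.5), learning_rate = c(0.5, 0.01),
                      seed = 1L) {
  labels <- curves$labels
  if (is.null(labels)) abort("training curves must be labeled")
  if (!all(STAGES %in% labels)) {
    abort("need at least one training curve per stage")
  }
  if (any(grid_shape < 2)) abort("grid must be at least 2x2")
  x <- normalize_curves(curves$values)
  n <- ncol(x); d <- nrow(x)
  grid <- hex_grid(grid_shape[1], grid_shape[2])
  k <- nrow(grid)
  # squared lattice distances between nodes
  dx <- outer(grid$x, grid$x, "-"); dy <- outer(grid$y, grid$y, "-")
  grid_d2 <- dx^2 + dy^2

  set.seed(seed)
  proto <- x[, sample.int(n, k, replace = n < k), drop = FALSE]
  qe <- numeric(epochs)
  for (e in seq_len(epochs)) {
    frac <- if (epochs == 1) 0 else (e - 1) / (epochs - 1)
    sigma <- radius[1] + frac * (radius[2] - radius[1])
    alpha <- learning_rate[1] + frac * (learning_rate[2] - learning_rate[1])
    ord <- sample.int(n)
    qsum <- 0
    for (i in ord) {
      diff <- proto - x[, i]
      d2 <- colSums(diff * diff)
      bmu <- which.min(d2)
      qsum <- qsum + d2[bmu]
      h <- alpha * exp(-grid_d2[, bmu] / (2 * sigma^2))
      proto <- proto - diff * rep(h, each = d)
    }
    qe[e] <- qsum / n
  }

  # label layer: majority vote per node, ties toward the earlier stage
  bmus <- bmu_scan(proto, x)
  node_labels <- character(k)
  mapped <- integer(k)
  for (j in seq_len(k)) {
    lab <- labels[bmus == j]
    mapped[j] <- length(lab)
    if (length(lab) > 0) {
      tab <- table(factor(lab, levels = STAGES))
      node_labels[j] <- STAGES[which.max(tab)]
    } else {
      diff <- x - proto[, j]
      node_labels[j] <- labels[which.min(colSums(diff * diff))]
    }
  }
  structure(list(grid = grid, prototypes = proto,
                 node_labels = node_labels, mapped_n = mapped,
                 times = curves$times, qe = qe,
                 params = list(grid_shape = grid_shape, epochs = epochs,
                               radius = radius,
                               learning_rate = learning_rate, seed = seed)),
            class = "som_stage_model")
}

# BMU index per curve column; ties resolve to the first node in
# (row, col) order because which.min returns the first minimum
bmu_scan <- function(proto, x) {
  apply(x, 2, function(v) {
    diff <- proto - v
    which.min(colSums(diff * diff))
  })
}

#' Classify OJIP transients into desiccation stages
#'
#' Each curve (min-max normalized) is assigned the label of its
#' best-matching unit, the node prototype at minimal Euclidean distance;
#' ties resolve deterministically in (row, col) node order.
#'
#' @param model A trained [train_som()] model.
#' @param values Numeric vector (one curve) or matrix (one per column),
#'   on the model's time grid.
#' @return A tibble with `curve`, `node`, `distance` and `stage`.
#' @export
classify_stage <- function(model, values) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  if (nrow(values) != nrow(model$prototypes)) {
    abort(sprintf("curve length %d does not match model dimension %d",
                  nrow(values), nrow(model$prototypes)))
  }
  x <- normalize_curves(values)
  bmus <- bmu_scan(model$prototypes, x)
  dist <- vapply(seq_len(ncol(x)), function(i) {
    sqrt(sum((model$prototypes[, bmus[i]] - x[, i])^2))
  }, numeric(1))
  tibble(curve = colnames(values) %||% as.character(seq_len(ncol(x))),
         node = as.integer(bmus), distance = dist,
         stage = model$node_labels[bmus])
}

#' @export
print.som_stage_model <- function(x, ...) {
  cat(sprintf("Hexagonal SOM stage classifier: %dx%d nodes, %d epochs\n",
              x$params$grid_shape[1], x$params$grid_shape[2],
              x$params$epochs))
  cat("node labels:", paste(x$node_labels, collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.som_stage_model <- function(x, ...) {
  bind_cols(x$grid, tibble(stage = x$node_labels, n_mapped = x$mapped_n))
}

#' @export
glance.som_stage_model <- function(x, ...) {
  tibble(n_nodes = nrow(x$grid), epochs = x$params$epochs,
         final_qe = x$qe[length(x$qe)],
         dim = nrow(x$prototypes))
}
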