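#' Rectangular SOM grid geometry
#'
#' The default 60 x 60 grid carries 3600 metagenes, a resolution at
#' which expression modules of typical single-cell data sets are well
#' resolved; the test suite and desk-scale runs use smaller grids.
#' Nodes are indexed 1..K in row-major order.
#'
#' @param rows,cols positive integers; `rows * cols >= 4`.
#' @return a `som_grid` list with `rows`, `cols` and `K = rows * cols`.
#' @export
som_grid <- function(rows = 60L, cols = 60L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L || rows * cols < 4L)
    stop_somscape("grid needs rows * cols >= 4")
  structure(list(rows = rows, cols = cols, K = rows * cols),
            class = "som_grid")
}

#' Train a batch self-organizing map on gene logFC profiles
#'
#' Genes are the training samples; the components of each profile are
#' the cells. Each grid node holds one prototype vector (a "metagene"):
#' a micro-cluster of genes with mutually similar expression profiles.
#' Training is the deterministic batch scheme: in every epoch all genes
#' are assigned to their best-matching unit (BMU, nearest prototype in
#' Euclidean distance) and every prototype is recomputed as the
#' Gaussian-neighborhood-weighted mean of the assigned profiles, with
#' the neighborhood radius shrinking linearly from `max(rows, cols) / 2`
#' to `radius_final` over the epochs.
#'
#' Prototypes are initialized on the plane spanned by the first two
#' principal components of the gene profiles (orientation-stable and
#' deterministic), falling back to seeded uniform noise for degenerate
#' data.
#'
#' @param data an [expr_matrix()] with layer `"logfc"` (other layers are
#'   accepted with a warning).
#' @param grid a [som_grid()].
#' @param epochs number of batch epochs (default 20).
#' @param seed integer seed; only consumed by the random fallback
#'   initialization, so runs are reproducible in either branch.
#' @param radius_final neighborhood radius in the last epoch
#'   (default 0.5; values near 0 make the final pass a plain k-means
#'   style assignment mean).
#' @return a `som_model` with `grid`, `prototypes` (K x cells), `bmu`
#'   (named gene-to-node map), the per-epoch quantization-error history
#'   and the final quantization error.
#' @export
train_som <- function(data, grid = som_grid(), epochs = 20L, seed = 1L,
                      radius_final = 0.5) {
  if (!inherits(data, "expr_matrix"))
    stop_somscape("'data' must be an expr_matrix")
  if (expr_layer(data) != "logfc")
    warning("training on layer '", expr_layer(data),
            "'; the portrayal workflow expects 'logfc'")
  X <- as_plain_matrix(data)
  if (anyNA(X) || any(!is.finite(X)))
    stop_somscape("training data contains non-finite values")
  if (nrow(X) < 2L || ncol(X) < 2L)
    stop_somscape("need at least 2 genes and 2 cells")
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop_somscape("'epochs' must be >= 1")
  K <- grid$K
  if (K > 4L * nrow(X))
    warning("grid has ", K, " nodes for only ", nrow(X),
            " genes; the map will be sparse")

  P <- init_prototypes(X, grid, seed)
  coords <- node_coords(grid)
  grid_d2 <- cross_dist2(coords, coords)     # K x K squared grid distances

  radius0 <- max(grid$rows, grid$cols) / 2
  radii <- if (epochs == 1L) radius_final else
    seq(radius0, radius_final, length.out = epochs)

  # qe_history[e] measures the map after epoch e's update (the distances
  # are reused for the next epoch's assignment, so this costs nothing)
  qe_history <- numeric(epochs)
  bmu <- integer(nrow(X))
  for (e in seq_len(epochs)) {
    d2 <- cross_dist2(X, P)
    bmu <- max.col(-d2, ties.method = "first")
    if (e > 1L)
      qe_history[e - 1L] <- mean(sqrt(d2[cbind(seq_len(nrow(X)), bmu)]))
    h <- exp(-grid_d2 / (2 * radii[e]^2))    # K x K neighborhood kernel
    counts <- tabulate(bmu, nbins = K)
    sums <- rowsum_by_node(X, bmu, K)
    denom <- as.vector(h %*% counts)
    upd <- denom > 0       # empty nodes keep their prototype at tiny radii
    P[upd, ] <- (h %*% sums)[upd, , drop = FALSE] / denom[upd]
  }
  d2 <- cross_dist2(X, P)
  bmu <- max.col(-d2, ties.method = "first")
  qe <- mean(sqrt(d2[cbind(seq_len(nrow(X)), bmu)]))
  qe_history[epochs] <- qe
  names(bmu) <- rownames(X)
  colnames(P) <- colnames(X)
  rownames(P) <- NULL

  structure(list(grid = grid, prototypes = P, bmu = bmu,
                 epochs = epochs, seed = as.integer(seed),
                 radius_final = radius_final,
                 qe_history = qe_history, quantization_error = qe),
            class = "som_model")
}

# K x n_cells sums of gene profiles grouped by BMU (zero rows for empty nodes)
rowsum_by_node <- function(X, bmu, K) {
  s <- rowsum(X, group = bmu)
  out <- matrix(0, nrow = K, ncol = ncol(X))
  out[as.integer(rownames(s)), ] <- s
  out
}

init_prototypes <- function(X, grid, seed) {
  m <- colMeans(X)
  Xc <- sweep(X, 2L, m)
  sv <- svd(Xc, nu = 0L, nv = 2L)
  coords <- node_coords(grid)
  # span the longer grid axis with the first principal direction
  ax_row <- if (grid$rows > 1L) 2 * (coords[, "row"] - 1) / (grid$rows - 1) - 1 else
    rep(0, grid$K)
  ax_col <- if (grid$cols > 1L) 2 * (coords[, "col"] - 1) / (grid$cols - 1) - 1 else
    rep(0, grid$K)
  if (grid$rows > grid$cols) { a1 <- ax_row; a2 <- ax_col } else {
    a1 <- ax_col; a2 <- ax_row
  }
  if (length(sv$d) >= 1L && sv$d[1L] > 1e-10) {
    s1 <- sv$d[1L] / sqrt(max(nrow(X) - 1L, 1L))
    dir1 <- sv$v[, 1L] * s1
    # rank-1 clouds span the grid along the first component only
    dir2 <- if (length(sv$d) >= 2L &&
                sv$d[2L] > 1e-10 * max(sv$d[1L], 1)) {
      sv$v[, 2L] * sv$d[2L] / sqrt(max(nrow(X) - 1L, 1L))
    } else rep(0, ncol(X))
    P <- outer(rep(1, grid$K), m) + outer(a1, dir1) + outer(a2, dir2)
  } else {
    # degenerate cloud: seeded uniform jitter around the mean profile
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    spread <- max(stats::sd(as.vector(Xc)), 1e-6)
    P <- outer(rep(1, grid$K), m) +
      matrix(stats::runif(grid$K * ncol(X), -spread, spread),
             nrow = grid$K)
  }
  P
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf(
    "<som_model> %d x %d grid (%d metagenes), %d genes, %d cells\n",
    x$grid$rows, x$grid$cols, x$grid$K, length(x$bmu), ncol(x$prototypes)))
  cat(sprintf("  epochs %d, seed %d, quantization error %.4g\n",
              x$epochs, x$seed, x$quantization_error))
  invisible(x)
}

#' Best-matching unit of an expression profile
#'
#' @param model a trained `som_model`.
#' @param profile numeric vector, one value per cell of the model.
#' @return the node index (row-major, 1-based) of the nearest prototype;
#'   ties go to the lowest index.
#' @export
assign_bmu <- function(model, profile) {
  if (length(profile) != ncol(model$prototypes))
    stop_somscape("profile length ", length(profile), " != number of cells ",
                  ncol(model$prototypes))
  d2 <- cross_dist2(matrix(profile, nrow = 1L), model$prototypes)
  which.min(d2[1L, ])
}

#' Portrait of a single cell
#'
#' The K metagene values of one cell: node k shows prototype k's
#' expression in that cell, i.e. a column slice through the prototype
#' matrix rendered on the grid.
#'
#' @param model a trained `som_model`.
#' @param cell cell id.
#' @param scale `"logfc"` (default) or `"loglogfc"` for the signed-log
#'   compressed scale.
#' @return a `som_portrait`: list of `values` (length K), `grid`,
#'   `subject` and `scale`.
#' @export
portrait_of_cell <- function(model, cell, scale = c("logfc", "loglogfc")) {
  scale <- match.arg(scale)
  if (!cell %in% colnames(model$prototypes))
    stop_somscape("unknown cell id '", cell, "'")
  v <- model$prototypes[, cell]
  if (scale == "loglogfc") v <- loglog_transform(v)
  new_portrait(v, model$grid, subject = cell, scale = scale)
}

#' Mean portrait of a cell group
#'
#' Node-wise arithmetic mean of the member portraits on the logFC
#' scale; the optional signed-log compression is applied to the mean.
#'
#' @param model a trained `som_model`.
#' @param cells nonempty character vector of cell ids.
#' @param scale `"logfc"` or `"loglogfc"`.
#' @param subject label for the resulting portrait.
#' @return a `som_portrait`.
#' @export
mean_portrait <- function(model, cells, scale = c("logfc", "loglogfc"),
                          subject = "group") {
  scale <- match.arg(scale)
  if (length(cells) == 0L) stop_somscape("'cells' must be nonempty")
  missing <- setdiff(cells, colnames(model$prototypes))
  if (length(missing) > 0L)
    stop_somscape("unknown cell id(s): ", paste(utils::head(missing, 3L),
                                                collapse = ", "))
  v <- rowMeans(model$prototypes[, cells, drop = FALSE])
  if (scale == "loglogfc") v <- loglog_transform(v)
  new_portrait(v, model$grid, subject = subject, scale = scale)
}

new_portrait <- function(values, grid, subject, scale) {
  stopifnot(length(values) == grid$K, all(is.finite(values)))
  structure(list(values = as.numeric(values), grid = grid,
                 subject = subject, scale = scale),
            class = "som_portrait")
}

#' @export
print.som_portrait <- function(x, ...) {
  cat(sprintf("<som_portrait> '%s' on %d x %d grid, scale %s, range [%.3g, %.3g]\n",
              x$subject, x$grid$rows, x$grid$cols, x$scale,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Number of genes assigned to each metagene node
#'
#' @param model a trained `som_model`.
#' @return integer vector of length K summing to the number of genes.
#' @export
population_map <- function(model) {
  tabulate(model$bmu, nbins = model$grid$K)
}

#' Variance of metagene expression across cells or cell groups
#'
#' For each node, the population variance of its prototype vector across
#' cells; when a grouping is supplied, the variance is taken across the
#' group-mean portraits instead, emphasizing between-type variability.
#'
#' @param model a trained `som_model`.
#' @param groups optional named factor/character vector mapping every
#'   cell id to a group (at least 2 groups).
#' @return numeric vector of length K.
#' @export
variance_map <- function(model, groups = NULL) {
  P <- model$prototypes
  if (is.null(groups)) {
    if (ncol(P) < 2L)
      stop_somscape("variance undefined for a single cell")
    return(rowMeans(P^2) - rowMeans(P)^2)
  }
  groups <- groups[colnames(P)]
  if (anyNA(groups))
    stop_somscape("'groups' must cover every cell of the model")
  levs <- unique(as.character(groups))
  if (length(levs) < 2L) stop_somscape("need at least 2 groups")
  M <- vapply(levs, function(g)
    rowMeans(P[, names(groups)[groups == g], drop = FALSE]),
    numeric(nrow(P)))
  rowMeans(M^2) - rowMeans(M)^2
}
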