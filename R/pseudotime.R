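#' Symmetrized k-nearest-neighbor graph of cells
#'
#' Builds the similarity graph driving the diffusion pseudotime. Each
#' cell is linked to its k nearest neighbors in feature space (by
#' default the cells' metagene portraits); weights use a Gaussian kernel
#' with a per-cell adaptive bandwidth equal to the distance to the
#' ceiling(k/2)-th neighbor, and the graph is symmetrized by taking the
#' maximum of the two directed weights. Duplicate cells (distance zero)
#' get weight 1.
#'
#' @param cell_features cells x d numeric matrix with cell ids as
#'   rownames.
#' @param k number of neighbors (default 15), `k < n_cells`.
#' @return a `cell_graph`: `weights` (dense symmetric matrix),
#'   `adjacency` (logical), `k`.
#' @export
knn_graph <- function(cell_features, k = 15L) {
  if (is.null(rownames(cell_features)))
    stop_somscape("'cell_features' needs cell ids as rownames")
  n <- nrow(cell_features)
  k <- as.integer(k)
  if (k < 1L || k >= n)
    stop_somscape("'k' must satisfy 1 <= k < n_cells (n = ", n, ")")
  d <- as.matrix(stats::dist(cell_features))
  nn <- t(apply(d, 1L, function(row) order(row)[2:(k + 1L)]))
  sigma <- vapply(seq_len(n), function(i)
    d[i, nn[i, ceiling(k / 2)]], numeric(1L))
  sigma[sigma <= 0] <- .Machine$double.eps
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) A[i, nn[i, ]] <- TRUE
  A <- A | t(A)
  W <- matrix(0, n, n, dimnames = list(rownames(cell_features),
                                       rownames(cell_features)))
  W[A] <- exp(-(d[A]^2) / (outer(sigma, sigma)[A]))
  W[A & d == 0] <- 1
  structure(list(weights = W, adjacency = A, k = k, max_dist = max(d)),
            class = "cell_graph")
}

#' Cell features for pseudotime: metagene portraits
#'
#' Returns the cells x K matrix of metagene expression (the transposed
#' prototype matrix), the default feature space for [knn_graph()].
#'
#' @param model a trained `som_model`.
#' @return cells x K numeric matrix.
#' @export
portrait_features <- function(model) {
  t(model$prototypes)
}

#' Diffusion pseudotime from root cells
#'
#' Orders cells by simulating a diffusion-like process from a root
#' population: the normalized transition operator of the kNN graph is
#' eigendecomposed, cells are embedded in the leading diffusion
#' components (eigenvectors scaled by `lambda / (1 - lambda)`, so the
#' coordinates aggregate diffusion over all path lengths), and the
#' pseudotime of a cell is its diffusion distance from the root
#' centroid. Values are affinely rescaled so that the minimum over root
#' cells is exactly 0 and the global maximum — the tip of largest
#' distance — is exactly 1.
#'
#' @param graph a [knn_graph()] result.
#' @param roots nonempty character vector of root cell ids (e.g. the
#'   stem cells).
#' @param n_components number of diffusion components (default 10).
#' @return a `pseudotime_result`: `pt` (named, in `[0, 1]`), `roots`,
#'   `knn_k`, `n_diffusion_components`. Cells outside the largest
#'   connected component (used with a warning) get `NA`.
#' @export
diffusion_pseudotime <- function(graph, roots, n_components = 10L) {
  W <- graph$weights
  ids <- rownames(W)
  if (!is.null(graph$max_dist) && graph$max_dist <= 0)
    stop_somscape("degenerate spectrum: all cells are identical")
  if (length(roots) == 0L) stop_somscape("'roots' must be nonempty")
  if (!all(roots %in% ids))
    stop_somscape("unknown root cell(s): ",
                  paste(utils::head(setdiff(roots, ids), 3L), collapse = ", "))
  comp <- graph_components(graph$adjacency)
  keep <- comp == as.integer(names(which.max(table(comp))))
  if (!all(keep)) {
    warning("graph is disconnected; using the largest component (",
            sum(keep), " of ", length(keep), " cells), rest set to NA")
    if (!any(roots %in% ids[keep]))
      stop_somscape("no root cell lies in the largest component")
    roots <- intersect(roots, ids[keep])
    W <- W[keep, keep]
  }
  n <- nrow(W)
  deg <- rowSums(W)
  if (any(deg <= 0)) stop_somscape("graph has isolated cells")
  A <- W / sqrt(outer(deg, deg))
  eig <- eigen(A, symmetric = TRUE)
  lambda <- eig$values
  n_components <- min(as.integer(n_components), n - 1L)
  use <- 2:(n_components + 1L)
  scale <- lambda[use] / pmax(1 - lambda[use], 1e-12)
  phi <- eig$vectors[, use, drop = FALSE] / sqrt(deg)
  psi <- sweep(phi, 2L, scale, `*`)
  rownames(psi) <- rownames(W)
  centroid <- colMeans(psi[roots, , drop = FALSE])
  pt_sub <- sqrt(rowSums(sweep(psi, 2L, centroid)^2))
  if (max(pt_sub) < 1e-12)
    stop_somscape("degenerate spectrum: all cells are identical")
  pt_sub <- pt_sub - min(pt_sub[roots])
  pt_sub <- pt_sub / max(pt_sub)
  # a non-root cell can sit marginally closer to the root centroid than
  # any root; clamp so the published scale stays in [0, 1]
  pt_sub <- pmax(pt_sub, 0)
  pt <- stats::setNames(rep(NA_real_, length(ids)), ids)
  pt[rownames(psi)] <- pt_sub
  structure(list(pt = pt, roots = roots, knn_k = graph$k,
                 n_diffusion_components = n_components),
            class = "pseudotime_result")
}

# connected component labels from a logical adjacency matrix (BFS)
graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(A[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.pseudotime_result <- function(x, ...) {
  cat(sprintf("<pseudotime_result> %d cells, %d roots, k = %d, %d components\n",
              length(x$pt), length(x$roots), x$knn_k,
              x$n_diffusion_components))
  invisible(x)
}

#' Module expression along pseudotime
#'
#' Pairs every lineage cell's pseudotime with its mean portrait value
#' over a spot's (or cluster's) nodes, and adds a LOESS local-regression
#' guide curve (tricube weights) when at least 5 cells are available.
#' This is how the decline of a stem module or the rise of a tissue
#' module along differentiation is profiled.
#'
#' @param pt a [diffusion_pseudotime()] result.
#' @param cells_of_lineage character vector of cell ids to profile.
#' @param model the trained `som_model`.
#' @param nodes integer node indices of the spot or cluster (e.g.
#'   `spot$members` or [cluster_nodes()]).
#' @param span LOESS span (default 0.5).
#' @return a `pt_profile`: `points` (data.frame `cell_id`, `pt`,
#'   `expression`) and `curve` (data.frame `pt`, `fitted`; `NULL` when
#'   fewer than 5 cells).
#' @export
pt_spot_profile <- function(pt, cells_of_lineage, model, nodes, span = 0.5) {
  cells <- intersect(cells_of_lineage, names(pt$pt))
  cells <- cells[!is.na(pt$pt[cells])]
  if (length(cells) == 0L) stop_somscape("no annotated cells with pseudotime")
  expr <- colMeans(model$prototypes[nodes, cells, drop = FALSE])
  points <- data.frame(cell_id = cells, pt = unname(pt$pt[cells]),
                       expression = unname(expr), stringsAsFactors = FALSE)
  curve <- NULL
  if (nrow(points) >= 5L) {
    fit <- stats::loess(expression ~ pt, data = points, span = span,
                        degree = 1L, family = "gaussian")
    grid_pt <- seq(min(points$pt), max(points$pt), length.out = 100L)
    curve <- data.frame(pt = grid_pt,
                        fitted = stats::predict(fit, newdata =
                                                  data.frame(pt = grid_pt)))
  }
  structure(list(points = points, curve = curve, span = span),
            class = "pt_profile")
}
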