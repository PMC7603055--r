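#' Detect overexpression spot modules in group portraits
#'
#' Self-organization concentrates correlated metagenes into "spot-like"
#' areas of concerted overexpression. A node is a spot member if its
#' value exceeds the per-portrait upper quantile threshold in at least
#' one of the supplied group portraits; 8-connected components of
#' members form the spots, and each spot's kernel is the node maximizing
#' the node-wise maximum over the portraits.
#'
#' @param group_portraits nonempty list of `som_portrait` objects on a
#'   common grid (typically mean portraits per cell type).
#' @param quantile membership threshold quantile, default 0.98.
#' @return list of `spot_module` objects (`members`, `kernel`, `label`),
#'   ordered by descending kernel height and labeled `"S1"`, `"S2"`, ...
#'   All-constant portraits yield an empty list.
#' @export
detect_spots <- function(group_portraits, quantile = 0.98) {
  if (length(group_portraits) == 0L)
    stop_somscape("need at least one portrait")
  if (quantile <= 0 || quantile >= 1)
    stop_somscape("'quantile' must be in (0, 1)")
  grid <- group_portraits[[1L]]$grid
  vals <- vapply(group_portraits, function(p) {
    if (!identical(p$grid[c("rows", "cols")], grid[c("rows", "cols")]))
      stop_somscape("portraits are on different grids")
    p$values
  }, numeric(grid$K))
  vals <- matrix(vals, nrow = grid$K)
  member <- rep(FALSE, grid$K)
  for (j in seq_len(ncol(vals))) {
    thr <- stats::quantile(vals[, j], quantile, names = FALSE)
    member <- member | vals[, j] > thr
  }
  if (!any(member)) return(list())
  comps <- connected_components(which(member), grid)
  height <- apply(vals, 1L, max)
  spots <- lapply(comps, function(nodes) {
    kernel <- nodes[which.max(height[nodes])]
    list(members = nodes, kernel = kernel, kernel_height = height[kernel])
  })
  ord <- order(vapply(spots, `[[`, numeric(1L), "kernel_height"),
               decreasing = TRUE)
  spots <- spots[ord]
  for (i in seq_along(spots)) {
    spots[[i]]$label <- paste0("S", i)
    class(spots[[i]]) <- "spot_module"
  }
  spots
}

# 8-connected components of a node subset; returns list of node vectors
connected_components <- function(nodes, grid) {
  in_set <- rep(FALSE, grid$K)
  in_set[nodes] <- TRUE
  seen <- rep(FALSE, grid$K)
  comps <- list()
  for (start in nodes) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- integer()
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      comp <- c(comp, v)
      for (nb in neighbors8(v, grid)) {
        if (in_set[nb] && !seen[nb]) {
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Space-filling k-means segmentation of the metagene landscape
#'
#' Clusters all prototype vectors with Lloyd's algorithm (k-means++
#' seeding, best of `restarts` runs), then assigns letters by descending
#' mean variance-map value so that highly variant tissue modules receive
#' the early letters: `"A"`..`"Z"`, `"A1"`, ... (32 clusters run
#' `"A"`-`"F1"`). Every node gets exactly one label and all `k` clusters
#' are non-empty.
#'
#' @param model a trained `som_model`.
#' @param k number of clusters, default 32.
#' @param seed integer seed controlling the k-means++ draws.
#' @param restarts number of seeded restarts (default 10).
#' @return a `som_segmentation`: `cluster` (node to cluster id 1..k),
#'   `letters`, `adjacency` (data.frame of letter pairs), per-cluster
#'   `variance_class` (via [classify_variance()] with no spots) and the
#'   grid.
#' @export
kmeans_segment <- function(model, k = 32L, seed = 1L, restarts = 10L) {
  K <- model$grid$K
  k <- as.integer(k)
  if (k < 1L || k > K)
    stop_somscape("'k' must be between 1 and the number of nodes (", K, ")")
  P <- model$prototypes
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(P, k)
    fit <- tryCatch(
      stats::kmeans(P, centers = centers, iter.max = 100L,
                    algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(P, centers = centers,
                                       iter.max = 200L,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
    }
    if (is.null(fit) || length(unique(fit$cluster)) != k) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    stop_somscape("k-means failed to produce ", k,
                  " non-empty clusters; are the prototypes degenerate?")
  cl <- best$cluster

  vm <- if (ncol(P) >= 2L) variance_map(model) else rep(0, K)
  mean_var <- vapply(seq_len(k), function(c) mean(vm[cl == c]), numeric(1L))
  ord <- order(mean_var, decreasing = TRUE)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  cl <- relabel[cl]

  letters <- cluster_letters(k)
  seg <- structure(
    list(cluster = cl, letters = letters, k = k, grid = model$grid,
         cluster_mean_variance = sort(mean_var, decreasing = TRUE),
         variance_class = NULL, adjacency = NULL),
    class = "som_segmentation")
  seg$adjacency <- cluster_adjacency(seg, model$grid)
  classify_variance(seg, model, spots = list())
}

# k-means++ seeding on the rows of P (returns a k x d center matrix)
kmeanspp_centers <- function(P, k) {
  n <- nrow(P)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rep(Inf, n)
  for (i in seq_len(k - 1L)) {
    d2 <- pmin(d2, rowSums(sweep(P, 2L, P[idx[i], ])^2))
    cand <- which(d2 > 0)
    if (length(cand) == 0L)
      cand <- setdiff(seq_len(n), idx[seq_len(i)])
    idx[i + 1L] <- if (length(cand) == 1L) cand else
      sample(cand, 1L, prob = d2[cand])
  }
  P[idx, , drop = FALSE]
}

#' @export
print.som_segmentation <- function(x, ...) {
  cat(sprintf("<som_segmentation> %d clusters ('%s'..'%s') on %d x %d grid\n",
              x$k, x$letters[1L], x$letters[x$k], x$grid$rows, x$grid$cols))
  if (!is.null(x$variance_class))
    cat("  variance classes: ",
        paste(names(table(x$variance_class)), table(x$variance_class),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Tag clusters as spot-variant, low-variant or invariant
#'
#' A cluster containing the kernel of a detected overexpression spot is
#' `spot-variant`; the cluster with the minimal mean variance-map value
#' is the single `invariant` cluster (it collects the genes that barely
#' change across cell types); every other cluster is `low-variant`.
#'
#' @param seg a `som_segmentation`.
#' @param model the `som_model` the segmentation came from.
#' @param spots a [detect_spots()] result (may be empty).
#' @return the segmentation with `variance_class` filled in.
#' @export
classify_variance <- function(seg, model, spots = list()) {
  vm <- if (ncol(model$prototypes) >= 2L) variance_map(model)
        else rep(0, seg$grid$K)
  mean_var <- vapply(seq_len(seg$k), function(c) mean(vm[seg$cluster == c]),
                     numeric(1L))
  cls <- rep("low-variant", seg$k)
  for (s in spots)
    cls[seg$cluster[s$kernel]] <- "spot-variant"
  cls[which.min(mean_var)] <- "invariant"
  names(cls) <- seg$letters
  seg$variance_class <- cls
  seg
}

#' Adjacency graph of segmentation clusters
#'
#' Two clusters are adjacent iff some node of one is an 8-neighbor of
#' some node of the other; the result is an undirected simple graph.
#'
#' @param seg a `som_segmentation` (or a plain integer label vector).
#' @param grid the [som_grid()].
#' @return data.frame with character columns `from` and `to` (cluster
#'   letters, `from < to` lexicographically).
#' @export
cluster_adjacency <- function(seg, grid) {
  if (inherits(seg, "som_segmentation")) {
    labels <- seg$letters[seg$cluster]
  } else {
    labels <- as.character(seg)
  }
  if (length(labels) != grid$K)
    stop_somscape("label vector must cover all ", grid$K, " nodes")
  pairs <- character()
  # scan the 4 forward offsets; symmetric pairs come for free
  rc <- node_coords(grid)
  offs <- list(c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  for (off in offs) {
    r2 <- rc[, "row"] + off[1L]; c2 <- rc[, "col"] + off[2L]
    ok <- r2 >= 1L & r2 <= grid$rows & c2 >= 1L & c2 <= grid$cols
    a <- labels[ok]
    b <- labels[node_index(r2[ok], c2[ok], grid)]
    diff <- a != b
    lo <- pmin(a[diff], b[diff]); hi <- pmax(a[diff], b[diff])
    pairs <- c(pairs, paste(lo, hi, sep = "\r"))
  }
  pairs <- sort(unique(pairs))
  parts <- strsplit(pairs, "\r", fixed = TRUE)
  data.frame(from = vapply(parts, `[[`, character(1L), 1L),
             to = vapply(parts, `[[`, character(1L), 2L),
             stringsAsFactors = FALSE)
}

#' Member nodes of a segmentation cluster
#' @param seg a `som_segmentation`.
#' @param letter cluster letter (e.g. `"A"`).
#' @return integer node indices.
#' @export
cluster_nodes <- function(seg, letter) {
  id <- match(letter, seg$letters)
  if (is.na(id)) stop_somscape("unknown cluster letter '", letter, "'")
  which(seg$cluster == id)
}
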