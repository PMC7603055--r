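#' Capacity network over segmentation clusters
#'
#' Turns the cluster adjacency graph into a weighted "capacity" network
#' for trajectory extraction. The raw weight of an edge is the
#' cumulative mean signed-log (loglogFC) value of the two adjacent
#' clusters in a lineage portrait (typically the mean portrait over all
#' cells of the lineage: stem, progenitors and the target tissue).
#' Because cluster means can be negative, all capacities are shifted by
#' `-2 * min(cluster means)` so they are non-negative while preserving
#' their ordering: `capacity(c1, c2) = m(c1) + m(c2) - 2 * min_c m(c)`.
#'
#' @param seg a `som_segmentation`.
#' @param lineage_portrait a `som_portrait` on the same grid, normally
#'   on the `"loglogfc"` scale.
#' @return a `capacity_graph`: `nodes` (cluster letters), `edges`
#'   (data.frame `from`, `to`, `capacity`) and the per-cluster means.
#' @export
build_capacity_graph <- function(seg, lineage_portrait) {
  if (!identical(seg$grid[c("rows", "cols")],
                 lineage_portrait$grid[c("rows", "cols")]))
    stop_somscape("segmentation and portrait are on different grids")
  m <- vapply(seq_len(seg$k), function(c)
    mean(lineage_portrait$values[seg$cluster == c]), numeric(1L))
  names(m) <- seg$letters
  adj <- seg$adjacency %||% cluster_adjacency(seg, seg$grid)
  shift <- -2 * min(m)
  edges <- data.frame(from = adj$from, to = adj$to,
                      capacity = m[adj$from] + m[adj$to] + shift,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = seg$letters, edges = edges, cluster_means = m),
            class = "capacity_graph")
}

#' Construct a capacity graph from explicit edges
#' @param nodes character vector of node names.
#' @param edges data.frame with `from`, `to`, `capacity` (>= 0).
#' @return a `capacity_graph`.
#' @export
capacity_graph <- function(nodes, edges) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (!all(c(edges$from, edges$to) %in% nodes))
    stop_somscape("edge endpoints must be listed in 'nodes'")
  if (any(edges$from == edges$to)) stop_somscape("self-loops not allowed")
  if (any(!is.finite(edges$capacity) | edges$capacity < 0))
    stop_somscape("capacities must be finite and >= 0")
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  if (anyDuplicated(key)) stop_somscape("duplicated edges")
  structure(list(nodes = nodes, edges = edges, cluster_means = NULL),
            class = "capacity_graph")
}

adjacency_list <- function(g) {
  adj <- stats::setNames(vector("list", length(g$nodes)), g$nodes)
  for (i in seq_len(nrow(g$edges))) {
    f <- g$edges$from[i]; t <- g$edges$to[i]; cap <- g$edges$capacity[i]
    adj[[f]] <- rbind(adj[[f]], data.frame(to = t, capacity = cap))
    adj[[t]] <- rbind(adj[[t]], data.frame(to = f, capacity = cap))
  }
  adj
}

new_trajectory <- function(path, score, per_step, method,
                           element_nodes = NULL) {
  structure(list(path = path, score = score,
                 per_step_expression = per_step, method = method,
                 element_nodes = element_nodes),
            class = "gene_trajectory")
}

#' @export
print.gene_trajectory <- function(x, ...) {
  cat(sprintf("<gene_trajectory> [%s] %s, score %.4g\n", x$method,
              paste(x$path, collapse = " -> "), x$score))
  invisible(x)
}

#' Maximum-capacity (widest) gene-state path
#'
#' Connects a source cluster (e.g. the stemness spot) to a sink cluster
#' (a differentiated-tissue spot) along the edges providing the maximum
#' cumulative weights: the returned path maximizes the minimum edge
#' capacity (the bottleneck), computed with a max-min variant of
#' Dijkstra's relaxation. Among all widest paths the one with the
#' largest capacity sum is chosen, remaining ties broken by
#' lexicographic node order.
#'
#' @param g a `capacity_graph`.
#' @param source,sink distinct node names in `g`.
#' @return a `gene_trajectory` with `method = "maxflow"`, `score` the
#'   bottleneck capacity and per-step cluster mean expression when the
#'   graph carries cluster means.
#' @export
max_capacity_path <- function(g, source, sink) {
  check_endpoints(g, source, sink)
  adj <- adjacency_list(g)
  width <- stats::setNames(rep(-Inf, length(g$nodes)), g$nodes)
  width[source] <- Inf
  done <- stats::setNames(rep(FALSE, length(g$nodes)), g$nodes)
  while (TRUE) {
    open <- names(width)[!done & width > -Inf]
    if (length(open) == 0L) break
    u <- open[which.max(width[open])]
    done[u] <- TRUE
    if (u == sink) break
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (i in seq_len(nrow(nb))) {
      v <- nb$to[i]
      w <- min(width[u], nb$capacity[i])
      if (w > width[v]) width[v] <- w
    }
  }
  if (!is.finite(width[sink]) || width[sink] == -Inf)
    stop_somscape("clusters '", source, "' and '", sink,
                  "' are disconnected in the capacity graph")
  bottleneck <- unname(width[sink])
  # all widest paths live in the subgraph of edges with capacity >= W*;
  # pick the maximum-sum simple path there (tie: lexicographic). A
  # Dijkstra-built widest path seeds the search so the branch-and-bound
  # can be budgeted on large cluster networks without losing validity.
  keep <- g$edges$capacity >= bottleneck - 1e-12
  sub <- list(nodes = g$nodes, edges = g$edges[keep, , drop = FALSE])
  seed_path <- widest_path_dijkstra(sub, source, sink)
  best <- best_sum_path(sub, source, sink, seed_path = seed_path,
                        budget = 2e5)
  per_step <- if (!is.null(g$cluster_means)) unname(g$cluster_means[best$path])
  new_trajectory(best$path, bottleneck, per_step, "maxflow")
}

#' Maximum cumulative-capacity gene-state path
#'
#' The alternative reading of "maximum cumulative weights": the simple
#' path whose capacity sum is maximal. This is a longest-simple-path
#' variant, solved exactly by branch-and-bound, so the graph size is
#' capped by `node_budget`.
#'
#' @param g a `capacity_graph`.
#' @param source,sink distinct node names.
#' @param node_budget refuse graphs with more nodes than this
#'   (default 40); use [max_capacity_path()] for larger networks.
#' @return a `gene_trajectory` with `method = "sumpath"` and `score` the
#'   capacity sum; ties prefer the larger bottleneck, then lexicographic
#'   order.
#' @export
max_sum_path <- function(g, source, sink, node_budget = 40L) {
  check_endpoints(g, source, sink)
  if (length(g$nodes) > node_budget)
    stop_somscape("graph has ", length(g$nodes), " nodes > node_budget (",
                  node_budget, "); use max_capacity_path() instead")
  best <- best_sum_path(g, source, sink)
  if (is.null(best$path))
    stop_somscape("clusters '", source, "' and '", sink,
                  "' are disconnected in the capacity graph")
  per_step <- if (!is.null(g$cluster_means)) unname(g$cluster_means[best$path])
  new_trajectory(best$path, best$sum, per_step, "sumpath")
}

check_endpoints <- function(g, source, sink) {
  if (!source %in% g$nodes) stop_somscape("unknown source '", source, "'")
  if (!sink %in% g$nodes) stop_somscape("unknown sink '", sink, "'")
  if (identical(source, sink)) stop_somscape("source and sink must differ")
}

# one widest (max-bottleneck) path via max-min Dijkstra with predecessors
widest_path_dijkstra <- function(g, source, sink) {
  adj <- adjacency_list(g)
  width <- stats::setNames(rep(-Inf, length(g$nodes)), g$nodes)
  pred <- stats::setNames(rep(NA_character_, length(g$nodes)), g$nodes)
  width[source] <- Inf
  done <- stats::setNames(rep(FALSE, length(g$nodes)), g$nodes)
  while (TRUE) {
    open <- names(width)[!done & width > -Inf]
    if (length(open) == 0L) break
    u <- open[which.max(width[open])]
    done[u] <- TRUE
    if (u == sink) break
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (i in seq_len(nrow(nb))) {
      v <- nb$to[i]
      w <- min(width[u], nb$capacity[i])
      if (w > width[v]) { width[v] <- w; pred[v] <- u }
    }
  }
  if (!is.finite(width[sink])) return(NULL)
  path <- sink
  while (path[1L] != source) path <- c(pred[path[1L]], path)
  unname(path)
}

path_sum_bottleneck <- function(g, path) {
  key <- paste(pmin(g$edges$from, g$edges$to), pmax(g$edges$from, g$edges$to))
  caps <- stats::setNames(g$edges$capacity, key)
  steps <- paste(pmin(path[-length(path)], path[-1L]),
                 pmax(path[-length(path)], path[-1L]))
  c(sum = sum(caps[steps]), bottleneck = min(caps[steps]))
}

# exact max-sum simple path via DFS with branch-and-bound;
# ties: larger bottleneck, then lexicographically smaller path.
# A seed path (if given) initializes the incumbent, so truncating the
# search at `budget` DFS expansions still returns a valid path.
best_sum_path <- function(g, source, sink, seed_path = NULL, budget = Inf) {
  adj <- adjacency_list(g)
  caps_sorted <- sort(g$edges$capacity, decreasing = TRUE)
  best <- list(path = NULL, sum = -Inf, bottleneck = -Inf)
  if (!is.null(seed_path)) {
    sb <- path_sum_bottleneck(g, seed_path)
    best <- list(path = seed_path, sum = unname(sb["sum"]),
                 bottleneck = unname(sb["bottleneck"]))
  }
  expansions <- 0L
  n <- length(g$nodes)

  better <- function(sum, bottleneck, path) {
    if (sum > best$sum + 1e-12) return(TRUE)
    if (sum < best$sum - 1e-12) return(FALSE)
    if (bottleneck > best$bottleneck + 1e-12) return(TRUE)
    if (bottleneck < best$bottleneck - 1e-12) return(FALSE)
    # lexicographic comparison of node sequences
    old <- best$path
    for (i in seq_len(min(length(path), length(old)))) {
      if (path[i] < old[i]) return(TRUE)
      if (path[i] > old[i]) return(FALSE)
    }
    length(path) < length(old)
  }

  visited <- stats::setNames(rep(FALSE, n), g$nodes)
  dfs <- function(u, path, sum, bottleneck) {
    expansions <<- expansions + 1L
    if (expansions > budget) return(invisible())
    if (u == sink) {
      if (better(sum, bottleneck, path))
        best <<- list(path = path, sum = sum, bottleneck = bottleneck)
      return(invisible())
    }
    # optimistic bound: add the globally largest remaining edge weights
    room <- n - length(path)
    bound <- sum + sum(caps_sorted[seq_len(min(room, length(caps_sorted)))])
    if (bound < best$sum - 1e-12) return(invisible())
    nb <- adj[[u]]
    if (is.null(nb)) return(invisible())
    ord <- order(nb$capacity, decreasing = TRUE)
    for (i in ord) {
      v <- nb$to[i]
      if (visited[v]) next
      visited[v] <<- TRUE
      dfs(v, c(path, v), sum + nb$capacity[i],
          min(bottleneck, nb$capacity[i]))
      visited[v] <<- FALSE
    }
  }
  visited[source] <- TRUE
  dfs(source, source, 0, Inf)
  best
}

#' Topographic least-cost path on a height portrait
#'
#' Interprets a portrait as elevation (typically the difference portrait
#' stem mean minus tissue mean, the package's rendering of a Waddington
#' landscape) and finds the least-cost path between two grid nodes.
#' Heights are rescaled to `h'(v) = h(v) - min(h) + 1e-6` and the cost
#' of a step between 8-neighbors is the geometric step length (1 or
#' sqrt(2)) times the mean rescaled height of its endpoints, so the path
#' runs downhill along valleys.
#'
#' @param height a `som_portrait` used as elevation.
#' @param source,sink node indices (row-major, 1-based) or length-2
#'   `(row, col)` vectors.
#' @return a `gene_trajectory` with `method = "topographic"`, `path` the
#'   node index sequence, `score` the total cost and per-step original
#'   heights.
#' @export
topographic_path <- function(height, source, sink) {
  grid <- height$grid
  source <- as_node_index(source, grid)
  sink <- as_node_index(sink, grid)
  h <- height$values - min(height$values) + 1e-6
  if (source == sink)
    return(new_trajectory(source, 0,
                          height$values[source], "topographic",
                          element_nodes = as.list(source)))
  el <- grid_edge_list(grid, h)
  ig <- igraph::graph_from_data_frame(el, directed = FALSE,
                                      vertices = data.frame(name = as.character(seq_len(grid$K))))
  sp <- igraph::shortest_paths(ig, from = as.character(source),
                               to = as.character(sink),
                               weights = igraph::E(ig)$weight,
                               output = "both", algorithm = "dijkstra")
  path <- as.integer(names(sp$vpath[[1L]]))
  cost <- sum(igraph::E(ig)$weight[as.integer(sp$epath[[1L]])])
  new_trajectory(path, cost, height$values[path], "topographic",
                 element_nodes = as.list(path))
}

# weighted 8-neighbor edge list: weight = step length * mean endpoint height
grid_edge_list <- function(grid, h) {
  rc <- node_coords(grid)
  offs <- list(c(0L, 1L, 1), c(1L, -1L, sqrt(2)), c(1L, 0L, 1),
               c(1L, 1L, sqrt(2)))
  from <- integer(); to <- integer(); w <- numeric()
  for (off in offs) {
    r2 <- rc[, "row"] + off[1L]; c2 <- rc[, "col"] + off[2L]
    ok <- r2 >= 1L & r2 <= grid$rows & c2 >= 1L & c2 <= grid$cols
    a <- which(ok)
    b <- node_index(r2[ok], c2[ok], grid)
    from <- c(from, a); to <- c(to, b)
    w <- c(w, off[3L] * (h[a] + h[b]) / 2)
  }
  data.frame(from = as.character(from), to = as.character(to), weight = w)
}

as_node_index <- function(x, grid) {
  if (length(x) == 2L) x <- node_index(x[1L], x[2L], grid)
  x <- as.integer(x)
  if (is.na(x) || x < 1L || x > grid$K)
    stop_somscape("node index out of range 1..", grid$K)
  x
}

#' Expression profile along a trajectory
#'
#' Tabulates how the expression of every path element evolves across an
#' ordered series of portraits (e.g. pseudotime-stage mean portraits):
#' entry `(i, t)` is the mean value of path element i's member nodes in
#' portrait t. Cluster paths need the segmentation to resolve members.
#'
#' @param traj a `gene_trajectory`.
#' @param portraits_along_pt ordered list of `som_portrait` objects.
#' @param seg the `som_segmentation` behind a cluster path (ignored for
#'   node paths, which carry their own elements).
#' @return numeric matrix, path elements x stages, dimnames set from the
#'   path and portrait subjects.
#' @export
trajectory_profile <- function(traj, portraits_along_pt, seg = NULL) {
  grid <- portraits_along_pt[[1L]]$grid
  elements <- traj$element_nodes
  if (is.null(elements)) {
    if (is.null(seg))
      stop_somscape("cluster trajectories need 'seg' to resolve member nodes")
    elements <- lapply(traj$path, function(l) cluster_nodes(seg, l))
  }
  out <- vapply(portraits_along_pt, function(p) {
    if (!identical(p$grid[c("rows", "cols")], grid[c("rows", "cols")]))
      stop_somscape("portraits are on different grids")
    vapply(elements, function(nodes) mean(p$values[nodes]), numeric(1L))
  }, numeric(length(elements)))
  out <- matrix(out, nrow = length(elements))
  dimnames(out) <- list(as.character(traj$path),
                        vapply(portraits_along_pt, function(p)
                          as.character(p$subject), character(1L)))
  out
}
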