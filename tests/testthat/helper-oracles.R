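# independent reference implementations used as oracles

# all simple paths between source and sink by plain DFS on an edge list
oracle_simple_paths <- function(g, source, sink) {
  adj <- list()
  for (i in seq_len(nrow(g$edges))) {
    f <- g$edges$from[i]; t <- g$edges$to[i]; cap <- g$edges$capacity[i]
    adj[[f]] <- rbind(adj[[f]], data.frame(to = t, cap = cap))
    adj[[t]] <- rbind(adj[[t]], data.frame(to = f, cap = cap))
  }
  paths <- list()
  walk <- function(u, path, caps) {
    if (u == sink) {
      paths[[length(paths) + 1L]] <<- list(path = path, caps = caps)
      return(invisible())
    }
    nb <- adj[[u]]
    if (is.null(nb)) return(invisible())
    for (i in seq_len(nrow(nb))) {
      v <- nb$to[i]
      if (v %in% path) next
      walk(v, c(path, v), c(caps, nb$cap[i]))
    }
  }
  walk(source, source, numeric())
  paths
}

# pick the best path under (primary, tie1, tie2 = lexicographic) rules
oracle_pick <- function(paths, primary, tie1) {
  stopifnot(length(paths) > 0L)
  score <- vapply(paths, primary, numeric(1L))
  best <- paths[score >= max(score) - 1e-12]
  if (length(best) > 1L) {
    s2 <- vapply(best, tie1, numeric(1L))
    best <- best[s2 >= max(s2) - 1e-12]
  }
  if (length(best) > 1L) {
    keys <- vapply(best, function(p) paste(p$path, collapse = "\r"),
                   character(1L))
    best <- best[order(keys, vapply(best, function(p) length(p$path),
                                    integer(1L)))]
  }
  best[[1L]]
}

oracle_widest <- function(g, source, sink) {
  paths <- oracle_simple_paths(g, source, sink)
  if (length(paths) == 0L) return(NULL)
  oracle_pick(paths, function(p) min(p$caps), function(p) sum(p$caps))
}

oracle_max_sum <- function(g, source, sink) {
  paths <- oracle_simple_paths(g, source, sink)
  if (length(paths) == 0L) return(NULL)
  oracle_pick(paths, function(p) sum(p$caps), function(p) min(p$caps))
}

# independent Dijkstra over an explicit weighted edge list (O(V^2) scan)
oracle_dijkstra <- function(n_nodes, edges, source, sink) {
  dist <- rep(Inf, n_nodes)
  prev <- rep(NA_integer_, n_nodes)
  done <- rep(FALSE, n_nodes)
  dist[source] <- 0
  repeat {
    open <- which(!done & is.finite(dist))
    if (length(open) == 0L) break
    u <- open[which.min(dist[open])]
    done[u] <- TRUE
    if (u == sink) break
    rows <- which(edges$from == u | edges$to == u)
    for (i in rows) {
      v <- if (edges$from[i] == u) edges$to[i] else edges$from[i]
      alt <- dist[u] + edges$weight[i]
      if (alt < dist[v] - 1e-15) { dist[v] <- alt; prev[v] <- u }
    }
  }
  path <- sink
  while (!is.na(prev[path[1L]])) path <- c(prev[path[1L]], path)
  list(cost = dist[sink], path = path)
}

# 8-neighbor weighted edge list for a height vector on a grid (costs as
# in the topographic model), built independently of the package
oracle_grid_edges <- function(rows, cols, h_raw) {
  h <- h_raw - min(h_raw) + 1e-6
  from <- integer(); to <- integer(); weight <- numeric()
  id <- function(r, c) (r - 1L) * cols + c
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    for (dr in 0:1) for (dc in -1:1) {
      if (dr == 0L && dc != 1L) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1L || r2 > rows || c2 < 1L || c2 > cols) next
      len <- sqrt(dr^2 + dc^2)
      from <- c(from, id(r, c)); to <- c(to, id(r2, c2))
      weight <- c(weight, len * (h[id(r, c)] + h[id(r2, c2)]) / 2)
    }
  }
  data.frame(from = from, to = to, weight = weight)
}

# brute-force nearest prototype
oracle_bmu <- function(prototypes, profile) {
  d2 <- colSums((t(prototypes) - profile)^2)
  which.min(d2)
}

# exact hypergeometric upper tail by direct enumeration of the pmf
oracle_hyper_tail <- function(overlap, n_set, n_universe, n_module) {
  i <- overlap:min(n_set, n_module)
  sum(choose(n_set, i) * choose(n_universe - n_set, n_module - i)) /
    choose(n_universe, n_module)
}

# flood-fill 8-connected components over a logical membership vector
oracle_components <- function(member, rows, cols) {
  lab <- rep(0L, rows * cols)
  cur <- 0L
  id <- function(r, c) (r - 1L) * cols + c
  for (s in which(member)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    while (length(stack) > 0L) {
      v <- stack[1L]; stack <- stack[-1L]
      r <- (v - 1L) %/% cols + 1L; c <- (v - 1L) %% cols + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1L || r2 > rows || c2 < 1L || c2 > cols) next
        w <- id(r2, c2)
        if (member[w] && lab[w] == 0L) { lab[w] <- cur; stack <- c(stack, w) }
      }
    }
  }
  lab
}
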