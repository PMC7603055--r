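# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Letter labels for expression modules
#'
#' Modules are labeled `"A"`..`"Z"`, then `"A1"`, `"B1"`, ... so that a
#' 32-cluster segmentation runs from `"A"` to `"F1"`.
#'
#' @param k number of labels required.
#' @return character vector of length `k`.
#' @export
cluster_letters <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  pool <- LETTERS
  i <- 1L
  while (length(pool) < k) {
    pool <- c(pool, paste0(LETTERS, i))
    i <- i + 1L
  }
  pool[seq_len(k)]
}

# row-major node linearization; rows/cols are 1-based
node_index <- function(row, col, grid) {
  (row - 1L) * grid$cols + col
}

node_rc <- function(idx, grid) {
  idx <- as.integer(idx)
  cbind(row = (idx - 1L) %/% grid$cols + 1L,
        col = (idx - 1L) %% grid$cols + 1L)
}

# K x 2 matrix of (row, col) for every node, in row-major order
node_coords <- function(grid) {
  cbind(row = rep(seq_len(grid$rows), each = grid$cols),
        col = rep(seq_len(grid$cols), times = grid$rows))
}

# 8-neighborhood (Moore) of one node; returns integer node indices
neighbors8 <- function(idx, grid) {
  rc <- node_rc(idx, grid)
  dr <- rep(-1:1, each = 3L)
  dc <- rep(-1:1, times = 3L)
  keep <- !(dr == 0L & dc == 0L)
  r <- rc[1L, "row"] + dr[keep]
  c <- rc[1L, "col"] + dc[keep]
  ok <- r >= 1L & r <= grid$rows & c >= 1L & c <= grid$cols
  node_index(r[ok], c[ok], grid)
}

# squared Euclidean distances between rows of x and rows of y
cross_dist2 <- function(x, y) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}

stop_somscape <- function(...) stop(..., call. = FALSE)
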