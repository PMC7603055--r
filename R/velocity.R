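#' Fit per-gene degradation ratios and RNA velocities
#'
#' Under first-order splicing/degradation kinetics the unspliced and
#' spliced abundances of a gene satisfy `u = gamma * s` at steady state
#' (with the splicing rate absorbed into `gamma`). For each gene the
#' slope `gamma` is fitted by least squares through the origin on the
#' cells in the extreme quantiles of spliced abundance (both ends, where
#' cells are closest to their steady states), and the velocity of every
#' cell is the residual `v = u - gamma * s`: positive when transcription
#' outruns degradation (induction), negative during repression.
#'
#' @param s,u [expr_matrix()] objects with layers `"spliced"` and
#'   `"unspliced"`, same genes and cells.
#' @param quantile fraction of cells taken from each end of the spliced
#'   distribution for the steady-state fit (default 0.05).
#' @return a `gene_kinetics`: `gamma` (named), `velocity` (genes x
#'   cells; `NA` rows for unfittable genes), `fittable` (logical),
#'   `fit_quantile`.
#' @export
fit_gamma <- function(s, u, quantile = 0.05) {
  check_layer(s, c("spliced", "raw"))
  check_layer(u, c("unspliced", "raw"))
  S <- as_plain_matrix(s); U <- as_plain_matrix(u)
  if (!identical(dim(S), dim(U)) ||
      !identical(rownames(S), rownames(U)) ||
      !identical(colnames(S), colnames(U)))
    stop_somscape("spliced and unspliced matrices must share genes and cells")
  if (quantile <= 0 || quantile >= 0.5)
    stop_somscape("'quantile' must be in (0, 0.5)")
  n_genes <- nrow(S)
  gamma <- stats::setNames(rep(NA_real_, n_genes), rownames(S))
  V <- matrix(NA_real_, n_genes, ncol(S), dimnames = dimnames(S))
  for (g in seq_len(n_genes)) {
    sg <- S[g, ]; ug <- U[g, ]
    lo <- stats::quantile(sg, quantile, names = FALSE)
    hi <- stats::quantile(sg, 1 - quantile, names = FALSE)
    idx <- which(sg <= lo | sg >= hi)
    ss2 <- sum(sg[idx]^2)
    if (ss2 <= 0) next   # all-zero spliced signal: unfittable
    gamma[g] <- sum(ug[idx] * sg[idx]) / ss2
    V[g, ] <- ug - gamma[g] * sg
  }
  structure(list(gamma = gamma, velocity = V,
                 fittable = !is.na(gamma), fit_quantile = quantile),
            class = "gene_kinetics")
}

#' @export
print.gene_kinetics <- function(x, ...) {
  cat(sprintf("<gene_kinetics> %d genes (%d fittable), %d cells, quantile %.3g\n",
              length(x$gamma), sum(x$fittable), ncol(x$velocity),
              x$fit_quantile))
  invisible(x)
}

#' Metagene velocity vectors
#'
#' The velocity of a metagene is the multidimensional vector whose
#' components are the cell-wise mRNA velocities of all member genes,
#' averaged: node vector = arithmetic mean over the velocity rows of the
#' fittable genes assigned to that node. Nodes with no fittable member
#' gene carry a zero vector and are flagged.
#'
#' @param model a trained `som_model`.
#' @param kin a [fit_gamma()] result; kinetics genes must be a subset of
#'   the model's genes.
#' @return K x cells numeric matrix with attribute `has_genes` (logical
#'   per node).
#' @export
metagene_velocity <- function(model, kin) {
  genes <- rownames(kin$velocity)
  missing <- setdiff(genes, names(model$bmu))
  if (length(missing) > 0L)
    stop_somscape("kinetics contain genes not in the model: ",
                  paste(utils::head(missing, 3L), collapse = ", "))
  K <- model$grid$K
  n_cells <- ncol(model$prototypes)
  out <- matrix(0, K, n_cells,
                dimnames = list(NULL, colnames(model$prototypes)))
  has <- rep(FALSE, K)
  usable <- genes[kin$fittable[genes]]
  if (length(usable) > 0L) {
    node <- model$bmu[usable]
    sums <- rowsum(kin$velocity[usable, , drop = FALSE], group = node)
    counts <- table(node)
    idx <- as.integer(rownames(sums))
    out[idx, ] <- sums / as.integer(counts[rownames(sums)])
    has[idx] <- TRUE
  }
  attr(out, "has_genes") <- has
  out
}

#' Project metagene velocities onto the grid as a 2-D vector field
#'
#' A metagene's high-dimensional velocity vector is turned into a grid
#' arrow by asking which neighboring expression state it points toward:
#' for node m and each 8-neighbor n, the weight is the Pearson
#' correlation between m's velocity vector and the prototype difference
#' `p_n - p_m`; the arrow is the positively-weighted mean of the unit
#' directions to the neighbors, normalized to unit length. The arrow is
#' zero where the node has no member velocity or no positive
#' correlation, so the field vanishes at local attractors of maximum
#' transcription.
#'
#' @param model a trained `som_model`.
#' @param node_velocities a [metagene_velocity()] result.
#' @param zero_tol velocity vectors with root-mean-square magnitude
#'   below this are treated as exactly zero (default 1e-10), so exact
#'   steady-state data yields a vanishing field instead of arrows built
#'   from rounding noise.
#' @return a `velocity_field`: `grid`, `arrows` (K x 2, columns `dx`
#'   along grid columns and `dy` along rows; each arrow is the
#'   positive-correlation-weighted mean of the unit directions to the
#'   neighbors, so its length is at most 1 and shrinks where opposing
#'   pulls balance), `node_velocity`, and `attractors`/`basin` slots
#'   filled by [detect_attractors()] and [velocity_trajectories()].
#' @export
grid_vector_field <- function(model, node_velocities, zero_tol = 1e-10) {
  grid <- model$grid
  K <- grid$K
  if (nrow(node_velocities) != K)
    stop_somscape("node velocities do not match the grid (", K, " nodes)")
  P <- model$prototypes
  rc <- node_coords(grid)
  arrows <- matrix(0, K, 2L, dimnames = list(NULL, c("dx", "dy")))
  for (m in seq_len(K)) {
    v <- node_velocities[m, ]
    if (sqrt(mean(v^2)) < zero_tol || stats::sd(v) == 0) next
    acc <- c(0, 0)
    wsum <- 0
    for (n in neighbors8(m, grid)) {
      diff <- P[n, ] - P[m, ]
      if (stats::sd(diff) == 0) next   # correlation undefined: weight 0
      w <- stats::cor(v, diff)
      if (!is.finite(w) || w <= 0) next
      dir <- c(rc[n, "col"] - rc[m, "col"], rc[n, "row"] - rc[m, "row"])
      acc <- acc + w * dir / sqrt(sum(dir^2))
      wsum <- wsum + w
    }
    # convex combination of unit directions: |arrow| <= 1, and it
    # shrinks where opposing pulls balance (attractor kernels)
    if (wsum > 0) arrows[m, ] <- acc / wsum
  }
  structure(list(grid = grid, arrows = arrows,
                 node_velocity = node_velocities,
                 attractors = NULL, basin = NULL, watershed = NULL),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  nz <- sum(rowSums(x$arrows^2) > 0)
  cat(sprintf("<velocity_field> %d x %d grid, %d non-zero arrows",
              x$grid$rows, x$grid$cols, nz))
  if (!is.null(x$attractors))
    cat(sprintf(", %d attractors", length(x$attractors)))
  cat("\n")
  invisible(x)
}

#' Detect attractor nodes of the velocity field
#'
#' RNA velocity vanishes in the kernel area of maximum expression:
#' attractors are nodes whose arrow magnitude is below `tol` and whose
#' summary expression is a strict local maximum over the 8-neighborhood
#' (at least one neighbor strictly lower, none higher — flat plateaus
#' are not maxima).
#'
#' @param field a [grid_vector_field()] result.
#' @param summary_expression a `som_portrait` of summary expression
#'   (e.g. the maximum or mean over group portraits).
#' @param tol arrow-magnitude tolerance (default 0.3: arrows are convex
#'   combinations of unit vectors, so kernels where neighbor pulls
#'   balance have short arrows even when member velocities are noisy).
#' @return the field with `attractors` (integer node set) attached.
#' @export
detect_attractors <- function(field, summary_expression, tol = 0.3) {
  grid <- field$grid
  if (!identical(grid[c("rows", "cols")],
                 summary_expression$grid[c("rows", "cols")]))
    stop_somscape("field and portrait are on different grids")
  h <- summary_expression$values
  speed <- sqrt(rowSums(field$arrows^2))
  att <- integer()
  for (m in seq_len(grid$K)) {
    if (speed[m] >= tol) next
    nb <- neighbors8(m, grid)
    if (all(h[m] >= h[nb]) && any(h[m] > h[nb])) att <- c(att, m)
  }
  field$attractors <- att
  field
}

#' Integrate velocity trajectories and label basins
#'
#' Follows the bilinearly-interpolated arrow field from each start node
#' by forward Euler steps until the local arrow vanishes, the grid
#' boundary is reached, or `max_steps` elapse. Each start is assigned to
#' the attractor nearest its endpoint (its basin); nodes whose
#' 8-neighborhood flows into more than one attractor mark the watershed
#' boundaries separating the basins.
#'
#' @param field a [detect_attractors()] result (attractors required for
#'   basin labeling; without them basins are `NA`).
#' @param starts integer node indices to integrate from (default: all
#'   nodes).
#' @param step Euler step in grid units (default 0.5).
#' @param max_steps iteration cap (default 200).
#' @param tol arrow-magnitude termination tolerance (default 1e-8).
#' @return the field with `basin` (per start node; `NA` for non-starts
#'   or unresolvable) and `watershed` (logical per node) attached, plus
#'   `trajectories`: a list of `gene_trajectory` objects (method
#'   `"velocity"`) holding the visited node sequences.
#' @export
velocity_trajectories <- function(field, starts = NULL, step = 0.5,
                                  max_steps = 200L, tol = 1e-8) {
  grid <- field$grid
  starts <- starts %||% seq_len(grid$K)
  rc <- node_coords(grid)
  dx <- matrix(field$arrows[, "dx"], grid$rows, grid$cols, byrow = TRUE)
  dy <- matrix(field$arrows[, "dy"], grid$rows, grid$cols, byrow = TRUE)
  att <- field$attractors
  att_rc <- if (length(att) > 0L) node_rc(att, grid)
  basin <- rep(NA_integer_, grid$K)
  trajectories <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    x <- rc[s, "col"]; y <- rc[s, "row"]
    visited <- s
    for (it in seq_len(max_steps)) {
      v <- bilinear_arrow(dx, dy, x, y)
      if (sqrt(sum(v^2)) < tol) break
      x <- x + step * v[1L]; y <- y + step * v[2L]
      if (x < 1 || x > grid$cols || y < 1 || y > grid$rows) {
        x <- min(max(x, 1), grid$cols); y <- min(max(y, 1), grid$rows)
        visited <- c(visited,
                     as.integer(node_index(round(y), round(x), grid)))
        break
      }
      visited <- c(visited, as.integer(node_index(round(y), round(x), grid)))
    }
    visited <- visited[c(TRUE, diff(visited) != 0L)]
    trajectories[[i]] <- new_trajectory(visited, length(visited) - 1L,
                                        NULL, "velocity",
                                        element_nodes = as.list(visited))
    if (length(att) > 0L) {
      d2 <- (att_rc[, "col"] - x)^2 + (att_rc[, "row"] - y)^2
      basin[s] <- att[which.min(d2)]
    }
  }
  watershed <- rep(FALSE, grid$K)
  if (length(att) > 0L) {
    for (m in seq_len(grid$K)) {
      nb <- c(m, neighbors8(m, grid))
      b <- unique(basin[nb])
      b <- b[!is.na(b)]
      if (length(b) > 1L) watershed[m] <- TRUE
    }
  }
  field$basin <- basin
  field$watershed <- watershed
  field$trajectories <- trajectories
  field
}

#' Mean arrow projection toward a target node
#'
#' Quantifies how strongly the velocity field converges on a spot
#' kernel: over all nodes with a non-zero arrow within `radius` grid
#' units of the target (the spot's approach zone, i.e. the transition
#' region around it), each arrow is projected onto the unit vector from
#' its node toward the target, and the mean projection is returned.
#' Values near +1 mean the zone flows into the target (an attractor of
#' the differentiation flow); values near 0 or below mean it does not.
#'
#' Note the projected field is an attractor field: arrows converge on
#' expression maxima, with watersheds between basins, so directional
#' claims are best evaluated per attractor with this measure rather
#' than by averaging arrows over a region between two attractors
#' (which cancels by construction).
#'
#' @param field a [grid_vector_field()] result.
#' @param target node index (row-major) of the spot kernel.
#' @param radius zone radius in grid units (default 5).
#' @return list with `mean_projection` and `n_arrows`.
#' @export
arrow_projection_toward <- function(field, target, radius = 5) {
  grid <- field$grid
  target <- as_node_index(target, grid)
  rc <- node_coords(grid)
  d <- sqrt((rc[, "row"] - rc[target, "row"])^2 +
              (rc[, "col"] - rc[target, "col"])^2)
  zone <- which(d > 0 & d <= radius)
  nonzero <- sqrt(rowSums(field$arrows[zone, , drop = FALSE]^2)) > 0
  zone <- zone[nonzero]
  if (length(zone) == 0L)
    return(list(mean_projection = NA_real_, n_arrows = 0L))
  dirs <- cbind((rc[target, "row"] - rc[zone, "row"]) / d[zone],
                (rc[target, "col"] - rc[zone, "col"]) / d[zone])
  proj <- field$arrows[zone, "dy"] * dirs[, 1L] +
    field$arrows[zone, "dx"] * dirs[, 2L]
  list(mean_projection = mean(proj), n_arrows = length(zone))
}

# bilinear interpolation of the arrow components at continuous (x, y)
bilinear_arrow <- function(dx, dy, x, y) {
  nr <- nrow(dx); nc <- ncol(dx)
  x0 <- floor(x); y0 <- floor(y)
  x0 <- min(max(x0, 1L), nc - 1L); y0 <- min(max(y0, 1L), nr - 1L)
  fx <- x - x0; fy <- y - y0
  fx <- min(max(fx, 0), 1); fy <- min(max(fy, 0), 1)
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy; w11 <- fx * fy
  c(w00 * dx[y0, x0] + w10 * dx[y0, x0 + 1L] +
      w01 * dx[y0 + 1L, x0] + w11 * dx[y0 + 1L, x0 + 1L],
    w00 * dy[y0, x0] + w10 * dy[y0, x0 + 1L] +
      w01 * dy[y0 + 1L, x0] + w11 * dy[y0 + 1L, x0 + 1L])
}
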