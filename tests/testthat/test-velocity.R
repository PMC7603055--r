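mk_layers <- function(S, U) {
  list(s = expr_matrix(S, "spliced"), u = expr_matrix(U, "unspliced"))
}

test_that("exact steady state recovers gamma and zero velocity", {
  set.seed(3)
  S <- matrix(runif(8 * 20, 1, 10), 8, 20,
              dimnames = list(sprintf("g%d", 1:8), sprintf("c%02d", 1:20)))
  ly <- mk_layers(S, 2 * S)
  kin <- fit_gamma(ly$s, ly$u)
  expect_equal(unname(kin$gamma), rep(2, 8))
  expect_true(all(abs(kin$velocity) < 1e-12))

  # residual arithmetic: v = u - gamma * s
  expect_equal(unname(3 - 2 * 1), 1)
  v_manual <- ly$u["g1", ] - kin$gamma["g1"] * ly$s["g1", ]
  expect_equal(unname(kin$velocity["g1", ]), unname(v_manual))
})

test_that("all-zero spliced genes are flagged unfittable", {
  S <- matrix(c(rep(0, 5), 1:5), 2, 5, byrow = TRUE,
              dimnames = list(c("dead", "ok"), sprintf("c%d", 1:5)))
  U <- matrix(1, 2, 5, dimnames = dimnames(S))
  kin <- fit_gamma(expr_matrix(S, "spliced"), expr_matrix(U, "unspliced"))
  expect_false(kin$fittable["dead"])
  expect_true(kin$fittable["ok"])
  expect_true(all(is.na(kin$velocity["dead", ])))
})

test_that("generator kinetics give positive velocity for induced genes", {
  sim <- generate_differentiation(n_cells = 400, n_genes = 600, seed = 4,
                                  noise_dispersion = NULL)
  kin <- fit_gamma(sim$spliced, sim$unspliced)
  t <- sim$truth$latent_time
  mid <- t > 0.4 & t < 0.7
  frac_pos <- c()
  for (l in 1:2) {
    genes <- names(which(sim$truth$gene_module == paste0("tissue_", l)))
    cells <- names(which(mid & sim$truth$lineage == paste0("tissue_", l)))
    frac_pos <- c(frac_pos, mean(kin$velocity[genes, cells] > 0))
  }
  expect_gte(min(frac_pos), 0.95)
})

test_that("metagene velocities are member-gene means", {
  fx <- medium_fixture()
  kin <- fit_gamma(fx$sim$spliced, fx$sim$unspliced)
  nv <- metagene_velocity(fx$model, kin)
  pm <- population_map(fx$model)
  for (node in sample(which(pm > 0), 5)) {
    genes <- names(fx$model$bmu)[fx$model$bmu == node]
    genes <- genes[kin$fittable[genes]]
    want <- colMeans(kin$velocity[genes, , drop = FALSE])
    expect_equal(unname(nv[node, ]), unname(want))
  }
  empty <- which(pm == 0)
  if (length(empty) > 0) {
    expect_true(all(nv[empty, ] == 0))
    expect_false(any(attr(nv, "has_genes")[empty]))
  }

  # cancellation of opposite member velocities
  P <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("x", "y")))
  m <- manual_model(P, som_grid(2, 2), bmu = c(g1 = 2L, g2 = 2L))
  kin2 <- list(gamma = c(g1 = 1, g2 = 1),
               velocity = rbind(g1 = c(1, -2), g2 = c(-1, 2)),
               fittable = c(g1 = TRUE, g2 = TRUE), fit_quantile = 0.05)
  colnames(kin2$velocity) <- c("x", "y")
  class(kin2) <- "gene_kinetics"
  nv2 <- metagene_velocity(m, kin2)
  expect_true(all(nv2[2L, ] == 0))
})

test_that("arrows point at the neighbor whose profile change matches", {
  set.seed(12)
  g <- som_grid(3, 3)
  # all prototypes identical except the east neighbor of the center, so
  # only that neighbor carries a non-degenerate profile difference
  base <- rnorm(40)
  P <- matrix(rep(base, each = 9), 9, 40,
              dimnames = list(NULL, sprintf("c%02d", 1:40)))
  delta <- rnorm(40)
  P[6L, ] <- P[6L, ] + delta
  m <- manual_model(P, g)
  nv <- matrix(0, 9, 40)
  nv[5L, ] <- 3 * delta          # exactly proportional to (p6 - p5)
  f <- grid_vector_field(m, nv)
  expect_equal(unname(f$arrows[5L, ]), c(1, 0), tolerance = 1e-6)
  expect_true(all(f$arrows[-5L, ] == 0))

  # zero velocity gives zero arrows everywhere
  f0 <- grid_vector_field(m, matrix(0, 9, 40))
  expect_true(all(f0$arrows == 0))
})

test_that("steady-state data yields a vanishing vector field", {
  sim <- generate_differentiation(n_cells = 200, n_genes = 300, seed = 6,
                                  noise_dispersion = NULL,
                                  steady_state = TRUE)
  fx_model <- suppressWarnings(
    train_som(compute_logfc(sim$counts), som_grid(8, 8), epochs = 10,
              seed = 6))
  kin <- fit_gamma(sim$spliced, sim$unspliced)
  nv <- metagene_velocity(fx_model, kin)
  f <- grid_vector_field(fx_model, nv)
  expect_true(all(abs(f$arrows) < 1e-6))
})

test_that("scaling all velocities leaves arrow directions unchanged", {
  fx <- medium_fixture()
  kin <- fit_gamma(fx$sim$spliced, fx$sim$unspliced)
  nv <- metagene_velocity(fx$model, kin)
  f1 <- grid_vector_field(fx$model, nv)
  f2 <- grid_vector_field(fx$model, nv * 7)
  expect_equal(f1$arrows, f2$arrows, tolerance = 1e-10)
})

test_that("attractors are zero-arrow local expression maxima", {
  g <- som_grid(5, 5)
  m <- manual_model(matrix(rnorm(25 * 4), 25, 4), g)
  zero_field <- grid_vector_field(m, matrix(0, 25, 4))
  peak <- rep(0, 25); peak[13L] <- 5
  f <- detect_attractors(zero_field, make_portrait(peak, g))
  expect_identical(f$attractors, 13L)

  # uniform non-zero field: no attractors
  f2 <- zero_field
  f2$arrows <- matrix(rep(c(1, 0), each = 25), 25, 2,
                      dimnames = list(NULL, c("dx", "dy")))
  f2 <- detect_attractors(f2, make_portrait(peak, g))
  expect_length(f2$attractors, 0L)
})

test_that("trajectories integrate the arrow field to its basin", {
  g <- som_grid(5, 5)
  m <- manual_model(matrix(rnorm(100), 25, 4), g)
  f <- grid_vector_field(m, matrix(0, 25, 4))

  # zero field: trajectory stays at the start
  f0 <- velocity_trajectories(f, starts = 7L)
  expect_identical(f0$trajectories[[1L]]$path, 7L)

  # constant eastward arrows: straight run to the boundary
  f$arrows <- matrix(rep(c(1, 0), each = 25), 25, 2,
                     dimnames = list(NULL, c("dx", "dy")))
  fr <- velocity_trajectories(f, starts = 11L, step = 0.5)  # row 3, col 1
  endpoint <- fr$trajectories[[1L]]$path
  endpoint <- endpoint[length(endpoint)]
  expect_identical(endpoint, 15L)                            # row 3, col 5
  rows <- (fr$trajectories[[1L]]$path - 1L) %/% 5L + 1L
  expect_true(all(rows == 3L))
})

test_that("two opposing attractors split the grid into basins", {
  g <- som_grid(5, 7)
  m <- manual_model(matrix(rnorm(35 * 4), 35, 4), g)
  f <- grid_vector_field(m, matrix(0, 35, 4))
  # arrows flow toward the outer columns, vanish on them and mid-grid
  rc <- cbind(rep(1:5, each = 7), rep(1:7, times = 5))
  dx <- ifelse(rc[, 2] %in% 2:3, -1, ifelse(rc[, 2] %in% 5:6, 1, 0))
  f$arrows <- cbind(dx = dx, dy = rep(0, 35))
  expr <- ifelse(rc[, 2] == 1 | rc[, 2] == 7, 1, 0)
  f <- detect_attractors(f, make_portrait(expr, g))
  expect_true(length(f$attractors) >= 2L)
  f <- velocity_trajectories(f, step = 0.5)

  att_cols <- (f$attractors - 1L) %% 7L + 1L
  west <- f$attractors[att_cols == 1L]
  east <- f$attractors[att_cols == 7L]
  left_nodes <- which(rc[, 2] <= 2)
  right_nodes <- which(rc[, 2] >= 6)
  expect_true(all(f$basin[left_nodes] %in% west))
  expect_true(all(f$basin[right_nodes] %in% east))

  # fine-step integration agrees on basin labels away from the watershed
  f_fine <- velocity_trajectories(f, step = 0.05, max_steps = 2000L)
  core <- c(left_nodes, right_nodes)
  expect_identical(f$basin[core], f_fine$basin[core])

  # every non-watershed node with a nonzero arrow has exactly one basin
  nonzero <- sqrt(rowSums(f$arrows^2)) > 0
  resolved <- nonzero & !f$watershed
  expect_true(all(!is.na(f$basin[resolved])))
})

test_that("the field converges on the planted tissue attractors", {
  fx <- landscape_fixture()
  ann <- fx$annotations
  for (ln in c("tissue_1", "tissue_2")) {
    cells <- ann$cell_id[ann$cell_type == ln]
    kernel <- which.max(mean_portrait(fx$model, cells)$values)
    pr <- arrow_projection_toward(fx$field, kernel, radius = 5)
    expect_gt(pr$n_arrows, 5L)
    expect_gt(pr$mean_projection, 0)
  }
})
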