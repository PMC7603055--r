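test_that("identical gene profiles collapse every prototype onto them", {
  v <- c(1, -2, 3, 0.5)
  X <- matrix(rep(v, each = 20), 20, 4,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%d", 1:4)))
  X <- X - rowMeans(X)
  model <- suppressWarnings(
    train_som(expr_matrix(X, "logfc"), som_grid(3, 3), epochs = 10, seed = 1))
  expect_lt(model$quantization_error, 1e-6)
  expect_true(all(abs(sweep(model$prototypes, 2L, X[1L, ])) < 1e-6))
})

test_that("with a vanishing final radius prototypes become block means", {
  # two orthogonal expression programs, equal-sized gene blocks
  v1 <- c(1, 1, -1, -1, 0, 0); v2 <- c(0, 0, 1, 1, -1, -1)
  X <- rbind(matrix(rep(v1, each = 10), 10, 6),
             matrix(rep(v2, each = 10), 10, 6))
  dimnames(X) <- list(sprintf("g%02d", 1:20), sprintf("c%d", 1:6))
  model <- suppressWarnings(
    train_som(expr_matrix(X, "logfc"), som_grid(2, 2), epochs = 15,
              seed = 1, radius_final = 0.01))
  # every gene's BMU prototype equals its own block profile
  for (g in seq_len(20)) {
    p <- model$prototypes[model$bmu[g], ]
    expect_equal(unname(p), unname(X[g, ]), tolerance = 1e-6)
  }
  # and the two blocks land on different nodes
  expect_true(model$bmu[1L] != model$bmu[11L])
})

test_that("training is deterministic given the seed", {
  lf <- compute_logfc(random_counts(60, 12, seed = 7))
  m1 <- train_som(lf, som_grid(4, 4), epochs = 8, seed = 42)
  m2 <- train_som(lf, som_grid(4, 4), epochs = 8, seed = 42)
  expect_identical(m1$prototypes, m2$prototypes)
  expect_identical(m1$bmu, m2$bmu)
})

test_that("quantization error is non-increasing over batch epochs", {
  fx <- medium_fixture()
  expect_true(all(diff(fx$model$qe_history) <= 1e-9))
})

test_that("training rejects NaNs and warns on oversized grids", {
  X <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("c%d", 1:4)))
  Xbad <- X; Xbad[2, 2] <- NaN
  em <- structure(Xbad, layer = "logfc", class = c("expr_matrix", "matrix"))
  expect_error(suppressWarnings(train_som(em, som_grid(2, 2))), "non-finite")
  X0 <- X - rowMeans(X)
  expect_warning(train_som(expr_matrix(X0, "logfc"), som_grid(8, 8),
                           epochs = 2), "sparse")
})

test_that("the default grid carries 60 x 60 = 3600 prototypes", {
  g <- som_grid()
  expect_identical(c(g$rows, g$cols, g$K), c(60L, 60L, 3600L))
  expect_error(som_grid(1, 2), ">= 4")
})

test_that("BMU assignment equals a brute-force nearest-prototype scan", {
  fx <- medium_fixture()
  set.seed(9)
  for (i in 1:100) {
    profile <- rnorm(ncol(fx$model$prototypes))
    expect_identical(assign_bmu(fx$model, profile),
                     oracle_bmu(fx$model$prototypes, profile))
  }
  expect_error(assign_bmu(fx$model, c(1, 2)), "length")
})

test_that("BMU ties break to the lowest row-major node index", {
  P <- rbind(c(0, 0), c(1, 1), c(0, 0), c(5, 5))
  model <- manual_model(P, som_grid(2, 2))
  expect_identical(assign_bmu(model, c(0, 0)), 1L)
  # equidistant between nodes 2 and 4
  expect_identical(assign_bmu(model, c(3, 3)), 2L)
})

test_that("portraits are column slices of the prototype matrix", {
  fx <- medium_fixture()
  cell <- colnames(fx$model$prototypes)[5L]
  p <- portrait_of_cell(fx$model, cell)
  expect_equal(p$values, unname(fx$model$prototypes[, cell]))
  pl <- portrait_of_cell(fx$model, cell, scale = "loglogfc")
  expect_equal(pl$values, loglog_transform(unname(fx$model$prototypes[, cell])))
  expect_error(portrait_of_cell(fx$model, "nope"), "unknown cell")

  zero <- manual_model(matrix(0, 4, 3), som_grid(2, 2))
  expect_true(all(portrait_of_cell(zero, "c01", "loglogfc")$values == 0))
})

test_that("mean portraits average member portraits node-wise", {
  fx <- medium_fixture()
  cells <- colnames(fx$model$prototypes)[c(2, 9, 17, 33, 41)]
  mp <- mean_portrait(fx$model, cells)
  expect_equal(mp$values, unname(rowMeans(fx$model$prototypes[, cells])))

  one <- mean_portrait(fx$model, cells[1L])
  expect_equal(one$values, portrait_of_cell(fx$model, cells[1L])$values)

  # antisymmetric pair cancels
  P <- cbind(a = c(1, -2, 3, 0), b = -c(1, -2, 3, 0))
  m <- manual_model(P, som_grid(2, 2))
  expect_true(all(abs(mean_portrait(m, c("a", "b"))$values) < 1e-12))
  expect_error(mean_portrait(fx$model, character(0)), "nonempty")
})

test_that("population map is the histogram of BMU assignments", {
  fx <- medium_fixture()
  pm <- population_map(fx$model)
  expect_identical(sum(pm), length(fx$model$bmu))
  expect_identical(pm, tabulate(fx$model$bmu, nbins = fx$model$grid$K))

  m <- manual_model(matrix(rnorm(8), 4, 2), som_grid(2, 2),
                    bmu = c(g1 = 3L))
  expect_identical(population_map(m), c(0L, 0L, 1L, 0L))
})

test_that("variance map is the population variance across cells", {
  P <- rbind(c(-1, 1), c(2, 2), c(0, 4), c(1, 3))
  m <- manual_model(P, som_grid(2, 2))
  vm <- variance_map(m)
  expect_equal(vm[1L], 1)        # population variance of (-1, 1)
  expect_equal(vm[2L], 0)        # constant prototype
  expect_equal(vm, apply(P, 1L, function(x) mean(x^2) - mean(x)^2))

  single <- manual_model(matrix(1:4, 4, 1), som_grid(2, 2))
  expect_error(variance_map(single), "single cell")
})

test_that("grouped variance equals the variance of group-mean portraits", {
  fx <- medium_fixture()
  ann <- fx$sim$annotations
  groups <- setNames(ann$cell_type, ann$cell_id)
  vm <- variance_map(fx$model, groups)
  M <- vapply(unique(ann$cell_type), function(ty)
    mean_portrait(fx$model, ann$cell_id[ann$cell_type == ty])$values,
    numeric(fx$model$grid$K))
  expect_equal(vm, apply(M, 1L, function(x) mean(x^2) - mean(x)^2))
})

test_that("same-module genes sit closer on the map than different-module genes", {
  fx <- medium_fixture()
  mod <- fx$sim$truth$gene_module
  rc <- cbind((fx$model$bmu - 1) %/% fx$model$grid$cols,
              (fx$model$bmu - 1) %% fx$model$grid$cols)
  mean_dist <- function(i, j) {
    d <- sqrt(outer(rc[i, 1], rc[j, 1], "-")^2 +
                outer(rc[i, 2], rc[j, 2], "-")^2)
    mean(d)
  }
  mods <- c("stem", "tissue_1", "tissue_2")
  for (mo in mods) {
    same <- which(mod == mo)
    other <- which(mod %in% setdiff(mods, mo))
    expect_lt(mean_dist(same, same), mean_dist(same, other))
  }
})
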