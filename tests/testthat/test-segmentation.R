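grid66 <- som_grid(6, 6)

test_that("spot detection finds planted plateaus", {
  g <- som_grid(6, 6)
  v <- rep(0, 36)
  plateau <- c(8, 9, 14, 15)               # 2x2 block
  v[plateau] <- 10
  spots <- detect_spots(list(make_portrait(v, g)), quantile = 0.8)
  expect_length(spots, 1L)
  expect_setequal(spots[[1L]]$members, plateau)
  expect_true(spots[[1L]]$kernel %in% plateau)

  # second plateau visible only in a second portrait
  v2 <- rep(0, 36)
  v2[c(28, 29)] <- 5
  spots2 <- detect_spots(list(make_portrait(v, g), make_portrait(v2, g)),
                         quantile = 0.8)
  expect_length(spots2, 2L)

  # all-constant portraits yield no spots, not an error
  expect_length(detect_spots(list(make_portrait(rep(1, 36), g))), 0L)
})

test_that("spot membership equals threshold + flood-fill oracle", {
  g <- som_grid(7, 5)
  set.seed(21)
  for (rep in 1:5) {
    vals <- replicate(3, rnorm(g$K), simplify = FALSE)
    q <- 0.85
    spots <- detect_spots(lapply(vals, make_portrait, grid = g), quantile = q)
    member <- Reduce(`|`, lapply(vals, function(v)
      v > quantile(v, q, names = FALSE)))
    lab <- oracle_components(member, g$rows, g$cols)
    expect_length(spots, max(lab))
    got <- sort(unlist(lapply(spots, `[[`, "members")))
    expect_identical(got, sort(which(member)))
  }
})

test_that("raising the spot quantile never adds member nodes", {
  g <- som_grid(6, 6)
  set.seed(4)
  vals <- list(make_portrait(rnorm(36), g), make_portrait(rnorm(36), g))
  members_at <- function(q)
    sort(unlist(lapply(detect_spots(vals, q), `[[`, "members")))
  prev <- members_at(0.5)
  for (q in c(0.7, 0.9, 0.98)) {
    cur <- members_at(q)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("k-means segmentation partitions the grid into k lettered clusters", {
  fx <- medium_fixture()
  seg <- kmeans_segment(fx$model, k = 12, seed = 3)
  expect_identical(sort(unique(seg$cluster)), 1:12)
  expect_identical(length(seg$cluster), fx$model$grid$K)
  expect_identical(seg$letters, LETTERS[1:12])

  seg1 <- kmeans_segment(fx$model, k = 1, seed = 3)
  expect_true(all(seg1$cluster == 1L))
  expect_identical(seg1$letters, "A")
  expect_identical(unname(seg1$variance_class), "invariant")
  expect_error(kmeans_segment(fx$model, k = 1000), "between 1 and")
})

test_that("32 clusters are lettered A..Z then A1..F1", {
  expect_identical(cluster_letters(32)[c(1, 26, 27, 32)],
                   c("A", "Z", "A1", "F1"))
  expect_identical(cluster_letters(3), c("A", "B", "C"))
})

test_that("well-separated prototype blocks are recovered as clusters", {
  # 12 nodes in two tight, distant blocks; compare against the best of
  # all 2-partitions by within-cluster sum of squares
  set.seed(8)
  P <- rbind(matrix(rnorm(6 * 2, mean = 0, sd = 0.1), 6, 2),
             matrix(rnorm(6 * 2, mean = 10, sd = 0.1), 6, 2))
  model <- manual_model(P, som_grid(3, 4))
  seg <- kmeans_segment(model, k = 2, seed = 1)
  got <- split(seq_len(12), seg$cluster)

  best <- NULL
  for (mask in 1:(2^11)) {
    members <- as.logical(bitwAnd(mask, 2^(0:11)) > 0)
    if (!any(members) || all(members)) next
    ss <- function(idx) sum(sweep(P[idx, , drop = FALSE], 2L,
                                  colMeans(P[idx, , drop = FALSE]))^2)
    tot <- ss(which(members)) + ss(which(!members))
    if (is.null(best) || tot < best$tot)
      best <- list(tot = tot, part = members)
  }
  ok <- setequal(got[[1L]], which(best$part)) ||
    setequal(got[[1L]], which(!best$part))
  expect_true(ok)
})

test_that("variance classes mark spot kernels and exactly one invariant", {
  fx <- landscape_fixture()
  seg <- fx$seg
  expect_identical(sum(seg$variance_class == "invariant"), 1L)
  kernel_clusters <- unique(vapply(fx$spots, function(s)
    seg$letters[seg$cluster[s$kernel]], character(1L)))
  tagged <- names(seg$variance_class)[seg$variance_class == "spot-variant"]
  expect_true(all(setdiff(kernel_clusters,
                          names(which(seg$variance_class == "invariant")))
                  %in% tagged))
})

test_that("planted tissue modules land in spot-variant clusters", {
  fx <- landscape_fixture()
  mod <- fx$sim$truth$gene_module
  for (mo in c("stem", "tissue_1", "tissue_2")) {
    genes <- names(mod)[mod == mo]
    nodes <- fx$model$bmu[genes]
    cl <- names(sort(table(fx$seg$cluster[nodes]), decreasing = TRUE))[1L]
    cls <- fx$seg$variance_class[as.integer(cl)]
    expect_identical(unname(cls), "spot-variant")
  }
})

test_that("cluster adjacency equals the exhaustive neighbor scan", {
  # half split: single edge
  half <- matrix(rep(c("A", "B"), each = 18), 6, 6)
  seg <- manual_seg(half)
  expect_identical(nrow(seg$adjacency), 1L)
  expect_identical(unlist(seg$adjacency[1L, ], use.names = FALSE),
                   c("A", "B"))

  one <- manual_seg(matrix("A", 4, 4))
  expect_identical(nrow(one$adjacency), 0L)

  set.seed(13)
  for (rep in 1:5) {
    labels <- matrix(sample(LETTERS[1:5], 36, replace = TRUE), 6, 6)
    seg <- manual_seg(labels)
    # O(K^2) oracle over all node pairs
    want <- character()
    for (i in 1:36) for (j in 1:36) {
      ri <- (i - 1) %/% 6 + 1; ci <- (i - 1) %% 6 + 1
      rj <- (j - 1) %/% 6 + 1; cj <- (j - 1) %% 6 + 1
      li <- labels[ri, ci]; lj <- labels[rj, cj]
      if (li != lj && max(abs(ri - rj), abs(ci - cj)) == 1)
        want <- c(want, paste(min(li, lj), max(li, lj)))
    }
    want <- sort(unique(want))
    got <- sort(paste(seg$adjacency$from, seg$adjacency$to))
    expect_identical(got, want)
  }
})

test_that("adjacency of a space-filling segmentation is connected", {
  fx <- landscape_fixture()
  ig <- igraph::graph_from_data_frame(fx$seg$adjacency, directed = FALSE,
                                      vertices = fx$seg$letters)
  expect_true(igraph::is_connected(ig))
  expect_identical(sum(table(fx$seg$cluster)), fx$model$grid$K)
})
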