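# shared fixtures, built lazily and cached for the whole test run

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# small random raw counts matrix with dimnames
random_counts <- function(n_genes, n_cells, seed = 1, lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("c%03d", seq_len(n_cells))))
  expr_matrix(m, "raw")
}

# a modest trained model on structured synthetic data (3 gene modules)
medium_fixture <- function() {
  cached("medium", function() {
    sim <- generate_differentiation(n_cells = 150, n_genes = 400,
                                    n_lineages = 2, seed = 11)
    lf <- compute_logfc(sim$counts)
    model <- train_som(lf, som_grid(10, 10), epochs = 15, seed = 11)
    list(sim = sim, logfc = lf, model = model)
  })
}

# the default synthetic differentiation landscape used by the
# end-to-end checks: 800 cells x 2000 genes, 2 lineages, 20x20 map
landscape_fixture <- function() {
  cached("landscape", function() {
    sim <- generate_differentiation(seed = 1)
    lf <- compute_logfc(sim$counts)
    model <- train_som(lf, som_grid(20, 20), epochs = 20, seed = 1)
    ann <- sim$annotations
    roots <- ann$cell_id[ann$cell_type == "stem"]
    seg <- kmeans_segment(model, seed = 1)
    types <- split(ann$cell_id, ann$cell_type)
    type_portraits <- lapply(names(types), function(ty)
      mean_portrait(model, types[[ty]], subject = ty))
    names(type_portraits) <- names(types)
    spots <- detect_spots(type_portraits)
    seg <- classify_variance(seg, model, spots)
    graph <- knn_graph(portrait_features(model), k = 15)
    pt <- diffusion_pseudotime(graph, roots)
    kin <- fit_gamma(sim$spliced, sim$unspliced)
    field <- grid_vector_field(model, metagene_velocity(model, kin))
    list(sim = sim, logfc = lf, model = model, seg = seg, spots = spots,
         type_portraits = type_portraits, roots = roots, pt = pt,
         kin = kin, field = field, annotations = ann)
  })
}

# hand-built som_model around explicit prototypes (for unit tests that
# need full control over the map)
manual_model <- function(prototypes, grid, bmu = NULL) {
  if (is.null(colnames(prototypes)))
    colnames(prototypes) <- sprintf("c%02d", seq_len(ncol(prototypes)))
  if (is.null(bmu)) {
    bmu <- integer(0)
  }
  structure(list(grid = grid, prototypes = prototypes, bmu = bmu,
                 epochs = 0L, seed = 0L, radius_final = 0.5,
                 qe_history = numeric(), quantization_error = NA_real_),
            class = "som_model")
}

# hand-built segmentation from a rows x cols matrix of cluster letters
manual_seg <- function(letter_matrix) {
  grid <- som_grid(nrow(letter_matrix), ncol(letter_matrix))
  labels <- as.vector(t(letter_matrix))      # row-major
  letters <- sort(unique(labels))
  seg <- structure(list(cluster = match(labels, letters), letters = letters,
                        k = length(letters), grid = grid,
                        variance_class = NULL, adjacency = NULL),
                   class = "som_segmentation")
  seg$adjacency <- cluster_adjacency(seg, grid)
  seg
}

# member nodes of the overexpression spot anchored at a cell group's
# portrait maximum (falls back to the kernel node alone)
spot_of_group <- function(fx, type) {
  cells <- fx$annotations$cell_id[fx$annotations$cell_type == type]
  kernel <- which.max(mean_portrait(fx$model, cells)$values)
  for (s in fx$spots) if (kernel %in% s$members) return(s$members)
  kernel
}

make_portrait <- function(values, grid, subject = "p", scale = "logfc") {
  structure(list(values = as.numeric(values), grid = grid,
                 subject = subject, scale = scale), class = "som_portrait")
}
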