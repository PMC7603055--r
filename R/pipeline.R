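#' Default run configuration
#'
#' One structure collects every tunable of the workflow so a run is
#' reproducible from a single serialized file; all randomness flows from
#' the one `seed`.
#'
#' @param ... named overrides of the defaults.
#' @return a `run_config` list: grid rows/cols (60 x 60), training
#'   epochs, seed, `k_segments` (32), `spot_quantile` (0.98), `pt_k`
#'   (15), `pt_components` (10), `velocity_quantile` (0.05) and
#'   simulation sizes used when no input files are given.
#' @export
run_config <- function(...) {
  cfg <- list(grid_rows = 60L, grid_cols = 60L, epochs = 20L, seed = 1L,
              k_segments = 32L, spot_quantile = 0.98, pseudocount = 1,
              pt_k = 15L, pt_components = 10L, velocity_quantile = 0.05,
              sim_cells = 800L, sim_genes = 2000L, sim_lineages = 2L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop_somscape("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param cfg a [run_config()].
#' @param file path.
#' @export
write_config <- function(cfg, file) {
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  do.call(run_config, yaml::read_yaml(file))
}

#' Run the full portrayal-to-trajectory workflow
#'
#' Executes the whole pipeline on an expression data set (or a fresh
#' simulation): logFC centering, SOM training, cell-type mean portraits,
#' spot detection and k-means segmentation, one maximum-capacity
#' gene-state trajectory per lineage (stem spot kernel cluster to
#' tissue spot kernel cluster), diffusion pseudotime from the root
#' cells, and — when spliced/unspliced layers are present — the
#' RNA-velocity vector field with attractors and basins. All artifacts
#' are written as plain-text files together with the configuration that
#' produced them.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param counts optional [expr_matrix()] (layer `"raw"`); simulated
#'   when `NULL`.
#' @param annotations cell annotation data.frame (`cell_id`,
#'   `cell_type`, `lineage`); required with `counts`.
#' @param spliced,unspliced optional kinetic layers.
#' @param root_type `cell_type` value marking the differentiation root
#'   (default `"stem"`).
#' @param write_portraits also render group mean portraits as PNG.
#' @return invisibly, a list with the fitted objects (`model`, `seg`,
#'   `spots`, `trajectories`, `pt`, `field`) and the artifact paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         counts = NULL, annotations = NULL,
                         spliced = NULL, unspliced = NULL,
                         root_type = "stem", write_portraits = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(counts)) {
    sim <- generate_differentiation(n_cells = config$sim_cells,
                                    n_genes = config$sim_genes,
                                    n_lineages = config$sim_lineages,
                                    seed = config$seed)
    counts <- sim$counts
    annotations <- sim$annotations
    spliced <- sim$spliced
    unspliced <- sim$unspliced
  }
  if (is.null(annotations))
    stop_somscape("'annotations' are required when counts are supplied")

  logfc <- compute_logfc(counts, pseudocount = config$pseudocount)
  grid <- som_grid(config$grid_rows, config$grid_cols)
  model <- train_som(logfc, grid, epochs = config$epochs, seed = config$seed)

  types <- split(annotations$cell_id, annotations$cell_type)
  type_portraits <- lapply(names(types), function(ty)
    mean_portrait(model, types[[ty]], subject = ty))
  names(type_portraits) <- names(types)
  spots <- detect_spots(type_portraits, quantile = config$spot_quantile)
  seg <- kmeans_segment(model, k = config$k_segments, seed = config$seed)
  seg <- classify_variance(seg, model, spots)
  write_segmentation_tsv(seg, file.path(out_dir, "segmentation.tsv"))
  write_spots_tsv(spots, model$grid, file.path(out_dir, "spots.tsv"))
  if (write_portraits) {
    dir.create(file.path(out_dir, "portraits"), showWarnings = FALSE)
    for (ty in names(type_portraits))
      write_portrait_png(type_portraits[[ty]],
                         file.path(out_dir, "portraits",
                                   paste0(ty, ".png")))
  }

  roots <- annotations$cell_id[annotations$cell_type == root_type]
  if (length(roots) == 0L)
    stop_somscape("no cells of root type '", root_type, "'")
  stem_portrait <- mean_portrait(model, roots, subject = root_type)

  lineages <- setdiff(unique(annotations$lineage), NA)
  trajectories <- list()
  for (ln in lineages) {
    lin_cells <- annotations$cell_id[annotations$lineage == ln]
    tissue_cells <- annotations$cell_id[annotations$cell_type == ln]
    if (length(tissue_cells) == 0L) next
    traj <- lineage_trajectory(model, seg, roots, tissue_cells, lin_cells)
    trajectories[[ln]] <- traj
    write_trajectory_json(traj, file.path(out_dir,
                                          paste0("trajectory_", ln, ".json")))
  }

  graph <- knn_graph(portrait_features(model), k = config$pt_k)
  pt <- diffusion_pseudotime(graph, roots,
                             n_components = config$pt_components)
  write_pt_csv(pt, file.path(out_dir, "pseudotime.csv"), annotations)

  field <- NULL
  if (!is.null(spliced) && !is.null(unspliced)) {
    kin <- fit_gamma(spliced, unspliced, quantile = config$velocity_quantile)
    nv <- metagene_velocity(model, kin)
    field <- grid_vector_field(model, nv)
    summary_expr <- new_portrait(
      apply(vapply(type_portraits, function(p) p$values,
                   numeric(model$grid$K)), 1L, max),
      model$grid, subject = "max_over_types", scale = "logfc")
    field <- detect_attractors(field, summary_expr)
    field <- velocity_trajectories(field)
    write_field_tsv(field, file.path(out_dir, "velocity_field.tsv"))
  }

  write_config(config, file.path(out_dir, "config.yaml"))
  invisible(list(model = model, seg = seg, spots = spots,
                 type_portraits = type_portraits,
                 trajectories = trajectories, pt = pt, field = field,
                 out_dir = out_dir))
}

#' Maximum-capacity trajectory between a stem and a tissue spot
#'
#' Convenience wrapper: forms the lineage mean portrait (all lineage
#' cells, loglogFC scale), builds the capacity network, locates the
#' stem and tissue spot kernels (highest node of each group portrait)
#' and extracts the widest path between their clusters.
#'
#' @param model a trained `som_model`.
#' @param seg a `som_segmentation`.
#' @param stem_cells,tissue_cells cell id vectors defining source and
#'   sink spots.
#' @param lineage_cells cells weighting the capacities (default: stem
#'   and tissue cells together).
#' @return a `gene_trajectory` (cluster letters), with the source/sink
#'   kernel nodes in attributes `source_kernel` / `sink_kernel`.
#' @export
lineage_trajectory <- function(model, seg, stem_cells, tissue_cells,
                               lineage_cells = NULL) {
  lineage_cells <- lineage_cells %||% union(stem_cells, tissue_cells)
  lineage_portrait <- mean_portrait(model, lineage_cells,
                                    scale = "loglogfc", subject = "lineage")
  g <- build_capacity_graph(seg, lineage_portrait)
  stem_kernel <- spot_kernel(model, stem_cells)
  tissue_kernel <- spot_kernel(model, tissue_cells)
  source <- seg$letters[seg$cluster[stem_kernel]]
  sink <- seg$letters[seg$cluster[tissue_kernel]]
  if (identical(source, sink))
    stop_somscape("stem and tissue kernels fall into the same cluster '",
                  source, "'")
  traj <- max_capacity_path(g, source, sink)
  attr(traj, "source_kernel") <- stem_kernel
  attr(traj, "sink_kernel") <- tissue_kernel
  traj
}

# node of maximal mean overexpression of a cell group
spot_kernel <- function(model, cells) {
  which.max(mean_portrait(model, cells)$values)
}
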