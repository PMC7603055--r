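# readers and writers for the plain-text formats the pipeline exchanges

#' Read a genes x cells matrix from MatrixMarket triplet files
#'
#' Expects the standard trio: an `.mtx` file with 1-based triplets plus
#' sidecar TSVs listing gene ids (rows) and cell barcodes (columns), one
#' id per line (first column used if there are several).
#'
#' @param mtx_file path to the MatrixMarket file.
#' @param genes_file,barcodes_file sidecar TSVs with row / column ids.
#' @param layer layer tag for the result (default `"raw"`).
#' @return an [expr_matrix()].
#' @export
read_mtx_expression <- function(mtx_file, genes_file, barcodes_file,
                                layer = "raw") {
  m <- as.matrix(Matrix::readMM(mtx_file))
  genes <- utils::read.table(genes_file, sep = "\t",
                             stringsAsFactors = FALSE)[[1L]]
  cells <- utils::read.table(barcodes_file, sep = "\t",
                             stringsAsFactors = FALSE)[[1L]]
  if (length(genes) != nrow(m))
    stop_somscape("gene sidecar has ", length(genes), " ids but matrix has ",
                  nrow(m), " rows")
  if (length(cells) != ncol(m))
    stop_somscape("barcode sidecar has ", length(cells), " ids but matrix has ",
                  ncol(m), " columns")
  dimnames(m) <- list(genes, cells)
  expr_matrix(m, layer = layer)
}

#' Write a genes x cells matrix as MatrixMarket triplets with sidecars
#'
#' @param x an [expr_matrix()].
#' @param mtx_file,genes_file,barcodes_file output paths.
#' @export
write_mtx_expression <- function(x, mtx_file, genes_file, barcodes_file) {
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(as_plain_matrix(x)),
                                          "generalMatrix"), "TsparseMatrix"),
                  mtx_file)
  writeLines(rownames(x), genes_file)
  writeLines(colnames(x), barcodes_file)
  invisible(c(mtx_file, genes_file, barcodes_file))
}

#' Read a dense TSV expression table
#'
#' First row holds cell ids, first column gene ids.
#'
#' @param file path.
#' @param layer layer tag for the result.
#' @return an [expr_matrix()].
#' @export
read_dense_tsv <- function(file, layer = "raw") {
  df <- utils::read.table(file, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE)
  expr_matrix(as.matrix(df), layer = layer)
}

#' Write a dense TSV expression table at full double precision
#' @param x an [expr_matrix()] (any layer).
#' @param file output path.
#' @export
write_dense_tsv <- function(x, file) {
  m <- as_plain_matrix(x)
  header <- paste(c("gene_id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), file)
  invisible(file)
}

#' Read a cell annotation table
#'
#' CSV with columns `cell_id`, `cell_type` and optionally `lineage`.
#'
#' @param file path.
#' @return data.frame with those columns (`lineage` NA when absent).
#' @export
read_annotations <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("cell_id", "cell_type")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop_somscape("annotation file lacks column(s): ",
                  paste(miss, collapse = ", "))
  if (is.null(df$lineage)) df$lineage <- NA_character_
  df[c("cell_id", "cell_type", "lineage")]
}

#' Write a cell annotation table
#' @param annotations data.frame with `cell_id`, `cell_type`, `lineage`.
#' @param file output path.
#' @export
write_annotations <- function(annotations, file) {
  utils::write.csv(annotations, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids.
#'
#' @param file path.
#' @return named list of [gene_set()] objects.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop_somscape("malformed GMT line: ", substr(ln, 1L, 60L))
    gene_set(parts[1L], unique(parts[-(1:2)]), description = parts[2L])
  })
  names(sets) <- vapply(sets, function(s) s$name, character(1L))
  sets
}

#' Write a module segmentation as TSV
#'
#' One row per grid node: `node_row`, `node_col`, `cluster_letter`,
#' `variance_class`.
#'
#' @param seg a [kmeans_segment()] result.
#' @param file output path.
#' @export
write_segmentation_tsv <- function(seg, file) {
  rc <- node_coords(seg$grid)
  df <- data.frame(node_row = rc[, "row"], node_col = rc[, "col"],
                   cluster_letter = seg$letters[seg$cluster],
                   variance_class = seg$variance_class[seg$cluster])
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a module segmentation TSV written by [write_segmentation_tsv()]
#' @param file path.
#' @return data.frame with node coordinates, letters and variance classes.
#' @export
read_segmentation_tsv <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write detected overexpression spots as TSV
#' @param spots a [detect_spots()] result.
#' @param grid the [som_grid()] the spots live on.
#' @param file output path.
#' @export
write_spots_tsv <- function(spots, grid, file) {
  rows <- lapply(spots, function(s) {
    rc <- node_rc(s$kernel, grid)
    data.frame(label = s$label, kernel_row = rc[1L, "row"],
               kernel_col = rc[1L, "col"], n_nodes = length(s$members))
  })
  df <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(label = character(), kernel_row = integer(),
               kernel_col = integer(), n_nodes = integer())
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Serialize a gene-state trajectory to JSON
#' @param traj a `gene_trajectory` object.
#' @param file output path.
#' @export
write_trajectory_json <- function(traj, file) {
  jsonlite::write_json(
    list(method = traj$method,
         source = traj$path[[1L]],
         sink = traj$path[[length(traj$path)]],
         path = traj$path,
         score = traj$score,
         per_step_expression = traj$per_step_expression),
    file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Read a trajectory JSON written by [write_trajectory_json()]
#' @param file path.
#' @return list with method, source, sink, path, score, per-step values.
#' @export
read_trajectory_json <- function(file) {
  jsonlite::read_json(file, simplifyVector = TRUE)
}

#' Write pseudotime values as CSV
#' @param pt a [diffusion_pseudotime()] result.
#' @param annotations optional annotation data.frame supplying lineages.
#' @param file output path.
#' @export
write_pt_csv <- function(pt, file, annotations = NULL) {
  df <- data.frame(cell_id = names(pt$pt), pt = pt$pt,
                   stringsAsFactors = FALSE)
  df$lineage <- if (!is.null(annotations))
    annotations$lineage[match(df$cell_id, annotations$cell_id)]
  else NA_character_
  rownames(df) <- NULL
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write a velocity vector field as TSV
#'
#' One row per grid node: position, arrow components, speed, basin label
#' and attractor flag.
#'
#' @param field a [grid_vector_field()] result (with attractors/basins
#'   attached when available).
#' @param file output path.
#' @export
write_field_tsv <- function(field, file) {
  rc <- node_coords(field$grid)
  K <- nrow(rc)
  basin <- field$basin %||% rep(NA_integer_, K)
  attract <- seq_len(K) %in% (field$attractors %||% integer())
  df <- data.frame(row = rc[, "row"], col = rc[, "col"],
                   arrow_dx = field$arrows[, 1L],
                   arrow_dy = field$arrows[, 2L],
                   speed = sqrt(rowSums(field$arrows^2)),
                   basin = basin, is_attractor = attract)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Save a trained SOM model as a plain-text bundle
#'
#' Writes a directory with full-precision TSV datasets: `prototypes.tsv`
#' (K x cells), `bmu.tsv` (gene to node), `grid.tsv` and `meta.yaml`.
#'
#' @param model a [train_som()] result.
#' @param dir output directory (created if missing).
#' @export
save_som_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  proto <- model$prototypes
  rownames(proto) <- paste0("node_", seq_len(nrow(proto)))
  write_dense_tsv(expr_matrix(proto, layer = "logfc"),
                  file.path(dir, "prototypes.tsv"))
  utils::write.table(
    data.frame(gene_id = names(model$bmu), node = unname(model$bmu)),
    file.path(dir, "bmu.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(rows = model$grid$rows, cols = model$grid$cols),
    file.path(dir, "grid.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(
    list(epochs = model$epochs, seed = model$seed,
         radius_final = model$radius_final,
         quantization_error = model$quantization_error,
         qe_history = model$qe_history),
    file.path(dir, "meta.yaml"), precision = 15L)
  invisible(dir)
}

#' Load a SOM model saved by [save_som_model()]
#' @param dir bundle directory.
#' @return a `som_model` object.
#' @export
load_som_model <- function(dir) {
  g <- utils::read.table(file.path(dir, "grid.tsv"), header = TRUE, sep = "\t")
  grid <- som_grid(g$rows[1L], g$cols[1L])
  proto <- as_plain_matrix(read_dense_tsv(file.path(dir, "prototypes.tsv"),
                                          layer = "logfc"))
  rownames(proto) <- NULL
  bm <- utils::read.table(file.path(dir, "bmu.tsv"), header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  bmu <- bm$node
  names(bmu) <- bm$gene_id
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  structure(list(grid = grid, prototypes = proto, bmu = bmu,
                 epochs = meta$epochs, seed = meta$seed,
                 radius_final = meta$radius_final,
                 quantization_error = meta$quantization_error,
                 qe_history = unlist(meta$qe_history)),
            class = "som_model")
}

#' Render a portrait as a PNG image
#'
#' One pixel per metagene node, diverging blue-white-red color scale
#' symmetric about zero so that the fold-change coast-line is white.
#'
#' @param portrait a [portrait_of_cell()] / [mean_portrait()] result.
#' @param file output path.
#' @param limit symmetric color range; defaults to `max(abs(values))`.
#' @export
write_portrait_png <- function(portrait, file, limit = NULL) {
  v <- portrait$values
  limit <- limit %||% max(abs(v), 1e-12)
  z <- pmin(pmax(v / limit, -1), 1)
  ramp <- grDevices::colorRamp(c("#2166AC", "#F7F7F7", "#B2182B"))
  rgb <- ramp((z + 1) / 2) / 255
  g <- portrait$grid
  img <- array(0, dim = c(g$rows, g$cols, 3L))
  for (ch in 1:3)
    img[, , ch] <- matrix(rgb[, ch], nrow = g$rows, ncol = g$cols, byrow = TRUE)
  png::writePNG(img, file)
  invisible(file)
}
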