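#' Expression matrix container
#'
#' A genes-by-cells numeric matrix with unique gene and cell identifiers
#' and a layer tag recording what the values mean: raw counts, gene-wise
#' centered log fold changes (`logfc`), their signed-log compression
#' (`loglogfc`), or spliced/unspliced abundances.
#'
#' @param values numeric matrix, genes in rows, cells in columns, with
#'   rownames (gene ids) and colnames (cell ids).
#' @param layer one of `"raw"`, `"logfc"`, `"loglogfc"`, `"spliced"`,
#'   `"unspliced"`. Raw, spliced and unspliced layers must be finite and
#'   non-negative; a `logfc` layer must have mean-zero gene rows.
#' @return the validated matrix with class `expr_matrix` and a `layer`
#'   attribute.
#' @export
expr_matrix <- function(values,
                        layer = c("raw", "logfc", "loglogfc",
                                  "spliced", "unspliced")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop_somscape("'values' must be a numeric matrix (genes x cells)")
  gid <- rownames(values)
  cid <- colnames(values)
  if (is.null(gid) || is.null(cid))
    stop_somscape("'values' needs rownames (gene ids) and colnames (cell ids)")
  if (anyDuplicated(gid))
    stop_somscape("duplicated gene ids: ", gid[duplicated(gid)][1L])
  if (anyDuplicated(cid))
    stop_somscape("duplicated cell ids: ", cid[duplicated(cid)][1L])
  if (layer %in% c("raw", "spliced", "unspliced")) {
    bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop_somscape(sprintf(
        "layer '%s' requires finite, non-negative values; offending entry gene '%s', cell '%s'",
        layer, gid[bad[1L, 1L]], cid[bad[1L, 2L]]))
  } else {
    bad <- which(!is.finite(values), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop_somscape(sprintf(
        "non-finite value at gene '%s', cell '%s'",
        gid[bad[1L, 1L]], cid[bad[1L, 2L]]))
  }
  if (layer == "logfc") {
    rm <- rowMeans(values)
    off <- which(abs(rm) > 1e-9)
    if (length(off) > 0L)
      stop_somscape("logfc rows must be mean-zero; gene '", gid[off[1L]],
                    "' has row mean ", rm[off[1L]])
  }
  structure(values, layer = layer, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells, layer '%s'\n",
              nrow(x), ncol(x), attr(x, "layer")))
  invisible(x)
}

#' Layer tag of an expression matrix
#' @param x an [expr_matrix()].
#' @return the layer string.
#' @export
expr_layer <- function(x) attr(x, "layer")

as_plain_matrix <- function(x) {
  attr(x, "layer") <- NULL
  class(x) <- "matrix"
  unclass(x)[, , drop = FALSE]
}

#' Center log expression into log fold changes
#'
#' Each gene is log2-transformed (after adding a pseudocount) and
#' centered on its mean over all cells:
#' `logFC(g, c) = log2(x[g,c] + pc) - mean_c log2(x[g,.] + pc)`.
#' The resulting rows are mean-zero, so red/blue portrait colors read as
#' over-/under-expression relative to the ensemble average of the gene.
#'
#' @param raw an [expr_matrix()] with layer `"raw"`.
#' @param pseudocount positive value added before taking logs (default 1).
#' @return an [expr_matrix()] with layer `"logfc"`.
#' @export
compute_logfc <- function(raw, pseudocount = 1) {
  check_layer(raw, "raw")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop_somscape("'pseudocount' must be a single non-negative number")
  lg <- log2(as_plain_matrix(raw) + pseudocount)
  if (any(!is.finite(lg))) {
    bad <- which(!is.finite(lg), arr.ind = TRUE)
    stop_somscape(sprintf(
      "zero count with pseudocount 0 gives -Inf at gene '%s', cell '%s'",
      rownames(raw)[bad[1L, 1L]], colnames(raw)[bad[1L, 2L]]))
  }
  lg <- lg - rowMeans(lg)
  expr_matrix(lg, layer = "logfc")
}

#' Signed-log compression of log fold changes
#'
#' Maps a logFC value onto a compressed scale that keeps its sign and
#' places the fold-change-one "coast-line" at zero:
#' `sign(x) * log2(1 + |x|)`. The function is odd, strictly increasing
#' and total on the finite reals, so over-expression stays red and
#' under-expression stays blue while subtle changes near zero are
#' resolved better than on the raw logFC scale.
#'
#' @param x finite numeric vector (logFC units).
#' @return numeric vector of the same length.
#' @export
loglog_transform <- function(x) {
  if (any(!is.finite(x)))
    stop_somscape("loglog_transform requires finite input")
  sign(x) * log2(1 + abs(x))
}

#' Keep genes detected in a minimum number of cells
#'
#' @param raw an [expr_matrix()] with layer `"raw"`.
#' @param min_cells keep genes with a positive value in at least this
#'   many cells; 0 keeps everything. Filtering is off by default in the
#'   pipeline.
#' @return the filtered [expr_matrix()], gene order preserved.
#' @export
filter_genes <- function(raw, min_cells = 0L) {
  check_layer(raw, "raw")
  if (min_cells > ncol(raw))
    stop_somscape("'min_cells' exceeds the number of cells (", ncol(raw), ")")
  keep <- rowSums(as_plain_matrix(raw) > 0) >= min_cells
  if (!any(keep))
    stop_somscape("no genes pass filter (min_cells = ", min_cells, ")")
  expr_matrix(as_plain_matrix(raw)[keep, , drop = FALSE], layer = "raw")
}

check_layer <- function(x, expected) {
  if (!inherits(x, "expr_matrix"))
    stop_somscape("expected an 'expr_matrix', got ", class(x)[1L])
  if (!attr(x, "layer") %in% expected)
    stop_somscape("expected layer '", paste(expected, collapse = "'/'"),
                  "', got '", attr(x, "layer"), "'")
  invisible(x)
}
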