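#' Gene set container
#' @param name set name.
#' @param genes nonempty character vector of unique gene ids.
#' @param description optional free-text description (GMT column 2).
#' @return a `gene_set` list.
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop_somscape("gene set '", name, "' is empty")
  if (anyDuplicated(genes))
    stop_somscape("gene set '", name, "' has duplicated ids")
  structure(list(name = name, genes = genes, description = description),
            class = "gene_set")
}

#' Hypergeometric overrepresentation of a gene set in a module
#'
#' Upper-tail hypergeometric test `P(X >= overlap)` with population the
#' gene universe, successes the set genes inside the universe, and draws
#' the module gene list; reports the overlap and `log10(p)` on the
#' scale functional-annotation tables usually print.
#'
#' @param module_genes character vector of module gene ids (subset of
#'   the universe).
#' @param set a [gene_set()] (genes outside the universe are dropped).
#' @param universe character vector of all analyzed gene ids.
#' @return list with `p_value`, `overlap`, `log10_p`.
#' @export
overrepresentation <- function(module_genes, set, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop_somscape("empty universe")
  module_genes <- unique(as.character(module_genes))
  if (length(module_genes) == 0L) stop_somscape("empty module gene list")
  if (!all(module_genes %in% universe))
    stop_somscape("module genes must be a subset of the universe")
  hits <- intersect(set$genes, universe)
  overlap <- length(intersect(module_genes, hits))
  p <- stats::phyper(overlap - 1L, m = length(hits),
                     n = length(universe) - length(hits),
                     k = length(module_genes), lower.tail = FALSE)
  list(p_value = p, overlap = overlap, log10_p = log10(p))
}

#' Overrepresentation of many sets across all segmentation modules
#'
#' Runs [overrepresentation()] for every (module, set) pair; p-values
#' are Benjamini-Hochberg adjusted across sets within each module (raw
#' p is reported alongside).
#'
#' @param model a trained `som_model`.
#' @param seg a `som_segmentation`.
#' @param gene_sets named list of [gene_set()] objects (e.g. from
#'   [read_gmt()]).
#' @return data.frame `module`, `set`, `overlap`, `module_size`, `p`,
#'   `fdr`, `log10_p`.
#' @export
module_enrichment <- function(model, seg, gene_sets) {
  universe <- names(model$bmu)
  rows <- list()
  for (letter in seg$letters) {
    nodes <- cluster_nodes(seg, letter)
    genes <- universe[model$bmu %in% nodes]
    if (length(genes) == 0L) next
    res <- lapply(gene_sets, function(s)
      overrepresentation(genes, s, universe))
    p <- vapply(res, `[[`, numeric(1L), "p_value")
    rows[[letter]] <- data.frame(
      module = letter,
      set = names(gene_sets),
      overlap = vapply(res, `[[`, numeric(1L), "overlap"),
      module_size = length(genes),
      p = p,
      fdr = stats::p.adjust(p, method = "BH"),
      log10_p = vapply(res, `[[`, numeric(1L), "log10_p"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene set enrichment Z-score (GSZ) profile across cell groups
#'
#' For each cell group, standardizes the deviation of the set's mean
#' expression from the global mean: `Z = (mean_set - mean_all) /
#' (sd_all / sqrt(n_set))`, where gene expression is taken from the
#' gene's metagene (BMU prototype) profile averaged over the group's
#' cells, and `n_set` counts the set genes mapped on the SOM.
#'
#' @param model a trained `som_model`.
#' @param set a [gene_set()]; at least one gene must be mapped.
#' @param groups named factor/character vector mapping cell ids to
#'   groups.
#' @return named numeric vector of Z scores, one per group (`NA` with a
#'   warning where the global standard deviation is zero).
#' @export
gsz_profile <- function(model, set, groups) {
  genes <- names(model$bmu)
  mapped <- intersect(set$genes, genes)
  if (length(mapped) == 0L)
    stop_somscape("no gene of set '", set$name, "' is mapped on the SOM")
  groups <- groups[colnames(model$prototypes)]
  if (anyNA(groups))
    stop_somscape("'groups' must cover every cell of the model")
  G <- model$prototypes[model$bmu, , drop = FALSE]   # gene-level metagene expr
  rownames(G) <- genes
  levs <- unique(as.character(groups))
  z <- stats::setNames(numeric(length(levs)), levs)
  for (g in levs) {
    x <- rowMeans(G[, names(groups)[groups == g], drop = FALSE])
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning("zero expression variance in group '", g, "'; GSZ undefined")
      z[g] <- NA_real_
    } else {
      z[g] <- (mean(x[mapped]) - mean(x)) / (s / sqrt(length(mapped)))
    }
  }
  z
}

#' Map a gene set onto the SOM grid
#'
#' BMU coordinates of every mapped set gene, for overlaying gene dots on
#' portraits; genes absent from the model are reported separately.
#'
#' @param model a trained `som_model`.
#' @param set a [gene_set()].
#' @return data.frame `gene`, `row`, `col` with attribute `unmapped`
#'   (character vector).
#' @export
gene_set_map <- function(model, set) {
  mapped <- intersect(set$genes, names(model$bmu))
  unmapped <- setdiff(set$genes, names(model$bmu))
  if (length(mapped) > 0L) {
    rc <- node_rc(model$bmu[mapped], model$grid)
    df <- data.frame(gene = mapped, row = rc[, "row"], col = rc[, "col"],
                     stringsAsFactors = FALSE, row.names = NULL)
  } else {
    df <- data.frame(gene = character(), row = integer(), col = integer(),
                     stringsAsFactors = FALSE)
  }
  attr(df, "unmapped") <- unmapped
  df
}
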