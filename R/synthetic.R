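#' Simulate a stem-to-multi-tissue differentiation snapshot
#'
#' Generates single-cell count data with known ground truth emulating a
#' differentiation landscape: one decaying stemness gene module, one
#' rising module per tissue lineage, and a large block of invariant
#' genes. Each cell carries a latent time `t ~ U(0, 1)` and a lineage;
#' mean expression is `mu[g, c] = baseline_g * (1 + a_g * w(t))` with
#' activation `w(t) = (1 - t)^p` for stem-module genes and `w(t) = t^p`
#' for genes of the cell's own lineage module (0 elsewhere and for
#' invariant genes; `p = activation_exponent`). Counts are negative
#' binomial around `mu`. Spliced and unspliced abundances follow the
#' closed-form solution of the first-order kinetics `du/dt = alpha(t) -
#' beta u`, `ds/dt = beta u - gamma s`, with transcription switching on
#' at `t_switch` for tissue modules (and off for the stem module), so
#' RNA-velocity ground truth (`ds/dt`) is available per gene and cell.
#'
#' @param n_cells,n_genes problem size (defaults 800 x 2000).
#' @param n_lineages number of tissue lineages (default 2).
#' @param frac_invariant fraction of invariant genes (default 0.65, the
#'   share typically seen in whole-organism single-cell maps).
#' @param noise_dispersion negative-binomial size parameter (default
#'   0.5; larger is less noisy, `Inf` gives the Poisson limit, `NULL`
#'   disables sampling and returns the exact means).
#' @param seed integer seed; identical seeds give identical output.
#' @param activation_exponent exponent `p` of the activation curves
#'   (default 2: smooth quadratic onset/decay).
#' @param kinetic_time total kinetic time spanned by `t` in units of
#'   `1/beta` (default 4, so switched genes approach their new steady
#'   state near `t = 1`).
#' @param t_switch latent time at which tissue transcription switches on
#'   and stem transcription off (default 0.3).
#' @param steady_state if `TRUE`, all genes sit exactly at their active
#'   steady state (`u = gamma * s / beta` ratios hold everywhere) —
#'   useful for validating steady-state fits.
#' @return a `synthetic_differentiation` list: `counts`, `spliced`,
#'   `unspliced` ([expr_matrix()] objects), `annotations` (data.frame
#'   `cell_id`, `cell_type`, `lineage`) and `truth` with `latent_time`,
#'   `lineage`, `gene_module`, `kinetics` (per-gene `alpha_on`,
#'   `alpha_off`, `beta`, `gamma_true`), the exact means (`mu`,
#'   `spliced_mean`, `unspliced_mean`), the true velocity `ds/dt` and
#'   the `seed`.
#' @export
generate_differentiation <- function(n_cells = 800L, n_genes = 2000L,
                                     n_lineages = 2L, frac_invariant = 0.65,
                                     noise_dispersion = 0.5, seed = 1L,
                                     activation_exponent = 2,
                                     kinetic_time = 4, t_switch = 0.3,
                                     steady_state = FALSE) {
  if (n_lineages < 1L) stop_somscape("'n_lineages' must be >= 1")
  if (frac_invariant < 0 || frac_invariant >= 1)
    stop_somscape("'frac_invariant' must be in [0, 1)")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  cell_ids <- sprintf("cell_%04d", seq_len(n_cells))
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))

  t <- stats::runif(n_cells)
  lineage_id <- sample.int(n_lineages, n_cells, replace = TRUE)
  lineage <- paste0("tissue_", lineage_id)
  cell_type <- ifelse(t < t_switch, "stem",
                      ifelse(t < 0.7, paste0("progenitor_", lineage_id),
                             lineage))

  n_inv <- round(frac_invariant * n_genes)
  n_var <- n_genes - n_inv
  per_mod <- n_var %/% (n_lineages + 1L)
  module <- c(rep("stem", n_var - n_lineages * per_mod),
              rep(paste0("tissue_", seq_len(n_lineages)), each = per_mod),
              rep("invariant", n_inv))
  names(module) <- gene_ids

  baseline <- exp(stats::rnorm(n_genes, log(3), 0.6))
  a <- stats::runif(n_genes, 1, 3)
  a[module == "invariant"] <- 0

  # activation weight per gene x cell
  W <- matrix(0, n_genes, n_cells)
  stem_g <- module == "stem"
  W[stem_g, ] <- matrix(rep((1 - t)^activation_exponent, sum(stem_g)),
                        nrow = sum(stem_g), byrow = TRUE)
  for (l in seq_len(n_lineages)) {
    gl <- module == paste0("tissue_", l)
    cl <- lineage_id == l
    W[gl, cl] <- matrix(rep(t[cl]^activation_exponent, sum(gl)),
                        nrow = sum(gl), byrow = TRUE)
  }
  mu <- baseline * (1 + a * W)
  dimnames(mu) <- list(gene_ids, cell_ids)

  # splicing/degradation kinetics; beta fixed to 1 sets the time unit,
  # gamma kept away from 1 so the closed form stays well-conditioned
  beta <- rep(1, n_genes)
  gr <- stats::runif(n_genes, 0.5, 1.95)
  gamma_true <- ifelse(gr < 0.95, gr, gr + 0.1)
  alpha_on <- baseline * gamma_true         # active steady state s* = baseline
  alpha_off <- 0.05 * alpha_on              # basal leak when switched off
  kin <- data.frame(gene_id = gene_ids, alpha_on = alpha_on,
                    alpha_off = alpha_off, beta = beta,
                    gamma_true = gamma_true, stringsAsFactors = FALSE)

  ab <- kinetic_abundances(module, lineage_id, t, kin, kinetic_time,
                           t_switch, steady_state)
  dimnames(ab$u) <- dimnames(ab$s) <- dimnames(ab$v) <- dimnames(mu)

  sample_counts <- function(m) {
    if (is.null(noise_dispersion)) return(m)
    x <- if (is.infinite(noise_dispersion))
      stats::rpois(length(m), lambda = m)
    else
      stats::rnbinom(length(m), mu = m, size = noise_dispersion)
    matrix(as.numeric(x), nrow = nrow(m), dimnames = dimnames(m))
  }
  counts <- sample_counts(mu)
  spliced <- sample_counts(ab$s)
  unspliced <- sample_counts(ab$u)

  annotations <- data.frame(cell_id = cell_ids, cell_type = cell_type,
                            lineage = lineage, stringsAsFactors = FALSE)
  truth <- list(latent_time = stats::setNames(t, cell_ids),
                lineage = stats::setNames(lineage, cell_ids),
                cell_type = stats::setNames(cell_type, cell_ids),
                gene_module = module, kinetics = kin,
                mu = mu, spliced_mean = ab$s, unspliced_mean = ab$u,
                velocity_true = ab$v, seed = as.integer(seed))
  structure(list(counts = expr_matrix(counts, "raw"),
                 spliced = expr_matrix(spliced, "spliced"),
                 unspliced = expr_matrix(unspliced, "unspliced"),
                 annotations = annotations, truth = truth),
            class = "synthetic_differentiation")
}

# closed-form u(t), s(t) and true velocity ds/dt for switch kinetics:
# before the switch the gene sits at the steady state of its initial
# transcription rate; afterwards the two-exponential relaxation applies
kinetic_abundances <- function(module, lineage_id, t, kin, kinetic_time,
                               t_switch, steady_state) {
  n_genes <- nrow(kin)
  n_cells <- length(t)
  u <- matrix(0, n_genes, n_cells)
  s <- matrix(0, n_genes, n_cells)
  v <- matrix(0, n_genes, n_cells)
  for (g in seq_len(n_genes)) {
    b <- kin$beta[g]; gm <- kin$gamma_true[g]
    on <- kin$alpha_on[g]; off <- kin$alpha_off[g]
    mod <- module[g]
    if (steady_state || mod == "invariant") {
      u[g, ] <- on / b
      s[g, ] <- on / gm
      next                               # v stays 0: steady state
    }
    if (mod == "stem") {
      a_pre <- on; a_post <- off
      switched <- rep(TRUE, n_cells)     # all cells share the stem program
    } else {
      l <- as.integer(sub("tissue_", "", mod))
      a_pre <- off; a_post <- on
      switched <- lineage_id == l        # only own-lineage cells induce
    }
    u0 <- a_pre / b; s0 <- a_pre / gm
    tau <- pmax(kinetic_time * (t - t_switch), 0)
    tau[!switched] <- 0
    eb <- exp(-b * tau); eg <- exp(-gm * tau)
    ug <- a_post / b + (u0 - a_post / b) * eb
    sg <- s0 * eg + (a_post / gm) * (1 - eg) +
      (b * u0 - a_post) / (gm - b) * (eb - eg)
    u[g, ] <- ug
    s[g, ] <- sg
    v[g, ] <- b * ug - gm * sg
  }
  list(u = u, s = s, v = v)
}

#' @export
print.synthetic_differentiation <- function(x, ...) {
  cat(sprintf(
    "<synthetic_differentiation> %d genes x %d cells, %d lineages, seed %d\n",
    nrow(x$counts), ncol(x$counts),
    length(unique(x$annotations$lineage)), x$truth$seed))
  invisible(x)
}

#' Deterministic toy fixtures for trajectory methods
#'
#' Small graphs and height landscapes with known optimal paths, used to
#' exercise the trajectory operations against closed-form expectations.
#'
#' * `"chain"`: `params = list(n, caps)` builds `S - X1 - ... - T` with
#'   the given edge capacities.
#' * `"diamond"`: `params = list(caps)` (length 4) builds the two-route
#'   diamond `S-A-T` / `S-B-T` with capacities `caps[1:2]` and
#'   `caps[3:4]`.
#' * `"grid"`: `params = list(rows, cols, valley_row, base)` returns a
#'   height portrait with a planted zero-height valley along
#'   `valley_row` on an otherwise flat landscape of height `base`.
#' * `"random"`: `params = list(n, p)` returns a connected random graph
#'   on `n` nodes, edge probability `p`, capacities `U(0, 10)`.
#'
#' @param kind one of `"chain"`, `"diamond"`, `"grid"`, `"random"`.
#' @param params list of parameters for the kind (see above).
#' @param seed seed for the `"random"` kind.
#' @return a `capacity_graph`, or a `som_portrait` for `"grid"`.
#' @export
generate_toy_graph <- function(kind = c("chain", "diamond", "grid", "random"),
                               params = list(), seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    chain = {
      n <- params$n %||% 3L
      caps <- params$caps %||% rep(1, n - 1L)
      stopifnot(length(caps) == n - 1L)
      nodes <- c("S", if (n > 2L) paste0("X", seq_len(n - 2L)), "T")
      capacity_graph(nodes, data.frame(from = nodes[-n], to = nodes[-1L],
                                       capacity = caps))
    },
    diamond = {
      caps <- params$caps %||% c(2, 5, 4, 3)
      stopifnot(length(caps) == 4L)
      capacity_graph(c("A", "B", "S", "T"),
                     data.frame(from = c("S", "A", "S", "B"),
                                to = c("A", "T", "B", "T"),
                                capacity = caps))
    },
    grid = {
      rows <- params$rows %||% 5L
      cols <- params$cols %||% 5L
      valley_row <- params$valley_row %||% ((rows + 1L) %/% 2L)
      base <- params$base %||% 5
      g <- som_grid(rows, cols)
      h <- rep(base, g$K)
      h[node_index(rep(valley_row, cols), seq_len(cols), g)] <- 0
      new_portrait(h, g, subject = "valley", scale = "logfc")
    },
    random = {
      n <- params$n %||% 8L
      p <- params$p %||% 0.4
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
      nodes <- sprintf("n%02d", seq_len(n))
      repeat {
        pairs <- utils::combn(nodes, 2L)
        pick <- stats::runif(ncol(pairs)) < p
        # always keep a random spanning path so the graph is connected
        perm <- sample(nodes)
        edges <- unique(rbind(
          data.frame(from = pmin(pairs[1L, pick], pairs[2L, pick]),
                     to = pmax(pairs[1L, pick], pairs[2L, pick]),
                     stringsAsFactors = FALSE),
          data.frame(from = pmin(perm[-n], perm[-1L]),
                     to = pmax(perm[-n], perm[-1L]),
                     stringsAsFactors = FALSE)))
        if (nrow(edges) >= n - 1L) break
      }
      edges$capacity <- stats::runif(nrow(edges), 0, 10)
      capacity_graph(nodes, edges)
    })
}

#' Write a synthetic data set in the pipeline's input formats
#'
#' Emits MTX + gene/barcode sidecars for counts, spliced and unspliced
#' layers plus the annotation CSV, so a simulated run exercises the same
#' readers as real data.
#'
#' @param sim a [generate_differentiation()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_synthetic_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mtx_expression(sim$counts, file.path(dir, "counts.mtx"),
                       file.path(dir, "genes.tsv"),
                       file.path(dir, "barcodes.tsv"))
  write_mtx_expression(sim$spliced, file.path(dir, "spliced.mtx"),
                       file.path(dir, "genes.tsv"),
                       file.path(dir, "barcodes.tsv"))
  write_mtx_expression(sim$unspliced, file.path(dir, "unspliced.mtx"),
                       file.path(dir, "genes.tsv"),
                       file.path(dir, "barcodes.tsv"))
  write_annotations(sim$annotations, file.path(dir, "annotations.csv"))
  invisible(dir)
}
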