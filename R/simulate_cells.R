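#' Simulate a single-nucleus expression reference with planted markers
#'
#' Generates negative-binomial counts for a gene x cell matrix over the same
#' gene universe as the probe annotation. Each cell subtype has a disjoint
#' marker set whose mean expression is multiplied by `marker_fold` in that
#' subtype; the planted subtype's markers overlap the trait module's gene
#' pool by `module_marker_overlap` genes. Cells carry two annotation
#' granularities (broad class, subtype).
#'
#' @param config a [sim_config()].
#' @return list of class `cell_reference` with `expr` (genes x cells count
#'   matrix), `cells` (cell, class, subtype) and `truth` (enriched subtype,
#'   marker sets).
#' @export
#' @examples
#' ref <- simulate_cell_reference(sim_config(n_genes = 300, n_celltypes = 3,
#'                                           cells_per_type = 40, seed = 2))
#' dim(ref$expr)
simulate_cell_reference <- function(config) {
  validate_sim_config(config)
  stop_if_not(config$n_celltypes >= 2, "need at least two cell types")
  with_seed(substream(config$seed, 2L), {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    pool <- genes[seq_len(config$trait_pool_size)]
    k <- config$n_celltypes
    subtypes <- sprintf("CT%d", seq_len(k))
    classes <- sprintf("Class%d", ceiling(seq_len(k) / 2))

    # disjoint marker sets; subtype CT1 is the planted (module-overlapping)
    # type: module_marker_overlap of its markers come from the trait pool
    markers <- vector("list", k); names(markers) <- subtypes
    used <- character(0)
    ov <- sample(pool, config$module_marker_overlap)
    extra <- sample(setdiff(genes, c(pool, used)),
                    config$markers_per_type - config$module_marker_overlap)
    markers[[1]] <- c(ov, extra); used <- markers[[1]]
    for (j in seq_len(k)[-1]) {
      markers[[j]] <- sample(setdiff(setdiff(genes, pool), used),
                             config$markers_per_type)
      used <- c(used, markers[[j]])
    }

    n_cells <- k * config$cells_per_type
    cell_ids <- sprintf("cell%05d", seq_len(n_cells))
    subtype_of <- rep(subtypes, each = config$cells_per_type)
    class_of <- rep(classes, each = config$cells_per_type)

    base_mu <- stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 1)
    expr <- matrix(0L, config$n_genes, n_cells,
                   dimnames = list(genes, cell_ids))
    for (j in seq_len(k)) {
      mu <- base_mu
      mu[genes %in% markers[[j]]] <- mu[genes %in% markers[[j]]] *
        config$marker_fold
      cols <- which(subtype_of == subtypes[j])
      expr[, cols] <- matrix(
        stats::rnbinom(config$n_genes * length(cols),
                       mu = rep(mu, length(cols)), size = 2),
        config$n_genes, length(cols))
    }

    structure(list(
      expr = expr,
      cells = data.frame(cell = cell_ids, class = class_of,
                         subtype = subtype_of, stringsAsFactors = FALSE),
      truth = list(enriched_celltype = subtypes[1],
                   enriched_class = classes[1],
                   markers = markers,
                   module_overlap_genes = ov)),
      class = "cell_reference")
  })
}
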