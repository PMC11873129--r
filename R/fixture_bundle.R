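#' Write a complete synthetic fixture bundle to disk
#'
#' Runs all three generators under `config` and writes every downstream
#' input in its external file format: per-region beta TSVs, metadata and
#' trait TSVs, probe annotation, expression MatrixMarket triplet with gene
#' and cell sidecars, whitespace-delimited summary statistics, dosage TSV,
#' longitudinal phenotype TSV and the planted-truth JSON. The genotype
#' generator is anchored to the trait module's CpG coordinates so the PRS
#' window refinement is exercised end to end. Re-running with the same
#' config reproduces byte-identical files.
#'
#' @param config a [sim_config()].
#' @param outdir existing writable directory; an error is raised (with no
#'   partial output) if it does not exist.
#' @return invisibly, the manifest: a list of file paths, the seed, and the
#'   truth file location.
#' @export
write_fixture_bundle <- function(config, outdir) {
  validate_sim_config(config)
  stop_if_not(dir.exists(outdir), "output directory does not exist: %s",
              outdir)
  study <- simulate_methylation_study(config)
  cells <- simulate_cell_reference(config)
  tm <- study$truth$trait_module_id
  cpgs <- if (is.na(tm)) NULL else study$annotation[
    study$truth$probe_module_truth[study$annotation$probe] == tm,
    c("chr", "pos")]
  cohort <- simulate_genetic_cohort(config, module_cpgs = cpgs)

  paths <- list()
  fp <- function(f) file.path(outdir, f)
  for (rg in names(study$betas)) {
    f <- sprintf("beta_%s.tsv", rg)
    write_matrix_tsv(study$betas[[rg]], fp(f))
    paths[[f]] <- f
  }
  utils::write.table(study$meta, fp("metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$traits, fp("traits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$annotation, fp("probe_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  Matrix::writeMM(Matrix::Matrix(cells$expr, sparse = TRUE),
                  fp("expression.mtx"))
  writeLines(rownames(cells$expr), fp("expression_genes.tsv"))
  utils::write.table(cells$cells, fp("expression_cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ss <- cohort$sumstats
  ss$BETA <- signif(ss$BETA, 8); ss$SE <- signif(ss$SE, 8)
  ss$P <- signif(ss$P, 8); ss$INFO <- signif(ss$INFO, 6)
  utils::write.table(ss, fp("sumstats.txt"), sep = " ", quote = FALSE,
                     row.names = FALSE)
  write_matrix_tsv(cohort$geno$dosage, fp("dosages.tsv"), id_col = "sample")
  utils::write.table(cohort$geno$variants, fp("variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$pheno, fp("phenotype_long.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  truth <- list(
    probe_module_truth = as.list(study$truth$probe_module_truth),
    trait_module_id = study$truth$trait_module_id,
    trait_region = study$truth$trait_region,
    trait_gene_pool = study$truth$trait_gene_pool,
    liability = as.list(round(study$truth$liability, 8)),
    enriched_celltype = cells$truth$enriched_celltype,
    module_overlap_genes = cells$truth$module_overlap_genes,
    causal_variants = cohort$truth$causal_variants,
    causal_in_window = cohort$truth$causal_in_window,
    genetic_liability = as.list(round(cohort$truth$liability, 8)))
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  for (f in c("metadata.tsv", "traits.tsv", "probe_annotation.tsv",
              "expression.mtx", "expression_genes.tsv",
              "expression_cells.tsv", "sumstats.txt", "dosages.tsv",
              "variants.tsv", "phenotype_long.tsv", "truth.json"))
    paths[[f]] <- f

  # file names are stored relative to the bundle so a bundle is portable
  # and byte-identical wherever it is written
  manifest <- list(seed = config$seed, files = paths,
                   truth_file = "truth.json",
                   regions = config$regions)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
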