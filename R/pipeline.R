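# End-to-end orchestration: preprocess -> network (per region) ->
# association -> enrichment (significant modules) -> PRS, with content-hash
# stage caching and a reproducibility report.

#' Pipeline configuration
#'
#' @param input_dir directory holding a fixture bundle (see
#'   [write_fixture_bundle()]) or files in the same formats.
#' @param outdir output directory (created if needed).
#' @param seed integer seed for the stochastic stages.
#' @param power optional per-region named soft-power override.
#' @param min_size,max_block,merge_cut module-detection parameters.
#' @param covariates metadata columns regressed out of the betas.
#' @param confounds metadata columns screened against module eigengenes
#'   before trait testing.
#' @param trait primary binary trait for probe-level and PRS analyses.
#' @param ewce_reps bootstrap replicates for cell-type enrichment.
#' @param prs_thresholds p-value thresholds for the score grid.
#' @param cox_threshold threshold whose scores enter the survival models.
#' @param use_cache reuse cached stage outputs when inputs and parameters
#'   are unchanged.
#' @param ... unknown keys are rejected.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, outdir, seed = 1, power = NULL,
                            min_size = 100, max_block = 10000,
                            merge_cut = 0.15,
                            covariates = c("age", "sex", "batch",
                                           "neun_prop", "pmi"),
                            confounds = c("braak_lb", "braak_nft"),
                            trait = "depression", ewce_reps = 10000,
                            prs_thresholds = c(1, 0.5, 0.05, 0.005, 5e-4,
                                               5e-5, 5e-6, 5e-7, 5e-8),
                            cox_threshold = 0.05, use_cache = TRUE, ...) {
  extra <- list(...)
  stop_if_not(length(extra) == 0, "unknown configuration keys: %s",
              paste(names(extra), collapse = ", "))
  structure(list(input_dir = input_dir, outdir = outdir, seed = seed,
                 power = power, min_size = min_size, max_block = max_block,
                 merge_cut = merge_cut, covariates = covariates,
                 confounds = confounds, trait = trait,
                 ewce_reps = ewce_reps, prs_thresholds = prs_thresholds,
                 cox_threshold = cox_threshold, use_cache = use_cache),
            class = "pipeline_config")
}

content_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f)
  unname(tools::md5sum(f))
}

cached_stage <- function(config, name, key, fun) {
  dir.create(file.path(config$outdir, "cache"), showWarnings = FALSE,
             recursive = TRUE)
  path <- file.path(config$outdir, "cache",
                    paste0(name, "-", content_hash(key), ".rds"))
  if (config$use_cache && file.exists(path)) return(readRDS(path))
  val <- fun()
  saveRDS(val, path)
  val
}

#' Run the full analysis pipeline
#'
#' Executes preprocess, per-region network construction and module
#' detection, module-trait association, cell-type enrichment for
#' Bonferroni-significant modules, and the base/refined PRS analysis with
#' survival modelling. Stages are cached by a content hash of their inputs
#' and parameters, so a rerun with identical inputs is a pure lookup.
#' When no module passes Bonferroni correction, the enrichment and PRS
#' stages are skipped with an explicit notice.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report` (per-stage outputs, parameters,
#'   notices, seed).
#' @export
run_pipeline <- function(config) {
  stop_if_not(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- jsonlite::read_json(file.path(config$input_dir,
                                            "manifest.json"),
                                  simplifyVector = TRUE)
  regions <- manifest$regions
  betas <- lapply(regions, function(rg)
    read_beta_matrix(file.path(config$input_dir,
                               sprintf("beta_%s.tsv", rg))))
  names(betas) <- regions
  meta <- utils::read.delim(file.path(config$input_dir, "metadata.tsv"),
                            stringsAsFactors = FALSE)
  traits <- utils::read.delim(file.path(config$input_dir, "traits.tsv"),
                              stringsAsFactors = FALSE)
  annotation <- utils::read.delim(
    file.path(config$input_dir, "probe_annotation.tsv"),
    colClasses = c(chr = "character"), stringsAsFactors = FALSE)
  notices <- character(0)

  ## stage: preprocess -----------------------------------------------------
  pre <- cached_stage(config, "preprocess",
                      list(betas, meta, config$covariates), function() {
    keep <- mad_variable_probes(betas)
    out <- list(probes = keep)
    out$betas <- lapply(regions, function(rg) {
      b <- betas[[rg]][keep, , drop = FALSE]
      m <- meta[meta$region == rg, , drop = FALSE]
      r <- residualize_covariates(b, m, config$covariates)
      fl <- pc_outlier_flags(r, n_pcs = min(4, ncol(r) - 1))
      r[, !fl$flagged, drop = FALSE]
    })
    names(out$betas) <- regions
    out
  })

  ## stage: network per region ---------------------------------------------
  net <- cached_stage(config, "network",
                      list(pre, config$power, config$min_size,
                           config$max_block, config$merge_cut), function() {
    lapply(regions, function(rg) {
      b <- pre$betas[[rg]]
      scan <- soft_threshold_scan(b)
      pw <- if (!is.null(config$power)) {
        if (!is.null(names(config$power))) config$power[[rg]]
        else config$power
      } else scan$selected
      asg <- detect_modules(b, pw, min_size = config$min_size,
                            max_block = config$max_block,
                            merge_cut = config$merge_cut)
      me <- if (any(asg != "grey")) module_eigengenes(b, asg) else NULL
      list(region = rg, power = pw, scan = scan$report,
           assignment = asg, eigengenes = me)
    }) |> stats::setNames(regions)
  })

  ## stage: association ----------------------------------------------------
  assoc <- cached_stage(config, "association",
                        list(net, traits, meta, config$confounds),
                        function() {
    res <- lapply(regions, function(rg) {
      if (is.null(net[[rg]]$eigengenes)) return(NULL)
      cf <- if (length(config$confounds))
        meta[meta$region == rg, c("sample", config$confounds)] else NULL
      module_trait_correlations(net[[rg]]$eigengenes, traits,
                                confounds = cf, region = rg)
    })
    do.call(rbind, Filter(Negate(is.null), res))
  })

  sig <- if (is.null(assoc)) NULL else
    assoc[assoc$significant, , drop = FALSE]
  enr <- NULL; prs_res <- NULL
  if (is.null(sig) || nrow(sig) == 0) {
    notices <- c(notices,
                 "no Bonferroni-significant module: enrichment and PRS stages skipped")
  } else {
    top <- sig[which.min(sig$p), ]
    asg <- net[[top$region]]$assignment
    mod_probes <- names(asg)[asg == top$module]

    ## stage: enrichment ---------------------------------------------------
    enr <- cached_stage(config, "enrichment",
                        list(mod_probes, config$ewce_reps, config$seed),
                        function() {
      expr <- read_expression_mtx(
        file.path(config$input_dir, "expression.mtx"),
        file.path(config$input_dir, "expression_genes.tsv"),
        file.path(config$input_dir, "expression_cells.tsv"))
      spec <- specificity_from_expression(expr$expr, expr$cells)
      genes <- map_probes_to_genes(mod_probes, annotation,
                                   background = pre$probes)
      ew <- lapply(names(spec), function(lv)
        tryCatch(ewce_bootstrap(genes$target_genes, spec[[lv]],
                                reps = config$ewce_reps,
                                seed = substream(config$seed, 11L)),
                 error = function(e)
                   data.frame(celltype = character(0),
                              sd_from_mean = numeric(0), p = numeric(0),
                              q = numeric(0), n_target_genes = integer(0),
                              note = conditionMessage(e)[0])))
      names(ew) <- names(spec)
      list(gene_set = genes$target_genes, ewce = ew,
           significant = lapply(ew, function(d)
             d$celltype[d$q < 0.05]))
    })

    ## stage: prs ----------------------------------------------------------
    prs_res <- cached_stage(config, "prs",
                            list(mod_probes, config$prs_thresholds,
                                 config$cox_threshold), function() {
      ss <- read_sumstats(file.path(config$input_dir, "sumstats.txt"))
      dos <- read_dosages(file.path(config$input_dir, "dosages.tsv"))
      var <- utils::read.delim(file.path(config$input_dir, "variants.tsv"),
                               colClasses = c(chr = "character"),
                               stringsAsFactors = FALSE)
      geno <- genotype_matrix(dos, var)
      pheno <- utils::read.delim(
        file.path(config$input_dir, "phenotype_long.tsv"),
        stringsAsFactors = FALSE)
      hs <- harmonize_sumstats(ss, geno)
      idx <- ld_clump(hs, geno)
      win <- module_windows(mod_probes, annotation)
      base <- compute_prs(geno, hs, idx, thresholds = config$prs_thresholds)
      refined <- compute_prs(geno, hs, idx,
                             thresholds = config$prs_thresholds,
                             restrict = win)
      et <- build_event_table(pheno)
      pcs <- genetic_pcs(geno)
      sexes <- pheno$sex[match(rownames(pcs), pheno$sample)]
      covs <- data.frame(sex = factor(sexes), pcs,
                         row.names = rownames(pcs))
      outcome <- et$binary[rownames(pcs)]
      names(outcome) <- rownames(pcs)
      r2 <- prs_trait_r2(list(base = base, refined = refined),
                         outcome[!is.na(outcome)],
                         covs[!is.na(outcome), , drop = FALSE])
      thc <- as.character(config$cox_threshold)
      cox <- lapply(list(base = base, refined = refined), function(sc) {
        v <- sc$scores[, thc]
        if (all(is.na(v))) return(NULL)
        cox_time_dependent(et, stats::setNames(v, rownames(sc$scores)))
      })
      km <- lapply(list(base = base, refined = refined), function(sc) {
        v <- stats::setNames(sc$scores[, thc], rownames(sc$scores))
        if (all(is.na(v))) return(NULL)
        km_percentile_strata(et, v)
      })
      list(harmonization = attr(hs, "harmonization"),
           n_index = length(idx), windows = as.data.frame(win)[, 1:3],
           association = r2, cox = cox, km = km,
           n_events = sum(et$events$event))
    })
  }

  structure(list(config = config, regions = regions,
                 preprocess = list(n_probes = length(pre$probes)),
                 network = lapply(net, function(x)
                   list(power = x$power,
                        n_modules = length(setdiff(unique(x$assignment),
                                                   "grey")))),
                 association = assoc, significant = sig,
                 enrichment = enr, prs = prs_res, notices = notices,
                 seed = config$seed),
            class = "run_report")
}

#' Write the run report as markdown and JSON
#'
#' The report records per-region module counts with their formatted
#' Bonferroni thresholds, the module-trait association table, enrichment
#' results, the PRS association grid, Cox/KM summaries, and seed
#' provenance.
#'
#' @param run a `run_report` from [run_pipeline()].
#' @param path output path stem; `<path>.md` and `<path>.json` are
#'   written.
#' @return invisibly, the report list written to JSON.
#' @export
write_run_report <- function(run, path) {
  md <- c("# Co-methylation pipeline run report", "",
          sprintf("seed: %d", run$seed), "", "## Modules per region", "")
  for (rg in run$regions) {
    n <- run$network[[rg]]$n_modules
    thr <- if (n > 0) format_sig_threshold(0.05 / n) else "NA"
    md <- c(md, sprintf("- %s: %d modules (power %s), Bonferroni P < %s",
                        rg, n, run$network[[rg]]$power, thr))
  }
  md <- c(md, "", "## Module-trait associations (significant)", "")
  if (!is.null(run$significant) && nrow(run$significant) > 0) {
    md <- c(md, utils::capture.output(print(run$significant)))
  } else md <- c(md, "none")
  if (length(run$notices))
    md <- c(md, "", "## Notices", "", paste("-", run$notices))
  if (!is.null(run$prs)) {
    md <- c(md, "", "## PRS association grid", "",
            utils::capture.output(print(run$prs$association)))
  }
  writeLines(md, paste0(path, ".md"))
  json <- list(seed = run$seed, regions = run$regions,
               network = run$network,
               n_stages_completed = sum(!vapply(
                 list(run$preprocess, run$network, run$association,
                      run$enrichment, run$prs), is.null, logical(1))),
               association = run$association,
               notices = run$notices)
  jsonlite::write_json(json, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(json)
}
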