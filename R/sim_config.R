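#' Configuration for the synthetic study generators
#'
#' Bundles every parameter of the three synthetic-data generators
#' ([simulate_methylation_study()], [simulate_cell_reference()],
#' [simulate_genetic_cohort()]) together with one master seed. The defaults
#' are the study conditions the package's tests and worked examples run
#' under; see the methods vignette for the rationale behind each value.
#'
#' @param n_samples donors per brain region.
#' @param n_probes total CpG probes on the synthetic array.
#' @param n_modules number of planted co-methylation modules.
#' @param module_sizes integer vector of planted module sizes
#'   (`sum(module_sizes) <= n_probes`; remaining probes are unstructured).
#' @param loading_sd magnitude of probe loadings on the module latent
#'   factor (0 disconnects probes from their module).
#' @param noise_sd standard deviation of probe-level Gaussian noise on the
#'   logit scale.
#' @param trait_module_r target correlation, in (-1, 1), between one
#'   module's latent factor and the binary trait's underlying liability.
#' @param covariate_effects named vector of per-covariate scales for
#'   probe-specific covariate weights (logit scale).
#' @param regions region labels; the first region carries the trait-linked
#'   module.
#' @param n_genes size of the gene-symbol universe shared by the probe
#'   annotation and the expression reference.
#' @param trait_pool_size number of gene symbols in the pool the trait
#'   module's annotation is preferentially drawn from.
#' @param n_celltypes number of cell subtypes in the expression reference.
#' @param cells_per_type nuclei simulated per subtype.
#' @param markers_per_type disjoint marker genes per subtype.
#' @param module_marker_overlap how many of the planted subtype's markers
#'   are drawn from the trait module's gene pool.
#' @param marker_fold fold-change of marker-gene mean expression in its own
#'   subtype (must be >= 1; 1 plants no signal).
#' @param n_variants number of biallelic variants in the genotype panel.
#' @param ld_block_len variants per LD block (independent across blocks).
#' @param ld_rho adjacent-variant latent correlation within a block
#'   (decays geometrically with distance).
#' @param variant_spacing_bp physical spacing between adjacent variants.
#' @param n_causal number of causal variants behind the liability.
#' @param causal_in_window_frac fraction of causal variants placed inside
#'   +/-1 Mb windows around trait-module CpG coordinates.
#' @param h2_liability liability-scale heritability in `[0, 1]`.
#' @param discovery_n effective sample size of the synthetic discovery GWAS.
#' @param n_target samples in the target (scored) cohort.
#' @param n_visits longitudinal visits per target sample (6-month spacing).
#' @param seed master integer seed; sub-streams for the three generators are
#'   derived by fixed offsets.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_probes = 400, module_sizes = c(60, 60), n_modules = 2)
#' cfg$trait_module_r
sim_config <- function(n_samples = 80,
                       n_probes = 2000,
                       n_modules = 3,
                       module_sizes = rep(200L, 3),
                       loading_sd = 1,
                       noise_sd = 0.5,
                       trait_module_r = 0.6,
                       covariate_effects = c(age = 0.15, sex = 0.2,
                                             batch = 0.2, neun_prop = 0.3,
                                             pmi = 0.1),
                       regions = c("SN", "FC", "CN"),
                       n_genes = 1200,
                       trait_pool_size = 250,
                       n_celltypes = 6,
                       cells_per_type = 100,
                       markers_per_type = 50,
                       module_marker_overlap = 40,
                       marker_fold = 5,
                       n_variants = 1000,
                       ld_block_len = 10,
                       ld_rho = 0.8,
                       variant_spacing_bp = 30000,
                       n_causal = 50,
                       causal_in_window_frac = 0.6,
                       h2_liability = 0.3,
                       discovery_n = 1e5,
                       n_target = 400,
                       n_visits = 9,
                       seed = 1) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_probes = as.integer(n_probes),
    n_modules = as.integer(n_modules),
    module_sizes = as.integer(module_sizes),
    loading_sd = loading_sd, noise_sd = noise_sd,
    trait_module_r = trait_module_r, covariate_effects = covariate_effects,
    regions = regions, n_genes = as.integer(n_genes),
    trait_pool_size = as.integer(trait_pool_size),
    n_celltypes = as.integer(n_celltypes),
    cells_per_type = as.integer(cells_per_type),
    markers_per_type = as.integer(markers_per_type),
    module_marker_overlap = as.integer(module_marker_overlap),
    marker_fold = marker_fold,
    n_variants = as.integer(n_variants),
    ld_block_len = as.integer(ld_block_len), ld_rho = ld_rho,
    variant_spacing_bp = as.integer(variant_spacing_bp),
    n_causal = as.integer(n_causal),
    causal_in_window_frac = causal_in_window_frac,
    h2_liability = h2_liability, discovery_n = discovery_n,
    n_target = as.integer(n_target), n_visits = as.integer(n_visits),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_if_not(length(cfg$module_sizes) == cfg$n_modules,
              "module_sizes must have length n_modules (%d)", cfg$n_modules)
  stop_if_not(sum(cfg$module_sizes) <= cfg$n_probes,
              "sum(module_sizes) = %d exceeds n_probes = %d",
              sum(cfg$module_sizes), cfg$n_probes)
  stop_if_not(cfg$loading_sd >= 0 && cfg$noise_sd >= 0,
              "loading_sd and noise_sd must be non-negative")
  stop_if_not(abs(cfg$trait_module_r) < 1,
              "trait_module_r must lie in (-1, 1)")
  stop_if_not(cfg$marker_fold >= 1, "marker_fold must be >= 1")
  stop_if_not(cfg$h2_liability >= 0 && cfg$h2_liability <= 1,
              "h2_liability must lie in [0, 1]")
  stop_if_not(cfg$causal_in_window_frac >= 0 && cfg$causal_in_window_frac <= 1,
              "causal_in_window_frac must lie in [0, 1]")
  stop_if_not(cfg$n_variants >= cfg$ld_block_len,
              "n_variants must be >= ld_block_len")
  stop_if_not(cfg$n_celltypes >= 2, "n_celltypes must be >= 2")
  stop_if_not(cfg$module_marker_overlap <= cfg$markers_per_type,
              "module_marker_overlap cannot exceed markers_per_type")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_samples, "samples/region,", x$n_probes, "probes,",
      x$n_modules, "modules; trait r =", x$trait_module_r,
      "; seed =", x$seed, "\n")
  invisible(x)
}
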