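#' Simulate a multi-region methylation study with planted modules
#'
#' Generates normalized beta matrices (probes x samples) for each brain
#' region, sample metadata, a clinical trait table and an Illumina-manifest
#' style probe annotation, together with the full planted truth. Member
#' probes of module m are a logistic squash of
#' `intercept + loading * L_m + covariate terms + noise`, where `L_m` is a
#' standard-normal latent factor over samples, so all betas lie in (0, 1).
#' Exactly one module's latent (module "M1", in the first region) has
#' correlation `trait_module_r` with the underlying liability of the binary
#' depression trait.
#'
#' @param config a [sim_config()].
#' @return a list of class `meth_study` with elements `betas` (named list of
#'   probes x samples matrices, one per region), `meta` (one row per
#'   sample x region), `traits` (one row per sample), `annotation`
#'   (probe, chr, pos, genes `;`-separated) and `truth` (planted module
#'   membership, trait module id/region, per-sample liability, trait gene
#'   pool).
#' @export
#' @examples
#' study <- simulate_methylation_study(
#'   sim_config(n_samples = 30, n_probes = 200, n_modules = 2,
#'              module_sizes = c(40, 40), regions = "SN", seed = 7))
#' range(study$betas$SN)
simulate_methylation_study <- function(config) {
  validate_sim_config(config)
  with_seed(substream(config$seed, 1L), {
    n <- config$n_samples
    p <- config$n_probes
    regions <- config$regions
    samples <- sprintf("S%03d", seq_len(n))
    probes <- sprintf("cg%07d", seq_len(p))

    # planted membership: modules first, remainder unstructured noise
    membership <- rep("noise", p)
    module_ids <- sprintf("M%d", seq_len(config$n_modules))
    at <- 1L
    for (m in seq_len(config$n_modules)) {
      membership[at:(at + config$module_sizes[m] - 1L)] <- module_ids[m]
      at <- at + config$module_sizes[m]
    }
    names(membership) <- probes

    # per-probe baseline and loadings (shared across regions, same array)
    intercept <- stats::rnorm(p, 0, 1.5)
    loading <- if (config$loading_sd == 0) rep(0, p) else
      sample(c(-1, 1), p, replace = TRUE) *
        abs(stats::rnorm(p, config$loading_sd, 0.1 * config$loading_sd))
    loading[membership == "noise"] <- 0

    # subject-level covariates (constant across regions) ...
    age <- pmin(95, pmax(50, stats::rnorm(n, 75, 8)))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    braak_lb <- sample(3:6, n, replace = TRUE)
    braak_nft <- sample(0:4, n, replace = TRUE)
    years_disease <- round(stats::rgamma(n, shape = 5, scale = 2.2), 1)

    # trait liability tied to module M1's latent in the first region
    r <- config$trait_module_r
    latents <- lapply(regions, function(rg)
      matrix(stats::rnorm(n * config$n_modules), n, config$n_modules,
             dimnames = list(samples, module_ids)))
    names(latents) <- regions
    L_trait <- if (config$n_modules > 0) latents[[1]][, 1] else
      stats::rnorm(n)  # no planted module: trait tied to a latent no probe sees
    liability <- r * L_trait + sqrt(1 - r^2) * stats::rnorm(n)
    depression <- as.integer(liability > stats::qnorm(0.6))  # ~40% prevalence
    premorbid <- integer(n)
    premorbid[depression == 1] <-
      stats::rbinom(sum(depression == 1), 1, 0.3)
    other <- vapply(c(dementia = 0.45, hallucinations = 0.3, anxiety = 0.35,
                      aggression = 0.2, sleep_disorder = 0.4),
                    function(pr) stats::rbinom(n, 1, pr),
                    integer(n))

    # per-probe covariate susceptibilities, scaled by covariate_effects
    eff <- config$covariate_effects
    W <- matrix(stats::rnorm(p * length(eff)), p, length(eff))
    W <- sweep(W, 2, eff, `*`)

    meta <- list(); betas <- list()
    for (rg in regions) {
      batch <- sample(c("A", "B"), n, replace = TRUE)
      neun <- stats::rbeta(n, 8, 14)            # neuronal proportion ~0.36
      pmi <- round(stats::rgamma(n, shape = 9, scale = 3.5), 1)
      Z <- cbind(age = as.numeric(scale(age)),
                 sex = as.numeric(sex == "M"),
                 batch = as.numeric(batch == "B"),
                 neun_prop = as.numeric(scale(neun)),
                 pmi = as.numeric(scale(pmi)))
      latent_part <- matrix(0, p, n)
      for (m in seq_len(config$n_modules)) {
        idx <- membership == module_ids[m]
        latent_part[idx, ] <- loading[idx] %o% latents[[rg]][, m]
      }
      logit <- intercept + latent_part + W %*% t(Z) +
        matrix(stats::rnorm(p * n, 0, config$noise_sd), p, n)
      beta <- stats::plogis(logit)
      dimnames(beta) <- list(probes, samples)
      betas[[rg]] <- beta
      meta[[rg]] <- data.frame(
        sample = samples, region = rg, age = round(age, 1), sex = sex,
        batch = batch, neun_prop = round(neun, 3), pmi = pmi,
        braak_lb = braak_lb, braak_nft = braak_nft,
        years_disease = years_disease, stringsAsFactors = FALSE)
    }

    annotation <- build_probe_annotation(probes, membership, config)

    traits <- data.frame(
      sample = samples, dementia = other[, "dementia"],
      hallucinations = other[, "hallucinations"], depression = depression,
      anxiety = other[, "anxiety"], aggression = other[, "aggression"],
      sleep_disorder = other[, "sleep_disorder"],
      premorbid_depression = premorbid, years_disease = years_disease,
      stringsAsFactors = FALSE)

    truth <- list(
      probe_module_truth = membership,
      trait_module_id = if (length(module_ids)) module_ids[1]
                        else NA_character_,
      trait_region = regions[1],
      liability = stats::setNames(liability, samples),
      trait_gene_pool = sprintf("G%04d", seq_len(config$trait_pool_size)),
      module_probes = split(probes, membership)[module_ids])

    structure(list(betas = betas, meta = do.call(rbind, meta),
                   traits = traits, annotation = annotation, truth = truth),
              class = "meth_study")
  })
}

# Probe annotation: module m probes sit together on chromosome m within a
# 6 Mb span (so +/-1 Mb windows are informative); noise probes scatter over
# the genome. Trait-module probes draw gene symbols preferentially from the
# designated trait gene pool.
build_probe_annotation <- function(probes, membership, config) {
  p <- length(probes)
  genes_all <- sprintf("G%04d", seq_len(config$n_genes))
  pool <- genes_all[seq_len(config$trait_pool_size)]
  rest <- setdiff(genes_all, pool)
  chr <- character(p); pos <- integer(p)
  module_ids <- sprintf("M%d", seq_len(config$n_modules))
  for (m in seq_len(config$n_modules)) {
    idx <- which(membership == module_ids[m])
    chr[idx] <- as.character(m)
    pos[idx] <- as.integer(round(stats::runif(length(idx), 10e6, 16e6)))
  }
  noise_idx <- which(membership == "noise")
  chr[noise_idx] <- as.character(sample(setdiff(1:22, seq_len(config$n_modules)),
                                        length(noise_idx), replace = TRUE))
  pos[noise_idx] <- as.integer(round(stats::runif(length(noise_idx), 1e6, 1e8)))
  genes <- vapply(seq_len(p), function(i) {
    k <- sample(1:3, 1)
    src <- if (length(module_ids) && membership[i] == module_ids[1])
      pool else rest
    paste(sample(src, k), collapse = ";")
  }, character(1))
  data.frame(probe = probes, chr = chr, pos = pos, genes = genes,
             stringsAsFactors = FALSE)
}
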