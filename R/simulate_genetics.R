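#' Simulate GWAS summary statistics, target genotypes and longitudinal
#' phenotypes with a partially window-localized polygenic liability
#'
#' Haplotypes are built in LD blocks of `ld_block_len` variants: within a
#' block, a latent Gaussian AR(1) with parameter `ld_rho` is thresholded at
#' each variant's allele frequency, so adjacent-variant correlation decays
#' geometrically; blocks are independent. A fraction
#' `causal_in_window_frac` of the `n_causal` causal variants lies inside
#' +/-1 Mb windows around trait-module CpG coordinates, the rest outside.
#' Summary statistics are the true per-allele effects plus sampling noise at
#' `discovery_n`, with an INFO column, a small fraction of strand-ambiguous
#' variants, and some rows reporting the effect for the panel's other allele
#' (exercising harmonization). Target-cohort liability is the standardized
#' genetic score scaled to `h2_liability` plus environment; longitudinal
#' GDS-like depression scores (integers 0-15) rise with liability, with a
#' visit-level motor (UPDRS-III-like) covariate.
#'
#' @param config a [sim_config()].
#' @param module_cpgs optional data.frame (chr, pos) of trait-module CpG
#'   coordinates; when `NULL` the generator plants its own (one per
#'   simulated chromosome).
#' @return list of class `genetic_cohort`: `sumstats` (SNP CHR BP A1 A2
#'   BETA SE P INFO), `geno` (a [genotype_matrix()]), `pheno` (sample,
#'   visit_month, GDS, UPDRS3, age, sex) and `truth` (causal variants,
#'   window flags, windows, per-sample liability).
#' @export
simulate_genetic_cohort <- function(config, module_cpgs = NULL) {
  validate_sim_config(config)
  with_seed(substream(config$seed, 3L), {
    nv <- config$n_variants
    if (is.null(module_cpgs)) {
      chrs <- as.character(1:5)
    } else {
      chrs <- sort(unique(as.character(module_cpgs$chr)))
    }
    per_chr <- diff(round(seq(0, nv, length.out = length(chrs) + 1)))
    chr <- rep(chrs, per_chr)
    bp <- integer(nv)
    cpg_list <- list()
    for (i in seq_along(chrs)) {
      idx <- which(chr == chrs[i])
      if (is.null(module_cpgs)) {
        start <- 1e6
        pos <- as.integer(start + (seq_along(idx) - 1) *
                            config$variant_spacing_bp)
        cpg_list[[i]] <- data.frame(chr = chrs[i],
                                    pos = as.integer(stats::median(pos)))
      } else {
        cp <- module_cpgs[as.character(module_cpgs$chr) == chrs[i], ,
                          drop = FALSE]
        lo <- max(1, min(cp$pos) - 2e6); hi <- max(cp$pos) + 2e6
        pos <- as.integer(round(seq(lo, hi, length.out = length(idx))))
        cpg_list[[i]] <- cp[, c("chr", "pos")]
      }
      bp[idx] <- pos
    }
    cpgs <- do.call(rbind, cpg_list)
    windows <- merge_cpg_windows(cpgs, flank_bp = 1e6)
    vr <- GenomicRanges::GRanges(chr, IRanges::IRanges(bp, bp))
    in_window <- IRanges::overlapsAny(vr, windows)

    ids <- sprintf("rs%06d", seq_len(nv))
    maf <- stats::runif(nv, 0.1, 0.5)

    # genotypes: two thresholded AR(1) haplotypes per sample
    n <- config$n_target
    dosage <- simulate_dosages(n, nv, maf, config$ld_block_len, config$ld_rho)
    samples <- sprintf("P%04d", seq_len(n))
    dimnames(dosage) <- list(samples, ids)

    # alleles: ~5% strand-ambiguous pairs (dropped downstream)
    safe <- rbind(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"),
                  c("C", "A"), c("G", "A"), c("C", "T"), c("G", "T"))
    amb <- rbind(c("A", "T"), c("C", "G"))
    pick <- stats::runif(nv) < 0.05
    al <- matrix("", nv, 2)
    al[!pick, ] <- safe[sample(nrow(safe), sum(!pick), replace = TRUE), ]
    al[pick, ] <- amb[sample(nrow(amb), sum(pick), replace = TRUE), ]

    # causal architecture: fixed-magnitude standardized effects with random
    # sign; z of a causal variant in the discovery GWAS is ~ N(+/-4, 1)
    b_std <- numeric(nv)
    n_in <- round(config$causal_in_window_frac * config$n_causal)
    cand_in <- which(in_window); cand_out <- which(!in_window)
    causal <- c(sample(cand_in, min(n_in, length(cand_in))),
                sample(cand_out, min(config$n_causal - n_in,
                                     length(cand_out))))
    b_std[causal] <- sample(c(-1, 1), length(causal), replace = TRUE) *
      4 / sqrt(config$discovery_n)

    b_allele <- b_std / sqrt(2 * maf * (1 - maf))
    se <- 1 / sqrt(2 * maf * (1 - maf) * config$discovery_n)
    bhat <- b_allele + stats::rnorm(nv, 0, se)
    pval <- 2 * stats::pnorm(-abs(bhat / se))
    info <- stats::runif(nv, 0.85, 1)

    # ~10% of rows report the effect for the panel's other allele
    flip <- stats::runif(nv) < 0.1 & !pick
    a1 <- ifelse(flip, al[, 2], al[, 1])
    a2 <- ifelse(flip, al[, 1], al[, 2])
    beta_rep <- ifelse(flip, -bhat, bhat)
    sumstats <- data.frame(SNP = ids, CHR = chr, BP = bp, A1 = a1, A2 = a2,
                           BETA = beta_rep, SE = se, P = pval, INFO = info,
                           stringsAsFactors = FALSE)

    geno <- genotype_matrix(dosage,
                            data.frame(id = ids, chr = chr, bp = bp,
                                       a1 = al[, 1], a2 = al[, 2],
                                       freq = maf, stringsAsFactors = FALSE))

    # liability: standardized genetic score scaled to h2 + environment
    G <- scale(dosage[, causal, drop = FALSE]) %*% b_std[causal]
    Gs <- if (stats::sd(G) > 0) as.numeric(scale(G)) else numeric(n)
    liability <- sqrt(config$h2_liability) * Gs +
      sqrt(1 - config$h2_liability) * stats::rnorm(n)

    pheno <- simulate_longitudinal(samples, liability, config$n_visits)

    structure(list(
      sumstats = sumstats, geno = geno, pheno = pheno,
      truth = list(causal_variants = ids[causal],
                   causal_in_window = in_window[causal],
                   variant_in_window = stats::setNames(in_window, ids),
                   windows = as.data.frame(windows)[, 1:3],
                   module_cpgs = cpgs,
                   liability = stats::setNames(liability, samples))),
      class = "genetic_cohort")
  })
}

simulate_dosages <- function(n, nv, maf, block_len, rho) {
  thr <- stats::qnorm(maf)
  hap <- function() {
    z <- matrix(stats::rnorm(n * nv), n, nv)
    if (block_len > 1 && rho > 0) {
      for (j in seq_len(nv)[-1]) {
        if ((j - 1) %% block_len != 0)  # block boundary resets the chain
          z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      }
    }
    sweep(z, 2, thr, `<`) + 0
  }
  hap() + hap()
}

simulate_longitudinal <- function(samples, liability, n_visits) {
  n <- length(samples)
  months <- 6 * (seq_len(n_visits) - 1)
  age0 <- round(stats::rnorm(n, 62, 8), 1)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  # latent depression trajectory: AR(1) noise around a liability-driven
  # rising mean, binned to the 0-15 integer GDS scale
  phi <- 0.6
  out <- vector("list", n)
  for (i in seq_len(n)) {
    e <- numeric(n_visits)
    e[1] <- stats::rnorm(1, 0, 1.2)
    for (t in seq_len(n_visits)[-1])
      e[t] <- phi * e[t - 1] + sqrt(1 - phi^2) * stats::rnorm(1, 0, 1.2)
    lat <- 3 + 1.2 * liability[i] + 0.10 * (seq_len(n_visits) - 1) + e
    gds <- pmin(15L, pmax(0L, as.integer(round(lat))))
    updrs <- pmax(0L, as.integer(round(18 + 0.5 * (seq_len(n_visits) - 1) +
                                         stats::rnorm(n_visits, 0, 4))))
    keep <- n_visits
    if (stats::runif(1) < 0.15) keep <- sample(2:n_visits, 1)  # dropout
    out[[i]] <- data.frame(
      sample = samples[i], visit_month = months[seq_len(keep)],
      GDS = gds[seq_len(keep)], UPDRS3 = updrs[seq_len(keep)],
      age = round(age0[i] + months[seq_len(keep)] / 12, 2), sex = sex[i],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# +/-flank windows around CpG coordinates, merged per chromosome
merge_cpg_windows <- function(cpgs, flank_bp) {
  gr <- GenomicRanges::GRanges(
    as.character(cpgs$chr),
    IRanges::IRanges(pmax(1, cpgs$pos - flank_bp), cpgs$pos + flank_bp))
  GenomicRanges::reduce(gr)
}
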