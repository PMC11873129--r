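# Clumping + thresholding polygenic scores, module-window refinement and
# trait-association testing.

#' Genotype panel container
#'
#' @param dosage samples x variants numeric matrix (dosages in `[0, 2]`,
#'   `NA` allowed).
#' @param variants data.frame with `id`, `chr`, `bp`, `a1` (counted
#'   allele), `a2` and optionally `freq`.
#' @return list of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants) {
  stop_if_not(ncol(dosage) == nrow(variants),
              "dosage columns (%d) and variant rows (%d) differ",
              ncol(dosage), nrow(variants))
  stop_if_not(!anyDuplicated(variants$id), "duplicate variant ids")
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

AMBIGUOUS <- c(AT = "A/T", TA = "T/A", CG = "C/G", GC = "G/C")

#' Harmonize GWAS summary statistics against a genotype panel
#'
#' Drops variants with INFO below `info_min`, drops strand-ambiguous
#' (A/T, C/G) variants, and aligns effect alleles with the panel's counted
#' allele, flipping the sign of the effect where the summary statistics
#' report the panel's other allele. Irresolvable allele mismatches are
#' dropped. Counts of dropped/flipped variants are attached as the
#' `"harmonization"` attribute.
#'
#' @param ss summary statistics (`SNP CHR BP A1 A2 BETA SE P INFO`).
#' @param geno a [genotype_matrix()].
#' @param info_min imputation-quality threshold (variants with
#'   `INFO < info_min` are removed).
#' @return harmonized summary statistics with `BETA` on the panel's
#'   counted allele.
#' @export
harmonize_sumstats <- function(ss, geno, info_min = 0.9) {
  need <- c("SNP", "A1", "A2", "BETA", "P", "INFO")
  stop_if_not(all(need %in% names(ss)), "summary statistics lack columns")
  n0 <- nrow(ss)
  ss <- ss[ss$INFO >= info_min, , drop = FALSE]
  n_info <- n0 - nrow(ss)
  amb <- paste0(ss$A1, ss$A2) %in% names(AMBIGUOUS)
  n_amb <- sum(amb)
  ss <- ss[!amb, , drop = FALSE]
  v <- geno$variants[match(ss$SNP, geno$variants$id), ]
  keep <- !is.na(v$id)
  ss <- ss[keep, , drop = FALSE]; v <- v[keep, , drop = FALSE]
  same <- ss$A1 == v$a1 & ss$A2 == v$a2
  flip <- ss$A1 == v$a2 & ss$A2 == v$a1
  bad <- !(same | flip)
  ss$BETA[flip] <- -ss$BETA[flip]
  tmp <- ss$A1[flip]; ss$A1[flip] <- ss$A2[flip]; ss$A2[flip] <- tmp
  out <- ss[!bad, , drop = FALSE]
  attr(out, "harmonization") <- list(
    dropped_info = n_info, dropped_ambiguous = n_amb,
    dropped_unmatched = sum(!keep) + sum(bad), flipped = sum(flip))
  out
}

#' Greedy LD clumping
#'
#' Sorts variants by ascending p (ties: smaller bp, then lexicographic
#' id), takes the best unclumped variant as an index, removes all variants
#' within `window_kb` of it on the same chromosome with dosage r-squared
#' above `r2_max`, and repeats.
#'
#' @param ss harmonized summary statistics.
#' @param geno a [genotype_matrix()].
#' @param r2_max LD threshold.
#' @param window_kb physical window (kb) around each index variant.
#' @return character vector of index variant ids.
#' @export
ld_clump <- function(ss, geno, r2_max = 0.1, window_kb = 1000) {
  common <- intersect(ss$SNP, geno$variants$id)
  stop_if_not(length(common) > 0,
              "no overlap between summary statistics and genotypes")
  ss <- ss[ss$SNP %in% common, , drop = FALSE]
  v <- geno$variants[match(ss$SNP, geno$variants$id), ]
  ord <- order(ss$P, v$bp, ss$SNP)
  ss <- ss[ord, , drop = FALSE]; v <- v[ord, , drop = FALSE]
  D <- geno$dosage[, ss$SNP, drop = FALSE]
  alive <- rep(TRUE, nrow(ss))
  index <- character(0)
  win <- window_kb * 1000
  for (i in seq_len(nrow(ss))) {
    if (!alive[i]) next
    index <- c(index, ss$SNP[i])
    near <- which(alive & v$chr == v$chr[i] & abs(v$bp - v$bp[i]) <= win)
    near <- setdiff(near, i)
    if (length(near)) {
      r2 <- suppressWarnings(
        stats::cor(D[, i], D[, near, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      drop <- near[!is.na(r2) & r2 > r2_max]
      alive[drop] <- FALSE
    }
    alive[i] <- FALSE
  }
  index
}

#' Genomic windows around module CpG sites
#'
#' Adds a `flank_bp` extension around each CpG coordinate (clamped at the
#' chromosome start) and merges overlapping intervals per chromosome.
#'
#' @param probes probe ids of the module.
#' @param annotation probe annotation with `probe`, `chr`, `pos`.
#' @param flank_bp extension in bp (default 1 Mb).
#' @return a [GenomicRanges::GRanges] of merged windows; the number of
#'   probes without coordinates is attached as attribute `"skipped"`.
#' @export
module_windows <- function(probes, annotation, flank_bp = 1e6) {
  ann <- annotation[match(probes, annotation$probe), ]
  skipped <- sum(is.na(ann$pos) | is.na(ann$chr))
  ann <- ann[!(is.na(ann$pos) | is.na(ann$chr)), , drop = FALSE]
  stop_if_not(nrow(ann) > 0, "no probe has coordinates")
  gr <- merge_cpg_windows(ann[, c("chr", "pos")], flank_bp)
  attr(gr, "skipped") <- skipped
  gr
}

#' Compute clumping + thresholding polygenic scores
#'
#' Per p-value threshold T, scores each sample over the clumped index
#' variants with `p <= T` (optionally restricted to genomic windows):
#' `score = sum(dosage * beta) / (2 * n_variants)` (average per counted
#' allele). Missing dosages are mean-imputed per variant. Thresholds with
#' zero variants yield `NA` scores.
#'
#' @param geno a [genotype_matrix()].
#' @param ss harmonized summary statistics.
#' @param index_set clumped index variant ids.
#' @param thresholds p-value thresholds.
#' @param restrict optional `GRanges` of windows to restrict variants to.
#' @param average divide by `2 * n_variants` (set `FALSE` for raw sums).
#' @return list of class `prs_scores`: `scores` (samples x thresholds
#'   matrix), `n_variants` (named vector), `variants` (list per
#'   threshold).
#' @export
compute_prs <- function(geno, ss, index_set,
                        thresholds = c(1, 0.5, 0.05, 0.005, 5e-4, 5e-5,
                                       5e-6, 5e-7, 5e-8),
                        restrict = NULL, average = TRUE) {
  thresholds <- sort(thresholds, decreasing = TRUE)
  ss <- ss[ss$SNP %in% index_set, , drop = FALSE]
  if (!is.null(restrict)) {
    v <- geno$variants[match(ss$SNP, geno$variants$id), ]
    vr <- GenomicRanges::GRanges(as.character(v$chr),
                                 IRanges::IRanges(v$bp, v$bp))
    ss <- ss[IRanges::overlapsAny(vr, restrict), , drop = FALSE]
  }
  D <- geno$dosage[, ss$SNP, drop = FALSE]
  if (anyNA(D)) {
    for (j in seq_len(ncol(D)))
      D[is.na(D[, j]), j] <- mean(D[, j], na.rm = TRUE)
  }
  tl <- as.character(thresholds)
  scores <- matrix(NA_real_, nrow(geno$dosage), length(thresholds),
                   dimnames = list(rownames(geno$dosage), tl))
  nv <- stats::setNames(integer(length(thresholds)), tl)
  used <- stats::setNames(vector("list", length(thresholds)), tl)
  for (j in seq_along(thresholds)) {
    sel <- ss$P <= thresholds[j]
    nv[j] <- sum(sel)
    used[[j]] <- ss$SNP[sel]
    if (nv[j] > 0) {
      s <- D[, sel, drop = FALSE] %*% ss$BETA[sel]
      scores[, j] <- if (average) s / (2 * nv[j]) else s
    }
  }
  if (all(nv == 0)) stop("no variant passes any threshold")
  structure(list(scores = scores, n_variants = nv, variants = used),
            class = "prs_scores")
}

#' Leading genetic principal components from dosages
#'
#' @param geno a [genotype_matrix()].
#' @param n number of components.
#' @return samples x n matrix of PC scores.
#' @export
genetic_pcs <- function(geno, n = 3) {
  D <- geno$dosage
  if (anyNA(D)) {
    for (j in seq_len(ncol(D)))
      D[is.na(D[, j]), j] <- mean(D[, j], na.rm = TRUE)
  }
  X <- scale(D, center = TRUE, scale = FALSE)
  sv <- svd(X, nu = n, nv = 0)
  pcs <- sv$u[, seq_len(n), drop = FALSE] %*% diag(sv$d[seq_len(n)], n)
  dimnames(pcs) <- list(rownames(D), paste0("PC", seq_len(n)))
  pcs
}

#' Incremental R-squared of polygenic scores for a binary outcome
#'
#' Linear model of the 0/1 outcome on covariates plus the PRS;
#' `incremental R2 = R2(full) - R2(covariates only)`; p from the Wald test
#' on the PRS coefficient; Benjamini-Hochberg FDR jointly across all
#' (score set x threshold) tests.
#'
#' @param score_sets named list of [compute_prs()] objects (e.g. `base`,
#'   `refined`).
#' @param outcome named binary 0/1 vector (names = sample ids).
#' @param covariates data.frame/matrix of covariates (e.g. sex and the
#'   first genetic PCs), rows aligned to samples by name.
#' @return data.frame score_set, threshold, n_variants, incremental_r2,
#'   p, q.
#' @export
prs_trait_r2 <- function(score_sets, outcome, covariates = NULL) {
  stop_if_not(is_binary01(outcome), "outcome must be binary 0/1")
  stop_if_not(length(unique(outcome[!is.na(outcome)])) == 2,
              "outcome is constant")
  samples <- names(outcome)
  if (is.null(covariates)) {
    X0 <- data.frame(row.names = samples)
    r2_0 <- 0
  } else {
    X0 <- as.data.frame(covariates)[
      match(samples, rownames(as.data.frame(covariates))), , drop = FALSE]
    stop_if_not(!anyNA(X0), "covariates must be complete")
    r2_0 <- summary(stats::lm(outcome ~ ., data = X0))$r.squared
  }
  rows <- list()
  for (sn in names(score_sets)) {
    sc <- score_sets[[sn]]$scores[samples, , drop = FALSE]
    nv <- score_sets[[sn]]$n_variants
    for (th in colnames(sc)) {
      if (all(is.na(sc[, th]))) {
        rows[[length(rows) + 1]] <- data.frame(
          score_set = sn, threshold = as.numeric(th),
          n_variants = unname(nv[th]), incremental_r2 = NA_real_,
          p = NA_real_, stringsAsFactors = FALSE)
        next
      }
      dat <- cbind(X0, PRS = sc[, th])
      fit <- stats::lm(outcome ~ ., data = dat)
      sm <- summary(fit)
      rows[[length(rows) + 1]] <- data.frame(
        score_set = sn, threshold = as.numeric(th),
        n_variants = unname(nv[th]),
        incremental_r2 = sm$r.squared - r2_0,
        p = sm$coefficients["PRS", 4], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out
}
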