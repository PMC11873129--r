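# Probe filtering, covariate residualization and sample-outlier flagging.

#' Select variable probes shared across brain regions
#'
#' Within each region, a probe is retained when its median absolute
#' deviation (MAD) across samples is strictly greater than the median MAD
#' of all probes in that region. The returned set is the intersection of
#' the per-region keep-sets, so only probes variable in every region enter
#' the network stage.
#'
#' @param betas_by_region a single probes x samples matrix or a (named)
#'   list of them, one per region. Regions must share probe ids.
#' @return character vector of retained probe ids.
#' @export
#' @examples
#' b <- matrix(runif(50), 10, 5, dimnames = list(paste0("cg", 1:10), NULL))
#' mad_variable_probes(b)
mad_variable_probes <- function(betas_by_region) {
  if (is.matrix(betas_by_region)) betas_by_region <- list(betas_by_region)
  stop_if_not(length(betas_by_region) >= 1, "need at least one region")
  shared <- Reduce(intersect, lapply(betas_by_region, rownames))
  stop_if_not(length(shared) > 0, "regions share no probe ids")
  keep <- lapply(betas_by_region, function(b) {
    b <- b[shared, , drop = FALSE]
    mads <- apply(b, 1, stats::mad)
    rownames(b)[mads > stats::median(mads)]
  })
  Reduce(intersect, keep)
}

#' Regress covariates out of a beta matrix
#'
#' Fits, per probe, an ordinary least squares regression of methylation on
#' the requested covariates (factors are treatment-coded against their
#' first level) and returns `intercept + residuals`, i.e. methylation
#' values controlled for the covariates and scaled like the raw values.
#' Output values may leave `[0, 1]`.
#'
#' @param beta probes x samples matrix.
#' @param meta data.frame with a `sample` column matching `colnames(beta)`
#'   and one column per covariate; covariates must be complete.
#' @param covariates character vector of covariate column names.
#' @return probes x samples matrix of adjusted methylation values.
#' @export
residualize_covariates <- function(beta, meta, covariates) {
  stop_if_not(all(covariates %in% names(meta)),
              "covariates absent from metadata: %s",
              paste(setdiff(covariates, names(meta)), collapse = ", "))
  meta <- meta[match(colnames(beta), meta$sample), , drop = FALSE]
  stop_if_not(!anyNA(meta[covariates]),
              "covariate columns must be complete for all samples")
  X <- stats::model.matrix(
    ~ ., data = as.data.frame(lapply(meta[covariates], function(v) {
      if (is.character(v)) factor(v) else v
    })))
  stop_if_not(nrow(X) > ncol(X),
              "need n_samples > n_covariates + 1 for residualization")
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  Y <- t(beta)                                  # samples x probes
  res <- Y - X %*% qr.coef(q, Y)
  coef1 <- qr.coef(q, Y)[1, ]                   # per-probe intercept
  t(res + rep(coef1, each = nrow(res)))
}

#' Flag outlying samples on leading principal components
#'
#' A reproducible surrogate for visual PC inspection: samples whose score
#' on any of the first `n_pcs` principal components lies more than
#' `sd_cut` standard deviations from that component's mean are flagged.
#' Flags are advisory; the caller decides removal.
#'
#' @param beta probes x samples matrix.
#' @param n_pcs number of leading components to inspect.
#' @param sd_cut z-score cutoff.
#' @return data.frame with sample, per-PC scores, and a logical `flagged`.
#' @export
pc_outlier_flags <- function(beta, n_pcs = 4, sd_cut = 3) {
  n <- ncol(beta)
  stop_if_not(n_pcs < n, "n_pcs (%d) must be smaller than n_samples (%d)",
              n_pcs, n)
  X <- scale(t(beta), center = TRUE, scale = FALSE)
  sv <- svd(X, nu = n_pcs, nv = 0)
  scores <- sv$u[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pcs)], n_pcs)
  z <- scale(scores)
  out <- data.frame(sample = colnames(beta), scores,
                    stringsAsFactors = FALSE)
  names(out)[1 + seq_len(n_pcs)] <- paste0("PC", seq_len(n_pcs))
  out$flagged <- apply(abs(z) > sd_cut, 1, any)
  out
}
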