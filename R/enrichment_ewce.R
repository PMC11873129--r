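# Expression specificity and the bootstrap cell-type enrichment test
# (with conditional, specificity-matched analysis).

#' Cell-type specificity from a single-nucleus expression matrix
#'
#' Drops genes with no overall expression, keeps genes with significant
#' differential expression between cell types (one-way F test on log1p
#' expression, Benjamini-Hochberg across genes, q < `fdr_cut`), and
#' returns per-level specificity matrices: mean expression per cell type
#' divided by the row sum of those means, so every row sums to 1.
#'
#' @param expr genes x cells count matrix.
#' @param cells data.frame with `cell`, `class` and `subtype` columns
#'   aligned to `colnames(expr)`.
#' @param fdr_cut differential-expression q-value threshold.
#' @param levels annotation granularities to compute.
#' @return list of class `specificity_set` with one gene x cell-type
#'   matrix per level and a `dropped` attribute.
#' @export
specificity_from_expression <- function(expr, cells, fdr_cut = 1e-5,
                                        levels = c("class", "subtype")) {
  stop_if_not(all(levels %in% names(cells)),
              "cell annotation lacks level column(s)")
  expr <- expr[rowSums(expr) > 0, , drop = FALSE]
  out <- list()
  for (lv in levels) {
    g <- factor(cells[[lv]][match(colnames(expr), cells$cell)])
    tab <- table(g)
    stop_if_not(all(tab >= 2), "cell type with < 2 cells at level '%s'", lv)
    p <- f_test_rows(log1p(expr), g)
    q <- stats::p.adjust(p, method = "BH")
    keep <- q < fdr_cut
    mu <- t(rowsum(t(expr[keep, , drop = FALSE]), g) / as.integer(tab))
    spec <- mu / rowSums(mu)
    out[[lv]] <- spec
  }
  structure(out, class = "specificity_set",
            dropped = sum(!keep))
}

# vectorized one-way F test across rows; zero within- and between-group
# variance yields p = 1 (uninformative gene)
f_test_rows <- function(Y, g) {
  n <- ncol(Y); k <- nlevels(g)
  ng <- as.integer(table(g))
  gm <- t(rowsum(t(Y), g) / ng)            # genes x groups means
  m <- rowMeans(Y)
  ssb <- rowSums(sweep(gm, 1, m)^2 %*% diag(ng, k))
  sst <- rowSums(Y^2) - n * m^2
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[ssw == 0 & ssb > 0] <- 0
  p[sst <= .Machine$double.eps] <- 1
  p
}

#' Bootstrap expression-weighted cell-type enrichment
#'
#' For each cell type, the observed statistic is the mean specificity of
#' the target genes; the null distribution is the mean specificity of
#' random same-sized gene sets from the specificity matrix's gene
#' universe. `sd_from_mean = (obs - mean_null) / sd_null`;
#' `p = (1 + #[null >= obs]) / (reps + 1)`; q-values are
#' Benjamini-Hochberg across the cell types tested.
#'
#' @param target character vector of gene symbols (restricted to the
#'   specificity matrix's universe first; an error is raised when the
#'   overlap is empty).
#' @param spec gene x cell-type specificity matrix (one annotation level).
#' @param reps bootstrap replicates.
#' @param seed integer seed.
#' @return data.frame celltype, sd_from_mean, p, q, n_target_genes.
#' @export
ewce_bootstrap <- function(target, spec, reps = 100000, seed = NULL) {
  ewce_conditional(target, spec, controlled = NULL, reps = reps,
                   seed = seed)
}

#' Conditional bootstrap cell-type enrichment
#'
#' Identical to [ewce_bootstrap()], except each null gene is
#' specificity-matched to a target gene in the controlled cell type: it is
#' drawn from the genes whose controlled-type specificity lies within one
#' bin width (the specificity range divided by `n_bins`) of the matched
#' gene's value, widened adaptively (with a warning) when a window holds
#' too few candidates. Null sets therefore reproduce the target's
#' controlled-type specificity profile at any universe size. With
#' `controlled = NULL` the window is the whole universe and the test
#' reduces exactly to the unconditional bootstrap.
#'
#' @inheritParams ewce_bootstrap
#' @param controlled cell type (column of `spec`) whose signal is
#'   controlled for, or `NULL`.
#' @param n_bins granularity of specificity matching (candidate windows
#'   span the specificity range divided by `n_bins`).
#' @return data.frame celltype, sd_from_mean, p, q, n_target_genes.
#' @export
ewce_conditional <- function(target, spec, controlled, reps = 100000,
                             seed = NULL, n_bins = 10) {
  target <- unique(toupper(target))
  universe <- rownames(spec)
  ti <- which(universe %in% target)
  stop_if_not(length(ti) > 0,
              "no target gene present in the specificity matrix (overlap 0 of %d)",
              length(target))
  if (!is.null(controlled))
    stop_if_not(controlled %in% colnames(spec),
                "controlled cell type '%s' not in specificity matrix",
                controlled)
  G <- length(universe); m <- length(ti)

  samp <- with_seed(seed, {
    if (is.null(controlled)) {
      idx <- matrix(0L, m, reps)
      for (r in seq_len(reps)) idx[, r] <- sample.int(G, m)
      idx
    } else {
      s <- spec[, controlled]
      delta <- diff(range(s)) / n_bins
      widened <- FALSE
      picks <- matrix(0L, m, reps)
      for (j in seq_len(m)) {
        d <- delta
        repeat {
          cj <- which(abs(s - s[ti[j]]) <= d)
          if (length(cj) >= 5 || d >= diff(range(s))) break
          d <- 2 * d; widened <- TRUE
        }
        # linear importance weights calibrated so the window's weighted
        # mean equals the matched gene's specificity (unbiased matching)
        sc <- s[cj]; mbar <- mean(sc); v <- mean((sc - mbar)^2)
        w <- if (v > 0) pmax(1 + (s[ti[j]] - mbar) / v * (sc - mbar), 0)
             else rep(1, length(cj))
        if (sum(w) == 0) w <- rep(1, length(cj))
        picks[j, ] <- cj[sample.int(length(cj), reps, replace = TRUE,
                                    prob = w)]
      }
      if (widened)
        warning("some specificity windows had few candidates; widened")
      picks
    }
  })

  types <- colnames(spec)
  res <- lapply(types, function(ct) {
    s <- spec[, ct]
    null_means <- colMeans(matrix(s[samp], m, reps))
    obs <- mean(s[ti])
    sdn <- stats::sd(null_means)
    data.frame(celltype = ct,
               sd_from_mean = if (sdn > 0) (obs - mean(null_means)) / sdn
                              else 0,
               p = (1 + sum(null_means >= obs)) / (reps + 1),
               n_target_genes = m, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("celltype", "sd_from_mean", "p", "q", "n_target_genes")]
}
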