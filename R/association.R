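# Module eigengene / trait association, module membership, probe
# significance and the sensitivity analyses.

# all permutations of 1..n as an n!-row matrix (used for exact tests)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  m <- nrow(sub)
  out <- matrix(0L, n * m, n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * m + seq_len(m)
    out[rows, 1] <- i
    out[rows, -1] <- sub + (sub >= i)
  }
  out
}

#' Spearman correlation with tie-aware exact or asymptotic p-value
#'
#' The coefficient is Pearson's correlation of midranks. For `n <=
#' exact_n_max` the two-sided p-value is computed by complete enumeration
#' of the permutation distribution (on midranks, so ties are respected);
#' otherwise a t approximation on the midrank correlation is used.
#'
#' @param x,y numeric vectors (pairwise-complete observations are used).
#' @param exact_n_max enumeration cutoff.
#' @return list with `estimate`, `p.value`, `n` and `method`.
#' @export
#' @examples
#' spearman_test(c(1, 2, 3, 4), c(0, 0, 1, 1))$estimate  # 4 / sqrt(20)
spearman_test <- function(x, y, exact_n_max = 9) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stop_if_not(n >= 3, "need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant input; Spearman correlation undefined")
    return(list(estimate = NA_real_, p.value = 1, n = n,
                method = "degenerate"))
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_n_max) {
    P <- all_perms(n)
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    num <- matrix(ryc[P], nrow(P), n) %*% rxc
    rho_all <- num / sqrt(sum(rxc^2) * sum(ryc^2))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    method <- "t approximation"
  }
  list(estimate = rho, p.value = p, n = n, method = method)
}

# one module eigengene against one confound, by confound type
confound_p <- function(me, v) {
  if (is.numeric(v) && !is_binary01(v)) {
    stats::cor.test(me, v)$p.value
  } else if (length(unique(v[!is.na(v)])) == 2) {
    spearman_test(me, as.numeric(factor(v)))$p.value
  } else {
    stats::kruskal.test(me, factor(v))$p.value
  }
}

#' Correlate module eigengenes with clinical traits
#'
#' Binary traits use Spearman correlation (exact permutation p for small
#' n, t approximation otherwise); continuous traits use Pearson with a
#' t-based p. Modules retaining any confound association with p < 0.05 are
#' excluded before trait testing (and reported via the
#' `"excluded_modules"` attribute); the Bonferroni threshold is 0.05
#' divided by the number of surviving modules.
#'
#' @param eigengenes a [module_eigengenes()] object or samples x modules
#'   matrix.
#' @param traits data.frame with a `sample` column and trait columns;
#'   two-level 0/1 columns are treated as binary, others as continuous.
#' @param confounds optional data.frame of confound variables (one row per
#'   sample, aligned to the eigengene rows by a `sample` column).
#' @param region optional region label carried into the result.
#' @param alpha_confound screening level for confound exclusion.
#' @return data.frame (one row per surviving module x trait) with
#'   `region, module, trait, method, coefficient, p, bonferroni_threshold,
#'   significant`; attribute `excluded_modules` records screened-out
#'   modules.
#' @export
module_trait_correlations <- function(eigengenes, traits, confounds = NULL,
                                      region = NA_character_,
                                      alpha_confound = 0.05) {
  me <- if (inherits(eigengenes, "module_eigengenes"))
    eigengenes$eigengenes else eigengenes
  shared <- intersect(rownames(me), traits$sample)
  stop_if_not(length(shared) >= 10,
              "eigengenes and traits share only %d samples (< 10)",
              length(shared))
  me <- me[shared, , drop = FALSE]
  traits <- traits[match(shared, traits$sample), , drop = FALSE]

  excluded <- data.frame(module = character(0), confound = character(0),
                         p = numeric(0))
  mods <- colnames(me)
  if (!is.null(confounds)) {
    cf <- confounds[match(shared, confounds$sample), , drop = FALSE]
    cf$sample <- NULL
    for (m in mods) {
      for (cn in names(cf)) {
        pv <- suppressWarnings(confound_p(me[, m], cf[[cn]]))
        if (!is.na(pv) && pv < alpha_confound)
          excluded <- rbind(excluded,
                            data.frame(module = m, confound = cn, p = pv))
      }
    }
    mods <- setdiff(mods, unique(excluded$module))
  }
  thr <- if (length(mods)) 0.05 / length(mods) else NA_real_

  trait_cols <- setdiff(names(traits), "sample")
  rows <- list()
  for (m in mods) for (tr in trait_cols) {
    v <- traits[[tr]]
    ok <- !is.na(v)
    if (length(unique(v[ok])) < 2) {
      warning("trait '", tr, "' has a single level; skipped")
      next
    }
    if (is_binary01(v)) {
      st <- spearman_test(me[ok, m], v[ok])
      rows[[length(rows) + 1]] <- data.frame(
        region = region, module = m, trait = tr, method = "spearman",
        coefficient = st$estimate, p = st$p.value)
    } else {
      ct <- stats::cor.test(me[ok, m], v[ok])
      rows[[length(rows) + 1]] <- data.frame(
        region = region, module = m, trait = tr, method = "pearson",
        coefficient = unname(ct$estimate), p = ct$p.value)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = character(0), module = character(0),
               trait = character(0), method = character(0),
               coefficient = numeric(0), p = numeric(0))
  out$bonferroni_threshold <- thr
  out$significant <- !is.na(out$p) & !is.na(thr) & out$p < thr
  attr(out, "excluded_modules") <- excluded
  attr(out, "n_modules_tested") <- length(mods)
  out
}

#' Module membership (MM)
#'
#' Pearson correlation between each probe and the eigengene of the module
#' it is assigned to; grey probes receive no MM.
#'
#' @param beta probes x samples matrix.
#' @param eigengenes a [module_eigengenes()] object.
#' @param assignment named probe -> module vector.
#' @param ps optional named per-probe significance p-values to attach as
#'   `PS_p`.
#' @return data.frame probe, module, MM (and PS_p when supplied).
#' @export
module_membership <- function(beta, eigengenes, assignment, ps = NULL) {
  me <- eigengenes$eigengenes
  assignment <- assignment[rownames(beta)]
  keep <- assignment != "grey" & assignment %in% colnames(me)
  probes <- rownames(beta)[keep]
  mm <- vapply(probes, function(pr)
    stats::cor(beta[pr, ], me[, assignment[pr]]), numeric(1))
  out <- data.frame(probe = probes, module = unname(assignment[keep]),
                    MM = unname(mm), stringsAsFactors = FALSE)
  if (!is.null(ps)) out$PS_p <- unname(ps[probes])
  out
}

#' Probe significance (PS) against a binary trait
#'
#' Per-probe Spearman correlation p-value against the trait, using the
#' same estimator as the module-level tests (exact enumeration at small n,
#' t approximation otherwise). Constant probes get p = 1 with a warning.
#'
#' @param beta probes x samples matrix.
#' @param trait binary 0/1 vector aligned to `colnames(beta)`.
#' @return named vector of per-probe p-values.
#' @export
probe_significance <- function(beta, trait) {
  ok <- !is.na(trait)
  x <- beta[, ok, drop = FALSE]; tr <- trait[ok]
  n <- length(tr)
  stop_if_not(length(unique(tr)) == 2, "trait must have two levels")
  if (n <= 9) {
    return(vapply(rownames(x), function(pr)
      suppressWarnings(spearman_test(x[pr, ], tr))$p.value, numeric(1)))
  }
  rt <- rank(tr)
  R <- t(apply(x, 1, rank))
  const <- apply(x, 1, function(v) stats::sd(v) == 0)
  if (any(const)) warning(sum(const), " constant probe(s); p set to 1")
  rho <- suppressWarnings(as.numeric(stats::cor(t(R), rt)))
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  p[const | is.na(p)] <- 1
  stats::setNames(p, rownames(x))
}

#' Correlation between module membership and probe significance
#'
#' Pearson correlation of MM against -log10(PS p), the standard check that
#' trait association concentrates in well-connected module probes.
#'
#' @param membership data.frame from [module_membership()] containing `MM`
#'   and `PS_p` columns.
#' @return list with `r`, `p` and `n`.
#' @export
mm_ps_relation <- function(membership) {
  ok <- stats::complete.cases(membership$MM, membership$PS_p)
  mm <- membership$MM[ok]
  lp <- -log10(membership$PS_p[ok])
  stop_if_not(length(mm) >= 3, "need at least 3 probes with MM and PS")
  if (stats::sd(lp) == 0 || stats::sd(mm) == 0)
    stop("degenerate input: MM or PS values are constant")
  ct <- stats::cor.test(mm, lp)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(mm))
}

#' Pairwise group comparison of a module eigengene
#'
#' Optionally residualizes the eigengene on covariates (OLS; residuals plus
#' intercept), then runs all pairwise two-sided Wilcoxon rank-sum tests
#' between groups with Benjamini-Hochberg correction.
#'
#' @param me numeric eigengene vector.
#' @param groups factor (typically 3 levels) aligned with `me`.
#' @param regress_out optional data.frame of covariates to regress out
#'   first.
#' @return data.frame group1, group2, p, q.
#' @export
eigengene_group_test <- function(me, groups, regress_out = NULL) {
  groups <- factor(groups)
  if (!is.null(regress_out)) {
    fit <- stats::lm(me ~ ., data = as.data.frame(regress_out))
    me <- as.numeric(stats::residuals(fit) + stats::coef(fit)[1])
  }
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- me[groups == pairs[1, j]]; b <- me[groups == pairs[2, j]]
    if (length(a) < 2 || length(b) < 2) {
      warning("pair ", pairs[1, j], " vs ", pairs[2, j],
              " skipped (empty or singleton group)")
      next
    }
    pv <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL)$p.value)
    rows[[length(rows) + 1]] <- data.frame(
      group1 = pairs[1, j], group2 = pairs[2, j], p = pv,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
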