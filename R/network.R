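# Unsigned weighted co-methylation network: soft thresholding, adjacency,
# topological overlap, block-wise module detection and module eigengenes.

#' Unsigned adjacency matrix
#'
#' `a_ij = |cor(probe_i, probe_j)|^power` with unit diagonal, using Pearson
#' correlation across samples.
#'
#' @param beta probes x samples matrix (typically residualized).
#' @param power soft-threshold exponent.
#' @return symmetric probes x probes matrix with entries in `[0, 1]`.
#' @export
adjacency_matrix <- function(beta, power) {
  stop_if_not(nrow(beta) >= 2, "need at least two probes")
  sds <- apply(beta, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance probe(s): ",
         paste(utils::head(rownames(beta)[sds == 0], 5), collapse = ", "))
  A <- abs(stats::cor(t(beta)))^power
  diag(A) <- 1
  A
}

#' Topological overlap from an adjacency matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i` is the connectivity
#' of node i. `TOM_ii = 1`; the clustering dissimilarity is `1 - TOM`.
#'
#' @param A symmetric adjacency with unit diagonal and entries in `[0, 1]`.
#' @return symmetric similarity matrix.
#' @export
tom_from_adjacency <- function(A) {
  stop_if_not(isSymmetric(unname(A)), "adjacency must be symmetric")
  stop_if_not(all(A >= 0 & A <= 1), "adjacency entries must lie in [0, 1]")
  A0 <- A; diag(A0) <- 0
  L <- A0 %*% A0                       # l_ij includes no u = i or j terms
  k <- colSums(A0)
  kmin <- outer(k, k, pmin)
  tom <- (L + A0) / (kmin + 1 - A0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

#' Scan soft-threshold powers for scale-free topology fit
#'
#' For each power, builds the unsigned adjacency, computes connectivities
#' and the scale-free fit R^2 (regression of log10 density on log10
#' connectivity over equal-occupancy bins; positive slopes score 0).
#'
#' @param beta probes x samples matrix (>= 30 probes).
#' @param powers integer powers to scan.
#' @param n_bins bins for the degree-distribution fit.
#' @return list with `report` (power, scale_free_r2, slope, mean_k,
#'   median_k, max_k) and `selected` (see [pick_soft_power()]).
#' @export
soft_threshold_scan <- function(beta, powers = 1:20, n_bins = 10) {
  stop_if_not(nrow(beta) >= 30,
              "degree-distribution fit needs >= 30 probes")
  sds <- apply(beta, 1, stats::sd)
  stop_if_not(all(sds > 0), "constant probes have undefined correlation")
  C <- abs(stats::cor(t(beta)))
  diag(C) <- 0
  rows <- lapply(powers, function(pw) {
    A <- C^pw
    k <- colSums(A)
    data.frame(power = pw, scale_free_r2 = scale_free_fit(k, n_bins),
               slope = attr(scale_free_fit(k, n_bins), "slope") %||% NA_real_,
               mean_k = mean(k), median_k = stats::median(k),
               max_k = max(k))
  })
  report <- do.call(rbind, rows)
  list(report = report, selected = pick_soft_power(report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scale_free_fit <- function(k, n_bins = 10) {
  br <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 4) return(structure(0, slope = NA_real_))
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  cnt <- tabulate(bin, nbins = length(levels(bin)))
  width <- diff(br)
  kmean <- tapply(k, bin, mean)
  ok <- cnt > 0 & width > 0 & kmean > 0
  if (sum(ok) < 3) return(structure(0, slope = NA_real_))
  x <- log10(kmean[ok])
  y <- log10(cnt[ok] / (length(k) * width[ok]))
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  sl <- stats::coef(fit)[2]
  structure(if (is.na(sl) || sl > 0) 0 else r2, slope = unname(sl))
}

#' Select a soft-threshold power from a scan report
#'
#' The smallest power whose scale-free R^2 reaches `r2_min`; if none does,
#' the power maximizing R^2. A user override is always allowed downstream.
#'
#' @param report data.frame with `power` and `scale_free_r2` columns.
#' @param r2_min fit threshold.
#' @return selected integer power.
#' @export
#' @examples
#' pick_soft_power(data.frame(power = c(6, 8, 10),
#'                            scale_free_r2 = c(0.75, 0.85, 0.9)))
pick_soft_power <- function(report, r2_min = 0.8) {
  hit <- report$power[report$scale_free_r2 >= r2_min]
  if (length(hit)) min(hit) else report$power[which.max(report$scale_free_r2)]
}

#' Detect co-methylation modules
#'
#' Block-wise unsigned module detection: probes are pre-partitioned into
#' blocks of at most `max_block` (k-means on the top principal-component
#' loadings of the probe correlation structure, balanced), each block is
#' clustered by average linkage on `1 - TOM`, and the tree is cut by a
#' simplified dynamic rule: the static cut height maximizing the number of
#' clusters of size `>= min_size` (ties broken by probes covered, then by
#' the higher cut) is selected, and clusters larger than `3 * min_size`
#' are re-cut recursively by the same rule.
#' Candidate clusters smaller than `min_size`, or whose first-PC variance
#' share does not exceed twice the Marchenko-Pastur white-noise edge
#' (the cluster-validity guard), are assigned to `"grey"`. Members whose
#' absolute correlation with their module eigengene falls below `kme_min`
#' are pruned back to grey. Modules whose eigengenes correlate in absolute
#' value above `1 - merge_cut` are merged, and surviving modules are
#' relabelled by decreasing size along a fixed colour sequence.
#'
#' @param beta probes x samples matrix (residualized).
#' @param power soft-threshold power.
#' @param min_size minimum module size.
#' @param max_block maximum probes clustered in one block.
#' @param merge_cut eigengene merge cut (merge when |cor| > 1 - merge_cut).
#' @param kme_min minimum |module membership| for a probe to stay in its
#'   module.
#' @return named character vector probe -> module label ("grey" =
#'   unassigned), with the planted colour order by decreasing size.
#' @export
detect_modules <- function(beta, power, min_size = 100, max_block = 10000,
                           merge_cut = 0.15, kme_min = 0.3) {
  p <- nrow(beta)
  stop_if_not(min_size <= p, "min_size (%d) exceeds n_probes (%d)",
              min_size, p)
  blocks <- if (p > max_block) partition_blocks(beta, max_block)
            else list(seq_len(p))
  clusters <- list()
  for (idx in blocks) {
    if (length(idx) < 2) next
    A <- adjacency_matrix(beta[idx, , drop = FALSE], power)
    D <- 1 - tom_from_adjacency(A)
    cl <- cut_tree_simplified(D, min_size)
    clusters <- c(clusters, lapply(cl, function(i) idx[i]))
  }
  keep <- Filter(function(idx) {
    length(idx) >= min_size && module_ve_ok(beta[idx, , drop = FALSE])
  }, clusters)
  assignment <- rep("grey", p)
  names(assignment) <- rownames(beta)
  if (length(keep) == 0) return(assignment)

  # prune members weakly connected to their module eigengene
  keep <- lapply(keep, function(idx) {
    if (length(idx) < 2) return(idx)
    eg <- eigengene_of(beta[idx, , drop = FALSE])
    kme <- abs(as.numeric(stats::cor(t(beta[idx, , drop = FALSE]),
                                     eg$score)))
    idx[kme >= kme_min]
  })
  keep <- keep[lengths(keep) >= max(min_size, 1L)]
  if (length(keep) == 0) return(assignment)

  # eigengene-based merge of close (or block-split) modules
  keep <- merge_by_eigengene(beta, keep, merge_cut)
  keep <- keep[order(vapply(keep, length, integer(1)), decreasing = TRUE)]
  labels <- module_colors(length(keep))
  for (i in seq_along(keep)) assignment[keep[[i]]] <- labels[i]
  assignment
}

# Simplified dynamic cut: scan candidate static cut heights and keep the
# one yielding the most clusters of size >= min_size (ties broken by the
# number of probes those clusters cover, then by the higher cut, so
# complete modules are preferred). Clusters larger than 3 * min_size are
# re-cut recursively with the same rule; unstructured branches fail the
# variance-explained guard downstream and fall back to grey.
cut_tree_simplified <- function(D, min_size, depth = 0) {
  p <- nrow(D)
  if (p < 2) return(list(seq_len(p)))
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  hs <- sort(unique(hc$height))
  if (length(hs) > 64)
    hs <- hs[unique(round(seq(1, length(hs), length.out = 64)))]
  cuts <- c((utils::head(hs, -1) + utils::tail(hs, -1)) / 2,
            max(hs) * (1 + 1e-9))
  best <- NULL; best_score <- c(-1, -1, -Inf)
  for (h in cuts) {
    cl <- stats::cutree(hc, h = h)
    sizes <- tabulate(cl)
    n_mod <- sum(sizes >= min_size)
    covered <- sum(sizes[sizes >= min_size])
    score <- c(n_mod, covered, h)
    if (score[1] > best_score[1] ||
        (score[1] == best_score[1] && score[2] > best_score[2]) ||
        (score[1] == best_score[1] && score[2] == best_score[2] &&
           score[3] > best_score[3])) {
      best_score <- score; best <- cl
    }
  }
  groups <- split(seq_len(p), best)
  out <- list()
  for (g in groups) {
    if (length(g) > 3 * min_size && length(g) < p && depth < 20) {
      sub <- cut_tree_simplified(D[g, g, drop = FALSE], min_size, depth + 1)
      out <- c(out, lapply(sub, function(i) g[i]))
    } else out <- c(out, list(g))
  }
  out
}

# cluster-validity guard: first-PC variance share must exceed twice the
# Marchenko-Pastur edge (1 + sqrt(p/n))^2 / p expected for white noise
module_ve_ok <- function(x) {
  pc <- nrow(x); n <- ncol(x)
  if (pc < 2) return(TRUE)
  thr <- min(0.9, 2 * (1 + sqrt(pc / n))^2 / pc)
  ve <- eigengene_of(x)$variance_explained
  ve >= thr
}

partition_blocks <- function(beta, max_block) {
  p <- nrow(beta)
  k <- ceiling(p / max_block)
  Xs <- t(scale(t(beta)))                 # probes standardized
  nv <- max(2, min(8, ncol(beta) - 1, p - 1))
  # probe loadings on the top components of the correlation structure;
  # absolute values, since the network is unsigned and module members may
  # load on their factor with either sign
  sv <- svd(t(Xs), nu = 0, nv = nv)
  load <- abs(sv$v)
  km <- stats::kmeans(load, centers = k, nstart = 10, iter.max = 50)
  blocks <- split(seq_len(p), km$cluster)
  # balance: spill overflow into the smallest blocks
  repeat {
    sizes <- vapply(blocks, length, integer(1))
    if (all(sizes <= max_block)) break
    big <- which.max(sizes); small <- which.min(sizes)
    mv <- blocks[[big]][seq_len(sizes[big] - max_block)]
    blocks[[big]] <- setdiff(blocks[[big]], mv)
    blocks[[small]] <- c(blocks[[small]], mv)
  }
  blocks
}

merge_by_eigengene <- function(beta, groups, merge_cut) {
  repeat {
    if (length(groups) < 2) return(groups)
    me <- vapply(groups, function(idx)
      eigengene_of(beta[idx, , drop = FALSE])$score, numeric(ncol(beta)))
    cc <- abs(stats::cor(me)); diag(cc) <- 0
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) <= 1 - merge_cut) return(groups)
    merged <- c(groups[[mx[1]]], groups[[mx[2]]])
    groups <- c(groups[-c(mx[1], mx[2])], list(merged))
  }
}

# first-PC sample scores of a module (rows = probes), unit variance,
# oriented so the score correlates non-negatively with the module's mean
# methylation profile
eigengene_of <- function(x) {
  xc <- x - rowMeans(x)
  sv <- svd(t(xc), nu = 1, nv = 0)
  score <- sv$u[, 1] * sv$d[1]
  s <- stats::sd(score)
  score <- if (s > 0) score / s else score
  mp <- colMeans(x)
  cr <- suppressWarnings(stats::cor(score, mp))
  if (!is.na(cr) && cr < 0) score <- -score
  ve <- if (sum(sv$d^2) > 0) sv$d[1]^2 / sum(sv$d^2) else 0
  list(score = score, variance_explained = ve)
}

#' Module eigengenes
#'
#' Per module: probes are centred and the first right-singular-vector
#' sample scores are scaled to unit variance and sign-oriented so the
#' eigengene correlates non-negatively with the module's mean methylation
#' profile. A single-probe module's eigengene is the standardized probe.
#'
#' @param beta probes x samples matrix.
#' @param assignment named probe -> module vector from [detect_modules()];
#'   "grey" probes are ignored.
#' @return list of class `module_eigengenes` with `eigengenes` (samples x
#'   modules matrix) and `variance_explained` (named vector).
#' @export
module_eigengenes <- function(beta, assignment) {
  assignment <- assignment[rownames(beta)]
  mods <- setdiff(unique(assignment), "grey")
  mods <- mods[order(-table(assignment)[mods])]
  stop_if_not(length(mods) > 0, "no non-grey modules to summarize")
  scores <- matrix(NA_real_, ncol(beta), length(mods),
                   dimnames = list(colnames(beta), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    eg <- eigengene_of(beta[assignment == m, , drop = FALSE])
    scores[, m] <- eg$score
    ve[m] <- eg$variance_explained
  }
  structure(list(eigengenes = scores, variance_explained = ve),
            class = "module_eigengenes")
}
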