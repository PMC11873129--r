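# Eigengene-trait correlation, membership, probe significance, group tests.

test_that("Spearman on a binary trait equals the midrank hand computation", {
  st <- spearman_test(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(st$estimate, 4 / sqrt(20), tolerance = 1e-12)  # 0.8944
  # oracle: full enumeration of the 4! permutations with plain cor()
  perms <- expand.grid(rep(list(1:4), 4))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  y <- c(0, 0, 1, 1)
  rho_all <- apply(perms, 1, function(ix)
    cor(rank(c(1, 2, 3, 4)), rank(y[as.integer(ix)])))
  p_oracle <- mean(abs(rho_all) >= abs(st$estimate) - 1e-12)
  expect_equal(st$p.value, p_oracle, tolerance = 1e-6)
})

test_that("Spearman coefficient equals Pearson on midranks and matches cor.test", {
  set.seed(31)
  for (i in 1:5) {
    x <- sample(1:6, 20, replace = TRUE)   # heavy ties
    y <- rnorm(20)
    st <- spearman_test(x, y)
    expect_equal(st$estimate, cor(rank(x), rank(y)), tolerance = 1e-12)
    expect_equal(st$estimate,
                 suppressWarnings(cor.test(x, y, method = "spearman")$estimate[[1]]),
                 tolerance = 1e-12)
  }
})

make_me <- function(n, k, seed) {
  set.seed(seed)
  matrix(rnorm(n * k), n, k,
         dimnames = list(paste0("s", seq_len(n)), paste0("ME", seq_len(k))))
}

test_that("module-trait correlations pick the right estimator and threshold", {
  set.seed(32)
  n <- 40
  me <- make_me(n, 4, 33)
  tr <- data.frame(sample = rownames(me),
                   depression = as.integer(me[, 1] + rnorm(n, 0, 0.5) > 0),
                   years_disease = me[, 2] * 0.8 + rnorm(n),
                   flat = 1L)
  expect_warning(res <- module_trait_correlations(me, tr), "single level")
  expect_equal(unique(res$method[res$trait == "depression"]), "spearman")
  expect_equal(unique(res$method[res$trait == "years_disease"]), "pearson")
  expect_equal(unique(res$bonferroni_threshold), 0.05 / 4)
  expect_true(all(res$significant == (res$p < 0.05 / 4)))
  expect_false("flat" %in% res$trait)
})

test_that("confounded modules are screened out before trait testing", {
  set.seed(34)
  n <- 40
  me <- make_me(n, 3, 35)
  conf <- data.frame(sample = rownames(me),
                     braak_lb = me[, 2] + rnorm(n, 0, 0.2))
  tr <- data.frame(sample = rownames(me),
                   depression = rbinom(n, 1, 0.5))
  res <- module_trait_correlations(me, tr, confounds = conf)
  excl <- attr(res, "excluded_modules")
  expect_true("ME2" %in% excl$module)
  expect_false("ME2" %in% res$module)
  expect_equal(unique(res$bonferroni_threshold),
               0.05 / attr(res, "n_modules_tested"))
})

test_that("Bonferroni keeps the family-wise error below 0.05 on null data", {
  any_sig <- vapply(1:100, function(s) {
    me <- make_me(30, 8, 400 + s)
    set.seed(s)
    tr <- data.frame(sample = rownames(me),
                     depression = rbinom(30, 1, 0.5))
    res <- module_trait_correlations(me, tr)
    any(res$significant)
  }, logical(1))
  expect_lte(mean(any_sig), 0.10)  # binomial slack around the nominal 0.05
})

test_that("module membership is the probe-eigengene correlation", {
  d <- make_factor_data(sizes = 20, n_noise = 0, n = 50, loading = 1,
                        noise = 0.4, seed = 36)
  asg <- setNames(rep("m", 20), rownames(d$x))
  me <- module_eigengenes(d$x, asg)
  x2 <- rbind(d$x, pos = me$eigengenes[, "m"], neg = -me$eigengenes[, "m"])
  asg2 <- c(asg, pos = "m", neg = "m")
  mm <- module_membership(x2, me, asg2)
  expect_equal(mm$MM[mm$probe == "pos"], 1, tolerance = 1e-10)
  expect_equal(mm$MM[mm$probe == "neg"], -1, tolerance = 1e-10)
  expect_true(all(abs(mm$MM) <= 1 + 1e-12))
})

test_that("true module members carry higher membership than noise probes", {
  d <- make_factor_data(sizes = 60, n_noise = 60, n = 80, loading = 1,
                        noise = 0.5, seed = 37)
  asg <- ifelse(d$labels == "M1", "m", "grey")
  me <- module_eigengenes(d$x, asg)
  mm_all <- vapply(rownames(d$x), function(p)
    abs(cor(d$x[p, ], me$eigengenes[, "m"])), numeric(1))
  expect_gt(mean(mm_all[d$labels == "M1"]), mean(mm_all[d$labels == "noise"]))
})

test_that("probe significance is calibrated and detects perfect association", {
  set.seed(38)
  n <- 80
  tr <- rbinom(n, 1, 0.5)
  b <- matrix(rnorm(500 * n), 500, n,
              dimnames = list(paste0("p", 1:500), paste0("s", 1:n)))
  ps <- probe_significance(b, tr)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  b2 <- rbind(b, hit = tr)
  ps2 <- probe_significance(b2, tr)
  expect_lt(ps2["hit"], 1e-15)
  b2["hit", ] <- 0.3
  expect_warning(ps3 <- probe_significance(b2, tr), "constant")
  expect_equal(unname(ps3["hit"]), 1)
})

test_that("probe significance at n = 4 matches the permutation enumeration", {
  b <- matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("p1", paste0("s", 1:4)))
  ps <- probe_significance(b, c(0, 0, 1, 1))
  expect_equal(unname(ps["p1"]), 8 / 24, tolerance = 1e-6)
})

test_that("MM-PS relation handles signal and degenerate inputs", {
  set.seed(39)
  mm <- data.frame(probe = paste0("p", 1:30), module = "m",
                   MM = runif(30, 0.2, 0.9))
  mm$PS_p <- 10^(-mm$MM)                 # exactly linear in -log10
  rel <- mm_ps_relation(mm)
  expect_equal(rel$r, 1, tolerance = 1e-10)
  mm$PS_p <- 0.5
  expect_error(mm_ps_relation(mm), "degenerate")
  expect_error(mm_ps_relation(mm[1:2, ]), "3 probes")
})

test_that("trait-linked modules show a positive MM-PS relation across seeds", {
  pos <- vapply(1:10, function(s) {
    d <- make_factor_data(sizes = 50, n_noise = 0, n = 80, loading = 1,
                          noise = 0.5, seed = 500 + s)
    set.seed(600 + s)
    L <- colMeans(d$x * sign(cor(t(d$x), colMeans(d$x))[, 1]))
    trait <- as.integer(L + rnorm(80, 0, 0.7) > 0)
    asg <- setNames(rep("m", 50), rownames(d$x))
    me <- module_eigengenes(d$x, asg)
    mm <- module_membership(d$x, me, asg,
                            ps = probe_significance(d$x, trait))
    mm$MM <- abs(mm$MM)
    mm_ps_relation(mm)$r > 0
  }, logical(1))
  expect_gte(sum(pos), 9)
})

test_that("pairwise group tests match the exact rank-sum distribution", {
  # complete separation of 3 vs 3: 2 of the 20 orderings are as extreme
  res <- eigengene_group_test(c(1, 2, 3, 11, 12, 13),
                              rep(c("a", "b"), each = 3))
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  # identical distributions -> p = 1
  res2 <- eigengene_group_test(rep(c(1, 2, 3), 2),
                               rep(c("a", "b"), each = 3))
  expect_equal(res2$p, 1)
  # three groups: q-values are the BH adjustment of the three p-values
  set.seed(40)
  me <- c(rnorm(10), rnorm(10, 2), rnorm(10, 4))
  g <- rep(c("low", "mid", "high"), each = 10)
  res3 <- eigengene_group_test(me, g)
  expect_equal(nrow(res3), 3)
  expect_equal(res3$q, p.adjust(res3$p, "BH"))
  expect_true(all(diff(res3$q[order(res3$p)]) >= -1e-12))
})

test_that("regressing covariates out of the eigengene changes the test input", {
  set.seed(41)
  g <- factor(rep(c("a", "b", "c"), each = 12))
  covar <- rnorm(36)
  me <- 2 * covar + rnorm(36, 0, 0.1) + as.integer(g)
  with_cov <- eigengene_group_test(me, g,
                                   regress_out = data.frame(covar = covar))
  without <- eigengene_group_test(me, g)
  expect_false(identical(with_cov$p, without$p))
})
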