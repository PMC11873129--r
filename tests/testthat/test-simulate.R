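# Synthetic-data generators: validity, planted structure, determinism.

test_that("sim_config rejects invalid study conditions", {
  expect_error(sim_config(n_probes = 100, module_sizes = c(60, 60),
                          n_modules = 2), "exceeds n_probes")
  expect_error(sim_config(h2_liability = 1.2), "h2_liability")
  expect_error(sim_config(marker_fold = 0.5), "marker_fold")
  expect_error(sim_config(trait_module_r = 1), "trait_module_r")
  expect_error(sim_config(n_variants = 5, ld_block_len = 10),
               "ld_block_len")
})

small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_samples = 40, n_probes = 160, n_modules = 1,
         module_sizes = 50L, regions = "SN", n_genes = 300,
         trait_pool_size = 80, seed = seed),
    list(...))
  do.call(sim_config, args)
}

test_that("methylation generator emits betas in (0,1) with consistent ids", {
  st <- simulate_methylation_study(small_cfg())
  b <- st$betas$SN
  expect_true(all(b > 0 & b < 1))
  expect_identical(rownames(b), st$annotation$probe)
  expect_setequal(names(st$truth$probe_module_truth), rownames(b))
  expect_true(all(st$truth$module_probes$M1 %in% rownames(b)))
  # premorbid depression implies depression
  expect_true(all(st$traits$depression[st$traits$premorbid_depression == 1]
                  == 1))
})

test_that("generators are pure functions of the config", {
  a <- simulate_methylation_study(small_cfg(seed = 9))
  b <- simulate_methylation_study(small_cfg(seed = 9))
  expect_identical(a$betas, b$betas)
  expect_identical(a$traits, b$traits)
  g1 <- simulate_genetic_cohort(small_cfg(seed = 3, n_variants = 100,
                                          n_target = 50, n_visits = 4))
  g2 <- simulate_genetic_cohort(small_cfg(seed = 3, n_variants = 100,
                                          n_target = 50, n_visits = 4))
  expect_identical(g1$geno$dosage, g2$geno$dosage)
  expect_identical(g1$pheno, g2$pheno)
})

test_that("trait_module_r = 0 gives a null eigengene-trait correlation", {
  cors <- vapply(1:50, function(s) {
    st <- simulate_methylation_study(small_cfg(seed = s,
                                               trait_module_r = 0))
    me <- module_eigengenes(st$betas$SN, st$truth$probe_module_truth)
    cor(me$eigengenes[, "M1"], st$traits$depression)
  }, numeric(1))
  se <- 1 / sqrt(40 - 3)
  expect_lt(abs(mean(cors)), 3 * se / sqrt(50))
})

test_that("zero loading disconnects module probes", {
  zero_cov <- c(age = 0, sex = 0, batch = 0, neun_prop = 0, pmi = 0)
  st <- simulate_methylation_study(small_cfg(seed = 2, n_samples = 100,
                                             loading_sd = 0,
                                             covariate_effects = zero_cov))
  b <- st$betas$SN[st$truth$module_probes$M1, ]
  cc <- cor(t(b))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.1)
})

test_that("eigengene-liability Spearman converges to trait_module_r", {
  cors <- vapply(1:3, function(s) {
    cfg <- sim_config(n_samples = 2000, n_probes = 120, n_modules = 1,
                      module_sizes = 60L, regions = "SN", n_genes = 300,
                      trait_pool_size = 80, seed = s)
    st <- simulate_methylation_study(cfg)
    me <- module_eigengenes(st$betas$SN, st$truth$probe_module_truth)
    abs(cor(me$eigengenes[, "M1"], st$truth$liability,
            method = "spearman"))
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.6), 0.05)
})

test_that("cell reference plants fold-change markers with module overlap", {
  cfg <- sim_config(n_genes = 400, trait_pool_size = 100, n_celltypes = 3,
                    cells_per_type = 50, markers_per_type = 30,
                    module_marker_overlap = 20, seed = 4)
  ref <- simulate_cell_reference(cfg)
  expect_equal(dim(ref$expr), c(400, 150))
  mk <- ref$truth$markers
  expect_length(unique(unlist(mk)), 3 * 30)  # disjoint marker sets
  expect_true(all(ref$truth$module_overlap_genes %in%
                    sprintf("G%04d", 1:100)))
  # markers really are overexpressed in their own type
  m1 <- mk$CT1
  own <- rowMeans(ref$expr[m1, ref$cells$subtype == "CT1"])
  other <- rowMeans(ref$expr[m1, ref$cells$subtype != "CT1"])
  expect_gt(median(own / pmax(other, 0.1)), 2)
})

test_that("marker_fold = 1 plants no cell-type signal", {
  cfg <- sim_config(n_genes = 300, n_celltypes = 3, cells_per_type = 500,
                    markers_per_type = 20, module_marker_overlap = 10,
                    marker_fold = 1, seed = 6)
  ref <- simulate_cell_reference(cfg)
  # without differential expression the specificity rows are near-uniform
  mu <- t(rowsum(t(ref$expr), ref$cells$subtype) /
            as.integer(table(ref$cells$subtype)))
  mu <- mu[rowSums(mu) > 0, ]
  spec <- mu / rowSums(mu)
  expect_lt(max(abs(spec - 1 / 3)), 0.1)
})

test_that("genetic cohort respects dosage, GDS and LD-block structure", {
  cfg <- sim_config(n_variants = 100, ld_block_len = 5, n_target = 300,
                    n_visits = 5, seed = 8)
  coh <- simulate_genetic_cohort(cfg)
  expect_true(all(coh$geno$dosage %in% 0:2))
  expect_true(all(coh$pheno$GDS >= 0 & coh$pheno$GDS <= 15))
  expect_true(all(coh$pheno$GDS == round(coh$pheno$GDS)))
  expect_named(coh$sumstats,
               c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "INFO"))
  # adjacent variants inside a block are correlated, across blocks not
  D <- coh$geno$dosage
  within <- vapply(which(seq_len(99) %% 5 != 0), function(j)
    cor(D[, j], D[, j + 1]), numeric(1))
  expect_gt(mean(within^2), 0.2)
})

test_that("ld_block_len = 1 yields independent variants", {
  cfg <- sim_config(n_variants = 100, ld_block_len = 1, n_target = 500,
                    seed = 12)
  coh <- simulate_genetic_cohort(cfg)
  D <- coh$geno$dosage
  r2 <- vapply(seq_len(99), function(j) cor(D[, j], D[, j + 1])^2,
               numeric(1))
  expect_lt(mean(r2), 0.02)
})

test_that("zero heritability gives uniform PRS association p-values", {
  pv <- vapply(1:60, function(s) {
    cfg <- sim_config(n_variants = 60, ld_block_len = 3, n_target = 120,
                      n_visits = 4, h2_liability = 0, n_causal = 20,
                      seed = 1000 + s)
    coh <- simulate_genetic_cohort(cfg)
    hs <- harmonize_sumstats(coh$sumstats, coh$geno)
    idx <- ld_clump(hs, coh$geno)
    prs <- compute_prs(coh$geno, hs, idx, thresholds = 1)
    et <- build_event_table(coh$pheno)
    oc <- et$binary
    sc <- prs$scores[names(oc), 1]
    if (length(unique(oc)) < 2) return(NA_real_)
    summary(lm(oc ~ sc))$coefficients[2, 4]
  }, numeric(1))
  expect_gt(ks.test(pv[!is.na(pv)], "punif")$p.value, 0.01)
})

test_that("fixture bundles are reproducible and round-trip through readers", {
  cfg <- small_cfg(seed = 21, n_variants = 80, n_target = 60, n_visits = 4,
                   n_celltypes = 3, cells_per_type = 30,
                   markers_per_type = 20, module_marker_overlap = 10)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_fixture_bundle(cfg, d1)
  write_fixture_bundle(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  sums1 <- tools::md5sum(file.path(d1, f1))
  sums2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(sums1), unname(sums2))

  b <- read_beta_matrix(file.path(d1, "beta_SN.tsv"))
  expect_true(all(b > 0 & b < 1))
  ss <- read_sumstats(file.path(d1, "sumstats.txt"))
  expect_equal(nrow(ss), 80)
  dos <- read_dosages(file.path(d1, "dosages.tsv"))
  expect_true(all(dos %in% 0:2))
  ex <- read_expression_mtx(file.path(d1, "expression.mtx"),
                            file.path(d1, "expression_genes.tsv"),
                            file.path(d1, "expression_cells.tsv"))
  expect_equal(ncol(ex$expr), nrow(ex$cells))
  expect_error(write_fixture_bundle(cfg, file.path(d1, "missing", "dir")),
               "does not exist")
})
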