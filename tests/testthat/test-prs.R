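# Summary-statistic harmonization, clumping, windows, scoring, R2 grid.

test_that("harmonization applies the INFO boundary, flips and drops", {
  geno <- make_tiny_panel()
  ss <- data.frame(SNP = paste0("rs", 1:6), CHR = "1",
                   BP = geno$variants$bp,
                   A1 = c("A", "G", "A", "A", "A", "A"),
                   A2 = c("G", "A", "T", "G", "G", "C"),
                   BETA = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                   SE = 0.1, P = 0.5,
                   INFO = c(1, 1, 1, 0.90, 0.89, 1),
                   stringsAsFactors = FALSE)
  out <- harmonize_sumstats(ss, geno)
  h <- attr(out, "harmonization")
  expect_true("rs4" %in% out$SNP)          # INFO = 0.90 kept ("< 0.9" rule)
  expect_false("rs5" %in% out$SNP)         # INFO = 0.89 dropped
  expect_false("rs3" %in% out$SNP)         # A/T strand-ambiguous
  expect_false("rs6" %in% out$SNP)         # alleles unmatched
  expect_equal(out$BETA[out$SNP == "rs2"], -0.2)  # effect allele flipped
  expect_equal(out$A1[out$SNP == "rs2"], "A")
  expect_equal(h$flipped, 1)
  expect_equal(h$dropped_ambiguous, 1)
})

test_that("clumping keeps only the best variant in complete LD", {
  set.seed(70)
  g <- rbinom(80, 2, 0.4)
  dosage <- cbind(v1 = g, v2 = g, v3 = g)
  rownames(dosage) <- paste0("T", 1:80)
  geno <- genotype_matrix(dosage,
                          data.frame(id = c("v1", "v2", "v3"), chr = "1",
                                     bp = c(100, 200, 300), a1 = "A",
                                     a2 = "G"))
  ss <- data.frame(SNP = c("v1", "v2", "v3"), CHR = "1",
                   BP = c(100, 200, 300), A1 = "A", A2 = "G",
                   BETA = 0.1, SE = 0.1, P = c(1e-8, 1e-6, 1e-4),
                   INFO = 1)
  expect_equal(ld_clump(ss, geno), "v1")
  # mutually independent variants are all retained
  set.seed(71)
  dos2 <- sapply(1:5, function(i) rbinom(200, 2, 0.4))
  colnames(dos2) <- paste0("w", 1:5); rownames(dos2) <- paste0("T", 1:200)
  geno2 <- genotype_matrix(dos2, data.frame(id = paste0("w", 1:5),
                                            chr = "1",
                                            bp = seq(100, 500, 100),
                                            a1 = "A", a2 = "G"))
  ss2 <- data.frame(SNP = paste0("w", 1:5), CHR = "1",
                    BP = seq(100, 500, 100), A1 = "A", A2 = "G",
                    BETA = 0.1, SE = 0.1, P = runif(5), INFO = 1)
  expect_setequal(ld_clump(ss2, geno2), paste0("w", 1:5))
})

test_that("clumping matches a brute-force greedy oracle at 20 variants", {
  for (s in 1:3) {
    cfg <- sim_config(n_variants = 20, ld_block_len = 4, n_target = 150,
                      seed = 80 + s)
    coh <- simulate_genetic_cohort(cfg)
    ss <- coh$sumstats; geno <- coh$geno
    got <- ld_clump(ss, geno, r2_max = 0.1, window_kb = 1000)
    # independent oracle: literal greedy re-derivation from the full
    # r2 matrix, written with no shared code
    v <- geno$variants
    R2 <- cor(geno$dosage)^2
    ord <- ss$SNP[order(ss$P, v$bp[match(ss$SNP, v$id)], ss$SNP)]
    pool <- ord; keep <- character(0)
    while (length(pool)) {
      top <- pool[1]
      keep <- c(keep, top)
      ti <- match(top, v$id)
      pool <- pool[-1]
      drop <- vapply(pool, function(q) {
        qi <- match(q, v$id)
        v$chr[qi] == v$chr[ti] &&
          abs(v$bp[qi] - v$bp[ti]) <= 1e6 && R2[ti, qi] > 0.1
      }, logical(1))
      pool <- pool[!drop]
    }
    expect_identical(got, keep)
    # order invariance given the tie rule
    perm <- sample(nrow(ss))
    expect_identical(ld_clump(ss[perm, ], geno), got)
  }
})

test_that("module windows extend, merge and clamp CpG coordinates", {
  ann <- data.frame(probe = c("cgA", "cgB", "cgC", "cgD"),
                    chr = c("1", "2", "2", "3"),
                    pos = c(2e6, 5e6, 5.5e6, 4e5),
                    genes = "G1", stringsAsFactors = FALSE)
  w <- module_windows(c("cgA"), ann)
  expect_equal(GenomicRanges::start(w), 1e6)
  expect_equal(GenomicRanges::end(w), 3e6)
  # two CpGs 500 kb apart merge into one 2.5 Mb window
  w2 <- module_windows(c("cgB", "cgC"), ann)
  expect_equal(length(w2), 1)
  expect_equal(GenomicRanges::width(w2), 2.5e6 + 1)
  # clamped at the chromosome start
  w3 <- module_windows("cgD", ann)
  expect_equal(GenomicRanges::start(w3), 1)
})

test_that("PRS arithmetic, missing thresholds, monotonicity and linearity", {
  dosage <- matrix(c(0, 1, 2), 1, 3,
                   dimnames = list("S1", c("v1", "v2", "v3")))
  geno <- genotype_matrix(rbind(S1 = c(0, 1, 2), S2 = c(1, 1, 1)),
                          data.frame(id = c("v1", "v2", "v3"), chr = "1",
                                     bp = c(1e6, 2e6, 3e6), a1 = "A",
                                     a2 = "G"))
  ss <- data.frame(SNP = c("v1", "v2", "v3"), CHR = "1",
                   BP = c(1e6, 2e6, 3e6), A1 = "A", A2 = "G",
                   BETA = c(0.1, -0.2, 0.3), SE = 0.1,
                   P = c(0.04, 0.5, 0.001), INFO = 1)
  prs <- compute_prs(geno, ss, ss$SNP, thresholds = c(1, 0.05, 1e-6))
  expect_equal(unname(prs$scores["S1", "1"]),
               (0 * 0.1 + 1 * -0.2 + 2 * 0.3) / (2 * 3))  # 0.0667
  expect_equal(unname(prs$n_variants), c(3L, 2L, 0L))
  expect_true(all(is.na(prs$scores[, "1e-06"])))
  # restriction to a window keeps the in-window subset
  win <- GenomicRanges::GRanges("1", IRanges::IRanges(5e5, 1.5e6))
  prs_w <- compute_prs(geno, ss, ss$SNP, thresholds = 1, restrict = win)
  expect_equal(unname(prs_w$n_variants), 1L)
  # linearity: doubling betas doubles scores
  ss2 <- ss; ss2$BETA <- 2 * ss2$BETA
  prs2 <- compute_prs(geno, ss2, ss$SNP, thresholds = c(1, 0.05))
  expect_equal(prs2$scores, 2 * prs$scores[, c("1", "0.05")])
})

test_that("refined variant sets are subsets of base sets at every threshold", {
  cfg <- sim_config(seed = 90, n_variants = 300, n_target = 150)
  coh <- simulate_genetic_cohort(cfg)
  hs <- harmonize_sumstats(coh$sumstats, coh$geno)
  idx <- ld_clump(hs, coh$geno)
  win <- GenomicRanges::GRanges(coh$truth$windows$seqnames,
                                IRanges::IRanges(coh$truth$windows$start,
                                                 coh$truth$windows$end))
  base <- compute_prs(coh$geno, hs, idx)
  refined <- compute_prs(coh$geno, hs, idx, restrict = win)
  for (th in names(base$variants))
    expect_true(all(refined$variants[[th]] %in% base$variants[[th]]))
  expect_true(all(diff(rev(base$n_variants)) >= 0))  # monotone in threshold
})

test_that("incremental R2 is exact in the deterministic limit", {
  set.seed(91)
  outcome <- rep(c(0, 1), each = 20)
  names(outcome) <- paste0("S", 1:40)
  scores <- matrix(outcome, 40, 1, dimnames = list(names(outcome), "1"))
  fake <- structure(list(scores = scores,
                         n_variants = c("1" = 5L)), class = "prs_scores")
  res <- prs_trait_r2(list(base = fake), outcome)
  expect_equal(res$incremental_r2, 1, tolerance = 1e-12)
  expect_error(prs_trait_r2(list(base = fake),
                            setNames(rep(1, 40), names(outcome))),
               "constant")
})

test_that("null scores give small incremental R2 and calibrated p", {
  set.seed(92)
  n <- 150
  pv <- numeric(40); r2 <- numeric(40)
  for (i in 1:40) {
    outcome <- setNames(rbinom(n, 1, 0.4), paste0("S", 1:n))
    sc <- matrix(rnorm(n), n, 1, dimnames = list(names(outcome), "1"))
    fake <- structure(list(scores = sc, n_variants = c("1" = 10L)),
                      class = "prs_scores")
    res <- prs_trait_r2(list(b = fake), outcome,
                        covariates = data.frame(x = rnorm(n),
                                                row.names = names(outcome)))
    pv[i] <- res$p; r2[i] <- res$incremental_r2
  }
  expect_lt(abs(mean(r2) - 1 / n), 3 / n)
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})
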