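# Small fixture builders shared across test files.

# planted factor data: `sizes` module sizes plus `n_noise` unstructured
# probes over `n` samples; returns the matrix and the true labels
make_factor_data <- function(sizes, n_noise, n, loading = 1, noise = 0.5,
                             seed = 1) {
  set.seed(seed)
  p <- sum(sizes) + n_noise
  labels <- c(rep(paste0("M", seq_along(sizes)), sizes), rep("noise", n_noise))
  x <- matrix(rnorm(p * n, 0, noise), p, n)
  at <- 1
  for (m in seq_along(sizes)) {
    L <- rnorm(n)
    idx <- at:(at + sizes[m] - 1)
    sgn <- sample(c(-1, 1), sizes[m], replace = TRUE)
    x[idx, ] <- x[idx, ] + (loading * sgn) %o% L
    at <- at + sizes[m]
  }
  rownames(x) <- sprintf("p%04d", seq_len(p))
  colnames(x) <- sprintf("s%03d", seq_len(n))
  list(x = x, labels = setNames(labels, rownames(x)))
}

# adjusted Rand index between two labelings (independent of mclust)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# tiny genotype panel + matching summary statistics for PRS unit tests
make_tiny_panel <- function(n = 60, nv = 6, seed = 11) {
  set.seed(seed)
  dosage <- matrix(rbinom(n * nv, 2, 0.3), n, nv)
  rownames(dosage) <- sprintf("T%03d", seq_len(n))
  variants <- data.frame(id = sprintf("rs%d", seq_len(nv)),
                         chr = "1", bp = seq(1e6, by = 5e4, length.out = nv),
                         a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  genotype_matrix(dosage, variants)
}

# counting-process rows with one (0, t] interval per sample
simple_events <- function(time, event, x = NULL, seed = 2) {
  set.seed(seed)
  n <- length(time)
  data.frame(sample = sprintf("E%03d", seq_len(n)), start = 0, stop = time,
             event = event, age = rnorm(n, 62, 5), UPDRS3 = rnorm(n, 20, 4),
             sex = sample(c("F", "M"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}
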