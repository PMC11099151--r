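# Sweep scans: SFS projection, the sweep spectrum transform, CLR, the mu
# statistic, top-fraction selection and gene overlap.

test_that("hypergeometric projection matches combinatorial enumeration", {
  # project a site with 3 derived of 10 alleles down to 4
  got <- sfs_project(3, 10, 4)
  # enumerate all choose(10,4) subsamples directly
  combs <- utils::combn(10, 4)
  derived <- c(rep(1, 3), rep(0, 7))
  counts <- apply(combs, 2, function(idx) sum(derived[idx]))
  oracle <- tabulate(counts + 1L, nbins = 5) / ncol(combs)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("background SFS of a single site is a point mass", {
  dos <- matrix(0L, 5, 1)
  dos[1, 1] <- 2L
  dos[2, 1] <- 1L   # derived count 3 of n = 10
  gm <- toy_gm(dos, ancestral = "A")
  sfs <- background_sfs(gm)
  expect_equal(sfs$proportions[3], 1)
  expect_equal(sum(sfs$proportions), 1)
})

test_that("neutral spectra are close to the 1/j expectation", {
  sim <- small_panmictic(seed = 31, n = 10, L = 2e5)
  sfs <- background_sfs(sim$gm)
  expected <- (1 / seq_len(sfs$n - 1)) / sum(1 / seq_len(sfs$n - 1))
  # aggregate over the first five classes to tame Monte-Carlo noise
  expect_lt(max(abs(cumsum(sfs$proportions)[1:5] - cumsum(expected)[1:5])),
            0.08)
})

test_that("sweep transform limits: p_e = 1 is identity, p_e = 0 fixes", {
  sim <- small_panmictic(seed = 33, n = 8, L = 5e4)
  bg <- background_sfs(sim$gm)
  t1 <- sweep_sfs_transform(bg, bg$n, 1)
  expect_equal(t1[2:bg$n] / sum(t1[2:bg$n]), bg$proportions,
               tolerance = 1e-12)
  t0 <- sweep_sfs_transform(bg, bg$n, 0)
  expect_equal(t0[1] + t0[bg$n + 1], 1, tolerance = 1e-12)
})

test_that("sweep transform sums to one for all escape probabilities", {
  sim <- small_panmictic(seed = 35, n = 6, L = 5e4)
  bg <- background_sfs(sim$gm)
  for (pe in c(0, 0.1, 0.37, 0.5, 0.9, 1))
    expect_equal(sum(sweep_sfs_transform(bg, bg$n, pe)), 1,
                 tolerance = 1e-12)
})

test_that("sweep transform matches brute-force enumeration at n = 4", {
  # toy background over derived classes 1..3 at nb = 4
  bg <- structure(list(n = 4L, counts = c(5, 3, 2), folded = FALSE,
                       proportions = c(0.5, 0.3, 0.2)), class = "sfs")
  n <- 4; pe <- 0.5
  # oracle: enumerate escape configurations and sample draws exhaustively
  oracle <- numeric(n + 1)
  proj <- function(m) {
    out <- numeric(m + 1)
    for (j in 1:3) out <- out + bg$proportions[j] * dhyper(0:m, j, 4 - j, m)
    out
  }
  for (k in 0:n) {
    wk <- dbinom(k, n, pe)
    if (k == n) { oracle <- oracle + wk * proj(n); next }
    m <- k + 1
    q <- proj(m)
    for (j in 0:m) {
      if (j > 0) oracle[(j - 1) + (n - k) + 1] <-
          oracle[(j - 1) + (n - k) + 1] + wk * q[j + 1] * j / m
      if (j < m) oracle[j + 1] <- oracle[j + 1] + wk * q[j + 1] * (1 - j / m)
    }
  }
  expect_equal(sweep_sfs_transform(bg, n, pe), oracle, tolerance = 1e-12)
})

test_that("a denser alpha grid never decreases the maximised CLR", {
  sim <- small_panmictic(seed = 41, n = 10, L = 1e5)
  gm <- inject_sweep(sim$gm, "pop1", "chr1", 5e4, strength = 2e4, seed = 42)
  coarse <- clr_scan(gm, grid_step = 2e4, alpha_grid = 10^c(-5, -4, -3))
  fine <- clr_scan(gm, grid_step = 2e4,
                   alpha_grid = 10^seq(-5, -3, by = 0.25))
  expect_true(all(fine$value >= coarse$value - 1e-9))
  expect_true(all(coarse$value >= 0))
})

test_that("mu factors reproduce direct arithmetic on a toy window", {
  set.seed(51)
  k <- 10; n <- 8
  dos <- matrix(rbinom(4 * k, 2, 0.4), nrow = 4)
  derived <- colSums(dos)
  f <- mu_factors(derived, dos, span = 500, n = n, genome_length = 1e5,
                  total_snps = 1000)
  expect_equal(f$mu_var, (500 / 10) / (1e5 / 1000))
  frac_exp <- (1 + 1 / (n - 1)) / sum(1 / seq_len(n - 1))
  expect_equal(f$mu_sfs, (sum(derived %in% c(1, n - 1)) / k) / frac_exp)
  left <- dos[, 1:5]; right <- dos[, 6:10]
  wl <- mean(cor(left)[upper.tri(diag(5))]^2, na.rm = TRUE)
  wr <- mean(cor(right)[upper.tri(diag(5))]^2, na.rm = TRUE)
  ac <- mean(cor(left, right)^2, na.rm = TRUE)
  expect_equal(f$mu_ld, (wl + wr) / (2 * ac + 1e-6))
  expect_equal(f$mu, f$mu_var * f$mu_sfs * f$mu_ld)
})

test_that("mu normalisations equal one at genome-average inputs", {
  n <- 10
  # window density exactly at the genome average
  f <- mu_factors(derived = rep(2, 20),
                  dosages = matrix(rep(c(0L, 1L, 1L, 0L, 0L), 20), 5),
                  span = 2000, n = n, genome_length = 1e6,
                  total_snps = 1e4)
  expect_equal(f$mu_var, 1)
  # SFS fraction at its neutral expectation
  a1 <- sum(1 / seq_len(n - 1))
  k <- 50
  n_sing <- round(k * (1 + 1 / (n - 1)) / a1)
  derived <- c(rep(1, n_sing), rep(3, k - n_sing))
  f2 <- mu_factors(derived, matrix(rbinom(5 * k, 2, 0.5), 5), span = 100,
                   n = n, genome_length = 1e5, total_snps = 1000)
  expect_equal(f2$mu_sfs, (n_sing / k) / ((1 + 1 / (n - 1)) / a1))
})

test_that("top_fraction keeps ties and nests across thresholds", {
  st <- tibble::tibble(value = c(1:99, 100))
  expect_identical(nrow(top_fraction(st, 0.01)), 1L)
  top5 <- top_fraction(st, 0.05)
  top1 <- top_fraction(st, 0.01)
  expect_true(all(top1$value %in% top5$value))
  tied <- tibble::tibble(value = rep(7, 20))
  sel <- top_fraction(tied, 0.01)
  expect_identical(nrow(sel), 20L)
  expect_true(attr(sel, "all_tied"))
})

test_that("gene overlap agrees with a quadratic interval check", {
  set.seed(61)
  genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:30), chrom = "chr1",
                          start = sample.int(5e4, 30),
                          end = 0L)
  genes$end <- genes$start + sample(100:2000, 30)
  windows <- tibble::tibble(chrom = "chr1",
                            start = sample.int(5e4, 10), end = 0L)
  windows$end <- windows$start + sample(500:5000, 10)
  got <- overlap_genes(windows, genes)
  oracle <- genes$gene_id[vapply(seq_len(30), function(i)
    any(genes$start[i] <= windows$end &
          genes$end[i] >= windows$start + 1), TRUE)]
  expect_setequal(got$gene_id, oracle)
  # half-open window coordinates: adjacency is not overlap
  g1 <- tibble::tibble(gene_id = "g", chrom = "c", start = 11L, end = 20L)
  w_adj <- tibble::tibble(chrom = "c", start = 0L, end = 10L)
  expect_identical(nrow(overlap_genes(w_adj, g1)), 0L)
  w_in <- tibble::tibble(chrom = "c", start = 5L, end = 30L)
  expect_identical(nrow(overlap_genes(w_in, g1)), 1L)
  expect_identical(intersect_gene_lists(c("a", "b"), c("b", "c")), "b")
})
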