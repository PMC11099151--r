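# Permutation enrichment, Fisher/chi-squared tests, Wald association.

test_that("permuted intervals conserve lengths and chromosomes", {
  genome <- tibble::tibble(chrom = c("chr1", "chr2"),
                           length = c(1e5, 5e4))
  iv <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                       start = c(0, 5000, 100), end = c(1000, 7000, 600))
  perms <- permute_intervals(genome, iv, 20, seed = 4)
  widths <- perms$end - perms$start
  expect_true(all(widths == rep(c(1000, 2000, 500), 20)))
  expect_true(all(perms$chrom == rep(iv$chrom, 20)))
  expect_true(all(perms$start >= 0))
  expect_true(all(perms$end <= rep(c(1e5, 1e5, 5e4), 20)))
})

test_that("an interval as long as its chromosome is placed at zero", {
  genome <- tibble::tibble(chrom = "c", length = 100)
  iv <- tibble::tibble(chrom = "c", start = 0, end = 100)
  p <- permute_intervals(genome, iv, 5, seed = 1)
  expect_true(all(p$start == 0))
  too_long <- tibble::tibble(chrom = "c", start = 0, end = 101)
  expect_error(permute_intervals(genome, too_long, 5), "longer")
})

test_that("null overlap matches the uniform-placement expectation", {
  # one family occupying 10% of a uniform genome
  genome <- tibble::tibble(chrom = "c", length = 1e5)
  genes <- tibble::tibble(chrom = "c", start = 0, end = 1e4, family = "f")
  iv <- tibble::tibble(chrom = "c", start = rep(0, 40), end = rep(1, 40))
  perms <- permute_intervals(genome, iv, 200, seed = 9)
  frac <- mean(vapply(split(perms, perms$perm), function(p)
    clonepop:::count_class_overlaps(p, genes)[["f"]], 0)) / 40
  expect_lt(abs(frac - 0.1), 0.02)
})

test_that("empirical p follows the add-one formula at the extremes", {
  genome <- tibble::tibble(chrom = "c", length = 1e4)
  # family covering everything: observed overlap can never be beaten
  genes_all <- tibble::tibble(chrom = "c", start = 0, end = 1e4,
                              family = "f")
  iv <- tibble::tibble(chrom = "c", start = c(0, 100), end = c(50, 200))
  res <- family_enrichment(iv, genes_all, genome, n_perm = 100, seed = 2)
  expect_equal(res$p, 1)  # null always >= observed
  # family that the observed intervals miss but permutations may hit
  genes_off <- tibble::tibble(chrom = "c", start = 5000, end = 1e4,
                              family = "g")
  res2 <- family_enrichment(tibble::tibble(chrom = "c", start = 0,
                                           end = 10),
                            genes_off, genome, n_perm = 100, seed = 3)
  expect_gte(res2$p, 1 / 101)
  expect_lte(res2$p, 1)
})

test_that("tiny-genome empirical p converges to exhaustive enumeration", {
  # genome of 6 positions, interval of width 1: 6 equally likely placements
  genome <- tibble::tibble(chrom = "c", length = 6)
  genes <- tibble::tibble(chrom = "c", start = 0, end = 2, family = "f")
  iv <- tibble::tibble(chrom = "c", start = 0, end = 1)  # overlaps
  # exact null: placement start uniform on 0..5; overlap iff start < 2
  # observed overlap = 1; P(null >= 1) = 2/6
  res <- family_enrichment(iv, genes, genome, n_perm = 6000, seed = 5)
  exact <- (1 + 6000 * (2 / 6)) / 6001
  expect_lt(abs(res$p - exact), 0.02)
})

test_that("planted enrichment is detected at q < 0.05", {
  set.seed(31)
  genome <- tibble::tibble(chrom = "c", length = 1e5)
  fams <- purrr::map_dfr(1:5, function(f)
    tibble::tibble(chrom = "c",
                   start = (f - 1) * 20000 + seq(0, 18000, by = 2000),
                   end = (f - 1) * 20000 + seq(0, 18000, by = 2000) + 500,
                   family = paste0("f", f)))
  # intervals concentrated in family f1's territory (3x enrichment)
  iv <- tibble::tibble(chrom = "c",
                       start = c(sample(0:19000, 90, TRUE),
                                 sample(20000:99000, 60, TRUE)))
  iv$end <- iv$start + 200
  res <- family_enrichment(iv, fams, genome, n_perm = 1000, seed = 32)
  expect_lt(res$q[res$family == "f1"], 0.05)
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2)), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "negative")
  # random tables against base R's implementation of the same definition
  set.seed(41)
  for (i in 1:100) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("chi-squared enrichment matches the O-E arithmetic", {
  perfect <- matrix(c(10, 10, 10, 10), 2)
  res <- chisq_enrichment(perfect)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  tab <- matrix(c(12, 3, 5, 10), 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  oracle <- sum((tab - expected)^2 / expected)
  expect_equal(chisq_enrichment(tab)$statistic, oracle, tolerance = 1e-12)
  degenerate <- matrix(c(0, 0, 3, 5), 2)
  expect_warning(res0 <- chisq_enrichment(degenerate), "expected")
  expect_true(is.na(res0$statistic))
})

test_that("Wald association recovers simple linear effects", {
  y <- c(1, 1, 1, 1)
  g <- c(0, 1, 2, 1)
  # a perfectly linear response triggers lm's perfect-fit warning
  expect_equal(suppressWarnings(wald_association(y, g)$beta), 0,
               tolerance = 1e-12)
  g2 <- c(0, 1, 2, 0, 1, 2)
  expect_equal(suppressWarnings(wald_association(2 * g2, g2)$beta), 2,
               tolerance = 1e-10)
  expect_error(wald_association(c(1, 2, 3), c(1, 1, 1)), "constant")
  set.seed(51)
  betas <- replicate(100, {
    g <- rbinom(50, 2, 0.4)
    y <- 0.5 * g + rnorm(50, 0, 0.5)
    wald_association(y, g)$beta
  })
  expect_lt(abs(mean(betas) - 0.5) / 0.5, 0.1)
})
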