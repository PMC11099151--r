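# Diversity statistics: pi, Nei-Gojobori site counts, Tajima's D, r^2,
# LD decay and sliding windows.

test_that("per-site pi matches the closed form and pair enumeration", {
  expect_equal(per_site_pi(0, 10), 0)
  expect_equal(per_site_pi(2, 4), 2 * 0.25 * (4 / 3))
  set.seed(5)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    k <- sample(0:n, 1)
    alleles <- sample(c(rep(1, k), rep(0, n - k)))
    pairs <- utils::combn(n, 2)
    oracle <- mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
    expect_equal(per_site_pi(k, n), oracle, tolerance = 1e-12)
  }
})

test_that("region pi divides by callable length and honours exclusions", {
  gm <- toy_gm(matrix(c(0L, 1L, 1L, 2L), 4, 1), pos = 5L)
  # k = 4, n = 8 -> per-site pi = 2*(1/2)*(1/2)*8/7
  expect_equal(region_pi(gm, callable_length = 10), (4 / 7) / 10)
  excl <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L)
  expect_equal(region_pi(gm, callable_length = 10, exclude = excl), 0)
  expect_error(region_pi(gm, callable_length = 0), "positive")
})

test_that("Nei-Gojobori site counts match codon enumeration", {
  expect_equal(unname(count_ns_sites("ATG")), c(3, 0))
  expect_equal(unname(count_ns_sites("TTT")), c(8 / 3, 1 / 3))
  # random CDS: exhaustive enumeration over the 9 changes per codon
  code <- Biostrings::GENETIC_CODE
  set.seed(9)
  codons <- sample(setdiff(names(code), c("TAA", "TAG", "TGA")), 30,
                   replace = TRUE)
  cds <- paste(codons, collapse = "")
  oracle_S <- 0
  for (cd in codons) {
    aa <- code[[cd]]
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                     substring(cd, p, p))) {
      alt <- cd
      substring(alt, p, p) <- b
      if (code[[alt]] == aa) oracle_S <- oracle_S + 1 / 3
    }
  }
  got <- count_ns_sites(cds)
  expect_equal(unname(got["S_sites"]), oracle_S, tolerance = 1e-12)
  # totals conserve the CDS length exactly
  expect_equal(unname(sum(got)), nchar(cds), tolerance = 1e-12)
})

test_that("piN/piS reproduces hand-computed ratios on a planted fixture", {
  # 2 nonsyn SNPs and 1 syn SNP, all with per-site pi = 4/7 (k=4, n=8)
  gm <- toy_gm(matrix(rep(c(0L, 1L, 1L, 2L), 3), 4, 3))
  eff <- tibble::tibble(chrom = "chr1", pos = gm$sites$pos,
                        effect = c("nonsynonymous", "nonsynonymous",
                                   "synonymous"))
  res <- pin_pis(gm, eff, n_sites_total = 100, s_sites_total = 50)
  pi_site <- 4 / 7
  expect_equal(res$pi_n, 2 * pi_site / 100)
  expect_equal(res$pi_s, pi_site / 50)
  expect_equal(res$ratio, (2 * pi_site / 100) / (pi_site / 50))
  # no nonsynonymous SNPs -> ratio 0; no synonymous -> undefined
  res0 <- pin_pis(gm, dplyr::mutate(eff, effect = "synonymous"), 100, 50)
  expect_equal(res0$ratio, 0)
  resu <- pin_pis(gm, dplyr::mutate(eff, effect = "nonsynonymous"), 100, 50)
  expect_true(is.na(resu$ratio))
})

test_that("Tajima's D matches an independently coded textbook oracle", {
  oracle <- function(S, n, pi) {
    a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    (pi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
  }
  set.seed(3)
  for (i in 1:30) {
    n <- sample(4:40, 1)
    S <- sample(1:80, 1)
    pit <- runif(1, 0, S)
    expect_equal(tajimas_d(S, n, pit), oracle(S, n, pit), tolerance = 1e-12)
  }
  expect_true(is.na(tajimas_d(0, 10, 0)))
  expect_true(is.na(tajimas_d(5, 3, 1)))
})

test_that("neutral simulations give Tajima's D near zero on average", {
  ds <- unlist(lapply(1:4, function(s) {
    sim <- small_panmictic(seed = 200 + s, n = 12, L = 2e5)
    w <- sliding_windows(sim$gm, size = 2e4, step = 2e4, stat = "tajD")
    w$value
  }))
  expect_lt(abs(mean(ds, na.rm = TRUE)), 0.35)
})

test_that("genotype r^2 equals the squared Pearson correlation", {
  expect_equal(genotype_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_equal(genotype_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0)
  expect_true(is.na(genotype_r2(c(0, 0, 0), c(0, 1, 2))))
  set.seed(13)
  for (i in 1:20) {
    x <- rbinom(12, 2, 0.4); y <- rbinom(12, 2, 0.6)
    miss <- sample(12, 2)
    x[miss] <- NA
    ok <- !is.na(x)
    if (var(x[ok]) == 0 || var(y[ok]) == 0) next
    num <- sum((x[ok] - mean(x[ok])) * (y[ok] - mean(y[ok])))
    oracle <- num^2 / (sum((x[ok] - mean(x[ok]))^2) *
                         sum((y[ok] - mean(y[ok]))^2))
    expect_equal(genotype_r2(x, y), oracle, tolerance = 1e-12)
  }
})

test_that("decay distance interpolates linearly between bins", {
  curve <- tibble::tibble(bin_lo = c(0, 10000), bin_hi = c(10000, 20000),
                          mid = c(5000, 15000), mean_r2 = c(0.3, 0.1),
                          n_pairs = c(100, 100))
  curve <- structure(curve, max_dist = 2e4,
                     class = c("ld_curve", class(curve)))
  expect_equal(decay_distance_at(curve, 0.2), 10000)
})

test_that("curves that never reach the threshold are censored", {
  curve <- tibble::tibble(bin_lo = 0, bin_hi = 1e5, mid = 5e4,
                          mean_r2 = 0.25, n_pairs = 50)
  curve <- structure(curve, max_dist = 1e5,
                     class = c("ld_curve", class(curve)))
  d <- decay_distance_at(curve, 0.2)
  expect_true(is.infinite(d))
  expect_equal(attr(d, "censored_at"), 1e5)
})

test_that("ld_decay bin means lie in [0,1] and pair counts are conserved", {
  sim <- small_panmictic(seed = 77, n = 12, L = 1e5)
  curve <- ld_decay(sim$gm, max_dist = 5e4, bin_width = 5e3)
  ok <- !is.na(curve$mean_r2)
  expect_true(all(curve$mean_r2[ok] >= 0 & curve$mean_r2[ok] <= 1))
  # recount qualifying pairs directly
  d <- sim$gm$dosage
  maf <- {
    alt <- colSums(d); called <- 2 * nrow(d)
    pmin(alt, called - alt) / called
  }
  use <- which(maf >= 0.05)
  pos <- sim$gm$sites$pos[use]
  dist <- abs(outer(pos, pos, `-`))[upper.tri(diag(length(pos)))]
  cc <- cor(d[, use])^2
  ok_pair <- dist <= 5e4 & dist >= 1 & !is.na(cc[upper.tri(cc)])
  expect_equal(sum(curve$n_pairs), sum(ok_pair))
})

test_that("LD pruning is unnecessary for pi: invariance under relabeling", {
  sim <- small_panmictic(seed = 81, n = 8, L = 2e4)
  gm <- sim$gm
  shuffled <- subset_samples(gm, sample(rownames(gm$dosage)))
  expect_equal(region_pi(gm, callable_length = 2e4),
               region_pi(shuffled, callable_length = 2e4))
  # ref/alt swap leaves pi unchanged
  swapped <- gm
  swapped$dosage <- 2L - gm$dosage
  expect_equal(region_pi(gm, callable_length = 2e4),
               region_pi(swapped, callable_length = 2e4))
})

test_that("sliding windows are invariant to chromosome concatenation", {
  a <- small_panmictic(seed = 91, n = 6, L = 3e4)$gm
  b <- small_panmictic(seed = 92, n = 6, L = 3e4)$gm
  b$sites$chrom <- "chr2"
  b$chrom_lengths <- c(chr2 = 3e4)
  both <- genotype_matrix(cbind(a$dosage, b$dosage),
                          dplyr::bind_rows(a$sites, b$sites),
                          chrom_lengths = c(chr1 = 3e4, chr2 = 3e4))
  wa <- sliding_windows(a, 1e4, 1e4, "pi")
  wb <- sliding_windows(b, 1e4, 1e4, "pi")
  wboth <- sliding_windows(both, 1e4, 1e4, "pi")
  sep <- dplyr::bind_rows(wa, wb)
  expect_equal(wboth$value, sep$value)
  expect_equal(wboth$n_sites, sep$n_sites)
})

test_that("windows without SNPs report zero pi and missing D", {
  gm <- toy_gm(matrix(c(0L, 1L, 2L), 3, 1), pos = 500L, L = 30000)
  w_pi <- sliding_windows(gm, 1e4, 1e4, "pi")
  expect_equal(w_pi$value[2:3], c(0, 0))
  w_d <- sliding_windows(gm, 1e4, 1e4, "tajD")
  expect_true(all(is.na(w_d$value[2:3])))
})
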