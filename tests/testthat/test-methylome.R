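# Bisulfite analysis: non-conversion, binomial calling, wML, metagene
# profiles, population comparisons, clustering and Mantel concordance.

toy_report <- function(m, u, context = "CpG", chrom = "chr1") {
  tibble::tibble(chrom = chrom, pos = seq_along(m) * 10L, strand = "+",
                 m_reads = as.integer(m), u_reads = as.integer(u),
                 context = context, trinucleotide = "CGA")
}

test_that("non-conversion rate is the pooled methylated-read fraction", {
  ctl <- toy_report(c(rep(0, 199), 5), c(rep(5, 199), 0),
                    chrom = "chloroplast")
  expect_equal(nonconversion_rate(ctl), 5 / 1000)
  clean <- toy_report(rep(0, 150), rep(4, 150), chrom = "chloroplast")
  expect_equal(nonconversion_rate(clean), 0)
  expect_error(nonconversion_rate(toy_report(0, 5, chrom = "chloroplast")),
               "covered cytosines")
})

test_that("fixture recovers the generating non-conversion within 3 SE", {
  fx <- generate_methylome_fixture(1, nonconv = 0.005, seed = 3)
  r <- fx$samples[[1]]
  e <- nonconversion_rate(r)
  n_ctl <- sum(r$m_reads[r$chrom == "chloroplast"] +
                 r$u_reads[r$chrom == "chloroplast"])
  se <- sqrt(0.005 * 0.995 / n_ctl)
  expect_lt(abs(e - 0.005), 3 * se)
})

test_that("binomial tail probabilities match a direct sum", {
  # n = 10, m = 3, e = 0.01
  oracle <- sum(vapply(3:10, function(k)
    choose(10, k) * 0.01^k * 0.99^(10 - k), 0))
  rec <- toy_report(c(3, 0), c(7, 10))
  called <- call_methylated(rec, e = 0.01, adjust = "none")
  expect_equal(called$p[1], oracle, tolerance = 1e-12)
  expect_equal(oracle, 1.1e-4, tolerance = 0.05)
  expect_true(called$methylated[1])
  # m = 0 has p = 1 and stays unmethylated
  expect_equal(called$p[2], 1)
  expect_false(called$methylated[2])
})

test_that("calling drops low coverage and preserves total coverage", {
  rec <- toy_report(c(3, 1, 2), c(7, 2, 8))
  called <- call_methylated(rec, e = 0.005, min_cov = 5)
  expect_identical(nrow(called), 2L)         # coverage-3 site dropped
  expect_identical(sum(called$m_reads + called$u_reads), 20L)
  # reads supporting methylation at non-called sites are excluded
  expect_true(all(called$m_reads[!called$methylated] == 0))
  expect_error(call_methylated(rec, e = 1), "< 1")
})

test_that("false calls on a zero-methylation fixture are FDR-controlled", {
  fx <- generate_methylome_fixture(1, nonconv = 0.005, seed = 7,
                                   n_sites = 2000,
                                   prop_methylated = c(CpG = 0, CHG = 0,
                                                       CHH = 0))
  r <- fx$samples[[1]]
  called <- call_methylated(r, e = 0.005)
  expect_lte(mean(called$methylated), 0.05)
})

test_that("mc proportion counts methylated sites among covered sites", {
  rec <- toy_report(c(6, 0), c(4, 10))
  called <- call_methylated(rec, e = 0.005)
  expect_equal(mc_proportion(called, "CpG"), 0.5)
  expect_equal(mc_proportion(call_methylated(toy_report(0, 10), 0.005),
                             "CpG"), 0)
})

test_that("weighted methylation level follows its definition", {
  rec <- toy_report(c(3, 0), c(7, 8))
  expect_equal(weighted_ml(rec), 3 / 18)
  expect_equal(weighted_ml(toy_report(5, 0)), 1)
  expect_true(is.na(weighted_ml(rec, region = c("chr9", 0, 100))))
  # coverage-weighted identity: wML equals weighted mean of site levels
  set.seed(9)
  m <- rbinom(50, 20, 0.3); u <- 20 - m
  rec2 <- toy_report(m, u)
  lv <- m / (m + u)
  expect_equal(weighted_ml(rec2), weighted.mean(lv, m + u))
})

test_that("metagene profiles are flat for uniform methylation", {
  set.seed(11)
  pos <- seq(100, 20000, by = 37)
  rec <- tibble::tibble(chrom = "chr1", pos = pos, strand = "+",
                        m_reads = 3L, u_reads = 7L, context = "CpG",
                        trinucleotide = "CGA")
  feats <- tibble::tibble(chrom = "chr1", start = c(5000L, 12000L),
                          end = c(8000L, 15000L), strand = c("+", "-"))
  prof <- metagene_profile(rec, feats)
  expect_true(all(abs(prof$wml - 0.3) < 1e-12, na.rm = TRUE))
})

test_that("reversing feature strands reverses the profile exactly", {
  set.seed(13)
  pos <- sort(sample.int(30000, 800))
  rec <- tibble::tibble(chrom = "chr1", pos = pos, strand = "+",
                        m_reads = rbinom(800, 10, runif(800, 0, 0.6)),
                        u_reads = 10L, context = "CpG",
                        trinucleotide = "CGA")
  rec$u_reads <- 10L - rec$m_reads
  feats <- tibble::tibble(chrom = "chr1", start = 10000L, end = 16000L,
                          strand = "+")
  fwd <- metagene_profile(rec, feats)
  rev <- metagene_profile(rec, dplyr::mutate(feats, strand = "-"))
  expect_equal(fwd$wml, rev(rev$wml))
})

test_that("single-gene profile matches hand-binned values", {
  # gene body 1001..2000, flanks 2 kb, 20 body bins of 50 bp
  rec <- tibble::tibble(chrom = "chr1",
                        pos = c(500L, 1025L, 1975L, 2500L),
                        strand = "+",
                        m_reads = c(1L, 2L, 3L, 4L),
                        u_reads = c(9L, 8L, 7L, 6L),
                        context = "CpG", trinucleotide = "CGA")
  feats <- tibble::tibble(chrom = "chr1", start = 1001L, end = 2000L,
                          strand = "+")
  prof <- metagene_profile(rec, feats, flank = 2000, body_bins = 20,
                           flank_bins = 10)
  # pos 500: upstream distance 501 -> bin 10 - floor(501/200) = 8
  expect_equal(prof$wml[8], 0.1)
  # pos 1025: body offset 24/1000 -> body bin 1 -> overall bin 11
  expect_equal(prof$wml[11], 0.2)
  # pos 1975: body offset 974/1000 -> body bin 20 -> overall bin 30
  expect_equal(prof$wml[30], 0.3)
  # pos 2500: downstream offset 499 -> bin 31 + floor(499/200) = 33
  expect_equal(prof$wml[33], 0.4)
})

test_that("population wML comparisons control identical groups", {
  swml <- tibble::tibble(sample = paste0("s", 1:8),
                         population = rep(c("A", "B"), each = 4),
                         wml = rep(c(0.1, 0.2, 0.3, 0.4), 2))
  res <- suppressWarnings(compare_population_wml(swml))
  expect_true(all(res$pairwise$p_adj > 0.9))
  expect_identical(unname(res$letters$letters[1]),
                   unname(res$letters$letters[2]))
})

test_that("planted group shifts are detected by the rank-sum test", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    swml <- tibble::tibble(
      sample = paste0("s", 1:10),
      population = rep(c("lo", "hi"), each = 5),
      wml = c(rnorm(5, 0.10, 0.02), rnorm(5, 0.30, 0.02)))
    res <- compare_population_wml(swml)
    res$pairwise$p_adj[1] < 0.05
  }, TRUE)
  expect_gte(sum(hits), 9)
})

test_that("exact rank-sum p on n = (3,3) matches full enumeration", {
  x <- c(1.2, 2.9, 3.1); y <- c(0.7, 1.9, 2.4)
  got <- suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
  # enumerate all 20 assignments of ranks to the first group
  pooled <- c(x, y)
  W_obs <- sum(rank(pooled)[1:3]) - 6
  combs <- utils::combn(6, 3)
  Ws <- apply(combs, 2, function(idx) sum(rank(pooled)[idx]) - 6)
  p_exact <- mean(abs(Ws - 4.5) >= abs(W_obs - 4.5))
  expect_equal(got, p_exact, tolerance = 1e-12)
})

test_that("methylome clustering merges duplicated samples first", {
  set.seed(17)
  base <- runif(40, 0, 0.5)
  m <- rbind(s1 = base, s2 = base + 1e-6,
             s3 = runif(40, 0, 0.5), s4 = runif(40, 0.2, 0.9))
  cl <- methylome_clustering(m)
  first <- sort(-cl$hclust$merge[1, ])
  expect_identical(sort(cl$hclust$labels[first]), c("s1", "s2"))
  # region order invariance
  cl2 <- methylome_clustering(m[, sample(40)])
  expect_equal(cophenetic(cl$hclust), cophenetic(cl2$hclust))
  p <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, p)
  expect_identical(sort(ape::read.tree(p)$tip.label),
                   c("s1", "s2", "s3", "s4"))
})

test_that("Mantel concordance: identity, null and exact enumeration", {
  set.seed(19)
  d1 <- as.matrix(dist(matrix(runif(12), 4)))
  res <- tree_concordance(d1, d1, exact = TRUE)
  expect_equal(res$r, 1)
  # exact p at n = 4 equals enumeration over all 4! permutations
  d2 <- as.matrix(dist(matrix(runif(12), 4)))
  got <- tree_concordance(d1, d2, exact = TRUE)
  perms <- clonepop:::all_permutations(4)
  lt <- lower.tri(d1)
  r_obs <- cor(d1[lt], d2[lt])
  rs <- vapply(perms, function(p) {
    dp <- d2[p, p]; cor(d1[lt], dp[lt])
  }, 0)
  expect_equal(got$p, mean(rs >= r_obs - 1e-12))
  expect_identical(got$n_perm, length(perms))
  # independent matrices: permutation p is roughly uniform over seeds
  ps <- vapply(1:20, function(s) {
    set.seed(100 + s)
    a <- as.matrix(dist(matrix(runif(18), 6)))
    b <- as.matrix(dist(matrix(runif(18), 6)))
    tree_concordance(a, b, n_perm = 99, seed = s)$p
  }, 0)
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
  expect_error(tree_concordance(d1, as.matrix(dist(matrix(runif(9), 3)))),
               "size")
})

test_that("methylome clustering concords with genetic distance when
           methylation tracks the genotype", {
  set.seed(23)
  geno <- matrix(rbinom(6 * 200, 2, 0.4), nrow = 6,
                 dimnames = list(paste0("s", 1:6), NULL))
  gdist <- as.matrix(dist(geno))
  mprof <- geno[, 1:100] / 2 + matrix(rnorm(600, 0, 0.05), 6)
  mdist <- 1 - cor(t(mprof))
  ours <- tree_concordance(gdist, mdist, n_perm = 999, seed = 3)
  ref <- vegan::mantel(as.dist(gdist), as.dist(mdist),
                       permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
  expect_lt(ours$p, 0.05)
})
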