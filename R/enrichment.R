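#' Random re-placement null for genomic intervals
#'
#' Each permutation re-places every interval uniformly at random on its
#' own chromosome (length preserved; placed intervals may overlap each
#' other). With `cross_chromosome = TRUE` the destination chromosome is
#' drawn proportional to length among chromosomes that can hold the
#' interval.
#'
#' @param genome Tibble with `chrom`, `length`.
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param cross_chromosome Allow placement on other chromosomes?
#' @return Tibble of placements with a `perm` index column.
#' @export
permute_intervals <- function(genome, intervals, n_perm, seed = NULL,
                              cross_chromosome = FALSE) {
  widths <- intervals$end - intervals$start
  stopifnot(all(widths > 0))
  glen <- setNames(genome$length, genome$chrom)
  if (!cross_chromosome) {
    if (any(widths > glen[intervals$chrom]))
      abort("interval longer than its chromosome")
  } else if (any(widths > max(glen))) {
    abort("interval longer than every chromosome")
  }
  ni <- nrow(intervals)
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_perm), function(p) {
      if (cross_chromosome) {
        chroms <- vapply(widths, function(w) {
          ok <- names(glen)[glen >= w]
          sample(ok, 1, prob = glen[ok])
        }, "")
      } else {
        chroms <- intervals$chrom
      }
      max_start <- glen[chroms] - widths
      starts <- floor(runif(ni) * (max_start + 1))
      tibble::tibble(perm = p, chrom = chroms, start = starts,
                     end = starts + widths)
    })
  })
}

# number of intervals overlapping any feature of each class
count_class_overlaps <- function(intervals, features, class_col = "family") {
  classes <- sort(unique(features[[class_col]]))
  out <- setNames(integer(length(classes)), classes)
  for (cl in classes) {
    fs <- features[features[[class_col]] == cl, ]
    hit <- rep(FALSE, nrow(intervals))
    for (ch in unique(fs$chrom)) {
      fc <- fs[fs$chrom == ch, ]
      ic <- which(intervals$chrom == ch)
      if (!length(ic)) next
      fr <- IRanges::IRanges(start = fc$start + 1, end = fc$end)
      ir <- IRanges::IRanges(start = intervals$start[ic] + 1,
                             end = intervals$end[ic])
      ov <- IRanges::countOverlaps(ir, fr)
      hit[ic] <- hit[ic] | ov > 0
    }
    out[cl] <- sum(hit)
  }
  out
}

#' Permutation enrichment of intervals in gene families
#'
#' Compares the observed number of intervals overlapping each gene
#' family's genes against the re-placement null from
#' [permute_intervals()]: empirical
#' `p = (1 + #{null >= observed}) / (N + 1)` per family, adjusted across
#' families with Benjamini-Hochberg.
#'
#' @param intervals Observed intervals (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param genes Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and a family column.
#' @param genome Tibble with `chrom`, `length`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param family_col Name of the family column (default `"family"`).
#' @param cross_chromosome Passed to [permute_intervals()].
#' @return Tibble `family`, `observed`, `null_mean`, `p`, `q`.
#' @export
family_enrichment <- function(intervals, genes, genome, n_perm = 1000,
                              seed = NULL, family_col = "family",
                              cross_chromosome = FALSE) {
  if (n_perm < 100) abort("need at least 100 permutations")
  obs <- count_class_overlaps(intervals, genes, family_col)
  perms <- permute_intervals(genome, intervals, n_perm, seed = seed,
                             cross_chromosome = cross_chromosome)
  null_mat <- vapply(split(perms, perms$perm), function(pl)
    count_class_overlaps(pl, genes, family_col), obs)
  if (is.null(dim(null_mat))) null_mat <- matrix(null_mat, nrow = 1,
                                                 dimnames = list(names(obs)))
  p <- vapply(names(obs), function(f)
    (1 + sum(null_mat[f, ] >= obs[f])) / (n_perm + 1), 0)
  tibble::tibble(family = names(obs), observed = as.integer(unname(obs)),
                 null_mean = unname(rowMeans(null_mat)), p = unname(p),
                 q = unname(p.adjust(p, method = "BH")))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing, over all tables with the observed
#' margins, the hypergeometric probabilities not exceeding that of the
#' observed table (with the customary `1 + 1e-7` relative tolerance).
#'
#' @param table 2x2 non-negative integer matrix.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2))
  if (any(table < 0)) abort("negative entries")
  m <- sum(table[1, ])      # row 1 margin
  nn <- sum(table[2, ])     # row 2 margin
  k <- sum(table[, 1])      # column 1 margin
  if (m == 0 || nn == 0 || k == 0 || sum(table[, 2]) == 0) return(1)
  support <- max(0, k - nn):min(k, m)
  probs <- dhyper(support, m, nn, k)
  p_obs <- dhyper(table[1, 1], m, nn, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Pearson chi-squared enrichment test for a 2x2 table
#'
#' No continuity correction by default. When any expected cell is zero
#' the statistic is undefined and Fisher's exact test is suggested.
#'
#' @param table 2x2 count matrix.
#' @param correct Apply Yates continuity correction?
#' @return Tibble `statistic`, `p`, `df`.
#' @export
chisq_enrichment <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2))
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) {
    warn("expected cell count of zero; consider fisher_exact_2x2()")
    return(tibble::tibble(statistic = NA_real_, p = NA_real_, df = 1L))
  }
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  tibble::tibble(statistic = unname(ct$statistic), p = ct$p.value, df = 1L)
}

#' Single-variant Wald association test
#'
#' Ordinary least squares of a quantitative trait on genotype dosage with
#' an intercept; the Wald p-value compares `beta / se` to the standard
#' Normal.
#'
#' @param y Per-sample trait values.
#' @param g Per-sample genotype dosages.
#' @return Tibble `beta`, `se`, `statistic`, `p`, `n`.
#' @export
wald_association <- function(y, g) {
  ok <- !is.na(y) & !is.na(g)
  if (sum(ok) < 3) abort("need at least 3 samples with called y and g")
  if (var(g[ok]) == 0) abort("genotype is constant")
  fit <- lm(y[ok] ~ g[ok])
  beta <- unname(coef(fit)[2])
  se <- sqrt(diag(vcov(fit)))[2]
  z <- beta / se
  tibble::tibble(beta = beta, se = unname(se), statistic = unname(z),
                 p = 2 * pnorm(-abs(z)), n = sum(ok))
}
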