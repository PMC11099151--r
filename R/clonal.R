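#' Pairwise genotype distances for clonal-family detection
#'
#' For each sample pair, `hom_frac` is the fraction of differing sites
#' among sites where both samples are called and both homozygous, and
#' `het_frac` the fraction of differing genotypes among sites where both
#' are called and at least one is heterozygous (the alternative
#' denominator, all jointly-called sites, is available via
#' `het_denominator = "joint"`). Pairs with an empty denominator get `NA`
#' and are flagged.
#'
#' @param gm A [genotype_matrix()].
#' @param het_denominator `"het_involving"` (default) or `"joint"`.
#' @return Tibble with `sample_i`, `sample_j`, `hom_frac`, `het_frac`,
#'   `n_hom_joint`, `n_het_joint`, `undefined`.
#' @export
pairwise_genotype_distances <- function(gm,
                                        het_denominator = c("het_involving",
                                                            "joint")) {
  het_denominator <- match.arg(het_denominator)
  d <- gm$dosage
  ns <- nrow(d)
  if (ns < 2) abort("need at least two samples")
  ids <- rownames(d)
  pairs <- utils::combn(ns, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    a <- d[i, ]; b <- d[j, ]
    both <- !is.na(a) & !is.na(b)
    hom_joint <- both & a != 1L & b != 1L
    het_any <- both & (a == 1L | b == 1L)
    n_hom <- sum(hom_joint)
    hom_frac <- if (n_hom == 0) NA_real_ else sum(a[hom_joint] != b[hom_joint]) / n_hom
    n_het <- if (het_denominator == "het_involving") sum(het_any) else sum(both)
    het_diff <- if (het_denominator == "het_involving")
      sum(a[het_any] != b[het_any]) else sum(a[both] != b[both] &
                                             (a[both] == 1L | b[both] == 1L))
    het_frac <- if (n_het == 0) NA_real_ else het_diff / n_het
    tibble::tibble(sample_i = ids[i], sample_j = ids[j],
                   hom_frac = hom_frac, het_frac = het_frac,
                   n_hom_joint = n_hom, n_het_joint = n_het,
                   undefined = is.na(hom_frac) || is.na(het_frac))
  })
  attr(res, "sample_ids") <- ids
  res
}

#' Clonal families from pairwise distances
#'
#' Two samples are clone-mates when `hom_frac <= hom_thresh` AND
#' `het_frac <= het_thresh` (defaults: no more than 0.01% differing
#' homozygous sites and 2% differing heterozygous sites). Families are the
#' connected components of the resulting graph (transitive closure);
#' undefined distances are non-edges.
#'
#' @param pairwise Output of [pairwise_genotype_distances()].
#' @param hom_thresh Homozygous-difference threshold (default 1e-4).
#' @param het_thresh Heterozygous-difference threshold (default 0.02).
#' @param gm Optional [genotype_matrix()], used to pick least-missing
#'   representatives.
#' @return A `clonal_partition`: list with `families` (list of sample-id
#'   vectors), `membership` tibble, `representative` (named vector), and
#'   the thresholds.
#' @export
clonal_families <- function(pairwise, hom_thresh = 1e-4, het_thresh = 0.02,
                            gm = NULL) {
  ids <- attr(pairwise, "sample_ids") %||%
    sort(unique(c(pairwise$sample_i, pairwise$sample_j)))
  edge <- !is.na(pairwise$hom_frac) & !is.na(pairwise$het_frac) &
    pairwise$hom_frac <= hom_thresh & pairwise$het_frac <= het_thresh
  g <- igraph::graph_from_data_frame(
    pairwise[edge, c("sample_i", "sample_j")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  fam_id <- comp$membership[ids]
  families <- split(ids, fam_id)
  names(families) <- sprintf("family%03d", seq_along(families))
  membership <- tibble::tibble(
    sample = ids,
    family = names(families)[match(fam_id, sort(unique(fam_id)))])
  part <- structure(list(families = families, membership = membership,
                         representative = NULL, hom_thresh = hom_thresh,
                         het_thresh = het_thresh),
                    class = "clonal_partition")
  if (!is.null(gm)) part$representative <- select_representatives(part, gm)
  part
}

#' @export
print.clonal_partition <- function(x, ...) {
  sizes <- lengths(x$families)
  cat("<clonal_partition> ", length(x$families), " families over ",
      sum(sizes), " samples (largest: ", max(sizes), ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.clonal_partition <- function(x, ...) x$membership

#' @exportS3Method generics::glance
glance.clonal_partition <- function(x, ...) {
  tibble::tibble(n_families = length(x$families),
                 n_samples = nrow(x$membership),
                 largest_family = max(lengths(x$families)),
                 n_singletons = sum(lengths(x$families) == 1),
                 hom_thresh = x$hom_thresh, het_thresh = x$het_thresh)
}

#' Representative genotype per clonal family
#'
#' The member with the smallest fraction of missing genotypes; ties are
#' broken by lexicographically smaller sample id.
#'
#' @param partition A `clonal_partition`.
#' @param gm A [genotype_matrix()].
#' @return Named character vector family -> sample id.
#' @export
select_representatives <- function(partition, gm) {
  missf <- rowMeans(is.na(gm$dosage))
  vapply(partition$families, function(members) {
    m <- missf[members]
    members[order(m, members)][1]
  }, "")
}

#' Per-individual genome-wide heterozygosity
#'
#' Heterozygosity rate is the number of heterozygous calls over the number
#' of called sites, per sample; samples with no calls are flagged.
#'
#' @param gm A [genotype_matrix()].
#' @return Tibble `sample`, `population`, `n_het`, `n_called`, `het_rate`.
#' @export
individual_heterozygosity <- function(gm) {
  d <- gm$dosage
  n_called <- rowSums(!is.na(d))
  n_het <- rowSums(d == 1L, na.rm = TRUE)
  tibble::tibble(sample = rownames(d),
                 population = unname(gm$populations[rownames(d)]),
                 n_het = n_het, n_called = n_called,
                 het_rate = ifelse(n_called > 0, n_het / n_called, NA_real_))
}

#' Median heterozygosity per population
#' @param gm A [genotype_matrix()].
#' @return Tibble `population`, `median_het`, `n_samples`.
#' @export
population_heterozygosity <- function(gm) {
  individual_heterozygosity(gm) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(median_het = median(.data$het_rate, na.rm = TRUE),
                     n_samples = dplyr::n(), .groups = "drop")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the heterozygote count given the allele
#' counts; the p-value sums the probabilities of all heterozygote counts
#' no more probable than the observed one. Probabilities are evaluated by
#' the standard recurrence over heterozygote counts.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (hom ref, het, hom alt).
#' @return Two-sided exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, 2 * n - n_a)
  hets <- seq(rare %% 2, rare, by = 2)
  # recurrence: P(h+2)/P(h) = 4*naa(h)*nbb(h) / ((h+2)*(h+1))
  logp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    naa <- (rare - h) / 2
    nbb <- (2 * n - rare - h) / 2
    logp[i] <- logp[i - 1] + log(4 * naa * nbb) - log((h + 2) * (h + 1))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_ab, hets)
  if (is.na(obs)) abort("heterozygote count inconsistent with allele counts")
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

#' Keep mask for population-structure input
#'
#' Removes sites deviating from Hardy-Weinberg equilibrium (exact test,
#' `p < hwe_alpha`), then greedily prunes linked sites: within each sliding
#' window of `window` SNPs (step `step`), the later member of any pair with
#' `r^2 > r2_max` is dropped.
#'
#' @param gm A [genotype_matrix()].
#' @param hwe_alpha HWE significance level (default 0.01).
#' @param r2_max Pruning threshold on genotype `r^2` (default 0.33).
#' @param window Window size in SNPs (default 50).
#' @param step Step in SNPs (default 5).
#' @return Logical keep mask over the sites of `gm`.
#' @export
structure_input_mask <- function(gm, hwe_alpha = 0.01, r2_max = 0.33,
                                 window = 50, step = 5) {
  d <- gm$dosage
  S <- ncol(d)
  keep <- rep(TRUE, S)
  for (s in seq_len(S)) {
    x <- d[, s]
    x <- x[!is.na(x)]
    p <- hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
    if (p < hwe_alpha) keep[s] <- FALSE
  }
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch & keep)
    if (length(idx) < 2) next
    alive <- rep(TRUE, length(idx))
    starts <- seq(1, max(1, length(idx) - 1), by = step)
    for (w0 in starts) {
      w <- seq(w0, min(w0 + window - 1, length(idx)))
      for (ii in seq_along(w)) {
        i <- w[ii]
        if (!alive[i]) next
        for (jj in seq_along(w)) {
          j <- w[jj]
          if (j <= i || !alive[j]) next
          r2 <- genotype_r2(d[, idx[i]], d[, idx[j]])
          if (!is.na(r2) && r2 > r2_max) alive[j] <- FALSE
        }
      }
      if (w0 + window - 1 >= length(idx)) break
    }
    keep[idx[!alive]] <- FALSE
  }
  keep
}
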