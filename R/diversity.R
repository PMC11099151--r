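#' Per-site nucleotide diversity
#'
#' Unbiased pairwise heterozygosity at a biallelic site:
#' `pi = 2 * (k/n) * (1 - k/n) * n/(n-1)` for `k` ALT alleles among `n`
#' called alleles, i.e. the probability that two alleles drawn without
#' replacement differ.
#'
#' @param alt_count ALT (or derived) allele count `k`.
#' @param called_alleles Number of called alleles `n` (>= 2).
#' @return Per-site pi (vectorised); `NA` when `n < 2`.
#' @export
per_site_pi <- function(alt_count, called_alleles) {
  k <- alt_count; n <- called_alleles
  ifelse(n >= 2, 2 * (k / n) * (1 - k / n) * n / (n - 1), NA_real_)
}

#' Nucleotide diversity of a region
#'
#' Sums per-site pi over the SNPs inside the region and divides by the
#' callable length, so monomorphic callable sites contribute zero through
#' the denominator. SNPs inside `exclude` intervals (e.g. structural
#' variants) are skipped.
#'
#' @param gm A [genotype_matrix()].
#' @param region Optional `c(chrom, start, end)` (1-based inclusive) or
#'   tibble row; `NULL` uses all sites.
#' @param callable_length Denominator in bp (> 0).
#' @param exclude Optional tibble of intervals (`chrom`, `start`, `end`,
#'   0-based half-open) whose SNPs are skipped.
#' @param samples Optional sample subset.
#' @return Pi per site (a single number).
#' @export
region_pi <- function(gm, region = NULL, callable_length, exclude = NULL,
                      samples = NULL) {
  if (callable_length <= 0) abort("callable_length must be positive")
  use <- rep(TRUE, n_sites(gm))
  if (!is.null(region)) {
    region <- as.list(region)
    use <- gm$sites$chrom == region[[1]] &
      gm$sites$pos >= as.numeric(region[[2]]) &
      gm$sites$pos <= as.numeric(region[[3]])
  }
  if (!is.null(exclude) && nrow(exclude)) {
    for (i in seq_len(nrow(exclude))) {
      use <- use & !(gm$sites$chrom == exclude$chrom[i] &
                     gm$sites$pos > exclude$start[i] &
                     gm$sites$pos <= exclude$end[i])
    }
  }
  if (!any(use)) return(0)
  ac <- site_allele_counts(gm, samples = samples)
  pis <- per_site_pi(ac$alt[use], ac$called[use])
  sum(pis, na.rm = TRUE) / callable_length
}

#' Nei-Gojobori synonymous and nonsynonymous site counts
#'
#' Each codon position contributes to the synonymous site count the
#' fraction of its three possible single-base changes that preserve the
#' amino acid (stop-gaining changes count as nonsynonymous), and the
#' complement to the nonsynonymous count, so `N + S` equals the CDS length
#' exactly. Codons containing ambiguous bases are skipped with a warning.
#'
#' @param cds_sequence In-frame CDS string (length divisible by 3).
#' @return Named numeric vector `c(N_sites, S_sites)`.
#' @export
count_ns_sites <- function(cds_sequence) {
  cds_sequence <- toupper(cds_sequence)
  L <- nchar(cds_sequence)
  if (L %% 3 != 0) abort("CDS length not divisible by 3")
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  S <- 0; N <- 0
  for (c0 in seq(1, L, 3)) {
    codon <- strsplit(substring(cds_sequence, c0, c0 + 2), "")[[1]]
    if (!all(codon %in% bases)) {
      warn(paste("ambiguous codon skipped at position", c0))
      next
    }
    aa <- code[[paste(codon, collapse = "")]]
    for (p in 1:3) {
      syn <- 0
      for (b in setdiff(bases, codon[p])) {
        alt <- codon; alt[p] <- b
        if (code[[paste(alt, collapse = "")]] == aa) syn <- syn + 1
      }
      S <- S + syn / 3
      N <- N + 1 - syn / 3
    }
  }
  c(N_sites = N, S_sites = S)
}

#' piN, piS and their ratio
#'
#' `pi_N` sums per-site pi over nonsynonymous SNPs and divides by the
#' total nonsynonymous site count; `pi_S` analogously. The ratio is `NA`
#' (undefined, not infinite) when `pi_S = 0`.
#'
#' @param gm A [genotype_matrix()].
#' @param effects Effect tibble from [classify_coding_effect()] aligned to
#'   `gm` sites (or any tibble with `chrom`, `pos`, `effect`).
#' @param n_sites_total,s_sites_total Nei-Gojobori totals over the CDS set
#'   (see [count_ns_sites()]).
#' @return Tibble with `pi_n`, `pi_s`, `ratio`.
#' @export
pin_pis <- function(gm, effects, n_sites_total, s_sites_total) {
  key <- paste(gm$sites$chrom, gm$sites$pos)
  eff <- effects$effect[match(key, paste(effects$chrom, effects$pos))]
  ac <- site_allele_counts(gm)
  pis <- per_site_pi(ac$alt, ac$called)
  pi_n <- sum(pis[eff %in% "nonsynonymous"], na.rm = TRUE) / n_sites_total
  pi_s <- sum(pis[eff %in% "synonymous"], na.rm = TRUE) / s_sites_total
  tibble::tibble(pi_n = pi_n, pi_s = pi_s,
                 ratio = dplyr::case_when(pi_n == 0 ~ 0,
                                          pi_s == 0 ~ NA_real_,
                                          TRUE ~ pi_n / pi_s))
}

#' Tajima's D
#'
#' Standard normalisation of the difference between mean pairwise
#' differences and Watterson's estimator. Returns `NA` (missing, not
#' zero) when there are no segregating sites or fewer than four
#' haplotypes.
#'
#' @param S Number of segregating sites.
#' @param n Number of haplotypes (>= 4).
#' @param pi_total Mean pairwise differences (sum of per-site pi over the
#'   window, NOT divided by length).
#' @return Tajima's D.
#' @export
tajimas_d <- function(S, n, pi_total) {
  if (is.na(S) || S == 0 || n < 4) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Genotype-based r-squared between two sites
#'
#' Squared Pearson correlation of dosage vectors over jointly-called
#' samples (the composite, phase-free LD estimator). `NA` when either site
#' is monomorphic in the joint subset or fewer than two joint calls exist.
#'
#' @param dosage_i,dosage_j Dosage vectors.
#' @return r-squared, or `NA`.
#' @export
genotype_r2 <- function(dosage_i, dosage_j) {
  both <- !is.na(dosage_i) & !is.na(dosage_j)
  if (sum(both) < 2) return(NA_real_)
  x <- dosage_i[both]; y <- dosage_j[both]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Linkage-disequilibrium decay curve
#'
#' All intra-chromosome SNP pairs within `max_dist` contribute genotype
#' r-squared to their distance bin, after dropping sites with missingness
#' above `miss_max` or MAF below `maf_min`.
#'
#' @param gm A [genotype_matrix()].
#' @param max_dist Maximum pair distance in bp (default 100 kb).
#' @param bin_width Distance bin width in bp (default 2 kb).
#' @param maf_min MAF filter (default 0.05).
#' @param miss_max Missingness filter (default 0.20).
#' @param samples Optional sample subset (e.g. clonal representatives).
#' @param max_sites Per-chromosome cap on sites used (evenly thinned) to
#'   bound the pairwise computation; `Inf` disables.
#' @return An `ld_curve`: tibble with `bin_lo`, `bin_hi`, `mid`,
#'   `mean_r2`, `n_pairs`, carrying `max_dist` as an attribute.
#' @export
ld_decay <- function(gm, max_dist = 1e5, bin_width = 2000, maf_min = 0.05,
                     miss_max = 0.20, samples = NULL, max_sites = 3000) {
  d <- gm$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  ns <- nrow(d)
  miss <- colMeans(is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  called <- colSums(!is.na(d)) * 2
  maf <- ifelse(called > 0, pmin(alt, called - alt) / called, 0)
  use <- miss <= miss_max & maf >= maf_min
  edges <- seq(0, max_dist, by = bin_width)
  if (edges[length(edges)] < max_dist) edges <- c(edges, max_dist)
  nb <- length(edges) - 1
  sum_r2 <- numeric(nb); n_pr <- numeric(nb)
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(use & gm$sites$chrom == ch)
    if (length(idx) > max_sites)
      idx <- idx[round(seq(1, length(idx), length.out = max_sites))]
    if (length(idx) < 2) next
    pos <- gm$sites$pos[idx]
    dm <- d[, idx, drop = FALSE]
    cc <- suppressWarnings(cor(dm, use = "pairwise.complete.obs"))^2
    dist <- abs(outer(pos, pos, `-`))
    ut <- upper.tri(dist)
    ok <- ut & dist <= max_dist & dist >= 1 & !is.na(cc)
    if (!any(ok)) next
    bin <- findInterval(dist[ok], edges, rightmost.closed = TRUE,
                        left.open = TRUE)
    bin[bin == 0] <- 1
    sums <- tapply(cc[ok], bin, sum)
    cnts <- tapply(cc[ok], bin, length)
    bi <- as.integer(names(sums))
    sum_r2[bi] <- sum_r2[bi] + sums
    n_pr[bi] <- n_pr[bi] + cnts
  }
  curve <- tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                          mid = (edges[-length(edges)] + edges[-1]) / 2,
                          mean_r2 = ifelse(n_pr > 0, sum_r2 / n_pr, NA_real_),
                          n_pairs = n_pr)
  structure(curve, max_dist = max_dist,
            class = c("ld_curve", class(curve)))
}

# weighted pool-adjacent-violators fit, decreasing
pava_decreasing <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; size <- rep(1L, n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]; wt[m] <- w[i]; size[m] <- 1L
    while (m > 1L && val[m - 1L] < val[m]) {
      tot <- wt[m - 1L] + wt[m]
      val[m - 1L] <- (val[m - 1L] * wt[m - 1L] + val[m] * wt[m]) / tot
      wt[m - 1L] <- tot
      size[m - 1L] <- size[m - 1L] + size[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], times = size[seq_len(m)])
}

#' LD-decay distance at an r-squared threshold
#'
#' The curve's bin means are first smoothed with a weighted
#' isotonic-decreasing fit (pair counts as weights), then the crossing of
#' the threshold is located by linear interpolation between the two bin
#' mid-points straddling it. If the smoothed curve never falls to the
#' threshold within `max_dist`, returns `Inf` with attribute
#' `censored_at = max_dist` (reported as "> max_dist").
#'
#' @param curve An `ld_curve` from [ld_decay()].
#' @param threshold r-squared threshold (default 0.2).
#' @return Decay distance in bp (possibly `Inf`).
#' @export
decay_distance_at <- function(curve, threshold = 0.2) {
  ok <- !is.na(curve$mean_r2) & curve$n_pairs > 0
  if (!any(ok)) return(NA_real_)
  x <- curve$mid[ok]; y <- curve$mean_r2[ok]; w <- curve$n_pairs[ok]
  ys <- pava_decreasing(y, w)
  max_dist <- attr(curve, "max_dist") %||% max(curve$bin_hi)
  if (ys[1] <= threshold) return(x[1])
  below <- which(ys <= threshold)
  if (!length(below)) {
    out <- Inf
    attr(out, "censored_at") <- max_dist
    return(out)
  }
  j <- below[1]; i <- j - 1
  x[i] + (ys[i] - threshold) / (ys[i] - ys[j]) * (x[j] - x[i])
}

#' Sliding-window diversity statistics
#'
#' Tiles each chromosome with windows of `size` bp advancing by `step` bp
#' and records the chosen statistic: `pi` (per-site, window length as
#' callable length; 0 for empty windows), `tajD` (missing when no SNPs),
#' or `het` (mean over the window's SNPs of the fraction of heterozygous
#' samples).
#'
#' @param gm A [genotype_matrix()].
#' @param size Window size in bp.
#' @param step Step in bp (<= size).
#' @param stat One of `"pi"`, `"tajD"`, `"het"`.
#' @param samples Optional sample subset.
#' @return Tibble `chrom`, `start`, `end` (0-based half-open), `value`,
#'   `n_sites`; genome-wide average in attribute `genome_avg`.
#' @export
sliding_windows <- function(gm, size = 5e4, step = 1e4,
                            stat = c("pi", "tajD", "het"), samples = NULL) {
  stat <- match.arg(stat)
  if (size < step) abort("size must be >= step")
  d <- gm$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  alt <- colSums(d, na.rm = TRUE)
  called <- colSums(!is.na(d)) * 2
  res <- list()
  for (ch in unique(gm$sites$chrom)) {
    on_ch <- gm$sites$chrom == ch
    L <- gm$chrom_lengths[ch] %||% NA
    if (is.na(L)) L <- max(gm$sites$pos[on_ch])
    starts <- seq(0, max(0, L - 1), by = step)
    starts <- starts[starts < L]
    pos <- gm$sites$pos[on_ch]
    idx_ch <- which(on_ch)
    vals <- vapply(starts, function(s0) {
      inw <- idx_ch[pos > s0 & pos <= min(s0 + size, L)]
      k <- alt[inw]; nn <- called[inw]
      switch(stat,
        pi = sum(per_site_pi(k, nn), na.rm = TRUE) / size,
        tajD = {
          seg <- inw[k > 0 & k < nn]
          if (!length(seg)) NA_real_
          else tajimas_d(length(seg), round(mean(called[seg])),
                         sum(per_site_pi(alt[seg], called[seg])))
        },
        het = {
          if (!length(inw)) NA_real_
          else mean(colSums(d[, inw, drop = FALSE] == 1L, na.rm = TRUE) /
                      pmax(1, colSums(!is.na(d[, inw, drop = FALSE]))))
        })
    }, 0)
    nsit <- vapply(starts, function(s0)
      sum(pos > s0 & pos <= min(s0 + size, L)), 0)
    res[[ch]] <- tibble::tibble(chrom = ch, start = starts,
                                end = pmin(starts + size, L), value = vals,
                                n_sites = as.integer(nsit))
  }
  out <- dplyr::bind_rows(res)
  attr(out, "genome_avg") <- mean(out$value, na.rm = TRUE)
  attr(out, "stat") <- stat
  class(out) <- c("window_stats", class(out))
  out
}
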