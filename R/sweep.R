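#' Background site-frequency spectrum
#'
#' Counts segregating sites by derived-allele class (unfolded; requires
#' polarized sites) or minor-allele class (folded). Sites called in more
#' alleles than `project_n` are projected down by the hypergeometric
#' expectation over subsamples; sites called in fewer are dropped.
#'
#' @param gm A [genotype_matrix()] (with `ancestral` set for unfolded).
#' @param folded Fold the spectrum?
#' @param project_n Common haploid sample size (default: the maximum
#'   fully-called size, i.e. the modal call count).
#' @param samples Optional sample subset.
#' @return An `sfs` object: list with `n`, `counts` (classes `1..n-1`
#'   unfolded or `1..floor(n/2)` folded), `folded`, `proportions`.
#' @export
background_sfs <- function(gm, folded = FALSE, project_n = NULL,
                           samples = NULL) {
  d <- gm$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  called <- colSums(!is.na(d)) * 2L
  alt <- colSums(d, na.rm = TRUE)
  if (!folded) {
    anc <- if ("ancestral" %in% names(gm$sites)) gm$sites$ancestral
    if (is.null(anc) || all(is.na(anc)))
      abort("unfolded spectrum requires polarized sites")
    derived <- ifelse(anc == gm$sites$ref, alt, called - alt)
    ok <- !is.na(anc)
  } else {
    derived <- alt
    ok <- rep(TRUE, length(alt))
  }
  n <- project_n %||% max(called)
  seg <- ok & called >= n & derived > 0 & derived < called
  if (!any(seg)) abort("no segregating sites")
  counts <- numeric(n + 1)
  full <- seg & called == n
  if (any(full))
    counts <- counts + tabulate(derived[full] + 1L, nbins = n + 1)
  for (s in which(seg & called > n)) {
    counts <- counts + dhyper(0:n, derived[s], called[s] - derived[s], n)
  }
  counts <- counts[2:n]  # classes 1..n-1
  if (folded) {
    nf <- floor(n / 2)
    fold <- sapply(seq_len(nf), function(j)
      if (j == n - j) counts[j] else counts[j] + counts[n - j])
    counts <- fold
  }
  structure(list(n = n, counts = counts, folded = folded,
                 proportions = counts / sum(counts)),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat("<sfs> n =", x$n, if (x$folded) "(folded)" else "(unfolded)",
      "; segregating mass =", round(sum(x$counts), 1), "\n")
  invisible(x)
}

#' Hypergeometric projection of a derived-allele count
#'
#' Distribution of the derived count in a subsample of size `n_to` drawn
#' without replacement from `n_from` alleles of which `j_derived` are
#' derived.
#'
#' @param j_derived Derived count in the full sample.
#' @param n_from Full sample size.
#' @param n_to Subsample size (<= `n_from`).
#' @return Probability vector over derived counts `0..n_to`.
#' @export
sfs_project <- function(j_derived, n_from, n_to) {
  stopifnot(n_to <= n_from, j_derived >= 0, j_derived <= n_from)
  dhyper(0:n_to, j_derived, n_from - j_derived, n_to)
}

# project a normalized background spectrum (classes 1..nb-1) to size m,
# returning probabilities over derived counts 0..m
project_spectrum <- function(bg_prop, nb, m) {
  out <- numeric(m + 1)
  for (j in seq_len(nb - 1)) {
    if (bg_prop[j] == 0) next
    out <- out + bg_prop[j] * dhyper(0:m, j, nb - j, m)
  }
  out
}

#' Sweep-transformed site-frequency spectrum
#'
#' Under a hard sweep, each of `n` sampled lineages escapes independently
#' with probability `p_e`; the `k` escapees together with the single swept
#' ancestral lineage form an effective sample of `k + 1` drawn from the
#' background spectrum, and the swept lineage's allelic state is
#' replicated into the `n - k` non-escapees. Returns the distribution of
#' derived counts `0..n` (monomorphic classes included). `p_e = 1`
#' recovers the background at size `n`; `p_e = 0` puts all mass on
#' `{0, n}`.
#'
#' @param bg An `sfs` (unfolded, normalized internally).
#' @param n Haploid sample size of the output (<= `bg$n`).
#' @param p_e Escape probability in `[0, 1]`.
#' @return Probability vector over derived counts `0..n`.
#' @export
sweep_sfs_transform <- function(bg, n, p_e) {
  stopifnot(inherits(bg, "sfs"), !bg$folded, p_e >= 0, p_e <= 1, n <= bg$n)
  prop <- bg$proportions
  nb <- bg$n
  out <- numeric(n + 1)
  for (k in 0:n) {
    wk <- dbinom(k, n, p_e)
    if (wk == 0) next
    if (k == n) {
      out <- out + wk * project_spectrum(prop, nb, n)
      next
    }
    m <- k + 1
    q <- project_spectrum(prop, nb, m)  # derived among the m draws
    for (j in 0:m) {
      if (q[j + 1] == 0) next
      p_swept_derived <- j / m
      if (p_swept_derived > 0)  # swept lineage derived: replicate
        out[(j - 1) + (n - k) + 1] <- out[(j - 1) + (n - k) + 1] +
          wk * q[j + 1] * p_swept_derived
      if (p_swept_derived < 1)  # swept lineage ancestral
        out[j + 1] <- out[j + 1] + wk * q[j + 1] * (1 - p_swept_derived)
    }
  }
  out
}

# conditional-on-segregating spectrum over classes 1..n-1
segregating_spectrum <- function(full) {
  seg <- full[2:(length(full) - 1)]
  s <- sum(seg)
  if (s <= 0) return(rep(1 / length(seg), length(seg)))
  seg / s
}

#' Composite-likelihood-ratio sweep scan
#'
#' At each grid position, compares the composite likelihood of the
#' derived-allele classes of flanking SNPs under a sweep-transformed
#' spectrum (escape probability `p_e(d, alpha) = 1 - exp(-alpha * d)` at
#' distance `d`, maximised over `alpha_grid`) against the genome-wide
#' background spectrum: `CLR = 2 * (max lnL_sweep - lnL_bg) >= 0` (the
#' neutral model is included in the maximisation). Transformed spectra are
#' conditioned on segregating classes, since only segregating sites enter
#' the data. Grid positions flanked by fewer than `min_snps` SNPs are
#' skipped.
#'
#' @param gm A polarized [genotype_matrix()].
#' @param samples Optional sample subset.
#' @param grid_step Spacing of test positions (bp).
#' @param flank Half-width of the SNP window around each position (bp).
#' @param alpha_grid Sweep-intensity grid (per bp).
#' @param bg Optional precomputed background `sfs`.
#' @param n_pe_bins Number of discretisation bins for `p_e`.
#' @param min_snps Minimum flanking SNPs (default 5).
#' @return Tibble (`window_stats`): `chrom`, `start`, `end`, `pos`,
#'   `value` (CLR), `n_sites`, `alpha_hat`.
#' @export
clr_scan <- function(gm, samples = NULL, grid_step = 1e4, flank = 5e4,
                     alpha_grid = 10^seq(-5.5, -2.5, by = 0.5),
                     bg = NULL, n_pe_bins = 21, min_snps = 5) {
  bg <- bg %||% background_sfs(gm, samples = samples)
  n <- bg$n
  d <- gm$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  called <- colSums(!is.na(d)) * 2L
  alt <- colSums(d, na.rm = TRUE)
  derived <- ifelse(gm$sites$ancestral == gm$sites$ref, alt, called - alt)
  usable <- !is.na(gm$sites$ancestral) & called == n & derived > 0 &
    derived < called

  pe_grid <- seq(0, 1, length.out = n_pe_bins)
  spectra <- vapply(pe_grid, function(pe)
    log(pmax(segregating_spectrum(sweep_sfs_transform(bg, n, pe)), 1e-300)),
    numeric(n - 1))
  log_bg <- log(pmax(bg$proportions, 1e-300))

  res <- list()
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(usable & gm$sites$chrom == ch)
    if (!length(idx)) next
    pos <- gm$sites$pos[idx]
    b <- derived[idx]
    L <- gm$chrom_lengths[ch] %||% max(pos)
    grid <- seq(grid_step / 2, L, by = grid_step)
    vals <- rep(NA_real_, length(grid))
    ahat <- rep(NA_real_, length(grid))
    nsnp <- integer(length(grid))
    for (gi in seq_along(grid)) {
      x <- grid[gi]
      inw <- which(pos >= x - flank & pos <= x + flank)
      nsnp[gi] <- length(inw)
      if (length(inw) < min_snps) next
      dist <- abs(pos[inw] - x)
      bw <- b[inw]
      lnL0 <- sum(log_bg[bw])
      best <- lnL0; besta <- NA_real_
      for (a in alpha_grid) {
        pe <- 1 - exp(-a * dist)
        bin <- pmin(n_pe_bins, pmax(1L, round(pe * (n_pe_bins - 1)) + 1L))
        lnL <- sum(spectra[cbind(bw, bin)])
        if (lnL > best) { best <- lnL; besta <- a }
      }
      vals[gi] <- 2 * (best - lnL0)
      ahat[gi] <- besta
    }
    res[[ch]] <- tibble::tibble(chrom = ch,
                                start = pmax(0, grid - grid_step / 2),
                                end = pmin(L, grid + grid_step / 2),
                                pos = grid, value = vals, n_sites = nsnp,
                                alpha_hat = ahat)
  }
  out <- dplyr::bind_rows(res)
  out <- out[!is.na(out$value), ]
  class(out) <- c("window_stats", class(out))
  attr(out, "stat") <- "clr"
  out
}

#' Mu-statistic factors for one SNP window
#'
#' The composite sweep score multiplies three factors evaluated on a
#' window of `k` consecutive SNPs split at its midpoint:
#' `mu_var = (span/k) / (genome_length/total_snps)` (local SNP sparsity =
#' diversity reduction), `mu_sfs` = the window's fraction of singleton and
#' `n-1` classes over its neutral expectation
#' `(1 + 1/(n-1)) / sum(1/j)`, and `mu_ld` = mean r-squared within the two
#' halves over twice the mean r-squared across halves (plus
#' `epsilon = 1e-6`).
#'
#' @param derived Derived counts of the window's SNPs.
#' @param dosages Dosage matrix (samples x window SNPs) for the r-squared
#'   terms.
#' @param span Window physical span (bp).
#' @param n Haploid sample size.
#' @param genome_length,total_snps Genome-wide normalisation constants.
#' @return Tibble `mu_var`, `mu_sfs`, `mu_ld`, `mu`, `ld_defined`.
#' @export
mu_factors <- function(derived, dosages, span, n, genome_length,
                       total_snps) {
  k <- length(derived)
  mu_var <- (span / k) / (genome_length / total_snps)
  frac_obs <- sum(derived == 1 | derived == n - 1) / k
  frac_exp <- (1 + 1 / (n - 1)) / sum(1 / seq_len(n - 1))
  mu_sfs <- frac_obs / frac_exp
  half <- k %/% 2
  eps <- 1e-6
  ld_defined <- TRUE
  mean_r2 <- function(m1, m2 = NULL) {
    cc <- suppressWarnings(
      if (is.null(m2)) cor(m1, use = "pairwise.complete.obs")^2
      else cor(m1, m2, use = "pairwise.complete.obs")^2)
    if (is.null(m2)) cc <- cc[upper.tri(cc)]
    mean(cc, na.rm = TRUE)
  }
  left <- dosages[, seq_len(half), drop = FALSE]
  right <- dosages[, (half + 1):k, drop = FALSE]
  wl <- mean_r2(left); wr <- mean_r2(right); ac <- mean_r2(left, right)
  if (any(is.na(c(wl, wr, ac)))) {
    mu_ld <- 1; ld_defined <- FALSE
  } else {
    mu_ld <- (wl + wr) / (2 * ac + eps)
  }
  tibble::tibble(mu_var = mu_var, mu_sfs = mu_sfs, mu_ld = mu_ld,
                 mu = mu_var * mu_sfs * mu_ld, ld_defined = ld_defined)
}

#' Sliding mu-statistic scan
#'
#' Applies [mu_factors()] to sliding windows of `k` consecutive SNPs.
#'
#' @param gm A polarized [genotype_matrix()].
#' @param samples Optional sample subset.
#' @param k SNPs per window (default 50).
#' @param step Step in SNPs.
#' @return Tibble (`window_stats`) with the window span, midpoint, the
#'   three factors and `value = mu`.
#' @export
mu_scan <- function(gm, samples = NULL, k = 50, step = 10) {
  d <- gm$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  called <- colSums(!is.na(d)) * 2L
  alt <- colSums(d, na.rm = TRUE)
  anc <- if ("ancestral" %in% names(gm$sites)) gm$sites$ancestral
         else rep(NA_character_, n_sites(gm))
  derived <- ifelse(!is.na(anc) & anc == gm$sites$ref, alt, called - alt)
  n <- max(called)
  # only segregating sites count as SNPs for the density factor
  seg <- alt > 0 & alt < called
  res <- list()
  genome_length <- sum(vapply(unique(gm$sites$chrom), function(ch)
    gm$chrom_lengths[ch] %||% max(gm$sites$pos[gm$sites$chrom == ch]), 0))
  total_snps <- sum(seg)
  for (ch in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == ch & seg)
    if (length(idx) < k) next
    pos <- gm$sites$pos[idx]
    starts <- seq(1, length(idx) - k + 1, by = step)
    rows <- purrr::map_dfr(starts, function(s0) {
      w <- idx[s0:(s0 + k - 1)]
      f <- mu_factors(derived[w], d[, w, drop = FALSE],
                      span = pos[s0 + k - 1] - pos[s0] + 1, n = n,
                      genome_length = genome_length,
                      total_snps = total_snps)
      dplyr::mutate(f, chrom = ch, start = pos[s0] - 1L,
                    end = pos[s0 + k - 1],
                    pos = (pos[s0] + pos[s0 + k - 1]) / 2,
                    n_sites = k, .before = 1)
    })
    res[[ch]] <- rows
  }
  out <- dplyr::bind_rows(res)
  out$value <- out$mu
  class(out) <- c("window_stats", class(out))
  attr(out, "stat") <- "mu"
  out
}

#' Top-fraction window selection
#'
#' Selects windows at or above the `(1 - q)` empirical quantile of the
#' score; ties at the quantile are included (when every value is equal the
#' whole set is selected and flagged).
#'
#' @param stats A tibble with a `value` column (e.g. from [clr_scan()]).
#' @param q Selected fraction (default 0.01, the top 1%).
#' @return The selected rows, with attributes `cutoff` and `all_tied`.
#' @export
top_fraction <- function(stats, q = 0.01) {
  v <- stats$value[!is.na(stats$value)]
  if (!length(v)) abort("no scores to select from")
  cutoff <- quantile(v, 1 - q, names = FALSE)
  sel <- stats[!is.na(stats$value) & stats$value >= cutoff, ]
  attr(sel, "cutoff") <- cutoff
  attr(sel, "all_tied") <- length(unique(v)) == 1
  sel
}

#' Genes overlapping selected windows
#'
#' A gene is reported when it overlaps any selected window by at least
#' 1 bp; window coordinates are 0-based half-open, gene coordinates
#' 1-based inclusive.
#'
#' @param windows Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end` (1-based
#'   inclusive), e.g. the `gene` rows of [read_gff3()].
#' @return Tibble `gene_id`, `chrom`, `gene_start`, `gene_end`,
#'   `n_windows`.
#' @export
overlap_genes <- function(windows, genes) {
  res <- list()
  for (ch in unique(genes$chrom)) {
    gs <- genes[genes$chrom == ch, ]
    ws <- windows[windows$chrom == ch, ]
    if (!nrow(ws) || !nrow(gs)) next
    gr <- IRanges::IRanges(start = gs$start, end = gs$end)
    wr <- IRanges::IRanges(start = ws$start + 1, end = ws$end)
    hits <- IRanges::findOverlaps(gr, wr)
    if (!length(hits)) next
    cnt <- table(S4Vectors::queryHits(hits))
    qi <- as.integer(names(cnt))
    res[[ch]] <- tibble::tibble(gene_id = gs$gene_id[qi], chrom = ch,
                                gene_start = gs$start[qi],
                                gene_end = gs$end[qi],
                                n_windows = as.integer(cnt))
  }
  if (!length(res))
    return(tibble::tibble(gene_id = character(0), chrom = character(0),
                          gene_start = integer(0), gene_end = integer(0),
                          n_windows = integer(0)))
  dplyr::bind_rows(res)
}

#' Intersection of candidate gene lists across methods
#'
#' @param ... Character vectors (or a single list) of gene ids, one per
#'   scan method.
#' @return Genes present in every list.
#' @export
intersect_gene_lists <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]])) lists <- lists[[1]]
  Reduce(intersect, lists)
}
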