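# Population bisulfite-sequencing analysis from per-cytosine reports.

#' Bisulfite non-conversion rate from an unmethylated control contig
#'
#' The fraction of methylated-state read calls among all read calls over
#' the cytosines of a contig with no true methylation (typically the
#' chloroplast): `e = sum(m) / sum(m + u)`.
#'
#' @param records Cytosine report tibble (`chrom`, `pos`, `strand`,
#'   `m_reads`, `u_reads`, `context`, ...).
#' @param control_contig Control contig name (default `"chloroplast"`).
#' @param min_cytosines Minimum covered control cytosines (default 100).
#' @return Non-conversion rate `e`.
#' @export
nonconversion_rate <- function(records, control_contig = "chloroplast",
                               min_cytosines = 100) {
  ctl <- records[records$chrom == control_contig &
                   (records$m_reads + records$u_reads) > 0, ]
  if (nrow(ctl) < min_cytosines)
    abort(sprintf("control contig has %d covered cytosines (< %d)",
                  nrow(ctl), min_cytosines))
  sum(ctl$m_reads) / sum(ctl$m_reads + ctl$u_reads)
}

#' Binomial methylation calling
#'
#' Drops cytosines covered by fewer than `min_cov` reads, then tests each
#' remaining site against the non-conversion background: the one-sided
#' binomial tail `P(X >= m | n = coverage, rate = e)`, adjusted across
#' sites (Benjamini-Hochberg by default). At sites NOT called methylated
#' the reads supporting methylation are excluded: `m_reads` is set to 0
#' and `u_reads` increased so coverage is preserved. Called sites are
#' left unchanged.
#'
#' @param records Cytosine report tibble.
#' @param e Non-conversion rate from [nonconversion_rate()] (must be < 1).
#' @param alpha Significance level (default 0.05).
#' @param min_cov Minimum coverage (default 5).
#' @param adjust `"BH"` (default) or `"none"` for raw-alpha calling.
#' @return The filtered tibble with columns `p`, `q`, `methylated`, and
#'   `m_reads`/`u_reads` updated as described.
#' @export
call_methylated <- function(records, e, alpha = 0.05, min_cov = 5,
                            adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  if (e >= 1) abort("non-conversion rate must be < 1")
  cov <- records$m_reads + records$u_reads
  rec <- records[cov >= min_cov, ]
  cov <- rec$m_reads + rec$u_reads
  p <- pbinom(rec$m_reads - 1, cov, e, lower.tail = FALSE)
  q <- if (adjust == "BH") p.adjust(p, method = "BH") else p
  meth <- q < alpha & rec$m_reads > 0
  rec$p <- p
  rec$q <- q
  rec$methylated <- meth
  rec$u_reads <- ifelse(meth, rec$u_reads, cov)
  rec$m_reads <- ifelse(meth, rec$m_reads, 0L)
  rec
}

#' Proportion of methylated cytosines (mC)
#'
#' Fraction of covered cytosines of a context that retain methylated
#' reads after binomial calling.
#'
#' @param called Output of [call_methylated()].
#' @param context One of `"CpG"`, `"CHG"`, `"CHH"`, or `NULL` for all.
#' @param nuclear_only Drop the chloroplast control contig (default TRUE).
#' @return Proportion in `[0, 1]`; `NA` if no covered sites.
#' @export
mc_proportion <- function(called, context = NULL, nuclear_only = TRUE) {
  x <- called
  if (!is.null(context)) x <- x[x$context == context, ]
  if (nuclear_only) x <- x[x$chrom != "chloroplast", ]
  if (!nrow(x)) return(NA_real_)
  mean(x$m_reads > 0)
}

#' Weighted methylation level (wML)
#'
#' Summed methylated reads over summed total reads across the covered
#' cytosines of a context in a region: coverage-weighted, so deeply
#' covered cytosines contribute proportionally more than in a mean of
#' per-site levels.
#'
#' @param called Output of [call_methylated()] (or any report tibble).
#' @param region Optional `c(chrom, start, end)` (0-based half-open);
#'   `NULL` for genome-wide.
#' @param context Optional context filter.
#' @param nuclear_only Drop the chloroplast control contig (default TRUE).
#' @return wML in `[0, 1]`; `NA` (flagged undefined) with no covered
#'   cytosines.
#' @export
weighted_ml <- function(called, region = NULL, context = NULL,
                        nuclear_only = TRUE) {
  x <- called
  if (!is.null(context)) x <- x[x$context == context, ]
  if (nuclear_only && is.null(region)) x <- x[x$chrom != "chloroplast", ]
  if (!is.null(region)) {
    region <- as.list(region)
    x <- x[x$chrom == region[[1]] & x$pos > as.numeric(region[[2]]) &
             x$pos <= as.numeric(region[[3]]), ]
  }
  tot <- sum(x$m_reads + x$u_reads)
  if (tot == 0) return(NA_real_)
  sum(x$m_reads) / tot
}

#' Per-region weighted methylation levels
#'
#' @param called Output of [call_methylated()].
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally a `label`.
#' @param context Optional context filter.
#' @return Tibble with one row per region: `label`, `chrom`, `start`,
#'   `end`, `context`, `wml`, `n_cytosines`, `total_reads`.
#' @export
wml_by_region <- function(called, regions, context = NULL) {
  x <- called
  if (!is.null(context)) x <- x[x$context == context, ]
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    inr <- x$chrom == r$chrom & x$pos > r$start & x$pos <= r$end
    tot <- sum(x$m_reads[inr] + x$u_reads[inr])
    tibble::tibble(label = r$label %||% sprintf("region%03d", i),
                   chrom = r$chrom, start = r$start, end = r$end,
                   context = context %||% "all",
                   wml = if (tot == 0) NA_real_ else sum(x$m_reads[inr]) / tot,
                   n_cytosines = sum(inr), total_reads = tot)
  })
}

#' Metagene methylation profile with flanks
#'
#' Pools wML into fixed bins across scaled feature bodies plus fixed-width
#' flanking bins (2 kb by default). Minus-strand features are reversed so
#' all features read 5' to 3'.
#'
#' @param called Output of [call_methylated()].
#' @param features Tibble with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `strand` (assumed `+` when absent).
#' @param context Optional context filter.
#' @param flank Flank width in bp (default 2000).
#' @param body_bins Bins across the body (default 20).
#' @param flank_bins Bins per flank (default 10).
#' @return Tibble `bin` (1..flank+body+flank), `zone` (upstream / body /
#'   downstream), `wml`, `m_reads`, `u_reads`.
#' @export
metagene_profile <- function(called, features, context = NULL, flank = 2000,
                             body_bins = 20, flank_bins = 10) {
  x <- called
  if (!is.null(context)) x <- x[x$context == context, ]
  nb <- flank_bins + body_bins + flank_bins
  m <- numeric(nb); u <- numeric(nb)
  fw <- flank / flank_bins
  strand <- features$strand %||% rep("+", nrow(features))
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    on <- x$chrom == f$chrom & x$pos >= f$start - flank &
      x$pos <= f$end + flank
    if (!any(on)) next
    xp <- x[on, ]
    bin <- integer(nrow(xp))
    body_len <- f$end - f$start + 1
    up <- xp$pos < f$start
    dn <- xp$pos > f$end
    body <- !up & !dn
    bin[up] <- flank_bins - pmin(flank_bins - 1,
                                 floor((f$start - xp$pos[up]) / fw))
    bin[body] <- flank_bins +
      pmin(body_bins, floor((xp$pos[body] - f$start) / body_len * body_bins) + 1)
    bin[dn] <- flank_bins + body_bins +
      pmin(flank_bins, floor((xp$pos[dn] - f$end - 1) / fw) + 1)
    if (strand[i] == "-") bin <- nb + 1L - bin
    mm <- tapply(xp$m_reads, bin, sum)
    uu <- tapply(xp$u_reads, bin, sum)
    bi <- as.integer(names(mm))
    m[bi] <- m[bi] + mm
    u[bi] <- u[bi] + uu
  }
  tibble::tibble(bin = seq_len(nb),
                 zone = rep(c("upstream", "body", "downstream"),
                            c(flank_bins, body_bins, flank_bins)),
                 wml = ifelse(m + u > 0, m / (m + u), NA_real_),
                 m_reads = m, u_reads = u)
}

#' Compare per-sample wML between populations
#'
#' Pairwise Wilcoxon rank-sum tests on per-sample weighted methylation
#' levels, Bonferroni-adjusted, with a compact letter display (groups
#' sharing a letter are not significantly different).
#'
#' @param sample_wml Tibble with `sample`, `population`, `wml`.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List with `pairwise` (tibble `pop_i`, `pop_j`, `p`, `p_adj`)
#'   and `letters` (tibble `population`, `letters`).
#' @export
compare_population_wml <- function(sample_wml, alpha = 0.05) {
  grp <- split(sample_wml$wml, sample_wml$population)
  sizes <- lengths(grp)
  if (any(sizes < 2)) {
    warn(paste("dropping groups of size 1:",
               paste(names(grp)[sizes < 2], collapse = ", ")))
    grp <- grp[sizes >= 2]
  }
  if (length(grp) < 2) abort("need at least two groups of size >= 2")
  pops <- names(grp)
  pairs <- utils::combn(pops, 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    p <- suppressWarnings(wilcox.test(grp[[i]], grp[[j]], exact = TRUE)$p.value)
    tibble::tibble(pop_i = i, pop_j = j, p = p)
  })
  pw$p_adj <- pmin(1, pw$p * nrow(pw))  # Bonferroni
  # compact letter display: greedy insert-absorb over groups ordered by mean
  ord <- pops[order(-vapply(grp, mean, 0))]
  differ <- function(i, j) {
    r <- pw[(pw$pop_i == i & pw$pop_j == j) | (pw$pop_i == j & pw$pop_j == i), ]
    nrow(r) > 0 && r$p_adj[1] < alpha
  }
  sets <- list()
  for (p in ord) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (!any(vapply(sets[[s]], differ, TRUE, j = p))) {
        sets[[s]] <- c(sets[[s]], p); placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- p
  }
  letters_tbl <- tibble::tibble(
    population = pops,
    letters = vapply(pops, function(p)
      paste(LETTERS[which(vapply(sets, function(s) p %in% s, TRUE))],
            collapse = ""), ""))
  list(pairwise = pw, letters = letters_tbl)
}

#' Hierarchical clustering of methylomes
#'
#' Distance is `1 - Pearson correlation` of per-region wML profiles
#' (regions with any missing sample are dropped); average-linkage
#' clustering. Constant profiles have undefined correlation and are
#' flagged.
#'
#' @param wml_matrix Numeric matrix samples x regions.
#' @return List of class `methylome_clust` with `hclust`, `dist` (matrix),
#'   `dropped_regions`, `flagged_samples`.
#' @export
methylome_clustering <- function(wml_matrix) {
  stopifnot(nrow(wml_matrix) >= 3)
  keep <- colSums(is.na(wml_matrix)) == 0
  m <- wml_matrix[, keep, drop = FALSE]
  sds <- apply(m, 1, sd)
  flagged <- rownames(m)[sds == 0]
  cc <- suppressWarnings(cor(t(m)))
  d <- 1 - cc
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  structure(list(hclust = hc, dist = d,
                 dropped_regions = sum(!keep), flagged_samples = flagged),
            class = "methylome_clust")
}

#' Export a methylome dendrogram as Newick
#' @param clust A `methylome_clust`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clust, path) {
  ape::write.tree(ape::as.phylo(clust$hclust), file = path)
  invisible(path)
}

#' Mantel concordance between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance
#' from joint row/column permutation of the second matrix. For `n <= 7`
#' with `exact = TRUE` all `n!` permutations are enumerated; otherwise
#' `n_perm` random permutations with the add-one empirical p.
#'
#' @param d1,d2 Square symmetric distance matrices over the same samples.
#' @param n_perm Random permutations (default 999).
#' @param seed Integer seed.
#' @param exact Enumerate all permutations (only for small n).
#' @return Tibble `r`, `p`, `n_perm`, `exact`.
#' @export
tree_concordance <- function(d1, d2, n_perm = 999, seed = NULL,
                             exact = FALSE) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) abort("distance matrices differ in size")
  n <- nrow(d1)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2)))
      abort("sample sets differ")
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  lt <- lower.tri(d1)
  r_obs <- cor(d1[lt], d2[lt])
  stat <- function(perm) {
    dp <- d2[perm, perm]
    cor(d1[lt], dp[lt])
  }
  if (exact) {
    if (n > 7) abort("exact enumeration limited to n <= 7")
    perms <- all_permutations(n)
    rs <- vapply(perms, stat, 0)
    p <- mean(rs >= r_obs - 1e-12)
    return(tibble::tibble(r = r_obs, p = p, n_perm = length(perms),
                          exact = TRUE))
  }
  rs <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    stat(sample.int(n)), 0))
  tibble::tibble(r = r_obs, p = (1 + sum(rs >= r_obs - 1e-12)) / (n_perm + 1),
                 n_perm = n_perm, exact = FALSE)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- list()
  for (s in sub) {
    for (k in seq_len(n)) {
      out[[length(out) + 1]] <- append(s, n, after = k - 1)
    }
  }
  out
}
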