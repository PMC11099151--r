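#' Genotype matrix container
#'
#' The substrate of all population-genetic statistics in the package:
#' diploid genotype dosages (count of ALT alleles, `NA` = missing) for a set
#' of samples at biallelic sites, together with per-site metadata and a
#' sample-to-population assignment.
#'
#' @param dosage Integer matrix, samples x sites, entries in `{0, 1, 2, NA}`.
#'   Row names are sample ids.
#' @param sites Tibble with one row per site. Must contain `chrom` and `pos`
#'   (1-based); usually also `ref`, `alt`, `ancestral` and filter annotations
#'   (`QD`, `QUAL`, `SOR`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`,
#'   `mean_depth`).
#' @param populations Named character vector mapping sample id to population
#'   label. Defaults to a single population `"pop1"`.
#' @param chrom_lengths Optional named numeric vector of chromosome lengths
#'   (bp); used as callable lengths by window statistics.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sites, populations = NULL,
                            chrom_lengths = NULL) {
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("s", seq_len(nrow(dosage)))
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("chrom", "pos") %in% names(sites)),
            nrow(sites) == ncol(dosage))
  if (is.null(populations))
    populations <- setNames(rep("pop1", nrow(dosage)), rownames(dosage))
  stopifnot(all(rownames(dosage) %in% names(populations)))
  populations <- populations[rownames(dosage)]
  storage.mode(dosage) <- "integer"
  structure(
    list(dosage = dosage, sites = sites, populations = populations,
         chrom_lengths = chrom_lengths),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " sites; populations: ",
      paste(names(table(x$populations)), table(x$populations),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Number of samples / sites in a genotype matrix
#' @param gm A [genotype_matrix()].
#' @return Integer count.
#' @export
n_samples <- function(gm) nrow(gm$dosage)

#' @rdname n_samples
#' @export
n_sites <- function(gm) ncol(gm$dosage)

#' Subset a genotype matrix by sites or samples
#'
#' @param gm A [genotype_matrix()].
#' @param keep Logical or integer index over sites (`subset_sites`) or a
#'   character vector of sample ids / logical index (`subset_samples`).
#' @return A new `genotype_matrix`.
#' @export
subset_sites <- function(gm, keep) {
  gm$dosage <- gm$dosage[, keep, drop = FALSE]
  gm$sites <- gm$sites[keep, , drop = FALSE]
  gm
}

#' @rdname subset_sites
#' @export
subset_samples <- function(gm, keep) {
  if (is.character(keep)) keep <- match(keep, rownames(gm$dosage))
  gm$dosage <- gm$dosage[keep, , drop = FALSE]
  gm$populations <- gm$populations[rownames(gm$dosage)]
  gm
}

#' Long-format view of a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per (sample, site) call.
#' @exportS3Method tibble::as_tibble
as_tibble.genotype_matrix <- function(x, ...) {
  tibble::tibble(
    sample = rep(rownames(x$dosage), times = ncol(x$dosage)),
    population = rep(unname(x$populations), times = ncol(x$dosage)),
    chrom = rep(x$sites$chrom, each = nrow(x$dosage)),
    pos = rep(x$sites$pos, each = nrow(x$dosage)),
    dosage = as.vector(x$dosage))
}

# per-site counts of called alleles and ALT alleles, optionally per group
site_allele_counts <- function(gm, samples = NULL) {
  d <- gm$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  called <- colSums(!is.na(d)) * 2L
  alt <- colSums(d, na.rm = TRUE)
  list(alt = alt, called = called)
}

#' ALT allele frequency at one site, per group of samples
#'
#' Frequency is the ALT dosage sum over twice the number of called samples in
#' the group; a group with no calls at the site yields `NA`.
#'
#' @param gm A [genotype_matrix()].
#' @param site Site index (position in `gm$sites`) or a single `chrom:pos`
#'   string.
#' @param grouping Named character vector sample -> group; defaults to the
#'   population assignment.
#' @return Tibble with columns `group`, `alt_freq`, `n_called`.
#' @export
allele_freq_by_group <- function(gm, site, grouping = NULL) {
  grouping <- grouping %||% gm$populations
  if (is.character(site)) {
    parts <- strsplit(site, ":", fixed = TRUE)[[1]]
    site <- which(gm$sites$chrom == parts[1] &
                  gm$sites$pos == as.numeric(parts[2]))
    if (length(site) != 1) abort("site not found")
  }
  if (site < 1 || site > n_sites(gm)) abort("site index out of range")
  bad <- setdiff(rownames(gm$dosage), names(grouping))
  if (length(bad)) abort(paste("unknown group label for samples:",
                               paste(bad, collapse = ", ")))
  d <- gm$dosage[, site]
  groups <- sort(unique(unname(grouping[rownames(gm$dosage)])))
  purrr::map_dfr(groups, function(g) {
    dg <- d[grouping[rownames(gm$dosage)] == g]
    nc <- sum(!is.na(dg))
    tibble::tibble(group = g,
                   alt_freq = if (nc == 0) NA_real_
                              else sum(dg, na.rm = TRUE) / (2 * nc),
                   n_called = nc)
  })
}

#' Per-site ALT allele frequencies for a set of samples
#'
#' @param gm A [genotype_matrix()].
#' @param samples Optional character vector of sample ids (default: all).
#' @return Tibble with `chrom`, `pos`, `alt_freq`, `n_alleles`.
#' @export
alt_freqs <- function(gm, samples = NULL) {
  ac <- site_allele_counts(gm, samples)
  tibble::tibble(chrom = gm$sites$chrom, pos = gm$sites$pos,
                 alt_freq = ifelse(ac$called > 0, ac$alt / ac$called, NA_real_),
                 n_alleles = ac$called)
}
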