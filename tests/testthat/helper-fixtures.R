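# Shared helpers for building small genotype matrices in code.

toy_gm <- function(dosage, pos = NULL, chrom = "chr1", populations = NULL,
                   ref = "A", alt = "T", ancestral = NULL, L = NULL) {
  dosage <- as.matrix(dosage)
  S <- ncol(dosage)
  sites <- tibble::tibble(chrom = chrom, pos = pos %||% (seq_len(S) * 100L),
                          ref = ref, alt = alt)
  if (!is.null(ancestral)) sites$ancestral <- ancestral
  genotype_matrix(dosage, sites, populations = populations,
                  chrom_lengths = if (!is.null(L)) setNames(L, chrom[1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# unwrap a partition into a canonical comparable form
canonical_partition <- function(families) {
  unname(sort(vapply(families, function(f) paste(sort(f), collapse = ","),
                     "")))
}

small_panmictic <- function(seed, n = 10, L = 5e4, sigma = 1,
                            theta = 0.001) {
  m <- demographic_model("panmictic", sexuality = c(pop1 = sigma),
                         theta_site = theta)
  simulate_population_set(m, n, L, seed = seed)
}
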