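# VCF reading, hard filters, the ordered cascade, cluster filtering,
# coding-effect classification and allele polarization.

test_that("GT strings map to dosages as documented", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    paste(c("chr1", "100", ".", "A", "T", "50", "PASS", ".", "GT",
            "0/0", "0/1", "1|1", "./."), collapse = "\t"),
    paste(c("chr1", "200", ".", "G", "C", "50", "PASS", ".", "GT",
            "0/.", "1/0", "1/1", "0|0"), collapse = "\t")), vcf)
  gm <- read_vcf(vcf)
  expect_identical(unname(gm$dosage[, 1]), c(0L, 1L, 2L, NA))
  expect_identical(unname(gm$dosage[, 2]), c(NA, 1L, 2L, 0L))  # half-call -> NA
  expect_identical(gm$sites$pos, c(100L, 200L))
})

test_that("hard filter fires on single clauses and respects boundaries", {
  mk <- function(...) {
    s <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                        QD = 25, QUAL = 500, SOR = 1, FS = 5, MQ = 60,
                        MQRankSum = 0, ReadPosRankSum = 0)
    over <- list(...)
    for (nm in names(over)) s[[nm]] <- over[[nm]]
    genotype_matrix(matrix(0L, 2, 1), s)
  }
  res <- hard_filter_sites(mk(QD = 1.9))
  expect_identical(n_sites(res$gm), 0L)
  expect_identical(unname(res$counts$n_removed[res$counts$rule == "QD"]), 1L)
  # all annotations exactly at their thresholds: retained
  at <- mk(QD = 2.0, QUAL = 30.0, SOR = 3.0, FS = 60.0, MQ = 40.0,
           MQRankSum = -12.5, ReadPosRankSum = -8.0)
  expect_identical(n_sites(hard_filter_sites(at)$gm), 1L)
  # missing annotation never fires
  expect_identical(n_sites(hard_filter_sites(mk(QD = NA))$gm), 1L)
})

test_that("planted hard-filter violations are counted exactly", {
  fx <- generate_vcf_fixture(c(qd = 5, sor = 2, clean = 30), seed = 2)
  res <- hard_filter_sites(read_vcf(fx$path))
  expect_identical(unname(res$counts$n_removed[res$counts$rule == "QD"]), 5L)
  expect_identical(unname(res$counts$n_removed[res$counts$rule == "SOR"]), 2L)
  expect_identical(n_sites(res$gm), 30L)
})

test_that("cascade attributes each site to the first firing rule", {
  # an organelle site that also has tiny MAF must count as organelle
  n <- 60
  dos <- rbind(matrix(rep(c(1L, rep(0L, n - 1)), 2), nrow = n),
               deparse.level = 0)
  dos <- matrix(c(1L, rep(0L, n - 1), 1L, rep(0L, n - 1)), nrow = n)
  sites <- tibble::tibble(chrom = c("chloroplast", "chr1"),
                          pos = c(100L, 200L), ref = "A", alt = "T",
                          mean_depth = 20, missingness = 0)
  gm <- genotype_matrix(dos, sites)
  res <- filter_cascade(gm)
  rep <- res$report
  expect_identical(rep$n_removed[rep$rule == "organelle"], 1L)
  expect_identical(rep$n_removed[rep$rule == "maf"], 1L)
  expect_identical(res$n_surviving, 0L)
})

test_that("MAF exactly at 1% is retained (strict inequality)", {
  n <- 50  # 100 alleles; one ALT allele = exactly 1%
  dos <- matrix(c(1L, rep(0L, n - 1)), nrow = n)
  gm <- genotype_matrix(dos, tibble::tibble(chrom = "chr1", pos = 100L,
                                            ref = "A", alt = "T",
                                            mean_depth = 20,
                                            missingness = 0))
  res <- filter_cascade(gm)
  expect_identical(res$n_surviving, 1L)
})

test_that("cascade reproduces planted per-rule counts and is idempotent", {
  fx <- generate_vcf_fixture(c(organelle = 3, missingness = 4, depth = 5,
                               multiallelic = 2, maf = 3, cluster = 6,
                               clean = 60), seed = 9)
  gm <- read_vcf(fx$path)
  res <- filter_cascade(gm)
  got <- setNames(res$report$n_removed, res$report$rule)
  expect_identical(got[["organelle"]], 3L)
  expect_identical(got[["missingness"]], 4L)
  expect_identical(got[["depth"]], 5L)
  expect_identical(got[["multiallelic"]], 2L)
  expect_identical(got[["maf"]], 3L)
  expect_identical(got[["cluster"]], 6L)
  expect_identical(res$n_surviving, 60L)
  # attribution partition: removals sum to input - surviving
  expect_identical(sum(res$report$n_removed),
                   res$n_input - res$n_surviving)
  # idempotence
  again <- filter_cascade(res$gm)
  expect_identical(sum(again$report$n_removed), 0L)
  expect_identical(again$n_surviving, res$n_surviving)
})

test_that("unknown cascade rules are a configuration error", {
  expect_error(cascade_config(rules = c("organelle", "frobnicate")),
               "unknown")
})

test_that("snp_cluster_filter condemns whole cluster spans", {
  expect_identical(snp_cluster_filter(c(100, 105, 109), k = 3, w = 10),
                   rep(FALSE, 3))
  expect_identical(snp_cluster_filter(c(100, 105, 120), k = 3, w = 10),
                   rep(TRUE, 3))
  # a fourth SNP inside the condemned span is removed too
  expect_identical(snp_cluster_filter(c(100, 103, 106, 109), k = 3, w = 10),
                   rep(FALSE, 4))
})

test_that("relaxed cluster rule matches direct window enumeration", {
  # 200 SNPs inside 1 kb: all removed; 199: none
  pos200 <- sort(sample(0:999, 200)) + 5000
  expect_true(all(!snp_cluster_filter(pos200, k = 200, w = 1000)))
  pos199 <- pos200[-1]
  expect_true(all(snp_cluster_filter(pos199, k = 200, w = 1000)))
  # random oracle: brute-force window check at small scale
  set.seed(4)
  for (rep in 1:20) {
    pos <- sort(sample.int(300, 40))
    k <- 3; w <- 10
    oracle <- rep(TRUE, 40)
    for (i in seq_len(38)) {
      if (pos[i + 2] - pos[i] <= w - 1)
        oracle[pos >= pos[i] & pos <= pos[i + 2]] <- FALSE
    }
    expect_identical(snp_cluster_filter(pos, k, w), oracle)
  }
})

test_that("coding effects match brute-force codon translation", {
  fx <- generate_annotation_fixture(L = 20000, n_genes = 4, seed = 5)
  genome <- read_fasta(fx$fasta)
  gff <- read_gff3(fx$gff)
  # put a SNP at every 7th CDS position of every gene
  sites <- list()
  for (i in seq_len(nrow(fx$genes))) {
    g <- fx$genes[i, ]
    for (p in seq(g$start, g$end, by = 7)) {
      ref <- substring(genome[["chr1"]], p, p)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[sample.int(3, 1)]
      sites[[length(sites) + 1]] <- tibble::tibble(chrom = "chr1", pos = p,
                                                   ref = ref, alt = alt)
    }
  }
  sites <- dplyr::arrange(dplyr::bind_rows(sites), pos)
  gm <- genotype_matrix(matrix(1L, 2, nrow(sites)), sites)
  eff <- classify_coding_effect(gm, gff, genome)
  # oracle: substitute the base genome-wide and translate the whole CDS
  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(sites))) {
    g <- fx$genes[fx$genes$start <= sites$pos[i] &
                    fx$genes$end >= sites$pos[i], ]
    cds_ref <- substring(genome[["chr1"]], g$start, g$end)
    mut <- genome[["chr1"]]
    substring(mut, sites$pos[i], sites$pos[i]) <- sites$alt[i]
    cds_alt <- substring(mut, g$start, g$end)
    if (g$strand == "-") {
      cds_ref <- clonepop:::revcomp(cds_ref)
      cds_alt <- clonepop:::revcomp(cds_alt)
    }
    aa_ref <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds_ref), no.init.codon = TRUE))
    aa_alt <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds_alt), no.init.codon = TRUE,
      if.fuzzy.codon = "solve"))
    want <- if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
    expect_identical(eff$effect[i], want)
  }
})

test_that("effect classification is strand-symmetric", {
  # codon examples on the forward strand
  genome <- c(chr1 = paste0("ATGTTTTAA"))
  gff <- tibble::tibble(chrom = "chr1", type = c("gene", "CDS"),
                        start = 1L, end = 9L, strand = "+", phase = 0L,
                        gene_id = "g1")
  gm <- genotype_matrix(
    matrix(1L, 2, 2),
    tibble::tibble(chrom = "chr1", pos = c(3L, 6L), ref = c("G", "T"),
                   alt = c("A", "C")))
  eff <- classify_coding_effect(gm, gff, genome)
  expect_identical(eff$effect, c("nonsynonymous", "synonymous"))  # M->I; F->F
  # the same gene on the reverse strand of the reverse-complement genome
  genome_rc <- c(chr1 = clonepop:::revcomp(genome[["chr1"]]))
  gff_rc <- dplyr::mutate(gff, strand = "-")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  gm_rc <- genotype_matrix(
    matrix(1L, 2, 2),
    tibble::tibble(chrom = "chr1", pos = 10L - c(3L, 6L),
                   ref = comp[c("G", "T")], alt = comp[c("A", "C")]))
  eff_rc <- classify_coding_effect(gm_rc, gff_rc, genome_rc)
  expect_setequal(paste(10L - eff$pos, eff$effect),
                  paste(eff_rc$pos, eff_rc$effect))
})

test_that("SNPs outside genes and CDS are classed by position", {
  genome <- c(chr1 = strrep("ACGT", 50))
  gff <- tibble::tibble(chrom = "chr1", type = c("gene", "CDS"),
                        start = c(50L, 60L), end = c(120L, 119L),
                        strand = "+", phase = 0L, gene_id = "g1")
  gm <- genotype_matrix(
    matrix(1L, 2, 2),
    tibble::tibble(chrom = "chr1", pos = c(10L, 55L), ref = "A", alt = "C"))
  eff <- suppressWarnings(classify_coding_effect(gm, gff, genome))
  expect_identical(eff$effect, c("intergenic", "intronic"))
})

test_that("polarization uses the outgroup allele only when it matches", {
  gm <- toy_gm(matrix(0L, 2, 3), ref = c("A", "A", "A"),
               alt = c("T", "T", "T"))
  gm <- polarize_alleles(gm, c("A", "T", "G"))
  expect_identical(gm$sites$ancestral, c("A", "T", NA))
  expect_identical(gm$sites$polarized, c(TRUE, TRUE, FALSE))
})

test_that("polarization recovers the simulated ancestral state exactly", {
  sim <- small_panmictic(seed = 61, n = 6, L = 2e4)
  truth_anc <- sim$gm$sites$ancestral
  gm <- sim$gm
  gm$sites$ancestral <- NULL
  gm <- polarize_alleles(gm, truth_anc)
  expect_identical(gm$sites$ancestral, truth_anc)
  expect_true(all(gm$sites$polarized))
})

test_that("group allele frequencies follow the hand count", {
  gm <- toy_gm(matrix(c(0L, 1L, 2L, NA), 4, 1),
               populations = setNames(rep("g1", 4), paste0("s", 1:4)))
  f <- allele_freq_by_group(gm, 1)
  expect_equal(f$alt_freq, 3 / 6)
  # all hom-ALT group
  gm2 <- toy_gm(matrix(2L, 3, 1))
  expect_equal(allele_freq_by_group(gm2, 1)$alt_freq, 1)
  # entirely missing group is undefined
  gm3 <- toy_gm(matrix(NA_integer_, 2, 1))
  expect_true(is.na(allele_freq_by_group(gm3, 1)$alt_freq))
  expect_error(allele_freq_by_group(gm, 1, grouping = c(s1 = "x")),
               "unknown group")
})

test_that("VCF writing round-trips dosages and annotations", {
  sim <- small_panmictic(seed = 71, n = 5, L = 2e4)
  p <- tempfile(fileext = ".vcf")
  write_vcf(sim$gm, p)
  back <- read_vcf(p)
  expect_identical(unname(back$dosage), unname(sim$gm$dosage))
  expect_identical(back$sites$pos, sim$gm$sites$pos)
  expect_identical(unname(back$chrom_lengths["chr1"]), 2e4)
})
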