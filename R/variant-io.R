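#' Read a multi-sample VCF into a genotype matrix
#'
#' Genotypes are encoded as ALT-allele dosages (`0/1` -> 1, `1/1` -> 2,
#' `./.` and half-calls -> `NA`); phased separators are accepted. Site order
#' is preserved. Per-site annotations `QD`, `SOR`, `FS`, `MQ`, `MQRankSum`,
#' `ReadPosRankSum` and `DP` are pulled from INFO (missing fields stay
#' `NA`); `mean_depth` is `DP / n_samples` and `missingness` the fraction
#' of uncalled genotypes.
#'
#' @param path VCF file (plain or gzipped).
#' @param populations Optional named character vector sample -> population.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, populations = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  allele_count <- function(g) {
    a <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    vapply(a, function(x) {
      if (length(x) != 2 || any(x == ".")) NA_integer_
      else sum(x != "0")
    }, 0L)
  }
  dosage <- t(apply(gt, 1, allele_count))
  if (nrow(gt) == 1) dosage <- matrix(dosage, nrow = 1)
  dosage <- t(dosage)  # samples x sites
  rownames(dosage) <- colnames(gt)

  fx <- vcfR::getFIX(v)
  info_num <- function(key) suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = key)))
  n <- nrow(dosage)
  sites <- tibble::tibble(
    chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
    ref = fx[, "REF"], alt = fx[, "ALT"],
    QUAL = suppressWarnings(as.numeric(fx[, "QUAL"])),
    QD = info_num("QD"), SOR = info_num("SOR"), FS = info_num("FS"),
    MQ = info_num("MQ"), MQRankSum = info_num("MQRankSum"),
    ReadPosRankSum = info_num("ReadPosRankSum"),
    mean_depth = info_num("DP") / n,
    missingness = colSums(is.na(dosage)) / n)
  meta <- v@meta[grepl("^##contig=", v@meta)]
  chrom_lengths <- NULL
  if (length(meta)) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", meta)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1",
                                            meta)))
    if (!anyNA(lens)) chrom_lengths <- setNames(lens, ids)
  }
  genotype_matrix(dosage, sites, populations = populations,
                  chrom_lengths = chrom_lengths)
}

#' GATK-style hard filtering of sites
#'
#' Removes a site if ANY clause fires: `QD < 2.0 | QUAL < 30.0 | SOR > 3.0 |
#' FS > 60.0 | MQ < 40.0 | MQRankSum < -12.5 | ReadPosRankSum < -8.0`
#' (defaults; all strict inequalities, so values at the threshold are
#' retained). A missing annotation never fires its clause. A site failing
#' several clauses is counted once per clause in the report.
#'
#' @param gm A [genotype_matrix()] whose `sites` carry the annotations.
#' @param thresholds Named list of clause thresholds.
#' @return List with `gm` (surviving sites) and `counts`, a tibble of
#'   per-clause removal counts.
#' @export
hard_filter_sites <- function(gm,
                              thresholds = list(QD = 2.0, QUAL = 30.0,
                                                SOR = 3.0, FS = 60.0,
                                                MQ = 40.0, MQRankSum = -12.5,
                                                ReadPosRankSum = -8.0)) {
  s <- gm$sites
  fire <- function(x, cmp, thr) !is.na(x) & cmp(x, thr)
  clauses <- list(
    QD = fire(s$QD, `<`, thresholds$QD),
    QUAL = fire(s$QUAL, `<`, thresholds$QUAL),
    SOR = fire(s$SOR, `>`, thresholds$SOR),
    FS = fire(s$FS, `>`, thresholds$FS),
    MQ = fire(s$MQ, `<`, thresholds$MQ),
    MQRankSum = fire(s$MQRankSum, `<`, thresholds$MQRankSum),
    ReadPosRankSum = fire(s$ReadPosRankSum, `<`, thresholds$ReadPosRankSum))
  clauses <- clauses[!vapply(thresholds[names(clauses)], is.null, TRUE)]
  removed <- Reduce(`|`, clauses)
  list(gm = subset_sites(gm, !removed),
       counts = tibble::tibble(rule = names(clauses),
                               n_removed = vapply(clauses, sum, 0L)),
       n_removed_total = sum(removed))
}

#' Configuration for the ordered site-filter cascade
#'
#' @param missingness_max Remove sites with missing genotypes above this
#'   fraction (strictly greater; default 20%).
#' @param depth_min,depth_max Mean-depth bounds; sites outside `[8, 41]`
#'   are removed.
#' @param maf_min Minor-allele-frequency threshold (strictly below 1% is
#'   removed; called-allele denominator).
#' @param cluster_k,cluster_w Remove SNPs in clusters of `>= k` SNPs whose
#'   span is `<= w` bp (defaults 3 SNPs / 10 bp; the relaxed alternative is
#'   `k = 200`, `w = 1000`).
#' @param organelle_contigs Contig names treated as organellar.
#' @param rules Rule order; a name outside the known set is a
#'   configuration error.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(missingness_max = 0.20, depth_min = 8,
                           depth_max = 41, maf_min = 0.01, cluster_k = 3,
                           cluster_w = 10,
                           organelle_contigs = c("chloroplast",
                                                 "mitochondrion"),
                           rules = c("organelle", "missingness", "depth",
                                     "multiallelic", "maf", "cluster")) {
  known <- c("organelle", "missingness", "depth", "multiallelic", "maf",
             "cluster")
  bad <- setdiff(rules, known)
  if (length(bad)) abort(paste("unknown cascade rule:",
                               paste(bad, collapse = ", ")))
  structure(list(missingness_max = missingness_max, depth_min = depth_min,
                 depth_max = depth_max, maf_min = maf_min,
                 cluster_k = cluster_k, cluster_w = cluster_w,
                 organelle_contigs = organelle_contigs, rules = rules),
            class = "cascade_config")
}

#' Ordered site-filter cascade
#'
#' Applies, in order: (1) organelle contigs, (2) missingness > 20%,
#' (3) mean depth outside `[8, 41]`, (4) non-biallelic sites,
#' (5) MAF < 1%, (6) SNP clusters (>= 3 SNPs within 10 bp). Every removed
#' site is attributed to the FIRST rule that removes it, so the per-rule
#' counts partition the removed sites and re-applying the cascade to its
#' own output removes nothing.
#'
#' @param gm A [genotype_matrix()].
#' @param config A [cascade_config()].
#' @return List with `gm` (survivors), `report` (tibble: `order`, `rule`,
#'   `n_removed`), `n_input`, `n_surviving`.
#' @export
filter_cascade <- function(gm, config = cascade_config()) {
  stopifnot(inherits(config, "cascade_config"))
  alive <- rep(TRUE, n_sites(gm))
  report <- tibble::tibble(order = seq_along(config$rules),
                           rule = config$rules, n_removed = 0L)
  miss <- if ("missingness" %in% names(gm$sites)) gm$sites$missingness
          else colSums(is.na(gm$dosage)) / nrow(gm$dosage)
  for (i in seq_along(config$rules)) {
    rule <- config$rules[i]
    idx <- which(alive)
    hit <- switch(rule,
      organelle = gm$sites$chrom[idx] %in% config$organelle_contigs,
      missingness = !is.na(miss[idx]) & miss[idx] > config$missingness_max,
      depth = {
        d <- gm$sites$mean_depth[idx]
        !is.na(d) & (d < config$depth_min | d > config$depth_max)
      },
      multiallelic = grepl(",", gm$sites$alt[idx], fixed = TRUE) |
        nchar(gm$sites$ref[idx]) != 1 |
        (nchar(gm$sites$alt[idx]) != 1 & !grepl(",", gm$sites$alt[idx])),
      maf = {
        ac <- site_allele_counts(gm)
        alt <- ac$alt[idx]; called <- ac$called[idx]
        f <- ifelse(called > 0, pmin(alt, called - alt) / called, NA)
        !is.na(f) & f < config$maf_min
      },
      cluster = {
        keep <- rep(TRUE, length(idx))
        for (ch in unique(gm$sites$chrom[idx])) {
          on_ch <- gm$sites$chrom[idx] == ch
          keep[on_ch] <- snp_cluster_filter(gm$sites$pos[idx][on_ch],
                                            k = config$cluster_k,
                                            w = config$cluster_w)
        }
        !keep
      })
    report$n_removed[i] <- sum(hit)
    alive[idx[hit]] <- FALSE
  }
  list(gm = subset_sites(gm, alive), report = report,
       n_input = length(alive), n_surviving = sum(alive))
}

#' SNP-cluster keep mask
#'
#' A SNP is removed if it lies inside the span of any run of `k`
#' consecutive SNPs whose inclusive physical span is `<= w` bp. The default
#' (`k = 3`, `w = 10`) removes clusters of three or more SNPs within a ten
#' base-pair window; the relaxed alternative is `k = 200`, `w = 1000`.
#'
#' @param positions Sorted physical positions on one chromosome.
#' @param k Minimum SNPs per cluster.
#' @param w Window width in bp (inclusive span).
#' @return Logical keep mask, `FALSE` for clustered SNPs.
#' @export
snp_cluster_filter <- function(positions, k = 3, w = 10) {
  n <- length(positions)
  if (is.unsorted(positions)) abort("positions must be sorted")
  keep <- rep(TRUE, n)
  if (n < k) return(keep)
  i <- seq_len(n - k + 1)
  bad <- positions[i + k - 1] - positions[i] <= w - 1
  for (b in which(bad)) {
    lo <- positions[b]; hi <- positions[b + k - 1]
    keep[positions >= lo & positions <= hi] <- FALSE
  }
  keep
}

#' Polarize alleles with an outgroup
#'
#' Sets the ancestral allele to the outgroup allele where it matches REF or
#' ALT; sites with an absent or mismatching outgroup allele are flagged
#' unpolarized (usable only by folded statistics).
#'
#' @param gm A [genotype_matrix()].
#' @param outgroup_alleles Character vector of outgroup alleles aligned to
#'   sites, or a tibble with `chrom`, `pos`, `allele`.
#' @return `gm` with `ancestral` and logical `polarized` columns in
#'   `sites`.
#' @export
polarize_alleles <- function(gm, outgroup_alleles) {
  if (is.data.frame(outgroup_alleles)) {
    key <- paste(gm$sites$chrom, gm$sites$pos)
    m <- match(key, paste(outgroup_alleles$chrom, outgroup_alleles$pos))
    og <- outgroup_alleles$allele[m]
  } else {
    stopifnot(length(outgroup_alleles) == n_sites(gm))
    og <- outgroup_alleles
  }
  match_ref <- !is.na(og) & og == gm$sites$ref
  match_alt <- !is.na(og) & og == gm$sites$alt
  gm$sites$ancestral <- dplyr::case_when(match_ref ~ gm$sites$ref,
                                         match_alt ~ gm$sites$alt,
                                         TRUE ~ NA_character_)
  gm$sites$polarized <- match_ref | match_alt
  gm
}

#' Read a GFF3 annotation into a tibble
#'
#' @param path GFF3 file.
#' @return Tibble with `chrom`, `source`, `type`, `start`, `end` (1-based
#'   inclusive), `strand`, `phase`, `gene_id` (ID for genes, innermost
#'   Parent's gene for CDS/mRNA).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  id <- as.character(df$ID)
  parent <- vapply(as.list(df$Parent), function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, "")
  # gene id: strip transcript/cds suffixes introduced by the fixture writer
  gene_id <- ifelse(df$type == "gene", id, sub("\\.(t1|cds)$", "", parent))
  gene_id <- sub("\\.(t1|cds)$", "", gene_id)
  tibble::tibble(chrom = as.character(df$seqnames),
                 type = as.character(df$type),
                 start = df$start, end = df$end,
                 strand = as.character(df$strand),
                 phase = if ("phase" %in% names(df))
                   as.integer(as.character(df$phase)) else NA_integer_,
                 gene_id = gene_id)
}

#' Read a FASTA genome as named character strings
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a BED file (0-based half-open) into a tibble
#' @param path BED file.
#' @return Tibble with `chrom`, `start`, `end` and optional `name`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name")[seq_len(ncol(df))]
  tibble::as_tibble(df)
}

#' Classify coding effects of SNPs
#'
#' For every SNP inside an annotated CDS, substitutes the ALT base into the
#' reference codon (reverse-strand codons are complemented) and translates
#' with the standard genetic code: `synonymous` when the amino acid is
#' unchanged, `nonsynonymous` otherwise. SNPs inside a gene but outside its
#' CDS are `intronic`, SNPs in no gene `intergenic`, non-SNP records
#' `other`. Genes whose CDS length is not divisible by three are skipped
#' with a warning.
#'
#' @param gm A [genotype_matrix()].
#' @param gff Annotation tibble from [read_gff3()] (needs `gene` and `CDS`
#'   rows).
#' @param fasta Named character vector of chromosome sequences (from
#'   [read_fasta()]).
#' @return Tibble `chrom`, `pos`, `effect`, `gene_id`, `codon_ref`,
#'   `codon_alt`, `aa_ref`, `aa_alt`.
#' @export
classify_coding_effect <- function(gm, gff, fasta) {
  code <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sites <- gm$sites
  out <- tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                        effect = NA_character_, gene_id = NA_character_,
                        codon_ref = NA_character_, codon_alt = NA_character_,
                        aa_ref = NA_character_, aa_alt = NA_character_)
  is_snp <- nchar(sites$ref) == 1 & nchar(sites$alt) == 1 &
    !grepl(",", sites$alt, fixed = TRUE)
  out$effect[!is_snp] <- "other"
  out$effect[is_snp] <- "intergenic"

  genes <- gff[gff$type == "gene", ]
  cds <- gff[gff$type == "CDS", ]
  for (g in seq_len(nrow(genes))) {
    gr <- genes[g, ]
    in_gene <- which(is_snp & sites$chrom == gr$chrom &
                     sites$pos >= gr$start & sites$pos <= gr$end)
    if (!length(in_gene)) next
    out$effect[in_gene] <- "intronic"
    out$gene_id[in_gene] <- gr$gene_id

    seg <- cds[cds$gene_id == gr$gene_id & cds$chrom == gr$chrom, ]
    if (!nrow(seg)) next
    seg <- seg[order(seg$start), ]
    cds_pos <- unlist(purrr::map2(seg$start, seg$end, seq))  # genomic, 5'->3' on +
    if (length(cds_pos) %% 3 != 0) {
      warn(paste("CDS length not divisible by 3; skipping gene", gr$gene_id))
      next
    }
    chrom_seq <- fasta[[gr$chrom]]
    if (is.null(chrom_seq)) abort(paste("chromosome missing in FASTA:",
                                        gr$chrom))
    bases <- strsplit(substring(chrom_seq, min(cds_pos), max(cds_pos)),
                      "")[[1]]
    cds_bases <- bases[cds_pos - min(cds_pos) + 1]
    if (gr$strand == "-") {
      cds_pos <- rev(cds_pos)
      cds_bases <- unname(comp[rev(cds_bases)])
    }
    idx_in_cds <- match(sites$pos[in_gene], cds_pos)
    coding <- which(!is.na(idx_in_cds))
    for (j in coding) {
      site <- in_gene[j]
      ci <- idx_in_cds[j]
      codon_i <- (ci - 1) %/% 3
      within <- (ci - 1) %% 3 + 1
      codon <- cds_bases[codon_i * 3 + 1:3]
      ref_b <- sites$ref[site]; alt_b <- sites$alt[site]
      if (gr$strand == "-") { ref_b <- comp[[ref_b]]; alt_b <- comp[[alt_b]] }
      if (codon[within] != ref_b) {
        warn(paste("REF mismatch at", sites$chrom[site], sites$pos[site]))
      }
      alt_codon <- codon
      alt_codon[within] <- alt_b
      aa_r <- code[[paste(codon, collapse = "")]]
      aa_a <- code[[paste(alt_codon, collapse = "")]]
      out$effect[site] <- if (aa_r == aa_a) "synonymous" else "nonsynonymous"
      out$codon_ref[site] <- paste(codon, collapse = "")
      out$codon_alt[site] <- paste(alt_codon, collapse = "")
      out$aa_ref[site] <- aa_r
      out$aa_alt[site] <- aa_a
    }
  }
  out
}

#' Write a genotype matrix as VCF v4.2
#'
#' INFO annotations present in `sites` (`QD`, `SOR`, `FS`, `MQ`,
#' `MQRankSum`, `ReadPosRankSum`, `mean_depth` as summed `DP`) are
#' written; absent ones get GATK-typical clean defaults so the output can
#' feed the hard-filter and cascade stages.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  n <- n_samples(gm)
  s <- gm$sites
  g <- function(col, dflt) if (!is.null(s[[col]])) ifelse(is.na(s[[col]]), dflt, s[[col]]) else rep(dflt, nrow(s))
  qd <- g("QD", 25); sor <- g("SOR", 1); fs <- g("FS", 5); mq <- g("MQ", 60)
  mqrs <- g("MQRankSum", 0); rprs <- g("ReadPosRankSum", 0)
  qual <- g("QUAL", 500)
  dp <- round(g("mean_depth", 20) * n)
  chroms <- unique(s$chrom)
  lens <- vapply(chroms, function(ch)
    round(gm$chrom_lengths[ch] %||% max(s$pos[s$chrom == ch])), 0)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", chroms, lens),
           paste0("##INFO=<ID=", c("QD", "SOR", "FS", "MQ", "MQRankSum",
                                   "ReadPosRankSum"),
                  ",Number=1,Type=Float,Description=\"x\">"),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(gm$dosage)), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(s)), function(i) {
    dos <- gm$dosage[, i]
    gt <- ifelse(is.na(dos), "./.", gt_code[dos + 1L])
    info <- sprintf("QD=%.2f;SOR=%.2f;FS=%.2f;MQ=%.2f;MQRankSum=%.2f;ReadPosRankSum=%.2f;DP=%d",
                    qd[i], sor[i], fs[i], mq[i], mqrs[i], rprs[i], dp[i])
    paste(c(s$chrom[i], s$pos[i], ".", s$ref[i], s$alt[i], qual[i], "PASS",
            info, "GT", gt), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}
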