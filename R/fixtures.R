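# Synthetic fixture generators: VCF with planted filter violations,
# bisulfite cytosine reports, genome annotation bundles, and clonal
# genotype panels.  All are pure functions of (parameters, seed).

hard_filter_classes <- c("qd", "qual", "sor", "fs", "mq", "mqranksum",
                         "readposranksum")
cascade_classes <- c("organelle", "missingness", "depth", "multiallelic",
                     "maf", "cluster")

#' Generate a VCF fixture with planted filter violations
#'
#' Emits a VCF v4.2 file in which every requested violation class is planted
#' exactly `spec[class]` times, each site violating only its own rule, plus
#' `spec["clean"]` sites passing every filter. Classes cover the GATK-style
#' hard-filter clauses (`qd`, `qual`, `sor`, `fs`, `mq`, `mqranksum`,
#' `readposranksum`) and the site cascade (`organelle`, `missingness`,
#' `depth`, `multiallelic`, `maf`, `cluster`). INFO fields `QD`, `SOR`,
#' `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`, `DP` are populated on every
#' line; `DP` is the summed depth over samples, so per-site mean depth is
#' `DP / n_samples`.
#'
#' @param spec Named integer vector of planted counts; names from the
#'   classes above plus `"clean"`. Unknown names are a configuration error.
#' @param seed Integer seed.
#' @param path Output VCF path (plain text).
#' @param n_samples Number of diploid samples (default 60, so a singleton
#'   heterozygote has MAF `1/120 < 1%`).
#'
#' @return Invisibly, a list with `path`, the planted `truth` record
#'   (`planted_filter_counts`, `n_clean`, `positions` per class) and
#'   `n_sites` written.
#' @export
generate_vcf_fixture <- function(spec, seed, path = tempfile(fileext = ".vcf"),
                                 n_samples = 60) {
  spec <- unlist(spec)
  valid <- c(hard_filter_classes, cascade_classes, "clean")
  bad <- setdiff(names(spec), valid)
  if (length(bad))
    abort(paste0("unknown violation class(es): ", paste(bad, collapse = ", "),
                 "; valid classes: ", paste(valid, collapse = ", ")))
  if (any(spec < 0)) abort("planted counts must be non-negative")
  counts <- setNames(rep(0L, length(valid)), valid)
  counts[names(spec)] <- as.integer(spec)

  with_seed(seed, {
    rows <- list()
    truth_pos <- list()
    next_pos <- 1000L

    clean_site <- function(pos, chrom = "chr1") {
      p <- runif(1, 0.15, 0.85)
      dos <- rbinom(n_samples, 2, p)
      # keep MAF comfortably above the 1% cascade threshold
      while (min(sum(dos), 2 * n_samples - sum(dos)) < 0.1 * n_samples)
        dos <- rbinom(n_samples, 2, p)
      list(chrom = chrom, pos = pos, ref = "A", alt = "T", qual = 500,
           qd = 25, sor = 1, fs = 5, mq = 60, mqrs = 0, rprs = 0,
           dp = 20L * n_samples, dos = dos, miss = rep(FALSE, n_samples))
    }

    add <- function(class, site) {
      rows[[length(rows) + 1]] <<- c(site, list(class = class))
      truth_pos[[class]] <<- c(truth_pos[[class]],
                               paste0(site$chrom, ":", site$pos))
    }

    for (class in valid) {
      k <- counts[[class]]
      if (k == 0 || class == "cluster") next
      for (i in seq_len(k)) {
        s <- clean_site(next_pos)
        next_pos <- next_pos + 50L
        switch(class,
          qd = { s$qd <- 1.0 },
          qual = { s$qual <- 10 },
          sor = { s$sor <- 4.0 },
          fs = { s$fs <- 80 },
          mq = { s$mq <- 30 },
          mqranksum = { s$mqrs <- -13 },
          readposranksum = { s$rprs <- -9 },
          organelle = { s$chrom <- "chloroplast"; s$pos <- 100L + 50L * i },
          missingness = { s$miss[seq_len(ceiling(0.3 * n_samples))] <- TRUE },
          depth = { s$dp <- 5L * n_samples },
          multiallelic = { s$alt <- "T,G" },
          maf = { s$dos <- c(1L, rep(0L, n_samples - 1L)) },
          clean = NULL)
        add(class, s)
      }
    }
    # clusters: groups of 3-5 SNPs spanning <= 10 bp
    k <- counts[["cluster"]]
    while (k > 0) {
      g <- if (k %% 3 == 0) 3L else if (k %% 3 == 1 && k > 3) 4L
           else if (k %% 3 == 2) 5L else k
      g <- min(g, k)
      if (g < 3) g <- k  # counts 1-2 cannot form a cluster alone
      if (g < 3) abort("cluster count must be 0 or >= 3")
      offs <- round(seq(0, 9, length.out = g))
      for (o in offs) add("cluster", clean_site(next_pos + o))
      next_pos <- next_pos + 100L
      k <- k - g
    }

    ord <- order(vapply(rows, function(r) r$chrom, ""),
                 vapply(rows, function(r) r$pos, 0))
    rows <- rows[ord]

    sample_ids <- sprintf("s%02d", seq_len(n_samples))
    hdr <- c("##fileformat=VCFv4.2",
             "##contig=<ID=chr1,length=10000000>",
             "##contig=<ID=chloroplast,length=150000>",
             paste0("##INFO=<ID=", c("QD", "SOR", "FS", "MQ", "MQRankSum",
                                     "ReadPosRankSum"),
                    ",Number=1,Type=Float,Description=\"x\">"),
             "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_ids), collapse = "\t"))
    body <- vapply(rows, function(r) {
      gt <- c("0/0", "0/1", "1/1")[r$dos + 1L]
      gt[r$miss] <- "./."
      info <- sprintf("QD=%.2f;SOR=%.2f;FS=%.2f;MQ=%.2f;MQRankSum=%.2f;ReadPosRankSum=%.2f;DP=%d",
                      r$qd, r$sor, r$fs, r$mq, r$mqrs, r$rprs, r$dp)
      paste(c(r$chrom, r$pos, ".", r$ref, r$alt, r$qual, "PASS", info, "GT",
              gt), collapse = "\t")
    }, "")
    writeLines(c(hdr, body), path)

    truth <- structure(
      list(planted_filter_counts = counts[counts > 0 | names(counts) == "clean"],
           n_clean = counts[["clean"]], positions = truth_pos, seed = seed),
      class = "sim_truth")
    invisible(list(path = path, truth = truth, n_sites = length(rows)))
  })
}

#' Generate bisulfite cytosine-report fixtures
#'
#' Per-sample cytosine reports in the bisulfite-aligner dialect (chrom,
#' 1-based pos, strand, methylated count, unmethylated count, context,
#' trinucleotide). A planted fraction of sites per context is truly
#' methylated with per-read methylation probability `target_wml[context]`;
#' all other sites, and every cytosine on the chloroplast control contig,
#' are truly unmethylated and show methylated reads only through bisulfite
#' non-conversion at rate `nonconv`.
#'
#' @param n_samples Number of samples.
#' @param target_wml Named vector: per-read methylation level at truly
#'   methylated sites, per context `CpG`, `CHG`, `CHH`.
#' @param nonconv Non-conversion rate in `[0, 0.1)`.
#' @param seed Integer seed.
#' @param n_sites Sites per context on the nuclear contig.
#' @param prop_methylated Named vector: fraction of truly methylated sites
#'   per context (defaults mirror a sparsely methylated aquatic plant:
#'   7.6% CpG, 2.3% CHG, 0.1% CHH).
#' @param mean_coverage Mean read coverage (Poisson).
#' @param n_chloroplast Cytosines on the chloroplast control contig.
#'
#' @return List with `samples` (named list of report tibbles) and `truth`
#'   (generating parameters and truly methylated positions per context).
#' @export
generate_methylome_fixture <- function(n_samples,
                                       target_wml = c(CpG = 0.8, CHG = 0.6,
                                                      CHH = 0.3),
                                       nonconv = 0.005, seed = 1,
                                       n_sites = 1000,
                                       prop_methylated = c(CpG = 0.076,
                                                           CHG = 0.023,
                                                           CHH = 0.001),
                                       mean_coverage = 20,
                                       n_chloroplast = 500) {
  stopifnot(nonconv >= 0, nonconv < 0.1,
            all(target_wml >= 0 & target_wml <= 1))
  contexts <- c("CpG", "CHG", "CHH")
  with_seed(seed, {
    # methylation status is a property of the site, shared across samples
    site_tbl <- purrr::map_dfr(contexts, function(ctx) {
      tibble::tibble(
        chrom = "chr1",
        pos = sort(sample.int(n_sites * 20L, n_sites)),
        strand = sample(c("+", "-"), n_sites, replace = TRUE),
        context = ctx,
        trinucleotide = switch(ctx, CpG = "CGA", CHG = "CAG", CHH = "CAT"),
        methylated = runif(n_sites) < prop_methylated[[ctx]])
    })
    chl <- tibble::tibble(
      chrom = "chloroplast",
      pos = sort(sample.int(n_chloroplast * 20L, n_chloroplast)),
      strand = sample(c("+", "-"), n_chloroplast, replace = TRUE),
      context = sample(contexts, n_chloroplast, replace = TRUE,
                       prob = c(0.25, 0.25, 0.5)),
      trinucleotide = "CNN", methylated = FALSE)
    site_tbl <- dplyr::bind_rows(site_tbl, chl)

    samples <- lapply(seq_len(n_samples), function(i) {
      cov <- pmax(1L, rpois(nrow(site_tbl), mean_coverage))
      rate <- ifelse(site_tbl$methylated,
                     target_wml[site_tbl$context], nonconv)
      m <- rbinom(nrow(site_tbl), cov, rate)
      tibble::tibble(chrom = site_tbl$chrom, pos = site_tbl$pos,
                     strand = site_tbl$strand, m_reads = m,
                     u_reads = cov - m, context = site_tbl$context,
                     trinucleotide = site_tbl$trinucleotide)
    })
    names(samples) <- sprintf("meth%02d", seq_len(n_samples))
    truth <- list(nonconv = nonconv, target_wml = target_wml,
                  prop_methylated = prop_methylated,
                  methylated_sites = site_tbl[site_tbl$methylated,
                                              c("chrom", "pos", "context")],
                  seed = seed)
    list(samples = samples, truth = truth)
  })
}

#' Write / read a cytosine report (tab-separated, no header)
#'
#' @param records Report tibble (`chrom`, `pos`, `strand`, `m_reads`,
#'   `u_reads`, `context`, `trinucleotide`).
#' @param path File path.
#' @return `write_cytosine_report` returns `path` invisibly;
#'   `read_cytosine_report` returns the report tibble.
#' @export
write_cytosine_report <- function(records, path) {
  utils::write.table(
    records[, c("chrom", "pos", "strand", "m_reads", "u_reads", "context",
                "trinucleotide")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_cytosine_report
#' @export
read_cytosine_report <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "pos", "strand", "m_reads",
                                        "u_reads", "context",
                                        "trinucleotide"),
                          colClasses = c("character", "integer", "character",
                                         "integer", "integer", "character",
                                         "character"))
  tibble::as_tibble(df)
}

# codons that do not translate to stop, used to build valid CDS
non_stop_codons <- function() {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  setdiff(codons, c("TAA", "TAG", "TGA"))
}

#' Generate a genome annotation fixture (FASTA + GFF3 + TE BED + families)
#'
#' Places `n_genes` non-overlapping single-exon genes with valid CDS
#' (start codon, in-frame, no internal stop, stop codon) on a random
#' genome, plus transposable-element intervals disjoint from all CDS, and
#' assigns every gene to exactly one gene family.
#'
#' @param L Genome length (bp).
#' @param n_genes Number of genes (>= 1).
#' @param n_families Number of gene families.
#' @param seed Integer seed.
#' @param dir Output directory for `genome.fa`, `genes.gff3`, `tes.bed`,
#'   `families.tsv`.
#' @param cds_codons Range of CDS length in codons (including start/stop).
#' @param n_tes Number of TE intervals.
#' @param max_tries Placement retries before giving up.
#'
#' @return List with file paths, the `genes` tibble (1-based inclusive
#'   coordinates), `tes` tibble (0-based half-open), `families` tibble and
#'   the genome as a named character vector.
#' @export
generate_annotation_fixture <- function(L, n_genes, n_families = 3, seed = 1,
                                        dir = tempfile("annot"),
                                        cds_codons = c(100, 300),
                                        n_tes = max(1, n_genes %/% 2),
                                        max_tries = 200) {
  stopifnot(n_genes >= 1, n_families >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    genome <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    ok_codons <- non_stop_codons()

    occupied <- tibble::tibble(start = integer(0), end = integer(0))
    place <- function(width) {
      for (i in seq_len(max_tries)) {
        s <- sample.int(L - width, 1)
        if (!any(s <= occupied$end & (s + width - 1) >= occupied$start))
          return(s)
      }
      abort("cannot place features without overlap; increase L")
    }

    genes <- purrr::map_dfr(seq_len(n_genes), function(g) {
      n_cod <- sample(seq(cds_codons[1], cds_codons[2]), 1)
      len <- 3L * n_cod
      if (len + 2 > L) abort("gene length exceeds genome length")
      cds <- paste0("ATG",
                    paste(sample(ok_codons, n_cod - 2, replace = TRUE),
                          collapse = ""),
                    "TAA")
      start <- place(len)
      end <- start + len - 1L
      occupied <<- dplyr::bind_rows(occupied,
                                    tibble::tibble(start = start, end = end))
      strand <- sample(c("+", "-"), 1)
      genomic <- if (strand == "+") cds else revcomp(cds)
      genome[start:end] <<- strsplit(genomic, "")[[1]]
      tibble::tibble(gene_id = sprintf("gene%03d", g), chrom = "chr1",
                     start = start, end = end, strand = strand,
                     cds_length = len)
    })

    tes <- purrr::map_dfr(seq_len(n_tes), function(t) {
      width <- sample(200:800, 1)
      start <- place(width)
      occupied <<- dplyr::bind_rows(occupied,
                                    tibble::tibble(start = start,
                                                   end = start + width - 1L))
      tibble::tibble(te_id = sprintf("te%03d", t), chrom = "chr1",
                     start = start - 1L, end = start + width - 1L)
    })

    families <- tibble::tibble(
      gene_id = genes$gene_id,
      family = sprintf("fam%02d", sample.int(n_families, n_genes,
                                             replace = TRUE)))

    genome_str <- paste(genome, collapse = "")
    fasta_path <- file.path(dir, "genome.fa")
    writeLines(c(">chr1", substring(genome_str,
                                    seq(1, L, 80),
                                    pmin(seq(1, L, 80) + 79, L))),
               fasta_path)
    gff_path <- file.path(dir, "genes.gff3")
    gff <- c("##gff-version 3",
             sprintf("##sequence-region chr1 1 %d", L),
             unlist(lapply(seq_len(n_genes), function(g) {
               r <- genes[g, ]
               c(sprintf("chr1\tclonepop\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                         r$start, r$end, r$strand, r$gene_id),
                 sprintf("chr1\tclonepop\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                         r$start, r$end, r$strand, r$gene_id, r$gene_id),
                 sprintf("chr1\tclonepop\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s.t1",
                         r$start, r$end, r$strand, r$gene_id, r$gene_id))
             })))
    writeLines(gff, gff_path)
    bed_path <- file.path(dir, "tes.bed")
    writeLines(sprintf("%s\t%d\t%d\t%s", tes$chrom, tes$start, tes$end,
                       tes$te_id), bed_path)
    fam_path <- file.path(dir, "families.tsv")
    utils::write.table(families, fam_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(fasta = fasta_path, gff = gff_path, te_bed = bed_path,
         families_path = fam_path, genes = genes, tes = tes,
         families = families, genome = setNames(genome_str, "chr1"))
  })
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""), "", USE.NAMES = FALSE))
}

#' Generate a genotype panel with a known clonal-family partition
#'
#' Builds a genotype matrix of divergent founder lineages, each expanded
#' into a clonal family whose members differ only by a small number of
#' homozygous differences and by missing calls, with ground truth recorded.
#'
#' @param n_lineages Number of founder lineages.
#' @param clones_per_lineage Members per clonal family (single count or
#'   vector).
#' @param n_sites Number of sites.
#' @param hom_divergence_within Per-member homozygous mutation rate away
#'   from the founder (pairwise divergence is about twice this; the
#'   default 1e-5 keeps clone pairs well under the 1e-4 clonal
#'   threshold).
#' @param hom_divergence_between Homozygous divergence between lineages
#'   (default 0.01, well above it).
#' @param het_rate Per-site heterozygosity of each founder.
#' @param missing_rate Per-call missingness.
#' @param seed Integer seed.
#'
#' @return List with `gm` and `truth` (true partition as a list of sample
#'   id sets).
#' @export
generate_clonal_fixture <- function(n_lineages = 5, clones_per_lineage = 4,
                                    n_sites = 50000,
                                    hom_divergence_within = 1e-5,
                                    hom_divergence_between = 0.01,
                                    het_rate = 0.05, missing_rate = 0.02,
                                    seed = 1) {
  if (length(clones_per_lineage) == 1)
    clones_per_lineage <- rep(clones_per_lineage, n_lineages)
  with_seed(seed, {
    base <- rbinom(n_sites, 1, 0.5) * 2L          # shared homozygous background
    founders <- lapply(seq_len(n_lineages), function(l) {
      g <- base
      flip <- runif(n_sites) < hom_divergence_between / 2
      g[flip] <- 2L - g[flip]
      het <- runif(n_sites) < het_rate
      g[het] <- 1L
      g
    })
    rows <- list(); ids <- character(0); fam <- list()
    for (l in seq_len(n_lineages)) {
      members <- character(0)
      for (c in seq_len(clones_per_lineage[l])) {
        g <- founders[[l]]
        mut <- runif(n_sites) < hom_divergence_within
        mut <- mut & g != 1L
        g[mut] <- 2L - g[mut]
        g[runif(n_sites) < missing_rate] <- NA_integer_
        id <- sprintf("L%02dc%02d", l, c)
        rows[[id]] <- g; ids <- c(ids, id); members <- c(members, id)
      }
      fam[[l]] <- members
    }
    dosage <- do.call(rbind, rows)
    rownames(dosage) <- ids
    gm <- genotype_matrix(
      dosage,
      tibble::tibble(chrom = "chr1", pos = seq_len(n_sites) * 10L,
                     ref = "A", alt = "T"),
      populations = setNames(rep("pop1", length(ids)), ids))
    list(gm = gm, truth = list(true_clonal_partition = fam, seed = seed))
  })
}
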