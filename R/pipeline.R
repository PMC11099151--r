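# End-to-end orchestration: a single configuration drives filtering,
# clonal structure, diversity, sweep scans, branch CLR, enrichment,
# methylome analysis and ABC, writing per-stage TSV/JSON outputs.

pipeline_stages <- c("filter", "clonal", "diversity", "sweeps", "branch",
                     "enrichment", "methylome", "abc")

#' Pipeline configuration
#'
#' @param vcf,gff,fasta,te_bed,families Input paths (VCF, GFF3 annotation,
#'   genome FASTA, TE BED, gene-family TSV).
#' @param cytosine_reports Named character vector of per-sample cytosine
#'   report paths (optional; methylome stage skipped without it).
#' @param population_table Path to a TSV with columns `sample`,
#'   `population`.
#' @param out_dir Output directory.
#' @param seed Global seed; every stochastic stage derives its own stream
#'   from it.
#' @param stages Stages to run, in dependency order (subset of
#'   `filter, clonal, diversity, sweeps, branch, enrichment, methylome,
#'   abc`).
#' @param params Named list of per-stage parameter overrides.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(vcf, gff = NULL, fasta = NULL, te_bed = NULL,
                            families = NULL, cytosine_reports = NULL,
                            population_table = NULL, out_dir = tempfile("run"),
                            seed = 1, stages = pipeline_stages,
                            params = list()) {
  structure(list(vcf = vcf, gff = gff, fasta = fasta, te_bed = te_bed,
                 families = families, cytosine_reports = cytosine_reports,
                 population_table = population_table, out_dir = out_dir,
                 seed = seed, stages = stages, params = params),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; returns diagnostics rather than
#' raising, and an empty tibble means the configuration is runnable.
#'
#' @param config A [pipeline_config()].
#' @return Tibble with `field` and `problem` (zero rows when valid).
#' @export
validate_config <- function(config) {
  probs <- list()
  note <- function(field, problem)
    probs[[length(probs) + 1]] <<- tibble::tibble(field = field,
                                                  problem = problem)
  if (!inherits(config, "pipeline_config")) {
    note("config", "not a pipeline_config object")
    return(dplyr::bind_rows(probs))
  }
  bad_stage <- setdiff(config$stages, pipeline_stages)
  if (length(bad_stage))
    note("stages", paste("unknown stage:", paste(bad_stage, collapse = ", ")))
  for (f in c("vcf", "gff", "fasta", "te_bed", "families",
              "population_table")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p))
      note(f, paste("file does not exist:", p))
  }
  if (is.null(config$vcf)) note("vcf", "required input missing")
  for (p in config$cytosine_reports %||% character(0)) {
    if (!file.exists(p)) note("cytosine_reports",
                              paste("file does not exist:", p))
  }
  if (!is_scalar_number(config$seed)) note("seed", "must be a single number")
  pr <- config$params
  if (!is.null(pr$abc$sigma_range) &&
      (any(pr$abc$sigma_range < 0) || any(pr$abc$sigma_range > 1)))
    note("params.abc.sigma_range", "sexuality fraction must lie in [0, 1]")
  if (!is.null(config$population_table) && !is.null(config$vcf) &&
      file.exists(config$population_table) && file.exists(config$vcf)) {
    pt <- utils::read.table(config$population_table, header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
    hdr <- readLines(config$vcf, n = 500)
    hdr <- hdr[startsWith(hdr, "#CHROM")]
    if (length(hdr)) {
      vcf_samples <- strsplit(hdr, "\t")[[1]][-(1:9)]
      missing <- setdiff(vcf_samples, pt$sample)
      if (length(missing))
        note("population_table",
             paste("samples missing from table:",
                   paste(utils::head(missing, 5), collapse = ", ")))
    }
  }
  dplyr::bind_rows(probs)
}

write_tsv_out <- function(x, dir, name) {
  utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing per-stage TSV
#' and JSON outputs under `config$out_dir` and returning a consolidated
#' report (per-population diversity panel, wML tables, selection tracks).
#' Every output is stamped with the configuration hash and seed, and the
#' whole run is deterministic given `(config, seed)`.
#'
#' @param config A [pipeline_config()]; must validate cleanly.
#' @return A `pipeline_report` list with one element per executed stage
#'   plus `config_hash`, `seed` and `out_dir`.
#' @export
run_pipeline <- function(config) {
  diag <- validate_config(config)
  if (nrow(diag))
    abort(paste("configuration invalid:",
                paste(diag$field, diag$problem, collapse = "; ")))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config_hash = rlang::hash(config[setdiff(names(config),
                                                          "out_dir")]),
                 seed = config$seed, out_dir = config$out_dir)
  stage_on <- function(s) s %in% config$stages
  run_stage <- function(name, code) {
    tryCatch(code, error = function(e)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e),
                   " (partial outputs kept in ", config$out_dir, ")")))
  }

  pops <- NULL
  if (!is.null(config$population_table)) {
    pt <- utils::read.table(config$population_table, header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
    pops <- setNames(pt$population, pt$sample)
  }

  # filter ---------------------------------------------------------------
  gm <- run_stage("filter", {
    gm0 <- read_vcf(config$vcf, populations = pops)
    hf <- hard_filter_sites(gm0)
    casc <- filter_cascade(hf$gm, config$params$cascade %||% cascade_config())
    if (stage_on("filter")) {
      write_tsv_out(hf$counts, config$out_dir, "hard_filter_counts.tsv")
      write_tsv_out(casc$report, config$out_dir, "cascade_report.tsv")
      write_vcf(casc$gm, file.path(config$out_dir, "filtered.vcf"))
      report$filter <- list(hard_filter = hf$counts, cascade = casc$report,
                            n_input = casc$n_input,
                            n_surviving = casc$n_surviving)
    }
    casc$gm
  })
  if (stage_on("clonal")) {
    report$clonal <- run_stage("clonal", {
      pw <- pairwise_genotype_distances(gm)
      part <- clonal_families(pw, gm = gm)
      het <- individual_heterozygosity(gm)
      write_tsv_out(pw, config$out_dir, "pairwise_distances.tsv")
      write_tsv_out(tidy(part), config$out_dir, "clonal_families.tsv")
      write_tsv_out(het, config$out_dir, "heterozygosity.tsv")
      list(partition = glance(part), het = het,
           representatives = part$representative)
    })
  }
  if (stage_on("diversity")) {
    report$diversity <- run_stage("diversity", {
      pops_u <- sort(unique(unname(gm$populations)))
      L <- sum(vapply(unique(gm$sites$chrom), function(ch)
        gm$chrom_lengths[ch] %||% max(gm$sites$pos[gm$sites$chrom == ch]),
        0))
      panel <- purrr::map_dfr(pops_u, function(p) {
        sam <- which(gm$populations == p)
        ld <- ld_decay(subset_samples(gm, sam))
        dd <- decay_distance_at(ld, 0.2)
        hetm <- population_heterozygosity(subset_samples(gm, sam))
        tibble::tibble(population = p,
                       pi = region_pi(gm, callable_length = L,
                                      samples = sam),
                       ld_decay_kb = if (is.infinite(dd)) NA_real_
                                     else dd / 1000,
                       median_het = hetm$median_het[1])
      })
      wins <- sliding_windows(gm, size = config$params$window_size %||% 5e4,
                              step = config$params$window_step %||% 1e4,
                              stat = "pi")
      write_tsv_out(panel, config$out_dir, "population_panel.tsv")
      write_tsv_out(wins, config$out_dir, "pi_windows.tsv")
      list(panel = panel, genome_avg_pi = attr(wins, "genome_avg"))
    })
  }
  genes_tbl <- NULL
  if (!is.null(config$gff)) {
    gff_tbl <- read_gff3(config$gff)
    genes_tbl <- gff_tbl[gff_tbl$type == "gene", ]
  }
  if (stage_on("sweeps")) {
    report$sweeps <- run_stage("sweeps", {
      # without an outgroup the REF allele serves as the ancestral state
      gm_pol <- if (!("ancestral" %in% names(gm$sites)) ||
                    all(is.na(gm$sites$ancestral)))
        polarize_alleles(gm, gm$sites$ref) else gm
      clr <- clr_scan(gm_pol)
      mu <- mu_scan(gm_pol, k = config$params$mu_k %||% 25)
      top_clr <- top_fraction(clr, 0.01)
      top_mu <- top_fraction(mu, 0.01)
      write_tsv_out(clr, config$out_dir, "clr_scan.tsv")
      write_tsv_out(mu[, c("chrom", "start", "end", "pos", "value")],
                    config$out_dir, "mu_scan.tsv")
      sel_genes <- NULL
      if (!is.null(genes_tbl)) {
        g_clr <- overlap_genes(top_clr, genes_tbl)
        g_mu <- overlap_genes(top_mu, genes_tbl)
        sel_genes <- intersect_gene_lists(g_clr$gene_id, g_mu$gene_id)
        write_tsv_out(tibble::tibble(gene_id = sel_genes), config$out_dir,
                      "selected_genes.tsv")
      }
      list(n_clr_windows = nrow(clr), n_top_clr = nrow(top_clr),
           n_top_mu = nrow(top_mu), selected_genes = sel_genes)
    })
  }
  if (stage_on("branch")) {
    report$branch <- run_stage("branch", {
      tab <- sort(table(gm$populations), decreasing = TRUE)
      if (length(tab) < 3) {
        list(skipped = "fewer than three populations")
      } else {
        trio <- names(tab)[1:3]
        sc <- threepop_scan(gm, out = trio[1], a = trio[2], b = trio[3],
                            window_snps = config$params$branch_window %||% 50,
                            focal_every = config$params$branch_every %||% 10,
                            min_snps = config$params$branch_min_snps %||% 100)
        write_tsv_out(sc$scan_a, config$out_dir, "branch_clr_a.tsv")
        write_tsv_out(sc$scan_b, config$out_dir, "branch_clr_b.tsv")
        list(tree = trio, omega_a = sc$params$omega_a,
             omega_b = sc$params$omega_b,
             top_a = nrow(top_fraction(sc$scan_a, 0.01)),
             top_b = nrow(top_fraction(sc$scan_b, 0.01)))
      }
    })
  }
  if (stage_on("enrichment") && !is.null(config$te_bed) &&
      !is.null(genes_tbl) && !is.null(config$families)) {
    report$enrichment <- run_stage("enrichment", {
      tes <- read_bed(config$te_bed)
      fam <- utils::read.table(config$families, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      gf <- dplyr::left_join(genes_tbl, fam, by = "gene_id")
      gf$start0 <- gf$start - 1
      genome <- tibble::tibble(
        chrom = unique(gm$sites$chrom),
        length = vapply(unique(gm$sites$chrom), function(ch)
          gm$chrom_lengths[ch] %||% max(gm$sites$pos[gm$sites$chrom == ch]),
          0))
      enr <- family_enrichment(
        tes[, c("chrom", "start", "end")],
        tibble::tibble(chrom = gf$chrom, start = gf$start0, end = gf$end,
                       family = gf$family),
        genome, n_perm = config$params$n_perm %||% 200,
        seed = derive_seed(config$seed, 6))
      write_tsv_out(enr, config$out_dir, "family_enrichment.tsv")
      list(enrichment = enr)
    })
  }
  if (stage_on("methylome") && length(config$cytosine_reports %||% c())) {
    report$methylome <- run_stage("methylome", {
      reports <- lapply(config$cytosine_reports, read_cytosine_report)
      called <- lapply(reports, function(r)
        call_methylated(r, e = nonconversion_rate(r)))
      wml_tbl <- purrr::map_dfr(names(called), function(s) {
        purrr::map_dfr(c("CpG", "CHG", "CHH"), function(ctx)
          tibble::tibble(sample = s, context = ctx,
                         wml = weighted_ml(called[[s]], context = ctx),
                         mc = mc_proportion(called[[s]], context = ctx)))
      })
      write_tsv_out(wml_tbl, config$out_dir, "wml_by_sample.tsv")
      list(wml = wml_tbl)
    })
  }
  if (stage_on("abc")) {
    report$abc <- run_stage("abc", {
      n_sims <- config$params$abc_n_sims %||% 90
      tab <- abc_reference_table(n_sims = n_sims,
                                 n_per_pop = 4,
                                 L = config$params$abc_L %||% 5e4,
                                 seed = derive_seed(config$seed, 8))
      obs <- summarize_gm(gm)
      res <- abc_reject(obs, tab, tolerance = 0.1)
      jsonlite::write_json(
        list(model_posterior = res$model_posterior,
             winning_scenario = res$winning_scenario),
        file.path(config$out_dir, "abc_result.json"))
      list(model_posterior = res$model_posterior,
           winning_scenario = res$winning_scenario)
    })
  }
  report_meta <- list(config_hash = report$config_hash, seed = report$seed,
                      stages = intersect(pipeline_stages, config$stages))
  jsonlite::write_json(report_meta, file.path(config$out_dir, "run_meta.json"),
                       auto_unbox = TRUE)
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed:", x$seed, "hash:", x$config_hash, "\n")
  cat("  stages:", paste(setdiff(names(x),
                                 c("config_hash", "seed", "out_dir")),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Build a demo configuration on bundled synthetic inputs
#'
#' Simulates a small four-population cohort, writes VCF / GFF3 / FASTA /
#' TE BED / gene-family / cytosine-report inputs into `dir`, and returns
#' a ready-to-run [pipeline_config()].
#'
#' @param dir Directory for the generated inputs.
#' @param seed Integer seed.
#' @param L Simulated chromosome length (default 100 kb).
#' @param n_per_pop Diploids per population (default 5).
#' @return A [pipeline_config()].
#' @export
demo_config <- function(dir = tempfile("demo"), seed = 1, L = 1e5,
                        n_per_pop = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_population_set(demographic_model(), n_per_pop, L,
                                 seed = derive_seed(seed, 1))
  gm <- sim$gm
  vcf <- file.path(dir, "cohort.vcf")
  write_vcf(gm, vcf)
  pt <- file.path(dir, "populations.tsv")
  utils::write.table(
    data.frame(sample = rownames(gm$dosage),
               population = unname(gm$populations)),
    pt, sep = "\t", quote = FALSE, row.names = FALSE)
  annot <- generate_annotation_fixture(L, n_genes = 12, n_families = 4,
                                       seed = derive_seed(seed, 2),
                                       dir = dir)
  meth <- generate_methylome_fixture(4, seed = derive_seed(seed, 3),
                                     n_sites = 400)
  reports <- vapply(names(meth$samples), function(s) {
    p <- file.path(dir, paste0(s, ".cov.tsv"))
    write_cytosine_report(meth$samples[[s]], p)
    p
  }, "")
  pipeline_config(vcf = vcf, gff = annot$gff, fasta = annot$fasta,
                  te_bed = annot$te_bed, families = annot$families_path,
                  cytosine_reports = reports, population_table = pt,
                  out_dir = file.path(dir, "out"), seed = seed)
}
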