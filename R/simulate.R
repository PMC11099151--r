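#' Demographic models for partially clonal populations
#'
#' Describes a population split history together with per-population diploid
#' effective sizes and sexuality fractions. Partial clonality enters the
#' coalescent only through effective recombination: a population reproducing
#' sexually in a fraction `sigma` of generations recombines at rate
#' `rho_site * sigma` per site per generation, so fully clonal populations
#' (`sigma = 0`) behave as single non-recombining genealogies.
#'
#' Four scenario topologies are built in:
#' * `"asia_ancestral"` / `"america_ancestral"`: one extant population is
#'   ancestral; Europe splits from SE-Asia most recently, then India, with
#'   the deep America/Asia split oldest.
#' * `"ghost_ancestral"`: America and SE-Asia both derive from an unsampled
#'   ancestral population at the deep split.
#' * `"panmictic"`: a single population (no splits); used for calibration.
#' * `"threepop"`: an (outgroup,(a,b)) tree for branch-specific selection
#'   scans.
#'
#' @param scenario Scenario id (see Details).
#' @param split_times Named vector of split times in generations before
#'   present. Keys `europe`, `india`, `deep` for the four-population
#'   scenarios; `ab`, `out` for `"threepop"`. Must satisfy the topology
#'   ordering (`europe < india < deep`, or `ab < out`).
#' @param pop_sizes Named vector of diploid effective sizes, one per
#'   population (including `ancestral` for the ghost scenario).
#' @param sexuality Named vector of sexuality fractions `sigma` in `[0, 1]`.
#' @param theta_site Expected pairwise nucleotide diversity per site in the
#'   reference (first sampled) population; fixes the mutation rate via
#'   `mu = theta_site / (4 * N_ref)`.
#' @param rho_site Sexual-phase recombination rate per site per generation.
#'
#' @return An object of class `demographic_model`.
#' @export
demographic_model <- function(scenario = c("asia_ancestral",
                                           "america_ancestral",
                                           "ghost_ancestral",
                                           "panmictic", "threepop"),
                              split_times = NULL, pop_sizes = NULL,
                              sexuality = NULL,
                              theta_site = 0.001, rho_site = 2.5e-9) {
  scenario <- match.arg(scenario)
  if (scenario == "panmictic") {
    pops <- "pop1"
    split_times <- split_times %||% numeric(0)
    pop_sizes <- pop_sizes %||% c(pop1 = 1e5)
    sexuality <- sexuality %||% c(pop1 = 1)
    merges <- tibble::tibble(time = numeric(0), child = character(0),
                             parent = character(0))
  } else if (scenario == "threepop") {
    pops <- c("out", "a", "b")
    split_times <- split_times %||% c(ab = 2e4, out = 1e5)
    pop_sizes <- pop_sizes %||% c(out = 5e5, a = 5e5, b = 5e5)
    sexuality <- sexuality %||% c(out = 1, a = 1, b = 1)
    if (!(split_times[["ab"]] < split_times[["out"]]))
      abort("invalid topology: require split ab < out")
    merges <- tibble::tibble(
      time = c(split_times[["ab"]], split_times[["out"]]),
      child = c("b", "a"), parent = c("a", "out"))
  } else {
    pops <- c("asia", "america", "europe", "india")
    split_times <- split_times %||% c(europe = 12e3, india = 51e3, deep = 1e6)
    dflt_N <- c(asia = 4e5, america = 4e5, europe = 4e5, india = 4e5,
                ancestral = 1.5e6)
    dflt_s <- c(asia = 1, america = 0.1, europe = 0.01, india = 0.1,
                ancestral = 1)
    pop_sizes <- pop_sizes %||% dflt_N
    sexuality <- sexuality %||% dflt_s
    st <- split_times
    if (!(st[["europe"]] < st[["india"]] && st[["india"]] < st[["deep"]]))
      abort("invalid topology: require europe < india < deep split times")
    merges <- tibble::tibble(
      time = c(st[["europe"]], st[["india"]]),
      child = c("europe", "india"), parent = c("asia", "asia"))
    merges <- switch(scenario,
      asia_ancestral = dplyr::bind_rows(merges,
        tibble::tibble(time = st[["deep"]], child = "america",
                       parent = "asia")),
      america_ancestral = dplyr::bind_rows(merges,
        tibble::tibble(time = st[["deep"]], child = "asia",
                       parent = "america")),
      ghost_ancestral = dplyr::bind_rows(merges,
        tibble::tibble(time = c(st[["deep"]], st[["deep"]]),
                       child = c("asia", "america"),
                       parent = c("ancestral", "ancestral"))))
  }
  all_pops <- union(pops, unique(c(merges$child, merges$parent)))
  missing_N <- setdiff(all_pops, names(pop_sizes))
  if (length(missing_N)) abort(paste("pop_sizes missing:",
                                     paste(missing_N, collapse = ", ")))
  missing_s <- setdiff(all_pops, names(sexuality))
  if (length(missing_s)) abort(paste("sexuality missing:",
                                     paste(missing_s, collapse = ", ")))
  stopifnot(all(sexuality >= 0 & sexuality <= 1), theta_site > 0,
            all(pop_sizes > 0), rho_site >= 0)
  structure(
    list(scenario_id = scenario, populations = pops, all_pops = all_pops,
         split_times = split_times, pop_sizes = pop_sizes[all_pops],
         sexuality = sexuality[all_pops], theta_site = theta_site,
         rho_site = rho_site, merges = merges),
    class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model> scenario:", x$scenario_id, "\n")
  cat("  populations:", paste(x$populations, collapse = ", "), "\n")
  if (nrow(x$merges))
    cat("  merges:", paste(sprintf("%s->%s@%g", x$merges$child,
                                   x$merges$parent, x$merges$time),
                           collapse = "; "), "\n")
  cat(sprintf("  theta/site=%g rho/site=%g\n", x$theta_site, x$rho_site))
  invisible(x)
}

# mutation rate per site per generation implied by theta and the reference
# (first sampled) population size
model_mu <- function(model) {
  model$theta_site / (4 * model$pop_sizes[[model$populations[1]]])
}

#' Simulate a sample of diploid genotypes under a demographic model
#'
#' Runs the built-in structured Hudson-style coalescent with
#' population-specific effective recombination `4*N*rho_site*sigma` per bp
#' and drops infinite-sites mutations at rate implied by `theta_site`. The
#' ancestral allele of every site is known (REF is ancestral), and the
#' number of recombination (genealogy-refresh) events is recorded per
#' population, so a fully clonal population (`sigma = 0`) records exactly
#' zero.
#'
#' @param model A [demographic_model()].
#' @param n_per_pop Diploid samples per population: a single count or a
#'   named vector over the model's sampled populations. Must be >= 4.
#' @param L Chromosome length in bp (>= 10 kb).
#' @param seed Integer seed; the simulation is a pure function of
#'   `(model, n_per_pop, L, seed)`.
#'
#' @return A list with elements `gm` (a [genotype_matrix()]) and `truth`
#'   (a `sim_truth` record: model, seed, per-population recombination-event
#'   counts, planted sweep sites, planted filter counts, and the true clonal
#'   partition).
#' @export
simulate_population_set <- function(model, n_per_pop, L, seed) {
  stopifnot(inherits(model, "demographic_model"))
  if (L < 1e4) abort("L must be at least 10 kb")
  pops <- model$populations
  if (length(n_per_pop) == 1 && is.null(names(n_per_pop)))
    n_per_pop <- setNames(rep(n_per_pop, length(pops)), pops)
  stopifnot(setequal(names(n_per_pop), pops), all(n_per_pop >= 4))
  n_per_pop <- n_per_pop[pops]

  all_pops <- model$all_pops
  nhap <- setNames(rep(0L, length(all_pops)), all_pops)
  nhap[pops] <- as.integer(2 * n_per_pop)
  N <- model$pop_sizes[all_pops]
  sig <- model$sexuality[all_pops]
  breaks_bp <- 4 * N * model$rho_site * sig
  mu <- model_mu(model)

  merges <- dplyr::arrange(model$merges, .data$time)
  pidx <- function(p) match(p, all_pops) - 1L
  # first demographic event involving each population ends its
  # block-stable within-population phase
  phase_end <- setNames(rep(Inf, length(all_pops)), all_pops)
  for (i in seq_len(nrow(merges))) {
    for (p in c(merges$child[i], merges$parent[i]))
      phase_end[p] <- min(phase_end[p], merges$time[i])
  }
  if (length(all_pops) > 1) {
    n_root <- sum(!(all_pops %in% merges$child))
    if (n_root != 1) abort("invalid topology: demography must form one tree")
  }

  res <- with_seed(seed, .sim_chromosome_cpp(
    npop = length(all_pops), nhap = unname(nhap), Ndip = unname(N),
    breaks_per_bp = unname(breaks_bp), mu_bp = mu, L = L,
    phase_end = unname(phase_end), merge_time = merges$time,
    merge_child = vapply(merges$child, pidx, 0L),
    merge_parent = vapply(merges$parent, pidx, 0L)))

  pos <- as.integer(floor(res$positions)) + 1L
  keep <- !duplicated(pos)
  pos <- pos[keep]
  hap <- res$haplotypes[, keep, drop = FALSE]

  sample_pops <- rep(pops, times = n_per_pop)
  sample_ids <- paste0(sample_pops, "_", unlist(lapply(n_per_pop, seq_len)))
  odd <- seq(1, nrow(hap), by = 2)
  dosage <- hap[odd, , drop = FALSE] + hap[odd + 1, , drop = FALSE]
  rownames(dosage) <- sample_ids

  sites <- tibble::tibble(chrom = "chr1", pos = pos, ref = "A", alt = "T",
                          ancestral = "A")
  gm <- genotype_matrix(dosage, sites,
                        populations = setNames(sample_pops, sample_ids),
                        chrom_lengths = c(chr1 = L))
  truth <- structure(
    list(model = model, seed = seed,
         recomb_events = setNames(as.integer(res$n_recomb), all_pops),
         n_blocks = res$n_blocks,
         sweep_sites = tibble::tibble(population = character(0),
                                      chrom = character(0), pos = integer(0),
                                      strength = numeric(0)),
         planted_filter_counts = integer(0),
         true_clonal_partition = as.list(sample_ids)),
    class = "sim_truth")
  list(gm = gm, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> scenario:", x$model$scenario_id,
      "seed:", x$seed, "\n  recombination events:",
      paste(names(x$recomb_events), x$recomb_events, sep = "=",
            collapse = ", "), "\n", sep = " ")
  invisible(x)
}

#' Inject a hard selective sweep into a genotype matrix
#'
#' Drives the derived allele at the focal site to fixation in the target
#' population and homogenises linked variation onto a template (sweeping)
#' haplotype: at a linked site at distance `d`, every haplotype of the
#' population independently escapes the sweep -- keeping its pre-sweep
#' allele -- with probability `1 - exp(-d/strength)`, and otherwise takes
#' the template haplotype's allele. Sites where the template carries the
#' derived allele therefore surface in the high-frequency derived classes
#' characteristic of hitchhiking, and low-frequency classes collect the
#' escapees. Other populations are never modified; `strength -> 0` gives
#' escape probability 1 at any distance, so only the focal site is
#' altered.
#'
#' @param gm A [genotype_matrix()].
#' @param pop Target population label.
#' @param chrom Chromosome of the focal site.
#' @param pos Focal position (bp); must lie within the simulated range.
#' @param strength Sweep footprint scale in bp (escape probability
#'   `1 - exp(-d/strength)`).
#' @param seed Integer seed controlling escape draws.
#'
#' @return The modified `genotype_matrix`, with attribute `"sweep_site"`
#'   recording the focal site actually used (nearest SNP to `pos`).
#' @export
inject_sweep <- function(gm, pop, chrom, pos, strength, seed) {
  stopifnot(strength >= 0)
  if (!pop %in% gm$populations) abort("target population not present")
  on_chrom <- which(gm$sites$chrom == chrom)
  if (!length(on_chrom)) abort("chromosome not present")
  Lmax <- gm$chrom_lengths[chrom] %||% max(gm$sites$pos[on_chrom])
  if (pos < 1 || pos > Lmax) abort("pos outside simulated range")
  focal <- on_chrom[which.min(abs(gm$sites$pos[on_chrom] - pos))]
  in_pop <- which(gm$populations == pop)
  np <- length(in_pop)
  anc <- if ("ancestral" %in% names(gm$sites)) gm$sites$ancestral[focal]
         else NA_character_
  derived_is_alt <- is.na(anc) || anc == gm$sites$ref[focal]

  with_seed(seed, {
    # template haplotype = a derived-allele carrier at the focal site
    dos_focal <- gm$dosage[in_pop, focal]
    score <- if (derived_is_alt) dos_focal else 2L - dos_focal
    template <- in_pop[order(-replace(score, is.na(score), -1L))][1]

    gm$dosage[in_pop, focal] <- if (derived_is_alt) 2L else 0L

    d <- abs(gm$sites$pos[on_chrom] - gm$sites$pos[focal])
    linked <- on_chrom[d > 0]
    p_escape <- if (strength == 0) rep(1, length(linked))
                else 1 - exp(-d[d > 0] / strength)
    for (k in seq_along(linked)) {
      pe <- p_escape[k]
      if (pe >= 1) next
      s <- linked[k]
      td <- gm$dosage[template, s]
      a_t <- if (is.na(td)) 0L
             else if (td == 2L) 1L
             else if (td == 1L) rbinom(1, 1, 0.5)
             else 0L
      # per-haplotype escape: escapees keep an allele drawn from their
      # own genotype, swept haplotypes take the template allele
      dos <- gm$dosage[in_pop, s]
      n_esc <- rbinom(np, 2L, pe)
      kept <- rbinom(np, n_esc, ifelse(is.na(dos), 0, dos) / 2)
      gm$dosage[in_pop, s] <- as.integer(a_t * (2L - n_esc) + kept)
    }
  })
  attr(gm, "sweep_site") <- gm$sites$pos[focal]
  gm
}
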