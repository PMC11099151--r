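# Rejection-ABC over demographic scenarios, driven by the built-in
# coalescent simulator.

#' Hudson's F_ST estimator
#'
#' Per-site numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `p1(1-p2) + p2(1-p1)`; the genome-wide value is the ratio
#' of averages (sum of numerators over sum of denominators).
#'
#' @param p1,p2 ALT-allele frequency vectors.
#' @param n1,n2 Numbers of sampled alleles behind each frequency (scalar
#'   or vector).
#' @return List with `fst`, per-site `num` and `den`.
#' @export
hudson_fst <- function(p1, n1, p2, n2) {
  ok <- !is.na(p1) & !is.na(p2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num[!ok] <- NA; den[!ok] <- NA
  dsum <- sum(den, na.rm = TRUE)
  list(fst = if (dsum == 0) NA_real_ else sum(num, na.rm = TRUE) / dsum,
       num = num, den = den)
}

#' Summary-statistic vector for ABC
#'
#' Deterministic vector over the sampled populations: per-population pi,
#' pairwise Hudson F_ST, the first folded-SFS bin proportions, LD-decay
#' distance at r^2 = 0.2 (censored at `ld_max_dist`), and median
#' individual heterozygosity.
#'
#' @param gm A [genotype_matrix()] (needs `chrom_lengths` for the pi
#'   denominator).
#' @param sfs_bins Number of folded-SFS bins reported (capped at
#'   `floor(n/2)`).
#' @param ld_max_dist,ld_bin_width,ld_max_sites LD-decay settings (the
#'   site cap bounds the pairwise computation).
#' @return Named numeric vector.
#' @export
summarize_gm <- function(gm, sfs_bins = 5, ld_max_dist = 1e5,
                         ld_bin_width = 5e3, ld_max_sites = 300) {
  pops <- sort(unique(unname(gm$populations)))
  L <- sum(unlist(gm$chrom_lengths))
  if (is.null(L) || L == 0) abort("gm must carry chrom_lengths")
  out <- c()
  freqs <- list(); ns <- list()
  for (p in pops) {
    sam <- which(gm$populations == p)
    if (length(sam) < 4) abort(paste("population below 4 samples:", p))
    ac <- site_allele_counts(gm, samples = sam)
    n <- max(ac$called)
    seg <- ac$alt > 0 & ac$alt < ac$called
    out[paste0("pi_", p)] <- sum(per_site_pi(ac$alt[seg], ac$called[seg])) / L
    full <- ac$called == n
    minor <- pmin(ac$alt[full & seg], n - ac$alt[full & seg])
    nf <- floor(n / 2)
    tab <- tabulate(minor, nbins = nf)
    props <- if (sum(tab) > 0) tab / sum(tab) else rep(0, nf)
    for (j in seq_len(min(sfs_bins, nf)))
      out[paste0("sfs_", p, "_", j)] <- props[j]
    ld <- ld_decay(subset_samples(gm, sam), max_dist = ld_max_dist,
                   bin_width = ld_bin_width, max_sites = ld_max_sites)
    dd <- decay_distance_at(ld, 0.2)
    out[paste0("ld_", p)] <- if (is.na(dd)) ld_max_dist else min(dd, ld_max_dist)
    het <- gm$dosage[sam, , drop = FALSE]
    out[paste0("het_", p)] <- median(rowSums(het == 1L, na.rm = TRUE) /
                                       pmax(1, rowSums(!is.na(het))))
    freqs[[p]] <- ifelse(ac$called > 0, ac$alt / ac$called, NA)
    ns[[p]] <- n
  }
  if (length(pops) > 1) {
    prs <- utils::combn(pops, 2)
    for (k in seq_len(ncol(prs))) {
      i <- prs[1, k]; j <- prs[2, k]
      f <- hudson_fst(freqs[[i]], ns[[i]], freqs[[j]], ns[[j]])$fst
      out[paste0("fst_", i, "_", j)] <- if (is.na(f)) 0 else f
    }
  }
  out
}

#' Prior specification for ABC
#'
#' Split times and effective sizes are log-uniform, sexuality fractions
#' uniform. The three split-time draws are sorted to satisfy the topology
#' ordering (europe < india < deep).
#'
#' @param split_range,ne_range Log-uniform bounds (generations; diploids).
#' @param sigma_range Uniform bounds for sexuality fractions.
#' @return A `prior_spec` list.
#' @export
abc_priors <- function(split_range = c(1e3, 5e6), ne_range = c(1e3, 1e6),
                       sigma_range = c(0.001, 1)) {
  stopifnot(all(split_range > 0), all(ne_range > 0),
            sigma_range[1] >= 0, sigma_range[2] <= 1)
  structure(list(split_range = split_range, ne_range = ne_range,
                 sigma_range = sigma_range), class = "prior_spec")
}

rlogunif <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

# draw one demographic model from the priors for a scenario; the mutation
# rate is held fixed at mu (theta is re-expressed for the drawn sizes)
draw_model <- function(scenario, priors, mu, rho_site) {
  st <- sort(rlogunif(3, priors$split_range))
  splits <- c(europe = st[1], india = st[2], deep = st[3])
  pops <- c("asia", "america", "europe", "india", "ancestral")
  ne <- setNames(rlogunif(length(pops), priors$ne_range), pops)
  sig <- setNames(runif(length(pops), priors$sigma_range[1],
                        priors$sigma_range[2]), pops)
  demographic_model(scenario, split_times = splits, pop_sizes = ne,
                    sexuality = sig, theta_site = 4 * ne[["asia"]] * mu,
                    rho_site = rho_site)
}

model_params <- function(model) {
  c(setNames(as.numeric(model$split_times),
             paste0("t_", names(model$split_times))),
    setNames(as.numeric(model$pop_sizes),
             paste0("ne_", names(model$pop_sizes))),
    setNames(as.numeric(model$sexuality),
             paste0("sigma_", names(model$sexuality))))
}

#' Simulate an ABC reference table
#'
#' Draws parameters from the priors for each scenario (equal shares of
#' `n_sims`), simulates with the built-in coalescent at desk scale, and
#' records parameters plus summary statistics.
#'
#' @param scenarios Scenario ids (default the three split histories).
#' @param priors An [abc_priors()].
#' @param n_sims Total simulations across scenarios.
#' @param n_per_pop Diploids per population in each simulation.
#' @param L Sequence length per simulation (bp).
#' @param seed Integer seed.
#' @param base_model Model fixing the mutation and recombination rates
#'   (default [demographic_model()] defaults).
#' @return List of class `abc_table`: `params` tibble (scenario +
#'   parameters), `summaries` matrix, settings.
#' @export
abc_reference_table <- function(scenarios = c("asia_ancestral",
                                              "america_ancestral",
                                              "ghost_ancestral"),
                                priors = abc_priors(), n_sims = 2000,
                                n_per_pop = 8, L = 2e5, seed = 1,
                                base_model = demographic_model()) {
  mu <- model_mu(base_model)
  per <- ceiling(n_sims / length(scenarios))
  draws <- list(); summ <- list()
  with_seed(seed, {
    k <- 0
    for (sc in scenarios) {
      for (i in seq_len(per)) {
        if (k >= n_sims) break
        k <- k + 1
        m <- draw_model(sc, priors, mu, base_model$rho_site)
        sim_seed <- sample.int(2^31 - 2, 1)
        s <- tryCatch({
          sim <- simulate_population_set(m, n_per_pop, L, seed = sim_seed)
          summarize_gm(sim$gm)
        }, error = function(e) NULL)
        if (is.null(s)) { k <- k - 1; next }
        draws[[k]] <- c(list(scenario = sc), as.list(model_params(m)))
        summ[[k]] <- s
      }
    }
  })
  params <- dplyr::bind_rows(draws)
  summaries <- do.call(rbind, summ)
  structure(list(params = params, summaries = summaries,
                 n_per_pop = n_per_pop, L = L, priors = priors,
                 base_model = base_model, seed = seed),
            class = "abc_table")
}

#' Rejection-ABC model choice and parameter posteriors
#'
#' Standardises every summary by its reference-table mean and SD
#' (zero-SD summaries are dropped with a warning), computes Euclidean
#' distances from the observed vector, and accepts the closest
#' `tolerance * n_sims` draws pooled across scenarios. The model
#' posterior is each scenario's share among accepted draws; parameter
#' posteriors come from the accepted draws of the winning scenario.
#'
#' @param observed Named summary vector from [summarize_gm()].
#' @param table An [abc_reference_table()].
#' @param tolerance Accepted fraction in `(0, 1]` (default 0.02).
#' @return An `abc_result`: `model_posterior` tibble, `accepted` tibble
#'   (scenario, parameters, distance), `winning_scenario`, `tolerance`.
#' @export
abc_reject <- function(observed, table, tolerance = 0.02) {
  stopifnot(inherits(table, "abc_table"), tolerance > 0, tolerance <= 1)
  S <- table$summaries
  common <- intersect(colnames(S), names(observed))
  S <- S[, common, drop = FALSE]
  ok_row <- stats::complete.cases(S)
  if (!all(ok_row)) {
    warn(sprintf("dropping %d reference rows with missing summaries",
                 sum(!ok_row)))
    S <- S[ok_row, , drop = FALSE]
    table$params <- table$params[ok_row, , drop = FALSE]
  }
  # robust standardization (MAD, as in standard rejection-ABC tooling);
  # SD fallback where the MAD degenerates to zero
  mu <- apply(S, 2, median)
  sdv <- apply(S, 2, stats::mad)
  sd2 <- apply(S, 2, sd)
  sdv[!is.na(sdv) & sdv == 0] <- sd2[!is.na(sdv) & sdv == 0]
  keep <- !is.na(sdv) & sdv > 0
  if (!all(keep))
    warn(paste("dropping zero-variance summaries:",
               paste(common[!keep], collapse = ", ")))
  Z <- sweep(sweep(S[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  zo <- (observed[common][keep] - mu[keep]) / sdv[keep]
  dist <- sqrt(rowSums(sweep(Z, 2, zo)^2))
  n_acc <- max(1, round(tolerance * nrow(Z)))
  ord <- order(dist)
  acc <- table$params[ord[seq_len(n_acc)], ]
  acc$distance <- dist[ord[seq_len(n_acc)]]
  scen <- sort(unique(table$params$scenario))
  post <- vapply(scen, function(s) mean(acc$scenario == s), 0)
  winner <- scen[which.max(post)]
  structure(list(model_posterior = tibble::tibble(scenario = scen,
                                                  posterior = post),
                 accepted = tibble::as_tibble(acc),
                 winning_scenario = winner, tolerance = tolerance,
                 n_accepted = n_acc),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat("<abc_result> accepted", x$n_accepted, "draws; model posterior:\n")
  print(x$model_posterior)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.abc_result <- function(x, ...) posterior_summary(x)

#' @exportS3Method generics::glance
glance.abc_result <- function(x, ...) {
  tibble::tibble(winning_scenario = x$winning_scenario,
                 posterior = max(x$model_posterior$posterior),
                 n_accepted = x$n_accepted, tolerance = x$tolerance)
}

#' Posterior parameter summaries
#'
#' Median and central 95% interval of each parameter among the accepted
#' draws of the winning scenario; optionally checks a truth vector for
#' coverage.
#'
#' @param result An `abc_result`.
#' @param truth Optional named vector of true parameter values.
#' @param min_accepted Minimum accepted draws (default 20).
#' @return Tibble `parameter`, `median`, `q025`, `q975` (and `truth`,
#'   `covered` when truth is given).
#' @export
posterior_summary <- function(result, truth = NULL, min_accepted = 20) {
  acc <- result$accepted[result$accepted$scenario ==
                           result$winning_scenario, ]
  if (nrow(acc) < min_accepted)
    abort(sprintf("only %d accepted draws for the winning scenario (< %d)",
                  nrow(acc), min_accepted))
  num <- names(acc)[vapply(acc, is.numeric, TRUE)]
  num <- setdiff(num, "distance")
  num <- num[vapply(num, function(p) any(!is.na(acc[[p]])), TRUE)]
  out <- purrr::map_dfr(num, function(par) {
    v <- acc[[par]][!is.na(acc[[par]])]
    tibble::tibble(parameter = par, median = median(v),
                   q025 = quantile(v, 0.025, names = FALSE),
                   q975 = quantile(v, 0.975, names = FALSE))
  })
  if (!is.null(truth)) {
    out$truth <- truth[out$parameter]
    out$covered <- !is.na(out$truth) & out$truth >= out$q025 &
      out$truth <= out$q975
  }
  out
}
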