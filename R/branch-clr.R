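# Branch-specific selection scan on a three-population tree
# (outgroup, (a, b)) from linked allele-frequency differentiation.

#' Method-of-moments drift scales for the two ingroup branches
#'
#' With the outgroup frequency `p` as the ancestral proxy, the drift
#' variance scale of branch a is estimated as the genome-wide mean of
#' `[(p_a - p)^2 - p_a(1-p_a)/(2 n_a) - p(1-p)/(2 n_out)] / [p(1-p)]`
#' over SNPs polymorphic in the outgroup, floored at zero (and branch b
#' analogously). Under pure drift the scale approximates `t / 2N`.
#'
#' @param freqs_a,freqs_b,freqs_out Allele-frequency vectors over the same
#'   SNPs.
#' @param n_a,n_b,n_out Diploid sample sizes behind the frequencies.
#' @param min_snps Minimum usable SNPs (default 1000).
#' @return List of class `branch_drift_params` with `omega_a`, `omega_b`,
#'   sample sizes and the number of SNPs used.
#' @export
estimate_drift_params <- function(freqs_a, freqs_b, freqs_out, n_a, n_b,
                                  n_out, min_snps = 1000) {
  ok <- !is.na(freqs_a) & !is.na(freqs_b) & !is.na(freqs_out) &
    freqs_out > 0 & freqs_out < 1
  if (sum(ok) < min_snps)
    abort(sprintf("too few outgroup-polymorphic SNPs (%d < %d)",
                  sum(ok), min_snps))
  p <- freqs_out[ok]
  q <- p * (1 - p)
  omega_of <- function(pb, nb) {
    num <- (pb[ok] - p)^2 - pb[ok] * (1 - pb[ok]) / (2 * nb) - q / (2 * n_out)
    max(0, mean(num / q))
  }
  structure(list(omega_a = omega_of(freqs_a, n_a),
                 omega_b = omega_of(freqs_b, n_b),
                 n_a = n_a, n_b = n_b, n_out = n_out, n_snps = sum(ok)),
            class = "branch_drift_params")
}

# per-SNP neutral variance of the branch frequency around the outgroup
# proxy: drift plus binomial sampling on both tips
branch_var <- function(q, omega, n_branch, n_out, inflate = 1) {
  q * (omega * inflate + 1 / (2 * n_out) + 1 / (2 * n_branch))
}

#' Branch CLR at one focal position
#'
#' Neutral model: the focal branch's frequencies are Normal around the
#' outgroup frequency with variance `omega * q + q/(2 n_out) +
#' q/(2 n_branch)`, `q = p_out (1 - p_out)`. Selection inflates the drift
#' term of SNP `i` by `1 + A * exp(-|pos_i - x| / r_scale)`; the CLR is
#' twice the log-likelihood gain maximised over the `(A, r_scale)` grids
#' (which include the neutral point `A = 0`, so CLR >= 0). SNPs with
#' `p_out` at 0 or 1 are excluded upstream.
#'
#' @param snps Tibble with `pos`, `p_a`, `p_b`, `p_out`.
#' @param params A `branch_drift_params`.
#' @param branch `"a"` or `"b"`.
#' @param x Focal position (bp).
#' @param A_grid Variance-inflation amplitudes (default
#'   `c(0, 0.5, 1, 2, 5, 10)`).
#' @param rscale_grid Decay scales in bp (default `c(5, 20, 50) kb`).
#' @param min_snps Minimum SNPs required in the window (default 10).
#' @return List with `clr`, `A_hat`, `rscale_hat`, `n_snps`.
#' @export
branch_clr_window <- function(snps, params, branch = c("a", "b"), x,
                              A_grid = c(0, 0.5, 1, 2, 5, 10),
                              rscale_grid = c(5e3, 2e4, 5e4),
                              min_snps = 10) {
  branch <- match.arg(branch)
  ok <- snps$p_out > 0 & snps$p_out < 1
  snps <- snps[ok, ]
  if (nrow(snps) < min_snps)
    abort(sprintf("need at least %d SNPs in the window", min_snps))
  pb <- if (branch == "a") snps$p_a else snps$p_b
  omega <- if (branch == "a") params$omega_a else params$omega_b
  nb <- if (branch == "a") params$n_a else params$n_b
  q <- snps$p_out * (1 - snps$p_out)
  dev2 <- (pb - snps$p_out)^2
  lnl <- function(v) sum(-0.5 * (log(2 * pi * v) + dev2 / v))
  v0 <- branch_var(q, omega, nb, params$n_out)
  lnL0 <- lnl(v0)
  best <- lnL0; Ah <- 0; rh <- NA_real_
  for (r in rscale_grid) {
    e <- exp(-abs(snps$pos - x) / r)
    for (A in A_grid) {
      if (A == 0) next
      v <- branch_var(q, omega, nb, params$n_out, inflate = 1 + A * e)
      ll <- lnl(v)
      if (ll > best) { best <- ll; Ah <- A; rh <- r }
    }
  }
  list(clr = 2 * (best - lnL0), A_hat = Ah, rscale_hat = rh,
       n_snps = nrow(snps))
}

#' Three-population branch-specific CLR scan
#'
#' Computes per-branch CLR tracks over sliding SNP windows (every
#' `focal_every`-th SNP is a focal candidate, with the surrounding
#' `window_snps` SNPs as data), using genome-wide drift scales from
#' [estimate_drift_params()].
#'
#' @param gm A [genotype_matrix()].
#' @param out,a,b Population labels: outgroup and the two ingroup
#'   branches.
#' @param window_snps SNPs per window (default 100).
#' @param focal_every Thinning of focal candidates (default 10).
#' @param A_grid,rscale_grid Passed to [branch_clr_window()].
#' @param min_diploids Minimum diploids per population (default 4).
#' @param min_snps Minimum genome-wide outgroup-polymorphic SNPs for the
#'   drift-scale estimate (default 1000).
#' @return List with `scan_a`, `scan_b` (`window_stats` tibbles with
#'   `value` = CLR) and `params`.
#' @export
threepop_scan <- function(gm, out, a, b, window_snps = 100,
                          focal_every = 10,
                          A_grid = c(0, 0.5, 1, 2, 5, 10),
                          rscale_grid = c(5e3, 2e4, 5e4),
                          min_diploids = 4, min_snps = 1000) {
  pops <- gm$populations
  for (p in c(out, a, b)) {
    if (sum(pops == p) < min_diploids)
      abort(paste("population missing or too small:", p))
  }
  freq_of <- function(p) {
    ac <- site_allele_counts(gm, samples = which(pops == p))
    ifelse(ac$called > 0, ac$alt / ac$called, NA_real_)
  }
  fa <- freq_of(a); fb <- freq_of(b); fo <- freq_of(out)
  params <- estimate_drift_params(fa, fb, fo,
                                  n_a = sum(pops == a), n_b = sum(pops == b),
                                  n_out = sum(pops == out),
                                  min_snps = min_snps)
  scan_branch <- function(branch) {
    res <- list()
    for (ch in unique(gm$sites$chrom)) {
      idx <- which(gm$sites$chrom == ch & !is.na(fo) & fo > 0 & fo < 1 &
                   !is.na(fa) & !is.na(fb))
      if (length(idx) < window_snps) next
      pos <- gm$sites$pos[idx]
      focal <- seq(window_snps %/% 2, length(idx) - window_snps %/% 2,
                   by = focal_every)
      rows <- purrr::map_dfr(focal, function(fi) {
        w <- idx[max(1, fi - window_snps %/% 2 + 1):
                 min(length(idx), fi + window_snps %/% 2)]
        snps <- tibble::tibble(pos = gm$sites$pos[w], p_a = fa[w],
                               p_b = fb[w], p_out = fo[w])
        r <- branch_clr_window(snps, params, branch, x = gm$sites$pos[idx[fi]],
                               A_grid = A_grid, rscale_grid = rscale_grid)
        tibble::tibble(chrom = ch, start = min(snps$pos) - 1L,
                       end = max(snps$pos), pos = gm$sites$pos[idx[fi]],
                       value = r$clr, n_sites = r$n_snps, A_hat = r$A_hat)
      })
      res[[ch]] <- rows
    }
    outt <- dplyr::bind_rows(res)
    class(outt) <- c("window_stats", class(outt))
    attr(outt, "stat") <- paste0("branch_clr_", branch)
    outt
  }
  list(scan_a = scan_branch("a"), scan_b = scan_branch("b"),
       params = params)
}

#' Validate sweep candidates with diversity tracks
#'
#' For each candidate window and population, reports pi (window length as
#' callable length), Tajima's D, and flags `low_pi` (below the
#' genome-wide per-population average) and `negative_d`. Windows without
#' SNPs in a population yield missing flags.
#'
#' @param windows Tibble of candidate windows (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @param gm A [genotype_matrix()].
#' @param populations Population labels to evaluate (default: all).
#' @return Tibble with one row per (window, population).
#' @export
validate_candidates <- function(windows, gm, populations = NULL) {
  populations <- populations %||% sort(unique(unname(gm$populations)))
  genome_len <- sum(vapply(unique(gm$sites$chrom), function(ch)
    gm$chrom_lengths[ch] %||% max(gm$sites$pos[gm$sites$chrom == ch]), 0))
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    purrr::map_dfr(populations, function(p) {
      sam <- which(gm$populations == p)
      ac <- site_allele_counts(gm, samples = sam)
      inw <- gm$sites$chrom == w$chrom & gm$sites$pos > w$start &
        gm$sites$pos <= w$end
      seg <- inw & ac$alt > 0 & ac$alt < ac$called
      gw_pi <- sum(per_site_pi(ac$alt, ac$called)[ac$alt > 0],
                   na.rm = TRUE) / genome_len
      if (!any(seg)) {
        return(tibble::tibble(chrom = w$chrom, start = w$start, end = w$end,
                              population = p, pi = 0, tajimas_d = NA_real_,
                              low_pi = NA, negative_d = NA))
      }
      pit <- sum(per_site_pi(ac$alt[seg], ac$called[seg]))
      piw <- pit / (w$end - w$start)
      td <- tajimas_d(sum(seg), round(mean(ac$called[seg])), pit)
      tibble::tibble(chrom = w$chrom, start = w$start, end = w$end,
                     population = p, pi = piw, tajimas_d = td,
                     low_pi = piw < gw_pi, negative_d = !is.na(td) && td < 0)
    })
  })
}
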