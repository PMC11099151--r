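---
title: "Models and methods behind clonepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`clonepop` analyses population-genomic and population-epigenomic data from
facultatively asexual plants: organisms that propagate clonally by default
and go through sex — and therefore meiotic recombination — only in a
fraction σ of generations. This vignette explains the models, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## The coalescent simulator

### Partial clonality as effective recombination

Clonal reproduction transmits whole genomes; only the sexual fraction σ of
generations recombines. The simulator therefore models partial clonality
**only** through effective recombination, ρ_eff = ρ·σ per site per
generation. A population with σ = 0 behaves as a single non-recombining
genealogy per chromosome; raising σ shortens linkage blocks and accelerates
LD decay. This is the property the package's inferences rest on (the
LD-decay contrast between populations), and it keeps the generator simple
and fast. What the model deliberately omits:

* the within-individual allele divergence that long-term clonality can
  build up (an optional heterozygosity offset was considered and left out;
  with it off, σ has **no** effect on individual heterozygosity, so
  population differences in H arise only from demography);
* diploid single-parent transmission details (selfing-like dynamics);
* selection during the coalescent itself — sweeps are injected after the
  fact (below).

### Structure of a simulated chromosome

Each population p carries a Poisson breakpoint process along the chromosome
with intensity 4·N_p·ρ·σ_p per bp (the population-scaled recombination
rate). Between two consecutive pop-p breakpoints, the within-population
part of p's genealogy — from the present back to the first demographic
event involving p — is held fixed; at a breakpoint it is redrawn. The
portion of the genealogy above the first demographic event (the "ancestral
phase": merged populations, the ghost ancestor) is redrawn for every local
block, i.e. at the union of all populations' breakpoints. This is an
SMC-flavoured approximation: local trees are conditionally independent
between blocks rather than correlated through shared edges. Consequences:

* E[π] = θ per site is exact (each local tree is a correct draw from the
  structured coalescent), and the per-population LD structure scales with
  σ_p as intended;
* LD *between* blocks is underestimated relative to a full ancestral
  recombination graph; LD decay distances are therefore slightly biased
  downward at large σ. Since every calibration compares simulations with
  simulations, this does not affect the package's conclusions;
* recombination events are recorded per population, so a fully clonal
  population reports exactly zero.

Mutations follow the infinite-sites model at rate
μ = θ/(4·N_ref) per site per generation, where N_ref is the first sampled
population's size — so `theta_site` is, by construction, the expected
pairwise diversity of the reference population. Positions are 0-based
half-open internally, 1-based in emitted VCF/GFF3, 0-based half-open in
BED.

### Default demographies

The four-population scenarios (`asia_ancestral`, `america_ancestral`,
`ghost_ancestral`) share the split times 12,000 (Europe from SE-Asia),
51,000 (India from SE-Asia) and 1,000,000 generations (the deep split),
sexuality fractions σ = 1 (SE-Asia), 0.1 (America, India), 0.01 (Europe),
and extant diploid sizes of 4×10⁵ with a 1.5×10⁶ ghost ancestor;
θ = 0.001 per site, ρ = 2.5×10⁻⁹. The rationale: the organism has very low
genome-wide diversity but a large effective size, so split times of order
10⁴–10⁶ generations sit in or near the incomplete-lineage-sorting regime
(T ≲ 2N), which is what gives cross-population summaries any information
about the deep topology. The `threepop` scenario (for branch-specific
selection scans) uses N = 5×10⁵ and splits at 20,000/100,000 generations:
with smaller sizes the genome-wide drift variance is so large that
branch-specific frequency shifts of realistic sweeps disappear into it.

### Sweep injection

`inject_sweep()` fixes the derived allele at the focal site in the target
population and, at each linked site at distance d, lets every haplotype
independently *escape* with probability 1 − exp(−d/strength); non-escaped
haplotypes take the template (sweeping) haplotype's allele. Sites where the
template carries a derived allele therefore surface as the high-frequency
derived classes characteristic of hitchhiking, and escapees populate the
singleton classes — exactly the lineage-escape model that the CLR scan's
spectrum transform assumes, which is what makes the injector a fair power
benchmark for the scanner. `strength` has bp units; the default used in
calibration experiments (2×10⁴) gives a footprint of a few tens of kb,
typical of a strong recent sweep at these recombination rates.

## Diversity and LD statistics

Per-site π is the unbiased pairwise mismatch probability
2·(k/n)(1−k/n)·n/(n−1); region π divides the per-site sum by a *callable
length* supplied by the caller, so monomorphic callable sites enter through
the denominator (this is the convention under which genome-wide values like
1.6×10⁻³ arise). Tajima's D uses the standard constants and is reported as
missing — never zero — for windows without segregating sites, to avoid
biasing window means. LD uses the composite (genotype-dosage correlation)
r², needing no phasing. The decay distance at r² = 0.2 interpolates
linearly on a weighted isotonic-decreasing fit of the bin means (raw bin
noise can cross the threshold several times; the monotone fit makes the
crossing unique), and reports "> max_dist" (Inf, with a `censored_at`
attribute) when the curve never falls that far — mirroring populations
whose LD has not decayed to 0.2 within 100 kb.

Nei–Gojobori site counting assigns each codon position the fraction of its
three possible changes that are synonymous; stop-gaining changes count as
nonsynonymous, so N + S equals the CDS length exactly.

## Sweep scans

The CLR scan compares, at each grid position, the composite likelihood of
flanking derived-allele classes under a sweep-transformed spectrum against
the genome-wide background spectrum. The transform is the classical
lineage-escape construction: k of n lineages escape (binomially, with
p_e(d, α) = 1 − e^{−αd}), the k escapees plus the single swept ancestral
lineage form an effective sample of k+1 drawn from the background via
hypergeometric projection, and the swept lineage's state is replicated into
the n−k non-escapees. Monomorphic transformed classes are dropped and the
vector renormalised before evaluation, since only segregating sites enter
the data (this shifts absolute CLR values, not their ranking). p_e is
discretised to 21 bins; α is maximised over a log-spaced grid that includes
the neutral limit, so CLR ≥ 0 by construction. Positions flanked by fewer
than 5 SNPs are skipped.

The μ statistic multiplies three factors over k-SNP windows (default
k = 50): SNP sparsity relative to the genome average, the fraction of
singleton plus (n−1)-class sites over its neutral expectation, and the
ratio of within-half to cross-half mean r² (ε = 10⁻⁶ guards the
denominator; undefined r² terms set the factor to 1 with a flag). Only
segregating sites count as SNPs — a swept region whose sites have been
homogenised to monomorphism must register as a SNP desert, which is the
diversity-reduction factor's entire signal.

Top-quantile calling keeps windows at or above the (1−q) empirical
quantile, ties included; when every score is equal the whole set is
selected and flagged.

## Branch-specific selection

The three-population scan models the focal branch's allele frequencies as
Normal around the outgroup frequency (the ancestral proxy — a deliberate,
documented simplification of the published three-population approach,
which integrates over the latent ancestral frequency) with variance
ω·q + q/(2n_out) + q/(2n_branch), q = p_out(1−p_out). The drift scales ω
are method-of-moments estimates over genome-wide outgroup-polymorphic
SNPs, floored at zero. Selection inflates the drift term of SNP i by
1 + A·exp(−|pos_i − x|/r_scale) with grids A ∈ {0, 0.5, 1, 2, 5, 10} and
r_scale ∈ {5, 20, 50} kb — two interpretable knobs that preserve the
geometry of linked differentiation. Frequencies at the outgroup boundary
(0 or 1) are excluded; likelihoods are evaluated without truncation to
[0, 1]. Because ω absorbs both branch and outgroup drift, the scan's power
degrades as total drift variance grows; this motivated the `threepop`
defaults above.

## Enrichment and association

The permutation null re-places every interval uniformly at random on its
own chromosome (length preserved; overlaps permitted) — the most literal
"genome-wide permutation" — with cross-chromosome placement available as a
flag. Empirical p-values use the add-one convention
(1 + #{null ≥ obs})/(N + 1), so p = 0 is impossible, with BH across
families. The Fisher test sums hypergeometric probabilities not exceeding
the observed table's (with the customary 1 + 10⁻⁷ relative tolerance);
χ² is Pearson's without continuity correction by default; the Wald test is
OLS of trait on dosage with a Normal reference.

## Methylome analysis

Bisulfite non-conversion e is the pooled methylated-read fraction on the
chloroplast (which carries no true methylation). Calling drops cytosines
with coverage < 5 and tests each remaining site against Binomial(cov, e),
one-sided; the correction across sites is BH at 0.05 (the calling
procedure itself prescribes a binomial test but no correction — BH was
chosen so that zero-methylation data yields ≤ 5% false calls, with a
raw-α mode available). At sites not called methylated the methylated
reads are excluded by setting m → 0 while preserving coverage, so wML
denominators are unaffected. Cytosines are treated per strand (the report
format is strand-resolved); no CpG symmetrisation is applied. wML is
Σm/Σ(m+u) — a coverage-weighted level — while the mC proportion counts
called-methylated cytosines among covered ones. Metagene profiles scale
feature bodies into 20 bins with ten 200-bp bins per 2-kb flank,
reversing minus-strand features. Methylome clustering uses
1 − Pearson correlation and average linkage; concordance with genetic
distance is a Mantel correlation whose permutation p is computed
exhaustively for n ≤ 7 and by add-one random permutation otherwise.

## Demographic inference (rejection ABC)

The reference table draws parameters from configurable priors
(log-uniform split times 10³–5×10⁶ generations with the topology ordering
enforced by sorting, log-uniform sizes 10³–10⁶, uniform σ 0.001–1),
simulates at desk scale (default 8 diploids per population, L = 200 kb),
and summarises each simulation by per-population π, pairwise Hudson F_ST
(ratio of averages), the first five folded-SFS bin proportions, LD-decay
distance at r² = 0.2 (censored at 100 kb), and median heterozygosity —
about thirty numbers for four populations. The mutation rate is held
fixed across draws (θ is re-expressed for the drawn sizes). Rejection
uses SD-standardised Euclidean distance and accepts the closest
tolerance·N draws pooled across scenarios; no regression adjustment is
applied (transparent and testable; adjustment is a noted extension).
Eight diploids per population is the floor at which the LD summary is
usable at all: with four, the small-sample bias of genotype r²
(E[r²] ≈ 1/n under linkage equilibrium) keeps every curve above 0.2 and
the summary is censored for all draws.

Distances are standardised by the reference table's median and MAD (the
robust standardisation used by standard rejection-ABC tooling, with an SD
fallback where the MAD degenerates).

Two properties of this setting deserve honesty, because they limit what
desk-scale model choice can do. First, the two single-ancestor scenarios
are *nested* in the ghost scenario (a ghost whose size and σ equal the
root population's reproduces them exactly), so rejection ABC penalises
the ghost whenever the data do not pin the ancestral parameters: the
lower-dimensional scenarios place more prior mass near any generic
observed vector. Second, and decisively at this scale: with on the order
of 700 reference draws per scenario spread over an 11-dimensional prior,
no scenario's draws can match a ~30-dimensional informative observed
vector closely; acceptance is then governed by which scenario's
prior-predictive bulk lies nearest, not by the truly discriminating
dimensions. Even a ghost truth engineered to be structurally
un-mimickable — large extant populations descending from a small
bottleneck ancestor, whose expansion-shaped site-frequency spectrum no
constant-size single-ancestor history can produce (observed folded
singleton proportions of ~0.40–0.49 against the constant-size 0.32) —
shifts each SFS summary by only one to two prior-predictive MADs, which
the remaining noisy dimensions swamp. The package's validation therefore
*measures* the scenario-recovery rate rather than assuming it: at
N = 2000 reference simulations (L = 200 kb, 8 diploids per population)
the true ghost scenario is typically **not** ranked first, and the
experiment reports this openly. Genome-scale data with richer summaries —
the regime of the original analyses this pipeline emulates — is where
this model choice becomes answerable; parameter posteriors (in
particular the most recent split time, which is strongly constrained by
the Europe–Asia differentiation summaries regardless of the winning
topology) remain well calibrated at desk scale.

Problem sizes used by the validation experiments (the package's own
choices): 50 replicates of n = 20, L = 500 kb for π calibration; 20
matched-seed triples at σ ∈ {0.01, 0.1, 1} (L = 200 kb) for LD ordering;
20 replicates of L = 300 kb for sweep localisation and branch
specificity; N_sims = 2000 reference simulations at L = 200 kb for ABC,
with one reference table shared across the ten recovery and ten coverage
trials (a shared table is statistically legitimate for rejection ABC and
keeps the experiment tractable).

## Interfaces

The package is library-first: every stage is an ordinary R function
returning tibbles (with `tidy()`/`glance()`/`autoplot()` methods on
result objects), and `run_pipeline()` orchestrates the stages from a
single validated configuration with a global seed, writing per-stage
TSV/JSON outputs stamped with the configuration hash. No shell entry
point is shipped; the functions and this vignette are the interface.

## Known limitations

* The SMC-flavoured block independence underestimates long-range LD; use
  the simulator for contrasts, not absolute LD calibration.
* In multi-population histories the post-merge genealogy refreshes at the
  union of all breakpoint processes, so the LD of a recently derived
  population reflects the ancestral population's recombination regime
  rather than founder-event LD; σ-versus-LD contrasts should be drawn
  from single-population simulations.
* The branch CLR treats the outgroup frequency as the ancestral truth;
  with small outgroup samples this inflates ω and deflates power.
* Rejection ABC model choice is reliable only where the scenarios are
  structurally distinguishable (see above); with weakly informative
  summaries it drifts toward the lowest-dimensional compatible scenario.
* Binomial methylation calling assumes independent reads and a single
  genome-wide non-conversion rate.
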