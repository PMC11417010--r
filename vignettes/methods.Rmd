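---
title: "Joint-SFS demographic inference for two populations: models, engine and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-SFS demographic inference for two populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(jointsfs)
```

## The question and the data shape

`jointsfs` implements the analysis chain used to ask whether two weakly
differentiated populations — in the motivating case, bonnethead sharks
(*Sphyrna tiburo*) sampled in Tampa Bay (Gulf coast, n = 20 diploids after
filtering) and Biscayne Bay (Atlantic coast, n = 69) — are demographically
one population or two, and if two, when they split and which way genes flow.
The data are RAD-style SNP genotypes: roughly ten thousand biallelic SNPs
spread over many thousand short (36 bp) 2bRAD tags, with substantial
missingness and a global Hudson F~ST~ below 0.01.

The chain is: site filters → population-structure summaries (IBS distances,
PCoA, PERMANOVA, F~ST~) → folded joint site frequency spectrum (2D-SFS) with
hypergeometric projection → expected SFS under a catalog of two-population
demographic models → Poisson composite-likelihood fits with multi-start
optimization → model ranking by median AIC over contig-bootstrap replicates →
conversion of the winning model's parameters to physical units.

Because the original raw data are not required, the package carries a
structured-coalescent simulator whose default preset reproduces the study's
statistical shape, so every stage is testable end to end.

## Units and conventions

All demographic models live in the "genetic" units of diffusion-based SFS
software:

* sizes `nu` are ratios to the ancestral effective size $N_e^{anc}$;
* times `T` are in units of $2 N_e^{anc}$ generations;
* migration `M = 2 N_e^{anc} m`, where `m` is the per-generation fraction of
  the receiving population replaced by migrants. `M_1to2` moves genes,
  forward in time, from deme 1 into deme 2. In the backward-time simulator a
  lineage currently in deme 2 therefore jumps into deme 1 at rate `M_1to2`;
  a dedicated one-way-migration test asserts that the two code paths agree
  on this orientation (the recipient deme shows elevated private
  polymorphism);
* `theta = 4 N_e^{anc} mu L` scales the whole spectrum and is profiled out
  of every fit analytically.

Conversions to physical units follow the standard definitions:
$N_e = \theta / (4 \mu L)$, current sizes $\nu_d N_e$, migrant fraction
$m = M / (2 N_e)$, split age $2 T N_e G$ years, and migrants per generation
$m \times N_e^{source}$.

## The expected-SFS engine

The numerical heart is a deterministic moment-equation engine for the
expected sample SFS $\Phi_n(i)$ (one population) or $\Phi(i,j)$ (two).
Writing sample moments in the Bernstein basis
$E[\binom{n}{i} x^i (1-x)^{n-i}]$, neutral drift gives the exactly closed
tridiagonal system

$$\frac{d\Phi_i}{d\tau} = \frac{1}{2\nu}\Big[(i-1)(n-i+1)\,\Phi_{i-1}
 - 2i(n-i)\,\Phi_i + (i+1)(n-i-1)\,\Phi_{i+1}\Big],$$

whose stationary state under the singleton influx $n\theta/2$ is the
Watterson spectrum $\theta/i$ — the engine reproduces it to machine
precision, which pins down the time scale (heterozygosity must decay by
$1/(2N)$ per generation). Size changes enter through $\nu(\tau)$ with
sudden, linear or exponential dynamics; each epoch is advanced by
Crank–Nicolson steps (A-stable, so bottlenecks do not constrain the step
size for stability).

Migration couples the two marginal frequencies and — unlike drift — requires
moments of order $n+1$. The closure is a local-interpolation jackknife:
the allele-frequency density is fitted locally by three basis functions with
closed-form Bernstein moments, and the fitted density predicts the
order-$(n+1)$ moments. Near the frequency boundaries the bases include the
$1/x$ (respectively $1/(1-x)$) singularity that a neutral spectrum carries;
a plain quadratic basis there leaves percent-level errors in the
rare-allele cells, which the singular bases remove. Because closure error
shrinks with sample size, small requested grids are integrated at an
oversampled size (default at least 32 per axis) and projected down exactly.

The migration operator is constant within an epoch. Two steppers share it:
an explicit midpoint rule when the stability-limited step count is modest
(mild migration — the common case), and a dense Crank–Nicolson step with a
single LAPACK factorization per epoch when migration is stiff (large `M`
anywhere in the optimizer's search box). Both are second order; they agree
to well below the Monte-Carlo resolution of the validation oracle.

Models without a split are integrated in one dimension at the pooled sample
size and spread over the two demes with the exact hypergeometric identity
$\Phi(i,j) = \binom{n_1}{i}\binom{n_2}{j}\big/\binom{n_1+n_2}{i+j} \cdot
\Phi_{pooled}(i+j)$; the same identity initializes the 2-D state at a split.
A split-time-to-zero limit check confirms the two paths agree.

Correctness is defined against two independent oracles, not against any
third-party engine: the Watterson closed form, and a structured-coalescent
Monte-Carlo estimator (`mc_expected_sfs`) that averages branch lengths
subtending each $(i,j)$ leaf configuration over ~10^6^ genealogies. At
sample sizes (6,6), every catalog model matches the oracle within ~3
Monte-Carlo standard errors per entry.

## The model catalog

The fixed catalog mirrors the seven structures compared in the motivating
study — `sc1ns`, `sc2ns`, `sc3ns` (panmictic with 1–3 epochs), `s2m`,
`s2msm` (split with asymmetric/symmetric migration), `sc2el`, `sc2elsm`
(those plus an ancestral size-change epoch) — plus `gadma_best`, the
structure found by the genetic-algorithm search on the shark data: sudden
ancestral growth, a recent split, linear growth in deme 1 (Tampa Bay),
sudden growth in deme 2 (Biscayne Bay), and one-way gene flow 1→2. The
published figure caption describes linear growth for Tampa Bay while the
results text says "sudden"; we follow the figure. The published table note
reverses the flow direction relative to the text and the column headers; we
follow the text and headers (Tampa Bay → Biscayne Bay).

Each entry fixes its free parameters and log-scale search box
(`nu` ∈ [1e-3, 1e3], `T` ∈ [1e-4, 5], `M` ∈ [~0, 50]; the migration lower
edge is a numerically-zero 1e-3 so rates can be searched on the log scale).
The AIC parameter count is the number of free parameters plus one for the
profiled `theta`.

## Fitting, ranking, uncertainty

Fits maximize the Poisson composite likelihood
$\sum_{\text{unmasked}} [S_{obs}\ln S_{exp} - S_{exp} - \ln\Gamma(S_{obs}+1)]$
over folded spectra with the monomorphic corners and the redundant folded
half masked. `theta` is profiled analytically
($\hat\theta = \sum S_{obs} / \sum S_{shape}$). Optimization is
derivative-free Nelder–Mead in log10-parameter space with log-uniform random
restarts plus one anchored start (`nu` = 1, `T` = 0.1, `M` = 1), followed by
up to three simplex restarts at the incumbent optimum ("polishing"), which
we found necessary for the 5–7-parameter migration models whose likelihood
surfaces are strongly ridged. Out-of-box proposals are clamped and softly
penalized.

Model selection follows the study's protocol in reduced form: each model is
fitted to the observed spectrum and warm-refitted to contig-bootstrap
replicates; models are ranked by the median AIC across replicates, with
$\Delta$AIC, relative likelihoods $e^{-\Delta/2}$ and AIC weights. The
contig bootstrap (resampling tags with replacement) is what makes the
composite likelihood's pseudo-replication honest: SNPs on one 36 bp tag are
effectively one draw.

Bootstrap uncertainty refits the winner to each replicate, warm-started at
the point estimate, and reports 2.5/50/97.5 percentiles. With the reduced
`B = 20` used in the validation harness, the extreme tail quantiles cannot
be resolved between order statistics, so type-6 quantiles (which fall on
the extreme draws) are used; with `B = 100` the choice is immaterial.

## The synthetic-data generator

`simulate_genealogy`/`emit_genotype_matrix` implement a standard
structured coalescent for one or two demes: per-deme pair coalescence at
rate $1/\nu_d(\tau)$, backward migration at the rates implied by the forward
convention above, epochs handled by exponential thinning (so time-varying
sizes are exact, not discretized), infinite-sites mutations dropped on
branches as a Poisson process, haplotypes paired within deme into diploids,
and uniform random missingness. Contigs are independent and non-recombining
— a good approximation for 36 bp 2bRAD tags, an approximation nonetheless.

The `bonnethead_preset()` emulates the study conditions: 20 + 69 diploids,
36 bp tags, $\mu = 3.92\times10^{-9}$, and the published best-fit history in
physical units ($N_e^{anc}$ = 10,263; sudden ancestral growth to ~51,000
around 390 kya; a split 1,532 years ago with growth to 158,639 / 1,026,319;
one-way flow at $m = 4.87\times10^{-4}$). The study never states its
realized tag count; 5,000 tags of 36 bp would yield only a few hundred
SNPs under this history, far from the reported ~10,000, so the preset's tag
count (129,000) was calibrated once so that the standard filters retain
roughly the reported SNP count — consistent with the study's ~4.97 M
genotyped sites (≈138,000 36-bp tags). The missing-call rate (0.15) makes
some sites hover near the 75% call-rate threshold, as in the study.
Two cautions about what the preset does and does not emulate: missingness
is uniform rather than depth-driven (only the call-rate filter consumes
it), and the global Hudson F~ST~ implied by the best-fit model itself
(~0.001) is several-fold smaller than the study's SFS-prior estimate
(0.0074) — printed F~ST~ values are context, not calibration targets,
since the estimators differ fundamentally.

## Structure statistics

IBS distance is the mean per-site allele mismatch over pairwise-complete
sites. PCoA is classical metric scaling (`stats::cmdscale`), with negative
eigenvalues reported and their axes dropped. PERMANOVA delegates to
`vegan::adonis2` — the tool the motivating study itself used — with 999
free permutations and a seeded generator; sample-size imbalance is handled
by the permutation scheme itself. F~ST~ is the Hudson estimator,
ratio-of-averages across sites (the average-of-ratios alternative is
asserted to differ on a constructed counterexample). The study's F~ST~ came
from genotype-likelihood machinery with an SFS prior; our substitution of
called genotypes is documented, and its printed values are not used as
acceptance anchors. Similarly, the study estimated individual
heterozygosity from single-sample SFS on high-coverage sites; we use the
called-genotype heterozygote fraction.

## Validation harnesses and problem sizes

Four experiments validate the pipeline end to end (all reproducible
one-liners, all seeded):

* `watterson_check` — equilibrium spectrum vs `theta / i`, exact;
* `engine_oracle_check` — all eight catalog models at (6,6) vs the
  10^6^-replicate coalescent oracle, one study-typical parameter draw per
  model (`nu` ∈ [0.5, 3], `T` ∈ [0.2, 0.8], `M` ∈ [0.5, 3]: the regime the
  data analyses actually visit);
* `recovery_experiment` — datasets of ~10–14k SNPs over 2,000 contigs
  simulated under `sc2ns` (nu = 5, T = 0.1) and `s2m` (nu = (2,3), T = 0.3,
  M = (1, 0.3)); the true values should fall inside the B = 20
  contig-bootstrap 95% intervals in ≥90% of (replicate, parameter) pairs.
  Folded spectra are taken at 24 (pooled) and (10,10) genomes respectively:
  projections this size keep the 2–5 free parameters well determined while
  holding the full experiment to minutes;
* `selection_experiment` — 20 datasets under the no-split `sc2ns` truth,
  ranked over the seven-model catalog with 2 bootstrap replicates and
  warm-started refits; a no-split model should win in ≥80%;
* `permanova_type1` — 400 panmictic datasets with arbitrary labels;
  rejection rate at α = 0.05 should sit within binomial error of 0.05.

Passing these shows the pipeline is internally consistent and statistically
calibrated *under the generator's assumptions* — unlinked tags, neutral
sites, uniform missingness, no genotyping error. Real 2bRAD data violate
all four to some degree; the contig bootstrap absorbs within-tag linkage,
but genotyping error and depth-dependent missingness would require the
genotype-likelihood machinery that is explicitly out of scope here.

## Numerical choices and degenerate inputs

* Folding ties (entries at exactly half the total sample size) are split
  half-and-half, the dominant convention in diffusion-SFS software.
* Projection happens at SFS-accumulation time as expected fractional
  counts, so partially missing sites contribute exactly unit mass.
* Poisson likelihood floors expected entries at 1e-12 (with a warning)
  rather than returning −∞.
* Degenerate inputs error loudly: single-contig bootstrap, folding a folded
  grid, projecting upward, non-coalescing two-island configurations (via a
  time cap), all-sites-removed filtering warns instead.
* Fit-grade integrations cap steps per epoch at 800; the cap binds only in
  absurd corners of the search box (e.g. `nu` near 1e-3 with `T` near 5)
  where the likelihood is hopeless anyway. Reference-grade calls
  (`expected_sfs` defaults) allow 20,000.

## Known limitations

* The jackknife closure leaves relative errors of order 10^-3^–10^-2^ in a
  few rare-allele cells at very small sample sizes; oversampled integration
  reduces but does not eliminate this.
* Plain AIC is used for ranking (as in the published table), not the
  composite-likelihood-adjusted CLAIC; the bootstrap-median protocol is the
  robustness device.
* The optimizer is local with random restarts; for the 7-parameter models a
  global search (as the genetic-algorithm stage of the motivating study
  used) can find better optima than any fixed restart budget.
* No recombination within contigs, no selection, no sequencing-error model,
  no genotype likelihoods.
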