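---
title: "Models and methods behind cherrydemog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cherrydemog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cherrydemog)
```

`cherrydemog` reimplements, as one tested pipeline, the population-genetic
workflow used to study the domestication of Chinese cherry (*Cerasus
pseudocerasus*): microsatellite diversity and bottleneck statistics,
Bayesian admixture clustering, directional migration networks, a
QST--FST comparison, and approximate Bayesian computation (ABC) over four
split-with-bottleneck demographic scenarios. Every stage can be exercised
on data from the package's own structured-coalescent simulator, so all
statistical behaviour documented here is reproducible without access to
the original genotypes.

## Data model

A `genotype_matrix` holds unordered diploid allele-size pairs per
accession and locus, a per-locus table (motif length, bp vs repeat-unit
coding), and per-accession metadata (population, geographic region,
wild/cultivated/relative status). Missing calls are whole-genotype only;
half-calls are normalised to missing, and every downstream frequency
computation simply drops missing cells locus-wise — no imputation
anywhere. Missingness filtering removes loci first (strictly more than
30% missing by default) and then recomputes accession fractions over the
retained loci (strictly more than 25%); both thresholds are strict, so a
boundary accession survives. The loci-first order follows the narrative
order of the original genotyping screen; it is a package choice, as the
order is not fixed by the data themselves.

Diversity statistics are conventional: unbiased gene diversity
$H_s = \frac{N}{N-1}\,(1-\sum_i p_i^2)$, observed heterozygosity $H_o$,
polymorphism information content, and $F_{is} = 1 - H_o/H_s$ per locus
with unweighted across-locus means (FSTAT convention). Allelic richness
and private allelic richness use hypergeometric rarefaction to a common
number of gene copies $g$; at $g = 2$ the identity $A_r = 1 + H_s$ holds
exactly, which the test suite asserts to machine precision and uses to
validate the rarefaction code against exhaustive subsample enumeration.

## The coalescent simulator

The simulator is a standard structured coalescent over piecewise-constant
diploid sizes: within an epoch, $k$ lineages in a population of size $N$
coalesce at rate $k(k-1)/(4N)$ per generation; demographic events are
size changes and (backwards-in-time) population merges, and a symmetric
island migration rate is available for generic simulations. Mutations
follow the generalized stepwise model (GSM): step magnitudes are
geometric with continuation probability $P$ (mean $1/(1-P)$; the Chinese cherry study's
prior range 0.1--0.3 corresponds to mean steps of 1.11--1.43), signs are
fair, and the repeat ladder is bounded at 40 contiguous states with the
root anchored at the window's centre. A mutation that would leave the
window is redrawn rather than reflected or truncated, which avoids
probability pile-up at the boundary; the exact boundary policy of the
original simulation software is not documented, so this is a package
decision. Single-nucleotide indels (SNI) are a separate Poisson process
that toggles a $\pm1$ bp off-ladder offset, so off-ladder alleles remain
distinct states, as they do on a gel.

Two engine-level checks anchor the implementation: the mean pairwise
coalescence time for two copies in a panmictic diploid population matches
$2N$ generations, and the squared difference in allele state across a
divergence time $t$ matches $\mu t\,\mathrm{E}[s^2]$ with
$\mathrm{E}[s^2] = (1+P)/(1-P)^2$ — both verified by simulation in the
test suite.

One practical wrinkle: a multi-deme island model with migration rate
exactly zero has no common ancestor, so `simulate_island(m = 0)` joins
the demes by a single ancient merge 40 N generations back ("long
isolation"); truly disconnected demographies remain an error in
`sample_genealogy`.

The four domestication scenarios share parameters
$N_1, N_2, N_3, N_{1b}, N_{2b}, T_1, T_2, D_{b1}, D_{b2}$: the wild
cluster WC keeps constant size $N_3$; each cultivated cluster is founded
from its model-specific ancestor (WC in models 1--2; CC2 or CC1 in
models 3--4) at $T_2$ (older event) or $T_1$, spends its first
$D_b$ generations at the bottleneck size $N_b$, and then takes its
current size. A bottleneck longer than the population's age is truncated
to the founding time — the published model-2 posterior medians themselves
have $D_{b2} = 875 > T_2 = 872$, i.e. a bottleneck spanning CC2's whole
history.

### Priors

The time prior $T_2 \sim U[697, 1700]$ generations reflects the
historical record of cherry cultivation (domestication older than
roughly 3,000 years at 4.5 years per generation). The remaining
supports are package choices, recorded here
once and used everywhere: $T_1 \sim U[10, 1700]$ truncated to
$T_1 < T_2$ by rejection (the $T_1$ support is not pinned by historical records);
$D_{bi} \sim U[1, T_i]$; all five effective sizes $U[10, 10^4]$ (the
study defers these to unpublished supplementary material); mean mutation
rate $U[10^{-4}, 10^{-3}]$; mean GSM coefficient $U[0.1, 0.3]$; mean SNI
rate log-uniform on $[10^{-8}, 10^{-5}]$ — a four-decade range is
conventionally sampled log-uniformly. Per-locus rates are drawn from
Gamma(shape 2) distributions centred on the dataset means, truncated to
wide per-locus supports ($\mu_l \in [10^{-6}, 10^{-2}]$,
$P_l \in [0.005, 0.95]$, SNI$_l \in [10^{-9}, 10^{-4}]$).

## Bottleneck detection

The heterozygosity-excess test simulates, for every polymorphic locus,
coalescent samples of the observed size at mutation-drift equilibrium
under a two-phase model — 10% single-step and 90% infinite-allele
mutations by default, taken literally from the published setting — and
keeps simulations whose allele count equals the observed $k$. $\theta$
is tuned by bisection so that the expected allele count matches $k$
(with an acceptance-probability floor of 2% and a budget of
$50\times$`n_iter` attempts). `Heq`, the expected equilibrium diversity
given $k$, is the mean over accepted simulations.

The across-locus Wilcoxon signed-rank step does **not** rank the raw
differences $H_e - H_{eq}$: the conditional distribution of $H_e$ given
$k$ is left-skewed, so ranking raw differences rejects at roughly four
times the nominal rate even when the data are simulated under the test's
own null (we measured ~20% at $\alpha = 0.05$). Instead each locus
contributes the normal score of its mid-rank percentile of $H_e$ within
the simulated `Heq` distribution, which makes the null symmetric; the
measured size is then ~8% at $\alpha = 0.05$ with 19 loci. The per-locus
table still reports the `Heq` mean, its standard deviation, and the
standardized difference.

The Garza--Williamson index is $M = k/(r+1)$ with $r$ the allele range
in repeat units, averaged over polymorphic loci and flagged below the
conventional 0.68 threshold. Off-ladder SNI alleles count toward $k$ but
contribute their nearest ladder slot to $r$, because $M$ is defined on
the repeat ladder. Note that $M$'s power to see a crash comes from
multi-step mutations: under a strictly single-step process the allele
set stays contiguous and $M$ barely moves, so the calibration fixtures
simulate with $P = 0.3$.

## Admixture clustering

`admixture_mcmc` is a Gibbs sampler for the admixture model with
*independent* cluster allele frequencies: allele-copy origins $z$,
cluster frequencies (Dirichlet($\lambda = 1$) prior), and per-accession
membership vectors $Q$ (Dirichlet($\alpha$)) are updated in turn, with
$\alpha$ following a Metropolis random walk under a uniform prior on
$(0, 10]$. The correlated-frequency F-model used by the original
STRUCTURE runs is deliberately not implemented; recovery targets in the
tests are set under the independent-frequency model. With sampling
location labels, each location carries its own $\alpha$ vector — a
location-informed prior for weakly structured (e.g. wild-only) data.
The model-evidence proxy is $\overline{\ln L} - \mathrm{Var}(\ln L)/2$,
the quantity Evanno's $\Delta K$ is defined on:
$\Delta K = |\overline{L}(K{+}1) - 2\overline{L}(K) +
\overline{L}(K{-}1)| / \mathrm{sd}(L(K))$, undefined where the
run-to-run spread is zero.

Run alignment permutes cluster labels per run to maximise agreement with
an incumbent consensus (exhaustive over $K!$ permutations for
$K \le 6$, greedy matching above); runs below 0.9 similarity form
separate modes and the consensus is the mean $Q$ of the largest mode.
Accessions are assigned to their argmax cluster at $Q \ge 0.800$
(inclusive at the boundary) and are "admixed" otherwise.

Default MCMC lengths in this package are a scaled-down 2,000 + 2,000
sweeps, which the planted-structure experiments below show to be
sufficient at 19 multi-allelic loci; the conventional production
setting for real data — 100,000 + 100,000 sweeps with 20 runs per $K$
from 1 to 12 — remains available as plain arguments.

Distance-based views use Nei's $D_A$ (one minus the mean Bhattacharyya
affinity across loci), a hand-written Saitou--Nei neighbour-joining
(smallest-index tie-break, negative branch lengths clamped with the
deficit moved to the sister edge, rooting at the midpoint of the
outgroup's pendant edge) — `ape` serves as the independent topology
oracle in the tests, not as the implementation — and classical-MDS PCoA
on a codominant genotype mismatch distance (0/1/2/3/4 per locus for
identical/one-shared/het--het/hom--het/hom--hom disjoint genotypes),
the centering being what "covariance-standardised" names.

## Migration networks

For an ordered pair $(a, b)$, a hypothetical pooled population takes the
unweighted mean of the two allele-frequency profiles; Nei's multi-locus
$G_{ST}$ between the *recipient* $b$ and the pool is transformed by the
plain Wright island-model relation $N_m = (1/G_{ST} - 1)/4$, and all
edges are scaled by the maximum so the strongest edge has relative
migration 1. Refinements of the published $N_m$ estimator
(finite-deme/allele-count corrections) are not reproduced; the transform
is isolated in one internal function so a refined formula can be swapped
in. Bootstrap significance resamples individuals within groups; an
asymmetry is significant when the two directions' percentile intervals
do not overlap. The display convention keeps only edges strictly over
0.35 relative migration.

## QST--FST

$Q_{ST} = V_{G,\text{among}} / (V_{G,\text{among}} + 2
V_{A,\text{within}})$ with components from one-way random-effects ANOVA
($n_0 = (N - \sum n_i^2/N)/(a-1)$, among-group component clamped at
zero). The measured accessions are clonally grafted into a common
garden, so accession values are total genotypic values and the
"additive" within component is really broad-sense; the formula is
applied verbatim and the resulting $Q_{ST}$ should be read as an
upper-bound-style proxy. $F_{ST}$ is Weir--Cockerham $\theta$ from
per-allele variance components, with a percentile CI from resampling
loci (the 10,000-bootstrap convention). The FDIST-style neutrality
screen simulates single-locus island-model datasets, tunes the migration
rate by bisection until the mean simulated $\theta$ matches the observed
10%-trimmed mean, bins simulations into ten equal-count
heterozygosity bins, and flags observed loci outside the 2.5--97.5%
$\theta$ envelope of their bin. The verdict rule is the standard
three-way comparison: divergent if $Q_{ST}$ exceeds the CI's upper
bound, stabilizing below the lower bound, drift otherwise.

## ABC

The summary vector has a fixed, versioned order: per group the mean
allele number and mean unbiased gene diversity; per unordered pair the
multi-locus $\theta$ and Goldstein's $(\delta\mu)^2$ in repeat units —
twelve statistics for three groups. Retention uses Euclidean distance on
reference-standardised statistics with the tolerance expressed as a
retained fraction (1% by default, following "the 1% simulated
datasets").

Two numerical safeguards matter on desk-scale references. First,
`estimate_params` floors the retained count at 200 (100 in model
choice): retaining 1% of a 5,000-row model block leaves 50 rows for a
12-covariate local-linear regression, which overfits and drove the
measured 95%-interval coverage of $N_3$ down to ~0.73; with the floor
the measured coverage is ~0.88. At the production scale of $10^6$ rows
per model the floor never binds. Second, the local-linear (Beaumont)
adjustment logit-transforms each parameter to its prior bounds before
the Epanechnikov-weighted regression and back-transforms afterwards, so
posterior summaries cannot leave the prior support; a singular
regression falls back to plain rejection quantiles and is flagged.

Model choice reports both the rejection estimate (model frequencies
among retained rows) and a polychotomous logistic estimate: a linear
discriminant projection of the retained statistics feeds a multinomial
logistic regression evaluated at the observed point, the standard
DIYABC-style pairing. Model-choice error rates follow the
pseudo-observed-dataset recipe: type I is the fraction of focal-model
pods not assigned to the focal model, mean type II the mean fraction of
other models' pods assigned to it. Years are reported as generations
times 4.5 (the mean generation time for a tree with a 3--6-year juvenile
phase), rounded half-up at the reporting boundary only.

## What the synthetic data do and do not show

The generator reproduces the features that drive every method exercised
here: three clusters with split-with-bottleneck histories, GSM mutation
with rare off-ladder alleles, configurable missingness, and trait data
with controllable among/within variance
($\mathrm{E}[Q_{ST}] = v_a/(v_a + 2 v_w)$). It does not emulate
genotyping artefacts (null alleles, allele-binning error, stutter),
linkage, selection, or clonal duplicates, so passing tests demonstrate
the correctness and calibration of the statistics, not robustness to
those artefacts. Null-allele estimation was screened out in the original
workflow before the data reached any stage implemented here.

## Problem sizes and tolerances

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the checks are statistically
meaningful: calibration tests use 40--100 replicates of 19-locus,
30-diploid samples (nominal size accepted within [0.01, 0.12] at
$\alpha = 0.05$); structure recovery uses five replicates of a planted
$K = 3$ island model with 201 accessions at $\theta \approx 0.15$ and a
$K$ scan over 1--5 with three runs each; the ABC reference holds 5,000
rows per model (2,500 in the acceptance script) with 30 diploids per
group, 50 model-choice pods at the published model-2 posterior medians,
and 50--100 coverage pods drawn from the priors. Identities
($A_r(2) = 1 + H_s$, $\theta$ vs a brute-force transcription, NJ on
additive distances) are asserted at machine precision or exact topology
equality. Production-scale settings (a $10^6$-row reference per model,
100k/100k MCMC, 10,000 bootstraps) are plain arguments.
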