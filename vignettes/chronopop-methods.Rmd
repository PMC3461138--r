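---
title: "Temporal population genetics with chronopop: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal population genetics with chronopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronopop)
```

## The problem

Populations sampled at two points in time carry information that single
"snapshot" samples cannot provide: the direction and tempo of change in
genetic diversity, the growth of differentiation among fragments, and the
magnitude of drift — hence effective population size — over the sampling
interval. chronopop implements the full analysis chain for diploid
microsatellite data from such designs: museum-era and contemporary samples
from the same sites, typically a century (tens of generations) apart, as
collected for declining songbirds and other vertebrates of conservation
concern.

The package has four analysis layers over a common data model
(`TemporalDataset`, a locus list plus `GenotypeSample` blocks read from
Genepop files):

1. **Diversity** — unbiased expected heterozygosity, rarefied allelic
   richness, Hardy–Weinberg exact tests, and nonparametric comparisons
   between sampling periods with loci as replicates.
2. **Differentiation** — pairwise Weir–Cockerham θ with permutation
   significance, the heterozygosity-based measures (G~ST~, standardized
   G''~ST~, Jost's D~EST~), and the locus-paired contrast of
   differentiation between epochs.
3. **Demographic inference (ABC)** — a serial-sample coalescent simulator
   of microsatellite loci under two-epoch bottleneck demographies, a
   reference table over candidate scenarios, rejection, local logistic
   regression for scenario posterior probabilities, and local-linear
   regression-adjusted parameter posteriors.
4. **Temporal N~e~** — the F~c~ moment estimator and a pseudo-maximum-
   likelihood estimator on a Wright–Fisher grid, closed or jointly with a
   migration rate from a fixed source pool.

A fifth layer, the synthetic-data generators (`wfForwardSim`,
`makePaperStudy`), produces all validation fixtures with recorded truth.

## Statistical methods and their assumptions

### Diversity

Unbiased expected heterozygosity at a locus with $N$ sampled gene copies
and allele frequencies $p_a$ is $H_{EXP} = \frac{N}{N-1}(1 - \sum_a
p_a^2)$. Allelic richness uses hypergeometric rarefaction to a common
gene-copy count $g$, $A_R(g) = \sum_a [1 - \binom{N-N_a}{g} /
\binom{N}{g}]$, removing the strong dependence of raw allele counts on
sample size; `diversityTable()` defaults $g$ to the smallest per-locus
$N$ among the samples being compared. Hardy–Weinberg exact tests use the
multi-allelic conditional (Levene) probability with Monte-Carlo
re-pairings of the observed gene copies (default $10^5$, seeded):
complete enumeration is infeasible for the allele counts typical of
microsatellites.

Comparisons between sampling periods treat loci as replicates. For a pair
of periods the Wilcoxon signed-rank test is exact (enumeration of sign
assignments when ties are present, the closed-form null otherwise) up to
25 informative loci and a tie-corrected normal approximation beyond. For
three or more periods, "blocked by locus" is implemented as within-block
ranking — a Friedman-type statistic referred to $\chi^2_{k-1}$ — because
ranking across all values at once would conflate between-locus diversity
differences with the period effect; an unblocked Kruskal–Wallis
(`kruskalByGroup`) is also provided for comparison. Tests of a decline
from the historical to the contemporary period are one-sided (the
directional hypothesis); everything else defaults to two-sided, and the
sidedness is always recorded in the result.

### Differentiation

θ follows the Weir–Cockerham variance-component estimator: per allele and
locus, components $a$ (among populations), $b$ (among individuals within
populations) and $c$ (within individuals, entered by the observed
heterozygote frequencies); per-locus θ is $\sum a / \sum(a+b+c)$ over
alleles and the multilocus value is the ratio of sums over loci. Negative
estimates are reported as computed — truncation would bias epoch
contrasts. Significance comes from permuting whole multilocus genotypes
between the two samples (3000 permutations by default) with the
$(1 + \#\{\theta^\* \ge \theta\})/(1 + n)$ convention so p is never 0.
Permuting individuals rather than gene copies preserves departures from
Hardy–Weinberg within samples under the null.

Because F~ST~-type measures are compressed when within-population
diversity is high — exactly the regime of hypervariable microsatellites
(H~S~ near 0.8–0.9) — `gstFamily()` also reports Nei–Chesser-corrected
G~ST~, Hedrick's G'~ST~, the Meirmans–Hedrick standardized G''~ST~ and
Jost's D~EST~ for two demes. The typeset literature is ambiguous about
which standardized variant any given study used, so both standardized
forms are emitted. Multilocus D~EST~ (and G~ST~) average numerator and
denominator terms across loci before taking the ratio: the
average-of-ratios alternative explodes at near-fixed loci. D~EST~ is
clipped at 0, following its source literature; θ and G~ST~ are not.

The epoch contrast (`compareDifferentiationEpochs`) applies the one-sided
signed-rank test to per-locus differentiation values of the same site
pair in the two epochs. Two caveats discovered during validation and
worth knowing: (i) θ's finite-sample distribution is skewed in a
sample-size-dependent way, so contrasting epochs with very different
sample sizes biases the one-sided test — the end-to-end checks
size-match the epochs by subsampling before contrasting; (ii) per-locus
values from overlapping sample pools are not independent replicates
across site pairs, so pooling pairs into one test pseudo-replicates.

### Coalescent simulator

`simulateLocus()` builds a heterochronous genealogy: contemporary gene
copies enter at time 0, historical copies at the sampling offset
(default 90 generations, one generation per year for a century-scale
design), pairs coalesce at rate $\binom{k}{2}/2N$ with $N$ switching
from the current to the ancestral size at the bottleneck time. The
continuous-time approximation to discrete generations is accurate
because $N \gg$ sample size in all scenarios considered. Mutations are
Poisson along branches under a generalized stepwise model: geometric
step sizes (parameter 0.22), reflecting boundaries on a 40-state allele
range, per-locus rates Gamma-distributed (shape 2) around a mean of
$5\times10^{-4}$ per generation. These mutation settings are a
documented stand-in chosen to match common practice for avian
microsatellite panels — the motivating study delegated them to its ABC
software without stating them — and give equilibrium heterozygosities of
0.75–0.9 at the ancestral sizes of the scenario set, matching the
high-diversity loci such studies report. Diploid genotypes are formed by
sequential pairing of simulated copies, which equals random pairing by
exchangeability.

Validation anchors the simulator to closed forms: mean pairwise
coalescence time $E[T_2] = 2N$, strict-SMM equilibrium heterozygosity
$1 - 1/\sqrt{1+2\theta}$, and linear growth of allele-size variance with
θ.

### The scenario set and ABC engine

`bottleneckScenarios()` encodes eleven two-epoch candidate demographies
for a population sampled ~90 generations apart: a constant-or-increasing
null (both sizes on U[10, 100000], ancestral ≤ current); three fully
fixed declines (4000→500, 5000→650, 6000→700) estimating only the
decline time t on U[10, 80]; four declines from fixed ancestral sizes
2000–5000 to a current size on U[200, 1000]; and three with priors on
both sizes (U[2500, 15000]→U[100, 1000] twice — kept as two distinct
candidates as printed in the source design — and
U[2000, 10000]→U[500, 750]). The null scenario has no decline time; its
size change is placed at the historical sampling offset so that the
ancestral size governs everything older than the historical sample.

Summary statistics (11, fixed order): per epoch the means over loci of
allele count, unbiased heterozygosity, allele-size variance and the
Garza–Williamson M-ratio (allele count over allele-size span — the
classic bottleneck signature); between epochs multilocus θ, mean Jaccard
shared-allele proportion, and $(\delta\mu)^2$. Monomorphic loci follow
zero conventions so the vector is always defined. Statistics are
standardized by the reference table's per-statistic median and MAD
(robust to the heavy tails wide priors produce) before Euclidean
rejection; the closest 1% are retained, with Epanechnikov weights on the
acceptance radius shared by both local regressions (the standard
regression-ABC kernel choice). Scenario probabilities come from weighted
multinomial logistic regression of scenario id on statistic deltas,
evaluated at delta zero, falling back to weighted acceptance frequencies
if the regression degenerates. Parameter posteriors use weighted
local-linear regression with sizes on the log scale (respecting
positivity across four-decade priors) and times on the natural scale;
adjusted draws are truncated to the prior support, the point estimate is
the weighted median and the credibility interval the weighted
0.025/0.975 quantiles.

Desk-scale defaults run $10^4$ simulations per scenario — the original
analyses used $10^6$ per scenario; calibration experiments in the test
suite (coverage of the 95% credibility interval over 100 prior-drawn
pseudo-observed datasets, confusion between the null and a bottleneck
scenario over 50 repetitions at $10^4$ rows/scenario) verify that this
scale supports the package's conclusions. One behaviour users should
expect of regression ABC at this scale: for weakly identified parameters
(the decline time, whose posterior spans half its prior even in the
original study), posterior medians shrink toward the prior centre across
repeated pseudo-observed datasets; the credibility intervals remain
calibrated.

### Temporal N~e~

The moment estimator uses the standardized temporal variance
$F_c = \frac{1}{K}\sum_i (x_i-y_i)^2 / (\bar{z}_i - x_i y_i)$ with
$\bar z_i = (x_i+y_i)/2$, over the K alleles present at either time
point; loci are weighted by their $K-1$ independent alleles, and
$\hat N_e = t / (2[F_c - 1/(2S_0) - 1/(2S_t)])$ under plan II sampling
(sampled birds are released, not removed). A non-positive bracket means
the drift signal is below sampling noise and is reported as
$N_e = \infty$ rather than a negative size. Confidence bounds come from
chi-square limits on $F_c$ with $\sum(K-1)$ degrees of freedom.

The pseudo-maximum-likelihood estimator models each allele class as a
biallelic frequency trajectory on a Wright–Fisher grid: exact count
states when $2N_e \le 400$, otherwise 401 equispaced frequencies with a
normal drift kernel (±6 SD window, midpoint rule, row-normalized).
Each generation applies the deterministic migration pull
$p' = (1-m)p + m\,p_{source}$ toward fixed source frequencies — the
infinitely-large-source assumption — followed by binomial drift. The
earlier sample enters through its binomial sampling posterior; the later
sample's likelihood is integrated over the propagated distribution;
class log-likelihoods are summed over loci (the "pseudo" part: allele
classes at a locus are treated as independent). Alleles with fewer than
3 copies in the earlier sample are pooled per locus to stabilize the
transition modelling. Estimates maximize over a user grid (default
log-spaced 10–5000 for N~e~), with profile-likelihood 95% intervals at
1.92 log-units; maxima on the grid edge are flagged. The exact-grid
branch is verified against brute-force transition-matrix likelihoods for
$2N_e \le 40$.

Generation length T converts the calendar gap to generations as
`round((year_t - year_0)/T)`; the analysis scans T ∈ {1, 1.5, 2} years
because songbird generation lengths are uncertain (females breed in
their first year, males usually from their second).

One directional fact, reproduced by simulation and matching the
published contrast between joint and closed estimates: on data generated
with genuine immigration from a differentiated source, the joint
estimator returns *smaller* N~e~ than the closed one. The migration pull
contracts frequency variance by $(1-m)^2$ per generation, so a model
that knows about migration needs more drift — smaller N~e~ — to explain
the same observed dispersion, while the closed model books the pull
itself as drift.

## The synthetic study generator

`makePaperStudy()` emulates the three-site, two-epoch design end-to-end:
historical samples (sites named Kerr, Bexar and Oklahoma; 1900–1915;
n = 8–20) drawn from one panmictic pre-bottleneck pool whose allele
frequencies come from a coalescent equilibrium simulation at the
ancestral size (5000 by default, 500 gene copies per locus), and
contemporary samples (2005–2008; n = 17–34) taken after independent
per-site drift since the bottleneck (67 generations before 2005 by
default). Fragmentation is modelled by splitting the species-wide
post-bottleneck size (450) equally across sites, each fragment drifting
at N/3: this keeps the pooled contemporary population consistent with
the single-population two-epoch scenario the ABC layer estimates.
Mutation during the ~100-year forward phase is omitted (≪1 expected
mutation per locus). The no-bottleneck control (`Nbot = Inf`) keeps all
sites in one pool drifting at the ancestral size, so epoch differences
are sampling noise only.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: genotyping error and allelic dropout in
museum material (handled upstream by dedicated tools in real studies),
null alleles, overlapping generations, post-bottleneck gene flow among
fragments (its omission makes synthetic inter-site differentiation
larger than field studies with ongoing gene flow typically report), and
uncertainty in historical sampling years. Recovery results on these fixtures demonstrate
correctness of the estimators under their own assumptions, not
robustness to those field realities.

## Numerical choices and degenerate inputs

* Rarefaction uses `lchoose` differences (no factorial overflow); an
  allele that cannot be missed contributes exactly 1.
* Monte-Carlo p-values use the +1 numerator/denominator convention.
* Signed-rank: zero differences dropped; mid-ranks with tie-corrected
  variance; exact enumeration only to $2^{16}$ sign vectors.
* θ: loci monomorphic across both samples are excluded and listed;
  all-monomorphic comparisons return NA rather than 0.
* Reference tables resimulate rows with undefined statistics and abort
  if more than 1% of rows fail; MAD scaling falls back to the SD, then
  to 1e-12, for near-constant statistics.
* Rejection ties are broken by a seeded shuffle so results are
  reproducible yet unbiased; boundary rows keep a tiny positive
  Epanechnikov weight.
* Local-linear adjustment tolerates rank-deficient design matrices by
  dropping collinear columns (R's pivoting), logged through `lm`.
* The pseudo-likelihood floors each chain's likelihood at 1e-300 before
  the log; initial posteriors incompatible with the data return -690 per
  chain.
* All stochastic entry points take explicit seeds; `runStudy()` spawns
  per-stage seeds from one master seed so stages stay independently
  reproducible.

## Problem sizes used by the validation suite

The shipped tests run the oracle equivalences exactly; the coalescent
closed forms at 4000–5000 replicate genealogies and 1500–2000 loci; ABC
calibration at $10^4$ rows per scenario with 100 coverage and 50
confusion repetitions; temporal-N~e~ recovery at 200 moment and 100
joint replicates (12-point N~e~ and 7-point m grids); and the end-to-end
study direction at 50 bottleneck and 50 control replicates. The
acceptance script builds a $4\times10^4$-row reference table for the
scenario-8 recovery experiment. These sizes are the package's chosen
trade-off between Monte-Carlo error and a test suite that runs in
minutes; all are parameters, not limits.

## Known limitations

* The Genepop dialect is fixed to 3-digit diploid alleles; no haploid,
  SNP, Arlequin or STRUCTURE support.
* No F~IS~ or linkage-disequilibrium inference; no hierarchical AMOVA or
  isolation-by-distance tests.
* The ABC engine is plain rejection + local regression; no sequential
  Monte Carlo, no neural posterior estimation, and no model-misspecification
  diagnostics beyond the calibration suite.
* The pseudo-likelihood treats allele classes as independent and the
  source pool as fixed and infinite; both are approximations the source
  methods themselves make.
* Coalescent and forward simulators assume neutrality, unlinked loci and
  no recombination within loci.
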