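# chronopop

Temporal population genetics of diploid microsatellite samples: quantify
genetic change between historical (museum-era) and contemporary samples of
the same populations, infer the demography that produced it, and estimate
effective population size from the allele-frequency change in between.

The package was built for century-scale songbird designs — three breeding
sites sampled around 1900–1915 and again around 2005–2008 at nine
hypervariable microsatellite loci — but all components are general to any
two-epoch diploid microsatellite dataset in Genepop format.

## What it computes

**Diversity and its change.** Unbiased expected heterozygosity
*H*<sub>EXP</sub> = *N*/(*N*−1)·(1 − Σ*p*²), rarefied allelic richness
*A*<sub>R</sub>(*g*) = Σ[1 − C(*N*−*N*<sub>a</sub>, *g*)/C(*N*, *g*)],
Monte-Carlo Hardy–Weinberg exact tests, and exact Wilcoxon signed-rank /
Friedman-type comparisons between sampling periods with loci as
replicates.

**Differentiation and its change.** Pairwise Weir–Cockerham θ from
variance components with permutation p-values, plus G<sub>ST</sub>,
standardized G''<sub>ST</sub> and Jost's D<sub>EST</sub> (the measures
that remain interpretable when within-population diversity is high), and
a one-sided locus-paired contrast of differentiation between epochs.

**Demographic inference.** A serial-sample coalescent simulator of
microsatellite loci (generalized stepwise mutation) under eleven
candidate two-epoch demographies — a constant-size null and ten bottleneck
variants with uniform priors — drives approximate Bayesian computation:
rejection on 11 summary statistics, local logistic regression for
scenario posterior probabilities, and local-linear regression-adjusted
parameter posteriors with 0.025–0.975 credibility intervals.

**Temporal *N*<sub>e</sub>.** The *F*<sub>c</sub> moment estimator
(*N*<sub>e</sub> = *t* / 2[*F*<sub>c</sub> − 1/(2*S*₀) − 1/(2*S*<sub>t</sub>)])
and a pseudo-maximum-likelihood estimator on a Wright–Fisher transition
grid, closed or jointly with a migration rate *m* from a fixed source
pool, at generation lengths *T* ∈ {1, 1.5, 2} years.

**Synthetic data.** Forward Wright–Fisher generators with known
(*N*<sub>e</sub>, *m*) truth and a full study-shaped three-site bottleneck
dataset generator with a JSON truth manifest — the package's validation
fixtures, and first-class tested code.

## Worked example

```r
library(chronopop)

## a study-shaped synthetic dataset with known truth:
## 5000 diploids declining to 450 (split over 3 sites) 67 generations ago
study <- makePaperStudy(seed = 1)
ds <- study$dataset
ds
#> TemporalDataset: 9 loci, 9 samples (5 historical, 4 contemporary)
#>   epochs separated by 97 generations
#>   Kerr         1900   historical    n = 8
#>   Kerr         1910   historical    n = 15
#>   Kerr         1915   historical    n = 20
#>   Bexar        1910   historical    n = 9
#>   Oklahoma     1910   historical    n = 8
#>   Kerr         2005   contemporary  n = 17
#>   Kerr         2008   contemporary  n = 25
#>   Bexar        2005   contemporary  n = 33
#>   Oklahoma     2006   contemporary  n = 34

## has diversity declined at Kerr? (loci as replicates, one-sided)
dt <- diversityTable(ds)
kerr <- dt$perLocus[dt$perLocus$site == "Kerr", ]
h15 <- kerr[kerr$year == 1915, ]; h05 <- kerr[kerr$year == 2005, ]
wilcoxonPairedByLocus(h15$Hexp, h05$Hexp, alternative = "greater")
#> exact signed-rank: statistic = 2.666, p = 0.001953 (greater, 9 blocks)

## ABC recovery of the decline parameters from the pooled epochs
sched <- sampleSchedule(nContemporary = 109, nHistorical = 60)
sc8 <- bottleneckScenarios()[[8]]        # 5000 -> U[200,1000] at t ~ U[10,80]
obs <- simulateDataset(c(Nanc = 5000, Ncur = 450, tbot = 67, offset = 90),
                       sched, nLoci = 9, seed = 2)
tab <- buildReferenceTable(list(sc8), 10000, sched, nLoci = 9, seed = 3)
abcFit(obs, tab, list(sc8), tolerance = 0.01, seed = 4)
#> PosteriorResult (100 accepted rows)
#>   scenario posterior probabilities:
#>     scenario 8   1.0000
#>   Ncur  median 413.9  (95% CI 207.8 - 789.4)
#>   tbot  median 59.36  (95% CI 29.73 - 80)

## temporal Ne from the simulated frequency change (moment estimator)
pair <- temporalPair(getSamples(obs, "historical")[[1]],
                     getSamples(obs, "contemporary")[[1]], T = 1, tGen = 90)
momentNe(pair)
#> NeEstimate (moment): Ne = 1021  [95% CI 655.2 - 1543.8]
```

The first block shows the synthetic bottleneck is detectable exactly as a
real decline would be (all nine loci lower in 2005, the minimum attainable
one-sided p of 1/2⁹). The ABC fit recovers the simulated truth — current
size 450 as a posterior median of 414 with a 208–789 credibility
interval, decline time 67 inside 30–80. The moment estimator integrates
drift over the whole 90-generation interval, most of which this
population spent at the large pre-decline size, so its single-realization
estimate (~1000, CI 655–1544) sits between the post-decline size and the
ancestral 5000 — a reminder that temporal estimators measure the
harmonic-mean size of the interval, not the endpoint.

The full analysis chain (diversity report, differentiation report, ABC,
temporal-*N*<sub>e</sub> report, with TSV + JSON outputs, a log, and one
master seed) runs from a YAML or list config via `runStudy()`.

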