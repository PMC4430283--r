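---
title: "Models and methods behind saltmigrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind saltmigrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltmigrate)
```

## The problem

saltmigrate analyses multilocus sequence surveys of species with very
little genetic variation — the situation typical of a recently founded,
disjunctly distributed plant such as a selfing salt cress sampled across
central Asia, northern China and North America. With a handful of
segregating sites spread over thousands of base pairs, the informative
signal lives in how the few variants are partitioned among geographic
groups, and inference has to be explicit about the demographic models it
compares. The package therefore combines descriptive statistics
(diversity, networks, AMOVA, clustering), classical neutrality and
expansion tests, and likelihood-free model choice over explicit
divergence-with-expansion scenarios, all driven by the same compiled
coalescent simulator.

The reference sampling design the synthetic-data generator emulates is 24
populations (99 haploid sequences; within-population variation absent),
10 unlinked nuclear loci totalling 6510 bp, and 9 chloroplast fragments
totalling 4379 bp of which only the 405-bp psbA-trnH spacer is
polymorphic. Three groups partition the populations: A (central Asia,
populations 17–18), B (northern China plus Buriatia, 1–16 and 20) and C
(North America plus Russia, 19 and 21–24).

## Data model and site handling

Sequences are haploid, one per individual per locus (the species is
self-compatible; individuals are effectively homozygous lines). Per-site
statistics (S, pi, theta) use complete deletion: any column containing a
gap or an `N` in any sequence is excluded, so only substitutions
contribute. For haplotype definition, network building and AMOVA
distances, each contiguous gap run and each annotated inversion block is
instead recoded as a *single mutational character*, the convention of
standard haplotyping software: a 7-bp inversion or a multi-base indel is
one evolutionary event, not seven. Both behaviours are selectable in
`collapse_haplotypes()`.

Synonymous/nonsynonymous partitioning uses Nei–Gojobori fractional site
counts on the consensus sequence. Single-base changes that create a stop
codon are counted as nonsynonymous, which keeps the fractional
synonymous + nonsynonymous site counts summing to exactly three per
codon (and hence to the number of analyzable coding sites). Annotation
uses 1-based inclusive coordinates.

## Diversity and neutrality statistics

`diversity_stats()` reports S, Watterson's theta (S divided by the
harmonic number and the analyzable length), nucleotide diversity pi
(mean pairwise proportion of differing sites), Nei's unbiased haplotype
diversity (with the n/(n−1) correction), and the Hudson–Kaplan minimum
number of recombination events Rm. For Rm, incompatible site pairs are
treated as closed intervals: pairs sharing a boundary site conflict, so
the overlapping pairs (1,2) and (2,3) imply a single event while (1,2)
and (3,4) imply two.

Neutrality tests are Tajima's D, Fu and Li's D\* and F\* (no-outgroup
versions, with the corrected variance constants in common use), Fay and
Wu's H (polarized against a designated outgroup; sites where the
outgroup carries a gap, ambiguity or third state are excluded and
logged) and Fu's Fs, computed from the Ewens sampling distribution via a
log-space Stirling-number recursion with theta estimated by the mean
number of pairwise differences. Null distributions condition on the
observed number of segregating sites (fixed-S mutation placement on
simulated constant-size genealogies), the convention of DnaSP; the
alternative of conditioning on theta would widen the nulls slightly but
is not what practitioners compare against. p-values are two-tailed for
D, D\* and F\* and lower-tailed for H and Fs, matching the directional
interpretation of those statistics (expansion and hitchhiking produce
large negative values).

## Median-joining networks

`median_joining()` implements the Bandelt median-joining construction
over the recoded characters: build the epsilon-relaxed minimum spanning
network, add the majority-consensus (median) vector of a connected triple
whenever it strictly shortens the spanning length, prune median vectors
that no longer shorten anything, and iterate to a fixed point. Epsilon
defaults to 0 (the usual program default); all characters, including
indel and inversion characters, default to weight 1. Ties in spanning
tree construction are broken by lexicographic node id so output is
reproducible. A guard aborts if more than ten times the observed number
of haplotypes in median vectors is generated.

## Admixture clustering and choosing K

`admixture_mcmc()` is a Gibbs sampler for the standard admixture model
on haploid multilocus data in which the "allele" at a locus is the
whole-locus haplotype id — the way sequence data are conventionally fed
to model-based clustering. Ancestry vectors have a symmetric
Dirichlet(alpha) prior with alpha updated by a Metropolis step under a
uniform prior on (0, 10]; allele frequencies have a symmetric
Dirichlet(lambda = 1) prior. The reported model score is the mean
post-burn-in log-likelihood minus half its variance, the usual evidence
proxy; at K = 1 the score is computed exactly as the multinomial
log-likelihood. Defaults (burn-in 5,000, 20,000 sweeps) are scaled for
interactive use and testing; production settings of 100,000/1,000,000
are reachable through the arguments. Replicate runs are combined by
greedy label matching of ancestry columns, and `evanno_delta_k()`
computes the second-difference statistic (undefined at the endpoints of
the K range, flagged infinite when the replicate standard deviation is
zero).

## AMOVA

`amova_three_level()` partitions squared pairwise distances (number of
differing characters, substitutions plus recoded indel/inversion
characters, concatenated across loci) among groups, among populations
within groups, and within populations, using the standard sums of
squares from pairwise distances and the method-of-moments expected mean
squares for unequal sample sizes. Permutation schemes follow the
standard design: individuals among populations for Phi_ST, individuals
among populations within their group for Phi_SC, and whole populations
among groups for Phi_CT. Negative variance components are reported
as-is with a warning. The tests verify the components against an
independent centroid-embedding computation (one-hot coding scaled so
squared Euclidean distance equals the difference count, with sums of
squares taken about centroids — Huygens' theorem makes the two routes
equivalent).

## Mismatch distributions and sudden expansion

The expected distribution of pairwise differences under an instantaneous
expansion from scaled size theta0 to theta1 at scaled time tau is
computed in closed form: the recent phase contributes a geometric
density damped by a regularized incomplete gamma, the ancient phase a
Poisson(tau)-convolved stationary geometric; the implementation works in
log space so extreme parameter values remain finite. Fitting minimizes
the sum of squared deviations between observed and expected relative
frequencies with Nelder–Mead over log-transformed parameters from four
starts; theta1 is capped at 99999 and fits at the cap are flagged. The
fitted class range extends five classes past the largest observed
difference. Significance uses a parametric bootstrap: samples are
re-simulated under the fitted model with the package's own coalescent
engine (a single deme with one size change, in mutation-scaled units),
refitted, and the p-value is the proportion of replicates with SSD at
least as large as observed; Harpending's raggedness is treated the same
way. The raggedness sum includes both boundary steps (from zero into the
first class and from the last class back to zero).

## The coalescent engine

`simulate_genealogies()` draws independent genealogies per locus under a
piecewise demography with deme splits (looking backwards: merges),
instantaneous size changes, admixture pulses and exponential growth.
Time is measured in years with a generation time of one year. Effective
sizes follow the theta = 4 Ne mu convention (pair coalescence rate
1/(2 Ne)), so the analytic checks E[T2] = 2 Ne and E[pi] = 4 Ne mu L
hold exactly; sequences themselves remain haploid. Mutations are laid
down under infinite sites (Poisson on branches, each hitting a fresh
position; a finite-length guard redraws if a locus would exceed its
length). The engine is validated three ways: closed-form expectations
(TMRCA, total length, S, pi, the 1/i site-frequency spectrum),
qualitative behaviour (star-like genealogies and negative Tajima's D
after a 100-fold expansion), and a frozen cross-check against an
independent coalescent simulator on three benchmark demographies whose
summary means are stored as a plain-text fixture.

## ABC model choice

Four migration scenarios are compared, all sharing a recent expansion of
group B from a small founder size `N_B0` at time `T_exp`: (1) A is the
source and the ancestor of (B, C) splits from it at T1 with B and C
separating at T2; (2) B is the source (A and C derived); (3) C is the
source (A and B derived); (4) A and C split at T1 and B is founded at T2
by admixture between them with proportion r from A. Summary statistics
are the standard one-sample set per group (number of haplotypes over
concatenated loci, segregating sites, mean pairwise differences) and the
two-sample pair statistics W (mean within-sample pairwise differences)
and B (mean between-sample pairwise differences), in a fixed ordering.

Priors, which the analysis must state because the data barely constrain
the sizes: log-uniform effective sizes on [1e2, 1e6] and uniform times
T1 on [1e3, 1e5] years, T2 on [5e2, T1], T_exp on [1e2, T2], admixture
proportion on [0.05, 0.95]. The mutation rate is fixed at 9.3e-9 per
site per year (the synonymous-rate calibration described below) rather
than drawn from a prior; a rate prior would mostly widen the time
posteriors.

Simulations mirror the sampling design of the observed data: because
within-population variation is absent, one lineage is simulated per
population and weighted by its number of sampled individuals. The
weighted summaries are identical to summaries computed on the copied
individual-level data, so observed and simulated vectors are exactly
comparable — and the trees are four times smaller.

Summaries are standardized by their simulation-table standard deviation
(zero-variance columns dropped with a warning) and compared by Euclidean
distance. The direct estimate is the scenario composition among the 400
closest simulations with a binomial confidence interval; the logistic
estimate fits a multinomial logistic regression (Epanechnikov-weighted)
over the closest 1% and evaluates it at the observed point, with a
delta-method interval. The winner is taken from the logistic estimate,
which is far sharper at moderate simulation counts — with 20,000
simulations per scenario, the direct composition over only 400
neighbours stays close to uniform even when the regression is
essentially certain. Parameters of the winning scenario are adjusted by
Beaumont local-linear regression (log scale for sizes and times,
identity for proportions; ridge fallback if the design is
rank-deficient). Model checking projects the observed vector and
posterior-predictive simulations into the PCA of the prior-predictive
summary table and flags observed points outside the 95% ellipse of the
posterior-predictive cloud on the first two components.

## Mutation-rate calibration and ITS dating

Per-locus rates follow the synonymous-rate calibration
mu = mu_CHS × (K_Total/K_S) × L with mu_CHS = 1.5e-8 synonymous
substitutions per site per year: K_Total is the Jukes–Cantor-corrected
total divergence to the outgroup over all analyzable sites, K_S the
corrected synonymous divergence from Nei–Gojobori counting (pathway
averaging over substitution orders within codons). ITS divergence times
use T = k/(2 mu L) — the factor two because substitutions accumulate on
both lineages after a split, which is the only reading consistent with a
single alignment length producing both the 240 and 480 kyr bounds at
rates 1e-8 and 5e-9. The ITS alignment length of 625 bp used in the
worked example is back-derived from those paired bounds and should be
treated as an assumption, not a measurement.

## The synthetic-data generator

`generate_study_like_dataset()` simulates the full design under scenario
1 at the point-estimate history: T1 = 23,000 years, T2 = 11,000 years,
expansion of B at 8,000 years, nuclear rate 9.3e-9 per site per year.
The effective sizes (A: 12,000; B: 60,000 after / 300 before the
expansion; C: 3,000; BC ancestor: 1,500) were chosen once so that the
emulated data reproduce the observed level of polymorphism — about 11
nuclear segregating sites over 6510 bp with most variation partitioned
between groups — and are the ground truth the acceptance experiments try
to recover. Calibration is enforced by redrawing (with the attempt count
logged): total nuclear S within [6, 18] and 5–8 chloroplast haplotypes
with polymorphism confined to psbA-trnH. Chloroplast fragments share one
genealogy (a single non-recombining molecule); all chloroplast mutation
is placed on the psbA-trnH spacer, which is hypervariable relative to
the conserved coding fragments, and the other eight fragments are
constant. One lineage is simulated per population and copied to each of
its individuals, mirroring the observed absence of within-population
variation.

What the generator does **not** emulate: base composition and codon
usage, sequencing error, missing data, indels and inversions (the
generated alignments are substitution-only; the indel/inversion recoding
path is exercised by hand-built fixtures in the tests), and any
within-population variation. Passing tests on these data therefore
demonstrate the correctness of the statistical machinery and the
recoverability of the simulated history, not robustness to alignment
artefacts in real data.

## Numerical choices and problem sizes

The test suite and the acceptance script are scaled for a single CPU:
20,000 coalescent simulations per scenario for ABC (one million is
config-reachable), 2,000–10,000 replicates for simulation nulls and
engine checks, bootstrap counts of 80–200 for mismatch p-values, and
clustering runs of a few thousand sweeps. The divergence-time recovery
experiment uses 20–50 seeded replicates; posterior medians of T1 and T2
then sit within a few tens of percent of the true 23 and 11 kyr, with
T1 mildly pulled upward by its wide uniform prior — visible, expected,
and well inside the stochastic tolerance of the experiment.

## Known limitations

Recombination within loci is not modelled (Rm is reported descriptively);
continuous migration is deliberately absent from the scenario set, which
contrasts divergence plus pulse admixture only; the logistic confidence
intervals are delta-method approximations and can be optimistic near
probability 0 or 1; and the three alternative scenarios are this
package's reconstruction of the natural source and admixture-origin
alternatives to the favoured history — other parameterizations of "B or
C is ancestral" are possible and would need their own simulation study.
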