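# saltmigrate

Phylogeographic inference for low-diversity, disjunctly distributed
plants from multilocus sequence data. The package covers the full
analysis arc of a modern intraspecific phylogeography study in one
place:

* **Diversity**: segregating sites *S*, Watterson's θ, nucleotide
  diversity π (total / nonsynonymous / silent via Nei–Gojobori site
  counting), Nei's haplotype diversity, Hudson–Kaplan *Rm*.
* **Neutrality**: Tajima's *D*, Fu & Li's *D\**/*F\**, Fay & Wu's *H*,
  Fu's *Fs*, with fixed-*S* coalescent null distributions.
* **Structure**: median-joining haplotype networks, a Gibbs-sampler
  admixture model (STRUCTURE-style) with Evanno ΔK, and three-level
  AMOVA (Φ statistics, permutation tests).
* **Demography**: mismatch distributions with sudden-expansion fits
  (τ, θ₀, θ₁, SSD, raggedness, parametric bootstrap), and approximate
  Bayesian computation (ABC) model choice over four explicit
  divergence-with-expansion migration scenarios, driven by a compiled
  multi-population coalescent simulator (splits, size changes,
  admixture pulses, growth; infinite-sites mutations).
* **Calibration**: per-locus mutation rates from synonymous-rate
  scaling (μ = μ_CHS · K_Total/K_S · L) and ITS divergence dating
  (T = k / 2μL).
* **Synthetic data**: a generator that emulates a 24-population /
  99-individual / 10-nuclear-locus / 9-chloroplast-fragment sampling
  design under a known divergence history, so the entire pipeline is
  testable end-to-end without any downloads.

The core ABC question the package is built around: given three
geographic groups A (central Asia), B (northern China + Buriatia) and C
(North America + Russia), which group is the source of the disjunction,
and when did the two divergences happen? Scenario 1 (A is the source;
the ancestor of B and C splits from A at time T1, B and C separate at
T2, and B then expands) is compared against source-B, source-C and
admixture-origin alternatives using haplotype counts, segregating
sites, and within/between-group pairwise differences as summary
statistics.

## Worked example

Generate a study-like dataset under the known history (T1 = 23 kyr,
T2 = 11 kyr, expansion of B at 8 kyr), then ask the ABC loop to
recover the history blind:

```r
library(saltmigrate)

ds <- generate_study_like_dataset(seed = 42)
ds
#> <multilocus_dataset> 19 loci, 99 individuals, 24 populations, 3 groups

diversity_stats(ds, genome = "nuclear") |> tail(2)
#>   locus    N    L     S  theta_t     pi_t ...   Nh    Hd   Rm
#> 1 Average 99  651   1.1 0.000322 0.000208 ...    2 0.114    0
#> 2 Aligned 99 6510  11   0.000327 0.000201 ...    6 0.431    0

amova_three_level(ds, genome = "nuclear", n_perms = 100, seed = 1) |> tidy()
#>   source                           df sum_sq sigma2 percent
#>   Among groups                      2  45.1   0.934   80.9
#>   Among populations within groups  21  19.0   0.220   19.1
#>   Within populations               75   0     0        0

res <- run_abc(compute_summaries(ds), abc_design(ds),
               n_sims = 20000, seed = 7)
res
#> <abc_result> winner: scenario 1
#>  scenario   method probability  lower  upper
#>         1 logistic       0.829  0.720  0.939
#>         2 logistic       0.004  0.000  0.010
#>         3 logistic       0.009  0.000  0.021
#>         4 logistic       0.158  0.052  0.263   (direct estimates omitted)

res$quantiles[res$quantiles$parameter %in% c("T1", "T2"), ]
#>   parameter lower median upper
#>   T1         3970  24353 75002
#>   T2          784   5488 25729
```

The logistic model choice identifies the generating scenario with
posterior probability 0.83, and the adjusted posterior median of the
older divergence time (24.4 kyr) lands next to the true 23 kyr; the
younger divergence (true 11 kyr) is recovered with more spread on a
single dataset, which is why the reproduction experiment below
aggregates over replicates. `plot_abc_probs(res)`,
`plot_mismatch(fit_sudden_expansion(mismatch_distribution(ds, group = "B")))`
and `plot_network(median_joining(collapse_haplotypes(ds$loci[["psbA-trnH"]])))`
draw the standard figures.

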