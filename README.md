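# pairdiv

Maximum-likelihood inference of speciation history from the distribution of
pairwise sequence differences in short genomic blocks, sampled **one haplotype
per species**.

## The problem

For many species pairs (the motivating case is *Drosophila*), public
whole-genome data provide only one usable haplotype per species. Even then,
the histogram of the number of nucleotide differences *S* across many short,
putatively neutral intronic blocks — the *S-distribution* — carries
information about how the two species diverged, because *S* in a block is
Poisson-distributed around the block's pairwise coalescence time, and the
distribution of coalescence times differs between divergence scenarios.

`pairdiv` fits and hierarchically compares four such scenarios:

| model | history | free parameters |
|---|---|---|
| SI  | strict isolation: split at `T0`, no gene flow | `θ, T0` |
| IM  | isolation with continuous symmetric migration `M` | `θ, T0, M` |
| IIM | migration from the split until it ceases at `T1` | `θ, T0, T1, M` |
| SC  | allopatric divergence plus one bidirectional admixture pulse of fraction `f` at `T1` | `θ, T0, T1, f` |

Conventions: time is measured in units of `2·Ne` generations; `θ = 4·Ne·μ`
per block; `M = 4·Ne·m` migrants per generation; a single `Ne` is shared by
the ancestor and both daughter species. Conditional on coalescence at time
`t`, `S ~ Poisson(θ·t)`.

The log-likelihood of an S-distribution with class counts `n_k` is

```
ln L(θ, T0, T1, M, f | n) = Σ_k n_k · ln P[S = k]
```

where `P[S = k]` is computed exactly from a piecewise-exponential
decomposition of each model's coalescence-time density. Heterozygous sites in
a block are handled by binomial phasing (a block with `d` fixed differences
and `h` heterozygous sites contributes `Binomial(h, 1/2)` weights to classes
`S = d, …, d + h`). Model choice uses likelihood-ratio tests at the
chi-square thresholds 3.841 (1 d.f.) and 5.99 (2 d.f.), always preferring
the most parsimonious adequately supported model, and estimates of continuous
and pulsed gene flow are made comparable through the per-lineage gene-flow
probability `1 − exp(−T0·M/2)`.

## Worked example

Simulate 5,000 blocks under isolation-with-migration and run the full
per-pair pipeline (fit all four models, select, convert to natural units):

```r
library(pairdiv)

blocks <- simulate_blocks(sim_config("IM",
  model_params(theta = 1.5, T0 = 1, M = 0.5),
  n_blocks = 5000, seed = 42))

res <- run_pair(blocks, pair_id = "example", normalize_total = NULL, seed = 1)

res$selection
#>   pair_id best_model two_delta_si_im two_delta_si_sc two_delta_im_sc two_delta_im_iim nonidentifiable tie
#> 1 example IM                    23.8            23.6               0          0.0223  FALSE           FALSE

tidy(res$fits$IM)
#>   term  estimate at_boundary
#> 1 theta    1.43  FALSE
#> 2 T0       1.22  FALSE
#> 3 M        0.657 FALSE

res$derived
#>   pair_id       Ne   T0_gen  p_geneflow   (CI columns omitted)
#> 1 example 1079919. 2643490.      0.331
```

The selection row says migration is strongly supported over strict isolation
(`2ΔlnL = 23.8 > 3.841`) while the extra secondary-contact parameter is not
(`2ΔlnL = 0` over IM), so IM is chosen. The IM estimates sit near the
simulated truth `(1.5, 1, 0.5)`. With the default mutation-rate model
(`μ = 3.32e-9` per base and generation, 100-bp blocks) the fitted `θ`
corresponds to an ancestral `Ne` of about 1.1 million, a divergence time of
about 2.6 million generations, and a 33% probability that a random lineage's
ancestry was affected by migration.

`autoplot(sdist, fits = ...)` overlays fitted pmfs on the S-distribution,
`plot_model_support()` draws the model-selection plane for many pairs, and
`compare_groups()` contrasts fitted quantities between sympatric and
allopatric pairs (Wilcoxon rank-sum / Fisher exact).

A thin command-line wrapper with `fit`, `simulate`, `power` and `compare`
subcommands is installed at
`system.file("cli", "pairdiv.R", package = "pairdiv")`.

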