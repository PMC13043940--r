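---
title: "Divergence models for pairwise differences in short blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence models for pairwise differences in short blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pairdiv` infers the demographic history of a species pair from the
distribution of pairwise sequence differences (*S*) in short, putatively
neutral blocks, using a single haplotype per species. This vignette is the
package's own account of the model, the numerical choices behind it, and
what the simulation-based tests do and do not establish.

## The model

For two haplotypes sampled one per species, each block has a pairwise
coalescence time $T$ (in units of $2N_e$ generations), and the number of
differences in the block is $S \mid T = t \sim \mathrm{Poisson}(\theta t)$
with $\theta = 4 N_e \mu_\text{block}$. A single $N_e$ is shared by the
ancestral population and both daughter species. Four histories determine the
law of $T$, looking backwards in time from the present:

* **SI (strict isolation).** The lineages sit in separate species until the
  split at $T_0$, then coalesce at rate 1 in the panmictic ancestor:
  $T = T_0 + \mathrm{Exp}(1)$.
* **IM (isolation with migration).** Before $T_0$ the pair follows the
  structured coalescent with two demes and symmetric scaled migration
  $M = 4 N_e m$: from *apart*, one lineage joins the other's deme at total
  rate $M$; from *together*, the pair separates again at rate $M$ or
  coalesces at rate 1. Any pair still uncoalesced at $T_0$ coalesces
  panmictically.
* **IIM (isolation with initial migration).** Gene flow operates from the
  split until it ceases at $T_1 < T_0$; on $(0, T_1)$ the lineages are
  strictly separate, so the law of $T$ is the IM law time-shifted by $T_1$.
* **SC (secondary-contact pulse).** Divergence is allopatric except for one
  instantaneous bidirectional pulse at $T_1$ in which a fraction $f$ of each
  population is introgressed. We model the pulse at lineage level: each
  sampled lineage independently switches demes with probability $f$, so the
  pair is brought into one deme — and can coalesce on $(T_1, T_0)$ — with
  probability $2f(1-f)$. This is the simplest single-parameter bidirectional
  pulse consistent with a "total proportion $f$ introgressed"; the package
  exposes both `f` (per-lineage) and `2f(1-f)` (per-pair) conversions in
  `sc_gene_flow_probability()` so users preferring the other convention can
  use it.

All four laws have the same backbone: a (possibly empty) set of exponential
density pieces on $(0, T_0)$ plus a residual mass $w$ that coalesces as
$T_0 + \mathrm{Exp}(1)$. `pairdiv` computes $P[S = k]$ exactly from this
decomposition: each exponential piece contributes a regularised
incomplete-gamma integral (evaluated in log space for stability at large
rates), and the panmictic tail contributes a
Poisson($\theta T_0$) $\ast$ geometric($\tfrac{\theta}{1+\theta}$)
convolution, computed by an exact linear recursion rather than FFT so that
the nested-model reduction identities (IM$\to$SI at $M=0$, IIM$\to$IM at
$T_1 = 0$, IIM$\to$SI at $T_1 = T_0$, SC$\to$SI at $f \in \{0, 1\}$) hold to
machine precision. For the IM/IIM pre-$T_0$ phase the $2\times 2$ transient
generator is eigendecomposed in closed form
($\lambda = (-(2M{+}1) \pm \sqrt{4M^2+1})/2$). Correctness is defined by
agreement with Monte-Carlo simulation of each model's coalescent process,
not by transcription of any particular published formula; the test suite
checks total-variation distance below 0.005 against $10^6$ draws per
parameter point, and the exact mean identity $E[S] = \theta(T_0 + 1)$ under
SI.

Degenerate corners are valid inputs with exact limits: $\theta = 0$ puts all
mass on $S = 0$; $T_0 = 0$ makes every model the panmictic geometric law.

### Truncation policy

The pmf is computed to `kmax`, by default the larger of 40 and the smallest
$k$ with cumulative mass above $1 - 10^{-10}$. When a caller fixes `kmax`,
residual tail mass above `tail_tol` (default $10^{-6}$) raises an error
rather than silently renormalising — short intronic blocks keep observed $S$
small, so in practice the default cap is generous.

## From block counts to likelihood

Each block record carries the count of fixed inter-specific differences $d$
and of heterozygous sites $h$. Heterozygous sites are phased binomially:
weight $\binom{h}{j} 2^{-h}$ goes to class $S = d + j$. Sites heterozygous
in both samples cannot be distinguished in this tabular input; each
heterozygous site is counted once in $h$ and phased by the same rule (a
genotype-level input would be required to do better). Class weights are
therefore fractional, and every likelihood in the package accepts fractional
weights. The binomial weights are computed as $\binom{h}{j}/2^h$, which is
exact in binary floating point for realistic $h$.

The blockwise log-likelihood is $\sum_k n_k \ln P[S=k]$. Two switches
mirror how the method is used on real data:

* **Cross-pair normalisation** (`normalize_total = 500`): rescaling each
  pair's S-distribution to a common total weight makes $\Delta \ln L$
  magnitudes comparable across pairs with different block counts. Because it
  also rescales the LRT statistics, normalisation is a flag, not hard-wired;
  calibration experiments in this package fit raw counts so that the
  chi-square reference distribution applies to the actual sample size.
* **Conditioning** (`conditioned = TRUE`): maximising
  $\sum_{k \ge 1} n_k \ln \frac{P[S=k]}{1 - P[S=0]}$ drops the monomorphic
  class, a robustness check for data in which the frequency of monomorphic
  blocks is unreliable (incomplete intron annotation, lab-culture
  contamination). On data with no monomorphic blocks the conditioned and
  full likelihoods differ by the constant $\sum n_k \ln(1 - P[S=0])$, which
  the tests verify.

## Fitting and model selection

`fit_model()` maximises the likelihood with bounded L-BFGS-B from multiple
Latin-hypercube starting points ($\theta$ and $T_0$ on log scale, $T_1$
reparameterised as a fraction of $T_0$, default 8 starts, deterministic
given a seed). Default bounds are $\theta \in [10^{-4}, 50]$,
$T_0 \in [10^{-4}, 20]$, $M \in [0, 10]$, $f \in [0, 1]$: wide enough to
bracket *Drosophila*-plausible values, with the migration ceiling encoding
the identifiability limit of pairwise-difference data — long-term gene flow
at $M \ge 10$ is indistinguishable from panmixia. `fit_all_models()` feeds
each nested optimum in as an extra start for the richer models, so fitted
log-likelihoods respect the nesting hierarchy up to numerical tolerance.
Estimates within relative tolerance $10^{-3}$ of a bound are flagged
`at_boundary`; fits with $\hat M$ or $\hat T_0$ at a bound, or
$\hat M \ge 10$, are flagged non-identifiable and excluded from group-level
parameter summaries (the flag changes group membership only, never a fit).
Correctness of the optimiser is defined against a coarse grid scan of the
likelihood surface, not against a specific algorithm.

`select_best()` implements the hierarchical rules: SI is kept unless IM
beats it at the 1-d.f. threshold (3.841) or SC beats it at the 2-d.f.
threshold (5.99); SC replaces IM only when its extra parameter is justified
at 3.841; IIM is tested against IM at 1 d.f. and compared with SC by raw
log-likelihood since they have equally many parameters. In the corner where
only the SC-vs-SI test is significant and SC does not beat IM by 3.841, SC
is still returned — the direct 2-d.f. test is then the only significant
evidence and it favours SC. Ties at exactly a threshold resolve to the
simpler model ("minimally complex"). Testing $M = 0$ places the null on the
boundary of the parameter space, so the plain $\chi^2_1$ threshold is
conservative; we keep the plain threshold deliberately and measure the
realised false-positive rate by simulation (it comes out near 2–3%, below
the nominal 5%).

## Natural units

With a mutation model ($\mu = 3.32 \times 10^{-9}$ per base and generation,
95% CI $2.52$–$4.30 \times 10^{-9}$, and the block length),
`to_natural_units()` maps $\hat\theta$ to
$N_e = \theta / (4 \mu L)$, $T_0$ to generations via $2 N_e$, and gene flow
to the per-lineage probability $1 - e^{-T_0 M / 2}$ (IM), using the
migration-epoch duration $T_0 - T_1$ for IIM, $f$ for SC, and 0 for SI.
Low/high variants are evaluated at the CI endpoints of $\mu$; larger $\mu$
gives smaller $N_e$, so orderings are exact by construction. Conversion to
years is out of scope — results stay in generations.

## What the simulator emulates

`simulate_blocks()` generates exactly the structure the likelihood assumes:
independent non-recombining blocks, one coalescence time each, Poisson
mutations, optional heterozygous sites at a within-species rate
`theta_within` shared by both species (consistent with the single-$N_e$
assumption), all differences emitted as fixed ($d = S$). Under these
conditions the phased S-distribution follows the model pmf convolved with
Poisson(`theta_within`/2), which the tests verify. Defaults follow the
study conditions the package targets: 100-bp blocks,
$\mu = 3.32\times10^{-9}$, and $r = 1.03$ cM/Mb $= 1.03\times10^{-8}$
crossovers per base per generation where recombination is enabled.

`simulate_si_recomb()` relaxes the one-tree-per-block assumption for the
strict-isolation null only, via a two-sample ancestral-recombination
simulation: crossovers (scaled rate $\rho = 4 N_e r L$, with $N_e$ recovered
from $\theta$, $\mu$ and $L$) split ancestral material into segments with
correlated marginal coalescence times; before $T_0$ segments can only
re-coalesce within their own species. Recombination leaves $E[S]$ unchanged
but shrinks $\mathrm{Var}(S)$ — at $\theta = 2$, $T_0 = 1$ the simulated
variance drops from the analytic 8 to about 5.3 — which is precisely the
distortion that can masquerade as gene flow when blocks are assumed
non-recombining. `power_analysis()` quantifies this: it simulates replicate
null datasets, fits SI and IM, and reports how often $2\Delta\ln L$ exceeds
a threshold. Recombination under the gene-flow models is out of scope.

What passing these tests does **not** show: real intronic blocks violate the
generator's assumptions in ways it does not emulate — selective constraint
varying across introns, mutation-rate heterogeneity among blocks, ghost
admixture from unsampled taxa, non-equilibrium population sizes, and
block-length differences between species. Conclusions about real data rest
on the robustness analyses (conditioning, the recombination null), not on
the recovery results alone.

## Problem sizes used in the checks

The package's own validation uses: $10^6$ Monte-Carlo draws per parameter
point (three points per model) for distributional agreement; 100 replicates
of 5,000 blocks for IM parameter recovery (median relative bias below 10%
per parameter, and the derived gene-flow probability within 0.05 of truth);
200 replicates of 5,000 blocks for the null false-positive rate of the
SI-vs-IM test; and a deliberately small configurable grid for the
recombination power analysis, since the original per-pair experiment
depends on maximum-likelihood estimates from the real WGS-derived block
tables. For the same reason, the headline tallies from the real 93-pair
dataset (best-model counts, mean gene-flow probabilities, printed rank-sum
and exact-test statistics, and the 25% maximum false-positive rate under
per-pair estimates) are not reproducible here and are not asserted anywhere
in the package; the property-based checks above are what stands in for
them.

## Known limitations

* Symmetric migration and a single shared $N_e$; no asymmetry, size
  changes, or per-block $\theta$ heterogeneity.
* No confidence intervals or profile likelihoods on fitted parameters.
* The SC pulse convention (per-lineage relocation probability $f$) is one
  of several readings of a "total proportion introgressed"; the per-pair
  quantity $2f(1-f)$ is exposed for users who prefer it.
* The Wilcoxon statistic's value depends on rank-sum convention;
  `compare_groups()` reports both the Mann-Whitney $W$ and the raw rank
  sum, and applies no multiple-testing correction across contrasts.
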