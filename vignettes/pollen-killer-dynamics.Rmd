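---
title: "Pollen-killer dynamics under selfing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pollen-killer dynamics under selfing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollendrive)
```

## The model

`pollendrive` models a genic segregation distorter of the toxin–antidote
type in a hermaphroditic plant. Two linked loci carry alleles A/a and
B/b; pollen bearing the *a* allele is destroyed with probability `k`
whenever the plant producing it also carries a *b* allele. The four
haplotypes AB, Ab, aB, ab act as neutral, killer, sensitive and suicide
respectively, and the state of the population is the frequency vector
$\theta$ over the ten diploid genotypes, with the two phases of the
double heterozygote (`AB|ab` vs `Ab|aB`) kept distinct because they
produce different gametes.

One generation consists of:

1. **Meiosis.** For genotype $h_1|h_2$, mass $(1-r)/2$ goes on each
   parental haplotype and $r/2$ on each recombinant; masses on identical
   haplotypes accumulate. This is the female gamete matrix $G^f$
   (rows sum to 1).
2. **Pollen killing.** $G^m$ equals $G^f$ with every *a*-bearing column
   (aB, ab) multiplied by $1-k$ in rows whose genotype carries at least
   one *b* allele. Row sums below 1 are pollen lost to killing.
3. **Pollen pool.** Cross-pollination pollen has haplotype frequencies
   $f = G^{m\top}\theta$, normalized. The pool's size `M_pool` is a
   constant of the model: killing inside one plant does not deplete the
   pool available to others.
4. **Fertilization.** A flower of genotype $i$ has pollen
   $N_i = M_\mathrm{pool} + M_\mathrm{self}\,\mathrm{rowsum}(G^m_i)$
   and fertility $\phi_i = \min(1, N_i R / (M_\mathrm{pool} +
   M_\mathrm{self}))$, linear below the redundancy threshold and 1 above
   it. Offspring pair a female gamete from $G^f_i$ with pollen drawn
   from the flower's own surviving pollen (weight $M_\mathrm{self}$)
   plus the pool (weight $M_\mathrm{pool}$), normalized by $N_i$.
5. **Renormalization.** The next generation is
   $\theta'_j \propto \sum_i \theta_i \phi_i p_{ij}$. The
   fertility-weighted masses sum to the mean fitness (< 1 under
   killing); dividing by that sum keeps $\theta$ a probability vector,
   which is what frequencies are. Entries are clipped to $[0,1]$ with
   tolerance $10^{-12}$; the sum is restored to 1 within $10^{-9}$ after
   every step.

Only the ratio of self to pool pollen matters, so the supply scale is
fixed at $M_\mathrm{self} + M_\mathrm{pool} = 1$ with
$M_\mathrm{self} = s$: the selfing rate is exactly
$M_\mathrm{self}/(M_\mathrm{self}+M_\mathrm{pool})$.

### Parameters

| parameter | meaning | range | default |
|---|---|---|---|
| `r` | recombination rate between toxin and antidote loci | [0, 0.5] | 0 |
| `s` | selfing rate (probability a flower is fertilized by own-plant pollen) | [0, 1] | 0 |
| `k` | killing efficiency on *a*-bearing pollen in *b*-carrying plants | [0, 1] | 1 |
| `R` | pollen redundancy: pollen delivered / pollen needed | ≥ 1 | 10 |

`k = 1` throughout the canonical experiments; with `k = 1` the suicide
haplotype can never be transmitted through pollen it kills itself in,
so it only persists transiently through female gametes. Both `s = 0`
and `s = 1` are admitted exactly; near-complete outcrossing is modelled
by passing small literal values such as `1e-5`, not by a special case.

### Stop rules and equilibrium states

Long-run iteration (`sd_iterate()`) stops when the killer (Ab) or
sensitive (aB) haplotype frequency falls below a threshold, or after
`max_generations` (default 10,000). Two published conventions for the
threshold exist side by side — an absolute cutoff of 0.001 and a
relative cutoff of 1% of the haplotype's initial frequency — and they
differ, so both are implemented (`stop_rule("absolute")`, the default,
and `stop_rule("relative")`); neither is guessed to be canonical.
`stop_rule("none")` runs a fixed horizon, used by the fixed-horizon
spread criterion below.

Terminal populations are classified by which haplotypes exceed a
presence threshold (default $10^{-3}$) into the five possible
equilibria — killer fixed, sensitive fixed, neutral fixed,
neutral+sensitive, neutral+killer — or `"unresolved"` otherwise.
Killer–sensitive coexistence is not an equilibrium of the model: every
Ab × aB fusion lowers the frequency of allele *a* relative to *A*, and
no mating compensates, so it is never reported as one. A low-frequency
suicide haplotype still present at termination is folded into
`"unresolved"` rather than given its own label.

**The `s = 1` boundary.** Under complete selfing an invasion population
(killer and sensitive homozygotes only) never forms a heterozygote: no
cross-pollination, no killing expressed, and the configuration is frozen
with both haplotypes present. This is a degenerate boundary equilibrium
outside the coexistence argument above, which requires Ab × aB fusions.
Parameter sweeps therefore use selfing grids up to 0.95, and the
selfing-threshold search verifies its upper bracket and steps down from
`s = 1` on a 0.005 grid when the boundary itself does not qualify.

## Numerical experiments

* `invasion_fate()` / `sd_sweep()`: killer homozygotes at `f0` invade
  sensitive homozygotes at `1 - f0`; the fate is `eliminated` (final
  killer below the presence threshold), else `increased` / `decreased`
  by comparing final with initial frequency (ties, which arise only at
  frozen boundary states, count as decreased).
* `min_invasion_frequency()`: smallest `f0` whose killer frequency after
  a 100-generation horizon exceeds `f0`, by bisection on (0, 1) to
  $10^{-4}$; sentinel 1 when even `f0` near 1 fails.
* `find_recombination_threshold()` / `find_selfing_threshold()`:
  bisection (tolerance $10^{-3}$) for the boundary of the `increased`
  region, brackets verified at both ends. Two spread criteria are
  exposed: the terminal-state rule of the fate grids (default) and the
  100-generation horizon rule of the minimum-frequency maps; they can
  disagree slightly near the boundary, so the choice is explicit.
* `mutation_origin_trajectory()`: a one-shot origin of the killer at
  `intro_freq` (default $10^{-3}$) in a neutral+sensitive background; no
  recurrent mutation. Reports the maximum killer frequency attained,
  which under full linkage is capped by the initial non-neutral share.

Bisection assumes the fate is monotone in the search variable, which
holds across the tested grids; brackets are always verified, and the
grid fallback (step 0.005) covers a failed bracket.

## Introgression statistics

`f4_statistic()` is the mean over sites of
$(p_A-p_B)(p_C-p_D)$; it is exactly antisymmetric in each pair and has
expectation 0 when the four populations are related by the unrooted tree
[(A,B),(C,D)]. `f4_scan()` enumerates every 4-population subset,
arranges it tree-consistently (the cherry of the restricted subtree in
front; unresolved restrictions are skipped with a warning), and takes
the **maximum |f4|** as the region's introgression indicator — absolute
value, because departure from 0 in either direction is evidence; the
signed value at the maximum is reported alongside. Tree-inconsistent
arrangements (whose expectation is nonzero under the tree itself) are
not enumerated.

Percentile p-values use the add-one empirical rule
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n)$, which avoids
$p = 0$ and is monotone non-increasing in the observation. Fisher's
combined test is $X^2 = -2\sum\log p \sim \chi^2(2m)$. The null
distribution of the indicator is supplied by the user (one value per
region) or generated synthetically; deriving it from real genomes is
out of scope.

## Synthetic generators

`simulate_wright_fisher()` is the finite-population counterpart of the
recursion: each of `N` offspring samples a maternal flower with
probability proportional to empirical genotype frequency × fertility
(soft selection — the fertility weight reallocates, rather than
destroys, reproductive opportunity), then a genotype from that flower's
offspring distribution. Its conditional per-generation expectation is
exactly the deterministic map, so at large `N` the replicate mean
converges on `sd_iterate()`; the suite verifies this at `N = 10,000`.
Note two structural facts about that comparison: the replicate mean
carries an $O(1/N)$ Jensen bias (the map is nonlinear), which at
`N = 10,000` sits well inside 3 Monte-Carlo standard errors of 200
replicates; and at absorbing states every replicate fixes exactly while
the recursion only approaches fixation, so the standard error collapses
to 0 — the convergence test therefore adds a $10^{-5}$ absolute guard,
two orders below the loss threshold, which is inert away from absorbing
states.

`simulate_species_alleles()` evolves each site's allele frequency down a
species tree by independent zero-mean Gaussian increments with standard
deviation `intensity * sqrt(branch length)`, truncated to [0, 1], from a
root frequency of 0.5. Shared drift cancels, so tree-consistent
quadruplets satisfy the f4 null by construction — the simplest process
with that property, chosen over a coalescent deliberately: no linkage,
no mutation model, no sample-size noise. Truncation biases extreme
sites, so the default intensity (0.05 per unit branch) keeps tip
standard deviations near 0.12 on the default seven-taxon unit-branch
ladder tree; at that setting fewer than $10^{-4}$ of simulated values
touch the bounds and the null holds within Monte-Carlo error, which the
suite verifies rather than assumes. What this generator does *not*
emulate: linked sites, ascertainment, finite sample sizes per
population, gene flow other than the single donor→recipient
replacement event — so passing tests show the statistics behave
correctly on clean tree-like data, not that real-data complications are
handled.

`write_fixtures()` freezes a seeded fixture set (frequency TSV,
per-population FASTA alignments that re-parse to exactly the TSV, a
Newick tree, null indicator values, an md5 manifest); file names carry a
`synthetic_` prefix because they are simulated, not real, data.

## Testing design notes

* **Neutrality.** With `k = 0` there is no selection, and the exact
  invariants are the two *allele* frequencies, for any `r`, `s`, `R`;
  haplotype frequencies are additionally invariant only under full
  linkage (`r = 0`). With `r > 0` and linkage disequilibrium,
  recombination relaxes haplotypes toward linkage equilibrium at
  constant allele frequencies — that relaxation is real dynamics (it is
  how the neutral haplotype arises from killer × sensitive matings),
  not a defect, and the suite tests the invariants in that form.
* **Coexistence.** The fate grids (20 recombination × 20 selfing values
  at each `R` ∈ {1, 1.5, 10} and `f0` ∈ {0.001, 0.1, 0.5}) are checked
  for killer–sensitive coexistence at termination. A handful of corner
  cells (high `r`, high `s`) are still in slow transit when the
  10,000-generation cap fires; because the claim concerns equilibrium,
  such cells are iterated on (up to $2\times10^6$ generations) until
  the loss threshold resolves them. They do resolve — the cap is an
  upper bound on patience, not a feature of the dynamics.
* **Simultaneous f4 checks.** The null test compares 35 quadruplet
  means against 0 at once; the familywise threshold is
  Bonferroni-adjusted (|z| < 3.97 for 35 tests at the marginal level of
  a single 3-SE check) so the family has the same false-alarm rate as
  one comparison.
* **Problem sizes.** The suite runs the full 3 × 3 grid battery, the
  `N = 10,000` × 200-replicate convergence check, 200 × 1,000-site f4
  null replicates, 50 detection replicates, and a 10,000-replicate
  calibration of Fisher's method, in under a minute of compute in
  total; the compiled recursion core makes a 10,000-generation run cost
  roughly a millisecond.

## Limitations

* `r`, `s`, `R` are fixed parameters, not evolvable modifier loci.
* Pollen killing only: no female-gamete killers, no viability selection
  on diploids, exactly two loci.
* The fertility function is piecewise linear in pollen number; other
  saturating forms would change quantitative thresholds but not the
  qualitative structure.
* The Wright–Fisher generator is one reasonable stochastic counterpart
  of the deterministic model (soft selection, non-overlapping
  generations), used as a convergence oracle rather than as a claim
  about any particular species' demography.
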