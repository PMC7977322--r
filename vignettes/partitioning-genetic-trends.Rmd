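---
title: "Partitioning genetic trends by selection path: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning genetic trends by selection path: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedpart)
```

## The model

An individual's additive genetic merit decomposes as

$$ a_i = \tfrac{1}{2} a_s + \tfrac{1}{2} a_d + w_i, $$

where $a_s$ and $a_d$ are the parents' breeding values and $w_i$ the
Mendelian sampling term — the deviation created by recombination and
segregation of parental genomes. In matrix form $\mathbf{a} =
\mathbf{T}\mathbf{w}$, with $\mathbf{T} = (\mathbf{I}-\mathbf{P})^{-1}$
the lower-triangular gene-flow matrix and $\mathbf{P}$ holding the
expected parental contributions. Assigning each individual a *selection
path* label splits $\mathbf{T}$ by columns, $\mathbf{T} = \sum_p
\mathbf{T}_p$, and hence

$$ \mathbf{a} = \sum_p \mathbf{T}_p \mathbf{w} = \sum_p \mathbf{a}_p, $$

an exact additive decomposition of breeding values (and of genetic
trends, their group means) into per-path contributions. Interpretation
rests on the usual assumptions of pedigree-based quantitative genetics:
additive inheritance, correct pedigree links, and breeding values
expressed relative to a meaningful base population.

`partition()` implements the decomposition as a single pedigree
recursion from oldest to youngest (in C++ via Rcpp): each individual
inherits half of each parent's partition vector and adds its own $w_i$
to the component of its own path. Founders get $pa = 0$ and $w = a$, so
their whole value is credited to their own path. The package fixes two
conventions the decomposition itself leaves open:

* **Unknown parents contribute 0** to the parent average. The missing
  half is then absorbed into $w_i$ and credited to the individual's own
  path — continuous with the founder rule, and consistent with a base
  population of mean zero after rebasing or standardisation.
* **Founders' parent average is 0**, not missing, so `pa + w = bv`
  holds for every record without special cases.

In maternal-grandsire pedigrees (`"sire-mgs"`), the expected
contributions are $\tfrac12$ (sire) and $\tfrac14$ (maternal
grandsire); the remaining half-plus-quarter again flows into the
individual's own term. These are the standard expectation coefficients
for that pedigree structure.

Multiple trait columns are carried through one pass but partitioned
independently — numerically identical to per-trait passes. Columns of
posterior samples of breeding values can be partitioned the same way to
propagate estimation uncertainty; no further uncertainty machinery is
provided.

`partition_matrix_oracle()` computes the identical quantities through
sparse linear algebra — $\mathbf{w} = (\mathbf{I}-\mathbf{P})\mathbf{a}$
and one triangular solve $(\mathbf{I}-\mathbf{P})\mathbf{a}_p =
\mathbf{w}_p$ per path — and exists purely as an independent
cross-check of the recursion (the test suite requires agreement below
$10^{-9}$ on random pedigrees in both parental modes). It is guarded at
20{,}000 individuals; the dense `gene_flow_matrix()` accessor, meant
for inspection of small pedigrees, at 5{,}000.

Setting every breeding value to 1 (`long_term_contributions()`) turns
the machinery into trait-agnostic long-term genetic contributions: each
row is a set of non-negative path fractions summing to one.

## Pedigree preparation

`validate_and_sort()` orders records canonically by (generation depth,
time, id), where depth is the longest known-ancestor chain. Depth
guarantees parents precede offspring regardless of recorded times
(which may be wrong or missing before repair); time and id break ties
deterministically, so the order is invariant to input row permutation.
Cycles are reported with the member ids.

`fix_birth_years()` imputes missing times using the generation interval
`interval` (in time units, default direction `down = FALSE`): a
parent's missing time becomes (time of its oldest offspring) −
`interval`; with `down = TRUE` an offspring's missing time becomes
(time of its youngest parent) + `interval`. Subtraction for parents is
deliberate — parents must be older than their offspring — and passes
repeat until a fixed point, so chains impute transitively. Existing
times are never altered and no parent/offspring consistency is
enforced; `check_time_consistency()` reports violations separately.
Times are integers; fractional years are rejected because the method
only ever groups by time.

`set_base()` rebases the pedigree by a logical mask: dropped records
disappear *including their role as parents*, so survivors with dropped
parents become founders of the analysis and their whole (ideally
standardised) breeding value is credited to their own path. Proper base
choice matters: contributions are always relative to the base
generation. Unknown parents may be written as `""`, `"0"` or `NA` in
input files; all normalise to one internal sentinel.

## Summaries, manipulation, plotting

`summarize_partition()` aggregates the breeding value (`Sum`) and every
path column by a grouping variable, default `mean`, giving genetic and
partial genetic trends; groups are ordered ascending (numerically when
the key parses as a number, otherwise lexicographically in the C
locale). A logical `subset` restricts records *before* `N` is counted,
so `N` reports the records actually summarised. Any scalar-valued
aggregation function is accepted; for non-mean functions the identity
"`Sum` equals the sum of path columns" need not hold and is documented
rather than enforced. `partition_and_summarize()` produces the same
mean summaries in one pass without materialising per-individual
partition columns (group totals are accumulated in extended precision;
the test suite requires agreement with the two-step route below
$10^{-12}$).

`subset_paths()` keeps named partition columns and flags the result as
partial (totals are deliberately untouched); `combine_paths()` sums
constituent paths into new ones, preserving the total exactly, with a
singleton mapping acting as a rename. Combining and mean-summarising
commute.

`plot()` on a summary draws, per trait, the overall trend (black) plus
one line per path. Output files (PNG via cairo, SVG) are rendered
headlessly; aesthetics are package conventions, not a fidelity target.

## The simulators

The simulators exist so that every operation is testable against known
truth without external data. All are deterministic given `seed` and
restore the caller's RNG state.

`generate_random_pedigree()` draws arbitrary acyclic pedigrees under
the single-trait infinitesimal model: founders $\sim N(0, \sigma^2_a)$,
non-founders $a = \tfrac12 a_s + \tfrac12 a_d + w$, $w \sim N(0,
\sigma^2_a/2)$ (non-inbred-parent value), independent traits, random
path labels, and a small rate of unknown parents to exercise the
missing-link rules.

`simulate_import_example()` emulates a small population (Population 1)
importing genetic material from two superior populations. Defaults,
chosen once as a realistic desk scale: 20 generations × 200 progeny per
population; male selection on own-population phenotype with
heritability 0.7 (Population 1) versus 0.9 (Populations 2 and 3);
8/8/5 sires selected — the smaller Population 3 sire count standing in
for its higher selection intensity (2.89 vs 2.67 at full scale);
genetic correlations of Population 1's recorded trait with the traits
under selection abroad of 0.9 and 0.8 (genotype-by-environment
interaction), with the cross-correlation of the foreign traits set to
their product (a single-common-factor structure, guaranteeing a valid
covariance matrix); from generation 11 each Population 1 offspring has
a Population 2 or Population 3 sire with probability 0.1 each. Breeding
values follow the trivariate infinitesimal model with Mendelian
covariance $\mathbf{G}/2$.

`simulate_multitier()` emulates a stylised two-tier pig/poultry
programme: a closed nucleus (selection on an equal-weight two-trait
index) feeding a multiplier. Trait 1 ($h^2 = 0.25$) is recorded in both
tiers, trait 2 ($h^2 = 0.10$) only in the nucleus. Default sizes are a
1/10 desk scale — nucleus 10 males / 100 females / 600 progeny,
multiplier 150 females / 900 progeny, 40 multiplier males under the
20%-male-flow scenario, 500 seed females, 5 burn-in + 10 evaluation
generations — with the full published sizes available via
`paper_scale = TRUE`. Burn-in selects on a phenotype index; evaluation
selects on an index of estimated breeding values refreshed before every
decision by the package's own animal-model solver, fitted to all
phenotypes from the base generation (the last burn-in generation, when
the multiplier is seeded with nucleus-born females) onward. The
`maleflow100` scenario sires all multiplier progeny with the selected
nucleus males; `maleflow20` mixes 10 nucleus with 40 multiplier males;
`random` replaces every ranking by a random one and is the null
scenario: no path should then show a partial trend. Analyses rebase at
the base generation and standardise true breeding values there (mean
0, genetic SD 1) *before* partitioning — for linear summaries the order
is immaterial, but standardising first keeps all reported partitions on
one scale.

What the simulators deliberately omit: genomes and linkage (an
infinitesimal model replaces locus-based simulation, with the two
traits independent), inbreeding in the Mendelian sampling variance,
overlapping generations, litter and maternal effects, and selective
phenotyping beyond the tier rule. Passing tests therefore demonstrate
the partitioning arithmetic and the qualitative selection-response
structure, not quantitative agreement with any locus-based simulation
or real programme.

`estimate_breeding_values()` solves Henderson's mixed-model equations
for `y = mu + a + e` with $\mathrm{Var}(a) = \mathbf{A}\sigma^2_a$ and
$\lambda = (1-h^2)/h^2$: $\mathbf{A}^{-1}$ is assembled directly from
the pedigree with the standard founder/non-founder rules, *ignoring
inbreeding* (a documented desk-scale approximation), and the sparse
symmetric positive-definite system is solved by supernodal Cholesky
(Matrix package). The tests require agreement with a dense generalised
least-squares oracle built from the same covariance model to $10^{-6}$,
exact parent-average estimates for unphenotyped progeny, and the
near-unit-heritability limit (estimates approach phenotype deviations
from the fitted mean).

## Numerical and testing choices

* No rounding anywhere internally; all test comparisons use explicit
  tolerances: $10^{-9}$ (relative) for conservation (`pa + w = bv`,
  partitions summing to the breeding value) and for
  recursion-vs-matrix agreement, $10^{-12}$ for streaming equivalence
  and path-combination totals, $10^{-6}$ for the mixed-model solver
  against its dense oracle.
* CSV writers print doubles with 17 significant digits so that
  write/read round-trips are exact and shell pipelines are
  byte-identical to the equivalent library composition.
* Missing path labels are an error by default; `strict = FALSE`
  buckets them into a literal `"Unknown"` path with a recorded
  warning, since silently dropping records would break conservation.
* Ties in selection rankings are broken by id; group keys sort
  numerically when possible, otherwise in the C locale — both for
  determinism across platforms.
* Stochastic properties are tested on fixed seed sets at the study
  conditions above: the random-selection null uses 20 replicates and a
  familywise t-test at $\alpha = 0.01$ (Bonferroni across the tested
  path × tier × trait combinations, since the null is the joint
  statement that *all* partial trends vanish); the directional
  properties of the two male-flow scenarios and the import example use
  10 replicates each, paired by seed where scenarios are compared.

## Limitations

Partitions are only as good as the breeding values and the pedigree:
errors in either propagate directly, and the decomposition of
*estimated* values inherits their shrinkage and bias. Contributions are
relative to the chosen base; rebasing re-attributes everything older to
the new founders' paths. Unknown-parent groups are not implemented —
unknown parents simply contribute zero — and neither are genomic
(marker-level) partitions nor partitions of genetic variance.
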