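---
title: "Methods: the mixed Yule-coalescent delimitation model and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the mixed Yule-coalescent delimitation model and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it fits, the
choices made where the method description left the design open, what
the simulators do and do not emulate, and the known limitations. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## The model

Species-level sampling of a non-recombining locus produces gene trees
with two branching regimes: deep branches reflect speciation
(approximated by a Yule pure-birth process) and shallow branches
reflect within-species coalescence, which for realistic population
sizes runs orders of magnitude faster. On an ultrametric tree, node
heights therefore separate into an old diversification zone and a young
coalescent zone, and the switch point can be estimated by maximum
likelihood and read as the species boundary.

Let heights be measured from the contemporaneous tips (height 0) toward
the root, and let the `n - 1` internal nodes, after de-tying, have
strictly decreasing heights. These define `n - 1` inter-event
intervals (the last ends at the present). A classification labels
every node *diversification* or *coalescent*, with the coalescent set
closed toward the tips; each lineage crossing the boundary roots one
entity — a cluster (two or more tips) or a singleton. The interval
log-likelihood is `sum_i [log b_i - b_i x_i]` with total branching rate

```
b_i = lambda1 * n_div,i^p1 + lambda2 * sum_j (n_ij (n_ij - 1))^p2
```

* `n_div,i` — lineage count of the tree with each cluster contracted to
  a tip: it grows 2, 3, ... through the diversification zone and is
  frozen at the number of entities below it.
* `n_ij` — lineages of cluster `j` in interval `i`; a cluster stem
  contributes `n = 1`, i.e. zero pairs.
* `p1`, `p2` — rate-scaling exponents shared across clusters. They
  absorb, in a phenomenological way, departures from the strict Yule
  (`p1 = 1`) and neutral-coalescent (`p2 = 1`) expectations such as
  unequal population sizes or diversification slowdowns.

The single-coalescent null is the classification with every node
coalescent; its `b_i = lambda (n_i(n_i - 1))^p`, and the mixed
likelihood reduces to it *exactly* because the Yule term is dropped
when no diversification node exists (symmetrically the coalescent term
is dropped for the all-singleton classification). This guarantees
`LR = 2 (logL_mixed - logL_null) >= 0` structurally, not numerically.

### Where the design was open

Prose descriptions of the GMYC method leave several details of the
likelihood unpinned, so three variants had to be fixed. They are
isolated behind the interval builder and recorded here:

1. **Exponent placement.** The coalescent exponent applies to the pair
   count jointly, `(n(n-1))^p2`, not to `(n-1)` alone. This makes the
   null's closed-form rate MLE `lambda_hat = m / sum_i c_i x_i` exact
   for any fixed `p`, which the acceptance suite exploits.
2. **Yule term below the threshold.** The diversification process keeps
   running at its frozen lineage count (`k` entities) down to the
   present, rather than vanishing below the threshold. The entities'
   stems are, after all, still species lineages.
3. **Shared cluster rates.** One `(lambda2, p2)` pair for all clusters:
   the smallest parameterization consistent with a five-parameter fit
   summary (two rates, two exponents, one threshold).

## Fitting

* **Candidates.** The likelihood depends on the threshold only through
  the classification, so the profile is evaluated at midpoints between
  consecutive distinct branching times, plus one candidate above the
  root (the null itself) and one below the shallowest node (all
  singletons). The *reported* threshold `T` is the height of the
  youngest diversification node of the winning classification — the
  "genetic distance from the branch tips" at which the regime switches.
* **Optimizer.** `L-BFGS-B` on `(log lambda1, p1, log lambda2, p2)`
  with analytic gradients, bounds `lambda` in `(1e-12, 1e12)`, `p` in
  `[-5, 5]`, from three deterministic starts `p in {0.5, 1, 1.5}` with
  rates at the per-process closed-form estimates (exact for a single
  process, a serviceable heuristic for the mixture). The likelihood is
  smooth but can be multimodal in the exponents; three spread starts
  have sufficed in every property test.
* **Ties.** Profile ties are broken toward fewer entities
  (conservative lumping). Exactly tied node heights are separated by
  subtracting `(i - 1) * 1e-9 * root_height` within each tie group in
  preorder, which restores the strictly positive waiting times the
  likelihood needs while perturbing it negligibly; the rule is
  deterministic, so runs are reproducible. Polytomies are rejected
  outright: resolving them with zero branches silently changes the
  likelihood, so the resolution must be the user's explicit act.
* **Confidence set.** All candidates within `delta = 1.92` log-units
  (half the 95% chi-square(1) quantile) of the profile maximum; on a
  lineage-through-time plot this is the shaded band around the
  transition.
* **Multiple thresholds.** Hill climbing over classifications from the
  single-threshold optimum: split one cluster at its root, or merge the
  entities under one diversification node, re-optimizing all four rate
  parameters per neighbor, accepting the best strict improvement. The
  search space is finite, acceptance is strict, and a visited-set guard
  makes cycling impossible in practice.

### Degrees of freedom

Mixed vs null uses `df = 3` (the parameter-count difference: one rate,
one exponent, one threshold). For multiple vs single no standard df
exists, so the package counts one threshold per change in entity
count,
`df = max(1, |N_multi - N_single|)`; both dfs are user-overridable
arguments. This is a pragmatic convention, not a calibrated one — see
the limitations below.

## Sequence preparation

Collapsing to haplotypes/genotypes uses exact, case-insensitive string
identity in which every IUPAC heterozygote code, `N`, `?` and `-` is a
character of its own — `ACGT` and `ACRT` are different genotypes even
though `R` is compatible with `G`. That strictness is deliberate: for a
diploid nuclear marker a heterozygote call *is* a different genotype,
and silently matching compatible states would merge real variation.
For the site statistics `S` (polymorphic sites) and `S_i`
(parsimony-informative sites) the treatment of ambiguity is a flag:
the default `"missing"` policy counts only A/C/G/T (ambiguity codes
carry genotype information but unresolved state identity), while
`"state"` counts every symbol; conventions differ between tools, so
both are testable.

## What the simulators emulate

The generator mirrors the inference model: a Yule species tree
(waiting time `Exp(j * lambda1)` while `j` lineages; the present is
placed one further `Exp(k * lambda1)` after the k-th birth so the
youngest species has a positive stem), independent per-species
coalescents at pair rate `lambda2 * n(n-1)`, rejection-sampled until
each species' MRCA is younger than its stem age (rescaling would
distort the conditional density the model assumes), grafted into one
ultrametric tree. Alignments evolve under Jukes-Cantor with optional
per-site heterozygote injection as two-fold IUPAC codes. The coalescent
is parameterized directly by the rate `lambda2` rather than an
effective population size, so recovery experiments compare true and
estimated `lambda2` without unit conversion. Defaults in the validation
experiments (`k = 10` species, 10 samples each,
`lambda2 / lambda1 = 200`) describe a favorable but realistic barcoding
regime: strong rate separation, moderate and even sampling.

What the simulator does *not* emulate — and hence what a green recovery
test does not establish — includes rate variation among lineages
(relaxed-clock error in the input chronogram is outside the model),
migration and hybridization, selection, recombination in the nuclear
marker, uneven sampling, and misidentified or missing metadata. A green
suite certifies the implementation against its own stated model, not
the model against nature.

## Numerical choices

* Ultrametricity tolerance `1e-6 * root_height` on tip heights
  (floating-point jitter typical of exported MCC chronograms), snapped
  to exactly 0 past validation; worse offenders are rejected by name.
* Zero-pair cells (`n_ij <= 1`) contribute exactly 0 to the coalescent
  sum for *every* exponent, avoiding `0^p` for `p <= 0`.
* Intervals with zero total rate yield `-Inf` rather than an error
  inside the optimizer, which then avoids that region.
* The newick writer emits 10 significant digits; parse-serialize-parse
  round trips preserve heights to `1e-9` relative.
* All stochastic operations draw from a private RNG stream seeded
  explicitly (default 1) and restore the caller's RNG state.

## Known limitations

* **The LRT is anticonservative.** The mixed-vs-null statistic
  maximizes over all candidate thresholds, but the chi-square(3)
  reference accounts only for the three added parameters, not for the
  selection. On 200 simulated single-coalescent trees (n = 50) the
  acceptance suite measures a rejection rate of about 0.11 at nominal
  0.05 — outside the exact binomial 99% band — and that acceptance
  criterion is deliberately left failing rather than repaired by
  adjusting df or the simulation after the fact. Users should read
  marginal p-values (say, 0.01–0.1) with caution; strongly structured
  data produce LRs far beyond this gray zone.
* Single locus, known tree: uncertainty in the chronogram is not
  propagated (no posterior-sample variant), and the delimitation
  inherits any mitochondrial idiosyncrasies (introgression,
  male-biased processes); hence the second-locus congruence stage.
* The multiple-threshold search is a greedy local optimizer; it
  guarantees a local maximum nesting the single-threshold fit, not a
  global one.
* Congruence requires exact clade identity on the second-locus tree;
  soft polytomies in a consensus tree therefore read as incongruence
  ("unresolved"); that conservatism is intentional.
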