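---
title: "Methods: association networks from group-scan proximity data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: association networks from group-scan proximity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxnet)
```

## The data model

`proxnet` analyses *group scans*: instantaneous censuses of a closed,
individually identifiable animal group in which each unordered pair
(dyad) is scored associated (within a fixed proximity criterion, e.g.
1 m), not associated, or indeterminate because at least one member was
not visible. Scans are indexed by date, observation context and a
within-day scan number. The package was built around a sanctuary gorilla
monitoring design — one nightly nesting scan, three morning scans in a
provisioned mixing yard, one scan at the afternoon recall from a forest
enclosure — but nothing in the code is specific to that species or
facility beyond the closed vocabularies for demographic attributes.

Two modelling rules sit at the base of everything and are worth stating
explicitly because they resolve ambiguities every scan dataset has:

1. **Daily collapsing.** Repeated scans within a day are collapsed to a
   single one/zero daily score to limit within-day autocorrelation: a
   dyad counts as associated for the day if associated in *at least one*
   scan, and an individual is not visible for the day only if unseen in
   *every* scan of that day.
2. **Absence is not zero.** A dyad absent from a scan's rows is treated
   as not-visible, never as "seen apart". Visibility of an individual on
   a day is derived from the data itself: it was seen if and only if at
   least one of its dyad rows that day has a determinate state.

## The simple-ratio index and its denominator

For each dyad the daily states of one context are tallied into `X`
(both seen, associated), `Y_AB` (both seen, apart), `Y_A`/`Y_B` (only
one member seen), and the association index is

$$\mathrm{SRI} = \frac{X}{X + Y_A + Y_B + Y_{AB}} \in [0, 1].$$

Days on which *both* members were unseen enter no term: the four terms
all presuppose that association status could have been at least
partially ascertained, and counting doubly-unseen days would deflate the
index with no information content. Dyads whose denominator is zero —
never jointly observable over the whole period — are assigned index 0
with a warning rather than dropped, so that matrices stay total and
binary density counts such pairs as absent edges. Both choices are
deliberate design decisions of this package; the second mirrors how the
field treats unobserved pairs (as zero-weight edges).

The resulting per-context matrix is exactly symmetric, zero-diagonal,
bounded in [0, 1], and satisfies the identity
`mean(strength) = (N − 1) × mean(index)` that the test suite asserts on
every run.

## Network statistics

*Density* is binary: the fraction of the $N(N-1)/2$ dyads with any
nonzero index. A weighted "mean index as density" variant was considered
and rejected — the binary definition is what reproduces densities at or
near 1.0 alongside mean indices near 0.05, the characteristic signature
of a highly connected but weakly associated group.

*Strength* is the row sum of the index matrix. *Eigenvector centrality*
is the principal eigenvector of the index matrix, computed by a
deterministic symmetric eigendecomposition (never an iterative solver
with a random start), oriented non-negative and scaled to **unit
Euclidean norm**. The normalisation convention is not universal across
software; unit norm was adopted because the squared per-individual
centralities of the reference study's published tables sum to ≈ 1.00 in
all three observation contexts (1.0011, 0.9938, 0.9833), which
identifies the convention its software used. A `normalize = "max"`
option is provided for comparison with max-entry-1 conventions. For a
disconnected network the leading eigenvector localises on the component
with the dominant eigenvalue; the function warns rather than fails,
since rare isolated individuals are a fact of field data.

Age associations use Spearman rank correlation with midranks and the
two-sided t approximation; this combination reproduces the reference
study's printed coefficients and p-values exactly to printed precision,
which pins down the convention.

## Dietz R and the node-label permutation null

The matrix correlation is implemented as the Pearson correlation of
midrank-transformed upper-triangle entries — i.e. Spearman over the
dyadic values. Dietz's statistic is classically presented as a raw
rank-product sum; that form differs from the midrank-Pearson form only
by an affine rescaling, to which permutation p-values are invariant, so
the correlation-scaled version in [−1, 1] is reported to match how such
statistics are printed. Two properties are asserted as invariants:
rank-invariance under strictly monotone transforms, and invariance under
jointly permuting node labels of both matrices.

The null distribution permutes the node labels of one matrix (rows and
columns jointly) — *not* the dyadic entries independently, which would
destroy the row/column dependence structure. Conventions:

* two-sided p with the add-one rule, $p = (1 + \#\{|R_\pi| \ge
  |R_{obs}|\})/(n_{perm}+1)$, so $p \ge 1/(n_{perm}+1)$;
* the significance *flag* follows the two-tailed quantile rule (observed
  R outside the central 95% of the null), matching the field's "greater
  or less than 97.5% of permutations" phrasing; the two can disagree
  marginally on discrete nulls, and both are reported;
* when $N! \le n_{perm}$ the test silently switches to exhaustive
  enumeration of all node permutations and the p-value is exact;
* every stochastic test takes an explicit seed and records it.

No gregariousness-controlled (row-sum-preserving) permutations are
offered: the methodology being mirrored uses plain identity
permutations, and adding a stronger null silently would change what the
p-values mean.

Between-context comparisons apply the printed Bonferroni convention
α = 0.016 for three pairwise tests; temporal stability compares the
matrices of the first and last 10 study weeks, where weeks are
consecutive 7-day blocks from the first observation date and a span
shorter than 20 weeks yields overlapping (flagged) windows rather than
an error, provided each window fits individually.

## Modularity and community detection

Weighted Newman modularity is used directly on the index matrix —
binarising first would discard exactly the weak-tie structure the index
was built to quantify. Detection is Newman's leading-eigenvector
bisection on the (generalised) modularity matrix with two refinements,
both deterministic:

1. Kernighan–Lin fine-tuning after each bisection: full passes in which
   every vertex is moved exactly once in order of best gain (lowest
   index breaking ties) and the best prefix is kept;
2. a final global pass of single-node moves between communities, because
   recursive bisection alone cannot transfer a node across an earlier
   split — without this step the search measurably missed the optimum
   (ratio ≈ 0.96 of the exhaustive maximum on adversarial random
   graphs; with it, the test suite's ≥ 0.99 bound holds with margin).

A subgroup whose generalised modularity matrix has no positive
eigenvalue is declared indivisible; a split is accepted only if it
increases global Q. An `exhaustive = TRUE` flag (N ≤ 10) searches all
set partitions as a check; the acceptance suite verifies the greedy
search attains ≥ 0.99 of that optimum across random graphs. The
subgrouping verdict applies the conventional threshold inclusively
(Q ≥ 0.30), and detected memberships can be tested against shared
origin/sex with the same permutation machinery via the binary
same-community matrix.

## Random vs scale-free classification

Centrality is regressed on its reverse rank (largest value gets rank N;
midranks for ties). The linear model is ordinary least squares. The
power model is fitted in log–log space — the convention of the
curve-fitting software this mirrors — but scored by residuals on the
*original* response scale, so both models are compared on one scale by
$AIC = n\ln(RSS/n) + 2k$. Both models are charged $k = 2$ (two fitted
parameters each); the source methodology says only "k is the degrees of
freedom", and with equal k the AIC comparison reduces to an RSS
comparison, which is also the only reading under which the comparison is
scale-coherent. `rss_scale = "log"` exposes the alternative scoring for
sensitivity analysis. A perfect fit (RSS = 0) yields −∞ by convention.

One reference-value caveat found while validating: the published AIC
values are mutually inconsistent with the published R² under the
published AIC formula itself (for the mixing context, R² = 0.927 implies
RSS ≈ 0.0066 and hence AIC ≈ −104, not the printed −80.4; no constant k
bridges a 24-point gap). The R² values, by contrast, reproduce from the
published per-individual tables to < 0.005. This package therefore
treats R² as the checkable quantity and reports AIC strictly by the
formula.

## The synthetic-data generator: what it emulates, and what not

`simulate_scans()` emulates the *design* of the monitoring study: 14
individuals (3 males — one silverback, two blackbacks — and 11 females;
origins 4/4/6), 224 days (~32 weeks), 192/157/159 observation days in
nesting/mixing/shifting, 1/3/1 scans per day, per-scan visibility 0.95.
Dyadic per-scan propensities are
$p_{ij} = \mathrm{clamp}(\text{base} \cdot g_i g_j \cdot
\text{context effect})$ with lognormal gregariousness $g_i$
(sdlog 0.35, mean 1). Defaults were fixed once from the stated
magnitudes of the system being emulated — mean daily indices ≈ 0.05
(mixing/shifting) and ≈ 0.07 (nesting), density near 1 — with the mixing
context effect 0.34 chosen so that OR-collapsing three scans of
propensity 0.017 yields a daily probability ≈ 0.05, and a sex-assorted
4-block nesting structure ($p_{within} = 0.18$, $p_{between} = 0.045$,
block sizes 5/4/3/2) giving the nesting context its larger mean and
variance. They were not revisited after seeing test outcomes.

Known simplifications, hence what a green test does *not* establish:

* dyadic states are independent across dyads within a scan — real
  proximity is transitive (if A–B and B–C are close, A–C tends to be).
  The statistics under test consume only dyad-level tallies, for which
  independence is adequate; conclusions about triadic structure are out
  of scope.
* visibility is independent across individuals and scans, whereas real
  not-visible events cluster (e.g. several animals out of their nests at
  once);
* gregariousness and block structure are stationary — the generator's
  stationary world is what makes the temporal-stability power checks
  interpretable, and regime switches are simulated by concatenating two
  independent runs;
* the default world reproduces design-level magnitudes (density, means,
  above-mean dyad fractions, linear-fit R²) but **not** dyad-specific
  published values: the observed group's single most extreme dyad
  (8.27× the nesting mean) and its nesting modularity (Q = 0.383)
  reflect one real group's idiosyncrasies; the stand-in's nesting Q
  under the chosen block strengths comes out near 0.20 and its top-dyad
  ratio near 4–8 depending on seed. These are reported honestly by
  `scripts/acceptance.R` rather than calibrated to match.

## Numerical choices and degenerate inputs

* Exact symmetry is enforced by averaging `(M + t(M))/2` after a 1e−12
  asymmetry check; matrix CSV round-trips at 17 significant digits.
* Eigen-solvers are deterministic (`eigen(symmetric = TRUE)`);
  eigenvector sign is fixed by orienting the sum positive; entries in
  (−1e−10, 0) from floating point are zapped to 0.
* Constant matrices make rank correlations undefined: reported as NA
  with a degenerate-test flag, never as 0.
* Modularity split acceptance and refinement use a 1e−10 improvement
  tolerance; ties in fine-tuning moves resolve to the lowest node index,
  making partitions platform-deterministic.
* `n_perm < 100` warns; seeds are required for reproducibility but not
  mandatory, matching interactive use.
* Empty scan files parse to empty record sets with a warning; a context
  with no records errors by name at the pipeline stage that needed it.

## Limitations

Half-weight/twice-weight indices, gregariousness-controlled permutation
nulls, MRQAP, Louvain/Leiden with resolution parameters, overlapping
communities and degree-distribution power-law testing (Clauset-style)
are deliberately out of scope; the package mirrors one specific,
internally consistent analysis methodology. Group sizes are assumed
closed over the study period (no demographic turnover), and attribute
vocabularies are fixed at construction.
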