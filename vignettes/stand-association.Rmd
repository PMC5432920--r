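---
title: "Interspecific association and spatial structure of stem-mapped stands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interspecific association and spatial structure of stem-mapped stands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standassoc)
```

## The problem

In a fully stem-mapped forest plot — every tree's position, species and
diameter at breast height (DBH) censused — two complementary questions
arise. Do species co-occur or segregate at the scale of the sampling
quadrat, i.e. is there interspecific *association*? And how are individual
trees arranged around each other, i.e. what is the fine-scale *spatial
pattern*? `standassoc` implements the standard analysis chain for both,
stratified by development stage (juvenile, medium, large trees), plus a
synthetic stand generator with known truth so every step can be validated
without field data.

The canonical use case is an old-growth mixed stand censused on a
140 × 70 m plot divided into fifty 14 × 14 m quadrats, with all stems of
DBH ≥ 5 cm mapped; those are the package defaults throughout
(`plot_geometry()`, `analysis_config()`).

## The statistics

### Importance value

For each species $i$ (optionally within one development stage) the package
computes density $D_i$ (stems/ha), frequency $F_i$ (share of quadrats
occupied) and dominance $d_i$ (summed stem basal area, m²/ha, with
per-stem basal area $\pi(\mathrm{DBH}/200)^2$). The relative forms are the
species' shares of the stage totals,

$$RD_i = 100\,\frac{D_i}{\sum_j D_j},\qquad
  RF_i = 100\,\frac{F_i}{\sum_j F_j},\qquad
  Rd_i = 100\,\frac{d_i}{\sum_j d_j},$$

and the importance value is their mean, $IV_i = (RD_i+RF_i+Rd_i)/3$. Each
column then sums to 100 % within a stage, which is what makes IV ranks
comparable across stages. Parts of the field literature print variant
denominators (individuals over total density for $RD$; frequency over the
*number of species* for $RF$). Those variants do not normalise to 100 %
and are almost certainly typesetting errata, but they are available
verbatim behind `iv_components(..., denominators = "printed")` for
comparison. The dominant species set is the IV top-$k$ (default
$k = 11$), ties broken by density then label (`select_dominant()`).

### Pairwise association: Yates χ² and the AC coefficient

Each unordered species pair is cross-tabulated over quadrats into a 2 × 2
table — $a$ quadrats with both, $b$ with A only, $c$ with B only, $d$
with neither, $N$ total — and tested with the continuity-corrected
chi-square

$$\chi^2 = \frac{N\left(\lvert ad-bc\rvert - N/2\right)^2}
  {(a+b)(c+d)(a+c)(b+d)},$$

reported *signed* by $\operatorname{sign}(ad-bc)$: positive means
co-occurrence beyond independence, negative means segregation. The
five-level classification uses the df = 1 chi-square quantiles at
cumulative 0.95 and 0.99 (3.841 and 6.635), computed at run time rather
than hard-coded: $\lvert\chi^2\rvert < 3.841$ no association;
$3.841 \le \lvert\chi^2\rvert < 6.635$ (extra) significant at
$P < 0.05$; $\lvert\chi^2\rvert \ge 6.635$ significant at $P < 0.01$,
each split by sign.

Association *strength* is measured by the piecewise AC coefficient,

$$AC = \begin{cases}
 \dfrac{ad-bc}{(a+b)(b+d)} & ad \ge bc\\[1ex]
 \dfrac{ad-bc}{(a+b)(a+c)} & ad < bc,\ d \ge a\\[1ex]
 \dfrac{ad-bc}{(b+d)(c+d)} & ad < bc,\ d < a,
\end{cases}$$

which runs from exactly $+1$ at complete positive association
($b = c = 0$) through 0 at independence to exactly $-1$ at complete
negative association ($a = d = 0$).

Two numerical choices deserve note. First, a pair in which one species
occupies *no* quadrat (or *every* quadrat) has a zero margin; the χ²
denominator vanishes and the pair is reported as `undefined` and excluded
from summary percentages rather than coerced to zero. Second, the
continuity correction is applied exactly as the formula reads — it is not
clamped at zero when $\lvert ad-bc\rvert < N/2$, and
`stats::chisq.test(correct = TRUE)`, which does clamp, will therefore
disagree on weakly associated tables; the test suite checks the
implementation against an independent expected-frequency evaluation of
the same unclamped formula instead.

### Overall association: the variance-ratio test

Whether the community as a whole covaries is tested by Schluter's
variance ratio on the species × quadrat presence matrix
$X_{ij} \in \{0,1\}$. With quadrat richness totals
$T_j = \sum_i X_{ij}$,

$$S_T^2 = \frac1N\sum_j (T_j-\bar t)^2,\qquad
  \delta_i^2 = \frac1N\sum_j (X_{ij}-\bar t_i)^2,\qquad
  V = \frac{S_T^2}{\sum_i \delta_i^2},$$

using population-style $1/N$ variances. $V = 1$ under independence;
$V > 1$ indicates net positive covariation, $V < 1$ net negative. The
test statistic is $W = N\,V$, compared against a two-sided 90 % band of
chi-square quantiles with df = $N$ — for $N = 50$ quadrats,
(34.764, 67.505). In upper-tail notation these are the
$\chi^2_{0.95,N}$ and $\chi^2_{0.05,N}$ points; the package exposes
cumulative-probability semantics (`chisq_bounds(N, level = 0.10)`). The
verdict combines direction ($V$ vs 1) with significance ($W$ outside the
band). The $\delta_i^2$ deviation is taken from the species mean
$\bar t_i$ — the only reading under which it is a species variance; an
abundance-mode matrix gives the abundance version of the same test.

### Uniform angle index

Fine-scale arrangement is summarised by the uniform angle index. For each
reference tree the four nearest neighbours (any species, Euclidean
distance, distance ties broken by tree id) define four directions; sort
them by azimuth and take the angle between each pair of adjacent
directions — always the *smaller* arc, at most 180°. $W_i$ is the
fraction of those four angles strictly smaller than the standard angle
$\alpha_0 = 72^\circ = 360^\circ/5$:
an evenly spread neighbourhood scores 0, a one-sided fan (all four
neighbours crowded on one side) scores 1, and $W_i$ takes the five
values $0, 0.25, 0.5, 0.75, 1$. The stand (or population) mean $\bar W$
classifies the pattern: below 0.475 regular, above 0.517 clumped,
in between random.

The smaller-arc construction matters: had the raw circular gaps been
tested instead, the four gaps would sum to 360° and at most three could
fall below 72°, making $W_i = 1$ unattainable and biasing $\bar W$
downward. The smaller-arc reading is the one under which the five-level
range and the (0.475, 0.517) random band are coherent, and simulated
homogeneous-Poisson stands indeed centre near 0.496 under it
(`mean_uniform_angle()`; the boundary test is strict, `< alpha0`, so a
gap of exactly 72° does not count).

Edge effects are handled by a buffer: only trees in the reduced window —
the plot inset by `buffer_width` (default 5 m, so 130 × 60 m) — serve as
reference trees, while buffer trees may still be neighbours. This
guarantees each reference tree's four nearest neighbours are genuine
rather than censored by the plot boundary. Per-population $\bar W$ uses
conspecific *references* with all-species *neighbours* by default (the
structure of the stand around that population);
`conspecific_neighbors = TRUE` restricts the neighbour pool too.

## The synthetic stand generator

Because analyses of this kind are usually published without the
underlying stem map, the package ships a seeded generator
(`simulate_community()`) whose defaults emulate the target stand class:
a 140 × 70 m plot of ≈ 870 stems (≈ 888 stems/ha) in 11 dominant
species, reverse-J diameter structure with 41.3 % juveniles (the
medium/large split of the remainder, 42 %/16.7 %, is the package's own
choice of a realistic reverse-J tail), and per-species spatial patterns
mixing Thomas clusters (most species), homogeneous Poisson and one
hard-core species. DBH is drawn per stage from a truncated exponential
(rate 1/5 cm⁻¹), giving declining abundance within and across stages.

Pairwise association truth is induced through *habitat patches* rather
than by coupling quadrat counts directly, so spatial and co-occurrence
structure stay mutually consistent: a pair with strength $s \in [0,1]$
confines each member (its points, or its cluster parents) to the
$f = 1 - s/2$ fraction of quadrat cells nearest a shared random anchor —
the same cells for a positive pair, the nearest-$f$ versus farthest-$f$
cells for a negative pair, whose patches then overlap in exactly the
$2f - 1$ fraction regardless of where the anchor falls. Strength 0
imposes no constraint (independence); strength 1 splits a negative pair
into disjoint half-plots. At strength 0.9 the intended χ² sign is
recovered in ≥ 90 % of seeded replicates in the test suite.

A single spec-level seed fans out into fixed per-species substreams, so
appending a species to a spec never perturbs the points of existing
ones, and identical specs reproduce byte-identical stem maps.

What the generator does *not* emulate: environmental gradients and
inhomogeneous intensity, size-dependent interactions (large trees do not
inhibit juveniles), mortality/growth dynamics, and measurement error in
coordinates. Passing recovery tests on these stands therefore shows the
statistics behave correctly under their stated models — not that any
particular field stand satisfies those models.

## Degenerate inputs and conventions

* Quadrat membership is half-open, $[ks, (k+1)s)$, with points on the far
  east/north plot edge clamped into the last cell, so the quadrat
  partition is exhaustive and every tree counts exactly once. How trees
  exactly on quadrat lines were assigned in any given field study is
  generally unstated; this convention is a deterministic choice.
* Stage intervals are left-closed/right-open with configurable breaks
  (defaults 5, 10, 25 cm); DBH below the census threshold is rejected.
* Species absent from a stage are kept as all-zero matrix rows so pair
  enumeration is stage-invariant; their pairs are `undefined`.
* `ad = bc` routes to the first AC branch (its condition is $ad \ge bc$);
  the second branch cannot be reached at equality.
* AC is not symmetric under swapping the two species' labels — its branch
  denominators single out $b$ and $d$ — so `pairwise_analysis()` reports
  each unordered pair once, in the fixed species order of the input
  matrix, and only the sign of AC is label-invariant. χ² and the
  five-level category are fully symmetric.
* Coincident tree coordinates are a data error for the uniform angle
  index (the direction to a zero-distance neighbour is undefined) and are
  reported with both offending ids.

## Validation problem sizes

The test suite validates the pairwise statistics by exhaustive
enumeration of all 2 × 2 tables with $N \le 12$ against independent
oracles; variance-ratio calibration on 300–500 simulated independent
11 × 50 presence matrices (mean $V$ within $1 \pm 0.05$, ≈ 10 % band
exceedance); and uniform-angle pattern recovery on 100 stands each of
jittered-lattice, Poisson and tight-cluster patterns at the default
plot's density (~900 stems), plus 200 seeded two-species communities per
association sign. These sizes give comfortable Monte-Carlo margins for
the stated thresholds while keeping the full suite under a couple of
minutes.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_community(community_spec(seed = 7))
res <- run_analysis(sim$stemmap, out_dir = "reports")

res$overall            # variance-ratio verdicts per stage
res$pairwise$all$summary
mean_uniform_angle(sim$stemmap)
```

## Known limitations

* The variance-ratio band relies on the chi-square approximation to
  $W = NV$; for very small quadrat counts a randomisation null would be
  preferable and is out of scope here.
* No multiple-testing correction is applied across the pair tests — the
  convention of the analysis this package systematises; treat individual
  significant pairs accordingly.
* Importance-value dispersion ("± " values sometimes printed alongside
  stage IVs in the literature) has no agreed definition and is not
  computed.
* The hard-core generator is sequential-inhibition, not a Gibbs process;
  extremely dense packings fail with an informative error rather than
  approximating.
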