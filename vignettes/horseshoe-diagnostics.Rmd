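---
title: "Distance saturation, horseshoes, and a nonsaturating transport metric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance saturation, horseshoes, and a nonsaturating transport metric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embad)
```

## The phenomenon

Community tables collected along an environmental gradient — soil bacteria
across a pH range, skin microbiota across weeks of carcass decomposition —
show *niche differentiation*: each taxon is abundant only in a restricted
window of the gradient. Order the samples by the gradient and the taxa by the
center of their window, and the nonzero entries of the table concentrate in a
diagonal band. We call the idealized version a **band table**: sample $j$
occupies band size $B$ consecutive feature rows starting at row
$j \cdot \text{shift}$, each nonzero cell holding $1/B$ so columns are
proportion vectors (`band_table()`).

The geometry of such tables breaks most community dissimilarities. While two
samples still share features, the Euclidean distance between their columns
grows with their gradient separation; as soon as the bands stop overlapping
($|i - j| \cdot \text{shift} \ge B$), every pair of samples differs in exactly
$2B$ cells by $1/B$ and the distance freezes at

$$ d_{\max} = \sqrt{2B \cdot (1/B)^2} = \sqrt{2/B}, $$

returned by `band_ball_radius()`. All mutually non-overlapping samples are
then *equidistant*. A set of many equidistant points cannot lie on a line:
points pairwise at least $\delta$ apart on a segment inside a ball of radius
$r$ number at most $\lfloor 2r/\delta \rfloor + 1$ (`max_collinear()`;
`is_collinear()` checks actual point sets via the second singular value). So
the gradient cannot embed as a line, and low-dimensional ordinations — PCA,
correspondence analysis, PCoA of any saturating metric — bend it into the
horseshoe (Guttman) arc, with the gradient extremes curling toward each
other. The same saturation logic is familiar from molecular evolution:
two sequences evolving under equal base frequencies plateau at 75% site
divergence no matter how much time passes
(`substitution_saturation()` computes
$0.75\,(1 - e^{-8\lambda t/3})$ for two lineages at rate $\lambda$).

`saturation_curve()` makes the property measurable: distances from a
reference sample listed in gradient order, plus a plateau estimate — the
smallest rank from which all later distances stay within a factor
$1-\varepsilon$ of the maximum. We use $\varepsilon = 0.01$ because real
curves (e.g. UniFrac on time series) approach their ceiling without exactly
reaching it; plateau detection must tolerate near-plateaus.

## The metrics

* `euclidean_dm()` — plain $L_2$ between sample columns.
* `chisq_dm()` — the metric induced by correspondence analysis:
  $d(i,j) = \sqrt{\sum_k (P_{ki}/r_i - P_{kj}/r_j)^2 / c_k}$ with sample
  masses $r$ and feature masses $c$ of the grand-total-normalized table.
  Features never observed are dropped ($c_k = 0$ is undefined). Note a
  finite-table subtlety: on a band table the last $\sim B$ features occur in
  fewer samples, so their weights $1/c_k$ are larger and the curve rises
  again near the far edge of the gradient; exact saturation holds on the
  interior ranks. The tests check both facts.
* `unifrac_unweighted()` — presence/absence phylogenetic dissimilarity:
  branch length unique to one sample over branch length present in either,
  a branch being present when any descendant tip is observed. Bounded in
  $[0,1]$; disjoint tip sets on a star tree attain exactly 1. A root stem
  is counted only when at least one of the pair is nonempty.
* `embad()` — **Earth Mover Band Aware Distance**, the nonsaturating
  alternative. Given prior knowledge of the band ordering (in practice:
  features sorted by their mean niche estimate), each sample's proportions
  become a probability distribution over ordered positions and the distance
  is the minimal total mass flow between the two distributions. In one
  dimension this is the Wasserstein-1 distance,
  $d(i,j) = \sum_{k=1}^{D-1} |C_{ik} - C_{jk}| (p_{k+1} - p_k)$ with $C$
  the cumulative ordered proportions. Moving mass farther always costs
  more, so the distance keeps growing after samples stop sharing features:
  on a band table with unit shift, $d(i,j) = |i-j|$ exactly.

Two EMBAD design choices were genuinely open. Positions default to the
*rank* of each feature in the ordering (unit spacing), which makes the
band-table identity exact; using raw gradient values as positions is exposed
through the `positions` argument for analyses where unequal niche spacing
matters. And EMBAD refuses non-proportion input rather than normalizing
silently, to keep the probability-mass interpretation auditable — call
`to_proportions()` first.

## Niche estimation and table sorting

The band ordering is estimated from the data itself. For feature $x$ with
abundances $x_i$ across samples with gradient values $g_i$,

$$ \bar g_x = \frac{\sum_i g_i x_i}{\sum_i x_i} $$

(`mean_niche_estimator()`) — an abundance-weighted mean, hence always inside
the observed gradient range. `niche_sort()` orders samples by $g_i$ and
features by $\bar g_x$; it is a pure permutation and idempotent. Ties are
broken by identifier (stable and reproducible), and never-observed features,
for which the estimator is undefined, are placed last in input order.

## Ordination and the arch diagnostic

`ordinate_pca()` (via `prcomp`), `ordinate_pcoa()` (Gower double-centering
and eigendecomposition) and `ordinate_ca()` (SVD of standardized residuals,
samples in principal coordinates) return a common result object. Negative
PCoA eigenvalues are reported and their axes dropped; we deliberately apply
no Cailliez/Lingoes correction because such corrections alter the distances
whose behavior is the object of study. Row-principal CA scaling is used so
that full-dimensional CA inter-sample distances reproduce `chisq_dm()`
exactly — a duality the tests verify to $10^{-9}$, alongside the classical
PCA $\equiv$ PCoA(Euclidean) identity. Every axis is oriented so its
largest-magnitude sample coordinate is positive, one uniform convention
across all three methods, making coordinates reproducible up to nothing.

"Horseshoe" has no standard quantitative definition, so `detect_arch()` is
our own operational diagnostic: fit $a_2 = a\,a_1^2 + b\,a_1 + c$ and flag
an arch when $|a| \cdot \mathrm{range}(a_1)^2 / \mathrm{range}(a_2) > 0.5$,
i.e. when the fitted curvature spans at least half the second axis. The 0.5
threshold is a calibration choice. `horseshoe_test()` combines it with the
axis-1 Spearman correlation against the gradient and an endpoint sign test
(both gradient extremes on one side of the axis-2 median, the midpoint on
the other). An ordination "passes the single-axis gradient test" when
$|\rho| \ge 0.99$ on axis 1 and no arch is detected; on band tables the
saturating metrics fail it and EMBAD passes it. Note that the *strength* of
axis-1 rank correlation under PCA depends on how tightly the horseshoe
curls: at two samples per band width ($n = 2B$) it exceeds 0.9, and it
decays slowly as $n/B$ grows while the arch signature remains.

## PERMANOVA

`permanova()` implements the single-factor pseudo-$F$:
$SS_\text{total} = \sum_{i<j} d_{ij}^2 / N$,
$SS_\text{within} = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g$, and
$F = (SS_\text{between}/(a-1)) / (SS_\text{within}/(N-a))$, with a
permutation p-value using the $(1 + \#\{F^\pi \ge F\})/(1 + n_\pi)$
convention so p can never fall below its floor $1/(n_\pi + 1)$. When the
number of distinct relabelings is at most 10,000 the distribution is
enumerated exhaustively instead. Perfect separation returns
$F = \infty$ with the smallest attainable p. The implementation is
cross-checked against an independent PERMANOVA implementation in the test
suite. On synthetic niche tables contrasted at the two gradient extremes
(bottom vs top quartile, our default grouping — published gradient analyses
use comparable extreme cuts such as pH below 3 vs above 8), EMBAD yields a
far larger pseudo-$F$ than chi-squared or Euclidean distances: a saturating
metric cannot tell the extremes apart more strongly than it can tell
anything else apart, so its between-group signal is capped.

## What the synthetic generator does and does not emulate

`niche_table()` draws Gaussian niche response curves: evenly spaced sample
gradient values and feature optima over `gradient_range`, expected counts
$\propto \exp(-(g_i-\mu_f)^2/2\sigma^2)$ rescaled so each sample's expected
total is `depth`, then independent Poisson counts. Defaults are chosen to
resemble a soil pH survey: 88 samples spanning pH 3–9, 200 taxa, niche
width $\sigma = 1$ pH unit, expected depth $10^4$ reads. The generator
reproduces the one property the methods depend on — band structure with
count noise and sparsity — and deliberately omits much of real data:
overdispersion beyond Poisson, uneven sample spacing, multi-modal or
asymmetric niches, taxon correlations, compositional coupling between taxa,
and varying sequencing depth. Tests passing on these tables therefore
demonstrate correctness of the algorithms under the niche model, not
robustness to every property of real sequencing data.

The centered log-ratio transform (`clr_transform()`) is provided for
visualizing such tables: $\mathrm{clr}(x) = \ln x - \overline{\ln x}$
per sample, after adding a pseudocount (default 1) to the raw counts —
before any normalization, so zeros are handled identically everywhere,
including when subsetting samples. A pseudocount of 0 is accepted only for
strictly positive tables; that limit is where the transform's scale
invariance is exact.

## Numerical conventions and degenerate inputs

* Proportion columns must sum to 1 within $10^{-9}$; sums within $10^{-6}$
  are renormalized at construction, anything further off is an error, and
  all-zero samples are rejected with the offending identifiers named.
* Distance matrices are validated as symmetric within $10^{-12}$, hollow,
  and nonnegative.
* PCoA of an all-zero distance matrix returns a single degenerate axis with
  a warning; requesting more axes than the rank truncates with a warning.
* Exhaustive PERMANOVA and its Monte-Carlo mode are both seeded explicitly;
  the same seed gives bitwise-identical p-values.

## Problem sizes used by the checks

The test suite and the reproduction script run at desk scale: band tables of
20–40 samples with band sizes 4–10, niche tables up to 88 × 200 at depth
$10^4$, PERMANOVA with 99–9,999 permutations, 200-replicate type-I-error
simulations on 12 samples, and a 10,000-site substitution simulation. These
sizes keep every property sharply testable (closed forms, exhaustive
enumerations, transport oracles) while completing in seconds.

## Known limitations

* EMBAD requires a trustworthy feature ordering; with a poorly estimated
  gradient the transport distances inherit that error. The estimator-based
  ordering works well when niches are unimodal.
* Chi-squared edge effects (above) mean "saturation" is exact only away
  from the table boundary.
* PERMANOVA is single-factor; no nested designs, no dispersion (PERMDISP)
  companion test.
* The arch detector is a heuristic; a gradient that is genuinely curved in
  feature space will also trigger it.
* Detrended correspondence analysis is intentionally absent: detrending
  removes the arc by construction and with it the information the arc
  carries about niche structure.
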