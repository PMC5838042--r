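---
title: "Point-pattern methods for comparing congeneric tree species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-pattern methods for comparing congeneric tree species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemspat)
```

## The problem

Fully mapped forest plots record every stem's location, species and
diameter at breast height (dbh). For co-occurring congeneric species —
here emulated after *Quercus*-dominated 1-ha plots — three questions
recur: do the congeners have similar spatial patterns and spatial
distributions; do they compete with (or facilitate) each other; and do
they relate to the surrounding heterospecific species in the same way?
`stemspat` implements the complete inferential workflow for these
questions on marked stem maps in rectangular windows, plus a synthetic
community generator so the whole machinery can be exercised and tested
without census data.

## Summary statistics

The workhorse is the pair correlation function $g(r)$: the density of
point pairs at interpoint distance $r$, relative to a Poisson process of
the same intensity, so $g = 1$ for a random pattern, $g > 1$ for
aggregation and $g < 1$ for regularity at scale $r$. It is the
derivative-based companion of Ripley's K,

$$K(r) = \frac{A}{n^2}\sum_{i \ne j} \mathbf{1}(d_{ij} < r)\, w_{ij},
\qquad g(r) = \frac{K'(r)}{2\pi r},$$

where $A$ is the window area, $n$ the stem count, and $w_{ij}$ Ripley's
isotropic edge-correction weight: the reciprocal of the fraction of the
circle of radius $d_{ij}$ around stem $i$ that lies inside the window.
For an axis-aligned rectangle this fraction has an exact closed form by
inclusion–exclusion over the four edges and their adjacent corners (arcs
cut off by opposite edges can never overlap, so the expression is exact
for every interior center and radius); the tests verify it against
numerical arc-length integration to $10^{-6}$.

Two normalization details are deliberate. The ordered double sum is
divided by $n^2$, not $n(n-1)$, so $E[\hat K(r)] = \pi r^2 (n-1)/n$
under complete spatial randomness — a bias of under 1% at the stem
counts used anywhere in the package, and irrelevant to envelope-based
inference, where observed and simulated curves share the estimator. The
indicator is strict ($d_{ij} < r$).

$\hat g$ uses an Epanechnikov kernel on the interpoint distances, divided
by $2\pi r$ and the squared intensity estimate. The default bandwidth is
Stoyan's rule of thumb $h = 0.26/\sqrt{\hat\lambda}$ (about 2.6 m for
100 stems on a hectare); bivariate estimates default to the rule
evaluated at the geometric mean of the two intensities. Kernel mass is
truncated below $r = 0$, so values at $r < h/2$ are reported as missing
rather than biased; $r = 0$ is `NaN` by convention. Difference
statistics compute the bandwidth once from the observed counts and hold
it fixed across all null replicates, so that label permutations change
only the labels, never the estimator.

The cross statistic $\hat g_{ab}(r)$ uses all ordered (a, b) pairs with
the edge weight centered on the a-point. The underlying cross pair
density is symmetric, so $g_{ab} = g_{ba}$ in theory; the two estimates
differ only through edge-weight centering, which the tests bound.

## Null models

Three null models, all conditioned on the observed stem count so that
envelopes compare patterns of equal abundance:

* **CSR** — complete spatial randomness: uniform independent locations.
* **HP** — heterogeneous Poisson: independent locations drawn from a
  kernel intensity surface $\hat\lambda(x, y)$ estimated from the
  observed pattern (Gaussian kernel, default 20 m bandwidth, 2 m grid).
  Edge correction divides the raw kernel sum at each grid location by
  the in-window kernel mass there, which is unbiased for a homogeneous
  pattern, and the surface is rescaled to integrate exactly to $n$.
  Sampling is by rejection against the surface maximum with bilinear
  interpolation between grid nodes. The surface is estimated **once**
  from the observed pattern, never re-estimated per replicate: the null
  is "this fixed intensity", and re-estimation would mix estimator noise
  into the null distribution.
* **RL** — random labeling: the joint locations of two species are held
  fixed and the labels are permuted uniformly, preserving both counts.

The 20 m intensity bandwidth is a deliberate compromise: wide enough
that cluster-scale aggregation (Thomas clusters with $\sigma \approx$
2–3 m) is *not* absorbed into the surface — otherwise HP would explain
away the biology — yet narrow enough to track plot-scale habitat
gradients. A pure log-linear gradient of about $e^{1.5}$-fold across
100 m is absorbed (the pattern reads as random under HP in most seeds);
steeper gradients ($e^2$-fold and beyond) start to leak into rejections
because the kernel estimate undershoots the extremes near the window
edge.

## Envelopes and the goodness-of-fit test

Pointwise simulation envelopes take the minimum and maximum of $s = 199$
simulated curves; an exchangeable realization falls outside at a given
scale with probability $2/(s+1) = 1\%$, hence "approximately 99%
envelopes". Because pointwise bands invite multiple-testing
over-interpretation across scales, each envelope is paired with a
goodness-of-fit test: for the observed curve and each simulated curve,
the total squared deviation over the scale interval from the mean of the
*other* curves (leave-one-out, which makes the $s + 1$ deviations
exchangeable under the null) is computed, and

$$\hat p = 1 - \frac{1}{s+1}\sum_{i=1}^{s} \mathbf{1}(u_0 > u_i).$$

The inequality is strict, so ties count toward non-significance (they
are reported via a message); the observed rank (1 = most extreme)
satisfies $\hat p = 1 - (s + 1 - \mathrm{rank})/(s + 1)$. The p-value is
computed in the algebraically equivalent form $(s+1-\sum I)/(s+1)$,
which avoids a floating-point wrinkle where attainable levels such as
$1 - 38/40$ drift just above a 0.05 cutoff. Scale intervals default to
the full positive grid; grid points where any curve is missing (below
half a bandwidth) are excluded. With a single simulation the two
leave-one-out deviations tie by construction and $\hat p = 1$.

Association calls combine both devices: `"none"` when $\hat p > \alpha$
or the observed curve never leaves the envelope, otherwise the sign of
the direction (below/above) with the larger summed squared excursion.
This reproduces the three-outcome reading (negative / positive / no
association) used in association tables, and applying it to both
orderings of a species pair yields the similar / one-sided /
both-different trichotomy for spatial distributions.

## Difference statistics

Two random-labeling difference statistics compare species against a
shared reference:

* **Case–control:** $D(r) = \hat g_{\mathrm{ctrl,case}}(r) -
  \hat g_{\mathrm{ctrl,ctrl}}(r)$ with envelopes from relabelings of the
  joint pattern. $D > 0$ flags case aggregation beyond (and independent
  of) the control's own structure. Under relabeling the expectation is
  not exactly zero — the mixed and within-label estimators weight pairs
  slightly differently, leaving a residual of order $g/n_1$ — which is
  harmless at the counts used and covered by the Monte-Carlo tolerance
  in the tests.
* **Shared heterospecific:** $D(r) = \hat g_{13}(r) - \hat g_{23}(r)$
  (or $\hat g_{31} - \hat g_{32}$), where 1, 2 are the congeners and 3 a
  heterospecific held fixed; only the congener labels are permuted. Here
  $E[D] = 0$ holds exactly under exchangeability, and the sign of a
  significant excursion says which congener bears the stronger relation
  to the heterospecific.

Both directions of every asymmetric statistic are always computed:
interspecific associations need not be symmetric, and the workflow
reports them pairwise.

## The synthetic community generator

The generator is first-class, tested code, not a fixture dump. Species
are drawn from CSR, a log-linear habitat gradient
($\lambda \propto e^{b_x x + b_y y}$, by rejection), or a Thomas cluster
process: Poisson($\kappa A$) parents on the window extended by a
4$\sigma$ guard buffer (avoiding offspring deficits at the boundary),
Poisson($\mu$) offspring per parent, isotropic Gaussian($\sigma$)
displacements, clipped to the window. The Thomas process was chosen
because it is the simplest cluster model with a closed-form pcf,
$g(r) = 1 + e^{-r^2/4\sigma^2} / (4\pi\sigma^2\kappa)$, which gives the
tests an independent oracle (about 4.10 at $r = 2$ for
$\kappa = 0.005$, $\sigma = 2$).

Interspecific structure comes from two mechanisms: *shared parents*
(the target species reuses a fraction of the source's parent points —
positive association at cluster scale) and *thinning* (target
candidates within a radius of any source point are kept with a
retention probability — negative association up to that radius). Links
form a directed acyclic graph; generation follows a topological order,
and fixed abundances are met by drawing offspring rounds from the same
parent set until the post-thinning yield reaches $n$, then subsampling.
Holding the parent set fixed across rounds keeps the cluster structure
consistent with a single Thomas realization of higher offspring
intensity.

Two named fixtures emulate the study's plot compositions: `plot1_like`
(QS 543, QV 214 on a shared gradient with 75% shared parents, plus 10
heterospecifics of 20–80 stems thinned around both congeners) and
`plot2_like` (QS 340, QV 169, QA 170 with divergent gradients, QV and
QA thinned around QS at 15% retention within 5 m, plus 10
heterospecifics). Stem counts are exact and dbh is lognormal, floored
at 1 cm to respect the census mapping threshold. Fixture constants
(gradient slopes $\pm 0.02$, $\sigma = 2.5$ m, link strengths) are
package constants chosen once so the qualitative contrasts — positive
congener association in plot 1, negative for the thinned pairs in plot
2 — are robust across seeds; they emulate structure and are not
estimates of any real plot.

What the generator does *not* emulate: dispersal anisotropy, elevation-
or soil-driven intensity beyond a log-linear gradient, size-dependent
interactions (dbh is independent of position), and mortality (all stems
are generated alive). Passing tests therefore demonstrate that the
inference machinery detects the mechanisms it claims to detect, not
that any particular real forest behaves this way.

## Neighborhood richness and diversity

For every stem, neighbors within 5 m (default) are counted as
individuals and as distinct species; per-species means are regressed on
the species' total basal area $\sum \pi(\mathrm{dbh}/200)^2$ by ordinary
least squares, with Pearson correlations (species are the observational
units; a constant response degenerates to $r = 0$ with a warning). No
edge correction is applied to neighborhood counts; stems nearer than
the radius to the boundary are included and counted in an `n_edge`
column so a user can filter them. Basal-area diversity uses
$H = -\sum p_i \ln p_i$ (nats) and $D = 1 - \sum p_i^2$ with $p_i$ the
basal-area share of species $i$; the quadrat defaults to the whole
plot, with arbitrary sub-quadrats available.

Dead stems, when present in a stem table, are retained by default (the
censuses map living and dead trees, and no analysis stage prescribes a
filter); `subset_status()` applies one explicitly.

## Numerical choices and problem sizes

Tie-breaks in the GoF test go toward non-significance. Rejection
sampling batches double until the target count is met; fixed-n cluster
generation caps at 500 offspring rounds before reporting an unreachable
configuration (e.g. over-aggressive thinning). Windows are validated,
points outside a declared window are an error naming the offending
rows, and every sampler is reproducible from an integer seed.

The test suite runs its statistical checks at deliberately modest sizes
chosen for tight Monte-Carlo bounds at desk scale: envelope coverage
with 500 repetitions of 199 simulations at $n = 100$; GoF calibration
with 500 repetitions of 39 simulations at $n = 50$ (the attainable
rejection probability at the 5% level is exactly 2/40); Thomas-pcf
recovery over 100 replicates; and the generator-to-call contrasts over
20 seeds with $s = 199$. The analysis scripts under `analysis/` use
$s = 199$ throughout, matching the envelope convention above.

## Known limitations

Rectangular windows only; no inhomogeneous (intensity-reweighted) pcf,
so HP inference relies on simulation rather than reweighting; no global
(simultaneous) envelopes — the GoF test is the multiple-testing guard;
pointwise envelopes are min/max, so single extreme replicates set the
band; and the HP null conditions on $n$ rather than treating it as
Poisson, a choice that keeps envelopes abundance-matched but understates
count variability if one wanted prediction rather than testing.
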