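---
title: "The categorical colour metric: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The categorical colour metric: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catmetric)
```

## The idea

When a population of speakers names colours, nearby colours evoke similar
distributions of names and distant colours different ones. catmetric turns
that observation into a Riemannian metric on the sRGB cube: the distance
between two infinitesimally close colours is the information distance
between the naming distributions they evoke. Colours are close when they
are named alike, however far apart a colorimeter would put them.

The machinery is the information geometry of categorical distributions. A
probability vector $P$ over $V$ names maps to the unit vector $\sqrt{P}$ on
the positive orthant of the $(V-1)$-sphere; the geodesic distance between
two such points is the Bhattacharyya angle
$d(P,Q) = \arccos \sum_n \sqrt{P_n Q_n} \in [0, \pi/2]$. Two distributions
with no names in common sit at $\pi/2$, which we take as the natural unit of
categorical extent: one *grain*. The corresponding area and volume units
come from spheres of radius $\pi/4$: $G_1 = \pi/2$, $G_2 = \pi^3/16$,
$G_3 = \pi^4/48$ (`grain_units()`).

## Why a model rather than raw counts

Empirical per-chip response distributions cannot be plugged into the
Bhattacharyya angle directly: with ~31 responses per chip over a vocabulary
of hundreds, the angle between two samples of the *same* population
distribution is around 0.85 radians — more than half the maximum possible —
purely from sampling noise. `bhattacharyya_bias_demo()` reproduces this
with a rank-power-law multinomial ($p_r \propto r^{-1.4}$ over 804 ranks,
matching a typical chip's 34/13/7/5% leading rates, ~15 distinct names and
~3.2 bits per 31-sample set). The metric therefore has to come from a
smooth fitted model of naming, not from raw counts.

## The response model

Each name $n$ gets an independent unimodal response-rate function over
CIELAB coordinates $z$:

$$Q_n(z) = \gamma g_n + (1-\gamma)\, k_n
  \exp\left(-\tfrac12\left[(z-\mu_n)^\top \Sigma_n^{-1}
  (z-\mu_n)\right]^{\alpha_n}\right)$$

* $k_n \in (0,1]$ — peak response rate;
* $\mu_n$ — peak location (CIELAB, D65/2°);
* $\Sigma_n$ — 3×3 SPD covariance in CIELAB² units, eigenvalues floored at
  $3^2$ so categories cannot be implausibly tight;
* $\alpha_n \in [1, 3]$ — sharpness: 1 is Gaussian falloff, larger values
  plateau near the peak and then fall faster;
* $\gamma = 0.01$ — lapse rate: a stimulus-independent response floor
  allocated in proportion to the global rates $g_n$.

`fit_name()` maximizes the binomial log-likelihood of the observed
per-chip counts minus the penalty $\lambda (k_n |\Sigma_n|)^{0.12}$ with
$\lambda = 100$. The exponent mirrors an empirical law of naming data: the
power-transformed (exponent 0.12) global rates are exponentially
distributed (`rate_law_fit()`), so the penalty acts as a prior that
discourages high, wide response functions for names the data barely
constrains. Fitted rate functions are normalized across the vocabulary,
$P_n(z) = Q_n(z)/\sum_s Q_s(z)$ (`normalize_model()`, `predict()`), giving
a distribution field over the cube.

### Numerical choices in the fit

The optimizer is conjugate-gradient ascent on an unconstrained
parameterization: logistic maps for $k$ and $\alpha$ into their boxes, and
$\Sigma = LL^\top + 3^2 I$ with $L$ log-Cholesky. The additive floor keeps
the objective smooth; spectral clipping after each step would achieve the
same invariant but introduces kinks that CG handles poorly. Five restarts
are used by default: the moment initialization (response-weighted mean and
covariance), a second start centred on the chip with the highest observed
rate, and jittered copies; fits are deterministic given a seed and
independent across names, so results do not depend on fitting order.

The sharpness floor deserves a note. Allowing $\alpha < 1$ admits
"spike plus heavy tail" shapes: the optimizer can collapse $|\Sigma|$ to
the floor (cutting the penalty by hundreds of nats), push $\alpha$ down
and hide a spike between chip locations while the heavy tail carries the
data. That solution beats the generating parameters' objective on every
synthetic dataset we generated while destroying parameter identifiability.
With $\alpha \ge 1$ the falloff is Gaussian or flatter-topped — the shape
the sharpness parameter was introduced to express — and the degeneracy
disappears.

Under the penalty, $k$, $\Sigma$ and $\alpha$ remain jointly only weakly
identified (a slightly wider $\Sigma$ with smaller $k$ fits almost as
well); the peak location $\mu$ and the normalized field $P_n$ are the
well-identified quantities, and rare names (likelihood gain below the
penalty, roughly below a couple of hundred responses at $\lambda = 100$)
are deliberately shrunk toward the lapse floor.

### Model comparison

`model_comparison()` evaluates the multinomial log-likelihood of a table
under three nested models — baseline (global rates at every chip; $N-1$
parameters), fitted ($12N$) and saturated (empirical per-chip frequencies;
$N_{chips}(N-1)$) — and applies the AIC-style rule that a deviance should
exceed the parameter-count difference. On adequately sized synthetic data
the fitted model beats both; on data generated from the baseline the
baseline wins, as it should.

## From model to metric

`categorical_metric()` runs the standard pipeline:

1. normalize the fitted rates to $P_n(z)$;
2. blur each $P_n$ with the separable 5³-point comb filter (spacing
   $\Delta/3$, weights $\tfrac1{12}(1,3,4,3,1)$, spread $0.36\Delta$) and
   renormalize — we blur the *normalized* field rather than the raw rates,
   an ordering the construction leaves open; the alternative is a
   one-line change and differs only at third order;
3. central-difference the square-rooted blurred field along R, G, B with
   step $\Delta$ ($\Delta = 0.1$ sRGB, roughly 10 CIELAB units — the scale
   below which categorical structure is not credibly articulated) to get
   per-axis derivative vectors $d_R, d_G, d_B$;
4. assemble $\Gamma = (d_R\, d_G\, d_B)^\top (d_R\, d_G\, d_B)$, a 3×3 PSD
   tensor, on a grid of spacing $\Delta/2$ for quadratic interpolation at
   query time (`tensor_grid()`, `tensor_at()`).

At the cube faces both the blur probes and the difference probes are
clamped into the cube and the difference normalization uses the actual
probe separation; this keeps $\Gamma$ defined on the closed cube without
inventing out-of-gamut naming behaviour (at a face the derivative becomes
one-sided). Interpolation is separable piecewise-quadratic on the 3³
neighbourhood of the nearest node, componentwise, with PSD clipping of the
result; nodes reproduce stored tensors exactly. Grids round-trip through a
plain-text TSV layout (`write_tensor_grid()`, `read_tensor_grid()`)
documenting spacing and R-fastest node order.

A useful invariance anchors the construction: a complete handover between
two names (rates going from (1,0) to (0,1)) measures exactly one grain
whatever the handover's speed profile, blur and step size, up to
$O(\Delta^2)$, because the sqrt-embedding traverses a quarter circle.

## Analysing the geometry

* `path_length()` integrates $\sqrt{\dot v^\top \Gamma \dot v}$
  (trapezoidal, at a configurable density; lengths are reported raw and in
  grains).
* `categorical_area()` restricts the tensor to each mesh triangle's plane
  (`restrict_tensor()`) and scales Euclidean areas by $\sqrt{\det}$;
  `categorical_volume()` integrates $\sqrt{\det\Gamma}$ by midpoint rule.
* `capacity()` applies the boundary-corrected count
  $C = |R|/G_n + \tfrac12 |\partial R|/G_{n-1}$: regions abutting the
  boundary need only half the usual extent, so a 1-D manifold of 1.7
  grains with two endpoints holds 2.7 categorically distinct colours.
  `cube_capacity()` reports the full cube with and without the correction,
  integrating restricted tensors over all six faces for the boundary term;
  the correction presumes consistently low boundary curvature and is an
  under-estimate otherwise.
* `local_distortion()` compares two metrics by
  $\tfrac12\log_2 (v^\top A v / v^\top B v)$; `global_distortion()` is the
  weighted standard deviation of local distortion over Monte Carlo samples
  (uniform locations; directions $v \sim N(0, C^{-1})$ and weights $|C|$
  with $C$ the SPD geometric mean $A\#B$). We use $A\#B$ itself rather
  than its square — the geometric mean is the self-consistent choice with
  $C = A = B$ at agreement — and with a shared seed the statistic is
  exactly symmetric in the two fields. The default sample count is $10^5$;
  the tests use smaller counts since the quantities asserted are
  invariances, not tight values.
* `embed_1d()` embeds 1-D sub-manifolds isometrically (always possible):
  open paths as arc-length maps, closed paths as circles of radius
  $L/2\pi$ with the first vertex at angle 0, counter-clockwise.
* `laplace_surface()` builds the full colour surface by harmonic extension
  of the full colour locus over a quadrilateral grid (direct sparse solve;
  interior vertices equal the mean of their neighbours to machine
  precision), and `embed_sphere()` places a mesh on a sphere minimizing
  the edge-length-weighted variance of log edge distortion. Because a
  common rescaling of the radius shifts all log distortions equally, the
  variance objective depends only on the placements; the radius is set
  afterwards so the weighted mean log distortion is zero. On the pullback
  metric of a known sphere the embedding recovers the radius to better
  than 1%.

Tensorization of the CIE colour-difference formulas (`cie_tensor_field()`)
uses 13 probe pairs per location — the 3 axes, 6 face diagonals and 4 body
diagonals of the RGB frame — each pair straddling the location at
$\Delta/2$ per side, solving the 13 equations $v^\top T v = d^2$ for the 6
free components in least squares and clipping to the PSD cone. Probe
centres shift inward near faces so all probes stay in gamut. With this
construction the CIE2000 locus-to-axis length ratio evaluates to 2.8,
against 3.5 for Euclidean sRGB; summing raw pairwise CIEDE2000 distances
along the paths instead gives 3.7, because CIEDE2000's non-quadratic local
structure (notably its lightness weighting) does not aggregate to the same
tensor lengths — the tensorized reading is the one consistent with the
rest of the distortion machinery. CIE94 is evaluated with the symmetric
chroma reference $\sqrt{C_1 C_2}$ so that all implemented distances are
symmetric in their arguments.

## What the synthetic data does and does not emulate

`synthetic_naming_model()` builds a ground-truth model of $n$ compact
categories (peak rates 0.4–0.7, axis scales 12–22 CIELAB units, sharpness
1–1.8, peaks spread over the interior of the gamut by greedy maximin) plus
one broad low-informative "other" category. The background stands in for
the long tail of rare names in real data: it keeps $\sum_n Q_n$ near 1
everywhere, so normalization preserves the bump structure. Without it the
normalized field turns isolated bumps into plateau-shaped cells whose
peaks sit tens of CIELAB units from the generating $\mu_n$, and "parameter
recovery" stops being well defined. `synthetic_naming_dataset()` draws
i.i.d. responses per chip from the normalized model over a jittered
8×8×8 chip grid (512 chips, ~30 responses per chip by default) and
arranges them into subject sessions of 20 presentations whose 18th repeats
the subject's 3rd chip, so the cleaning rules and agreement statistics can
be exercised end to end.

What passing tests show: the fitting, tensor and measurement machinery is
self-consistent on data whose generating process matches the model family.
What they do not show: robustness to display variation across subjects,
to name-similarity structure (a response of "dark purple" is as distinct
from "purple" as from "blue"), or to the unseen-name tail of real
vocabularies — none of which the generator emulates.

`toy_category_spec()` / `toy_manifold()` provide the 1-D analogue of the
whole pipeline (Gaussian bumps with optional edge plateaus, exact
Bhattacharyya-angle segment lengths). Three broad "chromatic" categories
give a capacity near 2.7; adding five narrow low-peak "tonal" categories
raises the capacity while evening out the metric (smaller sd of the log2
metric); tonals alone give about 5. The tests assert these orderings, not
the exact figures, since the underlying curves are a parameterized family
chosen once.

## Problem sizes used by the test-suite and acceptance script

The acceptance script estimates the sampling-bias statistics from $10^4$
Monte Carlo pairs and the CIE path ratio from ~1200 path samples; the
parameter-recovery check fits 5 synthetic names on 512 chips × 50
responses; module tests use 4³–6³-chip datasets, 5³–21³ tensor grids and
a few hundred Monte Carlo distortion samples. These sizes put every
stochastic assertion several standard errors from its threshold while
keeping a full run in a couple of minutes on one core.

## Known limitations

* The fitted $k$, $\Sigma$, $\alpha$ are reported as found but should be
  interpreted through the normalized field; only $\mu$ and $P_n$ are
  strongly identified under the penalty.
* Geodesics are not computed; lengths are measured along specified paths.
* Derivatives of the fitted model are numerical (blur + finite
  differences), not analytic.
* The sRGB cube is treated as the colour solid throughout; results near
  the faces inherit the clamped one-sided derivative convention.
* The released-grid import covers this package's own TSV layout; capacities
  and lengths for a *real* population metric require such a grid or a
  fitted model of real data.
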