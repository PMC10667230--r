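---
title: "Modeling calvarial growth from the cranial sutures"
author: "suturegrowth authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling calvarial growth from the cranial sutures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suturegrowth)
```

## The model

The neonatal calvaria is a set of bone plates (left/right frontal,
left/right parietal, occipital) joined by fibrous sutures (metopic,
left/right coronal, sagittal, left/right lambdoid). New bone is deposited
at the sutures, so the head expands perpendicular to them; premature
fusion of a suture (craniosynostosis) blocks growth in that direction and
deforms the head. `suturegrowth` models calvarial development between
birth and 10 years as a smooth, invertible spatial transformation driven
entirely by growth at the sutures plus a displacement of the
calvaria--cranial-base boundary that stands in for the growth of the
facial and basal structures the model does not represent.

Each suture is discretized into control points ("anchors") at
coordinates $x_a$. An anchor carries a locally affine velocity field with
two scalar rates:

* a **growth rate** $v_a(t) > 0$ (1/day) acting through the scaling term
  $v_a(t)\,\langle x - x_a, u_a\rangle\,u_a$, where the unit vector $u_a$
  is tangential to the cranial surface and perpendicular to the suture.
  Because the term is linear in the lever arm $\langle x - x_a,
  u_a\rangle$, points on either side of the suture move apart — bone
  deposition at the suture line. The sign of $u_a$ is immaterial (the
  term is even in $u_a$); it is fixed reproducibly toward the second of
  the two bones the suture separates.
* a **base displacement rate** $z_a(t)$ (mm/day, sign-free) acting along
  the outward surface normal $y_a$, carried only by anchors adjacent to
  the calvaria--cranial-base boundary ring.

Both rates are reciprocals of quadratics in age,
$v_a(t) = 1/(p_0 + p_1 t + p_2 t^2)$, the temporal derivative of a
logarithmic growth profile, matching the semi-logarithmic course of
cranial expansion. The growth-rate denominator must stay positive over
the whole model span; this is validated on a dense 1-day grid whenever a
parameter object is constructed.

The per-anchor fields are combined through a normalized spatial weight
field and integrated:

$$x(T) = x(t_0) + \int_{t_0}^{T}\!\!\sum_a w_l^a(x)\,
  \big[v_a(t)\,\langle x(t) - x_a(t), u_a\rangle\,u_a
  + z_a(t)\,y_a\big]\,dt .$$

Both the point and the anchors are advected by the same combined flow,
the standard locally-affine-combination construction; with a single
anchor it reduces to the per-anchor transform. Integration uses explicit
forward Euler with a 5-day step, and the flow is inverted by integrating
the negated field backward, which converges to the exact inverse at
first order in the step size.

## The area of suture influence

Growth at a suture may only move the two bone plates that the suture
separates (the mapping is derived from label adjacency on the grid, not
hard-coded). The locality field of suture $l$ is
$w_l(x) = e^{-k\,d_l(x)}$, where $d_l(x)$ is the straight-line Euclidean
distance from $x$ to the nearest grid point of the two adjacent bones or
of the suture band itself, so $w_l \equiv 1$ there and decays with rate
$k$ (1/mm) outside. Each anchor then modulates the locality field with a
Gaussian kernel,
$w_l^a(x) = w_l(x)\,e^{-\tfrac12 (x-x_a)^\top \Sigma_l (x-x_a)}$,
creating growth-rate gradients along a suture. $\Sigma_l$ enters the
exponent exactly as written — despite the conventional name "variance
matrix" it acts as a concentration: larger eigenvalues mean a tighter
kernel. By default $\Sigma_l = \sigma^{-2} I$ with a single $\sigma$ and
a single $k$ shared by all sutures (both inferable; full SPD matrices per
suture are accepted by the weight builder). Raw weights are normalized
per grid point to sum to one — the discrete form of the unit-integral
constraint — after zeroing raw values below $10^{-8}$; points whose total
raw weight falls below that threshold are flagged static and never move.
Weights are computed once on the reference geometry and held fixed during
integration, and since the spherical maps place all subjects in one
standardized 2D domain the same weights serve every subject.

## The standardized spherical map

All computation runs on a standardized 2D representation: an azimuth
$\times$ elevation grid where each point stores 3D coordinates (mm) and a
bone/suture label, with anatomical point correspondence across subjects.
Azimuth wraps; elevation row 1 is the cranial-base boundary ring; the
grid stops short of the vertex pole (default 82°) to avoid a degenerate
apex cell. Axis convention: $+x$ left, $+y$ anterior, $+z$ superior.
Surface frames are estimated by central finite differences (periodic in
azimuth, one-sided at elevation edges); on quadric surfaces the interior
normals are exact by symmetry, which the tests exploit as an analytic
oracle.

Anchors are sampled by reducing each suture band (about two grid cells
wide) to a centerline — breadth-first-search levels from a geometrically
chosen end, averaged per level — and placing control points uniformly by
arc length (default spacing 20 mm, endpoint-inclusive so base-touching
sutures anchor at the base ring). The local suture tangent is the leading
principal component of band points within three grid steps; $u_a$
completes it with the surface normal. On a left-right symmetric map each
sampled midline-suture cell also contributes its contralateral twin cell,
keeping the anchor set — and therefore the induced flow — exactly
mirror-symmetric; the rule is label-based, hence rigid-equivariant and
inert on asymmetric subjects.

## Parameter inference

All parameters — per-anchor $p_{v_a}$, per-base-anchor $p_{z_a}$, the
weight-shape pair $(k, \sigma)$, and one rigid nuisance transform
$R(\theta_s)$ per subject — are estimated from a cross-sectional cohort
by minimizing

$$\frac1N \sum_s \frac1M \sum_m \frac{1}{\lVert I_s(m)\rVert_2}
 \big\lVert \Phi^{t_0}(I_0(m), t_s; p) - R(\theta_s)\, I_s(m)\big\rVert_2 ,$$

where $I_0$ is the average birth anatomy and $t_s$ each subject's age
rounded to the Euler step. The size normalization $1/\lVert I_s(m)\rVert$
equalizes subjects of different cranial size; the rigid transform (axis-
angle + translation) absorbs pose-standardization error and is not part
of the model. Because ages share one trajectory of the template, a whole
cohort costs one forward integration per evaluation.

Optimization is Adam (default learning rate 0.01, full batch, hence
deterministic given the configuration) with **analytic adjoint
gradients**: the reverse-mode pass through the Euler recursion is derived
in closed form and implemented alongside the forward kernel, giving exact
gradients with respect to the per-step rates, the weights (through the
normalization, to $k$ and $\sigma$), the rigid parameters (through the
SO(3) right Jacobian) and the initial state. The tests verify it against
fourth-order central finite differences at $10^{-4}$ relative tolerance.

Optimizer parameterization. Adam's step size is roughly the learning
rate per coordinate, so the raw rational coefficients (which span orders
of magnitude in natural units) are optimized in a preconditioned space:
denominators are expressed as
$q(t) = s\,e^{c_0}\,(1 + B c_1 \tau + B c_2 \tau^2)$ with $\tau = t/10\,
\mathrm{yr}$ and $B = 10$. The log-amplitude makes scaling a rate up or
down multiplicative (a null growth rate is reachable in tens of
iterations), and $B$ maps realistic ten-year rate declines (factors of
10–30) to order-one coefficients. Displacement denominators stay affine
in the same scaled coefficients so $z_a$ keeps its sign freedom. The
exported model always carries the literal $(p_0, p_1, p_2)$ triples.
Initialization: $v$ at $5\times10^{-4}$/day and $z$ at $0.02$ mm/day
(order-of-magnitude values for 10% first-year growth with typical 30–40
mm lever arms), $k = 0.5$/mm, $\sigma = 50$ mm, rigids at identity.
Denominator positivity is enforced during optimization by a soft hinge
penalty (margin 0.05 in scaled units, weight 10, 30-day grid) and by a
hard validity check on the returned parameters; a non-finite loss halves
the learning rate and restarts from the last valid state (at most three
times).

The birth template is estimated separately (not jointly) as a
Nadaraya-Watson average of cohort coordinates over age with a Gaussian
kernel centered at birth (bandwidth 90 days) — a defensible choice given
few exact newborns in a cross-sectional cohort.

Personalized prediction starts from a subject's own anatomy: anchor
coordinates and the direction vectors $u_a, y_a$ are recomputed from the
subject's geometry at its observation age (grid correspondence keeps the
anchor locations), the standardized-domain weights are reused, and the
fitted rates are integrated to the target age — with selected sutures
fused ($v_a \equiv 0$, base displacement unaffected) to predict growth in
craniosynostosis.

## Strain analysis

Local expansion between a reference and a deformed configuration is
summarized by the trace of the Green-Lagrange strain computed
intrinsically on the surface: with reference metric $G$ and deformed
metric $C$ from finite-difference tangent vectors,
$\epsilon = \operatorname{tr}\!\big(G^{-1}(C - G)/2\big)$, the
two-tangential-direction realization of
$\operatorname{tr}((\nabla d + \nabla d^\top + \nabla d \nabla
d^\top)/2)$. Normal derivatives of a surface-sampled displacement are
undefined, so the intrinsic convention is the well-posed one; reported
values are comparable within it only. A uniform in-plane stretch by $s$
gives $\epsilon = s^2 - 1$, and any rigid motion gives zero (both are
test oracles). Strain rates are central differences over an age series,
reported per year (365.25 days); per-bone summaries are cell-area
weighted means. The cephalic index is reported as 100 × lateral extent /
antero-posterior extent of the coordinate ranges in the standardized
pose — an extent-based convention rather than landmark-based
euryon/glabella-opisthocranion distances.

## The synthetic cohort generator

Clinical calvarial CT collections cannot be shared, so the package ships
a generator that emulates the standardized representation end to end
with known ground truth. The birth template is an upper-ellipsoid
(semi-axes 49/60/45 mm lateral/AP/vertical, cephalic index 81.7% at
birth, matching normative newborns) with all five bones, six suture
bands — obtained as sign-change cell bands of smooth separating
functions, so they are connected, about two cells thick, and meet the
anatomically correct plates at every tested grid resolution — and the
base ring. Cohorts are produced by integrating the true forward model
from birth to each subject's age (one shared trajectory sampled per
subject), adding iid Gaussian coordinate noise and a random rigid pose
perturbation, both recorded as ground truth.

Default study conditions, chosen once against published head-growth
magnitudes and then left alone:

* true growth rates $v(0)$: 1.0 (metopic, sagittal), 3.0 (coronal), 1.2
  (lambdoid) $\times 10^{-3}$/day, declining 30-fold by 10 years via
  $p_1 > 0$ ($p_2 = 0$); coronal growth fastest, as required for the
  normative antero-posterior-dominant expansion;
* base displacement $z(0) = 0.04$ mm/day declining 10-fold;
* weight shape $k = 0.5$/mm, $\sigma = 50$ mm; anchor spacing 20 mm;
* noise 0.5 mm per coordinate; rigid perturbations up to 5° / 3 mm
  (the scale of pose-standardization error);
* ages from an exponential distribution with mean 1100 days truncated to
  0–3650 days — the young-skewed sampling of trauma-referral cohorts —
  or uniform on request.

Under these conditions a two-year normative simulation grows the
antero-posterior extent by ~20% and the lateral extent by ~15%, and the
cephalic index falls from 81.7% to ~78%, reproducing the clinically
reported decrease through faster coronal growth; by 10 years AP extent
has grown ~42%. The generator does **not** emulate spatially correlated
segmentation noise, sex differences, pathology other than suture fusion,
or the compensatory volume overdevelopment seen in real craniosynostosis
(brain-pressure effects are outside the model), so passing recovery
tests demonstrate correctness of the machinery under the model's own
assumptions, not clinical accuracy on real skulls.

## Numerical choices and study sizes

* Euler step 5 days everywhere (finer steps do not change predictions
  materially; the invertibility tests document the first-order error).
* Denominator floor $\epsilon_{den} = 10^{-4}$, checked on a 1-day grid.
* Weight support threshold $10^{-8}$ (raw); static points move exactly
  zero.
* Anchor centerline ties are broken on quantized distances (1 µm) and
  mirror-invariant geometry so left/right sutures sample identically.
* Recovery studies run on a 36 × 18 grid with 200 subjects, uniform ages,
  0.5 mm noise, and a reduced optimization budget of 400 Adam iterations
  at learning rate 0.03 — the preconditioned space converges in a few
  hundred iterations, and the larger step compensates the shortened
  schedule; the per-suture growth-curve recovery metric weights anchors
  by their influence mass (anchors with negligible weight are not
  identifiable from the flow and a plain mean would count their drift).
* The gradient check compares the adjoint against fourth-order central
  differences at $h = 10^{-3}$ in the scaled space; components below
  $10^{-6}$ gradient magnitude sit at the finite-difference roundoff
  floor and are checked for smallness instead of relative agreement.

## Known limitations

* Suture fusion reduces growth along the fused suture's direction in
  aggregate and wherever that suture dominates the local influence
  weights; at points where several sutures interact, the combined flow
  can redistribute small lateral components in either direction, so the
  reduction is not strictly pointwise.
* Predictions personalize direction frames from the observation-age
  geometry; for trajectories generated with birth-age frames this adds a
  small drift (~0.3 mm/year in the synthetic studies) on top of the
  discretization error.
* The discrete mirror symmetry of the template holds exactly only with
  the contralateral-twin anchor rule; single-cell anchor sets on an
  offset grid would break it at the half-cell scale.
* All headline numbers in this package are computed on synthetic
  calvaria; no claim is made about accuracy on clinical data.

## A short session

```{r session, eval = FALSE}
cfg <- synth_config(seed = 1, n_subjects = 100)
mdl <- synth_model(cfg)                 # template + anchors + weights + truth
cohort <- generate_cohort(cfg, mdl)

template <- estimate_template(cohort)   # kernel average near birth
fit <- fit_growth_model(cohort, template,
                        fit_config(iters = 400, lr = 0.03, seed = 2))
print(fit)

# normative two-year simulation and a sagittal-fusion counterfactual
norm2y <- integrate_flow(fit$template, fit$anchors, fit$weights, fit$vel,
                         flow_spec(0, 730))
scaph <- simulate_synostosis(fit$template, fit$anchors, fit$weights,
                             fit$vel, flow_spec(0, 730),
                             fused_sutures = "S")
cephalic_index(norm2y$map); cephalic_index(scaph$map)

strain <- strain_trace(fit$template, norm2y)
per_bone_average(strain, fit$template)
```
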