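# suturegrowth

Diffeomorphic modeling of pediatric calvarial growth driven by the
cranial sutures, in R.

The calvaria grows because new bone is deposited at the sutures, the
fibrous joints between the bone plates; when a suture fuses prematurely
(craniosynostosis, ~1 in 2100 births) growth perpendicular to it stops
and the head deforms. This package implements a data-driven growth model
for ages 0–10 years in which every anatomical change is explained by
sutural growth: suture control points ("anchors" at positions
`x_a`) carry locally affine velocity fields

```
dx/dt = sum_a w_l^a(x) [ v_a(t) <x - x_a, u_a> u_a + z_a(t) y_a ]
```

with growth rates `v_a(t) = 1/(p0 + p1 t + p2 t^2) > 0` perpendicular to
the suture (unit vector `u_a`, tangential to the surface), a sign-free
cranial-base displacement rate `z_a(t)` along the outward normal `y_a`
at the calvaria–cranial-base boundary, and normalized influence weights
`w_l^a(x) = exp(-k d_l(x)) exp(-(x-x_a)' Sigma_l (x-x_a)/2)` that confine
each suture's effect to the two bone plates it separates. The combined
field is integrated by forward Euler (5-day step) into a smooth,
invertible growth transformation.

All model parameters — per-anchor rate coefficients, the weight-shape
pair `(k, sigma)`, and one rigid nuisance transform per subject — are
inferred from a cross-sectional cohort of labeled calvaria surfaces by
Adam gradient descent on a size-normalized population objective, using
analytic adjoint (reverse-mode) gradients through the discretized flow.
Fitted models predict personalized growth from a single observation,
simulate single-suture craniosynostosis by zeroing the fused suture's
growth rates, and are analyzed via Green–Lagrange surface strain,
per-bone summaries, and the cephalic index.

Calvaria are represented as standardized spherical maps — azimuth ×
elevation grids of 3D coordinates with bone/suture labels and anatomical
point correspondence across subjects. Clinical CT collections of this
kind cannot be shared, so the package includes a first-class synthetic
cohort generator (labeled ellipsoid template, true forward-model growth,
observation noise, rigid pose perturbations) with full ground truth for
parameter-recovery studies.

Intended users: researchers in craniofacial image analysis and
computational anatomy who need an interpretable, simulatable growth
model — as a reference implementation, as a test bed for inference
methodology, or as a phenotype simulator.

## A worked example

```r
library(suturegrowth)

cfg    <- synth_config(seed = 1, n_subjects = 100)
mdl    <- synth_model(cfg)            # template, anchors, weights, true rates
cohort <- generate_cohort(cfg, mdl)

template <- estimate_template(cohort)
fit <- fit_growth_model(cohort, template,
                        fit_config(iters = 300, lr = 0.03, seed = 2))
print(fit)
#> fit_report: loss 0.015823 after 300 iterations; fitting error 0.89 +/- 0.07 mm; k=0.529 sigma=48.9

norm2y <- integrate_flow(fit$template, fit$anchors, fit$weights, fit$vel,
                         flow_spec(0, 730))
scaph  <- simulate_synostosis(fit$template, fit$anchors, fit$weights,
                              fit$vel, flow_spec(0, 730),
                              fused_sutures = "S")
round(c(birth = cephalic_index(fit$template),
        normative_2y = cephalic_index(norm2y$map),
        sagittal_fused_2y = cephalic_index(scaph$map)), 2)
#>             birth      normative_2y sagittal_fused_2y
#>             81.53             80.41             77.07
```

The fitting error is the mean point-to-point distance between the
fitted average model and each (noisy, pose-perturbed) synthetic subject;
with 0.5 mm coordinate noise the floor is about 0.9 mm. The cephalic
index (100 × lateral / antero-posterior extent) of the fitted normative
model decreases from birth to 2 years — faster coronal than midline
growth — while simulated sagittal fusion lowers it further, the
scaphocephaly direction.

The command-line surface wraps the same functions
(`inst/cli/suturegrowth.R` after installation):

```sh
Rscript inst/cli/suturegrowth.R synth --what cohort --seed 1 --out data/
Rscript inst/cli/suturegrowth.R fit --cohort data/ --out model/ --iters 300
Rscript inst/cli/suturegrowth.R predict --map data/subject0001.map \
        --model model/model.json --age-days 730 --out pred.map --mesh pred.ply
Rscript inst/cli/suturegrowth.R evaluate --pred pred.map --obs obs.map
```

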