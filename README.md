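# bggreg

Rigid 2-D registration of grayscale medical images by modelling the
**joint intensity scatter** with a **bounded generalized Gaussian mixture
model (BGGMM)**.

## The problem

Given a reference image $A$ and a floating image $B$ — possibly from
different acquisition physics (MR-T1 vs MR-T2, radiograph pairs) — find the
rigid transform $\theta = (t_x, t_y, \phi)$ that aligns them.  Feature-free,
intensity-based registration handles the multimodal case by modelling the
distribution of joint intensity vectors $I_x^\theta = [A_x; B_x^\theta]$: at
correct alignment the scatter collapses into a few tight clusters.  Here that
distribution is a mixture of generalized Gaussian components

$$p(I\mid\rho)=\sum_{m=1}^{M}\tau_m\,
  \frac{T(I\mid u_m,\sigma_m,\Lambda_m)\,H(I\mid\partial_m)}{\int_{\partial_m}T},
\qquad
T(x)=\alpha\,e^{-\beta|x-u|^{\Lambda}/\sigma^{\Lambda}},$$

truncated ("bounded") to the 8-bit intensity box $[0,255]$ and renormalized —
image intensities live on a finite range, and the truncation is estimated by
Monte Carlo.  The shape $\Lambda$ adapts per component and channel between
Laplace ($\Lambda=1$), Gaussian ($\Lambda=2$) and flatter-than-Gaussian
densities.  Parameters are fitted by expectation–maximization with
Monte-Carlo corrections for the bounded support and a damped Newton step for
$\Lambda$; the motion is updated by solving the linearized normal equations
of the expected log-likelihood, alternating with the EM phase inside a
coarse-to-fine resolution pyramid (scales 0.1, 0.2, 1).  Registration error
against a known truth is reported as **PAD** (average pixel displacement,
mean Euclidean displacement between the two mappings over the pixel grid;
PAD > 3 px counts as failure).

Audience: researchers in medical image analysis who need a transparent,
scriptable reference implementation of BGGMM registration with a synthetic
evaluation harness, not a clinical tool.

## Worked example

```r
library(bggreg)

# a synthetic multimodal pair (T1/T2-style contrast reversal), perfectly
# aligned, plus a known rigid perturbation of the floating image
pair  <- generate_phantom(128, seed = 3, modality = "multimodal")
truth <- rigid_transform(tx = 8, ty = -5, angle = 4)
flt   <- warp_image(pair$floating, invert_transform(truth), fill = 0)$image

res <- register_images(
  image_pair(pair$reference, flt),
  registration_config(components = 6,
                      em = em_config(t1 = 2, mc_count = 1e4, seed = 1),
                      outer_iterations = 8, seed = 1),
  truth = truth)
res
```

```
<registration_result> tx=8.306 ty=-5.141 angle=4.082 deg (converged)
  PAD vs truth: 0.3413 px
```

The estimate recovers the true transform (8, −5, 4°) to a fraction of a
pixel; `res$likelihood_trace` holds the per-level likelihood traces and
`res$level_transforms` the intermediate transforms.  A PAD of 0.34 px is
well under the conventional failure cut-off of 3 px.

Density estimation alone:

```r
X   <- sample_ggd(bgg_component(60, 10, 2), 5000, seed = 1)   # 1-channel data
fit <- run_em(X, kmeans_init(X, M = 1, seed = 2), em_config(t1 = 5, seed = 3))
fit$mixture
```

## Command line

```sh
Rscript -e 'bggreg::bgg_cli()' simulate --out-prefix demo --size 128 --seed 7
Rscript -e 'bggreg::bgg_cli()' register --reference demo_ref.png \
    --floating demo_flt.png --components 6 --seed 7 --out result.json
Rscript -e 'bggreg::bgg_cli()' evaluate --estimated result.json \
    --truth demo_truth.json --shape 128x128
Rscript -e 'bggreg::bgg_cli()' sweep --reference demo_ref.png \
    --floating demo_flt.png --protocol noise --levels 0,0.01,0.02,0.04 \
    --seeds 1,2,3 --out sweep.csv
```

(`inst/cli/bggreg` is an equivalent installed launcher script.)

## Scope

Rigid transforms on 2-D 8-bit grayscale images only; the methods vignette
(`vignettes/bggmm-registration.Rmd`) documents the model, the Monte-Carlo
estimators, every tunable parameter with its default and rationale, what the
phantom generator does and does not emulate, and known limitations.
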