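---
title: "Modeling transient neurogenic foci: renewal, clonal expansion, and 3D spatial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling transient neurogenic foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcdyn)
```

## The system

After an excitotoxic striatal lesion, parenchymal astrocytes with latent
neural-stem-cell potential activate and produce transient proliferative
clusters of progenitors: groups of at least four Ki67+ cells in direct
contact, called Ki67 clusters (KCs). Each KC contains transit-amplifying
progenitors (TAPs, Ki67+ DCX-) and proliferating neuroblasts (prNBs,
Ki67+ DCX+), may be flanked by postmitotic neuroblasts (pmNBs, Ki67- DCX+),
and often retains a dormant, clonally related astrocyte. KCs are born,
mature from TAP-rich to prNB-rich compositions, and exhaust, while the
population as a whole stays in a statistical steady state.

`kcdyn` implements the quantitative machinery for this system in three
layers: a steady-state *renewal model* of KC initiation and exhaustion, a
stochastic *clone-expansion model* of fate choice inside one KC, and *3D
point-pattern statistics* for marked KC patterns. Because the underlying
microscopy reconstructions are not publicly deposited, the package also
ships a first-class *synthetic-data generator* that produces cell tables,
KC tables, and point patterns with the statistical structure the analyses
assume; every analysis stage is tested against it.

## The renewal model

KCs are initiated at a constant rate $r$ (fraction of the standing pool
per day) and live a lifetime $\tau$. Steady state forces initiation to
balance exhaustion; under the default *fixed-lifetime* model,

$$ r = 1/\tau, \qquad \text{age} \sim \mathrm{Uniform}(0, \tau). $$

Two labeling experiments follow directly:

* **Saturating pulse-chase.** A pulse labels every KC alive at pulse
  time. After a chase of $c$ days the unlabeled fraction equals the
  fraction of the pool initiated during the chase,
  $\min(c/\tau, 1)$ — e.g. $4/10.64 \approx 0.38$ for a 4-day chase at
  the default turnover rate of 0.094/day.
* **Heritable lineage labeling.** If induction marks each subsequently
  initiated lineage with probability $p$, the labeling index is
  $\mathrm{LI}(t) = p\,\min(t, \tau)/\tau$: linear rise with initial
  slope $p \cdot r$, plateau $p$ reached at one lifetime.
  `fit_li_curve()` estimates $(p r, \tau, p)$ from LI observations by
  profiled least squares over a hinge-breakpoint grid (0.25-day step),
  with bootstrap standard errors.

An *exponential-lifetime* variant is available
(`renewal_params(lifetime_model = "exponential")`); both variants agree
to first order for chases much shorter than $\tau$. The fixed-lifetime
default reflects the sharp saturation of the observed labeling index
around one lifetime; an exponential lifetime would approach its plateau
much more gradually.

`simulate_turnover()` is the stochastic counterpart: a Poisson initiation
stream at rate $rN$ with per-KC lifetimes, started at the stationary age
distribution and always run past a burn-in of at least three lifetimes
before observation. `brdu_unlabeled_fraction()` and `simulated_li()`
reproduce the two closed forms from simulated event logs, which is how
the package cross-validates its own arithmetic.

The KC/astrocyte ratio integrates activation events over one KC
lifetime, so `activation_rate_from_ratio()` converts a standing ratio to
a per-day activation rate by dividing by $\tau$.

## The clone model

Within a clone (clock starting at astrocyte activation), TAP and prNB
counts $(K, D)$ evolve by a time-inhomogeneous birth-death process:

| event | effect | rate |
|---|---|---|
| TAP division | $K \to K + 1$ | $\lambda_K K$ |
| TAP differentiation | mode-dependent | $\gamma_K(t) K$ |
| prNB division | $D \to D + 1$ | $\lambda_D D$ |
| prNB cycle exit | $D \to D - 1$, $P \to P + 1$ | $\gamma_D(t) D$ |

with power-law differentiation propensities
$\gamma(t) = \gamma_0 t^{\alpha}$, $\alpha \ge 0$ ($\gamma_0$ is the rate
at $t = 1$ day; negative exponents are refused because the propensity
would be unbounded at $t \to 0$). The *accelerated* regime $\alpha > 1$
makes the cumulative hazard diverge, so every clone eventually stops
proliferating. TAP differentiation supports three coupling modes:
division-independent conversion ($K{-}1, D{+}1$; the default), symmetric
differentiating division ($K{-}1, D{+}2$), and asymmetric division
($K, D{+}1$). prNB cycle exit is always division-independent.

Simulation is exact, by thinning: within bounded windows (0.25 d) the
nondecreasing propensities are dominated by their window-end values, and
candidate events are accepted with probability actual/majorant. The core
loop is compiled (Rcpp) because likelihood fitting needs thousands of
trajectories per objective evaluation. `master_equation()` integrates
the forward Kolmogorov equations on a truncated $(K, D)$ lattice with
the identical rates (deSolve, `lsoda`, rtol 1e-8) and serves as the
independent oracle: the test suite requires total-variation agreement
below 0.02 at $10^5$ trajectories on parameter sets spanning all three
coupling modes. Probability leaking off the lattice is tracked; results
with boundary mass above $10^{-6}$ are flagged unreliable rather than
silently returned.

`sample_kc_snapshot()` observes independent clones once each at ages
drawn uniformly over one KC lifetime — the cross-sectional sampling
implied by steady-state turnover — and filters snapshots below the
4-cell KC definition, reporting the filter counts. Whether the real
observation scheme weighted ages by clone survival is not recoverable
from the published material; the uniform law is the declared default.

`fit_clone_model()` fits parameters by simulated maximum likelihood:
observed TAPs-per-KC and prNBs-per-KC counts are scored against
categorical distributions estimated from snapshots, with common random
numbers (a fixed simulation seed per objective evaluation) so the
Nelder-Mead search over log/sqrt-transformed parameters sees a smooth
surface. Bootstrap confidence intervals resample KCs *and* refresh the
simulation seed per replicate, so they reflect sampling and Monte-Carlo
noise together. Parameters whose ±30% profile moves the likelihood by
less than 0.05 are reported as non-identifiable rather than returned as
silent point estimates. `compare_variants()` ranks fitted variants by
AIC and reports differences below 2 as ties — with the consequence,
mirrored in the tests, that constant- versus accelerated-propensity
variants are distinguishable at realistic sample sizes while TAP
coupling modes may legitimately tie.

Default rates (`clone_params()`) are a calibration choice, not fitted
constants: they produce snapshot populations with sizes mostly in the
observed 4-38 range (mean near 12) and a median prNB fraction that rises
with size, matching the qualitative maturation crescent. The known
deviation regime of this model class — very small and very large KCs,
respectively over- and under-represented relative to data because late
prNB dispersal and KC fusion are not modeled — is documented here and
deliberately not asserted numerically.

## Spatial statistics

KC centroids form a 3D point pattern in an observation region (box,
spherical shell around a lesion border, or voxel mask). The package
uses:

* **$G(r)$, the nearest-neighbor distance CDF**, with *no edge
  correction*: inference is by Monte-Carlo envelopes, comparing the data
  with `n_sim` (conventionally 999) complete-spatial-randomness
  simulations of the same $n$ in the same region through the identical
  estimator, which makes the test exact without correcting the
  estimator. The global p-value ranks an integrated deviation statistic
  (mean absolute deviation of $G$ from the null mean over the $r$ grid;
  maximum deviation available as an option) among the simulations:
  $p = (k+1)/(n_\mathrm{sim}+1)$, so the smallest achievable p is
  $1/(n_\mathrm{sim}+1)$.
* **Moran's I** for numeric or 0/1-coded marks (size, prNB fraction,
  pmNB association), with significance from random permutations of
  marks over positions; the two-sided p doubles the smaller tail and is
  capped at 1. The permutation-null mean is $-1/(n-1)$. The weight
  scheme behind the published analysis is not stated; the default here
  is row-standardized inverse distance with cutoff twice the mean
  nearest-neighbor distance, with k-nearest-neighbor and user-supplied
  matrices as alternatives — a declared substitute, not a
  reconstruction.
* **Fisher pooling** across specimens ($-2\sum\log p_i$ against
  $\chi^2_{2k}$), again a declared choice where the original pooling
  method is unstated. Zero p-values are refused; Monte-Carlo p-values
  are bounded below by construction.
* **`distance_to_nearest_kc_test()`**: one-sided Wilcoxon rank-sum
  comparison of query-to-nearest-KC distances (e.g. isolated Ki67+
  singles/pairs/trios) against KC-to-KC nearest-neighbor distances,
  testing whether new activations avoid existing foci.

Both the envelope test and the Moran permutation test are calibrated in
the suite: over 200 null replicates their rejection rate at
$\alpha = 0.05$ must fall inside the binomial 99% band.

## The synthetic generator

`gen_specimen()` composes three generators into a specimen mirroring a
reconstructed tissue block:

* **Point patterns** (`gen_point_pattern()`): CSR (the envelope null),
  plus Thomas-cluster and hard-core fixtures whose only purpose is to
  give tests patterns with known departures from randomness.
* **Compositions** (`gen_kc_composition()`): KC sizes from an
  integer-rounded truncated law on [4, 38] calibrated at construction to
  the printed mean 11.8 and SD 7.6. The calibration prioritizes the
  mean and is exact for the default truncated-gamma family. A truncated
  normal is also offered, but on this support it provably cannot reach
  an SD of 7.6 once its mean is held at 11.8 (the SD saturates near
  6.9), which is why the gamma family is the default. Types follow a
  0.25/0.50/0.25 mixture of pure-TAP, mixed, and pure-prNB KCs ("about
  half pure", with the unprinted pure split divided evenly); pmNB
  association is logistic in prNB fraction and size; a dormant
  astrocyte accompanies 75% of KCs.
* **Labels** (`gen_labeled_population()`): KC ages drawn from the
  stationary age law, maturation advancing linearly with age (expected
  prNB fraction $= \mathrm{age}/\tau$ — the published material shows
  ordinal progression only, so linearity is the simplest declared
  coupling), and label states implied by the renewal model: pulse labels
  only KCs older than the chase; heritable reporters label only KCs
  initiated after induction, with per-lineage probability (0.361 for
  the single-color reporter) or the printed per-color recombination
  fractions (2.4/1.2/1.7%). Partially recombined lineages are modeled
  by a 1-/2-/3-cell recombination-stage mixture.

Member cells are grown in a contact-connected ball around each centroid
(every cell within 0.6 contact radii of an earlier cell), and centroids
come from a hard-core process with minimum separation
$2 r_\mathrm{KC} + r_\mathrm{contact}$, so `detect_kcs()` recovers the
emitted KC table exactly; configurations that violate this geometry
surface a warning in the bundle metadata. Contact itself is a Euclidean
ball of 12 um (about a soma diameter) standing in for the
image-morphological "direct contact" of the original reconstructions.

What the generator does *not* emulate: image stacks, vascular or
anatomical structure, intensity-based marker calls, spatially varying
KC density, or KC fusion. Tests passing on synthetic specimens therefore
validate the statistical machinery, not the segmentation or registration
steps that produce real cell tables.

## Numerical choices and problem sizes

* Size-law calibration: Nelder-Mead on the exact discrete moments of the
  rounded truncated law, mean weighted 25:1 over SD; deterministic.
* Maturation class cutoffs: prNB-fraction tertiles $(0, 1/3]$,
  $(1/3, 2/3]$, $(2/3, 1)$; the original bin edges are unpublished, so
  tertiles are the parameter-free stand-in, exposed as code rather than
  hidden constants.
* Hinge fitting: breakpoint profiled on a 0.25-day grid; ties broken
  toward the smaller residual sum of squares encountered first (grid
  order); all observations on the rising limb flag the plateau as
  unidentifiable.
* Master-equation truncation: boundary mass (outermost rows/columns plus
  integration leak) below $10^{-6}$ required for a result to be marked
  reliable.
* Degenerate inputs fail loudly: coincident points warn, constant marks
  refuse Moran's I, zero KCs flag the labeling index as undefined rather
  than returning 0, empty observed distributions refuse fitting, and
  infeasible hard-core packings error instead of looping.
* Every stochastic function is a pure function of (parameters, seed):
  the global RNG state is saved and restored around each call.

Test problem sizes are chosen to keep the full suite fast while leaving
Monte-Carlo error well below the asserted tolerances: $10^4$ KCs for
composition summaries, $10^5$ trajectories for simulator-oracle
agreement, 200 replicates for calibration bands, and reduced KC counts
(800-1500) with bootstrap resampling for fitting checks. These sizes are
the package's own choices and are stated in the tests themselves.

## Known limitations

* The exact derivations behind the published lifetime (10.6 ± 2.1 days)
  and the published propensity parameterization live in supplementary
  material that is not part of the text this package was built from;
  the `f/chase` linearization and the $\gamma_0 t^{\alpha}$ form are
  declared approximations in their place.
* Absolute time units of the clone model are not identifiable from a
  single cross-sectional snapshot; fits constrain rate *ratios* far
  better than rates, and the profile diagnostics in
  `fit_clone_model()` will flag this honestly.
* No inhomogeneous-intensity null models (density-varying CSR), no
  K/L-functions, no 2D section-wise analyses, and no spatial embedding
  of clones.

## A worked pass through the pipeline

```{r pipeline, eval = FALSE}
cfg <- run_config(seed = 1, n_kc = 120, analyses = c("spatial", "turnover"),
                  n_sim = 199, n_perm = 199, output_dir = "kcdyn_run")
res <- run_pipeline(cfg)
res$spatial          # G envelope + Moran's I per mark
res$manifest$stages  # per-stage status and timing
```

The manifest (JSON) records the seed, configuration, package version,
per-stage status, and the md5 of every output, which is sufficient to
regenerate any artifact from the configuration alone.
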