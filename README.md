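# kcdyn

Clonal dynamics and 3D spatial statistics of transient neurogenic foci.

After an excitotoxic striatal lesion in mice, parenchymal astrocytes with
latent neural-stem-cell potential activate and build transient clusters of
proliferating progenitors — Ki67 clusters (KCs): groups of at least four
Ki67+ cells in direct contact, containing transit-amplifying progenitors
(TAPs, Ki67+ DCX-) and proliferating neuroblasts (prNBs, Ki67+ DCX+).
`kcdyn` is an R package for the quantitative side of this biology, aimed
at researchers analysing lineage-traced, pulse-chased, or 3D-reconstructed
progenitor-cluster data:

* **Steady-state renewal model** of KC turnover. KCs are initiated at
  rate *r* (fraction of pool per day) and live a lifetime *τ*; at steady
  state *r* = 1/*τ* and pool ages are uniform on [0, *τ*]. Closed forms
  follow for the unlabeled-KC fraction after a saturating pulse-chase,
  min(*c*/*τ*, 1), and for the lineage labeling index after induction,
  LI(*t*) = *p*·min(*t*, *τ*)/*τ* (slope *p·r*, plateau *p*), plus a
  stochastic population simulator and a hinge-regression estimator
  (`fit_li_curve()`) for (*p·r*, *τ*, *p*).
* **Stochastic clone-expansion model** of fate choice inside one KC:
  TAP/prNB counts evolve by a time-inhomogeneous birth-death process with
  division rates λ_K, λ_D and power-law differentiation propensities
  γ(t) = γ₀·t^α (accelerated for α > 1), with selectable
  division-coupling variants. Exact simulation by thinning (compiled
  core), an independent master-equation oracle, snapshot sampling under
  the steady-state age law, simulated-likelihood fitting, and AIC model
  comparison.
* **3D point-pattern statistics** for marked KC patterns: nearest-neighbor
  G function with Monte-Carlo complete-spatial-randomness envelopes,
  Moran's I with permutation nulls, Fisher pooling across specimens, and
  a rank-sum test for whether new activations avoid existing foci.
* **Synthetic-data generator** producing cell tables, KC tables and point
  patterns with the statistical structure the analyses assume (calibrated
  size law, maturation-age coupling, label states implied by the renewal
  model), so the whole pipeline is testable without the unreleased
  microscopy reconstructions.

## Worked example

```r
library(kcdyn)

# a synthetic specimen: 120 KCs in a 1200-um block
sp  <- gen_specimen(specimen_config(n_kc = 120, seed = 1))
det <- detect_kcs(sp$cells, contact_radius = 12)
table(det$kcs$kc_type)
#>      prNBs-only       TAPs-only TAPs+prNBs_High  TAPs+prNBs_Low  TAPs+prNBs_Med
#>              37              27              11              29              16

# are KC centroids compatible with complete spatial randomness?
pat <- point_pattern(det$kcs[, c("x", "y", "z")], sp$region)
csr_envelope(pat, n_sim = 199, seed = 2)
#> <kc_envelope: mad statistic, 199 sims, p = 0.5>

# is KC size spatially autocorrelated?
morans_i(pat, marks = det$kcs$size, n_perm = 199, seed = 3)
#> <kc_moran: I = -0.0179 (E[I] = -0.0084), p = 0.98, 199 perms>

# renewal arithmetic and the labeling-index curve
rp <- renewal_params()           # rate 0.094/day
rp$lifetime                      # 10.64 days
expected_unlabeled_fraction(4, rp)
#> [1] 0.376                      # expected BrdU-negative KCs after 4 days

fit_li_curve(c(0, 4, 14, 20, 28), c(0, 0.094, 0.335, 0.361, 0.361),
             n_boot = 199, seed = 4)
#> <kc_li_fit: slope 0.02401/d, breakpoint 15 d, plateau 0.3602>
```

The simulated specimen is drawn with 120 KCs, so detection recovering
exactly 120 with zero leftover singles/pairs/trios confirms the contact
geometry; the envelope p of 0.5 and a Moran's I near its permutation-null
mean −1/(n−1) say the generated pattern is, as designed, random in space
and unmarked by location. The LI fit reads the initiation-rate-times-
labeling-probability slope (0.024/day), the saturation breakpoint (≈15 d
for this profile) and the plateau (0.36) off a five-point labeling-index
curve.

A full run — generation, detection, spatial and turnover analyses, tidy
CSV outputs and a JSON provenance manifest — is one call:

```r
res <- run_pipeline(run_config(seed = 1, n_kc = 120,
                               analyses = c("spatial", "turnover")))
```

See the methods vignette (`vignettes/kc-dynamics.Rmd`) for the models,
their assumptions, parameter meanings and defaults, and design decisions.

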