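---
title: "Methods: multispecies population assessment from camera traps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multispecies population assessment from camera traps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistical machinery it
implements: the SECR likelihood and its variants, the companion
estimators, the synthetic study generator that stands in for field data,
and the numerical and design choices that a maintainer would want spelled
out. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The SECR model

Each individual is assumed to hold a latent activity center; the chance of
recording it at a camera decays with the distance $d$ between camera and
center as a half-normal,

$$p(d) = g_0 \exp(-d^2/2\sigma^2) \quad\text{or}\quad
  \lambda(d) = \lambda_0 \exp(-d^2/2\sigma^2),$$

the first for a *Bernoulli* proximity detector (at most one detection per
individual, camera and 30-day occasion), the second for a *count* detector
(Poisson counts per occasion — appropriate when capture rates run far
above one event per occasion, as for the elephant-like preset with up to
~46 events per individual). Camera effort $e_{ks} \in [0,1]$ (the fraction
of occasion $s$ camera $k$ was filming; downtime is read from the activity
log) enters the Bernoulli model as an exponent,
$p_{ks} = 1-(1-p)^{e_{ks}}$, and the count model as a rate multiplier.
An optional per-camera coverage covariate offsets the detection intercept
on its link scale by $\log(\text{coverage})$.

Activity centers follow a homogeneous Poisson process with intensity
(density) $D$ over a habitat mask: a lattice of cells covering the camera
bounding box plus a buffer, with cells outside habitat polygons excluded.
The full likelihood, with classes $c$ (see below), class intensities
$\psi_c$, cell area $a$, and known-class weights $w_{ic}$, is

$$\log L = -\Lambda(\theta)
  + \sum_i \log\Big( a \sum_m \sum_c w_{ic}\, \psi_c\,
  \Pr(\omega_i \mid m, \theta_c) \Big), \qquad
  \Lambda = a \sum_m \sum_c \psi_c\, p^{\cdot}_c(m),$$

where $p^{\cdot}_c(m)$ is the probability an individual centered at cell
$m$ is detected at least once. Under the `binomial` n-distribution the
number of centers in the mask is fixed at $N = DA$ instead, replacing the
Poisson n-term (the two agree in the rare-detection, large-$N$ limit; a
property test checks this convergence).

### Variants and classes

* `null` — one $D$, one $(g_0, \sigma)$; 3 parameters.
* `sex` / `group` — density and detection split by a known two-level
  class (sex, or solitary-vs-group-living); 6 parameters. Individuals of
  unknown class are marginalized over both classes with their
  density-implied weights.
* `sexhet` / `grouphet` — additionally a 2-class latent finite mixture on
  detection, as link-scale offsets $(\delta_{g_0}, \delta_{\sigma})$
  shared across known classes plus one mixing proportion; 9 parameters.
  With the mixing proportion pinned at 1 the model collapses exactly to
  its 6-parameter parent (unit-tested).

Class-structured variants model the observed class labels (the likelihood
is that of a marked point process, the mark probabilities implied by the
class intensities). An AICc comparison against the unmarked `null` model
therefore includes the label-probability term, which penalizes class
models; this matches the behavior of the established SECR software the
parameter counts mirror, and keeping the null at 3 parameters precludes
the alternative of adding a sex-ratio parameter to every model.

### Numerics

* **Link scales:** $\log D$, $\mathrm{logit}\, g_0$ (Bernoulli) or
  $\log \lambda_0$ (counts), $\log \sigma$, logit mixing proportion.
* **Mask:** buffer defaults to $4 \times$ RPSV, where RPSV is the root
  pooled spatial variance of detection locations about individual
  centroids (the package's data-driven proxy for $\sigma$; defined with
  the pooled x+y sum of squares over $\sum_i (n_i - 1)$). Spacing defaults
  to roughly $\hat\sigma/2$: with a buffer deep enough that the integrand
  vanishes at the mask edge, the lattice-sum error of the likelihood is
  far below reporting precision (a refinement-invariance test asserts
  $|\Delta \log L| < 10^{-6}$ under halved spacing), while keeping masks
  in the hundreds of cells so that a model fit takes seconds. A much
  finer default (e.g. buffer/30) changes third-decimal digits of nothing
  that is reported but makes replicated validation studies an order of
  magnitude slower.
* **Optimizer:** `nlminb` quasi-Newton on the link scale with box
  constraints ($D$ in $[10^{-4}, 10^3]$/km², $\sigma$ in 50 m–50 km) so
  sparse data cannot send the fit to infinity; up to three deterministic
  jittered starts are screened at loose tolerance and the best is
  polished at `rel.tol` $10^{-9}$. Starts: $D$ from $n/A$ split by
  observed class counts, $g_0 = 0.05$, $\sigma$ from RPSV; the latent
  class starts well-separated ($\delta_{g_0} = -1.5$, mix 0.7), since a
  symmetric start makes the mixture locally unidentifiable. Fits at a
  box bound are flagged non-converged.
* **Uncertainty:** SEs from the inverse numerical Hessian; Wald intervals
  on the link scale back-transformed, and the derived total density
  $D = \sum_g D_g$ gets a delta-method SE with a log-normal-style
  asymmetric interval.

### Derived quantities

Region abundance is $\hat D \times$ area with the density interval scaled
by area. The circular 95% home-range radius is
$r_{95} = \sigma \sqrt{\chi^2_{0.95}(2)} \approx 2.4477\,\sigma$ with area
$\pi r_{95}^2$ (reported in km²; all area conversions happen in one
place). Precision is the entire 95% CI width divided by the estimate,
reported as a rounded percent.

## Companion estimators

**TIRM.** Capture counts per identified individual are modeled as a
two-component Poisson mixture (proportion $q$ "easy" at rate
$\alpha\lambda$, the rest at $\lambda$), with $N-n$ unobserved zero-count
individuals; $N$ is profiled in unit steps (a coarse pass plus local
refinement) and the CI is a parametric-bootstrap percentile interval
(default 200 replicates, seed 17; bootstrap profile searches are bounded
at $3\hat N$ since bootstrap populations have size $\hat N$). At
$\alpha = 1$ the likelihood reduces exactly to the single-rate model
(unit-tested); all-singleton data pin $\hat N$ at the search bound and are
flagged unidentifiable. The degenerate all-counts-equal case falls back to
the single-rate model with a warning.

**Sociality.** The co-detection rule links individuals captured on one
camera within 15 minutes (inclusive — "within" is read inclusively);
groups are the transitive closure (union-find, with component ids ordered
by smallest member). Whether a burst A–B–C chains through B is immaterial
for the partition, though edge lists can differ; only the closure is used
downstream. The anchored composition rule intentionally counts anonymous
rows in a clip as distinct animals: it is a *minimum* group size.
Residency uses observed capture periods; individuals present in fewer
than two biweeks are `unclassifiable` rather than forced into a class,
and waiting times strictly between the thresholds are `intermediate`.

**Ranging.** MCP areas use the convex hull of detection-camera locations
(degenerate hulls are flagged, not filtered). The sex-effect LM uses the
full-vs-null F test with df $(2, n-4)$; the LMM (random intercept per
group, ML fit) uses a likelihood-ratio test on 2 df, replacing MCMC-based
p-values of a deprecated package generation — the headline inference is
the full-vs-null comparison either way. Observation counts are
log-transformed then z-scored with the sample ($n-1$) standard deviation.

**Reliability.** The exact Wilcoxon distribution is built by convolution
over doubled mid-ranks, which is arithmetically identical to enumerating
all $2^n$ sign assignments (checked against explicit enumeration for
random tie patterns); zeros are dropped and reported as ties, and the
two-sided p doubles the smaller tail, capped at 1 — the convention of the
small-sample tables this field cites. The Friedman statistic carries the
tie correction; with no ties it equals the textbook statistic.

## The synthetic study generator

The generator emulates the study conditions the analyses assume: a 60-km²
grid of 1-km² cells with 45 cameras (one per occupied cell), 20 occasions
of 30 days, camera downtime (one gap of 15–45 days with probability 0.3
per camera), identification success applied per visit (anonymous rows are
emitted as `UNID` so identification-rate summaries remain computable), and
three presets with densities 1.72, 1.2 and 1.37 individuals/km², male to
female ratios 1:2.1, 1:3.2 and 1:2, and identification rates 42%, 22% and
43%. Detection intercepts were calibrated once so that simulated data
volumes match the emulated study's reported ones (~1045/471/2237 visits,
~439/103/963 identifications, on the order of 123/52/139 identified
individuals); spatial scales come from the species' home-range sizes
(e.g. a ~41 km² circular range corresponds to $\sigma \approx 1475$ m).

Three social systems, three observation models:

* **Fission–fusion** (chimpanzee-like): four communities hold contiguous
  adjacent territories tiling the region — community membership is
  assigned from a spatially jittered quadrant rule so realized density
  stays exactly uniform while territories overlap at boundaries.
  Detections are individual-level Bernoulli; each detection co-captures a
  given community member with probability $0.06 \times h_j(k)$, where
  $h_j(k)$ is that member's own half-normal kernel at the camera. The
  0.06 reflects party-size arithmetic (the chance a *specific* community
  member is in the detected party, roughly party size over community
  size, times capture-given-co-travel), and the kernel damping prevents
  the unrealistic teleporting of distant mates to a camera.
* **Stable one-male groups** (gorilla-like): groups of a silverback,
  ~1–6 adult females and adolescents, plus solitary males. Observation is
  a two-level *group-passage* process: the group passes a camera as a
  Poisson count process with half-normal decay from the group center, and
  each present member is captured with probability 0.5 (cohesion) given a
  passage. This keeps every member's marginal spatial kernel exactly
  half-normal — per-member co-trigger schemes instead give co-captures an
  $h^2$-shaped kernel that shrinks $\hat\sigma$ and biases density —
  while inducing the within-group detection correlation that inflates
  variance for group-living species.
* **Core groups plus solitary males** (elephant-like): female core groups
  of 2–4 (same passage model, cohesion 0.45), all males and 35% of
  females solitary, and a resident/nonresident mix: 65% of individuals
  are year-round residents, the rest occasional users present in any
  occasion with probability 0.12. Intermittent revisiting, rather than a
  single contiguous window, is what can generate the long between-capture
  waiting times (≥ 15 biweeks) that define nonresidents; a single pass
  concentrates captures in adjacent periods.

Unweaned juveniles and infants are attached to groups and appear only
through group passages or co-capture; the capture-history builder's
weaning filter (`age_class` in adult/adolescent, standing in for the
">6 years" criterion that individual records cannot express) excludes
them from all SECR analyses.

**What the estimand is under transience.** A closed-population SECR model
applied to a population with intermittent presence estimates the
time-averaged density of individuals actually present, not the
superpopulation: the truth bundle therefore reports `D_available`
$= D(r + (1-r)\,v)$ for resident fraction $r$ and availability $v$
(equal to $D$ when everyone is resident), and parameter-recovery
experiments compare fitted intervals against it. Treating the
superpopulation as recoverable would demand information the data do not
contain.

**Which variant is "correct" per preset.** The chimpanzee preset's
marginal detection classes are the sexes (`sex`); the gorilla preset's
are group-versus-solitary (`group`), with the group/solitary label taken
sex-aware from the co-detection graph (singleton females are group
animals that were never co-identified — labeling them solitary injects
class heterogeneity); the elephant preset adds the latent
resident/transient availability split, which is exactly a two-class
mixture on the detection intercept (`sexhet`). The latent-mixture
variants are fragile on sparse data (the gorilla-scale latent class can
escape to a degenerate optimum), which is why the mixture is reserved for
the preset whose generating process contains a genuine latent class.

**What the generator does not emulate.** Movement is not simulated
(activity centers are static; no Ornstein–Uhlenbeck paths or
step-selection), habitat does not modulate density, identification errors
are misses only (no false matches), and group membership is fixed for the
study (no transfers). Passing recovery tests therefore demonstrates the
estimator chain under the *assumed* data-generating structure plus the
social-correlation violations described above — not robustness to every
failure mode of real camera-trap data.

## Validation scale

The replicated checks in the test suite use sizes chosen to exercise the
full study geometry while keeping a complete run on one CPU comfortably
inside a half hour: 50 replicates per preset for density-interval
coverage (masks of roughly 400–900 cells, spacing 700–1200 m), 15
replicates with 59 bootstrap draws for TIRM recovery, 200 random graphs
against a BFS oracle for grouping, 200 null simulations for the F-test
calibration, and exhaustive enumeration oracles for the SECR likelihood
(≤ 2 detectors × 2 occasions × 6 cells) and the Wilcoxon distribution
(n ≤ 10). Coverage of nominal 95% intervals is asserted at ≥ 85% across
replicates, the slack reflecting the deliberate social-correlation
misspecification in the generator.

## Known limitations

* Density is homogeneous over the mask; no inhomogeneous surfaces.
* No behavioral (trap-response) effects; no open-population dynamics.
* The latent mixture shares its offsets across known classes — the
  9-parameter layout — so class-specific heterogeneity magnitudes are not
  estimable.
* Group-living species violate the independence assumption; intervals
  for such presets are honest about it only through the coverage slack
  described above (variance inflation is visible, e.g., in the gorilla
  preset's wide intervals).
* TIRM model choice (single-rate versus two-rates) is reported as a
  diagnostic, not tested formally.
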