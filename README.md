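# camsecr

Sociodemographic population assessment of elusive, individually
identifiable mammals from camera-trap video records.

Wildlife managers monitoring species such as chimpanzees, gorillas and
forest elephants need more than a density number: they need abundance with
defensible uncertainty, social structure (how many communities or groups,
their size and age–sex composition), residency patterns, home-range
summaries, and evidence that individual identification from footage is
reliable enough to be delegated to locally trained staff. `camsecr`
implements that whole workflow around maximum-likelihood spatially explicit
capture–recapture (SECR), for study designs of the "one camera per 1-km²
grid cell, 30-day occasions" type.

## What is inside

**SECR core.** Detections of individual *i* at detector *k* are modeled
through a latent activity center with half-normal detection,

```
p(d) = g0 · exp(−d² / 2σ²)        (probability, Bernoulli detector)
λ(d) = λ0 · exp(−d² / 2σ²)        (encounter rate, count detector)
```

integrated over a discretized habitat mask (buffered camera array, with
nonhabitat such as sea and lagoon removable via GeoJSON polygons). The full
Poisson-process log-likelihood

```
log L = −Λ(θ) + Σᵢ log ( a Σₘ Σ_c w_ic ψ_c Pr(ωᵢ | m, θ_c) )
```

is maximized on the link scale (`log D`, `logit g0`/`log λ0`, `log σ`).
Model variants mirror the standard heterogeneity ladder: `null`, `sex`
(density and detection split by sex), `sexhet` (sex plus a 2-class latent
finite mixture on detection, 9 parameters), and `group`/`grouphet` with
solitary-versus-group-living as the known class. Camera effort (partial
occasions) enters as an exponent (Bernoulli) or rate multiplier (counts);
per-species camera coverage can offset the detection intercept. AICc model
tables, expected abundance over a region, the circular 95% home-range
radius `σ·√χ²₀.₉₅(2)` and the precision metric (CI width / estimate) are
derived from fits. The likelihood kernel is in C++ (Rcpp).

**Comparison estimators.** The two-innate-rates model (TIRM) estimates
abundance from capture-count frequencies alone (two latent capture-rate
classes, profile likelihood over N, parametric-bootstrap CI), and
`naive_density()` divides abundance by sampled area.

**Social structure.** Individuals co-captured on the same camera within 15
minutes are linked; transitive closure of that graph defines social units.
Minimum group size and age–sex composition follow the anchored-clip rule
(tally everyone seen with the anchor male, take per-class maxima across
clips). Elephant-style residency splits a year into 26 biweeks and
classifies individuals by mean waiting time between capture periods
(≤ 5 resident, ≥ 15 nonresident).

**Home ranges.** Minimum convex polygons over detection cameras, and
sex-effect models on log range size: an LM with full-vs-null F test
(fission–fusion species) and a random-intercept LMM with a likelihood-ratio
test (group-living species).

**Reliability.** Cohen's kappa against a gold standard, exact Wilcoxon
signed-rank matched-pairs tests (full sign enumeration with mid-ranks and
zero-dropping), tie-corrected Friedman tests, and chi-square tail
utilities.

**Synthetic studies.** A generator that emulates a 45-camera, 60-km²,
20-occasion study for three social systems — fission–fusion communities,
stable one-male groups, and female core groups with solitary males and a
resident/transient mix — including identification failure (anonymous
`UNID` visits), camera downtime, and co-capture of group mates. Every
pipeline stage is testable against known truth without any field data.

## Worked example

```r
library(camsecr)

scenario <- default_scenarios()$chimpanzee       # D = 1.72 /km², 1:2.1 M:F
dataset  <- simulate_dataset(scenario, seed = 1)
history  <- build_capture_history(dataset$records, dataset$cameras,
                                  dataset$occasions, dataset$effort)
history
#> capture_history: 137 individuals, 45 detectors, 20 occasions, 327 detections
identification_rate(dataset$records)$percent
#> [1] 42

mask <- build_mask(dataset$cameras, suggest_buffer(history), spacing_m = 700)
fit  <- fit_secr(history, mask, secr_spec("sex", "bernoulli", "binomial"))
fit
#> secr_fit: sex ( bernoulli , n ~ binomial )
#>   D = 1.646 /km^2 (1.373-1.973), logLik = -1613.0, k = 6, AICc = 3238.7

ab <- region_abundance(fit, 60)  # expected N on the 60 km² camera grid
sprintf("N = %.0f (%.0f-%.0f)", ab$N, ab$lcl, ab$ucl)
#> [1] "N = 99 (82-118)"
precision(fit$derived$D, fit$derived$lcl_D, fit$derived$ucl_D)$percent
#> [1] 36

groups <- assign_groups(build_codetection_graph(dataset$records))
groups
#> group_assignment: 23 multi-member groups, 64 solitary individuals
```

The fitted density interval (1.37–1.97 /km²) covers the generating truth of
1.72 /km²; the identification rate reproduces the configured 42%; and the
co-detection components recover fragments of the four simulated
communities (fragments, because only 42% of visits are identified). The
precision of 36% is what a single synthetic survey of this intensity
supports.

A thin command-line wrapper with `simulate`, `assess` and `reliability`
subcommands is installed at `inst/cli/camsecr.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/camsecr.R", package="camsecr"))')" \
    simulate --species gorilla --dir data/ --seed 7
```

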