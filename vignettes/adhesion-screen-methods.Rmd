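---
title: "Methods: simulating and analysing siRNA adhesion screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing siRNA adhesion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhescreen)
```

# The screen and its latent model

A genome-scale siRNA adhesion screen asks which host genes an adherent
bacterium needs on the epithelial surface: silence every gene in turn,
let fluorescently labelled bacteria adhere to the monolayer, and look for
wells where adhesion drops. The raw readout of a well is the
**bacteria-to-nuclei ratio** `bac_nuc_ratio`: the number of labelled
bacterial objects (subobjects, green channel) divided by the number of
DAPI-stained nuclei (main objects, blue channel).

`adhescreen` models the well-level biology with a small latent model. Every
gene $g$ carries an adhesion effect $e_g \in [0,1]$, the fraction by which
*complete* silencing reduces adhesion; non-receptor genes have $e_g = 0$.
Every siRNA duplex $i$ has a knockdown efficacy $k_i \in [0,1]$. The
adhesion multiplier of a well is

$$ m = (1 - e_g \, k_{\mathrm{eff}}) \cdot \varepsilon,
   \qquad \varepsilon \sim \mathrm{LogNormal}(-\sigma^2/2, \sigma), $$

where $\varepsilon$ is a unit-mean, two-sided off-target noise term (screens
show wells with *increased* as well as decreased adhesion, so the noise must
be multiplicative and symmetric on the log scale). For pooled wells that
carry all duplexes of a gene, the default combination rule is independent
action, $k_{\mathrm{eff}} = 1 - \prod_i (1 - k_i)$; a `"max"` alternative
(strongest duplex wins) is available. Nuclei are Poisson around the seeded
cell number, and adherent bacteria are Poisson with mean
`nuclei * baseline * m`.

Control wells anchor the model: scrambled-siRNA negative controls and
untreated wells have $m = \varepsilon$; antiserum-block wells, where
antibodies against whole bacterial cells abolish specific adhesion, sit at a
small residual (default 5% of baseline); cell-death transfection controls
keep $m = 1$ but lose a `death_efficacy` fraction of their nuclei, which is
how transfection efficiency is verified.

## Default parameters and why

The latent effect and efficacy distributions are free parameters of the
simulator — published screens report hit rates, not per-duplex knockdown.
The defaults are chosen once, to be what a screening lab would call an
ordinary, well-behaved assay:

| parameter | default | rationale |
|---|---|---|
| planted `gene_effect` | Uniform(0.7, 0.95) | a usable receptor hit must lose most of its adhesion contribution when silenced; effects below ~0.5 are not separable from noise in a single well |
| `knockdown` | Beta(8, 2), mean 0.8 | validated commercial duplexes typically achieve 70–90% knockdown, with a tail of weak duplexes |
| `offtarget_sd` | 0.15 | gives a realistic spread of "grey" wells, including increased-adhesion wells |
| `death_efficacy` | 0.8 | a working lethal control clears most of the monolayer |
| `abblock_residual` | 0.05 | antiserum blocks adhesion but detectably nonzero signal remains |
| `nuclei_per_well` (counts mode) | 500 | a confluent 384-well monolayer summed over imaged fields |
| `baseline` bacteria/nucleus | 4 | a strongly adherent strain at the assay's bacterial load |

Under these defaults a pooled receptor well has
$k_{\mathrm{eff}} \approx 0.99$, so its expected decrease is
$\approx 100\,e_g\% \ge 70\%$ — comfortably beyond the 30% hit threshold —
while a null gene needs a $\approx 2.4\sigma$ noise excursion to cross it.

# Image rendering and quantification

`render_well()` draws each well as a two-channel 16-bit image: nuclei as
Gaussian blobs (default radius 8±2 px, truncated at ±2 sd so the rendered
blob respects the placement-separation guarantee), bacteria as point-spread
puncta (sigma 1.2 px), over a per-channel constant offset plus a linear
gradient, with optional Poisson photon noise and Gaussian read noise
(sd 2 counts). Objects are placed by dart throwing with a minimum
separation, so in noise-free renders no two objects can merge; if the
requested count cannot be placed, the record carries a `clipped` flag
rather than failing. The generating object list is embedded in the render,
which is what makes segmentation testable against exact ground truth.

Quantification mirrors a high-content instrument's pipeline:

1. **Background correction** (`gaussian_subtract`): the background surface
   is estimated by a Gaussian-weighted local *linear* fit (a 2-D
   Savitzky–Golay smoother, bandwidth 50 px, computed with moment
   convolutions against the image's support indicator) and subtracted,
   clipping at zero. The local-linear form was a deliberate choice over
   plain blurred-copy subtraction: it reproduces flat fields and linear
   illumination gradients *exactly*, including at image boundaries, where a
   blurred copy is biased by roughly $0.8\,\sigma \cdot |\nabla b|$. A
   morphological top-hat is available as an alternative.
2. **Thresholding**: Otsu per channel on a 256-bin histogram scaled to the
   channel's own maximum (so a global gain does not change the
   segmentation), or a fixed threshold. A corrected channel whose maximum
   is below one count is treated as blank — below quantization there is
   nothing to segment.
3. **Objects**: connected components, area-filtered (nuclei default
   20–4000 px²; bacteria 1–60 px² plus a minimum mean intensity). Touching
   nuclei can optionally be split by a distance-transform watershed; this
   is **off** by default because in confluent monolayers splitting is
   error-prone, and a systematic under-count cancels in per-plate
   normalization.
4. **Well summary**: counts, total punctum area, mean punctum intensity,
   `bac_nuc_ratio`, and flags (`zero_nuclei`, `low_confluence` below 10
   nuclei, `saturated` when >1% of pixels sit at 65535 — reported, never
   auto-excluded). Whether an instrument's "total amount" ratio means
   object counts or integrated intensities is ambiguous; counts are the
   primary readout and an intensity-sum ratio is reported alongside.
   Multiple fields of view per well are summed object-wise before the
   ratio.

# Plate QC, normalization, hit calling

**QC.** Per plate and control class, `summarize_controls()` reports medians,
means and sds of ratio and nucleus count over unflagged wells. The rules in
`qc_plate()` encode the expectations a screener checks by eye: the death
control must lose nuclei (median below `r_death = 0.5` of the negative
control), the antiserum block must suppress the ratio (below
`r_block = 0.3` of negative), and scrambled vs untreated medians must agree
within `r_reagent = 0.3` relative (reagent toxicity). These thresholds are
package defaults, exposed in the configuration — the underlying screens
report only that controls behaved. In the pipeline a failing plate is
re-assayed (re-simulated under a deterministically derived seed, up to three
attempts), as a lab repeats a failed plate; a plate that still fails is
excluded, and genes that thereby lose all wells are unmeasured rather than
"not hit".

**Normalization.** Percent-to-negative-control:
`100 * ratio / median(negative-control ratios on the same plate)`, so any
per-plate scalar cancels exactly and the negative-control median maps to
exactly 100. The validation round instead divides by the plate's
antiserum-block median (fold over the assay floor, block median exactly 1);
because that mode rescales rather than centres, per-well decreases are
measured against the plate's negative-control *fold* median, which makes
concordance calling identical in both modes.

**Hit cascade.** Round 1 (pooled, one well per gene): hit when the decrease
strictly exceeds 30%. Round 2 (the 3 duplexes tested separately): hit when
at least 2 of 3 duplexes each exceed the per-siRNA threshold. Round 3 (an
independent 5-duplex library from a second supplier, fresh efficacy draws):
at least 2 of 5. The per-siRNA threshold in rounds 2–3 defaults to the same
30% — the source screens state only that duplexes "showed a positive
effect", so consistency with round 1 is the least arbitrary choice, and it
is configurable. Decrease bins ((70,100], (50,70], (25,50], remainder) are
half-open and upper-inclusive so the three labels partition cleanly;
increased-adhesion wells are recorded in the remainder but never ranked or
followed up. Final candidates are genes that survive all three rounds; ties
in sorted reports break lexicographically by gene id.

One upstream ambiguity is worth naming: screen descriptions sometimes quote
decreases "relative to untreated cells" while the computation normalizes to
scrambled-siRNA medians. Both references exist in the layout (untreated
wells are a control class); scrambled is the default because it controls
for transfection-reagent effects, and the reagent QC rule checks that the
two agree.

# Blocking-assay statistics

Percent adhesion is `100 * adherent cpm / added cpm` per replicate well
(5 replicates), summarized as mean ± sample (n−1) sd. Each antibody
condition is compared against the basic assay with an unpaired, two-sided,
pooled-variance Student's t-test at $\alpha = 0.05$, implemented directly
from the textbook formula (the reference t implementation and a permutation
test serve as oracles in the test suite). "Pairwise" means each condition
vs basic — the replicate wells are independent, so a paired test would be
wrong; a Welch variant is available by flag. No multiple-testing correction
is applied across the four antibodies, matching the source analysis.
Degenerate inputs are pinned down: zero variance with equal means gives
t = 0, p = 1; `cpm_added = 0` is an argument error; adherent > added is
flagged as a possible counting error but still reported.

# Reproducibility and problem sizes

Every generator is a pure function of its arguments and a seed. A single
top-level seed expands to per-well seeds through a Lehmer-step counter
scheme (`child_seed()`), so any well can be re-rendered in isolation and a
whole run is reproducible from (config, seed) alone — including the QC
retry draws.

The test and acceptance workloads use desk-scale problem sizes chosen as
the package's own study conditions: 200-gene screens with 4 planted
receptors (the scale at which one plate holds a round), 50 seeded
repetitions for recovery/null statistics, 50 rendered wells at 512×512 px
with ~50 nuclei and ~200 puncta for the imaging oracle, and $10^4$ null
draws for the t-test's type-I error. The genome-scale library arithmetic
(21,585 genes × 3 duplexes; 57 plates) is checked symbolically rather than
simulated.

# What the simulator does and does not emulate

The generator reproduces the *statistical* structure the analysis relies
on: per-plate scale effects, control-class anchors, Poisson counting noise,
two-sided off-target variation, background gradients and photon noise in
the rendered images. It does **not** emulate transfection chemistry or mRNA
kinetics (knockdown is a scalar), cell-cycle or confluence gradients,
spatial edge effects within plates (none are corrected for downstream —
deliberately, as the analysis pipeline has no B-score step), optical
crosstalk between channels, or clumped bacterial adhesion. Passing
recovery tests therefore show that the *pipeline logic* is correct under
the stated noise model — not that the thresholds would perform identically
on real instrument data, where segmentation error and spatial artefacts
are structured rather than independent.

Other known limitations: nuclei are rendered as isotropic Gaussians, not
textured ellipses, so the watershed splitter is exercised on constructed
fixtures rather than realistic confluent fields; and the blocking-assay
generator draws lognormal replicate noise, which slightly misstates the
t-test's size in *its* simulations (the type-I error check uses normal
draws for exactly that reason).
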