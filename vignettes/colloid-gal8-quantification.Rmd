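---
title: "Quantifying colloid uptake and endo-lysosomal disruption: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying colloid uptake and endo-lysosomal disruption: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colloidquant)
```

# The scientific problem

Colloidal drug aggregates — drug-rich nanoparticles self-assembled from
supersaturated small-molecule drugs — are endocytosed by cells but tend to
stay trapped in the endo-lysosomal pathway. Giving the drug an ionizable
group lets it become cationic in acidic endosomes and disrupt their
membranes; but the same cationic chemistry, acting as free drug that diffuses
into lysosomes, drives phospholipidosis and toxicity. Disentangling these two
routes to endo-lysosomal disruption is the analytical core of this package.

The experimental readouts are fluorescence micrographs of reporter cells:

* a nuclear stain (cell count),
* an mCherry-Gal8 reporter — cytosolic galectin 8 is recruited to damaged
  endosome/lysosome membranes, so disruption events appear as punctate foci
  over a diffuse cytosolic background,
* a lipophilic dye (DiD) carried by the colloids — endocytosed
  colloid-containing vesicles appear as diffraction-limited puncta,
* a fluorescent lipid (NBD-PE) that accumulates in lysosomes —
  phospholipidosis appears as labelled vesicles.

Alongside imaging, two table-based assays are modelled: TNS titrations for
the apparent pKa of each analog, and plate-reader viability measurements for
dose-response curves.

# Pipeline overview

`colloidquant` implements the full chain:

1. **Synthetic data** (`simulate_micrograph()`, `simulate_titration()`,
   `simulate_dose_response()`, `simulate_mechanism_panel()`,
   `simulate_compound_library()`) — every input the pipeline consumes can be
   generated with known ground truth, so each stage is testable without any
   external data.
2. **Image quantification** (`tophat_filter()`, `segment_objects()`,
   `count_objects()`, `quantify_image()`, `aggregate_replicates()`) —
   background removal, thresholding, watershed splitting, counting, per-cell
   normalization, replicate averaging.
3. **Curve fits** (`fit_pka()`, `relative_activity()`, `original_activity()`,
   `fit_dose_response()`) — the titration, viability and dose-response
   models.
4. **Mechanism decomposition** (`fit_mechanism()`, `correlate_mechanism()`,
   `build_compound_summary()`) — the regression that separates
   colloid-mediated from free-drug-mediated disruption, and its correlation
   with phospholipidosis.
5. **Orchestration** (`run_config()`, `run_pipeline()`) — staged execution
   with seeds, standard-format artifacts and a hashed manifest.

# Models

## TNS titration (apparent pKa)

Fluorescence of the environment-sensitive dye against pH follows

$$F(\mathrm{pH}) = B + \frac{M - B}{1 + 10^{\,\mathrm{pH} - \mathrm{p}K_a}},$$

falling from the protonated plateau $M$ at low pH to the background $B$ at
high pH with midpoint at the pKa; $F(\mathrm{p}K_a) = (B + M)/2$ exactly.
`fit_pka()` fits $(B, M, \mathrm{p}K_a)$ by Levenberg–Marquardt least
squares with deterministic starts ($B$, $M$ from the data range, pKa from
the pH nearest half-maximal fluorescence).

A compound is reported **non-ionizable** when the fit does not converge,
when the fitted dynamic range $M - B$ is below three residual standard
deviations, or when the fitted pKa falls outside the sampled pH range
(3–10). The 3-sigma dynamic-range rule is this package's operationalization
of "no protonation detected over the assayed range"; on pure-noise curves it
has a small (a few percent) chance of a false ionizable call, which is the
price of keeping genuine low-amplitude titrations detectable. A converged
fit with $M \le B$ (fluorescence rising with pH) is reported as
non-converged: that direction is not a protonation titration.

## Viability normalizations

`relative_activity()` scales the endpoint signal of a well by the
blank-treated control, `original_activity()` by the same well's
pre-treatment signal, both background-corrected and in percent:

$$\%\mathrm{Rel} = 100\,\frac{I_{s,6d} - I_{b,6d}}{I_{c,6d} - I_{b,6d}},
\qquad
\%\mathrm{Orig} = 100\,\frac{I_{s,6d} - I_{b,6d}}{I_{s,0d} - I_{b,0d}}.$$

Both are constant rescalings of the same dose-response shape, so fitted
IC50s do not depend on which is used.

## Dose-response

The monophasic inhibition model is

$$Y = \mathrm{Bottom} + \frac{\mathrm{Top} - \mathrm{Bottom}}
{1 + ([\mathrm{Drug}]/\mathrm{IC}_{50})^{\mathrm{Hill}}},$$

decreasing in dose for $\mathrm{Hill} > 0$. The dose ratio is oriented as
$[\mathrm{Drug}]/\mathrm{IC}_{50}$ so that activity falls with dose — the
orientation consistent with growth suppression at sub-micromolar doses and
cytotoxicity at micromolar doses. The biphasic model adds a second
transition:

$$Y = \mathrm{Bottom}
 + \frac{\mathrm{Plateau} - \mathrm{Bottom}}{1 + ([\mathrm{Drug}]/\mathrm{IC}_{50,tox})^{\mathrm{Hill}_{tox}}}
 + \frac{\mathrm{Top} - \mathrm{Plateau}}{1 + ([\mathrm{Drug}]/\mathrm{IC}_{50,stat})^{\mathrm{Hill}_{stat}}},$$

a sub-micromolar static (growth-suppression) step from Top to Plateau and a
micromolar toxic step from Plateau to Bottom. With
$\mathrm{Plateau} = \mathrm{Top}$ it collapses exactly to the monophasic
model. Fitting is in $\log_{10}$-dose space for conditioning across wide
concentration spans; the ordering $\mathrm{IC}_{50,stat} \le
\mathrm{IC}_{50,tox}$ is imposed via the parameterization
$\log\mathrm{IC}_{50,tox} = \log\mathrm{IC}_{50,stat} + \delta$, $\delta \ge 0$,
which keeps the two terms identifiable. Zero-dose rows are allowed and
anchor Top. Convergence tolerance is a relative RSS change below 1e-10 or
500 iterations; non-convergence sets `converged = FALSE` rather than
erroring. Model choice (mono vs biphasic) is the caller's, matching how the
assay is analysed per cell line; no information-criterion selection is done.

## Mechanism decomposition

For each compound, wells are treated with colloids with or without an
endocytosis blocker (hydroxydynasore), imaged, and reduced to
replicate-level pairs (DiD puncta per cell, Gal8 foci per cell). The model
is a single pooled ordinary least-squares line

$$\text{foci/cell} = \beta_1\,\text{puncta/cell} + \beta_0 :$$

* $\beta_1$ (slope) — efficiency of colloid-mediated endo-lysosomal
  disruption, in foci per punctum;
* $\beta_0$ (intercept) — endocytosis-independent disruption attributable
  to free drug, in foci per cell.

Blocker wells enter the same regression as ordinary wells: their near-zero
uptake anchors the intercept (and, on the generator's panels, always reduces
its standard error relative to leaving them out — checked empirically over
seeds in the test suite). Negative intercept estimates are reported as-is;
truncating at zero would bias the downstream correlation. Unweighted OLS is
used: every image carries on the order of a hundred cells, so per-image
weights are near-uniform and no weighting scheme is part of the assay
description. Whether blocker and ordinary wells should be pooled into one
fit or fitted separately is genuinely open; pooling is this package's
declared choice since a single regression yields both quantities with their
standard errors.

`correlate_mechanism()` computes plain Pearson correlations across
compounds between mean phospholipidosis vesicles per cell and either the
slope ("efficiency" pairing) or the intercept ("intercept" pairing), on raw
estimates (no transformation). Group-comparison statistics (Welch-type
ANOVA, post-hoc tests) are deliberately not reimplemented: the module
exports estimates with standard errors so standard tests can be applied
externally.

# Image quantification: algorithms and numerical choices

**Channel preprocessing.** Each channel is reduced by its minimum (making
the whole chain exactly invariant to a uniform intensity offset), then
smoothed with a Gaussian of $\sigma = 1$ px. The smoothing is
matched-filter-like: it attenuates pixel noise roughly 3.5-fold while
reducing a diffraction-limited peak ($\sigma \approx 1.5$ px) by only about
30%, which is what makes a noise-relative threshold dependable.

**Top-hat.** `tophat_filter()` is the white top-hat: the image minus its
morphological opening with a digital disk ($dx^2 + dy^2 \le r^2$). It
removes anything wider than about twice the radius — including the diffuse
cytosolic Gal8 halo — and passes compact bright features. Defaults: radius
15 px for nuclei, 5 px for the spot channels, roughly twice the expected
object radius at the simulated scale (nuclei ~12 px, spots ~3 px). Images
smaller than twice the radius are rejected with a clear error.

**Threshold.** Three per-channel methods:

* `"noise"` (default for spot channels): threshold at
  $\mathrm{median} + k\,\hat\sigma$ with $k = 6$, where $\hat\sigma =
  (q_{0.90} - \mathrm{median})/z_{0.90}$ is estimated from the upper
  quantiles. The top-hat residual is strongly right-skewed (the opening
  clips its lower side), so symmetric estimators such as the MAD understate
  the upper tail by almost half; the upper-quantile estimator reproduces the
  true noise scale and is insensitive to the sparse object pixels. Six sigma
  sits above the maximum of the noise field across a megapixel image, while
  smoothed spots at peak-SNR 10 stand near twenty sigma. This keeps
  object-free channels (the phospholipidosis channel in untreated wells) at
  exactly zero counts.
* `"otsu"` (default for nuclei, whose top-hat histogram is genuinely
  bimodal): Otsu's threshold floored at the same noise level. Otsu alone is
  unreliable for very sparse spots — with tens of bright pixels per
  megapixel its split lands far up the spot intensity range and clips dim
  foci — which is why the spot channels default to `"noise"`.
* `"fixed"`: an explicit AU value.

On a constant raster the adaptive methods return an empty mask (no error).

**Segmentation.** Pixels above threshold are labelled by 4-connected
components. With watershed enabled, markers are local maxima of the
Euclidean distance transform of the mask, found after smoothing the
distance map with a $\sigma = 1$ Gaussian — the raw distance transform has
ring-shaped plateaus (repeated $\sqrt{n}$ values) that would seed spurious
splits inside a single convex object. Within each component, candidate
maxima are kept greedily in order of descending distance with ties broken
by row-major pixel order, enforcing a minimum pairwise seed separation
(5 px for spots, 9 px for nuclei); every component keeps at least one seed,
and a marker-based region growing on the distance map then splits
side-by-side objects. The procedure is fully deterministic. Components
outside `[min_area, max_area]` are discarded (defaults: 40 px² minimum for
nuclei, 3 px² for spots, no upper limit).

**Counting and normalization.** Counts are distinct labels per channel.
Per-cell ratios are ratios of image totals (foci/nuclei etc.), since each
stitched image carries ~100 cells and no cell-assignment step is part of
the assay; with zero nuclei the ratios are `NA` while counts are still
reported. Replicates average the ratios of (nominally three) images, each
from a separate well, with an unweighted mean. An optional mutual-centroid
colocalization count (`count_overlaps()`) is reported for inspection only
and feeds nothing downstream.

# The synthetic-data generator

`simulate_micrograph()` emulates one stitched wide-field image per well:

* objects are isotropic 2-D Gaussians with stated radius equal to
  $2\sigma$ (nuclei radius 12 px, spots 3 px), peak intensities lognormal
  with CV 0.1 around 20000 AU (nuclei) and 10000 AU (spots);
* the Gal8 channel adds a wide diffuse halo per nucleus
  ($\sigma$ = 25 px, 3000 AU) — exactly the background the top-hat stage
  must remove;
* a constant camera offset (400 AU) plus Gaussian read noise
  (default sd 1000 AU, i.e. spot peak-SNR 10) on a 16-bit scale, rounded
  and clipped to [0, 65535];
* centres are rejection-sampled with a minimum within-channel separation of
  3 object radii; unplaceable densities raise an error naming the channel;
* the default scene is ~100 nuclei, 250 puncta, 40 foci on 768×768 px.

Everything is a pure function of its parameters and seed (bit-identical
reruns). What the generator does **not** emulate — and therefore what
passing tests do not establish about real data — includes: optical PSF
structure beyond Gaussian spots, uneven illumination, cell-shaped cytosolic
texture, clustered or nucleus-associated spot placement, z-structure and
focal-plane selection, photobleaching, and colloid multiplicity within one
lysosome (puncta are atomic objects; a real punctum may contain several
colloids, so "uptake" is a per-vesicle, not per-particle, count).

`simulate_mechanism_panel()` draws per-well panels under the two-mechanism
model: uptake in unblocked wells is lognormal (non-negative, right-skewed;
mean 15, sd 5 puncta/cell by default — moderate, fairly uniform uptake),
blocker wells have exactly zero uptake, foci are
`efficiency × uptake + free_drug + noise` truncated at zero, and vesicles
are drawn around the compound's phospholipidosis rate. The default panel
geometry (15 wells per compound, 20% blocker wells, noise sd 0.1 foci/cell)
is the study condition used throughout the tests.

`simulate_compound_library()` creates the per-compound parameters for a
screening panel in which the free-drug disruption rate and the
phospholipidosis rate share a latent driver (both stem from free cationic
drug in lysosomes) while colloid efficiency varies independently, and
apparent pKa rises with the driver. On such panels the intercept pairing
correlates strongly with phospholipidosis while the efficiency pairing does
not — the qualitative two-mechanism signature. With 15 compounds the
efficiency-pairing correlation has sampling sd ≈ 0.27 around zero, so its
exact value varies noticeably between seeds; the signature is its small
magnitude relative to the intercept pairing, not a particular number.

# Statistical behaviour worth knowing

* **pKa recovery.** Over titrations with 2% multiplicative noise on a
  pH 3–10 grid at 0.5 steps, the median absolute pKa error is ~0.01 units.
* **Mechanism coverage.** With 15 wells per compound the OLS pivot has 13
  degrees of freedom, so "within 2 standard errors" captures each
  parameter ~93% of the time (not the Gaussian 95%), and both parameters
  jointly ~89%; in the zero-efficiency/zero-free-drug corner the truncation
  of foci at zero adds an upward intercept bias of
  $E[\max(N(0, 0.1), 0)] \approx 0.04$ foci/cell. These are properties of
  the estimator at this design size, not implementation defects.
* **Dose-response.** Noise-free curves refit to well under 1% in every
  parameter; scaling doses by $k$ scales fitted IC50s by exactly $k$.

# Orchestration and I/O

`run_pipeline()` executes the configured stages in dependency order
(simulate images → quantify → simulate curves → fit pKa → simulate panel →
mechanism → correlate), derives every stage seed deterministically from the
master seed, and writes: per-channel 16-bit TIFFs with a JSON ground-truth
sidecar, tidy CSVs (image counts, replicate means, titrations, pKa fits,
panel wells, mechanism estimates, compound summary, correlations), and a
`manifest.json` listing every artifact with its MD5 hash — identical
configurations reproduce identical manifests. A stage that fails removes
its partial outputs; a stage whose input is missing errors naming the stage
and file. Input errors carry condition class `colloidquant_bad_input`
(degenerate designs additionally `colloidquant_degenerate_design`),
numerical failures `colloidquant_numerical`.

Problem sizes used in the shipped tests and acceptance script (chosen as
desk-scale study conditions): 768×768 px scenes with ~100 nuclei, 250
puncta and 40 foci; 100-titration recovery sweeps; a 3×3 grid of mechanism
panels at 20 seeds each; 50 random 64×64 scenes for the
connected-components oracle; 15-compound correlation panels.

# Known limitations

* Counting, not instance segmentation: nuclei shapes and boundaries are not
  optimized beyond what counting requires, and no cell-boundary
  segmentation or per-cell object assignment is done.
* The watershed split is driven by the distance transform only; strongly
  overlapping objects (> ~60% overlap) merge.
* The biphasic model's static term becomes unidentifiable as
  Plateau → Top; the fit then matches the data but individual static-term
  parameters are arbitrary — compare fitted curves, not parameters, in that
  regime.
* Apparent pKa from TNS fluorescence is an operational quantity; strongly
  non-sigmoidal titrations (e.g. zwitterionic transitions) fit poorly and
  should be inspected via `autoplot()`.
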