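---
title: "Methods: avian perception of larval colour change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: avian perception of larval colour change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mothvision quantifies how well colour-changing caterpillars match their
backgrounds *as seen by an avian predator*, and provides the statistical
machinery to test whether experimental manipulations (rearing background
colour, occlusion of the ocelli, dowel position in choice arenas, life stage
in gene-expression assays) alter that match. This vignette is the package's
account of its models, parameter choices, and limitations.

## Spectral processing

All spectral work happens on a fixed integer grid of 300–700 nm at 1 nm
steps (401 points), the avian-visible range. Raw spectrometer output arrives
on arbitrary wavelength grids; `resample_1nm()` interpolates **linearly**
onto the fixed grid. Linear interpolation is the minimal assumption — no
smoothing is applied, because smoothing choices would silently alter cone
catches. Three pragmatic rules handle instrument reality:

* Native grids rarely hit 300.000/700.000 nm exactly, so endpoints may fall
  short by up to **2 nm**; edge values are then extended flat. Larger gaps
  are hard errors.
* Reflectance is a physical proportion: negative readings (instrument noise)
  are clipped to 0, values above 1 to 1.
* Spectra exported in percent are auto-detected (any value above 1.5 cannot
  be a proportion) and divided by 100, with a logged notice. The 1.5
  threshold cleanly separates the two scales: genuine proportions never
  exceed 1, and genuine percent spectra essentially always contain values
  well above 1.5.

The measurement protocol takes six readings per individual (three per
lateral surface). `individual_spectra()` averages them into one spectrum
per larva **before** visual modelling, so each larva contributes one catch
vector; a count other than six is allowed with a warning. Whether the
original analysis modelled per-individual means or all six measurements as
rows is not stated in the source text, and the residual degrees of freedom
printed there do not unambiguously match either choice; the pipeline
therefore exposes an `aggregate` switch (`"individual"`, the default, or
`"measurement"`), and reports its own degrees of freedom.

## The receiver

The modelled predator is the blue tit, a tetrachromat with UV, short-,
medium- and long-wave single cones plus a double (DD) cone mediating
luminance vision. Published catch-ready sensitivity curves for this receiver
are not freely redistributable, so the default viewer builds **stand-in**
sensitivities from the Govardovskii et al. (2000) A1 visual pigment
template, with peak wavelengths 371 (UV), 448 (SW), 503 (MW) and 563 nm
(LW); the DD cone shares the LW pigment. Oil-droplet and ocular-media
filtering are *not* modelled. This is a documented limitation: absolute
catch values differ from those obtained with measured blue tit curves, but
all contract-bearing quantities (JND limits, greenness ordering, colour-space
geometry) are template-independent properties, and `viewer_model()` accepts
user-supplied sensitivity tables for faithful reproduction. One template
subtlety: for the UV pigment the β-band shifts the combined curve's maximum
to 370 nm, one grid point below the nominal λmax; curves are normalised to
peak 1 wherever that peak falls.

The illuminant is CIE D65 converted to **quantal** units (energy × λ,
renormalised), shipped as a tabulated 5 nm table interpolated to 1 nm. The
source text's phrase "idealised irradiance (D65)" is ambiguous between D65
and a flat-quanta ideal light, so `illuminant("ideal")` is selectable; the
receptor-noise model is invariant to the overall illuminant scale either
way, and no von Kries/background adaptation is applied — none is described
in the source analysis, and the headline greenness ratio is scale-free.

Quantum catches are trapezoidal integrals of reflectance × irradiance ×
sensitivity (Δλ = 1 nm), floored at 1e-12 so that log-ratios stay defined
for degenerate all-zero spectra.

## Colour statistics

* **Greenness** = q_MW / (q_MW + q_LW), an opponent ratio in (0, 1); 0.5
  means the two channels are equally stimulated.
* **Luminance** = the DD cone catch.
* **Tetrahedral colour space**: relative chromatic catches r_i = q_i / Σq
  are barycentric coordinates in a regular tetrahedron centred on the
  origin with circumradius 0.75 and the UV vertex on +z (the other three
  vertices sit at z = −0.25). Equal stimulation maps to the origin;
  pure-cone stimulation maps to a vertex. The orientation and radius are
  conventions fixed in code; only the origin/vertex/affine properties are
  contract-bearing.

## Discriminability (RNL model)

Chromatic discriminability uses the receptor-noise-limited model. Receptor
signals are log catch ratios Δf_i = ln(q_i^A / q_i^B); channel noise is
e_i = w / √η_i with relative cone abundances η = 0.3704 (UV), 0.7111 (SW),
0.9926 (MW), 1.0 (LW) and Weber fraction w = 0.05 anchored to the most
abundant cone (LW). The package implements the general n-receptor quadratic
form (sum over receptor pairs, weighted by the noise of the remaining
receptors); with two receptors it collapses to |Δf₁ − Δf₂| / √(e₁² + e₂²),
which `dichromat_viewer()` exposes for the closed-form check. Achromatic
discriminability is |ln(q_DD^A / q_DD^B)| / w_DD. The achromatic Weber
fraction is not stated separately in the source, so w_DD defaults to the
same 0.05. Thresholds: below 1 JND the stimuli are indiscriminable, 1–3 JND
discriminable only under good conditions, above 3 increasingly easy to
separate.

RNL distance is *not* a metric on spectra (triangle-like monotonicity can
fail), so no such property is asserted; symmetry, scale invariance, and
agreement with an independently coded quadratic form are.

## Behavioural and expression statistics

Colour responses (greenness, luminance, larva-vs-dowel JND) are analysed
with ordinary linear models on **log10** responses, treatment and blindfold
as factors, and per-term F tests. The source text attaches log10 explicitly
to JND and lists the three responses together; the package applies log10 to
all three (all are strictly positive; greenness is bounded and the
transform is monotone, so F-test conclusions are insensitive at these
effect sizes, and the flag is switchable per call). F tests default to
**Type II** (marginal) sums of squares computed by explicit model
comparison — the original R analysis does not state the type, and with
near-balanced designs the two coincide; Type I is available via
`anova_type = 1`. A zero-residual fit reports F = ∞ with a warning rather
than failing.

Background choice is a trial-level binomial GLM (logit link, IRLS) of
matching success (1 if the chosen dowel colour equals the larva's colour)
on larval colour, blindfold, and — in the horizontal arena, where each
larva is tested twice with the dowel reversed — dowel position. Wald z
statistics are reported, matching the source's Z values; no mixed model is
fitted (the original analysis did not), but larva ids are retained in the
trial table for future clustering. Complete separation is flagged
(|coefficient| > 15 on the logit scale), not raised.

qPCR quantification: technical triplicates are collapsed to a mean Cp
(replicate SD above 0.5 cycles — a common lab convention, configurable —
is flagged), and expression relative to the *spectrin* reference is
(E_ref^Cp_ref)/(E_tgt^Cp_tgt) with efficiencies idealised to 2 (per-gene
efficiencies accepted). The dermal proportion sums the three dermal
tissues over head + dermal expression; exact 0/1 values are nudged 1e-6
into the open interval because the beta likelihood vanishes on the
boundary. Stage effects on the proportion use an in-package **beta
regression** (logit mean submodel, constant precision φ, numerical ML via
BFGS, Wald z from the inverse observed information) — no beta-regression
package is assumed present. Head and dermal log10 expression contrasts are
two-level linear models. Sign convention everywhere: **adult is the
reference level**, so stage coefficients and t statistics estimate the
larval shift (larva − adult); tenfold higher adult expression yields a
negative t.

## The synthetic-data generator

Because the study's raw measurements live in an external deposit, every
analysis stage is exercised against seeded generators whose structure
mirrors the experiments:

* **Spectra** — each larva's spectrum is (1 − ρ)·neutral + ρ·dowel plus a
  smooth random curve (a 4-term cosine series, not white noise, so clipping
  artefacts are rare — real reflectance curves are smooth). ρ ∈ [0, 1] is
  the colour-response slope, default 0.7, chosen once to give clear
  treatment separation without saturating; blindfolding shifts ρ by δ
  (default 0, the experimental null). Dowel curves are deterministic:
  black/white flat at 0.05/0.6, green a Gaussian band (centre 550 nm,
  width 50 nm, amplitude 0.3), brown a monotone long-wave rise. Six
  pseudo-replicates per larva add small smooth measurement noise
  (SD 0.01); individual noise SD defaults to 0.04. Group sizes default to
  the study's printed per-group ns (chromatic 44/50/36/31, achromatic
  29/45/26/49), so synthetic runs carry a comparable power profile.
* **Choice trials** — Bernoulli matching at p = 0.75 per cell (the reported
  70–80% range), position effects act on the logit, and horizontal-arena
  larvae contribute two trials with opposite dowel orientations
  (ns 60/56/59/51 diagonal, 34/34/37/32 horizontal).
* **qPCR** — Cp values invert the quantification formula
  (Cp_target = Cp_ref − log2 ratio) plus Gaussian replicate noise
  (0.2 cycles), with 4 biological replicates per stage. The default truth
  table gives adults ~10× larval head expression and stage-similar dermal
  expression, i.e. dermal proportions of 0.6 (larva) vs ≈0.35 (adult).

What the generators do **not** emulate: pigment biochemistry, instar
growth, spatial pattern, family structure, circadian trial structure, or
the true (unpublished) reaction-norm slope. A green test therefore
establishes that the *pipeline* is correct and well-calibrated (exact
round-trips at zero noise, nominal type-I rates under null generators,
parameter recovery within Wald bands, monotone power in δ) — it does not
re-establish the study's empirical findings, which require the archived
spectra and measured receiver curves.

## Numerical choices

* Catch floor 1e-12; reflectance clipped to [0, 1]; 2 nm edge tolerance.
* GLM convergence |Δdeviance| < 1e-8, max 50 IRLS iterations; beta
  regression BFGS with reltol 1e-12, cap 200 iterations, hard error on
  non-convergence.
* One global seed expands to fixed per-stream offsets (+1000 chromatic
  spectra, +1500 achromatic, +2000 choice, +3000 qPCR) so streams are
  reproducible independently; all generators restore the caller's RNG
  state.
* Deterministic outputs: identical configs give byte-identical CSVs,
  report, and manifest (config MD5, seed, package version).
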