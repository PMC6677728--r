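# mothvision

Colour-changing caterpillars (classically, peppered moth larvae) match the
twigs they rest on, and the ecologically meaningful question is not whether
*we* can see the match but whether a visually hunting bird can. `mothvision`
is an R package for answering that question end to end: it processes
reflectance spectra, models them through an avian (blue tit) visual system,
and runs the statistics used to test colour change, background-choice
behaviour, and the expression of visual genes in skin versus head tissue.
It is aimed at sensory ecologists analysing spectrophotometer output from
colour-plasticity or camouflage experiments.

## What it computes

* **Spectra** — delimited spectrometer tables are validated, resampled
  linearly onto the shared 300–700 nm, 1 nm grid, clipped to [0, 1], and
  averaged per individual (six replicate measurements by convention).
* **Cone catches** — quantum catch of receptor *i* is
  `q_i = Σ_λ R(λ) I(λ) S_i(λ) Δλ` with D65 quantal irradiance `I` and
  Govardovskii A1-template sensitivities `S_i` (λmax 371/448/503/563 nm for
  UV/SW/MW/LW; the double cone DD shares the LW pigment).
* **Colour statistics** — greenness `q_MW / (q_MW + q_LW)`, luminance
  `q_DD`, and tetrahedral colour-space coordinates (regular tetrahedron,
  circumradius 0.75, equal stimulation at the origin).
* **Discriminability** — the receptor-noise-limited (RNL) model in JND
  units: `Δf_i = ln(q_i^A / q_i^B)`, channel noise `e_i = w / √η_i` with
  cone abundances η = 0.3704/0.7111/0.9926/1.0 and Weber fraction
  w = 0.05; chromatic ΔS is the standard tetrachromat quadratic form, the
  achromatic contrast is `|ln(q_DD^A/q_DD^B)| / w_DD`. Below 1 JND two
  stimuli are indiscriminable; 1–3 JND marginal; above 3 discriminable.
* **Statistics** — linear models with Type II F tests on log10 responses,
  binomial GLMs of background-choice matching success (Wald z), qPCR
  relative expression `(E_ref^Cp_ref)/(E_tgt^Cp_tgt)` with E = 2, dermal
  proportions with in-package beta regression of stage effects.
* **Synthetic data** — seeded generators for spectra, choice trials and
  qPCR tables with the experiments' group sizes and effect structure, so
  the whole pipeline is testable without any external download.

## Worked example

Can a blue tit tell a green dowel from a brown one?

```r
library(mothvision)
v <- bluetit_viewer()
green <- make_dowel_spectrum("green"); brown <- make_dowel_spectrum("brown")
qg <- catch_vector(green, v); qb <- catch_vector(brown, v)
greenness(qg)            # 0.41
greenness(qb)            # 0.3631
discriminate(qg, qb, v)
#> <discrimination> chromatic 8.515 JND (discriminable), achromatic 10.49 JND (discriminable)
round(receptor_noise(v), 4)
#>     UV     SW     MW     LW
#> 0.0822 0.0593 0.0502 0.0500
```

The green dowel stimulates the MW channel relatively more (greenness 0.41
vs 0.36), and at 8.5 chromatic JND the two dowels are easily discriminable
— which is what makes background *choice* by the larvae measurable.

A full synthetic run (simulate → perceive → stats → expression → report):

```r
res <- run_pipeline(default_config(seed = 1, out_dir = "run1"))
cat(readLines("run1/report.txt"), sep = "\n")
```

which prints, among others (seed 1):

```
Colour response (chromatic experiment):
  response ~ treatment: F_1,158 = 15.4, P = 0.0001298
  response ~ blindfold: F_1,158 = 1.03, P = 0.3118
  ...
Background choice (binomial GLM):
  diagonal: (Intercept): estimate = 1.24, Z = 4.641, P = 3.47e-06
  ...
```

i.e. in the default synthetic world larvae track their dowel colour
(treatment effect), blindfolding has no effect (the null, δ = 0), and the
choice intercept ≈ logit(0.75). The same stages are scriptable from a
shell:

```sh
Rscript -e 'mothvision::mothvision_cli()' run --seed 1 --out run1
Rscript -e 'mothvision::mothvision_cli()' simulate --what qpcr --seed 1 --out sim
```

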