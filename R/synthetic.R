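# Seeded synthetic-data generators emulating the statistical structure the
# analysis assumes: smooth reflectance spectra whose greenness tracks the
# rearing dowel, Bernoulli background-choice trials, and qPCR Cp tables.

# Evaluate expr with a private, restored RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Smooth random deviation: low-order cosine series, so that clipping
# artefacts stay rare (real reflectance curves are smooth).
smooth_noise <- function(sd) {
  if (sd <= 0) return(rep(0, length(VIS_GRID)))
  t <- (VIS_GRID - 300) / 400
  k <- 1:4
  amp <- rnorm(4, 0, sd / k)
  phase <- runif(4, 0, 2 * pi)
  colSums(amp * cos(outer(pi * k, t) + phase))
}

#' Deterministic dowel reflectance curve
#'
#' Smooth idealised curves per dowel colour class: black and white are
#' flat at a low/high level; green adds a Gaussian band centred in the
#' medium wavelengths; brown adds a monotone long-wavelength rise. All
#' curves are clipped to \[0, 1\].
#'
#' @param colour `"black"`, `"white"`, `"brown"` or `"green"`.
#' @param base Baseline reflectance level (defaults per colour: black
#'   0.05, white 0.6, green 0.08, brown 0.08).
#' @param band_amplitude Height of the green Gaussian band (default 0.3).
#' @param band_centre Centre of the green band in nm (default 550).
#' @param band_width Gaussian width of the green band in nm (default 50).
#' @param lw_slope Long-wave rise of the brown curve per nm above 500 nm
#'   (default 0.0012).
#' @return A [refl_spectrum()] labelled `dowel_<colour>`.
#' @export
make_dowel_spectrum <- function(colour = c("black", "white", "brown", "green"),
                                base = NULL, band_amplitude = 0.3,
                                band_centre = 550, band_width = 50,
                                lw_slope = 0.0012) {
  colour <- match.arg(colour)
  if (is.null(base)) {
    base <- switch(colour, black = 0.05, white = 0.6, brown = 0.08,
                   green = 0.08)
  }
  wl <- VIS_GRID
  r <- switch(colour,
    black = rep(base, length(wl)),
    white = rep(base, length(wl)),
    green = base + band_amplitude * exp(-((wl - band_centre) / band_width)^2),
    brown = base + lw_slope * pmax(wl - 500, 0))
  refl_spectrum(r, label = paste0("dowel_", colour))
}

# Baseline (untreated) larval integument: dull, slightly long-wave rising.
neutral_larva_curve <- function() 0.12 + 0.0002 * (VIS_GRID - 300)

#' Default group sizes of the colour-change experiments
#'
#' Chromatic experiment: brown control 44, brown blindfolded 50, green
#' control 36, green blindfolded 31. Achromatic: black control 29, black
#' blindfolded 45, white control 26, white blindfolded 49. These mirror
#' the reported per-group sample sizes so synthetic runs carry a realistic
#' power profile.
#'
#' @param experiment `"chromatic"` or `"achromatic"`.
#' @return Data frame with columns `treatment`, `blindfold`, `n`.
#' @export
default_colour_design <- function(experiment = c("chromatic", "achromatic")) {
  experiment <- match.arg(experiment)
  if (experiment == "chromatic") {
    data.frame(treatment = rep(c("brown", "green"), each = 2L),
               blindfold = rep(c("control", "painted"), 2L),
               n = c(44L, 50L, 36L, 31L))
  } else {
    data.frame(treatment = rep(c("black", "white"), each = 2L),
               blindfold = rep(c("control", "painted"), 2L),
               n = c(29L, 45L, 26L, 49L))
  }
}

#' Simulate a colour-change rearing experiment
#'
#' Each larva's mean spectrum is a convex combination of the neutral
#' larval curve and its rearing dowel's curve,
#' `(1 - rho_eff) * neutral + rho_eff * dowel`, plus smooth individual
#' noise; `rho_eff = rho + delta` for blindfolded (painted) larvae. Six
#' pseudo-replicate measurements per larva carry small smooth measurement
#' noise. With `delta = 0` blindfolding has no effect, the experiment's
#' null condition.
#'
#' @param design Data frame with columns `treatment`, `blindfold`, `n`
#'   (defaults to [default_colour_design()]).
#' @param rho Response slope in \[0, 1\]: degree to which a larva's
#'   spectrum moves towards its dowel's (default 0.7).
#' @param delta Blindfold shift of `rho` for painted larvae (default 0;
#'   `rho + delta` must stay in \[0, 1\]).
#' @param noise_sd SD of the smooth between-individual spectral noise
#'   (default 0.04).
#' @param measurement_sd SD of the smooth within-individual replicate
#'   noise (default 0.01).
#' @param n_reps Replicate measurements per larva (default 6).
#' @param seed Integer seed; identical inputs give identical tables.
#' @return List with `table` (a `spectrum_table` of all measurements),
#'   `metadata` (individual_id, treatment, blindfold) and `dowels`
#'   (named list of dowel [refl_spectrum()]).
#' @export
simulate_colour_experiment <- function(design = default_colour_design(),
                                       rho = 0.7, delta = 0,
                                       noise_sd = 0.04,
                                       measurement_sd = 0.01,
                                       n_reps = 6L, seed = 1L) {
  stopifnot(rho >= 0, rho <= 1, rho + delta >= 0, rho + delta <= 1,
            all(c("treatment", "blindfold", "n") %in% names(design)))
  dowels <- lapply(setNames(nm = unique(design$treatment)),
                   make_dowel_spectrum)
  neutral <- neutral_larva_curve()
  with_seed(seed, {
    meta <- design[rep(seq_len(nrow(design)), design$n), c("treatment", "blindfold")]
    meta$individual_id <- sprintf("%s_%s_%03d", substr(meta$treatment, 1, 2),
                                  substr(meta$blindfold, 1, 1),
                                  seq_len(nrow(meta)))
    rownames(meta) <- NULL
    cols <- vector("list", nrow(meta) * n_reps)
    cn <- character(nrow(meta) * n_reps)
    k <- 0L
    for (i in seq_len(nrow(meta))) {
      rho_eff <- rho + if (meta$blindfold[i] == "painted") delta else 0
      target <- (1 - rho_eff) * neutral +
        rho_eff * dowels[[meta$treatment[i]]]$reflectance
      indiv <- target + smooth_noise(noise_sd)
      for (r in seq_len(n_reps)) {
        k <- k + 1L
        cols[[k]] <- pmin(pmax(indiv + smooth_noise(measurement_sd), 0), 1)
        cn[k] <- paste0(meta$individual_id[i], "_", r)
      }
    }
    m <- do.call(cbind, cols)
    colnames(m) <- cn
    list(table = spectrum_table(VIS_GRID, m,
                                metadata = meta[, c("individual_id",
                                                    "treatment", "blindfold")]),
         metadata = meta[, c("individual_id", "treatment", "blindfold")],
         dowels = dowels)
  })
}

#' Default group sizes of the background-choice experiments
#'
#' Diagonal arena: brown control 60, brown blindfolded 56, green control
#' 59, green blindfolded 51. Horizontal arena: 34, 34, 37, 32.
#'
#' @return Data frame with columns `arena`, `larval_colour`, `blindfold`,
#'   `n`.
#' @export
default_choice_design <- function() {
  data.frame(arena = rep(c("diagonal", "horizontal"), each = 4L),
             larval_colour = rep(rep(c("brown", "green"), each = 2L), 2L),
             blindfold = rep(c("control", "painted"), 4L),
             n = c(60L, 56L, 59L, 51L, 34L, 34L, 37L, 32L))
}

#' Simulate background-choice trials
#'
#' Each larva chooses the dowel colour matching its own body colour with
#' probability `p_match` (adjusted on the logit scale by a dowel-position
#' effect in the horizontal arena). Diagonal-arena larvae contribute one
#' trial each; horizontal-arena larvae contribute two trials with opposite
#' dowel positions.
#'
#' @param design Data frame of group sizes (defaults to
#'   [default_choice_design()]).
#' @param p_match Matching probability, either a single value for all
#'   cells (default 0.75) or a vector named `<colour>_<blindfold>`.
#' @param position_effect Additive shift of the matching logit when the
#'   dowel's green end is far from the chamber base (default 0).
#' @param seed Integer seed.
#' @return Data frame of trials: `larva_id`, `larval_colour`, `blindfold`,
#'   `arena`, `position` (`brown_far`/`green_far`/`none`),
#'   `chosen_colour`, `matching`.
#' @export
simulate_choice_trials <- function(design = default_choice_design(),
                                   p_match = 0.75, position_effect = 0,
                                   seed = 1L) {
  stopifnot(all(p_match > 0), all(p_match <= 1))
  cell_p <- function(colour, blindfold) {
    if (length(p_match) == 1L && is.null(names(p_match))) return(p_match)
    key <- paste0(colour, "_", blindfold)
    if (!key %in% names(p_match)) stop("no p_match for cell ", key)
    p_match[[key]]
  }
  with_seed(seed, {
    rows <- list()
    id <- 0L
    for (g in seq_len(nrow(design))) {
      p0 <- cell_p(design$larval_colour[g], design$blindfold[g])
      for (i in seq_len(design$n[g])) {
        id <- id + 1L
        larva <- sprintf("larva_%04d", id)
        positions <- if (design$arena[g] == "horizontal") {
          sample(c("brown_far", "green_far"))  # randomised order
        } else "none"
        for (pos in positions) {
          p <- plogis(qlogis(p0) +
                      position_effect * (pos == "green_far"))
          match_i <- rbinom(1L, 1L, p)
          chosen <- if (match_i == 1L) design$larval_colour[g] else
            setdiff(c("brown", "green"), design$larval_colour[g])
          rows[[length(rows) + 1L]] <- data.frame(
            larva_id = larva, larval_colour = design$larval_colour[g],
            blindfold = design$blindfold[g], arena = design$arena[g],
            position = pos, chosen_colour = chosen,
            matching = match_i)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

QPCR_TARGET_GENES <- c("Arr-1", "RDB", "UVA", "BlA", "BlB",
                       "MelA", "MelB", "LW1", "LW2")

#' Default true expression structure for the qPCR generator
#'
#' Target-gene head expression an order of magnitude higher in adults than
#' larvae; dermal expression similar across stages, giving a larval dermal
#' proportion of 0.6 and an adult dermal proportion of about 0.35.
#'
#' @return Data frame with columns `gene`, `stage`, `tissue`, `ratio`
#'   (true expression relative to the reference gene).
#' @export
default_qpcr_truth <- function() {
  grid <- expand.grid(gene = QPCR_TARGET_GENES,
                      stage = c("larva", "adult"),
                      tissue = VALID_TISSUES,
                      stringsAsFactors = FALSE)
  grid$ratio <- ifelse(grid$tissue == "head",
                       ifelse(grid$stage == "larva", 0.05, 0.5),
                       ifelse(grid$stage == "larva", 0.025, 0.09))
  grid
}

#' Simulate a long-format qPCR Cp table
#'
#' Target Cp values are generated by inverting the relative-expression
#' formula at efficiency 2: `Cp_target = Cp_ref - log2(ratio)`, plus
#' Gaussian replicate noise; with zero noise the analysis pipeline
#' recovers every true ratio exactly.
#'
#' @param truth Data frame of true ratios (default
#'   [default_qpcr_truth()]).
#' @param n_per_stage Biological replicates per life stage (default 4).
#' @param ref_cp Mean crossing point of the reference gene (default 20
#'   cycles).
#' @param noise_sd SD of replicate Cp noise in cycles (default 0.2).
#' @param n_reps Technical replicates per well (default 3).
#' @param seed Integer seed.
#' @return Data frame with columns `sample`, `stage`, `tissue`, `gene`,
#'   `rep`, `cp`, ready for [expression_ratios()].
#' @export
simulate_qpcr <- function(truth = default_qpcr_truth(), n_per_stage = 4L,
                          ref_cp = 20, noise_sd = 0.2, n_reps = 3L,
                          seed = 1L) {
  with_seed(seed, {
    stages <- unique(truth$stage)
    rows <- list()
    for (st in stages) {
      for (s in seq_len(n_per_stage)) {
        sample_id <- sprintf("%s_%02d", st, s)
        tt <- truth[truth$stage == st, ]
        for (r in seq_len(nrow(tt))) {
          cp_t <- ref_cp - log2(tt$ratio[r]) + rnorm(n_reps, 0, noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sample_id, stage = st, tissue = tt$tissue[r],
            gene = tt$gene[r], rep = seq_len(n_reps), cp = cp_t)
        }
        for (ts in unique(tt$tissue)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sample_id, stage = st, tissue = ts,
            gene = REFERENCE_GENE, rep = seq_len(n_reps),
            cp = ref_cp + rnorm(n_reps, 0, noise_sd))
        }
      }
    }
    out <- do.call(rbind, rows)
    if (any(out$cp <= 0 | out$cp > 45)) {
      out$cp <- pmin(pmax(out$cp, 1e-3), 45)
    }
    rownames(out) <- NULL
    out
  })
}
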