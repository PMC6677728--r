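# Receiver model: visual pigment templates, cone catches, greenness,
# luminance, and tetrahedral colour space.

#' Visual pigment absorbance template (Govardovskii A1 nomogram)
#'
#' Evaluates the Govardovskii et al. (2000) vitamin-A1 rhodopsin template
#' (alpha band plus beta band) on the shared 1 nm grid and peak-normalises
#' it to 1. Used to stand in for receptor sensitivity curves when measured
#' curves are unavailable; ocular-media and oil-droplet filtering are not
#' modelled.
#'
#' @param lambda_max Wavelength of peak absorbance, in nm, within
#'   \[300, 700\].
#' @return A `cone_sensitivity`: list with `wl`, `sensitivity` (401 values,
#'   max = 1), `lambda_max`.
#' @export
pigment_template <- function(lambda_max) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1L ||
      lambda_max < min(VIS_GRID) || lambda_max > max(VIS_GRID)) {
    stop("lambda_max must be a single wavelength in [300, 700] nm")
  }
  wl <- VIS_GRID
  x <- lambda_max / wl
  # alpha band
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  S_alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  # beta band
  lm_beta <- 189 + 0.315 * lambda_max
  b_beta <- -40.5 + 0.195 * lambda_max
  S_beta <- 0.26 * exp(-((wl - lm_beta) / b_beta)^2)
  s <- S_alpha + S_beta
  structure(list(wl = wl, sensitivity = s / max(s), lambda_max = lambda_max),
            class = "cone_sensitivity")
}

#' Construct a receiver (viewer) model
#'
#' Bundles one sensitivity curve per cone class, the relative abundances of
#' the chromatic cones, Weber fractions, and an illuminant. The double
#' (DD) cone mediates achromatic (luminance) vision; the four single cones
#' (UV, SW, MW, LW) mediate chromatic vision with receptor noise scaled by
#' abundance, anchored at the most abundant cone (LW, abundance 1).
#'
#' @param sensitivities Named list of `cone_sensitivity` objects with
#'   elements `UV`, `SW`, `MW`, `LW`, `DD`.
#' @param abundances Named numeric: relative abundance per chromatic cone;
#'   LW must equal 1.
#' @param weber Weber fraction of the reference (LW) chromatic channel.
#' @param weber_dd Achromatic Weber fraction for the DD channel.
#' @param illum An [illuminant()].
#' @return A `viewer_model`.
#' @export
viewer_model <- function(sensitivities, abundances, weber = 0.05,
                         weber_dd = 0.05, illum = illuminant("D65")) {
  chrom <- names(abundances)
  stopifnot(all(chrom %in% names(sensitivities)),
            all(abundances > 0), weber > 0, weber_dd > 0,
            inherits(illum, "illuminant"))
  if ("LW" %in% chrom && abs(abundances[["LW"]] - 1) > 1e-12) {
    stop("the reference cone (LW) must have abundance 1")
  }
  structure(list(sensitivities = sensitivities,
                 abundances = abundances,
                 weber = weber, weber_dd = weber_dd,
                 illuminant = illum,
                 chromatic = chrom),
            class = "viewer_model")
}

#' The default blue tit receiver
#'
#' Tetrachromatic viewer with nomogram sensitivities peaking at 371 (UV),
#' 448 (SW), 503 (MW) and 563 nm (LW); the DD cone shares the LW pigment.
#' Chromatic cone abundances UV = 0.3704, SW = 0.7111, MW = 0.9926,
#' LW = 1.0; Weber fraction 0.05 for both the chromatic reference channel
#' and the DD channel; D65 quantal illuminant by default.
#'
#' @param illum An [illuminant()] (default D65).
#' @param weber,weber_dd Weber fractions (default 0.05 each).
#' @return A [viewer_model()].
#' @export
bluetit_viewer <- function(illum = illuminant("D65"),
                           weber = 0.05, weber_dd = 0.05) {
  lw <- pigment_template(563)
  viewer_model(
    sensitivities = list(UV = pigment_template(371),
                         SW = pigment_template(448),
                         MW = pigment_template(503),
                         LW = lw, DD = lw),
    abundances = c(UV = 0.3704, SW = 0.7111, MW = 0.9926, LW = 1.0),
    weber = weber, weber_dd = weber_dd, illum = illum)
}

#' Reduced two-receptor (dichromat) viewer
#'
#' Keeps only two chromatic cone classes of an existing viewer; used for
#' the closed-form dichromat discriminability limit.
#'
#' @param viewer A [viewer_model()].
#' @param keep Character vector of two chromatic cone classes.
#' @return A [viewer_model()] with two chromatic cones (abundances
#'   rescaled so the more abundant kept cone is the reference only if it is
#'   LW; otherwise abundances are kept as-is, which the noise model
#'   supports).
#' @export
dichromat_viewer <- function(viewer, keep = c("MW", "LW")) {
  stopifnot(inherits(viewer, "viewer_model"), length(keep) == 2L,
            all(keep %in% viewer$chromatic))
  sens <- viewer$sensitivities[c(keep, "DD")]
  structure(list(sensitivities = sens,
                 abundances = viewer$abundances[keep],
                 weber = viewer$weber, weber_dd = viewer$weber_dd,
                 illuminant = viewer$illuminant,
                 chromatic = keep),
            class = "viewer_model")
}

#' Quantum catch of one receptor
#'
#' Trapezoidal integral of reflectance x illuminant x sensitivity over the
#' 1 nm grid, floored at 1e-12 so downstream log-ratios are defined for
#' pathological (all-zero) spectra.
#'
#' @param spectrum A [refl_spectrum()].
#' @param cone A `cone_sensitivity` (see [pigment_template()]).
#' @param illum An [illuminant()].
#' @return Single positive number.
#' @export
quantum_catch <- function(spectrum, cone, illum) {
  stopifnot(inherits(spectrum, "refl_spectrum"),
            inherits(cone, "cone_sensitivity"),
            inherits(illum, "illuminant"))
  integrand <- spectrum$reflectance * illum$irradiance * cone$sensitivity
  max(trapz_1nm(integrand), 1e-12)
}

# trapezoidal rule on the unit-step grid
trapz_1nm <- function(y) sum(y) - (y[1L] + y[length(y)]) / 2

#' Cone catch vector for all receptor classes of a viewer
#'
#' One quantum catch per cone class (chromatic classes plus DD). No von
#' Kries normalisation is applied; the RNL model is invariant to uniform
#' catch scaling, and the greenness ratio is scale-free.
#'
#' @param spectrum A [refl_spectrum()].
#' @param viewer A [viewer_model()].
#' @return A `cone_catch`: named numeric vector (one entry per cone class)
#'   with attributes `label` and `chromatic`.
#' @export
catch_vector <- function(spectrum, viewer) {
  stopifnot(inherits(viewer, "viewer_model"))
  q <- vapply(viewer$sensitivities, function(s)
    quantum_catch(spectrum, s, viewer$illuminant), numeric(1))
  structure(q, label = spectrum$label, chromatic = viewer$chromatic,
            class = "cone_catch")
}

#' Greenness: the MW/(MW + LW) opponent ratio
#'
#' @param catch A `cone_catch` (or any named vector with `MW`, `LW`).
#' @return Value in (0, 1); 0.5 when the two catches are equal.
#' @export
greenness <- function(catch) {
  unname(catch[["MW"]] / (catch[["MW"]] + catch[["LW"]]))
}

#' Luminance: the double-cone (DD) catch
#'
#' @param catch A `cone_catch` with a `DD` entry.
#' @return The DD quantum catch (positive).
#' @export
luminance <- function(catch) unname(catch[["DD"]])

# Vertices of the regular tetrahedron used for colour space: centred on the
# origin, circumradius 0.75, UV on +z; the other three vertices lie at
# z = -0.25 on a circle of radius 0.75 * sqrt(8)/3 = sqrt(2)/2.
TETRA_VERTICES <- local({
  r <- 0.75 * sqrt(8) / 3
  rbind(UV = c(0, 0, 0.75),
        SW = c(r, 0, -0.25),
        MW = c(-r / 2,  r * sqrt(3) / 2, -0.25),
        LW = c(-r / 2, -r * sqrt(3) / 2, -0.25))
})

#' Map a cone catch vector into tetrahedral colour space
#'
#' Relative chromatic catches r_i = q_i / sum(q) are barycentric
#' coordinates of a point in a regular tetrahedron centred on the origin
#' with circumradius 0.75 and the UV vertex on the +z axis. Equal
#' stimulation of all four cones maps to the origin; a pure-cone stimulus
#' maps to that cone's vertex.
#'
#' @param catch A `cone_catch` with positive `UV`, `SW`, `MW`, `LW`.
#' @return A `tetra_point`: named numeric `c(x, y, z)`.
#' @export
tetra_coords <- function(catch) {
  q <- unclass(catch)[c("UV", "SW", "MW", "LW")]
  r <- q / sum(q)
  p <- drop(r %*% TETRA_VERTICES)
  structure(setNames(as.numeric(p), c("x", "y", "z")), class = "tetra_point")
}

#' Per-individual perceptual summary
#'
#' @param spectra Named list of [refl_spectrum()] (one per individual).
#' @param viewer A [viewer_model()].
#' @return Data frame with columns `individual_id`, `greenness`,
#'   `luminance`, `tetra_x`, `tetra_y`, `tetra_z`.
#' @export
perceptual_summary <- function(spectra, viewer = bluetit_viewer()) {
  rows <- lapply(spectra, function(s) {
    q <- catch_vector(s, viewer)
    tp <- tetra_coords(q)
    data.frame(individual_id = s$label,
               greenness = greenness(q), luminance = luminance(q),
               tetra_x = tp[["x"]], tetra_y = tp[["y"]], tetra_z = tp[["z"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
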