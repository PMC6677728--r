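# Illuminants on the shared 1 nm grid, in relative quantal units.

# CIE standard illuminant D65, relative spectral power distribution (energy
# units), 300-700 nm at 5 nm steps (CIE 15 tabulation, 560 nm = 100).
D65_WL <- seq(300, 700, by = 5)
D65_SPD <- c(
    0.0341,   1.6643,   3.2945,  11.7652,  20.2360,  28.6447,  37.0535,
   38.5011,  39.9488,  42.4302,  44.9117,  45.7750,  46.6383,  49.3637,
   52.0891,  51.0323,  49.9755,  52.3118,  54.6482,  68.7015,  82.7549,
   87.1204,  91.4860,  92.4589,  93.4318,  90.0570,  86.6823,  95.7736,
  104.8650, 110.9360, 117.0080, 117.4100, 117.8120, 116.3360, 114.8610,
  115.3920, 115.9230, 112.3670, 108.8110, 109.0820, 109.3540, 108.5780,
  107.8020, 106.2960, 104.7900, 106.2390, 107.6890, 106.0470, 104.4050,
  104.2250, 104.0460, 102.0230, 100.0000,  98.1671,  96.3342,  96.0611,
   95.7880,  92.2368,  88.6856,  89.3459,  90.0062,  89.8026,  89.5991,
   88.6489,  87.6987,  85.4936,  83.2886,  83.4939,  83.6992,  81.8630,
   80.0268,  80.1207,  80.2146,  81.2462,  82.2778,  80.2810,  78.2842,
   74.0027,  69.7213,  70.6652,  71.6091)

#' Standard illuminants in quantal units
#'
#' Returns an illuminant on the 300--700 nm 1 nm grid as relative quantal
#' irradiance (photon flux). `"D65"` is the CIE daylight illuminant: the
#' tabulated energy spectrum is converted to quanta (multiplied by
#' wavelength), linearly interpolated to 1 nm, and normalised to a maximum
#' of 1. `"ideal"` is flat in quanta (equal photon flux at every
#' wavelength). Receptor-noise JNDs are invariant to the overall scale of
#' the illuminant, so the normalisation is cosmetic.
#'
#' @param name `"D65"` or `"ideal"`.
#' @return An `illuminant`: list with `name`, `wl` and `irradiance`
#'   (401 non-negative values).
#' @export
illuminant <- function(name = c("D65", "ideal")) {
  name <- match.arg(name)
  irr <- switch(name,
    D65 = {
      quanta <- D65_SPD * D65_WL
      q <- approx(D65_WL, quanta, xout = VIS_GRID, method = "linear")$y
      q / max(q)
    },
    ideal = rep(1, length(VIS_GRID)))
  structure(list(name = name, wl = VIS_GRID, irradiance = irr),
            class = "illuminant")
}

#' Build an illuminant from a user-supplied table
#'
#' @param wl Wavelengths (nm) covering 300--700 nm.
#' @param irradiance Relative quantal irradiance, all values >= 0, not all
#'   zero.
#' @param name Label.
#' @return An `illuminant` on the 1 nm grid.
#' @export
illuminant_from_table <- function(wl, irradiance, name = "custom") {
  stopifnot(length(wl) == length(irradiance))
  if (any(irradiance < 0)) stop("irradiance must be non-negative")
  y <- approx(wl, irradiance, xout = VIS_GRID, method = "linear", rule = 2)$y
  if (all(y == 0)) stop("irradiance is identically zero on the grid")
  structure(list(name = name, wl = VIS_GRID, irradiance = y),
            class = "illuminant")
}
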