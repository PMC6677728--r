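# Receptor-noise-limited (RNL) discriminability in JND units.

#' Receptor noise per chromatic channel
#'
#' Noise is limited by relative receptor abundance:
#' `e_i = w / sqrt(eta_i)`, with the Weber fraction `w` anchored to the
#' most abundant (reference) cone, LW (`eta_LW = 1`, so `e_LW = w`).
#'
#' @param viewer A [viewer_model()].
#' @return Named numeric vector of noise values, one per chromatic cone.
#' @export
receptor_noise <- function(viewer) {
  stopifnot(inherits(viewer, "viewer_model"))
  viewer$weber / sqrt(viewer$abundances)
}

#' Chromatic discriminability (RNL model) in JND units
#'
#' Receptor signals are log catch ratios `df_i = ln(q_i^a / q_i^b)`; the
#' discriminability is `sqrt(N/D)` with
#' `N = sum over cone pairs (i < j) of (prod of e over the other cones)^2
#' (df_j - df_i)^2` and `D = sum over cones i of (prod of e over the other
#' cones)^2`. This is the standard n-receptor form; with two receptors it
#' collapses to `|df_1 - df_2| / sqrt(e_1^2 + e_2^2)`, and it is zero
#' whenever the two catch vectors differ only by an overall scale.
#'
#' @param a,b `cone_catch` vectors (see [catch_vector()]).
#' @param viewer The [viewer_model()] providing abundances and Weber
#'   fraction.
#' @return Non-negative number (JND).
#' @export
chromatic_jnd <- function(a, b, viewer) {
  chrom <- viewer$chromatic
  e <- receptor_noise(viewer)[chrom]
  df <- log(unclass(a)[chrom] / unclass(b)[chrom])
  n <- length(chrom)
  if (n < 2L) stop("need at least two chromatic receptors")
  num <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      num <- num + prod(e[-c(i, j)])^2 * (df[j] - df[i])^2
    }
  }
  den <- sum(vapply(seq_len(n), function(i) prod(e[-i])^2, numeric(1)))
  unname(sqrt(num / den))
}

#' Achromatic (luminance) discriminability in JND units
#'
#' `|ln(q_DD^a / q_DD^b)| / w_DD`, the double-cone channel contrast scaled
#' by its Weber fraction.
#'
#' @inheritParams chromatic_jnd
#' @return Non-negative number (JND).
#' @export
achromatic_jnd <- function(a, b, viewer) {
  abs(log(a[["DD"]] / b[["DD"]])) / viewer$weber_dd
}

#' Classify a JND value against standard discriminability thresholds
#'
#' Values below 1 JND mean the two stimuli are indiscriminable to the
#' modelled receiver; 1--3 JND are discriminable only under good viewing
#' conditions; above 3 JND they are increasingly easy to tell apart.
#'
#' @param jnd Non-negative numeric (vectorised).
#' @return Character vector: `"indiscriminable"`, `"conditional"` or
#'   `"discriminable"`.
#' @export
classify_jnd <- function(jnd) {
  if (any(jnd < 0)) stop("JND must be non-negative")
  ifelse(jnd < 1, "indiscriminable",
         ifelse(jnd <= 3, "conditional", "discriminable"))
}

#' Full discrimination result for a stimulus pair
#'
#' @inheritParams chromatic_jnd
#' @return A `discrimination_result`: list with per-cone log contrasts
#'   `delta_f`, `jnd_chromatic`, `jnd_achromatic` and their threshold
#'   classes.
#' @export
discriminate <- function(a, b, viewer = bluetit_viewer()) {
  chrom <- viewer$chromatic
  df <- log(unclass(a)[chrom] / unclass(b)[chrom])
  jc <- chromatic_jnd(a, b, viewer)
  ja <- achromatic_jnd(a, b, viewer)
  structure(list(delta_f = df,
                 jnd_chromatic = jc, jnd_achromatic = ja,
                 class_chromatic = classify_jnd(jc),
                 class_achromatic = classify_jnd(ja)),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat("<discrimination> chromatic ", signif(x$jnd_chromatic, 4), " JND (",
      x$class_chromatic, "), achromatic ", signif(x$jnd_achromatic, 4),
      " JND (", x$class_achromatic, ")\n", sep = "")
  invisible(x)
}

#' Pairwise discrimination table
#'
#' @param spectra_a,spectra_b Named lists of [refl_spectrum()]; every
#'   spectrum in `spectra_a` is compared with every spectrum in
#'   `spectra_b`.
#' @param viewer A [viewer_model()].
#' @return Data frame with columns `id_a`, `id_b`, `jnd_chromatic`,
#'   `jnd_achromatic`, `class_chromatic`, `class_achromatic`.
#' @export
pairwise_jnd <- function(spectra_a, spectra_b, viewer = bluetit_viewer()) {
  qa <- lapply(spectra_a, catch_vector, viewer = viewer)
  qb <- lapply(spectra_b, catch_vector, viewer = viewer)
  grid <- expand.grid(a = seq_along(qa), b = seq_along(qb))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    i <- grid$a[k]; j <- grid$b[k]
    jc <- chromatic_jnd(qa[[i]], qb[[j]], viewer)
    ja <- achromatic_jnd(qa[[i]], qb[[j]], viewer)
    data.frame(id_a = attr(qa[[i]], "label"), id_b = attr(qb[[j]], "label"),
               jnd_chromatic = jc, jnd_achromatic = ja,
               class_chromatic = classify_jnd(jc),
               class_achromatic = classify_jnd(ja))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
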