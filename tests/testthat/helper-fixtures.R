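# Shared fixtures and independent oracles, all built in code.

GRID <- 300:700

flat_spectrum <- function(value, label = "flat") {
  refl_spectrum(rep(value, length(GRID)), label = label)
}

# cone catch assembled by hand (bypasses spectra) for algebraic tests
manual_catch <- function(uv, sw, mw, lw, dd = 1, label = "manual") {
  structure(c(UV = uv, SW = sw, MW = mw, LW = lw, DD = dd),
            label = label, chromatic = c("UV", "SW", "MW", "LW"),
            class = "cone_catch")
}

# write a wide spectra CSV (wavelength_nm + measurement columns)
write_spectra_fixture <- function(wl, mat, path = tempfile(fileext = ".csv")) {
  df <- data.frame(wavelength_nm = wl, mat, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  path
}

# Independent oracle for the tetrachromatic RNL discriminability: the
# explicit six-term quadratic form written out receptor pair by receptor
# pair (1 = UV, 2 = SW, 3 = MW, 4 = LW), kept separate from the package's
# generic loop implementation.
oracle_jnd_tetra <- function(qa, qb, e) {
  f <- log(qa / qb)
  num <- (e[1] * e[2])^2 * (f[4] - f[3])^2 +
         (e[1] * e[3])^2 * (f[4] - f[2])^2 +
         (e[1] * e[4])^2 * (f[3] - f[2])^2 +
         (e[2] * e[3])^2 * (f[4] - f[1])^2 +
         (e[2] * e[4])^2 * (f[3] - f[1])^2 +
         (e[3] * e[4])^2 * (f[2] - f[1])^2
  den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
         (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
  unname(sqrt(num / den))
}

random_catch <- function() {
  q <- exp(stats::rnorm(5, 0, 1))
  manual_catch(q[1], q[2], q[3], q[4], q[5])
}
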