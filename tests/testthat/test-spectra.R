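test_that("read_spectra parses delimited tables and validates wavelengths", {
  path <- write_spectra_fixture(GRID, matrix(0.5, length(GRID), 1,
                                             dimnames = list(NULL, "ind1_1")))
  tab <- read_spectra(path)
  expect_s3_class(tab, "spectrum_table")
  expect_equal(ncol(tab$measurements), 1L)
  expect_equal(nrow(tab$measurements), 401L)
  expect_equal(unname(tab$measurements[, 1]), rep(0.5, 401))
  expect_equal(tab$individual, "ind1")

  # tab-separated variant is auto-detected
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(wavelength_nm = GRID, ind2_1 = 0.25), tsv,
              sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(unname(read_spectra(tsv)$measurements[, 1]), rep(0.25, 401))

  desc <- write_spectra_fixture(rev(GRID),
                                matrix(0.5, 401, 1, dimnames = list(NULL, "a_1")))
  expect_error(read_spectra(desc), "wavelengths not increasing")
})

test_that("percent-scale columns are auto-detected and rescaled", {
  m <- cbind(pct_1 = seq(0, 100, length.out = 401),
             prop_1 = rep(0.4, 401))
  expect_message(tab <- spectrum_table(GRID, m), "percent-scale")
  expect_lte(max(tab$measurements[, "pct_1"]), 1)
  expect_equal(max(tab$measurements[, "pct_1"]), 1)      # 100 / 100
  expect_equal(tab$measurements[, "prop_1"], m[, "prop_1"])  # untouched
})

test_that("metadata must cover every measurement column", {
  m <- matrix(0.5, 401, 2, dimnames = list(NULL, c("a_1", "b_1")))
  md <- data.frame(individual_id = "a", treatment = "green")
  expect_error(spectrum_table(GRID, m, metadata = md), "b")
  md2 <- rbind(md, data.frame(individual_id = "b", treatment = "brown"))
  expect_silent(spectrum_table(GRID, m, metadata = md2))
})

test_that("resample_1nm interpolates, clips and respects the edge tolerance", {
  # identity on the native grid
  tab <- spectrum_table(GRID, matrix(seq(0, 1, length.out = 401), 401, 1,
                                     dimnames = list(NULL, "a_1")))
  s <- resample_1nm(tab, "a_1")
  expect_s3_class(s, "refl_spectrum")
  expect_equal(s$reflectance, seq(0, 1, length.out = 401))

  # irregular 0.37 nm grid over [299.8, 700.3] -> forced 401-point output
  wl <- seq(299.8, 700.3, by = 0.37)
  tab2 <- spectrum_table(wl, matrix(0.3, length(wl), 1,
                                    dimnames = list(NULL, "b_1")))
  s2 <- resample_1nm(tab2, 1L)
  expect_length(s2$reflectance, 401L)
  expect_equal(s2$wl, 300:700)

  # negative instrument noise is clipped to 0
  y <- rep(0.1, 401); y[GRID == 305] <- -0.02
  tab3 <- spectrum_table(GRID, matrix(y, 401, 1, dimnames = list(NULL, "c_1")))
  expect_equal(resample_1nm(tab3, 1L)$reflectance[GRID == 305], 0)

  # span short by <= 2 nm: flat edge extension
  wl4 <- 302:699
  tab4 <- spectrum_table(wl4, matrix(seq(0.2, 0.8, length.out = length(wl4)),
                                     ncol = 1, dimnames = list(NULL, "d_1")))
  s4 <- resample_1nm(tab4, 1L)
  expect_equal(s4$reflectance[1:3], rep(0.2, 3))

  # span short by > 2 nm: hard error naming the gap
  wl5 <- 305:700
  tab5 <- spectrum_table(wl5, matrix(0.5, length(wl5), 1,
                                     dimnames = list(NULL, "e_1")))
  expect_error(resample_1nm(tab5, 1L), "2 nm")
})

test_that("resample_1nm is idempotent and commutes with averaging", {
  set.seed(11)
  y <- pmin(pmax(0.4 + cumsum(rnorm(401, 0, 0.004)), 0), 1)
  tab <- spectrum_table(GRID, cbind(a_1 = y))
  once <- resample_1nm(tab, 1L)
  twice <- resample_1nm(spectrum_table(once$wl, cbind(a_1 = once$reflectance)), 1L)
  expect_identical(once$reflectance, twice$reflectance)

  # mean of interpolations equals interpolation of the mean (both linear)
  wl <- seq(299, 701, by = 0.7)
  m <- cbind(a_1 = runif(length(wl), 0.2, 0.4), a_2 = runif(length(wl), 0.3, 0.6))
  tab2 <- spectrum_table(wl, m)
  mean_of_interp <- suppressWarnings(
    average_individual(list(resample_1nm(tab2, 1L), resample_1nm(tab2, 2L)),
                       label = "a"))
  interp_of_mean <- resample_1nm(spectrum_table(wl, cbind(a_1 = rowMeans(m))), 1L)
  expect_equal(mean_of_interp$reflectance, interp_of_mean$reflectance,
               tolerance = 1e-12)
})

test_that("average_individual averages replicates and warns off the 6-count", {
  six <- replicate(6, flat_spectrum(0.37, "id_1"), simplify = FALSE)
  expect_equal(average_individual(six)$reflectance, rep(0.37, 401))

  two <- list(flat_spectrum(0.2, "id_1"), flat_spectrum(0.4, "id_2"))
  expect_warning(avg <- average_individual(two, label = "id"), "6")
  expect_equal(avg$reflectance, rep(0.3, 401))

  five <- replicate(5, flat_spectrum(0.1, "id_1"), simplify = FALSE)
  expect_warning(average_individual(five), "got 5")
  expect_error(average_individual(list()), "empty")
})

test_that("group_summary computes pointwise mean and SE", {
  one <- group_summary(list(flat_spectrum(0.42)), "solo")
  expect_equal(one$mean, rep(0.42, 401))
  expect_equal(one$se, rep(0, 401))
  expect_equal(one$n, 1L)

  # sd of {0.2, 0.4} = sqrt(0.02) = 0.1414..., SE = sd/sqrt(2) = 0.1
  two <- group_summary(list(flat_spectrum(0.2), flat_spectrum(0.4)), "pair")
  expect_equal(two$mean, rep(0.3, 401))
  expect_equal(two$se, rep(0.1, 401), tolerance = 1e-12)

  # n = 4: brute-force per-wavelength recomputation
  set.seed(21)
  specs <- replicate(4, refl_spectrum(runif(401, 0.1, 0.9)), simplify = FALSE)
  g <- group_summary(specs, "g4")
  m <- sapply(specs, function(s) s$reflectance)
  brute_mean <- apply(m, 1, mean)
  brute_se <- apply(m, 1, function(x) sqrt(sum((x - mean(x))^2) / 3) / 2)
  expect_equal(g$mean, brute_mean, tolerance = 1e-12)
  expect_equal(g$se, brute_se, tolerance = 1e-12)
})

test_that("emitted reflectances always lie in [0, 1] on the 401-point grid", {
  set.seed(31)
  for (i in 1:20) {
    wl <- sort(runif(60, 298, 702))
    if (min(wl) > 302 || max(wl) < 698) next
    y <- rnorm(60, 0.5, 0.6)  # deliberately out of range
    s <- resample_1nm(spectrum_table(wl, cbind(x_1 = y)), 1L)
    expect_length(s$reflectance, 401L)
    expect_true(all(s$reflectance >= 0 & s$reflectance <= 1))
  }
})

test_that("individual_spectra aggregates per individual or per measurement", {
  m <- cbind(a_1 = rep(0.2, 401), a_2 = rep(0.4, 401), a_3 = rep(0.3, 401),
             a_4 = rep(0.3, 401), a_5 = rep(0.3, 401), a_6 = rep(0.3, 401),
             b_1 = rep(0.6, 401), b_2 = rep(0.8, 401), b_3 = rep(0.7, 401),
             b_4 = rep(0.7, 401), b_5 = rep(0.7, 401), b_6 = rep(0.7, 401))
  tab <- spectrum_table(GRID, m)
  ind <- individual_spectra(tab)
  expect_named(ind, c("a", "b"))
  expect_equal(ind$a$reflectance, rep(0.3, 401))
  meas <- individual_spectra(tab, aggregate = "measurement")
  expect_length(meas, 12L)
  expect_equal(meas$b_2$reflectance, rep(0.8, 401))
})
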