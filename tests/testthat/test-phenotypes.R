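# Needle functional trait arithmetic and spectra preprocessing.

test_that("reflectance ratio behaves as identity, zero and scaling", {
  w <- c(10, 20, 30)
  expect_equal(reflectance_from_radiance(w, w), c(1, 1, 1))
  expect_equal(reflectance_from_radiance(c(0, 0, 0), w), c(0, 0, 0))
  expect_equal(reflectance_from_radiance(0.42 * w, w), rep(0.42, 3))
  expect_error(reflectance_from_radiance(w, c(10, 0, 30)), "band")
  expect_error(reflectance_from_radiance(w, w[1:2]), "length")
})

test_that("median spectrum is the per-band order statistic, permutation
           invariant, with the even-count convention", {
  one <- c(0.1, 0.5, 0.9)
  expect_equal(median_needle_spectrum(rbind(one, one, one, one, one)), one,
               ignore_attr = TRUE)
  scans <- matrix(c(0.1, 0.2, 0.3, 0.9, 0.95), 5, 1)
  expect_equal(unname(median_needle_spectrum(scans)), 0.3)
  expect_equal(unname(median_needle_spectrum(matrix(c(1, 2, 3, 10), 4, 1))),
               2.5)
  m <- matrix(runif(20), 5, 4)
  expect_equal(median_needle_spectrum(m),
               median_needle_spectrum(m[c(3, 1, 5, 2, 4), ]))
  expect_error(median_needle_spectrum(list(1:3, 1:4)), "ragged")
})

test_that("canopy preprocessing smooths pairs and trims to the analysis
           window", {
  wl <- seq(400, 1000, length.out = 269)
  const <- spectra_table("r1", wl, matrix(0.5, 1, 269))
  out <- preprocess_canopy_bands(const)
  expect_equal(length(out$wavelengths), 220L)
  expect_equal(unname(out$reflectance[1, ]), rep(0.5, 220))
  # alternating fluctuation collapses to the midpoint after pair-averaging
  alt <- spectra_table("r1", wl, matrix(rep(c(0.4, 0.6), length.out = 269),
                                        1, 269))
  sm <- preprocess_canopy_bands(alt)
  expect_true(all(abs(sm$reflectance[1, -220] - 0.5) < 1e-12))
  # band-count contract for arbitrary sizes
  for (n in c(60, 123)) {
    st <- spectra_table("x", seq_len(n), matrix(runif(n), 1, n))
    expect_equal(length(preprocess_canopy_bands(st, 7, 11)$wavelengths),
                 n - 18L)
  }
  expect_error(preprocess_canopy_bands(
    spectra_table("x", 1:20, matrix(0.1, 1, 20))), "few bands")
})

test_that("pigment equations match direct hand evaluation", {
  # A'664 = 0.5, A'647 = 0.2, A'480 = 0.6, 5 mL, 0.05 g
  out <- pigment_concentrations(a480 = 0.6, a647 = 0.2, a664 = 0.5,
                                a750 = 0, extract_volume = 5,
                                dry_mass = 0.05)
  chl_a <- 11.65 * 0.5 - 2.69 * 0.2          # 5.287 ug/mL
  chl_b <- 20.81 * 0.2 - 4.53 * 0.5          # 1.897
  car <- (1000 * 0.6 - 0.89 * chl_a - 52.02 * chl_b) / 245
  f <- 5 / 0.05 / 1000                       # ug/mL -> mg/g
  expect_equal(out$chl_a_M, chl_a * f)
  expect_equal(out$chl_b_M, chl_b * f)
  expect_equal(out$chl_T_M, (chl_a + chl_b) * f)
  expect_equal(out$car_M, car * f)
  expect_equal(out$car_chlT_ratio, car / (chl_a + chl_b))
  # doubling the extract volume doubles every mass-based pigment
  out2 <- pigment_concentrations(0.6, 0.2, 0.5, 0, 10, 0.05)
  expect_equal(out2$chl_a_M, 2 * out$chl_a_M)
  # zero absorbances: zero pigments, ratio flagged undefined
  z <- pigment_concentrations(0, 0, 0, 0, 5, 0.05)
  expect_equal(unlist(z[1:4]), c(chl_a_M = 0, chl_b_M = 0, chl_T_M = 0,
                                 car_M = 0))
  expect_true(is.na(z$car_chlT_ratio))
  # the 750 nm turbidity blank is subtracted first
  shifted <- pigment_concentrations(0.7, 0.3, 0.6, 0.1, 5, 0.05)
  expect_equal(shifted$chl_a_M, out$chl_a_M)
  expect_warning(pigment_concentrations(0.05, 0.2, 0.5, 0.1, 5, 0.05),
                 "clipped")
})

test_that("structural traits follow their defining ratios", {
  dry <- structural_traits(0.2, 0.2, 4)
  expect_equal(c(dry$LMA, dry$NWC, dry$EWT), c(0.05, 0, 0))
  s <- structural_traits(0.30, 0.12, 6, needle_length = 4.2)
  expect_equal(c(s$LMA, s$NWC, s$EWT, s$NL), c(0.02, 60, 0.03, 4.2))
  s2 <- structural_traits(0.60, 0.24, 6)
  expect_equal(s2$NWC, s$NWC)          # scale invariance of a percentage
  expect_equal(s2$LMA, 2 * s$LMA)
  expect_equal(s2$EWT, 2 * s$EWT)
  expect_error(structural_traits(0.1, 0.2, 5), "impossible")
})

test_that("mass-to-area conversion and its invariants", {
  expect_equal(area_based_pigments(2, LMA = 0.02), 40)
  expect_equal(area_based_pigments(0, LMA = 0.02), 0)
  expect_error(area_based_pigments(1, LMA = 0), "LMA")
  pig <- pigment_concentrations(0.6, 0.2, 0.5, 0, 5, 0.05)
  str <- structural_traits(0.30, 0.12, 6, 4.2)
  tab <- nft_table(pig, str, "ramet_1")
  expect_equal(tab$chl_T_A / tab$chl_T_M, 1000 * tab$LMA)
  expect_equal(tab$car_A / tab$car_M, 1000 * tab$LMA)
  # the carotenoid:chlorophyll ratio is basis-free
  expect_equal(tab$car_A / tab$chl_T_A, tab$car_chlT_ratio)
})

test_that("implausible reflectance is flagged per cell and per row", {
  R <- matrix(0.5, 3, 10)
  R[2, 1:2] <- 1.5
  sp <- spectra_table(c("a", "b", "c"), 1:10, R)
  sc <- screen_reflectance(sp)
  expect_equal(sum(sc$flags), 2L)
  expect_equal(sc$bad_rows, "b")
})
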