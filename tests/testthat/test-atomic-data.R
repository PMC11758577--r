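test_that("shipped Zn table carries the K-edge physics", {
  zn <- shipped_elements("Zn")$Zn
  expect_equal(round(zn$k_edge, 1), 9.7)
  expect_lt(zn$kalpha, zn$k_edge)
  expect_within(zn$omega_k, 0, 1)
  # photoelectric discontinuity at the edge: above/below ratio > 1
  expect_gt(element_k_jump(zn), 1)
  just_below <- mass_attenuation(builtin_material("ZnO"), 9.658,
                                 "photoelectric")
  just_above <- mass_attenuation(builtin_material("ZnO"), 9.660,
                                 "photoelectric")
  expect_gt(just_above / just_below, 1)
})

test_that("malformed element tables are rejected with the offending row", {
  d <- tempfile("badtab")
  dir.create(d)
  hdr <- "# element=X Z=9 mass=18 k_edge_keV=1.0 l_edge_keV=0.1 kalpha_keV=0.9 omega_k=0.1"
  # single data row: too short to interpolate
  writeLines(c(hdr, "energy_keV,pe_cm2g,incoh_cm2g,coh_cm2g",
               "1,10,0.1,0.1"), file.path(d, "X.csv"))
  writeLines(c("energy_keV,stopping_MeVcm2g", "1,10", "10,2"),
             file.path(d, "X_electron.csv"))
  expect_error(load_element_table(file.path(d, "X.csv")), "row")
  # non-monotone grid
  writeLines(c(hdr, "energy_keV,pe_cm2g,incoh_cm2g,coh_cm2g",
               "0.5,80,0.1,0.1", "1.5,10,0.1,0.1", "1.2,20,0.1,0.1"),
             file.path(d, "X.csv"))
  expect_error(load_element_table(file.path(d, "X.csv")), "row 3")
  # missing K-edge duplication (edge at 1.0 inside grid span)
  writeLines(c(hdr, "energy_keV,pe_cm2g,incoh_cm2g,coh_cm2g",
               "0.5,80,0.1,0.1", "1.5,10,0.1,0.1", "2,5,0.1,0.1"),
             file.path(d, "X.csv"))
  expect_error(load_element_table(file.path(d, "X.csv")), "duplicate")
  # malformed header
  writeLines(c("energy_keV,pe_cm2g", "1,2"), file.path(d, "X.csv"))
  expect_error(load_element_table(file.path(d, "X.csv")), "header")
})

test_that("toy tables round-trip field for field", {
  els <- toy_elements()
  d2 <- tempfile("roundtrip")
  write_element_table(els$T10, d2)
  back <- load_element_table(file.path(d2, "T10.csv"))
  expect_equal(back$photon, els$T10$photon, tolerance = 1e-12)
  expect_equal(back$electron, els$T10$electron, tolerance = 1e-12)
  expect_identical(back$z, els$T10$z)
  expect_equal(back$k_edge, els$T10$k_edge)
})

test_that("toy table generator enforces the edge and the E^-3 law", {
  expect_error(
    make_toy_tables(list(list(z = 5, k_edge = 1, jump_ratio = 1))),
    "jump_ratio")
  t10 <- toy_elements()$T10
  # below the 2 keV edge the photoelectric column is pure C * E^-3
  v1 <- element_pe(t10, 0.5)
  v2 <- element_pe(t10, 1.0)
  expect_equal(v2, v1 / 8, tolerance = 1e-5)  # 6-significant-digit files
  expect_equal(t10$k_edge, 2)
  expect_equal(element_k_jump(t10), 5, tolerance = 1e-4)
})

test_that("mixture mass attenuation interpolates log-log between cells", {
  els <- toy_elements()
  pure <- material("pure", 1, c(T10 = 1))
  tab <- els$T10$photon
  # at a grid energy the value is the table cell exactly
  i <- 10
  expect_equal(mass_attenuation(pure, tab$energy_keV[i], "photoelectric", els),
               tab$pe_cm2g[i])
  # midpoint: log-log interpolation against an independent recomputation
  e1 <- tab$energy_keV[i]; e2 <- tab$energy_keV[i + 1]
  emid <- sqrt(e1 * e2)
  wgt <- (log(emid) - log(e1)) / (log(e2) - log(e1))
  expected <- exp((1 - wgt) * log(tab$pe_cm2g[i]) + wgt * log(tab$pe_cm2g[i + 1]))
  expect_equal(mass_attenuation(pure, emid, "photoelectric", els), expected,
               tolerance = 1e-12)
  # no extrapolation
  expect_error(mass_attenuation(pure, 20, "total", els), "outside")
  # mixture rule: mass-fraction-weighted sum
  mix <- material("mix", 1, c(T10 = 0.3, T20 = 0.7))
  expect_equal(
    mass_attenuation(mix, 5, "photoelectric", els),
    0.3 * element_pe(els$T10, 5) + 0.7 * element_pe(els$T20, 5),
    tolerance = 1e-12)
})

test_that("total channel equals the sum of the three partial channels", {
  els <- shipped_elements()
  for (mat in list(builtin_material("SiO2"), builtin_material("ZnO"),
                   builtin_material("air"), builtin_material("TCPP"))) {
    e <- c(0.3, 1, 3.3, 6.6, 9.66, 10, 15)
    tot <- mass_attenuation(mat, e, "total", els)
    parts <- mass_attenuation(mat, e, "photoelectric", els) +
      mass_attenuation(mat, e, "incoherent", els) +
      mass_attenuation(mat, e, "coherent", els)
    expect_equal(tot, parts, tolerance = 1e-12)
  }
})

test_that("linear attenuation is the density-scaled unit bridge", {
  els <- toy_elements()
  m0 <- material("void", 0, c(T10 = 1))
  expect_equal(linear_attenuation(m0, 5, "total", els), 0)
  zno <- builtin_material("ZnO")
  expect_equal(linear_attenuation(zno, 6.6),
               mass_attenuation(zno, 6.6) * 5.61 * 1e-7, tolerance = 1e-12)
  m1 <- material("a", 2, c(T10 = 1))
  m2 <- material("b", 4, c(T10 = 1))
  expect_equal(linear_attenuation(m2, 5, "total", els),
               2 * linear_attenuation(m1, 5, "total", els), tolerance = 1e-12)
})

test_that("electron stopping obeys the mixture rule and its domain", {
  els <- toy_elements()
  pure <- material("pure", 2, c(T10 = 1))
  tab <- els$T10$electron
  i <- 5
  expect_equal(electron_stopping(pure, tab$energy_keV[i], els),
               tab$stopping_MeVcm2g[i] * 2 * 1e-4, tolerance = 1e-12)
  grid <- exp(seq(log(0.25), log(15), length.out = 40))
  expect_true(all(electron_stopping(pure, grid, els) > 0))
  expect_error(electron_stopping(pure, 0.1, els), "cutoff")
})

test_that("CSDA range agrees with an independent fine quadrature", {
  els <- shipped_elements()
  sio2 <- builtin_material("SiO2")
  r <- csda_range(sio2, 5, els)
  # composite Simpson on a dense uniform grid (independent of the log-grid
  # trapezoid used by csda_range)
  n <- 20001
  e <- seq(0.25, 5, length.out = n)
  f <- 1 / electron_stopping(sio2, e, els)
  h <- e[2] - e[1]
  oracle <- h / 3 * (f[1] + f[n] + 4 * sum(f[seq(2, n - 1, by = 2)]) +
                       2 * sum(f[seq(3, n - 2, by = 2)]))
  expect_equal(r, oracle, tolerance = 0.01)
})

test_that("material invariants are enforced", {
  expect_error(material("m", 1, c(Si = 0.5, O = 0.4)), "sum to 1")
  expect_error(material("m", -1, c(Si = 1)), "density")
  tcpp <- builtin_material("TCPP")
  expect_equal(sum(tcpp$composition), 1, tolerance = 1e-9)
  expect_equal(tcpp$density, 1.3)
})
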