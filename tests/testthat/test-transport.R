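test_that("a zero-density world transmits every primary untouched", {
  els <- toy_elements()
  m <- toy_sphere()
  m$media <- c(world = "vacuum", host = "vacuum", np = "vacuum")
  run <- run_transport(m, beam_config(8, n_histories = 500),
                       run_config(seed = 1, mode = "analog"),
                       materials = toy_materials(), elements = els)
  expect_equal(count_interactions(run)$interacting, 0)
  expect_equal(unname(sum(run$totals$edep_weighted)), 0)
  expect_equal(run$totals$escaped_weighted, 500 * 8, tolerance = 1e-9)
})

test_that("every history conserves energy to 1e-9 relative", {
  els <- toy_elements()
  m <- toy_satellite()
  for (mode in c("forced", "analog")) {
    run <- run_transport(m, beam_config(8, n_histories = 4000),
                         run_config(seed = 5, mode = mode),
                         materials = toy_materials(), elements = els)
    h <- run$histories
    lhs <- h$weight * 8
    rhs <- h$edep_world + h$edep_host + h$edep_np + h$escaped
    expect_lt(max(abs(lhs - rhs)), 1e-9 * 8)
    expect_equal(run$totals$n_conservation_fail, 0)
  }
})

test_that("analog interaction frequency matches the closed-form attenuation", {
  els <- toy_elements()
  mats <- toy_materials()
  m <- toy_sphere()
  mu <- linear_attenuation(mats$toy10, 8, "total", els)
  p_exp <- 1 - exp(-mu * 80)   # pencil beam along a diameter chord
  n <- 4e4
  run <- run_transport(m, beam_config(8, n_histories = n, beam_radius = 1e-9),
                       run_config(seed = 3, mode = "analog"),
                       materials = mats, elements = els)
  p_obs <- count_interactions(run)$per_primary
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("channel sampling follows the partial attenuation ratios", {
  els <- shipped_elements()
  sio2 <- builtin_material("SiO2")
  set.seed(2)
  n <- 1e5
  draws <- sample_channel(sio2, 6, n, els)
  p <- vapply(c("photoelectric", "incoherent", "coherent"),
              function(ch) mass_attenuation(sio2, 6, ch, els), numeric(1))
  p <- p / sum(p)
  for (ch in names(p)) {
    obs <- mean(draws == ch)
    expect_lt(abs(obs - p[[ch]]), 3 * sqrt(p[[ch]] * (1 - p[[ch]]) / n))
  }
  # 10 keV photons in ZnO interact mainly through the photoelectric effect
  zno <- builtin_material("ZnO")
  expect_gt(mass_attenuation(zno, 10, "photoelectric", els),
            mass_attenuation(zno, 10, "incoherent", els) +
              mass_attenuation(zno, 10, "coherent", els))
})

test_that("Compton sampling obeys the Klein-Nishina distribution", {
  s <- sample_compton_scatter(1e6, 10, seed = 5)
  k <- 10 / 510.99895
  # the Compton relation holds sample by sample (forward scatter -> E' = E)
  expect_equal(s$energy_out, 10 / (1 + k * (1 - s$cos_theta)),
               tolerance = 1e-12)
  expect_lt(max(s$energy_out), 10 + 1e-12)
  # mean scattered energy against independent numerical quadrature
  kn <- function(ct) {
    r <- 1 / (1 + k * (1 - ct))
    r^2 * (r + 1 / r - (1 - ct^2))
  }
  num <- stats::integrate(function(c) (10 / (1 + k * (1 - c))) * kn(c), -1, 1)$value
  den <- stats::integrate(kn, -1, 1)$value
  se <- sd(s$energy_out) / sqrt(length(s$energy_out))
  expect_lt(abs(mean(s$energy_out) - num / den), 3 * se)
})

test_that("Rayleigh sampling follows the Thomson angular law", {
  ct <- sample_thomson_scatter(1e6, seed = 7)
  # E[cos^2] under (1+c^2)*3/8 on [-1,1] is 2/5; E[cos] is 0
  se2 <- sd(ct^2) / 1000
  expect_lt(abs(mean(ct^2) - 0.4), 3 * se2)
  expect_lt(abs(mean(ct)), 3 * sd(ct) / 1000)
  # density check on coarse bins against the analytic integral
  br <- seq(-1, 1, length.out = 11)
  obs <- table(cut(ct, br))
  f <- function(c) 3 / 8 * (1 + c^2)
  expected <- vapply(seq_len(10), function(i)
    stats::integrate(f, br[i], br[i + 1])$value, numeric(1)) * 1e6
  expect_true(all(abs(obs - expected) < 4 * sqrt(expected)))
})

test_that("electron walks deposit their full energy and match the CSDA range", {
  els <- shipped_elements()
  big <- single_sphere_model(5000, 10000, "SiO2", "air")
  mats <- list(SiO2 = builtin_material("SiO2"), air = builtin_material("air"))
  one <- transport_electron(big, c(0, 0, 0), c(0, 0, 1), 5,
                            materials = mats, elements = els, seed = 3)
  expect_equal(sum(one$deposits$energy_keV) + one$escaped, 5,
               tolerance = 1e-12)
  paths <- vapply(1:25, function(s)
    transport_electron(big, c(0, 0, 0), c(0, 0, 1), 5, materials = mats,
                       elements = els, seed = s)$path_length, numeric(1))
  expect_equal(mean(paths), csda_range(builtin_material("SiO2"), 5, els),
               tolerance = 0.05)
  # just above the cutoff: a single local deposition
  tiny <- transport_electron(big, c(0, 0, 0), c(0, 0, 1), 0.2505,
                             materials = mats, elements = els, seed = 1)
  expect_equal(nrow(tiny$deposits), 1L)
  expect_equal(tiny$deposits$energy_keV, 0.2505, tolerance = 1e-12)
})

test_that("forced-first-interaction reproduces the analog estimators", {
  els <- toy_elements()
  mats <- toy_materials()
  m <- toy_satellite()
  rf <- run_transport(m, beam_config(8, n_histories = 2e4),
                      run_config(seed = 1, mode = "forced"),
                      materials = mats, elements = els)
  ra <- run_transport(m, beam_config(8, n_histories = 8e4),
                      run_config(seed = 2, mode = "analog"),
                      materials = mats, elements = els)
  cf <- count_interactions(rf)
  ca <- count_interactions(ra)
  # mean forced weight = analog interaction frequency within 3 sigma
  se <- sqrt(ca$per_primary / ca$n_histories)
  expect_lt(abs(cf$per_primary - ca$per_primary), 3 * se)
  # partition fractions agree between the two estimators
  pf <- partition_by_medium(rf, "all")
  pa <- partition_by_medium(ra, "all")
  for (med in c("toy10", "toy20")) {
    d <- abs(pf$fraction_pct[pf$medium == med] -
             pa$fraction_pct[pa$medium == med])
    expect_lt(d, 3)  # percent points; both runs are >=1e4 histories
  }
  # rays that miss every solid carry zero weight and deposit nothing
  wide <- run_transport(m, beam_config(8, n_histories = 2000,
                                       beam_radius = 150),
                        run_config(seed = 4, mode = "forced"),
                        materials = mats, elements = els)
  h <- wide$histories
  miss <- h$weight == 0
  expect_gt(sum(miss), 0)
  expect_equal(max(h$edep_world[miss] + h$edep_host[miss] +
                   h$edep_np[miss] + h$escaped[miss]), 0)
})

test_that("relaxation branches conserve energy and respect omega_K", {
  # toy element whose K edge sits just above the tracking cutoff: with
  # omega_K = 0 and single-Auger relaxation, nothing radiates and every
  # interacting history deposits the full beam energy locally
  d0 <- tempfile("w0")
  make_toy_tables(list(list(z = 12, k_edge = 0.28, jump_ratio = 8,
                            omega_k = 0)), dir = d0)
  e0 <- list(T12 = load_element_table(file.path(d0, "T12.csv")))
  mats <- list(dense = material("dense", 5000, c(T12 = 1)),
               vacuum = material("vacuum", 0, c(T12 = 1)))
  m <- single_sphere_model(40, 200, "dense", "vacuum")
  run <- run_transport(m, beam_config(0.3, n_histories = 3000),
                       run_config(seed = 6, mode = "forced",
                                  relaxation = "single-auger"),
                       materials = mats, elements = e0)
  expect_lt(run$totals$escaped_weighted, 1e-3)
  # omega_K = 1 in an optically thin sphere: every K vacancy radiates a
  # K-alpha photon (0.9 * k_edge) which almost always escapes the world
  d1 <- tempfile("w1")
  make_toy_tables(list(list(z = 12, k_edge = 0.28, jump_ratio = 1e9,
                            omega_k = 1)), dir = d1)
  e1 <- list(T12 = load_element_table(file.path(d1, "T12.csv")))
  mats_thin <- list(dense = material("dense", 5, c(T12 = 1)),
                    vacuum = material("vacuum", 0, c(T12 = 1)))
  run1 <- run_transport(m, beam_config(0.3, n_histories = 3000),
                        run_config(seed = 6, mode = "forced",
                                   relaxation = "single-auger"),
                        materials = mats_thin, elements = e1)
  w <- run1$totals$sum_weight_interacting
  expect_within(run1$totals$escaped_weighted / w,
                0.88 * 0.9 * 0.28, 1.001 * 0.9 * 0.28)
})

test_that("identical seeds reproduce identical runs", {
  els <- toy_elements()
  mats <- toy_materials()
  m <- toy_satellite()
  r1 <- run_transport(m, beam_config(8, n_histories = 2000),
                      run_config(seed = 17, mode = "forced"),
                      materials = mats, elements = els)
  r2 <- run_transport(m, beam_config(8, n_histories = 2000),
                      run_config(seed = 17, mode = "forced"),
                      materials = mats, elements = els)
  expect_identical(r1$histories, r2$histories)
  expect_identical(r1$radial, r2$radial)
  r3 <- run_transport(m, beam_config(8, n_histories = 2000),
                      run_config(seed = 18, mode = "forced"),
                      materials = mats, elements = els)
  expect_false(identical(r1$histories, r3$histories))
})
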