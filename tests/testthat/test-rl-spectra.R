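test_that("component model evaluation has its closed-form properties", {
  grid <- seq(1, 4, by = 0.002)
  empty <- component_set(numeric(0), numeric(0), numeric(0), character(0))
  expect_equal(eval_components(empty, grid), rep(0, length(grid)))
  # a unit-area Gaussian integrates to 1 over a wide grid
  one <- component_set(2.5, 0.1, 1, "positive")
  f <- eval_components(one, grid)
  expect_equal(sum(diff(grid) * (f[-1] + f[-length(f)]) / 2), 1,
               tolerance = 1e-6)
  # equal positive and negative components cancel exactly
  pair <- component_set(c(2.5, 2.5), c(0.1, 0.1), c(1, -1),
                        c("positive", "negative"))
  expect_equal(eval_components(pair, grid), rep(0, length(grid)),
               tolerance = 1e-12)
})

test_that("sign-inconsistent initial components are rejected", {
  expect_error(component_set(2, 0.1, 1, "negative"), "inconsistent")
  expect_error(component_set(2, 0.1, -1, "positive"), "inconsistent")
  expect_error(component_set(2, -0.1, 1, "positive"), "sigma")
})

test_that("a noiseless single Gaussian is recovered from a perturbed start", {
  truth <- component_set(2.5, 0.2, 3, "positive")
  grid <- seq(1, 4.6, 0.005)
  sp <- data.frame(energy_eV = grid, intensity = eval_components(truth, grid))
  fit <- fit_rl_spectrum(sp, component_set(2.4, 0.25, 2, "positive"))
  expect_true(fit$converged)
  expect_equal(fit$components$center, 2.5, tolerance = 1e-6)
  expect_equal(fit$components$sigma, 0.2, tolerance = 1e-6)
  expect_equal(fit$components$area, 3, tolerance = 1e-6)
})

test_that("fitting rejects bad grids and uncovered centers", {
  grid <- seq(2, 3, 0.01)
  sp <- data.frame(energy_eV = grid, intensity = rep(1, length(grid)))
  expect_error(fit_rl_spectrum(sp, component_set(4, 0.1, 1, "positive")),
               "cover")
  sp2 <- sp
  sp2$energy_eV[5] <- sp2$energy_eV[4]
  expect_error(fit_rl_spectrum(sp2, component_set(2.5, 0.1, 1, "positive")),
               "increasing")
})

test_that("fit descends monotonically and recovers a synthetic 6+4 spectrum", {
  truth <- example_truth_components("functionalized")
  sp <- simulate_rl_spectrum(truth, noise = "poisson", seed = 77)
  init <- perturb_components(truth, seed = 78)
  chisq0 <- sum(((eval_components(init, sp$energy_eV) - sp$intensity) /
                   sp$uncertainty)^2)
  fit <- fit_rl_spectrum(sp, init, nu = 2, max_iter = 2000)
  expect_true(fit$converged)
  expect_lte(fit$chi_square, chisq0)
  dev <- abs(fit$components$center - truth$center) / fit$components$se_center
  expect_true(all(dev <= 3))
  # dropping the four negative components strictly worsens the fit
  bare <- truth[truth$sign == "positive", ]
  class(bare) <- class(truth)
  fit0 <- fit_rl_spectrum(sp, perturb_components(bare, 79), nu = 2,
                          max_iter = 2000)
  expect_gt(fit0$chi_square, fit$chi_square)
})

test_that("the fitter matches an independent LM implementation", {
  skip_if_not_installed("minpack.lm")
  truth <- example_truth_components("functionalized")
  sp <- simulate_rl_spectrum(truth, seed = 31)
  fit <- fit_rl_spectrum(sp, truth)
  # same optimum from minpack.lm on the unconstrained parameterization
  E <- sp$energy_eV
  y <- sp$intensity
  w <- sp$uncertainty
  par0 <- c(rbind(truth$center, log(truth$sigma), truth$area))
  fmod <- function(p) {
    f <- 0
    for (i in seq_len(length(p) / 3)) {
      s <- exp(p[3 * i - 1])
      f <- f + p[3 * i] / (s * sqrt(2 * pi)) *
        exp(-(E - p[3 * i - 2])^2 / (2 * s^2))
    }
    f
  }
  ref <- minpack.lm::nls.lm(par0, fn = function(p) (fmod(p) - y) / w,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  expect_equal(fit$chi_square, sum(ref$fvec^2), tolerance = 1e-6)
  idx <- 3 * (seq_len(nrow(truth)) - 1)
  expect_equal(fit$components$center, unname(coef(ref)[idx + 1]),
               tolerance = 1e-4)
  expect_equal(fit$components$area, unname(coef(ref)[idx + 3]),
               tolerance = 1e-3)
})

test_that("default component sets match the sample variants", {
  fn <- default_component_set("functionalized")
  expect_equal(sum(fn$sign == "negative"), 4L)
  expect_equal(sort(fn$center[fn$sign == "negative"]),
               c(2.01, 2.2, 2.34, 2.5))
  bare <- default_component_set("bare")
  expect_equal(sum(bare$sign == "negative"), 0L)
  expect_gte(nrow(bare), 6L)
  expect_true(any(abs(bare$center - 2.22) < 1e-9))
  expect_true(any(abs(bare$center - 3.09) < 1e-9))
  dye <- default_component_set("dye-only")
  expect_false(any(abs(dye$center - 3.09) < 0.2))
  for (v in list(fn, bare, dye))
    expect_true(all(v$center >= 1.2 & v$center <= 4.5))
})

test_that("energy-wavelength conversion matches the Q-band pairs", {
  expect_equal(round(ev_to_nm(2.2)), 564)
  expect_equal(round(ev_to_nm(2.34)), 530)
  expect_equal(round(ev_to_nm(2.22)), 558)
  expect_equal(round(ev_to_nm(3.09)), 401)
  x <- c(0.5, 1.7, 3.2)
  expect_equal(ev_to_nm(nm_to_ev(x)), x, tolerance = 1e-12)
  expect_error(ev_to_nm(0), "positive")
  expect_error(nm_to_ev(-5), "positive")
})

test_that("component reports tabulate converged fits only", {
  truth <- component_set(c(2, 3), c(1, 0.2), c(5, 2), "positive")
  grid <- seq(0.5, 6, 0.01)
  sp <- data.frame(energy_eV = grid, intensity = eval_components(truth, grid))
  fit <- fit_rl_spectrum(sp, component_set(c(2.1, 2.9), c(0.8, 0.25),
                                           c(4, 3), "positive"))
  rep_df <- component_report(fit)
  expect_equal(rep_df$fwhm_eV[1], 2 * sqrt(2 * log(2)), tolerance = 1e-5)
  expect_equal(sum(rep_df$share_pos_pct, na.rm = TRUE), 100, tolerance = 1e-9)
  expect_equal(rep_df$center_nm, round(1239.84193 / rep_df$center_eV))
  f <- tempfile(fileext = ".csv")
  write.csv(rep_df, f, row.names = FALSE)
  expect_equal(read.csv(f), rep_df, tolerance = 1e-12)
  bad <- fit
  bad$converged <- FALSE
  expect_error(component_report(bad), "unconverged")
})

test_that("spectrum files round-trip and reject non-monotone grids", {
  sp <- simulate_rl_spectrum(example_truth_components("bare"), seed = 5)
  f <- tempfile(fileext = ".txt")
  write_spectrum(sp, f)
  back <- read_spectrum(f)
  expect_equal(back$energy_eV, sp$energy_eV)
  expect_equal(back$intensity, sp$intensity)
  expect_equal(back$uncertainty, sp$uncertainty)
  writeLines(c("1 5", "3 4", "2 2"), f)
  expect_error(read_spectrum(f), "increasing")
})
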