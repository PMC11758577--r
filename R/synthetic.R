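#' Generate a synthetic radioluminescence spectrum with known truth
#'
#' Evaluates a ground-truth component set on the grid and adds counting
#' noise: `"poisson"` draws `Poisson(scale * max(model, 0) + background)`
#' counts and rescales (per-point uncertainties `sqrt(counts) / scale`),
#' `"gaussian"` adds i.i.d. noise of standard deviation `sd`, `"none"`
#' returns the model itself.  Deterministic under `seed`; the truth set is
#' attached as attribute `"truth"`.
#'
#' @param truth A [component_set()].
#' @param grid Energy grid, eV; must cover every center +/- 4 sigma.
#' @param noise `"poisson"`, `"gaussian"` or `"none"`.
#' @param scale Counts per intensity unit (Poisson).
#' @param background Flat background counts per point (Poisson).
#' @param sd Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @return Spectrum data frame (`energy_eV`, `intensity`, `uncertainty`).
#' @export
simulate_rl_spectrum <- function(truth,
                                 grid = seq(1.0, 4.6, by = 0.005),
                                 noise = c("poisson", "gaussian", "none"),
                                 scale = 2e4, background = 100, sd = 0.01,
                                 seed = 1) {
  noise <- match.arg(noise)
  validate_components(truth)
  lo <- truth$center - 4 * truth$sigma
  hi <- truth$center + 4 * truth$sigma
  if (any(lo < min(grid)) || any(hi > max(grid)))
    stop("grid does not cover all components within 4 sigma")
  f <- eval_components(truth, grid)
  out <- with_local_seed(seed, {
    if (noise == "poisson") {
      lam <- scale * pmax(f, 0) + background
      counts <- rpois(length(grid), lam)
      data.frame(energy_eV = grid,
                 intensity = (counts - background) / scale,
                 uncertainty = pmax(sqrt(lam), 1) / scale)
    } else if (noise == "gaussian") {
      data.frame(energy_eV = grid, intensity = f + rnorm(length(grid), 0, sd),
                 uncertainty = rep(sd, length(grid)))
    } else {
      data.frame(energy_eV = grid, intensity = f)
    }
  })
  attr(out, "truth") <- truth
  out
}

#' Ground-truth component set emulating a functionalized-sample spectrum
#'
#' Six positive emission components (porphyrin bands at 1.55/1.72/1.90 eV,
#' ZnO defect band at 2.22 eV, a green defect shoulder at 2.60 eV and the
#' excitonic band at 3.09 eV) and, for `variant = "functionalized"`, four
#' narrow negative Q-band absorption components at 2.01/2.2/2.34/2.5 eV.
#'
#' @param variant `"bare"`, `"functionalized"` or `"dye-only"`.
#' @return A [component_set()].
#' @export
example_truth_components <- function(variant = c("functionalized", "bare",
                                                 "dye-only")) {
  variant <- match.arg(variant)
  pos <- component_set(
    center = c(1.55, 1.72, 1.90, 2.22, 2.60, 3.09),
    sigma = c(0.045, 0.07, 0.09, 0.28, 0.18, 0.07),
    area = c(0.5, 2.2, 0.8, 3.0, 0.9, 0.8), sign = "positive")
  neg <- component_set(
    center = c(2.01, 2.2, 2.34, 2.5), sigma = c(0.04, 0.05, 0.045, 0.05),
    area = c(-0.20, -0.25, -0.20, -0.15), sign = "negative",
    center_lo = c(2.01, 2.2, 2.34, 2.5) - 0.05,
    center_hi = c(2.01, 2.2, 2.34, 2.5) + 0.05)
  out <- switch(variant,
                functionalized = rbind(pos, neg),
                bare = pos,
                `dye-only` = pos[1:3, ])
  class(out) <- c("component_set", "data.frame")
  out
}

#' Perturb a component set into a fit starting point
#'
#' Jitters centers (Gaussian, clipped to any bounds) and scales widths and
#' areas by uniform factors: the standard initialization of a
#' parameter-recovery study, deterministic under `seed`.
#'
#' @param components A [component_set()].
#' @param seed RNG seed.
#' @param center_sd Center jitter standard deviation, eV.
#' @param sigma_range,area_range Uniform multiplicative factor ranges.
#' @return A perturbed [component_set()].
#' @export
perturb_components <- function(components, seed, center_sd = 0.015,
                               sigma_range = c(0.8, 1.3),
                               area_range = c(0.6, 1.5)) {
  with_local_seed(seed, {
    init <- components
    n <- nrow(init)
    init$center <- pmin(
      pmax(init$center + rnorm(n, 0, center_sd),
           ifelse(is.na(init$center_lo), -Inf, init$center_lo)),
      ifelse(is.na(init$center_hi), Inf, init$center_hi))
    init$sigma <- init$sigma * runif(n, sigma_range[1], sigma_range[2])
    init$area <- init$area * runif(n, area_range[1], area_range[2])
    init
  })
}

#' Benchmark configuration suite
#'
#' The satellite grid (0/10/100/215 ZnO NPs x 3.3/6.6/10 keV, 12 configs)
#' plus one powder config.  The powder size defaults to 2000 nanosystems
#' (an intensive-observable-preserving reduction of the 5e4 full size,
#' which remains available via `full_powder = TRUE`).  Seeds are fixed so
#' re-running the suite reproduces identical outputs.
#'
#' @param n_histories Histories per config.
#' @param full_powder Use the full 5e4-sphere powder assembly.
#' @param seed Base seed.
#' @return List of config lists accepted by [run_simulation()].
#' @export
make_benchmark_suite <- function(n_histories = 1e4, full_powder = FALSE,
                                 seed = 20260920) {
  energies <- c(3.3, 6.6, 10)
  nz <- c(0L, 10L, 100L, 215L)
  cfgs <- list()
  k <- 0L
  for (n in nz) {
    k <- k + 1L
    cfgs[[length(cfgs) + 1L]] <- list(
      geometry = list(kind = "satellite", n_zno = n, sio2_diameter = 80,
                      zno_np_diameter = 5, world_radius = 2000,
                      seed = seed + k),
      beam = list(energies = energies, n_histories = n_histories, tilt = 26,
                  air_column = FALSE),
      run = list(seed = seed + 100L + k, mode = "forced"))
  }
  cfgs[[length(cfgs) + 1L]] <- list(
    geometry = list(kind = "powder",
                    n_nanosystems = if (full_powder) 5e4 else 2e3,
                    sio2_diameter = 80, shell_thickness = 0.7,
                    holder_diameter_um = 8.5, holder_height_um = 1,
                    seed = seed + 50L),
    beam = list(energies = energies, n_histories = n_histories, tilt = 26,
                air_column = FALSE),
    run = list(seed = seed + 150L, mode = "forced"))
  lapply(cfgs, validate_config)
  cfgs
}
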