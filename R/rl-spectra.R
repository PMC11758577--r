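#' Gaussian component sets for radioluminescence decomposition
#'
#' A component set is a data frame with one row per Gaussian: `center` and
#' `sigma` in eV, signed `area` (arbitrary units; components are
#' area-normalized, `area / (sigma * sqrt(2*pi)) * exp(-(E - center)^2 /
#' (2 * sigma^2))`), a `sign` constraint (`"positive"`, `"negative"` or
#' `"free"`) and optional center bounds `center_lo` / `center_hi` (NA:
#' unbounded).
#'
#' @param center,sigma,area,sign,center_lo,center_hi Component fields
#'   (vectorized).
#' @return Data frame of class `component_set`.
#' @export
component_set <- function(center, sigma, area, sign = "free",
                          center_lo = NA_real_, center_hi = NA_real_) {
  n <- length(center)
  df <- data.frame(center = as.numeric(center), sigma = as.numeric(sigma),
                   area = as.numeric(area),
                   sign = rep_len(as.character(sign), n),
                   center_lo = rep_len(as.numeric(center_lo), n),
                   center_hi = rep_len(as.numeric(center_hi), n))
  validate_components(df)
  class(df) <- c("component_set", "data.frame")
  df
}

validate_components <- function(df) {
  if (any(df$sigma <= 0)) stop("sigma must be > 0")
  bad <- (df$sign == "positive" & df$area <= 0) |
         (df$sign == "negative" & df$area >= 0)
  if (any(bad))
    stop("component ", which(bad)[1L],
         " has an area inconsistent with its sign constraint")
  b <- !is.na(df$center_lo)
  if (any(b & (df$center < df$center_lo | df$center > df$center_hi)))
    stop("a component center lies outside its bounds")
  invisible(df)
}

#' Evaluate a sum of Gaussian components on an energy grid
#'
#' @param components A [component_set()] (or compatible data frame).
#' @param energy Energy grid, eV.
#' @return Numeric vector of model intensities (zero for an empty set).
#' @export
eval_components <- function(components, energy) {
  f <- numeric(length(energy))
  for (i in seq_len(nrow(components))) {
    s <- components$sigma[i]
    f <- f + components$area[i] / (s * sqrt(2 * pi)) *
      exp(-(energy - components$center[i])^2 / (2 * s^2))
  }
  f
}

#' Default initial component sets
#'
#' `bare`: six positive emission components spanning 1.5-3.1 eV, including
#' the ZnO defect band near 2.22 eV and the excitonic band near 3.09 eV.
#' `functionalized`: the bare set plus four negative-area absorption
#' components at the porphyrin Q-band energies (2.01, 2.2, 2.34, 2.5 eV),
#' each center bounded within +/- 0.05 eV.  `dye-only`: the porphyrin
#' emission bands (1.5-2 eV) only.  Initial widths are 0.15 eV
#' (0.05 eV for the narrow Q-band dips); initial areas can be scaled to a
#' spectrum's integrated intensity via `spectrum`.
#'
#' @param variant `"bare"`, `"functionalized"` or `"dye-only"`.
#' @param spectrum Optional spectrum data frame used to scale initial
#'   areas.
#' @return A [component_set()].
#' @export
default_component_set <- function(variant = c("bare", "functionalized",
                                              "dye-only"),
                                  spectrum = NULL) {
  variant <- match.arg(variant)
  dye <- data.frame(center = c(1.55, 1.72, 1.90), sigma = 0.15, area = 1,
                    sign = "positive", center_lo = NA_real_,
                    center_hi = NA_real_)
  zno <- data.frame(center = c(2.22, 2.60, 3.09), sigma = c(0.35, 0.25, 0.15),
                    area = 1, sign = "positive", center_lo = NA_real_,
                    center_hi = NA_real_)
  qb <- 0.05
  qbands <- data.frame(center = c(2.01, 2.2, 2.34, 2.5), sigma = 0.05,
                       area = -0.02, sign = "negative",
                       center_lo = c(2.01, 2.2, 2.34, 2.5) - qb,
                       center_hi = c(2.01, 2.2, 2.34, 2.5) + qb)
  df <- switch(variant,
               bare = rbind(dye, zno),
               functionalized = rbind(dye, zno, qbands),
               `dye-only` = dye)
  if (!is.null(spectrum)) df <- init_areas_ls(df, spectrum)
  class(df) <- c("component_set", "data.frame")
  df
}

# initial areas by (weighted) linear least squares at fixed centers/widths;
# sign-constraint violators are pinned to a small value of the right sign
# and the remaining areas re-solved
init_areas_ls <- function(df, spectrum) {
  E <- spectrum$energy_eV
  y <- spectrum$intensity
  w <- if (!is.null(spectrum$uncertainty) && all(spectrum$uncertainty > 0))
    spectrum$uncertainty else rep(1, length(E))
  G <- vapply(seq_len(nrow(df)), function(i) {
    s <- df$sigma[i]
    exp(-(E - df$center[i])^2 / (2 * s^2)) / (s * sqrt(2 * pi))
  }, numeric(length(E)))
  solve_ls <- function(cols, rhs) {
    a <- tryCatch(qr.solve(G[, cols, drop = FALSE] / w, rhs / w),
                  error = function(e) NULL)
    if (is.null(a)) rep(NA_real_, length(cols)) else a
  }
  a <- solve_ls(seq_len(nrow(df)), y)
  if (anyNA(a)) return(df)
  scale <- mean(abs(a))
  bad <- (df$sign == "positive" & a <= 0) | (df$sign == "negative" & a >= 0)
  if (any(bad)) {
    a[bad] <- ifelse(df$sign[bad] == "negative", -1, 1) * 0.05 * scale
    resid <- y - as.numeric(G[, bad, drop = FALSE] %*% a[bad])
    a2 <- solve_ls(which(!bad), resid)
    if (!anyNA(a2)) a[!bad] <- a2
    still <- (df$sign == "positive" & a <= 0) | (df$sign == "negative" & a >= 0)
    a[still] <- ifelse(df$sign[still] == "negative", -1, 1) * 0.05 * scale
  }
  df$area <- a
  df
}

# --- parameter transforms -------------------------------------------------
# center: smooth box (tanh) when bounded, identity otherwise
# sigma:  log
# area:   signed log under a sign constraint, identity when free
pack_components <- function(df) {
  u <- numeric(0)
  for (i in seq_len(nrow(df))) {
    if (!is.na(df$center_lo[i])) {
      lo <- df$center_lo[i]; hi <- df$center_hi[i]
      z <- 2 * (df$center[i] - lo) / (hi - lo) - 1
      z <- min(max(z, -1 + 1e-10), 1 - 1e-10)
      uc <- atanh(z)
    } else uc <- df$center[i]
    us <- log(df$sigma[i])
    ua <- switch(df$sign[i],
                 positive = log(df$area[i]),
                 negative = log(-df$area[i]),
                 free = df$area[i])
    u <- c(u, uc, us, ua)
  }
  u
}

# returns natural parameters and d(natural)/du for the chain rule
unpack_components <- function(u, df) {
  m <- nrow(df)
  center <- sigma <- area <- dc <- ds <- da <- numeric(m)
  for (i in seq_len(m)) {
    k <- 3 * (i - 1)
    if (!is.na(df$center_lo[i])) {
      lo <- df$center_lo[i]; hi <- df$center_hi[i]
      th <- tanh(u[k + 1])
      center[i] <- lo + (hi - lo) * (th + 1) / 2
      dc[i] <- (hi - lo) / 2 * (1 - th^2)
    } else {
      center[i] <- u[k + 1]; dc[i] <- 1
    }
    sigma[i] <- exp(u[k + 2]); ds[i] <- sigma[i]
    area[i] <- switch(df$sign[i],
                      positive = exp(u[k + 3]),
                      negative = -exp(u[k + 3]),
                      free = u[k + 3])
    da[i] <- if (df$sign[i] == "free") 1 else area[i]
  }
  list(center = center, sigma = sigma, area = area, dc = dc, ds = ds, da = da)
}

# reset bounded-center coordinates sitting on the saturated tanh tail
unstick_bounds <- function(u, df) {
  for (i in seq_len(nrow(df))) {
    k <- 3 * (i - 1) + 1
    if (!is.na(df$center_lo[i]) && abs(u[k]) > 4) u[k] <- 0
  }
  u
}

model_and_jacobian <- function(u, df, E) {
  p <- unpack_components(u, df)
  n <- length(E); m <- nrow(df)
  f <- numeric(n)
  J <- matrix(0, n, 3 * m)
  for (i in seq_len(m)) {
    c0 <- p$center[i]; s <- p$sigma[i]; a <- p$area[i]
    g <- exp(-(E - c0)^2 / (2 * s^2))
    amp <- a / (s * sqrt(2 * pi))
    fi <- amp * g
    f <- f + fi
    k <- 3 * (i - 1)
    J[, k + 1] <- fi * (E - c0) / s^2 * p$dc[i]
    J[, k + 2] <- fi * ((E - c0)^2 / s^2 - 1) / s * p$ds[i]
    J[, k + 3] <- g / (s * sqrt(2 * pi)) * p$da[i]
  }
  list(f = f, J = J, par = p)
}

#' Fit Gaussian components to a spectrum (damped least squares)
#'
#' Levenberg-Marquardt minimization of the (optionally
#' uncertainty-weighted) sum of squared residuals with an analytic
#' Jacobian.  Sign constraints on areas are enforced through a signed-log
#' parameterization and center bounds through a smooth tanh box transform.
#' The damping factor is multiplied by `nu` on a rejected step and divided
#' by `nu` on an accepted one; convergence is declared when the relative
#' chi-square decrease of an accepted step falls below `tol`.
#'
#' @param spectrum Data frame with `energy_eV` (strictly increasing),
#'   `intensity` and optional `uncertainty`.
#' @param components Initial [component_set()]; all centers must lie inside
#'   the grid span.
#' @param max_iter Cap on accepted steps (rejected damping trials are
#'   bounded separately at 40 per accepted step).
#' @param tol Relative chi-square convergence tolerance.
#' @param lambda0 Initial damping.
#' @param nu Damping multiplier.
#' @return Object of class `rl_fit`: fitted `components` (with standard
#'   errors from the delta method), `chi_square`, `iterations`,
#'   `converged`, `covariance` (transformed-parameter space), `residuals`
#'   and `dof`.
#' @export
fit_rl_spectrum <- function(spectrum, components, max_iter = 500,
                            tol = 1e-8, lambda0 = 1e-3, nu = 2) {
  E <- spectrum$energy_eV
  y <- spectrum$intensity
  if (any(diff(E) <= 0)) stop("energy grid must be strictly increasing")
  if (!nrow(components)) stop("at least one component is required")
  validate_components(components)
  if (any(components$center < min(E) | components$center > max(E)))
    stop("grid does not cover all component centers")
  w <- if (!is.null(spectrum$uncertainty) && all(spectrum$uncertainty > 0))
    spectrum$uncertainty else rep(1, length(E))
  weighted <- !is.null(spectrum$uncertainty) && all(spectrum$uncertainty > 0)
  df <- components
  u <- pack_components(df)
  np <- length(u)
  mj <- model_and_jacobian(u, df, E)
  r <- (mj$f - y) / w
  chisq <- sum(r^2)
  lambda <- lambda0
  iter <- 0L
  converged <- FALSE
  restarts <- 0L
  u_best <- u
  chisq_best <- chisq
  trials <- 0L
  while (iter < max_iter && trials < 40L * max_iter) {
    trials <- trials + 1L
    Jw <- mj$J / w
    A <- crossprod(Jw)
    g <- crossprod(Jw, r)
    D <- pmax(diag(A), 1e-12)
    delta <- tryCatch(solve(A + lambda * diag(D, np), -g),
                      error = function(e) NULL)
    if (is.null(delta)) {
      lambda <- lambda * nu
      if (lambda > 1e14) {
        if (restarts >= 3L) break
        restarts <- restarts + 1L
        u <- unstick_bounds(u, df)
        mj <- model_and_jacobian(u, df, E)
        r <- (mj$f - y) / w
        chisq <- sum(r^2)
        lambda <- 1
      }
      next
    }
    if (max(abs(delta)) < 1e-10) { converged <- TRUE; break }
    # trust-region-style step cap (all parameters are O(1)-scaled), and a
    # clamp keeping bounded centers off the saturated tail of the tanh box
    delta <- delta * min(1, 5 / max(abs(delta)))
    u_new <- pmin(pmax(u + as.numeric(delta), -15), 15)
    mj_new <- model_and_jacobian(u_new, df, E)
    r_new <- (mj_new$f - y) / w
    chisq_new <- sum(r_new^2)
    if (is.finite(chisq_new) && chisq_new <= chisq * (1 + 1e-12)) {
      iter <- iter + 1L
      rel <- (chisq - chisq_new) / max(chisq, 1e-300)
      u <- u_new; mj <- mj_new; r <- r_new; chisq <- chisq_new
      if (chisq < chisq_best) { chisq_best <- chisq; u_best <- u }
      lambda <- max(lambda / nu, 1e-14)
      # declare convergence only once damping is inactive, otherwise a
      # heavily damped (tiny) step would fake a small relative decrease
      if (rel < tol && lambda <= lambda0) { converged <- TRUE; break }
    } else {
      lambda <- lambda * nu
      if (lambda > 1e14) {
        # stalled: a component pinned on the saturated tail of its tanh box
        # freezes its Jacobian column; pull such coordinates back to the
        # box middle and re-seed the damping before giving up
        if (restarts >= 3L) break
        restarts <- restarts + 1L
        u <- unstick_bounds(u, df)
        mj <- model_and_jacobian(u, df, E)
        r <- (mj$f - y) / w
        chisq <- sum(r^2)
        lambda <- 1
      }
    }
  }
  if (chisq_best < chisq) { # a restart left us above the best visited point
    u <- u_best
    chisq <- chisq_best
    mj <- model_and_jacobian(u, df, E)
    r <- (mj$f - y) / w
  }
  p <- unpack_components(u, df)
  out <- df
  out$center <- p$center
  out$sigma <- p$sigma
  out$area <- p$area
  dof <- length(E) - np
  sig2 <- if (weighted) 1 else chisq / max(dof, 1)
  covu <- tryCatch(sig2 * solve(crossprod(mj$J / w)),
                   error = function(e) matrix(NA_real_, np, np))
  seu <- sqrt(pmax(diag(covu), 0))
  idx <- function(j) 3 * (seq_len(nrow(df)) - 1) + j
  out$se_center <- seu[idx(1)] * abs(p$dc)
  out$se_sigma <- seu[idx(2)] * abs(p$ds)
  out$se_area <- seu[idx(3)] * abs(p$da)
  structure(list(components = out, chi_square = chisq, iterations = iter,
                 converged = converged, covariance = covu,
                 residuals = r * w, dof = dof, weighted = weighted),
            class = "rl_fit")
}

#' @export
print.rl_fit <- function(x, ...) {
  cat(sprintf("<rl_fit> chi-square %.6g (dof %d), %d iterations, %s\n",
              x$chi_square, x$dof, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(x$components[, c("center", "sigma", "area", "sign", "se_center")])
  invisible(x)
}

#' Photon energy/wavelength conversion
#'
#' `lambda(nm) = 1239.84193 / E(eV)` and its inverse; rounding only at
#' presentation.
#'
#' @param energy Photon energy, eV (> 0).
#' @param wavelength Wavelength, nm (> 0).
#' @return Converted value(s).
#' @export
ev_to_nm <- function(energy) {
  if (any(energy <= 0)) stop("energy must be positive")
  1239.84193 / energy
}

#' @rdname ev_to_nm
#' @export
nm_to_ev <- function(wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  1239.84193 / wavelength
}

#' Tabulate a converged fit
#'
#' One row per component: center (eV and integer-rounded nm), FWHM
#' (`2 * sqrt(2 * log(2)) * sigma`), signed area, and the percentage share
#' of the summed positive area (positive components only).
#'
#' @param fit An [fit_rl_spectrum()] result; must have converged.
#' @return Data frame.
#' @export
component_report <- function(fit) {
  if (!inherits(fit, "rl_fit")) stop("fit must be an rl_fit")
  if (!fit$converged) stop("refusing to report an unconverged fit")
  co <- fit$components
  pos_tot <- sum(co$area[co$area > 0])
  data.frame(center_eV = co$center,
             center_nm = round(ev_to_nm(co$center)),
             fwhm_eV = 2 * sqrt(2 * log(2)) * co$sigma,
             area = co$area,
             share_pos_pct = ifelse(co$area > 0, 100 * co$area / pos_tot,
                                    NA_real_))
}

#' Read / write two-column spectrum files
#'
#' Delimited text with columns energy (eV), intensity and optionally a
#' per-point uncertainty.
#'
#' @param path File path.
#' @param spectrum Data frame with `energy_eV`, `intensity` and optional
#'   `uncertainty`.
#' @return `read_spectrum`: a data frame; `write_spectrum`: the path,
#'   invisibly.
#' @export
read_spectrum <- function(path) {
  df <- read.table(path, header = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("spectrum file must have at least two columns")
  names(df)[1:2] <- c("energy_eV", "intensity")
  if (ncol(df) >= 3) names(df)[3] <- "uncertainty"
  if (any(diff(df$energy_eV) <= 0))
    stop("energy grid must be strictly increasing")
  df[seq_len(min(3, ncol(df)))]
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  cols <- intersect(c("energy_eV", "intensity", "uncertainty"),
                    names(spectrum))
  write.table(spectrum[cols], path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
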