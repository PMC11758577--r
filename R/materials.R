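#' Define a material as a density plus element mass fractions
#'
#' @param name Material name.
#' @param density Bulk density in g/cm3 (zero is allowed for void-like
#'   toy media).
#' @param composition Named numeric vector of element mass fractions,
#'   summing to 1 within 1e-9.
#' @return An object of class `material`.
#' @export
material <- function(name, density, composition) {
  composition <- unlist(composition)
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop("composition must be a named vector of mass fractions")
  if (abs(sum(composition) - 1) > 1e-9)
    stop("mass fractions must sum to 1 (got ", format(sum(composition)), ")")
  if (density < 0) stop("density must be >= 0")
  structure(list(name = name, density = density, composition = composition),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s, rho = %.4g g/cm3\n", x$name, x$density))
  cat(paste(sprintf("  %s: %.4f", names(x$composition), x$composition),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Built-in materials of the nanoscintillator system
#'
#' `SiO2` (2.65 g/cm3), `ZnO` (5.61 g/cm3), standard dry `air`
#' (N 75.5 / O 23.2 / Ar 1.3 wt%, 1.205e-3 g/cm3) and the porphyrin dye
#' `TCPP` (C48H30N4O8, 1.3 g/cm3).
#'
#' @param name One of `"SiO2"`, `"ZnO"`, `"air"`, `"TCPP"`.
#' @return A [material()].
#' @export
builtin_material <- function(name = c("SiO2", "ZnO", "air", "TCPP")) {
  name <- match.arg(name)
  switch(name,
    SiO2 = material("SiO2", 2.65, c(Si = 28.085 / 60.083, O = 2 * 15.999 / 60.083)),
    ZnO  = material("ZnO", 5.61, c(Zn = 65.38 / 81.379, O = 15.999 / 81.379)),
    air  = material("air", 1.205e-3, c(N = 0.755, O = 0.232, Ar = 0.013)),
    TCPP = {
      m <- c(C = 48 * 12.011, H = 30 * 1.008, N = 4 * 14.007, O = 8 * 15.999)
      material("TCPP", 1.3, m / sum(m))
    })
}

resolve_elements <- function(material, elements) {
  miss <- setdiff(names(material$composition), names(elements))
  if (length(miss))
    stop("no element table for: ", paste(miss, collapse = ", "))
  elements[names(material$composition)]
}

#' Mass attenuation coefficient of a material
#'
#' Mass-fraction-weighted mixture of per-element coefficients, each
#' interpolated log-log linearly on its table grid.  `total` is the sum of
#' the photoelectric, incoherent and coherent channels.  Energies outside
#' any constituent's grid raise an error (no extrapolation).
#'
#' @param material A [material()].
#' @param energy Photon energy in keV (vectorized).
#' @param channel `"photoelectric"`, `"incoherent"`, `"coherent"` or
#'   `"total"`.
#' @param elements Named list of [element_record()]s
#'   (default: the shipped reference tables).
#' @return Mass attenuation coefficient(s) in cm2/g.
#' @export
mass_attenuation <- function(material, energy,
                             channel = c("total", "photoelectric",
                                         "incoherent", "coherent"),
                             elements = shipped_elements()) {
  channel <- match.arg(channel)
  recs <- resolve_elements(material, elements)
  w <- material$composition
  chan_fun <- switch(channel,
    photoelectric = element_pe,
    incoherent = element_incoh,
    coherent = element_coh,
    total = function(rec, e)
      element_pe(rec, e) + element_incoh(rec, e) + element_coh(rec, e))
  out <- 0
  for (i in seq_along(recs)) out <- out + w[[i]] * chan_fun(recs[[i]], energy)
  unname(out)
}

#' Linear attenuation coefficient in nm^-1
#'
#' [mass_attenuation()] times density, converted from cm^-1 to nm^-1
#' (factor 1e-7) for nanometre-scale transport.
#'
#' @inheritParams mass_attenuation
#' @return Linear attenuation coefficient(s) in nm^-1.
#' @export
linear_attenuation <- function(material, energy,
                               channel = c("total", "photoelectric",
                                           "incoherent", "coherent"),
                               elements = shipped_elements()) {
  mass_attenuation(material, energy, channel, elements) *
    material$density * 1e-7
}

#' Electron total stopping power of a material
#'
#' Mixture-rule (Bragg additivity) mass stopping power converted with the
#' material density to keV/nm.  Valid from the 0.25 keV tracking cutoff up
#' to the table maximum; below the cutoff transport deposits locally
#' instead of calling this.
#'
#' @inheritParams mass_attenuation
#' @param energy Electron kinetic energy in keV (vectorized), >= 0.25.
#' @return Stopping power(s) in keV/nm.
#' @export
electron_stopping <- function(material, energy, elements = shipped_elements()) {
  if (any(energy < 0.25 - 1e-12))
    stop("electron energy below the 0.25 keV cutoff; deposit locally instead")
  recs <- resolve_elements(material, elements)
  w <- material$composition
  out <- 0
  for (i in seq_along(recs)) out <- out + w[[i]] * element_stopping(recs[[i]], energy)
  # MeV cm2/g -> keV/nm: x1000 keV/MeV x rho g/cm3 x 1e-7 cm/nm
  unname(out * material$density * 1e-4)
}

#' Continuous-slowing-down range of an electron
#'
#' Integrates `1/S(E)` from the 0.25 keV cutoff to `energy` on a fine log
#' grid (trapezoid rule).
#'
#' @inheritParams electron_stopping
#' @param n Number of quadrature nodes.
#' @return Range(s) in nm.
#' @export
csda_range <- function(material, energy, elements = shipped_elements(), n = 400) {
  vapply(energy, function(e) {
    if (e <= 0.25) return(0)
    g <- exp(seq(log(0.25), log(e), length.out = n))
    f <- 1 / electron_stopping(material, g, elements)
    sum(diff(g) * (f[-1] + f[-n]) / 2)
  }, numeric(1))
}
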