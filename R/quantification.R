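#' Beer-Lambert dye concentration
#'
#' `c = A / (epsilon * d)`: molar concentration from the absorbance of the
#' first porphyrin Q-band.  The defaults are the TCPP values at 520 nm
#' (molar extinction 8900 1/(M cm), 0.1 cm cuvette).
#'
#' @param absorbance Measured absorbance (dimensionless, >= 0).
#' @param molar_extinction Molar extinction coefficient, 1/(M cm) (> 0).
#' @param path_length Optical path length, cm (> 0).
#' @param wavelength Wavelength of the measurement, nm (metadata only).
#' @return Concentration in mol/L.
#' @export
beer_lambert_concentration <- function(absorbance, molar_extinction = 8900,
                                       path_length = 0.1, wavelength = 520) {
  if (any(absorbance < 0)) stop("absorbance must be >= 0")
  if (any(molar_extinction <= 0)) stop("molar_extinction must be > 0")
  if (any(path_length <= 0)) stop("path_length must be > 0")
  absorbance / (molar_extinction * path_length)
}

#' Batch Beer-Lambert quantification from CSV
#'
#' Reads a CSV with columns `absorbance` and optional `molar_extinction`,
#' `path_length`, appends a `concentration_M` column and writes the result.
#'
#' @param input,output CSV paths.
#' @return The output data frame, invisibly.
#' @export
quantify_csv <- function(input, output) {
  df <- read.csv(input)
  if (!"absorbance" %in% names(df)) stop("input must have column 'absorbance'")
  eps <- if ("molar_extinction" %in% names(df)) df$molar_extinction else 8900
  d <- if ("path_length" %in% names(df)) df$path_length else 0.1
  df$concentration_M <- beer_lambert_concentration(df$absorbance, eps, d)
  write.csv(df, output, row.names = FALSE)
  invisible(df)
}
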