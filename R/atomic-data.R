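#' Per-element photon interaction and electron stopping-power record
#'
#' An `element_record` bundles everything the transport engine needs to know
#' about one element: identity (Z, symbol, atomic mass), K-shell quantities
#' (edge energy, mean L binding, K-alpha line, fluorescence yield), a photon
#' table with photoelectric/incoherent/coherent mass attenuation coefficients
#' on a strictly increasing keV grid, and a total mass stopping-power table
#' for electrons.
#'
#' The photoelectric column is discontinuous at the K edge.  When the edge
#' lies inside the grid span the grid carries the edge energy twice: one row
#' holds the below-edge value, the next the above-edge value, so that
#' interpolation never bridges the discontinuity.  Queries at exactly the
#' edge energy return the above-edge (right-continuous) value.
#'
#' @param z Atomic number.
#' @param symbol Element symbol.
#' @param mass Atomic mass in g/mol.
#' @param k_edge K-shell binding energy in keV.
#' @param l_edge Mean L-shell binding energy in keV.
#' @param kalpha K-alpha emission energy in keV (must be below `k_edge`).
#' @param omega_k K fluorescence yield in `[0, 1]`.
#' @param photon Data frame with columns `energy_keV`, `pe_cm2g`,
#'   `incoh_cm2g`, `coh_cm2g`.
#' @param electron Data frame with columns `energy_keV`,
#'   `stopping_MeVcm2g`.
#' @return An object of class `element_record`.
#' @export
element_record <- function(z, symbol, mass, k_edge, l_edge, kalpha, omega_k,
                           photon, electron) {
  rec <- structure(
    list(z = as.integer(z), symbol = as.character(symbol), mass = mass,
         k_edge = k_edge, l_edge = l_edge, kalpha = kalpha,
         omega_k = omega_k, photon = photon, electron = electron),
    class = "element_record")
  validate_element_record(rec)
  rec
}

validate_element_record <- function(rec) {
  ph <- rec$photon
  el <- rec$electron
  need <- c("energy_keV", "pe_cm2g", "incoh_cm2g", "coh_cm2g")
  if (!all(need %in% names(ph)))
    stop("photon table must have columns ", paste(need, collapse = ", "))
  if (nrow(ph) < 2L)
    stop("photon table has ", nrow(ph),
         " row(s); at least 2 are required for interpolation")
  if (nrow(el) < 2L)
    stop("electron table has ", nrow(el),
         " row(s); at least 2 are required for interpolation")
  e <- ph$energy_keV
  d <- diff(e)
  if (any(d < 0)) {
    bad <- which(d < 0)[1L] + 1L
    stop("photon grid not non-decreasing at row ", bad)
  }
  dup <- which(d == 0)
  edge_inside <- rec$k_edge > e[1L] && rec$k_edge < e[length(e)]
  if (edge_inside) {
    if (length(dup) != 1L || abs(e[dup] - rec$k_edge) > 1e-9 * rec$k_edge)
      stop("photon grid must duplicate the K-edge energy (",
           format(rec$k_edge), " keV) exactly once; found ",
           length(dup), " duplicate(s)",
           if (length(dup)) paste0(" at row ", dup[1L]) else "")
    if (ph$pe_cm2g[dup + 1L] <= ph$pe_cm2g[dup])
      stop("photoelectric value above the K edge (row ", dup + 1L,
           ") must exceed the below-edge value")
  } else if (length(dup) > 0L) {
    stop("duplicated grid energy at row ", dup[1L] + 1L,
         " does not coincide with the K edge")
  }
  for (col in need[-1L]) if (any(ph[[col]] <= 0))
    stop("non-positive ", col, " at row ", which(ph[[col]] <= 0)[1L])
  if (any(ph$pe_cm2g <= 0))
    stop("non-positive pe_cm2g at row ", which(ph$pe_cm2g <= 0)[1L])
  if (any(diff(el$energy_keV) <= 0))
    stop("electron grid not strictly increasing at row ",
         which(diff(el$energy_keV) <= 0)[1L] + 1L)
  if (any(el$stopping_MeVcm2g <= 0))
    stop("non-positive stopping power at row ",
         which(el$stopping_MeVcm2g <= 0)[1L])
  if (rec$omega_k < 0 || rec$omega_k > 1)
    stop("omega_k must lie in [0, 1]")
  if (rec$kalpha >= rec$k_edge)
    stop("kalpha_keV must be below k_edge_keV")
  invisible(rec)
}

#' @export
print.element_record <- function(x, ...) {
  cat(sprintf("<element_record> %s (Z=%d, A=%.3f g/mol)\n", x$symbol, x$z, x$mass))
  cat(sprintf("  K edge %.4g keV | Kalpha %.4g keV | omega_K %.3g | <L> %.4g keV\n",
              x$k_edge, x$kalpha, x$omega_k, x$l_edge))
  cat(sprintf("  photon grid: %d rows over %.3g-%.3g keV; electron grid: %d rows\n",
              nrow(x$photon), min(x$photon$energy_keV), max(x$photon$energy_keV),
              nrow(x$electron)))
  invisible(x)
}

#' Write an element record to the table-file pair
#'
#' Writes `<symbol>.csv` (photon table, with a `#`-prefixed metadata header)
#' and `<symbol>_electron.csv` into `dir`.  Energies and coefficients are
#' written with 6 significant digits.
#'
#' @param rec An [element_record()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path of the photon table file.
#' @export
write_element_table <- function(rec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(rec$symbol, ".csv"))
  hdr <- sprintf(
    "# element=%s Z=%d mass=%s k_edge_keV=%s l_edge_keV=%s kalpha_keV=%s omega_k=%s",
    rec$symbol, rec$z, signif(rec$mass, 6), signif(rec$k_edge, 6),
    signif(rec$l_edge, 6), signif(rec$kalpha, 6), signif(rec$omega_k, 6))
  ph <- rec$photon
  lines <- c(hdr, "energy_keV,pe_cm2g,incoh_cm2g,coh_cm2g",
             sprintf("%s,%s,%s,%s",
                     signif(ph$energy_keV, 9), signif(ph$pe_cm2g, 6),
                     signif(ph$incoh_cm2g, 6), signif(ph$coh_cm2g, 6)))
  writeLines(lines, path)
  el <- rec$electron
  writeLines(c("energy_keV,stopping_MeVcm2g",
               sprintf("%s,%s", signif(el$energy_keV, 9),
                       signif(el$stopping_MeVcm2g, 6))),
             file.path(dir, paste0(rec$symbol, "_electron.csv")))
  invisible(path)
}

#' Load an element record from a table-file pair
#'
#' Reads the photon table CSV written by [write_element_table()] (metadata in
#' a `# key=value` header line) together with the companion
#' `<symbol>_electron.csv` stopping-power file, validating all record
#' invariants (strictly increasing grids, positive coefficients, duplicated
#' K-edge grid energy).  Malformed input is rejected with the offending row.
#'
#' @param path Path to the photon table CSV.
#' @return An [element_record()].
#' @export
load_element_table <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#"))
    stop("malformed header in ", path, ": first line must start with '#'")
  toks <- strsplit(sub("^#\\s*", "", lines[1L]), "\\s+")[[1L]]
  kv <- strsplit(toks, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L))
    stop("malformed header in ", path, ": expected key=value tokens")
  meta <- setNames(vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L))
  need <- c("element", "Z", "mass", "k_edge_keV", "l_edge_keV",
            "kalpha_keV", "omega_k")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("malformed header in ", path, ": missing ", paste(miss, collapse = ", "))
  ph <- read.csv(text = paste(lines[-1L], collapse = "\n"))
  epath <- file.path(dirname(path), paste0(meta[["element"]], "_electron.csv"))
  if (!file.exists(epath)) stop("missing electron table ", epath)
  el <- read.csv(epath)
  element_record(
    z = as.integer(meta[["Z"]]), symbol = meta[["element"]],
    mass = as.numeric(meta[["mass"]]),
    k_edge = as.numeric(meta[["k_edge_keV"]]),
    l_edge = as.numeric(meta[["l_edge_keV"]]),
    kalpha = as.numeric(meta[["kalpha_keV"]]),
    omega_k = as.numeric(meta[["omega_k"]]),
    photon = ph, electron = el)
}

# log-log linear interpolation on a grid that may carry one duplicated
# (K-edge) energy; right-continuous at the duplicate.  Hard error outside
# the grid span -- extrapolated cross sections would corrupt the transport.
loglog_interp <- function(x, xs, ys) {
  n <- length(xs)
  if (any(x < xs[1L] - 1e-12 * xs[1L] | x > xs[n] + 1e-12 * xs[n]))
    stop("energy ", format(x[which(x < xs[1L] | x > xs[n])[1L]]),
         " keV outside table span [", format(xs[1L]), ", ", format(xs[n]),
         "] keV (no extrapolation)")
  x <- pmin(pmax(x, xs[1L]), xs[n])
  i <- findInterval(x, xs)        # rightmost xs[i] <= x; above-edge row wins
  i[i >= n] <- n - 1L
  exact <- xs[i] == x
  ly <- log(pmax(ys, 1e-300))
  lx <- log(xs)
  # guard zero-width intervals (duplicated edge): treated via `exact`
  w <- ifelse(exact, 0, (log(x) - lx[i]) / pmax(lx[i + 1L] - lx[i], 1e-300))
  out <- exp((1 - w) * ly[i] + w * ly[i + 1L])
  out[ys[i] <= 1e-299 & w == 0] <- 0
  out
}

element_pe <- function(rec, energy) loglog_interp(energy, rec$photon$energy_keV, rec$photon$pe_cm2g)
element_incoh <- function(rec, energy) loglog_interp(energy, rec$photon$energy_keV, rec$photon$incoh_cm2g)
element_coh <- function(rec, energy) loglog_interp(energy, rec$photon$energy_keV, rec$photon$coh_cm2g)
element_stopping <- function(rec, energy)
  loglog_interp(energy, rec$electron$energy_keV, rec$electron$stopping_MeVcm2g)

# effective K-edge jump ratio taken from the duplicated rows of the table
element_k_jump <- function(rec) {
  e <- rec$photon$energy_keV
  dup <- which(diff(e) == 0)
  if (!length(dup)) return(NA_real_)
  rec$photon$pe_cm2g[dup + 1L] / rec$photon$pe_cm2g[dup]
}
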