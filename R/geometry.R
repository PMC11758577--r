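#' Assembly configuration for the two simulated geometries
#'
#' `"satellite"`: a single SiO2 sphere (80 nm diameter by default) decorated
#' with `n_zno` ZnO nanoparticles (5 nm diameter) tangent to its surface,
#' inside an air-filled world sphere.  `"powder"`: `n_nanosystems`
#' ZnO-shelled SiO2 spheres placed uniformly at random, without overlap, in
#' an air-filled cylindrical sample holder (8.5 um diameter, 1 um height by
#' default).  The default shell thickness 0.7 nm carries the same ZnO
#' volume as 215 satellite nanoparticles (see
#' [equal_volume_shell_thickness()]).
#'
#' @param kind `"satellite"` or `"powder"`.
#' @param sio2_diameter SiO2 core diameter, nm.
#' @param zno_np_diameter ZnO nanoparticle diameter, nm (satellite).
#' @param n_zno Number of ZnO nanoparticles (satellite; 0, 10, 100 or 215
#'   in the benchmark grid).
#' @param shell_thickness ZnO shell thickness, nm (powder).  `NULL` selects
#'   the thickness whose shell volume equals `n_zno` nanoparticle volumes.
#' @param holder_diameter_um,holder_height_um Cylindrical holder size, um
#'   (powder).
#' @param n_nanosystems Number of coated spheres (powder).
#' @param world_radius Radius of the air world sphere, nm (satellite).
#' @param seed Default placement seed.
#' @return An object of class `assembly_config`.
#' @export
assembly_config <- function(kind = c("satellite", "powder"),
                            sio2_diameter = 80, zno_np_diameter = 5,
                            n_zno = 215, shell_thickness = NULL,
                            holder_diameter_um = 8.5, holder_height_um = 1,
                            n_nanosystems = 5e4, world_radius = 2000,
                            seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(sio2_diameter > 0, zno_np_diameter > 0, n_zno >= 0,
            holder_diameter_um > 0, holder_height_um > 0, n_nanosystems >= 1)
  R <- sio2_diameter / 2
  r <- zno_np_diameter / 2
  if (kind == "satellite" && n_zno > 0) {
    # geometric feasibility: total disc footprint below host surface area
    if (n_zno * pi * r^2 >= 4 * pi * (R + r)^2)
      stop("n_zno = ", n_zno, " is geometrically infeasible on this core")
  }
  if (is.null(shell_thickness))
    shell_thickness <- equal_volume_shell_thickness(R, r, n_zno)
  structure(list(kind = kind, sio2_diameter = sio2_diameter,
                 zno_np_diameter = zno_np_diameter, n_zno = as.integer(n_zno),
                 shell_thickness = shell_thickness,
                 holder_diameter_um = holder_diameter_um,
                 holder_height_um = holder_height_um,
                 n_nanosystems = as.integer(n_nanosystems),
                 world_radius = world_radius, seed = as.integer(seed)),
            class = "assembly_config")
}

#' Shell thickness with the same volume as n satellite nanoparticles
#'
#' Solves `(R + t)^3 - R^3 = n r^3` for `t`: the thickness of a spherical
#' shell around a core of radius `R` whose volume equals `n` spheres of
#' radius `r`.  With the defaults (40 nm core, 215 NPs of 2.5 nm radius)
#' this gives 0.688 nm, i.e. 0.7 nm after rounding.
#'
#' @param core_radius Core radius, nm.
#' @param np_radius Nanoparticle radius, nm.
#' @param n_np Number of nanoparticles.
#' @return Thickness in nm.
#' @export
equal_volume_shell_thickness <- function(core_radius = 40, np_radius = 2.5,
                                         n_np = 215) {
  (core_radius^3 + n_np * np_radius^3)^(1 / 3) - core_radius
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a geometry model from an assembly configuration
#'
#' Placement is random but fully reproducible: the same `(config, seed)`
#' always yields bit-identical body lists.  Satellite nanoparticle centers
#' are uniform on the sphere of radius `R + r` (tangent to the core) with
#' pairwise center distance at least one NP diameter, by rejection
#' sampling.  Powder sphere centers are uniform in the holder cylinder
#' (fully contained) with center distance at least one outer diameter,
#' using a cell-list overlap check.
#'
#' @param config An [assembly_config()].
#' @param seed Placement seed (default: the config's).
#' @param max_attempts Rejection-sampling budget per body.
#' @return An object of class `geometry_model`.
#' @export
build_assembly <- function(config, seed = config$seed, max_attempts = 1e6) {
  if (config$kind == "satellite") build_satellite(config, seed, max_attempts)
  else build_powder(config, seed, max_attempts)
}

#' @rdname build_assembly
#' @export
build_satellite_assembly <- function(config = assembly_config("satellite"),
                                     seed = config$seed, max_attempts = 1e6)
  build_satellite(config, seed, max_attempts)

#' @rdname build_assembly
#' @export
build_powder_assembly <- function(config = assembly_config("powder"),
                                  seed = config$seed, max_attempts = 1e6)
  build_powder(config, seed, max_attempts)

build_satellite <- function(config, seed, max_attempts) {
  R <- config$sio2_diameter / 2
  r <- config$zno_np_diameter / 2
  n <- config$n_zno
  rc <- R + r           # NP centers sit tangent to the core surface
  dmin2 <- (2 * r)^2
  centers <- matrix(numeric(0), 0, 3)
  if (n > 0) {
    centers <- with_local_seed(seed, {
      out <- matrix(NA_real_, n, 3)
      for (i in seq_len(n)) {
        placed <- FALSE
        for (att in seq_len(max_attempts)) {
          v <- rnorm(3)
          v <- v / sqrt(sum(v^2)) * rc
          if (i == 1L) { out[1, ] <- v; placed <- TRUE; break }
          d2 <- (out[seq_len(i - 1), 1, drop = TRUE] - v[1])^2 +
                (out[seq_len(i - 1), 2, drop = TRUE] - v[2])^2 +
                (out[seq_len(i - 1), 3, drop = TRUE] - v[3])^2
          if (min(d2) >= dmin2) { out[i, ] <- v; placed <- TRUE; break }
        }
        if (!placed)
          stop("failed to place nanoparticle ", i, " of ", n, " after ",
               max_attempts, " attempts")
      }
      out
    })
  }
  structure(list(kind = "satellite", world_radius = config$world_radius,
                 host_radius = R, np_radius = r, np_centers = centers,
                 media = c(world = "air", host = "SiO2", np = "ZnO"),
                 config = config, seed = as.integer(seed)),
            class = "geometry_model")
}

build_powder <- function(config, seed, max_attempts) {
  R <- config$sio2_diameter / 2
  r_out <- R + config$shell_thickness
  cyl_r <- config$holder_diameter_um * 1000 / 2
  hz <- config$holder_height_um * 1000 / 2
  n <- config$n_nanosystems
  if (cyl_r <= r_out || hz <= r_out)
    stop("holder too small to contain a single coated sphere")
  # random sequential addition saturates near packing fraction 0.38;
  # refuse configurations close to that limit (the benchmark is ~0.25)
  pf <- n * (4 / 3) * pi * r_out^3 / (pi * cyl_r^2 * 2 * hz)
  if (pf > 0.33)
    stop("requested packing fraction ", signif(pf, 3),
         " too dense for rejection placement")
  cell <- 2 * r_out
  ngx <- max(1L, ceiling(2 * cyl_r / cell))
  ngz <- max(1L, ceiling(2 * hz / cell))
  key <- function(p) {
    ix <- pmin(ngx - 1L, pmax(0L, as.integer((p[1] + cyl_r) / cell)))
    iy <- pmin(ngx - 1L, pmax(0L, as.integer((p[2] + cyl_r) / cell)))
    iz <- pmin(ngz - 1L, pmax(0L, as.integer((p[3] + hz) / cell)))
    c(ix, iy, iz)
  }
  centers <- with_local_seed(seed, {
    out <- matrix(NA_real_, n, 3)
    cells <- vector("list", ngx * ngx * ngz)
    dmin2 <- (2 * r_out)^2
    for (i in seq_len(n)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        rho <- sqrt(runif(1)) * (cyl_r - r_out)
        phi <- runif(1) * 2 * pi
        p <- c(rho * cos(phi), rho * sin(phi), runif(1, -(hz - r_out), hz - r_out))
        k <- key(p)
        ok <- TRUE
        for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
          jx <- k[1] + dx; jy <- k[2] + dy; jz <- k[3] + dz
          if (jx < 0 || jy < 0 || jz < 0 || jx >= ngx || jy >= ngx || jz >= ngz)
            next
          idx <- 1L + jx + ngx * (jy + ngx * jz)
          for (q in cells[[idx]]) {
            if (sum((out[q, ] - p)^2) < dmin2) { ok <- FALSE; break }
          }
          if (!ok) break
        }
        if (ok) {
          out[i, ] <- p
          idx <- 1L + k[1] + ngx * (k[2] + ngx * k[3])
          cells[[idx]] <- c(cells[[idx]], i)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("failed to place coated sphere ", i, " of ", n,
             " (placed ", i - 1L, ") after ", max_attempts, " attempts")
    }
    out
  })
  structure(list(kind = "powder", cyl_radius = cyl_r, cyl_half_height = hz,
                 core_radius = R, shell_outer = r_out, centers = centers,
                 media = c(world = "air", host = "SiO2", np = "ZnO"),
                 config = config, seed = as.integer(seed)),
            class = "geometry_model")
}

#' @export
print.geometry_model <- function(x, ...) {
  if (x$kind == "satellite")
    cat(sprintf(paste0("<geometry_model> satellite: SiO2 core r=%.3g nm, ",
                       "%d ZnO NPs r=%.3g nm, world r=%.3g nm\n"),
                x$host_radius, nrow(x$np_centers), x$np_radius, x$world_radius))
  else
    cat(sprintf(paste0("<geometry_model> powder: %d coated spheres ",
                       "(core %.3g nm, shell to %.4g nm) in cylinder ",
                       "r=%.4g nm, h=%.4g nm\n"),
                nrow(x$centers), x$core_radius, x$shell_outer, x$cyl_radius,
                2 * x$cyl_half_height))
  invisible(x)
}

# payload for the C++ core; media indices fixed: 0 world, 1 host/core,
# 2 np/shell
geom_payload <- function(model) {
  if (model$kind == "satellite") {
    list(kind = 1L, m_world = 0L, m_host = 1L, m_np = 2L,
         world_r = model$world_radius, host_r = model$host_radius,
         np_r = model$np_radius,
         np_centers = if (nrow(model$np_centers)) model$np_centers
                      else matrix(0, 0, 3))
  } else {
    list(kind = 2L, m_world = 0L, m_core = 1L, m_shell = 2L,
         cyl_r = model$cyl_radius, cyl_hz = model$cyl_half_height,
         core_r = model$core_radius, shell_r = model$shell_outer,
         centers = model$centers)
  }
}

medium_name <- function(model, idx) {
  nm <- unname(model$media[c("world", "host", "np")])
  out <- rep("outside", length(idx))
  ok <- idx >= 0
  out[ok] <- nm[idx[ok] + 1L]
  out
}

#' Locate points in a geometry model
#'
#' Innermost-body point location: shell wins over core at shell radii,
#' nanoparticles over the surrounding air; points in no body belong to the
#' world medium, points beyond the world to `"outside"`.
#'
#' @param model A [build_assembly()] model.
#' @param points Numeric matrix (n x 3) or length-3 vector, nm.
#' @return Data frame with `medium` (name) and `body` (integer id; -1 for
#'   the world, 0 for the satellite host, i >= 1 for nanoparticles or
#'   powder spheres).
#' @export
locate <- function(model, points) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  res <- cpp_locate(geom_payload(model), points)
  data.frame(medium = medium_name(model, res$medium), body = res$body)
}

#' Segment a ray through a geometry model
#'
#' Returns the contiguous (length, medium) segments from the origin to the
#' world exit, solving sphere and cylinder intersections in closed form.
#' An origin outside the world yields an empty segment list.
#'
#' @param model A [build_assembly()] model.
#' @param origin Length-3 numeric, nm.
#' @param direction Length-3 unit vector (|direction| = 1 within 1e-9).
#' @return Data frame with `t0`, `t1`, `length` (nm), `medium`, `body`.
#' @export
ray_segments <- function(model, origin, direction) {
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9)
    stop("direction must be a unit vector (|d| = ", format(nrm), ")")
  inside <- cpp_locate(geom_payload(model), matrix(origin, 1))$medium >= 0
  if (!inside)
    return(data.frame(t0 = numeric(0), t1 = numeric(0), length = numeric(0),
                      medium = character(0), body = integer(0)))
  seg <- cpp_ray_segments(geom_payload(model), origin, direction)
  seg$medium <- medium_name(model, seg$medium)
  seg
}

#' Export placed bodies as a data frame
#'
#' One row per body (id, shape, center, radii, medium), e.g. for plotting
#' or external checks.
#'
#' @param model A [build_assembly()] model.
#' @return Data frame.
#' @export
geometry_bodies <- function(model) {
  if (model$kind == "satellite") {
    n <- nrow(model$np_centers)
    rbind(
      data.frame(id = 0L, shape = "sphere", x = 0, y = 0, z = 0,
                 r_inner = 0, r_outer = model$host_radius,
                 medium = unname(model$media["host"])),
      if (n) data.frame(id = seq_len(n), shape = "sphere",
                        x = model$np_centers[, 1], y = model$np_centers[, 2],
                        z = model$np_centers[, 3], r_inner = 0,
                        r_outer = model$np_radius,
                        medium = unname(model$media["np"])))
  } else {
    n <- nrow(model$centers)
    rbind(
      data.frame(id = seq_len(n), shape = "sphere",
                 x = model$centers[, 1], y = model$centers[, 2],
                 z = model$centers[, 3], r_inner = 0,
                 r_outer = model$core_radius,
                 medium = unname(model$media["host"])),
      data.frame(id = seq_len(n), shape = "spherical_shell",
                 x = model$centers[, 1], y = model$centers[, 2],
                 z = model$centers[, 3], r_inner = model$core_radius,
                 r_outer = model$shell_outer,
                 medium = unname(model$media["np"])))
  }
}
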