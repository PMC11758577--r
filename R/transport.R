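#' Beam configuration
#'
#' A monochromatic parallel X-ray beam, generated at `source_distance_cm`
#' from the target with a tilt of `tilt` degrees with respect to the
#' geometry axis (the cylinder axis for powder assemblies; the same
#' convention is used for the satellite geometry).  The transverse profile
#' is a uniform disc circumscribing the target's projected footprint unless
#' `beam_radius` is given.  When `air_column` is on, attenuation in the
#' source-to-target air path (and, in forced mode, the in-world air ahead
#' of the first solid) is applied to the history weight.
#'
#' @param energy Photon energy, keV (3.3, 6.6 and 10 in the benchmark).
#' @param n_histories Number of primary histories.
#' @param tilt Beam tilt, degrees.
#' @param source_distance_cm Source-to-target distance, cm.
#' @param air_column Apply the air-column attenuation upstream of the
#'   target?  Default off: it is irrelevant for conditional partition
#'   fractions; switch on for per-incident-photon count observables.
#' @param beam_radius Uniform-disc radius, nm (`NULL`: auto).
#' @return Object of class `beam_config`.
#' @export
beam_config <- function(energy, n_histories = 1e4, tilt = 26,
                        source_distance_cm = 15, air_column = FALSE,
                        beam_radius = NULL) {
  stopifnot(energy > 0, n_histories >= 1)
  structure(list(energy = energy, n_histories = as.integer(n_histories),
                 tilt = tilt, source_distance_cm = source_distance_cm,
                 air_column = isTRUE(air_column), beam_radius = beam_radius),
            class = "beam_config")
}

#' Transport run configuration
#'
#' @param seed Master seed; every history uses an independent substream
#'   derived from it, so runs are reproducible and order-independent.
#' @param mode `"forced"` (forced first interaction with compensating
#'   statistical weight) or `"analog"`.
#' @param electron_step Condensed-history step in solids, nm.
#' @param electron_cutoff,photon_cutoff Tracking cutoffs, keV; particles
#'   below them deposit locally.
#' @param max_secondaries Per-history secondary budget; histories exceeding
#'   it are flagged and excluded.
#' @param ms_k Multiple-scattering strength; 2.2 makes the straight-line /
#'   path-length detour factor over a full CSDA range about 0.6.
#' @param relaxation Non-radiative K-vacancy relaxation: `"local"`
#'   (default) deposits the K binding energy at the interaction point,
#'   matching the reference Livermore configuration in which K-alpha
#'   fluorescence is tracked but Auger-electron generation is off;
#'   `"single-auger"` emits one KLL-like Auger electron of energy
#'   `k_edge - 2 * l_edge_mean` instead.
#' @param tag_rayleigh Count Rayleigh scattering as a taggable "first
#'   interaction" (default); if `FALSE` only energy-transferring events tag.
#' @param record_events Cap on deposition events returned event-by-event
#'   (0: none; keep small, every 1 nm electron step is an event).
#' @param record_histories Return the per-history table (needed for
#'   partition scoring).
#' @param nbatch Number of history batches for statistical errors.
#' @param r_bin_width,r_max Radial histogram bin width and span, nm
#'   (`NULL`: geometry-dependent default).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, mode = c("forced", "analog"),
                       electron_step = 1, electron_cutoff = 0.25,
                       photon_cutoff = 0.25, max_secondaries = 2e4,
                       ms_k = 2.2, relaxation = c("local", "single-auger"),
                       tag_rayleigh = TRUE, record_events = 0,
                       record_histories = TRUE, nbatch = 50,
                       r_bin_width = 1, r_max = NULL) {
  mode <- match.arg(mode)
  relaxation <- match.arg(relaxation)
  stopifnot(electron_step > 0, electron_cutoff >= 0.25, photon_cutoff >= 0.25)
  structure(list(seed = as.integer(seed), mode = mode,
                 electron_step = electron_step,
                 electron_cutoff = electron_cutoff,
                 photon_cutoff = photon_cutoff,
                 max_secondaries = as.integer(max_secondaries), ms_k = ms_k,
                 relaxation = relaxation,
                 tag_rayleigh = isTRUE(tag_rayleigh),
                 record_events = as.integer(record_events),
                 record_histories = isTRUE(record_histories),
                 nbatch = as.integer(nbatch), r_bin_width = r_bin_width,
                 r_max = r_max),
            class = "run_config")
}

#' Default materials for a geometry model
#'
#' @param model A [build_assembly()] model.
#' @return Named list of [material()]s covering the model's media.
#' @export
default_materials <- function(model) {
  nm <- unique(unname(model$media))
  out <- lapply(nm, function(x)
    switch(x, air = builtin_material("air"), SiO2 = builtin_material("SiO2"),
           ZnO = builtin_material("ZnO"),
           stop("no default material for medium '", x,
                "'; pass `materials` explicitly")))
  names(out) <- nm
  out
}

# per-material tables on a fine log grid (with element K edges resolved)
transport_table <- function(mat, elements) {
  recs <- resolve_elements(mat, elements)
  grid <- exp(seq(log(0.25), log(15), length.out = 220))
  for (r in recs) {
    ke <- r$k_edge
    if (ke > 0.25 && ke < 15) grid <- c(grid, ke * (1 - 1e-9), ke * (1 + 1e-9))
  }
  grid <- sort(unique(grid))
  mu <- function(ch) linear_attenuation(mat, grid, ch, elements)
  lg <- function(x) log(pmax(x, 1e-300))
  pe_el <- vapply(seq_along(recs), function(i)
    mat$composition[[i]] * element_pe(recs[[i]], grid), numeric(length(grid)))
  pe_el <- matrix(pe_el, nrow = length(grid))
  tot <- pmax(rowSums(pe_el), 1e-300)
  cumshare <- pe_el / tot
  if (ncol(cumshare) > 1)
    for (j in 2:ncol(cumshare))
      cumshare[, j] <- cumshare[, j - 1L] + cumshare[, j]
  cumshare[, ncol(cumshare)] <- 1
  if (mat$density > 0) {
    S <- electron_stopping(mat, grid, elements)
    invS <- 1 / S
    rng <- c(0, cumsum(diff(grid) * (invS[-1] + invS[-length(grid)]) / 2))
  } else {
    S <- rep(0, length(grid))
    rng <- rep(1e12, length(grid))
  }
  jump <- vapply(recs, function(r) {
    j <- element_k_jump(r)
    if (!is.na(j)) j else if (r$k_edge <= 0.25) 1e30 else 1
  }, numeric(1))
  list(logE = log(grid), lpe = lg(mu("photoelectric")),
       lin = lg(mu("incoherent")), lco = lg(mu("coherent")),
       lstop = lg(S), lrange = lg(pmax(rng, 1e-300)),
       cumshare = cumshare, density = mat$density,
       k_edge = vapply(recs, `[[`, numeric(1), "k_edge"),
       jump = unname(jump),
       omega = vapply(recs, `[[`, numeric(1), "omega_k"),
       kalpha = vapply(recs, `[[`, numeric(1), "kalpha"),
       lmean = vapply(recs, `[[`, numeric(1), "l_edge"))
}

#' Run a Monte Carlo transport simulation
#'
#' Transports `n_histories` primary photons (and all their secondaries,
#' down to the 250 eV cutoffs) through the geometry, in analog or
#' forced-first-interaction mode, and aggregates per-medium deposited
#' energy, first-interaction-conditioned radial histograms and
#' per-history results.
#'
#' @param model A [build_assembly()] model.
#' @param beam A [beam_config()].
#' @param run A [run_config()].
#' @param materials Named list of [material()]s for the model's media
#'   (default: [default_materials()]).
#' @param elements Named list of [element_record()]s.
#' @return Object of class `transport_run` with components `totals`,
#'   `histories`, `radial`, `batches`, `events` (if recorded) and the
#'   configuration echo.
#' @export
run_transport <- function(model, beam, run, materials = default_materials(model),
                          elements = shipped_elements()) {
  slots <- c("world", "host", "np")
  med_names <- unname(model$media[slots])
  mats <- lapply(med_names, function(nm) {
    m <- materials[[nm]]
    if (is.null(m)) stop("materials must include an entry for '", nm, "'")
    transport_table(m, elements)
  })
  tilt <- beam$tilt * pi / 180
  dirv <- c(sin(tilt), 0, -cos(tilt))
  dirv <- dirv / sqrt(sum(dirv^2))
  if (model$kind == "satellite") {
    backoff <- 2 * model$world_radius + 100
    br <- if (is.null(beam$beam_radius))
      model$host_radius + 2 * model$np_radius else beam$beam_radius
    rmax_def <- model$world_radius
  } else {
    backoff <- 2 * sqrt(model$cyl_radius^2 + model$cyl_half_height^2) + 100
    br <- if (is.null(beam$beam_radius))
      model$cyl_radius + model$cyl_half_height else beam$beam_radius
    rmax_def <- 500
  }
  wm <- materials[[med_names[1L]]]
  tau_col <- if (wm$density > 0)
    linear_attenuation(wm, beam$energy, "total", elements) *
      beam$source_distance_cm * 1e7
  else 0
  rmax <- if (is.null(run$r_max)) rmax_def else run$r_max
  cutoff <- max(run$electron_cutoff, run$photon_cutoff)
  res <- cpp_run_transport(
    geom_payload(model), mats,
    list(energy = beam$energy, direction = dirv, radius = br,
         backoff = backoff, air_column = beam$air_column,
         tau_column = tau_col),
    list(n_histories = beam$n_histories, seed = as.double(run$seed),
         mode = run$mode, cutoff = cutoff,
         electron_step = run$electron_step, ms_k = run$ms_k,
         max_secondaries = run$max_secondaries,
         relaxation = run$relaxation,
         tag_rayleigh = run$tag_rayleigh,
         record_histories = run$record_histories,
         record_events = run$record_events, nbatch = run$nbatch,
         r_bin_width = run$r_bin_width, r_max = rmax,
         powder_anchor_first = 0L))
  slot_of <- function(idx) {
    out <- rep(NA_character_, length(idx))
    out[idx == 0] <- "world"
    out[idx == 1] <- "host"
    out[idx == 2] <- "np"
    out
  }
  idx_name <- function(idx, names) {
    out <- rep(NA_character_, length(idx))
    ok <- idx >= 0
    out[ok] <- names[idx[ok] + 1L]
    out
  }
  histories <- NULL
  if (run$record_histories) {
    hh <- res$histories
    histories <- data.frame(
      weight = hh$weight,
      first_slot = slot_of(hh$first_medium),
      first_medium = idx_name(hh$first_medium, med_names),
      first_body = hh$first_body,
      first_channel = idx_name(hh$first_channel,
                               c("photoelectric", "incoherent", "coherent")),
      escaped = hh$escaped,
      edep_world = hh$edep_m0, edep_host = hh$edep_m1, edep_np = hh$edep_m2)
  }
  radial <- res$radial
  rownames(radial) <- c("first_host", "first_np")
  nb <- ncol(radial)
  batches <- res$batch_dep
  colnames(batches) <- slots
  events <- NULL
  if (run$record_events > 0 && !is.null(res$events)) {
    events <- res$events
    events$medium <- med_names[events$medium + 1L]
    events$first_medium <- idx_name(events$first_medium, med_names)
  }
  edep <- setNames(as.numeric(res$edep_weighted), slots)
  structure(list(
    kind = model$kind, media = model$media, beam = beam, run = run,
    totals = list(
      n_histories = res$n_histories, sum_weight = res$sum_weight,
      sum_weight_interacting = res$sum_weight_interacting,
      n_interacting = res$n_interacting, n_excluded = res$n_excluded,
      n_conservation_fail = res$n_conservation_fail,
      edep_weighted = edep, escaped_weighted = res$escaped_weighted),
    histories = histories, radial = radial,
    radial_edges = seq(0, by = run$r_bin_width, length.out = nb + 1L),
    batches = batches, batch_w = res$batch_w, events = events),
    class = "transport_run")
}

#' @export
print.transport_run <- function(x, ...) {
  t <- x$totals
  cat(sprintf("<transport_run> %s, %.4g keV, %s mode, %d histories\n",
              x$kind, x$beam$energy, x$run$mode, t$n_histories))
  cat(sprintf("  interacting weight %.4g (%.3g per primary); excluded %d\n",
              t$sum_weight_interacting,
              t$sum_weight_interacting / t$n_histories, t$n_excluded))
  dep <- t$edep_weighted
  nm <- unname(x$media[c("world", "host", "np")])
  for (i in seq_along(dep))
    cat(sprintf("  E_dep[%s] = %.5g keV (weighted)\n", nm[i], dep[i]))
  cat(sprintf("  escaped (weighted) = %.5g keV\n", t$escaped_weighted))
  invisible(x)
}

#' Sample interaction channels for a material
#'
#' Channels are drawn proportionally to the partial attenuation
#' coefficients at `energy`.
#'
#' @param material A [material()].
#' @param energy Photon energy, keV.
#' @param n Number of draws.
#' @param elements Element records.
#' @return Character vector of `"photoelectric"`, `"incoherent"`,
#'   `"coherent"`.
#' @export
sample_channel <- function(material, energy, n = 1,
                           elements = shipped_elements()) {
  p <- vapply(c("photoelectric", "incoherent", "coherent"),
              function(ch) mass_attenuation(material, energy, ch, elements),
              numeric(1))
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Sample Compton scattering angles and energies (Klein-Nishina)
#'
#' @param n Number of draws.
#' @param energy Incident photon energy, keV.
#' @param seed RNG seed.
#' @return Data frame with `cos_theta` and scattered `energy_out` (keV).
#' @export
sample_compton_scatter <- function(n, energy, seed = 1)
  cpp_sample_compton(as.integer(n), energy, as.double(seed))

#' Sample Rayleigh (Thomson-law) scattering angles
#'
#' @param n Number of draws.
#' @param seed RNG seed.
#' @return Numeric vector of cos(theta) drawn from (1 + cos^2)/normalization.
#' @export
sample_thomson_scatter <- function(n, seed = 1)
  cpp_sample_thomson(as.integer(n), as.double(seed))

#' Transport a single electron (condensed history)
#'
#' Walks one electron from `start` along `direction` with the engine's
#' condensed-history stepping and returns its deposition events, total path
#' length and escaped energy.  Useful for range/straggling checks.
#'
#' @param model Geometry model.
#' @param start,direction Position (nm) and unit direction.
#' @param energy Initial kinetic energy, keV.
#' @param run A [run_config()].
#' @param materials,elements As in [run_transport()].
#' @param seed RNG seed.
#' @return List with `deposits` (data frame), `path_length` (nm),
#'   `escaped` (keV).
#' @export
transport_electron <- function(model, start, direction, energy,
                               run = run_config(),
                               materials = default_materials(model),
                               elements = shipped_elements(), seed = 1) {
  med_names <- unname(model$media[c("world", "host", "np")])
  mats <- lapply(med_names, function(nm) transport_table(materials[[nm]], elements))
  res <- cpp_transport_electron(
    geom_payload(model), mats, start, direction, energy,
    list(cutoff = run$electron_cutoff, electron_step = run$electron_step,
         ms_k = run$ms_k),
    as.double(seed))
  res$deposits$medium <- medium_name(model, res$deposits$medium)
  res
}

#' A bare single-sphere model (for oracles and toy checks)
#'
#' One homogeneous sphere of `medium` in a `world_medium`-filled world
#' sphere: the minimal geometry for closed-form attenuation checks and
#' forced-vs-analog estimator comparisons.
#'
#' @param radius Sphere radius, nm.
#' @param world_radius World radius, nm.
#' @param medium,world_medium Medium names to which `materials` entries are
#'   matched in [run_transport()].
#' @return A `geometry_model`.
#' @export
single_sphere_model <- function(radius = 40, world_radius = 500,
                                medium = "SiO2", world_medium = "air") {
  cfg <- assembly_config("satellite", sio2_diameter = 2 * radius, n_zno = 0,
                         world_radius = world_radius)
  m <- build_assembly(cfg, seed = 1L)
  m$media <- c(world = world_medium, host = medium, np = medium)
  m
}
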