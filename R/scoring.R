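#' Per-medium energy partition
#'
#' Aggregates weighted deposited energy per medium, optionally conditioned
#' on where the primary's first interaction occurred, and normalizes to
#' percentages over the scored media.  Accepts either a
#' [run_transport()] result (per-history aggregates) or an event-level data
#' frame with columns `medium`, `first_medium`, `energy_keV`, `weight`.
#'
#' @param x `transport_run` or event data frame.
#' @param condition `"all"` or `"first_<medium>"` (e.g. `"first_SiO2"`,
#'   `"first_ZnO"`).
#' @return A `partition_table` data frame with `medium`, `energy_keV`
#'   (weighted deposited energy) and `fraction_pct`; batch statistical
#'   errors (percent points) are attached as attribute `stat_error_pct`
#'   when available.
#' @export
partition_by_medium <- function(x, condition = "all") {
  if (inherits(x, "transport_run")) {
    h <- x$histories
    if (is.null(h)) stop("run was executed without record_histories")
    sel <- if (condition == "all") rep(TRUE, nrow(h))
           else h$first_medium %in% sub("^first_", "", condition)
    if (!any(sel)) stop("empty conditioned event set for condition '",
                        condition, "'")
    slots <- c("world", "host", "np")
    dep <- c(sum(h$edep_world[sel]), sum(h$edep_host[sel]),
             sum(h$edep_np[sel]))
    med <- unname(x$media[slots])
    dep <- tapply(dep, med, sum)
    se <- NULL
    if (condition == "all" && !is.null(x$batches)) {
      bt <- x$batches
      bmed <- unname(x$media[colnames(bt)])
      bagg <- sapply(unique(bmed), function(m)
        rowSums(bt[, bmed == m, drop = FALSE]))
      tot <- rowSums(bagg)
      keep <- tot > 0
      if (sum(keep) >= 2) {
        fr <- 100 * bagg[keep, , drop = FALSE] / tot[keep]
        se <- apply(fr, 2, sd) / sqrt(sum(keep))
      }
    }
  } else {
    ev <- x
    need <- c("medium", "first_medium", "energy_keV", "weight")
    if (!all(need %in% names(ev)))
      stop("event table must have columns ", paste(need, collapse = ", "))
    sel <- if (condition == "all") rep(TRUE, nrow(ev))
           else !is.na(ev$first_medium) &
                ev$first_medium == sub("^first_", "", condition)
    if (!any(sel)) stop("empty conditioned event set for condition '",
                        condition, "'")
    ev <- ev[sel, ]
    dep <- tapply(ev$energy_keV * ev$weight, ev$medium, sum)
    se <- NULL
  }
  total <- sum(dep)
  if (total <= 0) stop("no deposited energy under condition '", condition, "'")
  out <- data.frame(medium = names(dep), energy_keV = as.numeric(dep),
                    fraction_pct = 100 * as.numeric(dep) / total)
  rownames(out) <- NULL
  attr(out, "condition") <- condition
  if (!is.null(se)) attr(out, "stat_error_pct") <- se
  class(out) <- c("partition_table", "data.frame")
  out
}

#' @export
print.partition_table <- function(x, ...) {
  cat("Energy partition (condition:", attr(x, "condition"), ")\n")
  se <- attr(x, "stat_error_pct")
  for (i in seq_len(nrow(x))) {
    line <- sprintf("  %-6s %10.5g keV  %6.2f %%", x$medium[i],
                    x$energy_keV[i], x$fraction_pct[i])
    if (!is.null(se) && x$medium[i] %in% names(se))
      line <- paste0(line, sprintf(" (+/- %.2f pp)", se[[x$medium[i]]]))
    cat(line, "\n")
  }
  invisible(x)
}

#' First-interaction-conditioned radial deposition profile
#'
#' Histograms the weighted deposited energy against the distance `r` from
#' the profile anchor.  For the satellite geometry the anchor is the
#' first-interaction body center: the SiO2 host center for `"r_SiO2"`
#' (first interaction in SiO2) or the struck nanoparticle center for
#' `"r_ZnO"` (first interaction in ZnO).  For the powder geometry
#' (`anchor = "r"`) the engine anchors each deposit to the center of the
#' nanosystem where the energy is deposited; pass `condition` to select
#' first-in-SiO2 or first-in-ZnO histories.  Event-level input measures
#' r as the distance from the deposit position to the first anchor.
#'
#' @param x `transport_run` or event data frame.
#' @param anchor `"r_SiO2"`, `"r_ZnO"` or `"r"`.
#' @param bin_width Bin width, nm; for a `transport_run` it must be a
#'   multiple of the run's histogram width (`NULL`: use as run).
#' @param condition For `anchor = "r"`: `"first_SiO2"` or `"first_ZnO"`.
#' @return A `radial_profile` data frame with `r_lo`, `r_hi` (nm; the last
#'   row is the overflow bin) and `energy_keV`.
#' @export
radial_profile <- function(x, anchor = c("r_SiO2", "r_ZnO", "r"),
                           bin_width = NULL, condition = NULL) {
  anchor <- match.arg(anchor)
  if (inherits(x, "transport_run")) {
    row <- switch(anchor,
      r_SiO2 = "first_host", r_ZnO = "first_np",
      r = switch(if (is.null(condition)) "first_SiO2" else condition,
                 first_SiO2 = "first_host", first_ZnO = "first_np",
                 stop("condition must be 'first_SiO2' or 'first_ZnO'")))
    if (anchor == "r" && x$kind != "powder")
      stop("anchor 'r' applies to the powder geometry")
    if (anchor != "r" && x$kind != "satellite")
      stop("anchor '", anchor, "' applies to the satellite geometry")
    v <- x$radial[row, ]
    w0 <- x$run$r_bin_width
    if (is.null(bin_width)) bin_width <- w0
    k <- bin_width / w0
    if (abs(k - round(k)) > 1e-9)
      stop("bin_width must be a multiple of the run's ", w0, " nm")
    k <- as.integer(round(k))
    nb <- length(v) - 1L                      # last engine bin = overflow
    ng <- ceiling(nb / k)
    grp <- c(rep(seq_len(ng), each = k)[seq_len(nb)], ng + 1L)
    e <- as.numeric(tapply(v, grp, sum))
    lo <- c((seq_len(ng) - 1L) * bin_width, ng * bin_width)
    hi <- c(seq_len(ng) * bin_width, Inf)
  } else {
    ev <- x
    need <- c("x", "y", "z", "energy_keV", "first_medium", "weight",
              "anchor_x", "anchor_y", "anchor_z")
    if (!all(need %in% names(ev)))
      stop("event table must have columns ", paste(need, collapse = ", "))
    want <- switch(anchor, r_SiO2 = "SiO2", r_ZnO = "ZnO",
                   r = sub("^first_", "",
                           if (is.null(condition)) "first_SiO2" else condition))
    sel <- !is.na(ev$first_medium) & ev$first_medium == want
    if (!any(sel))
      stop("anchor '", anchor, "' requires first-in-", want,
           " events; none present")
    ev <- ev[sel, ]
    if (is.null(bin_width)) bin_width <- 1
    r <- sqrt((ev$x - ev$anchor_x)^2 + (ev$y - ev$anchor_y)^2 +
              (ev$z - ev$anchor_z)^2)
    nb <- max(1L, ceiling(max(r) / bin_width))
    bin <- pmin(floor(r / bin_width), nb - 1L) + 1L
    e <- as.numeric(tapply(ev$energy_keV * ev$weight,
                           factor(bin, levels = seq_len(nb)), sum))
    e[is.na(e)] <- 0
    lo <- (seq_len(nb) - 1L) * bin_width
    hi <- seq_len(nb) * bin_width
  }
  out <- data.frame(r_lo = lo, r_hi = hi, energy_keV = e)
  attr(out, "anchor") <- anchor
  attr(out, "bin_width") <- bin_width
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Interaction counts and per-primary interaction probability
#'
#' The weighted number of histories whose primary photon interacted in a
#' solid body, normalized per incident photon.  In forced mode each
#' history's weight is the unconditional interaction probability of its
#' ray, so the weighted count matches the analog frequency in expectation.
#'
#' @param x A [run_transport()] result.
#' @return Data frame with `n_histories`, `interacting` (weighted) and
#'   `per_primary`.
#' @export
count_interactions <- function(x) {
  stopifnot(inherits(x, "transport_run"))
  t <- x$totals
  data.frame(n_histories = t$n_histories,
             interacting = t$sum_weight_interacting,
             per_primary = t$sum_weight_interacting / t$n_histories)
}

#' Export a partition table or radial profile as CSV with a JSON sidecar
#'
#' @param x A `partition_table` or `radial_profile`.
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @param meta Named list merged into the sidecar (seed, configs, ...).
#' @return Invisibly, `path`.
#' @export
export_scoring <- function(x, path, meta = list()) {
  df <- as.data.frame(x)
  write.csv(df, path, row.names = FALSE)
  side <- c(list(class = class(x)[1L],
                 condition = attr(x, "condition"),
                 anchor = attr(x, "anchor"),
                 stat_error_pct = as.list(attr(x, "stat_error_pct"))),
            meta)
  side <- side[!vapply(side, is.null, logical(1))]
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
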