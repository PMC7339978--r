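#' Define a binding site along the pore axis
#'
#' Default values describe the NPA constriction region of an
#' aquaglyceroporin pore (z in \[-5, +4\] Angstrom, extracellular side +z).
#'
#' @param name Site name.
#' @param z_range Length-2 axial interval (Angstrom).
#' @param lateral_cutoff Lateral distance cutoff for entering (Angstrom).
#' @param hysteresis Exit margin added to both ends of `z_range` (Angstrom):
#'   an open visit closes only when z leaves the expanded interval, so
#'   boundary-hugging oscillations count as a single visit.
#' @param min_dwell Visits shorter than this (ns) are discarded.
#' @return List of class `cf_site`.
#' @export
site_definition <- function(name = "NPA", z_range = c(-5, 4),
                            lateral_cutoff = 6, hysteresis = 1,
                            min_dwell = 1) {
  stopifnot(length(z_range) == 2L, z_range[2] > z_range[1],
            hysteresis >= 0, min_dwell >= 0, lateral_cutoff > 0)
  structure(list(name = name, z_range = sort(z_range),
                 lateral_cutoff = lateral_cutoff, hysteresis = hysteresis,
                 min_dwell = min_dwell), class = "cf_site")
}

#' Detect binding-site visits in a solute track
#'
#' A visit opens when the molecule's z enters the site interval while its
#' lateral distance from the axis is below the cutoff; it closes only when z
#' leaves the interval expanded by the hysteresis margin. Visits shorter than
#' `min_dwell` are discarded. Entry and exit sides are inferred from the
#' boundary crossed (+z extracellular, -z cytosolic).
#'
#' @param track A `cf_track` (pore-axis frame).
#' @param site A `cf_site` from [site_definition()].
#' @return Data frame of class `cf_visits`: `molecule_id`, `t_enter`,
#'   `t_exit`, `residence` (ns), `entry_side`, `exit_side`, `censored`
#'   (TRUE when the track ended with the visit still open).
#' @export
detect_visits <- function(track, site) {
  stopifnot(inherits(track, "cf_track"), inherits(site, "cf_site"))
  t <- track$times
  if (any(diff(t) <= 0)) stop("non-monotone times")
  z <- track$positions[, 3]
  lat <- sqrt(track$positions[, 1]^2 + track$positions[, 2]^2)
  lo <- site$z_range[1]; hi <- site$z_range[2]; h <- site$hysteresis
  side_of <- function(zv) {
    if (zv > hi) "extracellular" else if (zv < lo) "cytosolic" else NA_character_
  }
  ev <- list()
  open <- FALSE
  t_enter <- NA_real_; entry <- NA_character_
  for (i in seq_along(t)) {
    if (!open) {
      if (z[i] >= lo && z[i] <= hi && lat[i] < site$lateral_cutoff) {
        open <- TRUE
        t_enter <- t[i]
        entry <- if (i > 1) side_of(z[i - 1]) else NA_character_
      }
    } else if (z[i] < lo - h || z[i] > hi + h) {
      ev[[length(ev) + 1L]] <- data.frame(
        molecule_id = track$molecule_id, t_enter = t_enter, t_exit = t[i],
        residence = t[i] - t_enter, entry_side = entry,
        exit_side = side_of(z[i]), censored = FALSE,
        stringsAsFactors = FALSE)
      open <- FALSE
    }
  }
  if (open) {
    ev[[length(ev) + 1L]] <- data.frame(
      molecule_id = track$molecule_id, t_enter = t_enter,
      t_exit = t[length(t)], residence = t[length(t)] - t_enter,
      entry_side = entry, exit_side = NA_character_, censored = TRUE,
      stringsAsFactors = FALSE)
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(molecule_id = character(0), t_enter = numeric(0),
               t_exit = numeric(0), residence = numeric(0),
               entry_side = character(0), exit_side = character(0),
               censored = logical(0), stringsAsFactors = FALSE)
  out <- out[out$residence >= site$min_dwell, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cf_visits", "data.frame")
  out
}

#' Detect complete translocations across a region
#'
#' An event is recorded when the track passes from beyond one boundary to
#' beyond the other without first returning beyond the boundary of origin.
#' Direction "in" is extracellular-to-cytosolic (from above `z_top` to below
#' `z_bottom`); "out" is the reverse. Default boundaries are the bulk-onset
#' positions flanking the selectivity filter.
#'
#' @param track A `cf_track`.
#' @param z_top,z_bottom Boundaries in Angstrom, `z_top > z_bottom`.
#' @return Data frame of class `cf_translocations`: `molecule_id`,
#'   `direction`, `t_start`, `t_end`.
#' @export
detect_translocations <- function(track, z_top = 12, z_bottom = -8) {
  stopifnot(inherits(track, "cf_track"), z_top > z_bottom)
  t <- track$times
  z <- track$positions[, 3]
  ev <- list()
  state <- NA_character_   # which bulk side last visited
  t_last <- NA_real_       # last time beyond that boundary
  for (i in seq_along(t)) {
    if (z[i] > z_top) {
      if (identical(state, "bottom")) {
        ev[[length(ev) + 1L]] <- data.frame(
          molecule_id = track$molecule_id, direction = "out",
          t_start = t_last, t_end = t[i], stringsAsFactors = FALSE)
      }
      state <- "top"; t_last <- t[i]
    } else if (z[i] < z_bottom) {
      if (identical(state, "top")) {
        ev[[length(ev) + 1L]] <- data.frame(
          molecule_id = track$molecule_id, direction = "in",
          t_start = t_last, t_end = t[i], stringsAsFactors = FALSE)
      }
      state <- "bottom"; t_last <- t[i]
    } else if (!is.na(state)) {
      # still between boundaries; t_last stays at last bulk excursion
    }
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(molecule_id = character(0), direction = character(0),
               t_start = numeric(0), t_end = numeric(0),
               stringsAsFactors = FALSE)
  class(out) <- c("cf_translocations", "data.frame")
  out
}

#' Residence-time summary
#'
#' @param events A `cf_visits` data frame (or numeric vector of residence
#'   times in ns).
#' @return List with `count`, `mean`, `median` (ns); an empty event list
#'   yields count 0 with `NA` summaries (explicitly, not silent zeros).
#' @export
residence_stats <- function(events) {
  tau <- if (is.numeric(events)) events else events$residence
  if (length(tau) == 0L) {
    return(list(count = 0L, mean = NA_real_, median = NA_real_))
  }
  list(count = length(tau), mean = mean(tau), median = median(tau))
}

#' Visitation rate per pore per microsecond
#'
#' `rate = total visits / (n_pores * total time)`; the SEM is the standard
#' error (n-1 denominator) of the per-replica per-pore rates.
#'
#' @param counts_by_replica Integer vector of visit counts per replica.
#' @param n_pores Number of monomeric pores sampled per replica (>= 1).
#' @param time_per_replica Simulated time per replica in microseconds
#'   (scalar, recycled, or one value per replica).
#' @return List of class `cf_rate_summary`: `total_visits`, `counts`,
#'   `rate` (visits per pore per microsecond), `sem`, `n_pores`,
#'   `time_per_replica`.
#' @export
visitation_rate <- function(counts_by_replica, n_pores, time_per_replica) {
  stopifnot(n_pores >= 1)
  n <- length(counts_by_replica)
  times <- rep_len(time_per_replica, n)
  if (any(times <= 0) || sum(times) == 0) stop("replica times must be > 0")
  rate <- sum(counts_by_replica) / (n_pores * sum(times))
  per_rep <- counts_by_replica / (n_pores * times)
  sem <- if (n > 1) sd(per_rep) / sqrt(n) else 0
  if (sum(counts_by_replica) == 0) sem <- 0
  structure(list(total_visits = sum(counts_by_replica),
                 counts = counts_by_replica, rate = rate, sem = sem,
                 n_pores = n_pores, time_per_replica = times),
            class = "cf_rate_summary")
}

#' @export
print.cf_rate_summary <- function(x, ...) {
  cat(sprintf(
    "<visitation rate: %.2f +/- %.2f per pore per us (%d visits, %d pores)>\n",
    x$rate, x$sem, x$total_visits, x$n_pores))
  invisible(x)
}
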