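# volume of one water molecule: 18 cm^3/mol / Avogadro
.v_water <- 18 / 6.02214076e23

#' Collective permeation coordinate
#'
#' The dimensionless collective coordinate advances by
#' `dn = sum_molecules dz_i / L` at each step, counting only axial
#' displacements of molecules inside the pore region; one full pore
#' traversal by one molecule advances n by 1.
#'
#' @param dz Per-step summed in-pore axial displacements (Angstrom), or an
#'   n_steps x n_molecules matrix of per-molecule displacements (zeros when
#'   outside the pore).
#' @param times Times at the end of each step (ns), strictly increasing.
#' @param L Pore length (Angstrom, > 0).
#' @return List of class `cf_collective_series`: `times`, `n` (cumulative,
#'   n(0) = 0 prepended at the first time minus one step), `L`.
#' @export
collective_coordinate <- function(dz, times, L) {
  if (L <= 0) stop("pore length L must be > 0")
  if (is.matrix(dz)) dz <- rowSums(dz)
  stopifnot(length(dz) == length(times))
  structure(list(times = as.numeric(times), n = cumsum(dz) / L, L = L),
            class = "cf_collective_series")
}

#' Collective diffusion coefficient from a collective series
#'
#' Fits `<n^2(t)> = 2 D_n t` through the origin using mean-squared
#' displacements of the collective coordinate at a ladder of lag times.
#'
#' @param series A `cf_collective_series`.
#' @param max_lag_frac Largest lag as a fraction of the series length.
#' @param n_lags Number of lag points.
#' @return `D_n` in 1/ns.
#' @export
collective_diffusion <- function(series, max_lag_frac = 0.1, n_lags = 20) {
  n <- series$n
  t <- series$times
  dt <- mean(diff(t))
  max_lag <- max(1L, floor(length(n) * max_lag_frac))
  lags <- unique(pmax(1L, round(seq(1L, max_lag, length.out = n_lags))))
  msd <- vapply(lags, function(l) mean((n[-seq_len(l)] -
                                          n[seq_len(length(n) - l)])^2),
                numeric(1))
  tau <- lags * dt
  sum(msd * tau) / sum(tau^2) / 2   # least-squares slope through origin / 2
}

#' Single-channel permeability from event counts or collective diffusion
#'
#' Exactly one of `k0` (complete permeation events per ns per channel,
#' yielding the diffusive permeability `p_d = v_w * k0`) or `series` (a
#' collective series yielding the osmotic permeability `p_f = v_w * D_n`)
#' must be supplied. Conversion to an area-normalised coefficient (cm/s)
#' requires an explicit membrane area per channel; there is no hidden
#' default.
#'
#' @param k0 Event rate per ns per channel.
#' @param series A `cf_collective_series`.
#' @param v_w Volume of one water molecule in cm^3 (default 18 cm^3/mol
#'   divided by Avogadro's number, about 2.99e-23 cm^3).
#' @param area_per_channel Optional membrane area per channel (cm^2).
#' @param segment Optional label ("apo" or "bound").
#' @return List of class `cf_permeability`: `k0` (1/ns), `D_n` (1/ns or NA),
#'   `v_w`, `p_cm3_s` (single-channel, cm^3/s), `p_cm_s` (cm/s or NA),
#'   `segment`.
#' @export
permeability_estimates <- function(k0 = NULL, series = NULL, v_w = .v_water,
                                   area_per_channel = NULL,
                                   segment = NA_character_) {
  if (is.null(k0) == is.null(series)) {
    stop("supply exactly one of k0 or series")
  }
  if (v_w <= 0) stop("v_w must be > 0")
  D_n <- NA_real_
  if (!is.null(series)) {
    D_n <- collective_diffusion(series)
    rate <- D_n
  } else {
    if (k0 < 0) stop("k0 must be >= 0")
    rate <- k0
  }
  p <- v_w * rate * 1e9   # per ns -> per s
  structure(list(k0 = if (is.null(k0)) NA_real_ else k0, D_n = D_n,
                 v_w = v_w, p_cm3_s = p,
                 p_cm_s = if (is.null(area_per_channel)) NA_real_ else
                   p / area_per_channel,
                 segment = segment),
            class = "cf_permeability")
}

#' @export
print.cf_permeability <- function(x, ...) {
  cat(sprintf("<permeability%s: p = %.3g cm^3/s%s>\n",
              if (is.na(x$segment)) "" else paste0(" (", x$segment, ")"),
              x$p_cm3_s,
              if (is.na(x$p_cm_s)) "" else sprintf(", %.3g cm/s", x$p_cm_s)))
  invisible(x)
}

#' Water permeability segmented by glycerol occupancy
#'
#' Splits a water-permeation event stream into contiguous apo and
#' glycerol-bound segments according to a time-aligned occupancy series,
#' drops segments shorter than `min_segment` (to suppress boundary
#' transients), and estimates the event-counting permeability per class. A
#' class with no retained time is reported as absent (`NA`), not zero.
#'
#' @param water Data frame with `time` (ns, a regular grid labelling the end
#'   of each interval) and `events` (completed permeation events per
#'   interval), e.g. from [make_water_hopping()].
#' @param occupancy Data frame with `time` and logical `bound`, on the same
#'   time base as `water` (error otherwise).
#' @param min_segment Minimum segment length in ns.
#' @param v_w,area_per_channel Passed to [permeability_estimates()].
#' @return List of class `cf_segmented_pd` with elements `apo` and `bound`
#'   (each a `cf_permeability` or `NA`), `ratio` (apo/bound p, NA if either
#'   absent), and `segments` (data frame of retained segments).
#' @export
segmented_pd <- function(water, occupancy, min_segment = 5, v_w = .v_water,
                         area_per_channel = NULL) {
  if (length(water$time) != length(occupancy$time) ||
      max(abs(water$time - occupancy$time)) > 1e-9) {
    stop("misaligned time bases between water and occupancy series")
  }
  dt <- diff(water$time)
  if (length(dt) == 0L || max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
    stop("water series must be on a regular time grid")
  }
  dt <- dt[1]
  r <- rle(occupancy$bound)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  seg <- data.frame(start = water$time[starts] - dt, end = water$time[ends],
                    bound = r$values,
                    events = vapply(seq_along(starts), function(i) {
                      sum(water$events[starts[i]:ends[i]])
                    }, numeric(1)))
  seg$length <- seg$end - seg$start
  seg <- seg[seg$length >= min_segment, , drop = FALSE]
  est_class <- function(bound) {
    s <- seg[seg$bound == bound, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    k0 <- sum(s$events) / sum(s$length)
    permeability_estimates(k0 = k0, v_w = v_w,
                           area_per_channel = area_per_channel,
                           segment = if (bound) "bound" else "apo")
  }
  apo <- est_class(FALSE)
  bound <- est_class(TRUE)
  ratio <- if (is.null(apo) || is.null(bound) || bound$p_cm3_s == 0)
    NA_real_ else apo$p_cm3_s / bound$p_cm3_s
  structure(list(apo = apo, bound = bound, ratio = ratio, segments = seg),
            class = "cf_segmented_pd")
}
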