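# Oocyte swelling assays: the oocyte is modelled as a sphere whose
# cross-sectional area A gives r = sqrt(A/pi) and V = 4/3 pi r^3; the true
# membrane area exceeds the geometric sphere surface by a folding factor
# (microvilli), default 9. Osmolalities in mOsm convert to mol/cm^3 via
# 1 mOsm = 1e-6 mol/cm^3 (dilute-solution convention); the partial molar
# volume of water is 18 cm^3/mol.

.mosm_to_molcm3 <- 1e-6
.V_w_molar <- 18  # cm^3/mol

#' Sphere volume from cross-sectional area (and inverse)
#'
#' @param A Cross-sectional area in cm^2 (> 0).
#' @return Volume in cm^3.
#' @export
volume_from_area <- function(A) {
  if (any(A <= 0)) stop("area must be > 0")
  r <- sqrt(A / pi)
  4 / 3 * pi * r^3
}

#' @rdname volume_from_area
#' @param V Volume in cm^3 (> 0).
#' @export
area_from_volume <- function(V) {
  if (any(V <= 0)) stop("volume must be > 0")
  pi * (3 * V / (4 * pi))^(2 / 3)
}

#' Membrane surface area of an oocyte
#'
#' Geometric sphere surface times the membrane folding factor.
#'
#' @param V Volume in cm^3.
#' @param folding Membrane folding factor (default 9).
#' @return Surface area in cm^2.
#' @export
oocyte_surface <- function(V, folding = 9) {
  r <- (3 * V / (4 * pi))^(1 / 3)
  folding * 4 * pi * r^2
}

#' Relative-volume swelling slope
#'
#' Ordinary least squares of `V(t)/V0` against time within a window; `V0` is
#' the volume at the first sample in the window.
#'
#' @param times Times in s.
#' @param V Volumes in cm^3.
#' @param window Length-2 time window (s); default the first 60 s.
#' @return List with `slope` (1/s), `r_squared`, `V0` (cm^3), `n`, `window`.
#' @export
fit_relative_slope <- function(times, V, window = c(min(times),
                                                    min(times) + 60)) {
  sel <- times >= window[1] & times <= window[2]
  if (sum(sel) < 3L) stop("need at least 3 samples in the fit window")
  t <- times[sel]; v <- V[sel]
  V0 <- v[1]
  fit <- lm(I(v / V0) ~ t)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((v / V0 - mean(v / V0))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(slope = unname(coef(fit)[2]), r_squared = r2, V0 = V0,
       n = sum(sel), window = window)
}

#' Osmotic water permeability from a swelling slope
#'
#' `Pf = slope * V0 / (S * V_w * delta_osm)`, with `delta_osm` the internal
#' minus external osmolality so that swelling under a hypo-osmotic gradient
#' gives a positive Pf.
#'
#' @param slope d(V/V0)/dt in 1/s.
#' @param V0 Initial volume (cm^3).
#' @param S Membrane surface area (cm^2, > 0); see [oocyte_surface()].
#' @param delta_osm Osmotic gradient, internal minus external, in mOsm
#'   (non-zero).
#' @param V_w Partial molar volume of water (cm^3/mol).
#' @return Pf in cm/s.
#' @export
compute_pf <- function(slope, V0, S, delta_osm, V_w = .V_w_molar) {
  if (S <= 0) stop("surface area must be > 0")
  if (delta_osm == 0) stop("zero osmotic gradient: Pf undefined")
  slope * V0 / (S * V_w * delta_osm * .mosm_to_molcm3)
}

#' Channel-dependent permeability Pf*
#'
#' `Pf* = mean(group) - mean(day-matched control)`, with SEM combined in
#' quadrature.
#'
#' @param group_pf,control_pf Numeric vectors of per-oocyte Pf (cm/s),
#'   non-empty.
#' @param group,control Labels.
#' @return List of class `cf_group_summary`: per-group `mean`, `sem`, `n`,
#'   plus `pf_star` and `pf_star_sem`.
#' @export
pf_star <- function(group_pf, control_pf, group = "construct",
                    control = "H2O") {
  if (length(group_pf) == 0L || length(control_pf) == 0L) {
    stop("empty group")
  }
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  s1 <- sem(group_pf); s2 <- sem(control_pf)
  structure(list(group = group, control = control,
                 mean = mean(group_pf), sem = s1, n = length(group_pf),
                 control_mean = mean(control_pf), control_sem = s2,
                 control_n = length(control_pf),
                 pf_star = mean(group_pf) - mean(control_pf),
                 pf_star_sem = sqrt(s1^2 + s2^2)),
            class = "cf_group_summary")
}

#' @export
print.cf_group_summary <- function(x, ...) {
  cat(sprintf("<Pf* %s - %s: %.3g +/- %.3g cm/s (n = %d vs %d)>\n",
              x$group, x$control, x$pf_star, x$pf_star_sem, x$n,
              x$control_n))
  invisible(x)
}

#' Specification of the coupled water/solute flux model
#'
#' @param Pf Osmotic water permeability (cm/s, >= 0).
#' @param P_s Named numeric vector of membrane solute permeabilities (cm/s,
#'   >= 0), e.g. `c(glycerol = 3e-5)`.
#' @param osm_in0 Initial internal osmolality (mOsm; default 195).
#' @param V0 Initial volume (cm^3; default that of a 1.2 mm oocyte).
#' @param folding Membrane folding factor.
#' @param V_w Partial molar volume of water (cm^3/mol).
#' @param N_s0 Named initial internal solute amounts (mol); default zero.
#' @return List of class `cf_forward_spec`.
#' @export
forward_model_spec <- function(Pf, P_s = c(glycerol = 0), osm_in0 = 195,
                               V0 = volume_from_area(pi * 0.06^2),
                               folding = 9, V_w = .V_w_molar, N_s0 = NULL) {
  if (Pf < 0 || any(P_s < 0)) stop("permeabilities must be >= 0")
  if (osm_in0 <= 0) stop("osmolality must be > 0")
  if (is.null(names(P_s)) || any(names(P_s) == "")) {
    stop("P_s must be a named vector")
  }
  if (is.null(N_s0)) N_s0 <- setNames(rep(0, length(P_s)), names(P_s))
  structure(list(Pf = Pf, P_s = P_s, osm_in0 = osm_in0, V0 = V0,
                 folding = folding, V_w = V_w, N_s0 = N_s0[names(P_s)]),
            class = "cf_forward_spec")
}

#' Bath protocol constructor
#'
#' One row per bath solution: switch time, total osmolality, and the
#' external concentration of each permeant solute.
#'
#' @param start Switch times (s), first must be 0.
#' @param osm Total bath osmolality (mOsm).
#' @param ... Named per-solute concentrations (mM), recycled to the number
#'   of rows.
#' @return Data frame of class `cf_bath_protocol`.
#' @export
bath_protocol <- function(start, osm, ...) {
  d <- data.frame(start = start, osm = osm, ...)
  if (d$start[1] != 0) stop("first bath interval must start at 0")
  if (is.unsorted(d$start, strictly = TRUE)) {
    stop("bath start times must be strictly increasing")
  }
  class(d) <- c("cf_bath_protocol", "data.frame")
  d
}

#' Forward model of oocyte volume under coupled water/solute fluxes
#'
#' Integrates
#' `dN_s/dt = P_s * S * (C_s,out - N_s/V)` and
#' `dV/dt = Pf * S * V_w * (Osm_in - Osm_out)` with
#' `Osm_in = (N_impermeant + sum_s N_s)/V`, the membrane area `S` recomputed
#' from V via the sphere model times the folding factor, and the impermeant
#' internal solute amount held constant. Integration uses `deSolve::lsoda`
#' piecewise over the bath protocol. High Pf together with a substantial
#' glycerol permeability reproduces paradoxical swelling: glycerol influx in
#' a hyperosmotic glycerol bath reverses the osmotic gradient and the oocyte
#' swells instead of shrinking.
#'
#' @param spec A `cf_forward_spec`.
#' @param protocol A `cf_bath_protocol` (solute columns must match
#'   `names(spec$P_s)`; missing columns are treated as 0 mM).
#' @param duration Total time (s).
#' @param dt Output sampling interval (s).
#' @return Data frame of class `cf_forward_trace`: `time`, `V`, `A`,
#'   `osm_in` (mOsm), and one `N_<solute>` column (mol) per solute.
#' @export
forward_model <- function(spec, protocol, duration, dt = 1) {
  stopifnot(inherits(spec, "cf_forward_spec"))
  solutes <- names(spec$P_s)
  N_imp <- spec$osm_in0 * .mosm_to_molcm3 * spec$V0 - sum(spec$N_s0)
  if (N_imp < 0) stop("initial solute amounts exceed internal osmolality")
  state <- c(V = spec$V0, spec$N_s0)
  deriv <- function(t, y, parms) {
    V <- y[1]
    if (V <= 0) stop("volume became non-positive during integration at t = ",
                     signif(t, 4), " s")
    Ns <- y[-1]
    S <- oocyte_surface(V, spec$folding)
    osm_in <- (N_imp + sum(Ns)) / V
    dV <- spec$Pf * S * spec$V_w * (osm_in - parms$osm_out)
    dN <- spec$P_s * S * (parms$C_out - Ns / V)
    list(c(dV, dN))
  }
  edges <- c(protocol$start, duration)
  out <- NULL
  for (i in seq_len(nrow(protocol))) {
    t0 <- edges[i]; t1 <- edges[i + 1]
    if (t1 <= t0) next
    C_out <- setNames(rep(0, length(solutes)), solutes)
    for (s in solutes) {
      if (s %in% names(protocol)) C_out[s] <- protocol[[s]][i] * 1e-6
    }
    parms <- list(osm_out = protocol$osm[i] * .mosm_to_molcm3, C_out = C_out)
    tt <- unique(c(seq(t0, t1, by = dt), t1))
    sol <- deSolve::lsoda(state, tt, deriv, parms, rtol = 1e-8, atol = 1e-14)
    state <- sol[nrow(sol), -1]
    sol <- as.data.frame(sol)
    if (!is.null(out)) sol <- sol[-1, , drop = FALSE]
    out <- rbind(out, sol)
  }
  names(out) <- c("time", "V", paste0("N_", solutes))
  out$A <- area_from_volume(out$V)
  out$osm_in <- (N_imp + rowSums(out[, paste0("N_", solutes), drop = FALSE])) /
    out$V / .mosm_to_molcm3
  attr(out, "N_impermeant") <- N_imp
  attr(out, "spec") <- spec
  class(out) <- c("cf_forward_trace", "data.frame")
  out
}

#' Construct an oocyte recording
#'
#' @param oocyte_id,group Identifiers.
#' @param times Times (s), strictly increasing.
#' @param area Cross-sectional areas (cm^2, > 0).
#' @param protocol A `cf_bath_protocol`.
#' @return List of class `cf_recording`.
#' @export
oocyte_recording <- function(oocyte_id, group, times, area, protocol) {
  if (any(area <= 0)) stop("areas must be > 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(oocyte_id = oocyte_id, group = group,
                 times = as.numeric(times), area = as.numeric(area),
                 protocol = protocol), class = "cf_recording")
}

#' Estimate Pf from one oocyte recording
#'
#' Converts areas to volumes via the sphere model, fits the relative swelling
#' slope over the window following the (first) solution change, and applies
#' [compute_pf()]. Because the least-squares slope of a slowly curving
#' volume trace reflects mid-window conditions, the surface area and osmotic
#' gradient entering the formula are evaluated at the window midpoint, with
#' the internal osmolality inferred from conservation of the (impermeant-
#' dominated) internal solute: `osm_in(t) = osm_in(0) * V0 / V(t)`. This
#' dilution correction removes the leading-order underestimate of Pf for
#' swelling of a few percent over the window.
#'
#' @param rec A `cf_recording`.
#' @param osm_in Internal osmolality at the start of the window (mOsm;
#'   default 195).
#' @param window Fit window (s) relative to recording start; default first
#'   60 s.
#' @param folding Membrane folding factor.
#' @return List with `Pf` (cm/s), `slope`, `r_squared`, `V0`, `S`
#'   (mid-window), `delta_osm` (mid-window, mOsm).
#' @export
estimate_pf <- function(rec, osm_in = 195, window = c(0, 60), folding = 9) {
  stopifnot(inherits(rec, "cf_recording"))
  V <- volume_from_area(rec$area)
  fit <- fit_relative_slope(rec$times, V, window = window)
  osm_out <- rec$protocol$osm[findInterval(window[1], rec$protocol$start)]
  t_mid <- mean(fit$window) - fit$window[1]
  V_mid <- fit$V0 * (1 + fit$slope * t_mid)
  S <- oocyte_surface(V_mid, folding)
  d_osm <- osm_in * fit$V0 / V_mid - osm_out
  list(Pf = compute_pf(fit$slope, fit$V0, S, d_osm), slope = fit$slope,
       r_squared = fit$r_squared, V0 = fit$V0, S = S, delta_osm = d_osm)
}
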