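#' Parametric potential of mean force (sum of Gaussians)
#'
#' `G(z) = sum_i h_i exp(-(z - c_i)^2 / (2 w_i^2))` in kcal/mol: positive
#' heights are barriers, negative heights wells; G decays to 0 in bulk.
#'
#' @param centers,heights,widths Numeric vectors (Angstrom, kcal/mol,
#'   Angstrom; widths > 0).
#' @return Data frame of class `cf_pmf`.
#' @export
pmf_spec <- function(centers, heights, widths) {
  stopifnot(length(centers) == length(heights),
            length(centers) == length(widths), all(widths > 0))
  structure(data.frame(center = centers, height = heights, width = widths),
            class = c("cf_pmf", "data.frame"))
}

#' Default AQP7-like and GlpF-like free-energy landscapes
#'
#' Double-barrier aquaglyceroporin landscapes: a selectivity-filter barrier
#' centred at z = +7.5 Angstrom (4.0 kcal/mol for the AQP7 variant, 4.5 for
#' GlpF), an NPA-region feature centred at z = 0 (a -1.5 kcal/mol well for
#' AQP7, a shallow +0.5 kcal/mol bump for GlpF), and a ~1 kcal/mol cytosolic
#' barrier at z = -5.
#'
#' @return A `cf_pmf`.
#' @export
aqp7_pmf <- function() {
  pmf_spec(centers = c(7.5, 0, -5), heights = c(4.0, -1.5, 1.0),
           widths = c(2.0, 2.5, 1.5))
}

#' @rdname aqp7_pmf
#' @export
glpf_pmf <- function() {
  pmf_spec(centers = c(7.5, 0, -5), heights = c(4.5, 0.5, 1.0),
           widths = c(2.0, 2.5, 1.5))
}

#' Evaluate a PMF and its gradient
#'
#' @param pmf A `cf_pmf`.
#' @param z Positions (Angstrom).
#' @return `pmf_eval`: G(z) in kcal/mol; `pmf_grad`: dG/dz in
#'   kcal/mol/Angstrom.
#' @export
pmf_eval <- function(pmf, z) {
  out <- numeric(length(z))
  for (i in seq_len(nrow(pmf))) {
    out <- out + pmf$height[i] *
      exp(-0.5 * ((z - pmf$center[i]) / pmf$width[i])^2)
  }
  out
}

#' @rdname pmf_eval
#' @export
pmf_grad <- function(pmf, z) {
  out <- numeric(length(z))
  for (i in seq_len(nrow(pmf))) {
    d <- z - pmf$center[i]
    out <- out - pmf$height[i] * d / pmf$width[i]^2 *
      exp(-0.5 * (d / pmf$width[i])^2)
  }
  out
}

#' Analytic reference profile for a PMF
#'
#' Evaluates the PMF on a grid and anchors it like a WHAM output so that
#' [profile_features()] applies to generator truth and reconstruction alike.
#'
#' @param pmf A `cf_pmf`.
#' @param z Grid (Angstrom).
#' @param anchor Bulk anchor onset, as in [wham()].
#' @return Data frame with `z` and `dG` (class `cf_free_energy_profile`).
#' @export
pmf_profile <- function(pmf, z = seq(-20, 20, by = 0.25), anchor = 15) {
  g <- pmf_eval(pmf, z)
  bulk <- abs(z) >= anchor
  if (any(bulk)) g <- g - mean(g[bulk])
  out <- data.frame(z = z, dG = g)
  class(out) <- c("cf_free_energy_profile", "data.frame")
  out
}

#' Langevin simulation settings
#'
#' Overdamped 1-D dynamics with reflecting walls. The stability invariant
#' `D * dt * max|G'| / kT < 0.1` Angstrom is checked before running.
#'
#' @param D Diffusion coefficient (Angstrom^2/ns; default 100, the order of
#'   magnitude for a small solute in water).
#' @param kT Thermal energy (kcal/mol).
#' @param dt Time step (ns); the default satisfies the stability bound on
#'   both default landscapes.
#' @param steps Number of steps.
#' @param seed RNG seed, or `NULL` to continue the current RNG stream.
#' @param z0 Start position, or `NULL` to draw from the Boltzmann density.
#' @param bounds Reflecting walls (Angstrom).
#' @param umbrella Optional harmonic bias `list(z0 =, k =)`.
#' @param thin Record every `thin`-th step.
#' @return List of class `cf_langevin_spec`.
#' @export
langevin_spec <- function(D = 100, kT = .kT_default, dt = 2.5e-4, steps = 1e5,
                          seed = NULL, z0 = NULL, bounds = c(-25, 25),
                          umbrella = NULL, thin = 1) {
  stopifnot(D > 0, kT > 0, dt > 0, steps >= 1)
  structure(list(D = D, kT = kT, dt = dt, steps = as.integer(steps),
                 seed = seed, z0 = z0, bounds = sort(bounds),
                 umbrella = umbrella, thin = as.integer(thin)),
            class = "cf_langevin_spec")
}

#' Draw positions from the Boltzmann density of a PMF
#'
#' Inverse-CDF sampling of `exp(-G(z)/kT)` on a fine grid.
#'
#' @param pmf A `cf_pmf`.
#' @param n Number of draws.
#' @param kT Thermal energy (kcal/mol).
#' @param bounds Support (Angstrom).
#' @return Numeric vector of length `n`.
#' @export
sample_boltzmann <- function(pmf, n, kT = .kT_default, bounds = c(-25, 25)) {
  zg <- seq(bounds[1], bounds[2], length.out = 4001)
  w <- exp(-pmf_eval(pmf, zg) / kT)
  cdf <- cumsum(w) / sum(w)
  approx(cdf, zg, xout = runif(n), rule = 2)$y
}

#' Simulate overdamped Langevin dynamics on a PMF
#'
#' Euler-Maruyama propagation
#' `z <- z - (D/kT) * (G'(z) + U'(z)) * dt + sqrt(2 D dt) * xi` with
#' `xi ~ N(0, 1)`, reflecting walls, and an optional harmonic umbrella bias
#' `U = k/2 (z - z0)^2`. With a fixed seed the track is exactly
#' reproducible.
#'
#' @param pmf A `cf_pmf`.
#' @param spec A `cf_langevin_spec`.
#' @param molecule_id Track identifier.
#' @return A [solute_track()] with times in ns and z along the pore axis.
#' @export
simulate_langevin <- function(pmf, spec = langevin_spec(),
                              molecule_id = "langevin") {
  stopifnot(inherits(spec, "cf_langevin_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  # stability is checked over the region the walker will actually sample:
  # the whole box when unbiased, the restraint centre +/- 5 sigma when biased
  if (is.null(spec$umbrella)) {
    lo <- spec$bounds[1]; hi <- spec$bounds[2]
  } else {
    hw <- 5 * sqrt(spec$kT / max(spec$umbrella$k, 1e-12))
    lo <- max(spec$bounds[1], spec$umbrella$z0 - hw)
    hi <- min(spec$bounds[2], spec$umbrella$z0 + hw)
  }
  zg <- seq(lo, hi, length.out = 2001)
  gmax <- max(abs(pmf_grad(pmf, zg) +
                    if (is.null(spec$umbrella)) 0 else
                      spec$umbrella$k * (zg - spec$umbrella$z0)))
  if (spec$D * spec$dt * gmax / spec$kT >= 0.1) {
    stop(sprintf(
      "unstable integration: D*dt*max|G'|/kT = %.3g Angstrom >= 0.1; reduce dt",
      spec$D * spec$dt * gmax / spec$kT))
  }
  z0 <- spec$z0
  if (is.null(z0)) z0 <- sample_boltzmann(pmf, 1, spec$kT, spec$bounds)
  biased <- !is.null(spec$umbrella)
  z <- cf_langevin_cpp(z0, spec$steps, spec$dt, spec$D, spec$kT,
                       pmf$center, pmf$height, pmf$width,
                       biased,
                       if (biased) spec$umbrella$z0 else 0,
                       if (biased) spec$umbrella$k else 0,
                       spec$bounds[1], spec$bounds[2], spec$thin)
  times <- seq(0, by = spec$dt * spec$thin, length.out = length(z))
  solute_track(molecule_id, times, z)
}

#' Generate an umbrella-sampling dataset from a PMF
#'
#' One biased Langevin run per window, started at the window centre, with a
#' burn-in fraction discarded. Warns when the window spacing exceeds
#' `3 * sqrt(kT / k)` (poor overlap).
#'
#' @param pmf A `cf_pmf`.
#' @param centers Window centres (Angstrom); default 25 windows spanning
#'   -15..15.
#' @param k Force constant (kcal/mol/Angstrom^2).
#' @param steps_per_window Langevin steps per window.
#' @param seed RNG seed for the whole dataset.
#' @param dt Time step (ns).
#' @param D,kT As in [langevin_spec()].
#' @param burn_frac Fraction of each window discarded as equilibration.
#' @param thin Keep every `thin`-th sample.
#' @return List of `cf_window` objects.
#' @export
make_umbrella_dataset <- function(pmf, centers = seq(-15, 15, by = 1.25),
                                  k = 2.5, steps_per_window = 2e5,
                                  seed = 1, dt = 5e-5, D = 100,
                                  kT = .kT_default, burn_frac = 0.1,
                                  thin = 10) {
  spacing <- if (length(centers) > 1) max(diff(sort(centers))) else 0
  if (spacing > 3 * sqrt(kT / k)) {
    warning(sprintf(
      "window spacing %.3g exceeds 3*sqrt(kT/k) = %.3g: windows may not overlap",
      spacing, 3 * sqrt(kT / k)))
  }
  set.seed(seed)
  lapply(centers, function(z0) {
    sp <- langevin_spec(D = D, kT = kT, dt = dt, steps = steps_per_window,
                        seed = NULL, z0 = z0,
                        umbrella = list(z0 = z0, k = k), thin = thin)
    tr <- simulate_langevin(pmf, sp)
    z <- tr$positions[, 3]
    umbrella_window(z0, k, z[-seq_len(ceiling(length(z) * burn_frac))])
  })
}

#' Synthetic channel structure from stacked atom rings
#'
#' Builds a pore-profiler fixture: rings of atoms centred on the z axis with
#' given ring radii and vdW radii. The analytic constriction radius is
#' `min(ring_radius - vdw)` (negative values permitted and flagged when
#' rings overlap the axis).
#'
#' @param rings Data frame with columns `z`, `ring_radius`, `vdw` and
#'   optionally `n_atoms` (default 12 per ring).
#' @param id Structure id.
#' @return A `cf_structure` with attribute `"analytic_min_radius"`.
#' @export
make_channel_fixture <- function(rings, id = "ring-fixture") {
  stopifnot(nrow(rings) >= 1L)
  if (is.null(rings$n_atoms)) rings$n_atoms <- 12L
  rows <- list()
  serial <- 0L
  for (i in seq_len(nrow(rings))) {
    ang <- 2 * pi * (seq_len(rings$n_atoms[i]) - 1) / rings$n_atoms[i]
    for (j in seq_along(ang)) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, atom_name = "X", residue_name = "RNG",
        residue_number = i, ins = "", chain_id = "A",
        x = rings$ring_radius[i] * cos(ang[j]),
        y = rings$ring_radius[i] * sin(ang[j]), z = rings$z[i],
        element = "C", occupancy = 1, is_hetero = FALSE,
        vdw_radius = rings$vdw[i], stringsAsFactors = FALSE)
    }
  }
  st <- as_structure(do.call(rbind, rows), id = id)
  rmin <- min(rings$ring_radius - rings$vdw)
  if (rmin < 0) {
    attr(st, "overlapping_rings") <- TRUE
  }
  attr(st, "analytic_min_radius") <- rmin
  st
}

#' Orientation tracks with prescribed order parameter per region
#'
#' For each axial region, orientation vectors are drawn from a mixture of
#' perfectly axial (weight `|target|`, sign of the target) and isotropic
#' (weight `1 - |target|`) draws, so the expected P1 equals the target.
#'
#' @param regions Data frame with `z_lo`, `z_hi`, `p1_target` (each target
#'   in `[-1, 1]`).
#' @param n Samples per region.
#' @param seed RNG seed.
#' @return List of `cf_track` objects (one per region) with orientation
#'   endpoints.
#' @export
make_orientation_tracks <- function(regions, n = 1000, seed = 1) {
  if (any(abs(regions$p1_target) > 1)) {
    stop("unreachable target: |P1| must be <= 1 under the mixture scheme")
  }
  set.seed(seed)
  lapply(seq_len(nrow(regions)), function(i) {
    zlo <- regions$z_lo[i]; zhi <- regions$z_hi[i]
    tgt <- regions$p1_target[i]
    z <- runif(n, zlo, zhi)
    # isotropic unit vectors
    u <- rnorm(n); v <- rnorm(n); w <- rnorm(n)
    len <- sqrt(u^2 + v^2 + w^2)
    dir <- cbind(u, v, w) / len
    axial <- runif(n) < abs(tgt)
    dir[axial, ] <- matrix(rep(c(0, 0, sign(tgt)), sum(axial)),
                           ncol = 3, byrow = TRUE)
    pos <- cbind(0, 0, z)
    solute_track(sprintf("orient-%d", i), seq_len(n), pos,
                 orient1 = matrix(0, n, 3), orient2 = dir)
  })
}

#' Water permeation stream with occupancy-dependent rate
#'
#' Completed, directed water permeation events are drawn as Poisson counts
#' on a regular time grid, at `rate_apo` while the site is glycerol-free and
#' `rate_bound` while occupied. Feeds [segmented_pd()].
#'
#' @param rate_apo,rate_bound Event rates (per ns, >= 0).
#' @param schedule Data frame with `start` (ns; first must be 0) and logical
#'   `bound`, defining the occupancy schedule.
#' @param duration Total time (ns).
#' @param dt Grid spacing (ns).
#' @param L Pore length (Angstrom), carried for collective-coordinate use.
#' @param seed RNG seed.
#' @return List with `water` (data frame `time`, `events`), `occupancy`
#'   (data frame `time`, `bound`), `L`, and the true rates as attributes.
#' @export
make_water_hopping <- function(rate_apo, rate_bound, schedule, duration,
                               dt = 0.1, L = 20, seed = 1) {
  stopifnot(rate_apo >= 0, rate_bound >= 0, schedule$start[1] == 0)
  set.seed(seed)
  time <- seq(dt, duration, by = dt)
  bound <- schedule$bound[findInterval(time - dt / 2, schedule$start)]
  rate <- ifelse(bound, rate_bound, rate_apo)
  events <- rpois(length(time), rate * dt)
  out <- list(water = data.frame(time = time, events = events),
              occupancy = data.frame(time = time, bound = bound), L = L)
  attr(out, "rate_apo") <- rate_apo
  attr(out, "rate_bound") <- rate_bound
  out
}

#' Alternating occupancy schedule helper
#'
#' @param segment_ns Length of each segment (ns).
#' @param n_segments Number of segments (alternating apo/bound, apo first).
#' @return Schedule data frame for [make_water_hopping()].
#' @export
alternating_schedule <- function(segment_ns, n_segments) {
  data.frame(start = (seq_len(n_segments) - 1) * segment_ns,
             bound = rep(c(FALSE, TRUE), length.out = n_segments))
}

#' Simulate oocyte swelling recordings with known ground truth
#'
#' Integrates the coupled water/solute [forward_model()] and converts the
#' volume trace to a cross-sectional area series with multiplicative
#' log-normal noise.
#'
#' @param spec A `cf_forward_spec` with the true Pf and solute
#'   permeabilities.
#' @param protocol A `cf_bath_protocol`.
#' @param n_oocytes Number of recordings.
#' @param duration Recording length (s).
#' @param sample_interval Sampling interval (s).
#' @param noise_sd Multiplicative area noise (fraction; default 0.002).
#' @param seed RNG seed.
#' @param group Group label.
#' @return List of `cf_recording` objects.
#' @export
make_oocyte_recordings <- function(spec, protocol, n_oocytes = 10,
                                   duration = 60, sample_interval = 1,
                                   noise_sd = 0.002, seed = 1,
                                   group = "construct") {
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  trace <- forward_model(spec, protocol, duration, dt = sample_interval)
  lapply(seq_len(n_oocytes), function(i) {
    a <- trace$A * exp(rnorm(nrow(trace), 0, noise_sd))
    oocyte_recording(sprintf("%s-%02d", group, i), group, trace$time, a,
                     protocol)
  })
}
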