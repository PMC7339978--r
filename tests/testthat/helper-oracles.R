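# Independent oracles used across the suite. Each one deliberately avoids
# the code path it checks.

# --- rotation oracle: quaternion grid search + local refinement ------------
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# minimal rmsd over rotations (translation removed by centring), by coarse
# quaternion grid followed by Nelder-Mead refinement of the quaternion
quaternion_rmsd_oracle <- function(mobile, reference, n_grid = 4000) {
  M <- sweep(mobile, 2, colMeans(mobile))
  R0 <- sweep(reference, 2, colMeans(reference))
  obj <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((M %*% t(R) - R0)^2)))
  }
  set.seed(99)
  qs <- matrix(rnorm(4 * n_grid), ncol = 4)
  vals <- apply(qs, 1, obj)
  best <- qs[which.min(vals), ]
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-16, maxit = 5000))
  opt2 <- optim(opt$par, obj, method = "Nelder-Mead",
                control = list(reltol = 1e-16, maxit = 5000))
  opt2$value
}

# --- analytic SASA of two overlapping spheres ------------------------------
two_sphere_sasa <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  a1 <- 4 * pi * R1^2; a2 <- 4 * pi * R2^2
  if (d >= R1 + R2) return(c(a1, a2))
  # spherical cap buried on each sphere
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  c(a1 - 2 * pi * R1 * h1, a2 - 2 * pi * R2 * h2)
}

# --- literal state-machine replay for visit detection ----------------------
replay_visits_oracle <- function(times, z, lat, lo, hi, h, min_dwell) {
  n_open <- 0L
  events <- numeric(0)
  open <- FALSE
  t0 <- NA
  for (i in seq_along(times)) {
    if (!open && z[i] >= lo && z[i] <= hi && lat[i] < 6) {
      open <- TRUE; t0 <- times[i]
    } else if (open && (z[i] < lo - h || z[i] > hi + h)) {
      open <- FALSE
      if (times[i] - t0 >= min_dwell) events <- c(events, times[i] - t0)
    }
  }
  if (open && times[length(times)] - t0 >= min_dwell) {
    events <- c(events, times[length(times)] - t0)
  }
  events
}

# --- NeRF atom placement for torsion fixtures ------------------------------
place_atom <- function(a, b, c, r, theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# minimal PDB line writer for fixtures (strict fixed columns)
pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     record = "ATOM", occ = 1, elem = NULL, alt = " ") {
  if (is.null(elem)) elem <- substr(gsub("[0-9]", "", name), 1, 1)
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, resn, chain, resno, x, y, z, occ, 0, elem)
}

# a 4-atom "residue" with a prescribed chi1, embedded in a tiny PDB text
phe_fixture_lines <- function(chi1) {
  N <- c(0, 1.45, 0)
  CA <- c(0, 0, 0)
  CB <- place_atom(c(1.2, 2.4, 0), N, CA, 1.52, 111, 122)
  CG <- place_atom(N, CA, CB, 1.50, 114, chi1)
  at <- rbind(N = N, CA = CA, CB = CB, CG = CG)
  c(pdb_line(1, "N", "PHE", "A", 74, at[1, 1], at[1, 2], at[1, 3], elem = "N"),
    pdb_line(2, "CA", "PHE", "A", 74, at[2, 1], at[2, 2], at[2, 3], elem = "C"),
    pdb_line(3, "CB", "PHE", "A", 74, at[3, 1], at[3, 2], at[3, 3], elem = "C"),
    pdb_line(4, "CG", "PHE", "A", 74, at[4, 1], at[4, 2], at[4, 3], elem = "C"))
}

# --- enumerated Markov-chain oracle for translocation counts ---------------
# Expected completed crossings (per direction) for a reflecting random walk
# on a lattice over [zmin, zmax], starting from the uniform distribution,
# over total time T_ns with diffusion coefficient D. Exact propagation of
# the (site x last-boundary-flag) augmented chain.
chain_crossing_oracle <- function(zmin, zmax, z_top, z_bottom, D, T_ns,
                                  h = 0.5) {
  sites <- seq(zmin, zmax, by = h)
  M <- length(sites)
  dt <- h^2 / (2 * D)
  steps <- round(T_ns / dt)
  top_i <- which(sites >= z_top)
  bot_i <- which(sites <= z_bottom)
  # state: 3 flags (0 none, 1 top, 2 bottom) x M sites
  p <- matrix(0, 3, M)
  p[1, ] <- 1 / M
  # initial flag assignment for walkers already in bulk
  p[2, top_i] <- p[1, top_i]; p[1, top_i] <- 0
  p[3, bot_i] <- p[1, bot_i]; p[1, bot_i] <- 0
  step_walk <- function(v) {
    out <- numeric(M)
    out[2:M] <- out[2:M] + v[1:(M - 1)] / 2
    out[1:(M - 1)] <- out[1:(M - 1)] + v[2:M] / 2
    out[1] <- out[1] + v[1] / 2       # reflect
    out[M] <- out[M] + v[M] / 2
    out
  }
  e_in <- 0; e_out <- 0
  for (s in seq_len(steps)) {
    p <- t(apply(p, 1, step_walk))
    # flag updates and crossing counts
    e_out <- e_out + sum(p[3, top_i])   # bottom-flag mass entering top
    e_in <- e_in + sum(p[2, bot_i])     # top-flag mass entering bottom
    p[2, top_i] <- p[2, top_i] + p[1, top_i] + p[3, top_i]
    p[1, top_i] <- 0; p[3, top_i] <- 0
    p[3, bot_i] <- p[3, bot_i] + p[1, bot_i] + p[2, bot_i]
    p[1, bot_i] <- 0; p[2, bot_i] <- 0
  }
  list(expected_in = e_in, expected_out = e_out, dt = dt, steps = steps)
}

# Monte-Carlo expectation of the norm of a 3-D isotropic Gaussian
gaussian_norm_expectation <- function(sigma, n = 2e5) {
  set.seed(7)
  mean(sqrt(rowSums(matrix(rnorm(3 * n, sd = sigma), ncol = 3)^2)))
}
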