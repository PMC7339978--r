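make_jitter_frames <- function(n_res, n_frames, sigma, seed = 5) {
  set.seed(seed)
  base <- cbind(seq_len(n_res) * 3.8, 0, 0)  # extended chain of CA atoms
  arr <- array(0, dim = c(n_res, 3, n_frames))
  for (f in seq_len(n_frames)) {
    arr[, , f] <- base + matrix(rnorm(3 * n_res, sd = sigma), ncol = 3)
  }
  info <- data.frame(residue_number = seq_len(n_res), atom_name = "CA")
  list(frames = frame_ensemble(seq_len(n_frames), arr, info), ref = base,
       info = info)
}

test_that("per_residue_rmsd is zero for identical frames and localises a shift", {
  n <- 20
  base <- cbind(seq_len(n) * 3.8, rep(c(0, 1.5), n / 2), 0)
  arr <- array(rep(base, 5), dim = c(n, 3, 5))
  info <- data.frame(residue_number = seq_len(n), atom_name = "CA")
  fe <- frame_ensemble(1:5, arr, info)
  prof <- per_residue_rmsd(fe, base)
  expect_true(all(prof$rmsd < 1e-9))
  # displace residue 10 by 2 A in every frame
  arr2 <- arr
  arr2[10, 2, ] <- arr2[10, 2, ] + 2
  prof2 <- per_residue_rmsd(frame_ensemble(1:5, arr2, info), base)
  expect_equal(prof2$rmsd[10], 2, tolerance = 0.15)
  expect_true(all(prof2$rmsd[-10] < 0.15))
})

test_that("per_residue_rmsd matches the Monte-Carlo norm expectation under jitter", {
  sigma <- 0.5
  jf <- make_jitter_frames(n_res = 60, n_frames = 1000, sigma = sigma)
  prof <- per_residue_rmsd(jf$frames, jf$ref)
  expected <- gaussian_norm_expectation(sigma)
  expect_equal(mean(prof$rmsd), expected, tolerance = 0.05)
})

test_that("per_residue_rmsd is invariant under a common rigid motion of frames", {
  jf <- make_jitter_frames(n_res = 15, n_frames = 20, sigma = 0.3, seed = 9)
  base_prof <- per_residue_rmsd(jf$frames, jf$ref)
  ang <- 0.7
  Rz <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  arr <- jf$frames$coords
  for (f in seq_len(dim(arr)[3])) {
    arr[, , f] <- arr[, , f] %*% t(Rz) +
      matrix(rep(c(4, -6, 2), each = dim(arr)[1]), ncol = 3)
  }
  moved <- frame_ensemble(jf$frames$times, arr, jf$frames$atom_info)
  expect_equal(per_residue_rmsd(moved, jf$ref)$rmsd, base_prof$rmsd,
               tolerance = 1e-8)
})

test_that("orientation profile gives +/-1 for axial vectors and 0 for isotropic", {
  up <- make_orientation_tracks(
    data.frame(z_lo = -10, z_hi = 10, p1_target = 1), n = 500, seed = 2)
  pu <- orientation_profile(up, bins = 2)
  expect_true(all(abs(pu$p1[pu$n > 0] - 1) < 1e-12))
  down <- make_orientation_tracks(
    data.frame(z_lo = -10, z_hi = 10, p1_target = -1), n = 500, seed = 2)
  pd <- orientation_profile(down, bins = 2)
  expect_true(all(abs(pd$p1[pd$n > 0] + 1) < 1e-12))
  iso <- make_orientation_tracks(
    data.frame(z_lo = -10, z_hi = 10, p1_target = 0), n = 1e4, seed = 3)
  pi_ <- orientation_profile(iso, bins = 20)
  expect_lt(abs(pi_$p1[pi_$n > 5000]), 0.05)
  # half-weight mixture hits P1 = 0.5
  half <- make_orientation_tracks(
    data.frame(z_lo = -10, z_hi = 10, p1_target = 0.5), n = 1e4, seed = 4)
  ph <- orientation_profile(half, bins = 20)
  expect_equal(ph$p1[ph$n > 5000], 0.5, tolerance = 0.04)
})

test_that("orientation profile ignores time ordering and flags empty bins", {
  tr <- make_orientation_tracks(
    data.frame(z_lo = 0, z_hi = 5, p1_target = 0.3), n = 200, seed = 6)[[1]]
  fwd <- orientation_profile(tr, bins = 1)
  rev_tr <- solute_track(tr$molecule_id, tr$times,
                         tr$positions[rev(seq_along(tr$times)), ],
                         tr$orient1[rev(seq_along(tr$times)), ],
                         tr$orient2[rev(seq_along(tr$times)), ])
  expect_equal(orientation_profile(rev_tr, bins = 1)$p1, fwd$p1)
  wide <- orientation_profile(tr, bins = seq(-10, 10, 2))
  expect_true(all(is.na(wide$p1[wide$n == 0])))
})

test_that("rotamer classification is circular and counts label changes", {
  s <- classify_rotamer(rep(-90, 10))
  expect_equal(unique(s$labels), "gauche-")
  expect_equal(s$transitions, 0)
  alt <- classify_rotamer(rep(c(-90, 180), 5))
  expect_equal(alt$transitions, 9)
  wrap <- classify_rotamer(rep(c(179, -179), 5))
  expect_equal(wrap$transitions, 0)  # both sit in the trans sector
  expect_error(classify_rotamer(1:5, states = list(cuts = c(-120, 0),
                                                   labels = c("a", "b", "c"))),
               "partition")
  # rotating angles and boundaries together preserves the transition count
  set.seed(10)
  ang <- runif(200, -180, 180)
  base <- classify_rotamer(ang)$transitions
  rot <- classify_rotamer(wrap_angle(ang + 40),
                          states = list(cuts = wrap_angle(c(-120, 0, 120) + 40)[
                            order(wrap_angle(c(-120, 0, 120) + 40))],
                            labels = c("a", "b", "c")))
  expect_equal(rot$transitions, base)
})

test_that("dihedral_series computes wrapped angles from frame coordinates", {
  p1 <- c(1, 1, 0); p2 <- c(0, 1, 0); p3 <- c(0, 0, 0)
  angles <- c(-90, 60, 179)
  arr <- array(0, dim = c(4, 3, 3))
  for (f in 1:3) {
    arr[1, , f] <- p1; arr[2, , f] <- p2; arr[3, , f] <- p3
    arr[4, , f] <- place_atom(p1, p2, p3, 1.5, 110, angles[f])
  }
  ds <- dihedral_series(1:3, arr)
  expect_equal(ds$chi1, angles, tolerance = 1e-7)
})

test_that("occupancy profile localises mass and respects the lateral cutoff", {
  stat <- solute_track("m1", 1:100, cbind(0, 0, rep(0, 100)))
  oc <- occupancy_profile(stat, bins = seq(-5, 5, 1))
  expect_equal(sum(oc$count), 100)
  expect_equal(oc$count[oc$z == -0.5 | oc$z == 0.5][1] +
                 0 * oc$count[1], 100)
  outside <- solute_track("m2", 1:50, cbind(10, 0, rep(0, 50)))
  expect_equal(nrow(occupancy_profile(outside, lateral_cutoff = 6)), 0)
  # uniform track: density flat within binomial noise
  set.seed(11)
  u <- solute_track("m3", 1:20000, cbind(0, 0, runif(20000, -10, 10)))
  ou <- occupancy_profile(u, bins = seq(-10, 10, 2))
  p_bin <- 1 / nrow(ou)
  ci <- 3 * sqrt(20000 * p_bin * (1 - p_bin))
  expect_true(all(abs(ou$count - 20000 * p_bin) < ci))
})

test_that("track CSV round-trips with orientation endpoints", {
  trs <- make_orientation_tracks(
    data.frame(z_lo = 0, z_hi = 5, p1_target = 0.4), n = 20, seed = 12)
  tf <- tempfile(fileext = ".csv")
  write_tracks_csv(trs, tf)
  back <- read_tracks_csv(tf)
  expect_equal(length(back), 1)
  expect_equal(back[[1]]$positions, trs[[1]]$positions, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back[[1]]$orient2, trs[[1]]$orient2, tolerance = 1e-9,
               ignore_attr = TRUE)
  unlink(tf)
})
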