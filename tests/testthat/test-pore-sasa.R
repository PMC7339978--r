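test_that("pore profiler is exact on analytic ring fixtures", {
  ring <- make_channel_fixture(
    data.frame(z = 0, ring_radius = 5.0, vdw = 1.7))
  ax <- channel_axis(rbind(c(0, 0, -5), c(0, 0, 5)))
  pp <- pore_profile(ring, ax, z_min = -1, z_max = 1, step = 0.5)
  at0 <- pp[pp$z == 0, ]
  expect_equal(at0$radius, 5.0 - 1.7, tolerance = 1e-3)
  expect_equal(c(at0$cx, at0$cy), c(0, 0), tolerance = 1e-3)

  two <- make_channel_fixture(
    data.frame(z = c(0, 4), ring_radius = c(5.0, 3.5), vdw = 1.7))
  pp2 <- pore_profile(two, ax, z_min = -1, z_max = 5, step = 0.25,
                      slab_cutoff = 12)
  mc <- min_constriction(pp2)
  expect_equal(mc$diameter, 2 * (3.5 - 1.7), tolerance = 2e-3)
  expect_equal(mc$z, 4, tolerance = 1e-9)
})

test_that("pore profiler matches a dense-grid search on a randomized ring set", {
  set.seed(12)
  rings <- data.frame(z = c(-4, 0, 3, 6),
                      ring_radius = round(runif(4, 3, 6), 2),
                      vdw = c(1.5, 1.7, 1.6, 1.8))
  st <- make_channel_fixture(rings)
  ax <- channel_axis(rbind(c(0, 0, -5), c(0, 0, 5)))
  pp <- pore_profile(st, ax, z_min = -4, z_max = 6, step = 0.5,
                     slab_cutoff = 15)
  xyz <- coords(st)
  rv <- st$atoms$vdw_radius
  for (i in seq_len(nrow(pp))) {
    zq <- pp$z[i]
    # brute-force dense grid over in-plane centres
    grid <- as.matrix(expand.grid(x = seq(-2, 2, 0.05),
                                  y = seq(-2, 2, 0.05)))
    clear <- apply(grid, 1, function(c2) {
      min(sqrt((xyz[, 1] - c2[1])^2 + (xyz[, 2] - c2[2])^2 +
                 (xyz[, 3] - zq)^2) - rv)
    })
    expect_gte(pp$radius[i] + 1e-6, max(clear))
    expect_equal(pp$radius[i], max(clear), tolerance = 5e-3)
  }
})

test_that("slices with no atoms in reach are reported unbounded", {
  ring <- make_channel_fixture(data.frame(z = 0, ring_radius = 5, vdw = 1.7))
  ax <- channel_axis(rbind(c(0, 0, -30), c(0, 0, 30)))
  pp <- pore_profile(ring, ax, z_min = -25, z_max = 25, step = 25,
                     slab_cutoff = 8)
  expect_true(is.infinite(pp$radius[pp$z == -25]))
  expect_true(is.finite(pp$radius[pp$z == 0]))
})

test_that("min_constriction honours windows and breaks ties toward smaller z", {
  prof <- data.frame(z = 0:10, radius = 10 - (0:10))  # monotone
  expect_equal(min_constriction(prof, c(2, 6))$z, 6)  # window edge
  v <- data.frame(z = seq(5, 10, 0.5), radius = abs(seq(5, 10, 0.5) - 7.5) + 1.05)
  expect_equal(min_constriction(v)$z, 7.5)
  expect_equal(min_constriction(v)$diameter, 2.1)
  flat <- data.frame(z = 0:5, radius = rep(2, 6))
  expect_equal(min_constriction(flat)$z, 0)
  expect_error(min_constriction(prof, c(100, 200)), "no profile points")
})

test_that("SASA matches closed forms for free and paired spheres", {
  # single atom: 4 pi (R + probe)^2 within the sampling bound
  a <- sasa(matrix(0, 1, 3), probe_radius = 1.4, n_sphere_points = 960,
            radii = 1.7)
  truth <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(as.numeric(a), truth, tolerance = 0.01)
  # far-apart atoms are exactly additive
  b <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), radii = c(1.7, 1.5))
  expect_equal(attr(b, "total"),
               4 * pi * ((1.7 + 1.4)^2 + (1.5 + 1.4)^2), tolerance = 0.01)
  # overlapping pair vs the spherical-cap closed form
  d <- 2.0
  cc <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), radii = c(1.7, 1.5))
  truth2 <- two_sphere_sasa(1.7, 1.5, d, 1.4)
  expect_equal(as.numeric(cc), truth2, tolerance = 0.01)
  expect_error(sasa(matrix(0, 1, 3), n_sphere_points = 8, radii = 1),
               "undersampled")
})

test_that("buried_surface is symmetric, non-negative, zero without contact", {
  mk <- function(xoff, chain, resno) {
    data.frame(serial = 1:2 + resno * 10, atom_name = c("C1", "C2"),
               residue_name = "RES", residue_number = resno, ins = "",
               chain_id = chain, x = xoff + c(0, 1.2), y = 0, z = 0,
               element = "C", occupancy = 1, is_hetero = FALSE,
               vdw_radius = 1.7)
  }
  far_a <- as_structure(mk(0, "A", 1))
  far_b <- as_structure(mk(50, "B", 2))
  st <- as_structure(rbind(far_a$atoms, far_b$atoms))
  expect_equal(buried_surface(st, far_a, far_b), 0, tolerance = 1e-6)
  near_b <- as_structure(mk(3.0, "B", 2))
  st2 <- as_structure(rbind(far_a$atoms, near_b$atoms))
  ab <- buried_surface(st2, far_a, near_b)
  ba <- buried_surface(st2, near_b, far_a)
  expect_gt(ab, 0)
  expect_equal(ab, ba, tolerance = 1e-9)
  expect_error(buried_surface(st2, far_a, far_a), "overlapping")
})
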