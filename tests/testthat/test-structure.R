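test_that("read_pdb maps ATOM/HETATM records, chains, and hetero flags", {
  lines <- c(
    pdb_line(1, "CA", "GLY", "A", 1, 1.0, 2.0, 3.0),
    pdb_line(2, "CA", "GLY", "A", 2, 2.0, 2.0, 3.0),
    pdb_line(3, "CA", "GLY", "B", 1, 3.0, 2.0, 3.0),
    pdb_line(4, "CA", "GLY", "B", 2, 4.0, 2.0, 3.0),
    paste(pdb_line(5, "C1", "GOL", "A", 90, 0, 0, 0, record = "HETATM"))
  )
  st <- read_pdb(paste(lines, collapse = "\n"), id = "fixture")
  expect_s3_class(st, "cf_structure")
  expect_equal(nrow(st$atoms), 5)
  expect_equal(unname(unlist(st$atoms[1, c("x", "y", "z")])), c(1, 2, 3))
  expect_equal(nrow(select_atoms(st, chain = "A", hetero = FALSE)$atoms), 2)
  expect_equal(nrow(select_atoms(st, chain = "B")$atoms), 2)
  expect_true(st$atoms$is_hetero[5])
  expect_false(any(st$atoms$is_hetero[1:4]))
  # vdW radii assigned from the element table
  expect_equal(st$atoms$vdw_radius[1], 1.70)
})

test_that("read_pdb rejects malformed and empty inputs, resolves altlocs", {
  good <- pdb_line(1, "CA", "GLY", "A", 1, 1, 2, 3)
  bad <- substr(good, 1, 40)  # truncated coordinates
  expect_error(read_pdb(paste(c(good, bad), collapse = "\n")),
               "line 2")
  expect_error(read_pdb("HEADER only\nEND"), "empty model")
  # two altlocs of the same atom: highest occupancy wins
  alt <- c(
    "ATOM      1  CA AGLY A   1       1.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BGLY A   1       2.000   0.000   0.000  0.70  0.00           C")
  st <- read_pdb(paste(alt, collapse = "\n"))
  expect_equal(nrow(st$atoms), 1)
  expect_equal(st$atoms$x, 2.0)
})

test_that("gzipped PDB files read transparently", {
  lines <- c(pdb_line(1, "CA", "GLY", "A", 1, 1, 2, 3),
             pdb_line(2, "CA", "GLY", "A", 2, 4, 5, 6),
             pdb_line(3, "CA", "GLY", "A", 3, 7, 8, 10))
  gz <- tempfile(fileext = ".pdb.gz")
  con <- gzfile(gz, "w"); writeLines(lines, con); close(con)
  st <- read_pdb(gz)
  expect_equal(nrow(st$atoms), 3)
  unlink(gz)
})

test_that("superpose recovers exact rigid motions and excludes reflections", {
  set.seed(1)
  X <- matrix(rnorm(30), ncol = 3)
  sp <- superpose(X, X)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)
  # 90 degree rotation about z plus a shift
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Y <- X %*% t(R) + matrix(rep(c(5, -2, 1), each = 10), ncol = 3)
  sp2 <- superpose(X, Y)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_superposition(sp2, X), Y, tolerance = 1e-9)
  expect_error(superpose(X[1:2, ], X[1:2, ]), "3 paired")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("superpose matches the quaternion grid-search oracle on noisy data", {
  set.seed(42)
  X <- matrix(rnorm(30), ncol = 3)
  ang <- 0.8
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  Y <- X %*% t(R) + matrix(rnorm(30, sd = 0.1), ncol = 3)
  rmsd_kabsch <- superpose(X, Y)$rmsd
  rmsd_oracle <- quaternion_rmsd_oracle(X, Y)
  expect_lt(abs(rmsd_kabsch - rmsd_oracle), 1e-6)
  expect_lte(rmsd_kabsch, rmsd_oracle + 1e-9)  # Kabsch is the optimum
})

test_that("rmsd is invariant under a common rigid motion of both clouds", {
  set.seed(3)
  X <- matrix(rnorm(24), ncol = 3)
  Y <- X + matrix(rnorm(24, sd = 0.3), ncol = 3)
  base <- superpose(X, Y)$rmsd
  ang <- 1.1
  Rz <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  shift <- matrix(rep(c(-3, 7, 2), each = 8), ncol = 3)
  expect_equal(superpose(X %*% t(Rz) + shift, Y %*% t(Rz) + shift)$rmsd,
               base, tolerance = 1e-9)
})

test_that("dihedral_angle obeys symmetry, sign and wrap conventions", {
  p1 <- c(1, 1, 0); p2 <- c(0, 1, 0); p3 <- c(0, 0, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(1, -0.5, 0)), 0)     # cis
  expect_equal(dihedral_angle(p1, p2, p3, c(-1, -0.5, 0)), 180)  # trans
  # constructed +60 degrees via explicit placement
  p4 <- place_atom(p1, p2, p3, 1.5, 110, 60)
  expect_equal(dihedral_angle(p1, p2, p3, p4), 60, tolerance = 1e-8)
  # IUPAC conventions: invariant under atom-order reversal, negated by a
  # mirror reflection
  set.seed(8)
  for (i in 1:20) {
    q <- matrix(rnorm(12), ncol = 3)
    a <- tryCatch(dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ]),
                  error = function(e) NA)
    if (is.na(a)) next
    expect_equal(dihedral_angle(q[4, ], q[3, ], q[2, ], q[1, ]), a,
                 tolerance = 1e-8)
    qm <- q; qm[, 1] <- -qm[, 1]
    expect_equal(wrap_angle(dihedral_angle(qm[1, ], qm[2, ], qm[3, ],
                                           qm[4, ]) + a), 0,
                 tolerance = 1e-8)
  }
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "collinear")
})

test_that("chi_angles measures constructed rotamers and flags missing gammas", {
  st <- read_pdb(paste(phe_fixture_lines(-90), collapse = "\n"))
  res <- chi_angles(st, "A", 74)
  expect_equal(res$chi1, -90, tolerance = 1e-3)
  expect_true(is.na(res$chi2))  # no CD1 in the fixture
  st2 <- read_pdb(paste(phe_fixture_lines(179.5), collapse = "\n"))
  expect_equal(abs(chi_angles(st2, "A", 74)$chi1), 179.5, tolerance = 1e-3)
  ala <- c(pdb_line(1, "N", "ALA", "A", 5, 0, 1.45, 0, elem = "N"),
           pdb_line(2, "CA", "ALA", "A", 5, 0, 0, 0),
           pdb_line(3, "CB", "ALA", "A", 5, 1.3, -0.6, 0))
  expect_error(chi_angles(read_pdb(paste(ala, collapse = "\n")), "A", 5),
               "no chi angles")
})

test_that("ligand_shift returns 0 for identity and the exact translation", {
  prot <- c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
            pdb_line(2, "CA", "GLY", "A", 2, 3, 0, 0),
            pdb_line(3, "CA", "GLY", "A", 3, 0, 4, 0),
            pdb_line(4, "CA", "GLY", "A", 4, 0, 0, 5))
  lig_a <- pdb_line(5, "C1", "GOL", "A", 90, 1, 1, 1, record = "HETATM")
  lig_b <- pdb_line(5, "C1", "GOL", "A", 90, 1, 4, 1, record = "HETATM")
  sa <- read_pdb(paste(c(prot, lig_a), collapse = "\n"))
  sb <- read_pdb(paste(c(prot, lig_b), collapse = "\n"))
  align_a <- select_atoms(sa, atom_names = "CA")
  lig_sel_a <- select_atoms(sa, hetero = TRUE)
  expect_equal(as.numeric(ligand_shift(sa, sa, lig_sel_a, lig_sel_a,
                                       align_a, align_a)), 0,
               tolerance = 1e-9)
  expect_equal(as.numeric(ligand_shift(sa, sb, lig_sel_a,
                                       select_atoms(sb, hetero = TRUE),
                                       align_a,
                                       select_atoms(sb, atom_names = "CA"))),
               3, tolerance = 1e-9)
})
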