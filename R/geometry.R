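#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares optimal rotation and translation mapping `mobile` onto
#' `reference`, with reflections excluded (determinant +1).
#'
#' @param mobile,reference Paired n x 3 coordinate matrices, n >= 3.
#' @return An object of class `cf_superposition`: list with `rotation`
#'   (3 x 3, det +1), `translation` (length 3), `rmsd` (Angstrom) and
#'   `n_atoms_used`. Apply with [apply_superposition()].
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)) || ncol(mobile) != 3L) {
    stop("mobile and reference must be paired n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3L) stop("degenerate geometry: need at least 3 paired atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); R0 <- sweep(reference, 2, cr)
  sv_m <- svd(M)$d
  if (sv_m[2] < 1e-8 * max(sv_m[1], 1e-12)) {
    stop("degenerate geometry: points are collinear")
  }
  H <- crossprod(M, R0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- M %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - R0)^2)))
  structure(list(rotation = R, translation = as.numeric(cr - R %*% cm),
                 rmsd = rmsd, n_atoms_used = n),
            class = "cf_superposition")
}

#' Apply a superposition to coordinates
#'
#' @param sp A `cf_superposition` from [superpose()].
#' @param xyz n x 3 coordinate matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, xyz) {
  stopifnot(inherits(sp, "cf_superposition"))
  sweep(as.matrix(xyz) %*% t(sp$rotation), 2, sp$translation, "+")
}

#' @export
print.cf_superposition <- function(x, ...) {
  cat(sprintf("<superposition: rmsd %.4f A over %d atoms>\n",
              x$rmsd, x$n_atoms_used))
  invisible(x)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap angles to (-180, 180] degrees
#'
#' @param a Numeric vector of angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Signed torsion angle of four points
#'
#' IUPAC sign convention: looking from `p2` towards `p3`, a clockwise
#' rotation of the far bond relative to the near bond is positive. Cis is 0
#' degrees, trans is 180 degrees.
#'
#' @param p1,p2,p3,p4 Numeric length-3 position vectors.
#' @return Angle in degrees, wrapped to (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("degenerate geometry: collinear points in torsion")
  }
  b2u <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(.cross3(n1, n2) * b2u), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

.chi1_gamma <- c("CG", "CG1", "OG", "OG1", "SG")

#' Side-chain chi1/chi2 dihedrals of a residue
#'
#' chi1 is the N-CA-CB-CG torsion (with the residue-appropriate gamma atom:
#' CG, CG1, OG, OG1 or SG); chi2 (CA-CB-CG-CD1) is reported for residues that
#' carry a CD1 atom (e.g. Phe, Tyr, Trp, Leu, Ile).
#'
#' @param struct A `cf_structure`.
#' @param chain Chain id.
#' @param residue_number Residue number.
#' @return List of class `cf_dihedral` with `chi1`, `chi2` (or `NA`),
#'   `residue` (name/chain/number).
#' @export
chi_angles <- function(struct, chain, residue_number) {
  res <- select_atoms(struct, chain = chain, resno = residue_number)
  a <- res$atoms
  if (nrow(a) == 0L) stop("residue not found: ", chain, ":", residue_number)
  get <- function(nm) {
    i <- match(nm, a$atom_name)
    if (all(is.na(i))) return(NULL)
    as.numeric(a[i[!is.na(i)][1], c("x", "y", "z")])
  }
  gname <- intersect(.chi1_gamma, a$atom_name)
  if (length(gname) == 0L) {
    stop(sprintf("residue %s %s:%d has no chi angles (no gamma atom)",
                 a$residue_name[1], chain, residue_number))
  }
  pN <- get("N"); pCA <- get("CA"); pCB <- get("CB"); pG <- get(gname[1])
  if (is.null(pN) || is.null(pCA) || is.null(pCB)) {
    stop("residue lacks backbone atoms needed for chi1")
  }
  chi1 <- dihedral_angle(pN, pCA, pCB, pG)
  chi2 <- NA_real_
  pD <- get("CD1")
  if (!is.null(pD) && gname[1] == "CG") {
    chi2 <- dihedral_angle(pCA, pCB, pG, pD)
  }
  structure(list(chi1 = chi1, chi2 = chi2,
                 residue = sprintf("%s %s:%d", a$residue_name[1], chain,
                                   residue_number)),
            class = "cf_dihedral")
}

#' Lateral shift of a ligand between two aligned structures
#'
#' Superposes `struct_b` onto `struct_a` using paired alignment atoms, then
#' returns the distance between the two ligand centroids. Used e.g. for the
#' shift of a vestibule-bound glycerol between homologous channels.
#'
#' @param struct_a,struct_b `cf_structure` objects.
#' @param ligand_sel_a,ligand_sel_b `cf_structure` selections holding the
#'   ligand atoms in each structure (non-empty).
#' @param align_sel_a,align_sel_b Paired alignment selections; atoms are
#'   matched by (chain, residue number, atom name) order and must pair 1:1.
#' @return Distance in Angstrom, with the superposition as attribute
#'   `"superposition"`.
#' @export
ligand_shift <- function(struct_a, struct_b, ligand_sel_a, ligand_sel_b,
                         align_sel_a, align_sel_b) {
  if (nrow(ligand_sel_a$atoms) == 0L || nrow(ligand_sel_b$atoms) == 0L) {
    stop("empty ligand selection")
  }
  ka <- with(align_sel_a$atoms,
             paste(chain_id, residue_number, atom_name, sep = ":"))
  kb <- with(align_sel_b$atoms,
             paste(chain_id, residue_number, atom_name, sep = ":"))
  if (length(ka) != length(kb)) {
    un <- c(setdiff(ka, kb), setdiff(kb, ka))
    stop("unpaired alignment atoms: ", paste(un, collapse = ", "))
  }
  sp <- superpose(coords(align_sel_b), coords(align_sel_a))
  cb <- colMeans(apply_superposition(sp, coords(ligand_sel_b)))
  ca <- colMeans(coords(ligand_sel_a))
  d <- sqrt(sum((ca - cb)^2))
  attr(d, "superposition") <- sp
  d
}
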