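#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible surface by point counting on a deterministic
#' golden-spiral sphere lattice. The sampling error of a single free atom is
#' bounded by `4 * pi * (R + probe)^2 / n_sphere_points`.
#'
#' @param struct A `cf_structure`, or an n x 3 coordinate matrix (then
#'   `radii` must be supplied).
#' @param probe_radius Probe radius in Angstrom (default 1.4, water).
#' @param n_sphere_points Number of lattice points per atom (>= 16).
#' @param radii vdW radii when `struct` is a bare matrix.
#' @return Numeric vector of per-atom areas (Angstrom^2) with attribute
#'   `"total"`.
#' @export
sasa <- function(struct, probe_radius = 1.4, n_sphere_points = 960,
                 radii = NULL) {
  if (n_sphere_points < 16) stop("n_sphere_points < 16: undersampled")
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (inherits(struct, "cf_structure")) {
    xyz <- coords(struct)
    radii <- struct$atoms$vdw_radius
  } else {
    xyz <- as.matrix(struct)
    if (is.null(radii)) stop("radii required for bare coordinates")
  }
  a <- cf_sasa_cpp(xyz, radii, probe_radius, as.integer(n_sphere_points))
  attr(a, "total") <- sum(a)
  a
}

#' Buried surface area between two atom groups
#'
#' `BSA = SASA(A) + SASA(B) - SASA(A+B)`, with the two groups extracted in
#' isolation from the rest of the structure (the standard isolated-pair
#' interface definition).
#'
#' @param struct A `cf_structure` (used only for consistency checks).
#' @param group_a,group_b Disjoint `cf_structure` selections.
#' @param probe_radius,n_sphere_points Passed to [sasa()].
#' @return Buried area in Angstrom^2 (non-negative up to sampling error).
#' @export
buried_surface <- function(struct, group_a, group_b, probe_radius = 1.4,
                           n_sphere_points = 960) {
  stopifnot(inherits(group_a, "cf_structure"),
            inherits(group_b, "cf_structure"))
  if (nrow(group_a$atoms) == 0L || nrow(group_b$atoms) == 0L) {
    stop("empty group selection")
  }
  ka <- with(group_a$atoms, paste(chain_id, residue_number, ins, atom_name))
  kb <- with(group_b$atoms, paste(chain_id, residue_number, ins, atom_name))
  if (length(intersect(ka, kb))) stop("overlapping group selections")
  sa <- attr(sasa(group_a, probe_radius, n_sphere_points), "total")
  sb <- attr(sasa(group_b, probe_radius, n_sphere_points), "total")
  both <- as_structure(rbind(group_a$atoms, group_b$atoms), id = struct$id)
  sab <- attr(sasa(both, probe_radius, n_sphere_points), "total")
  sa + sb - sab
}
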