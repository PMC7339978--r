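#' Construct a solute track
#'
#' A time-stamped trajectory of one tracked molecule in the pore-axis frame
#' (+z extracellular), optionally carrying per-frame orientation endpoints
#' (e.g. the first and last carbon atoms of glycerol).
#'
#' @param molecule_id Identifier.
#' @param times Strictly increasing times in ns.
#' @param positions n x 3 matrix of positions (Angstrom), or a numeric vector
#'   of z values (x = y = 0 assumed).
#' @param orient1,orient2 Optional n x 3 matrices of orientation endpoints.
#' @return Object of class `cf_track`.
#' @export
solute_track <- function(molecule_id, times, positions,
                         orient1 = NULL, orient2 = NULL) {
  if (is.null(dim(positions))) {
    positions <- cbind(0, 0, as.numeric(positions))
  }
  positions <- as.matrix(positions)
  if (length(times) != nrow(positions)) {
    stop("times and positions must have equal length")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(orient1)) {
    stopifnot(nrow(orient1) == length(times), nrow(orient2) == length(times))
  }
  structure(list(molecule_id = as.character(molecule_id),
                 times = as.numeric(times), positions = positions,
                 orient1 = orient1, orient2 = orient2),
            class = "cf_track")
}

#' @export
print.cf_track <- function(x, ...) {
  cat(sprintf("<cf_track '%s': %d frames, %.3g-%.3g ns%s>\n",
              x$molecule_id, length(x$times), min(x$times), max(x$times),
              if (is.null(x$orient1)) "" else ", oriented"))
  invisible(x)
}

#' Read/write solute tracks as CSV
#'
#' Columns: `molecule_id,time_ns,x,y,z` plus optional
#' `ox1,oy1,oz1,ox2,oy2,oz2` orientation endpoints.
#'
#' @param path CSV path.
#' @return `read_tracks_csv`: list of `cf_track`.
#' @export
read_tracks_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, d$molecule_id), function(g) {
    g <- g[order(g$time_ns), , drop = FALSE]
    o1 <- o2 <- NULL
    if (all(c("ox1", "oy1", "oz1", "ox2", "oy2", "oz2") %in% names(g))) {
      o1 <- as.matrix(g[, c("ox1", "oy1", "oz1")])
      o2 <- as.matrix(g[, c("ox2", "oy2", "oz2")])
    }
    solute_track(g$molecule_id[1], g$time_ns,
                 as.matrix(g[, c("x", "y", "z")]), o1, o2)
  })
}

#' @rdname read_tracks_csv
#' @param tracks List of `cf_track`.
#' @export
write_tracks_csv <- function(tracks, path) {
  if (inherits(tracks, "cf_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    d <- data.frame(molecule_id = tr$molecule_id, time_ns = tr$times,
                    x = tr$positions[, 1], y = tr$positions[, 2],
                    z = tr$positions[, 3])
    if (!is.null(tr$orient1)) {
      d$ox1 <- tr$orient1[, 1]; d$oy1 <- tr$orient1[, 2]
      d$oz1 <- tr$orient1[, 3]
      d$ox2 <- tr$orient2[, 1]; d$oy2 <- tr$orient2[, 2]
      d$oz2 <- tr$orient2[, 3]
    }
    d
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Construct a backbone frame ensemble
#'
#' @param times Frame times (ns).
#' @param coords_array Array `[n_atoms, 3, n_frames]`.
#' @param atom_info Data frame with `residue_number` and `atom_name` per atom
#'   (constant across frames).
#' @return Object of class `cf_frames`.
#' @export
frame_ensemble <- function(times, coords_array, atom_info) {
  stopifnot(length(dim(coords_array)) == 3L, dim(coords_array)[2] == 3L,
            dim(coords_array)[3] == length(times),
            dim(coords_array)[1] == nrow(atom_info))
  structure(list(times = times, coords = coords_array,
                 atom_info = atom_info), class = "cf_frames")
}

#' Time-averaged per-residue backbone RMSD
#'
#' Each frame is globally superposed onto the reference using all selected
#' atoms, then the RMSD of each residue's atoms is computed per frame and
#' averaged over frames. Multiple ensembles (monomers/replicas) are pooled
#' frame-wise.
#'
#' @param frames A `cf_frames` or a list of them.
#' @param reference Reference coordinates: a `cf_structure` whose atoms match
#'   `atom_info` by (residue_number, atom_name), or an n x 3 matrix aligned
#'   with `atom_info` row order.
#' @param selection Optional logical/integer vector of atoms used for the
#'   global fit (default: all).
#' @return Data frame of class `cf_rmsd_profile`: `residue_number`, `rmsd`
#'   (Angstrom), `n_atoms`; attribute `n_frames`.
#' @export
per_residue_rmsd <- function(frames, reference, selection = NULL) {
  if (inherits(frames, "cf_frames")) frames <- list(frames)
  info <- frames[[1]]$atom_info
  if (inherits(reference, "cf_structure")) {
    key_f <- paste(info$residue_number, info$atom_name)
    key_r <- paste(reference$atoms$residue_number, reference$atoms$atom_name)
    idx <- match(key_f, key_r)
    if (anyNA(idx)) {
      stop("reference is missing atoms: ",
           paste(head(key_f[is.na(idx)], 5), collapse = ", "))
    }
    ref <- coords(reference)[idx, , drop = FALSE]
  } else {
    ref <- as.matrix(reference)
    if (nrow(ref) != nrow(info)) stop("reference/ensemble atom mismatch")
  }
  if (is.null(selection)) selection <- seq_len(nrow(info))
  res_ids <- sort(unique(info$residue_number))
  acc <- setNames(numeric(length(res_ids)), res_ids)
  n_frames <- 0L
  for (fe in frames) {
    if (!identical(fe$atom_info$atom_name, info$atom_name)) {
      stop("ensembles have mismatched atom tables")
    }
    for (f in seq_along(fe$times)) {
      X <- fe$coords[, , f]
      sp <- superpose(X[selection, , drop = FALSE],
                      ref[selection, , drop = FALSE])
      Xa <- apply_superposition(sp, X)
      dev2 <- rowSums((Xa - ref)^2)
      for (r in seq_along(res_ids)) {
        i <- info$residue_number == res_ids[r]
        acc[r] <- acc[r] + sqrt(mean(dev2[i]))
      }
      n_frames <- n_frames + 1L
    }
  }
  out <- data.frame(residue_number = res_ids, rmsd = unname(acc) / n_frames,
                    n_atoms = as.integer(table(info$residue_number)[
                      as.character(res_ids)]))
  attr(out, "n_frames") <- n_frames
  class(out) <- c("cf_rmsd_profile", "data.frame")
  out
}

.z_breaks <- function(bins, zr) {
  if (length(bins) == 1L) seq(floor(zr[1]), ceiling(zr[2]) + bins, by = bins)
  else bins
}

#' Axial orientation order-parameter profile (P1)
#'
#' For each frame, `cos(theta)` is the dot product of the unit end-to-end
#' orientation vector with the +z pore axis; samples are binned by the
#' molecule's axial position and `P1 = <cos theta>` per bin. P1 is about +1
#' (or -1) for parallel (antiparallel) alignment and about 0 for isotropic
#' orientations. Empty bins are reported as `NA`, not zero.
#'
#' @param tracks A `cf_track` or list of tracks carrying orientation
#'   endpoints.
#' @param bins Bin width in Angstrom (default 1) or a vector of break points.
#' @return Data frame of class `cf_orientation_profile`: `z` (bin centre),
#'   `p1`, `n`; attribute `n_skipped` counts zero-length vectors.
#' @export
orientation_profile <- function(tracks, bins = 1) {
  if (inherits(tracks, "cf_track")) tracks <- list(tracks)
  zs <- cs <- numeric(0)
  skipped <- 0L
  for (tr in tracks) {
    if (is.null(tr$orient1)) stop("track lacks orientation endpoints")
    v <- tr$orient2 - tr$orient1
    len <- sqrt(rowSums(v^2))
    ok <- len > 1e-10
    skipped <- skipped + sum(!ok)
    zs <- c(zs, tr$positions[ok, 3])
    cs <- c(cs, v[ok, 3] / len[ok])
  }
  if (skipped > 0) {
    warning(sprintf("%d frames with zero-length orientation vector skipped",
                    skipped))
  }
  br <- .z_breaks(bins, range(zs))
  idx <- cut(zs, br, include.lowest = TRUE, labels = FALSE)
  mid <- (br[-1] + br[-length(br)]) / 2
  n <- tabulate(idx, nbins = length(mid))
  p1 <- rep(NA_real_, length(mid))
  agg <- tapply(cs, idx, mean)
  p1[as.integer(names(agg))] <- agg
  out <- data.frame(z = mid, p1 = p1, n = n)
  attr(out, "n_skipped") <- skipped
  class(out) <- c("cf_orientation_profile", "data.frame")
  out
}

#' Dihedral time series of a residue's side chain
#'
#' @param times Frame times (ns).
#' @param chi1_coords Array `[4, 3, n_frames]` of the N, CA, CB, gamma atom
#'   positions per frame.
#' @param chi2_coords Optional array `[4, 3, n_frames]` for CA, CB, CG, CD1.
#' @return List of class `cf_dihedral_series` with `times`, `chi1`, `chi2`
#'   (degrees, wrapped to (-180, 180]).
#' @export
dihedral_series <- function(times, chi1_coords, chi2_coords = NULL) {
  nf <- length(times)
  stopifnot(dim(chi1_coords)[3] == nf)
  ang <- function(arr, f) {
    dihedral_angle(arr[1, , f], arr[2, , f], arr[3, , f], arr[4, , f])
  }
  chi1 <- vapply(seq_len(nf), function(f) ang(chi1_coords, f), numeric(1))
  chi2 <- if (is.null(chi2_coords)) NULL else
    vapply(seq_len(nf), function(f) ang(chi2_coords, f), numeric(1))
  structure(list(times = times, chi1 = chi1, chi2 = chi2),
            class = "cf_dihedral_series")
}

#' Default chi1 rotamer sectors
#'
#' Three 120-degree circular sectors centred at -60, +60 and 180 degrees
#' (gauche-, gauche+, trans).
#'
#' @return A rotamer-state definition (list with `cuts` and `labels`).
#' @export
rotamer_states_chi1 <- function() {
  list(cuts = c(-120, 0, 120), labels = c("gauche-", "gauche+", "trans"))
}

#' Classify a dihedral series into rotamer states
#'
#' States are circular sectors delimited by `cuts` (degrees, strictly
#' increasing within (-180, 180]); sector k spans `(cuts[k], cuts[k+1]]` and
#' the last sector wraps through 180/-180 (so -179 and +179 degrees share the
#' wrapped sector). Transitions are counted on label changes only.
#'
#' @param series A `cf_dihedral_series`, or a numeric vector of angles.
#' @param states List with `cuts` and `labels` (same length); the sectors
#'   partition the circle by construction.
#' @param which Which angle of a series to classify ("chi1" or "chi2").
#' @return List of class `cf_rotamer_series`: `labels` (per frame),
#'   `transitions` (count of label changes), `states`.
#' @export
classify_rotamer <- function(series, states = rotamer_states_chi1(),
                             which = "chi1") {
  ang <- if (is.numeric(series)) series else series[[which]]
  if (is.null(ang)) stop("series has no ", which, " angles")
  cuts <- states$cuts; labels <- states$labels
  if (length(cuts) != length(labels)) {
    stop("state boundaries do not partition the circle: ",
         "cuts and labels must have equal length")
  }
  if (is.unsorted(cuts, strictly = TRUE) || any(cuts <= -180) ||
      any(cuts > 180)) {
    stop("cuts must be strictly increasing within (-180, 180]")
  }
  a <- wrap_angle(ang)
  idx <- findInterval(a, cuts)        # 0 .. m
  m <- length(cuts)
  idx[idx == 0L] <- m                  # below first cut -> wrapped sector
  lab <- labels[idx]
  trans <- sum(lab[-1] != lab[-length(lab)])
  structure(list(labels = lab, transitions = trans, states = states),
            class = "cf_rotamer_series")
}

#' Axial occupancy profile of solute tracks
#'
#' Frame-count histogram over axial bins, restricted to in-pore samples
#' (lateral distance from the axis below `lateral_cutoff`), plus its
#' normalisation to mean density 1 over occupied bins.
#'
#' @param tracks A `cf_track` or list of tracks.
#' @param bins Bin width (Angstrom) or break points.
#' @param lateral_cutoff Lateral cutoff in Angstrom (> 0).
#' @return Data frame: `z` (bin centre), `count`, `density`.
#' @export
occupancy_profile <- function(tracks, bins = 1, lateral_cutoff = 6) {
  stopifnot(lateral_cutoff > 0)
  if (inherits(tracks, "cf_track")) tracks <- list(tracks)
  zs <- numeric(0)
  for (tr in tracks) {
    lat <- sqrt(tr$positions[, 1]^2 + tr$positions[, 2]^2)
    zs <- c(zs, tr$positions[lat < lateral_cutoff, 3])
  }
  if (length(zs) == 0L) {
    return(data.frame(z = numeric(0), count = integer(0),
                      density = numeric(0)))
  }
  br <- .z_breaks(bins, range(zs))
  idx <- cut(zs, br, include.lowest = TRUE, labels = FALSE)
  mid <- (br[-1] + br[-length(br)]) / 2
  cnt <- tabulate(idx, nbins = length(mid))
  dens <- rep(NA_real_, length(mid))
  occ <- cnt > 0
  dens[occ] <- cnt[occ] / mean(cnt[occ])
  data.frame(z = mid, count = cnt, density = dens)
}
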