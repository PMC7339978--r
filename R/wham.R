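#' Construct an umbrella-sampling window
#'
#' @param center Restraint centre z0 (Angstrom).
#' @param k Harmonic force constant (kcal/mol/Angstrom^2, >= 0; 0 means
#'   unbiased).
#' @param samples Reaction-coordinate samples (Angstrom, non-empty).
#' @return List of class `cf_window`.
#' @export
umbrella_window <- function(center, k, samples) {
  if (length(samples) == 0L) stop("window has no samples")
  if (k < 0) stop("force constant must be >= 0")
  structure(list(center = center, k = k, samples = as.numeric(samples)),
            class = "cf_window")
}

#' Read/write one umbrella window as CSV
#'
#' The file carries two header comment lines (`# center <z0>` and
#' `# k <force constant>`) followed by one sample per line under a `z`
#' column.
#'
#' @param path CSV path.
#' @return `read_umbrella_csv`: a `cf_window`.
#' @export
read_umbrella_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  center <- as.numeric(sub("^#\\s*center\\s*", "", hdr[1]))
  k <- as.numeric(sub("^#\\s*k\\s*", "", hdr[2]))
  if (is.na(center) || is.na(k)) stop("missing center/k header in ", path)
  d <- read.csv(path, comment.char = "#")
  umbrella_window(center, k, d$z)
}

#' @rdname read_umbrella_csv
#' @param window A `cf_window`.
#' @export
write_umbrella_csv <- function(window, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# center %.6g", window$center),
               sprintf("# k %.6g", window$k), "z"), con)
  writeLines(format(window$samples, digits = 10, trim = TRUE), con)
  invisible(path)
}

#' Weighted histogram analysis method (WHAM)
#'
#' Self-consistent reconstruction of an unbiased free-energy profile from
#' harmonically biased windows. Iterates
#' `P(z_b) = sum_i n_i(z_b) / sum_i N_i exp[(F_i - U_i(z_b))/kT]` and
#' `F_i = -kT log sum_b P(z_b) exp(-U_i(z_b)/kT)` until the largest change
#' in any window offset falls below `tol`. The profile
#' `dG = -kT log P` is anchored so its mean over the anchor region is zero.
#'
#' @param windows List of `cf_window` objects, pairwise overlapping along z
#'   (each window must share at least one occupied bin with its neighbour).
#' @param bin_width Histogram bin width (Angstrom); ignored if `bin_edges`
#'   is given. The 0.1 Angstrom default keeps the mid-bin approximation of
#'   the bias potential well below kT at typical force constants.
#' @param bin_edges Optional explicit bin edges.
#' @param kT Thermal energy (kcal/mol; default 0.596, i.e. 300 K).
#' @param tol Convergence tolerance on window offsets (kcal/mol).
#' @param max_iter Maximum iterations (warning with residual if reached).
#' @param anchor Anchor region: profile mean over bins with `|z| >= anchor`
#'   is set to zero (bulk reference).
#' @return Object of class `cf_free_energy_profile`: data frame `z`, `dG`
#'   plus attributes `offsets` (F_i per window), `iterations`, `residual`,
#'   `kT`, `anchor`.
#' @export
wham <- function(windows, bin_width = 0.1, bin_edges = NULL,
                 kT = .kT_default, tol = 1e-7, max_iter = 1e5,
                 anchor = 15) {
  stopifnot(length(windows) >= 1L, kT > 0)
  samp <- lapply(windows, function(w) w$samples)
  if (is.null(bin_edges)) {
    zr <- range(unlist(samp))
    bin_edges <- seq(floor(zr[1] / bin_width) * bin_width,
                     ceiling(zr[2] / bin_width) * bin_width + bin_width,
                     by = bin_width)
  }
  mids <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  nb <- length(mids)
  nw <- length(windows)
  counts <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    idx <- cut(samp[[i]], bin_edges, include.lowest = TRUE, labels = FALSE)
    counts[i, ] <- tabulate(idx[!is.na(idx)], nbins = nb)
  }
  # overlap check on the chain of windows ordered by centre
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  for (j in seq_len(max(nw - 1, 0))) {
    a <- ord[j]; b <- ord[j + 1]
    if (!any(counts[a, ] > 0 & counts[b, ] > 0)) {
      stop(sprintf(
        "non-overlapping window chain: no shared occupied bin between windows centred at %.3g and %.3g",
        windows[[a]]$center, windows[[b]]$center))
    }
  }
  N <- rowSums(counts)
  num <- colSums(counts)
  U <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    U[i, ] <- 0.5 * windows[[i]]$k * (mids - windows[[i]]$center)^2
  }
  A <- exp(-U / kT)                 # nw x nb
  Fi <- numeric(nw)
  iter <- 0L
  resid <- Inf
  occupied <- num > 0
  repeat {
    iter <- iter + 1L
    wts <- (N * exp(Fi / kT)) %*% A   # 1 x nb: sum_i N_i exp((F_i-U_ib)/kT)
    P <- rep(0, nb)
    P[occupied] <- num[occupied] / wts[occupied]
    P <- P / sum(P)
    Fnew <- -kT * log(A %*% P)
    Fnew <- Fnew - Fnew[1]
    resid <- max(abs(Fnew - Fi))
    Fi <- as.numeric(Fnew)
    if (resid < tol || iter >= max_iter) break
  }
  if (resid >= tol) {
    warning(sprintf("WHAM reached max_iter = %d with residual %.3g kcal/mol",
                    as.integer(max_iter), resid))
  }
  dG <- rep(NA_real_, nb)
  dG[occupied] <- -kT * log(P[occupied])
  bulk <- occupied & abs(mids) >= anchor
  ref <- if (any(bulk)) mean(dG[bulk]) else mean(dG[occupied])
  dG <- dG - ref
  out <- data.frame(z = mids, dG = dG)
  attr(out, "offsets") <- Fi
  attr(out, "iterations") <- iter
  attr(out, "residual") <- resid
  attr(out, "kT") <- kT
  attr(out, "anchor") <- anchor
  class(out) <- c("cf_free_energy_profile", "data.frame")
  out
}

#' Barrier height and well depth of a free-energy profile
#'
#' The barrier is the maximum of dG over the selectivity-filter region; the
#' well is the minimum over the NPA region, both relative to the bulk anchor
#' (dG = 0). Defaults match an aquaglyceroporin pore with the SF centred
#' near z = +7.5 Angstrom and the NPA region spanning z in \[-5, +4\].
#'
#' @param profile A `cf_free_energy_profile` or any data frame with `z` and
#'   `dG` columns.
#' @param sf_region,npa_region Length-2 z intervals (Angstrom).
#' @return List with `barrier` and `well` (kcal/mol).
#' @export
profile_features <- function(profile, sf_region = c(4, 12),
                             npa_region = c(-5, 4)) {
  grab <- function(region) {
    sel <- profile$z >= region[1] & profile$z <= region[2] &
      is.finite(profile$dG)
    if (!any(sel)) stop("region [", region[1], ", ", region[2],
                        "] contains no profile points")
    profile$dG[sel]
  }
  list(barrier = max(grab(sf_region)), well = min(grab(npa_region)))
}

#' Write a free-energy profile to CSV
#'
#' @param profile A `cf_free_energy_profile`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(as.data.frame(profile)[, c("z", "dG")], path, row.names = FALSE)
  invisible(path)
}
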