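#' Build a run configuration
#'
#' @param stage Stage name: one of `"events"`, `"wham"`, `"pf"`,
#'   `"simulate-langevin"`, `"simulate-oocyte"`, `"pore-profile"`.
#' @param inputs Named list of input file paths.
#' @param params Named list of stage parameters.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed; required for stochastic stages (no silent
#'   entropy).
#' @return List of class `cf_run_config`.
#' @export
run_config <- function(stage, inputs = list(), params = list(),
                       out_dir = ".", seed = NULL) {
  structure(list(stage = stage, inputs = inputs, params = params,
                 out_dir = out_dir, seed = seed), class = "cf_run_config")
}

#' Read/write a run configuration as JSON
#'
#' Configurations round-trip losslessly.
#'
#' @param config A `cf_run_config`.
#' @param path JSON path.
#' @return `read_run_config`: a `cf_run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(x$stage, as.list(x$inputs), as.list(x$params), x$out_dir,
             x$seed)
}

.stochastic_stages <- c("simulate-langevin", "simulate-oocyte")

.sidecar <- function(config, outputs) {
  list(stage = config$stage, params = config$params, seed = config$seed,
       inputs = lapply(config$inputs, function(p)
         list(path = p, md5 = unname(tools::md5sum(p)))),
       outputs = lapply(outputs, function(p)
         list(path = p, md5 = unname(tools::md5sum(p)))),
       package_version = as.character(utils::packageVersion("channelflux")),
       r_version = paste(R.version$major, R.version$minor, sep = "."))
}

#' Execute one pipeline stage
#'
#' Validates the configuration (all referenced inputs must exist; stochastic
#' stages require an explicit seed) before any computation, runs the stage,
#' and writes every output with a JSON provenance sidecar (parameters, seed,
#' input/output checksums, package version). Partial outputs are removed on
#' failure, and identical configurations reproduce byte-identical artifacts.
#'
#' @param config A `cf_run_config`.
#' @return Character vector of artifact paths, invisibly.
#' @export
run_stage <- function(config) {
  stopifnot(inherits(config, "cf_run_config"))
  known <- c("events", "wham", "pf", "simulate-langevin", "simulate-oocyte",
             "pore-profile")
  if (!config$stage %in% known) {
    stop("unknown stage '", config$stage, "'; expected one of: ",
         paste(known, collapse = ", "))
  }
  ins <- as.character(unlist(config$inputs))
  missing_in <- ins[!file.exists(ins)]
  if (length(missing_in)) {
    stop("missing input path(s): ", paste(missing_in, collapse = ", "))
  }
  if (config$stage %in% .stochastic_stages && is.null(config$seed)) {
    stop("stage '", config$stage, "' is stochastic: an explicit seed is required")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs))
  p <- config$params
  out <- function(name) file.path(config$out_dir, name)
  if (config$stage == "events") {
    tracks <- read_tracks_csv(config$inputs$tracks)
    site <- do.call(site_definition, p[intersect(names(p),
      c("name", "z_range", "lateral_cutoff", "hysteresis", "min_dwell"))])
    ev <- do.call(rbind, lapply(tracks, detect_visits, site = site))
    outputs <- out("events.csv")
    write.csv(ev, outputs, row.names = FALSE)
  } else if (config$stage == "wham") {
    wins <- lapply(unlist(config$inputs$windows), read_umbrella_csv)
    args <- c(list(windows = wins), p[intersect(names(p),
      c("bin_width", "kT", "tol", "max_iter", "anchor"))])
    prof <- do.call(wham, args)
    outputs <- out("profile.csv")
    write_profile_csv(prof, outputs)
  } else if (config$stage == "pf") {
    d <- read.csv(config$inputs$recordings, stringsAsFactors = FALSE)
    proto <- jsonlite::read_json(config$inputs$protocol,
                                 simplifyVector = TRUE)
    protocol <- do.call(bath_protocol, as.list(proto))
    res <- do.call(rbind, lapply(split(d, d$oocyte_id), function(g) {
      rec <- oocyte_recording(g$oocyte_id[1], g$group[1], g$time_s,
                              g$area_cm2, protocol)
      est <- estimate_pf(rec,
        osm_in = if (is.null(p$osm_in)) 195 else p$osm_in,
        window = if (is.null(p$window)) c(0, 60) else unlist(p$window))
      data.frame(oocyte_id = g$oocyte_id[1], group = g$group[1],
                 Pf = est$Pf, slope = est$slope, r_squared = est$r_squared)
    }))
    outputs <- out("pf_estimates.csv")
    write.csv(res, outputs, row.names = FALSE)
  } else if (config$stage == "simulate-langevin") {
    pmf <- if (identical(p$pmf, "glpf")) glpf_pmf() else aqp7_pmf()
    sp <- langevin_spec(
      D = if (is.null(p$D)) 100 else p$D,
      dt = if (is.null(p$dt)) 2.5e-4 else p$dt,
      steps = if (is.null(p$steps)) 1e5 else p$steps,
      seed = config$seed)
    tr <- simulate_langevin(pmf, sp)
    outputs <- out("tracks.csv")
    write_tracks_csv(tr, outputs)
  } else if (config$stage == "simulate-oocyte") {
    spec <- forward_model_spec(
      Pf = p$Pf, P_s = unlist(p$P_s),
      osm_in0 = if (is.null(p$osm_in0)) 195 else p$osm_in0)
    proto <- jsonlite::read_json(config$inputs$protocol,
                                 simplifyVector = TRUE)
    recs <- make_oocyte_recordings(spec, do.call(bath_protocol,
                                                 as.list(proto)),
      n_oocytes = if (is.null(p$n_oocytes)) 10 else p$n_oocytes,
      duration = if (is.null(p$duration)) 60 else p$duration,
      seed = config$seed)
    d <- do.call(rbind, lapply(recs, function(r) {
      data.frame(oocyte_id = r$oocyte_id, group = r$group,
                 time_s = r$times, area_cm2 = r$area)
    }))
    outputs <- out("recordings.csv")
    write.csv(d, outputs, row.names = FALSE)
  } else if (config$stage == "pore-profile") {
    st <- read_pdb(config$inputs$pdb)
    prof <- pore_profile(st,
      z_min = if (is.null(p$z_min)) -25 else p$z_min,
      z_max = if (is.null(p$z_max)) 25 else p$z_max,
      step = if (is.null(p$step)) 0.25 else p$step)
    outputs <- out("pore_profile.csv")
    write_pore_profile(prof, outputs)
  }
  sidecar_path <- out(paste0(config$stage, ".provenance.json"))
  jsonlite::write_json(.sidecar(config, as.list(outputs)), sidecar_path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  outputs <- c(outputs, sidecar_path)
  ok <- TRUE
  invisible(outputs)
}

#' Summarise the artifacts in a run directory
#'
#' Restates numbers from the stage artifacts (never recomputes them) as a
#' human-readable report.
#'
#' @param run_dir Directory containing stage outputs.
#' @return Character vector of report lines, invisibly; also printed.
#' @export
run_report <- function(run_dir) {
  files <- list.files(run_dir, full.names = TRUE)
  if (length(files) == 0L) stop("empty run directory: ", run_dir)
  lines <- c(sprintf("Run report: %s", run_dir), "")
  f <- function(name) file.path(run_dir, name)
  if (file.exists(f("events.csv"))) {
    ev <- read.csv(f("events.csv"))
    lines <- c(lines, "## Events",
               sprintf("  visits: %d; mean residence %.3g ns", nrow(ev),
                       mean(ev$residence)), "")
  }
  if (file.exists(f("profile.csv"))) {
    pr <- read.csv(f("profile.csv"))
    lines <- c(lines, "## Free-energy profile",
               sprintf("  %d bins, z in [%.3g, %.3g]; max dG %.3g, min dG %.3g kcal/mol",
                       nrow(pr), min(pr$z), max(pr$z),
                       max(pr$dG, na.rm = TRUE), min(pr$dG, na.rm = TRUE)),
               "")
  }
  if (file.exists(f("pf_estimates.csv"))) {
    pf <- read.csv(f("pf_estimates.csv"))
    for (g in unique(pf$group)) {
      x <- pf$Pf[pf$group == g]
      lines <- c(lines, "## Pf estimates",
                 sprintf("  %s: mean Pf %.3g cm/s (n = %d, sem %.3g)", g,
                         mean(x), length(x),
                         sd(x) / sqrt(max(1, length(x)))))
    }
    lines <- c(lines, "")
  }
  if (file.exists(f("pore_profile.csv"))) {
    pp <- read.csv(f("pore_profile.csv"))
    mc <- min_constriction(pp)
    lines <- c(lines, "## Pore profile",
               sprintf("  narrowest constriction: %.3g Angstrom diameter at z = %.3g",
                       mc$diameter, mc$z), "")
  }
  prov <- list.files(run_dir, pattern = "provenance\\.json$",
                     full.names = TRUE)
  for (pv in prov) {
    x <- jsonlite::read_json(pv, simplifyVector = TRUE)
    lines <- c(lines, sprintf("stage '%s' (seed %s, channelflux %s)",
                              x$stage,
                              if (is.null(x$seed)) "none" else x$seed,
                              x$package_version))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
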