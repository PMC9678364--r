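# Configuration and trajectory I/O ---------------------------------------
#
# Trajectories are stored as self-describing JSON text: a version header,
# the run configuration, and one record per snapshot (cylinder endpoint
# arrays, monomer counts, motor/linker site tables, compartment copy
# numbers, energy breakdown, cumulative end-event counters).  Configs are
# YAML with strict key checking against the built-in defaults.

TRAJ_FORMAT_VERSION <- 1L

snapshot_to_list <- function(s) {
  list(time = s$time,
       n_filaments = s$n_filaments,
       filaments = lapply(s$filaments, function(f)
         list(verts = f$verts, nmono = f$nmono, barbed = f$barbed)),
       motors = s$motors, linkers = s$linkers,
       grid_counts = s$grid_counts,
       counters = as.list(s$counters),
       energy = if (is.null(s$energy)) NULL else as.list(s$energy),
       labeled = if (is.null(s$labeled)) NULL else as.list(s$labeled),
       geom = unclass(s$geom))
}

list_to_snapshot <- function(x) {
  s <- list(
    time = as.numeric(x$time),
    n_filaments = as.integer(x$n_filaments),
    filaments = lapply(x$filaments, function(f)
      list(verts = matrix(unlist(f$verts), ncol = 3),
           nmono = as.integer(f$nmono), barbed = f$barbed)),
    motors = as.data.frame(x$motors),
    linkers = as.data.frame(x$linkers),
    grid_counts = if (is.null(x$grid_counts)) NULL else
      matrix(as.integer(unlist(x$grid_counts)),
             ncol = length(SPECIES), dimnames = list(NULL, SPECIES)),
    counters = vapply(x$counters, as.numeric, 0),
    energy = if (is.null(x$energy)) NULL else
      vapply(x$energy, as.numeric, 0),
    labeled = if (is.null(x$labeled)) NULL else unlist(x$labeled),
    geom = structure(x$geom, class = "boundary_geometry"))
  class(s) <- "acto_snapshot"
  s
}

#' Write a trajectory to a JSON file
#'
#' Numbers are written with 17 significant digits so that
#' \code{read_trajectory(write_trajectory(x))} round-trips all snapshot
#' fields exactly.
#'
#' @param traj an \code{acto_trajectory}
#' @param path output file
#' @return invisibly the path
#' @export
write_trajectory <- function(traj, path) {
  payload <- list(
    format = "actoring-trajectory",
    version = TRAJ_FORMAT_VERSION,
    status = traj$status,
    snapshots = lapply(traj$snapshots, snapshot_to_list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Read a trajectory written by \code{\link{write_trajectory}}
#' @param path input file
#' @return an \code{acto_trajectory} (without the live state)
#' @export
read_trajectory <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e) stop("cannot parse trajectory file: ",
                                         conditionMessage(e)))
  if (!identical(x$format, "actoring-trajectory"))
    stop("not a trajectory file")
  if (!identical(as.integer(x$version), TRAJ_FORMAT_VERSION))
    stop("trajectory format version mismatch: file has ", x$version)
  snaps <- lapply(x$snapshots, function(sn) {
    sn$filaments <- lapply(sn$filaments, function(f) {
      f$verts <- do.call(rbind, lapply(f$verts, unlist))
      f$nmono <- unlist(f$nmono)
      f
    })
    sn$motors <- rebind_df(sn$motors)
    sn$linkers <- rebind_df(sn$linkers)
    sn$grid_counts <- if (is.null(sn$grid_counts)) NULL else
      do.call(rbind, lapply(sn$grid_counts, unlist))
    list_to_snapshot(sn)
  })
  structure(list(snapshots = snaps, config = NULL, status = x$status),
            class = "acto_trajectory")
}

rebind_df <- function(x) {
  if (is.null(x) || !length(x)) return(data.frame())
  as.data.frame(lapply(x, unlist))
}

#' Load and validate a simulation configuration file
#'
#' YAML key/value file with nested sections \code{geometry}, \code{chem},
#' \code{sim} and a \code{schedule} list.  Unknown keys are rejected;
#' missing keys fall back to the built-in defaults (the standard
#' parameter tables).
#'
#' @param path YAML file
#' @return an \code{acto_config}
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  top_ok <- c("geometry", "G_uM", "formin_uM", "NMII_uM", "linker_uM",
              "n_seed", "seed_monomers", "t_total", "dt_chem",
              "snapshot_every", "seed", "chem", "sim", "schedule")
  bad <- setdiff(names(y), top_ok)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (nm in c("G_uM", "formin_uM", "NMII_uM", "linker_uM"))
    if (!is.null(y[[nm]]) && y[[nm]] < 0)
      stop("negative concentration: ", nm)
  if (!is.null(y$chem)) {
    badc <- setdiff(names(y$chem), names(chem_params()))
    if (length(badc)) stop("unknown chemistry keys: ",
                           paste(badc, collapse = ", "))
    if (any(unlist(y$chem) < 0)) stop("negative rate in config")
  }
  if (!is.null(y$sim)) {
    bads <- setdiff(names(y$sim), names(default_sim_config()))
    if (length(bads)) stop("unknown sim keys: ",
                           paste(bads, collapse = ", "))
  }
  geom <- if (is.null(y$geometry)) boundary_geometry() else {
    badg <- setdiff(names(y$geometry),
                    c("shape", "diameter_nm", "height_nm", "a0_nm"))
    if (length(badg)) stop("unknown geometry keys: ",
                           paste(badg, collapse = ", "))
    do.call(boundary_geometry, y$geometry)
  }
  args <- y[setdiff(names(y), "geometry")]
  args$geometry <- geom
  do.call(make_config, args)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run exactly: seed, full
#' parameter dump, simulated time span, and output files.
#'
#' @param cfg an \code{acto_config}
#' @param outputs character vector of output paths
#' @param path manifest file
#' @return invisibly the path
#' @export
write_manifest <- function(cfg, outputs, path) {
  m <- list(package = "actoring",
            version = as.character(utils::packageVersion("actoring")),
            seed = cfg$seed,
            t_total = cfg$t_total,
            dt_chem = cfg$dt_chem,
            geometry = unclass(cfg$geometry),
            chem = cfg$chem,
            schedule = cfg$schedule,
            outputs = outputs)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
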