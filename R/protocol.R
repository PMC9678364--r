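# Simulation protocol ----------------------------------------------------
#
# The mechanochemical iteration: chemistry evolves stochastically for a
# fixed window (10 ms), mechanics is then minimized, reaction rates are
# updated from the new force field, and the cycle repeats.  Scenario
# presets realize the experiment protocols: de novo assembly for 300 s,
# addition of motors and crosslinkers, treadmilling inhibition after ring
# formation, and motor perturbations of preformed rings.

#' Build a simulation configuration
#'
#' @param geometry a \code{\link{boundary_geometry}}
#' @param G_uM,formin_uM,NMII_uM,linker_uM initial soluble concentrations
#' @param n_seed,seed_monomers seed filament count and length (monomers)
#' @param t_total total simulated time, s
#' @param dt_chem chemistry window, s
#' @param snapshot_every snapshot cadence, s
#' @param seed RNG seed
#' @param chem named overrides for \code{\link{chem_params}} entries
#' @param mech,mechanochem optional full parameter sets
#' @param sim named overrides of the internal simulation configuration
#' @param schedule list of actions, each \code{list(time =, action =, ...)}
#'   with action one of "add_species" (species, conc_uM), "set_rate"
#'   (name, value), "latA" (level), "nmii_delta" (delta_uM), "label",
#'   "stop"
#' @return list of class \code{"acto_config"}
#' @export
make_config <- function(geometry = boundary_geometry(),
                        G_uM = 40, formin_uM = 0.1,
                        NMII_uM = 0, linker_uM = 0,
                        n_seed = 20L, seed_monomers = 30L,
                        t_total = 10, dt_chem = 0.01,
                        snapshot_every = 1, seed = 1L,
                        chem = list(), mech = mech_params(),
                        mechanochem = mechanochem_params(),
                        sim = list(), schedule = list()) {
  cfg <- as.list(environment())
  tms <- vapply(schedule, function(a) a$time, 0)
  if (is.unsorted(tms, strictly = FALSE))
    stop("schedule times must be nondecreasing")
  class(cfg) <- "acto_config"
  cfg
}

config_chem <- function(cfg) {
  cp <- chem_params()
  for (nm in names(cfg$chem)) {
    if (!nm %in% names(cp)) stop("unknown chemistry parameter: ", nm)
    cp[[nm]] <- cfg$chem[[nm]]
  }
  cp
}

init_state_from_config <- function(cfg) {
  state <- new_state(cfg$geometry, cfg$mech, config_chem(cfg),
                     cfg$mechanochem,
                     utils::modifyList(list(dt_chem = cfg$dt_chem,
                                            snapshot_every =
                                              cfg$snapshot_every),
                                       cfg$sim))
  V <- effective_volume_L(cfg$geometry)
  grid_scatter(state, "G", concentration_to_copies(cfg$G_uM, V))
  grid_scatter(state, "formin", concentration_to_copies(cfg$formin_uM, V))
  if (cfg$NMII_uM > 0)
    grid_scatter(state, "NMII", concentration_to_copies(cfg$NMII_uM, V))
  if (cfg$linker_uM > 0)
    grid_scatter(state, "linker", concentration_to_copies(cfg$linker_uM, V))
  for (k in seq_len(cfg$n_seed)) {
    p <- sample_position_in(state, 1L)
    u <- sample_orientation(cfg$geometry)
    sf <- straight_filament(p - u * cfg$seed_monomers * 2.7 / 2, u,
                            cfg$seed_monomers)
    add_filament(state, sf$verts, sf$nmono)
  }
  state
}

apply_action <- function(state, act) {
  V <- effective_volume_L(state$geom)
  switch(act$action,
    add_species = grid_scatter(state, act$species,
                               concentration_to_copies(act$conc_uM, V)),
    set_rate = { if (!act$name %in% names(state$cp))
      stop("unknown rate: ", act$name)
      state$cp[[act$name]] <- act$value },
    latA = apply_latA_rates(state, act$level),
    nmii_delta = apply_nmii_delta(state, act$delta_uM),
    label = label_all_monomers(state),
    stop = NULL,
    stop("unknown scheduled action: ", act$action))
  invisible(NULL)
}

apply_latA_rates <- function(state, level) {
  v <- latA_rate_set(level)
  for (nm in names(v)) state$cp[[nm]] <- v[[nm]]
  invisible(NULL)
}

latA_rate_set <- function(level) {
  switch(level,
         weak = list(k_on_BE = 11.6, k_off_BE = 2.1, k_off_PE = 2.4,
                     k_on_PE = 1.3),
         strong = list(k_on_BE = 3.48, k_off_BE = 11.2, k_off_PE = 4.8,
                       k_on_PE = 1.3),
         stop("unknown latA level: ", level))
}

apply_nmii_delta <- function(state, delta_uM) {
  V <- effective_volume_L(state$geom)
  n <- concentration_to_copies(abs(delta_uM), V)
  if (delta_uM >= 0) {
    grid_scatter(state, "NMII", n)
    return(invisible(NULL))
  }
  pool <- grid_total(state$grid, "NMII")
  bound <- which(state$motors$active)
  if (n > pool + length(bound))
    stop("NMII removal exceeds total motor count")
  take_pool <- min(n, pool)
  left <- take_pool
  for (c in sample(which(state$grid$counts[, "NMII"] > 0L))) {
    if (left == 0L) break
    k <- min(left, state$grid$counts[c, "NMII"])
    grid_add(state, c, "NMII", -k)
    left <- left - k
  }
  n_force <- n - take_pool
  if (n_force > 0L) {
    for (id in sample(bound, n_force)) {
      release_element(state, "motor", id)   # removed from the system
      state$counters[["forced_unbind"]] <-
        state$counters[["forced_unbind"]] + 1
    }
  }
  invisible(NULL)
}

#' Run the mechanochemical protocol
#'
#' Iterates chemistry windows, energy minimization and force-dependent
#' rate updates until \code{t_total} (or a scheduled stop), taking
#' snapshots at the configured cadence.  Fully reproducible for a fixed
#' seed.
#'
#' @param cfg an \code{acto_config} from \code{\link{make_config}}
#' @param quiet suppress progress messages
#' @return an \code{"acto_trajectory"}: list with \code{snapshots},
#'   \code{config}, \code{status}, and the final \code{state}
#' @export
run_simulation <- function(cfg, quiet = TRUE) {
  set.seed(cfg$seed)
  state <- init_state_from_config(cfg)
  mech <- minimize_state(state)
  mods <- compute_rate_mods(state, mech)
  snaps <- list(take_snapshot(state))
  next_snap <- cfg$snapshot_every
  sched <- cfg$schedule
  si <- 1L
  status <- "completed"
  nw <- ceiling(cfg$t_total / cfg$dt_chem)
  for (w in seq_len(nw)) {
    t_end <- min(w * cfg$dt_chem, cfg$t_total)
    while (si <= length(sched) && sched[[si]]$time <= state$time + 1e-12) {
      if (sched[[si]]$action == "stop") { status <- "stopped"; break }
      apply_action(state, sched[[si]])
      si <- si + 1L
    }
    if (status == "stopped") break
    chem <- run_chemistry_window(state, t_end, mods)
    if (chem$events > 0L || !isTRUE(mech$converged)) {
      mech <- minimize_state(state)
      mods <- compute_rate_mods(state, mech)
    }
    if (chem$frozen && mech$converged) { status <- "frozen"; break }
    if (state$time >= next_snap - 1e-9) {
      snaps[[length(snaps) + 1L]] <- take_snapshot(state)
      next_snap <- next_snap + cfg$snapshot_every
      if (!quiet) message(sprintf("t=%.0f s: %d filaments, %d events",
                                  state$time, length(fil_ids(state)),
                                  chem$events))
    }
  }
  traj <- list(snapshots = snaps, config = cfg, status = status,
               state = state)
  class(traj) <- "acto_trajectory"
  traj
}

#' Treadmilling-rate scaling of the kinetic parameter set
#'
#' Scales the barbed-end polymerization and pointed-end depolymerization
#' constants jointly by \code{s} relative to the in vitro baseline
#' (k_on_BE = 11.6 (uM s)^-1, k_off_PE = 0.8 s^-1), the same handle used
#' to emulate treadmilling promoters (formin, ADF/cofilin).  \code{s = 1}
#' gives a mean treadmilling rate near 0.6 s^-1 and \code{s = 3} near
#' 2.2 s^-1 in free filaments.
#'
#' @param s scale factor (>= 0)
#' @return named list of chemistry overrides
#' @export
treadmilling_scale <- function(s) {
  list(k_on_BE = 11.6 * s, k_off_PE = 0.8 * s, k_off_BE = 1.4,
       k_on_PE = 1.3)
}

#' Predicted free-filament treadmilling rate at kinetic steady state
#'
#' At steady state the G-actin concentration settles where net barbed-end
#' growth balances net pointed-end loss:
#' \eqn{G_{ss} = (k^{BE}_{off}+k^{PE}_{off})/(k^{BE}_{on}+k^{PE}_{on})},
#' and the treadmilling rate is \eqn{k^{BE}_{on} G_{ss} - k^{BE}_{off}}.
#'
#' @param cp a \code{\link{chem_params}}
#' @return list with \code{G_ss} (uM) and \code{r_TM} (monomers/s)
#' @export
predict_treadmilling <- function(cp) {
  G_ss <- (cp$k_off_BE + cp$k_off_PE) / (cp$k_on_BE + cp$k_on_PE)
  list(G_ss = G_ss, r_TM = cp$k_on_BE * G_ss - cp$k_off_BE)
}

#' Apply a treadmilling-inhibition (Latrunculin A-like) perturbation
#'
#' Adds (or replaces) a scheduled change of the assembly kinetics: weak
#' inhibition sets k_on_BE = 11.6 (uM s)^-1, k_off_BE = 2.1 s^-1,
#' k_off_PE = 2.4 s^-1; strong inhibition 3.48, 11.2 and 4.8; the
#' pointed-end polymerization constant stays 1.3 (uM s)^-1.  Idempotent.
#'
#' @param cfg an \code{acto_config}
#' @param level "weak" or "strong"
#' @param time application time, s (after ring formation in the standard
#'   protocol)
#' @return the modified config
#' @export
apply_latA <- function(cfg, level = c("weak", "strong"), time = 800) {
  level <- match.arg(level)
  latA_rate_set(level)  # validates
  keep <- vapply(cfg$schedule, function(a) a$action != "latA", TRUE)
  cfg$schedule <- c(cfg$schedule[keep],
                    list(list(time = time, action = "latA", level = level)))
  ord <- order(vapply(cfg$schedule, function(a) a$time, 0))
  cfg$schedule <- cfg$schedule[ord]
  cfg
}

#' Schedule a motor-concentration perturbation
#'
#' Positive \code{delta_uM} adds diffusing motor copies (Calyculin A-like
#' enhancement); negative removes them, taking from the diffusing pool
#' first and forcibly unbinding random bound motors if needed
#' (Y-27632-like inhibition).
#'
#' @param cfg an \code{acto_config}
#' @param delta_uM signed concentration change, uM
#' @param time application time, s
#' @return the modified config
#' @export
apply_nmii_perturbation <- function(cfg, delta_uM, time = 0) {
  if (delta_uM == 0) return(cfg)
  cfg$schedule <- c(cfg$schedule,
                    list(list(time = time, action = "nmii_delta",
                              delta_uM = delta_uM)))
  ord <- order(vapply(cfg$schedule, function(a) a$time, 0))
  cfg$schedule <- cfg$schedule[ord]
  cfg
}

#' Initialize a preformed ring-like network
#'
#' Places filaments tangentially inside an annulus adjacent to the
#' effective boundary, with the polymerized monomer budget matching the
#' requested actin concentration, then binds motors and linkers wherever
#' site pairs fall inside the admissible span windows.  Used by the
#' motor-perturbation scenarios, which start from an established ring
#' instead of growing one de novo.
#'
#' @param cfg an \code{acto_config}
#' @param annulus_nm annulus (ring) thickness, nm (> 0)
#' @param fil_monomers monomers per placed filament
#' @param polymerized_frac fraction of total actin placed in filaments
#' @return an initialized \code{acto_state}
#' @export
init_preformed_ring <- function(cfg, annulus_nm = 300, fil_monomers = 90L,
                                polymerized_frac = 0.85) {
  if (annulus_nm <= 0) stop("annulus thickness must be positive")
  geom <- cfg$geometry
  if (geom$shape != "oblate") stop("preformed rings require oblate geometry")
  state <- new_state(geom, cfg$mech, config_chem(cfg), cfg$mechanochem,
                     utils::modifyList(list(dt_chem = cfg$dt_chem),
                                       cfg$sim))
  V <- effective_volume_L(geom)
  n_total <- concentration_to_copies(cfg$G_uM, V)
  n_pol <- round(polymerized_frac * n_total)
  n_fil <- max(1L, floor(n_pol / fil_monomers))
  fil_len <- fil_monomers * 2.7
  r_out <- geom$R_eff - 20
  r_in <- max(50, r_out - annulus_nm)
  for (k in seq_len(n_fil)) {
    r <- sqrt(stats::runif(1, r_in^2, r_out^2))
    th <- stats::runif(1, 0, 2 * pi)
    c0 <- c(r * cos(th), r * sin(th),
            stats::runif(1, -geom$half_height_eff + 10,
                         geom$half_height_eff - 10))
    u <- c(-sin(th), cos(th), 0)          # tangential
    if (stats::runif(1) < 0.5) u <- -u
    # keep the filament inside the disk: chord must fit at this radius
    sf <- straight_filament(c0 - u * fil_len / 2, u, fil_monomers)
    rr <- sqrt(sf$verts[, 1]^2 + sf$verts[, 2]^2)
    if (max(rr) > geom$R_eff - 5) {
      # bend placement inward by shrinking radius
      sc <- (geom$R_eff - 10) / max(rr)
      sf$verts[, 1:2] <- sf$verts[, 1:2] * sc
    }
    add_filament(state, sf$verts, sf$nmono)
  }
  grid_scatter(state, "G", n_total - n_fil * fil_monomers)
  grid_scatter(state, "formin", concentration_to_copies(cfg$formin_uM, V))
  n_nmii <- concentration_to_copies(cfg$NMII_uM, V)
  n_link <- concentration_to_copies(cfg$linker_uM, V)
  grid_scatter(state, "NMII", n_nmii)
  grid_scatter(state, "linker", n_link)
  # bind what geometry permits
  for (sp in c("motor", "linker")) {
    avail <- grid_total(state$grid, if (sp == "motor") "NMII" else "linker")
    if (!avail) next
    prs <- find_binding_pairs(state, sp)
    if (!nrow(prs)) next
    take <- sample.int(nrow(prs), min(avail, nrow(prs)))
    for (r in take) {
      pr <- prs[r, ]
      ok <- tryCatch({
        # skip pairs whose sites were occupied by an earlier pick
        fa <- state$fil[[pr$fa]]; fb <- state$fil[[pr$fb]]
        occ <- if (sp == "motor") "m_occ" else "l_occ"
        fa[[occ]][pr$ca, pr$sa] == 0L && fb[[occ]][pr$cb, pr$sb] == 0L
      }, error = function(e) FALSE)
      if (!ok) next
      if (sp == "motor") bind_motor(state, pr) else bind_linker(state, pr)
      avail <- avail - 1L
      if (!avail) break
    }
  }
  v <- validate_state(state)
  if (length(v)) stop("preformed ring failed validation: ", v[1])
  state
}

#' Run a simulation from an explicit initial state
#'
#' Same loop as \code{\link{run_simulation}} but starting from a prepared
#' state (e.g. \code{\link{init_preformed_ring}}).
#'
#' @param state an initialized \code{acto_state}
#' @param cfg an \code{acto_config} (schedule, times, seed)
#' @return an \code{"acto_trajectory"}
#' @export
run_from_state <- function(state, cfg) {
  set.seed(cfg$seed)
  mech <- minimize_state(state)
  mods <- compute_rate_mods(state, mech)
  snaps <- list(take_snapshot(state))
  next_snap <- state$time + cfg$snapshot_every
  sched <- cfg$schedule
  si <- 1L
  status <- "completed"
  t0 <- state$time
  nw <- ceiling((cfg$t_total - t0) / cfg$dt_chem)
  for (w in seq_len(nw)) {
    t_end <- min(t0 + w * cfg$dt_chem, cfg$t_total)
    while (si <= length(sched) && sched[[si]]$time <= state$time + 1e-12) {
      if (sched[[si]]$action == "stop") { status <- "stopped"; break }
      apply_action(state, sched[[si]])
      si <- si + 1L
    }
    if (status == "stopped") break
    chem <- run_chemistry_window(state, t_end, mods)
    if (chem$events > 0L || !isTRUE(mech$converged)) {
      mech <- minimize_state(state)
      mods <- compute_rate_mods(state, mech)
    }
    if (chem$frozen && mech$converged) { status <- "frozen"; break }
    if (state$time >= next_snap - 1e-9) {
      snaps[[length(snaps) + 1L]] <- take_snapshot(state)
      next_snap <- next_snap + cfg$snapshot_every
    }
  }
  traj <- list(snapshots = snaps, config = cfg, status = status,
               state = state)
  class(traj) <- "acto_trajectory"
  traj
}

#' Named scenario presets
#'
#' Fully determined configurations for the standard experiments: de novo
#' assembly at slow/intermediate/fast treadmilling with motors and
#' crosslinkers added at 300 s (\code{baseline_cluster},
#' \code{baseline_mixed}, \code{baseline_ring}), treadmilling inhibition
#' of an established ring (\code{latA_weak}, \code{latA_strong}), motor
#' perturbations of a preformed dense ring (\code{calyA},
#' \code{y27632}), and a spherical cortex (\code{sphere_cortex}).
#' \code{scaled_down = TRUE} shrinks the disk to 2 um effective diameter
#' (concentrations preserved) for desk-scale runs.
#'
#' @param name preset name
#' @param seed RNG seed
#' @param scaled_down use the 2 um desk-scale disk
#' @param t_total override the preset duration, s
#' @return an \code{acto_config}
#' @export
scenario <- function(name = c("baseline_cluster", "baseline_mixed",
                              "baseline_ring", "latA_weak", "latA_strong",
                              "calyA", "y27632", "preformed_ring",
                              "sphere_cortex"),
                     seed = 1L, scaled_down = FALSE, t_total = NULL) {
  name <- match.arg(name)
  geom <- if (scaled_down)
    boundary_geometry("oblate", diameter_nm = 2200, height_nm = 400)
  else boundary_geometry("oblate", diameter_nm = 4000, height_nm = 400)
  # at desk scale the nucleator pool is small, so seed filaments carry the
  # filament number density; 60 seeds keep the steady-state mean filament
  # length near one fifth of the disk diameter, as in the full geometry.
  # The desk-scale mode also caps the per-window minimizer evaluations at
  # 200 (relaxation continues across windows); the 10 ms chemistry window
  # is kept.
  n_seed <- if (scaled_down) 60L else 20L
  dt <- 0.01
  sim_over <- if (scaled_down) list(fire_maxit = 200L) else list()
  motor_sched <- list(
    list(time = 300, action = "add_species", species = "NMII",
         conc_uM = 0.06),
    list(time = 300, action = "add_species", species = "linker",
         conc_uM = 4))
  tm <- function(s) utils::modifyList(treadmilling_scale(s),
                                      list(k_destruction =
                                             if (s > 2) 1.9 else 1.0))
  base <- function(s, tt)
    make_config(geometry = geom, G_uM = 40, formin_uM = 0.1,
                n_seed = n_seed, t_total = tt, seed = seed,
                dt_chem = dt, sim = sim_over,
                chem = tm(s), schedule = motor_sched)
  cfg <- switch(name,
    baseline_cluster = base(1, 800),
    baseline_mixed = base(1.6, 800),
    baseline_ring = base(3, 800),
    latA_weak = apply_latA(base(3, 1200), "weak", time = 800),
    latA_strong = apply_latA(base(3, 1200), "strong", time = 800),
    calyA = apply_nmii_perturbation(
      make_config(geometry = geom, G_uM = 80, formin_uM = 0.1,
                  NMII_uM = 0.18, linker_uM = 4, t_total = 300,
                  seed = seed, dt_chem = dt, sim = sim_over,
                  chem = tm(3)),
      delta_uM = 0.06, time = 0),
    y27632 = apply_nmii_perturbation(
      make_config(geometry = geom, G_uM = 80, formin_uM = 0.1,
                  NMII_uM = 0.18, linker_uM = 4, t_total = 300,
                  seed = seed, dt_chem = dt, sim = sim_over,
                  chem = tm(3)),
      delta_uM = -0.04, time = 0),
    preformed_ring =
      make_config(geometry = geom, G_uM = 80, formin_uM = 0.1,
                  NMII_uM = 0.18, linker_uM = 4, t_total = 300,
                  seed = seed, dt_chem = dt, sim = sim_over,
                  chem = tm(3)),
    sphere_cortex =
      make_config(geometry = boundary_geometry("sphere",
                                               diameter_nm =
                                                 if (scaled_down) 2200
                                               else 4000),
                  G_uM = 40, formin_uM = 0.1, n_seed = n_seed,
                  t_total = 800, seed = seed, dt_chem = dt,
                  sim = sim_over, chem = tm(3),
                  schedule = motor_sched))
  if (!is.null(t_total)) cfg$t_total <- t_total
  cfg
}

#' Phase scan over treadmilling rate and motor concentration
#'
#' Runs the standard assembly-then-motors protocol on a grid of
#' treadmilling scales and motor concentrations and returns the
#' steady-state R_median matrix (rows = treadmilling scales, columns =
#' motor concentrations).  Intended for offline batch use: each grid cell
#' is a full simulation.
#'
#' @param tm_scales numeric vector of treadmilling scale factors (see
#'   \code{\link{treadmilling_scale}})
#' @param nmii_uM numeric vector of motor concentrations, uM
#' @param seed RNG seed (each cell derives its own sub-seed)
#' @param scaled_down use the 2 um desk-scale disk
#' @param t_total total simulated time per cell, s
#' @param t_motors motor/crosslinker addition time, s
#' @param tail_s steady-state averaging window, s
#' @return list with \code{r_median} matrix and \code{u_mech} matrix
#' @export
phase_scan <- function(tm_scales = c(1, 1.6, 3),
                       nmii_uM = c(0.02, 0.06, 0.2),
                       seed = 1L, scaled_down = TRUE,
                       t_total = 400, t_motors = 100, tail_s = 60) {
  rmed <- umech <- matrix(NA_real_, length(tm_scales), length(nmii_uM),
                          dimnames = list(paste0("tm", tm_scales),
                                          paste0("nmii", nmii_uM)))
  cell <- 0L
  for (i in seq_along(tm_scales)) for (j in seq_along(nmii_uM)) {
    cell <- cell + 1L
    cfg <- scenario(if (tm_scales[i] > 2) "baseline_ring" else
      "baseline_cluster", seed = seed + 1000L * cell,
      scaled_down = scaled_down, t_total = t_total)
    cfg$chem <- utils::modifyList(cfg$chem, treadmilling_scale(tm_scales[i]))
    cfg$schedule <- list(
      list(time = t_motors, action = "add_species", species = "NMII",
           conc_uM = nmii_uM[j]),
      list(time = t_motors, action = "add_species", species = "linker",
           conc_uM = 4))
    tr <- run_simulation(cfg)
    rm <- r_median_series(tr)
    sel <- rm$time >= max(rm$time) - tail_s
    rmed[i, j] <- mean(rm$r_median[sel])
    umech[i, j] <- mechanical_energy_series(tr,
                                            tail_window = tail_s)$steady_mean
  }
  list(r_median = rmed, u_mech = umech)
}
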