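# Network state ---------------------------------------------------------
#
# The mutable simulation state is an environment (reference semantics keep
# the chemistry event loop cheap).  Filaments are ordered chains of
# cylinders, stored per filament as a (m+1) x 3 vertex matrix (row 1 =
# pointed end) plus an integer monomer count per cylinder.  Motors and
# linkers are stored in parallel vectors indexed by slot id; unbound slots
# are recycled.  Soluble species live on a compartment grid (a single
# well-mixed compartment unless the configured compartment edge subdivides
# the volume).

SPECIES <- c("G", "formin", "intermediate", "NMII", "linker")

default_sim_config <- function() {
  list(
    site_fractions = c(1, 3, 5, 7) / 8,  # binding sites per cylinder
    motor_span = c(175, 225),            # admissible pair separation, nm
    linker_span = c(30, 40),
    compartment_edge_nm = 500,
    use_grid = FALSE,                    # single well-mixed compartment
    excluded_volume = FALSE,
    ev_cutoff_nm = 100,
    minimizer = "lbfgs",                 # "lbfgs" or "fire"
    fire_tol = 1,                        # pN, max force component
    fire_maxit = 5000,
    fire_dt0 = 2e-3,                     # FIRE initial/maximal timesteps
    fire_dtmax = 2e-2,
    fire_maxstep = 5,                    # nm, per-coordinate step clamp
    pair_refresh = 10L,                  # windows between pair searches
    dt_chem = 0.01,                      # chemistry window, s
    snapshot_every = 1                   # s
  )
}

#' Create an empty network state
#'
#' @param geom a \code{\link{boundary_geometry}}
#' @param mp,cp,mcp parameter sets from \code{\link{mech_params}},
#'   \code{\link{chem_params}}, \code{\link{mechanochem_params}}
#' @param config optional list overriding entries of the internal
#'   simulation configuration (binding-site fractions, spans, compartment
#'   edge, excluded-volume switch, minimizer tolerances, chemistry window)
#' @return an environment of class \code{"acto_state"}
#' @export
new_state <- function(geom = boundary_geometry(),
                      mp = mech_params(), cp = chem_params(),
                      mcp = mechanochem_params(), config = list()) {
  cfg <- utils::modifyList(default_sim_config(), config)
  s <- new.env(parent = emptyenv())
  s$geom <- geom; s$mp <- mp; s$cp <- cp; s$mcp <- mcp; s$cfg <- cfg
  s$time <- 0
  s$topo <- 0L            # topology stamp; bumped by structural changes
  s$fil <- list()
  s$motors <- new.env(parent = emptyenv())
  s$motors$active <- logical(0)
  for (f in c("fa", "ca", "sa", "fb", "cb", "sb"))
    s$motors[[f]] <- integer(0)
  s$motors$l0 <- numeric(0); s$motors$n_heads <- integer(0)
  s$linkers <- new.env(parent = emptyenv())
  s$linkers$active <- logical(0)
  for (f in c("fa", "ca", "sa", "fb", "cb", "sb"))
    s$linkers[[f]] <- integer(0)
  s$linkers$l0 <- numeric(0)
  s$grid <- make_grid(geom, cfg)
  s$counters <- c(be_add = 0, be_rem = 0, pe_add = 0, pe_rem = 0,
                  nuc = 0, destr = 0, forced_unbind = 0)
  s$label <- list(active = FALSE, n0 = 0)
  s$energy <- NULL
  class(s) <- "acto_state"
  s
}

# Compartment grid (xy only; thin oblate systems use one z layer).
make_grid <- function(geom, cfg) {
  if (!isTRUE(cfg$use_grid)) {
    g <- list(edge = NA_real_, nx = 1L, ny = 1L, n = 1L,
              valid = TRUE, origin = c(0, 0),
              counts = matrix(0L, 1, length(SPECIES),
                              dimnames = list(NULL, SPECIES)),
              nbr = list(integer(0)))
    return(g)
  }
  edge <- cfg$compartment_edge_nm
  R <- geom$diameter_nm / 2
  nx <- max(1L, as.integer(ceiling(2 * R / edge)))
  ny <- nx
  origin <- c(-nx * edge / 2, -ny * edge / 2)
  n <- nx * ny
  cx <- origin[1] + (rep(seq_len(nx), ny) - 0.5) * edge
  cy <- origin[2] + (rep(seq_len(ny), each = nx) - 0.5) * edge
  valid <- sqrt(cx^2 + cy^2) <= R
  nbr <- vector("list", n)
  for (k in seq_len(n)) {
    i <- (k - 1L) %% nx + 1L; j <- (k - 1L) %/% nx + 1L
    cand <- c(if (i > 1) k - 1L, if (i < nx) k + 1L,
              if (j > 1) k - nx, if (j < ny) k + nx)
    nbr[[k]] <- cand[valid[cand]]
  }
  list(edge = edge, nx = nx, ny = ny, n = n, valid = valid,
       origin = origin,
       counts = matrix(0L, n, length(SPECIES),
                       dimnames = list(NULL, SPECIES)),
       nbr = nbr)
}

# compartment index of an xy position (clamped into the grid)
comp_of <- function(grid, x, y) {
  if (grid$n == 1L) return(1L)
  i <- pmin(grid$nx, pmax(1L, as.integer(floor((x - grid$origin[1]) /
                                                 grid$edge)) + 1L))
  j <- pmin(grid$ny, pmax(1L, as.integer(floor((y - grid$origin[2]) /
                                                 grid$edge)) + 1L))
  (j - 1L) * grid$nx + i
}

grid_total <- function(grid, species) sum(grid$counts[, species])

grid_add <- function(state, comp, species, n) {
  state$grid$counts[comp, species] <- state$grid$counts[comp, species] + n
  if (state$grid$counts[comp, species] < 0)
    stop("negative copy number for ", species)
  invisible(NULL)
}

# distribute n copies over valid compartments, uniformly at random
grid_scatter <- function(state, species, n) {
  g <- state$grid
  if (g$n == 1L) { grid_add(state, 1L, species, n); return(invisible(NULL)) }
  vcomp <- which(g$valid)
  tab <- tabulate(sample(vcomp, n, replace = TRUE), nbins = g$n)
  state$grid$counts[, species] <- state$grid$counts[, species] +
    as.integer(tab)
  invisible(NULL)
}

# Filaments --------------------------------------------------------------

new_filament <- function(verts, nmono, barbed = "BE") {
  m <- length(nmono)
  stopifnot(nrow(verts) == m + 1L, all(nmono >= 1L), all(nmono <= 40L))
  list(verts = verts, nmono = as.integer(nmono), barbed = barbed,
       m_occ = matrix(0L, m, 4L), l_occ = matrix(0L, m, 4L),
       lab = c(below = 0L, lab = 0L, above = 0L))
}

add_filament <- function(state, verts, nmono, barbed = "BE") {
  state$fil[[length(state$fil) + 1L]] <- new_filament(verts, nmono, barbed)
  state$topo <- state$topo + 1L
  length(state$fil)
}

fil_ids <- function(state) {
  which(!vapply(state$fil, is.null, TRUE))
}

fil_monomers <- function(f) sum(f$nmono)

# a straight filament with n monomers starting at `base` along unit `u`
straight_filament <- function(base, u, n_monomers, monomer_size = 2.7,
                              max_per_cyl = 40L) {
  n <- as.integer(n_monomers)
  ncyl <- max(1L, ceiling(n / max_per_cyl))
  nmono <- rep(max_per_cyl, ncyl)
  nmono[ncyl] <- n - max_per_cyl * (ncyl - 1L)
  if (nmono[ncyl] == 0L) { nmono <- nmono[-ncyl]; ncyl <- ncyl - 1L }
  lens <- cumsum(c(0, nmono * monomer_size))
  verts <- cbind(base[1] + lens * u[1], base[2] + lens * u[2],
                 base[3] + lens * u[3])
  list(verts = verts, nmono = as.integer(nmono))
}

# position of binding site `si` on cylinder `ci` of filament f
site_position <- function(f, ci, si, fractions = c(1, 3, 5, 7) / 8) {
  a <- f$verts[ci, ]; b <- f$verts[ci + 1L, ]
  a + fractions[si] * (b - a)
}

# per-monomer positions for a snapshot/state filament list (monomers spread
# uniformly along each cylinder axis)
monomer_positions <- function(filaments) {
  out <- vector("list", length(filaments))
  for (k in seq_along(filaments)) {
    f <- filaments[[k]]
    if (is.null(f)) next
    m <- length(f$nmono)
    a <- f$verts[seq_len(m), , drop = FALSE]
    b <- f$verts[seq_len(m) + 1L, , drop = FALSE]
    idx <- rep.int(seq_len(m), f$nmono)
    frac <- unlist(lapply(f$nmono, function(n) (seq_len(n) - 0.5) / n),
                   use.names = FALSE)
    out[[k]] <- a[idx, , drop = FALSE] +
      frac * (b[idx, , drop = FALSE] - a[idx, , drop = FALSE])
  }
  do.call(rbind, out)
}

# Motors / linkers -------------------------------------------------------

alloc_slot <- function(tab) {
  free <- which(!tab$active)
  if (length(free)) free[1L] else length(tab$active) + 1L
}

bind_element <- function(state, kind, fa, ca, sa, fb, cb, sb, l0,
                         n_heads = NA_integer_) {
  tab <- if (kind == "motor") state$motors else state$linkers
  id <- alloc_slot(tab)
  tab$active[id] <- TRUE
  tab$fa[id] <- fa; tab$ca[id] <- ca; tab$sa[id] <- sa
  tab$fb[id] <- fb; tab$cb[id] <- cb; tab$sb[id] <- sb
  tab$l0[id] <- l0
  if (kind == "motor") tab$n_heads[id] <- n_heads
  occ <- if (kind == "motor") "m_occ" else "l_occ"
  state$fil[[fa]][[occ]][ca, sa] <- id
  state$fil[[fb]][[occ]][cb, sb] <- id
  state$topo <- state$topo + 1L
  id
}

release_element <- function(state, kind, id) {
  tab <- if (kind == "motor") state$motors else state$linkers
  occ <- if (kind == "motor") "m_occ" else "l_occ"
  for (side in c("a", "b")) {
    fi <- tab[[paste0("f", side)]][id]
    ci <- tab[[paste0("c", side)]][id]
    si <- tab[[paste0("s", side)]][id]
    if (!is.null(state$fil[[fi]]) &&
        ci <= nrow(state$fil[[fi]][[occ]]) &&
        state$fil[[fi]][[occ]][ci, si] == id)
      state$fil[[fi]][[occ]][ci, si] <- 0L
  }
  tab$active[id] <- FALSE
  state$topo <- state$topo + 1L
  invisible(NULL)
}

element_length <- function(state, kind, id) {
  tab <- if (kind == "motor") state$motors else state$linkers
  pa <- site_position(state$fil[[tab$fa[id]]], tab$ca[id], tab$sa[id],
                      state$cfg$site_fractions)
  pb <- site_position(state$fil[[tab$fb[id]]], tab$cb[id], tab$sb[id],
                      state$cfg$site_fractions)
  sqrt(sum((pb - pa)^2))
}

# FRAP-style labeling ----------------------------------------------------
# Monomers polymerized at label time are marked; barbed-end additions pile
# on the "above" side, pointed-end additions on the "below" side, and the
# labeled block is consumed from whichever side reaches it first.

label_all_monomers <- function(state) {
  tot <- 0L
  for (i in fil_ids(state)) {
    n <- fil_monomers(state$fil[[i]])
    state$fil[[i]]$lab <- c(below = 0L, lab = n, above = 0L)
    tot <- tot + n
  }
  state$label <- list(active = TRUE, n0 = tot, t0 = state$time)
  invisible(tot)
}

labeled_count <- function(state) {
  sum(vapply(fil_ids(state),
             function(i) state$fil[[i]]$lab[["lab"]], 0L))
}

lab_add <- function(f, end) {  # end: "BE" (above) or "PE" (below)
  if (end == "BE") f$lab[["above"]] <- f$lab[["above"]] + 1L
  else f$lab[["below"]] <- f$lab[["below"]] + 1L
  f
}

lab_remove <- function(f, end) {
  if (end == "BE") {
    if (f$lab[["above"]] > 0L) f$lab[["above"]] <- f$lab[["above"]] - 1L
    else if (f$lab[["lab"]] > 0L) f$lab[["lab"]] <- f$lab[["lab"]] - 1L
    else f$lab[["below"]] <- max(0L, f$lab[["below"]] - 1L)
  } else {
    if (f$lab[["below"]] > 0L) f$lab[["below"]] <- f$lab[["below"]] - 1L
    else if (f$lab[["lab"]] > 0L) f$lab[["lab"]] <- f$lab[["lab"]] - 1L
    else f$lab[["above"]] <- max(0L, f$lab[["above"]] - 1L)
  }
  f
}

# Snapshots --------------------------------------------------------------

#' Take a snapshot of the current network state
#'
#' A snapshot is a plain (immutable) list carrying everything the analysis
#' stage consumes: filament geometry and monomer counts, motor/linker site
#' tables, compartment copy numbers, cumulative end-event counters, the
#' energy breakdown of the last minimization, and the confinement geometry.
#'
#' @param state an \code{acto_state}
#' @return a list of class \code{"acto_snapshot"}
#' @export
take_snapshot <- function(state) {
  ids <- fil_ids(state)
  fil <- lapply(ids, function(i) {
    f <- state$fil[[i]]
    list(verts = f$verts, nmono = f$nmono, barbed = f$barbed)
  })
  mot <- state$motors; lnk <- state$linkers
  mi <- which(mot$active); li <- which(lnk$active)
  snap <- list(
    time = state$time,
    filaments = fil,
    n_filaments = length(ids),
    motors = data.frame(fa = match(mot$fa[mi], ids),
                        ca = mot$ca[mi], sa = mot$sa[mi],
                        fb = match(mot$fb[mi], ids),
                        cb = mot$cb[mi], sb = mot$sb[mi],
                        l0 = mot$l0[mi], n_heads = mot$n_heads[mi]),
    linkers = data.frame(fa = match(lnk$fa[li], ids),
                         ca = lnk$ca[li], sa = lnk$sa[li],
                         fb = match(lnk$fb[li], ids),
                         cb = lnk$cb[li], sb = lnk$sb[li],
                         l0 = lnk$l0[li]),
    grid_counts = state$grid$counts,
    counters = state$counters,
    energy = state$energy,
    labeled = if (state$label$active)
      c(n = labeled_count(state), n0 = state$label$n0) else NULL,
    geom = state$geom)
  class(snap) <- "acto_snapshot"
  snap
}

#' Validate network-state invariants
#'
#' Checks every structural invariant of the state: cylinder monomer counts
#' in 1..40 with only terminal cylinders partial, filaments of at least two
#' monomers, consecutive cylinders sharing endpoints, motors/linkers
#' spanning two distinct filaments with head counts in range, and
#' nonnegative compartment copy numbers.
#'
#' @param state an \code{acto_state}
#' @return character vector of violations (empty if the state is valid)
#' @export
validate_state <- function(state) {
  v <- character(0)
  for (i in fil_ids(state)) {
    f <- state$fil[[i]]
    m <- length(f$nmono)
    if (any(f$nmono < 1L) || any(f$nmono > 40L))
      v <- c(v, sprintf("filament %d: cylinder monomer count outside 1..40", i))
    if (m > 2L && any(f$nmono[2:(m - 1L)] != 40L))
      v <- c(v, sprintf("filament %d: interior cylinder not full", i))
    if (fil_monomers(f) < 2L)
      v <- c(v, sprintf("filament %d: fewer than 2 monomers", i))
    if (nrow(f$verts) != m + 1L)
      v <- c(v, sprintf("filament %d: vertex/cylinder count mismatch", i))
    seg <- f$verts[-1L, , drop = FALSE] - f$verts[-(m + 1L), , drop = FALSE]
    if (any(sqrt(rowSums(seg^2)) <= 0))
      v <- c(v, sprintf("filament %d: zero-length cylinder", i))
    if (!f$barbed %in% c("BE", "FBE"))
      v <- c(v, sprintf("filament %d: invalid barbed state", i))
  }
  for (kind in c("motor", "linker")) {
    tab <- if (kind == "motor") state$motors else state$linkers
    for (id in which(tab$active)) {
      if (tab$fa[id] == tab$fb[id])
        v <- c(v, sprintf("%s %d: both sites on one filament", kind, id))
      if (is.null(state$fil[[tab$fa[id]]]) || is.null(state$fil[[tab$fb[id]]]))
        v <- c(v, sprintf("%s %d: site on destroyed filament", kind, id))
      if (kind == "motor" &&
          (tab$n_heads[id] < state$mcp$n_heads_range[1] ||
           tab$n_heads[id] > state$mcp$n_heads_range[2]))
        v <- c(v, sprintf("motor %d: head count outside range", id))
    }
  }
  if (any(state$grid$counts < 0))
    v <- c(v, "negative compartment copy number")
  v
}

#' Total actin monomers in all phases
#'
#' Soluble G-actin plus nucleation intermediates (one G-actin each) plus
#' all polymerized monomers; conserved exactly by every reaction channel.
#' @param state an \code{acto_state}
#' @return named vector with components and the total
#' @export
actin_inventory <- function(state) {
  pol <- sum(vapply(fil_ids(state),
                    function(i) fil_monomers(state$fil[[i]]), 0L))
  g <- grid_total(state$grid, "G")
  int <- grid_total(state$grid, "intermediate")
  c(G = g, intermediate = int, F = pol, total = g + int + pol)
}

#' Total formin in all phases (free + intermediate + filament-bound)
#' @param state an \code{acto_state}
#' @return named vector with components and the total
#' @export
formin_inventory <- function(state) {
  free <- grid_total(state$grid, "formin")
  int <- grid_total(state$grid, "intermediate")
  fbe <- sum(vapply(fil_ids(state),
                    function(i) state$fil[[i]]$barbed == "FBE", TRUE))
  c(free = free, intermediate = int, bound = fbe, total = free + int + fbe)
}
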