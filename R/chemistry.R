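# Chemistry event primitives --------------------------------------------
#
# Each reaction channel of the stochastic engine mutates the state through
# one of the functions below.  They are exported individually so every
# channel can be unit-tested in isolation; the Next Reaction Method engine
# (engine.R) drives them.

comp_of_point <- function(state, p) comp_of(state$grid, p[1], p[2])

comp_volume_L <- function(state) {
  g <- state$grid
  if (g$n == 1L) return(effective_volume_L(state$geom))
  g$edge^2 * (2 * state$geom$half_height_eff) * 1e-24
}

conc_uM_comp <- function(state, comp, species) {
  copies_to_concentration(state$grid$counts[comp, species],
                          comp_volume_L(state))
}

conc_uM_total <- function(state, species) {
  copies_to_concentration(grid_total(state$grid, species),
                          effective_volume_L(state$geom))
}

#' Transfer one molecule between neighboring compartments
#' @param state an \code{acto_state} (modified in place)
#' @param species one of "G", "formin", "intermediate", "NMII", "linker"
#' @param from,to compartment indices (must be neighbors on the grid)
#' @return invisibly the updated counts of the two compartments
#' @export
diffusion_hop <- function(state, species, from, to) {
  g <- state$grid
  if (g$n > 1L && !(to %in% g$nbr[[from]]))
    stop("compartments are not neighbors")
  if (g$counts[from, species] < 1L)
    stop("hop from empty compartment")
  grid_add(state, from, species, -1L)
  grid_add(state, to, species, +1L)
  invisible(state$grid$counts[c(from, to), species])
}

#' Add one monomer to a filament end
#'
#' Consumes one local G-actin; the end cylinder's equilibrium length grows
#' by 2.7 nm, and a new collinear 1-monomer cylinder is created when the
#' end cylinder is already at 40 monomers.  Vertex positions are updated by
#' the next minimization, not here.
#'
#' @param state an \code{acto_state} (modified in place)
#' @param fil_id filament index
#' @param end "BE" or "PE"
#' @return invisibly the filament id
#' @export
polymerize <- function(state, fil_id, end = c("BE", "PE")) {
  end <- match.arg(end)
  f <- state$fil[[fil_id]]
  if (is.null(f)) stop("no such filament")
  m <- length(f$nmono)
  vend <- if (end == "BE") f$verts[m + 1L, ] else f$verts[1L, ]
  comp <- comp_of_point(state, vend)
  if (state$grid$counts[comp, "G"] < 1L)
    stop("no local G-actin")
  if (end == "BE") {
    if (f$nmono[m] < state$cp$max_monomers_per_cylinder) {
      f$nmono[m] <- f$nmono[m] + 1L
    } else {
      u <- f$verts[m + 1L, ] - f$verts[m, ]
      u <- u / sqrt(sum(u^2))
      f$verts <- rbind(f$verts, f$verts[m + 1L, ] + state$cp$monomer_size * u)
      f$nmono <- c(f$nmono, 1L)
      f$m_occ <- rbind(f$m_occ, rep(0L, 4L))
      f$l_occ <- rbind(f$l_occ, rep(0L, 4L))
      state$topo <- state$topo + 1L
    }
    state$counters[["be_add"]] <- state$counters[["be_add"]] + 1
  } else {
    if (f$nmono[1L] < state$cp$max_monomers_per_cylinder) {
      f$nmono[1L] <- f$nmono[1L] + 1L
    } else {
      u <- f$verts[1L, ] - f$verts[2L, ]
      u <- u / sqrt(sum(u^2))
      f$verts <- rbind(f$verts[1L, ] + state$cp$monomer_size * u, f$verts)
      f$nmono <- c(1L, f$nmono)
      f$m_occ <- rbind(rep(0L, 4L), f$m_occ)
      f$l_occ <- rbind(rep(0L, 4L), f$l_occ)
      shift_element_rows(state, fil_id, +1L)
      state$topo <- state$topo + 1L
    }
    state$counters[["pe_add"]] <- state$counters[["pe_add"]] + 1
  }
  if (state$label$active) f <- lab_add(f, end)
  state$fil[[fil_id]] <- f
  grid_add(state, comp, "G", -1L)
  invisible(fil_id)
}

# renumber cylinder references of bound elements when a cylinder is
# prepended (+1) or the first cylinder removed (-1) on filament fil_id
shift_element_rows <- function(state, fil_id, delta) {
  for (kind in c("motors", "linkers")) {
    tab <- state[[kind]]
    for (id in which(tab$active)) {
      if (tab$fa[id] == fil_id) tab$ca[id] <- tab$ca[id] + delta
      if (tab$fb[id] == fil_id) tab$cb[id] <- tab$cb[id] + delta
    }
  }
  invisible(NULL)
}

#' Remove one monomer from a filament end
#'
#' Releases one G-actin into the end's compartment; empty cylinders are
#' removed.  A filament at exactly 2 monomers cannot depolymerize further
#' (the destruction channel owns that state).  Motors or linkers attached
#' to a removed cylinder are force-released to the diffusing pool.
#'
#' @inheritParams polymerize
#' @return invisibly the filament id
#' @export
depolymerize <- function(state, fil_id, end = c("BE", "PE")) {
  end <- match.arg(end)
  f <- state$fil[[fil_id]]
  if (is.null(f)) stop("no such filament")
  if (fil_monomers(f) <= 2L)
    stop("cannot depolymerize a 2-monomer filament (destruction channel)")
  m <- length(f$nmono)
  vend <- if (end == "BE") f$verts[m + 1L, ] else f$verts[1L, ]
  comp <- comp_of_point(state, vend)
  ci <- if (end == "BE") m else 1L
  f$nmono[ci] <- f$nmono[ci] - 1L
  if (state$label$active) f <- lab_remove(f, end)
  state$fil[[fil_id]] <- f
  if (f$nmono[ci] == 0L) {
    # release elements on the vanishing cylinder
    for (kd in c("motor", "linker")) {
      occ <- if (kd == "motor") f$m_occ else f$l_occ
      for (id in unique(occ[ci, occ[ci, ] > 0L])) {
        force_release(state, kd, id)
      }
    }
    f <- state$fil[[fil_id]]
    keep <- setdiff(seq_len(m), ci)
    f$nmono <- f$nmono[keep]
    f$m_occ <- f$m_occ[keep, , drop = FALSE]
    f$l_occ <- f$l_occ[keep, , drop = FALSE]
    f$verts <- f$verts[if (end == "BE") seq_len(m) else 2L:(m + 1L), ,
                       drop = FALSE]
    state$fil[[fil_id]] <- f
    if (end == "PE") shift_element_rows(state, fil_id, -1L)
    state$topo <- state$topo + 1L
  }
  state$counters[[if (end == "BE") "be_rem" else "pe_rem"]] <-
    state$counters[[if (end == "BE") "be_rem" else "pe_rem"]] + 1
  grid_add(state, comp, "G", +1L)
  invisible(fil_id)
}

force_release <- function(state, kind, id) {
  tab <- if (kind == "motor") state$motors else state$linkers
  fa <- tab$fa[id]
  pos <- tryCatch(site_position(state$fil[[fa]], tab$ca[id], tab$sa[id],
                                state$cfg$site_fractions),
                  error = function(e) c(0, 0, 0))
  comp <- comp_of_point(state, pos)
  release_element(state, kind, id)
  grid_add(state, comp, if (kind == "motor") "NMII" else "linker", +1L)
  state$counters[["forced_unbind"]] <- state$counters[["forced_unbind"]] + 1
  invisible(NULL)
}

#' Destroy a 2-monomer filament
#'
#' The terminal reaction of the treadmilling cycle: a filament reduced to a
#' barbed-end and a pointed-end monomer is removed and two G-actin are
#' returned to its compartment.  Only formin-free filaments are eligible
#' (a formin-bound barbed end must first dissociate).  Bound motors or
#' linkers are force-released to the diffusing pool.
#'
#' @param state an \code{acto_state} (modified in place)
#' @param fil_id filament index
#' @return invisibly NULL
#' @export
destroy_filament <- function(state, fil_id) {
  f <- state$fil[[fil_id]]
  if (is.null(f)) stop("no such filament")
  if (fil_monomers(f) != 2L)
    stop("destruction applies only to 2-monomer filaments")
  if (f$barbed == "FBE")
    stop("formin-bound filament cannot be destroyed")
  for (kd in c("motor", "linker")) {
    occ <- if (kd == "motor") f$m_occ else f$l_occ
    for (id in unique(occ[occ > 0L])) force_release(state, kd, id)
  }
  mid <- colMeans(state$fil[[fil_id]]$verts)
  comp <- comp_of_point(state, mid)
  state$fil[fil_id] <- list(NULL)
  state$topo <- state$topo + 1L
  grid_add(state, comp, "G", +2L)
  state$counters[["destr"]] <- state$counters[["destr"]] + 1
  invisible(NULL)
}

#' Dissociate formin from a filament barbed end
#' @param state an \code{acto_state} (modified in place)
#' @param fil_id filament index (must be formin-bound, "FBE")
#' @return invisibly the filament id
#' @export
formin_dissociate <- function(state, fil_id) {
  f <- state$fil[[fil_id]]
  if (is.null(f)) stop("no such filament")
  if (f$barbed != "FBE") stop("barbed end is not formin-bound")
  f$barbed <- "BE"
  state$fil[[fil_id]] <- f
  comp <- comp_of_point(state, f$verts[nrow(f$verts), ])
  grid_add(state, comp, "formin", +1L)
  invisible(fil_id)
}

# uniform random position inside compartment `comp` intersected with the
# effective confinement; NULL after `tries` failures
sample_position_in <- function(state, comp, tries = 50L) {
  g <- state$grid; geom <- state$geom
  for (k in seq_len(tries)) {
    if (g$n == 1L) {
      if (geom$shape == "oblate") {
        r <- geom$R_eff * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        p <- c(r * cos(th), r * sin(th),
               stats::runif(1, -geom$half_height_eff, geom$half_height_eff))
      } else {
        p <- stats::runif(3, -geom$R_eff, geom$R_eff)
        if (sqrt(sum(p^2)) > geom$R_eff) next
      }
      return(p)
    }
    i <- (comp - 1L) %% g$nx + 1L; j <- (comp - 1L) %/% g$nx + 1L
    x <- g$origin[1] + (i - 1L + stats::runif(1)) * g$edge
    y <- g$origin[2] + (j - 1L + stats::runif(1)) * g$edge
    z <- stats::runif(1, -geom$half_height_eff, geom$half_height_eff)
    if (sqrt(x^2 + y^2) <= geom$R_eff) return(c(x, y, z))
  }
  NULL
}

# random unit orientation: in-plane azimuth with +-5 degree polar jitter
# for oblate systems, uniform on the sphere otherwise
sample_orientation <- function(geom) {
  if (geom$shape == "oblate") {
    az <- stats::runif(1, 0, 2 * pi)
    pol <- pi / 2 + stats::runif(1, -1, 1) * (5 * pi / 180)
    c(sin(pol) * cos(az), sin(pol) * sin(az), cos(pol))
  } else {
    repeat {
      v <- stats::rnorm(3)
      n <- sqrt(sum(v^2))
      if (n > 1e-12) return(v / n)
    }
  }
}

#' Nucleate a filament by the two-step formin pathway
#'
#' Step 1 (rate-limiting): a free formin captures a G-actin, forming a
#' diffusing intermediate.  Step 2 (fast, applied immediately when a second
#' local G-actin is available): the intermediate becomes a 3-monomer
#' filament with a formin-bound barbed end, placed uniformly at random
#' inside the compartment intersected with the effective confinement.
#'
#' @param state an \code{acto_state} (modified in place)
#' @param comp compartment index
#' @return the new filament id, or NA if step 2 is pending (no G-actin)
#' @export
nucleate_filament <- function(state, comp = 1L) {
  if (state$grid$counts[comp, "formin"] < 1L ||
      state$grid$counts[comp, "G"] < 1L)
    stop("nucleation requires a free formin and a G-actin")
  grid_add(state, comp, "formin", -1L)
  grid_add(state, comp, "G", -1L)
  grid_add(state, comp, "intermediate", +1L)
  nucleation_step2(state, comp)
}

# consume intermediate + 2 G -> 3-monomer FBE filament (returns id or NA).
# The intermediate carries one actin, so two more G-actin are drawn to
# reach the 3 monomers of the nucleus, keeping total actin exactly
# conserved across nucleation/destruction cycles.
nucleation_step2 <- function(state, comp) {
  if (state$grid$counts[comp, "intermediate"] < 1L ||
      state$grid$counts[comp, "G"] < 2L)
    return(NA_integer_)
  p <- sample_position_in(state, comp)
  if (is.null(p)) return(NA_integer_)  # bounded retries exhausted; wait
  u <- sample_orientation(state$geom)
  half <- 1.5 * state$cp$monomer_size
  verts <- rbind(p - half * u, p + half * u)
  if (state$geom$shape == "oblate") {
    zl <- state$geom$half_height_eff - 1
    verts[, 3] <- pmax(-zl, pmin(zl, verts[, 3]))
  }
  grid_add(state, comp, "intermediate", -1L)
  grid_add(state, comp, "G", -2L)
  id <- add_filament(state, verts, 3L, barbed = "FBE")
  state$counters[["nuc"]] <- state$counters[["nuc"]] + 1
  id
}

# Binding-pair search ----------------------------------------------------

# all binding sites of a state: matrix of positions + index table
collect_sites <- function(state, kind = c("motor", "linker")) {
  kind <- match.arg(kind)
  occf <- if (kind == "motor") "m_occ" else "l_occ"
  fr <- state$cfg$site_fractions
  pos <- list(); fa <- ca <- sa <- list()
  for (i in fil_ids(state)) {
    f <- state$fil[[i]]
    m <- length(f$nmono)
    free <- which(f[[occf]] == 0L)        # column-major over m x 4
    if (!length(free)) next
    ci <- (free - 1L) %% m + 1L
    si <- (free - 1L) %/% m + 1L
    a <- f$verts[ci, , drop = FALSE]
    b <- f$verts[ci + 1L, , drop = FALSE]
    pos[[length(pos) + 1L]] <- a + fr[si] * (b - a)
    fa[[length(fa) + 1L]] <- rep.int(i, length(free))
    ca[[length(ca) + 1L]] <- ci; sa[[length(sa) + 1L]] <- si
  }
  if (!length(pos))
    return(list(pos = matrix(0, 0, 3), fil = integer(0),
                cyl = integer(0), site = integer(0)))
  list(pos = do.call(rbind, pos), fil = unlist(fa),
       cyl = unlist(ca), site = unlist(sa))
}

#' Find candidate binding-site pairs for motors or linkers
#'
#' Scans all free binding sites (4 per cylinder) and returns every pair on
#' distinct filaments whose separation falls in the species' admissible
#' span window (motor 175-225 nm, linker 30-40 nm by default).  Uses a
#' uniform spatial hash with cell size equal to the window maximum, so the
#' result equals a brute-force all-pairs scan.
#'
#' @param state an \code{acto_state}
#' @param species "motor" or "linker"
#' @return data.frame with columns fa, ca, sa, fb, cb, sb, dist (possibly
#'   zero rows)
#' @export
find_binding_pairs <- function(state, species = c("motor", "linker")) {
  species <- match.arg(species)
  win <- if (species == "motor") state$cfg$motor_span else
    state$cfg$linker_span
  st <- collect_sites(state, species)
  n <- nrow(st$pos)
  empty <- data.frame(fa = integer(0), ca = integer(0), sa = integer(0),
                      fb = integer(0), cb = integer(0), sb = integer(0),
                      dist = numeric(0))
  if (n < 2L) return(empty)
  pr <- .find_pairs_cpp(st$pos, st$fil, win[1], win[2])
  if (!length(pr$i)) return(empty)
  i1 <- pr$i; j1 <- pr$j
  res <- data.frame(fa = st$fil[i1], ca = st$cyl[i1], sa = st$site[i1],
                    fb = st$fil[j1], cb = st$cyl[j1], sb = st$site[j1],
                    dist = pr$d)
  # canonical ordering for deterministic output
  flip <- res$fa > res$fb |
    (res$fa == res$fb & (res$ca > res$cb | (res$ca == res$cb &
                                              res$sa > res$sb)))
  if (any(flip)) {
    tmp <- res[flip, c("fb", "cb", "sb", "fa", "ca", "sa", "dist")]
    names(tmp) <- names(res)
    res[flip, ] <- tmp
  }
  res <- res[order(res$fa, res$ca, res$sa, res$fb, res$cb, res$sb), ]
  rownames(res) <- NULL
  res
}

#' Bind a motor ensemble at a candidate site pair
#'
#' Draws the head count uniformly from the configured range (unless given),
#' consumes one diffusing motor copy, and sets the spring rest length to
#' the current site separation (zero initial stretching energy).
#'
#' @param state an \code{acto_state} (modified in place)
#' @param pair one-row data.frame as returned by
#'   \code{\link{find_binding_pairs}}
#' @param n_heads optional fixed head count
#' @return the new motor id
#' @export
bind_motor <- function(state, pair, n_heads = NULL) {
  if (grid_total(state$grid, "NMII") < 1L) stop("no free motor copies")
  if (is.null(n_heads)) {
    rg <- state$mcp$n_heads_range
    n_heads <- sample(rg[1]:rg[2], 1L)
  }
  l0 <- site_pair_distance(state, pair)
  comp <- consume_soluble(state, "NMII", pair)
  bind_element(state, "motor", pair$fa, pair$ca, pair$sa,
               pair$fb, pair$cb, pair$sb, l0, as.integer(n_heads))
}

#' Bind a crosslinker at a candidate site pair
#' @inheritParams bind_motor
#' @return the new linker id
#' @export
bind_linker <- function(state, pair) {
  if (grid_total(state$grid, "linker") < 1L) stop("no free linker copies")
  l0 <- site_pair_distance(state, pair)
  comp <- consume_soluble(state, "linker", pair)
  bind_element(state, "linker", pair$fa, pair$ca, pair$sa,
               pair$fb, pair$cb, pair$sb, l0)
}

site_pair_distance <- function(state, pair) {
  pa <- site_position(state$fil[[pair$fa]], pair$ca, pair$sa,
                      state$cfg$site_fractions)
  pb <- site_position(state$fil[[pair$fb]], pair$cb, pair$sb,
                      state$cfg$site_fractions)
  sqrt(sum((pb - pa)^2))
}

# take one copy from the compartment of site a (or the nearest stocked one)
consume_soluble <- function(state, species, pair) {
  pa <- site_position(state$fil[[pair$fa]], pair$ca, pair$sa,
                      state$cfg$site_fractions)
  comp <- comp_of_point(state, pa)
  if (state$grid$counts[comp, species] < 1L)
    comp <- which(state$grid$counts[, species] > 0L)[1L]
  grid_add(state, comp, species, -1L)
  comp
}

#' Unbind a motor or linker, returning it to the diffusing pool
#' @param state an \code{acto_state} (modified in place)
#' @param kind "motor" or "linker"
#' @param id element slot id
#' @return invisibly NULL
#' @export
unbind_element <- function(state, kind = c("motor", "linker"), id) {
  kind <- match.arg(kind)
  tab <- if (kind == "motor") state$motors else state$linkers
  if (!isTRUE(tab$active[id])) stop("element not bound")
  pos <- site_position(state$fil[[tab$fa[id]]], tab$ca[id], tab$sa[id],
                       state$cfg$site_fractions)
  comp <- comp_of_point(state, pos)
  release_element(state, kind, id)
  grid_add(state, comp, if (kind == "motor") "NMII" else "linker", +1L)
  invisible(NULL)
}

# next binding site toward the barbed end on one motor side, or NULL
next_site_toward_barbed <- function(state, id, side = c("a", "b")) {
  side <- match.arg(side)
  tab <- state$motors
  fi <- tab[[paste0("f", side)]][id]
  ci <- tab[[paste0("c", side)]][id]
  si <- tab[[paste0("s", side)]][id]
  f <- state$fil[[fi]]
  if (is.null(f)) return(NULL)
  m <- length(f$nmono)
  if (si < 4L) list(fil = fi, ci = ci, si = si + 1L)
  else if (ci < m) list(fil = fi, ci = ci + 1L, si = 1L)
  else NULL
}

#' Advance one motor end one binding site toward the barbed end
#'
#' The attachment point moves to the next site; the spring rest length set
#' at binding is kept, so the realized extension (and hence the motor
#' tension driving contraction) changes with each step.
#'
#' @param state an \code{acto_state} (modified in place)
#' @param id motor id
#' @param side "a" or "b" (the two ends walk independently)
#' @return invisibly the motor id
#' @export
motor_walk <- function(state, id, side = c("a", "b")) {
  side <- match.arg(side)
  tab <- state$motors
  if (!isTRUE(tab$active[id])) stop("motor not bound")
  nxt <- next_site_toward_barbed(state, id, side)
  if (is.null(nxt)) stop("no next binding site toward the barbed end")
  f <- state$fil[[nxt$fil]]
  if (f$m_occ[nxt$ci, nxt$si] != 0L) stop("target site occupied")
  ci <- tab[[paste0("c", side)]][id]; si <- tab[[paste0("s", side)]][id]
  f$m_occ[ci, si] <- 0L
  f$m_occ[nxt$ci, nxt$si] <- id
  state$fil[[nxt$fil]] <- f
  tab[[paste0("c", side)]][id] <- nxt$ci
  tab[[paste0("s", side)]][id] <- nxt$si
  state$topo <- state$topo + 1L
  invisible(id)
}
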