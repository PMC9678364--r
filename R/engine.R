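# Next Reaction Method engine -------------------------------------------
#
# The NRM (Gibson & Bruck) assigns each channel an absolute firing time
# t + Exp(1)/a.  After an event, channels whose propensity changed from
# a_old to a_new reuse their pending exponential via the rescaling
#   t' = now + (a_old/a_new) (t_old - now),
# drawing a fresh exponential only for the fired channel or channels coming
# back from zero propensity.  The generic core below is exposed for toy
# networks and testing; the simulator drives a specialized channel table.

#' Initialize a Next Reaction Method queue
#'
#' @param a numeric vector of channel propensities (events/s)
#' @param t0 current time
#' @return environment with fields \code{a} and \code{t} (absolute firing
#'   times; \code{Inf} where the propensity is 0)
#' @export
nrm_init <- function(a, t0 = 0) {
  if (any(a < 0)) stop("negative propensity")
  q <- new.env(parent = emptyenv())
  q$a <- a
  q$t <- ifelse(a > 0, t0 + stats::rexp(length(a)) / a, Inf)
  q
}

#' Index and time of the next channel to fire
#' @param q an NRM queue
#' @return list(j, t); \code{j = NA} and \code{t = Inf} when the system is
#'   chemically frozen (all propensities zero)
#' @export
nrm_peek <- function(q) {
  j <- which.min(q$t)
  if (!length(j) || !is.finite(q$t[j])) return(list(j = NA_integer_, t = Inf))
  list(j = j, t = q$t[j])
}

#' Apply the NRM propensity-update rule to a set of channels
#'
#' @param q an NRM queue
#' @param idx channel indices whose propensity changed
#' @param a_new their new propensities
#' @param now current time
#' @param fired index of the channel that just fired (gets a fresh
#'   exponential), or NA
#' @return invisibly the queue
#' @export
nrm_update <- function(q, idx, a_new, now, fired = NA_integer_) {
  if (any(a_new < 0)) stop("negative propensity")
  a_old <- q$a[idx]
  tnew <- numeric(length(idx))
  fresh <- (!is.na(fired) & idx == fired) | a_old == 0 | !is.finite(q$t[idx])
  resc <- !fresh & a_new > 0
  tnew[resc] <- now + (a_old[resc] / a_new[resc]) * (q$t[idx[resc]] - now)
  if (any(fresh)) {
    nf <- sum(fresh)
    tnew[fresh] <- ifelse(a_new[fresh] > 0,
                          now + stats::rexp(nf) / a_new[fresh], Inf)
  }
  tnew[a_new == 0] <- Inf
  q$a[idx] <- a_new
  q$t[idx] <- tnew
  invisible(q)
}

#' Run a small reaction network with the Next Reaction Method
#'
#' Generic driver for toy networks: \code{a_fn(x)} returns the propensity
#' vector for copy-number state \code{x}, and \code{fire_fn(x, j)} returns
#' the state after channel \code{j} fires.  All propensities are
#' recomputed after each event (exact for small systems).
#'
#' @param a_fn propensity function
#' @param fire_fn state-update function
#' @param x0 initial state (any R object)
#' @param t_max stop time
#' @param t0 start time
#' @param max_events optional event cap
#' @return list with \code{x} (final state), \code{t} (final time),
#'   \code{times} and \code{events} (the event log), \code{frozen}
#' @export
nrm_run <- function(a_fn, fire_fn, x0, t_max, t0 = 0, max_events = Inf) {
  x <- x0; now <- t0
  q <- nrm_init(a_fn(x), t0 = now)
  times <- numeric(0); events <- integer(0)
  n <- 0L
  repeat {
    nx <- nrm_peek(q)
    if (is.na(nx$j) || nx$t > t_max || n >= max_events) break
    now <- nx$t
    x <- fire_fn(x, nx$j)
    n <- n + 1L
    times <- c(times, now); events <- c(events, nx$j)
    nrm_update(q, seq_along(q$a), a_fn(x), now, fired = nx$j)
  }
  list(x = x, t = min(t_max, now), times = times, events = events,
       frozen = is.na(nrm_peek(q)$j))
}

# Candidate-pair cache ----------------------------------------------------
# Each admissible free site pair acts as a binding channel, so the total
# binding propensity is k_on * [soluble] * n_pairs (motors additionally
# scaled by the head count).  The full pair search runs only every
# `pair_refresh` windows (positions move only at minimization and then
# slowly); successful bindings prune the cache incrementally, and a firing
# whose sampled pair has gone stale is a null event.

pair_cache_refresh <- function(state, species) {
  pc <- mget("pair_cache", envir = state,
             ifnotfound = list(list()))[[1]]
  pc[[species]] <- list(pairs = find_binding_pairs(state, species),
                        age = 0L)
  state$pair_cache <- pc
  invisible(NULL)
}

pair_cache_tick <- function(state, refresh_every = 10L) {
  pc <- mget("pair_cache", envir = state,
             ifnotfound = list(list()))[[1]]
  for (species in c("motor", "linker")) {
    soluble <- if (species == "motor") "NMII" else "linker"
    if (grid_total(state$grid, soluble) < 1L) next
    entry <- pc[[species]]
    if (is.null(entry) || entry$age >= refresh_every) {
      pair_cache_refresh(state, species)
    } else {
      pc[[species]]$age <- entry$age + 1L
      state$pair_cache <- pc
    }
  }
  invisible(NULL)
}

# force a refresh at the next window tick (freed sites create new pairs)
pair_cache_expire <- function(state, species) {
  pc <- mget("pair_cache", envir = state,
             ifnotfound = list(list()))[[1]]
  if (!is.null(pc[[species]])) {
    pc[[species]]$age <- .Machine$integer.max
    state$pair_cache <- pc
  }
  invisible(NULL)
}

pair_count <- function(state, species) {
  pc <- mget("pair_cache", envir = state,
             ifnotfound = list(list()))[[1]]
  if (is.null(pc[[species]])) 0L else nrow(pc[[species]]$pairs)
}

# drop cached pairs that touch the given (fil, cyl, site) slots
pair_cache_prune <- function(state, species, fils, cyls, sites) {
  pc <- state$pair_cache
  df <- pc[[species]]$pairs
  if (is.null(df) || !nrow(df)) return(invisible(NULL))
  hit <- rep(FALSE, nrow(df))
  for (k in seq_along(fils)) {
    hit <- hit |
      (df$fa == fils[k] & df$ca == cyls[k] & df$sa == sites[k]) |
      (df$fb == fils[k] & df$cb == cyls[k] & df$sb == sites[k])
  }
  pc[[species]]$pairs <- df[!hit, , drop = FALSE]
  state$pair_cache <- pc
  invisible(NULL)
}

# sample one cached pair and check it is still realizable
pair_cache_draw <- function(state, species) {
  pc <- state$pair_cache
  df <- pc[[species]]$pairs
  if (is.null(df) || !nrow(df)) return(NULL)
  pick <- df[sample.int(nrow(df), 1L), ]
  occ <- if (species == "motor") "m_occ" else "l_occ"
  ok <- tryCatch({
    fa <- state$fil[[pick$fa]]; fb <- state$fil[[pick$fb]]
    !is.null(fa) && !is.null(fb) &&
      pick$ca <= length(fa$nmono) && pick$cb <= length(fb$nmono) &&
      fa[[occ]][pick$ca, pick$sa] == 0L &&
      fb[[occ]][pick$cb, pick$sb] == 0L
  }, error = function(e) FALSE)
  if (!ok) {
    pair_cache_prune(state, species, c(pick$fa, pick$fb),
                     c(pick$ca, pick$cb), c(pick$sa, pick$sb))
    return(NULL)
  }
  pick
}

# Simulator channel table -------------------------------------------------
# kinds: 1 poly_BE, 2 poly_PE, 3 depoly_BE, 4 depoly_PE, 5 destruction,
#        6 formin_diss, 7 nucleation(comp), 8 diffusion(comp, species),
#        9 motor_bind, 10 linker_bind, 11 motor_unbind, 12 linker_unbind,
#        13 motor_walk_a, 14 motor_walk_b

# default force modifiers (zero force everywhere)
default_mods <- function(state) {
  list(be = numeric(0), pe = numeric(0),
       motor_unbind = numeric(0), linker_unbind = numeric(0),
       walk_a = numeric(0), walk_b = numeric(0))
}

mod_lookup <- function(tab, id, default) {
  v <- tab[as.character(id)]
  ifelse(is.na(v), default, v)
}

# propensity of channel rows (vectorized per kind)
channel_propensity <- function(state, kind, e1, e2, mods, heads_next) {
  cp <- state$cp; mcp <- state$mcp
  n <- length(kind)
  a <- numeric(n)
  alive <- function(ids) !vapply(state$fil[ids], is.null, TRUE)
  one_comp <- state$grid$n == 1L
  for (kd in unique(kind)) {
    w <- which(kind == kd)
    ids <- e1[w]
    a[w] <- switch(as.character(kd),
      "0" = 0,
      "1" = { ok <- alive(ids)
        val <- numeric(length(w))
        if (any(ok)) {
          comp <- if (one_comp) rep(1L, sum(ok)) else
            vapply(ids[ok], function(i) {
              f <- state$fil[[i]]
              comp_of_point(state, f$verts[nrow(f$verts), ]) }, 1L)
          val[ok] <- cp$k_on_BE *
            copies_to_concentration(state$grid$counts[comp, "G"],
                                    comp_volume_L(state)) *
            mod_lookup(mods$be, ids[ok], 1)
        }
        val },
      "2" = { ok <- alive(ids)
        val <- numeric(length(w))
        if (any(ok)) {
          comp <- if (one_comp) rep(1L, sum(ok)) else
            vapply(ids[ok], function(i)
              comp_of_point(state, state$fil[[i]]$verts[1L, ]), 1L)
          val[ok] <- cp$k_on_PE *
            copies_to_concentration(state$grid$counts[comp, "G"],
                                    comp_volume_L(state)) *
            mod_lookup(mods$pe, ids[ok], 1)
        }
        val },
      "3" = { ok <- alive(ids)
        nm <- integer(length(w))
        nm[ok] <- vapply(ids[ok], function(i) fil_monomers(state$fil[[i]]), 0L)
        ifelse(ok & nm > 2L, cp$k_off_BE, 0) },
      "4" = { ok <- alive(ids)
        nm <- integer(length(w))
        nm[ok] <- vapply(ids[ok], function(i) fil_monomers(state$fil[[i]]), 0L)
        ifelse(ok & nm > 2L, cp$k_off_PE, 0) },
      "5" = { ok <- alive(ids)
        el <- logical(length(w))
        el[ok] <- vapply(ids[ok], function(i) {
          f <- state$fil[[i]]
          fil_monomers(f) == 2L && f$barbed == "BE" }, TRUE)
        ifelse(el, cp$k_destruction, 0) },
      "6" = { ok <- alive(ids)
        fb <- logical(length(w))
        fb[ok] <- vapply(ids[ok], function(i)
          state$fil[[i]]$barbed == "FBE", TRUE)
        ifelse(fb, cp$k_off_formin, 0) },
      "7" = cp$k_nu * state$grid$counts[ids, "formin"] *
        (state$grid$counts[ids, "G"] >= 1L),
      "8" = { g <- state$grid
        nn <- vapply(g$nbr[ids], length, 0L)
        cp$D_diff / g$edge^2 * nn * g$counts[cbind(ids, e2[w])] },
      "9" = cp$k_on_head * heads_next * conc_uM_total(state, "NMII") *
        pair_count(state, "motor"),
      "10" = cp$k_on_linker * conc_uM_total(state, "linker") *
        pair_count(state, "linker"),
      "11" = { act <- state$motors$active[ids]
        ifelse(act, mod_lookup(mods$motor_unbind, ids,
                               mcp$beta * cp$k_off_head /
                                 pmax(state$motors$n_heads[ids], 1L)), 0) },
      "12" = ifelse(state$linkers$active[ids],
                    mod_lookup(mods$linker_unbind, ids, cp$k_off_linker), 0),
      "13" = walk_propensity(state, ids, "a", mods),
      "14" = walk_propensity(state, ids, "b", mods),
      stop("unknown channel kind"))
  }
  a
}

walk_propensity <- function(state, ids, side, mods) {
  vapply(ids, function(id) {
    if (!isTRUE(state$motors$active[id])) return(0)
    nxt <- next_site_toward_barbed(state, id, side)
    if (is.null(nxt)) return(0)
    if (state$fil[[nxt$fil]]$m_occ[nxt$ci, nxt$si] != 0L) return(0)
    mod_lookup(mods[[paste0("walk_", side)]], id, state$cp$k_walk0)
  }, 0)
}

# Build the full channel table for the current state
build_channels <- function(state, mods) {
  Q <- new.env(parent = emptyenv())
  kind <- integer(0); e1 <- integer(0); e2 <- integer(0)
  rows_fil <- list(); rows_motor <- list(); rows_linker <- list()
  add_rows <- function(k, a1, a2 = 0L) {
    nr <- length(k)
    kind <<- c(kind, k); e1 <<- c(e1, a1); e2 <<- c(e2, rep(a2, nr))
    length(kind) - nr + seq_len(nr)
  }
  for (i in fil_ids(state))
    rows_fil[[as.character(i)]] <- add_rows(1:6, rep(i, 6L))
  Q$poly_rows <- unlist(lapply(rows_fil, `[`, 1:2), use.names = FALSE)
  g <- state$grid
  vcomp <- if (g$n == 1L) 1L else which(g$valid)
  Q$row_nuc <- stats::setNames(add_rows(rep(7L, length(vcomp)), vcomp), vcomp)
  Q$row_diff <- NULL
  if (g$n > 1L) {
    Q$row_diff <- matrix(NA_integer_, g$n, length(SPECIES))
    for (sp in seq_along(SPECIES))
      Q$row_diff[vcomp, sp] <- add_rows(rep(8L, length(vcomp)), vcomp, sp)
  }
  Q$row_mbind <- add_rows(9L, 0L)
  Q$row_lbind <- add_rows(10L, 0L)
  for (id in which(state$motors$active))
    rows_motor[[as.character(id)]] <- add_rows(c(11L, 13L, 14L), rep(id, 3L))
  for (id in which(state$linkers$active))
    rows_linker[[as.character(id)]] <- add_rows(12L, id)
  Q$kind <- kind; Q$e1 <- e1; Q$e2 <- e2
  Q$rows_fil <- rows_fil; Q$rows_motor <- rows_motor
  Q$rows_linker <- rows_linker
  rg <- state$mcp$n_heads_range
  Q$heads_next <- sample(rg[1]:rg[2], 1L)
  Q$a <- channel_propensity(state, kind, e1, e2, mods, Q$heads_next)
  Q$t <- ifelse(Q$a > 0, state$time + stats::rexp(length(Q$a)) / Q$a, Inf)
  Q
}

# recompute propensities for given rows and apply the NRM update rule
refresh_rows <- function(state, Q, rows, mods, now, fired = NA_integer_) {
  rows <- rows[!is.na(rows)]
  if (!length(rows)) return(invisible(NULL))
  a_new <- channel_propensity(state, Q$kind[rows], Q$e1[rows], Q$e2[rows],
                              mods, Q$heads_next)
  a_old <- Q$a[rows]
  fresh <- (!is.na(fired) & rows == fired) | a_old == 0 |
    !is.finite(Q$t[rows])
  tnew <- rep(Inf, length(rows))
  resc <- !fresh & a_new > 0
  tnew[resc] <- now + (a_old[resc] / a_new[resc]) * (Q$t[rows[resc]] - now)
  fr <- fresh & a_new > 0
  if (any(fr)) tnew[fr] <- now + stats::rexp(sum(fr)) / a_new[fr]
  Q$a[rows] <- a_new
  Q$t[rows] <- tnew
  invisible(NULL)
}

append_fil_channels <- function(state, Q, i, mods, now) {
  k <- 1:6
  nr <- length(Q$kind)
  Q$kind <- c(Q$kind, k); Q$e1 <- c(Q$e1, rep(i, 6L))
  Q$e2 <- c(Q$e2, rep(0L, 6L))
  rows <- nr + seq_len(6L)
  Q$rows_fil[[as.character(i)]] <- rows
  Q$poly_rows <- c(Q$poly_rows, rows[1:2])
  a <- channel_propensity(state, k, rep(i, 6L), rep(0L, 6L), mods,
                          Q$heads_next)
  Q$a <- c(Q$a, a)
  Q$t <- c(Q$t, ifelse(a > 0, now + stats::rexp(6L) / a, Inf))
  invisible(rows)
}

append_element_channels <- function(state, Q, kind, id, mods, now) {
  ks <- if (kind == "motor") c(11L, 13L, 14L) else 12L
  # element slot ids are recycled: permanently retire any channel rows of
  # a previous occupant of this slot (kind 0 = inert)
  map <- if (kind == "motor") Q$rows_motor else Q$rows_linker
  old <- map[[as.character(id)]]
  if (!is.null(old)) {
    Q$kind[old] <- 0L
    Q$a[old] <- 0
    Q$t[old] <- Inf
  }
  nr <- length(Q$kind)
  Q$kind <- c(Q$kind, ks); Q$e1 <- c(Q$e1, rep(id, length(ks)))
  Q$e2 <- c(Q$e2, rep(0L, length(ks)))
  rows <- nr + seq_along(ks)
  if (kind == "motor") Q$rows_motor[[as.character(id)]] <- rows
  else Q$rows_linker[[as.character(id)]] <- rows
  a <- channel_propensity(state, ks, rep(id, length(ks)),
                          rep(0L, length(ks)), mods, Q$heads_next)
  Q$a <- c(Q$a, a)
  Q$t <- c(Q$t, ifelse(a > 0, now + stats::rexp(length(ks)) / a, Inf))
  invisible(rows)
}

# rows affected by a change of soluble-species counts in compartment(s) cm
soluble_dep_rows <- function(state, Q, cm, species) {
  rows <- integer(0)
  if (species == "G") {
    # all end-polymerization channels of filaments whose end lies in cm
    # (with a single compartment: every filament), plus nucleation
    for (rf in Q$rows_fil) rows <- c(rows, rf[1:2])
    rows <- c(rows, Q$row_nuc[as.character(cm)])
  }
  if (species == "formin") rows <- c(rows, Q$row_nuc[as.character(cm)])
  if (species == "NMII") rows <- c(rows, Q$row_mbind)
  if (species == "linker") rows <- c(rows, Q$row_lbind)
  if (!is.null(Q$row_diff)) rows <- c(rows, Q$row_diff[cm, match(species,
                                                                 SPECIES)])
  rows[!is.na(rows)]
}

# rows of walk channels of motors attached to filament i (site occupancy
# or topology changed)
walk_rows_on_fil <- function(state, Q, i) {
  rows <- integer(0)
  for (id in which(state$motors$active)) {
    if (state$motors$fa[id] == i || state$motors$fb[id] == i) {
      rm <- Q$rows_motor[[as.character(id)]]
      if (!is.null(rm)) rows <- c(rows, rm[2:3])
    }
  }
  rows
}

# Multiplicative NRM update for all polymerization channels after a
# G-actin count change in a well-mixed (single-compartment) system: every
# poly propensity scales by n_new/n_old, so pending times rescale by
# n_old/n_new.  Falls back to full recomputation when a count was zero or
# the grid has several compartments.
update_G_rows <- function(state, Q, comp, n_old, mods, now) {
  n_new <- state$grid$counts[comp, "G"]
  if (state$grid$n == 1L && n_old > 0L && n_new > 0L) {
    rows <- Q$poly_rows
    live <- rows[Q$a[rows] > 0]
    ratio <- n_new / n_old
    Q$a[live] <- Q$a[live] * ratio
    Q$t[live] <- now + (Q$t[live] - now) / ratio
    refresh_rows(state, Q, Q$row_nuc[as.character(comp)], mods, now)
  } else {
    refresh_rows(state, Q, soluble_dep_rows(state, Q, comp, "G"),
                 mods, now)
  }
  invisible(NULL)
}

# Fire channel j and update all dependent channels; returns event record
fire_event <- function(state, Q, j, mods, now) {
  kd <- Q$kind[j]; id <- Q$e1[j]
  ev <- list(kind = kd, id = id)
  touch <- integer(0)
  if (kd %in% c(1L, 2L)) {
    end <- if (kd == 1L) "BE" else "PE"
    f <- state$fil[[id]]
    vend <- if (end == "BE") f$verts[nrow(f$verts), ] else f$verts[1L, ]
    comp <- comp_of_point(state, vend)
    n_old <- state$grid$counts[comp, "G"]
    if (n_old < 1L) {
      refresh_rows(state, Q, j, mods, now, fired = j)  # stale; null event
      return(ev)
    }
    polymerize(state, id, end)
    newf <- post_G_change(state, Q, comp, mods, now)
    update_G_rows(state, Q, comp, n_old, mods, now)
    touch <- c(Q$rows_fil[[as.character(id)]][3:5], newf)
  } else if (kd %in% c(3L, 4L)) {
    end <- if (kd == 3L) "BE" else "PE"
    f <- state$fil[[id]]
    vend <- if (end == "BE") f$verts[nrow(f$verts), ] else f$verts[1L, ]
    comp <- comp_of_point(state, vend)
    n_old <- state$grid$counts[comp, "G"]
    ncyl_before <- length(f$nmono)
    depolymerize(state, id, end)
    lost_cyl <- length(state$fil[[id]]$nmono) < ncyl_before
    newf <- post_G_change(state, Q, comp, mods, now)
    update_G_rows(state, Q, comp, n_old, mods, now)
    touch <- c(Q$rows_fil[[as.character(id)]][3:5], newf)
    if (lost_cyl) touch <- c(touch, walk_rows_on_fil(state, Q, id),
                             unlist(Q$rows_motor), unlist(Q$rows_linker))
  } else if (kd == 5L) {
    f <- state$fil[[id]]
    comp <- comp_of_point(state, colMeans(f$verts))
    had_elements <- any(f$m_occ > 0L) || any(f$l_occ > 0L)
    n_old <- state$grid$counts[comp, "G"]
    destroy_filament(state, id)
    newf <- post_G_change(state, Q, comp, mods, now)
    update_G_rows(state, Q, comp, n_old, mods, now)
    touch <- c(Q$rows_fil[[as.character(id)]], newf)
    if (had_elements)
      touch <- c(touch, unlist(Q$rows_motor), unlist(Q$rows_linker),
                 soluble_dep_rows(state, Q, comp, "NMII"),
                 soluble_dep_rows(state, Q, comp, "linker"))
  } else if (kd == 6L) {
    formin_dissociate(state, id)
    comp <- comp_of_point(state,
                          state$fil[[id]]$verts[nrow(state$fil[[id]]$verts), ])
    touch <- c(Q$rows_fil[[as.character(id)]][5:6],
               soluble_dep_rows(state, Q, comp, "formin"))
  } else if (kd == 7L) {
    n_old <- state$grid$counts[id, "G"]
    nid <- nucleate_filament(state, id)
    update_G_rows(state, Q, id, n_old, mods, now)
    touch <- soluble_dep_rows(state, Q, id, "formin")
    if (!is.na(nid)) append_fil_channels(state, Q, nid, mods, now)
  } else if (kd == 8L) {
    g <- state$grid
    nb <- g$nbr[[id]]
    to <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L)]
    sp <- SPECIES[Q$e2[j]]
    diffusion_hop(state, sp, id, to)
    touch <- c(soluble_dep_rows(state, Q, id, sp),
               soluble_dep_rows(state, Q, to, sp))
  } else if (kd == 9L) {
    pick <- pair_cache_draw(state, "motor")
    if (!is.null(pick)) {
      mid <- bind_motor(state, pick, n_heads = Q$heads_next)
      rg <- state$mcp$n_heads_range
      Q$heads_next <- sample(rg[1]:rg[2], 1L)
      append_element_channels(state, Q, "motor", mid, mods, now)
      pair_cache_prune(state, "motor", c(pick$fa, pick$fb),
                       c(pick$ca, pick$cb), c(pick$sa, pick$sb))
      comp <- comp_of_point(state, site_position(
        state$fil[[pick$fa]], pick$ca, pick$sa, state$cfg$site_fractions))
      touch <- c(soluble_dep_rows(state, Q, comp, "NMII"),
                 walk_rows_on_fil(state, Q, pick$fa),
                 walk_rows_on_fil(state, Q, pick$fb))
    } else touch <- Q$row_mbind  # stale/no pair: null event
  } else if (kd == 10L) {
    pick <- pair_cache_draw(state, "linker")
    if (!is.null(pick)) {
      lid <- bind_linker(state, pick)
      append_element_channels(state, Q, "linker", lid, mods, now)
      pair_cache_prune(state, "linker", c(pick$fa, pick$fb),
                       c(pick$ca, pick$cb), c(pick$sa, pick$sb))
      comp <- comp_of_point(state, site_position(
        state$fil[[pick$fa]], pick$ca, pick$sa, state$cfg$site_fractions))
      touch <- c(soluble_dep_rows(state, Q, comp, "linker"))
    } else touch <- Q$row_lbind
  } else if (kd == 11L) {
    fa <- state$motors$fa[id]; fb <- state$motors$fb[id]
    unbind_element(state, "motor", id)
    pair_cache_expire(state, "motor")
    touch <- c(Q$rows_motor[[as.character(id)]], Q$row_mbind,
               walk_rows_on_fil(state, Q, fa), walk_rows_on_fil(state, Q, fb))
  } else if (kd == 12L) {
    unbind_element(state, "linker", id)
    pair_cache_expire(state, "linker")
    touch <- c(Q$rows_linker[[as.character(id)]], Q$row_lbind)
  } else if (kd %in% c(13L, 14L)) {
    side <- if (kd == 13L) "a" else "b"
    fi <- state$motors[[paste0("f", side)]][id]
    motor_walk(state, id, side)
    # the cached pair list is not pruned here: a stale pair touching the
    # newly occupied site is rejected at draw time
    touch <- c(Q$rows_motor[[as.character(id)]],
               walk_rows_on_fil(state, Q, fi))
  }
  touch <- unique(c(touch, j))
  refresh_rows(state, Q, touch, mods, now, fired = j)
  ev
}

# after G-actin appears in a compartment, run any pending fast nucleation
# step 2; returns rows of newly created filaments (already appended)
post_G_change <- function(state, Q, comp, mods, now) {
  new_rows <- integer(0)
  while (state$grid$counts[comp, "intermediate"] >= 1L &&
         state$grid$counts[comp, "G"] >= 2L) {
    nid <- nucleation_step2(state, comp)
    if (is.na(nid)) break
    new_rows <- c(new_rows, append_fil_channels(state, Q, nid, mods, now))
  }
  new_rows
}

#' Advance the chemistry by one window of the protocol
#'
#' Runs the Next Reaction Method from the current state time to
#' \code{t_end} with reaction rates held at the values implied by the given
#' force modifiers (rates are only updated at protocol boundaries, after
#' each minimization).  The channel table is rebuilt at the window start;
#' re-drawing the pending exponentials at a deterministic boundary is
#' statistically exact by memorylessness.
#'
#' @param state an \code{acto_state} (modified in place)
#' @param t_end window end time, s
#' @param mods force-rate modifiers from \code{\link{compute_rate_mods}}
#'   (zero-force defaults if NULL)
#' @return invisibly a list with the number of events fired and whether the
#'   system is chemically frozen
#' @export
run_chemistry_window <- function(state, t_end, mods = NULL) {
  if (is.null(mods)) mods <- default_mods(state)
  pair_cache_tick(state, refresh_every = state$cfg$pair_refresh)
  age <- mget("chan_age", envir = state, ifnotfound = list(0L))[[1]]
  Q <- mget("chanQ", envir = state, ifnotfound = list(NULL))[[1]]
  if (is.null(Q) || age >= 200L) {
    Q <- build_channels(state, mods)
    state$chanQ <- Q
    state$chan_age <- 0L
  } else {
    # reuse the channel structure: recompute all propensities under the
    # new rate modifiers and redraw firing times (exact by memorylessness
    # at a deterministic window boundary)
    a <- channel_propensity(state, Q$kind, Q$e1, Q$e2, mods, Q$heads_next)
    Q$a <- a
    Q$t <- ifelse(a > 0, state$time + stats::rexp(length(a)) / a, Inf)
    state$chan_age <- age + 1L
  }
  n_ev <- 0L
  repeat {
    j <- which.min(Q$t)
    if (!length(j) || !is.finite(Q$t[j]) || Q$t[j] > t_end) break
    now <- Q$t[j]
    state$time <- now
    fire_event(state, Q, j, mods, now)
    n_ev <- n_ev + 1L
  }
  frozen <- !any(is.finite(Q$t))
  state$time <- t_end
  invisible(list(events = n_ev, frozen = frozen))
}

#' Force-dependent rate modifiers from a minimization result
#'
#' Translates the post-minimization force field into the per-channel rate
#' modifications used in the next chemistry window: Brownian-ratchet
#' factors for each filament end (from the boundary load), catch-bond
#' unbinding and Hill walking rates for each motor (from the spring
#' tension), and slip-bond unbinding rates for each linker.
#'
#' @param state an \code{acto_state}
#' @param mech result of \code{\link{minimize_state}}
#' @return a modifier list consumed by \code{\link{run_chemistry_window}}
#' @export
compute_rate_mods <- function(state, mech) {
  mods <- default_mods(state)
  mcp <- state$mcp; cp <- state$cp
  if (!is.null(mech$end_loads)) {
    ids <- names(mech$end_loads)
    be <- vapply(mech$end_loads, `[[`, 0, "be")
    pe <- vapply(mech$end_loads, `[[`, 0, "pe")
    mods$be <- stats::setNames(exp(-be / mcp$F_poly0), ids)
    mods$pe <- stats::setNames(exp(-pe / mcp$F_poly0), ids)
  }
  tm <- mech$tensions$motor
  if (!is.null(tm) && length(tm)) {
    ids <- as.integer(names(tm))
    nh <- state$motors$n_heads[ids]
    mods$motor_unbind <- stats::setNames(
      catch_unbind_rate(cp$k_off_head, pmax(tm, 0), nh,
                        beta = mcp$beta,
                        F_nmii_unbind = mcp$F_nmii_unbind), ids)
    # pulling force opposing walking on each end: the spring tension
    # projected on the barbed-ward step direction of that end (only a
    # step that further stretches the spring is resisted)
    fr <- state$cfg$site_fractions
    nm <- length(ids)
    sp_pos <- function(fv, cv, sv) {
      P <- matrix(0, nm, 3); W <- matrix(0, nm, 3)
      for (k in seq_len(nm)) {
        f <- state$fil[[fv[k]]]
        a <- f$verts[cv[k], ]; b <- f$verts[cv[k] + 1L, ]
        P[k, ] <- a + fr[sv[k]] * (b - a)
        W[k, ] <- b - a
      }
      list(P = P, W = W / sqrt(.rowSums(W * W, nm, 3L)))
    }
    A <- sp_pos(state$motors$fa[ids], state$motors$ca[ids],
                state$motors$sa[ids])
    B <- sp_pos(state$motors$fb[ids], state$motors$cb[ids],
                state$motors$sb[ids])
    D <- A$P - B$P
    L <- pmax(sqrt(.rowSums(D * D, nm, 3L)), 1e-9)
    for (side in c("a", "b")) {
      W <- if (side == "a") A$W else B$W
      Ds <- if (side == "a") D else -D
      fpull <- pmax(0, tm * .rowSums(W * Ds, nm, 3L) / L)
      mods[[paste0("walk_", side)]] <- stats::setNames(
        hill_walk_rate(cp$k_walk0, fpull, nh, F_stall = mcp$F_stall,
                       xi = mcp$xi), ids)
    }
  }
  tl <- mech$tensions$linker
  if (!is.null(tl) && length(tl)) {
    ids <- names(tl)
    mods$linker_unbind <- stats::setNames(
      slip_unbind_rate(cp$k_off_linker, tl,
                       F_linker_unbind = mcp$F_linker_unbind), ids)
  }
  mods
}
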