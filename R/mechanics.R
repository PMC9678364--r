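# Mechanical model -------------------------------------------------------
#
# Potential energy of the polymeric phase (units: pN, nm, pN nm):
#   U_str      = 1/2 K_str (l - l0)^2            per cylinder
#   U_bend     = K_bend (1 - cos(theta - theta0)) per cylinder junction
#   U_vol      = K_vol int int dl_i dl_j / r^4    per non-adjacent pair
#   U_spring   = 1/2 K_eff (l - l0)^2            per bound motor/linker
#   U_boundary = eps exp(-(d - a0)/lambda)        per boundary sample point
# Mechanics is quasi-static: after every chemistry window the total energy
# is minimized (FIRE) and the resulting forces feed the force-dependent
# rate laws.

#' Cylinder stretching energy
#' @param l actual cylinder length, nm
#' @param l0 equilibrium length (2.7 nm per monomer), nm
#' @param K_fil_str stretching constant, pN/nm
#' @return energy in pN nm
#' @export
stretch_energy <- function(l, l0, K_fil_str = 100) {
  0.5 * K_fil_str * (l - l0)^2
}

#' Bending energy between two consecutive cylinders
#' @param theta angle between the cylinder axes, rad
#' @param K_fil_bend bending constant, pN nm
#' @param theta0 equilibrium angle, rad
#' @return energy in pN nm
#' @export
bend_energy <- function(theta, K_fil_bend = 672, theta0 = 0) {
  K_fil_bend * (1 - cos(theta - theta0))
}

#' Bending angle from three consecutive vertices
#' @param p1,p2,p3 3-vectors (nm); cylinders are p1->p2 and p2->p3
#' @return angle in radians
#' @export
bend_angle <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p2
  lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
  if (lu == 0 || lv == 0) stop("zero-length cylinder: bending angle undefined")
  acos(max(-1, min(1, sum(u * v) / (lu * lv))))
}

#' Motor/linker spring energy
#' @param l actual end-to-end length, nm
#' @param l0 equilibrium length (set at binding), nm
#' @param K_eff effective spring constant, pN/nm (for motors: per-head
#'   constant times head count; heads act in parallel)
#' @return energy in pN nm
#' @export
spring_energy <- function(l, l0, K_eff) 0.5 * K_eff * (l - l0)^2

#' Boundary repulsion energy at a point
#' @param d distance from the point to the mechanical boundary surface, nm
#' @param eps repulsion amplitude, pN nm
#' @param lambda screening length, nm
#' @param a0 inward shift of the barrier, nm
#' @return energy in pN nm
#' @export
boundary_energy <- function(d, eps = 100, lambda = 2.7, a0 = 100) {
  eps * exp(-(d - a0) / lambda)
}

# Gauss-Legendre nodes/weights on [0,1] (Golub-Welsch)
gauss_legendre01 <- function(n) {
  if (n == 1) return(list(x = 0.5, w = 1))
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b; J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(x = (x[ord] + 1) / 2, w = w[ord] / 2)
}

#' Excluded-volume energy of a cylinder pair
#'
#' Double line integral of the \eqn{r^{-4}} pair potential over two
#' segments, evaluated with tensor-product Gauss-Legendre quadrature.
#' Near-intersecting geometries are capped: separations below
#' \code{r_min} contribute as if at \code{r_min} (the exact integral
#' diverges for intersecting segments).
#'
#' @param a1,b1 endpoints of the first cylinder (3-vectors, nm)
#' @param a2,b2 endpoints of the second cylinder
#' @param K_vol excluded-volume constant, pN nm^4
#' @param n quadrature order per segment
#' @param r_min separation floor, nm
#' @param grad if TRUE also return gradients w.r.t. the four endpoints
#' @return energy (pN nm), or list(U, g_a1, g_b1, g_a2, g_b2)
#' @export
excluded_volume_energy <- function(a1, b1, a2, b2, K_vol = 1e5, n = 16,
                                   r_min = 1, grad = FALSE) {
  gl <- gauss_legendre01(n)
  L1v <- b1 - a1; L2v <- b2 - a2
  L1 <- sqrt(sum(L1v^2)); L2 <- sqrt(sum(L2v^2))
  s <- gl$x; w <- gl$w
  # points: n x 3 each
  X1 <- outer(1 - s, a1) + outer(s, b1)
  X2 <- outer(1 - s, a2) + outer(s, b2)
  # pairwise difference tensor via expansion
  iu <- rep(seq_len(n), times = n); iv <- rep(seq_len(n), each = n)
  Dm <- X1[iu, , drop = FALSE] - X2[iv, , drop = FALSE]
  r2 <- rowSums(Dm^2)
  capped <- r2 < r_min^2
  if (any(capped)) {
    warning("excluded volume: near-intersecting segments capped")
    r2[capped] <- r_min^2
  }
  ww <- w[iu] * w[iv]
  core <- sum(ww / r2^2)
  U <- K_vol * L1 * L2 * core
  if (!grad) return(U)
  # dU/dr contribution (capped points treated as flat: zero radial gradient)
  fac <- -4 * K_vol * L1 * L2 * ww / r2^3
  fac[capped] <- 0
  dUdX1 <- Dm * fac                      # row-wise d/dx1 of ww r^-4 term
  g_a1 <- colSums(dUdX1 * (1 - s[iu])) - K_vol * (L1v / L1) * L2 * core
  g_b1 <- colSums(dUdX1 * s[iu]) + K_vol * (L1v / L1) * L2 * core
  g_a2 <- colSums(-dUdX1 * (1 - s[iv])) - K_vol * L1 * (L2v / L2) * core
  g_b2 <- colSums(-dUdX1 * s[iv]) + K_vol * L1 * (L2v / L2) * core
  list(U = U, g_a1 = g_a1, g_b1 = g_b1, g_a2 = g_a2, g_b2 = g_b2)
}

# boundary distance + gradient of U_boundary at arbitrary points (m x 3)
# returns list(U = per-point energy sum over surfaces, G = m x 3 gradient)
boundary_field <- function(P, geom, mp) {
  eps <- mp$eps_boundary; lam <- mp$lambda_screen; a0 <- mp$a0_nm
  m <- nrow(P)
  U <- numeric(m); G <- matrix(0, m, 3)
  if (geom$shape == "oblate") {
    R <- geom$diameter_nm / 2; H2 <- geom$height_nm / 2
    r <- sqrt(P[, 1]^2 + P[, 2]^2)
    uw <- eps * exp(-(R - r - a0) / lam)
    U <- U + uw
    rr <- pmax(r, 1e-9)
    G[, 1] <- G[, 1] + uw / lam * P[, 1] / rr
    G[, 2] <- G[, 2] + uw / lam * P[, 2] / rr
    ut <- eps * exp(-(H2 - P[, 3] - a0) / lam)   # top plane
    ub <- eps * exp(-(P[, 3] + H2 - a0) / lam)   # bottom plane
    U <- U + ut + ub
    G[, 3] <- G[, 3] + ut / lam - ub / lam
  } else {
    R <- geom$diameter_nm / 2
    r <- sqrt(rowSums(P^2))
    u <- eps * exp(-(R - r - a0) / lam)
    U <- U + u
    rr <- pmax(r, 1e-9)
    G <- G + (u / lam / rr) * P
  }
  list(U = U, G = G)
}

# scatter-add rows of V into G at (possibly duplicated) indices idx
scatter_add <- function(G, idx, V) {
  r <- rowsum(V, idx)
  ii <- as.integer(rownames(r))
  G[ii, ] <- G[ii, ] + r
  G
}

# Assemble global mechanical system from state -----------------------------
# Returns P (vertices) and index structures; `vmap` maps filament id ->
# global vertex rows.
assemble_mechanics <- function(state) {
  ids <- fil_ids(state)
  nv_per <- vapply(ids, function(i) nrow(state$fil[[i]]$verts), 0L)
  off <- cumsum(c(0L, nv_per))
  P <- do.call(rbind, lapply(ids, function(i) state$fil[[i]]$verts))
  vmap <- stats::setNames(off[seq_along(ids)], ids)
  si <- sj <- integer(0); l0 <- numeric(0); segfil <- integer(0)
  b1 <- b2 <- b3 <- integer(0)
  for (k in seq_along(ids)) {
    i <- ids[k]; f <- state$fil[[i]]
    m <- length(f$nmono); o <- off[k]
    si <- c(si, o + seq_len(m)); sj <- c(sj, o + seq_len(m) + 1L)
    l0 <- c(l0, f$nmono * state$cp$monomer_size)
    segfil <- c(segfil, rep.int(i, m))
    if (m >= 2L) {
      b1 <- c(b1, o + seq_len(m - 1L))
      b2 <- c(b2, o + seq_len(m - 1L) + 1L)
      b3 <- c(b3, o + seq_len(m - 1L) + 2L)
    }
  }
  # springs
  fr <- state$cfg$site_fractions
  springs <- list()
  for (kind in c("motor", "linker")) {
    tab <- if (kind == "motor") state$motors else state$linkers
    act <- which(tab$active)
    if (!length(act)) next
    ka <- match(tab$fa[act], ids); kb <- match(tab$fb[act], ids)
    ia <- off[ka] + tab$ca[act]; ib <- off[kb] + tab$cb[act]
    springs[[kind]] <- list(
      id = act,
      i1 = ia, i2 = ia + 1L, f1 = fr[tab$sa[act]],
      j1 = ib, j2 = ib + 1L, f2 = fr[tab$sb[act]],
      l0 = tab$l0[act],
      K = if (kind == "motor")
        state$mp$K_nmii_str_per_head * tab$n_heads[act]
      else rep(state$mp$K_linker_str, length(act)))
  }
  # excluded-volume pair list (optional)
  ev_pairs <- NULL
  if (isTRUE(state$cfg$excluded_volume) && length(si) > 1L) {
    mid <- (P[si, , drop = FALSE] + P[sj, , drop = FALSE]) / 2
    len <- sqrt(rowSums((P[sj, , drop = FALSE] - P[si, , drop = FALSE])^2))
    ns <- length(si)
    cand <- which(upper.tri(matrix(TRUE, ns, ns)), arr.ind = TRUE)
    dmid <- sqrt(rowSums((mid[cand[, 1], , drop = FALSE] -
                            mid[cand[, 2], , drop = FALSE])^2))
    keep <- dmid < state$cfg$ev_cutoff_nm +
      (len[cand[, 1]] + len[cand[, 2]]) / 2
    # drop segment pairs sharing a vertex (adjacent on a filament)
    shares <- (si[cand[, 1]] == si[cand[, 2]]) |
      (si[cand[, 1]] == sj[cand[, 2]]) |
      (sj[cand[, 1]] == si[cand[, 2]]) |
      (sj[cand[, 1]] == sj[cand[, 2]])
    ev_pairs <- cand[keep & !shares, , drop = FALSE]
  }
  # combined spring arrays for the compiled kernel (kind 0 motor, 1 linker)
  sp <- list(i1 = integer(0), i2 = integer(0), f1 = numeric(0),
             j1 = integer(0), j2 = integer(0), f2 = numeric(0),
             K = numeric(0), l0 = numeric(0), kind = integer(0),
             id = integer(0))
  for (kindnm in names(springs)) {
    s <- springs[[kindnm]]
    kk <- if (kindnm == "motor") 0L else 1L
    sp$i1 <- c(sp$i1, s$i1); sp$i2 <- c(sp$i2, s$i2)
    sp$f1 <- c(sp$f1, s$f1)
    sp$j1 <- c(sp$j1, s$j1); sp$j2 <- c(sp$j2, s$j2)
    sp$f2 <- c(sp$f2, s$f2)
    sp$K <- c(sp$K, s$K); sp$l0 <- c(sp$l0, s$l0)
    sp$kind <- c(sp$kind, rep(kk, length(s$i1)))
    sp$id <- c(sp$id, s$id)
  }
  list(P = P, ids = ids, off = off, vmap = vmap,
       si = si, sj = sj, l0 = l0, segfil = segfil,
       b1 = b1, b2 = b2, b3 = b3, springs = springs, sp = sp,
       ev_pairs = ev_pairs)
}

# Total energy and gradient of the assembled system (compiled kernel for
# stretch/bend/springs/boundary; optional excluded volume added in R).
# Returns list(Ubr = named breakdown, U = total, G = gradient, tensions).
energy_gradient <- function(P, sys, state, want_grad = TRUE) {
  sp <- sys$sp
  r <- .energy_gradient_cpp(P, sys$si, sys$sj, sys$l0,
                            sys$b1, sys$b2, sys$b3,
                            sp$i1, sp$i2, sp$f1, sp$j1, sp$j2, sp$f2,
                            sp$K, sp$l0, sp$kind,
                            state$mp$K_fil_str, state$mp$K_fil_bend,
                            if (state$geom$shape == "oblate") 0L else 1L,
                            state$geom$diameter_nm / 2,
                            if (state$geom$shape == "oblate")
                              state$geom$height_nm / 2 else 0,
                            state$mp$eps_boundary, state$mp$lambda_screen,
                            state$mp$a0_nm, want_grad)
  G <- if (want_grad) r$G else NULL
  U_vol <- 0
  if (!is.null(sys$ev_pairs) && nrow(sys$ev_pairs)) {
    for (rr in seq_len(nrow(sys$ev_pairs))) {
      s1 <- sys$ev_pairs[rr, 1]; s2 <- sys$ev_pairs[rr, 2]
      ev <- excluded_volume_energy(P[sys$si[s1], ], P[sys$sj[s1], ],
                                   P[sys$si[s2], ], P[sys$sj[s2], ],
                                   K_vol = state$mp$K_vol,
                                   grad = want_grad)
      if (want_grad) {
        U_vol <- U_vol + ev$U
        G[sys$si[s1], ] <- G[sys$si[s1], ] + ev$g_a1
        G[sys$sj[s1], ] <- G[sys$sj[s1], ] + ev$g_b1
        G[sys$si[s2], ] <- G[sys$si[s2], ] + ev$g_a2
        G[sys$sj[s2], ] <- G[sys$sj[s2], ] + ev$g_b2
      } else U_vol <- U_vol + ev
    }
  }
  tensions <- list(motor = NULL, linker = NULL)
  if (length(sp$kind)) {
    for (kk in c(0L, 1L)) {
      w <- sp$kind == kk
      if (any(w))
        tensions[[kk + 1L]] <- stats::setNames(r$tension[w], sp$id[w])
    }
  }
  Ubr <- c(U_fil_str = r$U_str, U_fil_bend = r$U_bend, U_vol = U_vol,
           U_motor_str = r$U_motor, U_linker_str = r$U_linker,
           U_boundary = r$U_bdy)
  list(Ubr = Ubr, U = sum(Ubr), G = G, tensions = tensions)
}

# Pure-R reference implementation of the same energies and gradients
# (kept as the independent cross-check for the compiled kernel).
energy_gradient_r <- function(P, sys, state, want_grad = TRUE) {
  mp <- state$mp; geom <- state$geom
  G <- if (want_grad) matrix(0, nrow(P), 3) else NULL
  # stretching
  D <- P[sys$sj, , drop = FALSE] - P[sys$si, , drop = FALSE]
  l <- sqrt(.rowSums(D * D, nrow(D), 3L))
  u <- D / l
  dl <- l - sys$l0
  U_str <- 0.5 * mp$K_fil_str * sum(dl * dl)
  if (want_grad) {
    fvec <- mp$K_fil_str * dl * u
    G[sys$sj, ] <- G[sys$sj, ] + fvec
    G[sys$si, ] <- G[sys$si, ] - fvec
  }
  # bending
  U_bend <- 0
  if (length(sys$b1)) {
    uv <- P[sys$b2, , drop = FALSE] - P[sys$b1, , drop = FALSE]
    vv <- P[sys$b3, , drop = FALSE] - P[sys$b2, , drop = FALSE]
    lu <- sqrt(.rowSums(uv * uv, nrow(uv), 3L))
    lv <- sqrt(.rowSums(vv * vv, nrow(vv), 3L))
    dot <- .rowSums(uv * vv, nrow(uv), 3L)
    co <- pmax(-1, pmin(1, dot / (lu * lv)))
    U_bend <- mp$K_fil_bend * sum(1 - co)
    if (want_grad) {
      dcu <- vv / (lu * lv) - co / lu^2 * uv
      dcv <- uv / (lu * lv) - co / lv^2 * vv
      K <- mp$K_fil_bend
      G[sys$b1, ] <- G[sys$b1, ] + K * dcu
      G[sys$b2, ] <- G[sys$b2, ] + K * (dcv - dcu)
      G[sys$b3, ] <- G[sys$b3, ] - K * dcv
    }
  }
  # springs
  U_motor <- 0; U_linker <- 0
  tensions <- list(motor = NULL, linker = NULL)
  for (kind in names(sys$springs)) {
    sp <- sys$springs[[kind]]
    pa <- (1 - sp$f1) * P[sp$i1, , drop = FALSE] +
      sp$f1 * P[sp$i2, , drop = FALSE]
    pb <- (1 - sp$f2) * P[sp$j1, , drop = FALSE] +
      sp$f2 * P[sp$j2, , drop = FALSE]
    dd <- pb - pa
    ll <- sqrt(rowSums(dd^2))
    tt <- sp$K * (ll - sp$l0)            # signed tension, + = stretched
    Uel <- 0.5 * sp$K * (ll - sp$l0)^2
    if (kind == "motor") U_motor <- sum(Uel) else U_linker <- sum(Uel)
    tensions[[kind]] <- stats::setNames(tt, sp$id)
    if (want_grad) {
      fv <- tt / pmax(ll, 1e-12) * dd    # dU/d pb
      G <- scatter_add(G, sp$j1, (1 - sp$f2) * fv)
      G <- scatter_add(G, sp$j2, sp$f2 * fv)
      G <- scatter_add(G, sp$i1, -(1 - sp$f1) * fv)
      G <- scatter_add(G, sp$i2, -sp$f1 * fv)
    }
  }
  # boundary: 3 samples per cylinder (both endpoints + midpoint)
  ns <- length(sys$si)
  Pi <- P[sys$si, , drop = FALSE]; Pj <- P[sys$sj, , drop = FALSE]
  bf <- boundary_field(rbind(Pi, Pj, (Pi + Pj) / 2), geom, mp)
  U_bdy <- sum(bf$U)
  if (want_grad) {
    i1 <- seq_len(ns)
    Gm <- bf$G[2L * ns + i1, , drop = FALSE]
    G[sys$si, ] <- G[sys$si, ] + bf$G[i1, , drop = FALSE] + 0.5 * Gm
    G[sys$sj, ] <- G[sys$sj, ] + bf$G[ns + i1, , drop = FALSE] + 0.5 * Gm
  }
  # excluded volume
  U_vol <- 0
  if (!is.null(sys$ev_pairs) && nrow(sys$ev_pairs)) {
    for (r in seq_len(nrow(sys$ev_pairs))) {
      s1 <- sys$ev_pairs[r, 1]; s2 <- sys$ev_pairs[r, 2]
      ev <- excluded_volume_energy(P[sys$si[s1], ], P[sys$sj[s1], ],
                                   P[sys$si[s2], ], P[sys$sj[s2], ],
                                   K_vol = mp$K_vol, grad = want_grad)
      if (want_grad) {
        U_vol <- U_vol + ev$U
        G[sys$si[s1], ] <- G[sys$si[s1], ] + ev$g_a1
        G[sys$sj[s1], ] <- G[sys$sj[s1], ] + ev$g_b1
        G[sys$si[s2], ] <- G[sys$si[s2], ] + ev$g_a2
        G[sys$sj[s2], ] <- G[sys$sj[s2], ] + ev$g_b2
      } else U_vol <- U_vol + ev
    }
  }
  Ubr <- c(U_fil_str = U_str, U_fil_bend = U_bend, U_vol = U_vol,
           U_motor_str = U_motor, U_linker_str = U_linker,
           U_boundary = U_bdy)
  list(Ubr = Ubr, U = sum(Ubr), G = G, tensions = tensions)
}

# FIRE (fast inertial relaxation engine) on the assembled coordinates.
fire_minimize <- function(P, efun, tol = 1, maxit = 5000,
                          dt0 = 2e-3, dtmax = 2e-2, maxstep = 5) {
  n_min <- 5L; f_inc <- 1.1; f_dec <- 0.5; a0 <- 0.1; f_a <- 0.99
  v <- matrix(0, nrow(P), 3)
  dt <- dt0; alpha <- a0; n_pos <- 0L
  eg <- efun(P)
  bestU <- eg$U; bestP <- P
  converged <- max(abs(eg$G)) <= tol
  it <- 0L
  while (!converged && it < maxit) {
    it <- it + 1L
    Fm <- -eg$G
    v <- v + dt * Fm
    p <- sum(Fm * v)
    if (p > 0) {
      n_pos <- n_pos + 1L
      nv <- sqrt(sum(v^2)); nf <- sqrt(sum(Fm^2))
      if (nf > 0) v <- (1 - alpha) * v + alpha * nv / nf * Fm
      if (n_pos > n_min) { dt <- min(dt * f_inc, dtmax); alpha <- alpha * f_a }
    } else {
      v[] <- 0; dt <- dt * f_dec; alpha <- a0; n_pos <- 0L
    }
    step <- dt * v
    mx <- max(abs(step))
    if (mx > maxstep) step <- step * (maxstep / mx)
    P <- P + step
    eg <- efun(P)
    if (eg$U < bestU) { bestU <- eg$U; bestP <- P }
    converged <- max(abs(eg$G)) <= tol
  }
  if (!converged) { P <- bestP; eg <- efun(P) }
  list(P = P, eg = eg, iterations = it, converged = converged)
}

# L-BFGS-B minimization.  fn/gr take the flattened coordinate vector;
# fngr(x) must return list(U =, Gv = flat gradient).  A last-point cache
# lets the gradient reuse the objective evaluation.
lbfgs_minimize <- function(P, fngr, tol = 1, maxit = 5000) {
  dm <- dim(P)
  cache <- new.env(parent = emptyenv())
  cache$x <- NULL
  ev <- function(x) {
    if (!identical(x, cache$x)) {
      cache$eg <- fngr(x)
      cache$x <- x
    }
    cache$eg
  }
  res <- stats::optim(as.vector(P), function(x) ev(x)$U,
                      function(x) ev(x)$Gv, method = "L-BFGS-B",
                      control = list(maxit = maxit, pgtol = tol,
                                     factr = 100, lmm = 10))
  P1 <- matrix(res$par, dm[1], dm[2])
  eg <- fngr(res$par)
  list(P = P1, U = eg$U, Gv = eg$Gv,
       iterations = res$counts[[1]],
       converged = max(abs(eg$Gv)) <= tol || res$convergence == 0)
}

#' Minimize the mechanical energy of the network
#'
#' Relaxes all vertex coordinates until the largest force component falls
#' below \code{state$cfg$fire_tol} (pN) or the iteration cap is reached
#' (best-so-far configuration returned in that case).  The default
#' algorithm is L-BFGS-B with analytic gradients; FIRE (fast inertial
#' relaxation) is available via \code{config = list(minimizer = "fire")}.
#' Chemistry-owned quantities (monomer counts, topology, bound elements)
#' are untouched.  Also computes the post-minimization force field
#' consumed by the mechanochemical rate laws: signed motor/linker
#' tensions and the boundary load on each filament end.
#'
#' @param state an \code{acto_state} (modified in place)
#' @return invisibly, a list with \code{energy} (named breakdown including
#'   \code{U_total}), \code{tensions}, \code{end_loads} (per filament id:
#'   \code{be}, \code{pe} compressive loads in pN), \code{converged},
#'   \code{iterations}
#' @export
minimize_state <- function(state) {
  ids <- fil_ids(state)
  if (!length(ids)) {
    state$energy <- c(U_fil_str = 0, U_fil_bend = 0, U_vol = 0,
                      U_motor_str = 0, U_linker_str = 0, U_boundary = 0,
                      U_total = 0)
    return(invisible(list(energy = state$energy, tensions = NULL,
                          end_loads = NULL, converged = TRUE,
                          iterations = 0L)))
  }
  cache <- mget("mech_cache", envir = state, ifnotfound = list(NULL))[[1]]
  if (!is.null(cache) && cache$topo == state$topo) {
    # topology unchanged since the last minimization: reuse the assembled
    # system; only rest lengths (monomer counts) may have changed
    sys <- cache$sys
    sys$l0 <- unlist(lapply(sys$ids,
                            function(i) state$fil[[i]]$nmono),
                     use.names = FALSE) * state$cp$monomer_size
  } else {
    sys <- assemble_mechanics(state)
  }
  res <- if (identical(state$cfg$minimizer, "fire")) {
    efun <- function(P) energy_gradient(P, sys, state)
    fire_minimize(sys$P, efun, tol = state$cfg$fire_tol,
                  maxit = state$cfg$fire_maxit,
                  dt0 = state$cfg$fire_dt0,
                  dtmax = state$cfg$fire_dtmax,
                  maxstep = state$cfg$fire_maxstep)
  } else if (is.null(sys$ev_pairs) || !nrow(sys$ev_pairs)) {
    # fully compiled L-BFGS path (no excluded volume)
    sp <- sys$sp; mp <- state$mp; geom <- state$geom
    r <- .lbfgs_min_cpp(sys$P, sys$si, sys$sj, sys$l0,
                        sys$b1, sys$b2, sys$b3,
                        sp$i1, sp$i2, sp$f1, sp$j1, sp$j2, sp$f2,
                        sp$K, sp$l0, sp$kind,
                        mp$K_fil_str, mp$K_fil_bend,
                        if (geom$shape == "oblate") 0L else 1L,
                        geom$diameter_nm / 2,
                        if (geom$shape == "oblate") geom$height_nm / 2
                        else 0,
                        mp$eps_boundary, mp$lambda_screen, mp$a0_nm,
                        state$cfg$fire_tol, state$cfg$fire_maxit)
    list(P = r$P, iterations = r$evals, converged = r$converged)
  } else {
    nv <- nrow(sys$P)
    fngr <- function(x) {
      eg <- energy_gradient(matrix(x, nv, 3L), sys, state)
      list(U = eg$U, Gv = as.vector(eg$G))
    }
    lbfgs_minimize(sys$P, fngr, tol = state$cfg$fire_tol,
                   maxit = state$cfg$fire_maxit)
  }
  # scatter coordinates back
  for (k in seq_along(sys$ids)) {
    i <- sys$ids[k]
    nvk <- nrow(state$fil[[i]]$verts)
    state$fil[[i]]$verts <- res$P[sys$off[k] + seq_len(nvk), , drop = FALSE]
  }
  sys$P <- res$P
  state$mech_cache <- list(topo = state$topo, sys = sys)
  eg <- energy_gradient(res$P, sys, state)
  state$energy <- c(eg$Ubr, U_total = eg$U)
  # boundary loads on filament ends (single-point boundary gradient,
  # projected on the outward growth direction of that end), vectorized
  # over all filaments
  nf <- length(sys$ids)
  Vbe <- matrix(0, nf, 3); Vbe2 <- matrix(0, nf, 3)
  Vpe <- matrix(0, nf, 3); Vpe2 <- matrix(0, nf, 3)
  for (k in seq_len(nf)) {
    V <- state$fil[[sys$ids[k]]]$verts
    nv <- nrow(V)
    Vbe[k, ] <- V[nv, ]; Vbe2[k, ] <- V[nv - 1L, ]
    Vpe[k, ] <- V[1L, ]; Vpe2[k, ] <- V[2L, ]
  }
  gb <- boundary_field(rbind(Vbe, Vpe), state$geom, state$mp)$G
  ub <- Vbe - Vbe2
  ub <- ub / sqrt(.rowSums(ub * ub, nf, 3L))
  up <- Vpe - Vpe2
  up <- up / sqrt(.rowSums(up * up, nf, 3L))
  be_load <- pmax(0, .rowSums(gb[seq_len(nf), , drop = FALSE] * ub, nf, 3L))
  pe_load <- pmax(0, .rowSums(gb[nf + seq_len(nf), , drop = FALSE] * up,
                              nf, 3L))
  end_loads <- lapply(seq_len(nf), function(k)
    c(be = be_load[k], pe = pe_load[k]))
  names(end_loads) <- as.character(sys$ids)
  invisible(list(energy = state$energy, tensions = eg$tensions,
                 end_loads = end_loads, converged = res$converged,
                 iterations = res$iterations))
}
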