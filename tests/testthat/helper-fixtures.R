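# Shared fixtures and independent oracles for the test suite.

sfil <- actoring:::straight_filament
addf <- actoring:::add_filament
scat <- actoring:::grid_scatter
gtot <- actoring:::grid_total

# small oblate state with optional species copies
tiny_state <- function(diameter = 1200, height = 400, config = list(),
                       cp = chem_params()) {
  new_state(boundary_geometry("oblate", diameter, height),
            cp = cp, config = config)
}

# two parallel filaments separated by `gap` nm (along y), length in monomers
two_parallel <- function(state, gap, n_monomers = 80, y0 = 0) {
  sf1 <- sfil(c(-n_monomers * 2.7 / 2, y0, 0), c(1, 0, 0), n_monomers)
  sf2 <- sfil(c(-n_monomers * 2.7 / 2, y0 + gap, 0), c(1, 0, 0), n_monomers)
  c(addf(state, sf1$verts, sf1$nmono), addf(state, sf2$verts, sf2$nmono))
}

# chemistry parameter set with everything switched off except `keep`
quiet_chem <- function(...) {
  args <- list(...)
  base <- list(D_diff = 0, k_on_BE = 0, k_on_PE = 0, k_off_BE = 0,
               k_off_PE = 0, k_destruction = 0, k_nu = 0,
               k_off_formin = 0, k_on_linker = 0, k_off_linker = 0,
               k_on_head = 0, k_off_head = 0, k_walk0 = 0)
  do.call(chem_params, utils::modifyList(base, args))
}

# direct SSA (Gillespie first-reaction by total-propensity) oracle
direct_ssa_step <- function(a) {
  atot <- sum(a)
  if (atot <= 0) return(list(tau = Inf, j = NA_integer_))
  tau <- stats::rexp(1, atot)
  j <- sample.int(length(a), 1L, prob = a)
  list(tau = tau, j = j)
}

# brute-force all-pairs binding-site scan (oracle for find_binding_pairs)
brute_pairs <- function(state, species) {
  win <- if (species == "motor") state$cfg$motor_span else
    state$cfg$linker_span
  st <- actoring:::collect_sites(state, species)
  n <- nrow(st$pos)
  res <- NULL
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (st$fil[i] == st$fil[j]) next
      d <- sqrt(sum((st$pos[i, ] - st$pos[j, ])^2))
      if (d >= win[1] && d <= win[2])
        res <- rbind(res, data.frame(fa = st$fil[i], ca = st$cyl[i],
                                     sa = st$site[i], fb = st$fil[j],
                                     cb = st$cyl[j], sb = st$site[j],
                                     dist = d))
    }
  }
  if (is.null(res))
    return(data.frame(fa = integer(0), ca = integer(0), sa = integer(0),
                      fb = integer(0), cb = integer(0), sb = integer(0),
                      dist = numeric(0)))
  flip <- res$fa > res$fb |
    (res$fa == res$fb & (res$ca > res$cb |
                           (res$ca == res$cb & res$sa > res$sb)))
  if (any(flip)) {
    tmp <- res[flip, c("fb", "cb", "sb", "fa", "ca", "sa", "dist")]
    names(tmp) <- names(res)
    res[flip, ] <- tmp
  }
  res <- res[order(res$fa, res$ca, res$sa, res$fb, res$cb, res$sb), ]
  rownames(res) <- NULL
  res
}

# independent connected-component labeling by union-find (4-connectivity)
uf_components <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  parent <- seq_len(n * m)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  for (j in seq_len(m)) for (i in seq_len(n)) {
    if (!mask[i, j]) next
    p <- (j - 1L) * n + i
    if (i > 1L && mask[i - 1L, j]) union(p, p - 1L)
    if (j > 1L && mask[i, j - 1L]) union(p, p - n)
  }
  lab <- matrix(0L, n, m)
  roots <- integer(0)
  for (p in which(as.vector(mask))) {
    r <- find(p)
    k <- match(r, roots)
    if (is.na(k)) { roots <- c(roots, r); k <- length(roots) }
    lab[p] <- k
  }
  lab
}

# finite-difference gradient of the assembled system (central differences)
fd_gradient <- function(state, P, sys, h = 1e-5) {
  G <- matrix(0, nrow(P), 3)
  for (k in seq_along(P)) {
    P1 <- P; P1[k] <- P1[k] + h
    P2 <- P; P2[k] <- P2[k] - h
    G[k] <- (actoring:::energy_gradient(P1, sys, state, want_grad = FALSE)$U -
             actoring:::energy_gradient(P2, sys, state,
                                        want_grad = FALSE)$U) / (2 * h)
  }
  G
}
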