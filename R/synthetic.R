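# Synthetic fixtures -----------------------------------------------------
#
# Ground-truth generators: network snapshots with prescribed morphology
# (uniform disk / annular ring / compact clusters), TIRF-like rendered
# intensity images, and synthetic end-event logs.  These exercise every
# analysis and image operation without running the simulator; they make no
# attempt at mechanical plausibility (no minimization).

#' Specification of a synthetic morphology
#'
#' @param kind "uniform", "ring" or "clusters"
#' @param geometry a \code{\link{boundary_geometry}}
#' @param n_monomers total polymerized monomers to place
#' @param fil_monomers monomers per filament (default one full cylinder,
#'   decoupling morphology tests from mechanics)
#' @param ring_radius_frac ring center radius as fraction of the
#'   effective radius
#' @param ring_width_nm radial Gaussian width of the ring, nm
#' @param n_clusters number of clusters
#' @param cluster_sigma_nm isotropic Gaussian width of each cluster, nm
#' @param cluster_centers optional k x 2 matrix of centers (nm); random
#'   inside half the radius otherwise
#' @param seed RNG seed (fully determines the fixture)
#' @return list of class \code{"morphology_spec"}
#' @export
morphology_spec <- function(kind = c("uniform", "ring", "clusters"),
                            geometry = boundary_geometry(),
                            n_monomers = 20000L, fil_monomers = 40L,
                            ring_radius_frac = 0.9, ring_width_nm = 50,
                            n_clusters = 3L, cluster_sigma_nm = 150,
                            cluster_centers = NULL, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_monomers > 0, fil_monomers >= 2L,
            ring_radius_frac > 0, ring_radius_frac <= 1,
            ring_width_nm >= 0, cluster_sigma_nm > 0)
  structure(as.list(environment()), class = "morphology_spec")
}

#' Generate a snapshot with prescribed morphology
#'
#' Places straight filaments according to the morphology: uniform specs
#' scatter centers area-uniformly with random in-plane orientation; ring
#' specs draw center radii from a Gaussian around the ring radius and
#' orient filaments tangentially; cluster specs scatter centers around
#' cluster seeds isotropically.  All mass stays inside the effective
#' boundary.
#'
#' @param spec a \code{\link{morphology_spec}}
#' @return an \code{acto_snapshot}
#' @export
make_snapshot <- function(spec) {
  set.seed(spec$seed)
  geom <- spec$geometry
  R <- geom$R_eff
  zh <- if (geom$shape == "oblate") geom$half_height_eff else R / 4
  n_fil <- max(1L, round(spec$n_monomers / spec$fil_monomers))
  fl <- spec$fil_monomers * 2.7
  margin <- fl / 2 + 5
  if (margin >= R) stop("infeasible: filament longer than the volume")
  # a tangential chord with center radius rc stays inside the disk iff
  # rc <= sqrt(R^2 - (L/2)^2); arbitrary orientations need rc <= R - L/2
  r_tang <- sqrt(max(0, R^2 - (fl / 2)^2)) - 1
  fils <- vector("list", n_fil)
  for (k in seq_len(n_fil)) {
    if (spec$kind == "uniform") {
      # centers area-uniform over the full disk; near the rim the
      # filament is laid tangentially so no mass leaves the boundary
      r <- r_tang * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      if (r <= R - margin) {
        u2 <- stats::runif(1, 0, 2 * pi)
        u <- c(cos(u2), sin(u2), 0)
      } else {
        u <- c(-sin(th), cos(th), 0)
        if (stats::runif(1) < 0.5) u <- -u
      }
    } else if (spec$kind == "ring") {
      r <- spec$ring_radius_frac * R + stats::rnorm(1, 0, spec$ring_width_nm)
      r <- max(0, min(r_tang, r))
      th <- stats::runif(1, 0, 2 * pi)
      u <- c(-sin(th), cos(th), 0)          # tangential
      if (stats::runif(1) < 0.5) u <- -u
    } else {
      ctrs <- spec$cluster_centers
      if (is.null(ctrs)) {
        rr <- R / 2 * sqrt(stats::runif(spec$n_clusters))
        aa <- stats::runif(spec$n_clusters, 0, 2 * pi)
        ctrs <- cbind(rr * cos(aa), rr * sin(aa))
        spec$cluster_centers <- ctrs
      }
      ci <- sample.int(nrow(ctrs), 1L)
      repeat {
        off <- stats::rnorm(2, 0, spec$cluster_sigma_nm)
        p2 <- ctrs[ci, ] + off
        if (sqrt(sum(p2^2)) <= R - margin) break
      }
      r <- sqrt(sum(p2^2)); th <- atan2(p2[2], p2[1])
      u2 <- stats::runif(1, 0, 2 * pi)
      u <- c(cos(u2), sin(u2), 0)
    }
    c0 <- c(r * cos(th), r * sin(th), stats::runif(1, -zh * 0.9, zh * 0.9))
    sf <- straight_filament(c0 - u * fl / 2, u, spec$fil_monomers)
    fils[[k]] <- list(verts = sf$verts, nmono = sf$nmono, barbed = "BE")
  }
  snap <- list(time = 0, filaments = fils, n_filaments = n_fil,
               motors = data.frame(), linkers = data.frame(),
               grid_counts = NULL,
               counters = c(be_add = 0, be_rem = 0, pe_add = 0,
                            pe_rem = 0, nuc = 0, destr = 0,
                            forced_unbind = 0),
               energy = NULL, labeled = NULL, geom = geom)
  class(snap) <- "acto_snapshot"
  snap
}

#' Rendering specification for TIRF-like images
#'
#' @param pixel_nm pixel size, nm
#' @param psf_sigma_nm Gaussian point-spread-function sigma, nm
#' @param photons_per_monomer expected photon count per monomer
#' @param background expected background photons per pixel
#' @param bleach_rate per-frame multiplicative intensity decay (0 = none)
#' @return list of class \code{"render_spec"}
#' @export
render_spec <- function(pixel_nm = 100, psf_sigma_nm = 150,
                        photons_per_monomer = 5, background = 2,
                        bleach_rate = 0) {
  stopifnot(pixel_nm > 0, psf_sigma_nm >= 0, photons_per_monomer >= 0,
            background >= 0, bleach_rate >= 0)
  structure(as.list(environment()), class = "render_spec")
}

#' Render a snapshot as a noisy intensity image
#'
#' Monomer positions are binned to pixels, convolved with a Gaussian PSF,
#' scaled to expected photons, Poisson shot noise is applied, and a flat
#' background added.  Expected integrated signal is proportional to the
#' total polymerized actin.
#'
#' @param snapshot an \code{acto_snapshot}
#' @param rs a \code{\link{render_spec}}
#' @param frame frame index (applies \code{bleach_rate} as
#'   \code{(1-rate)^(frame-1)})
#' @param noise apply Poisson noise (disable for PSF checks)
#' @return an \code{intensity_image} (list with \code{img} matrix rows =
#'   x, cols = y, and \code{pixel_nm})
#' @export
render_image <- function(snapshot, rs = render_spec(), frame = 1L,
                         noise = TRUE) {
  if (rs$pixel_nm <= 0) stop("pixel size must be positive")
  P <- snapshot_monomer_xy(snapshot)
  R <- snapshot$geom$R_eff
  ext <- R * 1.15
  np <- as.integer(ceiling(2 * ext / rs$pixel_nm))
  bx <- -ext + (0:np) * rs$pixel_nm
  ix <- pmin(np, pmax(1L, findInterval(P[, 1], bx, rightmost.closed = TRUE)))
  iy <- pmin(np, pmax(1L, findInterval(P[, 2], bx, rightmost.closed = TRUE)))
  img <- matrix(0, np, np)
  for (k in seq_along(ix)) img[ix[k], iy[k]] <- img[ix[k], iy[k]] + 1
  if (rs$psf_sigma_nm > 0)
    img <- gaussian_blur(img, rs$psf_sigma_nm / rs$pixel_nm)
  fade <- (1 - rs$bleach_rate)^(frame - 1L)
  expected <- img * rs$photons_per_monomer * fade + rs$background
  out <- if (noise)
    matrix(stats::rpois(length(expected), expected), np, np)
  else expected
  structure(list(img = out, pixel_nm = rs$pixel_nm,
                 center_px = c((1 + np) / 2, (1 + np) / 2)),
            class = "intensity_image")
}

# separable Gaussian convolution (reflective padding), sigma in pixels
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  hw <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-hw:hw, sd = sigma_px)
  k <- k / sum(k)
  pad_conv <- function(M) {
    n <- nrow(M)
    Mp <- rbind(M[hw:1, , drop = FALSE], M, M[n:(n - hw + 1L), , drop = FALSE])
    out <- matrix(0, n, ncol(M))
    for (d in -hw:hw)
      out <- out + k[d + hw + 1L] * Mp[(1 + hw + d):(n + hw + d), ,
                                       drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Generate a synthetic end-event log
#'
#' Produces a minimal trajectory whose snapshots carry cumulative
#' barbed-end addition and pointed-end removal counters drawn as Poisson
#' streams at the prescribed per-filament rates, for testing the
#' treadmilling-rate estimator.
#'
#' @param be_rate,pe_rate per-filament event rates, s^-1 (>= 0)
#' @param n_filaments constant filament count
#' @param t_total duration, s
#' @param dt snapshot interval, s
#' @param seed RNG seed
#' @return an \code{acto_trajectory}-like list
#' @export
make_event_log <- function(be_rate, pe_rate, n_filaments = 10L,
                           t_total = 1000, dt = 1, seed = 1L) {
  if (be_rate < 0 || pe_rate < 0) stop("rates must be nonnegative")
  set.seed(seed)
  tms <- seq(0, t_total, by = dt)
  n <- length(tms)
  be <- cumsum(c(0, stats::rpois(n - 1L, be_rate * n_filaments * dt)))
  pe <- cumsum(c(0, stats::rpois(n - 1L, pe_rate * n_filaments * dt)))
  snaps <- lapply(seq_len(n), function(i) {
    s <- list(time = tms[i], n_filaments = n_filaments,
              counters = c(be_add = be[i], be_rem = 0, pe_add = 0,
                           pe_rem = pe[i], nuc = 0, destr = 0,
                           forced_unbind = 0),
              filaments = list(), energy = NULL, labeled = NULL)
    class(s) <- "acto_snapshot"
    s
  })
  structure(list(snapshots = snaps, config = NULL, status = "synthetic"),
            class = "acto_trajectory")
}

#' Generate a synthetic turnover (FRAP-like) trajectory
#'
#' Labeled-monomer counts decay exponentially at the given rate, for
#' testing the turnover-halftime estimator against the analytic half-life
#' \eqn{\ln 2 / k}.
#'
#' @param k turnover rate, s^-1
#' @param n0 initially labeled monomers
#' @param t_total duration, s
#' @param dt snapshot interval, s
#' @return an \code{acto_trajectory}-like list
#' @export
make_turnover_log <- function(k, n0 = 10000L, t_total = 500, dt = 1) {
  tms <- seq(0, t_total, by = dt)
  snaps <- lapply(tms, function(t) {
    s <- list(time = t, n_filaments = 1L,
              counters = c(be_add = 0, be_rem = 0, pe_add = 0, pe_rem = 0,
                           nuc = 0, destr = 0, forced_unbind = 0),
              filaments = list(),
              labeled = c(n = round(n0 * exp(-k * t)), n0 = n0),
              energy = NULL)
    class(s) <- "acto_snapshot"
    s
  })
  structure(list(snapshots = snaps, config = NULL, status = "synthetic"),
            class = "acto_trajectory")
}
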