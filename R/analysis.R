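# Morphology and kinetics quantification ---------------------------------
#
# Readouts computed from simulation snapshots/trajectories: the radial
# density profile and its normalized median (R_median, the order parameter
# separating centripetal clusters from peripheral rings), remodeling
# speed, treadmilling rate, FRAP-like turnover halftime, grid-based
# cluster detection with local concentrations, filament orientation, and
# the mechanical energy U_Mech.

snapshot_monomer_xy <- function(snapshot) {
  P <- monomer_positions(snapshot$filaments)
  if (is.null(P) || nrow(P) == 0L) stop("empty snapshot")
  P
}

#' Radial filament density profile
#'
#' Assigns every polymerized monomer to a radial bin by its in-plane
#' distance from the volume center (normalized by the effective radius),
#' normalizes per unit annulus area, and rescales so the profile
#' integrates to 1 over r in [0, 1].
#'
#' @param snapshot an \code{acto_snapshot}
#' @param n_bins number of radial bins
#' @return data.frame with \code{r} (bin centers, fraction of effective
#'   radius) and \code{rho}
#' @export
radial_density <- function(snapshot, n_bins = 50L) {
  P <- snapshot_monomer_xy(snapshot)
  R <- snapshot$geom$R_eff
  r <- sqrt(P[, 1]^2 + P[, 2]^2) / R
  br <- seq(0, 1, length.out = n_bins + 1L)
  cnt <- tabulate(pmin(n_bins, findInterval(pmin(r, 1), br,
                                            rightmost.closed = TRUE)),
                  nbins = n_bins)
  ctr <- (br[-1] + br[-(n_bins + 1L)]) / 2
  area <- pi * (br[-1]^2 - br[-(n_bins + 1L)]^2)
  rho <- cnt / area
  dw <- diff(br)
  rho <- rho / sum(rho * dw)
  data.frame(r = ctr, rho = rho)
}

#' Normalized median of the radial filament distribution
#'
#' The median in-plane radius of all polymerized monomers divided by the
#' effective radius: near \eqn{1/\sqrt 2} for a uniform disk, near 1 for a
#' peripheral ring, near 0 for a central cluster.
#'
#' @param snapshot an \code{acto_snapshot}
#' @return dimensionless value in [0, 1]
#' @export
r_median <- function(snapshot) {
  P <- snapshot_monomer_xy(snapshot)
  stats::median(sqrt(P[, 1]^2 + P[, 2]^2)) / snapshot$geom$R_eff
}

#' R_median time series of a trajectory
#' @param traj an \code{acto_trajectory}
#' @return data.frame with \code{time} and \code{r_median}
#' @export
r_median_series <- function(traj) {
  keep <- vapply(traj$snapshots, function(s) length(s$filaments) > 0, TRUE)
  data.frame(
    time = vapply(traj$snapshots[keep], `[[`, 0, "time"),
    r_median = vapply(traj$snapshots[keep], r_median, 0))
}

#' Network remodeling rate from an R_median series
#'
#' Least-squares slope over the detected linear segment of the series
#' after \code{window_start}: the longest contiguous window of at least
#' \code{min_len} seconds whose linear fit has \eqn{R^2 \ge} \code{r2_min}
#' (constant stretches count as linear).  Positive slopes indicate
#' centrifugal remodeling (toward the boundary), negative centripetal
#' collapse.
#'
#' @param series data.frame with columns \code{time} and \code{r_median}
#' @param window_start only times >= this enter the detection, s
#' @param r2_min minimum R^2 of the accepted fit
#' @param min_len minimum window length, s
#' @return list with \code{slope} (s^-1), \code{window} (start/end times),
#'   \code{r_squared}
#' @export
remodeling_rate <- function(series, window_start = 300, r2_min = 0.9,
                            min_len = 50) {
  d <- series[series$time >= window_start, ]
  if (nrow(d) < 10L) stop("series too short (need >= 10 points)")
  t <- d$time; y <- d$r_median
  n <- length(t)
  fit_stats <- function(i, j) {
    tt <- t[i:j]; yy <- y[i:j]
    mx <- mean(tt); my <- mean(yy)
    sxx <- sum((tt - mx)^2); sxy <- sum((tt - mx) * (yy - my))
    syy <- sum((yy - my)^2)
    b <- sxy / sxx
    r2 <- if (syy < 1e-300) 1 else (sxy^2 / (sxx * syy))
    se_b <- if (j - i > 1L)
      sqrt(max(0, (syy - b * sxy) / (j - i - 1L)) / sxx) else 0
    c(b, r2, se_b)
  }
  # a window is linear if its fit explains the variance AND the slope is
  # stationary across its two halves (rejects ramp-plus-plateau windows
  # that a bare R^2 criterion would accept)
  window_ok <- function(i, j, fs) {
    if (fs[2] < r2_min) return(FALSE)
    mid <- (i + j) %/% 2L
    if (mid <= i || mid >= j) return(TRUE)
    f1 <- fit_stats(i, mid); f2 <- fit_stats(mid, j)
    # noise allowance from the half-window fits (their residuals are free
    # of the across-window curvature being tested)
    abs(f1[1] - f2[1]) <= max(0.05 * abs(fs[1]),
                              4 * max(f1[3], f2[3]), 1e-12)
  }
  best <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in seq(n, i + 1L)) {
      if (t[j] - t[i] < min_len) break
      fs <- fit_stats(i, j)
      if (window_ok(i, j, fs)) {
        if (is.null(best) || (t[j] - t[i]) > (best$window[2] -
                                                best$window[1])) {
          best <- list(slope = fs[1], window = c(t[i], t[j]),
                       r_squared = fs[2])
        }
        break  # longest window starting at i found
      }
    }
  }
  if (is.null(best)) {
    fs <- fit_stats(1L, n)   # no segment passes: full-series fit, flagged
    best <- list(slope = fs[1], window = c(t[1], t[n]), r_squared = fs[2])
    best$linear_segment_found <- FALSE
  } else best$linear_segment_found <- TRUE
  best
}

#' Treadmilling rate from trajectory end-event counters
#'
#' The mean barbed-end monomer addition rate per filament over
#' \code{[t_start, end]}: cumulative barbed-end additions divided by
#' duration times the time-averaged filament count; the pointed-end
#' removal rate analogously.  At kinetic steady state the two balance.
#'
#' @param traj an \code{acto_trajectory} (snapshots carry counters)
#' @param t_start start of the averaging window, s (at/after steady state)
#' @return list with \code{r_TM} (barbed-end rate, s^-1),
#'   \code{r_PE} (pointed-end removal rate), \code{mean_filaments},
#'   \code{window}
#' @export
treadmilling_rate <- function(traj, t_start = 1000) {
  tms <- vapply(traj$snapshots, `[[`, 0, "time")
  sel <- which(tms >= t_start)
  if (length(sel) < 2L) stop("no snapshots after t_start")
  s1 <- traj$snapshots[[sel[1]]]
  s2 <- traj$snapshots[[sel[length(sel)]]]
  dt <- s2$time - s1$time
  if (dt <= 0) stop("empty averaging window")
  nf <- mean(vapply(traj$snapshots[sel], `[[`, 0, "n_filaments"))
  if (nf == 0) stop("no filaments in window")
  # net elongation: additions minus removals at the same end
  be <- ((s2$counters[["be_add"]] - s1$counters[["be_add"]]) -
           (s2$counters[["be_rem"]] - s1$counters[["be_rem"]])) / (dt * nf)
  pe <- ((s2$counters[["pe_rem"]] - s1$counters[["pe_rem"]]) -
           (s2$counters[["pe_add"]] - s1$counters[["pe_add"]])) / (dt * nf)
  list(r_TM = be, r_PE = pe, mean_filaments = nf,
       window = c(s1$time, s2$time))
}

#' Mean filament length time series (nm)
#' @param traj an \code{acto_trajectory}
#' @return data.frame with \code{time} and \code{length_nm}
#' @export
filament_length_series <- function(traj) {
  data.frame(
    time = vapply(traj$snapshots, `[[`, 0, "time"),
    length_nm = vapply(traj$snapshots, function(s) {
      if (!length(s$filaments)) return(NA_real_)
      mean(vapply(s$filaments, function(f) sum(f$nmono) * 2.7, 0))
    }, 0))
}

#' Detect the onset of kinetic steady state
#'
#' First time from which the rolling mean filament length changes by less
#' than \code{tol_frac} per \code{window} seconds.
#'
#' @param traj an \code{acto_trajectory}
#' @param window rolling window, s
#' @param tol_frac relative change threshold per window
#' @return onset time, s (NA if never reached)
#' @export
steady_state_onset <- function(traj, window = 100, tol_frac = 0.02) {
  d <- filament_length_series(traj)
  d <- d[!is.na(d$length_nm), ]
  if (nrow(d) < 3L) return(NA_real_)
  for (i in seq_len(nrow(d))) {
    t0 <- d$time[i]
    w1 <- d$length_nm[d$time >= t0 & d$time < t0 + window]
    w2 <- d$length_nm[d$time >= t0 + window & d$time < t0 + 2 * window]
    if (!length(w1) || !length(w2)) break
    if (abs(mean(w2) - mean(w1)) / max(mean(w1), 1e-9) < tol_frac)
      return(t0)
  }
  NA_real_
}

#' FRAP-like turnover halftime
#'
#' Fraction of the monomers polymerized at label time that are still
#' polymerized as a function of time; the halftime is the first (linearly
#' interpolated) time at which the fraction drops to 0.5.
#'
#' @param traj an \code{acto_trajectory} whose schedule labeled the
#'   network (snapshots after the label event carry labeled counts)
#' @return list with \code{t_half} (s; NA with \code{censored = TRUE} if
#'   turnover never reaches 50 percent), \code{series} (time vs fraction)
#' @export
turnover_halftime <- function(traj) {
  lab <- lapply(traj$snapshots, `[[`, "labeled")
  keep <- !vapply(lab, is.null, TRUE)
  if (!any(keep)) stop("trajectory carries no labeling information")
  tms <- vapply(traj$snapshots[keep], `[[`, 0, "time")
  frac <- vapply(lab[keep], function(x) x[["n"]] / max(x[["n0"]], 1L), 0)
  ser <- data.frame(time = tms - tms[1], fraction = frac)
  below <- which(ser$fraction <= 0.5)
  if (!length(below))
    return(list(t_half = NA_real_, censored = TRUE, series = ser))
  j <- below[1]
  if (j == 1L) return(list(t_half = 0, censored = FALSE, series = ser))
  t1 <- ser$time[j - 1L]; t2 <- ser$time[j]
  f1 <- ser$fraction[j - 1L]; f2 <- ser$fraction[j]
  th <- t1 + (f1 - 0.5) / (f1 - f2) * (t2 - t1)
  list(t_half = th, censored = FALSE, series = ser)
}

# Cluster detection -------------------------------------------------------

#' Local F-actin concentration map
#'
#' In-plane 100 nm x 100 nm binning of polymerized monomers; per-bin
#' concentration in uM uses the bin footprint times the effective height
#' as the local volume.
#'
#' @param snapshot an \code{acto_snapshot}
#' @param bin_nm bin edge length, nm
#' @return list with \code{conc} (matrix, uM), \code{x}, \code{y} (bin
#'   centers, nm)
#' @export
concentration_map <- function(snapshot, bin_nm = 100) {
  P <- snapshot_monomer_xy(snapshot)
  R <- snapshot$geom$R_eff
  h <- 2 * snapshot$geom$half_height_eff
  nb <- as.integer(ceiling(2 * R / bin_nm))
  bx <- -R + (0:nb) * bin_nm
  ix <- pmin(nb, pmax(1L, findInterval(P[, 1], bx, rightmost.closed = TRUE)))
  iy <- pmin(nb, pmax(1L, findInterval(P[, 2], bx, rightmost.closed = TRUE)))
  cnt <- matrix(0, nb, nb)
  for (k in seq_along(ix)) cnt[ix[k], iy[k]] <- cnt[ix[k], iy[k]] + 1
  vol_L <- bin_nm^2 * h * 1e-24
  conc <- cnt / (6.022e23 * vol_L) * 1e6
  ctr <- (bx[-1] + bx[-(nb + 1L)]) / 2
  list(conc = conc, x = ctr, y = ctr)
}

# 4-connected component labeling of a logical matrix (flood fill)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- cur
      i <- (p - 1L) %% nrow(mask) + 1L; j <- (p - 1L) %/% nrow(mask) + 1L
      nb <- c(if (i > 1L) p - 1L, if (i < nrow(mask)) p + 1L,
              if (j > 1L) p - nrow(mask), if (j < ncol(mask)) p + nrow(mask))
      stack <- c(stack, nb[mask[nb] & lab[nb] == 0L])
    }
  }
  lab
}

#' Detect dense actin clusters on the concentration grid
#'
#' Bins with F-actin concentration above \code{threshold_uM} are grouped
#' into 4-connected components; components smaller than \code{min_bins}
#' are discarded.  Rings appear as one large high-density component; the
#' same machinery measures their local concentration.
#'
#' @param snapshot an \code{acto_snapshot}
#' @param threshold_uM concentration threshold, uM
#' @param min_bins minimum cluster size, bins
#' @param bin_nm bin edge length, nm
#' @return list of class \code{"cluster_set"}: per-cluster data.frames
#'   with bin indices and concentrations, plus \code{mean_conc} each
#' @export
detect_clusters <- function(snapshot, threshold_uM = 160, min_bins = 4L,
                            bin_nm = 100) {
  cm <- concentration_map(snapshot, bin_nm)
  detect_clusters_on_map(cm, threshold_uM, min_bins)
}

# core (also used directly on constructed maps in tests)
detect_clusters_on_map <- function(cm, threshold_uM = 160, min_bins = 4L) {
  mask <- cm$conc >= threshold_uM
  lab <- label_components(mask)
  out <- list()
  if (max(lab) > 0L) {
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k, arr.ind = TRUE)
      if (nrow(idx) < min_bins) next
      cl <- data.frame(i = idx[, 1], j = idx[, 2],
                       conc = cm$conc[idx])
      out[[length(out) + 1L]] <- list(bins = cl,
                                      n_bins = nrow(cl),
                                      mean_conc = mean(cl$conc))
    }
  }
  structure(list(clusters = out, threshold_uM = threshold_uM,
                 min_bins = min_bins), class = "cluster_set")
}

#' Mean local actin concentration over all detected clusters
#' @param cs a \code{cluster_set}
#' @return mean over member bins of all clusters, uM
#' @export
local_concentration <- function(cs) {
  if (!length(cs$clusters)) stop("empty cluster set")
  allc <- unlist(lapply(cs$clusters, function(cl) cl$bins$conc))
  mean(allc)
}

#' Filament orientation relative to the boundary tangent
#'
#' For every cylinder, the angle between its axis and the azimuthal
#' (tangential) direction at its midpoint, folded to [0, 90] degrees:
#' 0 = parallel to the boundary, 90 = radial.
#'
#' @param snapshot an \code{acto_snapshot}
#' @param n_bins histogram bins
#' @return list with \code{angles} (degrees, per cylinder) and
#'   \code{histogram} (data.frame angle/count)
#' @export
orientation_distribution <- function(snapshot, n_bins = 18L) {
  angs <- c()
  for (f in snapshot$filaments) {
    m <- length(f$nmono)
    a <- f$verts[seq_len(m), , drop = FALSE]
    b <- f$verts[seq_len(m) + 1L, , drop = FALSE]
    mid <- (a + b) / 2
    ax <- b - a
    ax <- ax / sqrt(rowSums(ax^2))
    r <- sqrt(mid[, 1]^2 + mid[, 2]^2)
    tang <- cbind(-mid[, 2], mid[, 1], 0) / pmax(r, 1e-9)
    co <- abs(rowSums(ax * tang))
    angs <- c(angs, acos(pmin(1, co)) * 180 / pi)
  }
  br <- seq(0, 90, length.out = n_bins + 1L)
  h <- hist(angs, breaks = br, plot = FALSE)
  list(angles = angs,
       histogram = data.frame(angle = h$mids, count = h$counts))
}

#' Mechanical energy (U_Mech) time series
#'
#' U_Mech is the sum of the filament bending energy and the stretching
#' energies of filaments, motors and linkers (boundary and excluded-volume
#' terms excluded).
#'
#' @param traj an \code{acto_trajectory} whose snapshots carry energy
#'   breakdowns
#' @param tail_window length of the steady-state window for the mean, s
#' @return list with \code{series} (time vs U_Mech, pN nm) and
#'   \code{steady_mean} over the final window
#' @export
mechanical_energy_series <- function(traj, tail_window = 500) {
  en <- lapply(traj$snapshots, `[[`, "energy")
  if (any(vapply(en, is.null, TRUE)))
    stop("snapshots lack energy breakdowns")
  um <- vapply(en, function(e)
    sum(e[c("U_fil_bend", "U_fil_str", "U_motor_str", "U_linker_str")]), 0)
  tms <- vapply(traj$snapshots, `[[`, 0, "time")
  ser <- data.frame(time = tms, U_Mech = um)
  t_end <- max(tms)
  sel <- tms >= t_end - tail_window
  list(series = ser, steady_mean = mean(um[sel]))
}
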