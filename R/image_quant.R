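# Intensity-image quantification ----------------------------------------
#
# The live-cell image pipeline, applied here to synthetic or rendered
# images: background subtraction, mask/centroid extraction, 50 radial
# line profiles, the intensity-based normalized radial median, and the
# center-to-plateau slope used to quantify ring integrity.

#' Construct an intensity image
#'
#' @param img numeric matrix (rows = x, cols = y), photon counts
#' @param pixel_nm pixel size, nm
#' @param background optional background frame (or scalar) subtracted
#'   first; negative results are clipped to zero
#' @return list of class \code{"intensity_image"}
#' @export
intensity_image <- function(img, pixel_nm, background = NULL) {
  if (!is.null(background)) img <- img - background
  img[img < 0] <- 0
  if (any(!is.finite(img))) stop("intensities must be finite")
  structure(list(img = img, pixel_nm = pixel_nm), class = "intensity_image")
}

#' Cell mask and centroid of an intensity image
#'
#' Thresholds the (lightly smoothed) image -- Otsu's method by default or
#' a fixed minimum intensity -- keeps the largest connected component, and
#' returns its intensity-unweighted centroid.
#'
#' @param im an \code{intensity_image}
#' @param threshold "otsu" or a numeric minimum intensity
#' @param smooth_sigma_px Gaussian smoothing before thresholding, pixels
#' @return list with \code{mask} (logical matrix) and \code{centroid}
#'   (c(x, y) in pixel coordinates)
#' @export
mask_and_centroid <- function(im, threshold = "otsu", smooth_sigma_px = 1) {
  img <- im$img
  if (all(img == 0)) stop("empty image")
  sm <- if (smooth_sigma_px > 0) gaussian_blur(img, smooth_sigma_px) else img
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(sm)
    if (diff(rng) == 0) stop("flat image, cannot threshold")
    sc <- (sm - rng[1]) / diff(rng)
    EBImage::otsu(EBImage::Image(sc)) * diff(rng) + rng[1]
  } else as.numeric(threshold)
  mask <- sm > thr
  if (!any(mask)) stop("empty mask")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  tab <- tabulate(labm[labm > 0])
  keep <- which.max(tab)
  mask <- labm == keep
  idx <- which(mask, arr.ind = TRUE)
  list(mask = mask, centroid = c(mean(idx[, 1]), mean(idx[, 2])))
}

# bilinear interpolation on a matrix at (x, y) in pixel coordinates
bilinear <- function(img, x, y) {
  n <- nrow(img); m <- ncol(img)
  x <- pmin(pmax(x, 1), n); y <- pmin(pmax(y, 1), m)
  x0 <- pmin(floor(x), n - 1L); y0 <- pmin(floor(y), m - 1L)
  fx <- x - x0; fy <- y - y0
  img[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    img[cbind(x0 + 1L, y0)] * fx * (1 - fy) +
    img[cbind(x0, y0 + 1L)] * (1 - fx) * fy +
    img[cbind(x0 + 1L, y0 + 1L)] * fx * fy
}

#' Radial line profiles from the centroid
#'
#' Draws \code{n_rays} uniformly spaced rays from the centroid, samples
#' the intensity bilinearly until each ray exits the mask, and normalizes
#' distances by the per-ray mask-edge distance.
#'
#' @param im an \code{intensity_image}
#' @param mask logical matrix (from \code{\link{mask_and_centroid}})
#' @param centroid c(x, y) pixel coordinates; must lie inside the mask
#' @param n_rays number of rays
#' @param step_px sampling step along each ray, pixels
#' @return data.frame with columns \code{ray}, \code{r} (normalized 0..1)
#'   and \code{intensity}
#' @export
radial_profiles <- function(im, mask, centroid, n_rays = 50L,
                            step_px = 0.5) {
  cx <- centroid[1]; cy <- centroid[2]
  ci <- round(cx); cj <- round(cy)
  if (ci < 1 || cj < 1 || ci > nrow(mask) || cj > ncol(mask) ||
      !mask[ci, cj]) stop("centroid outside mask")
  angs <- 2 * pi * (seq_len(n_rays) - 1L) / n_rays
  maxlen <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  out <- vector("list", n_rays)
  for (k in seq_len(n_rays)) {
    dx <- cos(angs[k]); dy <- sin(angs[k])
    d <- seq(0, maxlen, by = step_px)
    xs <- cx + d * dx; ys <- cy + d * dy
    inside <- xs >= 1 & ys >= 1 & xs <= nrow(mask) & ys <= ncol(mask)
    inside[inside] <- mask[cbind(round(xs[inside]), round(ys[inside]))]
    stop_at <- which(!inside)[1]
    nin <- if (is.na(stop_at)) length(d) else stop_at - 1L
    if (nin < 2L) next
    d <- d[seq_len(nin)]
    redge <- d[nin]
    out[[k]] <- data.frame(ray = k, r = d / redge,
                           intensity = bilinear(im$img, cx + d * dx,
                                                cy + d * dy))
  }
  do.call(rbind, out)
}

#' Intensity-based normalized radial median
#'
#' Median of the normalized radius over the pooled ray samples, weighted
#' by intensity times radius.  (Rays sample uniformly per unit radius, so
#' the annulus Jacobian r restores per-area mass weighting; the result
#' then estimates the radial median of the underlying F-actin mass, the
#' image-side counterpart of \code{\link{r_median}}.)
#'
#' @param profiles data.frame from \code{\link{radial_profiles}}
#' @return dimensionless median in [0, 1]
#' @export
intensity_r_median <- function(profiles) {
  w <- profiles$intensity * profiles$r
  if (sum(w) <= 0) stop("zero total intensity")
  ord <- order(profiles$r)
  r <- profiles$r[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  r[which(cw >= 0.5)[1]]
}

#' Quantify an image in one call
#'
#' Convenience wrapper: mask, centroid, 50 radial profiles, and the
#' normalized radial median.
#'
#' @param im an \code{intensity_image}
#' @param threshold passed to \code{\link{mask_and_centroid}}
#' @return list with \code{r_median}, \code{centroid}, \code{mask},
#'   \code{profiles}
#' @export
quantify_image <- function(im, threshold = "otsu") {
  mc <- mask_and_centroid(im, threshold)
  pr <- radial_profiles(im, mc$mask, mc$centroid)
  list(r_median = intensity_r_median(pr), centroid = mc$centroid,
       mask = mc$mask, profiles = pr)
}

#' Center-to-plateau slope of radial intensity profiles over time
#'
#' For each frame: the mean radial profile is normalized by the frame's
#' mean cell intensity (removing global photobleaching), the plateau is
#' estimated as the mean normalized intensity over the outer 20 percent
#' of radii, the transition region is where the profile rises between 10
#' and 90 percent of the plateau level, and its least-squares slope is
#' returned.  A flat ring gives a steep positive slope; disordered
#' networks give shallower slopes.
#'
#' @param profile_list list of per-frame profile data.frames (from
#'   \code{\link{radial_profiles}})
#' @param times frame times, s
#' @param n_grid radial grid size for the mean profile
#' @return data.frame with \code{time} and \code{slope} (normalized
#'   intensity per unit normalized radius; NA when no plateau transition
#'   is detectable)
#' @export
plateau_slope <- function(profile_list, times, n_grid = 50L) {
  stopifnot(length(profile_list) == length(times))
  slopes <- vapply(profile_list, function(pr) {
    br <- seq(0, 1, length.out = n_grid + 1L)
    bi <- pmin(n_grid, findInterval(pr$r, br, rightmost.closed = TRUE))
    mi <- tapply(pr$intensity, factor(bi, levels = seq_len(n_grid)), mean)
    rr <- (br[-1] + br[-(n_grid + 1L)]) / 2
    ok <- !is.na(mi)
    mi <- mi[ok]; rr <- rr[ok]
    mi <- mi / mean(pr$intensity)          # bleach normalization
    plateau <- mean(mi[rr >= 0.8])
    if (!is.finite(plateau) || plateau <= 0) return(NA_real_)
    lo <- 0.1 * plateau; hi <- 0.9 * plateau
    icross <- which(mi >= hi)[1]
    if (is.na(icross) || icross < 2L) return(NA_real_)
    istart <- which(mi[seq_len(icross)] <= lo)
    istart <- if (length(istart)) max(istart) else 1L
    sel <- istart:icross
    if (length(sel) < 2L) return(NA_real_)
    stats::coef(stats::lm(mi[sel] ~ rr[sel]))[2]
  }, 0)
  data.frame(time = times, slope = slopes)
}
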