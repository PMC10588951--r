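#' Straighten an image along a trace
#'
#' Resamples the image in a band following the (spline-smoothed) trace:
#' output columns are arc-length samples at 1-pixel spacing, output rows
#' are offsets along the local normal from `-(w-1)/2` to `+(w-1)/2`
#' pixels, interpolated bilinearly. This is the standard "straighten"
#' operation applied to chromosome traces before cross-profiles are taken.
#'
#' @param image2d numeric matrix `[y, x]`.
#' @param trace an [sc_trace()] (0-based pixel coordinates).
#' @param band_width_px band width in pixels (odd).
#' @return matrix with `band_width_px` rows and `round(arc length)`
#'   columns.
#' @export
straighten <- function(image2d, trace, band_width_px = 21L) {
  stopifnot(is.matrix(image2d))
  if (inherits(trace, "sc_trace")) trace <- trace$points
  trace <- as.data.frame(trace)
  if (nrow(trace) < 2L) stop("a trace needs at least 2 points")
  w <- as.integer(band_width_px)
  if (w < 1L || w %% 2L == 0L) stop("band_width_px must be odd and >= 1")

  path <- resample_polyline(trace)
  ncols <- length(path$s)
  offsets <- seq_len(w) - (w + 1L) / 2
  # sample positions: path point + offset * normal
  sx <- outer(offsets, path$nx) * 1 + matrix(path$x, w, ncols, byrow = TRUE)
  sy <- outer(offsets, path$ny) * 1 + matrix(path$y, w, ncols, byrow = TRUE)
  ny <- nrow(image2d); nx <- ncol(image2d)
  if (any(sx < 0 | sx > nx - 1 | sy < 0 | sy > ny - 1)) {
    stop("trace leaves the image after band expansion; shrink band_width_px")
  }
  matrix(bilinear_sample(image2d, as.vector(sx), as.vector(sy)), w, ncols)
}

# Interpolating-spline resampling of a polyline at 1-px arc spacing.
# Returns positions, unit normals and arc positions s = 0, 1, ..., ncol-1
# with ncol = round(total arc length).
resample_polyline <- function(trace) {
  x <- trace$x; y <- trace$y
  tpar <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  if (tpar[length(tpar)] == 0) stop("degenerate trace of zero length")
  keep <- c(TRUE, diff(tpar) > 0)
  x <- x[keep]; y <- y[keep]; tpar <- tpar[keep]
  n_dense <- max(200L, 20L * length(x))
  tt <- seq(0, tpar[length(tpar)], length.out = n_dense)
  if (length(x) > 2L) {
    xd <- spline(tpar, x, xout = tt)$y
    yd <- spline(tpar, y, xout = tt)$y
  } else {
    xd <- approx(tpar, x, xout = tt)$y
    yd <- approx(tpar, y, xout = tt)$y
  }
  sd_ <- c(0, cumsum(sqrt(diff(xd)^2 + diff(yd)^2)))
  L <- sd_[length(sd_)]
  ncols <- max(2L, as.integer(round(L)))
  s_targets <- seq(0, by = 1, length.out = ncols)
  s_targets[s_targets > L] <- L
  px <- approx(sd_, xd, xout = s_targets)$y
  py <- approx(sd_, yd, xout = s_targets)$y
  # tangents from neighbouring samples half a pixel away
  eps <- 0.5
  xm <- approx(sd_, xd, xout = pmax(s_targets - eps, 0))$y
  xp <- approx(sd_, xd, xout = pmin(s_targets + eps, L))$y
  ym <- approx(sd_, yd, xout = pmax(s_targets - eps, 0))$y
  yp <- approx(sd_, yd, xout = pmin(s_targets + eps, L))$y
  tx <- xp - xm; ty <- yp - ym
  len <- sqrt(tx^2 + ty^2); len[len == 0] <- 1
  list(x = px, y = py, nx = -ty / len, ny = tx / len,
       s = s_targets, arc_length = L)
}

# Bilinear interpolation at 0-based sub-pixel coordinates.
bilinear_sample <- function(image2d, x, y) {
  nx <- ncol(image2d); ny <- nrow(image2d)
  x0 <- pmin(pmax(floor(x), 0), nx - 2); x1 <- x0 + 1
  y0 <- pmin(pmax(floor(y), 0), ny - 2); y1 <- y0 + 1
  fx <- x - x0; fy <- y - y0
  idx <- function(yy, xx) image2d[cbind(yy + 1, xx + 1)]
  (1 - fx) * (1 - fy) * idx(y0, x0) + fx * (1 - fy) * idx(y0, x1) +
    (1 - fx) * fy * idx(y1, x0) + fx * fy * idx(y1, x1)
}

#' Sample evenly spaced perpendicular profiles from a straightened band
#'
#' Takes `n_points` sample positions evenly spaced along the band
#' (excluding a half-spacing margin at each end: centers at columns
#' `round((2k - 1) * ncol / (2 n))`), and at each position averages
#' `thickness_px` adjacent columns; the profile runs along the normal
#' (row) direction.
#'
#' @param straightened matrix from [straighten()].
#' @param n_points number of profiles (default 10).
#' @param thickness_px columns averaged per profile (default 3, odd).
#' @return list of numeric profiles; sample columns (1-based) in attribute
#'   `"centers"`.
#' @export
sample_profiles <- function(straightened, n_points = 10L, thickness_px = 3L) {
  stopifnot(is.matrix(straightened))
  ncols <- ncol(straightened)
  if (ncols < n_points) stop("straightened band has fewer columns than n_points")
  th <- as.integer(thickness_px)
  if (th < 1L) stop("thickness_px must be >= 1")
  if (ncols < th) stop("image narrower than thickness")
  half <- (th - 1L) %/% 2L
  centers <- pmin(pmax(round((2 * seq_len(n_points) - 1) * ncols /
                               (2 * n_points)), 1L + half), ncols - half)
  profs <- lapply(centers, function(cc) {
    cols <- (cc - half):(cc + half)
    rowMeans(straightened[, cols, drop = FALSE])
  })
  attr(profs, "centers") <- centers
  profs
}

#' Fit a cross-profile with a double Gaussian to locate the axis peaks
#'
#' Detects local maxima with a prominence threshold (default 3x a robust,
#' MAD-based noise estimate of the profile), keeps the two most prominent
#' (ties broken by amplitude), and refines their positions by least-squares
#' fitting of a sum of two Gaussians plus a constant baseline. The peak
#' separation in nm is `|mu2 - mu1| * pixel_size_nm`. Profiles with a
#' single detected peak are unresolved (`n_peaks = 1`, no separation);
#' fit failures are flagged via `converged = FALSE`.
#'
#' @param profile numeric vector (length >= 7).
#' @param pixel_size_nm nm per pixel.
#' @param prominence minimum peak prominence; default 3x a robust noise
#'   estimate, `3 * mad(diff(profile, differences = 2)) / sqrt(6)` (the
#'   second-difference MAD is insensitive to the smooth ridge signal).
#' @return list of class `profile_fit` with `n_peaks`, `positions_px`,
#'   `amplitudes`, `widths_px`, `separation_nm`, `residual`, `converged`.
#' @export
fit_profile <- function(profile, pixel_size_nm, prominence = NULL) {
  profile <- as.numeric(profile)
  if (length(profile) < 7L) stop("profile too short (need >= 7 samples)")
  if (is.null(prominence)) {
    prominence <- 3 * mad(diff(profile, differences = 2)) / sqrt(6)
    prominence <- max(prominence, 1e-9 * max(abs(profile), 1))
  }
  pk <- find_peaks(profile, prominence)
  empty <- list(n_peaks = length(pk$pos), positions_px = pk$pos - 1,
                amplitudes = profile[pk$pos], widths_px = numeric(0),
                separation_nm = NA_real_, residual = NA_real_,
                converged = TRUE)
  class(empty) <- "profile_fit"
  if (length(pk$pos) < 2L) return(empty)
  # two most prominent, ties by amplitude
  ord <- order(-pk$prominence, -profile[pk$pos])
  sel <- sort(pk$pos[ord[1:2]])
  x <- seq_along(profile) - 1
  y <- profile
  base0 <- min(y)
  start <- list(a1 = max(y[sel[1] ] - base0, 1e-6),
                m1 = x[sel[1]], s1 = 1.5,
                a2 = max(y[sel[2]] - base0, 1e-6),
                m2 = x[sel[2]], s2 = 1.5, c0 = base0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)) +
        a2 * exp(-(x - m2)^2 / (2 * s2^2)) + c0,
      start = start,
      lower = c(a1 = 0, m1 = min(x), s1 = 0.2, a2 = 0, m2 = min(x),
                s2 = 0.2, c0 = -Inf),
      upper = c(a1 = Inf, m1 = max(x), s1 = diff(range(x)),
                a2 = Inf, m2 = max(x), s2 = diff(range(x)), c0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- empty
    out$n_peaks <- 2L
    out$converged <- FALSE
    return(out)
  }
  cf <- stats::coef(fit)
  structure(list(n_peaks = 2L,
                 positions_px = sort(unname(cf[c("m1", "m2")])),
                 amplitudes = unname(cf[c("a1", "a2")]),
                 widths_px = unname(cf[c("s1", "s2")]),
                 separation_nm = abs(cf[["m2"]] - cf[["m1"]]) * pixel_size_nm,
                 residual = sqrt(mean(stats::resid(fit)^2)),
                 converged = TRUE),
            class = "profile_fit")
}

# Local maxima with prominences (standard topographic definition: height
# above the higher of the two key saddles toward higher terrain or the
# series ends).
find_peaks <- function(y, min_prominence = 0) {
  n <- length(y)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  # plateau maxima: first index of any flat top higher than both sides
  if (length(cand) == 0L && n >= 3L) {
    for (i in 2:(n - 1)) {
      if (y[i] > y[i - 1] && y[i] >= y[i + 1]) { cand <- c(cand, i); break }
    }
  }
  if (length(cand) == 0L) return(list(pos = integer(0), prominence = numeric(0)))
  # collapse flat-topped maxima: keep only the first index of each plateau
  if (length(cand) > 1L) {
    drop <- logical(length(cand))
    for (k in 2:length(cand)) {
      c1 <- cand[k - 1L]; c2 <- cand[k]
      if (y[c1] == y[c2] && all(y[c1:c2] == y[c1])) drop[k] <- TRUE
    }
    cand <- cand[!drop]
  }
  prom <- vapply(cand, function(i) {
    lmin <- y[i]; j <- i
    while (j > 1L && y[j - 1] <= y[i]) { j <- j - 1L; lmin <- min(lmin, y[j]) }
    left <- if (j == 1L && y[1] <= y[i]) min(y[1:i]) else lmin
    rmin <- y[i]; j <- i
    while (j < n && y[j + 1] <= y[i]) { j <- j + 1L; rmin <- min(rmin, y[j]) }
    right <- if (j == n && y[n] <= y[i]) min(y[i:n]) else rmin
    y[i] - max(left, right)
  }, numeric(1))
  keep <- prom >= min_prominence
  list(pos = cand[keep], prominence = prom[keep])
}

#' Mean axis separation over a set of profile fits
#'
#' Averages the separation over profiles where both peaks were resolved
#' (`n_peaks == 2` and the fit converged); single-peak profiles are
#' excluded as unresolved rather than treated as zero separation.
#'
#' @param fits list of [fit_profile()] results.
#' @return list with `mean_separation_nm` (`NA` if no valid profile) and
#'   `n_valid`.
#' @export
chromosome_distance <- function(fits) {
  if (length(fits) == 0L) stop("no profile fits supplied")
  seps <- vapply(fits, function(f) {
    if (inherits(f, "profile_fit") && f$n_peaks == 2L && isTRUE(f$converged) &&
        is.finite(f$separation_nm)) f$separation_nm else NA_real_
  }, numeric(1))
  valid <- !is.na(seps)
  if (!any(valid)) {
    warning("no profile resolved two peaks; separation undefined")
    return(list(mean_separation_nm = NA_real_, n_valid = 0L))
  }
  list(mean_separation_nm = mean(seps[valid]), n_valid = sum(valid))
}

#' Classify an axis pair as synapsed or unsynapsed
#'
#' Synapsed chromosome axes sit around 150 nm apart; aligned but
#' unsynapsed axes at 300-400 nm. The boundary itself counts as
#' unsynapsed.
#'
#' @param separation_nm measured separation (nm, >= 0).
#' @param threshold_nm decision threshold (default 250 nm).
#' @return `"synapsed"` or `"unsynapsed"`.
#' @export
classify_synapsis <- function(separation_nm, threshold_nm = 250) {
  if (any(separation_nm < 0)) stop("separation must be >= 0")
  ifelse(separation_nm < threshold_nm, "synapsed", "unsynapsed")
}

#' Measure the axis separation of a traced chromosome in a stack
#'
#' End-to-end distance pipeline: select the focal projection, straighten
#' along the trace, take evenly spaced perpendicular profiles of the given
#' thickness, fit each with a double Gaussian, and average the resolved
#' separations.
#'
#' @param stack an [image_stack()].
#' @param trace an [sc_trace()] following the chromosome midline.
#' @param n_points number of profiles (default 10).
#' @param thickness_px profile thickness (default 3).
#' @param band_width_px straightened band width (odd; default 21).
#' @param threshold_nm synapsis classification threshold.
#' @return list with `mean_separation_nm`, `n_valid`, `classification`,
#'   and the per-profile `fits`.
#' @export
measure_axis_separation <- function(stack, trace, n_points = 10L,
                                    thickness_px = 3L, band_width_px = 21L,
                                    threshold_nm = 250) {
  proj <- select_projection(stack)
  band <- straighten(proj, trace, band_width_px = band_width_px)
  profs <- sample_profiles(band, n_points = n_points,
                           thickness_px = thickness_px)
  fits <- lapply(profs, fit_profile, pixel_size_nm = stack$pixel_size_nm)
  cd <- chromosome_distance(fits)
  cls <- if (is.na(cd$mean_separation_nm)) NA_character_ else
    classify_synapsis(cd$mean_separation_nm, threshold_nm)
  c(cd, list(classification = cls, fits = fits))
}

#' Focal projection of a stack
#'
#' Finds the slice with the maximal total intensity (ties -> lowest index)
#' and projects the per-pixel maximum over the two slices above and two
#' below it (clamped at the stack bounds).
#'
#' @param stack an [image_stack()] (or bare `[y, x, z]` array).
#' @return 2-D numeric matrix.
#' @export
select_projection <- function(stack) {
  vox <- if (inherits(stack, "image_stack")) stack$voxels else stack
  if (length(dim(vox)) == 2L) return(vox)
  nz <- dim(vox)[3]
  totals <- vapply(seq_len(nz), function(s) sum(vox[, , s]), numeric(1))
  k <- which.max(totals)  # which.max takes the lowest index on ties
  lo <- max(1L, k - 2L); hi <- min(nz, k + 2L)
  out <- vox[, , lo]
  if (hi > lo) for (s in (lo + 1L):hi) out <- pmax(out, vox[, , s])
  out
}

#' Background-subtracted integrated ROI intensity
#'
#' Rasterizes the ROI polygon (even-odd rule, pixel centers, half-open
#' boundary convention), then reports
#' `integrated = (roi mean - background mean) * roi area`.
#'
#' @param image2d numeric matrix `[y, x]`.
#' @param roi polygon vertices (matrix/data.frame with x, y columns,
#'   0-based pixel coordinates).
#' @param background_roi background polygon in the same format.
#' @return list of class `intensity_result` with `area_px` (pixel count),
#'   `roi_mean`, `background_mean`, `integrated`, and `flag_negative`.
#' @export
measure_roi <- function(image2d, roi, background_roi) {
  stopifnot(is.matrix(image2d))
  in_roi <- rasterize_polygon(roi, dim(image2d))
  in_bg <- rasterize_polygon(background_roi, dim(image2d))
  if (!any(in_roi)) stop("ROI polygon covers no pixel centers")
  if (!any(in_bg)) stop("background polygon covers no pixel centers")
  if (any(in_roi & in_bg)) warning("ROI and background polygons overlap")
  area <- sum(in_roi)
  roi_mean <- mean(image2d[in_roi])
  bg_mean <- mean(image2d[in_bg])
  integrated <- (roi_mean - bg_mean) * area
  structure(list(area_px = area, roi_mean = roi_mean,
                 background_mean = bg_mean, integrated = integrated,
                 flag_negative = integrated < 0),
            class = "intensity_result")
}

# Even-odd polygon rasterization at pixel centers (0-based integer
# coordinates), half-open: a crossing counts when one endpoint's y is
# strictly above the scan row and the other is not, and the intersection
# lies strictly to the right of the pixel center.
rasterize_polygon <- function(poly, img_dim) {
  poly <- as.data.frame(poly)
  if (!all(c("x", "y") %in% names(poly))) names(poly)[1:2] <- c("x", "y")
  if (nrow(poly) < 3L) stop("polygon needs at least 3 vertices")
  ny <- img_dim[1]; nx <- img_dim[2]
  px <- rep(seq_len(nx) - 1, each = ny)
  py <- rep(seq_len(ny) - 1, times = nx)
  inside <- rep(FALSE, length(px))
  n <- nrow(poly)
  xs <- poly$x; ysv <- poly$y
  j <- n
  for (i in seq_len(n)) {
    yi <- ysv[i]; yj <- ysv[j]
    cond <- (yi > py) != (yj > py)
    if (any(cond)) {
      xint <- xs[i] + (py - yi) / (yj - yi) * (xs[j] - xs[i])
      inside <- xor(inside, cond & (px < xint))
    }
    j <- i
  }
  matrix(inside, ny, nx)
}
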