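#' Ground truth for a synthetic pair of fluorescent axes
#'
#' Describes two parallel axis ridges (the lateral elements of a synapsed
#' or unsynapsed chromosome pair) at a known separation, to be rendered
#' into a SIM-like image stack by [synthesize_axis_pair_stack()].
#'
#' @param separation_nm true axis separation (nm, >= 0). Synapsed axes sit
#'   around 150 nm; unsynapsed, aligned-only axes at 300-400 nm.
#' @param amplitude peak signal per axis (counts); length 1 or 2.
#' @param psf_fwhm_nm in-plane Gaussian PSF full width at half maximum
#'   (nm); default 120, SIM-scale resolution.
#' @param background uniform background level (counts).
#' @param poisson_noise apply Poisson shot noise.
#' @param read_noise_sd additive Gaussian read noise sd (counts).
#' @param midline optional midline polyline (data.frame/matrix with x, y in
#'   0-based pixel coordinates); default a straight horizontal midline.
#' @param seed RNG seed used when rendering noise.
#' @return list of class `axis_pair_truth`.
#' @export
axis_pair_truth <- function(separation_nm, amplitude = 500,
                            psf_fwhm_nm = 120, background = 50,
                            poisson_noise = TRUE, read_noise_sd = 5,
                            midline = NULL, seed = 1L) {
  if (separation_nm < 0) stop("separation must be >= 0")
  if (psf_fwhm_nm <= 0) stop("psf_fwhm_nm must be > 0")
  if (any(amplitude <= 0)) stop("amplitudes must be > 0")
  if (length(amplitude) == 1L) amplitude <- rep(amplitude, 2L)
  structure(list(separation_nm = separation_nm, amplitude = amplitude,
                 psf_fwhm_nm = psf_fwhm_nm, background = background,
                 poisson_noise = isTRUE(poisson_noise),
                 read_noise_sd = read_noise_sd,
                 midline = midline, seed = as.integer(seed)),
            class = "axis_pair_truth")
}

#' Image stack container
#'
#' @param voxels numeric array `[y, x, z]` of non-negative intensities.
#' @param pixel_size_nm nm per pixel in y/x.
#' @param z_step_um z spacing in micrometres (default 0.1).
#' @return object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size_nm, z_step_um = 0.1) {
  if (length(dim(voxels)) == 2L) voxels <- array(voxels, c(dim(voxels), 1L))
  if (length(dim(voxels)) != 3L || dim(voxels)[3] < 1L) {
    stop("voxels must be a [y, x, z] array with >= 1 slice")
  }
  if (any(voxels < 0)) stop("voxel intensities must be non-negative")
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be > 0")
  structure(list(voxels = voxels, pixel_size_nm = pixel_size_nm,
                 z_step_um = z_step_um),
            class = "image_stack")
}

#' Chromosome trace (polyline) in pixel coordinates
#'
#' @param points matrix or data.frame with columns `x`, `y` (0-based pixel
#'   coordinates, sub-pixel allowed), at least 2 points.
#' @param image_dim optional `c(ny, nx)` to validate bounds against.
#' @return object of class `sc_trace`.
#' @export
sc_trace <- function(points, image_dim = NULL) {
  points <- as.data.frame(points)
  if (!all(c("x", "y") %in% names(points))) {
    names(points)[1:2] <- c("x", "y")
  }
  if (nrow(points) < 2L) stop("a trace needs at least 2 points")
  if (!all(is.finite(points$x)) || !all(is.finite(points$y))) {
    stop("trace points must be finite")
  }
  if (!is.null(image_dim)) {
    if (any(points$x < 0 | points$x > image_dim[2] - 1 |
            points$y < 0 | points$y > image_dim[1] - 1)) {
      stop("trace points fall outside the image bounds")
    }
  }
  structure(list(points = points[, c("x", "y")]), class = "sc_trace")
}

#' Render a synthetic two-axis image stack
#'
#' Renders two Gaussian-profile ridges offset by half the true separation
#' on either side of the midline polyline (an infinitely thin line
#' convolved with the in-plane Gaussian PSF), modulated across slices by a
#' Gaussian focal envelope, plus uniform background, Poisson shot noise and
#' Gaussian read noise. Deterministic under the truth's seed.
#'
#' @param truth an [axis_pair_truth()].
#' @param pixel_size_nm nm per pixel (default 40).
#' @param n_slices number of z slices (default 7).
#' @param ny,nx image size in pixels.
#' @return list with `stack` (an [image_stack()]), `trace` (the midline
#'   [sc_trace()]), and `truth`.
#' @export
synthesize_axis_pair_stack <- function(truth, pixel_size_nm = 40,
                                       n_slices = 7L, ny = 96L, nx = 128L) {
  stopifnot(inherits(truth, "axis_pair_truth"))
  midline <- truth$midline
  if (is.null(midline)) {
    midline <- data.frame(x = c(8, nx - 9), y = rep(floor((ny - 1) / 2), 2))
  }
  midline <- as.data.frame(midline)
  half_sep_px <- truth$separation_nm / 2 / pixel_size_nm
  sigma_px <- truth$psf_fwhm_nm / 2.35482 / pixel_size_nm

  # offset polylines: midline points displaced along the local normal
  nrm <- polyline_normals(midline)
  ridge <- list(
    data.frame(x = midline$x + nrm$nx * half_sep_px,
               y = midline$y + nrm$ny * half_sep_px),
    data.frame(x = midline$x - nrm$nx * half_sep_px,
               y = midline$y - nrm$ny * half_sep_px))
  for (r in ridge) {
    if (any(r$x < 0 | r$x > nx - 1 | r$y < 0 | r$y > ny - 1)) {
      stop("separation too large: a ridge leaves the image frame")
    }
  }
  px <- rep(seq_len(nx) - 1, each = ny)
  py <- rep(seq_len(ny) - 1, times = nx)
  signal <- matrix(0, ny, nx)
  for (k in 1:2) {
    d <- dist_to_polyline(px, py, ridge[[k]])
    signal <- signal + truth$amplitude[k] *
      matrix(exp(-d^2 / (2 * sigma_px^2)), ny, nx)
  }
  focus <- (n_slices + 1) / 2
  env <- exp(-(seq_len(n_slices) - focus)^2 / (2 * 1.2^2))
  vox <- array(0, c(ny, nx, n_slices))
  set.seed(truth$seed)
  for (s in seq_len(n_slices)) {
    plane <- truth$background + env[s] * signal
    if (truth$poisson_noise) {
      plane <- matrix(rpois(length(plane), pmax(plane, 0)), ny, nx)
    }
    if (truth$read_noise_sd > 0) {
      plane <- plane + matrix(rnorm(length(plane), 0, truth$read_noise_sd),
                              ny, nx)
    }
    vox[, , s] <- pmax(plane, 0)
  }
  list(stack = image_stack(vox, pixel_size_nm),
       trace = sc_trace(midline, image_dim = c(ny, nx)),
       truth = truth)
}

# Unit normals at the vertices of a polyline (tangent by central
# differences, rotated +90 degrees).
polyline_normals <- function(pts) {
  n <- nrow(pts)
  tx <- c(pts$x[2] - pts$x[1],
          if (n > 2) pts$x[3:n] - pts$x[1:(n - 2)] else NULL,
          pts$x[n] - pts$x[n - 1])
  ty <- c(pts$y[2] - pts$y[1],
          if (n > 2) pts$y[3:n] - pts$y[1:(n - 2)] else NULL,
          pts$y[n] - pts$y[n - 1])
  len <- sqrt(tx^2 + ty^2)
  len[len == 0] <- 1
  list(nx = -ty / len, ny = tx / len)
}

# Minimum distance from points (px, py) to a polyline, vectorized over
# points, looping over segments.
dist_to_polyline <- function(px, py, pts) {
  d2 <- rep(Inf, length(px))
  for (s in seq_len(nrow(pts) - 1L)) {
    ax <- pts$x[s]; ay <- pts$y[s]
    bx <- pts$x[s + 1L]; by <- pts$y[s + 1L]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    d2 <- pmin(d2, (px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
  }
  sqrt(d2)
}

#' Write an image stack as a 16-bit single-channel TIFF
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @param max_value intensity mapped to the 16-bit ceiling; defaults to the
#'   stack maximum.
#' @return `path`, invisibly. The scale factor is stored in the return
#'   value's `"scale"` attribute.
#' @export
write_stack_tiff <- function(stack, path, max_value = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(max_value)) max_value <- max(stack$voxels)
  if (max_value <= 0) max_value <- 1
  nz <- dim(stack$voxels)[3]
  imgs <- lapply(seq_len(nz), function(s) {
    pmin(stack$voxels[, , s] / max_value, 1)
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  out <- invisible(path)
  attr(out, "scale") <- max_value
  out
}

#' Read a single-channel TIFF stack
#'
#' @param path TIFF path.
#' @param pixel_size_nm nm per pixel of the stack.
#' @param z_step_um z spacing (micrometres).
#' @param scale multiply intensities back to counts (inverse of the scale
#'   used when writing); default 1.
#' @return an [image_stack()].
#' @export
read_stack_tiff <- function(path, pixel_size_nm, z_step_um = 0.1, scale = 1) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  imgs <- lapply(imgs, function(m) if (length(dim(m)) == 3L) m[, , 1] else m)
  vox <- array(0, c(dim(imgs[[1]]), length(imgs)))
  for (s in seq_along(imgs)) vox[, , s] <- imgs[[s]] * scale
  image_stack(vox, pixel_size_nm, z_step_um)
}

#' Tubule apoptosis count model
#'
#' Two-component Poisson mixture for per-tubule apoptotic-nucleus (TUNEL)
#' counts: most tubules draw from a low baseline rate, a fraction `f` of
#' "bursting" tubules (those undergoing apoptotic arrest) from a high rate.
#'
#' @param n_tubules number of tubules.
#' @param lambda_low baseline Poisson rate.
#' @param burst_fraction fraction of high-rate tubules, in `[0, 1]`.
#' @param lambda_high high Poisson rate.
#' @return list of class `tubule_count_model`.
#' @export
tubule_count_model <- function(n_tubules = 200L, lambda_low = 0.2,
                               burst_fraction = 0.015, lambda_high = 8) {
  if (burst_fraction < 0 || burst_fraction > 1) {
    stop("burst_fraction must be in [0, 1]")
  }
  if (lambda_low < 0 || lambda_high < 0) stop("rates must be >= 0")
  if (n_tubules < 1L) stop("n_tubules must be >= 1")
  structure(list(n_tubules = as.integer(n_tubules), lambda_low = lambda_low,
                 burst_fraction = burst_fraction, lambda_high = lambda_high),
            class = "tubule_count_model")
}

#' Draw synthetic per-tubule apoptosis counts
#'
#' @param model a [tubule_count_model()].
#' @param seed RNG seed.
#' @return integer vector of per-tubule counts.
#' @export
synthesize_tubule_counts <- function(model, seed = 1L) {
  stopifnot(inherits(model, "tubule_count_model"))
  set.seed(seed)
  burst <- runif(model$n_tubules) < model$burst_fraction
  counts <- integer(model$n_tubules)
  counts[burst] <- rpois(sum(burst), model$lambda_high)
  counts[!burst] <- rpois(sum(!burst), model$lambda_low)
  counts
}

#' Expected fraction of tubules at or above a count threshold
#'
#' Closed form for the mixture model:
#' `f * P(Pois(hi) >= k) + (1 - f) * P(Pois(lo) >= k)`.
#'
#' @param model a [tubule_count_model()].
#' @param threshold count threshold (default 5).
#' @return expected fraction.
#' @export
expected_high_fraction <- function(model, threshold = 5L) {
  tail_p <- function(lam) 1 - ppois(threshold - 1L, lam)
  model$burst_fraction * tail_p(model$lambda_high) +
    (1 - model$burst_fraction) * tail_p(model$lambda_low)
}
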