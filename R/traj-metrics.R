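#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the (weighted) RMSD
#' of `X` onto `Y` via singular value decomposition of the covariance
#' matrix, with the usual sign correction guaranteeing `det(R) = +1`.
#'
#' @param X,Y n x 3 coordinate matrices (X is moved onto Y).
#' @param weights optional non-negative weights, length n.
#' @return list with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `X %*% t(rotation) + translation`), and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(X, Y, weights = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)) || ncol(X) != 3L) {
    stop("X and Y must be n x 3 matrices of equal shape")
  }
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 particles for a unique superposition")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)
  cx <- colSums(X * w); cy <- colSums(Y * w)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  H <- t(X0 * w) %*% Y0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Xr <- X0 %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((Xr - Y0)^2)))
  list(rotation = R, translation = as.numeric(cy - R %*% cx), rmsd = rmsd)
}

#' Brute-force rotational-minimum RMSD (validation oracle)
#'
#' Independent check of [kabsch_superpose()]: minimizes the superposed RMSD
#' by random search over rotations, exploiting
#' `rmsd^2(R) = c - (2/n) * <R, t(Y0) %*% X0>` so each candidate rotation
#' costs one dot product. A second sampling stage concentrates around the
#' stage-one incumbent to refine the minimum; no gradients and no SVD are
#' used anywhere.
#'
#' @param X,Y n x 3 coordinate matrices.
#' @param n_coarse,n_fine rotations sampled in the global and refinement
#'   stages.
#' @param fine_angle_sd angular spread (radians) of the refinement stage.
#' @return minimum RMSD found (Angstrom).
#' @export
rmsd_rotation_search <- function(X, Y, n_coarse = 200000L, n_fine = 100000L,
                                 fine_angle_sd = 0.03) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  X0 <- sweep(X, 2, colMeans(X)); Y0 <- sweep(Y, 2, colMeans(Y))
  M <- t(Y0) %*% X0                      # maximize tr(R M) = <R, t(M)>
  const <- (sum(X0^2) + sum(Y0^2)) / n
  obj <- function(Rflat) const - (2 / n) * as.numeric(Rflat %*% as.vector(t(M)))
  best_of <- function(Rflat) {
    v <- obj(Rflat)
    list(val = min(v), R = matrix(Rflat[which.min(v), ], 3, 3, byrow = TRUE))
  }
  s1 <- best_of(random_rotations(n_coarse))
  # refinement: small random rotations composed with the incumbent
  P <- random_rotations(n_fine, angle_sd = fine_angle_sd)
  Rf <- matrix(0, n_fine, 9)
  for (k in 1:3) for (l in 1:3) {
    # (P_i %*% incumbent)[k,l] = sum_m P_i[k,m] * inc[m,l]
    Rf[, (k - 1) * 3 + l] <-
      P[, (k - 1) * 3 + 1] * s1$R[1, l] +
      P[, (k - 1) * 3 + 2] * s1$R[2, l] +
      P[, (k - 1) * 3 + 3] * s1$R[3, l]
  }
  s2 <- best_of(rbind(matrix(as.vector(t(s1$R)), 1), Rf))
  sqrt(max(0, min(s1$val, s2$val)))
}

# Rotation matrices, flattened row-major into an m x 9 matrix. Uniform over
# SO(3) via normalized quaternions, or small-angle when angle_sd is given.
random_rotations <- function(m, angle_sd = NULL) {
  if (is.null(angle_sd)) {
    q <- matrix(rnorm(4 * m), m, 4)
  } else {
    q <- cbind(1, matrix(rnorm(3 * m, sd = angle_sd / 2), m, 3))
  }
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
        2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
        2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2))
}

#' RMSD time series against a reference frame
#'
#' Each frame is superposed (over the selection) onto the reference frame
#' before the RMSD is computed, so rigid-body motion does not contribute.
#'
#' @param traj a `cg_trajectory`.
#' @param reference_frame reference frame index (1-based, default 1).
#' @param selection integer vector of particle indices (default all).
#' @return data.frame with columns `time` (ns) and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference_frame = 1L, selection = NULL) {
  stopifnot(inherits(traj, "cg_trajectory"))
  nf <- n_frames(traj)
  if (reference_frame < 1L || reference_frame > nf) {
    stop("reference frame index out of range")
  }
  if (is.null(selection)) selection <- seq_len(dim(traj$coords)[1])
  if (length(selection) == 0L) stop("empty selection")
  ref <- traj$coords[selection, , reference_frame, drop = FALSE]
  dim(ref) <- dim(ref)[1:2]
  r <- vapply(seq_len(nf), function(f) {
    m <- traj$coords[selection, , f, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    kabsch_superpose(m, ref)$rmsd
  }, numeric(1))
  data.frame(time = traj$times, rmsd = r)
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of each selected particle about its time-mean position:
#' `sqrt(mean over frames of |x_t - <x>|^2)`. When `align_to_mean` is set
#' (the default) each frame is first superposed onto the running mean
#' structure (two fixed-point passes), so rigid-body drift is removed.
#'
#' @param traj a `cg_trajectory` with at least two frames.
#' @param selection particle indices (default all).
#' @param align_to_mean superpose frames onto the mean structure first.
#' @return numeric vector of per-particle RMSF values (Angstrom).
#' @export
rmsf <- function(traj, selection = NULL, align_to_mean = TRUE) {
  stopifnot(inherits(traj, "cg_trajectory"))
  nf <- n_frames(traj)
  if (nf < 2L) stop("RMSF needs at least two frames")
  if (is.null(selection)) selection <- seq_len(dim(traj$coords)[1])
  if (length(selection) == 0L) stop("empty selection")
  frames <- lapply(seq_len(nf), function(f) {
    m <- traj$coords[selection, , f, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    m
  })
  if (align_to_mean) {
    ref <- frames[[1]]
    for (pass in 1:2) {
      frames <- lapply(frames, function(m) {
        k <- kabsch_superpose(m, ref)
        sweep(m %*% t(k$rotation), 2, -k$translation)
      })
      ref <- Reduce(`+`, frames) / nf
    }
  }
  mean_pos <- Reduce(`+`, frames) / nf
  msf <- Reduce(`+`, lapply(frames, function(m) rowSums((m - mean_pos)^2))) / nf
  sqrt(msf)
}

#' Interdimer distance of one frame
#'
#' Euclidean distance between the centroids of all marker-residue particles
#' (human L109 / mouse L106) of the two dimers — the disruption metric of
#' the steered assay. Below 10 A the head-to-head interface is intact.
#'
#' @param frame n x 3 coordinate matrix.
#' @param structure an `assembly_structure` with dimer assignment and
#'   marker residue set.
#' @return distance in Angstrom.
#' @export
interdimer_distance <- function(frame, structure) {
  stopifnot(inherits(structure, "assembly_structure"))
  if (is.null(structure$dimer_assignment) || is.na(structure$marker_residue)) {
    stop("structure needs dimer_assignment and marker_residue")
  }
  frame <- as.matrix(frame)
  if (nrow(frame) != nrow(structure$particles)) {
    stop("frame particle count does not match structure")
  }
  p <- structure$particles
  dim_of <- structure$dimer_assignment[p$chain]
  cent <- function(which_dimer) {
    idx <- which(dim_of == which_dimer & p$resno == structure$marker_residue)
    if (length(idx) == 0L) {
      stop("marker residue ", structure$marker_residue,
           " absent from ", which_dimer)
    }
    colMeans(frame[idx, , drop = FALSE])
  }
  sqrt(sum((cent("dimer1") - cent("dimer2"))^2))
}

#' Interdimer-distance time series of a trajectory
#'
#' @param traj a `cg_trajectory` carrying an assigned structure (or pass
#'   `structure` explicitly).
#' @param structure optional `assembly_structure` override.
#' @return data.frame with columns `time` (ns) and `distance` (Angstrom).
#' @export
interdimer_series <- function(traj, structure = NULL) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (is.null(structure)) structure <- traj$structure
  if (is.null(structure)) stop("no structure metadata available")
  d <- vapply(seq_len(n_frames(traj)), function(f) {
    interdimer_distance(frame_coords(traj, f), structure)
  }, numeric(1))
  data.frame(time = traj$times, distance = d)
}

#' Classify a dissociation time course
#'
#' Applies the intact / loosened / dissociated criterion to an
#' interdimer-distance series. The series is smoothed with a centered
#' running median of `persistence_window` samples; the interface is
#' *dissociated* if the smoothed distance crosses `dissociated_threshold`
#' and stays above `intact_threshold` for the rest of the series (the
#' disruption time is the first such persistent crossing, at frame
#' resolution), *loosened* if the smoothed distance exceeds
#' `intact_threshold` for at least `persistence_window` consecutive samples
#' but never meets the dissociation rule, and *intact* otherwise.
#'
#' @param time numeric vector of times (ns), strictly increasing.
#' @param distance numeric vector of distances (Angstrom), same length.
#' @param intact_threshold distance below which the interface counts as
#'   intact (default 10 A).
#' @param dissociated_threshold distance marking full dissociation
#'   (default 30 A).
#' @param persistence_window smoothing / persistence window in samples
#'   (default 5).
#' @return list of class `dissociation_result` with `status`,
#'   `disruption_time` (ns or `NA`), `distance_series` (data.frame), and
#'   `thresholds`.
#' @export
detect_dissociation <- function(time, distance,
                                intact_threshold = 10,
                                dissociated_threshold = 30,
                                persistence_window = 5L) {
  if (is.data.frame(time)) { distance <- time$distance; time <- time$time }
  n <- length(time)
  if (n == 0L || length(distance) != n) {
    stop("time and distance must be non-empty vectors of equal length")
  }
  if (n > 1L && any(diff(time) <= 0)) stop("time stamps must be increasing")
  if (any(distance < 0)) stop("distances must be >= 0")
  if (dissociated_threshold <= intact_threshold) {
    stop("dissociated_threshold must exceed intact_threshold")
  }
  w <- max(1L, as.integer(persistence_window))
  sm <- running_median(distance, w)

  status <- "intact"; t_disrupt <- NA_real_
  above_intact_suffix <- rev(cumprod(rev(sm > intact_threshold))) > 0
  cand <- which(sm >= dissociated_threshold & above_intact_suffix)
  if (length(cand)) {
    status <- "dissociated"
    # report the first raw crossing consistent with the persistent smoothed
    # crossing, at frame resolution
    k <- cand[1]
    raw <- which(distance >= dissociated_threshold)
    raw <- raw[raw >= k - w %/% 2 & raw <= k + w %/% 2]
    t_disrupt <- time[if (length(raw)) raw[1] else k]
  } else {
    runs <- rle(sm > intact_threshold)
    if (any(runs$values & runs$lengths >= w)) status <- "loosened"
  }
  structure(list(status = status, disruption_time = t_disrupt,
                 distance_series = data.frame(time = time, distance = distance),
                 thresholds = list(intact = intact_threshold,
                                   dissociated = dissociated_threshold,
                                   persistence_window = w)),
            class = "dissociation_result")
}

#' @export
print.dissociation_result <- function(x, ...) {
  cat("dissociation_result:", x$status)
  if (!is.na(x$disruption_time)) {
    cat(sprintf(" at %.2f ns", x$disruption_time))
  }
  cat(sprintf(" (thresholds %g/%g A, window %d)\n",
              x$thresholds$intact, x$thresholds$dissociated,
              x$thresholds$persistence_window))
  invisible(x)
}

# Centered running median with shrinking windows at the edges.
running_median <- function(x, w) {
  if (w <= 1L) return(x)
  h <- w %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    median(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}
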