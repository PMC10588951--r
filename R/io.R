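#' Read a PDB file into an assembly structure
#'
#' Reads ATOM/HETATM records (first MODEL only) via bio3d and returns an
#' [assembly_structure()] with particles in file order and coordinates in
#' Angstrom. Dimer assignment is left unset; assign it with
#' [assign_dimers()] once the chain/dimer correspondence is known.
#'
#' @param path path to a PDB file.
#' @return an `assembly_structure`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atoms in PDB file: ", path)
  particles <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    resid = as.character(at$resid),
    name = as.character(at$elety),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    stringsAsFactors = FALSE)
  if (!all(is.finite(as.matrix(particles[, c("x", "y", "z")])))) {
    stop("non-numeric coordinate fields in PDB file: ", path)
  }
  assembly_structure(particles)
}

#' Write an assembly structure to a PDB file
#'
#' @param structure an `assembly_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  p <- structure$particles
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(p[, c("x", "y", "z")]))),
                   resno = p$resno, resid = p$resid,
                   chain = p$chain, elety = p$name)
  invisible(path)
}

#' Assign chains to the two dimers and set the marker residue
#'
#' @param structure an `assembly_structure`.
#' @param dimer_assignment named character vector chain -> "dimer1"/"dimer2".
#' @param marker_residue marker residue index (human 109 / mouse 106).
#' @return the updated structure.
#' @export
assign_dimers <- function(structure, dimer_assignment, marker_residue) {
  structure$dimer_assignment <- dimer_assignment
  structure$marker_residue <- as.integer(marker_residue)
  validate_dimer_assignment(structure)
  structure
}

#' Trajectory container
#'
#' Frames of particle coordinates with time stamps, referring back to the
#' structure that defines particle order.
#'
#' @param coords numeric array of dimension `c(n_particles, 3, n_frames)`
#'   (Angstrom), or a list of `n x 3` matrices.
#' @param times numeric vector of frame times in ns (strictly increasing).
#' @param names optional character vector of particle names (length n).
#' @param structure optional `assembly_structure` describing particle order.
#' @return object of class `cg_trajectory`.
#' @export
trajectory <- function(coords, times, names = NULL, structure = NULL) {
  if (is.list(coords)) {
    if (length(coords) == 0L) stop("trajectory has no frames")
    n <- nrow(coords[[1]])
    for (i in seq_along(coords)) {
      if (!is.matrix(coords[[i]]) || ncol(coords[[i]]) != 3L) {
        stop("frame ", i, " is not an n x 3 coordinate matrix")
      }
      if (nrow(coords[[i]]) != n) {
        stop("frame ", i, " has ", nrow(coords[[i]]),
             " particles; expected ", n)
      }
    }
    arr <- array(0, dim = c(n, 3L, length(coords)))
    for (i in seq_along(coords)) arr[, , i] <- coords[[i]]
    coords <- arr
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("coords must be an n x 3 x frames array")
  }
  nf <- dim(coords)[3]
  if (nf == 0L) stop("trajectory has no frames")
  times <- as.numeric(times)
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1L && any(diff(times) <= 0)) stop("frame times must be increasing")
  if (!is.null(structure) && nrow(structure$particles) != dim(coords)[1]) {
    stop("structure particle count does not match trajectory")
  }
  structure(list(coords = coords, times = times,
                 names = names, structure = structure),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("cg_trajectory:", d[3], "frames x", d[1], "particles; t =",
      format(x$times[1]), "..", format(x$times[d[3]]), "ns\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cg_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as an n x 3 matrix
#' @param traj a `cg_trajectory`.
#' @param i frame index (1-based).
#' @return numeric matrix.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  traj$coords[, , i, drop = TRUE]
}

#' Write a trajectory as a multi-frame XYZ file
#'
#' Plain XYZ dialect: per frame a particle-count line, a comment line
#' `t= <time> ns`, then one `name x y z` line per particle (Angstrom,
#' 6 decimal places).
#'
#' @param traj a `cg_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cg_trajectory"))
  n <- dim(traj$coords)[1]
  nm <- traj$names
  if (is.null(nm)) nm <- rep("CA", n)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , f, drop = TRUE]
    writeLines(c(as.character(n),
                 sprintf("t= %.6f ns", traj$times[f]),
                 sprintf("%s %.6f %.6f %.6f", nm, xyz[, 1], xyz[, 2], xyz[, 3])),
               con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path path to an XYZ file in the dialect of
#'   [write_xyz_trajectory()].
#' @param structure optional `assembly_structure` to attach.
#' @return a `cg_trajectory`.
#' @export
read_xyz_trajectory <- function(path, structure = NULL) {
  if (!file.exists(path)) stop("cannot read XYZ file: ", path)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > suppressWarnings(max(which(nzchar(lines)), 0)))]
  if (length(lines) == 0L) stop("empty XYZ file: ", path)
  frames <- list(); times <- numeric(0); nm <- NULL
  i <- 1L; f <- 0L; n0 <- NA_integer_
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0L) stop("malformed particle-count line ", i)
    f <- f + 1L
    if (is.na(n0)) n0 <- n
    if (n != n0) {
      stop("frame ", f, " has ", n, " particles; expected ", n0)
    }
    if (i + 1L + n > length(lines)) stop("truncated frame ", f)
    cm <- lines[i + 1L]
    tm <- regmatches(cm, regexpr("-?[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?", cm))
    times <- c(times, if (length(tm)) as.numeric(tm[1]) else f - 1)
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(lengths(parts) < 4L)
    if (length(bad)) stop("malformed coordinate line in frame ", f)
    m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                ncol = 3, byrow = TRUE)
    if (any(!is.finite(m))) stop("non-numeric coordinates in frame ", f)
    if (is.null(nm)) nm <- vapply(parts, `[`, "", 1L)
    frames[[f]] <- m
    i <- i + 2L + n
  }
  trajectory(frames, times, names = nm, structure = structure)
}
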