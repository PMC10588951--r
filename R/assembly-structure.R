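#' Assembly structure: particles of a head-to-head dimer-of-dimers
#'
#' Container for a coarse-grained or atomic structure of the SYCP1 alphaN-end
#' tetramer (two parallel-chain dimers joined head-to-head through their
#' alphaN-tips). Particles are stored in file/build order; each chain may be
#' assigned to one of the two dimers, and a marker residue (human L109 /
#' mouse L106) defines the interdimer-distance metric.
#'
#' @param particles data.frame with columns `chain` (character), `resno`
#'   (integer, 1-based residue index), `resid` (residue name), `name`
#'   (atom/bead name), `x`, `y`, `z` (Angstrom).
#' @param dimer_assignment named character vector mapping each chain id to
#'   `"dimer1"` or `"dimer2"`, or `NULL` if not yet assigned.
#' @param marker_residue integer residue index of the head-to-head marker
#'   (109 in human numbering, 106 in mouse), or `NA` if unset.
#' @param species_offset integer offset between human and mouse numbering
#'   (mouse = human - offset); default 3.
#'
#' @return An object of class `assembly_structure`.
#' @export
assembly_structure <- function(particles, dimer_assignment = NULL,
                               marker_residue = NA_integer_,
                               species_offset = 3L) {
  required <- c("chain", "resno", "resid", "name", "x", "y", "z")
  if (!is.data.frame(particles) || !all(required %in% names(particles))) {
    stop("`particles` must be a data.frame with columns: ",
         paste(required, collapse = ", "))
  }
  if (nrow(particles) == 0L) stop("structure has no atoms")
  pos <- as.matrix(particles[, c("x", "y", "z")])
  if (!all(is.finite(pos))) stop("particle positions must be finite")
  obj <- structure(
    list(particles = particles,
         dimer_assignment = dimer_assignment,
         marker_residue = as.integer(marker_residue),
         species_offset = as.integer(species_offset)),
    class = "assembly_structure")
  if (!is.null(dimer_assignment)) validate_dimer_assignment(obj)
  obj
}

validate_dimer_assignment <- function(structure) {
  da <- structure$dimer_assignment
  chains <- unique(structure$particles$chain)
  if (is.null(names(da)) || !setequal(names(da), chains)) {
    stop("dimer_assignment must name every chain exactly once")
  }
  if (!all(da %in% c("dimer1", "dimer2"))) {
    stop("dimer assignments must be 'dimer1' or 'dimer2'")
  }
  if (!all(c("dimer1", "dimer2") %in% da)) {
    stop("each dimer needs at least one chain")
  }
  mk <- structure$marker_residue
  if (!is.na(mk)) {
    by_chain <- split(structure$particles$resno, structure$particles$chain)
    missing <- names(by_chain)[!vapply(by_chain, function(r) mk %in% r, logical(1))]
    if (length(missing)) {
      stop("marker residue ", mk, " absent from chain(s): ",
           paste(missing, collapse = ", "))
    }
  }
  invisible(structure)
}

#' @export
print.assembly_structure <- function(x, ...) {
  cat("assembly_structure:", nrow(x$particles), "particles,",
      length(unique(x$particles$chain)), "chains\n")
  if (!is.null(x$dimer_assignment)) {
    cat("  dimers:", paste(names(x$dimer_assignment),
                           x$dimer_assignment, sep = "=", collapse = " "), "\n")
  }
  if (!is.na(x$marker_residue)) cat("  marker residue:", x$marker_residue, "\n")
  invisible(x)
}

#' Coordinates of an assembly structure as an n x 3 matrix (Angstrom)
#' @param structure an `assembly_structure`.
#' @return numeric matrix with one row per particle.
#' @export
coords <- function(structure) {
  as.matrix(structure$particles[, c("x", "y", "z")])
}

#' Human/mouse SYCP1 residue-numbering maps
#'
#' The mouse alphaN-end (residues 98-172) aligns gaplessly with the human
#' alphaN-end (residues 101-175): mouse = human - 3. Human V105 maps to
#' mouse L102 and human L109 to mouse L106.
#'
#' @param resno integer vector of residue numbers.
#' @param offset numbering offset (default 3).
#' @return integer vector of mapped residue numbers.
#' @export
human_to_mouse_resno <- function(resno, offset = 3L) {
  if (any(resno < 101L | resno > 175L)) {
    stop("human alphaN-end residue numbers lie in 101..175")
  }
  as.integer(resno) - as.integer(offset)
}

#' @rdname human_to_mouse_resno
#' @export
mouse_to_human_resno <- function(resno, offset = 3L) {
  if (any(resno < 98L | resno > 172L)) {
    stop("mouse alphaN-end residue numbers lie in 98..172")
  }
  as.integer(resno) + as.integer(offset)
}

#' Gapless pairwise sequence identity
#'
#' Positional identity of two pre-aligned, gapless sequences, as used to
#' report template/target identity in homology modelling. Both the exact
#' percentage and an integer percentage (truncated toward zero) are
#' returned; truncation is used because modelling servers commonly floor
#' the displayed value.
#'
#' @param seq_a,seq_b character scalars (residue strings) of equal length.
#' @return list with `percent` (exact), `percent_int` (truncated integer),
#'   `n_identical`, `length`.
#' @export
sequence_identity <- function(seq_a, seq_b) {
  if (!is.character(seq_a) || !is.character(seq_b) ||
      length(seq_a) != 1L || length(seq_b) != 1L) {
    stop("sequences must be single character strings")
  }
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) == 0L || length(b) == 0L) stop("sequences must be non-empty")
  if (length(a) != length(b)) {
    stop("sequences must have equal length (gapless positional alignment); got ",
         length(a), " and ", length(b))
  }
  n_id <- sum(a == b)
  pct <- 100 * n_id / length(a)
  list(percent = pct, percent_int = as.integer(trunc(pct)),
       n_identical = n_id, length = length(a))
}
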