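#' Coarse-grained model parameters
#'
#' One bead per residue of the SYCP1 alphaN-end (human 101-175, 75 beads per
#' chain). Lengths are in Angstrom, energies in reduced units of kT at
#' 310 K (1 energy unit = kT310 ~ 2.58 kJ/mol), time in ns, friction in
#' kT310 * ns / A^2.
#'
#' @param beads_per_chain beads per chain; default 75.
#' @param bond_length backbone bead spacing (A); default 1.5, the axial
#'   rise per residue of a coiled coil.
#' @param bond_stiffness backbone spring constant (kT/A^2).
#' @param bend_stiffness next-nearest-neighbour spring constant (kT/A^2)
#'   keeping chains extended.
#' @param pair_stiffness spring constant of the cross-links holding the two
#'   chains of a dimer together (kT/A^2).
#' @param interface_well_depth depth per attractive tip-tip well (kT);
#'   frozen calibration value, see the methods vignette.
#' @param interface_cutoff interface well length scale (A); the Gaussian
#'   well width is `interface_cutoff / 2`.
#' @param friction per-bead friction gamma (kT310 * ns / A^2); default 0.5,
#'   i.e. a free-bead diffusivity of 2 A^2/ns.
#' @param temperature simulation temperature (K); 310 by default. 0 is
#'   allowed and disables thermal noise (deterministic limit).
#' @param timestep integration timestep (ns).
#' @param force_scale frozen calibration factor converting the per-atom
#'   steering forces of the all-atom assay (kJ mol^-1 nm^-1) into per-bead
#'   CG forces; see the methods vignette.
#' @return list of class `cg_params`.
#' @export
cg_params <- function(beads_per_chain = 75L,
                      bond_length = 1.5,
                      bond_stiffness = 25,
                      bend_stiffness = 10,
                      pair_stiffness = 5,
                      interface_well_depth = 10,
                      interface_cutoff = 6,
                      friction = 0.5,
                      temperature = 310,
                      timestep = 0.005,
                      force_scale = 130) {
  p <- list(beads_per_chain = as.integer(beads_per_chain),
            bond_length = bond_length, bond_stiffness = bond_stiffness,
            bend_stiffness = bend_stiffness, pair_stiffness = pair_stiffness,
            interface_well_depth = interface_well_depth,
            interface_cutoff = interface_cutoff,
            friction = friction, temperature = temperature,
            timestep = timestep, force_scale = force_scale)
  if (p$beads_per_chain < 12L) {
    stop("beads_per_chain must be >= 12 to host the 11-bead alphaN-tip")
  }
  pos <- c("bond_length", "bond_stiffness", "bend_stiffness",
           "pair_stiffness", "interface_cutoff", "friction", "timestep",
           "force_scale")
  for (f in pos) if (!is.numeric(p[[f]]) || p[[f]] <= 0) {
    stop("`", f, "` must be positive")
  }
  if (p$interface_well_depth < 0) stop("interface_well_depth must be >= 0")
  if (p$temperature < 0) stop("temperature must be >= 0")
  class(p) <- "cg_params"
  p
}

#' Steering configuration: opposing axial forces on the two dimers
#'
#' Mirrors the steered assay in which a constant force is applied to every
#' atom of each dimer, directed along the axial axis in opposite directions
#' so that the head-to-head interacting dimers are pulled apart.
#'
#' @param force per-bead force magnitude in kJ mol^-1 nm^-1 (the units of
#'   the per-atom force grid 0.025/0.05/0.075/0.10); must be >= 0.
#' @param axis steering axis (3-vector, normalized internally). dimer1 is
#'   pulled along `-axis`, dimer2 along `+axis`.
#' @return list of class `steering_config`.
#' @export
steering_config <- function(force = 0.05, axis = c(0, 0, 1)) {
  if (!is.numeric(force) || length(force) != 1L || force < 0) {
    stop("steering force must be a single value >= 0")
  }
  if (length(axis) != 3L || !all(is.finite(axis)) || sum(axis^2) == 0) {
    stop("axis must be a finite non-zero 3-vector")
  }
  structure(list(force = force, axis = axis / sqrt(sum(axis^2))),
            class = "steering_config")
}

#' Genotype-dependent interface scale factors
#'
#' Glutamate substitution of the conserved tip leucines is modelled as a
#' weakening of the head-to-head interface: the well depth is multiplied by
#' a calibrated scale in `[0, 1]`. Scales were calibrated once so that, at
#' the mid steering force, the wild type holds and the single/double core
#' mutants dissociate, and then frozen (see methods vignette). The ordering
#' WT > L102E > L106E >= L102E/L106E always holds.
#'
#' @param label genotype label: `"WT"`, `"L102E"`, `"L106E"` or
#'   `"L102E/L106E"`.
#' @return list of class `genotype_factor` with `label` and `scale`.
#' @export
genotype_scale <- function(label) {
  scales <- c("WT" = 1.0, "L102E" = 0.55, "L106E" = 0.19,
              "L102E/L106E" = 0.11)
  if (!is.character(label) || length(label) != 1L || !label %in% names(scales)) {
    stop("unknown genotype label '", paste(label, collapse = ","),
         "'; valid labels: ", paste(names(scales), collapse = ", "))
  }
  structure(list(label = label, scale = unname(scales[[label]])),
            class = "genotype_factor")
}

# Geometry constants of the built tetramer (Angstrom): the two chains of a
# dimer sit at x = +/- CHAIN_HALF_SEP; the two dimers are offset laterally
# by +/- DIMER_HALF_SEP in y and their tips interdigitate axially over
# TIP_OVERLAP, placing the marker residues (tip position 9) of the two
# dimers side by side as in the closed head-to-head conformation.
.CHAIN_HALF_SEP <- 5
.DIMER_HALF_SEP <- 3
.TIP_OVERLAP <- 24
.TIP_LEN <- 11L   # alphaN-tip beads per chain (human residues 101-111)
.MARKER_HUMAN <- 109L

#' Build the head-to-head dimer-of-dimers coarse-grained model
#'
#' Places two parallel-chain dimers end-to-end along the steering axis (z)
#' with their alphaN-tips (first 11 beads per chain, human residues
#' 101-111) interdigitating, so that the marker residues (h.L109) of the
#' two dimers start less than 10 A apart — the geometry of an intact
#' interface. Attractive Gaussian wells connect tip beads of opposing
#' dimers; their depth is `interface_well_depth * scale(genotype)`.
#'
#' @param params a [cg_params()] object.
#' @param genotype a [genotype_scale()] object or genotype label string.
#' @return list of class `cg_model` with fields `structure`
#'   (`assembly_structure`), `coords`, spring and pair tables, and `params`.
#' @export
build_tetramer_model <- function(params = cg_params(), genotype = "WT") {
  stopifnot(inherits(params, "cg_params"))
  if (is.character(genotype)) genotype <- genotype_scale(genotype)
  stopifnot(inherits(genotype, "genotype_factor"))
  nb <- params$beads_per_chain
  rise <- params$bond_length

  chain_z <- function(dimer) {
    b <- seq_len(nb) - 1L
    if (dimer == 1L) .TIP_OVERLAP / 2 - b * rise else -.TIP_OVERLAP / 2 + b * rise
  }
  chains <- list(
    A = cbind(+.CHAIN_HALF_SEP, -.DIMER_HALF_SEP, chain_z(1L)),
    B = cbind(-.CHAIN_HALF_SEP, -.DIMER_HALF_SEP, chain_z(1L)),
    C = cbind(+.CHAIN_HALF_SEP, +.DIMER_HALF_SEP, chain_z(2L)),
    D = cbind(-.CHAIN_HALF_SEP, +.DIMER_HALF_SEP, chain_z(2L)))
  xyz <- do.call(rbind, chains)
  resno <- rep(100L + seq_len(nb), 4L)  # human numbering 101..(100+nb)
  particles <- data.frame(
    chain = rep(c("A", "B", "C", "D"), each = nb),
    resno = resno, resid = "GLY", name = "CA",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE)
  struct <- assembly_structure(particles)
  struct <- assign_dimers(
    struct,
    c(A = "dimer1", B = "dimer1", C = "dimer2", D = "dimer2"),
    marker_residue = .MARKER_HUMAN)

  # Harmonic springs: backbone (i,i+1), bend (i,i+2), inter-chain
  # cross-links between like-numbered beads of the two chains of a dimer.
  off <- setNames((0:3) * nb, c("A", "B", "C", "D"))
  springs <- list()
  for (ch in names(off)) {
    i <- off[[ch]] + seq_len(nb)
    springs[[length(springs) + 1L]] <- data.frame(
      i = i[-nb], j = i[-1], k = params$bond_stiffness, r0 = rise)
    springs[[length(springs) + 1L]] <- data.frame(
      i = i[seq_len(nb - 2L)], j = i[-(1:2)],
      k = params$bend_stiffness, r0 = 2 * rise)
  }
  for (pair in list(c("A", "B"), c("C", "D"))) {
    i <- off[[pair[1]]] + seq_len(nb)
    j <- off[[pair[2]]] + seq_len(nb)
    springs[[length(springs) + 1L]] <- data.frame(
      i = i, j = j, k = params$pair_stiffness, r0 = 2 * .CHAIN_HALF_SEP)
  }
  springs <- do.call(rbind, springs)

  # Interface wells: tip beads of each chain against the tip beads of the
  # laterally adjacent chain of the opposing dimer (A-C and B-D); the
  # contact well has its minimum at the lateral chain-chain distance.
  pairs <- rbind(
    expand.grid(i = off[["A"]] + seq_len(.TIP_LEN),
                j = off[["C"]] + seq_len(.TIP_LEN)),
    expand.grid(i = off[["B"]] + seq_len(.TIP_LEN),
                j = off[["D"]] + seq_len(.TIP_LEN)))
  eps <- params$interface_well_depth * genotype$scale
  structure(list(structure = struct, coords = xyz,
                 springs = springs, pairs = pairs,
                 interface_eps = eps,
                 interface_width = params$interface_cutoff / 2,
                 interface_rest = 2 * .DIMER_HALF_SEP,
                 dimer_index = rep(c(1L, 1L, 2L, 2L), each = nb),
                 genotype = genotype, params = params),
            class = "cg_model")
}

#' @export
print.cg_model <- function(x, ...) {
  cat("cg_model:", nrow(x$coords), "beads,", x$genotype$label,
      sprintf("(interface scale %.2f, eps %.2f kT/pair)\n",
              x$genotype$scale, x$interface_eps))
  invisible(x)
}

# Model with n unconnected beads; used for diffusion-limit validation.
cg_free_model <- function(n, spacing = 20) {
  g <- ceiling(n^(1 / 3))
  idx <- seq_len(n) - 1L
  xyz <- cbind(idx %% g, (idx %/% g) %% g, idx %/% (g * g)) * spacing
  particles <- data.frame(chain = "A", resno = seq_len(n), resid = "GLY",
                          name = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          stringsAsFactors = FALSE)
  structure(list(structure = assembly_structure(particles), coords = xyz,
                 springs = data.frame(i = integer(), j = integer(),
                                      k = numeric(), r0 = numeric()),
                 pairs = data.frame(i = integer(), j = integer()),
                 interface_eps = 0, interface_width = 1, interface_rest = 0,
                 dimer_index = rep(0L, n),
                 genotype = genotype_scale("WT"), params = cg_params()),
            class = "cg_model")
}
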