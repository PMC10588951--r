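#' Run overdamped Brownian dynamics on a coarse-grained model
#'
#' Integrates the position-Langevin equation
#' `dx = (F/gamma) dt + sqrt(2 kT dt / gamma) xi` for every bead, with
#' harmonic bonded terms, genotype-scaled attractive interface wells, and
#' (optionally) a constant steering force applied to every bead of each
#' dimer in opposite axial directions. Deterministic given the seed.
#'
#' @param model a [build_tetramer_model()] result.
#' @param steering a [steering_config()], or `NULL` for an unsteered run.
#' @param duration run length in ns (default 100).
#' @param seed RNG seed (integer).
#' @param record_interval time between recorded frames in ns (default 0.5).
#' @return a [trajectory()] (`cg_trajectory`) whose structure field holds
#'   the model's `assembly_structure`.
#' @export
simulate_assembly <- function(model, steering = NULL, duration = 100,
                              seed = 1L, record_interval = 0.5) {
  stopifnot(inherits(model, "cg_model"))
  if (!is.null(steering) && !inherits(steering, "steering_config")) {
    stop("`steering` must be a steering_config or NULL")
  }
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  p <- model$params
  dt <- p$timestep
  n_steps <- max(1L, as.integer(round(duration / dt)))
  stride <- max(1L, as.integer(round(record_interval / dt)))
  n <- nrow(model$coords)

  steer <- matrix(0, n, 3)
  if (!is.null(steering) && steering$force > 0) {
    f_internal <- steering_force_internal(steering$force, p$force_scale)
    # dimer1 pulled along -axis, dimer2 along +axis ("opposite directions
    # for each constituent dimer"); beads outside either dimer feel nothing
    sgn <- c(0, -1, 1)[model$dimer_index + 1L]
    steer <- outer(sgn * f_internal, steering$axis)
  }
  kT <- p$temperature / 310  # reduced units: kT310 = 1

  set.seed(seed)
  res <- .cg_run(model$coords,
                 as.integer(model$springs$i - 1L),
                 as.integer(model$springs$j - 1L),
                 as.numeric(model$springs$k), as.numeric(model$springs$r0),
                 as.integer(model$pairs$i - 1L),
                 as.integer(model$pairs$j - 1L),
                 model$interface_eps, model$interface_width,
                 model$interface_rest,
                 steer, p$friction, kT, dt, n_steps, stride,
                 p$bond_length * 3)
  nf <- length(res$times)
  arr <- array(res$frames, dim = c(n, 3, nf))
  trajectory(arr, res$times, names = model$structure$particles$name,
             structure = model$structure)
}

# Convert the user-facing per-bead steering force (kJ mol^-1 nm^-1, the
# per-atom units of the all-atom assay) into reduced kT310/A, including the
# frozen per-atom -> per-bead calibration factor.
steering_force_internal <- function(force_kj_mol_nm, force_scale) {
  kT310 <- .KB_KJ_PER_MOL_K * 310
  force_kj_mol_nm * 0.1 / kT310 * force_scale
}

#' Simulate one genotype and classify its dissociation behaviour
#'
#' Convenience wrapper chaining [build_tetramer_model()],
#' [simulate_assembly()], [interdimer_series()] and
#' [detect_dissociation()].
#'
#' @param genotype genotype label (see [genotype_scale()]).
#' @param force per-bead steering force (kJ mol^-1 nm^-1).
#' @param duration run length, ns.
#' @param seed RNG seed.
#' @param params a [cg_params()].
#' @param ... passed to [detect_dissociation()].
#' @return a `dissociation_result` (see [detect_dissociation()]) with the
#'   trajectory attached as attribute `"trajectory"`.
#' @export
run_dissociation_assay <- function(genotype, force = 0.05, duration = 100,
                                   seed = 1L, params = cg_params(), ...) {
  model <- build_tetramer_model(params, genotype)
  traj <- simulate_assembly(model, steering_config(force = force),
                            duration = duration, seed = seed)
  ser <- interdimer_series(traj)
  res <- detect_dissociation(ser$time, ser$distance, ...)
  attr(res, "trajectory") <- traj
  res
}
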