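# Marker-centroid positions projected on the steering axis; used for the
# closed-form drift checks where the Euclidean marker distance is still
# dominated by the fixed lateral offset.
axial_separation <- function(traj, axis = c(0, 0, 1)) {
  s <- traj$structure
  p <- s$particles
  dim_of <- s$dimer_assignment[p$chain]
  i1 <- which(dim_of == "dimer1" & p$resno == s$marker_residue)
  i2 <- which(dim_of == "dimer2" & p$resno == s$marker_residue)
  vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_coords(traj, f)
    sum((colMeans(m[i2, , drop = FALSE]) -
           colMeans(m[i1, , drop = FALSE])) * axis)
  }, numeric(1))
}

test_that("the default tetramer has 300 beads and an intact interface geometry", {
  m <- build_tetramer_model()
  expect_equal(nrow(m$coords), 300L)
  expect_equal(length(unique(m$structure$particles$chain)), 4L)
  d0 <- interdimer_distance(coords(m$structure), m$structure)
  expect_lt(d0, 10)
  expect_error(build_tetramer_model(cg_params(beads_per_chain = 8)),
               ">= 12")
})

test_that("genotype scales anchor WT at 1 and obey the severity ordering", {
  expect_equal(genotype_scale("WT")$scale, 1.0)
  s <- vapply(c("WT", "L102E", "L106E", "L102E/L106E"),
              function(g) genotype_scale(g)$scale, numeric(1))
  expect_true(s["WT"] > s["L102E"])
  expect_true(s["L102E"] > s["L106E"])
  expect_true(s["L106E"] >= s["L102E/L106E"])
  expect_error(genotype_scale("L999X"), "WT.*L102E.*L106E")
})

test_that("simulation is bitwise deterministic under a fixed seed", {
  m <- build_tetramer_model()
  t1 <- simulate_assembly(m, steering_config(0.05), duration = 2, seed = 42)
  t2 <- simulate_assembly(m, steering_config(0.05), duration = 2, seed = 42)
  expect_identical(t1$coords, t2$coords)
  t3 <- simulate_assembly(m, steering_config(0.05), duration = 2, seed = 43)
  expect_false(identical(t1$coords, t3$coords))
})

test_that("noise-free, interface-free steering separates dimers at 2F/gamma", {
  p <- cg_params(temperature = 0, interface_well_depth = 0)
  m <- build_tetramer_model(p, "WT")
  tr <- simulate_assembly(m, steering_config(0.05), duration = 10, seed = 1)
  sep <- axial_separation(tr)
  v_expected <- 2 * scassembly:::steering_force_internal(0.05, p$force_scale) /
    p$friction
  v_measured <- (sep[length(sep)] - sep[1]) / (tail(tr$times, 1) - tr$times[1])
  expect_equal(v_measured, v_expected, tolerance = 0.01)
  # and the growth is linear: residuals from the line are negligible
  fit <- lm(sep ~ tr$times)
  expect_lt(max(abs(residuals(fit))), 1e-6 * max(abs(sep)))
})

test_that("free beads diffuse with MSD = 6 (kT/gamma) t (Einstein relation)", {
  p <- cg_params()
  m <- scassembly:::cg_free_model(343)
  tt <- 8
  tr <- simulate_assembly(m, NULL, duration = tt, seed = 5,
                          record_interval = tt)
  msd <- mean(rowSums((frame_coords(tr, n_frames(tr)) -
                         frame_coords(tr, 1))^2))
  expect_equal(msd, 6 * (1 / p$friction) * tt, tolerance = 0.10)
})

test_that("an oversized timestep triggers the instability guard", {
  m <- build_tetramer_model(cg_params(timestep = 5))
  expect_error(simulate_assembly(m, NULL, duration = 50, seed = 1),
               "smaller timestep")
})

test_that("translating the whole model leaves the distance series unchanged", {
  m1 <- build_tetramer_model()
  m2 <- m1
  m2$coords <- m1$coords + matrix(rep(c(30, -12, 7), each = nrow(m1$coords)),
                                  ncol = 3)
  m2$structure$particles[, c("x", "y", "z")] <- m2$coords
  s1 <- interdimer_series(simulate_assembly(m1, steering_config(0.05),
                                            duration = 5, seed = 3))
  s2 <- interdimer_series(simulate_assembly(m2, steering_config(0.05),
                                            duration = 5, seed = 3))
  expect_equal(s1$distance, s2$distance, tolerance = 1e-10)
})

test_that("rotating the model about the steering axis is statistically neutral", {
  m1 <- build_tetramer_model()
  R <- rotation_about(c(0, 0, 1), pi / 2)
  m2 <- m1
  m2$coords <- m1$coords %*% t(R)
  m2$structure$particles[, c("x", "y", "z")] <- m2$coords
  s1 <- interdimer_series(simulate_assembly(m1, steering_config(0.05),
                                            duration = 20, seed = 4))
  s2 <- interdimer_series(simulate_assembly(m2, steering_config(0.05),
                                            duration = 20, seed = 4))
  expect_equal(mean(s2$distance), mean(s1$distance), tolerance = 0.10)
})

test_that("unsteered wild-type interfaces stay intact across seeds", {
  for (s in 1:3) {
    r <- run_dissociation_assay("WT", force = 0, duration = 60, seed = s)
    expect_equal(r$status, "intact")
  }
})
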