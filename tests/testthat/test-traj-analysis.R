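test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(1)
  X <- random_coords(8)
  expect_equal(kabsch_superpose(X, X)$rmsd, 0, tolerance = 1e-12)
  expect_equal(kabsch_superpose(X, X)$rotation, diag(3), tolerance = 1e-9)

  R <- rotation_about(c(0, 0, 1), pi / 2)
  Y <- X %*% t(R) + matrix(rep(c(5, 0, 0), each = 8), ncol = 3)
  k <- kabsch_superpose(X, Y)
  expect_equal(k$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(k$rotation), 1, tolerance = 1e-10)
  expect_equal(X %*% t(k$rotation) +
                 matrix(rep(k$translation, each = 8), ncol = 3),
               Y, tolerance = 1e-9)
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "3 particles")
  expect_error(kabsch_superpose(X, X[1:5, ]), "equal shape")
})

test_that("Kabsch RMSD matches the rotation-search oracle on noisy toys", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    X <- random_coords(n)
    Y <- X %*% t(rotation_about(rnorm(3), runif(1, 0, pi))) +
      matrix(rnorm(3 * n, sd = 0.5), n, 3)
    k <- kabsch_superpose(X, Y)$rmsd
    b <- rmsd_rotation_search(X, Y, n_coarse = 50000L, n_fine = 50000L)
    expect_gte(b, k - 1e-9)        # the search can never beat the optimum
    expect_lt(b - k, 1e-3)
    # superposed RMSD never exceeds the unsuperposed RMSD
    raw <- sqrt(mean(rowSums((sweep(X, 2, colMeans(X)) -
                                sweep(Y, 2, colMeans(Y)))^2)))
    expect_lte(k, raw + 1e-12)
  }
})

test_that("RMSD series is zero for itself and for rigidly moved copies", {
  set.seed(2)
  X <- random_coords(10)
  frames <- lapply(0:4, function(i) {
    X %*% t(rotation_about(c(1, 1, 0), i * 0.3)) + i * 2
  })
  traj <- toy_trajectory(frames)
  ser <- rmsd_series(traj)
  expect_equal(ser$rmsd[1], 0, tolerance = 1e-12)
  expect_true(all(ser$rmsd < 1e-9))
  expect_error(rmsd_series(traj, reference_frame = 9), "out of range")
  expect_error(rmsd_series(traj, selection = integer(0)), "empty selection")
})

test_that("RMSD of a symmetric two-particle stretch matches the hand value", {
  # octahedron anchors; stretch the two x-vertices outward by +/- 3 A along
  # x: centroid and optimal rotation are unchanged, so
  # rmsd = sqrt(2 * 3^2 / N) exactly
  a <- 4
  X <- rbind(c(a, 0, 0), c(-a, 0, 0), c(0, a, 0),
             c(0, -a, 0), c(0, 0, a), c(0, 0, -a))
  Y <- X
  Y[1, 1] <- a + 3
  Y[2, 1] <- -a - 3
  traj <- toy_trajectory(list(X, Y))
  ser <- rmsd_series(traj)
  expect_equal(ser$rmsd[2], sqrt(2 * 9 / nrow(X)), tolerance = 1e-10)
})

test_that("RMSF reproduces static, two-point and Gaussian-jitter cases", {
  set.seed(4)
  X <- random_coords(6)
  static <- toy_trajectory(list(X, X, X))
  expect_true(all(rmsf(static) < 1e-12))
  expect_error(rmsf(toy_trajectory(list(X))), "two frames")

  # one particle alternating +/- a about a fixed frame -> RMSF = a
  a <- 2.5
  up <- X; up[3, ] <- X[3, ] + c(0, 0, a)
  dn <- X; dn[3, ] <- X[3, ] - c(0, 0, a)
  alt <- toy_trajectory(rep(list(up, dn), 10))
  r <- rmsf(alt, align_to_mean = FALSE)
  expect_equal(r[3], a, tolerance = 1e-12)
  expect_true(all(r[-3] < 1e-12))

  # isotropic jitter of sd sigma per coordinate -> RMSF -> sigma * sqrt(3)
  sigma <- 0.8
  n_fr <- 10000L
  base <- random_coords(5, scale = 10)
  jit <- lapply(seq_len(n_fr), function(i) {
    base + matrix(rnorm(15, sd = sigma), 5, 3)
  })
  rj <- rmsf(toy_trajectory(jit), align_to_mean = FALSE)
  expect_equal(mean(rj), sigma * sqrt(3), tolerance = 0.03)
})

test_that("interdimer distance is the marker-centroid separation", {
  s <- toy_marker_structure()
  f <- coords(s)
  # marker particles sit at z = 0 (dimer1) and z = 6 (dimer2)
  expect_equal(interdimer_distance(f, s), 6)
  f2 <- f
  f2[3:4, 3] <- f2[3:4, 3] + 50   # translate dimer2 along the centroid axis
  expect_equal(interdimer_distance(f2, s), 56)
  # invariant under global rigid motion
  R <- rotation_about(c(1, 2, 3), 1.1)
  expect_equal(interdimer_distance(f %*% t(R) + 7, s), 6, tolerance = 1e-10)
  s_bad <- s
  s_bad$marker_residue <- 99L
  expect_error(interdimer_distance(f, s_bad), "absent")
})

test_that("dissociation classification follows the threshold rules", {
  tt <- seq(0, 100, by = 0.5)
  # constant 7 A: intact
  r <- detect_dissociation(tt, rep(7, length(tt)))
  expect_equal(r$status, "intact")
  expect_true(is.na(r$disruption_time))

  # step from 7 to 40 A at 50 ns: dissociated at 50 ns
  d <- ifelse(tt < 50, 7, 40)
  r <- detect_dissociation(tt, d)
  expect_equal(r$status, "dissociated")
  expect_equal(r$disruption_time, 50)

  # smooth oscillation between 8 and 15 A: loosened, never dissociated
  d <- 11.5 + 3.5 * sin(tt / 3)
  r <- detect_dissociation(tt, d)
  expect_equal(r$status, "loosened")
  expect_true(is.na(r$disruption_time))

  expect_error(detect_dissociation(c(0, 0, 1), c(1, 2, 3)), "increasing")
  expect_error(detect_dissociation(numeric(0), numeric(0)), "non-empty")
})

test_that("dissociation calls are stable under finer resampling", {
  tt <- seq(0, 100, by = 1)
  d <- ifelse(tt < 42, 7, 45) + 0.5 * sin(tt)
  r1 <- detect_dissociation(tt, d)
  tt2 <- seq(0, 100, by = 0.25)
  d2 <- approx(tt, d, xout = tt2)$y
  r2 <- detect_dissociation(tt2, d2)
  expect_equal(r1$status, r2$status)
  expect_lt(abs(r1$disruption_time - r2$disruption_time), 1 + 1e-9)
})

test_that("trajectory metrics are invariant under global rigid motion", {
  m <- build_tetramer_model()
  tr <- simulate_assembly(m, steering_config(0.05), duration = 5, seed = 9)
  R <- rotation_about(c(0.3, -1, 0.5), 0.8)
  shift <- c(12, -4, 30)
  tr2 <- tr
  for (f in seq_len(n_frames(tr))) {
    tr2$coords[, , f] <- tr$coords[, , f] %*% t(R) +
      matrix(rep(shift, each = dim(tr$coords)[1]), ncol = 3)
  }
  expect_equal(rmsd_series(tr2)$rmsd, rmsd_series(tr)$rmsd, tolerance = 1e-6)
  expect_equal(rmsf(tr2), rmsf(tr), tolerance = 1e-6)
  expect_equal(interdimer_series(tr2)$distance, interdimer_series(tr)$distance,
               tolerance = 1e-8)
})
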