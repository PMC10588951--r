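# Shared helpers: rotations, small structures and trajectories built in code.

rotation_about <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(theta); s_ <- sin(theta); C <- 1 - c_
  matrix(c(
    a[1] * a[1] * C + c_, a[1] * a[2] * C - a[3] * s_, a[1] * a[3] * C + a[2] * s_,
    a[2] * a[1] * C + a[3] * s_, a[2] * a[2] * C + c_, a[2] * a[3] * C - a[1] * s_,
    a[3] * a[1] * C - a[2] * s_, a[3] * a[2] * C + a[1] * s_, a[3] * a[3] * C + c_),
    3, 3, byrow = TRUE)
}

# Two-chain, two-dimer toy structure with one marker particle per chain.
toy_marker_structure <- function(marker = 9L) {
  particles <- data.frame(
    chain = rep(c("A", "B"), each = 2),
    resno = rep(c(1L, marker), 2),
    resid = "GLY", name = "CA",
    x = 0, y = 0, z = c(-5, 0, 5, 6),
    stringsAsFactors = FALSE)
  s <- assembly_structure(particles)
  assign_dimers(s, c(A = "dimer1", B = "dimer2"), marker_residue = marker)
}

# n-frame trajectory holding one matrix per frame.
toy_trajectory <- function(frames, dt = 1) {
  trajectory(frames, times = (seq_along(frames) - 1) * dt)
}

random_coords <- function(n, scale = 2) {
  matrix(rnorm(3 * n, sd = scale), n, 3)
}
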