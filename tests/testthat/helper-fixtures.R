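# Shared fixtures: small trajectory sets built in code, random rotations.

# uniform random rotation matrices from normalized quaternions
rand_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# reference marker constellation (one rigid pose of thigh + exo + heel),
# local coordinates as used by the synthetic generator
ref_constellation <- function() {
  list(EPSD = c(0, 400, 30), EASD = c(0, 400, -30),
       CMD = c(0, 0, -40), CLD = c(0, 0, 40),
       exoHR = c(0, 400, 0), exoKR = c(0, 0, 0),
       R3 = c(0, 250, 60), R4 = c(40, 200, 60), R5 = c(-40, 200, 60),
       HEEL = c(100, -400, 150))
}

# trajectory set holding the constellation rotated by R[i] at frame i
posed_trajectories <- function(rotations, rate = 100, origin = c(0, 0, 0)) {
  locals <- ref_constellation()
  n <- length(rotations)
  pos <- array(NA_real_, c(n, length(locals), 3L))
  for (i in seq_len(n))
    for (j in seq_along(locals))
      pos[i, j, ] <- origin + rotations[[i]] %*% locals[[j]]
  marker_trajectory_set(names(locals), pos, rate)
}

# tiny hand-built trajectory set: m markers moving linearly
linear_trajectories <- function(n = 20, labels = c("A", "B"), rate = 100) {
  pos <- array(NA_real_, c(n, length(labels), 3L))
  for (j in seq_along(labels))
    for (k in 1:3)
      pos[, j, k] <- (seq_len(n) - 1) * k + 10 * j
  marker_trajectory_set(labels, pos, rate)
}

# random gait_cycle_set for statistics oracles
random_cycle_set <- function(n_cycles, seed = 1) {
  set.seed(seed)
  cycles <- array(stats::rnorm(n_cycles * 101 * 3, sd = 5),
                  c(n_cycles, 101, 3))
  gait_cycle_set(events = seq_len(n_cycles + 3) * 110, cycles = cycles,
                 excluded = data.frame(cycle = integer(),
                                       reason = character()),
                 rate = 100)
}

cycle_set_from_array <- function(cycles, rate = 100) {
  gait_cycle_set(events = seq_len(dim(cycles)[1] + 3) * 110,
                 cycles = cycles,
                 excluded = data.frame(cycle = integer(),
                                       reason = character()),
                 rate = rate)
}
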