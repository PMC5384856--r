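# shared fixtures and independent oracles, built in code at test time

rand_quat <- function() shellfield:::quat_random_uniform()

# independent Coulomb field oracle: SI throughout, then MV/cm
coulomb_oracle <- function(q_e, r_angstrom) {
  e <- 1.602176634e-19
  k <- 8.9875517873681764e9
  E_V_per_m <- k * q_e * e / (r_angstrom * 1e-10)^2
  E_V_per_m / 1e8
}

# brute-force field of a set of point charges at `point` (e, Angstrom)
brute_force_field <- function(pos, q, point) {
  k <- coulomb_oracle(1, 1)  # MV/cm per e/A^2
  E <- c(0, 0, 0)
  for (i in seq_len(nrow(pos))) {
    R <- point - pos[i, ]
    r <- sqrt(sum(R^2))
    E <- E + k * q[i] * R / r^3
  }
  E
}

# hand-summed pairwise energy oracle for two 5-site waters in open space
pair_energy_oracle <- function(sites1, sites2, sigma, eps) {
  kq <- 8.9875517873681764e9 * 1.602176634e-19^2 / 1e-10 *
    6.02214076e23 / 1000
  o1 <- unlist(sites1[sites1$site == "O", c("x", "y", "z")])
  o2 <- unlist(sites2[sites2$site == "O", c("x", "y", "z")])
  r <- sqrt(sum((o1 - o2)^2))
  sr6 <- (sigma / r)^6
  e <- 4 * eps * (sr6^2 - sr6)
  for (a in seq_len(nrow(sites1))) {
    for (b in seq_len(nrow(sites2))) {
      if (sites1$charge[a] == 0 || sites2$charge[b] == 0) next
      d <- sqrt((sites1$x[a] - sites2$x[b])^2 +
                  (sites1$y[a] - sites2$y[b])^2 +
                  (sites1$z[a] - sites2$z[b])^2)
      e <- e + kq * sites1$charge[a] * sites2$charge[b] / d
    }
  }
  e
}

# two-water frame helper
two_water_frame <- function(p1, p2, q1 = shellfield:::quat_identity(),
                            q2 = shellfield:::quat_identity()) {
  frame_from_waters(list(rigid_water(p1, q1), rigid_water(p2, q2)))
}
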