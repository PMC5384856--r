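test_that("C2 probe geometry: midpoint, direction, label invariance", {
  mk2 <- function(P, O1, O2) {
    atoms <- tibble::tibble(label = c("P", "O1", "O2"),
                            x = c(P[1], O1[1], O2[1]),
                            y = c(P[2], O1[2], O2[2]),
                            z = c(P[3], O1[3], O2[3]),
                            charge = c(1, -1, -1),
                            sigma = 3, epsilon = 0.5)
    structure(list(name = "toy", atoms = atoms,
                   probe_atoms = list(P = "P", O1 = "O1", O2 = "O2")),
              class = "solute_geometry")
  }
  p <- c2_probe(mk2(c(0, 0, 0), c(1, 1, 0), c(1, -1, 0)))
  expect_equal(p$point, c(1, 0, 0))
  expect_equal(p$axis, c(1, 0, 0))
  # swapping the oxygen labels changes nothing
  p2 <- c2_probe(mk2(c(0, 0, 0), c(1, -1, 0), c(1, 1, 0)))
  expect_equal(p2$point, p$point)
  expect_equal(p2$axis, p$axis)
  # asymmetric geometry: still unit norm
  p3 <- c2_probe(mk2(c(0, 0, 0), c(2, 1.5, 0), c(1, -1, 0.3)))
  expect_equal(sqrt(sum(p3$axis^2)), 1, tolerance = 1e-12)
  # collinear atoms are degenerate
  expect_error(c2_probe(mk2(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "degenerate")
})

test_that("Coulomb kernel matches the closed-form SI oracle", {
  s <- multipole_site(c(0, 0, 0), charge = 1)
  E <- field_from_charge(s, c(3, 0, 0))
  # independent oracle: q/(4 pi eps0 r^2) in SI, converted to MV/cm
  expect_equal(sqrt(sum(E^2)), coulomb_oracle(1, 3), tolerance = 1e-12)
  # frozen value of that oracle (CODATA 2018 constants): 159.9961 MV/cm
  expect_equal(sqrt(sum(E^2)), 159.9961, tolerance = 1e-5)
  expect_true(all(E == c(sqrt(sum(E^2)), 0, 0)))  # away from + charge
  # inverse square
  E1 <- field_from_charge(s, c(1, 0, 0))
  expect_equal(sqrt(sum(E1^2)) / sqrt(sum(E^2)), 9, tolerance = 1e-9)
  # zero charge, singularity
  expect_equal(field_from_charge(multipole_site(c(0, 0, 0)), c(1, 1, 1)),
               c(0, 0, 0))
  expect_error(field_from_charge(s, c(0, 0, 0)), "singular")
})

test_that("dipole kernel matches a finite two-charge oracle", {
  mu <- c(0.3, -0.2, 0.5)
  s <- multipole_site(c(0, 0, 0), dipole = mu)
  # on-axis field is 2|mu|/r^3 along mu
  muhat <- mu / sqrt(sum(mu^2))
  r <- 4
  Eax <- field_from_dipole(s, r * muhat)
  expect_equal(Eax, coulomb_oracle(1, 1) * 2 * sqrt(sum(mu^2)) / r^3 * muhat,
               tolerance = 1e-12)
  # finite-difference oracle: +-q at separation d with q d = |mu|, d = r/1000
  point <- c(2.5, 1, -1.5)
  rr <- sqrt(sum(point^2))
  d <- rr / 1000
  q <- sqrt(sum(mu^2)) / d
  pos <- rbind(muhat * d / 2, -muhat * d / 2)
  Eo <- brute_force_field(pos, c(q, -q), point)
  expect_equal(field_from_dipole(s, point), Eo, tolerance = 1e-4)
  expect_equal(field_from_dipole(multipole_site(c(0, 0, 0)), point),
               c(0, 0, 0))
})

test_that("quadrupole kernel matches a four-charge oracle and its power law", {
  # linear quadrupole: +q at +-a on z, -2q at origin; net charge and dipole 0
  a <- 0.1
  q <- 1
  pos <- rbind(c(0, 0, a), c(0, 0, -a), c(0, 0, 0))
  qs <- c(q, q, -2 * q)
  # Buckingham moment from primitive second moments
  M <- matrix(0, 3, 3)
  for (i in 1:3) M <- M + qs[i] * outer(pos[i, ], pos[i, ])
  Th <- quadrupole_from_moments(M)
  s <- multipole_site(c(0, 0, 0), quadrupole = Th)
  point <- c(6, -4, 8)  # ~100x the arrangement size
  Eo <- brute_force_field(pos, qs, point)
  expect_equal(field_from_quadrupole(s, point), Eo, tolerance = 1e-3)
  # r^-4 scaling
  E2 <- field_from_quadrupole(s, 2 * point)
  expect_equal(sqrt(sum(E2^2)) / sqrt(sum(field_from_quadrupole(s, point)^2)),
               1 / 16, tolerance = 1e-6)
  expect_equal(field_from_quadrupole(multipole_site(c(0, 0, 0)), point),
               c(0, 0, 0))
  expect_error(multipole_site(c(0, 0, 0), quadrupole = diag(3)), "traceless")
})

test_that("solvent field superposes single-molecule contributions exactly", {
  set.seed(23)
  sol <- dmp_solute()
  probe <- c2_probe(sol)
  ws <- lapply(1:10, function(i) {
    repeat {
      p <- runif(3, -7, 7)
      if (sqrt(sum((p - probe$point)^2)) > 2.5) break
    }
    rigid_water(p, rand_quat())
  })
  f <- frame_from_waters(ws, sol)
  got <- solvent_field(f, probe)
  # brute-force loop oracle over every charged site
  m <- water_model()
  allsites <- do.call(rbind, lapply(ws, function(w) {
    s <- build_water_sites(w, m)
    cbind(s$x, s$y, s$z, s$charge)
  }))
  keep <- allsites[, 4] != 0
  Eo <- brute_force_field(allsites[keep, 1:3, drop = FALSE],
                          allsites[keep, 4], probe$point)
  expect_equal(c(got$Ex, got$Ey, got$Ez), Eo, tolerance = 1e-9)
  # sum of per-molecule fields equals the frame field
  Esum <- Reduce(`+`, lapply(seq_along(ws), function(i) {
    fi <- frame_from_waters(ws[i], sol)
    g <- solvent_field(fi, probe)
    c(g$Ex, g$Ey, g$Ez)
  }))
  expect_equal(c(got$Ex, got$Ey, got$Ez), Esum, tolerance = 1e-9)
  expect_lte(abs(got$E_parallel), got$E + 1e-12)
})

test_that("mirror-symmetric waters cancel transverse components", {
  sol <- dmp_solute()
  probe <- c2_probe(sol)
  ax <- probe$axis  # (1,0,0) for the packaged geometry
  w1 <- rigid_water(probe$point + c(3, 2, 0))
  # mirror through the xz-less plane: reflect y
  w2 <- rigid_water(probe$point + c(3, -2, 0))
  f <- frame_from_waters(list(w1, w2), sol)
  g <- solvent_field(f, probe)
  f1 <- solvent_field(frame_from_waters(list(w1), sol), probe)
  expect_lt(abs(g$Ey), 1e-9)
  expect_equal(g$E_parallel, 2 * f1$E_parallel, tolerance = 1e-9)
})

test_that("zero-water frame warns and returns a zero field", {
  sol <- dmp_solute()
  probe <- c2_probe(sol)
  f <- frame_from_waters(list(), sol)
  expect_warning(g <- solvent_field(f, probe), "no waters")
  expect_equal(g$E, 0)
})

test_that("body-frame multipoles rotate with the molecule", {
  sol <- dmp_solute()
  probe <- c2_probe(sol)
  mp <- tibble::tibble(site = "O", mux = 0, muy = 0, muz = 0.2)
  set.seed(5)
  qr <- rand_quat()
  w <- rigid_water(probe$point + c(4, 1, -2), qr)
  f <- frame_from_waters(list(w), sol)
  got <- solvent_field(f, probe, multipoles = mp)
  base <- solvent_field(f, probe)
  R <- shellfield:::quat_rotation_matrix(qr)
  mu_world <- as.numeric(R %*% c(0, 0, 0.2))
  extra <- field_from_dipole(multipole_site(w$oxygen_position,
                                            dipole = mu_world), probe$point)
  expect_equal(c(got$Ex - base$Ex, got$Ey - base$Ey, got$Ez - base$Ez),
               extra, tolerance = 1e-9)
})
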