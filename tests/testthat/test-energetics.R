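test_that("Coulomb energy matches the closed form and scales with dielectric", {
  pc <- make_point_charge_pair(1, -1, 10)
  expect_equal(coulomb_energy(pc, sel_chain_a, sel_chain_b, 1),
               -33.20637, tolerance = 1e-6)
  expect_equal(coulomb_energy(pc, sel_chain_a, sel_chain_b, 80),
               -0.4150796, tolerance = 1e-6)
  pc0 <- make_point_charge_pair(0, -1, 10)
  expect_equal(coulomb_energy(pc0, sel_chain_a, sel_chain_b, 1), 0)
})

test_that("Lennard-Jones energy has its minimum at Rmin and decays to zero", {
  # rmin_half 1.5 each: contact minimum at r = 3
  at_r <- function(r) make_point_charge_pair(0, 0, r)
  expect_equal(lj_energy(at_r(3), sel_chain_a, sel_chain_b), -0.1,
               tolerance = 1e-12)
  e_far <- lj_energy(at_r(40), sel_chain_a, sel_chain_b)
  expect_lt(e_far, 0)
  expect_gt(e_far, -1e-6)

  # 3-atom brute-force hand sum
  at <- data.frame(
    serial = 1:3, name = c("C1", "C1", "C1"), resname = "DMA",
    chain = c("A", "B", "B"), resno = 1:3,
    x = c(0, 3.1, 1.0), y = c(0, 0, 2.8), z = 0,
    mass = 12.011, charge = 0, radius = 1.7,
    lj_epsilon = c(0.11, 0.2, 0.05), lj_rmin_half = c(2.0, 1.6, 1.9),
    stringsAsFactors = FALSE)
  fr <- structure_frame(at)
  hand <- 0
  for (j in 2:3) {
    r <- sqrt((at$x[j] - at$x[1])^2 + (at$y[j] - at$y[1])^2)
    eij <- sqrt(at$lj_epsilon[1] * at$lj_epsilon[j])
    rij <- at$lj_rmin_half[1] + at$lj_rmin_half[j]
    hand <- hand + eij * ((rij / r)^12 - 2 * (rij / r)^6)
  }
  expect_equal(lj_energy(fr, sel_chain_a, sel_chain_b), hand,
               tolerance = 1e-12)
})

test_that("SASA matches the single-sphere closed form and detects burial", {
  b <- make_born_sphere(1, 2)
  s <- sasa(b, probe = 1.4, n_points = 1000)
  exact <- 4 * pi * 3.4^2
  expect_lt(abs(s$total - exact) / exact, 0.01)
  expect_equal(s$total, sum(s$per_atom))

  # an atom enclosed by a shell of overlapping neighbors has ~zero area
  shell <- cleftforce:::sphere_points(40) * 1.8
  at <- data.frame(
    serial = 1:41, name = c("Q1", rep("Q2", 40)), resname = "ION",
    chain = "A", resno = 1:41,
    x = c(0, shell[, 1]), y = c(0, shell[, 2]), z = c(0, shell[, 3]),
    mass = 22.99, charge = 0, radius = c(1.0, rep(1.5, 40)),
    stringsAsFactors = FALSE)
  buried <- sasa(structure_frame(at), n_points = 500)
  expect_equal(buried$per_atom[1], 0)

  # far-apart atoms are additive
  two <- make_point_charge_pair(0, 0, 50)
  two$atoms$radius <- 2
  s2 <- sasa(two, n_points = 1000)
  expect_equal(s2$total, 2 * s$total, tolerance = 1e-9)
  expect_error(sasa(b, n_points = 50), ">= 100")
})

test_that("SASA error against the closed form shrinks with sampling density", {
  b <- make_born_sphere(1, 2)
  exact <- 4 * pi * 3.4^2
  pc <- make_point_charge_pair(0, 0, 4)   # two overlapping r=1.5 spheres
  errs <- sapply(c(100, 1000, 10000), function(n) {
    abs(sasa(b, n_points = n)$total - exact) / exact
  })
  expect_lte(errs[3], errs[1])
  expect_lt(errs[3], 1e-3)
})

test_that("the nonpolar model is affine in SASA with the stated coefficients", {
  m <- nonpolar_model()
  expect_equal(nonpolar_energy(0, m), 0.92)
  expect_equal(nonpolar_energy(1000, m), 6.32)
  a <- runif(1, 0, 2000)
  expect_equal(nonpolar_energy(2 * a, m) - nonpolar_energy(a, m),
               0.0054 * a, tolerance = 1e-12)
  expect_error(nonpolar_energy(-5, m), "non-negative")
})

test_that("polar solvation reproduces the Born ion and its q^2 scaling", {
  med <- ionic_medium(80, 2, ionic_strength_mM = 0)
  b <- make_born_sphere(1, 2)
  exact <- born_energy(1, 2)
  e2 <- polar_solvation(b, med, grid_spec(resolution = 2))
  e4 <- polar_solvation(b, med, grid_spec(resolution = 4))
  expect_lt(abs(e2 - exact) / abs(exact), 0.10)
  expect_lt(abs(e4 - exact) / abs(exact), 0.05)
  expect_lt(abs(e4 - exact), abs(e2 - exact))   # refinement improves

  expect_equal(polar_solvation(make_born_sphere(0, 2), med), 0)
  eq2 <- polar_solvation(make_born_sphere(2, 2), med, grid_spec(2))
  expect_equal(eq2 / e2, 4, tolerance = 1e-6)   # linear response: q^2
})

test_that("energy breakdowns are additive to machine precision", {
  set.seed(71)
  tr <- make_two_domain_trajectory(1, 0.1, 8, 0, seed = 9)
  fr <- get_frame(tr, 1)
  fr$atoms$charge <- round(runif(8, -0.5, 0.5), 3)
  eb <- energy_breakdown(fr, sasa_points = 200)
  expect_equal(eb$total, eb$coulomb + eb$vdw + eb$polar + eb$nonpolar,
               tolerance = 1e-12)
})

test_that("MM/PBSA binding energy: intercept offset, cancellation, symmetry", {
  # far-apart neutral LJ-free parts: only the nonpolar intercepts survive
  at <- data.frame(
    serial = 1:2, name = c("Q1", "Q2"), resname = "ION",
    chain = c("A", "B"), resno = 1:2, mass = 22.99, charge = 0,
    radius = 1.5, lj_epsilon = 0, lj_rmin_half = 1.5,
    stringsAsFactors = FALSE)
  coords <- array(0, dim = c(2, 3, 2))
  coords[2, 1, ] <- 100
  tr <- trajectory(at, coords, c(0.1, 0.2))
  rec <- mmpbsa_binding(tr, sel_chain_a, sel_chain_b, sasa_points = 200)
  expect_equal(rec$delta_e, -0.92, tolerance = 1e-9)
  expect_equal(rec$d_coulomb, 0)
  expect_equal(rec$d_vdw, 0)
  expect_equal(rec$sd, 0)

  # charged attracting pair: favourable Coulomb, desolvation penalty
  pcq <- data.frame(
    serial = 1:2, name = c("Q1", "Q2"), resname = "ION",
    chain = c("A", "B"), resno = 1:2, mass = 22.99, charge = c(1, -1),
    radius = 1.6, lj_epsilon = 0.1, lj_rmin_half = 1.6,
    stringsAsFactors = FALSE)
  cq <- array(0, dim = c(2, 3, 1)); cq[2, 1, 1] <- 6
  trq <- trajectory(pcq, cq, 0.1)
  recq <- mmpbsa_binding(trq, sel_chain_a, sel_chain_b, sasa_points = 200)
  expect_lt(recq$d_coulomb, 0)
  expect_gt(recq$d_polar, 0)

  # label-swap symmetry
  recq_sw <- mmpbsa_binding(trq, sel_chain_b, sel_chain_a, sasa_points = 200)
  expect_equal(recq$delta_e, recq_sw$delta_e, tolerance = 1e-12)

  # intra-part Coulomb/LJ cancellation: the Coulomb delta equals the pure
  # inter-part term computed directly
  fr <- get_frame(trq, 1)
  inter <- coulomb_energy(fr, sel_chain_a, sel_chain_b, dielectric = 2)
  expect_equal(recq$d_coulomb, inter, tolerance = 1e-12)
  inter_lj <- lj_energy(fr, sel_chain_a, sel_chain_b)
  expect_equal(recq$d_vdw, inter_lj, tolerance = 1e-12)

  expect_error(mmpbsa_binding(trq, sel_chain_a, sel_chain_a), "overlap")
  expect_error(mmpbsa_binding(trq, sel_chain_a, sel_chain_b,
                              t_start = 10, t_end = 20), "window")
})
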