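two_atom_frame <- function(m1, m2, x1 = 0, x2 = 4) {
  structure_frame(data.frame(
    serial = 1:2, name = c("C1", "C2"), resname = "DMA", chain = "A",
    resno = 1:2, x = c(x1, x2), y = 0, z = 0, mass = c(m1, m2),
    stringsAsFactors = FALSE))
}

test_that("mass center is the mass-weighted mean position", {
  fr <- two_atom_frame(1, 1, 0, 2)
  expect_equal(mass_center(fr), c(1, 0, 0))
  fr2 <- two_atom_frame(1, 3, 0, 4)
  expect_equal(mass_center(fr2), c(3, 0, 0))     # (0*1 + 4*3)/4
  expect_equal(mass_center(fr2, weighted = FALSE), c(2, 0, 0))
  expect_equal(mass_center(fr2, sel = 1), c(0, 0, 0))  # single atom
})

test_that("cleft series equals the generator's internal draws", {
  tr <- make_two_domain_trajectory(200, 0.1, 10, 0.5, seed = 11)
  cs <- cleft_series(tr, sel_chain_a, sel_chain_b)
  expect_equal(cs$distance_A, tr$meta$draws, tolerance = 1e-12)
  expect_equal(cs$time_ns, tr$times)
  # identical selections give an all-zero series
  cs0 <- cleft_series(tr, sel_chain_a, sel_chain_a)
  expect_equal(cs0$distance_A, rep(0, 200))
})

test_that("mass-center distance is invariant under frame-wide rigid motion", {
  set.seed(99)
  tr <- make_two_domain_trajectory(1, 0.1, 10, 0, seed = 2)
  fr <- get_frame(tr, 1)
  d0 <- sqrt(sum((mass_center(fr, sel_chain_a) -
                    mass_center(fr, sel_chain_b))^2))
  for (rep in 1:5) {
    moved <- rigid_move(fr, random_rotation(), rnorm(3, sd = 5))
    d1 <- sqrt(sum((mass_center(moved, sel_chain_a) -
                      mass_center(moved, sel_chain_b))^2))
    expect_equal(d1, d0, tolerance = 1e-9)
  }
})

test_that("window statistics count half-open windows and match brute force", {
  tr <- make_two_domain_trajectory(1000, 0.1, 10, 0.5, seed = 7)
  cs <- cleft_series(tr, sel_chain_a, sel_chain_b)
  ws <- window_stats(cs, 70, 100)
  expect_equal(ws$n_frames, 300)   # frames at 70.1 .. 100.0 ns
  keep <- cs$time_ns > 70 & cs$time_ns <= 100
  expect_equal(ws$mean, mean(cs$distance_A[keep]), tolerance = 1e-12)
  expect_equal(ws$sd, sd(cs$distance_A[keep]), tolerance = 1e-12)

  tr0 <- make_two_domain_trajectory(100, 0.1, 10, 0, seed = 1)
  cs0 <- cleft_series(tr0, sel_chain_a, sel_chain_b)
  ws0 <- window_stats(cs0, 0, 10)
  expect_equal(ws0$mean, 10)
  expect_equal(ws0$sd, 0)
  expect_error(window_stats(cs0, 200, 300), "window")
})

test_that("Kabsch RMSD is zero under rigid motion and matches the quaternion oracle", {
  set.seed(5)
  tr <- make_two_domain_trajectory(1, 0.1, 10, 0, seed = 8)
  fr <- get_frame(tr, 1)
  expect_equal(kabsch_rmsd(fr, fr), 0, tolerance = 1e-12)
  moved <- rigid_move(fr, random_rotation(), c(3, -2, 7))
  expect_lt(kabsch_rmsd(moved, fr), 1e-9)

  # displaced-atom cases against an independent eigen-decomposition route
  for (rep in 1:10) {
    p <- matrix(rnorm(12, sd = 2), ncol = 3)
    q <- p + matrix(rnorm(12, sd = 0.8), ncol = 3)
    fp <- structure_frame(data.frame(
      serial = 1:4, name = "C1", resname = "DMA", chain = "A", resno = 1:4,
      x = p[, 1], y = p[, 2], z = p[, 3], mass = 12.011))
    fq <- structure_frame(data.frame(
      serial = 1:4, name = "C1", resname = "DMA", chain = "A", resno = 1:4,
      x = q[, 1], y = q[, 2], z = q[, 3], mass = 12.011))
    expect_equal(kabsch_rmsd(fp, fq), quaternion_rmsd(p, q),
                 tolerance = 1e-9)
    expect_equal(kabsch_rmsd(fp, fq), kabsch_rmsd(fq, fp),
                 tolerance = 1e-9)
  }
})

test_that("separation translates the mobile domain along the mass-center axis", {
  tr <- make_two_domain_trajectory(1, 0.1, 10, 0, seed = 4)
  fr <- get_frame(tr, 1)
  dist_ab <- function(f) sqrt(sum((mass_center(f, sel_chain_a) -
                                     mass_center(f, sel_chain_b))^2))
  expect_equal(dist_ab(separate(fr, sel_chain_b, sel_chain_a, 0)),
               10, tolerance = 1e-12)
  sep15 <- separate(fr, sel_chain_b, sel_chain_a, 15)
  expect_equal(dist_ab(sep15), 25, tolerance = 1e-9)

  # collinear composition: 10 then 10 equals 20
  sep10x2 <- separate(separate(fr, sel_chain_b, sel_chain_a, 10),
                      sel_chain_b, sel_chain_a, 10)
  sep20 <- separate(fr, sel_chain_b, sel_chain_a, 20)
  expect_lt(max(abs(as.matrix(sep10x2$atoms[, c("x", "y", "z")]) -
                      as.matrix(sep20$atoms[, c("x", "y", "z")]))), 1e-9)

  # internal geometry of the mobile domain is untouched
  ib <- resolve_selection(fr, sel_chain_b)
  d_before <- dist(as.matrix(fr$atoms[ib, c("x", "y", "z")]))
  d_after <- dist(as.matrix(sep15$atoms[ib, c("x", "y", "z")]))
  expect_lt(max(abs(d_before - d_after)), 1e-9)
  # fixed domain and axis errors
  ia <- resolve_selection(fr, sel_chain_a)
  expect_equal(sep15$atoms$x[ia], fr$atoms$x[ia])
  expect_error(separate(fr, sel_chain_a, sel_chain_a, 5), "overlap")
  expect_error(separate(fr, sel_chain_b, sel_chain_a, -1), "non-negative")
})
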