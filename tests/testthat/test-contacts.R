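test_that("salt-bridge detection honours the inclusive 4 Angstrom cutoff", {
  expect_equal(nrow(detect_salt_bridges(make_salt_bridge_pair(3.9))), 1)
  expect_equal(nrow(detect_salt_bridges(make_salt_bridge_pair(4.1))), 0)
  expect_equal(nrow(detect_salt_bridges(make_salt_bridge_pair(4.0))), 1)
})

test_that("a residue pair with two oxygens in range yields one record", {
  at <- data.frame(
    serial = 1:3, name = c("NZ", "OE1", "OE2"),
    resname = c("LYS", "GLU", "GLU"), chain = "A", resno = c(1L, 2L, 2L),
    x = c(0, 3.2, 3.8), y = 0, z = 0,
    mass = c(14.007, 15.999, 15.999), charge = c(1, -0.76, -0.76),
    radius = c(1.85, 1.7, 1.7), stringsAsFactors = FALSE)
  hits <- detect_salt_bridges(structure_frame(at))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$distance, 3.2)   # closest atom pair kept
  expect_equal(hits$atom_b, "OE1")
})

test_that("hydrogen-bond detection applies distance and angular deviation cutoffs", {
  crit <- contact_criteria()
  expect_equal(nrow(detect_hbonds(make_hbond_triple(3.0, 0), crit)), 1)
  expect_equal(nrow(detect_hbonds(make_hbond_triple(3.0, 25), crit)), 0)
  expect_equal(nrow(detect_hbonds(make_hbond_triple(3.6, 0), crit)), 0)
  # inclusive boundaries
  expect_equal(nrow(detect_hbonds(make_hbond_triple(3.5, 0), crit)), 1)
  expect_equal(nrow(detect_hbonds(make_hbond_triple(3.0, 20), crit)), 1)
  hit <- detect_hbonds(make_hbond_triple(3.0, 12), crit)
  expect_equal(hit$distance, 3.0, tolerance = 1e-9)
  expect_equal(hit$angle, 12, tolerance = 1e-9)
})

test_that("detection is invariant under frame-wide rigid motion", {
  set.seed(31)
  for (rep in 1:5) {
    fr <- make_hbond_triple(3.3, 17)
    moved <- rigid_move(fr, random_rotation(), rnorm(3, sd = 10))
    expect_equal(nrow(detect_hbonds(moved)), 1)
    sb <- rigid_move(make_salt_bridge_pair(3.95), random_rotation(),
                     rnorm(3, sd = 10))
    expect_equal(nrow(detect_salt_bridges(sb)), 1)
  }
})

test_that("loosening any cutoff never removes a detected contact", {
  set.seed(17)
  base <- contact_criteria()
  for (rep in 1:20) {
    fr <- make_hbond_triple(runif(1, 2.5, 4.2), runif(1, 0, 40))
    tight <- nrow(detect_hbonds(fr, base))
    loose <- nrow(detect_hbonds(fr, contact_criteria(
      hbond_distance_cutoff = 4.5, hbond_angle_cutoff = 45)))
    expect_gte(loose, tight)
  }
})

test_that("occupancy equals a brute-force per-frame recount", {
  set.seed(23)
  mask <- rep(FALSE, 1000)
  mask[sample(1000, 166)] <- TRUE
  tr <- make_occupancy_trajectory(mask)
  occ <- occupancy(tr, "hbond")
  expect_equal(nrow(occ), 1)
  expect_equal(occ$occupancy, 16.6)
  # brute force: run the detector frame by frame and count
  recount <- sum(sapply(seq_len(n_frames(tr)), function(k) {
    nrow(detect_hbonds(get_frame(tr, k))) > 0
  }))
  expect_identical(occ$n_present, as.integer(recount))
  expect_identical(occ$n_present, 166L)

  expect_equal(occupancy(make_occupancy_trajectory(rep(TRUE, 40)),
                         "hbond")$occupancy, 100)
  expect_equal(nrow(occupancy(make_occupancy_trajectory(rep(FALSE, 40)),
                              "hbond")), 0)
})

test_that("high-occupancy filtering is strict and sorted descending", {
  rec <- data.frame(partner_a = c("r1", "r2", "r3"),
                    partner_b = "ATP", pair = c("p1", "p2", "p3"),
                    type = "hbond", n_present = c(58L, 166L, 546L),
                    n_frames = 1000L,
                    occupancy = c(5.8, 16.6, 54.6),
                    stringsAsFactors = FALSE)
  class(rec) <- c("occupancy_records", "data.frame")
  expect_equal(filter_occupancy(rec, 10)$occupancy, c(54.6, 16.6))
  expect_equal(nrow(filter_occupancy(rec, 0)), 3)   # 5.8 > 0
  expect_equal(nrow(filter_occupancy(rec, 100)), 0)
  expect_equal(nrow(filter_occupancy(rec, 16.6)), 1)  # strictly greater
  expect_error(filter_occupancy(rec, 101), "\\[0, 100\\]")
})

test_that("per-residue occupancy sums over a residue's pairs", {
  rec <- data.frame(partner_a = c("A:LEU905", "A:LEU905", "A:ARG916"),
                    partner_b = c("L:ATP1", "L:ADP1", "L:ATP1"),
                    pair = c("p1", "p2", "p3"), type = "hbond",
                    n_present = c(690L, 443L, 207L), n_frames = 1000L,
                    occupancy = c(69.0, 44.3, 20.7),
                    stringsAsFactors = FALSE)
  class(rec) <- c("occupancy_records", "data.frame")
  per <- residue_occupancy(rec)
  expect_equal(per$total_occupancy[per$residue == "A:LEU905"], 113.3)
  expect_equal(per$total_occupancy[per$residue == "A:ARG916"], 20.7)
  expect_equal(nrow(residue_occupancy(rec[0, ])), 0)
})
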