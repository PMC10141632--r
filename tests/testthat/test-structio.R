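test_that("multi-model PDB round trip preserves frames, order and coordinates", {
  tr <- make_two_domain_trajectory(20, 0.1, 10, 0.5, seed = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr, path)
  tr2 <- read_trajectory(path)
  expect_equal(n_frames(tr2), 20)
  expect_equal(tr2$atoms$name, tr$atoms$name)
  expect_equal(tr2$atoms$resname, tr$atoms$resname)
  expect_equal(tr2$atoms$chain, tr$atoms$chain)
  expect_equal(tr2$atoms$resno, tr$atoms$resno)
  expect_lt(max(abs(tr2$coords - tr$coords)), 5e-4)  # 3-decimal format
  expect_equal(tr2$times, tr$times, tolerance = 1e-9)
})

test_that("a single-model PDB reads as a one-frame trajectory", {
  fr <- make_salt_bridge_pair(3.5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_frame_pdb(fr, path)
  tr <- read_trajectory(path)
  expect_equal(n_frames(tr), 1)
  expect_equal(tr$atoms$name, c("NZ", "OE1"))
})

test_that("a model with a missing atom is reported by model number", {
  tr <- make_two_domain_trajectory(3, 0.1, 10, 0, seed = 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr, path)
  lines <- readLines(path)
  atom_lines <- grep("^ATOM", lines)
  # drop one atom from the second model (atoms 9..16 of the file)
  lines <- lines[-atom_lines[10]]
  writeLines(lines, path)
  expect_error(read_trajectory(path), "model 2")
})

test_that("PQR write/read round trip preserves charge, radius, coordinates", {
  b <- make_born_sphere(1, 2)
  path <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(b, path)
  line <- grep("^ATOM", readLines(path), value = TRUE)[1]
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  expect_equal(toks[length(toks) - 1], "1.0000")
  expect_equal(toks[length(toks)], "2.0000")

  tr <- make_two_domain_trajectory(1, 0.1, 8, 0.3, seed = 5)
  fr <- get_frame(tr, 1)
  fr$atoms$charge <- seq(-0.8, 0.6, length.out = 8)
  path2 <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(fr, path2)
  fr2 <- read_pqr(path2)
  expect_equal(fr2$atoms$charge, fr$atoms$charge, tolerance = 5e-5)
  expect_equal(fr2$atoms$radius, fr$atoms$radius, tolerance = 5e-5)
  for (col in c("x", "y", "z")) {
    expect_lt(max(abs(fr2$atoms[[col]] - fr$atoms[[col]])), 5e-4)
  }
})

test_that("PQR writing refuses atoms without assigned parameters", {
  tr <- make_two_domain_trajectory(1, 0.1, 8, 0, seed = 1)
  fr <- get_frame(tr, 1)
  fr$atoms$charge[3] <- NA
  expect_error(write_pqr(fr, tempfile()), "A:DMA1:C3")
})

test_that("residue-interval selections resolve closed intervals", {
  # one CA-like atom per residue, numbered 815..1100 on chain A
  n <- 1100 - 815 + 1
  at <- data.frame(serial = seq_len(n), name = "CA", resname = "GLY",
                   chain = "A", resno = 815:1100,
                   x = seq_len(n), y = 0, z = 0, mass = 12.011,
                   stringsAsFactors = FALSE)
  fr <- structure_frame(at)
  idx <- resolve_selection(fr, selection("nlobe", chain = "A",
                                         intervals = "815-906"))
  expect_length(idx, 92)   # closed interval: 906 - 815 + 1
  expect_error(
    resolve_selection(fr, selection("x", chain = "Z", intervals = "815-906")),
    "matches no atoms")
  both <- resolve_selection(fr, selection("u", chain = "A",
                                          intervals = c("815-820", "900-906")))
  expect_length(both, 6 + 7)
  # idempotent and order-independent
  expect_equal(resolve_selection(fr, selection("n", intervals = "815-906")),
               idx)
})

test_that("residue-letter anchors are validated against residue types", {
  at <- data.frame(serial = 1:2, name = "CA", resname = c("THR", "PRO"),
                   chain = "A", resno = c(815L, 906L),
                   x = c(0, 1), y = 0, z = 0, mass = 12.011,
                   stringsAsFactors = FALSE)
  fr <- structure_frame(at)
  expect_silent(resolve_selection(fr, selection("n", intervals = "T815-P906")))
  expect_warning(resolve_selection(fr, selection("n", intervals = "S815-P906")),
                 "anchor")
  expect_error(
    resolve_selection(fr, selection("n", intervals = "S815-P906"),
                      strict = TRUE),
    "anchor")
})

test_that("parameter assignment populates fields and reports net charge", {
  tr <- make_two_domain_trajectory(1, 0.1, 8, 0, seed = 1)
  fr <- get_frame(tr, 1)
  fr$atoms$charge <- NA_real_
  expect_message(out <- assign_parameters(fr), "net charge")
  expect_false(anyNA(out$atoms$charge))
  expect_equal(attr(out, "total_charge"), 0)

  pc <- make_point_charge_pair(0, 0, 5)   # table carries ION Q1/Q2 as +1/-1
  pc$atoms$charge <- NA_real_
  out2 <- suppressMessages(assign_parameters(pc))
  expect_equal(attr(out2, "total_charge"), 0)
  expect_equal(out2$atoms$charge, c(1, -1))

  pc$atoms$name[2] <- "XX"
  expect_error(suppressMessages(assign_parameters(pc)), "B:ION2:XX")
})

test_that("phosphate protonation is an explicit choice, not a default", {
  tab <- default_parameter_table()
  expect_false(any(tab$resname == "PTR"))
  tab1 <- default_parameter_table(phosphate_charge = -1)
  tab2 <- default_parameter_table(phosphate_charge = -2)
  q1 <- sum(tab1$charge[tab1$resname == "PTR"])
  q2 <- sum(tab2$charge[tab2$resname == "PTR"])
  expect_equal(q1, -1, tolerance = 1e-9)
  expect_equal(q2, -2, tolerance = 1e-9)
})
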