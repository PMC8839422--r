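test_that("PDB structure round-trip preserves coordinates to field precision", {
  car <- small_carrier(channels = list(channel_spec(3L, 45L, 0.5, 0.5)))
  st <- car$structure
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, path)
  st2 <- read_structure(path)
  expect_equal(nrow(st2$atoms), nrow(st$atoms))
  expect_lt(max(abs(st2$xyz - st$xyz)), 0.001 + 1e-12)
  expect_identical(st2$atoms$resid, st$atoms$resid)
  expect_identical(st2$atoms$name, st$atoms$name)
})

test_that("hand-written 3-residue PDB parses with exact fields", {
  lines <- c(
    "ATOM      1  N   GLU A  29      11.000  2.000  3.500  1.00  0.00",
    "ATOM      2  CA  GLU A  29      12.345  2.500  3.000  1.00  0.00",
    "ATOM      3  CA  LYS A  32       1.000 -2.250  0.125  1.00  0.00",
    "ATOM      4  NZ  LYS A  32       1.500 -2.000  1.000  1.00  0.00",
    "ATOM      5  CA  ASP A 134      -3.000  4.000  5.000  1.00  0.00",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  st <- read_structure(path)
  expect_equal(length(unique(st$atoms$resid)), 3L)
  expect_equal(st$xyz[2L, ], c(12.345, 2.5, 3.0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(st$atoms$resname[st$atoms$name == "NZ"], "LYS")
})

test_that("structureless and malformed inputs are rejected", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("TITLE     nothing here", "END"), path)
  expect_error(read_structure(path), "zero atoms|malformed")
  expect_error(read_structure("no/such/file.pdb"), "not found")
  expect_error(read_trajectory(path), "zero atoms")
})

test_that("multi-model trajectory round-trips and validates frame counts", {
  car <- small_carrier(n_frames = 5L, noise_sigma = 0.2)
  sim <- simulate_trajectory(car)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(sim$trajectory, path)
  tr2 <- read_trajectory(path, car$structure)
  expect_equal(n_frames(tr2), 5L)
  expect_lt(max(abs(tr2$coords - sim$trajectory$coords)), 0.001 + 1e-12)

  # drop one atom from model 3 -> error naming the frame
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  atom_in_3 <- which(grepl("^ATOM", lines) & seq_along(lines) > starts[3L] &
                       seq_along(lines) < starts[4L])
  writeLines(lines[-atom_in_3[1L]], path)
  expect_error(read_trajectory(path, car$structure), "frame 3")
})

test_that("selection language is deterministic, ordered, and partition-complete", {
  car <- small_carrier()
  st <- car$structure
  expect_length(select_atoms(st, "resid 29 and name CA"), 1L)
  # segment H1 = residues 1..20 in the toy numbering
  h1 <- select_atoms(st, "segment H1 and name CA", car$helix_map)
  expect_length(h1, 20L)
  expect_identical(as.integer(h1), sort(as.integer(h1)))
  # idempotence and union-of-partition
  expect_identical(select_atoms(st, "name CA"), select_atoms(st, "name CA"))
  segs <- paste0("H", 1:6)
  parts <- lapply(segs, function(s)
    as.integer(select_atoms(st, paste("segment", s, "and name CA"), car$helix_map)))
  expect_identical(sort(unlist(parts)), as.integer(select_atoms(st, "name CA")))
  expect_error(select_atoms(st, "segment H9", car$helix_map), "unknown segment")
  expect_error(select_atoms(st, "frobnicate 3"), "unknown selection keyword")
  expect_warning(select_atoms(st, "resid 9999"), "matched no atoms")
})

test_that("arginine nitrogen selection picks all guanidinium N atoms", {
  st <- make_charged_structure(matrix(c(0, 0, 0), 1L), matrix(c(9, 0, 0), 1L))
  g <- select_atoms(st, "resname ARG and name NH1 NH2 NE")
  expect_length(g, 3L)
  expect_true(all(st$atoms$element[g] == "N"))
})

test_that("config loading fills defaults and validates", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("helix_map:", "  H1: [5, 36]", "  H3: [109, 140]"), path)
  cfg <- load_config(path)
  expect_equal(cfg$cutoffs$salt_bridge, 4.0)
  expect_equal(cfg$frame_window$start_fraction, 0.2)
  expect_equal(resolve_frame_window(cfg$frame_window, 100L), 21:100)

  writeLines(c("helix_map:", "  H1: [5, 36]", "  H2: [30, 60]"), path)
  expect_error(load_config(path), "overlap")

  # the six motif pairings: 3 intra + 3 inter candidates each way = 6 + 6
  json <- withr::local_tempfile(fileext = ".json")
  pairs <- list(
    list(type = "salt_bridge", a = 32, b = 29), list(type = "salt_bridge", a = 137, b = 134),
    list(type = "salt_bridge", a = 234, b = 231), list(type = "salt_bridge", a = 137, b = 29),
    list(type = "salt_bridge", a = 234, b = 134), list(type = "salt_bridge", a = 32, b = 231),
    list(type = "hbond", a = 32, b = 29), list(type = "hbond", a = 137, b = 134),
    list(type = "hbond", a = 234, b = 231), list(type = "hbond", a = 137, b = 29),
    list(type = "hbond", a = 234, b = 134), list(type = "hbond", a = 32, b = 231))
  jsonlite::write_json(list(interactions = pairs), json, auto_unbox = TRUE)
  cfg2 <- load_config(json)
  expect_length(cfg2$interactions, 12L)
  cls <- vapply(cfg2$interactions[1:6], function(sp)
    classify_interaction(sp$a, sp$b, cfg2$helix_map), character(1L))
  expect_identical(cls, c(rep("intra_helical", 3L), rep("inter_helical", 3L)))

  expect_error(as_mgate_config(list(cutoffs = list(salt_bridge = -1))), "cutoff")
  expect_error(as_mgate_config(list(interactions = list(list(type = "bogus", a = 1, b = 2)))),
               "interactions\\[1\\]")
})
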