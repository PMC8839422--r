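test_that("superpose: identity, rigid recovery, and quaternion-method oracle", {
  set.seed(3)
  ref <- matrix(rnorm(60, sd = 5), 20L)
  tr <- superpose(ref, ref)
  expect_lt(tr$rmsd, 1e-12)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-9)
  # rigidly moved copy fits back to RMSD 0 with a proper rotation
  rot <- random_rotation()
  moved <- ref %*% t(rot) + matrix(c(3, -2, 7), 20L, 3L, byrow = TRUE)
  tr2 <- superpose(moved, ref)
  expect_lt(tr2$rmsd, 1e-9)
  expect_equal(det(tr2$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(apply_transform(moved, tr2) - ref)), 1e-9)
  # noisy copy: RMSD matches bio3d's quaternion-based least-squares fit
  noisy <- moved + matrix(rnorm(60, sd = 0.4), 20L)
  tr3 <- superpose(noisy, ref)
  fitted <- suppressWarnings(bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(noisy))))
  oracle <- sqrt(mean(rowSums((matrix(fitted, ncol = 3L, byrow = TRUE) - ref)^2)))
  expect_equal(tr3$rmsd, oracle, tolerance = 1e-9)
  expect_error(superpose(matrix(0, 3L, 3L), matrix(0, 3L, 3L)), "degenerate")
})

test_that("rmsf: static profile is zero; two-point alternation gives d", {
  car <- small_carrier(n_frames = 5L)
  sim <- simulate_trajectory(car)
  prof <- rmsf(sim$trajectory, "name CA")
  expect_lt(max(prof$rmsf), 1e-9)
  # one atom alternating between z = -d and z = +d (fit disabled): RMSF = d
  topo <- carrier_structure(
    data.frame(serial = 1L, name = "CA", resname = "ALA", chain = "A",
               resid = 1L, element = "C"),
    matrix(c(0, 0, 0), 1L))
  d <- 1.7
  frames <- lapply(rep(c(-d, d), 10L), function(z) matrix(c(0, 0, z), 1L))
  tr <- carrier_trajectory(topo, frames)
  expect_equal(rmsf(tr, "name CA", fit = FALSE)$rmsf, d, tolerance = 1e-12)
  expect_error(rmsf(tr, "name CA", frame_window = 1L), "at least 2")
})

test_that("rmsf is invariant under per-frame global rigid motion when fitting", {
  car <- small_carrier(helix_length = 8L, n_frames = 200L, noise_sigma = 0.4)
  sim <- simulate_trajectory(car)
  base <- rmsf(sim$trajectory, "name CA")
  set.seed(9)
  coords <- sim$trajectory$coords
  for (k in seq_len(dim(coords)[3L])) {
    rot <- random_rotation()
    shift <- rnorm(3L, sd = 15)
    coords[, , k] <- coords[, , k] %*% t(rot) +
      matrix(shift, dim(coords)[1L], 3L, byrow = TRUE)
  }
  moved <- carrier_trajectory(sim$trajectory$topology, coords)
  expect_equal(rmsf(moved, "name CA")$rmsf, base$rmsf, tolerance = 1e-6)
})

test_that("min_distance_series equals brute force and bounds any single pair", {
  set.seed(14)
  topo <- carrier_structure(
    data.frame(serial = 1:8, name = "CA", resname = "ALA", chain = "A",
               resid = 1:8, element = "C"),
    matrix(rnorm(24, sd = 4), 8L))
  frames <- lapply(1:12, function(k) matrix(rnorm(24, sd = 4), 8L))
  tr <- carrier_trajectory(topo, frames)
  ga <- 1:4; gb <- 5:8
  ds <- min_distance_series(tr, ga, gb)
  for (k in 1:12) {
    want <- brute_min_distance(tr$coords[, , k], ga, gb)
    expect_equal(ds$distance[k], want, tolerance = 1e-12)
    # never exceeds any specific cross pair
    expect_lte(ds$distance[k],
               sqrt(sum((tr$coords[2L, , k] - tr$coords[7L, , k])^2)) + 1e-12)
  }
  expect_error(min_distance_series(tr, 1:4, 4:8), "overlap")
  # static two-atom case
  st2 <- carrier_structure(
    data.frame(serial = 1:2, name = "CA", resname = "ALA", chain = "A",
               resid = 1:2, element = "C"),
    rbind(c(0, 0, 0), c(5, 0, 0)))
  tr2 <- carrier_trajectory(st2, list(st2$xyz, st2$xyz, st2$xyz))
  expect_equal(min_distance_series(tr2, 1L, 2L)$distance, rep(5, 3L))
})

test_that("gap_events: run semantics, duration filter, shift equivariance", {
  d <- rep(4, 60)
  d[39:43] <- 9            # frames 38..42 (0-based) open
  expect_equal(nrow(gap_events(d, 6, 10L)), 0L)
  ev <- gap_events(d, 6, 3L)
  expect_equal(ev$start_frame, 38L)
  expect_equal(ev$end_frame, 42L)
  expect_equal(ev$max_gap, 9)
  # two openings of lengths 2 and 10: min_duration 3 keeps only the long one
  d2 <- rep(4, 40)
  d2[5:6] <- 9; d2[20:29] <- 8
  ev2 <- gap_events(d2, 6, 3L)
  expect_equal(nrow(ev2), 1L)
  expect_equal(c(ev2$start_frame, ev2$end_frame), c(19L, 28L))
  expect_equal(nrow(gap_events(rep(4, 30), 6, 1L)), 0L)
  # shifting the series and the cutoff together changes nothing
  ev3 <- gap_events(d2 + 2.5, 6 + 2.5, 3L)
  expect_equal(ev3$start_frame, ev2$start_frame)
  expect_equal(ev3$end_frame, ev2$end_frame)
})

test_that("bridging solvent counts match a brute-force double scan", {
  car <- small_carrier(n_frames = 10L, noise_sigma = 0.2,
                       solvent = solvent_spec(40L, x = c(-14, -4),
                                              y = c(-5, 5), z = c(0, 12)))
  sim <- simulate_trajectory(car)
  ga <- "resid 1 and name CA"; gb <- "resid 40 and name CA"
  counts <- solvent_count_series(sim$trajectory, ga, gb, radius = 9)
  sol <- car$solvent_atoms
  ia <- as.integer(select_atoms(car$structure, ga))
  ib <- as.integer(select_atoms(car$structure, gb))
  for (k in 1:10) {
    xyz <- sim$trajectory$coords[, , k]
    want <- sum(vapply(sol, function(s)
      brute_min_distance(xyz, s, ia) <= 9 && brute_min_distance(xyz, s, ib) <= 9,
      logical(1L)))
    expect_equal(counts$count[k], want)
  }
  # solvent-free topology errors with advice
  dry <- simulate_trajectory(small_carrier(n_frames = 2L))
  expect_error(solvent_count_series(dry$trajectory, ga, gb), "solvent-free")
})

test_that("a single bridging water within radius of both groups counts once", {
  atoms <- data.frame(serial = 1:3, name = c("CA", "CA", "O"),
                      resname = c("ALA", "ALA", "HOH"), chain = c("A", "A", "W"),
                      resid = 1:3, element = c("C", "C", "O"))
  st <- carrier_structure(atoms, rbind(c(-3, 0, 0), c(3, 0, 0), c(0, 0, 0)))
  tr <- carrier_trajectory(st, list(st$xyz))
  out <- solvent_count_series(tr, 1L, 2L, radius = 4)
  expect_equal(out$count, 1L)
  expect_equal(solvent_count_series(tr, 1L, 2L, radius = 2.5)$count, 0L)
})
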