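test_that("salt-bridge detection: boundary convention and brute-force equality", {
  st <- make_charged_structure(matrix(c(0, 0, 0), 1L), matrix(c(3.0, 0, 0), 1L))
  res_basic <- 1L; res_acidic <- 2L
  got <- detect_salt_bridge(st, res_basic, res_acidic)
  n_idx <- which(st$atoms$resid == 1L & st$atoms$name %in% c("NE", "NH1", "NH2"))
  o_idx <- which(st$atoms$resid == 2L & st$atoms$name %in% c("OD1", "OD2"))
  expect_equal(got$min_distance, brute_min_distance(st$xyz, n_idx, o_idx),
               tolerance = 1e-12)
  # place single-atom sites at controlled distances via CS pseudo-atoms
  mk <- function(d) carrier_structure(
    data.frame(serial = 1:2, name = "CS", resname = "ALA", chain = "A",
               resid = 1:2, element = "X"),
    rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_true(detect_salt_bridge(mk(3.0), 1L, 2L)$present)
  expect_false(detect_salt_bridge(mk(8.0), 1L, 2L)$present)
  expect_true(detect_salt_bridge(mk(4.0), 1L, 2L)$present)  # boundary counts
  expect_error(detect_salt_bridge(mk(3), 1L, 3L), "neither canonical")
})

test_that("hydrogen-bond detection honours distance, angle, and the
           hydrogen-free fallback", {
  mk_hb <- function(angle_deg, d = 2.9, with_h = TRUE) {
    atoms <- data.frame(serial = 1:3, name = c("OG", "H1", "OD1"),
                        resname = c("SER", "SER", "ASP"), chain = "A",
                        resid = c(1L, 1L, 2L),
                        element = c("O", "H", "O"))
    a <- angle_deg * pi / 180
    xyz <- rbind(c(0, 0, 0),
                 c(cos(a), sin(a), 0),       # H at 1 A from donor
                 c(d, 0, 0))                 # acceptor along +x
    if (!with_h) {
      atoms <- atoms[-2L, ]; xyz <- xyz[-2L, , drop = FALSE]
      atoms$serial <- 1:2
    }
    carrier_structure(atoms, xyz)
  }
  expect_true(detect_hbond(mk_hb(10), "resid 1 and name OG", "resid 2 and name OD1"))
  expect_false(detect_hbond(mk_hb(60), "resid 1 and name OG", "resid 2 and name OD1"))
  expect_false(detect_hbond(mk_hb(10, d = 3.8), "resid 1 and name OG",
                            "resid 2 and name OD1"))
  # hydrogen-free topology: distance-only fallback
  expect_true(detect_hbond(mk_hb(0, d = 3.4, with_h = FALSE),
                           "resid 1 and name OG", "resid 2 and name OD1"))
  expect_error(detect_hbond(mk_hb(10), "resid 9 and name XX", "resid 2 and name OD1"),
               "unresolvable")
})

test_that("guanidinium stacking needs parallel planes within range", {
  expect_true(detect_stacking(make_stacking_structure(c(0, 0, 4)), 1L, 2L))
  expect_false(detect_stacking(make_stacking_structure(c(0, 0, 4), c(1, 0, 0)), 1L, 2L))
  expect_false(detect_stacking(make_stacking_structure(c(0, 0, 7)), 1L, 2L))
  # anti-parallel normals fold to 0 degrees
  expect_true(detect_stacking(make_stacking_structure(c(0, 0, 4), c(0, 0, -1)), 1L, 2L))
  st <- make_charged_structure(matrix(c(0, 0, 0), 1L), matrix(c(5, 0, 0), 1L))
  expect_error(detect_stacking(st, 1L, 2L), "lacks guanidinium|not ARG")
})

test_that("occupancy equals the ground-truth on-fraction exactly and is
           window/permutation consistent", {
  car <- small_carrier(n_frames = 600L, noise_sigma = 0.3,
                       channels = list(channel_spec(3L, 45L, 0.15, 0.1)))
  sim <- simulate_trajectory(car)
  spec <- list(type = "salt_bridge", a = 3L, b = 45L)
  win <- 101:600
  occ <- occupancy(sim$trajectory, spec, win)
  expect_identical(occ$percentage,
                   100 * mean(sim$ground_truth$states[win, 1L]))
  expect_identical(occ$series$present, sim$ground_truth$states[, 1L])
  # all-window degenerate cases
  on_frames <- which(sim$ground_truth$states[, 1L])
  expect_equal(occupancy(sim$trajectory, spec, on_frames)$percentage, 100)
  off_frames <- which(!sim$ground_truth$states[, 1L])
  expect_equal(occupancy(sim$trajectory, spec, off_frames)$percentage, 0)
  # permuting the window leaves occupancy unchanged; relaxing the cutoff is monotone
  set.seed(1)
  expect_equal(occupancy(sim$trajectory, spec, sample(win))$percentage,
               occ$percentage)
  prev <- -Inf
  for (cutoff in c(2.5, 3.5, 4.0, 5, 9)) {
    o <- occupancy(sim$trajectory, c(spec, cutoff = cutoff), win)$percentage
    expect_gte(o, prev)
    prev <- o
  }
  expect_error(occupancy(sim$trajectory, spec, integer(0)), "empty")
})

test_that("classification matches the carrier fold fixtures and is symmetric", {
  hm <- aac_helix_map()
  expect_identical(classify_interaction(29L, 32L, hm), "intra_helical")
  expect_identical(classify_interaction(29L, 137L, hm), "inter_helical")
  expect_identical(classify_interaction(104L, 195L, hm), "other")
  expect_identical(classify_interaction(137L, 29L, hm), "inter_helical")
  expect_error(classify_interaction(29L, 500L, hm), "not covered")
  expect_identical(classify_interaction(29L, 500L, hm, default = "other"), "other")
})

test_that("build_network recovers channel occupancies, flags the floor, and
           auto-enumerates close pairs", {
  channels <- list(channel_spec(3L, 45L, 0.2, 0.1),
                   channel_spec(10L, 52L, 0.05, 0.05),
                   channel_spec(15L, 58L, 0.002, 0.2))  # rare: below 5% floor
  car <- small_carrier(n_frames = 2000L, noise_sigma = 0.3, channels = channels)
  sim <- simulate_trajectory(car)
  cfg <- as_mgate_config(list(
    helix_map = list(H1 = c(1, 20), H2 = c(21, 40), H3 = c(41, 60),
                     H4 = c(61, 80), H5 = c(81, 100), H6 = c(101, 120)),
    interactions = list(list(type = "salt_bridge", a = 3, b = 45),
                        list(type = "salt_bridge", a = 10, b = 52),
                        list(type = "salt_bridge", a = 15, b = 58))))
  tab <- build_network(sim$trajectory, cfg)
  expect_equal(nrow(tab), 3L)
  win <- resolve_frame_window(cfg$frame_window, 2000L)
  for (i in 1:3)
    expect_identical(tab$occupancy_pct[i],
                     100 * mean(sim$ground_truth$states[win, i]))
  expect_identical(tab$class, rep("inter_helical", 3L))
  expect_true(tab$below_floor[3L])
  expect_false(any(tab$below_floor[1:2]))

  # auto-enumeration: exactly the one basic/acidic pair within seed distance
  st <- make_charged_structure(rbind(c(0, 0, 0), c(30, 0, 0)),
                               rbind(c(4, 0, 0), c(60, 0, 0)))
  specs <- enumerate_salt_bridges(st, seed_distance = 6)
  expect_length(specs, 1L)
  expect_equal(specs[[1L]]$a, 1L)
  expect_equal(specs[[1L]]$b, 3L)
})

test_that("attachment scores sum inter-helical occupancy per domain pair", {
  hm <- helix_map(H1 = c(1, 20), H2 = c(21, 40), H3 = c(41, 60),
                  H4 = c(61, 80), H5 = c(81, 100), H6 = c(101, 120))
  empty <- data.frame(res_a = integer(0), res_b = integer(0),
                      type = character(0), class = character(0),
                      occupancy_pct = numeric(0), below_floor = logical(0),
                      n_frames_window = integer(0))
  expect_equal(attachment_scores(empty, hm)$score, c(0, 0, 0))
  one <- data.frame(res_a = 45L, res_b = 85L, type = "salt_bridge",
                    class = "inter_helical", occupancy_pct = 89,
                    below_floor = FALSE, n_frames_window = 100L)
  sc <- attachment_scores(one, hm)
  expect_equal(sc$score[sc$domain_a == 2 & sc$domain_b == 3], 89)
  expect_equal(sum(sc$score), 89)
  # a perfectly symmetric network gives three equal scores
  sym <- data.frame(res_a = c(3L, 43L, 83L), res_b = c(45L, 85L, 5L),
                    type = "salt_bridge", class = "inter_helical",
                    occupancy_pct = 70, below_floor = FALSE,
                    n_frames_window = 100L)
  expect_equal(unique(attachment_scores(sym, hm)$score), 70)
})

test_that("multi-trajectory occupancy: averaging vs pooling semantics", {
  car <- small_carrier(n_frames = 120L, noise_sigma = 0.3,
                       channels = list(channel_spec(3L, 45L, 0.2, 0.2)))
  sim1 <- simulate_trajectory(car)
  car2 <- build_toy_carrier(toy_carrier_spec(
    helix_length = 20L, n_frames = 360L, noise_sigma = 0.3, seed = 77L,
    channels = list(channel_spec(3L, 45L, 0.2, 0.2))))
  sim2 <- simulate_trajectory(car2)
  spec <- list(type = "salt_bridge", a = 3L, b = 45L)
  f1 <- 100 * mean(sim1$ground_truth$states[, 1L])
  f2 <- 100 * mean(sim2$ground_truth$states[, 1L])
  trajs <- list(sim1$trajectory, sim2$trajectory)
  avg <- occupancy_multi(trajs, spec, mode = "average")
  expect_equal(avg$percentage, mean(c(f1, f2)))
  pool <- occupancy_multi(trajs, spec, mode = "pool")
  expect_equal(pool$percentage, 100 * (120 * f1 / 100 + 360 * f2 / 100) / 480)
  expect_equal(avg$per_trajectory, c(f1, f2))
  # equal-length windows: the two modes coincide
  win <- list(1:120, 101:220)
  expect_equal(occupancy_multi(trajs, spec, win, "average")$percentage,
               occupancy_multi(trajs, spec, win, "pool")$percentage)
})
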