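#' Synthetic toy-carrier structures and trajectories with known ground truth
#'
#' The generator emulates, at toy scale, the structural setting the analyses
#' target: a three-domain, six-helix bundle with threefold pseudo-symmetry
#' about a central axis. Each domain contributes two ideal alpha-helical
#' C-alpha traces; domain 2 and domain 3 are exact 120 and 240 degree
#' rotations of domain 1, so with zero asymmetry parameters every residue
#' triplet forms an equilateral triangle (psi = 0). Controlled deviations are
#' injected as (a) a rigid rotation / radial shift of domain 1 about the
#' bundle axis, (b) isotropic Gaussian positional noise per frame, (c)
#' two-state Markov "contact channels" that switch a charge-site pseudo-atom
#' pair between a bound distance band and an unbound band (a stand-in for
#' salt-bridge formation and breakage), and (d) slab solvent pseudo-particles
#' resampled uniformly per frame. The realized channel states, the true psi
#' of the noiseless reference, and the noise level are all recorded as ground
#' truth, making every downstream analysis testable against exact answers.
#'
#' @name synthetic_data
NULL

#' Specify a two-state contact channel between two charge sites
#'
#' The channel's state follows a first-order two-state Markov chain over
#' frames: off -> on with probability `k_on` per frame, on -> off with
#' probability `k_off`. When on, the second site sits at distance
#' `d_on +/- jitter` from the first; when off, at `d_off +/- jitter`. The
#' bands must stay clear of the detection cutoff by three jitter widths so
#' that geometric detection reproduces the state sequence with zero errors.
#'
#' @param res_a,res_b residue numbers carrying the two charge-site
#'   pseudo-atoms (named `CS`).
#' @param k_on,k_off per-frame transition probabilities in `[0, 1]`.
#' @param d_on,d_off bound / unbound distances, Angstrom.
#' @param jitter half-width of the uniform distance jitter, Angstrom.
#' @param initial_state logical starting state; `NULL` draws it from the
#'   stationary distribution `k_on / (k_on + k_off)`.
#' @return list of class `channel_spec`.
#' @export
channel_spec <- function(res_a, res_b, k_on, k_off, d_on = 3.0, d_off = 8.0,
                         jitter = 0.2, initial_state = NULL) {
  stopifnot(k_on >= 0, k_on <= 1, k_off >= 0, k_off <= 1,
            d_on > 0, d_off > d_on, jitter >= 0)
  structure(list(res_a = as.integer(res_a), res_b = as.integer(res_b),
                 k_on = k_on, k_off = k_off, d_on = d_on, d_off = d_off,
                 jitter = jitter, initial_state = initial_state),
            class = "channel_spec")
}

check_channel_bands <- function(channel, cutoff) {
  lo <- channel$d_on + 3 * channel$jitter
  hi <- channel$d_off - 3 * channel$jitter
  if (!(lo < cutoff && cutoff < hi))
    stop(sprintf(paste0("channel %d:%d bands overlap the detection cutoff: ",
                        "need d_on + 3*jitter (%.2f) < cutoff (%.2f) < ",
                        "d_off - 3*jitter (%.2f)"),
                 channel$res_a, channel$res_b, lo, cutoff, hi))
  invisible(TRUE)
}

#' Specify slab solvent pseudo-particles
#'
#' @param count number of solvent pseudo-atoms (single `O` atoms, residue
#'   name `SOL`), resampled uniformly in the slab every frame.
#' @param x,y,z each `c(min, max)` Angstrom bounds of the slab.
#' @return list of class `solvent_spec`.
#' @export
solvent_spec <- function(count, x, y, z) {
  stopifnot(count >= 1, length(x) == 2L, length(y) == 2L, length(z) == 2L)
  structure(list(count = as.integer(count), x = as.numeric(x),
                 y = as.numeric(y), z = as.numeric(z)), class = "solvent_spec")
}

#' Specify a synthetic toy carrier
#'
#' Geometry defaults follow the standard alpha-helix idealization (1.5 A
#' rise per residue, 100 degree twist, 2.3 A helix radius); only relative
#' geometry matters for the analyses. The two helices of a domain sit at
#' +/- 25 degrees around the domain's bundle position; even-numbered helices
#' run antiparallel.
#'
#' @param helix_length residues per helix (>= 4).
#' @param bundle_radius distance of each helix axis from the bundle axis, A.
#' @param helix_radius C-alpha helix radius, A.
#' @param rise_per_residue,twist_per_residue ideal helix parameters (A, deg).
#' @param domain1_rotation rotation of domain 1 about the bundle axis, deg
#'   (asymmetry injection).
#' @param domain1_radial_shift outward translation of domain 1, A.
#' @param noise_sigma isotropic Gaussian positional noise per frame, A.
#' @param n_frames frames to simulate.
#' @param seed integer; expanded internally into independent per-component
#'   seeds (noise, each channel, solvent) so adding one channel never changes
#'   another component's realization.
#' @param channels list of [channel_spec()].
#' @param solvent optional [solvent_spec()].
#' @return list of class `toy_carrier_spec`.
#' @export
toy_carrier_spec <- function(helix_length = 30L, bundle_radius = 12,
                             helix_radius = 2.3, rise_per_residue = 1.5,
                             twist_per_residue = 100,
                             domain1_rotation = 0, domain1_radial_shift = 0,
                             noise_sigma = 0.3, n_frames = 1000L, seed = 1L,
                             channels = list(), solvent = NULL) {
  stopifnot(helix_length >= 4L, n_frames >= 1L, noise_sigma >= 0,
            bundle_radius > 0, helix_radius > 0)
  if (inherits(channels, "channel_spec")) channels <- list(channels)
  structure(list(n_domains = 3L, helices_per_domain = 2L,
                 helix_length = as.integer(helix_length),
                 bundle_radius = bundle_radius, helix_radius = helix_radius,
                 rise_per_residue = rise_per_residue,
                 twist_per_residue = twist_per_residue,
                 domain1_rotation = domain1_rotation,
                 domain1_radial_shift = domain1_radial_shift,
                 noise_sigma = noise_sigma, n_frames = as.integer(n_frames),
                 seed = as.integer(seed), channels = channels,
                 solvent = solvent),
            class = "toy_carrier_spec")
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

#' Build the toy-carrier reference structure
#'
#' Places six ideal helical C-alpha traces at C3-symmetric angular positions
#' (domains at 0, 120, 240 degrees about the z bundle axis), applies the
#' domain-1 asymmetry transform, and adds one charge-site pseudo-atom (`CS`,
#' offset radially from the C-alpha) to every residue referenced by a
#' channel. Residues are numbered contiguously: helix k spans residues
#' `(k-1)*L + 1 .. k*L`.
#'
#' @param spec a [toy_carrier_spec()].
#' @return list of class `toy_carrier` with elements `structure`
#'   (a [carrier_structure()]), `helix_map`, `triplet_map` (odd/even offsets
#'   and valid triplet range), `spec`, and internal site metadata.
#' @export
build_toy_carrier <- function(spec) {
  stopifnot(inherits(spec, "toy_carrier_spec"))
  L <- spec$helix_length
  n_res <- 6L * L
  for (ch in spec$channels) {
    for (r in c(ch$res_a, ch$res_b))
      if (r < 1L || r > n_res)
        stop(sprintf("channel references residue %d outside helices 1..%d", r, n_res))
  }
  # domain-1 template: helix A ascending at -25 deg, helix B antiparallel at +25
  helix_trace <- function(center_angle_deg, ascending) {
    ca <- center_angle_deg * pi / 180
    center <- c(spec$bundle_radius * cos(ca), spec$bundle_radius * sin(ca), 0)
    i <- seq_len(L)
    phase <- ca + (i - 1L) * spec$twist_per_residue * pi / 180
    z <- if (ascending) (i - 1L) * spec$rise_per_residue
         else (L - i) * spec$rise_per_residue
    cbind(center[1L] + spec$helix_radius * cos(phase),
          center[2L] + spec$helix_radius * sin(phase),
          z)
  }
  dom1 <- rbind(helix_trace(-25, TRUE), helix_trace(25, FALSE))
  xyz <- rbind(dom1, dom1 %*% t(rot_z(120)), dom1 %*% t(rot_z(240)))
  # asymmetry: rigid transform of domain 1 only
  d1 <- seq_len(2L * L)
  if (spec$domain1_rotation != 0)
    xyz[d1, ] <- xyz[d1, , drop = FALSE] %*% t(rot_z(spec$domain1_rotation))
  if (spec$domain1_radial_shift != 0) {
    u <- c(cos(spec$domain1_rotation * pi / 180),
           sin(spec$domain1_rotation * pi / 180), 0)
    xyz[d1, ] <- sweep(xyz[d1, , drop = FALSE], 2L, spec$domain1_radial_shift * u, `+`)
  }
  atoms <- data.frame(serial = seq_len(n_res), name = "CA", resname = "ALA",
                      chain = "A", resid = seq_len(n_res), element = "C",
                      stringsAsFactors = FALSE)
  # charge-site pseudo-atoms for channel residues, offset radially outward
  site_res <- sort(unique(unlist(lapply(spec$channels,
                                        function(ch) c(ch$res_a, ch$res_b)))))
  site_xyz <- NULL
  if (length(site_res)) {
    site_xyz <- t(vapply(site_res, function(r) {
      p <- xyz[r, ]
      rad <- p[1:2]
      nr <- sqrt(sum(rad^2))
      dir <- if (nr > 1e-9) c(rad / nr, 0) else c(1, 0, 0)
      p + 1.2 * dir
    }, numeric(3L)))
    atoms <- rbind(atoms, data.frame(serial = n_res + seq_along(site_res),
                                     name = "CS", resname = "ALA", chain = "A",
                                     resid = site_res, element = "X",
                                     stringsAsFactors = FALSE))
    xyz <- rbind(xyz, site_xyz)
  }
  sol_idx <- integer(0)
  if (!is.null(spec$solvent)) {
    ns <- spec$solvent$count
    n0 <- nrow(atoms)
    mid <- function(b) mean(b)
    sol_xyz <- matrix(c(rep(mid(spec$solvent$x), ns), rep(mid(spec$solvent$y), ns),
                        rep(mid(spec$solvent$z), ns)), ns, 3L)
    atoms <- rbind(atoms, data.frame(serial = n0 + seq_len(ns), name = "O",
                                     resname = "SOL", chain = "W",
                                     resid = n_res + seq_len(ns), element = "O",
                                     stringsAsFactors = FALSE))
    xyz <- rbind(xyz, sol_xyz)
    sol_idx <- n0 + seq_len(ns)
  }
  hm <- helix_map(H1 = c(1L, L), H2 = c(L + 1L, 2L * L),
                  H3 = c(2L * L + 1L, 3L * L), H4 = c(3L * L + 1L, 4L * L),
                  H5 = c(4L * L + 1L, 5L * L), H6 = c(5L * L + 1L, 6L * L))
  tm <- list(odd = c(0L, 2L * L, 4L * L), even = c(0L, 2L * L, 4L * L),
             odd_range = c(1L, L), even_range = c(L + 1L, 2L * L))
  st <- carrier_structure(atoms, xyz, title = "toy carrier")
  site_map <- if (length(site_res))
    stats::setNames(n_res + seq_along(site_res), site_res) else integer(0)
  structure(list(structure = st, helix_map = hm, triplet_map = tm, spec = spec,
                 site_atoms = site_map, solvent_atoms = sol_idx,
                 ca_atoms = seq_len(n_res)),
            class = "toy_carrier")
}

#' Simulate a two-state Markov chain of channel states
#'
#' @param k_on,k_off per-frame transition probabilities.
#' @param n_frames chain length.
#' @param initial_state logical start state; `NULL` draws from the stationary
#'   distribution.
#' @param seed integer RNG seed; the realization is reproducible.
#' @return logical vector of length `n_frames` (TRUE = on).
#' @export
markov_states <- function(k_on, k_off, n_frames, initial_state = NULL, seed = 1L) {
  stopifnot(k_on >= 0, k_on <= 1, k_off >= 0, k_off <= 1, n_frames >= 1L)
  set.seed(seed)
  s <- logical(n_frames)
  s[1L] <- if (is.null(initial_state)) {
    p_on <- if (k_on + k_off > 0) k_on / (k_on + k_off) else 0
    stats::runif(1L) < p_on
  } else isTRUE(initial_state)
  if (n_frames > 1L) {
    u <- stats::runif(n_frames - 1L)
    for (t in 2L:n_frames)
      s[t] <- if (s[t - 1L]) u[t - 1L] >= k_off else u[t - 1L] < k_on
  }
  s
}

#' Simulate a toy-carrier trajectory with ground truth
#'
#' Per frame: isotropic Gaussian noise (sd `noise_sigma`) is added to every
#' protein and charge-site atom; then each channel's second charge site is
#' re-placed on the axis through the two sites' reference positions, at the
#' exact per-frame distance (`d_on` or `d_off` plus clamped uniform jitter)
#' from the first site's current position — so the realized inter-site
#' distance always lies inside the state's band, whatever the noise did; and
#' solvent pseudo-atoms are resampled uniformly in their slab. Each
#' stochastic component consumes its own seed derived from `spec$seed`.
#'
#' @param carrier result of [build_toy_carrier()].
#' @param detection_cutoff salt-bridge detection cutoff, A, used only to
#'   verify the channel band-separation invariant up front.
#' @return list with `trajectory` (a [carrier_trajectory()]) and
#'   `ground_truth`: per-channel per-frame logical state matrix, realized
#'   on-fractions, the noiseless reference psi per odd-frame triplet, and
#'   `noise_sigma`.
#' @export
simulate_trajectory <- function(carrier, detection_cutoff = 4.0) {
  stopifnot(inherits(carrier, "toy_carrier"))
  spec <- carrier$spec
  for (ch in spec$channels) check_channel_bands(ch, detection_cutoff)
  st <- carrier$structure
  nat <- n_atoms(st)
  nf <- spec$n_frames
  ref <- st$xyz
  coords <- array(rep(ref, nf), dim = c(nat, 3L, nf))
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed + 1L)
    prot <- setdiff(seq_len(nat), carrier$solvent_atoms)
    noise <- array(stats::rnorm(length(prot) * 3L * nf, sd = spec$noise_sigma),
                   dim = c(length(prot), 3L, nf))
    coords[prot, , ] <- coords[prot, , , drop = FALSE] + noise
  }
  nchan <- length(spec$channels)
  states <- matrix(FALSE, nf, max(nchan, 0L))
  for (i in seq_len(nchan)) {
    ch <- spec$channels[[i]]
    set.seed(spec$seed + 100L + i)
    s <- logical(nf)
    s[1L] <- if (is.null(ch$initial_state)) {
      p_on <- if (ch$k_on + ch$k_off > 0) ch$k_on / (ch$k_on + ch$k_off) else 0
      stats::runif(1L) < p_on
    } else isTRUE(ch$initial_state)
    if (nf > 1L) {
      u <- stats::runif(nf - 1L)
      for (t in 2L:nf)
        s[t] <- if (s[t - 1L]) u[t - 1L] >= ch$k_off else u[t - 1L] < ch$k_on
    }
    eps <- if (ch$jitter > 0) stats::runif(nf, -ch$jitter, ch$jitter) else numeric(nf)
    d <- ifelse(s, ch$d_on, ch$d_off) + eps
    d <- pmin(pmax(d, ifelse(s, ch$d_on, ch$d_off) - ch$jitter),
              ifelse(s, ch$d_on, ch$d_off) + ch$jitter)
    ia <- carrier$site_atoms[[as.character(ch$res_a)]]
    ib <- carrier$site_atoms[[as.character(ch$res_b)]]
    u_hat <- ref[ib, ] - ref[ia, ]
    nu <- sqrt(sum(u_hat^2))
    u_hat <- if (nu > 1e-9) u_hat / nu else c(1, 0, 0)
    a_now <- coords[ia, , , drop = TRUE]              # 3 x nf
    coords[ib, , ] <- a_now + outer(u_hat, d)
    states[, i] <- s
  }
  if (!is.null(spec$solvent)) {
    sv <- spec$solvent
    ns <- sv$count
    set.seed(spec$seed + 2L)
    coords[carrier$solvent_atoms, 1L, ] <- stats::runif(ns * nf, sv$x[1L], sv$x[2L])
    coords[carrier$solvent_atoms, 2L, ] <- stats::runif(ns * nf, sv$y[1L], sv$y[2L])
    coords[carrier$solvent_atoms, 3L, ] <- stats::runif(ns * nf, sv$z[1L], sv$z[2L])
  }
  traj <- carrier_trajectory(st, coords)
  tm <- carrier$triplet_map
  trange <- seq.int(tm$odd_range[1L], tm$odd_range[2L])
  true_psi <- vapply(trange, function(t) {
    members <- t + tm$odd
    psi(ref[members[1L], ], ref[members[2L], ], ref[members[3L], ])
  }, numeric(1L))
  gt <- list(states = states[, seq_len(nchan), drop = FALSE],
             on_fraction = if (nchan) colMeans(states[, seq_len(nchan), drop = FALSE])
                           else numeric(0),
             true_psi = data.frame(triplet = trange, psi_deg = true_psi),
             noise_sigma = spec$noise_sigma, seed = spec$seed)
  list(trajectory = traj, ground_truth = gt)
}

#' Write a toy-carrier dataset to disk
#'
#' Writes the reference structure (`reference.pdb`), the trajectory as
#' multi-model PDB (`trajectory.pdb`), and the ground truth as JSON
#' (`ground_truth.json`).
#'
#' @param carrier result of [build_toy_carrier()].
#' @param sim result of [simulate_trajectory()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_toy_dataset <- function(carrier, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_structure(carrier$structure, file.path(dir, "reference.pdb"))
  write_trajectory(sim$trajectory, file.path(dir, "trajectory.pdb"))
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(states = apply(gt$states, 2L, as.integer, simplify = FALSE),
         on_fraction = gt$on_fraction, true_psi = gt$true_psi,
         noise_sigma = gt$noise_sigma, seed = gt$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
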