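#' Interaction detection, occupancies, and the m-gate network table
#'
#' Detects salt bridges, hydrogen bonds, arginine guanidinium stacking and
#' ligand contacts per frame; aggregates per-frame presence into percent
#' occupancy over a frame window; classifies each residue pair as
#' intra-helical (both partners on the same transmembrane helix),
#' inter-helical (two different helices) or other (a loop or matrix-helix
#' partner); and sums inter-helical occupancies into per-domain-pair
#' attachment scores. Geometric criteria default to widely used conventions
#' (salt bridge: minimum side-chain N-O distance <= 4.0 A, boundary
#' inclusive; H-bond: donor-acceptor <= 3.5 A and H-donor-acceptor <= 30
#' degrees when hydrogens exist, distance-only otherwise; stacking:
#' guanidinium-plane centroids <= 5.0 A and interplanar angle <= 30 degrees)
#' and are configurable throughout.
#'
#' @name interaction_network
NULL

basic_atom_names <- c("NH1", "NH2", "NE", "NZ")
acidic_atom_names <- c("OD1", "OD2", "OE1", "OE2")

# indices of a residue's charge-bearing atoms: canonical side-chain atoms
# when present, else the CS pseudo-atom of the synthetic generator
charge_atoms <- function(structure, resid, role = c("basic", "acidic")) {
  role <- match.arg(role)
  names_ok <- if (role == "basic") basic_atom_names else acidic_atom_names
  at <- structure$atoms
  idx <- which(at$resid == resid & at$name %in% names_ok)
  if (length(idx) == 0L)
    idx <- which(at$resid == resid & at$name == "CS")
  if (length(idx) == 0L)
    stop(sprintf("residue %d has neither canonical %s atoms (%s) nor a CS pseudo-atom",
                 resid, role, paste(names_ok, collapse = "/")))
  idx
}

min_pair_distance <- function(xyz, idx_a, idx_b) {
  d2 <- Inf
  for (i in idx_a) {
    di <- (xyz[idx_b, 1L] - xyz[i, 1L])^2 + (xyz[idx_b, 2L] - xyz[i, 2L])^2 +
      (xyz[idx_b, 3L] - xyz[i, 3L])^2
    d2 <- min(d2, min(di))
  }
  sqrt(d2)
}

#' Detect a salt bridge in one frame
#'
#' True iff the minimum distance over basic-N x acidic-O atom pairs (or the
#' residues' CS pseudo-atoms) is at or below the cutoff; the boundary counts
#' as formed.
#'
#' @param frame a `carrier_structure` holding the frame's coordinates
#'   (see [trajectory_frame()]).
#' @param res_basic,res_acidic residue numbers of the basic (Arg/Lys) and
#'   acidic (Asp/Glu) partner.
#' @param cutoff distance cutoff, Angstrom.
#' @return list with `present` (logical) and `min_distance` (A).
#' @export
detect_salt_bridge <- function(frame, res_basic, res_acidic, cutoff = 4.0) {
  stopifnot(inherits(frame, "carrier_structure"), cutoff > 0)
  ia <- charge_atoms(frame, res_basic, "basic")
  ib <- charge_atoms(frame, res_acidic, "acidic")
  d <- min_pair_distance(frame$xyz, ia, ib)
  list(present = d <= cutoff, min_distance = d)
}

residue_hydrogens_near <- function(structure, donor_idx) {
  at <- structure$atoms
  r <- at$resid[donor_idx]
  hs <- which(at$resid == r & (at$element == "H" | grepl("^[0-9]*H", at$name)))
  if (length(hs) == 0L) return(integer(0))
  dd <- sqrt(rowSums((structure$xyz[hs, , drop = FALSE] -
                        matrix(structure$xyz[donor_idx, ], length(hs), 3L,
                               byrow = TRUE))^2))
  hs[dd <= 1.25]
}

vec_angle_deg <- function(u, v) {
  cu <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cu))) * 180 / pi
}

#' Detect a hydrogen bond in one frame
#'
#' True iff the donor-acceptor heavy-atom distance is at or below `d_cutoff`
#' and — when the donor carries at least one covalently bound hydrogen in the
#' topology — some H satisfies H-donor-acceptor angle <= `angle_cutoff`.
#' Hydrogen-free topologies (crystal structures, toy models) use the
#' distance-only fallback.
#'
#' @param frame a `carrier_structure` with frame coordinates.
#' @param donor_sel,acceptor_sel selection strings or atom index vectors
#'   resolving the donor / acceptor heavy atoms.
#' @param d_cutoff donor-acceptor distance cutoff, A.
#' @param angle_cutoff H-donor-acceptor angle cutoff, degrees.
#' @param helix_map optional, for `segment` selections.
#' @return logical: any donor/acceptor pair satisfies the criterion.
#' @export
detect_hbond <- function(frame, donor_sel, acceptor_sel, d_cutoff = 3.5,
                         angle_cutoff = 30, helix_map = NULL) {
  stopifnot(inherits(frame, "carrier_structure"))
  don <- select_atoms(frame, donor_sel, helix_map, warn_empty = FALSE)
  acc <- select_atoms(frame, acceptor_sel, helix_map, warn_empty = FALSE)
  if (length(don) == 0L || length(acc) == 0L)
    stop("unresolvable donor or acceptor selection")
  for (i in don) {
    dd <- sqrt(colSums((t(frame$xyz[acc, , drop = FALSE]) - frame$xyz[i, ])^2))
    close <- acc[dd <= d_cutoff]
    if (length(close) == 0L) next
    hs <- residue_hydrogens_near(frame, i)
    if (length(hs) == 0L) return(TRUE)  # distance-only fallback
    for (j in close) {
      for (h in hs) {
        ang <- vec_angle_deg(frame$xyz[h, ] - frame$xyz[i, ],
                             frame$xyz[j, ] - frame$xyz[i, ])
        if (ang <= angle_cutoff) return(TRUE)
      }
    }
  }
  FALSE
}

guanidinium_plane <- function(structure, resid) {
  at <- structure$atoms
  need <- c("CZ", "NH1", "NH2", "NE")
  idx <- vapply(need, function(nm) {
    i <- which(at$resid == resid & at$name == nm)
    if (length(i) != 1L)
      stop(sprintf("residue %d lacks guanidinium atom %s", resid, nm))
    i
  }, integer(1L))
  if (at$resname[idx[["CZ"]]] != "ARG")
    stop(sprintf("residue %d is %s, not ARG", resid, at$resname[idx[["CZ"]]]))
  p <- structure$xyz[idx, , drop = FALSE]
  centroid <- colMeans(p)
  u <- p[2L, ] - p[1L, ]   # NH1 - CZ
  v <- p[3L, ] - p[1L, ]   # NH2 - CZ
  n <- c(u[2L] * v[3L] - u[3L] * v[2L],
         u[3L] * v[1L] - u[1L] * v[3L],
         u[1L] * v[2L] - u[2L] * v[1L])
  list(centroid = centroid, normal = n / sqrt(sum(n^2)))
}

#' Detect guanidinium pi-stacking between two arginines in one frame
#'
#' True iff the two guanidinium-plane centroids (CZ/NH1/NH2/NE) lie within
#' `d_cutoff` and the interplanar angle, folded into `[0, 90]` degrees, is at
#' or below `angle_cutoff`.
#'
#' @param frame a `carrier_structure` with frame coordinates.
#' @param res_i,res_j arginine residue numbers.
#' @param d_cutoff centroid distance cutoff, A.
#' @param angle_cutoff interplanar angle cutoff, degrees.
#' @return logical.
#' @export
detect_stacking <- function(frame, res_i, res_j, d_cutoff = 5.0,
                            angle_cutoff = 30) {
  gi <- guanidinium_plane(frame, res_i)
  gj <- guanidinium_plane(frame, res_j)
  d <- sqrt(sum((gi$centroid - gj$centroid)^2))
  ang <- vec_angle_deg(gi$normal, gj$normal)
  if (ang > 90) ang <- 180 - ang
  d <= d_cutoff && ang <= angle_cutoff
}

resolve_interaction_groups <- function(topology, spec, helix_map = NULL) {
  type <- spec$type %||% "salt_bridge"
  res_of <- function(x) if (is.numeric(x) && length(x) == 1L) as.integer(x) else NA_integer_
  if (type %in% c("salt_bridge")) {
    ra <- res_of(spec$a); rb <- res_of(spec$b)
    if (is.na(ra) || is.na(rb))
      stop("salt_bridge partners must be residue numbers (basic first)")
    list(a = charge_atoms(topology, ra, "basic"),
         b = charge_atoms(topology, rb, "acidic"),
         res_a = ra, res_b = rb)
  } else if (type %in% c("hbond", "ligand_contact")) {
    sel <- function(x) if (is.character(x)) select_atoms(topology, x, helix_map,
                                                         warn_empty = FALSE)
                       else select_atoms(topology, x, helix_map, warn_empty = FALSE)
    ga <- sel(if (is.numeric(spec$a) && length(spec$a) == 1L)
                paste("resid", spec$a) else spec$a)
    gb <- sel(if (is.numeric(spec$b) && length(spec$b) == 1L)
                paste("resid", spec$b) else spec$b)
    if (length(ga) == 0L || length(gb) == 0L)
      stop("interaction selection matches no atoms")
    list(a = ga, b = gb,
         res_a = res_of(spec$a) %||% NA_integer_,
         res_b = res_of(spec$b) %||% NA_integer_)
  } else if (type == "stacking") {
    ra <- res_of(spec$a); rb <- res_of(spec$b)
    if (is.na(ra) || is.na(rb)) stop("stacking partners must be residue numbers")
    list(a = NULL, b = NULL, res_a = ra, res_b = rb)
  } else stop("unknown interaction type: ", type)
}

# per-frame minimum distance between two atom groups, vectorized over frames
group_min_distance_frames <- function(coords, idx_a, idx_b) {
  nf <- dim(coords)[3L]
  best <- rep(Inf, nf)
  for (i in idx_a) {
    pi <- matrix(coords[i, , ], nrow = 3L)
    for (j in idx_b) {
      pj <- matrix(coords[j, , ], nrow = 3L)
      best <- pmin(best, sqrt(colSums((pi - pj)^2)))
    }
  }
  best
}

#' Per-frame presence and percent occupancy of one interaction
#'
#' Occupancy = 100 x (frames present in the window) / (frames in the
#' window). The full per-frame series (presence and minimum distance where
#' applicable) is retained for plotting and event analysis.
#'
#' @param trajectory a [carrier_trajectory()].
#' @param spec interaction spec: list with `type` (`salt_bridge`, `hbond`,
#'   `stacking`, `ligand_contact`), partners `a` and `b` (residue numbers or
#'   selections), and optional cutoff overrides (`cutoff`, `d_cutoff`,
#'   `angle_cutoff`).
#' @param frame_window 1-based frame indices (see [resolve_frame_window()]);
#'   `NULL` uses all frames.
#' @param cutoffs defaults used when the spec does not override (see
#'   [load_config()]).
#' @param helix_map optional, for `segment` selections.
#' @return list with `percentage` and `series` (data.frame `frame` 0-based,
#'   `present`, `min_distance`).
#' @export
occupancy <- function(trajectory, spec, frame_window = NULL,
                      cutoffs = default_cutoffs(), helix_map = NULL) {
  stopifnot(inherits(trajectory, "carrier_trajectory"))
  nf <- n_frames(trajectory)
  window <- frame_window %||% seq_len(nf)
  if (length(window) == 0L) stop("empty frame window")
  if (any(window < 1L | window > nf)) stop("frame window outside trajectory")
  type <- spec$type %||% "salt_bridge"
  grp <- resolve_interaction_groups(trajectory$topology, spec, helix_map)
  if (type == "salt_bridge") {
    cutoff <- spec$cutoff %||% cutoffs$salt_bridge
    mind <- group_min_distance_frames(trajectory$coords, grp$a, grp$b)
    present <- mind <= cutoff
  } else if (type %in% c("hbond", "ligand_contact")) {
    d_cutoff <- spec$d_cutoff %||% spec$cutoff %||% cutoffs$hbond_dist
    angle_cutoff <- spec$angle_cutoff %||% cutoffs$hbond_angle
    has_h <- any(trajectory$topology$atoms$element == "H")
    mind <- group_min_distance_frames(trajectory$coords, grp$a, grp$b)
    if (!has_h) {
      present <- mind <= d_cutoff
    } else {
      present <- vapply(seq_len(nf), function(k)
        detect_hbond(trajectory_frame(trajectory, k), grp$a, grp$b,
                     d_cutoff, angle_cutoff, helix_map), logical(1L))
    }
  } else if (type == "stacking") {
    d_cutoff <- spec$d_cutoff %||% spec$cutoff %||% cutoffs$stacking_dist
    angle_cutoff <- spec$angle_cutoff %||% cutoffs$stacking_angle
    present <- vapply(seq_len(nf), function(k)
      detect_stacking(trajectory_frame(trajectory, k), grp$res_a, grp$res_b,
                      d_cutoff, angle_cutoff), logical(1L))
    mind <- rep(NA_real_, nf)
  } else stop("unknown interaction type: ", type)
  list(percentage = 100 * mean(present[window]),
       series = data.frame(frame = seq_len(nf) - 1L, present = present,
                           min_distance = mind))
}

#' Classify a residue pair as intra-helical, inter-helical, or other
#'
#' @param res_i,res_j residue numbers.
#' @param helix_map a [helix_map()].
#' @param default class to assign when a residue falls in no segment
#'   (`NULL`, the default, raises an error instead).
#' @return `"intra_helical"`, `"inter_helical"`, or `"other"`; symmetric in
#'   its residue arguments.
#' @export
classify_interaction <- function(res_i, res_j, helix_map, default = NULL) {
  hm <- as.data.frame(helix_map)
  seg <- segment_of(c(res_i, res_j), helix_map)
  if (anyNA(seg)) {
    if (is.null(default))
      stop(sprintf("residue %d not covered by any segment",
                   c(res_i, res_j)[which(is.na(seg))[1L]]))
    return(default)
  }
  kind <- hm$kind[match(seg, hm$segment)]
  if (any(kind != "helix")) "other"
  else if (seg[1L] == seg[2L]) "intra_helical"
  else "inter_helical"
}

# round half away from zero at `digits` decimals (reporting convention)
round_half_away <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Enumerate candidate salt-bridge pairs on a reference structure
#'
#' All basic (Arg/Lys) x acidic (Asp/Glu) residue pairs whose charge-atom
#' minimum distance on the reference coordinates is at or below
#' `seed_distance`.
#'
#' @param structure a `carrier_structure` (reference coordinates).
#' @param seed_distance enumeration cutoff, A.
#' @return list of salt_bridge interaction specs.
#' @export
enumerate_salt_bridges <- function(structure, seed_distance = 6.0) {
  at <- structure$atoms
  basics <- unique(at$resid[at$resname %in% c("ARG", "LYS")])
  acidics <- unique(at$resid[at$resname %in% c("ASP", "GLU")])
  specs <- list()
  for (rb in basics) for (ra in acidics) {
    d <- min_pair_distance(structure$xyz,
                           charge_atoms(structure, rb, "basic"),
                           charge_atoms(structure, ra, "acidic"))
    if (d <= seed_distance)
      specs[[length(specs) + 1L]] <- list(type = "salt_bridge", a = rb, b = ra)
  }
  specs
}

#' Build the occupancy table over all configured interactions
#'
#' One row per candidate interaction, carrying its occupancy over the frame
#' window and its intra/inter-helical class. Rows below the reporting floor
#' (default 5%) are flagged `below_floor` but retained, so cross-system
#' comparisons never lose edges.
#'
#' @param trajectory a [carrier_trajectory()].
#' @param config an `mgate_config` (see [as_mgate_config()]); its
#'   `interactions`, `cutoffs`, `frame_window`, `helix_map` and
#'   `reporting_floor` fields are used.
#' @param auto_enumerate when TRUE and the config lists no interactions,
#'   candidates come from [enumerate_salt_bridges()] on frame 1.
#' @param seed_distance enumeration cutoff for `auto_enumerate`, A.
#' @return data.frame of class `occupancy_table` with columns `res_a`,
#'   `res_b`, `type`, `class`, `occupancy_pct` (exact percentage; round at
#'   reporting time), `below_floor`, `n_frames_window`.
#' @export
build_network <- function(trajectory, config, auto_enumerate = FALSE,
                          seed_distance = 6.0) {
  stopifnot(inherits(trajectory, "carrier_trajectory"))
  cfg <- if (inherits(config, "mgate_config")) config else as_mgate_config(config)
  specs <- cfg$interactions
  if (length(specs) == 0L && auto_enumerate)
    specs <- enumerate_salt_bridges(trajectory_frame(trajectory, 1L), seed_distance)
  if (length(specs) == 0L) stop("no interactions configured and auto_enumerate is FALSE")
  window <- resolve_frame_window(cfg$frame_window, n_frames(trajectory))
  rows <- lapply(specs, function(sp) {
    occ <- occupancy(trajectory, sp, window, cfg$cutoffs, cfg$helix_map)
    grp <- resolve_interaction_groups(trajectory$topology, sp, cfg$helix_map)
    cls <- if (!is.na(grp$res_a) && !is.na(grp$res_b))
      classify_interaction(grp$res_a, grp$res_b, cfg$helix_map, default = "other")
    else "other"
    data.frame(res_a = grp$res_a, res_b = grp$res_b,
               type = sp$type %||% "salt_bridge", class = cls,
               occupancy_pct = occ$percentage,
               below_floor = occ$percentage < cfg$reporting_floor,
               n_frames_window = length(window))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Per-domain-pair attachment scores
#'
#' score(Di, Dj) = sum of occupancy percentages over inter-helical rows whose
#' partner helices belong to domains Di and Dj. A large D2-D3 score with
#' small D1 scores is the signature of the asymmetric network in which
#' domains 2 and 3 bind strongly while domain 1 attaches loosely.
#'
#' @param table an `occupancy_table` from [build_network()].
#' @param helix_map a [helix_map()] whose helices carry `domain` assignments.
#' @return data.frame with columns `domain_a`, `domain_b`, `score` for the
#'   three unordered domain pairs.
#' @export
attachment_scores <- function(table, helix_map) {
  hm <- as.data.frame(helix_map)
  pairs <- data.frame(domain_a = c(1L, 1L, 2L), domain_b = c(2L, 3L, 3L),
                      score = 0)
  for (r in seq_len(nrow(table))) {
    if (table$class[r] != "inter_helical") next
    seg <- segment_of(c(table$res_a[r], table$res_b[r]), helix_map)
    dom <- sort(hm$domain[match(seg, hm$segment)])
    if (anyNA(dom) || dom[1L] == dom[2L]) next
    hit <- pairs$domain_a == dom[1L] & pairs$domain_b == dom[2L]
    pairs$score[hit] <- pairs$score[hit] + table$occupancy_pct[r]
  }
  pairs
}

#' Occupancy over several trajectories of one system
#'
#' Replicate production runs of one system can be combined two ways:
#' `"average"` takes the unweighted mean of per-trajectory occupancies
#' (each run counts equally regardless of length); `"pool"` concatenates the
#' window frames of all runs and computes one fraction (long runs weigh
#' more). The two agree exactly when all windows have equal length.
#'
#' @param trajectories list of [carrier_trajectory()] objects sharing a
#'   topology.
#' @param spec,cutoffs,helix_map as in [occupancy()].
#' @param frame_window list of per-trajectory 1-based index vectors, or
#'   `NULL` for all frames of each.
#' @param mode `"average"` or `"pool"`.
#' @return list with `percentage` and `per_trajectory` (vector of
#'   per-trajectory percentages).
#' @export
occupancy_multi <- function(trajectories, spec, frame_window = NULL,
                            mode = c("average", "pool"),
                            cutoffs = default_cutoffs(), helix_map = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(trajectories) >= 1L)
  per <- numeric(length(trajectories))
  n_present <- 0; n_total <- 0
  for (i in seq_along(trajectories)) {
    win <- if (is.null(frame_window)) NULL else frame_window[[i]]
    occ <- occupancy(trajectories[[i]], spec, win, cutoffs, helix_map)
    per[i] <- occ$percentage
    nw <- if (is.null(win)) n_frames(trajectories[[i]]) else length(win)
    n_present <- n_present + occ$percentage / 100 * nw
    n_total <- n_total + nw
  }
  pct <- if (mode == "average") mean(per) else 100 * n_present / n_total
  list(percentage = pct, per_trajectory = per)
}
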