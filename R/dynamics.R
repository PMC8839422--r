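#' Superposition, RMSF, distance series, and gap events
#'
#' Least-squares rigid superposition (Kabsch, proper rotation enforced),
#' per-residue RMSF about the window-average structure, per-frame minimum
#' heavy-atom distance between two groups, detection of interface "gap"
#' (crevice) events as maximal runs of frames exceeding an openness cutoff,
#' and counts of solvent pseudo-atoms bridging an interface.
#'
#' @name dynamics
NULL

#' Optimal rigid superposition of one coordinate set onto another
#'
#' Least-squares fit by the Kabsch algorithm; the rotation is constrained to
#' be proper (determinant +1), so reflections are never introduced.
#'
#' @param mobile,reference n x 3 coordinate matrices.
#' @param fit_idx indices of the rows used for the fit (default all);
#'   at least 3 non-collinear atoms.
#' @return list with `rotation` (3 x 3), `translation` (length 3; the fitted
#'   mobile is `mobile %*% rotation + translation`), `rmsd` (A, over the fit
#'   group after fitting).
#' @export
superpose <- function(mobile, reference, fit_idx = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference))
  idx <- fit_idx %||% seq_len(nrow(mobile))
  if (length(idx) < 3L) stop("fit group needs at least 3 atoms")
  m <- mobile[idx, , drop = FALSE]
  r <- reference[idx, , drop = FALSE]
  mc <- colMeans(m); rc <- colMeans(r)
  m0 <- sweep(m, 2L, mc); r0 <- sweep(r, 2L, rc)
  sv <- svd(crossprod(m0, r0))
  if (sv$d[2L] < 1e-10) stop("degenerate fit group (collinear or coincident atoms)")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  trans <- rc - mc %*% rot
  fitted <- m0 %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - r0)^2)))
  list(rotation = rot, translation = as.numeric(trans), rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param transform result of [superpose()].
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% transform$rotation, 2L, transform$translation, `+`)
}

#' Per-atom RMSF over a frame window
#'
#' Each window frame is superposed (on `fit_sel`, C-alpha by default) onto
#' the window-average structure, computed in two passes: frames are first
#' fitted to an initial average (itself built from frames fitted to the
#' first window frame), the average is recomputed from the fitted frames,
#' and RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2) is taken about that refined
#' average. With `fit = FALSE` raw coordinates are used.
#'
#' @param trajectory a [carrier_trajectory()].
#' @param selection atoms to report (selection string or indices; default
#'   `"name CA"`).
#' @param frame_window 1-based frame indices; `NULL` = all frames (at least 2).
#' @param fit superpose each frame before averaging (default TRUE).
#' @param fit_selection atoms used for the fit (default: the report
#'   selection).
#' @param helix_map optional, for `segment` selections.
#' @return data.frame of class `rmsf_profile` with columns `resid`, `name`,
#'   `rmsf` (A).
#' @export
rmsf <- function(trajectory, selection = "name CA", frame_window = NULL,
                 fit = TRUE, fit_selection = NULL, helix_map = NULL) {
  stopifnot(inherits(trajectory, "carrier_trajectory"))
  nf <- n_frames(trajectory)
  window <- frame_window %||% seq_len(nf)
  if (length(window) < 2L) stop("RMSF needs a window of at least 2 frames")
  sel <- select_atoms(trajectory$topology, selection, helix_map)
  if (length(sel) == 0L) stop("empty RMSF selection")
  fit_sel_local <- if (is.null(fit_selection)) seq_along(sel)
    else match(select_atoms(trajectory$topology, fit_selection, helix_map), sel)
  if (anyNA(fit_sel_local)) stop("fit selection must be a subset of the report selection")
  nw <- length(window)
  stack <- array(NA_real_, dim = c(length(sel), 3L, nw))
  for (k in seq_len(nw)) stack[, , k] <- trajectory$coords[sel, , window[k]]
  if (fit) {
    ref <- stack[, , 1L]
    for (pass in 1:2) {
      for (k in seq_len(nw)) {
        tr <- superpose(stack[, , k], ref, fit_sel_local)
        stack[, , k] <- apply_transform(stack[, , k], tr)
      }
      ref <- apply(stack, c(1L, 2L), mean)
    }
  }
  avg <- apply(stack, c(1L, 2L), mean)
  dev2 <- (stack - array(rep(avg, nw), dim = dim(stack)))^2
  # dev2 is (atom, coord, frame): per-atom mean over frames of summed squares
  msf <- rowMeans(apply(dev2, c(1L, 3L), sum))
  at <- trajectory$topology$atoms[sel, , drop = FALSE]
  out <- data.frame(resid = at$resid, name = at$name, rmsf = sqrt(msf))
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' Per-frame minimum distance between two atom groups
#'
#' @param trajectory a [carrier_trajectory()].
#' @param group_a,group_b disjoint atom selections (strings or indices);
#'   heavy atoms by convention — pass heavy-atom selections.
#' @param helix_map optional, for `segment` selections.
#' @return data.frame of class `distance_series` with columns `frame`
#'   (0-based) and `distance` (A).
#' @export
min_distance_series <- function(trajectory, group_a, group_b, helix_map = NULL) {
  stopifnot(inherits(trajectory, "carrier_trajectory"))
  ga <- select_atoms(trajectory$topology, group_a, helix_map)
  gb <- select_atoms(trajectory$topology, group_b, helix_map)
  if (length(ga) == 0L || length(gb) == 0L) stop("empty distance group")
  if (length(intersect(ga, gb))) stop("distance groups overlap")
  d <- group_min_distance_frames(trajectory$coords, ga, gb)
  out <- data.frame(frame = seq_len(n_frames(trajectory)) - 1L, distance = d)
  class(out) <- c("distance_series", "data.frame")
  out
}

#' Detect gap (crevice) opening events in a distance series
#'
#' An event is a maximal run of consecutive frames whose distance strictly
#' exceeds `open_cutoff`; runs shorter than `min_duration` frames are
#' discarded. Events are non-overlapping and ordered.
#'
#' @param series a [min_distance_series()] result, or a numeric vector of
#'   distances (frames then numbered from 0).
#' @param open_cutoff openness cutoff, A (default 6.0).
#' @param min_duration minimum event length in frames (default 10).
#' @return data.frame with columns `start_frame`, `end_frame` (0-based,
#'   inclusive), `max_gap` (A), `duration_frames`.
#' @export
gap_events <- function(series, open_cutoff = 6.0, min_duration = 10L) {
  stopifnot(open_cutoff > 0, min_duration >= 1L)
  d <- if (is.data.frame(series)) series$distance else as.numeric(series)
  frames0 <- if (is.data.frame(series)) series$frame else seq_along(d) - 1L
  open <- d > open_cutoff
  r <- rle(open)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  out <- data.frame(start_frame = frames0[starts[keep]],
                    end_frame = frames0[ends[keep]],
                    max_gap = vapply(which(keep), function(k)
                      max(d[starts[k]:ends[k]]), numeric(1L)),
                    duration_frames = r$lengths[keep])
  rownames(out) <- NULL
  out
}

#' Per-frame count of solvent pseudo-atoms bridging an interface
#'
#' Counts solvent oxygens (residue name `HOH`, `WAT`, or `SOL`) lying within
#' `radius` of at least one atom of group A and one atom of group B in the
#' same frame — solvent that bridges the interface.
#'
#' @param trajectory a [carrier_trajectory()].
#' @param group_a,group_b interface atom selections.
#' @param radius bridging radius, A.
#' @param solvent_resnames residue names treated as solvent.
#' @param helix_map optional, for `segment` selections.
#' @return data.frame with columns `frame` (0-based) and `count`.
#' @export
solvent_count_series <- function(trajectory, group_a, group_b, radius = 4.0,
                                 solvent_resnames = c("HOH", "WAT", "SOL"),
                                 helix_map = NULL) {
  stopifnot(inherits(trajectory, "carrier_trajectory"), radius > 0)
  at <- trajectory$topology$atoms
  sol <- which(at$resname %in% solvent_resnames & at$element == "O")
  if (length(sol) == 0L)
    stop("no solvent atoms in topology (residue names ",
         paste(solvent_resnames, collapse = "/"),
         "); run the analysis in solvent-free mode instead")
  ga <- select_atoms(trajectory$topology, group_a, helix_map)
  gb <- select_atoms(trajectory$topology, group_b, helix_map)
  if (length(ga) == 0L || length(gb) == 0L) stop("empty interface group")
  nf <- n_frames(trajectory)
  counts <- integer(nf)
  for (k in seq_len(nf)) {
    xyz <- trajectory$coords[, , k]
    ps <- xyz[sol, , drop = FALSE]
    near <- function(grp) {
      ok <- rep(FALSE, length(sol))
      for (i in grp) {
        di2 <- (ps[, 1L] - xyz[i, 1L])^2 + (ps[, 2L] - xyz[i, 2L])^2 +
          (ps[, 3L] - xyz[i, 3L])^2
        ok <- ok | di2 <= radius^2
        if (all(ok)) break
      }
      ok
    }
    counts[k] <- sum(near(ga) & near(gb))
  }
  data.frame(frame = seq_len(nf) - 1L, count = counts)
}
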