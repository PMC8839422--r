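#' Triplet-based C3 symmetry deviation (psi)
#'
#' In the three-domain carrier fold, residues at equivalent positions of the
#' three homologous domains form a "triplet". The three C-alpha atoms of a
#' triplet span a triangle; under perfect threefold symmetry that triangle is
#' equilateral. The symmetry deviation psi of a triplet is the mean absolute
#' deviation of the triangle's three interior angles from 60 degrees:
#' psi = (|t1 - 60| + |t2 - 60| + |t3 - 60|) / 3. psi is 0 exactly for an
#' equilateral configuration and approaches 80 degrees as the triangle
#' collapses toward collinearity (angles 180, 0, 0). Being internal to each
#' triangle, psi needs no superposition and is invariant under rigid motions
#' and uniform scaling.
#'
#' @name symmetry
NULL

#' Residue numbers of a triplet
#'
#' Triplets are indexed by the domain-1 residue number; the members are the
#' residues at the symmetric positions of the three domains, obtained by
#' adding one per-segment offset each.
#'
#' @param t triplet index (domain-1 residue number).
#' @param offsets integer vector of three per-domain offsets, e.g.
#'   `c(0, 105, 202)` for the odd-helix frame of bovine AAC1 (so triplet 33
#'   maps to residues 33, 138, 235).
#' @param segment_ranges optional list of three `c(start, end)` ranges; when
#'   given, each resulting residue is checked to lie in its segment.
#' @return integer vector of three residue numbers.
#' @export
triplet_members <- function(t, offsets, segment_ranges = NULL) {
  stopifnot(length(offsets) == 3L)
  res <- as.integer(t) + as.integer(offsets)
  if (!is.null(segment_ranges)) {
    stopifnot(length(segment_ranges) == 3L)
    for (k in 1:3) {
      rg <- segment_ranges[[k]]
      if (res[k] < rg[1L] || res[k] > rg[2L])
        stop(sprintf("triplet %d member %d (residue %d) outside segment range %d..%d",
                     t, k, res[k], rg[1L], rg[2L]))
    }
  }
  res
}

#' Interior angles of a triangle from its vertices
#'
#' @param p1,p2,p3 numeric 3-vectors (Angstrom).
#' @return numeric vector of the three angles in degrees (at p1, p2, p3);
#'   they sum to 180.
#' @export
triangle_angles <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p3)^2))  # side opposite p1
  b <- sqrt(sum((p1 - p3)^2))
  c <- sqrt(sum((p1 - p2)^2))
  if (min(a, b, c) < 1e-6)
    stop("degenerate triangle: coincident points")
  cosv <- c((b^2 + c^2 - a^2) / (2 * b * c),
            (a^2 + c^2 - b^2) / (2 * a * c),
            (a^2 + b^2 - c^2) / (2 * a * b))
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

#' Symmetry deviation psi of one triplet triangle
#'
#' @inheritParams triangle_angles
#' @param method `"mean_abs"` (default): mean of |angle - 60|;
#'   `"rms"`: root-mean-square of (angle - 60).
#' @return psi in degrees (>= 0; 0 iff equilateral).
#' @export
psi <- function(p1, p2, p3, method = c("mean_abs", "rms")) {
  method <- match.arg(method)
  th <- triangle_angles(p1, p2, p3)
  if (method == "mean_abs") mean(abs(th - 60)) else sqrt(mean((th - 60)^2))
}

# vectorized psi over frames: p1, p2, p3 are 3 x n matrices
psi_frames <- function(p1, p2, p3, method = "mean_abs") {
  a <- sqrt(colSums((p2 - p3)^2))
  b <- sqrt(colSums((p1 - p3)^2))
  cc <- sqrt(colSums((p1 - p2)^2))
  if (any(pmin(a, b, cc) < 1e-6))
    stop("degenerate triangle: coincident points in at least one frame")
  ang <- function(x, y, z) acos(pmin(1, pmax(-1, (y^2 + z^2 - x^2) / (2 * y * z)))) * 180 / pi
  t1 <- ang(a, b, cc); t2 <- ang(b, a, cc); t3 <- ang(cc, a, b)
  if (method == "mean_abs") (abs(t1 - 60) + abs(t2 - 60) + abs(t3 - 60)) / 3
  else sqrt(((t1 - 60)^2 + (t2 - 60)^2 + (t3 - 60)^2) / 3)
}

#' Per-triplet, per-frame psi series over a trajectory
#'
#' No superposition is applied: psi is internal to each triangle and thus
#' invariant to rigid motion of the whole structure.
#'
#' @param trajectory a [carrier_trajectory()].
#' @param triplet_map list with `odd` offsets (and optionally `even`) plus
#'   optional `odd_range`; as produced by [build_toy_carrier()], or built by
#'   hand from an analysis config.
#' @param triplets integer vector of triplet indices.
#' @param atom_name atom used per residue (default `"CA"`).
#' @param frame `"odd"` or `"even"` helix frame of reference.
#' @param method passed to psi (`"mean_abs"` or `"rms"`).
#' @return data.frame of class `symmetry_series` with columns `frame`
#'   (0-based), `triplet`, `psi_deg`.
#' @export
psi_series <- function(trajectory, triplet_map, triplets,
                       atom_name = "CA", frame = c("odd", "even"),
                       method = c("mean_abs", "rms")) {
  frame <- match.arg(frame)
  method <- match.arg(method)
  stopifnot(inherits(trajectory, "carrier_trajectory"))
  offsets <- triplet_map[[frame]]
  if (is.null(offsets)) stop("triplet_map lacks '", frame, "' offsets")
  at <- trajectory$topology$atoms
  nf <- n_frames(trajectory)
  out <- vector("list", length(triplets))
  for (k in seq_along(triplets)) {
    t <- triplets[k]
    members <- triplet_members(t, offsets)
    idx <- vapply(members, function(r) {
      i <- which(at$resid == r & at$name == atom_name)
      if (length(i) != 1L)
        stop(sprintf("residue %d has no unique atom '%s' (triplet %d)",
                     r, atom_name, t))
      i
    }, integer(1L))
    p1 <- matrix(trajectory$coords[idx[1L], , ], nrow = 3L)
    p2 <- matrix(trajectory$coords[idx[2L], , ], nrow = 3L)
    p3 <- matrix(trajectory$coords[idx[3L], , ], nrow = 3L)
    out[[k]] <- data.frame(frame = seq_len(nf) - 1L, triplet = t,
                           psi_deg = psi_frames(p1, p2, p3, method))
  }
  res <- do.call(rbind, out)
  class(res) <- c("symmetry_series", "data.frame")
  res
}

#' Mean psi per triplet over a frame window
#'
#' @param series a [psi_series()] result.
#' @param frame_window integer vector of 1-based frame indices (e.g. from
#'   [resolve_frame_window()]); `NULL` uses all frames.
#' @return data.frame with columns `triplet`, `mean_psi_deg`, `sd_psi_deg`,
#'   `n_frames`.
#' @export
psi_summary <- function(series, frame_window = NULL) {
  stopifnot(is.data.frame(series), all(c("frame", "triplet", "psi_deg") %in% names(series)))
  if (!is.null(frame_window)) {
    if (length(frame_window) == 0L) stop("empty frame window")
    series <- series[series$frame %in% (frame_window - 1L), , drop = FALSE]
    if (nrow(series) == 0L) stop("frame window selects no frames of the series")
  }
  sp <- split(series$psi_deg, series$triplet)
  out <- data.frame(triplet = as.integer(names(sp)),
                    mean_psi_deg = vapply(sp, mean, numeric(1L)),
                    sd_psi_deg = vapply(sp, stats::sd, numeric(1L)),
                    n_frames = vapply(sp, length, integer(1L)),
                    row.names = NULL)
  out[order(out$triplet), , drop = FALSE]
}
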