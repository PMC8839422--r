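# Independent oracles and small fixture builders. The oracles deliberately
# take different computational routes than the package code they check.

# psi via edge-vector dot products (the package uses side lengths + law of
# cosines on the triangle, this uses normalized direction vectors per vertex)
psi_oracle <- function(p1, p2, p3) {
  vertex_angle <- function(a, b, c) {
    u <- b - a; v <- c - a
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  th <- c(vertex_angle(p1, p2, p3), vertex_angle(p2, p1, p3),
          vertex_angle(p3, p1, p2))
  mean(abs(th - 60))
}

# all-pairs minimum distance, plain double loop
brute_min_distance <- function(xyz, idx_a, idx_b) {
  best <- Inf
  for (i in idx_a) for (j in idx_b) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < best) best <- d
  }
  best
}

random_rotation <- function() {
  # QR of a random matrix, sign-fixed to a proper rotation
  qr_d <- qr(matrix(stats::rnorm(9), 3L))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# minimal structure with arginine/aspartate side-chain atoms at given
# residue centers (plus jittered side-chain geometry) for salt-bridge tests
make_charged_structure <- function(centers_basic, centers_acidic, seed = 1L) {
  set.seed(seed)
  rows <- list(); xyz <- list(); serial <- 0L; resid <- 0L
  add_res <- function(resname, names, center) {
    resid <<- resid + 1L
    for (nm in names) {
      serial <<- serial + 1L
      rows[[serial]] <<- data.frame(serial = serial, name = nm,
                                    resname = resname, chain = "A",
                                    resid = resid, element = substr(nm, 1L, 1L),
                                    stringsAsFactors = FALSE)
      xyz[[serial]] <<- center + stats::rnorm(3L, sd = 0.4)
    }
  }
  for (k in seq_len(nrow(centers_basic)))
    add_res("ARG", c("CA", "NE", "NH1", "NH2"), centers_basic[k, ])
  for (k in seq_len(nrow(centers_acidic)))
    add_res("ASP", c("CA", "OD1", "OD2"), centers_acidic[k, ])
  carrier_structure(do.call(rbind, rows), do.call(rbind, xyz))
}

# a planar guanidinium group (CZ at center, NE/NH1/NH2 in the plane spanned
# by u, v), for stacking fixtures
guanidinium_atoms <- function(resid, center, u, v, serial0) {
  u <- u / sqrt(sum(u^2)); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
  pos <- rbind(center,
               center + 1.33 * u,
               center + 1.33 * (cos(2 * pi / 3) * u + sin(2 * pi / 3) * v),
               center + 1.33 * (cos(2 * pi / 3) * u - sin(2 * pi / 3) * v))
  atoms <- data.frame(serial = serial0 + 1:4,
                      name = c("CZ", "NE", "NH1", "NH2"), resname = "ARG",
                      chain = "A", resid = resid, element = c("C", "N", "N", "N"),
                      stringsAsFactors = FALSE)
  list(atoms = atoms, xyz = pos)
}

make_stacking_structure <- function(center_j, normal_j = c(0, 0, 1)) {
  # residue 1 in the xy-plane at the origin; residue 2 with the given plane
  n <- normal_j / sqrt(sum(normal_j^2))
  ref <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n; u <- u / sqrt(sum(u^2))
  v <- c(n[2L] * u[3L] - n[3L] * u[2L], n[3L] * u[1L] - n[1L] * u[3L],
         n[1L] * u[2L] - n[2L] * u[1L])
  g1 <- guanidinium_atoms(1L, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), 0L)
  g2 <- guanidinium_atoms(2L, center_j, u, v, 4L)
  carrier_structure(rbind(g1$atoms, g2$atoms), rbind(g1$xyz, g2$xyz))
}

# tiny deterministic toy carrier used across tests
small_carrier <- function(..., helix_length = 20L, n_frames = 50L,
                          noise_sigma = 0, seed = 11L) {
  spec <- toy_carrier_spec(helix_length = helix_length, n_frames = n_frames,
                           noise_sigma = noise_sigma, seed = seed, ...)
  build_toy_carrier(spec)
}
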