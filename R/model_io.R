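#' Structure and trajectory containers, PDB input/output, atom selection
#'
#' A `carrier_structure` holds one topology: an atom table (serial, name,
#' residue number/name, chain, element) plus an n x 3 coordinate matrix in
#' Angstrom. A `carrier_trajectory` holds an ordered stack of coordinate
#' frames sharing one topology, stored as an n_atoms x 3 x n_frames array.
#' Multi-model PDB (MODEL/ENDMDL) is the normative trajectory format; frames
#' are 0-based in all user-facing tables, residue numbering is 1-based as in
#' the PDB, times are picoseconds.
#'
#' @name model_io
NULL

#' Construct a structure from an atom table and coordinates
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resid`, `element` (one row per atom).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param title optional title string.
#' @return object of class `carrier_structure`.
#' @export
carrier_structure <- function(atoms, xyz, title = "") {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3L)
    stop("xyz must be an n_atoms x 3 matrix matching the atom table")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  need <- c("serial", "name", "resname", "chain", "resid", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$serial)) stop("duplicate atom serial numbers")
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key)) stop("duplicate atom name within a residue")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz, title = title),
            class = "carrier_structure")
}

#' @export
print.carrier_structure <- function(x, ...) {
  cat(sprintf("<carrier_structure> %d atoms, %d residues%s\n",
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resid))),
              if (nzchar(x$title)) paste0(" — ", x$title) else ""))
  invisible(x)
}

n_atoms <- function(structure) nrow(structure$atoms)

#' Construct a trajectory from a topology and a frame stack
#'
#' @param topology a `carrier_structure`.
#' @param coords n_atoms x 3 x n_frames numeric array (Angstrom), or a list of
#'   n_atoms x 3 matrices.
#' @param times optional frame times in ps, strictly increasing.
#' @return object of class `carrier_trajectory`.
#' @export
carrier_trajectory <- function(topology, coords, times = NULL) {
  stopifnot(inherits(topology, "carrier_structure"))
  if (is.list(coords)) {
    nf <- length(coords)
    arr <- array(NA_real_, dim = c(nrow(coords[[1L]]), 3L, nf))
    for (k in seq_len(nf)) arr[, , k] <- as.matrix(coords[[k]])
    coords <- arr
  }
  if (length(dim(coords)) != 3L || dim(coords)[2L] != 3L)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1L] != n_atoms(topology))
    stop(sprintf("frame atom count (%d) does not match topology (%d)",
                 dim(coords)[1L], n_atoms(topology)))
  if (dim(coords)[3L] < 1L) stop("empty trajectory")
  if (!is.null(times)) {
    if (length(times) != dim(coords)[3L]) stop("times length must equal frame count")
    if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  }
  structure(list(topology = topology, coords = coords, times = times),
            class = "carrier_trajectory")
}

#' @export
print.carrier_trajectory <- function(x, ...) {
  cat(sprintf("<carrier_trajectory> %d frames x %d atoms\n",
              n_frames(x), dim(x$coords)[1L]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a `carrier_trajectory`.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3L]

#' Extract one frame of a trajectory as a structure
#'
#' @param trajectory a `carrier_trajectory`.
#' @param i 1-based frame index.
#' @return `carrier_structure` with the frame's coordinates.
#' @export
trajectory_frame <- function(trajectory, i) {
  nf <- n_frames(trajectory)
  if (i < 1L || i > nf) stop(sprintf("frame index %d outside 1..%d", i, nf))
  out <- trajectory$topology
  out$xyz <- trajectory$coords[, , i, drop = TRUE]
  dimnames(out$xyz) <- list(NULL, c("x", "y", "z"))
  out
}

# bio3d column names differ from ours (elety = atom name, resid = residue
# name, resno = residue number); translate and apply altloc/insertion policy.
bio3d_to_structure <- function(pdb, title = "") {
  at <- pdb$atom
  if (nrow(at) == 0L) stop("zero atoms in PDB file")
  ins <- at$insert
  if (any(!is.na(ins) & nzchar(trimws(ins))))
    stop("insertion codes are not supported; renumber the structure first")
  alt <- at$alt
  has_alt <- !is.na(alt) & nzchar(trimws(alt))
  if (any(has_alt)) {
    # keep the highest-occupancy conformer per (chain, resno, name)
    key <- paste(at$chain, at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      keep[idx] <- FALSE
      keep[idx[which.max(occ[idx])]] <- TRUE
    }
    at <- at[keep, , drop = FALSE]
  }
  chain <- ifelse(is.na(at$chain) | !nzchar(trimws(at$chain)), "A", at$chain)
  elem <- at$elesy
  if (is.null(elem)) elem <- NA_character_
  elem <- ifelse(is.na(elem) | !nzchar(trimws(elem)),
                 substr(trimws(at$elety), 1L, 1L), trimws(elem))
  atoms <- data.frame(serial = at$eleno, name = trimws(at$elety),
                      resname = trimws(at$resid), chain = chain,
                      resid = at$resno, element = elem,
                      stringsAsFactors = FALSE)
  carrier_structure(atoms, cbind(at$x, at$y, at$z), title = title)
}

#' Read a structure from a PDB file
#'
#' ATOM and HETATM records are parsed (via bio3d); for alternate locations the
#' highest-occupancy conformer is kept; insertion codes are rejected so that
#' residue numbering stays unambiguous.
#'
#' @param path path to a PDB file.
#' @param format only `"pdb"` is supported.
#' @return a `carrier_structure`.
#' @export
read_structure <- function(path, format = "pdb") {
  if (!identical(format, "pdb")) stop("unsupported format: ", format)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("malformed PDB '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  bio3d_to_structure(pdb, title = basename(path))
}

pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z) {
  # PDB v3.3 fixed columns; atom names of <4 chars start in column 14
  nm <- ifelse(nchar(name) >= 4L, substr(name, 1L, 4L), sprintf(" %-3s", name))
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial %% 100000L, nm, substr(resname, 1L, 3L),
          substr(chain, 1L, 1L), resid %% 10000L, x, y, z)
}

structure_pdb_lines <- function(structure, xyz = structure$xyz) {
  a <- structure$atoms
  pdb_atom_line(a$serial, a$name, a$resname, a$chain, a$resid,
                xyz[, 1L], xyz[, 2L], xyz[, 3L])
}

#' Write a structure to a PDB file
#'
#' @param structure a `carrier_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "carrier_structure"))
  lines <- c(sprintf("TITLE     %s", structure$title),
             structure_pdb_lines(structure), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' One frame per MODEL record; a file without MODEL records yields a
#' single-frame trajectory. Every model must carry exactly the topology's
#' atom count, in topology order.
#'
#' @param path multi-model PDB path.
#' @param topology a `carrier_structure` the frames must match; when `NULL`
#'   the first model is used as topology.
#' @return a `carrier_trajectory`.
#' @export
read_trajectory <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_starts <- which(trimws(rec) == "MODEL")
  if (sum(is_atom) == 0L) stop("zero atoms in trajectory file")
  if (length(model_starts) == 0L) {
    str1 <- read_structure(path)
    if (is.null(topology)) topology <- str1
    if (n_atoms(str1) != n_atoms(topology))
      stop("atom count mismatch with topology")
    return(carrier_trajectory(topology, list(str1$xyz)))
  }
  ends <- c(model_starts[-1L] - 1L, length(lines))
  counts <- vapply(seq_along(model_starts), function(k)
    sum(is_atom[model_starts[k]:ends[k]]), integer(1L))
  nat_expect <- if (is.null(topology)) counts[1L] else n_atoms(topology)
  bad <- which(counts != nat_expect)
  if (length(bad))
    stop(sprintf("frame %d has %d atoms, expected %d",
                 bad[1L], counts[bad[1L]], nat_expect))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  if (is.null(topology)) topology <- bio3d_to_structure(pdb, basename(path))
  nf <- nrow(pdb$xyz)
  coords <- array(NA_real_, dim = c(nat_expect, 3L, nf))
  for (k in seq_len(nf))
    coords[, , k] <- matrix(pdb$xyz[k, ], ncol = 3L, byrow = TRUE)
  carrier_trajectory(topology, coords)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param trajectory a `carrier_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "carrier_trajectory"))
  nf <- n_frames(trajectory)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("TITLE     %s", trajectory$topology$title), con)
  for (k in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(structure_pdb_lines(trajectory$topology,
                                   trajectory$coords[, , k, drop = TRUE]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms with a small selection language
#'
#' Clauses are joined with `and`; each clause is a keyword followed by one or
#' more values: `resid 29 134`, `resname ARG LYS`, `name CA CB`, `chain A`,
#' `segment H1 H3` (requires `helix_map`), or the bare keyword `all`.
#' Residue ranges are written `resid 5:36`.
#'
#' @param structure a `carrier_structure`.
#' @param selection selection string, or an integer vector of atom indices
#'   (returned as-is after validation).
#' @param helix_map optional [helix_map()] giving `segment` meaning.
#' @param warn_empty warn when the selection matches nothing (default TRUE).
#' @return integer vector of atom indices (class `atom_group`), in topology
#'   order.
#' @export
select_atoms <- function(structure, selection, helix_map = NULL,
                         warn_empty = TRUE) {
  stopifnot(inherits(structure, "carrier_structure"))
  at <- structure$atoms
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (anyDuplicated(idx) || any(idx < 1L | idx > nrow(at)))
      stop("invalid atom indices in selection")
    return(structure(idx, class = "atom_group"))
  }
  clauses <- strsplit(trimws(selection), "\\s+and\\s+")[[1L]]
  keep <- rep(TRUE, nrow(at))
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1L]]
    if (length(tok) == 0L) stop("empty selection clause")
    kw <- tok[1L]
    vals <- tok[-1L]
    if (kw != "all" && length(vals) == 0L)
      stop("selection clause '", cl, "' has no values")
    m <- switch(kw,
      all = rep(TRUE, nrow(at)),
      resid = {
        nums <- unlist(lapply(vals, function(v) {
          if (grepl(":", v, fixed = TRUE)) {
            ab <- as.integer(strsplit(v, ":", fixed = TRUE)[[1L]])
            seq.int(ab[1L], ab[2L])
          } else as.integer(v)
        }))
        if (anyNA(nums)) stop("non-numeric residue id in '", cl, "'")
        at$resid %in% nums
      },
      resname = at$resname %in% vals,
      name = at$name %in% vals,
      chain = at$chain %in% vals,
      segment = {
        if (is.null(helix_map)) stop("selection uses 'segment' but no helix_map given")
        hm <- as.data.frame(helix_map)
        unknown <- setdiff(vals, hm$segment)
        if (length(unknown)) stop("unknown segment: ", paste(unknown, collapse = ", "))
        rows <- hm[hm$segment %in% vals, , drop = FALSE]
        ok <- rep(FALSE, nrow(at))
        for (r in seq_len(nrow(rows)))
          ok <- ok | (at$resid >= rows$start[r] & at$resid <= rows$end[r])
        ok
      },
      stop("unknown selection keyword '", kw, "'")
    )
    keep <- keep & m
  }
  idx <- which(keep)
  if (length(idx) == 0L && warn_empty)
    warning("selection '", selection, "' matched no atoms")
  structure(idx, class = "atom_group")
}

#' Define named segments (helices, loops, matrix helices) over residue ranges
#'
#' @param ... named arguments, each `c(start, end)`, e.g. `H1 = c(4, 36)`.
#' @param kinds named character vector giving each segment's kind
#'   (`"helix"`, `"loop"`, `"matrix_helix"`); segments named `H<d>` default to
#'   helix, `h<dd>` to matrix_helix, everything else to loop.
#' @param domains named integer vector assigning segments to domains 1..3;
#'   transmembrane helices H1/H2 default to domain 1, H3/H4 to 2, H5/H6 to 3.
#' @return data.frame of class `helix_map` with columns `segment`, `start`,
#'   `end`, `kind`, `domain`.
#' @export
helix_map <- function(..., kinds = NULL, domains = NULL) {
  segs <- list(...)
  if (length(segs) == 1L && is.list(segs[[1L]]) && is.null(names(segs)[1L]))
    segs <- segs[[1L]]
  if (is.null(names(segs)) || any(!nzchar(names(segs))))
    stop("all segments must be named")
  df <- data.frame(segment = names(segs),
                   start = vapply(segs, function(r) as.integer(r[1L]), integer(1L)),
                   end = vapply(segs, function(r) as.integer(r[2L]), integer(1L)),
                   stringsAsFactors = FALSE)
  if (any(df$end < df$start)) stop("segment end before start")
  o <- order(df$start)
  so <- df[o, ]
  if (any(so$start[-1L] <= so$end[-nrow(so)]))
    stop("overlapping segment ranges")
  guess_kind <- function(s) {
    if (grepl("^H[0-9]+$", s)) "helix"
    else if (grepl("^h[0-9]+$", s)) "matrix_helix"
    else "loop"
  }
  df$kind <- vapply(df$segment, guess_kind, character(1L))
  if (!is.null(kinds)) df$kind[match(names(kinds), df$segment)] <- unname(kinds)
  default_dom <- c(H1 = 1L, H2 = 1L, H3 = 2L, H4 = 2L, H5 = 3L, H6 = 3L)
  df$domain <- unname(default_dom[df$segment])
  if (!is.null(domains)) df$domain[match(names(domains), df$segment)] <- as.integer(unname(domains))
  class(df) <- c("helix_map", "data.frame")
  df
}

#' Segment containing a residue
#'
#' @param resid residue number(s).
#' @param helix_map a [helix_map()].
#' @return character vector of segment names (`NA` when uncovered).
#' @export
segment_of <- function(resid, helix_map) {
  hm <- as.data.frame(helix_map)
  vapply(resid, function(r) {
    hit <- which(hm$start <= r & hm$end >= r)
    if (length(hit)) hm$segment[hit[1L]] else NA_character_
  }, character(1L))
}

#' Default helix map for the bovine ADP/ATP carrier fold
#'
#' Transmembrane helices H1-H6, the three matrix helices h12/h34/h56, and the
#' connecting loops, with residue ranges following the c-state crystal
#' structure topology of bovine AAC1. Ranges are configuration, not dogma:
#' override per system in the analysis config.
#'
#' @return a [helix_map()].
#' @export
aac_helix_map <- function() {
  helix_map(
    Nter = c(1, 3),
    H1 = c(4, 36),   M1 = c(37, 55),  h12 = c(56, 64),  M1b = c(65, 72),
    H2 = c(73, 99),  C1 = c(100, 108),
    H3 = c(109, 140), M2 = c(141, 156), h34 = c(157, 165), M2b = c(166, 175),
    H4 = c(176, 200), C2 = c(201, 210),
    H5 = c(211, 237), M3 = c(238, 252), h56 = c(253, 261), M3b = c(262, 268),
    H6 = c(269, 293), Cter = c(294, 297)
  )
}

default_cutoffs <- function() {
  list(salt_bridge = 4.0, hbond_dist = 3.5, hbond_angle = 30,
       stacking_dist = 5.0, stacking_angle = 30, gap = 6.0)
}

#' Load an analysis configuration from YAML or JSON
#'
#' Fields: `helix_map` (named list of `[start, end]` ranges, optional `kinds`
#' and `domains`), `triplet_offsets` (`odd` and/or `even`, three integers),
#' `triplets` (indices to analyse), `interactions` (list of
#' `{type, a, b, cutoff?}` entries; `a`/`b` are residue numbers or selection
#' strings), `frame_window` (`start_fraction` or `start_frame`/`end_frame`),
#' `cutoffs`, `stride`, `output_dir`. Missing cutoffs take the package
#' defaults (salt bridge 4.0 A; H-bond 3.5 A / 30 deg; stacking 5.0 A /
#' 30 deg; gap 6.0 A); the default frame window discards the first 20% of
#' frames, mirroring occupancy analysis that drops the equilibration-adjacent
#' first fifth of a production run.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return validated config list of class `mgate_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE,
                                                    simplifyDataFrame = FALSE)
         else stop("unsupported config format: .", ext)
  as_mgate_config(raw)
}

#' Build/validate an analysis configuration from a list
#'
#' @param raw named list with the fields described in [load_config()].
#' @return config of class `mgate_config`.
#' @export
as_mgate_config <- function(raw) {
  if (!is.list(raw)) stop("config must be a mapping")
  cfg <- list()
  cfg$helix_map <- if (is.null(raw$helix_map)) aac_helix_map() else {
    hmraw <- raw$helix_map
    kinds <- if (!is.null(hmraw$kinds)) unlist(hmraw$kinds) else NULL
    domains <- if (!is.null(hmraw$domains)) unlist(hmraw$domains) else NULL
    hmraw$kinds <- NULL; hmraw$domains <- NULL
    helix_map(hmraw, kinds = kinds, domains = domains)
  }
  off <- raw$triplet_offsets
  cfg$triplet_offsets <- list(
    odd = if (!is.null(off$odd)) as.integer(unlist(off$odd)) else c(0L, 105L, 202L),
    even = if (!is.null(off$even)) as.integer(unlist(off$even)) else c(0L, 97L, 200L))
  if (length(cfg$triplet_offsets$odd) != 3L || length(cfg$triplet_offsets$even) != 3L)
    stop("config field 'triplet_offsets': each frame needs exactly 3 offsets")
  cfg$triplets <- if (!is.null(raw$triplets)) as.integer(unlist(raw$triplets)) else 25:37
  cfg$interactions <- lapply(seq_along(raw$interactions), function(i) {
    sp <- raw$interactions[[i]]
    if (is.null(sp$type) || !sp$type %in% c("salt_bridge", "hbond", "stacking", "ligand_contact"))
      stop(sprintf("config field 'interactions[%d].type': must be one of salt_bridge, hbond, stacking, ligand_contact", i))
    if (is.null(sp$a) || is.null(sp$b))
      stop(sprintf("config field 'interactions[%d]': needs partners 'a' and 'b'", i))
    sp
  })
  fw <- raw$frame_window
  cfg$frame_window <- list(
    start_fraction = if (!is.null(fw$start_fraction)) as.numeric(fw$start_fraction)
                     else if (is.null(fw$start_frame)) 0.2 else NULL,
    start_frame = if (!is.null(fw$start_frame)) as.integer(fw$start_frame) else NULL,
    end_frame = if (!is.null(fw$end_frame)) as.integer(fw$end_frame) else NULL)
  if (!is.null(cfg$frame_window$start_fraction) &&
      (cfg$frame_window$start_fraction < 0 || cfg$frame_window$start_fraction >= 1))
    stop("config field 'frame_window.start_fraction': must lie in [0, 1)")
  cfg$cutoffs <- utils::modifyList(default_cutoffs(),
                                   lapply(raw$cutoffs %||% list(), as.numeric))
  if (any(unlist(cfg$cutoffs) <= 0)) stop("config field 'cutoffs': all cutoffs must be > 0")
  cfg$stride <- if (!is.null(raw$stride)) as.integer(raw$stride) else 1L
  if (cfg$stride < 1L) stop("config field 'stride': must be >= 1")
  cfg$reporting_floor <- if (!is.null(raw$reporting_floor)) as.numeric(raw$reporting_floor) else 5
  cfg$distance_pairs <- raw$distance_pairs
  cfg$gap <- utils::modifyList(list(open_cutoff = cfg$cutoffs$gap, min_duration = 10L),
                               lapply(raw$gap %||% list(), as.numeric))
  cfg$rmsf_selection <- raw$rmsf_selection %||% "name CA"
  cfg$psi_atom <- raw$psi_atom %||% "CA"
  cfg$psi_method <- raw$psi_method %||% "mean_abs"
  cfg$output_dir <- raw$output_dir %||% "."
  class(cfg) <- "mgate_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a configured frame window to 1-based frame indices
#'
#' @param frame_window list with `start_fraction` or `start_frame` (0-based)
#'   and optional `end_frame` (0-based inclusive); or NULL for the default
#'   last 80%.
#' @param n_frames total number of frames.
#' @return integer vector of 1-based frame indices.
#' @export
resolve_frame_window <- function(frame_window, n_frames) {
  fw <- frame_window %||% list(start_fraction = 0.2)
  start1 <- if (!is.null(fw$start_frame)) fw$start_frame + 1L
            else floor((fw$start_fraction %||% 0.2) * n_frames) + 1L
  end1 <- if (!is.null(fw$end_frame)) fw$end_frame + 1L else n_frames
  if (start1 < 1L || end1 > n_frames || start1 > end1)
    stop(sprintf("frame window [%d, %d] empty or outside 1..%d", start1, end1, n_frames))
  seq.int(start1, end1)
}
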