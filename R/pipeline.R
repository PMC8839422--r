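#' Orchestration: configuration -> analyses -> report bundle, and
#' system-to-system comparison
#'
#' `run_pipeline()` executes every configured analysis (occupancy network,
#' attachment scores, psi series and summary, RMSF, minimum-distance series
#' with gap events, bridging-solvent counts) over one trajectory and writes
#' the result tables as CSV/JSON with a provenance block. `compare_systems()`
#' aligns two report bundles (e.g. wild type vs a mutant) and returns
#' per-edge occupancy differences, per-triplet mean-psi differences and
#' per-residue RMSF differences.
#'
#' @name pipeline
NULL

config_hash <- function(cfg) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                         force = TRUE, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

write_table <- function(df, path, round_cols = NULL, digits = 1L) {
  if (!is.null(round_cols))
    for (cl in intersect(round_cols, names(df)))
      df[[cl]] <- round_half_away(df[[cl]], digits)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages (each skipped when unconfigured): interaction occupancies and
#' classes; per-domain-pair attachment scores; psi series and per-triplet
#' summary; RMSF profile; minimum-distance series plus gap events for each
#' configured residue pair; bridging-solvent counts. Any stage error aborts
#' the run naming the stage. Outputs are deterministic for identical inputs:
#' the provenance block records the config hash and frame window, never a
#' timestamp.
#'
#' @param config an `mgate_config`, or a path to a YAML/JSON config.
#' @param topology a `carrier_structure` or PDB path.
#' @param trajectory a `carrier_trajectory` or multi-model PDB path.
#' @param out_dir output directory for CSV/JSON tables; `NULL` writes
#'   nothing.
#' @return list of class `report_bundle` with elements `occupancy_table`,
#'   `attachment_scores`, `psi_series`, `psi_summary`, `rmsf`,
#'   `distance_series` (list), `gap_events` (list), `solvent_counts`,
#'   `provenance`.
#' @export
run_pipeline <- function(config, topology, trajectory, out_dir = NULL) {
  cfg <- if (is.character(config)) load_config(config)
         else if (inherits(config, "mgate_config")) config
         else as_mgate_config(config)
  stage <- "load inputs"
  bundle <- tryCatch({
    topo <- if (is.character(topology)) read_structure(topology) else topology
    traj <- if (is.character(trajectory)) read_trajectory(trajectory, topo)
            else trajectory
    if (cfg$stride > 1L) {
      keep <- seq(1L, n_frames(traj), by = cfg$stride)
      traj <- carrier_trajectory(traj$topology,
                                 traj$coords[, , keep, drop = FALSE])
    }
    window <- resolve_frame_window(cfg$frame_window, n_frames(traj))
    out <- list()

    stage <- "interaction network"
    if (length(cfg$interactions)) {
      out$occupancy_table <- build_network(traj, cfg)
      stage <- "attachment scores"
      out$attachment_scores <- attachment_scores(out$occupancy_table, cfg$helix_map)
    }

    stage <- "symmetry (psi)"
    if (length(cfg$triplets)) {
      tm <- list(odd = cfg$triplet_offsets$odd, even = cfg$triplet_offsets$even)
      out$psi_series <- psi_series(traj, tm, cfg$triplets,
                                   atom_name = cfg$psi_atom,
                                   method = cfg$psi_method)
      out$psi_summary <- psi_summary(out$psi_series, window)
    }

    stage <- "RMSF"
    out$rmsf <- rmsf(traj, cfg$rmsf_selection, window,
                     helix_map = cfg$helix_map)

    stage <- "distance series / gap events"
    if (length(cfg$distance_pairs)) {
      out$distance_series <- list()
      out$gap_events <- list()
      for (i in seq_along(cfg$distance_pairs)) {
        dp <- cfg$distance_pairs[[i]]
        nm <- dp$name %||% paste0("pair", i)
        ds <- min_distance_series(traj, dp$a, dp$b, cfg$helix_map)
        out$distance_series[[nm]] <- ds
        out$gap_events[[nm]] <- gap_events(ds, cfg$gap$open_cutoff,
                                           cfg$gap$min_duration)
      }
    }

    stage <- "solvent counts"
    sv <- cfg$distance_pairs
    has_solvent <- any(topo$atoms$resname %in% c("HOH", "WAT", "SOL"))
    if (has_solvent && length(cfg$distance_pairs)) {
      dp <- cfg$distance_pairs[[1L]]
      out$solvent_counts <- solvent_count_series(traj, dp$a, dp$b,
                                                 helix_map = cfg$helix_map)
    }

    out$provenance <- list(config_hash = config_hash(cfg),
                           n_frames = n_frames(traj),
                           frame_window = c(min(window), max(window)) - 1L,
                           n_atoms = n_atoms(traj$topology),
                           package_version = as.character(utils::packageVersion("mgatekit")))
    out
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  class(bundle) <- "report_bundle"
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' Write a report bundle's tables to a directory
#'
#' Occupancies are rounded to one decimal (half away from zero) in the CSV;
#' the in-memory bundle keeps exact values.
#'
#' @param bundle a `report_bundle`.
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  if (!is.null(bundle$occupancy_table)) {
    write_table(bundle$occupancy_table, p("occupancy_table.csv"),
                round_cols = "occupancy_pct")
    nodes <- unique(c(bundle$occupancy_table$res_a, bundle$occupancy_table$res_b))
    jsonlite::write_json(
      list(nodes = nodes[!is.na(nodes)],
           edges = bundle$occupancy_table[, c("res_a", "res_b", "type",
                                              "class", "occupancy_pct")]),
      p("network.json"), auto_unbox = FALSE, digits = NA, dataframe = "rows")
  }
  if (!is.null(bundle$attachment_scores))
    write_table(bundle$attachment_scores, p("attachment_scores.csv"))
  if (!is.null(bundle$psi_series))
    write_table(bundle$psi_series, p("psi_series.csv"))
  if (!is.null(bundle$psi_summary))
    write_table(bundle$psi_summary, p("psi_summary.csv"))
  if (!is.null(bundle$rmsf)) write_table(bundle$rmsf, p("rmsf.csv"))
  for (nm in names(bundle$distance_series))
    write_table(bundle$distance_series[[nm]],
                p(sprintf("distance_series_%s.csv", nm)))
  for (nm in names(bundle$gap_events))
    write_table(bundle$gap_events[[nm]], p(sprintf("gap_events_%s.csv", nm)))
  if (!is.null(bundle$solvent_counts))
    write_table(bundle$solvent_counts, p("solvent_counts.csv"))
  jsonlite::write_json(bundle$provenance, p("provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Differences between two report bundles (system B minus system A)
#'
#' Edges are aligned on (res_a, res_b, type); an edge absent from one system
#' counts as 0% occupancy there. Triplets and residues are aligned on their
#' indices. The result is antisymmetric: swapping the arguments flips every
#' sign.
#'
#' @param report_a,report_b `report_bundle`s computed under compatible
#'   configs.
#' @return list of class `system_delta` with `occupancy_delta`
#'   (`res_a`, `res_b`, `type`, `occupancy_a`, `occupancy_b`, `delta`),
#'   `psi_delta` (`triplet`, `delta_mean_psi_deg`), `rmsf_delta`
#'   (`resid`, `delta_rmsf`).
#' @export
compare_systems <- function(report_a, report_b) {
  key <- function(tab) paste(tab$res_a, tab$res_b, tab$type)
  occ_delta <- NULL
  ta <- report_a$occupancy_table; tb <- report_b$occupancy_table
  if (!is.null(ta) || !is.null(tb)) {
    keys <- union(if (!is.null(ta)) key(ta) else character(0),
                  if (!is.null(tb)) key(tb) else character(0))
    lookup <- function(tab, keys) {
      if (is.null(tab)) return(rep(0, length(keys)))
      m <- match(keys, key(tab))
      ifelse(is.na(m), 0, tab$occupancy_pct[m])
    }
    parts <- do.call(rbind, strsplit(keys, " "))
    occ_delta <- data.frame(res_a = as.integer(parts[, 1L]),
                            res_b = as.integer(parts[, 2L]),
                            type = parts[, 3L],
                            occupancy_a = lookup(ta, keys),
                            occupancy_b = lookup(tb, keys))
    occ_delta$delta <- occ_delta$occupancy_b - occ_delta$occupancy_a
  }
  psi_delta <- NULL
  if (!is.null(report_a$psi_summary) && !is.null(report_b$psi_summary)) {
    sa <- report_a$psi_summary; sb <- report_b$psi_summary
    if (!identical(sa$triplet, sb$triplet))
      stop("incompatible configs: psi summaries cover different triplets")
    psi_delta <- data.frame(triplet = sa$triplet,
                            delta_mean_psi_deg = sb$mean_psi_deg - sa$mean_psi_deg)
  }
  rmsf_delta <- NULL
  if (!is.null(report_a$rmsf) && !is.null(report_b$rmsf)) {
    ra <- report_a$rmsf; rb <- report_b$rmsf
    if (!identical(ra$resid, rb$resid))
      stop("incompatible configs: RMSF profiles cover different residues")
    rmsf_delta <- data.frame(resid = ra$resid, delta_rmsf = rb$rmsf - ra$rmsf)
  }
  structure(list(occupancy_delta = occ_delta, psi_delta = psi_delta,
                 rmsf_delta = rmsf_delta), class = "system_delta")
}
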