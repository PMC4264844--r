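#' Write the analysis report bundle
#'
#' Emits the standard table layouts as TSV plus a JSON bundle with
#' deterministic field order: a region-by-alignment RMSD table (mean and
#' ensemble SD per protein region under A1/A2), a per-moiety table of
#' center-of-mass distances and RMSDs (bound-state reference value next to
#' the ensemble average), and the moiety-by-residue contact map with its
#' bridging-water layer.
#'
#' @param out_dir output directory (created if needed).
#' @param rmsd_table data.frame with columns `region`, `alignment`,
#'   `mean`, `sd` (may be NULL).
#' @param moiety_table data.frame with columns `moiety`, `dcm_ref`,
#'   `dcm_mean`, `dcm_sd`, `rmsd_mean`, `rmsd_sd` (may be NULL).
#' @param cmap a `contact_map` (may be NULL; an empty map is written as a
#'   valid empty file).
#' @param extra named list merged into the JSON bundle.
#' @return named character vector of the files written, invisibly.
#' @export
report_tables <- function(out_dir, rmsd_table = NULL, moiety_table = NULL,
                          cmap = NULL, extra = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  bundle <- list()
  if (!is.null(rmsd_table)) {
    f <- file.path(out_dir, "rmsd_by_region.tsv")
    utils::write.table(rmsd_table, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files["rmsd_by_region"] <- f
    bundle$rmsd_by_region <- rmsd_table
  }
  if (!is.null(moiety_table)) {
    f <- file.path(out_dir, "moiety_position.tsv")
    utils::write.table(moiety_table, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files["moiety_position"] <- f
    bundle$moiety_position <- moiety_table
  }
  if (!is.null(cmap)) {
    f <- file.path(out_dir, "contact_map.tsv")
    m <- as.data.frame(cmap$map)
    m <- cbind(group = rownames(cmap$map), m)
    utils::write.table(m, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["contact_map"] <- f
    bundle$contact_map <- list(map = cmap$map, residues = cmap$residues,
                               cutoff = cmap$cutoff)
    if (!is.null(cmap$waters)) {
      bundle$bridging_waters <- cmap$waters
      fw <- file.path(out_dir, "bridging_waters.tsv")
      w <- cbind(group = rownames(cmap$waters),
                 as.data.frame(cmap$waters))
      utils::write.table(w, fw, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files["bridging_waters"] <- fw
    }
  }
  bundle <- c(bundle, extra)
  fj <- file.path(out_dir, "report.json")
  jsonlite::write_json(bundle, fj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files["bundle"] <- fj
  invisible(files)
}

#' End-to-end intermediate search and analysis on a toy complex
#'
#' Runs the full pipeline: bound-state sampling, the three-step search
#' ([run_protocol()]), then the geometry and contact analysis of the
#' accepted cluster, and writes the report bundle.
#'
#' @param cx a [make_toy_complex()] system (default landscape when NULL).
#' @param seed master seed.
#' @param out_dir report output directory, or NULL to skip writing.
#' @param ... passed on to [run_protocol()].
#' @return list of class `pipeline_result`: `status` ("intermediate found"
#'   or "none found"), `protocol` (the `protocol_result`), `analysis`
#'   (tables and contact records for the accepted cluster, or NULL),
#'   `files` (report files written).
#' @export
run_pipeline <- function(cx = NULL, seed = 1L, out_dir = NULL, ...) {
  if (is.null(cx)) cx <- make_toy_complex()
  prot <- run_protocol(cx, seed = seed, ...)
  analysis <- NULL
  files <- NULL
  if (prot$found) {
    segs <- prot$accepted_segments
    trajs <- lapply(segs, function(s) s$traj)
    top <- cx$topology
    masses <- top$atoms$mass
    pocket <- group_atoms(top, "pocket")

    moiety_rows <- lapply(top$moieties, function(m) {
      midx <- group_atoms(top, m)
      dcm <- lapply(trajs, com_distance_series, group_a = pocket,
                    group_b = midx)
      rms <- lapply(trajs, rmsd_series, reference = cx$coords,
                    spec = alignment_spec("A1", m))
      sd_dcm <- summarize_series(dcm)
      sd_rms <- summarize_series(rms)
      data.frame(moiety = m,
                 dcm_ref = com_distance(cx$coords, pocket, midx, masses),
                 dcm_mean = sd_dcm$mean, dcm_sd = sd_dcm$ensemble_sd,
                 rmsd_mean = sd_rms$mean, rmsd_sd = sd_rms$ensemble_sd)
    })
    moiety_table <- do.call(rbind, moiety_rows)

    loop_grp <- if ("80s_loop" %in% names(top$groups)) "80s_loop" else NULL
    rmsd_rows <- list()
    nl <- summarize_series(lapply(trajs, rmsd_series,
                                  reference = cx$coords,
                                  spec = alignment_spec("A1", "nonloop")))
    rmsd_rows[[1]] <- data.frame(region = "nonloop", alignment = "A1",
                                 mean = nl$mean, sd = nl$ensemble_sd)
    if (!is.null(loop_grp)) {
      lp <- summarize_series(lapply(trajs, rmsd_series,
                                    reference = cx$coords,
                                    spec = alignment_spec("A2", loop_grp,
                                                          loop_grp)))
      rmsd_rows[[2]] <- data.frame(region = loop_grp, alignment = "A2",
                                   mean = lp$mean, sd = lp$ensemble_sd)
    }
    rmsd_table <- do.call(rbind, rmsd_rows)

    contacts <- candidate_contacts(trajs)
    cmap <- contact_map(trajs)
    analysis <- list(moiety_table = moiety_table, rmsd_table = rmsd_table,
                     contacts = contacts, contact_map = cmap)
    if (!is.null(out_dir))
      files <- report_tables(out_dir, rmsd_table, moiety_table, cmap,
                             extra = list(
                               seed = seed,
                               accepted_cluster = prot$report$accepted_id,
                               mean_rho = prot$report$clusters[[
                                 as.character(prot$report$accepted_id)]]$mean_rho))
  } else if (!is.null(out_dir)) {
    files <- report_tables(out_dir, extra = list(seed = seed,
                                                 status = "none found"))
  }
  structure(list(
    status = if (prot$found) "intermediate found" else "none found",
    protocol = prot, analysis = analysis, files = files),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", x$status, "\n")
  print(x$protocol)
  invisible(x)
}
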