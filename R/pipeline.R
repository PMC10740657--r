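#' Pipeline run configuration
#'
#' Bundles the synthetic-world configuration with the analysis parameters
#' of a full run. Each pipeline stage regenerates its inputs from the seed,
#' so a configuration fully determines every output file.
#'
#' @param synthetic a [synthetic_config()].
#' @param k envelope admission half-width in SD units.
#' @param aggregation multi-variable vulnerability combination,
#'   `"mean"` or `"max"`.
#' @param mode habitat rendering mode, `"inclusive"` or `"most_likely"`.
#' @param buffer_m habitat buffer distance in metres.
#' @param iterations randomization iterations.
#' @param connectivity patch adjacency, `"rook"` or `"queen"`.
#' @param mcnemar_correct correction trigger for [mcnemar_change()].
#' @param species species whose profiles are analyzed; default all eight.
#' @return List of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       k = 2, aggregation = "mean", mode = "inclusive",
                       buffer_m = 1000, iterations = 500,
                       connectivity = "rook",
                       mcnemar_correct = "any_cell_lt5",
                       species = NULL) {
  stopifnot(inherits(synthetic, "synthetic_config"))
  structure(list(synthetic = synthetic, k = k, aggregation = aggregation,
                 mode = mode, buffer_m = buffer_m, iterations = iterations,
                 connectivity = connectivity,
                 mcnemar_correct = mcnemar_correct, species = species),
            class = "run_config")
}

pipeline_objects <- function(config) {
  cfg <- config$synthetic
  tax <- eru_taxonomy()
  ls <- synthetic_landscape(cfg, tax)
  clim_now <- synthetic_climate(ls, cfg, warmed = FALSE)
  clim_2090 <- synthetic_climate(ls, cfg, warmed = TRUE)
  env <- fit_envelopes(ls, clim_now, cfg$interannual_sd)
  proj <- project_landscape(ls, clim_2090, env, k = config$k,
                            aggregation = config$aggregation)
  profiles <- default_owl_profiles(tax, cfg$n_zones)
  if (!is.null(config$species)) profiles <- profiles[config$species]
  list(taxonomy = tax, landscape = ls, climate_now = clim_now,
       climate_2090 = clim_2090, envelopes = env, projection = proj,
       profiles = profiles)
}

write_manifest <- function(dir, config, extra = character()) {
  cfg <- config$synthetic
  lines <- c(
    "owlshift run manifest",
    paste("package version:", as.character(utils::packageVersion("owlshift"))),
    paste("seed:", cfg$seed),
    sprintf("grid: %d x %d cells of %g m", cfg$nrow, cfg$ncol, cfg$cell_size),
    sprintf("warming offset: %g m equivalent uplift", cfg$warming_offset_m),
    sprintf("k = %g, aggregation = %s, mode = %s, buffer = %g m",
            config$k, config$aggregation, config$mode, config$buffer_m),
    sprintf("iterations = %d, connectivity = %s, mcnemar correction = %s",
            config$iterations, config$connectivity, config$mcnemar_correct),
    extra)
  writeLines(lines, file.path(dir, "manifest.txt"))
}

#' Pipeline stage: simulate the synthetic world
#'
#' Writes the landscape layers, present and 2090 climate surfaces, fitted
#' envelopes, and occurrence/territory points for the first configured
#' species, plus a run manifest. Identical configurations (including seed)
#' produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return Invisibly, the generated objects.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- pipeline_objects(config)
  write_landscape(obj$landscape, out_dir)
  for (v in names(obj$climate_now)) {
    write_ascii_grid(obj$climate_now[[v]],
                     file.path(out_dir, paste0("climate_current_", v, ".asc")),
                     obj$landscape$cell_size)
    write_ascii_grid(obj$climate_2090[[v]],
                     file.path(out_dir, paste0("climate_2090_", v, ".asc")),
                     obj$landscape$cell_size)
  }
  write_envelopes(obj$envelopes, file.path(out_dir, "envelopes.csv"))
  prof <- obj$profiles[[1]]
  hab <- render_habitat(prof, obj$landscape)
  occ <- synthetic_occurrences(hab, obj$landscape, config$synthetic,
                               species = prof$species)
  utils::write.csv(occ, file.path(out_dir, "occurrences.csv"),
                   row.names = FALSE)
  terr <- synthetic_territories(hab, obj$landscape,
                                seed = config$synthetic$seed,
                                species = prof$species)
  utils::write.csv(terr, file.path(out_dir, "territories.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, config,
                 c(sprintf("occurrences: %d rows", nrow(occ)),
                   sprintf("territories: %d rows", nrow(terr))))
  invisible(obj)
}

#' Pipeline stage: project 2090 vegetation
#'
#' Writes the most-likely 2090 ERU raster (integer codes), the current-ERU
#' vulnerability raster (score x 1000 as integer), and a manifest recording
#' the fraction of cells whose candidate set retains their current ERU.
#'
#' @inheritParams run_simulate
#' @export
run_project <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- pipeline_objects(config)
  ls <- obj$landscape; proj <- obj$projection
  code <- matrix(match(proj$most_likely, ls$taxonomy$eru_id), ls$nrow, ls$ncol)
  write_ascii_grid(code, file.path(out_dir, "eru_2090_most_likely.asc"),
                   ls$cell_size)
  write_ascii_grid(round(proj$vs_current * 1000),
                   file.path(out_dir, "vulnerability_x1000.asc"), ls$cell_size)
  cur <- as.vector(ls$eru)
  jj <- match(cur, proj$eru_ids)
  retain <- proj$candidates[cbind(seq_along(cur), jj)]
  retain[is.na(retain)] <- proj$riparian_cells[is.na(retain)]
  write_manifest(out_dir, config,
                 sprintf("current ERU among candidates: %.1f%% of cells",
                         100 * mean(retain)))
  invisible(obj)
}

#' Pipeline stage: species habitat maps and change summaries
#'
#' For each configured species: current and projected habitat rasters, a
#' change-summary table (extents, raw and rounded percent change,
#' persisted/gained/lost) and per-species patch statistics.
#'
#' @inheritParams run_simulate
#' @export
run_habitat <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- pipeline_objects(config)
  summaries <- NULL
  patches <- NULL
  for (prof in obj$profiles) {
    cur <- render_habitat(prof, obj$landscape)
    fut <- render_habitat(prof, obj$landscape, obj$projection,
                          mode = config$mode)
    write_ascii_grid(cur$mask,
                     file.path(out_dir, paste0(prof$species, "_current.asc")),
                     obj$landscape$cell_size)
    write_ascii_grid(fut$mask,
                     file.path(out_dir, paste0(prof$species, "_2090.asc")),
                     obj$landscape$cell_size)
    summaries <- rbind(summaries,
                       as.data.frame(change_summary(cur, fut, prof$species)))
    ps <- patch_statistics(cur, config$connectivity)
    pf <- patch_statistics(fut, config$connectivity)
    patches <- rbind(patches, data.frame(
      species = prof$species, period = c("current", "projected"),
      n_patches = c(ps$n_patches, pf$n_patches),
      min_ha = c(ps$min_ha, pf$min_ha), max_ha = c(ps$max_ha, pf$max_ha),
      mean_ha = c(ps$mean_ha, pf$mean_ha), sd_ha = c(ps$sd_ha, pf$sd_ha)))
  }
  utils::write.csv(summaries, file.path(out_dir, "change_summary.csv"),
                   row.names = FALSE, na = "NA")
  utils::write.csv(patches, file.path(out_dir, "patch_statistics.csv"),
                   row.names = FALSE, na = "NA")
  write_manifest(out_dir, config,
                 sprintf("species analyzed: %d", length(obj$profiles)))
  invisible(summaries)
}

#' Pipeline stage: model validation statistics
#'
#' For each configured species: generates occurrence records in its current
#' habitat, runs the spatially constrained randomization null with the
#' one-tailed z-test (without and with the buffer), and the McNemar paired
#' change test between current and projected capture, writing one
#' performance table and one change-test table.
#'
#' @inheritParams run_simulate
#' @export
run_validate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- pipeline_objects(config)
  ls <- obj$landscape
  tax <- ls$taxonomy
  wooded <- matrix(tax$is_forest_or_woodland[match(ls$eru, tax$eru_id)],
                   ls$nrow, ls$ncol)
  perf <- NULL; change <- NULL
  for (prof in obj$profiles) {
    cur <- render_habitat(prof, ls)
    fut <- render_habitat(prof, ls, obj$projection, mode = config$mode)
    occ <- synthetic_occurrences(cur, ls, config$synthetic,
                                 species = prof$species)
    cap_cur <- capture_records(occ, cur, config$buffer_m)
    cap_fut <- capture_records(occ, fut, config$buffer_m)
    sampling <- wooded & matrix(as.vector(ls$zone) %in% prof$zones,
                                ls$nrow, ls$ncol)
    rnd <- randomization_null(cap_cur$within_model, nrow(occ), sampling,
                              cur$mask, config$iterations,
                              seed = config$synthetic$seed)
    zt <- one_tailed_z(cap_cur$within_model, nrow(occ), rnd$captures)
    buf <- buffer_mask(cur, config$buffer_m)
    rnd_b <- randomization_null(cap_cur$within_model + cap_cur$within_buffer,
                                nrow(occ), sampling, buf$mask,
                                config$iterations,
                                seed = config$synthetic$seed + 1L)
    zt_b <- one_tailed_z(cap_cur$within_model + cap_cur$within_buffer,
                         nrow(occ), rnd_b$captures)
    perf <- rbind(perf, data.frame(
      species = prof$species, cap_cur,
      n_outperform = rnd$n_outperform,
      z = round(zt$z, 2), p = round(zt$p_value, 4),
      n_outperform_buffer = rnd_b$n_outperform,
      z_buffer = round(zt_b$z, 2), p_buffer = round(zt_b$p_value, 4)))
    # paired 2x2 between current and projected capture, per record
    rc <- point_to_cell(ls, occ$x, occ$y)
    ok <- !is.na(rc[, "row"])
    idx <- (rc[ok, "col"] - 1L) * ls$nrow + rc[ok, "row"]
    in_cur <- cur$mask[idx]; in_fut <- fut$mask[idx]
    mc <- mcnemar_change(b = sum(in_cur & !in_fut), c = sum(!in_cur & in_fut),
                         a = sum(in_cur & in_fut), d = sum(!in_cur & !in_fut),
                         correct = config$mcnemar_correct)
    change <- rbind(change, data.frame(
      species = prof$species, n = nrow(occ),
      b = mc$b, c = mc$c,
      chisq = round(mc$statistic, 2), p = round(mc$p_value, 4),
      corrected = mc$correction_applied))
  }
  utils::write.csv(perf, file.path(out_dir, "model_performance.csv"),
                   row.names = FALSE, na = "NA")
  utils::write.csv(change, file.path(out_dir, "mcnemar_change.csv"),
                   row.names = FALSE, na = "NA")
  write_manifest(out_dir, config,
                 sprintf("validation species: %d", nrow(perf)))
  invisible(list(performance = perf, change = change))
}

#' Pipeline stage: territory transition analysis
#'
#' Generates breeding territories in the first configured species' current
#' habitat, overlays them on current and projected generalized vegetation,
#' and writes the transition matrix plus profile-retention percentages.
#'
#' @inheritParams run_simulate
#' @param profile_labels generalized labels counted as the species profile.
#' @export
run_territories <- function(config, out_dir,
                            profile_labels = c("Dry Forest",
                                               "Mixed Conifer with Aspen")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- pipeline_objects(config)
  prof <- obj$profiles[[1]]
  cur <- render_habitat(prof, obj$landscape)
  terr <- synthetic_territories(cur, obj$landscape,
                                seed = config$synthetic$seed,
                                species = prof$species)
  terr <- overlay_territories(terr, obj$landscape, obj$projection)
  tm <- transition_matrix(terr)
  m <- cbind(data.frame(current_veg = rownames(tm$counts)),
             as.data.frame.matrix(tm$counts),
             Total = unname(tm$row_totals))
  utils::write.csv(m, file.path(out_dir, "territory_transitions.csv"),
                   row.names = FALSE)
  profile_labels <- intersect(profile_labels, rownames(tm$counts))
  ret <- profile_retention(tm, profile_labels)
  utils::write.csv(data.frame(metric = names(ret), percent = round(ret, 1)),
                   file.path(out_dir, "profile_retention.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, config,
                 sprintf("territories: %d", tm$total))
  invisible(list(territories = terr, matrix = tm, retention = ret))
}

#' Run the full pipeline
#'
#' Executes all stages into subdirectories of `out_dir`.
#'
#' @inheritParams run_simulate
#' @export
run_all <- function(config, out_dir) {
  run_simulate(config, file.path(out_dir, "simulate"))
  run_project(config, file.path(out_dir, "project"))
  run_habitat(config, file.path(out_dir, "habitat"))
  run_validate(config, file.path(out_dir, "validate"))
  run_territories(config, file.path(out_dir, "territories"))
  invisible(out_dir)
}
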