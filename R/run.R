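#' Configuration for an end-to-end screen run
#'
#' Collects every parameter of a run. The defaults are the screen's printed
#' rule set: MAD-based Z with scale constant 1.4826, hit threshold Z > 5 in
#' 2 replicates, exclusion above 60% cell death. Each run writes its fully
#' resolved configuration next to its outputs.
#'
#' @param mode `"summary"` (draw per-well counts directly) or `"image"`
#'   (render, segment and quantify every well).
#' @param seed integer master seed; determines every stochastic draw.
#' @param n_compounds,controls_per_role,n_replicates,plate_name screen
#'   design: compounds per plate, control wells per role, replicate plates,
#'   and the plate-id stem (plates are named `<plate_name>_r<replicate>`).
#' @param n_rows,n_cols plate geometry (default 384-well, 16 x 24).
#' @param sim named list of [sim_config()] overrides (`cells_per_well`,
#'   `planted_hits`, `hit_effect`, `death_by_compound`, ...).
#' @param quant named list: `sigma`, `threshold_method`, `threshold_value`,
#'   `min_area`, `max_area`, `dilation_radius_px`, `k`.
#' @param stats named list: `scope`, `min_wells`, `mad_zero`.
#' @param hits named list: `z_threshold`, `min_replicates`, `death_cutoff`.
#' @param paths named list: `output_dir`, optional `images_dir` (image mode:
#'   where TIFFs are written/read), optional `plate_map` (CSV replacing the
#'   generated layouts).
#' @param write_images logical; in image mode, also write every rendered
#'   well as TIFFs under `paths$images_dir`.
#' @param log_level `"debug"`, `"info"`, `"warning"` or `"error"`.
#' @return a validated `run_config` list.
#' @export
run_config <- function(mode = c("summary", "image"),
                       seed = 1L,
                       n_compounds = 320L, controls_per_role = 16L,
                       n_replicates = 2L, plate_name = "PLATE",
                       n_rows = 16L, n_cols = 24L,
                       sim = list(), quant = list(), stats = list(),
                       hits = list(), paths = list(),
                       write_images = FALSE,
                       log_level = "info") {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode, seed = as.integer(seed),
    n_compounds = as.integer(n_compounds),
    controls_per_role = as.integer(controls_per_role),
    n_replicates = as.integer(n_replicates),
    plate_name = as.character(plate_name),
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    sim = sim,
    quant = modifyList(list(sigma = 1, threshold_method = "otsu",
                            threshold_value = NULL, min_area = 10L,
                            max_area = 5000L, dilation_radius_px = 3L,
                            k = 3), quant),
    stats = modifyList(list(scope = "compound_only", min_wells = 8L,
                            mad_zero = "error"), stats),
    hits = modifyList(list(z_threshold = 5, min_replicates = 2L,
                           death_cutoff = 0.60), hits),
    paths = modifyList(list(output_dir = "lipidscreen_run",
                            images_dir = NULL, plate_map = NULL), paths),
    write_images = isTRUE(write_images),
    log_level = match.arg(log_level, names(LOG_LEVELS))
  )
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1")
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' [read_run_config()] layers the file's values over [run_config()]
#' defaults, so a config file only needs to state what differs.
#'
#' @param path YAML file.
#' @param config a `run_config`.
#' @return [read_run_config()]: a `run_config`; [write_run_config()]:
#'   `path`, invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(y$sim$death_by_compound)) {
    y$sim$death_by_compound <- unlist(y$sim$death_by_compound)
  }
  if (!is.null(y$sim$planted_hits)) {
    y$sim$planted_hits <- as.character(unlist(y$sim$planted_hits))
  }
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  if (length(y$sim$death_by_compound)) {
    y$sim$death_by_compound <- as.list(y$sim$death_by_compound)
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the screen pipeline end to end
#'
#' Simulation (or image ingestion) -> per-well quantification -> per-plate
#' robust statistics -> Z scoring -> replicate-consensus hit calling, with
#' every intermediate written to `output_dir`: `quants.csv`,
#' `plate_stats.csv`, `scored.csv`, `hits.csv`, `all_compounds.csv`, the
#' resolved `config.yaml` and a `run.log`. Fixed seed implies byte-identical
#' CSV outputs.
#'
#' In `"summary"` mode per-well counts are drawn from the generative model
#' directly (fast; statistical validation at scale). In `"image"` mode every
#' well is rendered as a two-channel image and quantified by segmentation —
#' or, when `paths$plate_map` and `paths$images_dir` are both supplied and
#' simulation is off, read from existing TIFFs.
#'
#' @param config a [run_config()], or the path to its YAML file.
#' @param output_dir overrides `config$paths$output_dir`.
#' @return a `screen_run`: list with `quants`, `plate_stats` (list per
#'   plate), `scored`, `hits` (a [call_hits()] object), `report`
#'   (a [hit_report()]), `config`, `output_dir`.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(mode = "summary", seed = 11, n_compounds = 80,
#'                   controls_per_role = 8, sim = list(cells_per_well = 200),
#'                   paths = list(output_dir = tempfile("run")))
#' run <- run_screen(cfg)
#' run$report
#' }
run_screen <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!is.null(output_dir)) config$paths$output_dir <- output_dir
  out_dir <- config$paths$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- open_log(file.path(out_dir, "run.log"), level = config$log_level)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  log_line(log, "info", "run start: mode=", config$mode,
           " seed=", config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line(log, "error", "stage '", name, "' failed: ",
               conditionMessage(e))
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  layouts <- stage("layout", {
    if (!is.null(config$paths$plate_map)) {
      read_plate_map(config$paths$plate_map)
    } else {
      lapply(seq_len(config$n_replicates), function(r) {
        generate_plate_layout(
          n_compounds = config$n_compounds,
          controls_per_role = config$controls_per_role,
          plate_id = sprintf("%s_r%d", config$plate_name, r),
          replicate_id = r,
          n_rows = config$n_rows, n_cols = config$n_cols,
          seed = derive_seed(config$seed, r, 0L))
      })
    }
  })
  log_line(log, "info", length(layouts), " replicate plate(s)")

  sim_cfg <- stage("config", {
    do.call(sim_config, modifyList(list(seed = config$seed), config$sim))
  })

  q <- config$quant
  quants_by_plate <- stage("quantify", lapply(layouts, function(lay) {
    if (config$mode == "summary") {
      simulate_summary_plate(lay, sim_cfg)
    } else {
      truth <- simulate_well_truth(lay, sim_cfg)
      truth <- truth[lay$well[lay$role != "empty"]]
      images <- lapply(truth, render_well_image, config = sim_cfg)
      if (config$write_images && !is.null(config$paths$images_dir)) {
        for (img in images) write_well_image(img, config$paths$images_dir)
      }
      quantify_plate(images, lay, k = q$k, sigma = q$sigma,
                     threshold_method = q$threshold_method,
                     threshold_value = q$threshold_value,
                     min_area = q$min_area, max_area = q$max_area,
                     dilation_radius_px = q$dilation_radius_px)
    }
  }))
  quants <- do.call(rbind, quants_by_plate)
  log_line(log, "info", "quantified ", nrow(quants), " wells")

  stats_by_plate <- stage("stats", lapply(quants_by_plate, function(qp) {
    compute_plate_stats(qp, scope = config$stats$scope,
                        min_wells = config$stats$min_wells)
  }))
  scored <- stage("score", do.call(rbind, Map(function(qp, st) {
    score_plate(qp, st, mad_zero = config$stats$mad_zero)
  }, quants_by_plate, stats_by_plate)))

  hits <- stage("call-hits", call_hits(
    scored, z_threshold = config$hits$z_threshold,
    min_replicates = config$hits$min_replicates,
    death_cutoff = config$hits$death_cutoff))
  report <- hit_report(hits)
  log_line(log, "info", sum(hits$results$is_hit), " hit(s) called")

  stage("write", {
    write_quants(quants, file.path(out_dir, "quants.csv"))
    st <- do.call(rbind, lapply(stats_by_plate, function(s) {
      data.frame(plate_id = s$plate_id, replicate_id = s$replicate_id,
                 n_scoring_wells = s$n_scoring_wells, mean = s$mean,
                 sd = s$sd, median = s$median, mad = s$mad,
                 scoring_scope = s$scoring_scope)
    }))
    write_csv6(st, file.path(out_dir, "plate_stats.csv"))
    sc <- scored
    sc$plate_median <- rep(vapply(stats_by_plate, `[[`, 0, "median"),
                           vapply(quants_by_plate,
                                  function(qp) sum(qp$role != "empty"),
                                  0L))
    sc$plate_mad <- rep(vapply(stats_by_plate, `[[`, 0, "mad"),
                        vapply(quants_by_plate,
                               function(qp) sum(qp$role != "empty"), 0L))
    write_quants(sc, file.path(out_dir, "scored.csv"))
    res <- hits$results
    write_csv6(res[res$is_hit, , drop = FALSE],
               file.path(out_dir, "hits.csv"))
    write_csv6(res, file.path(out_dir, "all_compounds.csv"))
  })
  log_line(log, "info", "run complete: outputs in ", out_dir)

  structure(list(quants = quants, plate_stats = stats_by_plate,
                 scored = scored, hits = hits, report = report,
                 config = config, output_dir = out_dir),
            class = "screen_run")
}

#' @export
print.screen_run <- function(x, ...) {
  cat(sprintf("Screen run (%s mode, seed %d): %d wells over %d plate(s)\n",
              x$config$mode, x$config$seed, nrow(x$quants),
              length(x$plate_stats)))
  print(x$hits)
  cat("outputs:", x$output_dir, "\n")
  invisible(x)
}
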