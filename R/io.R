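#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, applies defaults for every omitted
#' block, and rejects unknown keys. The configuration mirrors the function
#' arguments: `seed`, `severity`, `noise`, `controller` (sampling_period_s,
#' q_max, target, bands), `outflow` (any [outflow_config()] argument),
#' `waveform` (any [waveform_config()] argument), `vessels` (wb_curve /
#' crystalloid_curve with form, coefficients, valid_range, plus
#' variability_scale), `start_map`, `deficit_mL`.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list with elements `seed`, `severity`,
#'   `noise`, `ctrl`, `outflow`, `wf`, `wb_profile`, `crys_profile`,
#'   `start_map`, `deficit_mL`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("seed", "severity", "noise", "controller", "outflow",
             "waveform", "vessels", "start_map", "deficit_mL")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  seed <- raw$seed %||% 0L
  if (!is.numeric(seed) || seed != round(seed)) {
    stop("config key 'seed' must be an integer", call. = FALSE)
  }
  severity <- raw$severity %||% "low"
  if (!severity %in% c("low", "high")) {
    stop("config key 'severity' must be 'low' or 'high'", call. = FALSE)
  }
  ctrl_raw <- raw$controller %||% list()
  sp <- ctrl_raw$sampling_period_s %||% 120
  if (!is.numeric(sp) || sp <= 0) {
    stop("config key 'controller$sampling_period_s' must be > 0",
         call. = FALSE)
  }
  bands <- if (!is.null(ctrl_raw$bands)) {
    do.call(rbind, lapply(ctrl_raw$bands, function(b) {
      data.frame(lower = as.numeric(b$lower %||% -Inf),
                 fraction = b$fraction)
    }))
  } else default_decision_bands()
  table <- decision_table(bands = bands,
                          q_max = ctrl_raw$q_max %||% 500,
                          target = ctrl_raw$target %||% 68)
  ctrl <- controller_config(sampling_period = sp, table = table)
  outflow <- do.call(outflow_config, raw$outflow %||% list())
  wf <- do.call(waveform_config, raw$waveform %||% list())
  vessels <- raw$vessels %||% list()
  make_curve <- function(spec, default) {
    if (is.null(spec)) return(default)
    pv_curve(spec$form, unlist(spec$coefficients),
             valid_range = unlist(spec$valid_range %||% c(0, 100)))
  }
  wb <- design_vessel_from_curve(make_curve(vessels$wb_curve,
                                            default_wb_curve()))
  crys <- design_vessel_from_curve(make_curve(vessels$crystalloid_curve,
                                              default_crystalloid_curve()))
  if (!is.null(vessels$variability_scale)) {
    wb <- apply_subject_variation(wb, vessels$variability_scale)
    crys <- apply_subject_variation(crys, vessels$variability_scale)
  }
  structure(list(seed = as.integer(seed), severity = severity,
                 noise = isTRUE(raw$noise %||% TRUE), ctrl = ctrl,
                 outflow = outflow, wf = wf, wb_profile = wb,
                 crys_profile = crys,
                 start_map = raw$start_map %||% 40,
                 deficit_mL = raw$deficit_mL %||% 2300,
                 echo = raw),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a configured run
#'
#' Convenience wrapper: runs the four default scenarios at the configured
#' severity with the configured controller, vessels and outflow engine.
#'
#' @param config A `run_config` from [load_config()], or a path to one.
#' @return The combined run record (see [run_sequence()]).
#' @export
run_from_config <- function(config) {
  if (is.character(config)) config <- load_config(config)
  run_sequence(specs = default_scenarios(config$severity),
               ctrl = config$ctrl, wb_profile = config$wb_profile,
               crys_profile = config$crys_profile, cfg = config$outflow,
               wf = config$wf, seed = config$seed, noise = config$noise,
               start_map = config$start_map, deficit_mL = config$deficit_mL)
}

#' Write run outputs
#'
#' Writes the run record as CSV, the performance report as JSON and tidy
#' CSV, a metadata sidecar (seed, scenario summaries), and optionally the
#' two-panel pressure/flow figures per scenario.
#'
#' @param record A run record.
#' @param dir Output directory (created if needed).
#' @param report Optional precomputed [performance_report()].
#' @param plots Also write per-scenario PDF figures?
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(record, dir, report = NULL, plots = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(report)) report <- performance_report(record)
  files <- character(0)
  f_rec <- file.path(dir, "run_record.csv")
  utils::write.csv(record, f_rec, row.names = FALSE)
  f_rep_csv <- file.path(dir, "performance_report.csv")
  utils::write.csv(report, f_rep_csv, row.names = FALSE)
  f_rep_json <- file.path(dir, "performance_report.json")
  rep_list <- split(report[, c("metric", "value", "units")], report$scope)
  jsonlite::write_json(rep_list, f_rep_json, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  meta <- list(seed = attr(record, "seed"),
               target = attr(record, "target"),
               scenario_info = attr(record, "scenario_info"))
  f_meta <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(meta, f_meta, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  files <- c(f_rec, f_rep_csv, f_rep_json, f_meta)
  if (isTRUE(plots)) {
    for (sid in unique(record$scenario_id)) {
      f <- file.path(dir, sprintf("scenario_%s.pdf", sid))
      grDevices::pdf(f, width = 8, height = 6)
      print(plot_run(record[record$scenario_id == sid, , drop = FALSE],
                     target = attr(record, "target") %||% 68))
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Two-panel pressure and flow figure
#'
#' Mean pressure with the target line and event markers on top, infusion
#' versus total outflow rates below, mirroring the standard presentation of
#' a scenario trace.
#'
#' @param record A run record (one scenario or a whole run).
#' @param target Target MAP, mmHg.
#' @return A ggplot object.
#' @export
plot_run <- function(record, target = 68) {
  d1 <- data.frame(time_min = record$time_s / 60,
                   value = record$sensed_map_mmHg,
                   panel = "MAP (mmHg)", series = "sensed MAP")
  d2 <- rbind(
    data.frame(time_min = record$time_s / 60,
               value = record$q_infusion_mL_min,
               panel = "Flow (mL/min)", series = "infusion"),
    data.frame(time_min = record$time_s / 60,
               value = record$q_hemorrhage_mL_min + record$q_urine_mL_min,
               panel = "Flow (mL/min)", series = "outflow"))
  d <- rbind(d1, d2)
  ref <- data.frame(panel = "MAP (mmHg)", yintercept = target)
  ev <- record$time_s[record$event_active != ""] / 60
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min, y = .data$value,
                                       colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = ref,
                        ggplot2::aes(yintercept = .data$yintercept),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
  if (length(ev) > 0) {
    p <- p + ggplot2::annotate("rect", xmin = min(ev), xmax = max(ev),
                               ymin = -Inf, ymax = Inf, alpha = 0.08,
                               fill = "red")
  }
  p
}

#' Read a MAP trace CSV for standalone metric scoring
#'
#' Accepts any CSV with a time column (`time_s`) and a pressure column
#' (`sensed_map_mmHg` or `MAP_mmHg`), plus optional flow columns.
#'
#' @param path CSV path.
#' @param target Target MAP, mmHg.
#' @return A [map_series()].
#' @export
read_map_csv <- function(path, target = 68) {
  d <- utils::read.csv(path)
  pcol <- intersect(c("sensed_map_mmHg", "MAP_mmHg", "pressure_mmHg"),
                    names(d))
  if (!"time_s" %in% names(d) || length(pcol) == 0) {
    stop("CSV must contain 'time_s' and a MAP column", call. = FALSE)
  }
  t <- d$time_s
  # whole-run records restart the clock at each scenario; re-clock them
  # onto one continuous axis
  if ("scenario_id" %in% names(d) && any(diff(t) <= 0)) {
    offs <- 0
    t <- unlist(lapply(split(d$time_s, d$scenario_id), function(ts) {
      out <- ts + offs
      offs <<- out[length(out)] + 1
      out
    }), use.names = FALSE)
  }
  map_series(t, d[[pcol[1]]], target)
}
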