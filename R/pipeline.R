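#' Pipeline configuration
#'
#' Central, validated configuration for the extraction and comparison
#' pipeline. Every run echoes its effective configuration (and a content
#' hash of it) into the outputs so results are auditable.
#'
#' @param band_low,band_high Band-pass edges, Hz.
#' @param filter_order Butterworth order.
#' @param zero_phase Forward-backward filtering.
#' @param resample_rate Common accelerometer analysis rate, Hz.
#' @param lane_exclusion_m Metres excluded at each lane end (mocap).
#' @param com_prominence COM / foot peak prominence, m.
#' @param ellipsoid_conf Confidence level of the sway ellipsoid.
#' @param alpha Family-wise significance level.
#' @param edge_guard Transient guard trimmed from window ends, s.
#' @param seed Seed recorded with the run.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(band_low = 0.8, band_high = 20, filter_order = 4,
                            zero_phase = TRUE, resample_rate = 100,
                            lane_exclusion_m = 1, com_prominence = 0.005,
                            ellipsoid_conf = 0.95, alpha = 0.05,
                            edge_guard = 1, seed = 1L) {
  cfg <- list(band_low = band_low, band_high = band_high,
              filter_order = filter_order, zero_phase = zero_phase,
              resample_rate = resample_rate,
              lane_exclusion_m = lane_exclusion_m,
              com_prominence = com_prominence,
              ellipsoid_conf = ellipsoid_conf, alpha = alpha,
              edge_guard = edge_guard, seed = as.integer(seed))
  if (!(cfg$band_low > 0 && cfg$band_low < cfg$band_high)) {
    stop("need 0 < band_low < band_high")
  }
  if (cfg$band_high >= cfg$resample_rate / 2) {
    stop("band_high must be below half the analysis rate")
  }
  if (cfg$ellipsoid_conf <= 0 || cfg$ellipsoid_conf >= 1) {
    stop("ellipsoid_conf must be in (0, 1)")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unspecified fields fall back to the [pipeline_config()] defaults; the
#' merged configuration is re-validated.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else stop("unsupported config format: .", ext)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

config_hash <- function(config) rlang::hash(unclass(config))

gait_tasks <- c("normal", "backward", "tandem")

#' Run the full extraction and comparison pipeline on a directory
#'
#' Expects recordings named `subject_task_visit_system.csv` (e.g.
#' `S01_normal_T1_smartphone.csv`), smartphone files in acceleration CSV
#' format and mocap files in position CSV format, with optional
#' `subject_task_visit.truth.json` sidecars (whose lane windows, when
#' present, are used for turn removal in the smartphone gait path).
#' Produces a long per-recording feature table, per-task between-system
#' agreement tables (per visit) and the Bonferroni-gated pre/post test
#' table. Failures are isolated per recording and reported, the run
#' continues.
#'
#' @param input_dir Directory of recording CSVs.
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for `features.csv`,
#'   `agreement.csv`, `prepost.csv` and `config.json`.
#' @return A list with `features`, `agreement`, `prepost`, `errors`,
#'   `config`, `config_hash`, `log`.
#' @export
run_pipeline <- function(input_dir, config = pipeline_config(),
                         output_dir = NULL) {
  files <- list.files(input_dir, pattern = "\\.csv$", full.names = TRUE)
  log <- character(0)
  if (!length(files)) {
    warning("no recordings found in ", input_dir)
    empty <- data.frame(subject = character(0), system = character(0),
                        task = character(0), visit = character(0),
                        variable = character(0), value = numeric(0))
    return(list(features = empty,
                agreement = build_agreement_tables(
                  cbind(empty[, c("subject", "system", "task", "variable",
                                  "value")])),
                prepost = NULL, errors = character(0), config = config,
                config_hash = config_hash(config),
                log = "empty input directory"))
  }

  rows <- list(); errors <- character(0)
  for (f in files) {
    parts <- strsplit(sub("\\.csv$", "", basename(f)), "_")[[1]]
    if (length(parts) != 4L) {
      errors <- c(errors, paste0(basename(f), ": name not subject_task_visit_system"))
      next
    }
    subject <- parts[1]; task <- parts[2]; visit <- parts[3]
    system <- parts[4]
    truth_path <- file.path(dirname(f),
                            paste0(paste(parts[1:3], collapse = "_"),
                                   ".truth.json"))
    res <- tryCatch({
      if (system == "smartphone") {
        rec <- read_accel_csv(f, task = task, device = system)
        if (task %in% gait_tasks) {
          windows <- if (file.exists(truth_path)) {
            read_ground_truth(truth_path)$lane_boundaries
          } else NULL
          ft <- smartphone_gait_features(rec, task = task, windows = windows,
                                         edge_guard = config$edge_guard,
                                         config = config)
          data.frame(variable = c("stride_time", "cadence", "velocity"),
                     value = c(ft$stride_time, ft$cadence, ft$velocity))
        } else {
          ft <- smartphone_balance_features(rec, config = config)
          data.frame(variable = c("sway_volume", "sway_velocity"),
                     value = c(ft$sway_volume, ft$sway_velocity))
        }
      } else if (system == "mocap") {
        rec <- read_position_csv(f, task = task)
        if (task %in% gait_tasks) {
          ft <- mocap_gait_features(rec, task = task,
                                    exclusion_m = config$lane_exclusion_m,
                                    min_prominence = config$com_prominence)
          data.frame(variable = c("stride_time", "cadence", "velocity",
                                  "step_width"),
                     value = c(ft$stride_time, ft$cadence, ft$velocity,
                               ft$step_width))
        } else {
          ft <- mocap_balance_features(rec)
          data.frame(variable = c("sway_area", "sway_velocity"),
                     value = c(ft$sway_area, ft$sway_velocity))
        }
      } else {
        stop("unknown system: ", system)
      }
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors <- c(errors, paste0(basename(f), ": ", res))
      next
    }
    res$subject <- subject; res$system <- system; res$task <- task
    res$visit <- visit
    rows[[length(rows) + 1L]] <- res
    log <- c(log, sprintf("%s: %d features", basename(f), nrow(res)))
  }

  features <- if (length(rows)) {
    do.call(rbind, rows)[, c("subject", "system", "task", "visit",
                             "variable", "value")]
  } else {
    data.frame(subject = character(0), system = character(0),
               task = character(0), visit = character(0),
               variable = character(0), value = numeric(0))
  }

  agreement <- do.call(rbind, lapply(unique(features$visit), function(v) {
    fv <- features[features$visit == v,
                   c("subject", "system", "task", "variable", "value")]
    tb <- build_agreement_tables(fv)
    if (nrow(tb)) tb$visit <- v
    tb
  }))

  prepost <- NULL
  if (all(c("T1", "T2") %in% unique(features$visit))) {
    pp <- list()
    for (sys in unique(features$system)) {
      fs <- features[features$system == sys, ]
      m <- length(unique(fs$variable))  # variables per system in the family
      for (task in unique(fs$task)) for (v in unique(fs$variable)) {
        d1 <- fs[fs$task == task & fs$variable == v & fs$visit == "T1",
                 c("subject", "value")]
        d2 <- fs[fs$task == task & fs$variable == v & fs$visit == "T2",
                 c("subject", "value")]
        mg <- merge(d1, d2, by = "subject", suffixes = c("_t1", "_t2"))
        if (nrow(mg) < 3L) next
        if (nrow(mg) >= 4L) {  # the extreme-outlier rule needs quartiles
          keep <- !(mg$value_t1 %in%
                      exclude_extreme_outliers(mg$value_t1)$removed) &
                  !(mg$value_t2 %in%
                      exclude_extreme_outliers(mg$value_t2)$removed)
          mg <- mg[keep, ]
        }
        if (nrow(mg) < 3L) next
        r <- paired_change_test(mg$value_t1, mg$value_t2,
                                m_comparisons = m, alpha = config$alpha)
        pp[[length(pp) + 1L]] <- data.frame(
          system = sys, task = task, variable = v, n = r$n, test = r$test,
          statistic = r$statistic, p = r$p,
          alpha_corrected = r$alpha_corrected,
          alpha_reported = r$alpha_reported, significant = r$significant)
      }
    }
    prepost <- if (length(pp)) do.call(rbind, pp) else NULL
  }

  out <- list(features = features, agreement = agreement, prepost = prepost,
              errors = errors, config = config,
              config_hash = config_hash(config), log = log)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(features, file.path(output_dir, "features.csv"),
                     row.names = FALSE)
    if (!is.null(agreement) && nrow(agreement)) {
      utils::write.csv(agreement, file.path(output_dir, "agreement.csv"),
                       row.names = FALSE)
    }
    if (!is.null(prepost)) {
      utils::write.csv(prepost, file.path(output_dir, "prepost.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(c(unclass(config),
                           list(config_hash = out$config_hash)),
                         file.path(output_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
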