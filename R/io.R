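protocol_fields <- function() names(formals(trial_protocol))

protocol_to_list <- function(p) {
  list(duration_days = p$duration_min %/% 1440,
       duration_hours = (p$duration_min %% 1440) / 60,
       start_time = sprintf("%02d:%02d", p$start_clock %/% 60,
                            p$start_clock %% 60),
       dosing_step = p$dosing_step,
       start_glucose = p$start_glucose,
       start_glucose_sd = p$start_glucose_sd,
       insulin_on_board = if (is.na(p$insulin_on_board)) NULL
                          else p$insulin_on_board,
       meals = lapply(seq_len(nrow(p$meals)),
                      function(i) as.list(p$meals[i, ])),
       carb_error = p$carb_error,
       rescue_threshold = p$rescue_threshold,
       rescue_cho = p$rescue_cho,
       rescue_lockout = p$rescue_lockout,
       arm = p$arm,
       overnight = sprintf("%02d:%02d", p$overnight %/% 60,
                           p$overnight %% 60),
       seed = p$seed)
}

#' Read / write trial protocol files
#'
#' Protocols are stored as YAML (or JSON, by extension). On read the file
#' is validated: unknown keys are an error (nothing is silently ignored),
#' missing keys fall back to the [trial_protocol()] defaults and each
#' defaulted field is reported via `message()`.
#'
#' @param protocol a `trial_protocol`.
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return `read_protocol()` returns a validated `trial_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  x <- protocol_to_list(protocol)
  x <- x[!vapply(x, is.null, logical(1L))]
  if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_protocol
#' @param quiet suppress the defaulted-field messages.
#' @export
read_protocol <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such protocol file: ", path,
                               call. = FALSE)
  x <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  protocol_from_list(x, quiet = quiet)
}

protocol_from_list <- function(x, quiet = FALSE) {
  x <- x[!vapply(x, is.null, logical(1L))]
  known <- protocol_fields()
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown protocol field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(x$meals)) {
    m <- if (is.data.frame(x$meals)) x$meals
         else do.call(rbind, lapply(x$meals, as.data.frame))
    x$meals <- do.call(meal_plan, as.list(m))
  }
  defaulted <- setdiff(known, names(x))
  if (length(defaulted) && !quiet)
    message("protocol defaults applied for: ",
            paste(defaulted, collapse = ", "))
  if (!is.null(x$overnight)) x$overnight <- unlist(x$overnight)
  do.call(trial_protocol, x)
}

#' Canonical trial fixture protocol
#'
#' A 24-h trial starting 08:00 with four meals — breakfast 59 g at 08:00,
#' lunch 70 g at noon, dinner 95 g at 17:00 and a 20 g snack at 21:00 —
#' with day-to-day/patient-to-patient meal variability (SDs matched to the
#' reported interquartile spreads of that scenario), the 0-20%
#' carbohydrate-counting error enabled, starting glucose 7 +/- 1 mmol/L,
#' 10-min dosing steps, and the 3.3 mmol/L / 16 g rescue rule.
#'
#' @param arm treatment arm.
#' @param seed trial seed.
#' @return a [trial_protocol()].
#' @export
fixture_protocol <- function(arm = "open-loop", seed = 1L) {
  trial_protocol(
    duration_days = 1, start_time = "08:00", dosing_step = 10,
    start_glucose = 7, start_glucose_sd = 1,
    meals = meal_plan(time_sd_min = 15,
                      cho_sd_g = c(15, 4, 14, 7)),
    carb_error = TRUE, arm = arm, seed = seed)
}

#' Canonical 15-patient fixture cohort
#'
#' @param seed cohort seed.
#' @return a [sample_cohort()] result with 15 synthetic virtual patients.
#' @export
fixture_cohort <- function(seed = 20201204) {
  sample_cohort(cohort_spec(n_patients = 15, seed = seed))
}

#' Generate the canonical offline fixtures
#'
#' Writes a deterministic 15-patient synthetic cohort (`cohort.json`) and
#' the canonical 24-h four-meal protocol (`protocol.yaml`) into a
#' directory; the same seed always reproduces identical files.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed for the cohort and protocol.
#' @return invisibly, the two file paths.
#' @export
generate_fixtures <- function(dir, seed = 20201204) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort_path <- file.path(dir, "cohort.json")
  protocol_path <- file.path(dir, "protocol.yaml")
  write_patients(fixture_cohort(seed), cohort_path)
  write_protocol(fixture_protocol(seed = seed), protocol_path)
  invisible(c(cohort = cohort_path, protocol = protocol_path))
}

# --- run configuration ------------------------------------------------------

config_fields <- c("cohort", "protocol", "outdir", "arm", "seed", "verbose")

#' Load and validate a run configuration
#'
#' A run config names the cohort file, the protocol (a path or an inline
#' section), the output directory, and optional arm/seed overrides.
#' Unknown keys are an error; defaults are filled and reported.
#'
#' @param path YAML or JSON config file.
#' @param quiet suppress default/field messages.
#' @return a list of class `run_config`.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  x <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(x), config_fields)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(x$cohort)) stop("config must name a cohort file",
                              call. = FALSE)
  if (is.null(x$protocol)) stop("config must give a protocol",
                                call. = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(f) if (file.exists(f)) f else file.path(base, f)
  x$cohort <- resolve(x$cohort)
  if (!file.exists(x$cohort))
    stop("cohort file not found: ", x$cohort, call. = FALSE)
  protocol <- if (is.character(x$protocol)) {
    read_protocol(resolve(x$protocol), quiet = quiet)
  } else protocol_from_list(x$protocol, quiet = quiet)
  if (!is.null(x$arm)) protocol$arm <- match.arg(
    x$arm, c("open-loop", "single-hormone", "dual-hormone"))
  if (!is.null(x$seed)) protocol$seed <- as.integer(x$seed)
  if (is.null(x$outdir)) {
    x$outdir <- "glucosim-output"
    if (!quiet) message("config default applied: outdir = glucosim-output")
  }
  structure(list(cohort = x$cohort, protocol = protocol,
                 outdir = x$outdir, verbose = isTRUE(x$verbose),
                 config_hash = file_hash(path)),
            class = "run_config")
}

file_hash <- function(path) unname(tools::md5sum(path))

object_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  file_hash(tf)
}

stamp_line <- function(seed, hash) {
  sprintf("# glucosim seed=%s config=%s", seed, hash)
}

write_stamped_csv <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp_line(seed, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a patient run's state trace as CSV
#'
#' Tidy trace at the dosing-step grid: `time_min`, the 13 state variables,
#' then derived `Ip`, `Cp`, `G` (`Gs` is a state). A comment header embeds
#' the trial seed and config hash for provenance.
#'
#' @param run a `patient_run`.
#' @param patient the matching `patient_parameters`.
#' @param path output CSV path.
#' @param seed,hash provenance stamp values.
#' @return the path, invisibly.
#' @export
write_run_csv <- function(run, patient, path, seed = NA, hash = NA) {
  df <- data.frame(time_min = run$time, run$states)
  df$Ip <- df$Qi / (patient$Vi * patient$w) * 1e6
  df$Cp <- df$Qg2 / patient$tgmax / (patient$w * patient$MCRg) * 1e6 +
    patient$Cb
  df$G <- df$Q1 / patient$V
  write_stamped_csv(df, path, seed, hash)
}

run_log_records <- function(run) {
  recs <- list()
  add <- function(r) recs[[length(recs) + 1L]] <<- r
  for (i in seq_len(nrow(run$meals)))
    add(list(event = "meal", patient = run$id,
             t = run$meals$time[i], true_cho = run$meals$true_cho[i],
             announced_cho = run$meals$announced_cho[i]))
  for (i in seq_len(nrow(run$rescues)))
    add(list(event = "rescue", patient = run$id,
             t = run$rescues$time[i], cho = run$rescues$cho[i]))
  dt <- diff(run$time)[1L]
  for (k in seq_along(run$insulin)) {
    if (is.na(run$insulin[k])) break
    add(list(event = "dose", patient = run$id, t = (k - 1) * dt,
             insulin_U = run$insulin[k], glucagon_mg = run$glucagon[k]))
  }
  if (run$status != "completed")
    add(list(event = "failure", patient = run$id, status = run$status))
  recs
}

#' Execute a configured trial and write all artifacts
#'
#' Runs the trial described by a [load_config()] result with the reference
#' controller for its arm (or a supplied controller factory), then writes
#' per-patient trace CSVs, the per-patient and cohort report CSVs, the
#' baseline table, a JSON report, and a JSON-lines event log (one record
#' per meal, dose step, rescue and failure) into the output directory.
#' Every artifact embeds the seed and config hash.
#'
#' @param config a `run_config` (or a path to one).
#' @param controller_factory optional override of the arm's reference
#'   controller.
#' @return invisibly, a list with `result` (the [run_trial()] output),
#'   `status` (0 if every patient completed, 1 otherwise), and `files`.
#' @export
run_command <- function(config, controller_factory = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  patients <- read_patients(config$cohort)
  protocol <- config$protocol
  if (!dir.exists(config$outdir))
    dir.create(config$outdir, recursive = TRUE)
  res <- run_trial(patients, protocol,
                   controller_factory = controller_factory)
  seed <- protocol$seed
  hash <- config$config_hash
  files <- character()
  tdir <- file.path(config$outdir, "traces")
  if (!dir.exists(tdir)) dir.create(tdir)
  for (i in seq_along(res$runs)) {
    f <- file.path(tdir, paste0(res$runs[[i]]$id, ".csv"))
    write_run_csv(res$runs[[i]], patients[[i]], f, seed, hash)
    files <- c(files, f)
  }
  rep <- res$report
  f1 <- file.path(config$outdir, "report_cohort.csv")
  write_stamped_csv(rep$cohort, f1, seed, hash)
  f2 <- file.path(config$outdir, "report_patients.csv")
  write_stamped_csv(rep$per_patient, f2, seed, hash)
  f3 <- file.path(config$outdir, "baseline.csv")
  write_stamped_csv(rep$baseline, f3, seed, hash)
  f4 <- file.path(config$outdir, "report.json")
  jsonlite::write_json(
    list(seed = seed, config_hash = hash, arm = protocol$arm,
         statuses = as.list(rep$statuses), cohort = rep$cohort,
         baseline = rep$baseline),
    f4, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  f5 <- file.path(config$outdir, "log.jsonl")
  con <- file(f5, "w")
  for (r in res$runs)
    for (rec in run_log_records(r))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  close(con)
  for (r in res$runs)
    message(sprintf("patient %s: %s", r$id, r$status))
  status <- if (all(rep$statuses == "completed")) 0L else 1L
  invisible(list(result = res, status = status,
                 files = c(files, f1, f2, f3, f4, f5)))
}

#' Recompute outcome metrics from saved trace CSVs
#'
#' Reads the `Gs` column of every per-patient trace written by
#' [run_command()] and recomputes the glucose-based outcome battery and its
#' cohort summary (delivery metrics need the original run and are not
#' recomputed here).
#'
#' @param trace_dir directory of trace CSVs.
#' @return data.frame of cohort summary statistics per metric.
#' @export
report_from_traces <- function(trace_dir) {
  files <- list.files(trace_dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no trace CSVs in ", trace_dir, call. = FALSE)
  per <- lapply(files, function(f) {
    df <- utils::read.csv(f, comment.char = "#")
    metric_battery(glucose_trace(df$time_min, df$Gs))
  })
  metrics <- names(per[[1L]])
  out <- do.call(rbind, lapply(metrics, function(m) {
    v <- vapply(per, `[[`, numeric(1L), m)
    cbind(data.frame(metric = m), summarize_metric(v[!is.na(v)]))
  }))
  rownames(out) <- NULL
  out
}
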