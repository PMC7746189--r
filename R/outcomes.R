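#' Uniformly sampled sensor glucose trace
#'
#' @param times sample times (min), uniformly spaced, >= 2 samples.
#' @param values sensor glucose (mmol/L), finite and positive.
#' @return an object of class `glucose_trace`.
#' @export
glucose_trace <- function(times, values) {
  if (length(times) < 2L || length(times) != length(values))
    stop("a trace needs >= 2 (time, value) samples", call. = FALSE)
  h <- diff(times)
  if (any(abs(h - h[1L]) > 1e-9 * max(h[1L], 1)))
    stop("trace sampling must be uniform", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("trace values must be finite and > 0", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 interval = h[1L]), class = "glucose_trace")
}

#' Percent time in a glucose range
#'
#' Each sample is attributed to one sampling interval, so the result is
#' 100 times the fraction of samples with `lo <= Gs <= hi`. Together with
#' strict `<`/`>` attribution for time below/above, the three bands of a
#' two-sided partition sum to exactly 100.
#'
#' @param trace a [glucose_trace()].
#' @param lo,hi range bounds (mmol/L), `lo < hi`.
#' @return percent of time in `[lo, hi]`.
#' @export
time_in_range <- function(trace, lo, hi) {
  stopifnot(inherits(trace, "glucose_trace"), lo < hi)
  100 * mean(trace$values >= lo & trace$values <= hi)
}

#' Percent time below or above a threshold
#'
#' @param trace a [glucose_trace()].
#' @param threshold glucose threshold (mmol/L), > 0.
#' @param side `"below"` (strict `<`) or `"above"` (strict `>`).
#' @return percent of time outside the threshold.
#' @export
time_outside <- function(trace, threshold, side = c("below", "above")) {
  side <- match.arg(side)
  stopifnot(inherits(trace, "glucose_trace"), threshold > 0)
  100 * mean(if (side == "below") trace$values < threshold
             else trace$values > threshold)
}

#' Area under/over a glucose threshold
#'
#' Trapezoidal integral of the excursion beyond the threshold, treating the
#' trace as piecewise linear between samples with exact interpolation of
#' threshold crossings (a segment crossing the threshold contributes its
#' triangle, not a clamped trapezoid).
#'
#' @param trace a [glucose_trace()].
#' @param threshold glucose threshold (mmol/L), > 0.
#' @param side `"below"` integrates `max(0, threshold - Gs)`, `"above"`
#'   integrates `max(0, Gs - threshold)`.
#' @return area in mmol/L x min.
#' @export
auc_outside <- function(trace, threshold, side = c("below", "above")) {
  side <- match.arg(side)
  stopifnot(inherits(trace, "glucose_trace"), threshold > 0)
  v <- trace$values
  # signed depth of the excursion at each sample
  dpt <- if (side == "below") threshold - v else v - threshold
  a <- dpt[-length(dpt)]
  b <- dpt[-1L]
  h <- trace$interval
  seg <- ifelse(a <= 0 & b <= 0, 0,
         ifelse(a >= 0 & b >= 0, (a + b) / 2 * h,
                pmax(a, b)^2 / (pmax(a, b) - pmin(a, b)) * h / 2))
  sum(seg)
}

#' Count excursions beyond a threshold with hysteresis
#'
#' Counts maximal excursions below (or above) a threshold; after an
#' excursion starts, a new one is only counted once the trace has first
#' recovered beyond `threshold + hysteresis` (below) or
#' `threshold - hysteresis` (above), so a single clinical event dithering
#' around the threshold is not counted repeatedly.
#'
#' @param trace a [glucose_trace()].
#' @param threshold glucose threshold (mmol/L), > 0.
#' @param hysteresis recovery band (mmol/L).
#' @param side `"below"` or `"above"`.
#' @return integer event count.
#' @export
count_events <- function(trace, threshold, hysteresis = 0.6,
                         side = c("below", "above")) {
  side <- match.arg(side)
  stopifnot(inherits(trace, "glucose_trace"), threshold > 0,
            hysteresis >= 0)
  v <- if (side == "below") -trace$values else trace$values
  thr <- if (side == "below") -threshold else threshold
  rec <- if (side == "below") -(threshold + hysteresis)
         else threshold - hysteresis
  armed <- TRUE
  n <- 0L
  for (x in v) {
    if (armed && x > thr) { n <- n + 1L; armed <- FALSE }
    else if (!armed && x < rec) armed <- TRUE
  }
  n
}

#' Cohort summary statistics for one metric
#'
#' @param values per-patient metric values (length >= 1).
#' @return one-row data.frame with `median`, `q25`, `q75`, `mean`, `sd`.
#' @export
summarize_metric <- function(values) {
  stopifnot(length(values) >= 1)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE,
                       na.rm = TRUE)
  s <- stats::sd(values)
  data.frame(median = q[2L], q25 = q[1L], q75 = q[3L],
             mean = mean(values), sd = if (is.na(s)) 0 else s)
}

# split a run's samples into the protocol's overnight clock window;
# returns a list of contiguous glucose_trace blocks (one per night)
nocturnal_blocks <- function(times, values, protocol) {
  clock <- (times + protocol$start_clock) %% 1440
  w <- protocol$overnight
  inw <- if (w[1L] <= w[2L]) clock >= w[1L] & clock < w[2L]
         else clock >= w[1L] | clock < w[2L]
  r <- rle(inw)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  blocks <- list()
  for (j in seq_along(r$values)) {
    if (r$values[j] && r$lengths[j] >= 2L)
      blocks[[length(blocks) + 1L]] <-
        glucose_trace(times[starts[j]:ends[j]], values[starts[j]:ends[j]])
  }
  blocks
}

# the full metric battery on one trace (plus delivery totals supplied)
metric_battery <- function(trace) {
  c(time_in_4_8    = time_in_range(trace, 4, 8),
    time_in_4_10   = time_in_range(trace, 4, 10),
    time_below_4   = time_outside(trace, 4, "below"),
    time_below_3.5 = time_outside(trace, 3.5, "below"),
    time_below_3.3 = time_outside(trace, 3.3, "below"),
    time_below_3.1 = time_outside(trace, 3.1, "below"),
    auc_below_4    = auc_outside(trace, 4, "below"),
    auc_below_3.5  = auc_outside(trace, 3.5, "below"),
    auc_below_3.1  = auc_outside(trace, 3.1, "below"),
    hypo_events    = count_events(trace, 3.3, 0.6, "below"),
    time_above_8   = time_outside(trace, 8, "above"),
    time_above_10  = time_outside(trace, 10, "above"),
    auc_above_8    = auc_outside(trace, 8, "above"),
    auc_above_10   = auc_outside(trace, 10, "above"),
    hyper_events   = count_events(trace, 10, 0.6, "above"),
    mean_glucose   = mean(trace$values),
    sd_glucose     = stats::sd(trace$values))
}

#' Per-patient clinical outcomes of a trial run
#'
#' The full outcome battery on the run's sensor glucose trace: time in the
#' 4-8 and 4-10 mmol/L targets; hypoglycemia exposure (% time below 4, 3.5,
#' 3.3 and 3.1 mmol/L and AUC below 4, 3.5, 3.1), hypoglycemia incidence
#' (excursions below 3.3 mmol/L with a 0.6 mmol/L recovery hysteresis);
#' hyperglycemia exposure and incidence (above 8 and 10 mmol/L); mean and
#' SD of sensor glucose; insulin delivery in U/h and U/kg/day; glucagon
#' delivery in mg; and the number of rescue-carbohydrate doses. The same
#' battery is repeated on the protocol's overnight clock window with a
#' `nocturnal_` prefix.
#'
#' @param run a `patient_run` from [run_trial()].
#' @param patient the matching `patient_parameters`.
#' @param protocol the `trial_protocol`.
#' @return named numeric vector of metrics (NA-filled for failed runs).
#' @export
patient_outcomes <- function(run, patient, protocol) {
  noct_names <- c("time_in_4_8", "time_in_4_10", "time_below_4",
                  "time_below_3.3", "auc_below_4", "hypo_events",
                  "mean_glucose")
  if (run$status != "completed" || anyNA(run$Gs)) {
    base <- metric_battery(glucose_trace(c(0, 5), c(5, 5)))
    out <- c(base, insulin_U_per_h = NA_real_,
             insulin_U_per_kg_day = NA_real_, glucagon_mg = NA_real_,
             rescue_doses = NA_real_)
    out[] <- NA_real_
    noct <- stats::setNames(rep(NA_real_, length(noct_names)),
                            paste0("nocturnal_", noct_names))
    return(c(out, noct))
  }
  trace <- glucose_trace(run$time, run$Gs)
  hours <- protocol$duration_min / 60
  out <- c(metric_battery(trace),
           insulin_U_per_h = sum(run$insulin) / hours,
           insulin_U_per_kg_day =
             sum(run$insulin) / patient$w / (hours / 24),
           glucagon_mg = sum(run$glucagon),
           rescue_doses = nrow(run$rescues))

  blocks <- nocturnal_blocks(run$time, run$Gs, protocol)
  noct <- if (length(blocks)) {
    vals <- unlist(lapply(blocks, function(b) b$values))
    c(time_in_4_8 = 100 * mean(vals >= 4 & vals <= 8),
      time_in_4_10 = 100 * mean(vals >= 4 & vals <= 10),
      time_below_4 = 100 * mean(vals < 4),
      time_below_3.3 = 100 * mean(vals < 3.3),
      auc_below_4 = sum(vapply(blocks, auc_outside, numeric(1L),
                               threshold = 4, side = "below")),
      hypo_events = sum(vapply(blocks, count_events, numeric(1L),
                               threshold = 3.3, hysteresis = 0.6,
                               side = "below")),
      mean_glucose = mean(vals))
  } else {
    stats::setNames(rep(NA_real_, length(noct_names)), noct_names)
  }
  names(noct) <- paste0("nocturnal_", names(noct))
  c(out, noct)
}

#' Trial outcome report
#'
#' Aggregates per-patient outcomes across the cohort: for every metric the
#' cohort median, interquartile range, mean and SD over completed runs,
#' alongside the per-patient long table, the baseline-characteristics
#' table, and per-patient completion statuses.
#'
#' @param runs list of `patient_run` objects.
#' @param patients list of `patient_parameters` (same order as `runs`).
#' @param protocol the `trial_protocol`.
#' @return an object of class `trial_report` with elements `per_patient`
#'   (long data.frame: patient, status, metric, value), `cohort`
#'   (data.frame: metric, median, q25, q75, mean, sd, n), `baseline`, and
#'   `statuses`.
#' @export
trial_report <- function(runs, patients, protocol) {
  stopifnot(length(runs) == length(patients))
  per <- lapply(seq_along(runs), function(i)
    patient_outcomes(runs[[i]], patients[[i]], protocol))
  metrics <- names(per[[1L]])
  long <- do.call(rbind, lapply(seq_along(per), function(i) {
    data.frame(patient = runs[[i]]$id, status = runs[[i]]$status,
               metric = metrics, value = unname(per[[i]]))
  }))
  completed <- vapply(runs, function(r) r$status == "completed",
                      logical(1L))
  cohort_tab <- do.call(rbind, lapply(metrics, function(m) {
    v <- vapply(which(completed), function(i) per[[i]][[m]], numeric(1L))
    v <- v[!is.na(v)]
    if (!length(v))
      return(data.frame(metric = m, median = NA_real_, q25 = NA_real_,
                        q75 = NA_real_, mean = NA_real_, sd = NA_real_,
                        n = 0L))
    cbind(data.frame(metric = m), summarize_metric(v),
          data.frame(n = length(v)))
  }))
  rownames(cohort_tab) <- NULL
  structure(list(per_patient = long, cohort = cohort_tab,
                 baseline = baseline_characteristics(patients),
                 statuses = stats::setNames(
                   vapply(runs, `[[`, character(1L), "status"),
                   vapply(runs, `[[`, character(1L), "id")),
                 arm = protocol$arm),
            class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat(sprintf("<trial_report> %s arm, %d patients (%d completed)\n",
              x$arm, length(x$statuses),
              sum(x$statuses == "completed")))
  key <- c("time_in_4_8", "time_in_4_10", "time_below_4", "time_above_10",
           "mean_glucose", "sd_glucose", "insulin_U_per_h", "glucagon_mg",
           "hypo_events")
  tab <- x$cohort[x$cohort$metric %in% key, ]
  print(format(tab, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Extract one cohort-level statistic from a report
#'
#' @param report a [trial_report()].
#' @param metric metric name (row of `report$cohort`).
#' @param stat one of `"median"`, `"q25"`, `"q75"`, `"mean"`, `"sd"`.
#' @return scalar value.
#' @export
report_value <- function(report, metric, stat = "mean") {
  row <- report$cohort[report$cohort$metric == metric, ]
  if (!nrow(row)) stop("unknown metric: ", metric, call. = FALSE)
  row[[stat]]
}
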