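#' Meal plan table
#'
#' One row per configured daily meal. Times are clock times in minutes from
#' midnight; variabilities are SDs applied independently per patient and
#' day.
#'
#' @param name meal labels.
#' @param time_min clock times (min from midnight).
#' @param cho_g carbohydrate amounts (g).
#' @param time_sd_min SD of the meal-time perturbation (min).
#' @param cho_sd_g SD of the amount perturbation (g).
#' @return data.frame meal plan.
#' @export
meal_plan <- function(name = c("breakfast", "lunch", "dinner", "snack"),
                      time_min = c(480, 720, 1020, 1260),
                      cho_g = c(59, 70, 95, 20),
                      time_sd_min = 0, cho_sd_g = 0) {
  df <- data.frame(name = name, time_min = time_min, cho_g = cho_g,
                   time_sd_min = rep_len(time_sd_min, length(name)),
                   cho_sd_g = rep_len(cho_sd_g, length(name)))
  if (any(df$cho_g < 0) || any(df$time_sd_min < 0) || any(df$cho_sd_g < 0))
    stop("meal amounts and variabilities must be >= 0", call. = FALSE)
  if (any(df$time_min < 0 | df$time_min >= 1440))
    stop("meal clock times must be in [0, 1440)", call. = FALSE)
  df
}

parse_clock <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(x, ":", fixed = TRUE)[[1L]]
  as.numeric(parts[1L]) * 60 + as.numeric(parts[2L])
}

#' Trial protocol
#'
#' The machine-readable experiment design: duration, start clock time,
#' dosing step, starting-glucose level and variability, insulin on board,
#' the meal plan with its variabilities, the carbohydrate-counting-error
#' toggle, the rescue-carbohydrate rule, the treatment arm, and the RNG
#' seed that makes every stochastic element of the trial reproducible.
#'
#' @param duration_days,duration_hours trial length (total must be > 0).
#' @param start_time trial start clock time, `"HH:MM"` or minutes from
#'   midnight.
#' @param dosing_step controller dosing time step (min, >= 1).
#' @param start_glucose starting plasma glucose (mmol/L).
#' @param start_glucose_sd SD of the per-patient starting-glucose draw.
#' @param insulin_on_board insulin on board at trial start (U), or `NA` to
#'   preload each patient at their own titrated basal steady state.
#' @param meals a [meal_plan()].
#' @param carb_error enable the 0-20% carbohydrate counting error: the
#'   announced meal size is the true size times `1 + e`, `e` uniform on
#'   `[-0.2, 0.2]`.
#' @param rescue_threshold sensor glucose (mmol/L) below which rescue
#'   carbohydrates are given.
#' @param rescue_cho rescue carbohydrate dose (g), unannounced to the
#'   controller.
#' @param rescue_lockout minimum time (min) between rescue doses.
#' @param arm `"open-loop"`, `"single-hormone"` or `"dual-hormone"`.
#' @param overnight overnight reporting window as `c(start, end)` clock
#'   times (`"HH:MM"` or minutes), spanning midnight.
#' @param seed trial RNG seed (drives schedules, starting glucose, and
#'   day-to-day flux variability through per-patient streams).
#' @return an object of class `trial_protocol`.
#' @export
trial_protocol <- function(duration_days = 1, duration_hours = 0,
                           start_time = "08:00", dosing_step = 10,
                           start_glucose = 7, start_glucose_sd = 0,
                           insulin_on_board = NA_real_,
                           meals = meal_plan(), carb_error = FALSE,
                           rescue_threshold = 3.3, rescue_cho = 16,
                           rescue_lockout = 15,
                           arm = c("open-loop", "single-hormone",
                                   "dual-hormone"),
                           overnight = c("23:00", "07:00"),
                           seed = 1L) {
  arm <- match.arg(arm)
  duration_min <- duration_days * 1440 + duration_hours * 60
  if (duration_min <= 0) stop("trial duration must be > 0", call. = FALSE)
  if (dosing_step < 1) stop("dosing step must be >= 1 min", call. = FALSE)
  if (start_glucose_sd < 0 || rescue_threshold <= 0 || rescue_cho < 0 ||
      rescue_lockout < 0)
    stop("protocol variabilities and rescue settings must be >= 0",
         call. = FALSE)
  structure(list(
    duration_min = duration_min,
    start_clock = parse_clock(start_time),
    dosing_step = dosing_step,
    start_glucose = start_glucose, start_glucose_sd = start_glucose_sd,
    insulin_on_board = insulin_on_board,
    meals = meals, carb_error = isTRUE(carb_error),
    rescue_threshold = rescue_threshold, rescue_cho = rescue_cho,
    rescue_lockout = rescue_lockout, arm = arm,
    overnight = vapply(overnight, parse_clock, numeric(1L),
                       USE.NAMES = FALSE),
    seed = as.integer(seed)), class = "trial_protocol")
}

#' @export
print.trial_protocol <- function(x, ...) {
  cat(sprintf(
    "<trial_protocol> %s arm, %.1f h from %02d:%02d, %g-min steps, %d meals/day%s\n",
    x$arm, x$duration_min / 60, x$start_clock %/% 60, x$start_clock %% 60,
    x$dosing_step, nrow(x$meals),
    if (x$carb_error) ", carb-counting error on" else ""))
  invisible(x)
}

#' Build a perturbed per-day meal schedule for one patient
#'
#' Perturbs each configured meal's time and amount by the protocol's
#' variabilities using the current RNG stream (the trial engine seeds a
#' separate stream per patient), applies the carbohydrate counting error to
#' the announced amount when enabled, and converts clock times to minutes
#' from trial start. A perturbed time falling outside its day is redrawn a
#' bounded number of times, then clamped; clamped events are flagged.
#'
#' @param protocol a [trial_protocol()].
#' @param patient_index patient identifier (cohort position or id string),
#'   recorded in the schedule's `patient` column.
#' @return data.frame with columns `patient`, `day`, `name`, `time`
#'   (min from trial start), `true_cho`, `announced_cho`, `clamped`.
#' @export
build_schedule <- function(protocol, patient_index = 1L) {
  n_days <- ceiling(protocol$duration_min / 1440)
  rows <- list()
  for (day in seq_len(n_days)) {
    for (j in seq_len(nrow(protocol$meals))) {
      m <- protocol$meals[j, ]
      # offset of the nominal mealtime within this trial day
      base <- (m$time_min - protocol$start_clock) %% 1440
      off <- base
      clamped <- FALSE
      if (m$time_sd_min > 0) {
        ok <- FALSE
        for (try in 1:20) {
          off <- base + stats::rnorm(1L, 0, m$time_sd_min)
          if (off >= 0 && off < 1440) { ok <- TRUE; break }
        }
        if (!ok) { off <- min(max(off, 0), 1439); clamped <- TRUE }
      }
      cho <- m$cho_g
      if (m$cho_sd_g > 0) cho <- cho + stats::rnorm(1L, 0, m$cho_sd_g)
      cho <- max(cho, 1)
      ann <- cho   # announced equals true unless carb counting errs
      if (protocol$carb_error) {
        eps <- stats::runif(1L, -0.2, 0.2)
        # round to 1 g but keep the error inside the 0-20% envelope
        ann <- round(cho * (1 + eps))
        ann <- min(max(ann, ceiling(0.8 * cho), 0), floor(1.2 * cho))
      }
      t <- (day - 1) * 1440 + off
      if (t >= protocol$duration_min) next
      rows[[length(rows) + 1L]] <- data.frame(
        patient = patient_index, day = day, name = m$name, time = t,
        true_cho = cho, announced_cho = ann, clamped = clamped)
    }
  }
  if (!length(rows))
    return(data.frame(patient = integer(), day = integer(),
                      name = character(), time = numeric(),
                      true_cho = numeric(), announced_cho = numeric(),
                      clamped = logical()))
  out <- do.call(rbind, rows)
  out[order(out$time), , drop = FALSE]
}
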