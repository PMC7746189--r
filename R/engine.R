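# deterministic per-patient RNG stream seed, keyed by the trial seed and a
# stable hash of the patient id so runs do not depend on execution order;
# kept below 2^31 (R integers are 32-bit)
patient_seed <- function(seed, id) {
  h <- 0
  for (code in utf8ToInt(id)) h <- (h * 31 + code) %% 2147483647
  as.integer((as.double(seed %% 2147483647L) * 48271 + h) %% 2147483647)
}

# one day's flux variant: every knot value scaled by a fresh log-normal
# multiplier drawn from the patient's own day-to-day dispersion
day_flux_variant <- function(p) {
  if (p$flux_day_cv <= 0) return(p)
  jitter <- function(fl) {
    diurnal_flux(fl$times,
                 fl$values * exp(stats::rnorm(length(fl$values), 0,
                                              p$flux_day_cv)))
  }
  p$Im <- jitter(p$Im); p$fm <- jitter(p$fm); p$Fg <- jitter(p$Fg)
  p
}

#' Initial model state for a trial run
#'
#' Sets plasma and sensor glucose to the (possibly noise-perturbed)
#' starting level, preloads the subcutaneous and plasma insulin
#' compartments at the steady state of a basal rate — the patient's own
#' titrated basal, or, when the protocol specifies insulin on board, the
#' rate whose steady-state depot mass equals that IOB — and places the
#' remote-effect and non-accessible glucose compartments at their
#' conditional steady states. Glucagon compartments start empty.
#'
#' @param patient a `patient_parameters` object.
#' @param protocol a `trial_protocol`.
#' @param g0 starting glucose (mmol/L); when `NULL`, drawn from the
#'   protocol's starting level and SD using the current RNG stream
#'   (redrawn while non-positive).
#' @return a [model_state()].
#' @export
init_state <- function(patient, protocol, g0 = NULL) {
  if (is.null(g0)) {
    repeat {
      g0 <- protocol$start_glucose +
        stats::rnorm(1L, 0, protocol$start_glucose_sd)
      if (g0 > 0) break
    }
  }
  p <- patient
  iob <- protocol$insulin_on_board
  u <- if (is.na(iob)) {
    p$basal_rate
  } else {
    # steady-state subcutaneous depot mass per unit infusion rate
    depot <- p$pi * (1 / p$kis1 + 1 / p$kis2) + (1 - p$pi) * 2 / p$kif
    iob / depot
  }
  im0 <- flux_at(p$Im, protocol$start_clock)
  qi <- (u * im0 + p$ci) / p$ke
  ip <- qi / (p$Vi * p$w) * 1e6
  q1 <- g0 * p$V
  stx <- ip * p$St * 1e-4
  sdx <- ip * p$Sd * 1e-4
  q2 <- if (stx > 0) stx * q1 / (p$k12 + sdx) else 0
  model_state(
    Qis1 = u * p$pi / p$kis1, Qis2 = u * p$pi / p$kis2,
    Qif1 = u * (1 - p$pi) / p$kif, Qif2 = u * (1 - p$pi) / p$kif,
    Qi = qi, x1 = ip, x2 = ip, x3 = ip,
    Q1 = q1, Q2 = q2, Gs = g0)
}

#' Rescue carbohydrate rule
#'
#' Called once per dosing step: when sensor glucose is below the rescue
#' threshold and the previous rescue is outside the lockout window, emits a
#' rescue carbohydrate event (unannounced to the controller).
#'
#' @param gs current sensor glucose (mmol/L).
#' @param t current time (min from trial start).
#' @param last_rescue time of the previous rescue (`-Inf` if none).
#' @param protocol a `trial_protocol`.
#' @return `NULL`, or `list(time, cho)` for the rescue event.
#' @export
apply_rescue <- function(gs, t, last_rescue, protocol) {
  if (gs < protocol$rescue_threshold &&
      t - last_rescue >= protocol$rescue_lockout)
    list(time = t, cho = protocol$rescue_cho)
  else NULL
}

run_one_patient <- function(patient, protocol, controller_factory,
                            rtol, atol) {
  dt <- protocol$dosing_step
  n_steps <- ceiling(protocol$duration_min / dt)
  n_days <- ceiling(protocol$duration_min / 1440)
  seed_i <- patient_seed(protocol$seed, patient$id)

  # all of this patient's randomness is drawn up front from one stream,
  # so runs are identical regardless of cohort execution order
  drawn <- local_seed(seed_i, {
    sched <- build_schedule(protocol, patient$id)
    g0 <- NULL
    repeat {
      g0 <- protocol$start_glucose +
        stats::rnorm(1L, 0, protocol$start_glucose_sd)
      if (g0 > 0) break
    }
    day_p <- lapply(seq_len(n_days), function(d) day_flux_variant(patient))
    list(sched = sched, g0 = g0, day_p = day_p)
  })
  sched <- drawn$sched

  state <- init_state(patient, protocol, g0 = drawn$g0)
  states <- matrix(NA_real_, n_steps + 1L, 13L,
                   dimnames = list(NULL, STATE_NAMES))
  states[1L, ] <- state
  insulin <- rep(NA_real_, n_steps)
  glucagon <- rep(NA_real_, n_steps)
  announced <- numeric(n_steps)
  rescues <- list()
  last_rescue <- -Inf
  status <- "completed"

  ctrl <- NULL
  setup <- list(start_glucose = unname(state[["Gs"]]), dosing_step = dt,
                insulin_on_board = protocol$insulin_on_board,
                arm = protocol$arm)
  ok <- tryCatch({
    ctrl <- controller_factory(patient, protocol)
    stopifnot(inherits(ctrl, "controller"))
    ctrl$init(setup)
    TRUE
  }, error = function(e) {
    status <<- sprintf("controller-failed at t=0 (%s)",
                       conditionMessage(e))
    FALSE
  })

  meals_active <- sched[, c("time", "true_cho")]
  names(meals_active) <- c("time", "cho")

  if (ok) for (k in seq_len(n_steps)) {
    t0 <- (k - 1L) * dt
    t1 <- min(t0 + dt, protocol$duration_min)
    gs <- unname(state[["Gs"]])

    resc <- apply_rescue(gs, t0, last_rescue, protocol)
    if (!is.null(resc)) {
      last_rescue <- t0
      rescues[[length(rescues) + 1L]] <- as.data.frame(resc)
      meals_active <- rbind(meals_active,
                            data.frame(time = resc$time, cho = resc$cho))
    }
    announced[k] <- sum(sched$announced_cho[sched$time >= t0 &
                                              sched$time < t1])

    dose <- tryCatch(ctrl$step(gs, announced[k], t0), error = function(e) e)
    bad <- inherits(dose, "error") ||
      !is.list(dose) || is.null(dose$insulin) || is.null(dose$glucagon) ||
      !is.finite(dose$insulin) || !is.finite(dose$glucagon) ||
      dose$insulin < 0 || dose$glucagon < 0
    if (bad) {
      msg <- if (inherits(dose, "error")) conditionMessage(dose)
             else "invalid dose (negative or non-finite)"
      status <- sprintf("controller-failed at t=%g (%s)", t0, msg)
      break
    }
    gl <- if (protocol$arm == "dual-hormone") dose$glucagon else 0
    insulin[k] <- dose$insulin
    glucagon[k] <- gl

    day <- min((t0 %/% 1440) + 1L, n_days)
    inputs <- exogenous_inputs(
      ui = dose$insulin / (t1 - t0), ug = gl / (t1 - t0),
      meals = meals_active[meals_active$time < t1, , drop = FALSE],
      clock_offset = protocol$start_clock)
    state <- integrate_model(state, drawn$day_p[[day]], inputs, t0, t1,
                             rtol = rtol, atol = atol)
    states[k + 1L, ] <- state
  }

  rescues <- if (length(rescues)) do.call(rbind, rescues)
             else data.frame(time = numeric(), cho = numeric())
  structure(list(
    id = patient$id,
    time = seq(0L, n_steps) * dt,
    states = states,
    Gs = states[, "Gs"], G = states[, "Q1"] / patient$V,
    insulin = insulin, glucagon = glucagon,
    announced = announced, meals = sched, rescues = rescues,
    status = status, seed = seed_i), class = "patient_run")
}

#' @export
print.patient_run <- function(x, ...) {
  cat(sprintf("<patient_run> %s: %s, %d steps, %d meals, %d rescues\n",
              x$id, x$status, length(x$insulin), nrow(x$meals),
              nrow(x$rescues)))
  invisible(x)
}

#' Run a virtual clinical trial
#'
#' Simulates every patient in the cohort under the protocol: builds the
#' patient's perturbed meal schedule, initializes the model state, then
#' alternates controller dosing steps with ODE integration across each
#' dosing interval, applying rescue carbohydrates when sensor glucose falls
#' below the protocol threshold. Each patient draws all randomness from a
#' private stream keyed by the protocol seed and patient index, so the
#' trial is reproducible and independent of execution order. A controller
#' exception (or an invalid dose) marks only that patient's run as failed;
#' all other patients complete — fault isolation mirrors a platform in
#' which algorithm crashes never disrupt the trial.
#'
#' @param cohort a [sample_cohort()] result or list of `patient_parameters`.
#' @param protocol a [trial_protocol()].
#' @param controller_factory function `(patient, protocol) -> controller`;
#'   defaults to the reference controller for the protocol arm.
#' @param rtol,atol solver tolerances passed to [integrate_model()].
#' @return an object of class `trial_result`: list with `runs` (one
#'   `patient_run` per patient), `report` (a [trial_report()]), `protocol`,
#'   and `cohort`.
#' @export
run_trial <- function(cohort, protocol,
                      controller_factory = NULL,
                      rtol = 1e-8, atol = 1e-10) {
  patients <- if (inherits(cohort, "cohort")) cohort$patients else cohort
  if (!length(patients)) stop("empty cohort", call. = FALSE)
  if (is.null(controller_factory))
    controller_factory <- reference_controller_factory(protocol$arm)
  ids <- vapply(patients, `[[`, character(1L), "id")
  if (anyDuplicated(ids))
    stop("cohort patient ids must be unique", call. = FALSE)
  runs <- lapply(patients, function(p) {
    run_one_patient(p, protocol, controller_factory, rtol, atol)
  })
  report <- trial_report(runs, patients, protocol)
  structure(list(runs = runs, report = report, protocol = protocol,
                 cohort = patients), class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  ok <- sum(vapply(x$runs, function(r) r$status == "completed", logical(1L)))
  cat(sprintf("<trial_result> %s arm: %d/%d patients completed\n",
              x$protocol$arm, ok, length(x$runs)))
  print(x$report)
  invisible(x)
}
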