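#' The two-method controller contract
#'
#' A dosing algorithm plugs into the trial engine by implementing two
#' methods. `init(setup)` is called once before the trial with the
#' patient-visible setup: `start_glucose` (mmol/L), `dosing_step` (min),
#' `insulin_on_board` (U or `NA`), and `arm`. `step(gs, meal_cho, t)` is
#' then called repeatedly, once per dosing step, with the current sensor
#' glucose (mmol/L), the announced carbohydrate content of any meal falling
#' in this step (g; 0 otherwise), and the step's start time (min from trial
#' start); it must return `list(insulin = <U over the step>,
#' glucagon = <mg over the step>)`, both finite and non-negative. The engine
#' spreads returned doses as constant infusion rates across the step.
#' Controllers keep their own state (closures are the natural R idiom);
#' exceptions raised inside either method fail only that patient's run.
#'
#' @param init function of one argument (the setup list).
#' @param step function of `(gs, meal_cho, t)` returning the dose list.
#' @return an object of class `controller`.
#' @export
controller <- function(init, step) {
  stopifnot(is.function(init), is.function(step))
  structure(list(init = init, step = step), class = "controller")
}

#' Reference open-loop controller (conventional pump therapy)
#'
#' Delivers the patient's constant basal rate plus a meal bolus of
#' `announced CHO / ICR` units at announced mealtimes; never doses glucagon.
#' This is the comparator arm a closed-loop algorithm is judged against.
#'
#' @param patient a `patient_parameters` object (supplies `basal_rate` in
#'   U/min and `icr` in g/U).
#' @param protocol a `trial_protocol` (unused beyond the contract).
#' @return a [controller()].
#' @export
open_loop_controller <- function(patient, protocol) {
  if (is.null(patient$basal_rate) || is.null(patient$icr) ||
      !is.finite(patient$basal_rate) || !is.finite(patient$icr))
    stop(sprintf("patient '%s' lacks a basal rate or ICR for open loop",
                 patient$id), call. = FALSE)
  basal <- patient$basal_rate
  icr <- patient$icr
  dt <- NULL
  controller(
    init = function(setup) dt <<- setup$dosing_step,
    step = function(gs, meal_cho, t) {
      bolus <- if (meal_cho > 0) meal_cho / icr else 0
      list(insulin = basal * dt + bolus, glucagon = 0)
    })
}

# shared insulin logic of the reference closed-loop arms: meal boluses plus
# glucose-responsive basal modulation (suspend on lows, mild step-up on highs)
modulated_insulin <- function(gs, meal_cho, basal, icr, dt) {
  mult <- if (gs < 4.5) 0 else if (gs < 6) 0.5 else if (gs > 10) 1.5 else 1
  bolus <- if (meal_cho > 0) meal_cho / icr else 0
  basal * mult * dt + bolus
}

#' Reference single-hormone closed-loop controller
#'
#' Meal boluses by the patient's ICR plus glucose-responsive basal
#' modulation: basal is suspended below 4.5 mmol/L, halved below 6 mmol/L,
#' and increased by 50% above 10 mmol/L. No glucagon.
#'
#' @inheritParams open_loop_controller
#' @return a [controller()].
#' @export
single_hormone_controller <- function(patient, protocol) {
  basal <- patient$basal_rate
  icr <- patient$icr
  dt <- NULL
  controller(
    init = function(setup) dt <<- setup$dosing_step,
    step = function(gs, meal_cho, t) {
      list(insulin = modulated_insulin(gs, meal_cho, basal, icr, dt),
           glucagon = 0)
    })
}

#' Reference dual-hormone closed-loop controller
#'
#' The single-hormone insulin logic plus a glucagon-on-low rule: a 0.02 mg
#' glucagon mini-bolus when sensor glucose falls below 4.8 mmol/L, with a
#' 60-min lockout between boluses.
#'
#' @inheritParams open_loop_controller
#' @param glucagon_bolus mini-bolus size (mg).
#' @param glucagon_threshold sensor glucose (mmol/L) triggering a bolus.
#' @param glucagon_lockout minimum time (min) between boluses.
#' @return a [controller()].
#' @export
dual_hormone_controller <- function(patient, protocol,
                                    glucagon_bolus = 0.02,
                                    glucagon_threshold = 4.8,
                                    glucagon_lockout = 60) {
  basal <- patient$basal_rate
  icr <- patient$icr
  dt <- NULL
  last_glucagon <- -Inf
  controller(
    init = function(setup) { dt <<- setup$dosing_step
                             last_glucagon <<- -Inf },
    step = function(gs, meal_cho, t) {
      gl <- 0
      if (gs < glucagon_threshold && t - last_glucagon >= glucagon_lockout) {
        gl <- glucagon_bolus
        last_glucagon <<- t
      }
      list(insulin = modulated_insulin(gs, meal_cho, basal, icr, dt),
           glucagon = gl)
    })
}

#' Controller factory for a protocol's treatment arm
#'
#' Maps the protocol arm to the matching reference controller factory.
#'
#' @param arm `"open-loop"`, `"single-hormone"` or `"dual-hormone"`.
#' @return a function `(patient, protocol) -> controller`.
#' @export
reference_controller_factory <- function(arm) {
  switch(arm,
         "open-loop" = open_loop_controller,
         "single-hormone" = single_hormone_controller,
         "dual-hormone" = dual_hormone_controller,
         stop("unknown arm: ", arm, call. = FALSE))
}
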