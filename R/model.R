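#' @keywords internal
"_PACKAGE"

# State layout of the 13-variable glucoregulatory model:
#   Qis1, Qis2  slow-channel subcutaneous insulin masses (U)
#   Qif1, Qif2  fast-channel subcutaneous insulin masses (U)
#   Qi          plasma insulin mass (U)
#   x1, x2, x3  remote insulin effects on glucose distribution, disposal,
#               and endogenous glucose production (mU/L scale)
#   Qg1, Qg2    subcutaneous glucagon masses (units; 1 mg dose = 1 unit)
#   Q1, Q2      accessible / non-accessible glucose masses (micromol/kg)
#   Gs          interstitial (sensor) glucose (mmol/L)
STATE_NAMES <- c("Qis1", "Qis2", "Qif1", "Qif2", "Qi",
                 "x1", "x2", "x3", "Qg1", "Qg2", "Q1", "Q2", "Gs")

# micromol of glucose per gram of carbohydrate (1 g / 180.16 g/mol)
UMOL_PER_G <- 5551

# saturation constant (micromol/kg) of the non-insulin-dependent
# glucose utilization term F01 * (Q1/160) / (1 + Q1/160)
GLUC_SAT <- 160

#' Construct a model state vector
#'
#' @param ... named state components (unnamed components default to 0); see
#'   the state layout in the package documentation. All components must be
#'   non-negative and finite.
#' @return named numeric vector of length 13 with class `model_state`.
#' @examples
#' model_state(Q1 = 7 * 160, Gs = 7)
#' @export
model_state <- function(...) {
  y <- stats::setNames(numeric(13L), STATE_NAMES)
  args <- list(...)
  if (length(args)) {
    unknown <- setdiff(names(args), STATE_NAMES)
    if (length(unknown) || is.null(names(args)) || any(names(args) == ""))
      stop("unknown state component(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    y[names(args)] <- unlist(args)
  }
  check_state(y)
  class(y) <- c("model_state", "numeric")
  y
}

check_state <- function(y) {
  if (length(y) != 13L)
    stop("a model state has exactly 13 components", call. = FALSE)
  bad <- which(!is.finite(y) | y < 0)
  if (length(bad))
    stop("invalid model state: ", STATE_NAMES[bad[1L]],
         " is negative or non-finite", call. = FALSE)
  invisible(y)
}

#' Exogenous model inputs over an integration interval
#'
#' Insulin and glucagon infusion rates are held piecewise-constant across a
#' dosing interval (a returned dose is spread as a constant rate over the
#' step); meal glucose appearance varies continuously from the listed meal
#' events.
#'
#' @param ui insulin infusion rate (U/min), >= 0.
#' @param ug glucagon infusion rate (units/min, 1 mg = 1 unit), >= 0.
#' @param meals `NULL` or a data.frame with columns `time` (ingestion time,
#'   min on the model clock) and `cho` (true carbohydrate content, g, > 0).
#' @param clock_offset offset (min) added to model time to obtain clock time
#'   for the diurnal fluxes; e.g. 480 for a trial starting at 08:00.
#' @return an object of class `exogenous_inputs`.
#' @export
exogenous_inputs <- function(ui = 0, ug = 0, meals = NULL, clock_offset = 0) {
  if (!is.finite(ui) || ui < 0) stop("ui must be >= 0", call. = FALSE)
  if (!is.finite(ug) || ug < 0) stop("ug must be >= 0", call. = FALSE)
  if (!is.null(meals)) {
    meals <- as.data.frame(meals)
    stopifnot(all(c("time", "cho") %in% names(meals)))
    if (nrow(meals) && any(meals$cho <= 0))
      stop("meal CHO must be > 0", call. = FALSE)
  }
  structure(list(ui = ui, ug = ug, meals = meals,
                 clock_offset = clock_offset),
            class = "exogenous_inputs")
}

#' Plasma insulin concentration
#'
#' `Ip = Qi / (Vi * w) * 1e6` (mU/L) with the insulin distribution volume
#' fixed at `Vi = 190` ml/kg.
#'
#' @param state model state (or any vector with a `Qi` element).
#' @param params a `patient_parameters` object.
#' @return plasma insulin concentration (mU/L).
#' @export
plasma_insulin <- function(state, params) {
  if (params$w <= 0) stop("invalid patient: w must be > 0", call. = FALSE)
  unname(state[["Qi"]]) / (params$Vi * params$w) * 1e6
}

#' Plasma glucagon concentration
#'
#' `Cp = (1/tgmax) * Qg2 / (w * MCRg) * 1e6 + Cb`; the background level `Cb`
#' is the fasting plasma glucagon concentration.
#'
#' @param state model state (or any vector with a `Qg2` element).
#' @param params a `patient_parameters` object.
#' @return plasma glucagon concentration (model-internal scale).
#' @export
plasma_glucagon <- function(state, params) {
  if (params$MCRg <= 0)
    stop("invalid patient: MCRg must be > 0", call. = FALSE)
  unname(state[["Qg2"]]) / params$tgmax / (params$w * params$MCRg) * 1e6 +
    params$Cb
}

#' Gut glucose appearance from one meal
#'
#' Two parallel two-compartment absorption channels sharing the transfer
#' rate `km`, the second delayed by `d` min, allow double-peak absorption
#' profiles. With `tau = t - t_meal`:
#' `Um1 = km^2 tau e^(-km tau) CHO * 5551 * pm / w` and
#' `Um2 = km^2 (tau-d) e^(-km (tau-d)) CHO * 5551 * (1-pm) / w` for
#' `tau > d` (0 otherwise); the total is modulated by the diurnal factor
#' `fm` at clock time.
#'
#' @param t model time (min), `>= meal$time`.
#' @param meal list or one-row data.frame with `time` (min) and `cho` (g).
#' @param params a `patient_parameters` object.
#' @param clock_offset clock offset (min) for evaluating `fm`.
#' @return glucose appearance rate (micromol/kg/min).
#' @export
meal_appearance <- function(t, meal, params, clock_offset = 0) {
  tau <- t - meal$time
  if (any(tau < 0)) stop("t must be >= meal ingestion time", call. = FALSE)
  if (meal$cho <= 0) stop("meal CHO must be > 0", call. = FALSE)
  fmv <- flux_at(params$fm, t + clock_offset)
  um_channels(tau, meal$cho, params) * fmv
}

# raw two-channel appearance without the fm modulation; vectorized over tau
um_channels <- function(tau, cho, p) {
  base <- cho * UMOL_PER_G / p$w * p$km^2
  um1 <- base * p$pm * tau * exp(-p$km * tau)
  tau2 <- tau - p$d
  um2 <- ifelse(tau2 > 0,
                base * (1 - p$pm) * tau2 * exp(-p$km * tau2), 0)
  um1 + um2
}

#' Endogenous glucose production
#'
#' `EGP = Cp * Sg * (1 - x3 * Se * 1e-4)`, clamped at 0 once remote insulin
#' fully suppresses production, so `EGP >= 0` always.
#'
#' @param Cp plasma glucagon concentration.
#' @param x3 remote insulin effect on EGP (mU/L scale).
#' @param params a `patient_parameters` object.
#' @return EGP (micromol/kg/min).
#' @export
egp <- function(Cp, x3, params) {
  Cp * params$Sg * pmax(0, 1 - x3 * params$Se * 1e-4)
}

# total meal appearance at model time t (fm already applied)
total_meal_appearance <- function(t, inputs, p) {
  m <- inputs$meals
  if (is.null(m) || !nrow(m)) return(0)
  tau <- t - m$time
  on <- tau > 0
  if (!any(on)) return(0)
  fmv <- flux_at(p$fm, t + inputs$clock_offset)
  sum(um_channels(tau[on], 1, p) * m$cho[on]) * fmv
}

# ODE right-hand side. The solver may probe marginally negative states; the
# physics is evaluated on the non-negative part so transient undershoot
# cannot feed back as spurious sources.
model_rhs <- function(t, y, parms) {
  p <- parms$p
  inp <- parms$inputs
  y <- pmax(y, 0)
  tclk <- t + inp$clock_offset
  imv <- flux_at(p$Im, tclk)
  fgv <- flux_at(p$Fg, tclk)

  Ip <- y[5L] / (p$Vi * p$w) * 1e6
  Cp <- y[10L] / p$tgmax / (p$w * p$MCRg) * 1e6 + p$Cb
  EGP <- p$Sg * Cp * max(0, 1 - y[8L] * p$Se * 1e-4)
  Um <- total_meal_appearance(t, inp, p)
  q1s <- y[11L] / GLUC_SAT
  stx <- y[6L] * p$St * 1e-4
  sdx <- y[7L] * p$Sd * 1e-4

  list(c(
    inp$ui * p$pi - y[1L] * p$kis1,                     # Qis1
    y[1L] * p$kis1 - y[2L] * p$kis2,                    # Qis2
    inp$ui * (1 - p$pi) - y[3L] * p$kif,                # Qif1
    (y[3L] - y[4L]) * p$kif,                            # Qif2
    (y[2L] * p$kis2 + y[4L] * p$kif) * imv - y[5L] * p$ke + p$ci,  # Qi
    p$ka1 * (Ip - y[6L]),                               # x1
    p$ka2 * (Ip - y[7L]),                               # x2
    p$ka3 * (Ip - y[8L]),                               # x3
    inp$ug - y[9L] / p$tgmax,                           # Qg1
    (y[9L] - y[10L]) / p$tgmax,                         # Qg2
    -p$F01 * q1s / (1 + q1s) - stx * y[11L] +
      p$k12 * y[12L] + EGP + fgv + Um,                  # Q1
    stx * y[11L] - (p$k12 + sdx) * y[12L],              # Q2
    p$ks * (y[11L] / p$V - y[13L])                      # Gs
  ))
}

#' Time derivatives of the model state
#'
#' Evaluates the seven-subsystem right-hand side at one instant: the slow
#' and fast subcutaneous insulin chains, plasma insulin kinetics (with the
#' diurnal multiplier applied to absorbed insulin), the three remote insulin
#' effects, the glucagon chain, the two-compartment glucose kinetics with
#' saturating non-insulin-dependent utilization, endogenous production and
#' meal appearance, and the first-order sensor lag.
#'
#' @param state a [model_state()] (non-negative, finite).
#' @param params a `patient_parameters` object.
#' @param inputs an [exogenous_inputs()].
#' @param t model time (min), >= 0.
#' @return named numeric vector of 13 time derivatives.
#' @export
derivatives <- function(state, params, inputs = exogenous_inputs(), t = 0) {
  check_state(state)
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  d <- model_rhs(t, as.numeric(state), list(p = params, inputs = inputs))[[1L]]
  stats::setNames(d, STATE_NAMES)
}

#' Integrate the model over a time interval
#'
#' Adaptive stiff-capable integration (`deSolve::lsoda`) with the exogenous
#' infusion rates held constant over the interval and meal appearance varying
#' continuously. Accepted states are checked for non-negativity: a
#' significant undershoot triggers one retry at 100-fold tighter tolerances,
#' after which remaining negative components are clamped to zero with a
#' warning; sub-tolerance numerical noise is clamped silently.
#'
#' @param state initial [model_state()] at `t0`.
#' @param params a `patient_parameters` object.
#' @param inputs an [exogenous_inputs()], constant over `[t0, t1]`.
#' @param t0,t1 interval endpoints (min), `t1 > t0`.
#' @param times optional vector of output times within `[t0, t1]`; when
#'   supplied a trace data.frame is returned instead of the final state.
#' @param rtol,atol solver tolerances.
#' @return the final `model_state` at `t1`, or, when `times` is given, a
#'   data.frame with `time_min`, the 13 states, and derived `Ip`, `Cp`, `G`.
#' @export
integrate_model <- function(state, params, inputs = exogenous_inputs(),
                            t0, t1, times = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  if (t1 <= t0) stop("t1 must be > t0", call. = FALSE)
  check_state(state)
  tt <- if (is.null(times)) c(t0, t1) else unique(sort(c(t0, times, t1)))
  parms <- list(p = params, inputs = inputs)
  solve_once <- function(rt, at) {
    out <- try(deSolve::lsoda(y = as.numeric(state), times = tt,
                              func = model_rhs, parms = parms,
                              rtol = rt, atol = at, maxsteps = 50000L),
               silent = TRUE)
    if (inherits(out, "try-error") || anyNA(out))
      stop(sprintf("solver failed for patient '%s' on [%g, %g]",
                   params$id, t0, t1), call. = FALSE)
    out
  }
  out <- solve_once(rtol, atol)
  ymat <- out[, -1L, drop = FALSE]
  neg_floor <- -100 * atol
  if (min(ymat) < neg_floor) {
    out <- solve_once(rtol / 100, atol / 100)
    ymat <- out[, -1L, drop = FALSE]
    if (min(ymat) < neg_floor)
      warning(sprintf(
        "patient '%s': clamped negative %s (min %.3g) to 0 on [%g, %g]",
        params$id, STATE_NAMES[which.min(apply(ymat, 2, min))],
        min(ymat), t0, t1))
  }
  ymat[ymat < 0] <- 0
  colnames(ymat) <- STATE_NAMES
  if (is.null(times)) {
    y <- ymat[nrow(ymat), ]
    class(y) <- c("model_state", "numeric")
    return(y)
  }
  tr <- data.frame(time_min = out[, 1L], ymat)
  tr$Ip <- tr$Qi / (params$Vi * params$w) * 1e6
  tr$Cp <- tr$Qg2 / params$tgmax / (params$w * params$MCRg) * 1e6 + params$Cb
  tr$G <- tr$Q1 / params$V
  tr
}
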