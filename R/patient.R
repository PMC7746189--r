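#' Virtual patient parameter set
#'
#' Collects every time-invariant constant and the three diurnal flux
#' functions that define one virtual subject's glucoregulatory model, plus
#' the demographics reported in the baseline-characteristics table. Units
#' follow the model equations: rate constants in 1/min, insulin masses in U,
#' glucose masses in micromol/kg, concentrations in mmol/L (glucose) and
#' mU/L (insulin). The insulin sensitivities `St`, `Sd`, `Se` are stored in
#' their conventional 1e-4-scaled units and the 1e-4 factor is applied inside
#' the equations.
#'
#' @param id patient identifier (string).
#' @param pi fraction of subcutaneous insulin absorbed through the slow
#'   channel, in `[0, 1]`.
#' @param kis1,kis2 slow-channel fractional transfer rates (1/min).
#' @param kif fast-channel shared fractional transfer rate (1/min).
#' @param ke plasma insulin fractional clearance rate (1/min).
#' @param ci background insulin appearance (U/min).
#' @param w body weight (kg).
#' @param tgmax time-to-peak plasma glucagon after a bolus (min).
#' @param MCRg glucagon metabolic clearance rate (ml/kg/min, model-internal
#'   scale; see the methods vignette on glucagon units).
#' @param Cb background plasma glucagon concentration (model-internal scale).
#' @param ka1,ka2,ka3 insulin-action activation rates for glucose
#'   distribution, disposal, and endogenous glucose production (1/min).
#' @param km meal transfer rate (1/min).
#' @param d delay of the second meal-absorption channel (min).
#' @param pm fraction of carbohydrate absorbed through the first channel.
#' @param F01 non-insulin-dependent glucose utilization (micromol/kg/min).
#' @param k12 glucose intercompartment transfer rate (1/min).
#' @param St,Sd insulin sensitivities of glucose distribution and disposal
#'   (1e-4 /min per mU/L).
#' @param Se insulin sensitivity of endogenous glucose production
#'   (1e-4 per mU/L).
#' @param Sg glucagon sensitivity (micromol/kg/min per unit plasma glucagon).
#' @param V glucose distribution volume (ml/kg); with glucose mass in
#'   micromol/kg, `G = Q1/V` is in mmol/L because micromol/ml = mmol/L.
#' @param ks interstitial (sensor) glucose time constant (1/min).
#' @param Im,fm,Fg diurnal flux functions ([diurnal_flux()]): multiplicative
#'   for insulin kinetics and meal absorption, additive (micromol/kg/min)
#'   for glucose.
#' @param flux_day_cv log-scale SD of the fresh per-day flux multipliers
#'   modelling day-to-day intra-patient variability.
#' @param basal_rate basal insulin infusion rate (U/min); if `NA` it is
#'   titrated so the fasting steady state sits at `G_target`.
#' @param G_target fasting glucose target used for basal titration (mmol/L).
#' @param age,bmi,hba1c,duration,tdd demographics: age (yr), BMI (kg/m^2),
#'   HbA1c (%), diabetes duration (yr), total daily insulin dose (U/kg/day).
#'   If `tdd` is `NA` it is derived from the titrated basal assuming a 50%
#'   basal fraction.
#' @return an object of class `patient_parameters`.
#' @export
patient_parameters <- function(id = "patient",
                               pi = 0.5, kis1 = 0.01, kis2 = 0.015,
                               kif = 0.03, ke = 0.138, ci = 0.001,
                               w = 70, tgmax = 20, MCRg = 13, Cb = 0.38,
                               ka1 = 0.006, ka2 = 0.06, ka3 = 0.03,
                               km = 0.025, d = 40, pm = 0.7,
                               F01 = 9.7, k12 = 0.066,
                               St = 51.2, Sd = 8.2, Se = 520, Sg = 49,
                               V = 160, ks = 0.066,
                               Im = constant_flux(1),
                               fm = constant_flux(1),
                               Fg = constant_flux(1.5),
                               flux_day_cv = 0.1,
                               basal_rate = NA_real_, G_target = 7,
                               age = 47, bmi = 25, hba1c = 7.5,
                               duration = 28, tdd = NA_real_) {
  p <- structure(
    list(id = id, pi = pi, kis1 = kis1, kis2 = kis2, kif = kif, ke = ke,
         ci = ci, Vi = 190, w = w, tgmax = tgmax, MCRg = MCRg, Cb = Cb,
         ka1 = ka1, ka2 = ka2, ka3 = ka3, km = km, d = d, pm = pm,
         F01 = F01, k12 = k12, St = St, Sd = Sd, Se = Se, Sg = Sg,
         V = V, ks = ks, Im = Im, fm = fm, Fg = Fg,
         flux_day_cv = flux_day_cv,
         basal_rate = basal_rate, G_target = G_target,
         age = age, bmi = bmi, hba1c = hba1c, duration = duration,
         tdd = tdd),
    class = "patient_parameters")
  if (is.na(p$basal_rate)) p$basal_rate <- titrate_basal(p, G_target)
  if (is.na(p$tdd)) p$tdd <- 2 * p$basal_rate * 1440 / p$w
  p$icr <- if (p$tdd > 0) icr_500_rule(p) else NA_real_
  validate_patient(p)
  p
}

rate_fields <- c("kis1", "kis2", "kif", "ke", "ka1", "ka2", "ka3",
                 "km", "k12", "ks")

#' Validate a patient parameter set
#'
#' Checks the structural invariants: fractions in `[0, 1]`, rate constants
#' strictly positive, `Vi` fixed at 190 ml/kg, positive weight and volumes,
#' valid flux functions.
#'
#' @param p a `patient_parameters` object.
#' @return `p`, invisibly; signals an error naming the offending field.
#' @export
validate_patient <- function(p) {
  stopifnot(inherits(p, "patient_parameters"))
  bad <- function(field, why)
    stop(sprintf("invalid patient '%s': %s %s", p$id, field, why),
         call. = FALSE)
  for (f in rate_fields)
    if (!is.finite(p[[f]]) || p[[f]] <= 0) bad(f, "must be > 0")
  if (p$pi < 0 || p$pi > 1) bad("pi", "must be in [0, 1]")
  if (p$pm < 0 || p$pm > 1) bad("pm", "must be in [0, 1]")
  if (p$Vi != 190) bad("Vi", "is fixed at 190 ml/kg")
  for (f in c("w", "tgmax", "MCRg", "V"))
    if (!is.finite(p[[f]]) || p[[f]] <= 0) bad(f, "must be > 0")
  for (f in c("ci", "Cb", "F01", "St", "Sd", "Se", "Sg", "d",
              "basal_rate", "flux_day_cv"))
    if (!is.finite(p[[f]]) || p[[f]] < 0) bad(f, "must be >= 0")
  for (f in c("Im", "fm", "Fg"))
    if (!inherits(p[[f]], "diurnal_flux")) bad(f, "must be a diurnal_flux")
  if (any(flux_at(p$Im, 0:1439) <= 0)) bad("Im", "must stay > 0")
  if (any(flux_at(p$fm, 0:1439) <= 0)) bad("fm", "must stay > 0")
  invisible(p)
}

#' @export
print.patient_parameters <- function(x, ...) {
  cat(sprintf(
    "<patient_parameters> %s: w=%.1f kg, basal=%.2f U/h, ICR=%.1f g/U, TDD=%.2f U/kg/day\n",
    x$id, x$w, x$basal_rate * 60, x$icr, x$tdd))
  invisible(x)
}

# Net fasting glucose balance (micromol/kg/min) at glucose G and steady-state
# plasma insulin Ip, with fluxes at their 24-h means. Used by the titration.
fasting_balance <- function(p, G, Ip, fg_mean) {
  x <- Ip                                  # x1 = x2 = x3 = Ip at steady state
  egp <- p$Cb * p$Sg * max(0, 1 - x * p$Se * 1e-4)
  st <- x * p$St * 1e-4
  sd <- x * p$Sd * 1e-4
  Q1 <- G * p$V
  # steady-state Q2 = st*Q1/(k12+sd); net disposal = st*Q1 - k12*Q2
  net <- if (st > 0) st * Q1 * sd / (p$k12 + sd) else 0
  egp + fg_mean - p$F01 * G / (1 + G) - net
}

#' Titrate the basal insulin rate for a fasting glucose target
#'
#' Solves for the steady-state plasma insulin concentration at which the
#' fasting glucose balance (endogenous production plus the mean diurnal
#' glucose flux against insulin-dependent and independent utilization)
#' closes at `G_target`, then converts it to an infusion rate through the
#' steady state of the insulin chain, `Ip = (u + ci) / ke * 1e6 / (Vi w)`.
#' This mirrors clinical basal titration: the pump rate is adjusted until
#' fasting glucose holds at target.
#'
#' @param p a `patient_parameters` object (the `basal_rate` field is ignored).
#' @param G_target fasting glucose target (mmol/L).
#' @return basal rate in U/min (floored at 0).
#' @export
titrate_basal <- function(p, G_target = 7) {
  fg <- flux_mean(p$Fg)
  im <- flux_mean(p$Im)
  f <- function(Ip) fasting_balance(p, G_target, Ip, fg)
  # upper bracket: full EGP suppression (balance < 0 there for any patient
  # with some insulin-dependent disposal)
  hi <- if (p$Se > 0) 1 / (p$Se * 1e-4) else 1e6
  if (f(0) <= 0) return(0)             # no insulin needed to hold target
  if (f(hi) >= 0) {
    warning(sprintf(
      "patient '%s': fasting balance cannot close; basal set to 0", p$id))
    return(0)
  }
  root <- stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  u <- (root * p$ke * p$Vi * p$w / 1e6 - p$ci) / im
  max(u, 0)
}

#' Insulin-to-carbohydrate ratio by the 500 rule
#'
#' `ICR = 500 / TDD` with the total daily dose in U/day, the standard
#' clinical heuristic for meal bolus sizing.
#'
#' @param p a `patient_parameters` object with `tdd` (U/kg/day) and `w`.
#' @return grams of carbohydrate covered per unit of insulin.
#' @export
icr_500_rule <- function(p) {
  tdd_u <- p$tdd * p$w
  if (!is.finite(tdd_u) || tdd_u <= 0)
    stop("ICR requires a positive total daily dose", call. = FALSE)
  500 / tdd_u
}

# --- serialization ---------------------------------------------------------

flux_to_list <- function(fl) list(times = fl$times, values = fl$values)
flux_from_list <- function(x) diurnal_flux(unlist(x$times), unlist(x$values))

patient_to_list <- function(p) {
  out <- unclass(p)
  for (f in c("Im", "fm", "Fg")) out[[f]] <- flux_to_list(p[[f]])
  out
}

patient_from_list <- function(x) {
  for (f in c("Im", "fm", "Fg")) x[[f]] <- flux_from_list(x[[f]])
  x$Vi <- NULL
  args <- x[names(x) %in% names(formals(patient_parameters))]
  do.call(patient_parameters, args)
}

#' Read / write patient parameter files
#'
#' Patients are stored as JSON: one record per patient, field names exactly
#' as in [patient_parameters()], flux functions as paired knot time/value
#' arrays.
#'
#' @param patients a list of `patient_parameters` (or a `cohort`).
#' @param path file path.
#' @return `read_patients` returns a list of `patient_parameters`.
#' @export
write_patients <- function(patients, path) {
  if (inherits(patients, "cohort")) patients <- patients$patients
  recs <- lapply(patients, patient_to_list)
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, patient_from_list)
}
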