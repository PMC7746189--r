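#' Specification for a synthetic virtual-patient cohort
#'
#' Defines the sampling distributions from which a reproducible cohort of
#' virtual subjects is drawn. Strictly positive physiological parameters
#' (rate constants, sensitivities, weight) are drawn log-normally around the
#' template midpoint with the given coefficient of variation, which keeps
#' them positive by construction; the channel fractions `pi` and `pm` are
#' drawn from a normal truncated to `[0.05, 0.95]`. Each patient receives
#' diurnal flux functions built on an equally spaced knot grid with
#' log-normal multipliers (median 1), so multiplicative fluxes stay
#' positive. Draws falling outside the template validity range are redrawn a
#' bounded number of times.
#'
#' @param n_patients number of virtual subjects, >= 1.
#' @param cv default inter-subject coefficient of variation applied to the
#'   log-normally sampled parameters.
#' @param cv_overrides named list of per-parameter CV overrides.
#' @param frac_sd SD of the truncated-normal draws for `pi` and `pm`.
#' @param flux_knots number of equally spaced flux knots per 24 h.
#' @param flux_sigma log-scale SD of the inter-subject flux multipliers.
#' @param flux_day_cv log-scale SD of the fresh per-day flux multipliers
#'   (intra-patient day-to-day variability applied by the trial engine).
#' @param demo_sds named SDs of the truncated-normal demographic draws
#'   (age, bmi, hba1c, duration).
#' @param template named list of template midpoints; defaults to the
#'   package's physiological template (see the methods vignette).
#' @param seed RNG seed for [sample_cohort()].
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 15, cv = 0.15, cv_overrides = list(),
                        frac_sd = 0.08, flux_knots = 8, flux_sigma = 0.15,
                        flux_day_cv = 0.1,
                        demo_sds = c(age = 12, bmi = 3, hba1c = 0.8,
                                     duration = 12),
                        template = cohort_template(), seed = 20201204) {
  stopifnot(n_patients >= 1, cv >= 0, frac_sd >= 0,
            flux_knots >= 2, flux_sigma >= 0, flux_day_cv >= 0,
            all(demo_sds >= 0))
  structure(list(n_patients = as.integer(n_patients), cv = cv,
                 cv_overrides = cv_overrides, frac_sd = frac_sd,
                 flux_knots = as.integer(flux_knots),
                 flux_sigma = flux_sigma, flux_day_cv = flux_day_cv,
                 demo_sds = demo_sds,
                 template = template, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Template midpoints and validity ranges for the cohort generator
#'
#' Midpoints follow the two-compartment subcutaneous insulin / glucose
#' kinetics literature where the subsystem structure matches, and
#' physiologically argued values elsewhere; no fitted per-patient values are
#' published for the model, so these define the package's study conditions.
#' Each entry is `c(mid, low, high)`; draws outside `[low, high]` are
#' redrawn.
#'
#' @return named list of 3-vectors.
#' @export
cohort_template <- function() {
  tri <- function(mid, lo = mid / 3, hi = mid * 3) c(mid, lo, hi)
  list(
    pi    = c(0.5, 0.05, 0.95),
    pm    = c(0.7, 0.05, 0.95),
    kis1  = tri(0.01),  kis2 = tri(0.015), kif = tri(0.03),
    ke    = tri(0.138), ka1 = tri(0.006),  ka2 = tri(0.06),
    ka3   = tri(0.03),  ks = tri(0.066),   km = tri(0.025),
    d     = tri(40),    tgmax = tri(20),   MCRg = tri(13),
    Cb    = tri(0.38),  F01 = tri(9.7),    k12 = tri(0.066),
    St    = tri(51.2),  Sd = tri(8.2),     Se = tri(520), Sg = tri(49),
    V     = c(160, 120, 210),
    w     = c(70, 45, 110),
    ci    = c(0.001, 0, 0.003),
    age      = c(47, 18, 80),
    bmi      = c(25, 17, 40),
    hba1c    = c(7.5, 5.5, 11),
    duration = c(28, 1, 60)
  )
}

# log-normal draw with median mid and coefficient of variation cv,
# redrawn into [lo, hi]; errors after max_try attempts naming the parameter
draw_lognormal <- function(name, mid, lo, hi, cv, max_try = 200L) {
  if (cv == 0) return(mid)
  sdlog <- sqrt(log(1 + cv^2))
  for (i in seq_len(max_try)) {
    v <- mid * exp(stats::rnorm(1L, 0, sdlog))
    if (v >= lo && v <= hi) return(v)
  }
  stop(sprintf("could not sample '%s' within [%g, %g]", name, lo, hi),
       call. = FALSE)
}

draw_truncnorm <- function(name, mid, lo, hi, sd, max_try = 200L) {
  if (sd == 0) return(mid)
  for (i in seq_len(max_try)) {
    v <- stats::rnorm(1L, mid, sd)
    if (v >= lo && v <= hi) return(v)
  }
  stop(sprintf("could not sample '%s' within [%g, %g]", name, lo, hi),
       call. = FALSE)
}

sample_flux <- function(spec, base = 1) {
  kt <- seq(0, 1440 - 1440 / spec$flux_knots, length.out = spec$flux_knots)
  mult <- exp(stats::rnorm(spec$flux_knots, 0, spec$flux_sigma))
  diurnal_flux(kt, base * mult)
}

sample_one_patient <- function(spec, idx) {
  tpl <- spec$template
  cv_of <- function(nm)
    if (!is.null(spec$cv_overrides[[nm]])) spec$cv_overrides[[nm]] else spec$cv
  ln <- function(nm)
    draw_lognormal(nm, tpl[[nm]][1L], tpl[[nm]][2L], tpl[[nm]][3L], cv_of(nm))
  tn <- function(nm, sd)
    draw_truncnorm(nm, tpl[[nm]][1L], tpl[[nm]][2L], tpl[[nm]][3L], sd)

  patient_parameters(
    id = sprintf("vp%02d", idx),
    pi = tn("pi", spec$frac_sd), pm = tn("pm", spec$frac_sd),
    kis1 = ln("kis1"), kis2 = ln("kis2"), kif = ln("kif"),
    ke = ln("ke"), ka1 = ln("ka1"), ka2 = ln("ka2"), ka3 = ln("ka3"),
    ks = ln("ks"), km = ln("km"), d = ln("d"),
    tgmax = ln("tgmax"), MCRg = ln("MCRg"), Cb = ln("Cb"),
    F01 = ln("F01"), k12 = ln("k12"),
    St = ln("St"), Sd = ln("Sd"), Se = ln("Se"), Sg = ln("Sg"),
    V = ln("V"), w = ln("w"), ci = tpl$ci[1L],
    Im = sample_flux(spec), fm = sample_flux(spec),
    Fg = sample_flux(spec, base = 1.5),
    flux_day_cv = spec$flux_day_cv,
    age = tn("age", spec$demo_sds[["age"]]),
    bmi = tn("bmi", spec$demo_sds[["bmi"]]),
    hba1c = tn("hba1c", spec$demo_sds[["hba1c"]]),
    duration = tn("duration", spec$demo_sds[["duration"]])
  )
}

#' Sample a synthetic virtual-patient cohort
#'
#' Draws `spec$n_patients` parameter sets from the spec's distributions and
#' titrates each patient's basal rate (and hence total daily dose and
#' insulin-to-carbohydrate ratio) against their own physiology. The cohort
#' is a pure function of the spec and its seed: regenerating with the same
#' spec reproduces it exactly.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `cohort`: a list with `patients` (list of
#'   `patient_parameters`) and `spec`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  patients <- local_seed(spec$seed, {
    lapply(seq_len(spec$n_patients), function(i) sample_one_patient(spec, i))
  })
  structure(list(patients = patients, spec = spec), class = "cohort")
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d virtual patients (seed %d)\n",
              length(x$patients), x$spec$seed))
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$patients)

#' Baseline characteristics of a cohort
#'
#' Summarizes the five demographic fields reported in a trial's baseline
#' table — age, BMI, HbA1c, total daily insulin dose, and diabetes
#' duration — as mean, SD, median and interquartile range.
#'
#' @param cohort a [sample_cohort()] result or a plain list of
#'   `patient_parameters`.
#' @return data.frame with one row per characteristic.
#' @export
baseline_characteristics <- function(cohort) {
  patients <- if (inherits(cohort, "cohort")) cohort$patients else cohort
  if (!length(patients)) stop("empty cohort", call. = FALSE)
  fields <- c(age = "Age (yr)", bmi = "BMI (kg/m2)", hba1c = "HbA1c (%)",
              tdd = "Daily insulin dose (U/kg/day)",
              duration = "Duration of diabetes (yr)")
  rows <- lapply(names(fields), function(f) {
    v <- vapply(patients, function(p) p[[f]], numeric(1L))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(characteristic = fields[[f]],
               mean = mean(v), sd = stats::sd(v),
               median = q[2L], q25 = q[1L], q75 = q[3L])
  })
  out <- do.call(rbind, rows)
  out$sd[is.na(out$sd)] <- 0   # single-patient cohort
  rownames(out) <- NULL
  out
}
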