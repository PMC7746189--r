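# Independent analytic oracle for the linear time-invariant parts of the
# model: with the glucose nonlinearities switched off (F01 = St = Sd = Se =
# 0, constant fluxes, no meals) the full 13-state system is LTI with a
# constant input, and x(t) = expm(A_aug t) [x0; 1] for the augmented system
# [[A, b], [0, 0]]. This route never touches the package's ODE right-hand
# side or solver.

lti_matrices <- function(p, ui = 0, ug = 0, fg = NULL) {
  if (is.null(fg)) fg <- flux_at(p$Fg, 0)
  cI <- 1e6 / (p$Vi * p$w)
  cC <- 1e6 / (p$tgmax * p$w * p$MCRg)
  A <- matrix(0, 13, 13)
  A[1, 1] <- -p$kis1
  A[2, 1] <- p$kis1; A[2, 2] <- -p$kis2
  A[3, 3] <- -p$kif
  A[4, 3] <- p$kif; A[4, 4] <- -p$kif
  A[5, 2] <- p$kis2; A[5, 4] <- p$kif; A[5, 5] <- -p$ke
  A[6, 5] <- p$ka1 * cI; A[6, 6] <- -p$ka1
  A[7, 5] <- p$ka2 * cI; A[7, 7] <- -p$ka2
  A[8, 5] <- p$ka3 * cI; A[8, 8] <- -p$ka3
  A[9, 9] <- -1 / p$tgmax
  A[10, 9] <- 1 / p$tgmax; A[10, 10] <- -1 / p$tgmax
  A[11, 10] <- p$Sg * cC; A[11, 12] <- p$k12
  A[12, 12] <- -p$k12
  A[13, 11] <- p$ks / p$V; A[13, 13] <- -p$ks
  b <- c(ui * p$pi, 0, ui * (1 - p$pi), 0, p$ci, 0, 0, 0,
         ug, 0, p$Cb * p$Sg + fg, 0, 0)
  list(A = A, b = b)
}

lti_solution <- function(p, x0, t, ui = 0, ug = 0, fg = NULL) {
  m <- lti_matrices(p, ui, ug, fg)
  Aa <- rbind(cbind(m$A, m$b), 0)
  ex <- as.matrix(Matrix::expm(Matrix::Matrix(Aa * t)))
  (ex %*% c(x0, 1))[1:13]
}

# a patient whose full model is linear: glucose nonlinearities off,
# constant unit fluxes, no day-to-day flux jitter, basal not titrated
linear_patient <- function(id = "lin", Fg_value = 1.5, Cb = 0.38, Sg = 49,
                           ci = 0.001, ...) {
  patient_parameters(id = id, St = 0, Sd = 0, Se = 0, F01 = 0,
                     Cb = Cb, Sg = Sg, ci = ci,
                     Im = constant_flux(1), fm = constant_flux(1),
                     Fg = constant_flux(Fg_value),
                     flux_day_cv = 0, basal_rate = 0, tdd = 0.5, ...)
}

# draw a randomized linear patient around the template (log-normal jitter)
random_linear_patient <- function(i) {
  j <- function(mid) mid * exp(stats::rnorm(1, 0, 0.2))
  linear_patient(id = paste0("lin", i),
                 kis1 = j(0.01), kis2 = j(0.015), kif = j(0.03),
                 ke = j(0.138), ka1 = j(0.006), ka2 = j(0.06),
                 ka3 = j(0.03), ks = j(0.066), tgmax = j(20),
                 MCRg = j(13), w = j(70), V = j(160),
                 Cb = j(0.38), Sg = j(49), ci = j(0.001),
                 Fg_value = j(1.5))
}

# relative error against an oracle vector, guarded for near-zero components
rel_err <- function(num, ana) {
  max(abs(num - ana) / pmax(abs(ana), 1e-8))
}

zero_flux_patient <- function(...) {
  # drift-free patient: no endogenous sources at all
  patient_parameters(ci = 0, Cb = 0, Sg = 0, F01 = 0, St = 0, Sd = 0,
                     Se = 0, Fg = constant_flux(0), flux_day_cv = 0,
                     basal_rate = 0, tdd = 0.5, ...)
}

# run expr under a fixed seed without disturbing the session RNG
local_seed_for_tests <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
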