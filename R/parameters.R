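#' Construct the fixed-effect vector of the PKPD model
#'
#' The model couples a one-compartment first-order absorption PK model
#' (parameters `cl`, `v`, `ka`) to a sigmoidal Emax concentration-effect
#' model (parameters `base`, `emax`, `ec50`, `gamma`).
#'
#' @param base Baseline effect (effect units).
#' @param emax Maximum effect above baseline (effect units).
#' @param ec50 Concentration giving half-maximal effect (mg/L).
#' @param gamma Sigmoidicity (Hill) coefficient, dimensionless.
#' @param cl Clearance (L/h).
#' @param v Volume of distribution (L).
#' @param ka First-order absorption rate constant (1/h).
#'
#' @return A named numeric vector of class `fixed_effects`.
#' @export
#' @examples
#' fixed_effects(base = 1, emax = 100, ec50 = 7, gamma = 2,
#'               cl = 0.15, v = 8, ka = 1)
fixed_effects <- function(base, emax, ec50, gamma, cl, v, ka) {
  x <- c(base = base, emax = emax, ec50 = ec50, gamma = gamma,
         cl = cl, v = v, ka = ka)
  stopifnot(is.numeric(x), length(x) == 7L, all(is.finite(x)))
  if (ec50 <= 0) stop("`ec50` must be positive", call. = FALSE)
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (cl <= 0 || v <= 0 || ka <= 0) {
    stop("PK parameters `cl`, `v`, `ka` must be positive", call. = FALSE)
  }
  structure(x, class = "fixed_effects")
}

# canonical orderings used throughout
.beta_names <- c("base", "emax", "ec50", "gamma", "cl", "v", "ka")
.eta_names <- c("emax", "ec50", "cl", "v")
.lambda_names <- c("omega2_emax", "omega2_ec50", "omega2_cl", "omega2_v",
                   "sigma2_add", "sigma2_prop")

#' Construct the random-effect variance set
#'
#' Between-subject variability enters the model as log-normal random effects
#' on EMAX, EC50, CL and V (diagonal covariance, no correlation); residual
#' unexplained variability is a combined additive and proportional error.
#'
#' @param omega2 Named numeric vector of between-subject variances with
#'   entries `emax`, `ec50`, `cl`, `v` (variances of the log-scale eta).
#' @param sigma2_add Additive residual error variance (squared effect units).
#' @param sigma2_prop Proportional residual error variance (dimensionless).
#'
#' @return A list of class `random_effects`.
#' @export
random_effects <- function(omega2, sigma2_add, sigma2_prop) {
  omega2 <- omega2[.eta_names]
  if (anyNA(omega2)) {
    stop("`omega2` needs named entries: ", paste(.eta_names, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(omega2 >= 0), sigma2_add >= 0, sigma2_prop >= 0)
  structure(list(omega2 = omega2, sigma2_add = sigma2_add,
                 sigma2_prop = sigma2_prop),
            class = "random_effects")
}

#' Bundle fixed and random effects into a population parameter set
#'
#' @param fixed A [fixed_effects()] vector.
#' @param random A [random_effects()] list.
#' @param estimated Character vector naming the estimated parameters; the
#'   remaining parameters are treated as known and fixed ("FIX") in both
#'   design optimization and estimation. Fixed-effect names are `base`,
#'   `emax`, `ec50`, `gamma`, `cl`, `v`, `ka`; variance names are
#'   `omega2_emax`, `omega2_ec50`, `omega2_cl`, `omega2_v`, `sigma2_add`,
#'   `sigma2_prop`.
#'
#' @return A list of class `population_parameters`.
#' @export
population_parameters <- function(fixed, random,
                                  estimated = default_estimated()) {
  stopifnot(inherits(fixed, "fixed_effects"), inherits(random, "random_effects"))
  valid <- c(.beta_names, .lambda_names)
  bad <- setdiff(estimated, valid)
  if (length(bad)) {
    stop("unknown estimated parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(fixed = fixed, random = random,
                 estimated = intersect(valid, estimated)),
            class = "population_parameters")
}

#' Default estimated-parameter set of the dose-finding scenario
#'
#' The PK parameters and their variabilities, and the additive error, are
#' treated as known; the four PD fixed effects, the EMAX and EC50
#' between-subject variances and the proportional error are estimated.
#'
#' @return Character vector of parameter names.
#' @export
default_estimated <- function() {
  c("base", "emax", "ec50", "gamma", "omega2_emax", "omega2_ec50",
    "sigma2_prop")
}

estimated_beta <- function(theta) {
  intersect(theta$estimated, .beta_names)
}

estimated_lambda <- function(theta) {
  intersect(theta$estimated, .lambda_names)
}

# flat named parameter vector <-> population_parameters
theta_to_vector <- function(theta) {
  c(unclass(theta$fixed),
    stats::setNames(theta$random$omega2, paste0("omega2_", .eta_names)),
    sigma2_add = theta$random$sigma2_add,
    sigma2_prop = theta$random$sigma2_prop)
}

vector_to_theta <- function(x, template) {
  fx <- template$fixed
  fx[.beta_names] <- x[.beta_names]
  rnd <- template$random
  rnd$omega2[.eta_names] <- x[paste0("omega2_", .eta_names)]
  rnd$sigma2_add <- unname(x[["sigma2_add"]])
  rnd$sigma2_prop <- unname(x[["sigma2_prop"]])
  population_parameters(fx, rnd, template$estimated)
}

# replace a subset of fixed effects (named vector beta) in theta
set_fixed_effects <- function(theta, beta) {
  fx <- theta$fixed
  fx[names(beta)] <- beta
  theta$fixed <- fx
  theta
}

#' The warfarin-PK-driven dose-finding scenario parameters
#'
#' True simulation values and the deliberately misspecified initial guess
#' (+50% on the four PD fixed effects) for the sigmoidal Emax response
#' driven by warfarin-like one-compartment PK. PK parameters and their
#' between-subject variances, and the additive residual error, are fixed
#' (not estimated).
#'
#' @param guess If `TRUE`, return the misspecified initial parameter guess
#'   (Base 1.5, EMAX 150, EC50 10.5, gamma 3) instead of the true values.
#'
#' @return A [population_parameters()] object.
#' @export
#' @examples
#' scenario_parameters()           # true values
#' scenario_parameters(guess = TRUE)
scenario_parameters <- function(guess = FALSE) {
  fx <- if (guess) {
    fixed_effects(base = 1.5, emax = 150, ec50 = 10.5, gamma = 3,
                  cl = 0.15, v = 8, ka = 1)
  } else {
    fixed_effects(base = 1, emax = 100, ec50 = 7, gamma = 2,
                  cl = 0.15, v = 8, ka = 1)
  }
  rnd <- random_effects(
    omega2 = c(emax = 0.0625, ec50 = 0.0625, cl = 0.07, v = 0.02),
    sigma2_add = 0.001, sigma2_prop = 0.015
  )
  population_parameters(fx, rnd, default_estimated())
}

#' Fixed sampling schedules of the scenario
#'
#' @param schedule `"sparse"` (3 samples at 0.5, 3 and 60 h) or `"rich"`
#'   (8 samples at 0.5, 2, 3, 6, 24, 36, 72 and 120 h).
#' @return Numeric vector of sampling times in hours.
#' @export
schedule_times <- function(schedule = c("sparse", "rich")) {
  schedule <- match.arg(schedule)
  switch(schedule,
         sparse = c(0.5, 3, 60),
         rich = c(0.5, 2, 3, 6, 24, 36, 72, 120))
}

#' @export
print.population_parameters <- function(x, ...) {
  cat("<population_parameters>\n")
  v <- theta_to_vector(x)
  est <- names(v) %in% x$estimated
  cat(sprintf("  %-12s %10.4g %s\n", names(v), v,
              ifelse(est, "", "FIX")), sep = "")
  invisible(x)
}
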