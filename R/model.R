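#' Drug concentration of the one-compartment first-order absorption model
#'
#' `C(t) = dose * ka / (v * ka - cl) * (exp(-(cl/v) t) - exp(-ka t))`,
#' the standard oral one-compartment profile with elimination rate
#' `ke = cl/v`. Vectorized over `t`.
#'
#' @param t Time after dose, hours (>= 0).
#' @param dose Dose, mg (>= 0).
#' @param cl Clearance, L/h.
#' @param v Volume of distribution, L.
#' @param ka Absorption rate constant, 1/h.
#' @param tol Degeneracy tolerance: an error is raised when
#'   `|v * ka - cl|` falls below it (flip-flop limit where the profile
#'   becomes 0/0).
#'
#' @return Concentration in mg/L, same length as `t`.
#' @export
#' @examples
#' pk_concentration(3, dose = 160, cl = 0.15, v = 8, ka = 1)
pk_concentration <- function(t, dose, cl, v, ka, tol = 1e-8) {
  stopifnot(all(t >= 0), dose >= 0, cl > 0, v > 0, ka > 0)
  den <- v * ka - cl
  if (abs(den) < tol) {
    stop("degenerate PK model: |v*ka - cl| = ", format(abs(den)),
         " below tolerance ", format(tol), call. = FALSE)
  }
  dose * ka / den * (exp(-(cl / v) * t) - exp(-ka * t))
}

#' Sigmoidal Emax concentration-effect relationship
#'
#' `E(C) = base + C^gamma * emax / (C^gamma + ec50^gamma)`; at `C = 0`
#' the effect is the baseline (`0^gamma` taken as 0 for `gamma > 0`).
#' Vectorized over `conc` and over the parameters.
#'
#' @param conc Concentration, mg/L (>= 0).
#' @param base Baseline effect.
#' @param emax Maximum effect above baseline.
#' @param ec50 Half-maximal concentration, mg/L (> 0).
#' @param gamma Hill coefficient (> 0).
#'
#' @return Effect on the same scale as `base`/`emax`.
#' @export
effect_mean <- function(conc, base, emax, ec50, gamma) {
  stopifnot(all(conc >= 0), all(ec50 > 0), all(gamma > 0))
  # ratio form of C^g/(C^g + EC50^g): no overflow for extreme gamma;
  # conc = 0 gives the baseline (0^gamma = 0 for gamma > 0)
  hill <- ifelse(conc > 0, 1 / (1 + (ec50 / conc)^gamma), 0)
  base + emax * hill
}

# typical (eta = 0) response at a dose and times, given a fixed-effect vector
typical_response <- function(times, dose, beta) {
  conc <- pk_concentration(times, dose, cl = beta[["cl"]], v = beta[["v"]],
                           ka = beta[["ka"]])
  effect_mean(conc, base = beta[["base"]], emax = beta[["emax"]],
              ec50 = beta[["ec50"]], gamma = beta[["gamma"]])
}

#' Individual parameter realizations from random effects
#'
#' EMAX, EC50, CL and V are log-normal about their typical values:
#' `theta_i = beta * exp(eta)`. Baseline, gamma and ka carry no
#' between-subject variability and are inherited.
#'
#' @param beta A [fixed_effects()] vector.
#' @param eta Named numeric vector of random-effect deviations with entries
#'   `emax`, `ec50`, `cl`, `v` (missing entries default to 0).
#'
#' @return A named numeric vector of individual parameters with the same
#'   layout as `beta`.
#' @export
individual_parameters <- function(beta, eta = numeric()) {
  e <- stats::setNames(numeric(4), .eta_names)
  e[names(eta)] <- eta
  out <- unclass(beta)
  out[.eta_names] <- out[.eta_names] * exp(e)
  out
}

# individual response at times for a subject with deviations eta
individual_response <- function(times, dose, beta, eta) {
  typical_response(times, dose, individual_parameters(beta, eta))
}

#' Simulate a trial dataset from a design and true parameters
#'
#' For each subject, between-subject deviations `eta ~ N(0, Omega)` are
#' drawn, the individual concentration-effect profile is computed, and
#' combined additive + proportional residual error is applied:
#' `y = f * (1 + eps_prop) + eps_add`. Negative observations are retained;
#' nothing is censored.
#'
#' Each subject uses an independent substream keyed by `(seed, cohort,
#' subject index)`, so simulating additional cohorts never perturbs the
#' data of earlier subjects.
#'
#' @param design A [study_design()].
#' @param theta True [population_parameters()].
#' @param seed Integer seed.
#' @param cohort Cohort index stored with the records (and mixed into the
#'   subject substreams).
#' @param id_offset First subject id minus one (ids are sequential).
#'
#' @return A tibble with columns `id`, `cohort`, `dose`, `time`, `dv`, of
#'   class `trial_data`. The per-subject `eta` draws are attached as the
#'   `"eta"` attribute for diagnostics.
#' @export
#' @examples
#' d <- initial_design("sparse")
#' sim <- simulate_dataset(d, scenario_parameters(), seed = 1)
simulate_dataset <- function(design, theta, seed, cohort = 1L,
                             id_offset = 0L) {
  stopifnot(inherits(design, "study_design"),
            inherits(theta, "population_parameters"))
  beta <- theta$fixed
  om <- theta$random$omega2
  recs <- vector("list", nrow(design))
  etas <- vector("list", nrow(design))
  id <- id_offset
  subj_index <- 0L
  for (g in seq_len(nrow(design))) {
    tt <- design$times[[g]]
    dose <- design$dose[[g]]
    gr <- vector("list", design$n[[g]])
    ge <- vector("list", design$n[[g]])
    for (s in seq_len(design$n[[g]])) {
      id <- id + 1L
      subj_index <- subj_index + 1L
      set.seed(derive_seed(seed, cohort, subj_index))
      eta <- stats::setNames(stats::rnorm(4, 0, sqrt(om[.eta_names])),
                             .eta_names)
      f <- individual_response(tt, dose, beta, eta)
      eps_prop <- stats::rnorm(length(tt), 0, sqrt(theta$random$sigma2_prop))
      eps_add <- stats::rnorm(length(tt), 0, sqrt(theta$random$sigma2_add))
      dv <- f * (1 + eps_prop) + eps_add
      gr[[s]] <- tibble::tibble(id = id, cohort = as.integer(cohort),
                                dose = dose, time = tt, dv = dv)
      ge[[s]] <- tibble::tibble(id = id, !!!as.list(eta))
    }
    recs[[g]] <- dplyr::bind_rows(gr)
    etas[[g]] <- dplyr::bind_rows(ge)
  }
  out <- dplyr::bind_rows(recs)
  class(out) <- c("trial_data", class(out))
  attr(out, "eta") <- dplyr::bind_rows(etas)
  out
}

#' Write / read a trial dataset as tidy CSV
#'
#' Columns `id`, `cohort`, `dose`, `time`, `dv`; the round trip is
#' lossless up to the full double precision written.
#'
#' @param data A `trial_data` tibble.
#' @param path File path.
#' @return `write_trial_data` returns `path` invisibly; `read_trial_data`
#'   returns the `trial_data` tibble.
#' @export
write_trial_data <- function(data, path) {
  df <- as.data.frame(data[, c("id", "cohort", "dose", "time", "dv")])
  df$time <- format(df$time, digits = 17)
  df$dv <- format(df$dv, digits = 17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_data
#' @export
read_trial_data <- function(path) {
  df <- utils::read.csv(path, colClasses = c(id = "integer",
                                             cohort = "integer",
                                             dose = "integer",
                                             time = "numeric",
                                             dv = "numeric"))
  out <- tibble::as_tibble(df)
  class(out) <- c("trial_data", class(out))
  out
}
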