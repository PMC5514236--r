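#' Configuration of a model-based adaptive optimal design run
#'
#' Defaults reproduce the dose-optimization scenario: a first cohort of
#' two unoptimized groups (0 and 160 mg, four individuals each), then
#' cohorts of one two-individual group at an optimized dose from the
#' 0-500 mg integer grid, a maximum of 50 cohorts, a +50% misspecified
#' initial guess of the PD fixed effects, a 10% CV initial prior for the
#' robust criterion with 10 Latin hypercube samples, and a stopping rule
#' requiring the simulated 95% CI of the typical effect prediction
#' (100,000 multivariate-t draws) to lie within 60-140% of the predicted
#' mean at every sampled time and dose.
#'
#' @param schedule `"sparse"` or `"rich"` sampling schedule.
#' @param criterion `"lnD"` (local) or `"ELD"` (robust) design criterion.
#' @param theta_true True parameters used to simulate subjects.
#' @param theta_init Initial parameter guess used for the first fit and
#'   the first optimization.
#' @param init_design First-cohort design (unoptimized).
#' @param cohort_n Individuals added per adaptive cohort.
#' @param max_cohorts Maximum number of cohorts.
#' @param grid Candidate doses, mg.
#' @param prior_cv Coefficient of variation of the initial ELD prior.
#' @param n_lhs Latin hypercube samples for the ELD expectation.
#' @param n_stop_sim Multivariate-t draws for the stopping criterion.
#' @param band Stopping band multipliers around the predicted mean.
#' @param level CI level of the stopping criterion.
#' @param method Estimation method, `"FO"` or `"FOCEI"`.
#' @param seed Master seed; replicate and cohort substreams derive from it.
#'
#' @return A list of class `mbaod_config`.
#' @export
mbaod_config <- function(schedule = c("sparse", "rich"),
                         criterion = c("lnD", "ELD"),
                         theta_true = scenario_parameters(),
                         theta_init = scenario_parameters(guess = TRUE),
                         init_design = NULL,
                         cohort_n = 2L,
                         max_cohorts = 50L,
                         grid = 0:500,
                         prior_cv = 0.10,
                         n_lhs = 10L,
                         n_stop_sim = 100000L,
                         band = c(0.6, 1.4),
                         level = 0.95,
                         method = c("FO", "FOCEI"),
                         seed = 1L) {
  schedule <- match.arg(schedule)
  criterion <- match.arg(criterion)
  method <- match.arg(method)
  if (is.null(init_design)) init_design <- initial_design(schedule)
  stopifnot(inherits(init_design, "study_design"),
            band[1] < 1, band[2] > 1, max_cohorts >= 1, cohort_n >= 1,
            n_lhs >= 1, n_stop_sim >= 1, prior_cv >= 0)
  structure(list(schedule = schedule, criterion = criterion,
                 theta_true = theta_true, theta_init = theta_init,
                 init_design = init_design, cohort_n = as.integer(cohort_n),
                 max_cohorts = as.integer(max_cohorts), grid = grid,
                 prior_cv = prior_cv, n_lhs = as.integer(n_lhs),
                 n_stop_sim = as.integer(n_stop_sim), band = band,
                 level = level, method = method, seed = as.integer(seed)),
            class = "mbaod_config")
}

#' Update the working parameter guess from a fit
#'
#' Estimated entries are replaced by the estimates; FIX entries are
#' untouched. An unconverged fit leaves the guess unchanged.
#'
#' @param previous Current [population_parameters()] guess.
#' @param fit An `nlmem_fit`.
#' @return Updated [population_parameters()].
#' @export
update_guess <- function(previous, fit) {
  stopifnot(inherits(previous, "population_parameters"),
            inherits(fit, "nlmem_fit"))
  if (!fit$converged) return(previous)
  est <- c(fit$beta_hat, fit$lambda_hat)
  v <- theta_to_vector(previous)
  v[intersect(names(est), previous$estimated)] <-
    est[intersect(names(est), previous$estimated)]
  vector_to_theta(v, previous)
}

#' Update the design prior from a fit
#'
#' The prior mean becomes the estimates and the standard deviations the
#' square roots of the diagonal of the estimated fixed-effect covariance.
#' If the covariance is unavailable or was repaired, the previous
#' standard deviations are retained (the mean is still updated when the
#' fit converged).
#'
#' @param previous Current [parameter_prior()].
#' @param fit An `nlmem_fit`.
#' @return Updated [parameter_prior()].
#' @export
update_prior <- function(previous, fit) {
  stopifnot(inherits(previous, "parameter_prior"),
            inherits(fit, "nlmem_fit"))
  if (!fit$converged) return(previous)
  mean <- fit$beta_hat[names(previous$mean)]
  sd <- previous$sd
  # a degenerate (all-zero sd) prior is a point prior by construction and
  # stays one, so a zero-uncertainty configuration keeps ELD == lnD
  if (any(previous$sd > 0) &&
      !is.null(fit$cov_beta) && identical(fit$cov_repaired, FALSE)) {
    sd <- sqrt(pmax(diag(fit$cov_beta)[names(previous$mean)], 0))
  }
  parameter_prior(mean, sd = sd)
}

#' Run one model-based adaptive optimal design replicate
#'
#' The adaptive loop: cohort 1 uses the fixed initial design; every
#' subsequent cohort optimizes the new group's dose under the current
#' criterion and parameter guess, simulates the new subjects at the true
#' parameters, re-estimates the model on all accumulated data, evaluates
#' the stopping criterion, and updates the guess (and, for ELD, the
#' prior). The loop terminates when the stopping criterion is met or the
#' maximum number of cohorts is reached.
#'
#' All randomness derives from `(config$seed, replicate)` with
#' independent per-cohort substreams for data simulation, the LHS draws,
#' estimation retry jitter, and the stopping draws, so replicates are
#' independent and bitwise reproducible.
#'
#' @param config An [mbaod_config()].
#' @param replicate Replicate index (>= 1), part of the seed stream.
#'
#' @return A list of class `trial_history`: `config`, `cohorts` (one
#'   record per cohort: chosen dose, criterion value, fit, stopping
#'   report, cumulative design, ln-determinant of the cumulative FIM at
#'   the true parameters), `status` (`"stopped"` or
#'   `"max_cohorts_reached"`), and `n_id`.
#' @export
#' @examples
#' cfg <- mbaod_config(max_cohorts = 2, n_stop_sim = 500)
#' h <- run_mbaod(cfg, replicate = 1)
#' tidy(h)
run_mbaod <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "mbaod_config"), replicate >= 1)
  times <- schedule_times(config$schedule)
  guess <- config$theta_init
  prior <- parameter_prior(beta_estimates(guess), cv = config$prior_cv)
  design <- config$init_design
  data <- NULL
  cohorts <- list()
  status <- "max_cohorts_reached"
  last_fit <- NULL

  for (k in seq_len(config$max_cohorts)) {
    rs <- function(tag) derive_seed(config$seed, replicate, k, tag)

    if (k == 1L) {
      new_design <- design
      chosen <- NA_integer_
      crit_val <- NA_real_
      trace <- NULL
    } else {
      opt <- optimize_next_dose(
        criterion = config$criterion, theta = guess, base_design = design,
        new_group_n = config$cohort_n, times = times, grid = config$grid,
        prior = if (config$criterion == "ELD") prior,
        n_samples = config$n_lhs, seed = rs(1))
      chosen <- opt$dose
      crit_val <- opt$objective
      trace <- opt$trace
      new_design <- study_design(chosen, config$cohort_n, times)
      design <- add_group(design, chosen, config$cohort_n, times)
    }

    new_data <- simulate_dataset(new_design, config$theta_true,
                                 seed = rs(2), cohort = k,
                                 id_offset = if (is.null(data)) 0L else
                                   max(data$id))
    data <- if (is.null(data)) new_data else {
      out <- dplyr::bind_rows(data, new_data)
      class(out) <- c("trial_data", class(out))
      out
    }

    fit <- fit_nlmem(data, init = guess, method = config$method,
                     seed = rs(3))
    fit$objective <- NULL  # drop the closure from the stored record
    use_fit <- if (fit$converged) fit else last_fit
    if (fit$converged) last_fit <- fit

    # stopping evaluation (deferred while df <= 2 or without a usable fit)
    report <- NULL
    stopped <- FALSE
    if (!is.null(use_fit) && !is.null(use_fit$cov_beta)) {
      n_beta <- length(use_fit$beta_hat)
      n_lambda <- length(use_fit$lambda_hat)
      df <- tryCatch(degrees_of_freedom(design_n(design), n_beta, n_lambda),
                     error = function(e) NULL)
      if (!is.null(df) && df > 2) {
        S <- scale_matrix(use_fit$cov_beta, df)
        S <- nearest_psd(S)$mat
        sim_beta <- sample_fixed_effects(use_fit$beta_hat, S, df,
                                         n = config$n_stop_sim,
                                         seed = rs(4))
        sim_beta[sim_beta <= 0] <- .Machine$double.eps
        report <- evaluate_stopping(sim_beta, config$theta_true, design,
                                    beta_ref = use_fit$beta_hat,
                                    band = config$band,
                                    level = config$level)
        attr(report, "df") <- df
        stopped <- attr(report, "stop")
      }
    }

    ld_true <- lnd_objective(config$theta_true, design)
    cohorts[[k]] <- list(cohort = k, dose = chosen, criterion = crit_val,
                         trace = trace, fit = fit,
                         used_previous_fit = !fit$converged,
                         stopping = report, design = design,
                         logdet_fim_true = ld_true)

    if (!is.null(use_fit)) {
      guess <- update_guess(guess, use_fit)
      prior <- update_prior(prior, use_fit)
    }
    if (stopped) { status <- "stopped"; break }
  }

  structure(list(config = config, replicate = as.integer(replicate),
                 cohorts = cohorts, status = status,
                 n_id = design_n(design), data = data,
                 final_design = design, final_guess = guess),
            class = "trial_history")
}

#' Tidy a trial history into one row per cohort
#'
#' @param x A `trial_history`.
#' @param ... Unused.
#' @return A tibble: `cohort`, `dose` (NA for the fixed first cohort),
#'   `n_id`, `criterion`, `ofv`, `converged`, `stop_eval`, `stopped`,
#'   `logdet_fim_true`, and one column per estimated parameter.
#' @method tidy trial_history
#' @export
tidy.trial_history <- function(x, ...) {
  purrr::map_dfr(x$cohorts, function(co) {
    est <- c(co$fit$beta_hat, co$fit$lambda_hat)
    tibble::tibble(
      cohort = co$cohort, dose = co$dose, n_id = design_n(co$design),
      criterion = co$criterion, ofv = co$fit$ofv,
      converged = co$fit$converged,
      stop_eval = !is.null(co$stopping),
      stopped = if (is.null(co$stopping)) FALSE else
        attr(co$stopping, "stop"),
      logdet_fim_true = co$logdet_fim_true,
      !!!as.list(est))
  })
}

#' One-row summary of a trial history
#' @param x A `trial_history`.
#' @param ... Unused.
#' @return A tibble: `criterion`, `schedule`, `cohorts`, `n_id`, `status`.
#' @method glance trial_history
#' @export
glance.trial_history <- function(x, ...) {
  tibble::tibble(criterion = x$config$criterion,
                 schedule = x$config$schedule,
                 cohorts = length(x$cohorts), n_id = x$n_id,
                 status = x$status)
}

#' @export
print.trial_history <- function(x, ...) {
  cat("<trial_history>", x$config$criterion, "/", x$config$schedule,
      "|", length(x$cohorts), "cohorts |", x$n_id, "subjects |",
      x$status, "\n")
  invisible(x)
}
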