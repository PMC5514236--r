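#' lnD-optimality objective of a design
#'
#' The log determinant of the block-diagonal population FIM at a point
#' parameter guess. Designs whose FIM is singular (or numerically
#' indefinite) map to `-Inf`, so a grid search simply never prefers them.
#'
#' @param theta [population_parameters()].
#' @param design A [study_design()].
#' @return `ln|FIM|`, a scalar (possibly `-Inf`).
#' @export
lnd_objective <- function(theta, design) {
  Fm <- tryCatch(population_fim(theta, design, form = "block_diag"),
                 error = function(e) NULL)
  if (is.null(Fm)) return(-Inf)
  log_det(unclass(Fm))
}

#' Normal prior on the estimated fixed effects
#'
#' The robust (ELD) criterion integrates the design objective over an
#' independent normal prior on each estimated fixed effect. With all
#' standard deviations zero the prior is degenerate and ELD collapses to
#' lnD at the mean.
#'
#' @param mean Named numeric vector over the estimated fixed effects.
#' @param sd Matching named standard deviations (>= 0). A single number is
#'   interpreted as a coefficient of variation times `mean` (see `cv`).
#' @param cv Alternatively, a coefficient of variation from which
#'   `sd = cv * mean` is computed.
#' @return A list of class `parameter_prior`.
#' @export
#' @examples
#' th <- scenario_parameters(guess = TRUE)
#' parameter_prior(beta_estimates(th), cv = 0.10)
parameter_prior <- function(mean, sd = NULL, cv = NULL) {
  stopifnot(is.numeric(mean), !is.null(names(mean)))
  if (is.null(sd)) {
    stopifnot(!is.null(cv), cv >= 0)
    sd <- cv * abs(mean)
  }
  sd <- sd[names(mean)]
  stopifnot(all(is.finite(sd)), all(sd >= 0))
  structure(list(mean = mean, sd = stats::setNames(sd, names(mean))),
            class = "parameter_prior")
}

#' Estimated fixed effects of a parameter set, as a named vector
#' @param theta [population_parameters()].
#' @return Named numeric vector over the estimated fixed effects.
#' @export
beta_estimates <- function(theta) {
  eb <- estimated_beta(theta)
  stats::setNames(unclass(theta$fixed)[eb], eb)
}

#' Latin hypercube sample from the fixed-effect prior
#'
#' Stratified sampling: per dimension, exactly one draw falls in each of
#' the `n` equal-probability strata of the marginal normal. Sampled values
#' that violate the model's positivity requirements (a negative fixed
#' effect) are redrawn uniformly within their stratum; the number of
#' redraws is recorded in the `"n_redrawn"` attribute.
#'
#' @param prior A [parameter_prior()].
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return A list of `n` named fixed-effect vectors.
#' @export
lhs_sample <- function(prior, n, seed) {
  stopifnot(inherits(prior, "parameter_prior"), n >= 1)
  d <- length(prior$mean)
  set.seed(derive_seed(seed, 104729))
  U <- lhs::randomLHS(n, d)
  redrawn <- 0L
  out <- vector("list", n)
  vals <- matrix(0, n, d, dimnames = list(NULL, names(prior$mean)))
  for (j in seq_len(d)) {
    x <- stats::qnorm(U[, j], prior$mean[j], prior$sd[j])
    if (any(bad <- x <= 0)) {
      # redraw within the same stratum; give up after 100 tries and clamp
      stratum <- floor(U[, j] * n) / n
      for (i in which(bad)) {
        ok <- FALSE
        for (k in 1:100) {
          u <- stratum[i] + stats::runif(1) / n
          cand <- stats::qnorm(u, prior$mean[j], prior$sd[j])
          if (cand > 0) { x[i] <- cand; ok <- TRUE; break }
        }
        if (!ok) x[i] <- .Machine$double.eps * max(1, abs(prior$mean[j]))
        redrawn <- redrawn + 1L
      }
    }
    vals[, j] <- x
  }
  for (i in seq_len(n)) out[[i]] <- vals[i, ]
  attr(out, "n_redrawn") <- redrawn
  out
}

#' ELD (robust) design objective
#'
#' The expectation over the fixed-effect prior of the lnD objective,
#' approximated by the mean over a set of prior samples (typically a
#' Latin hypercube sample). Variance parameters and known (FIX) fixed
#' effects are taken from `theta_rest`. Samples with singular FIM
#' contribute `-Inf`, making the candidate design non-preferred.
#'
#' @param prior The [parameter_prior()] the samples were drawn from (kept
#'   with the call for auditability; the integration itself uses `samples`).
#' @param theta_rest [population_parameters()] supplying everything except
#'   the sampled fixed effects.
#' @param design A [study_design()].
#' @param samples List of fixed-effect vectors, e.g. from [lhs_sample()].
#' @return The Monte-Carlo expectation of `ln|FIM|`.
#' @export
eld_objective <- function(prior, theta_rest, design, samples) {
  stopifnot(length(samples) >= 1)
  vals <- vapply(samples, function(b) {
    lnd_objective(set_fixed_effects(theta_rest, b), design)
  }, numeric(1))
  mean(vals)
}

#' Optimize the next cohort's dose over a discrete grid
#'
#' Exhaustively evaluates the design criterion for the cumulative design
#' plus one new group of `new_group_n` individuals at every candidate
#' dose, and returns the arg-max. Ties break toward the lowest dose. For
#' the ELD criterion one common set of Latin hypercube draws is used for
#' all candidate doses, so the comparison between doses is not perturbed
#' by Monte-Carlo noise.
#'
#' @param criterion `"lnD"` or `"ELD"`.
#' @param theta Current parameter guess ([population_parameters()]);
#'   supplies the FIX parameters and variances in both criteria.
#' @param base_design Cumulative [study_design()] of all prior cohorts.
#' @param new_group_n Size of the new group (default 2).
#' @param times Sampling schedule of the new group, hours.
#' @param grid Candidate doses, mg (default all integers 0..500).
#' @param prior A [parameter_prior()] (required for ELD).
#' @param n_samples Number of LHS draws for ELD (default 10).
#' @param seed Integer seed (ELD draws).
#'
#' @return A list with elements `dose`, `objective`, and `trace` (a tibble
#'   of every candidate dose and its criterion value — the exhaustiveness
#'   certificate).
#' @export
optimize_next_dose <- function(criterion = c("lnD", "ELD"), theta,
                               base_design, new_group_n = 2L, times,
                               grid = 0:500, prior = NULL,
                               n_samples = 10L, seed = 1L) {
  criterion <- match.arg(criterion)
  grid <- sort(unique(as.integer(grid)))
  stopifnot(length(grid) >= 1, inherits(base_design, "study_design"))

  if (criterion == "ELD") {
    stopifnot(inherits(prior, "parameter_prior"))
    samples <- lhs_sample(prior, n_samples, seed)
    thetas <- lapply(samples, function(b) set_fixed_effects(theta, b))
  } else {
    thetas <- list(theta)
  }
  # the cumulative-design FIM is constant across candidate doses, and the
  # candidate-group FIMs are evaluated for the whole grid in one batch
  base_fims <- lapply(thetas, function(th) tryCatch(
    unclass(population_fim(th, base_design, form = "block_diag")),
    error = function(e) NULL))
  grid_fims <- lapply(thetas, function(th) tryCatch(
    .batch_block_fims(th, grid, times),
    error = function(e) NULL))

  vals <- vapply(seq_along(grid), function(d) {
    vapply(seq_along(thetas), function(s) {
      Fg <- if (is.null(grid_fims[[s]])) NULL else grid_fims[[s]][[d]]
      if (is.null(Fg) || is.null(base_fims[[s]])) return(-Inf)
      log_det(base_fims[[s]] + new_group_n * Fg)
    }, numeric(1))
  }, numeric(length(thetas)))
  vals <- matrix(vals, nrow = length(thetas))
  # a prior sample that is singular at every candidate dose carries no
  # design information (it reflects the sample, not the design) and is
  # excluded from the expectation; a dose-specific singularity still
  # demotes that dose to -Inf
  degenerate <- apply(vals, 1, function(v) all(v == -Inf))
  keep <- if (all(degenerate)) seq_along(thetas) else which(!degenerate)
  obj <- colMeans(vals[keep, , drop = FALSE])
  best <- which.max(obj)  # first maximum = lowest dose on ties
  list(dose = grid[best], objective = obj[best],
       trace = tibble::tibble(dose = grid, objective = obj),
       n_degenerate_samples = sum(degenerate))
}
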