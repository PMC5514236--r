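#' Degrees of freedom of the stopping-rule t-distribution
#'
#' `df = n_id - (n_beta + n_lambda / 2)`: the cumulative number of
#' included individuals penalized by the number of estimated fixed
#' effects and half the number of estimated variance parameters. May be
#' fractional.
#'
#' @param n_id Cumulative number of included individuals.
#' @param n_beta Number of estimated fixed effects.
#' @param n_lambda Number of estimated variance parameters.
#' @return The (possibly fractional) degrees of freedom.
#' @export
#' @examples
#' degrees_of_freedom(8, 4, 3)   # 2.5
degrees_of_freedom <- function(n_id, n_beta, n_lambda) {
  stopifnot(n_id >= 0, n_beta >= 0, n_lambda >= 0)
  df <- n_id - (n_beta + n_lambda / 2)
  if (df <= 0) {
    stop("too few subjects: df = ", df, " (needs n_id > n_beta + n_lambda/2)",
         call. = FALSE)
  }
  df
}

#' Scale matrix of the multivariate t parameter distribution
#'
#' `S = COV * (df - 2) / df`, so that a multivariate t with scale `S` and
#' `df` degrees of freedom has covariance exactly `COV` (the estimated
#' fixed-effect covariance).
#'
#' @param cov_beta Fixed-effect covariance matrix.
#' @param df Degrees of freedom, must exceed 2 (otherwise the t
#'   distribution has no finite covariance and the evaluation is
#'   deferred by the caller).
#' @return The scale matrix, symmetric PSD.
#' @export
scale_matrix <- function(cov_beta, df) {
  if (df <= 2) {
    stop("df must exceed 2 for the scale matrix (got ", df, ")",
         call. = FALSE)
  }
  S <- cov_beta * (df - 2) / df
  (S + t(S)) / 2
}

#' Simulate fixed-effect vectors from the multivariate t
#'
#' Draws `n` parameter vectors from a shifted multivariate Student t with
#' location `beta_hat`, scale matrix `S` and `df` degrees of freedom
#' (so the draw covariance is `S * df / (df - 2)`).
#'
#' @param beta_hat Named location vector (the estimates).
#' @param S Scale matrix from [scale_matrix()].
#' @param df Degrees of freedom.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return An `n` x `length(beta_hat)` matrix with named columns.
#' @export
sample_fixed_effects <- function(beta_hat, S, df, n, seed) {
  stopifnot(n >= 1, df > 0)
  p <- length(beta_hat)
  set.seed(derive_seed(seed, 15013))
  if (all(S == 0)) {
    draws <- matrix(rep(beta_hat, each = n), n, p)
  } else {
    draws <- mvtnorm::rmvt(n, sigma = S, df = df, delta = beta_hat,
                           type = "shifted")
  }
  colnames(draws) <- names(beta_hat)
  draws
}

#' Evaluate the effect-prediction stopping criterion
#'
#' For every dose arm included so far and every time of its sampling
#' schedule, the typical-individual (eta = 0) effect is computed under
#' each simulated fixed-effect vector; the empirical 95% (or `level`) CI
#' of those predictions is compared with the band
#' `[band[1] * ref, band[2] * ref]` around the reference prediction at
#' the estimates. The trial stops when every CI lies inside its band
#' (closed intervals). A zero reference makes the band undefined; that
#' point fails with a warning.
#'
#' @param sim_beta Matrix of simulated fixed-effect vectors
#'   ([sample_fixed_effects()]), columns named by parameter.
#' @param theta_rest [population_parameters()] supplying the FIX
#'   parameters (notably the PK fixed effects).
#' @param design Cumulative [study_design()] (all dose arms so far).
#' @param beta_ref Named vector of reference fixed-effect estimates.
#' @param band Lower and upper band multipliers, default `c(0.6, 1.4)`.
#' @param level CI level, default 0.95.
#'
#' @return A tibble of class `stopping_report` with one row per
#'   (dose, time): `lo`, `hi` (CI), `ref`, `within`; the overall decision
#'   is in attribute `"stop"`.
#' @export
evaluate_stopping <- function(sim_beta, theta_rest, design, beta_ref,
                              band = c(0.6, 1.4), level = 0.95) {
  stopifnot(is.matrix(sim_beta), nrow(sim_beta) >= 1,
            band[1] < 1, band[2] > 1, level > 0, level < 1)
  arms <- dplyr::distinct(
    tidyr::unnest(tibble::as_tibble(design)[, c("dose", "times")],
                  cols = "times"))
  fx_ref <- theta_rest$fixed
  fx_ref[names(beta_ref)] <- beta_ref
  alpha <- (1 - level) / 2
  rows <- vector("list", nrow(arms))
  for (i in seq_len(nrow(arms))) {
    dose <- arms$dose[[i]]; tt <- arms$times[[i]]
    conc <- pk_concentration(tt, dose, cl = fx_ref[["cl"]],
                             v = fx_ref[["v"]], ka = fx_ref[["ka"]])
    resp <- effect_mean(conc,
                        base = sim_beta[, "base"],
                        emax = sim_beta[, "emax"],
                        ec50 = sim_beta[, "ec50"],
                        gamma = sim_beta[, "gamma"])
    ci <- stats::quantile(resp, c(alpha, 1 - alpha), names = FALSE)
    ref <- effect_mean(conc, base = fx_ref[["base"]], emax = fx_ref[["emax"]],
                       ec50 = fx_ref[["ec50"]], gamma = fx_ref[["gamma"]])
    if (ref == 0) {
      warning("reference prediction is 0 at dose ", dose, ", t = ", tt,
              "; band undefined, point fails", call. = FALSE)
      within <- FALSE
    } else {
      lim <- sort(band * ref)
      # closed interval with a relative epsilon so an exactly-touching
      # CI limit is within the band despite rounding
      tol <- 1e-9 * abs(ref)
      within <- ci[1] >= lim[1] - tol && ci[2] <= lim[2] + tol
    }
    rows[[i]] <- tibble::tibble(dose = dose, time = tt, lo = ci[1],
                                hi = ci[2], ref = ref, within = within)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stopping_report", class(out))
  attr(out, "stop") <- all(out$within)
  attr(out, "n_sim") <- nrow(sim_beta)
  out
}

#' @export
print.stopping_report <- function(x, ...) {
  cat("<stopping_report> stop =", attr(x, "stop"),
      "| n_sim =", attr(x, "n_sim"), "\n")
  NextMethod()
}
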