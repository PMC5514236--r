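# ---- parameter transforms -------------------------------------------------
# Estimation works on an unconstrained scale: identity for the baseline,
# log for everything else (positive by construction). Reported estimates
# and covariances are on the natural scale (delta method).

.log_scale <- function(par) par != "base"

trans_par <- function(x, names) {
  ifelse(.log_scale(names), log(x), x)
}

untrans_par <- function(p, names) {
  ifelse(.log_scale(names), exp(p), p)
}

# d(natural)/d(transformed), evaluated at the natural value
.trans_jac <- function(x, names) {
  ifelse(.log_scale(names), x, 1)
}

# set the estimated entries of theta from a natural-scale named vector
.theta_with_estimates <- function(theta, est) {
  v <- theta_to_vector(theta)
  v[names(est)] <- est
  vector_to_theta(v, theta)
}

# ---- data layout ----------------------------------------------------------
# split a trial_data tibble into per-group (FO) and per-subject (FOCEI)
# structures; subjects sharing (dose, times) form one group
.prep_data <- function(data) {
  stopifnot(all(c("id", "dose", "time", "dv") %in% names(data)),
            nrow(data) > 0)
  data <- dplyr::arrange(data, .data$id, .data$time)
  subjects <- lapply(split(data, data$id), function(d) {
    list(id = d$id[[1]], dose = d$dose[[1]], times = d$time, y = d$dv)
  })
  keys <- vapply(subjects, function(s)
    paste(s$dose, paste(s$times, collapse = ","), sep = "|"), character(1))
  groups <- lapply(split(seq_along(subjects), keys), function(idx) {
    s1 <- subjects[[idx[1]]]
    Y <- t(vapply(subjects[idx], function(s) s$y, numeric(length(s1$times))))
    list(dose = s1$dose, times = s1$times, Y = Y)
  })
  list(subjects = subjects, groups = groups, n_id = length(subjects),
       n_obs = nrow(data))
}

# ---- FO marginal -2 log likelihood ---------------------------------------
.ofv_fo <- function(theta, groups) {
  total <- 0
  for (g in groups) {
    mom <- tryCatch(fo_moments(theta, g$dose, g$times),
                    error = function(e) NULL)
    if (is.null(mom)) return(Inf)
    ch <- tryCatch(chol(mom$var), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    Vi <- chol2inv(ch)
    R <- sweep(g$Y, 2, mom$mean)
    quad <- sum((R %*% Vi) * R)
    total <- total + nrow(g$Y) *
      (2 * sum(log(diag(ch))) + length(g$times) * log(2 * pi)) + quad
  }
  total
}

# ---- FOCEI approximate -2 log likelihood ---------------------------------
# per-subject Laplace-type approximation expanded at the empirical-Bayes
# mode, with interaction (residual variance at the conditional prediction)
# and a Gauss-Newton approximation of the inner Hessian
.ofv_focei <- function(theta, subjects, warm) {
  beta <- theta$fixed
  om <- theta$random$omega2[.eta_names]
  sa <- theta$random$sigma2_add
  sp <- theta$random$sigma2_prop
  active <- om > 0
  k <- sum(active)
  total <- 0
  for (s in subjects) {
    inner <- function(e) {
      eta <- stats::setNames(numeric(4), .eta_names)
      eta[active] <- e
      # extreme eta can cross the PK degeneracy v*ka = cl; penalize
      f <- tryCatch(individual_response(s$times, s$dose, beta, eta),
                    error = function(err) NULL)
      if (is.null(f) || any(!is.finite(f))) return(1e10)
      Rv <- sp * f^2 + sa
      if (any(Rv <= 0)) return(1e10)
      r <- s$y - f
      sum(r^2 / Rv) + sum(log(Rv)) + sum(e^2 / om[active])
    }
    key <- as.character(s$id)
    e0 <- warm[[key]] %||% numeric(k)
    opt <- if (k > 0) {
      stats::optim(e0, inner, method = "BFGS",
                   control = list(maxit = 100, reltol = 1e-10))
    } else list(par = numeric(0), value = inner(numeric(0)))
    warm[[key]] <- opt$par
    eta <- stats::setNames(numeric(4), .eta_names)
    eta[active] <- opt$par
    f <- tryCatch(individual_response(s$times, s$dose, beta, eta),
                  error = function(err) NULL)
    if (is.null(f)) return(Inf)
    Rv <- sp * f^2 + sa
    if (any(Rv <= 0)) return(Inf)
    r <- s$y - f
    # Jacobian of the conditional prediction w.r.t. the active etas
    G <- matrix(0, length(s$times), k)
    if (k > 0) {
      ia <- which(active)
      for (j in seq_len(k)) {
        h <- 1e-5
        ep <- eta; ep[ia[j]] <- eta[ia[j]] + h
        em <- eta; em[ia[j]] <- eta[ia[j]] - h
        g <- tryCatch(
          (individual_response(s$times, s$dose, beta, ep) -
             individual_response(s$times, s$dose, beta, em)) / (2 * h),
          error = function(err) NULL)
        if (is.null(g)) return(Inf)
        G[, j] <- g
      }
    }
    H <- t(G) %*% (G / Rv) + diag(1 / om[active], nrow = k)
    ldH <- if (k > 0) log_det_pd(H) else 0
    if (!is.finite(ldH)) return(Inf)
    total <- total + length(s$times) * log(2 * pi) + sum(log(Rv)) +
      sum(r^2 / Rv) + sum(log(om[active])) + sum(eta[active]^2 / om[active]) +
      ldH
  }
  total
}

# objective on the transformed scale for a given method
.make_objective <- function(theta0, est_names, prep, method) {
  warm <- new.env(parent = emptyenv())
  function(p) {
    est <- stats::setNames(untrans_par(p, est_names), est_names)
    if (any(!is.finite(est))) return(1e10)
    th <- tryCatch(.theta_with_estimates(theta0, est),
                   error = function(e) NULL)
    if (is.null(th)) return(1e10)
    val <- if (method == "FO") .ofv_fo(th, prep$groups) else
      .ofv_focei(th, prep$subjects, warm)
    if (!is.finite(val)) 1e10 else val
  }
}

#' Fit the nonlinear mixed-effects model by approximate maximum likelihood
#'
#' Maximizes an approximate marginal likelihood of the PKPD model over the
#' estimated parameters (all FIX parameters held at their values in
#' `init`). Two approximations are available: `FO` linearizes the model at
#' `eta = 0` (marginally normal observations with the moments of
#' [fo_moments()]); `FOCEI` uses a Laplace-type approximation expanded at
#' each subject's empirical-Bayes mode with interaction (residual variance
#' at the conditional prediction).
#'
#' Variance parameters, EC50, gamma and EMAX are optimized on the log
#' scale to enforce positivity; the baseline on the identity scale. On
#' optimizer failure the fit is retried up to 3 times from inits jittered
#' by 10% multiplicative noise; if all attempts fail the result carries
#' `converged = FALSE` rather than raising.
#'
#' @param data A `trial_data` tibble (columns `id`, `dose`, `time`, `dv`).
#' @param init [population_parameters()]: initial values, FIX values, and
#'   the estimated-parameter set.
#' @param method `"FO"` or `"FOCEI"`.
#' @param seed Integer seed (used only for retry jitter).
#' @param compute_cov Compute the fixed-effect covariance via
#'   [estimate_covariance()] and attach it (default `TRUE`).
#'
#' @return An object of class `nlmem_fit`: estimates on the natural scale
#'   (`beta_hat`, `lambda_hat`, full `theta_hat`), the objective value
#'   `ofv` (-2 log likelihood), `cov_beta`, and bookkeeping fields
#'   (`converged`, `n_id`, `n_obs`, `method`).
#' @export
#' @examples
#' d <- simulate_dataset(initial_design("sparse"), scenario_parameters(),
#'                       seed = 1)
#' fit <- fit_nlmem(d, scenario_parameters(guess = TRUE), method = "FO")
#' tidy(fit)
fit_nlmem <- function(data, init, method = c("FO", "FOCEI"), seed = 1L,
                      compute_cov = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(init, "population_parameters"))
  if (nrow(data) == 0) stop("empty dataset", call. = FALSE)
  prep <- .prep_data(data)
  est_names <- init$estimated
  v0 <- theta_to_vector(init)[est_names]
  if (any(.log_scale(est_names) & v0 <= 0)) {
    stop("initial values for log-scale parameters must be positive",
         call. = FALSE)
  }
  obj <- .make_objective(init, est_names, prep, method)

  attempt_fit <- function(start_nat) {
    p0 <- trans_par(start_nat, est_names)
    o1 <- stats::optim(p0, obj, method = "Nelder-Mead",
                       control = list(maxit = 750, reltol = 1e-9))
    o2 <- stats::optim(o1$par, obj, method = "BFGS",
                       control = list(maxit = 100, reltol = 1e-9))
    if (o2$value <= o1$value) o2 else o1
  }

  ofv0 <- obj(trans_par(v0, est_names))
  best <- NULL
  for (try in 0:3) {
    start <- if (try == 0) v0 else {
      set.seed(derive_seed(seed, 7001, try))
      v0 * exp(stats::rnorm(length(v0), 0, 0.1))
    }
    res <- tryCatch(attempt_fit(start), error = function(e) NULL)
    ok <- !is.null(res) && is.finite(res$value) && res$value < 1e9 &&
      res$value <= ofv0 + 1e-6
    if (ok && (is.null(best) || res$value < best$value)) best <- res
    if (!is.null(best)) break  # stop at the first successful attempt
  }
  converged <- !is.null(best)
  if (!converged) {
    best <- list(par = trans_par(v0, est_names), value = ofv0)
  }

  est <- stats::setNames(untrans_par(best$par, est_names), est_names)
  theta_hat <- .theta_with_estimates(init, est)
  fit <- structure(list(
    theta_hat = theta_hat,
    beta_hat = est[intersect(est_names, .beta_names)],
    lambda_hat = est[intersect(est_names, .lambda_names)],
    ofv = best$value,
    converged = converged,
    n_id = prep$n_id,
    n_obs = prep$n_obs,
    method = method,
    estimated = est_names,
    objective = obj,
    par_opt = best$par,
    cov_beta = NULL,
    cov_repaired = NA
  ), class = "nlmem_fit")
  if (compute_cov && converged) {
    cv <- tryCatch(estimate_covariance(fit), error = function(e) NULL)
    if (!is.null(cv)) {
      fit$cov_beta <- cv$cov_beta
      fit$cov_repaired <- cv$repaired
    }
  }
  fit
}

#' Fixed-effect covariance matrix from the observed information
#'
#' Computes the Hessian of the fitted objective (-2 log likelihood) at
#' the optimum by central finite differences on the transformed scale,
#' inverts the full observed information, maps the covariance back to the
#' natural scale by the delta method, and extracts the block of the
#' estimated fixed effects. A non-positive-definite Hessian is repaired
#' by clipping its eigenvalues at 1e-10 and the result is flagged.
#'
#' @param fit An `nlmem_fit`.
#' @return A list: `cov_beta` (matrix over the estimated fixed effects),
#'   `cov_all` (all estimated parameters, natural scale), and `repaired`.
#' @export
estimate_covariance <- function(fit) {
  stopifnot(inherits(fit, "nlmem_fit"))
  if (!fit$converged) stop("fit did not converge; no covariance",
                           call. = FALSE)
  H <- numDeriv::hessian(fit$objective, fit$par_opt)
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE)
  repaired <- any(ev$values <= 0)
  if (repaired) {
    warning("observed information not positive definite; ",
            "eigenvalues clipped at 1e-10", call. = FALSE)
    H <- ev$vectors %*% (pmax(ev$values, 1e-10) * t(ev$vectors))
  }
  # information = Hessian(-logL) = Hessian(OFV)/2, so COV = 2 * H^-1
  cov_t <- 2 * chol2inv(chol(H))
  est_names <- fit$estimated
  nat <- stats::setNames(untrans_par(fit$par_opt, est_names), est_names)
  J <- .trans_jac(nat, est_names)
  cov_nat <- cov_t * tcrossprod(J)
  dimnames(cov_nat) <- list(est_names, est_names)
  eb <- intersect(est_names, .beta_names)
  list(cov_beta = cov_nat[eb, eb, drop = FALSE], cov_all = cov_nat,
       repaired = repaired)
}

# ---- broom-style methods --------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an NLMEM fit into one row per estimated parameter
#'
#' @param x An `nlmem_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`
#'   (fixed effects only, `NA` elsewhere).
#' @method tidy nlmem_fit
#' @export
tidy.nlmem_fit <- function(x, ...) {
  est <- c(x$beta_hat, x$lambda_hat)
  se <- rep(NA_real_, length(est))
  names(se) <- names(est)
  if (!is.null(x$cov_beta)) {
    se[colnames(x$cov_beta)] <- sqrt(pmax(diag(x$cov_beta), 0))
  }
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se))
}

#' One-row summary of an NLMEM fit
#'
#' @param x An `nlmem_fit`.
#' @param ... Unused.
#' @return A tibble with `ofv`, `converged`, `n_id`, `n_obs`, `method`.
#' @method glance nlmem_fit
#' @export
glance.nlmem_fit <- function(x, ...) {
  tibble::tibble(ofv = x$ofv, converged = x$converged, n_id = x$n_id,
                 n_obs = x$n_obs, method = x$method)
}

#' @export
print.nlmem_fit <- function(x, ...) {
  cat("<nlmem_fit>", x$method, "| OFV", format(x$ofv, digits = 8),
      "| n_id", x$n_id, "| converged:", x$converged, "\n")
  print(tidy(x))
  invisible(x)
}

#' Serialize an estimation result to JSON (and back)
#'
#' @param fit An `nlmem_fit`.
#' @param path File path.
#' @return `path` invisibly; `read_estimation_json` returns a list with
#'   the stored fields (not a re-fittable object).
#' @export
write_estimation_json <- function(fit, path) {
  out <- list(
    method = fit$method,
    beta_hat = as.list(fit$beta_hat),
    lambda_hat = as.list(fit$lambda_hat),
    ofv = fit$ofv,
    converged = fit$converged,
    n_id = fit$n_id,
    n_obs = fit$n_obs,
    cov_beta = if (!is.null(fit$cov_beta)) {
      list(names = colnames(fit$cov_beta),
           values = as.vector(fit$cov_beta))
    },
    cov_repaired = fit$cov_repaired
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_estimation_json
#' @export
read_estimation_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$cov_beta)) {
    n <- length(x$cov_beta$names)
    x$cov_beta <- matrix(x$cov_beta$values, n, n,
                         dimnames = list(x$cov_beta$names, x$cov_beta$names))
  }
  x$beta_hat <- unlist(x$beta_hat)
  x$lambda_hat <- unlist(x$lambda_hat)
  x
}
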