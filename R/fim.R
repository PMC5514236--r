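#' First-order moment approximation of a dose group's response
#'
#' Linearizes the mixed-effects response around the typical values
#' `eta = 0`, `eps = 0` (the FO approximation): the expected response is
#' the typical-individual prediction, and the variance is
#' `L Omega L' + diag(sigma2_prop * f^2 + sigma2_add)` where `L` is the
#' Jacobian of the response with respect to the random effects at
#' `eta = 0` and `f` the typical prediction.
#'
#' @param theta [population_parameters()].
#' @param dose Group dose, mg.
#' @param times Sampling times, hours.
#'
#' @return A list of class `fo_moments` with elements `mean` (length-T
#'   vector), `var` (T x T matrix) and `jac_eta` (T x 4 Jacobian).
#' @export
fo_moments <- function(theta, dose, times) {
  beta <- theta$fixed
  f0 <- typical_response(times, dose, beta)
  resp_eta <- function(eta) individual_response(times, dose, beta,
                                                stats::setNames(eta, .eta_names))
  L <- matrix(0, length(times), 4, dimnames = list(NULL, .eta_names))
  e0 <- numeric(4)
  for (k in 1:4) {
    L[, k] <- central_diff(resp_eta, e0, k, floor = 1e-5)
  }
  V <- .assemble_var(L, f0, theta$random$omega2, theta$random$sigma2_add,
                     theta$random$sigma2_prop)
  if (!is.finite(log_det_pd(V))) {
    stop("FO variance not positive definite for dose ", dose, call. = FALSE)
  }
  structure(list(mean = f0, var = V, jac_eta = L), class = "fo_moments")
}

# V(y) from a linearization: linear in the variance parameters
.assemble_var <- function(L, f0, omega2, sigma2_add, sigma2_prop) {
  V <- L %*% (omega2[.eta_names] * t(L)) +
    diag(sigma2_prop * f0^2 + sigma2_add, nrow = length(f0))
  (V + t(V)) / 2
}

#' Assemble a Fisher information matrix from moment functions
#'
#' Generic FO-style information assembler for a marginally normal model
#' `y ~ N(E(beta), V(beta, lambda))`. Derivatives are taken by central
#' finite differences (relative step 1e-5, absolute floor 1e-8) with
#' respect to the supplied parameters only.
#'
#' The `block_diag` form is `1/2 diag(A, B)` with
#' `A = 2 (dE/dbeta)' V^-1 (dE/dbeta)` and
#' `B_ab = tr(dV/dlambda_a V^-1 dV/dlambda_b V^-1)`. The `full` form adds
#' `tr(dV/dbeta_a V^-1 dV/dbeta_b V^-1)` to `A` and the mixed
#' fixed-effect/variance block `C_ab = tr(dV/dbeta_a V^-1 dV/dlambda_b
#' V^-1)` off the diagonal.
#'
#' @param mean_fn Function of a named beta vector returning E(y).
#' @param var_fn Function of (beta, lambda) returning V(y).
#' @param beta Named numeric vector of fixed effects to differentiate.
#' @param lambda Named numeric vector of variance parameters to
#'   differentiate.
#' @param form `"block_diag"` or `"full"`.
#'
#' @return A symmetric `fim` matrix over `c(names(beta), names(lambda))`.
#' @export
#' @examples
#' # one-parameter linear model y = b*t + e: information = sum(t^2)/s2
#' fim_from_moments(function(b) b[["b"]] * c(1, 2, 3),
#'                  function(b, l) diag(l[["s2"]], 3),
#'                  beta = c(b = 1), lambda = c(s2 = 0.5))
fim_from_moments <- function(mean_fn, var_fn, beta, lambda,
                             form = c("block_diag", "full")) {
  form <- match.arg(form)
  eb <- names(beta); el <- names(lambda)
  nb <- length(eb); nl <- length(el)
  V <- var_fn(beta, lambda)
  Vi <- tryCatch(chol2inv(chol((V + t(V)) / 2)), error = function(e) NULL)
  if (is.null(Vi)) stop("singular model variance in FIM assembly",
                        call. = FALSE)

  M <- vapply(seq_len(nb),
              function(i) central_diff(mean_fn, beta, i),
              numeric(length(mean_fn(beta))))
  M <- matrix(M, ncol = nb, dimnames = list(NULL, eb))
  A <- 2 * t(M) %*% Vi %*% M

  dV_l <- lapply(seq_len(nl), function(i)
    central_diff(function(l) var_fn(beta, l), lambda, i))
  B <- matrix(0, nl, nl, dimnames = list(el, el))
  for (a in seq_len(nl)) {
    for (b in a:nl) {
      B[a, b] <- B[b, a] <- sum((Vi %*% dV_l[[a]] %*% Vi) * dV_l[[b]])
    }
  }

  Fm <- matrix(0, nb + nl, nb + nl, dimnames = list(c(eb, el), c(eb, el)))
  if (form == "full" && nb > 0) {
    dV_b <- lapply(seq_len(nb), function(i)
      central_diff(function(b) var_fn(b, lambda), beta, i))
    for (a in seq_len(nb)) {
      for (b in a:nb) {
        tr <- sum((Vi %*% dV_b[[a]] %*% Vi) * dV_b[[b]])
        A[a, b] <- A[a, b] + tr
        if (b > a) A[b, a] <- A[b, a] + tr
      }
    }
    if (nl > 0) {
      C <- matrix(0, nb, nl)
      for (a in seq_len(nb)) {
        for (b in seq_len(nl)) {
          C[a, b] <- sum((Vi %*% dV_b[[a]] %*% Vi) * dV_l[[b]])
        }
      }
      Fm[seq_len(nb), nb + seq_len(nl)] <- C
      Fm[nb + seq_len(nl), seq_len(nb)] <- t(C)
    }
  }
  if (nb > 0) Fm[seq_len(nb), seq_len(nb)] <- A
  if (nl > 0) Fm[nb + seq_len(nl), nb + seq_len(nl)] <- B
  Fm <- Fm / 2
  structure((Fm + t(Fm)) / 2, class = c("fim", "matrix", "array"),
            form = form)
}

#' Elementary (per-individual) Fisher information matrix
#'
#' The FO Fisher information of one individual on a group's elementary
#' design, over the estimated parameters only: parameters flagged as
#' known ("FIX") are excluded from differentiation entirely, not zeroed
#' out. The default `block_diag` form is the one the design criteria
#' maximize; the `full` form keeps the variance's sensitivity to the
#' fixed effects and the mixed block (see [fim_from_moments()]).
#'
#' @param theta [population_parameters()].
#' @param dose,times The group's elementary design.
#' @param form `"block_diag"` (default) or `"full"`.
#'
#' @return A symmetric `fim` matrix with parameter-name dimnames
#'   (estimated fixed effects first, then estimated variance parameters).
#' @export
elementary_fim <- function(theta, dose, times,
                           form = c("block_diag", "full")) {
  form <- match.arg(form)
  eb <- estimated_beta(theta)
  el <- estimated_lambda(theta)
  lam_full <- stats::setNames(theta_to_vector(theta)[el], el)

  mean_fn <- function(b) {
    fx <- theta$fixed
    fx[names(b)] <- b
    typical_response(times, dose, fx)
  }
  # cache the linearization: V depends on lambda only through Omega/Sigma,
  # so perturbing lambda can reuse the Jacobian computed at this beta
  cache <- new.env(parent = emptyenv())
  var_fn <- function(b, l) {
    key <- paste(format(b, digits = 17), collapse = ",")
    if (!identical(cache$key, key)) {
      th <- set_fixed_effects(theta, b)
      mom <- fo_moments(th, dose, times)
      cache$key <- key
      cache$L <- mom$jac_eta
      cache$f0 <- mom$mean
    }
    om <- theta$random$omega2
    sa <- theta$random$sigma2_add
    sp <- theta$random$sigma2_prop
    if ("omega2_emax" %in% names(l)) om[["emax"]] <- l[["omega2_emax"]]
    if ("omega2_ec50" %in% names(l)) om[["ec50"]] <- l[["omega2_ec50"]]
    if ("omega2_cl" %in% names(l)) om[["cl"]] <- l[["omega2_cl"]]
    if ("omega2_v" %in% names(l)) om[["v"]] <- l[["omega2_v"]]
    if ("sigma2_add" %in% names(l)) sa <- l[["sigma2_add"]]
    if ("sigma2_prop" %in% names(l)) sp <- l[["sigma2_prop"]]
    .assemble_var(cache$L, cache$f0, om, sa, sp)
  }
  beta0 <- stats::setNames(unclass(theta$fixed)[eb], eb)
  fim_from_moments(mean_fn, var_fn, beta0, lam_full, form)
}

#' Population Fisher information matrix of a study design
#'
#' The sum over groups of group size times the elementary FIM: the
#' information carried by the whole design under the FO approximation.
#'
#' @param theta [population_parameters()].
#' @param design A [study_design()].
#' @inheritParams elementary_fim
#' @return A `fim` matrix.
#' @export
#' @examples
#' population_fim(scenario_parameters(), initial_design("sparse"))
population_fim <- function(theta, design, form = c("block_diag", "full")) {
  form <- match.arg(form)
  stopifnot(inherits(design, "study_design"))
  total <- NULL
  for (g in seq_len(nrow(design))) {
    Fg <- elementary_fim(theta, design$dose[[g]], design$times[[g]], form)
    total <- if (is.null(total)) design$n[[g]] * unclass(Fg) else
      total + design$n[[g]] * unclass(Fg)
  }
  structure(total, class = c("fim", "matrix", "array"), form = form)
}

#' @export
print.fim <- function(x, ...) {
  cat("<fim> form =", attr(x, "form") %||% "?", "dim =", nrow(x), "\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Write a Fisher information matrix as CSV with a parameter-name header
#' @param fim A `fim` matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fim_csv <- function(fim, path) {
  df <- as.data.frame(unclass(fim))
  utils::write.csv(cbind(parameter = rownames(fim), df), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
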