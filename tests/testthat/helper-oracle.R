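# Independent oracles used across the test files. These deliberately do
# not reuse the package's differentiation or assembly code paths:
# derivatives come from numDeriv (Richardson extrapolation), densities
# from mvtnorm, determinants from eigen().

# scenario constants, hard-coded independently for fixture checks
scenario_true_fx <- c(base = 1, emax = 100, ec50 = 7, gamma = 2,
               cl = 0.15, v = 8, ka = 1)
scenario_guess_fx <- c(base = 1.5, emax = 150, ec50 = 10.5, gamma = 3,
                cl = 0.15, v = 8, ka = 1)
scenario_omega2 <- c(emax = 0.0625, ec50 = 0.0625, cl = 0.07, v = 0.02)
scenario_sigma2 <- c(add = 0.001, prop = 0.015)

# direct arithmetic for the oral one-compartment profile (ke form)
oracle_conc <- function(t, dose, cl, v, ka) {
  ke <- cl / v
  dose * ka / (v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

oracle_effect <- function(conc, base, emax, ec50, gamma) {
  base + conc^gamma * emax / (conc^gamma + ec50^gamma)
}

# typical response as a function of a full named fixed-effect vector
oracle_response <- function(times, dose, fx) {
  oracle_effect(oracle_conc(times, dose, fx[["cl"]], fx[["v"]], fx[["ka"]]),
                fx[["base"]], fx[["emax"]], fx[["ec50"]], fx[["gamma"]])
}

# FO moments computed with numDeriv: mean, and variance from the
# eta-Jacobian at zero plus the combined residual error
oracle_fo_moments <- function(theta, dose, times) {
  fx <- unclass(theta$fixed)
  f0 <- oracle_response(times, dose, fx)
  eta_names <- c("emax", "ec50", "cl", "v")
  L <- numDeriv::jacobian(function(eta) {
    fe <- fx
    fe[eta_names] <- fe[eta_names] * exp(eta)
    oracle_response(times, dose, fe)
  }, rep(0, 4))
  om <- theta$random$omega2[eta_names]
  V <- L %*% diag(om, 4) %*% t(L) +
    diag(theta$random$sigma2_prop * f0^2 + theta$random$sigma2_add,
         length(times))
  list(mean = f0, var = V, L = L)
}

# block-diagonal elementary FIM assembled independently (numDeriv
# derivatives, eigen-based inverse)
oracle_elementary_fim <- function(theta, dose, times) {
  eb <- intersect(theta$estimated,
                  c("base", "emax", "ec50", "gamma", "cl", "v", "ka"))
  el <- setdiff(theta$estimated, eb)
  mom <- oracle_fo_moments(theta, dose, times)
  Vi <- solve(mom$var)
  M <- numDeriv::jacobian(function(b) {
    fx <- unclass(theta$fixed)
    fx[eb] <- b
    oracle_response(times, dose, fx)
  }, unclass(theta$fixed)[eb])
  A <- t(M) %*% Vi %*% M
  dV <- lapply(el, function(p) {
    numDeriv::jacobian(function(x) {
      th <- theta
      if (p == "sigma2_add") th$random$sigma2_add <- x
      else if (p == "sigma2_prop") th$random$sigma2_prop <- x
      else th$random$omega2[[sub("omega2_", "", p)]] <- x
      as.vector(oracle_fo_moments(th, dose, times)$var)
    }, theta_entry(theta, p))
  })
  nt <- length(times)
  B <- matrix(0, length(el), length(el))
  for (a in seq_along(el)) {
    for (b in seq_along(el)) {
      Va <- matrix(dV[[a]], nt, nt)
      Vb <- matrix(dV[[b]], nt, nt)
      B[a, b] <- sum(diag(Va %*% Vi %*% Vb %*% Vi)) / 2
    }
  }
  out <- matrix(0, length(eb) + length(el), length(eb) + length(el),
                dimnames = list(c(eb, el), c(eb, el)))
  out[seq_along(eb), seq_along(eb)] <- A
  out[length(eb) + seq_along(el), length(eb) + seq_along(el)] <- B
  out
}

theta_entry <- function(theta, p) {
  if (p == "sigma2_add") return(theta$random$sigma2_add)
  if (p == "sigma2_prop") return(theta$random$sigma2_prop)
  if (startsWith(p, "omega2_")) {
    return(theta$random$omega2[[sub("omega2_", "", p)]])
  }
  unclass(theta$fixed)[[p]]
}

oracle_population_fim <- function(theta, design) {
  Reduce(`+`, lapply(seq_len(nrow(design)), function(g) {
    design$n[[g]] * oracle_elementary_fim(theta, design$dose[[g]],
                                          design$times[[g]])
  }))
}

# -2 log likelihood of the FO model via mvtnorm, using the oracle moments
oracle_fo_ofv <- function(theta, data) {
  total <- 0
  for (d in split(data, data$id)) {
    d <- d[order(d$time), ]
    mom <- oracle_fo_moments(theta, d$dose[[1]], d$time)
    total <- total - 2 * mvtnorm::dmvnorm(d$dv, mom$mean, mom$var, log = TRUE)
  }
  total
}

# log determinant recomputed from eigenvalues
oracle_log_det <- function(m) sum(log(eigen(m, symmetric = TRUE,
                                            only.values = TRUE)$values))

# random symmetric positive-definite matrix
random_pd <- function(p, seed) {
  set.seed(seed)
  a <- matrix(rnorm(p * p), p)
  crossprod(a) + diag(p) * 0.5
}
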