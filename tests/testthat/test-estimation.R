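# a pure-baseline parameter set: dose-0 data, no BSV, additive error only,
# so the MLE has a closed form (sample mean; variance with the 1/n divisor)
baseline_theta <- function(base = 1, sa = 0.04) {
  population_parameters(
    fixed_effects(base = base, emax = 100, ec50 = 7, gamma = 2,
                  cl = 0.15, v = 8, ka = 1),
    random_effects(c(emax = 0, ec50 = 0, cl = 0, v = 0),
                   sigma2_add = sa, sigma2_prop = 0),
    estimated = c("base", "sigma2_add"))
}

test_that("FO estimation reproduces the closed-form normal MLE", {
  th <- baseline_theta()
  d <- study_design(0, 30, times = c(1, 2, 3))
  dat <- simulate_dataset(d, th, seed = 14)
  fit <- fit_nlmem(dat, baseline_theta(base = 1.3, sa = 0.02), method = "FO")
  expect_true(fit$converged)
  mle_mean <- mean(dat$dv)
  mle_var <- mean((dat$dv - mle_mean)^2)
  expect_equal(unname(fit$beta_hat[["base"]]), mle_mean, tolerance = 1e-6)
  expect_equal(unname(fit$lambda_hat[["sigma2_add"]]), mle_var,
               tolerance = 1e-5)
  # OFV equals the exact normal deviance at the optimum
  expect_equal(fit$ofv,
               -2 * sum(dnorm(dat$dv, mle_mean, sqrt(mle_var), log = TRUE)),
               tolerance = 1e-6)
})

test_that("the FO objective equals an independent marginal likelihood", {
  th <- scenario_parameters()
  d <- study_design(c(0, 160), c(3, 3), schedule_times("sparse"))
  dat <- simulate_dataset(d, th, seed = 4)
  prep <- adaptod:::.prep_data(dat)
  for (mult in c(1, 1.3)) {
    th2 <- th
    th2$fixed[["emax"]] <- th$fixed[["emax"]] * mult
    expect_equal(adaptod:::.ofv_fo(th2, prep$groups),
                 oracle_fo_ofv(th2, dat), tolerance = 1e-8)
  }
})

test_that("estimates recover the truth as noise vanishes", {
  th <- scenario_parameters()
  th$random <- random_effects(c(emax = 0, ec50 = 0, cl = 0, v = 0),
                              sigma2_add = 1e-8, sigma2_prop = 1e-10)
  d <- study_design(c(0, 40, 160, 500), rep(3, 4), schedule_times("rich"))
  dat <- simulate_dataset(d, th, seed = 31)
  init <- th
  init$fixed[["emax"]] <- 120
  init$fixed[["ec50"]] <- 9
  init$estimated <- c("base", "emax", "ec50", "gamma")
  fit <- fit_nlmem(dat, init, method = "FO", compute_cov = FALSE)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta_hat),
               unname(unclass(th$fixed)[c("base", "emax", "ec50", "gamma")]),
               tolerance = 1e-3)
})

test_that("FOCEI agrees with FO when between-subject variability vanishes", {
  th <- scenario_parameters()
  th$random$omega2[] <- c(emax = 1e-8, ec50 = 1e-8, cl = 1e-8, v = 1e-8)
  d <- study_design(c(0, 160), c(4, 4), schedule_times("sparse"))
  dat <- simulate_dataset(d, th, seed = 12)
  init <- th
  init$estimated <- c("base", "emax", "ec50", "gamma", "sigma2_prop")
  fo <- fit_nlmem(dat, init, method = "FO", compute_cov = FALSE)
  focei <- fit_nlmem(dat, init, method = "FOCEI", compute_cov = FALSE)
  expect_true(fo$converged && focei$converged)
  expect_equal(unname(focei$beta_hat / fo$beta_hat), rep(1, 4),
               tolerance = 1e-3)
})

test_that("estimates are invariant to subject relabeling and record order", {
  th <- scenario_parameters()
  dat <- simulate_dataset(initial_design("sparse"), th, seed = 9)
  init <- scenario_parameters(guess = TRUE)
  f1 <- fit_nlmem(dat, init, method = "FO", compute_cov = FALSE)
  shuffled <- dat[sample(nrow(dat)), ]
  shuffled$id <- match(shuffled$id, c(5, 3, 8, 1, 7, 2, 6, 4))
  f2 <- fit_nlmem(shuffled, init, method = "FO", compute_cov = FALSE)
  expect_equal(f1$beta_hat, f2$beta_hat, tolerance = 1e-8)
  expect_equal(f1$ofv, f2$ofv, tolerance = 1e-8)
})

test_that("optimization never ends above the initial objective", {
  th <- scenario_parameters()
  dat <- simulate_dataset(initial_design("sparse"), th, seed = 77)
  init <- scenario_parameters(guess = TRUE)
  fit <- fit_nlmem(dat, init, method = "FO", compute_cov = FALSE)
  prep <- adaptod:::.prep_data(dat)
  expect_lte(fit$ofv, adaptod:::.ofv_fo(init, prep$groups) + 1e-6)
})

test_that("covariance inverts a known quadratic information", {
  # objective -2logL = (p - m)' H (p - m) + c has Hessian 2H, observed
  # information H, and covariance H^-1; 'base' uses the identity
  # transform so the delta method is trivial here
  H <- matrix(c(4, 1, 1, 3), 2)
  fake <- structure(list(
    objective = function(p) drop(t(p - c(1, 2)) %*% H %*% (p - c(1, 2))) + 5,
    par_opt = c(1, 2),
    estimated = c("base", "base2"),
    converged = TRUE
  ), class = "nlmem_fit")
  # both parameters identity-scaled: patch the transform lookup by using
  # names the transform treats as identity is not possible for 'base2',
  # so use a diagonal-consistent check through the natural-scale mapping
  cv <- estimate_covariance(fake)
  J <- diag(c(1, exp(2)))  # base identity, base2 log-scale (value e^2)
  expected <- J %*% (2 * solve(2 * H)) %*% J
  expect_equal(unname(cv$cov_all), expected, tolerance = 1e-6)
  expect_false(cv$repaired)
})

test_that("estimated covariance tracks the sampling distribution", {
  # the mean estimated variance of beta-hat should match the empirical
  # sampling variance over replicate fits within a generous factor
  th <- scenario_parameters()
  d <- study_design(c(0, 80, 320), c(20, 20, 20), schedule_times("sparse"))
  n_rep <- 24
  est <- matrix(NA_real_, n_rep, 4)
  vars <- matrix(NA_real_, n_rep, 4)
  for (r in seq_len(n_rep)) {
    dat <- simulate_dataset(d, th, seed = 1000 + r)
    fit <- suppressWarnings(fit_nlmem(dat, th, method = "FO", seed = r))
    if (!fit$converged || is.null(fit$cov_beta)) next
    est[r, ] <- fit$beta_hat
    vars[r, ] <- diag(fit$cov_beta)
  }
  ok <- stats::complete.cases(est)
  expect_gt(sum(ok), n_rep * 0.7)
  ratio <- apply(est[ok, ], 2, var) / colMeans(vars[ok, ])
  # same order of magnitude, parameter-wise
  expect_true(all(ratio > 1 / 3 & ratio < 3))
})

test_that("covariance diagonal shrinks like one over n", {
  th <- scenario_parameters()
  diags <- vapply(c(50, 200), function(n) {
    d <- study_design(c(0, 80, 320), rep(ceiling(n / 3), 3),
                      schedule_times("sparse"))
    dat <- simulate_dataset(d, th, seed = 500 + n)
    fit <- suppressWarnings(fit_nlmem(dat, th, method = "FO"))
    diag(fit$cov_beta)
  }, numeric(4))
  # quadrupling n shrinks each variance by roughly 4
  ratio <- diags[, 1] / diags[, 2]
  expect_true(all(ratio > 1.8 & ratio < 9))
})

test_that("estimation results serialize to JSON and back", {
  dat <- simulate_dataset(initial_design("sparse"), scenario_parameters(),
                          seed = 6)
  fit <- suppressWarnings(fit_nlmem(dat, scenario_parameters(guess = TRUE),
                                    method = "FO"))
  path <- withr::local_tempfile(fileext = ".json")
  write_estimation_json(fit, path)
  r <- read_estimation_json(path)
  expect_equal(r$beta_hat, fit$beta_hat)
  expect_equal(r$lambda_hat, fit$lambda_hat)
  expect_equal(r$ofv, fit$ofv)
  if (!is.null(fit$cov_beta)) {
    expect_equal(r$cov_beta, fit$cov_beta, tolerance = 1e-12)
  }
  # tidy/glance interfaces
  td <- tidy(fit)
  expect_identical(td$term, c(names(fit$beta_hat), names(fit$lambda_hat)))
  expect_identical(nrow(glance(fit)), 1L)
})
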