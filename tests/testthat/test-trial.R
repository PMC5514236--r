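# small run profile used across the trial tests
test_config <- function(...) {
  args <- utils::modifyList(list(schedule = "sparse", max_cohorts = 3,
                                 n_stop_sim = 500, seed = 11), list(...))
  do.call(mbaod_config, args)
}

test_that("guess and prior updates respect the estimated mask", {
  guess <- scenario_parameters(guess = TRUE)
  dat <- simulate_dataset(initial_design("sparse"), scenario_parameters(),
                          seed = 2)
  fit <- suppressWarnings(fit_nlmem(dat, guess, method = "FO"))
  up <- update_guess(guess, fit)
  v <- adaptod:::theta_to_vector(up)
  expect_equal(unname(v[c("base", "emax", "ec50", "gamma")]),
               unname(fit$beta_hat))
  # FIX rows untouched
  expect_equal(unname(v[c("cl", "v", "ka", "omega2_cl", "omega2_v",
                          "sigma2_add")]),
               c(0.15, 8, 1, 0.07, 0.02, 0.001))
  # unconverged fit leaves the guess unchanged
  bad <- fit
  bad$converged <- FALSE
  expect_identical(update_guess(guess, bad), guess)

  pr <- parameter_prior(beta_estimates(guess), cv = 0.1)
  cov <- diag(c(4, 1, 9, 0.25))
  dimnames(cov) <- list(names(pr$mean), names(pr$mean))
  fit2 <- fit
  fit2$cov_beta <- cov
  fit2$cov_repaired <- FALSE
  pr2 <- update_prior(pr, fit2)
  expect_equal(unname(pr2$sd), c(2, 1, 3, 0.5))
  expect_equal(pr2$mean, fit$beta_hat[names(pr$mean)])
  # zero covariance collapses the prior (ELD degenerates to lnD)
  fit3 <- fit2
  fit3$cov_beta <- cov * 0
  expect_equal(unname(update_prior(pr, fit3)$sd), rep(0, 4))
  expect_identical(update_prior(pr, bad), pr)
})

test_that("a vacuous band stops the trial after the first cohort", {
  cfg <- mbaod_config(schedule = "sparse", max_cohorts = 5,
                      n_stop_sim = 200, band = c(0, Inf), seed = 3)
  h <- suppressWarnings(run_mbaod(cfg, replicate = 1))
  expect_equal(length(h$cohorts), 1L)
  expect_equal(h$status, "stopped")
  expect_equal(h$n_id, 8L)
})

test_that("the cohort cap is honored", {
  cfg <- mbaod_config(schedule = "sparse", max_cohorts = 1,
                      n_stop_sim = 200, band = c(0.999, 1.001), seed = 3)
  h <- suppressWarnings(run_mbaod(cfg, replicate = 1))
  expect_equal(length(h$cohorts), 1L)
  expect_equal(h$status, "max_cohorts_reached")
})

test_that("identical seeds give identical histories", {
  cfg <- test_config()
  h1 <- suppressWarnings(run_mbaod(cfg, replicate = 2))
  h2 <- suppressWarnings(run_mbaod(cfg, replicate = 2))
  expect_identical(tidy(h1), tidy(h2))
  expect_identical(h1$data$dv, h2$data$dv)
  # a different replicate index gives different data
  h3 <- suppressWarnings(run_mbaod(cfg, replicate = 3))
  expect_false(identical(h1$data$dv, h3$data$dv))
})

test_that("sample size and information bookkeeping hold cohort by cohort", {
  cfg <- test_config(max_cohorts = 4, band = c(0.9999, 1.0001))
  h <- suppressWarnings(run_mbaod(cfg, replicate = 1))
  td <- tidy(h)
  expect_equal(td$n_id, 8 + 2 * (td$cohort - 1))
  expect_true(all(diff(td$logdet_fim_true) >= -1e-10))
  expect_equal(h$n_id, max(td$n_id))
  # cumulative design grows by exactly one group per cohort
  sizes <- vapply(h$cohorts, function(co) nrow(co$design), integer(1))
  expect_equal(sizes, 2 + (seq_along(sizes) - 1))
})

test_that("lnD and ELD pick the same dose under a degenerate prior", {
  # with the true parameters as the guess and a zero-sd prior, the ELD
  # expectation is exactly the lnD objective, so the optimized cohort-2
  # dose coincides under shared seeds
  cfg_l <- mbaod_config(criterion = "lnD", schedule = "sparse",
                        theta_init = scenario_parameters(),
                        max_cohorts = 3, n_stop_sim = 200,
                        band = c(0.999, 1.001), seed = 19)
  cfg_e <- mbaod_config(criterion = "ELD", schedule = "sparse",
                        theta_init = scenario_parameters(),
                        max_cohorts = 3, n_stop_sim = 200,
                        band = c(0.999, 1.001), prior_cv = 0, seed = 19)
  h_l <- suppressWarnings(run_mbaod(cfg_l, replicate = 1))
  h_e <- suppressWarnings(run_mbaod(cfg_e, replicate = 1))
  expect_equal(tidy(h_l)$dose, tidy(h_e)$dose)
})

test_that("histories persist and reload with their key quantities", {
  cfg <- test_config()
  h <- suppressWarnings(run_mbaod(cfg, replicate = 1))
  dir <- withr::local_tempdir()
  write_history(h, dir)
  r <- read_history(dir)
  expect_equal(r$status, h$status)
  expect_equal(r$n_id, h$n_id)
  td_h <- tidy(h)
  td_r <- tidy(r)
  common <- c("cohort", "dose", "n_id", "ofv", "logdet_fim_true",
              "base", "emax", "ec50", "gamma")
  expect_equal(as.data.frame(td_r[common]), as.data.frame(td_h[common]),
               tolerance = 1e-12)
  expect_equal(r$data$dv, h$data$dv, tolerance = 1e-15)
})
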