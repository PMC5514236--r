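test_that("concentration profile matches the oral one-compartment form", {
  # zero at t = 0 and proportional to dose
  expect_equal(pk_concentration(0, 160, 0.15, 8, 1), 0)
  expect_equal(pk_concentration(3, 0, 0.15, 8, 1), 0)
  # independent hand evaluation in the ke parameterization
  expect_equal(pk_concentration(3, 160, 0.15, 8, 1),
               oracle_conc(3, 160, 0.15, 8, 1), tolerance = 1e-12)
  expect_equal(round(pk_concentration(3, 160, 0.15, 8, 1), 2), 18.25)
  # ke-form equivalence across a time grid and several parameter sets
  for (p in list(c(0.15, 8, 1), c(0.5, 10, 2), c(1, 5, 0.3))) {
    t <- c(0, 0.5, 2, 7, 30, 120)
    expect_equal(pk_concentration(t, 80, p[1], p[2], p[3]),
                 oracle_conc(t, 80, p[1], p[2], p[3]), tolerance = 1e-12)
  }
})

test_that("concentration is non-negative when absorption is rate-limiting in", {
  t <- seq(0, 500, by = 0.5)
  conc <- pk_concentration(t, 160, 0.15, 8, 1)  # ka > cl/v
  expect_true(all(conc >= 0))
  expect_lt(conc[length(conc)], 0.01)  # -> 0 as t -> infinity
  expect_error(pk_concentration(1, 10, cl = 8, v = 8, ka = 1),
               "degenerate")
})

test_that("sigmoidal Emax effect has the half-maximal and limit properties", {
  expect_equal(effect_mean(7, 1, 100, 7, 1), 51)
  expect_equal(effect_mean(0, 1, 100, 7, 2), 1)
  expect_equal(effect_mean(7, 1, 100, 7, 2),
               oracle_effect(7, 1, 100, 7, 2), tolerance = 1e-12)
  # monotone in concentration and bounded by base + emax
  conc <- seq(0, 200, by = 0.5)
  eff <- effect_mean(conc, 1, 100, 7, 2)
  expect_true(all(diff(eff) >= 0))
  expect_true(all(eff <= 101))
  # stable for extreme Hill coefficients (no 0/0)
  expect_equal(effect_mean(0.5, 1, 100, 7, 500), 1)
  expect_equal(effect_mean(20, 1, 100, 7, 500), 101)
})

test_that("individual parameters are log-normal about the typical values", {
  beta <- scenario_parameters()$fixed
  expect_equal(individual_parameters(beta), unclass(beta))
  ind <- individual_parameters(beta, c(emax = log(2)))
  expect_equal(ind[["emax"]], 2 * beta[["emax"]])
  expect_equal(ind[["ec50"]], beta[["ec50"]])
  set.seed(99)
  eta <- rnorm(4)
  names(eta) <- c("emax", "ec50", "cl", "v")
  expect_true(all(individual_parameters(beta, eta) > 0))
})

test_that("simulated datasets are deterministic and correctly shaped", {
  th <- scenario_parameters()
  d <- initial_design("sparse")
  s1 <- simulate_dataset(d, th, seed = 3)
  s2 <- simulate_dataset(d, th, seed = 3)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_equal(nrow(s1), sum(d$n * lengths(d$times)))
  expect_equal(dplyr::n_distinct(s1$id), design_n(d))
  # each subject has exactly its group's times
  cnt <- dplyr::count(s1, id)
  expect_true(all(cnt$n == 3))
  # different seed changes the data
  expect_false(identical(s1$dv, simulate_dataset(d, th, seed = 4)$dv))
})

test_that("zero variances reproduce the typical prediction exactly", {
  th <- scenario_parameters()
  th$random <- random_effects(c(emax = 0, ec50 = 0, cl = 0, v = 0), 0, 0)
  d <- study_design(c(0, 160), c(2, 2), schedule_times("sparse"))
  s <- simulate_dataset(d, th, seed = 1)
  pred <- unlist(lapply(seq_len(nrow(d)), function(g) {
    f <- effect_mean(pk_concentration(d$times[[g]], d$dose[[g]], 0.15, 8, 1),
                     1, 100, 7, 2)
    rep(f, d$n[[g]])
  }))
  expect_equal(s$dv, pred, tolerance = 1e-12)
})

test_that("later cohorts never perturb earlier subjects' data", {
  th <- scenario_parameters()
  d <- initial_design("sparse")
  first <- simulate_dataset(d, th, seed = 5, cohort = 1)
  again <- simulate_dataset(d, th, seed = 5, cohort = 1)
  extra <- simulate_dataset(study_design(100, 2, schedule_times("sparse")),
                            th, seed = 5, cohort = 2, id_offset = 8)
  expect_identical(first$dv, again$dv)
  expect_false(any(extra$id %in% first$id))
})

test_that("Monte-Carlo response variance matches the FO approximation", {
  # one large group at a single time point: the sample variance of the
  # simulated observations should agree with the FO-predicted variance
  # at mild between-subject variability, where the linearization error
  # is negligible against the Monte-Carlo error
  th <- scenario_parameters()
  th$random$omega2[] <- 0.01
  d <- study_design(160, 10000, times = 3)
  s <- simulate_dataset(d, th, seed = 8)
  mom <- fo_moments(th, 160, 3)
  expect_equal(stats::var(s$dv) / mom$var[1, 1], 1, tolerance = 0.05)
})

test_that("trial data round-trips losslessly through CSV", {
  s <- simulate_dataset(initial_design("sparse"), scenario_parameters(),
                        seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_data(s, path)
  r <- read_trial_data(path)
  expect_equal(as.data.frame(r), as.data.frame(s)[names(r)],
               tolerance = 1e-15)
})
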