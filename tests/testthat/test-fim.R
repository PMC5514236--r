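test_that("FO moments match an independent differentiation scheme", {
  th <- scenario_parameters()
  for (dose in c(0, 160, 400)) {
    mom <- fo_moments(th, dose, schedule_times("sparse"))
    ora <- oracle_fo_moments(th, dose, schedule_times("sparse"))
    expect_equal(mom$mean, ora$mean, tolerance = 1e-10)
    expect_equal(unname(mom$jac_eta), ora$L, tolerance = 1e-6)
    expect_equal(mom$var, ora$var, tolerance = 1e-6)
  }
})

test_that("FO variance reduces to residual error without BSV", {
  th <- scenario_parameters()
  th$random <- random_effects(c(emax = 0, ec50 = 0, cl = 0, v = 0),
                              sigma2_add = 0.001, sigma2_prop = 0.015)
  mom <- fo_moments(th, 160, schedule_times("sparse"))
  expect_equal(mom$var, diag(0.015 * mom$mean^2 + 0.001, 3),
               tolerance = 1e-12)
  # dose-0 group: mean is the baseline at every time
  mom0 <- fo_moments(scenario_parameters(), 0, schedule_times("rich"))
  expect_equal(mom0$mean, rep(1, 8))
})

test_that("the moment assembler recovers closed-form linear information", {
  # y = b * t + e, e ~ N(0, s2): information for b is sum(t^2)/s2,
  # and for s2 it is T/(2 s2^2)
  t <- c(1, 2, 3, 5)
  s2 <- 0.5
  Fm <- fim_from_moments(function(b) b[["b"]] * t,
                         function(b, l) diag(l[["s2"]], length(t)),
                         beta = c(b = 2), lambda = c(s2 = s2))
  expect_equal(Fm["b", "b"], sum(t^2) / s2, tolerance = 1e-8)
  expect_equal(Fm["s2", "s2"], length(t) / (2 * s2^2), tolerance = 1e-8)
  expect_equal(Fm["b", "s2"], 0)
})

test_that("block-diagonal form has exactly zero off-diagonal blocks", {
  Fm <- elementary_fim(scenario_parameters(), 160, schedule_times("sparse"))
  eb <- c("base", "emax", "ec50", "gamma")
  el <- c("omega2_emax", "omega2_ec50", "sigma2_prop")
  expect_identical(unclass(Fm)[eb, el], matrix(0, 4, 3,
                                               dimnames = list(eb, el)))
  expect_identical(rownames(Fm), c(eb, el))
  expect_equal(nrow(Fm), 7)
})

test_that("elementary FIM agrees with the independent oracle", {
  th <- scenario_parameters()
  for (sched in c("sparse", "rich")) {
    for (dose in c(160, 320)) {
      Fm <- unclass(elementary_fim(th, dose, schedule_times(sched)))
      ora <- oracle_elementary_fim(th, dose, schedule_times(sched))
      expect_equal(Fm, ora[rownames(Fm), colnames(Fm)], tolerance = 1e-6,
                   ignore_attr = TRUE)
    }
  }
})

test_that("full-form FIM matches the expected score outer product", {
  # Monte-Carlo oracle: FIM = E[s s'] with s the score of the marginal
  # normal FO likelihood; estimated here for a reduced two-parameter
  # problem on a two-point design via vectorized finite-difference scores
  th <- scenario_parameters()
  th$estimated <- c("emax", "sigma2_prop")
  times <- c(3, 60)
  dose <- 160
  Fm <- unclass(elementary_fim(th, dose, times, form = "full"))

  mom <- oracle_fo_moments(th, dose, times)
  set.seed(1234)
  n <- 1e6
  Y <- mvtnorm::rmvnorm(n, mom$mean, mom$var)
  logdens <- function(emax, sp) {
    th2 <- th
    th2$fixed[["emax"]] <- emax
    th2$random$sigma2_prop <- sp
    m <- oracle_fo_moments(th2, dose, times)
    mvtnorm::dmvnorm(Y, m$mean, m$var, log = TRUE)
  }
  h1 <- 1e-4 * th$fixed[["emax"]]
  h2 <- 1e-4 * th$random$sigma2_prop
  s1 <- (logdens(th$fixed[["emax"]] + h1, th$random$sigma2_prop) -
           logdens(th$fixed[["emax"]] - h1, th$random$sigma2_prop)) / (2 * h1)
  s2 <- (logdens(th$fixed[["emax"]], th$random$sigma2_prop + h2) -
           logdens(th$fixed[["emax"]], th$random$sigma2_prop - h2)) / (2 * h2)
  S <- cbind(s1, s2)
  mc <- crossprod(S) / n
  expect_equal(unname(unclass(Fm)), unname(mc), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("population FIM is additive over groups and group sizes", {
  th <- scenario_parameters()
  ts <- schedule_times("sparse")
  d1 <- study_design(c(0, 160), c(4, 4), ts)
  d2 <- study_design(c(0, 160), c(8, 8), ts)
  F1 <- unclass(population_fim(th, d1))
  expect_equal(unclass(population_fim(th, d2)), 2 * F1, tolerance = 1e-12)
  # permutation invariance
  d1r <- study_design(c(160, 0), c(4, 4), ts)
  expect_equal(unclass(population_fim(th, d1r)), F1, tolerance = 1e-12)
  # sum of one-group FIMs
  g1 <- population_fim(th, study_design(0, 4, ts))
  g2 <- population_fim(th, study_design(160, 4, ts))
  expect_equal(unclass(g1) + unclass(g2), F1, tolerance = 1e-12)
  # single individual equals the elementary FIM
  expect_equal(unclass(population_fim(th, study_design(160, 1, ts))),
               unclass(elementary_fim(th, 160, ts)), tolerance = 1e-14)
})

test_that("batched grid FIMs agree with the per-dose reference path", {
  th <- scenario_parameters()
  ts <- schedule_times("sparse")
  doses <- c(0L, 10L, 160L, 499L)
  batch <- adaptod:::.batch_block_fims(th, doses, ts)
  for (i in seq_along(doses)) {
    expect_equal(batch[[i]], unclass(elementary_fim(th, doses[i], ts)),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("adding a group never decreases the log determinant", {
  th <- scenario_parameters()
  ts <- schedule_times("sparse")
  design <- initial_design("sparse")
  ld <- lnd_objective(th, design)
  for (dose in c(0, 40, 250)) {
    design <- add_group(design, dose, 2, ts)
    ld_new <- lnd_objective(th, design)
    expect_gte(ld_new, ld - 1e-10)
    ld <- ld_new
  }
})

test_that("FIM serializes to CSV with parameter names", {
  Fm <- elementary_fim(scenario_parameters(), 160, schedule_times("sparse"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fim_csv(Fm, path)
  r <- utils::read.csv(path)
  expect_equal(r$parameter, rownames(Fm))
  expect_equal(as.matrix(r[, -1]), unclass(Fm), tolerance = 1e-12,
               ignore_attr = TRUE)
})
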