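#' Design efficiency of one FIM against a reference
#'
#' `(|FIM_test| / |FIM_ref|)^(1/p)`: the per-parameter determinant ratio,
#' i.e. the relative information of one design against another on a
#' scale where doubling every group size gives efficiency 2.
#'
#' @param fim_test,fim_ref Fisher information matrices of equal dimension.
#' @param p Number of parameters (defaults to the matrix dimension).
#' @return A positive scalar; 1 when the designs are equally informative.
#' @export
design_efficiency <- function(fim_test, fim_ref, p = nrow(fim_ref)) {
  stopifnot(nrow(fim_test) == nrow(fim_ref))
  ld_ref <- log_det(unclass(fim_ref))
  if (!is.finite(ld_ref)) stop("singular reference FIM", call. = FALSE)
  ld_test <- log_det(unclass(fim_test))
  exp((ld_test - ld_ref) / p)
}

#' Relative estimation error
#'
#' `(estimate - true) / true`; e.g. the +50% misspecified initial guess
#' of each PD fixed effect has REE 0.5. Vectorized.
#'
#' @param estimate Estimated value(s).
#' @param true True value(s), nonzero.
#' @return REE on the same shape as the inputs.
#' @export
relative_estimation_error <- function(estimate, true) {
  if (any(true == 0)) stop("true value must be nonzero", call. = FALSE)
  (estimate - true) / true
}

#' Reference design trajectory at the true parameters
#'
#' The theoretically best adaptive trajectory: cohort-wise lnD dose
#' optimization assuming the true parameters, with the same cohort
#' structure as the adaptive runs but no estimation or updating. Cohort 1
#' is the fixed initial design. Fully deterministic.
#'
#' @param config An [mbaod_config()].
#' @param n_cohorts Number of cohorts to build (default
#'   `config$max_cohorts`).
#' @return A list of class `reference_trajectory`: `designs` (cumulative
#'   [study_design()] per cohort), `table` (tibble of `cohort`, `dose`,
#'   `logdet_fim_true`), and `p` (FIM dimension).
#' @export
reference_trajectory <- function(config, n_cohorts = config$max_cohorts) {
  stopifnot(inherits(config, "mbaod_config"))
  times <- schedule_times(config$schedule)
  theta <- config$theta_true
  design <- config$init_design
  designs <- vector("list", n_cohorts)
  dose <- rep(NA_integer_, n_cohorts)
  ld <- numeric(n_cohorts)
  for (k in seq_len(n_cohorts)) {
    if (k > 1L) {
      opt <- optimize_next_dose("lnD", theta, design,
                                new_group_n = config$cohort_n,
                                times = times, grid = config$grid)
      dose[k] <- opt$dose
      design <- add_group(design, opt$dose, config$cohort_n, times)
    }
    designs[[k]] <- design
    ld[k] <- lnd_objective(theta, design)
  }
  structure(list(designs = designs,
                 table = tibble::tibble(cohort = seq_len(n_cohorts),
                                        dose = dose,
                                        logdet_fim_true = ld),
                 p = length(theta$estimated)),
            class = "reference_trajectory")
}

#' Summarize a set of adaptive-trial replicates
#'
#' Computes, per cohort, the efficiency of every replicate's cumulative
#' design relative to the true-parameter reference trajectory (both FIMs
#' evaluated at the true parameters) and its 2.5th/50th/97.5th
#' percentiles; the distribution of total sample size; the histogram of
#' optimized dose selections (cohorts after the first, with the
#' reference-design selections alongside); and the relative estimation
#' error of the final estimates.
#'
#' Replicates that stopped before a given cohort carry their final design
#' forward for that cohort's percentile (flagged in the `carried`
#' column), so every cohort's percentile uses all replicates; set
#' `carry_forward = FALSE` to summarize survivors only.
#'
#' @param histories List of `trial_history` objects sharing a
#'   configuration.
#' @param reference A [reference_trajectory()]; built from the first
#'   history's config when omitted.
#' @param carry_forward Carry early-stopped replicates forward.
#' @return A list of class `mbaod_summary` with tibbles `efficiency`,
#'   `percentiles`, `sample_size`, `doses`, `dose_counts`, `ree`, plus
#'   the `reference` used.
#' @export
summarize_replicates <- function(histories, reference = NULL,
                                 carry_forward = TRUE) {
  stopifnot(length(histories) >= 1,
            all(vapply(histories, inherits, logical(1), "trial_history")))
  cfg <- histories[[1]]$config
  same <- vapply(histories, function(h) {
    identical(h$config$schedule, cfg$schedule) &&
      identical(h$config$criterion, cfg$criterion) &&
      identical(theta_to_vector(h$config$theta_true),
                theta_to_vector(cfg$theta_true))
  }, logical(1))
  if (!all(same)) stop("histories have incompatible configurations",
                       call. = FALSE)
  n_max <- max(vapply(histories, function(h) length(h$cohorts), integer(1)))
  if (is.null(reference)) reference <- reference_trajectory(cfg, n_max)
  stopifnot(inherits(reference, "reference_trajectory"),
            nrow(reference$table) >= n_max)
  p <- reference$p

  eff <- purrr::map_dfr(histories, function(h) {
    ld <- vapply(h$cohorts, function(co) co$logdet_fim_true, numeric(1))
    kk <- seq_len(if (carry_forward) n_max else length(ld))
    ld_k <- ld[pmin(kk, length(ld))]
    tibble::tibble(replicate = h$replicate, cohort = kk,
                   efficiency = exp((ld_k -
                     reference$table$logdet_fim_true[kk]) / p),
                   carried = kk > length(ld))
  })
  pct <- eff |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(
      p2.5 = stats::quantile(.data$efficiency, 0.025, names = FALSE),
      p50 = stats::median(.data$efficiency),
      p97.5 = stats::quantile(.data$efficiency, 0.975, names = FALSE),
      n = dplyr::n(), .groups = "drop")

  sizes <- purrr::map_dfr(histories, function(h)
    tibble::tibble(replicate = h$replicate, cohorts = length(h$cohorts),
                   n_id = h$n_id, status = h$status))

  doses <- purrr::map_dfr(histories, function(h)
    purrr::map_dfr(h$cohorts[-1], function(co)
      tibble::tibble(replicate = h$replicate, cohort = co$cohort,
                     dose = co$dose)))
  # reference selections matched to the cohorts each replicate actually ran
  ref_doses <- purrr::map_dfr(histories, function(h) {
    k <- length(h$cohorts)
    if (k < 2) return(tibble::tibble())
    tibble::tibble(replicate = h$replicate, cohort = 2:k,
                   dose = reference$table$dose[2:k])
  })
  dose_counts <- dplyr::bind_rows(
    dplyr::mutate(doses, which = "adaptive"),
    dplyr::mutate(ref_doses, which = "reference")) |>
    dplyr::count(.data$which, .data$dose, name = "count")

  true_v <- theta_to_vector(cfg$theta_true)
  ree <- purrr::map_dfr(histories, function(h) {
    fin <- h$cohorts[[length(h$cohorts)]]$fit
    est <- c(fin$beta_hat, fin$lambda_hat)
    tibble::tibble(replicate = h$replicate, term = names(est),
                   ree = relative_estimation_error(unname(est),
                                                   unname(true_v[names(est)])))
  })

  structure(list(efficiency = eff, percentiles = pct, sample_size = sizes,
                 doses = doses, dose_counts = dose_counts, ree = ree,
                 reference = reference,
                 criterion = cfg$criterion, schedule = cfg$schedule),
            class = "mbaod_summary")
}

#' @export
print.mbaod_summary <- function(x, ...) {
  cat("<mbaod_summary>", x$criterion, "/", x$schedule, "|",
      nrow(x$sample_size), "replicates\n")
  print(x$percentiles)
  invisible(x)
}

# ---- plots ----------------------------------------------------------------

#' Plot the design-efficiency percentiles per cohort
#' @param summary An [summarize_replicates()] result.
#' @return A ggplot object.
#' @export
plot_efficiency <- function(summary) {
  stopifnot(inherits(summary, "mbaod_summary"))
  ggplot2::ggplot(summary$percentiles, ggplot2::aes(x = .data$cohort)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p2.5, ymax = .data$p97.5),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$p50)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "Cohort", y = "Design efficiency",
                  title = paste(summary$criterion, summary$schedule,
                                sep = " / "),
                  subtitle = "median with 2.5th-97.5th percentile band")
}

#' Plot the histogram of optimized dose selections
#' @inheritParams plot_efficiency
#' @return A ggplot object.
#' @export
plot_dose_histogram <- function(summary) {
  stopifnot(inherits(summary, "mbaod_summary"))
  ggplot2::ggplot(summary$dose_counts,
                  ggplot2::aes(x = .data$dose, y = .data$count,
                               fill = .data$which)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6, width = 8) +
    ggplot2::scale_fill_manual(values = c(adaptive = "grey40",
                                          reference = NA)) +
    ggplot2::geom_col(data = ~dplyr::filter(.x, .data$which == "reference"),
                      fill = NA, colour = "black", width = 8) +
    ggplot2::labs(x = "Dose (mg)", y = "Selections", fill = NULL)
}

#' Plot the relative estimation error of the final estimates
#' @inheritParams plot_efficiency
#' @return A ggplot object.
#' @export
plot_ree <- function(summary) {
  stopifnot(inherits(summary, "mbaod_summary"))
  ggplot2::ggplot(summary$ree, ggplot2::aes(x = .data$term, y = .data$ree)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Relative estimation error")
}

#' Plot the total-sample-size distribution
#' @inheritParams plot_efficiency
#' @return A ggplot object.
#' @export
plot_sample_size <- function(summary) {
  stopifnot(inherits(summary, "mbaod_summary"))
  ggplot2::ggplot(summary$sample_size, ggplot2::aes(y = .data$n_id, x = "")) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Total individuals at endpoint")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for replicate summaries
#' @param object An `mbaod_summary`.
#' @param type One of `"efficiency"`, `"doses"`, `"ree"`, `"sample_size"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mbaod_summary
#' @export
autoplot.mbaod_summary <- function(object,
                                   type = c("efficiency", "doses", "ree",
                                            "sample_size"), ...) {
  switch(match.arg(type),
         efficiency = plot_efficiency(object),
         doses = plot_dose_histogram(object),
         ree = plot_ree(object),
         sample_size = plot_sample_size(object))
}
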