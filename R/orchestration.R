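# ---- YAML configuration ---------------------------------------------------

.config_scalar_keys <- c("schedule", "criterion", "cohort_n", "max_cohorts",
                         "prior_cv", "n_lhs", "n_stop_sim", "level",
                         "method", "seed")

#' Load an adaptive-design configuration from YAML
#'
#' Any omitted key falls back to the scenario default of
#' [mbaod_config()]; an empty file yields the full default scenario.
#' Recognized keys: `schedule`, `criterion`, `cohort_n`, `max_cohorts`,
#' `prior_cv`, `n_lhs`, `n_stop_sim`, `level`, `method`, `seed`,
#' `band` (two numbers), `dose_range` (two integers), and the parameter
#' maps `true_fixed_effects` / `guess_fixed_effects` (name: value).
#' Unknown keys raise an error naming the key.
#'
#' @param path YAML file path.
#' @return An [mbaod_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c(.config_scalar_keys, "band", "dose_range",
             "true_fixed_effects", "guess_fixed_effects")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  args <- raw[intersect(names(raw), .config_scalar_keys)]
  if (!is.null(raw$band)) args$band <- as.numeric(unlist(raw$band))
  if (!is.null(raw$dose_range)) {
    dr <- as.integer(unlist(raw$dose_range))
    if (length(dr) != 2 || dr[1] > dr[2]) {
      stop("config key `dose_range` must be two ordered integers",
           call. = FALSE)
    }
    args$grid <- dr[1]:dr[2]
  }
  patch_beta <- function(theta, patch) {
    if (is.null(patch)) return(theta)
    bad <- setdiff(names(patch), .beta_names)
    if (length(bad)) stop("unknown fixed effect(s) in config: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    set_fixed_effects(theta, unlist(patch))
  }
  args$theta_true <- patch_beta(scenario_parameters(), raw$true_fixed_effects)
  args$theta_init <- patch_beta(scenario_parameters(guess = TRUE),
                                raw$guess_fixed_effects)
  do.call(mbaod_config, args)
}

#' Save a configuration as YAML
#' @param config An [mbaod_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  out <- config[.config_scalar_keys]
  out$band <- as.numeric(config$band)
  out$dose_range <- c(min(config$grid), max(config$grid))
  out$true_fixed_effects <- as.list(unclass(config$theta_true$fixed))
  out$guess_fixed_effects <- as.list(unclass(config$theta_init$fixed))
  yaml::write_yaml(out, path)
  invisible(path)
}

# ---- run persistence ------------------------------------------------------

#' Persist a trial history to a directory
#'
#' Writes `config.yaml`, the cumulative dataset as `data.csv`, one
#' `cohort_XX.json` per cohort (dose, criterion value, estimates,
#' stopping summary, cumulative log-determinant at the true parameters),
#' and the per-cohort optimization traces as `trace_XX.csv`.
#'
#' @param history A `trial_history`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_history <- function(history, dir) {
  stopifnot(inherits(history, "trial_history"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_config(history$config, file.path(dir, "config.yaml"))
  write_trial_data(history$data, file.path(dir, "data.csv"))
  for (co in history$cohorts) {
    rec <- list(
      cohort = co$cohort,
      dose = co$dose,
      criterion = co$criterion,
      logdet_fim_true = co$logdet_fim_true,
      beta_hat = as.list(co$fit$beta_hat),
      lambda_hat = as.list(co$fit$lambda_hat),
      ofv = co$fit$ofv,
      converged = co$fit$converged,
      stop_evaluated = !is.null(co$stopping),
      stopped = if (is.null(co$stopping)) FALSE else
        attr(co$stopping, "stop"),
      stopping = if (!is.null(co$stopping)) {
        df <- as.data.frame(co$stopping)
        lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
      }
    )
    jsonlite::write_json(rec,
                         file.path(dir, sprintf("cohort_%02d.json", co$cohort)),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
    if (!is.null(co$trace)) {
      utils::write.csv(co$trace,
                       file.path(dir, sprintf("trace_%02d.csv", co$cohort)),
                       row.names = FALSE)
    }
  }
  meta <- list(replicate = history$replicate, status = history$status,
               n_id = history$n_id, n_cohorts = length(history$cohorts))
  jsonlite::write_json(meta, file.path(dir, "history.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a persisted trial history
#'
#' Reconstructs a summarizable `trial_history` (configuration, per-cohort
#' estimates, doses, information, status). Fit internals that are not
#' serialized (covariances, objective closures) are absent.
#'
#' @param dir Directory written by [write_history()].
#' @return A `trial_history`.
#' @export
read_history <- function(dir) {
  config <- load_config(file.path(dir, "config.yaml"))
  meta <- jsonlite::read_json(file.path(dir, "history.json"),
                              simplifyVector = TRUE)
  times <- schedule_times(config$schedule)
  files <- sort(list.files(dir, pattern = "^cohort_\\d+\\.json$",
                           full.names = TRUE))
  design <- config$init_design
  cohorts <- vector("list", length(files))
  for (i in seq_along(files)) {
    rec <- jsonlite::read_json(files[[i]], simplifyVector = TRUE)
    if (i > 1L) design <- add_group(design, rec$dose, config$cohort_n, times)
    fit <- structure(list(beta_hat = unlist(rec$beta_hat),
                          lambda_hat = unlist(rec$lambda_hat),
                          ofv = rec$ofv, converged = rec$converged,
                          n_id = design_n(design),
                          method = config$method, cov_beta = NULL),
                     class = "nlmem_fit")
    cohorts[[i]] <- list(cohort = rec$cohort,
                         dose = if (is.null(rec$dose)) NA_integer_ else
                           rec$dose,
                         criterion = rec$criterion %||% NA_real_,
                         fit = fit, stopping = NULL,
                         design = design,
                         logdet_fim_true = rec$logdet_fim_true)
  }
  data <- read_trial_data(file.path(dir, "data.csv"))
  structure(list(config = config, replicate = meta$replicate,
                 cohorts = cohorts, status = meta$status,
                 n_id = meta$n_id, data = data, final_design = design),
            class = "trial_history")
}

#' Run a batch of independent adaptive-trial replicates
#'
#' Replicates are seeded independently from `(config$seed, replicate)`,
#' so results do not depend on execution order. When `out_dir` is given,
#' each replicate is persisted under `replicate_XX/` together with a
#' `manifest.json` of per-replicate outcomes; re-running with the same
#' configuration and seed reproduces the manifest exactly.
#'
#' @param config An [mbaod_config()].
#' @param n_replicates Number of replicates.
#' @param out_dir Optional output directory.
#' @param quiet Suppress per-replicate progress messages.
#' @return A list of `trial_history` objects, invisibly when persisted.
#' @export
run_replicates <- function(config, n_replicates, out_dir = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(config, "mbaod_config"), n_replicates >= 1)
  histories <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    t0 <- Sys.time()
    histories[[r]] <- run_mbaod(config, replicate = r)
    if (!quiet) {
      message(sprintf("replicate %d/%d: %d cohorts, n_id %d, %s [%.1fs]",
                      r, n_replicates, length(histories[[r]]$cohorts),
                      histories[[r]]$n_id, histories[[r]]$status,
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in seq_len(n_replicates)) {
      write_history(histories[[r]],
                    file.path(out_dir, sprintf("replicate_%02d", r)))
    }
    manifest <- purrr::map_dfr(histories, glance)
    manifest$replicate <- seq_len(n_replicates)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA)
    return(invisible(histories))
  }
  histories
}

#' Build report tables (and optional figures) for one or more runs
#'
#' Each run is a list of `trial_history` objects or a directory written
#' by [run_replicates()]. Per run, the replicate summary tables are
#' written as CSV (`<criterion>_<schedule>_percentiles.csv` etc.); when
#' several runs are given a joint per-cohort comparison table is added.
#'
#' @param runs A list whose elements are either lists of histories or
#'   run-directory paths.
#' @param out_dir Output directory for the tables.
#' @param plots Also render PNG figures.
#' @return The list of `mbaod_summary` objects, invisibly.
#' @export
write_report <- function(runs, out_dir, plots = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(runs, "trial_history")) runs <- list(list(runs))
  summaries <- lapply(runs, function(run) {
    if (is.character(run)) {
      dirs <- sort(list.dirs(run, recursive = FALSE))
      run <- lapply(dirs[grepl("replicate_", dirs)], read_history)
    }
    summarize_replicates(run)
  })
  for (s in summaries) {
    stem <- file.path(out_dir, paste(s$criterion, s$schedule, sep = "_"))
    utils::write.csv(s$percentiles, paste0(stem, "_percentiles.csv"),
                     row.names = FALSE)
    utils::write.csv(s$efficiency, paste0(stem, "_efficiency.csv"),
                     row.names = FALSE)
    utils::write.csv(s$sample_size, paste0(stem, "_sample_size.csv"),
                     row.names = FALSE)
    utils::write.csv(s$dose_counts, paste0(stem, "_dose_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(s$ree, paste0(stem, "_ree.csv"), row.names = FALSE)
    if (plots) {
      for (ty in c("efficiency", "doses", "ree", "sample_size")) {
        ggplot2::ggsave(paste0(stem, "_", ty, ".png"),
                        autoplot(s, type = ty), width = 6, height = 4,
                        dpi = 120)
      }
    }
  }
  if (length(summaries) > 1) {
    joint <- purrr::map_dfr(summaries, function(s)
      dplyr::mutate(s$percentiles, criterion = s$criterion,
                    schedule = s$schedule))
    utils::write.csv(joint, file.path(out_dir, "comparison_percentiles.csv"),
                     row.names = FALSE)
  }
  invisible(summaries)
}
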