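#' Build a study design of dose groups
#'
#' A design is a tibble with one row per elementary group: the dose given
#' to the group, the number of individuals, and the (shared) sampling
#' times. All individuals in a group have the same elementary design.
#'
#' @param dose Integer dose per group, mg, in `[0, 500]`.
#' @param n Number of individuals per group (>= 1).
#' @param times Sampling times in hours: a numeric vector (recycled to all
#'   groups) or a list of numeric vectors, strictly increasing, all >= 0.
#'
#' @return A tibble of class `study_design` with columns `dose`, `n`,
#'   `times` (list-column).
#' @export
#' @examples
#' study_design(dose = c(0, 160), n = c(4, 4), times = schedule_times("sparse"))
study_design <- function(dose, n, times) {
  if (!is.list(times)) times <- rep(list(as.numeric(times)), length(dose))
  stopifnot(length(dose) >= 1L, length(n) == length(dose),
            length(times) == length(dose))
  for (tt in times) {
    stopifnot(is.numeric(tt), length(tt) >= 1L, all(tt >= 0),
              !is.unsorted(tt, strictly = TRUE))
  }
  if (any(dose < 0 | dose > 500 | dose != round(dose))) {
    stop("doses must be integers in [0, 500] mg", call. = FALSE)
  }
  if (any(n < 1 | n != round(n))) stop("group sizes must be integers >= 1",
                                       call. = FALSE)
  out <- tibble::tibble(dose = as.integer(dose), n = as.integer(n),
                        times = times)
  class(out) <- c("study_design", class(out))
  out
}

#' Append one dose group to a design
#'
#' @param design A [study_design()].
#' @param dose,n,times As in [study_design()]; `times` a numeric vector.
#' @return The extended `study_design`.
#' @export
add_group <- function(design, dose, n, times) {
  stopifnot(inherits(design, "study_design"))
  g <- study_design(dose, n, times)
  out <- dplyr::bind_rows(design, g)
  class(out) <- c("study_design", setdiff(class(out), "study_design"))
  out
}

#' Total number of individuals in a design
#' @param design A [study_design()].
#' @return Integer sample size.
#' @export
design_n <- function(design) sum(design$n)

#' The fixed initial cohort design of the scenario
#'
#' Two groups of four individuals at 0 and 160 mg, sharing the chosen
#' sampling schedule. This design is used, unoptimized, for the first
#' cohort of every adaptive trial.
#'
#' @param schedule `"sparse"` or `"rich"`, see [schedule_times()].
#' @return A `study_design` of 8 individuals.
#' @export
initial_design <- function(schedule = c("sparse", "rich")) {
  study_design(dose = c(0L, 160L), n = c(4L, 4L),
               times = schedule_times(schedule))
}
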