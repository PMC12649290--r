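#' Simulate a virtual cohort at steady state
#'
#' Each virtual subject receives the regimen from a drug-naive state; after a
#' run-in the final `window_h` hours (aligned to a cycle start) are evaluated
#' on a fine grid. Exposure metrics are the trapezoidal AUC over the window
#' (reported in mg/L x h), and the window extrema `c_max` / `c_min` (ug/L).
#' Outputs are individual predicted concentrations (no residual error).
#'
#' @param pop A [pk_population_parameters()] object.
#' @param regimen A [pk_regimen()] object; its `boosted` flag sets the
#'   cobicistat covariate for every subject.
#' @param n Number of virtual subjects.
#' @param seed Optional integer seed (recorded in the output attributes).
#' @param weight_policy `"reference"` (all subjects at the allometric
#'   reference weight, default) or `"sampled"` (log-normal body weights,
#'   median 78.5 kg, 15% CV, as in the modeled cohort).
#' @param eta Optional tibble from [pk_sample_eta()] (or a 2-column matrix)
#'   fixing the random effects; overrides `n`.
#' @param weights Optional numeric vector of body weights, recycled to `n`.
#' @param run_in_days Drug-naive run-in before the evaluation window (days).
#'   The window starts at the first cycle start at or after this run-in.
#' @param grid_step Evaluation grid step (h), at most 0.25.
#' @param window_h Evaluation window length (h).
#' @param keep_profiles If `TRUE`, attach the per-subject window profiles as
#'   a list-column `profile`.
#' @return A tibble with one row per subject x analyte: `regimen`, `subject`,
#'   `weight`, `eta_cl_parent`, `eta_cl_metab`, `analyte` (`"parent"` or
#'   `"metab"`), `auc_0_144` (mg/L x h), `c_max`, `c_min` (ug/L). Attributes
#'   `seed` and `window` record the simulation protocol.
#' @examples
#' pop <- pk_population_parameters()
#' typ <- pk_simulate_cohort(pop, pk_regimen("DL1"), n = 1,
#'                           eta = matrix(0, 1, 2))
#' typ$auc_0_144[typ$analyte == "parent"] # ~ 6 x 80 / 19 = 25.3 mg/L x h
#' @export
pk_simulate_cohort <- function(pop, regimen, n = 1000, seed = NULL,
                               weight_policy = c("reference", "sampled"),
                               eta = NULL, weights = NULL,
                               run_in_days = 21, grid_step = 0.25,
                               window_h = 144, keep_profiles = FALSE) {
  stopifnot(inherits(pop, "pk_population_parameters"),
            inherits(regimen, "pk_regimen"))
  weight_policy <- match.arg(weight_policy)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(eta)) {
    stopifnot(n >= 1)
    eta <- as.matrix(pk_sample_eta(pop, n)[, c("eta_cl_parent", "eta_cl_metab")])
  } else {
    eta <- etas_as_matrix(eta)
    n <- nrow(eta)
  }
  if (is.null(weights)) {
    weights <- switch(weight_policy,
      reference = rep(pop$wt_ref, n),
      sampled = rlnorm(n, meanlog = log(78.5), sdlog = sqrt(log(1 + 0.15^2))))
  } else {
    weights <- rep_len(weights, n)
  }
  sim_metrics(pop, regimen, eta, weights, run_in_days, grid_step, window_h,
              keep_profiles, seed)
}

etas_as_matrix <- function(eta) {
  if (is.data.frame(eta)) eta <- as.matrix(eta[, c("eta_cl_parent", "eta_cl_metab")])
  stopifnot(is.matrix(eta), ncol(eta) == 2)
  unname(eta)
}

sim_metrics <- function(pop, regimen, eta, weights, run_in_days, grid_step,
                        window_h, keep_profiles, seed) {
  w_start <- ceiling(run_in_days * 24 / regimen$cycle_length) *
    regimen$cycle_length
  times <- seq(w_start, w_start + window_h, by = grid_step)
  doses <- regimen_doses(regimen, w_start + window_h)
  n <- nrow(eta)
  rows <- vector("list", n)
  profiles <- if (keep_profiles) vector("list", n)
  for (i in seq_len(n)) {
    p <- pk_individual_parameters(pop, weight = weights[i],
                                  cobicistat = regimen$boosted, eta = eta[i, ])
    m <- cpp_profile(p$ka, p$v_parent, p$cl_parent, p$v_metab, p$cl_metab,
                     p$f_m, doses$time, doses$amount, times)
    rows[[i]] <- tibble::tibble(
      subject = i, weight = weights[i],
      eta_cl_parent = eta[i, 1], eta_cl_metab = eta[i, 2],
      analyte = c("parent", "metab"),
      auc_0_144 = c(pk_auc(times, m[, 1]), pk_auc(times, m[, 2])),
      c_max = c(max(m[, 1]), max(m[, 2])),
      c_min = c(min(m[, 1]), min(m[, 2])))
    if (keep_profiles) {
      profiles[[i]] <- new_profile(times - w_start, m[, 1], m[, 2])
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, regimen = regimen$label, .before = 1)
  if (keep_profiles) out$profile <- rep(profiles, each = 2)
  attr(out, "seed") <- seed
  attr(out, "window") <- c(start = w_start, length = window_h, step = grid_step)
  out
}

#' Simulate a virtual within-subject crossover across regimens
#'
#' Every virtual subject receives each regimen at steady state; the washout
#' between periods is modeled as an independent drug-naive run-in. The same
#' random-effect vector (and body weight) is reused across all regimens, so
#' ratios of exposure metrics are within-subject.
#'
#' @inheritParams pk_simulate_cohort
#' @param regimens A list of [pk_regimen()] objects (at least two).
#' @return A tibble as in [pk_simulate_cohort()], stacked over regimens.
#' @examples
#' pop <- pk_population_parameters()
#' x <- pk_crossover(pop, list(pk_regimen("DL1"), pk_regimen("DL3")),
#'                   n = 50, seed = 7)
#' pk_gmr(x, test = "DL3", ref = "DL1")
#' @export
pk_crossover <- function(pop, regimens, n = 1000, seed = NULL,
                         weight_policy = c("reference", "sampled"),
                         eta = NULL, weights = NULL, run_in_days = 21,
                         grid_step = 0.25, window_h = 144) {
  stopifnot(is.list(regimens), length(regimens) >= 2)
  weight_policy <- match.arg(weight_policy)
  labels <- vapply(regimens, function(r) r$label, character(1))
  if (anyDuplicated(labels)) stop("regimen labels must be unique", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(eta)) {
    eta <- as.matrix(pk_sample_eta(pop, n)[, c("eta_cl_parent", "eta_cl_metab")])
  } else {
    eta <- etas_as_matrix(eta)
    n <- nrow(eta)
  }
  if (is.null(weights)) {
    weights <- switch(weight_policy,
      reference = rep(pop$wt_ref, n),
      sampled = rlnorm(n, meanlog = log(78.5), sdlog = sqrt(log(1 + 0.15^2))))
  } else {
    weights <- rep_len(weights, n)
  }
  out <- purrr::map(regimens, function(r) {
    sim_metrics(pop, r, eta, weights, run_in_days, grid_step, window_h,
                FALSE, seed)
  })
  out <- dplyr::bind_rows(out)
  attr(out, "seed") <- seed
  out
}

#' Median and outer percentiles of exposure metrics
#'
#' Empirical 5th / 50th / 95th percentiles (linear-interpolation convention,
#' [stats::quantile()] type 7) of each exposure metric, per regimen and
#' analyte.
#'
#' @param metrics Tibble from [pk_simulate_cohort()] or [pk_crossover()].
#' @return A long tibble with `regimen`, `analyte`, `metric`, `p5`, `median`,
#'   `p95`.
#' @export
pk_summarize_percentiles <- function(metrics) {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 1)
  metrics |>
    tidyr::pivot_longer(dplyr::all_of(c("auc_0_144", "c_max", "c_min")),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("regimen", "analyte", "metric")))) |>
    dplyr::summarise(
      p5 = quantile(.data$value, 0.05, names = FALSE),
      median = median(.data$value),
      p95 = quantile(.data$value, 0.95, names = FALSE),
      .groups = "drop")
}
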