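#' Sparse-sampling PK study design
#'
#' Describes a two-occasion boosting study: subjects on osimertinib
#' monotherapy reach steady state, occasion-1 samples are drawn (pre-dose
#' and three jittered windows), cobicistat 150 mg QD is then added and after
#' 21 days of co-treatment occasion-2 samples are drawn. Both analytes
#' (parent and AZ5104) are measured at every sampling time.
#'
#' @param n_subjects Number of subjects (default 11).
#' @param dose_mg Osimertinib dose per administration (mg); scalar or one
#'   value per subject (a 160 mg subject can be expressed as an override).
#' @param weights Optional fixed body weights (kg), one per subject (e.g. to
#'   include a 47 kg subject); when `NULL`, weights are drawn log-normally.
#' @param weight_median,weight_cv Log-normal weight distribution used when
#'   `weights` is `NULL` (median 78.5 kg, 15% CV, as in the modeled cohort).
#' @param windows List of length-2 vectors: sampling windows per occasion in
#'   h after the occasion's dose. The pre-dose sample is the degenerate
#'   window `c(0, 0)`; jitter is uniform within each window.
#' @param run_in_days Monotherapy days before occasion-1 sampling
#'   (occasion 1 samples around the last monotherapy dose).
#' @param boost_days Days of cobicistat co-treatment before occasion-2
#'   sampling.
#' @param screening_threshold Monotherapy steady-state trough used by
#'   [pk_apply_screening()] (ug/L; the enrolment criterion was <= 195).
#' @return An object of class `pk_study_design`.
#' @export
pk_study_design <- function(n_subjects = 11, dose_mg = 80, weights = NULL,
                            weight_median = 78.5, weight_cv = 0.15,
                            windows = list(c(0, 0), c(0.5, 1.5),
                                           c(2.5, 3.5), c(7, 8)),
                            run_in_days = 30, boost_days = 21,
                            screening_threshold = 195) {
  stopifnot(n_subjects >= 1, all(dose_mg > 0), run_in_days >= 1,
            boost_days >= 1, is.list(windows), length(windows) >= 1)
  dt_max <- 24 # daily dosing interval
  for (w in windows) {
    if (length(w) != 2 || w[1] > w[2] || w[1] < 0 || w[2] >= dt_max) {
      stop("each sampling window must lie within one 24 h dosing interval",
           call. = FALSE)
    }
  }
  if (!is.null(weights)) stopifnot(length(weights) == n_subjects, all(weights > 0))
  structure(
    list(n_subjects = n_subjects, dose_mg = rep_len(dose_mg, n_subjects),
         weights = weights, weight_median = weight_median,
         weight_cv = weight_cv, windows = windows,
         run_in_days = run_in_days, boost_days = boost_days,
         screening_threshold = screening_threshold),
    class = "pk_study_design")
}

#' Generate a synthetic sparse PK dataset from known truth
#'
#' Simulates the full dosing history of each subject (daily monotherapy
#' doses through the run-in, then daily boosted doses through the
#' co-treatment period), evaluates true concentrations at the jittered
#' sampling times of both occasions, applies proportional residual error,
#' and emits long-format NONMEM-style records. The latent random effects
#' are returned alongside for recovery testing.
#'
#' @param design A [pk_study_design()] object.
#' @param truth A [pk_population_parameters()] object used as the data-
#'   generating truth.
#' @param seed Optional integer seed.
#' @param eta Optional fixed random-effect matrix (n x 2), e.g. zeros.
#' @return An object of class `pk_cohort`: a list with `data` (the record
#'   tibble with columns `ID, TIME, AMT, EVID, CMT, MDV, DV, DVID, WT, COBI,
#'   OCC`), `subjects` (per-subject weight, dose and latent eta), `design`
#'   and `truth`.
#' @examples
#' coh <- pk_generate_cohort(pk_study_design(), pk_population_parameters(),
#'                           seed = 1)
#' nrow(dplyr::filter(coh$data, EVID == 0, DVID == 1)) # 88 parent samples
#' @export
pk_generate_cohort <- function(design, truth, seed = NULL, eta = NULL) {
  stopifnot(inherits(design, "pk_study_design"),
            inherits(truth, "pk_population_parameters"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_subjects
  if (is.null(eta)) {
    eta <- as.matrix(pk_sample_eta(truth, n)[, c("eta_cl_parent", "eta_cl_metab")])
  } else {
    eta <- etas_as_matrix(eta)
    stopifnot(nrow(eta) == n)
  }
  weights <- design$weights %||%
    rlnorm(n, log(design$weight_median), sqrt(log(1 + design$weight_cv^2)))

  t_cobi <- design$run_in_days * 24               # first boosted dose
  t_occ1 <- t_cobi - 24                            # last monotherapy dose
  t_occ2 <- t_cobi + (design$boost_days - 1) * 24  # last boosted dose
  dose_times <- seq(0, t_occ2, by = 24)

  subj <- vector("list", n)
  for (i in seq_len(n)) {
    tau1 <- vapply(design$windows, function(w) runif(1, w[1], w[2]), numeric(1))
    tau2 <- vapply(design$windows, function(w) runif(1, w[1], w[2]), numeric(1))
    obs_t <- c(t_occ1 + tau1, t_occ2 + tau2)
    occ <- rep(1:2, each = length(design$windows))
    dose_rows <- tibble::tibble(
      ID = i, TIME = dose_times, AMT = design$dose_mg[i] * 1000, EVID = 1L,
      CMT = 1L, MDV = 1L, DV = NA_real_, DVID = NA_integer_,
      WT = weights[i], COBI = as.integer(dose_times >= t_cobi),
      OCC = ifelse(dose_times >= t_cobi, 2L, 1L))
    obs_rows <- tibble::tibble(
      ID = i, TIME = rep(obs_t, each = 2), AMT = NA_real_, EVID = 0L,
      CMT = rep(c(2L, 3L), length(obs_t)), MDV = 0L, DV = NA_real_,
      DVID = rep(c(1L, 2L), length(obs_t)), WT = weights[i],
      COBI = as.integer(rep(obs_t, each = 2) >= t_cobi),
      OCC = rep(occ, each = 2))
    rec <- dplyr::bind_rows(dose_rows, obs_rows)
    # stable sort: pre-dose observations precede the dose given at that time
    rec <- rec[order(rec$TIME, rec$EVID), ]
    ip <- pk_individual_parameters(truth, weight = weights[i],
                                   cobicistat = FALSE, eta = eta[i, ])
    pred <- cpp_sim_events(ip$ka, ip$v_parent, ip$cl_parent, ip$v_metab,
                           ip$cl_metab, ip$f_m, truth$theta_cobi,
                           rec$TIME, rec$EVID,
                           ifelse(is.na(rec$AMT), 0, rec$AMT),
                           rec$CMT, rec$COBI)
    rec$DV[rec$EVID == 0] <- pk_add_residual_error(pred, truth$sigma_prop)
    subj[[i]] <- rec
  }
  structure(
    list(data = dplyr::bind_rows(subj),
         subjects = tibble::tibble(subject = seq_len(n), weight = weights,
                                   dose_mg = design$dose_mg,
                                   eta_cl_parent = eta[, 1],
                                   eta_cl_metab = eta[, 2]),
         design = design, truth = truth),
    class = "pk_cohort")
}

#' @export
print.pk_cohort <- function(x, ...) {
  cat(sprintf("<pk_cohort> %d subjects, %d records (%d observations)\n",
              nrow(x$subjects), nrow(x$data), sum(x$data$EVID == 0)))
  invisible(x)
}

#' Apply the low-exposure screening criterion
#'
#' Retains only subjects whose *monotherapy* steady-state trough (model
#' predicted from their latent parameters, i.e. the physiologic selection of
#' the trial) is at or below the threshold. Models the enrolment bias toward
#' high-clearance subjects.
#'
#' @param cohort A `pk_cohort` from [pk_generate_cohort()].
#' @param threshold Trough threshold in ug/L (default from the design).
#' @return The filtered `pk_cohort`; the per-subject troughs and the
#'   selection flags are attached as attribute `"selection"`.
#' @export
pk_apply_screening <- function(cohort,
                               threshold = cohort$design$screening_threshold) {
  stopifnot(inherits(cohort, "pk_cohort"))
  sub <- cohort$subjects
  trough <- vapply(seq_len(nrow(sub)), function(i) {
    ip <- pk_individual_parameters(
      cohort$truth, weight = sub$weight[i], cobicistat = FALSE,
      eta = c(sub$eta_cl_parent[i], sub$eta_cl_metab[i]))
    reg <- pk_regimen("custom", cycle_length = 24, dose_times = 0,
                      amount_mg = sub$dose_mg[i], label = "QD")
    pk_conc_steady_state(ip, reg, grid_step = 0.25)$conc_parent[1]
  }, numeric(1))
  keep <- trough <= threshold
  if (!any(keep)) {
    stop("no subject passes screening at ", threshold,
         " ug/L; enlarge the candidate pool or raise the threshold",
         call. = FALSE)
  }
  out <- cohort
  out$subjects <- sub[keep, ]
  out$data <- dplyr::filter(cohort$data, .data$ID %in% sub$subject[keep])
  attr(out, "selection") <- tibble::tibble(
    subject = sub$subject, trough_ss = trough, retained = keep)
  out
}

#' Write / read a long-format PK dataset
#'
#' NONMEM-style rectangular comma-separated text with a header row and the
#' columns `ID, TIME, AMT, EVID, CMT, MDV, DV, DVID, WT, COBI, OCC`; missing
#' values (`DV` on dose rows, `AMT`/`DVID` on observation rows) are coded
#' `"."`. `DVID` 1 = parent, 2 = metabolite.
#'
#' @param data The record tibble (e.g. `pk_generate_cohort(...)$data`).
#' @param path File path.
#' @return `pk_write_dataset()` returns `path` invisibly;
#'   `pk_read_dataset()` returns the record tibble.
#' @export
pk_write_dataset <- function(data, path) {
  cols <- c("ID", "TIME", "AMT", "EVID", "CMT", "MDV", "DV", "DVID", "WT",
            "COBI", "OCC")
  stopifnot(is.data.frame(data), all(cols %in% names(data)))
  out <- dplyr::mutate(data[cols], dplyr::across(
    dplyr::everything(),
    function(x) ifelse(is.na(x), ".", format(x, digits = 15, trim = TRUE,
                                             scientific = FALSE))))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname pk_write_dataset
#' @export
pk_read_dataset <- function(path) {
  raw <- readr::read_csv(path, na = ".", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  cols <- c("ID", "TIME", "AMT", "EVID", "CMT", "MDV", "DV", "DVID", "WT",
            "COBI", "OCC")
  if (!all(cols %in% names(raw))) {
    stop("missing required columns: ",
         paste(setdiff(cols, names(raw)), collapse = ", "), call. = FALSE)
  }
  num <- function(col, integer = FALSE) {
    x <- raw[[col]]
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) {
      stop(sprintf("malformed value '%s' in column %s at data line %d",
                   x[bad[1]], col, bad[1] + 1), call. = FALSE)
    }
    if (integer) as.integer(v) else v
  }
  tibble::tibble(
    ID = num("ID", TRUE), TIME = num("TIME"), AMT = num("AMT"),
    EVID = num("EVID", TRUE), CMT = num("CMT", TRUE), MDV = num("MDV", TRUE),
    DV = num("DV"), DVID = num("DVID", TRUE), WT = num("WT"),
    COBI = num("COBI", TRUE), OCC = num("OCC", TRUE))
}

#' Build design / truth objects from YAML configuration files
#'
#' Small key-value configuration surface for scripted dataset generation:
#' the design file maps directly onto [pk_study_design()] arguments; the
#' truth file onto [pk_population_parameters()], with the BSV block given as
#' `omega: {var_cl_parent, var_cl_metab, cov}`.
#'
#' @param path YAML file path.
#' @return A `pk_study_design` or `pk_population_parameters` object.
#' @export
pk_design_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$windows)) cfg$windows <- lapply(cfg$windows, as.numeric)
  if (!is.null(cfg$weights)) cfg$weights <- as.numeric(cfg$weights)
  do.call(pk_study_design, cfg)
}

#' @rdname pk_design_from_yaml
#' @export
pk_truth_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$omega)) {
    om <- cfg$omega
    cfg$omega <- matrix(c(om$var_cl_parent, om$cov, om$cov, om$var_cl_metab),
                        2, 2)
  }
  do.call(pk_population_parameters, cfg)
}
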