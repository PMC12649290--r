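#' Population pharmacokinetic parameters
#'
#' Container for the fixed effects, between-subject variability (BSV)
#' covariance, residual error magnitude and covariate coefficients of the
#' parent-metabolite model. Defaults are the final published estimates for
#' cobicistat-boosted osimertinib: all volumes and clearances are apparent
#' (per bioavailability F), allometrically referenced to 70 kg, and the
#' cobicistat effect is a proportional multiplier on parent CL/F.
#'
#' @param ka First-order absorption rate constant (1/h); fixed at 0.24 in the
#'   final model (not identifiable from sparse data).
#' @param v_parent Apparent central volume of osimertinib, V/F (L).
#' @param cl_parent Apparent clearance of osimertinib, CL/F (L/h).
#' @param v_metab Apparent volume of the metabolite AZ5104 (L).
#' @param cl_metab Apparent clearance of AZ5104 (L/h).
#' @param theta_cobi Proportional effect of concomitant cobicistat on parent
#'   CL/F (0.704 = a 29.6% reduction).
#' @param f_m Fraction of eliminated parent converted to AZ5104
#'   (dimensionless, fixed at 0.25).
#' @param omega 2x2 covariance matrix of the log-normal BSV on
#'   (parent CL/F, metabolite CL/F).
#' @param sigma_prop Proportional residual error standard deviation.
#' @param wt_ref Reference body weight for allometry (kg).
#' @return An object of class `pk_population_parameters`.
#' @examples
#' pop <- pk_population_parameters()
#' pop$cl_parent * pop$theta_cobi # boosted typical CL/F
#' @export
pk_population_parameters <- function(ka = 0.24,
                                     v_parent = 990,
                                     cl_parent = 19.0,
                                     v_metab = 184,
                                     cl_metab = 47.3,
                                     theta_cobi = 0.704,
                                     f_m = 0.25,
                                     omega = matrix(c(0.0691, 0.0292,
                                                      0.0292, 0.0598), 2, 2),
                                     sigma_prop = 0.178,
                                     wt_ref = 70) {
  stopifnot(is.numeric(ka), is.numeric(omega), length(omega) == 4)
  omega <- matrix(as.numeric(omega), 2, 2)
  vals <- c(ka = ka, v_parent = v_parent, cl_parent = cl_parent,
            v_metab = v_metab, cl_metab = cl_metab, theta_cobi = theta_cobi,
            sigma_prop = sigma_prop, wt_ref = wt_ref)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all rates, volumes, clearances, theta_cobi, sigma_prop and wt_ref must be strictly positive", call. = FALSE)
  }
  if (f_m < 0 || f_m > 1) stop("f_m must lie in [0, 1]", call. = FALSE)
  if (max(abs(omega - t(omega))) > 1e-12) stop("omega must be symmetric", call. = FALSE)
  if (min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("omega must be positive definite", call. = FALSE)
  }
  structure(
    list(ka = ka, v_parent = v_parent, cl_parent = cl_parent,
         v_metab = v_metab, cl_metab = cl_metab, theta_cobi = theta_cobi,
         f_m = f_m, omega = omega, sigma_prop = sigma_prop, wt_ref = wt_ref),
    class = "pk_population_parameters")
}

#' @export
print.pk_population_parameters <- function(x, ...) {
  cat("<pk_population_parameters>\n")
  cat(sprintf("  ka %.3g /h | V/F %.4g L | CL/F %.4g L/h (parent)\n",
              x$ka, x$v_parent, x$cl_parent))
  cat(sprintf("  V/F %.4g L | CL/F %.4g L/h (metabolite), f_m %.3g\n",
              x$v_metab, x$cl_metab, x$f_m))
  cat(sprintf("  cobicistat effect on parent CL/F: %.3g (%.1f%% reduction)\n",
              x$theta_cobi, 100 * (1 - x$theta_cobi)))
  cat(sprintf("  BSV variances (CL parent, CL metab): %.4g, %.4g; cov %.4g\n",
              x$omega[1, 1], x$omega[2, 2], x$omega[1, 2]))
  cat(sprintf("  proportional residual SD %.3g; allometric reference %.3g kg\n",
              x$sigma_prop, x$wt_ref))
  invisible(x)
}

#' Realize individual parameters from population parameters
#'
#' Applies allometric scaling (exponent 1 on volumes, 0.75 on clearances,
#' -0.25 on the absorption rate constant), the cobicistat covariate on parent
#' CL/F, and log-normal random effects on the two clearances.
#'
#' @param pop A [pk_population_parameters()] object.
#' @param weight Body weight (kg).
#' @param cobicistat Logical; concomitant cobicistat 150 mg QD.
#' @param eta Numeric length-2 vector of random effects
#'   (parent CL/F, metabolite CL/F) on the log scale.
#' @return An object of class `pk_individual_parameters`: a list with
#'   `ka`, `v_parent`, `cl_parent`, `v_metab`, `cl_metab`, `f_m`.
#' @examples
#' pop <- pk_population_parameters()
#' pk_individual_parameters(pop, weight = 70, cobicistat = TRUE)$cl_parent
#' @export
pk_individual_parameters <- function(pop, weight = pop$wt_ref,
                                     cobicistat = FALSE, eta = c(0, 0)) {
  stopifnot(inherits(pop, "pk_population_parameters"), length(eta) == 2,
            all(is.finite(eta)))
  if (!is.finite(weight) || weight <= 0) {
    stop("weight must be a positive number of kilograms", call. = FALSE)
  }
  w <- weight / pop$wt_ref
  structure(
    list(ka = pop$ka * w^(-0.25),
         v_parent = pop$v_parent * w,
         cl_parent = pop$cl_parent * w^0.75 *
           (if (isTRUE(cobicistat)) pop$theta_cobi else 1) * exp(eta[[1]]),
         v_metab = pop$v_metab * w,
         cl_metab = pop$cl_metab * w^0.75 * exp(eta[[2]]),
         f_m = pop$f_m),
    class = "pk_individual_parameters")
}

#' Sample correlated between-subject random effects
#'
#' Draws iid bivariate-normal random effects on (log parent CL/F,
#' log metabolite CL/F) with the population BSV covariance.
#'
#' @inheritParams pk_individual_parameters
#' @param n Number of subjects.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `subject`, `eta_cl_parent`, `eta_cl_metab`.
#' @export
pk_sample_eta <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "pk_population_parameters"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = pop$omega)
  draws <- matrix(draws, ncol = 2)
  tibble::tibble(subject = seq_len(n),
                 eta_cl_parent = draws[, 1],
                 eta_cl_metab = draws[, 2])
}

#' Apply proportional residual error
#'
#' Observation model `y = c * (1 + eps)`, `eps ~ N(0, sigma_prop^2)`,
#' independent per observation. Negative simulated observations are retained
#' (no lower-limit-of-quantification censoring).
#'
#' @param conc Vector of true concentrations (ug/L).
#' @param sigma_prop Proportional residual SD.
#' @param seed Optional integer seed.
#' @return Vector of observed concentrations.
#' @export
pk_add_residual_error <- function(conc, sigma_prop, seed = NULL) {
  stopifnot(all(is.finite(conc)), sigma_prop >= 0)
  if (!is.null(seed)) set.seed(seed)
  conc * (1 + rnorm(length(conc), 0, sigma_prop))
}
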