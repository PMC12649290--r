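#' @noRd
assert_individual <- function(p) {
  stopifnot(inherits(p, "pk_individual_parameters"))
  vals <- unlist(p[c("ka", "v_parent", "cl_parent", "v_metab", "cl_metab")])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("individual rates, volumes and clearances must be strictly positive",
         call. = FALSE)
  }
  if (p$f_m < 0 || p$f_m > 1) stop("f_m must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

# Nudge near-equal rate constants apart (mirrors the compiled engine) so the
# distinct-rate tri-exponential expressions never divide by ~0.
separate_rates <- function(ka, k20, k30, tol = 1e-8, f = 1e-7) {
  if (abs(ka - k20) < tol * max(ka, k20)) k20 <- k20 * (1 + f)
  if (abs(ka - k30) < tol * max(ka, k30)) k30 <- k30 * (1 - f)
  if (abs(k20 - k30) < tol * max(k20, k30)) k30 <- k30 * (1 - f)
  c(ka, k20, k30)
}

# Exponential-term decomposition of the single-dose amount curves:
# A2(t) = sum(c2 * exp(-k t)), A3(t) = sum(c3 * exp(-k t)) over k = (ka, k20, k30).
exp_coefs <- function(p, amount) {
  k <- separate_rates(p$ka, p$cl_parent / p$v_parent, p$cl_metab / p$v_metab)
  ka <- k[1]; k20 <- k[2]; k30 <- k[3]
  b <- amount * ka / (ka - k20)
  cc <- p$f_m * k20 * ka * amount
  list(k = k,
       c2 = c(-b, b, 0),
       c3 = cc * c(1 / ((k20 - ka) * (k30 - ka)),
                   1 / ((ka - k20) * (k30 - k20)),
                   1 / ((ka - k30) * (k20 - k30))))
}

new_profile <- function(times, cp, cm) {
  tibble::new_tibble(
    tibble::tibble(time = as.numeric(times),
                   conc_parent = pmax(cp, 0),
                   conc_metab = pmax(cm, 0)),
    class = "pk_profile")
}

#' Concentration profile after a single oral dose
#'
#' Analytic solution of the first-order cascade depot -> parent central ->
#' metabolite: `dA1/dt = -ka A1`, `dA2/dt = ka A1 - (CL_p/V_p) A2`,
#' `dA3/dt = f_m (CL_p/V_p) A2 - (CL_m/V_m) A3`, concentrations `A2/V_p` and
#' `A3/V_m` in ug/L.
#'
#' @param p A [pk_individual_parameters()] object.
#' @param amount Dose amount in ug (80 mg = 80000).
#' @param times Time grid in h (non-decreasing).
#' @param dose_time Dose administration time in h.
#' @return A `pk_profile` tibble with `time`, `conc_parent`, `conc_metab`.
#' @export
pk_conc_single_dose <- function(p, amount, times, dose_time = 0) {
  pk_conc_profile(p, tibble::tibble(time = dose_time, amount = amount), times)
}

#' Concentration profile under an arbitrary dose list
#'
#' Superposition of analytic single-dose solutions (the kinetics are linear).
#' An empty dose list yields an all-zero profile.
#'
#' @inheritParams pk_conc_single_dose
#' @param doses Data frame with columns `time` (h, sorted) and `amount` (ug).
#' @return A `pk_profile` tibble.
#' @export
pk_conc_profile <- function(p, doses, times) {
  assert_individual(p)
  stopifnot(is.data.frame(doses), all(c("time", "amount") %in% names(doses)),
            all(diff(as.numeric(times)) >= 0))
  if (any(doses$amount < 0) || any(doses$time < 0)) {
    stop("dose times and amounts must be non-negative", call. = FALSE)
  }
  if (is.unsorted(doses$time)) stop("doses must be sorted by time", call. = FALSE)
  if (nrow(doses) == 0) return(new_profile(times, 0 * as.numeric(times), 0 * as.numeric(times)))
  m <- cpp_profile(p$ka, p$v_parent, p$cl_parent, p$v_metab, p$cl_metab, p$f_m,
                   as.numeric(doses$time), as.numeric(doses$amount),
                   as.numeric(times))
  new_profile(times, m[, 1], m[, 2])
}

#' Periodic steady-state profile over one dosing cycle
#'
#' Exact periodic solution for a repeating dose cycle, obtained by closing the
#' geometric series of dose superposition term-by-term: each exponential term
#' `c exp(-k tau)` accumulates to `c exp(-k tau) / (1 - exp(-k T))` over an
#' infinite dosing history with cycle length `T`. Alternatively a finite
#' run-in is iterated cycle by cycle until the profile converges.
#'
#' @inheritParams pk_conc_single_dose
#' @param regimen A [pk_regimen()] object (the `boosted` flag is *not*
#'   applied here; `p` already carries the realized clearance).
#' @param grid_step Output grid step in h (must be <= 0.25).
#' @param method `"closure"` (exact geometric-series closure, default) or
#'   `"run_in"` (iterate cycles until the maximum relative change of the
#'   cycle profile is < 1e-6; errors after `max_cycles`).
#' @param max_cycles Cycle cap for `method = "run_in"`.
#' @return A `pk_profile` tibble over `[0, cycle_length]`.
#' @export
pk_conc_steady_state <- function(p, regimen, grid_step = 0.25,
                                 method = c("closure", "run_in"),
                                 max_cycles = 200) {
  assert_individual(p)
  stopifnot(inherits(regimen, "pk_regimen"))
  method <- match.arg(method)
  if (grid_step > 0.25 + 1e-12 || grid_step <= 0) {
    stop("grid_step must be positive and at most 0.25 h", call. = FALSE)
  }
  T_cyc <- regimen$cycle_length
  times <- seq(0, T_cyc, by = grid_step)
  if (abs(tail(times, 1) - T_cyc) > 1e-9) times <- c(times, T_cyc)
  if (method == "closure") {
    co <- exp_coefs(p, regimen$amount)
    cp <- cm <- numeric(length(times))
    for (tj in regimen$dose_times) {
      tau <- (times - tj) %% T_cyc
      tau[abs(times - tj) < 1e-12] <- 0  # dose instant: depot jump only
      for (i in 1:3) {
        geo <- exp(-co$k[i] * tau) / (1 - exp(-co$k[i] * T_cyc))
        cp <- cp + co$c2[i] * geo
        cm <- cm + co$c3[i] * geo
      }
    }
    return(new_profile(times, cp / p$v_parent, cm / p$v_metab))
  }
  # run-in: superpose whole cycles until the cycle profile stabilizes
  prev <- NULL
  for (n_cyc in seq_len(max_cycles)) {
    doses <- tibble::tibble(
      time = rep((seq_len(n_cyc) - 1) * T_cyc, each = length(regimen$dose_times)) +
        rep(regimen$dose_times, n_cyc),
      amount = regimen$amount)
    prof <- pk_conc_profile(p, doses, (n_cyc - 1) * T_cyc + times)
    cur <- cbind(prof$conc_parent, prof$conc_metab)
    if (!is.null(prev)) {
      rel <- max(abs(cur - prev) / pmax(abs(cur), 1e-12))
      if (rel < 1e-6) return(new_profile(times, cur[, 1], cur[, 2]))
    }
    prev <- cur
  }
  stop("steady state not reached within ", max_cycles, " cycles", call. = FALSE)
}

#' Trapezoidal area under the curve
#'
#' @param time,conc Numeric vectors (h, ug/L).
#' @return AUC in mg/L x h (ug x h/L divided by 1000).
#' @export
pk_auc <- function(time, conc) {
  stopifnot(length(time) == length(conc), length(time) >= 2)
  sum(diff(time) * (head(conc, -1) + tail(conc, -1)) / 2) / 1000
}
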