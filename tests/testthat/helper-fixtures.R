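# Shared fixtures: the published population parameters, small study designs,
# and cohorts generated in code (no stored data).

pop_default <- function() pk_population_parameters()

typical_subject <- function(pop = pop_default(), ...) {
  pk_individual_parameters(pop, ...)
}

# sparse two-occasion design at reduced size for estimation fixtures
sparse_design <- function(n = 6) pk_study_design(n_subjects = n)

# rich design: eight point samples per occasion spread over the interval
rich_design <- function(n = 12) {
  pk_study_design(
    n_subjects = n,
    windows = lapply(c(0, 0.5, 1, 2, 4, 8, 12, 18), function(t) c(t, t)))
}

# numeric ODE oracle for the depot -> parent -> metabolite cascade
ode_profile <- function(p, amount, times, rtol = 1e-10, atol = 1e-8) {
  rhs <- function(t, y, parms) {
    k20 <- p$cl_parent / p$v_parent
    k30 <- p$cl_metab / p$v_metab
    list(c(-p$ka * y[1],
           p$ka * y[1] - k20 * y[2],
           p$f_m * k20 * y[2] - k30 * y[3]))
  }
  out <- deSolve::lsoda(c(amount, 0, 0), unique(c(0, times)), rhs, NULL,
                        rtol = rtol, atol = atol)
  out <- out[match(times, out[, 1]), , drop = FALSE]
  tibble::tibble(time = times,
                 conc_parent = out[, 3] / p$v_parent,
                 conc_metab = out[, 4] / p$v_metab)
}

# natural-scale free parameters reported by the reduced sparse fits
pop_to_natural_fit <- function(fit) {
  p <- fit$estimates
  c(cl_parent = p$cl_parent, cl_metab = p$cl_metab,
    theta_cobi = p$theta_cobi)
}


# relative error against an oracle, floored at 1e-6 of the profile scale so
# values beneath the integrator tolerance do not dominate
rel_err <- function(got, ref) {
  max(abs(got - ref) / (abs(ref) + 1e-6 * max(abs(ref))))
}
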