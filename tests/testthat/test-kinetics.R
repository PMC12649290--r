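test_that("zero or empty dosing yields identically zero profiles", {
  p <- typical_subject()
  times <- seq(0, 48, 0.5)
  prof <- pk_conc_single_dose(p, amount = 0, times = times)
  expect_true(all(prof$conc_parent == 0) && all(prof$conc_metab == 0))
  empty <- pk_conc_profile(p, tibble::tibble(time = numeric(), amount = numeric()),
                           times)
  expect_true(all(empty$conc_parent == 0) && all(empty$conc_metab == 0))
})

test_that("analytic cascade matches a stiff ODE integration to 1e-6", {
  p <- typical_subject()
  times <- c(1, 6, 24, 72)
  got <- pk_conc_single_dose(p, 80000, times)
  ref <- ode_profile(p, 80000, times)
  expect_lt(max(abs(got$conc_parent - ref$conc_parent) / ref$conc_parent), 1e-6)
  expect_lt(max(abs(got$conc_metab - ref$conc_metab) / ref$conc_metab), 1e-6)

  set.seed(42)
  for (r in 1:5) {
    pop <- pk_population_parameters(
      ka = runif(1, 0.1, 2), v_parent = runif(1, 100, 2000),
      cl_parent = runif(1, 5, 60), v_metab = runif(1, 50, 600),
      cl_metab = runif(1, 5, 90))
    pr <- pk_individual_parameters(pop)
    tt <- sort(runif(6, 0.5, 96))
    got <- pk_conc_single_dose(pr, 50000, tt)
    ref <- ode_profile(pr, 50000, tt)
    expect_lt(rel_err(got$conc_parent, ref$conc_parent), 1e-6)
    expect_lt(rel_err(got$conc_metab, ref$conc_metab), 1e-6)
  }
})

test_that("near-equal rate constants use the stable limit branch, never NaN", {
  pop <- pk_population_parameters(ka = 0.24, v_parent = 100, cl_parent = 24,
                                  v_metab = 100, cl_metab = 24)
  p <- pk_individual_parameters(pop)   # ka == k20 == k30 == 0.24 exactly
  prof <- pk_conc_single_dose(p, 80000, c(0.5, 2, 10, 40))
  expect_true(all(is.finite(prof$conc_parent)), all(is.finite(prof$conc_metab)))
  # and close to a slightly perturbed, well-separated system
  pop2 <- pk_population_parameters(ka = 0.24 * 1.001, v_parent = 100,
                                   cl_parent = 24 * 0.999, v_metab = 100,
                                   cl_metab = 24 * 1.002)
  ref <- pk_conc_single_dose(pk_individual_parameters(pop2), 80000,
                             c(0.5, 2, 10, 40))
  expect_lt(max(abs(prof$conc_parent - ref$conc_parent) / ref$conc_parent), 0.02)
})

test_that("all eliminated parent converts to metabolite in proportion f_m", {
  p <- typical_subject()
  times <- seq(0, 3000, 0.5)   # long enough for full washout
  prof <- pk_conc_single_dose(p, 80000, times)
  # metabolite AUC x CL_m = total metabolite eliminated = total formed
  formed <- pk_auc(times, prof$conc_metab) * 1000 * p$cl_metab
  expect_equal(formed, 0.25 * 80000, tolerance = 1e-3)
})

test_that("kinetics are linear: superposition and dose proportionality", {
  p <- typical_subject()
  times <- seq(0, 96, 1)
  one <- pk_conc_profile(p, tibble::tibble(time = 0, amount = 80000), times)
  halves <- pk_conc_profile(p, tibble::tibble(time = c(0, 0), amount = 40000),
                            times)
  expect_equal(halves$conc_parent, one$conc_parent, tolerance = 1e-12)

  a <- tibble::tibble(time = c(0, 24), amount = 80000)
  b <- tibble::tibble(time = c(12, 48), amount = 40000)
  both <- dplyr::arrange(dplyr::bind_rows(a, b), time)
  sum_ab <- pk_conc_profile(p, a, times)$conc_metab +
    pk_conc_profile(p, b, times)$conc_metab
  expect_equal(pk_conc_profile(p, both, times)$conc_metab, sum_ab,
               tolerance = 1e-10)

  tripled <- pk_conc_profile(p, dplyr::mutate(a, amount = amount * 3), times)
  expect_equal(tripled$conc_parent,
               3 * pk_conc_profile(p, a, times)$conc_parent, tolerance = 1e-12)
})

test_that("six daily doses accumulate to less than the steady-state bound", {
  p <- typical_subject()
  times <- seq(0, 144, 0.25)
  prof <- pk_conc_profile(p, tibble::tibble(time = (0:5) * 24, amount = 80000),
                          times)
  expect_lt(pk_auc(times, prof$conc_parent), 6 * 80 / 19)
})

test_that("finite run-in converges to the periodic steady state", {
  p <- typical_subject()
  reg <- pk_regimen("DL1")
  ss <- pk_conc_steady_state(p, reg)
  # 21 daily doses, evaluated over the final cycle
  doses <- tibble::tibble(time = (0:20) * 24, amount = 80000)
  prof <- pk_conc_profile(p, doses, 480 + ss$time)
  expect_lt(max(abs(prof$conc_parent - ss$conc_parent) / ss$conc_parent), 0.01)
  expect_lt(max(abs(prof$conc_metab - ss$conc_metab) / ss$conc_metab), 0.01)
  # iterative run-in method agrees with the geometric-series closure
  ss2 <- pk_conc_steady_state(p, reg, method = "run_in")
  expect_lt(max(abs(ss2$conc_parent - ss$conc_parent) / ss$conc_parent), 1e-4)
})

test_that("steady-state cycle AUCs obey the clearance identities", {
  pop <- pop_default()
  p <- typical_subject(pop)
  for (lvl in c("DL1", "DL3", "DL4")) {
    reg <- pk_regimen(lvl)
    p_i <- pk_individual_parameters(pop, cobicistat = reg$boosted)
    ss <- pk_conc_steady_state(p_i, reg, grid_step = 0.05)
    cycle_dose <- length(reg$dose_times) * reg$amount
    expect_equal(pk_auc(ss$time, ss$conc_parent) * 1000,
                 cycle_dose / p_i$cl_parent, tolerance = 1e-3)
    expect_equal(pk_auc(ss$time, ss$conc_metab) * 1000,
                 pop$f_m * cycle_dose / p_i$cl_metab, tolerance = 1e-3)
  }
})

test_that("steady-state trough and peak match the closed-form reference", {
  ss <- pk_conc_steady_state(typical_subject(), pk_regimen("DL1"))
  # independent closed-form superposition at tau = 0 (trough)
  ka <- 0.24; k20 <- 19 / 990
  trough <- 80000 * ka / (990 * (ka - k20)) *
    (exp(-k20 * 24) / (1 - exp(-k20 * 24)) -
       exp(-ka * 24) / (1 - exp(-ka * 24)))
  expect_equal(ss$conc_parent[1], trough, tolerance = 1e-8)
  expect_equal(ss$conc_parent[1], 149.8, tolerance = 1e-3)
  expect_equal(max(ss$conc_parent), 191.6, tolerance = 1e-3)
})

test_that("boosting scales parent cycle AUC by 1/0.704 and leaves metabolite AUC alone", {
  pop <- pop_default()
  reg <- pk_regimen("DL1")
  mono <- pk_conc_steady_state(pk_individual_parameters(pop), reg)
  boost <- pk_conc_steady_state(pk_individual_parameters(pop, cobicistat = TRUE),
                                reg)
  # trapezoid sums of differently shaped profiles agree to the grid error
  expect_equal(pk_auc(boost$time, boost$conc_parent),
               pk_auc(mono$time, mono$conc_parent) / 0.704, tolerance = 1e-4)
  expect_equal(pk_auc(boost$time, boost$conc_metab),
               pk_auc(mono$time, mono$conc_metab), tolerance = 1e-8)
})

test_that("invalid kinetic parameters are rejected", {
  pop <- pop_default()
  expect_error(pk_population_parameters(cl_parent = -1), "positive")
  expect_error(pk_population_parameters(f_m = 1.2), "f_m")
  expect_error(pk_individual_parameters(pop, weight = 0), "weight")
  bad <- typical_subject()
  bad$v_parent <- -5
  expect_error(pk_conc_single_dose(bad, 1000, 1:3), "positive")
})

test_that("a practically non-accumulating drug trips the run-in cycle cap", {
  slow <- pk_population_parameters(cl_parent = 0.001)  # t1/2 ~ years
  p <- pk_individual_parameters(slow)
  expect_error(pk_conc_steady_state(p, pk_regimen("DL1"), method = "run_in",
                                    max_cycles = 20), "not reached")
})
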