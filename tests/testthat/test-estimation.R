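test_that("FOCE-I agrees with adaptive quadrature on sparse and rich fixtures", {
  pop <- pop_default()
  sparse <- pk_generate_cohort(sparse_design(6), pop, seed = 71)
  f <- pk_ofv_foce(pop, sparse$data)
  q <- pk_ofv_quadrature(pop, sparse$data, nodes = 9)
  expect_lt(abs(f - q) / abs(q), 0.01)
  rich <- pk_generate_cohort(rich_design(6), pop, seed = 72)
  fr <- pk_ofv_foce(pop, rich$data)
  qr <- pk_ofv_quadrature(pop, rich$data, nodes = 9)
  expect_lt(abs(fr - qr) / abs(qr), 0.001)
})

test_that("quadrature is converged in the node count", {
  pop <- pop_default()
  coh <- pk_generate_cohort(sparse_design(4), pop, seed = 73)
  q9 <- pk_ofv_quadrature(pop, coh$data, nodes = 9)
  q15 <- pk_ofv_quadrature(pop, coh$data, nodes = 15)
  expect_lt(abs(q15 - q9), 1e-4)
})

test_that("vanishing BSV collapses the marginal likelihood to the fixed-effect fit", {
  pop <- pop_default()
  coh <- pk_generate_cohort(sparse_design(4), pop, seed = 74)
  tiny <- pk_population_parameters(omega = diag(1e-10, 2))
  f <- pk_ofv_foce(tiny, coh$data)
  q <- pk_ofv_quadrature(tiny, coh$data)
  # independent fixed-effects -2LL from the eta = 0 predictions
  det0 <- pk_ofv_foce(tiny, coh$data, details = TRUE)
  a <- osipk:::dataset_arrays(tiny, coh$data)
  m2ll <- sum(vapply(seq_len(a$n_subjects), function(i) {
    yv <- a$y[(a$ystarts[i] + 1):a$ystarts[i + 1]]
    fv <- osipk:::subject_pred(tiny, a, i, c(0, 0))
    sum(log(2 * pi * (0.178 * fv)^2) + (yv - fv)^2 / (0.178 * fv)^2)
  }, numeric(1)))
  expect_equal(f, m2ll, tolerance = 1e-6)
  expect_equal(q, m2ll, tolerance = 1e-6)
  expect_true(all(abs(det0$eta) < 1e-4))
})

test_that("likelihood is invariant to relabeling and adding empty subjects", {
  pop <- pop_default()
  coh <- pk_generate_cohort(sparse_design(5), pop, seed = 75)
  base <- pk_ofv_foce(pop, coh$data)
  shuffled <- dplyr::arrange(dplyr::mutate(coh$data, ID = 100 - ID), ID, TIME,
                             EVID)
  expect_equal(pk_ofv_foce(pop, shuffled), base, tolerance = 1e-10)
  # a subject with doses but no observations contributes nothing
  empty <- dplyr::mutate(coh$data[coh$data$ID == 1 & coh$data$EVID == 1, ],
                         ID = 99)
  expect_equal(pk_ofv_foce(pop, dplyr::bind_rows(coh$data, empty)), base,
               tolerance = 1e-10)
})

test_that("empirical Bayes estimates behave at the prior and data limits", {
  pop <- pop_default()
  coh <- pk_generate_cohort(rich_design(4), pop, seed = 76)
  doses_only <- dplyr::mutate(coh$data[coh$data$EVID == 1 & coh$data$ID == 1, ],
                              ID = 50)
  eb <- pk_empirical_bayes(pop, dplyr::bind_rows(coh$data, doses_only))
  expect_equal(eb$eta_cl_parent[eb$subject == 50], 0)
  expect_equal(eb$eta_cl_metab[eb$subject == 50], 0)
  # rich designs pin the latent effects
  expect_lt(max(abs(eb$eta_cl_parent[1:4] - coh$subjects$eta_cl_parent)), 0.1)
  expect_lt(max(abs(eb$eta_cl_metab[1:4] - coh$subjects$eta_cl_metab)), 0.1)
  # duplicating a subject's records leaves its mode unchanged
  dup <- dplyr::bind_rows(coh$data,
                          dplyr::mutate(coh$data[coh$data$ID == 2, ], ID = 60))
  eb2 <- pk_empirical_bayes(pop, dup)
  expect_equal(eb2$eta_cl_parent[eb2$subject == 60],
               eb2$eta_cl_parent[eb2$subject == 2], tolerance = 1e-6)
})

test_that("stepwise covariate rules apply the 3.84 / 6.63 thresholds", {
  # cobicistat on CL/F: drop of 62.6 points is an inclusion
  expect_true(pk_lrt(1000, 1000 - 62.6, "forward")$keep_parameter)
  # cobicistat on bioavailability alone: drop of 59.1 would also be included
  expect_true(pk_lrt(1000, 1000 - 59.1, "forward")$keep_parameter)
  expect_false(pk_lrt(1000, 997.0, "forward")$keep_parameter)
  expect_false(pk_lrt(1000, 1000 - 3.84 + 1e-9, "forward")$keep_parameter)
  # backward elimination: removal raising the OFV by > 6.63 retains
  expect_true(pk_lrt(1007, 1000, "backward")$keep_parameter)
  expect_false(pk_lrt(1006, 1000, "backward")$keep_parameter)
})

pop_to_natural_test <- function(f) unlist(f$estimates[c("cl_parent", "v_parent")])

test_that("a fully fixed model returns the objective without optimization", {
  pop <- pop_default()
  coh <- pk_generate_cohort(sparse_design(3), pop, seed = 77)
  fit <- pk_fit(coh$data, init = pop,
                fixed = c("ka", "f_m", "v_parent", "cl_parent", "v_metab",
                          "cl_metab", "theta_cobi", "sigma_prop", "omega"))
  expect_true(fit$converged)
  expect_equal(fit$ofv, pk_ofv_foce(pop, coh$data))
  expect_equal(pop_to_natural_test(fit), pop_to_natural_test(list(estimates = pop)))
})

test_that("the absorption-rate sensitivity grid covers 0.05 to 0.45", {
  pop <- pop_default()
  coh <- pk_generate_cohort(rich_design(8), pop, seed = 78)
  grid <- pk_ka_sensitivity(coh$data, init = pop,
                            fixed = c("ka", "f_m", "v_metab", "omega"))
  expect_equal(nrow(grid), 9)
  expect_equal(grid$ka, seq(0.05, 0.45, by = 0.05))
  expect_true(all(grid$converged | !is.na(grid$error)))
  # data simulated with ka = 0.24: the profile minimum sits at or below 0.25
  expect_lte(grid$ka[which.min(grid$ofv)], 0.25)
  # profiling at the default 0.24 reproduces the default fit
  at_default <- pk_ka_sensitivity(coh$data, init = pop, ka_grid = 0.24,
                                  fixed = c("ka", "f_m", "v_metab", "omega"))
  ref <- pk_fit(coh$data, init = pop,
                fixed = c("ka", "f_m", "v_metab", "omega"), hessian = FALSE)
  expect_equal(at_default$ofv, ref$ofv, tolerance = 1e-6)
})
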