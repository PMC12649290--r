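test_that("CWRES are calibrated on data simulated from the model", {
  pop <- pop_default()
  coh <- pk_generate_cohort(rich_design(20), pop, seed = 91)
  cw <- pk_cwres(pop, coh$data)
  expect_gte(nrow(cw), 500)
  expect_lt(abs(mean(cw$cwres)), 0.1)
  expect_gt(sd(cw$cwres), 0.9)
  expect_lt(sd(cw$cwres), 1.1)
  expect_false(any(cw$flagged))
})

test_that("observations equal to their expansion mean give zero CWRES", {
  # generate essentially noise-free data at the prior mode, then evaluate
  # CWRES under the ordinary residual model: y = f(0) = E exactly
  truth <- pk_population_parameters(sigma_prop = 1e-12)
  coh <- pk_generate_cohort(sparse_design(3), truth, seed = 92,
                            eta = matrix(0, 3, 2))
  cw <- pk_cwres(pk_population_parameters(), coh$data)
  # the interaction term shifts the posterior mode slightly even for exact
  # data (the log-variance depends on eta); the expansion cancels the linear
  # part, leaving an O(eta_hat^2) remainder
  expect_lt(max(abs(cw$cwres)), 0.01)
})

test_that("inflating the BSV shrinks the typical CWRES magnitude", {
  pop <- pop_default()
  coh <- pk_generate_cohort(sparse_design(8), pop, seed = 93)
  cw1 <- pk_cwres(pop, coh$data)
  big <- pk_population_parameters(omega = 4 * pop$omega)
  cw2 <- pk_cwres(big, coh$data)
  expect_lt(median(abs(cw2$cwres)), median(abs(cw1$cwres)))
})

test_that("prediction correction is exact under dose rescaling", {
  pop <- pop_default()
  coh <- pk_generate_cohort(sparse_design(8), pop, seed = 94)
  b1 <- pk_pcvpc(pop, coh$data, n_sim = 50, seed = 7)
  doubled <- dplyr::mutate(coh$data, AMT = AMT * 2)
  b2 <- pk_pcvpc(pop, doubled, n_sim = 50, seed = 7)
  expect_equal(b2$observed, b1$observed, tolerance = 1e-10)
})

test_that("pcVPC covers its own simulations", {
  pop <- pop_default()
  hits <- trials <- 0
  for (r in 1:20) {
    coh <- pk_generate_cohort(pk_study_design(), pop, seed = 900 + r)
    b <- pk_pcvpc(pop, coh$data, n_sim = 300, seed = r)
    med <- b[b$percentile == 50, ]
    hits <- hits + sum(med$observed >= med$sim_lo & med$observed <= med$sim_hi)
    trials <- trials + nrow(med)
  }
  expect_gte(hits / trials, 0.8)
})

test_that("sparse pcVPC bins merge into their neighbors", {
  pop <- pop_default()
  des <- pk_study_design(n_subjects = 1,
                         windows = list(c(0, 0), c(3, 3)))
  coh <- pk_generate_cohort(des, pop, seed = 95)
  # drop one of the two observations in the (2, 5] h bin: 1 left -> merge
  drop <- which(coh$data$EVID == 0 & coh$data$DVID == 1 &
                  coh$data$OCC == 2)
  thin <- coh$data[-drop[length(drop)], ]
  expect_message(pk_pcvpc(pop, thin, n_sim = 20, seed = 1),
                 "merging sparse bin")
})

test_that("NPDE is calibrated and respects its boundary convention", {
  pop <- pop_default()
  rejections <- 0
  for (r in 1:20) {
    coh <- pk_generate_cohort(pk_study_design(), pop, seed = 700 + r)
    nd <- pk_npde(pop, coh$data, n_sim = 200, seed = r)
    if (attr(nd, "ks_p") < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections, 2)  # at most 10% of 20 replicates
  # an observation below every simulation maps to the finite lower bound
  coh <- pk_generate_cohort(pk_study_design(), pop, seed = 96)
  low <- coh$data
  first_obs <- which(low$EVID == 0)[1]
  low$DV[first_obs] <- -1e6
  nd <- pk_npde(pop, low, n_sim = 200, seed = 3)
  expect_equal(min(nd$npde), qnorm(1 / (2 * 200)))
  # reproducible under a fixed seed
  nd2 <- pk_npde(pop, low, n_sim = 200, seed = 3)
  expect_equal(nd$npde, nd2$npde)
})

test_that("bootstrap of identical subjects collapses to zero-width intervals", {
  pop <- pop_default()
  des <- pk_study_design(n_subjects = 1, weights = 70,
                         windows = lapply(c(0, 2, 6, 12), function(t) c(t, t)))
  one <- pk_generate_cohort(des, pop, seed = 97, eta = matrix(0, 1, 2))
  five <- dplyr::bind_rows(lapply(1:5, function(i) {
    dplyr::mutate(one$data, ID = i)
  }))
  bt <- pk_bootstrap(five, init = pop,
                     fixed = c("ka", "f_m", "v_parent", "v_metab",
                               "theta_cobi", "sigma_prop", "omega"),
                     n_resamples = 6, seed = 5)
  expect_equal(bt$p2.5, bt$p97.5, tolerance = 1e-8)
  expect_equal(attr(bt, "n_failed"), 0)
})

test_that("bootstrap medians track the original estimates and seeds fix resamples", {
  pop <- pop_default()
  coh <- pk_generate_cohort(sparse_design(12), pop, seed = 98)
  fixed <- c("ka", "f_m", "v_parent", "v_metab", "omega", "sigma_prop")
  orig <- pk_fit(coh$data, init = pop, fixed = fixed, hessian = FALSE)
  bt <- pk_bootstrap(coh$data, init = pop, fixed = fixed, n_resamples = 25,
                     seed = 6)
  est <- pop_to_natural_fit(orig)
  for (tm in bt$term) {
    expect_lt(abs(bt$median[bt$term == tm] - est[[tm]]) / est[[tm]], 0.1)
  }
  bt2 <- pk_bootstrap(coh$data, init = pop, fixed = fixed, n_resamples = 25,
                      seed = 6)
  expect_equal(bt, bt2)
})

test_that("shrinkage hits its analytic limits", {
  pop <- pop_default()
  # no observations at all: complete collapse to the prior
  coh <- pk_generate_cohort(sparse_design(3), pop, seed = 99)
  doses_only <- coh$data[coh$data$EVID == 1, ]
  s <- pk_shrinkage(pop, doses_only)
  expect_equal(s$shrinkage_percent, rep(100, 3))
  # dense informative design: low eta-shrinkage (averaged over replicates,
  # since the sample SD of n latent effects is itself noisy)
  sh_eta <- sapply(1:3, function(r) {
    rich <- pk_generate_cohort(rich_design(40), pop, seed = 100 + r)
    pk_shrinkage(pop, rich$data)$shrinkage_percent[1:2]
  })
  expect_lt(max(rowMeans(sh_eta)), 15)
  # doubling sigma in evaluation halves the IWRES spread: ~50% eps-shrinkage
  rich <- pk_generate_cohort(rich_design(40), pop, seed = 100)
  wrong <- pk_population_parameters(sigma_prop = 2 * 0.178)
  sw <- pk_shrinkage(wrong, rich$data)
  expect_equal(sw$shrinkage_percent[sw$quantity == "epsilon"], 50,
               tolerance = 0.1)
})

test_that("condition numbers of known correlation structures", {
  expect_equal(pk_condition_number(diag(3)), 1)
  rho <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  expect_equal(pk_condition_number(rho), 9)
  collinear <- matrix(c(1, 1 - 1e-12, 1 - 1e-12, 1), 2, 2)
  expect_gt(pk_condition_number(collinear), 20)
})

test_that("a fitted sparse model reports finite uncertainty diagnostics", {
  pop <- pop_default()
  coh <- pk_generate_cohort(sparse_design(12), pop, seed = 101)
  fit <- pk_fit(coh$data, init = pop,
                fixed = c("ka", "f_m", "v_parent", "v_metab", "omega"))
  expect_true(fit$converged)
  td <- tidy(fit)
  expect_true(all(is.finite(td$rse_percent[!td$fixed])))
  cn <- pk_condition_number(fit)
  expect_true(is.finite(cn) && cn >= 1)
  g <- glance(fit)
  expect_equal(g$n_obs, sum(coh$data$EVID == 0))
})
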