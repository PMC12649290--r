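#' Conditional weighted residuals
#'
#' First-order expansion of the model about each subject's posterior mode:
#' `E = f(eta_hat) - G eta_hat`, `V = G Omega G' + R` with `G = df/deta` at
#' the mode and `R` the proportional residual variance at the conditional
#' predictions. The residual vector of each subject is decorrelated with the
#' Cholesky factor of `V`, so under the fitted model CWRES are approximately
#' iid standard normal. Observations in a numerically singular `V` are
#' flagged rather than dropped.
#'
#' @param fit A `pk_fit` object (or a [pk_population_parameters()] object,
#'   in which case `data` is required and posterior modes are recomputed).
#' @param data Record tibble; defaults to the fit's data.
#' @return A tibble with one row per observation: `subject`, `time`,
#'   `time_after_dose`, `analyte`, `dv`, `pred` (population prediction),
#'   `ipred` (conditional prediction), `cwres`, `flagged`.
#' @export
pk_cwres <- function(fit, data = NULL) {
  ctx <- diag_context(fit, data)
  pop <- ctx$pop; a <- ctx$a; eta <- ctx$eta
  out <- vector("list", a$n_subjects)
  for (i in seq_len(a$n_subjects)) {
    yr <- seq_len(a$ystarts[i + 1] - a$ystarts[i])
    if (length(yr) == 0) next
    y <- a$y[a$ystarts[i] + yr]
    fhat <- subject_pred(pop, a, i, eta[i, ])
    G <- subject_grad(pop, a, i, eta[i, ])
    E <- fhat - as.numeric(G %*% eta[i, ])
    V <- G %*% pop$omega %*% t(G) +
      diag((pop$sigma_prop * pmax(fhat, 1e-12))^2, nrow = length(y))
    ch <- try(chol(V), silent = TRUE)
    flagged <- inherits(ch, "try-error")
    cw <- if (flagged) rep(NA_real_, length(y)) else
      as.numeric(backsolve(ch, y - E, transpose = TRUE))
    rows <- (a$starts[i] + 1):a$starts[i + 1]
    obs_rows <- rows[a$evid[rows] == 0]
    out[[i]] <- tibble::tibble(
      subject = a$ids[i], time = a$times[obs_rows],
      time_after_dose = tad(a$times, a$evid, rows)[a$evid[rows] == 0],
      analyte = ifelse(a$cmt[obs_rows] == 3, "metab", "parent"),
      dv = y, pred = subject_pred(pop, a, i, c(0, 0)), ipred = fhat,
      cwres = cw, flagged = flagged)
  }
  dplyr::bind_rows(out)
}

# shared setup for the simulation-based diagnostics
diag_context <- function(fit, data) {
  if (inherits(fit, "pk_fit")) {
    pop <- fit$estimates
    data <- data %||% fit$data
    a <- dataset_arrays(pop, data)
    eta <- fit$eta
    if (nrow(eta) != a$n_subjects) {
      eta <- pk_ofv_foce(pop, data, details = TRUE)$eta
    }
  } else {
    stopifnot(inherits(fit, "pk_population_parameters"))
    if (is.null(data)) stop("data is required", call. = FALSE)
    pop <- fit
    a <- dataset_arrays(pop, data)
    eta <- pk_ofv_foce(pop, data, details = TRUE)$eta
  }
  list(pop = pop, a = a, eta = eta, data = data)
}

# time after most recent dose for a subject's record rows
tad <- function(times, evid, rows) {
  last_dose <- -Inf
  out <- numeric(length(rows))
  for (k in seq_along(rows)) {
    r <- rows[k]
    if (evid[r] == 1) last_dose <- times[r]
    out[k] <- if (is.finite(last_dose)) times[r] - last_dose else NA_real_
  }
  out
}

# simulate one replicate dataset (new eta + residual) -> observation vector
simulate_observations <- function(pop, a, eta_mat) {
  y <- numeric(length(a$y))
  for (i in seq_len(a$n_subjects)) {
    yr <- (a$ystarts[i] + 1):a$ystarts[i + 1]
    if (a$ystarts[i + 1] == a$ystarts[i]) next
    f <- subject_pred(pop, a, i, eta_mat[i, ])
    y[yr] <- f * (1 + rnorm(length(f), 0, pop$sigma_prop))
  }
  y
}

#' Prediction-corrected visual predictive check
#'
#' Observations and `n_sim` model-simulated replicates are prediction-
#' corrected (scaled by the ratio of the bin-median population prediction to
#' the observation's own population prediction), binned by time after dose,
#' and summarized as the 5th/50th/95th percentiles with the simulated 90%
#' confidence interval of each percentile. Bins with fewer than two
#' observations are merged with their left neighbor (with a message).
#'
#' @inheritParams pk_cwres
#' @param n_sim Number of simulated replicate datasets.
#' @param bins Bin edges for time after dose (h); the defaults follow the
#'   sampling windows of the sparse design.
#' @param seed Optional integer seed.
#' @return An object of class `pk_pcvpc`: a tibble with one row per analyte
#'   x bin x percentile: `analyte`, `bin_lo`, `bin_hi`, `t_mid`, `n_obs`,
#'   `percentile`, `observed`, `sim_lo`, `sim_hi`.
#' @export
pk_pcvpc <- function(fit, data = NULL, n_sim = 1000,
                     bins = c(0, 0.5, 2, 5, 9, 24), seed = NULL) {
  ctx <- diag_context(fit, data)
  pop <- ctx$pop; a <- ctx$a
  if (!is.null(seed)) set.seed(seed)
  obs_info <- observation_table(pop, a)
  obs_info$bin <- bin_merge(obs_info$time_after_dose, obs_info$analyte, bins)
  corr <- obs_info |>
    dplyr::group_by(.data$analyte, .data$bin) |>
    dplyr::mutate(pc_factor = median(.data$pred) / .data$pred) |>
    dplyr::ungroup()
  pct <- c(0.05, 0.5, 0.95)
  obs_stats <- corr |>
    dplyr::mutate(pc = .data$dv * .data$pc_factor) |>
    dplyr::group_by(.data$analyte, .data$bin) |>
    dplyr::summarise(n_obs = dplyr::n(),
                     t_mid = median(.data$time_after_dose),
                     value = list(quantile(.data$pc, pct, names = FALSE)),
                     .groups = "drop")
  sims <- array(NA_real_, dim = c(n_sim, nrow(obs_stats), 3))
  for (s in seq_len(n_sim)) {
    eta_s <- as.matrix(pk_sample_eta(pop, a$n_subjects)[, 2:3])
    ys <- simulate_observations(pop, a, eta_s)
    pc <- ys * corr$pc_factor
    st <- dplyr::tibble(analyte = corr$analyte, bin = corr$bin, pc = pc) |>
      dplyr::group_by(.data$analyte, .data$bin) |>
      dplyr::summarise(value = list(quantile(.data$pc, pct, names = FALSE)),
                       .groups = "drop")
    sims[s, , ] <- do.call(rbind, st$value)
  }
  out <- purrr::map_dfr(seq_len(nrow(obs_stats)), function(r) {
    tibble::tibble(
      analyte = obs_stats$analyte[r],
      bin = as.character(obs_stats$bin[r]),
      t_mid = obs_stats$t_mid[r], n_obs = obs_stats$n_obs[r],
      percentile = c(5, 50, 95),
      observed = obs_stats$value[[r]],
      sim_lo = apply(sims[, r, , drop = FALSE], 3, quantile, 0.05),
      sim_hi = apply(sims[, r, , drop = FALSE], 3, quantile, 0.95))
  })
  class(out) <- c("pk_pcvpc", class(out))
  out
}

observation_table <- function(pop, a) {
  out <- vector("list", a$n_subjects)
  for (i in seq_len(a$n_subjects)) {
    if (a$ystarts[i + 1] == a$ystarts[i]) next
    rows <- (a$starts[i] + 1):a$starts[i + 1]
    obs <- a$evid[rows] == 0
    out[[i]] <- tibble::tibble(
      subject = a$ids[i],
      time_after_dose = tad(a$times, a$evid, rows)[obs],
      analyte = ifelse(a$cmt[rows][obs] == 3, "metab", "parent"),
      dv = a$y[(a$ystarts[i] + 1):a$ystarts[i + 1]],
      pred = subject_pred(pop, a, i, c(0, 0)))
  }
  dplyr::bind_rows(out)
}

# assign bins within analyte; merge bins holding < 2 observations leftward
bin_merge <- function(tad_vec, analyte, edges) {
  f <- cut(tad_vec, breaks = edges, include.lowest = TRUE, right = FALSE)
  for (an in unique(analyte)) {
    repeat {
      tb <- table(droplevels(f[analyte == an]))
      small <- names(tb)[tb < 2]
      if (length(small) == 0) break
      lv <- levels(droplevels(f[analyte == an]))
      j <- match(small[1], lv)
      target <- if (j > 1) lv[j - 1] else lv[min(2, length(lv))]
      if (target == small[1]) break
      message("pcVPC: merging sparse bin ", small[1], " into ", target)
      f[analyte == an & f == small[1]] <- target
    }
  }
  f
}

#' Normalized prediction distribution errors
#'
#' For each subject, `n_sim` observation vectors are simulated under the
#' model; observed and simulated vectors are decorrelated with the Cholesky
#' factor of the empirical simulation covariance; the NPDE of each
#' decorrelated observation is the normal quantile of its rank-based
#' probability among its decorrelated simulations (half-rank ties,
#' probabilities clamped to `[1/(2 n_sim), 1 - 1/(2 n_sim)]` so boundary
#' observations map to finite values). If the empirical covariance is not
#' invertible a diagonal ridge is added (with a message).
#'
#' @inheritParams pk_pcvpc
#' @return An object of class `pk_npde`: a tibble with `subject`, `time`,
#'   `analyte`, `npde`, plus attribute `ks_p` (Kolmogorov-Smirnov test of
#'   the pooled NPDE against the standard normal).
#' @export
pk_npde <- function(fit, data = NULL, n_sim = 1000, seed = NULL) {
  stopifnot(n_sim >= 200)
  ctx <- diag_context(fit, data)
  pop <- ctx$pop; a <- ctx$a
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", a$n_subjects)
  for (i in seq_len(a$n_subjects)) {
    ni <- a$ystarts[i + 1] - a$ystarts[i]
    if (ni == 0) next
    y <- a$y[(a$ystarts[i] + 1):a$ystarts[i + 1]]
    etas <- MASS::mvrnorm(n_sim, c(0, 0), pop$omega)
    sims <- matrix(NA_real_, n_sim, ni)
    for (s in seq_len(n_sim)) {
      f <- subject_pred(pop, a, i, etas[s, ])
      sims[s, ] <- f * (1 + rnorm(ni, 0, pop$sigma_prop))
    }
    m <- colMeans(sims)
    S <- stats::cov(sims)
    ch <- try(chol(S), silent = TRUE)
    ridge <- 1e-8 * mean(diag(S))
    while (inherits(ch, "try-error")) {
      message("NPDE: adding ridge ", signif(ridge, 2),
              " to a singular simulation covariance")
      ch <- try(chol(S + diag(ridge, ni)), silent = TRUE)
      ridge <- ridge * 10
    }
    dec_y <- backsolve(ch, y - m, transpose = TRUE)
    dec_s <- t(backsolve(ch, t(sims) - m, transpose = TRUE))
    p <- vapply(seq_len(ni), function(j) {
      (sum(dec_s[, j] < dec_y[j]) + 0.5 * sum(dec_s[, j] == dec_y[j])) / n_sim
    }, numeric(1))
    p <- pmin(pmax(p, 1 / (2 * n_sim)), 1 - 1 / (2 * n_sim))
    rows <- (a$starts[i] + 1):a$starts[i + 1]
    obs_rows <- rows[a$evid[rows] == 0]
    out[[i]] <- tibble::tibble(
      subject = a$ids[i], time = a$times[obs_rows],
      analyte = ifelse(a$cmt[obs_rows] == 3, "metab", "parent"),
      npde = qnorm(p))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "ks_p") <- suppressWarnings(ks.test(res$npde, "pnorm")$p.value)
  class(res) <- c("pk_npde", class(res))
  res
}

#' Nonparametric bootstrap of the population model
#'
#' Resamples subjects with replacement (original cohort size), refits the
#' model on each resample, and summarizes the successful fits by the median
#' and 2.5/97.5 percentiles per parameter. Failed or non-converged fits are
#' counted and excluded; more than 50% failures is an error.
#'
#' @inheritParams pk_fit
#' @param n_resamples Number of bootstrap resamples.
#' @param seed Optional integer seed (fixes the resample indices).
#' @return A tibble with `term`, `median`, `p2.5`, `p97.5` for the free
#'   parameters; attributes `n_failed` and `n_resamples`.
#' @export
pk_bootstrap <- function(data, init = pk_population_parameters(),
                         fixed = c("ka", "f_m"), n_resamples = 1000,
                         seed = NULL, interaction = TRUE, ...) {
  validate_pkdataset(data)
  ids <- unique(data$ID)
  if (!is.null(seed)) set.seed(seed)
  by_id <- split(data, factor(data$ID, levels = ids))
  free_nat <- natural_free_names(free_indices(fixed))
  draws <- vector("list", n_resamples)
  n_failed <- 0
  for (b in seq_len(n_resamples)) {
    take <- sample(seq_along(ids), length(ids), replace = TRUE)
    res <- purrr::map2_dfr(take, seq_along(take), function(src, newid) {
      d <- by_id[[src]]
      d$ID <- newid  # each draw becomes a distinct pseudo-subject
      d
    })
    fit <- try(pk_fit(res, init = init, fixed = fixed, hessian = FALSE,
                      interaction = interaction, ...), silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged ||
        !is.finite(fit$ofv)) {
      n_failed <- n_failed + 1
      next
    }
    draws[[b]] <- pop_to_natural(fit$estimates)[free_nat]
  }
  if (n_failed > n_resamples / 2) {
    stop("more than half of the bootstrap fits failed (", n_failed, "/",
         n_resamples, ")", call. = FALSE)
  }
  mat <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  out <- tibble::tibble(
    term = colnames(mat),
    median = apply(mat, 2, median),
    p2.5 = apply(mat, 2, quantile, 0.025),
    p97.5 = apply(mat, 2, quantile, 0.975))
  attr(out, "n_failed") <- n_failed
  attr(out, "n_resamples") <- n_resamples
  out
}

#' Eta- and epsilon-shrinkage
#'
#' `eta`-shrinkage per random effect: `100 (1 - SD(eta_hat) / omega)` with
#' `omega` the model SD of that effect; `eps`-shrinkage:
#' `100 (1 - SD(IWRES))` with `IWRES = (y - f(eta_hat)) /
#' (sigma_prop f(eta_hat))`. Values below 30% conventionally indicate that
#' individual estimates are informative.
#'
#' @inheritParams pk_cwres
#' @return A tibble with `quantity` (`eta_cl_parent`, `eta_cl_metab`,
#'   `epsilon`) and `shrinkage_percent`.
#' @export
pk_shrinkage <- function(fit, data = NULL) {
  ctx <- diag_context(fit, data)
  pop <- ctx$pop; a <- ctx$a; eta <- ctx$eta
  om_sd <- sqrt(diag(pop$omega))
  if (any(om_sd == 0)) stop("omega has a zero variance; shrinkage undefined",
                            call. = FALSE)
  iwres <- unlist(lapply(seq_len(a$n_subjects), function(i) {
    if (a$ystarts[i + 1] == a$ystarts[i]) return(numeric(0))
    y <- a$y[(a$ystarts[i] + 1):a$ystarts[i + 1]]
    f <- subject_pred(pop, a, i, eta[i, ])
    (y - f) / (pop$sigma_prop * pmax(f, 1e-12))
  }))
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  tibble::tibble(
    quantity = c("eta_cl_parent", "eta_cl_metab", "epsilon"),
    shrinkage_percent = c(100 * (1 - sd0(eta[, 1]) / om_sd[1]),
                          100 * (1 - sd0(eta[, 2]) / om_sd[2]),
                          100 * (1 - sd0(iwres))))
}

#' Condition number of the estimation
#'
#' Ratio of the largest to the smallest eigenvalue of the *correlation*
#' matrix of the estimated (free) parameters; values above ~20 indicate an
#' overparameterized model.
#'
#' @param fit A `pk_fit` with an estimate covariance, or a correlation /
#'   covariance matrix.
#' @param quiet Suppress the not-computable warning.
#' @return A single number (`NA` when the covariance is unavailable).
#' @export
pk_condition_number <- function(fit, quiet = FALSE) {
  V <- if (inherits(fit, "pk_fit")) {
    if (is.null(fit$vcov)) {
      if (!quiet) warning("estimate covariance unavailable; condition number not computable")
      return(NA_real_)
    }
    fit$vcov[fit$free_natural, fit$free_natural, drop = FALSE]
  } else {
    as.matrix(fit)
  }
  d <- sqrt(diag(V))
  if (any(d == 0)) return(Inf)
  C <- V / tcrossprod(d)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  max(ev) / min(ev)
}
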