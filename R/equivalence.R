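#' Geometric mean ratio with 90% confidence interval
#'
#' Within-subject geometric mean ratio of exposure metrics between a test and
#' a reference regimen: `r_i = log(test_i / ref_i)`, `GMR = exp(mean r)`,
#' with a normal-quantile CI `exp(mean r +/- z_{1 - alpha/2} sd(r) / sqrt(n))`
#' on the log scale (a degenerate `sd(r) = 0` gives a zero-width CI).
#' A subject-resampling bootstrap CI is available as an alternative.
#'
#' @param metrics Tibble from [pk_crossover()] (paired by `subject`).
#' @param test,ref Regimen labels to compare.
#' @param alpha Two-sided error level; 0.10 gives the conventional 90% CI.
#' @param method `"normal"` (default) or `"bootstrap"` (subject resampling).
#' @param n_boot Bootstrap resamples when `method = "bootstrap"`.
#' @param seed Optional seed for the bootstrap CI.
#' @return A tibble of class `pk_gmr` with one row per analyte x metric:
#'   `analyte`, `metric`, `gmr`, `ci_lower`, `ci_upper`, `n`.
#' @export
pk_gmr <- function(metrics, test, ref, alpha = 0.10,
                   method = c("normal", "bootstrap"), n_boot = 1000,
                   seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(metrics),
            all(c("regimen", "subject", "analyte") %in% names(metrics)))
  if (!all(c(test, ref) %in% metrics$regimen)) {
    stop("test/ref labels not found in `metrics$regimen`", call. = FALSE)
  }
  long <- metrics |>
    tidyr::pivot_longer(dplyr::all_of(c("auc_0_144", "c_max", "c_min")),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(.data$regimen %in% c(test, ref))
  wide <- tidyr::pivot_wider(long, id_cols = c("subject", "analyte", "metric"),
                             names_from = "regimen", values_from = "value")
  if (anyNA(wide[[test]]) || anyNA(wide[[ref]])) {
    stop("test and reference arms are not paired subject-by-subject", call. = FALSE)
  }
  if (any(wide[[test]] <= 0) || any(wide[[ref]] <= 0)) {
    stop("all metric values must be strictly positive for a GMR", call. = FALSE)
  }
  z <- qnorm(1 - alpha / 2)
  if (!is.null(seed)) set.seed(seed)
  out <- wide |>
    dplyr::mutate(lr = log(.data[[test]] / .data[[ref]])) |>
    dplyr::group_by(.data$analyte, .data$metric) |>
    dplyr::summarise(gmr = exp(mean(.data$lr)),
                     ci_lower = ci_bound(.data$lr, z, -1, method, n_boot, alpha),
                     ci_upper = ci_bound(.data$lr, z, +1, method, n_boot, alpha),
                     n = dplyr::n(), .groups = "drop")
  class(out) <- c("pk_gmr", class(out))
  attr(out, "test") <- test
  attr(out, "ref") <- ref
  out
}

ci_bound <- function(lr, z, side, method, n_boot, alpha) {
  n <- length(lr)
  if (method == "normal") {
    s <- if (n > 1) sd(lr) else 0
    return(exp(mean(lr) + side * z * s / sqrt(n)))
  }
  means <- vapply(seq_len(n_boot),
                  function(i) mean(lr[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  exp(quantile(means, if (side < 0) alpha / 2 else 1 - alpha / 2, names = FALSE))
}

#' Equivalence verdict against an acceptance range
#'
#' Declares equivalence when the whole 90% CI of the GMR lies inside the
#' acceptance range; bounds are closed (a CI touching 0.8 or 1.25 exactly
#' still passes, the usual regulatory convention).
#'
#' @param gmr A `pk_gmr` tibble from [pk_gmr()].
#' @param range Length-2 acceptance range, default `c(0.8, 1.25)`.
#' @return The input with a logical column `equivalent` appended.
#' @export
pk_equivalence_verdict <- function(gmr, range = c(0.8, 1.25)) {
  stopifnot(inherits(gmr, "pk_gmr") ||
              all(c("ci_lower", "ci_upper") %in% names(gmr)),
            length(range) == 2, range[1] < range[2])
  dplyr::mutate(gmr, equivalent = .data$ci_lower >= range[1] &
                  .data$ci_upper <= range[2])
}

#' Time fractions relative to a therapeutic window
#'
#' Splits the duration of a (typically median steady-state) parent
#' concentration profile into the time-weighted fractions spent within,
#' below and above a concentration window. Crossing times are located by
#' linear interpolation between grid points, so the three fractions sum to 1
#' exactly.
#'
#' @param profile A `pk_profile` tibble (uses `conc_parent`).
#' @param window Length-2 window in ug/L; default the provisional
#'   osimertinib therapeutic window 125-259 ug/L.
#' @return A tibble with `within`, `below`, `above`.
#' @export
pk_window_assessment <- function(profile, window = c(125, 259)) {
  stopifnot(is.data.frame(profile),
            all(c("time", "conc_parent") %in% names(profile)),
            length(window) == 2, window[1] < window[2])
  t <- profile$time
  c0 <- profile$conc_parent
  if (length(t) < 2) stop("profile must contain at least two time points", call. = FALSE)
  seg_below <- seg_above <- 0
  for (i in seq_len(length(t) - 1)) {
    dt <- t[i + 1] - t[i]
    if (dt <= 0) next
    seg_below <- seg_below + dt * frac_below(c0[i], c0[i + 1], window[1])
    seg_above <- seg_above + dt * (1 - frac_below(c0[i], c0[i + 1], window[2]))
  }
  total <- t[length(t)] - t[1]
  tibble::tibble(within = 1 - (seg_below + seg_above) / total,
                 below = seg_below / total,
                 above = seg_above / total)
}

# fraction of a linear segment from a to b spent strictly below threshold L
frac_below <- function(a, b, L) {
  if (a < L && b < L) return(1)
  if (a >= L && b >= L) return(0)
  (L - min(a, b)) / abs(b - a)
}
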