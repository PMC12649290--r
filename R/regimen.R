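#' Dosing regimens
#'
#' Builds one of the four studied dose levels, or a custom cyclic regimen.
#' The studied levels (all osimertinib 80 mg per administration):
#'
#' * `DL1` - 80 mg once daily, monotherapy (reference; cycle 24 h).
#' * `DL2` - 80 mg once daily, boosted with cobicistat 150 mg QD (cycle 24 h).
#' * `DL3` - 80 mg 2 days on / 1 day off, boosted (cycle 72 h, doses at 0 and 24 h).
#' * `DL4` - 80 mg 1 day on / 1 day off, boosted (cycle 48 h, dose at 0 h).
#'
#' @param level One of `"DL1"`, `"DL2"`, `"DL3"`, `"DL4"`, or `"custom"`.
#' @param cycle_length,dose_times,amount_mg,boosted Custom pattern: cycle
#'   length (h), dose times within `[0, cycle_length)` (h), dose per
#'   administration (mg), and whether every day is boosted with cobicistat.
#' @param label Optional label; defaults to the level.
#' @return An object of class `pk_regimen` with fields `label`,
#'   `cycle_length` (h), `dose_times` (h), `amount` (ug), `boosted`.
#' @examples
#' pk_regimen("DL3")
#' pk_regimen("custom", cycle_length = 48, dose_times = 0, amount_mg = 40,
#'            boosted = TRUE, label = "40 mg every other day, boosted")
#' @export
pk_regimen <- function(level = c("DL1", "DL2", "DL3", "DL4", "custom"),
                       cycle_length = NULL, dose_times = NULL,
                       amount_mg = 80, boosted = FALSE, label = NULL) {
  level <- match.arg(level)
  pat <- switch(level,
    DL1 = list(cycle = 24, times = 0, boosted = FALSE),
    DL2 = list(cycle = 24, times = 0, boosted = TRUE),
    DL3 = list(cycle = 72, times = c(0, 24), boosted = TRUE),
    DL4 = list(cycle = 48, times = 0, boosted = TRUE),
    custom = {
      if (is.null(cycle_length) || is.null(dose_times)) {
        stop("custom regimens need cycle_length and dose_times", call. = FALSE)
      }
      list(cycle = cycle_length, times = sort(dose_times), boosted = boosted)
    })
  if (pat$cycle <= 0) stop("cycle_length must be positive", call. = FALSE)
  if (any(pat$times < 0 | pat$times >= pat$cycle)) {
    stop("dose_times must lie in [0, cycle_length)", call. = FALSE)
  }
  if (amount_mg < 0) stop("amount_mg must be non-negative", call. = FALSE)
  structure(
    list(label = label %||% level, cycle_length = pat$cycle,
         dose_times = pat$times, amount = amount_mg * 1000,
         boosted = pat$boosted),
    class = "pk_regimen")
}

#' @export
print.pk_regimen <- function(x, ...) {
  cat(sprintf("<pk_regimen> %s: %.5g mg at %s h of a %g h cycle%s\n",
              x$label, x$amount / 1000,
              paste(x$dose_times, collapse = ", "), x$cycle_length,
              if (x$boosted) ", cobicistat-boosted" else ""))
  invisible(x)
}

# All dose events of `regimen` in [0, t_end)
regimen_doses <- function(regimen, t_end) {
  n_cyc <- ceiling(t_end / regimen$cycle_length)
  t <- rep((seq_len(n_cyc) - 1) * regimen$cycle_length,
           each = length(regimen$dose_times)) +
    rep(regimen$dose_times, n_cyc)
  tibble::tibble(time = t[t < t_end], amount = regimen$amount)
}

#' Relative tablet consumption of two regimens
#'
#' Ratio of osimertinib doses per unit time (same tablet strength assumed);
#' under flat pricing this is the treatment-cost fraction of the test
#' regimen relative to the reference.
#'
#' @param test,ref [pk_regimen()] objects.
#' @return A single number, e.g. 2/3 for 2-on/1-off versus daily dosing.
#' @export
pk_cost_fraction <- function(test, ref) {
  stopifnot(inherits(test, "pk_regimen"), inherits(ref, "pk_regimen"))
  rate_ref <- length(ref$dose_times) / ref$cycle_length
  if (rate_ref == 0 || ref$amount == 0) {
    stop("reference regimen administers no doses", call. = FALSE)
  }
  (length(test$dose_times) / test$cycle_length) / rate_ref
}
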