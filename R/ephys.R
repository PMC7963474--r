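## linear-interpolated time at which the deflection s (sampled at t)
## crosses level L going up, searching backward from index `from`
cross_up_before <- function(t, s, L, from) {
  i <- from
  while (i > 1 && s[i - 1] >= L) i <- i - 1
  if (i == 1) return(NA_real_)       # level never undershot before peak
  ## s[i-1] < L <= s[i]
  t[i - 1] + (L - s[i - 1]) / (s[i] - s[i - 1]) * (t[i] - t[i - 1])
}

## first time after index `from` at which s falls to level L
cross_down_after <- function(t, s, L, from) {
  n <- length(s)
  i <- from
  while (i < n && s[i + 1] > L) i <- i + 1
  if (i == n) return(NA_real_)       # decay incomplete within the record
  t[i] + (s[i] - L) / (s[i] - s[i + 1]) * (t[i + 1] - t[i])
}

#' Measure a single evoked IPSC response
#'
#' Baseline is the mean current over `baseline_ms` immediately before the
#' stimulus. The peak is searched after an artifact-blanking window
#' (default 2 ms post-stimulus) up to the next stimulus (or
#' `response_window_ms`). Polarity is auto-detected from the dominant
#' deflection unless forced. Amplitude is baseline-to-peak;
#' the 20-80% rise time and the 100-33% decay time are obtained by linear
#' interpolation between samples at the respective level crossings.
#'
#' @param trace an `ipsc_trace` (or data frame with `time_ms`,
#'   `current_pA` plus a `stimulus_times_ms` attribute).
#' @param stimulus_index which stimulus to measure, default 1.
#' @param baseline_ms pre-stimulus baseline window, default 5 ms.
#' @param blank_ms artifact blank after the stimulus, default 2 ms.
#' @param response_window_ms maximum response window, default 100 ms
#'   (clipped at the next stimulus and the record end).
#' @param polarity `"auto"`, `"inward"` or `"outward"`.
#' @param baseline_override use this baseline (pA) instead of measuring
#'   one (used internally for overlap-corrected second responses).
#' @return an object of class `ipsc_metrics`: `amplitude_pA`,
#'   `rise_20_80_ms`, `decay_100_33_ms`, `baseline_pA`, `peak_time_ms`,
#'   `polarity`. An amplitude of 0 leaves both kinetic metrics `NA`;
#'   a peak whose decay does not reach 33% before the window end reports
#'   `decay_100_33_ms = NA` with a warning.
#' @export
measure_ipsc <- function(trace, stimulus_index = 1, baseline_ms = 5,
                         blank_ms = 2, response_window_ms = 100,
                         polarity = c("auto", "inward", "outward"),
                         baseline_override = NULL) {
  polarity <- match.arg(polarity)
  stims <- attr(trace, "stimulus_times_ms")
  stopifnot(!is.null(stims), stimulus_index >= 1,
            stimulus_index <= length(stims))
  t <- trace$time_ms; i <- trace$current_pA
  t0 <- stims[stimulus_index]
  t_end <- min(t0 + response_window_ms,
               if (stimulus_index < length(stims))
                 stims[stimulus_index + 1] else Inf,
               max(t))
  base_idx <- t >= t0 - baseline_ms & t < t0
  baseline <- baseline_override %||%
    (if (any(base_idx)) mean(i[base_idx]) else i[1])
  region <- which(t > t0 + blank_ms & t <= t_end)
  if (length(region) < 3) stop("response window contains too few samples")

  dev <- i[region] - baseline
  pol_sign <- switch(polarity,
    inward = -1, outward = 1,
    auto = if (abs(min(dev)) >= abs(max(dev))) -1 else 1)
  s_full <- pol_sign * (i - baseline)
  s <- s_full[region]
  pk_rel <- which.max(s)
  amplitude <- s[pk_rel]
  pk_idx <- region[pk_rel]

  if (!is.finite(amplitude) || amplitude <= 1e-9) {
    return(structure(
      list(amplitude_pA = 0, rise_20_80_ms = NA_real_,
           decay_100_33_ms = NA_real_, baseline_pA = baseline,
           peak_time_ms = NA_real_,
           polarity = if (pol_sign < 0) "inward" else "outward"),
      class = "ipsc_metrics"))
  }
  t20 <- cross_up_before(t, s_full, 0.2 * amplitude, pk_idx)
  t80 <- cross_up_before(t, s_full, 0.8 * amplitude, pk_idx)
  rise <- if (is.na(t20) || is.na(t80)) NA_real_ else t80 - t20
  ## decay search limited to the response window
  sub_t <- t[region]; sub_s <- s
  t33 <- cross_down_after(sub_t, sub_s, 0.33 * amplitude, pk_rel)
  if (is.na(t33))
    warning("decay incomplete within the response window")
  decay <- if (is.na(t33)) NA_real_ else t33 - t[pk_idx]
  structure(
    list(amplitude_pA = amplitude, rise_20_80_ms = rise,
         decay_100_33_ms = decay, baseline_pA = baseline,
         peak_time_ms = t[pk_idx],
         polarity = if (pol_sign < 0) "inward" else "outward"),
    class = "ipsc_metrics")
}

#' @export
print.ipsc_metrics <- function(x, ...) {
  cat(sprintf(
    "ipsc_metrics: amplitude %.2f pA (%s), rise 20-80%% %.3f ms, decay 100-33%% %.3f ms\n",
    x$amplitude_pA, x$polarity, x$rise_20_80_ms, x$decay_100_33_ms))
  invisible(x)
}

#' Paired-pulse ratio of two evoked responses
#'
#' Ratio of the second response amplitude to the first. At short
#' interstimulus intervals the first response's decay overlaps the
#' second; with `subtract_decay = TRUE` (default) a single exponential is
#' fitted to the late decay of response 1 and extrapolated through the
#' response-2 window, and the second amplitude is measured on the
#' residual. Without subtraction the second amplitude is measured from
#' the pre-train baseline and is biased high at short intervals.
#'
#' @param trace an `ipsc_trace` with at least two stimuli.
#' @param subtract_decay subtract the extrapolated response-1 decay,
#'   default TRUE.
#' @param fit_start_ms start of the decay-fit window, ms after the
#'   response-1 peak, default 2.
#' @param ... passed to [measure_ipsc()] (e.g. `blank_ms`).
#' @return an object of class `ppr_result`: `ratio`,
#'   `interstimulus_interval_ms`, `amplitude1_pA`, `amplitude2_pA`,
#'   `decay_subtracted`. A zero first amplitude yields an `NA` ratio with
#'   a warning.
#' @export
paired_pulse_ratio <- function(trace, subtract_decay = TRUE,
                               fit_start_ms = 2, ...) {
  stims <- attr(trace, "stimulus_times_ms")
  if (is.null(stims) || length(stims) < 2)
    stop("paired-pulse ratio needs two stimuli")
  interval <- stims[2] - stims[1]
  m1 <- measure_ipsc(trace, 1, ...)
  if (m1$amplitude_pA <= 0) {
    warning("first response amplitude is 0: ratio undefined")
    return(structure(
      list(ratio = NA_real_, interstimulus_interval_ms = interval,
           amplitude1_pA = 0, amplitude2_pA = NA_real_,
           decay_subtracted = subtract_decay),
      class = "ppr_result"))
  }
  t <- trace$time_ms; i <- trace$current_pA
  pol_sign <- if (m1$polarity == "inward") -1 else 1
  s <- pol_sign * (i - m1$baseline_pA)

  correction <- rep(0, length(t))
  if (subtract_decay) {
    fit_idx <- which(t >= m1$peak_time_ms + fit_start_ms &
                       t < stims[2] & s > 0)
    if (length(fit_idx) >= 5) {
      fit <- stats::lm(log(s[fit_idx]) ~ t[fit_idx])
      correction <- exp(stats::coef(fit)[1] + stats::coef(fit)[2] * t)
    } else {
      warning("too few points to fit the response-1 decay; no subtraction")
    }
  }
  corrected <- structure(
    data.frame(time_ms = t,
               current_pA = m1$baseline_pA + pol_sign * (s - correction)),
    stimulus_times_ms = stims, dt_ms = attr(trace, "dt_ms"),
    class = c("ipsc_trace", "data.frame"))
  m2 <- measure_ipsc(corrected, 2, polarity = m1$polarity,
                     baseline_override = m1$baseline_pA, ...)
  structure(
    list(ratio = m2$amplitude_pA / m1$amplitude_pA,
         interstimulus_interval_ms = interval,
         amplitude1_pA = m1$amplitude_pA,
         amplitude2_pA = m2$amplitude_pA,
         decay_subtracted = subtract_decay &&
           any(correction != 0)),
    class = "ppr_result")
}

#' @export
print.ppr_result <- function(x, ...) {
  cat(sprintf(
    "ppr_result: ratio %.3f at %g ms interval (A1 = %.1f pA, A2 = %.1f pA%s)\n",
    x$ratio, x$interstimulus_interval_ms, x$amplitude1_pA,
    x$amplitude2_pA,
    if (x$decay_subtracted) ", decay-subtracted" else ""))
  invisible(x)
}
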