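#' Parameters of a simulated evoked IPSC recording
#'
#' The response to each stimulus is a double exponential,
#' `baseline - A * norm * (exp(-s/tau_decay) - exp(-s/tau_rise))` for
#' `s = t - (stimulus + onset_latency) >= 0`, where `norm` scales the
#' waveform so its extremum magnitude equals `amplitude` (IPSCs recorded
#' at -70 mV with a high-chloride internal are inward, hence the negative
#' sign). Responses after the first are scaled by `ppr_true`.
#'
#' @param amplitude peak amplitude of the first response, pA (>= 0).
#' @param tau_rise,tau_decay rise and decay time constants, ms; must
#'   satisfy `tau_decay > tau_rise > 0`.
#' @param onset_latency delay from stimulus to response onset, ms.
#' @param baseline holding current, pA.
#' @param noise_sigma additive Gaussian noise SD, pA.
#' @param stimulus_times_ms stimulus times, ms.
#' @param ppr_true ratio applied to the amplitude of responses after the
#'   first (the ground-truth paired-pulse ratio).
#' @return an object of class `ipsc_params`.
#' @export
ipsc_params <- function(amplitude = 100,
                        tau_rise = 1,
                        tau_decay = 10,
                        onset_latency = 2,
                        baseline = 0,
                        noise_sigma = 0,
                        stimulus_times_ms = 10,
                        ppr_true = 1) {
  if (!(tau_decay > tau_rise && tau_rise > 0))
    stop("need tau_decay > tau_rise > 0")
  stopifnot(amplitude >= 0, noise_sigma >= 0, ppr_true >= 0,
            length(stimulus_times_ms) >= 1)
  structure(
    list(amplitude = amplitude, tau_rise = tau_rise, tau_decay = tau_decay,
         onset_latency = onset_latency, baseline = baseline,
         noise_sigma = noise_sigma,
         stimulus_times_ms = sort(as.numeric(stimulus_times_ms)),
         ppr_true = ppr_true),
    class = "ipsc_params")
}

## analytic peak time (after onset) and peak value of the unit double
## exponential g(s) = exp(-s/td) - exp(-s/tr)
dexp_peak <- function(tau_rise, tau_decay) {
  s_star <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  list(s = s_star,
       g = exp(-s_star / tau_decay) - exp(-s_star / tau_rise))
}

#' Simulate an evoked IPSC current trace
#'
#' @param params an [ipsc_params()] object.
#' @param duration_ms record length; default runs 120 ms past the last
#'   stimulus.
#' @param dt_ms sampling interval, ms; default 0.1 ms (10 kHz).
#' @param seed optional integer seed for the noise.
#' @return an `ipsc_trace`: a data frame with columns `time_ms` and
#'   `current_pA`, with the stimulus times, sampling interval and
#'   generating parameters stored as attributes.
#' @export
generate_ipsc_trace <- function(params, duration_ms = NULL, dt_ms = 0.1,
                                seed = NULL) {
  stopifnot(inherits(params, "ipsc_params"), dt_ms > 0)
  if (!is.null(seed)) set.seed(seed)
  duration_ms <- duration_ms %||% (max(params$stimulus_times_ms) + 120)
  t <- seq(0, duration_ms, by = dt_ms)
  i <- rep(params$baseline, length(t))
  pk <- dexp_peak(params$tau_rise, params$tau_decay)
  norm <- 1 / pk$g
  for (k in seq_along(params$stimulus_times_ms)) {
    t0 <- params$stimulus_times_ms[k] + params$onset_latency
    amp <- params$amplitude * if (k > 1) params$ppr_true else 1
    s <- t - t0
    on <- s >= 0
    i[on] <- i[on] - amp * norm *
      (exp(-s[on] / params$tau_decay) - exp(-s[on] / params$tau_rise))
  }
  if (params$noise_sigma > 0)
    i <- i + stats::rnorm(length(i), 0, params$noise_sigma)
  structure(
    data.frame(time_ms = t, current_pA = i),
    stimulus_times_ms = params$stimulus_times_ms,
    dt_ms = dt_ms, params = params,
    class = c("ipsc_trace", "data.frame"))
}

#' Read/write current traces as two-column CSV
#'
#' The CSV holds `time_ms, current_pA`; stimulus times travel in a JSON
#' sidecar (`<name>_stims.json`) or may be supplied directly.
#'
#' @param trace an `ipsc_trace`.
#' @param path CSV path.
#' @return `write_trace` invisibly returns the paths; `read_trace` returns
#'   an `ipsc_trace`.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("time_ms", "current_pA")],
                   path, row.names = FALSE)
  sidecar <- sub("\\.csv$", "_stims.json", path)
  jsonlite::write_json(list(stimulus_times_ms =
                              attr(trace, "stimulus_times_ms")),
                       sidecar, auto_unbox = FALSE, digits = NA)
  invisible(c(trace = path, stims = sidecar))
}

#' @param stimulus_times_ms stimulus times for `read_trace`; if `NULL` the
#'   JSON sidecar is read.
#' @rdname write_trace
#' @export
read_trace <- function(path, stimulus_times_ms = NULL) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_ms", "current_pA") %in% names(d)))
  if (is.null(stimulus_times_ms)) {
    sidecar <- sub("\\.csv$", "_stims.json", path)
    if (!file.exists(sidecar))
      stop("no stimulus times given and no sidecar found at ", sidecar)
    stimulus_times_ms <-
      unlist(jsonlite::read_json(sidecar, simplifyVector = TRUE))
  }
  dt <- stats::median(diff(d$time_ms))
  structure(d, stimulus_times_ms = as.numeric(stimulus_times_ms),
            dt_ms = dt, class = c("ipsc_trace", "data.frame"))
}

#' @export
print.ipsc_trace <- function(x, ...) {
  cat("ipsc_trace:", nrow(x), "samples @", attr(x, "dt_ms"), "ms;",
      length(attr(x, "stimulus_times_ms")), "stimulus(es) at",
      paste(attr(x, "stimulus_times_ms"), collapse = ", "), "ms\n")
  invisible(x)
}

#' @export
plot.ipsc_trace <- function(x, ...) {
  plot(x$time_ms, x$current_pA, type = "l", xlab = "time (ms)",
       ylab = "current (pA)", ...)
  graphics::abline(v = attr(x, "stimulus_times_ms"), lty = 3,
                   col = "grey50")
  invisible(x)
}
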