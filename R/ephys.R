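#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings with a refractory lockout, on a uniformly
#' sampled trace of at least 5 kHz.
#'
#' @param trace a data frame with columns `time_ms` and `mV`, or a
#'   numeric voltage vector with `dt_ms`.
#' @param threshold_mV crossing threshold.
#' @param refractory_ms lockout after each detection.
#' @param dt_ms sampling interval when `trace` is a bare vector.
#' @return strictly increasing spike times, ms.
#' @export
detect_spikes <- function(trace, threshold_mV = 0, refractory_ms = 2,
                          dt_ms = NULL) {
  tr <- as_trace(trace, dt_ms)
  dt <- check_uniform(tr$time_ms)
  if (dt > 0.2 + 1e-9)
    stop("trace must be sampled at >= 5 kHz (dt <= 0.2 ms)", call. = FALSE)
  v <- tr$mV
  up <- which(v[-1] >= threshold_mV & v[-length(v)] < threshold_mV) + 1
  times <- tr$time_ms[up]
  out <- numeric(0)
  last <- -Inf
  for (t in times) {
    if (t - last >= refractory_ms) {
      out <- c(out, t)
      last <- t
    }
  }
  out
}

as_trace <- function(trace, dt_ms = NULL) {
  if (is.numeric(trace)) {
    if (is.null(dt_ms)) stop("dt_ms required for a bare vector",
                             call. = FALSE)
    return(tibble::tibble(time_ms = (seq_along(trace) - 1) * dt_ms,
                          mV = trace))
  }
  if ("v_s" %in% names(trace) && !"mV" %in% names(trace))
    trace$mV <- trace$v_s
  stopifnot(all(c("time_ms", "mV") %in% names(trace)))
  trace
}

check_uniform <- function(t) {
  d <- diff(t)
  if (!length(d)) stop("trace too short", call. = FALSE)
  if (max(abs(d - d[1])) > 1e-6 * d[1])
    stop("trace time base is not uniform", call. = FALSE)
  d[1]
}

#' Action-potential waveform features
#'
#' For one spike: threshold voltage (first point where dV/dt exceeds
#' `dvdt_thresh` before the peak), peak voltage, width at half height
#' between threshold and peak, and the AHP minimum within 100 ms after
#' the peak. Requires at least 50 ms of context on either side of the
#' spike.
#'
#' @param trace as in [detect_spikes()].
#' @param spike_time_ms detection time of the spike, ms.
#' @param dvdt_thresh threshold criterion, mV/ms.
#' @param context_ms required context, ms.
#' @param dt_ms sampling interval when `trace` is a bare vector.
#' @return a one-row tibble: `threshold_mV`, `peak_mV`, `half_width_ms`,
#'   `ahp_min_mV`, `ahp_depth_mV` (threshold minus AHP minimum).
#' @export
ap_waveform_features <- function(trace, spike_time_ms, dvdt_thresh = 20,
                                 context_ms = 50, dt_ms = NULL) {
  tr <- as_trace(trace, dt_ms)
  dt <- check_uniform(tr$time_ms)
  if (spike_time_ms - tr$time_ms[1] < context_ms ||
      tr$time_ms[nrow(tr)] - spike_time_ms < context_ms)
    stop("spike too close to trace edge (need >= ", context_ms,
         " ms context)", call. = FALSE)
  win <- tr$time_ms >= spike_time_ms - context_ms &
    tr$time_ms <= spike_time_ms + 100
  t <- tr$time_ms[win]; v <- tr$mV[win]
  ipk_candidates <- which(t >= spike_time_ms - 2 & t <= spike_time_ms + 5)
  ipk <- ipk_candidates[which.max(v[ipk_candidates])]
  dvdt <- c(NA, diff(v) / dt)
  pre <- which(seq_along(v) < ipk & dvdt > dvdt_thresh)
  ithr <- if (length(pre)) {
    # first sample of the contiguous depolarisation run ending at the peak
    run_start <- pre[1]
    for (k in rev(pre)) if (all(dvdt[k:ipk][-1] > 0)) run_start <- k
    run_start
  } else ipk
  thr <- v[ithr]
  pk <- v[ipk]
  half <- (thr + pk) / 2
  above <- which(v >= half & seq_along(v) >= ithr)
  width <- if (length(above) >= 2)
    (max(above) - min(above)) * dt else dt
  post <- which(t > t[ipk] & t <= t[ipk] + 100)
  ahp_min <- if (length(post)) min(v[post]) else NA_real_
  tibble::tibble(threshold_mV = thr, peak_mV = pk, half_width_ms = width,
                 ahp_min_mV = ahp_min, ahp_depth_mV = thr - ahp_min)
}

#' Spike-train summary features
#'
#' @param spikes spike times, ms.
#' @param from_ms,to_ms analysis window.
#' @return one-row tibble: `rate_hz`, `isi_mean_ms`, `isi_median_ms`,
#'   `isi_cv`, `early_rate_hz` (first two spikes), `n_spikes`.
#' @export
spike_train_features <- function(spikes, from_ms = 0,
                                 to_ms = max(spikes, 0) + 1) {
  sp <- spikes[spikes >= from_ms & spikes < to_ms]
  isi <- diff(sp)
  tibble::tibble(
    rate_hz = 1000 * length(sp) / (to_ms - from_ms),
    isi_mean_ms = if (length(isi)) mean(isi) else NA_real_,
    isi_median_ms = if (length(isi)) stats::median(isi) else NA_real_,
    isi_cv = if (length(isi) > 1) stats::sd(isi) / mean(isi) else NA_real_,
    early_rate_hz = if (length(sp) >= 2) 1000 / (sp[2] - sp[1]) else
      NA_real_,
    n_spikes = length(sp))
}

#' Read a two-column voltage trace CSV
#'
#' @param path CSV with header `time_ms,mV`.
#' @return tibble with `time_ms`, `mV`.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "mV") %in% names(df)))
    stop("trace CSV needs columns time_ms, mV", call. = FALSE)
  tibble::as_tibble(df)
}
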