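#' Raw capnograph trace
#'
#' Container for a recorded CO2 trace: sample times in seconds and partial
#' pressure of CO2 in mmHg. Capnographs sample fast (here typically 200 Hz)
#' relative to the breathing cycle, so the per-breath end-tidal plateau is
#' well resolved.
#'
#' @param time Sample times (s), strictly increasing.
#' @param pco2 CO2 partial pressure (mmHg), finite and non-negative. If the
#'   recording is in another unit (e.g. %CO2), apply `scale` on read, e.g.
#'   `(P_bar - 47) / 100` for percent at body temperature.
#' @param scale Optional multiplicative conversion applied to `pco2`.
#' @return An object of class `capno_trace` with fields `time`, `pco2` and
#'   `sampling_rate` (Hz, median of the inverse sample spacing).
#' @export
capno_trace <- function(time, pco2, scale = 1) {
  time <- as.numeric(time); pco2 <- as.numeric(pco2) * scale
  if (length(time) < 2L || length(time) != length(pco2))
    stop("trace needs >= 2 samples with matching time/pco2 lengths")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(!is.finite(pco2)) || any(pco2 < 0))
    stop("pco2 must be finite and >= 0 mmHg")
  structure(list(time = time, pco2 = pco2,
                 sampling_rate = 1 / stats::median(diff(time))),
            class = "capno_trace")
}

#' Read a capnograph trace from a delimited text file
#'
#' Expects columns `time_s` and `pco2_mmhg` (TSV or CSV, autodetected).
#'
#' @param path File path.
#' @param scale Unit conversion passed to [capno_trace()].
#' @return A `capno_trace`.
#' @export
read_capno_trace <- function(path, scale = 1) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("time_s", "pco2_mmhg") %in% names(d)))
    stop("expected columns 'time_s' and 'pco2_mmhg' in ", path)
  capno_trace(d$time_s, d$pco2_mmhg, scale = scale)
}

#' Per-breath end-tidal CO2 series
#'
#' @param breath_end_time Breath-end times (s), strictly increasing.
#' @param petco2 End-tidal CO2 per breath (mmHg), within \[0, 100\].
#' @param hold_windows Two-column matrix of breath-hold (start, end) times,
#'   non-overlapping; may have zero rows.
#' @return An object of class `end_tidal_series`.
#' @export
end_tidal_series <- function(breath_end_time, petco2,
                             hold_windows = matrix(numeric(), ncol = 2)) {
  if (length(breath_end_time) != length(petco2))
    stop("breath_end_time and petco2 must have equal length")
  if (any(diff(breath_end_time) <= 0))
    stop("breath_end_time must be strictly increasing")
  if (any(petco2 < 0 | petco2 > 100))
    stop("petco2 outside the physiological range [0, 100] mmHg")
  hw <- matrix(as.numeric(hold_windows), ncol = 2)
  if (nrow(hw) > 1) {
    o <- order(hw[, 1])
    if (any(hw[o, 1][-1] < hw[o, 2][-nrow(hw)]))
      stop("hold windows must not overlap")
  }
  structure(list(breath_end_time = breath_end_time, petco2 = petco2,
                 hold_windows = hw),
            class = "end_tidal_series")
}

# Topographic prominence of local maxima: for each peak, walk outward on
# each side to the nearest higher sample (or the series end) and record the
# lowest valley passed; prominence = height - max(left valley, right valley).
.peak_prominence <- function(s, peaks) {
  vapply(peaks, function(i) {
    h <- s[i]
    left <- s[seq_len(i - 1)]
    right <- if (i < length(s)) s[(i + 1):length(s)] else numeric()
    hl <- which(left > h); lo_l <- if (length(hl)) min(left[(max(hl) + 1):(i - 1)]) else
      if (length(left)) min(left) else h
    hr <- which(right > h); lo_r <- if (length(hr)) min(right[seq_len(min(hr) - 1)]) else
      if (length(right)) min(right) else h
    h - max(lo_l, lo_r)
  }, numeric(1))
}

#' Detect per-breath end-tidal CO2 values in a capnograph trace
#'
#' Peak-detection on the CO2 trace: the series is lightly smoothed with a
#' moving average, local expiratory maxima are kept if their topographic
#' prominence exceeds `min_prominence`, maxima closer together than
#' `min_interval` are merged (the higher one is kept, so apnoeic pauses and
#' cardiogenic oscillations do not split a breath), and the end-tidal value
#' of each breath is read from the raw trace in a small window around the
#' detected peak. The first maximum after each breath-hold is the
#' quick-exhalation value that carries the CO2 accumulated during the hold.
#'
#' @param trace A [capno_trace()].
#' @param paradigm Optional [make_paradigm()]; when given, its hold windows
#'   are attached to the result and the trace must cover the task duration.
#' @param min_interval Minimum inter-breath interval (s).
#' @param min_prominence Minimum peak prominence (mmHg).
#' @param smooth_window Moving-average window (s) used for detection only.
#' @return An [end_tidal_series()].
#' @export
detect_end_tidal <- function(trace, paradigm = NULL, min_interval = 1.5,
                             min_prominence = 1, smooth_window = 0.25) {
  stopifnot(inherits(trace, "capno_trace"))
  if (trace$sampling_rate < 10)
    stop("sampling rate below 10 Hz: too coarse for end-tidal detection")
  if (!is.null(paradigm) &&
      (max(trace$time) - min(trace$time)) < paradigm$total_s - paradigm$tr)
    stop("coverage error: trace shorter than the breath-hold paradigm")
  x <- trace$pco2
  if (diff(range(x)) < min_prominence)
    stop("no breaths detected: trace is flat")

  w <- max(1L, round(smooth_window * trace$sampling_rate))
  s <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  s[is.na(s)] <- x[is.na(s)]

  d <- diff(s)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (!length(cand)) stop("no breaths detected: no local maxima in trace")
  prom <- .peak_prominence(s, cand)
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) stop("no breaths detected: no sufficiently prominent maxima")

  # merge maxima closer than min_interval, keeping the higher
  keep <- cand[order(s[cand], decreasing = TRUE)]
  sel <- integer()
  for (i in keep)
    if (!length(sel) || all(abs(trace$time[sel] - trace$time[i]) >= min_interval))
      sel <- c(sel, i)
  sel <- sort(sel)

  # end-tidal amplitude from the raw trace around each detected peak
  half <- max(1L, round(smooth_window * trace$sampling_rate))
  pe_t <- pe_v <- numeric(length(sel))
  for (k in seq_along(sel)) {
    idx <- max(1L, sel[k] - half):min(length(x), sel[k] + half)
    j <- idx[which.max(x[idx])]
    pe_t[k] <- trace$time[j]; pe_v[k] <- x[j]
  }
  o <- !duplicated(pe_t)
  hw <- if (is.null(paradigm)) matrix(numeric(), ncol = 2) else
    paradigm_hold_windows(paradigm)
  end_tidal_series(pe_t[o], pe_v[o], hold_windows = hw)
}

#' Uniformly sampled CO2 series
#'
#' @param values Series values (mmHg).
#' @param dt Sample spacing (s).
#' @param t0 Time of the first sample (s).
#' @return An object of class `co2_series`.
#' @export
co2_series <- function(values, dt, t0 = 0) {
  stopifnot(dt > 0, is.numeric(values))
  structure(list(values = as.numeric(values), dt = dt, t0 = t0),
            class = "co2_series")
}

#' @rdname co2_series
#' @param series A `co2_series`.
#' @export
co2_series_times <- function(series) {
  series$t0 + (seq_along(series$values) - 1) * series$dt
}

#' Interpolate end-tidal values onto a uniform grid, bridging breath-holds
#'
#' Successive per-breath end-tidal values are joined by straight lines.
#' Across each breath-hold the trace is the straight line from the end-tidal
#' value of the final breath before the hold to the quick-exhalation value
#' of the first breath after it; any maxima detected inside a hold window
#' (where no expiration occurs) are discarded first. Before the first and
#' after the last breath the trace is held constant.
#'
#' @param ets An [end_tidal_series()].
#' @param dt Output sample spacing (s); 0.1 s matches the delay-search grid.
#' @param t_end End of the output grid (s); defaults to the last breath.
#' @return A [co2_series()] starting at t = 0.
#' @export
interpolate_breath_hold <- function(ets, dt = 0.1, t_end = NULL) {
  stopifnot(inherits(ets, "end_tidal_series"))
  bt <- ets$breath_end_time; pv <- ets$petco2
  hw <- ets$hold_windows
  if (nrow(hw)) {
    for (r in seq_len(nrow(hw))) {
      if (!any(bt <= hw[r, 1]) || !any(bt >= hw[r, 2]))
        stop("unbounded hold: breath-hold window at ", hw[r, 1],
             " s lacks a bounding breath")
    }
    inside <- rep(FALSE, length(bt))
    for (r in seq_len(nrow(hw)))
      inside <- inside | (bt > hw[r, 1] & bt < hw[r, 2])
    bt <- bt[!inside]; pv <- pv[!inside]
  }
  if (length(bt) < 2) stop("need at least two breaths to interpolate")
  if (is.null(t_end)) t_end <- max(bt)
  grid <- seq(0, t_end, by = dt)
  co2_series(stats::approx(bt, pv, xout = grid, rule = 2)$y, dt = dt, t0 = 0)
}

#' Double-gamma haemodynamic response function specification
#'
#' The canonical two-gamma HRF: a positive gamma density peaking at
#' `peak_delay` minus a scaled gamma density peaking at `undershoot_delay`.
#' The discrete kernel is normalised to unit area so convolution is
#' scale-invariant: a sustained end-tidal step of A mmHg converges to an
#' output of A mmHg, keeping the regressor quantitative.
#'
#' @param peak_delay Time-to-peak of the positive lobe (s).
#' @param undershoot_delay Time-to-peak of the undershoot lobe (s).
#' @param peak_dispersion,undershoot_dispersion Dispersions (s).
#' @param undershoot_ratio Peak:undershoot amplitude ratio.
#' @param dt Sampling step of the kernel (s).
#' @param duration Kernel support (s).
#' @return An object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     undershoot_ratio = 6, dt = 0.1, duration = 32) {
  v <- c(peak_delay, undershoot_delay, peak_dispersion,
         undershoot_dispersion, undershoot_ratio, dt, duration)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all hrf_spec parameters must be positive")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 undershoot_ratio = undershoot_ratio, dt = dt,
                 duration = duration),
            class = "hrf_spec")
}

#' @rdname hrf_spec
#' @param hrf An `hrf_spec`.
#' @return `hrf_kernel()`: the discrete kernel sampled at `dt`, scaled so
#'   that `sum(kernel) * dt == 1`.
#' @export
hrf_kernel <- function(hrf = hrf_spec()) {
  t <- seq(0, hrf$duration, by = hrf$dt)
  h <- stats::dgamma(t, shape = hrf$peak_delay / hrf$peak_dispersion,
                     scale = hrf$peak_dispersion) -
    stats::dgamma(t, shape = hrf$undershoot_delay / hrf$undershoot_dispersion,
                  scale = hrf$undershoot_dispersion) / hrf$undershoot_ratio
  h / (sum(h) * hrf$dt)
}

#' Scale-invariant convolution of a CO2 series with the HRF
#'
#' Causal convolution with the unit-area double-gamma kernel. The input is
#' padded at its start with its first value so a series already at
#' steady state stays at steady state (no onset transient). Because the
#' kernel has unit area the output preserves the mmHg scale of the input,
#' so fitted slopes remain %BOLD per mmHg.
#'
#' @param series A [co2_series()] sampled at `hrf$dt`.
#' @param hrf An [hrf_spec()].
#' @return A [co2_series()] on the same grid.
#' @export
convolve_hrf <- function(series, hrf = hrf_spec()) {
  stopifnot(inherits(series, "co2_series"))
  if (abs(series$dt - hrf$dt) > 1e-9)
    stop("resolution error: series dt (", series$dt,
         ") does not match hrf dt (", hrf$dt, ")")
  k <- hrf_kernel(hrf)
  x <- series$values
  K <- length(k)
  xp <- c(rep(x[1], K - 1L), x)
  full <- stats::convolve(xp, rev(k), type = "open")
  co2_series(full[K:(K + length(x) - 1L)] * hrf$dt,
             dt = series$dt, t0 = series$t0)
}

#' Frame-aligned CO2 regressor
#'
#' @param values Regressor values at frame acquisition midpoints (mmHg).
#' @param tr Repetition time (s).
#' @param applied_delay Temporal shift applied before sampling (s).
#' @param t_start Time of the start of the first retained frame (s).
#' @return An object of class `co2_regressor`.
#' @export
co2_regressor <- function(values, tr, applied_delay = 0, t_start = 0) {
  stopifnot(all(is.finite(values)), tr > 0)
  structure(list(values = as.numeric(values), tr = tr,
                 applied_delay = applied_delay,
                 n_frames = length(values), t_start = t_start),
            class = "co2_regressor")
}

#' Shift a CO2 series and sample it at BOLD frame times
#'
#' The series is shifted by `delay` (a positive delay models the BOLD
#' response lagging the end-tidal trace, so the regressor at frame time t
#' takes the series value at t - delay) and sampled at frame acquisition
#' midpoints `t_start + (k - 1/2) * tr` by linear interpolation. Samples
#' falling outside the series take the nearest boundary value, avoiding
#' spurious transients at the run edges.
#'
#' @param series A [co2_series()].
#' @param tr Repetition time (s).
#' @param n_frames Number of frames to sample.
#' @param delay Applied delay (s).
#' @param t_start Start time of the first retained frame (s); use
#'   `paradigm$drop_first * tr` when leading frames were discarded.
#' @return A [co2_regressor()].
#' @export
resample_to_frames <- function(series, tr, n_frames, delay = 0, t_start = 0) {
  stopifnot(inherits(series, "co2_series"))
  if (n_frames <= 0) stop("n_frames must be positive")
  tf <- t_start + (seq_len(n_frames) - 0.5) * tr
  st <- co2_series_times(series)
  co2_regressor(stats::approx(st, series$values, xout = tf - delay,
                              rule = 2)$y,
                tr = tr, applied_delay = delay, t_start = t_start)
}

#' Build an HRF-convolved end-tidal CO2 series from a raw trace
#'
#' Convenience chain: [detect_end_tidal()] then [interpolate_breath_hold()]
#' then [convolve_hrf()]. The result is the high-resolution (dt = `hrf$dt`)
#' CO2 model from which frame-aligned regressors at any delay are drawn
#' with [resample_to_frames()].
#'
#' @inheritParams detect_end_tidal
#' @param hrf An [hrf_spec()].
#' @param ... Passed to [detect_end_tidal()].
#' @return A [co2_series()].
#' @export
build_co2_series <- function(trace, paradigm, hrf = hrf_spec(), ...) {
  ets <- detect_end_tidal(trace, paradigm, ...)
  convolve_hrf(interpolate_breath_hold(ets, dt = hrf$dt), hrf)
}
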