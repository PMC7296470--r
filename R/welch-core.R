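# Serial Welch estimator: segmentation plan, window generation, per-segment
# periodograms and their average. All segment indices are 0-based and segment
# sample ranges are inclusive [start, end].

#' Single-channel signal container
#'
#' Holds one EEG channel: an ordered sequence of real amplitudes and its
#' sampling rate. All estimator functions take their input through this type.
#'
#' @param samples numeric vector of amplitudes (arbitrary voltage units);
#'   must be non-empty and finite.
#' @param fs sampling rate in Hz; must be positive.
#' @param label channel identifier string.
#' @return An object of class `signal_channel` with fields `label`, `samples`
#'   and `fs`.
#' @examples
#' ch <- signal_channel(sin(2 * pi * 10 * (0:255) / 256), fs = 256, label = "FP1")
#' @export
signal_channel <- function(samples, fs, label = "ch1") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("'samples' must contain at least one value")
  }
  if (!all(is.finite(samples))) {
    stop("'samples' must be finite (no NA/NaN/Inf)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("'fs' must be a single positive number (Hz)")
  }
  structure(
    list(label = as.character(label)[1L], samples = samples, fs = as.numeric(fs)),
    class = "signal_channel"
  )
}

#' @export
print.signal_channel <- function(x, ...) {
  cat(sprintf(
    "<signal_channel> %s: %d samples at %g Hz (%.3f s)\n",
    x$label, length(x$samples), x$fs, length(x$samples) / x$fs
  ))
  invisible(x)
}

#' Welch estimator configuration
#'
#' Collects every tunable of the estimator. The defaults reproduce the
#' canonical EEG analysis call `pwelch(data, hamming(64), 32, 64, fs)`:
#' 64-sample segments with 50% overlap, symmetric Hamming window, one-sided
#' power spectral density in units^2/Hz.
#'
#' @param seg_len segment length L in samples (>= 2).
#' @param n_overlap overlap ND between consecutive segments in samples
#'   (0 <= ND < L). The segment start step is L - ND.
#' @param window window taper: "hamming", "hann" or "rectangular".
#' @param convention "symmetric" (cosine denominator L - 1, the convention of
#'   the common reference routines) or "periodic" (denominator L).
#' @param scaling "density" (periodogram divided by fs * L * U, units^2/Hz) or
#'   "textbook" (divided by L * U only; the literal textbook periodogram).
#' @param sided "one" (bins 0..L/2, interior bins doubled; requires even L) or
#'   "two" (all L bins).
#' @param detrend "none" (window applied to raw samples) or "constant"
#'   (per-segment mean removed before windowing).
#' @return An object of class `welch_config`.
#' @export
welch_config <- function(seg_len = 64L, n_overlap = 32L,
                         window = c("hamming", "hann", "rectangular"),
                         convention = c("symmetric", "periodic"),
                         scaling = c("density", "textbook"),
                         sided = c("one", "two"),
                         detrend = c("none", "constant")) {
  window <- match.arg(window)
  convention <- match.arg(convention)
  scaling <- match.arg(scaling)
  sided <- match.arg(sided)
  detrend <- match.arg(detrend)
  seg_len <- as.integer(seg_len)
  n_overlap <- as.integer(n_overlap)
  if (is.na(seg_len) || seg_len < 2L) {
    stop("'seg_len' (L) must be an integer >= 2")
  }
  if (is.na(n_overlap) || n_overlap < 0L || n_overlap >= seg_len) {
    stop(sprintf(
      "'n_overlap' (ND) must satisfy 0 <= ND < L; got ND = %d, L = %d",
      n_overlap, seg_len
    ))
  }
  if (sided == "one" && seg_len %% 2L != 0L) {
    stop("one-sided output requires an even segment length L")
  }
  structure(
    list(
      seg_len = seg_len, n_overlap = n_overlap, window = window,
      convention = convention, scaling = scaling, sided = sided,
      detrend = detrend
    ),
    class = "welch_config"
  )
}

#' @export
print.welch_config <- function(x, ...) {
  cat(sprintf(
    "<welch_config> L=%d ND=%d window=%s/%s scaling=%s sided=%s detrend=%s\n",
    x$seg_len, x$n_overlap, x$window, x$convention, x$scaling, x$sided,
    x$detrend
  ))
  invisible(x)
}

#' Plan the overlapped segmentation of a signal
#'
#' Splits a length-N signal into the maximal number of overlapped segments of
#' length L with start step L - ND. Segment i covers samples
#' i*(L - ND) .. i*(L - ND) + L - 1 (0-based, inclusive). Trailing samples that
#' do not fill a complete segment are discarded and counted.
#'
#' @param n total sample count N of the signal.
#' @param config a [welch_config()].
#' @return An object of class `segment_plan` with fields `n_segments`,
#'   `starts` (0-based), `seg_len` and `discarded_tail`.
#' @examples
#' plan_segments(256, welch_config()) # 7 segments: starts 0, 32, ..., 192
#' @export
plan_segments <- function(n, config = welch_config()) {
  stopifnot(inherits(config, "welch_config"))
  n <- as.integer(n)
  L <- config$seg_len
  nd <- config$n_overlap
  if (is.na(n) || n < L) {
    stop(sprintf("signal shorter than one segment (N = %d, L = %d)", n, L))
  }
  step <- L - nd
  ns <- (n - L) %/% step + 1L
  starts <- (seq_len(ns) - 1L) * step
  structure(
    list(
      n_segments = ns, starts = starts, seg_len = L,
      discarded_tail = n - (starts[ns] + L)
    ),
    class = "segment_plan"
  )
}

#' @export
print.segment_plan <- function(x, ...) {
  cat(sprintf(
    "<segment_plan> %d segments of length %d (starts %s%s), %d trailing samples discarded\n",
    x$n_segments, x$seg_len,
    paste(utils::head(x$starts, 4L), collapse = ", "),
    if (x$n_segments > 4L) ", ..." else "",
    x$discarded_tail
  ))
  invisible(x)
}

#' Inclusive sample range of one segment
#'
#' For segment index i (0-based) with segment length L and overlap ND, the
#' covered sample range is [i*(L - ND), i*(L - ND) + L - 1]. With the default
#' L = 64, ND = 32, segment 0 covers [0, 63] and segment 4 covers [128, 191].
#'
#' @param i 0-based segment index.
#' @param config a [welch_config()].
#' @return Integer vector `c(start, end)`, 0-based inclusive.
#' @export
segment_bounds <- function(i, config = welch_config()) {
  stopifnot(inherits(config, "welch_config"))
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 0L) {
    stop("segment index 'i' must be a single non-negative integer")
  }
  start <- i * (config$seg_len - config$n_overlap)
  c(start = start, end = start + config$seg_len - 1L)
}

#' Generate a window taper and its power normalization
#'
#' Raised-cosine tapers in two conventions: "periodic" uses cosine denominator
#' L (the literal w(n) = 0.54 - 0.46 cos(2 pi n / L) for Hamming), "symmetric"
#' uses L - 1 (the convention of pwelch/scipy default windows; an odd-length
#' symmetric window peaks at exactly 1 in the middle). The power normalization
#' U = mean(w^2) divides the periodogram so that windowing does not bias total
#' power; the rectangular window has U = 1 exactly.
#'
#' @param kind "hamming", "hann" or "rectangular".
#' @param convention "symmetric" or "periodic" (ignored for rectangular).
#' @param L window length in samples (>= 2).
#' @return An object of class `window_vector` with fields `coefficients`
#'   (length L) and `power_norm` (U).
#' @export
make_window <- function(kind = c("hamming", "hann", "rectangular"),
                        convention = c("symmetric", "periodic"), L) {
  kind <- match.arg(kind)
  convention <- match.arg(convention)
  L <- as.integer(L)
  if (is.na(L) || L < 2L) stop("window length 'L' must be an integer >= 2")
  n <- seq_len(L) - 1L
  if (kind == "rectangular") {
    w <- rep(1, L)
    u <- 1
  } else {
    den <- if (convention == "periodic") L else L - 1L
    w <- switch(kind,
      hamming = 0.54 - 0.46 * cos(2 * pi * n / den),
      hann = 0.5 - 0.5 * cos(2 * pi * n / den)
    )
    u <- mean(w^2)
  }
  structure(
    list(coefficients = w, power_norm = u, kind = kind,
         convention = convention),
    class = "window_vector"
  )
}

#' Frequency axis for a length-L transform
#'
#' @param L transform (= segment) length; must be even for one-sided output.
#' @param fs sampling rate in Hz.
#' @param sided "one" (k*fs/L for k = 0..L/2, DC through Nyquist) or "two"
#'   (k = 0..L-1).
#' @return Numeric vector of frequencies in Hz.
#' @examples
#' frequency_axis(64, 256, "one") # 0, 4, 8, ..., 128 Hz
#' @export
frequency_axis <- function(L, fs, sided = c("one", "two")) {
  sided <- match.arg(sided)
  L <- as.integer(L)
  if (is.na(L) || L < 2L) stop("'L' must be an integer >= 2")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a single positive number (Hz)")
  }
  if (sided == "one") {
    if (L %% 2L != 0L) stop("one-sided frequency axis requires an even L")
    (0:(L %/% 2L)) * fs / L
  } else {
    (0:(L - 1L)) * fs / L
  }
}

#' Windowed periodogram of one segment
#'
#' Extracts the samples of segment i per [segment_bounds()], optionally
#' removes the segment mean, multiplies by the window, computes the length-L
#' discrete Fourier transform A_i(k), and scales |A_i(k)|^2 by 1/(L*U)
#' (scaling "textbook") or additionally by 1/fs (scaling "density", units^2/Hz).
#' One-sided output keeps k = 0..L/2 and doubles every interior bin (neither
#' DC nor Nyquist), conserving total power.
#'
#' @param channel a [signal_channel()].
#' @param plan the [plan_segments()] result for this channel.
#' @param i 0-based segment index, < `plan$n_segments`.
#' @param window the [make_window()] result, length L.
#' @param config the [welch_config()] that produced `plan`.
#' @return An object of class `periodogram` with fields `segment_index`,
#'   `values` (all >= 0) and `n_bins`.
#' @export
segment_periodogram <- function(channel, plan, i, window, config) {
  stopifnot(
    inherits(channel, "signal_channel"), inherits(plan, "segment_plan"),
    inherits(window, "window_vector"), inherits(config, "welch_config")
  )
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 0L || i >= plan$n_segments) {
    stop(sprintf(
      "segment index %d out of range (Ns = %d)", i, plan$n_segments
    ))
  }
  L <- config$seg_len
  if (length(window$coefficients) != L) {
    stop(sprintf(
      "window length %d does not match segment length %d",
      length(window$coefficients), L
    ))
  }
  b <- segment_bounds(i, config)
  seg <- channel$samples[(b[["start"]] + 1L):(b[["end"]] + 1L)]
  if (config$detrend == "constant") seg <- seg - mean(seg)
  a <- stats::fft(seg * window$coefficients)
  phi <- (Mod(a)^2) / (L * window$power_norm)
  if (config$scaling == "density") phi <- phi / channel$fs
  if (config$sided == "one") {
    half <- L %/% 2L
    phi <- phi[1:(half + 1L)]
    if (half > 1L) phi[2:half] <- 2 * phi[2:half]
  }
  structure(
    list(segment_index = i, values = phi, n_bins = length(phi)),
    class = "periodogram"
  )
}

psd_result <- function(label, freqs, psd, n_segments_used, config) {
  structure(
    list(label = label, freqs = freqs, psd = psd,
         n_segments_used = n_segments_used, config = config),
    class = "psd_result"
  )
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf(
    "<psd_result> %s: %d bins over %g-%g Hz, averaged over %d segments\n",
    x$label, length(x$psd), x$freqs[1L], x$freqs[length(x$freqs)],
    x$n_segments_used
  ))
  invisible(x)
}

#' Welch power spectral density of one channel
#'
#' The Welch estimate S(k) is the arithmetic mean of the windowed segment
#' periodograms, accumulated in ascending segment-index order (fixed order so
#' that serial and parallel execution are bitwise identical). With N = L the
#' estimate equals the single segment's periodogram.
#'
#' @param channel a [signal_channel()] with at least L samples.
#' @param config a [welch_config()].
#' @return An object of class `psd_result` with fields `label`, `freqs` (Hz),
#'   `psd`, `n_segments_used` and `config`.
#' @examples
#' ch <- signal_channel(rnorm(256), fs = 256)
#' res <- welch_psd(ch)
#' res$n_segments_used # 7
#' @export
welch_psd <- function(channel, config = welch_config()) {
  stopifnot(inherits(channel, "signal_channel"))
  plan <- plan_segments(length(channel$samples), config)
  win <- make_window(config$window, config$convention, config$seg_len)
  wr <- worker_compute(
    channel, plan, win, config,
    assigned = seq_len(plan$n_segments) - 1L, rank = 0L
  )
  reduce_psd(list(wr), plan, config, label = channel$label, fs = channel$fs)
}
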