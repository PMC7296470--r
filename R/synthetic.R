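# Seeded generator of EEG-shaped test signals: sums of cosine tones plus
# white Gaussian noise, and whole middle-file datasets with the study
# dataset's dimensions (64 channels, 256 samples, 256 Hz) so every stage is
# testable without any download. The noise is independent Gaussian per
# sample; no 1/f or physiological band structure is simulated.

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Specify a cosine tone
#'
#' @param freq tone frequency in Hz (>= 0; must not exceed fs/2 when the
#'   channel is generated).
#' @param amplitude peak amplitude in signal units (>= 0).
#' @param phase phase offset in radians.
#' @return An object of class `tone_spec`.
#' @export
tone <- function(freq, amplitude = 1, phase = 0) {
  if (!is.numeric(freq) || length(freq) != 1L || !is.finite(freq) ||
      freq < 0) {
    stop("'freq' must be a single non-negative number (Hz)")
  }
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0) {
    stop("'amplitude' must be a single non-negative number")
  }
  structure(
    list(freq = freq, amplitude = amplitude, phase = as.numeric(phase)),
    class = "tone_spec"
  )
}

#' Generate one synthetic channel
#'
#' x[n] = sum over tones of amplitude * cos(2 pi freq n / fs + phase), plus
#' independent Gaussian noise of standard deviation `noise_sd`. The same seed
#' always yields a bitwise-identical channel; with `seed = NULL` the ambient
#' RNG stream is used (and advanced).
#'
#' @param tones list of [tone()] specs (possibly empty).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param n number of samples (>= 1).
#' @param fs sampling rate in Hz.
#' @param seed integer seed, or NULL for the ambient RNG stream.
#' @param label channel identifier.
#' @return A [signal_channel()].
#' @examples
#' ch <- gen_channel(list(tone(12, 1)), noise_sd = 0, n = 256, fs = 256,
#'                   seed = 1)
#' @export
gen_channel <- function(tones = list(), noise_sd = 1, n = 256L, fs = 256,
                        seed = NULL, label = "ch1") {
  if (inherits(tones, "tone_spec")) tones <- list(tones)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("'noise_sd' must be a single non-negative number")
  }
  for (tn in tones) {
    if (!inherits(tn, "tone_spec")) stop("'tones' must be a list of tone()")
    if (tn$freq > fs / 2) {
      stop(sprintf(
        "tone at %g Hz exceeds the Nyquist frequency %g Hz (aliasing)",
        tn$freq, fs / 2
      ))
    }
  }
  with_local_seed(seed, {
    idx <- seq_len(n) - 1L
    x <- numeric(n)
    for (tn in tones) {
      x <- x + tn$amplitude * cos(2 * pi * tn$freq * idx / fs + tn$phase)
    }
    if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
    signal_channel(x, fs = fs, label = label)
  })
}

#' Generate a directory of synthetic middle files
#'
#' Writes `n_files` middle files of `n_channels` channels x `n` samples at
#' `fs` Hz, plus a `manifest.tsv` listing file name, seed, channels, samples
#' and fs. The per-file seed is `seed + file_index` (0-based), so any file
#' can be regenerated independently and the same master seed always yields a
#' byte-identical dataset. Defaults emulate the study dataset's shape:
#' 64 electrodes sampled at 256 Hz for 1 second.
#'
#' @param out_dir output directory (created if needed).
#' @param n_files number of files (>= 1).
#' @param n_channels channels per file (>= 1).
#' @param n samples per channel (>= 1).
#' @param fs sampling rate in Hz.
#' @param seed master integer seed.
#' @param tones list of [tone()] specs shared by all channels.
#' @param noise_sd Gaussian noise standard deviation.
#' @return Invisibly, the manifest data.frame.
#' @export
gen_dataset <- function(out_dir, n_files = 3L, n_channels = 64L, n = 256L,
                        fs = 256, seed = 1L, tones = list(), noise_sd = 1) {
  n_files <- as.integer(n_files)
  n_channels <- as.integer(n_channels)
  if (is.na(n_files) || n_files < 1L || is.na(n_channels) ||
      n_channels < 1L) {
    stop("'n_files' and 'n_channels' must be positive integers")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory: %s", out_dir))
  }
  manifest <- data.frame(
    file = sprintf("synthetic_%03d.middle", seq_len(n_files) - 1L),
    seed = seed + (seq_len(n_files) - 1L),
    channels = n_channels, samples = as.integer(n), fs = fs
  )
  for (k in seq_len(n_files)) {
    channels <- with_local_seed(manifest$seed[k], {
      lapply(seq_len(n_channels), function(j) {
        gen_channel(tones, noise_sd, n, fs, seed = NULL,
                    label = sprintf("ch%02d", j))
      })
    })
    write_middle(fs, channels, file.path(out_dir, manifest$file[k]))
  }
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
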