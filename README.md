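# eegwelch

Welch power spectral density (PSD) estimation for multi-channel EEG, with a
master–worker parallel scheduler whose output is **bitwise-identical** to the
serial estimator for every backend and worker count.

Scalp EEG is routinely summarized by its PSD: each electrode's time series is
split into short overlapping segments, each segment is tapered and Fourier
transformed, and the squared spectra are averaged. When thousands of
recordings have to be processed, the per-channel work is embarrassingly
parallel — but naive parallelization changes floating-point summation order
and therefore the last bits of the result. This package is for
neurophysiology and signal-processing practitioners who want batch EEG
spectral features that are fast to compute *and* exactly reproducible.

## The estimator

For a channel x[n], n = 0..N−1 sampled at f_s, segments of length L with
overlap N_D start every L − N_D samples, giving

    N_s = floor((N − L) / (L − N_D)) + 1

segments (trailing samples that do not fill a segment are discarded). Each
segment is tapered by a window w(n) — by default the symmetric Hamming window
w(n) = 0.54 − 0.46·cos(2πn/(L−1)) — and transformed, and its periodogram is

    φ_i(k) = |A_i(k)|² / (f_s · L · U),   U = (1/L) Σ w(n)²

in units²/Hz (the `textbook` scaling omits the f_s divisor). The Welch estimate is
the arithmetic mean S(k) = (1/N_s) Σ_i φ_i(k). One-sided output keeps
k = 0..L/2 and doubles interior bins so total power is conserved. Defaults
(L = 64, N_D = 32, Hamming, one-sided density) reproduce the canonical EEG
call `pwelch(data, hamming(64), 32, 64, fs)`.

The scheduler assigns segment j to worker rank j mod size (round-robin, so
loads differ by at most one; the master takes its own share), computes each
rank's periodograms on a serial, forked-process, or socket message-passing
backend, and reduces on the master after re-sorting into ascending segment
order — so the accumulation order, and hence every output bit, matches the
serial path.

## Worked example

```r
library(eegwelch)
ch  <- gen_channel(list(tone(12, 1)), noise_sd = 0.5, n = 256, fs = 256,
                   seed = 1, label = "FP1")
res <- welch_psd(ch)           # defaults: L = 64, ND = 32, Hamming, density
res
#> <psd_result> FP1: 33 bins over 0-128 Hz, averaged over 7 segments
round(data.frame(freq_hz = res$freqs, psd = res$psd)[1:8, ], 5)
#>   freq_hz     psd
#> 1       0 0.00070
#> 2       4 0.00229
#> 3       8 0.02029
#> 4      12 0.09605
#> 5      16 0.01590
#> 6      20 0.00162
#> 7      24 0.00160
#> 8      28 0.00127
res$freqs[which.max(res$psd)]
#> [1] 12
identical(parallel_welch(ch, n_workers = 4)$psd, res$psd)
#> [1] TRUE
```

The 256-sample channel splits into 7 half-overlapping 64-sample segments
(bins every f_s/L = 4 Hz); the injected 12 Hz tone dominates its bin, the
surrounding bins hold the white-noise floor plus a little spectral leakage,
and a 4-worker run reproduces the serial result bit for bit.

## Files and command line

Recordings are exchanged as plain-text **middle files** (`#MIDDLE 1.0`
header, sampling rate, labels, then tab-separated sample rows; doubles are
written with 17 significant digits so they round-trip exactly). PSD results
are written as spreadsheet-readable TSV/CSV tables, one row per frequency
bin. The installed `eegwelch` script (see `inst/exec/`) exposes:

```sh
eegwelch gen   --output data --n-files 3 --channels 64 --samples 256 --seed 1
eegwelch psd   --input data/synthetic_000.middle --output out.psd.tsv --workers 4
eegwelch batch --input data --output psd/ --granularity segment
eegwelch bench --output bench.tsv --worker-counts 2,4 --reps 3
```

Exit codes: 0 success, 1 compute error, 2 input/format error.

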