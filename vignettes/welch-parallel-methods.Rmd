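---
title: "Methods: deterministic parallel Welch PSD estimation for EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deterministic parallel Welch PSD estimation for EEG}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegwelch)
```

## The model

Welch's method estimates the power spectral density of a stationary signal
by averaging windowed periodograms of overlapping segments. For a channel
$x[n]$, $n = 0,\dots,N-1$ at sampling rate $f_s$, segments of length $L$
with overlap $N_D$ start every $L-N_D$ samples; the number of segments is
the largest $N_s$ with $(N_s-1)(L-N_D)+L \le N$, i.e.

$$N_s = \left\lfloor \frac{N-L}{L-N_D} \right\rfloor + 1 .$$

Segment $i$ covers the inclusive sample range
$[\,i(L-N_D),\; i(L-N_D)+L-1\,]$ (all indices 0-based; with the defaults
$L=64$, $N_D=32$, segment 0 covers $[0,63]$ and segment 4 covers
$[128,191]$). Each segment is multiplied by a window $w(n)$, transformed
with a length-$L$ DFT $A_i(k)$, and scaled:

$$\varphi_i(k) = \frac{|A_i(k)|^2}{f_s\,L\,U}, \qquad
  U = \frac{1}{L}\sum_{n=0}^{L-1} w(n)^2 ,$$

which has units of signal$^2$/Hz ("density" scaling). The estimate is the
arithmetic mean $S(k) = N_s^{-1}\sum_i \varphi_i(k)$, which reduces the
periodogram's variance at the cost of frequency resolution $f_s/L$.

Key assumptions: the signal is (approximately) wide-sense stationary over
the analysis span, and segments are treated as equally informative — the
mean is unweighted. The estimator never zero-pads: the transform length
equals the segment length, as in the canonical EEG analysis call
`pwelch(data, hamming(64), 32, 64, 256)` whose defaults this package
mirrors.

## Conventions that had to be fixed

Textbook presentations of the method leave several choices open; each is a
constructor argument with the following defaults and rationale.

* **Window convention.** The raised-cosine family is written either with
  denominator $L$ ("periodic", $w(n)=0.54-0.46\cos(2\pi n/L)$ for Hamming)
  or $L-1$ ("symmetric", peaking at exactly 1 for odd $L$). Reference
  routines (Matlab `pwelch`, SciPy's default `hamming`) use the symmetric
  form, so `convention = "symmetric"` is the default and the periodic form
  remains available; the two differ in every coefficient but the first.
  The internal inconsistency of the usual index bounds (sums written over
  $L$ where $N_s$ is meant) is resolved in favour of averaging over the
  $N_s$ segments — this is stated here rather than silently absorbed.
* **Scaling.** "density" divides by $f_s L U$ (units$^2$/Hz, integrates to
  power); "textbook" divides by $LU$ only, the literal textbook periodogram.
  They differ by the constant $f_s$ and share one code path, so
  `density == textbook / fs` holds bin-wise exactly.
* **One-sided doubling.** One-sided output keeps $k = 0..L/2$ (even $L$
  only) and doubles every interior bin but neither DC nor Nyquist; this is
  the unique choice under which $\sum_k S(k)\,\Delta f$ equals the signal's
  mean power (Parseval), which the test suite checks on 65536 samples of
  unit white noise to within 5%.
* **Detrending.** Default `none`: the window is applied to raw samples.
  `constant` (subtract the segment mean) is offered because common
  reference implementations detrend by default; oracle comparisons must
  use matching settings on both sides.
* **Overlap.** The classic choice is 50%; the implementation accepts any
  $0 \le N_D < L$ with start step $L-N_D$. Trailing samples that do not
  fill a segment are discarded and reported in `discarded_tail` rather than
  padded, keeping every periodogram an honest length-$L$ transform.

## Parallel execution and bitwise reproducibility

The scheduler follows a master–worker map-reduce structure: *split* the
channel into $N_s$ segments, *map* segment $j$ to worker rank
$j \bmod \text{size}$ (round-robin; loads differ by at most one, and rank 0
— the master — computes its own share rather than only coordinating),
*reduce* on the master. Floating-point addition is not associative, so the
reduce step re-sorts incoming periodograms into ascending segment order
before accumulating; the summation order is therefore identical to the
serial path and the output is bitwise-identical for every worker count,
backend, and message arrival order. This deliberately trades a possible
tree-reduction speedup for exact reproducibility; a lost or duplicated
worker message is detected as a missing/duplicate segment index and raised
as an integrity error.

Three backends satisfy the same contract (broadcast the task, compute per
rank, gather tagged results): `serial` (in-process emulation, the reference
used throughout the tests), `process` (forked local process pool), and
`cluster`/`message-passing` (socket-connected worker pool). For directory
batches, the default granularity parallelizes segments within each file;
a whole-file-per-worker mode exists as plumbing for very large file counts,
where per-file open/close overhead otherwise caps the achievable speedup.
Both produce identical bytes.

`benchmark_speedup()` measures wall time with the serial baseline first and
reports speedup $= T_s/T_p$ per worker count, using the minimum over
repetitions to damp scheduler noise. Times are *measured and reported,
never asserted*: on a loaded or single-core host the measured speedup of a
small workload is routinely below 1 because of process start-up cost, and
the serial row's self-ratio is exactly 1 by construction.

## Synthetic data

`gen_channel()` produces $x[n] = \sum_t a_t\cos(2\pi f_t n/f_s + \phi_t)$
plus i.i.d. Gaussian noise, seeded; `gen_dataset()` writes middle files of
64 channels × 256 samples at 256 Hz by default — the shape of a standard
1-second, 64-electrode scalp EEG trial — with per-file seeds derived
additively from the master seed so any file regenerates independently.
This emulates the *dimensions* of real EEG, not its content: there is no
1/f background, no alpha/beta band structure, no artifacts, and no
inter-channel correlation. Passing tests therefore demonstrate numerical
correctness of the estimator and scheduler on signals of realistic shape,
not physiological validity of any downstream interpretation. Tones placed
at least 3 bins from DC and Nyquist are recovered at the nearest frequency
bin with zero noise, which is the property the generator is designed to
make testable.

## Numerical choices

* Transforms use R's built-in FFT; correctness is checked against an
  independent direct-summation DFT oracle (explicit loops over the
  segmentation, windowing, transform and averaging) to a relative
  $10^{-10}$ on 100 seeded random channels with $N \le 1024$ — sizes chosen
  so the quadratic-cost oracle runs in seconds while still covering 1–31
  segments per channel.
* Middle files and PSD tables render doubles with 17 significant digits,
  the minimum that guarantees bit-exact round-trip of IEEE-754 doubles
  through decimal text.
* Degenerate inputs: a signal shorter than one segment is an error naming
  $N$ and $L$; $N = L$ yields exactly the single segment's periodogram;
  more workers than segments leaves the surplus ranks idle with a correct
  result; an empty input directory is an error, a malformed file in a batch
  is logged, skipped and reflected in a nonzero exit status.
* One-sided output requires even $L$ (the Nyquist bin must exist); odd $L$
  is accepted only two-sided.

## Problem sizes used by the test suite

The suite and the acceptance script run entirely on generated data: random
channels of 64–1024 samples for oracle and determinism sweeps (100 and 20
channels respectively, 1–8 workers), one 65536-sample noise channel for the
Parseval check, and 3-file, 64-channel synthetic datasets for the batch and
CLI paths. The benchmark harness uses 16 channels of 4096 samples — enough
to time, small enough to rerun freely.

## Known limitations

No multitaper or time–frequency estimation; no window types beyond
Hamming/Hann/rectangular; no zero-padding or frequency interpolation; no
binary EEG formats (EDF/BDF) — recordings are converted to middle files
first; no dynamic load balancing or fault tolerance beyond integrity
errors. Observed speedup is hardware-bound and is deliberately outside the
package's claims.
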