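# Independent direct-summation Welch oracle: explicit loops over the
# segmentation, windowing, DFT-by-summation, periodogram and averaging steps.
# Deliberately shares no code with the package (no fft, no package helpers).

oracle_window <- function(kind, convention, L) {
  n <- 0:(L - 1)
  if (kind == "rectangular") return(rep(1, L))
  den <- if (convention == "periodic") L else L - 1
  a <- if (kind == "hamming") c(0.54, 0.46) else c(0.5, 0.5)
  a[1] - a[2] * cos(2 * pi * n / den)
}

# One-sided density-or-textbook Welch PSD via direct summation.
oracle_welch <- function(x, fs, L = 64, nd = 32, kind = "hamming",
                         convention = "symmetric", scaling = "density",
                         sided = "one") {
  step <- L - nd
  ns <- (length(x) - L) %/% step + 1
  w <- oracle_window(kind, convention, L)
  u <- sum(w^2) / L
  n <- 0:(L - 1)
  kmax <- if (sided == "one") L / 2 else L - 1
  acc <- numeric(kmax + 1)
  for (i in 0:(ns - 1)) {
    seg <- x[(i * step + 1):(i * step + L)] * w
    for (k in 0:kmax) {
      a_k <- sum(seg * exp(-2i * pi * n * k / L))
      p <- Mod(a_k)^2 / (L * u)
      if (scaling == "density") p <- p / fs
      if (sided == "one" && k != 0 && k != L / 2) p <- 2 * p
      acc[k + 1] <- acc[k + 1] + p
    }
  }
  acc / ns
}

max_rel_err <- function(got, want) {
  max(abs(got - want) / pmax(abs(want), .Machine$double.xmin))
}

random_channel <- function(seed, n = NULL, fs = 256) {
  set.seed(seed)
  if (is.null(n)) n <- sample(64:1024, 1)
  signal_channel(rnorm(n), fs = fs, label = sprintf("seed%d", seed))
}
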