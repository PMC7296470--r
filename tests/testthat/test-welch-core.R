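test_that("segmentation plan matches the overlap arithmetic", {
  cfg <- welch_config() # L = 64, ND = 32
  p <- plan_segments(256, cfg)
  expect_equal(p$n_segments, 7L)
  expect_equal(p$starts, seq(0L, 192L, by = 32L))
  expect_equal(p$discarded_tail, 0L)

  p1 <- plan_segments(64, cfg)
  expect_equal(p1$n_segments, 1L)
  expect_equal(p1$starts, 0L)
  expect_equal(p1$discarded_tail, 0L)

  # brute-force enumeration of all i with 32*i + 64 <= 255
  p2 <- plan_segments(255, cfg)
  expect_equal(p2$n_segments, sum(32 * (0:100) + 64 <= 255))
  expect_equal(p2$n_segments, 6L)
  expect_equal(p2$discarded_tail, 31L)

  expect_error(plan_segments(63, cfg), "shorter than one segment")
  expect_error(plan_segments(63, cfg), "N = 63, L = 64")
})

test_that("segmentation plan is maximal and tight for random N, L, ND", {
  set.seed(42)
  for (rep in 1:50) {
    L <- sample(2:128, 1)
    nd <- sample(0:(L - 1), 1)
    n <- sample(L:2048, 1)
    cfg <- welch_config(L, nd, sided = "two")
    p <- plan_segments(n, cfg)
    step <- L - nd
    expect_equal(p$starts, (seq_len(p$n_segments) - 1L) * step)
    expect_lte(p$starts[p$n_segments] + L, n)
    # maximality: one more segment would overrun
    expect_gt(p$n_segments * step + L, n)
    expect_equal(p$discarded_tail, n - (p$starts[p$n_segments] + L))
    expect_true(p$discarded_tail >= 0 && p$discarded_tail < step)
  }
})

test_that("segment bounds are inclusive 0-based ranges", {
  cfg <- welch_config()
  expect_equal(unname(segment_bounds(0, cfg)), c(0L, 63L))
  expect_equal(unname(segment_bounds(4, cfg)), c(128L, 191L))
  cfg2 <- welch_config(seg_len = 100L, n_overlap = 17L)
  expect_equal(unname(segment_bounds(0, cfg2)), c(0L, 99L))
  expect_error(segment_bounds(-1, cfg), "non-negative")
})

test_that("window tapers honour kind and convention", {
  for (conv in c("symmetric", "periodic")) {
    w <- make_window("hamming", conv, 64)
    expect_equal(w$coefficients[1], 0.08)
    expect_equal(w$power_norm, mean(w$coefficients^2))
    expect_true(all(w$coefficients >= 0 & w$coefficients <= 1))
  }
  # odd-length symmetric window peaks at exactly 1 in the centre
  w65 <- make_window("hamming", "symmetric", 65)
  expect_identical(w65$coefficients[33], 1)
  # periodic convention: denominator L, so w(L/2) = 1 for even L
  wp <- make_window("hamming", "periodic", 64)
  expect_identical(wp$coefficients[33], 1)
  expect_false(identical(wp$coefficients,
                         make_window("hamming", "symmetric", 64)$coefficients))

  wh <- make_window("hann", "symmetric", 64)
  expect_equal(wh$coefficients[1], 0)
  wr <- make_window("rectangular", L = 64)
  expect_identical(wr$coefficients, rep(1, 64))
  expect_identical(wr$power_norm, 1)
})

test_that("frequency axis spans DC to Nyquist with spacing fs/L", {
  expect_equal(frequency_axis(64, 256, "one"), seq(0, 128, by = 4))
  two <- frequency_axis(64, 256, "two")
  expect_length(two, 64)
  expect_equal(two[64], 252)
  expect_equal(frequency_axis(2, 1, "one"), c(0, 0.5))
  expect_error(frequency_axis(63, 256, "one"), "even")
})

test_that("segment periodogram matches closed forms and the DFT oracle", {
  fs <- 256
  cfg <- welch_config(window = "rectangular", scaling = "textbook", sided = "two")
  win <- make_window("rectangular", L = 64)

  # constant signal: all power at DC, phi(0) = c^2 * L
  c0 <- 3.5
  ch <- signal_channel(rep(c0, 64), fs)
  p <- segment_periodogram(ch, plan_segments(64, cfg), 0, win, cfg)
  expect_equal(p$values[1], c0^2 * 64)
  expect_equal(p$values[-1], rep(0, 63), tolerance = 1e-12)

  # bin-centred cosine of amplitude A: phi(k0) = phi(L - k0) = A^2 L / 4
  amp <- 2
  k0 <- 5
  x <- amp * cos(2 * pi * k0 * (0:63) / 64)
  p <- segment_periodogram(signal_channel(x, fs), plan_segments(64, cfg), 0,
                           win, cfg)
  expect_equal(p$values[k0 + 1], amp^2 * 64 / 4)
  expect_equal(p$values[64 - k0 + 1], amp^2 * 64 / 4)
  expect_equal(sum(p$values[-c(k0 + 1, 64 - k0 + 1)]), 0, tolerance = 1e-9)

  # seeded noise segment against the direct-summation oracle
  set.seed(7)
  x <- rnorm(64)
  chn <- signal_channel(x, fs)
  cfg1 <- welch_config(window = "hamming", scaling = "density", sided = "one")
  win1 <- make_window("hamming", "symmetric", 64)
  p1 <- segment_periodogram(chn, plan_segments(64, cfg1), 0, win1, cfg1)
  want <- oracle_welch(x, fs, L = 64, nd = 32)
  expect_lt(max_rel_err(p1$values, want), 1e-10)

  expect_error(
    segment_periodogram(chn, plan_segments(64, cfg1), 3, win1, cfg1),
    "out of range"
  )
})

test_that("welch_psd averages segment periodograms in index order", {
  cfg <- welch_config()
  set.seed(11)
  ch <- signal_channel(rnorm(256), 256)
  res <- welch_psd(ch, cfg)
  expect_equal(res$n_segments_used, 7L)
  expect_equal(res$freqs, seq(0, 128, by = 4))
  expect_true(all(res$psd >= 0))

  # mean property: each bin lies within the per-segment envelope
  plan <- plan_segments(256, cfg)
  win <- make_window("hamming", "symmetric", 64)
  pgs <- sapply(0:6, function(i) {
    segment_periodogram(ch, plan, i, win, cfg)$values
  })
  expect_true(all(res$psd >= apply(pgs, 1, min) - 1e-15))
  expect_true(all(res$psd <= apply(pgs, 1, max) + 1e-15))

  # single-segment identity
  ch64 <- signal_channel(ch$samples[1:64], 256)
  one <- welch_psd(ch64, cfg)
  seg <- segment_periodogram(ch64, plan_segments(64, cfg), 0, win, cfg)
  expect_identical(one$psd, seg$values)
})

test_that("density scaling is exactly the textbook scaling divided by fs", {
  set.seed(3)
  ch <- signal_channel(rnorm(300), 256)
  for (sided in c("one", "two")) {
    d <- welch_psd(ch, welch_config(scaling = "density", sided = sided))
    e <- welch_psd(ch, welch_config(scaling = "textbook", sided = sided))
    expect_identical(d$psd, e$psd / 256)
  }
})

test_that("one-sided bins conserve the two-sided total power", {
  set.seed(5)
  ch <- signal_channel(rnorm(512), 256)
  one <- welch_psd(ch, welch_config(sided = "one"))
  two <- welch_psd(ch, welch_config(sided = "two"))
  undoubled <- one$psd
  undoubled[2:32] <- undoubled[2:32] / 2
  # bins 1..L/2-1 of the one-sided output each stand for a conjugate pair
  expect_equal(sum(undoubled) + sum(undoubled[2:32]), sum(two$psd),
               tolerance = 1e-12)
})

test_that("constant detrend removes DC only via the segment mean", {
  ch <- signal_channel(rnorm(256, mean = 50), 256)
  raw <- welch_psd(ch, welch_config(detrend = "none"))
  det <- welch_psd(ch, welch_config(detrend = "constant"))
  expect_gt(raw$psd[1], det$psd[1] * 1e3)
  expect_true(all(det$psd >= 0))
})

test_that("input validation rejects malformed channels and configs", {
  expect_error(signal_channel(numeric(0), 256), "at least one")
  expect_error(signal_channel(c(1, NA), 256), "finite")
  expect_error(signal_channel(1:4, -1), "positive")
  expect_error(welch_config(seg_len = 1), ">= 2")
  expect_error(welch_config(n_overlap = 64), "ND")
  expect_error(welch_config(seg_len = 63, n_overlap = 10), "even")
  expect_error(welch_config(window = "blackman"))
})
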