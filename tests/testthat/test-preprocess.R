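# fixtures: small epochs with known analytic content
.sine_epochs <- function(freq, rate = 1000, n = 1200, C = 4, amp = 1) {
  lay <- random_layout(C, seed = 2)
  tt <- (seq_len(n) - 1) / rate
  x <- amp * sin(2 * pi * freq * tt)
  d <- array(0, c(1, C, n))
  for (ch in seq_len(C)) d[1, ch, ] <- x
  eeg_epochs(d, rate = rate, times = -200 + (seq_len(n) - 1) * 1000 / rate,
             layout = lay)
}

test_that("resampling preserves band-limited content and sample arithmetic", {
  ep <- .sine_epochs(10, rate = 1000, n = 1200)
  expect_identical(resample(ep, 1000), ep)                  # identity
  dn <- resample(ep, 500)
  expect_equal(dim(dn$data)[3], 600L)                       # 1200 -> 600
  # analytic oracle: the 10 Hz sine itself, away from the edges
  tt <- (seq_len(600) - 1) / 500
  ref <- sin(2 * pi * 10 * tt)
  err <- abs(dn$data[1, 1, ] - ref)[26:575]
  expect_lt(max(err), 0.01)
  expect_error(resample(ep, -1), "positive")
})

test_that("band-pass meets its passband and stopband contracts", {
  pass <- .sine_epochs(10, rate = 500, n = 1200)
  out <- bandpass(pass, 0.1, 30)
  mid <- 300:900
  expect_lt(max(abs(out$data[1, 1, mid] - pass$data[1, 1, mid])), 0.05)

  stopb <- .sine_epochs(60, rate = 500, n = 1200)
  out2 <- bandpass(stopb, 0.1, 30)
  expect_lt(max(abs(out2$data[1, 1, mid])), 0.10)           # >= 90% attenuated

  zero <- .sine_epochs(10, rate = 500, n = 600, amp = 0)
  expect_equal(bandpass(zero, 0.1, 30)$data, zero$data, tolerance = 1e-12)

  expect_error(bandpass(pass, 30, 10), "low < high")
  expect_error(bandpass(pass, 0.1, 300), "low < high")
})

test_that("epoching uses a half-open grid and baseline-corrects to zero", {
  lay <- random_layout(4, seed = 3)
  n <- 700
  tms <- -300 + (seq_len(n) - 1) * 2            # 500 Hz
  d <- array(rnorm(2 * 4 * n), c(2, 4, n))
  ep <- eeg_epochs(d, 500, tms, lay)
  out <- epoch_and_baseline(ep, c(-200, 1000), c(-200, 0))
  expect_equal(dim(out$data)[3], 600L)          # 1200 ms at 500 Hz
  expect_equal(out$times[1], -200)
  bl <- out$times >= -200 & out$times < 0
  for (tr in 1:2)
    expect_equal(max(abs(rowMeans(out$data[tr, , bl]))), 0, tolerance = 1e-9)

  # constant-voltage trial becomes all zero
  dc <- array(5, c(1, 4, n))
  epc <- eeg_epochs(dc, 500, tms, lay)
  expect_equal(max(abs(epoch_and_baseline(epc, c(-200, 1000),
                                          c(-200, 0))$data)), 0)
  expect_error(epoch_and_baseline(ep, c(-200, 1000), c(-400, 0)), "inside")
})

test_that("artifact rejection removes exactly the offending trials", {
  lay <- random_layout(4, seed = 4)
  d <- array(rnorm(3 * 4 * 100, sd = 5), c(3, 4, 100))
  d[2, 3, 50] <- 150                            # one large deflection
  ep <- eeg_epochs(d, 500, seq_len(100), lay)
  res <- reject_artifacts(ep, 100)
  expect_equal(res$rejected_count, 1L)
  expect_equal(dim(res$epochs$data)[1] + res$rejected_count, 3L)
  expect_equal(res$epochs$data[1, , ], d[1, , ])
  expect_equal(reject_artifacts(ep, 1e6)$rejected_count, 0L)
  dbad <- array(1000 * rnorm(3 * 4 * 100), c(3, 4, 100))
  expect_error(reject_artifacts(eeg_epochs(dbad, 500, seq_len(100), lay), 1e-6),
               "all trials")
})

test_that("bad-channel interpolation beats nearest-neighbor on a smooth field", {
  lay <- layout_1020()
  g <- c(0.7, -0.2, 0.5)                        # planar gradient on the sphere
  field <- as.vector(lay$positions %*% g)
  V <- matrix(field, 64, 10)                    # constant in time
  erp <- eeg_erp(V, 500, seq_len(10), lay)
  bad <- "Cz"
  corrupted <- erp
  corrupted$data[lay$channel_names == bad, ] <- 999
  fixed <- interpolate_bad_channels(corrupted, bad)
  err <- abs(fixed$data[lay$channel_names == bad, 1] -
               field[lay$channel_names == bad])
  # nearest-neighbor oracle
  i <- which(lay$channel_names == bad)
  dists <- sqrt(rowSums(sweep(lay$positions, 2, lay$positions[i, ])^2))
  dists[i] <- Inf
  nn_err <- abs(field[which.min(dists)] - field[i])
  expect_lt(err, nn_err + 1e-12)

  expect_identical(interpolate_bad_channels(erp, character(0)), erp)
  const <- eeg_erp(matrix(3, 64, 5), 500, 1:5, lay)
  fc <- interpolate_bad_channels(const, "Pz")
  expect_equal(fc$data[lay$channel_names == "Pz", ], rep(3, 5))
  expect_error(interpolate_bad_channels(erp, "nope"), "unknown channel")
})

test_that("average reference zeroes channel means and is idempotent", {
  lay <- random_layout(6, seed = 5)
  erp <- eeg_erp(matrix(rnorm(6 * 50), 6), 500, seq_len(50), lay)
  ar <- average_reference(erp)
  expect_equal(max(abs(colMeans(ar$data))), 0, tolerance = 1e-9)
  expect_equal(average_reference(ar)$data, ar$data, tolerance = 1e-12)
})

test_that("trial averaging and reference commute, and cancellation works", {
  lay <- random_layout(5, seed = 6)
  d <- array(rnorm(4 * 5 * 30), c(4, 5, 30))
  ep <- eeg_epochs(d, 500, seq_len(30), lay)
  a <- average_erp(average_reference(ep))
  b <- average_reference(average_erp(ep))
  expect_equal(a$data, b$data, tolerance = 1e-9)
  expect_equal(a$n_trials_averaged, 4L)

  # v and -v cancel
  d2 <- d[1:2, , , drop = FALSE]; d2[2, , ] <- -d2[1, , ]
  z <- average_erp(eeg_epochs(d2, 500, seq_len(30), lay))
  expect_equal(max(abs(z$data)), 0, tolerance = 1e-12)

  # single trial averages to itself
  one <- average_erp(eeg_epochs(d[1, , , drop = FALSE], 500, seq_len(30), lay))
  expect_equal(one$data[, ], d[1, , ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("noise-free trials sharing one label sequence average to any trial", {
  m <- make_prototype_maps(layout_1020(), 3, seed = 31)
  sim <- simulate_epoch(m, 100, snr = Inf, n_trials = 5, seed = 32)
  erp <- average_erp(sim$epochs)
  expect_equal(erp$data[, ], sim$epochs$data[3, , ], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("midline waveform extraction is exact and differences vanish for equal ERPs", {
  lay <- layout_1020()
  erp <- eeg_erp(matrix(rnorm(64 * 20), 64), 500, seq_len(20), lay)
  w <- midline_waveforms(erp)
  expect_equal(ncol(w), 6L)                     # time + 5 electrodes
  expect_identical(w$Cz, unname(erp$data[lay$channel_names == "Cz", ]))
  d0 <- midline_waveforms(erp, erp)
  expect_equal(max(abs(as.matrix(d0[, -1]))), 0)
  expect_error(midline_waveforms(erp, electrodes = "XX"), "unknown channel")
})
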