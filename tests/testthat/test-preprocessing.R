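make_flat_recording <- function(values, n = 1000, rate = 2000) {
  sigs <- lapply(values, function(v) rep(v, n))
  make_recording(sigs, rate = rate)
}

test_that("mastoid re-referencing subtracts the mastoid average", {
  # zero mastoids leave the data unchanged
  rec <- make_recording(list(Cz = sin(1:500), TP9 = rep(0, 500),
                             TP10 = rep(0, 500)))
  expect_equal(rereference(rec)$data["Cz", ], rec$data["Cz", ])

  # a common offset on all channels is rejected
  rec0 <- make_recording(list(Cz = sin(1:500), TP9 = cos(1:500),
                              TP10 = sin(1:500) * 0.5))
  recc <- rec0
  recc$data <- recc$data + 7
  expect_equal(rereference(recc)$data["Cz", ],
               rereference(rec0)$data["Cz", ])

  # three-channel toy against hand arithmetic
  rec3 <- make_recording(list(Cz = c(4, 8), TP9 = c(2, 2), TP10 = c(0, 4)))
  out <- rereference(rec3)
  expect_equal(unname(out$data["Cz", ]), c(4 - 1, 8 - 3))
  expect_equal(out$reference_label, "TP9/TP10")
  expect_error(rereference(make_recording(list(Cz = 1:5))), "TP9")
})

test_that("the filter chain attenuates stop bands and passes the band", {
  rate <- 2000
  t <- (0:(8 * rate - 1)) / rate
  mid <- (2 * rate):(6 * rate)   # avoid edges when measuring amplitude
  att_db <- function(f) {
    rec <- make_recording(list(Cz = 10 * sin(2 * pi * f * t)), rate = rate)
    out <- filter_chain(rec)
    20 * log10(max(abs(out$data["Cz", mid])) / 10)
  }
  expect_lt(att_db(50), -30)    # notch: residual of 10 uV input < 0.32 uV
  expect_lt(att_db(2), -24)     # below the high-pass edge
  expect_gt(att_db(30), -1)     # mid-band essentially untouched
  # zero in, zero out
  recz <- make_recording(list(Cz = rep(0, 4000)))
  expect_equal(max(abs(filter_chain(recz)$data)), 0)
})

test_that("ocular regression recovers a planted propagation coefficient", {
  set.seed(21)
  n <- 40000
  rate <- 2000
  clean <- pink_noise(n, rate)
  veog <- 60 * pink_noise(n, rate)
  rec <- make_recording(list(Cz = clean + 0.3 * veog,
                             TP9 = rep(0, n), TP10 = rep(0, n),
                             `VEOG+` = veog, `VEOG-` = rep(0, n),
                             `HEOG+` = rep(0, n), `HEOG-` = rep(0, n)),
                        rate = rate)
  out <- suppressWarnings(ocular_correct(rec))
  b <- attr(out, "eog_coefficients")
  expect_lt(abs(b["Cz", "bV"] - 0.3), 0.01)
  expect_lt(sd(out$data["Cz", ] - clean), 0.05 * sd(clean))
  # EOG channels are not modified
  expect_equal(out$data["VEOG+", ], rec$data["VEOG+", ])
})

test_that("zero EOG leaves the recording unchanged with a warning", {
  rec <- make_recording(list(Cz = sin(1:2000), TP9 = rep(0, 2000),
                             TP10 = rep(0, 2000),
                             `VEOG+` = rep(0, 2000), `VEOG-` = rep(0, 2000),
                             `HEOG+` = rep(0, 2000), `HEOG-` = rep(0, 2000)))
  expect_warning(out <- ocular_correct(rec), "degenerate")
  expect_equal(out$data, rec$data)
})

test_that("blink artifacts are suppressed by at least 90% at Cz", {
  set.seed(33)
  n <- 60000
  rate <- 2000
  blink <- numeric(n)
  at <- seq(4000, n - 4000, by = 9000)
  pulse <- 150 * 0.5 * (1 - cos(2 * pi * seq_len(500) / 501))
  for (a in at) blink[a:(a + 499)] <- blink[a:(a + 499)] + pulse
  clean <- 0.5 * pink_noise(n, rate)
  rec <- make_recording(list(Cz = clean + 0.25 * blink,
                             TP9 = rep(0, n), TP10 = rep(0, n),
                             `VEOG+` = blink, `VEOG-` = rep(0, n),
                             `HEOG+` = rep(0, n), `HEOG-` = rep(0, n)),
                        rate = rate)
  out <- suppressWarnings(ocular_correct(rec))
  pre_amp <- max(abs(rec$data["Cz", ] - clean))
  post_amp <- max(abs(out$data["Cz", ] - clean))
  expect_lt(post_amp, 0.1 * pre_amp)
})

test_that("segmentation yields one epoch per in-bounds marker", {
  rate <- 2000
  n <- 135
  onsets <- seq(1000, by = 3000, length.out = n)
  mk <- data.frame(sample = onsets, label = "S1")
  rec <- make_recording(list(Cz = rnorm(max(onsets) + 2000)), rate = rate,
                        markers = mk)
  ep <- segment(rec, "S1")
  expect_equal(dim(ep$epochs)[1], 135)
  # window arithmetic: (100 + 200) ms at 2000 Hz plus the onset sample
  expect_equal(dim(ep$epochs)[3], 601)
  expect_equal(ep$times[1], -100)
  expect_equal(ep$times[601], 200)
  expect_equal(ep$times[round(0.1 * rate) + 1], 0)

  # marker too close to the recording start is dropped with a reason
  mk2 <- rbind(data.frame(sample = 50, label = "S1"), mk)
  rec2 <- make_recording(list(Cz = rnorm(max(onsets) + 2000)), rate = rate,
                         markers = mk2)
  ep2 <- segment(rec2, "S1")
  expect_equal(dim(ep2$epochs)[1], 135)
  expect_equal(attr(ep2, "dropped_markers")$sample, 50)
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  rate <- 2000
  mk <- data.frame(sample = 500, label = "S1")
  # constant epoch collapses to zero
  rec <- make_recording(list(Cz = rep(5, 1500)), rate = rate, markers = mk)
  ep <- baseline_correct(segment(rec, "S1"))
  expect_equal(max(abs(ep$epochs)), 0)

  # step at onset: 2 before, 6 after -> 0 before, 4 after
  x <- c(rep(2, 499), rep(6, 1001))
  rec2 <- make_recording(list(Cz = x), rate = rate, markers = mk)
  ep2 <- baseline_correct(segment(rec2, "S1"))
  expect_equal(unname(ep2$epochs[1, 1, 1]), 0)
  expect_equal(unname(ep2$epochs[1, 1, 601]), 4)
  # onset sample belongs to the post-stimulus side
  expect_equal(unname(ep2$epochs[1, 1, 201]), 4)

  # idempotence
  ep3 <- baseline_correct(ep2)
  expect_equal(ep3$epochs, ep2$epochs)
})

test_that("artifact rejection applies amplitude and gradient rules", {
  rate <- 2000
  mk <- data.frame(sample = 500, label = "S1")
  base <- rep(0, 1500)

  x <- base
  x[700] <- 51
  rec <- make_recording(list(Cz = x), rate = rate, markers = mk)
  ep <- reject_artifacts(segment(rec, "S1"))
  expect_true(ep$rejected$rejected[1])
  expect_match(ep$rejected$reason[1], "amplitude")

  # one-sample 30 uV step at 2000 Hz = 60 uV/ms gradient, amplitude ok
  x <- base
  x[700:1500] <- 30
  rec2 <- make_recording(list(Cz = x), rate = rate, markers = mk)
  ep2 <- reject_artifacts(segment(rec2, "S1"))
  expect_true(ep2$rejected$rejected[1])
  expect_match(ep2$rejected$reason[1], "gradient")

  rec3 <- make_recording(list(Cz = base), rate = rate, markers = mk)
  ep3 <- reject_artifacts(segment(rec3, "S1"))
  expect_false(any(ep3$rejected$rejected))
})

test_that("averaging uses retained epochs only", {
  rate <- 2000
  mk <- data.frame(sample = c(500, 3000), label = "S1")
  x <- rep(0, 4000)
  x[500 + 0:400] <- 1
  x[3000 + 0:400] <- 3
  rec <- make_recording(list(Cz = x), rate = rate, markers = mk)
  ep <- segment(rec, "S1")
  ev <- average_epochs(ep)
  expect_equal(unname(ev$data[1, 300]), 2)
  expect_equal(ev$n_epochs_retained, 2)

  ep$rejected$rejected[2] <- TRUE
  ev1 <- average_epochs(ep)
  expect_equal(unname(ev1$data[1, 300]), 1)
  expect_equal(ev1$n_epochs_retained, 1)

  ep$rejected$rejected[] <- TRUE
  expect_error(average_epochs(ep), "no epochs")
})

test_that("averaging converges to the planted waveform as 1/sqrt(n)", {
  set.seed(55)
  rate <- 2000
  n_ep <- 100
  onsets <- seq(600, by = 800, length.out = n_ep)
  wave <- numeric(601)
  wave[250:350] <- sin(seq(0, pi, length.out = 101))
  x <- rnorm(max(onsets) + 1000, sd = 1)
  for (o in onsets) x[o + (-200:400)] <- x[o + (-200:400)] + wave
  rec <- make_recording(list(Cz = x), rate = rate,
                        markers = data.frame(sample = onsets, label = "S1"))
  ev <- average_epochs(segment(rec, "S1"))
  resid <- ev$data[1, ] - wave
  expect_lt(sd(resid), 3 / sqrt(n_ep))
})

test_that("the linear stages are homogeneous of degree one", {
  set.seed(66)
  n <- 8000
  rec <- make_recording(list(Cz = pink_noise(n, 2000),
                             TP9 = 0.3 * pink_noise(n, 2000),
                             TP10 = 0.3 * pink_noise(n, 2000)),
                        rate = 2000,
                        markers = data.frame(sample = c(2000, 5000),
                                             label = "S1"))
  chain <- function(r) {
    r <- rereference(r)
    r <- filter_chain(r)
    baseline_correct(segment(r, "S1"))$epochs
  }
  scaled <- rec
  scaled$data <- 3.5 * scaled$data
  expect_equal(chain(scaled), 3.5 * chain(rec), tolerance = 1e-8)
})
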