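test_that("resampling preserves in-band tones and suppresses aliases", {
  n <- 50000
  t5k <- (0:(n - 1)) / 5000
  tone10 <- new_recording(matrix(sin(2 * pi * 10 * t5k), 1), 5000, "A")
  out <- resample_recording(tone10, 500)
  expect_equal(out$rate, 500)
  mid <- 1000:4000
  # sampled peak of a 10 Hz sine at 500 Hz is 0.9980; require gain within 1%
  expect_gt(max(abs(out$data[1, mid])), 0.998 * 0.99)
  expect_lt(max(abs(out$data[1, mid])), 1.01)

  tone400 <- new_recording(matrix(sin(2 * pi * 400 * t5k), 1), 5000, "A")
  out4 <- resample_recording(tone400, 500)
  alias <- band_power(out4$data[1, mid], 500, 100)
  ref <- band_power(out$data[1, mid], 500, 10)
  expect_lt(10 * log10(alias / ref), -40)
})

test_that("resampling remaps events to the nearest new sample and validates rates", {
  rec <- make_test_recording(n_channels = 2, rate = 5000, n_trials = 1,
                             trial_len = 2, lead = 1)
  rec$events$sample <- 5001L  # t = 1 s
  out <- resample_recording(rec, 500)
  expect_equal(out$events$sample, 501)
  expect_error(resample_recording(out, 500), "below")
  expect_error(resample_recording(out, 499), "divide")
})

test_that("band-pass removes DC, keeps 6 Hz, and kills out-of-band tones", {
  n <- 20000
  tt <- (0:(n - 1)) / 500
  const <- new_recording(matrix(100, 1, n), 500, "A")
  out <- bandpass_recording(const, 0.1, 100)
  trim <- 2000:(n - 2000)
  expect_lt(mean(abs(out$data[1, trim])), 1)

  s6 <- new_recording(matrix(sin(2 * pi * 6 * tt), 1), 500, "A")
  out6 <- bandpass_recording(s6, 0.1, 100)
  expect_gt(max(abs(out6$data[1, trim])), 0.95)

  s200 <- new_recording(matrix(sin(2 * pi * 200 * tt), 1), 500, "A")
  out200 <- bandpass_recording(s200, 0.1, 100)
  p_in <- band_power(s200$data[1, trim], 500, 200)
  p_out <- band_power(out200$data[1, trim], 500, 200)
  expect_lt(10 * log10(p_out / p_in), -40)

  expect_error(bandpass_recording(s6, 0, 100))
  expect_error(bandpass_recording(s6, 100, 10))
  expect_error(bandpass_recording(s6, 0.1, 300), "rate/2")
})

test_that("line-noise regression removes 60 Hz and spares neighbors", {
  set.seed(21)
  n <- 20000
  tt <- (0:(n - 1)) / 500
  s6 <- sqrt(2) * sin(2 * pi * 6 * tt)       # unit variance
  s60 <- sqrt(2) * sin(2 * pi * 60 * tt + 1) # unit variance
  rec <- new_recording(matrix(s6 + s60, 1), 500, "A")
  out <- remove_line_noise(rec, 60)
  expect_lt(10 * log10(band_power(out$data[1, ], 500, 60) /
                         band_power(rec$data[1, ], 500, 60)), -20)
  p6 <- band_power(out$data[1, ], 500, 6) / band_power(rec$data[1, ], 500, 6)
  expect_lt(abs(p6 - 1), 0.05)

  clean <- new_recording(matrix(rnorm(n), 1), 500, "A")
  cl_out <- remove_line_noise(clean, 60)
  expect_lt(abs(sd(cl_out$data[1, ]) / sd(clean$data[1, ]) - 1), 0.02)

  pure <- new_recording(matrix(s60, 1), 500, "A")
  p_out <- remove_line_noise(pure, 60)
  expect_lt(sd(p_out$data[1, ]) / sd(pure$data[1, ]), 0.10)
})

test_that("epoch extraction counts, truncation, and disjoint spans behave", {
  set.seed(22)
  rec <- make_test_recording(n_channels = 3, rate = 500, n_trials = 4,
                             trial_len = 16, gap = 1, lead = 1)
  es <- extract_epochs(rec, 1, 16)
  expect_equal(dim(es$epochs), c(64, 3, 500))
  expect_equal(sum(es$flags == "retained"), 64)
  expect_equal(as.vector(table(es$meta$condition)), c(32, 32))

  # cut the recording at 10.5 s into the last trial
  last_onset <- max(rec$events$sample)
  rec2 <- rec
  rec2$data <- rec2$data[, seq_len(last_onset + 10.5 * 500), drop = FALSE]
  expect_warning(es2 <- extract_epochs(rec2, 1, 16), "truncated")
  expect_equal(sum(es2$flags == "absent"), 6)
  expect_equal(sum(es2$flags == "retained" & es2$meta$trial == 4), 10)
})

test_that("bad channels are detected by the amplitude-fraction rule and replaced", {
  set.seed(23)
  mont <- default_montage()
  ne <- 20; ns <- 250
  eps <- array(rnorm(ne * 32 * ns, sd = 20), c(ne, 32, ns))
  bad_idx <- match("T8", mont$channels)
  hot <- sample(ne, 12)  # 60% of epochs
  eps[hot, bad_idx, ] <- 600 * sign(sin(2 * pi * 8 * (1:ns) / 250))
  es <- make_epochset(eps, rep(c("joint", "parallel"), 10),
                      rate = 250, channel_names = mont$channels)
  out <- interpolate_bad_channels(es, mont, amp_thresh = 500,
                                  frac_thresh = 0.5)
  expect_identical(out$interpolated, "T8")
  expect_lt(max(abs(out$epochs[, bad_idx, ])), 500)
  # other channels untouched
  expect_equal(out$epochs[, -bad_idx, ], eps[, -bad_idx, ])

  # 40% of epochs exceeding: below the fraction threshold, not interpolated
  eps2 <- array(rnorm(ne * 32 * ns, sd = 20), c(ne, 32, ns))
  eps2[sample(ne, 8), bad_idx, ] <- 600
  es2 <- make_epochset(eps2, rep(c("joint", "parallel"), 10),
                       rate = 250, channel_names = mont$channels)
  out2 <- interpolate_bad_channels(es2, mont)
  expect_length(out2$interpolated, 0)
  expect_equal(out2$epochs, eps2)
})

test_that("epoch rejection triggers on windowed SD above threshold only", {
  set.seed(24)
  ne <- 10; nc <- 4; ns <- 500
  eps <- array(rnorm(ne * nc * ns, sd = 10), c(ne, nc, ns))
  # epoch 3: one channel gets a 200-ms burst of SD 120
  eps[3, 2, 151:250] <- rnorm(100, sd = 120)
  # epoch 7: strongest window SD just below threshold on every channel
  eps[7, , ] <- rnorm(nc * ns, sd = 70)
  es <- make_epochset(eps, rep("joint", ne))
  out <- reject_epochs(es, sd_thresh = 80, win_len = 0.2, step = 0.1)
  expect_equal(which(out$flags == "rejected"), 3)
  expect_equal(out$flags[7], "retained")
})

test_that("average re-reference zeroes the spatial mean, is idempotent, keeps bipolar differences", {
  set.seed(25)
  eps <- array(rnorm(8 * 5 * 100, sd = 30), c(8, 5, 100))
  es <- make_epochset(eps, rep("joint", 8), rate = 100)
  out <- rereference_average(es)
  mu <- apply(out$epochs, c(1, 3), mean)
  expect_lt(max(abs(mu)), 1e-9)
  out2 <- rereference_average(out)
  expect_equal(out2$epochs, out$epochs, tolerance = 1e-12)
  expect_equal(out$epochs[, 1, ] - out$epochs[, 4, ],
               eps[, 1, ] - eps[, 4, ], tolerance = 1e-10)
})

test_that("GFP selection matches the exhaustive rank oracle and flags exclusions", {
  set.seed(26)
  # 20 retained epochs, one condition, distinct GFPs
  eps <- array(rnorm(20 * 6 * 100, sd = runif(20 * 6 * 100, 5, 50)),
               c(20, 6, 100))
  es <- make_epochset(eps, rep("joint", 20), rate = 100)
  out <- select_epochs_gfp(es, n_select = 10)
  g <- epoch_gfp(es)
  expect_equal(which(out$flags == "selected"), oracle_gfp_select(g, 10))
  expect_false(out$excluded)
  # selected GFPs form a contiguous rank band around the median
  sel_ranks <- sort(rank(abs(g - median(g)))[out$flags == "selected"])
  expect_equal(sel_ranks, as.numeric(1:10))

  # exactly 10 retained: forced selection
  es10 <- make_epochset(eps[1:10, , , drop = FALSE], rep("joint", 10),
                        rate = 100)
  out10 <- select_epochs_gfp(es10, 10)
  expect_equal(sum(out10$flags == "selected"), 10)

  # 9 retained in one condition: exclusion flag
  es9 <- make_epochset(eps[1:19, , , drop = FALSE],
                       rep(c("joint", "parallel"), length.out = 19),
                       rate = 100)
  es9$flags[19] <- "rejected"  # joint drops to 9
  out9 <- select_epochs_gfp(es9, 10)
  expect_true(out9$excluded)
})

test_that("total GFP equals the summed spatial SD definition", {
  set.seed(27)
  eps <- array(rnorm(3 * 4 * 50), c(3, 4, 50))
  es <- make_epochset(eps, rep("joint", 3), rate = 50)
  g <- epoch_gfp(es)
  manual <- sapply(1:3, function(e) sum(apply(eps[e, , ], 2, sd)))
  expect_equal(g, manual, tolerance = 1e-10)
})
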