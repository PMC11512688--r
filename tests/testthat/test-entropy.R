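test_that("coarse-graining is block averaging", {
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  x <- rnorm(100)
  expect_equal(coarse_grain(x, 1), x)
  expect_equal(mean(coarse_grain(x, 5)), mean(x))  # 100 divisible by 5
  expect_length(coarse_grain(x, 101), 0)
  expect_length(coarse_grain(x, 33), 3)
  expect_error(coarse_grain(x, 0))
})

test_that("pooled sample entropy matches the brute-force oracle exactly", {
  set.seed(31)
  x <- c(1, 2, 3, 2, 1, 2, 3, 2, 1, 2)
  got <- sample_entropy_segments(x, m = 2, tolerance = 0.5)
  exp <- oracle_sampen(x, 2, 0.5)
  expect_equal(got$A, exp$A)
  expect_equal(got$B, exp$B)
  expect_equal(got$entropy, exp$entropy)

  for (i in 1:25) {
    nseg <- sample(1:4, 1)
    segs <- lapply(seq_len(nseg),
                   function(j) round(rnorm(sample(4:25, 1)), 1))
    m <- sample(1:3, 1)
    tol <- runif(1, 0.05, 1.2)
    got <- sample_entropy_segments(segs, m, tol)
    exp <- oracle_sampen(segs, m, tol)
    expect_equal(got$A, exp$A, info = paste("A, case", i))
    expect_equal(got$B, exp$B, info = paste("B, case", i))
  }
})

test_that("entropy is zero for constant signals and undefined counts are flagged", {
  got <- sample_entropy_segments(list(rep(2, 20), rep(2, 15)), 2, 0.1)
  expect_equal(got$entropy, 0)
  expect_equal(got$A, got$B)
  expect_true(got$valid)

  # strictly monotone ramp with tiny tolerance: no B matches at all
  none <- sample_entropy_segments(seq(0, 10, length.out = 20), 2, 1e-6)
  expect_false(none$valid)
  expect_true(is.na(none$entropy))
})

test_that("segment order does not change pooled counts; tolerance is monotone", {
  set.seed(32)
  segs <- lapply(1:4, function(i) rnorm(20))
  a <- sample_entropy_segments(segs, 2, 0.4)
  b <- sample_entropy_segments(rev(segs), 2, 0.4)
  expect_equal(a[c("A", "B", "entropy")], b[c("A", "B", "entropy")])

  tols <- c(0.1, 0.3, 0.6, 1, 2)
  ents <- sapply(tols, function(tl) {
    r <- sample_entropy_segments(segs, 2, tl)
    if (r$valid) r$entropy else Inf
  })
  expect_true(all(diff(ents[is.finite(ents)]) <= 1e-12))
  expect_true(all(sapply(tols, function(tl)
    sample_entropy_segments(segs, 2, tl)$A <=
      sample_entropy_segments(segs, 2, tl)$B)))
})

test_that("splitting a segment removes exactly the boundary-crossing templates", {
  set.seed(33)
  x <- rnorm(60)
  whole <- sample_entropy_segments(x, 2, 0.5)
  halves <- sample_entropy_segments(list(x[1:30], x[31:60]), 2, 0.5)
  ow <- oracle_sampen(x, 2, 0.5)
  oh <- oracle_sampen(list(x[1:30], x[31:60]), 2, 0.5)
  expect_equal(whole[c("A", "B")], ow[c("A", "B")])
  expect_equal(halves[c("A", "B")], oh[c("A", "B")])
  # fewer templates -> counts can only shrink
  expect_lte(halves$A, whole$A)
  expect_lte(halves$B, whole$B)
})

test_that("per-scale tolerance keeps white-noise entropy flat where fixed tolerance decays", {
  set.seed(34)
  segs <- replicate(50, rnorm(200), simplify = FALSE)
  per <- mse_curve(segs, scales = 1:8)
  fix <- mse_curve(segs, scales = 1:8, tolerance_mode = "fixed")
  expect_true(all(per$valid))
  expect_lt(max(abs(per$entropy - per$entropy[1])), 0.15)
  expect_gt(max(abs(fix$entropy - fix$entropy[1])), 0.2)
  # entropy decays with scale under a fixed tolerance (matches widen)
  expect_true(all(diff(fix$entropy) < 0))
})

test_that("mse_curve pools bookkeeping as stated and flags degenerate scales", {
  set.seed(35)
  segs <- replicate(10, rnorm(500), simplify = FALSE)
  cur <- mse_curve(segs, scales = c(1, 4))
  expect_equal(cur$n_points, c(5000, 1250))
  # constant signal: SD zero at every scale -> invalid
  flat <- mse_curve(list(rep(1, 50)), scales = c(1, 2))
  expect_false(any(flat$valid))
  # tolerance equals r * pooled coarse-grained SD
  cg <- unlist(lapply(segs, coarse_grain, scale = 4))
  expect_equal(cur$tolerance[2], 0.5 * sd(cg))
})

test_that("band-to-scale mapping follows both conventions", {
  expect_equal(scales_for_band(3, 8, 500), 63:166)
  expect_equal(scales_for_band(3, 8, 500, mapping = "halfcycle"), 32:83)
  expect_equal(scales_for_band(5, 5, 500), 100)
  expect_error(scales_for_band(300, 400, 500), "Nyquist")
  expect_error(scales_for_band(8, 3, 500))
  expect_error(scales_for_band(3.7, 3.7, 500), "no integer scale")
})

test_that("band/ROI aggregation averages valid cells within the partition", {
  mont <- default_montage()
  # hand-built: two channels of one ROI, two scales
  df <- data.frame(
    condition = "joint",
    channel = rep(c("Fp1", "F3"), each = 2),
    scale = rep(c(63, 64), 2),
    entropy = c(1.0, 1.2, 0.8, NA),
    A = 1, B = 1, n_points = 10,
    valid = c(TRUE, TRUE, TRUE, FALSE)
  )
  out <- aggregate_band_roi(df, mont, c(63, 64))
  lf <- out[out$roi == "LF", ]
  expect_equal(lf$entropy, mean(c(1.0, 1.2, 0.8)))
  expect_equal(lf$n_cells, 3)
  expect_true(lf$valid)

  # all channels in an ROI equal -> ROI value equals the common value
  df2 <- data.frame(condition = "joint",
                    channel = c("FC1", "C3"), scale = 63,
                    entropy = 0.77, A = 1, B = 1, n_points = 10, valid = TRUE)
  out2 <- aggregate_band_roi(df2, mont, 63)
  expect_equal(out2$entropy[out2$roi == "LC"], 0.77)

  # all cells invalid -> ROI invalid, not zero-filled
  df3 <- df2
  df3$valid <- FALSE
  out3 <- aggregate_band_roi(df3, mont, 63)
  expect_false(out3$valid[1])
  expect_true(is.na(out3$entropy[1]))

  expect_error(aggregate_band_roi(df, mont, integer(0)), "nonempty")
})
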