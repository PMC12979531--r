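test_that("HSV conversion round-trips and exposes the value channel", {
  set.seed(60)
  arr <- array(runif(32 * 32 * 3), c(32, 32, 3))
  hsv <- rgb_to_hsv_array(arr)
  expect_equal(hsv[, , 3], pmax(arr[, , 1], arr[, , 2], arr[, , 3]))
  back <- hsv_to_rgb_array(hsv)
  expect_equal(back, arr, tolerance = 1e-12)
})

test_that("target luminance is the masked pixel mean over all frames", {
  f1 <- matrix(0.2, 16, 16); f1[5:12, 5:12] <- 0.8
  mask <- matrix(FALSE, 16, 16); mask[5:12, 5:12] <- TRUE
  st <- gray_stack(list(f1), list(mask))
  tl <- compute_target_luminance(st)
  expect_equal(unname(tl), c(0.8, 0.2))
  # two frames with equal pixel counts: arithmetic mean of the fg means
  f2 <- matrix(0.2, 16, 16); f2[5:12, 5:12] <- 0.6
  f3 <- matrix(0.2, 16, 16); f3[5:12, 5:12] <- 0.4
  tl2 <- compute_target_luminance(gray_stack(list(f2, f3),
                                             list(mask, mask)))
  expect_equal(unname(tl2["fg_mean"]), 0.5)
  # naive pixel-loop oracle on a random stack
  set.seed(61)
  fr <- matrix(runif(256), 16, 16)
  mk <- matrix(runif(256) > 0.5, 16, 16)
  tl3 <- compute_target_luminance(gray_stack(list(fr), list(mk)))
  fg <- bg <- c()
  for (i in 1:16) for (j in 1:16) {
    if (mk[i, j]) fg <- c(fg, fr[i, j]) else bg <- c(bg, fr[i, j])
  }
  expect_equal(unname(tl3), c(mean(fg), mean(bg)), tolerance = 1e-12)
  expect_error(compute_target_luminance(
    gray_stack(list(fr), list(matrix(TRUE, 16, 16)))), "empty")
})

test_that("luminance matching hits targets exactly and is idempotent", {
  set.seed(62)
  fr <- matrix(runif(256, 0.2, 0.6), 16, 16)
  mk <- matrix(FALSE, 16, 16); mk[3:10, 3:10] <- TRUE
  st <- gray_stack(list(fr), list(mk))
  out <- luminance_match(st, 0.5, 0.4)
  v <- v_channel(out$frames[[1]])
  expect_equal(mean(v[mk]), 0.5, tolerance = 1e-12)
  expect_equal(mean(v[!mk]), 0.4, tolerance = 1e-12)
  # idempotent
  again <- luminance_match(out, 0.5, 0.4)
  expect_equal(again$frames[[1]], out$frames[[1]], tolerance = 1e-12)
  # clipping case: saturated pixels keep the realized mean at or below target
  fr2 <- matrix(0.95, 16, 16); fr2[1:2, ] <- 1.0
  out2 <- luminance_match(gray_stack(list(fr2), list(mk)), 0.99, 0.99)
  v2 <- v_channel(out2$frames[[1]])
  expect_lte(mean(v2[mk]), 0.99 + 1e-12)
  expect_true(all(v2 <= 1))
  expect_error(luminance_match(st, 1.2, 0.5), "\\[0, 1\\]")
})

test_that("spatial-frequency matching equalizes radial profiles, keeps phase and DC", {
  set.seed(63)
  mk <- matrix(FALSE, 32, 32)
  f1 <- matrix(runif(1024), 32, 32)
  f2 <- matrix(runif(1024), 32, 32)
  st1 <- gray_stack(list(f1), list(mk)); st2 <- gray_stack(list(f2), list(mk))
  # a single frame matched against itself is unchanged
  solo <- spatial_frequency_match(st1)
  expect_equal(solo$frames[[1]], st1$frames[[1]], tolerance = 1e-10)
  matched <- spatial_frequency_match(list(st1, st2))
  bins <- popspike:::.radial_bins(32, 32)
  prof <- lapply(matched, function(s) {
    popspike:::.radial_profile(Mod(fft(v_channel(s$frames[[1]]))), bins,
                               max(bins))
  })
  rel <- abs(prof[[1]] - prof[[2]]) / pmax(abs(prof[[1]]), 1e-15)
  expect_lt(max(rel[-1], na.rm = TRUE), 1e-6)
  # phases preserved wherever amplitude is non-negligible
  for (k in 1:2) {
    before <- fft(list(f1, f2)[[k]])
    after <- fft(v_channel(matched[[k]]$frames[[1]]))
    big <- Mod(before) > 1e-8
    dphi <- Arg(after)[big] - Arg(before)[big]
    expect_lt(max(abs(Arg(exp(1i * dphi)))), 1e-8)
  }
  # DC (frame mean) conserved per frame
  expect_equal(mean(v_channel(matched[[1]]$frames[[1]])), mean(f1),
               tolerance = 1e-10)
  expect_equal(mean(v_channel(matched[[2]]$frames[[1]])), mean(f2),
               tolerance = 1e-10)
})

test_that("non-square frames use normalized-radius annuli", {
  set.seed(64)
  f1 <- matrix(runif(24 * 40), 24, 40)
  f2 <- matrix(runif(24 * 40), 24, 40)
  mk <- matrix(FALSE, 24, 40)
  matched <- spatial_frequency_match(list(gray_stack(list(f1), list(mk)),
                                          gray_stack(list(f2), list(mk))))
  bins <- popspike:::.radial_bins(24, 40)
  prof <- lapply(matched, function(s)
    popspike:::.radial_profile(Mod(fft(v_channel(s$frames[[1]]))), bins,
                               max(bins)))
  rel <- abs(prof[[1]] - prof[[2]]) / pmax(abs(prof[[1]]), 1e-15)
  expect_lt(max(rel[-1], na.rm = TRUE), 1e-6)
})

test_that("frame dissimilarity is a bounded, symmetric correlation series", {
  set.seed(65)
  f <- matrix(runif(10000), 100, 100)
  st <- gray_stack(list(f))
  expect_equal(frame_dissimilarity(st, st), 1)
  inv <- gray_stack(list(1 - f))
  expect_equal(frame_dissimilarity(st, inv), -1)
  # independent noise frames at 10^4 pixels decorrelate
  g <- gray_stack(list(matrix(runif(10000), 100, 100)))
  r <- frame_dissimilarity(st, g)
  expect_lt(abs(r), 0.05)
  expect_equal(r, frame_dissimilarity(g, st))
  expect_gte(r, -1); expect_lte(r, 1)
  # zero-variance frame: missing value
  flat <- gray_stack(list(matrix(0.5, 100, 100)))
  expect_true(is.na(frame_dissimilarity(st, flat)))
  expect_error(frame_dissimilarity(st, gray_stack(list(f, f))),
               "frame count")
})

test_that("PNG round-trip preserves frames to 8-bit precision", {
  fp <- generate_frame_pair(height = 16, width = 16, seed = 66)
  st <- frame_stack(list(fp$frame_a), list(fp$fg_mask))
  dir <- tempfile("stack")
  paths <- write_frame_stack(st, dir)
  back <- read_frame_stack(paths)
  expect_equal(back$frames[[1]], st$frames[[1]], tolerance = 1 / 255)
})
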