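test_that("sliding windows follow the stated convention", {
  # 4000 ms trial: floor((4000 - 200) / 40) + 1 = 96 windows
  expect_length(sliding_bin(rep(1, 20)), 96)
  # constant rate stays constant
  expect_equal(sliding_bin(rep(3, 20)), rep(3, 96))
  # duration shorter than the window: empty
  expect_length(sliding_bin(numeric(0)), 0)
  # brute-force per-window overlap oracle
  set.seed(50)
  counts <- rpois(15, 4)
  got <- sliding_bin(counts)
  t_axis <- (seq_along(got) - 1) * 40
  oracle <- vapply(t_axis, function(t0) {
    s <- 0
    for (j in seq_along(counts)) {
      b0 <- (j - 1) * 200
      ov <- max(0, min(b0 + 200, t0 + 200) - max(b0, t0))
      s <- s + ov / 200 * counts[j]
    }
    s
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("condition averaging and Gaussian smoothing behave like the kernel", {
  trials <- matrix(rep(c(1, 2, 3, 4), each = 3), nrow = 3, byrow = FALSE)
  # identical trials: average equals any single trial (before smoothing a
  # constant check); constant series unchanged by a normalized kernel
  expect_equal(condition_average_and_smooth(matrix(5, 4, 30)), rep(5, 30))
  # impulse response is the kernel shape, peaked at the impulse
  x <- numeric(101); x[51] <- 1
  sm <- condition_average_and_smooth(matrix(x, 1), kernel_ms = 200,
                                     step_ms = 40)
  expect_equal(which.max(sm), 51)
  k <- popspike:::.gauss_kernel(200, 40, "sd")
  half <- (length(k) - 1) / 2
  expect_equal(sm[(51 - half):(51 + half)], k, tolerance = 1e-10)
  # fwhm reading gives a narrower kernel than the sd reading
  sm_fwhm <- condition_average_and_smooth(matrix(x, 1), kernel_ms = 200,
                                          step_ms = 40, kernel_kind = "fwhm")
  expect_gt(max(sm_fwhm), max(sm))
  expect_error(condition_average_and_smooth(matrix(0, 0, 5)), "at least one")
})

test_that("baseline z-scoring is exact arithmetic", {
  set.seed(51)
  s <- rnorm(40, 10, 2)
  z <- zscore_to_baseline(s, 10, 2)
  expect_equal(z, (s - 10) / 2)
  expect_equal(zscore_to_baseline(rep(7, 5), 7, 3), rep(0, 5))
  expect_error(zscore_to_baseline(s, 1, 1e-9), "below floor")
  # a stationary neuron's own baseline z-scores to mean ~ 0, sd ~ 1
  b <- rpois(2000, 4)
  z2 <- zscore_to_baseline(b, mean(b), sd(b))
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(sd(z2), 1, tolerance = 1e-12)
})

test_that("the activity matrix concatenates conditions with a trimmed baseline", {
  series <- list(
    nA = list(c1 = list(baseline = 1:20, video = 1:10)),
    nB = list(c1 = list(baseline = 21:40, video = 11:20)))
  am <- build_activity_matrix(series, baseline_trim_ms = 600, step_ms = 40)
  expect_equal(dim(am$matrix), c(2, 25))   # 15 trimmed baseline + 10 video
  expect_equal(nrow(am$index), 25)
  expect_equal(sum(am$index$segment == "baseline"), 15)
  # trimmed prefix is the LAST 600 ms of baseline
  expect_equal(am$matrix[1, 1:15], 6:20)
  # index round-trips columns to (condition, segment, time)
  key <- paste(am$index$condition, am$index$segment, am$index$time_idx)
  expect_equal(anyDuplicated(key), 0)
  series$nB$extra <- series$nB$c1
  expect_error(build_activity_matrix(series), "ragged condition")
})

test_that("PCA matches a brute-force eigendecomposition oracle", {
  set.seed(52)
  m <- matrix(rnorm(5 * 20), 5, 20)
  rownames(m) <- paste0("n", 1:5)
  am <- list(matrix = m,
             index = data.frame(condition = "c1", segment = "video",
                                time_idx = 1:20, time_s = (0:19) * 0.04))
  ts <- pca_trajectories(am, k = 3)
  centered <- m - rowMeans(m)
  eig <- eigen(tcrossprod(centered), symmetric = TRUE)
  # eigenvalue fractions and loadings (up to sign) to 1e-8
  expect_equal(ts$variance_explained, (eig$values / sum(eig$values))[1:3],
               tolerance = 1e-8)
  for (j in 1:3)
    expect_equal(abs(ts$loadings[, j]), abs(eig$vectors[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(abs(crossprod(ts$loadings) - diag(3)) < 1e-10))
  expect_true(all(diff(ts$variance_explained) <= 1e-12))
  expect_lte(sum(ts$variance_explained), 1 + 1e-12)
  # trajectories are the projections
  expect_equal(ts$trajectories$c1, t(crossprod(ts$loadings, centered)),
               ignore_attr = TRUE)
})

test_that("near-planar data leave almost nothing for the third component", {
  set.seed(53)
  basis <- qr.Q(qr(matrix(rnorm(6 * 2), 6, 2)))
  m <- basis %*% matrix(rnorm(2 * 40), 2, 40) + rnorm(240, 0, 1e-6)
  am <- list(matrix = m,
             index = data.frame(condition = "c1", segment = "video",
                                time_idx = 1:40, time_s = (0:39) * 0.04))
  ts <- pca_trajectories(am, k = 3)
  expect_lt(ts$variance_explained[3], 1e-9)
})

test_that("trajectory distances are Euclidean and rotation invariant", {
  set.seed(54)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(trajectory_distance(a, a), rep(0, 10))
  b <- sweep(a, 2, c(-3, -4, 0))
  expect_equal(trajectory_distance(a, b), rep(5, 10))
  # any rotation of the component space leaves distances unchanged
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  b2 <- a + matrix(rnorm(30, 0, 2), 10, 3)
  expect_equal(trajectory_distance(a %*% R, b2 %*% R),
               trajectory_distance(a, b2), tolerance = 1e-10)
  expect_error(trajectory_distance(a, a[1:5, ]), "differ in length")
})

test_that("top divergences pick the largest values, ties to earliest", {
  expect_equal(top_divergences(1:10), c(10, 9))
  expect_equal(top_divergences(rep(2, 6)), c(1, 2))
  expect_equal(top_divergences(c(1, 5, 2), k = 7), c(2, 3, 1))
  expect_error(top_divergences(numeric(0)), "empty")
})

test_that("the end-to-end analysis localizes a pigeon-only event", {
  ss <- full_stimulus_set()
  sch <- full_schedule()
  pop <- c(
    lapply(1:4, function(i)
      neuron_ground_truth(sprintf("ev%d", i), subject_id = "s1",
                          label = "non_selective",
                          baseline_log_rate = log(3), theta = 3,
                          sigma_trial = 0.1, event_gain = 1.2,
                          event_actors = "pigeon")),
    lapply(5:10, function(i)
      neuron_ground_truth(sprintf("bg%d", i), subject_id = "s2",
                          label = "non_selective",
                          baseline_log_rate = log(2), theta = 3,
                          sigma_trial = 0.1)))
  rec <- simulate_spike_counts(sch, pop, ss, seed = 55)
  ssa <- state_space_analysis(rec)
  expect_length(ssa$distances, 16)   # two-pigeon videos excluded
  expect_length(ssa$pca$variance_explained, 3)
  hits <- 0
  for (vd in names(ssa$top2)) {
    ev <- ss$videos$event_windows[ss$videos$unique_id ==
                                    paste0(vd, "_pigeon")][[1]]
    ok <- any(vapply(ssa$top2[[vd]], function(tt)
      any(vapply(ev, function(w) tt >= w$start - 0.2 && tt <= w$end + 0.2,
                 logical(1))), logical(1)))
    hits <- hits + ok
  }
  expect_gte(hits / length(ssa$top2), 0.8)
})
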