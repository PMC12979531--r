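test_that("make_population respects the label mix and structure", {
  pop <- make_population(10, label_mix = c(non_selective = 1),
                         regions = "MVL", seed = 1)
  expect_length(pop, 10)
  expect_true(all(vapply(pop, function(n) nrow(n$effect_map) == 0, logical(1))))
  expect_true(all(vapply(pop, function(n) n$event_gain == 0, logical(1))))

  # behavior-selective neurons: one behavior, both actors
  pop_b <- make_population(5, label_mix = c(behavior_selective = 1),
                           regions = "MVL", seed = 2)
  for (n in pop_b) {
    expect_equal(nrow(n$effect_map), 2)
    expect_setequal(n$effect_map$actor, c("pigeon", "greeble"))
    expect_equal(length(unique(n$effect_map$behavior)), 1)
  }
  expect_error(make_population(5, label_mix = c(non_selective = 0.5)),
               "sum to 1")
  expect_error(make_population(5, label_mix = c(bogus = 1)), "unknown label")
})

test_that("label assignment fluctuates binomially around the mix", {
  pop <- make_population(400, label_mix = c(actor_selective = 0.23,
                                            non_selective = 0.77),
                         regions = "MVL", effect_size = 0.5, seed = 3)
  k <- sum(vapply(pop, function(n) n$label == "actor_selective", logical(1)))
  # 3 binomial SDs around 92: sd = sqrt(400 * .23 * .77) ~ 8.4
  expect_gt(k, 92 - 3 * 8.42)
  expect_lt(k, 92 + 3 * 8.42)
})

test_that("spike counts hit the Poisson limit and NB2 moments", {
  ss <- full_stimulus_set()
  sch <- full_schedule()
  # theta -> infinity proxy, no trial noise, flat rate 5: Poisson limit
  lim <- neuron_ground_truth("lim", theta = 1e6, sigma_trial = 0,
                             baseline_log_rate = log(5))
  nb <- neuron_ground_truth("nb", theta = 1, sigma_trial = 0,
                            baseline_log_rate = log(5))
  rec <- simulate_spike_counts(sch, list(lim, nb), ss, seed = 4)
  y_lim <- rec$count[rec$neuron_id == "lim"]
  y_nb <- rec$count[rec$neuron_id == "nb"]
  expect_gt(length(y_lim), 4000)
  # mean within 3 SE of 5; Poisson variance ~ mean
  expect_lt(abs(mean(y_lim) - 5), 3 * sqrt(5 / length(y_lim)))
  expect_lt(abs(var(y_lim) - 5) / 5, 0.1)
  # NB2 moment oracle: var = mu + mu^2 / theta = 30 at mu = 5, theta = 1
  expect_lt(abs(mean(y_nb) - 5), 3 * sqrt(30 / length(y_nb)))
  expect_lt(abs(var(y_nb) - 30) / 30, 0.1)
})

test_that("event windows raise rates by exp(gain) in the covered bins", {
  ss <- full_stimulus_set()
  sch <- full_schedule()
  nr <- neuron_ground_truth("ev", theta = 1e6, sigma_trial = 0,
                            baseline_log_rate = log(3),
                            event_gain = 1.0, event_actors = "both")
  rec <- simulate_spike_counts(sch, list(nr), ss, seed = 5)
  vid <- rec[rec$phase == "video", ]
  # recompute in-window bins independently from the stimulus set
  v <- ss$videos
  in_window <- logical(nrow(vid))
  outside <- logical(nrow(vid))
  for (i in seq_len(nrow(vid))) {
    ev <- v$event_windows[[match(vid$video_id[i], v$video_id)]]
    t0 <- vid$bin_index[i] * 0.2
    cover <- vapply(ev, function(w) t0 >= w$start && t0 + 0.2 <= w$end,
                    logical(1))
    touch <- vapply(ev, function(w) t0 < w$end && t0 + 0.2 > w$start,
                    logical(1))
    in_window[i] <- any(cover)
    outside[i] <- !any(touch)
  }
  ratio <- mean(vid$count[in_window]) / mean(vid$count[outside])
  expect_lt(abs(ratio - exp(1)) / exp(1), 0.1)
})

test_that("identical seeds give bit-identical tables", {
  ss <- full_stimulus_set()
  sch <- full_schedule()
  pop <- make_population(2, regions = "MVL", seed = 6)
  a <- simulate_spike_counts(sch, pop, ss, seed = 7)
  b <- simulate_spike_counts(sch, pop, ss, seed = 7)
  expect_identical(a, b)
  c <- simulate_spike_counts(sch, pop, ss, seed = 8)
  expect_false(identical(a$count, c$count))
})

test_that("contralateral filtering keeps 3 of 6 presentations per video", {
  ss <- full_stimulus_set()
  sch <- full_schedule()
  nr <- neuron_ground_truth("c1", hemisphere = "left")
  rec <- simulate_spike_counts(sch, list(nr), ss, seed = 9)
  expect_true(all(rec$monitor == "right"))
  expect_equal(length(unique(rec$trial_number)), 216)
  all6 <- simulate_spike_counts(sch, list(nr), ss, seed = 9,
                                contralateral_only = FALSE)
  expect_equal(length(unique(all6$trial_number)), 432)
  # baseline bins: middle 2 s of the ITI = 10 bins per trial
  one_trial <- rec[rec$trial_number == rec$trial_number[1], ]
  expect_equal(sum(one_trial$phase == "baseline"), 10)
  dur <- one_trial$duration <- unique(
    ss$videos$duration_s[ss$videos$video_id == one_trial$video_id[1]])
  expect_equal(sum(one_trial$phase == "video"), floor(dur / 0.2 + 1e-9))
})

test_that("frame pairs are reproducible with exact masked means", {
  a <- generate_frame_pair(seed = 11)
  b <- generate_frame_pair(seed = 11)
  expect_identical(a, b)
  c <- generate_frame_pair(seed = 12)
  expect_lt(cor(as.vector(a$frame_a), as.vector(c$frame_a)), 1)
  expect_equal(mean(v_channel(a$frame_a)[a$fg_mask]), 0.6, tolerance = 1e-12)
  expect_equal(mean(v_channel(a$frame_b)[a$fg_mask]), 0.3, tolerance = 1e-12)
  expect_error(generate_frame_pair(fg_mask_spec = matrix(FALSE, 64, 64)),
               "degenerate mask")
  expect_error(generate_frame_pair(fg_mask_spec = list(cx = 2, cy = 32,
                                                       rx = 10, ry = 10)),
               "fit")
})
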