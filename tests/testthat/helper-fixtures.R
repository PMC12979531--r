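# Shared fixtures, built once per test run. The full stimulus set and
# schedule are the study's design constants; small variants keep individual
# tests fast.

.fx <- new.env(parent = emptyenv())

full_stimulus_set <- function() {
  if (is.null(.fx$stim)) .fx$stim <- build_stimulus_set(seed = 101)
  .fx$stim
}

full_schedule <- function() {
  if (is.null(.fx$sched)) .fx$sched <- schedule_session(full_stimulus_set(),
                                                        seed = 102)
  .fx$sched
}

# one neuron per planted label, reference conditions: effect 1.0 log-units,
# baseline 2 counts/bin, theta 2, trial SD 0.3
planted_neuron <- function(label, id, effect_size = 1.0, seed = id,
                           baseline = log(2), sigma_trial = 0.3,
                           event_gain = 1.0) {
  set.seed(seed)
  em <- popspike:::.effect_map_for(label, effect_size,
                                   c("courtship", "eating", "flying",
                                     "walking"))
  ev_actors <- if (label %in% c("actor_selective", "actor_selective_mixed")) {
    if (nrow(em)) em$actor[which.max(em$delta)] else "both"
  } else "both"
  neuron_ground_truth(sprintf("n%03d", id), subject_id = sprintf("s%d", id %% 3 + 1),
                      label = label, effect_map = em,
                      baseline_log_rate = baseline, theta = 2,
                      sigma_trial = sigma_trial,
                      event_gain = if (label == "non_selective") 0 else event_gain,
                      event_actors = ev_actors)
}

# NB GLMM training table: n_trials trials x n_bins bins from the generative
# model log mu = b0 + u_trial, u ~ N(0, sigma^2), y ~ NB2(mu, theta)
nb_glmm_table <- function(n_trials, n_bins, b0, theta, sigma) {
  trial <- factor(rep(seq_len(n_trials), each = n_bins))
  u <- rnorm(n_trials, 0, sigma)
  mu <- exp(b0 + u[as.integer(trial)])
  data.frame(trial = trial, y = rnbinom(n_trials * n_bins, size = theta,
                                        mu = mu))
}

# grayscale frame stack helper: V equal across channels
gray_stack <- function(mats, masks = NULL) {
  frames <- lapply(mats, function(m) array(rep(m, 3), c(dim(m), 3)))
  if (is.null(masks))
    masks <- lapply(mats, function(m) matrix(FALSE, nrow(m), ncol(m)))
  frame_stack(frames, masks)
}

v_channel <- function(frame) rgb_to_hsv_array(frame)[, , 3]
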