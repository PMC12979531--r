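.LABELS <- c("non_selective", "actor_selective", "actor_selective_mixed",
             "behavior_selective", "actor_and_behavior_selective",
             "visually_selective", "other_multi_behavior", "other_two_pigeon")

# coarse category a planted label should be recovered as
.label_category <- function(label) {
  switch(label,
         actor_selective_mixed = "actor_selective",
         other_multi_behavior = "other",
         other_two_pigeon = "other",
         label)
}

#' Construct a single simulated neuron's generative parameters
#'
#' Ground truth for one simulated unit: where it sits (region, subject), its
#' planted selectivity label, its baseline log-rate per 200 ms bin, NB2
#' dispersion, trial-level random-intercept SD, per-condition log-rate
#' increments, and how it responds to event windows and sound.
#'
#' @param neuron_id,subject_id,region Identifiers; \code{region} is typically
#'   one of MVL, Wulst, NCL.
#' @param label Planted label, one of
#'   \code{c("non_selective","actor_selective","actor_selective_mixed",
#'   "behavior_selective","actor_and_behavior_selective",
#'   "visually_selective","other_multi_behavior","other_two_pigeon")}.
#' @param baseline_log_rate Baseline log counts per 200 ms bin.
#' @param theta NB2 dispersion (> 0); variance is \eqn{\mu + \mu^2/\theta}.
#' @param sigma_trial Trial-level random-intercept SD (log scale, >= 0).
#' @param effect_map Data frame with columns \code{actor}, \code{behavior},
#'   \code{delta}: log-rate increments during the video phase of matching
#'   conditions. May be empty (non-selective).
#' @param event_gain Extra log-rate increment inside stimulus event windows.
#' @param event_actors Which actor's videos carry the event response:
#'   \code{"pigeon"}, \code{"greeble"} or \code{"both"}.
#' @param sound_modulated Logical; if \code{TRUE}, \code{sound_effect} is
#'   added during sound-on video bins of \code{sound_actors} videos.
#' @param sound_effect Log-rate increment for sound-on presentations.
#' @param sound_actors Actor(s) whose sound-on videos are modulated.
#' @param hemisphere Implanted hemisphere (\code{"left"}/\code{"right"});
#'   determines the contralateral monitor.
#' @return A list of class \code{"neuron_ground_truth"}.
#' @export
neuron_ground_truth <- function(neuron_id, subject_id = "s1", region = "MVL",
                                label = "non_selective",
                                baseline_log_rate = log(2), theta = 2,
                                sigma_trial = 0.3,
                                effect_map = data.frame(actor = character(0),
                                                        behavior = character(0),
                                                        delta = numeric(0)),
                                event_gain = 0, event_actors = "both",
                                sound_modulated = FALSE, sound_effect = 0,
                                sound_actors = "pigeon",
                                hemisphere = "left") {
  if (theta <= 0) stop("theta must be positive")
  if (sigma_trial < 0) stop("sigma_trial must be non-negative")
  if (!label %in% .LABELS) stop("unknown label: ", label)
  structure(list(neuron_id = neuron_id, subject_id = subject_id,
                 region = region, label = label,
                 category = .label_category(label),
                 baseline_log_rate = baseline_log_rate, theta = theta,
                 sigma_trial = sigma_trial, effect_map = effect_map,
                 event_gain = event_gain, event_actors = event_actors,
                 sound_modulated = sound_modulated,
                 sound_effect = sound_effect, sound_actors = sound_actors,
                 hemisphere = hemisphere),
            class = "neuron_ground_truth")
}

# build the per-condition increment table implied by a label
.effect_map_for <- function(label, effect_size, behaviors) {
  em <- function(actor, behavior, delta)
    data.frame(actor = actor, behavior = behavior, delta = delta,
               stringsAsFactors = FALSE)
  switch(label,
    non_selective = em(character(0), character(0), numeric(0)),
    actor_selective = {
      a <- sample(c("pigeon", "greeble"), 1)
      em(a, behaviors, effect_size)
    },
    actor_selective_mixed = {
      a <- sample(c("pigeon", "greeble"), 1)
      rbind(em(a, behaviors, effect_size),
            em(setdiff(c("pigeon", "greeble"), a), behaviors, -effect_size))
    },
    behavior_selective = {
      b <- sample(behaviors, 1)
      em(c("pigeon", "greeble"), b, effect_size)
    },
    actor_and_behavior_selective = {
      em(sample(c("pigeon", "greeble"), 1), sample(behaviors, 1), effect_size)
    },
    visually_selective = {
      rbind(em("pigeon", c(behaviors, "twoPigeon"), effect_size),
            em("greeble", behaviors, effect_size))
    },
    other_multi_behavior = {
      bs <- sample(behaviors, 2)
      em(rep(c("pigeon", "greeble"), each = 2), rep(bs, 2), effect_size)
    },
    other_two_pigeon = em("pigeon", "twoPigeon", effect_size),
    stop("unknown label: ", label)
  )
}

#' Generate a ground-truth neuron population
#'
#' Draws simulated neurons for each region with planted selectivity labels.
#' Labels are assigned independently per neuron from \code{label_mix} (so
#' realized counts fluctuate binomially around the mix). Baseline log-rates
#' are drawn from Normal(log 2, 0.7^2) per 200 ms bin, spanning near-zero
#' rates so that zero-heavy units occur; NB2 dispersions are drawn
#' log-normally. Neuron identifiers are nested within subjects, which are
#' nested within regions; subjects alternate implanted hemispheres.
#'
#' @param n_neurons_per_region Neurons per region.
#' @param label_mix Named proportions over the labels accepted by
#'   [neuron_ground_truth()]; must sum to 1.
#' @param effect_size Planted log-rate increment for selective conditions
#'   (negative values give inhibited responses).
#' @param regions Region names.
#' @param n_subjects_per_region Subjects per region (neurons distributed
#'   round-robin).
#' @param behaviors Behavior categories available to effect maps.
#' @param baseline_meanlog,baseline_sdlog Baseline log-rate distribution.
#' @param theta_meanlog,theta_sdlog NB2 dispersion distribution (log-normal).
#' @param sigma_trial Trial random-intercept SD shared by all neurons.
#' @param p_sound Probability a neuron is sound modulated.
#' @param sound_effect Log-rate increment for sound-on pigeon videos of
#'   sound-modulated neurons.
#' @param event_gain Log-rate increment inside event windows for selective
#'   neurons (actor-selective units respond to events of their preferred
#'   actor only; others to both actors). Non-selective units get 0.
#' @param seed Integer seed.
#' @return List of [neuron_ground_truth()] objects, with the label mix and
#'   seed attached as attributes.
#' @export
make_population <- function(n_neurons_per_region = 30,
                            label_mix = c(non_selective = 0.30,
                                          actor_selective = 0.20,
                                          behavior_selective = 0.10,
                                          actor_and_behavior_selective = 0.15,
                                          visually_selective = 0.10,
                                          actor_selective_mixed = 0.05,
                                          other_multi_behavior = 0.05,
                                          other_two_pigeon = 0.05),
                            effect_size = 1.0,
                            regions = c("MVL", "Wulst", "NCL"),
                            n_subjects_per_region = 3,
                            behaviors = c("courtship", "eating", "flying",
                                          "walking"),
                            baseline_meanlog = log(2), baseline_sdlog = 0.7,
                            theta_meanlog = log(2), theta_sdlog = 0.4,
                            sigma_trial = 0.3,
                            p_sound = 0.10, sound_effect = 0.5,
                            event_gain = 1.0, seed = 1) {
  if (abs(sum(label_mix) - 1) > 1e-8) stop("label_mix must sum to 1")
  if (any(label_mix < 0)) stop("label_mix proportions must be non-negative")
  unknown <- setdiff(names(label_mix), .LABELS)
  if (length(unknown)) stop("unknown label(s) in mix: ",
                            paste(unknown, collapse = ", "))
  set.seed(seed)
  pop <- list()
  for (r in regions) {
    subjects <- sprintf("%s_s%d", r, seq_len(n_subjects_per_region))
    hemis <- rep(c("left", "right"), length.out = n_subjects_per_region)
    for (i in seq_len(n_neurons_per_region)) {
      s_idx <- ((i - 1) %% n_subjects_per_region) + 1
      label <- sample(names(label_mix), 1, prob = label_mix)
      emap <- .effect_map_for(label, effect_size, behaviors)
      ev_actors <- if (label %in% c("actor_selective", "actor_selective_mixed")) {
        # events ride on the excited actor's videos
        emap$actor[which.max(emap$delta)]
      } else "both"
      pop[[length(pop) + 1]] <- neuron_ground_truth(
        neuron_id = sprintf("%s_n%03d", r, i),
        subject_id = subjects[s_idx], region = r, label = label,
        baseline_log_rate = rnorm(1, baseline_meanlog, baseline_sdlog),
        theta = exp(rnorm(1, theta_meanlog, theta_sdlog)),
        sigma_trial = sigma_trial, effect_map = emap,
        event_gain = if (label == "non_selective") 0 else event_gain,
        event_actors = ev_actors,
        sound_modulated = runif(1) < p_sound,
        sound_effect = sound_effect,
        hemisphere = hemis[s_idx])
    }
  }
  attr(pop, "label_mix") <- label_mix
  attr(pop, "seed") <- seed
  pop
}
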