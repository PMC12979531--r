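# Per-trial bin template: one row per 200 ms bin of every trial in the
# schedule, with phase, within-phase bin index, time relative to video onset
# and the event-window overlap fraction of each video bin.
.bin_template <- function(schedule, stimulus_set, bin_s, baseline_bins) {
  tr <- schedule$trials
  v <- stimulus_set$videos
  ev_by_unique <- setNames(v$event_windows, v$video_id)

  per_trial <- lapply(seq_len(nrow(tr)), function(i) {
    dur <- tr$duration_s[i]
    nb <- floor(dur / bin_s + 1e-9)        # last partial bin dropped
    ev <- ev_by_unique[[tr$video_id[i]]]
    t0 <- (seq_len(nb) - 1) * bin_s
    frac <- numeric(nb)
    for (w in ev) {
      ov <- pmax(0, pmin(t0 + bin_s, w$end) - pmax(t0, w$start))
      frac <- frac + ov / bin_s
    }
    data.frame(
      trial_number = tr$trial_index[i],
      phase = c(rep("baseline", baseline_bins), rep("video", nb)),
      bin_index = c(seq_len(baseline_bins), seq_len(nb)) - 1L,
      time_s = c(-2 + (seq_len(baseline_bins) - 1) * bin_s, t0),
      event_frac = c(numeric(baseline_bins), pmin(frac, 1)),
      stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, per_trial)
  nb_per_trial <- vapply(per_trial, nrow, integer(1))
  ti <- rep(seq_len(nrow(tr)), nb_per_trial)
  for (col in c("video_id", "unique_id", "behavior", "exemplar", "actor",
                "sound", "monitor"))
    bins[[col]] <- tr[[col]][ti]
  bins
}

#' Simulate negative-binomial spike-count tables with planted ground truth
#'
#' Generates one binned spike count per 200 ms bin per trial per neuron.
#' Counts follow NB2(\eqn{\mu}, \eqn{\theta}) with
#' \deqn{\log\mu = \mathrm{baseline} + u_{trial} + \mathrm{video\ phase}
#'   \cdot (\Delta_{actor,behavior} + \mathrm{event\ gain}\cdot
#'   \mathrm{overlap} + \mathrm{sound\ effect}\cdot 1[\mathrm{sound\ on}])}
#' where \eqn{u_{trial} \sim N(0, \sigma_{trial}^2)} is drawn per neuron and
#' trial, \eqn{\Delta} comes from the neuron's effect map, and the event
#' term applies the gain weighted by the fraction of the bin overlapping a
#' stimulus event window. Event responses ride on the conditions the neuron
#' is excited by (positive effect-map entries; all conditions when the map
#' has none), further restricted to the neuron's \code{event_actors}.
#' Baseline bins are the middle 2 s of the 6 s inter-trial interval (10
#' bins); video bins tile the video with the last partial bin dropped.
#'
#' By default only trials shown on the monitor contralateral to the
#' neuron's implanted hemisphere are emitted (3 of the 6 presentations per
#' video), mirroring the near-complete optic decussation.
#'
#' @param schedule A [schedule_session()] result.
#' @param population List of [neuron_ground_truth()] objects (e.g. from
#'   [make_population()]).
#' @param stimulus_set The [build_stimulus_set()] result the schedule was
#'   built from.
#' @param seed Integer seed; the table is bit-identical for identical seeds.
#' @param contralateral_only Keep only contralateral-monitor trials.
#' @param bin_s Bin width in seconds (200 ms).
#' @param baseline_bins Baseline bins per trial (10 x 200 ms = middle 2 s).
#' @return A data frame of spike-count records: identifiers, trial number,
#'   \code{phase}, within-phase 0-based \code{bin_index}, \code{time_s}
#'   relative to video onset, condition labels and the NB2 \code{count}.
#' @export
simulate_spike_counts <- function(schedule, population, stimulus_set,
                                  seed = 1, contralateral_only = TRUE,
                                  bin_s = 0.2, baseline_bins = 10) {
  stopifnot(inherits(schedule, "trial_schedule"))
  if (length(population) == 0) stop("population is empty")
  if (inherits(population, "neuron_ground_truth")) population <- list(population)
  set.seed(seed)
  bins <- .bin_template(schedule, stimulus_set, bin_s, baseline_bins)
  n_trials <- nrow(schedule$trials)
  is_video <- bins$phase == "video"
  sound_on <- bins$sound == "on"
  cond_key <- paste(bins$actor, bins$behavior, sep = ".")

  out <- vector("list", length(population))
  for (k in seq_along(population)) {
    nr <- population[[k]]
    keep <- if (contralateral_only) {
      contra <- if (nr$hemisphere == "left") "right" else "left"
      bins$monitor == contra
    } else rep(TRUE, nrow(bins))
    b <- bins[keep, , drop = FALSE]

    delta <- numeric(nrow(b))
    tuned <- rep(TRUE, nrow(b))   # conditions carrying the event response
    if (nrow(nr$effect_map)) {
      emap <- setNames(nr$effect_map$delta,
                       paste(nr$effect_map$actor, nr$effect_map$behavior,
                             sep = "."))
      hit <- match(cond_key[keep], names(emap))
      delta[!is.na(hit)] <- emap[hit[!is.na(hit)]]
      excited <- names(emap)[emap > 0]
      if (length(excited)) tuned <- cond_key[keep] %in% excited
    }
    ev_ok <- tuned &
      (nr$event_actors == "both" | b$actor %in% nr$event_actors)
    snd_ok <- nr$sound_modulated & sound_on[keep] & b$actor %in% nr$sound_actors

    u <- rnorm(n_trials, 0, nr$sigma_trial)
    eta <- nr$baseline_log_rate + u[b$trial_number] +
      as.numeric(is_video[keep]) *
      (delta + nr$event_gain * b$event_frac * ev_ok +
         nr$sound_effect * as.numeric(snd_ok))
    counts <- rnbinom(nrow(b), size = nr$theta, mu = exp(pmin(eta, 30)))

    out[[k]] <- data.frame(
      neuron_id = nr$neuron_id, subject_id = nr$subject_id,
      region = nr$region,
      b[c("trial_number", "phase", "bin_index", "time_s", "video_id",
          "unique_id", "behavior", "exemplar", "actor", "sound", "monitor")],
      count = counts, stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}
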