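.BEHAVIORS <- c("courtship", "eating", "flying", "walking")
.TWO_PIGEON <- "twoPigeon"

# feature tags plausibly attached to event windows, by behavior
.EVENT_TAGS <- list(
  courtship = c("bowing", "walking"),
  eating = c("pecking", "mandibulation", "walking"),
  flying = c("wing_flap", "body_shift"),
  walking = c("stepping", "head_bob"),
  twoPigeon = c("head_bob", "body_shift")
)
.tags_for <- function(behavior) {
  tags <- .EVENT_TAGS[[behavior]]
  if (is.null(tags)) tags <- c("motion_a", "motion_b")
  tags
}

# draw 1-3 non-overlapping event windows of 200-600 ms inside [0, dur]
.draw_event_windows <- function(dur, behavior) {
  k <- sample(1:3, 1)
  windows <- list()
  tries <- 0
  while (length(windows) < k && tries < 200) {
    tries <- tries + 1
    len <- runif(1, 0.2, 0.6)
    if (len >= dur) next
    start <- runif(1, 0, dur - len)
    ok <- all(vapply(windows, function(w) start >= w$end || start + len <= w$start,
                     logical(1)))
    if (ok) windows[[length(windows) + 1]] <-
        list(start = start, end = start + len,
             feature_tag = sample(.tags_for(behavior), 1))
  }
  windows[order(vapply(windows, `[[`, numeric(1), "start"))]
}

#' Enumerate the conspecific-video stimulus set
#'
#' Builds the full factorial video set: each behavior is shown by four
#' exemplar videos, each exemplar exists as a pigeon version and a greeble
#' (abstract control shape) version sharing duration and event windows, and
#' every visually unique video exists with the natural sound on and off.
#' Optionally four auxiliary "two pigeons, no specific behavior" videos are
#' added (pigeon actor only). With the defaults this gives 32 + 4 = 36
#' visually unique videos and 72 videos in total.
#'
#' @param n_behaviors Number of behavior categories (the canonical four are
#'   courtship, eating, flying, walking; further categories get generic
#'   names).
#' @param n_exemplars Exemplar videos per behavior.
#' @param include_two_pigeon Add the four auxiliary two-pigeon videos.
#' @param duration_range Video duration range in seconds, within
#'   \code{[0.2, 60]}; durations are drawn uniformly per visually unique
#'   video (pigeon and greeble versions share them).
#' @param seed Integer seed; the set is deterministic given the seed.
#' @return An object of class \code{"stimulus_set"}: a data frame of videos
#'   (\code{video_id}, \code{unique_id}, \code{behavior}, \code{exemplar},
#'   \code{actor}, \code{sound}, \code{duration_s}) with the per-video event
#'   windows stored in the list column \code{event_windows}.
#' @export
build_stimulus_set <- function(n_behaviors = 4, n_exemplars = 4,
                               include_two_pigeon = TRUE,
                               duration_range = c(2.2, 4.0), seed = 1) {
  if (n_behaviors < 1 || n_exemplars < 1)
    stop("n_behaviors and n_exemplars must be at least 1")
  if (length(duration_range) != 2 || any(!is.finite(duration_range)) ||
      duration_range[1] > duration_range[2] ||
      duration_range[1] < 0.2 || duration_range[2] > 60)
    stop("duration_range must be within [0.2, 60] seconds with min <= max")
  set.seed(seed)

  behaviors <- if (n_behaviors <= length(.BEHAVIORS)) .BEHAVIORS[seq_len(n_behaviors)]
  else c(.BEHAVIORS, sprintf("behavior%d", seq_len(n_behaviors - length(.BEHAVIORS)) +
                               length(.BEHAVIORS)))

  rows <- list()
  add_unique <- function(behavior, exemplar, actors) {
    dur <- runif(1, duration_range[1], duration_range[2])
    ev <- .draw_event_windows(dur, behavior)
    uid <- sprintf("%s%d", behavior, exemplar)
    for (actor in actors) for (snd in c("on", "off")) {
      rows[[length(rows) + 1]] <<- list(
        video_id = sprintf("%s_%s_%s", uid, actor, snd),
        unique_id = sprintf("%s_%s", uid, actor),
        behavior = behavior, exemplar = exemplar, actor = actor,
        sound = snd, duration_s = dur, event_windows = list(ev))
    }
  }
  for (b in behaviors) for (e in seq_len(n_exemplars))
    add_unique(b, e, c("pigeon", "greeble"))
  if (include_two_pigeon)
    for (e in 1:4) add_unique(.TWO_PIGEON, e, "pigeon")

  videos <- do.call(rbind, lapply(rows, function(r)
    data.frame(r[setdiff(names(r), "event_windows")], stringsAsFactors = FALSE)))
  videos$event_windows <- lapply(rows, function(r) r$event_windows[[1]])
  structure(list(videos = videos,
                 behaviors = behaviors,
                 include_two_pigeon = include_two_pigeon,
                 seed = seed),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("Stimulus set:", nrow(x$videos), "videos (",
      length(unique(x$videos$unique_id)), "visually unique )\n")
  cat("  behaviors:", paste(unique(x$videos$behavior), collapse = ", "), "\n")
  invisible(x)
}

# run lengths of behavioral categories in a trial ordering
.max_run <- function(behavior) max(rle(as.character(behavior))$lengths)

#' Pseudorandomized session schedule
#'
#' Each video is presented \code{reps_per_video} times, half on the left and
#' half on the right monitor, in an order where no behavioral category runs
#' for more than \code{max_consecutive} consecutive trials. A fixed number
#' of trials, \code{round(reward_fraction * n_trials)}, is drawn without
#' replacement as water-rewarded. With the full default stimulus set this
#' yields 432 trials (6 s inter-trial interval, 2.4 s reward access).
#'
#' The ordering is found by a random permutation followed by constraint
#' repair: any trial inside an over-long category run is swapped with a
#' random position where neither side ends up violating the constraint,
#' within a bounded number of attempts.
#'
#' @param stimulus_set A [build_stimulus_set()] result.
#' @param reps_per_video Presentations per video; must be even (split across
#'   monitors).
#' @param reward_fraction Fraction of trials followed by water access.
#' @param max_consecutive Longest permitted same-category run.
#' @param seed Integer seed.
#' @param max_attempts Bound on repair attempts before a scheduling error.
#' @return Class \code{"trial_schedule"}: data frame of trials
#'   (\code{trial_index}, \code{video_id}, condition labels, \code{monitor},
#'   \code{reward}) plus \code{iti_s = 6} and \code{reward_duration_s = 2.4}.
#' @export
schedule_session <- function(stimulus_set, reps_per_video = 6,
                             reward_fraction = 0.10, max_consecutive = 3,
                             seed = 1, max_attempts = 10000) {
  stopifnot(inherits(stimulus_set, "stimulus_set"))
  if (reps_per_video %% 2 != 0) stop("reps_per_video must be even (left/right split)")
  if (reward_fraction < 0 || reward_fraction > 1) stop("reward_fraction in [0,1]")
  set.seed(seed)
  v <- stimulus_set$videos
  idx <- rep(seq_len(nrow(v)), each = reps_per_video)
  monitor <- rep(rep(c("left", "right"), each = reps_per_video / 2), nrow(v))
  n <- length(idx)
  ord <- sample.int(n)
  beh <- v$behavior[idx]

  # constraint repair by pairwise swaps
  ok_after_swap <- function(ord, i, j) {
    o2 <- ord; o2[c(i, j)] <- ord[c(j, i)]
    lo <- max(1, min(i, j) - max_consecutive)
    hi <- min(n, max(i, j) + max_consecutive)
    .max_run(beh[o2[lo:hi]]) <= max_consecutive
  }
  attempts <- 0
  repeat {
    r <- rle(as.character(beh[ord]))
    if (max(r$lengths) <= max_consecutive) break
    bad_run <- which(r$lengths > max_consecutive)[1]
    pos <- sum(r$lengths[seq_len(bad_run)])  # last index of the offending run
    repeat {
      attempts <- attempts + 1
      if (attempts > max_attempts)
        stop("scheduling failed: could not satisfy the run-length constraint ",
             "(max ", max_consecutive, " consecutive same-category trials) ",
             "after ", max_attempts, " attempts")
      j <- sample.int(n, 1)
      if (beh[ord[j]] != beh[ord[pos]] && ok_after_swap(ord, pos, j)) {
        ord[c(pos, j)] <- ord[c(j, pos)]
        break
      }
    }
  }

  n_reward <- round(reward_fraction * n)
  reward <- rep(FALSE, n)
  if (n_reward > 0) reward[sample.int(n, n_reward)] <- TRUE

  trials <- data.frame(
    trial_index = seq_len(n),
    video_id = v$video_id[idx[ord]],
    unique_id = v$unique_id[idx[ord]],
    behavior = v$behavior[idx[ord]],
    exemplar = v$exemplar[idx[ord]],
    actor = v$actor[idx[ord]],
    sound = v$sound[idx[ord]],
    duration_s = v$duration_s[idx[ord]],
    monitor = monitor[ord],
    reward = reward,
    stringsAsFactors = FALSE)
  structure(list(trials = trials, iti_s = 6, reward_duration_s = 2.4,
                 max_consecutive = max_consecutive, seed = seed),
            class = "trial_schedule")
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat("Trial schedule:", nrow(x$trials), "trials;",
      sum(x$trials$reward), "rewarded;",
      "max category run =", .max_run(x$trials$behavior), "\n")
  invisible(x)
}
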