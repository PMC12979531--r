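#' Resample base-binned counts onto a sliding window
#'
#' Converts counts in consecutive 200 ms base bins into overlapping
#' 200 ms windows advanced in 40 ms steps, attributing each base bin's
#' count uniformly across its extent (linear resampling): a window's value
#' is the overlap-weighted sum of the base-bin counts it covers. Windows
#' are left-aligned and half-open; for a duration \eqn{D},
#' \eqn{T = \lfloor (D - w)/s \rfloor + 1} windows are produced (e.g. 96
#' for a 4 s trial).
#'
#' @param counts Numeric vector of counts per base bin (one trial).
#' @param base_ms Base bin width in ms (200).
#' @param width_ms Sliding window width in ms (200).
#' @param step_ms Window step in ms (40).
#' @return Numeric vector of length \eqn{T} (empty when the duration is
#'   shorter than the window).
#' @export
sliding_bin <- function(counts, base_ms = 200, width_ms = 200, step_ms = 40) {
  dur <- length(counts) * base_ms
  if (dur < width_ms) return(numeric(0))
  n_win <- floor((dur - width_ms) / step_ms) + 1
  starts <- (seq_len(n_win) - 1) * step_ms
  bin_start <- (seq_along(counts) - 1) * base_ms
  vapply(starts, function(t0) {
    ov <- pmax(0, pmin(bin_start + base_ms, t0 + width_ms) - pmax(bin_start, t0))
    sum(ov / base_ms * counts)
  }, numeric(1))
}

# normalized, truncated Gaussian kernel on the step grid
.gauss_kernel <- function(kernel_ms, step_ms, kind = c("sd", "fwhm")) {
  kind <- match.arg(kind)
  sd_ms <- if (kind == "sd") kernel_ms else kernel_ms / (2 * sqrt(2 * log(2)))
  sd_steps <- sd_ms / step_ms
  half <- max(1, ceiling(3 * sd_steps))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sd_steps^2))
  k / sum(k)
}

#' Condition-average a set of trial series and smooth in time
#'
#' Pointwise mean across trials of one condition followed by convolution
#' with a normalized Gaussian kernel (reflective boundaries). The kernel's
#' "200 ms" is read as its standard deviation by default; set
#' \code{kernel_kind = "fwhm"} to read it as full width at half maximum.
#'
#' @param trials A numeric matrix (trials x timepoints) or list of
#'   equal-length numeric vectors.
#' @param kernel_ms Kernel width in ms.
#' @param step_ms Sample spacing of the series in ms.
#' @param kernel_kind \code{"sd"} (default) or \code{"fwhm"}.
#' @return The averaged, smoothed series.
#' @export
condition_average_and_smooth <- function(trials, kernel_ms = 200,
                                         step_ms = 40,
                                         kernel_kind = c("sd", "fwhm")) {
  if (is.list(trials)) trials <- do.call(rbind, trials)
  if (is.vector(trials)) trials <- matrix(trials, nrow = 1)
  if (nrow(trials) < 1) stop("need at least one trial")
  avg <- colMeans(trials)
  k <- .gauss_kernel(kernel_ms, step_ms, match.arg(kernel_kind))
  half <- (length(k) - 1) / 2
  n <- length(avg)
  if (n == 0) return(avg)
  # reflective padding
  pre <- avg[pmin(pmax(half:1, 1), n)]
  post <- avg[pmax(pmin(n - (1:half) + 0, n), 1)]
  padded <- c(pre, avg, post)
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' Per-neuron baseline statistics
#'
#' Mean and SD of the 200 ms baseline spike counts (the middle 2 s of the
#' 6 s inter-trial interval) per neuron, pooled over trials.
#'
#' @param records A spike-count table.
#' @return Data frame with \code{neuron_id}, \code{mean}, \code{sd}.
#' @export
baseline_stats <- function(records) {
  b <- records[records$phase == "baseline", ]
  ids <- unique(b$neuron_id)
  data.frame(neuron_id = ids,
             mean = vapply(ids, function(i) mean(b$count[b$neuron_id == i]),
                           numeric(1)),
             sd = vapply(ids, function(i) sd(b$count[b$neuron_id == i]),
                         numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Z-score a series against a neuron's baseline
#'
#' @param series Numeric vector (condition-averaged activity).
#' @param baseline_mean,baseline_sd The neuron's baseline mean and SD per
#'   200 ms bin.
#' @param sd_floor Baseline SDs below this floor raise an error (silent
#'   neurons are excluded upstream).
#' @return \code{(series - baseline_mean) / baseline_sd}.
#' @export
zscore_to_baseline <- function(series, baseline_mean, baseline_sd,
                               sd_floor = 1e-6) {
  if (is.na(baseline_sd) || baseline_sd < sd_floor)
    stop("baseline SD below floor (", sd_floor, "); exclude this neuron")
  (series - baseline_mean) / baseline_sd
}

#' Assemble the pseudo-simultaneous population activity matrix
#'
#' Concatenates, per neuron, the per-condition z-scored series — a 600 ms
#' baseline prefix followed by the video-phase series — into one row, over
#' all conditions. All neurons must cover all conditions with equal series
#' lengths.
#'
#' @param series Nested list: \code{series[[neuron]][[condition]]} is a
#'   list with numeric \code{baseline} and \code{video} vectors (baseline
#'   on the same 40 ms grid).
#' @param baseline_trim_ms Baseline prefix to retain (600 ms).
#' @param step_ms Sample spacing (40 ms).
#' @return List with \code{matrix} (neurons x timepoints) and \code{index}
#'   (data frame mapping columns to condition, segment and within-segment
#'   time).
#' @export
build_activity_matrix <- function(series, baseline_trim_ms = 600,
                                  step_ms = 40) {
  if (!length(series)) stop("no neurons supplied")
  conds <- names(series[[1]])
  trim_pts <- round(baseline_trim_ms / step_ms)
  for (nn in names(series)) {
    missing <- setdiff(conds, names(series[[nn]]))
    extra <- setdiff(names(series[[nn]]), conds)
    if (length(missing) || length(extra))
      stop("ragged condition coverage for neuron ", nn, ": missing [",
           paste(missing, collapse = ", "), "] extra [",
           paste(extra, collapse = ", "), "]")
  }
  index <- do.call(rbind, lapply(conds, function(cd) {
    nb <- length(series[[1]][[cd]]$baseline)
    if (nb < trim_pts) stop("baseline series shorter than the trim for ", cd)
    nv <- length(series[[1]][[cd]]$video)
    data.frame(condition = cd,
               segment = c(rep("baseline", trim_pts), rep("video", nv)),
               time_idx = c(seq_len(trim_pts), seq_len(nv)),
               time_s = c((seq_len(trim_pts) - trim_pts - 1) * step_ms / 1000,
                          (seq_len(nv) - 1) * step_ms / 1000),
               stringsAsFactors = FALSE)
  }))
  rows <- lapply(names(series), function(nn) {
    unlist(lapply(conds, function(cd) {
      s <- series[[nn]][[cd]]
      nb <- length(s$baseline)
      c(s$baseline[(nb - trim_pts + 1):nb], s$video)
    }), use.names = FALSE)
  })
  lens <- vapply(rows, length, integer(1))
  if (length(unique(lens)) != 1 || lens[1] != nrow(index))
    stop("ragged series lengths across neurons")
  m <- do.call(rbind, rows)
  rownames(m) <- names(series)
  list(matrix = m, index = index)
}

#' Principal-component state-space trajectories
#'
#' Removes each neuron's mean across the concatenated columns, decomposes
#' the centered matrix (singular value decomposition, equivalent to the
#' eigendecomposition of the neuron-by-neuron covariance), and projects the
#' activity onto the top \code{k} components, reassembled into one
#' trajectory per condition. Component signs are fixed so each loading
#' vector's largest-magnitude entry is positive.
#'
#' @param activity A [build_activity_matrix()] result.
#' @param k Number of components to keep (3).
#' @return Class \code{"trajectory_set"}: per-condition \code{T x k}
#'   trajectories, orthonormal \code{loadings} (neurons x k),
#'   \code{variance_explained} fractions, and the column index.
#' @export
pca_trajectories <- function(activity, k = 3) {
  m <- activity$matrix
  if (ncol(m) <= k) stop("need more timepoint columns than components")
  centered <- m - rowMeans(m)
  sv <- svd(centered)
  rank <- sum(sv$d > max(dim(m)) * .Machine$double.eps * sv$d[1])
  k_eff <- min(k, rank)
  if (k_eff < k) warning("rank ", rank, " < k; returning ", k_eff,
                         " components")
  load <- sv$u[, seq_len(k_eff), drop = FALSE]
  flip <- vapply(seq_len(k_eff), function(j) {
    s <- sign(load[which.max(abs(load[, j])), j]); if (s == 0) 1 else s
  }, numeric(1))
  load <- sweep(load, 2, flip, `*`)
  scores <- t(load) %*% centered          # k x timepoints
  ve <- sv$d^2 / sum(sv$d^2)
  idx <- activity$index
  trajectories <- lapply(unique(idx$condition), function(cd) {
    t(scores[, idx$condition == cd, drop = FALSE])
  })
  names(trajectories) <- unique(idx$condition)
  structure(list(trajectories = trajectories,
                 loadings = structure(load, dimnames = list(rownames(m), NULL)),
                 variance_explained = ve[seq_len(k_eff)],
                 index = idx, k = k_eff),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("State-space trajectory set:", length(x$trajectories), "conditions,",
      x$k, "components\n")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-timepoint Euclidean distance between two trajectories
#'
#' @param traj_a,traj_b \code{T x k} coordinate matrices of equal size.
#' @return Numeric vector of length \eqn{T}.
#' @export
trajectory_distance <- function(traj_a, traj_b) {
  if (!all(dim(traj_a) == dim(traj_b)))
    stop("trajectories differ in length or dimension")
  sqrt(rowSums((traj_a - traj_b)^2))
}

#' Indices of the largest trajectory divergences
#'
#' @param distances Numeric distance series.
#' @param k How many peaks (2); ties resolved toward the earliest time.
#' @return Integer indices of the \code{k} largest values (all indices when
#'   \code{k} exceeds the length).
#' @export
top_divergences <- function(distances, k = 2) {
  if (!length(distances)) stop("empty distance series")
  order(-distances, seq_along(distances))[seq_len(min(k, length(distances)))]
}

#' End-to-end population state-space analysis
#'
#' For one region's spike-count table: per neuron and condition
#' (video x actor, sound versions pooled, two-pigeon videos excluded),
#' resamples each trial onto the 40 ms sliding grid, averages across
#' trials, smooths with the Gaussian kernel, z-scores against the neuron's
#' baseline, assembles the pseudo-simultaneous matrix with a 600 ms
#' baseline prefix, extracts three principal components, and computes the
#' per-timepoint pigeon-vs-greeble Euclidean distance for every video.
#' Neurons whose baseline SD is below the floor are excluded (recorded in
#' the result).
#'
#' @param records Spike-count table of one population (e.g. one region).
#' @param kernel_ms,kernel_kind Smoothing kernel, see
#'   [condition_average_and_smooth()].
#' @param step_ms Sliding step (40 ms).
#' @param width_ms Sliding window (200 ms).
#' @param baseline_trim_ms Baseline prefix retained in the matrix (600 ms).
#' @param k Components kept (3).
#' @param sd_floor Baseline-SD exclusion floor.
#' @return List with the [pca_trajectories()] result (\code{pca}),
#'   per-video distance series (\code{distances}, over the concatenated
#'   baseline+video segment with its time axis), top-2 divergence times
#'   (\code{top2}, seconds relative to video onset), and
#'   \code{excluded_neurons}.
#' @export
state_space_analysis <- function(records, kernel_ms = 200,
                                 kernel_kind = "sd", step_ms = 40,
                                 width_ms = 200, baseline_trim_ms = 600,
                                 k = 3, sd_floor = 1e-6) {
  bs <- baseline_stats(records)
  keep <- bs$neuron_id[!is.na(bs$sd) & bs$sd >= sd_floor]
  excluded <- setdiff(bs$neuron_id, keep)
  if (!length(keep)) stop("no neurons with usable baseline variability")
  vr <- records[records$behavior != "twoPigeon", ]
  conds <- sort(unique(vr$unique_id))

  series <- list()
  for (nn in keep) {
    nr <- vr[vr$neuron_id == nn, ]
    bmean <- bs$mean[bs$neuron_id == nn]
    bsd <- bs$sd[bs$neuron_id == nn]
    per_cond <- list()
    for (cd in conds) {
      cc <- nr[nr$unique_id == cd, ]
      trials <- unique(cc$trial_number)
      vid_mat <- t(vapply(trials, function(tt) {
        x <- cc[cc$trial_number == tt & cc$phase == "video", ]
        sliding_bin(x$count[order(x$bin_index)], width_ms = width_ms,
                    step_ms = step_ms)
      }, numeric(sliding_len(cc, width_ms, step_ms))))
      nbb <- max(cc$bin_index[cc$phase == "baseline"]) + 1
      bas_mat <- t(vapply(trials, function(tt) {
        x <- cc[cc$trial_number == tt & cc$phase == "baseline", ]
        sliding_bin(x$count[order(x$bin_index)], width_ms = width_ms,
                    step_ms = step_ms)
      }, numeric(floor((nbb * 200 - width_ms) / step_ms) + 1)))
      vs <- condition_average_and_smooth(vid_mat, kernel_ms, step_ms,
                                         kernel_kind)
      bss <- condition_average_and_smooth(bas_mat, kernel_ms, step_ms,
                                          kernel_kind)
      per_cond[[cd]] <- list(
        baseline = zscore_to_baseline(bss, bmean, bsd, sd_floor),
        video = zscore_to_baseline(vs, bmean, bsd, sd_floor))
    }
    series[[nn]] <- per_cond
  }

  activity <- build_activity_matrix(series, baseline_trim_ms, step_ms)
  pca <- pca_trajectories(activity, k = k)

  videos <- unique(sub("_(pigeon|greeble)$", "", conds))
  videos <- videos[paste0(videos, "_pigeon") %in% conds &
                     paste0(videos, "_greeble") %in% conds]
  idx <- pca$index
  distances <- list(); top2 <- list()
  for (vd in videos) {
    ta <- pca$trajectories[[paste0(vd, "_pigeon")]]
    tb <- pca$trajectories[[paste0(vd, "_greeble")]]
    d <- trajectory_distance(ta, tb)
    tax <- idx$time_s[idx$condition == paste0(vd, "_pigeon")]
    seg <- idx$segment[idx$condition == paste0(vd, "_pigeon")]
    distances[[vd]] <- data.frame(time_s = tax, segment = seg, distance = d)
    vid_mask <- seg == "video"
    ti <- top_divergences(d[vid_mask], 2)
    top2[[vd]] <- tax[vid_mask][ti]
  }
  list(pca = pca, distances = distances, top2 = top2,
       excluded_neurons = excluded, neurons = keep)
}

# expected sliding length for one trial of a condition subset
sliding_len <- function(cc, width_ms, step_ms) {
  nb <- max(cc$bin_index[cc$phase == "video"]) + 1
  max(0, floor((nb * 200 - width_ms) / step_ms) + 1)
}
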