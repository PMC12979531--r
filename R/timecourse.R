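# Data prep for the population time-course model of one video: cell factor
# with pooled baseline as reference and one level per actor x video-bin,
# random intercepts for trial x bin and subject:neuron.
.prepare_m2_data <- function(records, video) {
  key <- paste0(records$behavior, records$exemplar)
  d <- records[key == video, ]
  if (nrow(d) == 0) stop("no records for video '", video, "'")
  d$cell <- ifelse(d$phase == "baseline", "baseline",
                   paste0(d$actor, ".b", d$bin_index))
  bins <- sort(unique(d$bin_index[d$phase == "video"]))
  lev <- c("baseline",
           as.vector(t(outer(c("pigeon", "greeble"), bins,
                             function(a, b) paste0(a, ".b", b)))))
  d$cell <- factor(d$cell, levels = intersect(lev, unique(d$cell)))
  d$trialBin <- interaction(d$trial_number, d$phase, d$bin_index, drop = TRUE)
  d$subjNeuron <- interaction(d$subject_id, d$neuron_id, drop = TRUE)
  d
}

#' Fit the population time-course model for one video
#'
#' Pools a labeled subpopulation's 200 ms spike counts for one video (both
#' actor versions, all its trials plus their middle-2 s baselines) and fits
#' \code{count ~ cell + (1 | trialNumber:bin) + (1 | subjectID:neuronID)}
#' with the NB2 family, where \code{cell} has the pooled baseline as
#' reference and one level per actor x video-bin, so "differs from
#' baseline" is a within-model contrast. The subject:neuron intercept
#' absorbs per-unit baseline rate differences; with a single subject the
#' grouping degenerates to neuron identity (a warning is emitted when
#' subject-level variance is inestimable).
#'
#' @param records Spike-count records of the subpopulation (e.g. the
#'   pigeon-selective units of one region).
#' @param video Video identifier as behavior + exemplar, e.g.
#'   \code{"courtship1"}.
#' @param family,control Passed to [fit_glmm()].
#' @return A [fit_glmm()] object.
#' @export
fit_m2 <- function(records, video, family = "nbinom2",
                   control = glmm_control()) {
  d <- .prepare_m2_data(records, video)
  if (length(unique(d$subject_id)) < 2)
    warning("single subject: subject-level variance inestimable, ",
            "random intercept reduces to neuron identity")
  if (nlevels(d$subjNeuron) >= 2) {
    fit_glmm(count ~ cell + (1 | trialBin) + (1 | subjNeuron),
             data = d, family = family, control = control)
  } else {
    fit_glmm(count ~ cell + (1 | trialBin),
             data = d, family = family, control = control)
  }
}

# cell coefficients of one actor as a tidy table
.m2_cells <- function(fit, actor) {
  nm <- names(fit$beta)
  pat <- paste0("^cell", actor, "\\.b([0-9]+)$")
  hit <- grepl(pat, nm)
  data.frame(term = nm[hit],
             bin_index = as.integer(sub(pat, "\\1", nm[hit])),
             stringsAsFactors = FALSE)
}

#' Locate video bins whose population activity departs from baseline
#'
#' Tests each pigeon-actor video bin against the pooled baseline (Wald z on
#' the cell coefficient), Holm-adjusted across the bins of the video.
#'
#' @param fit A [fit_m2()] result.
#' @param alpha Significance level.
#' @param actor Actor whose marginal activity is tested against baseline
#'   (default \code{"pigeon"}, the subpopulation's preferred actor).
#' @return Data frame with one row per video bin: estimate (log-rate
#'   difference from baseline), se, z, raw and Holm-adjusted p, and
#'   \code{sig}.
#' @export
significant_bins <- function(fit, alpha = 0.05, actor = "pigeon") {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!fit$converged) warning("bin detection on a non-converged fit")
  cells <- .m2_cells(fit, actor)
  est <- fit$beta[cells$term]
  se <- fit$se[cells$term]
  p_raw <- 2 * pnorm(-abs(est / se))
  p_adj <- holm_adjust(p_raw)
  out <- data.frame(bin_index = cells$bin_index, estimate = unname(est),
                    se = unname(se), z = unname(est / se),
                    p_raw = unname(p_raw), p_adj = unname(p_adj),
                    sig = unname(p_adj < alpha), stringsAsFactors = FALSE)
  out[order(out$bin_index), ]
}

#' Pigeon-vs-greeble contrasts within selected bins
#'
#' For each supplied bin (typically the bins flagged by
#' [significant_bins()]), contrasts the pigeon and greeble cell estimates
#' (difference of log rates), with Holm adjustment across the supplied
#' bins.
#'
#' @param fit A [fit_m2()] result.
#' @param bins Integer vector of video bin indices; an empty vector yields
#'   an empty result.
#' @param alpha Significance level.
#' @return Data frame with one row per bin: estimate (pigeon minus greeble,
#'   log scale), se, z, raw and Holm-adjusted p, \code{sig}.
#' @export
actor_contrast_in_bins <- function(fit, bins, alpha = 0.05) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (length(bins) == 0)
    return(data.frame(bin_index = integer(0), estimate = numeric(0),
                      se = numeric(0), z = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), sig = logical(0)))
  tp <- paste0("cellpigeon.b", bins)
  tg <- paste0("cellgreeble.b", bins)
  missing <- c(tp, tg)[!c(tp, tg) %in% names(fit$beta)]
  if (length(missing)) stop("bins not in the model: ",
                            paste(missing, collapse = ", "))
  V <- fit$vcov_beta
  est <- fit$beta[tp] - fit$beta[tg]
  se <- sqrt(pmax(diag(V)[tp] + diag(V)[tg] - 2 * V[cbind(tp, tg)], 0))
  z <- est / se
  p_raw <- 2 * pnorm(-abs(z))
  p_adj <- holm_adjust(p_raw)
  data.frame(bin_index = bins, estimate = unname(est), se = unname(se),
             z = unname(z), p_raw = unname(p_raw), p_adj = unname(p_adj),
             sig = unname(p_adj < alpha), stringsAsFactors = FALSE)
}

#' Population time-course analysis across videos
#'
#' Runs [fit_m2()], [significant_bins()] and [actor_contrast_in_bins()] for
#' each requested video and assembles the per-bin results. Actor contrasts
#' are computed only in the bins whose baseline contrast is significant.
#'
#' @param records Subpopulation spike-count records.
#' @param videos Character vector of behavior+exemplar identifiers; default
#'   all non-two-pigeon videos present.
#' @param alpha Significance level.
#' @param family,control Passed to the model fits.
#' @return Named list per video with elements \code{fit}, \code{bins}
#'   (baseline contrasts) and \code{actor} (actor contrasts in the
#'   significant bins).
#' @export
timecourse_analysis <- function(records, videos = NULL, alpha = 0.05,
                                family = "nbinom2",
                                control = glmm_control()) {
  if (is.null(videos)) {
    vr <- records[records$phase == "video" & records$behavior != "twoPigeon", ]
    videos <- sort(unique(paste0(vr$behavior, vr$exemplar)))
  }
  out <- list()
  for (v in videos) {
    fit <- fit_m2(records, v, family = family, control = control)
    bins <- significant_bins(fit, alpha = alpha)
    ac <- actor_contrast_in_bins(fit, bins$bin_index[bins$sig], alpha = alpha)
    out[[v]] <- list(fit = fit, bins = bins, actor = ac)
  }
  out
}
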