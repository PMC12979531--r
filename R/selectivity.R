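# Data prep for the per-unit model: one combined condition factor whose
# reference level is the pooled baseline, so every video-cell coefficient is
# the modulation of that actor x behavior cell relative to baseline; the
# actor x sound interaction enters as one indicator per actor (sound-on
# video bins of that actor), keeping the design full rank.
.prepare_m1_data <- function(records) {
  d <- records
  d$condition <- ifelse(d$phase == "baseline", "baseline",
                        paste(d$actor, d$behavior, sep = "."))
  lev <- c("baseline", sort(unique(d$condition[d$condition != "baseline"])))
  d$condition <- factor(d$condition, levels = lev)
  d$pigeonSound <- as.numeric(d$phase == "video" & d$actor == "pigeon" &
                                d$sound == "on")
  d$greebleSound <- as.numeric(d$phase == "video" & d$actor == "greeble" &
                                 d$sound == "on")
  d$trialNumber <- factor(d$trial_number)
  d
}

#' Fit the per-unit selectivity model to one neuron's spike counts
#'
#' The model regresses 200 ms spike counts on a combined condition factor
#' (pooled baseline as reference; one level per actor x behavior cell,
#' including the two-pigeon videos as their own behavior level) plus one
#' sound-on indicator per actor (the actor x sound interaction), with a
#' trial-level random intercept:
#' \code{count ~ condition + pigeonSound + greebleSound + (1 | trialNumber)},
#' NB2 family. The data are the middle 2 s of each trial's baseline plus the
#' full video presentation.
#'
#' @param records Spike-count records of a single neuron (rows of a
#'   [simulate_spike_counts()] table).
#' @param family Count family, default \code{"nbinom2"}.
#' @param control Engine control, see [glmm_control()].
#' @return A [fit_glmm()] object (check \code{$singular}: singular units are
#'   excluded downstream rather than raising).
#' @export
fit_m1 <- function(records, family = "nbinom2", control = glmm_control()) {
  if (length(unique(records$neuron_id)) != 1)
    stop("fit_m1 expects the records of exactly one neuron")
  d <- .prepare_m1_data(records)
  fit_glmm(count ~ condition + pigeonSound + greebleSound + (1 | trialNumber),
           data = d, family = family, control = control)
}

# parse "conditionpigeon.courtship" style coefficient names into cells
.m1_cells <- function(fit) {
  nm <- names(fit$beta)
  cell <- grepl("^condition", nm) & nm != "conditionbaseline"
  cells <- sub("^condition", "", nm[cell])
  parts <- strsplit(cells, ".", fixed = TRUE)
  data.frame(term = nm[cell],
             actor = vapply(parts, `[`, "", 1),
             behavior = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Classify one unit's selectivity from its fitted model
#'
#' Applies the deterministic taxonomy to the pattern of significant
#' baseline-vs-cell contrasts (Wald z per cell coefficient, Holm-adjusted
#' within the unit): a unit is \emph{actor-selective} when exclusively one
#' actor's cells are modulated across two or more behaviors (or, with
#' opposite uniform signs for the two actors, \code{mixed_sign});
#' \emph{behavior-selective} when exactly one behavior is modulated under
#' both actors; \emph{actor-and-behavior-selective} when exactly one
#' actor x behavior cell is modulated; \emph{visually selective} when every
#' behavior is modulated under both actors with a common sign (stimulus
#' presence without content specificity); \emph{other} covers
#' multi-behavior patterns and two-pigeon-dominant units; otherwise
#' \emph{non-selective}. Sound modulation is flagged when either actor's
#' sound-on coefficient survives a Holm adjustment of the two sound tests.
#'
#' @param fit A [fit_m1()] result.
#' @param alpha Significance level (0.05).
#' @return List of class \code{"selectivity_label"}: \code{category},
#'   \code{detail}, \code{sound_modulated}, and the full contrast
#'   \code{pattern} table for audit. Singular or non-converged fits return
#'   category \code{"excluded"}.
#' @export
classify_unit <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (fit$singular || !fit$converged) {
    return(structure(list(category = "excluded", detail = NA_character_,
                          sound_modulated = NA, pattern = NULL),
                     class = "selectivity_label"))
  }
  cells <- .m1_cells(fit)
  est <- fit$beta[cells$term]
  se <- fit$se[cells$term]
  p_raw <- 2 * pnorm(-abs(est / se))
  p_adj <- holm_adjust(p_raw)
  sig <- p_adj < alpha
  pattern <- data.frame(cells, estimate = unname(est), se = unname(se),
                        p_raw = unname(p_raw), p_adj = unname(p_adj),
                        sig = unname(sig), stringsAsFactors = FALSE)

  main <- pattern[pattern$behavior != "twoPigeon", ]
  behaviors <- unique(main$behavior)
  P <- main$behavior[main$sig & main$actor == "pigeon"]
  G <- main$behavior[main$sig & main$actor == "greeble"]
  tp_row <- pattern[pattern$behavior == "twoPigeon", ]
  TP <- nrow(tp_row) > 0 && any(tp_row$sig)
  sign_of <- function(actor) {
    s <- sign(main$estimate[main$sig & main$actor == actor])
    if (length(unique(s)) == 1) unique(s) else 0
  }
  nsig <- length(P) + length(G)

  res <- if (nsig == 0 && !TP) {
    list(category = "non_selective", detail = NA_character_)
  } else if (TP && nsig <= 1) {
    list(category = "other", detail = "two_pigeon")
  } else if (nsig == 1) {
    a <- main$actor[main$sig]; b <- main$behavior[main$sig]
    list(category = "actor_and_behavior_selective", detail = paste(a, b, sep = "."))
  } else if (length(G) == 0) {
    list(category = "actor_selective", detail = "pigeon")
  } else if (length(P) == 0) {
    list(category = "actor_selective", detail = "greeble")
  } else if (setequal(P, G) && length(P) == 1 &&
             sign_of("pigeon") == sign_of("greeble") && sign_of("pigeon") != 0) {
    list(category = "behavior_selective", detail = P)
  } else if (sign_of("pigeon") != 0 && sign_of("greeble") != 0 &&
             sign_of("pigeon") != sign_of("greeble")) {
    list(category = "actor_selective", detail = "mixed_sign")
  } else if (setequal(P, behaviors) && setequal(G, behaviors)) {
    list(category = "visually_selective", detail = NA_character_)
  } else {
    list(category = "other", detail = "multi_behavior")
  }

  snd_terms <- c("pigeonSound", "greebleSound")
  snd_terms <- snd_terms[snd_terms %in% names(fit$beta)]
  snd_p <- 2 * pnorm(-abs(fit$beta[snd_terms] / fit$se[snd_terms]))
  sound_modulated <- length(snd_p) > 0 && any(holm_adjust(snd_p) < alpha)

  structure(c(res, list(sound_modulated = sound_modulated, pattern = pattern,
                        sound_p = snd_p)),
            class = "selectivity_label")
}

#' @export
print.selectivity_label <- function(x, ...) {
  cat("Selectivity:", x$category,
      if (!is.na(x$detail)) paste0("(", x$detail, ")") else "",
      if (isTRUE(x$sound_modulated)) "[sound modulated]" else "", "\n")
  invisible(x)
}

#' Fit and classify every neuron in a spike-count table
#'
#' @param records A [simulate_spike_counts()]-style table covering one or
#'   more neurons.
#' @param alpha Significance level for [classify_unit()].
#' @param family,control Passed to [fit_m1()].
#' @param keep_fits Keep the per-neuron model fits in the result (memory
#'   heavy for large populations).
#' @return A data frame with one row per neuron: \code{neuron_id},
#'   \code{subject_id}, \code{region}, \code{category}, \code{detail},
#'   \code{sound_modulated}, \code{singular}. Fits (if kept) and labels are
#'   attached as attributes \code{"fits"} and \code{"labels"}.
#' @export
classify_population <- function(records, alpha = 0.05, family = "nbinom2",
                                control = glmm_control(), keep_fits = FALSE) {
  ids <- unique(records$neuron_id)
  rows <- vector("list", length(ids))
  fits <- if (keep_fits) vector("list", length(ids)) else NULL
  labels <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rec <- records[records$neuron_id == ids[i], ]
    fit <- fit_m1(rec, family = family, control = control)
    lab <- classify_unit(fit, alpha = alpha)
    labels[[i]] <- lab
    if (keep_fits) fits[[i]] <- fit
    rows[[i]] <- data.frame(neuron_id = ids[i],
                            subject_id = rec$subject_id[1],
                            region = rec$region[1],
                            category = lab$category,
                            detail = if (is.na(lab$detail)) NA_character_ else lab$detail,
                            sound_modulated = lab$sound_modulated,
                            singular = fit$singular,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "labels") <- setNames(labels, ids)
  if (keep_fits) attr(out, "fits") <- setNames(fits, ids)
  out
}

#' Tabulate selectivity categories by region
#'
#' @param labels A [classify_population()] result (or any data frame with
#'   \code{region} and \code{category} columns).
#' @return A data frame of counts (categories x regions); percentages over
#'   task-modulated units (categories other than non-selective/excluded)
#'   are attached as attribute \code{"percent"}.
#' @export
region_summary <- function(labels) {
  tab <- table(category = labels$category, region = labels$region)
  counts <- as.data.frame.matrix(tab)
  task_mod <- labels$category != "non_selective" & labels$category != "excluded"
  denom <- table(factor(labels$region[task_mod],
                        levels = colnames(counts)))
  pct <- sweep(as.matrix(counts), 2, pmax(as.numeric(denom), 1), "/") * 100
  structure(counts, percent = round(pct, 1),
            task_modulated = as.numeric(denom))
}

#' Pairwise between-region comparison of a label's prevalence
#'
#' For every pair of regions, tests whether the proportion of units with
#' the given category (or the sound-modulated flag) differs, using the
#' chi-squared / Fisher rule of [proportion_test()], Holm-adjusted across
#' the pairs. The denominator is the region's task-modulated units.
#'
#' @param labels A [classify_population()] result.
#' @param category A category name, or \code{"sound_modulated"} for the
#'   sound flag.
#' @param denominator \code{"task_modulated"} (default) or \code{"all"}
#'   classified units.
#' @return Data frame with one row per region pair: counts, statistic,
#'   method, raw and Holm-adjusted p-values.
#' @export
compare_regions <- function(labels, category,
                            denominator = c("task_modulated", "all")) {
  denominator <- match.arg(denominator)
  labels <- labels[labels$category != "excluded", ]
  regions <- unique(labels$region)
  if (length(regions) < 2) stop("need at least two regions")
  in_denom <- if (denominator == "task_modulated")
    labels$category != "non_selective" else rep(TRUE, nrow(labels))
  hit <- if (category == "sound_modulated") labels$sound_modulated
  else labels$category == category
  pairs <- utils::combn(regions, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    na <- sum(in_denom & labels$region == a)
    nb <- sum(in_denom & labels$region == b)
    xa <- sum(hit & in_denom & labels$region == a)
    xb <- sum(hit & in_denom & labels$region == b)
    if (na == 0 || nb == 0) stop("region with no units in the denominator")
    pt <- proportion_test(xa, na, xb, nb)
    data.frame(region_a = a, region_b = b, count_a = xa, n_a = na,
               count_b = xb, n_b = nb, statistic = pt$statistic,
               method = pt$method, p_raw = pt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- holm_adjust(out$p_raw)
  out
}
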