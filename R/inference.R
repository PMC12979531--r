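#' Wald z-tests for every fixed-effect coefficient
#'
#' @param fit A [fit_glmm()] result.
#' @return A data frame with one row per coefficient: estimate, standard
#'   error, Wald z and two-sided normal p-value.
#' @export
wald_table <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!fit$converged) warning("Wald tests on a non-converged fit")
  z <- fit$beta / fit$se
  data.frame(term = names(fit$beta), estimate = unname(fit$beta),
             se = unname(fit$se), z = unname(z),
             p = unname(2 * pnorm(-abs(z))), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Compare two nested mixed-model fits
#'
#' Returns the AIC difference and the likelihood-ratio test of the richer
#' model against the nested one (e.g. NB2 against Poisson on the same
#' design, one extra dispersion parameter).
#'
#' @param fit_a,fit_b Two [fit_glmm()] results on the same data; the one with
#'   fewer parameters is treated as the nested model.
#' @return List with \code{delta_aic} (AIC of the richer model minus the
#'   nested one), \code{chisq}, \code{df} and \code{p}.
#' @export
compare_models <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "glmm_fit"), inherits(fit_b, "glmm_fit"))
  if (fit_a$n_obs != fit_b$n_obs)
    stop("models were fitted to different numbers of observations")
  if (!isTRUE(all.equal(sum(fit_a$y), sum(fit_b$y))))
    stop("models do not share a response; LRT undefined")
  nested <- if (fit_a$df <= fit_b$df) fit_a else fit_b
  full <- if (fit_a$df <= fit_b$df) fit_b else fit_a
  chisq <- max(0, 2 * (full$logLik - nested$logLik))
  df <- full$df - nested$df
  p <- if (df > 0) pchisq(chisq, df, lower.tail = FALSE) else NA_real_
  list(delta_aic = full$AIC - nested$AIC, chisq = chisq, df = df, p = p)
}

# Simulate response vectors from a fitted model, drawing fresh random
# intercepts from the estimated variances.
.simulate_fit <- function(fit, nsim) {
  eta_fix <- as.vector(fit$X %*% fit$beta)
  n <- fit$n_obs
  out <- matrix(0L, nrow = n, ncol = nsim)
  for (s in seq_len(nsim)) {
    eta <- eta_fix
    for (g in names(fit$group_factors)) {
      f <- fit$group_factors[[g]]
      u <- rnorm(nlevels(f), 0, fit$sigma[[g]])
      eta <- eta + u[as.integer(f)]
    }
    mu <- exp(pmin(eta, 30))
    out[, s] <- if (fit$family == "poisson") rpois(n, mu)
    else rnbinom(n, size = fit$theta, mu = mu)
  }
  out
}

#' Simulation-based zero-inflation diagnostic
#'
#' Compares the observed number of zero counts with the distribution of zero
#' counts in data simulated from the fitted model (fresh random intercepts
#' each replicate). A ratio near 1 with a large p-value indicates the model
#' accounts for the zeros.
#'
#' @param fit A converged [fit_glmm()] result.
#' @param n_sims Number of simulated replicates (values below 100 trigger a
#'   warning; the p-value resolution is 1/\code{n_sims}).
#' @param seed Integer seed for the simulation.
#' @return List with \code{ratio} (observed zeros / mean simulated zeros),
#'   two-sided \code{p}, \code{observed} and the simulated zero counts.
#' @export
zero_inflation_check <- function(fit, n_sims = 250, seed = 1) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!fit$converged) stop("zero-inflation check requires a converged fit")
  if (n_sims < 100) warning("n_sims < 100: zero-inflation p-value is coarse")
  set.seed(seed)
  sims <- .simulate_fit(fit, n_sims)
  zeros_sim <- colSums(sims == 0)
  obs <- sum(fit$y == 0)
  ratio <- obs / max(mean(zeros_sim), 1e-12)
  p_lo <- (sum(zeros_sim <= obs) + 1) / (n_sims + 1)
  p_hi <- (sum(zeros_sim >= obs) + 1) / (n_sims + 1)
  list(ratio = ratio, p = min(1, 2 * min(p_lo, p_hi)),
       observed = obs, simulated = zeros_sim)
}

#' Estimated marginal means on the link scale
#'
#' Builds the full grid of the model's fixed-effect factors, predicts each
#' cell on the link (log) scale, and averages the cells with equal weights
#' over every factor not listed in \code{keep}. The covariance of the
#' marginal means is propagated from the coefficient covariance.
#'
#' @param fit A [fit_glmm()] result.
#' @param keep Character vector of factor names to retain (empty: the grand
#'   mean over the whole grid).
#' @return A data frame of kept factor combinations with \code{emmean} and
#'   \code{se}; the full covariance matrix is attached as attribute
#'   \code{"vcov"} and the averaging matrix as \code{"L"}.
#' @export
marginal_means <- function(fit, keep = character(0)) {
  stopifnot(inherits(fit, "glmm_fit"))
  xlev <- fit$xlev
  if (length(xlev) == 0) {
    est <- fit$beta[1]
    out <- data.frame(emmean = unname(est), se = fit$se[1])
    attr(out, "vcov") <- fit$vcov_beta[1, 1, drop = FALSE]
    return(out)
  }
  unknown <- setdiff(keep, names(xlev))
  if (length(unknown)) stop("factor(s) not in the model: ",
                            paste(unknown, collapse = ", "))
  grid <- expand.grid(xlev, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (nm in names(xlev)) grid[[nm]] <- factor(grid[[nm]], levels = xlev[[nm]])
  Xg <- model.matrix(fit$fixed_terms, grid, contrasts.arg = fit$contrasts)
  if (length(keep)) {
    key <- interaction(grid[keep], drop = FALSE, sep = " / ")
    L <- t(vapply(levels(key), function(k) colMeans(Xg[key == k, , drop = FALSE]),
                  numeric(ncol(Xg))))
    cells <- unique(grid[keep])
    cells <- cells[order(interaction(cells, sep = " / ")), , drop = FALSE]
  } else {
    L <- matrix(colMeans(Xg), nrow = 1)
    cells <- data.frame(row.names = "overall")
  }
  est <- as.vector(L %*% fit$beta)
  V <- L %*% fit$vcov_beta %*% t(L)
  out <- cbind(cells, data.frame(emmean = est, se = sqrt(pmax(diag(V), 0))))
  rownames(out) <- NULL
  attr(out, "vcov") <- V
  attr(out, "L") <- L
  out
}

#' Holm (step-down Bonferroni) adjustment
#'
#' @param p_values Numeric vector of raw p-values in \code{[0, 1]} (may be
#'   empty). Input order is preserved.
#' @return Adjusted p-values, same length and order.
#' @export
holm_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "holm")
}

#' Two-sample proportion test with the small-expected-count rule
#'
#' Compares \code{count_a / n_a} with \code{count_b / n_b} using a 2x2
#' chi-squared test without continuity correction when all expected cell
#' counts are at least 5, and a two-sided Fisher exact test otherwise.
#'
#' @param count_a,n_a Successes and group size for the first group.
#' @param count_b,n_b Successes and group size for the second group.
#' @return List with \code{statistic} (chi-squared; \code{NA} for Fisher),
#'   \code{p}, \code{method}, and the expected-count matrix used for the
#'   rule.
#' @export
proportion_test <- function(count_a, n_a, count_b, n_b) {
  if (n_a <= 0 || n_b <= 0) stop("group sizes must be positive")
  if (count_a > n_a || count_b > n_b || count_a < 0 || count_b < 0)
    stop("counts must lie between 0 and the group size")
  tab <- matrix(c(count_a, n_a - count_a, count_b, n_b - count_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("yes", "no")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p = ct$p.value,
         method = "chisq", expected = expected)
  } else {
    ft <- fisher.test(tab)
    list(statistic = NA_real_, p = ft$p.value,
         method = "fisher", expected = expected)
  }
}
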