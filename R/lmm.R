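#' Fit the random-intercept population model by EM
#'
#' Fits \eqn{Y_{ij} = \mu_i + \epsilon_{ij}} with
#' \eqn{\mu_i \sim N(\mu, \tau^2)} and \eqn{\epsilon_{ij} \sim N(0,
#' \sigma_i^2)} — a random-intercept linear mixed model in which every
#' subject carries its own residual variance — by
#' expectation-maximisation over the latent intercepts. The E-step gives
#' each subject's posterior intercept moments
#' \deqn{m_i = \frac{\mu/\tau^2 + n_i \bar{y}_i/\sigma_i^2}
#'                  {1/\tau^2 + n_i/\sigma_i^2}, \qquad
#'       v_i = \frac{1}{1/\tau^2 + n_i/\sigma_i^2},}
#' and the M-step updates
#' \eqn{\mu = \frac{1}{I}\sum m_i},
#' \eqn{\tau^2 = \frac{1}{I}\sum [(m_i - \mu)^2 + v_i]},
#' \eqn{\sigma_i^2 = \frac{1}{n_i}\sum_j [(y_{ij} - m_i)^2 + v_i]}.
#' Only per-subject summary statistics \eqn{(n_i, \bar{y}_i, ss_i)} are
#' touched, so the fit is cheap at any series length. The marginal
#' log-likelihood is evaluated every iteration and is non-decreasing (this
#' is exact EM for the stated model, up to the variance floor).
#'
#' @param control A [series_collection()] (or list of
#'   [longitudinal_series()]) of control subjects; at least 2 subjects, each
#'   with \eqn{n_i \ge 1} and at least one with \eqn{n_i \ge 2}.
#' @param rtol Relative log-likelihood change declaring convergence.
#' @param max_iter Iteration cap; `converged` reports honestly.
#' @param var_floor Floor \eqn{\epsilon > 0} applied to \eqn{\tau^2} and
#'   every \eqn{\sigma_i^2} so the predictive interval stays finite.
#'
#' @return An object of class `population_model`: `mu`, `tau2`,
#'   `sigma2_by_subject` (named), `sigma2_pooled` (their mean), `posterior`
#'   (data frame of \eqn{m_i, v_i, n_i}), `loglik_trace`, `converged`,
#'   `n_iter`, `degenerate`.
#' @export
fit_population_em <- function(control, rtol = 1e-8, max_iter = 500L,
                              var_floor = 1e-8) {
  if (inherits(control, "longitudinal_series")) control <- list(control)
  if (length(control) < 2L)
    stop("population fit needs at least 2 subjects")
  ids <- vapply(control, function(s) s$subject_id, character(1))
  n_i <- vapply(control, function(s) length(s$values), numeric(1))
  ybar <- vapply(control, function(s) mean(s$values), numeric(1))
  ss <- vapply(control, function(s) sum((s$values - mean(s$values))^2),
               numeric(1))
  if (any(n_i < 1L)) stop("every subject needs at least one observation")
  if (!any(n_i >= 2L))
    stop("at least one subject must have two or more observations")
  I <- length(control)

  # init: grand mean; between-variance from subject means; per-subject
  # sample variances (subjects with a single value borrow the others' mean)
  mu <- sum(n_i * ybar) / sum(n_i)
  tau2 <- max(stats::var(ybar), var_floor)
  sig2 <- ifelse(n_i >= 2L, ss / pmax(n_i - 1, 1), NA_real_)
  sig2[is.na(sig2)] <- mean(sig2, na.rm = TRUE)
  sig2 <- pmax(sig2, var_floor)

  loglik <- function(mu, tau2, sig2) {
    marg <- tau2 + sig2 / n_i
    sum(-0.5 * n_i * log(2 * pi * sig2) - ss / (2 * sig2) +
          0.5 * log(sig2 / n_i) - 0.5 * log(marg) -
          0.5 * (ybar - mu)^2 / marg)
  }

  trace <- numeric(0)
  ll_old <- loglik(mu, tau2, sig2)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step: posterior moments of the random intercepts
    prec <- 1 / tau2 + n_i / sig2
    v <- 1 / prec
    m <- (mu / tau2 + n_i * ybar / sig2) / prec
    # M-step
    mu <- mean(m)
    tau2 <- max(mean((m - mu)^2 + v), var_floor)
    sig2 <- pmax((ss + n_i * (ybar - m)^2 + n_i * v) / n_i, var_floor)
    ll <- loglik(mu, tau2, sig2)
    trace <- c(trace, ll)
    if (abs(ll - ll_old) < rtol * (abs(ll_old) + rtol)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  # final posterior under the returned parameters
  prec <- 1 / tau2 + n_i / sig2
  posterior <- data.frame(subject = ids, m = (mu / tau2 + n_i * ybar / sig2) / prec,
                          v = 1 / prec, n = n_i, stringsAsFactors = FALSE)
  degenerate <- tau2 <= var_floor && all(sig2 <= var_floor)
  if (degenerate)
    warning("degenerate fit: no variation in the control data; ",
            "tau2 and all sigma_i^2 are at the variance floor")
  names(sig2) <- ids
  structure(list(mu = mu, tau2 = tau2, sigma2_by_subject = sig2,
                 sigma2_pooled = mean(sig2), posterior = posterior,
                 loglik_trace = trace, converged = converged, n_iter = iter,
                 degenerate = degenerate, var_floor = var_floor),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("<population_model> random-intercept LMM,",
      nrow(x$posterior), "control subjects\n")
  cat(sprintf("  mu = %.4g  tau2 = %.4g  mean sigma_i^2 = %.4g\n",
              x$mu, x$tau2, x$sigma2_pooled))
  cat(sprintf("  EM: %d iterations, converged = %s%s\n", x$n_iter,
              x$converged, if (x$degenerate) " (DEGENERATE)" else ""))
  invisible(x)
}

#' Per-occasion state for the LMM range
#'
#' Carries the pieces the predictive interval needs at occasion \eqn{j}: the
#' history count \eqn{j - 1}, the history mean \eqn{\bar{y}_{i(j-1)}} and
#' the working within-subject variance \eqn{\hat\sigma_i^2(j)} plugged into
#' the interval.
#'
#' @param n_history Number of prior admissible observations (\eqn{j - 1},
#'   may be 0 for a brand-new subject).
#' @param mean_history Their mean (ignored, may be `NA`, when `n_history` is 0).
#' @param sigma2 Working within-subject variance (> 0); see
#'   [update_subject_variance()] for the default rule.
#' @return An object of class `lmm_state`.
#' @export
lmm_state <- function(n_history, mean_history, sigma2) {
  n_history <- as.integer(n_history)
  stopifnot(n_history >= 0L, is.finite(sigma2), sigma2 > 0)
  if (n_history > 0L && !is.finite(mean_history))
    stop("'mean_history' required when history is non-empty")
  structure(list(n_history = n_history, mean_history = mean_history,
                 sigma2 = sigma2),
            class = "lmm_state")
}

#' Working within-subject variance for a subject under assessment
#'
#' The predictive interval needs a within-subject variance for the assessed
#' subject before that subject has contributed enough data to estimate one.
#' The default is a pooled-shrinkage rule blending the population's central
#' variance with the subject's accruing sum of squares,
#' \deqn{\hat\sigma_i^2(j) = \frac{a\,\bar\sigma^2 + ss_i}{a + \max(j-2, 0)},}
#' where \eqn{\bar\sigma^2} is the mean fitted within-subject variance of
#' the control population, \eqn{ss_i} the history's sum of squared
#' deviations and \eqn{a} a pseudo-observation count. With no usable history
#' (\eqn{j \le 2}) this is the pooled variance; as \eqn{j} grows it
#' converges to the subject's own sample variance; `a = 0` drops pooling
#' entirely.
#'
#' @param model A fitted [fit_population_em()] model.
#' @param history A [subject_summary()] (or numeric vector) of the
#'   subject's admissible history; may be empty.
#' @param a Pseudo-observation weight of the pooled variance (default 3).
#' @return The working variance \eqn{\hat\sigma_i^2(j)}, a positive scalar.
#' @export
update_subject_variance <- function(model, history = subject_summary(),
                                    a = 3) {
  stopifnot(inherits(model, "population_model"), a >= 0)
  history <- as_subject_summary(history)
  j <- history$n + 1L                      # occasion being predicted
  denom <- a + max(j - 2L, 0L)
  if (denom <= 0) return(model$sigma2_pooled)   # a = 0 with no history
  max((a * model$sigma2_pooled + history$ss) / denom, model$var_floor)
}

#' Population-informed adaptive reference range (LMM method)
#'
#' Empirical-Bayes prediction interval for a subject's \eqn{j}-th
#' observation, combining the fitted population parameters with the
#' subject's own history. The centre is the precision-weighted (shrinkage)
#' average of the population mean and the history mean,
#' \deqn{\frac{\hat\mu/\hat\tau^2 + (j-1)\bar{y}_{i(j-1)}/\hat\sigma_i^2}
#'            {1/\hat\tau^2 + (j-1)/\hat\sigma_i^2},}
#' and the half-width is
#' \eqn{z_{1-\alpha/2}\sqrt{1/(1/\hat\tau^2 + (j-1)/\hat\sigma_i^2) +
#' \hat\sigma_i^2}} (Normal quantile: the population parameters are treated
#' as known once fitted). At \eqn{j = 1} this is the population prediction
#' interval \eqn{\hat\mu \pm z\sqrt{\hat\tau^2 + \hat\sigma_i^2}}; as
#' \eqn{j \to \infty} it converges to the subject-specific interval
#' \eqn{\bar{y}_i \pm z \hat\sigma_i}.
#'
#' @param model A fitted [fit_population_em()] model.
#' @param state An [lmm_state()]; alternatively a numeric vector of the
#'   admissible history, in which case the working variance comes from
#'   [update_subject_variance()] with its defaults.
#' @param alpha Significance level in (0, 1).
#' @param sidedness `"two_sided"` or `"upper_only"` (lower limit clamped to 0).
#' @param occasion Occasion index the range applies to (defaults to
#'   `n_history + 1`).
#' @return A [reference_range()] with `method = "lmm"`.
#' @export
lmm_range <- function(model, state, alpha = 0.05,
                      sidedness = c("two_sided", "upper_only"),
                      occasion = NULL) {
  stopifnot(inherits(model, "population_model"))
  sidedness <- match.arg(sidedness)
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must lie in (0, 1)")
  if (is.numeric(state) || inherits(state, "subject_summary")) {
    h <- as_subject_summary(state)
    state <- lmm_state(h$n, h$mean, update_subject_variance(model, h))
  }
  stopifnot(inherits(state, "lmm_state"))
  k <- state$n_history
  prec <- 1 / model$tau2 + k / state$sigma2
  centre <- (model$mu / model$tau2 +
               if (k > 0L) k * state$mean_history / state$sigma2 else 0) / prec
  pred_sd <- sqrt(1 / prec + state$sigma2)
  if (is.null(occasion)) occasion <- k + 1L
  if (sidedness == "two_sided") {
    z <- stats::qnorm(1 - alpha / 2)
    lower <- centre - z * pred_sd
    upper <- centre + z * pred_sd
  } else {
    z <- stats::qnorm(1 - alpha)
    lower <- 0
    upper <- max(centre + z * pred_sd, 0)
  }
  reference_range(lower, upper, alpha = alpha, sidedness = sidedness,
                  occasion = occasion, method = "lmm")
}
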