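#' One cell of the simulation scenario grid
#'
#' A scenario fixes the between-subject SD \eqn{\tau}, the within- to
#' between-SD ratio \eqn{r} (hence \eqn{\sigma_i = r\tau} for every
#' subject), the population mean and the sampling counts of the
#' false-positive study.
#'
#' @param between_sd Between-subject standard deviation \eqn{\tau}.
#' @param ratio Within- to between-subject SD ratio \eqn{r}.
#' @param mu Population mean (default 5).
#' @param n_subjects_pop Subjects generated per scenario (default 1000).
#' @param n_per_subject Measurements per subject \eqn{n_i} (default 100).
#' @param n_sampled Subjects drawn for assessment (default 100).
#' @param n_control Control subjects for the population fit (default 120).
#' @param seed Integer seed, or `NA` to inherit the caller's RNG stream.
#' @return An object of class `scenario_spec`; `within_sd` is `ratio *
#'   between_sd` exactly.
#' @export
scenario_spec <- function(between_sd, ratio, mu = 5, n_subjects_pop = 1000L,
                          n_per_subject = 100L, n_sampled = 100L,
                          n_control = 120L, seed = NA_integer_) {
  stopifnot(between_sd > 0, ratio > 0, n_subjects_pop >= 1, n_per_subject >= 1,
            n_sampled >= 1, n_control >= 1)
  structure(list(between_sd = between_sd, ratio = ratio,
                 within_sd = ratio * between_sd, mu = mu,
                 n_subjects_pop = as.integer(n_subjects_pop),
                 n_per_subject = as.integer(n_per_subject),
                 n_sampled = as.integer(n_sampled),
                 n_control = as.integer(n_control),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' The 36-scenario variability grid
#'
#' Crosses 12 within- to between-SD ratios (0.001 to 5) with three
#' between-subject SDs (0.5, 1, 2); the implied within-subject SDs span
#' 0.0005 to 10. Extra arguments override the per-scenario counts, so the
#' same grid drives both full-scale and scaled-down studies.
#'
#' @param ratios,between_sds Grid axes (defaults are the canonical 12 x 3).
#' @param ... Passed on to [scenario_spec()] (e.g. `n_subjects_pop`,
#'   `n_sampled`).
#' @return A list of [scenario_spec()] of class `scenario_grid`, ordered
#'   ratio-major.
#' @export
#' @examples
#' g <- variability_grid()
#' length(g)             # 36
#' g[[8 * 3]]$within_sd  # ratio 0.250 x between 2 -> 0.5
variability_grid <- function(ratios = c(0.001, 0.005, 0.010, 0.025, 0.050,
                                        0.075, 0.100, 0.250, 0.500, 1.000,
                                        2.000, 5.000),
                             between_sds = c(0.5, 1, 2), ...) {
  grid <- list()
  for (r in ratios)
    for (b in between_sds)
      grid[[length(grid) + 1L]] <- scenario_spec(between_sd = b, ratio = r, ...)
  structure(grid, class = "scenario_grid")
}

#' @export
as.data.frame.scenario_grid <- function(x, ...) {
  do.call(rbind, lapply(x, function(s)
    data.frame(ratio = s$ratio, between_sd = s$between_sd,
               within_sd = s$within_sd, mu = s$mu,
               n_subjects_pop = s$n_subjects_pop,
               n_per_subject = s$n_per_subject)))
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat("<scenario_grid>", length(x), "scenarios\n")
  print(utils::head(as.data.frame(x), 6))
  if (length(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Simulate a population of longitudinal series from a scenario
#'
#' Draws subject means \eqn{\mu_i \sim N(\mu, \tau^2)} and measurements
#' \eqn{Y_{ij} = \mu_i + \epsilon_{ij}}, \eqn{\epsilon_{ij} \sim N(0,
#' \sigma_i^2)}, with a common \eqn{\sigma_i = r\tau} within the scenario.
#'
#' @param spec A [scenario_spec()]. When `spec$seed` is not `NA` the RNG is
#'   seeded first, making the scenario independently reproducible.
#' @return A [series_collection()] of `spec$n_subjects_pop` subjects.
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.na(spec$seed)) set.seed(spec$seed)
  I <- spec$n_subjects_pop
  n <- spec$n_per_subject
  mu_i <- stats::rnorm(I, spec$mu, spec$between_sd)
  y <- matrix(stats::rnorm(I * n, 0, spec$within_sd), nrow = I) + mu_i
  ids <- sprintf("S%04d", seq_len(I))
  series_collection(lapply(seq_len(I), function(i)
    longitudinal_series(ids[i], y[i, ])))
}

# ---- vectorised sequential flagging ----------------------------------------

# Sequential Z-score flags for one subject's full series at level alpha.
# Returns logical vector over occasions first_occasion..n (TRUE = flagged,
# NA = degenerate zero-variance history, skipped). qts may supply
# precomputed qt(1 - alpha/2, df = 1:(n-2)) to avoid repeated quantile calls.
zscore_flags_seq <- function(values, alpha = 0.05, first_occasion = 3L,
                             qts = NULL) {
  n <- length(values)
  if (n < first_occasion) return(logical(0))
  v <- values - mean(values)            # centring avoids cancellation
  k <- seq_len(n)
  cmean <- cumsum(v) / k
  css <- pmax(cumsum(v^2) - k * cmean^2, 0)
  occ <- first_occasion:n
  h <- occ - 1L                          # history length
  sd_h <- sqrt(css[h] / (h - 1))
  if (is.null(qts)) qts <- stats::qt(1 - alpha / 2, df = seq_len(n - 2))
  t_abs <- abs(v[occ] - cmean[h]) / (sd_h * sqrt(1 + 1 / h))
  out <- t_abs > qts[h - 1L]
  out[sd_h == 0] <- NA
  out
}

# Sequential two-sided LMM flags for one subject, model parameters given as
# scalars; working variance by the pooled-shrinkage rule with weight a.
lmm_flags_seq <- function(values, mu, tau2, sigma2_pooled, alpha = 0.05,
                          a = 3, first_occasion = 3L, var_floor = 1e-8) {
  n <- length(values)
  if (n < first_occasion) return(logical(0))
  v <- values - mean(values)
  k <- seq_len(n)
  cmean <- cumsum(v) / k + mean(values)
  css <- pmax(cumsum(v^2) - k * (cumsum(v) / k)^2, 0)
  occ <- first_occasion:n
  h <- occ - 1L
  sig2 <- pmax((a * sigma2_pooled + css[h]) / (a + pmax(occ - 2L, 0L)),
               var_floor)
  prec <- 1 / tau2 + h / sig2
  centre <- (mu / tau2 + h * cmean[h] / sig2) / prec
  half <- stats::qnorm(1 - alpha / 2) * sqrt(1 / prec + sig2)
  values[occ] < centre - half | values[occ] > centre + half
}

#' Run the false-positive-rate simulation study
#'
#' For every scenario: simulate the population, draw disjoint assessment and
#' control samples, fit the population model by EM on the control sample,
#' then walk each assessed subject's series computing sequential two-sided
#' reference ranges by both methods from `first_occasion` (default 3, the
#' first occasion at which the Z-score method is defined) to \eqn{n_i}. All
#' observations are generated from the null model, so every flag is a false
#' positive. Per-subject rates, per-occasion rate curves and pairwise
#' (LMM - Z-score) differences are returned.
#'
#' @param grid A [variability_grid()] / list of [scenario_spec()].
#' @param alpha Significance level (default 0.05).
#' @param seed Master seed; spawns one independent sub-seed per scenario so
#'   scenarios are individually reproducible.
#' @param a Pseudo-observation weight for the assessed subjects' working
#'   within-subject variance (see [update_subject_variance()]).
#' @param first_occasion First occasion entering rate denominators.
#' @param control_disjoint Draw the control sample disjoint from the
#'   assessment sample (default `TRUE`).
#' @return An object of class `simulation_result` with data frames
#'   `per_subject` (scenario, subject, method, fpr, flags, occasions,
#'   skipped), `per_occasion` (scenario, method, occasion, fpr),
#'   `differences` (per-subject LMM - Z-score), and a `summary` list of
#'   medians and quartiles by method.
#' @export
run_simulation_study <- function(grid, alpha = 0.05, seed = 1L, a = 3,
                                 first_occasion = 3L,
                                 control_disjoint = TRUE) {
  if (inherits(grid, "scenario_spec")) grid <- list(grid)
  stopifnot(length(grid) >= 1)
  set.seed(seed)
  scen_seeds <- sample.int(.Machine$integer.max - 1L, length(grid))

  per_subject <- vector("list", length(grid))
  per_occasion <- vector("list", length(grid))
  for (sc in seq_along(grid)) {
    spec <- grid[[sc]]
    if (is.na(spec$seed)) spec$seed <- scen_seeds[sc]
    pop <- simulate_population(spec)
    if (control_disjoint &&
        spec$n_sampled + spec$n_control > spec$n_subjects_pop)
      stop("population too small for disjoint assessment + control samples")
    idx <- sample.int(length(pop), spec$n_sampled)
    pool <- if (control_disjoint) setdiff(seq_along(pop), idx)
            else seq_along(pop)
    cidx <- pool[sample.int(length(pool), spec$n_control)]
    model <- fit_population_em(pop[cidx])

    n <- spec$n_per_subject
    occ <- first_occasion:n
    qts <- stats::qt(1 - alpha / 2, df = seq_len(n - 2))
    zs_mat <- matrix(NA, length(idx), length(occ))
    lm_mat <- matrix(NA, length(idx), length(occ))
    for (i in seq_along(idx)) {
      y <- pop[[idx[i]]]$values
      zs_mat[i, ] <- zscore_flags_seq(y, alpha, first_occasion, qts)
      lm_mat[i, ] <- lmm_flags_seq(y, model$mu, model$tau2,
                                   model$sigma2_pooled, alpha, a,
                                   first_occasion, model$var_floor)
    }
    subj <- names(pop)[idx]
    rate <- function(mat) rowMeans(mat, na.rm = TRUE)
    per_subject[[sc]] <- data.frame(
      scenario = sc, ratio = spec$ratio, between_sd = spec$between_sd,
      subject = rep(subj, 2L),
      method = rep(c("zscore", "lmm"), each = length(idx)),
      fpr = c(rate(zs_mat), rate(lm_mat)),
      flags = c(rowSums(zs_mat, na.rm = TRUE), rowSums(lm_mat, na.rm = TRUE)),
      occasions = c(rowSums(!is.na(zs_mat)), rowSums(!is.na(lm_mat))),
      skipped = c(rowSums(is.na(zs_mat)), rowSums(is.na(lm_mat))),
      stringsAsFactors = FALSE)
    per_occasion[[sc]] <- data.frame(
      scenario = sc, ratio = spec$ratio, between_sd = spec$between_sd,
      method = rep(c("zscore", "lmm"), each = length(occ)),
      occasion = rep(occ, 2L),
      fpr = c(colMeans(zs_mat, na.rm = TRUE), colMeans(lm_mat, na.rm = TRUE)),
      stringsAsFactors = FALSE)
  }
  per_subject <- do.call(rbind, per_subject)
  per_occasion <- do.call(rbind, per_occasion)

  wide <- merge(
    per_subject[per_subject$method == "lmm",
                c("scenario", "subject", "fpr")],
    per_subject[per_subject$method == "zscore",
                c("scenario", "subject", "fpr")],
    by = c("scenario", "subject"), suffixes = c("_lmm", "_zscore"))
  differences <- data.frame(wide[c("scenario", "subject")],
                            diff = wide$fpr_lmm - wide$fpr_zscore)

  summarise <- function(m) {
    x <- per_subject$fpr[per_subject$method == m]
    c(median = stats::median(x), q1 = unname(stats::quantile(x, 0.25)),
      q3 = unname(stats::quantile(x, 0.75)), mean = mean(x))
  }
  structure(list(per_subject = per_subject, per_occasion = per_occasion,
                 differences = differences,
                 summary = list(zscore = summarise("zscore"),
                                lmm = summarise("lmm"),
                                median_diff = stats::median(differences$diff)),
                 alpha = alpha, seed = seed,
                 first_occasion = first_occasion),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>", length(unique(x$per_subject$scenario)),
      "scenarios,", length(unique(x$per_subject$subject)) *
        length(unique(x$per_subject$scenario)), "assessed series, alpha =",
      x$alpha, "\n")
  cat(sprintf("  median per-subject FPR: zscore %.3f | lmm %.3f\n",
              x$summary$zscore["median"], x$summary$lmm["median"]))
  invisible(x)
}

#' Generate an hsCRP-like labelled fixture collection
#'
#' Stands in for unpublished inflammation-marker data: nonnegative
#' log-normal baselines with occasional multiplicative spikes. Spiked
#' occasions are labelled `"abnormal"`, everything else `"normal"`; context
#' tags alternate `"pre"`/`"post"` to mimic pre-/post-match sampling. The
#' labels are synthetic ground truth for exercising evaluation machinery,
#' not a reproduction of any real athlete's data.
#'
#' @param n_subjects,n_occasions Collection dimensions.
#' @param spike_prob Per-occasion spike probability (first two occasions are
#'   never spiked so every subject has a clean minimal history).
#' @param spike_factor Multiplicative spike size (e.g. 10 for a 10x rise).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters.
#' @param seed Integer seed.
#' @return A [series_collection()] with labels and context tags.
#' @export
make_hscrp_fixture <- function(n_subjects = 8L, n_occasions = 15L,
                               spike_prob = 0.2, spike_factor = 10,
                               baseline_meanlog = log(0.5),
                               baseline_sdlog = 0.4, seed = 1L) {
  stopifnot(spike_prob >= 0, spike_prob <= 1, spike_factor > 0)
  set.seed(seed)
  series_collection(lapply(seq_len(n_subjects), function(i) {
    subj_mu <- stats::rnorm(1, baseline_meanlog, 0.25)
    y <- stats::rlnorm(n_occasions, subj_mu, baseline_sdlog)
    spike <- stats::runif(n_occasions) < spike_prob
    if (n_occasions >= 2L) spike[1:2] <- FALSE
    y[spike] <- y[spike] * spike_factor
    longitudinal_series(
      sprintf("P%02d", i), y,
      labels = ifelse(spike, "abnormal", "normal"),
      context = rep_len(c("pre", "post"), n_occasions))
  }))
}
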