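#' Sequentially flag one labelled series
#'
#' Walks a series occasion by occasion, building each occasion's reference
#' range from the admissible history — all prior occasions, optionally
#' minus those whose truth label is `"abnormal"` (mirroring the practice of
#' omitting readings taken while a subject was known to be ill or injured,
#' so that genuine abnormalities do not contaminate the personal baseline).
#'
#' @param series A [longitudinal_series()].
#' @param method `"zscore"` or `"lmm"`.
#' @param model A fitted [fit_population_em()] model (required for
#'   `method = "lmm"`, ignored otherwise).
#' @param alpha Significance level.
#' @param sidedness `"two_sided"` or `"upper_only"`.
#' @param exclude_flagged_from_history Drop labelled-abnormal occasions from
#'   every later history (default `FALSE`).
#' @param a Pseudo-observation weight for [update_subject_variance()].
#' @param first_occasion First occasion given a verdict by the Z-score
#'   method (needs two prior values); the LMM method produces ranges from
#'   occasion 1. Earlier or degenerate occasions get verdict `NA`.
#' @return A data frame (class `flag_table`) with one row per occasion:
#'   `subject`, `occasion`, `observed`, `lower`, `upper`, `alpha`, `method`,
#'   `verdict` (`"normal"`/`"abnormal"`/`NA`), `label`, `context`.
#' @export
evaluate_series <- function(series, method = c("zscore", "lmm"),
                            model = NULL, alpha = 0.05,
                            sidedness = c("two_sided", "upper_only"),
                            exclude_flagged_from_history = FALSE,
                            a = 3, first_occasion = 3L) {
  stopifnot(inherits(series, "longitudinal_series"))
  method <- match.arg(method)
  sidedness <- match.arg(sidedness)
  if (method == "lmm" && !inherits(model, "population_model"))
    stop("method 'lmm' needs a fitted population_model")
  y <- series$values
  n <- length(y)
  labels <- series$labels %||% rep("unlabelled", n)

  lower <- upper <- rep(NA_real_, n)
  verdict <- rep(NA_character_, n)
  hist <- subject_summary()
  for (j in seq_len(n)) {
    rng <- NULL
    if (method == "zscore") {
      if (hist$n >= 2L && isTRUE(summary_sd(hist) > 0))
        rng <- zscore_range(hist, alpha, sidedness, occasion = j)
    } else {
      sig2 <- update_subject_variance(model, hist, a = a)
      rng <- lmm_range(model, lmm_state(hist$n, hist$mean, sig2),
                       alpha, sidedness, occasion = j)
    }
    if (!is.null(rng) && (method == "lmm" || j >= first_occasion)) {
      lower[j] <- rng$lower
      upper[j] <- rng$upper
      verdict[j] <- classify(y[j], rng)$verdict
    }
    if (!(exclude_flagged_from_history && labels[j] == "abnormal"))
      hist <- update_summary(hist, y[j])
  }
  out <- data.frame(subject = series$subject_id, occasion = seq_len(n),
                    observed = y, lower = lower, upper = upper,
                    alpha = alpha, method = method, verdict = verdict,
                    label = labels,
                    context = series$context %||% NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("flag_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sensitivity / FPR rates from a flag table, per subject and pooled,
# optionally within one context tag. Empty denominators give NA, never 0.
rates_from_flags <- function(flags, context = NULL) {
  if (!is.null(context)) flags <- flags[flags$context %in% context, ]
  flags <- flags[!is.na(flags$verdict), ]
  rate <- function(sub) {
    ab <- sub$label == "abnormal"
    no <- sub$label == "normal"
    c(sens = if (any(ab)) mean(sub$verdict[ab] == "abnormal") else NA_real_,
      fpr = if (any(no)) mean(sub$verdict[no] == "abnormal") else NA_real_,
      n_abnormal = sum(ab), n_normal = sum(no))
  }
  pooled <- rate(flags)
  by_subj <- do.call(rbind, lapply(split(flags, flags$subject), rate))
  c(sensitivity_pooled = unname(pooled["sens"]),
    fpr_pooled = unname(pooled["fpr"]),
    sensitivity_mean = mean(by_subj[, "sens"], na.rm = TRUE),
    fpr_mean = mean(by_subj[, "fpr"], na.rm = TRUE),
    n_abnormal = unname(pooled["n_abnormal"]),
    n_normal = unname(pooled["n_normal"]))
}

#' Sensitivity and false-positive rate across significance levels
#'
#' Evaluates every series at each alpha and method, and tabulates
#' sensitivity (fraction of labelled-abnormal occasions flagged) and false
#' positive rate (fraction of labelled-normal occasions flagged). Because
#' reference ranges are nested in alpha, both rates are non-decreasing in
#' alpha. Rates are reported two ways — the unweighted mean of per-subject
#' rates ("mean") and the occasion-weighted pooled rate ("pooled") — and
#' stratified by context tag. A rate with an empty denominator is `NA`.
#'
#' @param collection A labelled [series_collection()].
#' @param methods Character subset of `c("zscore", "lmm")`.
#' @param alphas Numeric vector of significance levels.
#' @param sidedness `"two_sided"` or `"upper_only"`.
#' @param model Optional pre-fitted [fit_population_em()] model for the LMM
#'   method; when `NULL` and `loo = FALSE`, a model is fitted on the whole
#'   collection.
#' @param loo Use the leave-one-subject-out protocol for the LMM method:
#'   each subject is assessed under a model fitted on all other subjects.
#' @param exclude_flagged_from_history Passed to [evaluate_series()].
#' @param a Passed to [update_subject_variance()].
#' @return An object of class `eval_report`: `rates` (data frame over
#'   method x alpha x context) and `flags` (the full audit flag table, from
#'   which every reported rate is exactly recomputable).
#' @export
alpha_sweep <- function(collection, methods = c("zscore", "lmm"),
                        alphas = 0.05,
                        sidedness = c("two_sided", "upper_only"),
                        model = NULL, loo = FALSE,
                        exclude_flagged_from_history = FALSE, a = 3) {
  stopifnot(inherits(collection, "series_collection"))
  methods <- match.arg(methods, c("zscore", "lmm"), several.ok = TRUE)
  sidedness <- match.arg(sidedness)
  if ("lmm" %in% methods) {
    if (loo) {
      models <- loo_models(collection)
    } else {
      if (is.null(model)) model <- fit_population_em(collection)
      models <- stats::setNames(rep(list(model), length(collection)),
                                names(collection))
    }
  }
  flags <- list()
  for (m in methods) for (al in alphas) for (id in names(collection)) {
    if (m == "lmm" && is.null(models[[id]])) next  # fit failed; reported
    flags[[length(flags) + 1L]] <- evaluate_series(
      collection[[id]], method = m,
      model = if (m == "lmm") models[[id]],
      alpha = al, sidedness = sidedness,
      exclude_flagged_from_history = exclude_flagged_from_history, a = a)
  }
  flags <- do.call(rbind, flags)
  contexts <- unique(stats::na.omit(flags$context))
  grid <- expand.grid(method = methods, alpha = alphas,
                      context = c("all", contexts),
                      stringsAsFactors = FALSE)
  rates <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sub <- flags[flags$method == grid$method[i] &
                   flags$alpha == grid$alpha[i], ]
    ctx <- if (grid$context[i] == "all") NULL else grid$context[i]
    cbind(grid[i, ], as.data.frame(as.list(rates_from_flags(sub, ctx))))
  }))
  rownames(rates) <- NULL
  out <- structure(list(rates = rates, flags = flags, sidedness = sidedness,
                        loo = loo),
                   class = "eval_report")
  if ("lmm" %in% methods && loo) attr(out, "models") <- models
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", nrow(x$flags), "flag records,",
      x$sidedness, if (x$loo) "(leave-one-subject-out)", "\n")
  print(utils::head(x$rates[x$rates$context == "all", ], 10))
  invisible(x)
}

# One model per held-out subject, each fitted without that subject's data.
loo_models <- function(collection) {
  if (length(collection) < 3L)
    stop("leave-one-subject-out needs at least 3 subjects")
  out <- lapply(names(collection), function(id) {
    tryCatch(fit_population_em(collection[setdiff(names(collection), id)]),
             error = function(e) {
               warning("fit failed for held-out subject ", id, ": ",
                       conditionMessage(e))
               NULL
             })
  })
  stats::setNames(out, names(collection))
}

#' Leave-one-subject-out evaluation protocol
#'
#' For each subject, the population model is re-fitted excluding that
#' subject's data and the subject is then assessed as a wholly new
#' individual — the honest analogue of deploying the method on someone who
#' was not in the reference population.
#'
#' @inheritParams alpha_sweep
#' @param alpha Significance level (scalar or vector).
#' @return An `eval_report` (see [alpha_sweep()]); the per-subject models
#'   are attached as attribute `"models"`.
#' @export
loo_protocol <- function(collection, alpha = 0.05,
                         sidedness = c("two_sided", "upper_only"),
                         methods = c("zscore", "lmm"),
                         exclude_flagged_from_history = FALSE, a = 3) {
  sidedness <- match.arg(sidedness)
  alpha_sweep(collection, methods = methods, alphas = alpha,
              sidedness = sidedness, loo = TRUE,
              exclude_flagged_from_history = exclude_flagged_from_history,
              a = a)
}
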