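test_that("evaluate_series walks a series occasion by occasion", {
  model <- toy_model(mu = 5, tau2 = 1, sigma2 = 1)

  # central values: a flat series at the population mean raises no LMM flag
  flat <- longitudinal_series("F", rep(5, 10))
  ft <- evaluate_series(flat, method = "lmm", model = model, alpha = 0.05)
  expect_equal(nrow(ft), 10L)
  expect_true(all(ft$verdict == "normal"))

  # the Z-score method gives no verdict before the third occasion
  set.seed(2)
  s <- longitudinal_series("S", rnorm(10, 5, 1))
  zt <- evaluate_series(s, method = "zscore", alpha = 0.05)
  expect_true(all(is.na(zt$verdict[1:2])))
  expect_true(all(!is.na(zt$verdict[3:10])))
  expect_error(evaluate_series(s, method = "lmm"), "population_model")
})

test_that("a 10x spike is flagged by both methods (upper-sided)", {
  # stable baseline ~0.5 with modest noise, spike at occasion 8
  base <- c(0.50, 0.60, 0.40, 0.55, 0.45, 0.50, 0.60)
  y <- c(base, 5.0, 0.52, 0.48)
  labs <- c(rep("normal", 7), "abnormal", "normal", "normal")
  s <- longitudinal_series("P", y, labels = labs)
  control <- make_hscrp_fixture(n_subjects = 6, n_occasions = 12,
                                spike_prob = 0, seed = 5)
  model <- fit_population_em(control)

  for (m in c("zscore", "lmm")) {
    ft <- evaluate_series(s, method = m, model = model, alpha = 0.05,
                          sidedness = "upper_only")
    expect_equal(ft$verdict[8], "abnormal")
    expect_true(all(ft$lower[!is.na(ft$lower)] == 0))
  }
})

test_that("label-driven history exclusion keeps the baseline clean", {
  base <- c(0.50, 0.60, 0.40, 0.55, 0.45, 0.50, 0.60)
  y <- c(base, 5.0, 0.52, 0.48)
  labs <- c(rep("normal", 7), "abnormal", "normal", "normal")
  s <- longitudinal_series("P", y, labels = labs)

  on <- evaluate_series(s, method = "zscore", alpha = 0.05,
                        sidedness = "upper_only",
                        exclude_flagged_from_history = TRUE)
  off <- evaluate_series(s, method = "zscore", alpha = 0.05,
                         sidedness = "upper_only",
                         exclude_flagged_from_history = FALSE)
  # with exclusion on, the post-spike history mean ignores the spike:
  # the occasion-9 range is centred near the baseline, not inflated
  expect_lt(on$upper[9], off$upper[9])
  expect_lt(on$upper[9], 2)       # baseline-sized
  expect_gt(off$upper[9], 2)      # spike-contaminated
  # occasions before the spike are untouched by the exclusion flag
  expect_equal(on$upper[3:7], off$upper[3:7])
})

test_that("flags are nested in alpha, so rates are monotone", {
  col <- make_hscrp_fixture(n_subjects = 5, n_occasions = 15,
                            spike_prob = 0.25, seed = 11)
  alphas <- c(0.01, 0.05, 0.10, 0.25)
  rpt <- alpha_sweep(col, methods = c("zscore", "lmm"), alphas = alphas,
                     sidedness = "upper_only")
  for (m in c("zscore", "lmm")) {
    prev <- NULL
    for (al in alphas) {
      f <- rpt$flags[rpt$flags$method == m & rpt$flags$alpha == al, ]
      f <- f[order(f$subject, f$occasion), ]
      cur <- !is.na(f$verdict) & f$verdict == "abnormal"
      if (!is.null(prev)) expect_true(all(cur[prev]))  # nested
      prev <- cur
    }
    r <- rpt$rates[rpt$rates$method == m & rpt$rates$context == "all", ]
    r <- r[order(r$alpha), ]
    expect_true(all(diff(r$sensitivity_pooled) >= 0))
    expect_true(all(diff(r$fpr_pooled) >= 0))
  }
})

test_that("every reported rate is recomputable from the audit flag table", {
  col <- make_hscrp_fixture(n_subjects = 6, n_occasions = 15,
                            spike_prob = 0.2, seed = 19)
  rpt <- alpha_sweep(col, methods = "zscore", alphas = c(0.05, 0.2),
                     sidedness = "upper_only")
  for (i in seq_len(nrow(rpt$rates))) {
    row <- rpt$rates[i, ]
    f <- rpt$flags[rpt$flags$method == row$method &
                     rpt$flags$alpha == row$alpha & !is.na(rpt$flags$verdict), ]
    if (row$context != "all") f <- f[f$context %in% row$context, ]
    ab <- f$label == "abnormal"; no <- f$label == "normal"
    expect_equal(row$sensitivity_pooled,
                 if (any(ab)) mean(f$verdict[ab] == "abnormal") else NA_real_)
    expect_equal(row$fpr_pooled,
                 if (any(no)) mean(f$verdict[no] == "abnormal") else NA_real_)
  }
  # a class with an empty denominator reports NA, never 0
  clean <- make_hscrp_fixture(n_subjects = 4, n_occasions = 10,
                              spike_prob = 0, seed = 23)
  rc <- alpha_sweep(clean, methods = "zscore", alphas = 0.05,
                    sidedness = "upper_only")
  expect_true(all(is.na(rc$rates$sensitivity_pooled)))
  expect_true(all(!is.na(rc$rates$fpr_pooled)))
})

test_that("LMM retains sensitivity under volatile early baselines", {
  # early readings are erratic, inflating the subject's own SD; the spike is
  # sized to clear the population-informed bound but not the t bound
  control <- normal_collection(n_subjects = 12, n_occasions = 10, mu = 0.5,
                               between_sd = 0.2, within_sd = 0.1, seed = 6)
  model <- fit_population_em(control)
  y <- c(0.1, 1.5, 0.2, 1.4, 0.3, 1.3, 0.2, 1.8, 0.5)
  labs <- c(rep("normal", 7), "abnormal", "normal")
  s <- longitudinal_series("V", y, labels = labs)
  z <- evaluate_series(s, "zscore", alpha = 0.05, sidedness = "upper_only")
  l <- evaluate_series(s, "lmm", model = model, alpha = 0.05,
                       sidedness = "upper_only")
  expect_equal(z$verdict[8], "normal")     # t interval inflated, spike missed
  expect_equal(l$verdict[8], "abnormal")   # shrunk interval catches it
  expect_lt(l$upper[8], z$upper[8])
})

test_that("alpha limits behave: rates vanish as alpha -> 0", {
  col <- make_hscrp_fixture(n_subjects = 4, n_occasions = 12,
                            spike_prob = 0.2, spike_factor = 3, seed = 29)
  rpt <- alpha_sweep(col, methods = "zscore", alphas = 1e-9,
                     sidedness = "upper_only")
  r <- rpt$rates[rpt$rates$context == "all", ]
  expect_true(all(r$fpr_pooled == 0))
  expect_true(all(r$sensitivity_pooled == 0))
})

test_that("the Z-score FPR tracks alpha on a clean normal baseline", {
  col <- normal_collection(n_subjects = 40, n_occasions = 30, seed = 13,
                           labelled = TRUE)
  rpt <- alpha_sweep(col, methods = "zscore", alphas = c(0.05, 0.1, 0.2))
  r <- rpt$rates[rpt$rates$context == "all", ]
  expect_true(all(abs(r$fpr_pooled - r$alpha) < 0.05))
})

test_that("leave-one-subject-out excludes exactly the held-out subject", {
  col <- make_hscrp_fixture(n_subjects = 4, n_occasions = 12,
                            spike_prob = 0.15, seed = 37)
  rpt <- loo_protocol(col, alpha = 0.05, sidedness = "upper_only")
  models <- attr(rpt, "models")
  expect_length(models, 4L)
  for (id in names(col)) {
    expect_false(id %in% names(models[[id]]$sigma2_by_subject))
    expect_setequal(names(models[[id]]$sigma2_by_subject),
                    setdiff(names(col), id))
  }

  # perturbing the held-out subject leaves the other fits untouched
  col2 <- col
  col2[["P01"]]$values <- col2[["P01"]]$values * 3
  col2 <- series_collection(unclass(col2))
  m2 <- adaptref:::loo_models(col2)
  expect_equal(m2[["P01"]]$mu, models[["P01"]]$mu)
  expect_equal(m2[["P01"]]$tau2, models[["P01"]]$tau2)
  expect_false(isTRUE(all.equal(m2[["P02"]]$mu, models[["P02"]]$mu)))

  expect_error(loo_protocol(col[1:2]), "at least 3")
})

test_that("LOO and full-fit centres differ by O(1/I) on homogeneous data", {
  col <- normal_collection(n_subjects = 30, n_occasions = 8, seed = 41)
  full <- fit_population_em(col)
  loo <- adaptref:::loo_models(col)
  shifts <- vapply(names(col), function(id) abs(loo[[id]]$mu - full$mu),
                   numeric(1))
  # removing one of I subjects moves the population mean by about
  # |m_i - mu| / (I - 1): small, and bounded well below one between-SD
  expect_true(all(shifts < 4 * 1 / (length(col) - 1)))
  expect_gt(max(shifts), 0)
})
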