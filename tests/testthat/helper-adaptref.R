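# Shared fixture builders; everything is generated in code at test time.

# A tiny long-format data frame with two subjects.
tiny_long_df <- function() {
  data.frame(subject = c("A", "A", "B", "B", "B"),
             occasion = c(1, 2, 1, 2, 3),
             value = c(4, 6, 1, 2, 3),
             stringsAsFactors = FALSE)
}

# Collection of iid-normal subjects (all truly normal), optionally labelled.
normal_collection <- function(n_subjects = 10, n_occasions = 20, mu = 5,
                              between_sd = 1, within_sd = 0.5, seed = 1,
                              labelled = FALSE) {
  set.seed(seed)
  series_collection(lapply(seq_len(n_subjects), function(i) {
    m <- rnorm(1, mu, between_sd)
    y <- rnorm(n_occasions, m, within_sd)
    longitudinal_series(sprintf("N%02d", i), y,
                        labels = if (labelled) rep("normal", n_occasions))
  }))
}

# A subject_summary with prescribed n, mean and sd (for formula-level tests).
summary_with <- function(n, mean, sd) {
  structure(list(n = as.integer(n), mean = mean, ss = sd^2 * (n - 1)),
            class = "subject_summary")
}

# Minimal hand-built population model (bypasses fitting).
toy_model <- function(mu = 5, tau2 = 1, sigma2 = 1) {
  structure(list(mu = mu, tau2 = tau2,
                 sigma2_by_subject = c(X = sigma2), sigma2_pooled = sigma2,
                 posterior = data.frame(), loglik_trace = numeric(0),
                 converged = TRUE, n_iter = 0L, degenerate = FALSE,
                 var_floor = 1e-8),
            class = "population_model")
}
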