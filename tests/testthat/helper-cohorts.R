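# Shared fixtures: everything is generated in code at test time.

default_mu <- function() subject_profile()$predicted_fev1

# Small seeded cohort with the default subject and given CVs.
make_cohort <- function(n_tests = 500, cv_t = 0.03, cv_m = 0.06, seed = 1,
                        n_maneuvers = 8, rounding_mode = "rounded_2dp") {
  subj <- subject_profile()
  vm <- derive_sigmas(subj, cv_t = cv_t, cv_m = cv_m,
                      rounding_mode = rounding_mode)
  simulate_cohort(simulation_config(subj, vm, n_tests = n_tests,
                                    n_maneuvers = n_maneuvers, seed = seed))
}

# Cohort built from an explicit maneuver matrix (bypasses the simulator),
# for brute-force oracle comparisons.
matrix_cohort <- function(X, mu = default_mu(), cv_t = 0.03, cv_m = 0.06) {
  colnames(X) <- paste0("maneuver_", seq_len(ncol(X)))
  df <- data.frame(test_index = seq_len(nrow(X)), test_mean = rowMeans(X))
  df <- cbind(df, as.data.frame(X))
  attr(df, "subject") <- subject_profile()
  attr(df, "variability") <- derive_sigmas(subject_profile(), cv_t, cv_m)
  class(df) <- c("spiro_cohort", "data.frame")
  df
}

# Numeric-integration oracle: P(top-two gap of m iid N(., sigma^2) > rc).
# Conditions on the maximum; the other m-1 draws must all fall below max-rc.
top_two_gap_exceeds_prob <- function(rc, sigma, m) {
  delta <- rc / sigma
  f <- function(x) m * stats::dnorm(x) * stats::pnorm(x - delta)^(m - 1)
  stats::integrate(f, -Inf, Inf)$value
}
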