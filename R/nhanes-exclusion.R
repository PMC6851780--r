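#' Maneuver counts from the NHANES 2009-2010 spirometry component
#'
#' Loads the packaged maneuver-count fixture: the number of maneuvers
#' performed at each maneuver index (1..9) across the NHANES 2009-2010
#' pulmonary function sample, together with the accepted/excluded counts
#' exactly as printed in the source table. The printed table is internally
#' inconsistent in two places (more second than first and more third than
#' second maneuvers; an excluded count at maneuver 6 that does not equal the
#' number of seventh maneuvers) -- the fixture preserves both, and
#' [exclusion_rates()] warns about them.
#'
#' @return A data frame with columns `maneuver`, `n_performed`, `n_accepted`,
#'   `n_excluded` (the latter two `NA` where the source prints none).
#' @export
nhanes_maneuver_counts <- function() {
  path <- system.file("extdata", "nhanes_table1_counts.csv",
                      package = "spirosim", mustWork = TRUE)
  utils::read.csv(path)
}

#' Exclusion-rate arithmetic for a maneuver-count table
#'
#' Under a minimum-three-maneuver protocol, the number of (m+1)-th maneuvers
#' performed equals the number of tests whose first m maneuvers failed the
#' repeatability criterion. So from counts \eqn{N_m} alone one can derive
#' accepted counts \eqn{A_m = N_m - N_{m+1}}, excluded counts
#' \eqn{E_m = N_{m+1}} and implied exclusion rates \eqn{E_m / N_m}.
#'
#' If the input carries printed `n_excluded` values they take precedence over
#' the derived \eqn{N_{m+1}} when computing rates (published tables sometimes
#' disagree with their own counts; a consistency warning is raised for each
#' mismatch). Counts that increase with maneuver index also draw a warning,
#' not an error. Rates are kept as exact fractions; rounding is a
#' presentation concern.
#'
#' @param counts Either a data frame with columns `maneuver` and
#'   `n_performed` (optionally `n_accepted`, `n_excluded`), or a numeric
#'   vector of performed counts for contiguous maneuver indices starting
#'   at 1.
#' @return A data frame of class `maneuver_count_table`: `maneuver`,
#'   `n_performed`, `n_accepted`, `n_excluded`, `exclusion_rate` (fraction in
#'   \[0, 1\], `NA` where undefined).
#' @examples
#' exclusion_rates(nhanes_maneuver_counts())
#' @export
exclusion_rates <- function(counts) {
  if (is.numeric(counts)) {
    counts <- data.frame(maneuver = seq_along(counts), n_performed = counts)
  }
  stopifnot(is.data.frame(counts),
            all(c("maneuver", "n_performed") %in% names(counts)))
  df <- counts[order(counts$maneuver), , drop = FALSE]
  if (!identical(as.integer(df$maneuver),
                 seq(min(df$maneuver), max(df$maneuver)))) {
    stop("`maneuver` indices must form a contiguous range", call. = FALSE)
  }
  n <- df$n_performed
  if (any(n < 0) || any(n != as.integer(n))) {
    stop("`n_performed` must be non-negative integers", call. = FALSE)
  }
  m <- nrow(df)
  nxt <- c(n[-1], NA_real_)
  up <- which(nxt > n)
  if (length(up) > 0L) {
    warning("count table is non-monotone: more maneuvers at index ",
            paste(df$maneuver[up] + 1L, collapse = ", "),
            " than at the preceding index", call. = FALSE)
  }
  derived_excluded <- nxt
  derived_accepted <- n - nxt
  excluded <- derived_excluded
  if ("n_excluded" %in% names(counts)) {
    printed <- df$n_excluded
    use <- !is.na(printed)
    bad <- use & !is.na(derived_excluded) & printed != derived_excluded
    if (any(bad)) {
      warning("printed excluded count differs from the derived count ",
              "N(m+1) at maneuver ", paste(df$maneuver[bad], collapse = ", "),
              " (printed ", paste(printed[bad], collapse = ", "),
              ", derived ", paste(derived_excluded[bad], collapse = ", "),
              ")", call. = FALSE)
    }
    excluded[use] <- printed[use]
    excluded[!use] <- NA_real_
  }
  rate <- ifelse(is.na(excluded) | n == 0, NA_real_, excluded / n)
  out <- data.frame(maneuver = df$maneuver, n_performed = n,
                    n_accepted = derived_accepted, n_excluded = excluded,
                    exclusion_rate = rate)
  class(out) <- c("maneuver_count_table", "data.frame")
  out
}

#' @export
print.maneuver_count_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$exclusion_rate <- ifelse(is.na(y$exclusion_rate), NA,
                             sprintf("%.1f%%", 100 * y$exclusion_rate))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Infer the population intratest CV from observed exclusion rates
#'
#' Grid search for the intratest coefficient of variation whose predicted
#' repeatability-failure fraction best matches a vector of observed
#' per-maneuver exclusion rates (e.g. the implied exclusion rates of a
#' published maneuver-count table). Two predictors are available:
#'
#' \describe{
#'   \item{`analytic_pair`}{the closed-form two-maneuver failure probability
#'     [pair_failure_probability()], constant across maneuvers.}
#'   \item{`simulated`}{per-maneuver continuation fractions from a full
#'     sequential-protocol simulation: the fraction of tests reaching
#'     maneuver m that still lack a repeatable pair and therefore need
#'     maneuver m+1.}
#' }
#'
#' The loss is the mean absolute deviation between observed and predicted
#' rates. The full loss profile is returned alongside the argmin so that a
#' flat or two-sided minimum can be assessed rather than asserted.
#'
#' @param observed_rates Numeric vector of observed exclusion fractions; if
#'   named, names are maneuver indices (used by the `simulated` method),
#'   otherwise maneuvers `3, 4, ...` are assumed.
#' @param rc Repeatability criterion (L/sec).
#' @param subject A [subject_profile()].
#' @param cv_grid Candidate intratest CVs (fractions).
#' @param method `"analytic_pair"` (default) or `"simulated"`.
#' @param cv_t Intertest CV, used by the `simulated` method.
#' @param n_tests Cohort size per candidate, `simulated` method.
#' @param n_maneuvers Maneuvers per test, `simulated` method.
#' @param seed Optional base seed; candidate i uses `seed + i`.
#' @param rounding_mode Passed to [derive_sigmas()].
#' @return An object of class `cvm_fit`: list with `best_cv_m`, `profile`
#'   (data frame `cv_m`, `loss`), `method`, `rc`.
#' @examples
#' obs <- rep(pair_failure_probability(0.15, 0.21), 5)
#' infer_cvm(obs)$best_cv_m # recovers 0.06
#' @export
infer_cvm <- function(observed_rates, rc = 0.15,
                      subject = subject_profile(),
                      cv_grid = seq(0.01, 0.10, by = 0.005),
                      method = c("analytic_pair", "simulated"),
                      cv_t = 0.03, n_tests = 20902, n_maneuvers = 8,
                      seed = NULL, rounding_mode = "rounded_2dp") {
  method <- match.arg(method)
  if (length(observed_rates) == 0L) {
    stop("`observed_rates` must be non-empty", call. = FALSE)
  }
  if (length(cv_grid) == 0L) stop("`cv_grid` must be non-empty", call. = FALSE)
  stopifnot(all(observed_rates >= 0), all(observed_rates <= 1))
  mans <- if (!is.null(names(observed_rates))) {
    as.integer(names(observed_rates))
  } else {
    seq(3, length.out = length(observed_rates))
  }
  loss <- numeric(length(cv_grid))
  for (i in seq_along(cv_grid)) {
    cv <- cv_grid[i]
    vm <- derive_sigmas(subject, cv_t = cv_t, cv_m = cv,
                        rounding_mode = rounding_mode)
    if (method == "analytic_pair") {
      pred <- rep(pair_failure_probability(rc, vm$sigma_m), length(mans))
    } else {
      cfg <- simulation_config(subject, vm, n_tests = n_tests,
                               n_maneuvers = n_maneuvers,
                               seed = if (is.null(seed)) NULL else seed + i)
      out <- protocol_outcomes(simulate_cohort(cfg),
                               protocol_config(rc = rc,
                                               max_maneuvers = n_maneuvers,
                                               stop_rule = "early_stop"))
      fq <- out$stop_maneuver
      # n_reaching(m): tests that performed maneuver m under early stopping
      n_reach <- function(m) {
        if (m <= 3) length(fq) else sum(is.na(fq) | fq >= m)
      }
      pred <- vapply(mans, function(m) {
        reach <- n_reach(m)
        if (reach == 0) return(NA_real_)
        sum(is.na(fq) | fq > m) / reach
      }, numeric(1))
    }
    loss[i] <- mean(abs(observed_rates - pred), na.rm = TRUE)
  }
  res <- list(best_cv_m = cv_grid[which.min(loss)],
              profile = data.frame(cv_m = cv_grid, loss = loss),
              method = method, rc = rc)
  class(res) <- "cvm_fit"
  res
}

#' @export
print.cvm_fit <- function(x, ...) {
  cat(sprintf("Intratest CV fit (%s, RC = %g L/sec): best CVm = %g%%\n",
              x$method, x$rc, 100 * x$best_cv_m))
  invisible(x)
}
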