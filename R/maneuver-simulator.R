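#' Simulation configuration
#'
#' Collects everything needed to generate a cohort of simulated spirometric
#' tests: the subject, the variability model, the number of tests and the
#' number of maneuvers per test.
#'
#' The default cohort size of 20,902 tests is the size used to guarantee 90%
#' power at a 5% nominal type I error rate in the source analysis; it is
#' treated here as a given constant.
#'
#' @param subject A [subject_profile()].
#' @param variability A [derive_sigmas()] variability model.
#' @param n_tests Number of simulated tests (>= 1).
#' @param n_maneuvers Maneuvers per test (1..30).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   cohorts.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(subject = subject_profile(),
                              variability = derive_sigmas(subject),
                              n_tests = 20902, n_maneuvers = 8, seed = NULL) {
  stopifnot(inherits(subject, "subject_profile"),
            inherits(variability, "variability_model"))
  if (!is.numeric(n_tests) || length(n_tests) != 1L || n_tests < 1 ||
      n_tests != as.integer(n_tests)) {
    stop("`n_tests` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(n_maneuvers) || length(n_maneuvers) != 1L ||
      n_maneuvers < 1 || n_maneuvers > 30 ||
      n_maneuvers != as.integer(n_maneuvers)) {
    stop("`n_maneuvers` must be an integer in 1..30", call. = FALSE)
  }
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    seed <- as.integer(seed)
  }
  out <- list(subject = subject, variability = variability,
              n_tests = as.integer(n_tests),
              n_maneuvers = as.integer(n_maneuvers), seed = seed)
  class(out) <- "simulation_config"
  out
}

#' Simulate a cohort of spirometric tests
#'
#' Draws a two-level normal cohort: each test's true mean FEV1 is
#' \eqn{N(\mu, \sigma_t^2)} around the subject's predicted FEV1, and each of
#' the test's maneuvers is an independent \eqn{N(\mu_t, \sigma_m^2)} draw
#' around that test mean. The intratest SD is held fixed across tests (it is
#' not rescaled by the simulated test mean); maneuvers are independent, with
#' no learning or fatigue structure.
#'
#' Draw order is fixed: all test means first, then maneuvers test by test, so
#' cohorts are reproducible for a given seed. Negative draws are not
#' truncated; at realistic spirometric CVs the probability of one is
#' negligible, and a warning is raised if `sigma_m` exceeds 30% of the
#' predicted mean.
#'
#' @param config A [simulation_config()].
#' @return A data frame of class `spiro_cohort` with columns `test_index`,
#'   `test_mean` and `maneuver_1` .. `maneuver_k`, carrying the subject,
#'   variability model and seed as attributes.
#' @examples
#' cfg <- simulation_config(n_tests = 100, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' dim(cohort)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  mu <- config$subject$predicted_fev1
  st <- config$variability$sigma_t
  sm <- config$variability$sigma_m
  n <- config$n_tests
  k <- config$n_maneuvers
  if (sm / mu > 0.3) {
    warning("sigma_m exceeds 30% of the predicted mean; untruncated normal ",
            "draws may go negative", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  test_mean <- stats::rnorm(n, mean = mu, sd = st)
  draws <- stats::rnorm(n * k, mean = rep(test_mean, each = k), sd = sm)
  maneuvers <- matrix(draws, nrow = n, ncol = k, byrow = TRUE)
  colnames(maneuvers) <- paste0("maneuver_", seq_len(k))
  out <- data.frame(test_index = seq_len(n), test_mean = test_mean)
  out <- cbind(out, as.data.frame(maneuvers))
  attr(out, "subject") <- config$subject
  attr(out, "variability") <- config$variability
  attr(out, "seed") <- config$seed
  class(out) <- c("spiro_cohort", "data.frame")
  out
}

#' Extract the maneuver matrix of a cohort
#'
#' @param cohort A `spiro_cohort` (or any data frame with `maneuver_*`
#'   columns).
#' @return A numeric matrix, tests in rows, maneuvers in columns
#'   (generation order).
#' @export
cohort_matrix <- function(cohort) {
  cols <- grep("^maneuver_[0-9]+$", names(cohort), value = TRUE)
  if (length(cols) == 0L) stop("no maneuver columns found", call. = FALSE)
  cols <- cols[order(as.integer(sub("^maneuver_", "", cols)))]
  as.matrix(cohort[, cols, drop = FALSE])
}

#' Write / read a cohort as CSV
#'
#' Floating point values are written with 17 significant digits so that
#' `read_cohort(write_cohort(x))` round-trips bit-identically.
#'
#' @param cohort A `spiro_cohort`.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `spiro_cohort` data frame.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  num <- vapply(cohort, is.double, logical(1))
  out <- cohort
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  required <- c("test_index", "test_mean")
  missing <- setdiff(required, names(df))
  man_cols <- grep("^maneuver_[0-9]+$", names(df), value = TRUE)
  if (length(missing) > 0L || length(man_cols) == 0L) {
    stop("malformed cohort CSV: expected columns test_index, test_mean, ",
         "maneuver_1..maneuver_k; missing: ",
         paste(c(missing, if (length(man_cols) == 0L) "maneuver_*"),
               collapse = ", "), call. = FALSE)
  }
  idx <- as.integer(sub("^maneuver_", "", man_cols))
  expected <- paste0("maneuver_", seq_len(max(idx)))
  gaps <- setdiff(expected, man_cols)
  if (length(gaps) > 0L) {
    stop("malformed cohort CSV: missing maneuver column(s) ",
         paste(gaps, collapse = ", "), call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df[, c(required, man_cols)]))
  if (length(bad) > 0L) {
    stop("malformed cohort CSV: non-numeric or missing value in row ",
         bad[1], call. = FALSE)
  }
  class(df) <- c("spiro_cohort", "data.frame")
  df
}
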