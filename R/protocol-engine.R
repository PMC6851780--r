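#' Protocol configuration
#'
#' Describes one reading of the ATS/ERS FEV1 selection protocol: the
#' repeatability criterion (RC), the minimum and maximum number of maneuvers,
#' the stopping rule, and the policy for tests that never satisfy the RC.
#'
#' Stopping rules:
#' \describe{
#'   \item{`early_stop`}{the full iterative protocol: examine the first
#'     `min_maneuvers` maneuvers; qualify if the highest and second-highest
#'     differ by at most `rc`; otherwise compare each further maneuver to the
#'     running maximum, stopping at the first success, up to
#'     `max_maneuvers`.}
#'   \item{`fixed_stop`}{only maneuvers `1..stop_at` are ever seen; with
#'     `stop_at = 3` this is the three-maneuver termination used for the
#'     headline error comparison.}
#'   \item{`no_stop`}{all maneuvers are consumed; the test is qualified if
#'     any repeatability check ever passed and the reported value is the
#'     overall maximum of the maneuvers seen.}
#' }
#'
#' Non-repeatable-test policies: `discard` drops the test (no reported
#' value), `report_highest` reports the highest maneuver seen anyway, and
#' `flag_only` reports the highest maneuver seen but leaves the test flagged
#' as not qualified for downstream discretion.
#'
#' @param rc Repeatability criterion in L/sec (> 0); 0.15 is the 2005
#'   ATS/ERS value.
#' @param min_maneuvers Minimum maneuvers before the first check (>= 3).
#' @param max_maneuvers Maximum maneuvers (>= `min_maneuvers`).
#' @param stop_rule One of `"early_stop"`, `"fixed_stop"`, `"no_stop"`.
#' @param stop_at Number of maneuvers seen under `fixed_stop`.
#' @param nonrepeatable_policy One of `"discard"`, `"report_highest"`,
#'   `"flag_only"`.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(rc = 0.15, min_maneuvers = 3, max_maneuvers = 8,
                            stop_rule = c("early_stop", "fixed_stop",
                                          "no_stop"),
                            stop_at = 3,
                            nonrepeatable_policy = c("discard",
                                                     "report_highest",
                                                     "flag_only")) {
  stop_rule <- match.arg(stop_rule)
  nonrepeatable_policy <- match.arg(nonrepeatable_policy)
  if (!is.numeric(rc) || length(rc) != 1L || !is.finite(rc) || rc <= 0) {
    stop("`rc` must be a single positive value (L/sec)", call. = FALSE)
  }
  if (min_maneuvers < 3 || min_maneuvers > max_maneuvers) {
    stop("need 3 <= min_maneuvers <= max_maneuvers", call. = FALSE)
  }
  if (stop_rule == "fixed_stop" &&
      (stop_at < min_maneuvers || stop_at > max_maneuvers)) {
    stop("`stop_at` must lie in [min_maneuvers, max_maneuvers]",
         call. = FALSE)
  }
  out <- list(rc = rc, min_maneuvers = as.integer(min_maneuvers),
              max_maneuvers = as.integer(max_maneuvers),
              stop_rule = stop_rule, stop_at = as.integer(stop_at),
              nonrepeatable_policy = nonrepeatable_policy)
  class(out) <- "protocol_config"
  out
}

row_max <- function(X) do.call(pmax, as.data.frame(X))

#' Apply the ATS/ERS selection protocol to a whole cohort
#'
#' Vectorised engine behind [apply_ats_protocol()]. Implements the sequential
#' rule verbatim: at `min_maneuvers` the test qualifies if the highest and
#' second-highest of the maneuvers seen so far differ by at most `rc`; each
#' subsequent maneuver qualifies the test if it differs from the running
#' maximum of all previous maneuvers by at most `rc`, in which case the
#' larger of the two is the reported maximum.
#'
#' `unrestricted_max` is always the maximum over *all* supplied maneuvers --
#' the unconstrained alternative protocol -- regardless of the stopping rule,
#' so that `unrestricted_max - reported_fev1` is the per-test measurement
#' error.
#'
#' @param maneuvers A numeric matrix (tests in rows, maneuvers in generation
#'   order) or a `spiro_cohort`.
#' @param config A [protocol_config()].
#' @return A data frame with one row per test: `qualified`, `stop_maneuver`
#'   (NA when the test never qualifies), `maneuvers_seen`, `reported_fev1`
#'   (NA for discarded tests) and `unrestricted_max`.
#' @export
protocol_outcomes <- function(maneuvers, config = protocol_config()) {
  stopifnot(inherits(config, "protocol_config"))
  X <- if (is.matrix(maneuvers)) maneuvers else cohort_matrix(maneuvers)
  n <- nrow(X)
  k_avail <- ncol(X)
  m0 <- config$min_maneuvers
  if (k_avail < m0) {
    stop("need at least `min_maneuvers` (", m0, ") maneuvers per test, got ",
         k_avail, call. = FALSE)
  }
  k_lim <- min(k_avail, config$max_maneuvers)
  if (config$stop_rule == "fixed_stop") k_lim <- min(k_lim, config$stop_at)

  # top-two of the first m0 maneuvers
  M <- pmax(X[, 1], X[, 2])
  S <- pmin(X[, 1], X[, 2])
  if (m0 > 2) {
    for (j in 3:m0) {
      x <- X[, j]
      S <- ifelse(x > M, M, pmax(S, x))
      M <- pmax(M, x)
    }
  }
  stop_m <- rep(NA_integer_, n)
  reported <- rep(NA_real_, n)
  ok <- (M - S) <= config$rc
  stop_m[ok] <- m0
  reported[ok] <- M[ok]

  if (k_lim > m0) {
    for (j in (m0 + 1):k_lim) {
      x <- X[, j]
      newly <- is.na(stop_m) & abs(x - M) <= config$rc
      Mnew <- pmax(M, x)
      stop_m[newly] <- j
      reported[newly] <- Mnew[newly]
      M <- Mnew
    }
  }

  qualified <- !is.na(stop_m)
  seen <- ifelse(qualified & config$stop_rule == "early_stop", stop_m, k_lim)
  if (config$stop_rule == "no_stop") {
    seen <- rep(k_lim, n)
    reported[qualified] <- M[qualified] # overall max of maneuvers seen
  }
  if (config$nonrepeatable_policy %in% c("report_highest", "flag_only")) {
    # highest value among the maneuvers actually seen
    reported[!qualified] <- row_max(X[, seq_len(k_lim), drop = FALSE])[!qualified]
  }
  data.frame(
    qualified = qualified,
    stop_maneuver = stop_m,
    maneuvers_seen = as.integer(seen),
    reported_fev1 = reported,
    unrestricted_max = row_max(X)
  )
}

#' Apply the ATS/ERS selection protocol to one maneuver sequence
#'
#' @param maneuvers Numeric vector of maneuver FEV1 values in the order they
#'   were performed (length >= `min_maneuvers`).
#' @param config A [protocol_config()].
#' @return A list with elements `reported_fev1` (NA if discarded),
#'   `qualified`, `stop_maneuver` (NA if the test never qualified),
#'   `maneuvers_seen` and `unrestricted_max`.
#' @examples
#' apply_ats_protocol(c(3.60, 3.30, 3.00, 3.52))
#' # fails at 3 (gap 0.30), qualifies at maneuver 4 (3.60 - 3.52 <= 0.15)
#' @export
apply_ats_protocol <- function(maneuvers, config = protocol_config()) {
  stopifnot(is.numeric(maneuvers))
  if (length(maneuvers) < config$min_maneuvers) {
    stop("need at least `min_maneuvers` (", config$min_maneuvers,
         ") maneuver values", call. = FALSE)
  }
  out <- protocol_outcomes(matrix(maneuvers, nrow = 1), config)
  list(
    reported_fev1 = out$reported_fev1,
    qualified = out$qualified,
    stop_maneuver = out$stop_maneuver,
    maneuvers_seen = out$maneuvers_seen,
    unrestricted_max = out$unrestricted_max
  )
}

#' Unconstrained test maximum
#'
#' The reported value of the alternative protocol: the highest FEV1 across
#' all maneuvers, with no repeatability screening and no early termination.
#'
#' @param maneuvers Non-empty numeric vector.
#' @return The maximum, in L/sec.
#' @export
unrestricted_result <- function(maneuvers) {
  if (length(maneuvers) == 0L || !is.numeric(maneuvers)) {
    stop("`maneuvers` must be a non-empty numeric vector", call. = FALSE)
  }
  max(maneuvers)
}

#' Brute-force oracle: first prefix with a repeatable top-two pair
#'
#' Independent re-statement of the sequential rule: the smallest
#' \eqn{m \ge} `min_maneuvers` such that the gap between the highest and
#' second-highest of the first \eqn{m} maneuvers is at most `rc`. For every
#' sequence this equals the stopping maneuver of the sequential protocol
#' under `early_stop` -- a property the test suite checks rather than
#' assumes. Deliberately implemented by sorting each prefix.
#'
#' @param maneuvers Numeric vector, length >= `min_maneuvers`.
#' @param rc Repeatability criterion (L/sec).
#' @param min_maneuvers First prefix length examined.
#' @return The qualifying prefix length, or `NA_integer_` if no prefix
#'   qualifies.
#' @export
first_qualifying_maneuver_oracle <- function(maneuvers, rc = 0.15,
                                             min_maneuvers = 3) {
  stopifnot(is.numeric(maneuvers), length(maneuvers) >= min_maneuvers)
  for (m in min_maneuvers:length(maneuvers)) {
    top2 <- sort(maneuvers[seq_len(m)], decreasing = TRUE)[1:2]
    if (top2[1] - top2[2] <= rc) return(m)
  }
  NA_integer_
}
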