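#' Predicted normal FEV1 from height and age
#'
#' Evaluates a published reference equation for the predicted maximum forced
#' expiratory volume in one second (FEV1) of a healthy adult:
#' \deqn{\hat{FEV_1} = \exp(-8.240 + 1.9095\,\ln H - 0.0037\,A - 0.000033\,A^2)}
#' with height \eqn{H} in centimetres and age \eqn{A} in years.
#'
#' The prediction is strictly increasing in height and strictly decreasing in
#' age (for any non-negative age), and is always positive.
#'
#' @param height Standing height in cm. Must be positive. Vectorised.
#' @param age Age in years. Must be positive. Vectorised.
#' @return Predicted FEV1 in L/sec.
#' @examples
#' predict_fev1(173, 59) # ~ 3.55 L/sec
#' @export
predict_fev1 <- function(height, age) {
  if (!is.numeric(height) || !is.numeric(age)) {
    stop("`height` and `age` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(height)) || any(!is.finite(age))) {
    stop("`height` and `age` must be finite", call. = FALSE)
  }
  if (any(height <= 0)) stop("`height` must be positive (cm)", call. = FALSE)
  if (any(age <= 0)) stop("`age` must be positive (years)", call. = FALSE)
  exp(-8.240 + 1.9095 * log(height) - 0.0037 * age - 0.000033 * age^2)
}

#' Subject profile
#'
#' Bundles the demographic inputs of the simulated subject together with the
#' predicted "true" FEV1 they imply. The default subject (173 cm, 59 years)
#' has a predicted FEV1 of 3.55 L/sec.
#'
#' `population_sd` is the between-subject standard deviation of FEV1 in the
#' reference population (0.51 L/sec). It is carried for context only and is
#' never used by the single-subject simulation.
#'
#' @param height Height in cm (> 0).
#' @param age Age in years (> 0).
#' @param population_sd Between-subject SD of FEV1 in L/sec (context only).
#' @return An object of class `subject_profile`: a list with elements
#'   `height`, `age`, `predicted_fev1` and `population_sd`.
#' @examples
#' subject_profile()
#' subject_profile(height = 160, age = 40)
#' @export
subject_profile <- function(height = 173, age = 59, population_sd = 0.51) {
  stopifnot(is.numeric(population_sd), length(population_sd) == 1L,
            population_sd >= 0)
  out <- list(
    height = height,
    age = age,
    predicted_fev1 = predict_fev1(height, age),
    population_sd = population_sd
  )
  class(out) <- "subject_profile"
  out
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "Subject: height %g cm, age %g y; predicted FEV1 = %.4f L/sec (pop. SD %.2f)\n",
    x$height, x$age, x$predicted_fev1, x$population_sd
  ))
  invisible(x)
}

#' Derive absolute standard deviations from coefficients of variation
#'
#' Converts the intertest (`cv_t`) and intratest (`cv_m`) coefficients of
#' variation into absolute standard deviations on the scale of the subject's
#' predicted FEV1: \eqn{\sigma_t = CV_t \mu} and \eqn{\sigma_m = CV_m \mu}.
#'
#' Under the default `rounded_2dp` mode each sigma is rounded to two decimal
#' places (banker's rounding, as in [round()]), matching the convention of
#' carrying e.g. CVt = 3% as 0.11 L/sec and CVm = 6% as 0.21 L/sec for the
#' default subject. `exact` keeps full precision; the two modes never differ
#' by more than 0.005 L/sec.
#'
#' @param profile A [subject_profile()] (or a single positive number taken as
#'   the predicted FEV1 in L/sec).
#' @param cv_t Intertest coefficient of variation, as a fraction (>= 0).
#' @param cv_m Intratest coefficient of variation, as a fraction (>= 0).
#' @param rounding_mode `"rounded_2dp"` (default) or `"exact"`.
#' @return An object of class `variability_model`: a list with elements
#'   `cv_t`, `cv_m`, `sigma_t`, `sigma_m` (L/sec) and `rounding_mode`.
#' @examples
#' derive_sigmas(subject_profile(), cv_t = 0.03, cv_m = 0.06)
#' # sigma_t = 0.11, sigma_m = 0.21
#' @export
derive_sigmas <- function(profile = subject_profile(), cv_t = 0.03,
                          cv_m = 0.06,
                          rounding_mode = c("rounded_2dp", "exact")) {
  rounding_mode <- match.arg(rounding_mode)
  mu <- if (inherits(profile, "subject_profile")) profile$predicted_fev1
        else profile
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu), mu > 0)
  if (!is.numeric(cv_t) || length(cv_t) != 1L || !is.finite(cv_t) || cv_t < 0) {
    stop("`cv_t` must be a single non-negative fraction", call. = FALSE)
  }
  if (!is.numeric(cv_m) || length(cv_m) != 1L || !is.finite(cv_m) || cv_m < 0) {
    stop("`cv_m` must be a single non-negative fraction", call. = FALSE)
  }
  sigma_t <- cv_t * mu
  sigma_m <- cv_m * mu
  if (rounding_mode == "rounded_2dp") {
    sigma_t <- round(sigma_t, 2)
    sigma_m <- round(sigma_m, 2)
  }
  out <- list(cv_t = cv_t, cv_m = cv_m, sigma_t = sigma_t, sigma_m = sigma_m,
              rounding_mode = rounding_mode)
  class(out) <- "variability_model"
  out
}

#' @export
print.variability_model <- function(x, ...) {
  cat(sprintf(
    "Variability: CVt = %g%% (sigma_t = %g L/sec), CVm = %g%% (sigma_m = %g L/sec) [%s]\n",
    100 * x$cv_t, x$sigma_t, 100 * x$cv_m, x$sigma_m, x$rounding_mode
  ))
  invisible(x)
}
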