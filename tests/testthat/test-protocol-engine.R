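test_that("hand-traced sequences follow the sequential rule", {
  # identical values qualify immediately
  out <- apply_ats_protocol(c(3.50, 3.50, 3.50))
  expect_true(out$qualified)
  expect_equal(out$reported_fev1, 3.50)
  expect_equal(out$stop_maneuver, 3L)

  # first-3 gap 0.30 fails; maneuver 4 within 0.08 of the running max
  out <- apply_ats_protocol(c(3.60, 3.30, 3.00, 3.52))
  expect_true(out$qualified)
  expect_equal(out$stop_maneuver, 4L)
  expect_equal(out$reported_fev1, 3.60)

  # strictly 0.2-spaced ramp never qualifies; discarded under default policy
  ramp <- seq(3.0, 4.4, by = 0.2)
  out <- apply_ats_protocol(ramp)
  expect_false(out$qualified)
  expect_true(is.na(out$reported_fev1))
  expect_equal(out$maneuvers_seen, 8L)
  expect_equal(out$unrestricted_max, 4.4)
})

test_that("oracle hand-traces and tie handling", {
  expect_equal(first_qualifying_maneuver_oracle(c(3.60, 3.30, 3.00, 3.52)),
               4L)
  expect_equal(first_qualifying_maneuver_oracle(c(3.50, 3.40, 3.00)), 3L)
  expect_true(is.na(first_qualifying_maneuver_oracle(seq(3.0, 4.4, 0.2),
                                                     rc = 0.15)))
  # boundary: gap exactly equal to rc qualifies (<=, as printed)
  expect_equal(first_qualifying_maneuver_oracle(c(3.65, 3.50, 3.20),
                                                rc = 0.15), 3L)
  expect_true(apply_ats_protocol(c(3.65, 3.50, 3.20))$qualified)
})

test_that("sequential rule is equivalent to the prefix top-two oracle", {
  # property check over random sequences at several RC values
  set.seed(2024)
  n_cases <- 4000
  for (rc in c(0.05, 0.15, 0.40)) {
    cfg <- protocol_config(rc = rc)
    lens <- sample(3:8, n_cases, replace = TRUE)
    for (i in seq_len(n_cases)) {
      x <- round(rnorm(lens[i], 3.55, 0.21), 3)
      out <- apply_ats_protocol(x, cfg)
      orc <- first_qualifying_maneuver_oracle(x, rc = rc)
      expect_identical(out$stop_maneuver, orc)
      if (!is.na(orc)) {
        expect_identical(out$reported_fev1, max(x[seq_len(orc)]))
      }
    }
  }
})

test_that("widening the RC is monotone in stop maneuver and reported value", {
  set.seed(99)
  rcs <- c(0.05, 0.10, 0.15, 0.20, 0.30)
  for (i in 1:300) {
    x <- rnorm(8, 3.55, 0.21)
    outs <- lapply(rcs, function(rc)
      apply_ats_protocol(x, protocol_config(rc = rc)))
    stops <- vapply(outs, function(o)
      ifelse(is.na(o$stop_maneuver), 9L, o$stop_maneuver), integer(1))
    reps <- vapply(outs, function(o)
      ifelse(is.na(o$reported_fev1), -Inf, o$reported_fev1), numeric(1))
    expect_true(all(diff(stops) <= 0))
    expect_true(all(diff(reps[is.finite(reps)]) <= 1e-12))
    # error is always non-negative
    err <- max(x) - reps[is.finite(reps)]
    expect_true(all(err >= -1e-12))
  }
})

test_that("stop rules see the right maneuvers", {
  x <- c(3.60, 3.30, 3.00, 3.52, 3.90, 3.91, 3.10, 3.20)
  # early_stop: qualifies at 4, later (higher) values unseen
  early <- apply_ats_protocol(x, protocol_config(stop_rule = "early_stop"))
  expect_equal(early$stop_maneuver, 4L)
  expect_equal(early$reported_fev1, 3.60)
  expect_equal(early$maneuvers_seen, 4L)
  # fixed_stop at 3: only first three ever seen; gap 0.30 -> discarded
  fixed <- apply_ats_protocol(x, protocol_config(stop_rule = "fixed_stop",
                                                 stop_at = 3))
  expect_false(fixed$qualified)
  expect_true(is.na(fixed$reported_fev1))
  expect_equal(fixed$maneuvers_seen, 3L)
  # no_stop: all consumed, reported is the overall max
  ns <- apply_ats_protocol(x, protocol_config(stop_rule = "no_stop"))
  expect_true(ns$qualified)
  expect_equal(ns$maneuvers_seen, 8L)
  expect_equal(ns$reported_fev1, 3.91)
  # unrestricted_max is the full-sequence max in every mode
  expect_equal(c(early$unrestricted_max, fixed$unrestricted_max,
                 ns$unrestricted_max), rep(3.91, 3))
})

test_that("non-repeatable-test policies differ as documented", {
  ramp <- seq(3.0, 4.4, by = 0.2)
  rh <- apply_ats_protocol(ramp,
    protocol_config(nonrepeatable_policy = "report_highest"))
  expect_false(rh$qualified)
  expect_equal(rh$reported_fev1, 4.4)
  fl <- apply_ats_protocol(ramp,
    protocol_config(nonrepeatable_policy = "flag_only"))
  expect_false(fl$qualified)
  expect_equal(fl$reported_fev1, 4.4)
  # under fixed_stop the highest *seen* maneuver is reported
  rh3 <- apply_ats_protocol(ramp,
    protocol_config(stop_rule = "fixed_stop", stop_at = 3,
                    nonrepeatable_policy = "report_highest"))
  expect_equal(rh3$reported_fev1, 3.4)
})

test_that("input validation", {
  expect_error(apply_ats_protocol(c(3.5, 3.5)), "min_maneuvers")
  expect_error(unrestricted_result(numeric(0)), "non-empty")
  expect_equal(unrestricted_result(c(3.1, 3.9, 3.5)), 3.9)
  expect_error(protocol_config(rc = 0), "rc")
  expect_error(protocol_config(min_maneuvers = 2), "min_maneuvers")
  expect_error(protocol_config(stop_rule = "fixed_stop", stop_at = 9),
               "stop_at")
})
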