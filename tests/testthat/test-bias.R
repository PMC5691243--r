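# Constructive fixtures: for each bias type one session engineered to fire
# exactly that detector, and matched sessions engineered to stay silent.

fire_session <- function(bias, seed = 11) {
  ec <- toy_case()
  log <- simulate_session(ec, simulation_profile(injected_bias = bias,
                                                 seed = seed))
  analyze_submission(log, ec, attr(log, "history"), toy_vocab())
}

test_that("each injected bias fires exactly its own detector", {
  for (bias in c("premature_closure", "availability", "confirmation",
                 "representativeness", "base_rate_neglect")) {
    out <- fire_session(bias)
    expect_equal(out$status, "mismatch")
    fired <- vapply(out$findings, `[[`, "", "bias_type")
    expect_equal(fired, bias)
    expect_setequal(out$options, c("try_again", "continue",
                                   "more_feedback"))
  }
})

test_that("a correct submission yields a match and no findings", {
  ec <- toy_case()
  log <- simulate_session(ec, simulation_profile(ability = 1, seed = 3))
  out <- analyze_submission(log, ec, attr(log, "history"), toy_vocab())
  expect_equal(out$status, "match")
  expect_length(out$findings, 0L)
  expect_setequal(out$options, c("continue", "more_feedback"))
})

test_that("premature closure requires later connected expert evidence", {
  ec <- toy_case()
  rep <- replay(simulate_session(ec, simulation_profile(
    injected_bias = "premature_closure", seed = 11)))
  sub <- latest_submission(rep)
  expect_lt(sub$stage, ec$n_stages - 1L)
  expect_s3_class(detect_premature_closure(rep, ec, sub),
                  "crt_bias_finding")

  # the same submission moved to the last stage can never fire
  late <- sub
  late$stage <- ec$n_stages - 1L
  expect_null(detect_premature_closure(rep, ec, late))

  # at stage 2 only the decisive last-stage test is still to come ...
  mid <- sub
  mid$stage <- 2L
  expect_s3_class(detect_premature_closure(rep, ec, mid),
                  "crt_bias_finding")
  # ... and with its connections stripped, later expert nodes exist but
  # none is connected to the final diagnosis: the rule stays silent
  ec2 <- ec
  ec2$map$connections <- Filter(
    function(cn) !(cn$source == "E_t_key" || cn$target == "E_t_key"),
    ec2$map$connections)
  expect_null(detect_premature_closure(rep, ec2, mid))
})

test_that("availability window is 5 days, relatedness one level", {
  ec <- toy_case()
  v <- toy_vocab()
  log <- simulate_session(ec, simulation_profile(
    injected_bias = "availability", seed = 11))
  rep <- replay(log)
  sub <- latest_submission(rep)
  related_dx <- attr(log, "history")$entries[[1L]]$final_diagnoses

  hist_days_ago <- function(days, dx = related_dx) {
    session_history(list(list(
      case_id = "prior-case",
      last_accessed = format(as.Date(substr(sub$submitted_at, 1, 10)) - days),
      final_diagnoses = dx)))
  }
  expect_s3_class(detect_availability(sub, rep$final, hist_days_ago(4), v),
                  "crt_bias_finding")
  expect_null(detect_availability(sub, rep$final, hist_days_ago(6), v))
  # unrelated prior case on the same day stays silent
  unrelated <- ec$map$nodes[["E_dx_correct"]]$term
  expect_null(detect_availability(sub, rep$final,
                                  hist_days_ago(0, unrelated), v))
  # empty history
  expect_null(detect_availability(sub, rep$final, session_history(), v))
})

test_that("confirmation detector distinguishes added, linked, and absent", {
  ec <- toy_case()
  v <- toy_vocab()
  # injected confirmation: disconfirming finding never added -> fires
  log <- simulate_session(ec, simulation_profile(
    injected_bias = "confirmation", seed = 11))
  rep <- replay(log)
  f <- detect_confirmation(rep, ec, v)
  expect_s3_class(f, "crt_bias_finding")
  expect_true("E_f_dis_alt" %in% f$evidence$disconfirming_expert_findings)

  # the other injected-bias sessions add finding + speaks_against link,
  # so the rule stays silent there
  log2 <- simulate_session(ec, simulation_profile(
    injected_bias = "base_rate_neglect", seed = 11))
  expect_null(detect_confirmation(replay(log2), ec, v))

  # expert defines no disconfirming finding for the submitted diagnosis:
  # not evaluable
  ec2 <- ec
  ec2$map$connections <- Filter(function(cn) cn$weight != "speaks_against",
                                ec2$map$connections)
  expect_identical(detect_confirmation(rep, ec2, v), NA)
})

test_that("representativeness needs the nonprototypical metadata", {
  ec <- toy_case()
  v <- toy_vocab()
  log <- simulate_session(ec, simulation_profile(
    injected_bias = "representativeness", seed = 11))
  rep <- replay(log)
  expect_s3_class(detect_representativeness(rep, ec, v),
                  "crt_bias_finding")

  # without the metadata the rule is not evaluable
  ec2 <- ec
  ec2$nonprototypical_findings <- character()
  expect_identical(detect_representativeness(rep, ec2, v), NA)

  # a session that never speaks against the correct diagnosis is silent
  silent <- replay(simulate_session(ec, simulation_profile(
    injected_bias = "confirmation", seed = 11)))
  expect_null(detect_representativeness(silent, ec, v))
})

test_that("base-rate neglect compares prevalences with the rare factor", {
  ec <- toy_case()
  v <- toy_vocab()
  log <- simulate_session(ec, simulation_profile(
    injected_bias = "base_rate_neglect", seed = 11))
  rep <- replay(log)
  sub <- latest_submission(rep)
  f <- detect_base_rate_neglect(sub, rep$final, ec, v)
  expect_s3_class(f, "crt_bias_finding")
  expect_lt(f$evidence$submitted_prevalence,
            0.1 * f$evidence$correct_prevalence)

  # equal prevalences are silent
  ec_eq <- ec
  ec_eq$prevalence[] <- 0.02
  expect_null(detect_base_rate_neglect(sub, rep$final, ec_eq, v))

  # prevalence missing for the submitted diagnosis: not evaluable
  ec_na <- ec
  ec_na$prevalence <- ec$prevalence["E_dx_correct"]
  expect_identical(detect_base_rate_neglect(sub, rep$final, ec_na, v), NA)
  # no prevalence at all: not evaluable, and reported as such
  ec_none <- ec
  ec_none$prevalence <- numeric()
  out <- analyze_submission(rep, ec_none, session_history(), v)
  expect_true("base_rate_neglect" %in% out$not_evaluable)
})

test_that("detectors are pure and single-submission analysis matches", {
  ec <- toy_case()
  v <- toy_vocab()
  log <- simulate_session(ec, simulation_profile(
    injected_bias = "premature_closure", seed = 13))
  h <- attr(log, "history")
  o1 <- analyze_submission(log, ec, h, v)
  o2 <- analyze_submission(log, ec, h, v)
  expect_equal(o1, o2)

  # analyzing the latest submission explicitly equals the default
  rep <- replay(log)
  o3 <- analyze_submission(rep, ec, h, v,
                           submission = latest_submission(rep))
  expect_equal(o1$status, o3$status)
  expect_equal(vapply(o1$findings, `[[`, "", "bias_type"),
               vapply(o3$findings, `[[`, "", "bias_type"))
})
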