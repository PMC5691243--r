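test_that("clusters map node categories onto the process model", {
  ec <- toy_case()
  v <- toy_vocab()
  perfect <- score_session(simulate_session(
    ec, simulation_profile(ability = 1, seed = 3)), ec, v)
  cl <- perfect$clusters
  expect_equal(unname(as.numeric(cl)), rep(1, 5))

  # hand-built final stage: one exact finding (1.0) and one matched to the
  # remaining expert finding three edges away (0.7) -> cluster 0.85; test
  # cluster 0 (expected but absent); therapy not applicable on both sides;
  # exact differential plus diagnosis 1 -> categorization 1
  tv <- tiny_vocab()
  expert <- h_map(
    map_node("e1", "finding", term = "D011014"),
    map_node("e2", "finding", term = "D001991"),
    map_node("e3", "test", label = "chest x-ray"),
    map_node("e4", "differential", term = "D011014"),
    map_node("e5", "differential", label = "other dx"))
  learner <- h_map(
    map_node("l1", "finding", term = "D011014"),
    map_node("l2", "finding", term = "D018410"),
    map_node("l4", "differential", term = "D011014"))
  ss <- score_stage(learner, expert, tv)
  cl2 <- compute_clusters(list(ss), diagnosis_score = 1,
                          summary_score = 1L)
  expect_equal(unname(cl2[["problem_representation"]]), 0.85)
  expect_equal(unname(cl2[["investigations"]]), 0)
  expect_true(is.na(cl2[["therapeutic"]]))
  expect_equal(unname(cl2[["categorization"]]), 1)
  expect_equal(unname(cl2[["semantic_transformation"]]), 0.5)
})

test_that("cluster values depend on snapshots, not event order", {
  # two logs adding the same nodes in different orders within one stage
  mk <- function(order_swap) {
    e1 <- ev("add_node", 0, node_id = "f1", category = "finding",
             label = "fever")
    e2 <- ev("add_node", 0, node_id = "d1", category = "differential",
             label = "flu")
    evs <- if (order_swap) list(e2, e1) else list(e1, e2)
    session_log("s", "c", "l", evs, started_at = NA)
  }
  tv <- tiny_vocab()
  expert <- h_map(map_node("e1", "finding", label = "fever"),
                  map_node("e2", "differential", label = "flu"))
  s1 <- score_stage(replay(mk(FALSE))$final, expert, tv)
  s2 <- score_stage(replay(mk(TRUE))$final, expert, tv)
  expect_equal(compute_clusters(list(s1), 1, 2L),
               compute_clusters(list(s2), 1, 2L))
})

test_that("self-directed fraction counts adds before the first consult", {
  adds <- function(n, stage = 0)
    lapply(seq_len(n), function(i)
      ev("add_node", stage, node_id = paste0("n", i),
         category = "finding", label = paste("f", i)))
  no_consult <- session_log("s", "c", "l", adds(5))
  expect_equal(self_directed_fraction(no_consult), 1)

  consult_first <- session_log("s", "c", "l",
                               c(list(ev("consult_expert", 0)), adds(5)))
  expect_equal(self_directed_fraction(consult_first), 0)

  mixed <- session_log("s", "c", "l",
                       c(adds(3), list(ev("consult_expert", 0)),
                         lapply(4, function(i)
                           ev("add_node", 0, node_id = "n9",
                              category = "finding", label = "late"))))
  expect_equal(self_directed_fraction(mixed), 0.75)

  # vacuous self-direction / consult with no adds
  expect_equal(self_directed_fraction(session_log("s", "c", "l", list())),
               1)
  expect_equal(self_directed_fraction(
    session_log("s", "c", "l", list(ev("consult_expert", 0)))), 0)
})

test_that("moving the consult earlier never raises the fraction", {
  base_adds <- lapply(1:6, function(i)
    ev("add_node", 0, node_id = paste0("n", i), category = "finding",
       label = paste("f", i)))
  fracs <- vapply(0:6, function(pos) {
    evs <- append(base_adds, list(ev("consult_expert", 0)), after = pos)
    self_directed_fraction(session_log("s", "c", "l", evs))
  }, 0)
  expect_true(all(diff(fracs) >= 0))  # later consult -> larger fraction
})

test_that("dual-processing indicator rescales the submission stage", {
  sub_at <- function(stage) session_log("s", "c", "l", list(
    ev("add_node", stage, node_id = "d1", category = "differential",
       label = "dx"),
    ev("submit_final", stage, diagnosis_nodes = "d1", confidence = 60)))
  expect_equal(dual_processing_indicator(sub_at(0), 6), 1)
  expect_equal(dual_processing_indicator(sub_at(5), 6), 0)
  expect_equal(dual_processing_indicator(sub_at(2), 6), 0.6)
  expect_equal(dual_processing_indicator(sub_at(0), 1), 1)
  expect_true(is.na(dual_processing_indicator(
    session_log("s", "c", "l", list()), 6)))
})

test_that("dashboard: trend order, peer exclusion, recommendations", {
  ec <- toy_case()
  v <- toy_vocab()
  score_one <- function(seed, ability) {
    log <- simulate_session(ec, simulation_profile(ability = ability,
                                                   seed = seed))
    s <- score_session(log, ec, v)
    s$session_id <- paste0("s", seed)
    s$started_at <- sprintf("2026-01-%02dT09:00:00Z", seed)
    s
  }
  mine <- list(score_one(3, 0.4), score_one(2, 1))
  d <- build_dashboard(mine)
  # ordered by start time: seed 2 before seed 3
  expect_equal(d$trend$session_id, c("s2", "s3"))
  expect_equal(nrow(d$peer_stats), 0L)
  # recommendations ascend by the latest session's cluster values
  latest <- d$trend[nrow(d$trend), d$recommendations]
  expect_true(all(diff(as.numeric(latest)) >= 0))

  # peers: focal learner's own sessions are excluded from peer stats
  peer <- score_one(5, 0.8)
  peer$learner_id <- "other-learner"
  with_self <- build_dashboard(mine, c(list(peer), mine))
  only_peer <- build_dashboard(mine, list(peer))
  expect_equal(with_self$peer_stats, only_peer$peer_stats)
  expect_equal(unique(with_self$peer_stats$n), 1L)

  expect_warning(d0 <- build_dashboard(list()), "empty")
  expect_equal(nrow(d0$trend), 0L)
})
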