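test_that("node scoring bases: exact, hierarchical, negation, free text", {
  v <- tiny_vocab()
  expert <- h_map(
    map_node("e1", "finding", term = "D011014"),            # Pneumonia
    map_node("e2", "finding", label = "pleural rub"),
    map_node("e3", "finding", term = "D001991", negated = TRUE))

  exact <- score_node(map_node("l1", "finding", term = "D011014"),
                      expert, v)
  expect_equal(exact$value, 1)
  expect_equal(exact$basis, "exact")

  # child of the expert term, one edge away: 1 - 1/10
  hier <- score_node(map_node("l2", "finding", term = "D018410"),
                     expert, v)
  expect_equal(hier$value, 0.9)
  expect_equal(hier$basis, "hierarchical")
  expect_equal(hier$distance, -1L)

  # negation flags must agree: against a map holding only the affirmative
  # term, the negated learner node finds no match at all
  affirm_only <- h_map(map_node("e1", "finding", term = "D011014"))
  neg <- score_node(map_node("l3", "finding", term = "D011014",
                             negated = TRUE), affirm_only, v)
  expect_equal(neg$value, 0)
  expect_equal(neg$basis, "none")
  # while the same flags on both sides match exactly
  neg_both <- score_node(
    map_node("l3", "finding", term = "D001991", negated = TRUE),
    expert, v)
  expect_equal(neg_both$value, 1)

  # free text against expert free text, case/whitespace-insensitive
  txt <- score_node(map_node("l4", "finding", label = "  Pleural  RUB "),
                    expert, v)
  expect_equal(txt$value, 1)
  expect_equal(txt$basis, "text")

  # free text hitting a vocabulary synonym
  syn <- score_node(map_node("l5", "finding", label = "Pulmonitis"),
                    expert, v)
  expect_equal(syn$value, 1)
  expect_equal(syn$basis, "synonym")

  # category mismatch never matches
  cat_m <- score_node(map_node("l6", "test", term = "D011014"), expert, v)
  expect_equal(cat_m$basis, "none")
})

test_that("one-to-one matching: an expert node absorbs only one learner node", {
  v <- tiny_vocab()
  expert <- h_map(map_node("e1", "differential", term = "D011014"))
  learner <- h_map(
    map_node("l1", "differential", term = "D018410",
             added_at = "2026-01-01T10:00:00Z"),
    map_node("l2", "differential", term = "D011014",
             added_at = "2026-01-01T10:01:00Z"))
  ss <- score_stage(learner, expert, v)
  pn <- ss$per_node[order(ss$per_node$learner_node_id), ]
  # best score first: the exact match takes the expert node, the other
  # learner node is left unmatched
  expect_equal(pn$value[pn$learner_node_id == "l2"], 1)
  expect_equal(pn$value[pn$learner_node_id == "l1"], 0)
  expect_equal(ss$n_added, 1L)
})

test_that("stage formula: worked values and edge cases", {
  v <- tiny_vocab()
  expert <- h_map(
    map_node("e1", "finding", term = "D011014"),
    map_node("e2", "finding", term = "D001991"),
    map_node("e3", "finding", label = "dyspnea"),
    map_node("e4", "finding", label = "chest pain"))

  # 2 exact matches of 4 expert nodes + 1 extra learner node:
  # (1+1)/(2+2) - 0.05 = 0.45
  learner <- h_map(
    map_node("l1", "finding", term = "D011014"),
    map_node("l2", "finding", term = "D001991"),
    map_node("l3", "finding", label = "something else"))
  ss <- score_stage(learner, expert, v)
  expect_equal(ss$overall, 0.45)
  expect_equal(ss$n_correct, 2L)
  expect_equal(ss$n_missed, 2L)
  expect_equal(ss$n_added, 1L)

  # empty learner map against 4 expert nodes
  expect_equal(score_stage(concept_map(), expert, v)$overall, 0)
  # empty against empty
  expect_equal(score_stage(concept_map(), concept_map(), v)$overall, 1)
  # nodes without expert expectations: clamped at zero, raw negative
  noisy <- h_map(map_node("x1", "finding", label = "a"),
                 map_node("x2", "finding", label = "b"))
  ss0 <- score_stage(noisy, concept_map(), v)
  expect_equal(ss0$overall, 0)
  expect_equal(ss0$overall_raw, -0.1)
})

test_that("identical maps score 1 regardless of size", {
  v <- toy_vocab()
  ids <- names(v$terms)
  set.seed(5)
  for (n in c(1, 4, 9)) {
    terms <- sample(ids, n)
    cats <- sample(c("finding", "differential", "test", "therapy"), n,
                   replace = TRUE)
    expert <- concept_map(); learner <- concept_map()
    for (i in seq_len(n)) {
      expert <- crtool:::add_node_to_map(expert,
        map_node(paste0("e", i), cats[i], term = terms[i]))
      learner <- crtool:::add_node_to_map(learner,
        map_node(paste0("l", i), cats[i], term = terms[i]))
    }
    expect_equal(score_stage(learner, expert, v)$overall, 1)
  }
})

test_that("each extra learner node costs exactly 0.05 before clamping", {
  v <- tiny_vocab()
  expert <- h_map(map_node("e1", "finding", term = "D011014"),
                  map_node("e2", "finding", term = "D001991"))
  learner <- h_map(map_node("l1", "finding", term = "D011014"))
  base <- score_stage(learner, expert, v)$overall_raw
  for (k in 1:3) {
    extra <- learner
    for (i in seq_len(k))
      extra <- crtool:::add_node_to_map(extra,
        map_node(paste0("x", i), "finding",
                 label = paste("noise", i)))
    got <- score_stage(extra, expert, v)$overall_raw
    expect_equal(base - got, 0.05 * k)
  }
})

test_that("final-diagnosis credit follows 1 - |d|/10 within the window", {
  v <- tiny_vocab()
  emap <- h_map(map_node("E1", "differential", term = "D011014"))
  ec <- expert_case(emap, final_diagnoses = "E1", n_stages = 1)

  score_for <- function(term) {
    lmap <- h_map(map_node("L1", "differential", term = term))
    sub <- list(diagnosis_nodes = "L1", confidence = 80, stage = 0)
    score_final_diagnosis(sub, lmap, ec, v)
  }
  # the learner one hierarchy level more specific: d = -1, score 0.9
  s <- score_for("D018410")
  expect_equal(s$per_diagnosis$distance, -1L)
  expect_equal(s$combined, 0.9)
  # exact term
  expect_equal(score_for("D011014")$combined, 1)
  # unrelated branch scores zero
  expect_equal(score_for("D001523")$combined, 0)

  # distance 6 sits outside the partial window
  chain <- make_toy_vocabulary(depth = 7, branching = 1, seed = 0)
  ids <- names(chain$terms)  # root ... leaf along one chain
  emap2 <- h_map(map_node("E1", "differential", term = ids[1L]))
  ec2 <- expert_case(emap2, final_diagnoses = "E1", n_stages = 1)
  lmap2 <- h_map(map_node("L1", "differential", term = ids[7L]))
  sub <- list(diagnosis_nodes = "L1", confidence = 50, stage = 0)
  expect_equal(score_final_diagnosis(sub, lmap2, ec2, chain)$combined, 0)

  # monotone non-increasing in |distance|; partial values within [0.5, 0.9]
  scores <- vapply(2:7, function(i) {
    lm <- h_map(map_node("L1", "differential", term = ids[i]))
    score_final_diagnosis(sub, lm, ec2, chain)$combined
  }, 0)
  expect_equal(scores, c(0.9, 0.8, 0.7, 0.6, 0.5, 0))
  expect_true(all(diff(scores) <= 0))
  partial <- scores[scores > 0 & scores < 1]
  expect_true(all(partial >= 0.5 & partial <= 0.9))
})

test_that("multiple submitted diagnoses are averaged without expert reuse", {
  v <- tiny_vocab()
  emap <- h_map(map_node("E1", "differential", term = "D011014"))
  ec <- expert_case(emap, final_diagnoses = "E1", n_stages = 1)
  lmap <- h_map(map_node("L1", "differential", term = "D011014"),
                map_node("L2", "differential", term = "D018410"))
  sub <- list(diagnosis_nodes = c("L1", "L2"), confidence = 70, stage = 0)
  s <- score_final_diagnosis(sub, lmap, ec, v)
  # L1 takes the exact match; L2 cannot reuse the expert diagnosis
  expect_equal(sort(s$per_diagnosis$score), c(0, 1))
  expect_equal(s$combined, 0.5)
})

test_that("summary rubric thresholds and boundaries", {
  ten <- paste("acute severe sudden unilateral localized productive",
               "febrile progressive new constant")
  expect_length(extract_qualifiers(ten), 10L)
  qs <- extract_qualifiers(ten)

  learner_with <- function(k) paste(qs[seq_len(k)], collapse = " ")
  expect_equal(score_summary(learner_with(6), ten)$rubric, 2L)  # 60%
  expect_equal(score_summary(learner_with(4), ten)$rubric, 1L)  # 40%
  expect_equal(score_summary(learner_with(2), ten)$rubric, 0L)  # 20%
  expect_equal(score_summary(learner_with(3), ten)$rubric, 1L)  # 30% boundary
  expect_equal(score_summary(ten, ten)$fraction_used, 1)
  expect_equal(score_summary(ten, ten)$rubric, 2L)
  expect_equal(score_summary("", ten)$rubric, 0L)

  # qualifiers outside the expert set do not help
  expect_equal(score_summary(paste(learner_with(2), "chronic mild"),
                             ten)$rubric, 0L)

  # an expert statement without lexicon qualifiers is a config error
  expect_error(score_summary("anything", "the patient has a problem"),
               "no lexicon qualifier")
})

test_that("rubric is monotone in coverage", {
  ten <- paste("acute severe sudden unilateral localized productive",
               "febrile progressive new constant")
  qs <- extract_qualifiers(ten)
  rubrics <- vapply(0:10, function(k)
    score_summary(paste(qs[seq_len(k)], collapse = " "), ten)$rubric, 0L)
  expect_true(all(diff(rubrics) >= 0))
  expect_equal(rubrics[1], 0L)
  expect_equal(rubrics[11], 2L)
})

test_that("session aggregation weights the three components", {
  expect_equal(aggregate_session(1, 1, 2), 1)
  expect_equal(aggregate_session(1, 0, 0), 1 / 3)
  # stage 0.45, diagnosis 0.9, rubric 1 (-> 0.5): uniform mean 0.6167
  expect_equal(aggregate_session(0.45, 0.9, 1), 0.6166667,
               tolerance = 1e-6)
  expect_equal(aggregate_session(0.5, 1, 2, weights = c(0, 1, 0)), 1)
  expect_error(aggregate_session(1, 1, 2, weights = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(aggregate_session(1, 1, 2, weights = c(-0.5, 1, 0.5)),
               "non-negative|summing")
})
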