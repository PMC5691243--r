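#' Cognitive-error detection on mismatched final diagnoses
#'
#' When the learner's final diagnosis disagrees with the expert's, five
#' rule-based detectors look for patterns associated with common cognitive
#' errors: premature closure, availability bias, confirmation bias,
#' representativeness, and base-rate neglect. Each detector is a pure
#' function of the session, the expert case (and its metadata), and — for
#' availability — the learner's prior-session history. Detectors that lack
#' the expert metadata they need are reported as not evaluable rather than
#' silently skipped.
#'
#' @name bias_rules
NULL

bias_types <- c("premature_closure", "availability", "confirmation",
                "representativeness", "base_rate_neglect")

bias_finding <- function(bias_type, evidence, explanation) {
  stopifnot(bias_type %in% bias_types)
  structure(list(bias_type = bias_type, evidence = evidence,
                 explanation = explanation),
            class = "crt_bias_finding")
}

#' @export
print.crt_bias_finding <- function(x, ...) {
  cat("<crt_bias_finding> ", x$bias_type, ": ", x$explanation, "\n", sep = "")
  invisible(x)
}

#' Prior-session history of a learner
#'
#' @param entries list of prior sessions, each a list with `case_id`,
#'   `last_accessed` (ISO-8601 date or datetime) and `final_diagnoses`
#'   (character vector of vocabulary term ids). Sorted most recent first on
#'   construction.
#' @return a `crt_history`.
#' @export
session_history <- function(entries = list()) {
  entries <- lapply(entries, function(e) {
    if (is.null(e$case_id) || is.null(e$last_accessed))
      abort("history entries need case_id and last_accessed")
    if (is.na(as.Date(substr(as.character(e$last_accessed), 1, 10))))
      abort("invalid last_accessed date: ", e$last_accessed)
    list(case_id = as.character(e$case_id),
         last_accessed = as.character(e$last_accessed),
         final_diagnoses = as.character(unlist(e$final_diagnoses)))
  })
  if (length(entries) > 1L) {
    ord <- order(vapply(entries, `[[`, "", "last_accessed"),
                 decreasing = TRUE)
    entries <- entries[ord]
  }
  structure(list(entries = entries), class = "crt_history")
}

# resolve the vocabulary terms behind a set of submitted learner node ids
submitted_terms <- function(submission, learner_map) {
  ids <- as.character(submission$diagnosis_nodes)
  terms <- lapply(learner_map$nodes[ids], `[[`, "term")
  unlist(Filter(Negate(is.null), terms))
}

# the expert final-diagnosis node best matching a submitted learner node
# (used to phrase evidence); NULL when nothing matches

#' Detect premature closure
#'
#' Fires when the diagnosis was submitted at a stage after which the
#' expert still adds findings or tests connected (by any supporting
#' weight) to an expert final diagnosis — i.e. decisive evidence was still
#' to come. No explicit "early stage" threshold is needed: the existence
#' of later connected expert evidence is the criterion.
#'
#' @param session a `crt_replay` (or `crt_session_log`).
#' @param expert a `crt_expert_case`.
#' @param submission the submission analyzed (default: the latest).
#' @return a `crt_bias_finding`, or `NULL` when the rule does not fire.
#' @export
detect_premature_closure <- function(session, expert,
                                     submission = latest_submission(session)) {
  if (is.null(submission)) return(NULL)
  s <- submission$stage
  emap <- expert$map
  later <- Filter(function(n)
    n$category %in% c("finding", "test") && n$stage_added > s,
    emap$nodes)
  hits <- character()
  for (n in later) {
    for (cn in connections_of(emap, n$node_id)) {
      other <- if (cn$source == n$node_id) cn$target else cn$source
      if (other %in% expert$final_diagnoses &&
          cn$weight != "speaks_against") {
        hits <- c(hits, n$node_id)
        break
      }
    }
  }
  if (length(hits) == 0L) return(NULL)
  bias_finding(
    "premature_closure",
    evidence = list(submission_stage = s, later_evidence_nodes = hits,
                    confidence = submission$confidence),
    explanation = paste0(
      "final diagnosis submitted at stage ", s, ", but the expert adds ",
      length(hits), " later finding(s)/test(s) connected to the final ",
      "diagnosis"))
}

#' Detect availability bias
#'
#' Fires when the learner recently (within `window_days`, default 5)
#' worked on a case whose final diagnosis is within one hierarchy level of
#' the (incorrect) diagnosis submitted now — the recently seen answer came
#' to mind.
#'
#' @param submission the analyzed submission.
#' @param learner_map the learner's final concept map (to resolve node ids
#'   to terms).
#' @param history a `crt_history` of the learner's prior sessions.
#' @param vocab a `crt_vocabulary`.
#' @param now reference date for the recency window (default: the
#'   submission timestamp).
#' @param window_days recency window in days.
#' @return a `crt_bias_finding`, or `NULL`.
#' @export
detect_availability <- function(submission, learner_map, history, vocab,
                                now = NULL, window_days = 5) {
  if (is.null(submission) || length(history$entries) == 0L) return(NULL)
  now <- now %||% submission$submitted_at
  if (is.null(now) || is.na(now)) return(NULL)
  now <- as.Date(substr(as.character(now), 1, 10))
  terms <- submitted_terms(submission, learner_map)
  if (length(terms) == 0L) return(NULL)
  for (e in history$entries) {
    age <- as.numeric(now - as.Date(substr(e$last_accessed, 1, 10)))
    if (age < 0 || age > window_days) next
    for (prior_dx in e$final_diagnoses) {
      if (!prior_dx %in% names(vocab$terms)) next
      for (t in terms) {
        if (is_related_one_level(vocab, t, prior_dx)) {
          return(bias_finding(
            "availability",
            evidence = list(prior_case = e$case_id,
                            prior_diagnosis = prior_dx,
                            last_accessed = e$last_accessed,
                            days_ago = age, submitted_term = t),
            explanation = paste0(
              "a related final diagnosis (", prior_dx, ") was seen in case ",
              e$case_id, " only ", age, " day(s) ago")))
        }
      }
    }
  }
  NULL
}

#' Detect confirmation bias
#'
#' The expert map defines the disconfirming findings for the submitted
#' diagnosis: findings connected "speaks against" to the matching expert
#' differential. The rule fires when the learner neither added any of
#' those findings nor drew a speaks-against connection from an added
#' disconfirming finding to the submitted diagnosis. When the expert
#' defines no disconfirming finding for that diagnosis the rule is not
#' evaluable (`NA` returned).
#'
#' @param session a `crt_replay` (or `crt_session_log`).
#' @param expert a `crt_expert_case`.
#' @param vocab a `crt_vocabulary`.
#' @param submission the analyzed submission.
#' @return a `crt_bias_finding`, `NULL` (silent), or `NA` (not evaluable).
#' @export
detect_confirmation <- function(session, expert, vocab,
                                submission = latest_submission(session)) {
  if (inherits(session, "crt_session_log")) session <- replay(session)
  if (is.null(submission)) return(NULL)
  lmap <- session$final
  emap <- expert$map

  # expert differentials matching the submitted diagnosis
  sub_nodes <- lmap$nodes[as.character(submission$diagnosis_nodes)]
  e_diff <- nodes_by_category(emap, "differential")
  matching_e <- character()
  for (ln in sub_nodes) {
    for (en in e_diff) {
      if (pair_score(ln, en, vocab)$value >= 0.5)
        matching_e <- c(matching_e, en$node_id)
    }
  }
  if (length(matching_e) == 0L) return(NA)

  # disconfirming findings: expert findings linked speaks_against to them
  disconf <- character()
  for (eid in unique(matching_e)) {
    for (cn in connections_of(emap, eid, weight = "speaks_against")) {
      other <- if (cn$source == eid) cn$target else cn$source
      if (emap$nodes[[other]]$category == "finding")
        disconf <- c(disconf, other)
    }
  }
  disconf <- unique(disconf)
  if (length(disconf) == 0L) return(NA)

  # did the learner add any of them, and link it speaks_against?
  l_findings <- nodes_by_category(lmap, "finding")
  added <- character(); linked <- FALSE
  for (d in disconf) {
    en <- emap$nodes[[d]]
    for (ln in l_findings) {
      if (pair_score(ln, en, vocab)$value >= 0.5) {
        added <- c(added, ln$node_id)
        for (cn in connections_of(lmap, ln$node_id,
                                  weight = "speaks_against")) {
          other <- if (cn$source == ln$node_id) cn$target else cn$source
          if (other %in% as.character(submission$diagnosis_nodes))
            linked <- TRUE
        }
      }
    }
  }
  if (length(added) > 0L && linked) return(NULL)
  if (length(added) > 0L && !linked) {
    # finding present but not weighed against the diagnosis
    return(bias_finding(
      "confirmation",
      evidence = list(disconfirming_expert_findings = disconf,
                      added_but_unlinked = unique(added)),
      explanation = paste0(
        "disconfirming finding(s) were added but never connected ",
        "'speaks against' the submitted diagnosis")))
  }
  bias_finding(
    "confirmation",
    evidence = list(disconfirming_expert_findings = disconf,
                    added_but_unlinked = character()),
    explanation = paste0(
      "none of the expert's ", length(disconf), " disconfirming ",
      "finding(s) for the submitted diagnosis were added"))
}

#' Detect representativeness error
#'
#' Fires when the learner connected a nonprototypical finding (flagged in
#' the expert metadata) "speaks against" a differential matching the
#' expert's *correct* final diagnosis — the atypical presentation was used
#' to argue away the right answer. Not evaluable (`NA`) when the expert
#' flags no nonprototypical findings.
#'
#' @inheritParams detect_confirmation
#' @return a `crt_bias_finding`, `NULL`, or `NA` (not evaluable).
#' @export
detect_representativeness <- function(session, expert, vocab,
                                      submission = latest_submission(session)) {
  if (inherits(session, "crt_session_log")) session <- replay(session)
  if (length(expert$nonprototypical_findings) == 0L) return(NA)
  lmap <- session$final
  emap <- expert$map
  e_final <- emap$nodes[expert$final_diagnoses]
  np_nodes <- emap$nodes[expert$nonprototypical_findings]

  for (cn in Filter(function(cn) cn$weight == "speaks_against",
                    lmap$connections)) {
    src <- lmap$nodes[[cn$source]]; tgt <- lmap$nodes[[cn$target]]
    ends <- list(src, tgt)
    fin <- Filter(function(n) n$category == "finding", ends)
    dif <- Filter(function(n) n$category == "differential", ends)
    if (length(fin) == 0L || length(dif) == 0L) next
    np_hit <- any(vapply(np_nodes, function(en)
      pair_score(fin[[1L]], en, vocab)$value >= 0.5, TRUE))
    dx_hit <- any(vapply(e_final, function(en)
      pair_score(dif[[1L]], en, vocab)$value >= 0.5, TRUE))
    if (np_hit && dx_hit) {
      return(bias_finding(
        "representativeness",
        evidence = list(finding_node = fin[[1L]]$node_id,
                        diagnosis_node = dif[[1L]]$node_id),
        explanation = paste0(
          "a nonprototypical finding was connected 'speaks against' the ",
          "correct final diagnosis")))
    }
  }
  NULL
}

#' Detect base-rate neglect
#'
#' Fires when the submitted diagnosis is rare relative to the correct one:
#' `prevalence(submitted) < rare_factor * prevalence(correct)` (default
#' factor 0.1). Not evaluable (`NA`) when the expert metadata lacks a
#' prevalence for either side.
#'
#' @param submission the analyzed submission.
#' @param learner_map the learner's final concept map.
#' @param expert a `crt_expert_case` with prevalence metadata.
#' @param vocab a `crt_vocabulary`.
#' @param rare_factor how many times rarer than the correct diagnosis a
#'   submission must be to count as base-rate neglect.
#' @return a `crt_bias_finding`, `NULL`, or `NA` (not evaluable).
#' @export
detect_base_rate_neglect <- function(submission, learner_map, expert, vocab,
                                     rare_factor = 0.1) {
  if (is.null(submission)) return(NULL)
  if (length(expert$prevalence) == 0L) return(NA)
  if (any(expert$prevalence < 0))
    abort("prevalence rates must be non-negative")

  # prevalence of the submitted diagnosis: match submitted learner nodes to
  # expert differentials carrying a prevalence annotation
  sub_nodes <- learner_map$nodes[as.character(submission$diagnosis_nodes)]
  e_diff <- nodes_by_category(expert$map, "differential")
  prev_sub <- NA_real_; matched_sub <- NA_character_
  for (ln in sub_nodes) {
    for (en in e_diff) {
      if (!en$node_id %in% names(expert$prevalence)) next
      if (pair_score(ln, en, vocab)$value >= 0.5) {
        p <- expert$prevalence[[en$node_id]]
        if (is.na(prev_sub) || p < prev_sub) {
          prev_sub <- p; matched_sub <- en$node_id
        }
      }
    }
  }
  correct_ids <- intersect(expert$final_diagnoses, names(expert$prevalence))
  if (is.na(prev_sub) || length(correct_ids) == 0L) return(NA)
  prev_correct <- max(unlist(expert$prevalence[correct_ids]))

  if (prev_sub < rare_factor * prev_correct) {
    return(bias_finding(
      "base_rate_neglect",
      evidence = list(submitted_diagnosis = matched_sub,
                      submitted_prevalence = prev_sub,
                      correct_prevalence = prev_correct,
                      rare_factor = rare_factor),
      explanation = paste0(
        "the submitted diagnosis (prevalence ", format(prev_sub),
        ") is much rarer than the correct one (prevalence ",
        format(prev_correct), ")")))
  }
  NULL
}

#' Analyze a final-diagnosis submission
#'
#' The submission flow: the submitted diagnosis is scored against the
#' expert's; a full match needs no error analysis, while a partial match
#' or mismatch opens the choice to try again, continue, or request more
#' feedback. On a mismatch all five cognitive-error detectors run (in the
#' fixed order premature closure, availability, confirmation,
#' representativeness, base-rate neglect); detectors whose required expert
#' metadata is missing are listed as not evaluable.
#'
#' @param session a `crt_session_log` or `crt_replay` containing at least
#'   one submission.
#' @param expert a `crt_expert_case`.
#' @param history a `crt_history` (prior sessions of the same learner).
#' @param vocab a `crt_vocabulary`.
#' @param submission which submission to analyze (default: the latest
#'   non-working one).
#' @param window_days availability recency window (days).
#' @param rare_factor base-rate threshold factor.
#' @return a `crt_submission_outcome`: `status` (match / partial_match /
#'   mismatch), `score` (the combined diagnosis score), `findings` (list
#'   of fired `crt_bias_finding`, empty unless mismatch),
#'   `not_evaluable` (bias types whose detector could not run), and
#'   `options` (the choices offered to the learner).
#' @export
analyze_submission <- function(session, expert, history = session_history(),
                               vocab, submission = NULL,
                               window_days = 5, rare_factor = 0.1) {
  if (inherits(session, "crt_session_log")) session <- replay(session)
  submission <- submission %||% latest_submission(session)
  if (is.null(submission))
    abort("session contains no final-diagnosis submission")
  if (length(expert$final_diagnoses) == 0L)
    abort("expert case defines no final diagnosis",
          class = "crtool_config_error")
  lmap <- session$final
  dx <- score_final_diagnosis(submission, lmap, expert, vocab)
  status <- if (dx$combined >= 1) "match"
            else if (dx$combined > 0) "partial_match" else "mismatch"

  findings <- list(); not_evaluable <- character()
  if (status == "mismatch") {
    res <- list(
      premature_closure = detect_premature_closure(session, expert,
                                                   submission),
      availability = detect_availability(submission, lmap, history, vocab,
                                         window_days = window_days),
      confirmation = detect_confirmation(session, expert, vocab, submission),
      representativeness = detect_representativeness(session, expert, vocab,
                                                     submission),
      base_rate_neglect = detect_base_rate_neglect(submission, lmap, expert,
                                                   vocab, rare_factor))
    for (bt in bias_types) {
      r <- res[[bt]]
      if (is.null(r)) next
      if (identical(r, NA)) not_evaluable <- c(not_evaluable, bt)
      else findings[[length(findings) + 1L]] <- r
    }
  }
  options <- if (status == "match") c("continue", "more_feedback")
             else c("try_again", "continue", "more_feedback")
  structure(list(status = status, score = dx$combined,
                 diagnosis_score = dx, findings = findings,
                 not_evaluable = not_evaluable, options = options,
                 confidence = submission$confidence),
            class = "crt_submission_outcome")
}

#' @export
print.crt_submission_outcome <- function(x, ...) {
  cat("<crt_submission_outcome> ", x$status, " (score ",
      format(round(x$score, 3)), ")\n", sep = "")
  for (f in x$findings) cat("  - ", f$bias_type, ": ", f$explanation, "\n",
                            sep = "")
  if (length(x$not_evaluable))
    cat("  not evaluable: ", paste(x$not_evaluable, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}
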