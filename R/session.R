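#' Score a whole session
#'
#' Replays the log, scores every stage the learner reached against the
#' expert map at that stage, scores the latest final-diagnosis submission
#' and the summary statement, runs the submission analysis, and combines
#' everything into a weighted total and cluster scores for the dashboard.
#'
#' @param log a `crt_session_log`.
#' @param expert a `crt_expert_case`.
#' @param vocab a `crt_vocabulary`.
#' @param history a `crt_history` for the availability detector.
#' @param weights aggregation weights, see [aggregate_session()].
#' @param lexicon qualifier lexicon for the summary rubric.
#' @param partial_window hierarchical partial-credit window.
#' @return a `crt_session_score` with components `session_id`,
#'   `learner_id`, `case_id`, `started_at`, `stage_scores`,
#'   `diagnosis_score`, `summary_score`, `outcome`
#'   (a `crt_submission_outcome`, `NULL` without a submission), `clusters`,
#'   `self_directed`, `dual_processing`, and `total`.
#' @export
score_session <- function(log, expert, vocab, history = session_history(),
                          weights = c(1, 1, 1) / 3,
                          lexicon = default_qualifier_lexicon(),
                          partial_window = 5L) {
  stopifnot(inherits(log, "crt_session_log"),
            inherits(expert, "crt_expert_case"))
  rep <- replay(log)
  n_score_stages <- min(rep$n_stages_seen, expert$n_stages)
  stage_scores <- lapply(seq_len(n_score_stages) - 1L, function(s)
    score_stage(rep$snapshots[[s + 1L]], expert_map_at_stage(expert, s),
                vocab, stage = s, partial_window = partial_window))

  submission <- latest_submission(rep)
  diagnosis_score <- NULL
  outcome <- NULL
  if (!is.null(submission)) {
    diagnosis_score <- score_final_diagnosis(submission, rep$final, expert,
                                             vocab, partial_window)
    outcome <- analyze_submission(rep, expert, history, vocab,
                                  submission = submission)
  }

  summary_score <- NULL
  expert_q <- if (!is.null(expert$summary_statement))
    extract_qualifiers(expert$summary_statement, lexicon) else character()
  if (length(expert_q) > 0L)
    summary_score <- score_summary(rep$final$summary_statement %||% "",
                                   expert$summary_statement, lexicon)

  # components missing on the expert side (no summary, scorable) drop out
  # and the remaining weights are renormalized
  comp <- c(stages = mean(vapply(stage_scores, `[[`, 0, "overall")),
            diagnosis = if (is.null(diagnosis_score)) NA_real_
                        else diagnosis_score$combined,
            summary = if (is.null(summary_score)) NA_real_
                      else summary_score$rubric / 2)
  avail <- !is.na(comp)
  total <- if (any(avail)) {
    w <- weights[avail] / sum(weights[avail])
    sum(w * comp[avail])
  } else NA_real_

  clusters <- compute_clusters(stage_scores,
                               if (is.null(diagnosis_score)) NA_real_
                               else diagnosis_score$combined,
                               summary_score)

  structure(list(session_id = log$session_id, learner_id = log$learner_id,
                 case_id = log$case_id, started_at = log$started_at,
                 stage_scores = stage_scores,
                 diagnosis_score = diagnosis_score,
                 summary_score = summary_score, outcome = outcome,
                 clusters = clusters,
                 self_directed = self_directed_fraction(log),
                 dual_processing = dual_processing_indicator(log,
                                                             expert$n_stages),
                 total = total),
            class = "crt_session_score")
}

#' @export
print.crt_session_score <- function(x, ...) {
  cat("<crt_session_score> ", x$session_id, ": total ",
      format(round(x$total, 4)), "\n", sep = "")
  cat("  stages: ",
      paste(vapply(x$stage_scores,
                   function(s) format(round(s$overall, 3)), ""),
            collapse = " "), "\n", sep = "")
  if (!is.null(x$outcome))
    cat("  final diagnosis: ", x$outcome$status, " (",
        format(round(x$outcome$score, 3)), ")\n", sep = "")
  if (!is.null(x$summary_score))
    cat("  summary rubric: ", x$summary_score$rubric, "/2\n", sep = "")
  invisible(x)
}
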