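#' Learning-analytics clusters and the learner dashboard
#'
#' All scores are clustered along a process model of clinical reasoning:
#' problem representation (finding nodes), investigations (test nodes),
#' therapeutic interventions (therapy nodes), categorization (differential
#' nodes and the final diagnosis), and semantic transformation (the
#' summary statement). Two further indicators — self-directed learning and
#' the dual-processing index — are computed per session; they are kept
#' internal (serialized but not part of learner-facing feedback).
#'
#' @name analytics
NULL

cluster_names <- c("problem_representation", "investigations",
                   "therapeutic", "categorization",
                   "semantic_transformation")

#' Cluster a session's scores
#'
#' Each node-category cluster is the mean score of the learner's
#' final-stage nodes in that category. A category the expert expects but
#' the learner left empty scores 0; a category empty on both sides is
#' not applicable (`NA`). Categorization averages the differential-node
#' cluster with the final-diagnosis score; semantic transformation is the
#' summary rubric rescaled to `[0, 1]`.
#'
#' @param stage_scores list of `crt_stage_score` (the last one is used).
#' @param diagnosis_score combined final-diagnosis score in `[0, 1]`, or
#'   `NA` if no submission was made.
#' @param summary_score a `crt_summary_score` or `NULL`/`NA`.
#' @return a `crt_cluster_scores`: named numeric vector over the five
#'   clusters, `NA` marking not-applicable ones.
#' @export
compute_clusters <- function(stage_scores, diagnosis_score = NA_real_,
                             summary_score = NULL) {
  if (inherits(stage_scores, "crt_stage_score"))
    stage_scores <- list(stage_scores)
  if (length(stage_scores) == 0L) abort("at least one stage score required")
  fin <- stage_scores[[length(stage_scores)]]

  cat_cluster <- function(cat) {
    vals <- fin$per_node$value[fin$per_node$category == cat]
    if (length(vals) > 0L) return(mean(vals))
    if (fin$expert_by_category[[cat]] > 0L) 0 else NA_real_
  }
  diff_cluster <- cat_cluster("differential")
  dx <- if (inherits(diagnosis_score, "crt_diagnosis_score"))
    diagnosis_score$combined else as.numeric(diagnosis_score)
  categ <- mean(c(diff_cluster, dx), na.rm = TRUE)
  if (is.nan(categ)) categ <- NA_real_

  sem <- if (inherits(summary_score, "crt_summary_score"))
    summary_score$rubric / 2
  else if (is.numeric(summary_score) && !is.na(summary_score))
    as.numeric(summary_score) / 2
  else NA_real_

  structure(c(problem_representation = cat_cluster("finding"),
              investigations = cat_cluster("test"),
              therapeutic = cat_cluster("therapy"),
              categorization = categ,
              semantic_transformation = sem),
            class = "crt_cluster_scores")
}

#' @export
print.crt_cluster_scores <- function(x, ...) {
  cat("<crt_cluster_scores>\n")
  for (nm in cluster_names)
    cat("  ", format(nm, width = 24), " ",
        if (is.na(x[[nm]])) "n/a" else format(round(x[[nm]], 3)), "\n",
        sep = "")
  invisible(x)
}

#' Self-directed-learning fraction
#'
#' The share of node and connection additions the learner made before (or
#' without) consulting the expert solution. A session with no additions
#' and no consult is vacuously self-directed (1); no additions but a
#' consult gives 0.
#'
#' @param log a `crt_session_log`.
#' @return a value in `[0, 1]`.
#' @export
self_directed_fraction <- function(log) {
  stopifnot(inherits(log, "crt_session_log"))
  actions <- vapply(log$events, `[[`, "", "action")
  adds <- which(actions %in% c("add_node", "add_connection"))
  consult <- which(actions == "consult_expert")
  if (length(adds) == 0L) return(if (length(consult) == 0L) 1 else 0)
  if (length(consult) == 0L) return(1)
  sum(adds < consult[1L]) / length(adds)
}

#' Dual-processing indicator
#'
#' Submitting a final diagnosis early in the scenario indicates a more
#' nonanalytic (pattern-recognition) approach. The indicator rescales the
#' stage of the first submission to `[0, 1]`:
#' `1 - stage / (n_stages - 1)`, so 1 means the earliest possible
#' submission and 0 a submission at the last stage. Single-stage
#' scenarios score 1.
#'
#' @param log a `crt_session_log`.
#' @param n_stages total number of stages of the scenario.
#' @return a value in `[0, 1]`, or `NA` when the session holds no
#'   submission.
#' @export
dual_processing_indicator <- function(log, n_stages) {
  stopifnot(inherits(log, "crt_session_log"))
  if (!is_count(n_stages) || n_stages < 1)
    abort("n_stages must be a positive count")
  subs <- Filter(function(e) e$action == "submit_final", log$events)
  if (length(subs) == 0L) return(NA_real_)
  if (n_stages == 1L) return(1)
  s <- subs[[1L]]$stage
  1 - min(s, n_stages - 1L) / (n_stages - 1L)
}

#' Assemble dashboard data for one learner
#'
#' @param learner_sessions list of `crt_session_score` for the focal
#'   learner, across the case collection.
#' @param peer_sessions list of `crt_session_score` for the peer group;
#'   sessions belonging to the focal learner are excluded from the peer
#'   statistics.
#' @return a `crt_dashboard`: `learner_id`, `trend` (data.frame of
#'   per-session cluster scores ordered by session start time),
#'   `peer_stats` (per-cluster mean and sd over the peer sessions),
#'   `recommendations` (cluster names ordered weakest first, by the
#'   learner's latest session; not-applicable clusters excluded), and the
#'   internal `self_directed` / `dual_processing` indicator columns.
#' @export
build_dashboard <- function(learner_sessions, peer_sessions = list()) {
  if (length(learner_sessions) == 0L) {
    warning("no sessions for this learner; dashboard is empty")
    return(structure(list(learner_id = NA_character_,
                          trend = data.frame(), peer_stats = data.frame(),
                          recommendations = character()),
                     class = "crt_dashboard"))
  }
  learner_id <- learner_sessions[[1L]]$learner_id

  session_row <- function(s) {
    data.frame(session_id = s$session_id, case_id = s$case_id,
               learner_id = s$learner_id,
               started_at = as.character(s$started_at %||% NA),
               total = s$total,
               as.list(stats::setNames(as.numeric(s$clusters),
                                       cluster_names)),
               self_directed = s$self_directed,
               dual_processing = s$dual_processing,
               stringsAsFactors = FALSE)
  }
  trend <- do.call(rbind, lapply(learner_sessions, session_row))
  trend <- trend[order(trend$started_at, trend$session_id), , drop = FALSE]
  rownames(trend) <- NULL

  peers <- Filter(function(s) !identical(s$learner_id, learner_id),
                  peer_sessions)
  peer_stats <- if (length(peers)) {
    pm <- do.call(rbind, lapply(peers, session_row))
    do.call(rbind, lapply(cluster_names, function(cl)
      data.frame(cluster = cl,
                 mean = mean(pm[[cl]], na.rm = TRUE),
                 sd = stats::sd(pm[[cl]], na.rm = TRUE),
                 n = sum(!is.na(pm[[cl]])),
                 stringsAsFactors = FALSE)))
  } else data.frame(cluster = character(), mean = numeric(),
                    sd = numeric(), n = integer(),
                    stringsAsFactors = FALSE)

  latest <- trend[nrow(trend), cluster_names, drop = FALSE]
  vals <- as.numeric(latest)
  ok <- !is.na(vals)
  recommendations <- cluster_names[ok][order(vals[ok],
                                             seq_along(vals[ok]))]

  structure(list(learner_id = learner_id, trend = trend,
                 peer_stats = peer_stats,
                 recommendations = recommendations),
            class = "crt_dashboard")
}

#' @export
print.crt_dashboard <- function(x, ...) {
  cat("<crt_dashboard> learner ", x$learner_id, ": ",
      nrow(x$trend), " session(s); weakest clusters: ",
      paste(utils::head(x$recommendations, 3), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
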