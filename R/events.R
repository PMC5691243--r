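event_actions <- c("add_node", "delete_node", "add_connection",
                   "delete_connection", "set_weight", "set_flag",
                   "consult_expert", "advance_stage", "submit_final",
                   "set_summary")

#' Create a session event
#'
#' One timestamped, stage-annotated learner action. The payload schema
#' depends on the action:
#' \describe{
#'   \item{add_node}{`node_id`, `category`, and `term` or `label`, plus
#'     optional flags `negated`, `must_not_miss`, `ruled_out`}
#'   \item{delete_node}{`node_id`}
#'   \item{add_connection / delete_connection / set_weight}{`source`,
#'     `target` (+ `weight` except for delete)}
#'   \item{set_flag}{`node_id`, `flag` (negated / must_not_miss /
#'     ruled_out), `value`}
#'   \item{consult_expert / advance_stage}{empty payload}
#'   \item{submit_final}{`diagnosis_nodes` (character vector of node ids),
#'     `confidence` in 1..100, optional `working` flag}
#'   \item{set_summary}{`text`}
#' }
#'
#' @param action one of the supported actions.
#' @param payload named list, schema per action.
#' @param stage 0-based stage index at which the action happened.
#' @param at timestamp (ISO-8601 string).
#' @return a `crt_event`.
#' @export
map_event <- function(action, payload = list(), stage = 0L, at = NA) {
  if (!is_string(action) || !action %in% event_actions)
    abort("unknown action: ", action)
  structure(list(action = action, payload = payload,
                 stage = as.integer(stage), at = at),
            class = "crt_event")
}

#' Create a session log
#'
#' The ordered record of everything a learner did in one virtual-patient
#' session. Timestamps must be non-decreasing and stage indices
#' non-decreasing (stages advance through `advance_stage` events and never
#' go back).
#'
#' @param session_id,case_id,learner_id identifiers.
#' @param events list of `crt_event`, in order.
#' @param started_at session start timestamp (ISO-8601).
#' @return a `crt_session_log`.
#' @export
session_log <- function(session_id, case_id, learner_id, events,
                        started_at = NA) {
  stopifnot(is_string(session_id), is_string(case_id), is_string(learner_id))
  events <- lapply(events, function(e) {
    if (!inherits(e, "crt_event"))
      e <- map_event(e$action, e$payload %||% list(),
                     e$stage %||% 0L, e$at %||% NA)
    e
  })
  stages <- vapply(events, `[[`, 0L, "stage")
  if (is.unsorted(stages))
    abort("event stage indices must be non-decreasing")
  ats <- vapply(events, function(e) as.character(e$at %||% NA), "")
  ats <- ats[!is.na(ats)]
  if (length(ats) > 1L && is.unsorted(ats))
    abort("event timestamps must be non-decreasing")
  structure(list(session_id = session_id, case_id = case_id,
                 learner_id = learner_id, events = events,
                 started_at = started_at),
            class = "crt_session_log")
}

#' @export
print.crt_session_log <- function(x, ...) {
  cat("<crt_session_log> ", x$session_id, " (case ", x$case_id,
      ", learner ", x$learner_id, "): ", length(x$events), " events\n",
      sep = "")
  invisible(x)
}

#' Apply one event to a concept-map state
#'
#' Pure state transition: returns the new map, never mutates. Deleting a
#' node cascades to its incident connections. Invalid events (dangling
#' references, duplicate ids, flags on the wrong category) raise a
#' validation error; `event_index` is quoted in the message when supplied.
#'
#' @param map a `crt_concept_map` (current state).
#' @param event a `crt_event`.
#' @param event_index optional position of the event in its log, used in
#'   error messages.
#' @return the updated `crt_concept_map`.
#' @export
apply_event <- function(map, event, event_index = NA) {
  stopifnot(inherits(map, "crt_concept_map"), inherits(event, "crt_event"))
  p <- event$payload
  at_idx <- function(msg) {
    if (!is.na(event_index)) paste0("event ", event_index, ": ", msg) else msg
  }
  tryCatch(
    switch(event$action,
      add_node = {
        node <- map_node(
          node_id = p$node_id, category = p$category,
          term = p$term, label = p$label,
          negated = isTRUE(p$negated),
          must_not_miss = isTRUE(p$must_not_miss),
          ruled_out = isTRUE(p$ruled_out),
          stage_added = event$stage, added_at = event$at)
        add_node_to_map(map, node)
      },
      delete_node = delete_node_from_map(map, p$node_id),
      add_connection = add_connection_to_map(map, p$source, p$target,
                                             p$weight),
      delete_connection = {
        key <- conn_key(p$source, p$target)
        if (!key %in% names(map$connections))
          abort("cannot delete unknown connection: ", key)
        map$connections[[key]] <- NULL
        map
      },
      set_weight = {
        key <- conn_key(p$source, p$target)
        if (!key %in% names(map$connections))
          abort("cannot reweight unknown connection: ", key)
        map$connections[[key]]$weight <- weight_name(p$weight)
        map
      },
      set_flag = {
        if (!p$node_id %in% names(map$nodes))
          abort("set_flag on unknown node: ", p$node_id)
        if (!p$flag %in% node_flags)
          abort("unknown flag: ", p$flag)
        node <- map$nodes[[p$node_id]]
        if (p$flag == "negated" && node$category != "finding")
          abort("negated only valid on findings (node ", p$node_id, ")")
        if (p$flag != "negated" && node$category != "differential")
          abort(p$flag, " only valid on differentials (node ", p$node_id, ")")
        node[[p$flag]] <- isTRUE(p$value)
        map$nodes[[p$node_id]] <- node
        map
      },
      set_summary = { map$summary_statement <- p$text; map },
      submit_final = {
        ids <- as.character(unlist(p$diagnosis_nodes))
        if (length(ids) == 0L) abort("submit_final with no diagnosis nodes")
        for (id in ids) {
          if (!id %in% names(map$nodes))
            abort("submitted diagnosis node does not exist: ", id)
          if (map$nodes[[id]]$category != "differential")
            abort("submitted node is not a differential: ", id)
        }
        conf <- p$confidence %||% NA
        if (!is.na(conf) && (conf < 1 || conf > 100 || conf != floor(conf)))
          abort("confidence must be an integer in [1, 100], got ", conf)
        if (!can_submit_final(map))
          abort("submission requires at least one differential in the map")
        map
      },
      consult_expert = map,
      advance_stage = map,
      abort("unknown action: ", event$action)
    ),
    crtool_error = function(e) abort(at_idx(conditionMessage(e)))
  )
}

#' Replay a session log into per-stage snapshots
#'
#' Deterministically reconstructs the learner's concept map from the event
#' stream. One snapshot is kept per stage boundary (the map as it stood
#' when the learner left that stage) plus the final state.
#'
#' @param log a `crt_session_log`.
#' @return a `crt_replay` list with components
#'   \describe{
#'     \item{snapshots}{list of `crt_concept_map`, element `s + 1` is the
#'       map at the end of stage `s`}
#'     \item{final}{the final concept map}
#'     \item{submissions}{list of final-diagnosis submissions, each with
#'       `diagnosis_nodes`, `confidence`, `working`, `stage`,
#'       `submitted_at`}
#'     \item{consults}{data.frame of expert-map consults (stage, at)}
#'     \item{first_consult_index}{index (in the event stream) of the first
#'       consult, or `NA`}
#'     \item{n_stages_seen}{number of stages touched by the log}
#'   }
#' @export
replay <- function(log) {
  stopifnot(inherits(log, "crt_session_log"))
  state <- concept_map()
  snapshots <- list()
  submissions <- list()
  consults <- data.frame(stage = integer(), at = character(),
                         stringsAsFactors = FALSE)
  first_consult <- NA_integer_
  cur_stage <- 0L

  for (i in seq_along(log$events)) {
    e <- log$events[[i]]
    if (e$stage > cur_stage) {
      # fill snapshots for every stage boundary crossed
      for (s in cur_stage:(e$stage - 1L)) snapshots[[s + 1L]] <- state
      cur_stage <- e$stage
    }
    state <- apply_event(state, e, event_index = i)
    if (e$action == "submit_final") {
      submissions[[length(submissions) + 1L]] <- list(
        diagnosis_nodes = as.character(unlist(e$payload$diagnosis_nodes)),
        confidence = e$payload$confidence %||% NA,
        working = isTRUE(e$payload$working),
        stage = e$stage, submitted_at = e$at)
    }
    if (e$action == "consult_expert") {
      consults <- rbind(consults, data.frame(
        stage = e$stage, at = as.character(e$at %||% NA),
        stringsAsFactors = FALSE))
      if (is.na(first_consult)) first_consult <- i
    }
  }
  snapshots[[cur_stage + 1L]] <- state

  structure(list(snapshots = snapshots, final = state,
                 submissions = submissions, consults = consults,
                 first_consult_index = first_consult,
                 n_stages_seen = cur_stage + 1L),
            class = "crt_replay")
}

#' The submission a session is scored on
#'
#' With several submissions in one session the latest non-working one is
#' analyzed; working diagnoses are excluded from scoring and error
#' analysis.
#'
#' @param rep a `crt_replay` (or a `crt_session_log`, replayed on the fly).
#' @return a submission record, or `NULL` if none.
#' @export
latest_submission <- function(rep) {
  if (inherits(rep, "crt_session_log")) rep <- replay(rep)
  subs <- Filter(function(s) !isTRUE(s$working), rep$submissions)
  if (length(subs) == 0L) return(NULL)
  subs[[length(subs)]]
}
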