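#' Case bundles: the on-disk exchange format
#'
#' A case bundle is a directory holding everything a VP system exchanges
#' with the assessment core, as plain JSON:
#' \describe{
#'   \item{vocabulary.json}{the native vocabulary dialect (array of
#'     `{id, label, synonyms, tree_addresses}`)}
#'   \item{case.json}{the expert case: staged nodes, weighted connections
#'     (weights as the integers -1, 1, 2, 3, 4), final diagnoses,
#'     prevalence and nonprototypical-finding annotations, summary
#'     statement, `n_stages`, and a `schema_version` tag}
#'   \item{sessions/*.json}{learner session logs: ISO-8601-timestamped,
#'     stage-annotated events}
#'   \item{history.json}{optional prior-session history for the
#'     availability detector}
#' }
#'
#' @name case_bundle
NULL

BUNDLE_SCHEMA_VERSION <- "1"

# drop NULL members so they are omitted from the JSON instead of
# serializing as empty objects
compact <- function(x) x[!vapply(x, is.null, TRUE)]

node_to_json <- function(n) {
  compact(list(node_id = n$node_id, category = n$category,
               term = n$term, label = n$label, negated = n$negated,
               must_not_miss = n$must_not_miss, ruled_out = n$ruled_out,
               stage_added = n$stage_added,
               added_at = if (is.null(n$added_at) || is.na(n$added_at))
                 NULL else as.character(n$added_at)))
}

node_from_json <- function(x) {
  map_node(node_id = x$node_id, category = x$category,
           term = x$term, label = x$label,
           negated = isTRUE(x$negated),
           must_not_miss = isTRUE(x$must_not_miss),
           ruled_out = isTRUE(x$ruled_out),
           stage_added = x$stage_added %||% 0L,
           added_at = x$added_at %||% NA)
}

map_to_json <- function(map) {
  ws <- connection_weights()
  list(nodes = lapply(unname(map$nodes), node_to_json),
       connections = lapply(unname(map$connections), function(cn)
         list(source = cn$source, target = cn$target,
              weight = unname(ws[[cn$weight]]))),
       summary_statement = map$summary_statement)
}

map_from_json <- function(x) {
  m <- concept_map()
  for (n in x$nodes %||% list()) m <- add_node_to_map(m, node_from_json(n))
  for (cn in x$connections %||% list())
    m <- add_connection_to_map(m, cn$source, cn$target, cn$weight)
  m$summary_statement <- x$summary_statement
  m
}

#' Write / read an expert case as JSON
#' @param expert a `crt_expert_case`.
#' @param path file path (`case.json`).
#' @return `path` / a `crt_expert_case`.
#' @export
write_expert_case <- function(expert, path) {
  stopifnot(inherits(expert, "crt_expert_case"))
  x <- c(compact(list(schema_version = BUNDLE_SCHEMA_VERSION,
                      n_stages = expert$n_stages,
                      final_diagnoses = as.list(expert$final_diagnoses),
                      prevalence = as.list(expert$prevalence),
                      nonprototypical_findings =
                        as.list(expert$nonprototypical_findings),
                      summary_statement = expert$summary_statement)),
         compact(map_to_json(expert$map)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_expert_case
#' @export
read_expert_case <- function(path) {
  if (!file.exists(path)) abort("case file not found: ", path,
                                class = "crtool_io_error")
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  expert_case(map_from_json(x),
              final_diagnoses = unlist(x$final_diagnoses),
              n_stages = x$n_stages,
              prevalence = unlist(x$prevalence) %||% numeric(),
              nonprototypical_findings =
                as.character(unlist(x$nonprototypical_findings)),
              summary_statement = x$summary_statement)
}

#' Write / read a session log as JSON
#' @param log a `crt_session_log`.
#' @param path file path.
#' @return `path` / a `crt_session_log`.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "crt_session_log"))
  x <- list(schema_version = BUNDLE_SCHEMA_VERSION,
            session_id = log$session_id, case_id = log$case_id,
            learner_id = log$learner_id,
            started_at = log$started_at,
            events = lapply(log$events, function(e)
              compact(list(action = e$action, stage = e$stage,
                           at = if (is.null(e$at) || is.na(e$at)) NULL
                                else as.character(e$at),
                           payload = compact(e$payload)))))
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) abort("session file not found: ", path,
                                class = "crtool_io_error")
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  events <- lapply(x$events, function(e) {
    p <- e$payload %||% list()
    # vectors flattened by JSON round-trip
    if (!is.null(p$diagnosis_nodes))
      p$diagnosis_nodes <- as.character(unlist(p$diagnosis_nodes))
    map_event(e$action, p, e$stage %||% 0L, e$at %||% NA)
  })
  session_log(x$session_id, x$case_id, x$learner_id, events,
              started_at = x$started_at %||% NA)
}

#' Write / read a prior-session history as JSON
#' @param history a `crt_history`.
#' @param path file path.
#' @return `path` / a `crt_history`.
#' @export
write_history <- function(history, path) {
  stopifnot(inherits(history, "crt_history"))
  jsonlite::write_json(
    list(schema_version = BUNDLE_SCHEMA_VERSION,
         entries = lapply(history$entries, function(e)
           list(case_id = e$case_id, last_accessed = e$last_accessed,
                final_diagnoses = as.list(e$final_diagnoses)))),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  if (!file.exists(path)) abort("history file not found: ", path,
                                class = "crtool_io_error")
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  session_history(x$entries %||% list())
}

#' Write a complete case bundle
#'
#' @param dir target directory (created if missing).
#' @param vocab a `crt_vocabulary`.
#' @param expert a `crt_expert_case`.
#' @param sessions list of `crt_session_log`.
#' @param history optional `crt_history`.
#' @return `dir`, invisibly.
#' @export
write_case_bundle <- function(dir, vocab, expert, sessions = list(),
                              history = NULL) {
  dir.create(file.path(dir, "sessions"), recursive = TRUE,
             showWarnings = FALSE)
  write_vocabulary(vocab, file.path(dir, "vocabulary.json"))
  write_expert_case(expert, file.path(dir, "case.json"))
  for (log in sessions)
    write_session_log(log, file.path(dir, "sessions",
                                     paste0(log$session_id, ".json")))
  if (!is.null(history)) write_history(history, file.path(dir,
                                                          "history.json"))
  invisible(dir)
}

#' Read a case bundle directory
#' @param dir bundle directory.
#' @return a `crt_bundle`: `vocab`, `expert`, `sessions` (named list),
#'   `history` (possibly empty).
#' @export
read_case_bundle <- function(dir) {
  if (!dir.exists(dir)) abort("bundle directory not found: ", dir,
                              class = "crtool_io_error")
  vocab <- read_vocabulary(file.path(dir, "vocabulary.json"))
  expert <- read_expert_case(file.path(dir, "case.json"))
  attr(expert, "vocab") <- vocab
  sess_files <- sort(list.files(file.path(dir, "sessions"),
                                pattern = "\\.json$", full.names = TRUE))
  sessions <- lapply(sess_files, read_session_log)
  names(sessions) <- vapply(sessions, `[[`, "", "session_id")
  hist_path <- file.path(dir, "history.json")
  history <- if (file.exists(hist_path)) read_history(hist_path)
             else session_history()
  structure(list(vocab = vocab, expert = expert, sessions = sessions,
                 history = history),
            class = "crt_bundle")
}

#' Validate a case bundle
#'
#' Runs structural and referential checks over a bundle directory and
#' reports every violation with a JSON-pointer-style location. An empty
#' report means the bundle is valid.
#'
#' @param dir bundle directory.
#' @return a `crt_validation_report` data.frame with columns `location`
#'   and `message` (zero rows when valid).
#' @export
validate_bundle <- function(dir) {
  violations <- data.frame(location = character(), message = character(),
                           stringsAsFactors = FALSE)
  add <- function(location, message) {
    violations <<- rbind(violations, data.frame(
      location = location, message = message, stringsAsFactors = FALSE))
  }
  if (!dir.exists(dir)) abort("bundle directory not found: ", dir,
                              class = "crtool_io_error")

  vocab <- tryCatch(read_vocabulary(file.path(dir, "vocabulary.json")),
                    error = function(e) {
                      add("/vocabulary.json", conditionMessage(e)); NULL })
  raw_case <- tryCatch(
    jsonlite::read_json(file.path(dir, "case.json"),
                        simplifyVector = FALSE),
    error = function(e) { add("/case.json", conditionMessage(e)); NULL })

  expert <- NULL
  if (!is.null(raw_case)) {
    if (is.null(raw_case$schema_version))
      add("/case.json/schema_version", "missing schema version tag")
    expert <- tryCatch(read_expert_case(file.path(dir, "case.json")),
                       error = function(e) {
                         add("/case.json", conditionMessage(e)); NULL })
  }
  if (!is.null(expert) && !is.null(vocab)) {
    for (i in seq_along(expert$map$nodes)) {
      n <- expert$map$nodes[[i]]
      if (!is.null(n$term) && !n$term %in% names(vocab$terms))
        add(paste0("/case.json/nodes/", i - 1L, "/term"),
            paste0("unknown term id '", n$term, "'"))
      if (n$stage_added < 0 || n$stage_added >= expert$n_stages)
        add(paste0("/case.json/nodes/", i - 1L, "/stage_added"),
            paste0("stage ", n$stage_added, " outside 0..",
                   expert$n_stages - 1L))
    }
  }

  sess_files <- sort(list.files(file.path(dir, "sessions"),
                                pattern = "\\.json$", full.names = TRUE))
  for (f in sess_files) {
    ptr <- paste0("/sessions/", basename(f))
    log <- tryCatch(read_session_log(f),
                    error = function(e) { add(ptr, conditionMessage(e)); NULL })
    if (is.null(log)) next
    rep <- tryCatch(replay(log),
                    error = function(e) {
                      add(paste0(ptr, "/events"), conditionMessage(e)); NULL })
    for (i in seq_along(log$events)) {
      e <- log$events[[i]]
      if (e$action == "add_node" && !is.null(e$payload$term) &&
          !is.null(vocab) && !e$payload$term %in% names(vocab$terms))
        add(paste0(ptr, "/events/", i - 1L, "/payload/term"),
            paste0("unknown term id '", e$payload$term, "'"))
      if (!is.null(expert) &&
          (e$stage < 0 || e$stage >= expert$n_stages))
        add(paste0(ptr, "/events/", i - 1L, "/stage"),
            paste0("stage ", e$stage, " outside 0..",
                   expert$n_stages - 1L))
    }
  }

  hist_path <- file.path(dir, "history.json")
  if (file.exists(hist_path))
    tryCatch(read_history(hist_path),
             error = function(e) add("/history.json", conditionMessage(e)))

  class(violations) <- c("crt_validation_report", "data.frame")
  violations
}

#' @export
print.crt_validation_report <- function(x, ...) {
  if (nrow(x) == 0L) cat("bundle valid: 0 violations\n")
  else {
    cat(nrow(x), "violation(s):\n")
    for (i in seq_len(nrow(x)))
      cat("  ", x$location[i], ": ", x$message[i], "\n", sep = "")
  }
  invisible(x)
}

#' Initialize API session state
#'
#' The library-level counterpart of the VP-system integration contract:
#' a state object is initialized from an expert case, then updated with
#' event batches ([api_session_update()]); each update returns the
#' refreshed performance payload.
#'
#' @param expert a `crt_expert_case`.
#' @param vocab a `crt_vocabulary`.
#' @param session_id,learner_id identifiers for the running session.
#' @param history a `crt_history`.
#' @param case_id case identifier.
#' @return a `crt_api_state`.
#' @export
init_session <- function(expert, vocab, session_id = "api-session",
                         learner_id = "api-learner", case_id = "api-case",
                         history = session_history()) {
  stopifnot(inherits(expert, "crt_expert_case"),
            inherits(vocab, "crt_vocabulary"))
  structure(list(expert = expert, vocab = vocab, history = history,
                 session_id = session_id, learner_id = learner_id,
                 case_id = case_id, events = list(),
                 started_at = NA),
            class = "crt_api_state")
}

#' Apply an event batch to an API session
#'
#' Batches are atomic: if any event in the batch is invalid the whole
#' batch is rejected and the state is unchanged. Applying batches one
#' after the other is equivalent to applying their concatenation.
#'
#' @param state a `crt_api_state` from [init_session()].
#' @param events list of `crt_event` (or payload lists accepted by
#'   [map_event()]).
#' @return a list with `state` (updated), `stage_scores` (scores of all
#'   stages reached so far), `outcome` (a `crt_submission_outcome` when
#'   the batch contains a final submission, else `NULL`) and `session`
#'   (the full `crt_session_score`).
#' @export
api_session_update <- function(state, events = list()) {
  stopifnot(inherits(state, "crt_api_state"))
  candidate <- c(state$events, events)
  log <- session_log(state$session_id, state$case_id, state$learner_id,
                     candidate, started_at = state$started_at)
  replay(log)  # validates the whole stream; abort here = batch rejected
  state$events <- log$events
  score <- score_session(log, state$expert, state$vocab, state$history)
  has_submit <- any(vapply(events, function(e)
    (e$action %||% "") == "submit_final", TRUE))
  list(state = state,
       stage_scores = score$stage_scores,
       outcome = if (has_submit) score$outcome else NULL,
       session = score)
}
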