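#' Create an expert case
#'
#' The reference against which learner maps are scored: a staged expert
#' concept map plus the metadata the bias detectors need. A node's
#' `stage_added` is interpreted as "expected from this stage on" — the
#' expert map *at* stage `s` contains every expert node with
#' `stage_added <= s` (and the connections whose endpoints are both
#' visible).
#'
#' @param map a `crt_concept_map` built from expert nodes.
#' @param final_diagnoses character vector of node ids (differentials in
#'   `map`) constituting the correct final diagnosis/-es.
#' @param n_stages total number of stages of the scenario (stages are
#'   0-based, so valid stages are `0 .. n_stages - 1`).
#' @param prevalence named numeric vector: differential node id ->
#'   non-negative disease prevalence (rate). Needed by the base-rate
#'   detector; may be empty, which makes that detector not evaluable.
#' @param nonprototypical_findings character vector of finding node ids
#'   flagged as nonprototypical (for the representativeness detector).
#' @param summary_statement the expert's summary statement text.
#' @return a `crt_expert_case`.
#' @export
expert_case <- function(map, final_diagnoses, n_stages,
                        prevalence = numeric(),
                        nonprototypical_findings = character(),
                        summary_statement = NULL) {
  stopifnot(inherits(map, "crt_concept_map"))
  if (!is_count(n_stages) || n_stages < 1)
    abort("n_stages must be a positive count")
  final_diagnoses <- as.character(final_diagnoses)
  if (length(final_diagnoses) == 0L)
    abort("an expert case needs at least one final diagnosis")
  for (id in final_diagnoses) {
    if (!id %in% names(map$nodes))
      abort("final diagnosis node not in expert map: ", id)
    if (map$nodes[[id]]$category != "differential")
      abort("final diagnosis node is not a differential: ", id)
  }
  if (length(prevalence)) {
    if (is.null(names(prevalence)) || any(!nzchar(names(prevalence))))
      abort("prevalence must be a named vector (differential node id -> rate)")
    if (any(prevalence < 0))
      abort("prevalence rates must be non-negative")
    bad <- setdiff(names(prevalence), names(map$nodes))
    if (length(bad)) abort("prevalence for unknown node(s): ",
                           paste(bad, collapse = ", "))
  }
  nonprototypical_findings <- as.character(nonprototypical_findings)
  for (id in nonprototypical_findings) {
    n <- map$nodes[[id]]
    if (is.null(n) || n$category != "finding")
      abort("nonprototypical_findings must reference finding nodes: ", id)
  }
  structure(list(map = map, final_diagnoses = final_diagnoses,
                 n_stages = as.integer(n_stages),
                 prevalence = prevalence,
                 nonprototypical_findings = nonprototypical_findings,
                 summary_statement = summary_statement),
            class = "crt_expert_case")
}

#' @export
print.crt_expert_case <- function(x, ...) {
  cat("<crt_expert_case> ", length(x$map$nodes), " nodes over ",
      x$n_stages, " stages; final: ",
      paste(x$final_diagnoses, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' The expert map as it stands at a given stage
#'
#' @param expert a `crt_expert_case`.
#' @param stage 0-based stage index.
#' @return a `crt_concept_map` restricted to nodes with
#'   `stage_added <= stage` and connections between them.
#' @export
expert_map_at_stage <- function(expert, stage) {
  stopifnot(inherits(expert, "crt_expert_case"))
  full <- expert$map
  keep <- vapply(full$nodes, function(n) n$stage_added <= stage, TRUE)
  sub <- concept_map()
  sub$nodes <- full$nodes[keep]
  sub$connections <- Filter(function(cn)
    cn$source %in% names(sub$nodes) && cn$target %in% names(sub$nodes),
    full$connections)
  sub$summary_statement <- full$summary_statement
  sub
}
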