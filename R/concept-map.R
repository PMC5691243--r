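#' Connection weight scale
#'
#' The five assignable connection weights, from the single negative level
#' (`speaks_against`, the "speaks against" red connection) through
#' increasing strengths of support up to `confirms`. Serialized as the
#' integers -1, 1, 2, 3, 4.
#'
#' @return named integer vector of length 5.
#' @export
connection_weights <- function() {
  c(speaks_against = -1L, slightly_related = 1L, related = 2L,
    highly_related = 3L, confirms = 4L)
}

node_categories <- c("finding", "differential", "test", "therapy")
node_flags <- c("negated", "must_not_miss", "ruled_out")

weight_name <- function(w) {
  ws <- connection_weights()
  if (is.numeric(w)) {
    i <- match(as.integer(w), ws)
    if (is.na(i)) abort("invalid connection weight: ", w)
    return(names(ws)[i])
  }
  w <- as.character(w)
  if (!w %in% names(ws)) abort("invalid connection weight: ", w)
  w
}

#' Create a concept-map node
#'
#' A node belongs to one of the four illness-script categories (finding,
#' differential, test, therapy) and refers either to a vocabulary term
#' (`term`) or to a free-text entry (`label`) — exactly one of the two.
#' `negated` marks negative findings ("no fever") and is only valid on
#' findings; `must_not_miss` and `ruled_out` only on differentials.
#'
#' @param node_id unique node identifier.
#' @param category one of `"finding"`, `"differential"`, `"test"`,
#'   `"therapy"`.
#' @param term vocabulary term id, or `NULL` for a free-text node.
#' @param label free-text label, or `NULL` for a vocabulary node.
#' @param negated,must_not_miss,ruled_out logical flags.
#' @param stage_added stage index at which the node was added (0-based).
#' @param added_at timestamp (ISO-8601 string or POSIXct).
#' @return a `crt_node`.
#' @export
map_node <- function(node_id, category, term = NULL, label = NULL,
                     negated = FALSE, must_not_miss = FALSE,
                     ruled_out = FALSE, stage_added = 0L, added_at = NA) {
  if (!is_string(node_id)) abort("node_id must be a single string")
  if (!is_string(category) || !category %in% node_categories)
    abort("category must be one of: ", paste(node_categories, collapse = ", "))
  if (is.null(term) == is.null(label))
    abort("node '", node_id, "': exactly one of term / label required")
  if (negated && category != "finding")
    abort("node '", node_id, "': negated only valid on findings")
  if ((must_not_miss || ruled_out) && category != "differential")
    abort("node '", node_id,
          "': must_not_miss/ruled_out only valid on differentials")
  structure(
    list(node_id = node_id, category = category,
         term = term, label = label,
         negated = isTRUE(negated), must_not_miss = isTRUE(must_not_miss),
         ruled_out = isTRUE(ruled_out),
         stage_added = as.integer(stage_added), added_at = added_at),
    class = "crt_node")
}

#' An empty concept map
#'
#' A concept map is a directed weighted graph: categorized nodes plus
#' weighted connections (at most one per ordered node pair), with an
#' optional summary statement.
#'
#' @return a `crt_concept_map` with no nodes.
#' @export
concept_map <- function() {
  structure(
    list(nodes = list(), connections = list(), summary_statement = NULL),
    class = "crt_concept_map")
}

#' @export
print.crt_concept_map <- function(x, ...) {
  tab <- table(factor(vapply(x$nodes, `[[`, "", "category"),
                      levels = node_categories))
  cat("<crt_concept_map> ", length(x$nodes), " nodes (",
      paste(paste0(tab, " ", names(tab)), collapse = ", "), "), ",
      length(x$connections), " connections",
      if (!is.null(x$summary_statement)) ", summary set", "\n", sep = "")
  invisible(x)
}

conn_key <- function(source, target) paste0(source, "->", target)

add_node_to_map <- function(map, node) {
  if (node$node_id %in% names(map$nodes))
    abort("duplicate node id: ", node$node_id)
  map$nodes[[node$node_id]] <- node
  map
}

delete_node_from_map <- function(map, node_id) {
  if (!node_id %in% names(map$nodes))
    abort("cannot delete unknown node: ", node_id)
  map$nodes[[node_id]] <- NULL
  # deletions cascade to incident connections
  keep <- vapply(map$connections, function(cn)
    cn$source != node_id && cn$target != node_id, TRUE)
  map$connections <- map$connections[keep]
  map
}

add_connection_to_map <- function(map, source, target, weight) {
  for (e in c(source, target))
    if (!e %in% names(map$nodes))
      abort("connection endpoint does not exist: ", e)
  if (identical(source, target))
    abort("self-connections are not allowed: ", source)
  key <- conn_key(source, target)
  if (key %in% names(map$connections))
    abort("duplicate connection: ", key)
  map$connections[[key]] <- list(source = source, target = target,
                                 weight = weight_name(weight))
  map
}

#' Nodes of one category
#' @param map a `crt_concept_map`.
#' @param category node category.
#' @return named list of `crt_node`.
#' @export
nodes_by_category <- function(map, category) {
  Filter(function(n) n$category == category, map$nodes)
}

#' Connections incident to a node
#' @param map a `crt_concept_map`.
#' @param node_id node id.
#' @param weight optional weight name to filter on.
#' @return list of connections touching `node_id`.
#' @export
connections_of <- function(map, node_id, weight = NULL) {
  out <- Filter(function(cn) cn$source == node_id || cn$target == node_id,
                map$connections)
  if (!is.null(weight))
    out <- Filter(function(cn) cn$weight == weight_name(weight), out)
  out
}

#' May a final diagnosis be submitted?
#'
#' The submit button is gated on the presence of at least one differential
#' diagnosis in the learner's map.
#'
#' @param map a `crt_concept_map`.
#' @return logical flag.
#' @export
can_submit_final <- function(map) {
  length(nodes_by_category(map, "differential")) > 0L
}
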