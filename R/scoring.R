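#' Scoring learner maps against expert maps
#'
#' Node matching uses the vocabulary: identical terms (or synonym hits)
#' score 1, hierarchically related terms earn graded credit
#' `1 - |d| / 10` for tree distance `d` within the accepted window
#' (`|d| <= 5` by default, so partial credit spans 0.5 to 0.9), and
#' unrelated nodes score 0. Negation flags must agree for any credit
#' ("no fever" never matches "fever").
#'
#' @name scoring
NULL

# score one learner/expert node pair -> list(value, basis, distance)
pair_score <- function(node, expert_node, vocab, partial_window = 5L) {
  none <- list(value = 0, basis = "none", distance = NA_integer_)
  if (node$category != expert_node$category) return(none)
  if (node$negated != expert_node$negated) return(none)

  if (!is.null(node$term) && !is.null(expert_node$term)) {
    if (identical(node$term, expert_node$term))
      return(list(value = 1, basis = "exact", distance = 0L))
    d <- signed_distance(vocab, node$term, expert_node$term)
    if (!is.na(d) && abs(d) <= partial_window)
      return(list(value = 1 - abs(d) / 10, basis = "hierarchical",
                  distance = d))
    return(none)
  }

  # at least one side is free text: normalized string matching
  labels_of <- function(n) {
    if (!is.null(n$term)) {
      t <- get_term(vocab, n$term)
      list(primary = normalize_label(t$preferred_label),
           all = normalize_label(c(t$preferred_label, t$synonyms)))
    } else {
      l <- normalize_label(n$label)
      list(primary = l, all = l)
    }
  }
  a <- labels_of(node); b <- labels_of(expert_node)
  if (any(a$all %in% b$all)) {
    basis <- if (is.null(node$term) && is.null(expert_node$term))
      "text" else "synonym"
    return(list(value = 1, basis = basis, distance = 0L))
  }
  none
}

# greedy one-to-one matching of learner nodes onto expert nodes within one
# category: best score first, ties broken by the learner node added first
greedy_match <- function(lnodes, enodes, vocab, partial_window = 5L) {
  ln_ids <- names(lnodes) %||% character()
  res <- data.frame(learner_node_id = ln_ids,
                    matched_expert_node_id = rep(NA_character_,
                                                 length(ln_ids)),
                    value = rep(0, length(ln_ids)),
                    basis = rep("none", length(ln_ids)),
                    distance = rep(NA_integer_, length(ln_ids)),
                    stringsAsFactors = FALSE)
  if (length(lnodes) == 0L) return(res)
  cands <- list()
  for (i in seq_along(lnodes)) {
    for (j in seq_along(enodes)) {
      s <- pair_score(lnodes[[i]], enodes[[j]], vocab, partial_window)
      if (s$value > 0)
        cands[[length(cands) + 1L]] <-
          list(i = i, j = j, value = s$value, basis = s$basis,
               distance = s$distance,
               added_at = as.character(lnodes[[i]]$added_at %||% ""))
    }
  }
  if (length(cands)) {
    ord <- order(-vapply(cands, `[[`, 0, "value"),
                 vapply(cands, `[[`, "", "added_at"),
                 vapply(cands, `[[`, 0L, "i"),
                 vapply(cands, `[[`, 0L, "j"))
    used_l <- logical(length(lnodes)); used_e <- logical(length(enodes))
    for (c in cands[ord]) {
      if (used_l[c$i] || used_e[c$j]) next
      used_l[c$i] <- TRUE; used_e[c$j] <- TRUE
      res$matched_expert_node_id[c$i] <- names(enodes)[c$j]
      res$value[c$i] <- c$value
      res$basis[c$i] <- c$basis
      res$distance[c$i] <- c$distance
    }
  }
  res
}

#' Score one learner node against the expert map at a stage
#'
#' Candidates are restricted to expert nodes of the same category; the best
#' match wins. This is the single-node view — inside [score_stage()] the
#' matching is one-to-one across all nodes, so a single expert node cannot
#' absorb several learner nodes.
#'
#' @param node a `crt_node` (the learner's).
#' @param expert_stage_map the expert `crt_concept_map` at the node's stage
#'   (see [expert_map_at_stage()]).
#' @param vocab a `crt_vocabulary`.
#' @param partial_window maximum tree distance that still earns partial
#'   credit (default 5, giving scores down to 0.5).
#' @return a one-row data.frame: `learner_node_id`,
#'   `matched_expert_node_id`, `value` in `[0, 1]`, `basis` (one of exact,
#'   synonym, hierarchical, text, none), `distance`.
#' @export
score_node <- function(node, expert_stage_map, vocab, partial_window = 5L) {
  stopifnot(inherits(node, "crt_node"),
            inherits(expert_stage_map, "crt_concept_map"))
  enodes <- nodes_by_category(expert_stage_map, node$category)
  lnodes <- stats::setNames(list(node), node$node_id)
  greedy_match(lnodes, enodes, vocab, partial_window)
}

#' Overall stage score
#'
#' Implements the stage scoring rule
#' \deqn{\mathrm{overall} = \frac{\sum \mathrm{scores}}{n_\mathrm{correct}
#'   + n_\mathrm{missed}} - 0.05 \times n_\mathrm{added}}
#' where correct nodes are learner nodes scoring at least 0.5, missed nodes
#' are expert nodes at this stage with no learner match, and added nodes
#' are learner nodes with no counterpart in the expert map. The raw value
#' can go negative with many extra nodes; the reported `overall` is clamped
#' at 0 (the pre-clamp value is kept in `overall_raw`). Two empty maps
#' score 1; an empty expert map with learner additions scores 0.
#'
#' @param learner_stage_map,expert_stage_map `crt_concept_map`s for the
#'   same stage index.
#' @param vocab a `crt_vocabulary`.
#' @param stage the stage index (annotation only).
#' @param partial_window see [score_node()].
#' @param add_penalty deduction per extra learner node (default 0.05).
#' @return a `crt_stage_score`: `stage`, `overall`, `overall_raw`,
#'   `n_correct`, `n_missed`, `n_added`, and `per_node` (a data.frame, one
#'   row per learner node).
#' @export
score_stage <- function(learner_stage_map, expert_stage_map, vocab,
                        stage = NA_integer_, partial_window = 5L,
                        add_penalty = 0.05) {
  stopifnot(inherits(learner_stage_map, "crt_concept_map"),
            inherits(expert_stage_map, "crt_concept_map"))
  per_node <- NULL
  for (cat in node_categories) {
    m <- greedy_match(nodes_by_category(learner_stage_map, cat),
                      nodes_by_category(expert_stage_map, cat),
                      vocab, partial_window)
    m$category <- rep(cat, nrow(m))
    per_node <- rbind(per_node, m)
  }
  matched <- per_node$matched_expert_node_id[
    !is.na(per_node$matched_expert_node_id)]
  n_correct <- sum(per_node$value >= 0.5)
  n_missed <- sum(!names(expert_stage_map$nodes) %in% matched)
  n_added <- sum(per_node$basis == "none")
  denom <- n_correct + n_missed
  base <- if (denom > 0) sum(per_node$value) / denom
          else if (n_added > 0) 0 else 1
  raw <- base - add_penalty * n_added
  expert_by_category <- vapply(
    node_categories,
    function(cat) length(nodes_by_category(expert_stage_map, cat)), 0L)
  structure(list(stage = stage, overall = max(0, raw), overall_raw = raw,
                 n_correct = n_correct, n_missed = n_missed,
                 n_added = n_added, per_node = per_node,
                 expert_by_category = expert_by_category),
            class = "crt_stage_score")
}

#' @export
print.crt_stage_score <- function(x, ...) {
  cat("<crt_stage_score> stage ", x$stage, ": overall ",
      format(round(x$overall, 4)), " (", x$n_correct, " correct, ",
      x$n_missed, " missed, ", x$n_added, " added)\n", sep = "")
  invisible(x)
}

#' Distance-based credit for the final diagnosis
#'
#' An exact (or synonym) match with one of the expert's final diagnoses
#' scores 1. Otherwise the closest expert diagnosis in the term tree is
#' used: `score = 1 - |d| / 10` when the distance magnitude is within the
#' partial window (default 5), so partial scores lie in `[0.5, 0.9]`;
#' anything farther, unrelated, or free-text-unmatched scores 0. With
#' several submitted diagnoses each is matched greedily to its best expert
#' diagnosis without reuse, and the combined score is their mean.
#'
#' @param submission a submission record (see [latest_submission()]) with
#'   `diagnosis_nodes` referring to nodes in `learner_map`.
#' @param learner_map the learner's concept map containing those nodes.
#' @param expert a `crt_expert_case`.
#' @param vocab a `crt_vocabulary`.
#' @param partial_window maximum `|distance|` that earns partial credit.
#' @return a `crt_diagnosis_score`: `per_diagnosis` (data.frame with
#'   `node_id`, `matched_expert_node_id`, `distance`, `score`) and
#'   `combined` (mean score in `[0, 1]`).
#' @export
score_final_diagnosis <- function(submission, learner_map, expert, vocab,
                                  partial_window = 5L) {
  stopifnot(inherits(learner_map, "crt_concept_map"),
            inherits(expert, "crt_expert_case"))
  ids <- as.character(submission$diagnosis_nodes)
  if (length(ids) == 0L) abort("submission carries no diagnosis nodes")
  lnodes <- learner_map$nodes[ids]
  if (any(vapply(lnodes, is.null, TRUE)))
    abort("submitted diagnosis node(s) not in learner map: ",
          paste(ids[vapply(lnodes, is.null, TRUE)], collapse = ", "))
  enodes <- expert$map$nodes[expert$final_diagnoses]
  m <- greedy_match(stats::setNames(lnodes, ids), enodes, vocab,
                    partial_window)
  per <- data.frame(node_id = m$learner_node_id,
                    matched_expert_node_id = m$matched_expert_node_id,
                    distance = m$distance, score = m$value,
                    stringsAsFactors = FALSE)
  structure(list(per_diagnosis = per, combined = mean(per$score)),
            class = "crt_diagnosis_score")
}

#' @export
print.crt_diagnosis_score <- function(x, ...) {
  cat("<crt_diagnosis_score> combined ", format(round(x$combined, 4)),
      " over ", nrow(x$per_diagnosis), " diagnosis/-es\n", sep = "")
  invisible(x)
}
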