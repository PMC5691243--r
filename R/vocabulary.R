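#' Controlled hierarchical vocabulary
#'
#' The term universe against which all concept-map nodes are matched. The
#' model follows the Medical Subject Headings (MeSH) design: every term
#' (descriptor) has an opaque identifier, one preferred label, optional
#' synonyms, and one or more dot-separated *tree addresses* that locate it
#' in the hierarchy (polyhierarchy is allowed). Distances between terms are
#' edge counts in this tree.
#'
#' @name vocabulary
NULL

#' Build a vocabulary from descriptor records
#'
#' @param records a list of descriptor records, each a list with elements
#'   `id` (unique identifier), `label` (preferred label), `synonyms`
#'   (character vector, may be empty) and `tree_addresses` (character
#'   vector of dot-separated hierarchy codes, at least one). Typically the
#'   parsed content of a JSON vocabulary file (see [read_vocabulary()]).
#' @return an object of class `crt_vocabulary` with components
#'   \describe{
#'     \item{terms}{named list of `crt_term` records, keyed by id}
#'     \item{label_index}{named character: normalized label/synonym -> id}
#'     \item{address_index}{named character: tree address -> id}
#'   }
#' @details Loading is order-independent: records are indexed after all have
#'   been validated. The hierarchy must be prefix-closed: for every address
#'   `"A.B.C"` the parent address `"A.B"` must belong to some term
#'   (top-level segments are roots). A tree address may belong to only one
#'   term, and preferred labels must be unique after normalization.
#' @examples
#' v <- load_vocabulary(list(
#'   list(id = "D1", label = "Pneumonia", synonyms = "Lung inflammation",
#'        tree_addresses = "C08"),
#'   list(id = "D2", label = "Bacterial Pneumonia", synonyms = character(),
#'        tree_addresses = "C08.381")
#' ))
#' signed_distance(v, "D2", "D1")  # -1: learner term one level more specific
#' @export
load_vocabulary <- function(records) {
  if (!is.list(records) || length(records) == 0L)
    abort("`records` must be a non-empty list of descriptor records")

  terms <- vector("list", length(records))
  ids <- character(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    id <- as.character(r$id %||% abort("record ", i, " has no id"))
    label <- as.character(r$label %||% abort("record ", i, " has no label"))
    if (!nzchar(trimws(label)))
      abort("record '", id, "': preferred label is empty")
    addrs <- as.character(unlist(r$tree_addresses))
    if (length(addrs) == 0L || any(!nzchar(addrs)))
      abort("record '", id, "': at least one non-empty tree address required")
    syns <- as.character(unlist(r$synonyms %||% character()))
    terms[[i]] <- structure(
      list(term_id = id, preferred_label = label,
           synonyms = unique(syns), tree_addresses = unique(addrs)),
      class = "crt_term")
    ids[i] <- id
  }
  if (anyDuplicated(ids))
    abort("duplicate term id(s): ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(terms) <- ids

  # address index; duplicate addresses across terms are a hard error
  addr_pairs <- do.call(rbind, lapply(terms, function(t)
    cbind(t$tree_addresses, t$term_id)))
  dup <- duplicated(addr_pairs[, 1L])
  if (any(dup)) {
    a <- addr_pairs[dup, 1L][1L]
    owners <- unique(addr_pairs[addr_pairs[, 1L] == a, 2L])
    abort("tree address '", a, "' assigned to more than one term: ",
          paste(owners, collapse = ", "))
  }
  address_index <- stats::setNames(addr_pairs[, 2L], addr_pairs[, 1L])

  # prefix closure: dropping the last segment of any multi-segment address
  # must land on an existing address
  for (a in names(address_index)) {
    segs <- strsplit(a, ".", fixed = TRUE)[[1L]]
    if (length(segs) > 1L) {
      parent <- paste(segs[-length(segs)], collapse = ".")
      if (!parent %in% names(address_index))
        abort("orphan tree address '", a, "' (term ",
              address_index[[a]], "): parent address '", parent,
              "' belongs to no term")
    }
  }

  # label/synonym index; preferred labels unique after normalization
  norm_labels <- normalize_label(vapply(terms, `[[`, "", "preferred_label"))
  if (anyDuplicated(norm_labels))
    abort("preferred labels not unique after normalization: '",
          norm_labels[duplicated(norm_labels)][1L], "'")
  label_index <- stats::setNames(ids, norm_labels)
  for (t in terms) {
    for (s in t$synonyms) {
      ns <- normalize_label(s)
      if (!ns %in% names(label_index))
        label_index[[ns]] <- t$term_id
    }
  }

  structure(
    list(terms = terms, label_index = label_index,
         address_index = address_index),
    class = "crt_vocabulary")
}

#' Read a vocabulary from its native JSON file
#'
#' The native dialect is a JSON array of
#' `{"id": ..., "label": ..., "synonyms": [...], "tree_addresses": [...]}`.
#'
#' @param path path to the JSON file.
#' @return a `crt_vocabulary`, see [load_vocabulary()].
#' @export
read_vocabulary <- function(path) {
  if (!file.exists(path)) abort("vocabulary file not found: ", path,
                                class = "crtool_io_error")
  load_vocabulary(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' Write a vocabulary to the native JSON dialect
#' @param vocab a `crt_vocabulary`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "crt_vocabulary"))
  recs <- lapply(unname(vocab$terms), function(t)
    list(id = t$term_id, label = t$preferred_label,
         synonyms = as.list(t$synonyms),
         tree_addresses = as.list(t$tree_addresses)))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.crt_vocabulary <- function(x, ...) {
  cat("<crt_vocabulary> ", length(x$terms), " terms, ",
      length(x$address_index), " tree addresses, max depth ",
      max(lengths(strsplit(names(x$address_index), ".", fixed = TRUE))),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.crt_term <- function(x, ...) {
  cat("<crt_term> ", x$term_id, ": ", x$preferred_label,
      if (length(x$synonyms)) paste0(" (", paste(x$synonyms, collapse = "; "), ")"),
      " @ ", paste(x$tree_addresses, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Look up a term id by label or synonym
#'
#' @param vocab a `crt_vocabulary`.
#' @param label a label or synonym (normalization applied).
#' @return the term id, or `NA_character_` if no term carries that label.
#' @export
lookup_term <- function(vocab, label) {
  stopifnot(inherits(vocab, "crt_vocabulary"))
  id <- vocab$label_index[normalize_label(label)]
  if (is.na(id)) NA_character_ else unname(id)
}

get_term <- function(vocab, term_id) {
  t <- vocab$terms[[term_id]]
  if (is.null(t)) abort("unknown term id: ", term_id)
  t
}

#' Type-ahead search over labels and synonyms
#'
#' Prefix matches rank above substring matches (tier 1 vs tier 2); within a
#' tier results are ordered alphabetically by preferred label, then by id,
#' so the ranking is fully deterministic.
#'
#' @param vocab a `crt_vocabulary`.
#' @param query search text; must be non-empty after normalization.
#' @param max_results maximum number of terms returned (default 10).
#' @return a data.frame with columns `term_id`, `label` (preferred label),
#'   `matched` (the label or synonym that matched) and `tier` (1 = prefix,
#'   2 = substring). Zero rows when nothing matches.
#' @export
search_terms <- function(vocab, query, max_results = 10L) {
  stopifnot(inherits(vocab, "crt_vocabulary"))
  q <- normalize_label(query)
  if (!nzchar(q)) abort("query is empty after normalization")
  if (!is_count(max_results) || max_results < 1)
    abort("max_results must be a positive count")

  hits <- lapply(vocab$terms, function(t) {
    cands <- c(t$preferred_label, t$synonyms)
    nc <- normalize_label(cands)
    pos <- regexpr(q, nc, fixed = TRUE)
    keep <- pos > 0L
    if (!any(keep)) return(NULL)
    tier <- ifelse(pos[keep] == 1L, 1L, 2L)
    best <- which.min(tier)
    data.frame(term_id = t$term_id, label = t$preferred_label,
               matched = cands[keep][best], tier = min(tier),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    return(data.frame(term_id = character(), label = character(),
                      matched = character(), tier = integer(),
                      stringsAsFactors = FALSE))
  ord <- order(hits$tier, normalize_label(hits$label), hits$term_id)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  utils::head(hits, max_results)
}

# split addresses once: list of segment vectors per term
term_address_segments <- function(vocab, term_id) {
  strsplit(get_term(vocab, term_id)$tree_addresses, ".", fixed = TRUE)
}

#' Signed hierarchical distance between two terms
#'
#' The magnitude is the tree-path length between the two terms: for a pair
#' of tree addresses sharing a common prefix of `L` segments, the path runs
#' up from one address to the deepest common ancestor and down to the other,
#' i.e. `(depth_a - L) + (depth_b - L)` edges. With polyhierarchy the
#' minimum over all address pairs is taken (most-charitable credit). The
#' sign is negative when the first term (the learner's) is a strict
#' descendant of the second (the expert's) on the minimizing pair — the
#' learner was *more specific* — and positive otherwise. Address pairs with
#' no shared leading segment are unrelated; if no pair is related the
#' sentinel `NA` is returned.
#'
#' @param vocab a `crt_vocabulary`.
#' @param learner_term,expert_term term ids (must exist in `vocab`).
#' @return a single integer edge count (0 iff the terms are identical,
#'   negative iff learner is a strict descendant of expert), or
#'   `NA_integer_` when the terms share no hierarchy branch.
#' @examples
#' v <- make_toy_vocabulary(depth = 3, branching = 2, seed = 1)
#' ids <- names(v$terms)
#' signed_distance(v, ids[1], ids[1])  # 0
#' @export
signed_distance <- function(vocab, learner_term, expert_term) {
  stopifnot(inherits(vocab, "crt_vocabulary"))
  if (identical(learner_term, expert_term)) {
    get_term(vocab, learner_term)  # still validate existence
    return(0L)
  }
  a_segs <- term_address_segments(vocab, learner_term)
  b_segs <- term_address_segments(vocab, expert_term)

  best <- NA_integer_
  best_negative <- FALSE
  for (a in a_segs) {
    for (b in b_segs) {
      n <- min(length(a), length(b))
      common <- 0L
      while (common < n && a[common + 1L] == b[common + 1L])
        common <- common + 1L
      if (common == 0L) next  # no shared branch on this pair
      d <- (length(a) - common) + (length(b) - common)
      neg <- common == length(b) && length(a) > length(b)  # strict descendant
      if (is.na(best) || d < best || (d == best && neg && !best_negative)) {
        best <- d
        best_negative <- neg
      }
    }
  }
  if (is.na(best)) return(NA_integer_)
  if (best_negative) -best else best
}

#' Are two terms within one hierarchy level of each other?
#'
#' True when the signed distance magnitude is at most one edge (same term,
#' parent, or child). Used by the availability-bias detector, which flags
#' prior cases whose final diagnosis sits one hierarchy level up or down
#' from the submitted one.
#'
#' @inheritParams signed_distance
#' @param a,b term ids.
#' @return logical flag.
#' @export
is_related_one_level <- function(vocab, a, b) {
  d <- signed_distance(vocab, a, b)
  !is.na(d) && abs(d) <= 1L
}
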