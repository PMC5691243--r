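#' Deterministic toy fixtures
#'
#' Generators for a complete toy vocabulary tree, a structurally valid
#' expert case on it, and simulated learner sessions with injectable
#' cognitive-error patterns. Everything is seeded and reproducible, so
#' every module of the package can be exercised without any external
#' vocabulary download.
#'
#' @name fixtures
NULL

#' Generate a complete toy vocabulary tree
#'
#' Builds a complete tree of `depth` levels with `branching` children per
#' node: `sum(branching^k, k = 0..depth-1)` terms in total. Labels and one
#' synonym per term are derived deterministically from the tree address,
#' so distances between any two terms are analytically known.
#'
#' @param depth number of levels (>= 1); the root is level 1.
#' @param branching children per internal node (>= 1).
#' @param seed recorded for provenance; the construction itself is fully
#'   deterministic.
#' @return a `crt_vocabulary`.
#' @examples
#' v <- make_toy_vocabulary(depth = 4, branching = 3, seed = 7)
#' length(v$terms)  # 1 + 3 + 9 + 27 = 40
#' @export
make_toy_vocabulary <- function(depth, branching, seed = 0L) {
  if (!is_count(depth) || depth < 1) abort("depth must be >= 1")
  if (!is_count(branching) || branching < 1) abort("branching must be >= 1")
  addrs <- "T1"
  level <- "T1"
  if (depth > 1) {
    for (k in seq_len(depth - 1L)) {
      level <- as.vector(vapply(level, function(a)
        paste(a, seq_len(branching), sep = "."), character(branching)))
      addrs <- c(addrs, level)
    }
  }
  recs <- lapply(addrs, function(a) list(
    id = paste0("D", gsub(".", "_", a, fixed = TRUE)),
    label = paste("Concept", a),
    synonyms = paste("Synonym", a),
    tree_addresses = a))
  v <- load_vocabulary(recs)
  attr(v, "seed") <- as.integer(seed)
  v
}

term_for_address <- function(vocab, addr) unname(vocab$address_index[[addr]])

#' Generate a structurally complete expert case
#'
#' Lays out a staged expert map on a toy vocabulary such that every score
#' component and all five cognitive-error detectors are exercisable:
#' early findings and a test, three differentials (the correct final
#' diagnosis, a comparably prevalent alternative, and a rare alternative,
#' placed in different branches of the tree so the alternatives are clear
#' mismatches), disconfirming findings connected "speaks against" each
#' alternative, one nonprototypical finding, a decisive test appearing
#' only at the last stage and connected to the correct diagnosis, a
#' therapy, prevalence annotations, and a qualifier-rich summary
#' statement.
#'
#' @param vocab a `crt_vocabulary` with at least 3 root children and 4
#'   levels (e.g. `make_toy_vocabulary(4, 3)`).
#' @param n_stages number of scenario stages (>= 3, default 4).
#' @param seed integer seed driving the term sampling.
#' @return a `crt_expert_case`.
#' @export
make_expert_case <- function(vocab, n_stages = 4L, seed = 1L) {
  stopifnot(inherits(vocab, "crt_vocabulary"))
  if (!is_count(n_stages) || n_stages < 3)
    abort("n_stages must be >= 3")
  addrs <- names(vocab$address_index)
  seglen <- lengths(strsplit(addrs, ".", fixed = TRUE))
  root_children <- addrs[seglen == 2L]
  leaves_depth <- max(seglen)
  if (length(root_children) < 3L || leaves_depth < 4L)
    abort("insufficient vocabulary: need >= 3 root branches and depth >= 4")

  set.seed(as.integer(seed))
  branches <- sample(root_children, 3L)
  pick_leaf <- function(branch) {
    cand <- addrs[seglen == leaves_depth & startsWith(addrs, paste0(branch, "."))]
    sample(cand, 1L)
  }
  dx_correct <- term_for_address(vocab, pick_leaf(branches[1L]))
  dx_alt     <- term_for_address(vocab, pick_leaf(branches[2L]))
  dx_rare    <- term_for_address(vocab, pick_leaf(branches[3L]))
  used <- c(dx_correct, dx_alt, dx_rare)
  others <- sample(setdiff(names(vocab$terms), used), 8L)

  last <- n_stages - 1L
  nodes <- list(
    map_node("E_f1", "finding", term = others[1L], stage_added = 0L),
    map_node("E_f2", "finding", term = others[2L], stage_added = 0L),
    map_node("E_f_dis_alt", "finding", term = others[3L], stage_added = 0L),
    map_node("E_f_dis_rare", "finding", term = others[4L], stage_added = 0L),
    map_node("E_f_np", "finding", term = others[5L], stage_added = 1L),
    map_node("E_t1", "test", term = others[6L], stage_added = 1L),
    map_node("E_dx_correct", "differential", term = dx_correct,
             must_not_miss = TRUE, stage_added = 1L),
    map_node("E_dx_alt", "differential", term = dx_alt, stage_added = 1L),
    map_node("E_dx_rare", "differential", term = dx_rare, stage_added = 1L),
    map_node("E_t_key", "test", term = others[7L], stage_added = last),
    map_node("E_th1", "therapy", term = others[8L], stage_added = last))
  emap <- concept_map()
  for (n in nodes) emap <- add_node_to_map(emap, n)
  emap <- add_connection_to_map(emap, "E_f1", "E_dx_correct", "highly_related")
  emap <- add_connection_to_map(emap, "E_f2", "E_dx_correct", "related")
  emap <- add_connection_to_map(emap, "E_f_np", "E_dx_correct",
                                "slightly_related")
  emap <- add_connection_to_map(emap, "E_f_dis_alt", "E_dx_alt",
                                "speaks_against")
  emap <- add_connection_to_map(emap, "E_f_dis_rare", "E_dx_rare",
                                "speaks_against")
  emap <- add_connection_to_map(emap, "E_t_key", "E_dx_correct", "confirms")
  emap$summary_statement <- paste(
    "An acute, sudden onset of severe, constant and unilateral pain,",
    "localized to one region, with a productive cough in a febrile",
    "patient; the symptoms are new and progressive.")

  ec <- expert_case(
    emap,
    final_diagnoses = "E_dx_correct",
    n_stages = n_stages,
    prevalence = c(E_dx_correct = 0.02, E_dx_alt = 0.02, E_dx_rare = 1e-5),
    nonprototypical_findings = "E_f_np",
    summary_statement = emap$summary_statement)
  # the generating vocabulary travels with the case so that downstream
  # fixtures (availability history, bundles) can resolve hierarchy context
  attr(ec, "vocab") <- vocab
  ec
}

#' Define a simulated-learner profile
#'
#' @param ability probability in `[0, 1]` of reproducing each expert node
#'   (and each expert connection between reproduced nodes) at its stage.
#' @param style `"analytic"` (submits at the last stage) or
#'   `"nonanalytic"` (submits at the first stage where a differential is
#'   available).
#' @param injected_bias `NULL`, or one of `"premature_closure"`,
#'   `"availability"`, `"confirmation"`, `"representativeness"`,
#'   `"base_rate_neglect"`: the event stream is edited constructively so
#'   that exactly that detector fires on the generated session.
#' @param consult_policy `"never"`, `"midway"` or `"immediately"`: when
#'   the simulated learner consults the expert map.
#' @param seed integer seed.
#' @return a `crt_sim_profile`.
#' @export
simulation_profile <- function(ability = 1, style = c("analytic",
                                                      "nonanalytic"),
                               injected_bias = NULL,
                               consult_policy = c("never", "midway",
                                                  "immediately"),
                               seed = 1L) {
  style <- match.arg(style)
  consult_policy <- match.arg(consult_policy)
  if (!is.numeric(ability) || ability < 0 || ability > 1)
    abort("ability must lie in [0, 1]")
  if (!is.null(injected_bias) && !injected_bias %in% bias_types)
    abort("unknown injected_bias: ", injected_bias)
  structure(list(ability = ability, style = style,
                 injected_bias = injected_bias,
                 consult_policy = consult_policy,
                 seed = as.integer(seed)),
            class = "crt_sim_profile")
}

#' Simulate a learner session on an expert case
#'
#' Generates a reproducible event log: per stage, each expert node (and
#' each expert connection whose endpoints were reproduced) is copied with
#' probability `ability`; a summary statement reuses each expert qualifier
#' with probability `ability`; the final diagnosis is submitted per the
#' profile's style. With `injected_bias` set, the stream is edited
#' constructively so that the named detector — and only that one — fires
#' on the session (for availability bias the required prior-session
#' history is attached as `attr(log, "history")`; it is an empty history
#' otherwise).
#'
#' @param expert a `crt_expert_case` from [make_expert_case()] (the
#'   injection rules rely on its node roles).
#' @param profile a `crt_sim_profile`.
#' @return a `crt_session_log` with a `history` attribute
#'   (`crt_history`).
#' @export
simulate_session <- function(expert, profile = simulation_profile()) {
  stopifnot(inherits(expert, "crt_expert_case"),
            inherits(profile, "crt_sim_profile"))
  set.seed(profile$seed)
  bias <- profile$injected_bias
  n_stages <- expert$n_stages
  emap <- expert$map

  # deterministic clock: one event per 10 s from a fixed session start
  t0 <- as.POSIXct("2026-01-05 09:00:00", tz = "UTC")
  clock <- 0L
  events <- list()
  emit <- function(action, payload = list(), stage) {
    clock <<- clock + 1L
    events[[length(events) + 1L]] <<- map_event(
      action, payload, stage = stage,
      at = format(t0 + 10 * clock, "%Y-%m-%dT%H:%M:%SZ"))
  }

  lid <- function(eid) sub("^E_", "L_", eid)
  added <- character()        # expert node ids reproduced so far
  connected <- character()    # expert connection keys reproduced
  add_learner_node <- function(eid, stage) {
    if (eid %in% added) return(invisible())
    n <- emap$nodes[[eid]]
    emit("add_node", list(node_id = lid(eid), category = n$category,
                          term = n$term, label = n$label,
                          negated = n$negated,
                          must_not_miss = n$must_not_miss,
                          ruled_out = n$ruled_out), stage)
    added <<- c(added, eid)
  }
  ensure_connection <- function(src_eid, tgt_eid, weight, stage) {
    key <- conn_key(src_eid, tgt_eid)
    if (key %in% connected) {
      emit("set_weight", list(source = lid(src_eid), target = lid(tgt_eid),
                              weight = weight), stage)
    } else {
      emit("add_connection", list(source = lid(src_eid),
                                  target = lid(tgt_eid), weight = weight),
           stage)
      connected <<- c(connected, key)
    }
    invisible()
  }

  # which expert node the profile submits, and when
  skip_nodes <- character()
  submit_target <- NULL
  submit_stage_rule <- profile$style
  if (!is.null(bias)) {
    submit_target <- switch(bias,
      premature_closure = "E_dx_alt",
      availability = "E_dx_alt",
      confirmation = "E_dx_alt",
      representativeness = "E_dx_alt",
      base_rate_neglect = "E_dx_rare")
    submit_stage_rule <- if (bias == "premature_closure") "nonanalytic"
                         else "analytic"
    if (bias == "confirmation") skip_nodes <- "E_f_dis_alt"
  }
  disconf_for <- c(E_dx_alt = "E_f_dis_alt", E_dx_rare = "E_f_dis_rare")

  expert_stage <- vapply(emap$nodes, `[[`, 0L, "stage_added")
  submitted <- FALSE

  do_submit <- function(stage) {
    if (is.null(submit_target)) {
      # no injected bias: prefer the correct diagnosis if reproduced,
      # otherwise the first reproduced differential
      cand <- intersect(expert$final_diagnoses, added)
      if (length(cand) == 0L)
        cand <- Filter(function(e) emap$nodes[[e]]$category == "differential",
                       added)
      if (length(cand) == 0L) return(FALSE)
      target <- cand[[1L]]
    } else {
      target <- submit_target
      add_learner_node(target, stage)
      # keep the confirmation detector silent unless it is the injected one
      d <- disconf_for[[target]]
      if (!is.null(bias) && bias != "confirmation" && !is.null(d)) {
        add_learner_node(d, stage)
        ensure_connection(d, target, "speaks_against", stage)
      }
      if (!is.null(bias) && bias == "representativeness") {
        add_learner_node("E_f_np", stage)
        add_learner_node("E_dx_correct", stage)
        ensure_connection("E_f_np", "E_dx_correct", "speaks_against", stage)
      }
    }
    emit("submit_final", list(diagnosis_nodes = lid(target),
                              confidence = 50L + as.integer(
                                round(40 * profile$ability))),
         stage)
    TRUE
  }

  for (s in seq_len(n_stages) - 1L) {
    if (s > 0L) emit("advance_stage", list(), s)
    if ((profile$consult_policy == "immediately" && s == 0L) ||
        (profile$consult_policy == "midway" && s == n_stages %/% 2L))
      emit("consult_expert", list(), s)

    for (eid in names(emap$nodes)[expert_stage == s]) {
      if (eid %in% skip_nodes) next
      if (stats::runif(1) < profile$ability) add_learner_node(eid, s)
    }
    for (key in names(emap$connections)) {
      cn <- emap$connections[[key]]
      if (key %in% connected) next
      if (max(expert_stage[[cn$source]], expert_stage[[cn$target]]) > s) next
      if (!all(c(cn$source, cn$target) %in% added)) next
      if (cn$source %in% skip_nodes || cn$target %in% skip_nodes) next
      if (stats::runif(1) < profile$ability)
        ensure_connection(cn$source, cn$target, cn$weight, s)
    }

    if (!submitted && submit_stage_rule == "nonanalytic") {
      has_diff <- !is.null(submit_target) ||
        any(vapply(added, function(e)
          emap$nodes[[e]]$category == "differential", TRUE))
      if (has_diff) submitted <- do_submit(s)
    }
    if (s == n_stages - 1L) {
      # summary statement: reuse each expert qualifier with prob ability
      q <- extract_qualifiers(expert$summary_statement %||% "")
      keep <- q[stats::runif(length(q)) < profile$ability]
      emit("set_summary",
           list(text = paste("The presentation is",
                             paste(keep, collapse = ", "), ".")), s)
      if (!submitted) submitted <- do_submit(s)
    }
  }

  log <- session_log(
    session_id = paste0("sim-", profile$seed),
    case_id = "toy-case", learner_id = "sim-learner",
    events = events,
    started_at = format(t0, "%Y-%m-%dT%H:%M:%SZ"))

  history <- session_history()
  if (!is.null(bias) && bias == "availability") {
    # a prior case, 4 days before this session, whose final diagnosis is
    # the hierarchy parent of the diagnosis submitted here
    sub_term <- emap$nodes[[submit_target]]$term
    addr <- get_term_address_parent(attr_vocab_of(expert), sub_term)
    history <- session_history(list(list(
      case_id = "prior-case", last_accessed = "2026-01-01",
      final_diagnoses = addr)))
  }
  attr(log, "history") <- history
  log
}

# the parent term (one hierarchy level up) of a term, via its first address
get_term_address_parent <- function(vocab, term_id) {
  segs <- term_address_segments(vocab, term_id)[[1L]]
  if (length(segs) < 2L) abort("term has no parent: ", term_id)
  parent_addr <- paste(segs[-length(segs)], collapse = ".")
  term_for_address(vocab, parent_addr)
}

# the vocabulary an expert case was generated from is needed to place the
# availability history; fixtures carry it alongside
attr_vocab_of <- function(expert) {
  v <- attr(expert, "vocab")
  if (is.null(v)) abort("expert case carries no vocabulary attribute; ",
                        "use make_case_bundle() or attach attr(expert, 'vocab')")
  v
}
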