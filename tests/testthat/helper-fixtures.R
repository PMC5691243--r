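# Shared in-code fixtures.

# A hand-written respiratory mini-vocabulary mirroring real MeSH layout.
tiny_vocab <- function() {
  load_vocabulary(list(
    list(id = "D012140", label = "Respiratory Tract Diseases",
         synonyms = character(), tree_addresses = "C08"),
    list(id = "D011014", label = "Pneumonia",
         synonyms = c("Lung Inflammation", "Pulmonitis"),
         tree_addresses = "C08.381"),
    list(id = "D018410", label = "Bacterial Pneumonia",
         synonyms = "Pneumonia, Bacterial",
         tree_addresses = "C08.381.677"),
    list(id = "D011024", label = "Viral Pneumonia",
         synonyms = character(), tree_addresses = "C08.381.880"),
    list(id = "D001991", label = "Bronchitis",
         synonyms = character(), tree_addresses = "C08.127"),
    list(id = "D001523", label = "Mental Disorders",
         synonyms = character(), tree_addresses = "F03")
  ))
}

# Toy vocabulary + generated expert case, shared across files.
toy_vocab <- function() make_toy_vocabulary(depth = 4, branching = 3,
                                            seed = 7)

toy_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_expert_case(toy_vocab(),
                                                   n_stages = 4, seed = 1)
    cache
  }
})

# Compact builder for hand-written session logs.
h_log <- function(..., session_id = "s1", case_id = "c1",
                  learner_id = "l1") {
  session_log(session_id, case_id, learner_id, list(...),
              started_at = "2026-01-05T08:00:00Z")
}

ev <- function(action, stage = 0L, at = NA, ...) {
  map_event(action, list(...), stage = stage, at = at)
}

# A one-category learner map built directly (bypassing the event log).
h_map <- function(...) {
  m <- concept_map()
  for (n in list(...)) m <- crtool:::add_node_to_map(m, n)
  m
}
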