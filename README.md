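# crtool

Assessment core for concept-map based clinical reasoning training.

Learners working through a virtual-patient (VP) scenario build their
patient's *illness script* as a concept map: findings, differential
diagnoses, tests and therapies as nodes, connected by weighted edges on a
five-level scale from "speaks against" to "confirms". `crtool` implements
the machinery that turns such maps into formative assessment:

* **Hierarchical term matching.** Nodes reference a MeSH-style controlled
  vocabulary in which every term carries dot-separated tree addresses.
  The signed distance between two terms is the edge count of the tree
  path between their addresses, negative when the learner's term is a
  strict descendant (more specific) of the expert's.
* **Final-diagnosis partial credit.** An exact or synonym match scores 1;
  otherwise `score = 1 − |d| / 10` for tree distance `d` within the
  accepted window (`|d| ≤ 5`), so partial credit spans 0.5–0.9.
* **Per-stage map scoring.** At each scenario stage the learner map is
  compared with the expert map as it stands at that stage:

  ```
  overall = Σ scores / (n_correct + n_missed) − 0.05 × n_added
  ```

  where correct nodes score ≥ 0.5, missed nodes are expert nodes the
  learner lacks, and added nodes have no expert counterpart.
* **Summary-statement rubric.** The learner's 2–3 sentence case
  abstraction is scored 0/1/2 by the fraction of the expert's semantic
  qualifiers (acute/chronic, unilateral/bilateral, ...) it reuses:
  ≥ 60 % → 2, 30–60 % → 1, < 30 % → 0.
* **Cognitive-error detection.** On a mismatched final diagnosis five
  rule-based detectors run: premature closure, availability bias,
  confirmation bias, representativeness, and base-rate neglect.
* **Learning analytics.** Scores are clustered along a clinical reasoning
  process model (problem representation, investigations, therapy,
  categorization, semantic transformation) and assembled into dashboard
  data with trends, peer statistics and weakest-cluster recommendations.

Everything is exercisable offline through seeded generators for toy
vocabularies, expert cases and simulated learner sessions.

## Worked example

```r
library(crtool)

vocab  <- make_toy_vocabulary(depth = 4, branching = 3, seed = 7)  # 40 terms
expert <- make_expert_case(vocab, n_stages = 4, seed = 1)

# a mid-ability learner session, then a session engineered to show
# premature closure
log <- simulate_session(expert, simulation_profile(ability = 1, seed = 3))
score_session(log, expert, vocab)
#> <crt_session_score> sim-3: total 1
#>   stages: 1 1 1 1
#>   final diagnosis: match (1)
#>   summary rubric: 2/2

hasty <- simulate_session(expert, simulation_profile(
  injected_bias = "premature_closure", seed = 11))
analyze_submission(hasty, expert, attr(hasty, "history"), vocab)
#> <crt_submission_outcome> mismatch (score 0)
#>   - premature_closure: final diagnosis submitted at stage 0, but the
#>     expert adds 2 later finding(s)/test(s) connected to the final diagnosis
```

The perfect learner reproduces every expert node, so each stage scores 1,
the diagnosis matches and no error analysis runs. The hasty learner
committed to an alternative diagnosis at stage 0 even though decisive
evidence (a key test) only appears later in the scenario — exactly the
pattern the premature-closure rule looks for.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/crt.R simulate --out bundle/ --seed 5
Rscript inst/cli/crt.R validate bundle/          # exit 0 ok, 1 invalid, 2 I/O
Rscript inst/cli/crt.R score bundle/ --session sim-5
Rscript inst/cli/crt.R detect bundle/ --history bundle/history.json
Rscript inst/cli/crt.R search bundle/vocabulary.json "concept t1.2"
```

## Package layout

| Path | Content |
| --- | --- |
| `R/vocabulary.R`, `R/mesh-xml.R` | vocabulary model, search, signed distance, MeSH XML import |
| `R/concept-map.R`, `R/events.R` | concept-map model, event log, replay |
| `R/scoring.R`, `R/qualifiers.R`, `R/session.R` | node/stage/diagnosis/summary scoring, aggregation |
| `R/bias.R` | the five cognitive-error detectors and submission analysis |
| `R/analytics.R` | clusters, indicators, dashboard |
| `R/bundle.R` | JSON case bundles, validation, batch-update API |
| `R/simulate.R` | toy vocabulary / expert case / session generators |
| `vignettes/assessment-model.Rmd` | the methods vignette |
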