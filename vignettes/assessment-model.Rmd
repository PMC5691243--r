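---
title: "The assessment model behind crtool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The assessment model behind crtool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtool)
```

## The problem

Clinical reasoning — collecting and integrating patient information into a
diagnosis and management plan — is usually assessed by its outcome: did the
learner name the right disease? `crtool` assesses the *process*. While a
learner works through a staged virtual-patient scenario they externalize
their illness script as a concept map; the package compares that map,
stage by stage, with a staged expert reference map, grades the final
diagnosis and the summary statement, and explains wrong final diagnoses
through rule-based cognitive-error detectors.

This vignette documents the model, its tunable parameters, the numerical
choices, and what the simulation-based tests do and do not establish.

## Vocabulary and hierarchical distance

All non-free-text nodes reference a controlled vocabulary in the style of
the Medical Subject Headings: a term owns one preferred label, synonyms,
and one or more dot-separated *tree addresses*. The hierarchy must be
prefix-closed (every non-root address has a parent address), and one
address belongs to exactly one term.

The signed distance between a learner term and an expert term is the
shortest tree path between any pair of their addresses: with a common
prefix of `L` segments the path runs `(depth_a − L) + (depth_b − L)`
edges through the deepest common ancestor. The sign is negative when the
learner term is a strict descendant of the expert term — the learner was
*more specific* — and positive otherwise, including paths across sibling
branches, where specificity has no direction. Address pairs sharing no
leading segment are unrelated; if no pair of addresses is related the
distance is the `NA` sentinel and no credit is given.

Three choices here were genuinely open:

* **Cross-branch credit.** Only ancestor/descendant pairs have an obvious
  distance; we also allow paths through a common ancestor because an edge
  count "in the tree" naturally reads as tree-path length. Callers who
  want stricter behavior can shrink the partial-credit window
  (`partial_window`, below).
* **Polyhierarchy.** A term may sit at several addresses; the minimum
  distance over address pairs is used — the most charitable reading, and
  the one consistent with how MeSH trees are used in practice.
* **Tie-breaking the sign.** If a descendant pair and a cross-branch pair
  achieve the same minimal magnitude, the descendant pair wins and the
  sign is negative, keeping "more specific" visible whenever it is true.

Labels and synonyms are matched after case-folding, trimming and
collapsing internal whitespace. This normalization is not in any source
material; it is required for deterministic matching.

## Scoring

**Node scores.** Candidate expert nodes are restricted to the learner
node's category (finding / differential / test / therapy). An identical
term, a synonym hit, or a normalized free-text string match scores 1.
Otherwise the closest same-category expert term within the partial window
earns `1 − |d|/10`. Negation flags must agree — "no fever" never matches
"fever". Matching is one-to-one and greedy, best score first with ties
broken by the learner node added earlier, so one expert node can never
absorb several learner nodes. The greedy discipline is this package's
choice; nothing in the source model prescribes a matching algorithm.

**Stage scores.** At each stage boundary the learner snapshot is compared
with the expert map *at that stage* (all expert nodes with
`stage_added ≤ s`):

```
overall = Σ scores / (n_correct + n_missed) − 0.05 × n_added
```

`n_correct` counts learner nodes scoring at least 0.5, `n_missed` expert
nodes without an assigned learner match, `n_added` learner nodes with no
match at all. Two boundary conventions are ours: an expert node matched
only weakly (learner score < 0.5) counts as *not* missed, since it was
consumed by the one-to-one matching; and a learner node with any match,
however weak, is not an "added" node. The formula can go negative under
many extra nodes, so the reported value is clamped at 0 (the pre-clamp
value is kept as `overall_raw`); empty-against-empty maps score 1, and an
empty expert stage against learner additions scores 0. Sessions that end
before the scenario's last stage are scored only for the stages they
reached. Connections are deliberately excluded from stage scores — the
score counts nodes; connections feed only the analytics indicators and
the bias rules.

**Final diagnosis.** An exact/synonym match with an expert final
diagnosis scores 1; otherwise `1 − |d|/10` for the nearest expert final
diagnosis within the window, else 0. The window default `|d| ≤ 5` is
implied by the partial-score range 0.5–0.9 and is configurable
(`partial_window`). Several simultaneously submitted diagnoses are each
matched without reuse and averaged; averaging is our convention. With
several submissions per session the latest non-working one is scored —
a "working diagnosis" is modeled as a submission flagged `working = TRUE`
and excluded from scoring and error analysis.

**Summary statement.** The rubric counts semantic qualifiers — paired
abstract descriptors such as acute/chronic — shared between learner and
expert statements: coverage ≥ 60 % scores 2, 30–60 % scores 1, below
30 % scores 0, with both boundaries landing in the upper band. Because
the full published qualifier list is not reproduced anywhere we can ship,
the default lexicon (`default_qualifier_lexicon()`) packages fifteen
classic antonym pairs with inflection variants; it is replaceable
wholesale via the `lexicon` argument. Matching is token-level and
case-insensitive; only hyphenated variants may span two adjacent words,
so separate words never fuse into spurious qualifiers. An expert
statement containing no lexicon qualifier makes the rubric undefined and
raises a configuration error rather than silently scoring 0.

**Aggregation.** The session total is a weighted sum of the mean stage
score, the diagnosis score, and the rubric rescaled to [0, 1]
(rubric/2). The published weighting scheme is cited but not printed in
our sources, so the default is uniform (1/3 each) and configurable. When
the expert case supports no summary scoring (or no submission was made),
the missing component drops out and the remaining weights are
renormalized.

## Cognitive-error detectors

All five detectors run only on a *mismatch* (diagnosis score 0); a
detector whose required expert metadata is missing is reported as
not-evaluable instead of silently skipped.

| Rule | Fires when |
| --- | --- |
| premature closure | an expert finding/test with `stage_added` after the submission stage is connected (any supporting weight) to an expert final diagnosis |
| availability | a prior session within `window_days` (default 5) has a final diagnosis within one hierarchy level of the submitted one |
| confirmation | none of the expert's disconfirming findings (findings linked "speaks against" the matching expert differential) was added, or none was linked "speaks against" the submitted diagnosis |
| representativeness | the learner linked a flagged nonprototypical finding "speaks against" the correct final diagnosis |
| base-rate neglect | `prevalence(submitted) < rare_factor × prevalence(correct)` (default `rare_factor = 0.1`) |

Two parameters required decisions. "Early stage" in premature closure
needs no threshold: the existence of later connected expert evidence *is*
the operational definition. "Rare ... instead of the more prevalent"
needs a cutoff ratio; 0.1 — an order of magnitude rarer — is our default
and is exposed as `rare_factor`. Availability relatedness is computed
against the learner's submitted (wrong) diagnosis, not the expert's,
because the bias explains why the wrong answer came to mind. The recorded
confidence value (1–100) is carried in the evidence but gates nothing:
the sources state that it is collected, not how it is used.

## Analytics

Scores are clustered along a process model of clinical reasoning:
finding nodes → problem representation, test nodes → investigations,
therapy nodes → therapeutic interventions, differential nodes plus the
final-diagnosis score → categorization, summary rubric → semantic
transformation. A cluster is the mean of the learner's final-stage node
scores in its category; a category the expert expects but the learner
left empty scores 0, and a category empty on both sides is
not-applicable. Rescaling the rubric to [0, 1] is our convention.

Two further indicators are computed but flagged internal (not part of
learner-facing feedback): the *self-directed learning* fraction — node
and connection additions made before the first expert-map consult,
over all additions — and the *dual-processing* indicator,
`1 − stage_first_submission / (n_stages − 1)`, where 1 marks the
earliest (most pattern-recognition-like) submission. The dashboard
orders per-session cluster rows by start time, computes peer mean/SD
excluding the focal learner, and recommends the weakest clusters of the
latest session, ties resolved in cluster declaration order — a
deliberately simple placeholder policy, as no recommendation logic is
specified anywhere.

## The simulator: what it emulates, and what it does not

`make_toy_vocabulary(depth, branching)` builds a complete tree
(`Σ branching^k` terms) with labels derived from addresses, so every
distance is analytically known. `make_expert_case()` lays out a staged
case whose structure makes every score component and every detector
exercisable: three differentials in *different* root branches (so the
alternatives are genuine mismatches, more than five edges from the
correct diagnosis), disconfirming findings linked "speaks against" each
alternative, a nonprototypical finding, a decisive test appearing only at
the last stage, prevalences of 0.02/0.02/10⁻⁵, and a summary statement
carrying ten lexicon qualifiers.

`simulate_session()` copies each expert node (and each connection whose
endpoints were copied) with probability `ability` at its stage, reuses
each expert qualifier with probability `ability`, and submits per the
profile style: analytic at the last stage, nonanalytic at the first stage
with an available differential. Bias injection is *constructive*, not
probabilistic: the event stream is edited so that the Table-style
predicate of exactly one detector holds — e.g. for confirmation bias the
disconfirming finding is withheld, while for every other injected bias it
is added and linked so the confirmation rule stays silent. Because the
availability rule needs cross-session data that cannot live in a session
log, the matching prior-session history (a related diagnosis accessed
four days earlier) is attached as `attr(log, "history")`. Timestamps tick
deterministically from a fixed start, so a profile and seed reproduce the
log byte for byte.

The simulator emulates behavior, not clinical content: node choices are
uniform draws, there are no response-time dynamics, no free-text noise,
no partial hierarchy confusions (a simulated learner either copies the
expert term or omits it), and no map edits or deletions. Passing tests
therefore establish that the scoring and detection rules behave as
specified on well-formed behavior patterns — they say nothing about
robustness to the messiness of real student maps, which is exactly the
part that would need field data.

Problem sizes used throughout the tests: a 40-term vocabulary
(depth 4, branching 3) with a 4-stage, 11-node expert case; the distance
oracle cross-check runs against breadth-first shortest paths (igraph) on
a 121-term tree; the ability-to-score linkage uses 200 simulated sessions
at ability 0.7 and checks the mean matched fraction within three standard
errors.

## Degenerate inputs and numerical conventions

* `score_stage` of two empty maps is 1 (nothing expected, nothing wrong);
  an empty expert stage with learner additions is 0 after clamping.
* A single-stage scenario has no meaningful submission timing; the
  dual-processing indicator is defined as 1 there, and `NA` when nothing
  was submitted.
* Self-directed learning is vacuously 1 with no additions and no consult,
  and 0 with a consult but no additions.
* Confidence must be an integer in [1, 100]; violations are rejected at
  replay time and reported by `validate_bundle()` with a JSON-pointer
  location.
* Weights passed to `aggregate_session` must be non-negative and sum to 1
  within 1e-8.
* All scores are plain doubles; no rounding happens inside the package —
  presentation rounding is left to callers.

## Known limitations

* Free-text nodes earn only exact-normalized-string credit; there is no
  fuzzy spelling correction, by design.
* The five-level connection weight scale carries this package's level
  names (`speaks_against`, `slightly_related`, `related`,
  `highly_related`, `confirms`, serialized −1/1/2/3/4); only the
  endpoints and the negative level are anchored in the source material.
* Connections do not contribute to stage scores; if future evidence shows
  they should, the scorer surface (`score_stage`) is the single place to
  extend.
* The qualifier lexicon is a packaged approximation; deployments should
  supply their curriculum's list via `qualifier_lexicon()`.
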