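#' Default semantic-qualifier lexicon
#'
#' Semantic qualifiers are paired abstract descriptors (acute/chronic,
#' unilateral/bilateral, ...) that turn patient-specific detail into an
#' abstract problem representation. The rubric counts which of the
#' qualifiers used by the expert also appear in the learner's summary
#' statement. This packaged lexicon covers the classic antonym pairs used
#' in summary-statement teaching; each entry carries common inflection and
#' spelling variants. It can be replaced wholesale via
#' [qualifier_lexicon()].
#'
#' @return a `crt_qualifier_lexicon` data.frame with columns `pair`
#'   (antonym pair label), `canonical` (the qualifier token) and `variant`
#'   (a surface form that counts as that qualifier).
#' @export
default_qualifier_lexicon <- function() {
  p <- list(
    "acute/chronic"              = list(acute = c("acute", "acutely"),
                                        chronic = c("chronic", "chronically")),
    "sudden/gradual"             = list(sudden = c("sudden", "suddenly", "abrupt"),
                                        gradual = c("gradual", "gradually", "insidious")),
    "constant/intermittent"      = list(constant = c("constant", "continuous", "persistent"),
                                        intermittent = c("intermittent", "episodic", "recurrent")),
    "unilateral/bilateral"       = list(unilateral = c("unilateral", "one-sided"),
                                        bilateral = c("bilateral", "both-sided")),
    "severe/mild"                = list(severe = c("severe", "severely"),
                                        mild = c("mild", "mildly")),
    "localized/diffuse"          = list(localized = c("localized", "localised", "focal"),
                                        diffuse = c("diffuse", "generalized", "generalised")),
    "new/longstanding"           = list(new = c("new", "recent", "newly"),
                                        longstanding = c("longstanding", "long-standing")),
    "painful/painless"           = list(painful = "painful",
                                        painless = "painless"),
    "productive/nonproductive"   = list(productive = "productive",
                                        nonproductive = c("nonproductive", "non-productive")),
    "febrile/afebrile"           = list(febrile = "febrile",
                                        afebrile = "afebrile"),
    "proximal/distal"            = list(proximal = "proximal",
                                        distal = "distal"),
    "young/elderly"              = list(young = "young",
                                        elderly = c("elderly", "aged")),
    "progressive/stable"         = list(progressive = c("progressive", "progressing", "worsening"),
                                        stable = "stable"),
    "exertional/atrest"          = list(exertional = c("exertional", "exercise-induced"),
                                        atrest = c("at-rest", "resting")),
    "sharp/dull"                 = list(sharp = "sharp", dull = "dull")
  )
  rows <- list()
  for (pair in names(p)) {
    for (canon in names(p[[pair]])) {
      for (v in p[[pair]][[canon]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          pair = pair, canonical = canon, variant = v,
          stringsAsFactors = FALSE)
      }
    }
  }
  qualifier_lexicon(do.call(rbind, rows))
}

#' Build (or validate) a qualifier lexicon
#'
#' @param df a data.frame with columns `pair`, `canonical`, `variant`.
#'   Variant tokens must be unique across the lexicon.
#' @return a `crt_qualifier_lexicon`.
#' @export
qualifier_lexicon <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("pair", "canonical", "variant") %in% names(df)))
  df$variant <- tolower(df$variant)
  df$canonical <- tolower(df$canonical)
  if (anyDuplicated(df$variant))
    abort("qualifier variants must be unique across the lexicon: '",
          df$variant[duplicated(df$variant)][1L], "'")
  structure(df, class = c("crt_qualifier_lexicon", "data.frame"))
}

#' Extract the semantic qualifiers used in a text
#'
#' Token-level, case-insensitive matching of lexicon variants; hyphenated
#' variants also match their unhyphenated and space-separated forms.
#'
#' @param text the summary statement.
#' @param lexicon a `crt_qualifier_lexicon`.
#' @return character vector of canonical qualifier tokens present.
#' @export
extract_qualifiers <- function(text, lexicon = default_qualifier_lexicon()) {
  toks <- tokenize_text(text)
  # word pairs, so "long standing" can match the hyphenated variant;
  # only hyphenated variants are allowed to span two tokens, otherwise
  # adjacent words would fuse into spurious single-word qualifiers
  bigrams <- if (length(toks) > 1L)
    paste(toks[-length(toks)], toks[-1L], sep = "-") else character()
  hyph <- grepl("-", lexicon$variant, fixed = TRUE)
  hit <- lexicon$variant %in% toks |
    (hyph & (lexicon$variant %in% bigrams |
               gsub("-", "", lexicon$variant, fixed = TRUE) %in% toks))
  sort(unique(lexicon$canonical[hit]))
}

#' Rubric score for a summary statement
#'
#' Counts the semantic qualifiers shared between learner and expert and
#' grades the coverage fraction on the 0–2 rubric: below 30% of the
#' expert's qualifiers scores 0, at least 30% but below 60% scores 1, and
#' 60% or more scores 2 (boundaries land in the upper band).
#'
#' @param learner_text,expert_text summary statements. The expert's must
#'   contain at least one lexicon qualifier, otherwise the rubric is
#'   undefined and a configuration error is raised.
#' @param lexicon a `crt_qualifier_lexicon`.
#' @return a `crt_summary_score`: `rubric` (0, 1 or 2), `fraction_used`,
#'   `qualifiers_expert`, `qualifiers_learner`.
#' @export
score_summary <- function(learner_text, expert_text,
                          lexicon = default_qualifier_lexicon()) {
  qe <- extract_qualifiers(expert_text, lexicon)
  if (length(qe) == 0L)
    abort("expert summary statement uses no lexicon qualifier; ",
          "the rubric is undefined (check the lexicon configuration)",
          class = "crtool_config_error")
  ql <- extract_qualifiers(learner_text %||% "", lexicon)
  fraction <- length(intersect(ql, qe)) / length(qe)
  rubric <- if (fraction >= 0.6) 2L else if (fraction >= 0.3) 1L else 0L
  structure(list(rubric = rubric, fraction_used = fraction,
                 qualifiers_expert = qe, qualifiers_learner = ql),
            class = "crt_summary_score")
}

#' @export
print.crt_summary_score <- function(x, ...) {
  cat("<crt_summary_score> rubric ", x$rubric, " (",
      round(100 * x$fraction_used), "% of ", length(x$qualifiers_expert),
      " expert qualifiers used)\n", sep = "")
  invisible(x)
}

#' Weighted session total
#'
#' Combines the three assessment components — mean stage score, final
#' diagnosis score, and the summary rubric rescaled to `[0, 1]` (rubric/2)
#' — into one weighted total. The component weighting is configurable;
#' the default is uniform.
#'
#' @param stage_scores list of `crt_stage_score` (or a numeric vector of
#'   stage overalls).
#' @param diagnosis_score a `crt_diagnosis_score` or a number in `[0, 1]`.
#' @param summary_score a `crt_summary_score` or a rubric value in 0..2.
#' @param weights numeric length 3 (stages, diagnosis, summary),
#'   non-negative, summing to 1.
#' @return the weighted total in `[0, 1]`.
#' @export
aggregate_session <- function(stage_scores, diagnosis_score, summary_score,
                              weights = c(1, 1, 1) / 3) {
  if (!is.numeric(weights) || length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    abort("weights must be 3 non-negative numbers summing to 1")
  stage_vals <- if (is.numeric(stage_scores)) stage_scores
    else vapply(stage_scores, `[[`, 0, "overall")
  dx <- if (inherits(diagnosis_score, "crt_diagnosis_score"))
    diagnosis_score$combined else as.numeric(diagnosis_score)
  rub <- if (inherits(summary_score, "crt_summary_score"))
    summary_score$rubric else as.numeric(summary_score)
  comps <- c(mean(stage_vals), dx, rub / 2)
  sum(weights * comps)
}
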