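FIELD_SELECTORS <- c("definition", "note", "organism", "taxonomy_group",
                     "source_tag", "any_text")
MATCH_KINDS <- c("substring", "prefix_wildcard", "keyword_list", "regex",
                 "date_range", "taxa_set")
RULE_ACTIONS <- c("EXCLUDE", "CANDIDATE", "CONTINUE")

#' Define one triage rule
#'
#' A rule inspects one field of an annotated record, tests it with one match
#' kind, and on firing either labels the record (`CANDIDATE`, `EXCLUDE`) or
#' passes it on (`CONTINUE`).
#'
#' @param rule_id Short unique identifier.
#' @param step_index Positive integer; rules run in ascending step order.
#' @param field_selector One of `"definition"`, `"note"`, `"organism"`,
#'   `"taxonomy_group"`, `"source_tag"`, `"any_text"`.
#' @param match_kind One of `"substring"`, `"prefix_wildcard"` (match at a
#'   word start, mirroring Entrez-style `allerg*` stemming),
#'   `"keyword_list"` (any whole-word keyword), `"regex"`, `"date_range"`
#'   (`pattern = c(from, to)` against the entry date), `"taxa_set"`.
#' @param pattern Text, character vector, or a length-2 date vector,
#'   according to `match_kind`. Text matching is case-insensitive.
#' @param action `"EXCLUDE"`, `"CANDIDATE"` or `"CONTINUE"`.
#' @param polarity `"when_matched"` (default) or `"when_not_matched"`.
#' @return An object of class `filter_rule`.
#' @export
filter_rule <- function(rule_id, step_index, field_selector, match_kind,
                        pattern, action, polarity = "when_matched") {
  if (!field_selector %in% FIELD_SELECTORS)
    stop_config("rule '%s': unknown field_selector '%s'", rule_id, field_selector)
  if (!match_kind %in% MATCH_KINDS)
    stop_config("rule '%s': unknown match_kind '%s'", rule_id, match_kind)
  if (!action %in% RULE_ACTIONS)
    stop_config("rule '%s': unknown action '%s'", rule_id, action)
  if (!polarity %in% c("when_matched", "when_not_matched"))
    stop_config("rule '%s': unknown polarity '%s'", rule_id, polarity)
  if (step_index < 1) stop_config("rule '%s': step_index must be positive", rule_id)
  structure(list(rule_id = rule_id, step_index = as.integer(step_index),
                 field_selector = field_selector, match_kind = match_kind,
                 pattern = pattern, action = action, polarity = polarity),
            class = "filter_rule")
}

#' Assemble and validate a rule set
#'
#' @param rules List of [filter_rule] objects with unique step indices.
#' @param default_action Terminal action when no rule fires. The default is
#'   `CANDIDATE` (fail-open): a triage rule set should rather pass a
#'   doubtful record to review than silently omit a potential allergen.
#' @return An object of class `filter_ruleset` (rules sorted by step).
#' @export
filter_ruleset <- function(rules, default_action = "CANDIDATE") {
  if (!default_action %in% c("EXCLUDE", "CANDIDATE"))
    stop_config("default_action must be EXCLUDE or CANDIDATE")
  ok <- vapply(rules, inherits, TRUE, "filter_rule")
  if (length(rules) && !all(ok))
    stop_config("element %d is not a filter_rule", which(!ok)[1])
  steps <- vapply(rules, `[[`, 0L, "step_index")
  if (anyDuplicated(steps))
    stop_config("duplicate step_index %d", steps[duplicated(steps)][1])
  structure(list(rules = rules[order(steps)], default_action = default_action),
            class = "filter_ruleset")
}

#' @export
print.filter_ruleset <- function(x, ...) {
  cat(sprintf("<filter_ruleset> %d rules, default action %s\n",
              length(x$rules), x$default_action))
  for (r in x$rules)
    cat(sprintf("  %2d. [%s] %s %s %s -> %s\n", r$step_index, r$rule_id,
                r$field_selector, r$match_kind,
                paste(format(r$pattern), collapse = "|"), r$action))
  invisible(x)
}

rule_field_text <- function(record, selector) {
  notes <- vapply(record$features, function(f) f[[2]], "")
  txt <- switch(selector,
    definition = record$definition,
    note = notes,
    organism = record$organism,
    source_tag = record$source_tag,
    any_text = c(record$definition, notes, record$organism, record$source_tag),
    character())
  txt[!is.na(txt) & nzchar(txt)]
}

regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

rule_matches <- function(rule, record) {
  matched <- switch(rule$match_kind,
    substring = {
      txt <- rule_field_text(record, rule$field_selector)
      any(vapply(rule$pattern, function(p)
        any(grepl(regex_escape(p), txt, ignore.case = TRUE, perl = TRUE)), TRUE))
    },
    prefix_wildcard = {
      txt <- rule_field_text(record, rule$field_selector)
      any(grepl(paste0("\\b", regex_escape(rule$pattern)), txt,
                ignore.case = TRUE, perl = TRUE))
    },
    keyword_list = {
      txt <- rule_field_text(record, rule$field_selector)
      any(vapply(rule$pattern, function(kw)
        any(grepl(paste0("\\b", regex_escape(kw), "\\b"), txt,
                  ignore.case = TRUE, perl = TRUE)), TRUE))
    },
    regex = {
      txt <- rule_field_text(record, rule$field_selector)
      any(grepl(rule$pattern, txt, ignore.case = TRUE, perl = TRUE))
    },
    date_range = {
      d <- record$entry_date
      !is.na(d) && d >= as.Date(rule$pattern[[1]]) && d <= as.Date(rule$pattern[[2]])
    },
    taxa_set = {
      !is.na(record$taxonomy_group) && record$taxonomy_group %in% rule$pattern
    })
  if (rule$polarity == "when_matched") matched else !matched
}

#' Boolean primary query over annotated records
#'
#' The broad first-pass retrieval: keeps records where any text field
#' contains an `allerg`-prefixed token (case-insensitive, word-start match,
#' covering allergen/allergy/allergenic/allergic), the entry date lies in
#' `[date_from, date_to]`, and the taxonomy group is in `taxa`. A
#' constraint passed as `NULL` is disabled; when a date or taxa constraint
#' is active, records lacking that field are dropped.
#'
#' @param records List of [sequence_record] objects.
#' @param date_from,date_to Dates (or `"YYYY-MM-DD"`), or `NULL` to disable
#'   the date window.
#' @param taxa Character subset of the taxonomy groups, or `NULL` to
#'   disable; the customary retrieval restricts to animals, plants, fungi
#'   and protists.
#' @return The kept records, in input order.
#' @export
primary_query <- function(records, date_from = NULL, date_to = NULL,
                          taxa = c("animal", "plant", "fungus", "protist")) {
  if (!is.null(date_from) && !is.null(date_to)) {
    date_from <- as.Date(date_from); date_to <- as.Date(date_to)
    if (date_from > date_to) stop_args("date_from is after date_to")
  }
  keep <- vapply(records, function(r) {
    txt <- rule_field_text(r, "any_text")
    if (!any(grepl("\\ballerg", txt, ignore.case = TRUE, perl = TRUE)))
      return(FALSE)
    if (!is.null(date_from) && !is.null(date_to)) {
      if (is.na(r$entry_date) || r$entry_date < date_from || r$entry_date > date_to)
        return(FALSE)
    }
    if (!is.null(taxa)) {
      if (is.na(r$taxonomy_group) || !r$taxonomy_group %in% taxa)
        return(FALSE)
    }
    TRUE
  }, TRUE)
  records[keep]
}

#' Default allergen-designation keywords
#'
#' Protein names typically associated with specific allergen designations,
#' used by the supplemental keyword search to recover allergen records whose
#' annotation never mentions an `allerg*` term. The shipped list is a
#' documented reconstruction covering well-known allergen families; it is
#' configurable, so a curated list can be supplied verbatim.
#'
#' @return Character vector of keywords.
#' @export
default_allergen_keywords <- function() {
  c("profilin", "tropomyosin", "parvalbumin", "ovalbumin", "ovomucoid",
    "vicilin", "conglutin", "glycinin", "gliadin", "casein",
    "thaumatin-like protein", "lipid transfer protein", "pathogenesis-related protein")
}

#' Supplemental keyword search
#'
#' Keeps records whose definition or note lines contain any of the given
#' keywords as a whole word (case-insensitive). Complements the primary
#' `allerg*` query: some true allergen records carry only a specific
#' designation such as profilin or tropomyosin.
#'
#' @param records List of [sequence_record] objects.
#' @param keywords Non-empty character vector;
#'   [default_allergen_keywords()] by default.
#' @return The kept records, in input order.
#' @export
supplemental_keyword_query <- function(records,
                                       keywords = default_allergen_keywords()) {
  if (!length(keywords)) stop_args("keywords must be non-empty")
  keep <- vapply(records, function(r) {
    txt <- c(rule_field_text(r, "definition"), rule_field_text(r, "note"))
    any(vapply(keywords, function(kw)
      any(grepl(paste0("\\b", regex_escape(kw), "\\b"), txt,
                ignore.case = TRUE, perl = TRUE)), TRUE))
  }, TRUE)
  records[keep]
}

#' Apply a rule set to annotated records
#'
#' Rules run in ascending step order; the first `EXCLUDE` or `CANDIDATE`
#' action halts evaluation for that record, `CONTINUE` proceeds, and records
#' that exhaust the rules receive the rule set's default action with
#' `fired_rule_id = "default"`. Records are judged independently, so the
#' result does not depend on input order.
#'
#' @param records List of [sequence_record] objects.
#' @param ruleset A [filter_ruleset].
#' @return `data.frame` with one row per record: `accession`, `label`
#'   (`CANDIDATE`/`EXCLUDED`), `fired_rule_id`, `fired_step_index` (`NA`
#'   for the default), in input order.
#' @export
apply_filter <- function(records, ruleset) {
  if (!inherits(ruleset, "filter_ruleset"))
    ruleset <- filter_ruleset(ruleset)
  dispose <- function(r) {
    for (rule in ruleset$rules) {
      if (rule_matches(rule, r)) {
        if (rule$action == "CONTINUE") next
        return(list(label = if (rule$action == "EXCLUDE") "EXCLUDED" else "CANDIDATE",
                    rule_id = rule$rule_id, step = rule$step_index))
      }
    }
    list(label = if (ruleset$default_action == "EXCLUDE") "EXCLUDED" else "CANDIDATE",
         rule_id = "default", step = NA_integer_)
  }
  out <- lapply(records, dispose)
  data.frame(
    accession = vapply(records, `[[`, "", "accession"),
    label = vapply(out, `[[`, "", "label"),
    fired_rule_id = vapply(out, `[[`, "", "rule_id"),
    fired_step_index = vapply(out, `[[`, 0L, "step"),
    stringsAsFactors = FALSE)
}

#' The shipped default rule set
#'
#' A documented reconstruction of the stepwise keyword filter's described
#' categories (the verbatim production rule set is not public):
#' \enumerate{
#'   \item exclude records submitted through an automated annotation
#'     pipeline (genome-project provenance tag);
#'   \item records with an `allerg*` token in the definition line are
#'     candidates;
#'   \item records matching the allergen-designation keyword list are
#'     candidates;
#'   \item exclude records whose only `allerg*` occurrence sits in a note
#'     about clinical/sample context unrelated to the protein itself;
#' }
#' with the conservative fail-open default `CANDIDATE`.
#'
#' @return A [filter_ruleset].
#' @export
default_ruleset <- function() {
  filter_ruleset(list(
    filter_rule("pipeline_exclude", 1L, "source_tag", "substring",
                "automated_pipeline", "EXCLUDE"),
    filter_rule("definition_allerg", 2L, "definition", "prefix_wildcard",
                "allerg", "CANDIDATE"),
    filter_rule("allergen_keyword", 3L, "any_text", "keyword_list",
                default_allergen_keywords(), "CANDIDATE"),
    filter_rule("note_context_exclude", 4L, "note", "regex",
                "\\ballerg\\w*\\b[^.]*\\b(clinic|clinical|patient|hospital|isolate|cohort)\\b",
                "EXCLUDE")
  ), default_action = "CANDIDATE")
}

#' Summarise filter dispositions
#'
#' @param dispositions Result of [apply_filter()].
#' @return List with `label_counts`, `rule_counts` (per fired rule) and the
#'   per-record `table`; counts always sum to the number of input records.
#' @export
filter_report <- function(dispositions) {
  label_counts <- c(CANDIDATE = sum(dispositions$label == "CANDIDATE"),
                    EXCLUDED = sum(dispositions$label == "EXCLUDED"))
  rule_counts <- table(dispositions$fired_rule_id)
  structure(list(label_counts = label_counts,
                 rule_counts = setNames(as.integer(rule_counts), names(rule_counts)),
                 n = nrow(dispositions),
                 table = dispositions),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d records: %d CANDIDATE, %d EXCLUDED\n",
              x$n, x$label_counts[["CANDIDATE"]], x$label_counts[["EXCLUDED"]]))
  for (nm in names(x$rule_counts))
    cat(sprintf("  fired %-22s %d\n", nm, x$rule_counts[[nm]]))
  invisible(x)
}

#' Read / write rule sets as YAML-style config files
#'
#' One entry per rule with the [filter_rule] fields, plus a top-level
#' `default_action`. Rule sets are data, not code, so a curated production
#' rule set can be dropped in without touching the package.
#'
#' @param path Config file path.
#' @return [read_ruleset()]: a [filter_ruleset]. [write_ruleset()]: `path`,
#'   invisibly.
#' @export
read_ruleset <- function(path) {
  if (!file.exists(path)) stop_io("cannot read rule set '%s': no such file", path)
  doc <- yaml::read_yaml(path)
  rules <- lapply(doc$rules, function(r)
    filter_rule(r$rule_id, r$step_index, r$field_selector, r$match_kind,
                unlist(r$pattern), r$action,
                r$polarity %||% "when_matched"))
  filter_ruleset(rules, doc$default_action %||% "CANDIDATE")
}

#' @rdname read_ruleset
#' @param ruleset A [filter_ruleset] to serialise.
#' @export
write_ruleset <- function(ruleset, path) {
  doc <- list(
    default_action = ruleset$default_action,
    rules = lapply(ruleset$rules, function(r)
      list(rule_id = r$rule_id, step_index = r$step_index,
           field_selector = r$field_selector, match_kind = r$match_kind,
           pattern = as.character(r$pattern), action = r$action,
           polarity = r$polarity)))
  yaml::write_yaml(doc, path)
  invisible(path)
}
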