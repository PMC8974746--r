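rec <- function(acc, def = "", note = NULL, org = NA, tax = NA, date = NA,
                tag = NA) {
  sequence_record(acc, "ACDEFGHIKL", definition = def,
                  organism = org, taxonomy_group = tax, entry_date = date,
                  features = if (is.null(note)) list() else list(c("note", note)),
                  source_tag = tag)
}

test_that("primary query combines the allerg* wildcard, dates and taxa", {
  r_in <- rec("A1", def = "major allergen Bet v 1", tax = "plant",
              date = "2015-06-01")
  r_note <- rec("A2", def = "uncharacterized", note = "allergy clinic isolate",
                tax = "other", date = "2015-06-01")
  r_none <- rec("A3", def = "ribosomal protein", tax = "plant",
                date = "2015-06-01")
  recs <- list(r_in, r_note, r_none)
  kept <- primary_query(recs, "2015-01-01", "2015-12-31")
  expect_equal(vapply(kept, `[[`, "", "accession"), "A1")  # A2 dropped by taxa
  # taxa constraint disabled: the note-matching record comes back
  kept2 <- primary_query(recs, "2015-01-01", "2015-12-31", taxa = NULL)
  expect_setequal(vapply(kept2, `[[`, "", "accession"), c("A1", "A2"))
  # date window excludes
  expect_length(primary_query(recs, "2016-01-01", "2016-12-31"), 0)
  # record lacking a date is dropped while the date constraint is active
  r_nodate <- rec("A4", def = "allergen precursor", tax = "plant")
  expect_length(primary_query(list(r_nodate), "2015-01-01", "2015-12-31"), 0)
  expect_length(primary_query(list(r_nodate)), 1)
  # the wildcard matches at a word start only
  r_mid <- rec("A5", def = "galactosidase-related", tax = "plant")
  expect_length(primary_query(list(r_mid)), 0)
  expect_error(primary_query(recs, "2016-01-01", "2015-01-01"),
               class = "allerscreen_argument_error")
})

test_that("primary query recovers the generator's planted ground truth", {
  gen <- make_annotated_records(fixture_spec(seed = 13, n_entries = 500,
                                             length_range = c(60, 150)))
  kept <- primary_query(gen$records, taxa = NULL)
  expect_identical(vapply(kept, `[[`, "", "accession"),
                   gen$ground_truth$accession[gen$ground_truth$has_allerg_text])
  # with taxa active (all four groups generated) the same set survives
  kept2 <- primary_query(gen$records)
  expect_identical(kept2, kept)
})

test_that("supplemental keyword query matches whole designations only", {
  expect_length(supplemental_keyword_query(
    list(rec("K1", def = "tropomyosin, partial"))), 1)
  expect_length(supplemental_keyword_query(
    list(rec("K2", def = "allergen-like protein"))), 0)
  expect_length(supplemental_keyword_query(
    list(rec("K3", def = "profilinase"))), 0)  # not a whole word
  expect_length(supplemental_keyword_query(
    list(rec("K4", note = "similar to profilin"))), 1)
  expect_error(supplemental_keyword_query(list(), keywords = character()),
               class = "allerscreen_argument_error")

  gen <- make_annotated_records(fixture_spec(seed = 17, n_entries = 200,
                                             length_range = c(60, 150)))
  kept <- supplemental_keyword_query(gen$records)
  expect_identical(
    vapply(kept, `[[`, "", "accession"),
    gen$ground_truth$accession[gen$ground_truth$category == "allergen_keyword"])
})

test_that("rule engine semantics: order, halting, default action", {
  # empty rule set: everything becomes CANDIDATE via the default
  d <- apply_filter(list(rec("R1"), rec("R2")), filter_ruleset(list()))
  expect_equal(d$label, c("CANDIDATE", "CANDIDATE"))
  expect_equal(d$fired_rule_id, c("default", "default"))

  pipeline_rule <- filter_rule("pipe", 1, "source_tag", "substring",
                               "automated_pipeline", "EXCLUDE")
  d2 <- apply_filter(list(rec("R3", tag = "automated_pipeline")),
                     filter_ruleset(list(pipeline_rule)))
  expect_equal(d2$label, "EXCLUDED")
  expect_equal(d2$fired_step_index, 1L)

  # first decisive rule wins; CONTINUE passes through
  rs <- filter_ruleset(list(
    filter_rule("skip", 1, "definition", "substring", "protein", "CONTINUE"),
    filter_rule("get", 2, "definition", "substring", "allergen", "CANDIDATE"),
    filter_rule("never", 3, "definition", "substring", "allergen", "EXCLUDE")))
  d3 <- apply_filter(list(rec("R4", def = "allergen protein")), rs)
  expect_equal(d3$fired_rule_id, "get")

  # polarity inversion
  rs4 <- filter_ruleset(list(
    filter_rule("no_org", 1, "organism", "substring", "Betula", "EXCLUDE",
                polarity = "when_not_matched")))
  d4 <- apply_filter(list(rec("R5", org = "Betula pendula"),
                          rec("R6", org = "Homo sapiens")), rs4)
  expect_equal(d4$label, c("CANDIDATE", "EXCLUDED"))

  expect_error(filter_rule("bad", 1, "header", "substring", "x", "EXCLUDE"),
               class = "allerscreen_config_error")
  expect_error(filter_ruleset(list(pipeline_rule, pipeline_rule)),
               "step_index", class = "allerscreen_config_error")
})

test_that("the default rule set reproduces planted ground truth exactly", {
  gen <- make_annotated_records(fixture_spec(seed = 19, n_entries = 500,
                                             length_range = c(60, 150)))
  disp <- apply_filter(gen$records, default_ruleset())
  expect_identical(disp$label, gen$ground_truth$expected_label)
  expect_identical(disp$accession, gen$ground_truth$accession)
  # conservation
  expect_equal(sum(disp$label == "CANDIDATE") + sum(disp$label == "EXCLUDED"),
               length(gen$records))
  # determinism
  expect_identical(apply_filter(gen$records, default_ruleset()), disp)
})

test_that("records are judged independently of input order", {
  gen <- make_annotated_records(fixture_spec(seed = 23, n_entries = 100,
                                             length_range = c(60, 150)))
  disp <- apply_filter(gen$records, default_ruleset())
  perm <- sample(length(gen$records))
  disp_perm <- apply_filter(gen$records[perm], default_ruleset())
  expect_identical(disp_perm$label[order(perm)], disp$label)
})

test_that("removing any EXCLUDE rule never decreases the candidate count", {
  gen <- make_annotated_records(fixture_spec(seed = 29, n_entries = 300,
                                             length_range = c(60, 150)))
  rs <- default_ruleset()
  n_full <- sum(apply_filter(gen$records, rs)$label == "CANDIDATE")
  excl_idx <- which(vapply(rs$rules, `[[`, "", "action") == "EXCLUDE")
  expect_gte(length(excl_idx), 2)
  for (i in excl_idx) {
    reduced <- filter_ruleset(rs$rules[-i], rs$default_action)
    n_red <- sum(apply_filter(gen$records, reduced)$label == "CANDIDATE")
    expect_gte(n_red, n_full)
  }
})

test_that("default rule set structure covers the described categories", {
  rs <- default_ruleset()
  expect_s3_class(rs, "filter_ruleset")
  expect_gte(length(rs$rules), 4)
  expect_equal(rs$default_action, "CANDIDATE")
  actions <- vapply(rs$rules, `[[`, "", "action")
  expect_true("EXCLUDE" %in% actions && "CANDIDATE" %in% actions)
})

test_that("filter report counts are conserved and match an independent tally", {
  gen <- make_annotated_records(fixture_spec(seed = 37, n_entries = 120,
                                             length_range = c(60, 150)))
  disp <- apply_filter(gen$records, default_ruleset())
  rep <- filter_report(disp)
  expect_equal(sum(rep$label_counts), nrow(disp))
  expect_equal(sum(rep$rule_counts), nrow(disp))
  expect_equal(rep$label_counts[["CANDIDATE"]],
               sum(disp$label == "CANDIDATE"))
  for (nm in names(rep$rule_counts))
    expect_equal(rep$rule_counts[[nm]], sum(disp$fired_rule_id == nm))
})

test_that("rule sets round-trip through the YAML config format", {
  rs <- default_ruleset()
  f <- withr::local_tempfile(fileext = ".yml")
  write_ruleset(rs, f)
  back <- read_ruleset(f)
  expect_equal(length(back$rules), length(rs$rules))
  expect_equal(back$default_action, rs$default_action)
  gen <- make_annotated_records(fixture_spec(seed = 41, n_entries = 80,
                                             length_range = c(60, 150)))
  expect_identical(apply_filter(gen$records, back),
                   apply_filter(gen$records, rs))
})
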