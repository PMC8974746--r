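ref1 <- list(list(id = "PMID:1", title = "IgE binding study", year = 2019))

entry <- function(acc = "E1", seq = "ACDEFGHIKLMNPQ", year = "2019",
                  kind = "full_protein", refs = ref1, ...) {
  allergen_entry(acc, species = "Betula pendula", common_name = "birch",
                 description = "major pollen allergen", sequence = seq,
                 year_adopted = year, references = refs, entry_kind = kind, ...)
}

test_that("entry validation encodes the inclusion criteria", {
  expect_length(validate_entry(entry()), 0)
  # mass-spectrometry peptides must be at least 10 residues
  expect_equal(validate_entry(entry(seq = "ACDEFGHIK", kind = "ms_peptide")),
               "PEPTIDE_TOO_SHORT")
  expect_length(validate_entry(entry(seq = "ACDEFGHIKL", kind = "ms_peptide")), 0)
  # reviewed entries need a supporting publication
  expect_equal(validate_entry(entry(refs = list())), "NO_REFERENCE")
  # ... but the imported pre-2017 base is exempt
  expect_length(validate_entry(entry(year = "2016", refs = list())), 0)
  expect_length(validate_entry(entry(year = "2015", refs = list())), 0)
  # historic labels still carry their adoption year
  expect_equal(validate_entry(entry(year = "2020H", refs = list())), "NO_REFERENCE")
  # structural checks
  broken <- entry(); broken$length <- 99L
  expect_true("LENGTH_MISMATCH" %in% validate_entry(broken))
  odd <- entry(); odd$sequence <- "AC1EF"
  expect_true("INVALID_RESIDUE" %in% validate_entry(odd))
})

test_that("review decisions enforce the controlled vocabulary", {
  led <- decision_ledger()
  led <- record_decision(led, "E1", "ACCEPT", "IGE_BINDING_EVIDENCE", 2019)
  led <- record_decision(led, "E2", "REJECT", "CCD_ONLY_BINDING", 2019,
                         comment = "binding exclusively to glycan moieties")
  expect_length(led$decisions, 2)
  expect_error(record_decision(led, "E3", "ACCEPT", "ASSAY_VALID", 2019),
               "IGE_BINDING_EVIDENCE", class = "allerscreen_argument_error")
  expect_error(record_decision(led, "E3", "REJECT", "SERA_QUALITY_OK", 2019),
               class = "allerscreen_argument_error")
  expect_error(record_decision(led, "E3", "ACCEPT", "MADE_UP_CODE", 2019),
               class = "allerscreen_argument_error")
  expect_error(record_decision(led, "E3", "MAYBE", "IGE_BINDING_EVIDENCE", 2019),
               class = "allerscreen_argument_error")
})

test_that("a rejected candidate can be revisited; the ledger is append-only", {
  led <- decision_ledger()
  led <- record_decision(led, "X9", "REJECT", "HOMOLOGY_ONLY", 2019)
  before <- led$decisions
  led2 <- record_decision(led, "X9", "ACCEPT", "IGE_BINDING_EVIDENCE", 2020,
                          comment = "new sera data")
  expect_length(led2$decisions, 2)
  expect_identical(led2$decisions[[1]], before[[1]])  # prior decision untouched
  expect_identical(led$decisions, before)             # old ledger unmodified
  expect_equal(vapply(led2$decisions, `[[`, 0L, "cycle_year"), c(2019L, 2020L))
})

make_base <- function(n = 10, label = "2020") {
  release(label, lapply(seq_len(n), function(i)
    allergen_entry(sprintf("B%02d", i), "Genus sp.", "common",
                   sprintf("allergen %d", i),
                   paste(rep("ACDEF", 4), collapse = ""), "2016")))
}

test_that("release building preserves the base and stamps new entries", {
  base <- make_base(10)
  accepted <- lapply(1:3, function(i)
    entry(acc = sprintf("N%02d", i), year = "unstamped"))
  rel <- build_release(base, accepted, "2021")
  expect_length(rel$entries, 13)
  for (acc in names(base$entries))
    expect_identical(rel$entries[[acc]], base$entries[[acc]])
  expect_equal(rel$entries[["N01"]]$year_adopted, "2021")

  d <- diff_releases(base, rel)
  expect_equal(d$added, c("N01", "N02", "N03"))
  expect_length(d$removed, 0)
  expect_length(d$changed, 0)

  # invalid entries are rejected with their violation list
  expect_error(build_release(base, list(entry(acc = "P1", seq = "ACDEFGHIK",
                                              kind = "ms_peptide")), "2021"),
               "PEPTIDE_TOO_SHORT", class = "allerscreen_argument_error")
  # duplicate accession without the explicit metadata-update flag is a conflict
  expect_error(build_release(base, list(entry(acc = "B01")), "2021"),
               "B01", class = "allerscreen_argument_error")
  amended <- build_release(base, list(entry(acc = "B01")), "2021",
                           update_metadata = TRUE)
  expect_length(amended$entries, 10)
  expect_equal(amended$entries[["B01"]]$year_adopted, "2016")  # year preserved
})

test_that("historic additions get H / H_MS adoption labels", {
  base <- make_base(5)
  rel <- build_release(base, list(
    entry(acc = "H1"),
    entry(acc = "H2", seq = "ACDEFGHIKL", kind = "ms_peptide")),
    "2020", historic = TRUE)
  expect_equal(rel$entries[["H1"]]$year_adopted, "2020H")
  expect_equal(rel$entries[["H2"]]$year_adopted, "2020H_MS")
})

test_that("release diffs equal independent set arithmetic", {
  set.seed(43)
  mk <- function(accs, descs) release("v", lapply(seq_along(accs), function(i)
    allergen_entry(accs[[i]], "sp", "cn", descs[[i]],
                   paste(rep("GHIKL", 3), collapse = ""), "2016")),
    validate = FALSE)
  old_acc <- sprintf("A%02d", 1:12)
  new_acc <- sprintf("A%02d", 5:18)
  old <- mk(old_acc, paste("d", 1:12))
  descs_new <- paste("d", 5:18)
  descs_new[2] <- "edited description"  # A06
  new <- mk(new_acc, descs_new)
  d <- diff_releases(old, new)
  expect_equal(d$added, sort(setdiff(new_acc, old_acc)))
  expect_equal(d$removed, sort(setdiff(old_acc, new_acc)))
  expect_equal(names(d$changed), "A06")
  expect_equal(d$changed[["A06"]], "description")
  expect_equal(length(new$entries),
               length(old$entries) - length(d$removed) + length(d$added))
  # identical releases diff empty
  d0 <- diff_releases(old, old)
  expect_length(d0$added, 0); expect_length(d0$removed, 0)
  expect_length(d0$changed, 0)
})

test_that("transparency export writes one row per decision", {
  led <- decision_ledger()
  led <- record_decision(led, "E1", "ACCEPT", c("IGE_BINDING_EVIDENCE",
                                                "ASSAY_VALID"), 2019, "solid")
  led <- record_decision(led, "E2", "REJECT", "INSUFFICIENT_PURITY", 2020,
                         "single band not discrete")
  f <- withr::local_tempfile(fileext = ".tsv")
  export_transparency(led, f)
  df <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(nrow(df), 2)
  expect_equal(df$Verdict, c("ACCEPT", "REJECT"))
  expect_equal(df$Criteria[[1]], "IGE_BINDING_EVIDENCE;ASSAY_VALID")
  expect_equal(df$Cycle, c(2019L, 2020L))
})

test_that("release export and re-import compose to the identity", {
  base <- make_base(6)
  rel <- build_release(base, list(
    entry(acc = "N1", iuis_name = "Bet v 1"),
    entry(acc = "N2", seq = "ACDEFGHIKL", kind = "ms_peptide",
          parent_accession = "B01")), "2021")
  fa <- withr::local_tempfile(fileext = ".fasta")
  tb <- withr::local_tempfile(fileext = ".tsv")
  export_release(rel, fa, tb)
  # table Length always equals FASTA length
  expect_true(check_entry_lengths(read_entry_table(tb), read_fasta(fa)))
  back <- import_release(fa, tb, version_label = "2021")
  expect_setequal(names(back$entries), names(rel$entries))
  for (acc in names(rel$entries)) {
    for (fld in c("accession", "species", "common_name", "description",
                  "iuis_name", "sequence", "length", "year_adopted",
                  "parent_accession"))
      expect_identical(back$entries[[acc]][[fld]], rel$entries[[acc]][[fld]])
  }
  # export is deterministic: rebuilding from identical inputs is byte-identical
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  tb2 <- withr::local_tempfile(fileext = ".tsv")
  export_release(rel, fa2, tb2)
  expect_identical(readLines(fa), readLines(fa2))
  expect_identical(readLines(tb), readLines(tb2))
})
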