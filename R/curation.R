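ENTRY_KINDS <- c("full_protein", "partial", "ms_peptide")

INCLUSION_CODES <- c("IGE_BINDING_EVIDENCE", "SERA_QUALITY_OK", "ASSAY_VALID")
EXCLUSION_CODES <- c("NO_NEGATIVE_CONTROL", "INSUFFICIENT_PURITY",
                     "CCD_ONLY_BINDING", "HOMOLOGY_ONLY", "SEQUENCE_MISMATCH")

#' Construct a curated allergen database entry
#'
#' Construction is permissive: structural problems are reported as
#' violation codes by [validate_entry()], not as errors, so draft entries
#' can be built, inspected and fixed.
#'
#' @param accession Accession string.
#' @param species Scientific name of the source organism.
#' @param common_name Common name of the source.
#' @param description Description of the allergen sequence.
#' @param sequence Residue string.
#' @param year_adopted Adoption label: a year (`"2019"`) or a historic
#'   screening label (`"2020H"`, `"2020H_MS"`).
#' @param iuis_name WHO/IUIS allergen designation (e.g. `"Bet v 1"`) or `NA`.
#' @param references List of citation records, each a list with `id`,
#'   `title`, `year`. Entries adopted in 2017 or later require at least one
#'   supporting publication; the imported pre-2017 base is exempt.
#' @param parent_accession For mass-spectrometry fragments, the accession of
#'   the full protein the fragment derives from (metadata only, not itself
#'   an entry), or `NA`.
#' @param entry_kind `"full_protein"`, `"partial"` or `"ms_peptide"`
#'   (peptides must be at least 10 residues).
#' @return An object of class `allergen_entry`.
#' @export
allergen_entry <- function(accession, species, common_name, description,
                           sequence, year_adopted, iuis_name = NA_character_,
                           references = list(),
                           parent_accession = NA_character_,
                           entry_kind = "full_protein") {
  if (!is.character(accession) || !nzchar(accession))
    stop_args("accession must be a non-empty string")
  if (!entry_kind %in% ENTRY_KINDS)
    stop_args("entry '%s': unknown entry_kind '%s'", accession, entry_kind)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  structure(
    list(accession = accession, species = species, common_name = common_name,
         description = description, iuis_name = iuis_name,
         sequence = sequence, length = nchar(sequence),
         year_adopted = as.character(year_adopted),
         references = references, parent_accession = parent_accession,
         entry_kind = entry_kind),
    class = "allergen_entry")
}

adoption_year <- function(label) {
  m <- regmatches(label, regexec("^(\\d{4})", label))[[1]]
  if (length(m) < 2L) NA_integer_ else as.integer(m[[2]])
}

#' Validate an allergen entry against the inclusion criteria
#'
#' Pure structural checks mirroring the database's declared criteria:
#' the stored length must equal the residue count; entries adopted in 2017
#' or later need at least one supporting publication; mass-spectrometry
#' peptides must be at least 10 residues; the sequence must use the accepted
#' amino-acid alphabet.
#'
#' @param entry An [allergen_entry].
#' @return Character vector of violation codes (`LENGTH_MISMATCH`,
#'   `NO_REFERENCE`, `PEPTIDE_TOO_SHORT`, `INVALID_RESIDUE`,
#'   `EMPTY_SEQUENCE`); empty when valid.
#' @export
validate_entry <- function(entry) {
  v <- character()
  if (!nzchar(entry$sequence)) v <- c(v, "EMPTY_SEQUENCE")
  if (entry$length != nchar(entry$sequence)) v <- c(v, "LENGTH_MISMATCH")
  if (nzchar(entry$sequence) &&
      length(setdiff(strsplit(entry$sequence, "")[[1]], AA_ALPHABET)))
    v <- c(v, "INVALID_RESIDUE")
  yr <- adoption_year(entry$year_adopted)
  if (!is.na(yr) && yr >= 2017L && length(entry$references) == 0L)
    v <- c(v, "NO_REFERENCE")
  if (entry$entry_kind == "ms_peptide" && entry$length < 10L)
    v <- c(v, "PEPTIDE_TOO_SHORT")
  v
}

#' Review-decision ledger
#'
#' An append-only record of peer-review decisions. The minimum criterion
#' for acceptance is peer-reviewed evidence of IgE binding, so an `ACCEPT`
#' must carry the `IGE_BINDING_EVIDENCE` code; a `REJECT` must carry at
#' least one exclusion code (lack of negative-control sera, insufficient
#' purity, carbohydrate-only binding, homology-only evidence, or a mismatch
#' between the candidate sequence and the sequence tested in the
#' literature). A rejected accession may be revisited in a later cycle;
#' every decision is retained in ledger order.
#'
#' @return An empty object of class `decision_ledger`.
#' @export
decision_ledger <- function() {
  structure(list(decisions = list()), class = "decision_ledger")
}

#' Record a peer-review decision
#'
#' @param ledger A [decision_ledger()].
#' @param accession Candidate accession.
#' @param verdict `"ACCEPT"` or `"REJECT"`.
#' @param criteria_codes Codes from the controlled vocabulary (inclusion:
#'   `IGE_BINDING_EVIDENCE`, `SERA_QUALITY_OK`, `ASSAY_VALID`; exclusion:
#'   `NO_NEGATIVE_CONTROL`, `INSUFFICIENT_PURITY`, `CCD_ONLY_BINDING`,
#'   `HOMOLOGY_ONLY`, `SEQUENCE_MISMATCH`).
#' @param cycle_year Review cycle year (integer).
#' @param comment Free-text reviewer comment.
#' @return The ledger with the decision appended (prior decisions
#'   untouched).
#' @export
record_decision <- function(ledger, accession, verdict, criteria_codes,
                            cycle_year, comment = "") {
  if (!inherits(ledger, "decision_ledger")) stop_args("ledger must be a decision_ledger")
  if (!verdict %in% c("ACCEPT", "REJECT"))
    stop_args("verdict must be ACCEPT or REJECT")
  unknown <- setdiff(criteria_codes, c(INCLUSION_CODES, EXCLUSION_CODES))
  if (length(unknown))
    stop_args("unknown criteria code '%s'", unknown[[1]])
  if (verdict == "ACCEPT" && !"IGE_BINDING_EVIDENCE" %in% criteria_codes)
    stop_args("ACCEPT requires the IGE_BINDING_EVIDENCE code")
  if (verdict == "REJECT" && !any(criteria_codes %in% EXCLUSION_CODES))
    stop_args("REJECT requires at least one exclusion code")
  decision <- list(accession = accession, verdict = verdict,
                   criteria_codes = criteria_codes,
                   cycle_year = as.integer(cycle_year), comment = comment)
  ledger$decisions <- c(ledger$decisions, list(decision))
  ledger
}

#' @export
print.decision_ledger <- function(x, ...) {
  cat(sprintf("<decision_ledger> %d decisions\n", length(x$decisions)))
  for (d in x$decisions)
    cat(sprintf("  %s %s %s [%s]\n", d$cycle_year, d$accession, d$verdict,
                paste(d$criteria_codes, collapse = ",")))
  invisible(x)
}

#' Construct a versioned release
#'
#' @param version_label Release label, e.g. `"2021"`.
#' @param entries List of valid [allergen_entry] objects (unique
#'   accessions).
#' @param provenance Character vector of provenance notes.
#' @param validate Check every entry with [validate_entry()] (default
#'   `TRUE`; imports of exported releases disable this because exports do
#'   not carry reference lists).
#' @return An object of class `release`, entries keyed by accession.
#' @export
release <- function(version_label, entries = list(), provenance = character(),
                    validate = TRUE) {
  accs <- vapply(entries, `[[`, "", "accession")
  if (anyDuplicated(accs))
    stop_args("duplicate accession '%s' in release", accs[duplicated(accs)][1])
  if (validate) {
    for (e in entries) {
      v <- validate_entry(e)
      if (length(v))
        stop_args("entry '%s' is invalid: %s", e$accession, paste(v, collapse = ", "))
    }
  }
  structure(list(version_label = version_label,
                 entries = setNames(entries, accs),
                 provenance = provenance),
            class = "release")
}

#' @export
print.release <- function(x, ...) {
  cat(sprintf("<release> %s: %d entries\n", x$version_label, length(x$entries)))
  invisible(x)
}

#' Build the next release from a base release plus accepted entries
#'
#' Base entries are never removed or modified: the foundational list stays
#' intact across versions, and updates only add. New entries are validated
#' and stamped with the version label; entries from a historic screening
#' (records dated before the process began, screened retrospectively) are
#' labelled with an `H` suffix, or `H_MS` for mass-spectrometry peptides,
#' to distinguish them from the regular annual screening.
#'
#' @param base A [release].
#' @param accepted List of [allergen_entry] objects accepted by review.
#' @param version_label Label of the new release.
#' @param historic Are the accepted entries from a historic screening?
#' @param update_metadata Explicit opt-in to replace metadata of an existing
#'   accession; without it a duplicate accession is a conflict error.
#' @param check_references Enforce the supporting-publication rule (default).
#'   Disable only when entries arrive through the FASTA/table exchange
#'   format, which does not carry literature lists.
#' @return A new [release] of size `|base| + |new accessions|`.
#' @export
build_release <- function(base, accepted, version_label, historic = FALSE,
                          update_metadata = FALSE, check_references = TRUE) {
  if (!inherits(base, "release")) stop_args("base must be a release")
  entries <- base$entries
  notes <- base$provenance
  for (e in accepted) {
    if (!inherits(e, "allergen_entry")) stop_args("accepted entries must be allergen_entry")
    e$year_adopted <- if (historic) {
      paste0(version_label, if (e$entry_kind == "ms_peptide") "H_MS" else "H")
    } else version_label
    v <- validate_entry(e)
    if (!check_references) v <- setdiff(v, "NO_REFERENCE")
    if (length(v))
      stop_args("entry '%s' rejected: %s", e$accession, paste(v, collapse = ", "))
    if (e$accession %in% names(entries)) {
      if (!update_metadata)
        stop_args("accession '%s' already present in base release (use update_metadata to amend)",
                  e$accession)
      notes <- c(notes, sprintf("%s: metadata updated in %s", e$accession, version_label))
      e$year_adopted <- entries[[e$accession]]$year_adopted
    } else {
      notes <- c(notes, sprintf("%s: added in %s%s", e$accession, version_label,
                                if (historic) " (historic screening)" else ""))
    }
    entries[[e$accession]] <- e
  }
  # entries were validated above (base entries on construction of `base`)
  release(version_label, unname(entries), provenance = notes, validate = FALSE)
}

#' Field-level diff between two releases
#'
#' @param old,new [release] objects.
#' @return List with `added` and `removed` accession vectors and `changed`,
#'   a named list mapping shared accessions to the names of fields that
#'   differ.
#' @export
diff_releases <- function(old, new) {
  fields <- c("species", "common_name", "description", "iuis_name",
              "sequence", "length", "year_adopted", "parent_accession",
              "entry_kind")
  old_acc <- names(old$entries); new_acc <- names(new$entries)
  shared <- intersect(old_acc, new_acc)
  changed <- list()
  for (acc in shared) {
    diffs <- fields[vapply(fields, function(f)
      !identical(old$entries[[acc]][[f]], new$entries[[acc]][[f]]), TRUE)]
    if (length(diffs)) changed[[acc]] <- diffs
  }
  list(added = sort(setdiff(new_acc, old_acc)),
       removed = sort(setdiff(old_acc, new_acc)),
       changed = changed)
}

#' Export the review ledger as a transparency file
#'
#' One tab-separated row per decision: accession, cycle year, verdict,
#' criteria codes (semicolon-joined) and the reviewer comment — the public
#' record of why each candidate was accepted or rejected.
#'
#' @param ledger A [decision_ledger].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
export_transparency <- function(ledger, path) {
  df <- data.frame(
    Accession = vapply(ledger$decisions, `[[`, "", "accession"),
    Cycle = vapply(ledger$decisions, `[[`, 0L, "cycle_year"),
    Verdict = vapply(ledger$decisions, `[[`, "", "verdict"),
    Criteria = vapply(ledger$decisions, function(d)
      paste(d$criteria_codes, collapse = ";"), ""),
    Comment = vapply(ledger$decisions, `[[`, "", "comment"),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a release as FASTA plus metadata table
#'
#' Writes the sequence FASTA (definition = description) and the standard
#' metadata table, mutually consistent by accession and length.
#'
#' @param rel A [release].
#' @param fasta_path,table_path Output paths.
#' @return Invisibly, a list with both paths.
#' @seealso [import_release()]
#' @export
export_release <- function(rel, fasta_path, table_path) {
  entries <- rel$entries[order(names(rel$entries))]
  records <- lapply(entries, function(e)
    sequence_record(e$accession, e$sequence, definition = e$description))
  write_fasta(unname(records), fasta_path)
  rows <- data.frame(
    `Species` = vapply(entries, `[[`, "", "species"),
    `Common Name` = vapply(entries, `[[`, "", "common_name"),
    `Description` = vapply(entries, `[[`, "", "description"),
    `IUIS Name` = vapply(entries, function(e) e$iuis_name %||% NA_character_, ""),
    `Accession` = vapply(entries, `[[`, "", "accession"),
    `Length` = vapply(entries, `[[`, 0L, "length"),
    `Year Adopted` = vapply(entries, `[[`, "", "year_adopted"),
    `Parent Accession` = vapply(entries, `[[`, "", "parent_accession"),
    check.names = FALSE, stringsAsFactors = FALSE)
  rows$`IUIS Name`[is.na(rows$`IUIS Name`)] <- ""
  rows$`Parent Accession`[is.na(rows$`Parent Accession`)] <- ""
  write_entry_table(rows, table_path)
  invisible(list(fasta = fasta_path, table = table_path))
}

#' Import a release from FASTA plus metadata table
#'
#' Rebuilds a [release] from the two export files, cross-checking that each
#' table row's `Length` equals its paired sequence length. Reference lists
#' are not part of the export format, so imported entries carry empty
#' reference lists and validation is skipped.
#'
#' @param fasta_path,table_path Paths written by [export_release()].
#' @param version_label Label for the reconstructed release.
#' @return A [release].
#' @export
import_release <- function(fasta_path, table_path, version_label = "imported") {
  records <- read_fasta(fasta_path)
  rows <- read_entry_table(table_path)
  check_entry_lengths(rows, records)
  seqs <- setNames(vapply(records, `[[`, "", "sequence"),
                   vapply(records, `[[`, "", "accession"))
  entries <- lapply(seq_len(nrow(rows)), function(i) {
    allergen_entry(
      accession = rows$Accession[[i]],
      species = rows$Species[[i]],
      common_name = rows$`Common Name`[[i]],
      description = rows$Description[[i]],
      sequence = seqs[[rows$Accession[[i]]]],
      year_adopted = rows$`Year Adopted`[[i]],
      iuis_name = if (nzchar(rows$`IUIS Name`[[i]])) rows$`IUIS Name`[[i]] else NA_character_,
      parent_accession = if (nzchar(rows$`Parent Accession`[[i]]))
        rows$`Parent Accession`[[i]] else NA_character_)
  })
  release(version_label, entries, validate = FALSE)
}
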