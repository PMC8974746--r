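#' Construct a protein sequence record
#'
#' The basic unit handled by the toolkit: one protein sequence together with
#' the annotation fields that the candidate filter inspects (definition line,
#' organism, broad taxonomic group, entry date, feature notes and a
#' submission-provenance tag).
#'
#' @param accession Non-empty accession string, unique within a file.
#' @param sequence Residue string over the 20 amino-acid letters plus the
#'   ambiguity letters B, Z, X, U, J, O. Normalised to upper case.
#' @param definition Free-text description line.
#' @param organism Scientific name of the source organism, or `NA`.
#' @param taxonomy_group One of `"animal"`, `"plant"`, `"fungus"`,
#'   `"protist"`, `"other"`, or `NA`.
#' @param entry_date A `Date` (or `"YYYY-MM-DD"` string), or `NA`.
#' @param features List of `c(key, value)` character pairs, e.g. note lines.
#' @param source_tag Provenance tag, e.g. `"automated_pipeline"`, or `NA`.
#' @return An object of class `sequence_record`.
#' @examples
#' sequence_record("a1", "ACDEF", definition = "test protein")
#' @export
sequence_record <- function(accession, sequence, definition = "",
                            organism = NA_character_,
                            taxonomy_group = NA_character_,
                            entry_date = NA,
                            features = list(),
                            source_tag = NA_character_) {
  if (!is.character(accession) || length(accession) != 1L || !nzchar(accession))
    stop_args("accession must be a single non-empty string")
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(sequence))
    stop_args("record '%s': sequence must be non-empty", accession)
  bad <- setdiff(strsplit(sequence, "")[[1]], AA_ALPHABET)
  if (length(bad))
    stop_parse("record '%s': unknown residue letter '%s'", accession, bad[[1]])
  if (!is.na(taxonomy_group) &&
      !taxonomy_group %in% c("animal", "plant", "fungus", "protist", "other"))
    stop_args("record '%s': unknown taxonomy_group '%s'", accession, taxonomy_group)
  if (!inherits(entry_date, "Date") && !all(is.na(entry_date))) {
    parsed <- tryCatch(as.Date(entry_date), error = function(e) NA)
    if (is.na(parsed))
      stop_parse("record '%s': unparseable date '%s'", accession, entry_date)
    entry_date <- parsed
  }
  if (all(is.na(entry_date))) entry_date <- as.Date(NA)
  structure(
    list(accession = accession,
         definition = definition %||% "",
         organism = organism,
         taxonomy_group = taxonomy_group,
         entry_date = entry_date,
         features = features,
         source_tag = source_tag,
         sequence = sequence,
         length = nchar(sequence)),
    class = "sequence_record"
  )
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%d aa)\n", x$accession, x$length))
  if (nzchar(x$definition)) cat("  definition:", x$definition, "\n")
  if (!is.na(x$organism)) cat("  organism:  ", x$organism, "\n")
  if (!is.na(x$taxonomy_group)) cat("  taxgroup:  ", x$taxonomy_group, "\n")
  if (!is.na(x$entry_date)) cat("  date:      ", format(x$entry_date), "\n")
  for (f in x$features) cat(sprintf("  /%s = \"%s\"\n", f[[1]], f[[2]]))
  seq_show <- if (x$length > 60) paste0(substr(x$sequence, 1, 57), "...") else x$sequence
  cat("  ", seq_show, "\n", sep = "")
  invisible(x)
}

check_unique_accessions <- function(records, path) {
  acc <- vapply(records, `[[`, "", "accession")
  dup <- acc[duplicated(acc)]
  if (length(dup))
    stop_parse("%s: duplicate accession '%s'", path, dup[[1]])
  invisible(acc)
}

#' Read protein sequences from a FASTA file
#'
#' One record per `>` header. The header token before the first whitespace
#' becomes the accession, the remainder the definition; sequence lines are
#' concatenated, whitespace-stripped and upper-cased. An empty file yields an
#' empty list. Sequence data before any header, a header with no sequence
#' lines, or residues outside the accepted amino-acid alphabet are parse
#' errors.
#'
#' @param path Path to a FASTA file.
#' @return List of [sequence_record] objects, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_io("cannot read FASTA file '%s': no such file", path)
  lines <- readLines(path, warn = FALSE)
  records <- list()
  acc <- NULL; def <- ""; chunks <- character(); header_line <- 0L
  flush <- function() {
    seq <- paste(chunks, collapse = "")
    if (!nzchar(seq))
      stop_parse("%s:%d: header '%s' has no sequence lines", path, header_line, acc)
    records[[length(records) + 1L]] <<- sequence_record(acc, seq, definition = def)
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (startsWith(line, ">")) {
      if (!is.null(acc)) flush()
      header <- sub("^>", "", line)
      acc <- sub("\\s.*$", "", header)
      def <- if (grepl("\\s", header)) trimws(sub("^\\S+\\s+", "", header)) else ""
      if (!nzchar(acc)) stop_parse("%s:%d: empty FASTA header", path, i)
      chunks <- character(); header_line <- i
    } else if (nzchar(trimws(line))) {
      if (is.null(acc))
        stop_parse("%s:%d: sequence data before any '>' header", path, i)
      chunks <- c(chunks, gsub("[[:space:]]", "", line))
    }
  }
  if (!is.null(acc)) flush()
  check_unique_accessions(records, path)
  records
}

#' Write sequence records to a FASTA file
#'
#' Headers are `>accession definition`; sequences are wrapped at `wrap`
#' columns and the file ends with a newline. An empty record list writes an
#' empty file.
#'
#' @param records List of [sequence_record] objects.
#' @param path Output path.
#' @param wrap Positive line width for sequence wrapping (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  if (!is.numeric(wrap) || wrap < 1) stop_args("wrap must be a positive integer")
  out <- tryCatch(file(path, "w"), error = function(e)
    stop_io("cannot write FASTA file '%s': %s", path, conditionMessage(e)))
  on.exit(close(out))
  for (r in records) {
    header <- if (nzchar(r$definition)) paste(r$accession, r$definition) else r$accession
    writeLines(paste0(">", header), out)
    starts <- seq(1L, r$length, by = as.integer(wrap))
    writeLines(substring(r$sequence, starts, pmin(starts + wrap - 1L, r$length)), out)
  }
  invisible(path)
}

# ---- simplified annotated flat-file dialect ------------------------------
# Blocks separated by "//" lines; keys ACCESSION, DEFINITION, ORGANISM,
# TAXGROUP, DATE, SOURCETAG, NOTE (repeatable), then SEQUENCE followed by
# residue lines until the end of the block.

#' Read annotated records from the simplified flat-file dialect
#'
#' The dialect is a minimal line-keyed format carrying the fields the
#' candidate filter inspects. Blocks end with a `//` line; each block has
#' `KEY  value` lines with keys `ACCESSION` (mandatory), `DEFINITION`,
#' `ORGANISM`, `TAXGROUP`, `DATE` (ISO-8601), `SOURCETAG`, `NOTE`
#' (repeatable), and a `SEQUENCE` line after which all lines up to `//` are
#' residues (mandatory).
#'
#' @param path Path to a flat file.
#' @return List of [sequence_record] objects.
#' @seealso [write_flatfile()]
#' @export
read_flatfile <- function(path) {
  if (!file.exists(path)) stop_io("cannot read flat file '%s': no such file", path)
  lines <- readLines(path, warn = FALSE)
  records <- list()
  block <- list(features = list(), seq_lines = character(), in_seq = FALSE)
  reset <- function() list(features = list(), seq_lines = character(), in_seq = FALSE)
  finish <- function(b, lineno) {
    if (is.null(b$accession))
      stop_parse("%s: block ending at line %d lacks mandatory key ACCESSION", path, lineno)
    seq <- paste(b$seq_lines, collapse = "")
    if (!nzchar(seq))
      stop_parse("%s: block '%s' lacks mandatory key SEQUENCE", path, b$accession)
    if (!is.null(b$date) && !grepl("^\\d{4}-\\d{2}-\\d{2}$", b$date))
      stop_parse("%s: block '%s': unparseable date '%s'", path, b$accession, b$date)
    records[[length(records) + 1L]] <<- sequence_record(
      b$accession, seq,
      definition = b$definition %||% "",
      organism = b$organism %||% NA_character_,
      taxonomy_group = b$taxgroup %||% NA_character_,
      entry_date = if (is.null(b$date)) NA else as.Date(b$date),
      features = b$features,
      source_tag = b$sourcetag %||% NA_character_)
  }
  saw_content <- FALSE
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (trimws(line) == "//") {
      if (saw_content) finish(block, i)
      block <- reset(); saw_content <- FALSE
      next
    }
    if (!nzchar(trimws(line))) next
    if (block$in_seq) {
      block$seq_lines <- c(block$seq_lines, gsub("[[:space:]]", "", line))
      saw_content <- TRUE
      next
    }
    m <- regmatches(line, regexec("^([A-Z]+)\\s*(.*)$", line))[[1]]
    if (length(m) < 2L)
      stop_parse("%s:%d: malformed line '%s'", path, i, line)
    key <- m[[2]]; val <- trimws(m[[3]])
    saw_content <- TRUE
    switch(key,
      ACCESSION  = { block$accession <- val },
      DEFINITION = { block$definition <- val },
      ORGANISM   = { block$organism <- val },
      TAXGROUP   = { block$taxgroup <- val },
      DATE       = { block$date <- val },
      SOURCETAG  = { block$sourcetag <- val },
      NOTE       = { block$features <- c(block$features, list(c("note", val))) },
      SEQUENCE   = {
        block$in_seq <- TRUE
        if (nzchar(val)) block$seq_lines <- gsub("[[:space:]]", "", val)
      },
      stop_parse("%s:%d: unknown key '%s'", path, i, key)
    )
  }
  if (saw_content) finish(block, length(lines))
  check_unique_accessions(records, path)
  records
}

#' Write annotated records in the simplified flat-file dialect
#'
#' @param records List of [sequence_record] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_flatfile <- function(records, path) {
  out <- tryCatch(file(path, "w"), error = function(e)
    stop_io("cannot write flat file '%s': %s", path, conditionMessage(e)))
  on.exit(close(out))
  for (r in records) {
    writeLines(paste0("ACCESSION  ", r$accession), out)
    if (nzchar(r$definition)) writeLines(paste0("DEFINITION  ", r$definition), out)
    if (!is.na(r$organism)) writeLines(paste0("ORGANISM  ", r$organism), out)
    if (!is.na(r$taxonomy_group)) writeLines(paste0("TAXGROUP  ", r$taxonomy_group), out)
    if (!is.na(r$entry_date)) writeLines(paste0("DATE  ", format(r$entry_date)), out)
    if (!is.na(r$source_tag)) writeLines(paste0("SOURCETAG  ", r$source_tag), out)
    for (f in r$features)
      writeLines(paste0(toupper(f[[1]]), "  ", f[[2]]), out)
    writeLines("SEQUENCE", out)
    starts <- seq(1L, r$length, by = 60L)
    writeLines(substring(r$sequence, starts, pmin(starts + 59L, r$length)), out)
    writeLines("//", out)
  }
  invisible(path)
}

# ---- allergen entry metadata table ---------------------------------------

ENTRY_TABLE_COLUMNS <- c("Species", "Common Name", "Description", "IUIS Name",
                         "Accession", "Length", "Year Adopted", "Parent Accession")

#' Read an allergen entry metadata table
#'
#' Tab-separated UTF-8 with the exact header `Species, Common Name,
#' Description, IUIS Name, Accession, Length, Year Adopted, Parent
#' Accession`. Missing columns and duplicate accessions are schema errors.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with those columns (`Length` integer).
#' @seealso [write_entry_table()], [check_entry_lengths()]
#' @export
read_entry_table <- function(path) {
  if (!file.exists(path)) stop_io("cannot read entry table '%s': no such file", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8",
                   quote = "", comment.char = "")
  missing <- setdiff(ENTRY_TABLE_COLUMNS, names(df))
  if (length(missing))
    stop_schema("%s: missing column(s): %s", path, paste(missing, collapse = ", "))
  df <- df[, ENTRY_TABLE_COLUMNS, drop = FALSE]
  dup <- df$Accession[duplicated(df$Accession)]
  if (length(dup))
    stop_schema("%s: duplicate accession '%s'", path, dup[[1]])
  df$Length <- as.integer(df$Length)
  df
}

#' Write an allergen entry metadata table
#'
#' @param rows `data.frame` with the columns listed in [read_entry_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_entry_table <- function(rows, path) {
  missing <- setdiff(ENTRY_TABLE_COLUMNS, names(rows))
  if (length(missing))
    stop_schema("entry table is missing column(s): %s", paste(missing, collapse = ", "))
  dup <- rows$Accession[duplicated(rows$Accession)]
  if (length(dup)) stop_schema("entry table has duplicate accession '%s'", dup[[1]])
  write.table(rows[, ENTRY_TABLE_COLUMNS, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Check that table Length values match sequence lengths
#'
#' Joins a metadata table to FASTA records by accession and verifies the
#' `Length` column equals the residue count of each paired sequence.
#'
#' @param rows Entry metadata `data.frame`.
#' @param records List of [sequence_record] objects.
#' @return `TRUE` invisibly if consistent; schema error otherwise.
#' @export
check_entry_lengths <- function(rows, records) {
  lens <- setNames(vapply(records, `[[`, 0L, "length"),
                   vapply(records, `[[`, "", "accession"))
  for (i in seq_len(nrow(rows))) {
    acc <- rows$Accession[[i]]
    if (!acc %in% names(lens))
      stop_schema("accession '%s' in table has no paired sequence", acc)
    if (lens[[acc]] != rows$Length[[i]])
      stop_schema("accession '%s': table Length %d != sequence length %d",
                  acc, rows$Length[[i]], lens[[acc]])
  }
  invisible(TRUE)
}
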