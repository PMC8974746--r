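# Deterministic synthetic data for every test surface. All generators draw
# from R's Mersenne-Twister stream seeded explicitly (and restore the
# caller's RNG state), so a fixed seed gives byte-identical fixtures.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

FIXTURE_CATEGORIES <- c("pipeline", "definition_allerg", "allergen_keyword",
                        "note_context_allerg", "irrelevant")

#' Specification for synthetic fixtures
#'
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @param n_entries Number of records to generate.
#' @param length_range Length-2 integer vector, inclusive sequence-length
#'   bounds (`min < max` not required but the range must be non-degenerate:
#'   `min <= max`, both positive).
#' @param category_mix Named numeric vector of proportions over the filter
#'   categories (`pipeline`, `definition_allerg`, `allergen_keyword`,
#'   `note_context_allerg`, `irrelevant`); must sum to 1.
#' @param alphabet Residue set to draw from (default the 20 standard amino
#'   acids).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_entries = 50L, length_range = c(90L, 400L),
                         category_mix = c(pipeline = 0.2,
                                          definition_allerg = 0.25,
                                          allergen_keyword = 0.15,
                                          note_context_allerg = 0.15,
                                          irrelevant = 0.25),
                         alphabet = AA_STANDARD) {
  if (length(length_range) != 2L || any(length_range < 1) ||
      length_range[[1]] > length_range[[2]])
    stop_args("length_range must be a valid (min, max) pair of positive integers")
  unknown <- setdiff(names(category_mix), FIXTURE_CATEGORIES)
  if (length(unknown)) stop_args("unknown fixture category '%s'", unknown[[1]])
  if (abs(sum(category_mix) - 1) > 1e-8)
    stop_args("category_mix proportions must sum to 1")
  structure(list(seed = as.integer(seed), n_entries = as.integer(n_entries),
                 length_range = as.integer(length_range),
                 category_mix = category_mix, alphabet = alphabet),
            class = "fixture_spec")
}

random_sequence <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic protein database
#'
#' `n_entries` records with lengths uniform over `length_range`, residues
#' i.i.d. over the spec's alphabet, and accessions `SYN000001`,
#' `SYN000002`, ...
#'
#' @param spec A [fixture_spec].
#' @param fasta_path Optional path; when given the database is also written
#'   as FASTA.
#' @return List of [sequence_record] objects.
#' @export
make_db <- function(spec, fasta_path = NULL) {
  if (!inherits(spec, "fixture_spec")) stop_args("spec must be a fixture_spec")
  records <- with_seed(spec$seed, {
    lrange <- seq(spec$length_range[[1]], spec$length_range[[2]])
    lens <- lrange[sample.int(length(lrange), spec$n_entries, replace = TRUE)]
    lapply(seq_len(spec$n_entries), function(i)
      sequence_record(sprintf("SYN%06d", i),
                      random_sequence(lens[[i]], spec$alphabet),
                      definition = sprintf("synthetic protein %d", i)))
  })
  if (!is.null(fasta_path)) write_fasta(records, fasta_path)
  records
}

fixture_organisms <- list(
  animal = c("Homo sapiens", "Penaeus monodon", "Gallus gallus"),
  plant = c("Betula pendula", "Arachis hypogaea", "Triticum aestivum"),
  fungus = c("Aspergillus fumigatus", "Alternaria alternata"),
  protist = c("Plasmodium falciparum"))

#' Generate annotated records with planted filter categories
#'
#' Each record carries exactly the textual features of its category:
#' \itemize{
#'   \item `pipeline`: tagged `automated_pipeline`, neutral definition;
#'   \item `definition_allerg`: an `allerg*` token in the definition line;
#'   \item `allergen_keyword`: a specific allergen designation (profilin,
#'     tropomyosin, ...) in the definition, no `allerg*` term;
#'   \item `note_context_allerg`: an `allerg*` term only in a clinical
#'     context note unrelated to the protein itself;
#'   \item `irrelevant`: none of the above.
#' }
#' The returned ground truth gives, per record, the category, the expected
#' disposition under [default_ruleset()], and whether any text field
#' contains an `allerg*` token (the primary-query match indicator).
#'
#' @param spec A [fixture_spec]; `category_mix` sets the category counts
#'   (largest-remainder rounding to `n_entries`).
#' @return List with `records` (list of [sequence_record]) and
#'   `ground_truth` (`data.frame`: `accession`, `category`,
#'   `expected_label`, `has_allerg_text`, `taxonomy_group`, `entry_date`).
#' @export
make_annotated_records <- function(spec) {
  if (!inherits(spec, "fixture_spec")) stop_args("spec must be a fixture_spec")
  mix <- spec$category_mix[spec$category_mix > 0]
  raw <- mix * spec$n_entries
  counts <- floor(raw)
  rem <- spec$n_entries - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  categories <- rep(names(counts), counts)
  keywords <- default_allergen_keywords()
  with_seed(spec$seed, {
    categories <- sample(categories)
    n <- length(categories)
    taxgroups <- sample(names(fixture_organisms), n, replace = TRUE)
    dates <- as.Date("2015-01-01") + sample(0:730, n, replace = TRUE)
    records <- vector("list", n)
    gt_label <- character(n); gt_allerg <- logical(n)
    for (i in seq_len(n)) {
      acc <- sprintf("REC%06d", i)
      org <- sample(fixture_organisms[[taxgroups[[i]]]], 1)
      seq <- random_sequence(sample(60:150, 1), spec$alphabet)
      cat_i <- categories[[i]]
      def <- switch(cat_i,
        pipeline = "hypothetical protein, genome assembly",
        definition_allerg = sample(c("major allergen Bet v 1 isoform",
                                     "minor allergen precursor",
                                     "allergenic seed storage globulin"), 1),
        allergen_keyword = paste0(sample(keywords, 1), ", partial"),
        note_context_allerg = "uncharacterized secreted protein",
        irrelevant = sample(c("DNA-directed RNA polymerase subunit",
                              "ribosomal protein L12",
                              "cytochrome c oxidase subunit II"), 1))
      features <- if (cat_i == "note_context_allerg")
        list(c("note", "sequenced from an allergy clinic patient isolate"))
      else list()
      records[[i]] <- sequence_record(
        acc, seq, definition = def, organism = org,
        taxonomy_group = taxgroups[[i]], entry_date = dates[[i]],
        features = features,
        source_tag = if (cat_i == "pipeline") "automated_pipeline" else NA_character_)
      gt_label[[i]] <- switch(cat_i,
        pipeline = "EXCLUDED",
        definition_allerg = "CANDIDATE",
        allergen_keyword = "CANDIDATE",
        note_context_allerg = "EXCLUDED",
        irrelevant = "CANDIDATE")
      gt_allerg[[i]] <- cat_i %in% c("definition_allerg", "note_context_allerg")
    }
    list(records = records,
         ground_truth = data.frame(
           accession = vapply(records, `[[`, "", "accession"),
           category = categories,
           expected_label = gt_label,
           has_allerg_text = gt_allerg,
           taxonomy_group = taxgroups,
           entry_date = dates,
           stringsAsFactors = FALSE))
  })
}

#' Implant a homolog with an exact identity count
#'
#' Returns a string of length `region_len` whose gap-free, position-by-
#' position alignment to `base[start .. start + region_len - 1]` has exactly
#' `n_identical` identical positions. Substituted positions receive the
#' highest-scoring non-identical standard residue under BLOSUM50 (ties
#' broken alphabetically), so substituted columns still score well and the
#' full-region alignment is also the optimal local alignment; when
#' `n_identical >= 2` the first and last region positions are kept identical
#' to anchor the alignment ends.
#'
#' @param base Residue string.
#' @param n_identical Number of identical positions, `0 <= n_identical <=
#'   region_len`.
#' @param region_len Length of the homologous region, `<= nchar(base)`.
#' @param seed Integer seed selecting which positions stay identical.
#' @param start 1-based start of the region within `base` (default 1).
#' @return Residue string of length `region_len`.
#' @export
implant_homolog <- function(base, n_identical, region_len, seed, start = 1L) {
  if (inherits(base, "sequence_record")) base <- base$sequence
  L <- nchar(base)
  if (region_len < 1 || start < 1 || start + region_len - 1L > L)
    stop_args("region [%d, %d] does not fit in a base of length %d",
              start, start + region_len - 1L, L)
  if (n_identical < 0 || n_identical > region_len)
    stop_args("n_identical must be between 0 and region_len")
  region <- strsplit(substr(base, start, start + region_len - 1L), "")[[1]]
  if (length(setdiff(region, AA_STANDARD)))
    stop_args("base region must use the 20 standard residues")
  mat <- bundled_matrix("BLOSUM50")[AA_STANDARD, AA_STANDARD]
  partner <- vapply(AA_STANDARD, function(a) {
    others <- setdiff(AA_STANDARD, a)
    others[which.max(mat[a, others])]
  }, "")
  ident_pos <- with_seed(seed, {
    if (n_identical >= 2 && region_len >= 2) {
      anchors <- c(1L, region_len)
      inner <- setdiff(seq_len(region_len), anchors)
      c(anchors, if (n_identical > 2)
        sort(inner[sample.int(length(inner), n_identical - 2L)]) else integer())
    } else if (n_identical >= 1) {
      sort(sample(seq_len(region_len), n_identical))
    } else integer()
  })
  variant <- region
  subst <- setdiff(seq_len(region_len), ident_pos)
  variant[subst] <- partner[region[subst]]
  paste(variant, collapse = "")
}
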