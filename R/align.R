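# Karlin-Altschul ungapped (lambda, K) pairs for the bundled matrices.
# Standard values from the BLAST statistics literature; documented stand-ins
# since gapped statistics would require an empirical regression.
KA_TABLE <- list(
  BLOSUM50 = c(lambda = 0.232, k = 0.11),
  BLOSUM62 = c(lambda = 0.318, k = 0.13)
)

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix format used by NCBI tools (`#` comment
#' lines, a header row of residue letters, one labelled row of integer
#' scores per residue).
#'
#' @param path Path to a matrix file.
#' @return Integer matrix with residue letters as dimnames.
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) stop_io("cannot read matrix file '%s': no such file", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_parse("%s: not a matrix file", path)
  letters <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  n <- length(letters)
  mat <- matrix(NA_integer_, n, n, dimnames = list(letters, letters))
  for (ln in lines[-1]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != n + 1L)
      stop_parse("%s: matrix row '%s' has %d values, expected %d",
                 path, parts[[1]], length(parts) - 1L, n)
    mat[parts[[1]], ] <- as.integer(parts[-1])
  }
  if (anyNA(mat)) stop_parse("%s: matrix is missing rows", path)
  mat
}

bundled_matrix <- function(name) {
  path <- system.file("extdata", paste0(name, ".txt"), package = "allerscreen")
  if (!nzchar(path))
    stop_config("no bundled substitution matrix named '%s'", name)
  read_score_matrix(path)
}

#' Alignment parameters
#'
#' Bundles a substitution matrix with affine gap penalties and the
#' Karlin-Altschul parameters used for E-values. Defaults mirror the
#' customary protein-search setup of the FASTA package: BLOSUM50 with gap
#' open -10 and gap extension -2 (a gap of length g costs
#' `gap_open + (g - 1) * gap_extend`).
#'
#' @param matrix_name Name of a bundled matrix (`"BLOSUM50"` or
#'   `"BLOSUM62"`), or a path to an NCBI-format matrix file.
#' @param gap_open Penalty for the first residue of a gap (negative).
#' @param gap_extend Penalty for each further gap residue (negative,
#'   `gap_open <= gap_extend < 0`).
#' @param ka_lambda,ka_k Positive Karlin-Altschul parameters; defaults are
#'   the standard ungapped values for the named matrix.
#' @return An object of class `align_params`.
#' @examples
#' align_params()
#' @export
align_params <- function(matrix_name = "BLOSUM50", gap_open = -10L,
                         gap_extend = -2L, ka_lambda = NULL, ka_k = NULL) {
  matrix <- if (file.exists(matrix_name)) read_score_matrix(matrix_name)
            else bundled_matrix(basename(matrix_name))
  if (!(gap_open <= gap_extend && gap_extend < 0))
    stop_args("gap penalties must satisfy gap_open <= gap_extend < 0")
  ka <- KA_TABLE[[sub("\\.[^.]*$", "", basename(matrix_name))]]
  ka_lambda <- ka_lambda %||% unname(ka["lambda"])
  ka_k <- ka_k %||% unname(ka["k"])
  if (is.null(ka_lambda) || is.na(ka_lambda) || ka_lambda <= 0 ||
      is.null(ka_k) || is.na(ka_k) || ka_k <= 0)
    stop_args("ka_lambda and ka_k must be positive (supply them for custom matrices)")
  structure(
    list(matrix_name = matrix_name, matrix = matrix,
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         ka_lambda = ka_lambda, ka_k = ka_k),
    class = "align_params")
}

#' @export
print.align_params <- function(x, ...) {
  cat(sprintf("<align_params> %s, gap open %d / extend %d, lambda %.3f, K %.3f\n",
              x$matrix_name, x$gap_open, x$gap_extend, x$ka_lambda, x$ka_k))
  invisible(x)
}

encode_residues <- function(seq, matrix, what = "sequence") {
  chars <- strsplit(seq, "")[[1]]
  codes <- match(chars, rownames(matrix))
  if (anyNA(codes))
    stop_args("%s contains residue '%s' absent from the substitution matrix",
              what, chars[which(is.na(codes))[1]])
  codes
}

new_local_alignment <- function(raw, query, subject, matrix) {
  letters <- rownames(matrix)
  decode <- function(v) {
    out <- rep("-", length(v))
    out[v > 0] <- letters[v[v > 0]]
    paste(out, collapse = "")
  }
  structure(
    list(score = raw$score,
         q_start = raw$q_start, q_end = raw$q_end,
         s_start = raw$s_start, s_end = raw$s_end,
         n_identities = raw$n_identities, n_columns = raw$n_columns,
         identity_fraction = if (raw$n_columns > 0)
           raw$n_identities / raw$n_columns else NA_real_,
         q_aligned = decode(raw$q_aln), s_aligned = decode(raw$s_aln)),
    class = "local_alignment")
}

#' Smith-Waterman local alignment
#'
#' Exact local alignment of two protein sequences under an affine-gap
#' model (no heuristic seeding stage), returning the maximal-scoring local
#' alignment. If no pairing scores above zero, an empty alignment
#' (`n_columns = 0`, score 0) is returned, flagging "no similarity".
#' Identity counting is conservative: an aligned X never counts as an
#' identity, even against another X.
#'
#' @param query,subject Non-empty residue strings (or [sequence_record]s).
#' @param params An [align_params] object.
#' @return A `local_alignment`: score, 1-based inclusive coordinates
#'   (`q_start`, `q_end`, `s_start`, `s_end`), `n_identities`, `n_columns`,
#'   `identity_fraction` and the two gapped alignment strings.
#' @examples
#' smith_waterman("HEAGAWGHEE", "HEAGAWGHEE")
#' @export
smith_waterman <- function(query, subject, params = align_params()) {
  if (inherits(query, "sequence_record")) query <- query$sequence
  if (inherits(subject, "sequence_record")) subject <- subject$sequence
  if (!is.character(query) || length(query) != 1L || !nzchar(query))
    stop_args("query must be a single non-empty residue string")
  if (!is.character(subject) || length(subject) != 1L || !nzchar(subject))
    stop_args("subject must be a single non-empty residue string")
  q <- encode_residues(toupper(query), params$matrix, "query")
  s <- encode_residues(toupper(subject), params$matrix, "subject")
  x_code <- match("X", rownames(params$matrix), nomatch = 0L)
  raw <- .sw_align_cpp(q, s, params$matrix, params$gap_open,
                       params$gap_extend, x_code)
  new_local_alignment(raw, query, subject, params$matrix)
}

#' @export
print.local_alignment <- function(x, ...) {
  if (x$n_columns == 0) {
    cat("<local_alignment> no similarity (score 0)\n")
    return(invisible(x))
  }
  cat(sprintf("<local_alignment> score %d, %d/%d identities (%.1f%%)\n",
              x$score, x$n_identities, x$n_columns, 100 * x$identity_fraction))
  cat(sprintf("  query   %4d %s %d\n", x$q_start, x$q_aligned, x$q_end))
  midline <- paste(ifelse(strsplit(x$q_aligned, "")[[1]] ==
                            strsplit(x$s_aligned, "")[[1]] &
                            strsplit(x$q_aligned, "")[[1]] != "-" &
                            strsplit(x$q_aligned, "")[[1]] != "X",
                          "|", " "), collapse = "")
  cat(sprintf("               %s\n", midline))
  cat(sprintf("  subject %4d %s %d\n", x$s_start, x$s_aligned, x$s_end))
  invisible(x)
}

#' Percent identity of a local alignment
#'
#' Identities divided by all alignment columns; gap columns count in the
#' denominator, never the numerator.
#'
#' @param aln A `local_alignment` with `n_columns > 0`.
#' @return Fraction in `[0, 1]`.
#' @export
percent_identity <- function(aln) {
  if (!inherits(aln, "local_alignment")) stop_args("aln must be a local_alignment")
  if (aln$n_columns == 0)
    stop_args("percent identity is undefined for an empty alignment")
  aln$n_identities / aln$n_columns
}

#' Karlin-Altschul E-value
#'
#' Expected number of chance local alignments scoring at least `score` in a
#' search of a query of `query_len` residues against a database of
#' `db_residues` total residues: `E = K * m * n * exp(-lambda * score)`
#' (ungapped form; an approximation for gapped searches).
#'
#' @param score Alignment score.
#' @param query_len,db_residues Positive lengths in residues.
#' @param params An [align_params] supplying `ka_lambda` and `ka_k`.
#' @return Non-negative expected count.
#' @export
evalue <- function(score, query_len, db_residues, params = align_params()) {
  if (query_len <= 0 || db_residues <= 0)
    stop_args("query_len and db_residues must be positive")
  params$ka_k * query_len * db_residues * exp(-params$ka_lambda * score)
}
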