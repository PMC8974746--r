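#' Screening configuration
#'
#' Thresholds and alignment parameters for the three-mode screen. The
#' sliding-window rule follows FAO/WHO and Codex Alimentarius guidance: a
#' window alignment is a hit when identity exceeds `identity_threshold`
#' (strictly greater than 0.35 by default) over at least `window` aligned
#' columns. The E-value threshold applies to the full-length search only and
#' is deliberately permissive by default (1.0); it is user-settable.
#'
#' @param params An [align_params] object.
#' @param e_threshold Positive E-value cutoff for full-length hits.
#' @param identity_threshold Window identity cutoff (strict inequality).
#' @param window Sliding-window width in residues (default 80).
#' @param kmer Exact-match word size (default 8).
#' @param modes Character subset of `c("full", "window", "kmer")`.
#' @param db_label Label identifying the database version screened against.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(params = align_params(), e_threshold = 1.0,
                          identity_threshold = 0.35, window = 80L, kmer = 8L,
                          modes = c("full", "window", "kmer"),
                          db_label = "unlabeled") {
  if (!inherits(params, "align_params")) stop_config("params must be align_params")
  if (!is.numeric(e_threshold) || e_threshold <= 0)
    stop_config("e_threshold must be positive")
  if (identity_threshold < 0 || identity_threshold >= 1)
    stop_config("identity_threshold must be in [0, 1)")
  if (window < 1 || kmer < 1) stop_config("window and kmer must be positive")
  bad <- setdiff(modes, c("full", "window", "kmer"))
  if (length(bad)) stop_config("unknown screening mode '%s'", bad[[1]])
  structure(list(params = params, e_threshold = e_threshold,
                 identity_threshold = identity_threshold,
                 window = as.integer(window), kmer = as.integer(kmer),
                 modes = modes, db_label = db_label),
            class = "screen_config")
}

check_db <- function(db) {
  if (!is.list(db) || length(db) == 0L)
    stop_args("db must be a non-empty list of sequence_record objects")
  ok <- vapply(db, inherits, TRUE, "sequence_record")
  if (!all(ok)) stop_args("db element %d is not a sequence_record", which(!ok)[1])
  invisible(db)
}

as_query_record <- function(query) {
  if (inherits(query, "sequence_record")) query
  else sequence_record("query", query)
}

#' Full-length search of a query against an allergen database
#'
#' Aligns the whole query against every database entry and reports those
#' with E-value at or below the threshold, sorted by ascending E-value,
#' ties broken by descending score then accession. The database size used
#' in the E-value is the summed length of all database sequences.
#'
#' @param query A [sequence_record] or residue string.
#' @param db Non-empty list of [sequence_record] objects.
#' @param params An [align_params] object.
#' @param e_threshold Positive E-value cutoff (`Inf` keeps every entry).
#' @return List of `full_hit` objects (`subject_accession`, `alignment`,
#'   `evalue`).
#' @export
fullseq_search <- function(query, db, params = align_params(), e_threshold = 1.0) {
  check_db(db)
  if (e_threshold <= 0) stop_args("e_threshold must be positive")
  query <- as_query_record(query)
  db_residues <- sum(vapply(db, `[[`, 0L, "length"))
  hits <- lapply(db, function(subject) {
    aln <- smith_waterman(query$sequence, subject$sequence, params)
    structure(list(subject_accession = subject$accession,
                   alignment = aln,
                   evalue = evalue(aln$score, query$length, db_residues, params)),
              class = "full_hit")
  })
  hits <- Filter(function(h) h$evalue <= e_threshold, hits)
  ord <- order(vapply(hits, `[[`, 0, "evalue"),
               -vapply(hits, function(h) h$alignment$score, 0),
               vapply(hits, `[[`, "", "subject_accession"))
  hits[ord]
}

#' Enumerate sliding windows of a query sequence
#'
#' For queries of at least `width` residues, every overlapping window of
#' `width` residues (starts 1 .. L - width + 1). Shorter queries yield one
#' whole-sequence window flagged `short`; these are still screened but fall
#' outside the Codex-defined 80-residue rule.
#'
#' @param query Residue string or [sequence_record].
#' @param width Window width (default 80).
#' @param stride Step between window starts (default 1).
#' @return `data.frame` with columns `start`, `window_seq`, `short`.
#' @export
make_windows <- function(query, width = 80L, stride = 1L) {
  if (inherits(query, "sequence_record")) query <- query$sequence
  if (!nzchar(query)) stop_args("query must be non-empty")
  L <- nchar(query)
  if (L >= width) {
    starts <- seq(1L, L - width + 1L, by = as.integer(stride))
    data.frame(start = starts,
               window_seq = substring(query, starts, starts + width - 1L),
               short = FALSE, stringsAsFactors = FALSE)
  } else {
    data.frame(start = 1L, window_seq = query, short = TRUE,
               stringsAsFactors = FALSE)
  }
}

#' Sliding-window identity scan
#'
#' Aligns every window of the query against every database entry
#' (local alignment of window versus full subject) and reports window hits:
#' identity strictly above the threshold over at least `window` columns
#' (for short queries, over at least the window's own length, flagged
#' `short`). Also returns a per-window trace of the best identity observed
#' across the database.
#'
#' @param query A [sequence_record] or residue string.
#' @param db Non-empty list of [sequence_record] objects.
#' @param config A [screen_config].
#' @return List with `hits` (list of `window_hit` objects) and `trace`
#'   (`data.frame`: `window_start`, `window_len`, `short`, `best_identity`,
#'   `best_subject`).
#' @export
window_scan <- function(query, db, config = screen_config()) {
  check_db(db)
  query <- as_query_record(query)
  params <- config$params
  q <- encode_residues(query$sequence, params$matrix, "query")
  subjects <- lapply(db, function(r)
    encode_residues(r$sequence, params$matrix, r$accession))
  x_code <- match("X", rownames(params$matrix), nomatch = 0L)
  raw <- .sw_window_scan_cpp(q, subjects, config$window, params$matrix,
                             params$gap_open, params$gap_extend, x_code,
                             config$identity_threshold)
  accs <- vapply(db, `[[`, "", "accession")
  short <- raw$window_len < config$window
  hits <- lapply(raw$hits, function(h) {
    w <- h$window_index
    structure(list(
      window_start = raw$window_start[[w]],
      window_seq = substr(query$sequence, raw$window_start[[w]],
                          raw$window_start[[w]] + raw$window_len[[w]] - 1L),
      short = short[[w]],
      subject_accession = accs[[h$subject_index]],
      alignment = new_local_alignment(h, NULL, NULL, params$matrix),
      is_hit = TRUE), class = "window_hit")
  })
  ord <- order(vapply(hits, `[[`, 0L, "window_start"),
               vapply(hits, `[[`, "", "subject_accession"))
  best_j <- max.col(raw$identity, ties.method = "first")
  trace <- data.frame(
    window_start = raw$window_start,
    window_len = raw$window_len,
    short = short,
    best_identity = raw$identity[cbind(seq_along(best_j), best_j)],
    best_subject = accs[best_j],
    stringsAsFactors = FALSE)
  list(hits = hits[ord], trace = trace)
}

kmer_is_exact <- function(kmers) {
  !grepl(paste0("[", paste(AA_AMBIGUOUS, collapse = ""), "]"), kmers)
}

#' Build an exact-match k-mer index over a database
#'
#' Indexes every k-length substring of every database sequence by position.
#' Words containing ambiguity letters (B, Z, X, U, J, O) are excluded: an
#' ambiguous residue is not an exact match. Entries shorter than `k`
#' contribute nothing.
#'
#' @param db Non-empty list of [sequence_record] objects.
#' @param k Word size (default 8).
#' @return An object of class `kmer_index`.
#' @export
build_kmer_index <- function(db, k = 8L) {
  check_db(db)
  if (k < 1) stop_args("k must be >= 1")
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (r in db) {
    if (r$length < k) next
    starts <- seq_len(r$length - k + 1L)
    words <- substring(r$sequence, starts, starts + k - 1L)
    keep <- kmer_is_exact(words)
    for (i in which(keep)) {
      w <- words[[i]]
      env[[w]] <- rbind(env[[w]],
                        data.frame(subject_accession = r$accession,
                                   subject_pos = starts[[i]],
                                   stringsAsFactors = FALSE))
    }
  }
  structure(list(k = as.integer(k), env = env), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k = %d, %d distinct words\n",
              x$k, length(ls(x$env))))
  invisible(x)
}

#' Scan a query for exact k-mer matches against an index
#'
#' Reports every position where `k` contiguous query residues exactly match
#' `k` contiguous residues of a database entry. Kept for guideline
#' completeness; the 8-mer criterion is known to have a high false-positive
#' rate and adds little to risk assessment on its own.
#'
#' @param query A [sequence_record] or residue string.
#' @param index A [build_kmer_index()] result.
#' @param k Word size; must equal the index's `k`.
#' @return `data.frame` with `query_pos`, `subject_accession`,
#'   `subject_pos`, `kmer`, sorted by query position, accession, subject
#'   position. Queries shorter than `k` yield zero rows.
#' @export
kmer_scan <- function(query, index, k = index$k) {
  if (!inherits(index, "kmer_index")) stop_args("index must be a kmer_index")
  if (k != index$k) stop_args("k (%d) does not match index k (%d)", k, index$k)
  query <- as_query_record(query)
  empty <- data.frame(query_pos = integer(), subject_accession = character(),
                      subject_pos = integer(), kmer = character(),
                      stringsAsFactors = FALSE)
  if (query$length < k) return(empty)
  starts <- seq_len(query$length - k + 1L)
  words <- substring(query$sequence, starts, starts + k - 1L)
  keep <- kmer_is_exact(words)
  out <- list()
  for (i in which(keep)) {
    m <- index$env[[words[[i]]]]
    if (is.null(m)) next
    out[[length(out) + 1L]] <- data.frame(
      query_pos = starts[[i]], subject_accession = m$subject_accession,
      subject_pos = m$subject_pos, kmer = words[[i]],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$query_pos, res$subject_accession, res$subject_pos), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Run the three-mode allergenicity screen for one query
#'
#' Aggregates the full-length search, the 80-aa sliding-window scan and the
#' 8-mer exact-match scan into one report carrying a parameter snapshot
#' sufficient to reproduce the run.
#'
#' @param query A [sequence_record] or residue string.
#' @param db Non-empty list of [sequence_record] objects (the allergen
#'   database).
#' @param config A [screen_config]; its `modes` field selects which of the
#'   three searches run.
#' @param kmer_index Optional prebuilt [build_kmer_index()] result for `db`
#'   (built on the fly if omitted).
#' @return An object of class `screen_report`.
#' @examples
#' db <- make_db(fixture_spec(seed = 1, n_entries = 3, length_range = c(90, 120)))
#' rep <- run_screen(db[[1]], db, screen_config(db_label = "demo"))
#' rep
#' @export
run_screen <- function(query, db, config = screen_config(), kmer_index = NULL) {
  check_db(db)
  query <- as_query_record(query)
  full_hits <- if ("full" %in% config$modes)
    fullseq_search(query, db, config$params, config$e_threshold) else list()
  win <- if ("window" %in% config$modes)
    window_scan(query, db, config) else list(hits = list(), trace = NULL)
  kmer_hits <- if ("kmer" %in% config$modes) {
    if (is.null(kmer_index)) kmer_index <- build_kmer_index(db, config$kmer)
    kmer_scan(query, kmer_index, config$kmer)
  } else NULL
  structure(
    list(query_accession = query$accession,
         query_length = query$length,
         db_version_label = config$db_label,
         parameters = list(
           matrix = config$params$matrix_name,
           gap_open = config$params$gap_open,
           gap_extend = config$params$gap_extend,
           ka_lambda = config$params$ka_lambda,
           ka_k = config$params$ka_k,
           e_threshold = config$e_threshold,
           identity_threshold = config$identity_threshold,
           window = config$window,
           kmer = config$kmer,
           modes = config$modes,
           db_size = length(db),
           db_residues = sum(vapply(db, `[[`, 0L, "length"))),
         full_hits = full_hits,
         window_hits = win$hits,
         window_trace = win$trace,
         kmer_hits = kmer_hits,
         any_full_hit_below_threshold = length(full_hits) > 0,
         any_window_hit = length(win$hits) > 0,
         any_kmer_hit = !is.null(kmer_hits) && nrow(kmer_hits) > 0),
    class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(format_report(x, style = "txt"))
  invisible(x)
}

report_tsv_rows <- function(report) {
  rows <- list()
  for (h in report$full_hits) {
    a <- h$alignment
    rows[[length(rows) + 1L]] <- data.frame(
      mode = "full", query_accession = report$query_accession,
      subject_accession = h$subject_accession,
      q_start = a$q_start, q_end = a$q_end,
      s_start = a$s_start, s_end = a$s_end,
      score = a$score,
      evalue = sprintf("%.6g", h$evalue),
      identity = sprintf("%.4f", a$identity_fraction),
      n_columns = a$n_columns,
      window_start = NA_integer_, kmer = NA_character_,
      stringsAsFactors = FALSE)
  }
  for (h in report$window_hits) {
    a <- h$alignment
    rows[[length(rows) + 1L]] <- data.frame(
      mode = if (h$short) "window(short)" else "window",
      query_accession = report$query_accession,
      subject_accession = h$subject_accession,
      q_start = a$q_start, q_end = a$q_end,
      s_start = a$s_start, s_end = a$s_end,
      score = a$score, evalue = NA_character_,
      identity = sprintf("%.4f", a$identity_fraction),
      n_columns = a$n_columns,
      window_start = h$window_start, kmer = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!is.null(report$kmer_hits) && nrow(report$kmer_hits)) {
    k <- report$kmer_hits
    rows[[length(rows) + 1L]] <- data.frame(
      mode = "kmer", query_accession = report$query_accession,
      subject_accession = k$subject_accession,
      q_start = k$query_pos, q_end = k$query_pos + nchar(k$kmer) - 1L,
      s_start = k$subject_pos, s_end = k$subject_pos + nchar(k$kmer) - 1L,
      score = NA_integer_, evalue = NA_character_,
      identity = NA_character_, n_columns = nchar(k$kmer),
      window_start = NA_integer_, kmer = k$kmer,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(mode = character(), query_accession = character(),
                      subject_accession = character(), q_start = integer(),
                      q_end = integer(), s_start = integer(), s_end = integer(),
                      score = integer(), evalue = character(),
                      identity = character(), n_columns = integer(),
                      window_start = integer(), kmer = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Format a screen report
#'
#' `"tsv"` renders one row per hit across all three modes with fixed
#' columns; `"txt"` renders a human-readable summary with the parameter
#' snapshot. Formatting is deterministic.
#'
#' @param report A [run_screen()] result.
#' @param style `"tsv"` or `"txt"`.
#' @return A single string (with embedded newlines).
#' @export
format_report <- function(report, style = c("tsv", "txt")) {
  style <- match.arg(style)
  if (!inherits(report, "screen_report")) stop_args("report must be a screen_report")
  if (style == "tsv") {
    df <- report_tsv_rows(report)
    con <- textConnection("out", "w", local = TRUE)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
    close(con)
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }
  p <- report$parameters
  lines <- c(
    sprintf("Screen report: query %s (%d aa) vs database '%s' (%d entries, %d residues)",
            report$query_accession, report$query_length, report$db_version_label,
            p$db_size, p$db_residues),
    sprintf("Parameters: %s, gap %d/%d, E<=%g, window %d (identity > %g), k-mer %d; modes: %s",
            p$matrix, p$gap_open, p$gap_extend, p$e_threshold, p$window,
            p$identity_threshold, p$kmer, paste(p$modes, collapse = ",")),
    sprintf("Full-length hits (E <= %g): %d%s", p$e_threshold,
            length(report$full_hits),
            if (length(report$full_hits)) {
              top <- report$full_hits[[1]]
              sprintf(" (best: %s, score %d, identity %.1f%%, E = %.3g)",
                      top$subject_accession, top$alignment$score,
                      100 * top$alignment$identity_fraction, top$evalue)
            } else ""),
    sprintf("Window hits (> %g%% identity over >= %d aa): %d",
            100 * p$identity_threshold, p$window, length(report$window_hits)),
    sprintf("8-mer exact matches: %d (high false-positive rate; interpret with caution)",
            if (is.null(report$kmer_hits)) 0L else nrow(report$kmer_hits)),
    sprintf("Flags: full=%s window=%s kmer=%s",
            report$any_full_hit_below_threshold, report$any_window_hit,
            report$any_kmer_hit))
  paste0(paste(lines, collapse = "\n"), "\n")
}
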