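# Independent oracles used across the suite. These deliberately use
# different algorithmic formulations from the package code paths they check.

# Optimal *global* affine-gap alignment score of two residue vectors, by
# plain recursion over column choices with memoisation on (i, j, previous
# column state). End gaps are penalised like internal ones.
oracle_global_affine <- function(qa, sa, mat, open, ext) {
  la <- length(qa); lb <- length(sa)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(i, j, prev) {
    key <- paste0(i, ",", j, ",", prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (i > la && j > lb) {
      val <- 0
    } else {
      opts <- numeric()
      if (i <= la && j <= lb)
        opts <- c(opts, mat[qa[i], sa[j]] + rec(i + 1L, j + 1L, "M"))
      if (j <= lb)
        opts <- c(opts, (if (prev == "E") ext else open) + rec(i, j + 1L, "E"))
      if (i <= la)
        opts <- c(opts, (if (prev == "F") ext else open) + rec(i + 1L, j, "F"))
      val <- max(opts)
    }
    memo[[key]] <- val
    val
  }
  rec(1L, 1L, "S")
}

# Exhaustive local oracle: the best local alignment score is the maximum,
# over every pair of substrings (plus the empty alignment, score 0), of the
# optimal global alignment score of that substring pair.
oracle_local_score <- function(q, s, mat, open, ext) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  best <- 0
  for (i1 in seq_along(qc)) for (i2 in i1:length(qc))
    for (j1 in seq_along(sc)) for (j2 in j1:length(sc))
      best <- max(best, oracle_global_affine(qc[i1:i2], sc[j1:j2], mat, open, ext))
  best
}

# Pure enumeration (no memoisation, no maximisation inside the recursion):
# the scores of *every* complete gapped alignment of two residue vectors.
# Used on tiny inputs to validate oracle_global_affine itself.
enumerate_alignment_scores <- function(qa, sa, mat, open, ext) {
  la <- length(qa); lb <- length(sa)
  rec <- function(i, j, prev) {
    if (i > la && j > lb) return(0)
    out <- numeric()
    if (i <= la && j <= lb)
      out <- c(out, mat[qa[i], sa[j]] + rec(i + 1L, j + 1L, "M"))
    if (j <= lb)
      out <- c(out, (if (prev == "E") ext else open) + rec(i, j + 1L, "E"))
    if (i <= la)
      out <- c(out, (if (prev == "F") ext else open) + rec(i + 1L, j, "F"))
    out
  }
  rec(1L, 1L, "S")
}

# Naive O(n*m) substring scan: every exact k-mer match by direct comparison.
naive_kmer_scan <- function(query, db, k = 8L) {
  if (inherits(query, "sequence_record")) query <- query$sequence
  empty <- data.frame(query_pos = integer(), subject_accession = character(),
                      subject_pos = integer(), kmer = character(),
                      stringsAsFactors = FALSE)
  qlen <- nchar(query)
  if (qlen < k) return(empty)
  res <- list()
  for (qp in 1:(qlen - k + 1)) {
    w <- substr(query, qp, qp + k - 1)
    if (grepl("[BZXUJO]", w)) next
    for (r in db) {
      if (r$length < k) next
      for (sp in 1:(r$length - k + 1)) {
        if (substr(r$sequence, sp, sp + k - 1) == w)
          res[[length(res) + 1L]] <- data.frame(
            query_pos = qp, subject_accession = r$accession,
            subject_pos = sp, kmer = w, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$query_pos, out$subject_accession, out$subject_pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Position-by-position identity recount of a gap-free pair of strings.
recount_identities <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  sum(ac == bc & ac != "X")
}

# Identity recount over the columns of a returned alignment.
recount_alignment <- function(aln) {
  qc <- strsplit(aln$q_aligned, "")[[1]]
  sc <- strsplit(aln$s_aligned, "")[[1]]
  list(n_columns = length(qc),
       n_identities = sum(qc == sc & qc != "-" & qc != "X"))
}

random_protein <- function(len, alphabet = c("A", "R", "N", "D", "C", "Q",
                                             "E", "G", "H", "I", "L", "K",
                                             "M", "F", "P", "S", "T", "W",
                                             "Y", "V")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
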