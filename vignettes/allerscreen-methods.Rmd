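---
title: "Methods: screening, triage and curation in allerscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, triage and curation in allerscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allerscreen)
```

`allerscreen` implements the computational workflow behind a curated
allergen sequence resource: screening query proteins against an allergen
database under FAO/WHO–Codex-style similarity rules, triaging annotated
protein records into review candidates, and managing versioned, auditable
database releases. This vignette records the models, the parameters that
matter, and the design decisions taken where practice leaves room, so that
results can be interpreted — and contested — precisely.

## The alignment model

All screening modes rest on exact Smith–Waterman local alignment with
affine gaps, implemented in compiled code. We deliberately use the exact
algorithm rather than a heuristic seeded search (the FASTA/BLAST family):
at database scales of a few thousand allergens the exact DP is affordable,
it is deterministic, and it is strictly more sensitive than any heuristic —
a screen whose purpose is to *not miss* potential cross-reactivity should
not trade sensitivity for speed it does not need. The cost of that choice
is that scores are not bit-for-bit identical to any particular FASTA
release; they are the alignments FASTA's heuristics approximate.

Scoring parameters (`align_params()`):

* `matrix_name` — substitution matrix; default **BLOSUM50**, with BLOSUM62
  also bundled (NCBI text format, readable via `read_score_matrix()` for
  custom matrices). BLOSUM50 with the gap penalties below mirrors the
  customary protein-search setup of the FASTA package.
* `gap_open = -10`, `gap_extend = -2` (score units per residue): a gap of
  length $k$ costs $g_{open} + (k-1)\,g_{ext}$. The invariant
  `gap_open <= gap_extend < 0` is enforced.
* `ka_lambda`, `ka_k` — Karlin–Altschul parameters for the E-value
  $E = K\,m\,n\,e^{-\lambda S}$, where $m$ is the query length and $n$ the
  summed residue count of the database. Defaults are the standard
  *ungapped* values for each matrix (BLOSUM50: $\lambda = 0.232$,
  $K = 0.11$; BLOSUM62: $\lambda = 0.318$, $K = 0.13$). Using the ungapped
  closed form rather than an empirically regressed gapped correction is an
  approximation: reported E-values are conservative ranking devices, not
  calibrated p-values, and the screen's decisive criteria (the window rule,
  the 8-mer rule) do not depend on them.

Numerical and degenerate-input choices:

* If no residue pairing scores above zero (e.g. `AAAA` vs `CCCC` under
  BLOSUM50), the aligner returns an *empty alignment* — score 0,
  `n_columns = 0` — flagged as "no similarity". Percent identity is
  undefined there and asking for it is an error rather than a silent 0 or 1.
* **Tie-breaking.** Equal-scoring optima are resolved deterministically:
  all maximal-score end cells are traced back (within a traceback,
  diagonal moves are preferred, then subject-gap, then query-gap, and gap
  closure over extension) and the alignment with the lexicographically
  smallest `(q_start, s_start, n_columns, q_end, s_end)` is returned. Two
  runs on the same input always produce the same alignment.
* **Ambiguity letters.** Sequences may contain B, Z, X, U, J, O on input.
  X scores whatever the matrix's X row assigns (−1 in BLOSUM50) and — the
  important choice — **never counts as an identity, even X against X**.
  Masked or unknown regions must not inflate a percent-identity that can
  trigger a regulatory flag. U, J and O are accepted by the parsers but are
  absent from the BLOSUM tables, so aligning them is an explicit error
  rather than a silent substitution.
* Percent identity divides identities by **all** alignment columns,
  including gap columns. This is the conservative reading (gaps can only
  lower identity, never raise it); the denominator choice matters exactly
  at threshold boundaries, so it is fixed and documented rather than left
  to the aligner's default.

## The three screening modes

`run_screen()` aggregates three searches, each independently switchable
(`modes`), into one report with a parameter snapshot sufficient to
reproduce the run.

1. **Full-length search** (`fullseq_search()`): the whole query against
   every database entry, results filtered by `e_threshold` (default 1.0 —
   deliberately permissive, and user-settable, since this mode is
   exploratory rather than decision-bearing) and sorted by ascending
   E-value, ties by descending score, then accession.
2. **Sliding-window scan** (`window_scan()`): every overlapping 80-residue
   window (starts 1 … L−79) is locally aligned against every full subject
   sequence; the window need not align end-to-end. A window is a **hit**
   when identity is strictly greater than `identity_threshold` (0.35) over
   at least 80 aligned columns. Two boundary decisions deserve emphasis:
   * *Strictness*: 28 identities over 80 columns is exactly 35% and is
     **not** a hit; 29/80 (36.25%) is. The guideline text says "greater
     than 35%", and the tests pin the boundary from both sides.
   * *Identity base*: identity is computed over the alignment's columns,
     not over the fixed 80 window positions. Where the two differ (gapped
     alignments), the column basis is the one consistent with how percent
     identity is defined everywhere else in the package; the
     `n_columns >= 80` requirement prevents short high-identity fragments
     from slipping under the rule.
   * *Short queries* (< 80 aa): practice guidance is silent; silently
     dropping them would be the one unforgivable behaviour. They are
     screened as a single whole-sequence window with the span requirement
     scaled to the query length, and every such hit is flagged `short` so
     downstream users know it falls outside the literal 80-aa rule.
3. **8-mer exact match** (`build_kmer_index()` + `kmer_scan()`): every
   position where eight contiguous residues match exactly. Words containing
   ambiguity letters are excluded from both index and query — an X is not
   an *exact* residue. The report labels this mode with its known caveat
   (high false-positive rate); it is included for guideline completeness,
   not because it discriminates well.

## The candidate triage filter

Records arriving from broad retrieval (`primary_query()`: any text field
containing an `allerg`-prefixed token, matched at word starts to mirror
Entrez-style stemming of `allerg*`, optionally restricted by entry-date
window and taxonomy group) are partitioned by an ordered rule engine.

Rules are **data, not code** (`filter_rule()`, `read_ruleset()` /
`write_ruleset()`): each has a step index, a field selector, a match kind
(substring, word-start prefix, whole-word keyword list, regex, date range,
taxa set), a polarity, and an action. Evaluation is first-decisive-rule:
`EXCLUDE` and `CANDIDATE` halt, `CONTINUE` passes on, and a record that
exhausts the rules receives the default action.

The shipped `default_ruleset()` is a documented **reconstruction** of the
production filter's described categories — the verbatim production rule
set (13 steps, 28 elements) is not public, so the package encodes the
categories it is known to cover: automated-pipeline provenance is
excluded; `allerg*` in the definition line marks a candidate; specific
allergen designations (profilin, tropomyosin, parvalbumin, …;
`default_allergen_keywords()`, configurable) mark candidates; an `allerg*`
term appearing only in a clinical-context note unrelated to the protein
itself is excluded. The default terminal action is **CANDIDATE**
(fail-open): a triage step should rather forward a doubtful record to
human review than silently omit a potential allergen. That asymmetry also
yields a testable monotonicity property — removing any EXCLUDE rule can
never shrink the candidate set.

## Curation, evidence rules and releases

The evidence model distils the published inclusion/exclusion criteria into
machine-checkable structure plus a controlled decision vocabulary:

* `validate_entry()` checks what structure *can* check: stored length
  equals residue count; entries adopted 2017 or later carry at least one
  supporting publication (the imported pre-2017 foundational entries are
  exempt, matching how the resource was seeded); mass-spectrometry
  peptide entries are at least 10 residues; sequences use the accepted
  alphabet. Violations are returned as data, not thrown.
* `record_decision()` enforces the decision grammar: an ACCEPT must carry
  `IGE_BINDING_EVIDENCE` (the minimum inclusion criterion); a REJECT must
  carry at least one exclusion code (`NO_NEGATIVE_CONTROL`,
  `INSUFFICIENT_PURITY`, `CCD_ONLY_BINDING`, `HOMOLOGY_ONLY`,
  `SEQUENCE_MISMATCH`). The ledger is append-only; a rejected accession may
  be revisited in a later cycle with both decisions retained. Scientific
  judgment itself is out of scope — the package records decisions, it does
  not make them.
* `build_release()` is **base-preserving**: entries of the base release are
  never removed or modified, new accepted entries are stamped with the
  version label (historic screening additions get an `H` suffix, `H_MS`
  for peptide fragments), metadata amendment of an existing accession
  requires an explicit flag, and a duplicate accession without it is a
  conflict. `diff_releases()` reports added/removed accessions and
  field-level changes on shared ones; what counts as a *material* change is
  left to the operator, the diff just surfaces every differing field.
* Exports: FASTA plus the standard eight-column metadata table (Species,
  Common Name, Description, IUIS Name, Accession, Length, Year Adopted,
  Parent Accession), mutually consistent by accession and length, and a
  transparency TSV with one row per review decision. The exchange format
  does not carry literature lists, so re-imported entries skip the
  reference rule (`check_references = FALSE` in the CLI build path) — a
  deliberate format limitation, noted rather than hidden.

The annotated-record flat file is a minimal line-keyed dialect (keys
`ACCESSION`, `DEFINITION`, `ORGANISM`, `TAXGROUP`, `DATE` in ISO-8601,
`SOURCETAG`, repeatable `NOTE`, `SEQUENCE`; blocks end with `//`). It
carries exactly the fields the filter inspects — a full GenPept/UniProt
grammar is a non-goal.

## Synthetic data: what it emulates and what it does not

All tests run on generated data (`fixture_spec()` and friends), seeded and
byte-reproducible (R's Mersenne–Twister stream, state saved and restored
around every generator call).

* `make_db()` draws i.i.d. uniform residues over the 20 standard amino
  acids, lengths uniform over a range. The default study conditions used
  by the acceptance checks are 50 entries of 90–400 residues — large
  enough that every entry exercises the window machinery (L ≥ 90 > 80)
  with realistic protein lengths, small enough that a full 50×50
  three-mode self-screen runs in minutes on one CPU.
* `make_annotated_records()` plants exactly one triage category's textual
  features per record (pipeline tag, definition-line `allerg*`, designation
  keyword, clinical-context note, or nothing), returning ground-truth
  labels alongside. Because categories are planted disjointly, the default
  rule set reproduces the ground truth *by construction* — which is
  precisely what makes the generator a specification of the engine's
  semantics rather than a hard benchmark.
* `implant_homolog()` builds variants with an exact identity count against
  a base region. Substituted positions receive the highest-scoring
  non-identical standard residue under BLOSUM50 (ties alphabetical), and
  for `n_identical >= 2` the region's first and last positions are kept
  identical. Both choices serve one purpose: the full gap-free 80-column
  alignment is also the *optimal local* alignment, so a 28/80 implant
  really presents the aligner with an exactly-35% decision instead of
  letting it trim low-scoring ends into a shorter, unrepresentative
  alignment.

What passing these tests does **not** show: real protein families are not
i.i.d. sequences (domain structure, low-complexity regions and shared
ancestry make both false positives and near-threshold cases more common
than in uniform noise); real annotation text is messier than the planted
categories (the shipped rule set is a reconstruction, and production use
should drop in a curated rule file); and E-values on small synthetic
databases are ranking devices only. The oracle-equivalence results, the
boundary strictness, the count laws and the round-trip guarantees, by
contrast, are exact properties and transfer to any input.

## Problem sizes and verification strategy

The suite verifies the aligner against an exhaustive oracle — the maximum
over all substring pairs of an independently computed optimal global
affine alignment — on 200 random pairs of length ≤ 6 over a four-letter
alphabet (the oracle itself is validated against a pure enumeration of all
alignments on even smaller cases), and against an independent established
aligner on longer random pairs. The self-screen law suite uses the
50-entry database above; the k-mer scan is compared with a naive
quadratic substring scan on 100 random instances; the filter is scored on
500 planted records. `scripts/acceptance.R` recomputes all of these from
scratch with a caller-supplied seed.

## Known limitations

* No heuristic acceleration: screening very large query sets is linear in
  total DP cells; the design target is database-scale (thousands of
  entries), not proteome-scale all-vs-all.
* Ungapped E-value statistics (see above).
* The default triage rule set is a faithful reconstruction of described
  categories, not the verbatim production filter; rule files exist so the
  latter can be supplied when available.
* The curation layer models decision *records*, not literature retrieval
  or reviewer judgment; IUIS nomenclature is stored, not assigned.
* Translated/nucleotide queries, web services and visualisation are out of
  scope.
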