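# allerscreen

Sequence-based allergenicity screening, record triage and curated-database
release tooling, in one R package.

Safety assessment of novel food and feed proteins (for example proteins
introduced into genetically modified crops) requires comparing a query
protein against a database of known allergens, following FAO/WHO and Codex
Alimentarius guidance. Building and maintaining such a database is itself a
bioinformatics problem: public protein repositories are dominated by
automatically annotated entries, so candidate allergen records must be
retrieved broadly, triaged by keyword rules, reviewed against evidence
criteria (peer-reviewed IgE-binding data), and published as versioned,
diffable releases with a transparent decision trail. `allerscreen`
implements both halves of that workflow for regulatory scientists,
bioinformaticians supporting allergenicity dossiers, and database curators.

## What it computes

**Three-mode screening engine.** A query protein `q` is compared with every
allergen `s` in a database:

1. *Full-length search.* Exact Smith–Waterman local alignment under an
   affine gap model: with substitution matrix `M` (BLOSUM50 by default) and
   gap penalties `g_open = -10`, `g_ext = -2` (a gap of length `k` costs
   `g_open + (k-1) g_ext`), the DP recurrences

   ```
   H(i,j) = max{ 0, H(i-1,j-1) + M(q_i, s_j), E(i,j), F(i,j) }
   E(i,j) = max{ H(i,j-1) + g_open, E(i,j-1) + g_ext }
   F(i,j) = max{ H(i-1,j) + g_open, F(i-1,j) + g_ext }
   ```

   give the optimal local score `S = max H`. Hits are ranked by the
   Karlin–Altschul expectation `E = K m n exp(-λS)` with a user-settable
   threshold (default 1.0).
2. *80-aa sliding window.* Every overlapping 80-residue fragment of the
   query is aligned against every database entry; an alignment is a hit
   when identity is **strictly greater than 35%** over **at least 80
   aligned columns** (gap columns count in the denominator) — the
   Codex-derived cross-reactivity criterion. Queries shorter than 80
   residues are screened as one whole-sequence window, flagged as falling
   outside the 80-aa rule.
3. *8-mer exact match.* Every identical stretch of eight contiguous amino
   acids shared with any database entry, found through a k-mer index.
   Reported for guideline completeness; this criterion is known for high
   false-positive rates.

**Candidate triage.** A configurable, ordered rule engine
(`default_ruleset()`, `apply_filter()`) partitions annotated protein
records into allergen candidates and excluded entries with full provenance
of which rule fired, plus the broad `allerg*` primary query and a
supplemental allergen-designation keyword search (profilin, tropomyosin,
...).

**Curation and releases.** Entry validation against evidence criteria
(supporting publication required for reviewed entries, a 10-residue floor
for mass-spectrometry peptides), an append-only peer-review decision ledger
with a controlled criteria vocabulary, base-preserving versioned release
construction (historic additions labelled `H` / `H_MS`), field-level
release diffs, and FASTA + metadata-table + transparency exports.

**Synthetic fixtures.** Deterministic generators (`make_db()`,
`make_annotated_records()`, `implant_homolog()`) produce databases,
annotated records with planted triage categories, and homolog pairs with
exact identity counts — every test surface is generated in code.

## Worked example

```r
library(allerscreen)

db    <- make_db(fixture_spec(seed = 11, n_entries = 6, length_range = c(100, 160)))
query <- sequence_record("QUERY1", implant_homolog(db[[2]]$sequence, 40, 100, seed = 3))
rep   <- run_screen(query, db, screen_config(db_label = "demo-db"))
cat(format_report(rep, "txt"))
```

```
Screen report: query QUERY1 (100 aa) vs database 'demo-db' (6 entries, 832 residues)
Parameters: BLOSUM50, gap -10/-2, E<=1, window 80 (identity > 0.35), k-mer 8; modes: full,window,kmer
Full-length hits (E <= 1): 4 (best: SYN000002, score 430, identity 40.0%, E = 4.33e-40)
Window hits (> 35% identity over >= 80 aa): 10
8-mer exact matches: 0 (high false-positive rate; interpret with caution)
Flags: full=TRUE window=TRUE kmer=FALSE
```

The query is a synthetic homolog carrying 40 identities over 100 positions
of database entry `SYN000002`. The full-length search finds that entry at
rank 1 (40% identity, E = 4.3e-40 — far below the threshold, i.e. not
expected by chance); ten of the 21 query windows exceed the strict 35%/80-aa
cross-reactivity rule, so the protein would be flagged for further
evaluation; no eight-residue stretch is perfectly conserved, so the 8-mer
screen raises nothing. `format_report(rep, "tsv")` renders the same hits as
a fixed-column table, one row per hit.

The same run is available from a shell via the bundled executable:

```sh
Rscript exec/allerscreen screen --query query.fasta --db allergens.fasta \
    --db-label demo-db --out report.tsv
```

(`exec/allerscreen --help` lists the `screen`, `filter`, `fixtures`,
`release` and `validate` subcommands.)

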