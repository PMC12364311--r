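---
title: "Methods: from raw primary-care extracts to analysis-ready variables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw primary-care extracts to analysis-ready variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

CPRD Aurum-style primary-care extracts arrive as thousands of tab-delimited
`.txt` files — patient registration files plus multi-part observation
(diagnoses and tests, keyed by `medcodeid`) and drug-issue files
(prescriptions, keyed by `prodcodeid`) — far too large to read into memory
at once. The files follow the naming convention
`<prefix>_setX_extract_<filetype>_0Y.txt`: `setX` partitions the patients
into batches, and every medical file carries the set token of the patients
it describes.

`aurumehr` turns such an extract into an analysis-ready dataset (one row per
cohort patient, one column per derived variable) in four stages:

1. **Cohort**: concatenate the patient files (`extract_cohort()`), apply the
   study's inclusion criteria as ordinary table filtering, and attach a
   per-patient index date (`assign_index_dates()`).
2. **Store**: bulk-load the observation/drugissue files for those patients
   into a single-file SQLite database (`cprd_extract()` /
   `add_to_database()`), stored on disk and queried from there.
3. **Variables**: query the store by codelist and reduce the matches to
   per-patient variables relative to the index date (`extract_ho()`,
   `extract_time_until()`, `extract_test_data()`, the phenotype functions).
4. **Assemble**: merge the variable tables on `patid`.

All downstream semantics are *index-date relative*: each variable is defined
by a window around each patient's `indexdt`, so the same machinery serves
baseline extraction and longitudinal extraction (via the `t` offset, which
shifts every window `t` days forward and is embedded in saved filenames).

## Conventions that decide edge cases

These choices are applied identically everywhere — in particular in both the
SQLite-backed extraction path and the brute-force raw-file oracle — so the
equivalence tests between the two are meaningful.

* **Window inclusivity.** All windows
  `[indexdt + t - time_prev, indexdt + t + time_post]` are closed on both
  ends. "History of" means a record dated **on or before** the (offset)
  index date: a diagnosis recorded on the day of cohort entry counts as
  history.
* **Time-to-event strictness.** `extract_time_until()` counts the first
  event **strictly after** `indexdt + t`, so survival times are always
  positive; events after the censoring date `censdt` are ignored and the
  patient contributes `(censdt - indexdt - t, 0)`. A record exactly on the
  index date therefore counts for history but not as an event — "history"
  stays maximal while zero survival times cannot occur.
* **"Most recent" ties.** Among records sharing the most recent date, test
  queries prefer the higher value; otherwise stable input order decides.
  Deterministic by construction.
* **Fewer rows than `numobs`**: return what exists, no padding.
* **Dates.** Raw files carry `dd/mm/yyyy` (the UK source convention);
  ISO-8601 is also accepted, and ambiguous strings resolve as `dd/mm/yyyy`.
  Unparseable cells become `NA` under a *counted warning*, never an error —
  one corrupt cell must not abort a multi-hour ingest. Inside the store,
  dates are ISO-8601 text, which sorts lexicographically in date order.
* **Identifiers are text.** `patid`/`medcodeid`/`prodcodeid` routinely
  exceed 2^53, so they are never held as numbers.
* **Duplicate patids** across patient files are an error, not a silent
  de-duplication: they indicate a malformed delivery.

## The store

The store is a plain SQLite file with one table per file type, no
constraints and (by default) no indexes — appends stay cheap and query time
scales linearly with table size. `cprd_extract()` orders files
deterministically by (set, part, name), ingests the first with overwrite and
the rest with append, so re-running it rebuilds the table identically
instead of double-loading. Files are read in chunks (default 10^6 rows) so
a file larger than memory streams through. `rm_duplicates = TRUE`
de-duplicates **globally across the whole extract** (exact equality on all
stored columns) by rebuilding the table with `SELECT DISTINCT` after the
load; per-file de-duplication would miss rows duplicated *between* parts.
An optional `build_index` flag adds a (patid, code) index after loading,
for workloads that will query the same table many times.

When the cohort is large, filtering every row against millions of patids is
the bottleneck. The *set fast path* exploits the file naming: pass
`subset_patids` as a data frame of (`patid`, `set`) — obtained from
`extract_cohort(..., set = TRUE)` — and a file carrying the `setX` token is
filtered only against the patids of set X. The result is required (and
tested) to be byte-identical to the plain filter.

## The synthetic generator and what it does (not) show

No real data can ship with the package, so `generate_fixture()` and
`generate_study()` emulate the extract format. Cell values follow a
deliberately minimal recipe: numeric variables are uniform integers 1–100,
dates uniform in [1900-01-01, 2000-01-01], gender 1 or 2, year of birth
1900–2000, IDs sequential. The default fixture is 12 patients across two
patient files (set1: patients 1–8, set2: 9–12) with three observation and
three drugissue parts, all set1 — the layout used throughout the examples.

`generate_study()` adds known ground truth: for each code with prevalence
*p*, each patient independently receives at least one record of that code
dated strictly before the study index date with probability *p*; remaining
records carry background codes disjoint from the prevalence map. The
per-patient flags are written to a `truth.csv` sidecar. This supports two
kinds of end-to-end check: *oracle equivalence* (store-backed `extract_ho()`
must equal both the brute-force raw-file loop and the sidecar, patient by
patient) and *prevalence recovery* (the mean extracted flag must fall inside
the 99% binomial band of *p*; at n = 5000 and p = 0.10 that band is
[0.0892, 0.1110]).

What passing these tests shows: the plumbing — naming, parsing, filtering,
storage, windowing, flagging — is faithful end to end. What it does not
show: robustness to clinically realistic code distributions, visit-driven
date clustering, unit heterogeneity or missingness patterns of real primary
care data; the generator makes no attempt to mimic those.

## The brute-force oracle

`brute_force_history()` recomputes history flags the way one would without a
database: initialise a zero vector over the cohort; loop over every raw
observation file; parse `obsdate`; subset to the codelist; merge with the
cohort and drop records after the index date; flag patients with a
surviving record. It shares no code with the store path beyond the file
reader, which is exactly what makes the equivalence test informative.

## Phenotype algorithms

Four variables need more than a windowed query. In all of them the search
window defaults to the five years up to the index date (`time_prev = 1825`,
`time_post = 0`) — a conventional "current value" horizon for slowly-moving
measurements; both are arguments.

* **BMI** is either recorded directly or derived as weight / height² from
  the most recent in-window weight and height. Heights whose `numunitid` is
  in a configurable centimetre set — or exceeding 3 after mapping (no adult
  is 3 m tall) — are divided by 100. The licensed unit lookup cannot be
  shipped, hence the configurable mapping plus heuristic. Each candidate is
  governed by a date (direct: its own; derived: the **later** of the two
  component dates, the earliest time the pair was knowable); the most
  recent governing date wins and ties go to the direct record, a recorded
  BMI being assumed more reliable than a reconstruction. Non-positive
  heights are skipped with a counted warning.
* **Cholesterol/HDL ratio**: same candidate logic with total/HDL; a zero
  HDL invalidates the derived candidate rather than dividing.
* **Diabetes status**: generic "diabetes mellitus" codes belong in the
  type 2 list; any pre-index type 1 code yields `type1` (a specific type 1
  code overrides the generic assumption), else any type 2/generic code
  yields `type2`, else `Absent`.
* **Smoking status**: five codelists (non/ex/light/moderate/heavy). The
  status is that of the most recent pre-index record; a most-recent
  non-smoker with any earlier smoking record is reclassified `Ex-smoker` —
  a quitter, not a never-smoker. Same-day ties resolve to the heavier
  category (deterministic); a code appearing in two categories is an error,
  since the categories must partition the codes. No records at all yields
  `NA` rather than a guessed category.

Phenotype definitions legitimately vary between studies; these functions
implement one defensible rule set and expose the pieces (`db_query()`,
`combine_query()`) from which alternatives are built.

## Workspace conventions

`create_directory_system()` creates `data/sql/` (stores, referable by bare
name via the `db` argument with the connection lifecycle handled
internally), `codelists/analysis/` (CSV codelists with a `medcodeid`,
`prodcodeid` or `ICD10` column, referable by name), and `data/extraction/`
(saved variables, `var_<varname>[_t<offset>].csv`). Precedence when a
codelist is supplied several ways: vector > data frame > name. Everything
resolves relative to one `root` argument rather than the process working
directory, so analyses move between machines without path edits. Variables
are saved as CSV — a portable, diffable serialization of the same
per-patient tables.

## Problem sizes used in the checks

The shipped test suite and acceptance script size their simulations to run
comfortably on one CPU: the 12-patient fixture for layout checks; 2000
patients × ~50 observations for the oracle-equivalence study; 5000
patients for prevalence recovery; 1000 patients × 6000 observations for
the windowed-test comparisons. These are the package's own choices of
desk-scale study conditions; the mechanisms they exercise (chunked ingest,
set-wise filtering, SQL-side code matching) are the same ones that carry
the workflow to full-size extracts.

## Known limitations

* Real-extract column inventories are licence-gated; readers type only the
  columns the toolkit consumes and pass everything else through verbatim,
  with the referral/problem/consultation readers taking a configurable
  date-column list.
* The `numunitid` → unit mapping ships as a small default table plus
  heuristic, not the licensed lookup.
* Linked hospital/death files can be ingested (`hes_primary`, `death`
  file types) but variable extraction from them is left to user functions,
  as those files are small enough to handle in memory.
* Single-writer use only: no concurrent ingest, no schema migration. The
  store must live on storage that meets the data provider's security
  requirements.
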