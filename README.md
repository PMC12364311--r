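# aurumehr

Build analysis-ready datasets from CPRD Aurum-style primary-care extracts.

UK primary-care extracts in the Aurum dialect arrive as thousands of
tab-delimited `.txt` files — patient registration files plus multi-part
observation files (diagnoses and test results, keyed by `medcodeid`) and
drug-issue files (prescriptions, keyed by `prodcodeid`), named
`<prefix>_setX_extract_<filetype>_0Y.txt`. At tens of millions of patients
the raw data cannot be held in memory, and every research group otherwise
rebuilds the same plumbing to query it. `aurumehr` is for the
statisticians and epidemiologists doing that work: it loads the relevant
files into an on-disk SQLite store and derives per-patient variables from
codelist queries, entirely from R, with no SQL required.

Every variable is defined **relative to a per-patient index date**
`indexdt`: a record in the closed window
`[indexdt + t − time_prev, indexdt + t + time_post]` qualifies, where the
offset `t` (default 0) supports longitudinal extraction at fixed intervals.
The built-in variable types are:

| Function | Variable |
| --- | --- |
| `extract_ho()` | 0/1 history of a coded condition or prescription on/before the index date |
| `extract_time_until()` | time to first event strictly after the index date, with censoring indicator |
| `extract_test_data()` | most recent `numobs` valid test values in a window and value range |
| `extract_test_data_var()` | sample SD of all valid in-window test values |
| `extract_bmi()`, `extract_cholhdl_ratio()` | direct record vs most-recent-component derivation (with cm→m height conversion) |
| `extract_diabetes()`, `extract_smoking()` | rule-based categorical phenotypes |

Underneath sit general building blocks — `db_query()`,
`combine_query()`, `combine_query_boolean()` — for rolling your own
variables, and a synthetic-data module (`generate_fixture()`,
`generate_study()`) that emulates the extract format with known ground
truth, so the whole pipeline is testable without access to real data.
`brute_force_history()` recomputes history flags by looping over the raw
files directly and serves as an independent oracle for the store-backed
path.

## Worked example

```r
library(aurumehr)

# a 12-patient synthetic extract: two patient files (set1/set2),
# three observation and three drugissue parts
raw_dir <- file.path(tempdir(), "demo_extract")
man <- generate_fixture(raw_dir, seed = 101)
man$files[, c("filename", "n_rows")]
#>                                           filename n_rows
#> 1:     aurum_allpatid_set1_extract_patient_001.txt      8
#> 2: aurum_allpatid_set1_extract_observation_001.txt     20
#> 3:   aurum_allpatid_set1_extract_drugissue_001.txt     20
#> 4: aurum_allpatid_set1_extract_observation_002.txt     20
#> 5:   aurum_allpatid_set1_extract_drugissue_002.txt     20
#> 6: aurum_allpatid_set1_extract_observation_003.txt     20
#> 7:   aurum_allpatid_set1_extract_drugissue_003.txt     20
#> 8:     aurum_allpatid_set2_extract_patient_001.txt      4

# cohort: the patients meeting the (hypothetical) inclusion criteria,
# with a fixed index date
cohort <- extract_cohort(raw_dir, patids = c("1", "3", "4", "6"))
cohort <- assign_index_dates(cohort, fixed_date = "2005-01-01")
cohort[, c("patid", "gender", "yob", "indexdt")]
#>     patid gender   yob    indexdt
#> 1:      1      2  1944 2005-01-01
#> 2:      3      1  1969 2005-01-01
#> 3:      4      1  1989 2005-01-01
#> 4:      6      2  1963 2005-01-01

# load their medical and prescription data into a SQLite store
store <- connect_database(file.path(tempdir(), "demo.sqlite"))
cprd_extract(store, raw_dir, "observation", subset_patids = cohort$patid)
cprd_extract(store, raw_dir, "drugissue",  subset_patids = cohort$patid)
list_tables(store)
#> [1] "drugissue"   "observation"

# codelist query: every stored record bearing one medcodeid
db_query(codelist_vector = "187341000000114", store = store)[,
  c("patid", "medcodeid", "obsdate", "value")]
#>     patid       medcodeid    obsdate value
#> 1:      3 187341000000114 1987-12-15    12
#> 2:      4 187341000000114 1946-02-17    25

# history-of variable: 1 iff a matching record on/before the index date
extract_ho(cohort, codelist_vector = "187341000000114", store = store,
           varname = "ho_example")
#>     patid ho_example
#> 1:      1          0
#> 2:      3          1
#> 3:      4          1
#> 4:      6          0
close_database(store)
```

Patients 3 and 4 have a pre-index record of the queried code, so their
history flag is 1; patients 1 and 6 have none, so 0. Merging such variable
tables on `patid` yields the analysis-ready dataset.

For large cohorts, pass `subset_patids` as a data frame of
(`patid`, `set`) from `extract_cohort(..., set = TRUE)`: each file is then
filtered only against the patids of its own set, with identical results.
`create_directory_system()` sets up a workspace (`data/sql/`,
`codelists/analysis/`, `data/extraction/`) in which stores and codelists
are referred to by bare name and extracted variables are saved to disk. The
methods vignette (`vignettes/aurumehr-methods.Rmd`) documents the
conventions — window inclusivity, tie-breaking, date parsing, the phenotype
rules — and their rationale.

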