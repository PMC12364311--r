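Package: aurumehr
Title: Build Analysis-Ready Datasets from CPRD Aurum-Style Primary Care Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning raw CPRD Aurum-structured primary-care extracts
    (large collections of delimited text files) into analysis-ready per-patient
    datasets. Provides cohort construction from patient files, bulk ingest of
    observation and prescription files into an on-disk SQLite store, codelist-driven
    queries, and index-date-relative variable extraction: history-of flags,
    time-to-event variables, windowed test values, and phenotype algorithms for
    BMI, cholesterol/HDL ratio, diabetes status and smoking status. A synthetic
    data generator emulates the Aurum file layout so the whole pipeline is testable
    without access to real data, and a brute-force raw-file scan acts as an
    independent oracle for the database-backed extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    DBI,
    RSQLite,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
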