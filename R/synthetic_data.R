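#' Generate the small worked-example fixture
#'
#' Writes an Aurum-shaped raw file tree for a handful of fake patients:
#' patient files split across sets, plus multi-part observation and drugissue
#' files. The default layout mirrors the package's worked example — 12
#' patients across two patient files (set1 holding patients 1–8, set2 holding
#' 9–12) with three observation and three drugissue parts, all for set1.
#'
#' Simulated cell values follow a deliberately simple recipe: numeric
#' variables are uniform integers 1–100, dates uniform between 1900-01-01 and
#' 2000-01-01, gender 1 or 2, year of birth 1900–2000, and patient/practice
#' IDs are assigned sequentially. Medical codes are drawn from a small fixed
#' pool so codelist queries on the fixture have known answers.
#'
#' @param out_dir Directory to write into (created if absent).
#' @param n_patients Number of fake patients (default 12).
#' @param patient_sets Integer vector of length `n_patients` assigning each
#'   patient (in patid order) to a set; every patient must belong to exactly
#'   one set. Default: first 8 to set 1, remainder to set 2.
#' @param parts_per_type Named integer vector: for each set (name) the number
#'   of observation and drugissue parts to write. Sets absent from the names
#'   get patient files only. Default: 3 parts for set 1 only.
#' @param rows_per_part Data rows per observation/drugissue part (default 20).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param prefix Filename prefix (default `"aurum_allpatid"`).
#' @param delimiter Field delimiter for the written files (default tab).
#' @param pad Zero-padding width of the part number (default 3).
#'
#' @return A fixture manifest: list with `root_dir`, `seed`, and a `files`
#'   data.frame (`filename`, `filetype`, `set_number`, `part_number`,
#'   `n_rows`). Also written as `manifest.json` in `out_dir`.
#' @export
#'
#' @examples
#' dir <- file.path(tempdir(), "fixture_example")
#' man <- generate_fixture(dir, seed = 1)
#' man$files
generate_fixture <- function(out_dir, n_patients = 12L,
                             patient_sets = NULL, parts_per_type = c("1" = 3L),
                             rows_per_part = 20L, seed = 101L,
                             prefix = "aurum_allpatid", delimiter = "\t",
                             pad = 3L) {
  stopifnot(n_patients >= 0L)
  if (is.null(patient_sets)) {
    patient_sets <- c(rep(1L, min(8L, n_patients)),
                      rep(2L, max(0L, n_patients - 8L)))
  }
  if (length(patient_sets) != n_patients || anyNA(patient_sets)) {
    stop("patient_sets must assign every patient to exactly one set", call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)

  set.seed(seed)
  patids <- as.character(seq_len(n_patients))
  sets <- sort(unique(as.integer(patient_sets)))
  if (n_patients == 0L) sets <- as.integer(names(parts_per_type))

  # pool of medical/product codes; the long code anchors worked-example queries
  med_pool <- c("187341000000114", as.character(sample(1:100, 8)))
  prod_pool <- as.character(sample(1:100, 6))

  files <- list()
  for (s in sets) {
    in_set <- patids[patient_sets == s]
    pat <- data.table(
      patid = in_set,
      pracid = as.character(seq_along(in_set)),
      gender = if (length(in_set)) sample(1:2, length(in_set), replace = TRUE) else integer(0),
      yob = if (length(in_set)) sample(1900:2000, length(in_set), replace = TRUE) else integer(0),
      regstartdate = random_fixture_dates(length(in_set)),
      regenddate = random_fixture_dates(length(in_set)),
      emis_ddate = random_fixture_dates(length(in_set)),
      filler_a = if (length(in_set)) sample(1:100, length(in_set), replace = TRUE) else integer(0),
      filler_b = if (length(in_set)) sample(1:100, length(in_set), replace = TRUE) else integer(0)
    )
    fn <- format_filename(prefix, s, "patient", 1L, pad)
    write_raw_table(pat, file.path(out_dir, fn), delimiter)
    files[[length(files) + 1L]] <- list(filename = fn, filetype = "patient",
                                        set_number = s, part_number = 1L,
                                        n_rows = nrow(pat))

    n_parts <- parts_per_type[as.character(s)]
    if (is.na(n_parts) || length(n_parts) == 0L) next
    for (p in seq_len(n_parts)) {
      n <- if (length(in_set)) rows_per_part else 0L
      obs <- data.table(
        patid = if (n) sample(in_set, n, replace = TRUE) else character(0),
        medcodeid = if (n) sample(med_pool, n, replace = TRUE) else character(0),
        obsdate = random_fixture_dates(n),
        value = if (n) sample(1:100, n, replace = TRUE) else integer(0),
        numunitid = if (n) as.character(sample(1:100, n, replace = TRUE)) else character(0),
        filler_a = if (n) sample(1:100, n, replace = TRUE) else integer(0),
        filler_b = if (n) sample(1:100, n, replace = TRUE) else integer(0)
      )
      fn <- format_filename(prefix, s, "observation", p, pad)
      write_raw_table(obs, file.path(out_dir, fn), delimiter)
      files[[length(files) + 1L]] <- list(filename = fn, filetype = "observation",
                                          set_number = s, part_number = p,
                                          n_rows = nrow(obs))

      drug <- data.table(
        patid = if (n) sample(in_set, n, replace = TRUE) else character(0),
        prodcodeid = if (n) sample(prod_pool, n, replace = TRUE) else character(0),
        issuedate = random_fixture_dates(n),
        filler_a = if (n) sample(1:100, n, replace = TRUE) else integer(0),
        filler_b = if (n) sample(1:100, n, replace = TRUE) else integer(0)
      )
      fn <- format_filename(prefix, s, "drugissue", p, pad)
      write_raw_table(drug, file.path(out_dir, fn), delimiter)
      files[[length(files) + 1L]] <- list(filename = fn, filetype = "drugissue",
                                          set_number = s, part_number = p,
                                          n_rows = nrow(drug))
    }
  }
  manifest <- list(root_dir = normalizePath(out_dir), seed = seed,
                   files = rbindlist(files))
  write_manifest(manifest, out_dir)
  manifest
}

random_fixture_dates <- function(n, from = as.Date("1900-01-01"),
                                 to = as.Date("2000-01-01")) {
  if (n == 0L) return(as.Date(character(0)))
  from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
}

write_raw_table <- function(dt, path, delimiter = "\t") {
  out <- copy(as.data.table(dt))
  for (col in names(out)) {
    if (inherits(out[[col]], "Date")) {
      data.table::set(out, j = col, value = format(out[[col]], "%d/%m/%Y"))
    }
  }
  fwrite(out, path, sep = delimiter, quote = FALSE, eol = "\n")
  invisible(path)
}

write_manifest <- function(manifest, out_dir) {
  m <- manifest
  m$files <- as.data.frame(m$files)
  jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Define a randomized study-set recipe
#'
#' A recipe fixes everything about a generated study: cohort size, how the
#' patients are split into sets and the medical files into parts, the mean
#' number of background observations per patient, and — the part that makes
#' recovery experiments possible — a per-code probability that a patient has
#' at least one record of that code strictly before the study index date.
#'
#' @param n_patients Number of patients.
#' @param n_sets Number of sets the patients are split across (default 1).
#' @param obs_files_per_set,drug_files_per_set Parts per set for the
#'   observation and drugissue file types (default 2 and 1).
#' @param obs_per_patient Mean number of background observations per patient
#'   (Poisson; default 10). Background observations carry codes disjoint from
#'   `code_prevalences`.
#' @param code_prevalences Named numeric vector: for each code (name), the
#'   probability in \[0,1\] that a patient has >= 1 record of it dated strictly
#'   before `index_date`.
#' @param index_date Study index date (default `"2010-01-01"`).
#' @param seed Integer seed.
#'
#' @return An object of class `study_recipe`.
#' @export
study_recipe <- function(n_patients, n_sets = 1L, obs_files_per_set = 2L,
                         drug_files_per_set = 1L, obs_per_patient = 10,
                         code_prevalences = c(H1 = 0.1),
                         index_date = as.Date("2010-01-01"), seed = 1L) {
  stopifnot(n_patients >= 1L, n_sets >= 1L, obs_files_per_set >= 1L,
            drug_files_per_set >= 1L, obs_per_patient >= 0)
  if (is.null(names(code_prevalences)) ||
      any(code_prevalences < 0) || any(code_prevalences > 1)) {
    stop("code_prevalences must be a named vector of probabilities in [0,1]",
         call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_sets = as.integer(n_sets),
                 obs_files_per_set = as.integer(obs_files_per_set),
                 drug_files_per_set = as.integer(drug_files_per_set),
                 obs_per_patient = obs_per_patient,
                 code_prevalences = code_prevalences,
                 index_date = as.Date(index_date),
                 seed = as.integer(seed)),
            class = "study_recipe")
}

#' Generate a randomized study set with known ground truth
#'
#' Writes a full raw file tree under the recipe's conditions and a truth
#' sidecar (`truth.csv`: `patid,code,flag`) recording, for every patient and
#' every code in the recipe's prevalence map, whether a pre-index record of
#' that code was planted. The sidecar is what recovery and oracle-equivalence
#' experiments compare against.
#'
#' Patients are split as evenly as possible across sets; each set's
#' observation and drugissue rows are split round-robin across that set's
#' parts. Planted records are dated uniformly in \[1900-01-01, index_date - 1\];
#' background records are dated uniformly in \[1900-01-01, 2000-01-01\] and
#' carry codes of the form `BG<k>`, disjoint from the prevalence map.
#'
#' @param recipe A [study_recipe()].
#' @param out_dir Directory to write into (created if absent).
#' @param prefix,delimiter,pad As in [generate_fixture()].
#'
#' @return The fixture manifest (see [generate_fixture()]), with an extra
#'   `truth_file` element.
#' @export
generate_study <- function(recipe, out_dir, prefix = "aurum_allpatid",
                           delimiter = "\t", pad = 3L) {
  stopifnot(inherits(recipe, "study_recipe"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  set.seed(recipe$seed)

  n <- recipe$n_patients
  patids <- as.character(seq_len(n))
  patient_sets <- rep(seq_len(recipe$n_sets), length.out = n)[order(seq_len(n))]
  patient_sets <- sort(patient_sets)  # contiguous blocks: 1..k set1, ...

  codes <- names(recipe$code_prevalences)
  truth <- rbindlist(lapply(codes, function(cd) {
    data.table(patid = patids, code = cd,
               flag = rbinom(n, 1L, recipe$code_prevalences[[cd]]))
  }))

  # planted pre-index records, one per (patient, code) flagged 1
  planted <- truth[flag == 1L]
  pre_span <- as.integer(recipe$index_date - as.Date("1900-01-01"))  # strictly before index
  planted_obs <- if (nrow(planted)) data.table(
    patid = planted$patid,
    medcodeid = planted$code,
    obsdate = as.Date("1900-01-01") + sample.int(pre_span, nrow(planted), replace = TRUE) - 1L,
    value = sample(1:100, nrow(planted), replace = TRUE),
    numunitid = as.character(sample(1:100, nrow(planted), replace = TRUE))
  ) else NULL

  n_bg <- rpois(n, recipe$obs_per_patient)
  bg_obs <- if (sum(n_bg)) data.table(
    patid = rep(patids, n_bg),
    medcodeid = paste0("BG", sample(1:50, sum(n_bg), replace = TRUE)),
    obsdate = random_fixture_dates(sum(n_bg)),
    value = sample(1:100, sum(n_bg), replace = TRUE),
    numunitid = as.character(sample(1:100, sum(n_bg), replace = TRUE))
  ) else NULL
  obs <- rbindlist(list(planted_obs, bg_obs))
  obs <- obs[sample.int(nrow(obs))]  # shuffle so parts interleave patients

  n_drug <- rpois(n, max(1, recipe$obs_per_patient / 5))
  drug <- data.table(
    patid = rep(patids, n_drug),
    prodcodeid = paste0("RX", sample(1:20, sum(n_drug), replace = TRUE)),
    issuedate = random_fixture_dates(sum(n_drug))
  )

  files <- list()
  for (s in seq_len(recipe$n_sets)) {
    in_set <- patids[patient_sets == s]
    pat <- data.table(
      patid = in_set,
      pracid = as.character(sample(1:100, length(in_set), replace = TRUE)),
      gender = sample(1:2, length(in_set), replace = TRUE),
      yob = sample(1900:2000, length(in_set), replace = TRUE),
      regstartdate = random_fixture_dates(length(in_set)),
      regenddate = random_fixture_dates(length(in_set)),
      emis_ddate = random_fixture_dates(length(in_set))
    )
    fn <- format_filename(prefix, s, "patient", 1L, pad)
    write_raw_table(pat, file.path(out_dir, fn), delimiter)
    files[[length(files) + 1L]] <- list(filename = fn, filetype = "patient",
                                        set_number = s, part_number = 1L,
                                        n_rows = nrow(pat))

    obs_s <- obs[patid %chin% in_set]
    part_of <- rep(seq_len(recipe$obs_files_per_set), length.out = max(1L, nrow(obs_s)))
    for (p in seq_len(recipe$obs_files_per_set)) {
      chunk <- obs_s[which(part_of[seq_len(nrow(obs_s))] == p)]
      fn <- format_filename(prefix, s, "observation", p, pad)
      write_raw_table(chunk, file.path(out_dir, fn), delimiter)
      files[[length(files) + 1L]] <- list(filename = fn, filetype = "observation",
                                          set_number = s, part_number = p,
                                          n_rows = nrow(chunk))
    }
    drug_s <- drug[patid %chin% in_set]
    part_of_d <- rep(seq_len(recipe$drug_files_per_set), length.out = max(1L, nrow(drug_s)))
    for (p in seq_len(recipe$drug_files_per_set)) {
      chunk <- drug_s[which(part_of_d[seq_len(nrow(drug_s))] == p)]
      fn <- format_filename(prefix, s, "drugissue", p, pad)
      write_raw_table(chunk, file.path(out_dir, fn), delimiter)
      files[[length(files) + 1L]] <- list(filename = fn, filetype = "drugissue",
                                          set_number = s, part_number = p,
                                          n_rows = nrow(chunk))
    }
  }

  truth_path <- file.path(out_dir, "truth.csv")
  fwrite(truth, truth_path)
  manifest <- list(root_dir = normalizePath(out_dir), seed = recipe$seed,
                   files = rbindlist(files), truth_file = truth_path)
  write_manifest(manifest, out_dir)
  manifest
}
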