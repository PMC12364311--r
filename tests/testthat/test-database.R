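test_that("store handles open, list tables, and fail cleanly once closed", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "s.sqlite")
  h <- connect_database(path)
  expect_true(file.exists(path))
  expect_length(list_tables(h), 0L)
  close_database(h)
  expect_error(list_tables(h), "closed")
  close_database(h)  # double close is a no-op
  expect_error(connect_database(file.path(dir, "missing", "s.sqlite")),
               "directory")
})

test_that("subset ingest stores exactly the raw rows of the cohort", {
  dir <- withr::local_tempdir()
  man <- generate_fixture(dir, seed = 1)
  ids <- c("1", "3", "4", "6")

  # brute-force oracle: count matching rows straight off the raw files
  obs_files <- man$files$filename[man$files$filetype == "observation"]
  raw <- data.table::rbindlist(lapply(obs_files, function(fn)
    read_raw_file(file.path(dir, fn), "observation")))
  expected_n <- nrow(raw[raw$patid %in% ids, ])

  h <- connect_database(tempfile(fileext = ".sqlite"))
  withr::defer(close_database(h))
  for (i in seq_along(obs_files)) {
    add_to_database(h, file.path(dir, obs_files[i]), "observation",
                    subset_patids = ids,
                    mode = if (i == 1) "overwrite" else "append")
  }
  stored <- read_table_df(h, "observation")
  expect_equal(nrow(stored), expected_n)
  expect_true(all(stored$patid %in% ids))          # filter soundness
  # completeness: every qualifying raw row appears exactly once
  expect_equal(sort(paste(stored$patid, stored$medcodeid, stored$obsdate)),
               sort(paste(raw$patid, raw$medcodeid,
                          format(raw$obsdate, "%Y-%m-%d"))[raw$patid %in% ids]))
})

test_that("pair-form subset (set fast path) matches plain id filtering", {
  dir <- withr::local_tempdir()
  generate_study(study_recipe(n_patients = 60, n_sets = 2,
                              obs_files_per_set = 2, seed = 13), dir)
  pat <- extract_cohort(dir, set = TRUE)
  ids <- pat$patid[seq(1, 60, by = 2)]
  pairs <- pat[pat$patid %in% ids, c("patid", "set")]

  h1 <- connect_database(tempfile(fileext = ".sqlite"))
  withr::defer(close_database(h1))
  cprd_extract(h1, dir, "observation", subset_patids = ids)

  h2 <- connect_database(tempfile(fileext = ".sqlite"))
  withr::defer(close_database(h2))
  cprd_extract(h2, dir, "observation", subset_patids = pairs)

  expect_identical(read_table_df(h1, "observation"),
                   read_table_df(h2, "observation"))
})

test_that("empty subsets, bad appends and unknown filetypes are handled", {
  dir <- withr::local_tempdir()
  man <- generate_fixture(dir, seed = 1)
  f <- file.path(dir, man$files$filename[man$files$filetype == "observation"][1])
  h <- connect_database(tempfile(fileext = ".sqlite"))
  withr::defer(close_database(h))

  n <- add_to_database(h, f, "observation", subset_patids = character(0),
                       mode = "overwrite")
  expect_equal(n, 0L)
  expect_true("observation" %in% list_tables(h))
  expect_equal(nrow(read_table_df(h, "observation")), 0L)
  expect_true("patid" %in% names(read_table_df(h, "observation")))

  expect_error(add_to_database(h, f, "observation", mode = "append",
                               table_name = "nope"), "overwrite")
  expect_error(add_to_database(h, f, "mystery"), "extract_txt_func")
  expect_error(add_to_database(h, f, "observation",
                               subset_patids = data.frame(patid = "1")),
               "set")
})

test_that("cprd_extract matches the manual per-file sequence and is idempotent", {
  dir <- withr::local_tempdir()
  man <- generate_fixture(dir, seed = 1)
  obs_files <- sort(man$files$filename[man$files$filetype == "observation"])

  h_manual <- connect_database(tempfile(fileext = ".sqlite"))
  withr::defer(close_database(h_manual))
  for (i in seq_along(obs_files)) {
    add_to_database(h_manual, file.path(dir, obs_files[i]), "observation",
                    mode = if (i == 1) "overwrite" else "append")
  }

  h <- connect_database(tempfile(fileext = ".sqlite"))
  withr::defer(close_database(h))
  cprd_extract(h, dir, "observation")
  expect_identical(read_table_df(h, "observation"),
                   read_table_df(h_manual, "observation"))

  cprd_extract(h, dir, "observation")  # re-run overwrites, not doubles
  expect_identical(read_table_df(h, "observation"),
                   read_table_df(h_manual, "observation"))

  cprd_extract(h, dir, "drugissue")
  expect_setequal(list_tables(h), c("observation", "drugissue"))
  expect_error(cprd_extract(h, dir, "consultation"), "no files matching")
})

test_that("rm_duplicates collapses a duplicated file to a single copy", {
  dir <- withr::local_tempdir()
  man <- generate_fixture(dir, seed = 1)
  obs_files <- man$files$filename[man$files$filetype == "observation"]

  # single-copy oracle count
  h0 <- connect_database(tempfile(fileext = ".sqlite"))
  withr::defer(close_database(h0))
  cprd_extract(h0, dir, "observation")
  n_single <- nrow(read_table_df(h0, "observation"))

  # duplicate one part on disk under a new part number
  dup_name <- sub("_001", "_009", obs_files[1])
  file.copy(file.path(dir, obs_files[1]), file.path(dir, dup_name))

  h <- connect_database(tempfile(fileext = ".sqlite"))
  withr::defer(close_database(h))
  cprd_extract(h, dir, "observation", rm_duplicates = TRUE)
  expect_equal(nrow(read_table_df(h, "observation")), n_single)

  h2 <- connect_database(tempfile(fileext = ".sqlite"))
  withr::defer(close_database(h2))
  cprd_extract(h2, dir, "observation", rm_duplicates = FALSE)
  expect_equal(nrow(read_table_df(h2, "observation")),
               n_single + man$files$n_rows[man$files$filetype == "observation"][1])
})

test_that("chunked ingest equals whole-file ingest", {
  dir <- withr::local_tempdir()
  man <- generate_fixture(dir, seed = 21)
  f <- file.path(dir, man$files$filename[man$files$filetype == "observation"][1])

  h1 <- connect_database(tempfile(fileext = ".sqlite"))
  withr::defer(close_database(h1))
  add_to_database(h1, f, "observation", mode = "overwrite")

  h2 <- connect_database(tempfile(fileext = ".sqlite"))
  withr::defer(close_database(h2))
  add_to_database(h2, f, "observation", mode = "overwrite", chunk_size = 7)

  expect_identical(read_table_df(h1, "observation"),
                   read_table_df(h2, "observation"))
})
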