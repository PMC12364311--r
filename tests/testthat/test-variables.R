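test_that("history flags count records on the index date but not after", {
  h <- store_with(observation = obs_rows(c("1", "2"), "A",
                                         c("2010-01-01", "2010-01-02")))
  withr::defer(close_database(h))
  coh <- cohort_rows(c("1", "2", "3"), "2010-01-01")
  got <- extract_ho(coh, codelist_vector = "A", store = h)
  expect_equal(got$ho, c(1L, 0L, 0L))
  expect_equal(got$patid, coh$patid)
})

test_that("history works off the drugissue table for prescriptions", {
  drug <- data.table::data.table(patid = c("1", "2"), prodcodeid = "RX1",
                                 issuedate = as.Date(c("2009-06-01", "2011-01-01")))
  h <- store_with(drugissue = drug)
  withr::defer(close_database(h))
  coh <- cohort_rows(c("1", "2"), "2010-01-01")
  got <- extract_ho(coh, codelist_vector = "RX1", store = h, tab = "drugissue")
  expect_equal(got$ho, c(1L, 0L))
})

test_that("store-backed history equals the raw-file loop on a generated study", {
  dir <- withr::local_tempdir()
  man <- generate_study(study_recipe(n_patients = 120, obs_per_patient = 8,
                                     code_prevalences = c(H1 = 0.25),
                                     seed = 23), dir)
  coh <- assign_index_dates(extract_cohort(dir), fixed_date = "2010-01-01")
  h <- connect_database(tempfile(fileext = ".sqlite"))
  withr::defer(close_database(h))
  cprd_extract(h, dir, "observation", subset_patids = coh$patid)

  via_store <- extract_ho(coh, codelist_vector = "H1", store = h)$ho
  via_loop <- brute_force_history(dir, coh, "H1")
  expect_equal(via_store, via_loop)
  truth <- data.table::fread(man$truth_file,
                             colClasses = list(character = "patid"))
  expect_equal(via_store, truth$flag[match(coh$patid, truth$patid)])
})

test_that("offsetting t equals shifting every index date by t days", {
  dir <- withr::local_tempdir()
  generate_study(study_recipe(n_patients = 60, obs_per_patient = 6,
                              code_prevalences = c(H1 = 0.4), seed = 29), dir)
  coh <- assign_index_dates(extract_cohort(dir), fixed_date = "1960-01-01")
  h <- connect_database(tempfile(fileext = ".sqlite"))
  withr::defer(close_database(h))
  cprd_extract(h, dir, "observation")

  offs <- extract_ho(coh, codelist_vector = "H1", store = h, t = 365)$ho
  shifted <- data.table::copy(coh)
  shifted$indexdt <- shifted$indexdt + 365
  expect_equal(offs, extract_ho(shifted, codelist_vector = "H1", store = h)$ho)
})

test_that("time-until returns event time or censoring per the stated rules", {
  idx <- as.Date("2010-01-01")
  obs <- obs_rows(c("1", "3", "4"), "E",
                  c(idx + 100, idx + 300, idx))  # patient 4: event on index day
  h <- store_with(observation = obs)
  withr::defer(close_database(h))
  coh <- cohort_rows(c("1", "2", "3", "4"), idx, censdt = idx + 200)

  got <- extract_time_until(coh, codelist_vector = "E", store = h,
                            varname = "ev")
  expect_equal(got$ev_time, c(100L, 200L, 200L, 200L))
  expect_equal(got$ev_indicator, c(1L, 0L, 0L, 0L))  # on-index event excluded
  expect_equal(got$patid, coh$patid)

  # indicator = 1 implies a record at exactly indexdt + time
  expect_equal(obs$obsdate[obs$patid == "1"], idx + got$ev_time[1])

  expect_error(extract_time_until(cohort_rows("1", idx),
                                  codelist_vector = "E", store = h), "censdt")
  coh_na <- coh; coh_na$censdt[2] <- NA
  expect_error(extract_time_until(coh_na, codelist_vector = "E", store = h),
               "patid.*2")
})

test_that("time-until stays within [0, censdt - indexdt] on random histories", {
  set.seed(37)
  idx <- as.Date("2010-01-01")
  coh <- cohort_rows(as.character(1:30), idx,
                     censdt = idx + sample(50:400, 30, replace = TRUE))
  obs <- obs_rows(sample(coh$patid, 150, replace = TRUE), "E",
                  idx + sample(-100:500, 150, replace = TRUE))
  h <- store_with(observation = obs)
  withr::defer(close_database(h))
  got <- extract_time_until(coh, codelist_vector = "E", store = h,
                            varname = "ev")
  expect_true(all(got$ev_time >= 0))
  expect_true(all(got$ev_time <= as.integer(coh$censdt - coh$indexdt)))
  expect_true(all(got$ev_indicator %in% 0:1))
  hit <- which(got$ev_indicator == 1L)
  for (i in hit) {
    expect_true(any(obs$patid == got$patid[i] &
                      obs$obsdate == idx + got$ev_time[i]))
  }
})

test_that("test-data extraction matches an independently coded filter", {
  set.seed(41)
  idx <- as.Date("2010-01-01")
  coh <- cohort_rows(as.character(1:50), idx)
  obs <- obs_rows(sample(coh$patid, 400, replace = TRUE), "T",
                  idx + sample(-300:50, 400, replace = TRUE),
                  value = sample(1:100, 400, replace = TRUE))
  h <- store_with(observation = obs)
  withr::defer(close_database(h))

  for (prm in list(list(tp = 100, po = 0, lo = -Inf, up = Inf, k = 1),
                   list(tp = 200, po = 30, lo = 20, up = 80, k = 3))) {
    got <- extract_test_data(coh, codelist_vector = "T", store = h,
                             time_prev = prm$tp, time_post = prm$po,
                             lower_bound = prm$lo, upper_bound = prm$up,
                             numobs = prm$k, varname = "v")
    want <- oracle_window_values(obs, coh, "T", prm$tp, prm$po,
                                 prm$lo, prm$up, prm$k)
    got <- got[order(as.numeric(got$patid), -got$v), ]
    want <- want[order(as.numeric(want$patid), -want$value), ]
    expect_equal(got$patid, want$patid)
    expect_equal(got$v, want$value)
  }
})

test_that("test metadata columns appear only when asked for", {
  h <- store_with(observation = obs_rows("1", "T", "2009-12-01", value = 7,
                                         numunitid = "u"))
  withr::defer(close_database(h))
  coh <- cohort_rows("1", "2010-01-01")
  plain <- extract_test_data(coh, codelist_vector = "T", store = h,
                             varname = "v")
  expect_setequal(names(plain), c("patid", "v"))
  meta <- extract_test_data(coh, codelist_vector = "T", store = h,
                            varname = "v", numunitid = TRUE)
  expect_true(all(c("obsdate", "medcodeid", "numunitid") %in% names(meta)))
})

test_that("test variability is the sample standard deviation, NA below n = 2", {
  idx <- as.Date("2010-01-01")
  obs <- obs_rows(c("1", "1", "1", "2"), "T",
                  c(idx - 10, idx - 20, idx - 30, idx - 10),
                  value = c(1, 2, 3, 9))
  h <- store_with(observation = obs)
  withr::defer(close_database(h))
  coh <- cohort_rows(c("1", "2", "3"), idx)
  got <- extract_test_data_var(coh, codelist_vector = "T", store = h,
                               varname = "v")
  expect_equal(got$v, c(1.0, NA_real_, NA_real_))
  expect_equal(got$patid, coh$patid)
})

test_that("test variability matches a two-pass oracle on random values", {
  set.seed(43)
  idx <- as.Date("2010-01-01")
  coh <- cohort_rows(as.character(1:40), idx)
  obs <- obs_rows(sample(coh$patid, 300, replace = TRUE), "T",
                  idx - sample(0:500, 300, replace = TRUE),
                  value = runif(300, 0, 50))
  h <- store_with(observation = obs)
  withr::defer(close_database(h))
  got <- extract_test_data_var(coh, codelist_vector = "T", store = h,
                               time_prev = 365, lower_bound = 5,
                               upper_bound = 45, varname = "v")
  for (i in seq_len(nrow(coh))) {
    vals <- obs$value[obs$patid == coh$patid[i] &
                        obs$obsdate >= idx - 365 & obs$obsdate <= idx &
                        obs$value >= 5 & obs$value <= 45]
    expect_equal(got$v[i], oracle_two_pass_sd(vals), label = coh$patid[i])
  }
})
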