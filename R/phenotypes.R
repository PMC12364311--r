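# Phenotype algorithms: variables whose definitions need cleaning/derivation
# steps beyond a plain windowed query (unit conversion, component formulas,
# category reconciliation). Default search window for the measurement-based
# ones: the five years up to the index date (time_prev = 1825, time_post = 0).

# unit codes whose height values are recorded in centimetres; configurable,
# since the licensed unit lookup cannot be shipped. Heights > 3 after mapping
# are additionally treated as cm (no adult is 3 m tall).
default_cm_units <- c("cm", "centimetre", "centimetres", "centimeters", "122")

# most recent value per patid from a reduced test query (keeps date + units)
most_recent_value <- function(cohort, q, time_prev, time_post, t) {
  combine_query(cohort, q, query_type = "test", time_prev = time_prev,
                time_post = time_post, numobs = 1L, value_na_rm = TRUE,
                reduce_output = TRUE, t = t)
}

# shared direct-vs-components candidate rule for BMI and cholesterol/HDL
# ratio: each candidate is governed by a date (direct: its own date;
# derived: the later of the two component dates); the most recent governing
# date wins, ties going to the direct measurement.
pick_candidate <- function(cohort, direct, derived) {
  out <- data.table(patid = cohort$patid)
  out <- merge(out, direct[, .(patid, direct_value = value, direct_date = obsdate)],
               by = "patid", all.x = TRUE, sort = FALSE)
  out <- merge(out, derived, by = "patid", all.x = TRUE, sort = FALSE)
  use_derived <- !is.na(out$derived_value) &
    (is.na(out$direct_value) | out$derived_date > out$direct_date)
  val <- ifelse(use_derived, out$derived_value, out$direct_value)
  data.table(patid = out$patid, value = val)[match(cohort$patid, out$patid)]
}

#' Extract body mass index
#'
#' BMI is either recorded directly or derived as weight / height^2 from the
#' most recent in-window weight (kg) and height measurements. Heights whose
#' unit code maps to centimetres — or that exceed 3 after mapping — are
#' converted to metres. Both components must themselves fall inside the
#' search window. When both a direct record and a derivable pair exist, the
#' candidate whose governing date (for the derived value, the later of the
#' two component dates) is most recent wins; ties go to the direct record.
#' Non-positive heights are skipped with a counted warning.
#'
#' @inheritParams extract_ho
#' @param codelist_bmi,codelist_height,codelist_weight Character vectors of
#'   medcodeids for the three concepts (or use
#'   `codelist_bmi_df`/... data frames).
#' @param codelist_bmi_df,codelist_height_df,codelist_weight_df Data-frame
#'   form of the three codelists.
#' @param time_prev,time_post Search window in days around `indexdt + t`
#'   (defaults: 1825 before, 0 after).
#' @param cm_units Unit codes treated as centimetres (see Details).
#' @param varname Output column name (default `"bmi"`).
#'
#' @return A `data.table`, one row per cohort patient: `patid` and the BMI
#'   value (`NA` when neither candidate exists).
#' @export
extract_bmi <- function(cohort, codelist_bmi = NULL, codelist_height = NULL,
                        codelist_weight = NULL, codelist_bmi_df = NULL,
                        codelist_height_df = NULL, codelist_weight_df = NULL,
                        db = NULL, db_filepath = NULL, store = NULL,
                        tab = "observation", time_prev = 1825, time_post = 0,
                        t = 0, cm_units = default_cm_units, varname = "bmi",
                        out_save_disk = FALSE, out_filepath = NULL,
                        return_output = TRUE, root = ".") {
  cohort <- as.data.table(cohort)
  with_store(db = db, db_filepath = db_filepath, store = store, root = root,
             function(handle) {
    q_bmi <- db_query(store = handle, tab = tab,
                      codelist_vector = codelist_bmi, codelist_df = codelist_bmi_df)
    q_ht <- db_query(store = handle, tab = tab,
                     codelist_vector = codelist_height, codelist_df = codelist_height_df)
    q_wt <- db_query(store = handle, tab = tab,
                     codelist_vector = codelist_weight, codelist_df = codelist_weight_df)

    direct <- most_recent_value(cohort, q_bmi, time_prev, time_post, t)
    ht <- most_recent_value(cohort, q_ht, time_prev, time_post, t)
    wt <- most_recent_value(cohort, q_wt, time_prev, time_post, t)

    if (nrow(ht) > 0L) {
      in_cm <- ht$numunitid %chin% cm_units | (!is.na(ht$value) & ht$value > 3)
      ht[in_cm, value := value / 100]
      n_bad <- sum(!is.na(ht$value) & ht$value <= 0)
      if (n_bad > 0L) {
        warning(sprintf("%d non-positive height value(s) skipped", n_bad),
                call. = FALSE)
        ht <- ht[is.na(value) | value > 0]
      }
    }
    derived <- merge(wt[, .(patid, wt_value = value, wt_date = obsdate)],
                     ht[, .(patid, ht_value = value, ht_date = obsdate)],
                     by = "patid")
    derived <- derived[, .(patid,
                           derived_value = wt_value / ht_value^2,
                           derived_date = pmax(wt_date, ht_date))]
    out <- pick_candidate(cohort, direct, derived)
    setnames(out, "value", varname)
    finalize_variable(out, varname, t, out_save_disk, out_filepath,
                      return_output, root)
  })
}

#' Extract total cholesterol / HDL ratio
#'
#' Same candidate logic as [extract_bmi()]: a directly recorded ratio
#' competes with total cholesterol / HDL derived from the most recent
#' in-window components, the most recent governing date winning and ties
#' going to the direct record. A zero HDL invalidates the derived candidate.
#'
#' @inheritParams extract_bmi
#' @param codelist_ratio,codelist_chol,codelist_hdl Character vectors of
#'   medcodeids for the directly recorded ratio, total cholesterol and HDL.
#' @param codelist_ratio_df,codelist_chol_df,codelist_hdl_df Data-frame form.
#' @param varname Output column name (default `"cholhdl_ratio"`).
#'
#' @return A `data.table`, one row per cohort patient.
#' @export
extract_cholhdl_ratio <- function(cohort, codelist_ratio = NULL,
                                  codelist_chol = NULL, codelist_hdl = NULL,
                                  codelist_ratio_df = NULL,
                                  codelist_chol_df = NULL,
                                  codelist_hdl_df = NULL,
                                  db = NULL, db_filepath = NULL, store = NULL,
                                  tab = "observation", time_prev = 1825,
                                  time_post = 0, t = 0,
                                  varname = "cholhdl_ratio",
                                  out_save_disk = FALSE, out_filepath = NULL,
                                  return_output = TRUE, root = ".") {
  cohort <- as.data.table(cohort)
  with_store(db = db, db_filepath = db_filepath, store = store, root = root,
             function(handle) {
    q_ratio <- db_query(store = handle, tab = tab,
                        codelist_vector = codelist_ratio, codelist_df = codelist_ratio_df)
    q_chol <- db_query(store = handle, tab = tab,
                       codelist_vector = codelist_chol, codelist_df = codelist_chol_df)
    q_hdl <- db_query(store = handle, tab = tab,
                      codelist_vector = codelist_hdl, codelist_df = codelist_hdl_df)

    direct <- most_recent_value(cohort, q_ratio, time_prev, time_post, t)
    chol <- most_recent_value(cohort, q_chol, time_prev, time_post, t)
    hdl <- most_recent_value(cohort, q_hdl, time_prev, time_post, t)
    hdl <- hdl[!is.na(value) & value != 0]    # division guard

    derived <- merge(chol[, .(patid, chol_value = value, chol_date = obsdate)],
                     hdl[, .(patid, hdl_value = value, hdl_date = obsdate)],
                     by = "patid")
    derived <- derived[, .(patid,
                           derived_value = chol_value / hdl_value,
                           derived_date = pmax(chol_date, hdl_date))]
    out <- pick_candidate(cohort, direct, derived)
    setnames(out, "value", varname)
    finalize_variable(out, varname, t, out_save_disk, out_filepath,
                      return_output, root)
  })
}

#' Extract diabetes status
#'
#' Categorical history variable over two codelists. Generic diabetes codes
#' (e.g. "diabetes mellitus", type unspecified) belong in the type 2 list:
#' the algorithm assumes a generic code means type 2 unless the patient also
#' has a specific type 1 code, so any pre-index type 1 code yields
#' `"type1"`, else any pre-index type 2/generic code yields `"type2"`, else
#' `"Absent"`.
#'
#' @inheritParams extract_ho
#' @param codelist_type1,codelist_type2 Character vectors of medcodeids
#'   (generic codes go in `codelist_type2`).
#' @param codelist_type1_df,codelist_type2_df Data-frame form.
#' @param varname Output column name (default `"diabetes"`).
#'
#' @return A `data.table`, one row per cohort patient: `patid` and a factor
#'   with levels `Absent`, `type1`, `type2`.
#' @export
extract_diabetes <- function(cohort, codelist_type1 = NULL,
                             codelist_type2 = NULL, codelist_type1_df = NULL,
                             codelist_type2_df = NULL, db = NULL,
                             db_filepath = NULL, store = NULL,
                             tab = "observation", t = 0, varname = "diabetes",
                             out_save_disk = FALSE, out_filepath = NULL,
                             return_output = TRUE, root = ".") {
  cohort <- as.data.table(cohort)
  with_store(db = db, db_filepath = db_filepath, store = store, root = root,
             function(handle) {
    ho1 <- extract_ho(cohort, codelist_vector = codelist_type1,
                      codelist_df = codelist_type1_df, store = handle,
                      tab = tab, t = t, varname = "h1")
    ho2 <- extract_ho(cohort, codelist_vector = codelist_type2,
                      codelist_df = codelist_type2_df, store = handle,
                      tab = tab, t = t, varname = "h2")
    status <- ifelse(ho1$h1 == 1L, "type1",
                     ifelse(ho2$h2 == 1L, "type2", "Absent"))
    out <- data.table(patid = cohort$patid,
                      v = factor(status, levels = c("Absent", "type1", "type2")))
    setnames(out, "v", varname)
    finalize_variable(out, varname, t, out_save_disk, out_filepath,
                      return_output, root)
  })
}

smoking_levels <- c("Non-smoker", "Ex-smoker", "Light smoker",
                    "Moderate smoker", "Heavy smoker")

#' Extract smoking status
#'
#' Five codelists, one per status. The status is that of the most recent
#' record on or before `indexdt + t`; if that status is non-smoker but any
#' earlier record indicates smoking (ex/light/moderate/heavy), the patient
#' is reclassified as an ex-smoker — a recorded non-smoker with a smoking
#' history is a quitter, not a never-smoker. When several records share the
#' most recent date, the heaviest category wins (deterministic). A single
#' code present in two codelists is an error: the categories must partition
#' the codes. Patients with no smoking records get `NA`.
#'
#' @inheritParams extract_ho
#' @param codelist_non,codelist_ex,codelist_light,codelist_moderate,codelist_heavy
#'   Character vectors of medcodeids for the five statuses.
#' @param varname Output column name (default `"smoking"`).
#'
#' @return A `data.table`, one row per cohort patient: `patid` and a factor
#'   with levels Non-smoker, Ex-smoker, Light/Moderate/Heavy smoker.
#' @export
extract_smoking <- function(cohort, codelist_non = NULL, codelist_ex = NULL,
                            codelist_light = NULL, codelist_moderate = NULL,
                            codelist_heavy = NULL, db = NULL,
                            db_filepath = NULL, store = NULL,
                            tab = "observation", t = 0, varname = "smoking",
                            out_save_disk = FALSE, out_filepath = NULL,
                            return_output = TRUE, root = ".") {
  cohort <- as.data.table(cohort)
  lists <- list("Non-smoker" = codelist_non, "Ex-smoker" = codelist_ex,
                "Light smoker" = codelist_light,
                "Moderate smoker" = codelist_moderate,
                "Heavy smoker" = codelist_heavy)
  all_codes <- unlist(lists, use.names = FALSE)
  dup <- unique(all_codes[duplicated(all_codes)])
  if (length(dup) > 0L) {
    stop(sprintf("ambiguous smoking codelists: code(s) %s appear in more than one category",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  cl_df <- rbindlist(lapply(names(lists), function(nm) {
    if (is.null(lists[[nm]])) return(NULL)
    data.table(medcodeid = as.character(lists[[nm]]), category = nm)
  }))
  if (is.null(cl_df) || nrow(cl_df) == 0L) {
    stop("at least one smoking codelist must be supplied", call. = FALSE)
  }
  with_store(db = db, db_filepath = db_filepath, store = store, root = root,
             function(handle) {
    q <- db_query(store = handle, tab = tab, codelist_df = cl_df)
    q <- as.data.table(q)[!is.na(obsdate)]
    m <- merge(q, cohort[, .(patid, indexdt)], by = "patid", sort = FALSE)
    m <- m[obsdate <= indexdt + t]
    # severity rank breaks same-day ties toward the heavier status
    m[, .aurumehr_ord := match(category, smoking_levels)]
    setorderv(m, c("patid", "obsdate", ".aurumehr_ord"), order = c(1L, -1L, -1L))
    latest <- m[, head(.SD, 1L), by = patid][, .(patid, category)]
    ever_smoked <- m[category != "Non-smoker", unique(patid)]
    latest[category == "Non-smoker" & patid %chin% ever_smoked,
           category := "Ex-smoker"]
    out <- data.table(patid = cohort$patid)
    out <- merge(out, latest, by = "patid", all.x = TRUE, sort = FALSE)
    out <- out[match(cohort$patid, out$patid)]
    out[, category := factor(category, levels = smoking_levels)]
    setnames(out, "category", varname)
    finalize_variable(out, varname, t, out_save_disk, out_filepath,
                      return_output, root)
  })
}
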