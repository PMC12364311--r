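#' File types recognised in Aurum-style extracts
#' @keywords internal
aurum_filetypes <- c("patient", "observation", "drugissue", "referral",
                     "problem", "consultation", "hes_primary", "death")

#' Parse a raw extract filename
#'
#' Raw Aurum-style extracts follow the convention
#' `<prefix>_setX_extract_<filetype>_0Y.txt`, where `setX` identifies the
#' batch of patients a file belongs to and `0Y` numbers the parts of each
#' file type within a set. The prefix varies between deliveries, so parsing
#' keys on the `set<digits>` token, a case-insensitive file-type substring
#' (`drug_issue` also matches `drugissue`), and a trailing `_<digits>.txt`
#' part number of any width.
#'
#' @param name A bare filename (no directory components are interpreted).
#'
#' @return A list with elements `prefix`, `set_number`, `filetype` and
#'   `part_number` (`NA` when the filename carries no trailing part token).
#' @seealso [format_filename()] for the inverse.
#' @export
#'
#' @examples
#' parse_filename("aurum_allpatid_set1_extract_observation_001.txt")
parse_filename <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  base <- basename(name)
  set_match <- regmatches(base, regexpr("set[0-9]+", base, ignore.case = TRUE))
  if (length(set_match) == 0L) {
    stop(sprintf("cannot parse '%s': no 'set<digits>' token in filename", base),
         call. = FALSE)
  }
  set_number <- as.integer(sub("set", "", set_match[1], ignore.case = TRUE))

  lower <- tolower(base)
  filetype <- NA_character_
  # longest names first so "hes_primary" is not shadowed; drug_issue aliases drugissue
  for (ft in c("hes_primary", "consultation", "observation", "drugissue",
               "drug_issue", "referral", "problem", "patient", "death")) {
    if (grepl(ft, lower, fixed = TRUE)) {
      filetype <- if (ft == "drug_issue") "drugissue" else ft
      break
    }
  }
  if (is.na(filetype)) {
    stop(sprintf("cannot parse '%s': no recognizable filetype in filename", base),
         call. = FALSE)
  }

  part_match <- regmatches(base, regexpr("_[0-9]+\\.txt$", lower))
  part_number <- if (length(part_match) == 0L) NA_integer_ else
    as.integer(gsub("[^0-9]", "", part_match[1]))

  prefix <- sub(sprintf("_?%s.*$", set_match[1]), "", base)

  list(prefix = prefix, set_number = set_number, filetype = filetype,
       part_number = part_number)
}

#' Format a raw extract filename
#'
#' @param prefix Filename prefix (default `"aurum_allpatid"`).
#' @param set_number Positive integer batch number (the `X` in `setX`).
#' @param filetype One of the recognised file types (see [parse_filename()]).
#' @param part_number Part number within the set, zero-padded to `pad` digits.
#' @param pad Minimum digit width of the part number (default 3).
#'
#' @return A filename string that round-trips through [parse_filename()].
#' @export
format_filename <- function(prefix = "aurum_allpatid", set_number, filetype,
                            part_number = 1L, pad = 3L) {
  stopifnot(set_number >= 1L, part_number >= 1L)
  sprintf("%s_set%d_extract_%s_%0*d.txt",
          prefix, as.integer(set_number), filetype, as.integer(pad),
          as.integer(part_number))
}

# date columns parsed for each filetype; others pass through verbatim
filetype_date_cols <- function(filetype) {
  switch(filetype,
    patient      = c("regstartdate", "regenddate", "emis_ddate", "cprd_ddate"),
    observation  = "obsdate",
    drugissue    = "issuedate",
    referral     = "obsdate",
    problem      = "obsdate",
    consultation = "consdate",
    hes_primary  = c("admidate", "discharged"),
    death        = c("reg_date_of_death", "dod"),
    character(0))
}

filetype_required_cols <- function(filetype) {
  switch(filetype,
    patient     = "patid",
    observation = c("patid", "medcodeid", "obsdate"),
    drugissue   = c("patid", "prodcodeid", "issuedate"),
    hes_primary = c("patid", "ICD10"),
    "patid")
}

#' Read one raw extract file into a typed table
#'
#' Reads a delimited raw file and applies the type conventions for its file
#' type: identifier columns (`patid`, `medcodeid`, `prodcodeid`) are always
#' read as text (Aurum identifiers exceed the exact-integer range of doubles),
#' date columns are parsed ([parse_ehr_date()]) with unparseable cells set to
#' `NA` under a counted warning, and unknown columns are preserved verbatim.
#' Files larger than memory can be read in chunks via `chunk_size` together
#' with `skip_rows`/`n_rows` (used by the ingest loop in [add_to_database()]).
#'
#' @param path Path to the raw `.txt` file.
#' @param filetype One of the recognised file types; determines which columns
#'   are mandatory and which are parsed as dates. Ignored when
#'   `extract_txt_func` is given.
#' @param extract_txt_func Optional function `(path, ...) -> data.frame`
#'   replacing the built-in reader, for file layouts the package does not
#'   know about.
#' @param delimiter Field delimiter (default tab).
#' @param date_format Passed to [parse_ehr_date()].
#' @param date_cols Override of the date-column set (used for the generic
#'   referral/problem/consultation readers whose layouts vary).
#' @param skip_rows,n_rows Read `n_rows` data rows starting after
#'   `skip_rows` (for chunked ingest); defaults read the whole file.
#'
#' @return A `data.table` with one row per non-header line read.
#' @export
read_raw_file <- function(path, filetype, extract_txt_func = NULL,
                          delimiter = "\t", date_format = "dmy",
                          date_cols = NULL, skip_rows = 0L, n_rows = Inf) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (!is.null(extract_txt_func)) {
    out <- extract_txt_func(path)
    return(as.data.table(out))
  }
  if (!filetype %in% aurum_filetypes) {
    stop(sprintf("unknown filetype '%s'; supply extract_txt_func for custom layouts",
                 filetype), call. = FALSE)
  }
  header <- names(fread(path, sep = delimiter, nrows = 0L, header = TRUE))
  required <- filetype_required_cols(filetype)
  missing <- setdiff(required, header)
  if (length(missing) > 0L) {
    stop(sprintf("file '%s' lacks mandatory column(s) for filetype '%s': %s",
                 basename(path), filetype, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  id_cols <- intersect(c("patid", "pracid", "medcodeid", "prodcodeid",
                         "numunitid", "ICD10"), header)
  dt <- fread(path, sep = delimiter, header = (skip_rows == 0L),
              skip = if (skip_rows > 0L) skip_rows + 1L else 0L,
              nrows = if (is.finite(n_rows)) n_rows else Inf,
              colClasses = list(character = match(id_cols, header)),
              keepLeadingZeros = TRUE, na.strings = c("", "NA"))
  if (skip_rows > 0L) setnames(dt, header[seq_len(ncol(dt))])
  for (col in id_cols) {
    data.table::set(dt, j = col, value = as.character(dt[[col]]))
  }
  dcols <- intersect(date_cols %||% filetype_date_cols(filetype), names(dt))
  for (col in dcols) {
    data.table::set(dt, j = col,
                    value = parse_ehr_date(dt[[col]], date_format, context = col))
  }
  if ("value" %in% names(dt)) {
    data.table::set(dt, j = "value", value = suppressWarnings(as.numeric(dt[["value"]])))
  }
  dt[]
}

# count data rows of a delimited file without loading it
count_file_rows <- function(path, delimiter = "\t") {
  nrow(fread(path, sep = delimiter, header = TRUE, select = 1L))
}
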