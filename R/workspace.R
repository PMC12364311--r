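#' Create the standard workspace directory system
#'
#' The package's convention layer: variables are saved under
#' `data/extraction/`, SQLite stores live under `data/sql/` and can be
#' referred to by name, and codelist CSVs live under `codelists/analysis/`.
#' Keeping these paths relative to one root avoids hard-coded file paths
#' when moving an analysis between machines.
#'
#' @param root Workspace root (default the current directory).
#'
#' @return Invisibly, a list with `root`, `extraction_dir`, `sql_dir` and
#'   `codelist_dir`. Idempotent; never deletes existing content.
#' @export
create_directory_system <- function(root = ".") {
  if (!dir.exists(root)) dir.create(root, recursive = TRUE)
  if (!dir.exists(root)) stop("cannot create workspace root", call. = FALSE)
  layout <- workspace_layout(root)
  for (d in layout[c("extraction_dir", "sql_dir", "codelist_dir")]) {
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  }
  invisible(layout)
}

workspace_layout <- function(root = ".") {
  list(root = root,
       extraction_dir = file.path(root, "data", "extraction"),
       sql_dir = file.path(root, "data", "sql"),
       codelist_dir = file.path(root, "codelists", "analysis"))
}

#' Run a function against a store resolved by name, path or handle
#'
#' Exactly one of `db` (a name resolving to `data/sql/<db>.sqlite` under the
#' workspace root), `db_filepath` (an explicit path) or `store` (an
#' already-open handle) must be given. For name/path forms the connection is
#' opened internally and closed again afterwards — callers never manage the
#' lifecycle. A handle passed in stays open.
#'
#' @param db Store name (without the `.sqlite` suffix).
#' @param db_filepath Explicit path to a store file.
#' @param store Open store handle.
#' @param root Workspace root.
#' @param fun Function of one argument (the open handle).
#'
#' @return The value of `fun`.
#' @export
with_store <- function(db = NULL, db_filepath = NULL, store = NULL,
                       root = ".", fun) {
  given <- c(!is.null(db), !is.null(db_filepath), !is.null(store))
  if (sum(given) != 1L) {
    stop("give exactly one of db (name), db_filepath, or store (open handle)",
         call. = FALSE)
  }
  if (!is.null(store)) return(fun(store))
  path <- if (!is.null(db)) {
    file.path(workspace_layout(root)$sql_dir, paste0(db, ".sqlite"))
  } else {
    db_filepath
  }
  if (!file.exists(path)) {
    stop(sprintf("store file not found: %s", path), call. = FALSE)
  }
  handle <- connect_database(path)
  on.exit(close_database(handle), add = TRUE)
  fun(handle)
}

#' Save an extracted variable to the workspace
#'
#' Writes a per-patient variable table as CSV. Without an explicit
#' `out_filepath` the file goes to
#' `data/extraction/var_<varname>[_t<t>].csv` under the workspace root; the
#' offset `t` is embedded in the filename (when nonzero) so longitudinal
#' extractions at different offsets do not overwrite each other.
#'
#' @param result The variable table.
#' @param varname Variable name used in the filename.
#' @param t Index-date offset in days (default 0).
#' @param out_filepath Explicit output path; overrides the convention.
#' @param root Workspace root.
#'
#' @return The path written, invisibly.
#' @export
save_variable <- function(result, varname, t = 0, out_filepath = NULL,
                          root = ".") {
  if (is.null(out_filepath)) {
    dir <- workspace_layout(root)$extraction_dir
    if (!dir.exists(dir)) {
      stop(sprintf("directory %s does not exist; run create_directory_system() first",
                   dir), call. = FALSE)
    }
    suffix <- if (t != 0) sprintf("_t%g", t) else ""
    out_filepath <- file.path(dir, sprintf("var_%s%s.csv", varname, suffix))
  }
  fwrite(as.data.table(result), out_filepath)
  invisible(out_filepath)
}

#' Read a saved variable back from the workspace
#'
#' @inheritParams save_variable
#' @return The variable table as a `data.table`.
#' @export
read_variable <- function(varname, t = 0, root = ".") {
  suffix <- if (t != 0) sprintf("_t%g", t) else ""
  path <- file.path(workspace_layout(root)$extraction_dir,
                    sprintf("var_%s%s.csv", varname, suffix))
  if (!file.exists(path)) {
    stop(sprintf("no saved variable at %s", path), call. = FALSE)
  }
  fread(path, colClasses = list(character = "patid"))
}
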