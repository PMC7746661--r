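# canonical record-table columns, in output order
RECORD_COLUMNS <- c(
  "moth_family", "moth_genus", "moth_species", "plant_name_raw",
  "plant_genus", "plant_species", "plant_family", "plant_order",
  "plant_group", "source", "setting"
)

REQUIRED_INPUT_COLUMNS <- c("moth_species", "plant_name_raw", "source", "setting")

#' Construct a record table
#'
#' A record table is a tibble with one row per source observation of a
#' caterpillar feeding on a plant, carrying the moth identity, the verbatim
#' plant name (and, after [resolve_records()], the resolved plant lineage),
#' the source database tag and the observation setting (`"wild"` or
#' `"captive"`). Source provenance (tag ids and free-text descriptions) is
#' kept in the `"sources"` attribute and is preserved by all record-table
#' operations.
#'
#' @param df data frame holding at least `moth_species`, `plant_name_raw`,
#'   `source` and `setting` columns. `setting` values are normalised:
#'   `"captive_or_introduced"` and `"introduced"` are mapped to `"captive"`.
#' @param sources optional tibble with columns `id`, `description`
#'   describing each source tag; defaults to the distinct tags present.
#' @return a `record_table` tibble.
#' @export
record_table <- function(df, sources = NULL) {
  df <- tibble::as_tibble(df)
  missing <- setdiff(REQUIRED_INPUT_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("record table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"moth_genus" %in% names(df)) {
    df$moth_genus <- first_token(df$moth_species)
  }
  if (!"moth_family" %in% names(df)) df$moth_family <- NA_character_
  if (!"questionable" %in% names(df)) df$questionable <- FALSE
  df$questionable[is.na(df$questionable)] <- FALSE
  df$setting <- normalize_setting(df$setting)
  if (any(is.na(df$setting))) {
    stop("setting must be 'wild' or 'captive' for every record", call. = FALSE)
  }
  if (any(is.na(df$plant_name_raw) | trimws(df$plant_name_raw) == "")) {
    stop("plant_name_raw must be non-empty for every record", call. = FALSE)
  }
  if (is.null(sources)) {
    sources <- tibble::tibble(id = unique(as.character(df$source)),
                              description = NA_character_)
  }
  sources <- tibble::as_tibble(sources)
  stopifnot(all(c("id", "description") %in% names(sources)))
  if (anyDuplicated(sources$id)) {
    stop("duplicate source tag id in provenance", call. = FALSE)
  }
  orphan <- setdiff(unique(as.character(df$source)), sources$id)
  if (length(orphan) > 0) {
    stop("records reference source tag(s) absent from provenance: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  new_record_table(df, sources)
}

new_record_table <- function(df, sources) {
  df <- tibble::as_tibble(df)
  attr(df, "sources") <- tibble::as_tibble(sources)
  class(df) <- unique(c("record_table", class(df)))
  df
}

#' Source provenance of a record table
#' @param table a record table.
#' @return tibble with columns `id`, `description`.
#' @export
record_sources <- function(table) {
  src <- attr(table, "sources")
  if (is.null(src)) {
    src <- tibble::tibble(id = unique(as.character(table$source)),
                          description = NA_character_)
  }
  src
}

normalize_setting <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("captive_or_introduced", "introduced", "captivity")] <- "captive"
  x[!x %in% c("wild", "captive")] <- NA_character_
  x
}

first_token <- function(x) {
  stringr::str_split_i(stringr::str_squish(as.character(x)), stringr::fixed(" "), 1)
}

#' Read a food-plant record table from disk
#'
#' Reads a CSV, TSV or XLSX table of source records, one row per observation.
#' Column names in the file are mapped to the canonical schema through
#' `mapping`, so the three source databases' differing headers can all be
#' ingested without positional assumptions. The verbatim plant name is
#' preserved unaltered and row order is kept.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"csv"`, `"tsv"` or `"xlsx"`.
#' @param mapping named character vector mapping canonical column names
#'   (`moth_species`, `plant_name_raw`, `source`, `setting`, optionally
#'   `moth_family`, `moth_genus`, `questionable`) to the file's column
#'   names. Canonical names present in the file need not be mapped.
#' @param source if the file lacks a source column, a single tag id applied
#'   to every row.
#' @param source_description optional free-text description of that tag.
#' @return a [record_table()].
#' @export
read_record_table <- function(path, dialect = c("auto", "csv", "tsv", "xlsx"),
                              mapping = NULL, source = NULL,
                              source_description = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, tsv = "tsv", tab = "tsv",
                      xlsx = "xlsx", xls = "xlsx", "csv")
  }
  df <- switch(dialect,
    csv  = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    tsv  = readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    xlsx = readxl::read_excel(path)
  )
  df <- tibble::as_tibble(df)
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      file_col <- mapping[[canon]]
      if (!file_col %in% names(df)) {
        stop("mapped column '", file_col, "' (for '", canon,
             "') not found in ", path, call. = FALSE)
      }
      df[[canon]] <- df[[file_col]]
    }
  }
  if (!is.null(source) && !"source" %in% names(df)) {
    df$source <- as.character(source)
  }
  missing <- setdiff(REQUIRED_INPUT_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("input ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "),
         " (use `mapping` to point at the file's headers)", call. = FALSE)
  }
  sources <- tibble::tibble(id = unique(as.character(df$source)),
                            description = source_description)
  record_table(df, sources = sources)
}

#' Write a record table to CSV
#'
#' Writes the canonical fixed column order (moth ranks, verbatim and
#' resolved plant identity, source, setting). Resolved-plant columns are
#' written as empty strings when resolution has not been run.
#'
#' @param table a record table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_record_table <- function(table, path) {
  df <- tibble::as_tibble(table)
  for (col in RECORD_COLUMNS) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  readr::write_csv(df[RECORD_COLUMNS], path, na = "")
  invisible(path)
}

#' Merge record tables from several sources
#'
#' Concatenates record tables while keeping every source tag: the same
#' (moth, plant) association reported by two sources yields two records,
#' because a record is defined as a unique combination of caterpillar,
#' plant and source. No deduplication happens at this stage. Provenance is
#' the union of the inputs' provenance; the same tag id appearing with two
#' different descriptions is a conflict and raises an error.
#'
#' @param tables list of record tables (may include empty tables).
#' @return a single record table.
#' @export
merge_sources <- function(tables) {
  if (!is.list(tables) || length(tables) == 0) {
    stop("`tables` must be a non-empty list of record tables", call. = FALSE)
  }
  srcs <- dplyr::distinct(dplyr::bind_rows(lapply(tables, record_sources)))
  dup <- srcs$id[duplicated(srcs$id)]
  if (length(dup) > 0) {
    stop("source tag id(s) used with conflicting descriptions: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  df <- dplyr::bind_rows(lapply(tables, tibble::as_tibble))
  new_record_table(df, srcs)
}

record_key <- function(table) {
  df <- tibble::as_tibble(table)
  plant_id <- if ("plant_resolved" %in% names(df)) {
    # finest resolved rank: species if present, else genus; unresolved
    # names fall back to the normalised verbatim string
    dplyr::case_when(
      !is.na(df$plant_species) ~ paste0("sp:", df$plant_species),
      !is.na(df$plant_genus)   ~ paste0("gen:", df$plant_genus),
      TRUE                     ~ paste0("raw:", normalize_name(df$plant_name_raw))
    )
  } else {
    paste0("raw:", normalize_name(df$plant_name_raw))
  }
  paste(df$moth_species, plant_id, df$source, df$setting, sep = "\x1f")
}

#' Deduplicate records on the (moth, plant, source, setting) key
#'
#' Collapses the table to one record per unique combination of moth
#' species, plant identity at the finest resolved rank (species if
#' resolved, else genus, else the normalised verbatim name), source tag
#' and setting. A wild and a captive observation of the same association
#' are both kept, as are observations of the same association in different
#' sources. The first occurrence of each key is retained, so the operation
#' is idempotent and order-stable.
#'
#' @param table a record table, ideally after [resolve_records()].
#' @return the deduplicated record table.
#' @export
dedupe_records <- function(table) {
  keep <- !duplicated(record_key(table))
  new_record_table(tibble::as_tibble(table)[keep, , drop = FALSE],
                   record_sources(table))
}

#' Split a record table into wild and captive parts
#'
#' Records from rearing in captivity or on introduced plants do not
#' represent natural associations and are kept separate throughout.
#'
#' @param table a record table.
#' @return named list with record tables `wild` and `captive`; their row
#'   counts always sum to the input's.
#' @export
partition_by_setting <- function(table) {
  df <- tibble::as_tibble(table)
  src <- record_sources(table)
  list(
    wild    = new_record_table(df[df$setting == "wild", , drop = FALSE], src),
    captive = new_record_table(df[df$setting == "captive", , drop = FALSE], src)
  )
}

#' Drop records flagged as questionable
#'
#' Source records recognised as questionable (for example inconsistent
#' locality or identification data) carry `questionable = TRUE` and are
#' removed before any analysis; the flag defaults to `FALSE` when a source
#' table has no such column.
#'
#' @param table a record table.
#' @param quiet suppress the message reporting how many records were dropped.
#' @return the filtered record table.
#' @export
drop_questionable <- function(table, quiet = FALSE) {
  df <- tibble::as_tibble(table)
  flagged <- isTRUE_vec(df$questionable)
  if (!quiet && any(flagged)) {
    message("dropped ", sum(flagged), " questionable record(s)")
  }
  new_record_table(df[!flagged, , drop = FALSE], record_sources(table))
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
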