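#' Run the full dataset build
#'
#' Orchestrates the whole pipeline: merge the per-source record tables,
#' drop questionable records, resolve plant and moth names, deduplicate on
#' the (moth, plant, source, setting) key, partition wild vs captive,
#' build the per-species (21-column) and per-genus (13-column) summary
#' tables and the per-species polyphagy scores. An audit table records
#' counts at every stage so runs are self-documenting and checkable
#' (records read per source, questionable dropped, unresolved names,
#' records kept after deduplication, wild/captive split, output row
#' counts, families missing from the tree).
#'
#' @param tables list of record tables (one per source), e.g. from
#'   [read_record_table()] or [simulate_dataset()].
#' @param lookup a [plant_lookup()].
#' @param checklist moth checklist tibble.
#' @param tree dated family-level phylogeny ([ape::phylo]); `NULL` skips
#'   the PD stage (the score column is left empty).
#' @param include_root root convention for [faith_pd()].
#' @param filter_questionable drop records flagged questionable first.
#' @return list with `ds1`, `ds2`, `pd` (per-species PD table), `records`
#'   (the resolved, deduplicated record table) and `audit`.
#' @export
build_dataset <- function(tables, lookup, checklist, tree = NULL,
                          include_root = TRUE, filter_questionable = TRUE) {
  merged <- merge_sources(tables)
  audit <- tibble::tibble(stage = "records_read_total", n = nrow(merged))
  per_src <- dplyr::count(tibble::as_tibble(merged), .data$source)
  audit <- dplyr::bind_rows(audit, tibble::tibble(
    stage = paste0("records_read_", per_src$source), n = per_src$n))

  flt <- if (filter_questionable) drop_questionable(merged, quiet = TRUE) else merged
  audit <- add_stage(audit, "questionable_dropped", nrow(merged) - nrow(flt))

  res <- resolve_records(flt, lookup, checklist)
  audit <- add_stage(audit, "plant_names_unresolved", sum(!res$plant_resolved))
  audit <- add_stage(audit, "moth_genera_not_in_checklist",
                     length(unique(res$moth_genus[!res$checklist_matched])))

  dd <- dedupe_records(res)
  audit <- add_stage(audit, "records_after_dedup", nrow(dd))
  parts <- partition_by_setting(dd)
  audit <- add_stage(audit, "records_wild", nrow(parts$wild))
  audit <- add_stage(audit, "records_captive", nrow(parts$captive))

  ds1 <- build_ds1(dd, checklist)
  audit <- add_stage(audit, "species_rows", nrow(ds1))

  pd <- NULL
  pd_scores <- NULL
  n_missing <- 0L
  if (!is.null(tree) && nrow(ds1) > 0) {
    pd <- withCallingHandlers(
      pd_table(ds1, tree, lookup, include_root = include_root),
      warning = function(w) invokeRestart("muffleWarning"))
    n_missing <- sum(pd$n_families_missing > 0)
    pd_scores <- setNames(pd$pd, pd$moth_species)
  }
  audit <- add_stage(audit, "species_with_families_missing_from_tree", n_missing)

  ds2 <- build_ds2(ds1, checklist, pd_scores)
  audit <- add_stage(audit, "genus_rows", nrow(ds2))

  list(ds1 = ds1, ds2 = ds2, pd = pd, records = dd, audit = audit)
}

add_stage <- function(audit, stage, n) {
  dplyr::bind_rows(audit, tibble::tibble(stage = stage, n = as.integer(n)))
}

#' Recompute polyphagy scores from a per-species table alone
#'
#' Computes per-species Faith's PD and the per-genus score column from an
#' existing 21-column per-species table — no raw records needed. The
#' table's header is validated first; a mismatch raises a named-column
#' error.
#'
#' @param ds1 per-species table ([build_ds1()] schema).
#' @param tree dated family-level phylogeny.
#' @param lookup a [plant_lookup()].
#' @param include_root root convention for [faith_pd()].
#' @param checklist optional moth checklist for the per-genus table.
#' @return list with `pd` (per-species PD table) and `ds2` (per-genus
#'   table with the recomputed score column).
#' @export
pd_from_ds1 <- function(ds1, tree, lookup, include_root = TRUE,
                        checklist = NULL) {
  validate_ds1(ds1)
  pd <- pd_table(ds1, tree, lookup, include_root = include_root)
  ds2 <- build_ds2(ds1, checklist, setNames(pd$pd, pd$moth_species))
  list(pd = pd, ds2 = ds2)
}

#' Write build outputs to a directory
#'
#' @param result list from [build_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_build_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_summary_csv(result$ds1, file.path(dir, "ds1_species.csv"))
  write_summary_csv(result$ds2, file.path(dir, "ds2_genera.csv"))
  if (!is.null(result$pd)) {
    write_summary_csv(result$pd, file.path(dir, "pd_species.csv"))
  }
  write_record_table(result$records, file.path(dir, "records_clean.csv"))
  readr::write_csv(result$audit, file.path(dir, "audit_log.csv"))
  invisible(dir)
}
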