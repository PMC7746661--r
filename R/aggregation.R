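# deposited-table headers, verbatim
DS1_COLUMNS <- c(
  "Family", "Subfamily", "Tribe", "Moth_Genus_name", "Moth_Species_Name",
  "Number_PlantGenus", "Plant_GenusNames",
  "Number_PlantSpecies", "Plant_SpeciesNames",
  "Number_PlantFamily", "Plant_FamilyNames",
  "Number_PlantOrders", "Plant_OrderNames",
  "Number_PlantGenus_Capt", "Plant_GenusNames_Capt",
  "Number_PlantSpecies_Capt", "Plant_SpeciesNames_Capt",
  "Number_PlantFamily_Capt", "Plant_FamilyNames_Capt",
  "Number_PlantOrders_Capt", "Plant_OrderNames_Capt"
)

DS2_COLUMNS <- c(
  "Family", "Subfamily", "Tribe", "Moth_Genus_Name",
  "NumberSampledMothSpecies", "TotalMothSpecies",
  "TotalNumberGenus", "AverageNumberGenus",
  "TotalNumberFamilies", "AverageNumberFamilies",
  "TotalNumberOrders", "AverageNumberOrders", "PD_score"
)

NAME_DELIM <- "; "

name_list <- function(x) {
  x <- sort(unique(x[!is.na(x)]))
  paste(x, collapse = NAME_DELIM)
}

#' Split a delimited name list back into a character vector
#' @param s a `"; "`-joined name list (length-1 character).
#' @return character vector (empty for an empty list).
#' @export
split_name_list <- function(s) {
  if (is.na(s) || s == "") return(character(0))
  strsplit(s, NAME_DELIM, fixed = TRUE)[[1]]
}

setting_stats <- function(df) {
  # distinct resolved names per rank; genus-only records contribute to
  # genus/family/order but, having no epithet, never to the species list
  list(
    n_genera = length(unique(df$plant_genus[!is.na(df$plant_genus)])),
    genera = name_list(df$plant_genus),
    n_species = length(unique(df$plant_species[!is.na(df$plant_species)])),
    species = name_list(df$plant_species),
    n_families = length(unique(df$plant_family[!is.na(df$plant_family)])),
    families = name_list(df$plant_family),
    n_orders = length(unique(df$plant_order[!is.na(df$plant_order)])),
    orders = name_list(df$plant_order)
  )
}

#' Summarise the food-plant breadth of one moth species
#'
#' Counts and lists the distinct plant genera, species, families and
#' orders eaten by a moth species, separately for wild and captive
#' records. Records must already be resolved and deduplicated; counting
#' is qualitative (distinct names, record frequency ignored). Name lists
#' are alphabetically sorted and joined with `"; "`.
#'
#' @param records a resolved record table.
#' @param moth_species the species to summarise; must have at least one
#'   record in `records`.
#' @return one-row tibble in the 21-column per-species schema (see
#'   [build_ds1()]).
#' @export
summarize_species <- function(records, moth_species) {
  df <- tibble::as_tibble(records)
  df <- df[df$moth_species == moth_species, , drop = FALSE]
  if (nrow(df) == 0) {
    stop("no records for moth species '", moth_species, "'", call. = FALSE)
  }
  w <- setting_stats(df[df$setting == "wild", , drop = FALSE])
  cp <- setting_stats(df[df$setting == "captive", , drop = FALSE])
  tibble::tibble(
    Family = df$moth_family[1], Subfamily = df$moth_subfamily[1],
    Tribe = df$moth_tribe[1],
    Moth_Genus_name = df$moth_genus[1], Moth_Species_Name = moth_species,
    Number_PlantGenus = w$n_genera, Plant_GenusNames = w$genera,
    Number_PlantSpecies = w$n_species, Plant_SpeciesNames = w$species,
    Number_PlantFamily = w$n_families, Plant_FamilyNames = w$families,
    Number_PlantOrders = w$n_orders, Plant_OrderNames = w$orders,
    Number_PlantGenus_Capt = cp$n_genera, Plant_GenusNames_Capt = cp$genera,
    Number_PlantSpecies_Capt = cp$n_species, Plant_SpeciesNames_Capt = cp$species,
    Number_PlantFamily_Capt = cp$n_families, Plant_FamilyNames_Capt = cp$families,
    Number_PlantOrders_Capt = cp$n_orders, Plant_OrderNames_Capt = cp$orders
  )
}

#' Build the per-species food-plant summary table
#'
#' One row per moth species with at least one (resolved, deduplicated)
#' record, 21 columns: moth ranks, then per-setting counts and sorted
#' name lists of the plant genera, species, families and orders eaten.
#' Wild and captive observations are summarised in separate column
#' blocks. Rows are sorted by moth family, genus, species.
#'
#' @param records a resolved, deduplicated record table.
#' @param checklist moth checklist tibble; used to fill higher moth ranks
#'   when the records were not resolved against it already.
#' @return tibble with the 21 per-species columns.
#' @export
build_ds1 <- function(records, checklist = NULL) {
  df <- tibble::as_tibble(records)
  if (!"plant_resolved" %in% names(df)) {
    stop("records must be resolved (see resolve_records()) before build_ds1()",
         call. = FALSE)
  }
  if (!"moth_subfamily" %in% names(df) && !is.null(checklist)) {
    moth <- resolve_moth(df$moth_species, checklist)
    df$moth_family <- moth$moth_family
    df$moth_subfamily <- moth$moth_subfamily
    df$moth_tribe <- moth$moth_tribe
  }
  species <- unique(df$moth_species)
  if (length(species) == 0) return(empty_ds1())
  out <- dplyr::bind_rows(lapply(species, function(sp) summarize_species(df, sp)))
  dplyr::arrange(out, .data$Family, .data$Moth_Genus_name, .data$Moth_Species_Name)
}

empty_ds1 <- function() {
  cols <- lapply(DS1_COLUMNS, function(nm) {
    if (startsWith(nm, "Number_")) integer(0) else character(0)
  })
  tibble::as_tibble(setNames(cols, DS1_COLUMNS))
}

species_sampled_wild <- function(ds1) {
  # a species counts as sampled when it has at least one wild record that
  # resolved at any rank
  ds1$Number_PlantGenus > 0 | ds1$Number_PlantFamily > 0 |
    ds1$Number_PlantSpecies > 0 | ds1$Number_PlantOrders > 0
}

union_count <- function(lists) {
  length(unique(unlist(lapply(lists, split_name_list))))
}

#' Summarise the food-plant breadth of one moth genus
#'
#' Aggregates per-species rows into the per-genus schema: totals are the
#' cardinality of the union of per-species wild name sets (never sums),
#' averages are arithmetic means of per-species wild counts over sampled
#' species, and the polyphagy score is the mean of the defined per-species
#' phylogenetic diversity values. Species known only from captivity are
#' not counted as sampled and do not enter the statistics, which are all
#' defined on natural-environment records.
#'
#' @param ds1_rows per-species rows ([build_ds1()] schema) of one genus.
#' @param total_species described species count for the genus (checklist);
#'   `NA` if unknown.
#' @param pd_scores named numeric vector of per-species PD scores (`NA`
#'   where undefined, e.g. gymnosperm-only diets); names are moth species.
#' @return one-row tibble in the 13-column per-genus schema.
#' @export
summarize_genus <- function(ds1_rows, total_species = NA_integer_,
                            pd_scores = NULL) {
  if (nrow(ds1_rows) == 0) stop("empty per-species input", call. = FALSE)
  g <- ds1_rows$Moth_Genus_name[1]
  sampled <- ds1_rows[species_sampled_wild(ds1_rows), , drop = FALSE]
  n_sampled <- nrow(sampled)
  if (!is.na(total_species) && n_sampled > total_species) {
    warning("genus ", g, ": ", n_sampled,
            " sampled species exceed checklist total ", total_species,
            call. = FALSE)
  }
  pd <- if (is.null(pd_scores)) NA_real_ else {
    vals <- pd_scores[sampled$Moth_Species_Name]
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }
  avg_or_na <- function(x) if (n_sampled == 0) NA_real_ else mean(x)
  tibble::tibble(
    Family = ds1_rows$Family[1], Subfamily = ds1_rows$Subfamily[1],
    Tribe = ds1_rows$Tribe[1], Moth_Genus_Name = g,
    NumberSampledMothSpecies = n_sampled,
    TotalMothSpecies = as.integer(total_species),
    TotalNumberGenus = union_count(sampled$Plant_GenusNames),
    AverageNumberGenus = avg_or_na(sampled$Number_PlantGenus),
    TotalNumberFamilies = union_count(sampled$Plant_FamilyNames),
    AverageNumberFamilies = avg_or_na(sampled$Number_PlantFamily),
    TotalNumberOrders = union_count(sampled$Plant_OrderNames),
    AverageNumberOrders = avg_or_na(sampled$Number_PlantOrders),
    PD_score = pd
  )
}

#' Build the per-genus polyphagy table
#'
#' One row per moth genus with at least one sampled species (a species
#' with wild records), 13 columns: moth ranks, sampling coverage
#' (sampled vs described species), total and average plant-taxon breadth
#' at genus/family/order rank over wild records, and the genus polyphagy
#' score (mean per-species Faith's PD). Genera absent from the checklist
#' get an empty described-species count and a warning.
#'
#' @param ds1 per-species table from [build_ds1()].
#' @param checklist moth checklist tibble (`genus`, `total_species`, ...).
#' @param pd_scores named numeric vector of per-species PD scores, e.g.
#'   from [pd_table()]; `NULL` leaves the score column empty.
#' @return tibble with the 13 per-genus columns, sorted by family, genus.
#' @export
build_ds2 <- function(ds1, checklist = NULL, pd_scores = NULL) {
  keep <- species_sampled_wild(ds1)
  ds1 <- ds1[keep, , drop = FALSE]
  if (nrow(ds1) == 0) return(empty_ds2())
  genera <- unique(ds1$Moth_Genus_name)
  totals <- if (is.null(checklist)) {
    setNames(rep(NA_integer_, length(genera)), genera)
  } else {
    tt <- setNames(as.integer(checklist$total_species[
      match(genera, checklist$genus)]), genera)
    if (any(is.na(tt))) {
      warning("genus(era) missing from checklist: ",
              paste(genera[is.na(tt)], collapse = ", "), call. = FALSE)
    }
    tt
  }
  out <- dplyr::bind_rows(lapply(genera, function(g) {
    summarize_genus(ds1[ds1$Moth_Genus_name == g, , drop = FALSE],
                    total_species = totals[[g]], pd_scores = pd_scores)
  }))
  dplyr::arrange(out, .data$Family, .data$Moth_Genus_Name)
}

empty_ds2 <- function() {
  tibble::tibble(
    Family = character(), Subfamily = character(), Tribe = character(),
    Moth_Genus_Name = character(), NumberSampledMothSpecies = integer(),
    TotalMothSpecies = integer(), TotalNumberGenus = integer(),
    AverageNumberGenus = double(), TotalNumberFamilies = integer(),
    AverageNumberFamilies = double(), TotalNumberOrders = integer(),
    AverageNumberOrders = double(), PD_score = double())
}

#' Validate a per-species (21-column) summary table
#'
#' Checks the header verbatim and the internal count/list consistency:
#' every count equals the length of its name list, families never
#' outnumber genera, orders never outnumber families.
#'
#' @param ds1 a data frame to check.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_ds1 <- function(ds1) {
  if (!identical(names(ds1), DS1_COLUMNS)) {
    bad <- setdiff(DS1_COLUMNS, names(ds1))
    stop("per-species table header mismatch",
         if (length(bad)) paste0("; missing: ", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  pairs <- list(
    c("Number_PlantGenus", "Plant_GenusNames"),
    c("Number_PlantSpecies", "Plant_SpeciesNames"),
    c("Number_PlantFamily", "Plant_FamilyNames"),
    c("Number_PlantOrders", "Plant_OrderNames"),
    c("Number_PlantGenus_Capt", "Plant_GenusNames_Capt"),
    c("Number_PlantSpecies_Capt", "Plant_SpeciesNames_Capt"),
    c("Number_PlantFamily_Capt", "Plant_FamilyNames_Capt"),
    c("Number_PlantOrders_Capt", "Plant_OrderNames_Capt"))
  for (pr in pairs) {
    lens <- vapply(ds1[[pr[2]]], function(s) length(split_name_list(s)), integer(1))
    if (!all(ds1[[pr[1]]] == lens)) {
      stop("count column ", pr[1], " disagrees with its name list", call. = FALSE)
    }
  }
  if (any(ds1$Number_PlantFamily > ds1$Number_PlantGenus)) {
    stop("more plant families than genera in a row", call. = FALSE)
  }
  if (any(ds1$Number_PlantOrders > ds1$Number_PlantFamily)) {
    stop("more plant orders than families in a row", call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a per-genus (13-column) summary table
#'
#' Checks the header verbatim and that averages never exceed totals.
#'
#' @param ds2 a data frame to check.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_ds2 <- function(ds2) {
  if (!identical(names(ds2), DS2_COLUMNS)) {
    stop("per-genus table header mismatch", call. = FALSE)
  }
  tol <- 1e-9
  for (rk in c("Genus", "Families", "Orders")) {
    tot <- ds2[[paste0("TotalNumber", rk)]]
    avg <- ds2[[paste0("AverageNumber", rk)]]
    if (any(!is.na(avg) & avg > tot + tol)) {
      stop("average exceeds total for plant ", tolower(rk), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a summary table to CSV
#'
#' Real-valued columns are written with 6 significant digits; undefined
#' values (e.g. PD of a gymnosperm-only genus) become empty cells.
#'
#' @param x a per-species or per-genus summary table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(x, path) {
  x <- dplyr::mutate(x, dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
  readr::write_csv(x, path, na = "")
  invisible(path)
}
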