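# rank qualifiers that mark a genus-only determination; matched after
# case-folding, with or without the trailing dot
RANK_QUALIFIERS <- c("sp", "spp", "cf", "aff", "nr", "near", "sp.nr")

#' Normalise a scientific plant or moth name
#'
#' Canonicalises verbatim name strings before any lookup: whitespace is
#' squashed, hybrid markers removed, the genus is capitalised and the
#' specific epithet lower-cased, and everything after the binomial
#' (author citations, subspecific epithets, qualifiers) is dropped. A
#' second token is accepted as an epithet only when it is written entirely
#' in lower case letters; capitalised or punctuated tokens are author
#' citations, so `"Quercus L."` normalises to the genus alone. Rank
#' qualifiers (`sp.`, `cf.`, `aff.` ...) likewise yield a genus-only name.
#' The function is idempotent.
#'
#' @param x character vector of verbatim names.
#' @return character vector of canonical names (`"Genus"` or
#'   `"Genus epithet"`); `NA` where nothing remains after normalisation.
#'   See [parse_plant_name()] to also recover the genus-only flag.
#' @export
normalize_name <- function(x) {
  parse_plant_name(x)$name
}

#' Parse a verbatim plant name into canonical form plus flags
#'
#' @param x character vector of verbatim names.
#' @return tibble with columns `raw` (input), `name` (canonical name or
#'   `NA`), `genus` (canonical genus or `NA`), `epithet` (species epithet
#'   or `NA`), `genus_only` (no usable epithet), and `unresolvable`
#'   (nothing left after normalisation).
#' @export
parse_plant_name <- function(x) {
  x <- as.character(x)
  squished <- stringr::str_squish(stringr::str_replace_all(
    x, stringr::fixed("×"), " "))
  # drop a leading latin hybrid marker token ("x Sorbaronia" style)
  squished <- stringr::str_remove(squished, "^[xX]\\s+")
  squished <- stringr::str_squish(squished)

  out <- tibble::tibble(
    raw = x,
    name = NA_character_, genus = NA_character_, epithet = NA_character_,
    genus_only = TRUE, unresolvable = FALSE
  )
  empty <- is.na(squished) | squished == ""
  out$unresolvable <- empty

  tokens <- stringr::str_split(squished, stringr::fixed(" "))
  genus_raw <- vapply(tokens, function(t) if (length(t) >= 1) t[[1]] else NA_character_,
                      character(1))
  second <- vapply(tokens, function(t) if (length(t) >= 2) t[[2]] else NA_character_,
                   character(1))

  genus <- ifelse(empty, NA_character_, capitalize_genus(genus_raw))
  is_qualifier <- !is.na(second) &
    tolower(stringr::str_remove(second, "\\.$")) %in% RANK_QUALIFIERS
  # an epithet must be all lower-case letters (hyphens allowed) as written
  is_epithet <- !is.na(second) & !is_qualifier &
    stringr::str_detect(second, "^[a-z][a-z-]+$")

  out$genus <- genus
  out$epithet <- ifelse(is_epithet, second, NA_character_)
  out$genus_only <- !is_epithet
  out$name <- ifelse(empty, NA_character_,
                     ifelse(is_epithet, paste(genus, second), genus))
  out
}

capitalize_genus <- function(g) {
  paste0(toupper(substr(g, 1, 1)), tolower(substr(g, 2, nchar(g))))
}

#' Build a plant taxonomy lookup
#'
#' The lookup is a local stand-in for a nomenclatural service: a table of
#' accepted plant genera with their family, order and major group
#' (angiosperm or gymnosperm), plus an optional synonym map from raw
#' (normalised) names to accepted names. Within one lookup the
#' genus-to-family and family-to-order maps must be functional, and every
#' family must carry a group.
#'
#' @param taxa data frame with columns `genus`, `family`, `order`, `group`
#'   (values `"angiosperm"` or `"gymnosperm"`).
#' @param synonyms optional data frame with columns `raw_name`,
#'   `accepted_name` (both canonical-form names).
#' @return a `plant_lookup` object.
#' @export
plant_lookup <- function(taxa, synonyms = NULL) {
  taxa <- tibble::as_tibble(taxa)
  stopifnot(all(c("genus", "family", "order", "group") %in% names(taxa)))
  taxa <- dplyr::distinct(taxa[, c("genus", "family", "order", "group")])
  if (!all(taxa$group %in% c("angiosperm", "gymnosperm"))) {
    stop("plant group must be 'angiosperm' or 'gymnosperm'", call. = FALSE)
  }
  if (anyDuplicated(taxa$genus)) {
    stop("lookup maps a genus to more than one family: ",
         paste(unique(taxa$genus[duplicated(taxa$genus)]), collapse = ", "),
         call. = FALSE)
  }
  fam <- dplyr::distinct(taxa[, c("family", "order", "group")])
  if (anyDuplicated(fam$family)) {
    stop("lookup maps a family to more than one order or group", call. = FALSE)
  }
  if (is.null(synonyms)) {
    synonyms <- tibble::tibble(raw_name = character(), accepted_name = character())
  }
  synonyms <- tibble::as_tibble(synonyms)
  stopifnot(all(c("raw_name", "accepted_name") %in% names(synonyms)))
  structure(list(taxa = taxa, families = fam,
                 synonyms = synonyms[, c("raw_name", "accepted_name")]),
            class = "plant_lookup")
}

#' Read a plant lookup from CSV files
#'
#' @param path CSV with columns `genus,family,order,group`.
#' @param synonyms_path optional CSV with columns `raw_name,accepted_name`.
#' @return a [plant_lookup()].
#' @export
read_plant_lookup <- function(path, synonyms_path = NULL) {
  taxa <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  syn <- if (!is.null(synonyms_path)) {
    readr::read_csv(synonyms_path, show_col_types = FALSE, progress = FALSE)
  }
  plant_lookup(taxa, syn)
}

#' @export
print.plant_lookup <- function(x, ...) {
  cat("<plant_lookup>", nrow(x$taxa), "genera in", nrow(x$families),
      "families;", nrow(x$synonyms), "synonym(s)\n")
  invisible(x)
}

#' Resolve verbatim plant names against a lookup
#'
#' Names are normalised ([parse_plant_name()]), synonym-mapped (first on
#' the full canonical name, then on the genus token alone) and looked up
#' by genus. Genus-only names resolve to a lineage without a species;
#' names whose genus is unknown to the lookup stay unresolved — an
#' unresolved name is a value, not an error, and callers report rather
#' than drop it silently.
#'
#' @param raw character vector of verbatim plant names.
#' @param lookup a [plant_lookup()].
#' @return tibble with one row per input: `plant_name_raw`, `plant_genus`,
#'   `plant_species`, `plant_family`, `plant_order`, `plant_group`,
#'   `plant_resolved` (logical).
#' @export
resolve_plant <- function(raw, lookup) {
  stopifnot(inherits(lookup, "plant_lookup"))
  p <- parse_plant_name(raw)

  # synonym pass on the full canonical name, then on the genus alone
  syn <- lookup$synonyms
  if (nrow(syn) > 0) {
    hit <- match(p$name, syn$raw_name)
    repl <- !is.na(hit)
    if (any(repl)) {
      rep_parsed <- parse_plant_name(syn$accepted_name[hit[repl]])
      p$name[repl] <- rep_parsed$name
      p$genus[repl] <- rep_parsed$genus
      p$epithet[repl] <- rep_parsed$epithet
      p$genus_only[repl] <- rep_parsed$genus_only
    }
    ghit <- match(p$genus, syn$raw_name)
    grepl_ <- !is.na(ghit) & !repl
    if (any(grepl_)) {
      new_gen <- parse_plant_name(syn$accepted_name[ghit[grepl_]])$genus
      p$genus[grepl_] <- new_gen
      p$name[grepl_] <- ifelse(is.na(p$epithet[grepl_]), new_gen,
                               paste(new_gen, p$epithet[grepl_]))
    }
  }

  idx <- match(p$genus, lookup$taxa$genus)
  resolved <- !is.na(idx)
  tibble::tibble(
    plant_name_raw = p$raw,
    plant_genus = ifelse(resolved, p$genus, NA_character_),
    plant_species = ifelse(resolved & !p$genus_only, p$name, NA_character_),
    plant_family = lookup$taxa$family[idx],
    plant_order = lookup$taxa$order[idx],
    plant_group = lookup$taxa$group[idx],
    plant_resolved = resolved
  )
}

#' Read a moth checklist from CSV
#'
#' @param path CSV with columns `family,subfamily,tribe,genus,total_species`;
#'   `total_species` is the number of described species in the genus.
#' @return tibble checklist.
#' @export
read_moth_checklist <- function(path) {
  cl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("family", "subfamily", "tribe", "genus", "total_species")
                %in% names(cl)))
  if (anyDuplicated(cl$genus)) {
    stop("moth checklist lists a genus more than once", call. = FALSE)
  }
  tibble::as_tibble(cl)
}

#' Resolve moth species names against a checklist
#'
#' The moth genus is the first token of the (normalised) species binomial;
#' family, subfamily and tribe are filled from the checklist. Genera
#' absent from the checklist are flagged and kept with empty higher ranks
#' rather than dropped.
#'
#' @param species character vector of moth species binomials.
#' @param checklist tibble from [read_moth_checklist()] (or equivalent).
#' @return tibble with `moth_species`, `moth_genus`, `moth_family`,
#'   `moth_subfamily`, `moth_tribe`, `checklist_matched`.
#' @export
resolve_moth <- function(species, checklist) {
  species <- stringr::str_squish(as.character(species))
  genus <- capitalize_genus(first_token(species))
  idx <- match(genus, checklist$genus)
  tibble::tibble(
    moth_species = species,
    moth_genus = genus,
    moth_family = checklist$family[idx],
    moth_subfamily = checklist$subfamily[idx],
    moth_tribe = checklist$tribe[idx],
    checklist_matched = !is.na(idx)
  )
}

#' Keep only angiosperm families
#'
#' Polyphagy scores are computed on an angiosperm phylogeny, so gymnosperm
#' families are removed from a family set before any phylogenetic
#' diversity calculation; the large phylogenetic distance between
#' angiosperms and gymnosperms would otherwise dominate the score.
#' Families unknown to the lookup pass through with a warning.
#'
#' @param families character vector (or set) of plant family names.
#' @param lookup a [plant_lookup()].
#' @return the angiosperm subset of `families`.
#' @export
exclude_gymnosperm_families <- function(families, lookup) {
  stopifnot(inherits(lookup, "plant_lookup"))
  families <- unique(as.character(families))
  idx <- match(families, lookup$families$family)
  unknown <- families[is.na(idx)]
  if (length(unknown) > 0) {
    warning("family(ies) not in lookup, passed through: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  grp <- lookup$families$group[idx]
  families[is.na(idx) | grp == "angiosperm"]
}

#' Resolve plant and moth identities for every record
#'
#' Adds resolved plant lineage columns and checklist-derived moth ranks to
#' a record table. Unresolved plant names are retained (flagged
#' `plant_resolved = FALSE`) so they can be reported; they are excluded
#' from breadth counts downstream.
#'
#' @param table a record table.
#' @param lookup a [plant_lookup()].
#' @param checklist a moth checklist tibble.
#' @return the record table with resolution columns added.
#' @export
resolve_records <- function(table, lookup, checklist) {
  df <- tibble::as_tibble(table)
  plant <- resolve_plant(df$plant_name_raw, lookup)
  moth <- resolve_moth(df$moth_species, checklist)
  df$moth_species <- moth$moth_species
  df$moth_genus <- moth$moth_genus
  df$moth_family <- moth$moth_family
  df$moth_subfamily <- moth$moth_subfamily
  df$moth_tribe <- moth$moth_tribe
  df$checklist_matched <- moth$checklist_matched
  df$plant_genus <- plant$plant_genus
  df$plant_species <- plant$plant_species
  df$plant_family <- plant$plant_family
  df$plant_order <- plant$plant_order
  df$plant_group <- plant$plant_group
  df$plant_resolved <- plant$plant_resolved
  new_record_table(df, record_sources(table))
}
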