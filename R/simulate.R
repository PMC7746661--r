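# run an expression under a temporary seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

int_to_letters <- function(i) {
  # bijective base-26 over a..z, so epithets stay all-letters
  vapply(i, function(n) {
    out <- character(0)
    while (n > 0) {
      r <- (n - 1) %% 26
      out <- c(letters[r + 1], out)
      n <- (n - 1) %/% 26
    }
    paste(out, collapse = "")
  }, character(1))
}

#' Configuration for the synthetic dataset generator
#'
#' Defines the study conditions the generator emulates: a plant taxonomy
#' of `n_plant_families` families (with a dated pure-birth phylogeny over
#' them) and `n_plant_genera` genera, a moth checklist of `n_moth_genera`
#' genera and `n_moth_species` species, and `n_sources` overlapping record
#' sources. Each moth species draws a host breadth of
#' `1 + Poisson(host_breadth_mean - 1)` plant species, so every species
#' has at least one host. Records are duplicated across sources at
#' `duplicate_rate`, flipped to captive at `captive_rate`, and rewritten
#' to a registered synonym variant at `synonym_noise_rate` (the complete
#' variant map is carried in the generated lookup, so reconciliation can
#' recover the clean dataset exactly). `gymnosperm_fraction` of plant
#' families are gymnosperms, which the polyphagy score must exclude.
#'
#' @param n_plant_families,n_plant_genera,n_moth_genera,n_moth_species,n_sources
#'   structure sizes (counts; `n_plant_genera >= n_plant_families`,
#'   `n_moth_species >= n_moth_genera`).
#' @param host_breadth_mean mean number of plant species per moth species.
#' @param duplicate_rate,captive_rate,gymnosperm_fraction,synonym_noise_rate
#'   probabilities in `[0, 1]`.
#' @param seed integer seed; all stochastic draws flow from it.
#' @param include_root root convention used for the ground-truth PD.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_plant_families = 60, n_plant_genera = 300,
                       n_moth_genera = 60, n_moth_species = 300,
                       n_sources = 3, host_breadth_mean = 5,
                       duplicate_rate = 0.15, captive_rate = 0.1,
                       gymnosperm_fraction = 0.05, synonym_noise_rate = 0.05,
                       seed = 1, include_root = TRUE) {
  cfg <- list(n_plant_families = n_plant_families,
              n_plant_genera = n_plant_genera,
              n_moth_genera = n_moth_genera,
              n_moth_species = n_moth_species,
              n_sources = n_sources, host_breadth_mean = host_breadth_mean,
              duplicate_rate = duplicate_rate, captive_rate = captive_rate,
              gymnosperm_fraction = gymnosperm_fraction,
              synonym_noise_rate = synonym_noise_rate,
              seed = seed, include_root = include_root)
  counts <- c("n_plant_families", "n_plant_genera", "n_moth_genera",
              "n_moth_species", "n_sources")
  for (nm in counts) {
    if (cfg[[nm]] < 1) stop(nm, " must be >= 1", call. = FALSE)
  }
  if (cfg$n_plant_families < 2) stop("need at least 2 plant families", call. = FALSE)
  if (cfg$n_plant_genera < cfg$n_plant_families) {
    stop("n_plant_genera must be >= n_plant_families", call. = FALSE)
  }
  if (cfg$n_moth_species < cfg$n_moth_genera) {
    stop("n_moth_species must be >= n_moth_genera", call. = FALSE)
  }
  probs <- c("duplicate_rate", "captive_rate", "gymnosperm_fraction",
             "synonym_noise_rate")
  for (nm in probs) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop(nm, " must be in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$host_breadth_mean < 1) {
    stop("host_breadth_mean must be >= 1", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a dated family-level phylogeny
#'
#' A rooted binary ultrametric tree from a pure-birth (Yule, rate 1)
#' process, rescaled to a root height of `height` time units, with tips
#' labelled `Family0001`, `Family0002`, ... Deterministic given `seed`.
#' This is a testing stand-in for a dated plant phylogeny, not a model of
#' plant history.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed optional integer; when `NULL`, draws from the current RNG
#'   stream.
#' @param height root height in time units.
#' @return an ultrametric [ape::phylo] tree.
#' @export
simulate_tree <- function(n_tips, seed = NULL, height = 100) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  tree <- with_local_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (height / depth)
  tree$tip.label <- sprintf("Family%04d", seq_len(n_tips))
  tree
}

#' Brute-force Faith's PD by explicit path union
#'
#' Independent oracle for [faith_pd()]: identifies each edge by its child
#' node, walks every selected tip's path to the root collecting edge
#' identifiers, takes the set union and sums the corresponding lengths.
#' For the rootless convention the most recent common ancestor is found
#' by exhaustive intersection of the tips' ancestor sets and the edges on
#' its root path are subtracted. Quadratic and slow on purpose; use
#' [faith_pd()] for real work.
#'
#' @inheritParams faith_pd
#' @return branch-length sum.
#' @export
pd_bruteforce <- function(tree, tips, include_root = TRUE) {
  tips <- unique(as.character(tips))
  if (length(tips) == 0) stop("empty tip set", call. = FALSE)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("tip(s) not in tree", call. = FALSE)
  root <- length(tree$tip.label) + 1L
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  len_of <- numeric(max(tree$edge))
  len_of[tree$edge[, 2]] <- tree$edge.length

  path_up <- function(node) {
    p <- integer(0)
    while (node != root) {
      p <- c(p, node)       # edge above `node`
      node <- parent_of[node]
    }
    p
  }
  paths <- lapply(idx, path_up)
  edges <- unique(unlist(paths))
  total <- sum(len_of[edges])
  if (!include_root) {
    ancestors <- lapply(idx, function(n) c(path_up(n), root))
    common <- Reduce(intersect, ancestors)  # tip-ward order preserved
    mrca <- common[1]
    above <- if (mrca == root) integer(0) else path_up(mrca)
    total <- total - sum(len_of[above])
  }
  total
}

#' Simulate a full multi-source food-plant dataset with ground truth
#'
#' Generates, from one seed, everything the pipeline consumes — per-source
#' record tables (with formatting noise, author strings, synonym variants,
#' cross-source duplicates and captive records), a plant lookup with a
#' complete synonym map, a moth checklist and a dated family phylogeny —
#' together with a `truth` element holding the per-species and per-genus
#' summaries and PD scores computed by direct bookkeeping at generation
#' time, independently of the pipeline code (PD truth uses
#' [pd_bruteforce()]).
#'
#' @param config a [sim_config()].
#' @return list with elements `records` (list of record tables, one per
#'   source), `lookup`, `checklist`, `tree`, `truth` (list `ds1`, `ds2`,
#'   `pd`), and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  tree <- simulate_tree(cfg$n_plant_families)

  ## plant taxonomy -----------------------------------------------------
  families <- sprintf("Family%04d", seq_len(cfg$n_plant_families))
  n_orders <- max(1L, ceiling(cfg$n_plant_families / 3))
  fam_order <- sprintf("Order%03d", sample.int(n_orders, cfg$n_plant_families,
                                               replace = TRUE))
  fam_group <- ifelse(runif(cfg$n_plant_families) < cfg$gymnosperm_fraction,
                      "gymnosperm", "angiosperm")
  genera <- sprintf("Plagen%04d", seq_len(cfg$n_plant_genera))
  # every family hosts at least one genus
  gen_family <- families[c(seq_len(cfg$n_plant_families),
                           sample.int(cfg$n_plant_families,
                                      cfg$n_plant_genera - cfg$n_plant_families,
                                      replace = TRUE))]
  taxa <- tibble::tibble(
    genus = genera, family = gen_family,
    order = fam_order[match(gen_family, families)],
    group = fam_group[match(gen_family, families)])

  n_sp_per_genus <- 1L + rpois(cfg$n_plant_genera, 1)
  plant_species <- unlist(lapply(seq_len(cfg$n_plant_genera), function(g) {
    paste(genera[g], paste0("spec", int_to_letters(seq_len(n_sp_per_genus[g]))))
  }))
  sp_genus <- rep(genera, n_sp_per_genus)

  # complete synonym map: every plant species has one registered variant
  syn_genus <- paste0(sp_genus, "syn")
  syn_raw <- paste(syn_genus, vapply(strsplit(plant_species, " ", fixed = TRUE),
                                     `[[`, character(1), 2))
  synonyms <- tibble::tibble(raw_name = syn_raw, accepted_name = plant_species)
  lookup <- plant_lookup(taxa, synonyms)

  ## moth checklist ------------------------------------------------------
  moth_genera <- sprintf("Mothgen%03d", seq_len(cfg$n_moth_genera))
  moth_fam <- ifelse(seq_len(cfg$n_moth_genera) %% 2 == 1,
                     "Saturniidae", "Sphingidae")
  moth_subfam <- ifelse(moth_fam == "Saturniidae", "Saturniinae", "Sphinginae")
  moth_tribe <- ifelse(moth_fam == "Saturniidae", "Saturniini", "Sphingini")

  gidx <- c(seq_len(cfg$n_moth_genera),
            sample.int(cfg$n_moth_genera,
                       cfg$n_moth_species - cfg$n_moth_genera, replace = TRUE))
  sp_per_genus <- tabulate(gidx, cfg$n_moth_genera)
  epi_counter <- integer(cfg$n_moth_genera)
  moth_species <- character(cfg$n_moth_species)
  for (i in seq_len(cfg$n_moth_species)) {
    g <- gidx[i]
    epi_counter[g] <- epi_counter[g] + 1L
    moth_species[i] <- paste(moth_genera[g],
                             paste0("mot", int_to_letters(epi_counter[g])))
  }
  checklist <- tibble::tibble(
    family = moth_fam, subfamily = moth_subfam, tribe = moth_tribe,
    genus = moth_genera,
    total_species = sp_per_genus + rpois(cfg$n_moth_genera, 2))

  ## associations --------------------------------------------------------
  assoc <- dplyr::bind_rows(lapply(seq_len(cfg$n_moth_species), function(i) {
    b <- min(1L + rpois(1, cfg$host_breadth_mean - 1), length(plant_species))
    hosts <- sample(plant_species, b)
    tibble::tibble(moth_species = moth_species[i], plant = hosts)
  }))
  assoc$setting <- ifelse(runif(nrow(assoc)) < cfg$captive_rate,
                          "captive", "wild")

  source_ids <- sprintf("Source%02d", seq_len(cfg$n_sources))
  recs <- assoc
  recs$source <- source_ids[sample.int(cfg$n_sources, nrow(recs),
                                       replace = TRUE)]
  dup <- recs[runif(nrow(recs)) < cfg$duplicate_rate, , drop = FALSE]
  if (nrow(dup) > 0) {
    dup$source <- source_ids[sample.int(cfg$n_sources, nrow(dup),
                                        replace = TRUE)]
    recs <- dplyr::bind_rows(recs, dup)
  }

  # verbatim plant strings: synonym variants plus formatting noise
  raw <- recs$plant
  use_syn <- runif(nrow(recs)) < cfg$synonym_noise_rate
  raw[use_syn] <- synonyms$raw_name[match(recs$plant[use_syn],
                                          synonyms$accepted_name)]
  messy <- runif(nrow(recs)) < 0.2
  style <- sample.int(3, nrow(recs), replace = TRUE)
  raw[messy & style == 1] <- paste0(raw[messy & style == 1], " L.")
  raw[messy & style == 2] <- tolower(paste0("  ", raw[messy & style == 2]))
  raw[messy & style == 3] <- gsub(" ", "   ", raw[messy & style == 3],
                                  fixed = TRUE)
  recs$plant_name_raw <- raw

  record_tables <- lapply(source_ids, function(s) {
    df <- recs[recs$source == s,
               c("moth_species", "plant_name_raw", "source", "setting")]
    record_table(df, sources = tibble::tibble(
      id = s, description = paste("synthetic source", s)))
  })
  names(record_tables) <- source_ids

  ## ground truth by direct bookkeeping ----------------------------------
  truth <- truth_tables(assoc, moth_species, gidx, checklist, taxa, tree, cfg)

  list(records = record_tables, lookup = lookup, checklist = checklist,
       tree = tree, truth = truth, config = cfg)
}

truth_tables <- function(assoc, moth_species, gidx, checklist, taxa, tree, cfg) {
  sp_row <- function(ms) {
    mine <- assoc[assoc$moth_species == ms, , drop = FALSE]
    per_setting <- function(setting) {
      sp <- sort(unique(mine$plant[mine$setting == setting]))
      gn <- sort(unique(vapply(strsplit(sp, " ", fixed = TRUE), `[[`,
                               character(1), 1)))
      fm <- sort(unique(taxa$family[match(gn, taxa$genus)]))
      od <- sort(unique(taxa$order[match(gn, taxa$genus)]))
      list(sp = sp, gn = gn, fm = fm, od = od)
    }
    w <- per_setting("wild"); cp <- per_setting("captive")
    g <- gidx[match(ms, moth_species)]
    tibble::tibble(
      Family = checklist$family[g], Subfamily = checklist$subfamily[g],
      Tribe = checklist$tribe[g], Moth_Genus_name = checklist$genus[g],
      Moth_Species_Name = ms,
      Number_PlantGenus = length(w$gn),
      Plant_GenusNames = paste(w$gn, collapse = "; "),
      Number_PlantSpecies = length(w$sp),
      Plant_SpeciesNames = paste(w$sp, collapse = "; "),
      Number_PlantFamily = length(w$fm),
      Plant_FamilyNames = paste(w$fm, collapse = "; "),
      Number_PlantOrders = length(w$od),
      Plant_OrderNames = paste(w$od, collapse = "; "),
      Number_PlantGenus_Capt = length(cp$gn),
      Plant_GenusNames_Capt = paste(cp$gn, collapse = "; "),
      Number_PlantSpecies_Capt = length(cp$sp),
      Plant_SpeciesNames_Capt = paste(cp$sp, collapse = "; "),
      Number_PlantFamily_Capt = length(cp$fm),
      Plant_FamilyNames_Capt = paste(cp$fm, collapse = "; "),
      Number_PlantOrders_Capt = length(cp$od),
      Plant_OrderNames_Capt = paste(cp$od, collapse = "; "))
  }
  ds1 <- dplyr::bind_rows(lapply(moth_species, sp_row))
  ds1 <- ds1[order(ds1$Family, ds1$Moth_Genus_name, ds1$Moth_Species_Name), ]

  fam_group <- setNames(
    taxa$group[!duplicated(taxa$family)],
    taxa$family[!duplicated(taxa$family)])
  pd_of_species <- function(row) {
    fams <- strsplit(row[["Plant_FamilyNames"]], "; ", fixed = TRUE)[[1]]
    fams <- fams[fams != "" & fam_group[fams] == "angiosperm"]
    fams <- fams[fams %in% tree$tip.label]
    if (length(fams) == 0) return(NA_real_)
    pd_bruteforce(tree, fams, include_root = cfg$include_root)
  }
  pd_truth <- vapply(seq_len(nrow(ds1)), function(i)
    pd_of_species(as.list(ds1[i, ])), numeric(1))
  pd_tbl <- tibble::tibble(moth_species = ds1$Moth_Species_Name, pd = pd_truth)

  sampled <- ds1$Number_PlantSpecies > 0   # >=1 wild association
  if (!any(sampled)) {
    return(list(ds1 = ds1, ds2 = empty_ds2(), pd = pd_tbl))
  }
  ds2 <- dplyr::bind_rows(lapply(
    unique(ds1$Moth_Genus_name[sampled]), function(g) {
      rows <- ds1[sampled & ds1$Moth_Genus_name == g, , drop = FALSE]
      pds <- pd_truth[sampled & ds1$Moth_Genus_name == g]
      uniq_n <- function(col) length(unique(unlist(
        strsplit(rows[[col]][rows[[col]] != ""], "; ", fixed = TRUE))))
      ci <- match(g, checklist$genus)
      tibble::tibble(
        Family = checklist$family[ci], Subfamily = checklist$subfamily[ci],
        Tribe = checklist$tribe[ci], Moth_Genus_Name = g,
        NumberSampledMothSpecies = nrow(rows),
        TotalMothSpecies = as.integer(checklist$total_species[ci]),
        TotalNumberGenus = uniq_n("Plant_GenusNames"),
        AverageNumberGenus = mean(rows$Number_PlantGenus),
        TotalNumberFamilies = uniq_n("Plant_FamilyNames"),
        AverageNumberFamilies = mean(rows$Number_PlantFamily),
        TotalNumberOrders = uniq_n("Plant_OrderNames"),
        AverageNumberOrders = mean(rows$Number_PlantOrders),
        PD_score = if (all(is.na(pds))) NA_real_ else mean(pds, na.rm = TRUE))
    }))
  ds2 <- ds2[order(ds2$Family, ds2$Moth_Genus_Name), ]
  list(ds1 = ds1, ds2 = ds2, pd = pd_tbl)
}

#' Write a simulated dataset bundle to a directory
#'
#' Writes the per-source record CSVs, the plant lookup and synonym CSVs,
#' the moth checklist CSV, the Newick tree and the ground-truth tables, in
#' the formats the pipeline readers expect.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(sim$records)) {
    df <- tibble::as_tibble(sim$records[[s]])
    readr::write_csv(df[, c("moth_species", "plant_name_raw",
                            "source", "setting")],
                     file.path(dir, paste0("records_", s, ".csv")))
  }
  readr::write_csv(sim$lookup$taxa, file.path(dir, "plant_lookup.csv"))
  readr::write_csv(sim$lookup$synonyms, file.path(dir, "plant_synonyms.csv"))
  readr::write_csv(sim$checklist, file.path(dir, "moth_checklist.csv"))
  ape::write.tree(sim$tree, file.path(dir, "plant_families.nwk"))
  write_summary_csv(sim$truth$ds1, file.path(dir, "truth_ds1.csv"))
  write_summary_csv(sim$truth$ds2, file.path(dir, "truth_ds2.csv"))
  invisible(dir)
}
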