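#' Parse a Newick tree with branch lengths
#'
#' Reads a single rooted tree whose tips are plant family names. Branch
#' lengths are required (the polyphagy score is a sum of branch lengths in
#' time units) and tip labels must be unique.
#'
#' @param text Newick string, or `NULL` to read from `path`.
#' @param path path to a Newick file (used when `text` is `NULL`).
#' @return an [ape::phylo] tree.
#' @export
parse_newick <- function(text = NULL, path = NULL) {
  stopifnot(!is.null(text) || !is.null(path))
  tree <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("Newick parse error: no tree could be read", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  tree
}

#' Total branch length of a tree
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return sum of all edge lengths.
#' @export
total_branch_length <- function(tree) sum(tree$edge.length)

#' Faith's phylogenetic diversity of a tip set
#'
#' Computes the total length of the tree branches connecting a set of
#' tips: the minimal spanning subtree of the named tips, including
#' (default) or excluding the path from their most recent common ancestor
#' to the root. With the root included, a single tip scores its
#' root-to-tip path length; with the root excluded it scores 0, and in
#' general only edges strictly below the MRCA of the set are counted.
#'
#' The implementation marks, in one postorder pass, how many selected
#' tips lie below each edge; an edge belongs to the spanning subtree iff
#' that count is positive (and, for the rootless convention, smaller than
#' the full set size — edges carrying the whole set are the MRCA-to-root
#' path).
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param tips character vector of tip labels (non-empty, all present in
#'   the tree; duplicates are ignored).
#' @param include_root include the MRCA-to-root path (default `TRUE`).
#' @return non-negative branch-length sum.
#' @export
faith_pd <- function(tree, tips, include_root = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  tips <- unique(as.character(tips))
  if (length(tips) == 0) stop("empty tip set", call. = FALSE)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) {
    stop("tip(s) not in tree: ", paste(tips[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  n_tip <- length(tree$tip.label)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)

  post <- ape::reorder.phylo(tree, "postorder")
  count <- integer(n_tip + tree$Nnode)
  count[idx] <- 1L
  parent <- post$edge[, 1]
  child <- post$edge[, 2]
  for (i in seq_along(parent)) {
    count[parent[i]] <- count[parent[i]] + count[child[i]]
  }
  k <- length(idx)
  below <- count[child]
  keep <- if (include_root) below > 0L else below > 0L & below < k
  sum(post$edge.length[keep])
}

#' Polyphagy score (Faith's PD) for one moth species
#'
#' Takes the set of plant families eaten in the wild by a moth species,
#' drops gymnosperm families ([exclude_gymnosperm_families()]), drops
#' families absent from the tree (recorded, with a warning), and computes
#' Faith's PD of the remainder. The score is undefined (`NA`) when no
#' usable family remains — notably for species feeding on gymnosperms
#' only.
#'
#' @param wild_families character vector of plant family names eaten in
#'   natural environments (e.g. a parsed `Plant_FamilyNames` list).
#' @param tree dated family-level phylogeny ([ape::phylo]).
#' @param lookup a [plant_lookup()] (classifies families into angiosperm
#'   vs gymnosperm).
#' @param include_root root-inclusion convention passed to [faith_pd()].
#' @param moth_species optional label carried into the result.
#' @param warn warn about families missing from the tree.
#' @return list with `moth_species`, `families_used`,
#'   `families_missing_from_tree`, `pd` (`NA` if undefined).
#' @export
species_pd <- function(wild_families, tree, lookup, include_root = TRUE,
                       moth_species = NA_character_, warn = TRUE) {
  fams <- unique(as.character(wild_families))
  fams <- fams[!is.na(fams) & fams != ""]
  angio <- suppressWarnings(exclude_gymnosperm_families(fams, lookup))
  in_tree <- angio[angio %in% tree$tip.label]
  missing <- setdiff(angio, tree$tip.label)
  if (warn && length(missing) > 0) {
    warning("family(ies) not in tree, dropped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  pd <- if (length(in_tree) == 0) NA_real_ else {
    faith_pd(tree, in_tree, include_root = include_root)
  }
  list(moth_species = moth_species, families_used = in_tree,
       families_missing_from_tree = missing, pd = pd)
}

#' Genus polyphagy score from per-species results
#'
#' The genus score is the arithmetic mean of the defined per-species PD
#' values; it is undefined when no species in the genus has a defined
#' score (gymnosperm-only feeders).
#'
#' @param pds numeric vector of per-species PD values (`NA` = undefined).
#' @return mean of the defined values, or `NA` if there are none.
#' @export
genus_pd_score <- function(pds) {
  if (length(pds) == 0) stop("empty PD list", call. = FALSE)
  if (all(is.na(pds))) return(NA_real_)
  mean(pds, na.rm = TRUE)
}

#' Per-species PD table from a per-species summary table
#'
#' Computes the polyphagy score for every row of a per-species table from
#' its wild plant-family list alone; no raw records are needed.
#'
#' @param ds1 per-species table in the [build_ds1()] schema.
#' @param tree dated family-level phylogeny.
#' @param lookup a [plant_lookup()].
#' @param include_root root-inclusion convention (default `TRUE`).
#' @return tibble with `moth_species`, `n_families_used`,
#'   `n_families_missing`, `pd`.
#' @export
pd_table <- function(ds1, tree, lookup, include_root = TRUE) {
  res <- lapply(seq_len(nrow(ds1)), function(i) {
    species_pd(split_name_list(ds1$Plant_FamilyNames[i]), tree, lookup,
               include_root = include_root,
               moth_species = ds1$Moth_Species_Name[i], warn = FALSE)
  })
  all_missing <- sort(unique(unlist(
    lapply(res, `[[`, "families_missing_from_tree"))))
  if (length(all_missing) > 0) {
    warning("family(ies) not in tree, dropped from PD: ",
            paste(all_missing, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    moth_species = vapply(res, `[[`, character(1), "moth_species"),
    n_families_used = vapply(res, function(r) length(r$families_used), integer(1)),
    n_families_missing = vapply(res, function(r)
      length(r$families_missing_from_tree), integer(1)),
    pd = vapply(res, `[[`, numeric(1), "pd")
  )
}

#' Collapse species-level tips to family-level tips
#'
#' When a supplied phylogeny has finer-than-family tips, keeps one
#' exemplar tip per family (the lexicographically first) and relabels it
#' with the family name, dropping all other tips.
#'
#' @param tree an [ape::phylo] tree.
#' @param tip_to_family named character vector mapping tip labels to
#'   family names; unmapped tips are dropped.
#' @return family-level [ape::phylo] tree.
#' @export
collapse_tips_to_families <- function(tree, tip_to_family) {
  fam <- tip_to_family[tree$tip.label]
  keep_df <- tibble::tibble(tip = tree$tip.label, family = unname(fam))
  keep_df <- keep_df[!is.na(keep_df$family), , drop = FALSE]
  keep_df <- keep_df[order(keep_df$family, keep_df$tip), , drop = FALSE]
  keep_df <- keep_df[!duplicated(keep_df$family), , drop = FALSE]
  if (nrow(keep_df) < 2) stop("fewer than two mapped families", call. = FALSE)
  pruned <- ape::keep.tip(tree, keep_df$tip)
  pruned$tip.label <- keep_df$family[match(pruned$tip.label, keep_df$tip)]
  pruned
}
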