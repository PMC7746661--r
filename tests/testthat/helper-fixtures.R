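# small in-code fixtures shared across test files

toy_lookup <- function() {
  plant_lookup(
    taxa = tibble::tibble(
      genus  = c("Quercus", "Salix", "Pinus", "Fagus", "Populus"),
      family = c("Fagaceae", "Salicaceae", "Pinaceae", "Fagaceae", "Salicaceae"),
      order  = c("Fagales", "Malpighiales", "Pinales", "Fagales", "Malpighiales"),
      group  = c("angiosperm", "angiosperm", "gymnosperm", "angiosperm",
                 "angiosperm")),
    synonyms = tibble::tibble(
      raw_name = c("Quercus pedunculata", "Salixoides"),
      accepted_name = c("Quercus robur", "Salix")))
}

toy_checklist <- function() {
  tibble::tibble(
    family = c("Saturniidae", "Saturniidae", "Sphingidae"),
    subfamily = c("Saturniinae", "Saturniinae", "Sphinginae"),
    tribe = c("Saturniini", "Attacini", "Sphingini"),
    genus = c("Actias", "Samia", "Manduca"),
    total_species = c(5L, 3L, 8L))
}

toy_records <- function() {
  record_table(tibble::tibble(
    moth_species = c("Actias luna", "Actias luna", "Actias luna",
                     "Samia cynthia", "Manduca sexta"),
    plant_name_raw = c("Quercus robur L.", "Quercus ilex", "Salix alba",
                       "Quercus sp.", "Pinus sylvestris"),
    source = c("A", "A", "B", "A", "B"),
    setting = c("wild", "wild", "wild", "wild", "captive")))
}

# a small deterministic random record table for property-style tests;
# plant/moth name pools are resolvable against toy_lookup()/toy_checklist()
random_record_table <- function(seed, n = NULL) {
  withr::with_seed(seed, {
    if (is.null(n)) n <- sample(1:40, 1)
    moths <- c("Actias luna", "Actias selene", "Samia cynthia",
               "Manduca sexta", "Nokona regalis")
    plants <- c("Quercus robur", "Quercus ilex", "Quercus sp.", "Salix alba",
                "Pinus sylvestris", "Fagus sylvatica", "Populus nigra",
                "quercus  robur  L.", "Unknownus mysticus")
    record_table(tibble::tibble(
      moth_species = sample(moths, n, replace = TRUE),
      plant_name_raw = sample(plants, n, replace = TRUE),
      source = sample(c("A", "B", "C"), n, replace = TRUE),
      setting = sample(c("wild", "captive"), n, replace = TRUE),
      questionable = runif(n) < 0.1))
  })
}

random_tip_subset <- function(tree, k = NULL) {
  labs <- tree$tip.label
  if (is.null(k)) k <- sample(seq_along(labs), 1)
  sample(labs, k)
}
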