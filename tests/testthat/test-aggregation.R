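resolved_toy <- function(rows) {
  dedupe_records(resolve_records(
    record_table(tibble::as_tibble(rows)), toy_lookup(), toy_checklist()))
}

test_that("per-species summary counts distinct plant taxa per rank and setting", {
  recs <- resolved_toy(tibble::tibble(
    moth_species = rep("Actias luna", 3),
    plant_name_raw = c("Quercus robur", "Quercus ilex", "Salix alba"),
    source = "A", setting = "wild"))
  s <- summarize_species(recs, "Actias luna")
  expect_equal(s$Number_PlantGenus, 2)
  expect_equal(s$Number_PlantSpecies, 3)
  expect_equal(s$Number_PlantFamily, 2)
  expect_equal(s$Number_PlantOrders, 2)
  expect_equal(s$Plant_FamilyNames, "Fagaceae; Salicaceae")
  expect_equal(s$Plant_SpeciesNames,
               "Quercus ilex; Quercus robur; Salix alba")
  expect_equal(s$Number_PlantGenus_Capt, 0)
  expect_equal(s$Plant_GenusNames_Capt, "")
})

test_that("genus-only plant records count at genus/family/order rank but not species rank", {
  recs <- resolved_toy(tibble::tibble(
    moth_species = "Actias luna", plant_name_raw = "Quercus sp.",
    source = "A", setting = "wild"))
  s <- summarize_species(recs, "Actias luna")
  expect_equal(s$Number_PlantGenus, 1)
  expect_equal(s$Number_PlantSpecies, 0)
  expect_equal(s$Plant_SpeciesNames, "")
  expect_equal(s$Number_PlantFamily, 1)
  expect_equal(s$Number_PlantOrders, 1)
})

test_that("captive-only species have zero wild counts and populated captive columns", {
  recs <- resolved_toy(tibble::tibble(
    moth_species = "Manduca sexta",
    plant_name_raw = c("Salix alba", "Populus nigra"),
    source = "A", setting = "captive"))
  s <- summarize_species(recs, "Manduca sexta")
  expect_equal(s$Number_PlantGenus, 0)
  expect_equal(s$Number_PlantGenus_Capt, 2)
  expect_equal(s$Plant_GenusNames_Capt, "Populus; Salix")
  expect_error(summarize_species(recs, "Actias luna"), "no records")
})

test_that("unresolved plant names are excluded from all counts", {
  recs <- resolved_toy(tibble::tibble(
    moth_species = "Actias luna",
    plant_name_raw = c("Quercus robur", "Xyzus blah"),
    source = "A", setting = "wild"))
  s <- summarize_species(recs, "Actias luna")
  expect_equal(s$Number_PlantGenus, 1)
  expect_equal(s$Number_PlantSpecies, 1)
})

test_that("the per-species table has the 21 deposited columns, sorted and validated", {
  recs <- resolved_toy(tibble::tibble(
    moth_species = c("Manduca sexta", "Actias luna"),
    plant_name_raw = c("Salix alba", "Quercus robur"),
    source = "A", setting = "wild"))
  ds1 <- build_ds1(recs, toy_checklist())
  expect_equal(ncol(ds1), 21)
  expect_equal(nrow(ds1), 2)
  expect_equal(names(ds1)[1:5],
               c("Family", "Subfamily", "Tribe",
                 "Moth_Genus_name", "Moth_Species_Name"))
  # sorted by moth family then genus then species
  expect_equal(ds1$Moth_Species_Name, c("Actias luna", "Manduca sexta"))
  expect_true(validate_ds1(ds1))

  empty <- resolved_toy(tibble::tibble(
    moth_species = character(), plant_name_raw = character(),
    source = character(), setting = character()))
  e <- build_ds1(empty, toy_checklist())
  expect_equal(nrow(e), 0)
  expect_equal(names(e), names(ds1))
})

test_that("per-species count/list invariants hold on random record tables", {
  for (seed in c(3, 17, 29, 41, 53)) {
    recs <- dedupe_records(resolve_records(
      random_record_table(seed, n = 30), toy_lookup(), toy_checklist()))
    ds1 <- build_ds1(recs, toy_checklist())
    expect_true(validate_ds1(ds1))
    expect_true(all(ds1$Number_PlantOrders_Capt <= ds1$Number_PlantFamily_Capt))
    expect_true(all(ds1$Number_PlantFamily_Capt <= ds1$Number_PlantGenus_Capt))
  }
})

test_that("genus summary takes unions for totals and means over sampled species", {
  recs <- resolved_toy(tibble::tibble(
    moth_species = c("Actias luna", "Actias luna", "Actias selene"),
    plant_name_raw = c("Quercus robur", "Salix alba", "Quercus ilex"),
    source = "A", setting = "wild"))
  ds1 <- build_ds1(recs, toy_checklist())
  g <- summarize_genus(ds1, total_species = 5L,
                       pd_scores = c("Actias luna" = 10, "Actias selene" = NA))
  expect_equal(g$TotalNumberGenus, 2)        # union {Quercus, Salix}
  expect_equal(g$AverageNumberGenus, 1.5)    # mean(2, 1)
  expect_equal(g$NumberSampledMothSpecies, 2)
  expect_equal(g$TotalMothSpecies, 5L)
  expect_equal(g$PD_score, 10)               # mean over defined scores only
  expect_error(summarize_genus(ds1[0, ]), "empty")
})

test_that("the per-genus table has the 13 deposited columns and honours the checklist", {
  recs <- resolved_toy(tibble::tibble(
    moth_species = c("Actias luna", "Samia cynthia", "Manduca sexta",
                     "Nokona regalis"),
    plant_name_raw = c("Quercus robur", "Salix alba", "Quercus ilex",
                       "Fagus sylvatica"),
    source = "A", setting = "wild"))
  expect_warning(
    ds2 <- build_ds2(build_ds1(recs, toy_checklist()), toy_checklist()),
    "Nokona")
  expect_equal(ncol(ds2), 13)
  expect_equal(nrow(ds2), 4)
  expect_true(validate_ds2(ds2))
  expect_true(is.na(ds2$TotalMothSpecies[ds2$Moth_Genus_Name == "Nokona"]))
  # single-species genus: averages equal that species' counts
  manduca <- ds2[ds2$Moth_Genus_Name == "Manduca", ]
  expect_equal(manduca$AverageNumberGenus, manduca$TotalNumberGenus)
  expect_true(all(is.na(ds2$PD_score)))  # no PD supplied
})

test_that("captive-only species are not sampled; captive-only genera drop out of the genus table", {
  recs <- resolved_toy(tibble::tibble(
    moth_species = c("Actias luna", "Actias selene", "Samia cynthia"),
    plant_name_raw = c("Quercus robur", "Salix alba", "Populus nigra"),
    source = "A", setting = c("wild", "captive", "captive")))
  ds1 <- build_ds1(recs, toy_checklist())
  ds2 <- build_ds2(ds1, toy_checklist())
  expect_equal(ds2$Moth_Genus_Name, "Actias")
  expect_equal(ds2$NumberSampledMothSpecies, 1)
  expect_equal(ds2$AverageNumberGenus, 1)
})

test_that("genus totals never exceed per-species sums and averages never exceed totals", {
  for (seed in c(7, 19, 31)) {
    recs <- dedupe_records(resolve_records(
      random_record_table(seed, n = 40), toy_lookup(), toy_checklist()))
    ds1 <- build_ds1(recs, toy_checklist())
    ds2 <- suppressWarnings(build_ds2(ds1, toy_checklist()))
    if (nrow(ds2) == 0) next
    expect_true(validate_ds2(ds2))
    sampled <- ds1[hostbreadth:::species_sampled_wild(ds1), ]
    sums <- tapply(sampled$Number_PlantGenus, sampled$Moth_Genus_name, sum)
    expect_true(all(ds2$TotalNumberGenus <=
                      sums[ds2$Moth_Genus_Name] + 1e-9))
  }
})

test_that("written summary CSVs use empty cells for undefined scores", {
  ds2 <- tibble::as_tibble(setNames(
    list("Saturniidae", "Saturniinae", "Saturniini", "Actias", 1L, 5L,
         2L, 1.5, 2L, 1.123456789, 1L, 1, NA_real_),
    c("Family", "Subfamily", "Tribe", "Moth_Genus_Name",
      "NumberSampledMothSpecies", "TotalMothSpecies", "TotalNumberGenus",
      "AverageNumberGenus", "TotalNumberFamilies", "AverageNumberFamilies",
      "TotalNumberOrders", "AverageNumberOrders", "PD_score")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary_csv(ds2, path)
  lines <- readLines(path)
  expect_true(endsWith(lines[2], ","))           # NA PD -> empty cell
  expect_true(grepl("1.12346", lines[2], fixed = TRUE))  # 6 significant digits
})
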