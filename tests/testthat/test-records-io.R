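test_that("record tables read from CSV/TSV preserve rows, order and verbatim names", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "moth_species,plant_name_raw,source,setting",
    "Actias luna,Quercus robur L.,A,wild",
    "Actias luna,Salix alba,A,captive_or_introduced",
    "Samia cynthia,Quercus sp.,A,wild"), csv)
  rt <- read_record_table(csv)
  expect_s3_class(rt, "record_table")
  expect_equal(nrow(rt), 3)
  expect_equal(rt$plant_name_raw[1], "Quercus robur L.")
  expect_equal(rt$setting, c("wild", "captive", "wild"))
  expect_equal(rt$moth_genus, c("Actias", "Actias", "Samia"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("moth_species\tplant_name_raw\tsource\tsetting",
               "Actias luna\tQuercus robur\tB\twild"), tsv)
  expect_equal(nrow(read_record_table(tsv)), 1)
})

test_that("header-only files yield an empty table; missing columns are schema errors", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines("moth_species,plant_name_raw,source,setting", csv)
  expect_equal(nrow(read_record_table(csv)), 0)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("moth_species,source,setting", "Actias luna,A,wild"), bad)
  expect_error(read_record_table(bad), "plant_name_raw")
  expect_error(read_record_table("no/such/file.csv"), "not found")
})

test_that("header-driven column mapping handles source-specific headers", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Moth,Hostplant,Origin",
               "Actias luna,Quercus robur,wild"), csv)
  rt <- read_record_table(csv,
    mapping = c(moth_species = "Moth", plant_name_raw = "Hostplant",
                setting = "Origin"),
    source = "HOSTS")
  expect_equal(rt$source, "HOSTS")
  expect_equal(rt$plant_name_raw, "Quercus robur")
  expect_error(
    read_record_table(csv, mapping = c(plant_name_raw = "NoSuchColumn")),
    "NoSuchColumn")
})

test_that("merging keeps the same association from different sources as distinct records", {
  t1 <- record_table(tibble::tibble(
    moth_species = c("Actias luna", "Actias luna"),
    plant_name_raw = c("Quercus robur", "Salix alba"),
    source = "HOSTS", setting = "wild"))
  t2 <- record_table(tibble::tibble(
    moth_species = c("Actias luna", "Samia cynthia", "Manduca sexta"),
    plant_name_raw = c("Quercus robur", "Quercus ilex", "Salix alba"),
    source = "JH", setting = "wild"))
  m <- merge_sources(list(t1, t2))
  expect_equal(nrow(m), 5)
  # same moth+plant, two sources: both retained
  qr <- m[m$plant_name_raw == "Quercus robur", ]
  expect_equal(sort(qr$source), c("HOSTS", "JH"))
  expect_setequal(record_sources(m)$id, c("HOSTS", "JH"))

  empty <- record_table(tibble::tibble(
    moth_species = character(), plant_name_raw = character(),
    source = character(), setting = character()))
  expect_equal(nrow(merge_sources(list(t1, empty))), nrow(t1))
})

test_that("merging is associative up to record order and flags tag conflicts", {
  a <- random_record_table(11); b <- random_record_table(12)
  c <- random_record_table(13)
  left <- merge_sources(list(merge_sources(list(a, b)), c))
  right <- merge_sources(list(a, merge_sources(list(b, c))))
  expect_equal(dplyr::arrange_all(tibble::as_tibble(left)),
               dplyr::arrange_all(tibble::as_tibble(right)))

  s1 <- record_table(tibble::tibble(moth_species = "Actias luna",
    plant_name_raw = "Salix alba", source = "X", setting = "wild"),
    sources = tibble::tibble(id = "X", description = "one thing"))
  s2 <- record_table(tibble::tibble(moth_species = "Actias luna",
    plant_name_raw = "Quercus ilex", source = "X", setting = "wild"),
    sources = tibble::tibble(id = "X", description = "another thing"))
  expect_error(merge_sources(list(s1, s2)), "conflicting")
})

test_that("dedup keeps one record per (moth, plant, source, setting) key and is idempotent", {
  lk <- toy_lookup(); cl <- toy_checklist()
  rt <- record_table(tibble::tibble(
    moth_species = rep("Actias luna", 5),
    plant_name_raw = c("Quercus robur", "Quercus robur", "Quercus robur",
                       "Quercus robur L.", "Quercus robur"),
    source = c("HOSTS", "HOSTS", "JH", "HOSTS", "HOSTS"),
    setting = c("wild", "wild", "wild", "wild", "captive")))
  dd <- dedupe_records(resolve_records(rt, lk, cl))
  # byte-identical dup collapses; author-citation variant collapses too;
  # a second source and a captive observation survive
  expect_equal(nrow(dd), 3)
  expect_setequal(paste(dd$source, dd$setting),
                  c("HOSTS wild", "JH wild", "HOSTS captive"))
  expect_equal(tibble::as_tibble(dedupe_records(dd)), tibble::as_tibble(dd))
})

test_that("dedup treats genus-only and species-level plant identities as distinct", {
  lk <- toy_lookup(); cl <- toy_checklist()
  rt <- record_table(tibble::tibble(
    moth_species = rep("Actias luna", 3),
    plant_name_raw = c("Quercus sp.", "Quercus robur", "Quercus cf. robur"),
    source = "A", setting = "wild"))
  dd <- dedupe_records(resolve_records(rt, lk, cl))
  # "Quercus sp." and "Quercus cf. robur" both resolve to genus rank and
  # collapse together; the species-level record stays separate
  expect_equal(nrow(dd), 2)
})

test_that("partition by setting is a conservative disjoint split, dedup idempotent, on random tables", {
  for (seed in 1:100) {
    rt <- random_record_table(seed)
    parts <- partition_by_setting(rt)
    expect_equal(nrow(parts$wild) + nrow(parts$captive), nrow(rt))
    expect_true(all(parts$wild$setting == "wild"))
    expect_true(all(parts$captive$setting == "captive"))

    dd <- dedupe_records(rt)
    expect_equal(tibble::as_tibble(dedupe_records(dd)), tibble::as_tibble(dd))
    expect_true(!anyDuplicated(hostbreadth:::record_key(dd)))
  }
})

test_that("questionable records are dropped, default flag is FALSE", {
  rt <- record_table(tibble::tibble(
    moth_species = paste("Actias", c("a", "b", "c", "d", "e")),
    plant_name_raw = "Salix alba", source = "A", setting = "wild",
    questionable = c(FALSE, TRUE, FALSE, FALSE, FALSE)))
  expect_message(out <- drop_questionable(rt), "1 questionable")
  expect_equal(nrow(out), 4)
  none <- toy_records()
  expect_equal(nrow(drop_questionable(none, quiet = TRUE)), nrow(none))
  all_flagged <- record_table(tibble::tibble(
    moth_species = "Actias luna", plant_name_raw = "Salix alba",
    source = "A", setting = "wild", questionable = TRUE))
  expect_equal(nrow(drop_questionable(all_flagged, quiet = TRUE)), 0)
})

test_that("write/read round-trip preserves the record set field by field", {
  rt <- resolve_records(toy_records(), toy_lookup(), toy_checklist())
  path <- withr::local_tempfile(fileext = ".csv")
  write_record_table(rt, path)
  back <- read_record_table(path)
  for (col in c("moth_species", "plant_name_raw", "source", "setting",
                "plant_genus", "plant_species", "plant_family")) {
    expect_equal(back[[col]], rt[[col]], label = col)
  }
})
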