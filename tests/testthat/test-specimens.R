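test_that("the packaged measurement table loads with its transcribed sections", {
  tab <- load_table1()
  expect_s3_class(tab, "specimen_table")
  expect_equal(nrow(tab), 158)
  counts <- table(tab$section)
  expect_equal(as.numeric(counts[["fossil"]]), 117)
  expect_equal(as.numeric(counts[["living_nonprimate"]]), 22)
  expect_equal(as.numeric(counts[["living_primate"]]), 19)
  # no row silently dropped: file data lines match record count
  expect_equal(length(readLines(paleo_fixture("table1_mammals"))) - 1, nrow(tab))
})

test_that("the within-species fixture holds the eight conspecific endocasts", {
  bat <- read_bathygenys()
  expect_equal(nrow(bat), 8)
  expect_true(all(bat$species == "Bathygenys reevesi"))
  expect_equal(bat$E_ml[1], 11.362)
})

test_that("the reader parses blanks, thousands separators, and rejects bad input", {
  hdr <- "species,specimen_id,section,taxon,S_cm2,OB_cm2,S_minus_OB_cm2,NC_cm2,L_cm,age_Ma,E_ml,P_g,pctNC,EQ"
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(hdr, 'A x,ID1,fossil,Carnivora,10,0,10,5,3,-30,4,"15,000",50,0.5'), f)
  tab <- suppressMessages(read_specimens(f))
  expect_equal(tab$P_g, 15000)
  expect_equal(tab$L_cm, 3)
  expect_equal(tab$OB_cm2, 0) # zero kept distinct from blank

  # blank cells become NA
  writeLines(c(hdr, "A x,ID1,fossil,Carnivora,,,,,,,,,,"), f)
  tab <- read_specimens(f)
  expect_true(all(is.na(tab$S_cm2)))
  expect_equal(nrow(tab), 1)

  # empty file with a valid header -> empty table
  writeLines(hdr, f)
  expect_equal(nrow(read_specimens(f)), 0)

  # malformed header names the missing column
  writeLines("species,specimen_id,section,taxon", f)
  expect_error(read_specimens(f), "S_cm2")

  # non-numeric cell names row and column
  writeLines(c(hdr, "A x,ID1,fossil,Carnivora,ten,,,,,,,,,"), f)
  expect_error(read_specimens(f), "S_cm2.*row 1")
})

test_that("positive fossil ages are normalized to the negative convention", {
  tab <- load_table1()
  expect_true(all(tab$age_Ma[tab$section == "fossil"] <= 0, na.rm = TRUE))
  flipped <- attr(tab, "age_normalized")
  expect_length(flipped, 2)
  expect_setequal(tab$species[flipped],
                  c("Arsinotherium zitelli", "Canis latrans"))
  expect_equal(tab$age_Ma[tab$species == "Arsinotherium zitelli"], -33)
})

test_that("write/read round-trips records value-for-value including blanks", {
  tab <- load_table1()
  f <- withr::local_tempfile(fileext = ".csv")
  write_specimens(tab, f)
  back <- read_specimens(f) # ages already negative; nothing to normalize
  for (col in names(tab)) {
    expect_equal(back[[col]], tab[[col]], info = col)
  }
})

test_that("validation recomputes derived columns without mutating records", {
  tab <- load_table1()
  before <- as.data.frame(tab)
  rep <- validate_specimens(tab)
  expect_identical(as.data.frame(tab), before)
  rep <- as.data.frame(rep)

  adapis <- subset(rep, grepl("M1340", specimen_id) & check == "pctNC")
  expect_equal(adapis$status, "pass")

  equus <- subset(rep, species == "Equus occidentalis" & check == "pctNC")
  expect_equal(equus$status, "fail")
  expect_equal(equus$recomputed, 58.66, tolerance = 1e-3)

  # rows without NC are skipped, not failed
  cet <- subset(rep, species == "Aulophyseter morricei" & check == "pctNC")
  expect_equal(cet$status, "skipped_missing")
})

test_that("the fixture's inconsistent printed cells are a stable, pinned set", {
  rep <- as.data.frame(validate_specimens(load_table1()))
  pct_fail <- subset(rep, check == "pctNC" & status == "fail")
  expect_setequal(pct_fail$species,
                  c("Enaliarctos sp.", "Equus occidentalis", "Equus caballus"))
  eq_fail <- subset(rep, check == "EQ" & status == "fail")
  expect_equal(eq_fail$species, "Argyrocetus joaquinensis")
  add_fail <- subset(rep, check == "additivity" & status == "fail")
  expect_setequal(add_fail$species,
                  c("Apterodon macrognathus", "Dinictis felina", "Panthera atrox",
                    "Platygonus compressus", "Procamelus grandis",
                    "Uintatherium anceps"))
})
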