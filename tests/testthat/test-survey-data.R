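test_that("duplicate triples collapse to a single use report", {
  recs <- data.frame(informant = c("i1", "i1"), species = c("s1", "s1"),
                     category = c("c1", "c1"))
  expect_warning(x <- survey_dataset(recs, n_informants = 5),
                 "duplicate")
  expect_equal(nrow(x), 1L)
  expect_equal(n_informants(x), 5L)
})

test_that("an empty survey with a valid header is a valid dataset", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("informant,species,category", f)
  x <- read_survey(f, n_informants = 200)
  expect_equal(nrow(x), 0L)
  expect_equal(n_informants(x), 200L)
})

test_that("reading rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("informant,species", "i1,s1"), f)
  expect_error(read_survey(f, n_informants = 10),
               class = "ethnotally_format_error")
  recs <- data.frame(informant = c("i1", "i2"), species = "s1",
                     category = "c1")
  expect_error(survey_dataset(recs, n_informants = 1),
               class = "ethnotally_validation_error")
  expect_error(survey_dataset(data.frame(informant = "i1", species = "s1",
                                         category = "c1", route = "smoke"),
                              n_informants = 1),
               class = "ethnotally_validation_error")
  expect_error(survey_dataset(data.frame(informant = "", species = "s1",
                                         category = "c1"), 1),
               class = "ethnotally_validation_error")
})

test_that("write/read round trip preserves the record set", {
  set.seed(42)
  x <- survey_dataset(random_small_records(), n_informants = 25, quiet = TRUE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_survey(x, f)
  y <- read_survey(f, n_informants = 25)
  expect_setequal(paste(x$informant, x$species, x$category),
                  paste(y$informant, y$species, y$category))
  expect_equal(n_informants(y), n_informants(x))
})

test_that("taxonomic synonyms resolve to the canonical species", {
  expect_equal(resolve_species("Amygdalus lycioides Spach"), "Prunus eburnea")
  expect_equal(resolve_species("A. lycioides Spach"), "Prunus eburnea")
  expect_equal(resolve_species("*Ferula assa-foetida* Boiss."),
               "Ferula assa-foetida")
  # unknown names pass through untouched
  expect_equal(resolve_species("Allium cepa"), "Allium cepa")
  # a survey row naming the synonym keys to the canonical species
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("informant,species,category",
               "i1,Amygdalus lycioides Spach,digestive"), f)
  x <- read_survey(f, n_informants = 5, synonyms = fars_fixture("synonyms"))
  expect_equal(x$species, "Prunus eburnea")
})

test_that("synonym resolution is idempotent and total on the packaged species list", {
  canon <- fars_fixture("table1")$species
  once <- resolve_species(canon)
  expect_equal(once, canon)          # canonical names are fixed points
  variants <- fars_fixture("synonyms")
  resolved <- resolve_species(variants$variant[!variants$ambiguous])
  expect_true(all(resolved %in% canon))
  expect_equal(resolve_species(resolved), resolved)
})

test_that("genus-level ambiguous names resolve to NA, not a guess", {
  expect_warning(out <- resolve_species("Ziziphus sp."), "ambiguous")
  expect_true(is.na(out))
})

test_that("the lumped synonym pair is confirmed by the tables' own arithmetic", {
  # fidelity rows printed under the synonym must sum (via Np) to the UR
  # printed under the canonical name, else the lumping would be wrong
  np <- reconstruct_np(fars_margins())
  t3 <- fars_fixture("table3", resolve = TRUE)
  expect_equal(sum(np$np[np$species == "Prunus eburnea"]),
               t3$ur[t3$species == "Prunus eburnea"])
})
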