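test_that("a single record gives UR = FC = NU = 1", {
  x <- survey_dataset(data.frame(informant = "i1", species = "s1",
                                 category = "c1"), n_informants = 1)
  t <- tally_survey(x)
  expect_equal(t$species$ur, 1L)
  expect_equal(t$species$fc, 1L)
  expect_equal(t$species$nu, 1L)
  expect_equal(t$categories$nur, 1L)
  expect_equal(t$cells$np, 1L)
})

test_that("an empty dataset yields four empty index tables", {
  x <- survey_dataset(tibble::tibble(informant = character(),
                                     species = character(),
                                     category = character()),
                      n_informants = 10)
  s <- summarize_survey(x)
  expect_equal(nrow(s$species), 0L)
  expect_equal(nrow(s$categories), 0L)
  expect_equal(nrow(s$cells), 0L)
  expect_equal(nrow(s$choices), 0L)
})

test_that("pipeline tallies equal a brute-force set enumeration on random surveys", {
  set.seed(101)
  for (rep in 1:8) {
    recs <- random_small_records(n_informants = sample(5:20, 1),
                                 n_species = sample(2:8, 1),
                                 n_categories = sample(2:5, 1),
                                 n_rows = sample(10:80, 1))
    x <- survey_dataset(recs, n_informants = 20, quiet = TRUE)
    t <- tally_survey(x)
    o <- brute_force_tally(recs)
    expect_equal(as.data.frame(t$species), o$species)
    expect_equal(as.data.frame(t$categories), o$categories)
    expect_equal(as.data.frame(t$cells), o$cells)
  }
})

test_that("use reports are conserved across marginalisations", {
  x <- fars_survey()
  t <- tally_survey(x)
  by_sp <- aggregate(np ~ species, t$cells, sum)
  expect_equal(by_sp$np[match(t$species$species, by_sp$species)],
               t$species$ur)
  by_cat <- aggregate(np ~ category, t$cells, sum)
  expect_equal(by_cat$np[match(t$categories$category, by_cat$category)],
               t$categories$nur)
})

test_that("summary reproduces the published survey's headline numbers", {
  s <- summarize_survey(fars_survey())
  g <- glance(s)
  expect_equal(g$fc_min, 1L)
  expect_equal(g$fc_max, 58L)
  expect_equal(g$uv_max, 0.44)
  expect_equal(g$n_fl_100, 30L)
  ferula <- s$species[s$species$species == "Ferula assa-foetida", ]
  expect_equal(ferula$ur, 88L)
  expect_equal(ferula$fc, 58L)
  expect_equal(ferula$nu, 9L)
  dig <- s$categories[s$categories$category == "digestive", ]
  expect_equal(dig$nur, 70L)
  expect_equal(dig$ntaxa, 11L)
  # UV and CI coincide for every species under the dedup convention
  expect_equal(s$species$uv, s$species$ci)
})

test_that("informant duplication scales every index by its known law", {
  # cloning each informant (fresh ids, same citations) with N -> 2N leaves
  # the per-informant-normalised indices (UV, RFC, CI, FL, RI) unchanged;
  # the report-count indices transform exactly: Np and Nur double while
  # Ntaxa does not, so CV doubles and ICF becomes (2Nur - Ntaxa)/(2Nur - 1)
  set.seed(7)
  x <- survey_dataset(random_small_records(), n_informants = 20, quiet = TRUE)
  s1 <- summarize_survey(x)
  doubled <- rbind(as.data.frame(x),
                   transform(as.data.frame(x),
                             informant = paste0(informant, "_copy")))
  x2 <- survey_dataset(doubled, n_informants = 2 * n_informants(x))
  s2 <- summarize_survey(x2)
  expect_equal(s2$species$uv, s1$species$uv)
  expect_equal(s2$species$rfc, s1$species$rfc)
  expect_equal(s2$species$ci, s1$species$ci)
  expect_equal(s2$species$ri, s1$species$ri)
  expect_equal(s2$cells$fl, s1$cells$fl)
  expect_equal(s2$cells$cv, 2 * s1$cells$cv)
  expect_equal(s2$categories$icf,
               informant_consensus_factor(2 * s1$categories$nur,
                                          s1$categories$ntaxa))
})

test_that("publication rounding is applied only on emission", {
  s <- summarize_survey(fars_survey())
  f <- format_index_tables(s)
  t3 <- fars_fixture("table3", resolve = TRUE)
  cmp <- merge(f$species, t3, by = "species", suffixes = c("", ".pub"))
  expect_equal(cmp$uv, cmp$uv.pub)
  expect_equal(cmp$rfc, cmp$rfc.pub)
  expect_equal(cmp$ri, cmp$ri.pub)
  # internal values stay unrounded
  eph <- s$species[s$species$species == "Ephedra pachyclada", ]
  expect_equal(eph$ri, (0.005 / 0.29 + 4 / 9) / 2)
})

test_that("route breakdown summarises tagged records only", {
  x <- data.frame(informant = sprintf("i%d", 1:5), species = "s1",
                  category = "c1",
                  route = c("oral", "oral", "topical", NA, "nasal"))
  rb <- route_breakdown(x)
  expect_equal(sum(rb$n), 4L)
  expect_equal(rb$percent[rb$route == "oral"], 50)
})
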