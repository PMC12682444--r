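test_that("cell counts are recovered by inverting the rounded fidelity levels", {
  np <- reconstruct_np(fars_margins())
  cell <- function(s, c) np$np[np$species == s & np$category == c]
  expect_equal(cell("Ferula assa-foetida", "digestive"), 47L)
  expect_equal(cell("Astragalus fasciculifolius", "fractures"), 13L)
  expect_equal(cell("Eruca sativa", "scabies"), 2L)
  # every species' cells sum back to its printed use-report total
  sums <- aggregate(np ~ species, np, sum)
  t3 <- fars_fixture("table3", resolve = TRUE)
  expect_equal(sums$np[match(t3$species, sums$species)], t3$ur)
})

test_that("a listed fidelity cell implying zero informants is rejected", {
  m <- margin_set(
    species = data.frame(species = "s1", fc = 2, ur = 1),
    cells = data.frame(species = "s1", category = "c1", fl = 10),
    n_informants = 10)
  expect_error(reconstruct_np(m), class = "ethnotally_validation_error")
})

test_that("margin set construction requires every fidelity species to have margins", {
  expect_error(
    margin_set(species = data.frame(species = "s1", fc = 1, ur = 1),
               cells = data.frame(species = "s2", category = "c1", fl = 100),
               n_informants = 5),
    class = "ethnotally_validation_error")
})

test_that("the validator surfaces the published tables' own inconsistencies", {
  report <- validate_margins(fars_margins())
  warnings <- report[report$severity == "warning", ]
  expect_equal(nrow(warnings), 2L)
  expect_false(any(report$severity == "failure"))
  ur_row <- report[report$check == "category_nur", ]
  expect_equal(ur_row$scope, "urinary retention")
  expect_equal(ur_row$expected, 1)
  expect_equal(ur_row$observed, 2)
  nt_row <- report[report$check == "category_ntaxa", ]
  expect_equal(nt_row$scope, "animal bite")
  expect_equal(nt_row$expected, 5)
  expect_equal(nt_row$observed, 3)
  # the per-species and per-category grand totals disagree by that same report
  gt <- report[report$check == "grand_total", ]
  expect_equal(gt$expected, 190)
  expect_equal(gt$observed, 191)
  # all other categories' column sums match the printed Nur
  expect_equal(sum(report$check == "category_nur"), 1L)
})

test_that("margins tallied from a dataset validate cleanly by construction", {
  set.seed(11)
  x <- survey_dataset(random_small_records(), n_informants = 25, quiet = TRUE)
  report <- validate_margins(margins_from_survey(x))
  expect_equal(nrow(report), 0L)
})

test_that("realize_survey is a right inverse of tally_survey on the paper margins", {
  m <- fars_margins()
  x <- realize_survey(reconstruct_np(m), m$species, m$n_informants)
  t <- tally_survey(x)
  ferula <- t$species[t$species$species == "Ferula assa-foetida", ]
  expect_equal(ferula$ur, 88L)
  expect_equal(ferula$fc, 58L)
  expect_equal(ferula$nu, 9L)
  expect_equal(t$species$fc, m$species$fc[order(m$species$species)])
  expect_equal(t$species$ur, m$species$ur[order(m$species$species)])
})

test_that("realization handles edge margins and rejects infeasible ones", {
  one <- realize_survey(data.frame(species = "s1", category = "c1", np = 1),
                        data.frame(species = "s1", fc = 1), n_informants = 1)
  expect_equal(nrow(one), 1L)
  expect_error(
    realize_survey(data.frame(species = "s1", category = "c1", np = 5),
                   data.frame(species = "s1", fc = 3), n_informants = 10),
    class = "ethnotally_infeasible_error")
  expect_error(
    realize_survey(data.frame(species = "s1", category = c("c1", "c2"),
                              np = c(1, 1)),
                   data.frame(species = "s1", fc = 3), n_informants = 10),
    class = "ethnotally_infeasible_error")
})

test_that("tally after realize reproduces random feasible margins exactly", {
  set.seed(2024)
  for (rep in 1:40) {
    m <- random_feasible_margins()
    x <- realize_survey(m$cells, m$fc, n_informants = sum(m$fc$fc))
    t <- tally_survey(x)
    got_cells <- as.data.frame(t$cells)
    want_cells <- m$cells[order(m$cells$species, m$cells$category), ]
    rownames(want_cells) <- NULL
    want_cells$np <- as.integer(want_cells$np)
    expect_equal(got_cells, want_cells)
    expect_equal(t$species$fc, as.integer(m$fc$fc))
  }
})
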