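#' Tally use reports by species, category and cell
#'
#' The raw counts behind every consensus index, in one pass over the
#' records: per species the use reports (UR), distinct citing informants
#' (FC) and distinct categories (NU); per ailment category the total use
#' reports (Nur) and distinct taxa (Ntaxa); and per species-by-category
#' cell the number of citing informants (Np). By construction
#' \eqn{UR_s = \sum_c Np_{s,c}} and \eqn{Nur_c = \sum_s Np_{s,c}}.
#'
#' @param x a [survey_dataset()].
#' @return a list of three tibbles, `species` (`species`, `ur`, `fc`, `nu`),
#'   `categories` (`category`, `nur`, `ntaxa`) and `cells` (`species`,
#'   `category`, `np`), each sorted alphabetically.
#' @examples
#' x <- simulate_survey(n_informants = 20, n_species = 5, n_categories = 3,
#'                      seed = 1)
#' tally_survey(x)$species
#' @export
tally_survey <- function(x) {
  recs <- as_tibble(x)
  # drop container attributes so derived tables are plain tibbles
  attr(recs, "n_informants") <- NULL
  attr(recs, "popularity") <- NULL
  species <- recs |>
    group_by(.data$species) |>
    summarise(ur = n(),
              fc = n_distinct(.data$informant),
              nu = n_distinct(.data$category),
              .groups = "drop") |>
    arrange(.data$species)
  categories <- recs |>
    group_by(category = .data$category) |>
    summarise(nur = n(),
              ntaxa = n_distinct(.data$species),
              .groups = "drop") |>
    arrange(.data$category)
  cells <- recs |>
    count(.data$species, .data$category, name = "np") |>
    arrange(.data$species, .data$category)
  if (nrow(recs) == 0) {
    species <- tibble(species = character(), ur = integer(),
                      fc = integer(), nu = integer())
    categories <- tibble(category = character(), nur = integer(),
                         ntaxa = integer())
    cells <- tibble(species = character(), category = character(),
                    np = integer())
  }
  list(species = species, categories = categories, cells = cells)
}

#' Compute all consensus indices of a survey
#'
#' One pass from records to the four index tables a survey report prints:
#' per-species UR/FC/NU with UV, RFC, CI and RI; per-category Nur/Ntaxa with
#' ICF; per-cell Np with FL and CV; and the per-ailment top choices (maximal
#' CV, ties kept). Values are unrounded; use [format_index_tables()] or
#' [write_index_tables()] for publication-style rounding.
#'
#' @param x a [survey_dataset()].
#' @return an object of class `ethno_summary`: a list with tibbles
#'   `species`, `categories`, `cells`, `choices` plus `n_informants` and
#'   `n_records`. Explore it with [tidy()], [glance()] and [autoplot()].
#' @examples
#' x <- fars_survey()
#' s <- summarize_survey(x)
#' glance(s)
#' tidy(s, "species")
#' @export
summarize_survey <- function(x) {
  n <- n_informants(x)
  t <- tally_survey(x)
  species <- t$species
  if (nrow(species) > 0) {
    species <- species |>
      mutate(uv  = use_value(.data$ur, n),
             rfc = relative_frequency_of_citation(.data$fc, n),
             ci  = cultural_importance(.data$ur, n),
             ri  = relative_importance(.data$rfc, .data$nu))
  } else {
    species <- mutate(species, uv = numeric(), rfc = numeric(),
                      ci = numeric(), ri = numeric())
  }
  categories <- t$categories
  if (nrow(categories) > 0) {
    categories <- mutate(categories,
                         icf = informant_consensus_factor(.data$nur, .data$ntaxa))
  } else {
    categories <- mutate(categories, icf = numeric())
  }
  cells <- t$cells |>
    left_join(select(t$species, "species", "fc"), by = "species") |>
    left_join(select(categories, "category", "ntaxa"), by = "category")
  if (nrow(cells) > 0) {
    cells <- cells |>
      mutate(fl = fidelity_level(.data$np, .data$fc),
             cv = choice_value(.data$np, .data$ntaxa)) |>
      select("species", "category", "np", "fl", "cv")
  } else {
    cells <- tibble(species = character(), category = character(),
                    np = integer(), fl = numeric(), cv = numeric())
  }
  choices <- if (nrow(cells) == 0) {
    tibble(category = character(), species = character(), cv = numeric())
  } else {
    cells |>
      group_by(.data$category) |>
      filter(.data$cv == max(.data$cv)) |>
      ungroup() |>
      select("category", "species", "cv") |>
      arrange(.data$category, .data$species)
  }
  structure(list(species = species, categories = categories, cells = cells,
                 choices = choices, n_informants = n, n_records = nrow(x)),
            class = "ethno_summary")
}

#' @export
print.ethno_summary <- function(x, ...) {
  cat(sprintf("Consensus-index summary: %d species, %d ailment categories, %d use reports, N = %d informants\n",
              nrow(x$species), nrow(x$categories), x$n_records, x$n_informants))
  if (nrow(x$species) > 0) {
    top <- arrange(x$species, desc(.data$uv)) |> head(5)
    cat("Top species by use value:\n")
    print(as.data.frame(mutate(top, across(c("uv", "rfc", "ci", "ri"),
                                           ~ round_half_up(.x, 3)))),
          row.names = FALSE)
  }
  invisible(x)
}

#' Apply publication rounding to an index summary
#'
#' UV, RFC, CI and RI are rounded to 3 decimals and ICF, FL and CV to 2,
#' ties away from zero, matching how published tables print them. Internal
#' values stay unrounded in the `ethno_summary`.
#'
#' @param s an [summarize_survey()] result.
#' @return a list of four tibbles with rounded index columns.
#' @export
format_index_tables <- function(s) {
  stopifnot(inherits(s, "ethno_summary"))
  list(
    species = mutate(s$species,
                     across(c("uv", "rfc", "ci", "ri"), ~ round_half_up(.x, 3))),
    categories = mutate(s$categories, icf = round_half_up(.data$icf, 2)),
    cells = mutate(s$cells, across(c("fl", "cv"), ~ round_half_up(.x, 2))),
    choices = mutate(s$choices, cv = round_half_up(.data$cv, 2))
  )
}

#' Write the four index tables as CSV
#'
#' @param s an [summarize_survey()] result.
#' @param dir output directory (created if needed).
#' @return the four file paths, invisibly.
#' @export
write_index_tables <- function(s, dir) {
  tabs <- format_index_tables(s)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(tabs), function(nm) {
    write_csv_atomic(tabs[[nm]], file.path(dir, paste0(nm, ".csv")))
  }, character(1))
  invisible(paths)
}

#' Administration-route breakdown
#'
#' Descriptive percentages of route-tagged records (oral, topical, nasal,
#' vapor). The denominator is the number of records carrying a route tag;
#' untagged records are ignored. Informational output, not a consensus
#' index.
#'
#' @param x a [survey_dataset()] or data frame with a `route` column.
#' @return tibble with `route`, `n`, `percent` (integer, half-up).
#' @export
route_breakdown <- function(x) {
  x <- as_tibble(x)
  if (!"route" %in% names(x)) {
    return(tibble(route = character(), n = integer(), percent = numeric()))
  }
  x |>
    filter(!is.na(.data$route)) |>
    count(.data$route, sort = TRUE) |>
    mutate(percent = round_half_up(100 * .data$n / sum(.data$n)))
}
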