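#' Build a use-report survey dataset
#'
#' The atomic datum of a quantitative ethnobotany survey is the *use report*:
#' one informant citing one species for one ailment category. A
#' `survey_dataset` is a tibble of such records together with the total
#' number of informants interviewed (`n_informants`), which is the
#' denominator of every relative index and may exceed the number of
#' informants that actually cited anything.
#'
#' An informant citing the same species for the same category more than once
#' (for example with two different preparations) still contributes a single
#' use report: duplicate (informant, species, category) triples are collapsed
#' with a warning. This convention is what makes the cultural importance
#' index coincide with the use value (see [cultural_importance()]).
#'
#' @param records data frame with character columns `informant`, `species`,
#'   `category`; optional `plant_part`, `preparation`, `route` columns are
#'   carried along. `route`, when present, must be one of `"oral"`,
#'   `"topical"`, `"nasal"`, `"vapor"` or `NA`.
#' @param n_informants positive integer, total informants interviewed. Must
#'   be at least the number of distinct informants in `records`.
#' @param quiet suppress the deduplication warning.
#' @return a tibble of class `survey_dataset` with attribute `n_informants`.
#' @seealso [read_survey()], [tally_survey()], [summarize_survey()]
#' @examples
#' recs <- data.frame(informant = c("i1", "i1", "i2"),
#'                    species   = c("s1", "s1", "s1"),
#'                    category  = c("c1", "c2", "c1"))
#' survey_dataset(recs, n_informants = 10)
#' @export
survey_dataset <- function(records, n_informants, quiet = FALSE) {
  records <- as_tibble(records)
  required <- c("informant", "species", "category")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ethnotally_format_error")
  }
  records <- mutate(records, across(all_of(required),
                                    ~ stringr::str_squish(as.character(.x))))
  if (nrow(records) > 0 &&
      any(!stats::complete.cases(records[required]) |
          records$informant == "" | records$species == "" |
          records$category == "")) {
    abort("informant, species and category must all be non-empty",
          class = "ethnotally_validation_error")
  }
  if ("route" %in% names(records)) {
    bad <- setdiff(unique(records$route[!is.na(records$route)]),
                   c("oral", "topical", "nasal", "vapor"))
    if (length(bad) > 0) {
      abort(paste0("unknown administration route(s): ",
                   paste(bad, collapse = ", ")),
            class = "ethnotally_validation_error")
    }
  }
  n_dup <- nrow(records) - nrow(distinct(records, .data$informant,
                                         .data$species, .data$category))
  if (n_dup > 0) {
    records <- distinct(records, .data$informant, .data$species,
                        .data$category, .keep_all = TRUE)
    if (!quiet) {
      warn(sprintf("collapsed %d duplicate (informant, species, category) triple%s",
                   n_dup, if (n_dup == 1) "" else "s"))
    }
  }
  n_informants <- as.integer(n_informants)
  if (length(n_informants) != 1L || is.na(n_informants) || n_informants < 1L) {
    abort("n_informants must be a single positive integer",
          class = "ethnotally_validation_error")
  }
  n_distinct_inf <- n_distinct(records$informant)
  if (n_informants < n_distinct_inf) {
    abort(sprintf("n_informants (%d) is smaller than the %d distinct informants in the records",
                  n_informants, n_distinct_inf),
          class = "ethnotally_validation_error")
  }
  structure(records,
            n_informants = n_informants,
            class = c("survey_dataset", class(records)))
}

#' Total number of informants in a survey
#'
#' @param x a [survey_dataset()].
#' @return integer scalar.
#' @export
n_informants <- function(x) {
  n <- attr(x, "n_informants", exact = TRUE)
  if (is.null(n)) abort("x has no n_informants attribute; is it a survey_dataset?")
  n
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("# A use-report survey: %d record%s, %d species, %d categories, N = %d informants\n",
              nrow(x), if (nrow(x) == 1) "" else "s",
              n_distinct(x$species), n_distinct(x$category), n_informants(x)))
  NextMethod()
}

#' Read a long-format survey CSV
#'
#' Expects one row per use report with at least `informant`, `species` and
#' `category` columns (extra columns such as `plant_part`, `preparation` and
#' `route` are kept). The informant total is not derivable from the records
#' (interviewed informants may have cited nothing), so it is supplied either
#' directly or through a small YAML sidecar with an `n_informants` key; when
#' neither is given the distinct-informant count is used with a message.
#'
#' @param file path to a CSV file.
#' @param n_informants total informants interviewed, overriding `config`.
#' @param config path to a YAML file with an `n_informants` field.
#' @param synonyms optional synonym table (columns `variant`, `canonical`,
#'   `ambiguous`) used to rewrite species names to canonical form before
#'   keying; see [resolve_species()].
#' @return a [survey_dataset()].
#' @export
read_survey <- function(file, n_informants = NULL, config = NULL,
                        synonyms = NULL) {
  records <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  required <- c("informant", "species", "category")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0(file, " is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ethnotally_format_error")
  }
  if (is.null(n_informants) && !is.null(config)) {
    n_informants <- yaml::read_yaml(config)$n_informants
  }
  if (is.null(n_informants)) {
    n_informants <- n_distinct(records$informant)
    inform(sprintf("n_informants not supplied; using the %d distinct informants found",
                   n_informants))
  }
  if (!is.null(synonyms)) {
    records$species <- resolve_species(records$species, synonyms)
  }
  survey_dataset(records, n_informants = n_informants)
}

#' Write survey records to CSV
#'
#' Writes the record table only; `n_informants` travels in a sidecar config
#' or is re-supplied on read. Reading the file back with the same
#' `n_informants` reproduces the dataset exactly.
#'
#' @param x a [survey_dataset()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_survey <- function(x, file) {
  write_csv_atomic(as_tibble(x), file)
  invisible(file)
}

#' Resolve species names through a synonym table
#'
#' Published tables frequently name the same taxon in several ways --
#' abbreviated genus, a taxonomic synonym, with or without the author
#' citation. Resolution matches names after normalisation (case, whitespace,
#' trailing period, markdown emphasis) against a table of known variants and
#' rewrites them to the canonical name. Names not in the table are returned
#' unchanged (they may already be canonical); variants flagged ambiguous
#' (e.g. a genus-level "Ziziphus sp." where two congeners occur) resolve to
#' `NA` with a warning rather than to a guess.
#'
#' Resolution is idempotent: canonical names resolve to themselves.
#'
#' @param names character vector of species names as printed.
#' @param synonyms data frame with columns `variant`, `canonical` and logical
#'   `ambiguous`; defaults to the packaged southern-Fars table.
#' @param quiet suppress the ambiguity warning.
#' @return character vector of canonical names (`NA` where ambiguous).
#' @examples
#' resolve_species("Amygdalus lycioides Spach")  # "Prunus eburnea"
#' @export
resolve_species <- function(names, synonyms = fars_fixture("synonyms"),
                            quiet = FALSE) {
  key <- normalize_label(names)
  syn <- mutate(synonyms, key = normalize_label(.data$variant))
  amb <- unique(syn$key[syn$ambiguous])
  syn <- filter(syn, !.data$ambiguous)
  idx <- match(key, syn$key)
  out <- ifelse(is.na(idx), names, syn$canonical[idx])
  is_amb <- key %in% amb
  if (any(is_amb)) {
    out[is_amb] <- NA_character_
    if (!quiet) {
      warn(paste0("ambiguous species name(s) resolved to NA: ",
                  paste(unique(names[is_amb]), collapse = ", ")))
    }
  }
  out
}
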