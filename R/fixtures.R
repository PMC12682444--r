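#' Packaged southern-Fars ethnoveterinary survey tables
#'
#' Transcriptions of the published index tables from an ethnoveterinary
#' survey of 200 informants in 27 communities of southern Fars, Iran
#' (31 plant species, 21 families, 15 ailment categories). These are the
#' package's worked fixture: every index implemented here can be checked
#' against them, and the species-by-ailment report matrix can be rebuilt
#' from their margins with [reconstruct_np()].
#'
#' Available tables:
#' \describe{
#'   \item{`table1`}{per-species ethnobotany: family, voucher, local usage
#'     text, plant part, administration route, literature-reported usage
#'     (`"_"` where the literature review found none), and the
#'     novel/divergent/corroborated label with a `provisional` flag where
#'     the published account does not pin the label down.}
#'   \item{`table3`}{per-species indices: UR, UV, FC, RFC, CI, RI, NU.}
#'   \item{`table4`}{per-ailment Nur, Ntaxa, ICF.}
#'   \item{`table5`}{highest choice values per ailment.}
#'   \item{`table6`}{fidelity levels by species and ailment.}
#'   \item{`literature`}{long-format literature-reported uses, one
#'     normalised term per row with its source tag.}
#'   \item{`synonyms`}{species-name variants mapped to canonical names.}
#'   \item{`vocabulary`}{use-term vocabulary mapping free-text ailment
#'     phrases to the 15 canonical categories.}
#' }
#'
#' Species names in `table3`, `table5` and `table6` are kept as printed;
#' set `resolve = TRUE` to rewrite them to canonical form (adding an
#' `ambiguous` column for `table5`, whose genus-level "Ziziphus sp." row
#' cannot be attributed to either congener). The Ephedra pachyclada row of
#' `table1` and its literature entry are synthetic: the species appears in
#' the published complex-remedy table without a literature cell, and is
#' carried with `provisional = TRUE` so the species, family and
#' classification totals close.
#'
#' @param table one of `"table1"`, `"table3"`, `"table4"`, `"table5"`,
#'   `"table6"`, `"literature"`, `"synonyms"`, `"vocabulary"`.
#' @param resolve rewrite printed species names to canonical form.
#' @return a tibble.
#' @examples
#' fars_fixture("table4")
#' @export
fars_fixture <- function(table = c("table1", "table3", "table4", "table5",
                                   "table6", "literature", "synonyms",
                                   "vocabulary"),
                         resolve = FALSE) {
  table <- match.arg(table)
  x <- readr::read_csv(fixture_path(table), show_col_types = FALSE,
                       progress = FALSE)
  expected <- .fixture_shape[[table]]
  if (nrow(x) != expected$rows || !all(expected$cols %in% names(x))) {
    abort(sprintf("fixture %s fails its integrity check (%d rows, expected %d): has the packaged file been altered?",
                  table, nrow(x), expected$rows),
          class = "ethnotally_integrity_error")
  }
  if (resolve && table %in% c("table3", "table5", "table6")) {
    if (table == "table5") {
      syn <- fars_fixture("synonyms")
      x <- mutate(x,
                  ambiguous = normalize_label(.data$species) %in%
                    normalize_label(syn$variant[syn$ambiguous]),
                  species = resolve_species(.data$species, syn, quiet = TRUE))
    } else {
      x <- mutate(x, species = resolve_species(.data$species))
    }
  }
  x
}

fixture_path <- function(table) {
  system.file("extdata", paste0("fars_", table, ".csv"),
              package = "ethnotally", mustWork = TRUE)
}

# row counts and required columns, frozen at transcription time
.fixture_shape <- list(
  table1     = list(rows = 31L, cols = c("species", "family", "voucher", "usage",
                                         "plant_part", "route", "reported_usage",
                                         "label", "provisional")),
  table3     = list(rows = 31L, cols = c("no", "species", "ur", "uv", "fc",
                                         "rfc", "ci", "ri", "nu")),
  table4     = list(rows = 15L, cols = c("ailment", "nur", "ntaxa", "icf")),
  table5     = list(rows = 19L, cols = c("ailment", "species", "cv")),
  table6     = list(rows = 59L, cols = c("ailment", "species", "fl")),
  literature = list(rows = 85L, cols = c("species", "term", "source", "provisional")),
  synonyms   = list(rows = 47L, cols = c("variant", "canonical", "ambiguous")),
  vocabulary = list(rows = 70L, cols = c("term", "category"))
)

#' Number of informants in the southern-Fars survey
#'
#' @return 200L, from the packaged survey configuration.
#' @export
fars_n_informants <- function() {
  cfg <- yaml::read_yaml(system.file("extdata", "fars_config.yaml",
                                     package = "ethnotally", mustWork = TRUE))
  as.integer(cfg$n_informants)
}
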