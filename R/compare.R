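#' Classify local uses against the literature
#'
#' Each locally documented species-use is compared with
#' literature-reported uses of the same species: a species with no
#' literature record at all is a **novel** use; one whose literature terms,
#' once normalised through the use-term vocabulary, share at least one
#' ailment category with the local uses is **corroborated**; literature
#' present but disjoint from the local categories is **divergent**.
#'
#' Literature phrases the vocabulary cannot map are never silently
#' dropped: they are carried in `unmatched_terms` (an unmatched term can
#' only weaken a corroboration call, so surfacing them is what makes the
#' labels auditable).
#'
#' @param local_uses tibble with `species`, `category` (one row per local
#'   species-use category).
#' @param literature tibble with `species`, `term` (free-text reported
#'   use), optional `source`.
#' @param vocabulary tibble with `term`, `category` mapping free-text
#'   phrases to the category vocabulary; defaults to the packaged one.
#' @return tibble with `species`, `label` (`"novel"`, `"divergent"`,
#'   `"corroborated"`), `matched_terms`, `unmatched_terms` (`"; "`-joined).
#' @examples
#' classify_uses(
#'   local_uses = tibble::tibble(species = "Tecomella undulata",
#'                               category = "animal bite"),
#'   literature = tibble::tibble(species = character(), term = character()))
#' @export
classify_uses <- function(local_uses, literature,
                          vocabulary = fars_fixture("vocabulary")) {
  local_uses <- as_tibble(local_uses)
  literature <- as_tibble(literature)
  stopifnot(all(c("species", "category") %in% names(local_uses)),
            all(c("species", "term") %in% names(literature)))
  voc <- mutate(vocabulary, key = normalize_label(.data$term))
  lit <- literature |>
    mutate(key = normalize_label(.data$term),
           mapped = voc$category[match(.data$key, voc$key)])

  local_uses |>
    group_by(.data$species) |>
    summarise(local_cats = list(unique(.data$category)), .groups = "drop") |>
    rowwise() |>
    mutate(classify_one(.data$species, .data$local_cats, lit)) |>
    ungroup() |>
    select("species", "label", "matched_terms", "unmatched_terms")
}

classify_one <- function(species, local_cats, lit) {
  mine <- lit[lit$species == species, ]
  if (nrow(mine) == 0) {
    return(tibble(label = "novel", matched_terms = "", unmatched_terms = ""))
  }
  hit <- !is.na(mine$mapped) & mine$mapped %in% local_cats
  tibble(label = if (any(hit)) "corroborated" else "divergent",
         matched_terms = paste(mine$term[hit], collapse = "; "),
         unmatched_terms = paste(mine$term[is.na(mine$mapped)], collapse = "; "))
}

#' Tabulate use classifications
#'
#' @param classifications a [classify_uses()] result (or any data frame
#'   with a `label` column).
#' @param total denominator for the percentages; defaults to the number of
#'   classified uses.
#' @return tibble with `label`, `n`, `percent` (integer, half-up), one row
#'   per label including zero counts.
#' @examples
#' summarize_classifications(
#'   data.frame(label = c("novel", "novel", "corroborated")))
#' @export
summarize_classifications <- function(classifications,
                                      total = nrow(classifications)) {
  if (total <= 0) abort("total must be positive",
                        class = "ethnotally_domain_error")
  lv <- c("novel", "divergent", "corroborated")
  tibble(label = lv) |>
    left_join(count(as_tibble(classifications), .data$label), by = "label") |>
    mutate(n = coalesce(.data$n, 0L),
           percent = round_half_up(100 * .data$n / total))
}

#' Classify the southern-Fars uses and compare with the published labels
#'
#' Runs the automatic matcher over the packaged fixture -- local ailment
#' categories taken from the reconstructed report matrix, literature terms
#' from the packaged literature table -- and joins the per-species label
#' carried by the fixture. The published account names only three labels
#' explicitly (the rest of the fixture labels are provisional), so
#' disagreements between matcher and fixture are returned in the `agrees`
#' column rather than hidden.
#'
#' @return tibble with `species`, `label` (matcher), `label_fixture`,
#'   `provisional`, `agrees`, `matched_terms`, `unmatched_terms`.
#' @export
fars_use_comparison <- function() {
  local_uses <- reconstruct_np(fars_margins()) |>
    select("species", "category")
  cls <- classify_uses(local_uses, fars_fixture("literature"))
  fixture <- select(fars_fixture("table1"), "species",
                    label_fixture = "label", "provisional")
  cls |>
    left_join(fixture, by = "species") |>
    mutate(agrees = .data$label == .data$label_fixture) |>
    arrange(.data$species)
}
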