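#' Tidy an index summary
#'
#' @param x an [summarize_survey()] result.
#' @param table which index table to return: `"species"`, `"categories"`,
#'   `"cells"` or `"choices"`.
#' @param rounded apply publication rounding (see [format_index_tables()]).
#' @param ... unused.
#' @return a tibble.
#' @method tidy ethno_summary
#' @export
tidy.ethno_summary <- function(x, table = c("species", "categories",
                                            "cells", "choices"),
                               rounded = FALSE, ...) {
  table <- match.arg(table)
  if (rounded) format_index_tables(x)[[table]] else x[[table]]
}

#' One-row overview of an index summary
#'
#' @param x an [summarize_survey()] result.
#' @param ... unused.
#' @return a tibble with one row: counts of informants, records, species
#'   and categories, the FC range, the maximum UV, and the number of cells
#'   at 100% fidelity.
#' @method glance ethno_summary
#' @export
glance.ethno_summary <- function(x, ...) {
  tibble(
    n_informants = x$n_informants,
    n_records = x$n_records,
    n_species = nrow(x$species),
    n_categories = nrow(x$categories),
    total_ur = sum(x$species$ur),
    fc_min = if (nrow(x$species)) min(x$species$fc) else NA_integer_,
    fc_max = if (nrow(x$species)) max(x$species$fc) else NA_integer_,
    uv_max = if (nrow(x$species)) max(x$species$uv) else NA_real_,
    n_fl_100 = sum(round_half_up(x$cells$fl, 2) == 100)
  )
}

#' @method glance consistency_report
#' @export
glance.consistency_report <- function(x, ...) {
  tibble(n_checks_flagged = nrow(x),
         n_failures = sum(x$severity == "failure"),
         n_warnings = sum(x$severity == "warning"),
         n_info = sum(x$severity == "info"))
}
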