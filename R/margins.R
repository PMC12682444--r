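#' Bundle published table margins for reconstruction
#'
#' A survey report usually prints aggregate tables, not the raw records:
#' per-species FC and UR, per-cell fidelity levels, per-ailment Nur and
#' Ntaxa. Those margins pin down the species-by-ailment report matrix, so
#' the analysis can be re-run and cross-checked without the field data.
#'
#' @param species tibble with `species`, `fc`, `ur` (optionally `nu`,
#'   `uv`, `rfc`, `ci`, `ri`).
#' @param cells tibble with `species`, `category`, `fl` (fidelity level,
#'   percent). Every species here must appear in `species`.
#' @param categories optional tibble with `category`, `nur`, `ntaxa`
#'   (optionally `icf`) as printed.
#' @param choices optional tibble of printed choice values: `category`,
#'   `species` (`NA` where the printed name is ambiguous), `cv`, and
#'   optionally a logical `ambiguous` column.
#' @param n_informants total informants interviewed.
#' @return an object of class `margin_set`.
#' @seealso [reconstruct_np()], [validate_margins()], [fars_margins()]
#' @export
margin_set <- function(species, cells, categories = NULL, choices = NULL,
                       n_informants) {
  species <- as_tibble(species)
  cells <- as_tibble(cells)
  stopifnot(all(c("species", "fc", "ur") %in% names(species)),
            all(c("species", "category", "fl") %in% names(cells)))
  orphans <- setdiff(cells$species, species$species)
  if (length(orphans) > 0) {
    abort(paste0("species in the fidelity table missing from the species margins: ",
                 paste(orphans, collapse = ", ")),
          class = "ethnotally_validation_error")
  }
  structure(list(species = species, cells = cells,
                 categories = if (!is.null(categories)) as_tibble(categories),
                 choices = if (!is.null(choices)) as_tibble(choices),
                 n_informants = as.integer(n_informants)),
            class = "margin_set")
}

#' Margins of the southern-Fars survey
#'
#' Builds a [margin_set()] from the packaged fixture tables with species
#' names resolved to canonical form.
#'
#' @return a `margin_set` with N = 200.
#' @export
fars_margins <- function() {
  t3 <- fars_fixture("table3", resolve = TRUE)
  t4 <- rename(fars_fixture("table4"), category = "ailment")
  t5 <- rename(fars_fixture("table5", resolve = TRUE), category = "ailment")
  t6 <- rename(fars_fixture("table6", resolve = TRUE), category = "ailment")
  margin_set(species = select(t3, "species", "fc", "ur", "nu"),
             cells = select(t6, "species", "category", "fl"),
             categories = t4,
             choices = t5,
             n_informants = fars_n_informants())
}

#' Rebuild the species-by-ailment report matrix from margins
#'
#' Inverts the fidelity-level formula: since \eqn{FL_{s,c} =
#' 100\,Np_{s,c}/FC_s} was printed after rounding, \eqn{Np_{s,c} =
#' \mathrm{round}(FL_{s,c} \cdot FC_s / 100)} (ties up) recovers the integer
#' cell counts. Cells absent from the fidelity table have \eqn{Np = 0}. A
#' listed cell reconstructing to zero informants contradicts its own FL
#' entry and raises a validation error.
#'
#' @param margins a [margin_set()].
#' @return tibble with `species`, `category`, `fl`, `np`.
#' @examples
#' np <- reconstruct_np(fars_margins())
#' subset(np, species == "Ferula assa-foetida" & category == "digestive")
#' @export
reconstruct_np <- function(margins) {
  stopifnot(inherits(margins, "margin_set"))
  out <- margins$cells |>
    inner_join(select(margins$species, "species", "fc"), by = "species") |>
    mutate(np = as.integer(round_half_up(.data$fl * .data$fc / 100))) |>
    select("species", "category", "fl", "np")
  if (any(out$np == 0)) {
    bad <- filter(out, .data$np == 0)
    abort(paste0("listed fidelity cell(s) reconstruct to zero informants: ",
                 paste(bad$species, bad$category, sep = "/", collapse = "; ")),
          class = "ethnotally_validation_error")
  }
  out
}

#' Cross-check reconstructed cells against printed margins
#'
#' Recomputes every derivable quantity from the reconstructed cell counts
#' and compares it with the printed tables: (a) row sums against UR, (b)
#' column sums against Nur, (c) distinct taxa against Ntaxa, (d) choice
#' values against the printed CV table, (e) ICF against the printed ICF,
#' plus the grand total \eqn{\sum_s UR_s} versus \eqn{\sum_c Nur_c}.
#'
#' Findings never stop the run; they are returned as a report, one row per
#' violation, with severities: `"warning"` for a direct contradiction
#' between printed tables, `"info"` for a downstream consequence of one
#' (e.g. the ICF implied by a miscounted Nur) or a printed-rounding
#' artefact, `"failure"` for structural impossibilities. Margins tallied
#' from an actual dataset are consistent by construction and give an empty
#' report.
#'
#' @param margins a [margin_set()].
#' @param cells reconstructed cells, by default [reconstruct_np()]`(margins)`.
#' @return a tibble of class `consistency_report` with columns `check`,
#'   `scope`, `expected`, `observed`, `severity`, `note`.
#' @examples
#' validate_margins(fars_margins())
#' @export
validate_margins <- function(margins, cells = reconstruct_np(margins)) {
  stopifnot(inherits(margins, "margin_set"))
  rows <- list()
  add <- function(check, scope, expected, observed, severity, note = "") {
    rows[[length(rows) + 1L]] <<- tibble(
      check = check, scope = scope,
      expected = as.numeric(expected), observed = as.numeric(observed),
      severity = severity, note = note)
  }

  # (a) row sums vs printed UR
  ur_obs <- cells |>
    group_by(.data$species) |>
    summarise(ur_obs = sum(.data$np), .groups = "drop") |>
    right_join(select(margins$species, "species", "ur"), by = "species") |>
    mutate(ur_obs = coalesce(.data$ur_obs, 0L))
  for (i in which(ur_obs$ur_obs != ur_obs$ur)) {
    add("species_ur", ur_obs$species[i], ur_obs$ur[i], ur_obs$ur_obs[i],
        "warning", "sum of reconstructed Np disagrees with printed UR")
  }

  cat_obs <- cells |>
    group_by(.data$category) |>
    summarise(nur_obs = sum(.data$np),
              ntaxa_obs = n_distinct(.data$species), .groups = "drop")

  flagged <- character()
  if (!is.null(margins$categories)) {
    cmp <- full_join(cat_obs, margins$categories, by = "category") |>
      mutate(nur_obs = coalesce(.data$nur_obs, 0L),
             ntaxa_obs = coalesce(.data$ntaxa_obs, 0L))
    # (b) column sums vs printed Nur
    for (i in which(cmp$nur_obs != cmp$nur)) {
      add("category_nur", cmp$category[i], cmp$nur[i], cmp$nur_obs[i],
          "warning", "sum of reconstructed Np disagrees with printed Nur")
      flagged <- c(flagged, cmp$category[i])
    }
    # (c) distinct taxa vs printed Ntaxa
    for (i in which(cmp$ntaxa_obs != cmp$ntaxa)) {
      add("category_ntaxa", cmp$category[i], cmp$ntaxa[i], cmp$ntaxa_obs[i],
          "warning", "taxa with nonzero Np disagree with printed Ntaxa")
      flagged <- c(flagged, cmp$category[i])
    }
    # (e) ICF recomputed from reconstructed margins vs printed
    if ("icf" %in% names(cmp)) {
      # inline ICF (with its Nur <= 1 convention) so empty observed
      # categories cannot trip the count validation of the public function
      cmp <- mutate(cmp, icf_obs = round_half_up(
        ifelse(.data$nur_obs <= 1, 0,
               (.data$nur_obs - .data$ntaxa_obs) / (.data$nur_obs - 1)), 2))
      for (i in which(cmp$icf_obs != cmp$icf)) {
        sev <- if (cmp$category[i] %in% flagged) "info" else "warning"
        add("category_icf", cmp$category[i], cmp$icf[i], cmp$icf_obs[i], sev,
            if (sev == "info") "follows from the Nur/Ntaxa discrepancy above"
            else "recomputed ICF disagrees with printed value")
      }
    }
    # grand totals
    tot_ur <- sum(margins$species$ur)
    tot_nur <- sum(margins$categories$nur)
    if (tot_ur != tot_nur) {
      add("grand_total", "all", tot_nur, tot_ur, "info",
          "printed per-species and per-category report totals disagree")
    }
  }

  # (d) choice values vs printed CV
  if (!is.null(margins$choices)) {
    cv_cells <- cells |>
      left_join(cat_obs, by = "category") |>
      mutate(cv_obs = round_half_up(choice_value(.data$np, .data$ntaxa_obs), 2))
    ch <- margins$choices
    if (!"ambiguous" %in% names(ch)) ch$ambiguous <- is.na(ch$species)
    for (i in seq_len(nrow(ch))) {
      pool <- filter(cv_cells, .data$category == ch$category[i])
      if (isTRUE(ch$ambiguous[i]) || is.na(ch$species[i])) {
        if (nrow(pool) == 0 || !any(pool$cv_obs == ch$cv[i])) {
          add("choice_cv", paste0(ch$category[i], " / <ambiguous>"), ch$cv[i],
              if (nrow(pool)) pool$cv_obs[which.min(abs(pool$cv_obs - ch$cv[i]))] else NA,
              "warning", "no reconstructed cell in the category matches the printed CV")
        }
        next
      }
      cell <- filter(pool, .data$species == ch$species[i])
      if (nrow(cell) == 0) {
        add("choice_cv", paste0(ch$category[i], " / ", ch$species[i]),
            ch$cv[i], NA, "failure", "printed choice has no reconstructed cell")
      } else if (cell$cv_obs[1] != ch$cv[i]) {
        sev <- if (abs(cell$cv_obs[1] - ch$cv[i]) <= 0.015) "info" else "warning"
        add("choice_cv", paste0(ch$category[i], " / ", ch$species[i]),
            ch$cv[i], cell$cv_obs[1], sev,
            if (sev == "info") "printed value rounded differently (half-down)"
            else "recomputed CV disagrees with printed value")
      }
    }
  }

  report <- if (length(rows)) bind_rows(rows) else
    tibble(check = character(), scope = character(), expected = numeric(),
           observed = numeric(), severity = character(), note = character())
  structure(report, class = c("consistency_report", class(report)))
}

#' @export
print.consistency_report <- function(x, ...) {
  n_by <- table(factor(x$severity, levels = c("failure", "warning", "info")))
  if (nrow(x) == 0) {
    cat("Consistency report: all checks passed\n")
    return(invisible(x))
  }
  cat(sprintf("Consistency report: %d failure(s), %d warning(s), %d informational note(s)\n",
              n_by[["failure"]], n_by[["warning"]], n_by[["info"]]))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %s @ %s: expected %s, observed %s%s\n",
                x$severity[i], x$check[i], x$scope[i],
                format(x$expected[i]), format(x$observed[i]),
                if (nzchar(x$note[i])) paste0(" (", x$note[i], ")") else ""))
  }
  invisible(x)
}

#' Tally a survey into a margin set
#'
#' The forward direction of the reconstruction round trip: compute the
#' margins (species FC/UR/NU, cell FL, category Nur/Ntaxa/ICF, top CV) that
#' a report would print for this dataset. `validate_margins()` on the
#' result is empty by construction, and
#' `tally_survey(realize_survey(...))` reproduces these margins exactly.
#'
#' @param x a [survey_dataset()].
#' @return a [margin_set()].
#' @export
margins_from_survey <- function(x) {
  s <- summarize_survey(x)
  margin_set(
    species = select(s$species, "species", "fc", "ur", "nu"),
    cells = select(s$cells, "species", "category", "fl"),
    categories = mutate(select(s$categories, "category", "nur", "ntaxa"),
                        icf = round_half_up(informant_consensus_factor(
                          .data$nur, .data$ntaxa), 2)),
    choices = mutate(s$choices, cv = round_half_up(.data$cv, 2),
                     ambiguous = FALSE),
    n_informants = s$n_informants)
}

#' Construct an informant-level dataset realizing a cell matrix
#'
#' The constructive inverse of [tally_survey()]: given cell counts
#' \eqn{Np_{s,c}} and per-species informant totals \eqn{FC_s}, emit
#' synthetic informant identifiers such that tallying the result returns
#' exactly the input margins. For each species, \eqn{FC_s} informant slots
#' are created and the \eqn{Np_{s,c}} citations of each category (taken
#' alphabetically) are dealt to consecutive slots by a single round-robin
#' pointer, so every slot receives at least one category whenever
#' \eqn{\sum_c Np_{s,c} \ge FC_s}. The construction is fully deterministic;
#' `seed` is accepted for interface symmetry with the generator and logged
#' by the command-line wrapper, but does not alter the output.
#'
#' Informant identifiers are namespaced per species: the printed tables
#' carry no information about which informants were shared between species,
#' so no cross-species overlap is modelled (a documented limitation --
#' total distinct informants is the sum of the FC values, and relative
#' indices are unaffected).
#'
#' @param cells tibble with `species`, `category`, `np` (positive counts).
#' @param fc tibble with `species`, `fc`.
#' @param n_informants total informants for the resulting dataset.
#' @param seed ignored (see above).
#' @return a [survey_dataset()].
#' @examples
#' m <- fars_margins()
#' x <- realize_survey(reconstruct_np(m), m$species, m$n_informants)
#' tally_survey(x)$species[tally_survey(x)$species$species ==
#'                           "Ferula assa-foetida", ]
#' @export
realize_survey <- function(cells, fc, n_informants, seed = NULL) {
  cells <- filter(as_tibble(cells), .data$np > 0)
  fc <- select(as_tibble(fc), "species", "fc")
  feas <- cells |>
    group_by(.data$species) |>
    summarise(max_np = max(.data$np), sum_np = sum(.data$np),
              .groups = "drop") |>
    inner_join(fc, by = "species")
  missing_fc <- setdiff(cells$species, fc$species)
  if (length(missing_fc) > 0) {
    abort(paste0("no FC margin for species: ",
                 paste(missing_fc, collapse = ", ")),
          class = "ethnotally_infeasible_error")
  }
  bad <- filter(feas, .data$max_np > .data$fc | .data$fc > .data$sum_np)
  if (nrow(bad) > 0) {
    abort(paste0("infeasible margins (need max Np <= FC <= sum Np) for species: ",
                 paste(bad$species, collapse = ", ")),
          class = "ethnotally_infeasible_error")
  }
  records <- cells |>
    arrange(.data$species, .data$category) |>
    group_by(.data$species) |>
    group_modify(function(d, key) {
      n_slots <- fc$fc[fc$species == key$species]
      ptr <- 0L
      out <- vector("list", nrow(d))
      for (j in seq_len(nrow(d))) {
        slots <- (ptr + seq_len(d$np[j]) - 1L) %% n_slots
        ptr <- (ptr + d$np[j]) %% n_slots
        out[[j]] <- tibble(category = d$category[j], slot = slots)
      }
      bind_rows(out)
    }) |>
    ungroup() |>
    transmute(informant = sprintf("%s#%03d", .data$species, .data$slot),
              species = .data$species, category = .data$category)
  survey_dataset(records, n_informants = n_informants)
}

#' The southern-Fars survey as an informant-level dataset
#'
#' Reconstructs the species-by-ailment report matrix from the packaged
#' margins and realizes it as use-report records with N = 200. Tallying
#' this dataset reproduces every printed per-species index.
#'
#' @return a [survey_dataset()].
#' @export
fars_survey <- function() {
  m <- fars_margins()
  realize_survey(reconstruct_np(m), m$species, m$n_informants)
}
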