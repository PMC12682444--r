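#' Consensus indices for use-report surveys
#'
#' Scalar (vectorised) forms of the standard quantitative-ethnobotany
#' indices. Writing `UR_s` for the use reports of species *s* (distinct
#' (informant, category) citations), `FC_s` for its frequency of citation
#' (distinct citing informants), `NU_s` for its number of use categories,
#' `N` for the total informants interviewed, `Nur_c` and `Ntaxa_c` for the
#' use reports and distinct taxa within ailment category *c*, and `Np_{s,c}`
#' for the informants citing species *s* for category *c*:
#'
#' \describe{
#'   \item{use value}{\eqn{UV_s = UR_s / N}}
#'   \item{relative frequency of citation}{\eqn{RFC_s = FC_s / N}}
#'   \item{cultural importance}{\eqn{CI_s = \sum_c Np_{s,c} / N = UR_s / N};
#'     identical to UV under the one-report-per-(informant, category)
#'     convention of [survey_dataset()].}
#'   \item{informant consensus factor}{\eqn{ICF_c = (Nur_c - Ntaxa_c) /
#'     (Nur_c - 1)}, defined as 0 when \eqn{Nur_c \le 1} (the formula is
#'     0/0 there and a single report carries no consensus information).}
#'   \item{fidelity level}{\eqn{FL_{s,c} = 100\, Np_{s,c} / FC_s}, a
#'     percentage.}
#'   \item{choice value}{\eqn{CV_{s,c} = Np_{s,c} / Ntaxa_c}.}
#'   \item{relative importance}{\eqn{RI_s = (RFC_s / \max_s RFC_s +
#'     NU_s / \max_s NU_s) / 2}, which is 1 exactly for a species maximal
#'     in both salience and versatility.}
#' }
#'
#' All functions return unrounded values; published tables round UV, RFC,
#' CI and RI to 3 decimals and ICF, FL and CV to 2, ties up (see
#' [round_half_up()] and [format_index_tables()]).
#'
#' @param ur,fc,nu,n,nur,ntaxa,np nonnegative integer counts as defined above.
#' @param rfc numeric RFC values.
#' @param max_rfc,max_nu the survey-wide maxima used for normalisation;
#'   default to the maxima of the supplied vectors.
#' @return numeric vector of index values.
#' @examples
#' use_value(88, 200)                         # 0.44
#' relative_frequency_of_citation(58, 200)    # 0.29
#' informant_consensus_factor(70, 11)         # 0.855...
#' fidelity_level(47, 58)                     # 81.03...
#' choice_value(47, 11)                       # 4.27...
#' relative_importance(0.07, 3, 0.29, 9)      # 0.287...
#' @name consensus-indices
NULL

#' @rdname consensus-indices
#' @export
use_value <- function(ur, n) {
  check_counts(ur = ur)
  if (any(n <= 0)) abort("n must be positive", class = "ethnotally_domain_error")
  ur / n
}

#' @rdname consensus-indices
#' @export
cultural_importance <- function(ur, n) use_value(ur, n)

#' @rdname consensus-indices
#' @export
relative_frequency_of_citation <- function(fc, n) {
  check_counts(fc = fc)
  if (any(n <= 0)) abort("n must be positive", class = "ethnotally_domain_error")
  if (any(fc > n)) {
    abort("fc cannot exceed n: a species cannot be cited by more informants than were interviewed",
          class = "ethnotally_validation_error")
  }
  fc / n
}

#' @rdname consensus-indices
#' @export
informant_consensus_factor <- function(nur, ntaxa) {
  check_counts(nur = nur, ntaxa = ntaxa)
  if (any(ntaxa < 1)) {
    abort("ntaxa must be at least 1", class = "ethnotally_validation_error")
  }
  if (any(ntaxa > nur)) {
    abort("ntaxa cannot exceed nur: every cited taxon contributes at least one report",
          class = "ethnotally_validation_error")
  }
  ifelse(nur <= 1, 0, (nur - ntaxa) / (nur - 1))
}

#' @rdname consensus-indices
#' @export
fidelity_level <- function(np, fc) {
  check_counts(np = np)
  if (any(fc <= 0)) abort("fc must be positive", class = "ethnotally_domain_error")
  if (any(np > fc)) {
    abort("np cannot exceed fc: a cell cannot have more citers than the species has overall",
          class = "ethnotally_validation_error")
  }
  100 * np / fc
}

#' @rdname consensus-indices
#' @export
choice_value <- function(np, ntaxa) {
  check_counts(np = np)
  if (any(ntaxa <= 0)) {
    abort("ntaxa must be positive", class = "ethnotally_domain_error")
  }
  np / ntaxa
}

#' @rdname consensus-indices
#' @export
relative_importance <- function(rfc, nu, max_rfc = max(rfc), max_nu = max(nu)) {
  if (length(rfc) == 0) {
    abort("cannot compute relative importance of an empty species table",
          class = "ethnotally_domain_error")
  }
  if (max_rfc <= 0 || max_nu <= 0) {
    abort("max_rfc and max_nu must be positive",
          class = "ethnotally_domain_error")
  }
  (rfc / max_rfc + nu / max_nu) / 2
}

check_counts <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
      abort(paste0(nm, " must be a nonnegative integer count"),
            class = "ethnotally_validation_error")
    }
  }
  invisible(NULL)
}
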