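#' Round half away from zero
#'
#' Decimal rounding with the "half-up" tie rule used when emitting index
#' tables: 0.005 rounds to 0.01, not to 0.00 as under the IEEE
#' round-half-even rule of [base::round()]. Published ethnobotanical tables
#' are rounded this way, so reproducing them bit-for-bit requires it.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded to `digits` places, ties away from zero.
#' @examples
#' round_half_up(0.005, 2)   # 0.01
#' round(0.005, 2)           # 0
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  scale <- 10^digits
  # nudge by an epsilon well below the data's precision so that values like
  # 2/3*100 = 66.666... survive binary representation of the .5 boundary
  trunc(abs(x) * scale + 0.5 + 1e-9) * sign(x) / scale
}

# lowercase, squish whitespace, strip markdown emphasis and a trailing period;
# the normal form used for species-name and use-term matching
normalize_label <- function(x) {
  x <- gsub("\\*", "", as.character(x))
  x <- stringr::str_squish(tolower(x))
  sub("\\.$", "", x)
}

# write a data frame as CSV atomically: build in a sibling temp file, then rename
write_csv_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  readr::write_csv(x, tmp, progress = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

# seed scoping: run code under a seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
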