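# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Percentages in summary tables are reported with conventional half-up
#' rounding (0.05 -> 0.1), not the IEEE banker's rounding of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Canonicalise a species binomial
#'
#' Trims and squashes whitespace, then case-normalises to "Genus epithet"
#' form so that matching across sources is case-insensitive. No synonym
#' resolution is attempted.
#'
#' @param x character vector of species names.
#' @return character vector of canonical binomials.
#' @keywords internal
canonical_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  x <- tolower(x)
  has <- nzchar(x)
  x[has] <- paste0(toupper(substring(x[has], 1, 1)), substring(x[has], 2))
  x
}

#' Normalise longitudes to (-180, 180]
#' @param lon numeric vector of longitudes in degrees.
#' @keywords internal
normalize_lon <- function(lon) {
  l <- ((lon + 180) %% 360) - 180
  l[!is.na(l) & l == -180] <- 180
  l
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(...)), call. = FALSE)
}
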