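# Strict-threshold hypothetical Red List categorisation from EOO alone.
#
# This is a criterion-B1 screening, not a full assessment: only the EOO
# thresholds are applied, with strict less-than comparisons, and an
# undefined EOO maps to Data Deficient. The NT cutoff (< 30,000 km^2) is a
# screening convention rather than an official criterion-B boundary.

#' Red List category labels, in table order
#'
#' `DD` (Data Deficient) then the ranked labels from most to least
#' threatened: `CR`, `EN`, `VU`, `NT`, `LC`.
#' @export
category_levels <- function() c("DD", "CR", "EN", "VU", "NT", "LC")

#' Threat rank of a category
#'
#' CR=4 > EN=3 > VU=2 > NT=1 > LC=0; DD is unranked (`NA`). Comparisons are
#' defined only between ranked labels.
#' @param category character or factor vector of category labels.
#' @return integer vector of ranks (`NA` for DD).
#' @export
threat_rank <- function(category) {
  ranks <- c(DD = NA_integer_, CR = 4L, EN = 3L, VU = 2L, NT = 1L, LC = 0L)
  unname(ranks[as.character(category)])
}

#' EOO threshold scheme
#'
#' Strictly increasing area thresholds (km^2) compared with strict `<`:
#' EOO < cr -> CR, < en -> EN, < vu -> VU, < nt -> NT, otherwise LC. An area
#' exactly at a threshold falls in the less-threatened category. Defaults
#' are the standard criterion-B1 values plus the NT screening cutoff.
#'
#' @param cr,en,vu,nt thresholds in km^2.
#' @return a `threshold_scheme` object.
#' @export
threshold_scheme <- function(cr = 100, en = 5000, vu = 20000, nt = 30000) {
  t <- c(cr = cr, en = en, vu = vu, nt = nt)
  if (anyNA(t) || any(t <= 0)) stop_stage("redlist_classifier", "thresholds must be positive")
  if (any(diff(t) <= 0)) stop_stage("redlist_classifier", "thresholds must be strictly increasing")
  structure(as.list(t), class = "threshold_scheme")
}

#' @export
print.threshold_scheme <- function(x, ...) {
  cat(sprintf("<threshold_scheme> CR < %g, EN < %g, VU < %g, NT < %g km^2 (strict <)\n",
              x$cr, x$en, x$vu, x$nt))
  invisible(x)
}

#' Classify an EOO value into a hypothetical Red List category
#'
#' Vectorised over areas. `NA` (undefined EOO: fewer than three data points)
#' maps to DD; a zero-area EOO (three or more coincident or collinear
#' records) is defined and maps to CR.
#'
#' @param area_km2 numeric vector of EOO areas (km^2), `NA` = undefined, or
#'   a single `eoo_hull` object.
#' @param scheme a [threshold_scheme()].
#' @return factor with levels [category_levels()].
#' @export
classify_eoo <- function(area_km2, scheme = threshold_scheme()) {
  if (inherits(area_km2, "eoo_hull")) area_km2 <- area_km2$area_km2
  if (!inherits(scheme, "threshold_scheme"))
    stop_stage("redlist_classifier", "scheme must be a threshold_scheme")
  area_km2 <- as.numeric(area_km2)
  if (any(!is.na(area_km2) & area_km2 < 0))
    stop_stage("redlist_classifier", "negative EOO area")
  lab <- ifelse(is.na(area_km2), "DD",
         ifelse(area_km2 < scheme$cr, "CR",
         ifelse(area_km2 < scheme$en, "EN",
         ifelse(area_km2 < scheme$vu, "VU",
         ifelse(area_km2 < scheme$nt, "NT", "LC")))))
  factor(lab, levels = category_levels())
}
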