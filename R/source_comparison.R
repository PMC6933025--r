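# Assessing every species under three source modes and tabulating the
# comparison: the category-by-source table, shift flags, and the derived
# percentages.

OCC_MODES <- c("LITERATURE", "GBIF", "COMBINED")

#' Assess all species of an occurrence set under one source mode
#'
#' Restricts the records to the chosen mode (LITERATURE-only, GBIF-only, or
#' the merged COMBINED set), filters to georeferenced records, computes the
#' EOO per species and classifies it. Every species in the set's universe
#' receives one assessment; species with no usable records in the mode are
#' Data Deficient.
#'
#' @param occ an `occ_set`.
#' @param mode one of `"LITERATURE"`, `"GBIF"`, `"COMBINED"`.
#' @param scheme a [threshold_scheme()].
#' @param rule three-point-rule mode passed to [eoo()].
#' @return data.frame: species, mode, n_records, eoo_km2, category.
#' @export
assess_all <- function(occ, mode = c("LITERATURE", "GBIF", "COMBINED"),
                       scheme = threshold_scheme(), rule = c("records", "distinct")) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  geo <- filter_georeferenced(occ)
  df <- as.data.frame(geo)
  if (mode != "COMBINED") df <- df[df$source == mode, , drop = FALSE]
  universe <- occ_species(occ)
  res <- lapply(universe, function(sp) {
    rec <- df[df$species == sp, , drop = FALSE]
    h <- eoo(rec, rule = rule)
    data.frame(species = sp, mode = mode, n_records = h$n_records,
               eoo_km2 = h$area_km2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res) %||% data.frame(species = character(0), mode = character(0),
                                             n_records = integer(0), eoo_km2 = numeric(0))
  if (nrow(out) == 0) {
    out$category <- factor(character(0), levels = category_levels())
    return(out)
  }
  out$category <- classify_eoo(out$eoo_km2, scheme)
  out
}

#' Compare per-species categories across the three source modes
#'
#' One row per species with the category under each mode and the shift
#' flags: `newly_assessable` (DD under literature, ranked under combined),
#' `changed_among_assessed` (ranked under both and different), `shifted`
#' (their union: literature and combined categories differ), and
#' `direction` (DOWNGRADE when the combined category is less threatened
#' than the literature one, UPGRADE for the converse, NONE otherwise —
#' movement toward less-threatened is a "downgrade" of the hypothetical
#' classification).
#'
#' @param literature,gbif,combined assessment data.frames from
#'   [assess_all()], covering the identical species set.
#' @return data.frame of comparison rows.
#' @export
compare_assessments <- function(literature, gbif, combined) {
  key <- function(a) sort(a$species)
  if (!identical(key(literature), key(gbif)) || !identical(key(literature), key(combined))) {
    offenders <- unique(c(setdiff(literature$species, combined$species),
                          setdiff(combined$species, literature$species),
                          setdiff(gbif$species, combined$species),
                          setdiff(combined$species, gbif$species)))
    stop_stage("source_comparison", "species sets differ across modes: %s",
               paste(offenders, collapse = ", "))
  }
  lit <- literature[order(literature$species), ]
  gb  <- gbif[order(gbif$species), ]
  cmb <- combined[order(combined$species), ]
  cat_lit <- as.character(lit$category)
  cat_cmb <- as.character(cmb$category)
  newly <- cat_lit == "DD" & cat_cmb != "DD"
  changed <- cat_lit != "DD" & cat_cmb != "DD" & cat_lit != cat_cmb
  r_lit <- threat_rank(cat_lit)
  r_cmb <- threat_rank(cat_cmb)
  direction <- ifelse(!changed, "NONE",
                      ifelse(r_cmb < r_lit, "DOWNGRADE", "UPGRADE"))
  data.frame(species = lit$species,
             cat_lit = factor(cat_lit, levels = category_levels()),
             cat_gbif = factor(as.character(gb$category), levels = category_levels()),
             cat_combined = factor(cat_cmb, levels = category_levels()),
             newly_assessable = newly,
             changed_among_assessed = changed,
             shifted = cat_lit != cat_cmb,
             direction = direction,
             stringsAsFactors = FALSE)
}

#' Build a category-by-source summary table
#'
#' Either from comparison rows ([summarize_comparison()]) or directly from a
#' 6 x 3 count matrix, as when re-deriving the percentages printed alongside
#' a published table. Percentages are reported with half-up rounding to one
#' decimal; unrounded values are kept in `$raw`.
#'
#' `percent_classifiable` per mode is `100 * (n_species - DD) / n_species`.
#' `percent_dd_reduction` is the share of species that are DD under
#' literature but not under combined data, computed from the table margins
#' (valid because adding records never makes a species DD).
#'
#' @param counts 6 x 3 matrix of category counts; rows in
#'   [category_levels()] order, columns Literature, GBIF, Combined.
#' @param species optional character vector of the species behind the
#'   counts (enables the overlap check in [pool_summaries()]).
#' @param shift_counts optional named list with n_shifted,
#'   n_newly_assessable, n_changed_among_assessed.
#' @return a `summary_table` object.
#' @export
summary_table <- function(counts, species = NULL, shift_counts = NULL) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(6, 3)))
    stop_stage("source_comparison", "counts must be a 6 x 3 matrix")
  rownames(counts) <- category_levels()
  colnames(counts) <- c("Literature", "GBIF", "Combined")
  cs <- colSums(counts)
  if (length(unique(cs)) != 1)
    stop_stage("source_comparison", "mode columns sum to different species totals: %s",
               paste(cs, collapse = ", "))
  n <- unname(cs[1])
  pc_raw <- if (n > 0) 100 * (n - counts["DD", ]) / n else stats::setNames(rep(0, 3), colnames(counts))
  ddred_raw <- if (n > 0) 100 * (counts["DD", "Literature"] - counts["DD", "Combined"]) / n else 0
  raw <- list(percent_classifiable = pc_raw, percent_dd_reduction = ddred_raw)
  pct <- list(percent_shifted = NA_real_, percent_newly_assessable = NA_real_,
              percent_changed_among_assessed = NA_real_)
  if (!is.null(shift_counts) && n > 0) {
    raw$percent_shifted <- 100 * shift_counts$n_shifted / n
    raw$percent_newly_assessable <- 100 * shift_counts$n_newly_assessable / n
    raw$percent_changed_among_assessed <- 100 * shift_counts$n_changed_among_assessed / n
    pct <- lapply(raw[names(pct)], round_half_up)
  }
  structure(list(counts = counts, n_species = n, species = species,
                 shift_counts = shift_counts,
                 percent_classifiable = round_half_up(pc_raw),
                 percent_dd_reduction = round_half_up(ddred_raw),
                 percent_shifted = pct$percent_shifted,
                 percent_newly_assessable = pct$percent_newly_assessable,
                 percent_changed_among_assessed = pct$percent_changed_among_assessed,
                 raw = raw),
            class = "summary_table")
}

#' Summarise comparison rows into the category-by-source table
#'
#' @param rows comparison rows from [compare_assessments()].
#' @return a `summary_table`.
#' @export
summarize_comparison <- function(rows) {
  counts <- cbind(Literature = table(factor(rows$cat_lit, levels = category_levels())),
                  GBIF = table(factor(rows$cat_gbif, levels = category_levels())),
                  Combined = table(factor(rows$cat_combined, levels = category_levels())))
  summary_table(counts, species = sort(rows$species),
                shift_counts = list(n_shifted = sum(rows$shifted),
                                    n_newly_assessable = sum(rows$newly_assessable),
                                    n_changed_among_assessed = sum(rows$changed_among_assessed)))
}

#' Pool two summary tables over disjoint species sets
#'
#' Counts add cell-wise; every percentage is recomputed over the pooled
#' species total. Pooling tables with overlapping species is an error (when
#' both tables carry their species lists).
#'
#' @param a,b `summary_table` objects.
#' @return a pooled `summary_table`.
#' @export
pool_summaries <- function(a, b) {
  if (!inherits(a, "summary_table") || !inherits(b, "summary_table"))
    stop_stage("source_comparison", "pool_summaries() needs summary_table inputs")
  if (!is.null(a$species) && !is.null(b$species)) {
    overlap <- intersect(a$species, b$species)
    if (length(overlap) > 0)
      stop_stage("source_comparison", "overlapping species across pooled tables: %s",
                 paste(overlap, collapse = ", "))
  }
  shifts <- NULL
  if (!is.null(a$shift_counts) && !is.null(b$shift_counts))
    shifts <- Map(`+`, a$shift_counts, b$shift_counts)
  species <- if (!is.null(a$species) && !is.null(b$species)) c(a$species, b$species) else NULL
  summary_table(a$counts + b$counts, species = species, shift_counts = shifts)
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("<summary_table> %d species\n", x$n_species))
  print(x$counts)
  cat("percent classifiable: ",
      paste(sprintf("%s %.1f", colnames(x$counts), x$percent_classifiable), collapse = ", "),
      "\n", sep = "")
  if (!is.na(x$percent_shifted))
    cat(sprintf("shifted %.1f%% = newly assessable %.1f%% + changed among assessed %.1f%%\n",
                x$percent_shifted, x$percent_newly_assessable,
                x$percent_changed_among_assessed))
  invisible(x)
}

#' @export
as.data.frame.summary_table <- function(x, ...) {
  data.frame(category = rownames(x$counts), x$counts, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}
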