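#' Plate-reader growth curve
#'
#' An ordered series of OD600 readings taken at a fixed interval, with a
#' free-form condition annotation. At least 10 readings are required because
#' baseline correction averages the first 10.
#'
#' @param od numeric vector of OD600 readings, in time order.
#' @param interval_min minutes between readings (default 15).
#' @param condition named list of labels (strain, carbon_source, compound,
#'   dose, pH, ...).
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(od, interval_min = 15, condition = list()) {
  if (!is.numeric(od) || length(od) < 10)
    stopf("a growth curve needs at least 10 numeric OD readings")
  interval_min <- assert_number(interval_min, "interval_min", min = 0,
                                strict = TRUE)
  structure(list(od = as.numeric(od), interval_min = interval_min,
                 condition = as.list(condition), baseline_corrected = FALSE),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("growth_curve: %d reads every %g min (%.1f h)%s\n",
              length(x$od), x$interval_min,
              length(x$od) * x$interval_min / 60,
              if (x$baseline_corrected) ", baseline-corrected" else ""))
  if (length(x$condition))
    cat("  condition:", paste(names(x$condition), unlist(x$condition),
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Zero the baseline of a growth curve
#'
#' The mean of the first 10 OD readings (before cells reach detectable
#' density) is subtracted from every reading, setting the curve's baseline
#' to zero. Negative corrected readings (noise below baseline) are kept.
#'
#' @param curve a [growth_curve()].
#' @return the corrected curve; the mean of its first 10 readings is 0.
#' @export
baseline_correct <- function(curve) {
  stopifnot(inherits(curve, "growth_curve"))
  if (length(curve$od) < 10)
    stopf("baseline correction needs at least 10 readings")
  curve$od <- curve$od - mean(curve$od[1:10])
  curve$baseline_corrected <- TRUE
  curve
}

# default read counts by carbon-source class: fermentable media reach
# saturation by ~12.5 h (50 reads), respiratory media by ~25 h (100 reads)
fermentable_carbons <- c("YPD", "YPGal", "dextrose", "galactose", "glucose")

default_reads <- function(carbon_source) {
  if (is.null(carbon_source)) return(100L)
  if (carbon_source %in% fermentable_carbons) 50L else 100L
}

#' Area under a growth curve
#'
#' Growth is summarized as the sum of the first `n_reads` baseline-corrected
#' OD readings (units: OD·reads). The default read count is keyed to the
#' curve's carbon source: 50 reads (12.5 h) for fermentable media, 100 reads
#' (25 h) for respiratory media; slower experiments (e.g. severely
#' copper-starved strains followed for 40 h) can opt into 160 reads.
#'
#' @param curve a baseline-corrected [growth_curve()].
#' @param n_reads how many readings to sum; defaults by carbon source as
#'   described above.
#' @return scalar AUC in OD·reads.
#' @export
auc <- function(curve, n_reads = NULL) {
  stopifnot(inherits(curve, "growth_curve"))
  if (!curve$baseline_corrected)
    stopf("curve must be baseline-corrected first (see baseline_correct())")
  if (is.null(n_reads)) n_reads <- default_reads(curve$condition$carbon_source)
  n_reads <- assert_count(n_reads, "n_reads")
  if (n_reads > length(curve$od))
    stopf("n_reads (%d) exceeds the %d available readings",
          n_reads, length(curve$od))
  sum(curve$od[seq_len(n_reads)])
}

#' Growth relative to a reference condition
#'
#' `(AUC_condition - AUC_control) / AUC_control`: 0 means growth identical
#' to the reference, positive values a growth boost, negative values
#' impaired growth.
#'
#' @param auc_condition AUC of the condition of interest (vectorized).
#' @param auc_control AUC of the on-plate reference condition (> 0).
#' @return signed relative growth.
#' @export
relative_growth <- function(auc_condition, auc_control) {
  if (any(!is.finite(auc_control)) || any(auc_control <= 0))
    stopf("'auc_control' must be positive: the reference did not grow")
  (auc_condition - auc_control) / auc_control
}

#' A plate of growth curves with a condition map
#'
#' @param curves list of [growth_curve()] objects, named by well.
#' @param map data.frame with columns `well`, `row_dose`, `col_dose`,
#'   `replicate` assigning each curve to a cell of a two-way dose grid.
#' @return object of class `plate_set`.
#' @export
plate_set <- function(curves, map) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("well", "row_dose", "col_dose", "replicate")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stopf("plate map is missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(vapply(curves, inherits, logical(1), "growth_curve")))
    stopf("'curves' must be a list of growth_curve objects")
  if (is.null(names(curves))) names(curves) <- map$well[seq_along(curves)]
  missing_wells <- setdiff(map$well, names(curves))
  if (length(missing_wells))
    stopf("no curve supplied for well(s): %s",
          paste(missing_wells, collapse = ", "))
  structure(list(curves = curves, map = map), class = "plate_set")
}

#' Assemble a dose-response matrix of relative growth
#'
#' For a plate laid out as a two-way dose grid (e.g. CuSO4 concentration by
#' chelator concentration), every curve is baseline-corrected and summed to
#' an AUC, relative growth is computed against the reference cell of the
#' same replicate, and replicate values are averaged per cell. The reference
#' cell is exactly 0 by construction.
#'
#' @param plate a [plate_set()].
#' @param reference length-2 vector `c(row_dose, col_dose)` naming the
#'   reference cell; it must appear exactly once in every replicate group.
#' @param n_reads readings to sum per curve (default: by carbon source).
#' @return object of class `dose_response_matrix`: a numeric matrix (rows =
#'   row doses, columns = col doses) with attributes `reference` and
#'   `n_replicates`.
#' @export
dose_response_matrix <- function(plate, reference, n_reads = NULL) {
  stopifnot(inherits(plate, "plate_set"))
  if (length(reference) != 2)
    stopf("'reference' must be c(row_dose, col_dose)")
  map <- plate$map
  map$row_dose <- as.character(map$row_dose)
  map$col_dose <- as.character(map$col_dose)
  ref_row <- as.character(reference[1])
  ref_col <- as.character(reference[2])

  map$auc <- vapply(map$well, function(w)
    auc(baseline_correct(plate$curves[[w]]), n_reads = n_reads), numeric(1))

  map$rel <- NA_real_
  for (rep_i in unique(map$replicate)) {
    in_rep <- map$replicate == rep_i
    is_ref <- in_rep & map$row_dose == ref_row & map$col_dose == ref_col
    if (sum(is_ref) == 0)
      stopf("reference cell (%s, %s) missing from replicate %s",
            ref_row, ref_col, rep_i)
    if (sum(is_ref) > 1)
      stopf("reference cell appears %d times in replicate %s",
            sum(is_ref), rep_i)
    map$rel[in_rep] <- relative_growth(map$auc[in_rep], map$auc[is_ref])
  }

  cell <- paste(map$row_dose, map$col_dose, sep = "\r")
  counts <- table(cell)
  if (length(unique(counts)) > 1)
    warnf("ragged replicate counts per cell (%s); using available curves",
          paste(range(counts), collapse = "-"))

  rows <- unique(map$row_dose)
  cols <- unique(map$col_dose)
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  agg <- tapply(map$rel, cell, mean)
  for (nm in names(agg)) {
    parts <- strsplit(nm, "\r", fixed = TRUE)[[1]]
    m[parts[1], parts[2]] <- agg[[nm]]
  }
  structure(m, class = c("dose_response_matrix", "matrix"),
            reference = c(row_dose = ref_row, col_dose = ref_col),
            n_replicates = length(unique(map$replicate)))
}
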