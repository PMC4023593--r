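#' The four respiratory pool assays
#'
#' The screen scores copper response in four assays: the full
#' homozygous-deletion (HD) pool grown on ethanol, glycerol or lactate
#' (YPE, YPG, YPL), and the respiration-deficient (RD) sub-pool grown on
#' ethanol (labelled `YPE*`). Fermentative growth (YPD) is part of the
#' experiment but is not a scored assay.
#'
#' @return data.frame with columns `assay`, `pool`, `carbon_source`.
#' @export
screen_assays <- function() {
  data.frame(assay = c("YPE", "YPG", "YPL", "YPE*"),
             pool = c("HD", "HD", "HD", "RD"),
             carbon_source = c("YPE", "YPG", "YPL", "YPE"),
             stringsAsFactors = FALSE)
}

#' Screen decision thresholds
#'
#' @param crs_threshold minimum |CRS| (log2 units) for a large response
#'   (default 1.5).
#' @param q_threshold significance level on BH q-values (default 0.05).
#' @param rd_low respiration-deficient pool filter: median log2 raw
#'   fluorescence on non-fermentable media must fall below this (default 7).
#' @param rd_high the same strain's median log2 raw fluorescence on YPD must
#'   exceed this (default 8), i.e. the strain is present in the pool but
#'   washes out under respiration.
#' @param allow_inverted permit `rd_low >= rd_high` (normally rejected).
#' @return object of class `screen_thresholds`.
#' @export
screen_thresholds <- function(crs_threshold = 1.5, q_threshold = 0.05,
                              rd_low = 7, rd_high = 8,
                              allow_inverted = FALSE) {
  crs_threshold <- assert_number(crs_threshold, "crs_threshold", min = 0,
                                 strict = TRUE)
  q_threshold <- assert_number(q_threshold, "q_threshold", min = 0,
                               strict = TRUE)
  if (q_threshold >= 1) stopf("'q_threshold' must be < 1")
  rd_low <- assert_number(rd_low, "rd_low")
  rd_high <- assert_number(rd_high, "rd_high")
  if (rd_low >= rd_high && !allow_inverted)
    stopf("'rd_low' must be below 'rd_high' (set allow_inverted = TRUE to override)")
  structure(list(crs_threshold = crs_threshold, q_threshold = q_threshold,
                 rd_low = rd_low, rd_high = rd_high),
            class = "screen_thresholds")
}

#' Copper Response Scores for one assay
#'
#' For every tag, the CRS input is the difference of mean normalized log2
#' intensity, copper-treated minus untreated. For a two-tag strain the CRS
#' is the difference of the tag with the greater absolute difference (the
#' two barcodes hybridize with different efficiencies, so the stronger tag
#' is the more reliable abundance proxy); for single-tag strains it is the
#' only tag's difference. Exact ties select the uptag.
#'
#' @param means a [replicate_means()] table.
#' @param map strain barcode map.
#' @param assay one row of [screen_assays()].
#' @param treated treatment label of the treated arm (default `"Cu"`).
#' @return data.frame per strain of the assay's pool: `strain`, `assay`,
#'   `delta_uptag`, `delta_downtag`, `crs`, `selected_tag`
#'   (`"uptag"`/`"downtag"`), `selected_tag_id`. Strains with no tag in the
#'   table keep `NA` scores and are excluded from downstream q-value
#'   universes.
#' @export
copper_response_score <- function(means, map, assay, treated = "Cu") {
  stopifnot(inherits(means, "condition_means"))
  map <- validate_strain_map(map)
  conds <- means$conditions
  t_col <- conds$condition[conds$pool == assay$pool &
                             conds$carbon_source == assay$carbon_source &
                             conds$treatment == treated]
  u_col <- conds$condition[conds$pool == assay$pool &
                             conds$carbon_source == assay$carbon_source &
                             conds$treatment != treated]
  if (length(t_col) != 1 || length(u_col) != 1)
    stopf("assay %s/%s needs exactly one treated and one untreated condition",
          assay$pool, assay$carbon_source)
  delta <- means$values[, t_col] - means$values[, u_col]

  pool_map <- map[map$pool == assay$pool, , drop = FALSE]
  du <- unname(delta[match(pool_map$uptag, rownames(means$values))])
  dd <- unname(delta[match(pool_map$downtag, rownames(means$values))])

  # tag with maximum |delta|; ties (including single-tag strains) -> uptag
  use_down <- !is.na(dd) & (is.na(du) | abs(dd) > abs(du))
  crs <- ifelse(use_down, dd, du)
  selected <- ifelse(is.na(crs), NA_character_,
                     ifelse(use_down, "downtag", "uptag"))
  selected_id <- ifelse(is.na(selected), NA_character_,
                        ifelse(use_down, pool_map$downtag, pool_map$uptag))
  if (anyNA(crs))
    warnf("%d strain(s) have no tag in the table and were recorded as missing",
          sum(is.na(crs)))
  data.frame(strain = pool_map$strain, assay = assay$assay,
             delta_uptag = unname(du), delta_downtag = unname(dd),
             crs = unname(crs), selected_tag = selected,
             selected_tag_id = selected_id,
             stringsAsFactors = FALSE)
}

#' Classify strains by CRS and q-value thresholds
#'
#' A strain's response in one assay is `increased` when `CRS >
#' crs_threshold` and `q < q_threshold`, `decreased` when `CRS <
#' -crs_threshold` and `q < q_threshold`, otherwise `neutral`. The overall
#' per-strain call is `increased`/`decreased` if any assay meets the
#' criterion, `conflicting` if different assays meet both, else `neutral`.
#'
#' @param results strain result table (rows = strain x assay) with `crs`
#'   and `q` columns, e.g. from [strain_level_inference()].
#' @param thresholds a [screen_thresholds()].
#' @return `results` with a per-row `class` column and a per-strain
#'   `overall_class` column.
#' @export
classify_strains <- function(results, thresholds = screen_thresholds()) {
  stopifnot(inherits(thresholds, "screen_thresholds"))
  if (!all(c("crs", "q") %in% names(results)))
    stopf("'results' must contain 'crs' and 'q' columns")
  cls <- rep("neutral", nrow(results))
  sig <- !is.na(results$q) & results$q < thresholds$q_threshold &
    !is.na(results$crs)
  cls[sig & results$crs > thresholds$crs_threshold] <- "increased"
  cls[sig & results$crs < -thresholds$crs_threshold] <- "decreased"
  cls[is.na(results$crs)] <- NA_character_
  results$class <- cls

  per_strain <- split(cls, results$strain)
  overall <- vapply(per_strain, function(v) {
    v <- v[!is.na(v)]
    inc <- any(v == "increased")
    dec <- any(v == "decreased")
    if (inc && dec) "conflicting"
    else if (inc) "increased"
    else if (dec) "decreased"
    else "neutral"
  }, character(1))
  results$overall_class <- overall[results$strain]
  results
}

#' Identify respiration-deficient strains
#'
#' Flags strains that are well represented in the fermentative (YPD)
#' samples but undetectable after competitive respiratory growth: per
#' strain, the median of log2 raw (un-normalized) fluorescence over all of
#' its tags and all untreated samples must be below `rd_low` in the
#' combined non-fermentable media (YPE, YPG, YPL) and above `rd_high` in
#' YPD. Only samples without added copper are used.
#'
#' @param raw a linear-scale (raw) [tag_table()] that includes untreated
#'   samples for YPD and the non-fermentable carbon sources.
#' @param thresholds a [screen_thresholds()].
#' @param nonferm_carbons the non-fermentable carbon sources (default YPE,
#'   YPG, YPL).
#' @param ferm_carbon the fermentative reference medium (default YPD).
#' @param untreated untreated label (default `"none"`).
#' @param floor linear floor before log2 (default 1).
#' @return character vector of respiration-deficient strain ids; the full
#'   per-strain median table is attached as attribute `"medians"`.
#' @export
respiration_deficient_filter <- function(raw,
                                         thresholds = screen_thresholds(),
                                         nonferm_carbons = c("YPE", "YPG", "YPL"),
                                         ferm_carbon = "YPD",
                                         untreated = "none", floor = 1) {
  stopifnot(inherits(raw, "tag_table"), inherits(thresholds, "screen_thresholds"))
  if (raw$scale != "linear")
    stopf("the RD filter uses raw (linear) fluorescence, not %s values",
          raw$scale)
  s <- raw$samples
  nf_cols <- which(s$treatment == untreated & s$carbon_source %in% nonferm_carbons)
  fm_cols <- which(s$treatment == untreated & s$carbon_source == ferm_carbon)
  present <- unique(s$carbon_source[c(nf_cols, fm_cols)])
  missing <- setdiff(c(nonferm_carbons, ferm_carbon), present)
  if (length(missing))
    stopf("no untreated samples for carbon source(s): %s",
          paste(missing, collapse = ", "))
  lg <- log2(pmax(raw$values, floor))
  rows_by_strain <- split(seq_len(nrow(lg)), raw$tags$strain)
  strains <- names(rows_by_strain)
  med_nf <- vapply(rows_by_strain, function(r)
    stats::median(lg[r, nf_cols]), numeric(1))
  med_fm <- vapply(rows_by_strain, function(r)
    stats::median(lg[r, fm_cols]), numeric(1))
  rd <- med_nf < thresholds$rd_low & med_fm > thresholds$rd_high
  medians <- data.frame(strain = strains, median_nonferm = unname(med_nf),
                        median_ferm = unname(med_fm), rd = unname(rd),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(unname(strains[rd]), medians = medians)
}
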