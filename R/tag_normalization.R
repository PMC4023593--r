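#' Log2-transform raw tag intensities
#'
#' Values are floored at `floor` before taking log2, so zero or near-zero
#' fluorescence maps to `log2(floor)` (0 with the default floor of 1) rather
#' than -Inf.
#'
#' @param x a linear-scale [tag_table()].
#' @param floor linear-intensity floor (> 0, default 1).
#' @return the table with `values = log2(pmax(values, floor))` and scale
#'   flag `"log2"`.
#' @export
log2_transform <- function(x, floor = 1) {
  stopifnot(inherits(x, "tag_table"))
  if (x$scale != "linear")
    stopf("table is already on the %s scale; refusing to log2-transform twice",
          x$scale)
  floor <- assert_number(floor, "floor", min = 0, strict = TRUE)
  x$values <- log2(pmax(x$values, floor))
  x$scale <- "log2"
  x
}

# Quantile-normalize the columns of one matrix to the cross-column mean of
# order statistics. Tied values within a column receive the mean of the
# reference values at the positions the tie occupies.
quantile_normalize_matrix <- function(m) {
  if (ncol(m) < 2) return(m)
  sorted <- apply(m, 2, sort)
  ref <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    o <- order(v)
    sv <- v[o]
    tie_group <- cumsum(c(TRUE, diff(sv) != 0))
    out[o, j] <- stats::ave(ref, tie_group)
  }
  out
}

#' Group-wise quantile normalization of log2 tag intensities
#'
#' Quantile normalization forces every sample's intensity distribution to a
#' common reference (the across-sample mean of the order statistics),
#' removing array-to-array intensity differences while preserving ranks.
#' Uptags and downtags hybridize with systematically different efficiencies
#' and the two pools contain different tag sets, so normalization is applied
#' independently within each (pool x tag group) block — e.g. the four groups
#' {HD uptags, HD downtags, RD uptags, RD downtags} — across all samples of
#' that pool (both treatments, all carbon sources, all replicates together).
#'
#' @param x a log2-scale [tag_table()].
#' @return the table with scale flag `"log2-normalized"`. A block with a
#'   single sample is returned unchanged with a warning.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "tag_table"))
  if (x$scale != "log2")
    stopf("quantile normalization expects log2-scale values (scale is '%s')",
          x$scale)
  for (pool in unique(x$tags$pool)) {
    cols <- which(x$samples$pool == pool)
    for (grp in unique(x$tags$tag_group[x$tags$pool == pool])) {
      rows <- which(x$tags$pool == pool & x$tags$tag_group == grp)
      if (length(cols) < 2) {
        warnf("pool %s has a single sample; %ss returned unnormalized",
              pool, grp)
        next
      }
      x$values[rows, cols] <-
        quantile_normalize_matrix(x$values[rows, cols, drop = FALSE])
    }
  }
  x$scale <- "log2-normalized"
  x
}

#' Per-condition replicate means
#'
#' Averages normalized log2 intensities over the replicate samples of each
#' condition, where a condition is a (pool, carbon source, treatment)
#' combination.
#'
#' @param x a normalized [tag_table()].
#' @return object of class `condition_means`: list with `values` (tag x
#'   condition matrix), `tags` (as in the input) and `conditions`
#'   (data.frame: condition, pool, carbon_source, treatment, n_replicates).
#' @export
replicate_means <- function(x) {
  stopifnot(inherits(x, "tag_table"))
  if (x$scale != "log2-normalized")
    stopf("replicate means expect quantile-normalized log2 values (scale is '%s')",
          x$scale)
  s <- x$samples
  cond_key <- paste(s$pool, s$carbon_source, s$treatment, sep = "_")
  conds <- unique(data.frame(condition = cond_key, pool = s$pool,
                             carbon_source = s$carbon_source,
                             treatment = s$treatment,
                             stringsAsFactors = FALSE))
  conds$n_replicates <- as.integer(table(cond_key)[conds$condition])
  if (any(conds$n_replicates < 1)) stopf("empty condition group")
  vals <- vapply(conds$condition, function(k)
    rowMeans(x$values[, cond_key == k, drop = FALSE]),
    numeric(nrow(x$values)))
  dimnames(vals) <- list(rownames(x$values), conds$condition)
  structure(list(values = vals, tags = x$tags, conditions = conds),
            class = "condition_means")
}

#' @export
print.condition_means <- function(x, ...) {
  cat(sprintf("condition_means: %d tags x %d conditions\n",
              nrow(x$values), ncol(x$values)))
  print(x$conditions, row.names = FALSE)
  invisible(x)
}
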