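#' Tag-by-sample intensity table
#'
#' The central container of the pipeline: a tags x samples matrix of barcode
#' fluorescence intensities together with per-tag annotation (owning strain,
#' tag group, pool) and the sample sheet. The `scale` flag tracks whether
#' values are raw linear fluorescence, log2, or log2 quantile-normalized;
#' downstream operations check it so that, for example, intensities cannot be
#' log2-transformed twice.
#'
#' @param values numeric matrix, rows = tags, columns = samples. Row names
#'   must be the tag ids, column names the sample ids.
#' @param tags data.frame with columns `tag_id`, `strain`, `tag_group`
#'   (`"uptag"` or `"downtag"`), `pool`. One row per row of `values`.
#' @param samples sample sheet: data.frame with columns `sample_id`, `pool`,
#'   `carbon_source`, `treatment`, `replicate`. One row per column of
#'   `values`; the (pool, carbon_source, treatment, replicate) combination
#'   must be unique.
#' @param scale one of `"linear"`, `"log2"`, `"log2-normalized"`.
#' @return an object of class `tag_table`: a list with elements `values`,
#'   `tags`, `samples`, `scale`.
#' @export
tag_table <- function(values, tags, samples,
                      scale = c("linear", "log2", "log2-normalized")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  tags <- as.data.frame(tags, stringsAsFactors = FALSE)
  samples <- validate_sample_sheet(samples)
  need <- c("tag_id", "strain", "tag_group", "pool")
  miss <- setdiff(need, names(tags))
  if (length(miss))
    stopf("'tags' is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(tags) != nrow(values))
    stopf("'tags' has %d rows but 'values' has %d", nrow(tags), nrow(values))
  if (nrow(samples) != ncol(values))
    stopf("'samples' has %d rows but 'values' has %d columns",
          nrow(samples), ncol(values))
  if (anyDuplicated(tags$tag_id))
    stopf("duplicated tag id(s): %s",
          paste(unique(tags$tag_id[duplicated(tags$tag_id)]), collapse = ", "))
  if (!all(tags$tag_group %in% c("uptag", "downtag")))
    stopf("'tag_group' must be 'uptag' or 'downtag'")
  if (is.null(rownames(values))) rownames(values) <- tags$tag_id
  if (!identical(rownames(values), as.character(tags$tag_id)))
    stopf("rownames(values) must equal tags$tag_id")
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  if (!identical(colnames(values), as.character(samples$sample_id)))
    stopf("colnames(values) must equal samples$sample_id")
  if (scale == "linear" && any(values < 0, na.rm = TRUE))
    stopf("linear intensities must be >= 0")
  structure(list(values = values, tags = tags, samples = samples,
                 scale = scale),
            class = "tag_table")
}

#' @export
print.tag_table <- function(x, ...) {
  cat(sprintf("tag_table: %d tags x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  pools: %s | strains: %d\n",
              paste(unique(x$tags$pool), collapse = ", "),
              length(unique(x$tags$strain))))
  cat(sprintf("  conditions: %s\n",
              paste(unique(paste0(x$samples$carbon_source,
                                  ifelse(x$samples$treatment == "none",
                                         "", "+Cu"))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.tag_table <- function(x) dim(x$values)

validate_sample_sheet <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "pool", "carbon_source", "treatment", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stopf("sample sheet is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stopf("duplicated sample id(s): %s",
          paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
                collapse = ", "))
  key <- samples[c("pool", "carbon_source", "treatment", "replicate")]
  if (anyDuplicated(key))
    stopf("(pool, carbon_source, treatment, replicate) must be unique")
  samples
}

#' Validate a strain barcode map
#'
#' A strain map associates each strain with its uptag and (optionally)
#' downtag barcode ids and a pool label. Most strains carry two tags; a
#' missing downtag is recorded as `NA`.
#'
#' @param map data.frame with columns `strain`, `uptag`, `downtag`, `pool`.
#' @return the validated map (invisibly the same data.frame).
#' @export
validate_strain_map <- function(map) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("strain", "uptag", "downtag", "pool")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stopf("strain map is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(map$strain))
    stopf("duplicated strain id(s) in map")
  if (anyNA(map$uptag)) stopf("every strain must have an uptag")
  ids <- c(map$uptag, map$downtag[!is.na(map$downtag)])
  if (anyDuplicated(ids)) stopf("tag ids must be unique across strains")
  map
}

# tags data.frame (long, one row per tag) from a strain map
tags_from_map <- function(map) {
  map <- validate_strain_map(map)
  up <- data.frame(tag_id = map$uptag, strain = map$strain,
                   tag_group = "uptag", pool = map$pool,
                   stringsAsFactors = FALSE)
  dn <- map[!is.na(map$downtag), , drop = FALSE]
  down <- data.frame(tag_id = dn$downtag, strain = dn$strain,
                     tag_group = "downtag", pool = dn$pool,
                     stringsAsFactors = FALSE)
  rbind(up, down)
}

write_tsv <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

read_tsv_comments <- function(path) {
  head <- readLines(path, n = 50)
  sub("^#\\s*", "", head[startsWith(head, "#")])
}

#' Read and write pipeline tables
#'
#' Plain UTF-8 TSV with a header row; `NA` marks missing values; lines
#' starting with `#` are comments (the intensity table records its scale
#' there as `scale=<flag>`).
#'
#' @param x object to write (`tag_table`, sample sheet, strain map or truth
#'   table as appropriate).
#' @param path file path.
#' @param comments extra comment lines to prepend.
#' @name screen_io
NULL

#' @rdname screen_io
#' @export
write_intensities <- function(x, path, comments = character()) {
  stopifnot(inherits(x, "tag_table"))
  df <- data.frame(tag_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, c(paste0("scale=", x$scale), comments))
  invisible(path)
}

#' @rdname screen_io
#' @param samplesheet_path,strainmap_path companion tables used to rebuild
#'   the per-tag and per-sample annotation when reading intensities.
#' @export
read_intensities <- function(path, samplesheet_path, strainmap_path) {
  df <- read_tsv(path)
  sheet <- validate_sample_sheet(read_tsv(samplesheet_path))
  map <- validate_strain_map(read_tsv(strainmap_path))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$tag_id
  tags <- tags_from_map(map)
  tags <- tags[match(rownames(m), tags$tag_id), , drop = FALSE]
  if (anyNA(tags$tag_id))
    stopf("intensity tag id(s) absent from strain map: %s",
          paste(utils::head(setdiff(rownames(m), tags$tag_id)), collapse = ", "))
  sheet <- sheet[match(colnames(m), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id))
    stopf("intensity sample id(s) absent from sample sheet")
  comments <- read_tsv_comments(path)
  scale <- sub("^scale=", "", grep("^scale=", comments, value = TRUE)[1])
  if (is.na(scale)) scale <- "linear"
  tag_table(m, tags, sheet, scale = scale)
}

#' @rdname screen_io
#' @export
write_sample_sheet <- function(x, path) {
  write_tsv(validate_sample_sheet(x), path)
  invisible(path)
}

#' @rdname screen_io
#' @export
write_strain_map <- function(x, path) {
  write_tsv(validate_strain_map(x), path)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_strain_map <- function(path) validate_strain_map(read_tsv(path))

#' @rdname screen_io
#' @export
read_sample_sheet <- function(path) validate_sample_sheet(read_tsv(path))
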