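#' Configuration of a full screen run
#'
#' Collects input paths, thresholds and stage options for [run_screen()].
#' The configuration round-trips losslessly through [saveRDS()]/TSV and its
#' hash is stamped into every output table for provenance.
#'
#' @param intensities,samplesheet,strainmap paths to the input TSVs.
#' @param out_dir output directory (created if needed).
#' @param thresholds a [screen_thresholds()].
#' @param floor linear floor before log2 (default 1).
#' @param treated treated arm label (default `"Cu"`).
#' @param distance,linkage clustering options (see
#'   [hierarchical_cluster()]).
#' @param gene2terms,ontology optional annotation inputs for enrichment
#'   (paths to TSVs: gene/term and child/parent).
#' @param alpha enrichment significance level.
#' @param seed integer seed recorded in the run log (the analysis itself is
#'   deterministic; the seed matters when the config drives simulation).
#' @return object of class `run_config`.
#' @export
run_config <- function(intensities, samplesheet, strainmap, out_dir,
                       thresholds = screen_thresholds(), floor = 1,
                       treated = "Cu", distance = "pearson",
                       linkage = "average", gene2terms = NULL,
                       ontology = NULL, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(thresholds, "screen_thresholds"))
  cfg <- structure(list(intensities = intensities, samplesheet = samplesheet,
                        strainmap = strainmap, out_dir = out_dir,
                        thresholds = thresholds, floor = floor,
                        treated = treated, distance = distance,
                        linkage = linkage, gene2terms = gene2terms,
                        ontology = ontology, alpha = alpha,
                        seed = as.integer(seed)),
                   class = "run_config")
  for (p in c(cfg$intensities, cfg$samplesheet, cfg$strainmap,
              cfg$gene2terms, cfg$ontology))
    if (!file.exists(p)) stopf("input path does not exist: %s", p)
  cfg
}

#' Validate screen input files
#'
#' Cross-checks the three input tables without running the pipeline:
#' duplicated ids, strain-map tags absent from the intensity table,
#' intensity columns absent from the sample sheet (and vice versa), and an
#' unexpected scale flag.
#'
#' @param intensities,samplesheet,strainmap paths to the input TSVs.
#' @return data.frame report with columns `type` and `message`; zero rows
#'   when the inputs are consistent.
#' @export
validate_inputs <- function(intensities, samplesheet, strainmap) {
  problems <- list()
  note <- function(type, fmt, ...)
    problems[[length(problems) + 1L]] <<- data.frame(
      type = type, message = sprintf(fmt, ...), stringsAsFactors = FALSE)

  sheet <- read_tsv(samplesheet)
  map <- read_tsv(strainmap)
  idf <- read_tsv(intensities)

  if (anyDuplicated(sheet$sample_id))
    note("duplicate", "duplicated sample id(s): %s",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "))
  if (anyDuplicated(map$strain))
    note("duplicate", "duplicated strain id(s): %s",
         paste(unique(map$strain[duplicated(map$strain)]), collapse = ", "))
  tag_ids <- c(map$uptag, map$downtag[!is.na(map$downtag)])
  if (anyDuplicated(tag_ids))
    note("duplicate", "duplicated tag id(s) in strain map")

  present_tags <- idf$tag_id
  missing_tags <- setdiff(tag_ids, present_tags)
  if (length(missing_tags))
    note("cross-reference", "strain map references %d tag(s) absent from the intensity table (e.g. %s)",
         length(missing_tags), missing_tags[1])
  orphan_tags <- setdiff(present_tags, tag_ids)
  if (length(orphan_tags))
    note("cross-reference", "%d intensity tag(s) not in the strain map (e.g. %s)",
         length(orphan_tags), orphan_tags[1])

  sample_cols <- setdiff(colnames(idf), "tag_id")
  missing_samples <- setdiff(sample_cols, sheet$sample_id)
  if (length(missing_samples))
    note("cross-reference", "intensity column(s) absent from sample sheet: %s",
         paste(missing_samples, collapse = ", "))
  unused_samples <- setdiff(sheet$sample_id, sample_cols)
  if (length(unused_samples))
    note("cross-reference", "sample sheet row(s) with no intensity column: %s",
         paste(unused_samples, collapse = ", "))

  comments <- read_tsv_comments(intensities)
  scale <- sub("^scale=", "", grep("^scale=", comments, value = TRUE)[1])
  if (!is.na(scale) && !scale %in% c("linear", "log2", "log2-normalized"))
    note("scale", "unknown scale flag '%s'", scale)

  if (!length(problems))
    return(data.frame(type = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, problems)
}

#' Run the screen analysis on in-memory objects
#'
#' Executes the full analysis chain: log2 transform, group-wise quantile
#' normalization, replicate condition means, per-assay Copper Response
#' Scores, moderated t-tests with strain-level BH q-values, threshold
#' classification, the respiration-deficient filter (when YPD untreated
#' samples are available), per-replicate fold changes with two-way
#' hierarchical clustering of the hit set, and (when annotations are given)
#' hypergeometric enrichment of the increased and decreased gene lists.
#'
#' @param raw linear-scale [tag_table()].
#' @param map strain barcode map.
#' @param thresholds a [screen_thresholds()].
#' @param assays data.frame like [screen_assays()]; defaults to the subset
#'   of the standard four assays present in the data.
#' @param annotations optional [propagate_annotations()] result for
#'   enrichment of the hit lists.
#' @param floor,treated,distance,linkage,alpha see [run_config()].
#' @return list of class `screen_result`: `results` (strain x assay table
#'   with CRS, t, p, q, class), `tag_tests`, `priors`, `rd_strains`,
#'   `fold_change`, `clustering` (strains and experiments trees),
#'   `enrichment` (list per hit class), `normalized` (the normalized
#'   tag_table).
#' @export
analyze_screen <- function(raw, map, thresholds = screen_thresholds(),
                           assays = NULL, annotations = NULL, floor = 1,
                           treated = "Cu", distance = "pearson",
                           linkage = "average", alpha = 0.05) {
  stopifnot(inherits(raw, "tag_table"))
  map <- validate_strain_map(map)

  s <- raw$samples
  if (is.null(assays)) {
    std <- screen_assays()
    keep <- vapply(seq_len(nrow(std)), function(i) {
      any(s$pool == std$pool[i] & s$carbon_source == std$carbon_source[i] &
            s$treatment == treated) &&
        any(s$pool == std$pool[i] & s$carbon_source == std$carbon_source[i] &
              s$treatment != treated)
    }, logical(1))
    assays <- std[keep, , drop = FALSE]
  }
  if (!nrow(assays)) stopf("no scorable assay found in the sample sheet")

  norm <- quantile_normalize(log2_transform(raw, floor = floor))
  means <- replicate_means(norm)

  results <- list()
  tag_tests <- list()
  priors <- list()
  for (i in seq_len(nrow(assays))) {
    assay <- assays[i, ]
    crs <- copper_response_score(means, map, assay, treated = treated)
    tt <- assay_tag_tests(norm, assay, treated = treated)
    results[[assay$assay]] <- strain_level_inference(tt, crs)
    tt$assay <- assay$assay
    tag_tests[[assay$assay]] <- tt
    priors[[assay$assay]] <- attr(tt, "prior")
  }
  results <- do.call(rbind, c(results, make.row.names = FALSE))
  tag_tests <- do.call(rbind, c(tag_tests, make.row.names = FALSE))
  results <- classify_strains(results, thresholds)

  rd_strains <- NULL
  has_ypd <- any(s$carbon_source == "YPD" & s$treatment != treated &
                   s$pool == "HD")
  nonferm <- intersect(c("YPE", "YPG", "YPL"),
                       s$carbon_source[s$pool == "HD" & s$treatment != treated])
  if (has_ypd && length(nonferm)) {
    hd_cols <- which(s$pool == "HD")
    hd_rows <- which(raw$tags$pool == "HD")
    hd_raw <- tag_table(raw$values[hd_rows, hd_cols, drop = FALSE],
                        raw$tags[hd_rows, ], s[hd_cols, ], scale = "linear")
    rd_strains <- respiration_deficient_filter(hd_raw, thresholds,
                                               nonferm_carbons = nonferm)
  }

  hits <- unique(results$strain[results$overall_class %in%
                                  c("increased", "decreased", "conflicting")])
  fold_change <- NULL
  clustering <- NULL
  if (length(hits) >= 2 && any(s$pool == "HD")) {
    fold_change <- cu_fold_change(norm, hits, pool = "HD", treated = treated)
    clustering <- list(
      strains = hierarchical_cluster(fold_change, "strains",
                                     distance = distance, linkage = linkage),
      experiments = if (ncol(fold_change) >= 2)
        hierarchical_cluster(fold_change, "experiments",
                             distance = distance, linkage = linkage))
  }

  enrichment <- NULL
  if (!is.null(annotations)) {
    enrichment <- list()
    for (cls in c("increased", "decreased")) {
      genes <- unique(results$strain[results$overall_class == cls])
      genes <- intersect(genes, annotations$universe)
      if (length(genes))
        enrichment[[cls]] <- hypergeometric_enrichment(genes, annotations,
                                                       alpha = alpha)
    }
  }

  structure(list(results = results, tag_tests = tag_tests, priors = priors,
                 rd_strains = rd_strains, fold_change = fold_change,
                 clustering = clustering, enrichment = enrichment,
                 normalized = norm, assays = assays,
                 thresholds = thresholds),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  tab <- table(unique(x$results[c("strain", "overall_class")])$overall_class)
  cat(sprintf("screen_result: %d strains x %d assays\n",
              length(unique(x$results$strain)), nrow(x$assays)))
  cat("  overall classes:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$rd_strains))
    cat(sprintf("  respiration-deficient strains: %d\n", length(x$rd_strains)))
  invisible(x)
}

#' Run the full screen pipeline from files
#'
#' Reads the input tables named in the configuration, validates them, runs
#' [analyze_screen()] and writes the result bundle to `out_dir`:
#' `results.tsv`, `tag_tests.tsv`, `rd_strains.txt`, `foldchange.tsv`,
#' `cluster_strains.newick`, `cluster_experiments.newick`,
#' `enrichment_<class>.tsv` and `run_log.txt`. Every table carries the
#' configuration hash in a header comment; outputs contain no timestamps,
#' so identical config + inputs give byte-identical files. Partial outputs
#' are removed if any stage fails.
#'
#' @param config a [run_config()].
#' @return the [analyze_screen()] result, invisibly.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- validate_inputs(config$intensities, config$samplesheet,
                            config$strainmap)
  if (nrow(report))
    stopf("input validation failed:\n%s",
          paste(sprintf("  [%s] %s", report$type, report$message),
                collapse = "\n"))

  raw <- read_intensities(config$intensities, config$samplesheet,
                          config$strainmap)
  map <- read_strain_map(config$strainmap)
  annotations <- NULL
  if (!is.null(config$gene2terms)) {
    g2t <- read_tsv(config$gene2terms)
    onto <- if (!is.null(config$ontology)) read_tsv(config$ontology)
    annotations <- propagate_annotations(g2t, onto, universe = map$strain)
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  # provenance hash covers the analysis parameters, not file locations
  hash <- config_hash(config[setdiff(names(config),
                                     c("intensities", "samplesheet",
                                       "strainmap", "out_dir"))])
  out <- function(name) {
    path <- file.path(config$out_dir, name)
    written <<- c(written, path)
    path
  }
  stamp <- paste0("config_hash=", hash)

  res <- tryCatch({
    res <- analyze_screen(raw, map, thresholds = config$thresholds,
                          annotations = annotations, floor = config$floor,
                          treated = config$treated,
                          distance = config$distance,
                          linkage = config$linkage, alpha = config$alpha)

    write_tsv(res$results, out("results.tsv"), stamp)
    write_tsv(res$tag_tests, out("tag_tests.tsv"), stamp)
    if (!is.null(res$rd_strains))
      writeLines(c(paste0("# ", stamp), res$rd_strains), out("rd_strains.txt"))
    if (!is.null(res$fold_change)) {
      fc <- data.frame(strain = rownames(res$fold_change), res$fold_change,
                       check.names = FALSE, stringsAsFactors = FALSE)
      write_tsv(fc, out("foldchange.tsv"), stamp)
      writeLines(res$clustering$strains$newick, out("cluster_strains.newick"))
      if (!is.null(res$clustering$experiments))
        writeLines(res$clustering$experiments$newick,
                   out("cluster_experiments.newick"))
    }
    if (!is.null(res$enrichment))
      for (cls in names(res$enrichment))
        write_tsv(res$enrichment[[cls]],
                  out(sprintf("enrichment_%s.tsv", cls)), stamp)

    log_lines <- c(
      sprintf("cuscreen version: %s",
              as.character(utils::packageVersion("cuscreen"))),
      sprintf("config hash: %s", hash),
      sprintf("seed: %d", config$seed),
      sprintf("thresholds: crs=%g q=%g rd_low=%g rd_high=%g",
              config$thresholds$crs_threshold, config$thresholds$q_threshold,
              config$thresholds$rd_low, config$thresholds$rd_high),
      sprintf("floor: %g", config$floor),
      sprintf("assays: %s", paste(res$assays$assay, collapse = ", ")),
      sprintf("strains: %d", length(unique(res$results$strain))))
    writeLines(log_lines, out("run_log.txt"))
    res
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  invisible(res)
}
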