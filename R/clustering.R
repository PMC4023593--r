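#' Per-replicate copper-induced fold changes
#'
#' For each treated replicate sample, the fold change of a tag is
#' `log2(I_treated_rep / mean(I_untreated))` computed on linear-scale
#' normalized intensities (the normalized log2 values back-transformed);
#' uptag and downtag fold changes of a strain are averaged. Rows are
#' restricted to a supplied hit list (e.g. the strains called
#' increased/decreased by the screen); a strain x experiment cell with no
#' tag data is imputed as 0 (no change) and counted.
#'
#' @param x a normalized [tag_table()].
#' @param strains character vector of strains to include (the hit set).
#' @param pool pool whose replicate experiments are used (default `"HD"`).
#' @param treated treated label (default `"Cu"`).
#' @return numeric matrix, rows = strains, columns = experiments labelled
#'   `<carbon>_rep<k>`; attribute `"n_imputed"` counts imputed cells.
#' @export
cu_fold_change <- function(x, strains, pool = "HD", treated = "Cu") {
  stopifnot(inherits(x, "tag_table"))
  if (x$scale != "log2-normalized")
    stopf("fold changes expect quantile-normalized log2 values")
  strains <- unique(as.character(strains))
  s <- x$samples
  linear <- 2^x$values
  carbons <- unique(s$carbon_source[s$pool == pool])
  cols <- list()
  for (cs in carbons) {
    t_cols <- which(s$pool == pool & s$carbon_source == cs &
                      s$treatment == treated)
    u_cols <- which(s$pool == pool & s$carbon_source == cs &
                      s$treatment != treated)
    if (!length(t_cols) || !length(u_cols))
      stopf("carbon source %s lacks treated and/or untreated replicates", cs)
    mean_u <- rowMeans(linear[, u_cols, drop = FALSE])
    if (any(mean_u <= 0)) stopf("untreated mean intensity <= 0")
    for (k in seq_along(t_cols)) {
      fc_tag <- log2(linear[, t_cols[k]] / mean_u)
      cols[[sprintf("%s_rep%d", cs, s$replicate[t_cols[k]])]] <- fc_tag
    }
  }
  fc_tags <- do.call(cbind, cols)

  m <- matrix(0, nrow = length(strains), ncol = ncol(fc_tags),
              dimnames = list(strains, colnames(fc_tags)))
  n_imputed <- 0L
  rows_by_strain <- split(seq_len(nrow(fc_tags)), x$tags$strain)
  for (i in seq_along(strains)) {
    rows <- rows_by_strain[[strains[i]]]
    if (is.null(rows)) {
      n_imputed <- n_imputed + ncol(m)
      next
    }
    m[i, ] <- colMeans(fc_tags[rows, , drop = FALSE])
  }
  structure(m, n_imputed = n_imputed)
}

#' Agglomerative hierarchical clustering of a fold-change matrix
#'
#' Clusters strains (rows) or experiments (columns) by average-linkage
#' agglomeration on 1 - Pearson correlation distance (the common choice for
#' log-ratio heatmaps), both configurable. A zero-variance item, for which
#' correlation is undefined, is placed at distance 1 from everything with a
#' warning.
#'
#' @param m numeric matrix (e.g. from [cu_fold_change()]).
#' @param axis `"strains"` to cluster rows, `"experiments"` for columns.
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return list of class `screen_clustering`: `hclust` (the tree), `order`,
#'   `labels`, `merge`, `height`, and `newick` (the tree serialized as a
#'   Newick string via \pkg{ape}).
#' @export
hierarchical_cluster <- function(m, axis = c("strains", "experiments"),
                                 distance = c("pearson", "euclidean"),
                                 linkage = "average") {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  if (axis == "experiments") m <- t(m)
  if (nrow(m) < 2) stopf("need at least 2 items to cluster")
  if (anyNA(m)) stopf("fold-change matrix contains missing values")
  if (distance == "pearson") {
    sds <- apply(m, 1, stats::sd)
    cc <- suppressWarnings(stats::cor(t(m)))
    if (any(sds == 0)) {
      warnf("%d zero-variance item(s): correlation undefined, distance set to 1",
            sum(sds == 0))
      cc[sds == 0, ] <- 0
      cc[, sds == 0] <- 0
    }
    D <- 1 - cc
    diag(D) <- 0
    d <- stats::as.dist(D)
  } else {
    d <- stats::dist(m)
  }
  hc <- stats::hclust(d, method = linkage)
  # zero-height branches confuse newick readers; nudge by nothing, ape copes
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, order = hc$order, labels = hc$labels,
                 merge = hc$merge, height = hc$height,
                 newick = ape::write.tree(phy)),
            class = "screen_clustering")
}

#' @export
print.screen_clustering <- function(x, ...) {
  cat(sprintf("screen_clustering: %d leaves, %s\n", length(x$labels),
              x$hclust$method))
  cat("  order:", paste(x$labels[x$order], collapse = " "), "\n")
  invisible(x)
}
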