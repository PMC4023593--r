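#' Empirical-Bayes variance prior
#'
#' The moderated t-statistic assumes the per-tag true variances follow a
#' scaled inverse chi-square prior with `d0` degrees of freedom and scale
#' `s0_sq`; observed residual variances are shrunk toward `s0_sq` with
#' weight `d0`. `d0 = Inf` corresponds to a common variance for all tags.
#'
#' @param d0 prior degrees of freedom (> 0, possibly `Inf`).
#' @param s0_sq prior variance (log2 units squared, > 0).
#' @return object of class `variance_prior`.
#' @export
variance_prior <- function(d0, s0_sq) {
  if (!(is.numeric(d0) && length(d0) == 1 && (is.infinite(d0) || d0 > 0)))
    stopf("'d0' must be a positive number or Inf")
  s0_sq <- assert_number(s0_sq, "s0_sq", min = 0, strict = TRUE)
  structure(list(d0 = d0, s0_sq = s0_sq), class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("variance_prior: d0 = %s, s0_sq = %.6g\n",
              format(x$d0), x$s0_sq))
  invisible(x)
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)), to absolute tolerance 1e-10 on the trigamma scale.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Fit the variance prior by method of moments
#'
#' On the log scale, a residual variance from `d` residual degrees of
#' freedom satisfies `E[log s^2] = log s0_sq + digamma(d/2) - log(d/2) -
#' digamma(d0/2) + log(d0/2)` and `Var[log s^2] = trigamma(d/2) +
#' trigamma(d0/2)`. Matching these moments gives `d0` (via the trigamma
#' inverse, solved by Newton iteration) and `s0_sq`. When the empirical
#' spread of `log s^2` does not exceed the sampling contribution
#' `trigamma(d/2)`, the prior degenerates to `d0 = Inf` (a common
#' variance).
#'
#' @param s_sq vector of observed residual variances (non-positive entries
#'   are excluded with a warning).
#' @param d residual degrees of freedom, a scalar shared by all entries.
#' @return a [variance_prior()].
#' @export
estimate_variance_prior <- function(s_sq, d) {
  d <- assert_count(d, "d", min = 1)
  ok <- is.finite(s_sq) & s_sq > 0
  if (!all(ok)) {
    if (!any(ok)) stopf("no positive finite variances to fit the prior")
    warnf("excluding %d non-positive/non-finite variance(s)", sum(!ok))
    s_sq <- s_sq[ok]
  }
  z <- log(s_sq)
  e <- z - digamma(d / 2) + log(d / 2)
  if (length(s_sq) < 10) {
    warnf("fewer than 10 variances; falling back to a common-variance prior (d0 = Inf)")
    return(variance_prior(Inf, exp(mean(z))))
  }
  evar <- stats::var(z) - trigamma(d / 2)
  # common-variance limit: the prior scale is the geometric mean of the
  # observed variances, so identical variances recover exactly that value
  if (evar <= 0) return(variance_prior(Inf, exp(mean(z))))
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  variance_prior(d0, s0_sq)
}

#' Moderated two-group t-statistic
#'
#' Shrinks each tag's residual variance toward the prior,
#' `s_tilde_sq = (d0 * s0_sq + d * s_sq) / (d0 + d)`, and tests the group
#' difference `delta` with `t = delta / sqrt(s_tilde_sq * (1/n_t + 1/n_u))`
#' on `d0 + d` degrees of freedom (a normal reference when `d0 = Inf`).
#' Two-sided p-values.
#'
#' @param delta per-tag difference of group means (treated - untreated),
#'   vectorized.
#' @param s_sq per-tag pooled residual variance.
#' @param d residual degrees of freedom (`n_t + n_u - 2`).
#' @param prior a [variance_prior()].
#' @param n_t,n_u group sample sizes (>= 2 each).
#' @return data.frame with columns `delta`, `s_sq`, `s_tilde_sq`, `t`,
#'   `df_total`, `p`.
#' @export
moderated_t <- function(delta, s_sq, d, prior, n_t, n_u) {
  stopifnot(inherits(prior, "variance_prior"))
  n_t <- assert_count(n_t, "n_t", min = 2)
  n_u <- assert_count(n_u, "n_u", min = 2)
  d <- assert_count(d, "d", min = 1)
  if (d != n_t + n_u - 2)
    stopf("'d' must equal n_t + n_u - 2")
  if (length(delta) != length(s_sq))
    stopf("'delta' and 's_sq' must have the same length")
  d0 <- prior$d0
  s_tilde_sq <- if (is.infinite(d0)) rep(prior$s0_sq, length(s_sq))
  else (d0 * prior$s0_sq + d * s_sq) / (d0 + d)
  if (any(s_tilde_sq <= 0))
    stopf("degenerate posterior variance (s_tilde_sq <= 0)")
  se <- sqrt(s_tilde_sq * (1 / n_t + 1 / n_u))
  t_mod <- delta / se
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  data.frame(delta = delta, s_sq = s_sq, s_tilde_sq = s_tilde_sq,
             t = t_mod, df_total = df_total, p = p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_i = min over {j : p_j >= p_i} of (m * p_j / rank_j)`, clipped at 1.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values, order-preserving in `p`.
#' @export
bh_qvalues <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-tag moderated t-tests for one assay
#'
#' For every tag of the assay's pool, computes the treated-minus-untreated
#' difference of mean normalized log2 intensity, the pooled residual
#' variance across the replicate samples, fits (or reuses) the
#' empirical-Bayes variance prior across all tags of the assay, and returns
#' moderated t-statistics with two-sided p-values.
#'
#' @param x a normalized [tag_table()].
#' @param assay one row of [screen_assays()] (or a list with `pool` and
#'   `carbon_source`).
#' @param prior optional [variance_prior()]; fitted from this assay's
#'   variances when `NULL`.
#' @param treated treatment label of the treated arm (default `"Cu"`); all
#'   other treatments are the untreated arm.
#' @return data.frame: `tag_id`, `strain`, `tag_group`, `delta`, `s_sq`,
#'   `s_tilde_sq`, `t`, `df_total`, `p`; the prior is attached as attribute
#'   `"prior"`.
#' @export
assay_tag_tests <- function(x, assay, prior = NULL, treated = "Cu") {
  stopifnot(inherits(x, "tag_table"))
  if (x$scale != "log2-normalized")
    stopf("tag tests expect quantile-normalized log2 values")
  s <- x$samples
  t_cols <- which(s$pool == assay$pool & s$carbon_source == assay$carbon_source &
                    s$treatment == treated)
  u_cols <- which(s$pool == assay$pool & s$carbon_source == assay$carbon_source &
                    s$treatment != treated)
  if (length(t_cols) < 2 || length(u_cols) < 2)
    stopf("assay %s/%s needs >= 2 treated and >= 2 untreated replicates",
          assay$pool, assay$carbon_source)
  rows <- which(x$tags$pool == assay$pool)
  mt <- x$values[rows, t_cols, drop = FALSE]
  mu <- x$values[rows, u_cols, drop = FALSE]
  n_t <- ncol(mt)
  n_u <- ncol(mu)
  d <- n_t + n_u - 2
  delta <- rowMeans(mt) - rowMeans(mu)
  ss <- (rowSums((mt - rowMeans(mt))^2) + rowSums((mu - rowMeans(mu))^2)) / d
  if (is.null(prior))
    prior <- suppressWarnings(estimate_variance_prior(ss, d))
  res <- moderated_t(delta, ss, d, prior, n_t, n_u)
  out <- cbind(x$tags[rows, c("tag_id", "strain", "tag_group")], res)
  rownames(out) <- NULL
  attr(out, "prior") <- prior
  out
}

#' Strain-level p- and q-values from tag-level tests
#'
#' Each strain inherits the p-value of its CRS-selected tag; q-values are
#' then computed by Benjamini-Hochberg over all strains present in the
#' assay.
#'
#' @param tag_results output of [assay_tag_tests()].
#' @param crs a strain result table from [copper_response_score()] (one
#'   assay), with `selected_tag_id` column.
#' @return `crs` with `t`, `p` and `q` columns added. Strains whose selected
#'   tag has no test result are excluded from the BH universe (q = NA) with
#'   a warning.
#' @export
strain_level_inference <- function(tag_results, crs) {
  idx <- match(crs$selected_tag_id, tag_results$tag_id)
  crs$t <- tag_results$t[idx]
  crs$p <- tag_results$p[idx]
  no_test <- !is.na(crs$selected_tag_id) & is.na(crs$p)
  if (any(no_test))
    warnf("%d strain(s) excluded: selected tag has no test result",
          sum(no_test))
  crs$q <- NA_real_
  ok <- !is.na(crs$p)
  crs$q[ok] <- bh_qvalues(crs$p[ok])
  crs
}
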