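# condition_means built directly from a matrix of per-condition means,
# bypassing replicate averaging, for unit tests of the scoring rules
mean_table <- function(values, map, pool = "HD") {
  conds <- data.frame(condition = colnames(values), pool = pool,
                      carbon_source = "YPE",
                      treatment = c("none", "Cu"),
                      n_replicates = 3L, stringsAsFactors = FALSE)
  tag_ids <- rownames(values)
  structure(list(values = values,
                 tags = data.frame(tag_id = tag_ids, stringsAsFactors = FALSE),
                 conditions = conds),
            class = "condition_means")
}

ype_assay <- data.frame(assay = "YPE", pool = "HD", carbon_source = "YPE",
                        stringsAsFactors = FALSE)

test_that("CRS is zero when treated and untreated means coincide", {
  map <- data.frame(strain = c("s1", "s2"), uptag = c("u1", "u2"),
                    downtag = c("d1", "d2"), pool = "HD",
                    stringsAsFactors = FALSE)
  v <- matrix(c(8, 7, 6, 5, 8, 7, 6, 5), 4, 2,
              dimnames = list(c("u1", "u2", "d1", "d2"),
                              c("HD_YPE_none", "HD_YPE_Cu")))
  out <- copper_response_score(mean_table(v, map), map, ype_assay)
  expect_equal(out$crs, c(0, 0))
})

test_that("the tag with the greater absolute difference provides the CRS", {
  map <- data.frame(strain = "s1", uptag = "u1", downtag = "d1", pool = "HD",
                    stringsAsFactors = FALSE)
  v <- matrix(c(8, 7, 8.4, 5), 2, 2,
              dimnames = list(c("u1", "d1"), c("HD_YPE_none", "HD_YPE_Cu")))
  out <- copper_response_score(mean_table(v, map), map, ype_assay)
  expect_equal(out$delta_uptag, 0.4)
  expect_equal(out$delta_downtag, -2.0)
  expect_equal(out$crs, -2.0)
  expect_equal(out$selected_tag, "downtag")

  # exact tie selects the uptag
  v_tie <- matrix(c(8, 7, 9, 6), 2, 2,
                  dimnames = list(c("u1", "d1"),
                                  c("HD_YPE_none", "HD_YPE_Cu")))
  tie <- copper_response_score(mean_table(v_tie, map), map, ype_assay)
  expect_equal(tie$selected_tag, "uptag")
  expect_equal(tie$crs, 1)

  # single-tag strains use their only tag
  map1 <- data.frame(strain = "s1", uptag = "u1", downtag = NA_character_,
                     pool = "HD", stringsAsFactors = FALSE)
  v1 <- matrix(c(8, 8.7), 1, 2,
               dimnames = list("u1", c("HD_YPE_none", "HD_YPE_Cu")))
  one <- copper_response_score(mean_table(v1, map1), map1, ype_assay)
  expect_equal(one$crs, 0.7)
  expect_equal(one$selected_tag, "uptag")
})

test_that("planted noise-free responders score exactly the closed-form log2 ratio", {
  n <- 1000
  design <- pool_design(n, carbon_sources = "YPE", frac_single_tag = 0,
                        seed = 17)
  map <- make_strain_map(design)
  truth <- make_truth(map, design, n_responders = 1, delta = 0.2,
                      responder_carbons = "YPE", affinity_sdlog = 0)
  sim <- simulate_pool(design, map, truth, noise_model(sigma_log = 0))

  # means of the log2 intensities (identical replicates), packaged directly
  lg <- log2_transform(sim$table)
  s <- lg$samples
  v <- cbind(HD_YPE_none = rowMeans(lg$values[, s$treatment == "none"]),
             HD_YPE_Cu = rowMeans(lg$values[, s$treatment == "Cu"]))
  out <- copper_response_score(mean_table(v, map), map, ype_assay)

  idx <- match(truth$responders, map$strain)
  delta_vec <- rep(0, n)
  delta_vec[idx] <- 0.2
  expected <- oracle_pool_log2_ratio(rep(0, n), delta_vec,
                                     design$generations, idx)
  expect_equal(out$crs[match(truth$responders, out$strain)], expected,
               tolerance = 1e-9)
  # non-responders share the small compensatory negative shift
  others <- setdiff(seq_len(n), idx)
  expected_null <- oracle_pool_log2_ratio(rep(0, n), delta_vec,
                                          design$generations, others[1])
  expect_equal(unname(out$crs[match(map$strain[others[1]], out$strain)]),
               expected_null, tolerance = 1e-9)
})

test_that("swapping treated and untreated labels negates every CRS", {
  scr <- make_screen(n_strains = 40, sigma_log = 0.2, affinity_sdlog = 0.5,
                     n_responders = 5, carbon_sources = "YPE",
                     responder_carbons = "YPE")
  norm <- quantile_normalize(log2_transform(scr$table))
  means <- replicate_means(norm)
  fwd <- copper_response_score(means, scr$map, ype_assay, treated = "Cu")
  rev <- copper_response_score(means, scr$map, ype_assay, treated = "none")
  expect_equal(fwd$crs, -rev$crs)
})

test_that("classification applies the CRS and q thresholds per assay", {
  thr <- screen_thresholds()
  res <- data.frame(
    strain = c("a", "a", "b", "c", "d", "d"),
    assay = c("YPE", "YPL", "YPE", "YPE*", "YPE", "YPG"),
    crs = c(0.2, 1.6, 1.6, -1.51, 1.8, -1.7),
    q = c(0.3, 0.01, 0.20, 0.049, 0.001, 0.02),
    stringsAsFactors = FALSE)
  out <- classify_strains(res, thr)
  expect_equal(out$class,
               c("neutral", "increased", "neutral", "decreased",
                 "increased", "decreased"))
  expect_equal(out$overall_class[out$strain == "a"][1], "increased")
  expect_equal(out$overall_class[out$strain == "b"][1], "neutral")
  expect_equal(out$overall_class[out$strain == "c"][1], "decreased")
  expect_equal(out$overall_class[out$strain == "d"][1], "conflicting")

  # boundary cases are exclusive: CRS must exceed 1.5 and q fall below 0.05
  edge <- data.frame(strain = c("e", "f"), assay = "YPE",
                     crs = c(1.5, 1.6), q = c(0.01, 0.05),
                     stringsAsFactors = FALSE)
  expect_equal(classify_strains(edge, thr)$class, c("neutral", "neutral"))
})

test_that("the RD filter applies the median thresholds exactly", {
  # three strains engineered around the < 7 and > 8 rules
  tags <- data.frame(tag_id = sprintf("t%d", 1:3),
                     strain = sprintf("s%d", 1:3),
                     tag_group = "uptag", pool = "HD",
                     stringsAsFactors = FALSE)
  samples <- expand.grid(carbon_source = c("YPD", "YPE", "YPG", "YPL"),
                         treatment = c("none", "Cu"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$pool <- "HD"
  samples$replicate <- 1L
  samples$sample_id <- paste(samples$carbon_source, samples$treatment,
                             sep = "_")
  samples <- samples[c("sample_id", "pool", "carbon_source", "treatment",
                       "replicate")]
  v <- matrix(0, 3, nrow(samples),
              dimnames = list(tags$tag_id, samples$sample_id))
  fill <- function(strain, nonferm, ypd) {
    nf_cols <- samples$carbon_source != "YPD"
    v[strain, nf_cols] <<- 2^nonferm
    v[strain, !nf_cols] <<- 2^ypd
  }
  fill(1, 6.5, 8.5) # passes both rules
  fill(2, 7.5, 8.5) # fails < 7
  fill(3, 6.5, 7.9) # fails > 8
  # make treated samples disagree wildly: they must be ignored
  v[, samples$treatment == "Cu"] <- 2^12
  raw <- tag_table(v, tags, samples, scale = "linear")
  rd <- respiration_deficient_filter(raw)
  expect_equal(rd, "s1", ignore_attr = TRUE)
  med <- attr(rd, "medians")
  expect_equal(med$median_nonferm, c(6.5, 7.5, 6.5))
  expect_equal(med$median_ferm, c(8.5, 8.5, 7.9))

  # missing carbon source errors
  keep <- samples$carbon_source != "YPG"
  raw2 <- tag_table(v[, keep], tags, samples[keep, ], scale = "linear")
  expect_error(respiration_deficient_filter(raw2), "YPG")
})

test_that("the RD filter recovers planted respiration-deficient strains exactly", {
  scr <- make_screen(n_strains = 60, sigma_log = 0, affinity_sdlog = 0,
                     n_rd = 10)
  rd <- respiration_deficient_filter(scr$table)
  expect_equal(sort(rd), scr$truth$rd_strains, ignore_attr = TRUE)
})

test_that("threshold constructor validates its arguments", {
  expect_error(screen_thresholds(crs_threshold = 0), "crs_threshold")
  expect_error(screen_thresholds(q_threshold = 1), "q_threshold")
  expect_error(screen_thresholds(rd_low = 9, rd_high = 8), "rd_low")
  thr <- screen_thresholds(rd_low = 9, rd_high = 8, allow_inverted = TRUE)
  expect_equal(thr$rd_low, 9)
})
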