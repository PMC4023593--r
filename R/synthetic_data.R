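#' Design of a synthetic pooled fitness screen
#'
#' Describes the layout of a competitively grown deletion-pool experiment:
#' how many barcoded strains, how many doublings of competitive growth, which
#' carbon sources and treatments, and how many replicate cultures per
#' condition. Defaults mirror a genome-scale copper screen: pools grown for
#' precisely 9 generations (diluted every three doublings so growth stays
#' logarithmic and the readout compositional), four carbon sources (dextrose
#' plus the non-fermentable ethanol, glycerol and lactate), untreated vs
#' copper-treated, in triplicate.
#'
#' @param n_strains number of strains in the pool (>= 2).
#' @param generations doublings of competitive growth (default 9).
#' @param carbon_sources character vector of media labels.
#' @param treatments character vector; the first entry is the untreated
#'   reference, any other entry receives the per-strain treatment effect.
#' @param replicates cultures per (carbon source, treatment) condition.
#' @param frac_single_tag fraction of strains carrying only an uptag,
#'   in `[0, 1)`.
#' @param pool pool label (e.g. `"HD"` for the full homozygous-deletion pool
#'   or `"RD"` for the respiration-deficient sub-pool).
#' @param seed integer seed from which all randomness of the design flows.
#' @return an object of class `pool_design`.
#' @export
pool_design <- function(n_strains, generations = 9,
                        carbon_sources = c("YPD", "YPE", "YPG", "YPL"),
                        treatments = c("none", "Cu"),
                        replicates = 3, frac_single_tag = 0.02,
                        pool = "HD", seed = 1L) {
  n_strains <- assert_count(n_strains, "n_strains", min = 2)
  generations <- assert_number(generations, "generations", min = 0)
  replicates <- assert_count(replicates, "replicates", min = 1)
  frac_single_tag <- assert_number(frac_single_tag, "frac_single_tag", min = 0)
  if (frac_single_tag >= 1) stopf("'frac_single_tag' must be < 1")
  if (!length(carbon_sources)) stopf("at least one carbon source is required")
  if (length(treatments) < 1) stopf("at least one treatment is required")
  structure(list(n_strains = n_strains, generations = generations,
                 carbon_sources = as.character(carbon_sources),
                 treatments = as.character(treatments),
                 replicates = replicates,
                 frac_single_tag = frac_single_tag,
                 pool = as.character(pool[1]),
                 seed = as.integer(seed)),
            class = "pool_design")
}

#' Generate a strain barcode map for a pool design
#'
#' Every strain receives an uptag; a fraction `frac_single_tag` of strains
#' (chosen at random under the design seed) lack the downtag, mirroring the
#' real deletion collection in which some strains carry a single barcode.
#'
#' @param design a [pool_design()].
#' @return data.frame with columns `strain`, `uptag`, `downtag` (`NA` for
#'   single-tag strains) and `pool`. Deterministic given `design$seed`.
#' @export
make_strain_map <- function(design) {
  stopifnot(inherits(design, "pool_design"))
  n <- design$n_strains
  strain <- sprintf("strain%05d", seq_len(n))
  map <- data.frame(strain = strain,
                    uptag = sprintf("%s_up", strain),
                    downtag = sprintf("%s_dn", strain),
                    pool = design$pool,
                    stringsAsFactors = FALSE)
  n_single <- round(design$frac_single_tag * n)
  if (n_single > 0) {
    single <- with_seed(design$seed, sample.int(n, n_single))
    map$downtag[single] <- NA_character_
  }
  validate_strain_map(map)
}

#' Noise model for simulated tag intensities
#'
#' @param sigma_log standard deviation of additive Gaussian noise applied to
#'   log2 intensities (so the linear-scale noise is log-normal).
#' @param background additive floor on linear intensities (>= 0).
#' @param saturation optional linear-scale cap emulating scanner saturation;
#'   must exceed `background` when set.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(sigma_log = 0.3, background = 0, saturation = NULL) {
  sigma_log <- assert_number(sigma_log, "sigma_log", min = 0)
  background <- assert_number(background, "background", min = 0)
  if (!is.null(saturation)) {
    saturation <- assert_number(saturation, "saturation")
    if (saturation <= background) stopf("'saturation' must exceed 'background'")
  }
  structure(list(sigma_log = sigma_log, background = background,
                 saturation = saturation),
            class = "noise_model")
}

#' Ground truth for a simulated pool
#'
#' Assembles the generative parameters of a synthetic screen: per
#' (strain, carbon source) a baseline fitness `f` (relative growth-rate
#' units per doubling; 0 = pool-typical) and a treatment effect `delta`
#' added to `f` under treatment, plus one multiplicative hybridization
#' affinity per tag. Responder strains model deletions whose copper response
#' differs from the pool; respiration-deficient (RD) strains carry a strong
#' fitness deficit on non-fermentable carbon sources only.
#'
#' @param map strain barcode map from [make_strain_map()].
#' @param design the [pool_design()].
#' @param n_responders number of strains given a non-zero treatment effect.
#' @param delta treatment effect per doubling for responders. A strain's
#'   noise-free log2 treated/untreated abundance ratio is
#'   `delta * generations` minus the compositional renormalization shift.
#' @param responder_carbons carbon sources in which the effect acts
#'   (defaults: the non-fermentable ones, where copper acts on respiration).
#' @param carbon_specific if `TRUE`, each responder's effect is scaled by an
#'   independent Uniform(0.5, 1.5) factor per carbon source, emulating
#'   carbon-source-specific response magnitudes.
#' @param n_rd number of planted respiration-deficient strains (disjoint
#'   from the responders).
#' @param rd_fitness baseline fitness of RD strains on `rd_carbons`
#'   (strongly negative so they wash out of respiratory pools).
#' @param rd_carbons carbon sources where the RD deficit applies.
#' @param baseline_sd standard deviation of pool-typical baseline fitness
#'   variation per (strain, carbon source); 0 gives an idealized
#'   equal-fitness pool.
#' @param affinity_sdlog sdlog of the log-normal tag affinity distribution
#'   (natural-log scale). Affinity spread is what makes uptag and downtag
#'   intensities of one strain disagree, motivating the max-|difference| tag
#'   selection rule downstream. Set 0 for equal affinities.
#' @param seed seed for the truth draw (defaults to `design$seed + 1`).
#' @return object of class `strain_truth`: list with data.frames `fitness`
#'   (strain, carbon_source, f, delta, rd) and `affinity` (tag_id,
#'   affinity), plus `responders` and `rd_strains` character vectors.
#' @export
make_truth <- function(map, design, n_responders = 0, delta = 1 / 3,
                       responder_carbons = c("YPE", "YPG", "YPL"),
                       carbon_specific = FALSE,
                       n_rd = 0, rd_fitness = -0.5,
                       rd_carbons = c("YPE", "YPG", "YPL"),
                       baseline_sd = 0, affinity_sdlog = 0.5,
                       seed = design$seed + 1L) {
  stopifnot(inherits(design, "pool_design"))
  map <- validate_strain_map(map)
  n_responders <- assert_count(n_responders, "n_responders", min = 0)
  n_rd <- assert_count(n_rd, "n_rd", min = 0)
  if (n_responders + n_rd > nrow(map))
    stopf("n_responders + n_rd exceeds the number of strains")
  tags <- tags_from_map(map)

  with_seed(seed, {
    picked <- sample(map$strain, n_responders + n_rd)
    responders <- if (n_responders) picked[seq_len(n_responders)] else character()
    rd_strains <- if (n_rd) picked[n_responders + seq_len(n_rd)] else character()

    fitness <- expand.grid(strain = map$strain,
                           carbon_source = design$carbon_sources,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    fitness$f <- if (baseline_sd > 0)
      stats::rnorm(nrow(fitness), 0, baseline_sd) else 0
    fitness$delta <- 0
    is_resp <- fitness$strain %in% responders &
      fitness$carbon_source %in% responder_carbons
    fitness$delta[is_resp] <- delta
    if (carbon_specific && any(is_resp))
      fitness$delta[is_resp] <- fitness$delta[is_resp] *
        stats::runif(sum(is_resp), 0.5, 1.5)
    fitness$rd <- fitness$strain %in% rd_strains
    is_rd_here <- fitness$rd & fitness$carbon_source %in% rd_carbons
    fitness$f[is_rd_here] <- fitness$f[is_rd_here] + rd_fitness

    affinity <- data.frame(tag_id = tags$tag_id,
                           affinity = if (affinity_sdlog > 0)
                             stats::rlnorm(nrow(tags), 0, affinity_sdlog)
                           else 1,
                           stringsAsFactors = FALSE)
    structure(list(fitness = fitness, affinity = affinity,
                   responders = sort(responders),
                   rd_strains = sort(rd_strains)),
              class = "strain_truth")
  })
}

#' Simulate a competitively grown pool and its tag intensity readout
#'
#' Strain abundances follow deterministic exponential competitive growth:
#' after `G` doublings the relative abundance of strain *i* is proportional
#' to `2^((f_i + delta_i * treated) * G)`, renormalized to a constant
#' per-sample total (serial dilution keeps the pool compositional). Each
#' tag's linear intensity is the strain abundance times the pool size times
#' `intensity_scale` times the tag's hybridization affinity, plus the
#' background floor; log-normal noise is then applied on the log2 scale and
#' an optional saturation cap truncates the linear values.
#'
#' @param design a [pool_design()].
#' @param map strain map from [make_strain_map()].
#' @param truth ground truth from [make_truth()]; must cover every strain in
#'   the map for every carbon source of the design.
#' @param noise a [noise_model()].
#' @param intensity_scale linear intensity of a pool-typical tag with unit
#'   affinity (default 1000, i.e. about 2^10 fluorescence units).
#' @param bottleneck_n optional cell count for a multinomial sampling
#'   bottleneck applied to the final abundances; `NULL` (default) keeps the
#'   growth model deterministic so closed-form oracles are exact.
#' @param seed seed for the noise draw (defaults to `design$seed + 2`).
#' @return list with elements `table` (a linear-scale [tag_table()]) and
#'   `samples` (the sample sheet).
#' @export
simulate_pool <- function(design, map, truth, noise = noise_model(),
                          intensity_scale = 1000, bottleneck_n = NULL,
                          seed = design$seed + 2L) {
  stopifnot(inherits(design, "pool_design"), inherits(truth, "strain_truth"),
            inherits(noise, "noise_model"))
  map <- validate_strain_map(map)
  tags <- tags_from_map(map)

  missing_aff <- setdiff(tags$tag_id, truth$affinity$tag_id)
  if (length(missing_aff))
    stopf("truth lacks affinities for tag(s): %s",
          paste(utils::head(missing_aff), collapse = ", "))
  key_need <- expand.grid(strain = map$strain,
                          carbon_source = design$carbon_sources,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  have <- paste(truth$fitness$strain, truth$fitness$carbon_source)
  need <- paste(key_need$strain, key_need$carbon_source)
  if (!all(need %in% have)) {
    bad <- key_need$strain[!(need %in% have)]
    stopf("truth lacks fitness entries for strain(s): %s",
          paste(utils::head(unique(bad)), collapse = ", "))
  }

  sheet <- expand.grid(replicate = seq_len(design$replicates),
                       treatment = design$treatments,
                       carbon_source = design$carbon_sources,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet <- sheet[, c("carbon_source", "treatment", "replicate")]
  sheet$pool <- design$pool
  sheet$sample_id <- sprintf("%s_%s_%s_%d", sheet$pool, sheet$carbon_source,
                             sheet$treatment, sheet$replicate)
  sheet <- sheet[, c("sample_id", "pool", "carbon_source", "treatment",
                     "replicate")]

  aff <- truth$affinity$affinity[match(tags$tag_id, truth$affinity$tag_id)]
  untreated <- design$treatments[1]
  G <- design$generations
  n <- design$n_strains

  vals <- matrix(NA_real_, nrow = nrow(tags), ncol = nrow(sheet),
                 dimnames = list(tags$tag_id, sheet$sample_id))
  with_seed(seed, {
    for (j in seq_len(nrow(sheet))) {
      cs <- sheet$carbon_source[j]
      treated <- sheet$treatment[j] != untreated
      ft <- truth$fitness[truth$fitness$carbon_source == cs, , drop = FALSE]
      ft <- ft[match(map$strain, ft$strain), , drop = FALSE]
      rate <- ft$f + if (treated) ft$delta else 0
      w <- 2^(rate * G)
      abund <- w / sum(w)
      if (!is.null(bottleneck_n)) {
        counts <- stats::rmultinom(1, assert_count(bottleneck_n, "bottleneck_n"),
                                   abund)[, 1]
        abund <- counts / sum(counts)
      }
      intensity <- abund[match(tags$strain, map$strain)] * n *
        intensity_scale * aff + noise$background
      if (noise$sigma_log > 0)
        intensity <- intensity *
          2^stats::rnorm(length(intensity), 0, noise$sigma_log)
      if (!is.null(noise$saturation))
        intensity <- pmin(intensity, noise$saturation)
      vals[, j] <- intensity
    }
  })
  list(table = tag_table(vals, tags, sheet, scale = "linear"),
       samples = sheet)
}

#' Logistic growth-curve parameters
#'
#' @param K carrying capacity above baseline (OD600 units, > 0; 0 is allowed
#'   and gives a flat curve at the baseline).
#' @param r growth rate (per hour, > 0).
#' @param t_m time of the logistic midpoint (hours).
#' @param baseline optical density offset of an uninoculated well (OD600).
#' @param od_noise standard deviation of Gaussian measurement noise (OD600).
#' @return object of class `growth_params`.
#' @export
growth_params <- function(K, r, t_m, baseline = 0.03, od_noise = 0) {
  K <- assert_number(K, "K", min = 0)
  r <- assert_number(r, "r", min = 0, strict = TRUE)
  t_m <- assert_number(t_m, "t_m")
  baseline <- assert_number(baseline, "baseline")
  od_noise <- assert_number(od_noise, "od_noise", min = 0)
  structure(list(K = K, r = r, t_m = t_m, baseline = baseline,
                 od_noise = od_noise),
            class = "growth_params")
}

#' Simulate a plate-reader growth curve
#'
#' Generates optical-density readings on the fixed plate-reader schedule
#' (one reading per `interval_min` minutes):
#' `OD(t) = baseline + K / (1 + exp(-r (t - t_m))) + N(0, od_noise)`.
#'
#' @param params a [growth_params()].
#' @param n_reads number of readings (>= 10; baseline correction downstream
#'   averages the first 10).
#' @param interval_min minutes between readings (default 15).
#' @param condition free-form label list attached to the curve (strain,
#'   carbon source, compound, dose, ...).
#' @param seed optional seed for the noise draw.
#' @return a [growth_curve()].
#' @export
simulate_growth_curve <- function(params, n_reads, interval_min = 15,
                                  condition = list(), seed = NULL) {
  stopifnot(inherits(params, "growth_params"))
  n_reads <- assert_count(n_reads, "n_reads", min = 10)
  t_h <- (seq_len(n_reads) - 1) * interval_min / 60
  od <- params$baseline + params$K / (1 + exp(-params$r * (t_h - params$t_m)))
  if (params$od_noise > 0)
    od <- od + with_seed(seed, stats::rnorm(n_reads, 0, params$od_noise))
  growth_curve(od, interval_min = interval_min, condition = condition)
}

#' @rdname screen_io
#' @export
write_truth <- function(x, path) {
  stopifnot(inherits(x, "strain_truth"))
  fit <- x$fitness
  aff <- x$affinity
  df <- data.frame(
    record = c(rep("fitness", nrow(fit)), rep("affinity", nrow(aff))),
    strain = c(fit$strain, rep(NA_character_, nrow(aff))),
    carbon_source = c(fit$carbon_source, rep(NA_character_, nrow(aff))),
    f = c(sprintf("%.17g", fit$f), rep(NA_character_, nrow(aff))),
    delta = c(sprintf("%.17g", fit$delta), rep(NA_character_, nrow(aff))),
    rd = c(as.character(fit$rd), rep(NA_character_, nrow(aff))),
    tag_id = c(rep(NA_character_, nrow(fit)), aff$tag_id),
    affinity = c(rep(NA_character_, nrow(fit)), sprintf("%.17g", aff$affinity)),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_truth <- function(path) {
  df <- read_tsv(path)
  fit <- df[df$record == "fitness", , drop = FALSE]
  aff <- df[df$record == "affinity", , drop = FALSE]
  fitness <- data.frame(strain = fit$strain,
                        carbon_source = fit$carbon_source,
                        f = as.numeric(fit$f),
                        delta = as.numeric(fit$delta),
                        rd = as.logical(fit$rd),
                        stringsAsFactors = FALSE)
  affinity <- data.frame(tag_id = aff$tag_id,
                         affinity = as.numeric(aff$affinity),
                         stringsAsFactors = FALSE)
  resp <- sort(unique(fitness$strain[fitness$delta != 0]))
  rd <- sort(unique(fitness$strain[fitness$rd]))
  structure(list(fitness = fitness, affinity = affinity,
                 responders = resp, rd_strains = rd),
            class = "strain_truth")
}
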