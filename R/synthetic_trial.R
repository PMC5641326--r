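# Synthetic trial generator: design table, per-plot RGB images, 11-band
# reflectance stacks, thermal rasters and yields from a known generative
# model, so every downstream stage is testable with full ground truth.
#
# Pixel class counts are allocated deterministically (largest-remainder
# rounding); only hue jitter, pixel placement and measurement noise are
# random. Each artifact draws from a per-plot seed derived from the master
# seed by plot index, so single plots are reproducible without global state.

#' Default endmember reflectance spectra
#'
#' Pure-class reflectance (unit scale, [0, 1]) of green canopy, senescent
#' tissue and bare soil at the 11 camera wavelengths: green vegetation shows
#' the chlorophyll absorption trough at 670 nm and the NIR plateau; senescent
#' tissue loses the trough; soil is a gently rising line.
#'
#' @return 3 x 11 matrix, rows green/senescent/soil, columns wavelengths.
#' @export
default_endmembers <- function() {
  wl <- ms_wavelengths()
  m <- rbind(
    green     = c(0.03, 0.08, 0.07, 0.04, 0.10, 0.25, 0.45, 0.48, 0.48, 0.47, 0.44),
    senescent = c(0.08, 0.18, 0.20, 0.25, 0.28, 0.32, 0.38, 0.39, 0.39, 0.38, 0.36),
    soil      = c(0.10, 0.16, 0.18, 0.22, 0.24, 0.26, 0.30, 0.31, 0.32, 0.33, 0.33))
  colnames(m) <- as.character(wl)
  m
}

#' Configuration of the synthetic trial
#'
#' Defaults emulate the reference trial: 3 genotypes x 10 N regimens x 3
#' replicates = 90 plots. Hue centres are 110 (green), 70 (senescent) and 30
#' (soil) degrees so the default GA/GGA windows separate the classes cleanly;
#' saturation and value of synthetic pixels are fixed mid-range so pixel
#' classification is a pure function of hue. The yield model is linear in
#' true green cover (t/ha).
#'
#' @param n_genotypes,n_reps design counts (>= 1).
#' @param treatments data.frame of N schedules; default the ten reference
#'   regimens of [n_treatment_schedules()].
#' @param image_size c(height, width) of plot RGB images in pixels.
#' @param fractions default green/senescent/soil proportions for single-plot
#'   generation (must sum to 1).
#' @param hue_centers named degrees for the three pixel populations.
#' @param hue_jitter sd of hue noise in degrees.
#' @param saturation,value fixed HSV saturation/value of synthetic pixels.
#' @param endmember_spectra 3 x 11 reflectance matrix ([default_endmembers()]).
#' @param ms_size,ms_noise_sd reflectance raster size and per-pixel noise sd.
#' @param thermal class temperatures (degC) per acquisition and pixel noise sd.
#' @param cover_model per-plot green-cover model: genotype baselines, slope on
#'   N supply (scaled by the maximum supply), plot noise sd, and the share of
#'   non-green cover that is senescent.
#' @param yield_model intercept (t/ha), slope on green cover, noise sd.
#' @param tgw_mean,tgw_sd thousand grain weight distribution (g).
#' @param seed master integer seed.
#' @return list of class `canopyx_config`.
#' @export
synthetic_config <- function(n_genotypes = 3, n_reps = 3,
                             treatments = n_treatment_schedules(),
                             image_size = c(100, 100),
                             fractions = c(green = 0.5, senescent = 0.15, soil = 0.35),
                             hue_centers = c(green = 110, senescent = 70, soil = 30),
                             hue_jitter = 3,
                             saturation = 0.5, value = 0.6,
                             endmember_spectra = default_endmembers(),
                             ms_size = c(20, 20), ms_noise_sd = 0.005,
                             thermal = list(
                               morning = c(green = 17, senescent = 20, soil = 24),
                               afternoon = c(green = 11.5, senescent = 13, soil = 16),
                               noise_sd = 0.3, size = c(20, 20)),
                             cover_model = list(
                               genotype_base = c(0.30, 0.38, 0.40),
                               n_slope = 0.5, noise_sd = 0.04,
                               senescent_share = 0.3),
                             yield_model = list(intercept = 1.41, slope = 6.46,
                                                noise_sd = 0.4),
                             tgw_mean = 45, tgw_sd = 3,
                             seed = 1L) {
  if (n_genotypes < 1 || n_reps < 1 || nrow(treatments) < 1)
    stop("design counts must be >= 1", call. = FALSE)
  .check_fractions(fractions)
  if (hue_jitter < 0) stop("hue_jitter must be >= 0", call. = FALSE)
  if (yield_model$noise_sd < 0) stop("yield noise sd must be >= 0", call. = FALSE)
  cfg <- list(n_genotypes = n_genotypes, n_reps = n_reps, treatments = treatments,
              image_size = image_size, fractions = fractions,
              hue_centers = hue_centers, hue_jitter = hue_jitter,
              saturation = saturation, value = value,
              endmember_spectra = endmember_spectra,
              ms_size = ms_size, ms_noise_sd = ms_noise_sd,
              thermal = thermal, cover_model = cover_model,
              yield_model = yield_model, tgw_mean = tgw_mean, tgw_sd = tgw_sd,
              seed = as.integer(seed))
  class(cfg) <- "canopyx_config"
  cfg
}

.check_fractions <- function(fr) {
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9) stop("fractions must sum to 1", call. = FALSE)
  invisible(TRUE)
}

# per-plot seed derived from master seed by plot index (kept under 2^31)
.plot_seed <- function(master, i, stream = 0L) {
  as.integer((as.double(master) + 7919 * i + 104729 * stream) %% 2147483647)
}

#' Generate the trial design table
#'
#' One record per genotype x treatment x replicate, with the four split doses
#' of each regimen and a randomized block assignment (plot order is shuffled
#' independently within each replicate block).
#'
#' @param config [synthetic_config()].
#' @return data.frame with plot_id, block, genotype, treatment, n_supply and
#'   the four split-dose columns.
#' @export
generate_design <- function(config = synthetic_config()) {
  tr <- config$treatments
  splits <- tr[, c("presowing", "january_emergence", "february_tillering",
                   "april_booting")]
  if (any(abs(rowSums(splits) - tr$total_n) > 1e-9))
    stop("treatment split doses do not sum to the declared total", call. = FALSE)
  geno <- paste0("G", seq_len(config$n_genotypes))
  des <- expand.grid(genotype = geno, treatment = tr$treatment,
                     block = seq_len(config$n_reps),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  des <- des[order(des$block, des$treatment, des$genotype), ]
  i <- match(des$treatment, tr$treatment)
  des$n_supply <- tr$total_n[i]
  des <- cbind(des, splits[i, ])
  set.seed(.plot_seed(config$seed, 0, 1L))
  des$field_position <- unlist(lapply(split(seq_len(nrow(des)), des$block),
                                      function(ix) sample(seq_along(ix))))
  des$plot_id <- sprintf("P%03d", seq_len(nrow(des)))
  rownames(des) <- NULL
  des[, c("plot_id", "block", "field_position", "genotype", "treatment",
          "n_supply", "presowing", "january_emergence", "february_tillering",
          "april_booting")]
}

#' Generate per-plot true cover fractions
#'
#' Green cover increases with N supply from a genotype-specific baseline plus
#' plot-level noise; the remaining cover splits between senescent tissue and
#' soil at a fixed senescent share.
#'
#' @param design from [generate_design()].
#' @param config [synthetic_config()].
#' @return data.frame: plot_id, green, senescent, soil (rows sum to 1).
#' @export
generate_fractions <- function(design, config = synthetic_config()) {
  cm <- config$cover_model
  base <- cm$genotype_base[as.integer(factor(design$genotype))]
  nmax <- max(design$n_supply, 1)
  set.seed(.plot_seed(config$seed, 0, 2L))
  eps <- rnorm(nrow(design), 0, cm$noise_sd)
  green <- pmin(pmax(base + cm$n_slope * design$n_supply / nmax + eps, 0.02), 0.97)
  sen <- cm$senescent_share * (1 - green)
  data.frame(plot_id = design$plot_id, green = green, senescent = sen,
             soil = 1 - green - sen, stringsAsFactors = FALSE)
}

# deterministic largest-remainder allocation of n pixels to class fractions
.allocate_counts <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

#' Generate a synthetic plot RGB image
#'
#' Pixels are a mixture of green, senescent and soil hue populations centred
#' at the configured hues with Gaussian jitter, fixed mid-range saturation
#' and value. Class counts are allocated deterministically (largest-remainder
#' rounding), so realized class fractions match the request to within one
#' pixel; pixel placement and jitter are the only randomness.
#'
#' @param fractions named proportions (green, senescent, soil) summing to 1.
#' @param config [synthetic_config()].
#' @param seed integer seed for jitter and placement.
#' @return H x W x 3 array of 8-bit RGB values.
#' @export
generate_plot_image <- function(fractions = NULL, config = synthetic_config(),
                                seed = config$seed) {
  if (is.null(fractions)) fractions <- config$fractions
  fractions <- fractions[c("green", "senescent", "soil")]
  .check_fractions(fractions)
  h <- config$image_size[1]; w <- config$image_size[2]
  n <- h * w
  counts <- .allocate_counts(n, fractions)
  set.seed(seed)
  hue <- rep(config$hue_centers[c("green", "senescent", "soil")], counts)
  if (config$hue_jitter > 0) hue <- hue + rnorm(n, 0, config$hue_jitter)
  hue <- hue %% 360
  hue <- hue[sample.int(n)]  # stochastic placement
  cols <- grDevices::col2rgb(grDevices::hsv(hue / 360, config$saturation, config$value))
  img <- array(0L, dim = c(h, w, 3))
  img[, , 1] <- matrix(cols[1, ], h, w)
  img[, , 2] <- matrix(cols[2, ], h, w)
  img[, , 3] <- matrix(cols[3, ], h, w)
  img
}

#' Generate a synthetic reflectance stack
#'
#' Per-band reflectance is the cover-weighted average of the class endmember
#' spectra, plus optional Gaussian pixel noise (clipped at 0).
#'
#' @inheritParams generate_plot_image
#' @param noise_sd per-pixel reflectance noise sd; default from config.
#' @return reflectance stack list (`bands`, `scale = "unit"`).
#' @export
generate_reflectance_stack <- function(fractions = NULL,
                                       config = synthetic_config(),
                                       seed = config$seed,
                                       noise_sd = config$ms_noise_sd) {
  if (is.null(fractions)) fractions <- config$fractions
  fractions <- fractions[c("green", "senescent", "soil")]
  .check_fractions(fractions)
  em <- config$endmember_spectra
  need <- as.character(ms_wavelengths())
  if (!all(need %in% colnames(em)))
    stop("endmember spectra missing bands: ",
         paste(setdiff(need, colnames(em)), collapse = ", "), call. = FALSE)
  mix <- as.vector(fractions %*% em[c("green", "senescent", "soil"), need])
  h <- config$ms_size[1]; w <- config$ms_size[2]
  set.seed(seed)
  bands <- lapply(mix, function(v) {
    m <- matrix(v, h, w)
    if (noise_sd > 0) m <- pmax(m + matrix(rnorm(h * w, 0, noise_sd), h, w), 0)
    m
  })
  names(bands) <- need
  list(bands = bands, scale = "unit", plot_id = NA_character_)
}

#' Generate a synthetic thermal raster
#'
#' Pixels take the class temperature (green canopy cooler than soil) plus
#' Gaussian noise; class counts use the same deterministic allocation as the
#' RGB generator, so the plot mean equals the cover-weighted class mixture up
#' to noise.
#'
#' @inheritParams generate_plot_image
#' @param session "morning" or "afternoon".
#' @return numeric matrix of temperatures in degC.
#' @export
generate_thermal_raster <- function(fractions = NULL,
                                    config = synthetic_config(),
                                    seed = config$seed,
                                    session = c("morning", "afternoon")) {
  session <- match.arg(session)
  if (is.null(fractions)) fractions <- config$fractions
  fractions <- fractions[c("green", "senescent", "soil")]
  .check_fractions(fractions)
  temps <- config$thermal[[session]][c("green", "senescent", "soil")]
  h <- config$thermal$size[1]; w <- config$thermal$size[2]
  n <- h * w
  counts <- .allocate_counts(n, fractions)
  set.seed(seed)
  tvec <- rep(temps, counts)
  if (config$thermal$noise_sd > 0) tvec <- tvec + rnorm(n, 0, config$thermal$noise_sd)
  matrix(tvec[sample.int(n)], h, w)
}

#' Generate yields and yield components from true green cover
#'
#' GY = intercept + slope x green cover + Normal(0, sd) in t/ha; the noiseless
#' yield is kept as ground truth. TGW is drawn per plot and NG derived so the
#' GY = 0.01 x NG x TGW (kg/ha) identity holds exactly by construction.
#' Ground-sensor columns are also simulated: NDVI from the plot's mixed
#' reflectance spectrum and SPAD linear in green cover, both lightly noised.
#'
#' @param design from [generate_design()].
#' @param truth from [generate_fractions()].
#' @param config [synthetic_config()].
#' @return list with `design` (gy t/ha, tgw g, ng per m2, spad, ndvi_ground
#'   columns added) and `truth` (noiseless yield added).
#' @export
generate_yields <- function(design, truth, config = synthetic_config()) {
  ym <- config$yield_model
  if (ym$noise_sd < 0) stop("yield noise sd must be >= 0", call. = FALSE)
  stopifnot(identical(design$plot_id, truth$plot_id))
  gy0 <- ym$intercept + ym$slope * truth$green
  set.seed(.plot_seed(config$seed, 0, 3L))
  gy <- gy0 + rnorm(nrow(design), 0, ym$noise_sd)
  tgw <- pmax(rnorm(nrow(design), config$tgw_mean, config$tgw_sd), 20)
  em <- config$endmember_spectra
  mix <- as.matrix(truth[, c("green", "senescent", "soil")]) %*%
    em[c("green", "senescent", "soil"), ]
  ndvi <- (mix[, "840"] - mix[, "670"]) / (mix[, "840"] + mix[, "670"]) +
    rnorm(nrow(design), 0, 0.01)
  spad <- 30 + 20 * truth$green + rnorm(nrow(design), 0, 1.5)
  design$gy <- gy
  design$tgw <- tgw
  design$ng <- (gy * 1000) / (0.01 * tgw)  # grains per m2, exact identity
  design$spad <- spad
  design$ndvi_ground <- ndvi
  truth$gy_noiseless <- gy0
  truth$yield_intercept <- ym$intercept
  truth$yield_slope <- ym$slope
  list(design = design, truth = truth)
}

#' Generate a complete synthetic trial
#'
#' Runs design, fractions, yields and (optionally) all per-plot rasters, and
#' writes them to disk in the standard layout when `out_dir` is given:
#' `design.csv`, `truth.json`, `manifest.json` and `plots/<id>_rgb.png`,
#' `plots/<id>_ms.tif` (multi-page TIFF, ascending wavelength),
#' `plots/<id>_thermal_{morning,afternoon}.tif` (16-bit counts).
#'
#' @param config [synthetic_config()].
#' @param out_dir output directory, or NULL to keep everything in memory.
#' @param rasters generate per-plot images/stacks/thermal rasters (TRUE) or
#'   only the tables (FALSE).
#' @param thermal_scale K per count used to encode thermal TIFFs.
#' @return list with `design`, `truth`, `config`, and when `rasters` is TRUE:
#'   `images`, `stacks`, `thermal_morning`, `thermal_afternoon` (named by
#'   plot id).
#' @export
generate_trial <- function(config = synthetic_config(), out_dir = NULL,
                           rasters = TRUE, thermal_scale = 0.01) {
  design <- generate_design(config)
  truth <- generate_fractions(design, config)
  yl <- generate_yields(design, truth, config)
  design <- yl$design; truth <- yl$truth
  out <- list(design = design, truth = truth, config = config)
  if (rasters) {
    n <- nrow(design)
    frl <- lapply(seq_len(n), function(i)
      c(green = truth$green[i], senescent = truth$senescent[i], soil = truth$soil[i]))
    out$images <- lapply(seq_len(n), function(i)
      generate_plot_image(frl[[i]], config, seed = .plot_seed(config$seed, i, 10L)))
    out$stacks <- lapply(seq_len(n), function(i)
      generate_reflectance_stack(frl[[i]], config, seed = .plot_seed(config$seed, i, 11L)))
    out$thermal_morning <- lapply(seq_len(n), function(i)
      generate_thermal_raster(frl[[i]], config, seed = .plot_seed(config$seed, i, 12L),
                              session = "morning"))
    out$thermal_afternoon <- lapply(seq_len(n), function(i)
      generate_thermal_raster(frl[[i]], config, seed = .plot_seed(config$seed, i, 13L),
                              session = "afternoon"))
    for (nm in c("images", "stacks", "thermal_morning", "thermal_afternoon"))
      names(out[[nm]]) <- design$plot_id
  }
  if (!is.null(out_dir)) .write_trial(out, out_dir, thermal_scale)
  out
}

.write_trial <- function(trial, out_dir, thermal_scale) {
  dir.create(file.path(out_dir, "plots"), recursive = TRUE, showWarnings = FALSE)
  write.csv(trial$design, file.path(out_dir, "design.csv"), row.names = FALSE)
  jsonlite::write_json(trial$truth, file.path(out_dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  cfg <- trial$config
  cfg$treatments <- NULL
  jsonlite::write_json(list(config = unclass(cfg)),
                       file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  if (is.null(trial$images)) return(invisible(out_dir))
  for (id in trial$design$plot_id) {
    png::writePNG(trial$images[[id]] / 255,
                  file.path(out_dir, "plots", paste0(id, "_rgb.png")))
    tiff::writeTIFF(trial$stacks[[id]]$bands,
                    file.path(out_dir, "plots", paste0(id, "_ms.tif")),
                    bits.per.sample = 16)
    for (ses in c("morning", "afternoon")) {
      tr <- trial[[paste0("thermal_", ses)]][[id]]
      dn <- round((tr + 273.15) / thermal_scale)
      tiff::writeTIFF(dn / 65535,
                      file.path(out_dir, "plots", paste0(id, "_thermal_", ses, ".tif")),
                      bits.per.sample = 16)
    }
  }
  invisible(out_dir)
}

#' Assemble the per-plot index table of a synthetic trial
#'
#' Runs the RGB, spectral and thermal index computations over an in-memory
#' trial and merges them with the design table into the common index table
#' consumed by the statistics layer.
#'
#' @param trial output of [generate_trial()] with rasters.
#' @param ... passed to [compute_rgb_indexset()].
#' @return data.frame, one row per plot.
#' @export
trial_index_table <- function(trial, ...) {
  stopifnot(!is.null(trial$images))
  ids <- trial$design$plot_id
  rgb <- do.call(rbind, lapply(ids, function(id)
    compute_rgb_indexset(trial$images[[id]], ...)))
  ms <- do.call(rbind, lapply(ids, function(id)
    compute_spectral_indexset(trial$stacks[[id]])))
  tm <- vapply(ids, function(id) thermal_summary(trial$thermal_morning[[id]])$mean,
               numeric(1))
  ta <- vapply(ids, function(id) thermal_summary(trial$thermal_afternoon[[id]])$mean,
               numeric(1))
  cbind(trial$design, rgb, ms, data.frame(t_mor = tm, t_aft = ta))
}
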