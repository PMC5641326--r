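test_that("the default design enumerates genotype x treatment x replicate", {
  des <- generate_design(synthetic_config())
  expect_equal(nrow(des), 90)
  expect_equal(anyDuplicated(des$plot_id), 0)
  n0 <- des[des$treatment == "N0", ]
  expect_true(all(n0$n_supply == 0))
  expect_true(all(n0[, c("presowing", "january_emergence", "february_tillering",
                         "april_booting")] == 0))
  # every treatment's split doses sum to its declared total
  splits <- des[, c("presowing", "january_emergence", "february_tillering",
                    "april_booting")]
  expect_equal(rowSums(splits), des$n_supply)
  # minimal design
  cfg1 <- synthetic_config(n_genotypes = 1, n_reps = 1,
                           treatments = n_treatment_schedules()[1, ])
  expect_equal(nrow(generate_design(cfg1)), 1)
  expect_error(synthetic_config(n_genotypes = 0), ">= 1")
  expect_error(synthetic_config(n_reps = 0), ">= 1")
})

test_that("plot images realize requested class fractions deterministically", {
  cfg <- synthetic_config(image_size = c(10, 10), hue_jitter = 0)
  # degenerate mixture: all pixels at the green hue centre
  img <- generate_plot_image(c(green = 1, senescent = 0, soil = 0), cfg, seed = 1)
  hues <- rgb_to_hsi(as.vector(img[, , 1]), as.vector(img[, , 2]),
                     as.vector(img[, , 3]))$hue
  expect_true(all(abs(hues - cfg$hue_centers["green"]) < 1))
  # jitter-free allocation is exact
  img2 <- generate_plot_image(c(green = 0.4, senescent = 0.2, soil = 0.4), cfg, seed = 2)
  h2 <- rgb_to_hsi(as.vector(img2[, , 1]), as.vector(img2[, , 2]),
                   as.vector(img2[, , 3]))$hue
  near <- function(center) sum(abs(h2 - center) < 1)
  expect_equal(near(110), 40)
  expect_equal(near(70), 20)
  expect_equal(near(30), 40)
  # seeded determinism
  a <- generate_plot_image(c(green = 0.5, senescent = 0.25, soil = 0.25), cfg, seed = 7)
  b <- generate_plot_image(c(green = 0.5, senescent = 0.25, soil = 0.25), cfg, seed = 7)
  expect_identical(a, b)
  expect_error(generate_plot_image(c(green = 0.9, senescent = 0.3, soil = -0.2), cfg),
               "\\[0, 1\\]")
  expect_error(generate_plot_image(c(green = 0.5, senescent = 0.1, soil = 0.1), cfg),
               "sum to 1")
})

test_that("reflectance stacks mix endmember spectra linearly", {
  cfg <- synthetic_config(ms_size = c(4, 4), ms_noise_sd = 0)
  em <- cfg$endmember_spectra
  pure <- generate_reflectance_stack(c(green = 1, senescent = 0, soil = 0), cfg, seed = 1)
  for (wl in colnames(em))
    expect_equal(mean(pure$bands[[wl]]), em["green", wl], tolerance = 1e-12)
  half <- generate_reflectance_stack(c(green = 0.5, senescent = 0, soil = 0.5), cfg, seed = 1)
  for (wl in colnames(em))
    expect_equal(mean(half$bands[[wl]]), (em["green", wl] + em["soil", wl]) / 2,
                 tolerance = 1e-12)
  # seeded reproducibility with noise
  cfgn <- synthetic_config(ms_size = c(4, 4), ms_noise_sd = 0.01)
  s1 <- generate_reflectance_stack(config = cfgn, seed = 5)
  s2 <- generate_reflectance_stack(config = cfgn, seed = 5)
  expect_identical(s1, s2)
  # missing band is a configuration error
  bad <- cfg
  bad$endmember_spectra <- em[, -1]
  expect_error(generate_reflectance_stack(config = bad, seed = 1), "missing bands")
})

test_that("monotone indices of a 50/50 mix lie between the pure endmember values", {
  cfg <- synthetic_config(ms_size = c(3, 3), ms_noise_sd = 0)
  stacks <- lapply(list(c(green = 1, senescent = 0, soil = 0),
                        c(green = 0.5, senescent = 0, soil = 0.5),
                        c(green = 0, senescent = 0, soil = 1)),
                   generate_reflectance_stack, config = cfg, seed = 1)
  for (nm in c("NDVI", "WBI")) {
    v <- vapply(stacks, function(s) compute_spectral_index(nm, s), numeric(1))
    expect_true(v[2] >= min(v[c(1, 3)]) && v[2] <= max(v[c(1, 3)]))
  }
})

test_that("yields follow the configured linear model in green cover", {
  cfg <- synthetic_config(seed = 5,
                          yield_model = list(intercept = 1.41, slope = 6.46,
                                             noise_sd = 0))
  des <- generate_design(cfg)
  tr <- generate_fractions(des, cfg)
  y <- generate_yields(des, tr, cfg)
  expect_equal(y$design$gy, 1.41 + 6.46 * tr$green, tolerance = 1e-12)
  expect_equal(y$truth$gy_noiseless, y$design$gy, tolerance = 1e-12)
  # null model: slope 0 puts every plot at the intercept
  cfg0 <- synthetic_config(seed = 5,
                           yield_model = list(intercept = 3, slope = 0, noise_sd = 0))
  y0 <- generate_yields(des, generate_fractions(des, cfg0), cfg0)
  expect_true(all(y0$design$gy == 3))
  expect_error(synthetic_config(yield_model = list(intercept = 1, slope = 1,
                                                   noise_sd = -1)), "sd")
})

test_that("a fixed master seed reproduces the trial byte for byte", {
  cfg <- synthetic_config(seed = 99, image_size = c(8, 8), ms_size = c(4, 4),
                          thermal = list(morning = c(green = 17, senescent = 20, soil = 24),
                                         afternoon = c(green = 11.5, senescent = 13, soil = 16),
                                         noise_sd = 0.3, size = c(4, 4)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  t1 <- generate_trial(cfg, out_dir = d1)
  t2 <- generate_trial(cfg, out_dir = d2)
  expect_identical(t1$design, t2$design)
  expect_identical(t1$truth, t2$truth)
  expect_identical(t1$images, t2$images)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_true(all(unname(h1) == unname(h2)))
  expect_true(all(c("design.csv", "truth.json", "manifest.json") %in% f1))
})

test_that("written artifacts read back into consistent plot data", {
  cfg <- synthetic_config(seed = 3, image_size = c(8, 8), ms_size = c(4, 4),
                          thermal = list(morning = c(green = 17, senescent = 20, soil = 24),
                                         afternoon = c(green = 11.5, senescent = 13, soil = 16),
                                         noise_sd = 0.1, size = c(4, 4)))
  dir <- withr::local_tempdir()
  trial <- generate_trial(cfg, out_dir = dir)
  id <- trial$design$plot_id[1]
  img <- read_plot_image(file.path(dir, "plots", paste0(id, "_rgb.png")))
  expect_identical(round(img), round(trial$images[[id]]))
  st <- read_reflectance_stack(file.path(dir, "plots", paste0(id, "_ms.tif")))
  expect_equal(mean(st$bands[["840"]]), mean(trial$stacks[[id]]$bands[["840"]]),
               tolerance = 1e-4)
  tm <- read_thermal_raster(file.path(dir, "plots", paste0(id, "_thermal_morning.tif")))
  expect_equal(tm, trial$thermal_morning[[id]], tolerance = 0.01)
})

test_that("the full pipeline recovers the generative yield model", {
  cfg <- synthetic_config(seed = 11, image_size = c(24, 24), ms_size = c(4, 4),
                          thermal = list(morning = c(green = 17, senescent = 20, soil = 24),
                                         afternoon = c(green = 11.5, senescent = 13, soil = 16),
                                         noise_sd = 0.3, size = c(4, 4)))
  trial <- generate_trial(cfg)
  it <- trial_index_table(trial)
  # GGA tracks true green cover through image generation + classification
  expect_lt(max(abs(it$gga - trial$truth$green)), 0.05)
  set.seed(12)
  for (k in 1:4) it[[paste0("noise", k)]] <- rnorm(nrow(it))
  fit <- stepwise_select(it, "gy", c("gga", paste0("noise", 1:4)))
  expect_true("gga" %in% fit$predictors)
  expect_equal(unname(fit$coefficients["gga"]), cfg$yield_model$slope,
               tolerance = 0.15 * cfg$yield_model$slope)
  expect_gt(fit$r2, 0.7)
})
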