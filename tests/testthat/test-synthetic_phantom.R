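test_that("phantom_spec validates its stated world", {
  expect_error(phantom_spec(compartments = list(
    bg = list(shape = "background", hu = 5000))), "HU values")
  expect_error(phantom_spec(noise_sd_ref = -1))
  expect_s3_class(phantom_spec(), "phantom_spec")
})

test_that("edge images follow the logistic model exactly and record ground truth", {
  spec <- small_spec(noise_sd_ref = 0)
  e <- generate_edge_image(spec, theta0 = 30, theta1 = 1.2)
  expect_equal(e$truth$steepness, abs(1.2 * 840 / 4))
  # every row equals the logistic profile, noiselessly
  l <- (0:127) * spec$spacing
  expect_equal(e$image$pixels[64, ], logistic_model(l, 30, 1.2, -800, 40))

  fit <- fit_logistic(extract_profile(e$image, profile_line(10, 64, 110, 64)))
  expect_equal(steepness_from_fit(fit), e$truth$steepness, tolerance = 1e-4)

  # rotating the orientation by 90 degrees leaves recovered steepness unchanged
  ev <- generate_edge_image(spec, 30, 1.2, orientation = "horizontal")
  fitv <- fit_logistic(extract_profile(ev$image, profile_line(64, 10, 64, 110)))
  expect_equal(steepness_from_fit(fitv), steepness_from_fit(fit), tolerance = 1e-6)
})

test_that("noisy edge recovery is unbiased within 5 % across seeds", {
  st <- vapply(1:100, function(seed) {
    spec <- small_spec(noise_sd_ref = 20, seed = seed)
    e <- generate_edge_image(spec, theta0 = 30, theta1 = 1.2)
    steepness_from_fit(
      fit_logistic(extract_profile(e$image, profile_line(10, 64, 110, 64))))
  }, 0)
  expect_lt(abs(median(st) - 252) / 252, 0.05)
})

test_that("phantom slices: compartments, z-order, noise injection, blur limit", {
  spec <- phantom_spec(noise_sd_ref = 0, seed = 2)
  sl <- generate_phantom_slice(spec)
  img <- sl$image
  expect_equal(dim(img), c(512L, 512L))
  # noiseless compartment interiors are constant at the nominal HU
  for (nm in c("trachea", "liver", "air")) {
    st <- roi_stats(img, default_rois(spec)[[nm]])
    nominal <- c(trachea = -1000, liver = 60, air = -1000)[[nm]]
    expect_equal(st$mean_hu, nominal, tolerance = 1e-3)
    expect_lt(st$sd_hu, 1)  # far from edges, blur leaves interiors flat
  }
  # trachea (drawn after the lungs) wins where shapes could overlap: its
  # centre pixel is air even though it sits between the lung fields
  expect_equal(unname(img$pixels[210 + 1, 256 + 1]), -1000, tolerance = 1e-6)

  # step edges (blur 0): the sampled profile jumps within one pixel
  step <- phantom_spec(noise_sd_ref = 0, edge_blur_sigma = 0, recon_blur_ref = 0)
  ssl <- generate_phantom_slice(step)
  expect_true(all(unique(as.vector(ssl$image$pixels)) %in% c(-1000, -800, 40, 60)))
})

test_that("default grid is in bounds, 39 x 12, and crosses lung-pleura edges", {
  spec <- phantom_spec(noise_sd_ref = 0)
  grid <- default_profile_grid(spec)
  expect_length(grid, 468L)
  labs <- table(vapply(grid, `[[`, "", "level"))
  expect_equal(as.integer(labs[c("apical", "mid", "basal")]), rep(156L, 3))

  sl <- generate_phantom_slice(spec)
  for (line in grid) {
    expect_true(all(c(line$x_begin, line$x_end) >= 0 &
                    c(line$x_begin, line$x_end) < 512))
    expect_true(all(c(line$y_begin, line$y_end) >= 0 &
                    c(line$y_begin, line$y_end) < 512))
  }
  # every profile spans the lung (-800) to soft-tissue (+40) transition
  hu_begin <- vapply(grid, function(g) unname(sl$image$pixels[g$y_begin + 1, g$x_begin + 1]), 0)
  hu_end <- vapply(grid, function(g) unname(sl$image$pixels[g$y_end + 1, g$x_end + 1]), 0)
  expect_true(all(hu_begin < -600))
  expect_true(all(hu_end > -150))
})

test_that("dose series: 1/sqrt(mAs) noise law, 13 levels, bit-identical reruns", {
  spec <- small_spec(noise_sd_ref = 40)
  recs <- list(scan_record(100, 10, 0.28), scan_record(100, 40, 0.28))
  series <- generate_dose_series(spec, recs)
  # quadrupling mAs halves the injected noise SD
  expect_equal(series[[1]]$truth$noise_sd / series[[2]]$truth$noise_sd, 2)

  levels <- default_dose_levels("adult")
  expect_length(levels, 13L)
  expect_equal(levels[[1]]$kvp, 140)
  expect_equal(levels[[13]]$ctdi_vol, 0.04)
  expect_equal(vapply(levels, function(r) compute_mas(r$ma, r$rotation_time), 0)[1:2],
               c(14, 11.2))

  rerun <- generate_dose_series(spec, recs)
  expect_identical(series[[2]]$image$pixels, rerun[[2]]$image$pixels)
  # slices within a stack and across levels differ
  st <- generate_phantom_stack(spec, n_slices = 2)
  expect_false(identical(st$images[[1]]$pixels, st$images[[2]]$pixels))
})

test_that("per-kVp noise multipliers apply on top of the mAs law", {
  spec <- small_spec(noise_sd_ref = 30,
                     kvp_noise_mult = c("70" = 1.5, "140" = 0.9))
  expect_equal(generate_phantom_slice(spec, mas = 14, kvp = 70)$truth$noise_sd,
               45)
  expect_equal(generate_phantom_slice(spec, mas = 14, kvp = 100)$truth$noise_sd,
               30)  # unlisted kVp: multiplier 1
})

test_that("ground-truth edge steepness comes from the noiseless blurred image", {
  spec <- phantom_spec(noise_sd_ref = 25, seed = 3)
  grid <- default_profile_grid(spec)
  sl <- generate_phantom_slice(spec, grid = grid)
  expect_length(sl$truth$edge_steepness, 468L)
  expect_true(is.finite(sl$truth$median_steepness))
  # the noisy measurement tracks the noiseless ground truth closely at 25 HU
  scan <- measure_scan(sl$image, grid)
  expect_lt(abs(scan$median_steepness - sl$truth$median_steepness) /
            sl$truth$median_steepness, 0.05)
})

test_that("images round-trip through the plain-text format", {
  spec <- small_spec()
  sl <- generate_phantom_slice(spec, mas = 5.6)
  stem <- file.path(withr::local_tempdir(), "slice")
  write_ct_image(sl$image, stem)
  back <- read_ct_image(stem)
  expect_equal(back$pixels, sl$image$pixels, tolerance = 1e-12)
  expect_equal(back$spacing_x, sl$image$spacing_x)
  expect_equal(back$metadata$mas, 5.6)
})
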