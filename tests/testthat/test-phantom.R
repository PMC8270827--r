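test_that("a noise-free unblurred UA phantom is flat at the target attenuation", {
  ph <- generate_phantom(stone_phantom_spec("UA", peak_hu = 550,
                                            diameter_mm = 8,
                                            blur_sigma_mm = 0, noise_sd_hu = 0))
  expect_equal(max(ph$volume$values), 550)
  centre <- ph$mask$seed
  expect_equal(ph$volume$values[centre[1], centre[2], centre[3]], 550)
  # interior voxels of the flat profile have zero Laplacian
  expect_equal(peakstone:::point_laplacian(ph$volume, centre), 0)
  f <- extract_features(ph$volume, ph$mask)
  expect_equal(f$max_hu, 550)
})

test_that("identical spec and seed give bit-identical phantoms", {
  spec <- stone_phantom_spec("non-UA", peak_hu = 1300, diameter_mm = 7,
                             seed = 421)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$mask$membership, b$mask$membership)
  c <- generate_phantom(stone_phantom_spec("non-UA", peak_hu = 1300,
                                           diameter_mm = 7, seed = 422))
  expect_false(identical(a$volume$values, c$volume$values))
})

test_that("the imaged non-UA core matches a dense numeric convolution of the intrinsic core", {
  peak <- 1400; edge <- 0.5 * peak; tip <- 1.2; s <- 0.6
  ph <- generate_phantom(stone_phantom_spec("non-UA", peak_hu = peak,
                                            diameter_mm = 10,
                                            blur_sigma_mm = s, noise_sd_hu = 0,
                                            tip_width_mm = tip))
  f <- extract_features(ph$volume, ph$mask)
  # oracle: the intrinsic (pre-blur) Gaussian core implied by the imaged
  # model, convolved numerically with the total smoothing kernel (PSF plus
  # voxel aperture) on a dense 0.01 mm grid; by separability the 3D peak
  # attenuates by the cubed 1D factor
  s <- sqrt(s^2 + 1 / 12)
  w2 <- tip^2 + s^2
  a0 <- (peak - edge) * (w2 / tip^2)^1.5  # intrinsic core amplitude
  h <- 0.01
  x <- seq(-8, 8, by = h)
  g <- exp(-x^2 / (2 * s^2)); g <- g / sum(g)
  core <- a0 * exp(-x^2 / (2 * tip^2))
  conv1 <- stats::convolve(core, rev(g), type = "open")
  att1 <- max(conv1) / a0
  expect_equal(f$max_hu, edge + a0 * att1^3, tolerance = 0.1)
  # off-centre imaged value 1 mm along the row axis (plateau fully inside)
  xx <- seq(-16, 16, by = h)
  c_at_1 <- conv1[which.min(abs(xx - 1))] / a0
  ctr <- ph$mask$seed
  got <- ph$volume$values[ctr[1], ctr[2] + 1L, ctr[3]]
  expect_equal(got, edge + a0 * c_at_1 * att1^2, tolerance = 0.1)
})

test_that("surrogate training features match the target moments and ranges", {
  spec <- feature_distribution_spec(n_ua = 10000, n_nonua = 10000, seed = 91)
  ts <- generate_training_set(spec)
  ua <- ts[ts$label == "UA", ]
  nu <- ts[ts$label == "non-UA", ]
  expect_equal(nrow(ua), 10000)
  # UA maxHU: mean 537 within 10 HU, all draws inside [223, 794]
  expect_lt(abs(mean(ua$max_hu) - 537), 10)
  expect_true(all(ua$max_hu >= 223 & ua$max_hu <= 794))
  expect_true(all(ua$pp_lapl >= 47 & ua$pp_lapl <= 212))
  expect_true(all(nu$max_hu >= 536 & nu$max_hu <= 1796))
  expect_true(all(nu$pp_lapl >= 51 & nu$pp_lapl <= 546))
  # the asymmetric truncation shifts the non-UA maxHU mean down to ~1264
  expect_lt(abs(mean(nu$max_hu) - 1264), 12)
})

test_that("zero correlation yields an uncorrelated sample", {
  spec <- feature_distribution_spec(n_ua = 10000, n_nonua = 2,
                                    correlation = 0, seed = 92)
  ts <- generate_training_set(spec)
  ua <- ts[ts$label == "UA", ]
  expect_lt(abs(stats::cor(ua$max_hu, ua$pp_lapl)), 0.05)
})

test_that("one stone per class still forms a valid training set", {
  ts <- generate_training_set(feature_distribution_spec(n_ua = 1, n_nonua = 1,
                                                        seed = 93))
  expect_s3_class(ts, "training_set")
  expect_setequal(ts$label, c("UA", "non-UA"))
})

test_that("generated UA features fall inside the UA cutoff rectangle almost surely", {
  ts <- generate_training_set(feature_distribution_spec(n_ua = 5000,
                                                        n_nonua = 2, seed = 94))
  ua <- ts[ts$label == "UA", ]
  inside <- ua$max_hu < 1000 & ua$pp_lapl < 195
  expect_gte(mean(inside), 0.95)
})

test_that("infeasible distribution specs are rejected", {
  bad <- stone_reference_moments()$ua[c("max_hu", "pp_lapl")]
  bad$max_hu$range <- c(794, 223)
  expect_error(feature_distribution_spec(ua = bad), "empty")
  bad$max_hu$range <- c(900, 1000)  # excludes the mean
  expect_error(feature_distribution_spec(ua = bad), "contain the mean")
})

test_that("simulated cohorts have the requested size, labels and determinism", {
  coh <- simulate_cohort(5, 9, seed = 3101)
  expect_equal(nrow(coh), 14L)
  expect_equal(sum(coh$reference == "UA"), 5L)
  expect_equal(sum(coh$reference == "non-UA"), 9L)
  coh2 <- simulate_cohort(5, 9, seed = 3101)
  expect_identical(coh, coh2)
  expect_error(simulate_cohort(0, 10, seed = 1), ">= 1")
})

test_that("phantom specs enforce the size inclusion range and attenuation ordering", {
  expect_error(stone_phantom_spec("UA", 500, diameter_mm = 2), "3-20")
  expect_error(stone_phantom_spec("UA", 500, diameter_mm = 25), "3-20")
  expect_error(stone_phantom_spec("UA", 20, diameter_mm = 8, background_hu = 30),
               "exceed")
})
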