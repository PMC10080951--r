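test_that("DoG receptive fields keep the center-surround ratios and scale with spacing", {
  dog <- dog_params(0.1075)
  expect_equal(dog$Ks / dog$Kc, 0.01)
  expect_equal(dog$sigma_s / dog$sigma_c, 6.7)
  # center radius (value Kc/e) equals the intercell spacing within 1%
  r_e <- dog$sigma_c * sqrt(2)
  expect_equal(r_e, 0.1075, tolerance = 0.01)
  # center dominates: surround/center volume = 0.01 * 6.7^2 = 0.449 < 1
  expect_equal((dog$Ks * dog$sigma_s^2) / (dog$Kc * dog$sigma_c^2), 0.01 * 6.7^2,
               tolerance = 1e-12)
  expect_lt(0.01 * 6.7^2, 1)  # surround never cancels the center
  kern <- perisum:::dog_lattice_kernel(dog, 0.1075)
  expect_gt(kern$norm, 0)
})

test_that("cone sampling is pointwise, linear in contrast, and coverage-checked", {
  m <- build_hex_mosaic(100, 2)
  img <- uniform_image(m)
  expect_equal(cone_response(img, m), rep(1, nrow(m$positions)))
  img0 <- uniform_image(m, 0)
  expect_equal(cone_response(img0, m), rep(0, nrow(m$positions)))
  disc <- make_stimulus_image(0.86, 0.02, extent = m$extent + 4 * m$spacing)
  half <- disc; half$pixels <- disc$pixels / 2
  expect_equal(cone_response(half, m), cone_response(disc, m) / 2)
  small <- make_stimulus_image(0.86, 0.02, extent = 1)
  expect_error(cone_response(small, m), "outside the image")
  expect_equal(sum(cone_response(small, m, outside = 0) == 0) > 0, TRUE)
})

test_that("grid convolution pooling equals the brute-force per-cell oracle", {
  m <- build_hex_mosaic(115.47, 2.4, phase_seed = 2)  # ~600 cells
  dog <- dog_params(m$spacing)
  img <- make_stimulus_image(0.43, 0.01, extent = 1)
  cv <- cone_response(img, m, outside = 0)
  grid <- rgc_responses(cv, m, dog = dog, convergence = 1.7, method = "grid")
  direct <- rgc_responses(cv, m, dog = dog, convergence = 1.7, method = "direct")
  oracle <- brute_force_pool(cv, m, m, dog, convergence = 1.7)
  expect_lt(max(abs(grid$values - oracle)), 1e-9)
  expect_lt(max(abs(direct$values - oracle)), 1e-9)
  # convergence is an exact multiplicative weight
  c1 <- rgc_responses(cv, m, dog = dog, convergence = 1, method = "grid")
  expect_equal(grid$values, 1.7 * c1$values)
  expect_error(rgc_responses(cv, m, dog = dog_params(m$spacing, truncate = 2)),
               "truncated")
})

test_that("interior cells respond uniformly to uniform input and pooling is linear", {
  # interior = cells whose full 4-sigma_s surround lies inside the mosaic
  m <- build_hex_mosaic(450, 3)
  dog <- dog_params(m$spacing)
  f <- rgc_responses(cone_response(uniform_image(m), m), m, dog = dog)
  interior <- abs(m$positions[, 1]) < 0.5 & abs(m$positions[, 2]) < 0.5
  expect_equal(diff(range(f$values[interior])), 0, tolerance = 1e-3)
  expect_equal(mean(f$values[interior]), 1, tolerance = 1e-3)
  # additivity of responses to summed images (signed mode linearity)
  a <- make_stimulus_image(0.43, 0.015, extent = 3.2)
  b <- make_stimulus_image(0.86, 0.015, extent = 3.2)
  ab <- a; ab$pixels <- a$pixels + b$pixels
  ra <- rgc_responses(cone_response(a, m, outside = 0), m, dog = dog)$values
  rb <- rgc_responses(cone_response(b, m, outside = 0), m, dog = dog)$values
  rab <- rgc_responses(cone_response(ab, m, outside = 0), m, dog = dog)$values
  expect_lt(max(abs(rab - (ra + rb))), 1e-9)
})

test_that("signed and absolute total input behave as documented", {
  m <- build_hex_mosaic(100, 3, phase_seed = 1)
  dog <- dog_params(m$spacing)
  img <- make_stimulus_image(0.43, 0.01, extent = 0.6)
  f <- rgc_responses(cone_response(img, m, outside = 0), m, dog = dog)
  expect_gte(spatial_input(f, "absolute"), spatial_input(f, "signed"))
  expect_true(any(f$values < 0))  # surround-inhibited ring exists
  pos_only <- f; pos_only$values <- abs(f$values)
  expect_equal(spatial_input(pos_only, "signed"), spatial_input(f, "absolute"))
})

test_that("a G-III disc drives ~area x density RGCs on a 100/deg2 mosaic", {
  # phase-averaged: the exactly centered lattice is a knife-edge case for
  # this size/density combination (a shell sits at 0.9998 r)
  S <- vapply(1:6, function(sd) {
    m <- build_hex_mosaic(100, 3, phase_seed = sd)
    img <- make_stimulus_image(0.43, 0.43 / 25, extent = 0.6)
    f <- rgc_responses(cone_response(img, m, outside = 0), m,
                       dog = dog_params(m$spacing))
    spatial_input(f)
  }, numeric(1))
  expect_equal(mean(S), 14.5, tolerance = 0.1)
})

test_that("signed input is blur-insensitive; absolute input is not", {
  # well-sampled regime: the stimulus spans many cells, so the sharp-disc
  # point-sample sum is itself accurate and only the optics effect remains
  opt <- optics_params(pupil_mm = 5)
  dog <- dog_params(hex_spacing(2000))
  m <- build_hex_mosaic(2000, 1.8)
  img <- make_stimulus_image(0.43, 0.005, extent = 1.9)
  bl <- blur_stimulus(img, opt)
  f0 <- rgc_responses(cone_response(img, m, outside = 0), m, dog = dog)
  f1 <- rgc_responses(cone_response(bl, m, outside = 0), m, dog = dog)
  signed_shift <- log10(spatial_input(f1) / spatial_input(f0))
  abs_shift <- log10(spatial_input(f1, "absolute") / spatial_input(f0, "absolute"))
  expect_equal(10^signed_shift, 1, tolerance = 0.02)
  # absolute summation greatly amplifies the optics effect
  expect_gt(abs(abs_shift), 10 * abs(signed_shift))
  expect_gt(abs(abs_shift), 0.02)
})

test_that("the area-input map is linear in density, consistent with geometry, and invertible", {
  ctx1 <- retinal_context(100, convergence = 2)
  ctx2 <- retinal_context(200, convergence = 2)
  expect_equal(area_to_input(area_input_map(ctx2, method = "product"), 0.2),
               2 * area_to_input(area_input_map(ctx1, method = "product"), 0.2))
  # G-V / G-I input ratio approaches the geometric area ratio on a
  # well-resolved mosaic
  dense <- area_input_map(retinal_context(2000),
                          areas = 10^seq(log10(0.005), log10(2.5), length.out = 20),
                          method = "mosaic", phase_seed = 1)
  ratio <- area_to_input(dense, goldmann_area("V")) / area_to_input(dense, goldmann_area("I"))
  expect_equal(ratio, (1.72 / 0.10)^2, tolerance = 0.05)
  # round-trip inversion over the ladder
  map <- area_input_map(retinal_context(100), areas = 10^seq(-1, 0.4, by = 0.1),
                        method = "mosaic")
  back <- input_to_area(map, area_to_input(map, map$areas))
  expect_lt(max(abs(log10(back) - log10(map$areas))), 0.01)
  expect_warning(area_to_input(map, 10^(-1.5)), "extrapolated")
  expect_error(area_to_input(map, 10^(-2.5)), "outside")
})
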