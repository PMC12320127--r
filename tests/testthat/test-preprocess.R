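test_that("FWHM-to-sigma conversion matches the closed form", {
  expect_equal(petmil:::fwhm_to_sigma(8, 2), 8 / (2 * sqrt(2 * log(2))) / 2,
               tolerance = 1e-12)
  expect_equal(petmil:::fwhm_to_sigma(8, 2), 1.69864, tolerance = 1e-4)
})

test_that("smoothing a unit impulse reproduces the sampled Gaussian kernel", {
  vol <- array(0, c(21, 21, 21))
  vol[11, 11, 11] <- 1
  sm <- gaussian_smooth(vol, fwhm_mm = 8, voxel_mm = 2)
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 2
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  # analytic separable impulse response, away from boundaries
  idx <- (11 - r):(11 + r)
  expected <- outer(outer(k, k), k)
  expect_equal(sm[idx, idx, idx], expected, tolerance = 1e-6,
               ignore_attr = TRUE)
  # mass conservation for interior-supported input
  expect_equal(sum(sm), 1, tolerance = 1e-9)
})

test_that("smoothing limits and errors behave", {
  set.seed(1)
  vol <- array(runif(10 * 12 * 8), c(10, 12, 8))
  out <- gaussian_smooth(vol, fwhm_mm = 1e-6, voxel_mm = 2)
  expect_equal(out, vol, tolerance = 1e-9)
  expect_error(gaussian_smooth(vol, fwhm_mm = 0), "positive")
  expect_equal(gaussian_smooth(array(3, c(6, 6, 6)), 8),
               array(3, c(6, 6, 6)), tolerance = 1e-12)
})

test_that("bag extraction yields K ordered standardized slices", {
  cohort <- generate_cohort(c(HC = 1), master_seed = 12L)
  vol <- render_volume(cohort$specs[[1]], cohort$atlas)
  bag <- extract_bag(vol, cohort$manifest[1, ], target_size = c(224, 224))
  expect_s3_class(bag, "slice_bag")
  expect_equal(bag$K, 79L)
  expect_equal(dim(bag$slices), c(224 * 224, 79))
  expect_true(all(is.finite(bag$slices)))
  expect_equal(bag$label, "HC")

  # order preservation: plant a marker block in one axial plane and find it
  v <- array(0, c(79, 95, 79))
  v[30:50, 38:58, 24] <- 100
  bag2 <- extract_bag(v, target_size = c(32, 32), standardize = "none")
  expect_equal(unname(which.max(colSums(bag2$slices))), 24L)
  expect_true(all(bag2$slices[, -24] == 0))

  expect_error(extract_bag(array(0, c(10, 10, 10))), "grid")
  v[1] <- NaN
  expect_error(extract_bag(v), "finite")
})

test_that("standardization modes behave as documented", {
  v <- array(5, c(79, 95, 79))
  # constant volume: volmean scaling maps to all ones
  bag <- extract_bag(v, target_size = c(32, 32), standardize = "volmean")
  expect_equal(unique(as.vector(bag$slices)), 1)
  # z-scoring maps constant (zero-variance) slices to all zeros
  bagz <- extract_bag(v, target_size = c(32, 32), standardize = "zscore")
  expect_true(all(bagz$slices == 0))
  # resizing a constant slice is constant before standardization
  bagn <- extract_bag(v, target_size = c(32, 32), standardize = "none")
  expect_equal(unique(as.vector(bagn$slices)), 5)
  # reference-region scaling removes a global gain exactly
  set.seed(2)
  base <- baseline_field()
  mask <- reference_region_mask()
  b1 <- extract_bag(base, target_size = c(32, 32), norm_mask = mask)
  b2 <- extract_bag(base * 1.3, target_size = c(32, 32), norm_mask = mask)
  expect_equal(b1$slices, b2$slices, tolerance = 1e-12)
})

test_that("reference-image centering removes the cohort-mean anatomy", {
  fx <- tiny_cohort_bags()
  tr <- fx$raw_bags[fx$split == "train"]
  ref <- reference_image(tr)
  expect_equal(dim(ref), dim(tr[[1]]$slices))
  centered <- center_bags(tr, ref)
  resid <- Reduce(`+`, lapply(centered, function(b) b$slices)) / length(tr)
  expect_lt(max(abs(resid)), 1e-10)
  expect_error(center_bags(list(random_bag(K = 3, size = c(8, 8))), ref),
               "mismatch")
})

test_that("cohort_bags preserves slice count and subject order", {
  fx <- tiny_cohort_bags()
  expect_identical(names(fx$bags), fx$cohort$manifest$subject_id)
  expect_true(all(vapply(fx$bags, function(b) b$K, integer(1)) == 79L))
  expect_true(all(vapply(fx$bags, function(b) ncol(b$slices), integer(1)) == 79L))
})
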