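test_that("region atlas has the expected regions at plausible positions", {
  atlas <- default_region_atlas()
  expect_setequal(names(atlas),
                  c("MTL_left", "MTL_right", "BG_left", "BG_right",
                    "OCCIPITAL"))
  for (r in atlas) {
    expect_true(any(r$voxel_mask))
    # recorded slice_range matches the mask's axial extent (0-based)
    zs <- which(apply(r$voxel_mask, 3, any)) - 1L
    expect_identical(r$slice_range, c(min(zs), max(zs)))
  }
  # MTL and BG in the inferior-to-middle third of the slice axis
  expect_true(all(atlas$MTL_left$slice_range >= 0 &
                    atlas$MTL_left$slice_range <= 52))
  expect_true(all(atlas$BG_left$slice_range <= 52))
  # occipital posterior: mask centroid in the posterior half of y
  occ_y <- which(apply(atlas$OCCIPITAL$voxel_mask, 2, any))
  expect_gt(min(occ_y), 95 / 2)
  # masks are inside the brain and mutually disjoint
  msum <- Reduce(`+`, lapply(atlas, function(r) r$voxel_mask * 1))
  expect_lte(max(msum), 1)
  base <- baseline_field()
  for (r in atlas) expect_true(all(base[r$voxel_mask] > 0))
})

test_that("subtype signatures encode the regional hypo/hyper patterns", {
  s <- subtype_signature("HC")
  expect_true(all(s == 1))
  expect_true(all(subtype_signature("DC") == 1))

  s <- subtype_signature("GAD65")
  expect_lt(s["MTL_right"], 1)
  expect_true(all(s[setdiff(names(s), "MTL_right")] == 1))

  s <- subtype_signature("LGI1")
  expect_true(all(s[c("MTL_left", "MTL_right", "BG_left", "BG_right")] > 1))

  s <- subtype_signature("NMDAR")
  expect_true(all(s[c("MTL_left", "MTL_right", "OCCIPITAL")] < 1))
  expect_true(all(s[c("BG_left", "BG_right")] > 1))

  s <- subtype_signature("GABAB")
  expect_true(all(s[c("MTL_left", "MTL_right")] < 1))
  expect_true(all(s[c("BG_left", "BG_right")] > 1))

  expect_error(subtype_signature("XYZ"))
})

test_that("rendering is deterministic and reduces to the baseline for HC", {
  atlas <- default_region_atlas()
  hc <- phantom_spec("S1", "HC", noise_sd = 0, seed = 5L)
  v <- render_volume(hc, atlas)
  expect_identical(dim(v$intensities), c(79L, 95L, 79L))
  expect_equal(v$intensities, baseline_field())

  sp <- phantom_spec("S2", "LGI1", noise_sd = 4, seed = 11L)
  v1 <- render_volume(sp, atlas)
  v2 <- render_volume(sp, atlas)
  expect_identical(v1$intensities, v2$intensities)
  expect_true(all(v1$intensities >= 0) && all(is.finite(v1$intensities)))
})

test_that("planted effects multiply masked means exactly (noise-free)", {
  atlas <- default_region_atlas()
  base <- baseline_field()
  sp <- phantom_spec("S1", "LGI1",
                     region_effects = subtype_signature("LGI1", hyper = 1.5),
                     noise_sd = 0, seed = 1L)
  v <- render_volume(sp, atlas)$intensities
  for (nm in names(atlas)) {
    m <- atlas[[nm]]$voxel_mask
    f <- sp$region_effects[[nm]]
    expect_equal(mean(v[m]) / mean(base[m]), f, tolerance = 1e-9)
  }
})

test_that("site gain/offset and noise follow the stated composition order", {
  atlas <- default_region_atlas()
  sp <- phantom_spec("S1", "HC", noise_sd = 0, site_gain = 1.1,
                     site_offset = 3, seed = 2L)
  v <- render_volume(sp, atlas)$intensities
  expect_equal(v, baseline_field() * 1.1 + 3, tolerance = 1e-12)
})

test_that("separability increases monotonically with effect size", {
  atlas <- default_region_atlas()
  m <- atlas$BG_left$voxel_mask
  tstats <- vapply(c(1.15, 1.4, 1.8), function(f) {
    hc <- vapply(1:8, function(i) {
      mean(render_volume(phantom_spec(paste0("H", i), "HC", noise_sd = 8,
                                      seed = 100 + i), atlas)$intensities[m])
    }, numeric(1))
    ae <- vapply(1:8, function(i) {
      sp <- phantom_spec(paste0("A", i), "LGI1",
                         region_effects = subtype_signature("LGI1", hyper = f),
                         noise_sd = 8, seed = 200 + i)
      mean(render_volume(sp, atlas)$intensities[m])
    }, numeric(1))
    unname(stats::t.test(ae, hc)$statistic)
  }, numeric(1))
  expect_true(all(diff(tstats) > 0))
})

test_that("cohort generation honors counts, site plan and split fractions", {
  cohort <- generate_cohort(c(HC = 10), site_plan = c(A = 1),
                            master_seed = 3L)
  expect_equal(nrow(cohort$manifest), 10)
  expect_true(all(cohort$manifest$class == "HC"))

  cohort <- generate_cohort(c(HC = 60, LGI1 = 40),
                            site_plan = c(A = 0.7, B = 0.3),
                            master_seed = 4L)
  expect_equal(sum(cohort$manifest$site == "A"), 70)
  expect_equal(sum(cohort$manifest$site == "B"), 30)
  # stratified 70/30 split per class (round(0.7 * n_c))
  for (cl in c("HC", "LGI1")) {
    n_tr <- sum(cohort$manifest$split == "train" &
                  cohort$manifest$class == cl)
    n_cl <- sum(cohort$manifest$class == cl)
    expect_equal(n_tr, round(0.7 * n_cl))
  }
  expect_error(generate_cohort(c(HC = 0)), "empty")
  expect_error(generate_cohort(c(HC = 4), site_plan = c(A = 0.5, B = 0.4)),
               "sum to 1")
})

test_that("cohort ages follow the class covariate models", {
  cohort <- generate_cohort(c(NMDAR = 50, LGI1 = 50, GABAB = 50, GAD65 = 50),
                            master_seed = 6L)
  ages <- cohort$manifest$age
  expect_true(all(ages >= 6 & ages <= 85))
  # sample mean within 3 standard errors of the AE model mean at n = 200
  se <- 16.21 / sqrt(200)
  expect_lt(abs(mean(ages) - 48.51), 3 * se)
})

test_that("external sites get shifted scanners and the external split", {
  cohort <- generate_cohort(c(HC = 20, LGI1 = 20),
                            site_plan = c(A = 0.5, X = 0.5),
                            external_sites = "X", master_seed = 8L)
  man <- cohort$manifest
  expect_true(all(man$split[man$site == "X"] == "external"))
  expect_false(any(man$split[man$site == "A"] == "external"))
  gains <- vapply(cohort$specs, function(s) s$site_gain, numeric(1))
  sites <- vapply(cohort$specs, function(s) s$site_id, character(1))
  expect_true(all(gains[sites == "A"] == 1))
  expect_true(all(gains[sites == "X"] != 1))
})

test_that("cohort generation writes NIfTI volumes and a manifest", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(c(HC = 2), master_seed = 9L, dir = dir)
  files <- list.files(dir)
  expect_setequal(files, c("S001.nii.gz", "S002.nii.gz", "manifest.csv",
                           "generator_config.yaml"))
  gcfg <- yaml::read_yaml(file.path(dir, "generator_config.yaml"))
  expect_equal(gcfg$master_seed, 9L)
  expect_length(gcfg$subject_seeds, 2)
  v <- RNifti::readNifti(file.path(dir, "S001.nii.gz"))
  expect_identical(dim(v), c(79L, 95L, 79L))
  back <- render_volume(cohort$specs[[1]], cohort$atlas)$intensities
  expect_equal(as.array(v), back, tolerance = 1e-6, ignore_attr = TRUE)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(names(man),
                   c("subject_id", "class", "age", "sex", "site", "split"))
})
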