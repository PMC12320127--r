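# ---------------------------------------------------------------------------
# Synthetic phantom cohort: a smooth brain-shaped baseline field on the
# 79 x 95 x 79 stereotactic grid (2 mm voxels), with planted multiplicative
# regional effects, per-site gain/offset shifts and additive Gaussian noise.
# Axis convention: x (left->right, 79), y (anterior->posterior, 95),
# z (inferior->superior, 79 axial slices). Slice indices are 0-based
# inclusive everywhere they are reported.
# ---------------------------------------------------------------------------

PET_GRID <- c(79L, 95L, 79L)
AE_CLASSES <- c("NMDAR", "LGI1", "GABAB", "GAD65")
ALL_CLASSES <- c(AE_CLASSES, "HC", "DC")

.petmil_cache <- new.env(parent = emptyenv())

ellipsoid_r2 <- function(center, semi) {
  x <- (seq_len(PET_GRID[1]) - center[1]) / semi[1]
  y <- (seq_len(PET_GRID[2]) - center[2]) / semi[2]
  z <- (seq_len(PET_GRID[3]) - center[3]) / semi[3]
  outer(outer(x^2, y^2, "+"), z^2, "+")
}

brain_mask <- function() {
  if (is.null(.petmil_cache$brain_mask))
    .petmil_cache$brain_mask <- ellipsoid_r2(c(40, 48, 40), c(35, 43, 35)) <= 1
  .petmil_cache$brain_mask
}

#' Baseline phantom intensity field
#'
#' A smooth brain-shaped ellipsoid with a brighter cortical rim, in arbitrary
#' FDG-uptake units, on the fixed 79x95x79 grid. Zero outside the brain.
#'
#' @return A 79x95x79 numeric array.
#' @export
baseline_field <- function() {
  if (is.null(.petmil_cache$baseline)) {
    r <- sqrt(ellipsoid_r2(c(40, 48, 40), c(35, 43, 35)))
    f <- 100 * (0.7 + 0.5 * exp(-((r - 0.82) / 0.15)^2))
    f[r > 1] <- 0
    .petmil_cache$baseline <- f
  }
  .petmil_cache$baseline
}

region_template <- function(name, center, semi) {
  mask <- ellipsoid_r2(center, semi) <= 1 & brain_mask()
  if (!any(mask)) stop("empty region mask for ", name)
  zs <- which(apply(mask, 3, any))
  structure(
    list(name = name, voxel_mask = mask,
         slice_range = c(min(zs), max(zs)) - 1L),  # 0-based inclusive
    class = "region_template")
}

#' Default phantom region atlas
#'
#' Ellipsoidal region masks at anatomically plausible relative positions:
#' bilateral medial temporal lobe (inferior-middle slices, anterior-medial),
#' bilateral basal ganglia (middle slices, central), and occipital cortex
#' (posterior y). All masks lie inside the brain and are mutually disjoint.
#'
#' @return A named list of region templates, each with fields `name`,
#'   `voxel_mask` (logical 79x95x79 array) and `slice_range` (0-based
#'   inclusive axial index pair).
#' @export
default_region_atlas <- function() {
  if (is.null(.petmil_cache$atlas)) {
    .petmil_cache$atlas <- list(
      MTL_left  = region_template("MTL_left",  c(24, 36, 28), c(7, 9, 7)),
      MTL_right = region_template("MTL_right", c(56, 36, 28), c(7, 9, 7)),
      BG_left   = region_template("BG_left",   c(31, 54, 37), c(6, 7, 6)),
      BG_right  = region_template("BG_right",  c(48, 54, 37), c(6, 7, 6)),
      OCCIPITAL = region_template("OCCIPITAL", c(40, 78, 38), c(14, 9, 9))
    )
  }
  .petmil_cache$atlas
}

#' Subtype-specific regional metabolic signature
#'
#' Maps a class label to multiplicative regional intensity factors
#' (1 = no effect). The four autoimmune-encephalitis subtypes carry distinct
#' patterns: NMDAR shows medial-temporal and occipital hypometabolism with
#' basal-ganglia hypermetabolism; LGI1 shows medial-temporal and
#' basal-ganglia hypermetabolism; GABAB shows medial-temporal hypometabolism
#' with basal-ganglia hypermetabolism; GAD65 shows right medial-temporal
#' hypometabolism only. Healthy controls (HC) and disease controls (DC) have
#' unit factors everywhere (DC additionally receives a small global
#' multiplicative jitter at render time).
#'
#' @param class_label One of `"NMDAR"`, `"LGI1"`, `"GABAB"`, `"GAD65"`,
#'   `"HC"`, `"DC"`.
#' @param hypo,hyper Factors used for hypo-/hypermetabolic regions.
#' @return Named numeric vector of factors over the atlas regions.
#' @export
subtype_signature <- function(class_label, hypo = 0.7, hyper = 1.4) {
  regions <- c("MTL_left", "MTL_right", "BG_left", "BG_right", "OCCIPITAL")
  f <- stats::setNames(rep(1, length(regions)), regions)
  switch(match.arg(class_label, ALL_CLASSES),
    NMDAR = { f[c("MTL_left", "MTL_right", "OCCIPITAL")] <- hypo
              f[c("BG_left", "BG_right")] <- hyper },
    LGI1  = { f[c("MTL_left", "MTL_right", "BG_left", "BG_right")] <- hyper },
    GABAB = { f[c("MTL_left", "MTL_right")] <- hypo
              f[c("BG_left", "BG_right")] <- hyper },
    GAD65 = { f["MTL_right"] <- hypo },
    HC    = { },
    DC    = { })
  f
}

#' Construct a phantom subject specification
#'
#' @param subject_id Subject identifier.
#' @param class_label Class label (see [subtype_signature()]).
#' @param region_effects Named factor map; defaults to the class signature.
#' @param noise_sd Additive Gaussian noise SD in intensity units.
#' @param site_id Site label.
#' @param site_gain,site_offset Multiplicative gain / additive offset applied
#'   to the whole volume (scanner shift).
#' @param age_years,sex Covariates; age in `[6, 85]`, sex `"M"` or `"F"`.
#' @param global_sd SD of a global multiplicative jitter (used for DC).
#' @param seed Integer seed making the rendered volume deterministic.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(subject_id, class_label,
                         region_effects = subtype_signature(class_label),
                         noise_sd = 0, site_id = "A",
                         site_gain = 1, site_offset = 0,
                         age_years = 50, sex = "M",
                         global_sd = if (class_label == "DC") 0.05 else 0,
                         seed = 0L) {
  class_label <- match.arg(class_label, ALL_CLASSES)
  stopifnot(noise_sd >= 0, site_gain > 0, all(region_effects > 0),
            age_years >= 6, age_years <= 85, sex %in% c("M", "F"))
  if (class_label == "HC" && any(region_effects != 1))
    stop("HC specs must have unit region effects")
  structure(list(subject_id = subject_id, class_label = class_label,
                 region_effects = region_effects, noise_sd = noise_sd,
                 site_id = site_id, site_gain = site_gain,
                 site_offset = site_offset, age_years = age_years,
                 sex = sex, global_sd = global_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Render a phantom volume from its specification
#'
#' The baseline field is multiplied inside each region mask by its factor,
#' scaled by the site gain and shifted by the site offset, then Gaussian
#' noise is added and intensities are clipped at zero. Rendering is
#' deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param atlas Region atlas from [default_region_atlas()].
#' @return A list with `intensities` (79x95x79 array) and `spec`.
#' @export
render_volume <- function(spec, atlas = default_region_atlas()) {
  missing <- setdiff(names(spec$region_effects), names(atlas))
  if (length(missing))
    stop("atlas lacks regions: ", paste(missing, collapse = ", "))
  vol <- baseline_field()
  for (nm in names(spec$region_effects)) {
    f <- spec$region_effects[[nm]]
    if (f != 1) {
      m <- atlas[[nm]]$voxel_mask
      if (!all(dim(m) == dim(vol))) stop("atlas/grid shape mismatch")
      vol[m] <- vol[m] * f
    }
  }
  vol <- with_seed(spec$seed, {
    if (spec$global_sd > 0) vol <- vol * stats::rnorm(1, 1, spec$global_sd)
    vol <- vol * spec$site_gain + spec$site_offset
    if (spec$noise_sd > 0)
      vol <- vol + stats::rnorm(length(vol), 0, spec$noise_sd)
    vol
  })
  vol[vol < 0] <- 0
  structure(list(intensities = vol, spec = spec), class = "synthetic_volume")
}

#' Default phantom noise level
#'
#' Noise SD chosen so that the voxel-level signal-to-noise ratio of the
#' weaker (hypometabolic) regional effect inside the medial temporal lobe is
#' approximately `snr`: `noise_sd = (1 - hypo) * mean(baseline[MTL]) / snr`.
#'
#' @param snr Target within-region SNR (default 2).
#' @param hypo Hypometabolic factor the SNR refers to.
#' @return Noise standard deviation in intensity units.
#' @export
default_noise_sd <- function(snr = 2, hypo = 0.7) {
  mu <- mean(baseline_field()[default_region_atlas()$MTL_left$voxel_mask])
  (1 - hypo) * mu / snr
}

# Deterministic largest-remainder allocation of n items to fractions.
allocate_counts <- function(n, fractions) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

default_covariate_model <- function() {
  list(age = list(AE = c(mean = 48.51, sd = 16.21),
                  HC = c(mean = 49.43, sd = 10.04),
                  DC = c(mean = 42.96, sd = 19.31)),
       male_frac = c(AE = 97 / 163, HC = 25 / 40, DC = 21 / 46),
       age_range = c(6, 85))
}

draw_age <- function(n, mean, sd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Generate a synthetic phantom cohort
#'
#' Builds per-subject specifications (class signature, covariates, site,
#' split) and optionally renders and writes the volumes. Sites are allocated
#' by deterministic largest-remainder rounding of `site_plan`; subjects on
#' `external_sites` form the external split and receive per-site gain/offset
#' shifts; the remaining subjects are split per class into training
#' (`internal_frac`, rounded) and internal validation. Ages are drawn from
#' truncated normal covariate models per class group; everything is
#' reproducible under `master_seed`.
#'
#' @param n_per_class Named integer vector of subjects per class.
#' @param site_plan Named fractions over sites (must sum to 1).
#' @param covariate_model Age/sex model; see `default_covariate_model()`.
#' @param master_seed Integer master seed.
#' @param noise_sd Noise SD; default [default_noise_sd()].
#' @param hypo,hyper Regional effect factors for the class signatures.
#' @param external_sites Character vector of site names held out as the
#'   external cohort.
#' @param site_gain_range,site_offset_frac Gain range and offset range
#'   (fraction of the in-brain baseline mean) for external-site shifts;
#'   non-external sites have gain 1 and offset 0.
#' @param internal_frac Training fraction of the non-external subjects.
#' @param dir If non-NULL, writes `<subject_id>.nii.gz` volumes and
#'   `manifest.csv` there.
#' @param keep_volumes Keep rendered volumes in the returned object.
#' @return A `phantom_cohort`: list with `manifest` (data.frame with columns
#'   subject_id, class, age, sex, site, split), `specs`, `atlas`, and
#'   optionally `volumes`.
#' @export
generate_cohort <- function(n_per_class,
                            site_plan = c(A = 1),
                            covariate_model = default_covariate_model(),
                            master_seed = 1L,
                            noise_sd = default_noise_sd(),
                            hypo = 0.7, hyper = 1.4,
                            external_sites = character(),
                            site_gain_range = c(0.9, 1.1),
                            site_offset_frac = 0.05,
                            internal_frac = 0.7,
                            dir = NULL, keep_volumes = FALSE) {
  n_per_class <- n_per_class[n_per_class > 0]
  if (!length(n_per_class)) stop("empty cohort request")
  if (!all(names(n_per_class) %in% ALL_CLASSES))
    stop("unknown class in n_per_class")
  n <- sum(n_per_class)

  with_seed(master_seed, {
    classes <- rep(names(n_per_class), n_per_class)
    ids <- sprintf("S%03d", seq_len(n))
    # sites allocated per class (stratified largest-remainder rounding), so
    # small cohorts cannot lose a whole class to one site
    sites <- character(n)
    for (cl in names(n_per_class)) {
      idx <- which(classes == cl)
      cnt <- allocate_counts(length(idx), site_plan)
      sites[idx] <- sample(rep(names(cnt), cnt))
    }
    grp <- ifelse(classes %in% AE_CLASSES, "AE", classes)
    age <- numeric(n); sex <- character(n)
    for (g in unique(grp)) {
      idx <- which(grp == g)
      am <- covariate_model$age[[g]]
      age[idx] <- round(draw_age(length(idx), am["mean"], am["sd"],
                                 covariate_model$age_range), 1)
      sex[idx] <- ifelse(stats::runif(length(idx)) <
                           covariate_model$male_frac[[g]], "M", "F")
    }
    # per-site scanner shift: identity for internal sites
    base_mean <- mean(baseline_field()[brain_mask()])
    site_shift <- lapply(stats::setNames(nm = names(site_plan)), function(s) {
      if (s %in% external_sites)
        c(gain = stats::runif(1, site_gain_range[1], site_gain_range[2]),
          offset = stats::runif(1, -1, 1) * site_offset_frac * base_mean)
      else c(gain = 1, offset = 0)
    })
    # split assignment
    split <- ifelse(sites %in% external_sites, "external", NA)
    for (cl in unique(classes)) {
      idx <- which(classes == cl & is.na(split))
      n_tr <- round(internal_frac * length(idx))
      idx <- sample(idx)
      tr <- idx[seq_len(n_tr)]
      split[tr] <- "train"
      split[setdiff(idx, tr)] <- "internal_val"
    }
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    specs <- lapply(seq_len(n), function(i) {
      sh <- site_shift[[sites[i]]]
      phantom_spec(ids[i], classes[i],
                   region_effects = subtype_signature(classes[i], hypo, hyper),
                   noise_sd = noise_sd, site_id = sites[i],
                   site_gain = sh["gain"], site_offset = sh["offset"],
                   age_years = age[i], sex = sex[i], seed = seeds[i])
    })
    manifest <- data.frame(subject_id = ids, class = classes, age = age,
                           sex = sex, site = sites, split = split,
                           stringsAsFactors = FALSE)
    cohort <- structure(
      list(manifest = manifest, specs = stats::setNames(specs, ids),
           atlas = default_region_atlas(),
           params = list(master_seed = master_seed, noise_sd = noise_sd,
                         hypo = hypo, hyper = hyper,
                         site_plan = site_plan,
                         external_sites = external_sites,
                         internal_frac = internal_frac)),
      class = "phantom_cohort")
    if (keep_volumes || !is.null(dir)) {
      vols <- lapply(specs, render_volume, atlas = cohort$atlas)
      if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        for (v in vols)
          RNifti::writeNifti(
            RNifti::asNifti(v$intensities, pixdim = c(2, 2, 2)),
            file.path(dir, paste0(v$spec$subject_id, ".nii.gz")))
        utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                         row.names = FALSE)
        yaml::write_yaml(
          c(cohort$params,
            list(subject_seeds = stats::setNames(as.list(seeds), ids))),
          file.path(dir, "generator_config.yaml"))
      }
      if (keep_volumes) cohort$volumes <- stats::setNames(vols, ids)
    }
    cohort
  })
}

#' Reference region for intensity normalization
#'
#' Brain voxels outside every atlas region: the analogue of a
#' reference-region (e.g. pons/cerebellar) normalization target, unaffected
#' by any planted class signature. Used to scale volumes so that regional
#' hypo-/hypermetabolism does not leak into the global scaling factor.
#'
#' @param atlas Region atlas.
#' @return Logical 79x95x79 mask.
#' @export
reference_region_mask <- function(atlas = default_region_atlas()) {
  m <- brain_mask()
  for (r in atlas) m <- m & !r$voxel_mask
  m
}

#' Axial slices carrying planted signal for a class
#'
#' Union of the 0-based slice ranges of all regions whose factor differs
#' from 1 in the class signature.
#'
#' @param class_label Class label.
#' @param atlas Region atlas.
#' @param hypo,hyper Factors used when the cohort was generated.
#' @return Integer vector of 0-based axial slice indices (empty for
#'   controls).
#' @export
signal_slices <- function(class_label, atlas = default_region_atlas(),
                          hypo = 0.7, hyper = 1.4) {
  f <- subtype_signature(class_label, hypo, hyper)
  out <- integer(0)
  for (nm in names(f)[f != 1]) {
    sr <- atlas[[nm]]$slice_range
    out <- union(out, seq.int(sr[1], sr[2]))
  }
  sort(out)
}
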