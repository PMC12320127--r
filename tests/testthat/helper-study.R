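# Reference study runs shared by the acceptance-level tests. Conditions are
# the package's documented desk-scale study design (see the methods
# vignette): effect factors 0.7/1.4, within-region SNR ~2, 8-mm smoothing,
# 32x32 slices, reference-region scaling, training-cohort centering,
# tiny backbone m-MIL, Adam lr 1e-3, batch of 4 bags.

# Binary study: 160 subjects, internal site A (75%, split 70/30) and
# shifted external site X (25%).
binary_study <- function() {
  if (!is.null(.fix$binary_study)) return(.fix$binary_study)
  cohort <- generate_cohort(
    c(NMDAR = 20, LGI1 = 20, GABAB = 20, GAD65 = 20, HC = 52, DC = 28),
    site_plan = c(A = 0.75, X = 0.25), external_sites = "X",
    master_seed = 2024L)
  bags <- cohort_bags(cohort)
  sp <- vapply(bags, function(b) b$split, "")
  ref <- reference_image(bags[sp == "train"])
  bags <- center_bags(bags, ref)
  model <- mil_model(encoder_config(seed = 101L), fusion_config(seed = 102L),
                     input_size = c(32L, 32L), seed = 103L)
  fit <- train_binary(bags[sp == "train"],
                      train_config(epochs = 8L, seed = 104L), model)
  .fix$binary_study <- list(cohort = cohort, bags = bags, split = sp,
                            model = fit$model, history = fit$history)
  .fix$binary_study
}

# Subtype study: 40 bags per AE subtype plus controls for the binary stage,
# one site, 70/30 split; binary pre-training then attention-gated 4-class
# fine-tuning.
subtype_study <- function() {
  if (!is.null(.fix$subtype_study)) return(.fix$subtype_study)
  cohort <- generate_cohort(
    c(NMDAR = 40, LGI1 = 40, GABAB = 40, GAD65 = 40, HC = 40, DC = 20),
    site_plan = c(A = 1), master_seed = 3024L)
  bags <- cohort_bags(cohort)
  sp <- vapply(bags, function(b) b$split, "")
  ref <- reference_image(bags[sp == "train"])
  bags <- center_bags(bags, ref)
  model <- mil_model(encoder_config(seed = 201L), fusion_config(seed = 202L),
                     input_size = c(32L, 32L), seed = 203L)
  fit <- train_binary(bags[sp == "train"],
                      train_config(epochs = 5L, seed = 204L), model)
  ae_tr <- Filter(function(b) b$label %in% AE4, bags[sp == "train"])
  fit2 <- train_subtype(ae_tr, fit$model,
                        train_config(epochs = 5L, seed = 205L))
  .fix$subtype_study <- list(cohort = cohort, bags = bags, split = sp,
                             model = fit2$model)
  .fix$subtype_study
}

# attention localization summary over positive bags
localization_summary <- function(model, bags, hypo = 0.7, hyper = 1.4) {
  pr <- predict_bags(model, bags, compute_subtype = "never")
  att <- attr(pr, "attention")
  pos <- which(pr$label %in% AE4)
  enrich <- ok <- numeric(0)
  for (i in pos) {
    ss <- signal_slices(pr$label[i], hypo = hypo, hyper = hyper) + 1L
    a <- att[[i]]$a
    enrich <- c(enrich, sum(a[ss]) / (length(ss) / length(a)))
    ok <- c(ok, which.max(a) %in% ss)
  }
  list(enrichment = mean(enrich), argmax_frac = mean(ok), n_pos = length(pos))
}
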