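# ---------------------------------------------------------------------------
# Classical baselines on bag-level pooled features: ridge logistic
# regression (glmnet) and random forest, consuming byte-identical splits and
# scored by the same metric code as the MIL arms. Bag features are the mean
# over instance embeddings (the canonical attention-free MIL reduction),
# optionally concatenated with the clinical one-hot block.
# ---------------------------------------------------------------------------

#' Mean-pooled bag features for the classical baselines
#'
#' @param bags List of `slice_bag`s.
#' @param encoder A built `encoder` (fixed weights) or [encoder_config()].
#' @param include_clinical Append the clinical one-hot vector.
#' @param fusion_cfg Fusion config supplying the age bins when
#'   `include_clinical = TRUE`.
#' @return List with `features` (n x D matrix) and `meta` (data.frame:
#'   subject_id, label, split).
#' @export
pool_features <- function(bags, encoder, include_clinical = FALSE,
                          fusion_cfg = fusion_config()) {
  if (!length(bags)) stop("no bags to pool")
  if (inherits(encoder, "encoder_config"))
    encoder <- build_encoder(encoder, bags[[1]]$dim_slice)
  rows <- lapply(bags, function(b) {
    x <- rowMeans(encode_bag(b, encoder))
    if (include_clinical)
      x <- c(x, encode_clinical(b$covariates$age, b$covariates$sex,
                                fusion_cfg)$vector)
    x
  })
  features <- do.call(rbind, rows)
  rownames(features) <- vapply(bags, function(b) b$subject_id, character(1))
  meta <- data.frame(
    subject_id = rownames(features),
    label = vapply(bags, function(b) b$label, character(1)),
    split = vapply(bags, function(b) b$split, character(1)),
    stringsAsFactors = FALSE)
  list(features = features, meta = meta)
}

#' Fit and evaluate a classical baseline on pooled bag features
#'
#' Trains on the rows with `split == "train"` and evaluates on
#' `eval_split`, using the identical metric code as the MIL arms. `"LR"` is
#' ridge-penalized logistic regression (fixed small lambda, unpenalized
#' intercept); `"RF"` is a 500-tree random forest. Both are deterministic
#' under `seed`.
#'
#' @param table Output of [pool_features()].
#' @param model `"LR"` or `"RF"`.
#' @param eval_split Split evaluated (`"internal_val"` or `"external"`).
#' @param seed Integer seed.
#' @param threshold Decision threshold.
#' @param positive_classes Labels counted as positive (default the AE
#'   subtypes).
#' @param lambda Ridge penalty for LR.
#' @param ntree Trees for RF.
#' @return An `eval_report` (see [binary_metrics()]) with the evaluated
#'   subject ids attached as attribute `subjects`.
#' @export
fit_eval_baseline <- function(table, model = c("LR", "RF"),
                              eval_split = "internal_val", seed = 1L,
                              threshold = 0.5,
                              positive_classes = AE_CLASSES,
                              lambda = 1e-2, ntree = 500L) {
  model <- match.arg(model)
  y <- as.integer(table$meta$label %in% positive_classes)
  tr <- table$meta$split == "train"
  ev <- table$meta$split == eval_split
  if (!any(ev)) stop("no rows in eval split '", eval_split, "'")
  if (length(unique(y[tr])) < 2) stop("single-class training split")
  xtr <- table$features[tr, , drop = FALSE]
  xev <- table$features[ev, , drop = FALSE]
  prob <- with_seed(seed, {
    if (model == "LR") {
      fit <- glmnet::glmnet(xtr, y[tr], family = "binomial", alpha = 0,
                            lambda = lambda, standardize = TRUE)
      as.vector(stats::predict(fit, xev, type = "response"))
    } else {
      fit <- randomForest::randomForest(xtr, factor(y[tr], levels = 0:1),
                                        ntree = ntree)
      stats::predict(fit, xev, type = "prob")[, "1"]
    }
  })
  rep <- binary_metrics(y[ev], prob, threshold)
  attr(rep, "subjects") <- table$meta$subject_id[ev]
  attr(rep, "model") <- model
  rep
}
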