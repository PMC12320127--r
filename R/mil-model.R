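# ---------------------------------------------------------------------------
# Attention-MIL model: slice encoder -> (optional) clinical fusion ->
# attention pooling -> sigmoid bag head (AE vs control), plus an
# attention-gated 4-way subtype head applied to the top-r attention slices.
# Training is bag-supervised only (weak supervision): no slice labels exist.
# ---------------------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Construct an attention-MIL model
#'
#' @param encoder_cfg An [encoder_config()].
#' @param fusion_cfg A [fusion_config()]; `enabled = FALSE` gives the
#'   single-modal MIL variant.
#' @param input_size Slice size the encoder is built for.
#' @param L Attention hidden size (default 128).
#' @param identity_V Projection-free attention variant (`V = I`).
#' @param subtype_classes Subtype label set for the multiclass head.
#' @param top_r Fraction of instances (by attention weight) the subtype head
#'   pools over (default 0.2, minimum one slice).
#' @param threshold Decision threshold for the binary head.
#' @param seed Seed for head initialization.
#' @return A `mil_model` object with seeded, untrained weights.
#' @export
mil_model <- function(encoder_cfg = encoder_config(),
                      fusion_cfg = fusion_config(),
                      input_size = if (encoder_cfg$backbone == "tiny")
                        c(32L, 32L) else c(224L, 224L),
                      L = 128L, identity_V = FALSE,
                      subtype_classes = AE_CLASSES,
                      top_r = 0.2, threshold = 0.5, seed = 1L) {
  if (fusion_cfg$enabled && fusion_cfg$out_dim != encoder_cfg$out_dim)
    stop("fusion out_dim must equal encoder out_dim")
  d <- encoder_cfg$out_dim
  encoder <- build_encoder(encoder_cfg, input_size)
  structure(list(
    encoder = encoder,
    fusion_cfg = fusion_cfg,
    fusion = init_fusion(fusion_cfg, in_dim = d),
    att = attention_params(d, L, identity_V, seed = seed + 1L),
    bin = with_seed(seed + 2L, list(u = stats::rnorm(d, sd = 1 / sqrt(d)),
                                    b = 0)),
    sub = with_seed(seed + 3L,
      list(W = matrix(stats::rnorm(length(subtype_classes) * d,
                                   sd = 1 / sqrt(d)),
                      length(subtype_classes), d),
           b = numeric(length(subtype_classes)))),
    subtype_classes = subtype_classes,
    top_r = top_r, threshold = threshold, seed = as.integer(seed)),
    class = "mil_model")
}

model_params <- function(model, include_encoder = TRUE) {
  p <- list()
  if (include_encoder && model$encoder$trainable)
    for (nm in names(ep <- encoder_params(model$encoder)))
      p[[paste0("enc.", nm)]] <- ep[[nm]]
  if (!is.null(model$fusion))
    for (nm in names(model$fusion))
      p[[paste0("fus.", nm)]] <- model$fusion[[nm]]
  if (!is.null(model$att$V)) p[["att.V"]] <- model$att$V
  p[["att.w"]] <- model$att$w
  p[["bin.u"]] <- model$bin$u
  p[["bin.b"]] <- model$bin$b
  p[["sub.W"]] <- model$sub$W
  p[["sub.b"]] <- model$sub$b
  p
}

model_set_params <- function(model, p) {
  encp <- p[startsWith(names(p), "enc.")]
  if (length(encp)) {
    names(encp) <- sub("^enc\\.", "", names(encp))
    model$encoder <- encoder_set_params(model$encoder, encp)
  }
  for (nm in names(p)) {
    if (startsWith(nm, "fus.")) model$fusion[[sub("^fus\\.", "", nm)]] <- p[[nm]]
    else if (nm == "att.V") model$att$V <- p[[nm]]
    else if (nm == "att.w") model$att$w <- p[[nm]]
    else if (nm == "bin.u") model$bin$u <- p[[nm]]
    else if (nm == "bin.b") model$bin$b <- as.numeric(p[[nm]])
    else if (nm == "sub.W") model$sub$W <- p[[nm]]
    else if (nm == "sub.b") model$sub$b <- as.numeric(p[[nm]])
  }
  model
}

# full forward pass; keep=TRUE retains every cache needed for backprop
model_forward <- function(model, bag, keep = FALSE) {
  er <- encoder_forward(bag$slices, model$encoder, keep)
  H1 <- er$H
  if (!is.null(model$fusion)) {
    cvec <- encode_clinical(bag$covariates$age, bag$covariates$sex,
                            model$fusion_cfg)$vector
    fr <- fusion_forward(H1, cvec, model$fusion, model$fusion_cfg, keep)
    H2 <- fr$H
  } else { fr <- NULL; H2 <- H1 }
  ar <- attention_forward(H2, model$att, keep)
  logit <- sum(model$bin$u * ar$s) + model$bin$b
  list(H2 = H2, a = ar$a, s = ar$s, logit = logit, p = sigmoid(logit),
       enc_caches = er$caches, fus_cache = fr$cache, att_cache = ar$cache)
}

n_top <- function(K, r) min(K, max(1L, as.integer(ceiling(r * K - 1e-9))))

subtype_head_forward <- function(model, H2, a, top_r) {
  K <- length(a)
  sel <- order(a, decreasing = TRUE)[seq_len(n_top(K, top_r))]
  at <- a[sel] / sum(a[sel])
  s_sel <- as.vector(H2[, sel, drop = FALSE] %*% at)
  logits <- as.vector(model$sub$W %*% s_sel) + model$sub$b
  p <- softmax_stable(logits)
  list(p = stats::setNames(p, model$subtype_classes), sel = sel, at = at,
       s_sel = s_sel)
}

#' Forward pass of a bag through the full model
#'
#' Encodes all slices, optionally fuses clinical covariates, pools with
#' attention, and applies the binary (AE vs control) head; the subtype head
#' is applied to the attention-gated top-r slices when the bag is predicted
#' (or forced) positive. Deterministic in inference mode.
#'
#' @param bag A `slice_bag`.
#' @param model A `mil_model`.
#' @param compute_subtype `"auto"` (when predicted positive), `"always"`, or
#'   `"never"`.
#' @return A `bag_prediction`: list with `p_binary`, `p_subtype` (named
#'   vector or NULL), and `attention` (an `attention_state`).
#' @export
bag_forward <- function(bag, model,
                        compute_subtype = c("auto", "always", "never")) {
  compute_subtype <- match.arg(compute_subtype)
  fw <- model_forward(model, bag)
  p_sub <- NULL
  if (compute_subtype == "always" ||
      (compute_subtype == "auto" && fw$p >= model$threshold))
    p_sub <- subtype_head_forward(model, fw$H2, fw$a, model$top_r)$p
  structure(list(p_binary = fw$p, p_subtype = p_sub,
                 attention = structure(list(a = fw$a, s = fw$s),
                                       class = "attention_state")),
            class = "bag_prediction")
}

#' Attention-gated subtype classification of a positive bag
#'
#' Selects the top `top_r` fraction of instances by attention weight
#' (minimum one slice), re-pools them with renormalized attention, and
#' applies the 4-way softmax subtype head. With `top_r = 1` this equals
#' pooling over all instances.
#'
#' @param bag A `slice_bag`.
#' @param model A `mil_model` (binary-trained, subtype head trained).
#' @param top_r Selected fraction; defaults to the model's setting.
#' @return Named probability vector over the model's subtype classes.
#' @export
subtype_forward <- function(bag, model, top_r = model$top_r) {
  if (is.null(bag$slices) || ncol(bag$slices) < 1) stop("bag has no instances")
  fw <- model_forward(model, bag)
  subtype_head_forward(model, fw$H2, fw$a, top_r)$p
}

# --- gradients -------------------------------------------------------------

backprop_common <- function(model, fw, ds, da_extra, grads,
                            freeze_encoder = FALSE) {
  ab <- attention_backward(ds, da_extra, fw$a, fw$att_cache, model$att)
  dH2 <- ab$dH
  if (!is.null(grads$extra_dH2)) { dH2 <- dH2 + grads$extra_dH2
                                   grads$extra_dH2 <- NULL }
  if (!is.null(model$att$V)) grads[["att.V"]] <- ab$grads$V
  grads[["att.w"]] <- ab$grads$w
  if (!is.null(model$fusion)) {
    fb <- fusion_backward(dH2, fw$fus_cache, model$fusion, model$fusion_cfg)
    for (nm in names(fb$grads)) grads[[paste0("fus.", nm)]] <- fb$grads[[nm]]
    dH1 <- fb$dH
  } else dH1 <- dH2
  if (model$encoder$trainable && !freeze_encoder) {
    eg <- encoder_backward(dH1, fw$enc_caches, model$encoder)
    for (nm in names(eg)) grads[[paste0("enc.", nm)]] <- eg[[nm]]
  }
  grads
}

bag_grad_binary <- function(model, bag, y, wt = 1, freeze_encoder = FALSE) {
  fw <- model_forward(model, bag, keep = TRUE)
  loss <- wt * (softplus(fw$logit) - y * fw$logit)
  dlogit <- wt * (fw$p - y)
  grads <- list("bin.u" = dlogit * fw$s, "bin.b" = dlogit)
  ds <- dlogit * model$bin$u
  grads <- backprop_common(model, fw, ds, NULL, grads, freeze_encoder)
  list(loss = loss, grads = grads)
}

bag_grad_subtype <- function(model, bag, yidx, wt = 1, top_r = model$top_r,
                             freeze_encoder = FALSE) {
  fw <- model_forward(model, bag, keep = TRUE)
  sh <- subtype_head_forward(model, fw$H2, fw$a, top_r)
  loss <- wt * (-log(max(sh$p[yidx], 1e-12)))
  dlogits <- wt * (as.vector(sh$p) - as.numeric(seq_along(sh$p) == yidx))
  grads <- list("sub.W" = outer(dlogits, sh$s_sel), "sub.b" = dlogits)
  ds_sel <- as.vector(crossprod(model$sub$W, dlogits))
  # gradient wrt the renormalized weights, then wrt the full softmax weights
  g <- as.vector(crossprod(fw$H2[, sh$sel, drop = FALSE], ds_sel))
  da <- numeric(length(fw$a))
  da[sh$sel] <- (g - sum(g * sh$at)) / sum(fw$a[sh$sel])
  # direct path into the selected instance embeddings
  extra_dH2 <- matrix(0, nrow(fw$H2), ncol(fw$H2))
  extra_dH2[, sh$sel] <- outer(ds_sel, sh$at)
  grads$extra_dH2 <- extra_dH2
  grads <- backprop_common(model, fw, numeric(length(ds_sel)), da, grads,
                           freeze_encoder)
  list(loss = loss, grads = grads)
}

# --- training --------------------------------------------------------------

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param epochs Number of passes over the training bags.
#' @param batch_bags Bags per gradient step (gradients averaged).
#' @param seed Seed controlling shuffling (weight seeds live in the model).
#' @param class_weights `"balanced"` (inverse frequency), `"none"`, or a
#'   named numeric vector.
#' @param threshold Binary decision threshold.
#' @param freeze_encoder If `TRUE`, encoder weights are not updated.
#' @param clip Global gradient-norm clip (Inf to disable).
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-3, epochs = 20L, batch_bags = 4L, seed = 1L,
                         class_weights = "balanced", threshold = 0.5,
                         freeze_encoder = FALSE, clip = 5) {
  stopifnot(epochs >= 1, threshold > 0, threshold < 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_bags = as.integer(batch_bags), seed = as.integer(seed),
                 class_weights = class_weights, threshold = threshold,
                 freeze_encoder = freeze_encoder, clip = clip),
            class = "train_config")
}

#' Inverse-frequency class weights
#'
#' @param labels Vector of class labels.
#' @return Named weights `n / (C * n_c)` per class.
#' @export
inverse_freq_weights <- function(labels) {
  tab <- table(labels)
  w <- length(labels) / (length(tab) * as.numeric(tab))
  stats::setNames(w, names(tab))
}

clip_grads <- function(grads, clip) {
  if (!is.finite(clip)) return(grads)
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (nrm > clip) grads <- lapply(grads, function(g) g * (clip / nrm))
  grads
}

sum_grads <- function(acc, g, scale) {
  if (is.null(acc)) return(lapply(g, function(x) x * scale))
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]] * scale
  acc
}

run_training <- function(model, bags, config, grad_fun, loss_label) {
  params <- model_params(model, include_encoder = !config$freeze_encoder)
  state <- adam_init(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(bags))
      losses <- numeric(0)
      i <- 1L
      while (i <= length(ord)) {
        idx <- ord[seq.int(i, min(i + config$batch_bags - 1L, length(ord)))]
        acc <- NULL
        for (j in idx) {
          r <- grad_fun(model, j)
          losses <- c(losses, r$loss)
          acc <- sum_grads(acc, r$grads, 1 / length(idx))
        }
        acc <- clip_grads(acc, config$clip)
        st <- adam_step(params, acc, state, lr = config$lr)
        params <- st$params; state <- st$state
        model <- model_set_params(model, params)
        i <- i + config$batch_bags
      }
      mloss <- mean(losses)
      if (!is.finite(mloss))
        stop(loss_label, " training diverged (non-finite loss) at epoch ", ep)
      history <- rbind(history, data.frame(epoch = ep, loss = mloss))
    }
  })
  list(model = model, history = history)
}

#' Train the binary (AE vs control) attention-MIL model
#'
#' Minimizes class-weighted binary cross-entropy on bag labels only; slices
#' carry no labels (weak supervision). Bags whose label is one of the
#' model's subtype classes are positive; `HC`/`DC` bags are negative.
#' Reproducible given the config seed and the model's weight seeds.
#'
#' @param bags List of `slice_bag`s (the training set).
#' @param config A [train_config()].
#' @param model A `mil_model`; a default tiny-backbone model matching the
#'   bags' slice size is built if omitted.
#' @return List with `model` (trained) and `history` (per-epoch mean loss).
#' @export
train_binary <- function(bags, config = train_config(), model = NULL) {
  if (!length(bags)) stop("empty training set")
  if (is.null(model))
    model <- mil_model(encoder_config(out_dim = 512L, seed = config$seed),
                       fusion_config(seed = config$seed),
                       input_size = bags[[1]]$dim_slice, seed = config$seed)
  y <- as.numeric(vapply(bags, function(b) b$label %in% model$subtype_classes,
                         logical(1)))
  if (length(unique(y)) < 2)
    stop("binary training needs both positive and negative bags")
  cw <- config$class_weights
  wts <- if (identical(cw, "balanced")) {
    w <- inverse_freq_weights(ifelse(y == 1, "pos", "neg"))
    ifelse(y == 1, w[["pos"]], w[["neg"]])
  } else if (identical(cw, "none")) rep(1, length(y))
  else ifelse(y == 1, cw[["pos"]], cw[["neg"]])
  model$threshold <- config$threshold
  run_training(model, bags, config,
               function(m, j) bag_grad_binary(m, bags[[j]], y[j], wts[j],
                                              config$freeze_encoder),
               "binary")
}

#' Train the attention-gated subtype head
#'
#' Cross-entropy on the subtype labels of AE bags, pooling over the top-r
#' attention slices. By default the whole network is fine-tuned end-to-end
#' from the binary-trained weights; set `config$freeze_encoder` to train
#' only fusion/attention/head. Classes absent from the data are dropped from
#' the head with a warning.
#'
#' @param bags AE-only list of `slice_bag`s (others are ignored with a
#'   message).
#' @param model A binary-trained `mil_model`.
#' @param config A [train_config()].
#' @return List with `model` and `history`.
#' @export
train_subtype <- function(bags, model, config = train_config()) {
  keep <- vapply(bags, function(b) b$label %in% model$subtype_classes,
                 logical(1))
  if (!all(keep)) {
    message("dropping ", sum(!keep), " non-subtype bags from subtype training")
    bags <- bags[keep]
  }
  labs <- vapply(bags, function(b) b$label, character(1))
  present <- model$subtype_classes[model$subtype_classes %in% labs]
  if (length(present) < 2) stop("need at least two subtype classes present")
  if (length(present) < length(model$subtype_classes)) {
    warning("restricting subtype head to observed classes: ",
            paste(present, collapse = ", "))
    sel <- match(present, model$subtype_classes)
    model$sub$W <- model$sub$W[sel, , drop = FALSE]
    model$sub$b <- model$sub$b[sel]
    model$subtype_classes <- present
  }
  yidx <- match(labs, model$subtype_classes)
  cw <- config$class_weights
  wts <- if (identical(cw, "balanced")) inverse_freq_weights(labs)[labs]
  else if (identical(cw, "none")) rep(1, length(labs))
  else cw[labs]
  run_training(model, bags, config,
               function(m, j) bag_grad_subtype(m, bags[[j]], yidx[j], wts[j],
                                               freeze_encoder = config$freeze_encoder),
               "subtype")
}

#' Save / load a model checkpoint with embedded configuration
#'
#' @param model A `mil_model`.
#' @param path Destination file.
#' @export
save_checkpoint <- function(model, path) {
  cfg <- list(encoder = unclass(model$encoder$config),
              fusion = unclass(model$fusion_cfg),
              subtype_classes = model$subtype_classes,
              top_r = model$top_r, threshold = model$threshold,
              input_size = model$encoder$input_size)
  saveRDS(list(config_json = jsonlite::toJSON(cfg, auto_unbox = TRUE),
               params = model_params(model),
               sub = model$sub, subtype_classes = model$subtype_classes,
               config = cfg), path)
}

#' @rdname save_checkpoint
#' @param path Checkpoint file written by [save_checkpoint()].
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- ck$config
  model <- mil_model(do.call(encoder_config, cfg$encoder[setdiff(names(cfg$encoder), NULL)]),
                     do.call(fusion_config, cfg$fusion),
                     input_size = cfg$input_size,
                     subtype_classes = cfg$subtype_classes,
                     top_r = cfg$top_r, threshold = cfg$threshold)
  model$sub <- ck$sub
  model$subtype_classes <- ck$subtype_classes
  model_set_params(model, ck$params)
}
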