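# ---------------------------------------------------------------------------
# Slice encoder: convolutional backbone without a classification head, with
# the final global average pooling replaced (by default) by a 2x2 local
# average pooling so focal regional abnormalities survive pooling; a linear
# map then produces the instance embedding.
# ---------------------------------------------------------------------------

#' Encoder configuration
#'
#' @param backbone `"tiny"` (4 conv blocks, trainable, 32x32 inputs by
#'   default) or `"resnet18"` (18-layer residual backbone, inference only,
#'   224x224 inputs).
#' @param pool `"local_avg"` (2x2 grid of regional averages, the default) or
#'   `"global_avg"` (single global average).
#' @param out_dim Instance embedding dimension (default 512).
#' @param pretrained_init If `TRUE`, weights are loaded from `weights_file`
#'   instead of seeded random initialization.
#' @param weights_file Optional RDS checkpoint written by
#'   [save_checkpoint()].
#' @param seed Seed for weight initialization.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(backbone = c("tiny", "resnet18"),
                           pool = c("local_avg", "global_avg"),
                           out_dim = 512L, pretrained_init = FALSE,
                           weights_file = NULL, seed = 1L) {
  structure(list(backbone = match.arg(backbone), pool = match.arg(pool),
                 out_dim = as.integer(out_dim),
                 pretrained_init = pretrained_init,
                 weights_file = weights_file, seed = as.integer(seed)),
            class = "encoder_config")
}

#' Local average pooling over a spatial grid
#'
#' Partitions the spatial extent into a `grid[1] x grid[2]` array of
#' sub-windows (window `i` along an axis of length `n` covers indices
#' `floor(n*(i-1)/g)+1 .. floor(n*i/g)`) and averages within each window,
#' per channel.
#'
#' @param feature_map Matrix `H x W` or array `H x W x C`.
#' @param grid Integer pair, default `c(2, 2)`.
#' @return A `(grid[1]*grid[2]) x C` matrix of window means (windows in
#'   column-major order).
#' @export
local_avg_pool <- function(feature_map, grid = c(2L, 2L)) {
  d <- dim(feature_map)
  if (length(d) == 2) { dim(feature_map) <- c(d, 1L); d <- dim(feature_map) }
  P <- local_pool_matrix(d[1], d[2], grid)
  dim(feature_map) <- c(d[1] * d[2], d[3])
  as.matrix(P %*% feature_map)
}

tiny_channels <- c(8L, 16L, 32L, 32L)

#' Build an encoder from its configuration
#'
#' @param config An [encoder_config()].
#' @param input_size Spatial slice size; tiny requires a multiple of 8.
#' @return An `encoder` object holding layers and initialized weights.
#' @export
build_encoder <- function(config, input_size = if (config$backbone == "tiny")
                            c(32L, 32L) else c(224L, 224L)) {
  enc <- with_seed(config$seed, {
    if (config$backbone == "tiny") build_tiny(config, input_size)
    else build_resnet18(config, input_size)
  })
  if (isTRUE(config$pretrained_init)) {
    if (is.null(config$weights_file))
      stop("pretrained_init=TRUE requires weights_file")
    enc <- encoder_set_params(enc, readRDS(config$weights_file)$params)
  }
  enc
}

build_tiny <- function(config, input_size) {
  h <- input_size[1]; w <- input_size[2]
  if (h %% 8 != 0 || w %% 8 != 0) stop("tiny backbone needs sizes divisible by 8")
  ch <- tiny_channels
  layers <- list()
  cin <- 1L
  for (b in 1:4) {
    layers <- c(layers, list(layer_conv(h, w, cin, ch[b])),
                list(layer_inorm(ch[b])), list(layer_relu()))
    if (b < 4) { layers <- c(layers, list(layer_pool(h, w, ch[b])))
                 h <- h %/% 2L; w <- w %/% 2L }
    cin <- ch[b]
  }
  # final per-slice re-centering before pooling keeps the embedding scale
  # well-conditioned for the attention and head layers
  layers <- c(layers, list(layer_inorm(cin)))
  if (config$pool == "local_avg") {
    layers <- c(layers, list(layer_local_pool(h, w, cin, c(2L, 2L))))
    feat <- 4L * cin
  } else {
    layers <- c(layers, list(layer_global_pool(h, w, cin)))
    feat <- cin
  }
  layers <- c(layers, list(layer_linear(feat, config$out_dim)))
  structure(list(config = config, input_size = input_size, layers = layers,
                 trainable = TRUE, in_channels = 1L),
            class = "encoder")
}

resnet_block <- function(H, W, C_in, C_out, stride) {
  list(conv1 = layer_conv(H, W, C_in, C_out, k = 3L, stride = stride, pad = 1L),
       bn1 = layer_inorm(C_out),
       conv2 = layer_conv(H %/% stride, W %/% stride, C_out, C_out),
       bn2 = layer_inorm(C_out),
       down = if (stride != 1L || C_in != C_out)
         layer_conv(H, W, C_in, C_out, k = 1L, stride = stride, pad = 0L))
}

build_resnet18 <- function(config, input_size) {
  h <- input_size[1]; w <- input_size[2]
  stem <- layer_conv(h, w, 3L, 64L, k = 7L, stride = 2L, pad = 3L)
  h <- h %/% 2L; w <- w %/% 2L
  stem_bn <- layer_inorm(64L)
  stem_pool <- layer_pool(h, w, 64L)
  h <- h %/% 2L; w <- w %/% 2L
  plan <- list(c(64, 1), c(64, 1), c(128, 2), c(128, 1),
               c(256, 2), c(256, 1), c(512, 2), c(512, 1))
  cin <- 64L
  blocks <- list()
  for (p in plan) {
    blocks <- c(blocks, list(resnet_block(h, w, cin, p[1], p[2])))
    h <- h %/% p[2]; w <- w %/% p[2]
    cin <- as.integer(p[1])
  }
  if (config$pool == "local_avg") {
    head_pool <- layer_local_pool(h, w, cin, c(2L, 2L)); feat <- 4L * cin
  } else {
    head_pool <- layer_global_pool(h, w, cin); feat <- cin
  }
  proj <- layer_linear(feat, config$out_dim)
  structure(list(config = config, input_size = input_size,
                 stem = stem, stem_bn = stem_bn, stem_pool = stem_pool,
                 blocks = blocks,
                 head_pool = head_pool, proj = proj,
                 trainable = FALSE, in_channels = 3L),
            class = "encoder")
}

relu_ <- function(x) x * (x > 0)

resnet_forward <- function(X, enc) {
  X <- rbind(X, X, X)  # replicate single channel to 3
  X <- layer_forward(enc$stem, X)$out
  X <- relu_(layer_forward(enc$stem_bn, X)$out)
  X <- layer_forward(enc$stem_pool, X)$out
  for (b in enc$blocks) {
    Y <- layer_forward(b$conv1, X)$out
    Y <- relu_(layer_forward(b$bn1, Y)$out)
    Y <- layer_forward(b$conv2, Y)$out
    Y <- layer_forward(b$bn2, Y)$out
    S <- if (is.null(b$down)) X else layer_forward(b$down, X)$out
    X <- relu_(Y + S)
  }
  X <- layer_forward(enc$head_pool, X)$out
  layer_forward(enc$proj, X)$out
}

encoder_forward <- function(X, enc, keep = FALSE) {
  if (enc$config$backbone == "resnet18")
    return(list(H = resnet_forward(X, enc), caches = NULL))
  caches <- vector("list", length(enc$layers))
  for (i in seq_along(enc$layers)) {
    r <- layer_forward(enc$layers[[i]], X, keep)
    X <- r$out
    if (keep) caches[[i]] <- r$cache
  }
  list(H = X, caches = caches)
}

encoder_backward <- function(dH, caches, enc) {
  grads <- list()
  dX <- dH
  for (i in rev(seq_along(enc$layers))) {
    r <- layer_backward(enc$layers[[i]], dX, caches[[i]])
    dX <- r$dX
    for (nm in names(r$grads)) grads[[paste0("l", i, ".", nm)]] <- r$grads[[nm]]
  }
  grads
}

encoder_params <- function(enc) {
  if (enc$config$backbone != "tiny") stop("flat params only for tiny backbone")
  out <- list()
  for (i in seq_along(enc$layers))
    for (nm in names(enc$layers[[i]]$params))
      out[[paste0("l", i, ".", nm)]] <- enc$layers[[i]]$params[[nm]]
  out
}

encoder_set_params <- function(enc, params) {
  if (enc$config$backbone != "tiny") stop("flat params only for tiny backbone")
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    i <- as.integer(sub("^l", "", parts[1]))
    enc$layers[[i]]$params[[parts[2]]] <- params[[nm]]
  }
  enc
}

#' Encode a bag of slices into instance embeddings
#'
#' Runs every slice through the convolutional backbone and the modified
#' pooling stage, producing one embedding per slice with order preserved.
#' A pure function of (slices, weights): repeated calls are bitwise equal.
#'
#' @param bag A `slice_bag` (see [extract_bag()]).
#' @param encoder An `encoder` from [build_encoder()], or an
#'   [encoder_config()] (built on the fly).
#' @return A `config$out_dim x K` matrix; column `i` is the embedding `h_i`
#'   of slice `i` (0-based axial index `i - 1`).
#' @export
encode_bag <- function(bag, encoder) {
  if (inherits(encoder, "encoder_config"))
    encoder <- build_encoder(encoder, bag$dim_slice)
  if (!all(bag$dim_slice == encoder$input_size))
    stop("bag slice size does not match encoder input size")
  H <- encoder_forward(bag$slices, encoder)$H
  if (!all(is.finite(H))) stop("non-finite activations in encoder")
  H
}
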