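# ---------------------------------------------------------------------------
# Multimodal fusion: one-hot clinical covariates (sex, binned age) fused with
# each instance embedding by linear compression of the image vector,
# concatenation with the clinical vector, and nonlinear expansion back to the
# embedding dimension. The image vector is compressed first so the ~11-d
# clinical block is not drowned by the 512-d image block.
# ---------------------------------------------------------------------------

#' Fusion configuration
#'
#' @param compress_dim Dimension the image embedding is compressed to before
#'   concatenation (default 128).
#' @param out_dim Fused embedding dimension (default 512; must equal the
#'   encoder's `out_dim` so single- and multi-modal heads are
#'   interchangeable).
#' @param age_bins Strictly increasing bin edges for age one-hot encoding;
#'   half-open bins `[lo, hi)`; must cover `[6, 85]`. Default decades 0-90.
#' @param enabled `FALSE` gives the single-modal pipeline (fusion is the
#'   identity).
#' @param seed Seed for fusion weight initialization.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(compress_dim = 128L, out_dim = 512L,
                          age_bins = seq(0, 90, by = 10), enabled = TRUE,
                          seed = 1L) {
  stopifnot(compress_dim >= 1, all(diff(age_bins) > 0))
  if (age_bins[1] > 6 || age_bins[length(age_bins)] <= 85)
    stop("age_bins must cover [6, 85]")
  structure(list(compress_dim = as.integer(compress_dim),
                 out_dim = as.integer(out_dim), age_bins = age_bins,
                 enabled = enabled, seed = as.integer(seed)),
            class = "fusion_config")
}

clinical_dim <- function(config) 2L + length(config$age_bins) - 1L

#' One-hot encode clinical covariates
#'
#' Sex maps to a 2-d indicator `(M, F)`; age maps to an indicator over the
#' configured half-open bins `[lo, hi)`. Exactly one entry is active in each
#' group.
#'
#' @param age_years Age in years, inside the covered bin range.
#' @param sex `"M"` or `"F"`.
#' @param config A [fusion_config()].
#' @return A `clinical_encoding`: list with `sex_onehot`, `age_onehot`, and
#'   the concatenated `vector`.
#' @export
encode_clinical <- function(age_years, sex, config = fusion_config()) {
  if (!sex %in% c("M", "F")) stop("unknown sex category: ", sex)
  edges <- config$age_bins
  if (age_years < edges[1] || age_years >= edges[length(edges)])
    stop("age ", age_years, " outside the covered bins")
  bin <- findInterval(age_years, edges)
  age_onehot <- integer(length(edges) - 1L)
  age_onehot[bin] <- 1L
  sex_onehot <- as.integer(c(sex == "M", sex == "F"))
  structure(list(sex_onehot = sex_onehot, age_onehot = age_onehot,
                 vector = c(sex_onehot, age_onehot)),
            class = "clinical_encoding")
}

init_fusion <- function(config, in_dim = 512L) {
  if (!config$enabled) return(NULL)
  dc <- clinical_dim(config)
  with_seed(config$seed, list(
    Wc = he_init(config$compress_dim, in_dim, gain = 1),
    bc = numeric(config$compress_dim),
    We = he_init(config$out_dim, config$compress_dim + dc),
    be = numeric(config$out_dim)))
}

fusion_forward <- function(H, cvec, params, config, keep = FALSE) {
  K <- ncol(H)
  Z1 <- params$Wc %*% H + params$bc
  Z <- rbind(Z1, matrix(cvec, length(cvec), K))
  A <- params$We %*% Z + params$be
  H2 <- A * (A > 0)
  list(H = H2, cache = if (keep) list(H = H, Z = Z, mask = A > 0, K = K))
}

fusion_backward <- function(dH2, cache, params, config) {
  dA <- dH2 * cache$mask
  dWe <- dA %*% t(cache$Z)
  dbe <- rowSums(dA)
  dZ <- crossprod(params$We, dA)
  dZ1 <- dZ[seq_len(config$compress_dim), , drop = FALSE]
  dWc <- dZ1 %*% t(cache$H)
  dbc <- rowSums(dZ1)
  dH <- crossprod(params$Wc, dZ1)
  list(dH = dH, grads = list(Wc = dWc, bc = dbc, We = dWe, be = dbe))
}

#' Fuse clinical covariates into instance embeddings
#'
#' Linear compression of the image embedding to `compress_dim`,
#' concatenation with the clinical one-hot vector, then linear expansion
#' with a ReLU nonlinearity back to `out_dim`, applied per instance (the
#' same clinical vector is appended to every slice). With
#' `config$enabled = FALSE` the input is returned unchanged (single-modal
#' pipeline).
#'
#' @param h Instance embedding(s): a vector or a `D x K` matrix.
#' @param c_enc A `clinical_encoding` from [encode_clinical()].
#' @param config A [fusion_config()].
#' @param params Fusion weights; seeded initialization by default.
#' @return Fused embedding(s) with the same shape contract as `h`
#'   (dimension `config$out_dim`).
#' @export
fuse <- function(h, c_enc, config = fusion_config(),
                 params = init_fusion(config, in_dim = NROW(h))) {
  if (!config$enabled) return(h)
  vec_in <- is.null(dim(h))
  H <- if (vec_in) matrix(h, ncol = 1) else h
  out <- fusion_forward(H, c_enc$vector, params, config)$H
  if (vec_in) as.vector(out) else out
}
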