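# ---------------------------------------------------------------------------
# Attention pooling over instance embeddings:
#   a_i = softmax_i( w^T tanh(V h_i) ),   s = sum_i a_i h_i
# The V projection (embedding dim -> hidden size L) makes w an L-vector; the
# projection-free variant (V = identity) is available via identity_V.
# ---------------------------------------------------------------------------

#' Initialize attention parameters
#'
#' @param d Instance embedding dimension.
#' @param L Attention hidden size (default 128).
#' @param identity_V Use the literal projection-free variant
#'   (`V = I`, `L = d`).
#' @param seed Seed for initialization.
#' @return List with `V` (L x d, or NULL for identity) and `w` (L).
#' @export
attention_params <- function(d = 512L, L = 128L, identity_V = FALSE,
                             seed = 1L) {
  with_seed(seed, {
    if (identity_V)
      list(V = NULL, w = stats::rnorm(d, sd = 1 / sqrt(d)), L = as.integer(d))
    else
      list(V = matrix(stats::rnorm(L * d, sd = 1 / sqrt(d)), L, d),
           w = stats::rnorm(L, sd = 1 / sqrt(L)), L = as.integer(L))
  })
}

softmax_stable <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Attention pooling of a bag of instance embeddings
#'
#' Computes attention weights `a_i = softmax_i(w^T tanh(V h_i))` (softmax
#' stabilized by max subtraction) and the pooled bag embedding
#' `s = sum_i a_i h_i`. The weights form a probability simplex and are the
#' per-slice values exported in attention heatmaps.
#'
#' @param H Instance embeddings: a `D x K` matrix (columns are instances) or
#'   a list of D-vectors.
#' @param params Attention parameters from [attention_params()].
#' @return An `attention_state`: list with `a` (K, nonnegative, sums to 1)
#'   and `s` (D).
#' @export
attention_pool <- function(H, params) {
  if (is.list(H) && !is.matrix(H)) H <- do.call(cbind, H)
  if (ncol(H) < 1) stop("empty bag")
  Z <- tanh(if (is.null(params$V)) H else params$V %*% H)
  scores <- as.vector(crossprod(params$w, Z))
  if (!all(is.finite(scores))) stop("non-finite attention scores")
  a <- softmax_stable(scores)
  structure(list(a = a, s = as.vector(H %*% a)), class = "attention_state")
}

# forward with cache for training
attention_forward <- function(H, params, keep = FALSE) {
  Z <- tanh(if (is.null(params$V)) H else params$V %*% H)
  scores <- as.vector(crossprod(params$w, Z))
  a <- softmax_stable(scores)
  s <- as.vector(H %*% a)
  list(a = a, s = s, cache = if (keep) list(H = H, Z = Z))
}

# Backward through attention pooling.
# ds: gradient wrt pooled s (D); da_extra: extra gradient wrt a (K) coming
# from paths that use the weights directly (e.g. renormalized top-r pooling).
attention_backward <- function(ds, da_extra, a, cache, params) {
  H <- cache$H; Z <- cache$Z
  da <- as.vector(crossprod(H, ds))
  if (!is.null(da_extra)) da <- da + da_extra
  dscore <- a * (da - sum(a * da))
  dZ <- outer(params$w, dscore)          # L x K
  dpre <- dZ * (1 - Z^2)
  dH_att <- if (is.null(params$V)) dpre else crossprod(params$V, dpre)
  dH <- outer(ds, a) + dH_att
  grads <- list(w = as.vector(Z %*% dscore))
  if (!is.null(params$V)) grads$V <- dpre %*% t(H)
  list(dH = dH, grads = grads)
}
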