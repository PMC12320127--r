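# Shared fixtures, built in code. Heavier objects are cached for the session.

AE4 <- c("NMDAR", "LGI1", "GABAB", "GAD65")

.fix <- new.env(parent = emptyenv())

# Independent oracle: literal evaluation of the attention equations,
# a_i = exp(w' tanh(V h_i)) / sum_j exp(w' tanh(V h_j)),  s = sum_i a_i h_i,
# written without reuse of the package's pooling code.
attention_oracle <- function(H, params) {
  K <- ncol(H)
  scores <- numeric(K)
  for (i in seq_len(K)) {
    z <- if (is.null(params$V)) tanh(H[, i]) else tanh(params$V %*% H[, i])
    scores[i] <- sum(params$w * z)
  }
  e <- exp(scores)
  a <- e / sum(e)
  s <- numeric(nrow(H))
  for (i in seq_len(K)) s <- s + a[i] * H[, i]
  list(a = a, s = s)
}

# random slice bag, independent of the phantom generator
random_bag <- function(K = 5L, size = c(16L, 16L), label = "NMDAR",
                       split = "train", age = 48, sex = "F", seed = 1L,
                       id = "T1") {
  set.seed(seed)
  structure(list(subject_id = id,
                 slices = matrix(rnorm(prod(size) * K), prod(size), K),
                 dim_slice = as.integer(size), K = as.integer(K),
                 covariates = list(age = age, sex = sex),
                 label = label, split = split),
            class = "slice_bag")
}

# small trainable model on 16x16 inputs with modest dims (fast)
small_model <- function(out_dim = 32L, L = 8L, fusion = TRUE, seed = 7L) {
  mil_model(encoder_config(out_dim = out_dim, seed = seed),
            fusion_config(compress_dim = 16L, out_dim = out_dim,
                          enabled = fusion, seed = seed + 1L),
            input_size = c(16L, 16L), L = L, seed = seed + 2L)
}

# tiny phantom cohort bagged at 32x32, cached (rendering dominates test time)
tiny_cohort_bags <- function() {
  if (is.null(.fix$tcb)) {
    cohort <- generate_cohort(
      c(NMDAR = 4, LGI1 = 4, GABAB = 4, GAD65 = 4, HC = 8, DC = 4),
      site_plan = c(A = 1), master_seed = 77)
    bags <- cohort_bags(cohort)
    sp <- vapply(bags, function(b) b$split, "")
    ref <- reference_image(bags[sp == "train"])
    .fix$tcb <- list(cohort = cohort, bags = center_bags(bags, ref),
                     raw_bags = bags, split = sp)
  }
  .fix$tcb
}
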