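# Backprop oracle: central finite differences through the full model
# (encoder + fusion + attention + heads) on a small bag.
test_that("analytic gradients match finite differences", {
  model <- small_model(out_dim = 16L, L = 6L, seed = 61)
  bag <- random_bag(K = 3, size = c(16, 16), seed = 62)
  params <- petmil:::model_params(model)

  check_grads <- function(grads, loss_fn) {
    eps <- 1e-5
    set.seed(63)
    for (nm in names(grads)) {
      for (i in sample(length(grads[[nm]]), min(2, length(grads[[nm]])))) {
        p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
        expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                     label = paste("grad", nm))
      }
    }
  }

  gb <- petmil:::bag_grad_binary(model, bag, 1, 1.3)
  check_grads(gb$grads, function(p)
    petmil:::bag_grad_binary(petmil:::model_set_params(model, p),
                             bag, 1, 1.3)$loss)
  gs <- petmil:::bag_grad_subtype(model, bag, 2, 0.8, top_r = 0.7)
  check_grads(gs$grads, function(p)
    petmil:::bag_grad_subtype(petmil:::model_set_params(model, p),
                              bag, 2, 0.8, top_r = 0.7)$loss)
})

make_toy_bags <- function(n_pos = 6, n_neg = 6, K = 6, seed = 70) {
  set.seed(seed)
  bags <- list()
  for (i in seq_len(n_pos + n_neg)) {
    pos <- i <= n_pos
    X <- matrix(rnorm(256 * K, sd = 0.5), 256, K)
    if (pos) {  # plant a bright patch on two "signal" slices
      patch <- as.vector(outer(5:9, (5:9 - 1) * 16, "+"))
      X[patch, 1:2] <- X[patch, 1:2] + 3
    }
    bags[[i]] <- structure(list(
      subject_id = sprintf("B%02d", i),
      slices = X, dim_slice = c(16L, 16L), K = as.integer(K),
      covariates = list(age = 50, sex = "M"),
      label = if (pos) AE4[(i - 1) %% 4 + 1] else "HC", split = "train"),
      class = "slice_bag")
  }
  bags
}

test_that("binary training reduces the loss and is seed-reproducible", {
  bags <- make_toy_bags()
  cfg <- train_config(epochs = 6, seed = 71, batch_bags = 3)
  fit1 <- train_binary(bags, cfg, small_model(seed = 72))
  expect_lt(tail(fit1$history$loss, 1), fit1$history$loss[1])
  expect_true(all(is.finite(fit1$history$loss)))
  expect_equal(nrow(fit1$history), 6)

  fit2 <- train_binary(bags, cfg, small_model(seed = 72))
  expect_identical(tail(fit1$history$loss, 1), tail(fit2$history$loss, 1))
  p1 <- vapply(bags, function(b) bag_forward(b, fit1$model)$p_binary, 1)
  p2 <- vapply(bags, function(b) bag_forward(b, fit2$model)$p_binary, 1)
  expect_identical(p1, p2)
})

test_that("class weights are inverse frequencies from the training labels", {
  labs <- c(rep("pos", 30), rep("neg", 10))
  w <- inverse_freq_weights(labs)
  expect_equal(w[["pos"]], 40 / (2 * 30))
  expect_equal(w[["neg"]], 40 / (2 * 10))
  expect_equal(sum(w[labs]), length(labs))
})

test_that("binary training rejects degenerate inputs", {
  bags <- make_toy_bags(n_pos = 0, n_neg = 4)
  expect_error(train_binary(bags, train_config(epochs = 1),
                            small_model()), "both positive and negative")
  expect_error(train_binary(list(), train_config(epochs = 1)), "empty")
})

test_that("subtype training fits, restricts to observed classes, reproduces", {
  bags <- make_toy_bags(n_pos = 10, n_neg = 0, seed = 80)
  # give the subtypes distinct signal locations so the head can learn
  for (i in seq_along(bags)) {
    cl <- match(bags[[i]]$label, AE4)
    patch <- as.vector(outer(1:4 + 3 * (cl - 1), (1:4 - 1) * 16, "+"))
    bags[[i]]$slices[patch, 3] <- bags[[i]]$slices[patch, 3] + 4
  }
  model <- small_model(seed = 81)
  cfg <- train_config(epochs = 5, seed = 82)
  fit <- train_subtype(bags, model, cfg)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  fit2 <- train_subtype(bags, model, cfg)
  expect_identical(tail(fit$history$loss, 1), tail(fit2$history$loss, 1))

  # class set restriction warns and shrinks the head
  two <- Filter(function(b) b$label %in% AE4[1:2], bags)
  expect_warning(fit3 <- train_subtype(two, model,
                                       train_config(epochs = 1, seed = 83)),
                 "restricting")
  expect_identical(fit3$model$subtype_classes,
                   AE4[AE4 %in% vapply(two, function(b) b$label, "")])
  p <- subtype_forward(two[[1]], fit3$model)
  expect_length(p, length(fit3$model$subtype_classes))

  # non-subtype bags are dropped with a message
  mixed <- make_toy_bags(n_pos = 4, n_neg = 2, seed = 84)
  expect_message(train_subtype(mixed, model,
                               train_config(epochs = 1, seed = 85)),
                 "dropping")
})

test_that("checkpoints round-trip the trained model", {
  bags <- make_toy_bags(n_pos = 3, n_neg = 3, seed = 90)
  fit <- train_binary(bags, train_config(epochs = 2, seed = 91),
                      small_model(seed = 92))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  back <- load_checkpoint(path)
  p0 <- vapply(bags, function(b) bag_forward(b, fit$model)$p_binary, 1)
  p1 <- vapply(bags, function(b) bag_forward(b, back)$p_binary, 1)
  expect_equal(p0, p1, tolerance = 1e-12)
})
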