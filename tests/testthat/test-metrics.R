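test_that("binary metrics reproduce hand confusion-table arithmetic", {
  # TP=9 FN=1 TN=8 FP=2 at threshold 0.5
  y <- c(rep(1, 10), rep(0, 10))
  p <- c(rep(0.9, 9), 0.1, rep(0.2, 8), 0.8, 0.8)
  m <- binary_metrics(y, p)
  expect_equal(m$sen, 0.9)
  expect_equal(m$spe, 0.8)
  expect_equal(m$acc, 0.85)
  expect_equal(m$precision, 9 / 11)
  expect_equal(m$f1, 2 * (9 / 11) * 0.9 / ((9 / 11) + 0.9))
  expect_equal(unname(as.vector(m$confusion)), c(8, 1, 2, 9))
  expect_equal(m$n, 20)
})

test_that("metric/confusion consistency holds on fuzzed inputs", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    y <- rbinom(n, 1, 0.5)
    p <- runif(n)
    thr <- runif(1, 0.2, 0.8)
    m <- binary_metrics(y, p, thr)
    cm <- m$confusion
    expect_equal(sum(cm), n)
    TP <- cm["pos", "pos"]; FN <- cm["pos", "neg"]
    TN <- cm["neg", "neg"]; FP <- cm["neg", "pos"]
    expect_equal(m$acc, (TP + TN) / n, tolerance = 1e-12)
    if (TP + FN > 0) expect_equal(m$sen, TP / (TP + FN), tolerance = 1e-12)
    if (TN + FP > 0) expect_equal(m$spe, TN / (TN + FP), tolerance = 1e-12)
    if (TP + FP > 0)
      expect_equal(m$precision, TP / (TP + FP), tolerance = 1e-12)
    else expect_identical(m$precision, 0)
  }
})

test_that("zero-division conventions: no positive predictions give PRE=F1=0", {
  y <- c(1, 1, 0, 0)
  p <- c(0.1, 0.2, 0.05, 0.3)
  m <- binary_metrics(y, p, threshold = 0.5)
  expect_identical(m$precision, 0)
  expect_identical(m$f1, 0)
  expect_equal(m$sen, 0)
})

test_that("AUC: trapezoid equals Mann-Whitney; edge conventions hold", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(c(8, 20, 51), 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    roc <- roc_points(y, p)
    expect_equal(petmil:::auc_trapezoid(roc), auc_mannwhitney_check(y, p),
                 tolerance = 1e-9)
    # antisymmetry under score reversal
    expect_equal(auc_mannwhitney_check(y, -p),
                 1 - auc_mannwhitney_check(y, p), tolerance = 1e-12)
  }
  # perfect separation
  expect_equal(binary_metrics(c(0, 0, 1, 1), c(.1, .2, .8, .9))$auc, 1)
  # all-tied scores
  expect_equal(auc_mannwhitney_check(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  # single-class truth: AUC undefined, not a number
  expect_true(is.na(binary_metrics(c(1, 1), c(0.2, 0.9))$auc))
  expect_error(auc_mannwhitney_check(c(1, 1), c(0.2, 0.9)), "single-class")
})

test_that("trapezoid AUC agrees with an independent ROC implementation", {
  set.seed(13)
  y <- rbinom(40, 1, 0.4)
  p <- runif(40)
  ours <- binary_metrics(y, p)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("multiclass metrics: accuracy, macro recall and confusion", {
  y <- c("A", "A", "B", "B", "C", "C")
  expect_equal(multiclass_metrics(y, y, c("A", "B", "C"))$acc, 1)

  yp <- c("A", "B", "B", "B", "C", "A")
  m <- multiclass_metrics(y, yp, c("A", "B", "C"))
  expect_equal(m$acc, 4 / 6)
  expect_equal(m$macro_acc, mean(c(1 / 2, 1, 1 / 2)))
  expect_equal(unname(rowSums(m$confusion)), c(2, 2, 2))
  expect_equal(sum(m$confusion), 6)
  expect_equal(nrow(m$per_class), 3)
  expect_error(multiclass_metrics(y, c(yp[-6], "D"), c("A", "B", "C")),
               "outside")

  # uniform random predictions over 4 classes: ACC near 1/4
  set.seed(17)
  yt <- sample(AE4, 2000, replace = TRUE)
  yr <- sample(AE4, 2000, replace = TRUE)
  acc <- multiclass_metrics(yt, yr, AE4)$acc
  expect_lt(abs(acc - 0.25), 3 * sqrt(0.25 * 0.75 / 2000))
})

test_that("heatmap export collects attention rows and writes artifacts", {
  model <- small_model(seed = 99)
  bags <- lapply(1:4, function(i)
    random_bag(K = 6, size = c(16, 16), seed = 100 + i,
               id = sprintf("S%02d", i), label = c("NMDAR", "HC")[i %% 2 + 1]))
  states <- lapply(bags, function(b) bag_forward(b, model)$attention)
  man <- data.frame(subject_id = vapply(bags, `[[`, "", "subject_id"),
                    class = vapply(bags, `[[`, "", "label"))
  M <- export_heatmap(states, man)
  expect_equal(dim(M), c(4L, 6L))
  expect_equal(unname(rowSums(M)), rep(1, 4), tolerance = 1e-6)
  expect_true(all(M >= 0))
  # rows are exactly the attention vectors produced at inference
  expect_equal(M[man$subject_id[order(man$class)][1], ],
               states[[order(man$class)[1]]]$a, tolerance = 1e-15,
               ignore_attr = TRUE)

  pre <- file.path(withr::local_tempdir(), "hm")
  export_heatmap(states, man, out_prefix = pre)
  expect_true(file.exists(paste0(pre, ".csv")))
  expect_true(file.exists(paste0(pre, ".png")))
  back <- read.csv(paste0(pre, ".csv"), check.names = FALSE)
  expect_equal(unname(rowSums(back[, -1])), rep(1, 4), tolerance = 1e-6)

  st2 <- states; st2[[2]]$a <- st2[[2]]$a[1:3]
  expect_error(export_heatmap(st2, man), "inconsistent")
})
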