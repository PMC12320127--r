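# ---------------------------------------------------------------------------
# Evaluation metric suite: ACC / SEN / SPE / precision / F1 from the
# confusion table, ROC points and trapezoid AUC, with a Mann-Whitney AUC as
# an internal cross-check. Zero-division convention: precision and F1 are 0
# when there are no positive predictions; AUC with single-class truth is
# undefined (NA), never 0.5.
# ---------------------------------------------------------------------------

#' ROC curve points
#'
#' Thresholds are the sorted unique scores plus sentinels, predicting
#' positive when `score >= threshold`.
#'
#' @param y_true 0/1 labels.
#' @param y_prob Scores/probabilities.
#' @return data.frame with `threshold`, `fpr`, `tpr`, sorted by increasing
#'   fpr.
#' @export
roc_points <- function(y_true, y_prob) {
  stopifnot(length(y_true) == length(y_prob), all(y_true %in% 0:1))
  thr <- c(Inf, sort(unique(y_prob), decreasing = TRUE), -Inf)
  P <- sum(y_true == 1); N <- sum(y_true == 0)
  tpr <- vapply(thr, function(t) if (P == 0) NA_real_ else
    sum(y_prob >= t & y_true == 1) / P, numeric(1))
  fpr <- vapply(thr, function(t) if (N == 0) NA_real_ else
    sum(y_prob >= t & y_true == 0) / N, numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

auc_trapezoid <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' AUC via the normalized Mann-Whitney U statistic
#'
#' Tie-corrected: equals the probability that a random positive scores above
#' a random negative, counting ties as 1/2. Used as the independent oracle
#' for the trapezoid ROC AUC; the two agree to numerical precision.
#'
#' @param y_true 0/1 labels (both classes required).
#' @param y_prob Scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_mannwhitney_check <- function(y_true, y_prob) {
  P <- sum(y_true == 1); N <- sum(y_true == 0)
  if (P == 0 || N == 0) stop("AUC undefined for single-class input")
  r <- rank(y_prob)
  (sum(r[y_true == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Binary classification metric suite
#'
#' Computes the confusion table at `threshold` and the derived metrics:
#' `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`, `PRE = TP/(TP+FP)`,
#' `F1 = 2*PRE*SEN/(PRE+SEN)`, `ACC = (TP+TN)/n`, plus trapezoid AUC over
#' the empirical ROC. `PRE` and `F1` are 0 when `TP+FP = 0`; AUC is `NA`
#' when only one class is present in `y_true`.
#'
#' @param y_true 0/1 labels.
#' @param y_prob Probabilities in `[0, 1]` (any scores accepted for ROC).
#' @param threshold Decision threshold (default 0.5); positive when
#'   `y_prob >= threshold`.
#' @return An `eval_report` list: `acc`, `sen`, `spe`, `precision`, `f1`,
#'   `auc`, `roc`, `confusion` (2x2, rows = truth), `n`, `threshold`.
#' @export
binary_metrics <- function(y_true, y_prob, threshold = 0.5) {
  stopifnot(length(y_true) > 0, length(y_true) == length(y_prob),
            all(y_true %in% 0:1))
  pred <- as.integer(y_prob >= threshold)
  TP <- sum(pred == 1 & y_true == 1); FN <- sum(pred == 0 & y_true == 1)
  TN <- sum(pred == 0 & y_true == 0); FP <- sum(pred == 1 & y_true == 0)
  n <- length(y_true)
  sen <- if (TP + FN == 0) NA_real_ else TP / (TP + FN)
  spe <- if (TN + FP == 0) NA_real_ else TN / (TN + FP)
  pre <- if (TP + FP == 0) 0 else TP / (TP + FP)
  f1 <- if (TP + FP == 0 || !isTRUE(pre + sen > 0)) 0 else
    2 * pre * sen / (pre + sen)
  roc <- NULL; auc <- NA_real_
  if (length(unique(y_true)) == 2) {
    roc <- roc_points(y_true, y_prob)
    auc <- auc_trapezoid(roc)
  }
  confusion <- matrix(c(TN, FN, FP, TP), 2, 2,
                      dimnames = list(truth = c("neg", "pos"),
                                      pred = c("neg", "pos")))
  structure(list(acc = (TP + TN) / n, sen = sen, spe = spe, precision = pre,
                 f1 = f1, auc = auc, roc = roc, confusion = confusion,
                 n = n, threshold = threshold),
            class = "eval_report")
}

#' Multiclass classification metrics
#'
#' Overall accuracy, macro accuracy (mean per-class recall), per-class
#' one-vs-rest SEN/SPE/precision/F1, and the CxC confusion table
#' (rows = truth).
#'
#' @param y_true,y_pred Label vectors within `classes`.
#' @param classes Class set.
#' @return An `eval_report` with `acc`, `macro_acc`, `per_class`
#'   (data.frame), `confusion`, `n`.
#' @export
multiclass_metrics <- function(y_true, y_pred, classes = sort(unique(y_true))) {
  if (!all(c(y_true, y_pred) %in% classes)) stop("label outside class set")
  y_true <- factor(y_true, classes); y_pred <- factor(y_pred, classes)
  confusion <- table(truth = y_true, pred = y_pred)
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    m <- binary_metrics(as.integer(y_true == cl),
                        as.integer(y_pred == cl), threshold = 0.5)
    data.frame(class = cl, sen = m$sen, spe = m$spe,
               precision = m$precision, f1 = m$f1)
  }))
  recalls <- diag(confusion) / rowSums(confusion)
  structure(list(acc = mean(y_true == y_pred),
                 macro_acc = mean(recalls, na.rm = TRUE),
                 per_class = per_class,
                 confusion = unclass(confusion), n = length(y_true)),
            class = "eval_report")
}

#' Export the patients-by-slices attention heatmap
#'
#' Collects per-bag attention weight vectors into a P x K matrix (rows are
#' patients, columns are 0-based axial slice indices; each row sums to 1 —
#' the rows are exactly the attention vectors produced at inference, with no
#' renormalization). Optionally writes a CSV and a rendered PNG with
#' brightness proportional to attention weight, patients grouped by class.
#'
#' @param states List of `attention_state`s (or `bag_prediction`s), one per
#'   patient.
#' @param manifest Manifest data.frame aligned with `states` (used for row
#'   labels and class grouping); optional.
#' @param out_prefix If non-NULL, writes `<out_prefix>.csv` and
#'   `<out_prefix>.png`.
#' @return The heatmap matrix (invisibly when writing).
#' @export
export_heatmap <- function(states, manifest = NULL, out_prefix = NULL) {
  avecs <- lapply(states, function(s) {
    if (inherits(s, "bag_prediction")) s <- s$attention
    s$a
  })
  K <- unique(lengths(avecs))
  if (length(K) != 1) stop("inconsistent slice count K across bags")
  M <- do.call(rbind, avecs)
  colnames(M) <- seq_len(K) - 1L
  if (!is.null(manifest)) {
    rownames(M) <- manifest$subject_id
    ord <- order(manifest$class)
    M <- M[ord, , drop = FALSE]
    cls <- manifest$class[ord]
  } else {
    rownames(M) <- names(states) %||% paste0("P", seq_len(nrow(M)))
    cls <- NULL
  }
  if (!is.null(out_prefix)) {
    utils::write.csv(data.frame(subject_id = rownames(M), M,
                                check.names = FALSE),
                     paste0(out_prefix, ".csv"), row.names = FALSE)
    grDevices::png(paste0(out_prefix, ".png"), width = 900, height = 600)
    graphics::image(x = seq_len(K) - 1L, y = seq_len(nrow(M)), z = t(M),
                    col = grDevices::gray.colors(256, 0, 1),
                    xlab = "axial slice (inferior to superior)",
                    ylab = "patient", main = "Attention weights (rows sum to 1)")
    if (!is.null(cls)) {
      br <- which(diff(as.integer(factor(cls))) != 0) + 0.5
      graphics::abline(h = br, col = "red", lwd = 0.8)
    }
    grDevices::dev.off()
    return(invisible(M))
  }
  M
}

`%||%` <- function(a, b) if (is.null(a)) b else a
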