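## k-fold cross-validation with leakage control, confusion metrics and
## ROC / precision-recall curves.

#' Partition positive pairs into k folds
#'
#' Positive pairs are shuffled by seed and split as evenly as possible
#' (fold sizes differ by at most 1); each fold serves once as the test
#' set.
#'
#' @param associations [md_associations].
#' @param k fold count (>= 2).
#' @param seed integer seed.
#' @return list of class `fold_plan`: `k`, `seed`, `pairs` (index matrix
#'   of positives), `fold` (fold assignment per pair).
#' @export
make_folds <- function(associations, k = 5L, seed = 1L) {
  stopifnot(inherits(associations, "md_associations"))
  k <- as.integer(k)
  pos <- which(associations$values == 1, arr.ind = TRUE)
  pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE]
  n <- nrow(pos)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of positive pairs (", n, ")")
  perm <- with_seed(stage_seed(seed, "folds"), sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), length.out = n)
  structure(list(k = k, seed = as.integer(seed),
                 pairs = unname(pos), fold = fold),
            class = "fold_plan")
}

#' Confusion-matrix metrics
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`
#' and F1 `2*Pre*R/(Pre+R)`.  Ratios with zero denominators are reported
#' as 0 with a warning.
#'
#' @param tp,tn,fp,fn non-negative confusion counts.
#' @return named list `acc`, `pre`, `r`, `f1`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("at least one count must be positive")
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting 0")
      return(0)
    }
    num / den
  }
  acc <- (tp + tn) / total
  pre <- safe_ratio(tp, tp + fp, "precision")
  r <- safe_ratio(tp, tp + fn, "recall")
  f1 <- if (pre + r == 0) {
    warning("F1 undefined (zero denominator); reporting 0")
    0
  } else 2 * pre * r / (pre + r)
  list(acc = acc, pre = pre, r = r, f1 = f1)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores; the AUC equals the
#' Mann-Whitney concordance probability with ties counted 0.5.
#'
#' @param scores numeric score vector.
#' @param labels 0/1 labels (both classes present).
#' @return list with `curve` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to compute a ROC curve")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  ## Mann-Whitney via midranks: handles ties exactly
  rk <- rank(scores)
  auc <- (sum(rk[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1)
  fp <- cumsum(labels[ord] == 0)
  keep <- c(diff(scores[ord]) != 0, TRUE)  # one point per score level
  curve <- data.frame(fpr = c(0, fp[keep] / n_neg),
                      tpr = c(0, tp[keep] / n_pos))
  list(curve = curve, auc = auc)
}

#' Precision-recall curve and AUPR
#'
#' Threshold sweep over unique scores; AUPR by average-precision style
#' step integration (precision summed over recall increments).
#'
#' @param scores numeric score vector.
#' @param labels 0/1 labels (at least one positive).
#' @return list with `curve` (data frame `recall`, `precision`) and
#'   `aupr`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("at least one positive label is required")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  keep <- c(diff(scores[ord]) != 0, TRUE)
  tpk <- tp[keep]; fpk <- fp[keep]
  precision <- tpk / (tpk + fpk)
  recall <- tpk / n_pos
  ## average precision: sum precision * recall increment
  aupr <- sum(precision * diff(c(0, recall)))
  list(curve = data.frame(recall = recall, precision = precision),
       aupr = aupr)
}

#' Cross-validate the full pipeline on one dataset
#'
#' For each fold the held-out positive pairs are removed from the
#' association matrix before anything downstream is computed: GIP
#' kernels, fused similarities, feature graphs, VGAE embeddings, the
#' attention refinement graph and the forest all see training positives
#' only.  Each fold is tested on its held-out positives plus an
#' equal-sized seeded sample of unknown pairs (disjoint from training
#' negatives).  Classification metrics use a score threshold of 0.5;
#' ROC/PR curves are computed from the pooled test scores.
#'
#' @param data list with `associations`, `sequences`, `drug_similarity`
#'   (as produced by [generate_synthetic()] or assembled from loaders).
#' @param params [pipeline_params()].
#' @param k fold count (default 5).
#' @param seed integer seed driving folds and negative sampling.
#' @param verbose print per-fold progress.
#' @return list of class `md_metrics`: `per_fold` data frame, `mean`,
#'   `sd`, `pooled` (ROC/PR curves and pooled AUC/AUPR), `folds`.
#' @export
cross_validate <- function(data, params = pipeline_params(), k = 5L,
                           seed = 1L, verbose = FALSE) {
  data <- align_dataset(data)
  assoc <- data$associations
  plan <- make_folds(assoc, k, seed)

  ## sequence/structure similarities carry no association information, so
  ## they are computed once outside the fold loop; the profile baseline
  ## never consumes them
  mss <- if (!is.null(data$sequences) && params$features == "embedding")
    sequence_similarity_matrix(data$sequences) else NULL
  dss <- data$drug_similarity

  per_fold <- vector("list", plan$k)
  pooled_scores <- numeric(0)
  pooled_labels <- numeric(0)

  for (f in seq_len(plan$k)) {
    test_pairs <- plan$pairs[plan$fold == f, , drop = FALSE]
    train_values <- assoc$values
    train_values[test_pairs] <- 0
    train_assoc <- md_associations(train_values, assoc$microbe_ids,
                                   assoc$drug_ids)
    ## leakage guard: no test positive may survive in any training input
    stopifnot(all(train_assoc$values[test_pairs] == 0))

    fold_seed <- stage_seed(seed, paste0("fold", f))
    test_neg <- sample_negatives(assoc, seed = stage_seed(fold_seed, "testneg"),
                                 n_exact = nrow(test_pairs))
    fit <- fit_pipeline(train_assoc, mss = mss, dss = dss, params = params,
                        seed = fold_seed,
                        exclude_pairs = rbind(test_pairs, test_neg))

    eval_pairs <- rbind(test_pairs, test_neg)
    eval_labels <- c(rep(1, nrow(test_pairs)), rep(0, nrow(test_neg)))
    scores <- predict_pairs(fit, eval_pairs)

    pred_pos <- scores >= 0.5
    cm <- suppressWarnings(confusion_metrics(
      tp = sum(pred_pos & eval_labels == 1),
      tn = sum(!pred_pos & eval_labels == 0),
      fp = sum(pred_pos & eval_labels == 0),
      fn = sum(!pred_pos & eval_labels == 1)))
    roc <- roc_auc(scores, eval_labels)
    pr <- pr_auc(scores, eval_labels)
    per_fold[[f]] <- data.frame(fold = f, acc = cm$acc, pre = cm$pre,
                                r = cm$r, f1 = cm$f1, auc = roc$auc,
                                aupr = pr$aupr)
    pooled_scores <- c(pooled_scores, scores)
    pooled_labels <- c(pooled_labels, eval_labels)
    if (verbose)
      message(sprintf("fold %d/%d: AUC %.3f AUPR %.3f", f, plan$k,
                      roc$auc, pr$aupr))
  }

  per_fold <- do.call(rbind, per_fold)
  metric_cols <- c("acc", "pre", "r", "f1", "auc", "aupr")
  pooled_roc <- roc_auc(pooled_scores, pooled_labels)
  pooled_pr <- pr_auc(pooled_scores, pooled_labels)
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[metric_cols]),
    sd = apply(per_fold[metric_cols], 2, sd),
    pooled = list(roc = pooled_roc, pr = pooled_pr),
    folds = plan
  ), class = "md_metrics")
}

#' @export
print.md_metrics <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%d test pairs pooled)\n",
              x$folds$k, 2L * nrow(x$folds$pairs)))
  m <- x$mean; s <- x$sd
  for (k in names(m))
    cat(sprintf("  %-4s %.4f +/- %.4f\n", toupper(k), m[[k]], s[[k]]))
  invisible(x)
}

#' @importFrom stats sd setNames
NULL
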