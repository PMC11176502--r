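## Pair assembly, negative sampling, random-forest training and candidate
## ranking.  The forest is the classical bagged-tree ensemble; association
## scores are the fraction of trees voting for the positive class.

#' Random-forest configuration
#'
#' @param n_estimators number of trees (default 100).
#' @param max_depth optional maximum node count limit (`NULL` = grow to
#'   purity, the classical default).
#' @param seed integer seed.
#' @return validated list of class `forest_config`.
#' @export
forest_config <- function(n_estimators = 100L, max_depth = NULL, seed = 1L) {
  cfg <- list(n_estimators = as.integer(n_estimators),
              max_depth = if (is.null(max_depth)) NULL else
                as.integer(max_depth),
              seed = as.integer(seed))
  if (cfg$n_estimators < 1) stop("n_estimators must be >= 1")
  class(cfg) <- "forest_config"
  cfg
}

#' Assemble labelled pair samples from embeddings
#'
#' One positive sample per association, one negative per provided unknown
#' pair; the feature vector of pair `(i, j)` is the concatenation of the
#' microbe and drug embeddings.
#'
#' @param zm,zd embedding matrices row-aligned with the association ids.
#' @param associations [md_associations].
#' @param negatives integer matrix (or 2-column data frame) of
#'   `(microbe_index, drug_index)` pairs with no known association.
#' @return list with `features` (matrix), `labels` (0/1 vector), `pairs`
#'   (index matrix).
#' @export
assemble_pairs <- function(zm, zd, associations, negatives = NULL) {
  stopifnot(inherits(associations, "md_associations"))
  a <- associations$values
  if (nrow(zm) != nrow(a) || nrow(zd) != ncol(a))
    stop("embeddings not aligned with association matrix")
  pos <- which(a == 1, arr.ind = TRUE)
  pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE]
  if (!is.null(negatives) && nrow(negatives) > 0) {
    negatives <- as.matrix(negatives)
    if (any(a[negatives] == 1))
      stop("a provided negative pair is a known association")
    pairs <- rbind(pos, negatives)
    labels <- c(rep(1, nrow(pos)), rep(0, nrow(negatives)))
  } else {
    pairs <- pos
    labels <- rep(1, nrow(pos))
  }
  features <- cbind(zm[pairs[, 1], , drop = FALSE],
                    zd[pairs[, 2], , drop = FALSE])
  colnames(features) <- c(paste0("m", seq_len(ncol(zm))),
                          paste0("d", seq_len(ncol(zd))))
  rownames(features) <- NULL
  list(features = features, labels = labels, pairs = unname(pairs))
}

#' Sample negative (unknown) pairs
#'
#' Uniform sample without replacement from the zero entries of the
#' association matrix, excluding any held-out pairs; reproducible by
#' seed.
#'
#' @param associations [md_associations].
#' @param ratio negatives per positive (default 1, balanced).
#' @param seed integer seed.
#' @param exclude optional integer matrix of `(i, j)` pairs to exclude
#'   (e.g. test-fold pairs).
#' @param n_exact optional exact number of negatives, overriding `ratio`.
#' @return integer matrix with columns `(microbe_index, drug_index)`.
#' @export
sample_negatives <- function(associations, ratio = 1, seed = 1L,
                             exclude = NULL, n_exact = NULL) {
  stopifnot(inherits(associations, "md_associations"))
  a <- associations$values
  zeros <- which(a == 0)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    excl_lin <- (as.matrix(exclude)[, 2] - 1L) * nrow(a) +
      as.matrix(exclude)[, 1]
    zeros <- setdiff(zeros, excl_lin)
  }
  n_want <- if (!is.null(n_exact)) as.integer(n_exact) else
    as.integer(round(ratio * sum(a)))
  if (n_want > length(zeros))
    stop("requested ", n_want, " negatives but only ", length(zeros),
         " unknown pairs are available")
  chosen <- with_seed(seed, sample(zeros, n_want))
  cbind(microbe_index = ((chosen - 1L) %% nrow(a)) + 1L,
        drug_index = ((chosen - 1L) %/% nrow(a)) + 1L)
}

#' Train the random-forest pair classifier
#'
#' Bagged ensemble of `n_estimators` decision trees, each grown on a
#' bootstrap sample of the training pairs.
#'
#' @param samples output of [assemble_pairs()] (both classes present).
#' @param config [forest_config].
#' @return fitted `randomForest` model.
#' @export
train_forest <- function(samples, config = forest_config()) {
  labels <- factor(samples$labels, levels = c(0, 1))
  if (length(unique(samples$labels)) < 2L)
    stop("training data must contain both classes")
  with_seed(stage_seed(config$seed, "forest"), {
    if (is.null(config$max_depth)) {
      randomForest::randomForest(x = samples$features, y = labels,
                                 ntree = config$n_estimators)
    } else {
      randomForest::randomForest(x = samples$features, y = labels,
                                 ntree = config$n_estimators,
                                 maxnodes = config$max_depth)
    }
  })
}

#' Score pairs by tree vote share
#'
#' The association score of a pair is the fraction of ensemble trees
#' voting for the positive class, in `[0, 1]`.
#'
#' @param model fitted forest from [train_forest()].
#' @param samples output of [assemble_pairs()].
#' @return numeric score vector.
#' @export
score_pairs <- function(model, samples) {
  if (!inherits(model, "randomForest")) stop("model is not a fitted forest")
  as.numeric(predict(model, samples$features, type = "vote",
                     norm.votes = TRUE)[, "1"])
}

#' Rank candidate microbes for a drug
#'
#' Scores every microbe without a known association to the drug and
#' returns the top `k` in descending score order, ties broken by id
#' order.
#'
#' @param model fitted forest.
#' @param zm,zd embeddings aligned with the association ids.
#' @param associations [md_associations].
#' @param drug_id drug to rank candidates for.
#' @param k number of candidates (default 10).
#' @return data frame with columns `microbe`, `score`.
#' @export
rank_candidates <- function(model, zm, zd, associations, drug_id, k = 10L) {
  stopifnot(inherits(associations, "md_associations"))
  j <- match(drug_id, associations$drug_ids)
  if (is.na(j)) stop("unknown drug id: ", drug_id)
  cand <- which(associations$values[, j] == 0)
  if (length(cand) == 0L)
    return(data.frame(microbe = character(0), score = numeric(0)))
  features <- cbind(zm[cand, , drop = FALSE],
                    matrix(zd[j, ], length(cand), ncol(zd), byrow = TRUE))
  colnames(features) <- c(paste0("m", seq_len(ncol(zm))),
                          paste0("d", seq_len(ncol(zd))))
  scores <- as.numeric(predict(model, features, type = "vote",
                               norm.votes = TRUE)[, "1"])
  ord <- order(-scores, associations$microbe_ids[cand])
  top <- head(ord, k)
  data.frame(microbe = associations$microbe_ids[cand[top]],
             score = scores[top], row.names = NULL)
}
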