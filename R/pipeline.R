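## End-to-end orchestration: similarity fusion -> feature graphs -> VGAE
## -> attention refinement -> random forest.

#' Pipeline hyperparameters
#'
#' Bundles the tuned defaults of the whole method: microbe/drug
#' binarization thresholds 0.8 / 0.7, smoothing window 5, hidden and
#' latent width 128, learning rate 0.01, 100 trees, balanced negative
#' sampling and 4 attention heads of width `latent/heads`.
#'
#' @param mth,dth microbe/drug binarization thresholds.
#' @param window smoothing window size (odd).
#' @param gamma_prime GIP bandwidth scale.
#' @param encoder [encoder_config].
#' @param attention [attention_config]; `out_dim` defaults to
#'   `encoder$latent_dim / heads` so refinement preserves width.
#' @param forest [forest_config].
#' @param negative_ratio training negatives per positive.
#' @param use_recon,use_kl,use_attention ablation switches (all `TRUE`
#'   for the full model; all `FALSE` is the untrained "blank" variant).
#' @param features `"embedding"` for the full model or `"profile"` for
#'   the degenerate baseline that feeds raw association profiles to the
#'   forest.
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(mth = 0.8, dth = 0.7, window = 5L,
                            gamma_prime = 1,
                            encoder = encoder_config(),
                            attention = NULL,
                            forest = forest_config(),
                            negative_ratio = 1,
                            use_recon = TRUE, use_kl = TRUE,
                            use_attention = TRUE,
                            features = c("embedding", "profile")) {
  features <- match.arg(features)
  if (is.null(attention)) {
    heads <- 4L
    attention <- attention_config(heads = heads,
                                  out_dim = max(1L, encoder$latent_dim %/% heads))
  }
  if (mth <= 0 || mth > 1 || dth <= 0 || dth > 1)
    stop("thresholds must lie in (0, 1]")
  structure(list(mth = mth, dth = dth, window = as.integer(window),
                 gamma_prime = gamma_prime, encoder = encoder,
                 attention = attention, forest = forest,
                 negative_ratio = negative_ratio,
                 use_recon = use_recon, use_kl = use_kl,
                 use_attention = use_attention, features = features),
            class = "pipeline_params")
}

#' Align sequences and similarity inputs with the association ids
#'
#' Edge lists order entities by first appearance and omit entities with
#' no associations, whereas FASTA and matrix inputs may carry more
#' entities in a different order.  This subsets and reorders the
#' sequence set and the drug similarity matrix to the association ids,
#' erroring when an association entity lacks its input.
#'
#' @param data list with `associations` and optional `sequences`,
#'   `drug_similarity`.
#' @return the same list with aligned components.
#' @export
align_dataset <- function(data) {
  assoc <- data$associations
  stopifnot(inherits(assoc, "md_associations"))
  if (!is.null(data$sequences)) {
    missing <- setdiff(assoc$microbe_ids, names(data$sequences))
    if (length(missing) > 0)
      stop("no sequence for microbe(s): ",
           paste(head(missing, 5), collapse = ", "))
    data$sequences <- data$sequences[assoc$microbe_ids]
  }
  if (!is.null(data$drug_similarity)) {
    ids <- data$drug_similarity$ids
    missing <- setdiff(assoc$drug_ids, ids)
    if (length(missing) > 0)
      stop("no structural similarity for drug(s): ",
           paste(head(missing, 5), collapse = ", "))
    ord <- match(assoc$drug_ids, ids)
    data$drug_similarity <- md_similarity(
      data$drug_similarity$values[ord, ord, drop = FALSE], assoc$drug_ids,
      kind = "structure", require_unit_diag = FALSE)
  }
  data
}

#' Build the encoder inputs for one entity side
#'
#' Fuses the primary similarity with the GIP kernel computed from the
#' association matrix, smooths rows, binarizes, and assembles the
#' adjacency + feature matrix.
#'
#' @param primary [md_similarity] (sequence-based for microbes,
#'   structure-based for drugs); `NULL` falls back to the GIP kernel
#'   alone.
#' @param associations [md_associations] (training-fold only during
#'   cross-validation, so the GIP kernel never sees test edges).
#' @param side `"microbe"` or `"drug"`.
#' @param params [pipeline_params].
#' @return list with `graph` ([build_feature_graph()] output) and
#'   `fused`.
#' @export
build_side_inputs <- function(primary, associations,
                              side = c("microbe", "drug"),
                              params = pipeline_params()) {
  side <- match.arg(side)
  profiles <- if (side == "microbe") associations$values else
    t(associations$values)
  ids <- if (side == "microbe") associations$microbe_ids else
    associations$drug_ids
  gip <- gip_similarity(profiles, ids,
                        gip_bandwidth(profiles, params$gamma_prime))
  fused <- if (is.null(primary)) gip else fuse_similarity(primary, gip)
  smoothed <- smooth_rows(fused, params$window)
  ## self-similarity is definitional; restore the unit diagonal the row
  ## smoothing averaged away so every entity keeps a self-loop after
  ## thresholding
  sm <- smoothed$values
  diag(sm) <- 1
  smoothed <- md_similarity(sm, smoothed$ids, kind = "smoothed")
  threshold <- if (side == "microbe") params$mth else params$dth
  binarized <- binarize_similarity(smoothed, threshold)
  graph <- build_feature_graph(binarized, fused, associations, side)
  list(graph = graph, fused = fused)
}

#' Fit the full model on one (training) association matrix
#'
#' Runs both entity-side VGAEs, optionally refines the embeddings with
#' bipartite multi-head attention, samples training negatives, and fits
#' the random forest.  All randomness derives from `seed`.
#'
#' @param associations training [md_associations].
#' @param mss microbe sequence similarity ([md_similarity]) or `NULL`.
#' @param dss drug structural similarity ([md_similarity]) or `NULL`.
#' @param params [pipeline_params].
#' @param seed integer seed.
#' @param exclude_pairs index pairs that must not be sampled as training
#'   negatives (held-out test pairs).
#' @return list of class `md_fit` with embeddings, the forest and the
#'   configuration used.
#' @export
fit_pipeline <- function(associations, mss = NULL, dss = NULL,
                         params = pipeline_params(), seed = 1L,
                         exclude_pairs = NULL) {
  stopifnot(inherits(associations, "md_associations"))
  if (params$features == "profile") {
    ## degenerate baseline: raw association profiles as features
    zm <- associations$values
    zd <- t(associations$values)
  } else {
    m_in <- build_side_inputs(mss, associations, "microbe", params)
    d_in <- build_side_inputs(dss, associations, "drug", params)
    enc_m <- params$encoder; enc_m$seed <- stage_seed(seed, "vgae_microbe")
    enc_d <- params$encoder; enc_d$seed <- stage_seed(seed, "vgae_drug")
    fit_m <- vgae_train(m_in$graph, enc_m,
                        use_recon = params$use_recon, use_kl = params$use_kl)
    fit_d <- vgae_train(d_in$graph, enc_d,
                        use_recon = params$use_recon, use_kl = params$use_kl)
    zm <- fit_m$embedding$z
    zd <- fit_d$embedding$z
    if (params$use_attention) {
      att <- params$attention; att$seed <- stage_seed(seed, "attention")
      ref <- refine_embeddings(zm, zd, associations, att)
      zm <- ref$zm
      zd <- ref$zd
    }
  }
  negatives <- sample_negatives(associations, ratio = params$negative_ratio,
                                seed = stage_seed(seed, "trainneg"),
                                exclude = exclude_pairs)
  samples <- assemble_pairs(zm, zd, associations, negatives)
  fc <- params$forest; fc$seed <- stage_seed(seed, "forest")
  model <- train_forest(samples, fc)
  structure(list(model = model, zm = zm, zd = zd,
                 associations = associations, params = params,
                 seed = as.integer(seed)),
            class = "md_fit")
}

#' Score arbitrary (microbe, drug) index pairs with a fitted model
#'
#' @param fit [fit_pipeline()] output.
#' @param pairs integer matrix of `(microbe_index, drug_index)` rows.
#' @return numeric vote-share scores in `[0, 1]`.
#' @export
predict_pairs <- function(fit, pairs) {
  stopifnot(inherits(fit, "md_fit"))
  pairs <- as.matrix(pairs)
  features <- cbind(fit$zm[pairs[, 1], , drop = FALSE],
                    fit$zd[pairs[, 2], , drop = FALSE])
  colnames(features) <- c(paste0("m", seq_len(ncol(fit$zm))),
                          paste0("d", seq_len(ncol(fit$zd))))
  as.numeric(predict(fit$model, features, type = "vote",
                     norm.votes = TRUE)[, "1"])
}

#' @export
print.md_fit <- function(x, ...) {
  cat(sprintf("md_fit: %d microbes x %d drugs, %s features, %d trees\n",
              nrow(x$zm), nrow(x$zd), x$params$features,
              x$model$ntree))
  invisible(x)
}
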