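## Multi-head graph attention refinement of microbe + drug embeddings on
## the bipartite association graph.  Attention follows the standard GAT
## formulation: per-head linear transform, additive attention scores over
## first-order neighbourhoods, softmax normalisation, LeakyReLU
## aggregation, heads concatenated.  Training minimises the weighted
## reconstruction cross-entropy of the training associations from refined
## embedding inner products; gradients are hand-derived.

#' Attention configuration
#'
#' @param heads number of attention heads (default 4).
#' @param out_dim per-head output width; defaults to `latent_dim / heads`
#'   in the pipeline so the refined width equals the latent width.
#' @param leaky_relu_slope negative slope for attention scores and
#'   aggregation (GAT convention 0.2).
#' @param epochs refinement training epochs (default 100).
#' @param learning_rate Adam step size (default 0.01).
#' @param seed integer seed.
#' @return validated list of class `attention_config`.
#' @export
attention_config <- function(heads = 4L, out_dim = 32L,
                             leaky_relu_slope = 0.2, epochs = 100L,
                             learning_rate = 0.01, seed = 1L) {
  cfg <- list(heads = as.integer(heads), out_dim = as.integer(out_dim),
              leaky_relu_slope = leaky_relu_slope,
              epochs = as.integer(epochs), learning_rate = learning_rate,
              seed = as.integer(seed))
  if (cfg$heads < 1) stop("heads must be >= 1")
  if (cfg$out_dim < 1) stop("out_dim must be >= 1")
  if (cfg$epochs < 0) stop("epochs must be >= 0")
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  class(cfg) <- "attention_config"
  cfg
}

#' Bipartite adjacency of the association graph
#'
#' Block matrix `[[0, A], [t(A), 0]]` with microbes first, then drugs.
#'
#' @param associations [md_associations] (training-fold associations
#'   during cross-validation).
#' @return `(i + j) x (i + j)` 0/1 matrix.
#' @export
build_bipartite_adjacency <- function(associations) {
  stopifnot(inherits(associations, "md_associations"))
  a <- associations$values
  i <- nrow(a); j <- ncol(a)
  m <- matrix(0, i + j, i + j)
  m[seq_len(i), i + seq_len(j)] <- a
  m[i + seq_len(j), seq_len(i)] <- t(a)
  ids <- c(associations$microbe_ids, associations$drug_ids)
  dimnames(m) <- list(ids, ids)
  m
}

#' Initialise multi-head attention weights
#'
#' One Glorot feature transform and one additive attention vector (split
#' into source and neighbour halves) per head.
#'
#' @param in_dim input embedding width.
#' @param config [attention_config].
#' @return list of class `attention_weights`: per-head `wz` (in x out) and
#'   `we` (length `2 * out_dim`).
#' @export
init_attention_weights <- function(in_dim, config = attention_config()) {
  with_seed(stage_seed(config$seed, "attention_init"), {
    heads <- lapply(seq_len(config$heads), function(h) {
      list(wz = glorot_init(in_dim, config$out_dim),
           we = as.numeric(glorot_init(2L * config$out_dim, 1L)))
    })
    structure(list(heads = heads), class = "attention_weights")
  })
}

#' Softmax-normalised attention coefficients for one head
#'
#' Raw scores `e_ij = LeakyReLU([Z'_i || Z'_j] . we)` for neighbouring
#' pairs, normalised by softmax over each node's first-order
#' neighbourhood.  Rows of isolated nodes are left at zero.
#'
#' @param transformed per-head transformed features `Z' = Z %*% wz`.
#' @param adjacency 0/1 graph adjacency.
#' @param we attention vector of length `2 * ncol(transformed)`.
#' @param slope LeakyReLU negative slope.
#' @return n x n matrix of coefficients; each non-isolated row sums to 1.
#' @export
attention_coefficients <- function(transformed, adjacency, we, slope = 0.2) {
  n <- nrow(transformed)
  if (nrow(adjacency) != n) stop("features not aligned with adjacency")
  d <- ncol(transformed)
  if (length(we) != 2L * d) stop("attention vector has wrong length")
  src <- as.numeric(transformed %*% we[seq_len(d)])
  dst <- as.numeric(transformed %*% we[d + seq_len(d)])
  e <- leaky_relu(outer(src, dst, "+"), slope)
  w <- exp(e) * (adjacency > 0)
  rs <- rowSums(w)
  keep <- rs > 0
  w[keep, ] <- w[keep, , drop = FALSE] / rs[keep]
  w
}

#' Single attention head: transform, attend, aggregate
#'
#' `out_i = LeakyReLU(sum_k a_ik * Z'_k)` over the first-order
#' neighbourhood.  Isolated nodes pass their transformed self-feature
#' through unchanged.
#'
#' @param features n x f input embeddings.
#' @param adjacency 0/1 adjacency.
#' @param head_weights list with `wz`, `we` for this head.
#' @param slope LeakyReLU negative slope.
#' @return n x out_dim matrix.
#' @export
gat_layer <- function(features, adjacency, head_weights, slope = 0.2) {
  zp <- features %*% head_weights$wz
  coef <- attention_coefficients(zp, adjacency, head_weights$we, slope)
  agg <- coef %*% zp
  iso <- rowSums(adjacency) == 0
  agg[iso, ] <- zp[iso, , drop = FALSE]
  leaky_relu(agg, slope)
}

#' Multi-head attention: concatenated per-head outputs
#'
#' @param features n x f input embeddings.
#' @param adjacency 0/1 adjacency.
#' @param weights [init_attention_weights()] output.
#' @param config [attention_config].
#' @return `n x (heads * out_dim)` matrix.
#' @export
gat_multi_head <- function(features, adjacency, weights,
                           config = attention_config()) {
  outs <- lapply(weights$heads, function(hw) {
    gat_layer(features, adjacency, hw, config$leaky_relu_slope)
  })
  do.call(cbind, outs)
}

## Forward + backward for the refinement objective.  Returns loss and
## gradients wrt each head's wz/we.  dout is assembled from the decoder
## gradient restricted to the microbe-drug blocks.
gat_backward <- function(z, adjacency, weights, config, a_target, mask) {
  n <- nrow(z)
  heads <- weights$heads
  slope <- config$leaky_relu_slope
  d <- config$out_dim
  iso <- rowSums(adjacency) == 0

  ## forward pass, caching per-head intermediates
  cache <- vector("list", length(heads))
  outs <- vector("list", length(heads))
  for (h in seq_along(heads)) {
    hw <- heads[[h]]
    zp <- z %*% hw$wz
    src <- as.numeric(zp %*% hw$we[seq_len(d)])
    dst <- as.numeric(zp %*% hw$we[d + seq_len(d)])
    pre <- outer(src, dst, "+")
    e <- leaky_relu(pre, slope)
    w <- exp(e) * (adjacency > 0)
    rs <- rowSums(w)
    coef <- w
    keep <- rs > 0
    coef[keep, ] <- coef[keep, , drop = FALSE] / rs[keep]
    agg <- coef %*% zp
    agg[iso, ] <- zp[iso, , drop = FALSE]
    outs[[h]] <- leaky_relu(agg, slope)
    cache[[h]] <- list(zp = zp, pre = pre, coef = coef, agg = agg)
  }
  zref <- do.call(cbind, outs)

  logits <- tcrossprod(zref)
  bce <- weighted_bce(logits, a_target, mask)
  dlogits <- bce$grad
  dzref <- (dlogits + t(dlogits)) %*% zref

  grads <- vector("list", length(heads))
  for (h in seq_along(heads)) {
    hw <- heads[[h]]
    ch <- cache[[h]]
    dout <- dzref[, (h - 1L) * d + seq_len(d), drop = FALSE]
    dagg <- dout * leaky_relu_grad(ch$agg, slope)
    ## isolated rows bypass aggregation
    dzp <- matrix(0, n, d)
    dzp[iso, ] <- dagg[iso, , drop = FALSE]
    dagg[iso, ] <- 0
    ## aggregation: agg = coef %*% zp
    dcoef <- dagg %*% t(ch$zp)
    dzp <- dzp + crossprod(ch$coef, dagg)
    ## softmax over neighbourhoods
    de <- ch$coef * (dcoef - rowSums(dcoef * ch$coef))
    dpre <- de * leaky_relu_grad(ch$pre, slope)
    dsrc <- rowSums(dpre)
    ddst <- colSums(dpre)
    dzp <- dzp + outer(dsrc, hw$we[seq_len(d)]) +
      outer(ddst, hw$we[d + seq_len(d)])
    dwe <- c(as.numeric(crossprod(ch$zp, dsrc)),
             as.numeric(crossprod(ch$zp, ddst)))
    dwz <- crossprod(z, dzp)
    grads[[h]] <- list(wz = dwz, we = dwe)
  }
  list(loss = bce$loss, grads = grads, zref = zref)
}

#' Refine VGAE embeddings with bipartite multi-head attention
#'
#' Stacks the microbe and drug embeddings, runs multi-head attention on
#' the bipartite association graph (training-fold edges only), and trains
#' the attention weights to reconstruct the training associations from
#' refined-embedding inner products (weighted cross-entropy restricted to
#' the microbe-drug blocks).  Nodes with no training associations pass
#' their VGAE embedding through unchanged.
#'
#' @param zm,zd microbe/drug embedding matrices (rows aligned with ids).
#' @param associations [md_associations] holding training-fold edges.
#' @param config [attention_config]; `out_dim` should equal
#'   `ncol(zm) / heads` to preserve width.
#' @return list with `zm`, `zd` (refined embeddings), `weights`,
#'   `loss_history`.
#' @export
refine_embeddings <- function(zm, zd, associations,
                              config = attention_config()) {
  stopifnot(inherits(associations, "md_associations"))
  if (nrow(zm) != length(associations$microbe_ids) ||
      nrow(zd) != length(associations$drug_ids))
    stop("embedding rows do not match association ids")
  if (sum(associations$values) == 0)
    stop("empty training associations; cannot refine")
  i <- nrow(zm); j <- nrow(zd)
  z <- rbind(zm, zd)
  adj <- build_bipartite_adjacency(associations)

  ## loss restricted to the microbe-drug blocks (the zero diagonal blocks
  ## carry no supervision)
  mask <- matrix(0, i + j, i + j)
  mask[seq_len(i), i + seq_len(j)] <- 1
  mask[i + seq_len(j), seq_len(i)] <- 1

  weights <- init_attention_weights(ncol(z), config)
  params <- unlist(lapply(seq_along(weights$heads), function(h) {
    setNames(weights$heads[[h]][c("wz", "we")],
             paste0(c("wz", "we"), h))
  }), recursive = FALSE)
  state <- adam_init(params)
  history <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    for (h in seq_along(weights$heads)) {
      weights$heads[[h]]$wz <- params[[paste0("wz", h)]]
      weights$heads[[h]]$we <- params[[paste0("we", h)]]
    }
    bk <- gat_backward(z, adj, weights, config, adj, mask)
    if (!is.finite(bk$loss))
      stop("refinement diverged (loss is not finite)")
    history[epoch] <- bk$loss
    grads <- unlist(lapply(seq_along(bk$grads), function(h) {
      setNames(bk$grads[[h]][c("wz", "we")], paste0(c("wz", "we"), h))
    }), recursive = FALSE)
    upd <- adam_step(params, grads, state, lr = config$learning_rate)
    params <- upd$params
    state <- upd$state
  }
  for (h in seq_along(weights$heads)) {
    weights$heads[[h]]$wz <- params[[paste0("wz", h)]]
    weights$heads[[h]]$we <- params[[paste0("we", h)]]
  }
  zref <- gat_multi_head(z, adj, weights, config)
  iso <- rowSums(adj) == 0
  if (ncol(zref) == ncol(z)) zref[iso, ] <- z[iso, , drop = FALSE]
  rownames(zref) <- rownames(adj)
  list(zm = zref[seq_len(i), , drop = FALSE],
       zd = zref[i + seq_len(j), , drop = FALSE],
       weights = weights, loss_history = history)
}
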