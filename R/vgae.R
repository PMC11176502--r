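## Variational graph autoencoder with a collapsed-weight ("modified")
## graph-convolution first layer, Gaussian latent heads, inner-product
## decoder and Adam training.  Gradients are derived by hand; the graphs
## handled here are small (hundreds of nodes) so dense BLAS is ample.

#' Encoder configuration
#'
#' @param hidden_dim hidden layer width `d` (default 128).
#' @param latent_dim latent embedding width (default 128).
#' @param learning_rate Adam step size (default 0.01).
#' @param epochs training epochs (default 200).
#' @param mgc_steps propagation steps `K` of the collapsed graph
#'   convolution (default 2).
#' @param leaky_relu_slope negative slope of the encoder activation.
#' @param seed integer seed for weight initialisation and latent noise.
#' @return validated list of class `encoder_config`.
#' @export
encoder_config <- function(hidden_dim = 128L, latent_dim = 128L,
                           learning_rate = 0.01, epochs = 200L,
                           mgc_steps = 2L, leaky_relu_slope = 0.01,
                           seed = 1L) {
  cfg <- list(hidden_dim = as.integer(hidden_dim),
              latent_dim = as.integer(latent_dim),
              learning_rate = learning_rate, epochs = as.integer(epochs),
              mgc_steps = as.integer(mgc_steps),
              leaky_relu_slope = leaky_relu_slope, seed = as.integer(seed))
  if (cfg$hidden_dim < 1 || cfg$latent_dim < 1) stop("dims must be >= 1")
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  if (cfg$mgc_steps < 1) stop("mgc_steps must be >= 1")
  if (cfg$epochs < 0) stop("epochs must be >= 0")
  class(cfg) <- "encoder_config"
  cfg
}

#' Symmetrically normalised adjacency matrix
#'
#' `D^(-1/2) A D^(-1/2)` with `D` the degree matrix; zero-degree nodes are
#' assigned degree 1 so the normalisation stays defined.
#'
#' @param adjacency symmetric 0/1 matrix.
#' @return normalised symmetric matrix.
#' @export
normalize_adjacency <- function(adjacency) {
  check_square(adjacency, "adjacency")
  deg <- rowSums(adjacency)
  deg[deg == 0] <- 1
  dinv <- 1 / sqrt(deg)
  a_norm <- adjacency * outer(dinv, dinv)
  (a_norm + t(a_norm)) / 2
}

#' Initialise encoder weights
#'
#' Glorot-uniform initialisation of the plain GCN weight `w0`, the
#' collapsed propagation weight `m_mgc`, and the shared second-layer
#' weight holding the mean and log-variance output slices.
#'
#' @param n_features input feature width.
#' @param config [encoder_config].
#' @return list of class `encoder_weights` with `w0`, `m_mgc`, `w_mu`,
#'   `w_sigma`.
#' @export
init_encoder_weights <- function(n_features, config = encoder_config()) {
  with_seed(stage_seed(config$seed, "encoder_init"), {
    w1 <- glorot_init(config$hidden_dim, 2L * config$latent_dim)
    structure(list(
      w0 = glorot_init(n_features, config$hidden_dim),
      m_mgc = glorot_init(n_features, config$hidden_dim),
      w_mu = w1[, seq_len(config$latent_dim), drop = FALSE],
      w_sigma = w1[, config$latent_dim + seq_len(config$latent_dim),
                   drop = FALSE]
    ), class = "encoder_weights")
  })
}

#' Plain graph-convolution layer
#'
#' `LeakyReLU(a_norm %*% features %*% w0)`.
#'
#' @param features n x f feature matrix.
#' @param a_norm normalised adjacency from [normalize_adjacency()].
#' @param w0 f x d weight matrix.
#' @param slope LeakyReLU negative slope.
#' @return n x d matrix.
#' @export
gcn_layer <- function(features, a_norm, w0, slope = 0.01) {
  if (ncol(features) != nrow(w0)) stop("feature/weight shape mismatch")
  if (nrow(features) != nrow(a_norm)) stop("feature/adjacency shape mismatch")
  leaky_relu(a_norm %*% features %*% w0, slope)
}

#' Collapsed-weight graph-convolution propagation
#'
#' `row_softmax(S^K %*% X %*% M)`: K propagation steps with a single
#' collapsed weight matrix and no inter-layer non-linearities, followed by
#' a row-wise softmax.  This replaces the stacked GCN layers of the
#' standard encoder to cut redundant computation.
#'
#' @param features n x f matrix `X`.
#' @param s normalised adjacency `S`.
#' @param m f x c collapsed weight matrix.
#' @param steps propagation step count `K >= 1`.
#' @return n x c matrix with rows summing to 1.
#' @export
mgc_propagate <- function(features, s, m, steps = 2L) {
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1")
  px <- features
  for (k in seq_len(steps)) px <- s %*% px
  row_softmax(px %*% m)
}

#' Encode node features into Gaussian latent parameters
#'
#' The hidden layer is the collapsed graph convolution
#' ([mgc_propagate()]); the mean and log-variance heads are
#' `a_norm %*% hidden %*% w_mu` and `a_norm %*% hidden %*% w_sigma`
#' (two output slices of one shared second-layer weight).
#'
#' @param features n x f feature matrix.
#' @param a_norm normalised adjacency.
#' @param weights [init_encoder_weights()] output.
#' @param config [encoder_config].
#' @return list of class `latent_embedding` with `mu`, `log_var`, `z`
#'   (`z = mu`; use [reparameterize()] to sample).
#' @export
vgae_encode <- function(features, a_norm, weights, config = encoder_config()) {
  hidden <- mgc_propagate(features, a_norm, weights$m_mgc, config$mgc_steps)
  ah <- a_norm %*% hidden
  mu <- ah %*% weights$w_mu
  log_var <- ah %*% weights$w_sigma
  if (anyNA(mu) || any(!is.finite(mu)))
    stop("NaN in forward pass at the mean head")
  if (anyNA(log_var) || any(!is.finite(log_var)))
    stop("NaN in forward pass at the log-variance head")
  structure(list(mu = mu, log_var = log_var, z = mu),
            class = "latent_embedding")
}

#' Reparameterised latent sample
#'
#' `z = mu + exp(0.5 * log_var) * eps` with `eps ~ N(0, 1)`.
#'
#' @param mu,log_var latent Gaussian parameters (same shape).
#' @param noise optional explicit `eps` matrix; when `NULL`, standard
#'   normal noise is drawn from the current RNG stream.
#' @return latent sample matrix `z`.
#' @export
reparameterize <- function(mu, log_var, noise = NULL) {
  stopifnot(all(dim(mu) == dim(log_var)))
  if (is.null(noise))
    noise <- matrix(rnorm(length(mu)), nrow(mu), ncol(mu))
  mu + exp(0.5 * log_var) * noise
}

#' Inner-product decoder
#'
#' `P = sigmoid(z %*% t(z))`: symmetric edge-probability matrix in (0, 1).
#'
#' @param z latent matrix.
#' @return n x n probability matrix.
#' @export
vgae_decode <- function(z) {
  sigmoid(tcrossprod(z))
}

#' VGAE loss: weighted reconstruction cross-entropy plus KL divergence
#'
#' The reconstruction term is binary cross-entropy between the decoded
#' edge probabilities and the target adjacency, averaged over entries with
#' positive entries up-weighted by the zero/one ratio; the KL term is
#' `-0.5 * sum(1 + log_var - mu^2 - exp(log_var)) / n`, the divergence of
#' the latent Gaussians from the standard-normal prior.
#'
#' @param reconstructed decoded probability matrix `P`.
#' @param adjacency target 0/1 matrix.
#' @param mu,log_var latent Gaussian parameters.
#' @param use_recon,use_kl ablation switches; disabled terms contribute 0.
#' @return list with `loss`, `recon`, `kl`.
#' @export
vgae_loss <- function(reconstructed, adjacency, mu, log_var,
                      use_recon = TRUE, use_kl = TRUE) {
  stopifnot(all(dim(reconstructed) == dim(adjacency)))
  eps <- 1e-12
  p <- pmin(pmax(reconstructed, eps), 1 - eps)
  n_pos <- sum(adjacency); n_neg <- length(adjacency) - n_pos
  w_pos <- if (n_pos > 0) n_neg / n_pos else 1
  recon <- -sum(w_pos * adjacency * log(p) +
                  (1 - adjacency) * log(1 - p)) / length(adjacency)
  kl <- -0.5 * sum(1 + log_var - mu^2 - exp(log_var)) / nrow(mu)
  loss <- (if (use_recon) recon else 0) + (if (use_kl) kl else 0)
  list(loss = loss, recon = recon, kl = kl)
}

#' Train the variational graph autoencoder on one entity graph
#'
#' Minimises the weighted reconstruction cross-entropy plus KL divergence
#' by Adam, resampling the latent noise every epoch.  Input feature
#' columns are standardised (zero mean, unit variance) before encoding:
#' the similarity and association-profile columns live on different
#' scales, and the softmax hidden layer resolves differences between
#' nodes much better on standardised inputs.  With both loss terms
#' disabled (full ablation) the initial weights are returned untouched.
#' Inference embeddings use `z = mu` (noise off).
#'
#' @param graph `feature_graph` from [build_feature_graph()].
#' @param config [encoder_config].
#' @param use_recon,use_kl ablation switches for the two loss terms.
#' @return list with `weights`, `embedding` ([vgae_encode()] output at the
#'   final weights), and the per-epoch `loss_history`.
#' @export
vgae_train <- function(graph, config = encoder_config(),
                       use_recon = TRUE, use_kl = TRUE) {
  stopifnot(inherits(graph, "feature_graph"))
  a <- graph$adjacency
  a_norm <- normalize_adjacency(a)
  ## column standardisation; constant columns pass through unscaled
  x <- graph$features
  csd <- apply(x, 2L, sd)
  csd[csd < 1e-12] <- 1
  x <- scale(x, center = TRUE, scale = csd)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  n <- nrow(x)
  weights <- init_encoder_weights(ncol(x), config)
  if (!use_recon && !use_kl) {
    emb <- vgae_encode(x, a_norm, weights, config)
    return(list(weights = weights, embedding = emb,
                loss_history = numeric(0)))
  }

  ## S^K X is constant across epochs
  px <- x
  for (k in seq_len(config$mgc_steps)) px <- a_norm %*% px

  n_pos <- sum(a); n_neg <- length(a) - n_pos
  w_pos <- if (n_pos > 0) n_neg / n_pos else 1

  params <- list(m_mgc = weights$m_mgc, w_mu = weights$w_mu,
                 w_sigma = weights$w_sigma)
  state <- adam_init(params)
  history <- numeric(config$epochs)

  with_seed(stage_seed(config$seed, "encoder_train"), {
    for (epoch in seq_len(config$epochs)) {
      ## forward
      u <- px %*% params$m_mgc
      h <- row_softmax(u)
      ah <- a_norm %*% h
      mu <- ah %*% params$w_mu
      lv <- ah %*% params$w_sigma
      sd_ <- exp(0.5 * lv)
      eps_mat <- matrix(rnorm(n * config$latent_dim), n, config$latent_dim)
      z <- mu + sd_ * eps_mat
      logits <- tcrossprod(z)
      pr <- sigmoid(logits)
      pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
      recon <- -sum(w_pos * a * log(pr) + (1 - a) * log(1 - pr)) / length(a)
      kl <- -0.5 * sum(1 + lv - mu^2 - exp(lv)) / n
      loss <- (if (use_recon) recon else 0) + (if (use_kl) kl else 0)
      if (!is.finite(loss))
        stop("training diverged (loss is not finite); lower learning_rate")
      history[epoch] <- loss

      ## backward
      dz <- matrix(0, n, config$latent_dim)
      if (use_recon) {
        dlogits <- ((1 - a) * pr - w_pos * a * (1 - pr)) / length(a)
        dz <- (dlogits + t(dlogits)) %*% z
      }
      dmu <- dz
      dlv <- dz * eps_mat * 0.5 * sd_
      if (use_kl) {
        dmu <- dmu + mu / n
        dlv <- dlv + 0.5 * (exp(lv) - 1) / n
      }
      grads <- list(
        m_mgc = crossprod(px, row_softmax_grad(h, (a_norm %*% (dmu %*% t(params$w_mu) + dlv %*% t(params$w_sigma))))),
        w_mu = crossprod(ah, dmu),
        w_sigma = crossprod(ah, dlv)
      )
      upd <- adam_step(params, grads, state, lr = config$learning_rate)
      params <- upd$params
      state <- upd$state
    }
  })

  weights$m_mgc <- params$m_mgc
  weights$w_mu <- params$w_mu
  weights$w_sigma <- params$w_sigma
  emb <- vgae_encode(x, a_norm, weights, config)
  list(weights = weights, embedding = emb, loss_history = history)
}
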