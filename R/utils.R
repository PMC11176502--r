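## Internal numerical helpers shared across modules.

#' Derive a per-stage RNG seed from a global seed and a stage label
#'
#' One global seed fans out deterministically to independent per-stage
#' seeds so that, e.g., fold assignment and negative sampling do not share
#' an RNG stream.  Uses a small polynomial string hash folded into the
#' 32-bit signed integer range.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return integer seed in `[0, 2^31 - 1]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

## Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
## global RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

leaky_relu <- function(x, slope = 0.01) {
  ifelse(x >= 0, x, slope * x)
}

leaky_relu_grad <- function(x, slope = 0.01) {
  ifelse(x >= 0, 1, slope)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## Numerically stable row-wise softmax.
row_softmax <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

## Gradient of L wrt the pre-softmax matrix given Y = row_softmax(U) and
## dL/dY: dL/dU = Y * (dY - rowSums(dY * Y)).
row_softmax_grad <- function(y, dy) {
  y * (dy - rowSums(dy * y))
}

## Glorot/Xavier uniform initialisation, drawn from the current RNG stream.
glorot_init <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

## One Adam update step; state carries first/second moments and step count.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.01,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^t)
    vhat <- state$v[[k]] / (1 - beta2^t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## Weighted binary cross-entropy over all matrix entries with its gradient
## wrt the logits.  Positive entries are up-weighted by the zero/one ratio
## so sparse adjacencies do not collapse to the all-zero reconstruction.
weighted_bce <- function(logits, target, mask = NULL, eps = 1e-12) {
  p <- sigmoid(logits)
  p <- pmin(pmax(p, eps), 1 - eps)
  if (is.null(mask)) mask <- array(1, dim = dim(target))
  n_pos <- sum(target * mask)
  n_neg <- sum((1 - target) * mask)
  w_pos <- if (n_pos > 0) n_neg / n_pos else 1
  n_eff <- sum(mask)
  ll <- -(w_pos * target * log(p) + (1 - target) * log(1 - p)) * mask
  loss <- sum(ll) / n_eff
  grad <- ((1 - target) * p - w_pos * target * (1 - p)) * mask / n_eff
  list(loss = loss, grad = grad)
}

## Validates a square numeric matrix, optionally that it is symmetric.
check_square <- function(m, what = "matrix", tol = 1e-8, symmetric = TRUE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix")
  if (nrow(m) != ncol(m))
    stop(what, " must be square (got ", nrow(m), "x", ncol(m), ")")
  if (anyNA(m)) stop(what, " contains NA/NaN entries")
  if (symmetric && max(abs(m - t(m))) > tol)
    stop(what, " is not symmetric within tolerance ", tol)
  invisible(m)
}
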