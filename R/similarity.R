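## Similarity matrices: sequence (Smith-Waterman), GIP kernels, fusion,
## smoothing, binarization and feature-graph assembly.

#' Square similarity matrix with aligned ids
#'
#' @param values n x n numeric matrix with entries in `[0, 1]`.
#' @param ids character ids aligned with rows/columns.
#' @param kind one of `"sequence"`, `"structure"`, `"gip"`, `"fused"`,
#'   `"smoothed"`, `"binarized"`.
#' @param require_unit_diag enforce a unit diagonal (default for kinds
#'   sequence/gip/fused).
#' @return object of class `md_similarity`.
#' @export
md_similarity <- function(values, ids, kind = "fused",
                          require_unit_diag = kind %in%
                            c("sequence", "gip", "fused")) {
  kinds <- c("sequence", "structure", "gip", "fused", "smoothed", "binarized")
  kind <- match.arg(kind, kinds)
  values <- as.matrix(values)
  if (length(ids) != nrow(values))
    stop("id count does not match matrix dimension")
  if (anyDuplicated(ids)) stop("duplicate ids")
  if (anyNA(values)) stop("similarity matrix contains NA")
  if (any(values < -1e-12) || any(values > 1 + 1e-12))
    stop("similarity entries must lie in [0, 1]")
  values <- pmin(pmax(values, 0), 1)
  ## smoothing is a row operation and may transiently break symmetry
  check_square(values, "similarity matrix", symmetric = kind != "smoothed")
  if (require_unit_diag && max(abs(diag(values) - 1)) > 1e-8)
    stop("similarity matrix of kind '", kind, "' must have unit diagonal")
  if (kind == "binarized" && !all(values %in% c(0, 1)))
    stop("binarized similarity must contain only 0/1")
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = as.character(ids), kind = kind),
            class = "md_similarity")
}

#' @export
print.md_similarity <- function(x, ...) {
  cat(sprintf("md_similarity (%s): %d x %d, mean %.3f\n",
              x$kind, nrow(x$values), ncol(x$values), mean(x$values)))
  invisible(x)
}

#' Smith-Waterman local alignment score
#'
#' Dynamic program over a `(a+1) x (b+1)` matrix with zero first row and
#' column; each cell takes the maximum of the diagonal move plus the match
#' score (+1 match, -1 mismatch), a gap step costing 2, and 0.  The score
#' is the maximum over the matrix.
#'
#' @param seq_a,seq_b non-empty nucleotide strings.
#' @return non-negative integer alignment score.
#' @export
local_align_score <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  .sw_score_cpp(toupper(seq_a), toupper(seq_b))
}

#' Normalised sequence similarity between two sequences
#'
#' `sw(A, B) / sqrt(sw(A, A) * sw(B, B))`, so self-similarity is 1 and the
#' value lies in `[0, 1]`.
#'
#' @param seq_a,seq_b non-empty nucleotide strings.
#' @return similarity in `[0, 1]`.
#' @export
sequence_similarity <- function(seq_a, seq_b) {
  saa <- local_align_score(seq_a, seq_a)
  sbb <- local_align_score(seq_b, seq_b)
  if (saa == 0 || sbb == 0)
    stop("internal error: non-empty sequence with zero self-score")
  sab <- local_align_score(seq_a, seq_b)
  min(sab / sqrt(saa * sbb), 1)
}

#' All-pairs sequence similarity matrix
#'
#' @param seqs named character vector of sequences.
#' @return [md_similarity] of kind `"sequence"`.
#' @export
sequence_similarity_matrix <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  sw <- .sw_score_matrix_cpp(unname(seqs))
  self <- diag(sw)
  if (any(self == 0))
    stop("internal error: non-empty sequence with zero self-score")
  sim <- sw / sqrt(outer(self, self))
  sim <- pmin(sim, 1)
  diag(sim) <- 1
  md_similarity(sim, names(seqs), kind = "sequence")
}

#' Resolve the Gaussian interaction-profile kernel bandwidth
#'
#' `gamma = gamma_prime / mean(||profile_i||^2)` over the n interaction
#' profiles (rows of the matrix passed in).
#'
#' @param profiles numeric matrix, one interaction profile per row.
#' @param gamma_prime positive scale parameter (default 1, the GIP
#'   literature convention).
#' @return list with `gamma_prime` and resolved `gamma`.
#' @export
gip_bandwidth <- function(profiles, gamma_prime = 1) {
  stopifnot(is.matrix(profiles), gamma_prime > 0)
  msq <- mean(rowSums(profiles^2))
  if (msq == 0) stop("all interaction profiles are zero; bandwidth undefined")
  list(gamma_prime = gamma_prime, gamma = gamma_prime / msq)
}

#' Gaussian interaction-profile kernel similarity
#'
#' `K(i, j) = exp(-gamma * ||profile_i - profile_j||^2)`.  Used for both
#' microbe profiles (rows of the association matrix) and drug profiles
#' (columns).
#'
#' @param profiles numeric matrix, one profile per row.
#' @param ids ids aligned with rows.
#' @param params bandwidth list from [gip_bandwidth()]; resolved from
#'   `profiles` when `NULL`.
#' @return [md_similarity] of kind `"gip"`.
#' @export
gip_similarity <- function(profiles, ids, params = NULL) {
  if (is.null(params)) params <- gip_bandwidth(profiles)
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2 <- pmax(d2, 0)
  k <- exp(-params$gamma * d2)
  k <- (k + t(k)) / 2
  diag(k) <- 1
  md_similarity(k, ids, kind = "gip")
}

#' Fuse a primary similarity with the GIP kernel
#'
#' Entry-wise: the mean of the two where the primary similarity is
#' non-zero, the GIP value where it is zero.
#'
#' @param primary [md_similarity] (sequence or structure based).
#' @param gip [md_similarity] of kind `"gip"` with identical ids.
#' @return [md_similarity] of kind `"fused"`.
#' @export
fuse_similarity <- function(primary, gip) {
  stopifnot(inherits(primary, "md_similarity"), inherits(gip, "md_similarity"))
  if (!identical(primary$ids, gip$ids))
    stop("id mismatch between similarity matrices")
  p <- primary$values; g <- gip$values
  fused <- ifelse(p != 0, (p + g) / 2, g)
  md_similarity(fused, primary$ids, kind = "fused")
}

#' Row-wise centred moving-average smoothing
#'
#' Each row is replaced by its centred moving average with window `n`; at
#' the boundaries the window truncates to the available entries.  `n = 1`
#' is the identity.
#'
#' @param sim [md_similarity].
#' @param n odd positive window size, at most the row length.
#' @return [md_similarity] of kind `"smoothed"`.
#' @export
smooth_rows <- function(sim, n = 5L) {
  stopifnot(inherits(sim, "md_similarity"))
  n <- as.integer(n)
  if (n < 1L || n %% 2L == 0L) stop("window size must be odd and positive")
  m <- sim$values
  if (n > ncol(m)) stop("window size exceeds row length")
  half <- n %/% 2L
  nc <- ncol(m)
  ## cumulative-sum sliding mean with truncated edges, all rows at once
  cs <- cbind(0, t(apply(m, 1L, cumsum)))
  lo <- pmax(seq_len(nc) - half, 1L)
  hi <- pmin(seq_len(nc) + half, nc)
  out <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(m))
  dimnames(out) <- dimnames(m)
  md_similarity(out, sim$ids, kind = "smoothed")
}

#' Threshold a similarity matrix into a binary adjacency
#'
#' Entries at or above `threshold` map to 1, others to 0.  Because row
#' smoothing can break symmetry, the input is symmetrised by averaging
#' with its transpose before thresholding.
#'
#' @param sim [md_similarity].
#' @param threshold cut-off in `(0, 1]` (defaults: 0.8 for microbes, 0.7
#'   for drugs in the pipeline).
#' @return [md_similarity] of kind `"binarized"`.
#' @export
binarize_similarity <- function(sim, threshold) {
  stopifnot(inherits(sim, "md_similarity"))
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  m <- (sim$values + t(sim$values)) / 2
  b <- (m >= threshold) * 1
  md_similarity(b, sim$ids, kind = "binarized")
}

#' Assemble the encoder input graph for one entity side
#'
#' The adjacency is the binarized similarity graph; node features are the
#' continuous fused similarity row concatenated with the node's
#' association profile (row of the association matrix for microbes, column
#' for drugs), so the feature width is `n_side + n_other`.
#'
#' @param binarized [md_similarity] of kind `"binarized"`.
#' @param fused [md_similarity] of kind `"fused"` with the same ids.
#' @param associations [md_associations].
#' @param side `"microbe"` or `"drug"`.
#' @return list of class `feature_graph` with `adjacency`, `features`,
#'   `ids`.
#' @export
build_feature_graph <- function(binarized, fused, associations,
                                side = c("microbe", "drug")) {
  side <- match.arg(side)
  stopifnot(inherits(binarized, "md_similarity"),
            inherits(fused, "md_similarity"),
            inherits(associations, "md_associations"))
  if (!identical(binarized$ids, fused$ids))
    stop("binarized and fused similarity ids disagree")
  ref_ids <- if (side == "microbe") associations$microbe_ids else
    associations$drug_ids
  if (!identical(binarized$ids, ref_ids))
    stop("similarity ids do not match association ", side, " ids")
  profile <- if (side == "microbe") associations$values else
    t(associations$values)
  features <- cbind(fused$values, profile)
  structure(list(adjacency = binarized$values, features = features,
                 ids = binarized$ids, side = side),
            class = "feature_graph")
}
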