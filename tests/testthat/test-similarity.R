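test_that("local alignment scores match hand-checked cases", {
  expect_equal(local_align_score("ACGT", "ACGT"), 4)
  expect_equal(local_align_score("AAAA", "TTTT"), 0)
  expect_equal(local_align_score("ACGT", "ACGG"), 3)
  expect_equal(local_align_score("ACACAC", "ACGCAC"),
               brute_force_local_align("ACACAC", "ACGCAC"))
  expect_error(local_align_score("", "ACGT"), "non-empty")
})

test_that("local alignment equals the exhaustive oracle on short pairs", {
  set.seed(101)
  for (i in 1:100) {
    a <- random_dna(sample(2:8, 1))
    b <- random_dna(sample(2:8, 1))
    expect_equal(local_align_score(a, b), brute_force_local_align(a, b),
                 info = paste(a, b))
  }
})

test_that("local alignment agrees with an established aligner on longer pairs", {
  set.seed(202)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:20) {
    a <- random_dna(sample(20:60, 1))
    b <- random_dna(sample(20:60, 1))
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
    expect_equal(local_align_score(a, b), as.numeric(ref))
  }
})

test_that("sequence similarity is normalised, symmetric and unit on self", {
  expect_equal(sequence_similarity("ACGTACGT", "ACGTACGT"), 1)
  expect_equal(sequence_similarity("AAAA", "TTTT"), 0)
  expect_equal(sequence_similarity("ACGT", "ACGG"), 0.75)
  expect_equal(sequence_similarity("ACGT", "ACGG"),
               sequence_similarity("ACGG", "ACGT"))
  seqs <- c(a = "ACGTAC", b = "ACGCAC", c = "TTTTTT")
  m <- sequence_similarity_matrix(seqs)
  expect_equal(diag(m$values), c(a = 1, b = 1, c = 1))
  expect_equal(m$values, t(m$values))
  expect_equal(m$values["a", "b"], sequence_similarity("ACGTAC", "ACGCAC"))
})

test_that("GIP bandwidth follows the mean squared profile norm", {
  p <- rbind(c(1, 0), c(0, 1))
  expect_equal(gip_bandwidth(p, 1)$gamma, 1)
  # identical profiles with k ones
  p2 <- rbind(c(1, 1, 1, 0), c(1, 1, 1, 0))
  expect_equal(gip_bandwidth(p2, 1)$gamma, 1 / 3)
  expect_error(gip_bandwidth(matrix(0, 2, 2)), "undefined")
})

test_that("GIP similarity matches its closed form and is a valid kernel", {
  p <- rbind(c(1, 0), c(0, 1))
  g <- gip_similarity(p, c("a", "b"))
  expect_equal(g$values["a", "b"], exp(-2))
  expect_equal(diag(g$values), c(a = 1, b = 1))

  # identical profiles give similarity 1 everywhere
  g2 <- gip_similarity(rbind(c(1, 1), c(1, 1)), c("x", "y"))
  expect_true(all(g2$values == 1))

  # positive semidefinite on random profiles
  set.seed(11)
  for (i in 1:5) {
    pr <- matrix(rbinom(40, 1, 0.4), 8)
    ev <- eigen(gip_similarity(pr, letters[1:8],
                               gip_bandwidth(pr))$values,
                symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})

test_that("GIP similarity is equivariant under profile permutation", {
  set.seed(12)
  pr <- matrix(rbinom(60, 1, 0.3), 10)
  ids <- paste0("n", 1:10)
  g <- gip_similarity(pr, ids, gip_bandwidth(pr))
  perm <- sample(10)
  gp <- gip_similarity(pr[perm, ], ids[perm], gip_bandwidth(pr[perm, ]))
  expect_equal(gp$values, g$values[perm, perm])
})

test_that("similarity fusion averages where the primary is informative", {
  ids <- c("a", "b")
  prim <- md_similarity(matrix(c(1, 0.4, 0.4, 1), 2), ids, "sequence")
  gip <- md_similarity(matrix(c(1, 0.2, 0.2, 1), 2), ids, "gip")
  expect_equal(fuse_similarity(prim, gip)$values[1, 2], 0.3)

  prim0 <- md_similarity(matrix(c(1, 0, 0, 1), 2), ids, "sequence")
  expect_equal(fuse_similarity(prim0, gip)$values[1, 2], 0.2)

  # fixed point: primary == gip with no zeros
  expect_equal(fuse_similarity(gip, gip)$values, gip$values)

  gip_bad <- md_similarity(matrix(c(1, 0.2, 0.2, 1), 2), c("a", "c"), "gip")
  expect_error(fuse_similarity(prim, gip_bad), "mismatch")
})

test_that("row smoothing is a truncated centred moving average", {
  ids <- paste0("x", 1:3)
  m <- md_similarity(matrix(c(1, 0, 0.5, 0, 1, 0.5, 0.5, 0.5, 1), 3,
                            byrow = TRUE), ids, "fused")
  s1 <- smooth_rows(m, 1)
  expect_equal(s1$values, m$values)       # window 1 is the identity

  spike <- md_similarity(rbind(c(0, 1, 0), c(0, 1, 0), c(0, 1, 0)),
                         ids, kind = "smoothed")
  sm <- smooth_rows(spike, 3)
  expect_equal(unname(sm$values[1, ]), c(0.5, 1 / 3, 0.5))

  const <- md_similarity(matrix(0.6, 3, 3), ids, kind = "smoothed")
  expect_equal(smooth_rows(const, 3)$values, const$values)

  expect_error(smooth_rows(m, 2), "odd")
  expect_error(smooth_rows(m, -1), "odd|positive")
})

test_that("binarization thresholds, symmetrises and is monotone", {
  ids <- c("a", "b")
  m <- md_similarity(matrix(c(0.9, 0.3, 0.3, 0.9), 2), ids,
                     kind = "smoothed")
  expect_equal(unname(binarize_similarity(m, 0.8)$values), diag(2))
  expect_true(all(binarize_similarity(m, 0.95)$values == 0))
  expect_error(binarize_similarity(m, 0), "threshold")
  expect_error(binarize_similarity(m, 1.2), "threshold")

  # smoothing with window 1 never changes the binarization
  set.seed(3)
  r <- matrix(runif(25), 5); r <- (r + t(r)) / 2; diag(r) <- 1
  ms <- md_similarity(r, paste0("n", 1:5), "fused")
  expect_equal(binarize_similarity(smooth_rows(ms, 1), 0.5)$values,
               binarize_similarity(ms, 0.5)$values)

  # raising the threshold never adds edges
  th <- sort(runif(5, 0.1, 1))
  edge_counts <- vapply(th, function(t)
    sum(binarize_similarity(ms, t)$values), numeric(1))
  expect_true(all(diff(edge_counts) <= 0))
})

test_that("feature graphs concatenate fused similarity and profiles", {
  syn <- generate_synthetic(synthetic_config(
    n_microbes = 3, n_drugs = 4, n_blocks = 2, within_block_density = 0.9,
    background_density = 0.05, sequence_length = 30, seed = 2))
  mss <- sequence_similarity_matrix(syn$sequences)
  gip <- gip_similarity(syn$associations$values, syn$associations$microbe_ids)
  fused <- fuse_similarity(mss, gip)
  bin <- binarize_similarity(fused, 0.5)
  fg <- build_feature_graph(bin, fused, syn$associations, "microbe")
  expect_equal(dim(fg$features), c(3, 7))  # n_side + n_other
  expect_equal(fg$adjacency, bin$values)

  # zero associations: profile block of the features is all zero
  a0 <- md_associations(matrix(0, 3, 4), syn$associations$microbe_ids,
                        syn$associations$drug_ids)
  fg0 <- build_feature_graph(bin, fused, a0, "microbe")
  expect_true(all(fg0$features[, 4:7] == 0))
})

test_that("planted blocks dominate the binarized similarity graph", {
  syn <- tiny_dataset()
  params <- tiny_params()
  inp <- build_side_inputs(sequence_similarity_matrix(syn$sequences),
                           syn$associations, "microbe", params)
  adj <- inp$graph$adjacency
  same <- outer(syn$microbe_blocks, syn$microbe_blocks, "==")
  off <- row(adj) != col(adj)
  within_rate <- mean(adj[same & off])
  between_rate <- mean(adj[!same])
  expect_gte(within_rate, between_rate)
})
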