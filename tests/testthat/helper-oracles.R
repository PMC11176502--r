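# Independent oracles used to validate the package implementations.
# These deliberately avoid the code paths they check.

# Exhaustive local-alignment score: enumerate every order-preserving
# pairing of position subsets of a and b; score = matches(+1) /
# mismatches(-1) minus 2 per interior unaligned position; floor at 0.
# Feasible for sequences up to length ~8.
brute_force_local_align <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  best <- 0
  for (k in seq_len(min(la, lb))) {
    ia <- utils::combn(la, k, simplify = FALSE)
    ib <- utils::combn(lb, k, simplify = FALSE)
    for (sa in ia) {
      for (sb in ib) {
        sc <- sum(ifelse(av[sa] == bv[sb], 1, -1))
        if (k > 1) {
          gaps <- sum(diff(sa) - 1L) + sum(diff(sb) - 1L)
          sc <- sc - 2 * gaps
        }
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# All-pairs Mann-Whitney concordance: fraction of (positive, negative)
# score pairs with the positive ranked higher; ties count one half.
concordance_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Small synthetic dataset + fast hyperparameters for pipeline-level tests.
tiny_dataset <- function(seed = 7) {
  generate_synthetic(synthetic_config(
    n_microbes = 24, n_drugs = 36, n_blocks = 3,
    within_block_density = 0.5, background_density = 0.03,
    sequence_length = 60, mutation_rate = 0.05, seed = seed))
}

tiny_params <- function(seed = 1) {
  pipeline_params(
    encoder = encoder_config(hidden_dim = 16L, latent_dim = 16L,
                             epochs = 30L, seed = seed),
    attention = attention_config(heads = 2L, out_dim = 8L, epochs = 20L,
                                 seed = seed),
    forest = forest_config(n_estimators = 50L, seed = seed))
}
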