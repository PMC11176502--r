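## Association tables, sequence I/O and the synthetic benchmark generator.

#' Construct a binary microbe-drug association matrix
#'
#' @param values numeric matrix of 0/1 entries, rows = microbes,
#'   columns = drugs.
#' @param microbe_ids,drug_ids character id vectors aligned with rows and
#'   columns.
#' @return an object of class `md_associations`.
#' @export
md_associations <- function(values, microbe_ids, drug_ids) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("association matrix contains NA")
  if (!all(values %in% c(0, 1))) stop("association entries must be 0 or 1")
  if (nrow(values) != length(microbe_ids))
    stop("row count does not match number of microbe ids")
  if (ncol(values) != length(drug_ids))
    stop("column count does not match number of drug ids")
  if (anyDuplicated(microbe_ids)) stop("duplicate microbe ids")
  if (anyDuplicated(drug_ids)) stop("duplicate drug ids")
  storage.mode(values) <- "double"
  dimnames(values) <- list(microbe_ids, drug_ids)
  structure(list(values = values,
                 microbe_ids = as.character(microbe_ids),
                 drug_ids = as.character(drug_ids)),
            class = "md_associations")
}

#' @export
print.md_associations <- function(x, ...) {
  cat(sprintf("md_associations: %d microbes x %d drugs, %d associations\n",
              length(x$microbe_ids), length(x$drug_ids), sum(x$values)))
  invisible(x)
}

#' Load a microbe-drug association edge list
#'
#' Reads a TSV/CSV edge list with at least two columns (microbe id, drug id;
#' an optional third label column is ignored).  A header row is recognised
#' when its first two fields look like column names (`microbe`, `drug`,
#' `microbe_id`, ...).  Entity order is first-appearance order; duplicate
#' edges collapse to a single association.
#'
#' @param path path to the edge list.
#' @return an [md_associations] object with `MD[i, j] = 1` exactly for the
#'   listed pairs.
#' @export
load_association_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty association file: ", path)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  header_names <- c("microbe", "drug", "microbe_id", "drug_id", "label",
                    "source", "target")
  first <- tolower(trimws(fields[[1]][1:2]))
  start <- if (all(first %in% header_names)) 2L else 1L
  if (start > length(fields)) stop("association file has no data rows: ", path)
  mids <- character(0); dids <- character(0)
  edges_m <- character(length(fields)); edges_d <- character(length(fields))
  n_edges <- 0L
  for (ln in seq(start, length(fields))) {
    f <- trimws(fields[[ln]])
    if (length(f) < 2L || !nzchar(f[[1]]) || !nzchar(f[[2]]))
      stop("malformed association row at line ", ln, " of ", path)
    n_edges <- n_edges + 1L
    edges_m[n_edges] <- f[[1]]
    edges_d[n_edges] <- f[[2]]
  }
  edges_m <- edges_m[seq_len(n_edges)]
  edges_d <- edges_d[seq_len(n_edges)]
  mids <- unique(edges_m)
  dids <- unique(edges_d)
  values <- matrix(0, length(mids), length(dids))
  values[cbind(match(edges_m, mids), match(edges_d, dids))] <- 1
  md_associations(values, mids, dids)
}

#' Write an association matrix back to an edge list
#'
#' Emits one `microbe<TAB>drug` row per association, microbes in row order.
#'
#' @param assoc an [md_associations] object.
#' @param path output path.
#' @export
write_association_table <- function(assoc, path) {
  stopifnot(inherits(assoc, "md_associations"))
  idx <- which(assoc$values == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(microbe = assoc$microbe_ids[idx[, 1]],
                   drug = assoc$drug_ids[idx[, 2]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Load microbial sequences from a FASTA file
#'
#' Sequences are uppercased and validated to be non-empty with unique ids.
#'
#' @param path FASTA path.
#' @return named character vector of uppercase sequences.
#' @export
load_sequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    stop("FASTA record with empty sequence body: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in sequences: ",
         paste(ids[bad], collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_sequences <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  invisible(path)
}

#' Load a labelled square similarity matrix
#'
#' Reads a TSV with row and column labels, validates squareness, symmetry
#' (tolerance 1e-8) and value sanity, and zeroes entries below the
#' structural-similarity reporting cut-off (off-diagonal scores below
#' `cutoff` are treated as absent).
#'
#' @param path TSV path (row names in first column).
#' @param cutoff minimum reported similarity; smaller off-diagonal entries
#'   become 0.  Default 0.01.
#' @return an [md_similarity] object of kind `"structure"`.
#' @export
load_similarity_matrix <- function(path, cutoff = 0.01) {
  df <- read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cell in similarity matrix: ", path)
  if (nrow(m) != ncol(m))
    stop("similarity matrix is not square: ", nrow(m), "x", ncol(m))
  if (anyNA(m)) stop("similarity matrix contains NA/NaN: ", path)
  if (any(m < 0)) stop("similarity matrix contains negative entries: ", path)
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels disagree: ", path)
  check_square(m, "similarity matrix")
  off <- m < cutoff & row(m) != col(m)
  m[off] <- 0
  md_similarity(m, rownames(m), kind = "structure", require_unit_diag = FALSE)
}

#' Write a labelled matrix as TSV
#' @param m matrix with dimnames, or [md_similarity].
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  if (inherits(m, "md_similarity")) m <- m$values
  write.table(m, path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Synthetic benchmark configuration
#'
#' Parameters of the planted-block generator.  Microbes and drugs are
#' partitioned into `n_blocks` matched communities; associations are dense
#' within matched blocks and sparse elsewhere, sequences descend from one
#' ancestor per block, and drug structural similarity mirrors block
#' membership.
#'
#' @param n_microbes,n_drugs entity counts.
#' @param n_blocks number of matched communities.
#' @param within_block_density association probability inside matched
#'   blocks.
#' @param background_density association probability elsewhere; must be
#'   below `within_block_density`.
#' @param sequence_length length of generated marker sequences (bases).
#' @param mutation_rate per-base substitution probability from the block
#'   ancestor.
#' @param seed integer RNG seed.
#' @return validated config list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_microbes = 120, n_drugs = 180, n_blocks = 4,
                             within_block_density = 0.3,
                             background_density = 0.02,
                             sequence_length = 200, mutation_rate = 0.05,
                             seed = 1L) {
  cfg <- list(n_microbes = as.integer(n_microbes),
              n_drugs = as.integer(n_drugs),
              n_blocks = as.integer(n_blocks),
              within_block_density = within_block_density,
              background_density = background_density,
              sequence_length = as.integer(sequence_length),
              mutation_rate = mutation_rate,
              seed = as.integer(seed))
  if (cfg$n_microbes < 1 || cfg$n_drugs < 1) stop("entity counts must be >= 1")
  if (cfg$n_blocks < 1 || cfg$n_blocks > min(cfg$n_microbes, cfg$n_drugs))
    stop("n_blocks must be in [1, min(n_microbes, n_drugs)]")
  if (cfg$within_block_density < 0 || cfg$within_block_density > 1 ||
      cfg$background_density < 0 || cfg$background_density > 1)
    stop("densities must lie in [0, 1]")
  if (cfg$within_block_density <= cfg$background_density)
    stop("within_block_density must exceed background_density")
  if (cfg$sequence_length < 1) stop("sequence_length must be >= 1")
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 1)
    stop("mutation_rate must lie in [0, 1]")
  class(cfg) <- "synthetic_config"
  cfg
}

## Split n items into k contiguous blocks of near-equal size.
block_labels <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k), times = sizes)
}

#' Generate a synthetic microbe-drug benchmark with planted blocks
#'
#' Emulates the statistical structure the pipeline assumes: a bipartite
#' association matrix whose density is elevated inside matched
#' microbe/drug blocks, nucleotide sequences whose pairwise similarity
#' tracks block membership (iid per-base mutants of one ancestor per
#' block), and a drug structural-similarity matrix equal to 1 minus the
#' 0/1 block distance plus small Gaussian noise, clipped to `[0, 1]`,
#' symmetrised, with unit diagonal.  Fully reproducible from
#' `config$seed`.
#'
#' @param config a [synthetic_config].
#' @return list with elements `associations` ([md_associations]),
#'   `sequences` (named character), `drug_similarity` ([md_similarity]),
#'   `microbe_blocks`, `drug_blocks` (integer ground-truth labels).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    i <- config$n_microbes; j <- config$n_drugs
    mb <- block_labels(i, config$n_blocks)
    db <- block_labels(j, config$n_blocks)
    mids <- sprintf("microbe_%03d", seq_len(i))
    dids <- sprintf("drug_%03d", seq_len(j))

    same <- outer(mb, db, "==")
    prob <- ifelse(same, config$within_block_density,
                   config$background_density)
    values <- matrix(as.numeric(runif(i * j) < prob), i, j)
    assoc <- md_associations(values, mids, dids)

    bases <- c("A", "C", "G", "T")
    ancestors <- replicate(config$n_blocks,
                           sample(bases, config$sequence_length,
                                  replace = TRUE),
                           simplify = FALSE)
    seqs <- vapply(seq_len(i), function(s) {
      anc <- ancestors[[mb[s]]]
      mut <- runif(config$sequence_length) < config$mutation_rate
      if (any(mut)) {
        anc[mut] <- vapply(anc[mut], function(b) {
          sample(setdiff(bases, b), 1L)
        }, character(1))
      }
      paste(anc, collapse = "")
    }, character(1))
    names(seqs) <- mids

    dist <- 1 - outer(db, db, "==")        # 0 same block, 1 otherwise
    sim <- 1 - dist + matrix(rnorm(j * j, sd = 0.05), j, j)
    sim <- (sim + t(sim)) / 2
    sim <- pmin(pmax(sim, 0), 1)
    diag(sim) <- 1
    dimnames(sim) <- list(dids, dids)
    dss <- md_similarity(sim, dids, kind = "structure",
                         require_unit_diag = FALSE)

    list(associations = assoc, sequences = seqs, drug_similarity = dss,
         microbe_blocks = mb, drug_blocks = db)
  })
}
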