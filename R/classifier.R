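# 8-mer naive Bayesian taxonomy classifier with bootstrap confidence.
# Word model: presence/absence of k-mers per reference sequence.  Word prior
# P(w) = (n(w) + 0.5) / (N + 1) over all N references; per-leaf conditional
# P(w|G) = (m(w) + P(w)) / (M + 1) where a leaf G is one distinct full
# 7-rank taxonomy path with M member sequences.  A query is scored per leaf
# as the sum of log conditionals over its distinct valid words; words
# containing non-ACGT letters are skipped.  Confidence is the percent of
# bootstrap trials (subsampled words, with replacement) whose winning leaf
# agrees with the full-score winner down to each rank.

#' Build the k-mer index of a reference database
#'
#' Trains the naive Bayes word model: groups references into leaves (distinct
#' full 7-rank paths), computes per-word priors and per-leaf conditional log
#' probabilities.  Only word presence/absence per reference counts; words
#' containing ambiguity codes are skipped.  Leaves are stored in
#' lexicographic path order, which is the classifier's deterministic
#' tie-break.
#'
#' @param db A [ReferenceDB-class]; every sequence must have length >= `k`.
#' @param k Word size, default 8.
#' @return A [KmerIndex-class].
#' @export
buildKmerIndex <- function(db, k = 8L) {
  stopifnot(is(db, "ReferenceDB"), k >= 1L)
  k <- as.integer(k)
  seqs <- refSequences(db)
  short <- Biostrings::width(seqs) < k
  if (any(short))
    stop("reference sequence(s) shorter than k: ",
         paste(head(names(seqs)[short], 5L), collapse = ", "))
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  presence <- counts > 0           # N x 4^k logical
  N <- nrow(presence)
  prior <- (colSums(presence) + 0.5) / (N + 1)

  keys <- apply(taxonomy(db), 1L, paste, collapse = ";")
  leaf_keys <- sort(unique(keys))
  leaf_of <- match(keys, leaf_keys)
  L <- length(leaf_keys)
  m <- matrix(0, ncol(presence), L)  # words x leaves: members containing w
  sizes <- integer(L)
  for (l in seq_len(L)) {
    rows <- which(leaf_of == l)
    sizes[l] <- length(rows)
    m[, l] <- colSums(presence[rows, , drop = FALSE])
  }
  logp <- log((m + prior) / rep(sizes + 1, each = nrow(m)))
  paths <- do.call(rbind, strsplit(leaf_keys, ";", fixed = TRUE))
  colnames(paths) <- .RANKS
  new("KmerIndex", k = k, leafPaths = paths, wordPrior = unname(prior),
      leafLogProb = logp, leafSizes = sizes, label = dbLabel(db))
}

# Distinct valid word indices (1-based into the 4^k table) of one sequence.
.queryWords <- function(seq, k) {
  if (length(seq) < k) return(integer())
  which(Biostrings::oligonucleotideFrequency(seq, width = k) > 0)
}

#' Classify sequences against a k-mer index
#'
#' For each query, the full score of every leaf is the sum of log conditional
#' probabilities over the query's distinct valid words; the assignment is the
#' argmax (ties broken towards the lexicographically smallest leaf path).
#' Bootstrap confidence at each rank is the percent of `nBoot` trials --
#' each re-running the argmax on `max(1, floor(|W| * subsampleFrac))` words
#' drawn from the query's word set with replacement -- whose winner shares
#' the full-score winner's names down to that rank; it is non-increasing
#' from coarse to fine by construction.
#'
#' Bootstrap seeds are derived per query from `(seed, query id)`, so results
#' are independent of query order and bit-reproducible for identical
#' `(sequence, index, seed)`.
#'
#' Queries with no valid word (e.g. all-ambiguous) come back fully
#' unclassified with confidence 0.
#'
#' @param queries Named [Biostrings::DNAStringSet] (or single `DNAString`
#'   plus `ids`).
#' @param index A [KmerIndex-class].
#' @param nBoot Bootstrap trials, default 100.
#' @param subsampleFrac Fraction of the word set drawn per trial, default
#'   1/8.
#' @param seed Integer seed for the bootstrap.
#' @return A [TaxAssignmentSet-class] in input order, with `source` set to
#'   the index's database label.
#' @export
classifySequences <- function(queries, index, nBoot = 100L,
                              subsampleFrac = 1 / 8, seed = 1L) {
  stopifnot(is(index, "KmerIndex"), nBoot >= 1L,
            subsampleFrac > 0, subsampleFrac <= 1)
  queries <- Biostrings::DNAStringSet(queries)
  ids <- names(queries)
  if (is.null(ids)) stop("queries must be named")
  n <- length(queries)
  k <- index@k
  logp <- index@leafLogProb
  paths <- index@leafPaths
  L <- nrow(paths)
  ranks <- matrix(.UNCL, n, 7L)
  conf <- matrix(0, n, 7L)
  nb <- as.integer(nBoot)
  for (i in seq_len(n)) {
    W <- .queryWords(queries[[i]], k)
    if (!length(W)) next
    full <- colSums(logp[W, , drop = FALSE])
    win <- which.max(full)          # leaves pre-sorted: first max = lex smallest
    s <- max(1L, as.integer(length(W) * subsampleFrac))
    old <- .Random.seed.save()
    set.seed(.deriveSeed(seed, ids[i]))
    draws <- matrix(W[sample.int(length(W), s * nb, replace = TRUE)], s, nb)
    .Random.seed.restore(old)
    agree <- integer(7L)
    for (b in seq_len(nb)) {
      sc <- colSums(logp[draws[, b], , drop = FALSE])
      bw <- which.max(sc)
      if (bw == win) {
        agree <- agree + 1L
      } else {
        same <- paths[bw, ] == paths[win, ]
        d <- which(!same)[1L] - 1L
        if (d > 0L) agree[seq_len(d)] <- agree[seq_len(d)] + 1L
      }
    }
    ranks[i, ] <- paths[win, ]
    conf[i, ] <- 100 * agree / nb
  }
  TaxAssignmentSet(ids, ranks, conf, source = rep(index@label, n))
}

# Save/restore the global RNG state so per-query seeding does not disturb
# the caller's stream.
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed.restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Apply a bootstrap confidence threshold
#'
#' Working finest to coarsest, every rank whose confidence falls below the
#' threshold is replaced by the unclassified sentinel.  Because confidences
#' are non-increasing with rank depth, the result keeps the
#' unclassified-prefix property.
#'
#' @param assignments A [TaxAssignmentSet-class].
#' @param threshold Percent in \[0, 100\]; default 80, matching common
#'   practice for the Wang classifier.  Ranks with `NA` confidence are left
#'   untouched.
#' @return The thresholded [TaxAssignmentSet-class].
#' @export
applyConfidenceThreshold <- function(assignments, threshold = 80) {
  stopifnot(is(assignments, "TaxAssignmentSet"))
  if (threshold < 0 || threshold > 100)
    stop("threshold must lie in [0, 100]")
  rk <- taxonomy(assignments)
  cf <- confidences(assignments)
  below <- !is.na(cf) & cf < threshold
  rk[below] <- .UNCL
  # enforce the prefix property explicitly (NA-confidence rows could break it)
  for (j in 2:7) {
    blank <- rk[, j - 1L] == .UNCL
    rk[blank, j] <- .UNCL
  }
  TaxAssignmentSet(otuIds(assignments), rk, cf, sourceDb(assignments))
}
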