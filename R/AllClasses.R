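#' ReferenceDB: one reference taxonomy database
#'
#' Holds the reference sequences and 7-rank taxonomy strings of a single
#' database, either the curated ecosystem-specific one or the comprehensive
#' one.  Reference ids link the two slots; every sequence must have a
#' taxonomy row.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of reference sequences, named
#'   by reference id.
#' @slot taxonomy Character matrix (one row per reference, 7 columns, rownames
#'   = reference ids) of taxonomic names; unassigned ranks carry
#'   `unclassifiedLabel()` and obey the unclassified-prefix property.
#' @slot label Database tag, conventionally `"ecosystem"` or
#'   `"comprehensive"`.
#'
#' @aliases ReferenceDB-class
#' @exportClass ReferenceDB
setClass("ReferenceDB",
  slots = c(sequences = "DNAStringSet", taxonomy = "matrix", label = "character"))

setValidity("ReferenceDB", function(object) {
  msg <- character()
  ids <- names(object@sequences)
  if (length(object@sequences) < 1L)
    msg <- c(msg, "a ReferenceDB needs at least one sequence")
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "all sequences must be named")
  if (anyDuplicated(ids))
    msg <- c(msg, "duplicate reference ids")
  if (!is.character(object@taxonomy) || ncol(object@taxonomy) != 7L)
    msg <- c(msg, "taxonomy must be a character matrix with 7 columns")
  else {
    if (!identical(rownames(object@taxonomy), ids))
      msg <- c(msg, "taxonomy rownames must match sequence ids (same order)")
    else if (!all(.hasUnclassifiedPrefix(object@taxonomy)))
      msg <- c(msg, "taxonomy rows violate the unclassified-prefix property")
  }
  if (length(object@label) != 1L || is.na(object@label) || object@label == "")
    msg <- c(msg, "label must be a single non-empty string")
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceDB
#'
#' @param sequences Named [Biostrings::DNAStringSet] (or object coercible to
#'   one) of reference sequences.
#' @param taxonomy Either a character matrix (rows = references, 7 columns) or
#'   a [TaxAssignmentSet-class]; rows are matched to `sequences` by id.
#' @param label Database tag, `"ecosystem"` or `"comprehensive"`.
#' @return A [ReferenceDB-class] object.
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(r1 = "ACGTACGTACGT"))
#' tax <- matrix(c("Bacteria", "P1", "C1", "O1", "F1", "G1", "S1"),
#'               nrow = 1, dimnames = list("r1", NULL))
#' ReferenceDB(seqs, tax, label = "ecosystem")
#' @export
ReferenceDB <- function(sequences, taxonomy, label = "ecosystem") {
  sequences <- Biostrings::DNAStringSet(sequences)
  if (is(taxonomy, "TaxAssignmentSet")) {
    idx <- match(names(sequences), otuIds(taxonomy))
    if (anyNA(idx))
      stop("no taxonomy for reference(s): ",
           paste(names(sequences)[is.na(idx)], collapse = ", "))
    taxonomy <- taxonomy(taxonomy)[idx, , drop = FALSE]
  }
  if (is.null(rownames(taxonomy))) rownames(taxonomy) <- names(sequences)
  taxonomy <- taxonomy[names(sequences), , drop = FALSE]
  colnames(taxonomy) <- .RANKS
  new("ReferenceDB", sequences = sequences, taxonomy = taxonomy, label = label)
}

#' KmerIndex: word-frequency model of a reference database
#'
#' The trained naive Bayes model: per-word priors over all references and
#' per-leaf conditional log probabilities, where a leaf is one distinct full
#' 7-rank taxonomy path.  Built by [buildKmerIndex()].
#'
#' @slot k Word size (8 by default).
#' @slot leafPaths Character matrix (leaves x 7) of leaf taxonomy paths, in
#'   lexicographic order of the collapsed path (the classifier's
#'   deterministic tie-break order).
#' @slot wordPrior Numeric vector of length `4^k`: prior probability that a
#'   reference sequence contains each word.
#' @slot leafLogProb Numeric matrix (`4^k` x leaves) of log conditional word
#'   probabilities per leaf.
#' @slot leafSizes Integer vector: reference sequences per leaf.
#' @slot label Database tag copied from the source [ReferenceDB-class].
#'
#' @aliases KmerIndex-class
#' @exportClass KmerIndex
setClass("KmerIndex",
  slots = c(k = "integer", leafPaths = "matrix", wordPrior = "numeric",
            leafLogProb = "matrix", leafSizes = "integer", label = "character"))

setValidity("KmerIndex", function(object) {
  msg <- character()
  nw <- 4L^object@k
  if (length(object@wordPrior) != nw)
    msg <- c(msg, "wordPrior length must be 4^k")
  else if (any(object@wordPrior <= 0) || any(object@wordPrior >= 1))
    msg <- c(msg, "word priors must lie in (0, 1)")
  if (nrow(object@leafLogProb) != nw ||
      ncol(object@leafLogProb) != nrow(object@leafPaths))
    msg <- c(msg, "leafLogProb must be 4^k x nLeaves")
  if (any(object@leafLogProb > 0))
    msg <- c(msg, "conditional probabilities must be <= 1")
  if (length(object@leafSizes) != nrow(object@leafPaths) ||
      any(object@leafSizes < 1L))
    msg <- c(msg, "every leaf needs at least one reference sequence")
  keys <- apply(object@leafPaths, 1L, paste, collapse = ";")
  if (is.unsorted(keys))
    msg <- c(msg, "leaves must be in lexicographic path order")
  if (length(msg)) msg else TRUE
})

#' TaxAssignmentSet: per-OTU taxonomy paths with bootstrap confidence
#'
#' The result container of [classifySequences()] and [runTaxAss()], and the
#' in-memory form of a taxonomy table read with [readTaxonomyTable()].  One
#' row per OTU: a 7-rank path, per-rank confidence (percent, `NA` when
#' unknown), and the tag of the database that classified it (`NA` when not
#' applicable).
#'
#' @slot ids Character vector of OTU ids (unique).
#' @slot ranks Character matrix (n x 7) of taxonomic names obeying the
#'   unclassified-prefix property.
#' @slot confidence Numeric matrix (n x 7) of bootstrap confidences in
#'   \[0, 100\], non-increasing from coarse to fine rank; may be `NA`.
#' @slot source Character vector: `"ecosystem"`, `"comprehensive"` or `NA`.
#'
#' @aliases TaxAssignmentSet-class
#' @exportClass TaxAssignmentSet
setClass("TaxAssignmentSet",
  slots = c(ids = "character", ranks = "matrix", confidence = "matrix",
            source = "character"))

setValidity("TaxAssignmentSet", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (anyDuplicated(object@ids))
    msg <- c(msg, "duplicate OTU ids")
  if (nrow(object@ranks) != n || ncol(object@ranks) != 7L)
    msg <- c(msg, "ranks must be an n x 7 character matrix")
  else if (n > 0L && !all(.hasUnclassifiedPrefix(object@ranks)))
    msg <- c(msg, "ranks violate the unclassified-prefix property")
  if (nrow(object@confidence) != n || ncol(object@confidence) != 7L)
    msg <- c(msg, "confidence must be an n x 7 numeric matrix")
  else {
    cv <- object@confidence
    if (any(cv < 0 | cv > 100, na.rm = TRUE))
      msg <- c(msg, "confidences must lie in [0, 100]")
  }
  if (length(object@source) != n)
    msg <- c(msg, "source must have one entry per OTU")
  else if (!all(object@source %in% c("ecosystem", "comprehensive", NA)))
    msg <- c(msg, "source entries must be 'ecosystem', 'comprehensive' or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a TaxAssignmentSet
#'
#' @param ids Character vector of OTU ids.
#' @param ranks Character matrix n x 7 of names (or vector for n = 1).
#' @param confidence Numeric matrix n x 7 of percent confidences; defaults to
#'   all-`NA`.
#' @param source Character vector of database tags; defaults to `NA`.
#' @return A [TaxAssignmentSet-class].
#' @export
TaxAssignmentSet <- function(ids, ranks, confidence = NULL, source = NULL) {
  ids <- as.character(ids)
  if (!is.matrix(ranks)) ranks <- matrix(ranks, nrow = length(ids), byrow = TRUE)
  dimnames(ranks) <- list(ids, .RANKS)
  if (is.null(confidence))
    confidence <- matrix(NA_real_, length(ids), 7L)
  if (!is.matrix(confidence))
    confidence <- matrix(confidence, nrow = length(ids), byrow = TRUE)
  storage.mode(confidence) <- "double"
  dimnames(confidence) <- list(ids, .RANKS)
  if (is.null(source)) source <- rep(NA_character_, length(ids))
  new("TaxAssignmentSet", ids = ids, ranks = ranks,
      confidence = confidence, source = as.character(source))
}

#' SplitResult: the cutoff partition of a query set
#'
#' Records which query ids were routed to the ecosystem-specific
#' classification group and which to the comprehensive group, the cutoff
#' applied, and the best recalculated full-length percent identity of each
#' query that had any hit.  Built by [splitOtus()].
#'
#' @slot ecoIds Ids with best full-length identity >= cutoff.
#' @slot compIds All remaining ids (low identity or no hit at all).
#' @slot identities Named numeric vector of best full-length percent
#'   identities; ids without hits are absent.
#' @slot cutoff The percent identity cutoff applied (percent scale, e.g. 98).
#'
#' @aliases SplitResult-class
#' @exportClass SplitResult
setClass("SplitResult",
  slots = c(ecoIds = "character", compIds = "character",
            identities = "numeric", cutoff = "numeric"))

setValidity("SplitResult", function(object) {
  msg <- character()
  if (length(intersect(object@ecoIds, object@compIds)))
    msg <- c(msg, "eco and comp groups must be disjoint")
  all_ids <- c(object@ecoIds, object@compIds)
  if (anyDuplicated(all_ids))
    msg <- c(msg, "duplicate ids in the partition")
  if (!all(names(object@identities) %in% all_ids))
    msg <- c(msg, "identities carry ids outside the partition")
  eco_fl <- object@identities[object@ecoIds]
  if (anyNA(eco_fl) || any(eco_fl < object@cutoff))
    msg <- c(msg, "every eco id must have identity >= cutoff")
  if (length(msg)) msg else TRUE
})
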