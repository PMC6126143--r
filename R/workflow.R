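# End-to-end run (split -> classify twice -> recombine) and the diagnostic
# metrics: percent of reads classified per rank, taxonomic richness, the
# percent identity cutoff sweep, and the coarse-rank conflict check.

#' Run the full dual-database assignment workflow
#'
#' Splits the queries by their best recalculated full-length identity against
#' the ecosystem-specific references, classifies the high-identity group with
#' the ecosystem-specific database and the rest (including no-hit queries)
#' with the comprehensive database, applies the bootstrap confidence
#' threshold, and recombines in input order.
#'
#' @param queries Named [Biostrings::DNAStringSet] of query sequences.
#' @param ecoDb,compDb [ReferenceDB-class] objects (or prebuilt
#'   [KmerIndex-class] objects, accepted to avoid re-indexing).
#' @param hits Hit data.frame from [readBlastTable()] (queries vs the
#'   ecosystem-specific references); queries absent from it are treated as
#'   no-hit.
#' @param cutoff Percent identity cutoff (percent scale), default 98.
#' @param confidence Bootstrap confidence threshold, default 80.
#' @param topN Leading BLAST hits recalculated per query, default 5.
#' @param nBoot,seed Passed to [classifySequences()].
#' @return A [TaxAssignmentSet-class] in query order with per-OTU `source`
#'   tags; the [SplitResult-class] is attached as attribute `"split"`.
#' @export
runTaxAss <- function(queries, ecoDb, compDb, hits, cutoff = 98,
                      confidence = 80, topN = 5L, nBoot = 100L, seed = 1L) {
  queries <- Biostrings::DNAStringSet(queries)
  ids <- names(queries)
  if (!length(queries)) {
    out <- TaxAssignmentSet(character(), matrix(character(), 0L, 7L))
    attr(out, "split") <- splitOtus(character(), numeric(), cutoff)
    return(out)
  }
  ecoIdx <- if (is(ecoDb, "KmerIndex")) ecoDb else buildKmerIndex(ecoDb)
  compIdx <- if (is(compDb, "KmerIndex")) compDb else buildKmerIndex(compDb)
  split <- splitOtus(ids, bestHits(hits, topN = topN), cutoff)
  parts <- partitionFasta(queries, split)
  pieces <- list()
  if (length(parts$eco))
    pieces$eco <- classifySequences(parts$eco, ecoIdx, nBoot = nBoot,
                                    seed = seed)
  if (length(parts$comp))
    pieces$comp <- classifySequences(parts$comp, compIdx, nBoot = nBoot,
                                     seed = seed)
  combined <- do.call(.rbindAssignments, unname(pieces))
  combined <- applyConfidenceThreshold(combined, confidence)
  out <- combined[ids]
  attr(out, "split") <- split
  out
}

.rbindAssignments <- function(...) {
  parts <- list(...)
  TaxAssignmentSet(
    unlist(lapply(parts, otuIds)),
    do.call(rbind, lapply(parts, taxonomy)),
    do.call(rbind, lapply(parts, confidences)),
    unlist(lapply(parts, sourceDb))
  )
}

#' Percent of the data set classified at a rank
#'
#' Computes `100 * total reads classified / total reads`, where an OTU
#' counts as classified at a rank iff its name there is not the unclassified
#' sentinel.  Read-weighted by default; set `weights = "otus"` (or omit the
#' abundance table) to weight every OTU equally.
#'
#' @param assignments A [TaxAssignmentSet-class].
#' @param abundance Abundance data.frame from [readAbundanceTable()], or
#'   `NULL` for OTU weighting.
#' @param level Rank name, alias or index 1..7.
#' @param weights `"reads"` (default when `abundance` given) or `"otus"`.
#' @return Percent in \[0, 100\].
#' @export
percentClassified <- function(assignments, abundance = NULL, level,
                              weights = c("reads", "otus")) {
  stopifnot(is(assignments, "TaxAssignmentSet"))
  weights <- if (is.null(abundance)) "otus" else match.arg(weights)
  j <- .matchRank(level)
  ids <- otuIds(assignments)
  if (!length(ids)) stop("no assignments")
  if (weights == "reads") {
    totals <- otuTotals(abundance)
    missing <- setdiff(ids, names(totals))
    if (length(missing))
      stop("assignment id(s) absent from abundance table: ",
           paste(head(missing, 5L), collapse = ", "))
    w <- totals[ids]
  } else {
    w <- rep(1, length(ids))
  }
  if (sum(w) == 0) stop("zero total reads")
  named <- taxonomy(assignments)[, j] != .UNCL
  100 * sum(w[named]) / sum(w)
}

#' Taxonomic richness at a rank
#'
#' Number of distinct classifications at a rank: unique taxonomy paths
#' truncated at `level`.  Paths that end in the unclassified sentinel before
#' `level` count as distinct per their named prefix; the fully unclassified
#' path is excluded.
#'
#' @param assignments A [TaxAssignmentSet-class].
#' @param level Rank name, alias or index 1..7.
#' @return Non-negative integer count.
#' @export
taxonomicRichness <- function(assignments, level) {
  stopifnot(is(assignments, "TaxAssignmentSet"))
  j <- .matchRank(level)
  if (!length(assignments)) return(0L)
  trunc <- taxonomy(assignments)[, seq_len(j), drop = FALSE]
  keys <- apply(trunc, 1L, paste, collapse = ";")
  named <- rowSums(trunc != .UNCL) > 0
  length(unique(keys[named]))
}

#' Sweep the percent identity cutoff
#'
#' Runs the workflow across a grid of cutoffs and tabulates the percent of
#' reads classified at every rank under each cutoff.  A cutoff that
#' maximises reads classified at fine ranks has minimised placement errors
#' of the abundant OTUs, so the table (and [plotCutoffSweep()]) guide the
#' cutoff choice.  Queries are classified once per database and the results
#' reused across cutoffs, so the grid costs two classification passes.
#'
#' @inheritParams runTaxAss
#' @param cutoffs Numeric vector of cutoffs to evaluate.
#' @param abundance Abundance data.frame from [readAbundanceTable()], or
#'   `NULL` to weight OTUs equally.
#' @return A 7 x `length(cutoffs)` matrix (ranks x cutoffs) of percent
#'   classified, with a tidy data.frame (`level`, `cutoff`,
#'   `pct_reads_classified`) attached as attribute `"long"`.
#' @export
cutoffSweep <- function(queries, ecoDb, compDb, hits, cutoffs,
                        confidence = 80, abundance = NULL, topN = 5L,
                        nBoot = 100L, seed = 1L) {
  stopifnot(length(cutoffs) >= 1L)
  queries <- Biostrings::DNAStringSet(queries)
  ids <- names(queries)
  ecoIdx <- if (is(ecoDb, "KmerIndex")) ecoDb else buildKmerIndex(ecoDb)
  compIdx <- if (is(compDb, "KmerIndex")) compDb else buildKmerIndex(compDb)
  # classify everything once with each database; group membership under a
  # given cutoff then just selects rows
  byEco <- applyConfidenceThreshold(
    classifySequences(queries, ecoIdx, nBoot = nBoot, seed = seed), confidence)
  byComp <- applyConfidenceThreshold(
    classifySequences(queries, compIdx, nBoot = nBoot, seed = seed), confidence)
  best <- bestHits(hits, topN = topN)
  out <- matrix(NA_real_, 7L, length(cutoffs),
                dimnames = list(.RANKS, as.character(cutoffs)))
  for (c_i in seq_along(cutoffs)) {
    split <- suppressMessages(splitOtus(ids, best, cutoffs[c_i]))
    inEco <- ids %in% ecoIds(split)
    merged <- TaxAssignmentSet(
      ids,
      ifelse(matrix(inEco, length(ids), 7L),
             taxonomy(byEco), taxonomy(byComp)),
      ifelse(matrix(inEco, length(ids), 7L),
             confidences(byEco), confidences(byComp)),
      ifelse(inEco, "ecosystem", "comprehensive"))
    for (j in 1:7)
      out[j, c_i] <- percentClassified(merged, abundance, j)
  }
  long <- data.frame(
    level = rep(.RANKS, times = length(cutoffs)),
    cutoff = rep(cutoffs, each = 7L),
    pct_reads_classified = as.vector(out))
  attr(out, "long") <- long
  out
}

#' Plot a cutoff sweep
#'
#' Line chart of percent of reads classified against cutoff, one line per
#' rank -- the visual aid for choosing the percent identity cutoff.
#'
#' @param sweep Matrix returned by [cutoffSweep()].
#' @return A ggplot object.
#' @export
plotCutoffSweep <- function(sweep) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  long <- attr(sweep, "long")
  if (is.null(long)) {
    long <- data.frame(
      level = rep(rownames(sweep), times = ncol(sweep)),
      cutoff = rep(as.numeric(colnames(sweep)), each = nrow(sweep)),
      pct_reads_classified = as.vector(sweep))
  }
  long$level <- factor(long$level, levels = .RANKS)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff,
                                     y = .data$pct_reads_classified,
                                     colour = .data$level)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "percent identity cutoff", y = "% reads classified",
                  colour = "rank") +
    ggplot2::theme_minimal()
}

#' Check ecosystem-classified OTUs for coarse-rank conflicts
#'
#' Phylum- and class-level names are more reliable from a large
#' comprehensive database; disagreement at these coarse ranks between the
#' dual-database result and a comprehensive-only classification indicates
#' the percent identity cutoff is too low.  Only OTUs classified by the
#' ecosystem-specific database *and* named at the rank in both
#' classifications enter the denominator.
#'
#' @param taxass [TaxAssignmentSet-class] from [runTaxAss()].
#' @param compOnly [TaxAssignmentSet-class] of the same ids classified with
#'   the comprehensive database alone.
#' @param ranks Ranks to compare, default phylum and class.
#' @return List with one element per compared rank, each containing
#'   `n_compared`, `n_conflicts`, `fraction`, and a data.frame `pairs` of the
#'   disagreeing names.
#' @export
coarseConflictCheck <- function(taxass, compOnly,
                                ranks = c("phylum", "class")) {
  stopifnot(is(taxass, "TaxAssignmentSet"), is(compOnly, "TaxAssignmentSet"))
  if (!setequal(otuIds(taxass), otuIds(compOnly)))
    stop("the two classifications must cover the same OTU ids")
  compOnly <- compOnly[otuIds(taxass)]
  eco <- !is.na(sourceDb(taxass)) & sourceDb(taxass) == "ecosystem"
  out <- list()
  for (r in ranks) {
    j <- .matchRank(r)
    a <- taxonomy(taxass)[, j]
    b <- taxonomy(compOnly)[, j]
    comparable <- eco & a != .UNCL & b != .UNCL
    conflict <- comparable & a != b
    out[[.RANKS[j]]] <- list(
      n_compared = sum(comparable),
      n_conflicts = sum(conflict),
      fraction = if (sum(comparable)) sum(conflict) / sum(comparable) else 0,
      pairs = data.frame(otu_id = otuIds(taxass)[conflict],
                         taxass = a[conflict], comp_only = b[conflict],
                         row.names = NULL))
  }
  out
}
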