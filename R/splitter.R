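# Partition the query set into the ecosystem-specific and comprehensive
# classification groups by applying the percent identity cutoff to each
# query's best recalculated hit.

#' Split queries into ecosystem-specific and comprehensive groups
#'
#' A query is routed to the ecosystem-specific group if and only if its best
#' recalculated full-length percent identity is greater than or equal to the
#' cutoff (the boundary is inclusive).  Queries without any hit -- blastn
#' omits them from tabular output -- go to the comprehensive group; their
#' count is reported via `message()`.
#'
#' @param queryIds Character vector of all query ids (the FASTA ids).
#' @param best Either the data.frame returned by [bestHits()] or a named
#'   numeric vector of best full-length identities; ids covered must be a
#'   subset of `queryIds`.
#' @param cutoff Percent identity cutoff on the percent scale (e.g. 98).
#'   Comparison uses the unrounded identity.
#' @return A [SplitResult-class].
#' @export
splitOtus <- function(queryIds, best, cutoff) {
  stopifnot(length(cutoff) == 1L, is.finite(cutoff))
  if (is.data.frame(best)) {
    fl <- setNames(best$fl_pident, best$qseqid)
  } else {
    fl <- best
  }
  unknown <- setdiff(names(fl), queryIds)
  if (length(unknown))
    stop("best hits for unknown query id(s): ",
         paste(head(unknown, 5L), collapse = ", "))
  eco <- as.character(names(fl)[fl >= cutoff])
  comp <- as.character(setdiff(queryIds, eco))
  nohit <- setdiff(queryIds, names(fl))
  if (length(nohit))
    message(length(nohit), " quer", if (length(nohit) == 1L) "y" else "ies",
            " without hits routed to the comprehensive group")
  new("SplitResult", ecoIds = eco, compIds = comp,
      identities = fl, cutoff = as.numeric(cutoff))
}

#' Partition a sequence set according to a SplitResult
#'
#' @param records Named [Biostrings::DNAStringSet] covering every id in the
#'   split.
#' @param split A [SplitResult-class].
#' @return List with elements `eco` and `comp`, each a `DNAStringSet` in the
#'   input order; together a permutation-free partition of `records`.
#' @export
partitionFasta <- function(records, split) {
  stopifnot(is(split, "SplitResult"))
  ids <- names(records)
  all_split <- c(ecoIds(split), compIds(split))
  missing <- setdiff(all_split, ids)
  if (length(missing))
    stop("split references id(s) absent from records: ",
         paste(head(missing, 5L), collapse = ", "))
  extra <- setdiff(ids, all_split)
  if (length(extra))
    stop("records not covered by the split: ",
         paste(head(extra, 5L), collapse = ", "))
  list(eco = records[ids %in% ecoIds(split)],
       comp = records[ids %in% compIds(split)])
}
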