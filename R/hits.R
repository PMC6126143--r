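# BLAST tabular (outfmt 6, custom columns) post-processing: parsing,
# recalculation of local percent identity to full-query-length percent
# identity, best-of-top-N hit selection, and the hit-rank agreement table.

.FMT6_DEFAULT <- c("qseqid", "pident", "length", "qlen", "qstart", "qend",
                   "sseqid", "mismatch")
.FMT6_NUMERIC <- c("pident", "length", "qlen", "qstart", "qend", "mismatch",
                   "slen", "sstart", "send", "evalue", "bitscore", "gapopen")

#' Default custom outfmt-6 column order
#'
#' The column order the workflow asks blastn for; default tabular output
#' lacks `qlen`, which the recalculation needs.
#'
#' @return Character vector of field names.
#' @export
blastColumns <- function() .FMT6_DEFAULT

#' Parse a BLAST tabular hit file
#'
#' Reads tab-separated outfmt-6 output with a configurable column order.  The
#' file order within each query defines the hit rank (blastn sorts hits by
#' score; the parser never re-sorts).  Per-row invariants are enforced:
#' `qstart <= qend <= qlen`, query span `<=` alignment length, and
#' `pident <= 100`.
#'
#' @param path Path to the hit file.
#' @param columns Ordered field names; must include
#'   `qseqid, sseqid, pident, length, qlen, qstart, qend`.
#' @return A data.frame of hits with an added integer `hit_rank` column
#'   (1-based position within each query, in file order).  Empty file gives a
#'   zero-row frame.
#' @export
readBlastTable <- function(path, columns = blastColumns()) {
  if (!file.exists(path)) stop("no such file: ", path)
  need <- c("qseqid", "sseqid", "pident", "length", "qlen", "qstart", "qend")
  miss <- setdiff(need, columns)
  if (length(miss))
    stop("column spec must include: ", paste(miss, collapse = ", "))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    df <- as.data.frame(setNames(rep(list(character()), length(columns)),
                                 columns), stringsAsFactors = FALSE)
    for (nm in intersect(columns, .FMT6_NUMERIC)) df[[nm]] <- numeric()
    df$hit_rank <- integer()
    return(df)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != length(columns)
  if (any(bad))
    stop("line ", which(bad)[1L], ": expected ", length(columns),
         " tab-separated fields, found ", lengths(parts)[which(bad)[1L]])
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- columns
  for (nm in intersect(columns, .FMT6_NUMERIC)) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (anyNA(v))
      stop("line ", which(is.na(v))[1L], ": non-numeric '", nm, "'")
    df[[nm]] <- v
  }
  .checkHitInvariants(df)
  if (all(c("sstart", "send") %in% columns) && any(df$sstart > df$send))
    warning(sum(df$sstart > df$send),
            " minus-strand subject hit(s); queries are assumed pre-oriented")
  # hit_rank = running position within each query, in file order
  df$hit_rank <- stats::ave(seq_len(nrow(df)), df$qseqid,
                            FUN = seq_along)
  df
}

.checkHitInvariants <- function(df) {
  chk <- function(cond, what) {
    if (any(cond)) stop("line ", which(cond)[1L], ": ", what)
  }
  chk(df$qstart > df$qend, "qstart > qend")
  chk(df$qend > df$qlen, "qend > qlen")
  chk(df$length < 1, "alignment length < 1")
  chk((df$qend - df$qstart + 1) > df$length, "query span exceeds alignment length")
  chk(df$pident > 100 | df$pident <= 0, "pident outside (0, 100]")
  invisible(df)
}

#' Recalculate local percent identity to full query length
#'
#' BLAST's `pident` covers only the locally aligned region; unaligned query
#' nucleotides (the overhang) can hide mismatches that matter when a single
#' mismatch changes a classification.  The full-length percent identity
#' treats every overhang nucleotide as a mismatch:
#'
#' \deqn{fl = \frac{pident \times length}{qlen + [length - (qend - qstart + 1)]}}
#'
#' The denominator is the query length plus the alignment's query-gap
#' columns, so the value equals 100 x matches / (qlen + query gap columns)
#' and never exceeds `pident`, with equality exactly when the alignment
#' spans the whole query.  The unrounded value is stored; round for display
#' only.
#'
#' @param hits A hit data.frame from [readBlastTable()] (or with the same
#'   numeric columns).
#' @return The data.frame with an added numeric `fl_pident` column.
#' @examples
#' h <- data.frame(qseqid = "q", sseqid = "s", pident = 100, length = 230,
#'                 qlen = 250, qstart = 21, qend = 250)
#' recalcIdentity(h)$fl_pident  # 92: 20-nt overhang counted as mismatches
#' @export
recalcIdentity <- function(hits) {
  .checkHitInvariants(hits)
  span <- hits$qend - hits$qstart + 1
  hits$fl_pident <- hits$pident * hits$length / (hits$qlen + hits$length - span)
  hits
}

#' Best recalculated hit per query
#'
#' Recalculates the first `topN` hits of each query (file order = BLAST score
#' order) and keeps, per query, the hit with the maximal full-length percent
#' identity; ties go to the lowest hit rank.  The best BLAST hit does not
#' always have the highest recalculated identity, because a shorter
#' higher-scoring alignment can hide overhang mismatches that a longer,
#' lower-ranked alignment resolves.
#'
#' @param hits A hit data.frame from [readBlastTable()].
#' @param topN Number of leading hits per query to consider (default 5).
#' @return A data.frame with one row per query id present in `hits`, carrying
#'   `fl_pident` and the winning `hit_rank`.  Queries absent from `hits`
#'   (blastn omits no-hit queries) simply have no row; the caller routes them
#'   to the comprehensive group.
#' @export
bestHits <- function(hits, topN = 5L) {
  stopifnot(topN >= 1L)
  if (!nrow(hits)) {
    return(data.frame(qseqid = character(), sseqid = character(),
                      fl_pident = numeric(), hit_rank = integer()))
  }
  if (is.null(hits$hit_rank))
    hits$hit_rank <- stats::ave(seq_len(nrow(hits)), hits$qseqid,
                                FUN = seq_along)
  hits <- hits[hits$hit_rank <= topN, , drop = FALSE]
  hits <- recalcIdentity(hits)
  # stable order: by query (first appearance), then hit_rank; max.col-free
  # scan keeps the lowest rank on ties because order is rank-ascending
  first <- !duplicated(hits$qseqid)
  qlevels <- hits$qseqid[first]
  qi <- match(hits$qseqid, qlevels)
  o <- order(qi, hits$hit_rank)
  hits <- hits[o, , drop = FALSE]
  qi <- qi[o]
  best <- vapply(split(seq_len(nrow(hits)), qi), function(rows) {
    rows[which.max(hits$fl_pident[rows])]
  }, integer(1L))
  out <- hits[best, c("qseqid", "sseqid", "fl_pident", "hit_rank"),
              drop = FALSE]
  out <- out[order(match(out$qseqid, qlevels)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Agreement between BLAST hit order and recalculated identities
#'
#' For each cutoff, restricts to queries whose best recalculated identity
#' meets the cutoff and tabulates, as a percentage, which BLAST hit rank
#' provided that best recalculated hit.  High agreement in the first row
#' indicates `topN` hits suffice; mass in later rows suggests requesting more
#' BLAST hits.
#'
#' @param hits A hit data.frame from [readBlastTable()].
#' @param cutoffs Numeric vector of percent identity cutoffs (columns).
#' @param topN Hits examined per query (rows), default 5.
#' @return A `topN` x `length(cutoffs)` matrix of percentages; each column
#'   sums to 100 for a non-empty restriction.  Columns with no qualifying
#'   query are zero and flagged in the `"empty"` attribute.
#' @export
hitRankAgreement <- function(hits, cutoffs, topN = 5L) {
  stopifnot(length(cutoffs) >= 1L)
  bh <- bestHits(hits, topN = topN)
  out <- matrix(0, nrow = topN, ncol = length(cutoffs),
                dimnames = list(paste0("hit_", seq_len(topN)),
                                as.character(cutoffs)))
  empty <- logical(length(cutoffs))
  for (j in seq_along(cutoffs)) {
    keep <- bh$fl_pident >= cutoffs[j]
    if (!any(keep)) { empty[j] <- TRUE; next }
    tab <- tabulate(bh$hit_rank[keep], nbins = topN)
    out[, j] <- 100 * tab / sum(keep)
  }
  attr(out, "empty") <- empty
  out
}

#' Write a hit table in BLAST outfmt-6 layout
#'
#' @param hits Hit data.frame (the `hit_rank` and `fl_pident` columns, if
#'   present, are dropped).
#' @param path Output path.
#' @param columns Column order to write; defaults to [blastColumns()].
#' @return `path`, invisibly.
#' @export
writeBlastTable <- function(hits, path, columns = blastColumns()) {
  write.table(hits[, columns, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
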