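# Readers and writers for the three plain-text formats the workflow consumes:
# FASTA, 7-rank semicolon taxonomy tables (mothur-compatible dialect), and
# OTU-by-sample abundance tables.

#' Read a quality-controlled FASTA file
#'
#' Reads standard FASTA (wrapped or unwrapped).  Header text up to the first
#' whitespace becomes the sequence id; sequences are upper-cased and RNA `U`
#' is normalised to `T`.  Ids must be unique, sequences non-empty, and the
#' alphabet restricted to IUPAC nucleotide codes.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(chartr("Uu", "Tt", as.character(raw)))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence(s): ", paste(ids[empty], collapse = ", "))
  bad <- grepl(sprintf("[^%s]", paste(.IUPAC_LETTERS, collapse = "")), seqs)
  if (any(bad)) {
    # locate the first offending line for the error message
    lines <- readLines(path, warn = FALSE)
    body <- toupper(chartr("Uu", "Tt", lines))
    off <- which(!startsWith(lines, ">") &
                 grepl(sprintf("[^%s[:space:]]",
                               paste(.IUPAC_LETTERS, collapse = "")), body))
    stop("non-IUPAC character in sequence '", ids[bad][1L], "' (line ",
         if (length(off)) off[1L] else NA, ")")
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences as FASTA
#'
#' One unwrapped sequence line per record; round-trips exactly through
#' [readFasta()].
#'
#' @param records A named [Biostrings::DNAStringSet] (or coercible).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(records, path) {
  records <- Biostrings::DNAStringSet(records)
  Biostrings::writeXStringSet(records, path, width = 20001L)
  invisible(path)
}

#' Read a 7-rank taxonomy table
#'
#' Parses a two-column tab-separated file of `id<TAB>k;p;c;o;f;g;s;` lines.
#' Per-name bootstrap confidences in parentheses (the mothur dialect,
#' `Bacteria(100);...`) are parsed and stripped into the confidence matrix.
#' Lineages shorter than 7 ranks are padded with the unclassified sentinel; a
#' trailing semicolon is tolerated; more than 7 ranks is an error.
#'
#' @param path Path to a taxonomy TSV.
#' @return A [TaxAssignmentSet-class]; confidences are `NA` where the file
#'   carries none.
#' @export
readTaxonomyTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(TaxAssignmentSet(character(), matrix(character(), 0L, 7L)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop("line ", which(bad)[1L], ": expected 'id<TAB>lineage'")
  ids <- vapply(parts, `[[`, "", 1L)
  lineages <- vapply(parts, `[[`, "", 2L)
  ranks <- matrix(.UNCL, length(ids), 7L)
  conf <- matrix(NA_real_, length(ids), 7L)
  for (i in seq_along(lineages)) {
    toks <- strsplit(sub(";$", "", lineages[i]), ";", fixed = TRUE)[[1]]
    toks <- trimws(toks)
    if (length(toks) > 7L)
      stop("line ", i, ": more than 7 ranks for id '", ids[i], "'")
    has_par <- grepl("(", toks, fixed = TRUE)
    if (any(has_par)) {
      m <- regmatches(toks, regexec("^(.*)\\(([0-9]+(\\.[0-9]+)?)\\)$", toks))
      ok <- lengths(m) >= 3L
      if (!all(ok[has_par]))
        stop("line ", i, ": malformed confidence parenthetical in '",
             toks[has_par & !ok][1L], "'")
      conf[i, which(has_par)] <- as.numeric(vapply(m[has_par], `[[`, "", 3L))
      toks[has_par] <- vapply(m[has_par], `[[`, "", 2L)
    }
    ranks[i, seq_along(toks)] <- toks
  }
  TaxAssignmentSet(ids, ranks, conf)
}

#' Write a 7-rank taxonomy table
#'
#' One line per OTU: id, tab, the 7 semicolon-delimited names each suffixed
#' with its confidence in parentheses (omitted when `NA`).  Round-trips
#' through [readTaxonomyTable()].
#'
#' @param assignments A [TaxAssignmentSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTaxonomyTable <- function(assignments, path) {
  stopifnot(is(assignments, "TaxAssignmentSet"))
  n <- length(assignments)
  lines <- character(n)
  rk <- taxonomy(assignments)
  cf <- confidences(assignments)
  for (i in seq_len(n)) {
    toks <- if (anyNA(cf[i, ])) rk[i, ] else paste0(rk[i, ], "(", cf[i, ], ")")
    lines[i] <- paste0(otuIds(assignments)[i], "\t",
                       paste(toks, collapse = ";"), ";")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an OTU-by-sample abundance table
#'
#' Expects a TSV with header `otu_id<TAB>sample1<TAB>...` and one row of
#' non-negative counts per OTU.  Ragged rows and negative counts are errors.
#'
#' @param path Path to the TSV.
#' @return A data.frame with column `otu_id` followed by one numeric column
#'   per sample; per-OTU totals are available via [otuTotals()].
#' @export
readAbundanceTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty abundance table")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(parts[[1L]])
  if (ncols < 2L) stop("abundance table needs at least one sample column")
  ragged <- lengths(parts) != ncols
  if (any(ragged))
    stop("ragged row at line ", which(ragged)[1L])
  header <- parts[[1L]]
  body <- parts[-1L]
  ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate otu ids in abundance table")
  counts <- matrix(NA_real_, length(body), ncols - 1L)
  for (i in seq_along(body))
    counts[i, ] <- suppressWarnings(as.numeric(body[[i]][-1L]))
  if (anyNA(counts)) stop("non-numeric count at line ",
                          which(apply(is.na(counts), 1L, any))[1L] + 1L)
  if (any(counts < 0)) stop("negative count at line ",
                            which(apply(counts < 0, 1L, any))[1L] + 1L)
  out <- data.frame(otu_id = ids, counts, stringsAsFactors = FALSE)
  names(out) <- c("otu_id", header[-1L])
  out
}

#' Per-OTU total read counts
#'
#' @param abundance A data.frame as returned by [readAbundanceTable()].
#' @return Named numeric vector of row sums.
#' @export
otuTotals <- function(abundance) {
  stopifnot(is.data.frame(abundance), "otu_id" %in% names(abundance))
  setNames(rowSums(abundance[, -match("otu_id", names(abundance)),
                             drop = FALSE]),
           abundance$otu_id)
}
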