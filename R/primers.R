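# In-silico primer trimming: locate a degenerate forward primer and the
# reverse complement of the reverse primer downstream of it, and return the
# inter-primer region -- emulating how short variable-region tags are
# simulated from full-length 16S sequences.

.PRIMER_REGISTRY <- list(
  "V4" = list(forward_name = "515F", forward = "GTGCCAGCMGCCGCGGTAA",
              reverse_name = "806R", reverse = "GGACTACHVGGGTWTCTAAT"),
  "V4-V5" = list(forward_name = "515FB", forward = "GTGYCAGCMGCCGCGGTAA",
                 reverse_name = "926R", reverse = "CCGYCAATTYMTTTRAGTTT"),
  "V3-V4" = list(forward_name = "341F", forward = "CCTACGGGNGGCWGCAG",
                 reverse_name = "805R", reverse = "GACTACHVGGGTATCTAATCC")
)

#' Built-in primer pairs
#'
#' Registry of the three commonly used 16S variable-region primer pairs:
#' V4 (515F/806R), V4-V5 (515FB/926R) and V3-V4 (341F/805R).  Reverse
#' primers are given in their own 5'->3' orientation.
#'
#' @param name Optional region name; omit to list all.
#' @return A `PrimerPair` (list with `name`, `forward`, `reverse`) or, with
#'   no argument, the named list of all pairs.
#' @examples
#' primerPair("V4")$forward
#' @export
primerPair <- function(name) {
  if (missing(name)) {
    return(lapply(setNames(names(.PRIMER_REGISTRY), names(.PRIMER_REGISTRY)),
                  primerPair))
  }
  p <- .PRIMER_REGISTRY[[name]]
  if (is.null(p))
    stop("unknown primer pair '", name, "'; available: ",
         paste(names(.PRIMER_REGISTRY), collapse = ", "))
  structure(list(name = name, forward = p$forward, reverse = p$reverse,
                 forward_name = p$forward_name,
                 reverse_name = p$reverse_name),
            class = "PrimerPair")
}

#' Trim full-length sequences to an amplified region
#'
#' For each sequence, finds the forward primer site (IUPAC-degenerate exact
#' match, zero mismatches: M matches A or C, H matches A/C/T, and so on) and
#' the reverse complement of the reverse primer downstream of it, and
#' returns the inter-primer insert with both primer sites removed.  With
#' multiple forward sites the first is taken (and noted via `message()`).
#' Sequences lacking either site are reported in `failures`, never silently
#' dropped.
#'
#' @param fullLength Named [Biostrings::DNAStringSet] of full-length
#'   sequences.
#' @param primers A `PrimerPair` from [primerPair()], or a list with
#'   `forward` and `reverse` IUPAC strings (reverse primer in its own
#'   5'->3' orientation).
#' @param maxMismatch Mismatches tolerated per primer site, default 0.
#' @return List with `trimmed` (a `DNAStringSet` of inserts, input names
#'   kept, successful sequences only) and `failures` (data.frame `id`,
#'   `reason` with reasons `"no_forward_site"`, `"no_reverse_site"` or
#'   `"empty_insert"`).
#' @export
simulateTags <- function(fullLength, primers, maxMismatch = 0L) {
  fullLength <- Biostrings::DNAStringSet(fullLength)
  if (is.null(names(fullLength))) stop("sequences must be named")
  fwd <- Biostrings::DNAString(primers$forward)
  rev_rc <- Biostrings::reverseComplement(Biostrings::DNAString(primers$reverse))
  trimmed <- character(); kept <- character()
  fail_id <- character(); fail_reason <- character()
  n_multi <- 0L
  for (i in seq_along(fullLength)) {
    s <- fullLength[[i]]
    fm <- Biostrings::matchPattern(fwd, s, max.mismatch = maxMismatch,
                                   fixed = "subject")
    if (!length(fm)) {
      fail_id <- c(fail_id, names(fullLength)[i])
      fail_reason <- c(fail_reason, "no_forward_site")
      next
    }
    if (length(fm) > 1L) n_multi <- n_multi + 1L
    f_end <- IRanges::end(fm)[1L]
    rm_ <- Biostrings::matchPattern(rev_rc, s, max.mismatch = maxMismatch,
                                    fixed = "subject")
    rm_ <- rm_[IRanges::start(rm_) > f_end]
    if (!length(rm_)) {
      fail_id <- c(fail_id, names(fullLength)[i])
      fail_reason <- c(fail_reason, "no_reverse_site")
      next
    }
    r_start <- IRanges::start(rm_)[1L]
    if (r_start - 1L < f_end + 1L) {
      fail_id <- c(fail_id, names(fullLength)[i])
      fail_reason <- c(fail_reason, "empty_insert")
      next
    }
    trimmed <- c(trimmed, as.character(Biostrings::subseq(s, f_end + 1L,
                                                          r_start - 1L)))
    kept <- c(kept, names(fullLength)[i])
  }
  if (n_multi)
    message(n_multi, " sequence(s) had multiple forward-primer sites; ",
            "first site used")
  out <- Biostrings::DNAStringSet(trimmed)
  names(out) <- kept
  list(trimmed = out,
       failures = data.frame(id = fail_id, reason = fail_reason,
                             row.names = NULL))
}
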