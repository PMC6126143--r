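# Canonical rank vocabulary.  Curated freshwater-style databases call the
# three finest ranks lineage/clade/tribe; those aliases resolve to
# family/genus/species.
.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

.RANK_ALIASES <- c(
  kingdom = 1L, domain = 1L, phylum = 2L, class = 3L, order = 4L,
  family = 5L, lineage = 5L, genus = 6L, clade = 6L, species = 7L, tribe = 7L
)

.UNCL <- "unclassified"

.IUPAC_LETTERS <- strsplit("ACGTMRWSYKVHDBN", "")[[1]]

#' Rank names used throughout dualTax
#'
#' @return Character vector of the seven rank names, coarse to fine.
#' @export
taxRanks <- function() .RANKS

#' Unclassified sentinel
#'
#' @return The string used to mark an unassigned rank.
#' @export
unclassifiedLabel <- function() .UNCL

# Resolve a rank given as index 1..7 or name/alias to an integer index.
.matchRank <- function(level) {
  if (is.numeric(level)) {
    level <- as.integer(level)
    if (length(level) != 1L || is.na(level) || level < 1L || level > 7L)
      stop("rank index must be a single integer in 1..7")
    return(level)
  }
  idx <- .RANK_ALIASES[tolower(as.character(level))]
  if (length(idx) != 1L || is.na(idx))
    stop("unknown rank '", level, "'; use one of: ",
         paste(names(.RANK_ALIASES), collapse = ", "))
  unname(idx)
}

# Once a rank is unclassified every finer rank must be too.
.hasUnclassifiedPrefix <- function(ranks) {
  # ranks: character matrix n x 7
  uncl <- ranks == .UNCL
  ok <- rep(TRUE, nrow(ranks))
  for (j in seq_len(ncol(ranks) - 1L)) {
    ok <- ok & !(uncl[, j] & !uncl[, j + 1L])
  }
  ok
}

# Pad a list of rank vectors (length <= 7) with the unclassified sentinel.
.padRanks <- function(x) {
  c(x, rep(.UNCL, 7L - length(x)))
}

# Deterministic per-id seed derivation so that classification of a query does
# not depend on the order queries are processed in.  Polynomial string hash
# folded into [1, 2^31 - 2]; exact in double arithmetic (values < 2^53).
.deriveSeed <- function(seed, id) {
  h <- 0
  for (code in utf8ToInt(id)) h <- (h * 31 + code) %% 2147483647
  as.integer((h + seed) %% 2147483646) + 1L
}

# Collapse a taxonomy matrix row to the semicolon form used in files.
.pathString <- function(row, conf = NULL) {
  if (is.null(conf)) {
    paste0(paste(row, collapse = ";"), ";")
  } else {
    paste0(paste0(row, "(", conf, ")", collapse = ";"), ";")
  }
}
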