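# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the alignment oracle builds explicit aligned
# strings and counts columns; the classifier oracle enumerates leaves and
# multiplies probabilities in linear (non-log) space.

BASES <- c("A", "C", "G", "T")

randomSeq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# Construct one explicit pairwise alignment (with mismatches, query-gap and
# subject-gap columns, and unaligned query overhangs) and derive both the
# fmt6-style hit fields and the ground-truth full-length identity
# 100 * matches / (qlen + query-gap columns).
randomAlignmentCase <- function() {
  repeat {
    qlen <- sample(60:300, 1)
    qstart <- sample(1:max(1, qlen %/% 4), 1)
    qend <- sample(min(qlen, qlen - qlen %/% 4 + 1):qlen, 1)
    span <- qend - qstart + 1
    if (span < 20) next
    qseg <- sample(BASES, span, replace = TRUE)
    cols_q <- character(0); cols_s <- character(0)
    i <- 1
    while (i <= span) {
      r <- runif(1)
      if (r < 0.04) {            # query-gap column (insertion in subject)
        cols_q <- c(cols_q, "-")
        cols_s <- c(cols_s, sample(BASES, 1))
      } else if (r < 0.08) {     # subject-gap column
        cols_q <- c(cols_q, qseg[i]); cols_s <- c(cols_s, "-"); i <- i + 1
      } else if (r < 0.2) {      # mismatch column
        cols_q <- c(cols_q, qseg[i])
        cols_s <- c(cols_s, sample(setdiff(BASES, qseg[i]), 1)); i <- i + 1
      } else {                   # match column
        cols_q <- c(cols_q, qseg[i]); cols_s <- c(cols_s, qseg[i]); i <- i + 1
      }
    }
    matches <- sum(cols_q != "-" & cols_q == cols_s)
    len <- length(cols_q)
    if (matches == 0) next
    qgap <- sum(cols_q == "-")
    hit <- data.frame(
      qseqid = "q", sseqid = "s",
      pident = 100 * matches / len, length = len, qlen = qlen,
      qstart = qstart, qend = qend,
      mismatch = sum(cols_q != "-" & cols_s != "-" & cols_q != cols_s))
    return(list(hit = hit,
                oracle_fl = 100 * matches / (qlen + qgap),
                spans_query = span == qlen))
  }
}

# A random internally consistent fmt6 hit row (no explicit alignment).
randomHitRow <- function(q = "q", s = "s") {
  qlen <- sample(60:300, 1)
  qstart <- sample(seq_len(qlen), 1)
  qend <- if (qstart == qlen) qlen else qstart + sample.int(qlen - qstart + 1, 1) - 1L
  span <- qend - qstart + 1
  len <- span + sample(0:10, 1)          # extra columns = query gaps
  matches <- sample(1:len, 1)
  data.frame(qseqid = q, sseqid = s, pident = 100 * matches / len,
             length = len, qlen = qlen, qstart = qstart, qend = qend,
             mismatch = len - matches)
}

# --- linear-space naive Bayes oracle ------------------------------------

oracleWords <- function(seq, k = 8) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  words <- substring(seq, 1:(n - k + 1), k:n)
  unique(words[grepl("^[ACGT]+$", words)])
}

# refs: named character vector; leaf_of: leaf key per reference.
# Returns the winning leaf key for `query` (lexicographic tie-break),
# multiplying probabilities without logs.
oracleClassify <- function(refs, leaf_of, query, k = 8) {
  N <- length(refs)
  W <- oracleWords(query, k)
  ref_words <- lapply(refs, oracleWords, k = k)
  prior <- vapply(W, function(w) {
    (sum(vapply(ref_words, function(ws) w %in% ws, TRUE)) + 0.5) / (N + 1)
  }, numeric(1))
  leaves <- sort(unique(leaf_of))
  scores <- vapply(leaves, function(g) {
    members <- ref_words[leaf_of == g]
    M <- length(members)
    prod(vapply(seq_along(W), function(wi) {
      m <- sum(vapply(members, function(ws) W[wi] %in% ws, TRUE))
      (m + prior[wi]) / (M + 1)
    }, numeric(1)))
  }, numeric(1))
  leaves[which.max(scores)]
}

# Small helper to build a ReferenceDB from character sequences + path strings.
makeDb <- function(seqs, paths, label = "ecosystem") {
  tax <- do.call(rbind, strsplit(paths, ";", fixed = TRUE))
  rownames(tax) <- names(seqs)
  ReferenceDB(Biostrings::DNAStringSet(seqs), tax, label = label)
}

# Percent identity of two sequences via an independent alignment oracle.
alignmentIdentity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "global")
  100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}
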