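# Seeded generators emulating the curated-subset / comprehensive database
# setup: hierarchically mutated reference sequences, mutated amplicon reads
# with a per-read truth table, fmt6-style hit emulation via local alignment,
# and the gold-standard category scoring of a validation run.

.BASES <- c("A", "C", "G", "T")

# Substitute each position independently with probability `rate`, always to
# a different base.
.mutate <- function(base_vec, rate) {
  if (rate <= 0) return(base_vec)
  hit <- which(runif(length(base_vec)) < rate)
  if (length(hit)) {
    for (i in hit) {
      base_vec[i] <- sample(setdiff(.BASES, base_vec[i]), 1L)
    }
  }
  base_vec
}

#' Generate a paired ecosystem-specific / comprehensive reference set
#'
#' Builds a hierarchy of reference sequences by mutating a shared root along
#' rank-level branches, calibrated so the expected pairwise divergence
#' between two leaves equals the ladder value at their deepest shared rank
#' (0.25 when they share only the kingdom, down the ladder as they share
#' finer ranks).  Branch substitution rates are
#' `(ladder[r-1] - ladder[r]) / 2` per level plus a terminal branch of
#' `ladder[7] / 2` below the species node, so each pair accumulates the full
#' ladder value.
#'
#' The comprehensive database contains every leaf, named to genus with
#' species left unclassified (mirroring a broad reference whose finest
#' ranks are unresolved).  The ecosystem-specific database contains the
#' requested fraction of leaves -- taken phylum-block-wise so that entire
#' phyla remain unrepresented, as with a habitat-specific curated set --
#' named to all 7 ranks with distinct lineage/clade/tribe-style names at the
#' three finest ranks.
#'
#' @param nPhyla Number of phyla, default 4.
#' @param leavesPerPhylum Leaves (distinct finest taxa) per phylum, default 6.
#' @param seqLen Reference length in nt, default 500.
#' @param divergenceLadder Strictly decreasing 7-vector of expected pairwise
#'   divergences by deepest shared rank; default
#'   `c(0.25, 0.18, 0.12, 0.08, 0.05, 0.03, 0.01)`.
#' @param ecoFraction Fraction of leaves included in the ecosystem-specific
#'   database, in (0, 1]; default 0.5.
#' @param seed Integer seed; identical seeds give byte-identical databases.
#' @return List with elements `eco` and `comp` ([ReferenceDB-class]) and
#'   `lineage`, a data.frame mapping each leaf id to its phylum and its
#'   eco-membership flag.
#' @export
generateReferenceSets <- function(nPhyla = 4L, leavesPerPhylum = 6L,
                                  seqLen = 500L,
                                  divergenceLadder = c(0.25, 0.18, 0.12,
                                                       0.08, 0.05, 0.03,
                                                       0.01),
                                  ecoFraction = 0.5, seed = 1L) {
  stopifnot(nPhyla >= 1L, leavesPerPhylum >= 1L, seqLen >= 8L)
  if (length(divergenceLadder) != 7L || any(diff(divergenceLadder) >= 0))
    stop("divergenceLadder must be 7 strictly decreasing fractions")
  if (any(divergenceLadder <= 0) || any(divergenceLadder >= 1))
    stop("divergenceLadder values must lie in (0, 1)")
  if (ecoFraction <= 0 || ecoFraction > 1)
    stop("ecoFraction must lie in (0, 1]")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(as.integer(seed))

  # branch rates: levels 2..7 then the terminal branch below species
  branch <- c(diff(-divergenceLadder) / 2, divergenceLadder[7L] / 2)
  root <- sample(.BASES, seqLen, replace = TRUE)

  leaf_seq <- list(); leaf_phylum <- integer(); leaf_tag <- character()
  # recursive bisection: each split at rank r applies branch[r-1] mutations
  descend <- function(seq_vec, rank, slots, tag) {
    if (rank == 8L) {
      leaf_seq[[length(leaf_seq) + 1L]] <<- .mutate(seq_vec, branch[7L])
      leaf_tag[length(leaf_tag) + 1L] <<- tag
      return(invisible(NULL))
    }
    groups <- if (slots > 1L) {
      first <- ceiling(slots / 2)
      c(first, slots - first)
    } else 1L
    for (g in seq_along(groups)) {
      child <- .mutate(seq_vec, branch[rank - 1L])
      descend(child, rank + 1L, groups[g], paste0(tag, ".", g))
    }
  }
  for (p in seq_len(nPhyla)) {
    phylum_seq <- .mutate(root, branch[1L])
    n0 <- length(leaf_seq)
    descend(phylum_seq, 3L, leavesPerPhylum, as.character(p))
    leaf_phylum <- c(leaf_phylum, rep(p, length(leaf_seq) - n0))
  }
  nLeaf <- length(leaf_seq)
  ids <- sprintf("ref_%02d", seq_len(nLeaf))
  seqs <- Biostrings::DNAStringSet(vapply(leaf_seq, paste, "", collapse = ""))
  names(seqs) <- ids

  # taxonomy from the recursion tags: tag "p.g1.g2.g3.g4.g5" gives the node
  # path phylum..species; names shared between databases at coarse ranks
  tag_parts <- strsplit(leaf_tag, ".", fixed = TRUE)
  node <- function(parts, depth) paste(parts[seq_len(depth)], collapse = ".")
  comp_tax <- t(vapply(tag_parts, function(tp) {
    c("Bacteria",
      paste0("Phylum_", node(tp, 1L)),
      paste0("Class_", node(tp, 2L)),
      paste0("Order_", node(tp, 3L)),
      paste0("Family_", node(tp, 4L)),
      paste0("Genus_", node(tp, 5L)),
      .UNCL)
  }, character(7L)))
  eco_tax <- comp_tax
  eco_tax[, 5L] <- paste0("lin-", vapply(tag_parts, node, "", 4L))
  eco_tax[, 6L] <- paste0("clade-", vapply(tag_parts, node, "", 5L))
  eco_tax[, 7L] <- paste0("tribe-", vapply(tag_parts, node, "", 6L))
  rownames(comp_tax) <- rownames(eco_tax) <- ids

  nEco <- max(1L, round(ecoFraction * nLeaf))
  eco_sel <- seq_len(nEco)  # leaves are in phylum-block order
  lineage <- data.frame(leaf_id = ids, phylum = leaf_phylum,
                        in_eco = seq_len(nLeaf) %in% eco_sel)
  list(
    eco = ReferenceDB(seqs[eco_sel], eco_tax[eco_sel, , drop = FALSE],
                      label = "ecosystem"),
    comp = ReferenceDB(seqs, comp_tax, label = "comprehensive"),
    lineage = lineage
  )
}

#' Generate mutated amplicon reads from a reference database
#'
#' Each read is a uniformly placed substring of a uniformly sampled
#' reference with independent substitutions at the stated rate (no indels).
#' A truth table records each read's gold taxonomy (the source database's
#' naming), source reference, applied divergence, and whether the source
#' lineage is represented in the ecosystem-specific database.
#'
#' @param db [ReferenceDB-class] to sample from.
#' @param nReads Number of reads.
#' @param readLen Read length in nt; must not exceed the reference length.
#' @param divergence Per-site substitution probability in \[0, 1).
#' @param indelRate Per-site indel probability (half insertions, half
#'   deletions), default 0: substitution-only reads keep read length and
#'   mismatch counts exactly interpretable.
#' @param seed Integer seed.
#' @param ecoIds Reference ids represented in the ecosystem-specific
#'   database, used to set the truth flag; defaults to all ids of `db` when
#'   its label is `"ecosystem"`, otherwise none.
#' @param prefix Read id prefix, default `"read"`.
#' @return List with `reads` (named `DNAStringSet`), `truth` (data.frame:
#'   `read_id`, `source_ref`, `in_eco`, `divergence`, `start` -- the 1-based
#'   substring offset -- and the 7 gold rank columns) and `abundance`
#'   (single-sample table, one read count each).
#' @export
generateReads <- function(db, nReads, readLen = 250L, divergence = 0.01,
                          indelRate = 0, seed = 1L, ecoIds = NULL,
                          prefix = "read") {
  stopifnot(is(db, "ReferenceDB"), nReads >= 0L,
            divergence >= 0, divergence < 1,
            indelRate >= 0, indelRate < 1)
  seqs <- refSequences(db)
  if (any(Biostrings::width(seqs) < readLen))
    stop("readLen exceeds the length of at least one reference")
  if (is.null(ecoIds))
    ecoIds <- if (dbLabel(db) == "ecosystem") names(seqs) else character()
  if (nReads == 0L) {
    truth <- data.frame(read_id = character(), source_ref = character(),
                        in_eco = logical(), divergence = numeric())
    truth[.RANKS] <- rep(list(character()), 7L)
    return(list(reads = Biostrings::DNAStringSet(), truth = truth,
                abundance = data.frame(otu_id = character(), S1 = numeric())))
  }
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(as.integer(seed))
  ref_i <- sample.int(length(seqs), nReads, replace = TRUE)
  out <- character(nReads)
  starts <- integer(nReads)
  for (i in seq_len(nReads)) {
    full <- strsplit(as.character(seqs[[ref_i[i]]]), "")[[1]]
    start <- sample.int(length(full) - readLen + 1L, 1L)
    starts[i] <- start
    rd <- .mutate(full[start:(start + readLen - 1L)], divergence)
    if (indelRate > 0) {
      res <- character(0)
      for (b in rd) {
        if (runif(1) < indelRate / 2) next                         # deletion
        res <- c(res, b)
        if (runif(1) < indelRate / 2) res <- c(res, sample(.BASES, 1L))
      }
      rd <- if (length(res)) res else sample(.BASES, 1L)
    }
    out[i] <- paste(rd, collapse = "")
  }
  read_ids <- sprintf("%s_%04d", prefix, seq_len(nReads))
  reads <- Biostrings::DNAStringSet(out)
  names(reads) <- read_ids
  gold <- taxonomy(db)[ref_i, , drop = FALSE]
  truth <- data.frame(read_id = read_ids,
                      source_ref = names(seqs)[ref_i],
                      in_eco = names(seqs)[ref_i] %in% ecoIds,
                      divergence = divergence, start = starts,
                      row.names = NULL)
  truth <- cbind(truth, as.data.frame(gold, row.names = NULL))
  abundance <- data.frame(otu_id = read_ids, S1 = rep(1, nReads))
  list(reads = reads, truth = truth, abundance = abundance)
}

#' Emulate BLAST tabular hits with local alignments
#'
#' Locally aligns every query against every reference and emits, per query,
#' the `topN` highest-scoring alignments as a hit data.frame in outfmt-6
#' layout (ordered by score, as blastn orders hits).  This is test
#' scaffolding so the full workflow can run without an external aligner,
#' not a BLAST reimplementation: scoring is +1/-2 with affine gaps, which
#' keeps alignments of substitution-only reads ungapped.
#'
#' @param queries Named [Biostrings::DNAStringSet].
#' @param db [ReferenceDB-class] of subject sequences.
#' @param topN Hits kept per query, default 5.
#' @param minScore Alignments scoring below this are dropped (default 20,
#'   roughly blastn's reporting floor for short words).
#' @return Hit data.frame in [blastColumns()] order plus `hit_rank`,
#'   suitable for [bestHits()], [runTaxAss()] and [writeBlastTable()].
#' @export
localAlignmentHits <- function(queries, db, topN = 5L, minScore = 20) {
  stopifnot(is(db, "ReferenceDB"))
  queries <- Biostrings::DNAStringSet(queries)
  refs <- refSequences(db)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  rows <- vector("list", length(refs))
  for (s in seq_along(refs)) {
    aln <- Biostrings::pairwiseAlignment(queries, refs[[s]], type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    alen <- Biostrings::nchar(aln)
    nmat <- Biostrings::nmatch(aln)
    rows[[s]] <- data.frame(
      qseqid = names(queries),
      pident = 100 * nmat / alen,
      length = alen,
      qlen = Biostrings::width(queries),
      qstart = IRanges::start(Biostrings::pattern(aln)),
      qend = IRanges::end(Biostrings::pattern(aln)),
      sseqid = names(refs)[s],
      mismatch = Biostrings::nmismatch(aln),
      score = Biostrings::score(aln), row.names = NULL)
  }
  all <- do.call(rbind, rows)
  all <- all[all$score >= minScore, , drop = FALSE]
  # blastn emits hits per query ordered by score; stable tie-break = subject
  # order, preserved by a stable sort on (query input order, -score)
  all <- all[order(match(all$qseqid, names(queries)), -all$score), ,
             drop = FALSE]
  keep <- stats::ave(seq_len(nrow(all)), all$qseqid,
                     FUN = seq_along) <= topN
  all <- all[keep, , drop = FALSE]
  all$score <- NULL
  all$hit_rank <- stats::ave(seq_len(nrow(all)), all$qseqid, FUN = seq_along)
  rownames(all) <- NULL
  all
}

#' Score assignments against a synthetic gold standard
#'
#' Assigns each evaluated read exactly one category at the evaluation rank,
#' testing rules in a fixed precedence order:
#' \enumerate{
#'   \item `incorrect_inclusion` -- classified by the ecosystem-specific
#'     database although the source lineage is not represented there;
#'   \item `lost_ecosystem_specific` -- the source lineage is represented,
#'     but the read was routed to the comprehensive database and its name at
#'     the rank is unclassified or not the gold (ecosystem-style) name;
#'   \item `correct` -- named and equal to the gold name (reads unclassified
#'     at a rank where the gold is also unclassified count here too);
#'   \item `underclassified` -- unclassified where the gold is named (not an
#'     error: expected for short reads);
#'   \item `overclassified` -- named where the gold is unclassified;
#'   \item `misclassified` -- named, but a different name than the gold.
#' }
#'
#' @param assigned A [TaxAssignmentSet-class] (post-thresholding).
#' @param truth Truth data.frame from [generateReads()] (or with columns
#'   `read_id`, `in_eco` and the 7 rank columns).
#' @param rank Evaluation rank (name, alias or index).
#' @return List of class `EvalCounts`: `counts` (named integer vector over
#'   the six categories, summing to `n`), `n`, `rank`, and `categories`
#'   (per-read factor, named by read id).
#' @export
evaluateAgainstGold <- function(assigned, truth, rank) {
  stopifnot(is(assigned, "TaxAssignmentSet"))
  j <- .matchRank(rank)
  ids <- otuIds(assigned)
  ti <- match(ids, truth$read_id)
  if (anyNA(ti))
    stop("no truth row for read(s): ",
         paste(head(ids[is.na(ti)], 5L), collapse = ", "))
  gold <- truth[[.RANKS[j]]][ti]
  flag <- truth$in_eco[ti]
  name <- taxonomy(assigned)[, j]
  src <- sourceDb(assigned)
  cats <- c("correct", "lost_ecosystem_specific", "overclassified",
            "misclassified", "incorrect_inclusion", "underclassified")
  cat_of <- character(length(ids))
  a_named <- name != .UNCL
  g_named <- gold != .UNCL
  for (i in seq_along(ids)) {
    cat_of[i] <-
      if (!is.na(src[i]) && src[i] == "ecosystem" && !flag[i])
        "incorrect_inclusion"
      else if (flag[i] && !is.na(src[i]) && src[i] == "comprehensive" &&
               (!a_named[i] || name[i] != gold[i]))
        "lost_ecosystem_specific"
      else if ((a_named[i] && name[i] == gold[i]) ||
               (!a_named[i] && !g_named[i]))
        "correct"
      else if (!a_named[i] && g_named[i])
        "underclassified"
      else if (a_named[i] && !g_named[i])
        "overclassified"
      else
        "misclassified"
  }
  counts <- table(factor(cat_of, levels = cats))
  structure(list(counts = setNames(as.integer(counts), cats),
                 n = length(ids), rank = .RANKS[j],
                 categories = setNames(factor(cat_of, cats), ids)),
            class = "EvalCounts")
}

#' @export
print.EvalCounts <- function(x, ...) {
  cat("Gold-standard evaluation at rank '", x$rank, "' over ", x$n,
      " reads\n", sep = "")
  pct <- 100 * x$counts / max(x$n, 1L)
  for (nm in names(x$counts))
    cat(sprintf("  %-24s %6d  (%.1f%%)\n", nm, x$counts[[nm]], pct[[nm]]))
  invisible(x)
}
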