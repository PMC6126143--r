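# Generators, primer trimming and the gold-standard scoring scheme.

test_that("reference generation is deterministic and structured", {
  d1 <- generateReferenceSets(seed = 3)
  d2 <- generateReferenceSets(seed = 3)
  expect_identical(as.character(refSequences(d1$comp)),
                   as.character(refSequences(d2$comp)))
  expect_identical(taxonomy(d1$eco), taxonomy(d2$eco))

  expect_equal(length(refSequences(d1$comp)), 24)  # 4 phyla x 6 leaves
  expect_equal(length(refSequences(d1$eco)), 12)   # ecoFraction 0.5
  # comp names to genus only; eco resolves all 7 ranks
  expect_true(all(taxonomy(d1$comp)[, 7] == unclassifiedLabel()))
  expect_true(all(taxonomy(d1$eco) != unclassifiedLabel()))
  # coarse ranks agree between the databases for shared leaves
  shared <- rownames(taxonomy(d1$eco))
  expect_identical(taxonomy(d1$eco)[shared, 1:4],
                   taxonomy(d1$comp)[shared, 1:4])

  all_in <- generateReferenceSets(ecoFraction = 1, seed = 3)
  expect_setequal(names(refSequences(all_in$eco)),
                  names(refSequences(all_in$comp)))

  expect_error(generateReferenceSets(divergenceLadder = rep(0.1, 7)),
               "strictly decreasing")
})

test_that("pairwise leaf divergence tracks the ladder", {
  d <- generateReferenceSets(seed = 11)
  seqs <- refSequences(d$comp)
  tax <- taxonomy(d$comp)
  # two leaves sharing only the phylum: expected identity ~ 100 * (1 - 0.18)
  same_phylum <- which(tax[, 2] == tax[1, 2] & tax[, 3] != tax[1, 3])
  id_phy <- alignmentIdentity(as.character(seqs[[1]]),
                              as.character(seqs[[same_phylum[1]]]))
  expect_gt(id_phy, 77); expect_lt(id_phy, 87)
  # two leaves in different phyla: expected identity ~ 100 * (1 - 0.25)
  other_phylum <- which(tax[, 2] != tax[1, 2])
  id_diff <- alignmentIdentity(as.character(seqs[[1]]),
                               as.character(seqs[[other_phylum[1]]]))
  expect_gt(id_diff, 70); expect_lt(id_diff, 82)
  # sharing a genus: expected identity ~ 100 * (1 - 0.03)
  same_genus <- which(tax[, 6] == tax[1, 6])
  same_genus <- setdiff(same_genus, 1)
  if (length(same_genus)) {
    id_gen <- alignmentIdentity(as.character(seqs[[1]]),
                                as.character(seqs[[same_genus[1]]]))
    expect_gt(id_gen, 92)
  }
})

test_that("read generation honours divergence and bookkeeping", {
  d <- generateReferenceSets(seed = 2)
  g0 <- generateReads(d$eco, 20, 250, 0, seed = 4)
  # divergence 0: every read is an exact substring of its source reference
  for (i in seq_len(20)) {
    ref <- as.character(refSequences(d$eco)[[g0$truth$source_ref[i]]])
    expect_identical(as.character(g0$reads[[i]]),
                     substring(ref, g0$truth$start[i],
                               g0$truth$start[i] + 249))
  }
  expect_true(all(g0$truth$in_eco))
  expect_equal(sum(g0$abundance$S1), 20)

  # divergence 0.02 over 1000 reads: mean substitutions ~ 5 +/- 0.5
  g2 <- generateReads(d$comp, 1000, 250, 0.02, seed = 9)
  mism <- vapply(seq_len(1000), function(i) {
    ref <- as.character(refSequences(d$comp)[[g2$truth$source_ref[i]]])
    win <- substring(ref, g2$truth$start[i], g2$truth$start[i] + 249)
    sum(strsplit(win, "")[[1]] != strsplit(as.character(g2$reads[[i]]),
                                           "")[[1]])
  }, numeric(1))
  expect_gt(mean(mism), 4.5); expect_lt(mean(mism), 5.5)

  g_none <- generateReads(d$eco, 0)
  expect_length(g_none$reads, 0)
  expect_equal(nrow(g_none$truth), 0)
  expect_error(generateReads(d$eco, 5, readLen = 501), "readLen exceeds")

  # optional indel model perturbs read lengths around readLen
  gi <- generateReads(d$eco, 50, 250, 0.01, indelRate = 0.02, seed = 3)
  w <- Biostrings::width(gi$reads)
  expect_true(any(w != 250))
  expect_true(all(abs(w - 250) < 30))
})

test_that("local hit emulation yields valid, well-ordered fmt6 records", {
  d <- generateReferenceSets(seed = 6)
  g <- generateReads(d$eco, 15, 250, 0.01, seed = 6)
  hits <- localAlignmentHits(g$reads, d$eco)
  expect_true(all(hits$qend <= hits$qlen))
  expect_true(all(hits$qstart <= hits$qend))
  expect_true(all(hits$hit_rank <= 5))
  # an exact substring read: its best hit is a perfect full-length match
  ex <- generateReads(d$eco, 3, 250, 0, seed = 7)
  bh <- bestHits(localAlignmentHits(ex$reads, d$eco))
  expect_equal(bh$fl_pident, rep(100, 3))
  expect_identical(bh$sseqid,
                   ex$truth$source_ref[match(bh$qseqid, ex$truth$read_id)])
})

test_that("primer trimming recovers the exact inter-primer insert", {
  set.seed(14)
  # concrete degenerate expansions of each primer pair
  concrete <- list(
    "V4" = c(fwd = "GTGCCAGCAGCCGCGGTAA", rev = "GGACTACTAGGGTATCTAAT"),
    "V4-V5" = c(fwd = "GTGTCAGCCGCCGCGGTAA", rev = "CCGTCAATTCATTTGAGTTT"),
    "V3-V4" = c(fwd = "CCTACGGGAGGCTGCAG", rev = "GACTACAGGGGTATCTAATCC"))
  for (region in names(concrete)) {
    insert <- randomSeq(150)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(concrete[[region]]["rev"])))
    full <- paste0(randomSeq(40), concrete[[region]]["fwd"], insert, rc,
                   randomSeq(40))
    out <- simulateTags(Biostrings::DNAStringSet(c(s1 = full)),
                        primerPair(region))
    expect_identical(as.character(out$trimmed[["s1"]]), insert)
    expect_equal(nrow(out$failures), 0)
  }
})

test_that("primer matching is IUPAC-degenerate and failures are reported", {
  # M in the forward primer matches A in the target
  target <- paste0("TT", "GTGCCAGCAGCCGCGGTAA", randomSeq(60),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString("GGACTACAAGGGTTTCTAAT"))), "TT")
  out <- simulateTags(Biostrings::DNAStringSet(c(x = target)),
                      primerPair("V4"))
  expect_equal(length(out$trimmed), 1)

  set.seed(15)
  none <- simulateTags(Biostrings::DNAStringSet(c(y = randomSeq(300))),
                       primerPair("V4"))
  expect_length(none$trimmed, 0)
  expect_equal(nrow(none$failures), 1)
  expect_identical(none$failures$reason, "no_forward_site")

  # multiple forward sites: the first is used, with a message
  fwd <- "GTGCCAGCAGCCGCGGTAA"
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("GGACTACTAGGGTATCTAAT")))
  dbl <- paste0(fwd, "AAAA", fwd, "CCCCCC", rc)
  expect_message(
    out2 <- simulateTags(Biostrings::DNAStringSet(c(z = dbl)),
                         primerPair("V4")),
    "multiple forward")
  expect_identical(as.character(out2$trimmed[["z"]]),
                   paste0("AAAA", fwd, "CCCCCC"))
})

test_that("gold-standard categories follow the precedence rules", {
  u <- unclassifiedLabel()
  truth <- data.frame(
    read_id = paste0("r", 1:6),
    source_ref = "ref", in_eco = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    divergence = 0, start = 1)
  truth[taxRanks()] <- NA_character_
  truth$kingdom <- "B"; truth$phylum <- "P"; truth$class <- "C"
  truth$order <- "O"; truth$family <- "lin"; truth$genus <- "clade"
  truth$species <- c("tribe", "tribe", u, "tribe", "tribe", "tribe")

  assigned <- TaxAssignmentSet(
    paste0("r", 1:6),
    rbind(c("B", "P", "C", "O", "lin", "clade", "tribe"),    # correct
          c("B", "P", "C", "O", "Fam", "Gen", u),            # lost (comp name)
          c("B", "P", "C", "O", "lin", "clade", "tribeX"),   # overclassified
          c("B", "P", "C", "O", "lin", "clade", "tribeY"),   # misclassified
          c("B", "P", "C", "O", "lin", "clade", "tribe"),    # incorrect incl.
          c("B", "P", "C", "O", "lin", "clade", u)),         # underclassified
    source = c("ecosystem", "comprehensive", "ecosystem", "ecosystem",
               "ecosystem", "ecosystem"))
  ev <- evaluateAgainstGold(assigned, truth, "species")
  expect_equal(unname(ev$counts["correct"]), 1)
  expect_equal(unname(ev$counts["lost_ecosystem_specific"]), 1)
  expect_equal(unname(ev$counts["overclassified"]), 1)
  expect_equal(unname(ev$counts["misclassified"]), 1)
  expect_equal(unname(ev$counts["incorrect_inclusion"]), 1)
  expect_equal(unname(ev$counts["underclassified"]), 1)
  expect_equal(sum(ev$counts), ev$n)

  expect_error(evaluateAgainstGold(assigned, truth[-1, ], "species"),
               "no truth row")
})

test_that("trimming leaves coarse-rank classifications intact", {
  dbs <- generateReferenceSets(seed = 9)
  idx <- buildKmerIndex(dbs$comp)
  refs <- refSequences(dbs$comp)
  fwd <- "GTGCCAGCAGCCGCGGTAA"
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("GGACTACTAGGGTATCTAAT")))
  # full-length constructs: leading context, primer, the V4-like insert,
  # reverse site, trailing context
  full <- setNames(vapply(seq_along(refs), function(i) {
    s <- as.character(refs[[i]])
    paste0(substring(s, 1, 100), fwd, substring(s, 101, 350), rc,
           substring(s, 351, 500))
  }, ""), paste0("fl_", names(refs)))
  out <- simulateTags(Biostrings::DNAStringSet(full), primerPair("V4"))
  expect_equal(length(out$trimmed), length(refs))
  fullRes <- applyConfidenceThreshold(
    classifySequences(Biostrings::DNAStringSet(full), idx, seed = 4), 80)
  trimRes <- applyConfidenceThreshold(
    classifySequences(out$trimmed, idx, seed = 4), 80)
  agree <- mean(taxonomy(fullRes)[, 3] == taxonomy(trimRes)[, 3])
  expect_gte(agree, 0.95)
})
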