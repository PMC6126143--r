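# End-to-end run and the diagnostic metrics.

# A small two-database world shared by several tests: the eco database
# resolves all 7 ranks, the comp database names the same organisms only to
# genus, plus one comp-only phylum.
makeToyWorld <- function(seed = 123) {
  set.seed(seed)
  a <- randomSeq(400); b <- randomSeq(400); z <- randomSeq(400)
  eco <- makeDb(c(A = a, B = b),
                c("Bacteria;P1;C1;O1;linA;cladeA;tribeA",
                  "Bacteria;P1;C2;O2;linB;cladeB;tribeB"),
                label = "ecosystem")
  comp <- makeDb(c(A = a, B = b, Z = z),
                 c(paste0("Bacteria;P1;C1;O1;FamA;GenA;", unclassifiedLabel()),
                   paste0("Bacteria;P1;C2;O2;FamB;GenB;", unclassifiedLabel()),
                   paste0("Bacteria;PZ;CZ;OZ;FamZ;GenZ;", unclassifiedLabel())),
                 label = "comprehensive")
  list(eco = eco, comp = comp, seqs = c(A = a, B = b, Z = z))
}

test_that("runTaxAss recombines split groups in input order", {
  world <- makeToyWorld()
  # A: exact match to an eco reference; B: degraded (fl 90); C: no hit
  queries <- Biostrings::DNAStringSet(c(
    qA = substring(world$seqs[["A"]], 1, 250),
    qB = substring(world$seqs[["B"]], 1, 250),
    qC = world$seqs[["Z"]]))
  hits <- data.frame(
    qseqid = c("qA", "qB"), sseqid = c("A", "B"),
    pident = c(100, 100), length = c(250, 225), qlen = c(250, 250),
    qstart = c(1, 26), qend = c(250, 250))
  res <- suppressMessages(
    runTaxAss(queries, world$eco, world$comp, hits, cutoff = 98, seed = 1))
  expect_identical(otuIds(res), c("qA", "qB", "qC"))
  expect_identical(unname(sourceDb(res)),
                   c("ecosystem", "comprehensive", "comprehensive"))
  # A gets its eco reference's full path; B and C comp paths
  expect_identical(unname(taxonomy(res)["qA", ]),
                   c("Bacteria", "P1", "C1", "O1", "linA", "cladeA", "tribeA"))
  expect_identical(unname(taxonomy(res)["qB", 6]), "GenB")
  expect_identical(unname(taxonomy(res)["qC", 2]), "PZ")

  split <- attr(res, "split")
  expect_s4_class(split, "SplitResult")
  expect_setequal(c(ecoIds(split), compIds(split)), otuIds(res))

  empty <- runTaxAss(Biostrings::DNAStringSet(), world$eco, world$comp,
                     hits[0, ], cutoff = 98)
  expect_length(empty, 0)
})

test_that("runTaxAss matches a single-cutoff sweep column", {
  world <- makeToyWorld()
  set.seed(6)
  queries <- Biostrings::DNAStringSet(c(
    qA = substring(world$seqs[["A"]], 51, 300),
    qB = substring(world$seqs[["B"]], 51, 300),
    qZ = substring(world$seqs[["Z"]], 51, 300)))
  hits <- localAlignmentHits(queries, world$eco)
  res <- suppressMessages(
    runTaxAss(queries, world$eco, world$comp, hits, cutoff = 98, seed = 3))
  sw <- suppressMessages(
    cutoffSweep(queries, world$eco, world$comp, hits, cutoffs = 98, seed = 3))
  for (j in 1:7)
    expect_equal(unname(sw[j, 1]), percentClassified(res, NULL, j))
})

test_that("percentClassified implements the read-weighted formula", {
  a <- TaxAssignmentSet(
    c("A", "B", "C"),
    rbind(c("k", "p", "c", "o", "f", "g", "sA"),
          c("k", "p", "c", "o", "f", "g", "sB"),
          c("k", "p", "c", "o", "f", "g", unclassifiedLabel())))
  ab <- data.frame(otu_id = c("A", "B", "C"), s1 = c(10, 20, 70))
  expect_equal(percentClassified(a, ab, "species"), 30)   # 30/100 reads
  expect_equal(percentClassified(a, ab, "genus"), 100)
  expect_equal(percentClassified(a, NULL, "species"), 100 * 2 / 3)

  none <- TaxAssignmentSet("A", rep(unclassifiedLabel(), 7))
  expect_equal(percentClassified(none, data.frame(otu_id = "A", s1 = 5),
                                 "species"), 0)
  expect_error(percentClassified(a, data.frame(otu_id = "A", s1 = 5),
                                 "genus"), "absent from abundance")
  zero <- data.frame(otu_id = c("A", "B", "C"), s1 = c(0, 0, 0))
  expect_error(percentClassified(a, zero, "genus"), "zero total")
})

test_that("taxonomicRichness counts distinct truncated named paths", {
  u <- unclassifiedLabel()
  a <- TaxAssignmentSet(
    c("x", "y", "z"),
    rbind(c("k", "p1", "c1", u, u, u, u),
          c("k", "p1", "c2", u, u, u, u),
          c("k", "p2", "c1x", u, u, u, u)))
  expect_equal(taxonomicRichness(a, "phylum"), 2)
  expect_equal(taxonomicRichness(a, "class"), 3)

  # duplicates counted once; partially unclassified distinct per prefix;
  # fully unclassified excluded
  b <- TaxAssignmentSet(
    c("x", "y", "z", "w"),
    rbind(c("k", "p1", "c1", u, u, u, u),
          c("k", "p1", "c1", u, u, u, u),
          c("k", "p1", u, u, u, u, u),
          rep(u, 7)))
  expect_equal(taxonomicRichness(b, "class"), 2)
  empty <- TaxAssignmentSet(character(), matrix(character(), 0, 7))
  expect_equal(taxonomicRichness(empty, "class"), 0)
})

test_that("cutoff sweep: eco-resolvable species vanish at an excluding cutoff", {
  world <- makeToyWorld()
  set.seed(8)
  mkread <- function(s) substring(s, 101, 350)
  queries <- Biostrings::DNAStringSet(c(
    q1 = mkread(world$seqs[["A"]]), q2 = mkread(world$seqs[["B"]]),
    q3 = world$seqs[["Z"]]))
  hits <- localAlignmentHits(queries, world$eco)
  sw <- suppressMessages(cutoffSweep(queries, world$eco, world$comp, hits,
                                     cutoffs = c(98, 100.1), seed = 2))
  # only the eco database names species, so excluding every OTU from the eco
  # group wipes out species-level classification
  expect_gt(sw["species", "98"], sw["species", "100.1"])
  expect_equal(unname(sw["species", "100.1"]), 0)
  # within any cutoff, percent classified never increases towards fine ranks
  for (j in seq_len(ncol(sw)))
    expect_true(all(diff(sw[, j]) <= 1e-9))
  # plot-ready long form mirrors the matrix
  long <- attr(sw, "long")
  expect_equal(nrow(long), 14)
  expect_equal(long$pct_reads_classified[long$level == "species" &
                                           long$cutoff == 98],
               unname(sw["species", "98"]))
})

test_that("coarse conflicts are counted only among comparable eco OTUs", {
  u <- unclassifiedLabel()
  taxass <- TaxAssignmentSet(
    c("a", "b", "c", "d"),
    rbind(c("k", "Actinobacteria", "c1", u, u, u, u),
          c("k", "Actinobacteria", "c1", u, u, u, u),
          c("k", "Bacteroidetes", "c2", u, u, u, u),
          c("k", "Cyanobacteria", "c3", u, u, u, u)),
    source = c("ecosystem", "ecosystem", "ecosystem", "comprehensive"))
  compOnly <- TaxAssignmentSet(
    c("a", "b", "c", "d"),
    rbind(c("k", "Actinobacteria", "c1", u, u, u, u),
          c("k", "Cyanobacteria", "cX", u, u, u, u),
          c("k", u, u, u, u, u, u),              # not comparable at phylum
          c("k", "Cyanobacteria", "c3", u, u, u, u)))
  rep <- coarseConflictCheck(taxass, compOnly)
  expect_equal(rep$phylum$n_compared, 2)  # a, b (c unclassified; d not eco)
  expect_equal(rep$phylum$n_conflicts, 1)
  expect_equal(rep$phylum$fraction, 0.5)
  expect_identical(rep$phylum$pairs$otu_id, "b")
  expect_identical(rep$phylum$pairs$comp_only, "Cyanobacteria")
  expect_equal(rep$class$n_conflicts, 1)

  ident <- coarseConflictCheck(taxass, taxass)
  expect_equal(ident$phylum$n_conflicts, 0)
  expect_error(coarseConflictCheck(taxass, compOnly[1:2]), "same OTU ids")
})

test_that("reads from lineages absent from the eco database never enter it", {
  dbs <- generateReferenceSets(seed = 5)
  nonEco <- dbs$lineage$leaf_id[!dbs$lineage$in_eco]
  outDb <- ReferenceDB(refSequences(dbs$comp)[nonEco],
                       taxonomy(dbs$comp)[nonEco, , drop = FALSE],
                       label = "comprehensive")
  gen <- generateReads(outDb, 100, 250, 0.03, seed = 5)
  hits <- localAlignmentHits(gen$reads, dbs$eco)
  res <- suppressMessages(
    runTaxAss(gen$reads, dbs$eco, dbs$comp, hits, cutoff = 98, seed = 5))
  expect_equal(sum(sourceDb(res) == "ecosystem"), 0)
})
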