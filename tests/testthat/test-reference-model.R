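test_that("EC code validation accepts the grammar and nothing else", {
  valid <- c("1.1.1.1", "2.8.4.1", "3.4.-.-", "7.12.3.100", "1.-.-.-")
  invalid <- c("1.1.1", "1.1.1.1.1", "a.b.c.d", "3.-.21.-", "0.1.1.1",
               "-.-.-.-2", "1..1.1", "", "1.01.1.1")
  expect_true(all(vapply(valid, isValidEC, logical(1))))
  expect_false(any(vapply(invalid, isValidEC, logical(1))))
})

test_that("wildcard ECs match by specified prefix only", {
  expect_equal(ecMatches(c("3.4.21.1", "3.4.1.1", "3.5.21.1"), "3.4.-.-"),
               c(TRUE, TRUE, FALSE))
  # fully specified reference matches only itself
  expect_equal(ecMatches(c("2.8.4.1", "2.8.4.2"), "2.8.4.1"),
               c(TRUE, FALSE))
})

test_that("ERSC load collapses within-module duplicates, keeps cross-module ones", {
  tab <- erscTable(c("1.1.1.1", "M1", "m one", "X"),
                   c("1.1.1.1", "M1", "m one", "X"),
                   c("2.2.2.2", "M2", "m two", "X"),
                   c("1.1.1.1", "M2", "m two", "X"))
  ersc <- readERSC(writeTempTSV(tab))
  expect_equal(nUniqueECs(ersc), 2)
  expect_equal(nModules(ersc), 2)
  expect_equal(sort(moduleECs(ersc, "M2")), c("1.1.1.1", "2.2.2.2"))
  expect_equal(moduleECs(ersc, "M1"), "1.1.1.1")
})

test_that("ERSC without sequences flags every EC as lacking a sequence", {
  tab <- erscTable(c("1.1.1.1", "M1", "m", "X"), c("2.2.2.2", "M2", "m", "X"))
  ersc <- readERSC(writeTempTSV(tab))
  expect_setequal(ecsWithoutSequence(ersc), c("1.1.1.1", "2.2.2.2"))
  expect_setequal(attr(ersc, "load_report")$ecs_without_sequence,
                  c("1.1.1.1", "2.2.2.2"))
})

test_that("ERSC load errors name malformed ECs and orphan sequences", {
  bad <- erscTable(c("1.1.1.1", "M1", "m", "X"), c("not-an-ec", "M1", "m", "X"))
  expect_error(readERSC(writeTempTSV(bad)), "malformed EC.*2.*not-an-ec")
  tab <- erscTable(c("1.1.1.1", "M1", "m", "X"))
  fa <- tempfile(fileext = ".fasta")
  writeFasta(c(seqA = "ACGTACGT"), fa)
  map <- writeTempTSV(data.frame(seq_id = "seqA", ec = "9.9.9.9"))
  expect_error(readERSC(writeTempTSV(tab), fa, map),
               "absent from module table.*9\\.9\\.9\\.9")
})

test_that("ERSC round-trips through write and re-read", {
  set.seed(11)
  ersc <- simulateERSC(nModules = 8, nUniqueECs = 30)
  mt <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".tsv")
  writeERSC(ersc, mt, mp)
  fa <- tempfile(fileext = ".fasta")
  writeFasta(setNames(
    vapply(ersc@sequences$length_bp,
           function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = ""),
           character(1)),
    ersc@sequences$seq_id), fa)
  back <- readERSC(mt, fa, mp)
  expect_equal(back@modules, ersc@modules)
  expect_equal(back@sequences[, c("seq_id", "ec", "length_bp")],
               ersc@sequences[, c("seq_id", "ec", "length_bp")])
})

test_that("unique-EC count is invariant to row order and duplicated rows", {
  set.seed(3)
  tab <- erscTable(c("1.1.1.1", "M1", "m", "X"), c("2.2.2.2", "M1", "m", "X"),
                   c("3.3.3.3", "M2", "m", "X"))
  for (i in 1:5) {
    shuffled <- tab[sample(c(seq_len(nrow(tab)), sample.int(nrow(tab), 2))), ]
    ersc <- readERSC(writeTempTSV(shuffled))
    expect_equal(nUniqueECs(ersc), 3)
    expect_equal(nModules(ersc), 2)
  }
})

test_that("lca matches hand-derivable cases on the fixed tree", {
  tr <- fixedTree()
  expect_equal(lca(tr, "s1a"), "s1a")              # singleton identity
  expect_equal(lca(tr, c("s1a", "s1b")), "g1")     # sibling species -> genus
  expect_equal(lca(tr, c("s1a", "sa1")), "root")   # bacterial x archaeal
  expect_equal(lca(tr, c("s1a", "s2a")), "bac")    # same domain, diff phylum
  expect_error(lca(tr, character(0)), "empty")
  expect_error(lca(tr, "nope"), "unknown node")
})

test_that("lca agrees with brute-force oracle and is a common ancestor (property)", {
  set.seed(202)
  for (rep in 1:60) {
    tr <- randomTree(sample(2:200, 1))
    ids <- sample(tr@nodes$node_id, sample.int(5, 1), replace = TRUE)
    a <- lca(tr, ids)
    expect_identical(a, oracleLCA(tr, ids))
    # commutativity over set permutation
    expect_identical(lca(tr, rev(ids)), a)
    # ancestor-or-self of every member
    for (id in ids) expect_true(a %in% ancestorPath(tr, id))
    # associativity over set union
    if (length(ids) > 1) {
      k <- sample(length(ids) - 1, 1)
      expect_identical(lca(tr, c(lca(tr, ids[1:k]), ids[-(1:k)])), a)
    }
  }
})

test_that("taxonomy validation reports cycles, orphans, multiple roots", {
  good <- fixedTree()
  expect_true(validateTaxonomy(good)$ok)

  cyc <- data.frame(node_id = c("r", "a", "b"), parent_id = c("r", "b", "a"),
                    rank = "x", name = "x")
  v <- validateTaxonomy(cyc)
  expect_false(v$ok)
  expect_match(paste(v$defects, collapse = " "), "cycle")

  multi <- data.frame(node_id = c("r1", "r2"), parent_id = c("r1", "r2"),
                      rank = "root", name = "r")
  v <- validateTaxonomy(multi)
  expect_false(v$ok)
  expect_match(paste(v$defects, collapse = " "), "multiple roots")

  orphan <- data.frame(node_id = c("r", "a"), parent_id = c("r", "ghost"),
                       rank = "x", name = "x")
  expect_match(paste(validateTaxonomy(orphan)$defects, collapse = " "),
               "parent ids not in table")
})

test_that("taxonomy TSV round-trips and constructor rejects defects", {
  tr <- fixedTree()
  f <- tempfile(fileext = ".tsv")
  writeTaxonomy(tr, f)
  back <- readTaxonomy(f)
  expect_equal(back@nodes, tr@nodes)
  expect_equal(back@root, tr@root)
  expect_error(taxonomyTree(data.frame(
    node_id = c("a", "b"), parent_id = c("a", "b"),
    rank = "root", name = "r")), "exactly one root")
})

test_that("rank helpers walk the lineage correctly", {
  tr <- fixedTree()
  expect_equal(rankOf(tr, "g1"), "genus")
  expect_equal(ancestorAtRank(tr, "s1a", "phylum"), "p1")
  expect_equal(ancestorAtRank(tr, "s1a", "domain"), "bac")
  expect_true(is.na(ancestorAtRank(tr, "bac", "species")))
})
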