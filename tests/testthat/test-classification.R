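test_that("contig fragmentation windows and tail handling", {
  expect_equal(fragmentContig(1000), data.frame(start = 1L, end = 1000L))
  expect_equal(fragmentContig(2500),
               data.frame(start = c(1L, 1001L, 2001L),
                          end = c(1000L, 2000L, 2500L)))
  # 100 bp tail merged into the previous fragment
  expect_equal(fragmentContig(2100),
               data.frame(start = c(1L, 1001L), end = c(1000L, 2100L)))
  # tail exactly at min_tail kept as its own fragment
  expect_equal(fragmentContig(1200, minTailBp = 200),
               data.frame(start = c(1L, 1001L), end = c(1000L, 1200L)))
  # short contig -> single fragment
  expect_equal(fragmentContig(400), data.frame(start = 1L, end = 400L))
  # fragments tile the contig exactly
  set.seed(8)
  for (len in sample(1000:20000, 20)) {
    fr <- fragmentContig(len)
    expect_equal(fr$start[1], 1L)
    expect_equal(fr$end[nrow(fr)], len)
    if (nrow(fr) > 1) expect_true(all(fr$start[-1] == fr$end[-nrow(fr)] + 1L))
  }
})

mkHits <- function(q, taxon, bit, evalue = 1e-30, subj = NULL) {
  data.frame(query_id = q, subject_id = if (is.null(subj)) paste0("r|", taxon)
             else subj,
             percent_identity = 90, alignment_length = 100L, mismatches = 1L,
             gap_opens = 0L, q_start = 1L, q_end = 300L, s_start = 1L,
             s_end = 100L, e_value = evalue, bit_score = bit,
             subject_taxon = taxon, stringsAsFactors = FALSE)
}

test_that("top hit picks max bit score with deterministic tie-breaks", {
  h <- rbind(mkHits("f1", "tA", 80), mkHits("f1", "tB", 60))
  expect_equal(topHit(h)$subject_taxon, "tA")
  # single hit
  expect_equal(topHit(mkHits("f1", "tC", 10))$subject_taxon, "tC")
  # equal bit score: lower e-value wins
  h2 <- rbind(mkHits("f1", "tA", 80, evalue = 1e-10),
              mkHits("f1", "tB", 80, evalue = 1e-20))
  expect_equal(topHit(h2)$subject_taxon, "tB")
  # equal bit score and e-value: lexicographically smaller subject id
  h3 <- rbind(mkHits("f1", "tB", 80, subj = "zzz"),
              mkHits("f1", "tA", 80, subj = "aaa"))
  expect_equal(topHit(h3)$subject_taxon, "tA")
  expect_null(topHit(h3[0, ]))
})

test_that("taxon scores are top-hit counts over bin fragment count", {
  s <- scoreTaxa(c(rep("X", 6), rep(NA, 4)), 10)
  expect_equal(unname(s["X"]), 0.6)
  expect_equal(attr(s, "n_fragments"), 10L)
  expect_equal(unname(scoreTaxa(rep("X", 5), 5)["X"]), 1.0)
  expect_length(scoreTaxa(rep(NA_character_, 3), 3), 0)
  expect_error(scoreTaxa(character(0), 0), "zero fragments")
  # scores sum to at most 1
  set.seed(4)
  v <- sample(c("a", "b", "c", NA), 50, TRUE)
  expect_lte(sum(scoreTaxa(v, 50)), 1)
})

test_that("bin classification resolves top-scoring set by LCA", {
  tr <- fixedTree()
  # single dominant taxon -> itself at its own rank
  a1 <- classifyBin(c(s1a = 0.9, s2a = 0.1), tr)
  expect_equal(a1$node, "s1a")
  expect_equal(a1$rank, "species")
  # sibling species with equal score -> their genus
  a2 <- classifyBin(c(s1a = 0.5, s1b = 0.5), tr)
  expect_equal(a2$node, "g1")
  expect_equal(a2$rank, "genus")
  # near-tied species in different phyla fall back to the domain LCA
  a3 <- classifyBin(c(s1a = 0.5, s2a = 0.45), tr, topFrac = 0.8)
  expect_equal(a3$node, "bac")
  # strict-max behaviour via topFrac = 1
  a4 <- classifyBin(c(s1a = 0.5, s2a = 0.45), tr, topFrac = 1.0)
  expect_equal(a4$node, "s1a")
  # empty score vector -> unclassified
  a5 <- classifyBin(setNames(numeric(0), character(0)), tr)
  expect_true(is.na(a5$node))
  # assignment agrees with brute-force LCA of the top set
  expect_equal(a3$node, oracleLCA(tr, a3$top_set))
})

test_that("assignment is never deeper than any top-set member (property)", {
  set.seed(99)
  for (rep in 1:40) {
    tr <- randomTree(sample(5:200, 1))
    taxa <- sample(tr@nodes$node_id, sample(2:6, 1))
    sc <- setNames(runif(length(taxa), 0.1, 1), taxa)
    sc <- sc / sum(sc)
    a <- classifyBin(sc, tr)
    expect_identical(a$node, oracleLCA(tr, a$top_set))
    for (t in a$top_set) expect_true(a$node %in% ancestorPath(tr, t))
  }
})

test_that("classification is invariant to fragment order and score rescaling", {
  tr <- fixedTree()
  frags <- data.frame(fragment_id = paste0("f", 1:10), bin_id = "b1")
  hits <- rbind(mkHits(paste0("f", 1:6), "s1a", bit = runif(6, 100, 200)),
                mkHits(paste0("f", 7:9), "s1b", bit = runif(3, 100, 200)))
  base <- classifyBins(hits, frags, tr)
  set.seed(2)
  shuf <- classifyBins(hits[sample(nrow(hits)), ],
                       frags[sample(nrow(frags)), ], tr)
  expect_equal(shuf$assigned_node, base$assigned_node)
  scaled <- hits; scaled$bit_score <- scaled$bit_score * 7.3
  expect_equal(classifyBins(scaled, frags, tr)$assigned_node,
               base$assigned_node)
})

test_that("hybrid flag requires a domain-or-above LCA spanning both domains", {
  tr <- fixedTree()
  # top set all bacterial -> not hybrid
  a <- classifyBin(c(s1a = 0.5, s2a = 0.5), tr)
  expect_false(flagHybrid(a, tr))
  # bacterial + archaeal species -> hybrid, low completeness as cause
  b <- classifyBin(c(s1a = 0.5, sa1 = 0.5), tr)
  expect_equal(b$node, "root")
  hy <- flagHybrid(b, tr, completeness_pct = 15)
  expect_true(hy)
  expect_equal(attr(hy, "suspected_cause"), "low_completeness")
  expect_null(attr(flagHybrid(b, tr, completeness_pct = 50),
                   "suspected_cause"))
  # empty top set (unclassified) -> not hybrid
  u <- classifyBin(setNames(numeric(0), character(0)), tr)
  expect_false(flagHybrid(u, tr))
})

test_that("classifyBins rejects hits for unknown fragments", {
  tr <- fixedTree()
  frags <- data.frame(fragment_id = "f1", bin_id = "b1")
  expect_error(classifyBins(mkHits("ghost", "s1a", 50), frags, tr),
               "unknown fragment")
})

test_that("synthetic bins with low hit error recover the true lineage", {
  sim <- simulateCommunity(simulationConfig(seed = 13, nBins = 60,
                                            epsilon = 0.1))
  cls <- classifyBins(sim$hits, sim$fragments, sim$taxonomy)
  ev <- evaluateRecovery(sim, list(
    classification = cls,
    completeness = setNames(rep(0, 60), sim$bins$bin_id) +
      sim$truth$bin_completeness_pct,
    moduleDiff = setNames(numeric(52), moduleIds(sim$ersc))), minEffect = 99)
  expect_gte(ev$genus_or_below_accuracy, 0.95)
})
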