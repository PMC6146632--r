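test_that("rpkm follows count/((len/1000)*(total/1e6)) and its invariants", {
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(5, 500, 2e6), 5)
  expect_error(rpkm(1, 1000, 0), "total_mapped")
  # joint scale invariance in (count, total)
  set.seed(14)
  for (i in 1:20) {
    cnt <- sample.int(1000, 1); len <- sample(100:5000, 1)
    tot <- sample(1e5:1e7, 1); k <- sample(2:50, 1)
    expect_equal(rpkm(k * cnt, len, k * tot), rpkm(cnt, len, tot))
  }
})

test_that("module abundance is log2(mean RPKM + pseudocount)", {
  expect_equal(moduleAbundance(c(3, 5)), log2(5))        # mean 4 + 1
  expect_equal(moduleAbundance(1), 1)                    # log2(2)
  expect_equal(moduleAbundance(c(0, 0, 0)), 0)           # log2(1)
  expect_equal(moduleAbundance(c(3, 5), pseudocount = 0.5), log2(4.5))
  na <- moduleAbundance(numeric(0))
  expect_true(is.na(na))
  expect_true(attr(na, "no_reference"))
  # monotone non-decreasing in every constituent value
  set.seed(21)
  for (i in 1:20) {
    v <- runif(5, 0, 50)
    j <- sample.int(5, 1)
    v2 <- v; v2[j] <- v2[j] + runif(1, 0, 10)
    expect_gte(moduleAbundance(v2), moduleAbundance(v))
  }
})

test_that("module RPM sums counts, normalizes per million, log2-transforms", {
  expect_equal(moduleRPM(0, 1e6), 0)
  expect_equal(moduleRPM(500, 1e6), log2(501))
  expect_equal(moduleRPM(500, 1e6, log2 = FALSE), 500)
  # doubling counts and total leaves RPM unchanged
  expect_equal(moduleRPM(1000, 2e6), moduleRPM(500, 1e6))
})

test_that("genes are assigned to ECs with wildcard expansion, many-to-many", {
  tab <- erscTable(c("3.4.-.-", "Mprot", "proteases", "polymer degradation"),
                   c("1.1.1.1", "M1", "m1", "X"),
                   c("1.1.1.1", "M2", "m2", "X"),
                   c("5.5.5.5", "M2", "m2", "X"))
  ersc <- readERSC(writeTempTSV(tab))
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), stringsAsFactors = FALSE)
  genes$ec_codes <- list("3.4.21.1", character(0), c("1.1.1.1", "5.5.5.5"))
  ga <- assignGenesToECs(genes, ersc)
  expect_equal(ga[["3.4.-.-"]], "g1")       # wildcard match
  expect_equal(ga[["1.1.1.1"]], "g3")
  expect_equal(ga[["5.5.5.5"]], "g3")       # multi-EC gene in both ECs
  expect_false("g2" %in% unlist(ga))        # no-EC gene excluded
})

test_that("annotation coverage reproduces the worked pie-chart fractions", {
  # tryptophan-style module: one of three ECs annotated -> 33.3%
  tab <- erscTable(c("1.1.1.1", "Mtrp", "tryptophan", "amino acid metabolism"),
                   c("2.2.2.2", "Mtrp", "tryptophan", "amino acid metabolism"),
                   c("3.3.3.3", "Mtrp", "tryptophan", "amino acid metabolism"),
                   c("4.4.4.4", "Mma", "methylamine", "methanogenesis"),
                   c("5.5.5.5", "Mma", "methylamine", "methanogenesis"),
                   c("6.6.6.6", "Mma", "methylamine", "methanogenesis"),
                   c("7.7.7.7", "Mma", "methylamine", "methanogenesis"))
  ersc <- readERSC(writeTempTSV(tab))
  ga <- list("1.1.1.1" = "g1", "2.2.2.2" = character(0),
             "3.3.3.3" = character(0), "4.4.4.4" = "g2",
             "5.5.5.5" = character(0), "6.6.6.6" = character(0),
             "7.7.7.7" = character(0))
  cov <- annotationCoverage(ersc, ga)
  expect_equal(cov$annotation_coverage_pct[cov$module_id == "Mtrp"], 33.3)
  expect_equal(cov$annotation_coverage_pct[cov$module_id == "Mma"], 25)
  # all ECs annotated -> 100%
  gaFull <- setNames(as.list(paste0("g", 1:7)), names(ga))
  expect_true(all(annotationCoverage(ersc, gaFull)$annotation_coverage_pct == 100))
})

test_that("expression coverage counts ECs with >=1 read in >=1 sample", {
  tab <- erscTable(c("1.1.1.1", "M1", "m", "X"), c("2.2.2.2", "M1", "m", "X"),
                   c("3.3.3.3", "M1", "m", "X"))
  ersc <- readERSC(writeTempTSV(tab))
  cm <- matrix(c(5L, 0L, 1L, 0L, 0L, 0L), nrow = 3,
               dimnames = list(c("ga", "gb", "gc"), c("s1", "s2")))
  ga <- list("1.1.1.1" = "ga", "2.2.2.2" = "gb", "3.3.3.3" = "gc")
  cov <- expressionCoverage(ersc, cm, ga)
  # reads on ga and gc only -> 2 of 3 ECs expressed
  expect_equal(cov$expression_coverage_pct, 66.7)
  expect_equal(attr(cov, "global_n_expressed"), 2)
  # no reads -> 0%, every EC expressed -> 100%
  expect_equal(expressionCoverage(ersc, cm * 0L, ga)$expression_coverage_pct, 0)
  cm2 <- cm; cm2[] <- 1L
  expect_equal(expressionCoverage(ersc, cm2, ga)$expression_coverage_pct, 100)
})

test_that("abundance matrix equals brute-force recomputation (oracle, property)", {
  set.seed(31)
  for (rep in 1:8) {
    ersc <- simulateERSC(nModules = 6, nUniqueECs = 18)
    ecs <- unique(ersc@modules$ec)
    genes <- data.frame(gene_id = sprintf("g%02d", 1:30),
                        stringsAsFactors = FALSE)
    genes$ec_codes <- lapply(1:30, function(i)
      if (runif(1) < 0.8) sample(ecs, sample.int(2, 1)) else character(0))
    cm <- matrix(rpois(30 * 3, 40), 30, 3,
                 dimnames = list(genes$gene_id, c("s1", "s2", "s3")))
    totals <- colSums(cm) + sample(0:100, 3)
    ga <- assignGenesToECs(genes, ersc)
    got <- SummarizedExperiment::assay(
      moduleAbundanceMatrix(cm, totals, ersc, geneAssignment = ga,
                            normalization = "log2_rpm"), "abundance")
    want <- oracleModuleRPM(cm, totals, ersc, ga)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("RPKM-mode abundance pools reference sequences of the module", {
  tab <- erscTable(c("1.1.1.1", "M1", "m", "X"), c("2.2.2.2", "M1", "m", "X"))
  mt <- writeTempTSV(tab)
  ersc <- readERSC(mt)
  ersc@sequences <- data.frame(
    seq_id = c("r1", "r2", "r3"), ec = c("1.1.1.1", "1.1.1.1", "2.2.2.2"),
    length_bp = c(1000L, 500L, 2000L), source = "public-db")
  cm <- matrix(c(10L, 5L, 0L), 3, 1, dimnames = list(c("r1", "r2", "r3"), "s1"))
  tot <- c(s1 = 1e6)
  got <- SummarizedExperiment::assay(
    moduleAbundanceMatrix(cm, tot, ersc, normalization = "log2_mean_rpkm"),
    "abundance")
  # RPKM: r1 = 10, r2 = 10, r3 = 0; pooled mean = 20/3
  expect_equal(got["M1", "s1"], log2(20 / 3 + 1))
  # per-EC-mean alternative: mean(mean(10,10), mean(0)) = 5
  got2 <- SummarizedExperiment::assay(
    moduleAbundanceMatrix(cm, tot, ersc, normalization = "log2_mean_rpkm",
                          perECMean = TRUE), "abundance")
  expect_equal(got2["M1", "s1"], log2(6))
})

test_that("sample clustering is deterministic and permutation invariant", {
  mat <- rbind(mod1 = c(A = 1, B = 1, C = 9),
               mod2 = c(A = 2, B = 2, C = 8),
               mod3 = c(A = 3, B = 3, C = 7))
  cl <- clusterSamples(mat)
  # identical samples merge first, at height 0
  h <- cl$samples
  first <- h$merge[1, ]
  expect_setequal(h$labels[-first], c("A", "B"))
  expect_equal(h$height[1], 0)
  # permuting sample order leaves topology and leaf order unchanged
  cl2 <- clusterSamples(mat[, c(3, 1, 2)])
  expect_equal(cl2$sample_order, cl$sample_order)
  expect_equal(cl2$heatmap, cl$heatmap)
  expect_error(clusterSamples(mat[, 1, drop = FALSE]), "at least 2 samples")
  # three-sample distances: first merge is the closest pair (oracle check)
  set.seed(6)
  r <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("m", 1:10),
                                                c("X", "Y", "Z")))
  d <- as.matrix(dist(t(r)))
  pair <- sort(c(row(d)[which.min(d + diag(Inf, 3))],
                 col(d)[which.min(d + diag(Inf, 3))]))
  clr <- clusterSamples(r)
  expect_setequal(clr$samples$labels[-clr$samples$merge[1, ]],
                  colnames(r)[pair])
})

test_that("dendrograms export to readable Newick", {
  mat <- rbind(mod1 = c(A = 1, B = 1.1, C = 9),
               mod2 = c(A = 2, B = 2.2, C = 8))
  cl <- clusterSamples(mat)
  f <- tempfile(fileext = ".nwk")
  writeDendrogram(cl$samples, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
})

test_that("top expressed summary ranks by mean RPKM and tallies GO terms", {
  cm <- matrix(c(100L, 10L, 50L,
                 100L, 10L, 50L), nrow = 3,
               dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  lens <- c(t1 = 1000, t2 = 100, t3 = 1000)
  tot <- c(s1 = 1e6, s2 = 1e6)
  gos <- list(t1 = c("GO:1", "GO:2"), t2 = "GO:1", t3 = c("GO:1", "GO:3"))
  # RPKM: t1 = 100, t2 = 100, t3 = 50; tie at the top broken by id
  top <- topExpressedSummary(cm, lens, tot, gos, n = 2)
  expect_equal(top$ranked$transcript_id, c("t1", "t2"))
  expect_equal(top$go_frequencies$count[top$go_frequencies$go == "GO:1"], 2)
  # n = 1 keeps only the higher-expressed of two
  top1 <- topExpressedSummary(cm[1:2, ], lens, tot, gos, n = 1)
  expect_equal(nrow(top1$ranked), 1)
  # n larger than transcript count -> all ranked, flagged truncated
  topAll <- topExpressedSummary(cm, lens, tot, gos, n = 500)
  expect_equal(nrow(topAll$ranked), 3)
  expect_true(attr(topAll, "truncated"))
  # GO term shared by all 3 of top-n -> frequency 3
  expect_equal(topAll$go_frequencies$count[topAll$go_frequencies$go == "GO:1"],
               3)
})

test_that("module-level expression differences recover simulated signs", {
  set.seed(55)
  correct <- 0L; total <- 0L
  for (r in seq_len(30)) {
    sim <- simulateCommunity(simulationConfig(
      seed = 1000 + r, nBins = 8, nModules = 6, nUniqueECs = 20,
      genesPerBin = c(10, 16), nSamplesRNA = 6, totalReadsRNA = 5e4,
      effectSize = 1))
    ga <- assignGenesToECs(sim$genes, sim$ersc)
    ab <- moduleAbundanceMatrix(sim$counts, sim$total_mapped, sim$ersc,
                                geneAssignment = ga)
    m <- SummarizedExperiment::assay(ab, "abundance")
    dd <- rowMeans(m[, names(sim$conditions)[sim$conditions == "B"]]) -
      rowMeans(m[, names(sim$conditions)[sim$conditions == "A"]])
    eff <- sim$truth$module_effects
    simulated <- unique(sim$ersc@modules$module_id[
      sim$ersc@modules$ec %in% stats::na.omit(sim$truth$gene_ec)])
    big <- intersect(names(eff)[abs(eff) >= 0.5], simulated)
    correct <- correct + sum(sign(dd[big]) == sign(eff[big]))
    total <- total + length(big)
  }
  expect_gte(correct / total, 0.95)
})
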