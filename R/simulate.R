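#' Configuration for synthetic community simulation
#'
#' Defines the conditions under which a synthetic anaerobic-digester
#' community is generated: a two-domain taxonomy, genomic bins with known
#' taxa and completeness, marker presence, fragment-level alignment hits
#' with a controllable wrong-phylum error rate, EC-labelled genes, and
#' metatranscriptomic counts with module-level log2 effects between two
#' reactor conditions. The seed fully determines the output.
#'
#' @param seed integer RNG seed.
#' @param nBins number of genomic bins.
#' @param nMarkers size of the marker panel (default 137).
#' @param completenessRange range the per-bin true completeness is drawn
#'   from (uniform).
#' @param markerMode \code{"binomial"} (each marker present independently
#'   with probability = true completeness) or \code{"exact"} (exactly
#'   \code{round(c * nMarkers)} markers present).
#' @param epsilon fragment hit error rate: probability a fragment's top
#'   hit points to a random species in a different phylum instead of the
#'   bin's true species.
#' @param hitRate probability a fragment has any hit at all.
#' @param contigsPerBin integer range of contigs per bin.
#' @param contigLengthRange contig length range in bp.
#' @param nSamplesDNA number of metagenomic samples (support rule).
#' @param supportRange range of truly supporting samples per bin.
#' @param genesPerBin integer range of genes per bin.
#' @param ecLabeledFrac fraction of genes carrying an EC label.
#' @param nModules,nUniqueECs structure of the synthetic EC reference
#'   collection (defaults mirror the curated collection: 52 modules, 235
#'   unique ECs).
#' @param nSamplesRNA number of metatranscriptome samples (split into
#'   two condition groups).
#' @param totalReadsRNA expected mapped reads per RNA sample.
#' @param exprMu,exprSigma per-gene log-normal expression parameters
#'   (natural-log scale).
#' @param effectSize module-level log2 fold difference applied to
#'   affected modules between the two condition groups.
#' @param effectFrac fraction of modules receiving a (random-sign)
#'   effect.
#' @param dispersion NA for Poisson counts (default); a positive value
#'   switches to negative binomial with that size parameter, since real
#'   metatranscriptomes are overdispersed.
#' @return a list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1, nBins = 50, nMarkers = 137,
                             completenessRange = c(0.05, 1),
                             markerMode = c("binomial", "exact"),
                             epsilon = 0, hitRate = 0.95,
                             contigsPerBin = c(4, 12),
                             contigLengthRange = c(1500, 12000),
                             nSamplesDNA = 4, supportRange = c(2, 4),
                             genesPerBin = c(6, 16), ecLabeledFrac = 0.7,
                             nModules = 52, nUniqueECs = 235,
                             nSamplesRNA = 6, totalReadsRNA = 2e5,
                             exprMu = 2, exprSigma = 1,
                             effectSize = 1, effectFrac = 0.5,
                             dispersion = NA) {
  markerMode <- match.arg(markerMode)
  stopifnot(epsilon >= 0, epsilon <= 1, hitRate >= 0, hitRate <= 1,
            ecLabeledFrac >= 0, ecLabeledFrac <= 1,
            effectFrac >= 0, effectFrac <= 1, nBins >= 1,
            all(completenessRange >= 0), all(completenessRange <= 1))
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Simulate a two-domain taxonomy
#'
#' Builds a rooted taxonomy with ranks root, domain (Bacteria, Archaea),
#' phylum, class, order, family, genus, species. Draws on the current RNG
#' state (seed it for reproducibility).
#'
#' @param nPhylaBacteria,nPhylaArchaea phyla per domain.
#' @param maxChildren maximum children at class/order/family levels.
#' @param generaPerFamily,speciesPerGenus fan-out at the deepest levels.
#' @return a [TaxonomyTree-class].
#' @export
simulateTaxonomy <- function(nPhylaBacteria = 6, nPhylaArchaea = 2,
                             maxChildren = 2, generaPerFamily = 2,
                             speciesPerGenus = 2) {
  counter <- 0L
  newId <- function() {
    counter <<- counter + 1L
    sprintf("t%04d", counter)
  }
  rows <- list()
  add <- function(id, parent, rank, name)
    rows[[length(rows) + 1L]] <<- data.frame(
      node_id = id, parent_id = parent, rank = rank, name = name,
      stringsAsFactors = FALSE)
  root <- newId(); add(root, root, "root", "cellular organisms")
  for (dom in c("Bacteria", "Archaea")) {
    d <- newId(); add(d, root, "domain", dom)
    np <- if (dom == "Bacteria") nPhylaBacteria else nPhylaArchaea
    for (p in seq_len(np)) {
      ph <- newId(); add(ph, d, "phylum", paste0(dom, "_phylum_", p))
      for (cl in seq_len(sample.int(maxChildren, 1))) {
        c_ <- newId(); add(c_, ph, "class", paste0("class_", c_))
        for (or in seq_len(sample.int(maxChildren, 1))) {
          o <- newId(); add(o, c_, "order", paste0("order_", o))
          for (fa in seq_len(sample.int(maxChildren, 1))) {
            f <- newId(); add(f, o, "family", paste0("family_", f))
            for (ge in seq_len(generaPerFamily)) {
              g <- newId(); add(g, f, "genus", paste0("genus_", g))
              for (sp in seq_len(speciesPerGenus)) {
                s <- newId(); add(s, g, "species", paste0("species_", s))
              }
            }
          }
        }
      }
    }
  }
  taxonomyTree(do.call(rbind, rows))
}

#' Simulate an EC reference sequence collection
#'
#' Emulates the structure of the curated anaerobic-digestion collection:
#' unique ECs partitioned into modules across the pathway categories
#' (polymer degradation through methanogenesis), a few wildcard
#' protease/lipase-style ECs, occasional ECs shared between modules, and
#' some ECs without any reference sequence. EC codes themselves are
#' synthetic.
#'
#' @param nModules number of metabolic modules.
#' @param nUniqueECs number of distinct EC codes.
#' @param noSequenceFrac fraction of ECs left without reference
#'   sequences.
#' @return an [ERSC-class].
#' @export
simulateERSC <- function(nModules = 52, nUniqueECs = 235,
                         noSequenceFrac = 0.08) {
  stopifnot(nUniqueECs >= nModules)
  categories <- c("polymer degradation", "carbohydrate metabolism",
                  "lipid metabolism", "amino acid metabolism",
                  "acetogenesis", "methanogenesis", "coenzyme metabolism")
  # distinct synthetic EC codes; a couple of class-level wildcards
  ecs <- character(0)
  while (length(ecs) < nUniqueECs) {
    cand <- sprintf("%d.%d.%d.%d", sample.int(7, nUniqueECs, TRUE),
                    sample.int(20, nUniqueECs, TRUE),
                    sample.int(30, nUniqueECs, TRUE),
                    sample.int(200, nUniqueECs, TRUE))
    ecs <- unique(c(ecs, cand))
  }
  ecs <- ecs[seq_len(nUniqueECs)]
  nWild <- min(2L, nUniqueECs)
  wild <- vapply(seq_len(nWild), function(i) {
    p <- strsplit(ecs[i], ".", fixed = TRUE)[[1]]
    paste(c(p[1:2], "-", "-"), collapse = ".")
  }, character(1))
  ecs[seq_len(nWild)] <- ifelse(wild %in% ecs[-seq_len(nWild)],
                                ecs[seq_len(nWild)], wild)
  # partition into modules, every module non-empty
  modOf <- c(seq_len(nModules),
             sample.int(nModules, nUniqueECs - nModules, replace = TRUE))
  rows <- data.frame(
    ec = ecs, module_id = sprintf("M%02d", modOf),
    stringsAsFactors = FALSE)
  # a few ECs redundantly shared by a second module
  nShared <- max(1L, round(0.05 * nUniqueECs))
  sharedIdx <- sample.int(nUniqueECs, nShared)
  extra <- data.frame(
    ec = ecs[sharedIdx],
    module_id = sprintf("M%02d", ((modOf[sharedIdx]) %% nModules) + 1L),
    stringsAsFactors = FALSE)
  rows <- unique(rbind(rows, extra))
  modCat <- stats::setNames(
    sample(categories, nModules, replace = TRUE), sprintf("M%02d", 1:nModules))
  rows$module_name <- paste0("module ", rows$module_id)
  rows$category <- unname(modCat[rows$module_id])
  rows <- rows[order(rows$module_id, rows$ec),
               c("ec", "module_id", "module_name", "category")]
  rownames(rows) <- NULL
  # reference sequences: 1-3 per EC, some ECs without known sequence
  noSeq <- sample(ecs, round(noSequenceFrac * nUniqueECs))
  seqRows <- list()
  for (e in setdiff(ecs, noSeq)) {
    k <- sample.int(3, 1)
    seqRows[[e]] <- data.frame(
      seq_id = paste0("ref_", gsub("[.-]", "_", e), "_", seq_len(k)),
      ec = e, length_bp = sample(300:3000, k, replace = TRUE),
      source = sample(c("public-db", "assembly-derived"), k, TRUE),
      stringsAsFactors = FALSE)
  }
  seqs <- if (length(seqRows)) do.call(rbind, seqRows) else
    data.frame(seq_id = character(0), ec = character(0),
               length_bp = integer(0), source = character(0))
  rownames(seqs) <- NULL
  new("ERSC", modules = rows, sequences = seqs)
}

#' Generate a synthetic marker panel
#' @param n panel size (default 137).
#' @return a [MarkerGeneSet-class].
#' @export
simulateMarkerSet <- function(n = 137) {
  markerGeneSet(sprintf("MK%04d", seq_len(n)))
}

#' Simulate a synthetic community with known ground truth
#'
#' Generates, from one seed, every input the downstream stages consume:
#' taxonomy, EC reference collection, marker panel, genomic bins (contigs,
#' marker presence, per-sample read support), per-fragment alignment hits
#' with the configured wrong-phylum error rate, EC-labelled genes, and
#' two-condition metatranscriptomic counts with module-level effects. The
#' returned \code{truth} element records the generating values so
#' recovery can be scored with [evaluateRecovery()].
#'
#' @param cfg a [simulationConfig()].
#' @return list with elements \code{taxonomy}, \code{ersc},
#'   \code{markers}, \code{bins}, \code{binMembership},
#'   \code{contigLengths}, \code{markerHits}, \code{contigMapped},
#'   \code{fragments}, \code{hits}, \code{genes}, \code{counts},
#'   \code{total_mapped}, \code{conditions}, \code{truth}, \code{config}.
#' @export
simulateCommunity <- function(cfg = simulationConfig()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  tree <- simulateTaxonomy()
  ersc <- simulateERSC(cfg$nModules, cfg$nUniqueECs)
  markers <- simulateMarkerSet(cfg$nMarkers)
  species <- tree@nodes$node_id[tree@nodes$rank == "species"]
  phylumOf <- vapply(species, function(s) ancestorAtRank(tree, s, "phylum"),
                     character(1))

  binIds <- sprintf("bin%03d", seq_len(cfg$nBins))
  trueTaxon <- stats::setNames(sample(species, cfg$nBins, replace = TRUE),
                               binIds)
  trueComp <- stats::setNames(
    stats::runif(cfg$nBins, cfg$completenessRange[1], cfg$completenessRange[2]),
    binIds)

  # contigs
  memb <- list(); lens <- list()
  for (b in binIds) {
    nc <- sample(cfg$contigsPerBin[1]:cfg$contigsPerBin[2], 1)
    ids <- paste0(b, "_c", seq_len(nc))
    memb[[b]] <- data.frame(bin_id = b, contig_id = ids,
                            stringsAsFactors = FALSE)
    lens[[b]] <- stats::setNames(
      sample(cfg$contigLengthRange[1]:cfg$contigLengthRange[2], nc, TRUE), ids)
  }
  binMembership <- do.call(rbind, memb); rownames(binMembership) <- NULL
  contigLengths <- unlist(unname(lens))

  # marker presence
  panel <- markers@marker_ids
  mh <- list(); realized <- numeric(length(binIds)); names(realized) <- binIds
  for (b in binIds) {
    found <- if (cfg$markerMode == "exact") {
      sample(panel, round(trueComp[[b]] * length(panel)))
    } else {
      panel[stats::runif(length(panel)) < trueComp[[b]]]
    }
    realized[b] <- round(100 * length(found) / length(panel), 1)
    if (length(found))
      mh[[b]] <- data.frame(bin_id = b, marker_id = found,
                            stringsAsFactors = FALSE)
  }
  markerHits <- if (length(mh)) do.call(rbind, mh) else
    data.frame(bin_id = character(0), marker_id = character(0))
  rownames(markerHits) <- NULL

  # metagenomic sample support: supporting samples map every bin contig
  dnaSamples <- sprintf("dna%d", seq_len(cfg$nSamplesDNA))
  trueSupport <- stats::setNames(
    sample(cfg$supportRange[1]:cfg$supportRange[2], cfg$nBins, TRUE), binIds)
  contigMapped <- stats::setNames(
    replicate(cfg$nSamplesDNA, character(0), simplify = FALSE), dnaSamples)
  for (b in binIds) {
    sup <- sample(dnaSamples, trueSupport[[b]])
    for (s in sup)
      contigMapped[[s]] <- c(contigMapped[[s]],
                             binMembership$contig_id[binMembership$bin_id == b])
  }

  # fragment hits
  fragments <- enumerateFragments(binMembership, contigLengths)
  nF <- nrow(fragments)
  binOfFrag <- fragments$bin_id
  hasHit <- stats::runif(nF) < cfg$hitRate
  wrong <- hasHit & stats::runif(nF) < cfg$epsilon
  subj <- rep(NA_character_, nF)
  subj[hasHit] <- trueTaxon[binOfFrag[hasHit]]
  if (any(wrong)) {
    subj[wrong] <- vapply(which(wrong), function(i) {
      pool <- species[phylumOf != phylumOf[[trueTaxon[[binOfFrag[i]]]]]]
      sample(pool, 1)
    }, character(1))
  }
  hi <- which(hasHit)
  hits <- data.frame(
    query_id = fragments$fragment_id[hi],
    subject_id = paste0("ref|", subj[hi]),
    percent_identity = round(stats::runif(length(hi), 60, 100), 1),
    alignment_length = sample(100:333, length(hi), TRUE),
    mismatches = sample(0:40, length(hi), TRUE),
    gap_opens = sample(0:4, length(hi), TRUE),
    q_start = 1L, q_end = 999L,
    s_start = 1L, s_end = 333L,
    e_value = 10^-stats::runif(length(hi), 10, 60),
    bit_score = round(stats::runif(length(hi), 120, 400), 1),
    subject_taxon = subj[hi], stringsAsFactors = FALSE)
  # weaker decoy hits for a subset of fragments
  nd <- round(0.3 * nrow(hits))
  if (nd > 0) {
    di <- sample.int(nrow(hits), nd)
    decoy <- hits[di, , drop = FALSE]
    decoy$subject_taxon <- sample(species, nd, replace = TRUE)
    decoy$subject_id <- paste0("ref|", decoy$subject_taxon)
    decoy$bit_score <- decoy$bit_score - stats::runif(nd, 5, 60)
    decoy$e_value <- decoy$e_value * 10^stats::runif(nd, 1, 5)
    hits <- rbind(hits, decoy)
  }
  rownames(hits) <- NULL

  # genes with EC labels, placed on contigs
  ecPool <- unique(ersc@modules$ec)
  ecConcrete <- ecPool[!grepl("-", ecPool, fixed = TRUE)]
  geneRows <- list(); gi <- 0L
  for (b in binIds) {
    ng <- sample(cfg$genesPerBin[1]:cfg$genesPerBin[2], 1)
    cts <- binMembership$contig_id[binMembership$bin_id == b]
    pos <- stats::setNames(rep(1L, length(cts)), cts)
    for (k in seq_len(ng)) {
      len <- sample(300:2400, 1)
      ct <- cts[which(pos + len - 1 <= contigLengths[cts])[1]]
      if (is.na(ct)) next
      gi <- gi + 1L
      ec <- if (stats::runif(1) < cfg$ecLabeledFrac)
        sample(ecConcrete, 1) else NA_character_
      geneRows[[gi]] <- data.frame(
        gene_id = sprintf("gene%05d", gi), contig_id = ct,
        start = pos[[ct]], end = pos[[ct]] + len - 1L,
        strand = sample(c("+", "-"), 1), length_bp = len,
        gene_name = if (stats::runif(1) < 0.4) sprintf("g%05d", gi)
                    else NA_character_,
        ec = ec, stringsAsFactors = FALSE)
      pos[ct] <- pos[[ct]] + len + 100L
    }
  }
  genes <- do.call(rbind, geneRows); rownames(genes) <- NULL
  genes$ec_codes <- lapply(genes$ec, function(e)
    if (is.na(e)) character(0) else e)
  goPool <- sprintf("GO:%07d", sample.int(9999999, 40))
  genes$go_terms <- lapply(seq_len(nrow(genes)), function(i)
    if (stats::runif(1) < 0.5) sample(goPool, sample.int(3, 1)) else character(0))
  genes$annotated <- !is.na(genes$gene_name) | lengths(genes$ec_codes) > 0

  # two-condition metatranscriptomic counts
  rnaSamples <- sprintf("rna%d", seq_len(cfg$nSamplesRNA))
  conditions <- stats::setNames(
    rep(c("A", "B"), length.out = cfg$nSamplesRNA), rnaSamples)
  modEffect <- stats::setNames(numeric(cfg$nModules), moduleIds(ersc))
  affected <- stats::runif(cfg$nModules) < cfg$effectFrac
  modEffect[affected] <- cfg$effectSize * sample(c(-1, 1), sum(affected), TRUE)
  firstModule <- vapply(ecPool, function(e)
    ersc@modules$module_id[ersc@modules$ec == e][1], character(1))
  geneEffect <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  hasEC <- !is.na(genes$ec)
  geneEffect[hasEC] <- modEffect[firstModule[genes$ec[hasEC]]]
  baseRate <- exp(stats::rnorm(nrow(genes), cfg$exprMu, cfg$exprSigma))
  names(baseRate) <- genes$gene_id
  counts <- matrix(0L, nrow(genes), cfg$nSamplesRNA,
                   dimnames = list(genes$gene_id, rnaSamples))
  for (s in rnaSamples) {
    rate <- baseRate * 2^(geneEffect * (conditions[[s]] == "B"))
    lam <- rate * genes$length_bp / 1000
    lam <- lam / sum(lam) * cfg$totalReadsRNA
    counts[, s] <- if (is.na(cfg$dispersion)) stats::rpois(length(lam), lam)
      else stats::rnbinom(length(lam), mu = lam, size = cfg$dispersion)
  }
  total_mapped <- colSums(counts)

  list(taxonomy = tree, ersc = ersc, markers = markers,
       bins = data.frame(bin_id = binIds, stringsAsFactors = FALSE),
       binMembership = binMembership, contigLengths = contigLengths,
       markerHits = markerHits, contigMapped = contigMapped,
       fragments = fragments, hits = hits, genes = genes,
       counts = counts, total_mapped = total_mapped,
       conditions = conditions,
       truth = list(bin_taxon = trueTaxon,
                    bin_completeness_target = 100 * trueComp,
                    bin_completeness_pct = realized,
                    bin_support = trueSupport,
                    module_effects = modEffect,
                    gene_ec = stats::setNames(genes$ec, genes$gene_id)),
       config = cfg)
}

#' Write a simulated community to files
#'
#' Emits the community in the toolkit's external interface formats:
#' taxonomy TSV, ERSC module table and sequence map, bin membership,
#' marker hits, per-sample contig mapping, 13-column hit table, GFF3 gene
#' annotation, counts + totals TSV, contig/reference FASTA (random
#' sequences of the recorded lengths) and \code{truth.json}.
#'
#' @param sim result of [simulateCommunity()].
#' @param dir output directory (created if needed).
#' @param writeSequences also write contig and reference FASTA files.
#' @return named character vector of written paths, invisibly.
#' @export
writeCommunity <- function(sim, dir, writeSequences = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- c(taxonomy = p("taxonomy.tsv"), ersc = p("ersc_modules.tsv"),
             ersc_map = p("ersc_seq_map.tsv"), bins = p("bin_membership.tsv"),
             contigs = p("contig_lengths.tsv"), markers = p("marker_panel.txt"),
             marker_hits = p("marker_hits.tsv"),
             mapping = p("contig_mapping.tsv"), hits = p("hits.tsv"),
             genes = p("genes.gff3"), counts = p("counts.tsv"),
             totals = p("totals.tsv"), truth = p("truth.json"))
  writeTaxonomy(sim$taxonomy, paths["taxonomy"])
  writeERSC(sim$ersc, paths["ersc"], paths["ersc_map"])
  wt <- function(x, f) utils::write.table(x, f, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(sim$binMembership, paths["bins"])
  wt(data.frame(contig_id = names(sim$contigLengths),
                length_bp = unname(sim$contigLengths)), paths["contigs"])
  writeLines(sim$markers@marker_ids, paths["markers"])
  wt(sim$markerHits, paths["marker_hits"])
  mapRows <- do.call(rbind, lapply(names(sim$contigMapped), function(s)
    if (length(sim$contigMapped[[s]]))
      data.frame(sample_id = s, contig_id = sim$contigMapped[[s]])
    else NULL))
  wt(mapRows, paths["mapping"])
  hcols <- c(.HIT_COLS, "subject_taxon")
  utils::write.table(sim$hits[, hcols], paths["hits"], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  .writeGenesGFF3(sim$genes, paths["genes"])
  writeCounts(sim$counts, paths["counts"], sim$total_mapped, paths["totals"])
  jsonlite::write_json(
    list(bin_taxon = as.list(sim$truth$bin_taxon),
         bin_completeness_pct = as.list(sim$truth$bin_completeness_pct),
         bin_support = as.list(sim$truth$bin_support),
         module_effects = as.list(sim$truth$module_effects)),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  if (writeSequences) {
    paths <- c(paths, contig_fasta = p("contigs.fasta"),
               ref_fasta = p("ersc_seqs.fasta"))
    # sequence content is derived from the simulation seed so repeated
    # writes of the same community are byte-identical
    oldSeed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(oldSeed))
      assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
    set.seed(sim$config$seed + 1L)
    rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
    ct <- vapply(sim$contigLengths, rnd, character(1))
    writeFasta(stats::setNames(ct, names(sim$contigLengths)),
               paths["contig_fasta"])
    if (nrow(sim$ersc@sequences)) {
      rs <- vapply(sim$ersc@sequences$length_bp, rnd, character(1))
      writeFasta(stats::setNames(rs, sim$ersc@sequences$seq_id),
                 paths["ref_fasta"])
    }
  }
  invisible(paths)
}

# internal: minimal GFF3 writer for simulated gene records
.writeGenesGFF3 <- function(genes, path) {
  attrs <- vapply(seq_len(nrow(genes)), function(i) {
    a <- paste0("ID=", genes$gene_id[i])
    if (!is.na(genes$gene_name[i]))
      a <- paste0(a, ";gene=", genes$gene_name[i])
    if (length(genes$ec_codes[[i]]))
      a <- paste0(a, ";eC_number=", paste(genes$ec_codes[[i]], collapse = ","))
    if (length(genes$go_terms[[i]]))
      a <- paste0(a, ";go_terms=", paste(genes$go_terms[[i]], collapse = ","))
    a
  }, character(1))
  lines <- sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                   genes$contig_id, genes$start, genes$end, genes$strand,
                   attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Run the downstream pipeline on a simulated community
#'
#' Convenience wrapper chaining bin QC (completeness + support + filter),
#' fragment-vote LCA classification, and module profiling (log2 RPM
#' abundance and the mean log2 difference between the two simulated
#' condition groups) on the in-memory output of [simulateCommunity()].
#'
#' @param sim result of [simulateCommunity()].
#' @param filterCfg a [binFilterConfig()].
#' @param topFrac see [classifyBin()].
#' @return list with \code{completeness} (named vector), \code{support}
#'   (named vector), \code{filter} (retained/rejected),
#'   \code{classification} (data.frame), \code{abundance}
#'   (SummarizedExperiment), \code{moduleDiff} (named vector, condition B
#'   minus A).
#' @export
runCommunityPipeline <- function(sim, filterCfg = binFilterConfig(),
                                 topFrac = 0.8) {
  binIds <- sim$bins$bin_id
  comp <- vapply(binIds, function(b) as.numeric(markerCompleteness(
    sim$markerHits$marker_id[sim$markerHits$bin_id == b], sim$markers)),
    numeric(1))
  supp <- vapply(binIds, function(b) as.integer(sampleSupport(
    sim$contigMapped,
    sim$binMembership$contig_id[sim$binMembership$bin_id == b])),
    integer(1))
  filt <- filterBins(data.frame(bin_id = binIds, completeness_pct = comp,
                                support = supp, stringsAsFactors = FALSE),
                     filterCfg)
  cls <- classifyBins(sim$hits, sim$fragments, sim$taxonomy,
                      completeness = comp, topFrac = topFrac)
  ga <- assignGenesToECs(sim$genes, sim$ersc)
  ab <- moduleAbundanceMatrix(sim$counts, sim$total_mapped, sim$ersc,
                              geneAssignment = ga,
                              normalization = "log2_rpm")
  m <- SummarizedExperiment::assay(ab, "abundance")
  grpA <- names(sim$conditions)[sim$conditions == "A"]
  grpB <- names(sim$conditions)[sim$conditions == "B"]
  moduleDiff <- rowMeans(m[, grpB, drop = FALSE]) -
    rowMeans(m[, grpA, drop = FALSE])
  list(completeness = comp, support = supp, filter = filt,
       classification = cls, abundance = ab, moduleDiff = moduleDiff)
}

#' Score recovery of simulated ground truth
#'
#' Compares pipeline outputs against the generating truth: exact-node and
#' per-rank classification accuracy (a bin scores at rank r when its
#' assignment is at or below r and its ancestor at r matches the true
#' lineage), RMSE of estimated completeness, and sign accuracy of module
#' effects at least \code{minEffect} log2 units in magnitude.
#'
#' @param sim result of [simulateCommunity()].
#' @param results result of [runCommunityPipeline()] (or a compatible
#'   list with \code{classification}, \code{completeness},
#'   \code{moduleDiff}).
#' @param minEffect magnitude floor for effect-sign scoring (default 0.5).
#' @return list with \code{exact_accuracy}, \code{rank_accuracy} (named
#'   by rank), \code{genus_or_below_accuracy}, \code{completeness_rmse},
#'   \code{effect_sign_accuracy}, \code{n_bins}, \code{n_effect_modules}.
#' @export
evaluateRecovery <- function(sim, results, minEffect = 0.5) {
  tree <- sim$taxonomy
  truth <- sim$truth
  cls <- results$classification
  if (!setequal(cls$bin_id, names(truth$bin_taxon)))
    stop("bin ids of classification and truth do not match")
  trueT <- truth$bin_taxon[cls$bin_id]
  exact <- mean(!is.na(cls$assigned_node) & cls$assigned_node == trueT)
  ranks <- setdiff(taxRanks(), "root")
  rankAcc <- vapply(ranks, function(r) {
    ok <- vapply(seq_len(nrow(cls)), function(i) {
      if (is.na(cls$assigned_node[i])) return(FALSE)
      a <- ancestorAtRank(tree, cls$assigned_node[i], r)
      !is.na(a) && a == ancestorAtRank(tree, trueT[[i]], r)
    }, logical(1))
    mean(ok)
  }, numeric(1))
  comp <- results$completeness[names(truth$bin_completeness_pct)]
  if (anyNA(comp)) stop("completeness estimates missing for some bins")
  rmse <- sqrt(mean((comp - truth$bin_completeness_pct)^2))
  eff <- truth$module_effects
  big <- names(eff)[abs(eff) >= minEffect]
  simulated <- unique(sim$ersc@modules$module_id[
    sim$ersc@modules$ec %in% stats::na.omit(truth$gene_ec)])
  big <- intersect(big, simulated)
  signAcc <- if (length(big))
    mean(sign(results$moduleDiff[big]) == sign(eff[big])) else NA_real_
  list(exact_accuracy = exact, rank_accuracy = rankAcc,
       genus_or_below_accuracy = unname(rankAcc["genus"]),
       completeness_rmse = rmse, effect_sign_accuracy = signAcc,
       n_bins = nrow(cls), n_effect_modules = length(big))
}
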