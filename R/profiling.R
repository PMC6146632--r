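#' Assign genes to reference ECs
#'
#' A gene contributes to every reference EC it matches: exact EC codes
#' match themselves, and wildcard reference ECs (e.g. the protease class
#' \code{3.4.-.-}) match any gene EC sharing the specified prefix. Genes
#' without a matching EC are excluded. Because an EC may sit in several
#' modules, a gene can count toward more than one module (once per
#' module).
#'
#' @param genes gene-record data.frame ([readGFF3()]) with list-column
#'   \code{ec_codes}, or a data.frame with columns \code{gene_id},
#'   \code{ec} (one row per gene/EC pair).
#' @param ersc an [ERSC-class].
#' @return named list: reference EC code -> character vector of gene ids.
#' @export
assignGenesToECs <- function(genes, ersc) {
  if ("ec_codes" %in% names(genes)) {
    pairs <- data.frame(
      gene_id = rep(genes$gene_id, lengths(genes$ec_codes)),
      ec = unlist(genes$ec_codes, use.names = FALSE),
      stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("gene_id", "ec") %in% names(genes)))
    pairs <- genes[, c("gene_id", "ec")]
  }
  refECs <- unique(ersc@modules$ec)
  out <- stats::setNames(vector("list", length(refECs)), refECs)
  if (nrow(pairs) == 0) return(out)
  uec <- unique(pairs$ec)
  for (ref in refECs) {
    matched <- uec[ecMatches(uec, ref)]
    out[[ref]] <- unique(pairs$gene_id[pairs$ec %in% matched])
  }
  out
}

#' Reads per kilobase per million mapped reads
#'
#' \code{count / ((length_bp / 1000) * (total_mapped / 1e6))}. Vectorised
#' over counts and lengths.
#'
#' @param count non-negative read count(s).
#' @param length_bp gene length(s) in bp (>= 1).
#' @param total_mapped total mapped reads in the sample (>= 1).
#' @return RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, length_bp, total_mapped) {
  if (any(total_mapped < 1)) stop("total_mapped must be >= 1")
  if (any(length_bp < 1)) stop("gene length must be >= 1 bp")
  count / ((length_bp / 1000) * (total_mapped / 1e6))
}

#' Module abundance: log2 of mean RPKM over the module's gene sequences
#'
#' The abundance of a metabolic module in a sample is the log2-transformed
#' mean RPKM over every EC gene sequence of the module (zero-count
#' sequences included in the mean), with a pseudocount added inside the
#' log so all-zero modules map to \code{log2(pseudocount)} (0 for the
#' default pseudocount of 1).
#'
#' @param rpkmValues numeric vector of per-sequence RPKM values for all
#'   gene sequences of the module (in one sample).
#' @param pseudocount added to the mean before log2 (default 1).
#' @return numeric(1) log2 abundance; \code{NA} (flagged by attribute
#'   \code{"no_reference"}) for a module with zero reference sequences.
#' @examples
#' moduleAbundance(c(3, 5))  # log2(4 + 1) = 2.3219
#' @export
moduleAbundance <- function(rpkmValues, pseudocount = 1) {
  if (length(rpkmValues) == 0) {
    out <- NA_real_
    attr(out, "no_reference") <- TRUE
    return(out)
  }
  log2(mean(rpkmValues) + pseudocount)
}

#' Module RPM: reads per million summed over module genes
#'
#' \code{1e6 * sum(module counts) / total_mapped}, then
#' \code{log2(x + pseudocount)} when \code{log2 = TRUE}. Scale-invariant:
#' doubling counts and total leaves RPM unchanged.
#'
#' @param moduleCountSum summed read count over the module's genes.
#' @param total_mapped total mapped reads in the sample (>= 1).
#' @param pseudocount pseudocount inside the log2.
#' @param log2 return log2-transformed value (default TRUE).
#' @return numeric(1).
#' @examples
#' moduleRPM(500, 1e6)  # log2(501) = 8.969
#' @export
moduleRPM <- function(moduleCountSum, total_mapped, pseudocount = 1,
                      log2 = TRUE) {
  if (any(total_mapped < 1)) stop("total_mapped must be >= 1")
  x <- 1e6 * moduleCountSum / total_mapped
  if (log2) base::log2(x + pseudocount) else x
}

#' Module x sample abundance matrix
#'
#' Computes the full module-by-sample abundance matrix from a gene count
#' table, a gene-to-EC assignment and the reference collection, under
#' either normalization:
#' \describe{
#'   \item{\code{"log2_mean_rpkm"}}{log2(mean RPKM over all reference
#'     gene sequences of the module's ECs + pseudocount). Counts are read
#'     per reference sequence (rows of \code{counts} are sequence ids);
#'     reference sequences absent from the count table count as zero.}
#'   \item{\code{"log2_rpm"}}{log2(reads-per-million summed over all
#'     genes assigned to the module's ECs + pseudocount).}
#' }
#'
#' @param counts integer matrix, genes (or reference sequences) x samples.
#' @param total_mapped named numeric vector of per-sample totals.
#' @param ersc an [ERSC-class].
#' @param geneAssignment for \code{"log2_rpm"}: named list EC -> gene ids
#'   ([assignGenesToECs()]); ignored for \code{"log2_mean_rpkm"}, which
#'   uses the ERSC's own sequence index.
#' @param geneLengths named numeric vector of gene lengths in bp
#'   (required for RPKM when rows are genes; defaults to the ERSC
#'   sequence lengths).
#' @param normalization \code{"log2_rpm"} or \code{"log2_mean_rpkm"}.
#' @param pseudocount pseudocount inside the log2 (default 1).
#' @param perECMean for RPKM: average per-EC means instead of pooling all
#'   sequences of the module (default FALSE, pooled).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{"abundance"} (modules x samples) and the normalization
#'   settings in \code{metadata()}.
#' @export
moduleAbundanceMatrix <- function(counts, total_mapped, ersc,
                                  geneAssignment = NULL, geneLengths = NULL,
                                  normalization = c("log2_rpm",
                                                    "log2_mean_rpkm"),
                                  pseudocount = 1, perECMean = FALSE) {
  normalization <- match.arg(normalization)
  samples <- colnames(counts)
  stopifnot(!is.null(samples), all(samples %in% names(total_mapped)))
  total_mapped <- total_mapped[samples]
  mods <- moduleIds(ersc)
  mat <- matrix(NA_real_, nrow = length(mods), ncol = length(samples),
                dimnames = list(mods, samples))
  getCounts <- function(ids) {
    m <- matrix(0, nrow = length(ids), ncol = length(samples),
                dimnames = list(ids, samples))
    present <- intersect(ids, rownames(counts))
    m[present, ] <- counts[present, , drop = FALSE]
    m
  }
  if (normalization == "log2_rpm") {
    if (is.null(geneAssignment))
      geneAssignment <- stats::setNames(
        lapply(unique(ersc@modules$ec),
               function(e) intersect(rownames(counts),
                                     ersc@sequences$seq_id[ersc@sequences$ec == e])),
        unique(ersc@modules$ec))
    for (m in mods) {
      ids <- unique(unlist(geneAssignment[moduleECs(ersc, m)]))
      cs <- if (length(ids)) colSums(getCounts(ids)) else
        stats::setNames(numeric(length(samples)), samples)
      mat[m, ] <- moduleRPM(cs, total_mapped, pseudocount = pseudocount)
    }
  } else {
    seqs <- ersc@sequences
    if (nrow(seqs) == 0) stop("RPKM normalization needs reference sequences")
    if (is.null(geneLengths))
      geneLengths <- stats::setNames(seqs$length_bp, seqs$seq_id)
    for (m in mods) {
      ecs <- moduleECs(ersc, m)
      sub <- seqs[seqs$ec %in% ecs, , drop = FALSE]
      if (nrow(sub) == 0) { mat[m, ] <- NA_real_; next }
      cm <- getCounts(sub$seq_id)
      lens <- geneLengths[sub$seq_id]
      for (s in samples) {
        rv <- rpkm(cm[, s], lens, total_mapped[[s]])
        mat[m, s] <- if (perECMean) {
          log2(mean(tapply(rv, sub$ec, mean)) + pseudocount)
        } else moduleAbundance(rv, pseudocount)
      }
    }
  }
  md <- unique(ersc@modules[, c("module_id", "module_name", "category")])
  md <- md[match(mods, md$module_id), ]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = mat),
    rowData = S4Vectors::DataFrame(md),
    metadata = list(normalization = normalization, pseudocount = pseudocount,
                    per_ec_mean = perECMean, total_mapped = total_mapped))
}

#' Annotation coverage of metabolic modules
#'
#' Fraction of a module's (unique) ECs represented by at least one
#' annotated gene in the database: the gray pie-chart quantity of the
#' pathway overview. Also reported globally over all unique ECs.
#'
#' @param ersc an [ERSC-class].
#' @param geneAssignment named list EC -> gene ids ([assignGenesToECs()]).
#' @return data.frame with one row per module (\code{module_id},
#'   \code{n_ecs}, \code{n_ecs_annotated}, \code{annotation_coverage_pct})
#'   plus attributes \code{"global_pct"} and \code{"n_genes"}.
#' @export
annotationCoverage <- function(ersc, geneAssignment) {
  covered <- names(geneAssignment)[lengths(geneAssignment) > 0]
  rows <- lapply(moduleIds(ersc), function(m) {
    ecs <- moduleECs(ersc, m)
    n <- length(ecs)
    k <- sum(ecs %in% covered)
    data.frame(module_id = m, n_ecs = n, n_ecs_annotated = k,
               annotation_coverage_pct = round(100 * k / n, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  allECs <- unique(ersc@modules$ec)
  attr(out, "global_pct") <- round(100 * mean(allECs %in% covered), 1)
  attr(out, "n_genes") <- length(unique(unlist(geneAssignment)))
  out
}

#' Expression coverage of metabolic modules
#'
#' An EC is \emph{expressed} when any of its genes (or reference
#' sequences) has at least one read in at least one of the selected
#' samples. Reports per-module percentages and the global tally of
#' expressed ECs.
#'
#' @param ersc an [ERSC-class].
#' @param counts integer matrix, genes x samples.
#' @param geneAssignment named list EC -> gene ids.
#' @param samples character vector of sample ids to consider (default
#'   all columns).
#' @return data.frame per module (\code{module_id}, \code{n_ecs},
#'   \code{n_ecs_expressed}, \code{expression_coverage_pct}); attributes
#'   \code{"global_n_expressed"}, \code{"global_n_ecs"},
#'   \code{"global_pct"}.
#' @export
expressionCoverage <- function(ersc, counts, geneAssignment,
                               samples = colnames(counts)) {
  cm <- counts[, samples, drop = FALSE]
  expressedGenes <- rownames(cm)[rowSums(cm) >= 1]
  expressedECs <- names(geneAssignment)[vapply(geneAssignment, function(g)
    any(g %in% expressedGenes), logical(1))]
  rows <- lapply(moduleIds(ersc), function(m) {
    ecs <- moduleECs(ersc, m)
    k <- sum(ecs %in% expressedECs)
    data.frame(module_id = m, n_ecs = length(ecs), n_ecs_expressed = k,
               expression_coverage_pct = round(100 * k / length(ecs), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  allECs <- unique(ersc@modules$ec)
  attr(out, "global_n_expressed") <- sum(allECs %in% expressedECs)
  attr(out, "global_n_ecs") <- length(allECs)
  attr(out, "global_pct") <- round(100 * mean(allECs %in% expressedECs), 1)
  out
}

#' Hierarchical clustering of samples and modules
#'
#' Agglomerative clustering (Euclidean distance, average linkage by
#' default) of the columns (samples) and rows (modules) of an abundance
#' matrix, as used to compare metatranscriptomes across reactors. Leaf
#' order is made deterministic by reordering each dendrogram on label
#' rank, so permuting the input columns leaves the result unchanged.
#'
#' @param x abundance matrix (modules x samples) or the
#'   SummarizedExperiment from [moduleAbundanceMatrix()].
#' @param distance distance measure for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @return list with \code{samples} and \code{modules} (hclust objects),
#'   \code{sample_order}, \code{module_order} (leaf labels) and
#'   \code{heatmap} (the matrix reordered accordingly).
#' @export
clusterSamples <- function(x, distance = "euclidean", linkage = "average") {
  if (is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, "abundance")
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (ncol(x) < 2) stop("need at least 2 samples to cluster")
  clus <- function(m) {
    h <- stats::hclust(stats::dist(m, method = distance), method = linkage)
    stats::as.hclust(stats::reorder(stats::as.dendrogram(h),
                                    rank(rownames(m)), agglo.FUN = mean))
  }
  hs <- clus(t(x))
  hm <- if (nrow(x) >= 2) clus(x) else NULL
  sampleOrder <- hs$labels[hs$order]
  moduleOrder <- if (is.null(hm)) rownames(x) else hm$labels[hm$order]
  list(samples = hs, modules = hm, sample_order = sampleOrder,
       module_order = moduleOrder,
       heatmap = x[moduleOrder, sampleOrder, drop = FALSE])
}

#' Export a dendrogram as Newick
#' @param hc an hclust object (from [clusterSamples()]).
#' @param path output file path.
#' @export
writeDendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Plot the clustered module heatmap
#'
#' Renders the module x sample abundance heatmap with the deterministic
#' dendrograms of [clusterSamples()]. Requires the pheatmap package.
#'
#' @param x matrix or SummarizedExperiment as for [clusterSamples()].
#' @param filename optional output file (png/pdf) passed to pheatmap.
#' @param ... further arguments to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plotModuleHeatmap <- function(x, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plotModuleHeatmap requires the pheatmap package")
  cl <- clusterSamples(x)
  p <- pheatmap::pheatmap(cl$heatmap, cluster_rows = FALSE,
                          cluster_cols = FALSE, filename = filename, ...)
  invisible(p)
}

#' Top expressed transcripts and their GO-term frequencies
#'
#' Ranks transcripts by mean normalized expression (RPKM) over the
#' selected samples, takes the top \code{n} (ties at the cut broken by
#' transcript id for determinism) and tallies GO terms with multiplicity
#' across those transcripts.
#'
#' @param counts integer matrix, transcripts x samples.
#' @param geneLengths named numeric vector of transcript lengths (bp).
#' @param total_mapped named numeric per-sample totals.
#' @param goTerms named list transcript id -> character vector of GO
#'   terms (empty/missing allowed).
#' @param n number of top transcripts (default 500).
#' @param samples sample ids to average over (default all).
#' @return list with \code{ranked} (data.frame \code{transcript_id},
#'   \code{mean_rpkm}) and \code{go_frequencies} (data.frame \code{go},
#'   \code{count}, decreasing); attribute \code{"truncated"} notes when
#'   fewer than \code{n} transcripts were available.
#' @export
topExpressedSummary <- function(counts, geneLengths, total_mapped,
                                goTerms = NULL, n = 500,
                                samples = colnames(counts)) {
  cm <- counts[, samples, drop = FALSE]
  miss <- setdiff(rownames(cm), names(geneLengths))
  if (length(miss)) stop("no length for transcript(s): ",
                         paste(utils::head(miss, 3), collapse = ", "))
  rp <- vapply(samples, function(s)
    rpkm(cm[, s], geneLengths[rownames(cm)], total_mapped[[s]]),
    numeric(nrow(cm)))
  if (is.null(dim(rp))) rp <- matrix(rp, nrow = nrow(cm),
                                     dimnames = list(rownames(cm), samples))
  meanrp <- rowMeans(rp)
  ord <- order(-meanrp, rownames(cm))
  k <- min(n, length(ord))
  ranked <- data.frame(transcript_id = rownames(cm)[ord[seq_len(k)]],
                       mean_rpkm = meanrp[ord[seq_len(k)]],
                       stringsAsFactors = FALSE)
  rownames(ranked) <- NULL
  gos <- character(0)
  if (!is.null(goTerms))
    gos <- unlist(goTerms[ranked$transcript_id], use.names = FALSE)
  gf <- if (length(gos)) {
    tab <- sort(table(gos), decreasing = TRUE)
    data.frame(go = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  } else data.frame(go = character(0), count = integer(0))
  out <- list(ranked = ranked, go_frequencies = gf)
  attr(out, "truncated") <- k < n
  out
}
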