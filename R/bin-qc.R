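#' Bin retention configuration
#'
#' Thresholds for genomic-bin retention: bins are kept when their marker
#' profile completeness is at least \code{minCompletenessPct} percent
#' ("10\% or more") and they are supported by at least
#' \code{minSampleSupport} of the \code{nSamples} metagenomic samples
#' ("at least 2 out of 4"). Contigs shorter than \code{minContigBp} are
#' singletons and discarded upstream.
#'
#' @param minCompletenessPct minimum profile completeness, percent.
#' @param minSampleSupport minimum number of supporting samples.
#' @param nSamples number of metagenomic samples available.
#' @param minContigBp minimum contig length in bp.
#' @return a validated list of class \code{"BinFilterConfig"}.
#' @export
binFilterConfig <- function(minCompletenessPct = 10, minSampleSupport = 2,
                            nSamples = 4, minContigBp = 1000) {
  stopifnot(minCompletenessPct >= 0, minCompletenessPct <= 100,
            minSampleSupport >= 1, minSampleSupport <= nSamples,
            minContigBp >= 1)
  structure(list(minCompletenessPct = minCompletenessPct,
                 minSampleSupport = minSampleSupport,
                 nSamples = nSamples, minContigBp = minContigBp),
            class = "BinFilterConfig")
}

#' Marker-gene profile completeness of a bin
#'
#' Completeness is the percentage of the universal single-copy marker
#' panel detected in the bin: \code{100 * |found| / |panel|}, reported to
#' one decimal (round-half-even). Detection is presence/absence —
#' duplicate marker observations do not inflate the score; duplicate
#' counts are reported separately as a contamination hint.
#'
#' @param found character vector of marker ids detected in the bin
#'   (duplicates allowed, collapsed).
#' @param markers a [MarkerGeneSet-class].
#' @return numeric(1) percent in [0, 100], rounded to 0.1. Attribute
#'   \code{"duplicated_markers"} lists markers observed more than once.
#' @examples
#' ms <- markerGeneSet(paste0("M", 1:137))
#' markerCompleteness(paste0("M", 1:64), ms)  # 46.7
#' @export
markerCompleteness <- function(found, markers) {
  stopifnot(is(markers, "MarkerGeneSet"))
  panel <- markers@marker_ids
  if (length(panel) == 0) stop("empty marker set")
  found <- as.character(found)
  unknown <- setdiff(found, panel)
  if (length(unknown))
    stop("unknown marker id(s): ", paste(unknown, collapse = ", "))
  pct <- round(100 * length(unique(found)) / length(panel), 1)
  attr(pct, "duplicated_markers") <- unique(found[duplicated(found)])
  pct
}

#' Construct a MarkerGeneSet
#' @param marker_ids character vector of distinct marker ids.
#' @return a [MarkerGeneSet-class].
#' @export
markerGeneSet <- function(marker_ids) {
  new("MarkerGeneSet", marker_ids = as.character(marker_ids))
}

#' Read a marker panel (one id per line) or bin marker hits
#' @param path file path. \code{readMarkerSet} expects one marker id per
#'   line; \code{readMarkerHits} a TSV with header
#'   \code{bin_id<TAB>marker_id}.
#' @return a [MarkerGeneSet-class], or a data.frame of hits.
#' @export
readMarkerSet <- function(path) {
  ids <- readLines(path, warn = FALSE)
  markerGeneSet(ids[ids != "" & !startsWith(ids, "#")])
}

#' @rdname readMarkerSet
#' @export
readMarkerHits <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", quote = "")
}

#' Count metagenomic samples supporting a bin
#'
#' A sample supports a bin when at least \code{minFrac} of the bin's
#' contigs receive at least one mapped read from that sample. The
#' retention rule then requires support from a minimum number of samples.
#'
#' @param contigMapped named list: sample id -> character vector of
#'   contig ids with >= 1 mapped read from that sample.
#' @param binContigs character vector of the bin's contig ids (non-empty).
#' @param minFrac fraction of bin contigs a sample must map (default 0.5).
#' @return integer count of supporting samples; attribute
#'   \code{"per_sample"} gives the mapped fraction per sample.
#' @export
sampleSupport <- function(contigMapped, binContigs, minFrac = 0.5) {
  if (length(binContigs) == 0) stop("bin has zero contigs")
  if (anyDuplicated(names(contigMapped)))
    stop("sample ids must be distinct")
  frac <- vapply(contigMapped, function(ct)
    mean(binContigs %in% ct), numeric(1))
  res <- as.integer(sum(frac >= minFrac))
  attr(res, "per_sample") <- frac
  res
}

#' Filter genomic bins by completeness and sample support
#'
#' Retains bins with \code{completeness_pct >= minCompletenessPct} and
#' \code{support >= minSampleSupport}; boundary values are retained
#' ("10\% or more", "at least 2 out of 4"). Rejected bins carry the
#' failed criterion.
#'
#' @param bins data.frame with columns \code{bin_id},
#'   \code{completeness_pct}, \code{support}.
#' @param cfg a [binFilterConfig()].
#' @return list with \code{retained} and \code{rejected} data.frames; the
#'   latter has a \code{reason} column.
#' @export
filterBins <- function(bins, cfg = binFilterConfig()) {
  stopifnot(inherits(cfg, "BinFilterConfig"))
  if (nrow(bins) == 0)
    return(list(retained = bins, rejected = cbind(bins, reason = character(0))))
  passC <- bins$completeness_pct >= cfg$minCompletenessPct
  passS <- bins$support >= cfg$minSampleSupport
  reason <- ifelse(!passC & !passS, "completeness+support",
            ifelse(!passC, "completeness",
            ifelse(!passS, "support", "")))
  rejected <- bins[!(passC & passS), , drop = FALSE]
  rejected$reason <- reason[!(passC & passS)]
  rownames(rejected) <- NULL
  retained <- bins[passC & passS, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, rejected = rejected)
}

#' Discard singleton contigs below the length threshold
#'
#' Contigs smaller than \code{minContigBp} (default 1000 bp) are treated
#' as unsupported singletons and discarded; a contig of exactly the
#' threshold length is kept.
#'
#' @param contigs data.frame with columns \code{contig_id},
#'   \code{length_bp} (or a named numeric vector of lengths).
#' @param cfg a [binFilterConfig()].
#' @return retained contigs in input form; attribute \code{"removed"}
#'   summarises count and total bp removed.
#' @export
contigPrefilter <- function(contigs, cfg = binFilterConfig()) {
  if (is.numeric(contigs))
    contigs <- data.frame(contig_id = names(contigs), length_bp = unname(contigs))
  keep <- contigs$length_bp >= cfg$minContigBp
  out <- contigs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- list(n = sum(!keep),
                               total_bp = sum(contigs$length_bp[!keep]))
  out
}

#' Per-contig sample support
#'
#' Contig-granularity variant of the support rule: counts, for each
#' contig, how many samples map at least one read to it. Useful for
#' removing short contigs not mapped by the required number of samples.
#'
#' @param contigMapped named list: sample id -> contig ids mapped.
#' @param contig_ids contigs to score.
#' @return named integer vector of supporting-sample counts per contig.
#' @export
contigSampleSupport <- function(contigMapped, contig_ids) {
  counts <- integer(length(contig_ids))
  names(counts) <- contig_ids
  for (ct in contigMapped) {
    hit <- contig_ids %in% ct
    counts[hit] <- counts[hit] + 1L
  }
  counts
}
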