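#' Split a contig into fixed-size fragments
#'
#' Contigs are cut into consecutive non-overlapping windows of
#' \code{fragmentBp} (default 1000 bp) before fragment-wise alignment. A
#' terminal remainder shorter than \code{minTailBp} is merged into the
#' previous fragment rather than kept as an uninformatively short query.
#'
#' @param length_bp contig length (>= 1).
#' @param fragmentBp window size in bp.
#' @param minTailBp minimum length for the terminal fragment.
#' @return data.frame with 1-based inclusive \code{start}, \code{end}.
#' @examples
#' fragmentContig(2500)  # [1,1000] [1001,2000] [2001,2500]
#' fragmentContig(2100)  # [1,1000] [1001,2100]  (100 bp tail merged)
#' @export
fragmentContig <- function(length_bp, fragmentBp = 1000, minTailBp = 200) {
  stopifnot(length_bp >= 1, fragmentBp >= minTailBp, minTailBp >= 1)
  if (length_bp <= fragmentBp)
    return(data.frame(start = 1L, end = as.integer(length_bp)))
  nfull <- length_bp %/% fragmentBp
  tail <- length_bp %% fragmentBp
  starts <- seq.int(1L, by = fragmentBp, length.out = nfull)
  ends <- starts + fragmentBp - 1L
  if (tail == 0) {
    # exact multiple
  } else if (tail >= minTailBp) {
    starts <- c(starts, nfull * fragmentBp + 1L)
    ends <- c(ends, length_bp)
  } else {
    ends[nfull] <- length_bp
  }
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' Top-scoring hit of one fragment
#'
#' Picks the hit with maximal bit score; ties are broken by lower
#' e-value, then lexicographically smaller subject id, so repeated runs
#' are deterministic.
#'
#' @param hits hit-record data.frame (rows for a single query fragment).
#' @return one-row data.frame (the winning hit) or \code{NULL} when the
#'   fragment has no hits.
#' @export
topHit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  ord <- order(-hits$bit_score, hits$e_value, hits$subject_id)
  hits[ord[1], , drop = FALSE]
}

#' Fragment-vote taxon scores for a bin
#'
#' Each fragment casts one vote for the taxon of its top-scoring hit; the
#' score of a taxon is its vote count divided by the number of fragments
#' in the bin. Fragments without hits contribute nothing, so scores sum
#' to at most 1.
#'
#' @param topTaxa character vector of per-fragment top-hit taxa
#'   (\code{NA} for fragments without a hit or with unmappable subjects).
#' @param nFragments total number of fragments in the bin (>= 1).
#' @return named numeric vector of scores with attribute
#'   \code{"n_fragments"}; empty when no fragment has a hit.
#' @export
scoreTaxa <- function(topTaxa, nFragments) {
  if (nFragments < 1) stop("bin has zero fragments")
  topTaxa <- topTaxa[!is.na(topTaxa)]
  if (length(topTaxa) == 0) {
    s <- numeric(0)
  } else {
    tab <- table(topTaxa)
    s <- as.numeric(tab) / nFragments
    names(s) <- names(tab)
  }
  attr(s, "n_fragments") <- as.integer(nFragments)
  s
}

#' Assign a bin to a taxonomy node by LCA of top-scoring taxa
#'
#' The top-scoring set contains every taxon whose score is at least
#' \code{topFrac} times the maximum score (and above \code{minScore});
#' the bin is assigned to the lowest common ancestor of that set, a
#' conservative rank reflecting how unanimous the fragment votes are.
#' With \code{topFrac = 1} only strict co-maxima enter the set.
#'
#' @param scores named score vector from [scoreTaxa()].
#' @param tree a [TaxonomyTree-class] containing all scored taxa.
#' @param topFrac relative band defining "top-scoring" (default 0.8).
#' @param minScore absolute score floor (default 0).
#' @return list with \code{node} (node id or \code{NA} if unclassified),
#'   \code{rank}, \code{score_max}, \code{top_set} (character vector).
#' @export
classifyBin <- function(scores, tree, topFrac = 0.8, minScore = 0) {
  if (length(scores) == 0)
    return(list(node = NA_character_, rank = NA_character_,
                score_max = 0, top_set = character(0)))
  smax <- max(scores)
  top <- names(scores)[scores >= topFrac * smax & scores > minScore]
  node <- lca(tree, top)
  list(node = node, rank = rankOf(tree, node), score_max = smax,
       top_set = sort(top))
}

#' Flag hybrid (bacterial/archaeal) bins
#'
#' A bin is a hybrid when its assignment lands at or above the domain
#' level \emph{and} its top-scoring taxa span more than one domain (e.g.
#' both Bacteria and Archaea), so no domain can be chosen. Low estimated
#' completeness (below \code{lowCompleteness} percent) is recorded as the
#' suspected cause when present.
#'
#' @param assignment result of [classifyBin()].
#' @param tree a [TaxonomyTree-class].
#' @param completeness_pct the bin's profile completeness (optional).
#' @param lowCompleteness completeness threshold noted as suspected cause
#'   (default 20).
#' @return logical(1); attribute \code{"suspected_cause"} is
#'   \code{"low_completeness"} when applicable.
#' @export
flagHybrid <- function(assignment, tree, completeness_pct = NA,
                       lowCompleteness = 20) {
  top <- assignment$top_set
  if (length(top) == 0) return(FALSE)  # unclassified, not hybrid
  ranks <- taxRanks()
  atOrAbove <- match(assignment$rank, ranks) <= match("domain", ranks)
  if (is.na(atOrAbove)) atOrAbove <- FALSE
  domains <- unique(stats::na.omit(
    vapply(top, function(t) ancestorAtRank(tree, t, "domain"),
           character(1))))
  res <- isTRUE(atOrAbove) && length(domains) > 1
  if (res && !is.na(completeness_pct) && completeness_pct < lowCompleteness)
    attr(res, "suspected_cause") <- "low_completeness"
  res
}

#' Classify all bins from a hit table
#'
#' End-to-end fragment-vote classification: per-fragment top hits are
#' tallied per bin over all fragments of all its contigs, scored, and
#' resolved to an LCA assignment with a hybrid flag.
#'
#' @param hits hit-record data.frame ([readHits()]); \code{query_id} must
#'   be fragment ids.
#' @param fragments data.frame with columns \code{fragment_id},
#'   \code{bin_id} giving every fragment of every contig of every bin
#'   (including fragments without hits).
#' @param tree a [TaxonomyTree-class].
#' @param completeness optional named vector of completeness percentages
#'   per bin (for the hybrid report).
#' @param topFrac,minScore see [classifyBin()].
#' @return data.frame with one row per bin: \code{bin_id},
#'   \code{assigned_node}, \code{rank}, \code{score_max},
#'   \code{hybrid_flag}.
#' @export
classifyBins <- function(hits, fragments, tree, completeness = NULL,
                         topFrac = 0.8, minScore = 0) {
  stopifnot(all(c("fragment_id", "bin_id") %in% names(fragments)))
  known <- hits$query_id %in% fragments$fragment_id
  if (!all(known))
    stop("hits reference unknown fragment id(s): ",
         paste(utils::head(unique(hits$query_id[!known]), 3), collapse = ", "))
  # one vote per fragment: deterministic top hit
  topPerFrag <- rep(NA_character_, nrow(fragments))
  names(topPerFrag) <- fragments$fragment_id
  if (nrow(hits)) {
    ord <- order(hits$query_id, -hits$bit_score, hits$e_value,
                 hits$subject_id)
    h <- hits[ord, , drop = FALSE]
    first <- !duplicated(h$query_id)
    topPerFrag[h$query_id[first]] <- h$subject_taxon[first]
  }
  binIds <- unique(fragments$bin_id)
  res <- lapply(binIds, function(b) {
    fr <- fragments$fragment_id[fragments$bin_id == b]
    sc <- scoreTaxa(topPerFrag[fr], length(fr))
    asg <- classifyBin(sc, tree, topFrac = topFrac, minScore = minScore)
    comp <- if (!is.null(completeness) && b %in% names(completeness))
      completeness[[b]] else NA
    data.frame(bin_id = b, assigned_node = asg$node, rank = asg$rank,
               score_max = asg$score_max,
               hybrid_flag = flagHybrid(asg, tree, comp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Enumerate fragments for bins of contigs
#'
#' Builds the fragment table [classifyBins()] expects from bin
#' membership and contig lengths, using [fragmentContig()] windows.
#'
#' @param binMembership data.frame with columns \code{bin_id},
#'   \code{contig_id}.
#' @param contigLengths named numeric vector of contig lengths.
#' @param fragmentBp,minTailBp see [fragmentContig()].
#' @return data.frame with \code{fragment_id} (\code{<contig>:<start>-<end>}),
#'   \code{bin_id}, \code{contig_id}, \code{start}, \code{end}.
#' @export
enumerateFragments <- function(binMembership, contigLengths,
                               fragmentBp = 1000, minTailBp = 200) {
  miss <- setdiff(binMembership$contig_id, names(contigLengths))
  if (length(miss)) stop("no length for contig(s): ",
                         paste(utils::head(miss, 3), collapse = ", "))
  res <- lapply(seq_len(nrow(binMembership)), function(i) {
    ct <- binMembership$contig_id[i]
    fr <- fragmentContig(contigLengths[[ct]], fragmentBp, minTailBp)
    data.frame(fragment_id = sprintf("%s:%d-%d", ct, fr$start, fr$end),
               bin_id = binMembership$bin_id[i], contig_id = ct,
               start = fr$start, end = fr$end, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
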