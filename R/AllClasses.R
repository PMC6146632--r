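#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' TaxonomyTree: a rank-annotated rooted taxonomy
#'
#' Stores a taxonomy as a node table (one row per node) with parent
#' pointers. The root is its own parent. Ranks follow the conventional
#' vocabulary \code{root, domain, phylum, class, order, family, genus,
#' species}; other rank labels are preserved verbatim but excluded from
#' rank-level summaries.
#'
#' @slot nodes data.frame with columns \code{node_id}, \code{parent_id},
#'   \code{rank}, \code{name}; row order is not significant.
#' @slot root character(1), the node id of the unique root.
#'
#' @seealso [readTaxonomy()], [lca()], [validateTaxonomy()]
#' @export
setClass("TaxonomyTree",
  representation(nodes = "data.frame", root = "character"))

setValidity("TaxonomyTree", function(object) {
  msgs <- validateTaxonomy(object)$defects
  if (length(msgs) == 0) TRUE else msgs
})

#' MarkerGeneSet: a universal single-copy marker-gene panel
#'
#' Profile completeness of a genomic bin is the percentage of this panel
#' detected in the bin. The canonical panel in this workflow has 137
#' markers; the marker list itself is data and is supplied by the user
#' (or by [simulateMarkerSet()]).
#'
#' @slot marker_ids character vector of distinct marker identifiers.
#' @export
setClass("MarkerGeneSet", representation(marker_ids = "character"))

setValidity("MarkerGeneSet", function(object) {
  ids <- object@marker_ids
  if (length(ids) == 0) return("marker set must be non-empty")
  if (anyDuplicated(ids)) return("marker ids must be distinct")
  TRUE
})

#' ERSC: an EC reference sequence collection
#'
#' A curated mapping of enzyme-commission (EC) numbers to metabolic
#' modules of the anaerobic-digestion pathway, plus reference gene
#' sequences per EC. An EC may belong to several modules (modules may
#' share redundant ECs); duplicates of an EC within one module are
#' collapsed on load. An EC may have zero reference sequences ("no known
#' sequence").
#'
#' @slot modules data.frame with columns \code{ec}, \code{module_id},
#'   \code{module_name}, \code{category}; one row per (module, EC) pair.
#' @slot sequences data.frame with columns \code{seq_id}, \code{ec},
#'   \code{length_bp}, \code{source} (\code{"public-db"} or
#'   \code{"assembly-derived"}); zero rows allowed.
#' @seealso [readERSC()], [nUniqueECs()], [nModules()]
#' @export
setClass("ERSC",
  representation(modules = "data.frame", sequences = "data.frame"))

setValidity("ERSC", function(object) {
  m <- object@modules
  s <- object@sequences
  need <- c("ec", "module_id", "module_name", "category")
  if (!all(need %in% names(m)))
    return(paste("modules table must have columns:", paste(need, collapse = ", ")))
  bad <- m$ec[!vapply(m$ec, isValidEC, logical(1))]
  if (length(bad))
    return(paste("malformed EC code(s):", paste(unique(bad), collapse = ", ")))
  if (anyDuplicated(paste(m$module_id, m$ec)))
    return("duplicate EC within a module (must be collapsed on load)")
  if (nrow(s)) {
    needs <- c("seq_id", "ec", "length_bp", "source")
    if (!all(needs %in% names(s)))
      return(paste("sequences table must have columns:", paste(needs, collapse = ", ")))
    orphan <- setdiff(s$ec, m$ec)
    if (length(orphan))
      return(paste("sequence mapped to EC absent from module table:",
                   paste(orphan, collapse = ", ")))
    if (anyDuplicated(s$seq_id)) return("duplicate reference sequence ids")
  }
  TRUE
})

setMethod("show", "TaxonomyTree", function(object) {
  n <- object@nodes
  cat("TaxonomyTree with", nrow(n), "nodes (root:", object@root, ")\n")
  tab <- table(factor(n$rank, levels = taxRanks()))
  cat(" ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
})

setMethod("show", "MarkerGeneSet", function(object) {
  cat("MarkerGeneSet with", length(object@marker_ids), "markers\n")
})

setMethod("show", "ERSC", function(object) {
  cat("ERSC:", nUniqueECs(object), "unique ECs in", nModules(object),
      "metabolic modules;", nrow(object@sequences), "reference sequences\n")
  nos <- ecsWithoutSequence(object)
  if (length(nos))
    cat(" ", length(nos), "ECs without known sequence\n")
})
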