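#' Canonical taxonomic rank vocabulary
#'
#' Ranks recognised by rank-level summaries, from shallowest to deepest.
#' Unknown rank labels in input files are preserved but excluded from
#' rank-level summaries.
#'
#' @return character vector of rank labels.
#' @export
taxRanks <- function() {
  c("root", "domain", "phylum", "class", "order", "family", "genus", "species")
}

#' Construct a TaxonomyTree from a node table
#'
#' @param nodes data.frame with columns \code{node_id}, \code{parent_id},
#'   \code{rank}, \code{name}. Exactly one node must be its own parent
#'   (the root).
#' @return a [TaxonomyTree-class] object.
#' @export
taxonomyTree <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  need <- c("node_id", "parent_id", "rank", "name")
  if (!all(need %in% names(nodes)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  nodes$node_id <- as.character(nodes$node_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  if (anyDuplicated(nodes$node_id))
    stop("duplicate node ids in taxonomy")
  root <- nodes$node_id[nodes$node_id == nodes$parent_id]
  if (length(root) != 1L)
    stop("taxonomy must have exactly one root (self-parented node), found ",
         length(root))
  new("TaxonomyTree", nodes = nodes, root = root)
}

#' Read a taxonomy from a 4-column TSV
#'
#' Expected header: \code{node_id<TAB>parent_id<TAB>rank<TAB>name}.
#'
#' @param path file path.
#' @return a [TaxonomyTree-class].
#' @export
readTaxonomy <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "#")
  taxonomyTree(tab)
}

#' Write a taxonomy to TSV
#' @param tree a [TaxonomyTree-class].
#' @param path output file path.
#' @export
writeTaxonomy <- function(tree, path) {
  utils::write.table(tree@nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# internal: named parent lookup vector
.parentMap <- function(tree) {
  stats::setNames(tree@nodes$parent_id, tree@nodes$node_id)
}

#' Validate taxonomy invariants
#'
#' Report-based check for the structural invariants of a taxonomy: a
#' single self-parented root, no cycles, no orphan parent pointers, and
#' every node reaching the root by parent traversal.
#'
#' @param tree a [TaxonomyTree-class] (validity is not re-triggered) or a
#'   raw node data.frame.
#' @return list with elements \code{ok} (logical) and \code{defects}
#'   (character vector of human-readable findings, empty when ok).
#' @export
validateTaxonomy <- function(tree) {
  nodes <- if (is(tree, "TaxonomyTree")) tree@nodes else as.data.frame(tree)
  defects <- character(0)
  ids <- as.character(nodes$node_id)
  parents <- as.character(nodes$parent_id)
  if (anyDuplicated(ids))
    defects <- c(defects, paste("duplicate node ids:",
                                paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  roots <- ids[ids == parents]
  if (length(roots) == 0) defects <- c(defects, "no root (self-parented node)")
  if (length(roots) > 1)
    defects <- c(defects, paste("multiple roots:", paste(roots, collapse = ", ")))
  orphan <- setdiff(parents, ids)
  if (length(orphan))
    defects <- c(defects, paste("parent ids not in table:",
                                paste(orphan, collapse = ", ")))
  # cycle / reachability check by iterative parent hops
  if (length(roots) >= 1 && length(orphan) == 0) {
    pm <- stats::setNames(parents, ids)
    for (id in ids) {
      seen <- character(0)
      cur <- id
      repeat {
        if (cur %in% roots) break
        if (cur %in% seen) {
          defects <- c(defects, paste0("cycle involving node ", id))
          break
        }
        seen <- c(seen, cur)
        cur <- pm[[cur]]
      }
    }
  }
  list(ok = length(defects) == 0, defects = unique(defects))
}

#' Ancestor path of a node
#'
#' @param tree a [TaxonomyTree-class].
#' @param node_id character(1) node id.
#' @return character vector of node ids from \code{node_id} up to and
#'   including the root (self first).
#' @export
ancestorPath <- function(tree, node_id) {
  pm <- .parentMap(tree)
  if (!node_id %in% names(pm)) stop("unknown node id: ", node_id)
  path <- node_id
  cur <- node_id
  while (cur != tree@root) {
    cur <- pm[[cur]]
    path <- c(path, cur)
  }
  path
}

#' Rank and name lookups
#' @param tree a [TaxonomyTree-class].
#' @param node_id character vector of node ids.
#' @return character vector of rank labels (or names).
#' @export
rankOf <- function(tree, node_id) {
  idx <- match(node_id, tree@nodes$node_id)
  if (anyNA(idx)) stop("unknown node id: ",
                       paste(node_id[is.na(idx)], collapse = ", "))
  tree@nodes$rank[idx]
}

#' @rdname rankOf
#' @export
nameOf <- function(tree, node_id) {
  idx <- match(node_id, tree@nodes$node_id)
  if (anyNA(idx)) stop("unknown node id: ",
                       paste(node_id[is.na(idx)], collapse = ", "))
  tree@nodes$name[idx]
}

#' Ancestor of a node at a given rank
#'
#' @param tree a [TaxonomyTree-class].
#' @param node_id character(1).
#' @param rank character(1) rank label.
#' @return node id of the ancestor-or-self at \code{rank}, or \code{NA}
#'   if the lineage has no node of that rank.
#' @export
ancestorAtRank <- function(tree, node_id, rank) {
  path <- ancestorPath(tree, node_id)
  hit <- path[rankOf(tree, path) == rank]
  if (length(hit)) hit[1] else NA_character_
}

#' Lowest common ancestor of a taxon set
#'
#' The deepest node that is an ancestor-or-self of every input node: the
#' "closest common ancestor" used to assign a conservative taxonomic
#' level to a genomic bin. Implemented by walking the root-to-node path
#' of the first taxon and keeping the longest prefix shared by all other
#' paths.
#'
#' @param tree a [TaxonomyTree-class].
#' @param node_ids character vector (a set; duplicates ignored) of node
#'   ids, all present in the tree.
#' @return character(1) node id of the LCA.
#' @examples
#' tr <- taxonomyTree(data.frame(
#'   node_id = c("r", "a", "b"), parent_id = c("r", "r", "r"),
#'   rank = c("root", "domain", "domain"), name = c("root", "A", "B")))
#' lca(tr, c("a", "b"))  # "r"
#' @export
lca <- function(tree, node_ids) {
  node_ids <- unique(as.character(node_ids))
  if (length(node_ids) == 0) stop("lca of an empty set is undefined")
  # root-to-node paths; shared prefix is the common-ancestor chain
  paths <- lapply(node_ids, function(id) rev(ancestorPath(tree, id)))
  ref <- paths[[1]]
  k <- length(ref)
  for (p in paths[-1]) {
    m <- min(k, length(p))
    same <- ref[seq_len(m)] == p[seq_len(m)]
    k <- if (all(same)) m else which(!same)[1] - 1L
  }
  ref[k]
}
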