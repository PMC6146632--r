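# Shared fixtures and independent oracles, built in code.

# Small fixed taxonomy: two domains, two bacterial phyla, down to species.
fixedTree <- function() {
  taxonomyTree(data.frame(
    node_id   = c("root", "bac", "arc", "p1", "p2", "pa",
                  "g1", "g2", "ga",
                  "s1a", "s1b", "s2a", "sa1"),
    parent_id = c("root", "root", "root", "bac", "bac", "arc",
                  "p1", "p2", "pa",
                  "g1", "g1", "g2", "ga"),
    rank = c("root", "domain", "domain", "phylum", "phylum", "phylum",
             "genus", "genus", "genus",
             "species", "species", "species", "species"),
    name = c("cellular organisms", "Bacteria", "Archaea", "P1", "P2", "PA",
             "G1", "G2", "GA", "S1a", "S1b", "S2a", "SA1"),
    stringsAsFactors = FALSE))
}

# Random rooted tree with n nodes: node i's parent drawn among nodes < i.
randomTree <- function(n) {
  stopifnot(n >= 1)
  ids <- sprintf("n%03d", seq_len(n))
  parent <- c(ids[1], if (n > 1)
    ids[vapply(2:n, function(i) sample.int(i - 1L, 1), integer(1))])
  taxonomyTree(data.frame(
    node_id = ids, parent_id = parent,
    rank = sample(c(taxRanks(), "strain"), n, replace = TRUE),
    name = paste0("name_", ids), stringsAsFactors = FALSE))
}

# Brute-force LCA oracle: intersect full ancestor sets of all inputs and
# pick the deepest member (ancestor sets built by repeated parent hops).
oracleLCA <- function(tree, ids) {
  pm <- setNames(tree@nodes$parent_id, tree@nodes$node_id)
  anc <- function(id) {
    out <- id
    while (id != tree@root) {
      id <- pm[[id]]
      out <- c(out, id)
    }
    out
  }
  common <- Reduce(intersect, lapply(unique(ids), anc))
  depth <- vapply(common, function(x) length(anc(x)), integer(1))
  common[which.max(depth)]
}

writeTempTSV <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

# Independent oracle: recompute module log2-RPM abundance by naive loops.
oracleModuleRPM <- function(counts, totals, ersc, ga, pseudocount = 1) {
  mods <- moduleIds(ersc)
  out <- matrix(NA_real_, length(mods), ncol(counts),
                dimnames = list(mods, colnames(counts)))
  for (m in mods) {
    gset <- character(0)
    for (e in unique(ersc@modules$ec[ersc@modules$module_id == m]))
      gset <- union(gset, ga[[e]])
    for (s in colnames(counts)) {
      tot <- 0
      for (g in gset) if (g %in% rownames(counts)) tot <- tot + counts[g, s]
      out[m, s] <- log2(1e6 * tot / totals[[s]] + pseudocount)
    }
  }
  out
}

# Minimal valid ERSC module table rows.
erscTable <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(ec = r[1], module_id = r[2], module_name = r[3],
               category = r[4], stringsAsFactors = FALSE)))
}
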