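#' Read a FASTA file
#'
#' Sequences are uppercased on read; duplicate ids are a hard error;
#' non-IUPAC characters trigger a warning but the record is kept.
#'
#' @param path FASTA file path.
#' @return a [Biostrings::BStringSet] (uppercased); empty set for an
#'   empty file.
#' @export
readFasta <- function(path) {
  info <- file.info(path)
  if (is.na(info$size)) stop("no such file: ", path)
  if (info$size == 0) return(Biostrings::BStringSet())
  x <- Biostrings::readBStringSet(path)
  x <- Biostrings::BStringSet(toupper(as.character(x)))
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  iupac <- paste0(names(Biostrings::IUPAC_CODE_MAP), collapse = "")
  bad <- grepl(paste0("[^", iupac, "]"), as.character(x))
  if (any(bad))
    warning(sum(bad), " record(s) contain non-IUPAC characters (kept)")
  x
}

#' Write sequences to FASTA
#' @param records a \code{XStringSet}/\code{BStringSet} (or named
#'   character vector).
#' @param path output path.
#' @export
writeFasta <- function(records, path) {
  if (is.character(records))
    records <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(records, path)
  invisible(path)
}

#' Read gene records from a GFF3 file
#'
#' Parses CDS features into a gene-record table. EC numbers are read from
#' the \code{eC_number} attribute, gene names from \code{gene} (falling
#' back to \code{Name}), GO terms from \code{go_terms} or
#' \code{Ontology_term}. A predicted CDS counts as \emph{annotated} when
#' either a gene name or at least one EC number is known.
#'
#' @param path GFF3 file path (1-based inclusive coordinates).
#' @param featureType feature types to keep (default \code{"CDS"}).
#' @return data.frame with columns \code{gene_id}, \code{contig_id},
#'   \code{start}, \code{end}, \code{strand}, \code{length_bp},
#'   \code{gene_name}, \code{annotated}, and list-columns
#'   \code{ec_codes}, \code{go_terms}.
#' @export
readGFF3 <- function(path, featureType = "CDS") {
  # line-level sanity pass so coordinate errors can name their line
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    if (startsWith(ln, ">")) break  # trailing FASTA section
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) stop("GFF3 line ", i, ": expected 9 columns, got ",
                            length(f))
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || s < 1 || s > e)
      stop("GFF3 line ", i, ": out-of-range coordinates (start=", f[4],
           ", end=", f[5], ")")
  }
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  g <- g[g$type %in% featureType, , drop = FALSE]
  if (nrow(g) == 0)
    return(data.frame(gene_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), length_bp = integer(0),
                      gene_name = character(0), annotated = logical(0),
                      ec_codes = I(list()), go_terms = I(list())))
  getcol <- function(nm) if (nm %in% names(g)) g[[nm]] else rep(NA, nrow(g))
  aslist <- function(x) {
    if (is.list(x)) lapply(x, function(v) as.character(v[!is.na(v)]))
    else lapply(x, function(v) if (is.na(v)) character(0)
                else strsplit(as.character(v), ",", fixed = TRUE)[[1]])
  }
  ids <- as.character(getcol("ID"))
  ids[is.na(ids)] <- paste0("cds_", which(is.na(ids)))
  gname <- as.character(getcol("gene"))
  alt <- as.character(getcol("Name"))
  gname[is.na(gname)] <- alt[is.na(gname)]
  ecs <- aslist(getcol("eC_number"))
  gos <- getcol("go_terms")
  if (all(is.na(unlist(gos)))) gos <- getcol("Ontology_term")
  res <- data.frame(gene_id = ids,
                    contig_id = as.character(g$seqid),
                    start = as.integer(g$start), end = as.integer(g$end),
                    strand = as.character(g$strand),
                    gene_name = gname, stringsAsFactors = FALSE)
  res$length_bp <- res$end - res$start + 1L
  res$ec_codes <- ecs
  res$go_terms <- aslist(gos)
  res$annotated <- !is.na(res$gene_name) | lengths(res$ec_codes) > 0
  rownames(res) <- NULL
  res[, c("gene_id", "contig_id", "start", "end", "strand", "length_bp",
          "gene_name", "annotated", "ec_codes", "go_terms")]
}

.HIT_COLS <- c("query_id", "subject_id", "percent_identity",
               "alignment_length", "mismatches", "gap_opens", "q_start",
               "q_end", "s_start", "s_end", "e_value", "bit_score")

#' Read an alignment hit table (BLAST/DIAMOND tabular, outfmt 6)
#'
#' Parses the canonical 12-column tabular dialect (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore), with
#' an optional 13th \code{staxid} column. Subject taxa may alternatively
#' be supplied via \code{taxonMap}; rows whose subject cannot be mapped
#' are kept with \code{subject_taxon = NA} and counted in a warning.
#'
#' @param path hit table path.
#' @param taxonMap optional named character vector mapping
#'   \code{subject_id} to taxonomy node ids.
#' @return data.frame of typed hit records, including
#'   \code{subject_taxon}; empty for an empty file.
#' @export
readHits <- function(path, taxonMap = NULL) {
  info <- file.info(path)
  if (is.na(info$size)) stop("no such file: ", path)
  if (info$size == 0) {
    out <- data.frame(matrix(nrow = 0, ncol = length(.HIT_COLS)))
    names(out) <- .HIT_COLS
    out$subject_taxon <- character(0)
    return(out)
  }
  raw <- readLines(path, warn = FALSE)
  raw <- raw[raw != "" & !startsWith(raw, "#")]
  fields <- strsplit(raw, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(!(ncols %in% c(12L, 13L)))
  if (length(bad))
    stop("hit table line(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": expected 12 (or 13) columns, got ", ncols[bad[1]])
  m <- do.call(rbind, lapply(fields, function(f) f[1:12]))
  out <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                    stringsAsFactors = FALSE)
  numcols <- list(percent_identity = 3, alignment_length = 4, mismatches = 5,
                  gap_opens = 6, q_start = 7, q_end = 8, s_start = 9,
                  s_end = 10, e_value = 11, bit_score = 12)
  for (nm in names(numcols)) {
    v <- suppressWarnings(as.numeric(m[, numcols[[nm]]]))
    if (anyNA(v))
      stop("hit table line(s) ", paste(which(is.na(v)), collapse = ", "),
           ": non-numeric value in column ", numcols[[nm]])
    out[[nm]] <- v
  }
  intish <- c("alignment_length", "mismatches", "gap_opens", "q_start",
              "q_end", "s_start", "s_end")
  for (nm in intish) out[[nm]] <- as.integer(out[[nm]])
  if (any(out$bit_score < 0) || any(out$e_value < 0) ||
      any(out$percent_identity < 0 | out$percent_identity > 100))
    stop("hit table contains out-of-range scores")
  # subject taxon: explicit 13th column wins, then taxonMap
  tax <- rep(NA_character_, nrow(out))
  has13 <- ncols == 13L
  if (any(has13))
    tax[has13] <- vapply(fields[has13], `[[`, character(1), 13L)
  if (!is.null(taxonMap)) {
    unresolved <- is.na(tax)
    tax[unresolved] <- unname(taxonMap[out$subject_id[unresolved]])
  }
  if (anyNA(tax) && (any(has13) || !is.null(taxonMap)))
    warning(sum(is.na(tax)), " hit(s) with unmappable subject taxon (kept)")
  out$subject_taxon <- tax
  out
}

#' Merge bacterial and archaeal gene annotations
#'
#' Prokaryotic gene callers run separately for Bacteria and Archaea
#' produce overlapping CDS calls on the same contigs. The merge
#' complements the bacterial CDS set with annotated archaeal CDS: every
#' bacterial CDS is kept, except where an \emph{unannotated} bacterial
#' CDS is reciprocally overlapped (same contig, same strand, each by more
#' than \code{overlapFrac} of its length) by an \emph{annotated} archaeal
#' CDS, in which case the archaeal record replaces it. Annotated archaeal
#' CDS overlapping nothing are appended; those overlapping an annotated
#' bacterial CDS are dropped. Unannotated archaeal CDS are never added.
#'
#' @param bacterial,archaeal gene-record data.frames as returned by
#'   [readGFF3()], called on the same contig set.
#' @param overlapFrac reciprocal-overlap fraction defining "same locus"
#'   (default 0.5, i.e. >50\% of each CDS's length).
#' @return merged gene-record data.frame; attribute \code{"merge_report"}
#'   tallies added, replaced and dropped records.
#' @export
mergeAnnotations <- function(bacterial, archaeal, overlapFrac = 0.5) {
  stopifnot(is.data.frame(bacterial), is.data.frame(archaeal))
  if (nrow(archaeal) == 0) return(bacterial)
  archA <- archaeal[archaeal$annotated, , drop = FALSE]
  dropBact <- logical(nrow(bacterial))
  addArch <- logical(nrow(archA))
  if (nrow(archA) && nrow(bacterial)) {
    contigs <- union(bacterial$contig_id, archA$contig_id)
    gb <- GenomicRanges::GRanges(
            factor(bacterial$contig_id, levels = contigs),
            IRanges::IRanges(bacterial$start, bacterial$end),
            strand = bacterial$strand)
    ga <- GenomicRanges::GRanges(
            factor(archA$contig_id, levels = contigs),
            IRanges::IRanges(archA$start, archA$end), strand = archA$strand)
    ov <- GenomicRanges::findOverlaps(ga, gb)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(GenomicRanges::pintersect(ga[qh], gb[sh]))
    recip <- w > overlapFrac * archA$length_bp[qh] &
             w > overlapFrac * bacterial$length_bp[sh]
    qh <- qh[recip]; sh <- sh[recip]
    for (i in seq_len(nrow(archA))) {
      mates <- sh[qh == i]
      if (length(mates) == 0) {
        addArch[i] <- TRUE
      } else if (any(bacterial$annotated[mates])) {
        # annotated bacterial call wins; archaeal duplicate dropped
      } else {
        addArch[i] <- TRUE
        dropBact[mates] <- TRUE
      }
    }
  } else if (nrow(archA)) {
    addArch[] <- TRUE
  }
  out <- rbind(bacterial[!dropBact, , drop = FALSE],
               archA[addArch, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "merge_report") <- list(
    bacterial_kept = sum(!dropBact), bacterial_replaced = sum(dropBact),
    archaeal_added = sum(addArch),
    archaeal_dropped = nrow(archaeal) - sum(addArch))
  out
}

#' Read a gene read-count table plus per-sample totals
#'
#' Counts TSV has header \code{gene_id<TAB><sample>...}; the sidecar
#' totals TSV has header \code{sample_id<TAB>total_mapped}. When no
#' totals file is given, totals are the column sums (mode
#' \code{"equal"}); otherwise totals may exceed column sums (mode
#' \code{"includes_non_gene"}).
#'
#' @param path counts TSV path.
#' @param totalsPath optional totals TSV path.
#' @return list with \code{counts} (integer matrix, genes x samples),
#'   \code{total_mapped} (named numeric) and \code{mode}.
#' @export
readCounts <- function(path, totalsPath = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "")
  if (names(tab)[1] != "gene_id") stop("counts table must start with gene_id")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  storage.mode(m) <- "integer"
  if (any(m < 0, na.rm = TRUE) || anyNA(m))
    stop("counts must be non-negative integers")
  if (is.null(totalsPath)) {
    list(counts = m, total_mapped = colSums(m), mode = "equal")
  } else {
    tot <- utils::read.delim(totalsPath, header = TRUE, sep = "\t", quote = "")
    tm <- stats::setNames(as.numeric(tot$total_mapped), tot$sample_id)
    missing <- setdiff(colnames(m), names(tm))
    if (length(missing)) stop("totals missing for sample(s): ",
                              paste(missing, collapse = ", "))
    tm <- tm[colnames(m)]
    if (any(tm < colSums(m)))
      stop("total_mapped smaller than column sum for some sample")
    list(counts = m, total_mapped = tm, mode = "includes_non_gene")
  }
}

#' Write a counts matrix (and totals) to TSV
#' @param counts integer matrix, genes x samples.
#' @param path counts TSV output path.
#' @param total_mapped optional named totals vector; written to
#'   \code{totalsPath}.
#' @param totalsPath optional totals TSV output path.
#' @export
writeCounts <- function(counts, path, total_mapped = NULL, totalsPath = NULL) {
  tab <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(total_mapped) && !is.null(totalsPath))
    utils::write.table(
      data.frame(sample_id = names(total_mapped), total_mapped = total_mapped),
      totalsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
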