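#' Load an EC reference sequence collection
#'
#' Reads the module definition table (one row per module/EC pair) and,
#' optionally, the reference sequence index: a FASTA of reference genes
#' plus a two-column mapping TSV assigning each sequence id to an EC.
#' Duplicate rows of the same EC within one module are collapsed;
#' duplicates of an EC across different modules are preserved (modules of
#' the anaerobic-digestion pathway may share enzymes).
#'
#' @param moduleTable path to a TSV with header
#'   \code{ec<TAB>module_id<TAB>module_name<TAB>category}.
#' @param sequenceFasta optional path to a nucleotide FASTA of reference
#'   gene sequences.
#' @param sequenceMap optional path to a TSV with header
#'   \code{seq_id<TAB>ec} mapping FASTA ids to EC codes. Required when
#'   \code{sequenceFasta} is given.
#' @param sequenceSource source tag recorded for loaded sequences,
#'   \code{"public-db"} or \code{"assembly-derived"}.
#' @return an [ERSC-class] object. The attribute \code{"load_report"}
#'   lists ECs without any reference sequence.
#' @examples
#' tf <- tempfile(); writeLines(c("ec\tmodule_id\tmodule_name\tcategory",
#'   "1.1.1.1\tM1\tEthanol\tacidogenesis",
#'   "2.8.4.1\tM2\tMethyl-CoM to methane\tmethanogenesis"), tf)
#' ersc <- readERSC(tf)
#' nUniqueECs(ersc)  # 2
#' @export
readERSC <- function(moduleTable, sequenceFasta = NULL, sequenceMap = NULL,
                     sequenceSource = c("public-db", "assembly-derived")) {
  sequenceSource <- match.arg(sequenceSource)
  tab <- utils::read.delim(moduleTable, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "#")
  need <- c("ec", "module_id", "module_name", "category")
  if (!all(need %in% names(tab)))
    stop("module table must have columns: ", paste(need, collapse = ", "))
  ok <- vapply(tab$ec, isValidEC, logical(1))
  if (!all(ok))
    stop("malformed EC code in module table row(s) ",
         paste(which(!ok), collapse = ", "), ": ",
         paste(unique(tab$ec[!ok]), collapse = ", "))
  # collapse duplicates of an EC within one module
  tab <- tab[!duplicated(paste(tab$module_id, tab$ec)), need, drop = FALSE]
  rownames(tab) <- NULL

  seqs <- data.frame(seq_id = character(0), ec = character(0),
                     length_bp = integer(0), source = character(0),
                     stringsAsFactors = FALSE)
  if (!is.null(sequenceFasta)) {
    if (is.null(sequenceMap))
      stop("sequenceMap is required when sequenceFasta is given")
    fa <- readFasta(sequenceFasta)
    map <- utils::read.delim(sequenceMap, header = TRUE, sep = "\t",
                             colClasses = "character", quote = "")
    if (!all(c("seq_id", "ec") %in% names(map)))
      stop("sequence map must have columns seq_id, ec")
    missing <- setdiff(map$seq_id, names(fa))
    if (length(missing))
      stop("sequence ids in map absent from FASTA: ",
           paste(missing, collapse = ", "))
    orphanEC <- setdiff(map$ec, tab$ec)
    if (length(orphanEC))
      stop("sequence mapped to EC absent from module table: ",
           paste(orphanEC, collapse = ", "))
    seqs <- data.frame(seq_id = map$seq_id, ec = map$ec,
                       length_bp = Biostrings::width(fa)[match(map$seq_id, names(fa))],
                       source = sequenceSource, stringsAsFactors = FALSE)
  }
  obj <- new("ERSC", modules = tab, sequences = seqs)
  attr(obj, "load_report") <- list(ecs_without_sequence = ecsWithoutSequence(obj))
  obj
}

#' Write an ERSC module table (and sequence map) back to TSV
#'
#' Inverse of [readERSC()] for the tabular parts; round-trips every
#' module-table field.
#'
#' @param ersc an [ERSC-class].
#' @param moduleTable output path for the module table TSV.
#' @param sequenceMap optional output path for the seq_id/ec mapping.
#' @export
writeERSC <- function(ersc, moduleTable, sequenceMap = NULL) {
  utils::write.table(ersc@modules, moduleTable, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sequenceMap))
    utils::write.table(ersc@sequences[, c("seq_id", "ec")], sequenceMap,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(moduleTable)
}

#' ERSC summary accessors
#'
#' \code{nUniqueECs} counts distinct EC codes across all modules;
#' \code{nModules} counts modules; \code{ecsWithoutSequence} lists EC
#' codes with no reference sequence ("ECs without known sequence");
#' \code{moduleECs} returns the (unique) ECs of one module.
#'
#' @param ersc an [ERSC-class].
#' @return integer counts or character vectors of EC codes.
#' @export
nUniqueECs <- function(ersc) length(unique(ersc@modules$ec))

#' @rdname nUniqueECs
#' @export
nModules <- function(ersc) length(unique(ersc@modules$module_id))

#' @rdname nUniqueECs
#' @export
ecsWithoutSequence <- function(ersc) {
  setdiff(unique(ersc@modules$ec), unique(ersc@sequences$ec))
}

#' @rdname nUniqueECs
#' @param module_id character(1) module identifier.
#' @export
moduleECs <- function(ersc, module_id) {
  unique(ersc@modules$ec[ersc@modules$module_id == module_id])
}

#' @rdname nUniqueECs
#' @export
moduleIds <- function(ersc) unique(ersc@modules$module_id)
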