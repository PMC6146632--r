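#' Validate an EC number
#'
#' An EC code has four dot-separated fields; each is a positive integer or
#' a dash wildcard, and once a dash appears every later field must also be
#' a dash (e.g. \code{"3.4.-.-"} is valid, \code{"3.-.21.-"} is not).
#'
#' @param code character(1) candidate EC code.
#' @return logical(1)
#' @examples
#' isValidEC("2.8.4.1")   # TRUE
#' isValidEC("3.4.-.-")   # TRUE (wildcard)
#' isValidEC("3.-.21.-")  # FALSE
#' @export
isValidEC <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code)) return(FALSE)
  parts <- strsplit(code, ".", fixed = TRUE)[[1]]
  if (length(parts) != 4L) return(FALSE)
  isInt <- grepl("^[0-9]+$", parts) & parts != "0" & !grepl("^0", parts)
  isDash <- parts == "-"
  if (!all(isInt | isDash)) return(FALSE)
  # a dash may only be followed by dashes
  if (any(isDash) && !all(isDash[seq(which(isDash)[1], 4L)])) return(FALSE)
  TRUE
}

#' Match EC codes against a (possibly wildcard) reference EC
#'
#' A wildcard reference such as \code{"3.4.-.-"} matches any fully or
#' partially specified EC sharing its specified prefix, so protease genes
#' annotated \code{"3.4.21.1"} fall under the protease wildcard. A fully
#' specified reference matches only itself.
#'
#' @param codes character vector of EC codes carried by genes.
#' @param ref character(1) reference EC, possibly with trailing dashes.
#' @return logical vector parallel to \code{codes}.
#' @export
ecMatches <- function(codes, ref) {
  stopifnot(isValidEC(ref))
  refp <- strsplit(ref, ".", fixed = TRUE)[[1]]
  spec <- refp != "-"
  vapply(codes, function(code) {
    if (!isValidEC(code)) return(FALSE)
    p <- strsplit(code, ".", fixed = TRUE)[[1]]
    all(p[spec] == refp[spec])
  }, logical(1), USE.NAMES = FALSE)
}
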