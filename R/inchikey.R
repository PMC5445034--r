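#' Extract the first (skeleton) block of an InChIKey
#'
#' The first 14 characters of a standard InChIKey encode the molecular
#' skeleton/connectivity; the remaining blocks carry stereochemistry,
#' protonation and charge.  Collapsing candidates to this block merges
#' enantiomers and diastereomers, which is the structure-identity rule used
#' throughout this package: two candidates with equal first blocks are the
#' same structure.
#'
#' @param inchikey character vector of InChIKeys (e.g.
#'   `"BSYNRYMUTXBXSQ-UHFFFAOYSA-N"`).
#' @return character vector of 14-character key blocks.
#' @examples
#' first_block("BSYNRYMUTXBXSQ-UHFFFAOYSA-N")
#' @export
first_block <- function(inchikey) {
  ik <- as.character(inchikey)
  hy <- regexpr("-", ik, fixed = TRUE)
  bad <- is.na(ik) | hy < 15L
  if (any(bad)) {
    stop("malformed InChIKey (need >= 14 characters before the first hyphen): ",
         paste(sQuote(unique(ik[bad])), collapse = ", "), call. = FALSE)
  }
  substr(ik, 1L, 14L)
}

# TRUE where first_block() would succeed; used for drop-and-log row filtering.
is_parseable_inchikey <- function(inchikey) {
  ik <- as.character(inchikey)
  hy <- regexpr("-", ik, fixed = TRUE)
  !is.na(ik) & hy >= 15L
}
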