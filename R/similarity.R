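#' Configuration for spectral library matching
#'
#' @param precursor_tol_ppm precursor matching window, ppm (default 5).
#' @param fragment_tol fragment matching tolerance (default 0.01 Da).
#' @param fragment_tol_unit `"Da"` or `"ppm"`.
#' @param intensity_power exponent applied to peak intensities before the
#'   cosine (default 0.5, i.e. square-root scaling).
#' @param mz_power exponent applied to peak m/z as a weight (default 0).
#' @param hit_threshold dot-product score a library match must *strictly*
#'   exceed to count as an MS/MS hit (default 400 on the 0-999 scale).
#' @return an object of class `"similarity_config"`.
#' @export
similarity_config <- function(precursor_tol_ppm = 5, fragment_tol = 0.01,
                              fragment_tol_unit = c("Da", "ppm"),
                              intensity_power = 0.5, mz_power = 0,
                              hit_threshold = 400) {
  fragment_tol_unit <- match.arg(fragment_tol_unit)
  stopifnot(precursor_tol_ppm > 0, fragment_tol > 0,
            hit_threshold >= 0, hit_threshold <= 999)
  structure(
    list(precursor_tol_ppm = precursor_tol_ppm,
         fragment_tol = fragment_tol,
         fragment_tol_unit = fragment_tol_unit,
         intensity_power = intensity_power,
         mz_power = mz_power,
         hit_threshold = hit_threshold),
    class = "similarity_config"
  )
}

#' Restrict a spectral library to a query's precursor window
#'
#' Retains library spectra whose precursor m/z lies within `tol_ppm` parts
#' per million of the query precursor (relative to the query) and whose ion
#' mode matches the query's.
#'
#' @param query a [spectrum()].
#' @param library list of [spectrum()] records.
#' @param tol_ppm precursor tolerance in ppm (> 0).
#' @return the retained subset of `library`.
#' @export
precursor_window <- function(query, library, tol_ppm = 5) {
  stopifnot(inherits(query, "spectrum"), tol_ppm > 0)
  keep <- vapply(library, function(l) {
    l$ion_mode == query$ion_mode &&
      abs(l$precursor_mz - query$precursor_mz) / query$precursor_mz * 1e6 <= tol_ppm
  }, logical(1))
  library[keep]
}

# Greedy one-to-one peak pairing: among all (query, library) peak pairs
# within tolerance, repeatedly take the pair with the smallest m/z
# difference whose peaks are both still unassigned.  Returns a 2-column
# index matrix (query row, library row).
match_peaks <- function(q_mz, l_mz, tol, unit = "Da") {
  tol_da <- if (unit == "ppm") tol * 1e-6 * outer(rep(1, length(q_mz)), l_mz)
            else matrix(tol, length(q_mz), length(l_mz))
  d <- abs(outer(q_mz, l_mz, "-"))
  cand <- which(d <= tol_da, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(cbind(q = integer(0), l = integer(0)))
  cand <- cand[order(d[cand]), , drop = FALSE]
  q_used <- rep(FALSE, length(q_mz))
  l_used <- rep(FALSE, length(l_mz))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    qi <- cand[i, 1L]; li <- cand[i, 2L]
    if (!q_used[qi] && !l_used[li]) {
      keep[i] <- TRUE
      q_used[qi] <- TRUE
      l_used[li] <- TRUE
    }
  }
  m <- cand[keep, , drop = FALSE]
  colnames(m) <- c("q", "l")
  m
}

#' Dot-product similarity between two MS/MS spectra (0-999 scale)
#'
#' Peaks are paired greedily one-to-one within the fragment tolerance
#' (closest m/z difference first), each peak is weighted
#' `intensity^intensity_power * mz^mz_power`, and the cosine between the
#' two weight vectors -- unmatched peaks contribute to their own spectrum's
#' norm only -- is scaled to 0-999 and rounded to the nearest integer.  A
#' spectrum scored against itself yields 999; spectra sharing no peaks
#' within tolerance yield 0.  The score is symmetric in its arguments.
#'
#' @param query,library [spectrum()] records (both non-empty).
#' @param config a [similarity_config()].
#' @return integer score in `[0, 999]`.
#' @export
dot_product <- function(query, library, config = similarity_config()) {
  stopifnot(inherits(query, "spectrum"), inherits(library, "spectrum"),
            inherits(config, "similarity_config"))
  wq <- query$peaks[, "intensity"]^config$intensity_power *
        query$peaks[, "mz"]^config$mz_power
  wl <- library$peaks[, "intensity"]^config$intensity_power *
        library$peaks[, "mz"]^config$mz_power
  m <- match_peaks(query$peaks[, "mz"], library$peaks[, "mz"],
                   config$fragment_tol, config$fragment_tol_unit)
  if (nrow(m) == 0L) return(0L)
  num <- sum(wq[m[, "q"]] * wl[m[, "l"]])
  den <- sqrt(sum(wq^2) * sum(wl^2))
  if (den == 0) return(0L)
  as.integer(round(999 * num / den))
}

#' MS/MS-hit flags for a challenge's candidate structures
#'
#' Searches the query spectrum against an annotated reference library
#' restricted to the precursor window, aggregates scores per structure
#' (InChIKey first block) by maximum, and flags every candidate structure
#' whose best library match *strictly* exceeds the hit threshold.  Only the
#' binary flag is propagated downstream; the continuous score is discarded,
#' because query and library spectra typically come from different
#' instruments and collision energies.
#'
#' @param x a [challenge()].
#' @param query the challenge's query [spectrum()].
#' @param library list of [spectrum()] records, each carrying an
#'   `annotation_key_block` (a library without annotations is a
#'   configuration error).
#' @param config a [similarity_config()].
#' @return named integer vector (0/1) over the challenge's deduplicated
#'   candidate key blocks.
#' @export
msms_hit_flags <- function(x, query, library, config = similarity_config()) {
  stopifnot(inherits(x, "challenge"))
  if (length(library) > 0 &&
      all(is.na(vapply(library, `[[`, "", "annotation_key_block")))) {
    config_error("library spectra carry no annotation_key_block; ",
                 "an annotated library is required for MS/MS-hit flags")
  }
  blocks <- id_sorted_ranking(x)
  flags <- stats::setNames(integer(length(blocks)), blocks)
  windowed <- precursor_window(query, library, config$precursor_tol_ppm)
  windowed <- Filter(function(l) !is.na(l$annotation_key_block), windowed)
  if (length(windowed) == 0L) return(flags)
  ann <- vapply(windowed, `[[`, "", "annotation_key_block")
  relevant <- ann %in% blocks
  if (!any(relevant)) return(flags)
  scores <- vapply(windowed[relevant], dot_product, numeric(1),
                   query = query, config = config)
  best <- tapply(scores, ann[relevant], max)
  hit <- names(best)[best > config$hit_threshold]
  flags[hit] <- 1L
  flags
}

#' Search a set of query spectra against a library
#'
#' Convenience wrapper producing one hit table row per (query, windowed
#' library spectrum) pair.
#'
#' @param queries list of [spectrum()] records.
#' @param library list of annotated [spectrum()] records.
#' @param config a [similarity_config()].
#' @return `data.frame` with columns `query_id`, `library_spectrum_id`,
#'   `key_block`, `dot_score`, `flag`.
#' @export
library_search <- function(queries, library, config = similarity_config()) {
  rows <- lapply(queries, function(q) {
    windowed <- precursor_window(q, library, config$precursor_tol_ppm)
    if (length(windowed) == 0L) return(NULL)
    data.frame(
      query_id = q$spectrum_id,
      library_spectrum_id = vapply(windowed, `[[`, "", "spectrum_id"),
      key_block = vapply(windowed, `[[`, "", "annotation_key_block"),
      dot_score = vapply(windowed, dot_product, numeric(1),
                         query = q, config = config),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(query_id = character(0), library_spectrum_id = character(0),
                      key_block = character(0), dot_score = numeric(0))
  }
  out$flag <- as.integer(out$dot_score > config$hit_threshold)
  rownames(out) <- NULL
  out
}
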