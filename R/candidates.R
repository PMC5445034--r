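#' Read a ChemSpider-style candidate list
#'
#' Candidate lists are delimited text files (comma or tab separated) with a
#' header row and at least the columns `chemspider_id` and `inchikey`;
#' `name`, `monoisotopic_mass`, `formula`, `smiles` and `inchi` are carried
#' through when present.  Rows whose InChIKey cannot be parsed (salt forms,
#' isotope or radical conversion artifacts and similar) are dropped, and the
#' number of dropped rows is reported via [message()]; no attempt is made to
#' repair the structure.
#'
#' @param path path to a delimited text file, UTF-8, with a header row.
#' @param dialect `"auto"` (default) sniffs comma vs. tab from the header
#'   line; `"comma"` or `"tab"` force a separator.
#' @return a `data.frame` with one row per retained candidate and an added
#'   `key_block` column (the 14-character InChIKey first block).
#' @seealso [first_block()], [challenge()]
#' @export
read_candidate_list <- function(path, dialect = c("auto", "comma", "tab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) config_error("candidate file not found: ", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) {
    stop("empty candidate file: ", path, call. = FALSE)
  }
  sep <- switch(dialect,
    comma = ",",
    tab   = "\t",
    auto  = if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  )
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          fileEncoding = "UTF-8")
  names(df) <- tolower(names(df))
  for (col in c("chemspider_id", "inchikey")) {
    if (!col %in% names(df)) {
      config_error("candidate file ", path, " lacks mandatory column '", col, "'")
    }
  }
  if (nrow(df) == 0L) stop("candidate file has no data rows: ", path, call. = FALSE)
  ok <- is_parseable_inchikey(df$inchikey)
  if (any(!ok)) {
    message("read_candidate_list: dropped ", sum(!ok),
            " row(s) with unparseable InChIKey from ", basename(path))
    df <- df[ok, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no candidate rows with a parseable InChIKey in: ", path,
                           call. = FALSE)
  df$chemspider_id <- as.integer(df$chemspider_id)
  if ("monoisotopic_mass" %in% names(df)) {
    df$monoisotopic_mass <- as.numeric(df$monoisotopic_mass)
  }
  df$key_block <- first_block(df$inchikey)
  rownames(df) <- NULL
  df
}

#' Construct a challenge (one query spectrum plus its candidate list)
#'
#' A challenge couples one measured MS/MS spectrum with the set of database
#' structures falling inside the precursor-mass search window, among which
#' the true structure must be ranked.  The true structure, when known
#' (training/validation use), is identified by its InChIKey first block.
#'
#' @param challenge_id text label for the challenge.
#' @param candidates a `data.frame` as returned by [read_candidate_list()];
#'   a `key_block` column is derived from `inchikey` when absent.
#' @param ion_mode `"positive"` (`[M+H]+`) or `"negative"` (`[M-H]-`).
#' @param precursor_mz precursor m/z in Da (optional, `NA` allowed).
#' @param truth_key_block 14-character InChIKey first block of the true
#'   structure, or a full InChIKey (first block is extracted), or `NULL`
#'   for blind use.  A truth absent from the candidate list marks the
#'   challenge unsolvable (see [challenge_solvable()]); by default such
#'   challenges still count as misses in every accuracy denominator.
#' @return an object of class `"challenge"`.
#' @export
challenge <- function(challenge_id, candidates,
                      ion_mode = c("positive", "negative"),
                      precursor_mz = NA_real_, truth_key_block = NULL) {
  ion_mode <- match.arg(ion_mode)
  stopifnot(is.character(challenge_id), length(challenge_id) == 1L)
  if (!is.data.frame(candidates) || nrow(candidates) == 0L) {
    stop("challenge ", challenge_id, ": candidates must be a non-empty data.frame",
         call. = FALSE)
  }
  if (!"key_block" %in% names(candidates)) {
    if (!"inchikey" %in% names(candidates)) {
      config_error("candidates need a 'key_block' or 'inchikey' column")
    }
    candidates$key_block <- first_block(candidates$inchikey)
  }
  if (!"chemspider_id" %in% names(candidates)) {
    config_error("candidates need a 'chemspider_id' column")
  }
  if (anyDuplicated(candidates$chemspider_id)) {
    stop("challenge ", challenge_id, ": duplicate chemspider_id in candidate list",
         call. = FALSE)
  }
  if ("monoisotopic_mass" %in% names(candidates) &&
      any(!is.na(candidates$monoisotopic_mass) & candidates$monoisotopic_mass <= 0)) {
    stop("challenge ", challenge_id, ": monoisotopic_mass must be > 0", call. = FALSE)
  }
  if (!is.null(truth_key_block)) {
    truth_key_block <- if (grepl("-", truth_key_block, fixed = TRUE)) {
      first_block(truth_key_block)
    } else {
      if (nchar(truth_key_block) != 14L) {
        stop("truth_key_block must be 14 characters (or a full InChIKey)",
             call. = FALSE)
      }
      truth_key_block
    }
  }
  structure(
    list(challenge_id = challenge_id,
         ion_mode = ion_mode,
         precursor_mz = precursor_mz,
         candidates = candidates,
         truth_key_block = truth_key_block),
    class = "challenge"
  )
}

#' @export
print.challenge <- function(x, ...) {
  cat("<challenge>", x$challenge_id, "\n",
      " ion mode: ", x$ion_mode,
      "  precursor m/z: ", format(x$precursor_mz), "\n",
      " candidates: ", nrow(x$candidates),
      " (", length(unique(x$candidates$key_block)), " unique structures)\n",
      sep = "")
  if (!is.null(x$truth_key_block)) {
    cat(" truth: ", x$truth_key_block,
        if (challenge_solvable(x)) " (present in candidate list)"
        else " (ABSENT from candidate list - unsolvable)", "\n", sep = "")
  }
  invisible(x)
}

#' Is the true structure present in the candidate list?
#'
#' @param x a [challenge()] with a known truth.
#' @return `TRUE` when the truth key block occurs among the candidates.
#' @export
challenge_solvable <- function(x) {
  stopifnot(inherits(x, "challenge"))
  if (is.null(x$truth_key_block)) {
    stop("challenge ", x$challenge_id, " has no truth_key_block", call. = FALSE)
  }
  x$truth_key_block %in% x$candidates$key_block
}

#' Baseline ranking by ChemSpider entry number
#'
#' Database entry numbers grow with date of entry, so low-numbered entries
#' tend to be older, better-studied compounds; ranking candidates by
#' ascending ID is therefore a surprisingly strong non-fragmentation
#' baseline.  Candidates sharing a key block (stereoisomers) collapse to a
#' single entry keeping the lowest ID.
#'
#' @param x a [challenge()].
#' @return character vector of deduplicated key blocks; position is the
#'   1-based rank (rank 1 is best).
#' @export
id_sorted_ranking <- function(x) {
  stopifnot(inherits(x, "challenge"))
  ord <- order(x$candidates$chemspider_id)
  blocks <- x$candidates$key_block[ord]
  blocks[!duplicated(blocks)]
}

#' Baseline ranking by uniform random permutation
#'
#' @param x a [challenge()].
#' @param seed integer seed; the same seed always yields the same
#'   permutation, and the caller's RNG state is left untouched.
#' @return character vector of deduplicated key blocks in random order.
#' @export
randomize_ranking <- function(x, seed) {
  blocks <- id_sorted_ranking(x)
  if (length(blocks) == 1L) return(blocks)
  withr::with_seed(as.integer(seed), sample(blocks))
}
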