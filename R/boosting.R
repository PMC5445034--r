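#' Database-membership table
#'
#' Maps structures (InChIKey first blocks) to the set of compound databases
#' that contain them, e.g. the 13 metabolomics databases behind the local
#' structure lookup (BMDB, ChEBI, DrugBank, ECMDB, FooDB, HMDB, KNApSAcK,
#' PlantCyc, SMPDB, T3DB, UNPD, YMDB and STOFF-IDENT).  Lookups for unknown
#' key blocks return the empty set.
#'
#' @param memberships `data.frame` with columns `key_block` and
#'   `database_name` (long format, one row per membership).
#' @param vocabulary optional character vector restricting the allowed
#'   database names; names outside it are an error.
#' @return an object of class `"db_table"`.
#' @export
db_table <- function(memberships, vocabulary = NULL) {
  stopifnot(is.data.frame(memberships),
            all(c("key_block", "database_name") %in% names(memberships)))
  if (!is.null(vocabulary)) {
    unknown <- setdiff(unique(memberships$database_name), vocabulary)
    if (length(unknown) > 0) {
      config_error("database name(s) outside the declared vocabulary: ",
                   paste(sQuote(unknown), collapse = ", "))
    }
  }
  sets <- lapply(split(memberships$database_name, memberships$key_block), unique)
  structure(list(sets = sets, vocabulary = vocabulary), class = "db_table")
}

#' @export
print.db_table <- function(x, ...) {
  cat("<db_table> ", length(x$sets), " structures across ",
      length(unique(unlist(x$sets))), " databases\n", sep = "")
  invisible(x)
}

#' Look up the databases containing a structure
#'
#' @param table a [db_table()].
#' @param key_block structure key block(s).
#' @return for a single key block, a character vector (possibly empty); for
#'   several, a list of such vectors.
#' @export
db_lookup <- function(table, key_block) {
  stopifnot(inherits(table, "db_table"))
  res <- lapply(key_block, function(kb) table$sets[[kb]] %||% character(0))
  if (length(key_block) == 1L) res[[1L]] else res
}

#' Database-presence and STOFF-IDENT flags for a structure
#'
#' `db_presence` is 1 iff the structure occurs in at least one database;
#' `stoff_ident` is 1 iff it occurs in the environmentally-relevant
#' STOFF-IDENT database.  Both flags can be 1 simultaneously, in which case
#' the structure collects both boost terms (1 + 2 with default factors).
#'
#' @param key_block structure key block (vectorized).
#' @param table a [db_table()].
#' @param stoff_name database name treated as the emphasized environmental
#'   database (default `"STOFF-IDENT"`).
#' @return `data.frame` with columns `key_block`, `db_presence`,
#'   `stoff_ident` (0/1 integers).
#' @export
db_flags <- function(key_block, table, stoff_name = "STOFF-IDENT") {
  sets <- lapply(key_block, function(kb) table$sets[[kb]] %||% character(0))
  data.frame(
    key_block = key_block,
    db_presence = as.integer(lengths(sets) > 0),
    stoff_ident = as.integer(vapply(sets, function(s) stoff_name %in% s,
                                    logical(1))),
    stringsAsFactors = FALSE
  )
}

#' Final boosted score of a candidate structure
#'
#' `final_score = 1/consensus_rank + db * db_presence + stoff * stoff_ident
#' + msms * msms_hit`, with default boost factors (db, stoff, msms) =
#' (1, 2, 4).  The in-silico consensus contribution enters as the
#' reciprocal rank, so the integer boost terms dominate while candidates
#' with equal flags always order by their consensus rank -- the better
#' in-silico solution keeps priority.  Higher final score means better
#' boosted rank.  With the default factors the score lies in (0, 8] and
#' attains 8 only at consensus rank 1 with all three flags set.
#'
#' @param consensus_rank 1-based consensus rank (vectorized).
#' @param db_presence,stoff_ident,msms_hit 0/1 flags (vectorized).
#' @param factors named numeric vector of boost factors `c(db=, stoff=,
#'   msms=)`; tune them to the compound classes under study (e.g. boost
#'   biochemical databases when annotating endogenous metabolites).
#' @return numeric final score(s).
#' @export
final_score <- function(consensus_rank, db_presence = 0, stoff_ident = 0,
                        msms_hit = 0, factors = c(db = 1, stoff = 2, msms = 4)) {
  stopifnot(all(consensus_rank >= 1),
            all(db_presence %in% 0:1), all(stoff_ident %in% 0:1),
            all(msms_hit %in% 0:1),
            all(c("db", "stoff", "msms") %in% names(factors)))
  1 / consensus_rank +
    factors[["db"]] * db_presence +
    factors[["stoff"]] * stoff_ident +
    factors[["msms"]] * msms_hit
}

#' Re-rank a consensus ordering with database and MS/MS boosting
#'
#' Computes each candidate's [final_score()] from its consensus rank, its
#' database flags and its MS/MS-hit flag, then sorts by final score
#' descending.  Equal final scores are broken by consensus rank ascending
#' (an explicit guard; redundant under the default reciprocal-rank term but
#' kept for non-default boost factors), then lexicographically by key
#' block.
#'
#' @param consensus_ranking character vector of key blocks, best first
#'   (e.g. from [consensus_rank()] or a single tool / baseline).
#' @param table a [db_table()], or `NULL` for no database boosting.
#' @param msms_flags named 0/1 vector (key block -> MS/MS-hit flag), e.g.
#'   from [msms_hit_flags()]; missing entries count as 0.  `NULL` disables
#'   MS/MS boosting.
#' @param factors boost factors, see [final_score()].
#' @param stoff_name see [db_flags()].
#' @return `data.frame` with one row per candidate, columns `key_block`,
#'   `consensus_rank`, `db_presence`, `stoff_ident`, `msms_hit`,
#'   `final_score`, `boosted_rank`, ordered by `boosted_rank`.
#' @export
boosted_rank <- function(consensus_ranking, table = NULL, msms_flags = NULL,
                         factors = c(db = 1, stoff = 2, msms = 4),
                         stoff_name = "STOFF-IDENT") {
  stopifnot(is.character(consensus_ranking), length(consensus_ranking) > 0,
            !anyDuplicated(consensus_ranking))
  n <- length(consensus_ranking)
  if (is.null(table)) {
    fl <- data.frame(key_block = consensus_ranking,
                     db_presence = 0L, stoff_ident = 0L,
                     stringsAsFactors = FALSE)
  } else {
    fl <- db_flags(consensus_ranking, table, stoff_name = stoff_name)
  }
  msms <- integer(n)
  if (!is.null(msms_flags)) {
    hit <- match(consensus_ranking, names(msms_flags))
    msms <- ifelse(is.na(hit), 0L, as.integer(msms_flags[hit]))
  }
  rec <- data.frame(
    key_block = consensus_ranking,
    consensus_rank = seq_len(n),
    db_presence = fl$db_presence,
    stoff_ident = fl$stoff_ident,
    msms_hit = msms,
    stringsAsFactors = FALSE
  )
  rec$final_score <- final_score(rec$consensus_rank, rec$db_presence,
                                 rec$stoff_ident, rec$msms_hit, factors)
  ord <- order(-rec$final_score, rec$consensus_rank, rec$key_block)
  rec <- rec[ord, , drop = FALSE]
  rec$boosted_rank <- seq_len(n)
  rownames(rec) <- NULL
  rec
}
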