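#' Top-k identification counts for one ranking method
#'
#' For each k, counts the challenges whose true structure sits at rank <= k
#' in the method's ranking.  A truth absent from a ranking (tool failure,
#' truth missing from the candidate list) is a miss at every k.  Challenges
#' present in `truths` but absent from `rankings` are an error by default;
#' with `allow_missing = TRUE` they are excluded from the row's denominator
#' and logged.
#'
#' @param rankings named list: challenge_id -> character vector of key
#'   blocks, best first.
#' @param truths named character vector: challenge_id -> truth key block.
#' @param ks top-k thresholds (default 1, 5, 10, 20).
#' @param method_label label for the output row.
#' @param allow_missing exclude (rather than error on) challenges the
#'   method did not rank.
#' @return one-row `data.frame`: `method_label`, one `top<k>` count column
#'   per k, `n_challenges`.
#' @export
topk_counts <- function(rankings, truths, ks = c(1, 5, 10, 20),
                        method_label = "method", allow_missing = FALSE) {
  stopifnot(!is.null(names(truths)), length(truths) > 0)
  missing <- setdiff(names(truths), names(rankings))
  if (length(missing) > 0) {
    if (!allow_missing) {
      stop("no ranking for challenge(s): ",
           paste(sQuote(missing), collapse = ", "), call. = FALSE)
    }
    message("topk_counts [", method_label, "]: excluding ", length(missing),
            " unranked challenge(s)")
    truths <- truths[setdiff(names(truths), missing)]
  }
  truth_rank <- vapply(names(truths), function(cid) {
    match(truths[[cid]], rankings[[cid]])
  }, integer(1))
  row <- data.frame(method_label = method_label, stringsAsFactors = FALSE)
  for (k in ks) {
    row[[paste0("top", k)]] <- sum(!is.na(truth_rank) & truth_rank <= k)
  }
  row$n_challenges <- length(truths)
  row
}

#' Integer percentage of an identification count
#'
#' @param count numerator count (vectorized).
#' @param n_total denominator (> 0).
#' @param mode `"round"` (nearest integer, default) or `"floor"`.
#' @return integer percent, `100 * count / n_total`.
#' @examples
#' percent(290, 312)  # 93
#' @export
percent <- function(count, n_total, mode = c("round", "floor")) {
  mode <- match.arg(mode)
  stopifnot(length(n_total) == 1L, n_total > 0)
  p <- 100 * count / n_total
  as.integer(if (mode == "round") round(p) else floor(p))
}

#' Non-fragmentation baseline rankings for a challenge set
#'
#' Builds the ID-sorted and Randomize baseline rankers in the same
#' structure as real tool rankings, so they can enter consensus models and
#' sweeps on equal footing.  The Randomize permutation of challenge i uses
#' `seed + i`, making the whole baseline reproducible from one seed.
#'
#' @param challenges named list of [challenge()]s.
#' @param seed integer base seed for the Randomize baseline.
#' @param which subset of `c("ID_sorted", "Randomize")` to build.
#' @return named list: baseline name -> named list challenge_id -> ranking.
#' @export
baseline_rankings <- function(challenges, seed = 1,
                              which = c("ID_sorted", "Randomize")) {
  which <- match.arg(which, several.ok = TRUE)
  out <- list()
  if ("ID_sorted" %in% which) {
    out$ID_sorted <- lapply(challenges, id_sorted_ranking)
  }
  if ("Randomize" %in% which) {
    out$Randomize <- stats::setNames(
      lapply(seq_along(challenges), function(i) {
        randomize_ranking(challenges[[i]], seed = seed + i)
      }),
      names(challenges))
  }
  out
}

#' Sweep tool/boost combinations and report top-k accuracy per combination
#'
#' Evaluates every requested combination of rankers and boost modes on one
#' challenge set: a single-member combination uses that ranker's own
#' ranking; multi-member combinations are aggregated with the two-level
#' voting/consensus model; the resulting ranking is optionally re-ranked by
#' database boosting (`"db"`) or database plus MS/MS-hit boosting
#' (`"db_msms"`).  Rows are sorted by top-1 count descending, then label.
#'
#' @param challenges named list of [challenge()]s with truths set.
#' @param rankings_by_tool named list: ranker name -> named list
#'   challenge_id -> ranking.  Include baseline rankers (see
#'   [baseline_rankings()]) under their own names if combinations use them.
#' @param weights a [calibrate()] result covering every ranker that appears
#'   in a multi-member combination.
#' @param combos `data.frame` with columns `label`, `tools`
#'   (`;`-separated ranker names) and `boost` (`"none"`, `"db"` or
#'   `"db_msms"`); see [default_combinations()].
#' @param db_table a [db_table()] (required for boosted combinations).
#' @param msms_flags named list: challenge_id -> named 0/1 vector of
#'   MS/MS-hit flags (required for `"db_msms"` combinations).
#' @param k sensitivity column used by the consensus secondary score.
#' @param factors boost factors, see [final_score()].
#' @param allow_missing passed to [topk_counts()].
#' @return `data.frame` with one [topk_counts()] row per combination plus
#'   integer percent columns (`pct_top<k>`, nearest-integer convention).
#' @export
combination_sweep <- function(challenges, rankings_by_tool, weights, combos,
                              db_table = NULL, msms_flags = NULL, k = 10,
                              factors = c(db = 1, stoff = 2, msms = 4),
                              allow_missing = FALSE) {
  stopifnot(is.data.frame(combos),
            all(c("label", "tools", "boost") %in% names(combos)))
  if (nrow(combos) == 0L) {
    return(data.frame(method_label = character(0), top1 = integer(0),
                      top5 = integer(0), top10 = integer(0), top20 = integer(0),
                      n_challenges = integer(0)))
  }
  truths <- vapply(challenges, function(ch) {
    if (is.null(ch$truth_key_block)) {
      stop("challenge ", ch$challenge_id, " has no truth; sweeps need truths",
           call. = FALSE)
    }
    ch$truth_key_block
  }, character(1))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    members <- strsplit(combos$tools[i], ";", fixed = TRUE)[[1L]]
    members <- trimws(members)
    unknown <- setdiff(members, names(rankings_by_tool))
    if (length(unknown) > 0) {
      stop("combination ", sQuote(combos$label[i]),
           " references unavailable ranker(s): ",
           paste(sQuote(unknown), collapse = ", "), call. = FALSE)
    }
    base <- if (length(members) == 1L) {
      rankings_by_tool[[members]]
    } else {
      consensus_rank_all(challenges, rankings_by_tool[members], weights, k = k)
    }
    boost <- combos$boost[i]
    ranked <- switch(boost,
      none = base,
      db = {
        if (is.null(db_table)) config_error("combination ", sQuote(combos$label[i]),
                                            " needs a db_table")
        lapply(base, function(r) boosted_rank(r, db_table, NULL,
                                              factors = factors)$key_block)
      },
      db_msms = {
        if (is.null(db_table) || is.null(msms_flags)) {
          config_error("combination ", sQuote(combos$label[i]),
                       " needs db_table and msms_flags")
        }
        stats::setNames(lapply(names(base), function(cid) {
          boosted_rank(base[[cid]], db_table, msms_flags[[cid]],
                       factors = factors)$key_block
        }), names(base))
      },
      stop("unknown boost mode ", sQuote(boost), call. = FALSE)
    )
    topk_counts(ranked, truths, method_label = combos$label[i],
                allow_missing = allow_missing)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$top1, out$method_label), , drop = FALSE]
  kcols <- grep("^top", names(out), value = TRUE)
  for (kc in kcols) {
    out[[paste0("pct_", kc)]] <- mapply(percent, out[[kc]], out$n_challenges)
  }
  rownames(out) <- NULL
  out
}
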