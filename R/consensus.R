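#' One tool's ranked candidate list for one challenge
#'
#' @param tool_name text name of the ranking tool.
#' @param challenge_id challenge the ranking belongs to.
#' @param ranking character vector of candidate key blocks, best first
#'   (1-based ranks implied by position); no duplicates.
#' @return an object of class `"tool_ranking"`.
#' @export
tool_ranking <- function(tool_name, challenge_id, ranking) {
  stopifnot(is.character(ranking), length(ranking) > 0)
  if (anyDuplicated(ranking)) {
    stop("tool ", tool_name, ", challenge ", challenge_id,
         ": duplicate key_block in ranking", call. = FALSE)
  }
  structure(list(tool_name = tool_name, challenge_id = challenge_id,
                 ranking = ranking),
            class = "tool_ranking")
}

#' Per-tool sensitivity from top-k assignment counts
#'
#' The sensitivity of a ranking tool is the fraction of training challenges
#' in which it placed the true structure within the top k:
#' `omega = correct / (correct + false)`.  Every challenge has exactly one
#' true structure, so the denominator is simply the number of challenges.
#'
#' @param n_correct_at_k number of challenges with the truth at rank <= k.
#' @param n_total total number of challenges scored.
#' @return sensitivity in `[0, 1]`.
#' @examples
#' compute_sensitivity(171, 312)  # 0.548...
#' @export
compute_sensitivity <- function(n_correct_at_k, n_total) {
  if (length(n_total) != 1L || is.na(n_total) || n_total <= 0) {
    stop("undefined calibration: n_total must be a positive count", call. = FALSE)
  }
  if (any(n_correct_at_k < 0) || any(n_correct_at_k > n_total)) {
    stop("n_correct_at_k must lie in [0, n_total]", call. = FALSE)
  }
  n_correct_at_k / n_total
}

#' Calibrate sensitivity weights on a training set
#'
#' Computes each tool's sensitivity omega at k in `ks` over a training set
#' with known true structures.  A challenge for which a tool produced no
#' ranking, or whose truth the tool did not rank, counts as a miss at every
#' k.  The k used downstream by the secondary consensus score defaults
#' to 10 (experts typically inspect a tool's top-10 candidates); `k_use`
#' must have a strictly positive omega for every tool since the secondary
#' score divides by it.
#'
#' @param rankings_by_tool named list: tool name -> named list of
#'   challenge_id -> character vector of key blocks (best first).
#' @param truths named character vector: challenge_id -> truth key block.
#' @param ks top-k thresholds at which to calibrate.
#' @param k_use the k whose omega the consensus will divide by.
#' @param label free-text label for the training set (provenance).
#' @return a `data.frame` of class `"sensitivity_weights"` with columns
#'   `tool_name`, `k`, `omega`, and attributes `k_use` and `calibrated_on`.
#' @export
calibrate <- function(rankings_by_tool, truths, ks = c(1, 5, 10, 20),
                      k_use = 10, label = "training") {
  stopifnot(length(truths) > 0, !is.null(names(truths)),
            k_use %in% ks)
  if (length(rankings_by_tool) == 0L || is.null(names(rankings_by_tool))) {
    stop("rankings_by_tool must be a non-empty named list", call. = FALSE)
  }
  rows <- lapply(names(rankings_by_tool), function(tool) {
    rl <- rankings_by_tool[[tool]]
    if (length(rl) == 0L) {
      stop("tool ", sQuote(tool), " supplied zero rankings", call. = FALSE)
    }
    truth_rank <- vapply(names(truths), function(cid) {
      r <- rl[[cid]]
      if (is.null(r)) NA_integer_ else match(truths[[cid]], r)
    }, integer(1))
    data.frame(
      tool_name = tool,
      k = ks,
      omega = vapply(ks, function(k) {
        compute_sensitivity(sum(!is.na(truth_rank) & truth_rank <= k),
                            length(truths))
      }, numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  w <- do.call(rbind, rows)
  bad <- w$tool_name[w$k == k_use & w$omega == 0]
  if (length(bad) > 0) {
    stop("omega is 0 at k = ", k_use, " for tool(s) ",
         paste(sQuote(bad), collapse = ", "),
         "; choose a larger k_use or drop the tool (the secondary score ",
         "divides by omega)", call. = FALSE)
  }
  structure(w,
            class = c("sensitivity_weights", "data.frame"),
            k_use = k_use,
            calibrated_on = list(label = label, n = length(truths)))
}

#' Look up a tool's sensitivity at a given k
#'
#' @param weights a [calibrate()] result (or equivalent data.frame).
#' @param tool tool name.
#' @param k top-k threshold.
#' @return omega, a scalar in `[0, 1]`.
#' @export
get_omega <- function(weights, tool, k) {
  i <- which(weights$tool_name == tool & weights$k == k)
  if (length(i) != 1L) {
    stop("no calibrated omega for tool ", sQuote(tool), " at k = ", k,
         call. = FALSE)
  }
  weights$omega[i]
}

# normalize consensus input: accept a named list of character vectors or a
# list of tool_ranking objects; enforce a single challenge_id where known
normalize_rankings <- function(rankings, challenge_id = NULL) {
  if (length(rankings) == 0L) stop("at least one tool ranking required", call. = FALSE)
  if (all(vapply(rankings, inherits, logical(1), "tool_ranking"))) {
    cids <- unique(vapply(rankings, `[[`, "", "challenge_id"))
    if (length(cids) > 1L ||
        (!is.null(challenge_id) && !identical(cids, challenge_id))) {
      stop("tool rankings refer to inconsistent challenge_ids: ",
           paste(sQuote(unique(c(cids, challenge_id))), collapse = ", "),
           call. = FALSE)
    }
    rankings <- stats::setNames(lapply(rankings, `[[`, "ranking"),
                                vapply(rankings, `[[`, "", "tool_name"))
  }
  if (is.null(names(rankings)) || any(!nzchar(names(rankings)))) {
    stop("rankings must be named by tool", call. = FALSE)
  }
  lapply(rankings, as.character)
}

#' Primary consensus score: the tool vote count
#'
#' The number of supplied tools whose ranking contains the candidate
#' structure at all.  With four tools the score is 4 when every tool found
#' the candidate and 0 when none did.
#'
#' @param key_block candidate structure (InChIKey first block).
#' @param rankings named list of per-tool rankings for one challenge
#'   (character vectors, best first), or a list of [tool_ranking()]s.
#' @return integer vote count in `0..length(rankings)`.
#' @export
primary_score <- function(key_block, rankings) {
  rankings <- normalize_rankings(rankings)
  sum(vapply(rankings, function(r) key_block %in% r, logical(1)))
}

#' Secondary consensus score: the sensitivity-weighted rank sum
#'
#' `S = sum over voting tools A of rank_A / omega_A(k)`: each tool that
#' ranked the candidate contributes its 1-based rank divided by that tool's
#' calibrated sensitivity at `k`.  Lower S is better.  Tools that did not
#' rank the candidate contribute nothing; a candidate ranked by no tool has
#' no S (`NA`) and is ordered by the primary tier alone.
#'
#' @inheritParams primary_score
#' @param weights a [calibrate()] result covering every tool in `rankings`.
#' @param k which calibrated top-k sensitivity to divide by (default 10).
#' @return S (>= 0), or `NA_real_` when no tool ranked the candidate.
#' @export
secondary_score <- function(key_block, rankings, weights, k = 10) {
  rankings <- normalize_rankings(rankings)
  ranks <- vapply(rankings, function(r) match(key_block, r), integer(1))
  voted <- !is.na(ranks)
  if (!any(voted)) return(NA_real_)
  omegas <- vapply(names(rankings)[voted], get_omega, numeric(1),
                   weights = weights, k = k)
  if (any(omegas == 0)) {
    stop("omega is 0 at k = ", k, " for a voting tool; recalibrate with a ",
         "larger k", call. = FALSE)
  }
  sum(ranks[voted] / omegas)
}

#' Two-level voting/consensus ranking of a challenge's candidates
#'
#' Aggregates several tools' rankings into one: candidates are sorted by
#' the primary vote count (descending), then by the sensitivity-weighted
#' rank sum S (ascending), with a final lexicographic key-block tie-break
#' for reproducibility.  Candidates that no tool ranked are appended after
#' all voted candidates in ID-sorted order, so the output is a total
#' ranking of the challenge's deduplicated structures.
#'
#' @param x a [challenge()].
#' @param rankings named list of per-tool rankings for this challenge, or a
#'   list of [tool_ranking()]s (whose challenge_ids must agree with `x`).
#' @param weights a [calibrate()] result.
#' @param k sensitivity column used by the secondary score (default 10).
#' @return character vector of key blocks, best first (1-based contiguous
#'   ranks by position).
#' @export
consensus_rank <- function(x, rankings, weights, k = 10) {
  stopifnot(inherits(x, "challenge"))
  rankings <- normalize_rankings(rankings, challenge_id = x$challenge_id)
  blocks <- id_sorted_ranking(x)
  known <- unlist(rankings, use.names = FALSE)
  if (!all(known %in% blocks)) {
    stop("challenge ", x$challenge_id, ": tool rankings contain key blocks ",
         "absent from the candidate list", call. = FALSE)
  }
  vmat <- vapply(rankings, function(r) blocks %in% r, logical(length(blocks)))
  votes <- rowSums(matrix(vmat, nrow = length(blocks)))
  omegas <- vapply(names(rankings), get_omega, numeric(1),
                   weights = weights, k = k)
  contrib <- vapply(seq_along(rankings), function(j) {
    pos <- match(blocks, rankings[[j]])
    pos / omegas[j]
  }, numeric(length(blocks)))
  contrib <- matrix(contrib, nrow = length(blocks))
  s <- rowSums(contrib, na.rm = TRUE)
  voted <- which(votes > 0)
  unvoted <- which(votes == 0)  # already in id_sorted order
  ord <- voted[order(-votes[voted], s[voted], blocks[voted])]
  blocks[c(ord, unvoted)]
}

#' Consensus rankings for a whole challenge set
#'
#' @param challenges named list of [challenge()]s (names = challenge ids).
#' @param rankings_by_tool named list: tool -> named list of challenge_id
#'   -> ranking.  Tools may lack individual challenges; each challenge is
#'   aggregated over the tools that processed it.
#' @param weights a [calibrate()] result.
#' @param k sensitivity column for the secondary score.
#' @return named list: challenge_id -> consensus ranking.
#' @export
consensus_rank_all <- function(challenges, rankings_by_tool, weights, k = 10) {
  stats::setNames(lapply(names(challenges), function(cid) {
    per_tool <- lapply(rankings_by_tool, `[[`, cid)
    per_tool <- Filter(Negate(is.null), per_tool)
    if (length(per_tool) == 0L) {
      stop("no tool ranked challenge ", sQuote(cid), call. = FALSE)
    }
    consensus_rank(challenges[[cid]], per_tool, weights, k = k)
  }), names(challenges))
}
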