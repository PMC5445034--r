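# Independent brute-force oracles.  These transcribe the two consensus
# formulas and the weighted-cosine definition directly, with plain loops
# and no shared code with the implementation they check.

# score every candidate from the printed formulas, then sort
oracle_consensus <- function(ch, rankings, weights, k = 10) {
  ord <- order(ch$candidates$chemspider_id)
  blocks <- unique(ch$candidates$key_block[ord])
  prim <- numeric(length(blocks))
  sec <- numeric(length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[i]
    s <- 0
    votes <- 0
    for (tool in names(rankings)) {
      r <- rankings[[tool]]
      pos <- which(r == b)
      if (length(pos) == 1) {
        votes <- votes + 1
        omega <- weights$omega[weights$tool_name == tool & weights$k == k]
        s <- s + pos / omega
      }
    }
    prim[i] <- votes
    sec[i] <- s
  }
  voted <- which(prim > 0)
  unvoted <- which(prim == 0)
  voted <- voted[order(-prim[voted], sec[voted], blocks[voted])]
  blocks[c(voted, unvoted)]
}

# weighted cosine for spectra whose peaks either coincide exactly in m/z or
# lie farther apart than the tolerance (pairing is then unambiguous)
oracle_cosine_score <- function(q_peaks, l_peaks, intensity_power = 0.5,
                                mz_power = 0) {
  all_mz <- sort(unique(c(q_peaks[, 1], l_peaks[, 1])))
  qv <- numeric(length(all_mz))
  lv <- numeric(length(all_mz))
  for (i in seq_along(all_mz)) {
    qi <- which(q_peaks[, 1] == all_mz[i])
    li <- which(l_peaks[, 1] == all_mz[i])
    if (length(qi) == 1) {
      qv[i] <- q_peaks[qi, 2]^intensity_power * q_peaks[qi, 1]^mz_power
    }
    if (length(li) == 1) {
      lv[i] <- l_peaks[li, 2]^intensity_power * l_peaks[li, 1]^mz_power
    }
  }
  round(999 * sum(qv * lv) / sqrt(sum(qv^2) * sum(lv^2)))
}

# random small consensus instance for property tests
random_consensus_instance <- function(n_cand, n_tools) {
  blocks <- vapply(seq_len(n_cand), function(i) {
    paste(sample(LETTERS, 14, replace = TRUE), collapse = "")
  }, character(1))
  ch <- make_challenge(blocks, ids = sample.int(10000, n_cand))
  rankings <- lapply(seq_len(n_tools), function(t) {
    m <- sample.int(n_cand, 1)
    sample(blocks, m)
  })
  names(rankings) <- paste0("tool", seq_len(n_tools))
  w <- flat_weights(names(rankings))
  w$omega <- round(stats::runif(nrow(w), 0.2, 0.9), 3)  # per-tool, per-k
  list(challenge = ch, rankings = rankings, weights = w)
}
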