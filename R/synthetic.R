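#' Performance profile of a simulated ranking tool
#'
#' Controls where a simulated in silico fragmentation tool places the true
#' structure: rank 1 with probability `p_top1`, otherwise uniformly within
#' ranks 2..10 with probability `p_top10`, otherwise uniformly below rank
#' 10.  `coverage` is the probability that the tool ranks any given
#' candidate at all (real tools skip structures they cannot fragment).
#'
#' @param tool_name text name.
#' @param p_top1 probability the truth lands at rank 1.
#' @param p_top10 probability the truth lands within ranks 2..10 (given not
#'   rank 1); `p_top1 + p_top10 <= 1`.
#' @param coverage probability each candidate appears in the tool's output
#'   (default 1).
#' @return an object of class `"tool_profile"`.
#' @export
tool_profile <- function(tool_name, p_top1, p_top10, coverage = 1) {
  stopifnot(p_top1 >= 0, p_top10 >= 0, p_top1 + p_top10 <= 1,
            coverage >= 0, coverage <= 1)
  structure(list(tool_name = tool_name, p_top1 = p_top1, p_top10 = p_top10,
                 coverage = coverage),
            class = "tool_profile")
}

# unique synthetic key blocks: 14 uppercase letters each
random_key_blocks <- function(n) {
  repeat {
    kb <- vapply(seq_len(n), function(i) {
      paste(sample(LETTERS, 14, replace = TRUE), collapse = "")
    }, character(1))
    if (!anyDuplicated(kb)) return(kb)
  }
}

#' Generate synthetic annotation challenges
#'
#' Each challenge gets one true structure plus a drawn number of mass-
#' matched decoys: synthetic 14-letter key blocks (collision-free within
#' the dataset), ChemSpider-like integer IDs, and monoisotopic masses
#' within +/- 5 ppm of the neutral mass implied by a drawn precursor --
#' mimicking the +/- 5 ppm candidate retrieval window of real contests,
#' where list sizes ranged from a single candidate to several thousand.
#'
#' @param n_challenges number of challenges.
#' @param n_decoys_range integer range `c(lo, hi)` for the decoy count per
#'   challenge; `c(0, 0)` yields single-candidate challenges.
#' @param seed integer seed; the dataset is a pure function of the
#'   parameters and the seed.
#' @param mass_range precursor m/z range to draw from (Da).
#' @return named list of [challenge()]s with `truth_key_block` set.
#' @export
generate_challenges <- function(n_challenges, n_decoys_range = c(5, 50),
                                seed = 1, mass_range = c(100, 800)) {
  stopifnot(n_challenges >= 1, length(n_decoys_range) == 2L,
            n_decoys_range[1] >= 0, n_decoys_range[2] >= n_decoys_range[1])
  proton <- 1.007276
  withr::with_seed(as.integer(seed), {
    dec_choices <- seq(n_decoys_range[1], n_decoys_range[2])
    sizes <- if (length(dec_choices) == 1L) rep(dec_choices, n_challenges)
             else sample(dec_choices, n_challenges, replace = TRUE)
    sizes <- sizes + 1L
    all_blocks <- random_key_blocks(sum(sizes))
    all_ids <- sample.int(5e7, sum(sizes))
    offset <- 0L
    out <- vector("list", n_challenges)
    for (i in seq_len(n_challenges)) {
      n <- sizes[i]
      blocks <- all_blocks[offset + seq_len(n)]
      ids <- all_ids[offset + seq_len(n)]
      offset <- offset + n
      mode <- sample(c("positive", "negative"), 1L)
      pre <- stats::runif(1, mass_range[1], mass_range[2])
      neutral <- if (mode == "positive") pre - proton else pre + proton
      mass <- neutral * (1 + stats::runif(n, -5e-6, 5e-6))
      cand <- data.frame(
        chemspider_id = ids,
        name = paste0("compound_", ids),
        monoisotopic_mass = mass,
        formula = "C10H12N2O4",
        smiles = "CC(C)C",
        inchi = paste0("InChI=1S/synthetic/", blocks),
        inchikey = paste0(blocks, "-UHFFFAOYSA-N"),
        key_block = blocks,
        stringsAsFactors = FALSE
      )
      # shuffle rows so the truth is not systematically the lowest ID
      cand <- cand[sample.int(n), , drop = FALSE]
      rownames(cand) <- NULL
      cid <- sprintf("chal_%04d", i)
      out[[i]] <- challenge(cid, cand, ion_mode = mode, precursor_mz = pre,
                            truth_key_block = blocks[1L])
    }
    stats::setNames(out, vapply(out, `[[`, "", "challenge_id"))
  })
}

# Draw the random variates steering one tool's ranking of one challenge:
# u drives the truth-placement band, v/w the position within band, and
# perm_seed the decoy shuffle.  Sharing a variate set across tools (the
# correlation knob) makes them fail on the same challenges.
draw_placement_variates <- function() {
  list(u = stats::runif(1), v = stats::runif(1), w = stats::runif(1),
       perm_seed = sample.int(.Machine$integer.max - 1L, 1L))
}

# Rank one challenge's candidates given a profile and a variate set.
place_ranking <- function(ch, profile, variates) {
  blocks <- id_sorted_ranking(ch)
  truth <- ch$truth_key_block
  keep <- stats::runif(length(blocks)) < profile$coverage
  kept <- blocks[keep]
  if (length(kept) == 0L) kept <- sample(blocks, 1L)  # never emit nothing
  decoys <- setdiff(kept, truth)
  if (length(decoys) > 1L) {
    decoys <- withr::with_seed(variates$perm_seed, sample(decoys))
  }
  if (is.null(truth) || !truth %in% kept) return(decoys)
  m <- length(decoys) + 1L
  pos <- if (variates$u < profile$p_top1 || m == 1L) {
    1L
  } else if (variates$u < profile$p_top1 + profile$p_top10) {
    2L + floor(variates$v * (min(10L, m) - 1L))
  } else if (m > 10L) {
    11L + floor(variates$w * (m - 10L))
  } else {
    m  # no ranks below 10 exist; park the truth at the bottom
  }
  append(decoys, truth, after = as.integer(pos) - 1L)
}

#' Simulate one tool's rankings over a challenge set
#'
#' Applies a [tool_profile()] to every challenge: each candidate is kept
#' with probability `coverage`; if the truth is kept, it is placed at rank
#' 1 with `p_top1`, else uniformly within ranks 2..min(10, n) with
#' `p_top10`, else uniformly below rank 10; kept decoys fill the remaining
#' ranks in random order.
#'
#' @param challenges named list of [challenge()]s.
#' @param profile a [tool_profile()].
#' @param seed integer seed.
#' @param shared optional list (one element per challenge, `NULL` entries
#'   allowed) of shared placement variates, used by [simulate_tools()] to
#'   induce correlated errors across tools; leave `NULL` for an
#'   independent tool.
#' @return named list: challenge_id -> character vector of key blocks.
#' @export
simulate_tool <- function(challenges, profile, seed = 1, shared = NULL) {
  stopifnot(inherits(profile, "tool_profile"))
  withr::with_seed(as.integer(seed), {
    stats::setNames(lapply(seq_along(challenges), function(i) {
      v <- draw_placement_variates()  # always consume the tool's own stream
      if (!is.null(shared) && !is.null(shared[[i]])) v <- shared[[i]]
      place_ranking(challenges[[i]], profile, v)
    }), names(challenges))
  })
}

#' Simulate a panel of tools with optionally correlated errors
#'
#' Tool i draws from its own RNG stream (`seed + i`), so errors are
#' conditionally independent across tools by default.  With `correlation`
#' > 0, each tool reuses a shared per-challenge variate set (one common
#' draw steering the truth-placement band and the decoy shuffle) with that
#' probability, inducing shared mistakes -- real in silico tools fail on
#' the same sparse spectra -- while leaving every tool's marginal top-k
#' placement probabilities unchanged.
#'
#' @param challenges named list of [challenge()]s.
#' @param profiles list of [tool_profile()]s.
#' @param seed base seed.
#' @param correlation probability in `[0, 1]` that a tool uses the shared
#'   variates on a given challenge (0 = independent tools).
#' @return named list: tool name -> rankings (as [simulate_tool()]).
#' @export
simulate_tools <- function(challenges, profiles, seed = 1, correlation = 0) {
  stopifnot(correlation >= 0, correlation <= 1)
  shared_all <- if (correlation > 0) {
    withr::with_seed(as.integer(seed) + 499979L, {
      lapply(seq_along(challenges), function(i) draw_placement_variates())
    })
  } else NULL
  stats::setNames(
    lapply(seq_along(profiles), function(i) {
      shared_i <- NULL
      if (correlation > 0) {
        use <- withr::with_seed(as.integer(seed) + 900000L + i,
                                stats::runif(length(challenges)) < correlation)
        shared_i <- vector("list", length(challenges))
        shared_i[use] <- shared_all[use]
      }
      simulate_tool(challenges, profiles[[i]], seed = seed + i,
                    shared = shared_i)
    }),
    vapply(profiles, `[[`, "", "tool_name"))
}

#' Generate a query/library spectrum pair with controlled peak overlap
#'
#' Draws a library spectrum annotated with `key_block` and a query sharing
#' `overlap_fraction` of its peaks (intensities jittered by a lognormal
#' factor of spread `noise`); the query's remaining peaks sit on an m/z
#' grid offset from the library grid so they can never match within the
#' default fragment tolerance.  The expected dot product grows
#' monotonically with the overlap fraction; overlap 1 with zero noise
#' reproduces the library spectrum (score 999) and overlap 0 scores 0.
#'
#' @param key_block annotation for the library spectrum.
#' @param overlap_fraction fraction of shared peaks in `[0, 1]`.
#' @param n_peaks peaks per spectrum (default 20).
#' @param noise lognormal sd of the intensity jitter on shared peaks
#'   (0 = identical intensities).
#' @param seed integer seed.
#' @return list with elements `query` and `library` ([spectrum()]s sharing
#'   one precursor m/z and ion mode).
#' @export
generate_spectrum_pair <- function(key_block, overlap_fraction, n_peaks = 20,
                                   noise = 0, seed = 1) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1, n_peaks >= 1)
  withr::with_seed(as.integer(seed), {
    grid <- seq(50, 500, by = 0.2)
    pre <- stats::runif(1, 200, 800)
    lib_mz <- sort(sample(grid, n_peaks))
    lib_int <- stats::runif(n_peaks, 10, 100)
    n_shared <- round(overlap_fraction * n_peaks)
    shared <- if (n_shared > 0) sort(sample.int(n_peaks, n_shared)) else integer(0)
    extra_n <- n_peaks - n_shared
    # grid + 0.07 keeps unshared query peaks >= 0.07 Da from any library peak
    extra_mz <- if (extra_n > 0) sample(grid + 0.07, extra_n) else numeric(0)
    q_mz <- c(lib_mz[shared], extra_mz)
    q_int <- c(lib_int[shared] * exp(stats::rnorm(n_shared, 0, noise)),
               stats::runif(extra_n, 10, 100))
    list(
      query = spectrum(paste0("query_", key_block), pre,
                       cbind(q_mz, q_int)),
      library = spectrum(paste0("lib_", key_block), pre,
                         cbind(lib_mz, lib_int),
                         annotation_key_block = key_block)
    )
  })
}

#' Generate a complete synthetic benchmark dataset
#'
#' Bundles everything the downstream modules consume: challenges with
#' truths, per-tool rankings, a database-membership table and per-challenge
#' MS/MS-hit flags, plus (optionally) a small annotated spectral library
#' with matching query spectra.  Database membership and MS/MS hits are
#' drawn truthfully by default: true structures carry flags with high
#' probability and decoys with low probability, emulating well-curated
#' metadata for known-unknown compounds.
#'
#' @param n_challenges number of challenges.
#' @param profiles list of [tool_profile()]s.
#' @param seed master seed; every component derives from it.
#' @param n_decoys_range decoy count range per challenge.
#' @param truth_db_prob,decoy_db_prob probability a truth/decoy structure
#'   is a member of at least one compound database.
#' @param truth_stoff_prob,decoy_stoff_prob probability of STOFF-IDENT
#'   membership given database membership.
#' @param truth_msms_prob,decoy_msms_prob probability of an MS/MS library
#'   hit (dot score above the gate) for truths/decoys.
#' @param with_spectra also generate query/library [spectrum()] pairs for
#'   the challenges flagged as MS/MS truth hits (slower; off by default).
#' @return list with elements `challenges`, `rankings_by_tool`, `truths`,
#'   `db_table`, `msms_flags`, optionally `queries` and `library`, and
#'   `seed`.
#' @export
generate_dataset <- function(n_challenges, profiles, seed = 1,
                             n_decoys_range = c(5, 50),
                             truth_db_prob = 0.9, decoy_db_prob = 0.25,
                             truth_stoff_prob = 0.5, decoy_stoff_prob = 0.1,
                             truth_msms_prob = 0.85, decoy_msms_prob = 0.02,
                             with_spectra = FALSE) {
  challenges <- generate_challenges(n_challenges, n_decoys_range, seed = seed)
  rankings_by_tool <- simulate_tools(challenges, profiles, seed = seed)
  truths <- vapply(challenges, `[[`, "", "truth_key_block")
  dbs <- c("BMDB", "ChEBI", "DrugBank", "ECMDB", "FooDB", "HMDB", "KNApSAcK",
           "PlantCyc", "SMPDB", "T3DB", "UNPD", "YMDB", "STOFF-IDENT")
  withr::with_seed(as.integer(seed) + 104729L, {
    rows <- list()
    msms_flags <- list()
    for (cid in names(challenges)) {
      ch <- challenges[[cid]]
      blocks <- id_sorted_ranking(ch)
      is_truth <- blocks == ch$truth_key_block
      p_db <- ifelse(is_truth, truth_db_prob, decoy_db_prob)
      p_st <- ifelse(is_truth, truth_stoff_prob, decoy_stoff_prob)
      p_ms <- ifelse(is_truth, truth_msms_prob, decoy_msms_prob)
      member <- stats::runif(length(blocks)) < p_db
      stoff <- member & (stats::runif(length(blocks)) < p_st)
      if (any(member)) {
        plain <- setdiff(dbs, "STOFF-IDENT")
        rows[[cid]] <- data.frame(
          key_block = c(blocks[member],
                        blocks[stoff]),
          database_name = c(sample(plain, sum(member), replace = TRUE),
                            rep("STOFF-IDENT", sum(stoff))),
          stringsAsFactors = FALSE
        )
      }
      msms_flags[[cid]] <- stats::setNames(
        as.integer(stats::runif(length(blocks)) < p_ms), blocks)
    }
    membership <- do.call(rbind, rows)
    if (is.null(membership)) {
      membership <- data.frame(key_block = character(0),
                               database_name = character(0))
    }
    out <- list(challenges = challenges,
                rankings_by_tool = rankings_by_tool,
                truths = truths,
                db_table = db_table(membership, vocabulary = dbs),
                msms_flags = msms_flags,
                seed = seed)
  })
  if (with_spectra) {
    pairs <- lapply(seq_along(challenges), function(i) {
      ch <- challenges[[i]]
      hit <- out$msms_flags[[ch$challenge_id]][ch$truth_key_block] == 1L
      generate_spectrum_pair(ch$truth_key_block,
                             overlap_fraction = if (hit) 0.9 else 0.1,
                             noise = 0.1, seed = seed + 7919L + i)
    })
    out$queries <- stats::setNames(lapply(pairs, `[[`, "query"),
                                   names(challenges))
    out$library <- lapply(pairs, `[[`, "library")
  }
  out
}
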