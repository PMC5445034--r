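test_that("compute_sensitivity is the correct/total fraction", {
  # the best single tool placed 171 of 312 training truths in its top 10
  expect_equal(round(compute_sensitivity(171, 312), 3), 0.548)
  expect_identical(compute_sensitivity(0, 312), 0)
  expect_identical(compute_sensitivity(312, 312), 1)
  expect_error(compute_sensitivity(5, 0), "undefined calibration")
  expect_error(compute_sensitivity(-1, 10), "\\[0, n_total\\]")
  expect_error(compute_sensitivity(11, 10), "\\[0, n_total\\]")
})

test_that("calibrate recovers a generated tool's top-k placement rates", {
  p1 <- 0.5
  ch <- generate_challenges(1000, c(20, 40), seed = 8)
  truths <- vapply(ch, `[[`, "", "truth_key_block")
  rk <- list(synth = simulate_tool(ch, tool_profile("synth", p1, 0.3), seed = 8))
  w <- calibrate(rk, truths)
  # 99% binomial CI around the generator's parameter
  ci <- qnorm(0.995) * sqrt(p1 * (1 - p1) / 1000)
  expect_lt(abs(get_omega(w, "synth", 1) - p1), ci)
  # nested events: omega monotone non-decreasing in k
  om <- vapply(c(1, 5, 10, 20), get_omega, numeric(1), weights = w, tool = "synth")
  expect_true(all(diff(om) >= 0))
})

test_that("a perfect tool calibrates to omega = 1 at every k", {
  ch <- generate_challenges(50, c(3, 10), seed = 2)
  truths <- vapply(ch, `[[`, "", "truth_key_block")
  rk <- list(perfect = simulate_tool(ch, tool_profile("perfect", 1, 0), seed = 2))
  w <- calibrate(rk, truths)
  expect_equal(w$omega, rep(1, 4))
})

test_that("calibrate rejects empty tools and zero sensitivity at k_use", {
  ch <- generate_challenges(20, c(3, 5), seed = 3)
  truths <- vapply(ch, `[[`, "", "truth_key_block")
  expect_error(calibrate(list(empty = list()), truths), "zero rankings")
  # a tool that never ranks the truth: omega(k) = 0 for all k
  hopeless <- lapply(ch, function(c1) setdiff(id_sorted_ranking(c1),
                                              c1$truth_key_block))
  expect_error(calibrate(list(bad = hopeless), truths), "omega is 0")
})

test_that("primary and secondary scores follow the printed formulas", {
  rankings <- list(t1 = c(kb("A"), kb("B")), t2 = c(kb("B"), kb("A")),
                   t3 = kb("B"), t4 = c(kb("A"), kb("C")))
  expect_equal(primary_score(kb("A"), rankings), 3)
  expect_equal(primary_score(kb("B"), rankings), 3)
  expect_equal(primary_score(kb("Z"), rankings), 0)
  expect_equal(primary_score(kb("C"), rankings[1:3]), 0)
  expect_equal(primary_score(kb("C"), rankings), 1)

  # S = rank / omega summed over voting tools only
  w <- flat_weights("t1", omega = 0.548)
  expect_equal(secondary_score(kb("B"), list(t1 = c(kb("A"), kb("X"), kb("B"))), w),
               3 / 0.548)
  w2 <- flat_weights(c("t1", "t2"))
  w2$omega <- ifelse(w2$tool_name == "t1", 0.5, 0.25)
  expect_equal(secondary_score(kb("A"), list(t1 = kb("A"), t2 = kb("A")), w2),
               1 / 0.5 + 1 / 0.25)
  # no-vote sentinel
  expect_true(is.na(secondary_score(kb("Z"), rankings[1:2],
                                    flat_weights(c("t1", "t2")))))
})

test_that("consensus_rank reproduces the worked three-candidate instance", {
  ch <- make_challenge(c(kb("X"), kb("Y"), kb("Z")), ids = c(3, 1, 2))
  rankings <- list(A = c(kb("X"), kb("Y"), kb("Z")), B = c(kb("Y"), kb("X")))
  w <- flat_weights(c("A", "B"), omega = 0.5)
  # votes: X=2 (S=6), Y=2 (S=6), Z=1; X before Y on the lexicographic tie
  expect_equal(consensus_rank(ch, rankings, w), c(kb("X"), kb("Y"), kb("Z")))
})

test_that("consensus with one tool preserves that tool's order", {
  withr::local_seed(21)
  for (i in 1:10) {
    inst <- random_consensus_instance(n_cand = sample(2:6, 1), n_tools = 1)
    out <- consensus_rank(inst$challenge, inst$rankings, inst$weights)
    r <- inst$rankings[[1]]
    expect_identical(out[seq_along(r)], r)
  }
})

test_that("identical tools reproduce the shared order", {
  ch <- make_challenge(c(kb("A"), kb("B"), kb("C"), kb("D")))
  shared <- c(kb("C"), kb("A"), kb("D"), kb("B"))
  rankings <- list(t1 = shared, t2 = shared, t3 = shared)
  expect_identical(consensus_rank(ch, rankings, flat_weights(names(rankings))),
                   shared)
})

test_that("consensus_rank agrees with the brute-force oracle", {
  withr::local_seed(99)
  for (i in 1:500) {
    inst <- random_consensus_instance(n_cand = sample(2:6, 1),
                                      n_tools = sample(1:4, 1))
    expect_identical(
      consensus_rank(inst$challenge, inst$rankings, inst$weights),
      oracle_consensus(inst$challenge, inst$rankings, inst$weights))
  }
})

test_that("consensus is invariant to the order tools are supplied in", {
  withr::local_seed(7)
  for (i in 1:50) {
    inst <- random_consensus_instance(n_cand = sample(3:6, 1),
                                      n_tools = sample(2:4, 1))
    base <- consensus_rank(inst$challenge, inst$rankings, inst$weights)
    perm <- sample(length(inst$rankings))
    expect_identical(
      consensus_rank(inst$challenge, inst$rankings[perm], inst$weights),
      base)
  }
})

test_that("raising a candidate in one tool never demotes it in the consensus", {
  withr::local_seed(31)
  for (i in 1:100) {
    inst <- random_consensus_instance(n_cand = sample(3:6, 1),
                                      n_tools = sample(2:4, 1))
    # pick a tool ranking with >= 2 entries and promote a non-top candidate
    lens <- lengths(inst$rankings)
    eligible <- which(lens >= 2)
    if (length(eligible) == 0) next
    t <- eligible[[1]]
    r <- inst$rankings[[t]]
    pos <- if (length(r) == 2L) 2L else sample(2:length(r), 1)
    target <- r[pos]
    promoted <- inst$rankings
    promoted[[t]] <- append(r[-pos], target, after = pos - 2)
    before <- match(target, consensus_rank(inst$challenge, inst$rankings,
                                           inst$weights))
    after <- match(target, consensus_rank(inst$challenge, promoted,
                                          inst$weights))
    expect_lte(after, before)
  }
})

test_that("zero-vote candidates append in ID-sorted order", {
  ch <- make_challenge(c(kb("A"), kb("B"), kb("C"), kb("D")),
                       ids = c(40, 30, 20, 10))
  rankings <- list(t1 = kb("A"))
  out <- consensus_rank(ch, rankings, flat_weights("t1"))
  expect_identical(out, c(kb("A"), kb("D"), kb("C"), kb("B")))
})

test_that("tool_ranking objects carry and enforce challenge identity", {
  ch <- make_challenge(c(kb("A"), kb("B")), id = "c9")
  ok <- tool_ranking("t1", "c9", kb("A"))
  other <- tool_ranking("t2", "other", kb("B"))
  expect_error(consensus_rank(ch, list(ok, other), flat_weights(c("t1", "t2"))),
               "inconsistent")
  expect_error(tool_ranking("t1", "c9", c(kb("A"), kb("A"))), "duplicate")
  # rankings may only mention candidate-list members
  stray <- list(t1 = c(kb("A"), kb("Q")))
  expect_error(consensus_rank(ch, stray, flat_weights("t1")), "absent")
})

test_that("correlated multi-tool ensembles match or beat the best tool top-1", {
  profs <- lapply(1:3, function(i) tool_profile(paste0("T", i), 0.15, 0.38))
  ch <- generate_challenges(600, c(5, 50), seed = 13)
  rk <- simulate_tools(ch, profs, seed = 13, correlation = 0.9)
  truths <- vapply(ch, `[[`, "", "truth_key_block")
  w <- calibrate(rk, truths)
  cons <- topk_counts(consensus_rank_all(ch, rk, w), truths)
  singles <- vapply(names(rk), function(t) topk_counts(rk[[t]], truths)$top1,
                    numeric(1))
  best <- max(singles)
  noise3 <- 3 * sqrt(600 * (best / 600) * (1 - best / 600))
  expect_gte(cons$top1, best - noise3)
})

test_that("independent ensembles average out deep-rank noise (top-10 gain)", {
  profs <- lapply(1:3, function(i) tool_profile(paste0("T", i), 0.15, 0.38))
  ch <- generate_challenges(600, c(5, 50), seed = 17)
  rk <- simulate_tools(ch, profs, seed = 17)
  truths <- vapply(ch, `[[`, "", "truth_key_block")
  w <- calibrate(rk, truths)
  cons <- topk_counts(consensus_rank_all(ch, rk, w), truths)
  best10 <- max(vapply(names(rk), function(t) topk_counts(rk[[t]], truths)$top10,
                       numeric(1)))
  expect_gte(cons$top10, best10)
})
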