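test_that("generated datasets are pure functions of the seed", {
  profs <- list(tool_profile("T1", 0.2, 0.4), tool_profile("T2", 0.1, 0.3))
  a <- generate_dataset(30, profs, seed = 77, n_decoys_range = c(2, 8))
  b <- generate_dataset(30, profs, seed = 77, n_decoys_range = c(2, 8))
  expect_identical(lapply(a$challenges, `[[`, "candidates"),
                   lapply(b$challenges, `[[`, "candidates"))
  expect_identical(a$rankings_by_tool, b$rankings_by_tool)
  expect_identical(a$db_table$sets, b$db_table$sets)
  expect_identical(a$msms_flags, b$msms_flags)
  c <- generate_dataset(30, profs, seed = 78, n_decoys_range = c(2, 8))
  expect_false(identical(a$rankings_by_tool, c$rankings_by_tool))
})

test_that("challenge generation respects the decoy range and mass window", {
  ch <- generate_challenges(40, c(0, 0), seed = 3)
  expect_true(all(vapply(ch, function(x) nrow(x$candidates), integer(1)) == 1L))

  ch2 <- generate_challenges(40, c(5, 12), seed = 4)
  sizes <- vapply(ch2, function(x) nrow(x$candidates), integer(1))
  expect_true(all(sizes >= 6 & sizes <= 13))
  # all candidate masses within 5 ppm of the challenge's neutral mass
  proton <- 1.007276
  ok <- vapply(ch2, function(x) {
    neutral <- if (x$ion_mode == "positive") x$precursor_mz - proton
               else x$precursor_mz + proton
    all(abs(x$candidates$monoisotopic_mass - neutral) / neutral * 1e6 <= 5 + 1e-9)
  }, logical(1))
  expect_true(all(ok))
  # key blocks unique across the whole dataset
  all_blocks <- unlist(lapply(ch2, function(x) x$candidates$key_block))
  expect_false(anyDuplicated(all_blocks) > 0)
})

test_that("a deterministic profile pins the truth at rank 1 everywhere", {
  ch <- generate_challenges(25, c(3, 10), seed = 6)
  rk <- simulate_tool(ch, tool_profile("perfect", 1, 0), seed = 6)
  top <- vapply(rk, `[`, "", 1L)
  expect_identical(unname(top), unname(vapply(ch, `[[`, "", "truth_key_block")))
})

test_that("simulated placement frequencies match the profile parameters", {
  # magnitude of the best real single tool: 17% top-1
  p1 <- 0.17
  ch <- generate_challenges(5000, c(20, 40), seed = 10)
  rk <- simulate_tool(ch, tool_profile("T", p1, 0.38), seed = 10)
  truths <- vapply(ch, `[[`, "", "truth_key_block")
  hit1 <- mean(vapply(names(truths), function(cid)
    rk[[cid]][1] == truths[[cid]], logical(1)))
  ci99 <- qnorm(0.995) * sqrt(p1 * (1 - p1) / 5000)
  expect_lt(abs(hit1 - p1), ci99)

  # calibrate() recovers p_top1 and p_top1 + p_top10 (lists all > 10 long)
  w <- calibrate(list(T = rk), truths)
  expect_lt(abs(get_omega(w, "T", 1) - p1), ci99)
  ci99_10 <- qnorm(0.995) * sqrt(0.55 * 0.45 / 5000)
  expect_lt(abs(get_omega(w, "T", 10) - (p1 + 0.38)), ci99_10)
})

test_that("spectrum pairs hit the overlap contract and score monotonically", {
  full <- generate_spectrum_pair(kb("A"), 1, noise = 0, seed = 2)
  expect_identical(dot_product(full$query, full$library), 999L)
  none <- generate_spectrum_pair(kb("A"), 0, seed = 2)
  expect_identical(dot_product(none$query, none$library), 0L)
  expect_identical(full$library$annotation_key_block, kb("A"))

  # overlap sweep at fixed seed: scores non-decreasing within jitter
  scores <- vapply(seq(0, 1, by = 0.1), function(ov) {
    pr <- generate_spectrum_pair(kb("B"), ov, n_peaks = 20, noise = 0, seed = 14)
    as.numeric(dot_product(pr$query, pr$library))
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("correlated simulation preserves each tool's marginal rates", {
  p1 <- 0.2
  profs <- list(tool_profile("A", p1, 0.3), tool_profile("B", p1, 0.3))
  ch <- generate_challenges(3000, c(15, 30), seed = 21)
  truths <- vapply(ch, `[[`, "", "truth_key_block")
  rk <- simulate_tools(ch, profs, seed = 21, correlation = 0.8)
  w <- calibrate(rk, truths)
  ci <- qnorm(0.9995) * sqrt(p1 * (1 - p1) / 3000)
  expect_lt(abs(get_omega(w, "A", 1) - p1), ci)
  expect_lt(abs(get_omega(w, "B", 1) - p1), ci)
  # and induces agreement: both tools top-1 correct together more often
  # than the independent product predicts
  both <- mean(vapply(names(truths), function(cid) {
    rk$A[[cid]][1] == truths[[cid]] && rk$B[[cid]][1] == truths[[cid]]
  }, logical(1)))
  expect_gt(both, p1^2 + 3 * sqrt(p1^2 * (1 - p1^2) / 3000))
})

test_that("datasets can round-trip through the on-disk exchange formats", {
  profs <- list(tool_profile("T1", 0.3, 0.3))
  ds <- generate_dataset(10, profs, seed = 31, n_decoys_range = c(2, 5),
                         with_spectra = TRUE)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  rk <- read_tool_rankings(file.path(dir, "rankings.tsv"))
  expect_identical(rk$T1, ds$rankings_by_tool$T1)
  tr <- read_truths(file.path(dir, "truths.tsv"))
  expect_identical(tr[names(ds$truths)], ds$truths)
  tab <- read_db_table(file.path(dir, "db_table.tsv"))
  expect_identical(lapply(tab$sets, sort)[order(names(tab$sets))],
                   lapply(ds$db_table$sets, sort)[order(names(ds$db_table$sets))])
  cand <- read_candidate_list(
    file.path(dir, "candidates", paste0(names(ds$challenges)[1], ".csv")))
  expect_identical(cand$key_block,
                   ds$challenges[[1]]$candidates$key_block)
  queries <- read_mgf(file.path(dir, "queries.mgf"))
  expect_length(queries, 10L)
  lib <- read_msp(file.path(dir, "library.msp"))
  expect_identical(vapply(lib, `[[`, "", "annotation_key_block"),
                   unname(ds$truths))
})

test_that("an end-to-end synthetic study reproduces the boosting headline", {
  # four tools echoing the observed omega spread (~0.10-0.17 at k=1)
  profs <- list(tool_profile("MetFragCL", 0.167, 0.381),
                tool_profile("MAGMa+",    0.160, 0.324),
                tool_profile("CFM-ID",    0.154, 0.391),
                tool_profile("MS-FINDER", 0.103, 0.272))
  ds <- generate_dataset(600, profs, seed = 41)
  train <- names(ds$challenges)[1:300]
  test <- setdiff(names(ds$challenges), train)
  w <- calibrate(lapply(ds$rankings_by_tool, `[`, train), ds$truths[train])
  cons <- consensus_rank_all(ds$challenges[test],
                             lapply(ds$rankings_by_tool, `[`, test), w)
  boosted <- stats::setNames(lapply(test, function(cid) {
    boosted_rank(cons[[cid]], ds$db_table, ds$msms_flags[[cid]])$key_block
  }), test)
  boosted_top1 <- topk_counts(boosted, ds$truths[test])$top1
  singles <- vapply(names(ds$rankings_by_tool), function(t) {
    topk_counts(ds$rankings_by_tool[[t]][test], ds$truths[test])$top1
  }, numeric(1))
  expect_gt(boosted_top1, max(singles))
})
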