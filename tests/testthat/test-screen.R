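test_that("bone score arithmetic follows the signed definition", {
  # build a profile where the up-set sits on top and the down-set at bottom
  ids <- sprintf("g%02d", 1:20)
  prof <- stats::setNames(1:20, ids)
  sig <- list(up = ids[1:4], down = ids[17:20])
  sc <- score_compound(sig, prof)
  eu <- enrichment_score(sig$up, prof)$es
  ed <- enrichment_score(sig$down, prof)$es
  expect_equal(sc$es_up, eu)
  expect_equal(sc$es_down, ed)
  expect_equal(sc$bone_score, eu - ed)
  expect_equal(sc$abs_gap, abs(eu - ed))
  # identical up/down enrichment cancels exactly
  sym <- score_compound(list(up = ids[1:3], down = ids[1:3]), prof)
  expect_identical(sym$bone_score, 0)
  expect_identical(sym$abs_gap, 0)
  expect_error(score_compound(list(up = character(0), down = ids[1:2]), prof),
               "up-set is empty")
  expect_error(
    suppressWarnings(score_compound(list(up = "zzz", down = ids[1:2]), prof)),
    "up-set.*disjoint")
})

test_that("a strength-1 reverser scores exactly as the oracle predicts", {
  sig <- list(up = sprintf("g%03d", 1:10), down = sprintf("g%03d", 11:20))
  lib <- simulate_ctp_library(sig, n_genes = 200, n_compounds = 6,
                              n_reversers = 1, strength = 1, seed = 21)
  prof <- lib$ranks[, lib$truth$reversers]
  sc <- score_compound(sig, prof)
  exp_up <- oracle_es(unname(prof[sig$up]), 200)$es
  exp_down <- oracle_es(unname(prof[sig$down]), 200)$es
  expect_equal(sc$es_up, exp_up, tolerance = 1e-14)
  expect_equal(sc$es_down, exp_down, tolerance = 1e-14)
  expect_equal(sc$bone_score, exp_up - exp_down, tolerance = 1e-14)
  # forced placement implies the closed-form extremes: up-set on ranks 1..10,
  # down-set on ranks 191..200
  expect_equal(sc$es_up, 1 - 10 / 200)
  expect_equal(sc$es_down, -191 / 200)
})

test_that("rank_library reproduces the independent full-library oracle", {
  sim <- simulate_expression(1000, 50, 50, effect_fc = 4, noise_sd = 0.25,
                             seed = 7)
  sig <- extract_signature(compute_deg(sim$expr, sim$condition))
  lib <- simulate_ctp_library(sig, n_genes = 1000, n_compounds = 100,
                              n_reversers = 5, strength = 0.8, seed = 11)
  scr <- rank_library(sig, lib, mode = "signed", k = 10)
  oracle <- oracle_rank_library(sig$up, sig$down, lib$ranks, "signed")
  expect_identical(scr$scores$compound_id, oracle$ordering)
  expect_equal(scr$scores$bone_score,
               unname(oracle$bone[scr$scores$compound_id]), tolerance = 1e-12)
  # planted reversers out-score every null compound
  nulls <- setdiff(colnames(lib$ranks), lib$truth$reversers)
  expect_gt(min(oracle$bone[lib$truth$reversers]), max(oracle$bone[nulls]))
  expect_identical(recovery_rate(scr, lib$truth, 10),
                   recovery_rate(oracle$ordering, lib$truth, 10))
  expect_identical(recovery_rate(scr, lib$truth, 10), 1)
})

test_that("ranking is invariant to library column order and breaks ties by id", {
  sig <- list(up = sprintf("g%02d", 1:5), down = sprintf("g%02d", 6:10))
  lib <- simulate_ctp_library(sig, n_genes = 50, n_compounds = 20,
                              n_reversers = 2, strength = 1, seed = 2)
  scr <- rank_library(sig, lib, k = 5)
  perm <- sample(ncol(lib$ranks))
  scr_perm <- rank_library(sig, lib$ranks[, perm], k = 5)
  expect_identical(scr$scores, scr_perm$scores)
  expect_identical(scr$scores$rank, seq_len(20L))
  # duplicated column -> identical scores; order must follow compound id
  dup <- lib$ranks[, c(1, 1, 2)]
  colnames(dup) <- c("cpdB", "cpdA", "cpdC")
  scr_dup <- rank_library(sig, dup, k = 1)
  tied <- scr_dup$scores[scr_dup$scores$bone_score ==
                           scr_dup$scores$bone_score[match("cpdA", scr_dup$scores$compound_id)], ]
  expect_identical(tied$compound_id[order(tied$rank)][1:2], c("cpdA", "cpdB"))
})

test_that("single-compound library and argument errors behave as specified", {
  sig <- list(up = sprintf("g%02d", 1:3), down = sprintf("g%02d", 4:6))
  lib <- simulate_ctp_library(sig, n_genes = 30, n_compounds = 1, seed = 4)
  scr <- rank_library(sig, lib, k = 1)
  expect_identical(scr$scores$rank, 1L)
  expect_true(scr$scores$selected)
  expect_error(rank_library(sig, lib, k = 2), "between 1 and the library size")
  bad <- lib$ranks
  bad[1, 1] <- bad[2, 1]
  expect_error(rank_library(sig, bad, k = 1), "not permutations")
  expect_error(rank_library(list(up = "zz", down = "g04"), lib$ranks, k = 1),
               "up-set is disjoint")
})

test_that("signed score equals abs_gap exactly when es_up >= es_down", {
  set.seed(33)
  sig <- list(up = sprintf("g%03d", 1:12), down = sprintf("g%03d", 13:24))
  lib <- simulate_ctp_library(sig, n_genes = 300, n_compounds = 40,
                              n_reversers = 3, strength = 0.6, seed = 8)
  scr <- rank_library(sig, lib, k = 10)
  s <- scr$scores
  idx <- s$es_up >= s$es_down
  expect_true(any(idx))
  expect_identical(s$bone_score[idx], s$abs_gap[idx])
})

test_that("mimickers top the absolute ranking but sink in the signed one", {
  sig <- list(up = sprintf("g%03d", 1:10), down = sprintf("g%03d", 11:20))
  lib <- simulate_ctp_library(sig, n_genes = 500, n_compounds = 100,
                              n_mimickers = 5, strength = 0.8, seed = 13)
  signed <- rank_library(sig, lib, mode = "signed", k = 10)
  absolute <- rank_library(sig, lib, mode = "absolute", k = 10)
  mim <- lib$truth$mimickers
  rank_of <- function(scr, ids) scr$scores$rank[match(ids, scr$scores$compound_id)]
  expect_true(all(rank_of(absolute, mim) <= 10))
  expect_true(all(rank_of(signed, mim) > 50))
  # flip turns mimickers into the signed-mode winners
  flipped <- rank_library(sig, lib, mode = "signed", k = 5, flip = TRUE)
  expect_setequal(flipped$selected, mim)
  # intersect mode selects within the signed top-k only what the absolute
  # top-k also contains
  inter <- rank_library(sig, lib, mode = "intersect", k = 10)
  expect_true(all(inter$selected %in% signed$selected))
  expect_true(all(inter$selected %in% absolute$selected))
})

test_that("permutation null is reproducible with order-statistic quantiles", {
  null <- permutation_null(10, 10, n = 200, n_perm = 500, seed = 3)
  null2 <- permutation_null(10, 10, n = 200, n_perm = 500, seed = 3)
  expect_identical(null$draws, null2$draws)
  expect_identical(unname(quantile(null, 0)), min(null$draws))
  expect_identical(unname(quantile(null, 1)), max(null$draws))
  one <- permutation_null(3, 3, n = 50, n_perm = 1, seed = 1)
  expect_identical(unname(quantile(one, c(0, 0.5, 1))), rep(one$draws, 3))
  expect_error(permutation_null(30, 30, n = 50, n_perm = 10), "exceeds the universe")
  expect_error(permutation_null(0, 3, n = 50, n_perm = 10), ">= 1")
})

test_that("two independent null runs agree within Monte-Carlo error", {
  a <- permutation_null(10, 10, n = 200, n_perm = 2000, seed = 3)
  b <- permutation_null(10, 10, n = 200, n_perm = 2000, seed = 1003)
  se <- sqrt(stats::var(a$draws) / 2000 + stats::var(b$draws) / 2000)
  expect_lt(abs(mean(a$draws) - mean(b$draws)), 3 * se)
})
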