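test_that("weighted peak distance reproduces the methyl-group worked example", {
  # sulfoxide-methyl prediction (2.55, 39.57) vs experimental (2.70, 39.06)
  expect_equal(weighted_peak_distance(2.55, 39.57, 2.70, 39.06), 1.5843,
               tolerance = 1e-4)
  expect_equal(weighted_peak_distance(1, 20, 1, 20), 0)
  expect_equal(weighted_peak_distance(1.1, 20, 1.0, 20), 1.0)
  cfg <- match_config(distance = "manhattan")
  expect_equal(weighted_peak_distance(1.1, 21, 1.0, 20, cfg), 2.0,
               tolerance = 1e-12)
})

test_that("self-match is perfect and the 5-of-6 fixture scores 0.83", {
  set.seed(3)
  peaks <- random_peaks(4)
  m <- match_hsqc(peaks, peaks)
  expect_equal(m$matching_ratio, 1)
  expect_equal(m$mean_dh, 0)
  expect_equal(m$mean_dc, 0)

  # six predicted cross-peaks, five with an experimental counterpart
  pred <- tibble::tibble(
    h_ppm = c(3.62, 2.21, 1.02, 0.88, 5.50, 2.00),
    c_ppm = c(60.3, 29.5, 19.2, 17.1, 100.0, 29.9)
  )
  exp <- tibble::tibble(
    h_ppm = c(3.60, 2.20, 1.00, 0.90, 2.05),
    c_ppm = c(60.0, 30.0, 19.0, 17.0, 30.2)
  )
  m2 <- match_hsqc(pred, exp)
  expect_equal(m2$n_matched, 5L)
  expect_equal(round(m2$matching_ratio, 2), 0.83)

  # nothing in cutoffs: ratio 0, means flagged NA, distance sorts last
  far <- dplyr::mutate(exp, h_ppm = h_ppm + 3)
  m3 <- match_hsqc(pred, far)
  expect_equal(m3$matching_ratio, 0)
  expect_true(is.na(m3$mean_dh) && is.na(m3$mean_dc))
  expect_equal(m3$mean_dist, Inf)
})

test_that("tidy/glance expose pairs and summary", {
  peaks <- tibble::tibble(h_ppm = c(1, 2), c_ppm = c(20, 40))
  m <- match_hsqc(peaks, peaks)
  expect_equal(nrow(tidy(m)), 2)
  g <- glance(m)
  expect_equal(g$n_matched, 2L)
  expect_equal(g$matching_ratio, 1)
})

test_that("assignment matches the exhaustive oracle on small instances", {
  set.seed(17)
  cfg_opt <- match_config(assignment = "optimal")
  n_greedy_diff <- 0
  for (i in 1:60) {
    np <- sample(2:6, 1)
    ne <- sample(2:6, 1)
    p <- random_peaks(np, c(1, 4), c(20, 60))
    e <- random_peaks(ne, c(1, 4), c(20, 60))
    dh <- outer(p$h_ppm, e$h_ppm, "-")
    dc <- outer(p$c_ppm, e$c_ppm, "-")
    dw <- sqrt((10 * dh)^2 + dc^2)
    allowed <- abs(dh) <= 0.5 & abs(dc) <= 5
    orc <- oracle_assignment(dw, allowed)
    mo <- match_hsqc(p, e, cfg_opt)
    expect_equal(mo$n_matched, orc$n)
    expect_equal(sum(mo$pairs$dist_w), orc$total, tolerance = 1e-9)
    mg <- match_hsqc(p, e)
    expect_lte(mg$n_matched, orc$n)
    expect_gte(sum(mg$pairs$dist_w) + 1e-9,
               orc$total * (mg$n_matched == orc$n))
    if (mg$n_matched != orc$n ||
        abs(sum(mg$pairs$dist_w) - orc$total) > 1e-9) {
      n_greedy_diff <- n_greedy_diff + 1
    }
  }
  # greedy is near-optimal on random instances; discrepancies are expected
  # to be rare (the optimal mode exists for exactness)
  expect_lte(n_greedy_diff, 5)
})

test_that("candidate ranking sorts by ratio, distance, then label", {
  set.seed(5)
  truth <- random_peaks(5)
  pred_true <- perturb_hsqc(truth, 0.02, 0.2, seed = 9)
  decoys <- setNames(
    lapply(1:20, function(i) out_of_cutoff_decoy(truth)),
    sprintf("decoy%02d", 1:20)
  )
  cands <- c(list(truth_cand = pred_true), decoys)
  res <- rank_hsqc_candidates(cands, truth)
  expect_equal(res$label[res$rank == 1], "truth_cand")
  expect_equal(nrow(res), 21)

  # byte-identical candidates tie-break by label, both reported
  res2 <- rank_hsqc_candidates(list(b_cand = truth, a_cand = truth), truth)
  expect_equal(res2$label, c("a_cand", "b_cand"))
  expect_equal(res2$rank, c(1L, 2L))

  # single candidate gets rank 1
  res3 <- rank_hsqc_candidates(list(only = truth), truth)
  expect_equal(res3$rank, 1L)

  expect_error(
    rank_hsqc_candidates(list(truth, truth), truth),
    "named"
  )
})

test_that("scores are invariant to decoy additions and weight scaling", {
  set.seed(31)
  truth <- random_peaks(5)
  pred <- perturb_hsqc(truth, 0.03, 0.3)
  base <- rank_hsqc_candidates(list(cand = pred), truth)
  with_decoy <- rank_hsqc_candidates(
    list(cand = pred, dec = out_of_cutoff_decoy(truth)), truth
  )
  got <- dplyr::filter(with_decoy, label == "cand")
  expect_equal(got$matching_ratio, base$matching_ratio)
  expect_equal(got$mean_dist, base$mean_dist)

  # doubling both weights scales distances but leaves ranks unchanged
  cands <- c(list(cand = pred),
             setNames(lapply(1:5, function(i) random_peaks(5)),
                      paste0("r", 1:5)))
  r1 <- rank_hsqc_candidates(cands, truth, match_config(w_h = 10, w_c = 1))
  r2 <- rank_hsqc_candidates(cands, truth, match_config(w_h = 20, w_c = 2))
  expect_equal(r1$label, r2$label)
  expect_equal(r1$rank, r2$rank)
})
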