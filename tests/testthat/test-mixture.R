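test_that("connectivity grouping forms transitive spin systems", {
  hsqc <- tibble::tibble(h_ppm = c(3.60, 1.20, 0.95), c_ppm = c(60, 20, 15))
  tocsy <- tibble::tibble(h1_ppm = c(3.60, 1.20), h2_ppm = c(1.20, 0.95))
  g <- group_peaks_by_connectivity(hsqc, tocsy)
  expect_equal(length(unique(g$group)), 1)

  # no TOCSY: every peak its own group
  g0 <- group_peaks_by_connectivity(hsqc, NULL)
  expect_equal(length(unique(g0$group)), 3)

  # three disjoint spin systems deconvolute into three groups
  sc <- build_scenario(n_features = 3, decoys_per_feature = 2, seed = 19)
  g3 <- group_peaks_by_connectivity(sc$experimental_hsqc, sc$tocsy)
  expect_equal(length(unique(g3$group)), 3)
  # groups partition the peaks and ids follow ascending minimum 1H shift
  expect_equal(nrow(g3), nrow(sc$experimental_hsqc))
  mins <- tapply(g3$h_ppm, g3$group, min)
  expect_equal(names(sort(mins)), paste0("g", seq_along(mins)))
})

test_that("grouping is stable under peak order permutation", {
  set.seed(37)
  sc <- build_scenario(n_features = 4, decoys_per_feature = 2, seed = 4)
  g1 <- group_peaks_by_connectivity(sc$experimental_hsqc, sc$tocsy)
  perm <- sample(nrow(sc$experimental_hsqc))
  g2 <- group_peaks_by_connectivity(sc$experimental_hsqc[perm, ], sc$tocsy)
  bykey <- function(g) g$group[order(g$h_ppm, g$c_ppm)]
  expect_equal(bykey(g1), bykey(g2))
})

test_that("pairwise mixture ranking reduces to plain ranking for one group", {
  set.seed(13)
  truth <- random_peaks(5)
  cands <- list(cand = perturb_hsqc(truth, 0.02, 0.2),
                dec = out_of_cutoff_decoy(truth))
  plain <- rank_hsqc_candidates(cands, truth)
  grouped <- dplyr::mutate(truth, group = "g1")
  mix <- rank_mixture_candidates(cands, grouped)
  expect_equal(mix$label, plain$label)
  expect_equal(mix$matching_ratio, plain$matching_ratio)
  expect_equal(mix$mean_dist, plain$mean_dist)
  expect_equal(mix$rank, plain$rank)
})

test_that("the true candidate-group pair wins a mixture comparison", {
  # one feature's candidate set against a deconvoluted three-group HSQC:
  # the perturbed true list must find its own spin system
  sc <- build_scenario(n_features = 3, decoys_per_feature = 10, seed = 21)
  grouped <- group_peaks_by_connectivity(sc$experimental_hsqc, sc$tocsy)
  f2 <- sc$truth$feature_id[2]
  cands <- dplyr::filter(sc$candidates_nmr, feature_id == f2)
  res <- rank_mixture_candidates(cands[, c("label", "h_ppm", "c_ppm")],
                                 grouped)
  top <- res[res$rank == 1, ]
  expect_equal(top$label, sc$truth$label[2])
  expect_equal(top$group, sc$truth$true_group[2])

  # a candidate matching no group carries ratio 0 and sorts last
  far <- out_of_cutoff_decoy(dplyr::bind_rows(sc$experimental_hsqc))
  res2 <- rank_mixture_candidates(
    list(cand = cands[cands$label == sc$truth$label[2],
                      c("h_ppm", "c_ppm")][1:4, ],
         nowhere = dplyr::mutate(far[1:4, ], h_ppm = h_ppm + 6)),
    grouped
  )
  nw <- res2[res2$label == "nowhere", ]
  expect_true(all(nw$matching_ratio == 0))
  expect_true(all(nw$rank > min(res2$rank[res2$label == "cand"])))
})

test_that("combine_evidence reproduces the published rank-product example", {
  # NMR ranks 1 vs 2 flip once MS2 ranks 167 vs 26 are factored in
  nmr <- tibble::tibble(label = c("proline", "piperidinone"), rank = c(2, 1))
  ms2 <- tibble::tibble(label = c("proline", "piperidinone"), rank = c(26, 167))
  comb <- combine_evidence(nmr, ms2)
  expect_equal(comb$combined_key,
               c(proline = 52, piperidinone = 167), ignore_attr = TRUE)
  expect_equal(comb$label[comb$combined_rank == 1], "proline")

  # identical rankings combine to the identical order
  r <- tibble::tibble(label = letters[1:4], rank = 1:4)
  same <- combine_evidence(r, r)
  expect_equal(same$label, letters[1:4])

  # a candidate absent from MS2 is imputed worst+1 and cannot beat a
  # candidate strong in both
  nmr2 <- tibble::tibble(label = c("a", "b"), rank = c(1, 2))
  ms22 <- tibble::tibble(label = "a", rank = 1)
  comb2 <- combine_evidence(nmr2, ms22)
  expect_equal(comb2$ms2_rank[comb2$label == "b"], 2)
  expect_equal(comb2$label[comb2$combined_rank == 1], "a")

  expect_error(
    combine_evidence(nmr2, tibble::tibble(label = "zz", rank = 1)),
    "share no"
  )
})
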