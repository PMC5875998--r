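test_that("perturbation is seed-deterministic with half-normal magnitude", {
  peaks <- random_peaks(10)
  expect_equal(perturb_hsqc(peaks, 0, 0), peaks)
  p1 <- perturb_hsqc(peaks, 0.05, 0.5, seed = 33)
  p2 <- perturb_hsqc(peaks, 0.05, 0.5, seed = 33)
  expect_equal(p1, p2)
  expect_false(isTRUE(all.equal(p1, perturb_hsqc(peaks, 0.05, 0.5, seed = 34))))

  # mean |dH| of N(0, sigma) is sigma * sqrt(2/pi)
  big <- tibble::tibble(h_ppm = rep(4, 1000), c_ppm = rep(50, 1000))
  pb <- perturb_hsqc(big, 0.08, 0.2, seed = 35)
  expect_equal(mean(abs(pb$h_ppm - 4)), 0.08 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("simulated spectra are reproducible and self-annotatable", {
  lib <- metabolite_library()
  s1 <- simulate_ms2(lib$smiles[2], seed = 12)
  s2 <- simulate_ms2(lib$smiles[2], seed = 12)
  expect_equal(s1$peaks, s2$peaks)

  # with no noise and all fragments kept, every peak annotates at 0 ppm
  sp <- simulate_ms2(lib$smiles[2], frac_fragments = 1, n_noise_peaks = 0,
                     seed = 14)
  frags <- generate_fragments(lib$smiles[2], h_window = 0)
  ann <- annotate_spectrum(sp, frags, tol_ppm = 5)
  expect_true(all(ann$matched))
  expect_equal(max(abs(ann$ppm_error)), 0, tolerance = 1e-9)

  # a fragmentless structure falls back to a precursor-only spectrum
  expect_warning(pre <- simulate_ms2("C", seed = 2), "no fragments")
  expect_equal(nrow(pre$peaks), 1)
})

test_that("decoy sampling respects the separation contract", {
  truth <- tibble::tibble(h_ppm = c(2, 4, 6), c_ppm = c(30, 60, 90))
  set.seed(44)
  for (i in 1:10) {
    d <- sample_decoy_hsqc(6, truth, min_sep_h = 0.3)
    expect_true(all(vapply(d$h_ppm, function(h) {
      all(abs(truth$h_ppm - h) >= 0.3)
    }, logical(1))))
  }
})

test_that("scenarios are deterministic and internally consistent", {
  a <- build_scenario(n_features = 3, decoys_per_feature = 3, seed = 99)
  b <- build_scenario(n_features = 3, decoys_per_feature = 3, seed = 99)
  expect_equal(a$features$mz, b$features$mz)
  expect_equal(a$candidates_nmr, b$candidates_nmr)
  expect_equal(a$spectra[["F1"]]$peaks, b$spectra[["F1"]]$peaks)

  # truth table covers every feature; labels unique within each feature
  expect_equal(nrow(a$truth), 3)
  per_feature <- split(a$candidates_nmr, a$candidates_nmr$feature_id)
  for (cf in per_feature) {
    expect_equal(anyDuplicated(unique(cf$label)), 0)
    expect_true(any(cf$label %in% a$truth$label))
  }
  # with no decoys every ranking trivially places the truth first
  nd <- build_scenario(n_features = 2, decoys_per_feature = 0, seed = 5)
  grouped <- group_peaks_by_connectivity(nd$experimental_hsqc, nd$tocsy)
  for (i in 1:2) {
    cands <- dplyr::filter(nd$candidates_nmr,
                           feature_id == nd$truth$feature_id[i])
    res <- rank_mixture_candidates(cands[, c("label", "h_ppm", "c_ppm")],
                                   grouped)
    expect_equal(res$label[res$rank == 1], nd$truth$label[i])
  }
  expect_error(build_scenario(n_features = 0), "at least one")
  expect_error(build_scenario(n_features = 99), "at most")
})

test_that("a scenario survives a write/read round trip", {
  sc <- build_scenario(n_features = 2, decoys_per_feature = 2, seed = 3)
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  rt <- read_scenario(dir)
  expect_equal(as.data.frame(rt$experimental_hsqc),
               as.data.frame(sc$experimental_hsqc))
  expect_equal(as.data.frame(rt$tocsy), as.data.frame(sc$tocsy))
  expect_equal(rt$features$mz, sc$features$mz, tolerance = 1e-6)
  expect_equal(rt$spectra[["F1"]]$peaks$mz, sc$spectra[["F1"]]$peaks$mz,
               tolerance = 1e-6)
  expect_equal(rt$spectra[["F2"]]$polarity, sc$spectra[["F2"]]$polarity)
  expect_equal(rt$truth$true_group, sc$truth$true_group)
  expect_equal(rt$config$seed, 3)
})
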