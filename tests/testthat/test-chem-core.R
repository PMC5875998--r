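test_that("formula parsing round-trips through canonical Hill order", {
  expect_equal(parse_formula("C5H11NO2"),
               c(C = 5L, H = 11L, N = 1L, O = 2L))
  expect_equal(parse_formula("H2O"), c(H = 2L, O = 1L))
  expect_equal(parse_formula("C12H23NO10S3"),
               c(C = 12L, H = 23L, N = 1L, O = 10L, S = 3L))
  # non-Hill input canonicalizes; no-carbon formulas sort alphabetically
  expect_equal(format_formula(parse_formula("O2NH11C5")), "C5H11NO2")
  expect_equal(format_formula(parse_formula("OH2")), "H2O")
  expect_error(parse_formula("C5Xx2"), "Xx")
  expect_error(parse_formula(""), "empty")
})

test_that("monoisotopic masses match hand-summed IUPAC values", {
  expect_equal(monoisotopic_mass("C5H11NO2"), 117.078979, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("H"), 1.0078250, tolerance = 1e-6)
})

test_that("monoisotopic mass is additive over formula union", {
  set.seed(11)
  els <- c("C", "H", "N", "O", "S", "P")
  for (i in 1:25) {
    f1 <- setNames(sample(0:6, 6, replace = TRUE), els)
    f2 <- setNames(sample(0:6, 6, replace = TRUE), els)
    if (sum(f1) == 0 || sum(f2) == 0) next
    merged <- f1 + f2
    expect_equal(
      monoisotopic_mass(merged[merged > 0]),
      monoisotopic_mass(f1[f1 > 0]) + monoisotopic_mass(f2[f2 > 0]),
      tolerance = 1e-9
    )
  }
})

test_that("adduct m/z uses the proton-mass convention", {
  expect_equal(adduct_mz("C9H11NO2", "[M+H]+"), 166.086255, tolerance = 1e-6)
  expect_equal(adduct_mz("C12H23NO10S3", "[M-H]-"), 436.041132,
               tolerance = 1e-6)
  expect_equal(adduct_mz("H2O", "[M+H]+"), 19.017841, tolerance = 1e-6)
  # unicode minus in the adduct name is tolerated
  expect_equal(adduct_mz("C12H23NO10S3", "[M−H]−"),
               adduct_mz("C12H23NO10S3", "[M-H]-"))
  expect_error(adduct_mz("H2O", "[M+X]+"), "unknown adduct")
})

test_that("[M+H]+ and [M-H]- differ by two proton masses for any formula", {
  set.seed(7)
  for (i in 1:20) {
    cnt <- c(C = sample(1:20, 1), H = sample(1:30, 1),
             N = sample(0:3, 1), O = sample(0:8, 1))
    f <- format_formula(cnt[cnt > 0])
    expect_equal(adduct_mz(f, "[M+H]+") - adduct_mz(f, "[M-H]-"),
                 2 * mass_constants[["proton"]], tolerance = 1e-10)
  }
})

test_that("ppm errors follow the truncated-absolute convention", {
  expect_equal(ppm_error(100, 100), 0)
  expect_equal(truncated_abs_ppm(166.0859, adduct_mz("C9H11NO2")), 2L)
  expect_equal(truncated_abs_ppm(118.0850, adduct_mz("C5H11NO2")), 10L)
  # flooring, not rounding: 5.51 ppm -> 5, 0.85 ppm -> 0
  expect_equal(truncated_abs_ppm(150.0575, adduct_mz("C5H11NO2S")), 5L)
  expect_equal(truncated_abs_ppm(124.0392, adduct_mz("C6H5NO2")), 0L)
  expect_error(ppm_error(100, 0), "must be > 0")
})

test_that("RDBE follows the CHNOPS-halogen valence formula", {
  expect_equal(rdbe("C9H11NO2"), 5)
  expect_equal(rdbe("CH4"), 0)
  expect_equal(rdbe("C6H6"), 4)
  expect_equal(rdbe("CHCl3"), 0)
  expect_equal(rdbe(c("C5H9NO2", "C10H14N2O5")), c(2, 5))
})

test_that("isotope patterns match known ratios and the enumeration oracle", {
  pc <- isotope_pattern("C", 2)
  expect_equal(pc$abundance, c(1, 0.0107 / 0.9893), tolerance = 1e-4)
  expect_equal(pc$mass, c(12, 13.00335), tolerance = 1e-5)
  ch4 <- isotope_pattern("CH4", 3)
  expect_equal(ch4$abundance[2], 0.0113, tolerance = 5e-3)
  h2s <- isotope_pattern("H2S", 3)
  expect_equal(h2s$abundance[3], 0.0425 / 0.9499, tolerance = 1e-3)
  expect_true(all(diff(isotope_pattern("C6H12O6")$mass) > 0))

  # exhaustive atom-wise enumeration oracle, molecules <= 6 atoms
  iso <- pkg_isotope_table()
  for (f in list(c(C = 1L, H = 4L), c(H = 2L, S = 1L), c(C = 2L, O = 2L),
                 c(N = 2L, O = 1L), c(C = 1L, Cl = 2L))) {
    orc <- oracle_isotope_pattern(f, iso)
    expect_equal(sum(orc$prob), 1, tolerance = 1e-9)
    pat <- isotope_pattern(f, max_isotopologues = length(orc$shift))
    norm <- orc$prob / max(orc$prob)
    expect_equal(pat$abundance, unname(norm[norm > 0][seq_len(nrow(pat))]),
                 tolerance = 1e-9)
    expect_equal(pat$mass, unname(orc$mass[norm > 0][seq_len(nrow(pat))]),
                 tolerance = 1e-6)
  }
})
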