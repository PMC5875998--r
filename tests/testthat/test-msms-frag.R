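test_that("single-break fragments follow the molecular graph", {
  eth <- generate_fragments("CC", max_bond_breaks = 1)
  expect_true("CH3" %in% eth$formula[eth$bonds_broken == 1])
  expect_true("C2H6" %in% eth$formula[eth$bonds_broken == 0])

  # every benzene bond is a ring bond: one cut never disconnects
  benz <- generate_fragments("c1ccccc1", max_bond_breaks = 1)
  expect_equal(sum(benz$bonds_broken > 0), 0)
  # two cuts open the ring
  benz2 <- generate_fragments("c1ccccc1", max_bond_breaks = 2, h_window = 0)
  expect_true("C3H3" %in% benz2$formula[benz2$bonds_broken == 2])

  # zero breaks: only the intact molecule
  intact <- generate_fragments("CC(C)C(N)C(O)=O", max_bond_breaks = 0)
  expect_equal(nrow(intact), 1)
  expect_equal(intact$formula, "C5H11NO2")
  expect_error(generate_fragments("C1CC"), "ring")
})

test_that("fragment formulas are sub-formulas with smaller mass", {
  frags <- generate_fragments("CSCCC(N)C(O)=O", max_bond_breaks = 2,
                              h_window = 0)
  parent <- parse_formula("C5H11NO2S")
  parent_mass <- monoisotopic_mass("C5H11NO2S")
  proper <- frags[frags$bonds_broken > 0, ]
  expect_gt(nrow(proper), 0)
  for (i in seq_len(nrow(proper))) {
    cnt <- parse_formula(proper$formula[i])
    expect_true(all(names(cnt) %in% names(parent)))
    expect_true(all(cnt <= parent[names(cnt)]))
    expect_lt(proper$neutral_mass[i], parent_mass)
  }
})

test_that("one-break enumeration equals the bridge-edge oracle", {
  set.seed(29)
  for (i in 1:15) {
    smi <- random_smiles(sample(4:8, 1))
    mol <- parse_smiles(smi)
    got <- generate_fragments(mol, max_bond_breaks = 1, h_window = 0)
    got <- sort(unique(got$formula[got$bonds_broken == 1]))
    expect_equal(got, oracle_bridge_fragments(mol), label = smi)
  }
})

test_that("spectrum annotation applies tolerance and tie-breaking", {
  frags <- generate_fragments("CSCCC(N)C(O)=O", h_window = 0)
  ion <- frags$neutral_mass[frags$formula == "CH3S" &
                              frags$h_shift == 0] + mass_constants[["proton"]]
  sp <- ms2_spectrum(
    tibble::tibble(mz = c(ion, ion * (1 + 50e-6)), intensity = c(10, 5)),
    precursor_mz = adduct_mz("C5H11NO2S"), polarity = "positive"
  )
  ann <- annotate_spectrum(sp, frags, tol_ppm = 30)
  expect_true(ann$matched[1])
  expect_equal(ann$ppm_error[1], 0, tolerance = 1e-9)
  expect_false(ann$matched[2]) # 50 ppm away with a 30 ppm window
  # widening the tolerance never unmatches
  ann2 <- annotate_spectrum(sp, frags, tol_ppm = 60)
  expect_true(all(ann2$matched[ann$matched]))
})

test_that("the printed glucosinolate fragment peak annotates in tolerance", {
  frags <- generate_fragments(
    "CS(=O)CCCCC(=NOS(=O)(=O)O)SC1OC(CO)C(O)C(O)C1O"
  )
  sp <- ms2_spectrum(tibble::tibble(mz = 178.0166, intensity = 100),
                     precursor_mz = 436.0332, polarity = "negative")
  ann <- annotate_spectrum(sp, frags, tol_ppm = 30)
  expect_true(ann$matched[1])
  expect_equal(ann$formula[1], "C5H9NO4S")
  expect_lt(abs(ann$ppm_error[1]), 30)
  expect_equal(ann$fragment_mz[1], 178.017954, tolerance = 1e-5)
})

test_that("MS2 scoring is monotone and scale-invariant", {
  ann <- tibble::tibble(
    matched = c(TRUE, TRUE, FALSE),
    rel_intensity = c(1, 0.5, 0.2),
    mz = c(100, 80, 60)
  )
  expect_equal(score_ms2_candidate(ann[3, ]), 0)
  expect_equal(score_ms2_candidate(ann[1, ]), 1e6)
  expect_gt(score_ms2_candidate(ann), score_ms2_candidate(ann[1, ]))

  # normalized candidate scores ignore a global intensity scale
  set.seed(41)
  lib <- metabolite_library()
  sp <- simulate_ms2(lib$smiles[4], n_noise_peaks = 2, seed = 13)
  cands <- tibble::tibble(label = lib$name[c(4, 1, 7)],
                          smiles = lib$smiles[c(4, 1, 7)])
  r1 <- rank_ms2_candidates(cands, sp)
  sp2 <- sp
  sp2$peaks$intensity <- sp2$peaks$intensity * 37
  r2 <- rank_ms2_candidates(cands, sp2)
  expect_equal(r1$score, r2$score, tolerance = 1e-12)
  expect_equal(r1$label, r2$label)
})

test_that("candidate ranking recovers the true structure", {
  lib <- metabolite_library()
  sp <- simulate_ms2(lib$smiles[1], n_noise_peaks = 0, seed = 8)
  cands <- tibble::tibble(label = lib$name, smiles = lib$smiles)
  res <- rank_ms2_candidates(cands, sp)
  expect_equal(res$label[res$rank == 1], lib$name[1])
  expect_equal(res$score[res$rank == 1], 1.0)

  # single candidate with any match normalizes to 1
  one <- rank_ms2_candidates(cands[1, ], sp)
  expect_equal(one$score, 1.0)

  # all-zero case warns and ranks by label
  empty_sp <- ms2_spectrum(tibble::tibble(mz = 1000, intensity = 1),
                           precursor_mz = 1000)
  expect_warning(z <- rank_ms2_candidates(cands[2:3, ], empty_sp), "zero")
  expect_equal(z$score, c(0, 0))
  expect_equal(z$label, sort(z$label))
})
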