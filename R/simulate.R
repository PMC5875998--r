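# Seeded synthetic-scenario generator. The stated world mirrors the
# ten-metabolite model-mixture design: known small metabolites with
# idealized, fully resolved HSQC spin systems, Gaussian predictor error on
# the "predicted" peak lists, uniform decoy peak lists kept a minimum
# proton distance from the truth, simulated MS2 spectra from the package's
# own fragmenter, and isotope envelopes with multiplicative noise.

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Built-in metabolite library for synthetic scenarios
#'
#' Ten common metabolites with structures (SMILES), formulas and idealized
#' HSQC cross-peak lists. Proton shifts of different metabolites are kept
#' more than 0.02 ppm apart so that TOCSY-based deconvolution at the
#' default tolerance separates the spin systems cleanly; real mixtures
#' overlap more than this (see the package vignette).
#'
#' @return A tibble with columns `name`, `smiles`, `formula`, `n_peaks` and
#'   a list-column `peaks` of tibbles (`h_ppm`, `c_ppm`).
#' @export
metabolite_library <- function() {
  pk <- function(h, c) tibble(h_ppm = h, c_ppm = c)
  lib <- list(
    valine = list(
      smiles = "CC(C)C(N)C(O)=O",
      peaks = pk(c(3.61, 2.26, 0.99, 1.04), c(61.2, 29.8, 18.7, 17.5))
    ),
    leucine = list(
      smiles = "CC(C)CC(N)C(O)=O",
      peaks = pk(c(3.73, 1.71, 1.67, 0.91, 0.95),
                 c(54.2, 40.7, 25.0, 22.8, 21.7))
    ),
    isoleucine = list(
      smiles = "CCC(C)C(N)C(O)=O",
      peaks = pk(c(3.66, 1.98, 1.47, 1.26, 1.08, 1.12),
                 c(60.4, 36.7, 25.2, 25.2, 15.6, 11.9))
    ),
    methionine = list(
      smiles = "CSCCC(N)C(O)=O",
      peaks = pk(c(3.86, 2.64, 2.19, 2.14), c(54.6, 29.6, 30.6, 14.8))
    ),
    glutamine = list(
      smiles = "NC(=O)CCC(N)C(O)=O",
      peaks = pk(c(3.77, 2.45, 2.08), c(55.1, 31.8, 27.1))
    ),
    proline = list(
      smiles = "OC(=O)C1CCCN1",
      peaks = pk(c(4.13, 3.44, 3.31, 2.34, 2.04),
                 c(61.9, 46.9, 46.9, 29.9, 24.6))
    ),
    phenylalanine = list(
      smiles = "NC(Cc1ccccc1)C(O)=O",
      peaks = pk(c(3.99, 3.28, 3.12, 7.33, 7.38, 7.43),
                 c(56.9, 37.2, 37.2, 129.9, 129.5, 128.3))
    ),
    nicotinate = list(
      smiles = "OC(=O)C1=CC=CN=C1",
      peaks = pk(c(8.94, 8.71, 8.26, 7.52), c(146.1, 150.0, 138.3, 124.8))
    ),
    pantothenate = list(
      smiles = "CC(C)(CO)C(O)C(=O)NCCC(O)=O",
      peaks = pk(c(3.96, 3.52, 3.38, 2.53, 0.82, 0.87),
                 c(76.1, 69.1, 47.1, 36.1, 19.6, 21.1))
    ),
    thymidine = list(
      smiles = "CC1=CN(C2CC(O)C(CO)O2)C(=O)NC1=O",
      peaks = pk(c(7.65, 6.28, 4.45, 4.02, 3.82, 2.40, 1.88),
                 c(137.4, 85.6, 71.1, 87.1, 61.6, 38.6, 12.3))
    )
  )
  tibble(
    name = names(lib),
    smiles = unname(vapply(lib, `[[`, character(1), "smiles")),
    formula = unname(vapply(lib, function(x) molecular_formula(x$smiles),
                            character(1))),
    n_peaks = unname(vapply(lib, function(x) nrow(x$peaks), integer(1))),
    peaks = unname(lapply(lib, `[[`, "peaks"))
  )
}

#' Perturb an HSQC peak list with Gaussian predictor error
#'
#' Adds independent Gaussian offsets per peak and dimension, emulating the
#' error of an empirical chemical-shift predictor.
#'
#' @param peaks Data frame with `h_ppm`, `c_ppm`.
#' @param sigma_h,sigma_c Standard deviations in ppm (defaults 0.05 and
#'   0.5, the order of magnitude of empirical HSQC prediction errors).
#' @param seed Optional integer seed (caller RNG state is restored).
#' @return A tibble of the same shape with perturbed shifts.
#' @export
perturb_hsqc <- function(peaks, sigma_h = 0.05, sigma_c = 0.5, seed = NULL) {
  stopifnot(sigma_h >= 0, sigma_c >= 0)
  peaks <- check_peaks(peaks, "peak list")
  with_seed(seed, {
    n <- nrow(peaks)
    mutate(peaks,
           h_ppm = h_ppm + rnorm(n, 0, sigma_h),
           c_ppm = c_ppm + rnorm(n, 0, sigma_c))
  })
}

#' Sample a decoy HSQC peak list
#'
#' Draws peaks uniformly over plausible shift ranges, rejecting proton
#' shifts closer than `min_sep_h` to any peak of the true list so the
#' decoy difficulty is controlled.
#'
#' @param n_peaks Number of peaks.
#' @param truth True peak list the decoy must stay away from (may be NULL).
#' @param min_sep_h Minimum proton distance to any true peak (ppm).
#' @param h_range,c_range Sampling ranges in ppm.
#' @param seed Optional seed.
#' @return A tibble with `h_ppm`, `c_ppm`.
#' @export
sample_decoy_hsqc <- function(n_peaks, truth = NULL, min_sep_h = 0.15,
                              h_range = c(0.5, 9), c_range = c(10, 160),
                              seed = NULL) {
  stopifnot(n_peaks >= 1)
  with_seed(seed, {
    h <- numeric(n_peaks)
    for (i in seq_len(n_peaks)) {
      repeat {
        cand <- runif(1, h_range[1], h_range[2])
        if (is.null(truth) || all(abs(truth$h_ppm - cand) >= min_sep_h)) break
      }
      h[i] <- cand
    }
    tibble(h_ppm = h, c_ppm = runif(n_peaks, c_range[1], c_range[2]))
  })
}

#' Simulate an isotope envelope with multiplicative abundance noise
#'
#' @param formula Formula string.
#' @param noise Multiplicative noise fraction on abundances (default 0.05).
#' @param k Number of isotopologues.
#' @param seed Optional seed.
#' @return Tibble `mass`, `abundance` re-normalized to base peak = 1.
#' @export
simulate_envelope <- function(formula, noise = 0.05, k = 3, seed = NULL) {
  pat <- isotope_pattern(formula, k)
  with_seed(seed, {
    ab <- pat$abundance * pmax(1 + rnorm(nrow(pat), 0, noise), 1e-6)
    tibble(mass = pat$mass, abundance = ab / max(ab))
  })
}

#' Simulate an MS2 spectrum from a structure
#'
#' Fragments the structure with the package fragmenter, keeps a random
#' subset of the fragment ion m/z values as peaks with random intensities,
#' and adds uniform-random noise peaks. By construction every non-noise
#' peak is annotatable by the structure's own fragments at 0 ppm.
#'
#' @param smiles Structure to fragment.
#' @param polarity `"positive"` or `"negative"`.
#' @param frac_fragments Fraction of fragment ions kept (>= 0.5 enforced).
#' @param n_noise_peaks Number of uniform-random noise peaks.
#' @param max_bond_breaks Fragmenter depth (default 2).
#' @param collision_energy Metadata (default 30 V).
#' @param seed Optional seed.
#' @return An [ms2_spectrum()]; when the structure yields no proper
#'   fragment the spectrum contains the precursor only and a warning is
#'   raised.
#' @export
simulate_ms2 <- function(smiles, polarity = "positive", frac_fragments = 0.8,
                         n_noise_peaks = 5, max_bond_breaks = 2,
                         collision_energy = 30, seed = NULL) {
  stopifnot(frac_fragments >= 0.5, frac_fragments <= 1, n_noise_peaks >= 0)
  polarity <- arg_match(polarity, c("positive", "negative"))
  adduct <- fragment_ion_adduct(polarity)
  formula <- molecular_formula(smiles)
  precursor <- adduct_mz(formula, adduct)
  frags <- generate_fragments(smiles, max_bond_breaks = max_bond_breaks,
                              h_window = 0)
  proper <- frags[frags$bonds_broken > 0, , drop = FALSE]
  with_seed(seed, {
    if (nrow(proper) == 0) {
      warn(paste0("structure '", smiles, "' yields no fragments; ",
                  "spectrum contains the precursor only"))
      peaks <- tibble(mz = precursor, intensity = 1)
    } else {
      a <- resolve_adduct(adduct)
      ion_mz <- (proper$neutral_mass + a$delta_mass) / abs(a$charge)
      ion_mz <- ion_mz[ion_mz > 0]
      n_keep <- max(1, ceiling(frac_fragments * length(ion_mz)))
      keep <- sort(sample(seq_along(ion_mz), n_keep))
      peaks <- tibble(mz = ion_mz[keep],
                      intensity = runif(n_keep, 0.05, 1))
      if (n_noise_peaks > 0) {
        peaks <- bind_rows(peaks, tibble(
          mz = runif(n_noise_peaks, 50, max(precursor, 51)),
          intensity = runif(n_noise_peaks, 0.01, 0.3)
        ))
      }
    }
    ms2_spectrum(peaks, precursor, polarity, collision_energy,
                 title = formula)
  })
}

#' Build a complete synthetic benchmark scenario
#'
#' Emits an internally consistent mixture scenario: accurate-mass features
#' with noisy isotope envelopes, one experimental HSQC containing every
#' metabolite's (idealized) spin system plus the TOCSY connectivity that
#' deconvolutes it, per-feature candidate sets consisting of the true
#' structure's perturbed "predicted" peak list and uniform decoys, MS2
#' spectra simulated from the true structures, and structural decoys for
#' MS2 ranking (other library metabolites). A truth table links features to
#' candidate labels and peak groups.
#'
#' @param n_features Number of metabolites in the mixture (1-10; default
#'   10, the model-mixture size).
#' @param decoys_per_feature Decoy candidates per feature (default 20).
#' @param sigma_h,sigma_c Predictor-error standard deviations in ppm
#'   (defaults 0.05 and 0.5).
#' @param ms2_noise_peaks Noise peaks per simulated MS2 spectrum.
#' @param envelope_noise Multiplicative isotope-envelope noise fraction.
#' @param mz_error_ppm Gaussian mass error (ppm) applied to feature m/z.
#' @param seed Integer seed; the same seed reproduces the scenario exactly.
#' @return A list of class `hybrid_scenario` with elements `features`,
#'   `experimental_hsqc`, `tocsy`, `candidates_nmr` (stacked predicted peak
#'   lists with `feature_id` and `label`), `candidates_ms2` (label/smiles
#'   per feature), `spectra` (named list of [ms2_spectrum()]), `truth`
#'   (feature_id, name, formula, true label, true group) and `config`.
#' @export
build_scenario <- function(n_features = 10, decoys_per_feature = 20,
                           sigma_h = 0.05, sigma_c = 0.5,
                           ms2_noise_peaks = 5, envelope_noise = 0.05,
                           mz_error_ppm = 2, seed = 1) {
  lib <- metabolite_library()
  if (n_features < 1) abort("scenario needs at least one feature")
  if (n_features > nrow(lib)) {
    abort(paste0("at most ", nrow(lib), " features supported"))
  }
  lib <- lib[seq_len(n_features), ]
  set.seed(seed)

  feature_ids <- paste0("F", seq_len(n_features))

  # accurate-mass features ([M+H]+ with small mass error) + noisy envelopes
  theo_mz <- unname(vapply(lib$formula, adduct_mz, numeric(1),
                           adduct = "[M+H]+"))
  features <- tibble(
    feature_id = feature_ids,
    mz = theo_mz * (1 + rnorm(n_features, 0, mz_error_ppm) * 1e-6),
    polarity = "positive",
    adduct = "[M+H]+",
    envelope = lapply(lib$formula, function(f) {
      simulate_envelope(f, noise = envelope_noise)
    })
  )

  # experimental HSQC: the union of the true (idealized) spin systems,
  # with TOCSY cross-peaks chaining each metabolite's protons
  experimental_hsqc <- bind_rows(lapply(seq_len(n_features), function(i) {
    mutate(lib$peaks[[i]], true_feature = feature_ids[i])
  }))
  tocsy <- bind_rows(lapply(lib$peaks, function(p) {
    h <- p$h_ppm
    if (length(h) < 2) return(NULL)
    tibble(h1_ppm = pmin(h[-length(h)], h[-1]),
           h2_ppm = pmax(h[-length(h)], h[-1]))
  }))

  # NMR candidate sets: perturbed truth + decoys with the same peak count
  candidates_nmr <- bind_rows(lapply(seq_len(n_features), function(i) {
    truth_peaks <- lib$peaks[[i]]
    true_pred <- mutate(
      perturb_hsqc(truth_peaks, sigma_h, sigma_c),
      feature_id = feature_ids[i], label = lib$name[i]
    )
    decoys <- bind_rows(lapply(seq_len(decoys_per_feature), function(j) {
      mutate(
        sample_decoy_hsqc(nrow(truth_peaks), truth_peaks,
                          min_sep_h = 3 * max(sigma_h, 0.01)),
        feature_id = feature_ids[i],
        label = sprintf("%s_decoy%02d", lib$name[i], j)
      )
    }))
    bind_rows(true_pred, decoys)
  }))

  # MS2: spectra of the true structures; structural decoys borrowed from
  # the other library metabolites, mapped onto the first decoy labels
  spectra <- setNames(lapply(seq_len(n_features), function(i) {
    simulate_ms2(lib$smiles[i], polarity = "positive",
                 n_noise_peaks = ms2_noise_peaks)
  }), feature_ids)
  full_lib <- metabolite_library()
  candidates_ms2 <- bind_rows(lapply(seq_len(n_features), function(i) {
    others <- full_lib[full_lib$name != lib$name[i], ]
    k <- min(decoys_per_feature, nrow(others))
    bind_rows(
      tibble(feature_id = feature_ids[i], label = lib$name[i],
             smiles = lib$smiles[i]),
      if (k > 0) tibble(
        feature_id = feature_ids[i],
        label = sprintf("%s_decoy%02d", lib$name[i], seq_len(k)),
        smiles = others$smiles[seq_len(k)]
      )
    )
  }))

  grouped <- group_peaks_by_connectivity(
    select(experimental_hsqc, h_ppm, c_ppm), tocsy
  )
  truth <- tibble(
    feature_id = feature_ids,
    name = lib$name,
    formula = lib$formula,
    label = lib$name,
    true_group = vapply(seq_len(n_features), function(i) {
      rows <- experimental_hsqc$true_feature == feature_ids[i]
      names(sort(table(grouped$group[rows]), decreasing = TRUE))[1]
    }, character(1))
  )

  structure(
    list(
      features = features,
      experimental_hsqc = select(experimental_hsqc, h_ppm, c_ppm),
      tocsy = tocsy,
      candidates_nmr = candidates_nmr,
      candidates_ms2 = candidates_ms2,
      spectra = spectra,
      truth = truth,
      config = list(
        n_features = n_features, decoys_per_feature = decoys_per_feature,
        sigma_h = sigma_h, sigma_c = sigma_c,
        ms2_noise_peaks = ms2_noise_peaks,
        envelope_noise = envelope_noise, mz_error_ppm = mz_error_ppm,
        seed = seed
      )
    ),
    class = "hybrid_scenario"
  )
}

#' @export
print.hybrid_scenario <- function(x, ...) {
  cat("<hybrid_scenario> ", nrow(x$truth), " features, ",
      x$config$decoys_per_feature, " decoys/feature, seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}
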