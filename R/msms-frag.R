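#' Generate fragments of a structure by systematic bond disconnection
#'
#' Enumerates every connected fragment obtainable by removing up to
#' `max_bond_breaks` non-hydrogen bonds from the molecular graph (so one
#' break cleaves a chain bond; two breaks can open a ring). Each proper
#' fragment is emitted with hydrogen-rearrangement variants `h_shift` in
#' `-h_window..+h_window`; the intact molecule is included with zero breaks
#' and no rearrangement. Fragments are deduplicated by `(formula, h_shift)`,
#' keeping the smallest break count.
#'
#' @param structure A SMILES string or a `mol_graph` from [parse_smiles()].
#' @param max_bond_breaks Maximum number of simultaneously removed bonds
#'   (default 2: chain cleavages plus single ring openings).
#' @param max_tree_depth Maximum number of successive cleavage steps; acts
#'   as an additional cap on the removed-bond count (default 2).
#' @param h_window Hydrogen rearrangement half-window (default 2).
#' @return A tibble with columns `formula`, `h_shift`, `neutral_mass`
#'   (monoisotopic mass of the formula plus `h_shift` hydrogen-atom
#'   masses), `bonds_broken`, `n_atoms`, sorted by mass. The intact
#'   molecule is the row with `bonds_broken == 0`.
#' @examples
#' generate_fragments("CC", max_bond_breaks = 1)
#' @export
generate_fragments <- function(structure, max_bond_breaks = 2,
                               max_tree_depth = 2, h_window = 2) {
  stopifnot(max_bond_breaks >= 0, max_tree_depth >= 0, h_window >= 0)
  mol <- if (is.character(structure)) parse_smiles(structure) else structure
  stopifnot(inherits(mol, "mol_graph"))
  n_atoms <- nrow(mol$atoms)
  n_bonds <- nrow(mol$bonds)
  # each cleavage step removes at least one bond, so the tree depth also
  # bounds the removable-bond budget
  budget <- min(max_bond_breaks, if (max_tree_depth == 0) 0 else max_bond_breaks)
  if (max_tree_depth == 0) budget <- 0

  g <- mol_igraph(mol)
  seen <- new.env(parent = emptyenv()) # atom-subset key -> bonds_broken
  record <- function(members, nb) {
    key <- paste(sort(members), collapse = ",")
    prev <- get0(key, envir = seen, ifnotfound = Inf)
    if (nb < prev) assign(key, nb, envir = seen)
  }
  record(mol$atoms$idx, 0L)

  if (budget > 0 && n_bonds > 0) {
    for (size in seq_len(min(budget, n_bonds))) {
      combos <- utils::combn(n_bonds, size)
      for (ci in seq_len(ncol(combos))) {
        cut <- combos[, ci]
        gg <- igraph::delete_edges(g, cut)
        comp <- igraph::components(gg)
        if (comp$no == 1) next # removal did not disconnect (ring bonds)
        membership <- comp$membership
        for (cmp in seq_len(comp$no)) {
          members <- as.integer(names(membership)[membership == cmp])
          if (length(members) == n_atoms) next
          record(members, size)
        }
      }
    }
  }

  keys <- ls(envir = seen)
  rows <- purrr::map(keys, function(key) {
    members <- as.integer(strsplit(key, ",")[[1]])
    nb <- get(key, envir = seen)
    f <- molecular_formula(mol, atoms = members)
    base_mass <- monoisotopic_mass(f)
    shifts <- if (nb == 0) 0L else seq(-h_window, h_window)
    tibble(
      formula = f,
      h_shift = as.integer(shifts),
      neutral_mass = base_mass + shifts * mass_constants[["h_atom"]],
      bonds_broken = as.integer(nb),
      n_atoms = length(members)
    )
  })
  out <- bind_rows(rows)
  # dedupe (formula, h_shift) keeping the fewest breaks
  out <- out |>
    arrange(bonds_broken) |>
    distinct(formula, h_shift, .keep_all = TRUE) |>
    arrange(neutral_mass, formula, h_shift)
  out
}

#' Construct an MS2 spectrum object
#'
#' @param peaks Data frame with columns `mz`, `intensity`.
#' @param precursor_mz Precursor m/z.
#' @param polarity `"positive"` or `"negative"`.
#' @param collision_energy Collision energy metadata in volts (default 30).
#' @param title Optional label.
#' @return An object of class `ms2_spectrum` (peaks stored sorted by m/z).
#' @export
ms2_spectrum <- function(peaks, precursor_mz, polarity = "positive",
                         collision_energy = 30, title = NULL) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (any(peaks$intensity < 0)) abort("negative peak intensity")
  if (any(peaks$mz <= 0)) abort("non-positive peak m/z")
  peaks <- arrange(as_tibble(peaks[, c("mz", "intensity")]), mz)
  structure(
    list(
      peaks = peaks,
      precursor_mz = precursor_mz,
      polarity = arg_match(polarity, c("positive", "negative")),
      collision_energy = collision_energy,
      title = title %||% ""
    ),
    class = "ms2_spectrum"
  )
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat("<ms2_spectrum> ", if (nzchar(x$title)) paste0(x$title, " ") else "",
      "precursor m/z ", sprintf("%.4f", x$precursor_mz), " (", x$polarity,
      "), ", nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' Peak table of an MS2 spectrum
#'
#' @param x An `ms2_spectrum`.
#' @param ... Unused.
#' @return Tibble of `mz`, `intensity`.
#' @method tidy ms2_spectrum
#' @export
tidy.ms2_spectrum <- function(x, ...) x$peaks

# default fragment ion convention per polarity: [F+H]+ / [F-H]-
fragment_ion_adduct <- function(polarity) {
  if (polarity == "negative") "[M-H]-" else "[M+H]+"
}

#' Annotate an MS2 spectrum with in-silico fragments
#'
#' Computes each fragment's ion m/z under the adduct convention
#' (`[F+H]+` in positive mode, `[F-H]-` in negative mode by default) and
#' matches spectrum peaks to fragment ions within a ppm tolerance. Each
#' peak receives at most one annotation: ties are resolved by smallest
#' absolute ppm error, then fewest bonds broken, then smallest absolute
#' hydrogen shift.
#'
#' @param spectrum An [ms2_spectrum()].
#' @param fragments Fragment tibble from [generate_fragments()].
#' @param tol_ppm Match tolerance in ppm (default 30).
#' @param adduct Fragment ion adduct; defaults to the polarity convention.
#' @return A tibble of class `ms2_annotation` with one row per spectrum
#'   peak: `peak_idx`, `mz`, `intensity`, `rel_intensity`, `matched`,
#'   `formula`, `h_shift`, `fragment_mz`, `ppm_error`, `bonds_broken`.
#' @export
annotate_spectrum <- function(spectrum, fragments, tol_ppm = 30,
                              adduct = NULL) {
  stopifnot(inherits(spectrum, "ms2_spectrum"), tol_ppm > 0)
  if (!is.data.frame(fragments) || nrow(fragments) == 0) {
    abort("no fragments supplied")
  }
  a <- resolve_adduct(adduct %||% fragment_ion_adduct(spectrum$polarity))
  frag_mz <- (fragments$neutral_mass + a$delta_mass) / abs(a$charge)
  peaks <- spectrum$peaks
  base <- max(peaks$intensity)
  rows <- purrr::map(seq_len(nrow(peaks)), function(i) {
    mz_i <- peaks$mz[i]
    ppm <- (mz_i - frag_mz) / frag_mz * 1e6
    hits <- which(abs(ppm) <= tol_ppm & frag_mz > 0)
    if (length(hits) == 0) {
      return(tibble(
        peak_idx = i, mz = mz_i, intensity = peaks$intensity[i],
        rel_intensity = if (base > 0) peaks$intensity[i] / base else 0,
        matched = FALSE, formula = NA_character_, h_shift = NA_integer_,
        fragment_mz = NA_real_, ppm_error = NA_real_,
        bonds_broken = NA_integer_
      ))
    }
    ord <- order(abs(ppm[hits]), fragments$bonds_broken[hits],
                 abs(fragments$h_shift[hits]))
    best <- hits[ord[1]]
    tibble(
      peak_idx = i, mz = mz_i, intensity = peaks$intensity[i],
      rel_intensity = if (base > 0) peaks$intensity[i] / base else 0,
      matched = TRUE, formula = fragments$formula[best],
      h_shift = fragments$h_shift[best], fragment_mz = frag_mz[best],
      ppm_error = ppm[best], bonds_broken = fragments$bonds_broken[best]
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("ms2_annotation", class(out))
  attr(out, "tol_ppm") <- tol_ppm
  attr(out, "adduct") <- a$name
  out
}

#' MS2 candidate raw score from an annotated spectrum
#'
#' Matched peaks contribute `rel_intensity^int_exp * mz^mz_exp` (MetFrag-
#' style weighting; defaults 0.6 and 3), where relative intensity is
#' normalized to the spectrum base peak. Unmatched peaks contribute zero.
#'
#' @param annotation An `ms2_annotation` from [annotate_spectrum()].
#' @param int_exp,mz_exp Weighting exponents.
#' @return A non-negative raw score.
#' @export
score_ms2_candidate <- function(annotation, int_exp = 0.6, mz_exp = 3) {
  stopifnot(is.data.frame(annotation))
  hit <- annotation[annotation$matched, , drop = FALSE]
  if (nrow(hit) == 0) return(0)
  sum(hit$rel_intensity^int_exp * hit$mz^mz_exp)
}

#' Rank candidate structures by in-silico MS2 agreement
#'
#' Fragments every candidate structure, annotates the experimental spectrum
#' and scores each candidate; scores are normalized by the best raw score
#' so the top candidate reports 1.0.
#'
#' @param candidates Data frame with columns `label` and `smiles`.
#' @param spectrum An [ms2_spectrum()].
#' @param tol_ppm MS2 match tolerance in ppm (default 30).
#' @param max_bond_breaks,max_tree_depth,h_window Passed to
#'   [generate_fragments()].
#' @param int_exp,mz_exp Passed to [score_ms2_candidate()].
#' @param adduct Optional fragment-ion adduct override.
#' @return A tibble with one row per candidate: `label`, `n_matched`,
#'   `raw_score`, `score` (normalized to `[0, 1]`), and dense 1-based
#'   `rank` (normalized score descending, label ascending on ties). When
#'   every raw score is zero all normalized scores are 0 and a warning is
#'   emitted.
#' @export
rank_ms2_candidates <- function(candidates, spectrum, tol_ppm = 30,
                                max_bond_breaks = 2, max_tree_depth = 2,
                                h_window = 2, int_exp = 0.6, mz_exp = 3,
                                adduct = NULL) {
  stopifnot(is.data.frame(candidates),
            all(c("label", "smiles") %in% names(candidates)))
  if (nrow(candidates) == 0) abort("no candidates supplied")
  if (anyDuplicated(candidates$label)) abort("duplicate candidate labels")
  rows <- purrr::map(seq_len(nrow(candidates)), function(i) {
    frags <- generate_fragments(candidates$smiles[i], max_bond_breaks,
                                max_tree_depth, h_window)
    ann <- annotate_spectrum(spectrum, frags, tol_ppm, adduct)
    tibble(
      label = candidates$label[i],
      n_matched = sum(ann$matched),
      raw_score = score_ms2_candidate(ann, int_exp, mz_exp)
    )
  })
  out <- bind_rows(rows)
  best <- max(out$raw_score)
  if (best <= 0) {
    warn("no candidate matched any peak; all MS2 scores are zero")
    out$score <- 0
  } else {
    out$score <- out$raw_score / best
  }
  out <- arrange(out, desc(score), label)
  out$rank <- seq_len(nrow(out))
  out
}
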