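#' Default element bounds for formula enumeration
#'
#' Builds per-element count bounds for [enumerate_formulas()]. The default
#' element set is CHNOPS with maxima scaled to the target mass (every count
#' whose isotopic mass still fits below the mass is allowed), i.e. the
#' bounds are deliberately loose and completeness is left to enumeration.
#'
#' @param mass Neutral mass (Da) the bounds should cover.
#' @param elements Character vector of element symbols.
#' @return A tibble with columns `element`, `min_count`, `max_count`.
#' @export
element_bounds <- function(mass, elements = c("C", "H", "N", "O", "P", "S")) {
  unknown <- setdiff(elements, names(.isotope_table))
  if (length(unknown) > 0) {
    abort(paste0("unknown element symbol(s): ", paste(unknown, collapse = ", ")))
  }
  tibble(
    element = elements,
    min_count = 0L,
    max_count = as.integer(floor(mass * (1 + 1e-4) / .monoisotopic[elements]))
  )
}

#' Enumerate elemental formulas consistent with a neutral mass
#'
#' Complete enumeration of all formulas within the given per-element bounds
#' whose monoisotopic mass falls within `tol_ppm` of `neutral_mass`.
#' Elements are expanded one at a time in order of decreasing atomic mass
#' with cumulative-mass pruning; the final (lightest) element count range is
#' solved directly, so the search is exact and complete relative to the
#' bounds.
#'
#' @param neutral_mass Target neutral monoisotopic mass (Da), > 0.
#' @param tol_ppm Mass tolerance in ppm, > 0.
#' @param bounds Element bounds tibble as from [element_bounds()]; defaults
#'   to CHNOPS bounds at `neutral_mass`.
#' @param max_candidates Safety cap on the number of partial assemblies; an
#'   error suggests tightening the bounds when exceeded.
#' @return A tibble with columns `formula`, `mass`, `ppm_error`, sorted by
#'   increasing `abs(ppm_error)`. Zero rows when nothing fits.
#' @examples
#' enumerate_formulas(18.010565, 5)
#' @export
enumerate_formulas <- function(neutral_mass, tol_ppm, bounds = NULL,
                               max_candidates = 2e6) {
  stopifnot(neutral_mass > 0, tol_ppm > 0)
  if (is.null(bounds)) bounds <- element_bounds(neutral_mass)
  if (!is.data.frame(bounds) ||
      !all(c("element", "min_count", "max_count") %in% names(bounds)) ||
      nrow(bounds) == 0) {
    abort("bounds must be a non-empty tibble with element/min_count/max_count")
  }
  if (any(bounds$min_count > bounds$max_count) || any(bounds$min_count < 0)) {
    abort("invalid bounds: need 0 <= min_count <= max_count")
  }
  lo <- neutral_mass * (1 - tol_ppm * 1e-6)
  hi <- neutral_mass * (1 + tol_ppm * 1e-6)
  masses <- .monoisotopic[bounds$element]
  ord <- order(masses, decreasing = TRUE) # heaviest first, lightest solved last
  elems <- bounds$element[ord]
  emass <- unname(masses[ord])
  emin <- bounds$min_count[ord]
  emax <- bounds$max_count[ord]
  n_el <- length(elems)

  # progressive expansion: matrix of partial count assemblies + running mass
  partial <- matrix(0L, nrow = 1, ncol = 0)
  pmass <- 0
  for (k in seq_len(max(n_el - 1, 0))) {
    counts <- emin[k]:emax[k]
    nc <- length(counts)
    np <- length(pmass)
    if (np * nc > max_candidates) {
      abort("formula search space too large; tighten the element bounds")
    }
    newmass <- rep(pmass, each = nc) + rep(counts * emass[k], times = np)
    # prune: remaining elements can only add mass (min counts add a floor)
    min_rest <- sum(emin[(k + 1):n_el] * emass[(k + 1):n_el])
    keep <- newmass + min_rest <= hi
    partial <- cbind(
      partial[rep(seq_len(np), each = nc), , drop = FALSE],
      rep(counts, times = np)
    )[keep, , drop = FALSE]
    pmass <- newmass[keep]
    if (length(pmass) == 0) break
  }

  if (length(pmass) == 0 && n_el > 1) {
    return(tibble(formula = character(), mass = numeric(), ppm_error = numeric()))
  }
  # solve the last (lightest) element count range directly per partial row
  last <- n_el
  cmin <- pmax(emin[last], ceiling((lo - pmass) / emass[last] - 1e-9))
  cmax <- pmin(emax[last], floor((hi - pmass) / emass[last] + 1e-9))
  ok <- which(cmin <= cmax)
  rows <- list()
  for (i in ok) {
    for (cl in cmin[i]:cmax[i]) {
      m <- pmass[i] + cl * emass[last]
      if (m < lo || m > hi) next
      cnt <- c(if (ncol(partial) > 0) setNames(partial[i, ], elems[seq_len(n_el - 1)]),
               setNames(cl, elems[last]))
      cnt <- cnt[cnt > 0]
      if (length(cnt) == 0) next
      rows[[length(rows) + 1]] <- tibble(
        formula = format_formula(cnt),
        mass = m,
        ppm_error = (m - neutral_mass) / neutral_mass * 1e6
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(formula = character(), mass = numeric(), ppm_error = numeric()))
  }
  out <- bind_rows(rows)
  # the signed ppm convention here is (candidate - target)/target; callers
  # that compare observed vs theoretical flip via ppm_error() directly
  arrange(out, abs(ppm_error), formula)
}

#' Isotope-pattern agreement score
#'
#' Normalized L1 agreement between an observed and a theoretical
#' base-peak-normalized isotope pattern over the first `k` aligned
#' isotopologues: `1 - sum(|obs - theo|) / sum(theo)`, clipped to `[0, 1]`.
#' The score is 1 exactly when the patterns agree over the compared window
#' and decreases toward 0 as they diverge.
#'
#' @param observed,theoretical Tibbles with an `abundance` column (base peak
#'   = 1), as from [isotope_pattern()]; isotopologues aligned by position.
#' @param k Number of isotopologues to compare; defaults to the theoretical
#'   pattern length.
#' @return A score in `[0, 1]`.
#' @export
isotope_fit_score <- function(observed, theoretical, k = NULL) {
  obs <- if (is.data.frame(observed)) observed$abundance else as.numeric(observed)
  theo <- if (is.data.frame(theoretical)) theoretical$abundance else as.numeric(theoretical)
  if (length(obs) == 0 || length(theo) == 0) abort("empty isotope pattern")
  if (is.null(k)) k <- length(theo)
  pad <- function(x) c(x, rep(0, max(0, k - length(x))))[seq_len(k)]
  obs <- pad(obs)
  theo <- pad(theo)
  score <- 1 - sum(abs(obs - theo)) / sum(theo)
  min(max(score, 0), 1)
}

#' Infer candidate elemental formulas for accurate-mass features
#'
#' For each feature row, recovers the neutral mass through the declared
#' adduct, enumerates all formulas within `tol_ppm`, applies the RDBE
#' plausibility filter (drop RDBE < 0 or non-integer RDBE), and ranks
#' candidates by isotope-pattern fit (when an isotope envelope is supplied)
#' and then by absolute ppm error.
#'
#' @param features A data frame with columns `mz` and `adduct` (adduct name,
#'   see [adducts()]); optional `feature_id` and `envelope` (either a
#'   list-column of tibbles with `mass`/`abundance`, or a string
#'   `"mass:abundance;mass:abundance;..."`).
#' @param tol_ppm Mass tolerance in ppm (default 10).
#' @param bounds Optional element bounds tibble (per call, shared across
#'   features); defaults to CHNOPS bounds at each feature's neutral mass.
#' @param rdbe_filter Apply the RDBE plausibility filter (default TRUE).
#' @param envelope_k Number of isotopologues used in the fit score.
#' @return A tibble with one row per (feature, candidate): `feature_id`,
#'   `formula`, `mass`, `ppm_error`, `rdbe`, `isotope_score` (NA without an
#'   envelope) and dense 1-based `rank` within each feature. Features with
#'   no candidate in tolerance contribute zero rows and raise a warning.
#' @examples
#' feats <- tibble::tibble(mz = adduct_mz("C5H11NO2"), adduct = "[M+H]+")
#' infer_formula(feats, tol_ppm = 5)
#' @export
infer_formula <- function(features, tol_ppm = 10, bounds = NULL,
                          rdbe_filter = TRUE, envelope_k = 3) {
  stopifnot(is.data.frame(features), all(c("mz", "adduct") %in% names(features)))
  if (!"feature_id" %in% names(features)) {
    features$feature_id <- paste0("F", seq_len(nrow(features)))
  }
  out <- purrr::map(seq_len(nrow(features)), function(i) {
    row <- features[i, ]
    nm <- neutral_mass(row$mz, row$adduct)
    if (nm <= 0) {
      warn(paste0("feature ", row$feature_id, ": non-positive neutral mass"))
      return(NULL)
    }
    b <- if (is.null(bounds)) element_bounds(nm) else bounds
    cand <- enumerate_formulas(nm, tol_ppm, b)
    if (nrow(cand) == 0) {
      warn(paste0("feature ", row$feature_id,
                  ": no formula within ", tol_ppm, " ppm"))
      return(NULL)
    }
    cand$rdbe <- rdbe(cand$formula)
    if (rdbe_filter) {
      cand <- cand[cand$rdbe >= 0 & cand$rdbe %% 1 == 0, , drop = FALSE]
    }
    if (nrow(cand) == 0) {
      warn(paste0("feature ", row$feature_id,
                  ": all candidates removed by RDBE filter"))
      return(NULL)
    }
    env <- extract_envelope(row)
    if (is.null(env)) {
      cand$isotope_score <- NA_real_
      cand <- arrange(cand, abs(ppm_error), formula)
    } else {
      cand$isotope_score <- unname(vapply(cand$formula, function(f) {
        isotope_fit_score(env, isotope_pattern(f, envelope_k), k = envelope_k)
      }, numeric(1)))
      cand <- arrange(cand, desc(isotope_score), abs(ppm_error), formula)
    }
    cand$rank <- seq_len(nrow(cand))
    cand$feature_id <- row$feature_id
    select(cand, feature_id, formula, mass, ppm_error, rdbe, isotope_score, rank)
  })
  bind_rows(out)
}

# envelope from a list-column of tibbles or a "mass:abund;..." string
extract_envelope <- function(row) {
  if (!"envelope" %in% names(row)) return(NULL)
  env <- row$envelope
  if (is.list(env) && !is.data.frame(env)) env <- env[[1]]
  if (is.null(env) || (is.atomic(env) && length(env) == 1 && is.na(env))) {
    return(NULL)
  }
  if (is.character(env)) {
    if (!nzchar(env)) return(NULL)
    parts <- strsplit(strsplit(env, ";")[[1]], ":")
    env <- tibble(
      mass = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
      abundance = vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    )
  }
  if (!is.data.frame(env) || nrow(env) == 0) return(NULL)
  env$abundance <- env$abundance / max(env$abundance)
  env
}
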