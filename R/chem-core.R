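#' Parse an elemental formula string
#'
#' Parses a Hill-notation-like formula such as `"C5H11NO2"` into a named
#' integer vector of element counts. Multi-digit counts and two-letter
#' element symbols (`Cl`, `Br`, ...) are supported.
#'
#' @param text A single formula string.
#' @return Named integer vector of element counts, e.g. `c(C = 5, H = 11,
#'   N = 1, O = 2)`, ordered canonically (Hill order).
#' @examples
#' parse_formula("C5H11NO2")
#' parse_formula("H2O")
#' @seealso [format_formula()], [monoisotopic_mass()]
#' @export
parse_formula <- function(text) {
  if (is.list(text) || (is.numeric(text) && !is.null(names(text)))) {
    return(as_formula_counts(text))
  }
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) {
    abort("empty formula string")
  }
  tokens <- stringr::str_match_all(text, "([A-Z][a-z]?)(\\d*)")[[1]]
  consumed <- paste0(tokens[, 1], collapse = "")
  if (!identical(consumed, text)) {
    abort(paste0("cannot parse formula '", text, "'"))
  }
  counts <- ifelse(tokens[, 3] == "", 1L, suppressWarnings(as.integer(tokens[, 3])))
  elements <- tokens[, 2]
  unknown <- setdiff(elements, names(.isotope_table))
  if (length(unknown) > 0) {
    abort(paste0("unknown element symbol(s): ", paste(unknown, collapse = ", ")))
  }
  out <- tapply(counts, elements, sum)
  out <- setNames(as.integer(out), names(out))
  out <- out[out > 0]
  if (length(out) == 0) abort("formula has no atoms")
  out[hill_order(names(out))]
}

# coerce named vector/list to validated counts
as_formula_counts <- function(f) {
  if (is.character(f)) return(parse_formula(f))
  counts <- unlist(f)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort("formula counts must be named by element symbol")
  }
  unknown <- setdiff(names(counts), names(.isotope_table))
  if (length(unknown) > 0) {
    abort(paste0("unknown element symbol(s): ", paste(unknown, collapse = ", ")))
  }
  if (any(counts < 0)) abort("negative element count")
  counts <- setNames(as.integer(counts), names(counts))
  counts <- counts[counts > 0]
  if (length(counts) == 0) abort("formula has no atoms")
  counts[hill_order(names(counts))]
}

# Hill order: C first, H second, then alphabetical; no C -> all alphabetical
hill_order <- function(elements) {
  if ("C" %in% elements) {
    c(intersect(c("C", "H"), elements), sort(setdiff(elements, c("C", "H"))))
  } else {
    sort(elements)
  }
}

#' Format element counts as a Hill-notation formula string
#'
#' @param counts Named integer vector (or list) of element counts, or a
#'   formula string (returned canonicalized).
#' @return A single formula string in Hill order.
#' @examples
#' format_formula(c(O = 1, H = 2))
#' @export
format_formula <- function(counts) {
  counts <- as_formula_counts(counts)
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the mass of the element's most abundant
#' isotope. Vectorized over formula strings.
#'
#' @param formula Character vector of formula strings, or a single named
#'   count vector.
#' @return Numeric vector of masses in Da.
#' @examples
#' monoisotopic_mass("C5H11NO2")
#' monoisotopic_mass(c("H2O", "C6H6"))
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) {
    return(vapply(formula, function(x) {
      cnt <- parse_formula(x)
      sum(.monoisotopic[names(cnt)] * cnt)
    }, numeric(1), USE.NAMES = FALSE))
  }
  cnt <- as_formula_counts(formula)
  sum(.monoisotopic[names(cnt)] * cnt)
}

#' Built-in adduct definitions
#'
#' Returns the table of supported ionization adducts. `delta_mass` is the
#' signed mass added to the neutral molecule (protonation uses the proton
#' mass 1.00727646 Da, not the hydrogen-atom mass).
#'
#' @return A tibble with columns `name`, `delta_mass`, `charge`, `polarity`.
#' @examples
#' adducts()
#' @export
adducts <- function() {
  pr <- mass_constants[["proton"]]
  na <- .monoisotopic[["Na"]] - mass_constants[["electron"]]
  k <- .monoisotopic[["K"]] - mass_constants[["electron"]]
  nh4 <- monoisotopic_mass("NH4") - mass_constants[["electron"]]
  tibble(
    name = c("[M+H]+", "[M-H]-", "[M+Na]+", "[M+K]+", "[M+NH4]+",
             "[M+2H]2+", "[M-2H]2-"),
    delta_mass = c(pr, -pr, na, k, nh4, 2 * pr, -2 * pr),
    charge = c(1L, -1L, 1L, 1L, 1L, 2L, -2L),
    polarity = c("positive", "negative", "positive", "positive", "positive",
                 "positive", "negative")
  )
}

# resolve an adduct given by name (unicode minus tolerated) or as a list
resolve_adduct <- function(adduct) {
  if (is.list(adduct)) {
    stopifnot(all(c("name", "delta_mass", "charge") %in% names(adduct)))
    if (adduct$charge == 0) abort("adduct charge must be non-zero")
    return(adduct)
  }
  stopifnot(is.character(adduct), length(adduct) == 1)
  name <- gsub("−", "-", adduct)
  tab <- adducts()
  hit <- which(tab$name == name)
  if (length(hit) != 1) {
    abort(paste0("unknown adduct '", adduct, "'; see adducts()"))
  }
  as.list(tab[hit, ])
}

#' m/z of an ionized formula
#'
#' @param formula Formula string (or named counts) of the neutral molecule.
#' @param adduct Adduct name such as `"[M+H]+"` or `"[M-H]-"` (see
#'   [adducts()]), or a list with `delta_mass` and `charge`.
#' @return m/z value: `(monoisotopic_mass + delta_mass) / |charge|`.
#' @examples
#' adduct_mz("C9H11NO2", "[M+H]+")
#' @export
adduct_mz <- function(formula, adduct = "[M+H]+") {
  a <- resolve_adduct(adduct)
  (monoisotopic_mass(formula) + a$delta_mass) / abs(a$charge)
}

#' Neutral monoisotopic mass recovered from an observed m/z
#'
#' @param mz Observed m/z.
#' @param adduct Adduct name or definition (see [adducts()]).
#' @return Neutral mass in Da.
#' @export
neutral_mass <- function(mz, adduct = "[M+H]+") {
  a <- resolve_adduct(adduct)
  mz * abs(a$charge) - a$delta_mass
}

#' Relative mass error in parts per million
#'
#' `ppm_error()` returns the signed relative deviation; `truncated_abs_ppm()`
#' returns the floor of its absolute value, the convention used when
#' reporting integer ppm columns (5.51 ppm prints as 5, 0.85 ppm as 0).
#'
#' @param observed Observed m/z (vectorized).
#' @param theoretical Theoretical m/z (> 0).
#' @return Signed ppm (numeric), or truncated absolute ppm (integer).
#' @examples
#' ppm_error(118.0850, adduct_mz("C5H11NO2"))
#' truncated_abs_ppm(118.0850, adduct_mz("C5H11NO2"))
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) abort("theoretical m/z must be > 0")
  (observed - theoretical) / theoretical * 1e6
}

#' @rdname ppm_error
#' @export
truncated_abs_ppm <- function(observed, theoretical) {
  as.integer(floor(abs(ppm_error(observed, theoretical))))
}

#' Ring-plus-double-bond equivalents
#'
#' RDBE = C + 1 + (N - H - halogens)/2; oxygen, sulfur and phosphorus are
#' treated as divalent/neutral contributors (0). Closed-shell neutral
#' molecules have integer RDBE >= 0.
#'
#' @param formula Formula string(s) or named counts.
#' @return Numeric vector of RDBE values.
#' @examples
#' rdbe("C9H11NO2") # 5
#' rdbe("C6H6")     # 4
#' @export
rdbe <- function(formula) {
  one <- function(x) {
    cnt <- as_formula_counts(x)
    get0 <- function(e) if (e %in% names(cnt)) cnt[[e]] else 0L
    hal <- sum(vapply(.halogens, get0, integer(1)))
    get0("C") + 1 + (get0("N") - get0("H") - hal) / 2
  }
  if (is.character(formula)) {
    vapply(formula, one, numeric(1), USE.NAMES = FALSE)
  } else {
    one(formula)
  }
}

#' Theoretical isotope pattern of a formula
#'
#' Computes the isotopologue distribution aggregated at nominal-mass
#' (neutron-count) resolution by repeated convolution of the per-element
#' isotope distributions, then normalizes to base peak = 1. Fine structure
#' within a nominal mass is merged; each aggregated isotopologue's mass is
#' the abundance-weighted mean of its contributors. This resolution is
#' appropriate for Q-TOF class instruments.
#'
#' @param formula Formula string or named counts.
#' @param max_isotopologues Number of isotopologues (M, M+1, ...) to keep.
#' @return A tibble with columns `shift` (neutron count), `mass` (Da) and
#'   `abundance` (base peak = 1), sorted by increasing mass, zero-abundance
#'   entries dropped.
#' @examples
#' isotope_pattern("C6H12O6")
#' @export
isotope_pattern <- function(formula, max_isotopologues = 5) {
  stopifnot(max_isotopologues >= 1)
  cnt <- as_formula_counts(formula)
  kmax <- max_isotopologues + 3 # headroom before truncation
  # distribution as two vectors indexed by neutron shift 0..kmax:
  # prob and conditional mean mass
  dist <- list(prob = c(1, rep(0, kmax)), mass = rep(0, kmax + 1))
  for (el in names(cnt)) {
    iso <- .isotope_table[[el]]
    shifts <- round(iso$mass - iso$mass[1])
    atom <- list(prob = rep(0, kmax + 1), mass = rep(0, kmax + 1))
    keep <- shifts <= kmax
    atom$prob[shifts[keep] + 1] <- iso$abundance[keep]
    atom$mass[shifts[keep] + 1] <- iso$mass[keep]
    for (i in seq_len(cnt[[el]])) {
      dist <- convolve_iso(dist, atom, kmax)
    }
  }
  out <- tibble(
    shift = 0:kmax,
    mass = dist$mass,
    abundance = dist$prob
  )
  out <- out[out$abundance > 0, , drop = FALSE]
  out <- out[seq_len(min(nrow(out), max_isotopologues)), , drop = FALSE]
  out$abundance <- out$abundance / max(out$abundance)
  as_tibble(out)
}

# convolve two shift-indexed isotopologue distributions, tracking
# probability-weighted mean masses per aggregated shift
convolve_iso <- function(a, b, kmax) {
  prob <- rep(0, kmax + 1)
  mass <- rep(0, kmax + 1)
  for (i in 0:kmax) {
    if (a$prob[i + 1] == 0) next
    js <- 0:(kmax - i)
    pj <- a$prob[i + 1] * b$prob[js + 1]
    prob[i + js + 1] <- prob[i + js + 1] + pj
    mass[i + js + 1] <- mass[i + js + 1] + pj * (a$mass[i + 1] + b$mass[js + 1])
  }
  nz <- prob > 0
  mass[nz] <- mass[nz] / prob[nz]
  list(prob = prob, mass = mass)
}
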