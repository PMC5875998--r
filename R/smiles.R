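# A small SMILES reader covering the subset needed for metabolite-scale
# structures: organic-subset atoms (B C N O P S F Cl Br I, aromatic
# b c n o p s), bracket atoms with isotope/charge/explicit H, single,
# double, triple and aromatic bonds, branches and ring closures (including
# %nn). Stereo markers (/ \ @) are accepted and ignored. Implicit hydrogens
# follow the SMILES valence rules (lowest standard valence >= bond-order
# sum; aromatic atoms contribute one extra to the bond-order sum).

.default_valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

#' Parse a SMILES string into a molecular graph
#'
#' Builds an explicit heavy-atom graph with implicit hydrogen counts
#' assigned by standard valence rules. Supports the organic subset,
#' aromatic (lowercase) atoms, bracket atoms with charges and explicit
#' hydrogens, branches and ring-bond closures. Stereochemistry is ignored.
#'
#' @param smiles A single SMILES string describing a connected molecule.
#' @return An object of class `mol_graph`: a list with `atoms` (tibble:
#'   `idx`, `element`, `aromatic`, `charge`, `n_h` implicit+explicit
#'   hydrogens) and `bonds` (tibble: `a1`, `a2`, `order`, `aromatic`), plus
#'   the input `smiles`.
#' @examples
#' mol <- parse_smiles("CC(C)C(N)C(O)=O") # valine
#' molecular_formula(mol)
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (!nzchar(smiles)) abort("empty SMILES string")
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  atoms <- list()
  bonds <- list()
  stack <- integer() # branch stack of atom indices
  prev <- NA_integer_
  pending_bond <- NA_character_ # explicit bond symbol awaiting next atom
  ring <- list() # ring-closure digit -> list(atom, bond)
  i <- 1

  add_atom <- function(element, aromatic, charge = 0L, explicit_h = NA_integer_) {
    atoms[[length(atoms) + 1]] <<- list(
      element = element, aromatic = aromatic,
      charge = charge, explicit_h = explicit_h
    )
    length(atoms)
  }
  add_bond <- function(a1, a2, sym) {
    aromatic_bond <- FALSE
    if (is.na(sym)) {
      if (atoms[[a1]]$aromatic && atoms[[a2]]$aromatic) {
        aromatic_bond <- TRUE
        order <- 1
      } else {
        order <- 1
      }
    } else {
      order <- switch(sym, "-" = 1, "=" = 2, "#" = 3, ":" = 1,
                      "/" = 1, "\\" = 1,
                      abort(paste0("unsupported bond symbol '", sym, "'")))
      if (sym == ":") aromatic_bond <- TRUE
    }
    bonds[[length(bonds) + 1]] <<- list(
      a1 = a1, a2 = a2, order = order, aromatic = aromatic_bond
    )
  }
  close_or_open_ring <- function(key, atom_idx, bond_sym) {
    if (!is.null(ring[[key]])) {
      open <- ring[[key]]
      sym <- if (!is.na(bond_sym)) bond_sym else open$bond
      add_bond(open$atom, atom_idx, sym)
      ring[[key]] <<- NULL
    } else {
      ring[[key]] <- list(atom = atom_idx, bond = bond_sym)
      ring <<- ring
    }
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch
      i <- i + 1
    } else if (ch == "(") {
      if (is.na(prev)) abort("branch opened before any atom")
      stack <- c(stack, prev)
      i <- i + 1
    } else if (ch == ")") {
      if (length(stack) == 0) abort("unmatched ')' in SMILES")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (is.na(prev)) abort("ring closure before any atom")
      if (ch == "%") {
        if (i + 2 > n) abort("truncated %nn ring closure")
        key <- paste0(chars[i + 1], chars[i + 2])
        i <- i + 3
      } else {
        key <- ch
        i <- i + 1
      }
      close_or_open_ring(key, prev, pending_bond)
      pending_bond <- NA_character_
    } else if (ch == "[") {
      close_idx <- i
      while (close_idx <= n && chars[close_idx] != "]") close_idx <- close_idx + 1
      if (close_idx > n) abort("unmatched '[' in SMILES")
      body <- paste0(chars[(i + 1):(close_idx - 1)], collapse = "")
      at <- parse_bracket_atom(body, smiles)
      idx <- add_atom(at$element, at$aromatic, at$charge, at$explicit_h)
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      pending_bond <- NA_character_
      prev <- idx
      i <- close_idx + 1
    } else if (ch == ".") {
      abort("disconnected SMILES ('.') not supported; supply one structure")
    } else {
      # organic-subset atom, possibly two letters (Cl, Br)
      two <- if (i < n) paste0(ch, chars[i + 1]) else ""
      if (two %in% c("Cl", "Br")) {
        element <- two
        aromatic <- FALSE
        i <- i + 2
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        element <- ch
        aromatic <- FALSE
        i <- i + 1
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        element <- toupper(ch)
        aromatic <- TRUE
        i <- i + 1
      } else {
        abort(paste0("cannot parse SMILES '", smiles, "' at character '",
                     ch, "' (position ", i, ")"))
      }
      idx <- add_atom(element, aromatic)
      if (!is.na(prev)) add_bond(prev, idx, pending_bond)
      pending_bond <- NA_character_
      prev <- idx
    }
  }
  if (length(stack) > 0) abort("unmatched '(' in SMILES")
  if (length(ring) > 0) abort("unclosed ring bond in SMILES")
  if (length(atoms) == 0) abort(paste0("no atoms in SMILES '", smiles, "'"))

  atoms_df <- tibble(
    idx = seq_along(atoms),
    element = vapply(atoms, `[[`, character(1), "element"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    charge = vapply(atoms, `[[`, integer(1), "charge"),
    explicit_h = vapply(atoms, `[[`, integer(1), "explicit_h")
  )
  bonds_df <- if (length(bonds) > 0) {
    tibble(
      a1 = vapply(bonds, `[[`, numeric(1), "a1"),
      a2 = vapply(bonds, `[[`, numeric(1), "a2"),
      order = vapply(bonds, `[[`, numeric(1), "order"),
      aromatic = vapply(bonds, `[[`, logical(1), "aromatic")
    )
  } else {
    tibble(a1 = numeric(), a2 = numeric(), order = numeric(),
           aromatic = logical())
  }
  atoms_df$n_h <- implicit_hydrogens(atoms_df, bonds_df)
  mol <- structure(
    list(atoms = atoms_df, bonds = bonds_df, smiles = smiles),
    class = "mol_graph"
  )
  if (nrow(atoms_df) > 1 && !mol_connected(mol)) {
    abort(paste0("SMILES '", smiles, "' is not a connected structure"))
  }
  mol
}

# [body] of a bracket atom: isotope? symbol stereo? Hcount? charge? class?
parse_bracket_atom <- function(body, smiles) {
  m <- stringr::str_match(
    body,
    "^(\\d*)([A-Z][a-z]?|[bcnops])(@{0,2})(H\\d*)?([+-]\\d*|[+]+|[-]+)?(:\\d+)?$"
  )
  if (is.na(m[1, 1])) {
    abort(paste0("cannot parse bracket atom '[", body, "]' in '", smiles, "'"))
  }
  sym <- m[1, 3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
  element <- if (aromatic) toupper(sym) else sym
  if (!element %in% names(.isotope_table)) {
    abort(paste0("unsupported element '", element, "' in '", smiles, "'"))
  }
  hspec <- m[1, 5]
  explicit_h <- if (is.na(hspec) || !nzchar(hspec)) {
    0L
  } else if (hspec == "H") {
    1L
  } else {
    as.integer(sub("H", "", hspec))
  }
  cspec <- m[1, 6]
  charge <- if (is.na(cspec) || !nzchar(cspec)) {
    0L
  } else if (cspec %in% c("+", "-") || grepl("^[+]+$|^[-]+$", cspec)) {
    as.integer(nchar(cspec)) * (if (substr(cspec, 1, 1) == "+") 1L else -1L)
  } else {
    as.integer(paste0(substr(cspec, 1, 1), sub("^[+-]", "", cspec)))
  }
  list(element = element, aromatic = aromatic, charge = charge,
       explicit_h = explicit_h)
}

# implicit hydrogen count per atom; bracket atoms carry their explicit count
implicit_hydrogens <- function(atoms, bonds) {
  bond_sum <- rep(0, nrow(atoms))
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      o <- bonds$order[r]
      bond_sum[bonds$a1[r]] <- bond_sum[bonds$a1[r]] + o
      bond_sum[bonds$a2[r]] <- bond_sum[bonds$a2[r]] + o
    }
  }
  vapply(seq_len(nrow(atoms)), function(i) {
    if (!is.na(atoms$explicit_h[i])) return(atoms$explicit_h[i])
    el <- atoms$element[i]
    val <- .default_valences[[el]]
    if (is.null(val)) return(0L) # non-organic-subset: no implicit H
    bs <- bond_sum[i] + as.integer(atoms$aromatic[i])
    fit <- val[val >= bs]
    if (length(fit) == 0) return(0L)
    as.integer(fit[1] - bs)
  }, integer(1))
}

mol_connected <- function(mol) {
  g <- mol_igraph(mol)
  igraph::is_connected(g)
}

# igraph view of the heavy-atom graph
mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = mol$bonds[, c("a1", "a2")],
    directed = FALSE,
    vertices = data.frame(name = mol$atoms$idx)
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles, "\n  ",
      nrow(x$atoms), " heavy atoms, ", nrow(x$bonds), " bonds, formula ",
      molecular_formula(x), "\n", sep = "")
  invisible(x)
}

#' Molecular formula of a parsed structure
#'
#' Element counts over heavy atoms plus implicit/explicit hydrogens, in
#' Hill notation. The net formal charge is ignored in the formula string.
#'
#' @param mol A `mol_graph` from [parse_smiles()], or a SMILES string.
#' @param atoms Optional integer vector of atom indices restricting the
#'   formula to a substructure (implicit hydrogens of those atoms are
#'   retained).
#' @return A formula string.
#' @examples
#' molecular_formula("c1ccccc1")
#' @export
molecular_formula <- function(mol, atoms = NULL) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  at <- mol$atoms
  if (!is.null(atoms)) at <- at[at$idx %in% atoms, , drop = FALSE]
  if (nrow(at) == 0) abort("no atoms selected")
  counts <- tapply(rep(1L, nrow(at)), at$element, sum)
  counts <- setNames(as.integer(counts), names(counts))
  nh <- sum(at$n_h)
  if (nh > 0) counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + nh
  format_formula(counts)
}
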