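# Independent oracles and fixture generators used across the suite.
# These deliberately avoid the code paths they check: the assignment oracle
# is a plain recursion (no igraph), the isotope oracle enumerates atom-wise
# isotope choices (no convolution), the formula oracle is a grid filter,
# and the bridge oracle finds cut edges by BFS.

# exhaustive one-to-one assignment: maximize matched pairs, then minimize
# total distance, over all injective predicted -> experimental maps
oracle_assignment <- function(dw, allowed) {
  np <- nrow(dw)
  ne <- ncol(dw)
  best <- list(n = -1L, total = Inf)
  rec <- function(p, used, n, total) {
    if (p > np) {
      if (n > best$n || (n == best$n && total < best$total - 1e-12)) {
        best <<- list(n = n, total = total)
      }
      return(invisible())
    }
    rec(p + 1L, used, n, total)
    for (e in seq_len(ne)) {
      if (allowed[p, e] && !used[e]) {
        used[e] <- TRUE
        rec(p + 1L, used, n + 1L, total + dw[p, e])
        used[e] <- FALSE
      }
    }
  }
  rec(1L, logical(ne), 0L, 0)
  best
}

# exhaustive isotopologue distribution for tiny molecules: every atom picks
# an isotope; aggregate probability and mean mass by total neutron shift
oracle_isotope_pattern <- function(counts, iso_table) {
  atoms <- rep(names(counts), counts)
  choices <- lapply(atoms, function(el) seq_along(iso_table[[el]]$mass))
  grid <- expand.grid(choices)
  shift_of <- function(el, i) {
    m <- iso_table[[el]]$mass
    round(m[i] - m[1])
  }
  agg <- list()
  for (r in seq_len(nrow(grid))) {
    prob <- 1
    mass <- 0
    shift <- 0
    for (a in seq_along(atoms)) {
      el <- atoms[a]
      i <- grid[r, a]
      prob <- prob * iso_table[[el]]$abundance[i]
      mass <- mass + iso_table[[el]]$mass[i]
      shift <- shift + shift_of(el, i)
    }
    key <- as.character(shift)
    prev <- agg[[key]]
    if (is.null(prev)) prev <- c(0, 0)
    agg[[key]] <- c(prev[[1]] + prob, prev[[2]] + prob * mass)
  }
  shifts <- sort(as.integer(names(agg)))
  prob <- vapply(as.character(shifts), function(k) agg[[k]][[1]], numeric(1))
  mass <- vapply(as.character(shifts), function(k) agg[[k]][[2]], numeric(1)) / prob
  list(shift = shifts, prob = prob, mass = mass)
}

# grid-filter formula enumeration over explicit per-element ranges
oracle_enumerate <- function(target, tol_ppm, ranges) {
  grid <- expand.grid(ranges)
  masses <- as.matrix(grid) %*% monoisotopic_mass(colnames(grid))[]
  # monoisotopic_mass of single-element symbols gives per-element masses
  lo <- target * (1 - tol_ppm * 1e-6)
  hi <- target * (1 + tol_ppm * 1e-6)
  hits <- which(masses >= lo & masses <= hi & rowSums(grid) > 0)
  sort(vapply(hits, function(r) {
    cnt <- unlist(grid[r, ])
    format_formula(cnt[cnt > 0])
  }, character(1)))
}

# bridge edges of a mol_graph by BFS reachability (no igraph)
oracle_bridge_fragments <- function(mol) {
  n <- nrow(mol$atoms)
  bonds <- mol$bonds
  reach <- function(start, skip_bond) {
    adj <- vector("list", n)
    for (b in seq_len(nrow(bonds))) {
      if (b == skip_bond) next
      adj[[bonds$a1[b]]] <- c(adj[[bonds$a1[b]]], bonds$a2[b])
      adj[[bonds$a2[b]]] <- c(adj[[bonds$a2[b]]], bonds$a1[b])
    }
    seen <- logical(n)
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    which(seen)
  }
  frags <- character()
  for (b in seq_len(nrow(bonds))) {
    side <- reach(bonds$a1[b], b)
    if (length(side) == n) next # ring bond, not a bridge
    other <- setdiff(seq_len(n), side)
    frags <- c(frags,
               molecular_formula(mol, atoms = side),
               molecular_formula(mol, atoms = other))
  }
  sort(unique(frags))
}

# random branched molecule (tree + optional single ring) as a SMILES string
random_smiles <- function(n_atoms, ring_prob = 0.3,
                          elements = c("C", "C", "C", "N", "O", "S")) {
  stopifnot(n_atoms >= 2)
  parent <- c(NA, vapply(2:n_atoms, function(i) sample.int(i - 1, 1), integer(1)))
  elem <- sample(elements, n_atoms, replace = TRUE)
  # O and S must stay divalent: force degree-heavy nodes to carbon
  deg <- tabulate(parent[!is.na(parent)], nbins = n_atoms) + (!is.na(parent))
  elem[deg > 2] <- "C"
  ring <- stats::runif(1) < ring_prob && n_atoms >= 4
  ring_pair <- NULL
  if (ring) {
    leaves <- which(tabulate(parent[!is.na(parent)], nbins = n_atoms) == 0)
    if (length(leaves) >= 2) {
      ring_pair <- sample(leaves, 2)
      elem[ring_pair] <- "C"
    }
  }
  children <- lapply(seq_len(n_atoms), function(i) which(parent == i))
  emit <- function(i) {
    s <- elem[i]
    if (!is.null(ring_pair) && i %in% ring_pair) s <- paste0(s, "1")
    kids <- children[[i]]
    if (length(kids) == 0) return(s)
    inner <- vapply(kids, emit, character(1))
    paste0(s, paste0("(", inner[-length(inner)], ")", collapse = ""),
           inner[length(inner)])
  }
  emit(1)
}

# random HSQC peak list over plausible shift ranges
random_peaks <- function(n, h_range = c(0.5, 9), c_range = c(10, 160)) {
  tibble::tibble(
    h_ppm = stats::runif(n, h_range[1], h_range[2]),
    c_ppm = stats::runif(n, c_range[1], c_range[2])
  )
}

# decoy list guaranteed outside the match cutoffs of every peak in `truth`
out_of_cutoff_decoy <- function(truth, max_dh = 0.5) {
  n <- nrow(truth)
  h <- truth$h_ppm + sample(c(-1, 1), n, replace = TRUE) *
    (max_dh + 0.2 + stats::runif(n, 0, 0.5))
  tibble::tibble(h_ppm = h, c_ppm = truth$c_ppm)
}

# the printed worked-example table: experimental [M+H]+ m/z, formula, and
# the published integer ppm deviation for ten common metabolites
reference_ppm_table <- function() {
  tibble::tibble(
    metabolite = c("phenylalanine", "valine", "nicotinate", "pantothenate",
                   "glutamine", "methionine", "isoleucine", "proline",
                   "thymidine", "leucine"),
    mz = c(166.0859, 118.0850, 124.0392, 220.1174, 147.0746,
           150.0575, 132.1016, 116.0703, 243.0971, 132.1018),
    formula = c("C9H11NO2", "C5H11NO2", "C6H5NO2", "C9H17NO5", "C5H10N2O3",
                "C5H11NO2S", "C6H13NO2", "C5H9NO2", "C10H14N2O5", "C6H13NO2"),
    ppm = c(2L, 10L, 0L, 2L, 12L, 5L, 2L, 2L, 1L, 0L)
  )
}

# isotope table accessor for oracle use
pkg_isotope_table <- function() {
  get(".isotope_table", envir = asNamespace("hybridrank"))
}
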