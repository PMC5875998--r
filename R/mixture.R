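#' Deconvolute an experimental HSQC into spin-system peak groups
#'
#' Builds a graph whose nodes are HSQC cross-peaks, with an edge between
#' two peaks whenever a TOCSY (or optional HMBC) cross-peak's two proton
#' shifts match the two HSQC peaks' proton shifts within `tol_h` (in either
#' orientation). The connected components of this graph are the peak
#' groups; in a mixture each group collects one metabolite's spin system.
#' Group ids `g1, g2, ...` are assigned by ascending minimum proton shift
#' of the group members, so the labelling is deterministic.
#'
#' @param hsqc Data frame with columns `h_ppm`, `c_ppm` (experimental).
#' @param tocsy Data frame with columns `h1_ppm`, `h2_ppm`; may have zero
#'   rows, in which case every HSQC peak is its own group.
#' @param tol_h Proton-shift matching tolerance in ppm (default 0.02).
#' @param hmbc Optional extra edge list in the same two-column format,
#'   merged into the same connectivity graph.
#' @return The `hsqc` tibble with an added `group` column; the groups
#'   partition the peaks.
#' @examples
#' hsqc <- tibble::tibble(h_ppm = c(3.60, 1.20, 0.95), c_ppm = c(60, 20, 15))
#' tocsy <- tibble::tibble(h1_ppm = c(3.60, 1.20), h2_ppm = c(1.20, 0.95))
#' group_peaks_by_connectivity(hsqc, tocsy)
#' @export
group_peaks_by_connectivity <- function(hsqc, tocsy = NULL, tol_h = 0.02,
                                        hmbc = NULL) {
  hsqc <- check_peaks(hsqc, "experimental HSQC")
  stopifnot(tol_h > 0)
  edges_from <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0) return(NULL)
    if (!all(c("h1_ppm", "h2_ppm") %in% names(tab))) {
      abort("connectivity table needs h1_ppm and h2_ppm columns")
    }
    out <- list()
    for (r in seq_len(nrow(tab))) {
      side1 <- which(abs(hsqc$h_ppm - tab$h1_ppm[r]) <= tol_h)
      side2 <- which(abs(hsqc$h_ppm - tab$h2_ppm[r]) <= tol_h)
      if (length(side1) == 0 || length(side2) == 0) next
      out[[length(out) + 1]] <- expand.grid(a = side1, b = side2)
    }
    if (length(out) == 0) return(NULL)
    bind_rows(out)
  }
  ed <- bind_rows(edges_from(tocsy), edges_from(hmbc))
  n <- nrow(hsqc)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(ed) && nrow(ed) > 0) {
    ed <- ed[ed$a != ed$b, , drop = FALSE]
    if (nrow(ed) > 0) {
      g <- igraph::add_edges(g, as.vector(rbind(ed$a, ed$b)))
    }
  }
  comp <- igraph::components(g)$membership
  min_h <- tapply(hsqc$h_ppm, comp, min)
  ord <- rank(min_h, ties.method = "first")
  hsqc$group <- paste0("g", ord[as.character(comp)])
  hsqc
}

#' Score all candidate-by-group pairs of a mixture
#'
#' Runs [match_hsqc()] for every combination of a predicted candidate peak
#' list and a deconvoluted experimental peak group, and orders all pairs
#' globally by matching ratio (descending) and mean weighted distance
#' (ascending), with label and group as deterministic tie-breaks. With one
#' group this reduces exactly to [rank_hsqc_candidates()].
#'
#' @param candidates Stacked predicted peak lists (`label`, `h_ppm`,
#'   `c_ppm`) or a named list of peak-list data frames. Candidate labels
#'   must be unique across all candidate sets.
#' @param grouped_hsqc Output of [group_peaks_by_connectivity()] (an
#'   experimental peak tibble with a `group` column).
#' @param config A [match_config()].
#' @return A tibble with one row per (candidate, group) pair: `label`,
#'   `group`, the [glance.hsqc_match()] summary columns, global 1-based
#'   `rank`, and `best_in_group` flagging each group's best pair.
#' @export
rank_mixture_candidates <- function(candidates, grouped_hsqc,
                                    config = match_config()) {
  sets <- candidate_peak_sets(candidates)
  if (!"group" %in% names(grouped_hsqc)) {
    abort("grouped_hsqc must carry a group column; see group_peaks_by_connectivity()")
  }
  groups <- split(as_tibble(grouped_hsqc), grouped_hsqc$group)
  combos <- expand.grid(group = names(groups), label = names(sets),
                        stringsAsFactors = FALSE)
  matches <- lapply(seq_len(nrow(combos)), function(r) {
    match_hsqc(sets[[combos$label[r]]], groups[[combos$group[r]]], config)
  })
  grab <- function(field, type) unname(vapply(matches, `[[`, type, field))
  rows <- tibble(
    label = combos$label,
    group = combos$group,
    n_pred = grab("n_pred", integer(1)),
    n_exp = grab("n_exp", integer(1)),
    n_matched = grab("n_matched", integer(1)),
    matching_ratio = grab("matching_ratio", numeric(1)),
    mean_dh = grab("mean_dh", numeric(1)),
    mean_dc = grab("mean_dc", numeric(1)),
    mean_dist = grab("mean_dist", numeric(1))
  )
  out <- if (config$rank_by == "ratio_first") {
    arrange(rows, desc(matching_ratio), mean_dist, label, group)
  } else {
    arrange(rows, mean_dist, desc(matching_ratio), label, group)
  }
  out$rank <- seq_len(nrow(out))
  out |>
    group_by(group) |>
    mutate(best_in_group = rank == min(rank)) |>
    ungroup()
}

#' Combine NMR and MS2 rankings into a consensus
#'
#' Joins a per-candidate NMR ranking and MS2 ranking by label and computes
#' a combined key, by default the rank product. A candidate missing from
#' one ranking is imputed the worst rank of that ranking plus one, so the
#' consensus never silently drops candidates. Ties on the combined key are
#' broken by NMR rank, then label.
#'
#' @param nmr Data frame with columns `label` and `rank` (e.g. from
#'   [rank_hsqc_candidates()]).
#' @param ms2 Data frame with columns `label` and `rank` (e.g. from
#'   [rank_ms2_candidates()]).
#' @param method Combination rule; only `"rank_product"` is implemented.
#' @return A tibble with `label`, `nmr_rank`, `ms2_rank`, `combined_key`
#'   and dense 1-based `combined_rank`, sorted by the consensus.
#' @examples
#' nmr <- tibble::tibble(label = c("proline", "piperidinone"), rank = c(2, 1))
#' ms2 <- tibble::tibble(label = c("proline", "piperidinone"), rank = c(26, 167))
#' combine_evidence(nmr, ms2)
#' @export
combine_evidence <- function(nmr, ms2, method = "rank_product") {
  method <- arg_match(method, "rank_product")
  for (tab in list(nmr, ms2)) {
    if (!is.data.frame(tab) || !all(c("label", "rank") %in% names(tab))) {
      abort("rankings must be data frames with label and rank columns")
    }
  }
  if (anyDuplicated(nmr$label) || anyDuplicated(ms2$label)) {
    abort("duplicate labels within a ranking")
  }
  if (length(intersect(nmr$label, ms2$label)) == 0) {
    abort("rankings share no candidate labels")
  }
  labels <- union(nmr$label, ms2$label)
  nr <- setNames(nmr$rank, nmr$label)[labels]
  mr <- setNames(ms2$rank, ms2$label)[labels]
  nr[is.na(nr)] <- max(nmr$rank) + 1
  mr[is.na(mr)] <- max(ms2$rank) + 1
  out <- tibble(
    label = labels,
    nmr_rank = as.numeric(nr),
    ms2_rank = as.numeric(mr),
    combined_key = as.numeric(nr) * as.numeric(mr)
  )
  out <- arrange(out, combined_key, nmr_rank, label)
  out$combined_rank <- seq_len(nrow(out))
  out
}
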