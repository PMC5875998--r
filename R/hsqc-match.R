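#' Configuration for HSQC peak-list matching
#'
#' @param w_h,w_c Dimensionless weights for the proton and carbon chemical
#'   shift differences in the peak distance (defaults 10 and 1: a 0.1 ppm
#'   proton error counts as much as a 1 ppm carbon error).
#' @param max_dh,max_dc Per-dimension match cutoffs in ppm; a predicted and
#'   an experimental peak may only pair when both `|dH| <= max_dh` and
#'   `|dC| <= max_dc`. Defaults (0.5, 5.0) are permissive relative to
#'   typical empirical-predictor errors.
#' @param assignment `"greedy"` (pairs accepted in ascending distance order)
#'   or `"optimal"` (maximum-cardinality, minimum-total-distance bipartite
#'   assignment).
#' @param distance `"euclidean"` (default) or `"manhattan"` functional form
#'   of the weighted peak distance.
#' @param rank_by `"ratio_first"` (default: matching ratio desc, then mean
#'   weighted distance asc) or `"distance_first"` (the reverse priority).
#' @return A list of class `match_config`.
#' @export
match_config <- function(w_h = 10, w_c = 1, max_dh = 0.5, max_dc = 5.0,
                         assignment = c("greedy", "optimal"),
                         distance = c("euclidean", "manhattan"),
                         rank_by = c("ratio_first", "distance_first")) {
  stopifnot(w_h > 0, w_c > 0, max_dh > 0, max_dc > 0)
  structure(
    list(
      w_h = w_h, w_c = w_c, max_dh = max_dh, max_dc = max_dc,
      assignment = arg_match(assignment),
      distance = arg_match(distance),
      rank_by = arg_match(rank_by)
    ),
    class = "match_config"
  )
}

#' Weighted chemical-shift distance between HSQC cross-peaks
#'
#' Euclidean form: `sqrt((w_h * dH)^2 + (w_c * dC)^2)`; Manhattan form:
#' `w_h * |dH| + w_c * |dC|`. Vectorized over peaks.
#'
#' @param h1,c1 Shifts (ppm) of the first peak(s).
#' @param h2,c2 Shifts (ppm) of the second peak(s).
#' @param config A [match_config()].
#' @return Numeric vector of dimensionless distances.
#' @examples
#' weighted_peak_distance(2.55, 39.57, 2.70, 39.06)
#' @export
weighted_peak_distance <- function(h1, c1, h2, c2, config = match_config()) {
  dh <- config$w_h * (h1 - h2)
  dc <- config$w_c * (c1 - c2)
  if (config$distance == "euclidean") sqrt(dh^2 + dc^2) else abs(dh) + abs(dc)
}

# validate a peak-list data frame, warn on implausible shift ranges
check_peaks <- function(peaks, what = "peak list") {
  if (!is.data.frame(peaks) || !all(c("h_ppm", "c_ppm") %in% names(peaks))) {
    abort(paste0(what, " must be a data frame with h_ppm and c_ppm columns"))
  }
  if (nrow(peaks) == 0) abort(paste0(what, " is empty"))
  if (any(!is.finite(peaks$h_ppm)) || any(!is.finite(peaks$c_ppm))) {
    abort(paste0(what, " contains non-finite shifts"))
  }
  if (any(peaks$h_ppm < -2 | peaks$h_ppm > 15) ||
      any(peaks$c_ppm < -10 | peaks$c_ppm > 230)) {
    warn(paste0(what, " has shifts outside typical ranges ",
                "(-2..15 ppm 1H, -10..230 ppm 13C)"))
  }
  as_tibble(peaks)
}

#' Match a predicted HSQC peak list against an experimental one
#'
#' Builds the full weighted-distance matrix between predicted and
#' experimental cross-peaks and assigns one-to-one pairs, considering only
#' pairs within the per-dimension cutoffs. The matching ratio is the number
#' of matched predicted peaks divided by the number of predicted peaks, so
#' 5 matches out of 6 predicted cross-peaks gives 0.83 (at 2 decimals).
#'
#' @param predicted,experimental Data frames with columns `h_ppm`, `c_ppm`.
#' @param config A [match_config()].
#' @return An object of class `hsqc_match`: a list with `pairs` (tibble of
#'   matched `pred_idx`, `exp_idx`, `dh`, `dc`, `dist_w`), `n_pred`,
#'   `n_exp`, `n_matched`, `matching_ratio`, `mean_dh`, `mean_dc` (mean
#'   absolute shift differences over matched pairs; NA when nothing
#'   matches), `mean_dist` (mean weighted distance; Inf when nothing
#'   matches, so unmatched candidates sort last), and the `config` used.
#' @examples
#' exp <- tibble::tibble(h_ppm = c(3.6, 2.26, 0.98), c_ppm = c(61, 29.7, 18.6))
#' match_hsqc(exp, exp)
#' @export
match_hsqc <- function(predicted, experimental, config = match_config()) {
  predicted <- check_peaks(predicted, "predicted peak list")
  experimental <- check_peaks(experimental, "experimental peak list")
  np <- nrow(predicted)
  ne <- nrow(experimental)

  dh <- outer(predicted$h_ppm, experimental$h_ppm, "-")
  dc <- outer(predicted$c_ppm, experimental$c_ppm, "-")
  dw <- if (config$distance == "euclidean") {
    sqrt((config$w_h * dh)^2 + (config$w_c * dc)^2)
  } else {
    abs(config$w_h * dh) + abs(config$w_c * dc)
  }
  allowed <- abs(dh) <= config$max_dh & abs(dc) <= config$max_dc

  pairs <- if (config$assignment == "greedy") {
    assign_greedy(dw, allowed)
  } else {
    assign_optimal(dw, allowed)
  }

  nm <- length(pairs$pred_idx)
  ij <- cbind(pairs$pred_idx, pairs$exp_idx)
  pairs <- tibble::new_tibble(
    list(pred_idx = pairs$pred_idx, exp_idx = pairs$exp_idx,
         dh = dh[ij], dc = dc[ij], dist_w = dw[ij]),
    nrow = nm
  )
  structure(
    list(
      pairs = pairs,
      n_pred = np,
      n_exp = ne,
      n_matched = nm,
      matching_ratio = nm / np,
      mean_dh = if (nm > 0) mean(abs(pairs$dh)) else NA_real_,
      mean_dc = if (nm > 0) mean(abs(pairs$dc)) else NA_real_,
      mean_dist = if (nm > 0) mean(pairs$dist_w) else Inf,
      config = config
    ),
    class = "hsqc_match"
  )
}

# greedy one-to-one assignment: accept allowed pairs in ascending distance,
# skipping pairs whose predicted or experimental peak is already consumed
assign_greedy <- function(dw, allowed) {
  idx <- which(allowed, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(pred_idx = integer(), exp_idx = integer()))
  ord <- order(dw[idx], idx[, 1], idx[, 2]) # distance, then indices for determinism
  idx <- idx[ord, , drop = FALSE]
  used_p <- logical(nrow(dw))
  used_e <- logical(ncol(dw))
  keep <- logical(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, 1]
    e <- idx[r, 2]
    if (!used_p[p] && !used_e[e]) {
      used_p[p] <- TRUE
      used_e[e] <- TRUE
      keep[r] <- TRUE
    }
  }
  list(pred_idx = as.integer(idx[keep, 1]), exp_idx = as.integer(idx[keep, 2]))
}

# exact assignment: maximum cardinality first, minimum total distance second.
# Solved as a maximum-weight bipartite matching with weight BIG - distance,
# BIG large enough that one extra match always beats any distance saving.
assign_optimal <- function(dw, allowed) {
  idx <- which(allowed, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(pred_idx = integer(), exp_idx = integer()))
  np <- nrow(dw)
  ne <- ncol(dw)
  big <- sum(dw[idx]) + max(dw[idx]) + 1
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, np), rep(TRUE, ne)),
    edges = as.vector(rbind(idx[, 1], np + idx[, 2]))
  )
  m <- igraph::max_bipartite_match(g, weights = big - dw[idx])
  mate <- m$matching[seq_len(np)]
  matched <- which(!is.na(mate))
  list(pred_idx = as.integer(matched),
       exp_idx = as.integer(mate[matched] - np))
}

#' @export
print.hsqc_match <- function(x, ...) {
  cat("<hsqc_match> ", x$n_matched, "/", x$n_pred,
      " predicted peaks matched (ratio ",
      sprintf("%.2f", x$matching_ratio), ")\n", sep = "")
  if (x$n_matched > 0) {
    cat(sprintf("  mean |dH| %.4f ppm, mean |dC| %.4f ppm, mean weighted distance %.4f\n",
                x$mean_dh, x$mean_dc, x$mean_dist))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Matched peak pairs of an HSQC match
#'
#' @param x An `hsqc_match` object.
#' @param ... Unused.
#' @return A tibble of matched pairs with signed shift differences
#'   (predicted minus experimental) and weighted distances.
#' @method tidy hsqc_match
#' @export
tidy.hsqc_match <- function(x, ...) {
  x$pairs
}

#' One-row summary of an HSQC match
#'
#' @param x An `hsqc_match` object.
#' @param ... Unused.
#' @return A one-row tibble with `n_pred`, `n_exp`, `n_matched`,
#'   `matching_ratio`, `mean_dh`, `mean_dc`, `mean_dist`.
#' @method glance hsqc_match
#' @export
glance.hsqc_match <- function(x, ...) {
  tibble(
    n_pred = x$n_pred, n_exp = x$n_exp, n_matched = x$n_matched,
    matching_ratio = x$matching_ratio,
    mean_dh = x$mean_dh, mean_dc = x$mean_dc, mean_dist = x$mean_dist
  )
}

#' Rank candidate structures by predicted-vs-experimental HSQC agreement
#'
#' Each candidate's predicted peak list is matched against the experimental
#' list with [match_hsqc()]; candidates are then sorted by maximum matching
#' ratio and minimum mean weighted chemical-shift distance (lexicographic;
#' the priority can be reversed via the config), with the candidate label
#' as the final deterministic tie-break.
#'
#' @param candidates Either a data frame with columns `label`, `h_ppm`,
#'   `c_ppm` (stacked predicted peak lists) or a named list of peak-list
#'   data frames.
#' @param experimental Data frame with columns `h_ppm`, `c_ppm`.
#' @param config A [match_config()].
#' @return A tibble with one row per candidate: `label`, `n_pred`,
#'   `n_matched`, `matching_ratio`, `mean_dh`, `mean_dc`, `mean_dist` and
#'   1-based `rank`.
#' @export
rank_hsqc_candidates <- function(candidates, experimental,
                                 config = match_config()) {
  sets <- candidate_peak_sets(candidates)
  matches <- lapply(sets, match_hsqc, experimental = experimental,
                    config = config)
  grab <- function(field, type) unname(vapply(matches, `[[`, type, field))
  out <- tibble(
    label = names(sets),
    n_pred = grab("n_pred", integer(1)),
    n_matched = grab("n_matched", integer(1)),
    matching_ratio = grab("matching_ratio", numeric(1)),
    mean_dh = grab("mean_dh", numeric(1)),
    mean_dc = grab("mean_dc", numeric(1)),
    mean_dist = grab("mean_dist", numeric(1))
  )
  out <- sort_nmr_ranking(out, config)
  out$rank <- seq_len(nrow(out))
  out
}

sort_nmr_ranking <- function(df, config) {
  if (config$rank_by == "ratio_first") {
    arrange(df, desc(matching_ratio), mean_dist, label)
  } else {
    arrange(df, mean_dist, desc(matching_ratio), label)
  }
}

# normalize candidate input (stacked tibble with label column, or named
# list of peak lists) into a named list of tibbles; duplicate labels error
candidate_peak_sets <- function(candidates) {
  if (is.data.frame(candidates)) {
    if (!all(c("label", "h_ppm", "c_ppm") %in% names(candidates))) {
      abort("stacked candidates need label, h_ppm, c_ppm columns")
    }
    sets <- split(as_tibble(candidates), candidates$label)
  } else if (is.list(candidates)) {
    if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
      abort("candidate list must be named by label")
    }
    if (anyDuplicated(names(candidates))) {
      abort("duplicate candidate labels")
    }
    sets <- lapply(candidates, as_tibble)
  } else {
    abort("candidates must be a data frame or a named list of data frames")
  }
  if (length(sets) == 0) abort("no candidates supplied")
  sets
}
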