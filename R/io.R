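# Interchange formats. Inputs accept comma- or tab-separated tables
# (delimiter sniffed from the header line); outputs are TSV with fixed
# precision so reruns are byte-identical.

sniff_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

read_table_sniffed <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_delim(path, delim = sniff_delim(path), show_col_types = FALSE,
                    progress = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("file '", path, "' is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in cols) {
    vals <- df[[col]]
    if (!is.numeric(vals)) {
      suppressWarnings(num <- as.numeric(vals))
      bad <- which(is.na(num) & !is.na(vals))
      if (length(bad) > 0) {
        abort(paste0("file '", path, "', column '", col,
                     "': non-numeric value in row ", bad[1]))
      }
      df[[col]] <- num
    }
  }
  df
}

#' Read a typed peak/feature table
#'
#' Reads CSV or TSV (delimiter sniffed) and validates the columns required
#' for the record kind: `hsqc` needs `h_ppm`, `c_ppm`; `tocsy` needs
#' `h1_ppm`, `h2_ppm` (rows canonicalized so `h1_ppm <= h2_ppm`); `ms2`
#' needs `mz`, `intensity`; `feature` needs `mz`, `polarity`, `adduct`
#' (optional `envelope` strings `"mass:abundance;..."` are kept verbatim).
#'
#' @param path File path.
#' @param kind One of `"hsqc"`, `"tocsy"`, `"ms2"`, `"feature"`.
#' @return A validated tibble.
#' @export
read_peak_table <- function(path, kind = c("hsqc", "tocsy", "ms2", "feature")) {
  kind <- arg_match(kind)
  df <- read_table_sniffed(path)
  switch(kind,
    hsqc = require_columns(df, c("h_ppm", "c_ppm"), path),
    tocsy = {
      df <- require_columns(df, c("h1_ppm", "h2_ppm"), path)
      lo <- pmin(df$h1_ppm, df$h2_ppm)
      hi <- pmax(df$h1_ppm, df$h2_ppm)
      df$h1_ppm <- lo
      df$h2_ppm <- hi
      df
    },
    ms2 = require_columns(df, c("mz", "intensity"), path),
    feature = {
      missing <- setdiff(c("mz", "polarity", "adduct"), names(df))
      if (length(missing) > 0) {
        abort(paste0("file '", path, "' is missing required column(s): ",
                     paste(missing, collapse = ", ")))
      }
      require_columns(df, "mz", path)
    }
  )
}

#' Read MS2 spectra from an MGF file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, `CHARGE` (e.g.
#' `1+`, `1-`), optional `TITLE`/`COLLISIONENERGY`, and m/z-intensity peak
#' lines. Polarity is inferred from the charge sign.
#'
#' @param path MGF file path.
#' @return A list of [ms2_spectrum()] objects.
#' @export
read_ms2_mgf <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  spectra <- list()
  in_block <- FALSE
  block <- NULL
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    if (line == "BEGIN IONS") {
      if (in_block) abort(paste0("line ", ln, ": nested BEGIN IONS"))
      in_block <- TRUE
      block <- list(peaks_mz = numeric(), peaks_int = numeric(),
                    pepmass = NA_real_, charge = 1L, title = "",
                    ce = 30, start = ln)
    } else if (line == "END IONS") {
      if (!in_block) abort(paste0("line ", ln, ": END IONS without BEGIN"))
      if (is.na(block$pepmass)) {
        abort(paste0("spectrum starting at line ", block$start,
                     " has no PEPMASS"))
      }
      spectra[[length(spectra) + 1]] <- ms2_spectrum(
        tibble(mz = block$peaks_mz, intensity = block$peaks_int),
        precursor_mz = block$pepmass,
        polarity = if (block$charge < 0) "negative" else "positive",
        collision_energy = block$ce,
        title = block$title
      )
      in_block <- FALSE
    } else if (in_block) {
      if (grepl("^PEPMASS=", line)) {
        block$pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", line), "\\s+")[[1]][1])
      } else if (grepl("^CHARGE=", line)) {
        spec <- sub("^CHARGE=", "", line)
        mag <- as.integer(gsub("[+-]", "", spec))
        block$charge <- if (grepl("-", spec, fixed = TRUE)) -mag else mag
      } else if (grepl("^TITLE=", line)) {
        block$title <- sub("^TITLE=", "", line)
      } else if (grepl("^COLLISIONENERGY=", line)) {
        block$ce <- as.numeric(sub("^COLLISIONENERGY=", "", line))
      } else if (grepl("^[0-9.]", line)) {
        parts <- strsplit(line, "\\s+")[[1]]
        if (length(parts) < 2 || anyNA(suppressWarnings(as.numeric(parts[1:2])))) {
          abort(paste0("line ", ln, ": malformed peak line '", line, "'"))
        }
        block$peaks_mz <- c(block$peaks_mz, as.numeric(parts[1]))
        block$peaks_int <- c(block$peaks_int, as.numeric(parts[2]))
      } else if (!grepl("=", line, fixed = TRUE)) {
        abort(paste0("line ", ln, ": unrecognized content '", line, "'"))
      }
    }
  }
  if (in_block) abort("unterminated BEGIN IONS block at end of file")
  spectra
}

#' Write MS2 spectra to an MGF file
#'
#' Inverse of [read_ms2_mgf()]; masses and intensities are written to six
#' decimals so a write-read round trip reproduces the spectra.
#'
#' @param spectra A single [ms2_spectrum()] or a list of them.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ms2_mgf <- function(spectra, path) {
  if (inherits(spectra, "ms2_spectrum")) spectra <- list(spectra)
  out <- character()
  for (sp in spectra) {
    out <- c(
      out, "BEGIN IONS",
      if (nzchar(sp$title)) paste0("TITLE=", sp$title),
      sprintf("PEPMASS=%.6f", sp$precursor_mz),
      paste0("CHARGE=1", if (sp$polarity == "negative") "-" else "+"),
      sprintf("COLLISIONENERGY=%g", sp$collision_energy),
      sprintf("%.6f %.6f", sp$peaks$mz, sp$peaks$intensity),
      "END IONS", ""
    )
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a ranking table in a fixed-layout TSV
#'
#' Column layouts mirror the package's ranking outputs: `nmr_table` has
#' label, mean shift differences (4 decimals), matching ratio (2 decimals)
#' and rank; `ms2_table` has label, score (4 decimals; top candidate
#' 1.0000) and rank; `combined` has label, both input ranks, the combined
#' key and the combined rank.
#'
#' @param results Ranking tibble from [rank_hsqc_candidates()],
#'   [rank_ms2_candidates()] or [combine_evidence()].
#' @param path Output path.
#' @param style One of `"nmr_table"`, `"ms2_table"`, `"combined"`.
#' @return The path, invisibly.
#' @export
write_ranking <- function(results, path,
                          style = c("nmr_table", "ms2_table", "combined")) {
  style <- arg_match(style)
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0) abort("empty results")
  fmt <- function(x, digits) {
    ifelse(is.na(x) | is.infinite(x), "NA", sprintf(paste0("%.", digits, "f"), x))
  }
  out <- switch(style,
    nmr_table = tibble(
      label = results$label,
      mean_dh = fmt(results$mean_dh, 4),
      mean_dc = fmt(results$mean_dc, 4),
      matching_ratio = fmt(results$matching_ratio, 2),
      rank = results$rank
    ),
    ms2_table = tibble(
      label = results$label,
      score = fmt(results$score, 4),
      rank = results$rank
    ),
    combined = tibble(
      label = results$label,
      nmr_rank = results$nmr_rank,
      ms2_rank = results$ms2_rank,
      combined_key = fmt(results$combined_key, 4),
      combined_rank = results$combined_rank
    )
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a synthetic scenario to a directory
#'
#' Serializes every component of a [build_scenario()] result in the
#' package's interchange formats: `features.csv` (with envelopes encoded
#' as `"mass:abundance;..."` strings), `experimental_hsqc.csv`,
#' `tocsy.csv`, `candidates_nmr.csv`, `candidates_ms2.csv`, `spectra.mgf`,
#' `truth.yaml` and `config.yaml`.
#'
#' @param scenario A `hybrid_scenario`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "hybrid_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  feats <- scenario$features
  feats$envelope <- vapply(feats$envelope, function(env) {
    paste(sprintf("%.6f:%.6f", env$mass, env$abundance), collapse = ";")
  }, character(1))
  readr::write_csv(feats, p("features.csv"), progress = FALSE)
  readr::write_csv(scenario$experimental_hsqc, p("experimental_hsqc.csv"),
                   progress = FALSE)
  readr::write_csv(scenario$tocsy, p("tocsy.csv"), progress = FALSE)
  readr::write_csv(scenario$candidates_nmr, p("candidates_nmr.csv"),
                   progress = FALSE)
  readr::write_csv(scenario$candidates_ms2, p("candidates_ms2.csv"),
                   progress = FALSE)
  spectra <- scenario$spectra
  for (id in names(spectra)) spectra[[id]]$title <- id
  write_ms2_mgf(spectra, p("spectra.mgf"))
  yaml::write_yaml(lapply(split(scenario$truth, seq_len(nrow(scenario$truth))),
                          as.list),
                   p("truth.yaml"))
  yaml::write_yaml(scenario$config, p("config.yaml"))
  invisible(dir)
}

#' Read a scenario directory back into memory
#'
#' @param dir Directory written by [write_scenario()].
#' @return A `hybrid_scenario` list (config and truth restored from YAML).
#' @export
read_scenario <- function(dir) {
  p <- function(...) file.path(dir, ...)
  feats <- read_peak_table(p("features.csv"), "feature")
  feats$envelope <- lapply(feats$envelope, function(s) {
    parts <- strsplit(strsplit(s, ";")[[1]], ":")
    tibble(mass = vapply(parts, function(x) as.numeric(x[1]), numeric(1)),
           abundance = vapply(parts, function(x) as.numeric(x[2]), numeric(1)))
  })
  spectra <- read_ms2_mgf(p("spectra.mgf"))
  names(spectra) <- vapply(spectra, function(s) s$title, character(1))
  truth <- bind_rows(lapply(yaml::read_yaml(p("truth.yaml")), as_tibble))
  structure(
    list(
      features = feats,
      experimental_hsqc = read_peak_table(p("experimental_hsqc.csv"), "hsqc"),
      tocsy = read_peak_table(p("tocsy.csv"), "tocsy"),
      candidates_nmr = read_table_sniffed(p("candidates_nmr.csv")),
      candidates_ms2 = read_table_sniffed(p("candidates_ms2.csv")),
      spectra = spectra,
      truth = truth,
      config = yaml::read_yaml(p("config.yaml"))
    ),
    class = "hybrid_scenario"
  )
}

#' Read candidate peak lists from a stacked file or a directory
#'
#' A single CSV/TSV must carry a `label` column (stacked peak lists); a
#' directory is read as one peak list per file, labelled by file name
#' without extension.
#'
#' @param path File or directory path.
#' @return A stacked tibble with `label`, `h_ppm`, `c_ppm`.
#' @export
read_table_from_path_or_dir <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(csv|tsv)$", full.names = TRUE)
    if (length(files) == 0) abort(paste0("no csv/tsv files in ", path))
    bind_rows(lapply(files, function(f) {
      mutate(read_peak_table(f, "hsqc"),
             label = sub("\\.(csv|tsv)$", "", basename(f)))
    }))
  } else {
    df <- read_table_sniffed(path)
    if (!"label" %in% names(df)) {
      abort(paste0("stacked candidate file '", path, "' needs a label column"))
    }
    require_columns(df, c("h_ppm", "c_ppm"), path)
  }
}

#' Load the run configuration used by the command-line interface
#'
#' Reads a YAML file of tolerances, weights and defaults, fills in package
#' defaults for absent keys and validates the values.
#'
#' @param path Optional YAML path; NULL returns the defaults.
#' @return A named list with `tol_ppm`, `ms2_tol_ppm`, `w_h`, `w_c`,
#'   `max_dh`, `max_dc`, `adduct`, `combination`, `seed`.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    tol_ppm = 10, ms2_tol_ppm = 30, w_h = 10, w_c = 1,
    max_dh = 0.5, max_dc = 5.0, adduct = "[M+H]+",
    combination = "rank_product", seed = 1
  )
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, user)
  for (key in c("tol_ppm", "ms2_tol_ppm", "w_h", "w_c", "max_dh", "max_dc")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0) {
      abort(paste0("config key '", key, "' must be a positive number"))
    }
  }
  cfg
}
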