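#' Build a spectra table
#'
#' The package represents centroided MS/MS peak lists as a tibble with one row
#' per spectrum: `spectrum_id`, `precursor_mz`, `precursor_charge` (0 when
#' unknown), `retention_time` (seconds) and a `peaks` list-column holding a
#' tibble of `mz`/`intensity` pairs per spectrum. Peaks are kept sorted
#' ascending by m/z, intensities must be non-negative, and `precursor_mz`
#' positive.
#'
#' @param spectrum_id Character vector of spectrum identifiers.
#' @param precursor_mz Precursor m/z values (> 0).
#' @param precursor_charge Integer charges (0 = unknown).
#' @param retention_time Retention times in seconds.
#' @param peaks List of data frames with columns `mz` and `intensity`.
#' @return A spectra tibble.
#' @export
spectra_tbl <- function(spectrum_id, precursor_mz, precursor_charge,
                        retention_time, peaks) {
  stopifnot(
    length(spectrum_id) == length(precursor_mz),
    length(spectrum_id) == length(peaks)
  )
  if (any(precursor_mz <= 0)) {
    stop("precursor_mz must be positive", call. = FALSE)
  }
  peaks <- purrr::map(peaks, function(p) {
    p <- tibble::as_tibble(p[, c("mz", "intensity")])
    if (any(p$intensity < 0)) {
      stop("peak intensities must be non-negative", call. = FALSE)
    }
    dplyr::arrange(p, .data$mz)
  })
  tibble::tibble(
    spectrum_id = as.character(spectrum_id),
    precursor_mz = as.numeric(precursor_mz),
    precursor_charge = as.integer(precursor_charge),
    retention_time = as.numeric(retention_time),
    peaks = peaks
  )
}

#' Read and write Mascot generic format (MGF) peak lists
#'
#' A minimal, lossless reader/writer for the standard MGF dialect with
#' `TITLE`, `PEPMASS`, `CHARGE` and `RTINSECONDS` headers. Values round-trip
#' at the precision written. Blocks without a `PEPMASS` are skipped with a
#' warning; a `BEGIN IONS` block with no matching `END IONS` is an error
#' reporting the block index.
#'
#' @param path File path.
#' @return `read_mgf()` returns a spectra tibble (see [spectra_tbl()]);
#'   `write_mgf()` invisibly returns `path`.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) {
    stop("no such file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) == 0L) {
    return(spectra_tbl(character(), numeric(), integer(), numeric(), list()))
  }
  records <- vector("list", length(begins))
  kept <- logical(length(begins))
  for (b in seq_along(begins)) {
    start <- begins[b]
    end_candidates <- ends[ends > start]
    if (b < length(begins)) {
      end_candidates <- end_candidates[end_candidates < begins[b + 1]]
    }
    if (length(end_candidates) == 0L) {
      stop("MGF block ", b, " has no END IONS", call. = FALSE)
    }
    block <- lines[(start + 1L):(end_candidates[1] - 1L)]
    is_header <- grepl("^[A-Z]+=", block)
    headers <- block[is_header]
    keys <- sub("=.*$", "", headers)
    vals <- sub("^[A-Z]+=", "", headers)
    header <- stats::setNames(vals, keys)
    if (!"PEPMASS" %in% keys) {
      warning("MGF block ", b, " lacks PEPMASS; spectrum skipped", call. = FALSE)
      next
    }
    peak_lines <- block[!is_header & nzchar(trimws(block))]
    if (length(peak_lines) > 0L) {
      m <- do.call(rbind, strsplit(trimws(peak_lines), "[ \t]+"))
      pk <- tibble::tibble(
        mz = as.numeric(m[, 1]),
        intensity = as.numeric(m[, 2])
      )
    } else {
      pk <- tibble::tibble(mz = numeric(), intensity = numeric())
    }
    charge <- 0L
    if ("CHARGE" %in% keys) {
      charge <- as.integer(sub("\\+$", "", header[["CHARGE"]]))
    }
    records[[b]] <- list(
      spectrum_id = if ("TITLE" %in% keys) header[["TITLE"]] else paste0("spectrum_", b),
      precursor_mz = as.numeric(strsplit(header[["PEPMASS"]], "[ \t]+")[[1]][1]),
      precursor_charge = charge,
      retention_time = if ("RTINSECONDS" %in% keys) as.numeric(header[["RTINSECONDS"]]) else NA_real_,
      peaks = pk
    )
    kept[b] <- TRUE
  }
  records <- records[kept]
  spectra_tbl(
    spectrum_id = purrr::map_chr(records, "spectrum_id"),
    precursor_mz = purrr::map_dbl(records, "precursor_mz"),
    precursor_charge = purrr::map_int(records, "precursor_charge"),
    retention_time = purrr::map_dbl(records, "retention_time"),
    peaks = purrr::map(records, "peaks")
  )
}

#' @rdname read_mgf
#' @param spectra A spectra tibble.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- purrr::pmap_chr(
    spectra,
    function(spectrum_id, precursor_mz, precursor_charge, retention_time, peaks) {
      header <- c(
        "BEGIN IONS",
        paste0("TITLE=", spectrum_id),
        paste0("PEPMASS=", format(precursor_mz, digits = 10, scientific = FALSE, trim = TRUE)),
        if (!is.na(precursor_charge) && precursor_charge > 0L) {
          paste0("CHARGE=", precursor_charge, "+")
        },
        if (!is.na(retention_time)) {
          paste0("RTINSECONDS=", format(retention_time, digits = 10, scientific = FALSE, trim = TRUE))
        }
      )
      peak_lines <- sprintf("%.5f %.4f", peaks$mz, peaks$intensity)
      paste(c(header, peak_lines, "END IONS"), collapse = "\n")
    }
  )
  writeLines(blocks, path)
  invisible(path)
}

#' Mass tolerance windows
#'
#' Helper computing the half-width (in Da) of a tolerance around a target m/z,
#' in either ppm or Da.
#'
#' @param target Target m/z (used for ppm tolerances).
#' @param tol Tolerance value (> 0).
#' @param unit `"ppm"` or `"da"`.
#' @return Half-width in Da.
#' @export
tol_width <- function(target, tol, unit = c("ppm", "da")) {
  unit <- match.arg(tolower(unit), c("ppm", "da"))
  if (any(tol <= 0)) stop("tolerance must be positive", call. = FALSE)
  if (unit == "ppm") target * tol * 1e-6 else rep_len(tol, length(target))
}

#' Diagnostic-ion spectral filter
#'
#' Keeps only spectra containing the OPP diagnostic fragment ion: a peak
#' within tolerance of `ion_mz` whose intensity is at least
#' `min_relative_intensity` times the base-peak intensity. With the default
#' `min_relative_intensity = 0`, presence of the ion suffices; spectra of
#' well-fragmented OPP-modified peptides typically show it as the base peak,
#' and `min_relative_intensity = 1` selects exactly that stricter behaviour.
#' The filter is idempotent and partitions its input.
#'
#' @param spectra A spectra tibble.
#' @param ion_mz Diagnostic ion m/z; default the computed exact
#'   C7H10N5+ mass, [opp_diagnostic_mz()].
#' @param tol,tol_unit Match tolerance (default 30 ppm, the fragment-ion
#'   tolerance of the search).
#' @param min_relative_intensity Minimum intensity relative to the base peak.
#' @return A list with `kept` (spectra tibble) and `removed_count` (integer).
#' @export
diagnostic_filter <- function(spectra, ion_mz = opp_diagnostic_mz(),
                              tol = 30, tol_unit = "ppm",
                              min_relative_intensity = 0) {
  width <- tol_width(ion_mz, tol, tol_unit)
  has_ion <- purrr::map_lgl(spectra$peaks, function(p) {
    if (nrow(p) == 0L) {
      return(FALSE)
    }
    in_window <- abs(p$mz - ion_mz) <= width
    any(in_window & p$intensity >= min_relative_intensity * max(p$intensity))
  })
  list(
    kept = spectra[has_ion, , drop = FALSE],
    removed_count = sum(!has_ion)
  )
}
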