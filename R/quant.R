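#' Extracted-ion-chromatogram intensity from an MS1 scan table
#'
#' Aggregates MS1 intensity for a target m/z over a retention-time window
#' anchored at the moment the precursor was selected for MS/MS. The default
#' window is -10/+30 s around the selection time, closed at both ends, and the
#' default aggregation is the sum of in-window, in-tolerance intensities
#' (area-like); `aggregate = "apex"` takes the maximum instead.
#'
#' @param ms1 A data frame with columns `retention_time` (seconds), `mz`,
#'   `intensity`, sorted by time.
#' @param target_mz Target m/z.
#' @param selection_time Time (seconds) at which the precursor was selected.
#' @param tol,tol_unit Match tolerance (default 10 ppm).
#' @param window Length-2 numeric, offsets of the window ends relative to
#'   `selection_time` (default `c(-10, 30)`).
#' @param aggregate `"sum"` or `"apex"`.
#' @return A single non-negative intensity; 0 when nothing matches.
#' @export
extract_xic <- function(ms1, target_mz, selection_time, tol = 10,
                        tol_unit = "ppm", window = c(-10, 30),
                        aggregate = c("sum", "apex")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(window) == 2L, window[1] < window[2])
  width <- tol_width(target_mz, tol, tol_unit)
  sel <- ms1$retention_time >= selection_time + window[1] &
    ms1$retention_time <= selection_time + window[2] &
    abs(ms1$mz - target_mz) <= width
  if (!any(sel)) {
    return(0)
  }
  if (aggregate == "sum") sum(ms1$intensity[sel]) else max(ms1$intensity[sel])
}

#' Default protein ranking for shared-peptide assignment
#'
#' Ranks proteins the way a search-engine report is ordered: descending count
#' of distinct peptide sequences contained in the protein, then descending
#' total intensity of those peptides, then lexicographic accession. The result
#' is a deterministic total order.
#'
#' @param peptides A tibble with columns `sequence` and optionally
#'   `intensity` (summed over samples if absent per-sample).
#' @param proteins A tibble with columns `accession`, `sequence`.
#' @return Character vector of accessions, highest rank first.
#' @export
rank_proteins <- function(peptides, proteins) {
  peps <- dplyr::distinct(
    tibble::tibble(
      sequence = peptides$sequence,
      intensity = if ("intensity" %in% names(peptides)) peptides$intensity else 0
    ) |>
      dplyr::group_by(.data$sequence) |>
      dplyr::summarise(intensity = sum(.data$intensity, na.rm = TRUE), .groups = "drop")
  )
  stats_tbl <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    contained <- stringr::str_detect(
      proteins$sequence[i],
      stringr::fixed(peps$sequence)
    )
    tibble::tibble(
      accession = proteins$accession[i],
      n_peptides = sum(contained),
      total_intensity = sum(peps$intensity[contained])
    )
  })
  stats_tbl <- dplyr::arrange(
    stats_tbl,
    dplyr::desc(.data$n_peptides), dplyr::desc(.data$total_intensity), .data$accession
  )
  stats_tbl$accession
}

#' Assign shared peptides uniquely to the highest-ranked protein
#'
#' Each peptide entity is assigned to the single highest-ranked protein whose
#' sequence contains it; peptides contained in no ranked protein are dropped
#' (their count is reported in a message). After assignment every peptide key
#' belongs to exactly one protein, so downstream rollup counts each intensity
#' once.
#'
#' @param peptides A tibble with at least a `sequence` column (plus any
#'   identity/quant columns, carried through).
#' @param proteins A tibble with columns `accession`, `sequence`.
#' @param ranking Total order over accessions (highest rank first); defaults
#'   to [rank_proteins()].
#' @return `peptides` with an `assigned_protein` column, unassignable rows
#'   removed.
#' @export
assign_shared_peptides <- function(peptides, proteins, ranking = NULL) {
  if (is.null(ranking)) {
    ranking <- rank_proteins(peptides, proteins)
  }
  prot_seq <- stats::setNames(proteins$sequence, proteins$accession)[ranking]
  unique_seqs <- unique(peptides$sequence)
  assigned <- vapply(unique_seqs, function(s) {
    hit <- which(stringr::str_detect(prot_seq, stringr::fixed(s)))
    if (length(hit) == 0L) NA_character_ else ranking[hit[1]]
  }, character(1))
  out <- peptides
  out$assigned_protein <- unname(assigned[match(out$sequence, unique_seqs)])
  dropped <- sum(is.na(out$assigned_protein))
  if (dropped > 0L) {
    message(dropped, " peptide row(s) matched no ranked protein and were dropped")
    out <- out[!is.na(out$assigned_protein), , drop = FALSE]
  }
  tibble::as_tibble(out)
}

#' Roll peptide intensities up to protein quant records
#'
#' Protein intensity per sample is the sum of the MS1 intensities of the
#' peptide entities (sequence + modifications + charge, quantified separately
#' per charge state) assigned to the protein; missing peptide intensities
#' contribute nothing (no imputation, no zero-fill). The unique-peptide count
#' per sample is the number of distinct peptide sequences (modifications and
#' charge collapsed) with a non-missing intensity in that sample.
#'
#' @param peptides A long tibble with columns `assigned_protein`, `sequence`,
#'   `sample`, `intensity` (NA = missing), and optionally `charge`/`mods`
#'   distinguishing peptide entities.
#' @return A tibble with one row per (`accession`, `sample`):
#'   `unique_peptides`, `summed_intensity`.
#' @export
rollup_proteins <- function(peptides) {
  stopifnot(all(c("assigned_protein", "sequence", "sample", "intensity") %in% names(peptides)))
  peptides |>
    dplyr::filter(!is.na(.data$intensity)) |>
    dplyr::group_by(accession = .data$assigned_protein, sample = .data$sample) |>
    dplyr::summarise(
      unique_peptides = dplyr::n_distinct(.data$sequence),
      summed_intensity = sum(.data$intensity),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$accession, .data$sample)
}
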