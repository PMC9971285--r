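#' Tryptic cleavage sites of a protein sequence
#'
#' Positions `i` such that trypsin cleaves after residue `i`: residue `i` is K
#' or R and residue `i + 1` is not proline. The protein C terminus is not a
#' cleavage site.
#'
#' @param sequence Protein sequence string.
#' @return Integer vector of cleavage positions (possibly empty).
#' @export
cleavage_sites <- function(sequence) {
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(residues)
  if (n < 2L) {
    return(integer())
  }
  which(residues[-n] %in% c("K", "R") & residues[-1] != "P")
}

#' In silico digestion into peptide candidates
#'
#' Enumerates peptide candidates from one protein. With `semi_cterm = FALSE`
#' all fully tryptic peptides with at most `missed_cleavages` internal missed
#' cleavage sites are produced. With `semi_cterm = TRUE` (the OPP-modified
#' search mode) the N terminus must still be tryptic (position 1 or preceded
#' by K/R not before P) but the C terminus is unconstrained — any end position
#' giving a peptide of at least `min_length` residues — because premature
#' chain termination by OPP can occur anywhere. Internal cleavage sites
#' strictly before the candidate's C-terminal residue count as missed
#' cleavages; a non-tryptic C terminus itself does not. Candidates containing
#' non-canonical residues (e.g. X) are excluded. No duplicate (start, end)
#' pairs are emitted.
#'
#' @param sequence Protein sequence string.
#' @param accession Protein accession carried into the output.
#' @param missed_cleavages Maximum internal missed cleavages (default 2).
#' @param semi_cterm Allow any C-terminal position (default FALSE).
#' @param min_length Minimum peptide length in residues (default 6).
#' @return A tibble with columns `accession`, `start`, `end` (1-based,
#'   inclusive), `sequence`, `missed_cleavages`.
#' @export
digest <- function(sequence, accession = "protein", missed_cleavages = 2L,
                   semi_cterm = FALSE, min_length = 6L) {
  n <- nchar(sequence)
  sites <- cleavage_sites(sequence)
  starts <- c(1L, sites + 1L)
  # site_rank[p]: number of cleavage sites at positions <= p
  site_rank <- cumsum(tabulate(sites, nbins = n))

  if (semi_cterm) {
    pieces <- lapply(starts, function(s) {
      ends <- seq.int(s + min_length - 1L, n)
      if (length(ends) == 0L || ends[1] > n) {
        return(NULL)
      }
      mc <- site_rank[ends - 1L] - if (s > 1L) site_rank[s - 1L] else 0L
      ends <- ends[mc <= missed_cleavages]
      if (length(ends) == 0L) {
        return(NULL)
      }
      tibble::tibble(
        start = s, end = ends,
        missed_cleavages = site_rank[ends - 1L] - if (s > 1L) site_rank[s - 1L] else 0L
      )
    })
  } else {
    bounds <- c(sites, n) # allowed tryptic C termini
    pieces <- lapply(seq_along(starts), function(i) {
      s <- starts[i]
      ends <- bounds[bounds >= s + min_length - 1L]
      if (length(ends) == 0L) {
        return(NULL)
      }
      mc <- site_rank[ends - 1L] - if (s > 1L) site_rank[s - 1L] else 0L
      ends <- ends[mc <= missed_cleavages]
      if (length(ends) == 0L) {
        return(NULL)
      }
      tibble::tibble(
        start = s, end = ends,
        missed_cleavages = site_rank[ends - 1L] - if (s > 1L) site_rank[s - 1L] else 0L
      )
    })
  }
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      accession = character(), start = integer(), end = integer(),
      sequence = character(), missed_cleavages = integer()
    ))
  }
  out$sequence <- substring(sequence, out$start, out$end)
  canonical <- !grepl(paste0("[^", paste(.canonical_residues, collapse = ""), "]"), out$sequence)
  out <- out[canonical, , drop = FALSE]
  out <- dplyr::distinct(out, .data$start, .data$end, .keep_all = TRUE)
  tibble::tibble(
    accession = accession,
    start = as.integer(out$start),
    end = as.integer(out$end),
    sequence = out$sequence,
    missed_cleavages = as.integer(out$missed_cleavages)
  )
}
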