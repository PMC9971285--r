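#' Minimal polypeptide length from peptide evidence
#'
#' The minimal length of a nascent polypeptide at the moment of labeling is
#' estimated by the last (most C-terminal) residue identified in its set of
#' peptides: the maximum `end` coordinate per protein.
#'
#' @param evidence A tibble with columns `accession`, `start`, `end`
#'   (1-based inclusive protein coordinates).
#' @return A tibble with columns `accession`, `minimal_length`.
#' @export
minimal_length <- function(evidence) {
  evidence |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(minimal_length = max(.data$end), .groups = "drop")
}

#' Histogram of peptide start positions
#'
#' Bins the first-residue positions of peptide evidence into fixed-width bins
#' `[1, w]`, `[w+1, 2w]`, ... The total count is conserved. Nascent protein
#' pools show an excess of N-terminal (early-bin) starts relative to
#' background, the signature of premature chain termination.
#'
#' @param evidence A tibble with a `start` column.
#' @param bin_width Bin width in residues (default 50).
#' @return A tibble with columns `bin_start`, `bin_end`, `count` (empty bins
#'   up to the last occupied bin included).
#' @export
start_histogram <- function(evidence, bin_width = 50L) {
  stopifnot(bin_width >= 1L)
  if (nrow(evidence) == 0L) {
    return(tibble::tibble(bin_start = integer(), bin_end = integer(), count = integer()))
  }
  bin <- (evidence$start - 1L) %/% bin_width
  n_bins <- max(bin) + 1L
  counts <- tabulate(bin + 1L, nbins = n_bins)
  tibble::tibble(
    bin_start = as.integer((seq_len(n_bins) - 1L) * bin_width + 1L),
    bin_end = as.integer(seq_len(n_bins) * bin_width),
    count = counts
  )
}

#' Merged protein sequence coverage
#'
#' Fraction of a protein covered by the union of peptide evidence intervals,
#' typically pooled across biological replicates.
#'
#' @param evidence A tibble with columns `start`, `end` for one protein.
#' @param protein_length Protein length in residues (must be at least the
#'   largest `end`).
#' @return Covered fraction in \[0, 1\].
#' @export
merged_coverage <- function(evidence, protein_length) {
  if (nrow(evidence) == 0L) {
    return(0)
  }
  if (max(evidence$end) > protein_length) {
    stop("evidence end exceeds protein length", call. = FALSE)
  }
  covered <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = evidence$start, end = evidence$end)
  )))
  covered / protein_length
}

#' Annotate the OPP incorporation site with the next residue and codon
#'
#' For a C-terminally modified peptide ending at residue `end`, the OPP
#' incorporation position is `end + 1`: the residue the ribosome would have
#' added next. Given the protein sequence and its in-frame coding sequence,
#' this returns the next amino acid, the DNA codon that encodes it, and
#' optionally its usage frequency per thousand codons from a supplied table.
#' When `end` equals the protein length, OPP was incorporated at the protein
#' C terminus and there is no next residue (the codon, if a coding sequence is
#' given, is the stop codon).
#'
#' @param evidence A tibble with columns `accession`, `end`.
#' @param proteins A tibble with columns `accession`, `sequence`.
#' @param cds Optional tibble with columns `accession`, `cds` (in-frame coding
#'   DNA, length `3 * protein_length` or `3 * (protein_length + 1)` with the
#'   stop codon).
#' @param codon_usage Optional tibble with columns `codon`,
#'   `frequency_per_thousand` (see [read_codon_usage()]).
#' @return `evidence` with added columns `incorporation_position`, `next_aa`
#'   (NA for C-terminal incorporation), `next_codon`, `frequency_per_thousand`
#'   (NA where unavailable).
#' @export
annotate_incorporation <- function(evidence, proteins, cds = NULL,
                                   codon_usage = NULL) {
  prot_seq <- stats::setNames(proteins$sequence, proteins$accession)
  seqs <- unname(prot_seq[evidence$accession])
  if (anyNA(seqs)) {
    stop("evidence references unknown protein accession(s)", call. = FALSE)
  }
  plen <- nchar(seqs)
  if (any(evidence$end > plen)) {
    stop("evidence end exceeds protein length", call. = FALSE)
  }
  pos <- evidence$end + 1L
  next_aa <- ifelse(pos > plen, NA_character_, substr(seqs, pos, pos))
  next_codon <- rep(NA_character_, nrow(evidence))
  if (!is.null(cds)) {
    cds_seq <- stats::setNames(cds$cds, cds$accession)[evidence$accession]
    has_cds <- !is.na(cds_seq)
    ok_len <- nchar(cds_seq) %in% c(3L * plen, 3L * (plen + 1L))
    if (any(has_cds & !ok_len)) {
      stop("coding sequence not in frame with protein length", call. = FALSE)
    }
    idx <- has_cds & (pos <= plen | nchar(cds_seq) == 3L * (plen + 1L))
    next_codon[idx] <- substr(cds_seq[idx], 3L * (pos[idx] - 1L) + 1L, 3L * pos[idx])
    translated <- Biostrings::GENETIC_CODE[next_codon[idx]]
    expected <- ifelse(is.na(next_aa[idx]), "*", next_aa[idx])
    bad <- !is.na(next_codon[idx]) & translated != expected
    if (any(bad)) {
      stop(
        "codon/amino-acid conflict at incorporation site(s): ",
        paste(evidence$accession[idx][bad], collapse = ", "),
        call. = FALSE
      )
    }
  }
  fpt <- rep(NA_real_, nrow(evidence))
  if (!is.null(codon_usage)) {
    fpt <- codon_usage$frequency_per_thousand[match(next_codon, codon_usage$codon)]
  }
  out <- evidence
  out$incorporation_position <- pos
  out$next_aa <- next_aa
  out$next_codon <- next_codon
  out$frequency_per_thousand <- fpt
  tibble::as_tibble(out)
}

#' Codon usage table
#'
#' Reads a two-column TSV of DNA codons and their usage frequency per
#' thousand codons. A human table covering the codons observed at OPP
#' incorporation sites in the bundled peptide set ships with the package.
#'
#' @param path Path to a TSV with columns `codon`,
#'   `frequency_per_thousand`; default the bundled table.
#' @return A tibble.
#' @export
read_codon_usage <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "codon_usage.tsv", package = "oppkit")
  }
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("codon", "frequency_per_thousand") %in% names(out)))
  out
}

#' Curated C-terminally OPP-modified peptides
#'
#' The bundled reference set of peptides identified with the OPP + residual
#' linker modification at their C terminus in OPP-treated K562 cells: protein
#' accession and gene, observed precursor m/z and charge, the modified peptide
#' sequence, and the incorporation-site annotation (next amino acid, its DNA
#' codon, and codon frequency per thousand). Three entries represent
#' incorporation at the protein C terminus (`next_aa` `"-"`). The
#' peptide/next-residue boundary of each entry was resolved with the
#' mass-accuracy rule: the split whose computed m/z at the reported charge
#' matches the observed value within the precursor tolerance and whose codon
#' translates to the next residue.
#'
#' @return A tibble with columns `accession`, `gene`, `protein_name`, `mz`,
#'   `z`, `peptide`, `next_aa`, `next_codon`, `fpt`.
#' @export
opp_cterm_peptides <- function() {
  path <- system.file("extdata", "opp_cterm_peptides.tsv", package = "oppkit")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
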