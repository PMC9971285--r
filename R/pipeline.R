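#' Run the full desk-scale pipeline on a simulated experiment
#'
#' Chains every stage on one seeded synthetic experiment: generate the
#' ground-truth proteome, spectra and quant tables; filter spectra on the
#' diagnostic ion; search the kept spectra against the proteome for
#' OPP-modified peptides with target-decoy FDR control; roll the accepted
#' identifications into positional evidence (minimal lengths, start-position
#' histogram, merged coverage, incorporation-site annotation); and run the
#' nascent-protein filter plus differential statistics on the quant tables.
#' When `out_dir` is given, every result is also written as a TSV (plus FASTA
#' and MGF inputs), so two runs with the same configuration can be compared
#' byte for byte.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Optional output directory (created if needed).
#' @return A list with `experiment`, `kept_spectra`, `psms`, `accepted`,
#'   `evidence`, `minimal_lengths`, `start_hist`, `coverage`, `annotation`,
#'   `diffexpr`, and (when written) `files`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL) {
  exp <- simulate_experiment(config)

  filt <- diagnostic_filter(exp$spectra)
  params <- search_params(rng_seed = config$rng_seed)
  psms <- search_spectra(filt$kept, exp$proteome[, c("accession", "sequence")], params)
  accepted <- accept_results(psms)

  evidence <- accepted$psms[, c("accession", "start", "end", "sequence")]
  lengths_tbl <- minimal_length(evidence)
  start_hist <- start_histogram(evidence)
  prot_len <- stats::setNames(exp$proteome$length, exp$proteome$accession)
  coverage <- evidence |>
    dplyr::group_by(.data$accession) |>
    dplyr::group_modify(~ tibble::tibble(
      coverage = merged_coverage(.x, prot_len[[.y$accession]])
    )) |>
    dplyr::ungroup()
  annotation <- annotate_incorporation(
    evidence, exp$proteome[, c("accession", "sequence")]
  )

  diffexpr <- diff_expression(exp$quant$protein_table, exp$quant$design)

  out <- list(
    experiment = exp,
    kept_spectra = filt$kept,
    psms = psms,
    accepted = accepted,
    evidence = evidence,
    minimal_lengths = lengths_tbl,
    start_hist = start_hist,
    coverage = coverage,
    annotation = annotation,
    diffexpr = diffexpr
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      proteome = file.path(out_dir, "proteome.fasta"),
      spectra = file.path(out_dir, "spectra.mgf"),
      psms = file.path(out_dir, "psms.tsv"),
      proteins = file.path(out_dir, "protein_quant.tsv"),
      diffexpr = file.path(out_dir, "diffexpr.tsv"),
      minimal_lengths = file.path(out_dir, "minimal_lengths.tsv"),
      start_hist = file.path(out_dir, "start_histogram.tsv"),
      coverage = file.path(out_dir, "coverage.tsv"),
      annotation = file.path(out_dir, "incorporation.tsv")
    )
    write_fasta(exp$proteome, files[["proteome"]])
    write_mgf(exp$spectra, files[["spectra"]])
    flat_psms <- psms
    readr::write_tsv(flat_psms, files[["psms"]], progress = FALSE)
    readr::write_tsv(exp$quant$protein_table, files[["proteins"]], progress = FALSE)
    readr::write_tsv(tidy(diffexpr), files[["diffexpr"]], progress = FALSE)
    readr::write_tsv(lengths_tbl, files[["minimal_lengths"]], progress = FALSE)
    readr::write_tsv(start_hist, files[["start_hist"]], progress = FALSE)
    readr::write_tsv(coverage, files[["coverage"]], progress = FALSE)
    readr::write_tsv(annotation, files[["annotation"]], progress = FALSE)
    out$files <- files
  }
  out
}
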