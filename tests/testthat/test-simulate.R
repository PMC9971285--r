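test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- sim_config(n_proteins = 15, n_contaminants = 3, rng_seed = 101)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fasta(a$proteome, file.path(d1, "p.fasta"))
  write_fasta(b$proteome, file.path(d2, "p.fasta"))
  write_mgf(a$spectra, file.path(d1, "s.mgf"))
  write_mgf(b$spectra, file.path(d2, "s.mgf"))
  readr::write_tsv(a$quant$peptides, file.path(d1, "q.tsv"), progress = FALSE)
  readr::write_tsv(b$quant$peptides, file.path(d2, "q.tsv"), progress = FALSE)
  for (f in c("p.fasta", "s.mgf", "q.tsv")) {
    expect_identical(
      readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
      readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    )
  }
  # different seeds give different data
  other <- simulate_proteome(sim_config(n_proteins = 15, rng_seed = 102))
  expect_false(identical(a$proteome$sequence[1], other$sequence[1]))
})

test_that("degenerate and boundary configurations behave", {
  empty <- simulate_proteome(sim_config(n_proteins = 0L, n_contaminants = 0L))
  expect_identical(nrow(empty), 0L)
  expect_error(sim_config(missing_rate = 2), "rates")
})

test_that("simulated proteomes hit the target K/R density", {
  cfg <- sim_config(n_proteins = 100, n_contaminants = 0, rng_seed = 107)
  prot <- simulate_proteome(cfg)
  res <- strsplit(paste(prot$sequence, collapse = ""), "")[[1]]
  expect_lt(abs(mean(res %in% c("K", "R")) - 0.10), 0.03)
})

test_that("round-tripping the proteome through FASTA is lossless", {
  cfg <- sim_config(n_proteins = 8, rng_seed = 109)
  prot <- simulate_proteome(cfg)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(prot, path)
  back <- read_fasta(path)
  expect_identical(back$accession, prot$accession)
  expect_identical(back$sequence, prot$sequence)
})

test_that("noise-free spectra are fully recovered by the search", {
  cfg <- sim_config(
    n_proteins = 14, nascent_fraction = 0.5, n_contaminants = 0,
    protein_length_range = c(80, 160),
    peak_dropout_rate = 0, n_noise_peaks = 0, mz_jitter_ppm = 1e-9,
    n_noise_spectra = 0, rng_seed = 113
  )
  prot <- simulate_proteome(cfg)
  sim <- simulate_spectra(cfg, prot)
  psms <- search_spectra(
    sim$spectra, prot[, c("accession", "sequence")],
    search_params(rng_seed = 3)
  )
  acc <- accept_results(psms)
  modified <- sim$truth[!is.na(sim$truth$cterm_mod), ]
  hits <- merge(acc$psms, modified, by = "spectrum_id")
  expect_identical(
    sum(hits$sequence.x == hits$sequence.y), nrow(modified)
  )
})

test_that("disabling the diagnostic ion leaves only false-positive spectra in the filter", {
  cfg <- sim_config(
    n_proteins = 60, nascent_fraction = 1, n_contaminants = 0,
    diagnostic_ion_enabled = FALSE, false_diagnostic_rate = 0.1,
    n_noise_spectra = 0, rng_seed = 127
  )
  sim <- simulate_spectra(cfg, simulate_proteome(cfg))
  got <- diagnostic_filter(sim$spectra)
  n <- nrow(sim$spectra)
  kept <- nrow(got$kept)
  ci <- binom.test(kept, n)$conf.int
  expect_true(ci[1] <= cfg$false_diagnostic_rate && cfg$false_diagnostic_rate <= ci[2])
})

test_that("fully sticky contaminants never pass the nascent filter", {
  cfg <- sim_config(
    n_proteins = 50, n_contaminants = 15, contaminant_pbs_prob = 1,
    missing_rate = 0, rng_seed = 131
  )
  q <- simulate_quant(cfg)
  got <- filter_nascent(
    q$protein_table[, c("accession", "sample", "unique_peptides")], q$design
  )
  cont <- q$truth$accession[q$truth$is_contaminant]
  expect_identical(intersect(got$kept, cont), character(0))
})

test_that("without missingness every kept protein is tested", {
  cfg <- sim_config(missing_rate = 0, nascent_pbs_carryover_prob = 0, rng_seed = 137)
  q <- simulate_quant(cfg)
  dx <- diff_expression(q$protein_table, q$design)
  expect_identical(sum(!tidy(dx)$tested), 0L)
})

test_that("null proteins recover a centered fold change near zero", {
  cfg <- sim_config(rng_seed = 139)
  q <- simulate_quant(cfg)
  dx <- diff_expression(q$protein_table, q$design)
  res <- dplyr::inner_join(tidy(dx), q$truth, by = "accession")
  null_fc <- res$log2_fc[!is.na(res$true_log2fc) & res$true_log2fc == 0]
  expect_lt(abs(mean(null_fc, na.rm = TRUE)), 0.1)
})
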