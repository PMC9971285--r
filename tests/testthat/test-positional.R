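test_that("minimal polypeptide length is the furthest identified residue", {
  ev <- tibble::tibble(
    accession = c("P", "P", "P", "Q"),
    start = c(10, 90, 50, 10),
    end = c(40, 120, 85, 25)
  )
  got <- minimal_length(ev)
  expect_identical(got$minimal_length[got$accession == "P"], 120)
  expect_identical(got$minimal_length[got$accession == "Q"], 25)
  withr::with_seed(71, {
    for (i in 1:10) {
      starts <- sample(1:200, 20, replace = TRUE)
      ends <- starts + sample(5:40, 20, replace = TRUE)
      ev <- tibble::tibble(accession = "X", start = starts, end = ends)
      expect_identical(minimal_length(ev)$minimal_length, max(ends))
    }
  })
})

test_that("start-position histograms bin correctly and conserve counts", {
  ev <- tibble::tibble(start = c(1, 2, 51))
  got <- start_histogram(ev, bin_width = 50L)
  expect_identical(got$count, c(2L, 1L))
  expect_identical(got$bin_start, c(1L, 51L))
  expect_identical(got$bin_end, c(50L, 100L))
  expect_identical(nrow(start_histogram(tibble::tibble(start = integer()))), 0L)
  withr::with_seed(73, {
    for (w in c(1L, 25L, 50L)) {
      ev <- tibble::tibble(start = sample(1:500, 200, replace = TRUE))
      expect_identical(sum(start_histogram(ev, w)$count), 200L)
    }
  })
})

test_that("merged coverage is the union of evidence intervals", {
  ev <- tibble::tibble(start = c(1, 5), end = c(10, 20))
  expect_equal(merged_coverage(ev, 100), 0.20)
  disjoint <- tibble::tibble(start = c(1, 91), end = c(10, 100))
  expect_equal(merged_coverage(disjoint, 100), 0.20)
  expect_equal(merged_coverage(tibble::tibble(start = 1, end = 60), 60), 1.0)
  expect_error(merged_coverage(tibble::tibble(start = 1, end = 61), 60), "exceeds")
  withr::with_seed(79, {
    for (i in 1:20) {
      L <- sample(50:300, 1)
      starts <- sample(seq_len(L - 5), 15, replace = TRUE)
      ends <- pmin(starts + sample(4:30, 15, replace = TRUE), L)
      ev <- tibble::tibble(start = starts, end = ends)
      expect_equal(merged_coverage(ev, L), oracle_coverage(starts, ends, L))
    }
  })
})

test_that("incorporation sites annotate the next residue and codon", {
  proteins <- tibble::tibble(
    accession = "NUC",
    sequence = "MTLVLSNLSYSATEETLQEVFEK"
  )
  cds <- tibble::tibble(
    accession = "NUC",
    cds = paste0(
      "ATG", "ACT", "CTG", "GTT", "CTG", "AGT", "AAT", "CTG", "AGC", "TAT",
      "TCA", "GCC", "ACT", "GAG", "GAA", "ACT", "CTG", "CAG", "GAG", "GTA",
      "TTT", "GAG", "AAA", "TAA"
    )
  )
  usage <- read_codon_usage()
  ev <- tibble::tibble(accession = "NUC", end = 19L)
  got <- annotate_incorporation(ev, proteins, cds, usage)
  expect_identical(got$incorporation_position, 20L)
  expect_identical(got$next_aa, "V")
  expect_identical(got$next_codon, "GTA")
  expect_equal(got$frequency_per_thousand, 7.66)

  # incorporation at the protein C terminus: no next residue, stop codon
  cterm <- annotate_incorporation(
    tibble::tibble(accession = "NUC", end = 23L), proteins, cds, usage
  )
  expect_true(is.na(cterm$next_aa))
  expect_identical(cterm$next_codon, "TAA")

  # frame mismatch and codon conflicts are errors
  bad_cds <- tibble::tibble(accession = "NUC", cds = "ATGACT")
  expect_error(annotate_incorporation(ev, proteins, bad_cds), "not in frame")
  wrong <- cds
  substr(wrong$cds, 58, 60) <- "CCC" # codon 20 no longer encodes V
  expect_error(annotate_incorporation(ev, proteins, wrong, usage), "conflict")
})

test_that("every curated OPP peptide reproduces its observed precursor m/z", {
  tbl <- opp_cterm_peptides()
  expect_identical(nrow(tbl), 27L)
  calc <- vapply(seq_len(nrow(tbl)), function(i) {
    mz_from_mass(peptide_mass(tbl$peptide[i], cterm_mod = "OPP_full"), tbl$z[i])
  }, numeric(1))
  ppm <- (calc - tbl$mz) / tbl$mz * 1e6
  expect_lt(max(abs(ppm)), 10) # within the precursor mass tolerance
  # the two canonical worked examples agree at printed precision
  expect_lt(abs(calc[tbl$gene == "LMNA"] - 696.3437), 5e-4)
  expect_lt(abs(calc[tbl$gene == "HIST1H2AB"] - 653.3621), 5e-4)
})

test_that("the curated peptide/next-residue splits are the unique mass-consistent ones", {
  tbl <- opp_cterm_peptides()
  gc <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(tbl))) {
    # codon translates the next residue (stop for C-terminal incorporation)
    expected <- ifelse(tbl$next_aa[i] == "-", "*", tbl$next_aa[i])
    expect_identical(unname(gc[tbl$next_codon[i]]), expected)
  }
  # moving the boundary by one residue in either direction breaks the mass match
  for (i in c(1, 8, 14, 27)) {
    full <- if (tbl$next_aa[i] == "-") tbl$peptide[i] else paste0(tbl$peptide[i], tbl$next_aa[i])
    for (cut in c(nchar(tbl$peptide[i]) - 1L, nchar(tbl$peptide[i]) + 1L)) {
      if (cut < 6L || cut > nchar(full)) next
      alt <- substr(full, 1, cut)
      if (identical(alt, tbl$peptide[i])) next
      alt_mz <- mz_from_mass(peptide_mass(alt, cterm_mod = "OPP_full"), tbl$z[i])
      expect_gt(abs(alt_mz - tbl$mz[i]) / tbl$mz[i] * 1e6, 10)
    }
  }
})

test_that("codon frequencies in the curated set are consistent", {
  tbl <- opp_cterm_peptides()
  usage <- read_codon_usage()
  fpt <- usage$frequency_per_thousand[match(tbl$next_codon, usage$codon)]
  expect_equal(fpt, tbl$fpt)
})
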