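test_that("tryptic digestion matches hand enumeration and the substring oracle", {
  got <- digest("MKTAYIAK", min_length = 2L)
  expect_setequal(got$sequence, c("MK", "TAYIAK", "MKTAYIAK"))

  withr::with_seed(19, {
    for (i in 1:12) {
      prot <- random_protein(sample(20:60, 1))
      for (semi in c(FALSE, TRUE)) {
        mc <- sample(0:2, 1)
        ml <- sample(c(2L, 6L), 1)
        got <- digest(prot, missed_cleavages = mc, semi_cterm = semi, min_length = ml)
        want <- oracle_digest(prot, missed_cleavages = mc, semi_cterm = semi, min_length = ml)
        expect_identical(
          as.data.frame(got[order(got$start, got$end), c("start", "end")]),
          data.frame(start = want$start, end = want$end),
          info = paste("semi =", semi, "mc =", mc, "protein", prot)
        )
      }
    }
  })
})

test_that("semi-specific candidates are a superset of fully tryptic ones", {
  withr::with_seed(23, {
    prot <- random_protein(50)
    full <- digest(prot, semi_cterm = FALSE)
    semi <- digest(prot, semi_cterm = TRUE)
    expect_true(all(paste(full$start, full$end) %in% paste(semi$start, semi$end)))
  })
})

test_that("modification variants carry the right masses and never clash", {
  cand <- digest("TLVLSNLSYSATEETLQEK", semi_cterm = TRUE)
  cand <- cand[cand$sequence == "TLVLSNLSYSATEETLQE", ]
  vars <- apply_mods(cand, search_params())
  opp <- vars[vars$cterm_mod == "OPP_full" & lengths(vars$mod_names) == 0, ]
  expect_equal(round(opp$neutral_mass, 4), 2574.2714)

  # fixed carbamidomethylation is applied unconditionally
  cys <- apply_mods(
    digest("AAACAAAK", min_length = 6L),
    search_params(cterm_mods = character(), require_cterm_mod = FALSE)
  )
  expect_equal(
    cys$neutral_mass[cys$sequence == "AAACAAAK"][1],
    peptide_mass("AAACAAAK"),
    tolerance = 1e-6
  )

  # with no variable mods allowed, each candidate yields one variant per
  # C-terminal option
  v0 <- apply_mods(cand, search_params(max_variable_mods = 0L))
  expect_identical(nrow(v0), 2L)
  expect_setequal(v0$cterm_mod, c("OPP_full", "OPP_purine_loss"))

  # two modifications are never placed on one site
  mm <- apply_mods(
    digest("MMAAAAK", min_length = 6L),
    search_params()
  )
  expect_true(all(vapply(
    mm$mod_positions, function(p) !anyDuplicated(p), logical(1)
  )))
})

test_that("fragment ladders share b ions and shift y ions under the C-terminal mod", {
  opp_delta <- monoisotopic_mass("C27H35N11O4")
  canonical <- theoretical_fragments("TLVLSNLSYSATEETLQEVFEK")
  modified <- theoretical_fragments("TLVLSNLSYSATEETLQE", cterm_delta = opp_delta)
  b_can <- canonical[canonical$series == "b", ]
  b_mod <- modified[modified$series == "b", ]
  expect_equal(
    b_mod$mz[order(b_mod$index)][1:17],
    b_can$mz[order(b_can$index)][1:17],
    tolerance = 1e-9
  )
  plain <- theoretical_fragments("TLVLSNLSYSATEETLQE")
  y_mod <- modified[modified$series == "y", ]
  y_plain <- plain[plain$series == "y", ]
  expect_equal(
    y_mod$mz[order(y_mod$index)] - y_plain$mz[order(y_plain$index)],
    rep(opp_delta, 17),
    tolerance = 1e-9
  )
  # b1 closed form
  ga <- theoretical_fragments("GAAAAK")
  expect_equal(
    ga$mz[ga$series == "b" & ga$index == 1], 57.02146 + 1.00728,
    tolerance = 1e-4
  )
})

test_that("the binomial score is maximal on self-matches and flat on noise", {
  pep <- "SAMPLELVNGK"
  frags <- theoretical_fragments(pep)
  peaks <- tibble::tibble(mz = sort(frags$mz), intensity = 100)
  self <- score_psm(peaks, frags$mz)
  expect_identical(self$matched, self$n_fragments)

  withr::with_seed(41, {
    # permuted-sequence decoys score strictly below the true candidate
    for (i in 1:10) {
      res <- strsplit(pep, "")[[1]]
      dec <- paste(sample(res[-length(res)]), collapse = "")
      dec_frags <- theoretical_fragments(paste0(dec, "K"))
      expect_lt(score_psm(peaks, dec_frags$mz)$score, self$score)
    }
    # on uniform noise the matched count follows its binomial null
    n_draws <- 300
    k <- replicate(n_draws, {
      noise <- tibble::tibble(mz = sort(runif(60, 150, 1500)), intensity = 1)
      score_psm(noise, frags$mz)$matched
    })
    width <- mean(tol_width(sort(unique(frags$mz)), 30, "ppm"))
    p <- 60 * 2 * width / 1350
    n <- length(unique(frags$mz))
    expect_lt(abs(mean(k) - n * p), 4 * sqrt(n * p / n_draws) + 0.05)
    scores <- replicate(50, {
      noise <- tibble::tibble(mz = sort(runif(60, 150, 1500)), intensity = 1)
      score_psm(noise, frags$mz)$score
    })
    expect_lt(mean(scores), 1.5)
  })
})

test_that("widening the fragment tolerance never loses matches", {
  withr::with_seed(43, {
    frags <- theoretical_fragments("ELVISLIVESK")
    noise <- tibble::tibble(mz = sort(runif(80, 150, 1500)), intensity = 1)
    narrow <- score_psm(noise, frags$mz, tol = 30)
    wide <- score_psm(noise, frags$mz, tol = 60)
    expect_gte(wide$matched, narrow$matched)
  })
})

test_that("decoy shuffling preserves K/R positions and composition", {
  prot <- tibble::tibble(accession = "P1", sequence = random_protein(80))
  dec <- decoy_proteins(prot, seed = 9)
  expect_identical(dec$accession, "DECOY_P1")
  a <- strsplit(prot$sequence, "")[[1]]
  b <- strsplit(dec$sequence, "")[[1]]
  expect_identical(which(a %in% c("K", "R")), which(b %in% c("K", "R")))
  expect_identical(sort(a), sort(b))
})

test_that("the search recovers simulated OPP peptides and controls decoys", {
  cfg <- sim_config(
    n_proteins = 16, nascent_fraction = 0.5, n_contaminants = 0,
    protein_length_range = c(80, 160), peak_dropout_rate = 0,
    n_noise_peaks = 10, n_noise_spectra = 0, rng_seed = 17
  )
  prot <- simulate_proteome(cfg)
  sim <- simulate_spectra(cfg, prot)
  psms <- search_spectra(
    sim$spectra, prot[, c("accession", "sequence")],
    search_params(rng_seed = 5)
  )
  acc <- accept_results(psms)
  modified <- sim$truth[!is.na(sim$truth$cterm_mod), ]
  hits <- merge(acc$psms, modified, by = "spectrum_id")
  recovered <- sum(hits$sequence.x == hits$sequence.y)
  expect_gte(recovered / nrow(modified), 0.95)

  # searching against a decoy-only database yields nothing at 1% FDR
  shuffled <- decoy_proteins(prot, seed = 99)
  shuffled$accession <- sub("DECOY_", "SHUF_", shuffled$accession)
  null_psms <- search_spectra(sim$spectra, shuffled, search_params(rng_seed = 5))
  null_acc <- accept_results(null_psms)
  # with all matches random, only the short leading run of target PSMs before
  # the first decoy can slip under the q threshold; that run is geometric with
  # mean 1, so a handful at most
  expect_lte(nrow(null_acc$psms), 3L)
  # no decoy PSM is ever accepted, by construction of the q-value
  expect_identical(sum(null_psms$is_decoy & null_psms$q_value <= 0.01), 0L)
})
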