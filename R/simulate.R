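#' Configuration for the synthetic-experiment generator
#'
#' Collects every knob of the ground-truth generator. Defaults describe the
#' desk-scale study conditions used throughout the package's tests: a
#' 200-protein proteome, half of it undergoing synthesis during the labeling
#' window, three biological replicates of PBS control / OPP-vehicle /
#' OPP-inhibitor, log-normal MS1 intensity noise of 0.2 on the log2 scale,
#' per-protein log2 fold changes drawn from \{-2, -1, 0, +1\} with mostly-null
#' proportions skewed toward repression (the expected signature of acute mTOR
#' inhibition), a 3.5% missing-at-random rate (chosen so that roughly 80% of
#' proteins are complete across the six OPP samples), and sticky background
#' contaminants that show up in PBS controls with more than one peptide.
#'
#' @param n_proteins Number of proteome proteins (contaminants are extra).
#' @param protein_length_range Length range (residues), uniform.
#' @param nascent_fraction Fraction of proteome proteins that are nascent.
#' @param kr_fraction Combined target frequency of K and R residues.
#' @param n_truncations Labeling (truncation) events simulated per nascent
#'   protein in the spectrum generator.
#' @param n_noise_peaks Uniform noise peaks added per spectrum.
#' @param peak_dropout_rate Probability that a fragment-ladder peak is lost.
#' @param mz_jitter_ppm Gaussian m/z jitter (1 sd, ppm) on all peaks.
#' @param diagnostic_ion_enabled Emit the m/z 164.0931 diagnostic ion in
#'   OPP-modified spectra.
#' @param false_diagnostic_rate Probability that a spectrum which should not
#'   carry the diagnostic ion contains a spurious peak at its m/z.
#' @param n_noise_spectra Pure-noise spectra appended per simulated run.
#' @param base_log2_intensity,base_log2_sd Log-normal model of per-protein
#'   base MS1 intensity (log2 scale).
#' @param sigma_rep Replicate noise sd on the log2 scale, per sample.
#' @param fc_levels,fc_props True log2 fold-change levels
#'   (inhibitor/vehicle) and their proportions among nascent proteins.
#' @param missing_rate Missing-at-random probability per peptide and sample.
#' @param peptides_lambda Peptides per protein are `2 + Poisson(peptides_lambda)`.
#' @param nascent_pbs_carryover_prob Probability that a nascent protein leaves
#'   a trace (exactly one peptide) in a given PBS control.
#' @param n_contaminants Number of sticky background proteins.
#' @param contaminant_pbs_prob Probability that a contaminant is detected in a
#'   given PBS control sample (with > 1 peptide).
#' @param n_replicates Biological replicates per condition.
#' @param rng_seed Integer seed; a fixed seed makes every output byte-identical.
#' @return A list of class `"sim_config"`, with `config_hash` attached.
#' @export
sim_config <- function(n_proteins = 200L,
                       protein_length_range = c(100L, 400L),
                       nascent_fraction = 0.5,
                       kr_fraction = 0.10,
                       n_truncations = 1L,
                       n_noise_peaks = 30L,
                       peak_dropout_rate = 0.10,
                       mz_jitter_ppm = 5,
                       diagnostic_ion_enabled = TRUE,
                       false_diagnostic_rate = 0.02,
                       n_noise_spectra = 20L,
                       base_log2_intensity = 20,
                       base_log2_sd = 2,
                       sigma_rep = 0.2,
                       fc_levels = c(-2, -1, 0, 1),
                       fc_props = c(0.10, 0.15, 0.65, 0.10),
                       missing_rate = 0.035,
                       peptides_lambda = 3,
                       nascent_pbs_carryover_prob = 0.10,
                       n_contaminants = 20L,
                       contaminant_pbs_prob = 0.9,
                       n_replicates = 3L,
                       rng_seed = 1L) {
  rates <- c(
    nascent_fraction, kr_fraction, peak_dropout_rate, false_diagnostic_rate,
    missing_rate, nascent_pbs_carryover_prob, contaminant_pbs_prob
  )
  stopifnot(all(rates >= 0 & rates <= 1), length(fc_levels) == length(fc_props))
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    protein_length_range = as.integer(protein_length_range),
    nascent_fraction = nascent_fraction,
    kr_fraction = kr_fraction,
    n_truncations = as.integer(n_truncations),
    n_noise_peaks = as.integer(n_noise_peaks),
    peak_dropout_rate = peak_dropout_rate,
    mz_jitter_ppm = mz_jitter_ppm,
    diagnostic_ion_enabled = isTRUE(diagnostic_ion_enabled),
    false_diagnostic_rate = false_diagnostic_rate,
    n_noise_spectra = as.integer(n_noise_spectra),
    base_log2_intensity = base_log2_intensity,
    base_log2_sd = base_log2_sd,
    sigma_rep = sigma_rep,
    fc_levels = fc_levels,
    fc_props = fc_props / sum(fc_props),
    missing_rate = missing_rate,
    peptides_lambda = peptides_lambda,
    nascent_pbs_carryover_prob = nascent_pbs_carryover_prob,
    n_contaminants = as.integer(n_contaminants),
    contaminant_pbs_prob = contaminant_pbs_prob,
    n_replicates = as.integer(n_replicates),
    rng_seed = as.integer(rng_seed)
  )
  cfg$config_hash <- rlang::hash(cfg)
  structure(cfg, class = "sim_config")
}

# Background residue frequencies (non-K/R mass renormalised to 1 - kr_fraction).
.residue_background <- c(
  G = 0.071, A = 0.078, S = 0.081, P = 0.063, V = 0.066, T = 0.054, C = 0.019,
  L = 0.096, I = 0.047, N = 0.037, D = 0.053, Q = 0.040, E = 0.063, M = 0.022,
  H = 0.023, F = 0.039, Y = 0.029, W = 0.012
)

#' Simulate a ground-truth proteome
#'
#' Draws random protein sequences with a realistic combined K/R density (so
#' that tryptic peptide lengths resemble real digests), marks a fraction as
#' nascent, assigns each nascent protein a true log2 fold change, and appends
#' sticky background contaminants. Deterministic under the config seed.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `accession`, `sequence`, `length`,
#'   `is_nascent`, `is_contaminant`, `true_log2fc` (NA for non-nascent), with
#'   the config hash attached as attribute `"config_hash"`.
#' @export
simulate_proteome <- function(config = sim_config()) {
  withr::with_seed(config$rng_seed, {
    n <- config$n_proteins + config$n_contaminants
    if (n == 0L) {
      return(structure(
        tibble::tibble(
          accession = character(), sequence = character(), length = integer(),
          is_nascent = logical(), is_contaminant = logical(), true_log2fc = numeric()
        ),
        config_hash = config$config_hash
      ))
    }
    probs <- c(
      .residue_background / sum(.residue_background) * (1 - config$kr_fraction),
      K = config$kr_fraction / 2, R = config$kr_fraction / 2
    )
    lens <- sample(
      seq.int(config$protein_length_range[1], config$protein_length_range[2]),
      n,
      replace = TRUE
    )
    seqs <- vapply(lens, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs), collapse = "")
    }, character(1))
    is_cont <- c(
      rep(FALSE, config$n_proteins),
      rep(TRUE, config$n_contaminants)
    )
    accession <- c(
      sprintf("PROT%04d", seq_len(config$n_proteins)),
      sprintf("CONT%03d", seq_len(config$n_contaminants))
    )[seq_len(n)]
    is_nascent <- rep(FALSE, n)
    if (config$n_proteins > 0L) {
      n_nascent <- round(config$nascent_fraction * config$n_proteins)
      is_nascent[sample(config$n_proteins, n_nascent)] <- TRUE
    }
    true_fc <- rep(NA_real_, n)
    true_fc[is_nascent] <- sample(
      config$fc_levels,
      sum(is_nascent),
      replace = TRUE, prob = config$fc_props
    )
    structure(
      tibble::tibble(
        accession = accession, sequence = seqs, length = lens,
        is_nascent = is_nascent, is_contaminant = is_cont,
        true_log2fc = true_fc
      ),
      config_hash = config$config_hash
    )
  })
}

#' Write a proteome to FASTA
#'
#' @param proteome Output of [simulate_proteome()] (or any tibble with
#'   `accession` and `sequence`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  set <- Biostrings::AAStringSet(stats::setNames(proteome$sequence, proteome$accession))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a protein FASTA into a tibble
#'
#' @param path FASTA file.
#' @return A tibble with columns `accession`, `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    accession = sub("\\s.*$", "", names(set)),
    sequence = unname(as.character(set))
  )
}

# Pick the semi-tryptic peptide ending at a truncation position: tryptic
# N-terminus, length >= min_length, and at most max_mc internal missed
# cleavages; the shortest qualifying peptide is used (fewest missed cleavages).
truncation_peptide <- function(sequence, trunc_pos, min_length = 6L, max_mc = 2L) {
  sites <- cleavage_sites(sequence)
  starts <- c(1L, sites + 1L)
  starts <- starts[starts <= trunc_pos - min_length + 1L]
  if (length(starts) == 0L) {
    return(NULL)
  }
  site_count <- vapply(starts, function(s) {
    sum(sites >= s & sites <= trunc_pos - 1L)
  }, integer(1))
  ok <- which(site_count <= max_mc)
  if (length(ok) == 0L) {
    return(NULL)
  }
  s <- max(starts[ok])
  pep <- substr(sequence, s, trunc_pos)
  if (grepl(paste0("[^", paste(.canonical_residues, collapse = ""), "]"), pep)) {
    return(NULL)
  }
  list(start = s, end = trunc_pos, sequence = pep)
}

#' Simulate MS/MS spectra with ground truth
#'
#' For each nascent protein, draws truncation positions uniformly along the
#' chain (the stochastic-incorporation premise of puromycylation), emits the
#' b/y ladder of the OPP-modified semi-tryptic peptide ending there (with
#' peak dropout and ppm jitter), the diagnostic ion at m/z 164.0931 as the
#' base peak (when enabled), and uniform noise peaks. Non-nascent,
#' non-contaminant identities contribute spectra of unmodified fully tryptic
#' peptides, and a configurable number of pure-noise spectra is appended.
#' Spectra lacking a true diagnostic ion acquire a spurious one at the
#' configured false-diagnostic rate.
#'
#' @param config A [sim_config()] object.
#' @param proteome Output of [simulate_proteome()].
#' @return A list with `spectra` (spectra tibble) and `truth` (one row per
#'   spectrum: source accession/peptide/modification, NA for noise spectra).
#' @export
simulate_spectra <- function(config = sim_config(), proteome = simulate_proteome(config)) {
  registry <- opp_modifications()
  opp_delta <- mod_delta("OPP_full", registry)
  diag_mz <- opp_diagnostic_mz()
  withr::with_seed(config$rng_seed + 1L, {
    specs <- list()
    truths <- list()
    add_spectrum <- function(id, pre_mz, z, rt, peaks, truth_row) {
      specs[[length(specs) + 1L]] <<- list(
        spectrum_id = id, precursor_mz = pre_mz, precursor_charge = z,
        retention_time = rt, peaks = peaks
      )
      truths[[length(truths) + 1L]] <<- truth_row
    }
    jitter <- function(mz) {
      mz * (1 + stats::rnorm(length(mz), 0, config$mz_jitter_ppm * 1e-6))
    }
    build_peaks <- function(frag_mz, with_diagnostic) {
      keep <- stats::runif(length(frag_mz)) >= config$peak_dropout_rate
      mz <- jitter(frag_mz[keep])
      intensity <- stats::runif(length(mz), 300, 1000)
      base <- if (length(intensity) > 0) max(intensity) else 1000
      if (with_diagnostic) {
        mz <- c(mz, jitter(diag_mz))
        intensity <- c(intensity, base * 1.2)
      } else if (stats::runif(1) < config$false_diagnostic_rate) {
        mz <- c(mz, jitter(diag_mz))
        intensity <- c(intensity, stats::runif(1, 100, base))
      }
      if (config$n_noise_peaks > 0L) {
        mz <- c(mz, stats::runif(config$n_noise_peaks, 150, 1800))
        intensity <- c(intensity, stats::runif(config$n_noise_peaks, 50, 0.3 * base))
      }
      tibble::tibble(mz = mz, intensity = intensity)[order(mz), ]
    }

    counter <- 0L
    for (i in seq_len(nrow(proteome))) {
      if (proteome$is_contaminant[i]) next
      if (proteome$is_nascent[i]) {
        for (ev in seq_len(config$n_truncations)) {
          trunc_pos <- sample(seq_len(proteome$length[i]), 1L)
          pep <- truncation_peptide(proteome$sequence[i], trunc_pos)
          if (is.null(pep)) next
          counter <- counter + 1L
          z <- sample(2:3, 1L)
          mass <- peptide_mass(pep$sequence, cterm_mod = "OPP_full")
          frags <- theoretical_fragments(pep$sequence,
            cterm_delta = opp_delta,
            max_charge = max(1L, z - 1L)
          )
          add_spectrum(
            id = sprintf("sim_%05d", counter),
            pre_mz = mz_from_mass(mass, z), z = z,
            rt = stats::runif(1, 0, 3600),
            peaks = build_peaks(frags$mz, config$diagnostic_ion_enabled),
            truth_row = tibble::tibble(
              spectrum_id = sprintf("sim_%05d", counter),
              accession = proteome$accession[i],
              start = pep$start, end = pep$end, sequence = pep$sequence,
              cterm_mod = "OPP_full", charge = z,
              truncation_position = trunc_pos
            )
          )
        }
      } else {
        cand <- digest(proteome$sequence[i],
          accession = proteome$accession[i],
          missed_cleavages = 0L, semi_cterm = FALSE, min_length = 7L
        )
        if (nrow(cand) == 0L) next
        pick <- cand[sample(nrow(cand), 1L), ]
        counter <- counter + 1L
        z <- sample(2:3, 1L)
        mass <- peptide_mass(pick$sequence)
        frags <- theoretical_fragments(pick$sequence, max_charge = max(1L, z - 1L))
        add_spectrum(
          id = sprintf("sim_%05d", counter),
          pre_mz = mz_from_mass(mass, z), z = z,
          rt = stats::runif(1, 0, 3600),
          peaks = build_peaks(frags$mz, FALSE),
          truth_row = tibble::tibble(
            spectrum_id = sprintf("sim_%05d", counter),
            accession = proteome$accession[i],
            start = pick$start, end = pick$end, sequence = pick$sequence,
            cterm_mod = NA_character_, charge = z,
            truncation_position = NA_integer_
          )
        )
      }
    }
    for (j in seq_len(config$n_noise_spectra)) {
      counter <- counter + 1L
      n_pk <- max(10L, config$n_noise_peaks)
      mz <- stats::runif(n_pk, 150, 1800)
      peaks <- tibble::tibble(
        mz = mz,
        intensity = stats::runif(n_pk, 50, 1000)
      )[order(mz), ]
      add_spectrum(
        id = sprintf("sim_%05d", counter),
        pre_mz = stats::runif(1, 400, 1200), z = sample(2:3, 1L),
        rt = stats::runif(1, 0, 3600),
        peaks = peaks,
        truth_row = tibble::tibble(
          spectrum_id = sprintf("sim_%05d", counter),
          accession = NA_character_, start = NA_integer_, end = NA_integer_,
          sequence = NA_character_, cterm_mod = NA_character_,
          charge = NA_integer_, truncation_position = NA_integer_
        )
      )
    }
    spectra <- spectra_tbl(
      spectrum_id = purrr::map_chr(specs, "spectrum_id"),
      precursor_mz = purrr::map_dbl(specs, "precursor_mz"),
      precursor_charge = purrr::map_int(specs, "precursor_charge"),
      retention_time = purrr::map_dbl(specs, "retention_time"),
      peaks = purrr::map(specs, "peaks")
    )
    list(spectra = spectra, truth = dplyr::bind_rows(truths))
  })
}

#' Simulate the multi-condition quantitative experiment
#'
#' Builds the peptide-level intensity table for the full design (PBS control,
#' OPP-vehicle, OPP-inhibitor, `n_replicates` biological replicates each).
#' Nascent proteins contribute their tryptic peptides to the OPP samples with
#' log-normal replicate noise and the protein's true log2 fold change applied
#' to the inhibitor condition; they occasionally leave a single-peptide trace
#' in a PBS control (tolerated by the background rule). Contaminants appear in
#' every OPP sample and, with the configured probability, in each PBS control
#' with more than one peptide — the signature the background filter removes.
#' Intensities are deleted missing-at-random at the configured rate; missing
#' stays missing (no imputation).
#'
#' @param config A [sim_config()] object.
#' @param proteome Output of [simulate_proteome()].
#' @return A list with `peptides` (long tibble: `accession`, `sequence`,
#'   `charge`, `sample`, `intensity`), `protein_table` (per accession/sample
#'   `unique_peptides` and `summed_intensity`), `design`, and `truth` (per
#'   protein: nascent/contaminant flags and true log2 FC).
#' @export
simulate_quant <- function(config = sim_config(), proteome = simulate_proteome(config)) {
  design <- experiment_design(config$n_replicates)
  withr::with_seed(config$rng_seed + 2L, {
    rows <- list()
    base_by_protein <- rep(NA_real_, nrow(proteome))
    for (i in seq_len(nrow(proteome))) {
      nascent <- proteome$is_nascent[i]
      cont <- proteome$is_contaminant[i]
      if (!nascent && !cont) next
      cand <- digest(proteome$sequence[i],
        accession = proteome$accession[i],
        missed_cleavages = 0L, semi_cterm = FALSE, min_length = 6L
      )
      if (nrow(cand) < 2L) next
      n_pep <- min(2L + stats::rpois(1L, config$peptides_lambda), nrow(cand))
      peps <- cand$sequence[sample(nrow(cand), n_pep)]
      base_protein <- config$base_log2_intensity + stats::rnorm(1, 0, config$base_log2_sd)
      base_by_protein[i] <- base_protein
      pep_share <- stats::rnorm(n_pep, 0, 1)
      fc <- if (nascent) proteome$true_log2fc[i] else 0

      for (s in seq_len(nrow(design))) {
        samp <- design$sample[s]
        state <- design$label_state[s]
        if (state == "PBS") {
          if (nascent) {
            if (stats::runif(1) < config$nascent_pbs_carryover_prob) {
              rows[[length(rows) + 1L]] <- tibble::tibble(
                accession = proteome$accession[i], sequence = peps[1],
                charge = 2L, sample = samp,
                intensity = 2^(base_protein - 4 + stats::rnorm(1, 0, config$sigma_rep))
              )
            }
          } else if (stats::runif(1) < config$contaminant_pbs_prob) {
            rows[[length(rows) + 1L]] <- tibble::tibble(
              accession = proteome$accession[i], sequence = peps,
              charge = 2L, sample = samp,
              intensity = 2^(base_protein + pep_share +
                stats::rnorm(n_pep, 0, config$sigma_rep))
            )
          }
        } else {
          shift <- if (design$treatment[s] == "inhibitor") fc else 0
          rows[[length(rows) + 1L]] <- tibble::tibble(
            accession = proteome$accession[i], sequence = peps,
            charge = 2L, sample = samp,
            intensity = 2^(base_protein + pep_share + shift +
              stats::rnorm(n_pep, 0, config$sigma_rep))
          )
        }
      }
    }
    peptides <- dplyr::bind_rows(rows)
    if (nrow(peptides) > 0L && config$missing_rate > 0) {
      peptides$intensity[stats::runif(nrow(peptides)) < config$missing_rate] <- NA_real_
    }
    protein_table <- peptides |>
      dplyr::filter(!is.na(.data$intensity)) |>
      dplyr::group_by(accession = .data$accession, sample = .data$sample) |>
      dplyr::summarise(
        unique_peptides = dplyr::n_distinct(.data$sequence),
        summed_intensity = sum(.data$intensity),
        .groups = "drop"
      )
    list(
      peptides = peptides,
      protein_table = protein_table,
      design = design,
      truth = dplyr::mutate(
        proteome[, c("accession", "is_nascent", "is_contaminant", "true_log2fc")],
        base_log2_intensity = base_by_protein
      )
    )
  })
}

#' Simulate a complete ground-truth experiment
#'
#' Convenience wrapper generating the proteome, the MS/MS spectra, and the
#' quantitative tables from one configuration. Everything is deterministic
#' under the configuration seed.
#'
#' @param config A [sim_config()] object.
#' @return A list with `config`, `proteome`, `spectra`, `spectra_truth`,
#'   `quant` (see [simulate_quant()]).
#' @export
simulate_experiment <- function(config = sim_config()) {
  proteome <- simulate_proteome(config)
  sp <- simulate_spectra(config, proteome)
  qt <- simulate_quant(config, proteome)
  list(
    config = config,
    proteome = proteome,
    spectra = sp$spectra,
    spectra_truth = sp$truth,
    quant = qt
  )
}
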