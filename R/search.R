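#' Search parameter set
#'
#' Collects the settings of the peptide-spectrum matching stage. Defaults
#' mirror the standard configuration of the OPP-modified search: 10 ppm
#' precursor and 30 ppm fragment tolerances, trypsin with two missed
#' cleavages, fixed cysteine carbamidomethylation, up to two variable
#' modifications per peptide, a semi-specific C terminus carrying exactly one
#' of the OPP C-terminal modifications, and a 1% target-decoy FDR.
#'
#' @param precursor_tol,precursor_tol_unit Precursor tolerance (default 10 ppm).
#' @param fragment_tol,fragment_tol_unit Fragment tolerance (default 30 ppm).
#' @param max_missed_cleavages Maximum missed cleavages (default 2).
#' @param max_variable_mods Maximum variable modifications per peptide
#'   (default 2, not counting the C-terminal OPP modification).
#' @param variable_mods Names of variable modifications from
#'   [opp_modifications()] to consider (default oxidation of Met, protein
#'   N-terminal acetylation, and N-terminal Gln to pyroGlu).
#' @param cterm_mods C-terminal modification names; each candidate variant
#'   carries exactly one of them (default the full OPP adduct and its
#'   purine-loss form).
#' @param require_cterm_mod If TRUE (default) only C-terminally modified
#'   variants are searched; if FALSE unmodified variants are searched too.
#' @param semi_cterm Semi-specific C terminus (default TRUE; set FALSE with
#'   empty `cterm_mods` for a canonical tryptic search).
#' @param min_peptide_length Minimum candidate length (default 6).
#' @param decoy_mode `"shuffle"` (per-protein residue shuffle preserving K/R
#'   positions) or `"reverse"`.
#' @param fdr_target Target false discovery rate (default 0.01).
#' @param rng_seed Seed for decoy generation.
#' @return A list of class `"search_params"`.
#' @export
search_params <- function(precursor_tol = 10, precursor_tol_unit = "ppm",
                          fragment_tol = 30, fragment_tol_unit = "ppm",
                          max_missed_cleavages = 2L,
                          max_variable_mods = 2L,
                          variable_mods = c("Oxidation", "Acetyl", "Gln_pyroGlu"),
                          cterm_mods = c("OPP_full", "OPP_purine_loss"),
                          require_cterm_mod = TRUE,
                          semi_cterm = TRUE,
                          min_peptide_length = 6L,
                          decoy_mode = c("shuffle", "reverse"),
                          fdr_target = 0.01,
                          rng_seed = 1L) {
  stopifnot(
    precursor_tol > 0, fragment_tol > 0,
    fdr_target > 0, fdr_target < 1
  )
  structure(
    list(
      precursor_tol = precursor_tol, precursor_tol_unit = precursor_tol_unit,
      fragment_tol = fragment_tol, fragment_tol_unit = fragment_tol_unit,
      max_missed_cleavages = as.integer(max_missed_cleavages),
      max_variable_mods = as.integer(max_variable_mods),
      variable_mods = variable_mods,
      cterm_mods = cterm_mods,
      require_cterm_mod = isTRUE(require_cterm_mod),
      semi_cterm = isTRUE(semi_cterm),
      min_peptide_length = as.integer(min_peptide_length),
      decoy_mode = match.arg(decoy_mode),
      fdr_target = fdr_target,
      rng_seed = as.integer(rng_seed)
    ),
    class = "search_params"
  )
}

#' Decoy protein database
#'
#' Builds one decoy per target protein. In `"shuffle"` mode the non-K/R
#' residues are permuted while every K and R stays at its original position,
#' preserving the tryptic peptide-length distribution; in `"reverse"` mode the
#' sequence is reversed. Decoy accessions are prefixed `DECOY_`.
#'
#' @param proteins A tibble with columns `accession` and `sequence`.
#' @param mode `"shuffle"` or `"reverse"`.
#' @param seed Integer seed making the shuffle reproducible.
#' @return A tibble of decoy proteins.
#' @export
decoy_proteins <- function(proteins, mode = c("shuffle", "reverse"), seed = 1L) {
  mode <- match.arg(mode)
  seqs <- withr::with_seed(seed, {
    vapply(proteins$sequence, function(s) {
      res <- strsplit(s, "", fixed = TRUE)[[1]]
      if (mode == "reverse") {
        return(paste(rev(res), collapse = ""))
      }
      movable <- which(!res %in% c("K", "R"))
      res[movable] <- res[sample(movable)]
      paste(res, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  tibble::tibble(
    accession = paste0("DECOY_", proteins$accession),
    sequence = seqs
  )
}

#' Expand peptide candidates with modification variants
#'
#' Applies the fixed and variable modifications of a parameter set to a table
#' of unmodified digestion candidates. Fixed carbamidomethylation of Cys is
#' always included in the mass. Variable modifications are placed at their
#' admissible sites (each Met for oxidation; position 0 for protein N-terminal
#' acetylation when the candidate starts the protein; an N-terminal Gln for
#' pyroGlu formation) and all subsets of at most `max_variable_mods`
#' placements are enumerated, never two on one site. Each variant additionally
#' carries exactly one C-terminal modification from `cterm_mods` (plus an
#' unmodified variant when `require_cterm_mod` is FALSE or `cterm_mods` is
#' empty).
#'
#' @param candidates Output of [digest()] (any number of proteins, bound
#'   rowwise).
#' @param params A [search_params()] object.
#' @return A tibble of candidate variants with list-columns `mod_names`,
#'   `mod_positions` (0 = N terminus, residue index otherwise), `mod_deltas`,
#'   plus `cterm_mod` (NA for none) and `neutral_mass`.
#' @export
apply_mods <- function(candidates, params = search_params()) {
  registry <- opp_modifications()
  cam <- mod_delta("Carbamidomethyl", registry)
  base_mass <- vapply(candidates$sequence, function(s) {
    res <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(.residue_mass_values[res]) + .water_mass + cam * sum(res == "C")
  }, numeric(1), USE.NAMES = FALSE)

  use_ox <- "Oxidation" %in% params$variable_mods
  use_ac <- "Acetyl" %in% params$variable_mods
  use_pq <- "Gln_pyroGlu" %in% params$variable_mods
  d_ox <- if (use_ox) mod_delta("Oxidation", registry) else 0
  d_ac <- if (use_ac) mod_delta("Acetyl", registry) else 0
  d_pq <- if (use_pq) mod_delta("Gln_pyroGlu", registry) else 0

  cterm <- params$cterm_mods
  cterm_opts <- if (length(cterm) == 0L) {
    tibble::tibble(cterm_mod = NA_character_, cterm_delta = 0)
  } else {
    opts <- tibble::tibble(
      cterm_mod = cterm,
      cterm_delta = vapply(cterm, mod_delta, numeric(1), registry = registry,
        USE.NAMES = FALSE
      )
    )
    if (!params$require_cterm_mod) {
      opts <- dplyr::bind_rows(opts, tibble::tibble(cterm_mod = NA_character_, cterm_delta = 0))
    }
    opts
  }

  # flat accumulation: one entry per (candidate, variable-mod subset)
  v_row <- integer(0)
  v_names <- list()
  v_pos <- list()
  v_delta <- list()
  v_sum <- numeric(0)

  has_m <- if (use_ox) grepl("M", candidates$sequence, fixed = TRUE) else logical(nrow(candidates))
  leading_q <- if (use_pq) startsWith(candidates$sequence, "Q") else logical(nrow(candidates))
  no_placements <- !has_m & !(use_ac & candidates$start == 1L) & !leading_q
  plain <- which(no_placements)
  if (length(plain) > 0L) {
    v_row <- plain
    v_names <- rep(list(character(0)), length(plain))
    v_pos <- rep(list(integer(0)), length(plain))
    v_delta <- rep(list(numeric(0)), length(plain))
    v_sum <- numeric(length(plain))
  }
  for (i in which(!no_placements)) {
    seq_i <- candidates$sequence[i]
    placements_pos <- integer()
    placements_name <- character()
    placements_delta <- numeric()
    if (use_ox && has_m[i]) {
      mpos <- stringr::str_locate_all(seq_i, "M")[[1]][, 1]
      placements_pos <- c(placements_pos, mpos)
      placements_name <- c(placements_name, rep("Oxidation", length(mpos)))
      placements_delta <- c(placements_delta, rep(d_ox, length(mpos)))
    }
    if (use_ac && candidates$start[i] == 1L) {
      placements_pos <- c(placements_pos, 0L)
      placements_name <- c(placements_name, "Acetyl")
      placements_delta <- c(placements_delta, d_ac)
    }
    if (use_pq && leading_q[i]) {
      placements_pos <- c(placements_pos, 0L)
      placements_name <- c(placements_name, "Gln_pyroGlu")
      placements_delta <- c(placements_delta, d_pq)
    }
    np <- length(placements_pos)
    subsets <- list(integer(0))
    for (k in seq_len(min(params$max_variable_mods, np))) {
      cmb <- utils::combn(np, k, simplify = FALSE)
      # at most one modification per site
      cmb <- cmb[vapply(cmb, function(idx) !anyDuplicated(placements_pos[idx]), logical(1))]
      subsets <- c(subsets, cmb)
    }
    for (sub in subsets) {
      v_row <- c(v_row, i)
      v_names[[length(v_names) + 1L]] <- placements_name[sub]
      v_pos[[length(v_pos) + 1L]] <- as.integer(placements_pos[sub])
      v_delta[[length(v_delta) + 1L]] <- placements_delta[sub]
      v_sum <- c(v_sum, sum(placements_delta[sub]))
    }
  }

  nct <- nrow(cterm_opts)
  nv <- length(v_row)
  idx <- rep(seq_len(nv), each = nct)
  rows <- v_row[idx]
  out <- tibble::tibble(
    accession = candidates$accession[rows],
    start = candidates$start[rows],
    end = candidates$end[rows],
    sequence = candidates$sequence[rows],
    missed_cleavages = candidates$missed_cleavages[rows],
    mod_names = v_names[idx],
    mod_positions = v_pos[idx],
    mod_deltas = v_delta[idx],
    cterm_mod = rep(cterm_opts$cterm_mod, times = nv),
    neutral_mass = base_mass[rows] + v_sum[idx] + rep(cterm_opts$cterm_delta, times = nv)
  )
  out
}

#' Theoretical b/y fragment ladder
#'
#' Computes the b- and y-series m/z values of a (possibly modified) peptide.
#' N-terminal and internal modifications shift the b ions covering their
#' position; the C-terminal modification mass appears in every y ion and in no
#' b ion. Fragment charges 1 up to `max_charge` are produced. Optional
#' satellite series with neutral loss of water or ammonia can be added.
#'
#' @param sequence Peptide sequence.
#' @param mod_positions Integer positions of variable modifications (0 = N
#'   terminus).
#' @param mod_deltas Mass deltas matching `mod_positions`.
#' @param cterm_delta Mass delta of the C-terminal modification (0 for none).
#' @param fixed_cys Apply carbamidomethylation at every Cys (default TRUE).
#' @param max_charge Highest fragment charge to generate (default 1).
#' @param satellites Also emit -H2O/-NH3 satellites (default FALSE).
#' @return A tibble with columns `ion` (e.g. `"b3"`, `"y7^2"`), `series`,
#'   `index`, `charge`, `mz`, sorted by m/z.
#' @export
theoretical_fragments <- function(sequence, mod_positions = integer(),
                                  mod_deltas = numeric(), cterm_delta = 0,
                                  fixed_cys = TRUE, max_charge = 1L,
                                  satellites = FALSE) {
  res <- check_sequence(sequence)
  n <- length(res)
  masses <- unname(.residue_mass_values[res])
  if (fixed_cys) {
    masses[res == "C"] <- masses[res == "C"] + mod_delta("Carbamidomethyl")
  }
  shifts <- numeric(n + 1L) # index p+1 holds delta at position p (0 = N-term)
  if (length(mod_positions) > 0L) {
    for (j in seq_along(mod_positions)) {
      shifts[mod_positions[j] + 1L] <- shifts[mod_positions[j] + 1L] + mod_deltas[j]
    }
  }
  prefix <- cumsum(masses) + cumsum(shifts[-1]) + shifts[1]
  total <- prefix[n] + cterm_delta
  idx <- seq_len(n - 1L)
  b_sum <- prefix[idx]
  y_sum <- total - prefix[n - idx] + .water_mass
  rows <- list()
  for (z in seq_len(max_charge)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      series = "b", index = idx, charge = z,
      mz = (b_sum + z * .proton_mass) / z
    )
    rows[[length(rows) + 1L]] <- tibble::tibble(
      series = "y", index = idx, charge = z,
      mz = (y_sum + z * .proton_mass) / z
    )
    if (satellites) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        series = "b-H2O", index = idx, charge = z,
        mz = (b_sum - .water_mass + z * .proton_mass) / z
      )
      nh3 <- monoisotopic_mass("H3N")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        series = "y-NH3", index = idx, charge = z,
        mz = (y_sum - nh3 + z * .proton_mass) / z
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$ion <- paste0(out$series, out$index, ifelse(out$charge > 1L, paste0("^", out$charge), ""))
  dplyr::arrange(out[, c("ion", "series", "index", "charge", "mz")], .data$mz)
}

#' Score one peptide-spectrum match
#'
#' Greedy one-to-one matching of the theoretical fragment ladder to observed
#' peaks within the fragment tolerance, scored by a binomial tail: with `n`
#' theoretical fragments, `k` matched, and a per-fragment chance hit
#' probability `p = n_peaks * 2 * width / mz_range`, the score is
#' `-log10 P(X >= k)` for `X ~ Binomial(n, p)`, floored at 0. This is a
#' deliberately simple, well-characterised null model.
#'
#' @param peaks A tibble of `mz`/`intensity`, sorted by m/z.
#' @param fragment_mz Theoretical fragment m/z values.
#' @param tol,tol_unit Fragment tolerance (default 30 ppm).
#' @return A list with `matched` (integer), `n_fragments`, and `score`.
#' @export
score_psm <- function(peaks, fragment_mz, tol = 30, tol_unit = "ppm") {
  frag <- sort(unique(fragment_mz))
  n <- length(frag)
  if (n == 0L || nrow(peaks) == 0L) {
    return(list(matched = 0L, n_fragments = n, score = 0))
  }
  widths <- tol_width(frag, tol, tol_unit)
  used <- logical(nrow(peaks))
  k <- 0L
  pos <- findInterval(frag, peaks$mz)
  for (i in seq_len(n)) {
    lo <- frag[i] - widths[i]
    hi <- frag[i] + widths[i]
    j <- pos[i]
    hit <- 0L
    for (cand in c(j, j + 1L)) {
      if (cand >= 1L && cand <= nrow(peaks) && !used[cand] &&
        peaks$mz[cand] >= lo && peaks$mz[cand] <= hi) {
        hit <- cand
        break
      }
    }
    if (hit > 0L) {
      used[hit] <- TRUE
      k <- k + 1L
    }
  }
  mz_range <- max(peaks$mz) - min(peaks$mz)
  mz_range <- max(mz_range, 1)
  p <- min(0.999, nrow(peaks) * 2 * mean(widths) / mz_range)
  score <- -stats::pbinom(k - 1L, n, p, lower.tail = FALSE, log.p = TRUE) / log(10)
  list(matched = k, n_fragments = n, score = max(0, score))
}

#' Search spectra against a protein database
#'
#' The full desk-scale search: digests the target proteins and a seeded decoy
#' database ([decoy_proteins()]), expands modification variants
#' ([apply_mods()]), matches each spectrum's precursor mass within the
#' precursor tolerance (at the annotated charge, or charges 2-4 when
#' unknown), scores every matching candidate ([score_psm()]), keeps the best
#' match per spectrum, and estimates q-values from the target-decoy score
#' distribution: the q-value of a PSM is the minimum, over score thresholds at
#' or below its score, of `#decoys / #targets` above threshold.
#'
#' @param spectra A spectra tibble (see [spectra_tbl()] / [read_mgf()]).
#' @param proteins A tibble with columns `accession`, `sequence` (targets
#'   only; decoys are generated internally).
#' @param params A [search_params()] object.
#' @return A tibble of best PSMs per spectrum (targets and decoys) with
#'   q-values, sorted by decreasing score, with the parameter set attached as
#'   attribute `"params"`.
#' @export
search_spectra <- function(spectra, proteins, params = search_params()) {
  if (nrow(proteins) == 0L) stop("empty protein database", call. = FALSE)
  if (nrow(spectra) == 0L) stop("no spectra to search", call. = FALSE)
  decoys <- decoy_proteins(proteins, mode = params$decoy_mode, seed = params$rng_seed)
  db <- dplyr::bind_rows(
    dplyr::mutate(proteins[, c("accession", "sequence")], is_decoy = FALSE),
    dplyr::mutate(decoys, is_decoy = TRUE)
  )
  cand <- purrr::map(seq_len(nrow(db)), function(i) {
    d <- digest(db$sequence[i],
      accession = db$accession[i],
      missed_cleavages = params$max_missed_cleavages,
      semi_cterm = params$semi_cterm,
      min_length = params$min_peptide_length
    )
    d
  })
  cand <- dplyr::bind_rows(cand)
  variants <- apply_mods(cand, params)
  variants$is_decoy <- startsWith(variants$accession, "DECOY_")
  ord <- order(variants$neutral_mass)
  variants <- variants[ord, , drop = FALSE]
  vmass <- variants$neutral_mass

  registry <- opp_modifications()
  best <- vector("list", nrow(spectra))
  for (s in seq_len(nrow(spectra))) {
    peaks <- spectra$peaks[[s]]
    charges <- spectra$precursor_charge[s]
    if (is.na(charges) || charges == 0L) charges <- 2:4
    best_row <- NULL
    for (z in charges) {
      neutral <- mass_from_mz(spectra$precursor_mz[s], z)
      width <- tol_width(neutral, params$precursor_tol, params$precursor_tol_unit)
      lo <- findInterval(neutral - width, vmass) + 1L
      hi <- findInterval(neutral + width, vmass)
      if (hi < lo) next
      for (v in lo:hi) {
        cterm_delta <- if (is.na(variants$cterm_mod[v])) 0 else mod_delta(variants$cterm_mod[v], registry)
        frags <- theoretical_fragments(
          variants$sequence[v],
          mod_positions = variants$mod_positions[[v]],
          mod_deltas = variants$mod_deltas[[v]],
          cterm_delta = cterm_delta,
          max_charge = max(1L, z - 1L)
        )
        sc <- score_psm(peaks, frags$mz,
          tol = params$fragment_tol,
          tol_unit = params$fragment_tol_unit
        )
        row <- tibble::tibble(
          spectrum_id = spectra$spectrum_id[s],
          accession = variants$accession[v],
          start = variants$start[v],
          end = variants$end[v],
          sequence = variants$sequence[v],
          mods = paste(
            c(
              variants$mod_names[[v]],
              if (!is.na(variants$cterm_mod[v])) paste0("Cterm:", variants$cterm_mod[v])
            ),
            collapse = ";"
          ),
          charge = as.integer(z),
          theo_mz = mz_from_mass(variants$neutral_mass[v], z),
          obs_mz = spectra$precursor_mz[s],
          ppm_error = (spectra$precursor_mz[s] - mz_from_mass(variants$neutral_mass[v], z)) /
            mz_from_mass(variants$neutral_mass[v], z) * 1e6,
          matched_fragments = sc$matched,
          n_fragments = sc$n_fragments,
          score = sc$score,
          is_decoy = variants$is_decoy[v]
        )
        if (is.null(best_row) ||
          row$score > best_row$score ||
          (row$score == best_row$score && row$matched_fragments > best_row$matched_fragments) ||
          (row$score == best_row$score && row$matched_fragments == best_row$matched_fragments &&
            best_row$is_decoy && !row$is_decoy)) {
          best_row <- row
        }
      }
    }
    best[[s]] <- best_row
  }
  psms <- dplyr::bind_rows(best)
  if (nrow(psms) == 0L) {
    return(structure(tibble::tibble(), params = params))
  }
  psms <- compute_qvalues(psms)
  structure(psms, params = params)
}

#' Target-decoy q-values for a PSM table
#'
#' @param psms A tibble with `score` and `is_decoy` columns.
#' @return The table sorted by decreasing score with a `q_value` column.
#' @export
compute_qvalues <- function(psms) {
  ord <- order(-psms$score)
  psms <- psms[ord, , drop = FALSE]
  # a threshold at score s accepts every PSM with score >= s, so tied scores
  # share one FDR estimate taken at the end of their tie group
  n_decoy <- cumsum(psms$is_decoy)
  n_target <- cumsum(!psms$is_decoy)
  last_of_group <- rev(!duplicated(rev(psms$score)))
  idx <- which(last_of_group)
  group <- idx[findInterval(seq_len(nrow(psms)), c(0, idx), left.open = TRUE)]
  fdr <- n_decoy[group] / pmax(n_target[group], 1L)
  psms$q_value <- rev(cummin(rev(fdr)))
  psms
}

#' Accepted identifications at a given FDR
#'
#' Filters a PSM table to target PSMs with `q_value` at or below the target
#' FDR, and derives a protein-level list controlled at the same FDR by picked
#' target-decoy competition: each target protein competes against its own
#' decoy, only the higher-scoring member of each pair survives, and protein
#' q-values are computed over the winners.
#'
#' @param psms Output of [search_spectra()].
#' @param fdr_target FDR threshold (default taken from the attached params, or
#'   0.01).
#' @return A list with `psms` (accepted target PSMs) and `proteins` (accepted
#'   protein accessions with protein-level q-values).
#' @export
accept_results <- function(psms, fdr_target = NULL) {
  params <- attr(psms, "params")
  if (is.null(fdr_target)) {
    fdr_target <- if (!is.null(params)) params$fdr_target else 0.01
  }
  accepted <- psms[!psms$is_decoy & psms$q_value <= fdr_target, , drop = FALSE]

  prot <- psms |>
    dplyr::mutate(base_accession = sub("^DECOY_", "", .data$accession)) |>
    dplyr::group_by(.data$base_accession, .data$is_decoy) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop")
  picked <- prot |>
    dplyr::group_by(.data$base_accession) |>
    dplyr::slice_max(.data$score, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  picked <- compute_qvalues(picked)
  proteins <- picked[!picked$is_decoy & picked$q_value <= fdr_target, , drop = FALSE]
  list(
    psms = accepted,
    proteins = tibble::tibble(
      accession = proteins$base_accession,
      score = proteins$score,
      q_value = proteins$q_value
    )
  )
}
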