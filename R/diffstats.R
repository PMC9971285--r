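#' Experiment design table
#'
#' Describes the samples of a labeling experiment: each sample is either a
#' PBS-treated control (no OPP label) or OPP-treated, OPP samples are split by
#' pretreatment (vehicle or mTOR inhibitor), and replicates are paired across
#' treatments by replicate index. The standard design is three biological
#' replicates per condition.
#'
#' @param n_replicates Number of biological replicates per condition.
#' @param conditions Character vector of conditions to include.
#' @return A tibble with columns `sample`, `label_state` (`"PBS"`/`"OPP"`),
#'   `treatment` (`"vehicle"`/`"inhibitor"`, NA for PBS), `replicate`.
#' @export
experiment_design <- function(n_replicates = 3L,
                              conditions = c("PBS", "OPP_vehicle", "OPP_inhibitor")) {
  rows <- purrr::map_dfr(conditions, function(cond) {
    tibble::tibble(
      sample = paste0(cond, "_", seq_len(n_replicates)),
      label_state = if (cond == "PBS") "PBS" else "OPP",
      treatment = dplyr::case_when(
        cond == "OPP_vehicle" ~ "vehicle",
        cond == "OPP_inhibitor" ~ "inhibitor",
        TRUE ~ NA_character_
      ),
      replicate = seq_len(n_replicates)
    )
  })
  rows
}

#' Nascent-protein inclusion/exclusion filter
#'
#' Applies the two filtering rules that define candidate nascent proteins:
#' \itemize{
#'   \item background exclusion — a protein identified in any PBS-treated
#'     control sample with more than `background_max_peptides` peptides is
#'     removed (reason `"background"`); the rule is applied per control
#'     sample, not pooled;
#'   \item replication inclusion — a protein is kept only if at least
#'     `min_replicates` samples within a single OPP-treated condition have at
#'     least `min_unique_peptides` unique peptides (otherwise reason
#'     `"insufficient_replication"`).
#' }
#'
#' @param protein_counts A tibble with columns `accession`, `sample`,
#'   `unique_peptides` (absent samples may simply be missing rows).
#' @param design An [experiment_design()] tibble covering the samples.
#' @param background_max_peptides Maximum tolerated peptides in any single PBS
#'   control (default 1).
#' @param min_unique_peptides Minimum unique peptides for a sample to count as
#'   a detection (default 2).
#' @param min_replicates Minimum qualifying replicates within one OPP
#'   condition (default 2).
#' @return A list with `kept` (character vector of accessions) and `excluded`
#'   (tibble of `accession`, `reason`).
#' @export
filter_nascent <- function(protein_counts, design,
                           background_max_peptides = 1L,
                           min_unique_peptides = 2L,
                           min_replicates = 2L) {
  unknown <- setdiff(unique(protein_counts$sample), design$sample)
  if (length(unknown) > 0L) {
    stop(
      "sample(s) not in design: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  counts <- dplyr::left_join(protein_counts, design, by = "sample")
  per_protein <- counts |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(
      background = any(.data$label_state == "PBS" &
        .data$unique_peptides > background_max_peptides),
      replicated = {
        opp <- .data$label_state == "OPP" &
          .data$unique_peptides >= min_unique_peptides
        any(tapply(opp, .data$treatment, sum, default = 0L) >= min_replicates)
      },
      .groups = "drop"
    )
  excluded <- dplyr::bind_rows(
    tibble::tibble(
      accession = per_protein$accession[per_protein$background],
      reason = "background"
    ),
    tibble::tibble(
      accession = per_protein$accession[!per_protein$background & !per_protein$replicated],
      reason = "insufficient_replication"
    )
  )
  list(
    kept = per_protein$accession[!per_protein$background & per_protein$replicated],
    excluded = excluded
  )
}

#' Per-replicate log2 intensity ratios
#'
#' Ratios are inhibitor-treated over vehicle-treated, paired by replicate
#' index. A ratio is defined only where both intensities are present and
#' positive; otherwise it is missing.
#'
#' @param protein_intensities A tibble with columns `accession`, `sample`,
#'   `summed_intensity`.
#' @param design An [experiment_design()] tibble.
#' @return A tibble with columns `accession`, `replicate`, `log2_ratio`
#'   (one row per protein/replicate pair present in the design; missing
#'   ratios are NA).
#' @export
log2_ratios <- function(protein_intensities, design) {
  opp <- design[design$label_state == "OPP", ]
  joined <- dplyr::left_join(
    protein_intensities, design,
    by = "sample"
  ) |>
    dplyr::filter(.data$label_state == "OPP")
  wide <- tidyr::expand_grid(
    accession = unique(protein_intensities$accession),
    replicate = sort(unique(opp$replicate))
  )
  get_int <- function(trt) {
    sub <- joined[joined$treatment == trt, c("accession", "replicate", "summed_intensity")]
    sub$summed_intensity[match(
      paste(wide$accession, wide$replicate),
      paste(sub$accession, sub$replicate)
    )]
  }
  v <- get_int("vehicle")
  i <- get_int("inhibitor")
  ok <- !is.na(v) & !is.na(i) & v > 0 & i > 0
  wide$log2_ratio <- ifelse(ok, log2(i / v), NA_real_)
  wide
}

#' Center replicate medians to the global median
#'
#' The global median `g` is the median of all non-missing log2 ratios pooled
#' across replicates; each replicate column is then shifted so that its median
#' equals `g`. An alternative definition of the centering target — the mean of
#' the replicate medians — is available via `method`.
#'
#' @param ratios Output of [log2_ratios()] (columns `accession`, `replicate`,
#'   `log2_ratio`).
#' @param method `"pooled"` (default) or `"mean_of_medians"`.
#' @return `ratios` with `log2_ratio` replaced by the centered values.
#' @export
median_center <- function(ratios, method = c("pooled", "mean_of_medians")) {
  method <- match.arg(method)
  col_medians <- tapply(ratios$log2_ratio, ratios$replicate, stats::median, na.rm = TRUE)
  if (any(is.na(col_medians))) {
    stop("replicate column with no non-missing ratios", call. = FALSE)
  }
  g <- if (method == "pooled") {
    stats::median(ratios$log2_ratio, na.rm = TRUE)
  } else {
    mean(col_medians)
  }
  shift <- as.numeric(g - col_medians[as.character(ratios$replicate)])
  out <- ratios
  out$log2_ratio <- ratios$log2_ratio + shift
  out
}

#' Two-tailed one-sample t test against zero
#'
#' Wraps the Student t test for a vector of per-replicate log2 ratios under
#' the null hypothesis of mean zero. With fewer than two non-missing values,
#' any missing value, or zero variance, the protein is flagged untested and no
#' p-value is produced.
#'
#' @param values Numeric vector of (centered) log2 ratios.
#' @return A tibble with columns `mean`, `t`, `p_value`, `tested`.
#' @export
one_sample_ttest <- function(values) {
  complete <- !anyNA(values) && length(values) >= 2L
  if (!complete || stats::sd(values) == 0) {
    return(tibble::tibble(
      mean = if (length(values) > 0L) mean(values, na.rm = TRUE) else NA_real_,
      t = NA_real_, p_value = NA_real_, tested = FALSE
    ))
  }
  fit <- stats::t.test(values, mu = 0, alternative = "two.sided")
  tibble::tibble(
    mean = unname(fit$estimate),
    t = unname(fit$statistic),
    p_value = fit$p.value,
    tested = TRUE
  )
}

#' Volcano significance classes
#'
#' A protein is significant when its absolute centered mean log2 fold change
#' strictly exceeds `fc_cutoff` and its p-value is strictly below `p_cutoff`
#' (both inequalities strict); significant proteins split into up- and
#' down-regulated by sign. Untested proteins (missing values or zero
#' variance) are classed `"untested"`.
#'
#' @param results A tibble with columns `log2_fc`, `p_value`, `tested`.
#' @param fc_cutoff Absolute log2 fold-change cutoff (default 1).
#' @param p_cutoff p-value cutoff (default 0.05).
#' @return `results` with an added `class` column (factor: down_significant,
#'   up_significant, not_significant, untested).
#' @export
classify_volcano <- function(results, fc_cutoff = 1, p_cutoff = 0.05) {
  cls <- dplyr::case_when(
    !results$tested ~ "untested",
    abs(results$log2_fc) > fc_cutoff & results$p_value < p_cutoff & results$log2_fc < 0 ~
      "down_significant",
    abs(results$log2_fc) > fc_cutoff & results$p_value < p_cutoff ~ "up_significant",
    TRUE ~ "not_significant"
  )
  results$class <- factor(
    cls,
    levels = c("down_significant", "up_significant", "not_significant", "untested")
  )
  results
}

#' Differential expression of the nascent proteome
#'
#' The full filtering and statistics stage: applies the nascent-protein
#' inclusion/exclusion filter ([filter_nascent()]), computes per-replicate
#' inhibitor/vehicle log2 ratios ([log2_ratios()]), centers replicate medians
#' to the global median ([median_center()]), tests each complete protein with
#' a two-tailed one-sample t test against zero ([one_sample_ttest()]), and
#' classifies the volcano ([classify_volcano()]). Proteins with incomplete
#' ratio vectors are reported with their fold change but left untested. Raw
#' p-values are thresholded by default; set `p_adjust = "BH"` for
#' Benjamini-Hochberg adjusted values instead.
#'
#' @param protein_table A tibble with columns `accession`, `sample`,
#'   `unique_peptides`, `summed_intensity` (e.g. from [rollup_proteins()]).
#' @param design An [experiment_design()] tibble.
#' @param background_max_peptides,min_unique_peptides,min_replicates Filter
#'   rules, see [filter_nascent()].
#' @param fc_cutoff,p_cutoff Significance cutoffs, see [classify_volcano()].
#' @param center_method Centering target, see [median_center()].
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return An object of class `"opp_diffexpr"`: a list with `results` (one
#'   row per kept protein), `ratios` (centered per-replicate ratios),
#'   `excluded`, `design` and the cutoffs. [tidy()], [glance()] and
#'   `autoplot()` methods are provided.
#' @export
diff_expression <- function(protein_table, design = experiment_design(),
                            background_max_peptides = 1L,
                            min_unique_peptides = 2L,
                            min_replicates = 2L,
                            fc_cutoff = 1, p_cutoff = 0.05,
                            center_method = "pooled",
                            p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  filt <- filter_nascent(
    protein_table[, c("accession", "sample", "unique_peptides")], design,
    background_max_peptides = background_max_peptides,
    min_unique_peptides = min_unique_peptides,
    min_replicates = min_replicates
  )
  kept_tbl <- protein_table[protein_table$accession %in% filt$kept, , drop = FALSE]
  ratios <- log2_ratios(
    kept_tbl[, c("accession", "sample", "summed_intensity")], design
  )
  centered <- median_center(ratios, method = center_method)
  results <- centered |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(
      test = list(one_sample_ttest(.data$log2_ratio)),
      .groups = "drop"
    ) |>
    tidyr::unnest("test") |>
    dplyr::rename(log2_fc = "mean")
  if (p_adjust == "BH") {
    results$p_value[results$tested] <- stats::p.adjust(
      results$p_value[results$tested],
      method = "BH"
    )
  }
  results <- classify_volcano(results, fc_cutoff = fc_cutoff, p_cutoff = p_cutoff)
  structure(
    list(
      results = results,
      ratios = centered,
      excluded = filt$excluded,
      design = design,
      fc_cutoff = fc_cutoff,
      p_cutoff = p_cutoff
    ),
    class = "opp_diffexpr"
  )
}

#' @export
print.opp_diffexpr <- function(x, ...) {
  counts <- table(x$results$class)
  cat("Nascent-proteome differential expression\n")
  cat("  proteins kept:    ", nrow(x$results), "\n", sep = "")
  cat("  excluded:         ", nrow(x$excluded), "\n", sep = "")
  cat(
    "  down/up/ns/untested: ",
    paste(counts[c("down_significant", "up_significant", "not_significant", "untested")],
      collapse = "/"
    ), "\n",
    sep = ""
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-protein differential results
#'
#' @param x An `opp_diffexpr` object.
#' @param ... Unused.
#' @return The per-protein results tibble (`accession`, `log2_fc`, `t`,
#'   `p_value`, `tested`, `class`).
#' @exportS3Method generics::tidy
#' @export
tidy.opp_diffexpr <- function(x, ...) {
  x$results
}

#' One-row summary of a differential analysis
#'
#' @param x An `opp_diffexpr` object.
#' @param ... Unused.
#' @return A one-row tibble with protein counts per class and the cutoffs.
#' @exportS3Method generics::glance
#' @export
glance.opp_diffexpr <- function(x, ...) {
  counts <- table(x$results$class)
  tibble::tibble(
    n_kept = nrow(x$results),
    n_excluded = nrow(x$excluded),
    n_tested = sum(x$results$tested),
    n_down = unname(counts["down_significant"]),
    n_up = unname(counts["up_significant"]),
    n_not_significant = unname(counts["not_significant"]),
    n_untested = unname(counts["untested"]),
    fc_cutoff = x$fc_cutoff,
    p_cutoff = x$p_cutoff
  )
}

#' Volcano plot of a differential analysis
#'
#' @param object An `opp_diffexpr` object.
#' @param ... Unused.
#' @return A ggplot: -log10(p) against centered mean log2 fold change,
#'   significant proteins highlighted.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.opp_diffexpr <- function(object, ...) {
  df <- object$results[object$results$tested, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2_fc, y = -log10(.data$p_value),
    colour = .data$class %in% c("down_significant", "up_significant")
  )) +
    ggplot2::geom_point(alpha = 0.7, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::geom_vline(
      xintercept = c(-object$fc_cutoff, object$fc_cutoff),
      linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::geom_hline(
      yintercept = -log10(object$p_cutoff),
      linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::labs(
      x = "log2 fold change (inhibitor / vehicle)",
      y = "-log10(p-value)"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
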