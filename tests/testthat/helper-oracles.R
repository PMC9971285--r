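# Independent brute-force oracles, deliberately written without reference to
# the package internals they check.

CANONICAL20 <- strsplit("GASPVTCLINDQKEMHFRYW", "")[[1]]

random_protein <- function(n, kr = 0.1) {
  probs <- rep((1 - kr) / 18, 20)
  probs[CANONICAL20 %in% c("K", "R")] <- kr / 2
  paste(sample(CANONICAL20, n, replace = TRUE, prob = probs), collapse = "")
}

# Exhaustive substring enumeration implementing the digestion rules literally.
oracle_digest <- function(sequence, missed_cleavages = 2, semi_cterm = FALSE,
                          min_length = 6) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  is_site <- function(p) p >= 1 && p < n && res[p] %in% c("K", "R") && res[p + 1] != "P"
  rows <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (e - s + 1 < min_length) next
      nterm_ok <- s == 1 || is_site(s - 1)
      cterm_ok <- if (semi_cterm) TRUE else (e == n || is_site(e))
      if (!nterm_ok || !cterm_ok) next
      internal <- if (e > s) sum(vapply(s:(e - 1), is_site, logical(1))) else 0
      if (internal > missed_cleavages) next
      rows[[length(rows) + 1L]] <- data.frame(start = s, end = e)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer()))
  }
  out[order(out$start, out$end), , drop = FALSE]
}

# Literal transcription of the inclusion/exclusion rule sentence.
oracle_filter <- function(counts, design, background_max = 1, min_pep = 2,
                          min_rep = 2) {
  keep <- character()
  for (acc in unique(counts$accession)) {
    sub <- counts[counts$accession == acc, ]
    get <- function(sample) {
      i <- match(sample, sub$sample)
      if (is.na(i)) 0 else sub$unique_peptides[i]
    }
    pbs <- design$sample[design$label_state == "PBS"]
    if (any(vapply(pbs, get, numeric(1)) > background_max)) next
    ok <- FALSE
    for (trt in c("vehicle", "inhibitor")) {
      samp <- design$sample[!is.na(design$treatment) & design$treatment == trt]
      if (sum(vapply(samp, get, numeric(1)) >= min_pep) >= min_rep) ok <- TRUE
    }
    if (ok) keep <- c(keep, acc)
  }
  keep
}

# Residue-by-residue interval union.
oracle_coverage <- function(starts, ends, protein_length) {
  covered <- logical(protein_length)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  mean(covered)
}

# Closed-form peptide mass from an independent constant table (4 d.p. values
# as tabulated in standard proteomics references).
ORACLE_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

oracle_peptide_mass <- function(sequence, extra = 0) {
  sum(ORACLE_RESIDUE[strsplit(sequence, "")[[1]]]) + 18.01056 + extra
}
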