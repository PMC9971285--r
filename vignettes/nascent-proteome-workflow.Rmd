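---
title: "Identifying and quantifying OPP-tagged nascent proteins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and quantifying OPP-tagged nascent proteins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oppkit)
```

## The experiment this package models

O-propargyl-puromycin (OPP) enters the ribosomal A site and is incorporated at
the C terminus of elongating polypeptide chains, terminating them. Labeled,
truncated chains are captured by click chemistry through a cleavable
biotin-azide linker, released by hydrazine cleavage, digested with trypsin,
and analyzed by LC-MS/MS. Two analytical consequences drive everything in this
package:

1. **Chemistry.** After linker cleavage, every labeled chain carries OPP plus
   a residual fragment of the linker at its C terminus — a mass addition of
   C~27~H~35~N~11~O~4~ (577.2873 Da). Under collision-induced dissociation the
   labile purine moiety is lost (−C~7~H~9~N~5~, −163.0858 Da, leaving a
   C~20~H~26~N~6~O~4~ adduct of 414.2016 Da) and a diagnostic fragment cation
   C~7~H~10~N~5~^+^ appears at m/z 164.0931 (printed 164.09 at two decimals).
   Because incorporation terminates the chain anywhere, the modified peptide
   has a tryptic N terminus but an *arbitrary* C terminus: the search must be
   semi-specific.
2. **Statistics.** Nascent proteins are called from a three-replicate design
   (PBS control, OPP + vehicle, OPP + mTOR-inhibitor) by label-free MS1
   quantification, a background/replication filter, and a one-sample t test
   on median-centered log2 ratios.

The package implements both halves plus a seeded synthetic-data generator, so
that every stage is testable at desk scale without any external download.

## Mass arithmetic and its constants

All masses are monoisotopic, computed from one embedded element table
(C 12, H 1.0078250319, N 14.0030740052, O 15.9949146221, S 31.97207069;
electron 0.00054858). Protonated-ion m/z uses a proton mass of 1.00728 Da:
m/z = (M + z·1.00728)/z. The modification registry ships as a TSV whose
`delta_mass` column is a rounded check value; the elemental formula is the
source of truth and is what the package actually sums.

Worked examples computed by the package:

```{r masses}
monoisotopic_mass("C27H35N11O4")
opp_diagnostic_mz()
mz_from_mass(peptide_mass("TLVLSNLSYSATEETLQEVFEK"), 3)
mz_from_mass(peptide_mass("TLVLSNLSYSATEETLQE", cterm_mod = "OPP_full"), 3)
```

Published worked-example m/z values for these species are *observed* precursor
masses; they agree with the theoretical values above to within a few parts per
million, not necessarily at the fourth decimal. Comparisons in the test suite
therefore use ±0.0005 m/z where agreement at printed precision holds, and the
10 ppm precursor tolerance for observed-mass tables. The bundled table of 27
C-terminally modified peptides (`opp_cterm_peptides()`) was frozen with its
peptide/next-residue boundary resolved by exactly this mass rule: the split is
accepted only if the computed m/z at the reported charge matches the observed
value within tolerance *and* the annotated codon translates to the next
residue. For one entry (a glycine run at the boundary) the naive "last three
letters are the codon" reading fails and only the mass rule gives the correct
split.

## The semi-specific modified search

Candidates are generated per protein: tryptic N terminus (after K/R, not
before P, or position 1), any C terminus at least `min_peptide_length = 6`
residues downstream, and at most two internal missed cleavages. A non-tryptic
C terminus is not itself a missed cleavage. Each candidate carries fixed
cysteine carbamidomethylation, up to `max_variable_mods = 2` variable
modifications (Met oxidation, protein N-terminal acetylation, N-terminal
Gln→pyroGlu; N-terminal Met removal is a sequence variant rather than a site
delta and is not enumerated), and exactly one of the C-terminal OPP
modifications — or none, when `require_cterm_mod = FALSE`.

Scoring is a deliberately simple declared model: theoretical b/y ladders
(fragment charges up to the precursor charge minus one) are greedily matched
one-to-one to peaks within the 30 ppm fragment tolerance, and the score is
the binomial tail −log10 P(X ≥ k) with n theoretical fragments, k matches,
and per-fragment chance probability p = n_peaks × 2 × tolerance-width /
scanned-range. Decoys are per-protein shuffles that keep every K and R in
place, preserving the tryptic length distribution under a fixed seed.

### q-values at desk scale

The q-value of a peptide-spectrum match is the minimum, over score thresholds
at or below its score, of decoy/target counts above threshold. Two numerical
choices matter:

- **Tied scores share one estimate.** A threshold accepts every match at or
  above it, so ties are evaluated as a block; otherwise a block of zero-score
  matches could be ordered targets-first and be accepted with q = 0.
- **No +1 decoy pseudo-count.** The conservative correction would make
  q ≤ 0.01 unattainable with fewer than about a hundred matches, which is the
  entire regime of the desk-scale simulations. The cost is that q-values from
  very small runs are optimistic; where the tests measure empirical FDR they
  pool the matches of twenty seeded repeats before estimating q, which is
  statistically a single larger run.

When a simulated run contains spectra of *unmodified* peptides, the search is
run with `require_cterm_mod = FALSE` so those spectra have their true
candidate available. With modified-only candidates they can only match
same-precursor-mass ("homeometric") candidates; at full scale the decoy tail
absorbs these, but a desk-scale decoy set is too small to calibrate them, and
the measured false-discovery proportion inflates for that artifactual reason.

## Quantification

MS1 extracted-ion intensities use a closed retention-time window of −10/+30 s
around the moment the precursor was selected, and by default the *sum* of
in-window, in-tolerance intensities (an area-like aggregate; `"apex"` is
available). Shared peptides are assigned uniquely to the highest-ranked
protein containing their sequence, the ranking being descending distinct
peptide count, then descending total intensity, then accession — a
deterministic stand-in for a search-engine report order. Protein intensity
per sample is the sum of assigned peptide-entity intensities (charge states
quantified separately and summed); the unique-peptide count collapses charge
and modification and counts distinct sequences. Missing intensities stay
missing — no imputation, no zero-fill — because the downstream filter and
test distinguish complete from incomplete proteins.

## The nascent filter and differential statistics

A protein is excluded if **any single** PBS control sample identifies it with
more than one peptide (the rule is read per sample, not pooled across
controls), and kept only if at least two replicates **within one** OPP
condition identify it with at least two unique peptides. Per-replicate log2
ratios (inhibitor/vehicle, paired by replicate index) are defined only where
both intensities are present and positive. The "global median" used for
centering is the median of all pooled non-missing ratios (an alternative,
the mean of replicate medians, is exposed as a flag); every replicate column
is shifted so its median equals it. Proteins with a complete ratio vector are
tested with a two-tailed one-sample Student t test against zero
(`stats::t.test`); incomplete or zero-variance proteins are reported with
their fold change but classed `untested`. Significance uses the strict
inequalities |log2 FC| > 1 and p < 0.05 on raw p-values; Benjamini-Hochberg
adjustment is available but off by default, matching the thresholding of raw
p-values in this workflow.

```{r diffexpr}
q <- simulate_quant(sim_config(rng_seed = 1))
dx <- diff_expression(q$protein_table, q$design)
glance(dx)
```

## Positional analyses

The minimal polypeptide length of a nascent protein is the largest end
coordinate among its peptides; start positions are binned into fixed-width
bins of 50 residues (a display choice — the width is a free parameter);
merged coverage is the union of evidence intervals (computed with IRanges)
divided by protein length. The OPP incorporation site of a C-terminally
modified peptide is the residue after its last identified one; given an
in-frame coding sequence the package reports the codon at that position and
its usage frequency per thousand from a user-supplied table (a small human
table covering the bundled peptide set ships with the package). Incorporation
at the protein C terminus is reported with no next residue and, where a
coding sequence is present, the stop codon.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults define the study conditions used across the tests:

- 200 proteins of 100-400 residues with ~10% combined K/R (so tryptic
  peptide lengths are realistic), half of them nascent;
- one uniform truncation position per nascent protein per labeling event —
  the stochastic-incorporation premise; pause-site enrichment is *not*
  modeled;
- spectra with full b/y ladders, 10% peak dropout, 5 ppm m/z jitter, 30
  uniform noise peaks, the diagnostic ion as base peak, and a 2% false
  diagnostic rate on unlabeled spectra;
- log-normal MS1 intensities (log2 sd 2 between proteins, 0.2 between
  replicates), true log2 fold changes drawn from {−2, −1, 0, +1} with
  proportions (0.10, 0.15, 0.65, 0.10) — mostly null, skewed toward
  repression as expected under acute mTOR inhibition;
- a 3.5% missing-at-random rate, chosen so that roughly 80% of kept proteins
  are complete across the six OPP samples, mirroring the completeness
  reported for this kind of design;
- 20 sticky contaminants present in each PBS control with probability 0.9
  (with >1 peptide), and a 10% chance that a nascent protein leaves a
  single-peptide trace in a control — exercising the "≤1 peptide in PBS is
  tolerated" side of the background rule.

Every output is byte-identical under a fixed seed (`withr::with_seed`
around each stage; the configuration hash travels with the proteome).

The generator does **not** emulate chromatographic peak shapes, isotope
envelopes, chimeric spectra, charge-state-dependent fragmentation efficiency,
intensity-dependent missingness, or shared peptides between paralogs. Passing
tests therefore demonstrate the correctness of the implemented rules and
estimators under the stated noise model, not instrument-level realism.

Problem sizes in the test suite and acceptance script are the package's own
desk-scale choices: searches use 12-16 proteins of 80-160 residues with a few
dozen spectra (pooled over 20 seeds where an FDR is estimated), and the
quantitative pipeline uses the default 200-protein, 3-replicate design.

## Known limitations

- The binomial score is a null model, not a discriminant trained on real
  spectra; its absolute values are not comparable to commercial engine
  scores.
- q-values from a single tiny run are optimistic (see above); interpret
  desk-scale q-values only in pooled form.
- The semi-specific search space grows quadratically with protein length;
  the implementation is meant for the desk scale, not for a 20,000-protein
  database.
- Codon annotation requires a user-supplied, in-frame coding sequence; the
  package does not fetch or reconcile transcript isoforms.
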