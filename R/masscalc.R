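#' Parse a chemical formula into an element composition
#'
#' Splits a Hill-style formula string such as `"C27H35N11O4"` into a named
#' integer vector of element counts. Only elements present in the embedded
#' monoisotopic mass table are accepted; anything else is an error naming the
#' offending token. A trailing `"+"` (charge marker, as in `"C7H10N5+"`) is
#' stripped and must be handled by the caller via the `charge` argument of
#' [monoisotopic_mass()].
#'
#' @param text A chemical formula string, e.g. `"C27H35N11O4"` or `"H2O"`.
#' @return A named integer vector of element counts (class
#'   `"element_composition"`), in Hill order (C, H, then alphabetical).
#' @examples
#' parse_formula("C27H35N11O4")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  body <- sub("\\+$", "", trimws(text))
  if (!nzchar(body)) {
    stop("empty chemical formula", call. = FALSE)
  }
  tokens <- stringr::str_match_all(body, "([A-Z][a-z]?)([0-9]*)")[[1]]
  parsed <- paste0(tokens[, 1], collapse = "")
  if (!identical(parsed, body)) {
    bad <- substr(body, nchar(parsed) + 1L, nchar(body))
    stop("malformed formula near '", bad, "' in '", text, "'", call. = FALSE)
  }
  elements <- tokens[, 2]
  unknown <- setdiff(elements, names(.element_masses))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
      " in '", text, "'",
      call. = FALSE
    )
  }
  counts <- ifelse(tokens[, 3] == "", 1L, suppressWarnings(as.integer(tokens[, 3])))
  comp <- tapply(counts, elements, sum)
  composition(stats::setNames(as.integer(comp), names(comp)))
}

#' @rdname parse_formula
#' @param counts A named non-negative integer vector of element counts.
#' @export
composition <- function(counts) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  if (any(counts < 0)) {
    stop("element counts must be non-negative", call. = FALSE)
  }
  unknown <- setdiff(names(counts), names(.element_masses))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- counts[counts > 0]
  ord <- hill_order(names(counts))
  structure(as.integer(counts[ord]), names = ord, class = "element_composition")
}

hill_order <- function(elements) {
  rest <- sort(setdiff(elements, c("C", "H")))
  c(intersect(c("C", "H"), elements), rest)
}

#' @rdname parse_formula
#' @param comp An element composition.
#' @export
formula_string <- function(comp) {
  paste0(names(comp), ifelse(comp == 1L, "", comp), collapse = "")
}

#' Add or subtract element compositions
#'
#' Composition arithmetic for building modification chemistries (for instance
#' the full OPP-plus-linker adduct minus its purine neutral loss). Subtraction
#' that would drive any element count negative is an error.
#'
#' @param a,b Element compositions (or formula strings, which are parsed).
#' @return An element composition.
#' @export
composition_add <- function(a, b) {
  a <- as_composition(a)
  b <- as_composition(b)
  all_el <- union(names(a), names(b))
  counts <- stats::setNames(numeric(length(all_el)), all_el)
  counts[names(a)] <- counts[names(a)] + a
  counts[names(b)] <- counts[names(b)] + b
  composition(counts)
}

#' @rdname composition_add
#' @export
composition_subtract <- function(a, b) {
  a <- as_composition(a)
  b <- as_composition(b)
  all_el <- union(names(a), names(b))
  counts <- stats::setNames(numeric(length(all_el)), all_el)
  counts[names(a)] <- counts[names(a)] + a
  counts[names(b)] <- counts[names(b)] - b
  if (any(counts < 0)) {
    stop("composition subtraction yields negative count for: ",
      paste(names(counts)[counts < 0], collapse = ", "),
      call. = FALSE
    )
  }
  composition(counts)
}

as_composition <- function(x) {
  if (inherits(x, "element_composition")) {
    return(x)
  }
  if (is.character(x)) {
    return(parse_formula(x))
  }
  composition(x)
}

#' Monoisotopic mass of an element composition
#'
#' For `charge = 0` the neutral monoisotopic mass is returned. For a positive
#' charge the mass of the cation is returned (neutral mass minus `charge`
#' electron masses); this is the mass of the charged species itself, not an
#' m/z — use [mz_from_mass()] for protonated-ion m/z.
#'
#' @param comp An element composition or formula string.
#' @param charge Non-negative integer charge of the (cationic) species.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C27H35N11O4") # 577.2873, the OPP + residual linker adduct
#' monoisotopic_mass("C7H10N5", charge = 1) # 164.0931, the diagnostic ion
#' @export
monoisotopic_mass <- function(comp, charge = 0L) {
  comp <- as_composition(comp)
  stopifnot(length(charge) == 1L, charge >= 0)
  .sum_formula_mass(comp) - charge * .electron_mass
}

#' Monoisotopic residue mass table
#'
#' @return A tibble with one row per canonical residue: `residue`, `formula`,
#'   and monoisotopic `mass` (Da).
#' @export
residue_masses <- function() {
  tibble::tibble(
    residue = .canonical_residues,
    formula = vapply(.residue_formulas, formula_string, character(1)),
    mass = unname(.residue_mass_values)
  )
}

#' Neutral monoisotopic mass of a peptide
#'
#' The mass is the sum of residue masses plus one water, plus the mass deltas
#' of any applied modifications. Cysteine carbamidomethylation (the standard
#' fixed alkylation, +57.02146 Da per Cys) is applied by default. At most one
#' C-terminal modification (e.g. the full OPP adduct `"OPP_full"` or its
#' purine-loss form `"OPP_purine_loss"`) may be applied; the peptide keeps its
#' C-terminal hydroxyl and the adduct is a pure mass delta.
#'
#' @param sequence Peptide sequence (canonical one-letter residues).
#' @param cterm_mod Name of a C-terminal modification from
#'   [opp_modifications()], or `NULL` for none.
#' @param fixed_cys Apply carbamidomethylation to every cysteine (default TRUE).
#' @param extra_delta Additional mass delta in Da (e.g. oxidation), default 0.
#' @param registry Modification registry tibble, defaults to
#'   [opp_modifications()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("TLVLSNLSYSATEETLQE", cterm_mod = "OPP_full")
#' @export
peptide_mass <- function(sequence, cterm_mod = NULL, fixed_cys = TRUE,
                         extra_delta = 0, registry = opp_modifications()) {
  residues <- check_sequence(sequence)
  mass <- sum(.residue_mass_values[residues]) + .water_mass + extra_delta
  if (fixed_cys) {
    mass <- mass + sum(residues == "C") * mod_delta("Carbamidomethyl", registry)
  }
  if (!is.null(cterm_mod)) {
    if (length(cterm_mod) > 1L) {
      stop("at most one C-terminal modification may be applied", call. = FALSE)
    }
    mod <- registry[registry$name == cterm_mod, ]
    if (nrow(mod) != 1L) {
      stop("unknown modification: ", cterm_mod, call. = FALSE)
    }
    if (mod$site != "peptide-C-terminus") {
      stop("'", cterm_mod, "' is not a C-terminal modification", call. = FALSE)
    }
    mass <- mass + mod$delta_mass
  }
  mass
}

check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) {
    stop("empty peptide sequence", call. = FALSE)
  }
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(residues, .canonical_residues)
  if (length(bad) > 0L) {
    stop("non-canonical residue(s): ", paste(unique(bad), collapse = ", "),
      call. = FALSE
    )
  }
  residues
}

mod_delta <- function(name, registry = opp_modifications()) {
  i <- match(name, registry$name)
  if (is.na(i)) stop("unknown modification: ", name, call. = FALSE)
  registry$delta_mass[i]
}

#' Convert between neutral mass and m/z of protonated ions
#'
#' `mz_from_mass()` computes the m/z of the MH^z+ ion,
#' \eqn{(M + z \cdot 1.00728)/z}; `mass_from_mz()` inverts it. The two
#' round-trip to well below 1e-6 Da.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param mz Observed or theoretical m/z.
#' @param z Positive integer charge.
#' @return m/z (or neutral mass) as a double.
#' @examples
#' mz_from_mass(peptide_mass("TLVLSNLSYSATEETLQEVFEK"), 3)
#' @export
mz_from_mass <- function(neutral_mass, z) {
  check_charge(z)
  (neutral_mass + z * .proton_mass) / z
}

#' @rdname mz_from_mass
#' @export
mass_from_mz <- function(mz, z) {
  check_charge(z)
  mz * z - z * .proton_mass
}

check_charge <- function(z) {
  if (any(z < 1) || any(z != round(z))) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  invisible(z)
}

#' Registry of OPP / linker modification chemistry
#'
#' The registry ships as a plain TSV under `inst/extdata/modifications.tsv` so
#' that users can add chemistries; this function reads, validates and caches
#' it. Key entries:
#' \describe{
#'   \item{OPP_full}{OPP plus the residual linker fragment remaining after
#'     hydrazine cleavage of the Dde biotin-azide (C27H35N11O4, +577.2873 Da),
#'     applied to the peptide C terminus of prematurely terminated chains. It
#'     carries a purine neutral loss (C7H9N5, 163.0858 Da) and the diagnostic
#'     fragment ion C7H10N5+ at m/z 164.0931.}
#'   \item{OPP_purine_loss}{The same adduct after loss of the purine moiety
#'     (C20H26N6O4, +414.2016 Da).}
#'   \item{Carbamidomethyl}{Fixed cysteine alkylation (+57.0215 Da).}
#' }
#' Delta masses in the TSV are validated against their formulas to within
#' 5e-4 Da at load time.
#'
#' @param path Path to a registry TSV; defaults to the bundled registry.
#' @return A tibble with columns `name`, `formula`, `delta_mass`, `site`,
#'   `classification`, `neutral_loss`, `diagnostic_ion_mz`.
#' @export
opp_modifications <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.oppkit_cache$modifications)) {
      return(.oppkit_cache$modifications)
    }
    path <- system.file("extdata", "modifications.tsv", package = "oppkit")
  }
  reg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c(
    "name", "formula", "delta_mass", "site", "classification",
    "neutral_loss", "diagnostic_ion_mz"
  )
  missing <- setdiff(required, names(reg))
  if (length(missing) > 0L) {
    stop("modification registry lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  for (i in seq_len(nrow(reg))) {
    f <- reg$formula[i]
    if (is.na(f) || !nzchar(f)) next
    sign <- 1
    if (startsWith(f, "-")) {
      sign <- -1
      f <- substring(f, 2)
    }
    m <- sign * monoisotopic_mass(f)
    if (abs(m - reg$delta_mass[i]) > 5e-4) {
      stop(
        "registry entry '", reg$name[i], "': delta_mass ", reg$delta_mass[i],
        " disagrees with formula mass ", round(m, 4),
        call. = FALSE
      )
    }
    # the formula is the source of truth; the TSV column is a rounded check value
    reg$delta_mass[i] <- m
  }
  if (is.null(.oppkit_cache$modifications) &&
    identical(path, system.file("extdata", "modifications.tsv", package = "oppkit"))) {
    .oppkit_cache$modifications <- reg
  }
  reg
}

.oppkit_cache <- new.env(parent = emptyenv())

#' Exact m/z of the OPP diagnostic fragment ion
#'
#' The singly charged purine-derived immonium-type fragment C7H10N5+ released
#' from OPP-modified peptides, computed from the element table with electron
#' correction. Prints as 164.09 at two decimals.
#'
#' @return A double, approximately 164.0931.
#' @export
opp_diagnostic_mz <- function() {
  monoisotopic_mass("C7H10N5", charge = 1L)
}
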