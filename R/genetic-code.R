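# Standard genetic code (translation table 1) over the DNA alphabet, plus
# the amino-acid property scales used throughout: Fauchere-Pliska side-chain
# hydrophobicity and free amino-acid molecular weight (Da).

DNA_BASES <- c("A", "C", "G", "T")

#' The twenty canonical amino acids
#'
#' @return Character vector of the 20 one-letter codes, in fixed
#'   alphabetical order. This ordering is the internal row/column order of
#'   every matrix in the package; hydrophobicity ordering is applied only
#'   at plotting time.
#' @export
#' @examples
#' aa_codes()
aa_codes <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Standard genetic code table
#'
#' @return A tibble with columns `codon` (64 rows, DNA alphabet) and `aa`
#'   (one-letter amino-acid code, `"*"` for the three stop codons).
#' @export
genetic_code_table <- function() {
  cached("genetic_code", {
    readr::read_tsv(aamut_extdata("genetic_code.tsv"),
                    col_types = readr::cols(codon = "c", aa = "c"))
  })
}

# named vector codon -> aa, for fast lookup
code_map <- function() {
  cached("code_map", {
    tab <- genetic_code_table()
    setNames(tab$aa, tab$codon)
  })
}

#' The 61 sense codons
#' @return Character vector of codons that encode an amino acid.
#' @export
sense_codons <- function() {
  cached("sense_codons", {
    m <- code_map()
    sort(names(m)[m != "*"])
  })
}

assert_codon <- function(codon, arg = "codon") {
  if (!is.character(codon)) {
    abort(sprintf("`%s` must be a character vector of 3-base codons.", arg))
  }
  bad <- is.na(codon) | !grepl("^[ACGT]{3}$", codon)
  if (any(bad)) {
    abort(sprintf(
      "`%s` contains invalid codons (need 3-mers over A/C/G/T): %s",
      arg, paste(unique(codon[bad])[1:min(5, sum(bad))], collapse = ", ")))
  }
  invisible(codon)
}

assert_aa <- function(aa, arg = "aa") {
  bad <- is.na(aa) | !(aa %in% aa_codes())
  if (any(bad)) {
    abort(sprintf("`%s` contains unknown amino-acid codes: %s", arg,
                  paste(unique(aa[bad])[1:min(5, sum(bad))], collapse = ", ")))
  }
  invisible(aa)
}

#' Translate codons under the standard genetic code
#'
#' @param codon Character vector of 3-mers over A/C/G/T.
#' @return Character vector of one-letter amino-acid codes, `"*"` for stops.
#' @export
#' @examples
#' translate_codon(c("ATG", "TGG", "TGA"))
translate_codon <- function(codon) {
  assert_codon(codon)
  unname(code_map()[codon])
}

#' Codons encoding an amino acid
#'
#' @param aa A single one-letter amino-acid code.
#' @return Character vector of its codons (1 to 6).
#' @export
#' @examples
#' codons_of("R") # six codons, four of which contain a CpG
codons_of <- function(aa) {
  if (length(aa) != 1) abort("`aa` must be a single amino-acid code.")
  assert_aa(aa)
  m <- code_map()
  sort(names(m)[m == aa])
}

#' Does a codon contain a CpG dinucleotide?
#'
#' True when `"CG"` occurs within the codon's three bases. CpG contexts
#' spanning a codon boundary are a property of the surrounding sequence and
#' are handled by the variant simulator, not here.
#'
#' @param codon Character vector of codons.
#' @return Logical vector.
#' @export
#' @examples
#' contains_cpg(c("CGA", "TCG", "CTG"))
contains_cpg <- function(codon) {
  assert_codon(codon)
  grepl("CG", codon, fixed = TRUE)
}

#' CpG class of an amino acid
#'
#' Classifies each amino acid by the CpG content of its codons:
#' `RED` if any codon contains a CpG dinucleotide; otherwise `YELLOW` if any
#' codon starts with a G (so a CpG can form across the preceding codon
#' boundary); otherwise `BLUE`.
#'
#' @param aa Character vector of one-letter codes.
#' @return Character vector over `c("RED", "YELLOW", "BLUE")`.
#' @seealso [cpg_class_table()]
#' @export
#' @examples
#' cpg_class(c("R", "G", "L"))
cpg_class <- function(aa) {
  assert_aa(aa)
  tab <- cpg_class_table()
  tab$cpg_class[match(aa, tab$aa)]
}

#' @rdname cpg_class
#' @return For `cpg_class_table()`: a tibble with columns `aa`, `cpg_class`.
#' @export
cpg_class_table <- function() {
  cached("cpg_class_table", {
    cls <- vapply(aa_codes(), function(a) {
      cod <- codons_of(a)
      if (any(contains_cpg(cod))) "RED"
      else if (any(startsWith(cod, "G"))) "YELLOW"
      else "BLUE"
    }, character(1))
    tibble(aa = aa_codes(), cpg_class = unname(cls))
  })
}

#' Single-base codon neighborhood
#'
#' Every (sense codon, single-base substitution) pair: 61 codons times 9
#' alternatives, annotated with the encoded change. This is the elementary
#' move set for the exchange matrices, the codon rate matrix, and the
#' variant simulator.
#'
#' @return Tibble with columns `from_codon`, `to_codon`, `pos` (1-3),
#'   `from_base`, `to_base`, `from_aa`, `to_aa` (`"*"` if the substitution
#'   creates a stop), `is_transition`, `synonymous`, `to_stop`.
#' @export
codon_neighbors <- function() {
  cached("codon_neighbors", {
    from <- sense_codons()
    grid <- tidyr::expand_grid(from_codon = from, pos = 1:3,
                               to_base = DNA_BASES)
    grid$from_base <- substr(grid$from_codon, grid$pos, grid$pos)
    grid <- grid[grid$from_base != grid$to_base, ]
    to <- grid$from_codon
    substr(to, grid$pos, grid$pos) <- grid$to_base
    grid$to_codon <- to
    grid$from_aa <- translate_codon(grid$from_codon)
    grid$to_aa <- translate_codon(grid$to_codon)
    purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
    grid$is_transition <- purine[grid$from_base] == purine[grid$to_base]
    grid$synonymous <- grid$from_aa == grid$to_aa
    grid$to_stop <- grid$to_aa == "*"
    as_tibble(grid[, c("from_codon", "to_codon", "pos", "from_base",
                       "to_base", "from_aa", "to_aa", "is_transition",
                       "synonymous", "to_stop")])
  })
}

#' Amino-acid pairs reachable by a single base change
#'
#' All ordered pairs (X, Y), X != Y, such that some sense codon of X turns
#' into some sense codon of Y by one nucleotide substitution. Changes through
#' stop codons are excluded. In a single-base variant set these are the only
#' cells of the 20x20 exchange matrix that can be populated.
#'
#' @return Tibble with columns `from`, `to` (150 ordered pairs under the
#'   standard code).
#' @export
single_base_exchanges <- function() {
  cached("single_base_exchanges", {
    nb <- codon_neighbors()
    nb <- nb[!nb$synonymous & !nb$to_stop, ]
    out <- dplyr::distinct(tibble(from = nb$from_aa, to = nb$to_aa))
    dplyr::arrange(out, .data$from, .data$to)
  })
}

#' Amino-acid property scales
#'
#' @param mass One of `"free"` (free amino-acid molecular weight, default)
#'   or `"residue"` (free weight minus one water, 18.02 Da), selecting the
#'   mass convention used for size changes.
#' @return Tibble with columns `aa`, `hydrophobicity` (Fauchere-Pliska
#'   octanol/water side-chain scale, dimensionless) and `mass` (Da).
#' @export
aa_properties <- function(mass = c("free", "residue")) {
  mass <- match.arg(mass)
  tab <- cached("aa_properties", {
    hyd <- readr::read_tsv(aamut_extdata("hydrophobicity_fauchere_pliska.tsv"),
                           col_types = readr::cols(aa = "c", value = "d"))
    ms <- readr::read_tsv(aamut_extdata("aa_mass.tsv"),
                          col_types = readr::cols(aa = "c", value = "d"))
    tibble(aa = hyd$aa, hydrophobicity = hyd$value,
           mass = ms$value[match(hyd$aa, ms$aa)])
  })
  if (mass == "residue") tab$mass <- tab$mass - 18.02
  tab
}

#' Amino acids ordered by increasing hydrophobicity
#'
#' Presentation order used by the exchange-matrix heatmaps.
#' @return Character vector of the 20 codes.
#' @export
hydrophobicity_order <- function() {
  p <- aa_properties()
  p$aa[order(p$hydrophobicity)]
}

#' Physicochemical change of an amino-acid exchange
#'
#' @param from,to Character vectors of one-letter codes (recycled).
#' @inheritParams aa_properties
#' @return Tibble with columns `from`, `to`, `d_hydrophobicity`
#'   (hydrophobicity(to) - hydrophobicity(from)) and `d_mass` (Da).
#'   Antisymmetric: `delta_properties(x, y)` is the negative of
#'   `delta_properties(y, x)`.
#' @export
#' @examples
#' delta_properties("G", "W")
delta_properties <- function(from, to, mass = c("free", "residue")) {
  assert_aa(from, "from"); assert_aa(to, "to")
  n <- max(length(from), length(to))
  from <- rep_len(from, n); to <- rep_len(to, n)
  p <- aa_properties(mass = match.arg(mass))
  i <- match(from, p$aa); j <- match(to, p$aa)
  tibble(from = from, to = to,
         d_hydrophobicity = p$hydrophobicity[j] - p$hydrophobicity[i],
         d_mass = p$mass[j] - p$mass[i])
}

#' Default human-like proteome occurrence table
#'
#' A synthetic stand-in for a human proteome amino-acid census, assembled
#' from literature-typical human composition percentages and scaled to
#' 10.5 million residues. Any analysis against real data should supply its
#' own occurrence table; this fixture makes the examples and the simulator
#' defaults self-contained.
#'
#' @return Tibble with columns `aa`, `percent`, `count`.
#' @export
human_occurrences <- function() {
  cached("human_occurrences", {
    readr::read_tsv(aamut_extdata("aa_frequencies_human_synthetic.tsv"),
                    col_types = readr::cols(aa = "c", percent = "d",
                                            count = "d"))
  })
}
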