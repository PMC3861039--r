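# Directional exchange count matrices and the statistics derived from them:
# per-amino-acid mutability, gain/loss asymmetry, exchange profiles, and
# aggregate protein mutability.

new_exchange_counts <- function(counts, allow_multi_base, label) {
  stopifnot(is.matrix(counts))
  structure(list(counts = counts, total = sum(counts),
                 allow_multi_base = allow_multi_base, label = label),
            class = "exchange_counts")
}

#' Build a directional 20x20 amino-acid exchange count matrix
#'
#' Cell (X, Y) counts the records with ancestral amino acid X and derived
#' amino acid Y. Direction is preserved, so the matrix is asymmetric in
#' general. The input should already be deduplicated
#' ([deduplicate_variants()]) so each cell counts variation events.
#'
#' @param x A variant tibble.
#' @param allow_multi_base Whether records with 2-3 base changes are
#'   admissible (disease sets). When `FALSE` (default, natural sets) any
#'   multi-base record raises an error naming offenders, because single-base
#'   data can only populate the cells in [single_base_exchanges()].
#' @param label Name carried into printing and plots.
#' @return An `exchange_counts` object: integer matrix `counts` with
#'   amino-acid dimnames, `total`, `allow_multi_base`, `label`. Use
#'   [tidy()] for the long form.
#' @export
exchange_counts <- function(x, allow_multi_base = FALSE, label = "variants") {
  if (!all(c("ref_aa", "alt_aa") %in% names(x))) {
    abort("`x` must be a variant table with ref_aa/alt_aa columns.")
  }
  if (!allow_multi_base && any(x$n_base_changes > 1)) {
    bad <- which(x$n_base_changes > 1)
    abort(sprintf(
      "%d record(s) need >1 base change (e.g. rows %s); set allow_multi_base = TRUE for disease-style sets.",
      length(bad), paste(head(bad, 5), collapse = ", ")))
  }
  aa <- aa_codes()
  m <- matrix(0L, 20, 20, dimnames = list(from = aa, to = aa))
  if (nrow(x)) {
    tab <- table(factor(x$ref_aa, aa), factor(x$alt_aa, aa))
    m[] <- as.integer(tab)
  }
  if (any(diag(m) > 0)) abort("Synonymous events found on the diagonal.")
  new_exchange_counts(m, allow_multi_base, label)
}

#' @export
print.exchange_counts <- function(x, ...) {
  cat(sprintf("<exchange_counts> %s: %d events, %s\n", x$label, x$total,
              if (x$allow_multi_base) "multi-base allowed"
              else "single-base only"))
  nz <- sum(x$counts > 0)
  cat(sprintf("  %d of %d off-diagonal cells populated\n", nz, 380L))
  invisible(x)
}

#' @method tidy exchange_counts
#' @export
tidy.exchange_counts <- function(x, ...) {
  long <- as.data.frame.table(x$counts, responseName = "count",
                              stringsAsFactors = FALSE)
  as_tibble(long[long$from != long$to, ])
}

#' Build a directional 61x61 codon exchange count matrix
#'
#' @param x A variant tibble (single-base records only).
#' @param label Name carried along.
#' @return A `codon_counts` object with a 61x61 integer matrix over the
#'   sense codons.
#' @export
codon_exchange_counts <- function(x, label = "variants") {
  if (any(x$n_base_changes != 1)) {
    abort("Codon matrices are defined for single-base changes only.")
  }
  cod <- sense_codons()
  m <- matrix(0L, 61, 61, dimnames = list(from = cod, to = cod))
  if (nrow(x)) {
    tab <- table(factor(x$ref_codon, cod), factor(x$alt_codon, cod))
    m[] <- as.integer(tab)
  }
  structure(list(counts = m, total = sum(m), label = label),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat(sprintf("<codon_counts> %s: %d events, %d of %d single-base cells populated\n",
              x$label, x$total, sum(x$counts > 0),
              nrow(unique(codon_neighbors()[!codon_neighbors()$synonymous &
                                              !codon_neighbors()$to_stop,
                                            c("from_codon", "to_codon")]))))
  invisible(x)
}

#' @method tidy codon_counts
#' @export
tidy.codon_counts <- function(x, ...) tidy.exchange_counts(x, ...)

as_occurrence_vector <- function(occurrences) {
  if (is.data.frame(occurrences)) {
    if (!all(c("aa", "count") %in% names(occurrences))) {
      abort("`occurrences` needs columns `aa` and `count`.")
    }
    occurrences <- setNames(occurrences$count, occurrences$aa)
  }
  miss <- setdiff(aa_codes(), names(occurrences))
  if (length(miss)) {
    abort(paste0("`occurrences` missing amino acids: ",
                 paste(miss, collapse = ", ")))
  }
  v <- occurrences[aa_codes()]
  if (any(!is.finite(v)) || any(v <= 0)) {
    abort("Occurrence counts must be positive for all 20 amino acids.")
  }
  v
}

#' Per-amino-acid mutability
#'
#' Mutability of X is the number of observed variation events originating
#' from X divided by the occurrence of X in the proteome. With absolute
#' occurrence counts (the default interpretation) the scores live on the
#' events-per-residue scale; `denominator = "proportion"` divides by
#' the compositional fraction instead, for sensitivity analysis.
#'
#' @param m An `exchange_counts` object.
#' @param occurrences A data frame (`aa`, `count`) or named numeric vector
#'   covering all 20 amino acids; see [human_occurrences()].
#' @param denominator `"count"` or `"proportion"`.
#' @return Tibble with columns `aa`, `n_from`, `occurrence`, `mutability`.
#'   The occurrence-weighted mean mutability equals
#'   `total_events / total_residues` exactly.
#' @export
mutability <- function(m, occurrences = human_occurrences(),
                       denominator = c("count", "proportion")) {
  denominator <- match.arg(denominator)
  occ <- as_occurrence_vector(occurrences)
  n_from <- rowSums(m$counts)[aa_codes()]
  den <- if (denominator == "count") occ else occ / sum(occ)
  tibble(aa = aa_codes(), n_from = unname(n_from),
         occurrence = unname(occ),
         mutability = unname(n_from / den))
}

#' Gain/loss asymmetry of an exchange matrix
#'
#' For each amino acid, how often it mutates away (`from_total`, row sum)
#' versus how often it is mutated to (`to_total`, column sum). `net`
#' (to - from) is positive for gainers and negative for losers and sums to
#' zero over the alphabet. Each amino acid carries its CpG class for the
#' classic colouring of this plot.
#'
#' @param m An `exchange_counts` object.
#' @return Tibble with columns `aa`, `from_total`, `to_total`, `net`,
#'   `cpg_class`.
#' @export
gain_loss <- function(m) {
  tibble(aa = aa_codes(),
         from_total = unname(rowSums(m$counts)[aa_codes()]),
         to_total = unname(colSums(m$counts)[aa_codes()])) |>
    dplyr::mutate(net = .data$to_total - .data$from_total,
                  cpg_class = cpg_class(.data$aa))
}

#' Exchange profile of one or all amino acids
#'
#' The percentage distribution of targets for mutations leaving an amino
#' acid: `profile(Y) = 100 * counts(X, Y) / row_sum(X)`.
#'
#' @param m An `exchange_counts` object.
#' @param aa A single source amino acid, or `NULL` for all with nonzero
#'   rows (zero rows are dropped with a warning).
#' @return Tibble with columns `from`, `to`, `count`, `percent`; percentages
#'   sum to 100 within each `from`.
#' @export
exchange_profile <- function(m, aa = NULL) {
  rs <- rowSums(m$counts)
  if (!is.null(aa)) {
    if (length(aa) != 1) abort("`aa` must be a single amino acid.")
    assert_aa(aa)
    if (rs[aa] == 0) {
      abort(sprintf("No observed mutations from %s; profile undefined.", aa))
    }
    keep <- aa
  } else {
    keep <- names(rs)[rs > 0]
    if (length(keep) < 20) {
      warn(paste0("Dropping zero rows: ",
                  paste(setdiff(names(rs), keep), collapse = ", ")))
    }
  }
  long <- tidy.exchange_counts(m)
  long <- long[long$from %in% keep, ]
  long$percent <- 100 * long$count / unname(rs[long$from])
  as_tibble(long)
}

#' Aggregate mutability of protein sequences
#'
#' Sums the per-residue mutabilities over a sequence and normalizes by its
#' length, i.e. the mean mutability of its residues.
#'
#' @param sequence Character vector of amino-acid sequences (one-letter).
#' @param mutability_table Output of [mutability()], or any data frame with
#'   `aa` and `mutability` columns.
#' @return Numeric vector of per-protein scores.
#' @export
#' @examples
#' mt <- tibble::tibble(aa = aa_codes(), mutability = 0.01)
#' aggregate_protein_mutability("ACDEFG", mt) # 0.01 under a constant table
aggregate_protein_mutability <- function(sequence, mutability_table) {
  if (!all(c("aa", "mutability") %in% names(mutability_table))) {
    abort("`mutability_table` needs columns `aa` and `mutability`.")
  }
  if (!length(sequence) || any(is.na(sequence)) || any(nchar(sequence) == 0)) {
    abort("`sequence` must be nonempty amino-acid strings.")
  }
  mv <- setNames(mutability_table$mutability, mutability_table$aa)
  vapply(sequence, function(s) {
    res <- strsplit(s, "", fixed = TRUE)[[1]]
    assert_aa(res, "sequence")
    mean(mv[res])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write / read a 20x20 exchange matrix as TSV
#'
#' Plain 20x20 tab-separated layout with one-letter row and column headers,
#' rows = source amino acid.
#'
#' @param m An `exchange_counts` object.
#' @param path File path.
#' @return `write_exchange_counts()` returns `path` invisibly;
#'   `read_exchange_counts()` returns an `exchange_counts` object.
#' @export
write_exchange_counts <- function(m, path) {
  df <- as.data.frame(m$counts)
  df <- cbind(from = rownames(m$counts), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_exchange_counts
#' @param allow_multi_base,label Metadata for the reconstructed object.
#' @export
read_exchange_counts <- function(path, allow_multi_base = FALSE,
                                 label = basename(path)) {
  df <- readr::read_tsv(path, col_types = readr::cols(from = "c",
                                                      .default = "i"),
                        progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$from
  m <- m[aa_codes(), aa_codes()]
  names(dimnames(m)) <- c("from", "to")
  new_exchange_counts(m, allow_multi_base, label)
}
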