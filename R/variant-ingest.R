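# Reading and filtering nonsynonymous variant records.
#
# A variant table is an ordinary tibble with one row per observed
# ancestral->derived change: protein_id, position (1-based residue index),
# ref_codon, alt_codon, ref_aa, alt_aa, populations (comma-joined labels,
# may be NA for sets without population information), dataset tag, and
# n_base_changes (Hamming distance between the codons).

variant_columns <- c("protein_id", "position", "ref_codon", "alt_codon",
                     "ref_aa", "alt_aa", "populations", "dataset",
                     "n_base_changes")

codon_hamming <- function(a, b) {
  d <- integer(length(a))
  for (k in 1:3) d <- d + (substr(a, k, k) != substr(b, k, k))
  d
}

n_populations <- function(populations) {
  ifelse(is.na(populations) | populations == "", 0L,
         lengths(strsplit(populations, ",", fixed = TRUE)))
}

#' Validate a data frame of variant records
#'
#' Checks each row for codon validity, translation consistency between the
#' codon and amino-acid columns, and nonsynonymity (including stop-codon
#' alternates). Rows failing a check are dropped; the per-row report is
#' attached as the `"rejected"` attribute and summarized in a warning.
#' `n_base_changes` is (re)computed from the codons.
#'
#' @param x A data frame with at least `protein_id`, `position`,
#'   `ref_codon`, `alt_codon`. Missing `ref_aa`/`alt_aa` are derived by
#'   translation; missing `populations` or `dataset` become `NA`.
#' @param dataset Optional tag overriding/filling the `dataset` column.
#' @return A validated variant tibble (possibly with fewer rows).
#' @export
as_variants <- function(x, dataset = NULL) {
  x <- as_tibble(x)
  need <- c("protein_id", "position", "ref_codon", "alt_codon")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("Variant table is missing required columns: ",
                 paste(miss, collapse = ", ")))
  }
  if (!"populations" %in% names(x)) x$populations <- NA_character_
  if (!is.null(dataset)) x$dataset <- dataset
  if (!"dataset" %in% names(x)) x$dataset <- NA_character_
  x$position <- as.integer(x$position)

  reason <- rep(NA_character_, nrow(x))
  ok_codon <- grepl("^[ACGT]{3}$", x$ref_codon) &
    grepl("^[ACGT]{3}$", x$alt_codon)
  reason[!ok_codon] <- "invalid codon"
  ref_aa <- alt_aa <- rep(NA_character_, nrow(x))
  ref_aa[ok_codon] <- translate_codon(x$ref_codon[ok_codon])
  alt_aa[ok_codon] <- translate_codon(x$alt_codon[ok_codon])
  bad_stop <- ok_codon & (ref_aa == "*" | alt_aa == "*")
  reason[bad_stop & is.na(reason)] <- "stop codon"
  syn <- ok_codon & !bad_stop & ref_aa == alt_aa
  reason[syn & is.na(reason)] <- "synonymous"
  if ("ref_aa" %in% names(x)) {
    mism <- ok_codon & !is.na(x$ref_aa) & x$ref_aa != ref_aa
    reason[mism & is.na(reason)] <- "ref_aa/ref_codon mismatch"
  }
  if ("alt_aa" %in% names(x)) {
    mism <- ok_codon & !is.na(x$alt_aa) & x$alt_aa != alt_aa
    reason[mism & is.na(reason)] <- "alt_aa/alt_codon mismatch"
  }

  keep <- is.na(reason)
  rejected <- tibble(row = which(!keep), reason = reason[!keep])
  out <- x[keep, ]
  out$ref_aa <- ref_aa[keep]
  out$alt_aa <- alt_aa[keep]
  out$n_base_changes <- codon_hamming(out$ref_codon, out$alt_codon)
  out <- out[, variant_columns]
  if (nrow(rejected)) {
    warn(sprintf("Rejected %d of %d variant rows (%s).", nrow(rejected),
                 nrow(x), paste(sprintf("%s: %d",
                                        names(table(rejected$reason)),
                                        table(rejected$reason)),
                                collapse = "; ")))
  }
  if (!nrow(out)) warn("Variant table is empty after validation.")
  attr(out, "rejected") <- rejected
  out
}

#' Read nonsynonymous variant records from disk
#'
#' @param path Path to a tab-separated file (UTF-8, LF, header required).
#' @param format `"tsv"` for the native dialect (columns `protein_id`,
#'   `position`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `populations`, `dataset`), or `"vcf-min"` for a minimal pre-annotated
#'   VCF-derived table (columns `ID`, `POS`, `REF_CODON`, `ALT_CODON`,
#'   `POPS`); raw VCF consequence calling is out of scope.
#' @inheritParams as_variants
#' @return A validated variant tibble; see [as_variants()].
#' @export
read_variants <- function(path, format = c("tsv", "vcf-min"),
                          dataset = NULL) {
  format <- match.arg(format)
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (format == "vcf-min") {
    need <- c("ID", "POS", "REF_CODON", "ALT_CODON")
    miss <- setdiff(need, names(x))
    if (length(miss)) {
      abort(paste0("vcf-min table is missing columns: ",
                   paste(miss, collapse = ", ")))
    }
    x <- tibble(protein_id = x$ID, position = x$POS,
                ref_codon = x$REF_CODON, alt_codon = x$ALT_CODON,
                populations = if ("POPS" %in% names(x)) x$POPS
                              else NA_character_)
  }
  as_variants(x, dataset = dataset)
}

#' Keep variants observed in exactly one population
#'
#' Implements the ancestral-allele convention for recent variants: a derived
#' allele seen in a single population is oriented ref(ancestral) ->
#' alt(derived); alleles shared by several (or all) populations are ambiguous
#' and dropped, as are records with no population information.
#'
#' @param x A variant tibble.
#' @param all_populations Optional character vector of the admissible
#'   population labels; an error is raised if a record mentions a label
#'   outside this set.
#' @return Filtered variant tibble in which every record has exactly one
#'   population label.
#' @export
filter_single_population <- function(x, all_populations = NULL) {
  npop <- n_populations(x$populations)
  if (!is.null(all_populations)) {
    labs <- unique(unlist(strsplit(x$populations[npop > 0], ",",
                                   fixed = TRUE)))
    extra <- setdiff(labs, all_populations)
    if (length(extra)) {
      abort(paste0("Unknown population labels: ",
                   paste(extra, collapse = ", ")))
    }
  }
  dropped <- sum(npop != 1)
  if (dropped) {
    inform(sprintf(
      "filter_single_population: dropped %d record(s) (%d without populations, %d multi-population).",
      dropped, sum(npop == 0), sum(npop > 1)))
  }
  x[npop == 1, ]
}

#' Count each variant site once
#'
#' Collapses records sharing `(protein_id, position, alt_aa)` to a single
#' row: recurrence of the same derived allele across individuals is taken to
#' be one inherited variation event. Two different derived amino acids at
#' one site remain two events.
#'
#' @param x A variant tibble.
#' @return Deduplicated variant tibble; the number of removed rows is
#'   reported via a message.
#' @export
deduplicate_variants <- function(x) {
  out <- dplyr::distinct(x, .data$protein_id, .data$position, .data$alt_aa,
                         .keep_all = TRUE)
  if (nrow(out) < nrow(x)) {
    inform(sprintf("deduplicate_variants: removed %d duplicate record(s).",
                   nrow(x) - nrow(out)))
  }
  out
}

#' Clean a disease variant set against a natural background
#'
#' Removes records requiring three base changes (curation errors in the
#' source databases), removes records whose `(protein_id, position, alt_aa)`
#' also occurs in the natural set (so overlap cannot bias the contrast), and
#' flags -- but keeps -- two-base changes in a `multi_base` column.
#'
#' @param x Disease variant tibble (deduplicated).
#' @param natural Natural variant tibble (deduplicated).
#' @return Filtered disease tibble with a logical `multi_base` column.
#' @export
apply_disease_filters <- function(x, natural) {
  n0 <- nrow(x)
  x <- x[x$n_base_changes < 3, ]
  n_triple <- n0 - nrow(x)
  key <- function(d) paste(d$protein_id, d$position, d$alt_aa, sep = "\r")
  overlap <- key(x) %in% key(natural)
  x <- x[!overlap, ]
  x$multi_base <- x$n_base_changes > 1
  inform(sprintf(
    "apply_disease_filters: removed %d triple-base and %d overlapping record(s); flagged %d two-base change(s).",
    n_triple, sum(overlap), sum(x$multi_base)))
  x
}

#' Write a variant table in the native TSV dialect
#'
#' @param x A variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(x, path) {
  readr::write_tsv(x[, intersect(variant_columns, names(x))], path)
  invisible(path)
}
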