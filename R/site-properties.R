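# Structural-context contrasts computed from user-supplied per-residue
# annotation tables (relative solvent accessibility, secondary structure,
# conservation, functional flags). Computing these annotations from
# structures is out of scope; the package consumes precomputed tables.

FUNCTIONAL_CATEGORIES <- c("site", "ligand", "metal", "catalytic")

#' Validate a per-site annotation table
#'
#' @param x Data frame with columns `protein_id`, `position`,
#'   `rel_accessibility` (percent, 0-100), `secondary_structure` (collapsed
#'   to helix/strand/coil), `conservation` (0-1) and `flags` (comma-joined
#'   subset of site, ligand, metal, catalytic; empty/NA for none). Rows with
#'   out-of-range values are dropped with a warning and reported in the
#'   `"rejected"` attribute.
#' @return Validated annotation tibble.
#' @export
as_annotations <- function(x) {
  x <- as_tibble(x)
  need <- c("protein_id", "position", "rel_accessibility",
            "secondary_structure", "conservation", "flags")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("Annotation table missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  x$position <- as.integer(x$position)
  x$rel_accessibility <- as.numeric(x$rel_accessibility)
  x$conservation <- as.numeric(x$conservation)
  bad_acc <- is.na(x$rel_accessibility) | x$rel_accessibility < 0 |
    x$rel_accessibility > 100
  bad_cons <- is.na(x$conservation) | x$conservation < 0 |
    x$conservation > 1
  flags <- strsplit(ifelse(is.na(x$flags), "", x$flags), ",", fixed = TRUE)
  bad_flag <- vapply(flags, function(f) any(!f %in% FUNCTIONAL_CATEGORIES),
                     logical(1))
  reason <- dplyr::case_when(bad_acc ~ "rel_accessibility out of [0,100]",
                             bad_cons ~ "conservation out of [0,1]",
                             bad_flag ~ "unknown functional flag",
                             .default = NA_character_)
  keep <- is.na(reason)
  if (!all(keep)) {
    warn(sprintf("Rejected %d of %d annotation rows.", sum(!keep), nrow(x)))
  }
  out <- x[keep, need]
  attr(out, "rejected") <- tibble(row = which(!keep),
                                  reason = reason[!keep])
  out
}

#' Read a per-site annotation TSV
#'
#' @param path Tab-separated file with the columns of [as_annotations()].
#' @return Validated annotation tibble.
#' @export
read_annotations <- function(path) {
  as_annotations(readr::read_tsv(path,
                                 col_types = readr::cols(.default = "c"),
                                 progress = FALSE))
}

#' Classify residues as buried or exposed
#'
#' @param rel_accessibility Numeric vector of relative solvent
#'   accessibilities in percent (0-100).
#' @param cutoff Exposure cutoff in percent (default 5). Values at the
#'   cutoff are classed exposed (`>=`).
#' @return Character vector over `c("buried", "exposed")`.
#' @export
#' @examples
#' classify_exposure(c(0, 5, 73))
classify_exposure <- function(rel_accessibility, cutoff = 5) {
  if (any(is.na(rel_accessibility) | rel_accessibility < 0 |
            rel_accessibility > 100)) {
    abort("`rel_accessibility` must lie in [0, 100].")
  }
  ifelse(rel_accessibility >= cutoff, "exposed", "buried")
}

has_any_flag <- function(flags) {
  !is.na(flags) & flags != ""
}

count_flag <- function(flags, category) {
  vapply(strsplit(ifelse(is.na(flags), "", flags), ",", fixed = TRUE),
         function(f) category %in% f, logical(1))
}

#' Fraction of sites with a functional annotation
#'
#' Per-category counts plus the non-redundant union: a site counts once
#' toward the overall fraction no matter how many flag categories it
#' carries.
#'
#' @param sites Annotation tibble ([as_annotations()]).
#' @return One-row tibble: `n`, per-category counts (`n_site`, `n_ligand`,
#'   `n_metal`, `n_catalytic`), `n_functional` (union) and `fraction`.
#' @export
functional_fraction <- function(sites) {
  if (!nrow(sites)) abort("`sites` must be nonempty.")
  counts <- vapply(FUNCTIONAL_CATEGORIES,
                   function(cg) sum(count_flag(sites$flags, cg)),
                   integer(1))
  n_fun <- sum(has_any_flag(sites$flags))
  tibble(n = nrow(sites), n_site = counts[["site"]],
         n_ligand = counts[["ligand"]], n_metal = counts[["metal"]],
         n_catalytic = counts[["catalytic"]], n_functional = n_fun,
         fraction = n_fun / nrow(sites))
}

#' Contrast variant sites with a background site set
#'
#' Compares solvent exposure (two-proportion test, or Fisher exact when any
#' expected count is small), secondary-structure composition, conservation
#' (distribution shift test plus means) and functional annotation fractions
#' between the sites carrying variants and a background set (typically all
#' residues).
#'
#' @param variant_sites,all_sites Annotation tibbles ([as_annotations()]).
#' @param cutoff Exposure cutoff passed to [classify_exposure()].
#' @param conservation_test `"wilcoxon"` or `"ks"`, see
#'   [distribution_shift_test()].
#' @return A `site_comparison` object; `glance()` gives the headline one-row
#'   summary, the `secondary_structure` element the composition table.
#' @export
compare_site_sets <- function(variant_sites, all_sites, cutoff = 5,
                              conservation_test = c("wilcoxon", "ks")) {
  conservation_test <- match.arg(conservation_test)
  if (!nrow(variant_sites) || !nrow(all_sites)) {
    abort("Both site sets must be nonempty.")
  }
  exp_a <- classify_exposure(variant_sites$rel_accessibility, cutoff)
  exp_b <- classify_exposure(all_sites$rel_accessibility, cutoff)
  x <- c(sum(exp_a == "exposed"), sum(exp_b == "exposed"))
  n <- c(length(exp_a), length(exp_b))
  p_pool <- sum(x) / sum(n)
  expected <- min(n * p_pool, n * (1 - p_pool))
  p_exposure <- if (expected < 5) {
    fisher.test(matrix(c(x[1], n[1] - x[1], x[2], n[2] - x[2]), 2,
                       byrow = TRUE))$p.value
  } else {
    suppressWarnings(prop.test(x, n)$p.value)
  }
  cons <- distribution_shift_test(variant_sites$conservation,
                                  all_sites$conservation,
                                  test = conservation_test)
  ss <- dplyr::bind_rows(
    variant_sites |> dplyr::count(.data$secondary_structure) |>
      dplyr::mutate(set = "variants", fraction = .data$n / sum(.data$n)),
    all_sites |> dplyr::count(.data$secondary_structure) |>
      dplyr::mutate(set = "background", fraction = .data$n / sum(.data$n)))
  fun_a <- functional_fraction(variant_sites)
  fun_b <- functional_fraction(all_sites)
  structure(list(
    exposure = tibble(exposed_fraction_variants = x[1] / n[1],
                      exposed_fraction_background = x[2] / n[2],
                      p_value = p_exposure, cutoff = cutoff),
    conservation = cons,
    secondary_structure = ss,
    functional = dplyr::bind_rows(
      variants = fun_a, background = fun_b, .id = "set")),
    class = "site_comparison")
}

#' @export
print.site_comparison <- function(x, ...) {
  e <- x$exposure; k <- x$conservation
  cat("<site_comparison>\n")
  cat(sprintf("  exposed (>= %g%%): variants %.1f%% vs background %.1f%% (p = %.3g)\n",
              e$cutoff, 100 * e$exposed_fraction_variants,
              100 * e$exposed_fraction_background, e$p_value))
  cat(sprintf("  mean conservation: variants %.3f vs background %.3f (p = %.3g)\n",
              k$mean_a, k$mean_b, k$p_value))
  f <- x$functional
  cat(sprintf("  functional fraction: variants %.1f%% vs background %.1f%%\n",
              100 * f$fraction[f$set == "variants"],
              100 * f$fraction[f$set == "background"]))
  invisible(x)
}

#' @method glance site_comparison
#' @export
glance.site_comparison <- function(x, ...) {
  f <- x$functional
  tibble(exposed_fraction_variants = x$exposure$exposed_fraction_variants,
         exposed_fraction_background = x$exposure$exposed_fraction_background,
         p_exposure = x$exposure$p_value,
         mean_conservation_variants = x$conservation$mean_a,
         mean_conservation_background = x$conservation$mean_b,
         p_conservation = x$conservation$p_value,
         functional_fraction_variants = f$fraction[f$set == "variants"],
         functional_fraction_background = f$fraction[f$set == "background"])
}
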