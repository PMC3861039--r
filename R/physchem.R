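# Physicochemical consequences of an exchange set: count-weighted fractions
# of events that increase hydrophobicity or size, and how extreme the
# changes are.

#' Summarize physicochemical changes of an exchange matrix
#'
#' For every observed event (cells weighted by their counts) computes the
#' hydrophobicity and mass change of the exchange and reports the fractions
#' of events that increase hydrophobicity, increase mass, change mass by
#' less than 50 Da, and change hydrophobicity by less than 1 unit.
#' Thresholds are strict inequalities; ties at exactly zero change count as
#' non-increase.
#'
#' @param m An `exchange_counts` object with `total > 0`.
#' @inheritParams aa_properties
#' @return A `change_summary` object; `glance()` gives the one-row fraction
#'   table, `tidy()` the per-cell delta table (with counts) for histograms.
#' @export
summarize_changes <- function(m, mass = c("free", "residue")) {
  mass <- match.arg(mass)
  if (m$total == 0) abort("Empty matrix; change summary undefined.")
  long <- tidy.exchange_counts(m)
  long <- dplyr::bind_cols(
    long,
    delta_properties(long$from, long$to, mass = mass)[
      , c("d_hydrophobicity", "d_mass")])
  ev <- long[long$count > 0, ]
  w <- ev$count / sum(ev$count)
  fractions <- tibble(
    n_events = sum(ev$count),
    fraction_hydrophobicity_increase = sum(w * (ev$d_hydrophobicity > 0)),
    fraction_mass_increase = sum(w * (ev$d_mass > 0)),
    fraction_abs_mass_lt_50 = sum(w * (abs(ev$d_mass) < 50)),
    fraction_abs_hydro_lt_1 = sum(w * (abs(ev$d_hydrophobicity) < 1)))
  structure(list(fractions = fractions, deltas = as_tibble(long),
                 label = m$label, mass = mass),
            class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  f <- x$fractions
  cat(sprintf("<change_summary> %s (%d events)\n", x$label, f$n_events))
  cat(sprintf("  hydrophobicity increase: %.1f%%\n",
              100 * f$fraction_hydrophobicity_increase))
  cat(sprintf("  mass increase:           %.1f%%\n",
              100 * f$fraction_mass_increase))
  cat(sprintf("  |d mass| < 50 Da:        %.1f%%\n",
              100 * f$fraction_abs_mass_lt_50))
  cat(sprintf("  |d hydrophobicity| < 1:  %.1f%%\n",
              100 * f$fraction_abs_hydro_lt_1))
  invisible(x)
}

#' @method glance change_summary
#' @export
glance.change_summary <- function(x, ...) x$fractions

#' @method tidy change_summary
#' @export
tidy.change_summary <- function(x, ...) x$deltas
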