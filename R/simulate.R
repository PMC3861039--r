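# Synthetic data with known ground truth: proteomes, CpG-hypermutable
# natural variant sets, disease sets biased toward conserved/buried sites
# and large physicochemical changes, and per-site structural annotations.
#
# The mutation model is deliberately minimal: every nonsynonymous,
# non-stop single-base substitution is a candidate event with weight
# 1 x kappa (transitions) x lambda (additionally, for C->T / G->A deaminations
# at CpG dinucleotides, with context read across codon boundaries within a
# protein). Events are drawn independently from the normalized candidate
# weights, so the expected per-amino-acid mutability is known exactly.

#' Simulation configuration
#'
#' @param n_proteins Number of coding sequences.
#' @param mean_length Mean protein length in residues (lengths are drawn
#'   from a Gamma with shape 3, floored at 50).
#' @param aa_freqs Target amino-acid proportions (named vector or data
#'   frame `aa` + `count`/`percent`); default is the human-like composition
#'   of [human_occurrences()].
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param lambda Additional multiplier for CpG transitions (default 20,
#'   the middle of the 10-50x range reported for CpG dinucleotides);
#'   must be >= 1.
#' @param populations Population labels (default the five continental
#'   labels AFR, AMR, ASN, EUR, SAS).
#' @param n_events Number of natural variant events to draw.
#' @param shared_allele_rate Fraction of natural events contaminated with a
#'   multi-population allele, which [filter_single_population()] must
#'   remove (default 0.02).
#' @param n_disease_events Number of disease events to draw.
#' @param beta_conservation,beta_mass,beta_hydro,beta_buried Disease
#'   sampling log-weights: weight is proportional to
#'   `exp(b_cons * conservation + b_mass * |d mass|/100 + b_hydro * |d hydrophobicity| + b_buried * buried)`.
#' @param p_two_base Fraction of disease events converted to two-base codon
#'   changes (kept, flagged downstream).
#' @param p_three_base Fraction of disease events emitted as triple-base
#'   curation errors that [apply_disease_filters()] must remove.
#' @param p_overlap Fraction of disease events copied from the natural set
#'   (overlap contamination, removed downstream).
#' @param exposed_fraction Target exposed fraction of the annotation
#'   generator at the 5 percent accessibility cutoff (default 0.73).
#' @param conservation_shape1,conservation_shape2 Beta parameters of the
#'   background conservation distribution (defaults 2.4, 2.6: mean 0.48).
#' @param flag_rate Probability that a site carries at least one functional
#'   flag (default 0.29).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 300, mean_length = 450,
                       aa_freqs = NULL, kappa = 2, lambda = 20,
                       populations = c("AFR", "AMR", "ASN", "EUR", "SAS"),
                       n_events = 20000, shared_allele_rate = 0.02,
                       n_disease_events = 5000,
                       beta_conservation = 2, beta_mass = 1,
                       beta_hydro = 1, beta_buried = 1,
                       p_two_base = 0.008, p_three_base = 3e-4,
                       p_overlap = 0.005,
                       exposed_fraction = 0.73,
                       conservation_shape1 = 2.4,
                       conservation_shape2 = 2.6,
                       flag_rate = 0.29) {
  if (lambda < 1) abort("`lambda` must be >= 1.")
  if (kappa <= 0) abort("`kappa` must be positive.")
  if (is.null(aa_freqs)) {
    occ <- human_occurrences()
    aa_freqs <- setNames(occ$count, occ$aa)
  }
  if (is.data.frame(aa_freqs)) {
    val <- intersect(c("count", "percent", "freq"), names(aa_freqs))[1]
    aa_freqs <- setNames(aa_freqs[[val]], aa_freqs$aa)
  }
  miss <- setdiff(aa_codes(), names(aa_freqs))
  if (length(miss)) {
    abort(paste0("`aa_freqs` missing amino acids: ",
                 paste(miss, collapse = ", ")))
  }
  f <- aa_freqs[aa_codes()]
  if (any(!is.finite(f)) || any(f <= 0)) {
    abort("`aa_freqs` must be strictly positive.")
  }
  structure(list(
    n_proteins = n_proteins, mean_length = mean_length,
    aa_freqs = f / sum(f), kappa = kappa, lambda = lambda,
    populations = populations, n_events = n_events,
    shared_allele_rate = shared_allele_rate,
    n_disease_events = n_disease_events,
    beta_conservation = beta_conservation, beta_mass = beta_mass,
    beta_hydro = beta_hydro, beta_buried = beta_buried,
    p_two_base = p_two_base, p_three_base = p_three_base,
    p_overlap = p_overlap, exposed_fraction = exposed_fraction,
    conservation_shape1 = conservation_shape1,
    conservation_shape2 = conservation_shape2, flag_rate = flag_rate),
    class = "sim_config")
}

#' Simulate a coding proteome
#'
#' Residues are drawn i.i.d. from the target amino-acid frequencies and a
#' codon is chosen uniformly within each synonymous family, so translated
#' composition converges to the targets as total length grows and no stop
#' codons appear inside coding regions.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; identical seeds give identical proteomes.
#' @return A `sim_proteome` object: `proteins` tibble (`protein_id`,
#'   `length`, `aa_seq`, `cds`), `residues` tibble (one row per residue
#'   with its codon), `occurrences` tibble (`aa`, `count`), plus the config
#'   and seed.
#' @export
simulate_proteome <- function(cfg = sim_config(), seed = 1) {
  set.seed(seed)
  len <- pmax(50L, as.integer(round(rgamma(cfg$n_proteins, shape = 3,
                                           scale = cfg$mean_length / 3))))
  n <- sum(len)
  aa <- sample(aa_codes(), n, replace = TRUE, prob = cfg$aa_freqs)
  codon <- character(n)
  for (a in unique(aa)) {
    i <- which(aa == a)
    codon[i] <- sample(codons_of(a), length(i), replace = TRUE)
  }
  prot <- rep.int(seq_len(cfg$n_proteins), len)
  protein_id <- sprintf("P%05d", seq_len(cfg$n_proteins))
  residues <- tibble(protein = prot,
                     protein_id = protein_id[prot],
                     position = sequence(len),
                     codon = codon, aa = aa)
  proteins <- tibble(
    protein_id = protein_id, length = len,
    aa_seq = unname(vapply(split(aa, prot), paste0, collapse = "", "")),
    cds = unname(vapply(split(codon, prot), paste0, collapse = "", "")))
  occ <- table(factor(aa, aa_codes()))
  if (any(occ == 0)) {
    abort("Some amino acids never occurred; increase the proteome size.")
  }
  structure(list(proteins = proteins, residues = residues,
                 occurrences = tibble(aa = aa_codes(),
                                      count = as.integer(occ)),
                 config = cfg, seed = seed),
            class = "sim_proteome")
}

#' @export
print.sim_proteome <- function(x, ...) {
  cat(sprintf("<sim_proteome> %d proteins, %d residues (seed %d)\n",
              nrow(x$proteins), nrow(x$residues), x$seed))
  invisible(x)
}

#' Enumerate candidate nonsynonymous events with their mutation weights
#'
#' Every (residue, single-base substitution) pair whose alternate codon is
#' a sense codon encoding a different amino acid, weighted by the mutation
#' model of the configuration: 1, times `kappa` for transitions, times
#' `lambda` additionally for C->T / G->A transitions at CpG dinucleotides
#' (CpG context spans codon boundaries within a protein). Precompute this
#' once when drawing many replicate variant sets from one proteome.
#'
#' @param proteome A `sim_proteome`.
#' @param cfg Configuration supplying `kappa` and `lambda`; defaults to the
#'   proteome's own.
#' @return Tibble of candidates with columns `protein_id`, `position`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `is_transition`,
#'   `cpg_context`, `weight`.
#' @export
variant_candidates <- function(proteome, cfg = proteome$config) {
  res <- proteome$residues
  c1 <- substr(res$codon, 1, 1)
  c2 <- substr(res$codon, 2, 2)
  c3 <- substr(res$codon, 3, 3)
  same_prev <- c(FALSE, res$protein[-1] == res$protein[-nrow(res)])
  prev_c3 <- c(NA_character_, c3[-length(c3)])
  prev_c3[!same_prev] <- NA_character_
  same_next <- c(same_prev[-1], FALSE)
  next_c1 <- c(c1[-1], NA_character_)
  next_c1[!same_next] <- NA_character_

  nb <- codon_neighbors()
  nb <- nb[!nb$synonymous & !nb$to_stop, ]
  res_ctx <- tibble(ri = seq_len(nrow(res)), codon = res$codon,
                    c1 = c1, c2 = c2, c3 = c3,
                    prev_c3 = prev_c3, next_c1 = next_c1)
  cand <- dplyr::inner_join(res_ctx, nb, by = c(codon = "from_codon"),
                            relationship = "many-to-many")
  prev_base <- ifelse(cand$pos == 1, cand$prev_c3,
                      ifelse(cand$pos == 2, cand$c1, cand$c2))
  next_base <- ifelse(cand$pos == 1, cand$c2,
                      ifelse(cand$pos == 2, cand$c3, cand$next_c1))
  cpg <- (cand$from_base == "C" & cand$to_base == "T" &
            !is.na(next_base) & next_base == "G") |
    (cand$from_base == "G" & cand$to_base == "A" &
       !is.na(prev_base) & prev_base == "C")
  weight <- ifelse(cand$is_transition, cfg$kappa, 1) *
    ifelse(cpg, cfg$lambda, 1)
  ri <- cand$ri
  tibble(protein_id = res$protein_id[ri], position = res$position[ri],
         ref_codon = cand$codon, alt_codon = cand$to_codon,
         ref_aa = cand$from_aa, alt_aa = cand$to_aa,
         is_transition = cand$is_transition, cpg_context = cpg,
         weight = weight)
}

sample_events <- function(candidates, n) {
  idx <- sample.int(nrow(candidates), n, replace = TRUE,
                    prob = candidates$weight)
  candidates[idx, ]
}

#' Simulate a natural variant set with CpG hypermutability
#'
#' Draws `n_events` events from the candidate weights (see
#' [variant_candidates()]); each event is assigned to exactly one
#' population, except for a `shared_allele_rate` fraction contaminated with
#' multi-population alleles that the single-population filter must remove.
#'
#' @param proteome A `sim_proteome`.
#' @param cfg Configuration (defaults to the proteome's).
#' @param seed Integer seed.
#' @param candidates Optional precomputed [variant_candidates()] table.
#' @return A `sim_variants` object: `variants` (a variant tibble with the
#'   extra columns `cpg_context`, `is_transition`) and `ground_truth`, a
#'   list holding the exact expected per-amino-acid mutability implied by
#'   the candidate weights.
#' @export
simulate_variants <- function(proteome, cfg = proteome$config, seed = 1,
                              candidates = NULL) {
  set.seed(seed)
  cand <- candidates %||% variant_candidates(proteome, cfg)
  ev <- sample_events(cand, cfg$n_events)
  n <- nrow(ev)
  pops <- sample(cfg$populations, n, replace = TRUE)
  shared <- runif(n) < cfg$shared_allele_rate &
    length(cfg$populations) > 1
  if (any(shared)) {
    pops[shared] <- vapply(which(shared), function(i) {
      k <- sample(2:length(cfg$populations), 1)
      paste(sort(sample(cfg$populations, k)), collapse = ",")
    }, character(1))
  }
  variants <- tibble(protein_id = ev$protein_id, position = ev$position,
                     ref_codon = ev$ref_codon, alt_codon = ev$alt_codon,
                     ref_aa = ev$ref_aa, alt_aa = ev$alt_aa,
                     populations = pops, dataset = "natural",
                     n_base_changes = 1L,
                     cpg_context = ev$cpg_context,
                     is_transition = ev$is_transition)
  w_aa <- tapply(cand$weight, factor(cand$ref_aa, aa_codes()), sum)
  occ <- setNames(proteome$occurrences$count, proteome$occurrences$aa)
  share <- as.numeric(w_aa) / sum(cand$weight)
  gt <- tibble(aa = aa_codes(), weight_share = share,
               expected_events = cfg$n_events * share,
               occurrence = as.numeric(occ[aa_codes()]),
               expected_mutability = cfg$n_events * share /
                 as.numeric(occ[aa_codes()]))
  structure(list(variants = variants,
                 ground_truth = list(expected_mutability = gt,
                                     kappa = cfg$kappa,
                                     lambda = cfg$lambda, seed = seed)),
            class = "sim_variants")
}

#' @export
print.sim_variants <- function(x, ...) {
  cat(sprintf("<sim_variants> %d events (seed %d, lambda %g, kappa %g)\n",
              nrow(x$variants), x$ground_truth$seed, x$ground_truth$lambda,
              x$ground_truth$kappa))
  invisible(x)
}

#' Simulate per-site structural annotations
#'
#' Emits one annotation row per proteome residue: relative accessibility
#' from a buried/exposed mixture hitting the target exposed fraction at the
#' 5 percent cutoff, conservation from a Beta distribution (default mean
#' 0.48), a three-class secondary-structure label, and sparse functional
#' flags.
#'
#' @inheritParams simulate_variants
#' @return An annotation tibble (see [as_annotations()]).
#' @export
simulate_annotations <- function(proteome, cfg = proteome$config,
                                 seed = 1) {
  set.seed(seed)
  res <- proteome$residues
  n <- nrow(res)
  exposed <- runif(n) < cfg$exposed_fraction
  acc <- numeric(n)
  acc[!exposed] <- runif(sum(!exposed), 0, 5)
  acc[exposed] <- 5 + 95 * rbeta(sum(exposed), 1.2, 2)
  cons <- rbeta(n, cfg$conservation_shape1, cfg$conservation_shape2)
  ss <- sample(c("helix", "strand", "coil"), n, replace = TRUE,
               prob = c(0.35, 0.22, 0.43))
  flagged <- runif(n) < cfg$flag_rate
  flags <- character(n)
  nf <- sum(flagged)
  if (nf) {
    primary <- sample(FUNCTIONAL_CATEGORIES, nf, replace = TRUE,
                      prob = c(0.45, 0.45, 0.09, 0.01))
    extra <- runif(nf) < 0.4 & primary %in% c("site", "ligand")
    second <- ifelse(primary == "site", "ligand", "site")
    flags[flagged] <- ifelse(extra, paste(primary, second, sep = ","),
                             primary)
  }
  tibble(protein_id = res$protein_id, position = res$position,
         rel_accessibility = acc, secondary_structure = ss,
         conservation = cons, flags = flags)
}

# hamming-3 alternate codon encoding a different amino acid, or NA
triple_base_alt <- function(ref_codon, alt_aa) {
  alts <- codons_of(alt_aa)
  h3 <- alts[codon_hamming(rep(ref_codon, length(alts)), alts) == 3]
  if (length(h3)) h3[1] else NA_character_
}

#' Simulate a disease-associated variant set
#'
#' Samples events over the candidate set with weight proportional to
#' `exp(b_cons * conservation + b_mass * |d mass|/100 + b_hydro * |d hydrophobicity| + b_buried * 1[buried])`,
#' emulating the enrichment of disease variants at conserved, buried sites
#' with extreme physicochemical changes. With all coefficients zero the set
#' is indistinguishable from uniform sampling over candidates. Optional
#' contaminations exercise the downstream filters: a fraction of events is
#' converted to two-base codon changes (legitimate, flagged), a fraction is
#' emitted as triple-base curation errors, and a fraction is copied from
#' the natural set (overlap).
#'
#' @inheritParams simulate_variants
#' @param annotations Annotation tibble covering the proteome sites
#'   ([simulate_annotations()]).
#' @param natural Optional natural variant tibble used for overlap
#'   contamination.
#' @return A `sim_disease` object: `variants` (dataset tag `"disease"`,
#'   `populations` NA) and `ground_truth` (per-event sampling weights and
#'   the beta coefficients).
#' @export
simulate_disease_set <- function(proteome, annotations,
                                 cfg = proteome$config, seed = 1,
                                 candidates = NULL, natural = NULL) {
  set.seed(seed)
  cand <- candidates %||% variant_candidates(proteome, cfg)
  ann <- annotations[, c("protein_id", "position", "conservation",
                         "rel_accessibility")]
  cand <- dplyr::inner_join(cand, ann, by = c("protein_id", "position"))
  if (!nrow(cand)) abort("No candidate sites have annotations.")
  dp <- delta_properties(cand$ref_aa, cand$alt_aa)
  buried <- cand$rel_accessibility < 5
  lw <- cfg$beta_conservation * cand$conservation +
    cfg$beta_mass * abs(dp$d_mass) / 100 +
    cfg$beta_hydro * abs(dp$d_hydrophobicity) +
    cfg$beta_buried * buried
  w <- exp(lw - max(lw))
  if (all(w == 0)) abort("All disease sampling weights are zero.")
  n <- cfg$n_disease_events
  idx <- sample.int(nrow(cand), n, replace = TRUE, prob = w)
  ev <- cand[idx, ]
  alt_codon <- ev$alt_codon
  alt_aa <- ev$alt_aa

  # two-base changes: mutate a second position of the alternate codon
  two <- which(runif(n) < cfg$p_two_base)
  for (i in two) {
    pos <- sample(1:3, 1)
    cur <- substr(alt_codon[i], pos, pos)
    for (b in sample(setdiff(DNA_BASES, cur))) {
      cand_codon <- alt_codon[i]
      substr(cand_codon, pos, pos) <- b
      a <- translate_codon(cand_codon)
      if (a != "*" && a != ev$ref_aa[i] &&
            codon_hamming(ev$ref_codon[i], cand_codon) == 2) {
        alt_codon[i] <- cand_codon
        alt_aa[i] <- a
        break
      }
    }
  }

  # triple-base curation errors (downstream filters must remove these)
  n_triple <- stats::rbinom(1, n, cfg$p_three_base)
  if (n_triple > 0) {
    pool <- which(!seq_len(n) %in% two)
    tr <- sample(pool, min(n_triple, length(pool)))
    for (i in tr) {
      target <- c(F = "K", M = "Y", W = "I", A = "F")[[
        if (ev$ref_aa[i] %in% c("F", "M", "W")) ev$ref_aa[i] else "A"]]
      alt3 <- triple_base_alt(ev$ref_codon[i], target)
      if (!is.na(alt3)) {
        alt_codon[i] <- alt3
        alt_aa[i] <- target
      }
    }
  }

  variants <- tibble(protein_id = ev$protein_id, position = ev$position,
                     ref_codon = ev$ref_codon, alt_codon = alt_codon,
                     ref_aa = ev$ref_aa, alt_aa = alt_aa,
                     populations = NA_character_, dataset = "disease",
                     n_base_changes = codon_hamming(ev$ref_codon,
                                                    alt_codon))
  variants <- variants[variants$ref_aa != variants$alt_aa, ]

  if (!is.null(natural) && cfg$p_overlap > 0 && nrow(natural)) {
    n_over <- stats::rbinom(1, n, cfg$p_overlap)
    if (n_over > 0) {
      ov <- natural[sample.int(nrow(natural), min(n_over, nrow(natural))),
                    variant_columns]
      ov$dataset <- "disease"
      ov$populations <- NA_character_
      variants <- dplyr::bind_rows(variants, ov)
    }
  }

  structure(list(
    variants = variants,
    ground_truth = list(
      betas = c(conservation = cfg$beta_conservation,
                mass = cfg$beta_mass, hydro = cfg$beta_hydro,
                buried = cfg$beta_buried),
      sampled_weight = w[idx], seed = seed)),
    class = "sim_disease")
}

#' @export
print.sim_disease <- function(x, ...) {
  cat(sprintf("<sim_disease> %d events (seed %d)\n", nrow(x$variants),
              x$ground_truth$seed))
  invisible(x)
}
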