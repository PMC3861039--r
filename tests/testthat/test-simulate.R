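test_that("the proteome generator is deterministic and stop-free", {
  cfg <- sim_config(n_proteins = 5, mean_length = 80)
  p1 <- simulate_proteome(cfg, seed = 42)
  p2 <- simulate_proteome(cfg, seed = 42)
  expect_identical(p1$proteins, p2$proteins)
  expect_identical(p1$occurrences, p2$occurrences)
  expect_false(identical(p1$proteins,
                         simulate_proteome(cfg, seed = 43)$proteins))
  # coding regions contain no stop codons and translate back to aa_seq
  for (i in seq_len(nrow(p1$proteins))) {
    cds <- p1$proteins$cds[i]
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    aa <- translate_codon(codons)
    expect_false(any(aa == "*"))
    expect_equal(paste(aa, collapse = ""), p1$proteins$aa_seq[i])
  }
  expect_equal(nchar(p1$proteins$cds), 3 * p1$proteins$length)
})

test_that("translated composition converges to the targets", {
  uni <- setNames(rep(1 / 20, 20), aa_codes())
  cfg <- sim_config(n_proteins = 400, mean_length = 450, aa_freqs = uni)
  pr <- simulate_proteome(cfg, seed = 8)
  n <- sum(pr$occurrences$count)
  sigma <- sqrt(n * 0.05 * 0.95)
  expect_true(all(abs(pr$occurrences$count - n * 0.05) < 3.5 * sigma))
})

test_that("candidate weights implement the kappa/lambda mutation model", {
  cfg0 <- sim_config(n_proteins = 10, mean_length = 60, kappa = 1,
                     lambda = 1)
  pr <- simulate_proteome(cfg0, seed = 12)
  cand <- variant_candidates(pr, cfg0)
  expect_true(all(cand$weight == 1)) # null model: uniform over candidates

  cfg <- sim_config(n_proteins = 10, mean_length = 60, kappa = 2,
                    lambda = 20)
  cand2 <- variant_candidates(pr, cfg)
  expect_equal(cand2$weight,
               ifelse(cand2$is_transition, 2, 1) *
                 ifelse(cand2$cpg_context, 20, 1))
  # CpG-context transitions are deamination moves only
  expect_true(all(cand2$is_transition[cand2$cpg_context]))
  # all candidates are nonsynonymous sense changes one base away
  expect_true(all(cand2$ref_aa != cand2$alt_aa))
  expect_false(any(translate_codon(cand2$alt_codon) == "*"))
})

test_that("simulated natural sets are valid and deterministic", {
  cfg <- sim_config(n_proteins = 40, mean_length = 120, n_events = 4000,
                    shared_allele_rate = 0)
  pr <- simulate_proteome(cfg, seed = 3)
  s1 <- simulate_variants(pr, cfg, seed = 3)
  s2 <- simulate_variants(pr, cfg, seed = 3)
  expect_identical(s1$variants, s2$variants)
  v <- s1$variants
  # every record validates unchanged and passes the population filter
  revalidated <- as_variants(v)
  expect_equal(nrow(revalidated), nrow(v))
  expect_identical(filter_single_population(v), v)
  expect_true(all(v$n_base_changes == 1))
  # with contamination, the filter removes exactly the multi-population rows
  cfgc <- sim_config(n_proteins = 40, mean_length = 120, n_events = 4000,
                     shared_allele_rate = 0.1)
  vc <- simulate_variants(pr, cfgc, seed = 3)$variants
  kept <- suppressMessages(filter_single_population(vc))
  expect_equal(nrow(kept), sum(!grepl(",", vc$populations)))
})

test_that("CpG hypermutability raises RED-class mutability above BLUE", {
  s <- small_sim()
  occ <- setNames(s$proteome$occurrences$count, s$proteome$occurrences$aa)
  mt <- mutability(exchange_counts(s$natural), occ)
  mt$cpg_class <- cpg_class(mt$aa)
  means <- tapply(mt$mutability, mt$cpg_class, mean)
  expect_gt(means[["RED"]], means[["BLUE"]])
})

test_that("annotation generator hits its calibration targets", {
  cfg <- sim_config(n_proteins = 150, mean_length = 300)
  pr <- simulate_proteome(cfg, seed = 21)
  ann <- simulate_annotations(pr, cfg, seed = 21)
  expect_identical(ann, simulate_annotations(pr, cfg, seed = 21))
  n <- nrow(ann)
  expect_gt(n, 3e4)
  exposed <- mean(classify_exposure(ann$rel_accessibility) == "exposed")
  expect_lt(abs(exposed - 0.73), 0.01)
  expect_lt(abs(mean(ann$conservation) - 0.48), 0.01)
  ff <- functional_fraction(ann)
  expect_lt(abs(ff$fraction - 0.29), 0.015)
  # flag rate 0 silences the functional channel
  cfg0 <- sim_config(n_proteins = 10, mean_length = 100, flag_rate = 0)
  pr0 <- simulate_proteome(cfg0, seed = 2)
  expect_equal(functional_fraction(
    simulate_annotations(pr0, cfg0, seed = 2))$fraction, 0)
})

test_that("disease sampling responds to its bias coefficients", {
  s <- small_sim()
  ann <- simulate_annotations(s$proteome, s$cfg, seed = 33)

  # conservation bias shifts the disease set upward
  dz <- simulate_disease_set(s$proteome, ann, s$cfg, seed = 33,
                             candidates = s$candidates)
  key <- function(v) paste(v$protein_id, v$position)
  cons_of <- function(v) ann$conservation[match(key(v), key(ann))]
  shift <- distribution_shift_test(cons_of(dz$variants),
                                   cons_of(s$natural))
  expect_lt(shift$p_value, 0.01)
  expect_gt(shift$mean_a, shift$mean_b)

  # buried bias raises the buried fraction over the background
  cfgb <- sim_config(n_proteins = 60, mean_length = 150,
                     n_disease_events = 3000, beta_conservation = 0,
                     beta_mass = 0, beta_hydro = 0, beta_buried = 1.5)
  dzb <- simulate_disease_set(s$proteome, ann, cfgb, seed = 34,
                              candidates = s$candidates)
  buried_of <- function(v) {
    mean(ann$rel_accessibility[match(key(v), key(ann))] < 5)
  }
  expect_gt(buried_of(dzb$variants), buried_of(ann))

  # all-zero coefficients: indistinguishable from mutation-blind sampling
  cfg0 <- sim_config(n_proteins = 60, mean_length = 150,
                     n_disease_events = 10000, beta_conservation = 0,
                     beta_mass = 0, beta_hydro = 0, beta_buried = 0,
                     p_two_base = 0, p_three_base = 0)
  dz0 <- simulate_disease_set(s$proteome, ann, cfg0, seed = 35,
                              candidates = s$candidates)
  set.seed(36)
  null_ref <- s$candidates[sample.int(nrow(s$candidates), 10000), ]
  null_p <- distribution_shift_test(cons_of(dz0$variants),
                                    ann$conservation[match(
                                      key(null_ref), key(ann))])$p_value
  expect_gt(null_p, 0.01)
})

test_that("estimated mutability recovers the simulated ground truth", {
  cfg <- sim_config(n_proteins = 150, mean_length = 300, n_events = 2e4)
  pr <- simulate_proteome(cfg, seed = 55)
  sv <- simulate_variants(pr, cfg, seed = 55)
  v <- suppressMessages(deduplicate_variants(
    filter_single_population(sv$variants)))
  mt <- mutability(exchange_counts(v), pr$occurrences)
  gt <- sv$ground_truth$expected_mutability
  rho <- cor(mt$mutability, gt$expected_mutability, method = "spearman")
  expect_gte(rho, 0.9)
  expect_equal(mt$aa[which.max(mt$mutability)], "R")
  expect_equal(gt$aa[which.max(gt$expected_mutability)], "R")
})
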