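test_that("exchange counts record direction and conserve the total", {
  one <- suppressWarnings(as_variants(tibble::tibble(
    protein_id = "P1", position = 5, ref_codon = "CGA",
    alt_codon = "CAA", populations = "EUR", dataset = "natural")))
  m <- exchange_counts(one)
  expect_equal(m$counts["R", "Q"], 1L)
  expect_equal(m$total, 1L)
  expect_equal(sum(m$counts), 1L)

  both <- suppressWarnings(as_variants(tibble::tibble(
    protein_id = c("P1", "P2"), position = c(5L, 9L),
    ref_codon = c("CGA", "CAA"), alt_codon = c("CAA", "CGA"),
    populations = "EUR", dataset = "natural")))
  m2 <- exchange_counts(both)
  expect_equal(m2$counts["R", "Q"], 1L)
  expect_equal(m2$counts["Q", "R"], 1L)

  empty <- suppressWarnings(as_variants(tiny_variants()[0, ]))
  m0 <- exchange_counts(empty)
  expect_equal(m0$total, 0L)
  expect_true(all(m0$counts == 0))

  multi <- tibble::tibble(protein_id = "P1", position = 1,
                          ref_codon = "AAA", alt_codon = "ATG",
                          ref_aa = "K", alt_aa = "M",
                          populations = "EUR", dataset = "d",
                          n_base_changes = 2L)
  expect_error(exchange_counts(multi), "allow_multi_base")
  expect_equal(exchange_counts(multi, allow_multi_base = TRUE)$total, 1L)
})

test_that("matrix totals equal record counts and order does not matter", {
  s <- small_sim()
  m <- exchange_counts(s$natural)
  expect_equal(m$total, nrow(s$natural))
  perm <- s$natural[sample.int(nrow(s$natural)), ]
  expect_identical(exchange_counts(perm)$counts, m$counts)
  # every populated cell is reachable by a single base change
  long <- tidy(m)
  nz <- long[long$count > 0, ]
  reach <- paste(single_base_exchanges()$from, single_base_exchanges()$to)
  expect_true(all(paste(nz$from, nz$to) %in% reach))
})

test_that("mutability is the events-per-occurrence quotient", {
  one <- suppressWarnings(as_variants(tibble::tibble(
    protein_id = "P1", position = 5, ref_codon = "CGA",
    alt_codon = "CAA", populations = "EUR", dataset = "natural")))
  m <- exchange_counts(one)
  m$counts["R", "Q"] <- 20000L
  m$total <- sum(m$counts)
  occ <- setNames(rep(500000, 20), aa_codes())
  occ["R"] <- 645161
  mt <- mutability(m, occ)
  expect_equal(mt$mutability[mt$aa == "R"], 20000 / 645161,
               tolerance = 1e-12)
  expect_true(all(mt$mutability[mt$aa != "R"] == 0))
  expect_error(mutability(m, occ * 0), "positive")
})

test_that("occurrence-weighted mean mutability is the overall event rate", {
  s <- small_sim()
  m <- exchange_counts(s$natural)
  occ <- setNames(s$proteome$occurrences$count,
                  s$proteome$occurrences$aa)
  mt <- mutability(m, occ)
  expect_equal(sum(mt$occurrence * mt$mutability) / sum(occ),
               m$total / sum(occ), tolerance = 1e-14)
  # proportion denominator rescales by total residues
  mt2 <- mutability(m, occ, denominator = "proportion")
  expect_equal(mt2$mutability, mt$mutability * sum(occ), tolerance = 1e-9)
})

test_that("gain/loss bookkeeping balances", {
  one <- suppressWarnings(as_variants(tibble::tibble(
    protein_id = "P1", position = 5, ref_codon = "CGA",
    alt_codon = "CAA", populations = "EUR", dataset = "natural")))
  gl <- gain_loss(exchange_counts(one))
  expect_equal(gl$net[gl$aa == "R"], -1)
  expect_equal(gl$net[gl$aa == "Q"], 1)
  expect_equal(sum(gl$net), 0)

  s <- small_sim()
  gl2 <- gain_loss(exchange_counts(s$natural))
  expect_equal(sum(gl2$net), 0)
  expect_equal(gl2$from_total + 0, rowSums(exchange_counts(s$natural)$counts)[gl2$aa],
               ignore_attr = TRUE)
})

test_that("exchange profiles are percentages that sum to 100", {
  one <- suppressWarnings(as_variants(tibble::tibble(
    protein_id = "P1", position = 5, ref_codon = "CGA",
    alt_codon = "CAA", populations = "EUR", dataset = "natural")))
  p <- exchange_profile(exchange_counts(one), "R")
  expect_equal(p$percent[p$to == "Q"], 100)
  expect_error(exchange_profile(exchange_counts(one), "W"),
               "No observed mutations")

  s <- small_sim()
  prof <- exchange_profile(exchange_counts(s$natural))
  sums <- tapply(prof$percent, prof$from, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("aggregate protein mutability averages per-residue scores", {
  const <- tibble::tibble(aa = aa_codes(), mutability = 0.0102)
  expect_equal(aggregate_protein_mutability(c("RRRR", "ACDWY"), const),
               c(0.0102, 0.0102))
  mt <- tibble::tibble(aa = aa_codes(),
                       mutability = seq(0.001, 0.02, length.out = 20))
  mR <- mt$mutability[mt$aa == "R"]
  expect_equal(aggregate_protein_mutability("RRRR", mt), mR)
  expect_error(aggregate_protein_mutability("RRX", mt), "unknown")
  # proteome-wide event rate is recovered when scores come from the data
  s <- small_sim()
  occ <- setNames(s$proteome$occurrences$count, s$proteome$occurrences$aa)
  m <- exchange_counts(s$natural)
  scores <- aggregate_protein_mutability(s$proteome$proteins$aa_seq,
                                         mutability(m, occ))
  overall <- sum(scores * s$proteome$proteins$length) /
    sum(s$proteome$proteins$length)
  expect_equal(overall, m$total / sum(occ), tolerance = 1e-12)
})

test_that("exchange matrices round-trip through TSV", {
  s <- small_sim()
  m <- exchange_counts(s$natural, label = "roundtrip")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_exchange_counts(m, path)
  back <- read_exchange_counts(path)
  expect_identical(back$counts, m$counts)
  expect_equal(back$total, m$total)
})
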