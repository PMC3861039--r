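uniform_counts <- function(d = 20) {
  states <- if (d == 20) aa_codes() else sense_codons()
  m <- matrix(1L, d, d, dimnames = list(from = states, to = states))
  diag(m) <- 0L
  m
}

test_that("count-to-rate conversion has the expected closed form", {
  pi <- setNames(rep(1 / 20, 20), aa_codes())
  rm <- dcfreq(uniform_counts(), pi)
  off <- rm$Q[row(rm$Q) != col(rm$Q)]
  expect_true(all(abs(off - 1 / 19) < 1e-12))
  expect_true(all(abs(rowSums(rm$Q)) < 1e-12))
  expect_equal(-sum(rm$freqs * diag(rm$Q)), 1, tolerance = 1e-12)
})

test_that("rates are scale-invariant and reversible when symmetrized", {
  s <- small_sim()
  m <- exchange_counts(s$natural)
  occ <- setNames(s$proteome$occurrences$count, s$proteome$occurrences$aa)
  rm1 <- dcfreq(m, occ)
  expect_true(all(abs(rowSums(rm1$Q)) < 1e-12))
  doubled <- m
  doubled$counts <- m$counts * 2L
  expect_equal(dcfreq(doubled, occ)$Q, rm1$Q, tolerance = 1e-12)

  rev <- dcfreq(m, occ, directed = FALSE)
  expect_lt(glance(rev)$max_detailed_balance_gap, 1e-12)

  expect_error(dcfreq(m, occ * 0), "positive")
  zero <- m; zero$counts[] <- 0L
  expect_error(dcfreq(zero, occ), "All-zero")
})

test_that("rates recover a known generator from sampled counts", {
  # ground truth: random reversible Q; counts drawn from the event
  # distribution pi_i * Q_ij, so dcfreq should recover Q up to noise
  set.seed(20)
  pi <- setNames(as.numeric(stats::rgamma(20, 5)), aa_codes())
  pi <- pi / sum(pi)
  S <- matrix(stats::rgamma(400, 2), 20, 20)
  S <- S + t(S)
  Q <- S * rep(pi, each = 20)
  diag(Q) <- 0; diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(pi * diag(Q)))
  dimnames(Q) <- list(from = aa_codes(), to = aa_codes())

  flux <- pi * Q; diag(flux) <- 0
  draw <- function(n) {
    counts <- stats::rmultinom(1, n, as.numeric(flux))
    C <- matrix(as.integer(counts), 20, 20,
                dimnames = list(from = aa_codes(), to = aa_codes()))
    dcfreq(C, pi)$Q
  }
  off <- row(Q) != col(Q)
  err <- function(Qhat) max(abs(Qhat[off] - Q[off]) / max(Q[off]))
  e_small <- err(draw(1e3))
  e_big <- err(draw(1e5))
  expect_lt(e_big, e_small)
  expect_lt(e_big, 0.1)
  expect_gt(cor(draw(1e5)[off], Q[off]), 0.99)
})

test_that("codon rates label CpG-status changes and reject bad counts", {
  expect_equal(cpg_change_label("CGA", "CAA"), "destroys CpG")
  expect_equal(cpg_change_label("AAA", "AAG"), "CpG-neutral")
  expect_equal(cpg_change_label("CAA", "CGA"), "creates CpG")
  expect_equal(cpg_change_label("CGA", "CGG"), "CpG-neutral")

  s <- small_sim()
  cc <- codon_exchange_counts(s$natural)
  freqs <- table(factor(s$proteome$residues$codon, sense_codons()))
  cr <- codon_rates(cc, setNames(as.numeric(freqs), names(freqs)))
  expect_true(all(abs(rowSums(cr$Q)) < 1e-12))
  expect_equal(nrow(cr$cpg_changes),
               nrow(dplyr::distinct(
                 codon_neighbors()[!codon_neighbors()$synonymous &
                                     !codon_neighbors()$to_stop,
                                   c("from_codon", "to_codon")])))

  bad <- cc
  bad$counts["AAA", "CCC"] <- 5L
  expect_error(codon_rates(bad, setNames(as.numeric(freqs), names(freqs))),
               "non-adjacent")
})

test_that("PCA of matrices is deterministic and variance-complete", {
  s <- small_sim()
  m <- exchange_counts(s$natural)
  occ <- setNames(s$proteome$occurrences$count, s$proteome$occurrences$aa)
  r1 <- dcfreq(m, occ)
  r2 <- dcfreq(m, occ, directed = FALSE)
  m3 <- m; m3$counts <- m$counts + 5L; m3$total <- sum(m3$counts)
  r3 <- dcfreq(m3, occ)

  pca <- pca_compare(list(a = r1, b = r2, c = r3, a2 = r1))
  sc <- pca$scores
  expect_equal(unlist(sc[sc$name == "a", -(1:2)]),
               unlist(sc[sc$name == "a2", -(1:2)]), tolerance = 1e-9)
  expect_equal(sum(pca$explained_variance), 1, tolerance = 1e-9)
  expect_true(all(diff(pca$explained_variance) < 1e-9))

  # collinear trio: midpoint matrix forces rank 1
  mid <- r1
  mid$Q <- (r1$Q + r3$Q) / 2
  tri <- pca_compare(list(x = r1, y = r3, mid = mid), standardize = FALSE)
  expect_lt(tri$explained_variance[2], 1e-9)
  expect_error(pca_compare(list(a = r1, b = r2)), "at least 3")
})

test_that("empirical matrix files round-trip and validate", {
  skip_if_not_installed("phangorn")
  coll <- empirical_matrix_collection(c("WAG", "Dayhoff"))
  wag <- coll$WAG
  expect_equal(-sum(wag$freqs * diag(wag$Q)), 1, tolerance = 1e-12)
  expect_lt(glance(wag)$max_detailed_balance_gap, 1e-12)

  path <- withr::local_tempfile(fileext = ".dat")
  write_empirical_matrix(wag, path)
  back <- read_empirical_matrix(path)
  expect_equal(back$Q, wag$Q, tolerance = 1e-10)
  expect_equal(back$freqs, wag$freqs, tolerance = 1e-10)

  # degenerate and malformed files are rejected
  zero <- c(rep(0, 190), rep(0.05, 20))
  bad <- withr::local_tempfile(fileext = ".dat")
  writeLines(paste(zero, collapse = " "), bad)
  expect_error(read_empirical_matrix(bad), "all-zero")
  writeLines("1 2 3", bad)
  expect_error(read_empirical_matrix(bad), "Expected at least")
  writeLines(c(paste(rep("0.5", 190), collapse = " "),
               paste(rep("0.5", 20), collapse = " ")), bad)
  expect_error(read_empirical_matrix(bad), "sum to ~1")
})
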