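# Shared fixture builders. Everything is generated in code; larger shared
# objects are memoised per test run.

.helper_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .helper_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .helper_cache)
  }
  get(key, envir = .helper_cache, inherits = FALSE)
}

# a handful of hand-checked single-base records
tiny_variants <- function() {
  tibble::tibble(
    protein_id = c("P1", "P1", "P2"),
    position = c(10L, 11L, 3L),
    ref_codon = c("CGA", "AAA", "GGC"),
    alt_codon = c("CAA", "GAA", "GAC"),
    populations = c("EUR", "AFR", "EUR"),
    dataset = "natural")
}

# random valid single-base nonsynonymous records drawn from the codon
# neighborhood
random_variants <- function(n, seed, populations = c("EUR", "AFR")) {
  set.seed(seed)
  nb <- codon_neighbors()
  nb <- nb[!nb$synonymous & !nb$to_stop, ]
  i <- sample.int(nrow(nb), n, replace = TRUE)
  suppressWarnings(as_variants(tibble::tibble(
    protein_id = sprintf("P%02d", sample(1:20, n, replace = TRUE)),
    position = sample(1:200, n, replace = TRUE),
    ref_codon = nb$from_codon[i],
    alt_codon = nb$to_codon[i],
    populations = sample(populations, n, replace = TRUE),
    dataset = "natural")))
}

# small shared simulation (one proteome, one natural set) reused by the
# pipeline-level unit tests
small_sim <- function() {
  memo("small_sim", {
    cfg <- sim_config(n_proteins = 60, mean_length = 150, n_events = 8000,
                      n_disease_events = 3000)
    pr <- simulate_proteome(cfg, seed = 101)
    cand <- variant_candidates(pr)
    sv <- simulate_variants(pr, cfg, seed = 101, candidates = cand)
    nat <- suppressMessages(deduplicate_variants(
      filter_single_population(sv$variants)))
    list(cfg = cfg, proteome = pr, candidates = cand, sim = sv,
         natural = nat)
  })
}

# two-sided Fisher p by direct hypergeometric enumeration (independent of
# stats::fisher.test): sum the probabilities of all tables with the same
# margins that are no more probable than the observed one
fisher_oracle <- function(a, at, b, bt) {
  k <- a + b
  lo <- max(0, k - bt); hi <- min(k, at)
  x <- lo:hi
  pr <- stats::dhyper(x, at, bt, k)
  sum(pr[pr <= pr[x == a] * (1 + 1e-7)])
}

# Benjamini-Yekutieli step-up executed from the published formula
by_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- m * cm * p[o] / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}
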