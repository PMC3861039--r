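# Count-to-rate conversion (DCFreq style), codon-level rates with CpG-change
# labels, PCA comparison of rate matrices, and I/O for the standard
# lower-triangular empirical-matrix text format.

new_rate_matrix <- function(Q, freqs, directed, normalized,
                            level = c("aa", "codon"), label = "rates") {
  level <- match.arg(level)
  structure(list(Q = Q, freqs = freqs, directed = directed,
                 normalized = normalized, level = level, label = label),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("<rate_matrix> %s: %dx%d (%s), %s, %s\n", x$label,
              nrow(x$Q), ncol(x$Q), x$level,
              if (x$directed) "directed" else "undirected (symmetrized)",
              if (x$normalized) "mean rate 1" else "unnormalized"))
  invisible(x)
}

#' @method tidy rate_matrix
#' @export
tidy.rate_matrix <- function(x, ...) {
  long <- as.data.frame.table(x$Q, responseName = "rate",
                              stringsAsFactors = FALSE)
  names(long)[1:2] <- c("from", "to")
  as_tibble(long[long$from != long$to, ])
}

#' @method glance rate_matrix
#' @export
glance.rate_matrix <- function(x, ...) {
  flux <- x$freqs * x$Q # (i, j) = pi_i * Q_ij
  tibble(dim = nrow(x$Q), directed = x$directed,
         normalized = x$normalized, level = x$level,
         mean_rate = -sum(x$freqs * diag(x$Q)),
         max_detailed_balance_gap = max(abs(flux - t(flux))))
}

as_freq_vector <- function(freqs, states) {
  if (is.data.frame(freqs)) {
    key <- intersect(c("aa", "codon", "state"), names(freqs))[1]
    val <- intersect(c("freq", "count", "percent"), names(freqs))[1]
    if (is.na(key) || is.na(val)) {
      abort("`freqs` data frame needs a state column (aa/codon) and a value column (freq/count/percent).")
    }
    freqs <- setNames(freqs[[val]], freqs[[key]])
  }
  miss <- setdiff(states, names(freqs))
  if (length(miss)) {
    abort(paste0("`freqs` missing states: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  v <- as.numeric(freqs[states])
  if (any(!is.finite(v)) || any(v <= 0)) {
    abort("Frequencies must be strictly positive for every state.")
  }
  v / sum(v)
}

#' Convert an exchange count matrix into an instantaneous rate matrix
#'
#' Count-to-rate conversion in the Dayhoff-counts-with-frequencies family:
#' off-diagonal rates are counts scaled by the source-state frequency,
#' `Q_ij = C_ij / pi_i` (directed), or the same applied to symmetrized
#' counts `C + t(C)` when direction is unknown (which forces detailed
#' balance `pi_i Q_ij = pi_j Q_ji`). The diagonal is set to minus the row
#' sum and the matrix scaled so that the mean rate `-sum_i pi_i Q_ii` is 1,
#' i.e. one expected event per unit time. Rates are therefore invariant
#' under uniform rescaling of the counts.
#'
#' @param counts An `exchange_counts` / `codon_counts` object or a plain
#'   square count matrix with state dimnames.
#' @param freqs Stationary state frequencies: named vector or data frame
#'   (`aa`/`codon` + `freq`/`count`); strictly positive, normalized to
#'   sum 1.
#' @param directed Keep the observed direction (`TRUE`) or symmetrize
#'   counts first (`FALSE`).
#' @param normalize Scale to mean rate 1 (default `TRUE`).
#' @param label Name carried into printing and plots.
#' @return A `rate_matrix` object: `Q`, `freqs`, `directed`, `normalized`,
#'   `level`.
#' @export
dcfreq <- function(counts, freqs, directed = TRUE, normalize = TRUE,
                   label = NULL) {
  C <- if (is.matrix(counts)) counts else counts$counts
  if (nrow(C) != ncol(C)) abort("`counts` must be square.")
  states <- rownames(C)
  if (is.null(states)) abort("`counts` must carry state dimnames.")
  if (sum(C) == 0) abort("All-zero count matrix; rates undefined.")
  pi <- as_freq_vector(freqs, states)
  if (!directed) C <- C + t(C)
  Q <- C / pi # rows scaled by source-state frequency
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    mu <- -sum(pi * diag(Q))
    Q <- Q / mu
  }
  dimnames(Q) <- list(from = states, to = states)
  new_rate_matrix(Q, setNames(pi, states), directed, normalize,
                  level = if (nrow(C) == 61) "codon" else "aa",
                  label = label %||%
                    (if (is.matrix(counts)) "rates" else counts$label))
}

#' Label a codon change by its effect on CpG content
#'
#' @param from,to Character vectors of codons (recycled).
#' @return Character vector over `c("creates CpG", "destroys CpG",
#'   "CpG-neutral")`; a change between two CpG-containing codons is
#'   CpG-neutral.
#' @export
#' @examples
#' cpg_change_label("CGA", "CAA") # destroys CpG
cpg_change_label <- function(from, to) {
  a <- contains_cpg(from); b <- contains_cpg(to)
  dplyr::case_when(a & !b ~ "destroys CpG",
                   !a & b ~ "creates CpG",
                   .default = "CpG-neutral")
}

#' Codon-level rate matrix with CpG change labels
#'
#' Applies [dcfreq()] on the 61x61 sense-codon level and annotates every
#' single-base nonsynonymous codon change with its CpG-status transition,
#' for summaries of how rates depend on CpG creation/destruction.
#'
#' @param codon_counts A `codon_counts` object (single-base changes only;
#'   counts on codon pairs that are not single-base neighbours raise an
#'   error).
#' @param codon_freqs Stationary codon frequencies (named vector or data
#'   frame with `codon` + `freq`/`count`).
#' @inheritParams dcfreq
#' @return A `rate_matrix` (level `"codon"`) with an extra element
#'   `cpg_changes`: a tibble of all nonsynonymous single-base codon pairs
#'   with their `rate` and `cpg_change` label.
#' @export
codon_rates <- function(codon_counts, codon_freqs, directed = TRUE,
                        normalize = TRUE) {
  C <- codon_counts$counts
  nb <- codon_neighbors()
  nb <- nb[!nb$synonymous & !nb$to_stop, ]
  adj <- matrix(FALSE, 61, 61, dimnames = dimnames(C))
  adj[cbind(nb$from_codon, nb$to_codon)] <- TRUE
  bad <- C > 0 & !adj
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)
    abort(sprintf(
      "Counts on non-adjacent codon pairs (e.g. %s->%s); codon rates are defined for single-base changes.",
      rownames(C)[w[1, 1]], colnames(C)[w[1, 2]]))
  }
  rm <- dcfreq(codon_counts, codon_freqs, directed = directed,
               normalize = normalize)
  changes <- dplyr::distinct(nb[, c("from_codon", "to_codon")])
  changes$rate <- rm$Q[cbind(changes$from_codon, changes$to_codon)]
  changes$cpg_change <- cpg_change_label(changes$from_codon,
                                         changes$to_codon)
  rm$cpg_changes <- as_tibble(changes)
  rm
}

#' Mean codon rate by CpG-change class
#'
#' @param rm A codon-level `rate_matrix` from [codon_rates()].
#' @return Tibble with `cpg_change`, `n_changes`, `mean_rate`.
#' @export
cpg_rate_summary <- function(rm) {
  if (is.null(rm$cpg_changes)) {
    abort("`rm` must come from codon_rates() (no cpg_changes found).")
  }
  rm$cpg_changes |>
    dplyr::group_by(.data$cpg_change) |>
    dplyr::summarise(n_changes = dplyr::n(), mean_rate = mean(.data$rate),
                     .groups = "drop")
}

#' Compare rate matrices by principal component analysis
#'
#' Vectorizes the off-diagonal rates of each matrix in a fixed order,
#' centers (and by default standardizes) each coordinate, and projects with
#' PCA. Component signs are fixed by forcing the largest-magnitude loading
#' of each component positive, so results are deterministic.
#'
#' @param matrices Named list of at least three `rate_matrix` objects of
#'   identical dimension.
#' @param standardize Scale each off-diagonal coordinate to unit variance
#'   (coordinates that are constant across matrices are dropped first).
#' @param tags Optional character vector (recycled against `matrices`) of
#'   provenance tags (for example nuclear / mitochondrial / this-study)
#'   carried into the score table and plots.
#' @return A `matrix_pca` object: `scores` tibble (`name`, `tag`, `PC1`,
#'   `PC2`, ...), `explained_variance` (fractions, non-increasing, summing
#'   to 1 over the returned components), and the `prcomp` fit.
#' @export
pca_compare <- function(matrices, standardize = TRUE, tags = NULL) {
  if (length(matrices) < 3) abort("Need at least 3 matrices.")
  if (is.null(names(matrices)) || anyDuplicated(names(matrices))) {
    abort("`matrices` must be a uniquely named list.")
  }
  dims <- vapply(matrices, function(m) nrow(m$Q), integer(1))
  if (length(unique(dims)) != 1) {
    abort("All matrices must have the same dimension.")
  }
  d <- dims[[1]]
  off <- which(diag(d) == 0)
  X <- t(vapply(matrices, function(m) as.numeric(m$Q)[off],
                numeric(length(off))))
  if (standardize) {
    keep <- apply(X, 2, stats::sd) > 0
    X <- X[, keep, drop = FALSE]
  }
  fit <- prcomp(X, center = TRUE, scale. = standardize)
  # deterministic sign: largest-magnitude loading positive
  for (k in seq_len(ncol(fit$rotation))) {
    j <- which.max(abs(fit$rotation[, k]))
    if (fit$rotation[j, k] < 0) {
      fit$rotation[, k] <- -fit$rotation[, k]
      fit$x[, k] <- -fit$x[, k]
    }
  }
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- as_tibble(fit$x)
  scores <- dplyr::bind_cols(tibble(name = names(matrices),
                                    tag = rep_len(tags %||% NA_character_,
                                                  length(matrices))),
                             scores)
  structure(list(scores = scores, explained_variance = ev, fit = fit),
            class = "matrix_pca")
}

#' @export
print.matrix_pca <- function(x, ...) {
  cat(sprintf("<matrix_pca> %d matrices; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$explained_variance[1],
              100 * x$explained_variance[2]))
  invisible(x)
}

#' @method tidy matrix_pca
#' @export
tidy.matrix_pca <- function(x, ...) x$scores

#' @method glance matrix_pca
#' @export
glance.matrix_pca <- function(x, ...) {
  tibble(n = nrow(x$scores),
         pc1_variance = x$explained_variance[1],
         pc2_variance = x$explained_variance[2])
}

PAML_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read an empirical amino-acid rate matrix in dat format
#'
#' Parses the standard lower-triangular text format used for published
#' empirical models: 19 rows of exchangeabilities `s_ij` (row i listing
#' columns 1..i-1, amino acids in ARNDCQEGHILKMFPSTWYV order) followed by a
#' line of 20 stationary frequencies. The reversible generator is assembled
#' as `Q_ij = s_ij * pi_j`, normalized to mean rate 1, and reordered to the
#' package's alphabetical state order.
#'
#' @param path File path; `#` comments and blank lines are ignored.
#' @param label Name for the resulting matrix.
#' @return A normalized, reversible `rate_matrix`.
#' @export
read_empirical_matrix <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  toks <- unlist(strsplit(paste(lines, collapse = " "), "[ \t]+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (any(is.na(vals))) abort("Non-numeric content in matrix file.")
  if (length(vals) < 210) {
    abort(sprintf("Expected at least 210 numbers (190 exchangeabilities + 20 frequencies), found %d.",
                  length(vals)))
  }
  s <- vals[1:190]; pi <- vals[191:210]
  if (any(s < 0)) abort("Negative exchangeabilities.")
  if (all(s == 0)) abort("Degenerate (all-zero) exchangeability triangle.")
  if (abs(sum(pi) - 1) > 0.02 || any(pi <= 0)) {
    abort("Frequencies must be positive and sum to ~1.")
  }
  pi <- pi / sum(pi)
  S <- matrix(0, 20, 20, dimnames = list(PAML_AA_ORDER, PAML_AA_ORDER))
  k <- 0
  for (i in 2:20) for (j in 1:(i - 1)) {
    k <- k + 1
    S[i, j] <- S[j, i] <- s[k]
  }
  build_reversible(S, setNames(pi, PAML_AA_ORDER), label)
}

# S symmetric exchangeabilities + freqs -> normalized reversible Q in
# alphabetical state order
build_reversible <- function(S, pi, label) {
  ord <- sort(names(pi))
  S <- S[ord, ord]; pi <- pi[ord]
  Q <- S * rep(pi, each = length(pi))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(pi * diag(Q)))
  dimnames(Q) <- list(from = ord, to = ord)
  new_rate_matrix(Q, pi, directed = FALSE, normalized = TRUE,
                  level = if (length(pi) == 61) "codon" else "aa",
                  label = label)
}

#' Write a reversible rate matrix in dat format
#'
#' Inverse of [read_empirical_matrix()]: recovers the exchangeabilities
#' `s_ij = Q_ij / pi_j` (symmetrized) and writes the lower triangle plus the
#' frequency line in ARNDCQEGHILKMFPSTWYV order.
#'
#' @param rm A 20-state `rate_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_empirical_matrix <- function(rm, path) {
  if (nrow(rm$Q) != 20) abort("dat format is defined for 20-state matrices.")
  Q <- rm$Q[PAML_AA_ORDER, PAML_AA_ORDER]
  pi <- rm$freqs[PAML_AA_ORDER]
  S <- Q / rep(pi, each = 20)
  S <- (S + t(S)) / 2
  con <- file(path, "w")
  on.exit(close(con))
  for (i in 2:20) {
    writeLines(paste(sprintf("%.10g", S[i, 1:(i - 1)]), collapse = " "),
               con)
  }
  writeLines("", con)
  writeLines(paste(sprintf("%.10g", pi), collapse = " "), con)
  invisible(path)
}

#' Published empirical rate matrices for comparison
#'
#' Builds a named collection of published reversible amino-acid models from
#' the model store of the phangorn package (if installed), normalized to
#' mean rate 1 and tagged by provenance: nuclear (WAG, JTT, LG, Dayhoff),
#' mitochondrial (mtREV24, mtmam, mtArt, MtZoa) and chloroplast (cpREV).
#' Use these as the reference cloud in [pca_compare()] next to matrices
#' estimated from variant data.
#'
#' @param models Character vector of model names understood by phangorn;
#'   default is the roster above.
#' @return Named list of `rate_matrix` objects plus a `"tags"` attribute
#'   (character vector of provenance tags in the same order).
#' @export
empirical_matrix_collection <- function(models = NULL) {
  if (!requireNamespace("phangorn", quietly = TRUE)) {
    abort("The phangorn package is required for the published-model collection.")
  }
  default_tags <- c(WAG = "nuclear", JTT = "nuclear", LG = "nuclear",
                    Dayhoff = "nuclear", mtREV24 = "mitochondrial",
                    mtmam = "mitochondrial", mtArt = "mitochondrial",
                    MtZoa = "mitochondrial", cpREV = "chloroplast")
  models <- models %||% names(default_tags)
  avail <- get(".aamodels", envir = asNamespace("phangorn"))
  bad <- setdiff(models, avail)
  if (length(bad)) {
    abort(paste0("Models not available in phangorn: ",
                 paste(bad, collapse = ", ")))
  }
  out <- lapply(models, function(nm) {
    mod <- get(paste0(".", nm), envir = asNamespace("phangorn"))
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- mod$Q
    S <- S + t(S)
    pi <- as.numeric(mod$bf)
    dimnames(S) <- list(PAML_AA_ORDER, PAML_AA_ORDER)
    build_reversible(S, setNames(pi / sum(pi), PAML_AA_ORDER), nm)
  })
  names(out) <- models
  attr(out, "tags") <- unname(default_tags[models]) |>
    (\(x) ifelse(is.na(x), "other", x))()
  out
}
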