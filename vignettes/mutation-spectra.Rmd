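---
title: "Directional mutation spectra: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional mutation spectra: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aamut)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made.

## The analysis

A nonsynonymous variant whose ancestral allele is known is a directed
event: ancestral codon → derived codon, hence ancestral amino acid →
derived amino acid. The package establishes direction with the
single-population convention: an alternate allele observed in exactly one
population is taken to be the derived state, the allele shared by all
populations the ancestral one. Alleles seen in several populations are
ambiguous (the variant may predate the population split) and are dropped,
as are records with no population information. Recurrences of the same
derived allele at the same site are collapsed to one event
(`deduplicate_variants()`, keyed on protein, position and derived amino
acid): a cluster of carriers is interpreted as one inherited mutation
event, and two different derived alleles at one site remain two events.
Whether a real dataset counted such double-hit sites as one or two events
is usually unstated; keying on the derived amino acid is the conservative
choice that never merges chemically different outcomes.

From the filtered events, `exchange_counts()` builds the directional 20×20
matrix. For a single-base dataset the only reachable cells are the 150
ordered pairs returned by `single_base_exchanges()`; the constructor
enforces this (multi-base records are admitted only with
`allow_multi_base = TRUE`, the disease-set case). Mutability divides each
row sum by the amino acid's occurrence in the proteome. Two readings of
"frequency of occurrence" are possible — absolute counts or compositional
proportion. The default divides by the **absolute count**, which makes the
score an events-per-residue rate whose occurrence-weighted mean is exactly
`total events / total residues`; the proportional variant is available via
`denominator = "proportion"` and differs only by that constant factor.

## CpG classes and property scales

Each amino acid carries one of three CpG classes computed from its codons:
`RED` if any codon contains a CpG dinucleotide, else `YELLOW` if any codon
starts with G — so a CpG can form across the boundary with a preceding
codon ending in C — else `BLUE`. The yellow rule is applied literally to
codon-initial G only; a codon *ending* in C can likewise form a boundary
CpG with a following G, but extending yellow to that case would make the
class depend on a symmetric argument the original three-way colouring does
not use, so it is not done here. The class is a property of the codon
repertoire; actual boundary context is handled where it belongs, in the
simulator's per-site weights.

Physicochemical changes use the Fauchère–Pliska octanol/water side-chain
hydrophobicity scale (dimensionless) and molecular masses in Da. Masses
default to **free amino-acid** weights; whether size thresholds were meant
on free or residue (minus water) masses is a genuine ambiguity, and since
deltas are identical under both conventions the choice only affects
nothing observable — the `mass = "residue"` switch exists for
completeness. Threshold fractions ("changes mass by less than 50 Da",
"hydrophobicity by less than 1 unit") use strict inequalities, and all
fractions are **event-weighted** (cells weighted by counts), matching the
phrase "of mutations" rather than "of exchange types". Ile and Leu share a
mass, so a zero mass-delta between distinct amino acids is possible and is
counted as a non-increase.

## Contrasting two matrices

Each reachable cell (plus any multi-base cell observed in either set) is
tested with a two-sided Fisher exact test on
`[[a_xy, A − a_xy], [b_xy, B − b_xy]]`, conditioning the cell against
**all other cells of its dataset** (`A`, `B` are the matrix totals).
Conditioning on the source amino acid's row total instead is offered
(`conditioning = "row"`) because the choice is not forced by anything in
the problem; against totals is the default since the question asked is
"does this exchange occupy a different share of the two spectra".
Multi-base cells, when present, are part of the totals.

P-values are adjusted with the Benjamini–Yekutieli step-up (valid under
arbitrary dependence — the cells of a compositional table are dependent),
via `stats::p.adjust(method = "BY")`; the tests verify it against the
published formula with `c(m) = Σ 1/i` executed by hand. Cells are classed
at adjusted p < 0.01 into `MORE_IN_A` / `MORE_IN_B` by direction of the
proportional excess, `ABSENT_IN_A` for reachable cells with no events in
the first set (regardless of the second set's count, which is what a "no
events observed here" map shows), else `NOT_SIGNIFICANT`.

Correlation reports label |r| > 0.7 strong and 0.4 < |r| ≤ 0.7 moderate;
the band [0.3, 0.4] is left unlabelled by that convention and is mapped to
weak here. The conservation-shift comparison needs a two-sample test that
is happy with large n and bounded scores; the default is the two-sided
Mann–Whitney (its p-values floor out in the `< 2.2e-16` style familiar
from R), with Kolmogorov–Smirnov as the alternative.

## From counts to rates

`dcfreq()` converts counts plus stationary frequencies into an
instantaneous rate matrix: off-diagonal `Q_ij ∝ C_ij / π_i` (counts scaled
by the source-state frequency), diagonal set to minus the row sum, and the
whole matrix scaled so the mean rate `−Σ π_i Q_ii` is 1 — one expected
event per unit time, which makes matrices comparable and leaves rates
invariant under uniform rescaling of counts. With direction unknown the
counts are symmetrized (`C + Cᵀ`) first, which forces detailed balance
`π_i Q_ij = π_j Q_ji` by construction. The formula sits in one small
function so a different count-to-rate scheme can be substituted without
touching anything else. Degenerate inputs (a zero frequency, an all-zero
count matrix) are errors, not silent zeros. The same algebra runs on the
61×61 sense-codon level, where each single-base change additionally gets a
CpG label (creates / destroys / CpG-neutral, from the codon's own bases);
counts on codon pairs that are not single-base neighbours are rejected.

For comparison with published empirical models the package parses and
writes the standard lower-triangular `dat` text format (19 exchangeability
rows plus a frequency line, ARNDCQEGHILKMFPSTWYV order) and can assemble a
named collection of published reversible models (WAG, JTT, LG, Dayhoff,
mtREV24, mtmam, mtArt, MtZoa, cpREV) from the phangorn package's model
store at run time. `pca_compare()` vectorizes all off-diagonal rates of
each normalized matrix in a fixed order, drops coordinates constant across
the collection, standardizes the rest (whether to standardize, and whether
frequencies should enter the vector, are not settled anywhere; per-
coordinate standardization is the default so that a handful of huge rates
does not own the projection, and frequencies stay out of the vector), and
runs `stats::prcomp`. Component signs are made deterministic by forcing
each component's largest-magnitude loading positive.

## The synthetic-data generator

The generator's defaults are the study conditions of the package's own
end-to-end checks:

| parameter | default | meaning |
|---|---|---|
| `aa_freqs` | human-like composition | target amino-acid proportions |
| `kappa` | 2 | transition/transversion rate ratio |
| `lambda` | 20 | extra multiplier for CpG transitions (middle of the reported 10–50× range) |
| `populations` | AFR, AMR, ASN, EUR, SAS | five continental labels, one per event |
| `shared_allele_rate` | 0.02 | fraction of events contaminated with multi-population alleles |
| `beta_conservation` … `beta_buried` | 2, 1, 1, 1 | disease sampling log-weights |
| `exposed_fraction` | 0.73 | annotation target at the 5% cutoff |
| conservation Beta(2.4, 2.6) | mean 0.48 | background conservation |
| `flag_rate` | 0.29 | sites with ≥1 functional flag |

Proteins are i.i.d. residues drawn from the target composition with codons
uniform within each synonymous family (real codon-usage bias can be
injected through the frequencies, but uniform-within-family is the neutral
default). Candidate events are **all** nonsynonymous, non-stop single-base
substitutions, weighted 1 × κ (transitions) × λ (additionally, for C→T and
G→A at CpG dinucleotides, with context read across codon boundaries within
a protein — the deamination mechanism; applying λ to all changes at CpG
sites is a documented alternative). Events are i.i.d. draws from the
normalized weights, so the exact expected per-amino-acid mutability is
known and recorded as ground truth. Disease events are drawn with weight
`exp(β_cons·conservation + β_mass·|Δmass|/100 + β_hydro·|Δh| +
β_buried·1[buried])` over the same candidates, with optional
contaminations that exercise the downstream filters: two-base codon
changes (kept, flagged), triple-base curation errors, and copies of
natural records (overlap). The disease generator optionally takes the
natural set so that overlap contamination is real, not simulated in name
only.

What the generator does **not** emulate: linkage and demography (events
are independent; there are no haplotypes, so the single-population filter
sees label noise rather than real population structure), selection
(candidate weights are mutation-only; a real natural set is
mutation × weak selection), codon-usage bias, sequencing error, and any
correlation between a site's structural context and its mutation rate.
Passing the recovery checks therefore shows that the estimators invert the
assumed mutation model correctly — not that the model captures everything
shaping a real variant census. Conversely the generator's mutabilities are
on a much higher events-per-residue scale than a real population census
(10⁵ events on 10⁶ residues); only rankings and ratios transfer.

## Site-property contrasts

Structural annotations (relative accessibility in percent, a three-class
secondary-structure label, conservation in [0, 1], functional flags from
{site, ligand, metal, catalytic}) are **inputs**: computing them from
structures is a different pipeline's job. Exposure is classed at a 5%
cutoff with the boundary counted as exposed (a tie rule that had to be
picked; ≥ is the one that keeps "0% means buried" unambiguous). Exposure
fractions are compared with a two-proportion z-test, switching to Fisher's
exact test when any pooled expected count drops below 5. The functional
fraction is the non-redundant union — a site with three flags counts once.

## Numerical conventions and problem sizes

Matrices are stored in fixed alphabetical amino-acid order; the
hydrophobicity ordering is applied only when plotting. Rate-matrix
invariants (zero row sums, mean rate, detailed balance after
symmetrization) hold to ~1e-12 and are asserted at that tolerance. The
test suite runs its end-to-end checks at 10⁶ residues, 10⁵ events and 20
replicate seeds — sizes at which the rank correlation between estimated
and true mutability is ≈ 0.99 and arginine's top rank is stable — and the
statistical power checks at 10⁴ events per set. All randomness flows
through explicit integer seeds; identical seeds give byte-identical
outputs.

## Known limitations

- The ingest layer accepts pre-annotated tables only; mapping raw VCF to
  codons and consequences is out of scope.
- Ancestral-state inference is purely the single-population rule; no
  outgroup or ancestral-genome reconstruction.
- The disease generator's biases are log-linear and site-independent;
  real disease ascertainment is lumpier.
- Codon rate matrices are restricted to sense codons and single-base
  moves; rates through stop codons are not modelled.
- The count-to-rate conversion assumes the observation window is short
  enough that multiple hits per site are negligible (consistent with the
  one-event-per-site deduplication upstream).
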