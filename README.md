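# aamut

Direction-aware amino-acid exchange matrices, mutability scores and
instantaneous rate matrices from human coding variants.

## The problem

When the ancestral allele of a nonsynonymous SNP is known, every variant is
a directed event X → Y between amino acids, and the 20×20 exchange matrix
built from such events is asymmetric. Counts of events leaving each amino
acid, normalized by how often that amino acid occurs in the proteome, give
its *mutability*:

    mutability(X) = (number of observed variant events from X) / (occurrences of X in the proteome)

Mutability differences among amino acids are dominated by the DNA-level
mutation process — above all the hypermutability of CpG dinucleotides, whose
methylated cytosines deaminate and raise C→T/G→A rates by an order of
magnitude or more. Arginine, with a CpG in four of its six codons at
non-wobble positions, is the textbook case. Disease-associated variant sets
behave very differently from population ("natural") variant sets: they favor
conserved, buried sites and more extreme physicochemical changes.

`aamut` implements the full analysis for anyone who wants to run it on their
own variant tables, or to study its statistical behavior on synthetic data
with known ground truth:

- **Ingest & filtering** — a small TSV dialect for nonsynonymous variant
  records; single-population filtering (the shared allele is ancestral,
  fixing the direction), one-event-per-site deduplication, and disease-set
  cleanup (triple-base curation errors, overlap with the natural set).
- **Exchange matrices** — directional 20×20 amino-acid and 61×61 codon
  count matrices; mutability; gain/loss asymmetry with CpG codon classes;
  per-amino-acid exchange profiles; aggregate protein mutability.
- **Contrast statistics** — per-cell Fisher exact tests against dataset
  totals with Benjamini–Yekutieli FDR correction and a four-class cell map;
  correlation reports with the strong/moderate/weak convention; two-sample
  distribution-shift tests.
- **Rate matrices** — count-to-rate conversion in the
  Dayhoff-counts-with-frequencies family (`Q_ij ∝ C_ij/π_i`, mean rate 1),
  directed or symmetrized (reversible); codon-level rates labelled by CpG
  creation/destruction; PCA comparison against published empirical models
  (WAG, JTT, LG, Dayhoff, mtREV24, …) and a reader/writer for the standard
  lower-triangular `dat` format.
- **Physicochemical summaries** — count-weighted fractions of events that
  increase hydrophobicity (Fauchère–Pliska scale) or mass, and how extreme
  the changes are.
- **Site properties** — buried/exposed classification at a 5% relative
  accessibility cutoff and variant-vs-background contrasts of exposure,
  secondary structure, conservation and functional annotation, computed
  from user-supplied per-residue annotation tables.
- **Synthetic data** — a generator for proteomes, CpG-hypermutable variant
  sets (transition/transversion ratio κ, CpG transition multiplier λ),
  biased disease sets and site annotations, with exact expected mutability
  recorded as ground truth.

Everything takes and returns tibbles, so the pieces chain with the pipe;
matrix-shaped results are small S3 objects with `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

```r
library(aamut)

cfg      <- sim_config(n_proteins = 300, mean_length = 450, n_events = 20000)
proteome <- simulate_proteome(cfg, seed = 1)
sim      <- simulate_variants(proteome, cfg, seed = 1)

natural <- sim$variants |>
  filter_single_population() |>
  deduplicate_variants()
#> filter_single_population: dropped 373 record(s) (0 without populations, 373 multi-population).
#> deduplicate_variants: removed 1732 duplicate record(s).

counts <- exchange_counts(natural, label = "natural")
counts
#> <exchange_counts> natural: 17895 events, single-base only
#>   150 of 380 off-diagonal cells populated

mutability(counts, proteome$occurrences) |>
  dplyr::arrange(dplyr::desc(mutability)) |>
  head(5)
#> # A tibble: 5 × 4
#>   aa    n_from occurrence mutability
#>   <chr>  <dbl>      <int>      <dbl>
#> 1 R       2966       7434      0.399
#> 2 A       1966       9214      0.213
#> 3 D       1047       6186      0.169
#> 4 V       1210       7912      0.153
#> 5 E       1420       9368      0.152

glance(dcfreq(counts, proteome$occurrences, directed = TRUE))
#> # A tibble: 1 × 6
#>     dim directed normalized level mean_rate max_detailed_balance_gap
#>   <int> <lgl>    <lgl>      <chr>     <dbl>                    <dbl>
#> 1    20 TRUE     TRUE       aa            1                   0.0387
```

The 150 populated cells are exactly the amino-acid pairs reachable by one
nucleotide substitution (`single_base_exchanges()`). Arginine tops the
mutability ranking because the λ = 20 CpG multiplier concentrates events on
its CGN codons — the mutability values themselves are events-per-residue on
the scale of this synthetic set, an order of magnitude above a real
population census, but their ranking and ratios are the object of study.
The directed rate matrix is normalized to one expected event per unit time;
its nonzero detailed-balance gap is the signature of direction-aware counts
(the symmetrized variant, `directed = FALSE`, is exactly reversible).

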