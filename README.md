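# neoforge

Structure-guided prioritization of tumor neoantigens from somatic variants.

Personalized cancer vaccines need a short list of peptides that (i) arise
from the tumor's own mutations, (ii) are actually expressed and clonal,
(iii) fit the patient's MHC class I molecules, and (iv) present a changed,
TCR-visible surface. `neoforge` implements that selection end to end for
protein-level somatic variant tables: it enumerates mutant/wild-type 9-mer
pairs for missense variants and tiled neo-peptides for frameshifts, scores
them with a pan-allele position-specific weight matrix (PSWM) trained on
qualitative peptide/MHC binding records and structural positives, crosses
the ranking with external predictor percentile ranks (NetMHCpan-4 /
MHCflurry style tables), applies RNA-expression and clonality filters, and
classifies the survivors into four tiers that separate MHC-anchor
mutations from solvent-exposed, physicochemically drastic (TCR-facing)
mutations. The package targets computational immunologists building or
benchmarking neoantigen pipelines; every input can be simulated, so all
stages are testable without any external data.

## The model

A 9-mer peptide is factorized into independent positions. Each
(allele, position) pair carries a *pocket environment* — the MHC residues
contacting that peptide position, read from a contact map distilled from
crystal structures. Environments whose pocket compositions are similar
(average BLOSUM62 residue similarity ≥ 0.7 on a unit self-similarity
scale) are clustered by single linkage and share one weight vector, so
binding data pools across alleles with similar local environments; this is
what makes the model pan-allele, and lets it score alleles absent from
training by projecting their pockets onto the trained clusters.

For cluster *c* and amino acid *a*, with binder / structural / nonbinder
counts *n_b*, *n_s*, *n_n* (totals *N_b*, *N_s*, *N_n*), background *q_a*,
pseudocount κ, structural weight λ and nonbinder weight η:

    w(c,a) = log2[(n_b + λ·n_s + κ·q_a) / (N_b + λ·N_s + κ)] − log2 q_a
           − η·( log2[(n_n + κ·q_a) / (N_n + κ)] − log2 q_a )

A peptide's score is the sum of its per-position weights — not an
affinity, but a log-odds measure of how well the peptide fits the groove.
Training uses only qualitative binder/nonbinder labels.

Tiers (first match wins, precedence 4 → 1 → 2 → 3):

| Tier | Rule |
|------|------|
| 4 | frameshift-derived (entirely novel sequence) |
| 1 | mutation at an MHC anchor position, score gain ≥ `delta_big` |
| 2 | external consensus ≤ cutoff, solvent-exposed position, drastic physicochemical change |
| 3 | \|score change\| ≤ `delta_small`, exposed position, moderate/conservative change |

## Worked example

Every input is generated here, so the example runs anywhere:

```r
library(neoforge)

dir   <- tempfile()
files <- simulate_inputs(dir, seed = 7)       # writes all pipeline inputs
prot  <- read_proteins(files$proteins)
vars  <- parse_variant_table(files$variants, prot)
map   <- read_contact_map(files$contact_map)

fit <- noah(read.delim(files$binding), read.delim(files$structural),
            contact_map = map)
fit
#> Pan-allele peptide/MHC-I position weight matrix (k = 9 )
#>   alleles: H2-Db, H2-Dd, H2-Kb
#>   environment clusters: 7  (similarity threshold 0.7 )
#>   training records: 2000 binding, 50 structural

sel <- select_neoantigens(vars, prot, fit, contact_map = map,
                          external = files$external)
sel
#> Neoantigen selection: 63 variants -> 63 candidates -> 51 after filters
#>   stage counts: variants=63, enumerated=516, scored=513, candidates=63,
#>     post_consensus=59, post_expression=55, post_clonality=51, tiered=21
#>   tiers: T1=6, T2=10, T3=2, T4=3, TNA=30  unassigned = 30

head(sel$candidates[, c("variant_id", "mut_peptide", "allele",
                        "noah_score", "score_delta", "tier")], 3)
#>   variant_id mut_peptide allele noah_score score_delta tier
#> 1       v055   TCRRQMCWP  H2-Dd   7.142300    1.335427    1
#> 2       v035   ACQSFTDVL  H2-Db   5.266912    1.271012    1
#> 3       v029   GKRMTYILP  H2-Dd   3.733037    1.388620    1
```

Of the 63 simulated variants, 12 were designed to fail exactly one filter
(4 each for consensus, expression > 5 RNA reads, clonality VAF > 0.2),
leaving 51 ranked candidates; the 3 frameshifts survive as long peptides
in Tier 4, and the tier columns record which rule fired for each survivor
(`reasons`), with candidates matching no rule retained as unassigned.
`write_selection(sel, "out.tsv")` writes the table plus a JSON run
manifest with every effective parameter and per-stage count.

The same pipeline is scriptable from a shell via the thin CLI wrapper
(`inst/cli/neoforge.R`): subcommands `simulate`, `build-pswm`, `score`,
`select`, `tiers`.

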