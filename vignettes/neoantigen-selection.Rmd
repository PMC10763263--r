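---
title: "Structure-guided neoantigen selection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-guided neoantigen selection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the scoring model
and its assumptions, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, the numerical choices
made where the design was genuinely open, and the known limitations.

## The selection problem

A tumor's somatic mutations create peptides absent from normal tissue.
Only a small fraction are useful vaccine targets: the variant must be
expressed and clonal, the mutant peptide must fit an MHC class I molecule,
and — for a T cell to see anything new — the mutation should either change
binding itself (an anchor-position change) or change the solvent-exposed
surface the TCR reads. `neoforge` encodes that cascade as: enumerate →
score → rank → external consensus → expression filter → clonality filter →
tier.

## The scoring model

### Factorization and pooling

A k-mer peptide (k = 9 throughout; multi-length models are a non-goal) is
treated as k independent positions. The model's structural prior is a
*contact map*: per allele and peptide position, the one-letter identities
of the MHC pocket residues contacting that position. Positions from
different alleles whose pockets look alike are clustered and share one
weight vector, which is what lets qualitative binding data pool across
alleles and gives the model its pan-allele character.

Pocket similarity is the mean per-residue BLOSUM62 similarity after
sorting both pocket strings and padding the shorter with zero-similarity
gaps, normalized so self-similarity is 1
(`s(a,b) = B(a,b) / sqrt(B(a,a) B(b,b))`). Two empty pockets (fully
exposed positions) are maximally similar: with no structural information
to distinguish them, their data pool. Clustering is single linkage on the
thresholded similarity graph, deterministic given the (allele, position)
sort order; ties in later projection are broken toward the lowest cluster
id.

### Weights

For cluster $c$ and amino acid $a$, with binder/structural/nonbinder
counts $n_b, n_s, n_n$ pooled over every (allele, position) assigned to
$c$, totals in capitals, and background frequency $q_a$:

$$w(c,a) = \log_2\frac{n_b + \lambda n_s + \kappa q_a}{N_b + \lambda N_s +
\kappa} - \log_2 q_a - \eta\left[\log_2\frac{n_n + \kappa q_a}{N_n +
\kappa} - \log_2 q_a\right]$$

This is the standard log-odds-with-pseudocounts PSWM construction,
chosen because it satisfies every constraint the method imposes:
qualitative labels only (no affinity regression), structural observations
mixed in as weighted positives, strictly additive local contributions,
and pooling across alleles. A peptide's score is the sum of its
per-position weights; it is a fit likelihood, not an IC50 — scores are
reported as raw sums, unnormalized per allele.

Degenerate cases are pinned down: with no data and a uniform background
every weight is exactly 0 (the formula collapses to $\log_2 q_a/q_a$);
a cluster with no positive observations falls back to the all-zero
background with a warning rather than learning from nonbinders alone;
non-standard residues (X) contribute 0 at scoring time, with a warning.

### Parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `kappa` | 1 | pseudocount mass | one uniform prior observation per cluster; keeps empty cells finite without washing out small clusters |
| `lambda` | 1 | binder-equivalents | one crystal-structure positive counts as one binder record |
| `eta` | 1 | unitless | nonbinders used discriminatively at full weight; set 0 to train on positives only |
| `background` | uniform 1/20 | frequency | synthetic peptides are uniform; substitute proteome frequencies for real data |
| `similarity_threshold` | 0.7 | on [0, 1] self-similarity scale | merges conservatively substituted pockets but keeps chemically distinct anchors apart |
| `delta_big` | 1.0 | log2 score units | one two-fold odds unit of binding gain for a Tier-1 anchor call |
| `delta_small` | 0.5 | log2 score units | "similar to wild type" for Tier 3 |
| `min_reads` | 5 | RNA reads, strict `>` | expression evidence; 6 passes, 5 does not |
| `min_vaf` | 0.2 | allele frequency, strict `>` | clonality; ~0.4 of cells for a heterozygous variant |
| `consensus_cutoff` | 2 | percentile rank | the conventional strong-binder cutoff of external predictors |
| `exposure_threshold` | 4 | pocket contacts | positions with < 4 contacts are solvent-exposed, TCR-facing |
| `long_len` | 25 | residues | frameshift long peptide, junction centred |

Anchor positions default to the two highest-contact positions per allele
in the contact map, overridable per allele in the run config (the shipped
default map reproduces the canonical H2-Db P5/P9 and H2-Kb P5/P8 anchors
by construction). The shipped contact map itself is a curated stand-in
with pocket compositions consistent with published class I structures; it
is package data, not a runtime crystal-structure parser.

## Enumeration conventions

Protein positions and peptide offsets are 1-based inclusive, matching
L10P-style mutation notation. For a missense variant every 9-mer window
containing the mutated residue is enumerated (mutations near a terminus
keep their reduced window set); all windows compete and the ranking
decides which register represents the variant. For a frameshift the
chimeric sequence (wild-type prefix + novel tail) is tiled with every
9-mer containing at least one novel residue — these have no wild-type
counterpart by construction — plus one long peptide (≤ 25 residues)
centred on the junction for vaccine-cassette use; whether the window is
symmetric around the junction is a free choice, and centring is the
least-committal one. In-frame indels are accepted and routed through the
same chimeric path. The candidate table reports one row per variant: its
best-ranked window, with frameshift candidates represented by the long
peptide carrying the best tile's score, allele and external ranks.

## Filters and tiers

Expression (`rna_reads > 5`) and clonality (`vaf > 0.2`) are strict
inequalities applied per variant (inherited by all its peptides).
Consensus keeps records whose available external percentile ranks pass
the cutoff under an `any` (default) or `all` policy; records with no
external rank are dropped unless explicitly kept. All three filters are
order-independent and idempotent, and tightening any threshold can only
shrink the survivor set — properties the test suite checks by brute
force.

Tier precedence is 4 → 1 → 2 → 3 with first match wins. The tiers are
descriptive groups; an explicit precedence makes the partition
deterministic, and a record matching no rule stays in the output flagged
unassigned, for auditability, rather than being silently dropped.
Physicochemical severity uses a six-class partition (aliphatic, aromatic,
polar, positive, negative, special); drastic pairs are charge reversals,
any charged/uncharged swap, polar/aliphatic and aromatic/polar swaps;
same-class substitutions are conservative; the remainder moderate.

## The synthetic-data generator

The generator exists so every stage is testable offline; it emulates the
*shape* of real inputs, not their biology:

* `simulate_planted_model()` builds a pool of mutually dissimilar pockets
  (pairwise similarity < 0.55, below the clustering threshold), assigns
  them to (allele, position), and draws i.i.d. zero-mean Gaussian weights
  (`weight_scale` 1). Two alleles share identical pockets so clustering
  has a planted merge to recover.
* `sample_binding_records()` labels uniform random peptides binder above
  the sample median of true scores — balanced classes keep recovery
  statistics stable at small n — then flips labels at the noise rate.
  Truth goes to a sidecar file, never into pipeline inputs.
* `simulate_variant_cohort()` realizes a per-variant pass/fail design at
  each filter with single-cause failures, so expected per-stage counts
  follow from the design exactly. The default cohort (60 SNVs + 3
  frameshifts, 12 designed failures) produces a 51-candidate list with 3
  frameshift long peptides.
* `simulate_external_ranks()` produces percentile ranks whose agreement
  with the model's ranking is a knob from 0 (independent) to 1
  (identical order).

What passing tests on these data do *not* show: performance on real
immunopeptidome data. Uniform peptides have no proteome composition bias,
planted weights are position-independent Gaussians, label noise is
symmetric, and external ranks are generated rather than computed by real
predictors. The generator validates the machinery (recovery, invariance,
bookkeeping), not clinical accuracy.

## Numerical choices and problem sizes

* Weights are plain doubles; model JSON serializes them at 17 significant
  digits so a round trip reproduces scores bit for bit.
* Ranking ties break by (peptide, variant id) lexicographically, making
  rankings invariant under input permutation.
* Additivity of scoring is exact in real arithmetic; summed doubles can
  differ from the single-weight difference by rounding, so tests assert
  per-position contributions identically and score differences to 1e-12.
* Parameter recovery is measured as Spearman correlation between
  recovered and planted scores on 500 held-out peptides after training on
  2,000 records at 10% label noise; under these conditions the
  correlation sits in the low-to-mid 0.9s, close to the information limit
  imposed by median-thresholded binary labels spread over nine positions.
* Test and acceptance problem sizes (1,000-case enumeration sweeps,
  1,000 Hamming-1 pairs, 2,000-record training, 500-variant filter
  cohorts) were chosen as the smallest scales at which the statistical
  checks are stable.

## Limitations

* Variants are consumed at protein level; variant calling, transcript
  isoform resolution, proteasomal cleavage and TAP transport are out of
  scope. The VCF reader handles missense ANN annotations only, since
  frameshift ANN terms do not carry the novel peptide sequence.
* The model is fixed-length (9-mers); 8/10/11-mer registers are not
  scored.
* External predictors are consumed as rank tables, never executed.
* Scores are unnormalized across alleles; cross-allele comparisons rely
  on the shared training scale.
* Tier thresholds (`delta_big`, `delta_small`) are score-scale
  conventions, not calibrated immunogenicity probabilities; tiers are
  categorical labels.
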