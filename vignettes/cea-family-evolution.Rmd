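---
title: "Methods: molecular evolution of CEACAM-like receptor families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular evolution of CEACAM-like receptor families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceafam)
```

## The analysis problem

CEACAM-like gene families evolve by repeated duplication, rapid
diversifying selection on the pathogen-binding N (IgV-like) domain,
pseudogenization, and gene conversion between paired
inhibitory/activating receptors. `ceafam` packages the corresponding
analyses — motif classification, gene/pseudogene delineation, gene
counting, dN/dS profiling, neighbour-joining phylogenetics and
conversion-tract detection — so they can be run end-to-end,
reproducibly, on aligned exon sequences plus an exon-structure table.
This vignette records the statistical models, the tunable parameters
and the design decisions taken where the problem was genuinely open.

## Sequence handling and the codon mask

All codon-based statistics run on a `codon_alignment`: equal-length
nucleotide rows whose length is a multiple of three. A codon column is
*masked* when any row carries a gap or ambiguity character in it, and
masked columns are excluded from every computation for every pair
(complete deletion at codon granularity). This is the deterministic
programmatic stand-in for the manual gap editing that codon-level
analyses traditionally perform; the cost is that a gap in one sequence
discards the column for all, which is conservative but
order-independent. Coordinates are 0-based half-open internally;
reports print 1-based positions.

## Motif grammar

The consensus patterns are fixed:

| motif | pattern |
|---|---|
| ITIM | `[ILVS] x Y x x [LV]` |
| ITSM | `T x Y x x [VI]` |
| ITAM | `[DE] x{0–2} Yxx[LI] x{6–8} Yxx[LI]` |
| ITAM-like | `Yxx[LI] x{6–8} Yxx[LI]`, no D/E at −1..−3 before the first Y |
| endocytic | `Y x x [LMVIF]` |
| GRB2-type | `Y x N` |
| YxxM variant | `Y x x M` |
| TEHKxS box | `T E H K x S` |

Three decisions are worth recording. First, the ITAM's acidic residue
is accepted anywhere at offsets −1..−3 before the first tyrosine
(i.e. `[DE]` followed by 0–2 spacers), which generalizes the common
`(D/E)xx` spelling; the ITAM-like rule is its exact complement, so an
ITAM-like hit is automatically suppressed whenever the same tyrosine
pair satisfies the ITAM. Second, every admissible spacer length is
reported as a separate hit, but classification counts distinct
first-tyrosine offsets, so nested spacer variants of one physical motif
count once — receptors are classified by motifs, not regex matches.
Third, the membrane-proximal box appears in the literature in two
spellings (`TEHKxS` and `THEKxS`); rather than silently picking one,
the scanner reports both and flags the transposed spelling with
`variant = TRUE`.

Classification precedence is ITAM > ITAM-like > ITIM+ITSM > two ITIM >
one ITIM > none. An activation motif anywhere in the cytoplasmic domain
dominates because it changes the receptor's signalling sign; the
inhibitory labels then refine by motif inventory. Sequences whose
ITAM second half ends in methionine rather than leucine/isoleucine
(a YxxM, PI3K/Vav-recruiting variant) are classified by the
first-half rule; `itam_second_half_variant()` exposes the distinction.

## Gene models and pseudogene rules

A gene is an ordered list of typed exons (`L`, `N`, IgC-like `A`/`B`,
`TM`, `Cyt1`–`Cyt4`) with splice dinucleotides, intron phase and frame
offset. Pseudogene calling applies two rules: an in-frame stop codon
within an N-domain exon, or a non-canonical splice dinucleotide
(acceptor ≠ `AG`, donor ≠ `GT`) on the N exon. In opossum mode a
corrupted leader-peptide exon (stop or splice lesion on `L`) is a third
rule. Calling is monotone by construction: lesions only accumulate
reasons, and status is pseudogene iff the reason list is non-empty.

`detect_donor_readthrough()` models the characteristic
secreted-truncated products of defective donors: translation continues
in frame across the exon/intron boundary (any leftover partial codon is
completed from the intron) and the first two in-frame stops within
60 intronic nucleotides are reported. The 60-nt window is a pragmatic
bound — read-through stops that matter biologically sit immediately
behind the exon.

Gene counting follows the 1% rule: distinct N-domain exons with
pairwise divergence above 1% count as distinct genes. Divergence is
the uncorrected nucleotide p-distance with pairwise deletion of
ambiguous sites, and clustering is single linkage — "distinct" is a
connectivity notion (an exon chain at ≤1% steps is one gene), not a
centroid one. Whether the original rule meant nucleotides or amino
acids is not documented anywhere we could find; nucleotide p-distance
is the stand-in, and the threshold is exposed (`cluster_threshold`).

Receptor pairing emits, for every intact inhibitory gene, the
same-species activating gene with maximal N-domain amino-acid identity,
subject to a floor of 0.80. The floor is an invented operational
parameter (paired receptors are extracellularly near-identical, usually
>0.9); it is exposed in `run_config()`.

## Nei–Gojobori dN/dS

Site counting assigns each codon position the fraction of its three
possible single-nucleotide changes that are synonymous; stop-creating
changes count as nonsynonymous, and s + n = 3 exactly per codon.
Between two codons differing at k positions, synonymous/nonsynonymous
difference counts are averaged over the k! substitution orderings;
orderings that pass through a stop codon are excluded from the average,
and when every ordering is blocked the average falls back to all
orderings with stop steps counted as nonsynonymous (a rare corner —
sense-to-sense pairs whose every path crosses a stop). Proportions
pS = Sd/S and pN = Nd/N are Jukes–Cantor corrected,
d = −(3/4)·ln(1 − (4/3)p), which assumes equal base frequencies and no
transition/transversion bias; proportions ≥ 3/4 raise a saturation
error naming the pair rather than returning a silent `NaN`. ω = dN/dS
is *undefined* (never infinity) when dS = 0 — two identical or purely
nonsynonymously diverged sequences carry no information about the
ratio.

`dnds_summary()` reports the mean ± SD of ω over all sequence pairs
with defined ω. This is a deliberate approximation: branch-wise ω via
ancestral reconstruction would weight independent lineages properly,
but needs a codon model and reconstruction machinery that is out of
scope; the pairwise mean is reported as such (`pairwise
approximation`) and its recovery properties are validated by
simulation (below).

`substitution_profile()` averages the per-codon difference counts over
all pairs and accumulates them along the coding region — the classic
cumulative-average synonymous/nonsynonymous curves. Conserved regions
are delineated from the nonsynonymous track by a sliding mean (centred
window of 10 codons, shrunk at the ends) thresholded at 0.5× the
exon-wide mean, merged into maximal runs of ≥5 codons; runs longer
than 20 codons are flagged as extended conserved regions. Window,
factor and minimum length are operational choices (exposed as
arguments) that turn a visual delineation practice into a reproducible
rule; a profile with zero nonsynonymous signal reports the whole exon
as one conserved region.

## Neighbour joining and bootstrap

Distances: nucleotide p or JC69, amino-acid p or Poisson
(d = −ln(1 − p)), all with pairwise-complete deletion. NJ is the
Saitou–Nei agglomeration with selection criterion
Q(i,j) = (r−2)d(i,j) − R_i − R_j. Two details are fixed for
reproducibility because they are unspecified in the classical
description and vary between programs: ties in Q are broken by the
lexicographically smallest pair of taxon labels (each cluster
represented by the smallest label it contains), and negative
intermediate branch lengths are clamped to zero. On additive matrices
the algorithm is exact (tree-metric round trip), which the tests verify
on random instances.

Bootstrap resampling draws columns with replacement — *codon* columns
for codon alignments, so codon-internal correlation survives
resampling, and single sites otherwise. Support for each internal
bipartition of the point-estimate tree is the percentage of replicate
trees containing that bipartition; supports land on internal node
labels and survive newick round trips. The replicate count default is
100 in the pipeline (1000 is conventional for publication figures; the
cost is linear in B) and the whole procedure is deterministic given the
seed.

## Gene-conversion detection

A recent conversion tract between paralogs shows up as a stretch of
codons with no synonymous differences embedded in a synonymously
diverged background. The statistic is the length of the longest run of
consecutive usable codons whose per-codon synonymous difference is ≤
epsilon (default 0 — the "no accumulation" reading; epsilon > 0 serves
the "minimal accumulation" reading; no claim is made about which
reading matches any particular prior analysis). Masked codons carry no
information and do not break runs. The null distribution permutes the
observed per-codon values B times (default 1000), which conditions on
the observed synonymous opportunities instead of assuming a parametric
rate; p = (1 + #{null run ≥ observed}) / (B + 1), so p-values are valid
(super-uniform) by construction. An all-zero track is *inapplicable*
(identical sequences are uninformative), reported as an error rather
than p = something.

Percent-identity segments between raw gene loci are computed by exact
k-mer seeding (k = 11), ungapped bidirectional extension with match +1
/ mismatch −1 under an X-drop of 20, merging of overlapping extensions
on a diagonal, and filtering at ≥40 nt and ≥60% identity. These
parameters are invented but conventional for seeded ungapped
extension; all are arguments. The output is tabular (no plotting), and
`locate_high_identity_region()` intersects the top segment with an
exon-coordinate annotation.

## What the simulator emulates — and what it does not

`simulate_codon_evolution()` evolves a random sense-codon root along a
tree; each branch receives Poisson(μ · 3L · t) single-nucleotide
proposals, accepted with probability 1 (synonymous), ω (nonsynonymous)
or 0 (stop-creating). This acceptance scheme was chosen over a full
codon rate matrix for transparency: its realized dN/dS approximates ω
closely enough that the estimator-recovery bands (ω = 0.1 recovered in
[0.05, 0.2]; ω = 1.0 in [0.8, 1.25] for 7 taxa × 300 codons) hold, with
a small downward bias at high ω because proposals into stop codons are
rejected by the generator yet counted as nonsynonymous opportunity by
the estimator. Default random topologies have 7 tips with uniform
branch lengths in [0.02, 0.12] proposals per site, keeping pairwise
synonymous divergence in the well-conditioned range far from
saturation.

`simulate_gene_family()` assembles genes from exon scaffolds. N-exon
clusters are built by allocating mutually exclusive mutated positions
(within-cluster target p-distance 0.004, between-cluster 0.04 —
bracketing the 1% counting threshold from both sides), cytoplasmic
exons are built from motif cassettes over a reduced "inert" amino-acid
alphabet (no Y/T/D/E) with rejection sampling (bounded at 10,000
attempts) guaranteeing that exactly the configured motif class is
present, lesions are introduced as directed, and the activating member
of a receptor pair derives from its inhibitory template by per-codon
synonymous scrambling at rate 0.2 (≈ dS 0.3, the classic
paired-receptor signature: high protein identity over a synonymously
saturated background) plus rare nonsynonymous changes (rate 0.02,
keeping N-domain identity ≈ 0.98), before a 60-codon conversion tract
(codons 21–80 by default) is copied across.

The simulator deliberately omits: indels (so alignment is trivial and
the codon mask exercises only ambiguity handling), base-composition
and codon-usage bias, transition/transversion bias, rate variation
among sites, and duplication/loss dynamics. A green simulation test
therefore establishes algorithmic correctness and statistical
calibration under an idealized neutral-ish background — it does not
establish robustness to compositional or alignment artefacts in real
genome-extracted data.

## Numerical and degenerate-input conventions

- Residues are upper-cased on input; `U` maps to `T`.
- Translation renders stops `*`, gap/ambiguity codons `X`, and drops
  incomplete trailing codons.
- All stochastic entry points (`nj_bootstrap`, `conversion_test`, the
  simulators, the pipeline) require an explicit seed; the pipeline
  derives per-stage seeds from the run seed, so reports are
  reproducible from inputs + config + seed.
- Saturation (p ≥ 3/4 nucleotide, p ≥ 1 amino acid) raises errors
  naming the offending pair; the dN/dS summary skips such pairs with a
  warning rather than failing the whole alignment.
- Empty FASTA files parse to empty collections; an empty gene set is a
  configuration error before any computation.

## Known limitations

Pairwise-mean ω is an approximation to branch-wise estimation and will
compress genuinely lineage-specific signals. The conversion test's run
statistic detects one dominant tract per pair; multiple tracts shorten
the reported maximal run. The 1%-threshold gene count inherits the
arbitrariness of that threshold — the count's monotonicity in the
threshold is tested, but the value itself is a convention. The NJ
implementation targets family-sized problems (tens of taxa); its dense
O(n³) agglomeration is not meant for thousands of leaves.
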