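# ceafam

Molecular-evolution toolkit for CEACAM-like immunoreceptor gene
families.

Mammalian carcinoembryonic antigen-related cell adhesion molecule
(CEACAM) genes form rapidly evolving clusters of paralogs whose
cytoplasmic domains carry immunoreceptor tyrosine-based motifs: the
inhibition motif ITIM `(I/L/V/S)xYxx(L/V)`, the switch motif ITSM
`TxYxx(V/I)`, the activation motif ITAM
`(D/E)x0-2 Yxx(L/I) x6-8 Yxx(L/I)`, and the ITAM-like motif (the same
two-tyrosine pattern without an acidic residue at positions −1..−3
before the first tyrosine). Inhibitory/activating members of such
families form paired receptors whose extracellular domains are kept
near-identical by gene conversion, and the families accumulate
pseudogenes through in-frame stops and splice-site lesions. `ceafam`
implements the analyses such a family calls for, as a reusable,
seed-reproducible R pipeline for evolutionary immunologists and
comparative genomicists:

- **Motif scanning and receptor classification** — exhaustive consensus
  matching with the precedence rule
  ITAM > ITAM-like > ITIM+ITSM > 2×ITIM > 1×ITIM > none
  (`scan_motifs()`, `classify_cytoplasmic()`).
- **Gene/pseudogene delineation** — GT-AG splice checks, in-frame-stop
  scanning of N-domain exons, opossum-mode leader-exon rules, and
  splice-donor read-through detection (`call_pseudogene()`,
  `detect_donor_readthrough()`).
- **Gene counting** — single-linkage clustering of N-domain exons at a
  1% nucleotide divergence threshold (`cluster_n_exons()`).
- **Nei–Gojobori dN/dS** — per-codon synonymous/nonsynonymous site
  counts (s + n = 3 per codon; stop-creating changes count as
  nonsynonymous), pathway-averaged difference counts, Jukes–Cantor
  correction `d = −(3/4) ln(1 − (4/3) p)`, pairwise ω = dN/dS summaries,
  cumulative substitution profiles and conserved-region delineation
  (`ng_pairwise()`, `dnds_summary()`, `substitution_profile()`).
- **Phylogenetics** — p/JC69 nucleotide and p/Poisson
  (`d = −ln(1 − p)`) amino-acid distances, exact Saitou–Nei neighbour
  joining with deterministic tie-breaking, codon-aware bootstrap
  supports, newick I/O (`nj_tree()`, `nj_bootstrap()`).
- **Gene-conversion detection** — the longest run of codons without
  synonymous differences between a paralog pair, tested against a
  permutation null (`syn_diff_track()`, `conversion_test()`), plus
  percent-identity segments between gene loci by seeded ungapped
  X-drop extension (`pip_segments()`).
- **Synthetic families with ground truth** — a seedable simulator of
  codon evolution under a chosen ω, implanted conversion tracts, motif
  cassettes, lesions and divergence-controlled N-exon clusters
  (`simulate_codon_evolution()`, `simulate_gene_family()`).

## Worked example

Simulate a five-gene family (two near-identical inhibitory genes, an
activating partner derived from one of them with a 60-codon conversion
tract, a secreted member and a pseudogene), then run the full analysis:

```r
library(ceafam)
fam <- simulate_gene_family(family_config(seed = 42))
rep <- run_full_analysis(run_config(genes = fam$genes, seed = 42,
                                    bootstrap_B = 100, conversion_B = 1000))
rep$catalog
#>   gene_id    species     status        reasons receptor_class  anchor_class cluster
#> 1    CC1a synthetica       gene                     ITIM_ITSM transmembrane       1
#> 2    CC1b synthetica       gene                     ITIM_ITSM transmembrane       1
#> 3     CC3 synthetica       gene                     ITAM_like transmembrane       2
#> 4     CC5 synthetica       gene                          none      secreted       3
#> 5    CCps synthetica pseudogene stop in N exon           none transmembrane       4
```

The catalog reads exactly like a per-gene family table: `CC1a`/`CC1b`
share one N-exon cluster (divergence below 1%, counted as one gene),
the lesioned gene is called a pseudogene with its reason, and the
receptor classes recover the implanted motif cassettes. Pairing and
conversion testing then flag the implanted pair:

```r
rep$pairs
#>   inhibitory activating  identity    species
#> 1       CC1a        CC3 0.9907407 synthetica
#> 2       CC1b        CC3 0.9722222 synthetica
rep$conversion_calls
#>   inhibitory activating run_start run_end run_length     p_value    B
#> 1       CC1a        CC3        14      83         70 0.000999001 1000
#> 2       CC1b        CC3        14      83         70 0.001998002 1000
```

`CC3` is the maximal-identity activating partner of each inhibitory
gene (99.1% N-domain identity for `CC1a`), and the conversion test
finds a 70-codon run without synonymous differences (codons 14–83,
permutation p ≈ 0.001) — covering the implanted tract at codons 21–80.
The pairwise Nei–Gojobori estimate for the pair shows the expected
purifying signature outside the tract:

```r
n_aln <- build_codon_alignment(lapply(fam$genes[c(1, 3)], function(g)
  cea_seq(g$gene_id, g$exons[[2]]$sequence, "nucleotide")))
ng_pairwise("CC1a", "CC3", n_aln)
#> <ng_pair CC1a/CC3: dS=0.1164 dN=0.0135 omega=0.116 (108 codons)>
```

Motif scanning on a cytoplasmic fragment:

```r
scan_motifs("FGLQLFSVYSELPKHTAYCSI", c("ITIM", "ITSM"))
#>   motif start end matched anchors variant
#> 1  ITIM     6  12  SVYSEL       8   FALSE
#> 2  ITSM    15  21  TAYCSI      17   FALSE
```

Real data enter through `read_fasta()` (pre-aligned exon/CDS FASTA) and
`read_gene_table()` (a tab-separated exon-structure table documented in
`?read_gene_table`); `run_config(gene_table = "family.tsv", ...)` drives
the same pipeline from files, and `out_dir =` writes every report as an
annotated TSV plus the bootstrapped newick tree.

## Acceptance script

`scripts/acceptance.R` regenerates the packaged synthetic family from
the given seed, runs the complete pipeline on it (classification,
pseudogene calling, clustering, NJ bootstrap, dN/dS profiling, receptor
pairing, conversion testing), and writes the JSON manifest:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope notes

Inputs are assumed pre-aligned (no aligner is bundled); membrane-anchor
class (transmembrane/GPI/secreted) is taken from the input annotation,
not predicted; and dN/dS summaries are pairwise approximations —
branch-wise estimation on ancestral reconstructions is out of scope.
See the methods vignette (`vignettes/cea-family-evolution.Rmd`) for the
statistical details and design decisions.
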