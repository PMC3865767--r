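# paralogdiv

Tools for quantifying how two paralog clades diverge after a gene
duplication, built around the questions raised by the vertebrate BACE1/BACE2
aspartyl protease family: did one copy evolve faster, where along the gene
does purifying selection relax, and how do you tell a true family member from
its cathepsin-like relatives using sequence evidence alone?

The package is written for molecular evolution analyses that start from a
protein multiple alignment (plus, optionally, the matching coding sequences)
and a table saying which sequence belongs to which paralog clade and species.
A bundled codon-level simulator generates duplicated gene families with known
trees, clade rate multipliers and per-region selection strength, so every
stage can be validated end to end without touching a database.

## What it computes

**Paralog rate asymmetry.** For every species present in both clades, the
within-clade distances `d_A(i,j)` and `d_B(i,j)` are compared over all
species pairs. Distances are p-distances with pairwise deletion, optionally
Poisson-corrected (`d = -ln(1 - p)`). The headline statistic is the
arithmetic mean of the per-pair ratios `d_B / d_A` (the ratio of the two
means is reported alongside, since the two aggregates differ), with direction
counts and an exact two-sided sign test on the non-tie pairs.

**BioNJ trees.** Distance trees are built with the variance-weighted
neighbour-joining agglomeration (Gascuel 1997): standard Q-criterion pair
selection, NJ branch lengths, and the BIONJ reduction
`d_uk = λ d_ik + (1-λ) d_jk - λ b_i - (1-λ) b_j` with
`λ = 1/2 + Σ_k (v_jk - v_ik) / (2 (n-2) v_ij)` and pair-variance bookkeeping.
Column-bootstrap supports are reported per internal edge as bipartition
frequencies.

**Counting-based Ka/Ks.** Nei–Gojobori (1986) counting: per sense codon, each
of the nine single-nucleotide neighbours is classified synonymous or
nonsynonymous (stop neighbours dropped without renormalisation), multi-hit
codons are averaged over substitution path orderings with stop-crossing paths
excluded, and proportions are Jukes–Cantor corrected,
`k = -3/4 ln(1 - 4p/3)`. Two estimators are provided: the mean over all
sequence pairs, and a SLAC-style variant that reconstructs ancestral codons
by Fitch parsimony on a tree and counts substitutions per branch. Both run on
whole coding regions or on domain/exon partitions mapped through a reference
sequence (1-based residue coordinates, as in CCDS-style tables).

**Homolog triage.** A seven-point checklist classifies candidates as
`bace-like`, `borderline` or `cathepsin-like`: reciprocal best hit into the
reference set, Smith–Waterman identity/coverage/gap thresholds (BLOSUM62,
affine gaps, ~35% identity over most of the ORF), relative identity to
cathepsins, a ~100-residue length excess, an N-terminal hydrophobic
signal-peptide window, a C-terminal transmembrane window (19-residue
Kyte–Doolittle mean ≥ 1.6 near the C terminus), and the count of full
PROSITE PS00141 aspartyl active-site matches (one proximal match for
BACE1-like sequences, two for cathepsin-like ones).

**Conserved blocks.** Gap-free, high-information column runs of a protein
alignment are reported with per-column information content
(`IC = log2 20 - H`, sequence-logo semantics) and per-block logo tables.

## Worked example

Simulate a duplicated family in which clade B evolves twice as fast, then
quantify the asymmetry:

```r
library(paralogdiv)

params <- sim_params(n_species = 8, r = 2, codon_length = 400, seed = 42)
fam <- simulate_gene_family(params)
dm <- distance_matrix(fam$protein_msa, model = "poisson")
asymmetry_summary(pair_table(dm, fam$labels))
#> Paralog rate asymmetry over 28 species pairs
#>   mean d(A) = 0.138, mean d(B) = 0.295
#>   mean per-pair B/A ratio = 2.094 (ratio of means 2.138)
#>   direction: B>A 28, A>B 0, ties 0; sign test p = 7.45e-09
```

All 28 species pairs are more diverged in clade B, the mean per-pair ratio
recovers the generative rate multiplier `r = 2`, and the sign test rejects
rate symmetry. Partitioned Ka/Ks on a shallow 8-species clade with a relaxed
N-terminal region (omega 0.3 over codons 1–48, 0.05 elsewhere):

```r
sp <- simulate_species_tree(8, total_height = 0.06, seed = 42)
params <- sim_params(n_species = 8, total_height = 0.06, codon_length = 400,
                     seed = 42,
                     omega = tibble::tibble(name = c("nterm", "core"),
                                            start = c(1L, 49L),
                                            end = c(48L, 400L),
                                            omega = c(0.3, 0.05)))
sim <- simulate_codon_msa(sp, params)
tr <- build_bionj(distance_matrix(translate_alignment(sim$alignment)))
parts <- tibble::tibble(name = c("nterm", "core"),
                        start_aa = c(1L, 49L), end_aa = c(48L, 400L))
tab <- kaks_partition(sim$alignment, parts, reference_id = "sp01",
                      method = "both", tree = tr)
print(as.data.frame(tab[, c("partition", "method", "sd", "nd", "ka_ks",
                            "flag")]), digits = 3)
#>   partition             method     sd   nd  ka_ks flag
#> 1       All ng86-mean-pairwise  60.64 14.1 0.0635   ok
#> 2       All          slac-like 144.00 29.0 0.0701   ok
#> 3     nterm ng86-mean-pairwise   5.96  4.0 0.1710   ok
#> 4     nterm          slac-like  15.00  8.0 0.1670   ok
#> 5      core ng86-mean-pairwise  54.68 10.1 0.0509   ok
#> 6      core          slac-like 129.00 21.0 0.0574   ok
```

Both estimators place the relaxed N-terminal partition about three-fold above
the purifying core, matching the generative contrast. `run_pipeline()` chains
simulate → tree → asymmetry → Ka/Ks → blocks → triage into one seeded,
reproducible run with TSV/Newick/JSON artifacts.

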