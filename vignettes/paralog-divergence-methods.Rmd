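---
title: "Methods: quantifying post-duplication paralog divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying post-duplication paralog divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogdiv)
```

This vignette is the package's account of its models and the design choices
behind them. The running example is a duplicated protease family of the
BACE1/BACE2 type: one ancestral gene duplicates, the two daughter clades track
the species phylogeny, and the questions are (i) whether one clade accumulated
protein change faster, (ii) how strongly purifying selection acts along the
coding region of each copy, and (iii) how to recognise genuine family members
among cathepsin-like relatives from sequence evidence alone.

## The synthetic gene-family model

`simulate_gene_family()` is first-class, tested code, not a fixture. It
emulates:

* a Yule species tree (`simulate_species_tree()`), rescaled so the mean
  root-to-tip path equals `total_height`, in expected nucleotide
  substitutions per site;
* one duplication at the root (`graft_duplication()`): the gene tree is two
  independent copies of the species tree joined by stem edges, with every
  branch of copy B — stem included — multiplied by the rate multiplier `r`;
* codon evolution (`simulate_codon_msa()`): root codons are drawn uniformly
  from the 61 sense codons (or from supplied frequencies); along each branch a
  continuous-time process proposes single-nucleotide changes, weighting
  transitions by `kappa` and accepting nonsynonymous changes at relative rate
  `omega` of the partition the codon sits in; changes that would create a stop
  codon are rejected without renormalising the remaining rates.

Branch lengths are calibrated so that one unit equals one expected nucleotide
substitution per nucleotide site at the root composition (the per-codon flux
is normalised to 3). This makes simulated branch lengths directly comparable
to the protein-level distance estimators and is why the clade-B/clade-A
distance ratio recovers `r`.

Defaults, with units and rationale:

| parameter | default | meaning |
|---|---|---|
| `n_species` | 10 | species per clade |
| `total_height` | 0.25 subs/site | root-to-tip depth; the scale of observed within-clade divergence in a vertebrate paralog family |
| `r` | 2 | clade-B acceleration, the BACE2-like regime |
| `kappa` | 2 | transition/transversion rate ratio, the canonical mammalian value |
| `omega` profile | 0.3 / 0.05 / 0.3 | relaxed termini around a strongly purifying core, mirroring the 5'-exon vs catalytic-core contrast seen in real duplicated protease genes |
| `dup_stem` | `total_height` | age of the duplication relative to the crown groups |
| `codon_freqs` | uniform | root codon distribution |

What the simulator does **not** emulate: indels (the simulated columns are the
true alignment, so alignment error is outside every test), among-site rate
variation beyond the omega partitions, codon usage bias, lineage-specific
`kappa`, gene conversion between paralogs, and duplication/loss after the
founding event. Passing tests therefore demonstrate that the estimators
recover known truth under a clean generative model — not that they are robust
to misalignment or model violation on real data.

Determinism: every `sim_params()` seed fixes one R RNG stream; the root draw
happens first, then branches are processed in cladewise order and codon sites
left to right within each branch, so identical parameters give byte-identical
alignments.

## Distances and BIONJ

Protein distances are p-distances with pairwise deletion (columns with a gap
or `X` in either row are skipped), optionally Poisson-corrected,
`d = -ln(1 - p)`. The default is the corrected distance; both are available
because published distance analyses of this kind rarely state the model, so a
reproduction must try both.

`build_bionj()` implements the variance-weighted neighbour-joining
agglomeration: Q-criterion selection `Q_ij = (n-2) d_ij - R_i - R_j`, NJ
branch lengths `b_i = d_ij/2 + (R_i - R_j)/(2(n-2))`, and the BIONJ reduction
with `lambda` chosen from the pair variances (`v`, initialised to `d`):
reduced distances `lambda (d_ik - b_i) + (1-lambda)(d_jk - b_j)` and variances
`lambda v_ik + (1-lambda) v_jk - lambda(1-lambda) v_ij`. Numerical choices:
ties on Q go to the smallest row/column index pair; negative branch-length
estimates are clamped to zero with the deficit moved to the sister branch
(which preserves path lengths through the joined pair); `lambda` is clamped
to [0, 1]; the final three clusters are resolved by the exact three-point
formulas, leaving the conventional trifurcating root. On additive matrices
any `lambda` gives the exact generating tree, which is what the additivity
tests exploit; an independent implementation (`ape::bionj`) is used in the
test suite as a cross-check only.

Bootstrap supports resample alignment columns with replacement (codon-wise
for codon alignments), rebuild the tree per replicate, and report for every
internal edge of the point-estimate tree the percentage of replicates whose
tree contains the same leaf bipartition. An alignment with no variation gives
identical replicate matrices, identical trees and supports of 100 — the
degenerate case is defined, not an error.

## The rate-asymmetry statistic

Species present in both clades are matched (`match_species()`); lineage-
specific extra copies are excluded explicitly by id, with the exclusion list
part of the input rather than a heuristic. For all `C(n, 2)` species pairs
the within-clade distances are compared. Two aggregates are reported because
they answer different questions and genuinely differ: the arithmetic mean of
per-pair ratios `d_B/d_A` (sensitive to pairs with small `d_A`) and the ratio
of the two mean distances. The direction counts come with an exact two-sided
binomial sign test on the non-tie pairs (`tie_epsilon` defaults to 1e-12 —
exact ties only). The sign test is an inferential layer the distance
comparison itself does not include; it is labelled as such in the output.

A caveat the test suite documents: the species pairs share tree paths, so
under rate symmetry the direction counts are overdispersed relative to a
binomial with 190 or 45 independent trials. The sign test is therefore
anticonservative at face value; the package still reports it because the
observed direction counts in the motivating analyses are far beyond any
plausible overdispersion correction.

## Counting-based Ka/Ks

`ng86_sites()` enumerates, for each sense codon, its nine single-nucleotide
neighbours and classifies each as synonymous or nonsynonymous under the
standard code. Neighbours that are stop codons are dropped **without**
renormalisation, so site counts per codon sum to at most 3; alternatives that
redistribute the dropped fraction exist in the literature and change site
counts slightly. Codons with every substitution path crossing a stop are
excluded from difference counts and flagged (`n_blocked`); their site counts
are kept, since sites are a property of the individual row.

The pairwise estimator (`kaks_ng86()`) averages the two rows' site counts
over mutually ungapped codon columns, path-averages multi-hit codons over the
orderings of single steps, corrects `pS` and `pN` with Jukes–Cantor
(`-3/4 ln(1 - 4p/3)`; `p >= 0.75` is flagged saturated), and reports the
dataset values as means over all unordered pairs with ratio
`mean(Ka)/mean(Ks)`. A `Ks = 0` result is flagged, never reported as an
infinite or zero ratio — a `0.000` ratio always means `Ka = 0`.

The SLAC-style estimator (`kaks_slac()`) reconstructs ancestral codons by
Fitch parsimony per nucleotide column (gaps at leaves are missing data;
multifurcations are resolved with zero-length edges first) and counts
synonymous/nonsynonymous changes on every branch with the same path-averaging
convention. Where the top-down pass leaves a choice, the codon minimising
nonsynonymous change against the parent is taken, ties lexicographic; at the
root the lexicographically smallest admissible codon is used, with stop
codons avoided whenever a sense codon is available. These tie-breaks cannot
change the parsimony score (the tests verify the score against an exhaustive
minimum). The tree-wide aggregates are **not** Jukes–Cantor corrected — the
sums grow with tree length, so a correction designed for pairwise proportions
would always saturate; the ratio is taken on the raw aggregate proportions
`(sum Nd / N) / (sum Sd / S)`, and per-unit-tree-length rates plus the tree
length are emitted for anyone who wants a differently normalised rate. This
substitutes a distance tree plus parsimony ancestors for the original
likelihood machinery of SLAC, so second-decimal agreement with
likelihood-based results is the expected regime, not bit-exactness.

Partitioned runs (`kaks_partition()`) map 1-based residue coordinates on a
named reference row through that row's gaps to alignment columns, expand to
codon columns, and prepend a whole-alignment `"All"` row. When partitions
tile the reference exactly, the per-partition difference counts sum to the
whole-alignment counts.

**Problem sizes for the recovery experiments.** Counting methods are
small-divergence methods; the motivating analyses restricted Ka/Ks to
mammalian cDNAs for exactly that reason. The package's recovery experiments
therefore run on a single 8-species clade at root-to-tip depth 0.06
substitutions/site with 400 codons — a mammalian-scale design — while the
asymmetry experiments use the full duplicated family (10 species per clade,
500 codons, depth 0.25 plus stem) where protein distances, not synonymous
sites, carry the signal. At the deep setting synonymous sites saturate by
construction and Ka/Ks would measure the correction, not the selection.

## Homolog triage

External signal-peptide/transmembrane predictors are replaced by fixed
hydropathy-window heuristics so the classifier is self-contained and
deterministic: a signal peptide is an 8-residue window within the first 40
residues with mean Kyte–Doolittle hydropathy at least 1.5; a C-terminal
transmembrane stretch is a 19-residue window starting within the final 80
residues with mean at least 1.6. Both are documented approximations — they
capture the architecture contrast that matters here (cathepsins lack the
C-terminal membrane anchor) but are not calibrated predictors of cleavage
sites or membrane topology.

Alignment evidence uses Smith–Waterman with BLOSUM62 and affine gap costs
(open 11, extend 1, the BLASTP-like regime the identity thresholds were
calibrated on). E-values are deliberately not computed: Karlin–Altschul
statistics depend on database size and are meaningless for a fixed reference
panel; identity, coverage of the shorter ORF and gap fraction substitute for
them. Identity is identical columns over all alignment columns, gap columns
included in the denominator.

The seven-point checklist and label logic are described in
`?triage_classify`. Three criteria are mandatory (reciprocal best hit,
identity/coverage/gaps, C-terminal transmembrane); a candidate meeting the
mandatory set but missing corroborative evidence is `borderline`, mirroring
how uncertain database matches are triaged in practice. "Proximal" for the
active-site motif means a match starting within the first 40% of the
sequence, a coordinate-free reading of an N-terminal-proximal match. The
exon-count criterion (≥ 9 exons) is consumed from optional metadata and never
computed from sequence — exon structure needs genome annotation, which is out
of scope. The coverage default (0.7 of the shorter ORF) is a calibration
knob: the source evidence says "the major part of the ORF" without a number.

The architecture decoys (`decorate_architecture()`) are synthetic stand-ins,
never database sequences: template-derived proteins with frozen functional
islands (signal peptide, active-site motifs, transmembrane stretch) and
seeded residue noise outside them. BACE-like decoys carry two D-[ST]-G cores
of which only the proximal one sits in a full PS00141 context — the same
asymmetry real BACE1 shows — so the motif-count criterion separates the two
kinds. Any accidental full-pattern match created by the noise is removed
deterministically, keeping the designed count exact.

## Conserved blocks

Block extraction is deterministic column scoring, not Gibbs sampling: rows
with more than `max_gap_rows_frac` gaps (default 0.5) are dropped — the
"very divergent sequences are excluded" behaviour of classic block tools —
then columns are eligible iff gap-free among retained rows with information
content `log2(20) - H` of at least `min_mean_ic` bits (default 2.0), and
maximal eligible runs of width at least `min_width` (default 6) become
blocks, reported N- to C-terminal with inter-block spacing. A small-sample
correction (`19/(2 ln 2 n)`, floored at 0) is available for logo rendering.
Reproducing a specific published block count on real data is a
calibration-level exercise (thresholds set once against that alignment), not
an algorithmic guarantee.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → tree → asymmetry → Ka/Ks → blocks →
triage under a single JSON-style configuration with one global seed;
per-stage seeds are fixed offsets of it, so any stage can be reproduced in
isolation. Unknown configuration keys are rejected by name. A stage error is
recorded and its dependents are skipped while independent stages still run.
All tabular artifacts are TSV; the consolidated report is JSON. The package
is function-first: the pipeline, the documented functions and
`scripts/acceptance.R` are the operational interface, and no shell
entry-point is shipped.

## Known limitations

* NG86 counting ignores the transition/transversion bias when counting
  sites; with `kappa = 2` this biases `Ka/Ks` modestly downward at moderate
  divergence, within the ±30% envelope the recovery experiments check.
* Fitch parsimony underestimates changes on long branches, so the SLAC-style
  estimator degrades with depth alongside the counting assumptions.
* The hydropathy heuristics are threshold classifiers, not probabilistic
  predictors; sequences with unusual composition near the termini can be
  misread.
* The sign test treats species pairs as independent; they are not (shared
  tree paths), and the test suite quantifies the resulting overdispersion.
* The simulator's no-indel assumption means alignment uncertainty is entirely
  outside the validated pipeline.
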