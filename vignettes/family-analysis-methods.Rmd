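---
title: "Methods: motif-defined gene families, intron architecture, and expression-metabolite linking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-defined gene families, intron architecture, and expression-metabolite linking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`glycofam` re-implements, as a tested pipeline, the standard survey of a
plant gene family defined by a conserved protein motif: membership calling,
phylogenetic grouping, exon–intron architecture, expression-pattern
summaries, and transcript–metabolite candidate ranking. The model system is
the UDP-glycosyltransferase (UGT) family, whose members carry a ~44-residue
C-terminal consensus (the PSPG box) and whose exon–intron structure and
expression are routinely used to trace duplication history and assign
putative function. This vignette records the methods, the tunable
parameters, and the design choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Family identification by motif scan

Membership is called by Smith–Waterman local alignment of the 44-residue
consensus against each proteome entry (`scan_proteome()`), delegating the
alignment itself to `Biostrings::pairwiseAlignment`. Scoring is BLOSUM62
with affine gaps, open 10 and extend 1 (a gap of length $k$ costs
$10 + k$); these are conventional protein local-alignment defaults. The raw
score is normalised by the motif's self-score, so the calling threshold
(`min_fraction`, default **0.40**) is independent of motif length and
scoring scale. 0.40 is permissive by design: diverged family members retain
only part of the motif, and the permutation-null test shows shuffled motifs
score well below it. The observed protein-length range of a family is
reported as a result, never applied as a filter (an optional length filter
exists but is off by default). No E-values, profiles or HMMs are provided:
the scan is a flat-consensus screen, and borderline calls should be
confirmed by the phylogeny.

The test suite cross-checks the aligner two ways: exhaustive
path-enumeration scores on short random pairs (enumeration is only
tractable up to ~7 residues; path counts explode combinatorially beyond
that), and frozen scores from an independent aligner implementation on
20–30-residue pairs under the identical gap convention.

## Distances, neighbor joining, group assignment

Pairwise distances are **p-distances with pairwise gap deletion**:
mismatches over columns where neither row has a gap (`X` counts as
non-comparable). No Poisson or Kimura correction is applied — with no
stated model to reproduce, the simplest defensible choice wins, and for
tree *topology* at the divergence levels of a single family the ranking of
distances is what matters. Pairs with zero comparable columns are an error
naming the pair.

`neighbor_joining()` is a from-scratch Saitou–Nei implementation: join the
pair minimising $Q(i,j) = (n-2)\,d(i,j) - R_i - R_j$, standard
branch-length formulas, reduce, repeat; the final three nodes are resolved
by the three-point formulas. Two behaviours are pinned for determinism
across platforms: exact $Q$ ties join the lowest (i, j) index pair, and
negative branch lengths are clamped to zero with the deficit both logged
and recorded as an attribute. On additive matrices the implementation
recovers the generating tree exactly (topology and lengths), which the
suite verifies on 50 random additive matrices against `ape::nj` as an
independent oracle. Bootstrap support and likelihood methods are out of
scope.

Groups are assigned from labelled **anchor leaves** (functionally
characterised reference proteins): each family leaf takes the label of its
nearest anchor by path length. This formalises what surveys do by eye on a
figure; because nearest-anchor assignment and clade structure can
disagree, every label's tip set is audited for monophyly (in the unrooted
sense) and violations are warned about, not hidden. Exact ties go to the
lexicographically smaller label and are flagged. Default labels are A–P,
the sixteen groups seen in Rosaceae UGT surveys.

## Intron phases, projection, insertion events

Intron phase is computed from the cumulative coding length $L$ upstream of
the intron: $\mathrm{phase} = L \bmod 3$ — phase 0 between codons, phase 1
after the first base, phase 2 after the second. The GFF3 `phase` column is
**never** read: it encodes bases-to-skip, a different convention, and
conflating the two is a classic error. Genes whose CDS length is not a
multiple of three are flagged partial and excluded from phase analysis;
introns in UTRs are ignored (phase is undefined outside codons).

Each intron is anchored to a residue for alignment projection: the split
codon's residue for phases 1 and 2, and the residue immediately following
the insertion point for phase 0 (both equal $\lfloor L/3\rfloor + 1$). The
anchor is mapped to its alignment column by counting non-gap positions in
the gene's row; an anchor beyond the ungapped row length signals an
MSA/gene-model mismatch and is an error rather than a silent skip.

`detect_events()` clusters projected introns by column with single-linkage
merging at gaps ≤ `window` and numbers clusters I-1, I-2, … by increasing
column. The default **window is 0**: with a correct alignment, introns
descending from one ancestral gain co-project exactly; a positive window
exists for gappy alignments. Events with fewer than `min_members` genes are
kept but flagged. Reported percentages (carrier share, dominant-phase
share, intronless share) are rounded **half away from zero**, which is how
such tables are conventionally printed; `round_half_up(68.75) = 69`,
`round_half_up(96.97) = 97`, `round_half_up(42.86) = 43`.

## Expression summaries

Row z-scores use the population (n-denominator) standard deviation — the
convention of the common heatmap tools behind the usual −2..2 colour scale;
constant rows map to zero and are flagged. Heatmap row order comes from
average-linkage clustering on 1−Pearson; the suite checks the merge
sequence against a naive re-averaging agglomeration oracle at small n.

Tissue-max calls take the sample group with the largest replicate-mean
abundance; ties go to the first group in metadata order and are flagged,
and all-zero genes are excluded from the denominators. Induction calls in
paired treated/control designs use
$\mathrm{lfc} = \log_2\frac{\bar{t}+1}{\bar{c}+1}$ against a threshold of
1 by default. A fold-change rule stands in for a formal test because the
pipeline consumes normalised matrices without count-level variance
information; the threshold is exposed, and the calls are exactly
antisymmetric under swapping the treated and control labels.

## Transcript–metabolite linking

Stage-mean expression is correlated with compound abundance per
gene×compound pair over shared stages (≥ 3 required; stages are matched by
name or an explicit mapping table, never by heuristics). Significance is a
two-sided t-test on $t = r\sqrt{(n-2)/(1-r^2)}$ with Benjamini–Hochberg
correction **across all pairs**; "significant positive" means $r > 0$ and
$q \le 0.05$. Constant profiles are skipped and flagged.

A power fact worth recording: at six stages (df = 4), $r = 0.95$ gives
$p \approx 3.7\times 10^{-3}$, and with ~2,000 pairs in the BH family the
resulting $q$ is near 1 — no correlation below ~0.99 can clear $q \le
0.05$ in a survey-sized analysis with so few stages. The recovery
benchmark in the test suite therefore plants its eight linked genes as a
tightly co-regulated module (shared latent stage profile, see below) with
the compound calibrated to the module mean at $r = 0.9995$, profiled at
low technical noise (sd 0.05); under those conditions exact recovery of
all eight succeeds in ≈96% of seeds. Real six-stage designs should expect
correspondingly low power.

The glycoside ion-mass calculator does the nominal-mass arithmetic of
negative-mode LC–MS: each hexose adds 162 (glucose − water), deprotonation
subtracts 1, and the formate adduct adds a further 46; for a 122-Da
aglycone the mono-hexoside gives m/z 283 and 329. A monoisotopic mode
(162.0528 / 1.00728 / 46.00548) exists for high-resolution work but the
nominal mode is the default, matching how such assignments are printed.

## The synthetic-family generator

`simulate_family()` emits a complete, internally consistent bundle: genome
FASTA, GFF3 gene models, proteome with motif-free decoys, the true protein
alignment, the generating tree, and truth tables for every planted fact.
Its defaults are the study conditions the rest of the package is tested
under: 168 genes in 16 groups (A–P) on 8 chromosomes, 480-residue
proteins with the 44-residue motif 10 residues from the C-terminus, 43%
intronless members, and ten planted insertion events at well-separated
columns with phase 1 dominant.

Mechanics and choices:

- **Tree and sequences.** Group clades hang off a caterpillar backbone
  (stem and backbone branches 0.5, within-group branches 0.05–0.1);
  sequences evolve down the tree with per-site substitution probability
  `substitution_rate` × branch length (default 0.3), with motif columns at
  one tenth of that rate so the motif stays recognisable while the rest
  diverges strongly. Tree shape is not itself a tested quantity; what
  matters is strong between-group and weak within-group divergence.
- **Indel policy.** The default generator is indel-free, so the true MSA
  equals the raw sequences and planted truth is exact. An optional indel
  mode gives every other group a 5-residue insertion (gap blocks in all
  other rows), placed away from event columns and the motif, to stress
  alignment projection.
- **Introns.** A planted event (column, phase, carrier groups) puts an
  intron into every non-intronless carrier gene at
  `cds_offset = 3 (r - 1) + phase`, where r is the gene's residue at that
  alignment column; intron lengths are uniform on [80, 2000] nt (no
  published length distribution to emulate; configurable) with GT…AG
  termini. Back-translation draws uniformly among synonymous codons —
  deterministic under the seed, with no codon-bias modelling.
- **Assembly.** Genes go round-robin onto chromosomes (or as group blocks
  with `tandem_clusters = TRUE`, emulating the tandem-duplicate clusters
  real families show), separated by fixed 500-nt random spacers, with
  strands drawn at random and both strands guaranteed present.
- **Expression and metabolites.** Expression is lognormal around planted
  group means (the planted group exceeds every other group by at least
  `effect_size`-fold before noise) — lognormal on a TPM-like scale rather
  than negative-binomial counts, because the pipeline consumes normalised
  matrices. Each gene has its own seeded stream, so identical plantings
  still get independent noise. Correlated sets share a lognormal latent
  profile (spread `latent_sd`, default 2; member jitter
  `profile_jitter_sd`). Linked compound profiles are built from the linked
  genes' mean stage profile with an orthogonalised noise component, so the
  sample correlation equals `r_target` exactly (r = 1 gives a noise-free
  affine copy).
- **Determinism.** All randomness flows from one root seed through named
  substreams (one per stage and per gene/compound); a fixed seed fixes
  every emitted byte, which the suite asserts file by file.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: alignment error (the true MSA is known),
annotation error in gene models, intron loss after gain (carriers are
exactly the planted sets), codon bias, count-level sampling noise,
batch effects, and any relationship between sequence divergence and
expression divergence. Recovery results on synthetic data are checks of
the pipeline's correctness, not estimates of sensitivity on a real
proteome.

## Problem sizes and numerical notes

The shipped tests run the full stack at family sizes 16–168 with 0–500
decoys, 50 random additive matrices at n ≤ 12 for the NJ property, the
phase rule over all prefix lengths 1..3000, and 10,000 independent pairs
for the correlation null calibration — sizes chosen to exercise every code
path while keeping the default suite quick on a laptop. Ties are broken
deterministically everywhere (NJ pair order, argmax metadata order,
anchor-label lexicographic order); floating-point comparisons in tie
detection use a 1e-12 tolerance. Degenerate inputs (empty proteomes,
constant rows, zero-signal genes, partial CDS, missing anchors) are
handled as flagged exclusions or named errors rather than silent drops.

## The orchestrated pipeline

`run_pipeline()` chains the stages from a single config (synthetic spec or
real-data paths), fails fast naming any missing input, and writes every
stage table with a provenance header (package version, root seed, config
hash) so each reported number can be recomputed from the table it cites.
The synthetic demonstration design plants eight linked genes as one
co-regulated module profiled at noise sd 0.05 (the link-power constraint
above); everything else uses the generator defaults. Two runs under one
seed produce byte-identical reports, which both the pipeline tests and the
acceptance battery assert.
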