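---
title: "Mining genomes for steroid degraders: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining genomes for steroid degraders: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`steromine` predicts aerobic steroid catabolism from genome content. This
vignette explains the models behind each stage, the parameters that matter,
the design decisions taken where the underlying procedure leaves room, and
what the simulation-based validation does and does not show.

## The screening model

Aerobic degradation of the steroid nucleus proceeds through the 9,10-seco
pathway, whose key enzymes are conserved across the characterized
cholesterol, cholate and testosterone gene clusters. The pipeline encodes
that biology as a decision rule over eight orthologous enzyme groups (KstD,
KshA, HsaA, HsaC, HsaD, HsaE, HsaF, HsaG family representatives): a genome
is called a putative degrader when at least `min_groups = 6` of the eight
groups have a profile-HMM hit at E ≤ 1e−25, **including both mandatory
groups** — the 3-ketosteroid 9α-hydroxylase oxygenase subunit (KshA-like)
and the A-ring extradiol dioxygenase (HsaC-like), without which the nucleus
cannot be opened. The mandatory groups count toward the six; reading the
rule inclusively is a documented choice (the alternative — six groups plus
two mandatory on top — is stricter and can be obtained by raising
`min_groups`).

Upstream of the rule, reference proteins are binned into homologous groups
as connected components of a similarity graph with joint thresholds
(identity ≥ 30 %, E ≤ 1e−30), each group is split into taxon/substrate
subclusters by greedy incremental clustering at 50 % identity (word size
3), and one profile HMM is built per subcluster. Downstream, hits are
confirmed as orthologs by reciprocal best hits (identity ≥ 25 %,
E ≤ 1e−25), pathways are assigned when a genome covers at least
`coverage_threshold = 0.7` of a pathway reference panel, hits are chained
into gene clusters, and a four-marker phylogeny is compared against the
16S-like tree.

## Alignment and E-values

All "BLASTp" steps are exact Smith–Waterman with affine gaps: a gap of
length *k* costs `gap_open + k * gap_extend` (defaults 11/1, BLOSUM62).
Identity is identical aligned pairs over all alignment columns, gap columns
included — the convention heat-map identities are usually reported in; how
the original filters counted the denominator is not documented, so this
choice is stated rather than inferred. Only the single best local alignment
per pair is used, since every stage consumes best hits only.

E-values follow Karlin–Altschul statistics, `E = K·m·n·exp(−λS)`. λ and K
cannot be copied from BLAST because they depend on the aligner; they are
fitted by maximum likelihood to a Gumbel law over optimal scores of seeded
random sequence pairs (`calibrate_karlin()`, 4000 length-150 pairs for the
shipped default; the package constants were produced by exactly that call).
The fitted tail tracks a Monte-Carlo null within a factor of three over the
calibrated range, which is the accuracy the thresholds need: the working
cutoffs (1e−25, 1e−30) sit far from the decision boundaries of true
orthologs (E below 1e−100) and random decoys (E near 1).

The same logic applies to profile HMMs: each model's forward scores on
`n_random = 1000` background sequences are fitted with a Gumbel law, and
`E(score) = database_size × P(score′ ≥ score)`. Consequences worth knowing:
E-values are exactly linear in database size, and the far tail (1e−25) is
an extrapolation of a parametric fit — adequate here because scores of true
family members exceed the null by hundreds of bits.

## Profile HMMs

Models are Plan7-lite: begin/end flanks (`N`, `C`) that self-loop over
background residues with probability `eta = L/(L+2)` handle local
alignment; the core is the standard match/insert/delete chain. Entry is
uniform over match states, each match state exits with probability
`1/(m+1)` (the last with 1). Insert emissions equal the background, so they
cancel in log-odds. Match columns are alignment columns with gap fraction
< 0.5 (the community convention; the original trimming was manual).
Emissions get background-proportional pseudocounts with total mass
`20/(rows + 20)` — strong smoothing, because subclusters can be small.
Scoring is all-path forward (not Viterbi) in bits; a Viterbi scorer exists
for diagnostics and is bounded above by the forward score. The forward
implementation is verified against exhaustive path enumeration on toy
models to 1e−10 relative error, and probability conservation is checked by
enumerating all short sequences of a two-letter model.

## The synthetic community

There is no public fixture that could stand in for thousands of annotated
genomes, so validation is simulation-based, and the generator is
first-class, tested code. It emulates:

* **protein families at controlled divergence** — a reversible
  continuous-time Markov substitution process whose exchangeabilities are
  the BLOSUM62 implied target frequencies over Robinson–Robinson
  backgrounds (so simulated divergence is commensurate with the scoring
  matrix), plus a Poisson indel process (rate 0.005 per site per unit
  divergence, geometric mean length 3). `evolve_sequence()` verifies the
  realized global-alignment identity and redraws with an adjusted
  divergence up to 20 times; across repeated draws the mean realized
  identity sits within 0.03 of the target over 0.3–0.9;
* **reference panels** — per enzyme group, one reference per pathway
  template, diverged between templates to ~36 % identity. That value makes
  templates bin together (comfortably above the 30 %/1e−30 edge at the
  default 300–450 residue lengths) yet subcluster apart (below 50 %), which
  is how the real reference pathways behave. Panel references diverge by
  substitution only so each family keeps a fixed length; indels enter via
  related proteomes and communities. Each template also carries six
  pathway-specific *accessory* genes (side-chain degradation/transport
  stand-ins, unrelated across templates): they are part of each pathway's
  cluster and coverage panel — and what makes pathway assignment
  discriminating, exactly as the full reference gene clusters do for the
  real procedure — but carry no HMM;
* **genomes** — non-overlapping genes on a circular chromosome (plus a
  plasmid when a cluster is placed there, probability
  `plasmid_probability`), geometric intergenic spacing (mean 120 bp), decoy
  genes drawn from background frequencies at 80–400 residues, and a few
  "near-decoys" evolved to 15–20 % identity to exercise the thresholds near
  their decision boundary;
* **vertical descent and transfer** — pathway genes evolve *along the
  species tree* (scaled so root-to-leaf identity matches the configured
  band, default 50–70 %), so gene trees are congruent with the species tree
  by construction; a horizontal-transfer event re-derives the recipient's
  pathway genes from the donor leaf while the 16S-like marker always
  follows the species tree.

What the generator does **not** emulate: real domain architecture or
composition bias (decoys are i.i.d. background, so the false-positive side
of the screen is easier than in nature), paralog-rich genomes,
draft-genome fragmentation, nucleotide-level effects (codon usage,
intragenic recombination), and rate heterogeneity across sites. Passing
the end-to-end tests therefore demonstrates the internal consistency and
calibration of the pipeline — thresholds, rule, localization and
congruence logic — not its performance on real proteomes.

## Gene clusters

"Cluster" has no stated definition in the original analysis, which judged
localization visually. Here two hits on one replicon join a cluster when at
most `max_gap_genes = 10` non-hit genes lie between them (single linkage);
gene counts rather than base pairs make the criterion robust to the
simulated intergenic-length distribution. Circular replicons are evaluated
with wraparound, so the partition is invariant under rotation of the
origin. Strand is recorded but ignored for chaining, since reference
clusters contain genes on both strands. A genome whose pathway clusters
all sit on plasmids is flagged `plasmid_only`.

## Phylogeny

Markers are the KshA-, HsaA-, HsaC- and HsaD-group orthologs, one taxon per
gene cluster (a genome with two clusters contributes two taxa). Blocks are
aligned progressively — shared 3-mer guide distances, average-linkage
guide tree, profile–profile merges under BLOSUM62 expected scores, then a
refinement pass that rebuilds the tree from realized identities and keeps
the better sum-of-pairs alignment — trimmed at gap fraction 0.5 and
concatenated.

Distances are Poisson-corrected, `d = −ln(1 − p)` with *p* counted under
pairwise deletion; trees are neighbor joining with negative branch
estimates clamped to zero; support comes from column bootstrap. Neighbor
joining, bipartition support counting and the Robinson–Foulds comparison
are implemented in the package (plain R; the NJ is cross-checked against
an independent implementation in the test suite), which keeps the
thousand-replicate bootstrap loop free of external tree machinery. **This
replaces the maximum-likelihood search used in the original analysis**: a
full ML engine is out of scope, NJ on corrected distances is consistent on
additive inputs (verified exhaustively for all binary topologies up to six
leaves), and the congruence conclusions being tested are purely
topological. Congruence is operationalized as the Robinson–Foulds distance
between the marker tree and the 16S-like tree after pruning to shared
leaves: 0 under vertical descent, positive after one long-range transfer.
The bootstrap default is 2,500 replicates; the validation suite and
acceptance runs use 100, which is ample for a yes/no topology comparison.

## Numerical and degenerate-input behavior

* Alignment ties (equal bit scores) break by lower E-value, then
  lexicographic target id; greedy-clustering ties (equal lengths) break
  lexicographically; clusters are scanned in creation order.
* Saturated distance pairs (p ≥ 1) and alignments trimmed to nothing raise
  typed errors rather than returning NA.
* The forward recursion runs in scaled linear space; rescaling triggers
  only when values threaten the double range, at which point still-waiting
  flank paths are negligible by hundreds of orders of magnitude.
* Identity targets at or below the substitution model's chance floor
  (~6 % expected site identity) are rejected as unattainable.
* Every stochastic step is seeded, and sub-seeds are derived
  deterministically from the master seed, so a pipeline rerun with the
  same seed is byte-identical file for file.

## Problem sizes

The validation community is 20 genomes with ten planted degraders at
50–70 % identity and 500 decoy genes each — large enough that each HMM
screens ten thousand proteins and the E-value semantics are actually
exercised — with smaller seeded communities (6–8 genomes, 25–40 decoys)
for the faster unit checks, and the congruence experiment at 8 genomes
with bootstrap 100. These sizes are the package's validation design;
nothing in the implementation depends on them.

## Known limitations

* E-values live on the package's own calibrated scale, not BLAST's or
  HMMER's; thresholds carried over from tools with different statistics
  are interpretations, not reproductions (they are configuration, not
  constants).
* The back search of a reciprocal best hit is unthresholded (the forward
  filter alone decides); whether the original procedure also filtered the
  back direction is undocumented.
* The progressive aligner is adequate for the ≥ 50 %-identity subclusters
  it aligns, but it is not a general MSA tool.
* No multi-domain handling: one best local alignment (or one forward score)
  per sequence pair.
* Pathway assignment relies on panel composition; panels consisting only
  of the eight universal groups cannot discriminate pathways (hence the
  accessory genes in the default panel).
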