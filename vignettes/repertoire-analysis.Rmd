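---
title: "Mining and comparative analysis of bitter-taste receptor repertoires"
author: "bitteRep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and comparative analysis of bitter-taste receptor repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Bitter-taste receptors (TAS2Rs) are single-exon G-protein-coupled receptor
genes of roughly 900 bp. Their copy number varies enormously across mammals
— from zero intact genes in some marine mammals to more than fifty in
insectivorous shrews — and the working hypothesis is that dietary toxin
exposure drives this variation: lineages that eat plants or insects retain
and duplicate receptors, while lineages that swallow prey whole let them
decay into pseudogenes.

Testing that hypothesis from genome assemblies requires a long chain of
inference: mining candidate loci from contigs, deciding which candidates
are functional genes versus pseudogenes versus assembly-truncated
fragments, assigning genes to named ortholog clades, reconstructing when
clades were gained (duplication) and lost (pseudogenisation or deletion)
along a time-calibrated species tree, and finally testing the association
between repertoire size and diet while correcting for phylogenetic
relatedness. `bitteRep` implements that chain end to end, together with a
synthetic-genome generator that provides ground truth for every step.

## The annotation rule set

A merged homology locus becomes exactly one of three statuses, decided in
this order:

1. **Disrupted** — the locus, aligned to its clade's reference ORF with
   free end gaps, shows a lost start codon, an in-frame premature stop
   strictly before the reference's final codon, or an internal indel run
   whose length is not a multiple of three. Disruption evidence is checked
   first: a pseudogene with a shorter clean ORF is still a pseudogene.
2. **Complete** — no disruptions, and the longest ATG-to-stop open reading
   frame overlapping the locus is strictly longer than 750 bp and its
   translation shows exactly seven transmembrane segments.
3. **Partial** — no disruptions, no qualifying ORF, but the locus lies
   within 30 bp (inclusive) of a contig end: a possibly complete gene
   truncated by the assembly. Both boundaries follow the printed
   inequalities: `> 750` is strict, `<= 30` is inclusive.

Loci that fail all three rules (mid-contig, undisrupted, no complete ORF)
are not covered by the printed rules; they are recorded as disrupted with
an `unclassifiable` flag so that statuses remain a partition. Intact
genes are complete plus partial copies.

Two further guards mirror annotation practice. Hits shorter than 100 bp
are discarded before merging (strictly less than). Assemblies whose contig
N50 falls below 10 kb are flagged — fragmented assemblies inflate partial
counts — but never excluded.

### The transmembrane caller

External HMM-based TM predictors are replaced by a deterministic
Kyte-Doolittle sliding-window caller (window 19 residues, mean hydropathy
threshold 1.6, below-threshold runs shorter than 3 positions do not split
a segment). The synthetic receptor templates are constructed so that every
template shows exactly seven segments under this caller, which means the
seven-TM completeness requirement is exercised faithfully at the rule
level; for real data an external prediction can be substituted. Whether
"seven" should be exact or a minimum is configurable (`tm_required`);
exact is the default, matching the canonical receptor architecture.

## The homology search

A built-in seed-and-extend matcher keeps the pipeline self-contained:
exact `word_size`-mer seeding (default 11) on both strands, diagonal
clustering of seeds, and gapped local-alignment extension of each
candidate window (match +1, mismatch −2, gap open 5, extend 2). Hit
significance uses a Karlin-Altschul-style E-value analog
`E = K m n exp(−λS)` with fixed parameters (nucleotide λ = 1.28,
K = 0.46; translated search: BLOSUM62 with λ = 0.267, K = 0.041) rather
than empirically fitted ones; the cutoffs default to 1e-5 (nucleotide)
and 1e-10 (translated). Because the clade queries are mutually homologous,
a seeding heuristic extends, within one candidate region, only queries
whose seed count reaches half the best query's (`seed_ratio = 0.5`);
setting it to 0 restores exhaustive extension. Users who prefer an
external search can ingest 12-column tabular hits (`readHitsTable()`),
whose on-disk coordinates are 1-based inclusive with minus-strand hits
carrying `sstart > send`; internally everything is 0-based half-open on
the forward strand.

The reciprocal self-search step is implemented as *expansion*: merged-locus
subsequences are used as new queries against the same genome until the
merged locus set reaches a fixpoint. This is the conservative superset
reading of a self-BLAST step; a `confirm` mode (keep only seed hits
re-found from the genome's own loci) is also provided.

## Ortholog clades and gene trees

Pairwise p-distances (global alignment, gap and ambiguity columns removed
per pair) feed a Saitou-Nei neighbour-joining implementation with
documented determinism: Q-criterion ties break toward the
lexicographically lowest cluster pair, and negative branch lengths are
clamped to zero with the deficit moved to the sister branch. Pairwise
gap-free columns stand in for gap-site removal from a full multiple
alignment — a deliberate simplification; on additive matrices the NJ
reconstruction is exact, which the tests verify against both path-length
recomputation and `ape::nj`.

Genes join the clade of their nearest reference (free-end-gap p-distance,
so truncated genes are not penalised), with two abstention rules: a
distance ceiling (default 0.4) and a minimal margin to the second-best
clade (default 0.02). The margin rule is the package's proxy for declaring
a clade "not found". Within-genome duplications are visualised by exact
word-match self-dotplots with collinear runs chained into duplicated
blocks.

## Repertoire evolution

Each clade's intact copy number is reconstructed by linear-cost (Sankoff)
parsimony over integer states, under a Dollo constraint: a clade
originates once, at the most recent common ancestor of the species
carrying it, is absent above that node, and is never regained once lost.
Among co-optimal origin states the minimum is reported — the "at least"
reading of an ancestral repertoire. Per branch, gains are
`sum_clades max(0, child − parent)` and losses the mirror image; under
this bookkeeping the copies appearing at a clade's origin node fall on
the branch entering it. The root repertoire bound counts clades inferred
present at the root; a clade observed in a single species never reaches
the root under Dollo logic, so the bound is conservative. Exhaustive
enumeration over every bifurcating topology with up to six tips and every
presence pattern confirms both the Dollo loss counts and the Sankoff
totals.

## Comparative tests

Diet is coded for expected toxin exposure: herbivores and insectivores 1,
omnivores 0.5, carnivores 0, with three documented refinements — a
hyper-specialised scent-guided ant-feeder flag that forces 0, an
alternative scheme coding insectivores 0, and subset analyses that drop
herbivores, or insectivores, or insectivores plus tylopods. Foraging is
coded 0 for swallowing food whole and 1 for chewing. Codes are treated as
continuous when contrasted, following common practice in this literature.

Felsenstein's independent contrasts are computed by the standard
recursion; a bifurcating tree with `n` tips yields exactly `n − 1`
contrasts. Contrast signs are fixed by a deterministic child order (left
child = the one whose smallest descendant tip label sorts first).
Polytomies are rejected by default because the n−1 contrast count
presumes a bifurcating tree; `resolve_polytomies = TRUE` resolves them
with near-zero (1e-8 Myr) branches. Association is tested with Spearman's
rank correlation on mid-ranks, one-tailed (positive by default: more
toxins, more receptors; chewing, more receptors). P values are exact by
full permutation enumeration for eight or fewer contrasts and otherwise
use the t approximation `t = ρ sqrt((n−2)/(1−ρ²))`; the method used is
always labelled in the result. The through-origin regression slope of
count contrasts on code contrasts is reported alongside, because contrast
regressions have no intercept.

## The synthetic-data generator

The generator is the package's study system, not a fixture. A pure-birth
(Yule) tree rescaled to an 80 Myr crown age stands in for a
time-calibrated species phylogeny; the simplest ultrametric generator
suffices because only the timed tree matters downstream. Clade
repertoires start from 25 single-copy clades at the root (of 28 named
clade templates, mirroring the Boreoeutherian clade count) and evolve by
per-branch, per-clade Poisson events — duplication of an existing copy
(default 0.005 events per clade per Myr) and loss (default 0.007),
where a loss is a pseudogenisation or a whole-gene deletion with equal
probability. These defaults were chosen once to give tip repertoires
spanning roughly ten to thirty intact genes with occasional clade
extinctions on an eight-species, 80 Myr tree, the regime the annotation
rules must handle.

Genes are planted verbatim from clade templates into contigs (default
12 kb) with i.i.d. uniform flanking sequence: a configurable fraction of
intact copies (default 0.1) is truncated to 40–85% of its length and
placed within 30 bp of a contig end; pseudogenisation losses accumulated
on a tip's root path are planted as disrupted copies carrying one drawn
disruption (premature stop, frameshift indel of 1–2 bp, or a lost start
codon). All clade templates share one 300-residue seven-TM protein
scaffold and differ by independent synonymous codon choices, so
within-clade identity is 100% while between-clade nucleotide divergence
is substantial; the scaffold contains no internal methionine, so a lost
start cannot be rescued by a downstream in-frame ATG. An in-frame stop
codon is placed immediately upstream of every full-length planted ORF so
the reading frame cannot extend into random flank. Trait codes come from
tertiles of a latent trait: `coupling`·standardised(count) plus Brownian
noise whose root-to-tip standard deviation is `noise_sd`; `coupling = 0`
gives codes independent of counts given the tree, the null used for the
type-I experiments.

What the generator does *not* emulate: introns (the receptors are
single-exon, so none are needed), repeat families, GC isochores,
selection on sequences, and post-planting neutral divergence between
species (templates are planted verbatim by default). Passing the
round-trip tests therefore shows the rule set is implemented exactly, not
that the pipeline is robust to real assembly noise.

## Numerical choices and degenerate inputs

* All generators are bit-reproducible under a fixed seed; the pipeline
  fans one global seed out to per-stage seeds.
* E-value parameters are constants, not fits; scores below zero or
  E-values above the cutoff are dropped before any bookkeeping.
* The ORF floor for extraction is 300 bp (shorter ORFs are never
  reported); the complete-gene threshold of 750 bp measures the ORF, not
  the hit, since the rule's subject is the reading frame.
* The lost-start test is evaluated only when the template's start region
  (first 30 bp) is represented in the alignment; a locus truncated
  upstream of it is a contig-edge fragment, not a lost start.
* `mergeHits` unions intervals sharing at least one base pair; adjacent
  intervals stay separate. Opposite orientations never merge.
* Spearman P values are reported in (0, 1]; degenerate rank vectors
  (zero variance) return `NA` with a `degenerate` label rather than a
  fabricated value.
* An all-absent clade has no origin: its reconstruction is all-absent
  with zero losses.

## Problem sizes used by the test suite

The suite validates the pipeline at desk scale, chosen so each property
is exercised meaningfully: the classification round-trip uses eight
species with 25 root clades (roughly 200 planted genes); NJ exactness
uses 100 additive 8-taxon matrices; contrast equivalence uses 100
16-tip trees; the type-I experiment uses 1000 replicates on a 41-tip
tree; the parsimony oracle enumerates every rooted bifurcating topology
with up to six tips against brute force. The 41-tip tree matches the
scale of a full Laurasiatherian genome survey; reproducing empirical
repertoire numbers would require the real assemblies and a calibrated
phylogeny, which are deliberately outside the package's scope.

## A minimal run

```{r, eval = FALSE}
library(bitteRep)

cfg <- pipelineConfig(
  seed = 42L,
  paths = list(out_dir = "bitterep_out"),
  simulate = list(n_species = 5L, root_clades = 10L, n_clades = 12L))
report <- runPipeline(cfg)

report$counts                      # complete/partial/disrupted per species
report$reconstruct$root_bound      # clades inferred intact at the root
report$stats                       # diet/foraging association per scheme
```

Real assemblies enter through `simulate = list(enabled = FALSE)` plus
`paths$genomes_dir` (one FASTA per species), `paths$tree` (Newick, Myr)
and `paths$traits` (TSV with species, diet_category, foraging_behaviour);
`validateInputs()` checks label agreement, tree shape and the N50 guard
before anything runs.

## Known limitations

* The seeded search is a desk-scale matcher, not a tuned aligner: its
  E-values are analogs on fixed parameters and its seeding heuristic can
  miss homologies that share no exact word with any query.
* Clade assignment is nearest-reference by distance; it does not test
  monophyly per gene (the joint NJ tree and a per-clade monophyly report
  are emitted for inspection).
* The Dollo constraint forbids clade re-gain; a genuinely regained clade
  would be booked as an independent origin at its new MRCA.
* Contrasts assume Brownian motion of (possibly discretised) codes;
  the tertile discretisation in the generator slightly departs from that
  model, which is precisely why the type-I experiment checks the test's
  size empirically.
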