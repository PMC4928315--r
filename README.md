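# bitteRep

Mining and comparative evolution of bitter-taste receptor (TAS2R) gene
repertoires.

## What it does, and for whom

Bitter-taste receptors are single-exon, ~900 bp G-protein-coupled receptor
genes whose copy number varies dramatically across mammals, plausibly
tracking dietary toxin exposure: herbivores and insectivores keep and
duplicate receptors, while lineages that swallow prey whole (whales,
pinnipeds, pangolins) let them decay. `bitteRep` is for researchers who
want to run — or validate — the full inference chain behind that kind of
claim:

1. **Mine** candidate receptor loci from genome contigs with a built-in
   seed-and-extend homology search (E-value analog cutoff 1e-5 nucleotide
   / 1e-10 translated), discard hits under 100 bp, and merge overlapping
   same-orientation hits into loci.
2. **Classify** each locus as *complete* (ORF > 750 bp with start and stop
   codons and exactly 7 transmembrane segments), *partial* (undisrupted
   but within 30 bp of a contig end), or *disrupted* (lost start,
   premature stop, or frame-disrupting indel against a clade reference).
   Intact = complete + partial. A contig-N50 < 10 kb guard flags
   assemblies whose partial counts are untrustworthy.
3. **Assign clades** with nearest-reference p-distances and
   neighbour-joining gene trees (Saitou–Nei, exact on additive matrices);
   detect within-genome duplications with self-dotplots.
4. **Reconstruct** per-branch gains (duplication) and losses
   (pseudogenisation / deletion) of intact clades on a time-calibrated
   species tree by Sankoff parsimony under a Dollo single-origin
   constraint, including a conservative lower bound on the root
   repertoire.
5. **Test** diet and foraging associations with Felsenstein's
   phylogenetically independent contrasts (n species → n − 1 contrasts)
   and one-tailed Spearman rank correlation, exact by permutation for
   small n; the diet codes (herbivore/insectivore 1, omnivore 0.5,
   carnivore 0, with documented variants and subset analyses) follow the
   conventions of this literature.

A synthetic-genome generator plants intact, contig-edge-truncated and
pseudogenised receptor copies with a ground-truth ledger, so every rule
above is testable end to end without external data. See the methods
vignette (`vignettes/repertoire-analysis.Rmd`) for the model details and
design decisions.

## Worked example

```r
library(bitteRep)

cfg <- pipelineConfig(
  seed = 42L,
  paths = list(out_dir = file.path(tempdir(), "demo")),
  simulate = list(n_species = 5L, root_clades = 10L, n_clades = 12L),
  search = list(reciprocal_rounds = 0L))
report <- runPipeline(cfg)
```

The run logs its funnel per species and prints the stage summaries:

```
simulate: 5 species, 50 planted genes
search sp01: 13 hits -> 13 >= 100 bp -> 13 merged loci
...
classify: 37 complete, 5 partial, 8 disrupted
clades: 50 of 50 genes assigned
reconstruct: root repertoire bound = 6 clades
stats main_diet: rho = 0.000, one-tailed P = 0.5417 (n = 4 contrasts)
stats foraging: rho = -0.400, one-tailed P = 0.7917 (n = 4 contrasts)
```

```r
report$counts
#>   species n_complete n_partial n_disrupted n_intact
#> 1    sp01         11         1           1       12
#> 2    sp02          5         0           1        5
#> 3    sp03          7         1           2        8
#> 4    sp04          7         3           3       10
#> 5    sp05          7         0           1        7
```

Reading the output: the per-species rows are the classification tallies
(here they match the generator's truth ledger exactly — zero-noise
planting is the package's round-trip check); the root bound of 6 says six
clades survive on both sides of the root of this small simulated tree,
a lower bound on the ancestral repertoire; and with the default
`coupling = 0` the simulated diet codes are independent of repertoire
size given the tree, so the association tests are (correctly) null —
four contrasts from five species, ρ ≈ 0, one-tailed P ≫ 0.05. Raising
`simulate$coupling` makes the positive association appear.

Real data enter via `simulate = list(enabled = FALSE)` with
`paths$genomes_dir` (one FASTA per species), `paths$tree` (Newick,
branch lengths in Myr) and `paths$traits` (TSV: species, diet_category,
foraging_behaviour); run `validateInputs(cfg)` first. A thin CLI wrapper
lives at `inst/scripts/tas2r-pipeline.R` (`run` / `validate`
subcommands). External BLAST tabular hits can replace the built-in search
via `readHitsTable()`.

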