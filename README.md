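# orevo

Olfactory receptor (OR) gene repertoires evolve by birth-and-death:
duplication creates new receptor genes, pseudogenization and deletion
remove them, and repertoire sizes vary enormously across mammals — marine
lineages in particular have shed large parts of the repertoire their
terrestrial relatives retain. `orevo` is an R package for studying this
process end to end:

* **mine** intact OR genes, pseudogenes and truncated genes from genome
  assemblies (six-frame seeded translated search, ORF extension, the
  standard intactness filters: >= 250 aa, no transmembrane segment with an
  alignment gap > 5 aa, N-terminus of 21-34 aa before TM1, and the
  "< 30 bp from a contig end" truncation rule);
* **group** genes into orthologous gene groups (OGGs) with Markov
  clustering of a protein similarity graph, bootstrapped neighbor-joining
  trees on Poisson distances for leftover singletons, best-hit assignment
  of non-intact genes, and Class I/II labeling against anchor references;
* **reconstruct** ancestral OGG content on a dated species tree
  (Dollo presence + linear-cost copy-number parsimony) and count
  per-branch gene/OGG gains, contractions and losses;
* **estimate** per-branch gain and loss rates from the closed-form
  inversion of the growth model

  dg/dt = (A0 + g − l)·β,  dl/dt = (A0 + g − l)·δ

  which gives, with G = g(T), L = l(T) on a branch of T million years (MY),

  β = G/((G−L)·T) · ln(1 + (G−L)/A0),  δ = L/((G−L)·T) · ln(1 + (G−L)/A0),

  in genes per gene per MY (analytic limit β = G/(A0·T) at G = L);
* **compare** repertoires: exact Mann-Whitney tests, Pearson
  correlations, per-OGG similarity and size variability, and a
  Nei-Gojobori dN/dS proxy with its correlations to gains and losses.

A fully seeded synthetic-genome generator with complete ground truth
(planted intact/pseudo/truncated genes, decoy non-OR GPCRs, known
per-branch event counts) makes every stage testable without any external
downloads. See the methods vignette
(`vignettes/or-repertoire-evolution.Rmd`) for the model details, design
choices and known limitations.

## Worked example

Simulate a ground-truthed 4-species dataset, mine every genome, build
OGGs, and estimate per-species gain/loss rates:

```r
library(orevo)

tree <- dated_tree(ape::read.tree(text = "((A:40,B:40):30,(C:50,D:50):20);"))
cfg <- sim_config(tree = tree, ancestral_family_count = 20,
                  beta = 0.002, delta = 0.002, contig_count = 10,
                  contig_length = 15000, pseudogenization_fraction = 0.2,
                  truncation_fraction = 0.1, decoy_gpcr_count = 4, seed = 11)
ds <- simulate_dataset(cfg)

calls <- do.call(rbind, lapply(tree$phylo$tip.label, function(sp)
  mine_genome(ds$genomes[[sp]], ds$refset, ds$decoys, species = sp)$calls))
table(calls$species, calls$status)
#>     intact pseudogene truncated
#>   A     12          4         2
#>   B     15          4         2
#>   C     11          3         2
#>   D     16          4         2

cls <- classify_repertoire(calls, ds$refset, ds$decoys, replicates = 100)
cls$census
#> $n_multi      18
#> $n_singleton   0
#> $n_total      18
#> $n_intact_genes 54
#> $mean_multi_size 3

counts  <- ogg_count_matrix(cls$ogg_table, tree$phylo$tip.label)
content <- reconstruct_ancestral(counts, tree)
rates   <- estimate_rates(count_branch_events(content, tree))
rates[rates$terminal, c("branch", "A0", "G", "L", "T", "beta", "delta")]
#>   branch A0 G L  T    beta   delta
#> 2      A 18 0 6 40 0.00000 0.01014
#> 3      B 18 1 4 40 0.00152 0.00608
#> 5      C 16 0 5 50 0.00000 0.00749
#> 6      D 16 1 1 50 0.00125 0.00125
```

Reading the output: the miner recovered every planted gene with its true
status (the truth table is in `ds$truth`); all 54 intact genes fall into
18 multi-member OGGs (the other 2 of the 20 ancestral OGGs died out in
all four species); and the terminal-branch estimates show loss dominating
gain, with per-branch δ̂ of 0.001-0.010 losses per gene per MY derived
from the reconstructed ancestral content (18 genes at the A/B ancestor,
16 at C/D's).

The same stages run as one reproducible pipeline with a manifest of
checksums:

```r
run_pipeline(list(ancestral_family_count = 20, bootstrap = 100, seed = 1),
             out_dir = "run1")
```

or from the shell via the thin CLI at `inst/cli/orevo.R`
(`Rscript inst/cli/orevo.R run --config cfg.yaml --out-dir run1`, with
`simulate`, `mine`, `gainloss` and `stats` as standalone subcommands).

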