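---
title: "Methods: OR repertoire mining and gain/loss rate estimation"
author: "orevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OR repertoire mining and gain/loss rate estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Mammalian olfactory receptor (OR) genes are intronless G-protein-coupled
receptors of roughly 310 amino acids with seven transmembrane (TM) helices.
The family evolves by birth-and-death: duplications create new copies,
pseudogenization and deletion remove them, and repertoire sizes differ by an
order of magnitude between species. Comparing marine mammals with their
terrestrial relatives requires four coupled analyses, which `orevo`
implements end to end:

1. **Mining** intact OR genes, pseudogenes and truncated genes out of a
   genome assembly.
2. **Grouping** genes into orthologous gene groups (OGGs) — sets descending
   from one gene in the most recent common ancestor of the studied species —
   and assigning Class I/II labels.
3. **Reconstructing** ancestral OGG content on a dated species tree and
   counting per-branch gains and losses.
4. **Estimating** per-branch gain (beta) and loss (delta) rates, in genes
   per gene per million years (MY), plus comparative statistics.

Because the real input genomes are external downloads, a fully seeded
synthetic-genome generator with complete ground truth is a first-class part
of the package: every stage is validated against data whose true repertoire
history is known exactly.

# The gain/loss model and its inversion

On a branch of duration $T$ starting with $A_0$ genes, gains $g(t)$ and
losses $l(t)$ accumulate proportionally to the current gene count:

$$\frac{dg}{dt} = (A_0 + g - l)\,\beta, \qquad
  \frac{dl}{dt} = (A_0 + g - l)\,\delta .$$

With $G = g(T)$ and $L = l(T)$ the closed-form inversion is

$$\beta = \frac{G}{(G-L)\,T}\,\ln\!\Big(1 + \frac{G-L}{A_0}\Big), \qquad
  \delta = \frac{L}{(G-L)\,T}\,\ln\!\Big(1 + \frac{G-L}{A_0}\Big),$$

implemented in `estimate_rates()`. Numerical notes:

* The factor $\ln(1+x)/x$ with $x = (G-L)/A_0$ is computed with `log1p`,
  which is stable arbitrarily close to $x = 0$; at $x = 0$ exactly the
  analytic limit $\beta = G/(A_0 T)$, $\delta = L/(A_0 T)$ is used. The two
  branches agree to well below 1% for $A_0 \ge 100$ at $G - L = \pm 1$.
* $L = A_0 + G$ (complete loss) makes $\delta$ infinite; it is reported as
  `Inf` with a warning rather than an error. $L > A_0 + G$ is impossible
  under the model and raises an error.
* `ode_forward_oracle()` integrates the ODE pair numerically with
  `deSolve::ode` (lsoda, tolerances $10^{-12}$) and is deliberately kept
  independent of the closed form; the test suite checks that
  `estimate_rates(ode_forward_oracle(...))` returns the input rates to a
  relative error of $10^{-6}$ over $\beta,\delta \in [0, 0.05]$,
  $T \in [1, 100]$, $A_0 \in [10, 1000]$, including the $G = L$ path.

The simulator draws events per gene with exponential waiting times
(Gillespie), i.e. a linear birth-death process whose expectations are
exactly the ODE means, so the estimator's assumptions are literally true in
the synthetic data. With $\beta = \delta$ the expected gains on a branch
reduce to $A_0\beta T$; the suite checks the simulated mean against this
value at $A_0 = 830$, $\beta = \delta = 0.003$, $T = 100$ (the value 249)
within three standard errors over 1000 replicates.

# Ancestral content reconstruction

The source analyses report per-branch OGG expansions, contractions and
losses without stating a reconstruction method, so the method here is a
package design choice, made for determinism and additive bookkeeping:

* **Presence** follows Dollo parsimony: an OGG arises once, at the MRCA of
  the tips that carry it, and can only be lost afterwards. A node carries
  the OGG iff it lies in the minimal subtree connecting the carrying tips.
* **Copy numbers** on carrying nodes follow linear-cost parsimony (unit
  cost per gene copy) by the interval method on the binary species tree.
  Ties are resolved deterministically: top-down, each node takes the value
  in its optimal interval closest to its parent; the root takes the
  smallest optimal value, so expansions are dated as late as the data
  allow.

`count_branch_events()` then reports, per branch, gene-level
$G = \sum_{\mathrm{OGG}} \max(0, c_{\mathrm{child}} - c_{\mathrm{parent}})$
and $L$ analogously, and OGG-level gains, contractions (shrank but
survived) and losses (went to zero). The additive identity
$A_0 + G - L = \text{end count}$ holds exactly on every branch.

**Bias.** Parsimony sees only net changes: when $\beta = \delta$ many gain
and loss events cancel inside a branch and both rates are underestimated
(by roughly 40% in the regime $A_0 = 830$, $\beta = \delta = 0.003$ on the
23-tip tree — measured, not assumed). The estimator itself is nearly
unbiased when applied to true event counts (the suite checks < 20% relative
bias, and observes a few percent). Group *contrasts* are robust: with
marine-like loss ($\delta = 0.017$) on the 11 marine terminal branches, the
reconstructed group ordering $\hat\delta_{marine} > \hat\delta_{terr}$ and
the Mann-Whitney significance of the per-species contrast are recovered in
essentially every replicate. Rates are computed on terminal branches for
per-species comparisons; internal branches are reported but excluded from
group means.

Gene-copy counts are the default unit for $G$, $L$ and $A_0$ (rates of
gene gain per gene per MY); `estimate_rates(unit = "oggs")` switches to
whole-OGG turnover.

# Mining: filters and their boundaries

`mine_genome()` implements the standard OR-mining cascade with every
threshold exposed as a parameter defaulting to the field-standard value:

| parameter | default | meaning |
|---|---|---|
| `identity_ceiling` | 0.5 | query dereplication: retained queries share < 50% identity |
| `evalue1` / `evalue2` | 1e-10 / 1e-20 | first/second-pass E-value cutoffs |
| `min_aa` | 250 | minimum intact protein length (inclusive) |
| `tm_gap_max` | 5 | maximum alignment gap inside a TM segment (inclusive) |
| `nterm_min`, `nterm_max` | 21, 34 | allowed N-terminus length before TM1 (inclusive) |
| `trunc_dist` | 30 | contig-end distance for truncated genes (exclusive, "< 30 bp") |

The translated search is an internal six-frame translation with exact
amino-acid 5-mer seeding and local Smith-Waterman (BLOSUM62, gap open 11,
extend 1); raw scores become bit scores and E-values through the standard
gapped Karlin-Altschul constants ($\lambda = 0.267$, $K = 0.041$). Two
seeds within 150 aa are required before a window is aligned, which keeps
random matches out while guaranteeing hits for homologs at the divergence
levels of interest (a 100-aa region at 60% identity carries ~20 exact
5-mers in expectation). No external aligner or BLAST binary is needed;
the engine is deterministic and strand-symmetric (mining a genome and its
reverse complement yields mirrored calls, which is tested).

Design choices worth knowing:

* **Hit collapsing**: overlapping hits (>= 1 bp, same strand) collapse to
  the single highest-scoring one; ties break by lower start coordinate,
  then query id.
* **ORF extension** walks in frame from the hit: upstream to the first
  in-frame stop (collecting ATG options), downstream to the first stop.
  Extension never crosses an upstream in-frame stop.
* **TM transfer** aligns the candidate to its closest reference (shared
  5-mer count) with the reference global and the candidate local, then maps
  the annotated TM intervals through the alignment — a deterministic
  pairwise stand-in for a full multiple alignment, which is equivalent for
  segment transfer.
* **Start choice**: among in-frame ATGs the one giving the longest
  N-terminus within [21, 34] wins.
* **Second pass** uses the species' own intact genes *plus* the
  dereplicated references as queries. At real-data scale the intact set
  spans nearly all OGGs and the references are redundant; at desk scale a
  species may have lost an OGG entirely, and pseudogenes of that OGG would
  otherwise be invisible.
* **Disruption calls**: internal stops are detected inside the matched
  region (a stop bounding the region is a normal ORF end); frameshifts are
  detected structurally, by adjacent same-strand regions in different
  frames with complementary query coverage (< 50% overlap, < 60 bp apart),
  which are merged into one pseudogene call.
* **Truncation distance** is measured from the matched region's boundary
  to the contig end (either end, strand-aware), mirroring how a BLAST-style
  match against a cut-off gene would be measured. Truncated calls may also
  carry the pseudogene flag; the flags are recorded separately.
* **OR identity** is confirmed on a neighbor-joining tree (Poisson
  distances) over candidates, OR references and non-OR GPCR outgroups; a
  candidate whose nearest patristic neighbor is an outgroup is removed.
  With fewer than four sequences the decision falls back to plain
  nearest-neighbor identity (logged).

# OGG construction

Intact proteins are clustered with Markov clustering (MCL, implemented in
the package: expansion/inflation iteration on the column-stochastic
similarity matrix) over a graph whose edge weights are BLOSUM62 alignment
scores normalized by the geometric mean of self-scores; edges below
`sim_threshold = 0.4` are dropped and the inflation default is 1.5. Both
are configuration keys: the upstream tools' parameters are not published,
so these defaults were chosen once to separate the within-OGG (~0.6-0.8)
from the between-OGG (~0.1-0.25) similarity regimes of OR families and are
not tuned per dataset. Clustering is order-invariant (tested by permuting
the input).

Singletons left over by MCL are re-examined on a bootstrapped NJ tree
(Poisson distances, column resampling, seeded RNG) rooted with the non-OR
GPCR outgroups; every maximal all-singleton clade with bootstrap support
strictly greater than 70 becomes a new OGG. Singletons are never merged
into pre-existing MCL clusters. Non-intact genes join the OGG of their
single best-scoring intact gene (5-mer prescreen, local alignment; ties by
identity then gene id; no hit above the score floor leaves the gene
unassigned and reported).

Class I/II labels come from anchored tree placement: an NJ tree over genes
plus labeled anchor references is built and each gene takes the class of
its patristically nearest anchor (ties favor Class I, the basal class).
This is a deterministic operationalization of "joining the anchor clade";
a bootstrap-supported clade criterion (the `class_support = 90`
configuration key) is reserved but not used by the default method.

OGGs are named `OGG1-k` / `OGG2-k` (Class I/II) by decreasing intact-member
count, ties broken by higher mean pairwise identity then smallest member
id. ASCII hyphens are used in names.

# Comparative statistics

* `mann_whitney()` computes the exact two-sided permutation p by full
  enumeration of group assignments for combined $n \le 20$ (midranks
  handle ties) and the tie-corrected, continuity-corrected normal
  approximation above that. The exact path is verified against a
  brute-force enumeration oracle.
* `pearson()` is the product-moment coefficient with the t-transform p
  value, checked against closed forms.
* `pairwise_omega()` estimates dN/dS with Nei-Gojobori (1986) counting:
  per-codon synonymous site fractions (mutations to stops excluded),
  pathway-averaged difference counts (stop-crossing pathways dropped when
  avoidable), Jukes-Cantor correction of the proportions, and the median
  over member pairs (median rather than mean damps dS ≈ 0 instability;
  pairs with dS = 0 are excluded and OGGs need >= 3 sequences). This is a
  counting proxy for codon-model maximum likelihood: absolute values are
  not comparable to ML estimates, but rank-level correlations — which is
  how omega is used here — are. Under neutral simulation the per-OGG
  median omega lands near 1 (checked within [0.8, 1.25] over 100 OGGs).

# What the synthetic generator emulates — and what it does not

`sim_config()` defaults encode the study conditions: a 23-tip dated tree
(11 marine tips in three independent aquatic lineages, 11 terrestrial
relatives, one outgroup; round divergence-time-like ages, root 160 MY),
830 ancestral OGGs of one gene each, baseline $\beta = \delta = 0.003$ per
gene per MY with marine-like overrides ($\beta = 4\times10^{-4}$,
$\delta = 0.017$) available via `marine_rate_overrides()`. Genome emission
plants each surviving gene as an intronless ORF on a random contig and
strand with Jukes-Cantor-style substitutions (rate $5\times10^{-4}$ per
site per MY along the species' root-to-tip path, no indels in intact
genes), converts configured fractions into pseudogenes (internal stop or
1-2 bp frameshift, redrawn until no reading frame retains an intact-length
ORF) and truncated genes (disruption-free ORF cut by a contig end, ending
within 30 bp of the boundary), and plants decoy non-OR GPCRs. Flanks are
random DNA at the configured GC (0.42). Coordinates are 0-based half-open
internally and 1-based inclusive in every written table. Identical
configurations (including the seed) produce byte-identical FASTA and truth
tables; the master seed fans out to per-stage, per-species sub-seeds.

Deliberate simplifications, and their consequences for what passing tests
mean:

* Protein prototypes are template-generated (34-aa N-terminus, seven 21-aa
  hydrophobic TM segments, 18-aa loops, 309 aa total) rather than real OR
  sequences; TM segmentation is meaningful but binding-site structure is
  not represented.
* The mutation model has no indels in intact genes, no rate heterogeneity
  and no GC-biased substitution; within-OGG divergence is therefore
  homogeneous. In particular, mean within-OGG similarity does *not*
  decrease with OGG size under the default generator (all members are
  equidistant from the prototype), so the similarity-size trend seen in
  real repertoires is tested on a constructed regime in which divergence
  scales with family size, not on generator output.
* Genomes contain no repeats, no introns, no isochores and no assembly
  gaps; miner sensitivity/precision of 0.95+ on these clean genomes bounds
  performance from above relative to real assemblies.
* Pseudogenization during genome emission is applied on top of the
  birth-death history (it emulates the observational status of surviving
  genes, not additional loss events), so rates estimated from *mined*
  repertoires include this extra apparent loss; rate-recovery claims are
  therefore made on the simulation's content matrices, where the model is
  exact.

# Problem sizes used by the tests and the acceptance script

Module tests run on a 4-species fixture (20 ancestral OGGs, ~15 kb
contigs). The rate-recovery checks use the full 23-tip tree with
$A_0 = 830$ and 20 replicates; the single-branch expectation check uses
1000 replicates. Miner fidelity runs on four genomes with 52 ancestral
OGGs (about 210 planted genes across statuses, ~3.5% per-lineage
nucleotide divergence). `scripts/acceptance.R` repeats these computations
from scratch at the same sizes (10 recovery replicates) and writes the
resulting quantities as JSON. Bootstrap replicates default to 1000 in the
configuration and are set to 30-100 in tests.

# Known limitations

* Ancestral copy-number reconstruction is parsimony, not probabilistic;
  absolute rate estimates from reconstructed content are conservative
  (biased toward zero), and only contrasts should be interpreted.
* The internal search engine approximates BLAST statistics; E-values are
  comparable in order of magnitude, not digit-for-digit.
* `pairwise_omega` is a counting estimator; use it for ranks, not for
  absolute selection strength.
* Multifurcating species trees are not supported by the reconstruction
  (binary trees only).
* Singleton placement never merges a singleton into an existing
  multi-member OGG, even when the tree nests it inside that OGG's clade.
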