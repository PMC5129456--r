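---
title: "Divergence and migration inference from blockwise site frequency spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence and migration inference from blockwise site frequency spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divmig)
```

## The inference problem

Two taxa with large genomes and no reference assembly can still be
compared genome-wide through their transcriptomes: one sequenced diploid
individual per taxon yields, after careful orthology filtering, a few
thousand loci on which within- and between-taxon variation can be typed.
`divmig` implements the full chain from such data to a fitted model of
population divergence:

1. reduce per-taxon de novo assemblies and a cross-taxon peptide
   clustering to a set of *robust orthogroups* (module `orthofilter`);
2. type variation at *fourfold degenerate sites* of codon alignments and
   cut it into blocks of 150 consecutive such sites (module
   `haploblocks`);
3. fit two-population divergence models by maximum likelihood on either
   the folded joint site frequency spectrum (SFS) or the *blockwise* SFS
   (bSFS), compare models, bootstrap, and convert the scaled estimates
   to absolute quantities (modules `coalcore`, `infer`).

A coalescent simulator with exactly the same model dynamics serves both
as a Monte-Carlo oracle for the analytic likelihood machinery and as the
engine of a synthetic-data generator, so every stage of the pipeline is
testable without any external data.

## Data model

For one unphased diploid genome per taxon there are four folded variable
site types: heterozygous only in taxon A ($k_A$), only in B ($k_B$), in
both ($k_{AB}$), and alternate homozygotes ($k_{AABB}$).  A *block* is a
run of 150 consecutive fourfold degenerate sites from one orthogroup,
summarised by its count vector $k = (k_A, k_B, k_{AB}, k_{AABB})$.
Because phase is unknown, the classification is invariant to swapping the
two haplotypes within a taxon and to relabeling alleles; the package
asserts this folding property in its tests.

Blocks carrying both shared-heterozygous sites and fixed differences are
flagged: that combination is the one two-site incompatibility detectable
without phase (no single genealogy of the four haplotypes has both a
branch ancestral to one lineage from each taxon and a branch ancestral to
both lineages of one taxon).  Such blocks indicate recombination within
the block and are excluded from the blockwise likelihood, which assumes a
single non-recombining genealogy per block.

## The demographic models

All models descend from an ancestral population of effective size
$N_{anc}$ that splits into populations A and B at time $T$ (units of
$2N_{anc}$ generations).  Mutation is parameterised by
$\theta = 4 N_{anc} \mu$ per site.

* **Div** — strict divergence, equal sizes;
* **IM** — unidirectional migration at rate $M = 4 N_{anc} m$ after the
  split (both directions are always evaluated);
* **Div2** — no migration, but one descendant's size is
  `size_factor` $\times N_{anc}$ (both target populations evaluated);
* **IM2** — both migration and a one-sided size change.

Migration convention: $M$ counts effective migrants per generation moving
from the donor to the recipient population in forward time.  Backward in
time, each lineage currently in the recipient population jumps to the
donor at rate $M/2$ per $2N_{anc}$ generations.  Within a population of
relative size $f$, each lineage pair coalesces at rate $1/f$.  $\theta$
always refers to the *ancestral* population; descendant sizes are
expressed relative to it, with the non-target descendant fixed at
$N_{anc}$.

## Exact likelihood machinery

The sampled lineages (two from each taxon) evolve backward in time as a
finite-state structured-coalescent Markov chain; states record, for each
surviving lineage, how many a- and b-labels it is ancestral to and which
population it currently occupies (lumped over the exchangeable within-
taxon relabelings).  Each lineage is a branch whose folded mutation class
follows from the labels it subtends.

**Expected branch lengths.** $E[t_c]$, the expected total branch length
per class, is computed exactly: over $[0, T)$ by a single matrix
exponential of the generator augmented with per-class reward columns,
and after $T$ by a linear solve on the panmictic chain
(`expected_branch_lengths()`).  Per-site class frequencies follow as
$E[k_c] = (\theta/2)\,E[t_c]$ with the invariant complement
$1 - \sum_c E[k_c]$ (a small-$\theta$ linearisation; the constructor
refuses parameter values for which the linearisation breaks down).

**Blockwise pattern probabilities.** $p(k)$ is the probability that a
block of $n$ sites carries exactly $k$ mutations of each class, with
per-branch intensity $\lambda = n\theta/2$.  The chain is augmented with
a per-class mutation counter truncated to the *down-set* of the queried
count vectors (counts only grow, so mass leaving that set can never
return and is simply dropped — the returned probabilities are exact, not
truncated approximations).  The pre-split phase is integrated by
uniformization of the augmented chain (assembled once per evaluation as
a sparse matrix; Poisson series truncated at relative tolerance
$10^{-12}$, $10^{-10}$ inside the optimiser); the ancestral phase is
resolved by level-wise linear solves of the absorbing panmictic chain;
the two phases are joined by a convolution over the split-time state.
The panmictic limit has the closed form
$p(0) = \frac{6}{6+4\lambda}\frac{3}{3+3\lambda}\frac{1}{1+2\lambda}$,
which the implementation reproduces to $10^{-10}$ and the test suite
pins.

**Simulator.** `simulate_blocks()` draws genealogies by Gillespie
simulation of the same lineage process and overlays Poisson mutation
counts; it is exact in distribution and shares nothing with the
analytic code path beyond the state-space definition, so agreement
between the two (asserted at 3 Monte-Carlo standard errors on grids of
frequent patterns) is a genuine cross-validation.

## Fitting, model comparison, uncertainty

`fit_divergence()` maximises either the 5-category multinomial SFS
likelihood (classes plus invariant complement, over all sites) or the
bSFS likelihood $\sum_{blocks} \ln p(k)$ (cached over distinct $k$).
Parameters are optimised on log scale ($\theta$, $T$, size factor) with
$M$ on its natural scale so the $M = 0$ boundary is reachable, under
bounds $\theta \in [10^{-5}, 0.05]$, $T \in [0.01, 100]$,
$M \in [0, 2]$, factor $\in [0.05, 20]$ — generous brackets around any
plausible estimate; a fit on a bound is a warning sign, not an answer.
Each variant gets a moment-based start, the optima of its nested
submodels (so nested-likelihood orderings hold up to optimiser
tolerance), and random log-uniform starts up to `n_starts`.  IM-type
fits whose $\hat M$ collapses below $10^{-4}$ are flagged as boundary
collapses onto their strict-divergence counterpart rather than reported
as distinct optima.  `IM2` is refused in SFS mode: four frequencies
cannot identify four parameters plus a direction, and the near-absence
of shared heterozygous sites restricts SFS fits to three-parameter
models.

The SFS point estimates use all-site category counts; the
one-variable-site-per-block scheme — which keeps exactly one variable
site per block and is therefore robust to within-block recombination and
rate heterogeneity — is used for the bootstrap (`bootstrap_sfs()`):
each replicate redraws one site per block, refits, and the spread of the
estimates gives $\pm 1.96\,\mathrm{SD}$ intervals.  This split follows
from identifiability: $\theta$ needs the invariant category, which the
one-site scheme distorts, while the resampling scheme needs exactly the
per-block draw.

`excess_block_test()` asks whether blocks *lacking* chosen classes are
over-represented: the model probability of such a block is an exact
Laplace-transform evaluation (`pattern_probability_marginal()`), and the
observed count is referred to the upper tail of the exact binomial.  The
test is one-sided because the scientific question — has introgression or
a selective sweep produced an excess of undifferentiated blocks — is
one-sided.

`to_absolute()` converts with $N_{anc} = \theta/(4\mu)$,
$t = T \cdot 2N_{anc} \cdot g$, waiting time $g/M$ between effective
immigrants, and introgressed fraction $1 - e^{-MT}$; the defaults
$\mu = 9.15 \times 10^{-9}$ and $g = 3$ years suit fourfold degenerate
sites in archaeobatrachian frogs and are plain arguments.

## Orthology filtering

The filter aims at a *robust ortholog set*, accepting false-positive
paralog calls as the price of a clean retained set:

* Within an assembly component, the representative is the contig with
  the longest ORF (ties: longer contig, then smallest id — determinism
  matters for reproducibility).
* `classify_pair()` computes a sliding-window identity profile over the
  both-ungapped columns of a contig-pair alignment (window 100, step 1,
  within-window cutoff 0.85 by default).  Low-identity tracts touching
  an alignment terminus (within 50 columns) are excluded as structural
  variation; an *internal* tract of 60+ columns marks sub-gene paralogy
  (alternate use of duplicated exons) regardless of the mean; otherwise
  a mean identity below 0.98 marks a paralog.  The window parameters are
  package defaults chosen at exon scale and are all configurable; the
  0.98 global threshold is the load-bearing rule.
* Cluster filtering annotates *every* violated criterion (a known
  paralog pair, a missing required taxon, more than three backbone
  contigs) so per-criterion tallies are meaningful, then keeps only
  clusters whose non-backbone membership is reproduced exactly at every
  other inflation value of the clustering.  Backbone contigs are ignored
  in that comparison because outgroup attachment is the most volatile
  part of graph clustering; exact non-backbone identity is deliberately
  the strictest reading of robustness.

## The synthetic generator

`synthetic_scenario()` defaults describe the study conditions the
package targets: 1,479 blocks of 150 fourfold sites, an IM2 model with
$\theta = 0.00154$, $T = 19.8$, $M = 0.015$ into A and size factor 1.36
on A, coding sequences of ~520 codons with 35% of codons from fourfold
families (~180 fourfold sites, comfortably above one block).
`simulate_fixture()` writes FASTA/VCF/cluster files with planted
paralogs (global and sub-gene), an isoform, spurious indel and
alternate-homozygote VCF records, a backbone-excess cluster and an
inflation-unstable cluster — each recorded in truth tables so the
pipeline's recovery can be asserted *exactly*, not statistically.

What the generator does **not** emulate: read-level error,
allele-specific expression, within-block recombination, mutation-rate
heterogeneity across blocks, linkage between blocks, and indel
polymorphism beyond the planted spurious records.  Passing round-trip
tests therefore validate the bookkeeping and the coalescent machinery,
not robustness to those real-data complications; the SFS/bSFS agreement
checks are the tool the package offers for judging the latter on real
data.

## Numerical choices and problem sizes

* Matrix exponentials: `Matrix::expm` (scaling-and-squaring) on the
  reward-augmented generator (state spaces: 4–17 pre-split states).
* Uniformization: Poisson weights in log space; series cut when the
  cumulative weight reaches $1 - 10^{-12}$ (likelihood optimisation:
  $10^{-10}$, with the final comparison re-evaluated tightly).
* Multiallelic or ambiguous fourfold columns keep their position inside
  the 150-site block span but contribute to no class; the infinite-sites
  model has no category for them, and dropping the column entirely would
  shift block boundaries.
* Optimiser: `optim(L-BFGS-B)` with a Nelder-Mead fallback, convergence
  tolerance below $10^{-8}$ in log-likelihood.
* Test problem sizes were chosen to exercise the asymptotics the claims
  rely on while staying comfortably runnable: $10^5$ simulated blocks
  per model for oracle equivalence, 20 replicates of 1,479 blocks for
  parameter recovery (median relative error of $\hat\theta$, $\hat T$
  within 15%), 8-orthogroup sequence fixtures for the pipeline
  round-trip.

## Known limitations

* Migration is unidirectional within a variant; bidirectional gene flow
  is represented only by comparing the two directions' fits.
* One diploid per taxon: no within-population frequency information.
* The per-site SFS probabilities linearise in $\theta$; for
  $\sum_c E[k_c] \ge 1$ the model is rejected rather than approximated.
* A divergence-time estimate at the upper optimisation bound (e.g. for
  very deep splits fitted with migration) should be read as "unbounded
  under this model", and the fit object leaves it visible rather than
  masking it.
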