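---
title: "Tracing complex origins through duplications and intron positions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing complex origins through duplications and intron positions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceotrace)
```

## The problem

Large eukaryotic molecular machines such as the spliceosome assembled during
eukaryogenesis, between the first eukaryotic common ancestor's prokaryotic
forebears and the last eukaryotic common ancestor (LECA). Two record types
carry signal about that assembly process: the topology of gene trees, which
records the duplications that multiplied a complex's components, and the
positions of spliceosomal introns within genes, which record *when* introns
had already spread relative to those duplications. An intron position shared
between two paralogs at the same alignment column and codon phase is most
parsimoniously a single insertion that predated their duplication.

`spliceotrace` implements the inference machinery for this style of
analysis as reusable, tested components: intron-position homology detection
across paralogs, ancestral intron reconstruction (Dollo parsimony and a
two-state Markov model), duplication-origin classification, collapsing of
within-complex duplications into ancestral units, recurrent-loss counting on
a species tree, and recurrent-fate (subfunctionalization) detection after
independent duplications. A synthetic gene-family generator with known truth
underpins every validation; the package makes no claim about real proteomes,
which require upstream homology searching, alignment and tree inference that
are deliberately out of scope.

## Intron positions in protein coordinates

A gene model's coding exons determine its intron positions on the mRNA.
With $n$ the number of coding nucleotides 5′ of an exon–exon junction, the
intron has

$$\text{residue} = \lfloor n/3 \rfloor + 1, \qquad \text{phase} = n \bmod 3 .$$

Phase-0 introns (between codons) are anchored to the *following* residue;
this is a convention, stated once and used everywhere, so that fixtures,
mapping and back-projection agree. Minus-strand genes are read 3′→5′ in
genomic coordinates so that counting is always along the mRNA. Terminal
introns are impossible by construction ($0 < n < 3L$).

Two introns are *homologous* when they project to the same alignment column
with the same phase. The criterion is exact identity — no near-position
window. A slack window would trade false homology for sensitivity; at the
scale this package targets (curated families, simulated truth), exactness
keeps every downstream count interpretable, and near-position matching is a
declared non-goal. Projection uses the untrimmed alignment: gap-rich-column
trimming (`trim_alignment()`, threshold 0.5 by default, columns *exceeding*
the threshold removed) is for tree-inference input only, and the returned
column map re-expresses trimmed coordinates in original columns.

## Ancestral intron reconstruction

**Dollo parsimony.** An intron position arises once and may be lost any
number of times. The gain node of a site is therefore the most recent common
ancestor of the tips that carry it; internal nodes carry the site exactly on
the paths from the gain node to present tips, which minimizes losses under
the single-gain constraint. `dollo_reconstruct()` is checked against an
exhaustive enumeration over all single-gain internal-state assignments on
random trees.

**Two-state Markov model.** `markov_posterior()` models presence/absence as
a continuous-time chain with gain rate $\lambda$ (per site) and loss rate
$\mu$ (per intron), both per unit branch length:

$$P_{01}(t) = \frac{\lambda}{\lambda+\mu}\left(1 - e^{-(\lambda+\mu)t}\right),
\qquad
P_{10}(t) = \frac{\mu}{\lambda+\mu}\left(1 - e^{-(\lambda+\mu)t}\right).$$

Posteriors come from Felsenstein pruning (tip-to-root) followed by a
root-to-tip pass; a node is called present at posterior ≥ 0.5 (symmetric
default, configurable). Rates are *inputs*, as in the workflow this package
supports; estimating them by maximum likelihood is a non-goal.

Design choices worth recording:

* **Root prior.** The default is the stationary distribution
  $(\mu, \lambda)/(\lambda+\mu)$. When either rate is zero the stationary
  distribution is degenerate and would zero out data-compatible histories,
  so the implementation falls back to a uniform $(1/2, 1/2)$ prior; with
  gains impossible, a present tip then correctly forces presence back to the
  root, and $\lambda = \mu = 0$ with conflicting tips raises a
  zero-likelihood error rather than returning numbers.
* **Dollo limit.** As $\mu \to 0$ with loss-free data the *likelihood*
  concentrates on the Dollo states, but the stationary prior simultaneously
  degenerates towards all-present; the convergence to Dollo therefore holds
  under a fixed root prior, which is how the property is tested.
* **Preduplication sites.** A site is preduplication for duplication node
  $d$ when its Dollo gain node is $d$ or an ancestor of $d$. This is
  deliberately phrased through gain ancestry rather than "present in both
  child clades" so that sites shared only with the duplication's outgroup
  are counted correctly.
* **Rounding.** Reported percentages round halves up to the nearest integer
  (`45%` from 13/29, `46%` from 18/39 in the worked examples); the expansion
  factor is reported to one decimal.

## Duplication classification and ancestral units

On a rooted homolog tree whose tips are labelled orthogroups, the parent
node of a complex-member orthogroup is classified five ways: sister clade
entirely prokaryotic → *acquisition*; sister entirely complex-member →
*within*; no homolog outside the orthogroup → *invention*; otherwise the
preduplication ancestor's function is reconstructed by small parsimony
(Sankoff with unit costs, most-parsimonious-reconstruction sets at the
parent) and the class is *from* when that ancestor is unambiguously a
complex member, *to* when it is unambiguously not. A parsimony tie is
reported as *ambiguous* rather than forced — in the source workflow such
cases were resolved by hand, and silently picking a side would fabricate
certainty.

Maximal clades whose internal nodes are all within-complex duplications
collapse into one *ancestral unit*; `expansion_factor()` is the ratio of
orthogroup count to unit count. Recurrent losses of a trait (a domain, a
whole subcomplex) on a species tree are counted by Dollo with presence
assumed at the root: each maximal all-absent clade is one loss event.

`select_slow_representatives()` implements shortest-branch representative
selection per orthogroup per clade. The "deviating long branch" exclusion is
made explicit as: longer than `outlier_factor` (default 5) times the median
terminal branch length of the clade's tips across the tree — a clade-wide
norm, so a lone, fast-evolving representative of a clade is excluded rather
than trivially accepted. The bidirectional-best-hit mode selects the
mutually nearest Opimoda/Diphoda pair by patristic distance.

## Recurrent fates after independent duplications

Independent duplications of one gene in many lineages can repeatedly resolve
the same way (the U1A/U2Bʺ pattern: recurrent substitutions in one domain of
one fate, recurrent loss of another domain in the other). The published
upstream pipeline for this analysis is not fully specified by its
description, so the package defines its own operationalization as the
contract:

* A duplication is detected when the species sets of a node's two children
  intersect (`find_duplications()`).
* For a fate assignment (one binary side choice per duplication; the global
  fate1/fate2 flip is removed), a column supports the assignment when at
  least `min_events` duplications have both sides non-gap with differing
  residues, all fate-1 sides share one residue and all fate-2 sides share a
  different one. The default `min_events` is *every duplication with data at
  the column* (minimum 2) — the strictest recurrence reading. A side's
  residue is defined only when all its non-gap tips agree; a gapped paralog
  contributes no evidence at that column, neither for nor against.
* The recurrence score of an assignment is its number of supporting
  columns; `fate_partition()` maximizes it exhaustively up to 12
  duplications. Beyond that, assignments implied by each candidate
  two-state column seed a greedy single-flip refinement. The seeding matters:
  under the all-or-nothing column criterion an unseeded hill climb starts on
  a flat score surface and cannot move, whereas each genuinely recurrent
  column proposes essentially the correct assignment directly.
* Identical residue means identical character; conservative-substitution
  grouping is off by default.

Domain losses per fate are Dollo loss counts on the gene tree pruned to the
fate's tips, with partial domain presence counted as presence.

## The synthetic generator: what it emulates, what it does not

`simulate_family()` emulates the study design the inference targets: a
two-supergroup species layout (defaults: 3 Opimoda, 3 Diphoda, 2 Discoba,
2 Metamonada), 0–4 serial stem duplications that each spawn a full paralog
copy of the species tree (so every duplication predates all speciations),
uniform branch lengths on (0.05, 0.3) substitutions/site, and intron
evolution with gains as a Poisson process of rate $\lambda L$ per unit
branch length spread uniformly over the $3L-1$ intra-CDS positions
(jointly encoding residue and phase; a position never gains twice) and
exponential per-branch survival $e^{-\mu t}$ per intron. The paper trail
for the real data does not print its gain/loss rates, so the generator's
defaults are free parameters chosen once as plausible for intron-rich
deep-eukaryote families — $\lambda = 0.05$ gains/residue/unit length,
$\mu = 0.2$ losses/intron/unit length, protein length 200 — and surfaced in
`sim_config()`, never hard-coded downstream. The root carries 10 intron
sites by default (`root_introns`): genes in this scenario were typically
intron-bearing before their duplications, and a root with introns is what
makes preduplication sites traceable through every stem duplication.

Sequences evolve under a uniform-exchangeability stationary process (per
site, substitution probability $1-e^{-t}$, new residue uniform over the
other 19). This is deliberately not a realistic substitution matrix: the
fate analysis needs controllable per-column signals, which the generator
injects explicitly (fixed residues per fate at chosen columns, deletion of
a domain block in one fate). Consequently passing tests demonstrate the
*inference machinery* is correct on data satisfying its assumptions; they
do not demonstrate robustness to alignment error, indels, rate
heterogeneity, compositional bias or intron sliding, none of which the
generator produces.

`simulate_fate_family()` builds the independent-duplication scenario (a
ladder species tree whose last $k$ species each duplicated the gene), and
`simulate_loss_survey()` plants pairwise-disjoint lost clades on a random
species tree with an explicit no-tiling rejection check, so the planted
event count is the ground-truth minimal loss count by construction —
independent of the counting code it validates. Both validate their planting
constraints (for example, the two innermost duplications may not both lose
the domain, which would merge two planted events into one clade).

All generator functions require a seed; identical configuration and seed
give byte-identical emitted fixtures.

## Numerical and degenerate-input choices

* Branch lengths absent from a Newick file default to 0; `gl_transition`
  returns the identity at $t = 0$ or $\lambda + \mu = 0$.
* A site present in no tip cannot enter an intron matrix and is rejected by
  `dollo_reconstruct()`.
* `trim_alignment()` keeps columns whose gap fraction *equals* the
  threshold, and errors when no column survives.
* An all-absent trait vector is a contradiction for Dollo loss counting
  (no evidence of ancestral presence) and errors.
* `branch_asymmetry()` reports ratio 1 for equal stems and requires a
  binary duplication node; multi-edge stems are summed along the path to
  each child orthogroup's ancestral node.
* Ties and flips: the fate search fixes the first duplication's side to
  remove the global flip; reported fates are unique only up to that flip,
  and a zero score leaves all paralogs unassigned.

## Problem sizes used in the validation suite

The test suite and the acceptance script size their simulations for a
single CPU: oracle equivalence uses exhaustive enumeration on trees of up
to 8 leaves (200 random instances for Dollo and loss counting, 50 for
Markov posteriors at tolerance $10^{-9}$, 20 for the fate search at up to
4 duplications); recovery runs use the default family (30 tips, protein
length 200), a 22-duplication fate family with 16 planted domain losses,
and a 60-species loss survey with 23 planted events. The full suite runs
in well under a minute.

## Limitations

Everything upstream of the package's inputs — homology search, orthogroup
construction, alignment, tree inference, rooting — is out of scope and must
be supplied. The intron homology criterion is exact by design; families
with substantial intron sliding would need a different criterion. The
recurrence score is a simplified, declared operationalization of fate
clustering, not a reimplementation of any published pipeline; column
weighting, substitution-matrix similarity and embedding-based clustering
are knowingly absent. Rates for the Markov reconstruction are taken as
given, and LECA-presence calling implements a fixed two-clades-by-two
species rule.
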