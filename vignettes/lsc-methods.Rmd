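---
title: "Detecting latent structural characters from rate and frequency shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting latent structural characters from rate and frequency shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lscscan)
```

## The problem

Protein families keep their fold for billions of years while individual
structural motifs — a zinc finger, a salt bridge, a substrate-recognition
loop — are born, die, or change roles between subfamilies. Such transitions
are latent in a sequence alignment: no single column shows them, but groups
of columns that are neighbours in a representative 3D structure shift
*together*, either in substitution rate (heterotachy; "type I" divergence)
or in the chemical class of the residue they fix ("type II" divergence).

`lscscan` detects both kinds of shifted sites between subfamilies (clades)
of a protein family, tests whether the shifted sites cluster spatially in a
reference crystal structure, assembles **latent structural characters
(LSCs)** — connected components of typed sites on a residue contact graph —
and uses the per-clade states of those characters for maximum-parsimony
inference of the deep, otherwise poorly resolved subfamily phylogeny.

## Substitution counting

All downstream statistics consume per-column, per-clade substitution counts.

For each clade tree, ancestral residues are reconstructed at every internal
node. Two reconstruction models are available:

* **`marginal-ml`** (default): marginal maximum-likelihood states under the
  equal-exchangeability (Poisson) amino-acid model, where a branch of length
  $b$ (expected substitutions/site) has transition matrix
  $P(b) = e^{-\kappa b} I + (1 - e^{-\kappa b})\,J/20$ with
  $\kappa = 20/19$ so lengths stay on the substitutions-per-site scale.
* **`fitch`**: minimum-change states (Hartigan's generalisation, exact on
  multifurcations), ties broken in lexicographic amino-acid order so every
  run is deterministic.

Ancestors always receive amino acids, never gaps. A gapped leaf therefore
always differs from its parent, so an aligned position with $N$ gaps in a
clade is assigned at least $N$ substitutions; a segment that is conserved in
one subfamily but deleted in another consequently surfaces as a run of
high-rate (type I) sites, which is the desired behaviour. Columns gapped in
*every* leaf of a clade are flagged uninformative and receive one
substitution per terminal edge.

The raw count $m$ for a column is the number of tree edges whose endpoint
states differ. Raw minimum-change counts undercount when multiple hits pile
onto one edge, so a multiple-hit correction replaces $m$ by
$\hat\lambda\,t$, where $t$ is the clade tree length and $\hat\lambda$
solves

$$\sum_e \tfrac{19}{20}\left(1 - e^{-\kappa \hat\lambda b_e}\right) = m,$$

the left side being the expected number of *visibly changed* edges at rate
$\hat\lambda$. The correction is zero at $m = 0$, strictly increasing in
$m$, and saturates smoothly (counts at or beyond the geometric ceiling are
solved against 99.9% of it). An `identity` mode returns $m$ untouched for
transparency, and a TSV import path accepts externally computed counts so
users of other reconstruction software can inject their own.

With marginal-ML reconstruction the solve targets the posterior **expected**
number of changed edges, $\sum_e \Pr(\text{endpoint states differ} \mid
\text{column})$, rather than the discretised count from point-estimate
states, and one **rate-aware refinement pass** recomputes those
probabilities with branch lengths scaled by each column's first-pass rate.
Both refinements are plain empirical-Bayes estimators of the same quantity;
on the standard benchmark below they improve both the divergence-coefficient
estimate and the ranking of shifted sites. Fitch-mode counting remains the
literal minimum-change count for users who want it.

Normalised **relative rates** divide each column's corrected count by the
clade mean, so rates average 1 within a clade and region-level summaries are
comparable across clades of very different tree lengths.

## The two-clade type I mixture

For clades $A, B$ with tree lengths $t_A, t_B$, a column's counts are
modelled as conditionally Poisson: $x_A \sim \mathrm{Pois}(\lambda_A t_A)$,
$x_B \sim \mathrm{Pois}(\lambda_B t_B)$. With probability $1-\theta$ the
column shares one rate $\lambda_A = \lambda_B = \lambda \sim
\Gamma(\alpha, \beta)$; with probability $\theta$ (the **coefficient of
type I functional divergence**) the two clades draw independent rates from
the same gamma. Integrating the gamma out gives closed negative-binomial
forms, e.g. for the shared component

$$L_0(x_A, x_B) = \frac{\Gamma(\alpha + x_A + x_B)}{\Gamma(\alpha)\,x_A!\,x_B!}
\; \frac{t_A^{x_A} t_B^{x_B}\,\beta^\alpha}{(\beta + t_A + t_B)^{\alpha + x_A + x_B}},$$

so the likelihood needs no quadrature. The fit maximises the mixture
likelihood over $(\theta, \alpha, \beta)$ by bounded quasi-Newton
(L-BFGS-B on $(\mathrm{logit}\,\theta, \log\alpha, \log\beta)$, box bounds
keeping $\alpha, \beta \in [10^{-3}, 10^3]$) from five deterministic starts
$\theta_0 \in \{0.05, 0.25, 0.5, 0.75, 0.95\}$ with method-of-moments gamma
initialisation; the best optimum wins, boundary estimates are flagged, and
the standard error comes from the observed information via the delta
method. Corrected counts enter the likelihood real-valued — the
negative-binomial forms extend analytically through `lgamma` — which keeps
the information that integer rounding would discard.

Per-column posteriors
$\Pr(\text{type I} \mid x) = \theta L_1 / (\theta L_1 + (1-\theta) L_0)$
rank sites; a site is *called* type I above a posterior cutoff (default
0.90, configurable in $(0.5, 1)$). Each type I call carries a direction:
the clade pair ordered by corrected rate $x/t$ at that column.

**Type II** sites are identified deterministically: the reconstructed states
at the two clade roots must fall in different *radical* property groups —
positive $\{K,R,H\}$, negative $\{D,E\}$, hydrophilic
$\{S,T,N,Q,C,G,P\}$, hydrophobic $\{A,I,L,M,F,W,V,Y\}$ — and both clades
must be conserved at the column (corrected count at most a ceiling,
default 0.5). $\theta_{II}$ is the proportion of type II columns among
columns conserved in both clades, reported with a binomial standard error
and flagged in output as a proportion estimator rather than a likelihood
fit. Site classes are mutually exclusive with precedence
typeII > typeI > type0: a radical fixed difference is the stronger
statement than a rate shift, and type 0 (zero raw substitutions in both
clades, identical consensus residue) is claimed only when nothing else
triggers.

## Spatial clustering of type I sites

The **contact graph** has structure-mapped alignment columns as vertices and
an edge wherever the representative atoms of two residues lie within a
distance threshold. The default follows the family convention of
alpha-carbons within 4 Å — a deliberately sparse rule that captures mostly
chain neighbours — with `CB` and minimum-heavy-atom modes exposed because a
4 Å Cα rule misses many genuine side-chain contacts; users probing
side-chain interactions (e.g. the four cysteines of a zinc finger) should
consider `atom_mode = "min"` with a 4–5 Å threshold.

For a quartet of clades $((A,B),(C,D))$, the test asks whether type I
transitions on the two independent edges co-locate: take the top $N$
(default 25) columns per edge by type I posterior, discard columns common to
both lists (leaving $N'$ per edge), and count

$$S = \#\{\text{within-set pairs that are contact edges, both sets}\}.$$

Because rate shifts may concentrate in intrinsically variable regions even
without concerted evolution, the null **conditions on the observed sites**
and permutes only their edge assignments: null draws are random
equipartitions of the $2N'$ pooled sites into two labelled halves. Pools of
at most 12 sites are enumerated exactly (the exact tail proportion is
reported); larger pools use Monte-Carlo with the plus-one correction
$p = (1 + \#\{S_{\text{perm}} \ge S_{\text{obs}}\})/(1 + n_{\text{perm}})$,
which never reports zero. The upper tail is used: clustering inflates $S$.
A companion **consecutive-pair statistic** counts within-set pairs that are
chain neighbours, separating mere sequence adjacency from genuine 3D
clustering.

## Region and rate-uniformity tests

A named region (for instance a substrate-recognition loop) is compared with
the remainder of the protein by resampling same-size column sets: a
**location test** (mean count) and a **distribution test** (sum of
mid-ranks). Both default to the one-sided lower tail — the scientific
question is whether the region evolves more slowly than the background —
with `greater` and `two.sided` available. Small designs
($\binom{n}{k} \le 10^5$) are enumerated exactly.

Uniformity of the summary rate across $n$ trees uses the fact that sums of
Poisson processes are Poisson: with totals $x_i$ and exposures $t_i$, the
likelihood-ratio statistic

$$-2\log\Lambda = 2\sum_i x_i \log\frac{x_i}{\hat\lambda t_i},
\qquad \hat\lambda = \frac{\sum x_i}{\sum t_i}, \quad 0\log 0 = 0,$$

is asymptotically $\chi^2_{n-1}$. The statistic depends only on the counts
and the proportions $t_i/\sum t_j$, so rescaling all exposures leaves it
unchanged. For families with replicate subtrees over the same organisms,
`replicate_tree_rate_tests()` runs the LRT twice: on whole-subtree totals
and on the stem edges joining the subtrees to their common ancestor.

## LSCs, character states, parsimony

An **LSC** is a maximal connected component of the typed-column contact
graph with at least two members, at least one of which is type I or II.
Components are found with `igraph` and ordered by smallest member column,
so output is deterministic.

Per-clade **states** are assigned by a reproducible surrogate for what a
structural biologist does by eye with sequence logos: two clades share a
state iff their conservation status (consensus frequency $\ge 0.7$ vs
below) matches at every member column and, wherever both are conserved, the
consensus residues share a radical group. The resulting equivalence classes
are labelled in order of first appearance over alphabetically sorted
clades; if the similarity relation is intransitive the character falls back
to single-linkage grouping and is flagged. A clade with the whole region
gapped gets a missing state. A **manual override table is first-class**, so
expert assignments can replace the automatic rule verbatim — the automatic
rule is a default, not a claim that it reproduces expert judgement.

The clade-by-LSC state matrix feeds exhaustive **maximum parsimony**: every
unrooted binary topology on up to 9 taxa — $(2n-5)!!$, i.e. 135,135 at
$n = 9$ — is generated exactly once by stepwise addition and scored with
bit-parallel Fitch operations (all characters as one bitmask vector);
missing states are wildcards. All minimal topologies are returned, with a
per-character score breakdown on one of them. Parsimony is unrooted;
reports store unrooted topologies even if a drawing is rooted for display.
More than 9 taxa is out of scope by design (no heuristic search).

## The synthetic generator

Because real datasets of this kind are rarely redistributable, the package
ships a fully specified generator whose defaults are the package's standard
benchmark:

* two balanced 16-leaf clades, total tree length 8 each (about 0.27
  substitutions/site per branch — the per-branch scale of typical subfamily
  trees, whose totals run roughly 6–42 over 40–120 branches);
* 500 columns; site rates $\lambda \sim \Gamma(0.5, 0.5)$ (mean 1, strong
  among-site variation);
* a fraction $\theta = 0.5$ of type I columns whose rate in every clade
  after the first is **redrawn independently from the same gamma and
  amplified 8-fold up or down with equal probability** (`shift_ratio = 1`
  degenerates to the pure independent redraw of the mixture model itself);
* 5% type II columns: fully conserved within clades, fixed for residues
  from different radical groups between clades;
* 2% gaps, inserted as one contiguous block per sequence, emulating indel
  segments;
* residues evolved along each clade tree under the same
  equal-exchangeability model the counting machinery assumes, from a shared
  per-column root state.

Synthetic coordinates place residues on a straight backbone-like chain with
3.8 Å consecutive spacing — so chain neighbours are genuine contacts at a
4 Å threshold, mirroring the consecutive-pair statistic — and reposition
each planted cluster into a tight, well-separated blob in which all
intra-cluster pairs fall within the threshold and no cross pair does.
`simulate_quartet_fixture()` plants type I columns for the $(A,B)$ edge in
one cluster and for $(C,D)$ in another (or scatters them, for calibration).

What the generator does **not** emulate: realistic indel evolution, empirical
amino-acid exchangeabilities, compositional heterogeneity, alignment error,
and real protein geometry. Passing tests therefore demonstrate correctness
of the statistics and the recoverability of planted structure under the
model's own assumptions — not performance on real alignments, where model
violations (especially alignment error near indels) will add noise the
benchmark does not contain.

Measured on this benchmark (20 seeded replicates; the same computation the
acceptance script reruns), the divergence coefficient is recovered within
$\pm 0.1$ of the planted $\theta = 0.5$ in all replicates and the mean
posterior-ranking AUROC against planted type I truth is about 0.81.

## Numerical choices and degenerate inputs

* All ties — Fitch root sets, marginal-ML posterior ties, consensus-residue
  ties — break in lexicographic amino-acid order; given inputs and a seed,
  every result in a scan report is bit-reproducible, and `run_full_scan()`
  writes byte-identical files on reruns.
* The mixture optimiser never reports a silent boundary collapse: estimates
  with $\theta$ within $10^{-3}$ of 0 or 1 carry a `boundary` flag.
* Monte-Carlo p-values use the plus-one rule and can never be 0; exact
  enumerations report the true tail proportion, which can be.
* Degenerate inputs fail loudly: ragged alignments name the offending
  sequence, trees without branch lengths are rejected (lengths are load
  bearing for both counting and the LRT), regions must be strict non-empty
  subsets, clades with all-zero counts cannot be rate-normalised, and an
  all-gap reference row cannot be mapped to a structure.
* Structure mapping tolerates up to 5% residue mismatches between the
  alignment's reference row and the crystal sequence (engineered constructs
  differ from database entries) and scans all offsets when lengths differ;
  mismatches are reported.
* Problem sizes in the shipped tests (500-column alignments, 16-leaf
  clades, 10–20 replicates, $10^4$–$10^5$ permutation draws, one full
  9-taxon parsimony enumeration) are the package's chosen benchmark scale:
  large enough to measure calibration and recovery, small enough that the
  whole suite runs in a couple of minutes.

## Known limitations

* The type II coefficient is a thresholded proportion, not a likelihood
  estimate; its standard error ignores reconstruction uncertainty at the
  clade roots.
* The mixture treats corrected counts as Poisson realisations; counts
  produced by ancestral-state counting are slightly underdispersed and
  saturate on long branches, which biases $\hat\theta$ toward the centre at
  extreme tree lengths. The rate-aware counting pass reduces but does not
  remove this.
* The default Cα/4 Å contact rule is conservative; side-chain-mediated
  LSCs may be split into fragments under it.
* Exhaustive parsimony stops at 9 taxa.
* Direction is reported for type I sites only; no direction is defined for
  type II.

## A minimal session

```{r example, eval = FALSE}
spec <- simulation_spec(seed = 1)
sim <- simulate_alignment(spec)

counts <- clade_site_counts(sim$aln, sim$trees, sim$partition)
fit <- fit_type_I(counts, "A", "B")
tidy(fit)

posteriors <- type_I_posteriors(fit)
plot_posterior_profile(posteriors)

graph <- build_contact_graph(sim$structmap,
                             posteriors$column[posteriors$posterior > 0.9])
lscs <- find_lscs(
  classify_sites(sim$aln, sim$partition, posteriors,
                 classify_type_II(
                   reconstruct_ancestral_states(sim$aln, sim$trees$A),
                   reconstruct_ancestral_states(sim$aln, sim$trees$B),
                   counts, "A", "B"),
                 counts, "A", "B"),
  graph)
```
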