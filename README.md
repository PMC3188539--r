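# lscscan

Protein families conserve their fold while individual structural motifs — a
zinc finger, a salt bridge, a recognition loop — are gained, lost, or change
roles between subfamilies. These transitions are invisible to column-wise
conservation scores but leave two fingerprints in an alignment: sites whose
**substitution rate** shifts between subfamilies (heterotachy, "type I"
divergence) and sites that stay conserved within each subfamily but are
**fixed for chemically radical alternatives** between them ("type II").
Because a motif is a set of residues that are neighbours in space, these
shifted sites should cluster in a reference 3D structure.

`lscscan` is an R package for molecular evolutionists that implements this
programme end to end:

* per-site substitution counts from native ancestral-state reconstruction
  (marginal ML under the equal-exchangeability amino-acid model, or Fitch),
  with the gap rule that a position with *N* gaps gets at least *N*
  substitutions, and a multiple-hit correction;
* the two-clade mixture model behind the **coefficient of type I functional
  divergence** θ: with probability 1−θ a site's rate λ ~ Gamma(α, β) is
  shared by both clades, with probability θ the clades draw independent
  rates; counts are conditionally Poisson(λ·t), so the marginals have closed
  negative-binomial forms and sites are ranked by posterior probability of
  divergence;
* rule-based **type II** calls from radical property groups
  (K,R,H | D,E | S,T,N,Q,C,G,P | A,I,L,M,F,W,V,Y) at the clade roots;
* a conditional **permutation test for spatial clustering** of type I sites
  in a quartet of clades: the statistic *S* counts same-edge site pairs
  within 4 Å in the structure, and the null permutes only the edge
  assignments of the observed sites (exact enumeration for small pools,
  Monte-Carlo with the plus-one rule otherwise);
* region tests (resampled mean and rank-sum) and the Poisson
  likelihood-ratio test −2 log Λ = 2 Σ xᵢ log(xᵢ/λ̂tᵢ) ~ χ²(n−1) for rate
  uniformity across trees;
* **latent structural characters (LSCs)**: connected components of typed
  sites on the residue contact graph (≥ 2 members, ≥ 1 type I/II), per-clade
  state assignment, and exhaustive maximum parsimony over the clade × LSC
  state matrix (all (2n−5)!! unrooted topologies for up to 9 clades);
* a seeded synthetic-data generator (alignments with planted rate shifts,
  clade trees, coordinates with planted contact clusters) so every claim is
  testable without external data.

## Worked example

Simulate the standard benchmark (two balanced 16-leaf clades, 500 columns,
half the columns with an 8-fold rate shift), count substitutions, and fit
the divergence mixture:

```r
library(lscscan)

spec <- simulation_spec(seed = 1)
sim  <- simulate_alignment(spec)
sim
#> <lsc_sim> 32 sequences x 500 columns; clades: A, B; seed 1

counts <- clade_site_counts(sim$aln, sim$trees, sim$partition)
fit <- fit_type_I(counts, "A", "B")
fit
#> <theta_fit> kind=typeI  theta = 0.582 (se 0.039)
#>   gamma shape 0.639, rate 0.664, logLik -2980.83, n = 500
```

Half the simulated columns were planted as rate-shifted, and the fitted
coefficient of functional divergence θ̂ = 0.58 ± 0.04 recovers that
(the generator's default also mixes in 5% type II columns and 2% gaps,
which sit on the divergent side). Per-site posteriors rank the shifted
columns:

```r
posteriors <- type_I_posteriors(fit)
dplyr::arrange(posteriors, dplyr::desc(posterior))[1:3, ]
#>   column posterior slow_clade fast_clade
#> 1    163     1.000 A          B
#> 2    386     1.000 A          B
#> 3    259     1.000 A          B
sum(posteriors$posterior > 0.9)
#> [1] 124
```

124 columns exceed the 0.90 call cutoff; each call is directed (which clade
is slow, which fast). Downstream, `build_contact_graph()` +
`classify_sites()` + `find_lscs()` turn typed columns into LSCs on the
structure, `clustering_permutation_test()` tests their spatial clustering in
a quartet, and `mp_search()` finds all most-parsimonious subfamily
topologies from LSC states. Rate uniformity across clades is a one-liner:

```r
poisson_lrt(c(31, 12), c(8, 8))   # totals 31 vs 12 on equal tree lengths
#> <rate_lrt> -2 log Lambda = 8.6924, df = 1, p = 0.003195
```

`run_full_scan(scan_config(...))` chains every stage (counts → divergence →
contacts → quartet test → LSC → parsimony → region tests) into one seeded,
byte-reproducible report, and `inst/cli/lscscan.R` exposes the same
pipeline as a command-line tool with a JSON config. The methods vignette
(`vignettes/lsc-methods.Rmd`) documents the models, defaults, and
limitations.

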