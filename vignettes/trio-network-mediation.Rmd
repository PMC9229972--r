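---
title: "Methods: penalized trio-omics networks and serial mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penalized trio-omics networks and serial mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomics)
```

## The analytic problem

Mother–offspring ("trio-omics") studies measure genotypes, metabolites
and clinical phenotypes in both members of each pair: maternal SNP
dosages and fasting/1-hr OGTT metabolites, offspring SNP dosages and
cord-blood metabolites, maternal exposure phenotypes (e.g. glycemia,
BMI) and newborn outcomes (birthweight, sum of skinfolds, cord glucose,
cord C-peptide).  The scientific question is mechanistic: which ordered
chains of maternal features, transmitted genetics and cord-blood
metabolites plausibly *mediate* the association between a maternal
exposure and a newborn outcome?

`triomics` implements a four-stage pipeline:

1. **Metabotype pre-filtering** (`run_metabotype_scan()`, `ld_trim()`) —
   per-metabolite GWAS with covariate adjustment retains SNPs at
   *p* < 10^−7.5, then trims each metabolite's hit list to approximately
   independent SNPs by greedy r² pruning.
2. **Blocklist-constrained network estimation** (`learn_dag()`,
   `learn_solution_path()`) — a sparse Gaussian Bayesian network over
   the typed node set, estimated along a decreasing penalty grid.
3. **Candidate pathway extraction** (`extract_candidates()`) — all
   shortest directed paths from maternal features to newborn outcomes
   in the least-penalized network, with subpath exclusion.
4. **Serial mediation with discovery/replication**
   (`bootstrap_smm()`, `discover_and_validate()`) — PROCESS Model-6
   style chains fit by OLS, bootstrap indirect effects, BH-FDR discovery
   on training data and nominal replication on validation data.

A synthetic cohort generator (`simulate_cohort()`) with known
linear-Gaussian ground truth makes every stage testable without access
to restricted cohort data.

## The network model

A Bayesian network over nodes $x_1,\dots,x_p$ factorizes the joint
distribution as $\prod_j P(x_j \mid \mathrm{pa}(x_j))$ along a DAG.  For
conditional-Gaussian nodes this is the structural model
$x_j = \sum_i B_{ij} x_i + \varepsilon_j$, $\varepsilon_j \sim
N(0,\omega_j^2)$.  On column-standardized data with sample correlation
matrix $S$ the package minimizes the per-$n$-normalized penalized
profile likelihood

$$
f(B) \;=\; \sum_j \tfrac12\bigl(1+\log 2\pi q_j\bigr)
\;+\; \sum_{i\to j}\operatorname{pen}_{\lambda_n}\!\bigl(|B_{ij}|\bigr),
\qquad q_j = 1 - 2B_{\cdot j}'s_j + B_{\cdot j}'SB_{\cdot j},
$$

where $q_j$ is the profiled conditional variance of node $j$ given its
parents.  `penalized_score()` reports $n\,f(B)$, the conventional
likelihood scale.

**Penalty.**  The default is the minimax concave penalty (MCP) with
concavity $\gamma = 2$, the concave penalty used by the CCDr family of
sparse DAG learners; an L1 penalty is selectable.  MCP caps the price of
a strong edge at $\gamma\lambda_n^2/2$, so well-supported edges enter
even under stringent penalties while weak ones are thresholded exactly
to zero.

**Penalty scale.**  Published analyses of this kind quote an integer
grid $\lambda = 15,\dots,1$ whose internal units are software-specific
and not recoverable.  `triomics` defines its own convention: the
multiplier applied to the penalty on standardized data is
$\lambda_n = \lambda/\sqrt{n}$.  This is the $\sqrt{n}$ scaling on which
CCDr-type learners operate, and it makes the same integer grid behave
comparably across sample sizes: from an empty graph, an edge can enter
only if the absolute marginal correlation exceeds roughly
$\lambda/\sqrt{n}$.  `lambda_max()` returns the smallest $\lambda$ at
which the empty graph is stationary.

**Blocklist.**  Structure search is constrained a priori by eleven
rules: the ten forbidden ordered type pairs (offspring SNPs to maternal
SNPs/phenotypes/fasting- and 1-hr metabolites; newborn outcomes and cord
metabolites to either SNP set; maternal phenotypes to offspring SNPs;
maternal metabolites to either SNP set) plus a rule forbidding SNP-to-
SNP edges across different chromosomes.  Ground-truth simulation models
are validated against the same blocklist, so the generator can never
produce data whose causal structure the learner is forbidden to state.
Edge tallies (`tally_edges_by_type()`) report all 26 ordered type pairs
the blocklist leaves available, including pairs that rarely occur in
practice.

**Optimization.**  The objective is minimized by block-cyclic coordinate
descent over ordered node pairs (implemented in C++): for each pair
$(i,j)$ the three options {no edge, $i\to j$, $j\to i$} are compared by
exact objective value, re-optimizing the full coefficient columns of
both nodes under each option so that an entering chain edge can displace
a now-redundant ancestor shortcut in the same move.  Updates that would
create a directed cycle or enter a blocklisted direction are rejected;
every acceptance strictly decreases the objective, so the score trace is
monotone (asserted in `debug` mode).  Exact ties between directions go
to the blocklist-permitted direction, then to the lower (parent, child)
lexicographic order.

Two devices address the orientation local optima inherent in greedy
pairwise search.  Cold starts use a deterministic multi-start over node
orderings (identity plus seven fixed pseudo-random permutations;
different sweep orders reach different orientation basins, and the best
exact score wins).  The winning basin is then refined by edge-reversal
perturbation: each current edge is trial-reversed with its old direction
tabu, coordinate descent reconverges under a small sweep budget, and the
move is kept only if the total objective improves.  Warm-started fits —
every model after the first on a solution path — skip both devices and
inherit the basin of the initializing solution, which keeps the path
coherent and fast.

**Solution path.**  `learn_solution_path()` fits from the most to the
least stringent penalty (default integer grid 15 → 1), warm-starting
each fit.  Rather than selecting one penalty, the whole path is kept:
`glance()` tabulates edge and connected-node counts per $\lambda$,
`first_occurrence()` reports the most stringent penalty at which an edge
class (e.g. genotype → metabolite) first appears, and
`export_growth_frames()` writes per-$\lambda$ GraphML plus static PNG
frames (frame 1 ↔ the most stringent penalty) in place of an
interactive animation.

## Serial mediation

For a candidate path $X \to M_1 \to \dots \to M_k \to Y$,
`fit_serial_chain()` fits, with adjustment covariates in every
equation: each mediator on the exposure and all earlier mediators, the
outcome on the exposure and all mediators (direct effect $c'$), and the
outcome on the exposure alone (total effect).  The serial indirect
effect is the product $a_1 d_{21} \cdots b_k$ of the chain coefficients.
For recursive linear-Gaussian path models these per-equation OLS
estimates coincide with the SEM maximum-likelihood estimates, so the
package fits by OLS directly.

`bootstrap_smm()` resamples individuals with replacement (default 1000
replicates), reporting the replicate standard deviation as the standard
error, the percentile 95% interval, and the two-sided
normal-approximation p-value $2\Phi(-|\mathrm{IDE}|/\widehat{se})$.
Replicate count, interval type and p-value construction are
conventions of PROCESS-style practice and are configurable.  The
proportion mediated is $\mathrm{IDE}/\mathrm{TE}$ with the total
effect in the denominator; unlike $\mathrm{IDE}/(\mathrm{IDE} +
\mathrm{DE})$, this definition can legitimately be negative or exceed
100% when direct and indirect effects oppose each other, and it is
flagged undefined when the total effect is numerically zero.

`discover_and_validate()` applies the two-stage protocol: BH-FDR
adjustment of IDE p-values within each analysis family (fasting-network
and 1-hr-network paths are adjusted separately), discovery at adjusted
*p* < 0.05 with positive PM, then refitting survivors on held-out
validation data with replication at nominal *p* < 0.05 and positive PM.
Requiring positive PM at validation is a switch
(`require_positive_pm`), since descriptions of the protocol support
either reading.

## The synthetic cohort generator

`simulate_cohort()` draws from a `true_model()`: a typed DAG with
linear coefficients, node intercepts and noise standard deviations.
Maternal SNP dosages are Binomial(2, maf) under Hardy–Weinberg
equilibrium; a newborn SNP with a maternal-SNP parent edge receives one
allele drawn uniformly from the mother's two alleles plus a paternal
allele at the population frequency.  Paternal genotypes are not modeled
as nodes — only maternal and offspring genotypes are observed in the
target study design — so the implied maternal–offspring dosage
correlation is the parent–offspring additive value of 1/2, and the
implied linear coefficient of offspring on maternal dosage is 0.5
(used by the covariance oracle in the test suite).  All non-genotype
nodes are generated in topological order as
intercept + Σ coefficient·parent + Gaussian noise.  Covariates are
independent standard normals by default; `covariate_effects` can inject
confounding edges.  Ancestry strata are sampled from Dirichlet
proportions over four groups — mirroring a four-group multi-ancestry
cohort without claiming any particular composition — and
`split_train_validation()` splits two-thirds/one-third within strata,
rounding half up per stratum (a 1385-pair single-stratum cohort yields
923 training pairs under this rule).

What the generator deliberately does **not** emulate: population
structure and ancestry principal components, genotype imputation
uncertainty, non-Gaussian metabolite distributions, batch effects, and
missingness mechanisms (missingness handling is exercised separately
through `preprocess_metabolites()`).  Passing tests therefore
demonstrate correctness of the estimators under the stated
linear-Gaussian trio model, not robustness to those real-data
complications.

### Packaged fixtures

* `example_true_model()` — seven nodes (two maternal SNPs, one fetal
  SNP at the first locus, two maternal fasting metabolites, two
  cord-blood metabolites), every drawn edge with coefficient 0.8; used
  for covariance-oracle checks against
  $(I-B')^{-1}\Omega(I-B)^{-1}$.
* `trio_benchmark_model()` — twelve typed nodes whose DAG is fully
  identifiable under the blocklist: every edge is either
  blocklist-forced (its reversal is a forbidden type pair) or compelled
  by an unshielded collider, with Meek-rule propagation orienting the
  rest.  This is the structure-recovery benchmark; with $|coef| = 0.8$
  and $n = 2000$ the solution path recovers the true DAG at some
  $\lambda$ in essentially every replicate.

## Numerical choices and degenerate inputs

* Data are standardized to zero mean and unit variance (variance with
  denominator $n$) before learning; reported edge weights are on the
  standardized scale.  Constant columns are an error.
* Profiled conditional variances are floored at $10^{-12}$ so
  deterministic children keep a finite objective.
* Coordinate updates use a closed-form threshold proposal polished by a
  guarded Newton step, with exact-objective acceptance among {zero,
  proposal, OLS value, previous value}; convergence is declared when
  the largest coefficient change in a sweep falls below `tol`
  (default 1e-8), and non-convergence at `max_iter` returns the fit
  with a warning.
* Association fits drop incomplete rows per fit, raise a monomorphic
  error on constant dosage, and name the collinear columns on rank
  deficiency.  The p-value floor is the smallest positive double, so
  p stays in (0, 1] even for noiseless fits.
* LD trimming visits SNPs in ascending p order (strongest signal kept
  per correlated block); the r² threshold defaults to 0.5 and is
  exposed because downstream SNP counts depend on it.
* Bootstrap replicates whose resampled design is singular are dropped
  and counted; more than 10% failures aborts with an unstable-fit
  error.
* `is_subpath()` requires a contiguous ordered slice; subpath
  elimination is applied across the pooled candidate set, and because
  contiguous containment is transitive, one pass against all longer
  pooled paths equals the exhaustive fixpoint.

## Problem sizes used by the test suite

The acceptance checks run at desk scale: 4-node exhaustive-enumeration
oracle comparisons over 543 DAGs at $n = 500$ (20 replicates); 12-node
structure recovery at $n = 2000$ (20 replicates); mediation coverage
with 200 simulation replicates of $n = 500$ at 500 bootstrap draws and
null calibration with 1000 replicates of the same size; the
discovery/replication protocol with 50 replicates of one planted
pathway among 50 null pathways at $n_{train} = 900$, $n_{valid} = 450$
and 200 bootstrap draws; and trio-transmission checks at
$n = 50{,}000$ pairs.  These sizes were chosen so each property is
measured with comfortable statistical margin while the whole suite
completes in minutes.

## Known limitations

* All nodes, including 0/1/2 genotype dosages, are treated as
  conditional-Gaussian; genotypes enter additively, matching the
  additive-coding GWAS stage, but the likelihood is an approximation
  for discrete nodes.
* Candidate pathways are analysed as independent serial chains;
  combined parallel+serial mediation models are out of scope.
* Penalized structure search is non-convex; the multi-start and
  reversal refinements empirically reach the global optimum on small
  problems, but no global guarantee exists for large node sets.
* Bootstrap-ensemble edge stability, discrete node likelihoods,
  kinship-adjusted association scans and automatic single-$\lambda$
  selection are deliberately not implemented.
* `run_pipeline()` applies a single covariate set to every scan and
  mediation equation; analyses needing different adjustment lists per
  metabolite timepoint should call the stage functions directly, which
  accept covariates per call.
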