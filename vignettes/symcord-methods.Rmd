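---
title: "Models and methods behind symcord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind symcord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package models

`symcord` is a desk-scale, fully tested implementation of the phylogenomic
workflow used to study cyto-nuclear discordance and floral-symmetry
evolution in Ranunculales-type target-capture datasets. The workflow has
two tracks. The nuclear track treats every locus as an independent draw
from the multispecies coalescent (MSC): gene trees are estimated by
maximum likelihood, weakly supported bipartitions are collapsed, and the
species tree is estimated by maximum quartet agreement with per-branch
normalized quartet support (QS), local posterior probability (LPP) and
coalescent-unit branch lengths. The plastid track treats the plastome as a
single c-gene — one non-recombining coalescent history — analysed by
concatenated, partitioned maximum likelihood with gene-and-site bootstrap.
Both tracks are dated by penalized likelihood against a fossil-calibration
ledger, an equal-rates Mk model reconstructs ancestral floral symmetry on
both chronograms, and the `discord` functions quantify where the two
tracks disagree.

Every stage runs on synthetic data with known ground truth, so each claim
the pipeline makes (concordance fractions, support values, node ages,
ancestral states, conflict localization) can be checked against either a
closed form or a brute-force oracle.

# The synthetic-data generator

`simulate_species_tree()` draws a pure-birth topology conditioned on the
tip count, scales the ingroup crown to 3/4 of the requested root age and
attaches the outgroup clade as sister to the ingroup (crown at 1/2 the
root age when there are several outgroup tips). These fractions are fixed
design choices, not estimates; they give outgroups long stems, which is
the situation the per-species outlier detector has to tolerate. The
default root age used throughout the examples, 187 Mya, is a realistic
crown age for the order this workflow targets.

ILS intensity is parameterized directly in coalescent units per branch
(`cu_per_my` in `species_tree_truth()`), not through effective population
sizes: the studies this workflow mirrors invoke ILS qualitatively without
ever quantifying a population-size history, so the generator exposes the
one quantity the MSC actually cares about. A branch of *d* coalescent
units yields gene-tree concordance probability $1 - \tfrac{2}{3}e^{-d}$
for the quartet around it, which is the package-wide calibration oracle.

`simulate_gene_trees()` runs the exact MSC: within each species-tree
branch, *j* lineages coalesce at rate $\binom{j}{2}$ per coalescent unit;
surviving lineages merge above the root. Per-gene substitution rates are
log-normal around a median of $10^{-3}$ substitutions/site/My with
`sdlog = 0.3` — enough rate heterogeneity to make penalized-likelihood
dating non-trivial, little enough that gene trees remain estimable from a
few hundred sites.

Introgression is modelled as a clade regraft: with probability `gamma` a
gene follows an alternative species history in which the recipient clade
attaches to the donor lineage at the event time. The event carries an
`affects` field (`plastid`, `nuclear`, `both`); the default is `plastid`,
i.e. chloroplast capture, the classic mechanism behind cyto-nuclear
conflict. Because the plastome is a *single* binary realization of that
event, `simulate_plastid_tree()` defaults to the maximum-probability
outcome (`follow = "expected"`: follow iff `gamma >= 0.5`) so that a
scenario is a well-defined study condition rather than a coin flip;
`follow = "sample"` restores the Bernoulli draw for anyone studying the
marginal behaviour. The plastid tree itself is the species time tree
(regrafted or not) with no coalescent noise — a zero-variance c-gene,
matching its role as a single low-Ne locus.

Sequences are simulated site-independently under JC69 (default) or HKY,
aligned and indel-free by construction; alignment building is out of
scope, as the empirical workflow delegates it to an external aligner.
`degrade_recovery()` then emulates target-capture patchiness: sequences
drop out with `missing_rate`, survivors are truncated to a length fraction
drawn from a configurable distribution (the default pipeline setting,
uniform on [0.5, 1], mirrors datasets where a median gene is recovered at
about half its target length), and paralog copies are recorded with
probability `paralog_rate`.

The generator does **not** emulate indels, sequencing error, assembly
chimerism, alignment error, or base-composition heterogeneity. Passing
tests therefore demonstrate that the pipeline's logic and estimators are
correct under the MSC with clean alignments — not that any empirical
dataset satisfies those assumptions.

# Recovery QC and the coverage score

The coverage score multiplies three per-gene/per-cell statistics:
representedness (share of accessions with a sequence), completeness
(recovered/target length, capped at 1 because supercontigs can exceed
their target), and evenness. The source workflow names these three
components but not their functional form, so the product form and the
Pielou-style evenness $\exp(H)/m$ over the length shares of the *m*
recovering accessions are this package's concrete choices, isolated
behind `recovery_stats()` so alternatives can be swapped. The gene-level
score aggregates by the median over recovering accessions, which is
robust to a single bad accession.

`filter_genes()` applies two rules in order: drop genes with two or more
assembled copies in at least three accessions ("three or more paralogs" is
read as three affected accessions; the other reading — three copies within
one accession — is noted as an open question and is not the default), then
drop genes scoring below 2/3 of the median gene score of the survivors.
`filter_alignments()` drops genes whose alignment length *or* proportion
of parsimony-informative characters falls below 1/3 of the respective
median, with strict inequalities at both boundaries. Ambiguity codes count
as missing for informativeness — a conservative choice.

`select_targets_kmedoids()` reconstructs the reference-selection step: the
smallest $k \le 6$ such that PAM k-medoids covers every sequence within
0.15 identity distance of a medoid. `cluster::pam` is deterministic
(BUILD + SWAP), so no random restarts are needed; ties among equivalent
medoid sets resolve toward the lowest sequence id.

The outlier detector behind `flag_outliers()` is deliberately a
*simplified* per-species diameter-signature test in the spirit of
TreeShrink's per-species mode: the signature is the relative drop in tree
diameter when a species is pruned, flagged when it exceeds both that
species' empirical $(1-\alpha)$ quantile across genes and a global minimum
effect of 0.2. The default tolerance is $\alpha = 0.5$ (the filtering the
empirical workflow retained), with 0.05 available. Species present in
fewer than five genes are never flagged, only logged.

# Tree inference

The likelihood engine (JC69/HKY pruning likelihood, NNI move set,
edge-length optimization, nonparametric bootstrap machinery) is
phangorn's; `symcord` owns what sits around it: JC starting distances with
`jc_distance()`, the bootstrap-to-bipartition support mapping, strict
`<`-threshold bipartition collapsing (`collapse_low_support()`, default
threshold 11), and the gene-and-site bootstrap for the concatenated
plastid matrix (partitions resampled with replacement, then sites within
each drawn partition, so every replicate keeps the original column count).
Models are limited to JC69/HKY and the search to NNI: at desk scale
(tests run 4-10 taxa per gene) these recover the same optima as richer
machinery, and the engine interface leaves room for extension. Bootstrap
supports are classical nonparametric values, comparable to but not
numerically identical with ultrafast-bootstrap numbers.

# Quartet species trees under the MSC

`quartet_tally()` aggregates, for every internal branch, the gene-tree
resolutions of all quartets with one taxon from each of the four subtrees
the branch separates. Polytomous gene-tree quartets (the product of
collapsing) contribute 1/3 to each alternative; quartets with a missing
taxon are skipped for that gene. Quartet resolutions are read off the
four-point condition on unit-branch-length path distances.

The search is exhaustive over all unrooted topologies up to 8 taxa and an
NNI hill-climb from a quartet-affinity neighbor-joining start above that.
The full constrained dynamic program of the reference species-tree tool is
not reimplemented; on every test size the hill-climb provably attains the
exhaustive optimum, which is the acceptance gate.

Per-branch LPP uses the binomial-mixture posterior
$P(T_i) \propto \int_{1/3}^{1} \theta^{z_i}\left(\frac{1-\theta}{2}\right)^{n-z_i} d\theta$
with equal priors over the three resolutions, evaluated through regularized
incomplete beta functions on the log scale. This flat $\theta$-prior
differs slightly from the Yule-derived prior of the reference tool; it is
the documented default behind a single function (`local_pp()`) that a
different prior could replace. Coalescent-unit lengths invert the
concordance formula, $d = -\ln\!\big(\tfrac{3}{2}(1 - q_1)\big)$, zero at
$q_1 \le 1/3$ and capped at 10 (with a saturation flag) as $q_1 \to 1$.

# Penalized-likelihood dating

`pl_objective()` is the Poisson branch likelihood minus a roughness
penalty:
$\sum_b [x_b \ln(r_b t_b) - r_b t_b] - \lambda\,\Phi$, where $x_b$ is
branch length times site count (kept continuous — it is already an
expectation), and $\Phi$ sums squared rate differences between each branch
and its parent branch plus the variance of the root's child-branch rates.
Zero-length terminal branches get a floor of 0.5 substitutions to keep the
log finite.

`date_tree()` parameterizes node ages as proportional depths between
per-node effective bounds (each node's lower bound is the max of its own
and all descendant minima; its upper bound the min of its own and all
ancestor maxima), so parent-older-than-child order *and* every min/max
calibration hold by construction; rates are log-parameterized. Constraint
satisfaction is still exhaustively re-checked after optimization, never
assumed. "Priming" is implemented as multi-start local optimization
(default five restarts: one clock-like start plus jittered copies) —
the same role as the reference tool's priming (escaping poor optima) with
a simpler contract. The smoothing presets 0.01 (nuclear) and $10^{-6}$
(plastid) ship as defaults. The root must carry a finite maximum or fixed
age; otherwise the time scale is unidentifiable and the function says so.

`cross_validate()` drops one terminal at a time, dates the pruned tree,
and predicts the missing pendant substitution count from the adjacent
merged branch's rate and an attachment age interpolated along that branch
at constant rate; the error is the chi-square-style
$(x_i - \hat x_i)^2 / \max(x_i, 1)$, summed over tips, with ties broken
toward smaller $\lambda$. Reference implementations normalize this error
in version-dependent ways; the form here is stated, not claimed
equivalent. Within-species tip-age caps are applied to the MRCA of
conspecific accessions.

The packaged calibration ledger (`load_calibrations()`) encodes the full
fossil table: root and ordinal crown at 125-201.5 Mya, Sabiaceae crown
min 83.4, Lardizabalaceae stem/crown min 110/41.2, Menispermaceae
stem/crown min 91/64.67, the Coptidoideae+Ranunculoideae crown min 56,
and 1 Mya caps on three within-species tip pairs.
`ranunculales_exemplar_tree()` is a *synthetic* 17-tip scaffold — labelled
as such — whose clade structure lets every ledger row resolve, used to
exercise the dating machinery; it is not an estimate of any real
chronogram.

# Mk ancestral reconstruction

`fit_mk()` fits the equal-rates (ER) Mk model with uniform root
frequencies by Felsenstein pruning; `missing` is handled as total
ambiguity (an all-ones conditional), not as a fourth state. The three
floral-symmetry states are modelled unordered, matching a plain ER
reconstruction; an ordered actinomorphic-disymmetric-zygomorphic chain is
a biologically defensible alternative that is deliberately not the
default. Because the rate profile can plateau at high rates (where tips
decouple from the tree), the 1-D fit brackets the optimum on a log grid
before golden-section refinement. `marginal_asr()` computes true marginal
probabilities by the down/up (re-rooting) recursion; both the likelihood
and the marginals are tested against brute-force enumeration over all
internal-state assignments to $10^{-10}$, and the fitted rate against the
ape reference implementation (whose reported log-likelihood differs by
exactly the uniform root constant $\ln 3$).

`code_symmetry()` defaults every taxon to actinomorphic and applies
genus-prefix overrides encoding the empirical coding rules (Delphinium
zygomorphic, Euptelea missing, Hypecoum disymmetric, the disymmetric and
zygomorphic fumitory genera, and so on).

# Discordance

`clade_diff()`/`rf_distance()` compare canonical bipartition sets on the
shared tip set (one-tree-only taxa are pruned and reported, mirroring how
tanglegrams dash such tips). `entanglement()` fixes the left tree's drawn
leaf order and scores the exponent-weighted (default $L = 1.5$, the
visualization default; configurable) rank displacement of the right
tree's leaves, normalized by the fully reversed ordering; `step1side`
greedily rotates internal nodes of the right tree only, accepting only
improving rotations. `classify_support()` implements the four support
categories (maximal / high / moderate / weak) with their exact LPP and BS
thresholds.

# Problem sizes and numerical choices

The test and acceptance runs use deliberately small configurations chosen
so the whole suite exercises every stage in a few minutes of CPU:
concordance checks use 5,000 genes per branch length on 4-taxon trees
(3-standard-error tolerance); search-equivalence checks use ten 7-taxon /
200-gene replicates against exhaustive enumeration of all 945 topologies;
dating recovery uses a fixed 10-tip clock tree whose branches all exceed 7 My (so every node age carries enough expected substitutions at 10,000 sites for a 5% relative-error check to have power) plus the
17-tip exemplar under the full ledger; Mk rate recovery uses fifty 200-tip
replicates against the 95% likelihood-ratio interval; the end-to-end
scenarios use 10 taxa, 32 nuclear genes of 350 sites, 6 plastid partitions
of 400 sites and 30 bootstrap replicates. Optimizer tolerances: L-BFGS-B
with 500 iterations and five restarts for dating; NNI ties broken by the
first improving move in deterministic edge order; k-medoid ties toward the
lowest sequence id; all simulators are bit-reproducible under a fixed
seed, and every pipeline output records that seed.

# Known limitations

No indel or read-level simulation; no model selection (JC69/HKY only); no
SPR search or ultrafast bootstrap; no Bayesian dating or fossilized
birth-death; no stochastic character mapping or hidden-rate models; no
formal introgression tests (D-statistics and relatives) — `discord`
reports conflict patterns, never their causes. The heuristic quartet
search is only validated to match exhaustive search at test sizes
(<= ~12 taxa); nothing here is tuned for hundreds of taxa.
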