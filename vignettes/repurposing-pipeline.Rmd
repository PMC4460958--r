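---
title: "Inferring repurposable drugs from interaction-network factorization"
author: "pmfrepurpose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring repurposable drugs from interaction-network factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfrepurpose)
```

## The problem

A drug-target interaction network records which approved drugs are known
to bind which protein targets. Such a network is sparse and incomplete:
absence of an edge usually means *untested*, not *non-binding*. For a
query target with a set of known ligands — the motivating case is a
neurotransmitter transporter with a panel of known substrates and
blockers — we want to nominate approved drugs that plausibly bind it but
are not yet annotated to do so. Those are candidates for repurposing.

`pmfrepurpose` implements that inference as a four-stage chain:

1. **Ensemble matrix factorization.** The binary drug × target matrix
   $R$ is factorized as $R \approx UV^\top$ with $D$-dimensional latent
   vectors per drug and per target. The fit is repeated under many seeds;
   each run's top-$k$ scoring unknown drugs for the query target are
   pooled, and drugs appearing in at least a threshold fraction of runs
   become candidates.
2. **Latent-space clustering with known-ligand enrichment.** The pooled
   set (approved known ligands plus candidates) is clustered
   agglomeratively on the drugs' latent vectors under three distance
   metrics (Euclidean, cosine, city-block). Tree nodes significantly
   enriched in known ligands (one-sided hypergeometric test,
   Benjamini–Hochberg corrected) mark neighborhoods of the latent space
   where the target's pharmacology lives.
3. **Cross-metric consensus.** Candidates recovered inside enriched
   clusters under *every* metric are the consensus hits; metric choice is
   a nuisance parameter and consensus guards against it.
4. **Chemical similarity filtering.** A reference panel is expanded
   around the known ligands by fingerprint similarity, and consensus hits
   must score at least a combo threshold against the panel. Latent-space
   proximity reflects shared interaction *profiles*; the chemical filter
   demands that the candidate also look like the known ligands as a
   molecule.

## The factorization model

With observed cells $\mathcal{O}$ (known positives plus sampled
negatives), the fit minimizes

$$\sum_{(i,j)\in\mathcal{O}} (R_{ij} - U_i \cdot V_j)^2
  + \lambda_U\lVert U\rVert^2 + \lambda_V\lVert V\rVert^2 .$$

Choices that matter, and their defaults:

* **Negative sampling** (`neg_ratio = 1`). The binary matrix has no true
  negatives, so unobserved cells are sampled 1:1 with positives, once per
  fit, seeded. Drawing them once (rather than fresh per iteration) makes
  the objective a fixed function, so convergence and the monotonicity of
  the objective are well defined; the ensemble averages over the sampling
  anyway, seed by seed.
* **Optimizer.** Full-batch gradient descent with step halving: a step
  that would increase the objective is retried at half length, so the
  accepted objective sequence is non-increasing and divergence is
  impossible for any starting `learn_rate` (default 0.01). A non-finite
  objective still aborts with advice to lower the rate.
* **Initialization.** Entries i.i.d. Normal(0, sd 0.1), seeded; two fits
  with the same seed are bit-identical, which the ensemble's
  reproducibility contract relies on.
* **Dimensions and regularization.** `latent_dim = 20`,
  `reg_u = reg_v = 0.1`, `max_iter = 500`, `tol = 1e-6` on the absolute
  objective change. These are deliberately ordinary values for
  implicit-feedback factorization; all are configuration, not constants.
* **Scores are raw dot products.** Only rank order feeds the downstream
  stages, so no link function is applied.

Held-out validation uses the exact pairwise AUC (Mann–Whitney with ½ for
ties): the probability that a withheld true association outscores a
sampled negative cell. On the default planted network (200 × 50, true
rank 5, 5% density, 20 withheld positives) a single fit reaches mean AUC
around 0.93 over 20 seeds.

## The ensemble and its pooling rule

Run $r$ of the ensemble uses seed `seed_base + r`, fits the model,
ranks unknown drugs for the query target (ties broken by drug id), and
keeps the top $k$ (default 10). Appearance counts across runs become
frequencies; drugs at or above `freq_threshold` are selected. The
package default threshold is 0.5 (a majority rule). The production
protocol this mirrors pooled top-10 lists from $10^5$ runs into a
candidate set several times larger than $k$, which is only possible
under a permissive pooling rule; the planted end-to-end analyses in
this package therefore run the scenario at `freq_threshold = 0.2` with
30 runs. Both the threshold and the run count are exposed
configuration; sequential and any permuted execution order give
identical tables.

## Clustering, enrichment, consensus

Latent factors are identified only up to rotation, so "the" latent
vectors of a run are not comparable across runs — but pairwise
*distances* between drugs are. The pipeline therefore averages the
drug-drug distance matrix over `n_ref_fits = 5` seeded fits before
clustering. Averaging distances damps two noise sources of a single
fit: initialization and, more importantly, the chance event that a
withheld true association is drawn as a training negative, which can
push exactly the drug one hopes to find away from its family.

Agglomeration is the standard Lance–Williams scheme (average linkage by
default; complete and single supported, all height-monotone) written
in-package so that ties in the minimal distance are broken by the
lowest pair of cluster creation indices — a documented, deterministic
rule that a generic implementation does not guarantee. An independent
naive implementation (recomputing set-to-set linkage from the raw
distance matrix at every step) serves as a test oracle.

Every tree node with size in `[min_size, max_size]` (defaults 3 and
$n-1$) is scored with the one-sided hypergeometric tail: the chance
that a random size-$n_c$ subset of the $N$ pooled drugs contains at
least the observed number $x$ of the $K$ known ligands. P-values are BH
corrected across the evaluated nodes and nodes with adjusted $p \le
\alpha$ (default 0.05) are kept.

**Collapsing nested significant nodes.** Significant nodes along one
ancestor-descendant chain describe the same signal. The package keeps
the *maximal* significant node per chain. The alternatives — keeping
the most significant or the smallest node — degenerate in a systematic
way: a node containing only known ligands maximizes the enrichment
statistic, so those rules preferentially return pure known-drug cores,
which by construction contain zero repurposable members and starve the
downstream consensus. The maximal significant node is the widest
neighborhood that still passes the corrected test, which is exactly the
set whose non-known members one wants to extract. Returned clusters are
pairwise disjoint (tree nodes are nested or disjoint).

The per-metric hit sets are the unions of enriched-cluster members;
consensus hits are their intersection, restricted to the
ensemble-selected candidates (known ligands seed the enrichment but are
not themselves repurposing hits).

## Chemical similarity scoring

The similarity stage uses a two-component combo score in $[0, 2]$: a
structural-fingerprint Tanimoto plus a chemical-feature-fingerprint
Tanimoto, with the conventional 1.5 threshold marking strong
similarity. Two scorer backends implement the same interface:

* `openbabel`: Open Babel path fingerprints (FP2) as the structural
  component and functional-group fingerprints (FP4) as the feature
  component, computed from SMILES via ChemmineR/ChemmineOB. Parsing goes
  through the molecular graph, so equivalent SMILES spellings give
  identical descriptors. The two components mirror the shape + color
  decomposition of 3D combo scoring while remaining deterministic and
  conformer-free; a 3D backend can be plugged in behind the same
  descriptor interface.
* `hex`: precomputed fingerprints serialized as hex strings in the
  molecule file's SMILES slot. The synthetic library generator emits
  this format, so the full pipeline runs without any chemistry backend.

Degenerate inputs: the Tanimoto of two all-zero vectors is defined as 1
(two empty molecules are identical), but `featurize()` rejects empty
fingerprint components upstream, so the case is unreachable through the
public path. A hit that is itself a member of the reference panel
scores 2.0 by self-match and trivially passes any threshold; this is
intended (identity is maximal similarity).

## What the synthetic generators emulate

`make_planted_dti()` draws nonnegative factors and defines positives as
the top density quantile of $U_{true}V_{true}^\top$, so the planted
rank is exact rather than sampled — sharper ground truth for recovery
tests. A seeded subset of positives is withheld as hidden true
associations; optional label noise drops a fraction of training
positives and adds as many false ones.

`make_drug_library()` plants fingerprint families: per-family prototype
bit vectors (density 0.3) with a fraction `mutation = 0.04` of bits
flipped per member. With 256-bit components this gives expected
within-family Tanimoto ≈ 0.78 (combo ≈ 1.57, above the 1.5 cut) and
between-family ≈ 0.18 (combo ≈ 0.35, far below it).

`make_planted_scenario()` couples the two: one family of drugs —
approved known ligands of the query target, one illicit known ligand,
and hidden repurposable members — shares a latent prototype
concentrated on two dedicated latent dimensions, a set of family-marker
targets whose factors load on the same dimensions, and a fingerprint
family. Three generator choices are deliberate:

* The query/marker target factors are rescaled so that every planted
  family association clears the global density threshold whatever the
  background draw; otherwise the plant itself can silently fail at some
  seeds, which would make recovery tests measure generator luck rather
  than method behavior.
* Hidden members sit at the family core (a quarter of the family's
  latent noise): their interaction profile is family-typical, which is
  the premise of the whole inference.
* Decoy drugs with random latent vectors and unrelated random
  fingerprints are planted as negative controls.

Default sizes (60 drugs × 25 targets, 11-member family, 3 decoys, 30
ensemble runs) keep a 20-replicate end-to-end recovery study around two
minutes on one CPU; the problem sizes are stated here as the package's
study conditions, and scale up by configuration.

What passing these tests does *not* show: real interaction networks
have heavy-tailed degree distributions, correlated annotation biases,
and chemistry far richer than mutated prototype fingerprints. The
planted structure demonstrates that each stage does what it claims and
that the chain composes; it does not calibrate expected hit rates on
real data.

## Reproducibility

Every stochastic step is a pure function of an integer seed. The
pipeline derives all stage seeds from one global seed by fixed offsets
(ensemble run $r$: `seed + 10000 + r`; reference fit $f$:
`seed + 20000 + f - 1`), so one integer reproduces a full run
bit-identically; the report records the seed list and a configuration
hash.

## Known limitations

* Binary associations only: multi-typed interactions (substrate vs
  inhibitor) are collapsed to positive edges, and the factorization
  treats all positives alike.
* Negative sampling treats unobserved cells as exchangeable; on real
  data, untested pairs are not missing at random.
* The hypergeometric null assumes the pooled drug set is a simple
  universe; candidates were themselves selected by the ensemble, so the
  enrichment p-values are conservative screening scores, not calibrated
  error rates.
* The 2D fingerprint surrogate ignores conformational shape; molecules
  with similar graphs but different 3D character are not distinguished.
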