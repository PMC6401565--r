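---
title: "Metabolite prioritization by network propagation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolite prioritization by network propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metrwr)
```

## The model

`metrwr` scores metabolites by their proximity to disease seed nodes in a
three-layer heterogeneous network. The layers are genes, metabolites and
phenotypes; the six edge sets are gene–gene interactions (confidence-scored,
STRING-style), metabolite–metabolite interactions (confidence-scored,
STITCH-style), phenotype–phenotype similarity scores, gene–metabolite
associations (confidence-scored), and curated phenotype–gene and
phenotype–metabolite associations (weight exactly 1 — a curated link is
treated as full-confidence evidence). All weights live in (0, 1] and are
used directly as transition propensities; no weight transform is applied
because none is canonical, and the identity keeps scores interpretable
against the input confidences.

A random walk with restart (RWR) on the composite network has fixed point

$$ p = (1-\beta)\,W p + \beta\,p_0 $$

where $W$ is column-stochastic, $\beta$ is the restart probability and
$p_0$ the restart (seed) distribution. Node scores are the stationary
probabilities; metabolites are ranked by score.

## The transition model on three layers

A heterogeneous walk must decide how to split a node's transition mass
between its own layer and other layers. We use the standard two-layer RWR-H
construction generalized to three layers: from a node with intra-layer
weighted degree $d_\text{intra} > 0$ and $k \in \{0,1,2\}$ cross-layer
blocks containing at least one of its edges,

* mass $1-\lambda$ is distributed over intra-layer neighbors proportional
  to edge weight,
* mass $\lambda$ is split **equally among the $k$ available cross-layer
  blocks**, within each proportional to edge weight,
* if $d_\text{intra} = 0$ the full mass crosses layers; if $k = 0$ it all
  stays intra-layer; if both are zero the node is dangling.

Splitting $\lambda$ equally among *available* blocks (rather than fixed
thirds) keeps columns stochastic without renormalization artifacts at nodes
that touch only some layers. The jump probability $\lambda$ is not a
published constant for this construction; the default 0.5 is the
conventional neutral choice and it is exposed as a parameter everywhere.

Dangling (isolated) nodes get all-zero columns, and the walk adds
$(1-\beta)\,m_d\,p_0$ at each step, where $m_d$ is the probability mass on
dangling nodes. Teleporting this mass to the seeds (instead of dropping it)
conserves total probability exactly, which makes the conservation invariant
in the test suite strict (1e-12) rather than approximate.

## Restart vector and parameters

The restart vector gives fraction $\eta$ (default 0.5) of its mass to the
phenotype seeds, split equally, and $1-\eta$ to the gene and metabolite
seeds, split equally; an empty category donates its mass to the other. With
the archetypal configuration of 6 seed genes and one disease phenotype, the
phenotype gets 0.5 and each gene 0.5/6.

Parameter defaults, units and rationale:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | strict FDR cutoff for DEG calls (`fdr < alpha`) |
| `min_combine_score` | 0.8 | gene-interaction confidence threshold, kept edges satisfy score ≥ 0.8 ("not less than") |
| `min_score_mm`, `min_score_gm` | 0 | no canonical threshold exists for these sources; keep all |
| `lambda_jump` | 0.5 | cross-layer jump probability |
| `beta` | 0.7 | restart probability, the convention of the heterogeneous-RWR literature |
| `eta_phenotype` | 0.5 | phenotype share of restart mass |
| `tol` | 1e-10 | L1 convergence tolerance of the power iteration |
| `max_iter` | 1000 | iteration cap; non-convergence is a warning, not an error |
| `top_k_metabolites` | 50 | ranking truncation |
| `top_n_genes` | 100 | co-expressed gene truncation |

Since the update map is an L1-contraction with factor $(1-\beta)$,
convergence is geometric and monotone; at $\beta = 0.7$ the default
tolerance is reached in well under 30 iterations on every network we
generate.

## Differential expression stage

The t-test is Welch by default: the archetypal design has unequal group
sizes (13 vs 21 whole-blood samples), where the unequal-variance form is
the safer default; the pooled Student form is available behind a flag for
exact replication attempts. Benjamini–Hochberg was chosen as the FDR
procedure as the near-universal default of array toolchains; the call uses
strict `fdr < alpha`. Degenerate genes (zero variance in both groups) give
`p = 1` when the group means are equal and `p = 0` with a warning when they
differ — the scan never crashes on constant rows.

## What the synthetic generator emulates — and what it does not

`generate_hetnet()` draws each of the six blocks as an independent-edge
(Erdős–Rényi) graph with uniform weights, then plants a disease
neighborhood: each seed gene is wired to the disease phenotype with weight
1 (the curated-association convention) and each true metabolite is wired to
at least one seed gene with its weight multiplied by `planted_boost`
(capped at 1). Defaults: 1000 genes, 400 metabolites, 100 phenotypes, 6
seed genes, 10 true metabolites, boost 5.

Density defaults (gg 0.01, mm 0.02, pp 0.05, gm 0.005, gp 0.002, mp 0.01)
were chosen once so mean degrees sit in the 2–10 range typical of
confidence-thresholded biological networks at this scale, and weights are
drawn Uniform(0.4, 1), emulating medium-to-high retained confidences. The
generator makes no attempt at realistic degree distributions (no scale-free
structure), community structure, weight–degree correlation, or biological
ID vocabularies. A green planted-recovery test therefore establishes that
the propagation machinery concentrates mass where the topology says it
should — not that the method would recover true disease metabolites from
real, heavy-tailed, ascertainment-biased networks.

`generate_expression()` draws i.i.d. Gaussian noise with a pure mean-shift
signal in the first `n_de` genes; it emulates the two-group design (13 case
/ 21 control by default) but not array artifacts, correlation between
genes, or heavy-tailed noise. The DEG calibration tests inherit these
limits: they verify the statistics, not robustness to real microarray
structure.

## Numerical choices and edge cases

* **Convergence metric**: L1 norm of successive differences, matching the
  probability-mass structure; every iterate sums to 1 to 1e-12.
* **Tie-breaking**: all rankings sort by score descending with ties broken
  by node ID ascending, making outputs fully deterministic.
* **Duplicate edges** collapse to the maximum weight — idempotent and
  preserves the strongest evidence; self-loops are dropped.
* **Strict thresholds**: score filtering keeps `score ≥ min_score`
  (0.799 < 0.8 is excluded, 0.800 included); DEG calls use `fdr < alpha`;
  the score report uses `score > threshold`.
* **Degenerate inputs**: empty seed sets, unmapped IDs, all-zero densities
  and unknown node IDs raise immediate, named errors; an unseeded
  disconnected component legitimately scores zero.
* The oracle solver is dense and guarded to 2000 nodes; it exists to verify
  the sparse power iteration, never to replace it.

## Design decisions that were genuinely open

* **"Co-expressed genes"** are operationalized as *genes adjacent to ranked
  metabolites through gene–metabolite edges, ordered by their own walk
  score*. The walk score is the only score distribution in the pipeline,
  and gene–metabolite adjacency is the only stated interaction; no
  expression-correlation computation is implied anywhere in the method, so
  none is performed.
* **Subnetwork node sets**: the top-metabolite subnetwork is induced on the
  ranked metabolites plus seed genes and seed phenotypes; the co-expression
  network on ranked metabolites, top genes and seed genes. Degrees are
  unweighted integer counts of induced edges.
* **Score threshold reporting** takes the threshold as a parameter and
  decides nothing: published threshold values for such scores can be
  internally inconsistent, so the report is purely descriptive.
* **Association cross-filtering**: gene–metabolite, phenotype–gene and
  phenotype–metabolite edges are restricted to nodes present in the
  *background* gene network (not the DEG-restricted one) and in the
  metabolite/phenotype networks, matching the reported magnitudes of such
  pipelines where the gene–metabolite layer retains far more genes than
  the DEG set.
* **Synthetic bundles disable the combine-score filter** (`config.txt`
  sets `min_combine_score = 0`): generator weights model *retained*
  confidences, i.e. the synthetic world is post-threshold. Re-applying a
  0.8 cut to Uniform(0.4, 1) weights would thin the gene layer and, at
  small test scales, strand seed genes — which the pipeline correctly
  treats as a hard error.

## Known limitations

* Three layers are hard-wired; directed or signed edges are out of scope.
* The dense oracle limits verification to networks of ≤ 2000 nodes;
  correctness at larger scales rests on the contraction argument and
  conservation invariants, not on a second solver.
* The pipeline starts from a normalized expression matrix; array
  preprocessing and probe-to-gene collapsing must happen upstream.
* Real-data headline numbers from source databases are not reproducible
  without their unversioned snapshots; the test suite is therefore
  property-based (oracle equivalence, conservation, analytic limits,
  planted recovery, calibration, determinism) rather than value-based.
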