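---
title: "Propagating metabolomic enrichment over a gene network: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating metabolomic enrichment over a gene network: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboprop)
```

## The problem

In patients with suspected inborn errors of metabolism (IEMs), exome
filtering typically leaves hundreds of candidate genes. Untargeted
metabolomics of the patient against a control cohort offers an orthogonal
line of evidence: if the metabolites annotated to a gene are abnormally
abundant, the gene's function is plausibly perturbed. Direct per-gene
enrichment, however, is blind to every gene whose metabolites are
unmeasured or unannotated — a large fraction in practice, since any one
chromatography/MS platform sees only part of the metabolome and many
genes have no annotated metabolites at all. This package scores genes by
their own metabolic enrichment *and* by the enrichment of their network
neighborhood, so that a gene can be prioritized when the metabolic
disturbance it causes is visible only around it.

## The model

**Seed scores.** For one patient, every measured metabolite carries a
z-score against controls; metabolites with |z| ≥ 2 (inclusive) are
differentially abundant (DAMs). For each gene with m annotated measured
metabolites, of which k are DAMs, with K DAMs among the M
measured-and-annotated metabolites, the one-sided over-representation
p-value is the hypergeometric upper tail P(X ≥ k). The metabolic
enrichment (ME) score combines the **unadjusted** p with the gene's
largest-magnitude metabolite z-score Z (BH-adjusted FDRs are reported but
deliberately not used for scoring). Two transforms are available:

* `neglog` (default): ME = −log2(p) · Z. Jointly monotone — stronger
  enrichment and stronger perturbation both increase the score.
* `eq3_literal`: ME = −log2(2 + p) · Z, retained for strict reproduction
  of the originally published transform. Because −log2(2 + p) lies in
  [−1.585, −1], this raw score *decreases* as Z grows, which contradicts
  the transform's own motivating description ("multiply the scaled
  p-value by the absolute value of the largest z-score"). We treat the
  printed form as a transcription artifact, default to `neglog`, and test
  both.

Raw ME scores of genes with k ≥ 1 are min–max scaled; genes with k = 0
(including genes with no measured metabolites) are pinned to exactly 0.
The minimum-scoring k ≥ 1 gene therefore also receives 0 — an unavoidable
property of min–max scaling; the invariants that matter downstream (zero
floor for unenriched genes, maximum seed exactly 1, all-equal scores
scale to 1) all hold.

**Propagation.** Seeds y are smoothed over the weighted functional-linkage
network with symmetrically normalized weights
w′~ij~ = w~ij~ / √(d~i~ d~j~), d~i~ = Σ~j~ w~ij~, by iterating

f^(r)^ = λ W′ f^(r−1)^ + (1 − λ) y.

Since the spectral radius of W′ is at most 1 and 0 < λ < 1, this
contracts to the unique fixed point f = (1 − λ)(I − λW′)^−1^ y, which
`propagate_exact()` computes by a dense solve and which serves as the
oracle in the test suite. λ defaults to 0.99 — the standard value for
this family of semi-supervised graph algorithms, placing almost all
weight on the network term — and is deliberately not tuned. STRING-style
combined scores (integers 0–1000) are used as raw weights: the
normalization is invariant to global weight scaling, so no rescaling is
needed.

**Ranking and fusion.** Candidates are ranked by descending score with
competition (minimum) ranks for ties — conservative for any top-k
criterion — and percentile 100·rank/N; "top 20th percentile" (rank ≤ 60
of 300) is the conventional success criterion. When an external
phenotype score E (e.g. Exomiser's hiPHIVE phenotype score) is available,
the combined score is

C = scaled(p·E) + scaled((1 − p)·M),

where M is the propagated score and p is a per-gene prior: network genes
are binned by the percentage of their first-degree neighbors carrying
metabolite annotations (deciles, last bin closed), and p is the fraction
of each bin's genes that the patient's full-network propagated ranking
already places in the top 20%. Genes with metabolite-rich neighborhoods
are structurally prone to high propagated scores regardless of disease
status, so the prior shifts their weight onto the phenotype evidence.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `dam_threshold` | 2 | |z| cut-off (in control SDs) for differential abundance, boundary inclusive |
| `lambda` | 0.99 | propagation weight on the network term |
| `tol` | 1e−6 | L∞ convergence tolerance of the iterative solver |
| `ppm_tol` | 15 | relative mass tolerance for feature annotation, boundary inclusive |
| `adduct_model` | protonation | ±1.007276 Da by ionization mode for raw LC-MS features; `neutral` for tables already on the neutral-mass scale |
| `scoring_mode` | neglog | ME transform (see above) |
| `top_fraction` | 0.20 | "prioritized" cut-off used in the fusion prior |

## Numerical choices

* **Convergence.** The iterate stops when the L∞ change drops below
  `tol`; with λ = 0.99 the distance to the fixed point is bounded by
  roughly 100× the last change, so `tol = 1e-6` keeps scores stable well
  past ranking resolution. Initialization is f^(0)^ = y (any start
  converges; this one is documented for reproducibility).
  Non-convergence raises a structured error carrying the last iterate
  and residual.
* **ppm boundary.** Matching is inclusive with the candidate
  (theoretical) mass in the denominator; an epsilon of 1e−6 ppm absorbs
  IEEE representation error exactly at the boundary (e.g. 300.0045 vs
  300.0000 evaluates to 15.000000000024 ppm in doubles).
* **z-scores.** Sample (n−1) standard deviation, patient included in the
  reference by default (a leave-patient-out flag exists). Constant
  features are dropped with a warning. Positive- and negative-mode
  tables are merged keeping the z of largest magnitude per metabolite.
* **Baseline normalization is not strictly idempotent.** The baseline is
  the per-feature *median* profile while the scaling factor is a ratio
  of *means*; after one pass all sample means are equal, so a second
  pass multiplies every sample by one common factor (generally ≠ 1).
  This global rescale leaves all downstream z-scores, and hence every
  ranking, unchanged — the invariant the tests assert.
* **Ties and absentees.** Competition ranks everywhere; candidates
  absent from the network or score table get score 0 and sort last.
  Off-network candidates receive fusion prior p = 1 (their propagated
  term is 0 regardless, and down-weighting their only evidence stream
  would be perverse).
* **Degenerate enrichment.** k = 0 gives p = 1 exactly; K = M (every
  measured metabolite differential) gives p = 1 for every gene; genes
  with m = 0 are reported untested rather than assigned a p.

## What the synthetic generator emulates — and what it does not

`synth_config()` fixes the desk-scale study conditions: a 500-gene
scale-free network (preferential attachment, 3 edges/node, STRING-like
integer weights 150–999), 60% of genes annotated with 2–6 metabolites
drawn from a shared pool (so metabolites can belong to several genes, as
in HMDB), standard-normal background z-scores, and a disease signal
implanted as a randomly signed z-shift of 3 on the metabolites of the
perturbed gene(s). The three causative modes correspond to the method's
regimes: `direct` (the gene's own metabolites move — direct enrichment
suffices), `neighbor_only` (the causative gene is unannotated and only
its ≥3 annotated first neighbors move — only propagation can rescue it),
and `null` (an unrelated gene moves). Patient i derives its RNG stream
from the configured seed plus i, so cohorts are reproducible
patient-by-patient. Raw-mode fixtures add log-normal intensities, 5-ppm
m/z jitter on protonated masses, unannotated noise features and [M+1]
isotope features for the filters to remove.

The generator does **not** emulate: correlated metabolite panels,
batch/injection-order effects, heteroscedastic or missing-not-at-random
intensities, retention-time information, adducts beyond ±H, or the
literature biases of a real functional-linkage network. Passing tests
therefore demonstrate algorithmic correctness and the intended
qualitative behavior (neighborhood rescue, mode contrasts), not clinical
performance on real cohorts.

A note on the signal model: with a signed shift of 3 against unit noise,
~16% of planted metabolites stay below the |z| ≥ 2 threshold, so in
`direct` mode the causative gene has the single smallest enrichment p in
about 85% of patients (and is within the top 3 in ~95%) — dominance is
frequent, not universal, which is the realistic regime the defaults are
meant to occupy.

## Problem sizes used in the checks

The bundled verification runs use 50-patient cohorts on 500-gene
networks, 50 random graphs up to 500 nodes for the solver-vs-resolvent
comparison, exhaustive hypergeometric enumeration for all margins with
M ≤ 12, and the full 1000 × 300 permutation protocol on a 2000-gene
universe. These sizes make every property checkable in seconds to a few
minutes on a single core while leaving the algorithms identical to what
one would run on a full 19k-gene network — the propagation solver is
sparse and scales linearly in edges per iteration.

## Known limitations

* Propagation is defined only on the network: genes absent from it can
  never gain metabolomic signal and are ranked by external evidence
  alone.
* The fusion prior is computed per patient from that patient's
  propagated ranking; pooling across a cohort would estimate it more
  stably but would make the tool cohort-dependent. Whether the original
  analysis pooled is ambiguous; the per-patient choice keeps the tool
  applicable to a single case.
* The stage at which min–max scaling enters the fusion (inputs, then
  weighted terms) is one defensible reading of "each term is scaled
  before being added"; it is fixed in code and covered by the
  degeneracy tests (prior 1 ⇒ phenotype-only ranking, prior 0 ⇒
  propagation-only ranking).
* Isotope handling trusts the upstream annotation column verbatim (any
  flag containing a non-zero index, e.g. `[M+1]`, is non-base); isotope
  envelopes are not re-derived.
* Physical-only network filtering keeps edges whose `binding` channel
  sub-score is positive; other extraction recipes from channel evidence
  are possible but out of scope.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- synth_config(n_genes = 200, causative_mode = "neighbor_only",
                    seed = 11)
net <- make_network(cfg)
map <- make_gene_metabolite_map(cfg, net)
pat <- make_patient(cfg, net, map)

res <- run_score(net, map, pat$zscores,
                 candidates = c(pat$causative,
                                sample(net$nodes, 99)))
subset(res$rankings$netprop, gene == pat$causative)
subset(res$rankings$ME, gene == pat$causative)   # zero-score floor
```
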