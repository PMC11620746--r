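---
title: "Simulating and analysing thymocyte TCR repertoires across life stages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing thymocyte TCR repertoires across life stages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thymorep)
```

## The scientific setting

T-cell receptors (TCRs) are assembled by somatic V(D)J recombination:
each alpha chain joins one TRAV to one TRAJ gene segment, each beta chain
one TRBV to (a D segment and) one TRBJ. The junction between the chosen
segments — the CDR3 — is diversified by exonucleolytic trimming of the
germline ends and by non-template (N) nucleotides added by the enzyme TdT.
Thymocyte development proceeds from CD4+CD8+ double-positive (DP) cells
through MHC-restricted positive selection into CD4 (SP4) or CD8 (SP8)
single-positive cells.

The foetal thymus differs from the young adult thymus in ways that leave
clear statistical fingerprints on clonotype tables:

* **TdT is absent before birth**, so foetal junctions carry few
  N-nucleotides and are shorter; with less junctional entropy, different
  individuals converge on the same CDR3s more often (higher inter-individual
  Jaccard sharing) and a higher fraction of out-of-frame transcripts
  survives to be sequenced.
* **Progressive TRA rearrangement is rarer in foetal DP cells.** Secondary
  rearrangements consume TRAV segments 3'→5' and TRAJ segments 5'→3', so
  foetal alpha repertoires stay biased toward 3' TRAV and 5' TRAJ segments;
  adult repertoires walk away from that proximal corner. Hydrocortisone
  depletion of the adult thymus synchronises a recovering DP cohort that is
  "young" in this respect and re-acquires the foetal-like proximal bias
  while keeping adult insertion machinery.
* **Foetal repertoires are smaller and more clonally expanded**: clone-size
  spectra have a heavier tail (lower power-law exponent), the top 1% of
  clones holds a larger share of all molecules, and rarefied Shannon
  entropy is lower / Gini index higher.
* **MHC restriction shapes adult SP repertoires more strongly**, visible as
  per-V (equivalently CDR1×CDR2) usage divergence between SP4 and SP8 and a
  dominant principal component separating the lineages.

This package implements the full analysis repertoire for such clonotype
tables — discrete power-law maximum likelihood, rarefied diversity indices,
combinatorial V×J differential usage with FDR control, junction
decomposition, CDR1×CDR2 recoding, and the log10/z-score/PCA procedure —
plus a seeded simulator that reproduces all of the fingerprints above, so
every analysis stage is testable without sequencing data.

## The generative model

`build_catalog()` creates a synthetic germline locus at mouse scale (98
TRAV, 60 TRAJ, 22 TRBV, 12 TRBJ by default). Every V junction region begins
with a cysteine codon, every J region ends with a phenylalanine codon, all
regions are length-divisible by 3 and stop-free in the anchored frame, and
TRBJ segments split into a 5' cluster 1 and a 3' cluster 2. Segment names
are opaque keys — TRAJ names descend 5'→3' exactly because the real locus
does, so that no code is tempted to parse chromosomal order out of names;
order always comes from `chromosomal_index`.

One sample is generated by `simulate_sample()` in seeded stages (one root
seed split into named substreams, so adding a stage never perturbs earlier
draws):

1. **Segment choice.** The initial V is drawn at a geometric rank distance
   (rate `proximal_bias`) from the 3' end of the V array, the initial J
   from the 5' end of the J array; `proximal_bias = 0` degenerates to
   uniform choice. For TRA, `Poisson(rearrangement_rounds_mean)` additional
   rounds each move the V index 5'-ward and the J index 3'-ward by
   independent `1 + Geometric(0.5)` steps (a round must consume at least
   one segment), clamped at the array ends; only the final pair is emitted,
   matching excision of intermediates. For TRB a single round picks the
   TRBJ cluster first (cluster 1 with probability `trbj_cluster1_weight`).
2. **Junction formation.** `Geometric(deletion_mean)` basepairs are trimmed
   from each germline end (capped so the anchor codons survive) and
   `Geometric(insert_mean)` uniform-random nucleotides inserted. For the
   beta chain the D-region nucleotides are deliberately folded into the
   insert — "insert" here means *non-V, non-J* nucleotides, the same
   convention the downstream decomposition measures.
3. **Selection.** In SP populations each clonotype is retained with
   probability `(w/max w)^selection_strength`, where `w` is a fixed per-V
   lineage weight (lognormal, seeded with the catalog). DP populations pass
   through; `selection_strength = 0` is neutral.
4. **Composition and deduplication.** Candidates are generated in batches,
   deduplicated on (V, J, junction), and composed so that the retained
   out-of-frame fraction is `Binomial(n, nonproductive_rate)` — modelling
   nonsense-mediated decay that eliminates most, but not all,
   non-productive transcripts.
5. **Clone sizes.** Each unique clonotype receives an abundance drawn from
   the zeta distribution `P(K = k) ∝ k^(-alpha)` on `k ≥ 1` via inverse-CDF
   on the Hurwitz-zeta-normalised pmf. Sizes are independent of V/J
   identity.

## Preset parameters

`preset()` bundles the life-stage conditions. Directions come from the
biology summarised above; magnitudes are this package's own choices, fixed
once and documented here.

| parameter | unit | foetal | adult | adult_hc | why |
|---|---|---|---|---|---|
| `proximal_bias` | /rank | 0.25 | 0.10 | 0.10 | foetal V–J pairing sits nearer the proximal corner |
| `rearrangement_rounds_mean` | rounds | 0.3 | 2.0 | 0.3 | progressive TRA rearrangement rare in foetal and in the synchronised HC-recovery cohort |
| `insert_mean` (TRA / TRB) | bp | 1.0 / 2.0 | 3.5 / 4.5 | 3.5 / 4.5 | TdT absent in foetal; beta inserts include D-region nucleotides, hence never ~0 |
| `deletion_mean` | bp | 0.08 | 0.08 | 0.08 | see *Numerical choices* |
| `clone_size_alpha` | – | 2.2 | 3.2 | 3.2 | heavier foetal tail = more clonal expansion |
| `selection_strength` | – | 0.5 | 2.0 | 2.0 | weaker MHC-restriction of the foetal repertoire |
| `nonproductive_rate` | fraction | 0.12 | 0.08 | 0.08 | more out-of-frame transcripts persist in foetal samples |
| `trbj_cluster1_weight` | prob. | 0.65 | 0.50 | 0.50 | foetal preference for the 5' TRBJ1 cluster |
| `n_clonotypes` (DP / SP) | clones | 4500 / 1500 | 12000 / 3000 | 12000 / 3000 | foetal repertoires are genuinely smaller; see below |

The hydrocortisone preset is adult in every respect except the
rearrangement-round count: the recovering DP cohort has had little time for
secondary TRA rearrangement.

**Why foetal defaults are smaller.** At TdT-free insertion rates the space
of distinct productive beta junctions over a 22×12 segment grid is only a
few thousand sequences; a foetal-sized unique-clonotype table simply cannot
be as large as an adult one. This is not an artefact — it is the mechanism
behind the foetal diversity deficit — but it means requesting
`n_clonotypes` far above that bound triggers a warning and a smaller
sample.

**Convergent recombination.** Because samples are deduplicated to unique
clonotypes, the *clonotype-level* insert-length distribution is not the raw
geometric: zero-insert junctions collapse into few unique sequences while
long-insert junctions almost never collide. Distribution-level checks on
the junction model therefore test `make_junction()` draws directly, and
sample-level statistics (e.g. the abundance-weighted mean insert length)
are compared between groups, not against the raw `insert_mean`.

## The analysis procedures

* **Clone-size spectrum and power law.** `clone_size_spectrum()` reports,
  for each clone size `k`, the proportion of all molecules in clones of
  that size. `fit_power_law()` maximises the discrete power-law
  log-likelihood `-alpha * sum(log k_i) - n * log zeta(alpha, xmin)` over
  `alpha` in (1.01, 30]. `xmin` is fixed at 1 by default (the whole
  distribution is fitted and plotted); a Clauset-style
  `estimate_xmin = TRUE` mode minimises the tail Kolmogorov–Smirnov
  distance for users who want it. `clonality_stats()` uses the nearest-rank
  99th percentile and takes clonotypes *strictly above* it; when ties empty
  that set it falls back to the `ceiling(0.01 n)` largest clonotypes and
  says so.
* **Rarefied diversity.** `rarefy()` subsamples molecules without
  replacement (every UMI equally likely). Shannon entropy uses the natural
  logarithm (base is an argument); the Gini index is computed on the
  unique-clonotype abundance vector of the subsample, with absent
  clonotypes excluded rather than zero-padded. Jaccard similarity is
  computed on amino-acid CDR3 sets of productive clonotypes, subsampling a
  fixed number of *distinct* CDR3s uniformly per repeat; nucleotide-level
  and abundance-weighted modes are both provided because published
  pipelines differ on this choice.
* **V×J differential tiling.** Per-sample proportions over the full V×J
  grid (abundance-weighted by default); a combination is "detected" in a
  sample iff its count is positive; combinations missing from a whole
  group are tiled `absent_*`, those detected in fewer than `min_detected`
  samples per group are `not_compared`, and the rest get an unpaired
  Student's t-test with Benjamini–Hochberg adjustment across the panel's
  compared cells.
* **Junction decomposition.** Greedy maximal contiguous matching, V before
  J, no mismatches — appropriate for UMI-corrected clonotypes, where
  sequencing errors have already been collapsed. The insert is whatever
  matches neither germline end, which for beta chains includes the D
  segment.
* **PCA.** Counts (zeros replaced by a 0.01 pseudocount — applied to zeros
  only), log10, per-feature z-score, then SVD of the centred matrix; this
  equals correlation-matrix PCA. No additional library-size normalisation
  is applied: the log/z transform is the size correction. Component signs
  are fixed by making each component's largest-magnitude loading positive.
* **Scalar group tests.** "Student's or Welch's t-test as appropriate" is
  operationalised by a Levene pre-test at alpha = 0.05 (two-group form:
  pooled t-test on absolute deviations from the group mean); `method =
  "student"`/`"welch"` forces either.

## Numerical choices

* **Hurwitz zeta** is evaluated by 25 direct terms plus an Euler–Maclaurin
  tail with Bernoulli corrections through `B12`; relative error is far
  below the 1e-10 target across the optimisation range. The zeta sampler
  inverts the exact CDF, growing its cumulative table geometrically and
  clamping only beyond `2^22` (probability < 1e-8 at the presets' smallest
  exponent).
* **Degenerate power-law inputs**: if every observation equals `xmin` the
  likelihood increases without bound, so the fit returns
  `converged = FALSE` instead of a number; a maximiser within 1e-3 of the
  upper bound is likewise flagged.
* **deletion_mean = 0.08 bp** is deliberately small. The greedy
  decomposition can only mis-measure an insert when a trimmed germline end
  is mimicked by chance (probability 1/4 per adjacent nucleotide), so exact
  insert recovery is about `(1 - P(del ≥ 1)/4)^2` ≈ 96% at 0.08 bp and
  would fall to ~68% at a biologically realistic 2.5 bp. The package keeps
  the documented ≥95% recovery contract and flags the shallow trimming as a
  known unrealism of the simulator; users fitting real data should expect
  the inferred insert to be a lower bound on the true one.
* **Ties and empty cases**: the top-1% fallback above; Gini on a rarefied
  subsample that happens to contain a single clonotype is defined as 0;
  constant features are dropped (with a warning) before z-scoring because
  they carry no variance direction.
* **Reproducibility**: every stochastic routine either takes an explicit
  `seed` or documents that it uses the current RNG stream; seeded routines
  pin the RNG kind (Mersenne-Twister / Rejection sampling) and restore the
  caller's RNG state, and simulation substreams are derived by a
  deterministic hash of (seed, stage name).

## What a green test establishes — and what it does not

The test suite demonstrates that the analysis stack recovers the parameters
and the qualitative life-stage contrasts of the *simulated* world: power
law exponents within ±0.05 at n = 50,000, the foetal/adult Shannon and Gini
ordering with p < 0.05 at cohort-realistic group sizes, the 3'V/5'J centroid
shift of foetal-increased V×J tiles, the selection-driven SP4/SP8 PC1
dominance in adult repertoires, and the hydrocortisone 5'TRAJ recovery.
The simulator is a stylised mechanism, not mouse germline reality: segment
sequences are random (not IMGT alleles), trimming is unrealistically
shallow (above), D segments are not called explicitly, alpha/beta pairing
and allelic exclusion are not modelled, and clone sizes are independent of
segment identity. Green tests therefore establish the correctness of the
*procedures* and the internal consistency of the simulator's stated world —
they do not, by themselves, reproduce any specific published effect size
from sequencing data. The `read_airr()`/`read_manifest()` path exists to
run the identical procedures on real clonotype tables.

## Session info

```{r}
sessionInfo()
```
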