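# thymorep

Clonotype-level analysis of mouse thymocyte T-cell receptor (TCR) α- and
β-chain repertoires across life stages, plus a seeded V(D)J rearrangement
simulator for testing every analysis stage without sequencing data.

## Who this is for

Immunologists and computational biologists comparing TCR repertoires of
FACS-sorted thymocyte populations (DP, SP4, SP8) between conditions —
foetal vs young adult, or hydrocortisone-depleted recovering thymus vs
control — starting from UMI-corrected clonotype tables (AIRR Rearrangement
TSV: `v_call`, `j_call`, `junction`, `duplicate_count`, ...).

## What it computes

* **Clone-size spectra and power laws.** The clone-size distribution is
  fitted to a discrete power law *f*(*k*) = *Ck*<sup>−α</sup> by maximum
  likelihood: α maximises −α Σ ln *k<sub>i</sub>* − *n* ln ζ(α, *x*min),
  with ζ the Hurwitz zeta function. Lower α = heavier tail = more clonal
  expansion. Top-1% clonality statistics use the nearest-rank 99th
  percentile.
* **Rarefied diversity.** Repertoires are subsampled without replacement to
  a common molecule depth (1000 repeats by default) before computing
  Shannon entropy *H* = −Σ *p<sub>i</sub>* ln *p<sub>i</sub>*, the Gini
  index *G* = Σ<sub>ij</sub>|*x<sub>i</sub>*−*x<sub>j</sub>*|/(2*n*²x̄),
  and the Jaccard similarity |A∩B|/|A∪B| of CDR3 sets between individuals.
* **V×J differential usage.** Per-sample proportional usage over the full
  V×J grid in chromosomal order; combinations detected in ≥ 3
  mice/embryos per group are compared by unpaired Student's t-test with
  Benjamini–Hochberg FDR adjustment, and every grid cell is tiled
  (increased / decreased / no_change / absent / not_compared), as in the
  red-blue tile plots of repertoire papers.
* **Junction features.** Productivity classification (frame, stops, C/F-W
  anchors), greedy decomposition of each junction into V match + insert +
  J match (β inserts include D-region nucleotides), abundance-weighted
  mean insertion length, mean CDR3 length, CDR1×CDR2 recoding of V usage.
* **PCA.** log10 with pseudocount 0.01 on zero counts, per-feature
  z-score, SVD; variance fractions and per-feature contributions per
  component.
* **Simulator.** `preset("foetal"/"adult"/"adult_hc")` +
  `simulate_sample()` generate repertoires with the life-stage structure
  the analyses are meant to detect: proximal 3'V/5'J bias and progressive
  TRA rearrangement, TdT-dependent insert lengths, zeta-distributed clone
  sizes, per-V lineage selection in SP populations, and a retained
  out-of-frame fraction — with full ground truth per clonotype.

See `vignettes/thymocyte-repertoires.Rmd` for the model, parameter
rationale, and numerical choices.

## Worked example

```r
library(thymorep)
catalog <- build_catalog(seed = 1)                    # synthetic germline loci
foetal  <- simulate_group("foetal", 3, "DP", "TRB", catalog, seed = 10)
adult   <- simulate_group("adult",  3, "DP", "TRB", catalog, seed = 20)

fit_power_law(foetal[[1]]$clonotypes$abundance)
#> <power_law_fit> alpha = 2.1787 (xmin = 1, n_tail = 4500, converged)

clonality_stats(foetal[[1]])$top_share
#> [1] 0.2874656

H_f <- sapply(seq_along(foetal), function(i)
  rarefied_index(foetal[[i]], "shannon", depth = 10000,
                 n_repeats = 200, seed = i)$mean)
H_a <- sapply(seq_along(adult), function(i)
  rarefied_index(adult[[i]], "shannon", depth = 10000,
                 n_repeats = 200, seed = 10 + i)$mean)
round(c(foetal = mean(H_f), adult = mean(H_a)), 2)
#> foetal  adult
#>   6.76   8.90
scalar_group_test(H_f, H_a)[c("test_name", "p_value")]
#> $test_name
#> [1] "welch"
#> $p_value
#> [1] 0.008916562

table(differential_vxj(foetal, adult, catalog)$tile)
#>    decreased    increased    no_change not_compared
#>           87            3          155           19
```

Reading: the simulated foetal DP β repertoire has a heavier clone-size tail
(α ≈ 2.18; its top 1% of clones holds ~29% of all molecules), is
significantly less diverse than the adult one at matched depth (Shannon
6.76 vs 8.90, Welch p ≈ 0.009), and its V×J usage differs across 90 grid
cells at 5% FDR. Real AIRR TSVs enter the same functions via `read_airr()`
or `read_manifest()`; `run_cohort(cohort_config(...))` runs the whole
study design end-to-end.

## Command line

```sh
thymorep simulate --preset foetal --cell-type DP --chain TRB \
    --n 5000 --seed 7 --out sample.tsv --truth sample.truth.tsv
thymorep stats --in sample.tsv --out stats.json
thymorep diversity --manifest samples.tsv --stat shannon \
    --depth 10000 --repeats 1000 --seed 7 --out div.tsv
thymorep run --out-dir results/ --seed 1
```

(`exec/thymorep` after installation, or
`Rscript -e 'thymorep::thymorep_cli(...)'`.)

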