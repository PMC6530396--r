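# dupribo

Translational-efficiency divergence between duplicate genes, from paired
ribosome-profiling and mRNA-seq counts.

## The problem

Plant genomes are full of duplicate genes — paralog pairs left by
whole-genome duplications (WGD) and by tandem duplication. How the two
copies of a pair diverge in expression is usually measured at the mRNA
level only. Ribosome profiling (ribo-seq) adds the translational layer:
the ribosome-footprint (RF) abundance of a gene, and its translational
efficiency TE = RF FPKM / mRNA FPKM. `dupribo` is for researchers asking
whether translation *buffers* or *reinforces* the transcriptional
divergence between paralogs, whether expression divergence is mostly
transcriptional, whether the faster-evolving copy is the lower-expressed
one, and whether duplicates change TE across tissues or stresses more
often than singletons.

## What it computes

For each paralog pair, in its fixed gene order, the signed relative
divergence of any per-copy quantity X (mRNA, RF, TE, Ka):

    RD = (X2 - X1) / (X1 + X2)   in [-1, 1]

and the symmetric fold difference FD = max(X1,X2)/min(X1,X2), with
FD = (1+|RD|)/(1-|RD|). A pair is **buffered** when |RD_RF| < |RD_mRNA|
and **reinforced** when the inequality is reversed; directionality is
tested with an exact two-sided binomial test. Transcription and
translation are contrasted by a paired Wilcoxon signed-rank test on
log2 fold differences. Sequence divergence per pair uses
Nei–Gojobori-style Ka/Ks counting with Jukes–Cantor correction on
(paralog1, paralog2, outgroup) codon triplets, and asymmetric evolution
is called by a likelihood-ratio test of a molecular clock (paralog branch
lengths equal vs free) under JC69, 2ΔlnL ~ χ²(1), with BH-FDR.
Differential TE between two conditions is detected per gene by a
negative-binomial GLM with an assay × condition interaction and a χ²(1)
LRT. Duplicate classes (WGD / tandem / other / singleton) come from a
curated WGD pair list, rule-based tandem clustering (same family, ≤ 10
intervening genes, within 100 kb on one chromosome), and BLAST E-value
thresholds (1e-10 / 1e-3).

Every input can be simulated with known ground truth — paralog expression
with a tunable buffering coefficient, NB replicate counts, annotations
with planted tandem clusters, and codon triplets evolved under known
branch lengths — so the whole pipeline is testable end to end.

## Worked example

```r
library(dupribo)

params <- sim_params(n_pairs = 500, beta = 0.5, seed = 42)
ds <- simulate_te_dataset(params)

mrna <- average_replicates(fpkm_from_counts(ds$counts$mrna_c1, ds$lengths))
ribo <- average_replicates(fpkm_from_counts(ds$counts$ribo_c1, ds$lengths))
pd <- pair_divergence_table(ds$pairs, mrna, ribo)
calls <- classify_buffering(pd[pd$pass, ])
buffering_summary(calls)
#>         subset n_pairs n_buffered n_reinforced n_ties buffered_fraction      binom_p
#> 1          all     500        330          170      0         0.6600000 7.407669e-13
#> 2 te_fold_ge_2     102         87           15      0         0.8529412 1.653403e-13

correlate_divergences(calls$rd_mrna, calls$rd_te)
#> Pearson r(RD_mRNA, RD_TE) = -0.759 (p = 4.72e-95, n = 500)

compare_fold_differences(calls$fd_mrna, calls$fd_te)
#> mRNA fold difference dominant in 324/500 pairs (Wilcoxon p = 1.3e-14)
```

With a buffering coefficient of 0.5, 66% of pairs are buffered (binomial
p ≈ 7e-13), rising to 85% among pairs with at least a twofold TE
difference; the mRNA/TE divergence correlation is strongly negative; and
the mRNA fold difference exceeds the TE fold difference for 65% of pairs
— transcription sets the divergence, translation modulates it.

A triplet with one fast paralog branch:

```r
tri <- simulate_triplet_sequences(b1 = 0.3, b2 = 0.05, b_out = 0.4,
                                  n_codons = 500, seed = 1)
rate_estimates(tri)[, c("ka_1out", "ka_2out", "rd_ka", "lrt_stat", "lrt_p")]
#>   ka_1out ka_2out  rd_ka lrt_stat    lrt_p
#> 1   0.668   0.397 -0.255      118 1.95e-27
```

Copy 1 (the long branch) shows the larger Ka to the outgroup, the signed
Ka divergence points at it, and the clock is rejected decisively.

The full pipeline — simulate, classify, quantify, test, report — runs from
one seed:

```r
report <- run_pipeline(run_config(seed = 1, out_dir = "run1"))
```

or from the shell via the bundled script:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/dupribo.R", package="dupribo"))')" \
    run --seed 1 --out-dir run1
```

Reruns with the same seed produce a byte-identical `report.json`.

## Layout

- `R/` — simulators, classification, quantification, divergence
  statistics, Ka/Ks and clock LRT, differential TE, pipeline, CLI.
- `tests/testthat/` — unit, property and end-to-end tests, with
  independent oracles (PMF enumeration, step-up arithmetic, exhaustive
  codon-pathway enumeration) in `helper-oracles.R`.
- `vignettes/duplicate-translational-divergence.Rmd` — the methods
  vignette: models, assumptions, parameter defaults, numerical choices
  and limitations.
- `inst/scripts/dupribo.R` — command-line entry point
  (`simulate`, `classify`, `quantify`, `stats`, `rates`, `diffte`, `run`).
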