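---
title: "Translational-efficiency divergence between duplicate genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translational-efficiency divergence between duplicate genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupribo)
```

# Scope

`dupribo` implements an analysis pipeline for translational regulation of
plant duplicate genes from paired ribosome-profiling (ribo-seq) and
mRNA-seq fragment counts. The questions it addresses are: when two paralogs
diverge in mRNA abundance, does translational efficiency (TE) tend to
counteract ("buffer") or amplify ("reinforce") that divergence; is
expression divergence mostly transcriptional or translational; does the
faster-evolving copy carry lower ribosome-footprint (RF) abundance; and are
duplicates more likely than singletons to change TE across tissues or
stress conditions. All statistics are exercised end-to-end on synthetic
cohorts with known ground truth.

# Statistics and models

## Relative divergence and fold difference

For any positive per-copy quantity (mRNA FPKM, RF FPKM, TE, Ka), the signed
relative divergence of a pair in its fixed gene order is

$$RD = \frac{X_2 - X_1}{X_1 + X_2} \in [-1, 1],$$

antisymmetric under swapping the copies and strictly increasing in the
ratio $X_2/X_1$. The symmetric fold difference is
$FD = \max(X_1,X_2)/\min(X_1,X_2)$, related to RD by
$FD = (1+|RD|)/(1-|RD|)$; both identities are property-tested.

## Expression quantification

FPKM is computed from counts as
$\mathrm{count} / (L/10^3) / (N/10^6)$ with $L$ the effective gene length
and $N$ the per-replicate total of counted fragments over all genes — a
count-based normalization, not a transcript-assembly estimate. Replicates
are averaged arithmetically; genes with average FPKM below 0.1 in an assay
and condition are filtered out (the boundary value 0.1 passes). TE is the
ratio of ribo-seq to mRNA-seq average FPKM. A pair contributes to a
condition only if both copies pass the filter in both assays, so TE and all
four relative divergences are defined; no pseudocounts are used anywhere —
the filter removes near-zero denominators. The filter is applied per assay
and condition separately.

## Translational buffering

A pair is *buffered* when $|RD_{RF}| < |RD_{mRNA}|$ and *reinforced* when
the inequality is reversed; equality (exactly the case of equal TE between
copies) is a *tie* and is excluded from the binomial denominator. Because
RD is strictly monotone in the ratio, this criterion is equivalent to
comparing $|\log_2$ RF ratio$|$ against $|\log_2$ mRNA ratio$|$, and the
implementation is tested for total agreement with that brute-force oracle.
The buffered count is tested against 0.5 with an exact two-sided binomial
test (minimum-likelihood two-sidedness, identical to equal-tail doubling at
$p_0 = 0.5$). The same machinery is applied to the subset with TE fold
difference at least 2.

One subtlety worth stating: with *independent* TE noise and no buffering
at all, $|RD_{RF}|$ is stochastically larger than $|RD_{mRNA}|$, so the
expected buffered fraction sits slightly *below* 0.5 (about 0.45 at
$\sigma_t = 0.3$, $\sigma_d = 1$) and approaches 0.5 only as the TE noise
vanishes. An observed buffered *majority* is therefore conservative
evidence for buffering. The generator's null behaviour is tested in the
vanishing-noise limit, where every pair approaches a tie and the
informative fraction is a fair coin.

## Transcription versus translation

The contrast of per-pair fold differences uses the paired two-sided
Wilcoxon signed-rank test on $\log_2 FD_{mRNA} - \log_2 FD_{TE}$ (zero
differences dropped, exact null distribution for up to 25 informative
pairs without ties, normal approximation with continuity correction
otherwise), alongside counts of pairs with the larger mRNA fold difference
and an exact binomial test.

## The shared-measurement control

$RD_{TE}$ contains the mRNA measurement in its denominator
($TE = RF/mRNA$), so mRNA measurement noise pushes the
$RD_{mRNA}$–$RD_{TE}$ correlation negative even without any biology. The
package therefore also reports a split-replicate control: $RD_{mRNA}$ is
computed from one disjoint subset of mRNA replicates and the TE
denominator from the other, so no replicate contributes noise to both
axes. On simulations with no buffering and heavy count noise the naive
correlation is visibly negative while the split control is centred on
zero; with true buffering the split control stays negative. This control
is an addition beyond the headline analysis and is labelled as such in the
outputs.

## Duplicate classification

Tandem clusters require same family, at most 10 intervening genes, and at
most 100 kb on the same chromosome; both bounds are inclusive ("at most",
"within"). The intervening count is the number of representative gene
models whose start lies strictly between the two members' starts, and
distance is start-to-start — the counting basis is not fixed by the
published rule, so the simplest one is used and documented. Clusters are
maximal under single-linkage chaining of the pairwise relation (the
minimal reading of "clustered"); consecutive same-family genes realise
single linkage exactly because eligibility is monotone in genomic order.
Clusters larger than two contribute one uniformly chosen representative
pair, deterministic given the seed. Remaining genes are *other* duplicates
when their best non-self protein hit has E ≤ 1e-10 and *singletons* when
no non-self hit reaches E ≤ 1e-3; the gap (1e-10, 1e-3] fits neither
printed rule and becomes an explicit *unclassified* class excluded from
duplicate-versus-singleton contrasts. Isoforms are reduced to the longest
per gene, ties broken by smallest isoform id for determinism. Strand is
carried but ignored by the tandem rule. Gene pairs are ordered with the
lexicographically smaller id first unless a curated list fixes the order,
making every signed statistic reproducible.

## Sequence evolution: Ka/Ks and the clock test

Ka and Ks are estimated by Nei–Gojobori-style counting: per-codon
synonymous site fractions (mutations creating a stop codon are
disregarded in both numerator and denominator), site counts averaged over
the two sequences, multi-nucleotide codon differences averaged over all
minimal mutational pathways that avoid stop codons, and a Jukes–Cantor
multiple-hit correction $K = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$.
Proportions at or above 3/4 are saturated and yield `NA`. Columns
containing a gap, an ambiguous base or a stop codon are wholly excluded.
Triplets where the paralog–paralog Ka strictly exceeds either
paralog–outgroup Ka are discarded (the outgroup then cannot predate the
duplication).

Asymmetric evolution is tested on (paralog1, paralog2, outgroup) codon
alignments with a likelihood-ratio test under the Jukes–Cantor nucleotide
model on the 3-taxon star tree: the unconstrained model has three free
branch lengths, the clock model constrains the two paralog branches equal,
and $2\Delta \ln L$ is referred to $\chi^2_1$, with BH-FDR across triplets.
Under JC the site likelihood depends only on which leaves share a base, so
the five site-pattern classes are sufficient statistics and the
optimisation is effectively instantaneous. Branch lengths are maximised by
bounded quasi-Newton (L-BFGS-B, bounds $[10^{-9}, 10]$) from starts 0.01,
0.1 and 0.5 substitutions/site to avoid local optima near zero. This is a
deliberate methodological simplification relative to full ML codon models:
the test structure ($2\Delta\ln L \sim \chi^2_1$) is the same, the
substitution model is not, and results are labelled accordingly. The
faster-evolving copy is attributed by the larger paralog-to-outgroup Ka,
matching the triplet construction. When several outgroups are available
the first listed is used.

## Differential translational efficiency

Across two conditions, each gene's counts are modelled as negative
binomial with a log link, a log library-size offset and terms
`assay + condition + assay:condition`; the interaction coefficient is the
log TE change between conditions, and its LRT (deviance difference at
fixed dispersion) is referred to $\chi^2_1$, with BH-FDR flagging at
adjusted p < 0.05. This is a deliberately simple single-dispersion GLM in
the spirit of GLM-based differential-TE tools, not a numerical clone of
any of them.

Dispersion is estimated per gene by a df-weighted pooled method of moments
across assay-by-condition groups,
$\hat\phi = \sum_j (n_j-1)(s_j^2 - \bar m_j) \big/ \sum_j (n_j-1)\bar m_j^2$,
floored at the larger of 0.01 and the cohort-wide median of the raw
estimates. The cohort floor matters: with two or three replicates the
gene-wise moment estimate is extremely noisy, and its underestimates make
the interaction LRT sharply anti-conservative (empirical type-I error near
0.10 at a nominal 0.05 with three replicates). Flooring at the cohort
median — a crude form of sharing information across genes, in the same
spirit as taking the maximum of gene-wise and trended dispersions in
standard RNA-seq practice — restores calibration (empirical type-I error
0.04–0.05 across seeds) without empirical-Bayes machinery. For a single
gene the estimator reduces to the plain $(s^2-\bar m)/\bar m^2$.

Library-size offsets default to per-sample totals. When many genes shift
TE in one direction, data-driven totals absorb part of the shift into the
offsets (composition bias); the synthetic pipeline therefore passes the
generator's known equal depths, and analyses of real data with widespread
TE changes should prefer robust size factors. Per pair, flags are
summarised as *neither*, *either* or *both* copies differentially
translated, and duplicate-versus-singleton enrichment uses a 2×2
chi-squared test with continuity correction.

# The synthetic-data generator

The generator is first-class, tested code and defines the study
conditions. Per pair $i$:

$$\mu_i \sim N(\mu_0, \sigma_0^2),\quad d_i \sim N(0, \sigma_d^2),\quad
t_i = -\beta d_i + \epsilon_i,\ \epsilon_i \sim N(0, \sigma_t^2),$$

with mRNA FPKM split symmetrically as $2^{\mu_i \pm d_i/2}$ and TE as
$TE_0\, 2^{\pm t_i/2}$, so neither copy is privileged and the pair's total
abundance is independent of divergence direction. True RF FPKM is exactly
mRNA × TE. $\beta$ is the buffering coefficient: $\beta > 0$ makes TE
oppose transcriptional divergence, $\beta = 0$ decouples them. Replicate
counts are negative binomial with mean
$m = \mathrm{FPKM} \times L/10^3 \times N/10^6$ and
$\mathrm{Var} = m + \phi m^2$ ($\phi = 0$ degenerates to Poisson) — the
same parameterisation as the differential-TE GLM. Defaults are
$\beta = 0.5$, $\sigma_d = 1$, $\sigma_t = 0.3$, $\mu_0 = 4$,
$\sigma_0 = 2$ (a wide bulk-expression spread in log2 FPKM), three
replicates, $\phi = 0.1$ (typical bulk RNA-seq biological variability),
library depth $2\times10^7$ and effective length 1500 bp — values a
practitioner would call realistic for plant bulk data; the published
analyses report no generative noise model, so the NB structure is an
explicit assumption of the harness. Each operation consumes one RNG stream
seeded explicitly, so all fixtures are bit-reproducible.

Annotation fixtures plant tandem clusters with exact control of the
intervening-gene count, the start-to-start span and chromosome sharing
(for clusters above two members the geometry applies per adjacent pair),
so the clustering rules can be checked against planted truth including
both boundary cases. Codon triplets evolve a uniformly drawn sense-codon
root along three branches under Jukes–Cantor; leaf codons that become
stops are re-evolved along the same branch. That resampling removes a
little substitution mass — measured as a 2–4% downward bias on branch
lengths around 0.2–0.5 substitutions/site — which is why the
branch-recovery check averages several long alignments and why branch
lengths in that range are used.

What the generator does *not* emulate: positional footprint profiles,
isoform structure, mapping artifacts, GC- or length-dependent biases,
correlated noise between assays, and real gene-family structure. Passing
tests therefore validate the statistical machinery and its calibration,
not the biology of any particular dataset.

# Numerical choices and degenerate inputs

- Optimiser tolerance: L-BFGS-B with `factr = 1e2` (about $10^{-14}$
  relative on lnL, effectively 1e-8 absolute at these magnitudes);
  non-convergence flags the triplet rather than failing the run.
- $2\Delta\ln L$ is floored at 0 (nested models; tiny negative values can
  arise from optimiser tolerance).
- GLM fits: IRLS with `epsilon = 1e-8`, 100 iterations maximum;
  non-converged or separated genes are reported untested rather than
  given a p-value.
- Zero-sum pairs give `NA` relative divergence; zero values give infinite
  fold differences and are flagged by the expression filter upstream.
- Identical sequences give $K_a/K_s = 0/0$, reported `NA` with the
  saturation flag unset; saturated proportions ($\ge 3/4$) give `NA` with
  the flag set.
- All randomness in the pipeline flows from a single configured seed with
  fixed per-stage offsets; reports are written with deterministic JSON
  formatting so identical runs are byte-identical.

# Problem sizes

The bundled end-to-end fixture runs 400 pairs plus 150 singletons, three
replicates, two conditions, and 120 triplets of 300 codons — a scale at
which a full run takes well under a minute on one core while every
downstream contingency stays populated. Calibration checks use 500
clock-like triplets (type I error of the clock LRT), cohorts of 2000 pairs
(buffering recovery), and 2000-gene null simulations (differential-TE type
I error); branch-length recovery uses five alignments of $10^4$ codons.

# Known limitations

- The Jukes–Cantor clock test is a stand-in for codon-model ML; absolute
  lnL values are not comparable to codon-model outputs, only the test's
  structure and calibration are.
- NG86 counting underestimates rates under strong codon bias; no gamma
  rate variation is modelled.
- The per-gene GLM shares no information across genes beyond the
  dispersion floor; very low counts yield conservative `untested` flags.
- FPKM normalisation uses per-sample totals, which is exact for the
  generator but subject to composition bias on strongly asymmetric real
  libraries.
- The tandem rule needs externally supplied family ids; family inference
  is out of scope.
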