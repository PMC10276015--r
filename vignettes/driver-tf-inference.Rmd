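---
title: "Inferring driver transcription factors from multi-omics concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring driver transcription factors from multi-omics concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicdriver)
```

## The problem

A perturbation experiment -- here modeled after a two-condition in-vivo
design with a surgical treatment versus sham -- is profiled on many omics
layers at once: chromatin accessibility at promoters and distal elements,
transcript abundance at two timepoints, bulk and regional proteomes, and
phosphoproteomes. Each layer is reduced to one per-gene
log2(treatment/control) summary. The question the package answers is: *which
transcription factor's activity change drives the response?* The evidence it
assembles is (i) a coordinated shift of the TF's curated target genes
(regulon) relative to the rest of the measured genes, (ii) concordant
differential behavior of the same genes across many independent layers, and
(iii) chromatin corroboration -- motif enrichment in differentially
accessible peaks and a transposase-insertion footprint at the motif.

## The concordance score

For layer $j$ with observed log2 ratios $x_{gj}$, each gene gets a
standardized score

$$ z_{gj} = \frac{x_{gj} - \bar{x}_{\cdot j}}{s_{\cdot j}}, $$

with $\bar{x}_{\cdot j}$ and $s_{\cdot j}$ the mean and sample SD (denominator
$n-1$) over the genes observed in that layer. A gene is called differential
in layer $j$ when $|z_{gj}| > 1.96$ (strict), receiving a logical flag of 1,
otherwise 0; a gene missing from a layer contributes nothing. The
concordance score is the flag sum across layers, and a gene is *selected*
when its score strictly exceeds 3 -- with nine layers, differential in at
least four of them. Under independent null layers with flag rate 0.05, the
selection rate is the binomial tail $P(\mathrm{Bin}(9, 0.05) \ge 4) \approx
6.4\times10^{-4}$, which is the calibration the test suite checks.

Design notes on points the scheme leaves open:

* **Z-scoring direction.** Standardization is *within a layer, across
  genes* (each dataset normalized separately), not across layers per gene.
* **Sample SD** (not population SD) is used; at the gene counts involved the
  difference is negligible, but it is fixed and documented.
* **Direction-agnostic flags.** The published scheme flags $|z|$
  exceedances, discarding sign concordance; `zscore_binarize(mode =
  "signed")` is a clearly-marked extension that scores `|sum|` of signed
  flags instead.
* **Missingness.** Genes absent from a layer score 0 there. This biases
  against sparsely observed genes -- a gene seen in 4 layers can reach at
  most score 4 -- which mirrors the scheme as designed.

## Differential summarization

`differential_summary()` is a generic two-group engine: log2 ratio of group
mean abundances with a pseudocount (default 0.5), a two-sided Welch t-test
on log2-transformed replicates, and Benjamini-Hochberg adjustment over the
retained features. It deliberately is *not* a count-model engine; dispersion
shrinkage and count likelihoods are out of scope, and tables from DESeq2,
edgeR or DiffBind can be imported through the TSV schema instead. Layer
threshold presets mirror the usual printed cutoffs: transcripts at adjusted
p < 0.05 with |log2 ratio| > 0.5; proteomes at raw p < 0.1 with |log2
ratio| > 0.2 (a band chosen as a >99% null confidence interval for reporter
ratios); accessibility at an FDR-only cutoff, where both a 0.05 and a
stricter 0.01 variant are in circulation -- both ship
(`policy_atac_dar(fdr = )`), defaulting to 0.05. All threshold inequalities
are strict, so a feature sitting exactly on a cutoff is not flagged.

## Regulon activity and enrichment

`target_set_shift()` compares the distribution of a regulon's log2 ratios
against the non-target background (default) or against zero. The two-sample
default is the conservative reading of a per-set activity claim: a set can
drift from zero for global reasons (normalization, batch), while a shift
against the within-layer background is specifically attributable to the
set. The test is Student's pooled-variance t (as the convention for these
set comparisons), with Welch available. Intervals are reported as mean ±
1.96×SD of the target ratios -- an SD band, as printed in the convention
this follows, even though an SEM band would be the usual inferential choice;
`ci = "sem"` exists but is not the default. For expression layers, genes
with mean abundance (TPM) below 1 are excluded; accessibility layers are
analyzed unfiltered.

`preranked_enrichment()` implements the weighted Kolmogorov-Smirnov
running-sum statistic: on a list ranked by `sign(log2 ratio) ×
-log10(FDR)` (the ranking combines effect direction with FDR strength; the
exact published recipe is unstated beyond "based on the FDR and the log2
ratio", so the metric tag travels with the output), set members add
$|s|^p / \sum_{hits} |s|^p$ and non-members subtract $1/(N - N_h)$; the
enrichment score is the signed maximum deviation. The null is built from
size-matched random gene sets -- a gene-set permutation, chosen because only
summary tables (not per-sample phenotypes) exist at this pipeline stage --
with NES = ES / mean(|permuted ES| of the same sign) and the add-one
permutation p-value. With weight 0 the statistic reduces to the classic KS
walk; a closed-form consequence worth knowing is that a single member at the
bottom of the list yields ES exactly −1 (N−1 misses of 1/(N−1) each).

## Peak annotation

A promoter-TSS region is the window from 1,000 bp upstream to 100 bp
downstream of a TSS *in the gene's orientation*; for minus-strand genes the
genomic window is mirrored. "Within the window" is read as *overlap of at
least one base* -- the more inclusive of the two common conventions --
rather than midpoint containment. One peak annotates at most one gene
(smallest |distance to TSS|, then lexicographic gene id) to prevent double
counting in gene-level integration. Region precedence is promoter-TSS >
intronic > intergenic; intronic requires overlap of a gene body with no
exon overlap, so the rare peak overlapping only exonic, non-promoter
sequence falls to intergenic -- a deliberate simplification of the
three-class scheme. Signed distances are measured from the peak midpoint
(rounded toward the TSS when fractional), negative upstream.
`collapse_features_to_gene()` reduces peak- or site-level tables to gene
level; the default max-|log2| policy keeps the strongest feature per gene
with provenance, the `mean` alternative averages.

## Motifs and footprints

Motif scanning is consensus/IUPAC matching, not PWM log-odds scoring: a
motif is a degenerate-base word and a hit is an exact class match at every
position, scanned on both strands with minus-strand hits reported at
plus-strand coordinates. An `N` in the sequence matches only the motif
symbol `N`. PWM scoring is declared out of scope rather than
half-implemented. Motif-proportion enrichment compares the motif-carrying
fraction of all peaks versus the differentially accessible subset with a
one-sided hypergeometric tail (the same cumulative hypergeometric family
used by standard motif-enrichment tools), plus a 2×2 odds ratio with a
Haldane 0.5 correction only when a cell is zero. Footprint profiles average
per-base insertion counts across motif sites after reversing minus-strand
rows; the published normalization is not stated, so the profile carries its
`scale_factor` explicitly and defaults to raw means over a ±100 bp window.

## The synthetic study generator

`simulate_study()` emulates the *derived* structure of the multi-layer
design -- per-gene log2 ratio summaries over nine layers with replicate
matrices -- not raw reads or spectra. Its defaults are the package's study
conditions:

| parameter | default | rationale |
|---|---|---|
| genes | 2,000 | enough for stable layer z-scores at test cost |
| regulons | 10 × 50 targets, disjoint | curated-set sizes, no overlap confound |
| layers | 9 named layers | two ATAC, two RNA, three proteome, two phospho |
| replicates/group | 4 | small-animal group sizes |
| driver | TF01, δ = 1 log2 unit, 4 of 9 layers | an activated TF visible in expression, proteome and phosphoproteome |
| background DE | 5% of non-targets, ±1, per layer independently | makes concordance (not per-layer DE count) the driver signal |
| noise SD | 0.25 log2 units | replicate scatter typical of TPM-scale summaries |
| baseline | log2 abundance ~ N(6, 1.5) | expressed-gene TPM scale; keeps pseudocount shrinkage negligible so null flag rates stay at 5% |
| motif planting | 0.60 target / 0.28 background | background matches a typical all-peak motif proportion |
| footprint | depth 0.5, λ = 20, ±100 bp | a clear dip recoverable within Poisson error at a few hundred sites |

Noise is Gaussian on the log2 scale -- the simplest model consistent with
the pipeline's log2-ratio arithmetic. Background shifts are symmetric ±δ so
that per-layer differential counts alone cannot identify driver targets.
The genome fixture is one linear chromosome with equally pitched genes on
alternating strands and three exons each: enough geometry to exercise
strand-aware promoter logic and region classes, with no claim of genomic
realism. The two ATAC layers are keyed by peak id (promoter peaks in one,
intronic/intergenic in the other) and flow through annotation and collapse;
the remaining layers are gene-keyed.

What the generator does **not** emulate: residual inter-layer correlation
beyond shared planted effects (no correlation knob -- real layers share
biology and technical structure the generator cannot represent),
heavy-tailed abundance distributions, missingness patterns of proteomics,
batch effects, or realistic annotation. Passing recovery tests therefore
demonstrates the *machinery* is correct and calibrated, not that real
studies will behave as cleanly.

## Numerical choices and degenerate inputs

* Features with zero variance in both groups: p = 1 when the means agree,
  p = 0 otherwise (defined, not an error).
* Fewer than two usable regulon targets: a flagged result with `p = NA`
  and a warning, not an error.
* A layer with zero spread aborts z-scoring with the layer named; z-scores
  are undefined there and silently skipping would corrupt scores.
* Ties in ranked lists, driver ranking and peak-gene assignment always
  resolve deterministically (documented sort keys ending in lexicographic
  ids), so reruns are bit-identical.
* All generator randomness flows from one integer seed; component
  operations use fixed offsets from it so `simulate_regulons()` and the
  fixture agree whether called standalone or inside `simulate_study()`.

## Problem sizes used by the validation suite

The test suite checks null calibration on 100,000 simulated null genes
across nine layers, driver recovery and selection precision over 100 seeded
studies at the default configuration, oracle equality of the BH step-up on
all permutations of up to six p-values, of the enrichment walk on lists up
to 20 genes, of promoter assignment on 1,000 random peak/gene
configurations against a per-base oracle, and of hypergeometric tails
against direct enumeration at universe sizes up to 200. These sizes give
comfortable Monte-Carlo margins for every claim while keeping a full run in
a few minutes.

## Known limitations

* The Welch stand-in engine will not reproduce count-model results on real
  count data; import real engine output via the TSV schema instead.
* Consensus motif scanning has no notion of binding affinity; motifs with
  substantial information-content gradients are poorly represented.
* One-peak-one-gene annotation ignores enhancer-promoter interactions
  beyond nearest-TSS logic.
* Permutation NES values at small permutation counts are noisy; the
  defaults (1,000) are a floor, not a recommendation, for publication use.
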