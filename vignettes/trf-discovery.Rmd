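---
title: "Discovering a tRNA-derived fragment and tracing its regulatory footprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering a tRNA-derived fragment and tracing its regulatory footprint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(trfscan)
library(dplyr)
```

## The analysis this package implements

Small-RNA sequencing of skin tissue from coarse- and fine-wool lambs shows,
besides the canonical ~22 nt microRNA peak, a second read-length peak at
32 nt that is far taller in the coarse-wool group. One sequence makes up
more than 90% of the coarse 32 nt reads; it maps exactly to 15 genomic
copies of the glycine tRNA genes TRNAG-CCC/TRNAG-GCC, always anchored at
the gene's 5' end — a 5' tRNA half, reported in the field's shorthand
simply as a tRF. The fragment is ~5.8-fold higher in coarse-wool skin by
qPCR while the intact glycine tRNA runs ~6.3-fold higher in fine-wool
skin, suggesting two competing fates for the same tRNA: amino-acid
transport (fine) versus processing into a regulatory fragment (coarse).
Downstream, the fragment's predicted targets overlap about half of the
proteins down-regulated in coarse-wool skin, and a chemometric screen of
the metabolome (Pareto scaling, PLS-DA, VIP > 1 then a t-test) picks out
glutathione- and oxidative-stress-related metabolites.

`trfscan` re-implements that discovery pipeline as reusable, tested
components:

1. **read_spectrum** — FASTQ loading, the 18–41 nt length filter,
   per-sample length spectra in reads per million (RPM), anomalous-peak
   detection between groups, and decomposition of a peak into its unique
   sequences;
2. **trf_annotation** — exact genomic placement of a candidate sequence on
   both strands, strand-aware intersection with tRNA gene loci, and
   fragment classification (tRF-5 / tRF-3 / tRF-1 / halves / internal /
   full-length);
3. **differential** — exact-sequence count matrices, Welch t-tests on RPM,
   and 2^-ddCt relative quantification for qPCR;
4. **target_prediction** — a seed-weighted, affine-gap local duplex
   aligner scanned across 3'UTRs;
5. **omics_integration** — DEP calling (fold 1.20/0.83 with p < 0.05),
   target-versus-down-DEP overlap under a hypergeometric model, and
   gene-set over-representation with BH correction;
6. **metabolomics** — prevalence filtering, total-intensity
   normalisation, Pareto scaling, PCA with QC assessment, NIPALS PLS-DA
   with VIP, and the VIP > 1 & p < 0.05 screen;
7. a **synthetic-data generator** that reproduces the statistical
   structure of the study so every stage is testable offline, plus a
   manifest-driven **pipeline** (`run_pipeline()`).

Raw sequencing from the original study is deposited publicly, but nothing
here downloads it: the generator is a first-class module and the package's
tests run on generated data alone.

## The synthetic study

`sim_config()` fixes the conditions every generator emulates. The defaults
are the study's printed values where printed, and one-time choices
documented here where not.

```{r}
cfg <- sim_config(seed = 1, read_depth = 20000)
cfg
```

**What the motivating study pins down.** A 71 nt tRNA gene in 15 genomic copies on
both strands (`trna_gene_length`, `trna_copies`); a 32 nt 5'-anchored
fragment (`fragment_length`); a coarse/fine fragment fold of 5.77
(`trf_fold`) and a fine/coarse intact-tRNA fold of 6.28 (`trna_fold`);
a dominant sequence carrying 90% of the fragment component in coarse
(`dominant_fraction_coarse`); three sequenced samples per group in the
small-RNA arm (`n_per_group = 3`); ten per group in the omics arms (set
per analysis); pooled QC injections in the metabolome; the 18–41 nt
retention window.

**What had to be chosen.** The read-length background is uniform over
18–41 nt — the simplest null that still makes peak detection non-trivial.
Mixture weights (`mirna_weight = 0.28`, `trf_weight = 0.35` in coarse)
were set once so that the coarse 32 nt sub-peak rivals the canonical miRNA
peak, as in the study's histograms, and so that the dominant sequence
keeps ≥ 85% of *all* 32 nt reads after the uniform background dilutes the
fragment component. The fine group's dominant fraction (0.55) is not
printed in the study (only "significantly higher" in coarse); 0.55 leaves
the fine-group pie visibly mixed. The fine group's fragment weight is
`trf_weight / trf_fold` and the lost mass goes to background, so the
expected coarse/fine ratio of fragment reads is exactly `trf_fold` by
construction. Per-sample depth, protein/metabolite counts and noise
scales are desk-scale defaults (1e5 reads, 500 proteins at residual
log2-sd 0.25, 120 metabolites at log-sd 0.3) — the study reports none of
them.

Every generator is deterministic given `seed` (each draws from its own
seed stream so call order does not matter), and every generator emits its
ground truth separately; truth files are named `truth_*` and no pipeline
stage reads them — a contract asserted in the tests.

## Worked example: from reads to an annotated fragment

```{r}
toy <- simulate_genome(cfg)
rs  <- simulate_reads(toy, cfg)

reads <- filter_by_length(rs$reads)          # closed [18, 41] window
sp    <- length_spectrum(reads)
calls <- detect_anomalous_peaks(sp, group_order = c("coarse", "fine"))
calls
```

The detector formalises what the study did by eye. A length outside the
canonical miRNA window (20–24 nt) is called when it is (a) a local maximum
of a group's mean-RPM spectrum, (b) at least `min_ratio = 0.25` of that
group's canonical peak height, and (c) significantly different between
groups — a two-sided Welch t-test on per-sample RPM with `p < alpha` and a
fold of at least `min_fold = 2` in either direction. The source analysis never
defines "peak"; these three gates are the package's operationalisation,
and each is a plain parameter. No multiple-testing correction is applied
across lengths by default, mirroring the single-test usage in the source
analysis (`p_adjust = "BH"` is available). Rows where both groups have
zero variance and equal means get `p = 1`, so constant spectra can never
fire. With 24 candidate lengths and three gates, the empirical
false-positive rate at null is far below the nominal alpha (the package's
checks observe zero calls across 100 null simulations at depth 1e5).

```{r}
comp <- decompose_peak(reads, calls$length[1])
comp %>% filter(scope != "pooled", rank <= 2)
```

Decomposition collapses reads of exactly the peak length to unique
sequences per group and pooled; fractions sum to 1, ties in counts break
lexicographically, and reads containing `N` are dropped (they cannot be
genome-matched exactly). The dominant fraction here is the share of *all*
32 nt reads, i.e. the planted 0.90 within-component fraction diluted by
uniform background at that length.

```{r}
ann <- annotate_fragment(comp$sequence[comp$scope == "pooled"][1],
                         toy$genome, toy$loci)
count(ann, fragment_class, reported_label)
```

`match_genome()` (Biostrings exact matching behind the interface) reports
minus-strand hits in forward-reference coordinates; `intersect_trna()`
pairs a hit with a locus when it lies within the gene or within 50 nt
downstream of its 3' end (the tRF-1 trailer zone), strand-aware, and
computes the 5' offset with 0 at the gene's 5' end — for a minus-strand
gene that is its *higher* genomic coordinate. Classification uses an
offset/length rule table: 5'-anchored (offset ≤ 1) fragments under 30 nt
are tRF-5 and 30–40 nt are 5' halves; the mirror rules at the 3' end give
tRF-3 / half-3; trailer starts give tRF-1; everything else is internal or
full-length. The ±1 anchor tolerance, the 30–40 half window and the 50 nt
trailer are package choices — the source text names the classes but no
thresholds. A 32 nt fragment of a 71 nt gene is precisely a `half-5`, but
because such molecules are reported as "tRFs" in this literature both the
precise class and the reported label are emitted.

All coordinates everywhere are 1-based fully closed (a 71 nt gene has
`end - start + 1 = 71`), matching printed tRNA gene tables. This is *not*
UCSC BED; `read_loci(..., bed_zero_based = TRUE)` converts on the way in.

## Quantification and qPCR

`build_count_matrix()` counts reads exactly equal to each target sequence
— at desk scale this replaces aligner-plus-featureCounts quantification
and is checked against a brute-force tally. `group_ttest()` normalises to
RPM and applies a Welch test per sequence (the source says only
"t-test"; unequal-variance is the robust default and `var_equal = TRUE`
gives Student's). Fold direction is configuration (`group_order`), not
hard-coded. `ddct()` implements 2^-ddCt with the reference gene as a
column, honouring the study's use of different references for the
fragment (U6) and tRNA (beta-actin) assays.

Recovery behaviour at the study's reference scenario (fold 5.77, depth
1e5, n = 10 per group) is exercised in the acceptance checks: the
fragment-component fold is recovered within ±20% and the qPCR fold within
±15% at Ct noise sd 0.1. Note the *component* fold is what equals 5.77;
the dominant sequence alone runs higher because the dominant fraction also
differs between groups.

## Target prediction

`align_duplex()` is a local (Smith–Waterman-style) alignment of the small
RNA, read 5'→3', against the reverse of a UTR window, so antiparallel
hybridisation is colinear. Watson–Crick pairs score +5, G:U wobbles +2,
mismatches −3, gaps are affine at −9/−4 (Gotoh three-state recursion), and
substitution scores at small-RNA positions 2–8 are multiplied by 4 — the
conventional seed weighting, kept at positions 2–8 even for a 32 nt query
because the fragment is modelled as acting like a miRNA. A 20 nt query
against its perfect complement therefore scores
5·13 + 5·4·7 = 205. Scores are verified against an independent
brute-force dynamic program that charges explicit gap-run costs with no
Gotoh state machine.

Two symmetry notes. The physical duplex is unchanged when the two strands
swap roles or when both are read in the opposite direction, and the score
respects both (under a flat seed weighting, which position-dependent
scaling necessarily breaks). A literal joint reverse-complement is *not*
a symmetry once wobble is scored: complementing a G:U pair yields C:A,
which does not pair — that asymmetry is chemistry, not a bug.

`scan_targets()` slides a window of width fragment-length + 15 at step 5,
merges overlapping hits keeping the best score, and calls a gene a target
if any site survives two gates: the published score threshold of 140, and
a stability proxy ≥ 0.7. The proxy replaces the thermodynamic free-energy
term of the original tool with a hydrogen-bond-weighted paired fraction
(G:C = 1, A:U = 0.65, G:U = 0.35, averaged over the query length). Its
threshold was calibrated once on shuffled-sequence nulls: random UTRs
that sneak past the score gate reach stabilities of ~0.45–0.69, while a
perfect complementary site sits at ~0.75–0.85 for any plausible GC
content. Raising either threshold can only shrink the hit set (a tested
monotonicity property).

## Proteome integration

`call_deps()` computes the linear-scale fold (coarse over fine by
default), tests on log2 abundances, and gates at fold > 1.20 or < 0.83
with p < 0.05 — the published cutoffs, nearly symmetric on the log scale.
`overlap_targets_deps()` intersects predicted targets with down-regulated
DEPs and attaches the hypergeometric upper-tail enrichment p-value; with
the study's printed 606 overlapping genes out of 1157 down-regulated
DEPs it reproduces 52.38%. `ora()` is the generic over-representation
replacement for the web-tool enrichment step: one-sided hypergeometric p
per user-supplied gene set (GMT), BH-adjusted. The overlap/ORA universe
defaults to all quantified proteins; the source never names its universe,
so the universe is always an explicit argument.

## Metabolomics

The chemometric chain is fixed in this order, and an integration test
asserts the order: prevalence filter (keep a metabolite iff strictly more
than 50% nonzero in at least one biological group; QC samples do not
vote; missing values are zeros) → total-intensity normalisation (columns
scaled to the median column total, so a uniformly doubled sample maps
back exactly) → Pareto scaling ((x − mean)/sqrt(sd); constant rows scale
to zero with a warning) → PCA / PLS-DA → the VIP > 1 then t-test screen.

PCA is the singular value decomposition of the scaled matrix with a
deterministic sign convention (largest-magnitude loading positive); at
full rank it reconstructs the input to machine precision, and on
simulated data the pooled-QC samples cluster tighter than the groups
separate — the study's quality check.

The discriminant step is implemented as standard NIPALS PLS-DA with a
single centred ±1 response and the usual VIP statistic,
`VIP_j = sqrt(p · Σ_a SSY_a (w_aj/‖w_a‖)² / Σ_a SSY_a)`, whose squared
values average to exactly 1 (enforced, and an identity in the tests).
The orthogonal-filtering variant of the original software is deliberately
not implemented: with one binary response the VIP ranking that the screen
consumes coincides for this purpose, and only the VIP > 1 gate feeds the
downstream screen. Model-validation machinery (seven-fold
cross-validation, response permutation) is likewise out of scope, though
`plsda_vip_permute()` ships for null calibration.

Two properties of this screen are worth stating because they shaped the
generator's planted scenario. First, the screen double-dips: VIP and the
subsequent t-test both measure association with the group label, so
null metabolites that pass the VIP gate carry inflated type-I error, and
the screen's false-discovery proportion is only controlled when genuine
discriminators dominate the called set. Second, Pareto scaling retains a
sqrt(sd) magnitude weight, so a discriminator far below average abundance
is structurally invisible to VIP no matter how large its fold change.
The generator therefore plants a sizeable block of strong discriminators
(18 of 120 metabolites at a log-shift of 2, i.e. linear folds around 7)
drawn from the detectable upper abundance range — the situation the
source study's top-differential heatmap depicts. Under those conditions
the screen recovers essentially all planted discriminators with a
false-discovery proportion of a few percent; under sparse or
low-abundance planting it degrades exactly as the two properties above
predict, and users should expect that on real data.

## The pipeline

`run_pipeline(pipeline_config(seed = 1), outdir)` chains the stages
`simulate → spectrum → decompose → annotate → diff → targets → proteome →
integrate → metabolome → report`, writing TSV/JSON between stages plus a
manifest per stage with the configuration hash and input/output MD5s; a
rerun with unchanged hashes is a no-op unless forced. The report stage
aggregates peak calls, the dominant sequence and its per-group fractions,
fragment classes, fold changes, qPCR relative expression, the
target/DEP overlap and the significant metabolites into one JSON file.
Configurations validate strictly (unknown keys error) and can be read
from YAML. The target-scan stage uses the `utr_count` (default 40)
synthetic UTRs, half of them carrying planted sites, which keeps a full
run near a minute at the default depths.

## Numerical choices and degenerate inputs

* Welch–Satterthwaite tests fall back to `p = 1` for zero-variance
  equal-mean rows and `p = 0` (infinite t) for zero-variance unequal
  means; folds with a zero denominator are flagged `Inf`, not dropped
  silently.
* RPM normalisation of an empty sample is defined as all-zero with
  `total_retained = 0` as the flag.
* Alignment tie-breaks prefer the diagonal (fewer gaps) and, among equal
  scores, the smaller UTR start; tRNA-locus ties resolve to the smallest
  5' offset.
* `pca_scores()` reduces `k` with a warning beyond the centred-rank bound
  `min(n − 1, p)`.
* Sequence alphabets are validated everywhere; `U` is accepted and mapped
  to `T` at the boundary.

## Problem sizes used by the checks

The packaged verification uses read depths of 1e5 (3 or 10 samples per
group), 100-seed null studies at the spectrum level (the peak detector
consumes only spectra, so nulls are drawn from the generator's exact
length-mixture marginal rather than materialised reads), 50-seed
metabolome recoveries, 1e4-row null matrices for t-test calibration, 500
random pairs for the aligner oracle and every hypergeometric
configuration up to a universe of 25. These sizes were chosen so the full
suite stays in the minutes range on a laptop while keeping Monte-Carlo
error well inside the tested tolerances.

## Known limitations

* The generator has no sequencing-error or adapter model, no
  heteroscedastic proteome option turned on by default, and its uniform
  length background is deliberately simplistic; passing tests show the
  *methods* behave as specified, not that real skin small-RNA libraries
  look like the simulation.
* Exact matching is the default for genomic placement (the fragment is a
  perfect tRNA prefix in the study); `max_mismatch` exists for the
  polymorphism case but hit semantics with mismatches are only as good as
  Biostrings' mismatch counting.
* The duplex stability proxy is not a thermodynamic energy; its
  calibration is empirical.
* PLS-DA VIP here is the plain (not orthogonalised) variant; VIP values
  for individual metabolites can differ from OPLS-DA software even though
  the VIP > 1 screen behaves equivalently for two-class problems.
* The ORA replaces curated pathway databases with user-supplied sets; no
  annotation ships with the package.
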