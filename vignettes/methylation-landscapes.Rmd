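---
title: "Methylation landscapes of drug-metabolizing enzyme genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation landscapes of drug-metabolizing enzyme genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methscape)
```

# The analysis

methscape analyzes per-CpG DNA methylation (array beta values, the fraction
methylated in `[0,1]`) over a curated panel of drug-metabolizing enzyme (DME)
genes — cytochrome P450s and the phase II conjugation families GST, NAT,
SULT, and UGT — and classifies each gene by its methylation landscape:

* **HVM** (highly variable methylation): the gene's promoter methylation
  differs substantially between individuals *and* tracks expression
  inversely. These are candidates for explaining inter-individual variation
  in drug metabolism.
* **TSG** (tumor-suppressor-like): stable promoter methylation across normal
  livers, but promoter hypermethylation in hepatoma cell lines that is
  relieved (with expression re-activation) by a demethylating agent.
* **HKG** (housekeeping-like): rigidly hypomethylated promoter, methylated
  gene body, and expression as stable as the classical housekeeping genes.
* **UNCLASSIFIED**: none of the above patterns.

## The variability statistic

For each CpG site, the cohort of normal livers is summarized by box
statistics (min, quartiles, max) and the inter-individual range

$$\beta_R = \beta_{\max} - \beta_{\min},$$

computed across the cohort. A gene's variability score is the **maximum**
beta_R over the CpGs of its 5' regulatory region (the array annotation
groups TSS1500, TSS200, and 5'UTR). The maximum — rather than a region
average — is used deliberately: regulation can be confined to one or a few
CpG sites, and averaging would dilute exactly the signal of interest.

The HVM calling threshold is not a fixed constant. It is derived from eight
control genes (housekeeping: ACTB, B2M, GAPDH, TBP; tumor suppressor: BMP4,
IGFBP3; DNA repair: MLH1, MGMT) whose promoter methylation is expected to be
tightly regulated: the threshold is the **largest** max-beta_R among the
controls, and a panel gene is flagged only when it is **strictly** more
variable than every control. On the original 20-liver cohort this
construction yields a threshold of 0.296; on synthetic data it reproduces
whatever spread the generator plants in its control genes.

Quartiles and percentiles throughout the package use the type-7
(linear-interpolation) convention, R's default; the box statistics of a
published figure do not pin down the convention, so we fix and document one.

## Methylation–expression correlation

Expression arrays are normalized per sample by the 75th percentile, then
optionally expressed as percent of a reference gene (ACTB = 100%). For each
5' regulatory CpG of a gene, Spearman's rank correlation is computed between
the CpG's beta values and the gene's expression across the matched samples.
`spearman_rho_p()` uses average ranks (Pearson on ranks under ties) and the
two-sided t-approximation with n−2 degrees of freedom; at |rho| = 1 the
p-value is floored at the smallest representable positive double and
flagged. A CpG is *inverse significant* when rho < 0 and p < alpha (0.05);
a gene is inverse-correlated when at least one of its 5' CpGs is.

Two-sidedness is a design choice: the significance convention behind an
"inverse correlation at p < 0.05" could equally be read as one-sided, so the
one-sided variant is available (`one_sided_correlation = TRUE`) but off by
default. No multiple-testing correction is applied — the gene-level call is
deliberately sensitive, mirroring exploratory practice — and the run summary
reports the number of tests so users can correct downstream. Note the
consequence, visible in the null-calibration tests: under independence the
per-probe inverse-call rate is alpha/2 (the sign restriction halves the
two-sided rate), and a gene with k probes has roughly k·alpha/2 odds of a
spurious inverse call.

Expression stability is measured by the coefficient of variation
CV% = 100·sd/mean (sample sd). Its threshold is again data-derived: the
largest CV among the housekeeping expression controls (17.1% on the
original transcriptome cohort).

## Tumor hypermethylation and demethylation response

A CpG is called hypermethylated in a hepatoma line when
beta(line) − beta(normal reference) **> 0.5** (strict), hypomethylated when
below −0.5. The published criterion — "a beta value of more than 0.5 for
comparisons between cell lines and normal liver" — is ambiguous between a
difference and an absolute level; we implement the difference reading as the
default (`tumor_call_mode = "difference"`) because it is the only reading
under which the phrase "for comparisons" does work, and expose the
absolute-level rule (`beta_cell > 0.5` and `beta_ref <= 0.5`) as
`tumor_call_mode = "absolute"`.

The demethylation response of a gene in a line is the maximum
treated/control expression ratio over the treated conditions, responsive
when **strictly** greater than 2. Conditions containing only a histone
deacetylase inhibitor (TSA) are excluded by default — HDAC inhibition is not
a demethylation readout — but can be included (`include_tsa = TRUE`).

A gene is called *regulated by DNA methylation* only when some **single**
cell line shows both the 5' hypermethylation and the expression response;
hyper in one line plus response in another is not accepted, because the
causal claim is per cell line.

## Landscape classification

With theta_var (control-derived variability threshold) and theta_cv
(housekeeping CV threshold):

1. **HVM** — max beta_R > theta_var AND inverse-correlated;
2. else **TSG** — max beta_R <= theta_var AND some line is hyper *and*
   responsive;
3. else **HKG** — max beta_R <= theta_var AND every 5' median beta <= 0.3
   AND at least one gene-body median beta >= 0.7 AND CV <= theta_cv;
4. else **UNCLASSIFIED**.

Precedence HVM > TSG > HKG is a package decision: the TSG and HKG rules
presuppose a stable normal cohort, which is exactly what a gene above
theta_var lacks, so instability is evaluated first. The HKG beta cutoffs 0.3
and 0.7 operationalize "hypomethylated 5'UTR / hypermethylated gene body",
which the source analysis left qualitative; both are configuration knobs
(`hkg_low_beta`, `hkg_high_body_beta`). Missing evidence never satisfies a
rule (fail-closed) and is recorded in the per-gene rule trace. The TSG label
describes a methylation pattern, not a claim of tumor-suppressor function.

## Shared-locus isoform analysis

UGT1A-type loci encode isoforms with private first exons spliced onto shared
downstream exons. Each isoform is classed hepatic or intestinal by dominant
mean expression, with explicit (never silent) per-isoform overrides — the
curated exception being UGT1A8, which shows higher liver signal yet is
biologically intestinal. For each isoform, the CpGs of its transcript in
TSS200/5'UTR/first-exon groups are retained (TSS1500 excluded as too
distal), and the most TSS-proximal probe's beta values in the 18-liver
cohort are tested against the single reference-tissue value with a
**one-sample Wilcoxon signed-rank test**: exact two-sided p from the full
2^n signed-rank distribution (computed by convolution, identical to explicit
enumeration) for n <= 25, with average ranks for tied absolute differences
and zero differences dropped; a tie-corrected normal approximation with
continuity correction above. An isoform is *concordant* when the
non-dominant tissue is significantly more methylated at its first exon
(hepatic: intestine high; intestinal: liver high).

Treating the single reference beta as fixed is a real limitation: the
reference is itself one noisy draw, and comparing a cohort against one
random draw from the same distribution inflates the false-positive rate to
about 2/(n+1) by exchangeability, regardless of the test. The package's
null-calibration tests therefore evaluate the test against a fixed center,
and reports based on a single reference tissue sample should be read as
descriptive, not population inference. The fetal-liver comparison reuses the
same machinery with the NLF sample as reference.

# The synthetic-data generator

`generate_cohort()` emulates the study conditions every other module
assumes: 20 normal livers (10 with matched expression arrays), one normal
reference liver, and 3 hepatoma lines; a panel of 30 genes — 5 planted per
landscape class plus 15 background genes — and the 8 control genes. Defaults
(all `simulation_config()` arguments):

* Beta values are drawn from beta distributions so bounds hold **by
  construction** — a probe with mean mu gets per-sample draws from
  Beta(mu·k, (1−mu)·k) with concentration k = 500 (technical sd about 0.013
  at mu = 0.1, a realistic array noise level).
* Probe-level baselines: 5' CpGs from Beta(2,18) (mean 0.1, hypomethylated
  promoters), gene-body CpGs from Beta(9,3) (mean 0.75, methylated bodies).
* Every probe also carries an *inter-individual* spread: per-sample means
  uniform within a window of width up to 0.15 (`stable_range_max`). Control
  genes carry the **largest** uninteresting spread — one designated control
  spans exactly `control_range_anchor` = 0.25, so the derived threshold
  lands near 0.25. This mirrors the real data, where the control maximum
  (0.296) is far above technical noise, and it is what makes
  threshold-based recovery well-posed: were controls and background drawn
  from one distribution, the background maximum over 25 genes would exceed
  the control maximum over 8 by order statistics alone.
* Planted HVM genes: one TSS200 CpG whose per-sample means span exactly
  `hvm_range_effect` = 0.6 (evenly spaced, randomly assigned to samples);
  expression is log-linear in that CpG's beta with slope
  −`coupling_strength` = −5 plus log-normal noise (`noise_sd` = 0.1), i.e.
  about a 20-fold range over the planted beta range — of the order seen for
  strongly methylation-coupled DME genes.
* Planted TSG genes: stable low promoter (spread 0) in all normals; one
  line gains `tumor_delta` = 0.7 at that CpG, is transcriptionally silenced
  there, and responds to the demethylating agent with `dac_fold` = 4;
  non-planted fold changes are log-normal around 1 (sd 0.05 on the log
  scale), far from the 2-fold cutoff.
* Planted HKG genes: rigid landscape (5' means in 0.05–0.15 and body means
  in 0.80–0.90 with zero spread) and near-constant expression (log-sd
  0.005 versus 0.02 for the housekeeping controls).
* Raw expression carries a per-sample scale factor (log-sd 0.15) on top of
  a dense block of 600 stable filler transcripts with a fixed profile. The
  fillers stand in for the rest of the transcriptome: they make each
  sample's 75th percentile an estimate from many stable genes, so the
  normalization removes the scale factor, as on a real array. With only the
  ~34 panel genes, the column quantile itself would inject shared noise of
  the order of the planted biology.
* One master seed; every gene draws from a deterministically derived child
  seed, so adding a planted class does not perturb other genes' values.

`generate_isoform_locus()` plants 5 hepatic and 4 intestinal isoforms
(cohort n = 18 plus single NSI and NLF samples); first-exon methylation is
low (0.1) in the dominant tissue and high (0.8) in the other, with the fetal
liver intermediate for hepatic isoforms. "Discordant" isoforms carry the
*opposite* methylation pattern for their expression class — a deterministic
anti-pattern, recovered as non-concordant at every seed — rather than a null
pattern, whose detection would be a coin flip at the significance boundary.

## What passing the synthetic tests does and does not show

The generator produces clean margins by design: planted effects (0.6 range,
0.7 delta-beta, 4-fold response) sit far from the derived thresholds, so
exact recovery across seeds demonstrates the *pipeline logic* — thresholds
derived from the right genes, strict inequalities, same-line conjunction,
precedence, probe-region filters — not statistical power at realistic effect
sizes. Real 450K cohorts add probe cross-hybridization, SNP-affected probes,
cell-type composition, batch structure, and copy-number effects in tumor
lines, none of which are simulated; beta_R on small effects near the
threshold will not reproduce with this reliability on real data.

# Numerical and degenerate-input conventions

* Missing beta values are kept missing and dropped pairwise; never imputed.
  A probe needs >= 2 usable values to be summarized; a correlation needs
  >= `min_pairs_for_correlation` (default 5) complete pairs.
* Ties in the gene-level argmax beta_R go to the 5'-most probe.
* All threshold comparisons for *calling* (HVM, hyper/hypo, responsive) are
  strict; the HKG pattern bounds are inclusive.
* Constant vectors make rank correlation undefined (flagged degenerate, not
  an error); an expression mean of zero makes the CV undefined (flagged).
* A zero 75th percentile or a missing/zero reference gene is an error
  naming the offending samples.
* Probe order within a gene follows genomic position, ascending for plus-
  and descending for minus-strand genes (strand from the panel config, not
  manifest row order); multi-gene probes are scored under every annotated
  gene.
* Exact signed-rank enumeration is used up to n = 25 (the convolution is
  O(n^3) in doubled-rank units, exact in double precision up to 2^53).

# Problem sizes

The test suite and the acceptance script run the default conditions: 30
panel + 8 control genes x 10 probes x 24 samples per cohort, 20 seeds for
recovery, 2000 replicates for null calibration of the correlation test and
1000 for the signed-rank test, and 1000 random vectors for oracle
equivalence. These sizes give binomial standard errors below 0.5 percentage
points on the calibration rates while keeping a full run in well under a
minute; they are the package's chosen defaults, and all scale up through
`simulation_config()`.

# Known limitations

* Beta matrices are the input contract: no IDAT preprocessing, detection
  p-values, or normalization of raw methylation signal.
* No batch-effect correction and no multiple-testing correction (both
  deliberate mirror-the-source choices; counts of tests are reported).
* The single-reference Wilcoxon design is descriptive (see above).
* The HKG rule set is an explicit operationalization of a qualitative
  pattern; genes near the 0.3/0.7 beta cutoffs or the CV threshold are
  sensitive to those knobs.
* The packaged default panel reproduces the documented family sizes (55
  CYP; 17 GST + 10 NAT + 13 SULT + 22 UGT = 62 phase II); membership of the
  less-standard families is a curated plausible list, editable via
  `read_gene_panel()`.
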