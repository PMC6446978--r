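---
title: "Inferring an oxygen-responsive regulon: models, parameters, and design choices"
author: "fnrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring an oxygen-responsive regulon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnrscan)
```

# Scope

`fnrscan` reconstructs the regulon of an oxygen-sensing CRP/FNR-family
transcription factor from (i) a genome with gene annotations, (ii) a
short time series of gene-level RNA-seq counts spanning anaerobic and
microaerobic phases, and optionally (iii) RT-qPCR copy-number series for
validation and (iv) additional genomes with an orthology (gene-family)
mapping for conservation analysis. It does not assemble genomes, call
genes, align reads, or count them: counts and annotations are inputs.

# Normalization model

Counts are converted to log2 RPKM with an *effective* library size. In a
competitively mapped metatranscriptome only a fraction of the filtered
library derives from the target organism, so the per-sample library is

    N_eff = merged_filtered_reads * mapped_fraction

and

    log2RPKM(g, s) = log2( (count + pseudocount) * 1e9 / (length_bp(g) * N_eff(s)) )

This is the only reading of the four published normalization quantities
(total unmerged reads, merged reads after rRNA filtering, mapped
fraction, gene length) that yields units of "reads per kilobase per
million mapped-to-genome reads". The total unmerged read count does not
enter the per-value formula; it is carried as provenance metadata on the
expression matrix so cross-run comparisons can audit sequencing depth.
The pseudocount (default 1 read, configurable) keeps the logarithm
defined at zero counts; whether the original analysis used one is not
documented, so it is exposed rather than hidden.

Figures and downstream stages work with minimum-subtracted profiles
(delta log2 RPKM, `relative_to_min()`): each gene's minimum over the
cycle maps to exactly 0. The operation is idempotent and shift-invariant,
and Pearson correlation — used everywhere downstream — is invariant to
the subtraction, so operon calling on relative or absolute log2 values is
equivalent.

# Operon model

Adjacent genes are merged into one putative transcription unit when they
lie on the same contig and strand, the intergenic region between them is
at most 1,000 bp, and their expression profiles correlate at Pearson
r >= 0.7. Both thresholds are exposed in `operon_config()`.

Two interpretations of "co-expressed" are possible: correlation between
each gene and its predecessor (chaining), or among all members. The
chaining convention is the default — it is the common operon-prediction
choice and the published criteria do not distinguish them — and an
`all_pairs` strict mode is available behind a flag. Overlapping genes
(negative gap) satisfy the distance rule. An undefined correlation
(constant profile, or a missing profile) never merges, so degenerate
genes become singletons rather than poisoning a neighbour's operon.

The caller is a single left-to-right scan; a brute-force oracle in the
test suite re-derives every boundary decision independently and the two
agree on 100 random layouts.

# Promoters

The promoter of a gene (or of an operon, via its 5'-most member) is up to
300 bp of *strictly intergenic* sequence immediately upstream of the
annotated coding start, truncated at the nearest annotated feature on
either strand and at the contig edge; minus-strand promoters are
reverse-complemented so they read 5'->3' relative to the gene. The
annotated start stands in for the transcriptional start site, which is
not mapped in draft genomes. Genes whose upstream flank is entirely
covered by another feature get an empty promoter and are excluded from
scanning with a message — not an error, since overlapping annotations are
routine in draft assemblies. Coordinates in files are 1-based inclusive
(GFF3); the single conversion happens at the I/O boundary.

Promoters can be extracted per gene (the default, matching a scan of all
protein-coding sequences) or per operon leader; both modes use the same
function over different anchor sets.

# Motif discovery: ZOOPS EM

`discover_motif()` fits a zero-or-one-occurrence-per-sequence model: each
promoter carries at most one site; with prior probability gamma (the
occupancy) a site occurs at a position and strand chosen uniformly; the
site is emitted by the PWM and all other positions by a 0-order
background. The background is estimated once from the input and held
fixed, which makes the EM objective provably non-decreasing — the
per-iteration trace is retained and asserted in the tests. The M-step
adds a small Dirichlet pseudocount (0.5, apportioned by the background)
to every column; the trace therefore records the penalized objective,
the quantity MAP-EM guarantees monotone.

Two standard failure modes are addressed explicitly:

* **Restart variance.** Each of `n_restarts` (default 5) initializations
  seeds the PWM from a randomly chosen promoter window (0.9 on the
  observed base). The best final objective wins.
* **Phase shift.** EM reliably finds the motif *region* but often locks
  one to three columns off. After the restarts, the best model is
  re-seeded from copies of itself shifted by +/-1 and +/-2 columns
  (vacated columns filled with background) and re-run to convergence,
  iterating while the objective improves. The correctly phased model
  captures more informative columns and wins on likelihood.

The motif width default of 14 follows the canonical FNR box geometry
(TTGAT-N4-ATCAA); the width actually used by the original MEME analysis
is unreported, so the parameter is exposed (6–30) and the default is a
package choice, not a replication claim.

# Exact scanning p-values

A window's score is the log2 likelihood ratio summed over columns. For
the null distribution, each column's four scores are rounded to integers
at `granularity` steps per bit (default 1,000) and the distribution of
the total under the background is built by exact convolution across
columns — the same construction FIMO uses. The scanner computes each
window's integer score from the *same* rounded column table, so reported
p-values are exact for the discretized statistic; the only approximation
anywhere is the rounding, which perturbs a width-w score by at most
w/(2 * granularity) bits. Tests verify the distribution against exhaustive
enumeration of all 4^w windows for widths up to 6.

Scanning covers both strands (each window reported in promoter-relative
coordinates), skips windows containing ambiguous bases, reports all
overlapping hits, and applies no multiple-testing correction — matching
the raw p < 1e-5 convention of the source analysis. The p-value is
computed against a single-strand null (no doubling for the second
strand); this is documented behavior, not an option, because it matches
how the threshold was used. The default background for scanning is
estimated from the scanned promoter set; a uniform or explicit background
can be supplied.

# Conservation matrix

For each genome and gene family exactly one state holds: `absent` (no
member gene), `present_with_motif` (some member's promoter has a hit), or
`present_no_motif`. Orthology is an input mapping, never inferred. The
support filter keeps families with motifs in at least 4 genomes
(configurable), and `summarize_categories()` tallies retained families by
an externally supplied functional-category mapping (e.g. KEGG level III);
no database lookup is performed.

# Clustering and regulation signs

Regulated profiles are grouped by agglomerative clustering at distance
1 - Pearson (average linkage by default; complete and single exposed).
The number of clusters is user-supplied (`k`) or implied by a cut height
— the "six clusters" of the motivating analysis are an observed outcome,
not an algorithm parameter, so no automatic model selection is built in.
Constant profiles have undefined correlation and are set aside in a
dedicated flat cluster. Input order does not affect the partition.

Each cluster's mean relative profile is contrasted between oxygen
phases: `contrast = mean(low-oxygen timepoints) - mean(high-oxygen
timepoints)`. At or above the tolerance (default 0.5 delta log2 RPKM,
motivated by the flat-gene language used for norZ, where the maximum
delta log2 RPKM stayed below 1) the cluster is positively regulated
(FNR-activated: expression anti-correlates with oxygen); at or below the
negative tolerance it is negatively regulated; otherwise flat.

# RT-qPCR validation

Copy numbers are normalized by a reference gene (rpoN by convention, a
constitutively expressed sigma-54 factor), then by the series minimum.
The verdict formalizes the published narrative rules: if the fold change
(max/min) is below 2 the gene shows no significant change and the
correlation is reported but not judged; otherwise the profile is
validated iff the Pearson correlation between the log2 qPCR series and
the RNA-seq delta log2 RPKM profile exceeds 0.5. Correlation is computed
log-scale against log-scale, since those are the two profile shapes the
comparison plots. The verdict is invariant to multiplicative rescaling of
the copy numbers, so absolute quantification accuracy does not matter —
only profile shape and amplitude.

`amplicon_length()` uses the convention `reverse_end - forward_start`
(no +1): it is the arithmetic under which each primer's printed span
equals its length, and it reproduces five of the seven published amplicon
lengths exactly (nirS-1 164, norZ 375, nosZ 363, ccoN 124, ctaD 135).
The remaining two rows (narG: printed 91 vs computed 88; rpoN: printed
487 vs computed 458) are internally inconsistent in the source table;
`check_primer_table()` surfaces the mismatch and never silently corrects
it. The no-RT control check reports the mean CT difference between cDNA
and NRTC reactions with an advisory flag below 5 cycles (the motivating
data showed 10 cycles, i.e. negligible DNA contamination).

# The synthetic-data module

`synthetic_scenario()` encodes the emulated study design; its defaults
*are* the study conditions and are not tuned per run:

* **Genome**: 80 genes on one contig, GC-rich background (62.5% GC),
  operon sizes 1–4 (probabilities 0.55/0.2/0.15/0.1), within-operon gaps
  20–200 bp (inside the 1,000-bp rule), between-operon gaps 320–900 bp
  (so most leaders have a full 300-bp promoter), gene lengths
  600–1,500 bp.
* **Motif**: consensus `TTGATCGGGATCAA` (the FNR-box TTGAT/ATCAA
  half-sites), 1.8 bits/column target information content, planted in
  80% of regulon leader promoters at a uniform position and strand. Under
  the GC-rich background a C/G consensus column can carry at most
  log2(1/0.3125) ~ 1.68 bits; such columns are capped there.
* **Regulation**: 8 positively and 6 negatively regulated operons; six
  timepoints labelled (low, low, low, low, high, high) oxygen — two
  anaerobic samples plus four microaerobic samples of which the last two
  sit at elevated dissolved oxygen; regulated genes are induced 4-fold in
  their active phase.
* **Counts**: negative binomial (dispersion 0.02; 0 degenerates to
  Poisson) around mean proportional to expression x gene length x
  effective library size; per-sample library depths 5–20 M filtered reads
  with mapped fractions 0.48–0.50. Operon members share their operon's
  baseline temporal profile (s.d. 1 log2 unit) up to small lognormal
  jitter (0.05).
* **qPCR**: lognormal noise at 10% coefficient of variation around a
  profile proportional to truth, with a constant-truth reference series.

One deliberate stylization: the per-operon baseline temporal variation is
centered within each oxygen phase, so an *unregulated* operon has exactly
zero realized phase contrast. Uncentered random variation would leak
oxygen signal into unregulated genes purely by sampling noise over six
timepoints — i.e. it would make genes that are defined as non-responsive
respond. With centering, the induction term is the only source of phase
signal, which is precisely what "unregulated" means in this model.

What the generator does *not* emulate: read-level artifacts (mapping
bias, rRNA carry-over), multi-contig fragmentation, horizontal transfer
or paralogy (the family mapping is exact by construction), TSS offsets
from coding starts, condition-dependent motif affinity, and community
context. Passing tests on synthetic data therefore demonstrate
correctness of the inference machinery under the stated model, not
robustness to every artifact of real metatranscriptomes.

Every generator is a pure function of (scenario, seed); per-component
random streams (layout, sequence, planting, counts, qPCR) are derived
from the master seed so changing one knob does not reshuffle unrelated
outputs.

# Numerical and degenerate-input choices

* Score discretization: 1,000 steps/bit; the sole approximation in
  p-value computation (error <= width/2000 bits per window).
* PWM columns with a zero probability entry would give -Inf log-odds;
  the integer table caps them far below any attainable threshold so such
  windows can never pass.
* `pearson()` returns `NA` (never 0) for constant series; each caller
  documents its treatment (operon caller: no merge; clustering: flat
  cluster; validation: not validated).
* EM non-convergence within `max_iter` returns the best-so-far model
  with a warning flag rather than failing.
* Ties in hierarchical clustering are resolved deterministically by
  sorting items by identifier before building the distance matrix.
* `alpha = 1` thresholds degenerate to the minimum attainable score;
  alphas below the probability of the maximum score yield an empty hit
  set rather than an error.

# Problem sizes used in the automated checks

The test suite and the acceptance script run on deliberately small
instances: 20–80-gene genomes, 20-promoter motif sets, widths <= 6 for
exhaustive p-value enumeration, 100 random layouts for the operon oracle,
20 seeds for scanner sensitivity and end-to-end sign recovery, and 5
seeds for EM recovery. These sizes were chosen as the smallest at which
each property is statistically meaningful; all scale linearly if larger
instances are wanted.

# Known limitations

* The EM is a functional ZOOPS implementation, not a replication of
  MEME's output; with unreported original parameters, motif identity is
  validated against planted ground truth, not against the published
  logo.
* Exact p-values assume a 0-order background; higher-order backgrounds
  are out of scope.
* Operon calling uses expression and distance only; terminator signals
  and coverage continuity are not modelled.
* The pipeline's conservation stage requires an input orthology mapping;
  it will not detect family assignment errors.
* Cluster-count selection is the user's responsibility, by design.
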